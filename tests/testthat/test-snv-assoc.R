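toy_calls <- stats::setNames(rep(c(TRUE, FALSE), each = 3),
                             sprintf("S%d", 1:6))

test_that("burden counts individuals once per gene and class", {
  mut <- data.frame(
    sample = c("S1", "S1", "S1", "S2", "S2", "S4"),
    gene = c("TP53", "TP53", "TP53", "TP53", "TP53", "TP53"),
    class = c("missense", "missense", "missense", "LOF", "missense",
              "synonymous"),
    stringsAsFactors = FALSE)
  bc <- burden_counts(mut, toy_calls)
  get <- function(cl, col) bc[bc$gene == "TP53" & bc$class == cl, col]
  expect_equal(get("missense", "n_chromo"), 2L)        # S1's 3 count once
  expect_equal(get("LOF", "n_chromo"), 1L)
  expect_equal(get("nonsynonymous", "n_chromo"), 2L)   # S1 union, S2 union
  expect_equal(get("synonymous", "n_nonchromo"), 1L)
  expect_equal(attr(bc, "n_chromo_total"), 3L)

  empty <- burden_counts(mut[0, ], toy_calls)
  expect_equal(nrow(empty), 0L)
})

test_that("class counts respect the union ordering invariant", {
  set.seed(14)
  n <- 40
  calls <- stats::setNames(rep(c(TRUE, FALSE), each = n / 2),
                           sprintf("P%02d", 1:n))
  mut <- data.frame(
    sample = sample(names(calls), 300, replace = TRUE),
    gene = sample(c("A", "B", "C"), 300, replace = TRUE),
    class = sample(c("LOF", "missense", "synonymous"), 300, replace = TRUE),
    stringsAsFactors = FALSE)
  bc <- burden_counts(mut, calls)
  for (g in unique(bc$gene)) {
    for (col in c("n_chromo", "n_nonchromo")) {
      v <- function(cl) bc[bc$gene == g & bc$class == cl, col]
      expect_gte(v("nonsynonymous"), max(v("LOF"), v("missense")))
      expect_lte(v("nonsynonymous"), v("LOF") + v("missense"))
      expect_lte(v("nonsynonymous"), if (col == "n_chromo") n / 2 else n / 2)
    }
  }
})

test_that("differential scan recovers a TP53-like driver", {
  counts <- data.frame(gene = c("TP53", "RARE", "FLAT"),
                       class = "nonsynonymous",
                       n_chromo = c(127L, 1L, 40L),
                       n_nonchromo = c(51L, 0L, 75L),
                       stringsAsFactors = FALSE)
  sc <- scan_mutations(counts, n_chromo_total = 160, n_nonchromo_total = 300)
  tp53 <- sc[sc$gene == "TP53", ]
  expect_lt(tp53$p, 5e-7)
  expect_equal(tp53$direction, "chromo")
  expect_true(tp53$reported)
  expect_gt(sc$p[sc$gene == "RARE"], 0.3)
  expect_false(sc$reported[sc$gene == "RARE"])
  # identical proportions: p = 1
  flat <- data.frame(gene = "X", class = "nonsynonymous",
                     n_chromo = 30L, n_nonchromo = 30L)
  expect_equal(scan_mutations(flat, 100, 100)$p, 1)
  expect_equal(sc$p, sort(sc$p))
})

test_that("BH q-values follow the step-up arithmetic", {
  expect_equal(bh_qvalues(0.04), 0.04)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_qvalues(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_qvalues(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  p <- runif(50)
  q <- bh_qvalues(p)
  expect_true(all(q >= p))
  o <- sample(50)
  expect_equal(bh_qvalues(p[o]), q[o])           # order invariance
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
})

test_that("mutual exclusivity matches the hypergeometric closed form", {
  n <- 100
  ids <- sprintf("S%03d", 1:n)
  imp <- matrix(FALSE, 2, n, dimnames = list(c("A", "B"), ids))
  imp["A", 1:20] <- TRUE
  imp["B", 21:40] <- TRUE                         # perfectly exclusive
  mx <- mutual_exclusivity(imp, "A", "B", q_threshold = Inf)
  expect_equal(mx$both, 0L)
  expect_equal(mx$p, oracle_hyper_lower(0, 20, 80, 20), tolerance = 1e-12)
  expect_equal(mx$q, mx$p)                        # single pair: q = p

  imp2 <- imp
  imp2["B", ] <- imp2["A", ]                      # always co-mutated
  mx2 <- mutual_exclusivity(imp2, "A", "B", q_threshold = Inf)
  expect_equal(mx2$p, 1)

  expect_error(mutual_exclusivity(imp, "A", "ZZZ"), "ZZZ")
})

test_that("one-sided exclusivity p equals the enumerated lower tail", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(10:30, 1)
    a <- sample(0:n, 1); b <- sample(0:n, 1)
    both_range <- seq(max(0, a + b - n), min(a, b))
    both <- both_range[sample.int(length(both_range), 1)]
    imp <- matrix(FALSE, 2, n, dimnames = list(c("A", "B"), seq_len(n)))
    if (both > 0) { imp["A", 1:both] <- TRUE; imp["B", 1:both] <- TRUE }
    if (a > both) imp["A", (both + 1):a] <- TRUE
    if (b > both) imp["B", (a + 1):(a + b - both)] <- TRUE
    mx <- mutual_exclusivity(imp, "A", "B", q_threshold = Inf)
    expect_equal(mx$p, oracle_hyper_lower(both, a, n - a, b),
                 tolerance = 1e-12)
  }
})

test_that("the exclusivity test keeps its size under an independent null", {
  set.seed(33)
  n <- 500
  rejections <- 0L
  reps <- 200
  for (i in seq_len(reps)) {
    a <- runif(n) < 0.2
    b <- runif(n) < 0.2
    p <- stats::phyper(sum(a & b), sum(a), n - sum(a), sum(b))
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("cohort burden summary totals per group", {
  expect_equal(nrow(cohort_burden_summary(
    data.frame(sample = character(), gene = character(),
               class = character()), toy_calls)), 2L)
  mut <- data.frame(sample = c("S1", "S1"), gene = c("A", "B"),
                    class = c("missense", "missense"),
                    stringsAsFactors = FALSE)
  cs <- cohort_burden_summary(mut, toy_calls, drivers = "A")
  chromo <- cs[cs$group == "chromo", ]
  expect_equal(chromo$total_snv, 2L)
  expect_equal(chromo$n_affected_genes, 2L)
  expect_equal(chromo$n_missense, 2L)
  expect_equal(chromo$n_driver_genes, 1L)
  expect_equal(cs[cs$group == "nonchromo", "total_snv"], 0L)
})

test_that("a five-fold group rate difference shows in the summary", {
  cfg <- sim_config(n_samples = 400, prevalence = 0.5,
                    n_chromosomes = 3, genes_per_arm = 20,
                    chromo_driver = "G1P005", nonchromo_driver = "G2Q010",
                    chromo_driver_rates = c(chromo = 0.05, nonchromo = 0.05),
                    nonchromo_driver_rates = c(chromo = 0.05,
                                               nonchromo = 0.05),
                    n_passengers = 60, passenger_rate = 0.05,
                    synonymous_rate = 0.05,
                    mutation_rate_multiplier = c(chromo = 1, nonchromo = 5),
                    seed = 17)
  sim <- simulate_cohort(cfg)
  mut <- simulate_mutations(cfg, sim$meta, sim$gene_map)
  cs <- cohort_burden_summary(mut, stats::setNames(sim$meta$chromoanagenesis,
                                                   sim$meta$sample_id))
  ratio <- cs$total_snv[cs$group == "nonchromo"] /
    cs$total_snv[cs$group == "chromo"]
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 6.5)
})
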