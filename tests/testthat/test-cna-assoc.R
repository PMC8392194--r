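test_that("two-sided Fisher handles canonical tables", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10))
  # zero margin carries no information
  expect_equal(fisher_exact_two_sided(matrix(c(0, 0, 5, 7), 2)), 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 0, 0, 1), 2)),
               "non-negative")
})

test_that("Fisher agrees with stats::fisher.test and the enumeration oracle", {
  tabs <- list(matrix(c(13, 7, 158, 56), 2),     # HPV-vs-status counts
               matrix(c(3, 9, 12, 2), 2),
               matrix(c(1, 0, 0, 40), 2),
               matrix(c(17, 12, 5, 25), 2))
  for (tab in tabs) {
    p <- fisher_exact_two_sided(tab)
    expect_equal(p, oracle_fisher(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("transposing the groups leaves the p-value unchanged", {
  set.seed(12)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact_two_sided(tab), fisher_exact_two_sided(t(tab)))
    expect_equal(fisher_exact_two_sided(tab),
                 fisher_exact_two_sided(tab[2:1, 2:1]))
  }
})

make_scan_fixture <- function(p_values, cytobands, modes = "deletion") {
  ca <- parse_cytoband(cytobands)
  key <- paste0(ca$chromosome, ca$arm)
  data.frame(symbol = sprintf("G%02d", seq_along(p_values)),
             chromosome = ca$chromosome, arm = ca$arm,
             order_index = unlist(lapply(split(seq_along(key), key)[unique(key)],
                                         seq_along)) - 1L,
             cytoband = cytobands, mode = modes,
             n_chromo_alt = 0L, n_chromo = 60L,
             n_nonchromo_alt = 0L, n_nonchromo = 60L,
             p = p_values, significant = p_values < cna_alpha(),
             stringsAsFactors = FALSE)
}

test_that("per-gene scan flags a fully separating gene and skips small cohorts", {
  gm <- make_gene_map(n_chromosomes = 1, genes_per_arm = 5)
  n <- 120
  ids <- sprintf("S%03d", 1:n)
  calls <- stats::setNames(rep(c(TRUE, FALSE), each = 60), ids)
  states <- matrix(0L, nrow(gm), n, dimnames = list(gm$symbol, ids))
  states[3, calls] <- -1L               # altered in 100% chromo, 0% non-chromo
  cna <- cna_matrix(gm, states, collapsed = TRUE)

  scan <- scan_cna(cna, calls, mode = "deletion")
  expect_true(scan$significant[3])
  expect_lt(scan$p[3], cna_alpha())
  expect_equal(scan$p[1], 1)            # gene altered in nobody
  expect_false(any(scan$significant[-3]))

  # amplification mode sees nothing (all alterations are deletions)
  scan_amp <- scan_cna(cna, calls, mode = "amplification")
  expect_true(all(scan_amp$p == 1))

  # inclusion rule: 49 in one group is not enough
  calls49 <- stats::setNames(rep(c(TRUE, FALSE), c(49, 71)), ids)
  expect_message(res <- scan_cna(cna, calls49, mode = "deletion"),
                 "skipped")
  expect_null(res)
})

test_that("significant genes merge into arm-bounded regions", {
  # pattern S S S N S on one arm -> regions of 3 and 1
  p <- c(1e-9, 1e-8, 1e-10, 0.2, 1e-9)
  scan <- make_scan_fixture(p, c("1p11", "1p12", "1p13", "1p14", "1p15"))
  reg <- merge_regions(scan)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$n_genes, c(3L, 1L))
  expect_equal(reg$genes[1], "G01,G02,G03")

  # no significant genes -> no regions
  reg0 <- merge_regions(make_scan_fixture(rep(0.5, 4),
                                          c("1p11", "1p12", "1p13", "1p14")))
  expect_equal(nrow(reg0), 0L)

  # significance spanning the centromere stays two regions
  regc <- merge_regions(make_scan_fixture(rep(1e-9, 4),
                                          c("1p11", "1p12", "1q11", "1q12")))
  expect_equal(nrow(regc), 2L)
  expect_equal(regc$arm, c("p", "q"))
})

test_that("region counts are invariant to reversing within-arm order", {
  set.seed(3)
  p <- 10^-runif(12, 0, 12)
  bands <- sprintf("3p%d", 11:22)
  scan <- make_scan_fixture(p, bands)
  rev_scan <- scan[rev(seq_len(nrow(scan))), ]
  rev_scan$order_index <- seq_len(nrow(scan)) - 1L
  expect_equal(nrow(merge_regions(scan)), nrow(merge_regions(rev_scan)))
})

test_that("regions significant only in 'any' mode are counted as additional", {
  del <- make_scan_fixture(c(1e-9, 0.5, 0.5, 0.5), rep("1p11", 4))
  del$order_index <- 0:3
  amp <- del; amp$mode <- "amplification"; amp$p <- 0.5
  amp$significant <- FALSE
  anym <- del; anym$mode <- "any"
  anym$p <- c(1e-9, 0.5, 0.5, 1e-9); anym$significant <- anym$p < cna_alpha()
  reg <- merge_regions(rbind(del, amp, anym))
  expect_setequal(reg$mode, c("deletion", "additional"))
  expect_equal(reg$genes[reg$mode == "additional"], "G04")
})

test_that("the focality rule requires the gap against both neighbors", {
  scan <- make_scan_fixture(c(1e-2, 1e-10, 5e-3), c("2p11", "2p12", "2p13"))
  foc <- detect_focal(scan, gap_orders = 2.5)
  expect_equal(foc$symbol, "G02")
  expect_equal(foc$min_gap, log10(5e-3) - log10(1e-10), tolerance = 1e-9)

  # a near-significant neighbor blocks the call
  scan2 <- make_scan_fixture(c(1e-9, 1e-10, 5e-3), c("2p11", "2p12", "2p13"))
  expect_equal(nrow(detect_focal(scan2, gap_orders = 2.5)), 0L)

  # UCEC-style stricter gap: 3.5 and 5.0 orders fail at 4.0
  scan3 <- make_scan_fixture(c(10^-6.5, 1e-10, 1e-5), c("2p11", "2p12", "2p13"))
  expect_equal(nrow(detect_focal(scan3, gap_orders = 2.5)), 1L)
  expect_equal(nrow(detect_focal(scan3, gap_orders = 4.0)), 0L)

  # arm-terminal gene compares against its single neighbor
  scan4 <- make_scan_fixture(c(1e-10, 1e-2), c("2p11", "2p12"))
  expect_equal(detect_focal(scan4, gap_orders = 2.5)$symbol, "G01")
})

test_that("Manhattan table keeps genomic order and the strict threshold", {
  p <- c(5e-7, 1, 1e-8)
  scan <- make_scan_fixture(p, c("1p11", "1p12", "1q11"))
  tab <- manhattan_table(scan)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$position, 1:3)
  expect_false(tab$significant[1])      # exactly at the threshold: not called
  expect_true(tab$significant[3])
  expect_equal(tab$neg_log10_p[2], 0)
  expect_equal(attr(tab, "threshold"), 5e-7)
  expect_s3_class(plot_manhattan(scan), "ggplot")
})

test_that("a null cohort produces a calibrated (conservative) type-I rate", {
  sim <- simulate_differential_cna(n_per_group = 80, rate_alt = 0.2,
                                   rate_null = 0.2, n_region_genes = 0,
                                   n_chromosomes = 2, genes_per_arm = 250,
                                   seed = 6)
  scan <- scan_cna(sim$cna, sim$calls, mode = "deletion")
  frac <- mean(scan$p < 0.05)
  # Fisher is conservative; allow 3 binomial SDs above the nominal rate
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(scan)))
})
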