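## Synthetic labeled cohorts: gene maps, CNA profiles with class-dependent
## oscillation structure, and mutation tables with injected differential and
## mutually exclusive drivers. The generator's defaults encode the study
## conditions the pipeline is calibrated against: 46.4% chromoanagenesis
## prevalence, chromoanagenesis concentrated as an oscillation burst on one
## or two arms, a "dispersed-high" minority of negatives with many moderately
## oscillating arms, and driver impairment rates of 79.4% vs 17%
## (chromoanagenesis-linked, TP53-like) and 18.25% vs 72.5%
## (non-chromoanagenesis-linked, PTEN-like).

#' Synthetic cohort configuration
#'
#' @param n_samples Cohort size.
#' @param prevalence Chromoanagenesis prevalence (default 0.464, the labeled
#'   cohort rate).
#' @param n_chromosomes Number of chromosomes, 1..22 then X (default 23; no
#'   Y, as in the gene-level CNA release).
#' @param genes_per_arm Genes annotated per arm.
#' @param n_affected_arms Candidate numbers of burst arms per chromoanagenesis
#'   sample (sampled uniformly; default 1 or 2).
#' @param lambda_burst Poisson mean of the per-affected-arm oscillation count.
#' @param burst_run_lengths Candidate run lengths (genes) inside a burst.
#' @param lambda_background Poisson mean of background runs per arm, all
#'   samples.
#' @param background_run_lengths Candidate background run lengths.
#' @param dispersed_fraction Fraction of non-chromoanagenesis samples in the
#'   "dispersed-high" mode: many arms with moderately elevated counts, which
#'   keeps high oscillation totals from implying chromoanagenesis.
#' @param lambda_dispersed Poisson mean of per-arm runs in the dispersed-high
#'   mode.
#' @param cancer_types Cancer type codes assigned uniformly at random.
#' @param chromo_driver,nonchromo_driver Driver gene symbols (must exist in
#'   the generated map).
#' @param chromo_driver_rates,nonchromo_driver_rates Impairment probability
#'   `c(chromo = ..., nonchromo = ...)` for each driver.
#' @param exclusive If `TRUE`, co-impairment of the two drivers is forbidden:
#'   a sample drawn impaired for both keeps only its class-linked driver.
#' @param lof_given_impaired Probability an impairing mutation is LOF rather
#'   than missense.
#' @param n_passengers Number of passenger genes mutated at background rate.
#' @param passenger_rate Per-gene per-sample impairment probability for
#'   passengers.
#' @param synonymous_rate Per-gene per-sample synonymous mutation probability
#'   (drivers and passengers).
#' @param mutation_rate_multiplier Overall mutation-rate multiplier per group,
#'   `c(chromo = 1, nonchromo = 1)`; raise one side to emulate cohorts where
#'   one group carries several-fold more SNVs.
#' @param seed Integer seed; fully determines every generated object.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 800L, prevalence = 0.464,
                       n_chromosomes = 23L, genes_per_arm = 120L,
                       n_affected_arms = c(1L, 2L), lambda_burst = 30,
                       burst_run_lengths = 1:3, lambda_background = 1.5,
                       background_run_lengths = 1:5,
                       dispersed_fraction = 0.15, lambda_dispersed = 4,
                       cancer_types = c("UCEC", "BRCA", "LGG"),
                       chromo_driver = "G17P005",
                       nonchromo_driver = "G10Q060",
                       chromo_driver_rates = c(chromo = 0.794,
                                               nonchromo = 0.17),
                       nonchromo_driver_rates = c(chromo = 0.1825,
                                                  nonchromo = 0.725),
                       exclusive = TRUE, lof_given_impaired = 0.5,
                       n_passengers = 50L, passenger_rate = 0.03,
                       synonymous_rate = 0.03,
                       mutation_rate_multiplier = c(chromo = 1,
                                                    nonchromo = 1),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(prevalence >= 0, prevalence <= 1, lambda_burst >= 0,
            lambda_background >= 0, dispersed_fraction >= 0,
            dispersed_fraction <= 1, genes_per_arm >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic ordered gene map
#'
#' Deterministic (no randomness): `n_chromosomes` chromosomes labeled 1..22
#' then X, arms p and q, `genes_per_arm` genes each. Symbols follow the
#' pattern `G<chrom><P|Q><index>` and cytobands are synthesized to satisfy
#' [parse_cytoband()].
#'
#' @param n_chromosomes Number of chromosomes (<= 23).
#' @param genes_per_arm Genes per arm.
#' @return A `gene_map`.
#' @export
make_gene_map <- function(n_chromosomes = 23L, genes_per_arm = 120L) {
  stopifnot(n_chromosomes >= 1L, n_chromosomes <= 23L, genes_per_arm >= 1L)
  chroms <- chrom_levels()[seq_len(n_chromosomes)]
  rows <- expand.grid(idx = seq_len(genes_per_arm) - 1L, arm = c("p", "q"),
                      chromosome = chroms, stringsAsFactors = FALSE)
  symbol <- sprintf("G%s%s%03d", rows$chromosome, toupper(rows$arm), rows$idx)
  cytoband <- sprintf("%s%s%d.%d", rows$chromosome, rows$arm,
                      11L + rows$idx %/% 10L, rows$idx %% 10L + 1L)
  # build_gene_map keeps input order within arm; input is already ordered
  build_gene_map(symbol, cytoband)
}

## Place one run of `len` genes with `state` into `vec`, keeping >= 1 neutral
## gene between runs. Returns vec unchanged when no position fits.
place_run <- function(vec, len, state) {
  L <- length(vec)
  if (len > L) return(vec)
  occ <- vec != 0L
  blocked <- occ | c(FALSE, occ[-L]) | c(occ[-1], FALSE)
  ok <- !blocked
  cs <- cumsum(ok)
  starts <- seq_len(L - len + 1L)
  fits <- (cs[starts + len - 1L] - c(0, cs)[starts]) == len
  cand <- starts[fits]
  if (!length(cand)) return(vec)
  s <- cand[sample.int(length(cand), 1L)]
  vec[s:(s + len - 1L)] <- state
  vec
}

## Fill an arm with an alternating amp/del oscillation burst of (up to)
## `n_runs` runs separated by single neutral genes; returns the arm vector
## and the realized run count.
place_burst <- function(L, n_runs, run_lengths) {
  vec <- integer(L)
  if (n_runs < 1L) return(list(vec = vec, realized = 0L))
  lens <- sample(run_lengths, n_runs, replace = TRUE)
  # truncate to arm capacity (runs + single-gene separators)
  total <- cumsum(lens) + seq_len(n_runs) - 1L
  k <- max(which(total <= L), 0L)
  if (k == 0L) { k <- 1L; lens[1] <- min(lens[1], L) }
  lens <- lens[seq_len(k)]
  block <- sum(lens) + k - 1L
  s <- sample.int(L - block + 1L, 1L)
  state <- sample(c(-1L, 1L), 1L)
  for (i in seq_len(k)) {
    vec[s:(s + lens[i] - 1L)] <- state
    s <- s + lens[i] + 1L
    state <- -state
  }
  list(vec = vec, realized = k)
}

#' Simulate a labeled synthetic cohort
#'
#' Chromoanagenesis samples receive an oscillation burst — alternating
#' amplification/deletion runs separated by single neutral genes — on one or
#' two arms, on top of the background run process every sample gets. A
#' configurable fraction of negatives is "dispersed-high": elevated run
#' counts spread over many arms. Bursts exceeding arm capacity are truncated
#' (and the truncation logged via `message`).
#'
#' @param config A [sim_config()].
#' @return List with `cna` (a collapsed `cna_matrix`), `meta` (sample
#'   metadata data frame with `sample_id`, `cancer_type`, `label`,
#'   `chromoanagenesis`) and `gene_map`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  gm <- make_gene_map(config$n_chromosomes, config$genes_per_arm)
  arms <- arm_levels(gm)
  keyf <- factor(arm_keys(gm), levels = arms)
  arm_len <- as.integer(table(keyf))
  n <- config$n_samples
  with_seed(config$seed, {
    ids <- sprintf("TCGA-SY-%04d", seq_len(n))
    chromo <- stats::runif(n) < config$prevalence
    # labeled subtype mix follows the labeled cohort's 64/143/164 split
    subtype <- sample(c("chromothripsis", "chromothripsis+other",
                        "other-complex"), n, replace = TRUE,
                      prob = c(64, 143, 164) / 371)
    label <- ifelse(chromo, subtype, "none")
    cancer_type <- sample(config$cancer_types, n, replace = TRUE)
    dispersed <- !chromo & stats::runif(n) < config$dispersed_fraction
    states <- matrix(0L, nrow(gm), n, dimnames = list(gm$symbol, ids))
    n_truncated <- 0L
    for (i in seq_len(n)) {
      sample_arms <- vector("list", length(arms))
      for (a in seq_along(arms)) sample_arms[[a]] <- integer(arm_len[a])
      if (chromo[i]) {
        k_arms <- if (length(config$n_affected_arms) > 1L)
          sample(config$n_affected_arms, 1L) else config$n_affected_arms
        burst_arms <- sample.int(length(arms), k_arms)
        for (a in burst_arms) {
          want <- stats::rpois(1L, config$lambda_burst)
          b <- place_burst(arm_len[a], max(want, 1L),
                           config$burst_run_lengths)
          if (b$realized < max(want, 1L)) n_truncated <- n_truncated + 1L
          sample_arms[[a]] <- b$vec
        }
      }
      lambda_bg <- if (dispersed[i]) config$lambda_dispersed else
        config$lambda_background
      for (a in seq_along(arms)) {
        r <- stats::rpois(1L, lambda_bg)
        if (r > 0L) {
          vec <- sample_arms[[a]]
          for (j in seq_len(r)) {
            vec <- place_run(vec, sample(config$background_run_lengths, 1L),
                             sample(c(-1L, 1L), 1L))
          }
          sample_arms[[a]] <- vec
        }
      }
      states[, i] <- unlist(sample_arms, use.names = FALSE)
    }
    if (n_truncated > 0L)
      message(n_truncated, " burst(s) truncated to arm capacity")
    meta <- data.frame(sample_id = ids, cancer_type = cancer_type,
                       label = label, chromoanagenesis = chromo,
                       stringsAsFactors = FALSE)
    list(cna = cna_matrix(gm, states, collapsed = TRUE), meta = meta,
         gene_map = gm)
  })
}

#' Simulate somatic mutations with injected drivers
#'
#' Two drivers are injected at the configured class-conditional impairment
#' probabilities: a chromoanagenesis-linked gene (defaults 0.794 in
#' chromoanagenesis vs 0.17 in non-chromoanagenesis samples) and a
#' non-chromoanagenesis-linked gene (0.1825 vs 0.725). With `exclusive =
#' TRUE`, a sample drawn impaired for both keeps only its class-linked
#' driver, making the pair perfectly mutually exclusive. Passenger genes are
#' impaired at a flat background rate, and every gene also emits synonymous
#' mutations at `synonymous_rate`.
#'
#' @param config A [sim_config()].
#' @param meta Sample metadata from [simulate_cohort()].
#' @param gene_map The cohort's gene map (for passenger gene sampling).
#' @return Mutation table data frame (`sample`, `gene`, `class`,
#'   `variant_classification`).
#' @export
simulate_mutations <- function(config, meta, gene_map) {
  stopifnot(all(c(config$chromo_driver, config$nonchromo_driver) %in%
                  gene_map$symbol))
  n <- nrow(meta)
  chromo <- meta$chromoanagenesis
  mult <- ifelse(chromo, config$mutation_rate_multiplier[["chromo"]],
                 config$mutation_rate_multiplier[["nonchromo"]])
  with_seed(config$seed + 104729L, {   # offset keeps CNA/mutation draws apart
    imp_a <- stats::runif(n) < ifelse(chromo,
                                      config$chromo_driver_rates[["chromo"]],
                                      config$chromo_driver_rates[["nonchromo"]])
    imp_b <- stats::runif(n) < ifelse(chromo,
                                      config$nonchromo_driver_rates[["chromo"]],
                                      config$nonchromo_driver_rates[["nonchromo"]])
    if (config$exclusive) {
      clash <- imp_a & imp_b
      imp_a[clash] <- chromo[clash]
      imp_b[clash] <- !chromo[clash]
    }
    passengers <- setdiff(gene_map$symbol,
                          c(config$chromo_driver, config$nonchromo_driver))
    passengers <- sample(passengers, min(config$n_passengers,
                                         length(passengers)))
    rec <- list()
    emit <- function(sample_ids, gene, class) {
      if (!length(sample_ids)) return()
      rec[[length(rec) + 1L]] <<- data.frame(sample = sample_ids, gene = gene,
                                             class = class,
                                             stringsAsFactors = FALSE)
    }
    impair_class <- function(k)
      ifelse(stats::runif(k) < config$lof_given_impaired, "LOF", "missense")
    for (d in list(list(g = config$chromo_driver, imp = imp_a),
                   list(g = config$nonchromo_driver, imp = imp_b))) {
      who <- which(d$imp)
      emit(meta$sample_id[who], d$g, impair_class(length(who)))
    }
    for (g in passengers) {
      who <- which(stats::runif(n) < config$passenger_rate * mult)
      emit(meta$sample_id[who], g, impair_class(length(who)))
    }
    for (g in c(config$chromo_driver, config$nonchromo_driver, passengers)) {
      who <- which(stats::runif(n) < config$synonymous_rate * mult)
      emit(meta$sample_id[who], g, "synonymous")
    }
    out <- if (length(rec)) do.call(rbind, rec) else
      data.frame(sample = character(), gene = character(),
                 class = character(), stringsAsFactors = FALSE)
    out$variant_classification <- c(LOF = "Nonsense_Mutation",
                                    missense = "Missense_Mutation",
                                    synonymous = "Silent")[out$class]
    out <- out[order(out$sample, out$gene, out$class), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a cohort with one injected differential CNA region
#'
#' A two-group design for exercising the per-gene CNA scan: every gene is
#' altered independently at `rate_null` in both groups, except a contiguous
#' block of `n_region_genes` genes (on the first arm) altered at `rate_alt`
#' in the chromoanagenesis group. Alterations are assigned deletion state.
#'
#' @param n_per_group Samples per group (default 150).
#' @param rate_alt Alteration probability of region genes in the
#'   chromoanagenesis group (default 0.6).
#' @param rate_null Background alteration probability (default 0.05).
#' @param n_region_genes Region width in genes (default 30).
#' @param n_chromosomes,genes_per_arm Gene map dimensions (default 4 x 250 =
#'   2000 genes).
#' @param seed Integer seed.
#' @return List with `cna`, `calls` (named logical), and `region_genes`.
#' @export
simulate_differential_cna <- function(n_per_group = 150L, rate_alt = 0.6,
                                      rate_null = 0.05, n_region_genes = 30L,
                                      n_chromosomes = 4L, genes_per_arm = 250L,
                                      seed = 1L) {
  gm <- make_gene_map(n_chromosomes, genes_per_arm)
  n_genes <- nrow(gm)
  region <- gm$symbol[seq_len(n_region_genes) + 10L]   # inside the first arm
  with_seed(seed, {
    ids <- sprintf("DIFF-%04d", seq_len(2L * n_per_group))
    calls <- stats::setNames(rep(c(TRUE, FALSE), each = n_per_group), ids)
    pr <- matrix(rate_null, n_genes, length(ids))
    pr[match(region, gm$symbol), calls] <- rate_alt
    states <- matrix(0L, n_genes, length(ids), dimnames = list(gm$symbol, ids))
    states[stats::runif(length(pr)) < pr] <- -1L
    list(cna = cna_matrix(gm, states, collapsed = TRUE), calls = calls,
         region_genes = region)
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the GISTIC-style CNA TSV, a MAF, the sample metadata TSV and a
#' provenance JSON recording the configuration (including the seed).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  mut <- simulate_mutations(config, sim$meta, sim$gene_map)
  paths <- c(cna = file.path(dir, "cna_thresholded.tsv"),
             maf = file.path(dir, "mutations.maf"),
             meta = file.path(dir, "samples.tsv"),
             provenance = file.path(dir, "provenance.json"))
  write_cna_matrix(sim$cna, paths[["cna"]])
  write_maf(mut, paths[["maf"]])
  write_sample_meta(sim$meta, paths[["meta"]])
  cfg <- unclass(config)
  jsonlite::write_json(cfg, paths[["provenance"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
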