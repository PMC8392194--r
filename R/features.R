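## Oscillation features.
##
## An oscillation is a maximal run of adjacent genes on one chromosomal arm
## sharing the same non-neutral CNA state. Neutral (0) genes terminate runs
## and are not runs themselves; a +1 -> -1 boundary separates two runs.

#' Segment one arm into constant-state runs
#'
#' @param states Integer vector of collapsed CNA states (-1/0/+1) ordered by
#'   within-arm position.
#' @return Data frame with one row per run: `state`, `start` (0-based
#'   within-arm index of the first gene) and `length` (genes).
#' @examples
#' segment_arm(c(0, 1, 1, 0, -1))  # two runs: (+1, 1, 2) and (-1, 4, 1)
#' @export
segment_arm <- function(states) {
  states <- as.integer(states)
  if (!length(states))
    return(data.frame(state = integer(), start = integer(), length = integer()))
  r <- rle(states)
  ends <- cumsum(r$lengths)
  keep <- r$values != 0L
  data.frame(state = r$values[keep],
             start = (ends - r$lengths)[keep],
             length = r$lengths[keep])
}

## Per-arm oscillation counts for every sample at once: a run starts wherever
## a gene is non-neutral and either opens an arm or differs from the previous
## gene's state. Returns an arms x samples integer matrix.
oscillation_count_matrix <- function(cna) {
  st <- sign(cna$states)
  keys <- arm_keys(cna$genes)
  n <- nrow(st)
  prev <- rbind(0L, st[-n, , drop = FALSE])
  new_arm <- c(TRUE, keys[-1] != keys[-n])
  starts <- st != 0L & (new_arm | st != prev)
  counts <- rowsum(starts + 0L, keys, reorder = FALSE)
  counts <- counts[arm_levels(cna$genes), , drop = FALSE]
  storage.mode(counts) <- "integer"
  counts
}

#' Count oscillations per chromosomal arm for one sample
#'
#' Every arm present in the gene map gets an entry; arms with no non-neutral
#' gene report 0.
#'
#' @param cna A `cna_matrix`.
#' @param sample Sample identifier.
#' @return Named integer vector, one count per arm (names like `"17p"`).
#' @export
count_oscillations <- function(cna, sample) {
  if (!sample %in% cna$samples) stop("unknown sample: ", sample)
  st <- sign(cna$states[, sample])
  keys <- arm_keys(cna$genes)
  counts <- vapply(split(st, factor(keys, levels = arm_levels(cna$genes))),
                   function(v) nrow(segment_arm(v)), 1L)
  counts
}

#' The two selected oscillation-distribution features
#'
#' From the per-arm oscillation counts of a sample, computes
#' `f1 = max(counts) - 3 * mean(counts)` and `f2 = ` the population (divide
#' by N) standard deviation of the counts, both over all arms in the gene map
#' including zero-count arms. High `f1`/`f2` indicate one or a few arms
#' carrying exceptionally many oscillations — the chromoanagenesis signature —
#' whereas genomes with many moderately oscillating arms score low.
#'
#' @param arm_counts Named numeric vector of per-arm oscillation counts
#'   (at least 2 arms).
#' @return Named numeric vector `c(f1 = ..., f2 = ...)`.
#' @examples
#' feature_vector(c(`1p` = 10, `1q` = 1, `2p` = 1, `2q` = 0))
#' @export
feature_vector <- function(arm_counts) {
  if (length(arm_counts) < 2L)
    stop("need counts for at least 2 arms (the spread feature is undefined)")
  m <- mean(arm_counts)
  c(f1 = max(arm_counts) - 3 * m,
    f2 = sqrt(mean((arm_counts - m)^2)))
}

## All runs of one sample across the genome (arms never merge).
sample_runs <- function(cna, sample) {
  if (!sample %in% cna$samples) stop("unknown sample: ", sample)
  st <- sign(cna$states[, sample])
  keys <- factor(arm_keys(cna$genes), levels = arm_levels(cna$genes))
  do.call(rbind, c(lapply(split(st, keys), segment_arm),
                   make.row.names = FALSE))
}

#' Extended candidate features for one sample
#'
#' The wider candidate set considered alongside the two selected features:
#' genome-wide amplified/deleted gene totals, maximal and mean run length (in
#' genes), and the number of runs in highly varied chromosomes — defined here
#' as the total run count over chromosomes whose run count exceeds the
#' cross-chromosome mean by more than one population standard deviation (this
#' candidate is a named but underspecified quantity; the definition is this
#' package's reconstruction and the feature is not used by the classifier).
#'
#' @param cna A `cna_matrix`.
#' @param sample Sample identifier.
#' @return Named numeric vector with `n_amplified_genes`, `n_deleted_genes`,
#'   `max_run_length`, `mean_run_length`, `n_runs_high_var_chrom`.
#' @export
extended_features <- function(cna, sample) {
  runs <- sample_runs(cna, sample)
  st <- sign(cna$states[, sample])
  if (nrow(runs)) {
    keys <- cna$genes$chromosome
    n <- length(st)
    prev <- c(0L, st[-n])
    new_chr <- c(TRUE, keys[-1] != keys[-n])
    arm <- arm_keys(cna$genes)
    new_arm <- c(TRUE, arm[-1] != arm[-n])
    starts <- st != 0L & (new_arm | st != prev)
    per_chrom <- tapply(starts, factor(keys, levels = unique(keys)), sum)
    per_chrom[is.na(per_chrom)] <- 0
    thr <- mean(per_chrom) + sqrt(mean((per_chrom - mean(per_chrom))^2))
    n_high <- sum(per_chrom[per_chrom > thr])
  } else {
    n_high <- 0
  }
  c(n_amplified_genes = sum(st > 0L),
    n_deleted_genes = sum(st < 0L),
    max_run_length = if (nrow(runs)) max(runs$length) else 0,
    mean_run_length = if (nrow(runs)) mean(runs$length) else 0,
    n_runs_high_var_chrom = as.numeric(n_high))
}

#' Per-sample feature table
#'
#' Computes, for every sample of a CNA matrix, the two selected features plus
#' the extended candidate set.
#'
#' @param cna A `cna_matrix`.
#' @return Data frame with one row per sample: `sample_id`, `f1`, `f2` and the
#'   [extended_features()] columns.
#' @export
sample_features <- function(cna) {
  counts <- oscillation_count_matrix(cna)
  m <- colMeans(counts)
  mx <- apply(counts, 2L, max)
  f2 <- sqrt(colMeans(sweep(counts, 2L, m)^2))
  ext <- t(vapply(cna$samples, function(s) extended_features(cna, s),
                  numeric(5)))
  out <- data.frame(sample_id = cna$samples, f1 = mx - 3 * m, f2 = f2,
                    ext, stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Write a feature table
#'
#' @param features Data frame from [sample_features()].
#' @param path Output path (TSV).
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with `sample_id` and feature columns.
#' @export
read_features <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
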