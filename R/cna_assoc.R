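## Genome-wide per-gene Fisher scans of CNA frequency between
## chromoanagenesis and non-chromoanagenesis samples, with region merging,
## the single-gene focality rule, and Manhattan output.
##
## The genome-wide significance threshold is 5e-7, a Bonferroni correction of
## a conservative 0.01 level for ~20,000 genes; significance is strict
## (p < 5e-7).

utils::globalVariables(c("position", "neg_log10_p", "stripe"))

#' Genome-wide CNA significance threshold
#'
#' Bonferroni correction of a conservative 0.01 level across 20,000 genes.
#'
#' @param level Family-wise level (default 0.01).
#' @param n_genes Number of genes corrected for (default 20,000).
#' @return The per-gene threshold (5e-7 at the defaults).
#' @export
cna_alpha <- function(level = 0.01, n_genes = 20000) level / n_genes

## relative tie tolerance for probability-mass ordering (the convention of
## mainstream exact-test implementations: analytically tied tables must not
## be dropped by floating-point noise)
.fisher_tie_tol <- 1 + 1e-7

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-mass ordering: with all margins fixed, the p-value is the sum
#' of hypergeometric probabilities of every table whose probability does not
#' exceed the observed table's (up to a relative tie tolerance of 1e-7). A
#' zero margin carries no information and yields p = 1.
#'
#' @param table 2x2 numeric matrix (or length-4 vector, column-major) of
#'   non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact_two_sided <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L || any(x < 0) || any(x != round(x)))
    stop("table must be 2x2 non-negative integer counts")
  a <- x[1]; b <- x[3]; c <- x[2]; d <- x[4]     # rows (a,b) / (c,d)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= p_obs * .fisher_tie_tol]))
}

## memoised per-gene Fisher over shared count patterns
fisher_vec <- function(k1, n1, k2, n2) {
  key <- paste(k1, k2, sep = ":")
  u <- !duplicated(key)
  pu <- vapply(which(u), function(i)
    fisher_exact_two_sided(matrix(c(k1[i], n1 - k1[i], k2[i], n2 - k2[i]), 2,
                                  byrow = TRUE)), 1.0)
  pu[match(key, key[u])]
}

align_calls <- function(cna, calls) {
  if (is.data.frame(calls)) {
    flag_col <- intersect(c("chromoanagenesis", "call", "predicted"),
                          names(calls))[1]
    if (is.na(flag_col)) stop("calls data frame needs a chromoanagenesis/call column")
    calls <- stats::setNames(as.logical(calls[[flag_col]]), calls$sample_id)
  }
  calls[cna$samples]
}

#' Per-gene CNA frequency scan between chromoanagenesis groups
#'
#' For every gene, builds the 2x2 table of altered/unaltered samples in the
#' chromoanagenesis vs non-chromoanagenesis group and applies the two-sided
#' Fisher exact test. A sample counts as altered under mode `"any"` when its
#' state is non-zero, `"deletion"` when negative and `"amplification"` when
#' positive. Cohorts with fewer than `min_group_size` samples in either group
#' are skipped (returns `NULL` with a message), mirroring the inclusion rule
#' of at least 50 samples per group.
#'
#' @param cna A `cna_matrix` restricted to one cancer type.
#' @param calls Named logical vector (or data frame with `sample_id` and a
#'   `chromoanagenesis`/`call` column): chromoanagenesis status per sample.
#' @param mode One of `"any"`, `"deletion"`, `"amplification"`.
#' @param alpha Significance threshold (strict `<`), default [cna_alpha()].
#' @param min_group_size Minimum samples per group, default 50.
#' @return Data frame with per-gene counts, `p` and `significant`, in genomic
#'   order; `NULL` (invisibly) when the cohort is skipped.
#' @export
scan_cna <- function(cna, calls, mode = c("any", "deletion", "amplification"),
                     alpha = cna_alpha(), min_group_size = 50L) {
  mode <- match.arg(mode)
  calls <- align_calls(cna, calls)
  keep <- !is.na(calls)
  if (any(!keep))
    message(sum(!keep), " sample(s) without a chromoanagenesis call dropped")
  st <- cna$states[, keep, drop = FALSE]
  grp <- calls[keep]
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < min_group_size || n2 < min_group_size) {
    message(sprintf(
      "cohort skipped: %d chromoanagenesis / %d non-chromoanagenesis samples (need >= %d each)",
      n1, n2, min_group_size))
    return(invisible(NULL))
  }
  alt <- switch(mode, any = st != 0L, deletion = st < 0L,
                amplification = st > 0L)
  k1 <- rowSums(alt[, grp, drop = FALSE])
  k2 <- rowSums(alt[, !grp, drop = FALSE])
  p <- fisher_vec(k1, n1, k2, n2)
  out <- data.frame(cna$genes, mode = mode,
                    n_chromo_alt = k1, n_chromo = n1,
                    n_nonchromo_alt = k2, n_nonchromo = n2,
                    p = p, significant = p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha") <- alpha
  out
}

#' Run the CNA scan in all three modes
#'
#' @inheritParams scan_cna
#' @return Row-bound scan results for modes deletion, amplification and any;
#'   `NULL` when the cohort fails the group-size rule.
#' @export
scan_cna_modes <- function(cna, calls, alpha = cna_alpha(),
                           min_group_size = 50L) {
  res <- lapply(c("deletion", "amplification", "any"), function(m)
    scan_cna(cna, calls, m, alpha, min_group_size))
  if (is.null(res[[1]])) return(invisible(NULL))
  out <- do.call(rbind, res)
  attr(out, "alpha") <- alpha
  out
}

regions_one_mode <- function(scan) {
  key <- paste0(scan$chromosome, scan$arm)
  out <- list()
  for (a in unique(key)) {
    s <- scan[key == a, , drop = FALSE]
    s <- s[order(s$order_index), , drop = FALSE]
    r <- rle(s$significant)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      g <- s[starts[i]:ends[i], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = g$chromosome[1], arm = g$arm[1],
        start_index = g$order_index[1],
        end_index = g$order_index[nrow(g)],
        cytoband_span = if (g$cytoband[1] == g$cytoband[nrow(g)])
          g$cytoband[1] else paste0(g$cytoband[1], "-", g$cytoband[nrow(g)]),
        n_genes = nrow(g), genes = paste(g$symbol, collapse = ","),
        mode = g$mode[1], min_p = min(g$p), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(), arm = character(),
                      start_index = integer(), end_index = integer(),
                      cytoband_span = character(), n_genes = integer(),
                      genes = character(), mode = character(),
                      min_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Merge significant genes into altered regions
#'
#' A region is a maximal run of adjacent significant genes on one arm (one
#' non-significant gene splits a region; arms never merge across the
#' centromere; a single significant gene is a region). Given a scan over the
#' three modes, regions significant only in mode `"any"` — i.e. sharing no
#' gene with a deleted or amplified region — are reported with mode
#' `"additional"`, matching the "additional altered regions" bookkeeping.
#'
#' @param scan A scan result from [scan_cna()] or [scan_cna_modes()].
#' @return Data frame of regions: chromosome, arm, index span, cytoband span,
#'   member genes, mode, minimum p.
#' @export
merge_regions <- function(scan) {
  modes <- unique(scan$mode)
  per <- lapply(modes, function(m)
    regions_one_mode(scan[scan$mode == m, , drop = FALSE]))
  names(per) <- modes
  if ("any" %in% modes && length(intersect(c("deletion", "amplification"),
                                           modes))) {
    taken <- unlist(lapply(per[intersect(c("deletion", "amplification"),
                                         modes)],
                           function(d) strsplit(d$genes, ",")))
    anyr <- per[["any"]]
    if (nrow(anyr)) {
      keep <- vapply(strsplit(anyr$genes, ","),
                     function(g) !any(g %in% taken), TRUE)
      anyr <- anyr[keep, , drop = FALSE]
      if (nrow(anyr)) anyr$mode <- "additional"
    }
    per[["any"]] <- anyr
  }
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Single-gene focal alteration calls
#'
#' A gene is a distinct focal CNA gene when its scan p-value passes the
#' genome-wide threshold and is at least `gap_orders` orders of magnitude
#' more significant than both immediate flanking genes on the same arm
#' (arm-terminal genes are compared against their single neighbor). The
#' default gap is 2.5 orders of magnitude; for extreme cohorts such as UCEC a
#' stricter gap of 4 is used.
#'
#' @param scan A single-mode scan result from [scan_cna()].
#' @param gap_orders Required log10 p-value gap to both neighbors (> 0).
#' @param alpha Significance threshold, default [cna_alpha()].
#' @return Data frame of focal calls with the gene's p, neighbor p-values,
#'   the minimum log10 gap and the threshold used.
#' @export
detect_focal <- function(scan, gap_orders = 2.5, alpha = cna_alpha()) {
  stopifnot(gap_orders > 0, length(unique(scan$mode)) <= 1L)
  key <- paste0(scan$chromosome, scan$arm)
  out <- list()
  for (a in unique(key)) {
    s <- scan[key == a, , drop = FALSE]
    s <- s[order(s$order_index), , drop = FALSE]
    np <- nrow(s)
    for (i in seq_len(np)) {
      if (s$p[i] >= alpha) next
      nb <- c(if (i > 1) s$p[i - 1], if (i < np) s$p[i + 1])
      if (!length(nb)) next                      # single-gene arm: no context
      gaps <- log10(nb) - log10(s$p[i])
      if (all(gaps >= gap_orders)) {
        out[[length(out) + 1L]] <- data.frame(
          symbol = s$symbol[i], chromosome = s$chromosome[i], arm = s$arm[i],
          cytoband = s$cytoband[i], mode = s$mode[i], p = s$p[i],
          p_left = if (i > 1) s$p[i - 1] else NA_real_,
          p_right = if (i < np) s$p[i + 1] else NA_real_,
          min_gap = min(gaps), gap_orders = gap_orders,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(symbol = character(), chromosome = character(),
                      arm = character(), cytoband = character(),
                      mode = character(), p = numeric(), p_left = numeric(),
                      p_right = numeric(), min_gap = numeric(),
                      gap_orders = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Manhattan table of a gene scan
#'
#' Rows in genomic order with a cumulative position index and -log10 p, ready
#' for plotting; the significance threshold is strict (`p < alpha`), so a
#' gene sitting exactly on the threshold is not flagged.
#'
#' @param scan A single-mode scan result.
#' @param alpha Threshold recorded with the table, default [cna_alpha()].
#' @return Data frame: `symbol`, `chromosome`, `arm`, `position`,
#'   `neg_log10_p`, `significant`; the threshold is stored in the
#'   `"threshold"` attribute.
#' @export
manhattan_table <- function(scan, alpha = cna_alpha()) {
  stopifnot(length(unique(scan$mode)) <= 1L)
  chrom_f <- factor(scan$chromosome, levels = chrom_levels())
  arm_f <- factor(scan$arm, levels = c("p", "q"))
  s <- scan[order(chrom_f, arm_f, scan$order_index), , drop = FALSE]
  out <- data.frame(symbol = s$symbol, chromosome = s$chromosome, arm = s$arm,
                    position = seq_len(nrow(s)), neg_log10_p = -log10(s$p),
                    significant = s$p < alpha, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "threshold") <- alpha
  out
}

#' Manhattan plot of a gene scan
#'
#' Chromosomes alternately colored, with a horizontal line at the genome-wide
#' threshold.
#'
#' @param scan A single-mode scan result.
#' @param alpha Threshold line, default [cna_alpha()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, alpha = cna_alpha()) {
  tab <- manhattan_table(scan, alpha)
  tab$stripe <- factor(match(tab$chromosome, unique(tab$chromosome)) %% 2)
  ggplot2::ggplot(tab, ggplot2::aes(x = position, y = neg_log10_p,
                                    colour = stripe)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue4")) +
    ggplot2::labs(x = "gene (genomic order)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
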