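## Differential per-gene mutation-class burden between chromoanagenesis
## groups, and pairwise mutual-exclusivity screening.
##
## Burden is counted per individual: a patient contributes at most once per
## (gene, class) however many qualifying variants they carry. The
## "nonsynonymous" class is the union of LOF and missense. Differential
## results are reported below p = 5e-3; mutual exclusivity is a one-sided
## Fisher test of co-occurrence under-representation, screened at
## Benjamini-Hochberg q < 0.005.

mutation_classes <- c("LOF", "missense", "nonsynonymous", "synonymous")

as_call_vector <- function(calls) {
  if (is.data.frame(calls)) {
    flag_col <- intersect(c("chromoanagenesis", "call", "predicted"),
                          names(calls))[1]
    if (is.na(flag_col))
      stop("calls data frame needs a chromoanagenesis/call column")
    stats::setNames(as.logical(calls[[flag_col]]), calls$sample_id)
  } else calls
}

#' Per-gene, per-class mutated-individual counts by group
#'
#' For each gene and mutation class (LOF, missense, nonsynonymous = LOF or
#' missense, synonymous), counts how many individuals carry at least one such
#' mutation, separately in the chromoanagenesis and non-chromoanagenesis
#' groups. Samples with mutations but no call are excluded with a message.
#'
#' @param mutations Mutation table (see [read_maf()]): `sample`, `gene`,
#'   `class`.
#' @param calls Named logical vector (or calls data frame) of
#'   chromoanagenesis status per sample.
#' @return Data frame `gene`, `class`, `n_chromo`, `n_nonchromo` plus the
#'   group sizes in attributes `n_chromo_total` / `n_nonchromo_total`.
#' @export
burden_counts <- function(mutations, calls) {
  calls <- as_call_vector(calls)
  known <- mutations$sample %in% names(calls)[!is.na(calls)]
  if (any(!known))
    message(length(unique(mutations$sample[!known])),
            " sample(s) with mutations but no chromoanagenesis call excluded")
  mut <- mutations[known, , drop = FALSE]
  recs <- mut[mut$class %in% c("LOF", "missense", "synonymous"), ,
              drop = FALSE]
  nonsyn <- recs[recs$class %in% c("LOF", "missense"), , drop = FALSE]
  if (nrow(nonsyn)) nonsyn$class <- "nonsynonymous"
  recs <- rbind(recs, nonsyn)
  recs <- unique(recs[, c("sample", "gene", "class")])
  if (!nrow(recs)) {
    out <- data.frame(gene = character(), class = character(),
                      n_chromo = integer(), n_nonchromo = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "n_chromo_total") <- sum(calls, na.rm = TRUE)
    attr(out, "n_nonchromo_total") <- sum(!calls, na.rm = TRUE)
    return(out)
  }
  grp <- calls[recs$sample]
  tab <- table(gene = recs$gene,
               class = factor(recs$class, levels = mutation_classes),
               group = factor(ifelse(grp, "chromo", "nonchromo"),
                              levels = c("chromo", "nonchromo")))
  out <- as.data.frame.table(tab, responseName = "n", stringsAsFactors = FALSE)
  out <- stats::reshape(out, direction = "wide", idvar = c("gene", "class"),
                        timevar = "group")
  names(out) <- c("gene", "class", "n_chromo", "n_nonchromo")
  rownames(out) <- NULL
  attr(out, "n_chromo_total") <- sum(calls, na.rm = TRUE)
  attr(out, "n_nonchromo_total") <- sum(!calls, na.rm = TRUE)
  out
}

#' Differential mutation-class scan
#'
#' Two-sided Fisher exact test of (mutated, not mutated) x (chromoanagenesis,
#' non-chromoanagenesis) for every gene and mutation class. Results are
#' sorted by p-value, carry a direction flag, and rows below the report
#' threshold (default 5e-3) are marked `reported`.
#'
#' @param counts Output of [burden_counts()] (group totals may be overridden
#'   with `n_chromo_total` / `n_nonchromo_total`).
#' @param n_chromo_total,n_nonchromo_total Group sizes; default taken from
#'   the `counts` attributes.
#' @param report_threshold Report threshold on p (default 5e-3).
#' @return Data frame `gene`, `class`, counts, rates, `direction`
#'   (`"chromo"`/`"nonchromo"` enrichment), `p`, `reported`.
#' @export
scan_mutations <- function(counts,
                           n_chromo_total = attr(counts, "n_chromo_total"),
                           n_nonchromo_total = attr(counts, "n_nonchromo_total"),
                           report_threshold = 5e-3) {
  stopifnot(n_chromo_total > 0, n_nonchromo_total > 0)
  p <- fisher_vec(counts$n_chromo, n_chromo_total,
                  counts$n_nonchromo, n_nonchromo_total)
  rate1 <- counts$n_chromo / n_chromo_total
  rate2 <- counts$n_nonchromo / n_nonchromo_total
  out <- data.frame(counts, rate_chromo = rate1, rate_nonchromo = rate2,
                    direction = ifelse(rate1 >= rate2, "chromo", "nonchromo"),
                    p = p, reported = p < report_threshold,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$gene, out$class), , drop = FALSE]
}

#' Gene-impairment indicator matrix
#'
#' A sample is impaired in a gene when it carries at least one LOF or
#' missense mutation there.
#'
#' @param mutations Mutation table (`sample`, `gene`, `class`).
#' @param samples Character vector defining the cohort (columns).
#' @param genes Optional gene subset (rows); defaults to all mutated genes.
#' @return Logical matrix genes x samples.
#' @export
impairment_matrix <- function(mutations, samples, genes = NULL) {
  mut <- mutations[mutations$class %in% c("LOF", "missense") &
                     mutations$sample %in% samples, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(mut$gene))
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  mut <- mut[mut$gene %in% genes, , drop = FALSE]
  m[cbind(mut$gene, mut$sample)] <- TRUE
  m
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]), with
#' input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
bh_qvalues <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise mutual-exclusivity screen
#'
#' For each gene pair, tests whether the two genes are impaired in the same
#' patients less often than expected by chance: a one-sided Fisher exact test
#' on the co-occurrence table with fixed margins, lower tail (p = P(X <=
#' observed co-occurrences) under the hypergeometric null). By default the
#' pair universe is the cross product of a chromoanagenesis-enriched and a
#' non-chromoanagenesis-enriched gene list; q-values are Benjamini-Hochberg
#' over all tested pairs and pairs with q below `q_threshold` (default 0.005)
#' are returned.
#'
#' @param impaired Logical genes x samples matrix (see
#'   [impairment_matrix()]).
#' @param genes_a,genes_b Gene sets whose cross product is tested (a gene
#'   pairing with itself is dropped).
#' @param q_threshold Report threshold on q; use 1 to keep every pair.
#' @return Data frame per pair: `gene_a`, `gene_b`, `both`, `only_a`,
#'   `only_b`, `neither`, `p`, `q`, sorted by p.
#' @export
mutual_exclusivity <- function(impaired, genes_a, genes_b,
                               q_threshold = 0.005) {
  missing <- setdiff(c(genes_a, genes_b), rownames(impaired))
  if (length(missing))
    stop("gene(s) absent from the impairment matrix: ",
         paste(missing, collapse = ", "))
  pairs <- expand.grid(gene_a = genes_a, gene_b = genes_b,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  if (!nrow(pairs)) stop("no valid gene pairs to test")
  n <- ncol(impaired)
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- impaired[pairs$gene_a[i], ]
    b <- impaired[pairs$gene_b[i], ]
    both <- sum(a & b)
    na_ <- sum(a); nb_ <- sum(b)
    # under-representation: lower hypergeometric tail
    p <- stats::phyper(both, na_, n - na_, nb_)
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               both = both, only_a = na_ - both, only_b = nb_ - both,
               neither = n - na_ - nb_ + both, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_qvalues(res$p)
  res <- res[order(res$p, res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  res[res$q < q_threshold, , drop = FALSE]
}

#' Cohort-level mutation burden summary
#'
#' Per group totals of somatic SNVs, affected genes, LOF / missense /
#' synonymous occurrences and, given a driver list, affected driver genes.
#'
#' @param mutations Mutation table.
#' @param calls Chromoanagenesis calls (named logical or data frame).
#' @param drivers Optional character vector of driver gene symbols.
#' @return Data frame with one row per group.
#' @export
cohort_burden_summary <- function(mutations, calls, drivers = NULL) {
  calls <- as_call_vector(calls)
  groups <- list(chromo = names(calls)[!is.na(calls) & calls],
                 nonchromo = names(calls)[!is.na(calls) & !calls])
  do.call(rbind, lapply(names(groups), function(g) {
    mut <- mutations[mutations$sample %in% groups[[g]], , drop = FALSE]
    data.frame(group = g, n_samples = length(groups[[g]]),
               total_snv = nrow(mut),
               n_affected_genes = length(unique(mut$gene)),
               n_lof = sum(mut$class == "LOF"),
               n_missense = sum(mut$class == "missense"),
               n_synonymous = sum(mut$class == "synonymous"),
               n_driver_genes = if (is.null(drivers)) NA_integer_ else
                 length(unique(mut$gene[mut$gene %in% drivers])),
               stringsAsFactors = FALSE)
  }))
}
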