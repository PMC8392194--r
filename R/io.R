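#' @keywords internal
"_PACKAGE"

## Chromosome ordering used everywhere: autosomes then X; no Y (the gene-level
## CNA release carries no Y-chromosome genes).
chrom_levels <- function() c(as.character(1:22), "X")

#' Parse cytobands into chromosome and arm
#'
#' Splits cytoband addresses of the form `<chromosome><p|q><band>` (e.g.
#' `"8p11.21"`, `"17q12"`, `"Xq28"`) into their chromosome label and arm
#' letter. Chromosomes are restricted to 1-22 and X.
#'
#' @param cytoband Character vector of cytoband strings.
#' @return A data frame with columns `chromosome` (character) and `arm`
#'   (`"p"` or `"q"`), one row per input element.
#' @examples
#' parse_cytoband(c("8p11.21", "17q12", "Xq28"))
#' @export
parse_cytoband <- function(cytoband) {
  cytoband <- as.character(cytoband)
  m <- regmatches(cytoband, regexec("^([0-9]{1,2}|X)([pq])", cytoband))
  bad <- vapply(m, length, 1L) != 3L
  chroms <- arms <- rep(NA_character_, length(cytoband))
  chroms[!bad] <- vapply(m[!bad], `[`, "", 2L)
  arms[!bad] <- vapply(m[!bad], `[`, "", 3L)
  bad <- bad | (!is.na(chroms) & !chroms %in% chrom_levels())
  if (any(bad)) {
    stop("cytoband(s) lacking a valid chromosome and p/q arm prefix: ",
         paste(utils::head(cytoband[bad], 5L), collapse = ", "))
  }
  data.frame(chromosome = chroms, arm = arms, stringsAsFactors = FALSE)
}

## TRUE where the cytoband is parseable (used by the reader, which excludes
## rather than errors).
cytoband_ok <- function(cytoband) {
  m <- regmatches(cytoband, regexec("^([0-9]{1,2}|X)([pq])", cytoband))
  ok <- vapply(m, length, 1L) == 3L
  ok[ok] <- vapply(m[ok], `[`, "", 2L) %in% chrom_levels()
  ok
}

#' Build an ordered gene map
#'
#' Orders genes genomically: by chromosome (1-22 then X), arm (p before q),
#' and within-arm position. Within an arm, the supplied order is kept (a
#' stable sort), so position-sorted input files keep their order; an explicit
#' `position` vector overrides it. `order_index` numbers genes 0,1,2,... within
#' each arm.
#'
#' @param symbol Character vector of gene symbols (must be unique).
#' @param cytoband Character vector of cytoband strings, same length.
#' @param position Optional numeric within-arm sort key overriding input order.
#' @return A `gene_map` data frame with columns `symbol`, `chromosome`, `arm`,
#'   `order_index`, `cytoband`.
#' @export
build_gene_map <- function(symbol, cytoband, position = NULL) {
  if (anyDuplicated(symbol))
    stop("duplicate gene symbols in gene map: ",
         paste(utils::head(unique(symbol[duplicated(symbol)]), 5L), collapse = ", "))
  ca <- parse_cytoband(cytoband)
  chrom_f <- factor(ca$chromosome, levels = chrom_levels())
  arm_f <- factor(ca$arm, levels = c("p", "q"))
  key <- if (is.null(position)) seq_along(symbol) else position
  o <- order(chrom_f, arm_f, key)
  gm <- data.frame(symbol = symbol[o],
                   chromosome = ca$chromosome[o],
                   arm = ca$arm[o],
                   order_index = 0L,
                   cytoband = cytoband[o],
                   stringsAsFactors = FALSE)
  arm_key <- paste0(gm$chromosome, gm$arm)
  gm$order_index <- stats::ave(seq_len(nrow(gm)), arm_key,
                               FUN = function(i) seq_along(i) - 1L)
  class(gm) <- c("gene_map", "data.frame")
  gm
}

## "17p"-style key per gene, in map order
arm_keys <- function(gene_map) paste0(gene_map$chromosome, gene_map$arm)

## unique arms in genomic order
arm_levels <- function(gene_map) unique(arm_keys(gene_map))

#' Read a gene-level thresholded CNA matrix
#'
#' Reads the GISTIC `all_thresholded.by_genes` dialect: a tab-separated file
#' with columns `Gene Symbol`, `Locus ID` (optional), `Cytoband`, followed by
#' one integer column per sample with states in -2..2. Genes are reordered
#' genomically (see [build_gene_map()]); rows whose cytoband cannot be parsed
#' are dropped with a warning reporting the count.
#'
#' @param path Path to the TSV file.
#' @param collapse If `TRUE`, states are collapsed to their sign, merging the
#'   high-level and low-level gain/loss calls into -1/0/+1.
#' @return A `cna_matrix`: a list with `genes` (a `gene_map`), `samples`,
#'   `states` (integer matrix, genes x samples), and `collapsed`.
#' @export
read_cna_matrix <- function(path, collapse = FALSE) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = NULL)
  meta_cols <- intersect(c("Gene Symbol", "Locus ID", "Cytoband"), names(raw))
  if (!all(c("Gene Symbol", "Cytoband") %in% meta_cols))
    stop("CNA file must have 'Gene Symbol' and 'Cytoband' columns; found: ",
         paste(names(raw), collapse = ", "))
  sample_cols <- setdiff(names(raw), meta_cols)
  if (!length(sample_cols)) stop("CNA file has no sample columns")
  for (sc in sample_cols) {
    v <- raw[[sc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num != round(num))
    if (length(bad))
      stop(sprintf("non-integer CNA state '%s' at gene '%s', sample column '%s'",
                   v[bad[1]], raw[["Gene Symbol"]][bad[1]], sc))
    raw[[sc]] <- as.integer(num)
  }
  ok <- cytoband_ok(raw[["Cytoband"]])
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) with unparseable cytoband excluded")
    raw <- raw[ok, , drop = FALSE]
  }
  gm <- build_gene_map(raw[["Gene Symbol"]], raw[["Cytoband"]])
  states <- as.matrix(raw[match(gm$symbol, raw[["Gene Symbol"]]), sample_cols,
                          drop = FALSE])
  storage.mode(states) <- "integer"
  dimnames(states) <- list(gm$symbol, sample_cols)
  if (collapse) {
    states <- sign(states)
    storage.mode(states) <- "integer"
  }
  structure(list(genes = gm, samples = sample_cols, states = states,
                 collapsed = collapse),
            class = "cna_matrix")
}

#' Construct a CNA matrix from components
#'
#' @param gene_map A `gene_map` (see [build_gene_map()]).
#' @param states Integer matrix (genes x samples) in the gene map's row order.
#' @param collapsed Whether states are already sign-collapsed.
#' @return A `cna_matrix`.
#' @export
cna_matrix <- function(gene_map, states, collapsed = FALSE) {
  stopifnot(inherits(gene_map, "gene_map"), nrow(states) == nrow(gene_map))
  storage.mode(states) <- "integer"
  rownames(states) <- gene_map$symbol
  structure(list(genes = gene_map, samples = colnames(states), states = states,
                 collapsed = collapsed),
            class = "cna_matrix")
}

#' Collapse CNA states to their sign
#'
#' @param x A `cna_matrix`.
#' @return The matrix with states in -1/0/+1.
#' @export
collapse_cna <- function(x) {
  x$states <- sign(x$states)
  storage.mode(x$states) <- "integer"
  x$collapsed <- TRUE
  x
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat(sprintf("cna_matrix: %d genes x %d samples (%s states), %d arms\n",
              nrow(x$states), ncol(x$states),
              if (x$collapsed) "collapsed -1/0/+1" else "thresholded -2..2",
              length(arm_levels(x$genes))))
  invisible(x)
}

#' Write a gene-level CNA matrix
#'
#' Writes the same TSV dialect [read_cna_matrix()] reads, so matrices
#' round-trip exactly.
#'
#' @param x A `cna_matrix`.
#' @param path Output path.
#' @export
write_cna_matrix <- function(x, path) {
  out <- data.frame(x$genes$symbol, seq_len(nrow(x$genes)), x$genes$cytoband,
                    x$states, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("Gene Symbol", "Locus ID", "Cytoband", x$samples)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Variant_Classification -> mutation class mapping (standard consequence
## semantics; "other" is excluded from all burden scans).
maf_lof_classes <- c("Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins",
                     "Splice_Site", "Translation_Start_Site", "Nonstop_Mutation")

#' Map MAF Variant_Classification values to mutation classes
#'
#' @param variant_classification Character vector of MAF
#'   `Variant_Classification` values.
#' @return Character vector in `{"LOF", "missense", "synonymous", "other"}`.
#' @export
variant_class <- function(variant_classification) {
  out <- rep("other", length(variant_classification))
  out[variant_classification %in% maf_lof_classes] <- "LOF"
  out[variant_classification == "Missense_Mutation"] <- "missense"
  out[variant_classification == "Silent"] <- "synonymous"
  out
}

## TCGA barcodes identify the patient by their first 12 characters.
patient_id <- function(barcode) {
  tcga <- grepl("^TCGA-", barcode)
  barcode[tcga] <- substr(barcode[tcga], 1L, 12L)
  barcode
}

#' Read a somatic mutation table (MAF)
#'
#' Reads a tab-separated MAF requiring at least `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification`. TCGA-style barcodes
#' are truncated to the 12-character patient id; each variant row becomes one
#' record with its mapped mutation class (see [variant_class()]).
#'
#' @param path Path to the MAF file. Lines starting with `#` are skipped.
#' @return A data frame with columns `sample`, `gene`, `class`,
#'   `variant_classification`.
#' @export
read_maf <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("MAF is missing required column(s) ", paste(miss, collapse = ", "),
         "; columns found: ", paste(names(raw), collapse = ", "))
  data.frame(sample = patient_id(raw[["Tumor_Sample_Barcode"]]),
             gene = raw[["Hugo_Symbol"]],
             class = variant_class(raw[["Variant_Classification"]]),
             variant_classification = raw[["Variant_Classification"]],
             stringsAsFactors = FALSE)
}

#' Write a minimal MAF
#'
#' @param mutations Data frame with `sample`, `gene` and either
#'   `variant_classification` or `class` columns.
#' @param path Output path.
#' @export
write_maf <- function(mutations, path) {
  vc <- mutations$variant_classification
  if (is.null(vc)) {
    vc <- c(LOF = "Nonsense_Mutation", missense = "Missense_Mutation",
            synonymous = "Silent", other = "3'UTR")[mutations$class]
  }
  out <- data.frame(Hugo_Symbol = mutations$gene,
                    Tumor_Sample_Barcode = mutations$sample,
                    Variant_Classification = vc,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with header `sample_id`, `cancer_type`, `label`, where
#' `label` is one of `none`, `chromothripsis`, `chromothripsis+other`,
#' `other-complex`, `unknown`. A sample is flagged as chromoanagenesis when it
#' has chromothripsis and/or another complex chromosomal event, i.e. whenever
#' `label` is neither `none` nor `unknown`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the three columns plus logical `chromoanagenesis`
#'   (`NA` for `unknown`).
#' @export
read_sample_meta <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cancer_type", "label")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  m$chromoanagenesis <- ifelse(m$label == "unknown", NA, m$label != "none")
  m
}

#' Write sample metadata
#'
#' @param meta Data frame with `sample_id`, `cancer_type`, `label`.
#' @param path Output path.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta[, c("sample_id", "cancer_type", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
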