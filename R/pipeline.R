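## End-to-end orchestration: simulate -> features -> train -> predict ->
## differential CNA -> focal -> differential SNV -> mutual exclusivity ->
## prevalence report, with a manifest recording configuration, seeds, input
## checksums and per-stage row counts so that reruns are verifiably
## identical.

#' Pipeline configuration
#'
#' Collects every fixed constant of the analysis: the genome-wide CNA
#' threshold (5e-7 = 0.01/20,000, Bonferroni), the SNV report threshold
#' (5e-3), the mutual-exclusivity q threshold (0.005), the focality gaps (2.5
#' orders of magnitude; 4.0 for UCEC), the minimum per-group cohort size
#' (50), and the 70/15/15 split.
#'
#' @param out_dir Run directory.
#' @param sim A [sim_config()] describing the cohort to simulate (stage
#'   `simulate`).
#' @param stages Character vector of enabled stages, a subset of the default.
#' @param split_fractions Train/dev/test fractions.
#' @param split_seed Seed for the stratified split.
#' @param max_depth,min_leaf Decision-tree hyperparameters.
#' @param alpha_cna Genome-wide CNA significance threshold.
#' @param snv_report_threshold Differential SNV report threshold.
#' @param mutex_q Mutual-exclusivity q threshold.
#' @param focal_gap,focal_gap_ucec Focality gaps (log10 orders).
#' @param min_group_size Minimum samples per group for a cancer type to be
#'   scanned.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       sim = sim_config(),
                       stages = c("simulate", "features", "train", "predict",
                                  "diff_cna", "focal", "diff_snv", "mutex",
                                  "report"),
                       split_fractions = c(0.70, 0.15, 0.15),
                       split_seed = 1L, max_depth = 3L, min_leaf = 5L,
                       alpha_cna = cna_alpha(),
                       snv_report_threshold = 5e-3, mutex_q = 0.005,
                       focal_gap = 2.5, focal_gap_ucec = 4.0,
                       min_group_size = 50L) {
  stopifnot(alpha_cna > 0, snv_report_threshold > 0, mutex_q > 0,
            abs(sum(split_fractions) - 1) < 1e-8)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage_file <- function(cfg, name) file.path(cfg$out_dir, name)

require_upstream <- function(cfg, stage, paths) {
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop(sprintf("stage '%s' requires missing input(s): %s", stage,
                 paste(miss, collapse = ", ")))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, writing each stage's outputs under
#' `out_dir` and a `manifest.json` recording the configuration, seeds, file
#' checksums (MD5) and per-stage row counts. Rerunning with the same
#' configuration reproduces identical outputs. A stage whose upstream files
#' are absent raises an error naming the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list())
  note <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(
      files = as.list(tools::md5sum(files)), rows = rows)
  }
  p_cna <- stage_file(cfg, "cna_thresholded.tsv")
  p_maf <- stage_file(cfg, "mutations.maf")
  p_meta <- stage_file(cfg, "samples.tsv")
  p_feat <- stage_file(cfg, "features.tsv")
  p_model <- stage_file(cfg, "model.json")
  p_calls <- stage_file(cfg, "calls.tsv")

  if ("simulate" %in% cfg$stages) {
    paths <- write_cohort(cfg$sim, cfg$out_dir)
    note("simulate", paths[c("cna", "maf", "meta")],
         rows = cfg$sim$n_samples)
  }
  if ("features" %in% cfg$stages) {
    require_upstream(cfg, "features", p_cna)
    cna <- read_cna_matrix(p_cna, collapse = TRUE)
    feats <- sample_features(cna)
    write_features(feats, p_feat)
    note("features", p_feat, nrow(feats))
  }
  if ("train" %in% cfg$stages) {
    require_upstream(cfg, "train", c(p_feat, p_meta))
    feats <- read_features(p_feat)
    meta <- read_sample_meta(p_meta)
    lab <- meta$chromoanagenesis[match(feats$sample_id, meta$sample_id)]
    keep <- !is.na(lab)
    split <- stratified_split(feats$sample_id[keep], lab[keep],
                              cfg$split_fractions, cfg$split_seed)
    tr <- match(split$train, feats$sample_id)
    tree <- train_tree(feats[tr, c("f1", "f2")], lab[tr],
                       max_depth = cfg$max_depth, min_leaf = cfg$min_leaf)
    write_tree_json(tree, p_model)
    dev_i <- match(split$dev, feats$sample_id)
    test_i <- match(split$test, feats$sample_id)
    ev <- list(
      dev = evaluate_predictions(
        predict(tree, feats[dev_i, , drop = FALSE]), lab[dev_i]),
      test = evaluate_predictions(
        predict(tree, feats[test_i, , drop = FALSE]), lab[test_i]))
    jsonlite::write_json(ev, stage_file(cfg, "eval.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("train", c(p_model, stage_file(cfg, "eval.json")),
         length(split$train))
  }
  if ("predict" %in% cfg$stages) {
    require_upstream(cfg, "predict", c(p_model, p_feat))
    tree <- read_tree_json(p_model)
    feats <- read_features(p_feat)
    calls <- data.frame(sample_id = feats$sample_id,
                        chromoanagenesis = predict(tree, feats),
                        score = predict(tree, feats, type = "prob"),
                        stringsAsFactors = FALSE)
    utils::write.table(calls, p_calls, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("predict", p_calls, nrow(calls))
  }
  scan_by_type <- NULL
  if (any(c("diff_cna", "focal") %in% cfg$stages)) {
    require_upstream(cfg, intersect(c("diff_cna", "focal"), cfg$stages)[1],
                     c(p_cna, p_calls, p_meta))
    cna <- read_cna_matrix(p_cna, collapse = TRUE)
    calls_df <- utils::read.delim(p_calls, stringsAsFactors = FALSE)
    meta <- read_sample_meta(p_meta)
    calls <- stats::setNames(as.logical(calls_df$chromoanagenesis),
                             calls_df$sample_id)
    scan_by_type <- list()
    for (ct in sort(unique(meta$cancer_type))) {
      ids <- meta$sample_id[meta$cancer_type == ct]
      sub <- cna
      sub$states <- sub$states[, intersect(sub$samples, ids), drop = FALSE]
      sub$samples <- colnames(sub$states)
      sc <- scan_cna_modes(sub, calls, cfg$alpha_cna, cfg$min_group_size)
      if (is.null(sc)) next
      scan_by_type[[ct]] <- sc
    }
  }
  if ("diff_cna" %in% cfg$stages) {
    rows <- 0L
    files <- character()
    for (ct in names(scan_by_type)) {
      sc <- scan_by_type[[ct]]
      f <- stage_file(cfg, sprintf("cna_scan_%s.tsv", ct))
      utils::write.table(sc, f, sep = "\t", quote = FALSE, row.names = FALSE)
      reg <- merge_regions(sc)
      fr <- stage_file(cfg, sprintf("cna_regions_%s.tsv", ct))
      utils::write.table(reg, fr, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      rows <- rows + nrow(sc)
      files <- c(files, f, fr)
    }
    note("diff_cna", files, rows)
  }
  if ("focal" %in% cfg$stages) {
    rows <- 0L
    files <- character()
    for (ct in names(scan_by_type)) {
      sc <- scan_by_type[[ct]]
      gap <- if (ct == "UCEC") cfg$focal_gap_ucec else cfg$focal_gap
      foc <- do.call(rbind, lapply(split(sc, sc$mode), detect_focal,
                                   gap_orders = gap, alpha = cfg$alpha_cna))
      f <- stage_file(cfg, sprintf("cna_focal_%s.tsv", ct))
      utils::write.table(foc, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      rows <- rows + nrow(foc)
      files <- c(files, f)
    }
    note("focal", files, rows)
  }
  snv_scan <- NULL
  if (any(c("diff_snv", "mutex") %in% cfg$stages)) {
    require_upstream(cfg, intersect(c("diff_snv", "mutex"), cfg$stages)[1],
                     c(p_maf, p_calls))
    mut <- read_maf(p_maf)
    calls_df <- utils::read.delim(p_calls, stringsAsFactors = FALSE)
    calls <- stats::setNames(as.logical(calls_df$chromoanagenesis),
                             calls_df$sample_id)
    counts <- burden_counts(mut, calls)
    snv_scan <- scan_mutations(counts,
                               report_threshold = cfg$snv_report_threshold)
  }
  if ("diff_snv" %in% cfg$stages) {
    f <- stage_file(cfg, "snv_scan.tsv")
    utils::write.table(snv_scan, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("diff_snv", f, nrow(snv_scan))
  }
  if ("mutex" %in% cfg$stages) {
    rep_ns <- snv_scan[snv_scan$reported & snv_scan$class == "nonsynonymous", ]
    ga <- unique(rep_ns$gene[rep_ns$direction == "chromo"])
    gb <- unique(rep_ns$gene[rep_ns$direction == "nonchromo"])
    f <- stage_file(cfg, "mutex.tsv")
    if (length(ga) && length(gb)) {
      mut <- read_maf(p_maf)
      calls_df <- utils::read.delim(p_calls, stringsAsFactors = FALSE)
      imp <- impairment_matrix(mut, calls_df$sample_id)
      mx <- mutual_exclusivity(imp, intersect(ga, rownames(imp)),
                               intersect(gb, rownames(imp)),
                               q_threshold = cfg$mutex_q)
    } else {
      mx <- data.frame()
      message("mutex stage: no differentially impaired gene pair to test")
    }
    utils::write.table(mx, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("mutex", f, nrow(mx))
  }
  if ("report" %in% cfg$stages) {
    require_upstream(cfg, "report", c(p_calls, p_meta))
    calls_df <- utils::read.delim(p_calls, stringsAsFactors = FALSE)
    meta <- read_sample_meta(p_meta)
    rep <- predicted_prevalence_report(calls_df, meta)
    f <- stage_file(cfg, "prevalence.tsv")
    utils::write.table(rep$table, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("report", f, nrow(rep$table))
  }
  cfg_plain <- unclass(cfg)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  cfg_plain$out_dir <- NULL          # hash the analysis content, not the path
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  manifest$config <- jsonlite::fromJSON(cfg_json, simplifyVector = TRUE)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  manifest$config_md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest$seeds <- list(sim = cfg$sim$seed, split = cfg$split_seed)
  jsonlite::write_json(manifest, stage_file(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Predicted chromoanagenesis prevalence per cancer type
#'
#' Tabulates the predicted chromoanagenesis fraction per cancer type and,
#' when a reference table is supplied, the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` of the predictions against the reference
#' rates (SS_tot about the reference mean). Cancer types without samples are
#' omitted.
#'
#' @param calls Data frame with `sample_id` and `chromoanagenesis` (logical).
#' @param meta Sample metadata with `sample_id`, `cancer_type`.
#' @param reference Optional data frame with `cancer_type` and
#'   `reference_rate`.
#' @return List with `table` (cancer_type, n, predicted_rate, and
#'   `reference_rate` when given) and `r_squared` (`NA` without a reference).
#' @export
predicted_prevalence_report <- function(calls, meta, reference = NULL) {
  flag <- as_call_vector(calls)
  ct <- meta$cancer_type[match(names(flag), meta$sample_id)]
  keep <- !is.na(ct)
  tab <- do.call(rbind, lapply(sort(unique(ct[keep])), function(tt) {
    f <- flag[keep][ct[keep] == tt]
    data.frame(cancer_type = tt, n = length(f), predicted_rate = mean(f),
               stringsAsFactors = FALSE)
  }))
  r2 <- NA_real_
  if (!is.null(reference)) {
    tab$reference_rate <- reference$reference_rate[
      match(tab$cancer_type, reference$cancer_type)]
    ok <- !is.na(tab$reference_rate)
    ss_res <- sum((tab$predicted_rate[ok] - tab$reference_rate[ok])^2)
    ss_tot <- sum((tab$reference_rate[ok] - mean(tab$reference_rate[ok]))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else
      if (ss_res == 0) 1 else NA_real_
  }
  list(table = tab, r_squared = r2)
}
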