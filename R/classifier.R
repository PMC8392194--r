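## Deterministic CART on the two oscillation features.
##
## The trainer is a plain binary CART with the Gini criterion: candidate
## thresholds are midpoints between consecutive distinct sorted feature
## values, the split maximising the impurity decrease wins, and ties are
## broken towards the lower feature index and then the lower threshold.
## Zero-gain splits are allowed while the node is impure (so e.g. an
## XOR-arranged training set is still solved at depth 2); a node becomes a
## leaf when pure, at max depth, or when no candidate split can respect the
## minimum leaf size. Training is fully deterministic: no randomness is used.

## run RNG-dependent code under a seed without disturbing the global stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified train/development/test split
#'
#' Partitions labeled samples into train, development (model/feature
#' selection) and final test sets, preserving the label proportion within
#' each set to +/- 1 sample per stratum. Set sizes follow the target
#' fractions by largest-remainder allocation, remainders going to the set
#' currently furthest below its global target. Deterministic given `seed`.
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels Logical (or 2-level) vector aligned with `sample_ids`.
#' @param fractions Numeric of length 3 summing to 1; default `c(0.70, 0.15,
#'   0.15)` for train/dev/test.
#' @param seed Integer seed controlling the within-stratum shuffle.
#' @return List with character vectors `train`, `dev`, `test`.
#' @export
stratified_split <- function(sample_ids, labels,
                             fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  if (length(sample_ids) < 3L) stop("need at least 3 labeled samples")
  stopifnot(length(labels) == length(sample_ids))
  n <- length(sample_ids)
  target <- n * fractions
  assigned <- c(0, 0, 0)
  out <- list(character(0), character(0), character(0))
  strata <- split(sample_ids, labels)
  with_seed(seed, {
    for (ids in strata) {
      ids <- sample(ids)
      ns <- length(ids)
      want <- ns * fractions
      base <- floor(want)
      rem <- ns - sum(base)
      frac <- want - base
      extra <- c(0L, 0L, 0L)
      if (rem > 0) {
        open <- 1:3                       # each set gets at most one extra
        for (r in seq_len(rem)) {
          deficit <- target - (assigned + base + extra)
          # most fractional remainder first; break ties by global deficit,
          # then by set order
          pick <- open[order(-frac[open], -deficit[open], open)][1]
          extra[pick] <- extra[pick] + 1L
          open <- setdiff(open, pick)
        }
      }
      sizes <- base + extra
      cut <- c(0, cumsum(sizes))
      for (j in 1:3)
        out[[j]] <- c(out[[j]], ids[seq_len(sizes[j]) + cut[j]])
      assigned <- assigned + sizes
    }
  })
  names(out) <- c("train", "dev", "test")
  out
}

gini <- function(n_pos, n_tot) {
  if (n_tot == 0) return(0)
  p <- n_pos / n_tot
  2 * p * (1 - p)
}

## best axis-aligned split of (X, y); NULL when no candidate exists
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  parent <- gini(sum(y), n)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xo <- X[o, j]
    yo <- y[o]
    i <- which(xo[-n] < xo[-1])              # split after position i
    i <- i[i >= min_leaf & (n - i) >= min_leaf]
    if (!length(i)) next
    cum_pos <- cumsum(yo)
    nl <- i; nr <- n - i
    pl <- cum_pos[i]; pr <- sum(yo) - pl
    gl <- 1 - (pl / nl)^2 - ((nl - pl) / nl)^2
    gr <- 1 - (pr / nr)^2 - ((nr - pr) / nr)^2
    dec <- parent - (nl * gl + nr * gr) / n
    k <- which.max(dec)                      # first max = lowest threshold
    if (is.null(best) || dec[k] > best$decrease) {
      best <- list(feature = j, threshold = (xo[i[k]] + xo[i[k] + 1]) / 2,
                   decrease = dec[k], left = o[seq_len(i[k])],
                   right = o[(i[k] + 1):n])
    }
  }
  best
}

#' Train a decision tree on sample features
#'
#' @param x Numeric matrix or data frame of features (rows = samples). By
#'   default the two selected oscillation features `f1` and `f2`.
#' @param y Logical vector: `TRUE` for chromoanagenesis.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum number of training samples per leaf.
#' @return A `cna_tree`: a node table with split features/thresholds and leaf
#'   class counts, plus the feature names. Routing uses `x <= threshold` to
#'   the left child; leaf prediction is the majority class (ties predict
#'   negative).
#' @export
train_tree <- function(x, y, max_depth = 3L, min_leaf = 5L) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.logical(y)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    node <- list(id = id, feature = NA_integer_, threshold = NA_real_,
                 left = NA_integer_, right = NA_integer_,
                 n_pos = sum(y[idx]), n_neg = sum(!y[idx]))
    nodes[[id]] <<- node
    pure <- node$n_pos == 0L || node$n_neg == 0L
    if (!pure && depth < max_depth) {
      sp <- best_split(X[idx, , drop = FALSE], y[idx], min_leaf)
      if (!is.null(sp)) {
        nodes[[id]]$feature <<- sp$feature
        nodes[[id]]$threshold <<- sp$threshold
        nodes[[id]]$left <<- grow(idx[sp$left], depth + 1L)
        nodes[[id]]$right <<- grow(idx[sp$right], depth + 1L)
      }
    }
    id
  }
  grow(seq_along(y), 0L)
  tab <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(id = nd$id, feature = nd$feature, threshold = nd$threshold,
               left = nd$left, right = nd$right, n_pos = nd$n_pos,
               n_neg = nd$n_neg)))
  rownames(tab) <- NULL
  structure(list(nodes = tab,
                 features = colnames(X) %||% paste0("x", seq_len(ncol(X)))),
            class = "cna_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cna_tree <- function(x, ...) {
  n_leaf <- sum(is.na(x$nodes$feature))
  cat(sprintf("cna_tree: %d nodes (%d leaves) on features %s\n",
              nrow(x$nodes), n_leaf, paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Predict chromoanagenesis status with a trained tree
#'
#' Routes each sample through the tree (`feature <= threshold` goes left) and
#' returns the majority class of the reached leaf, or the leaf's positive
#' class proportion.
#'
#' @param object A `cna_tree`.
#' @param newdata Data frame or matrix containing the training feature
#'   columns.
#' @param type `"class"` (logical calls) or `"prob"` (leaf positive
#'   proportion).
#' @param ... Unused.
#' @return Logical or numeric vector, one element per row of `newdata`.
#' @export
predict.cna_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss))
    stop("newdata is missing feature(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  nd <- object$nodes
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    id <- 1L
    while (!is.na(nd$feature[id])) {
      id <- if (X[i, nd$feature[id]] <= nd$threshold[id])
        nd$left[id] else nd$right[id]
    }
    out[i] <- nd$n_pos[id] / (nd$n_pos[id] + nd$n_neg[id])
  }
  if (type == "prob") out else out > 0.5
}

#' Classification metrics against known labels
#'
#' Accuracy is (TP + TN) / (TP + TN + FP + FN); sensitivity TP / (TP + FN);
#' specificity TN / (TN + FP); positive predictive value TP / (TP + FP).
#'
#' @param predictions Logical vector of calls.
#' @param truth Logical vector of true labels, same length.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `ppv` and the
#'   confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (!length(predictions)) stop("empty prediction vector")
  stopifnot(length(predictions) == length(truth))
  p <- as.logical(predictions); t <- as.logical(truth)
  tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
  list(accuracy = (tp + tn) / length(p),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

tree_to_list <- function(nodes, id) {
  if (is.na(nodes$feature[id])) {
    list(leaf = TRUE, n_pos = nodes$n_pos[id], n_neg = nodes$n_neg[id])
  } else {
    # thresholds as 17-significant-digit strings: decimal JSON numbers do not
    # round-trip doubles bit-exactly, %.17g does
    list(leaf = FALSE, feature = nodes$feature[id],
         threshold = sprintf("%.17g", nodes$threshold[id]),
         n_pos = nodes$n_pos[id], n_neg = nodes$n_neg[id],
         left = tree_to_list(nodes, nodes$left[id]),
         right = tree_to_list(nodes, nodes$right[id]))
  }
}

#' Serialize a tree to JSON
#'
#' Writes the tree as nested JSON nodes (feature, threshold, children, leaf
#' class counts) at full floating-point precision, so that
#' [read_tree_json()] restores a bit-exact equivalent model.
#'
#' @param tree A `cna_tree`.
#' @param path Output path.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(features = tree$features, root = tree_to_list(tree$nodes, 1L))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

list_to_nodes <- function(node, env) {
  id <- env$next_id
  env$next_id <- id + 1L
  row <- data.frame(id = id, feature = NA_integer_, threshold = NA_real_,
                    left = NA_integer_, right = NA_integer_,
                    n_pos = as.integer(node$n_pos),
                    n_neg = as.integer(node$n_neg))
  env$rows[[id]] <- row
  if (!isTRUE(node$leaf)) {
    env$rows[[id]]$feature <- as.integer(node$feature)
    env$rows[[id]]$threshold <- as.numeric(node$threshold)
    env$rows[[id]]$left <- list_to_nodes(node$left, env)
    env$rows[[id]]$right <- list_to_nodes(node$right, env)
  }
  id
}

#' Read a tree serialized by [write_tree_json()]
#'
#' @param path Path to the JSON model file.
#' @return A `cna_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  env <- new.env()
  env$next_id <- 1L
  env$rows <- list()
  list_to_nodes(obj$root, env)
  structure(list(nodes = do.call(rbind, env$rows),
                 features = unlist(obj$features)),
            class = "cna_tree")
}
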