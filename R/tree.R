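#' Build the binary diagnosis-code feature table
#'
#' One row per claim, one column per distinct truncated diagnosis code seen in
#' either arm, entries 1 when the code is present in the claim and 0
#' otherwise. Columns are ordered lexicographically (C locale), so column
#' order never depends on input order; every column has at least one nonzero
#' entry by construction, while claims with no diagnosis codes become all-zero
#' rows.
#'
#' @param claims A `claims_df`.
#' @param labels Binary vector (1 = service claim), one per claim.
#' @return An object of class `feature_table`: list with `matrix` (integer),
#'   `claim_ids`, `codes`, `labels`.
#' @export
build_feature_table <- function(claims, labels) {
  stopifnot(nrow(claims) > 0L, length(labels) == nrow(claims))
  codes <- sort(unique(unlist(claims$dx_codes, use.names = FALSE)),
                method = "radix")
  m <- matrix(0L, nrow(claims), length(codes),
              dimnames = list(NULL, codes))
  if (length(codes)) {
    lens <- lengths(claims$dx_codes)
    i <- rep.int(seq_len(nrow(claims)), lens)
    j <- match(unlist(claims$dx_codes, use.names = FALSE), codes)
    m[cbind(i, j)] <- 1L
  }
  structure(list(matrix = m, claim_ids = claims$claim_id, codes = codes,
                 labels = as.integer(labels != 0)),
            class = "feature_table")
}

#' Feature table for one arm pair of a matched sample
#'
#' Stacks the service and control claims of the requested arm, labelling
#' service claims 1.
#'
#' @param matched A `matched_sample` from [match_controls()].
#' @param arm `"train"` or `"valid"`.
#' @return A `feature_table`.
#' @export
sample_feature_table <- function(matched, arm = c("train", "valid")) {
  arm <- match.arg(arm)
  svc <- matched[[paste0("service_", arm)]]
  ctl <- matched[[paste0("control_", arm)]]
  build_feature_table(rbind(svc, ctl),
                      c(rep(1L, nrow(svc)), rep(0L, nrow(ctl))))
}

# Shannon entropy in bits of a two-class node, vectorized over count pairs.
entropy_bits <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  p <- ifelse(n > 0, n_pos / n, 0)
  q <- 1 - p
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + q[ok] * log2(q[ok]))
  h
}

# information gain of splitting a node (np positives out of n) on each code:
# k1 = rows with the code, k1p = positives among them. Invalid (one-sided)
# splits get -Inf.
split_gains <- function(n, np, k1, k1p) {
  k0 <- n - k1
  k0p <- np - k1p
  child <- (k1 * entropy_bits(k1p, k1 - k1p) +
              k0 * entropy_bits(k0p, k0 - k0p)) / n
  g <- entropy_bits(np, n - np) - child
  g[k1 == 0L | k0 == 0L] <- -Inf
  g
}

#' Fit an entropy classification tree on binary code indicators
#'
#' Greedy binary recursive partitioning: at each node the diagnosis code with
#' the largest information gain (entropy reduction, in bits) splits the
#' node's claims by code presence. Growth stops when a node is pure, all
#' feature patterns in it are identical (no valid split), the best gain is
#' non-positive, or the maximum depth is reached. Ties on gain are broken by
#' lexicographic code order, so the fit is deterministic and independent of
#' column order. Optional C4.5-style pessimistic pruning (subtree
#' replacement, confidence factor 0.25) is applied when `config$prune` is
#' set; the default leaves the full-depth tree intact so that as many
#' candidate codes as possible surface with positive importance.
#'
#' @param ft A [build_feature_table()] result with both classes present.
#' @param config A [study_config()]; uses `max_depth` and `prune`.
#' @return An object of class `tree_model`: list with `nodes` (data.frame:
#'   `id`, `depth`, `n`, `n_pos`, `entropy`, `split_code`, `gain`, `left`,
#'   `right`, `pred`), `n_root`, `max_depth_used`, `importance` (named
#'   numeric in (0,1], see [relative_importance()]).
#' @export
fit_tree <- function(ft, config = study_config()) {
  X <- ft$matrix
  y <- ft$labels
  if (length(unique(y)) < 2L) {
    stop(errorCondition(
      "degenerate tree: both classes must be present in the training labels",
      class = c("claimdef_degenerate_tree", "error", "condition")))
  }
  max_depth <- config$max_depth

  nodes <- vector("list", 64L)
  n_nodes <- 0L
  add_node <- function(rec) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(nodes)) length(nodes) <<- 2L * length(nodes)
    nodes[[n_nodes]] <<- rec
    n_nodes
  }

  # majority-vote leaf prediction, ties -> control (0)
  leaf_pred <- function(np, n) as.integer(np > n - np)

  grow <- function(idx, depth) {
    n <- length(idx)
    np <- sum(y[idx])
    h <- entropy_bits(np, n - np)
    id <- add_node(list(depth = depth, n = n, n_pos = np, entropy = h,
                        split_code = NA_character_, gain = NA_real_,
                        left = NA_integer_, right = NA_integer_,
                        pred = leaf_pred(np, n)))
    if (np == 0L || np == n || depth >= max_depth) return(id)
    Xs <- X[idx, , drop = FALSE]
    if (ncol(Xs) == 0L) return(id)
    k1 <- colSums(Xs)
    k1p <- if (np > 0L) colSums(Xs[y[idx] == 1L, , drop = FALSE]) else
      numeric(ncol(Xs))
    g <- split_gains(n, np, k1, k1p)
    best <- max(g)
    if (!is.finite(best) || best <= 0) return(id)
    j <- which(g >= best - 1e-12)[1L]  # ties: first = lexicographic smallest
    present <- Xs[, j] == 1L
    left <- grow(idx[present], depth + 1L)
    right <- grow(idx[!present], depth + 1L)
    nodes[[id]]$split_code <<- ft$codes[j]
    nodes[[id]]$gain <<- g[j]
    nodes[[id]]$left <<- left
    nodes[[id]]$right <<- right
    id
  }
  old_exp <- options(expressions = 500000L)
  on.exit(options(old_exp))
  root <- grow(seq_along(y), 0L)

  model <- structure(list(nodes = nodes_df(nodes[seq_len(n_nodes)]),
                          root = root, n_root = length(y)),
                     class = "tree_model")
  if (isTRUE(config$prune)) model <- prune_c45(model, cf = 0.25)
  model$max_depth_used <- max(model$nodes$depth[leaves_of(model)])
  model$importance <- relative_importance(model)
  model
}

nodes_df <- function(nlist) {
  data.frame(
    id = seq_along(nlist),
    depth = vapply(nlist, `[[`, integer(1L), "depth"),
    n = vapply(nlist, `[[`, integer(1L), "n"),
    n_pos = vapply(nlist, function(x) as.integer(x$n_pos), integer(1L)),
    entropy = vapply(nlist, `[[`, numeric(1L), "entropy"),
    split_code = vapply(nlist, `[[`, character(1L), "split_code"),
    gain = vapply(nlist, `[[`, numeric(1L), "gain"),
    left = vapply(nlist, `[[`, integer(1L), "left"),
    right = vapply(nlist, `[[`, integer(1L), "right"),
    pred = vapply(nlist, `[[`, integer(1L), "pred"),
    stringsAsFactors = FALSE
  )
}

leaves_of <- function(model) which(is.na(model$nodes$split_code))

# C4.5 pessimistic-error subtree replacement: a subtree is collapsed to a
# leaf when the leaf's upper-confidence error estimate (Clopper-Pearson at
# confidence factor cf) does not exceed the sum over its leaves.
prune_c45 <- function(model, cf = 0.25) {
  nd <- model$nodes
  ucl_errors <- function(id) {
    n <- nd$n[id]
    e <- min(nd$n_pos[id], n - nd$n_pos[id])
    n * stats::qbeta(1 - cf, e + 1, max(n - e, 0) + .Machine$double.eps)
  }
  walk <- function(id) {
    if (is.na(nd$split_code[id])) return(ucl_errors(id))
    sub <- walk(nd$left[id]) + walk(nd$right[id])
    as_leaf <- ucl_errors(id)
    if (as_leaf <= sub) {
      nd$split_code[id] <<- NA_character_
      nd$gain[id] <<- NA_real_
      nd$left[id] <<- NA_integer_
      nd$right[id] <<- NA_integer_
      return(as_leaf)
    }
    sub
  }
  walk(model$root)
  keep <- rep(FALSE, nrow(nd))
  mark <- function(id) {
    keep[id] <<- TRUE
    if (!is.na(nd$split_code[id])) {
      mark(nd$left[id]); mark(nd$right[id])
    }
  }
  mark(model$root)
  nd <- nd[keep, , drop = FALSE]
  remap <- match(seq_len(nrow(model$nodes)), nd$id)
  nd$left <- remap[nd$left]
  nd$right <- remap[nd$right]
  nd$id <- seq_len(nrow(nd))
  model$nodes <- nd
  model$root <- remap[model$root]
  model
}

#' Relative variable importance of a fitted tree
#'
#' The raw importance of a code is the sum, over the nodes that split on it,
#' of the node's information gain weighted by the fraction of training claims
#' reaching that node; relative importance rescales so the top code scores 1.
#' Codes never used in a split are absent from the map, so "positive relative
#' importance" is exactly "used somewhere in the tree".
#'
#' @param model A `tree_model`.
#' @return Named numeric vector in (0, 1], sorted by decreasing importance
#'   (ties broken lexicographically); empty for a leaf-only model.
#' @export
relative_importance <- function(model) {
  nd <- model$nodes
  sp <- !is.na(nd$split_code)
  if (!any(sp)) return(stats::setNames(numeric(), character()))
  raw <- tapply((nd$n[sp] / model$n_root) * nd$gain[sp], nd$split_code[sp], sum)
  rel <- raw / max(raw)
  ord <- order(-rel, names(rel), method = "radix")
  stats::setNames(as.numeric(rel[ord]), names(rel)[ord])
}

#' Predict service status for claims in a feature table
#'
#' Walks each claim down the tree; a split code missing from the feature
#' table's columns counts as absent. Leaf prediction is the leaf's majority
#' class, ties predicting control.
#'
#' @param model A `tree_model`.
#' @param ft A `feature_table`.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_tree <- function(model, ft) {
  nd <- model$nodes
  pred <- integer(nrow(ft$matrix))
  recurse <- function(id, rows) {
    if (!length(rows)) return(invisible())
    code <- nd$split_code[id]
    if (is.na(code)) {
      pred[rows] <<- nd$pred[id]
      return(invisible())
    }
    col <- match(code, ft$codes)
    present <- if (is.na(col)) rep(FALSE, length(rows)) else
      ft$matrix[rows, col] == 1L
    recurse(nd$left[id], rows[present])
    recurse(nd$right[id], rows[!present])
  }
  old_exp <- options(expressions = 500000L)
  on.exit(options(old_exp))
  recurse(model$root, seq_len(nrow(ft$matrix)))
  pred
}

#' Classification metrics from labels and predictions
#'
#' Sensitivity is the percentage of service claims predicted as service,
#' specificity the percentage of controls predicted as control, and the
#' misclassification rate the percentage of all claims predicted wrongly.
#' Percentages are reported half-up to 2 decimals.
#'
#' @param labels,pred Binary vectors.
#' @return An object of class `class_metrics`: list with `sensitivity`,
#'   `specificity`, `misclassification`, `n_pos`, `n_neg`.
#' @export
class_metrics <- function(labels, pred) {
  labels <- as.integer(labels != 0)
  pred <- as.integer(pred != 0)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  sens <- 100 * sum(pred == 1L & labels == 1L) / n_pos
  spec <- 100 * sum(pred == 0L & labels == 0L) / n_neg
  mis <- 100 * sum(pred != labels) / (n_pos + n_neg)
  structure(list(sensitivity = round_half_up(sens, 2L),
                 specificity = round_half_up(spec, 2L),
                 misclassification = round_half_up(mis, 2L),
                 n_pos = n_pos, n_neg = n_neg),
            class = "class_metrics")
}

#' Evaluate a fitted tree on a feature table
#'
#' @param model A `tree_model`.
#' @param ft A `feature_table` with labels (training or validation arm).
#' @return A [class_metrics()] object.
#' @export
evaluate <- function(model, ft) {
  class_metrics(ft$labels, predict_tree(model, ft))
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  misclassification %.2f%%  (n+ = %d, n- = %d)\n",
              x$sensitivity, x$specificity, x$misclassification,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf("tree_model: %d nodes, depth %d, %d codes with positive importance\n",
              nrow(x$nodes), x$max_depth_used, length(x$importance)))
  invisible(x)
}
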