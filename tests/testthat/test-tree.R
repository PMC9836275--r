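test_that("feature tables are binary, lexicographically ordered, truncation-merged", {
  cl <- mk_claims(list("S832", c("S832", "M171")))
  ft <- build_feature_table(cl, c(1L, 0L))
  expect_identical(ft$codes, c("M171", "S832"))
  expect_identical(unname(ft$matrix), matrix(c(0L, 1L, 1L, 1L), 2L))
  # two 5-char codes sharing a stem give one column with value 1
  cl2 <- mk_claims(list(c("M1711", "M1712")))
  ft2 <- build_feature_table(cl2, 1L)
  expect_identical(ft2$codes, "M171")
  expect_identical(unname(ft2$matrix), matrix(1L, 1L, 1L))
  # a claim with no codes is an all-zero row, not an error
  cl3 <- mk_claims(list("I10", character()))
  ft3 <- build_feature_table(cl3, c(1L, 0L))
  expect_identical(unname(ft3$matrix[2L, ]), 0L)
  # every column has at least one nonzero entry by construction
  expect_true(all(colSums(ft3$matrix) >= 1L))
})

test_that("a perfectly separating code yields a depth-1 tree with importance 1", {
  cl <- mk_claims(c(rep(list(c("S832", "I10")), 6L), rep(list("I10"), 6L)))
  ft <- build_feature_table(cl, rep(c(1L, 0L), each = 6L))
  model <- fit_tree(ft, study_config("29877"))
  expect_equal(model$max_depth_used, 1L)
  expect_identical(model$importance, c(S832 = 1))
  expect_equal(evaluate(model, ft)$sensitivity, 100)
  expect_equal(evaluate(model, ft)$misclassification, 0)
})

test_that("labels independent of every code give a single leaf and empty importance", {
  # each code splits 50/50 within both classes: zero gain everywhere
  dx <- list(c("A001"), c("A001"), character(), character(),
             c("A001"), c("A001"), character(), character())
  ft <- build_feature_table(mk_claims(dx), c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  model <- fit_tree(ft, study_config())
  expect_equal(nrow(model$nodes), 1L)
  expect_length(model$importance, 0L)
})

test_that("jointly informative codes both receive positive importance", {
  # XOR-like: label = presence of exactly one of A, B (asymmetric counts so
  # marginal gains are positive and greedy can find the joint structure)
  dx <- c(list(c("A001", "B001")), rep(list("A001"), 2L),
          rep(list("B001"), 2L), rep(list(character()), 3L))
  y <- c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L)
  ft <- build_feature_table(mk_claims(dx), y)
  model <- fit_tree(ft, study_config())
  expect_setequal(names(model$importance), c("A001", "B001"))
  expect_true(all(model$importance > 0))
  expect_equal(max(model$importance), 1)
  expect_equal(evaluate(model, ft)$misclassification, 0)
})

test_that("the greedy root split matches exhaustive search on small instances", {
  for (rep_i in 1:40) {
    set.seed(1000L + rep_i)
    n <- sample(4:12, 1L)
    p <- sample(2:4, 1L)
    X <- matrix(rbinom(n * p, 1L, 0.5), n, p,
                dimnames = list(NULL, sort(paste0("C", 1:p, "00"))))
    y <- rbinom(n, 1L, 0.5)
    if (length(unique(y)) < 2L) next
    cl <- mk_claims(apply(X == 1L, 1L, function(r) colnames(X)[r],
                          simplify = FALSE))
    ft <- build_feature_table(cl, y)
    oracle <- brute_force_root_split(X[, ft$codes, drop = FALSE], y)
    model <- fit_tree(ft, study_config())
    root_code <- model$nodes$split_code[model$root]
    if (is.na(oracle)) expect_true(is.na(root_code)) else
      expect_identical(root_code, oracle)
  }
})

test_that("every accepted split strictly reduces weighted entropy", {
  truth <- small_truth(n_claims = 2500L)
  cl <- generate_population(truth, 3L)
  cfg <- study_config("29877", train_max = 150L, valid_max = 30L, seed = 2L)
  s <- select_service_claims(cl, cfg)
  m <- match_controls(s$train, s$valid, cl, cfg)
  ft <- sample_feature_table(m, "train")
  model <- fit_tree(ft, cfg)
  splits <- !is.na(model$nodes$split_code)
  expect_true(any(splits))
  expect_true(all(model$nodes$gain[splits] > 0))
  # children partition the parent's claims
  nd <- model$nodes
  for (id in which(splits)) {
    expect_equal(nd$n[nd$left[id]] + nd$n[nd$right[id]], nd$n[id])
    expect_equal(nd$n_pos[nd$left[id]] + nd$n_pos[nd$right[id]], nd$n_pos[id])
  }
})

test_that("importance is the normalized claim-weighted gain and ignores column order", {
  # hand-checkable two-split model: root gain 0.8 on all 100 claims, child
  # gain 0.5 on 40 -> raw 0.8 and 0.2, relative 1.0 and 0.25
  model <- structure(list(
    nodes = data.frame(
      id = 1:5, depth = c(0L, 1L, 1L, 2L, 2L), n = c(100L, 40L, 60L, 20L, 20L),
      n_pos = c(50L, 20L, 30L, 10L, 10L), entropy = c(1, 1, 1, 0, 0),
      split_code = c("A001", "B001", NA, NA, NA), gain = c(0.8, 0.5, NA, NA, NA),
      left = c(2L, 4L, NA, NA, NA), right = c(3L, 5L, NA, NA, NA),
      pred = c(0L, 0L, 1L, 0L, 1L), stringsAsFactors = FALSE),
    root = 1L, n_root = 100L), class = "tree_model")
  expect_equal(relative_importance(model), c(A001 = 1, B001 = 0.25))

  # column/input order invariance on generated data
  truth <- small_truth(n_claims = 2000L)
  cl <- generate_population(truth, 5L)
  y <- as.integer(has_service(cl, study_config("29877")))
  cl_rev <- cl
  cl_rev$dx_codes <- lapply(cl$dx_codes, rev)
  perm <- rev(seq_len(nrow(cl)))
  m1 <- fit_tree(build_feature_table(cl, y), study_config())
  m2 <- fit_tree(build_feature_table(cl_rev[perm, ], y[perm]), study_config())
  expect_equal(m1$importance, m2$importance)
})

test_that("classification metrics follow the confusion-count arithmetic", {
  mk <- function(n_pos, n_neg, tp, tn) {
    labels <- c(rep(1L, n_pos), rep(0L, n_neg))
    pred <- c(rep(1L, tp), rep(0L, n_pos - tp),
              rep(1L, n_neg - tn), rep(0L, tn))
    class_metrics(labels, pred)
  }
  m <- mk(5000L, 5000L, 4411L, 4781L)
  expect_equal(m$sensitivity, 88.22)
  expect_equal(m$specificity, 95.62)
  expect_equal(m$misclassification, 8.08)
  # misclassification is the complement of the count-weighted mean accuracy
  expect_equal(m$misclassification,
               100 - (m$sensitivity * m$n_pos + m$specificity * m$n_neg) /
                 (m$n_pos + m$n_neg))
  perfect <- mk(100L, 100L, 100L, 100L)
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$misclassification), c(100, 100, 0))
  allneg <- mk(100L, 100L, 0L, 100L)
  expect_equal(c(allneg$sensitivity, allneg$specificity,
                 allneg$misclassification), c(0, 100, 50))
})

test_that("single-class training input is rejected", {
  ft <- build_feature_table(mk_claims(list("A001", "B001")), c(1L, 1L))
  expect_error(fit_tree(ft, study_config()),
               class = "claimdef_degenerate_tree")
})

test_that("pessimistic pruning shrinks an overfitted tree", {
  set.seed(99)
  n <- 400L
  dx <- replicate(n, paste0("N", sprintf("%03d", sample(0:49, 6L))),
                  simplify = FALSE)
  y <- rbinom(n, 1L, 0.5)  # pure noise
  ft <- build_feature_table(mk_claims(dx), y)
  full <- fit_tree(ft, study_config(prune = FALSE))
  pruned <- fit_tree(ft, study_config(prune = TRUE))
  expect_lt(nrow(pruned$nodes), nrow(full$nodes))
  expect_lte(length(pruned$importance), length(full$importance))
  # pruning preserves the node bookkeeping invariants
  nd <- pruned$nodes
  sp <- which(!is.na(nd$split_code))
  for (id in sp) {
    expect_equal(nd$n[nd$left[id]] + nd$n[nd$right[id]], nd$n[id])
  }
})

test_that("prediction treats codes unseen in training as absent", {
  cl <- mk_claims(c(rep(list("S832"), 5L), rep(list(character()), 5L)))
  ft <- build_feature_table(cl, rep(c(1L, 0L), each = 5L))
  model <- fit_tree(ft, study_config())
  # the split code exists in the new table: routing follows its value
  new_ft <- build_feature_table(mk_claims(list("Z999", "S832")), c(0L, 1L))
  expect_identical(predict_tree(model, new_ft), c(0L, 1L))
  # the split code is absent from the new table entirely: counts as 0
  new_ft2 <- build_feature_table(mk_claims(list("Z999")), 1L)
  expect_identical(predict_tree(model, new_ft2), 0L)
})
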