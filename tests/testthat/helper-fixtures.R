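# Build a claims_df directly from a list of dx-code vectors.
mk_claims <- function(dx, age = 70L, sex = "F", setting = "carrier",
                      service = FALSE, service_code = "29877",
                      id_prefix = "C") {
  n <- length(dx)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  service <- rep_len(service, n)
  svc <- lapply(service, function(s) if (s) service_code else character())
  claimdef:::new_claims(data.frame(
    claim_id = paste0(id_prefix, seq_len(n)),
    patient_id = paste0("P", seq_len(n)),
    age = age, sex = sex, setting = rep_len(setting, n),
    service_codes = I(svc), dx_codes = I(dx),
    stringsAsFactors = FALSE
  ))
}

# Minimal matched_sample wrapper around explicit train arms.
mk_matched <- function(service_train, control_train,
                       service_valid = NULL, control_valid = NULL) {
  empty <- service_train[0, , drop = FALSE]
  structure(list(
    service_train = service_train, control_train = control_train,
    service_valid = if (is.null(service_valid)) empty else service_valid,
    control_valid = if (is.null(control_valid)) empty else control_valid,
    match_report = data.frame(), n_unmatched = 0L
  ), class = "matched_sample")
}

# A small synthetic-population spec for fast generator tests.
small_truth <- function(...) {
  sim_truth_default(n_claims = 4000L, n_filler = 30L, ...)
}

# Independent beta-quantile oracle: bisection inversion of the regularized
# incomplete beta function (pbeta), never qbeta.
beta_quantile_bisect <- function(q, a, b, tol = 1e-12) {
  lo <- 0
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pbeta(mid, a, b) < q) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force iterative grouping by explicit set subtraction.
brute_force_groups <- function(dx, ranked_codes) {
  remaining <- seq_along(dx)
  out <- list()
  for (code in ranked_codes) {
    members <- remaining[vapply(dx[remaining], function(d) code %in% d,
                                logical(1L))]
    if (!length(members)) next
    out[[length(out) + 1L]] <- list(code = code, members = members)
    remaining <- setdiff(remaining, members)
  }
  list(groups = out, unassigned = remaining)
}

# Service sample shaped like the knee-arthroscopy worked example: 1,906
# claims carry the top code, 1,544 carry the second, 532 carry both, the
# remainder carry neither (5,000 claims overall).
grouping_fixture <- function() {
  dx <- c(rep(list(c("S832", "M942")), 532L),
          rep(list("S832"), 1906L - 532L),
          rep(list("M942"), 1544L - 532L),
          rep(list("X000"), 5000L - 1906L - (1544L - 532L)))
  mk_claims(dx)
}

# Build a masked table whose per-code total ranges equal `ranges` (named
# list of c(lo, hi)), by giving each code (hi-lo)/9 masked cells plus an
# exact remainder cell. Group structure is immaterial to the count engine.
masked_from_ranges <- function(ranges, sample_n = 5000L, threshold = 11L) {
  cells <- do.call(rbind, lapply(names(ranges), function(code) {
    lo <- ranges[[code]][1L]
    hi <- ranges[[code]][2L]
    n_masked <- (hi - lo) / (threshold - 2L)
    stopifnot(n_masked == round(n_masked), lo >= n_masked)
    exact <- lo - n_masked
    rbind(
      if (exact > 0L) data.frame(rank = 1L, group_code = "G1", code = code,
                                 cell_lo = as.integer(exact),
                                 cell_hi = as.integer(exact)),
      if (n_masked > 0L) data.frame(rank = seq_len(n_masked) + 1L,
                                    group_code = paste0("G", seq_len(n_masked) + 1L),
                                    code = code, cell_lo = 1L,
                                    cell_hi = threshold - 1L)
    )
  }))
  ranks <- sort(unique(cells$rank))
  structure(list(
    sample_n = sample_n, mask_threshold = threshold,
    groups = data.frame(rank = ranks, group_code = paste0("G", ranks),
                        member_lo = 100L, member_hi = 100L, pct = NA_real_),
    cells = cells, unassigned_lo = 0L, unassigned_hi = 0L),
    class = "masked_group_table")
}

# 26 exclusion codes with their count ranges in a 5,000-claim sample
# (spinal-fusion style worked example: cancer, cauda equina, discitis,
# fracture, osteomyelitis, scoliosis and kyphosis criteria).
exclusion_ranges <- list(
  Z858 = c(228L, 264L), C795 = c(5L, 50L), M845 = c(4L, 40L),
  C794 = c(1L, 10L), D166 = c(1L, 10L), G834 = c(33L, 69L),
  M464 = c(7L, 70L), M463 = c(1L, 10L), S320 = c(22L, 67L),
  M800 = c(4L, 40L), M844 = c(3L, 30L), M808 = c(3L, 30L),
  S321 = c(3L, 30L), S220 = c(3L, 30L), M846 = c(2L, 20L),
  M462 = c(9L, 90L), M418 = c(183L, 255L), M419 = c(158L, 239L),
  M412 = c(33L, 60L), M415 = c(19L, 37L), M411 = c(3L, 30L),
  M413 = c(2L, 20L), M402 = c(48L, 111L), M963 = c(4L, 40L),
  M400 = c(2L, 20L), M401 = c(3L, 30L)
)

# Exhaustive search for the information-gain-maximal root split (entropy in
# bits computed from scratch), with the same larger-gain-then-lexicographic
# tie rule the tree engine promises.
brute_force_root_split <- function(X, y) {
  ent <- function(yy) {
    if (!length(yy)) return(0)
    p <- mean(yy)
    if (p == 0 || p == 1) return(0)
    -(p * log2(p) + (1 - p) * log2(1 - p))
  }
  n <- length(y)
  gains <- vapply(seq_len(ncol(X)), function(j) {
    inL <- X[, j] == 1L
    if (!any(inL) || all(inL)) return(-Inf)
    ent(y) - (sum(inL) * ent(y[inL]) + sum(!inL) * ent(y[!inL])) / n
  }, numeric(1L))
  best <- max(gains)
  if (!is.finite(best) || best <= 0) return(NA_character_)
  colnames(X)[which(gains >= best - 1e-12)[1L]]
}
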