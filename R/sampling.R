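#' Select the service-claim training and validation samples
#'
#' Restricts claims to the configured setting, the configured service
#' (prefix match on service codes) and the minimum age, then draws the
#' training and validation samples. When at least `train_max + valid_max`
#' claims are eligible, a simple random sample without replacement of exactly
#' `train_max` training and `valid_max` validation claims is taken. Smaller
#' cohorts are used in full and split at the `train_max:valid_max` ratio
#' (default 5:1), with the training side receiving the rounding remainder
#' (half-up), so e.g. 1,364 eligible claims yield 1,137 training and 227
#' validation claims.
#'
#' @param claims A `claims_df`.
#' @param config A [study_config()]; uses `setting`, `min_age`,
#'   `service_code_prefixes`, `train_max`, `valid_max` and `seed`.
#' @return A list with `claims_df` elements `train` and `valid`.
#' @export
select_service_claims <- function(claims, config) {
  eligible <- claims[claims$setting == config$setting &
                       claims$age >= config$min_age &
                       has_service(claims, config), , drop = FALSE]
  n <- nrow(eligible)
  if (n == 0L) {
    stop(errorCondition("no eligible service claims in the configured setting",
                        class = c("claimdef_empty_cohort", "error", "condition")))
  }
  tmax <- config$train_max
  vmax <- config$valid_max
  with_seed(config$seed, {
    if (n >= tmax + vmax) {
      pick <- sample.int(n, tmax + vmax)
      n_train <- tmax
    } else {
      pick <- sample.int(n, n)
      n_train <- as.integer(min(n, round_half_up(n * tmax / (tmax + vmax), 0)))
    }
    train <- eligible[pick[seq_len(n_train)], , drop = FALSE]
    valid <- eligible[pick[setdiff(seq_along(pick), seq_len(n_train))], ,
                      drop = FALSE]
  })
  rownames(train) <- rownames(valid) <- NULL
  list(train = train, valid = valid)
}

# greedy 1:1 nearest-neighbour matching of one service arm against the pool.
# Exact on sex; exact on dx count, widening the dx-count tolerance to +-1,
# +-2, +-3 if no exact match is available; nearest age within the admitted
# candidates, ties broken by a seeded random draw. `avail` is a logical
# vector over pool rows shared across arms so no control is reused.
match_one_arm <- function(service, pool, avail, arm) {
  n_pool <- nrow(pool)
  key <- paste(pool$sex, pool$ndx)
  buckets <- split(seq_len(n_pool), key)
  order_idx <- sample.int(nrow(service))
  ctrl <- integer(nrow(service))  # 0 = unmatched
  for (i in order_idx) {
    s_sex <- service$sex[i]
    s_ndx <- service$ndx[i]
    s_age <- service$age[i]
    found <- 0L
    for (tol in 0:3) {
      offs <- unique(c(0L, seq_len(tol), -seq_len(tol)))
      cand <- integer()
      for (o in offs) {
        b <- buckets[[paste(s_sex, s_ndx + o)]]
        if (!is.null(b)) cand <- c(cand, b[avail[b]])
      }
      if (length(cand)) {
        d <- abs(pool$age[cand] - s_age)
        best <- cand[d == min(d)]
        found <- if (length(best) == 1L) best else
          best[sample.int(length(best), 1L)]
        break
      }
    }
    if (found > 0L) {
      avail[found] <- FALSE
      ctrl[i] <- found
    }
  }
  list(ctrl = ctrl, avail = avail, arm = arm)
}

#' Match non-service control claims 1:1 to the service samples
#'
#' Greedy nearest-neighbour matching without replacement, processing service
#' claims in seeded random order: exact on sex, exact on the number of
#' diagnosis codes (tolerance widened stepwise to +-3 only when no exact
#' dx-count match remains), and nearest age among admitted candidates with
#' random tie-breaks. Matching balances the arms on the demographic drivers
#' of code prevalence so that codes confounded with age, sex or coding
#' intensity do not masquerade as service indications. Service claims with no
#' admissible control are dropped from both arms and reported; a warning is
#' raised when more than 5% of service claims go unmatched. Validation
#' controls are matched the same way, after (and disjoint from) the training
#' controls.
#'
#' @param service_train,service_valid `claims_df` samples from
#'   [select_service_claims()]. `service_valid` may have zero rows.
#' @param pool A `claims_df` of candidate controls; claims carrying the
#'   service, from other settings, or under the age minimum are dropped here.
#' @param config A [study_config()].
#' @return An object of class `matched_sample`: a list with `claims_df`
#'   elements `service_train`, `control_train`, `service_valid`,
#'   `control_valid`, a `match_report` data.frame (one row per pair: ids,
#'   ages, age difference, sex, dx counts, arm), and `n_unmatched`.
#' @export
match_controls <- function(service_train, service_valid, pool, config) {
  pool <- pool[pool$setting == config$setting &
                 pool$age >= config$min_age &
                 !has_service(pool, config), , drop = FALSE]
  if (nrow(pool) == 0L) {
    stop(errorCondition("control pool is empty after eligibility filtering",
                        class = c("claimdef_empty_pool", "error", "condition")))
  }
  rownames(pool) <- NULL
  pool$ndx <- dx_count(pool)
  service_train$ndx <- dx_count(service_train)
  service_valid$ndx <- dx_count(service_valid)

  with_seed(config$seed + 1L, {
    avail <- rep(TRUE, nrow(pool))
    m_tr <- match_one_arm(service_train, pool, avail, "train")
    m_va <- if (nrow(service_valid)) {
      match_one_arm(service_valid, pool, m_tr$avail, "valid")
    } else list(ctrl = integer())
  })

  take <- function(service, m, arm) {
    ok <- m$ctrl > 0L
    ctrl <- pool[m$ctrl[ok], , drop = FALSE]
    svc <- service[ok, , drop = FALSE]
    report <- data.frame(
      arm = rep(arm, sum(ok)),
      service_claim_id = svc$claim_id,
      control_claim_id = ctrl$claim_id,
      age_service = svc$age, age_control = ctrl$age,
      age_diff = abs(svc$age - ctrl$age),
      sex = svc$sex, dx_count_service = svc$ndx, dx_count_control = ctrl$ndx,
      stringsAsFactors = FALSE
    )
    svc$ndx <- NULL
    ctrl$ndx <- NULL
    rownames(svc) <- rownames(ctrl) <- NULL
    list(service = svc, control = ctrl, report = report,
         n_unmatched = sum(!ok))
  }
  tr <- take(service_train, m_tr, "train")
  va <- take(service_valid, m_va, "valid")
  n_unmatched <- tr$n_unmatched + va$n_unmatched
  n_service <- nrow(service_train) + nrow(service_valid)
  if (n_service > 0 && n_unmatched / n_service > 0.05) {
    warning(sprintf("%d of %d service claims (%.1f%%) could not be matched and were dropped",
                    n_unmatched, n_service, 100 * n_unmatched / n_service))
  }
  structure(list(
    service_train = tr$service, control_train = tr$control,
    service_valid = va$service, control_valid = va$control,
    match_report = rbind(tr$report, va$report),
    n_unmatched = n_unmatched
  ), class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("matched_sample: %d train + %d validation pairs (%d unmatched, dropped)\n",
              nrow(x$service_train), nrow(x$service_valid), x$n_unmatched))
  cat(sprintf("  mean |age difference|: %.3f years\n",
              mean(x$match_report$age_diff)))
  invisible(x)
}
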