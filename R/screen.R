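#' Beta-distribution proportion interval
#'
#' Interval for the true proportion of claims carrying a code, from `k`
#' carriers out of `n` claims. The proportion is modelled as a beta
#' distribution with shapes `alpha = 1 + k` and `beta = 1 + n - k` (a uniform
#' prior updated by the observed counts), and the interval is the pair of
#' beta quantiles at the configured levels — by default the 5th and 95th
#' percentiles. The interval is wide where the proportion is near 50% (e.g.
#' 2,500 of 5,000 gives 0.49–0.51) and narrow where it is small (100 of 5,000
#' gives 0.017–0.024).
#'
#' @param k Number of claims carrying the code, `0 <= k <= n` (vectorized).
#' @param n Total claims in the arm, `n >= 1`.
#' @param quantiles Length-2 numeric, lower and upper quantile levels.
#' @return A data.frame with columns `k`, `n`, `p`, `alpha`, `beta`, `lo`,
#'   `hi`, one row per element of `k`.
#' @examples
#' beta_interval(246, 1364)   # 16.40% to 19.82%
#' @export
beta_interval <- function(k, n, quantiles = c(0.05, 0.95)) {
  if (any(n < 1)) {
    stop(errorCondition("n must be at least 1",
                        class = c("claimdef_domain_error", "error", "condition")))
  }
  if (any(k < 0) || any(k > n)) {
    stop(errorCondition("k must satisfy 0 <= k <= n",
                        class = c("claimdef_domain_error", "error", "condition")))
  }
  stopifnot(length(quantiles) == 2L, quantiles[1L] < quantiles[2L])
  alpha <- 1 + k
  beta_ <- 1 + n - k
  data.frame(
    k = k, n = n, p = k / n, alpha = alpha, beta = beta_,
    lo = stats::qbeta(quantiles[1L], alpha, beta_),
    hi = stats::qbeta(quantiles[2L], alpha, beta_)
  )
}

#' Screen important codes by proportion-interval overlap
#'
#' For each code with positive tree importance, compares the proportion of
#' training service claims carrying the code against the proportion of
#' training control claims carrying it, each summarized by a
#' [beta_interval()]. A code is retained only when its service interval lies
#' strictly above its control interval (`lo_service > hi_control`): overlap —
#' even a shared endpoint — removes the code, as does a code that is
#' credibly LESS frequent in service claims, since only codes more frequent
#' in service claims are candidate indications.
#'
#' @param importance Named numeric vector from [relative_importance()].
#' @param matched A `matched_sample`; counts come from the training arms.
#' @param config A [study_config()]; supplies the interval quantile levels.
#' @return A data.frame of class `code_screen`, one row per important code,
#'   sorted by decreasing importance (ties lexicographic): `code`,
#'   `importance`, `k_service`, `k_control`, `n_service`, `n_control`,
#'   `lo_service`, `hi_service`, `lo_control`, `hi_control`, `retained`.
#' @export
screen_codes <- function(importance, matched, config = study_config()) {
  codes <- names(importance)
  ord <- order(-importance, codes, method = "radix")
  codes <- codes[ord]
  imp <- as.numeric(importance[ord])

  count_in <- function(claims) {
    present <- unlist(lapply(claims$dx_codes, unique), use.names = FALSE)
    tab <- table(factor(present, levels = codes))
    as.integer(tab)
  }
  k_s <- count_in(matched$service_train)
  k_c <- count_in(matched$control_train)
  if (any(k_s + k_c == 0L)) {
    stop(errorCondition(
      sprintf("important code %s absent from both training arms; importance and sample are inconsistent",
              codes[which(k_s + k_c == 0L)[1L]]),
      class = c("claimdef_consistency_error", "error", "condition")))
  }
  n_s <- nrow(matched$service_train)
  n_c <- nrow(matched$control_train)
  q <- config$interval_quantiles
  iv_s <- beta_interval(k_s, n_s, q)
  iv_c <- beta_interval(k_c, n_c, q)
  out <- data.frame(
    code = codes, importance = imp,
    k_service = k_s, k_control = k_c,
    n_service = n_s, n_control = n_c,
    lo_service = iv_s$lo, hi_service = iv_s$hi,
    lo_control = iv_c$lo, hi_control = iv_c$hi,
    retained = iv_s$lo > iv_c$hi,
    stringsAsFactors = FALSE
  )
  class(out) <- c("code_screen", "data.frame")
  out
}

#' Ranked codes surviving the screen
#' @param screen A `code_screen` table.
#' @return Character vector of retained codes, in screen (importance) order.
#' @export
retained_codes <- function(screen) {
  screen$code[screen$retained]
}
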