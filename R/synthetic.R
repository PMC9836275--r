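#' Specify a synthetic claims population with known ground truth
#'
#' Describes a Medicare-like claims population in which some diagnosis codes
#' are true indications for a service (enriched in service claims), some are
#' confounders (tied to age, sex and diagnosis count, which also drive
#' service use), some are background comorbidities (equal prevalence in both
#' arms given the matching variables), and the rest of each claim's diagnosis
#' list is padded from a pool of low-information filler codes. Because the
#' generating mechanism is known, every downstream stage — matching, tree,
#' interval screen, grouping, masking — can be tested for parameter recovery
#' without access to restricted claims data.
#'
#' Service status is generated from indication-code presence through a
#' logistic link (not the other way around): each indication code is drawn at
#' its marginal prevalence, and its coefficient in the service model is the
#' log odds ratio implied by its two arm prevalences, so the realized
#' enrichment approximates the configured one while diagnosis counts stay
#' directly controllable. Demographic terms in the same model create the
#' confounding that matching is meant to remove.
#'
#' @param indication data.frame with columns `code`, `prev_service`,
#'   `prev_control`: per-arm prevalence of each true indication code.
#' @param background data.frame with columns `code`, `prev`: comorbidity codes
#'   with the same prevalence in both arms.
#' @param confounder data.frame with columns `code`, `base_prev`, `beta_age`,
#'   `beta_sexF`, `beta_ndx`: presence follows a logistic model on
#'   standardized age, female sex and standardized diagnosis count, identical
#'   in both arms given those covariates.
#' @param service_rate Target fraction of claims carrying the service.
#' @param n_claims Number of claims to generate.
#' @param setting Claim setting written on every claim.
#' @param service_code The service/procedure code written on service claims.
#' @param svc_beta_age,svc_beta_sexF,svc_beta_ndx Demographic coefficients of
#'   the service model (these induce confounding).
#' @param sex_ratio_f Probability a claim's patient is female.
#' @param age_p_under65 Fraction of (disability-entitled) patients under 65.
#' @param age_shape,age_scale Gamma parameters for years above 65.
#' @param dx_nb_size,dx_nb_mu Negative-binomial parameters for the per-claim
#'   diagnosis count, shifted by 1 (so the default mean is 8).
#' @param dx_max Cap on diagnosis codes per claim (claims formats have a
#'   fixed number of diagnosis slots).
#' @param n_filler Size of the filler-code pool (Zipf-weighted).
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(indication,
                      background,
                      confounder = NULL,
                      service_rate = 0.15,
                      n_claims = 50000L,
                      setting = "carrier",
                      service_code = "29877",
                      svc_beta_age = 0.3,
                      svc_beta_sexF = -0.2,
                      svc_beta_ndx = 0.3,
                      sex_ratio_f = 0.55,
                      age_p_under65 = 0.09,
                      age_shape = 2,
                      age_scale = 5,
                      dx_nb_size = 3,
                      dx_nb_mu = 7,
                      dx_max = 25L,
                      n_filler = 240L) {
  indication <- as.data.frame(indication)
  background <- as.data.frame(background)
  stopifnot(all(c("code", "prev_service", "prev_control") %in% names(indication)),
            all(c("code", "prev") %in% names(background)))
  if (is.null(confounder)) {
    confounder <- data.frame(code = character(), base_prev = numeric(),
                             beta_age = numeric(), beta_sexF = numeric(),
                             beta_ndx = numeric())
  }
  confounder <- as.data.frame(confounder)
  indication$code <- normalize_dx_code(indication$code)
  background$code <- normalize_dx_code(background$code)
  if (nrow(confounder)) confounder$code <- normalize_dx_code(confounder$code)
  probs <- c(indication$prev_service, indication$prev_control,
             background$prev, confounder$base_prev,
             service_rate, sex_ratio_f, age_p_under65)
  if (any(probs < 0 | probs > 1)) {
    stop(errorCondition("all prevalences/probabilities must lie in [0, 1]",
                        class = c("claimdef_spec_error", "error", "condition")))
  }
  all_codes <- c(indication$code, background$code, confounder$code)
  if (anyDuplicated(all_codes)) {
    stop(errorCondition(
      "indication, background and confounder codes must be disjoint",
      class = c("claimdef_spec_error", "error", "condition")))
  }
  # capacity: expected structural codes per claim must fit the dx-count budget
  marg_ind <- service_rate * indication$prev_service +
    (1 - service_rate) * indication$prev_control
  expected_struct <- sum(marg_ind) + sum(background$prev) +
    sum(confounder$base_prev)
  mean_dx <- 1 + dx_nb_mu
  if (expected_struct > mean_dx) {
    stop(errorCondition(
      sprintf("configured prevalences imply %.1f structural codes per claim on average, exceeding the mean diagnosis count %.1f",
              expected_struct, mean_dx),
      class = c("claimdef_spec_error", "error", "condition")))
  }
  structure(list(
    indication = indication, background = background, confounder = confounder,
    service_rate = service_rate, n_claims = as.integer(n_claims),
    setting = setting, service_code = service_code,
    svc_beta_age = svc_beta_age, svc_beta_sexF = svc_beta_sexF,
    svc_beta_ndx = svc_beta_ndx,
    sex_ratio_f = sex_ratio_f, age_p_under65 = age_p_under65,
    age_shape = age_shape, age_scale = age_scale,
    dx_nb_size = dx_nb_size, dx_nb_mu = dx_nb_mu, dx_max = as.integer(dx_max),
    n_filler = as.integer(n_filler)
  ), class = "sim_truth")
}

#' Default synthetic-population specification
#'
#' The fixture population used throughout the package's tests and examples:
#' 50,000 carrier claims, a 15% service rate, 10 indication codes at 10-fold
#' enrichment (service prevalence 6–45%), 20 equal-prevalence background
#' comorbidities, 4 demographically driven confounder codes, and a 240-code
#' filler pool, for roughly 270 distinct codes overall.
#'
#' @param ... Overrides passed on to [sim_truth()].
#' @return A `sim_truth` object.
#' @export
sim_truth_default <- function(...) {
  ind_prev <- c(0.45, 0.35, 0.30, 0.25, 0.20, 0.15, 0.12, 0.10, 0.08, 0.06)
  indication <- data.frame(
    code = c("S832", "M942", "M224", "M171", "M232",
             "M233", "M239", "M255", "M170", "S836"),
    prev_service = ind_prev,
    prev_control = ind_prev / 10
  )
  background <- data.frame(
    code = c("I10", "E785", "E119", "I251", "N179", "J449", "F329", "G473",
             "K219", "M810", "D649", "E039", "I489", "N183", "H409", "L309",
             "M545", "R600", "E669", "I341"),
    prev = c(0.35, 0.30, 0.22, 0.15, 0.05, 0.12, 0.10, 0.08,
             0.14, 0.07, 0.06, 0.11, 0.09, 0.04, 0.05, 0.03,
             0.20, 0.06, 0.13, 0.02)
  )
  confounder <- data.frame(
    code = c("Z794", "I509", "N390", "R296"),
    base_prev = c(0.15, 0.10, 0.12, 0.08),
    beta_age = c(0.5, 0.9, 0.6, 0.8),
    beta_sexF = c(0.0, 0.1, 0.7, 0.2),
    beta_ndx = c(0.8, 0.7, 0.5, 0.9)
  )
  defaults <- list(indication = indication, background = background,
                   confounder = confounder)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_truth, args)
}

# filler code names: X000..X239 (never overlaps the structural code sets)
filler_codes <- function(truth) {
  if (truth$n_filler < 1L) return(character())
  sprintf("X%03d", seq_len(truth$n_filler) - 1L)
}

#' Generate a synthetic claims population
#'
#' Deterministic given `(truth, seed)`. See [sim_truth()] for the generating
#' model. Each claim's diagnosis list contains its structural codes
#' (indication/background/confounder draws) followed by filler codes sampled
#' from a Zipf-weighted pool up to the claim's drawn diagnosis count.
#'
#' @param truth A [sim_truth()] specification.
#' @param seed Integer seed.
#' @return A `claims_df` with `truth$n_claims` rows.
#' @export
generate_population <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  n <- truth$n_claims
  if (n < 1L) {
    stop(errorCondition("n_claims must be positive",
                        class = c("claimdef_spec_error", "error", "condition")))
  }
  with_seed(seed, {
    # demographics
    under <- stats::runif(n) < truth$age_p_under65
    age <- integer(n)
    age[under] <- sample(45:64, sum(under), replace = TRUE)
    age[!under] <- pmin(99L, 65L + as.integer(
      stats::rgamma(sum(!under), shape = truth$age_shape, scale = truth$age_scale)))
    sex <- ifelse(stats::runif(n) < truth$sex_ratio_f, "F", "M")
    ndx <- 1L + stats::rnbinom(n, size = truth$dx_nb_size, mu = truth$dx_nb_mu)
    ndx <- pmin(ndx, truth$dx_max)
    z_age <- (age - 75) / 10
    z_ndx <- (ndx - (1 + truth$dx_nb_mu)) / 4

    # indication-code presence at marginal prevalence
    ind <- truth$indication
    n_ind <- nrow(ind)
    rho <- truth$service_rate
    X_ind <- matrix(0L, n, n_ind)
    if (n_ind) {
      marg <- rho * ind$prev_service + (1 - rho) * ind$prev_control
      for (j in seq_len(n_ind)) {
        X_ind[, j] <- as.integer(stats::runif(n) < marg[j])
      }
    }

    # service via logistic link: per-code log odds ratio + demographic terms,
    # intercept calibrated so the realized mean service probability is rho
    lor <- if (n_ind) log(ind$prev_service / (1 - ind$prev_service)) -
      log(ind$prev_control / (1 - ind$prev_control)) else numeric()
    eta0 <- drop(X_ind %*% lor) + truth$svc_beta_age * z_age +
      truth$svc_beta_sexF * (sex == "F") + truth$svc_beta_ndx * z_ndx
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) - rho,
                         lower = -30, upper = 30)$root
    service <- stats::runif(n) < stats::plogis(b0 + eta0)

    # confounders: logistic on covariates only (no direct service term)
    conf <- truth$confounder
    X_conf <- matrix(0L, n, nrow(conf))
    for (j in seq_len(nrow(conf))) {
      p <- stats::plogis(stats::qlogis(conf$base_prev[j]) +
                           conf$beta_age[j] * z_age +
                           conf$beta_sexF[j] * (sex == "F") +
                           conf$beta_ndx[j] * z_ndx)
      X_conf[, j] <- as.integer(stats::runif(n) < p)
    }

    # background comorbidities: equal prevalence everywhere
    bg <- truth$background
    X_bg <- matrix(0L, n, nrow(bg))
    for (j in seq_len(nrow(bg))) {
      X_bg[, j] <- as.integer(stats::runif(n) < bg$prev[j])
    }

    struct_codes <- c(ind$code, conf$code, bg$code)
    X_struct <- cbind(X_ind, X_conf, X_bg)
    n_struct <- as.integer(rowSums(X_struct))

    # assemble dx lists: structural codes (shuffled within claim), then filler
    pool <- filler_codes(truth)
    dx <- vector("list", n)
    struct_list <- apply(X_struct == 1L, 1L, function(r) struct_codes[r],
                         simplify = FALSE)
    fill_n <- pmax(0L, ndx - n_struct)
    if (length(pool)) {
      w <- 1 / seq_along(pool)
      tot_fill <- sum(fill_n)
      draws <- sample(pool, tot_fill, replace = TRUE, prob = w)
      owner <- rep.int(seq_len(n), fill_n)
      dup <- duplicated(paste0(owner, "\r", draws))
      fill_list <- split(draws[!dup], factor(owner[!dup], levels = seq_len(n)))
    } else {
      fill_list <- rep(list(character()), n)
    }
    for (i in seq_len(n)) {
      s <- struct_list[[i]]
      if (length(s) > 1L) s <- s[sample.int(length(s))]
      dx[[i]] <- c(s, fill_list[[i]])
    }

    svc_codes <- vector("list", n)
    svc_codes[service] <- list(c(truth$service_code, "99213"))
    svc_codes[!service] <- list("99213")

    new_claims(data.frame(
      claim_id = sprintf("C%07d", seq_len(n)),
      patient_id = sprintf("P%07d", seq_len(n)),
      age = age, sex = sex, setting = truth$setting,
      service_codes = I(svc_codes), dx_codes = I(dx),
      stringsAsFactors = FALSE
    ))
  })
}

#' Expected screening outcome for every structural code
#'
#' The oracle for parameter-recovery tests: applies the proportion-interval
#' overlap rule to each code's TRUE prevalences at a given per-arm sample
#' size, using the same beta construction as the empirical screen
#' ([beta_interval()] with shapes `1 + p*n` and `1 + n - p*n`). Indication
#' codes use their configured per-arm prevalences; background and confounder
#' codes have equal prevalence in both arms once the matching variables are
#' balanced, so they are always expected to be removed.
#'
#' @param truth A [sim_truth()].
#' @param n_per_arm Claims per arm the screen will see.
#' @param quantiles Interval quantile levels.
#' @return data.frame with columns `code`, `class`, `p_service`, `p_control`,
#'   `expected_retained`.
#' @export
truth_report <- function(truth, n_per_arm = 5000L,
                         quantiles = c(0.05, 0.95)) {
  stopifnot(inherits(truth, "sim_truth"))
  block <- function(codes, class, p_s, p_c) {
    if (!length(codes)) return(NULL)
    data.frame(code = codes, class = class, p_service = p_s, p_control = p_c)
  }
  rows <- rbind(
    block(truth$indication$code, "indication",
          truth$indication$prev_service, truth$indication$prev_control),
    block(truth$confounder$code, "confounder",
          truth$confounder$base_prev, truth$confounder$base_prev),
    block(truth$background$code, "background",
          truth$background$prev, truth$background$prev)
  )
  n <- n_per_arm
  lo_s <- stats::qbeta(quantiles[1L], 1 + rows$p_service * n,
                       1 + n - rows$p_service * n)
  hi_c <- stats::qbeta(quantiles[2L], 1 + rows$p_control * n,
                       1 + n - rows$p_control * n)
  rows$expected_retained <- lo_s > hi_c
  rownames(rows) <- NULL
  rows
}

#' Read / write a population specification as a YAML config file
#'
#' The serialized form holds every [sim_truth()] field under its own key,
#' with the three code tables as lists of records. A file written by
#' [write_sim_truth()] reproduces an identical specification when read back.
#'
#' @param path YAML file path.
#' @return `read_sim_truth()` returns a `sim_truth`; `write_sim_truth()`
#'   returns `path` invisibly.
#' @export
read_sim_truth <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read sim_truth config files")
  }
  y <- yaml::read_yaml(path)
  to_df <- function(x) do.call(rbind, lapply(x, as.data.frame))
  y$indication <- to_df(y$indication)
  y$background <- to_df(y$background)
  y$confounder <- if (!is.null(y$confounder)) to_df(y$confounder)
  do.call(sim_truth, y)
}

#' @rdname read_sim_truth
#' @param truth A `sim_truth` to serialize.
#' @export
write_sim_truth <- function(truth, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write sim_truth config files")
  }
  x <- unclass(truth)
  df_to_list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  x$indication <- df_to_list(x$indication)
  x$background <- df_to_list(x$background)
  x$confounder <- df_to_list(x$confounder)
  yaml::write_yaml(x, path)
  invisible(path)
}
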