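#' Normalize a diagnosis code to its 4-character analysis form
#'
#' Diagnosis codes are analysed as uppercase, dot-free stems truncated to at
#' most four characters. Truncation exploits the chapter structure of ICD-10:
#' the first four characters carry the clinical category (e.g. `"M1711"` and
#' `"M1712"` both denote unilateral primary knee osteoarthritis and collapse
#' to `"M171"`), which sharply reduces the number of binary predictors the
#' classification tree has to consider.
#'
#' @param raw Character vector of raw diagnosis codes (e.g. `"S83.2"`).
#' @return Character vector of normalized codes, same length as `raw`.
#' @examples
#' normalize_dx_code(c("S83.2", "M1711", "m942"))
#' @export
normalize_dx_code <- function(raw) {
  if (length(raw) == 0L) return(character())
  x <- gsub("[.[:space:]]", "", as.character(raw))
  bad <- is.na(x) | !nzchar(x)
  if (any(bad)) {
    stop(errorCondition(
      sprintf("invalid diagnosis code: empty or blank input at position %d",
              which(bad)[1L]),
      class = c("claimdef_invalid_code", "error", "condition")))
  }
  toupper(substr(x, 1L, 4L))
}

#' Study configuration
#'
#' Bundles every tunable parameter of the pipeline. Defaults mirror the
#' analysis conditions the pipeline is designed for: Medicare-style claims for
#' patients aged 65 and over, a training sample capped at 5,000 service claims
#' with 1,000 held out for validation, a disclosure threshold of 11 for cell
#' masking, an unpruned tree grown to maximum depth 75, and proportion
#' intervals at the 5th and 95th beta percentiles.
#'
#' @param service_code_prefixes Character vector of service/procedure code
#'   prefixes; a claim "has the service" if any of its service codes starts
#'   with any prefix (so `"0SG0"` covers any approach, device or qualifier).
#' @param setting Claim setting to analyse: `"carrier"`, `"outpatient"` or
#'   `"inpatient"`.
#' @param min_age Minimum patient age in years (claims below are excluded).
#' @param train_max,valid_max Maximum number of service claims in the training
#'   and validation samples.
#' @param mask_threshold Counts strictly below this are suppressed to a range.
#' @param max_depth Maximum classification-tree depth.
#' @param interval_quantiles Length-2 numeric, the lower and upper beta
#'   quantile levels for proportion intervals.
#' @param prune Logical; apply C4.5-style pessimistic pruning to the tree.
#'   Off by default: the goal is to surface as many candidate codes as
#'   possible, not to generalize, so the full-depth tree is preferred.
#' @param seed Integer seed governing all randomized steps.
#' @return An object of class `study_config` (a validated list).
#' @export
study_config <- function(service_code_prefixes = character(),
                         setting = c("carrier", "outpatient", "inpatient"),
                         min_age = 65L,
                         train_max = 5000L,
                         valid_max = 1000L,
                         mask_threshold = 11L,
                         max_depth = 75L,
                         interval_quantiles = c(0.05, 0.95),
                         prune = FALSE,
                         seed = 1L) {
  setting <- match.arg(setting)
  stopifnot(is.numeric(min_age), min_age >= 0,
            is.numeric(train_max), train_max >= 1,
            is.numeric(valid_max), valid_max >= 1,
            is.numeric(mask_threshold), mask_threshold >= 1,
            is.numeric(max_depth), max_depth >= 1,
            is.logical(prune), length(prune) == 1L,
            is.numeric(seed), length(seed) == 1L)
  q <- as.numeric(interval_quantiles)
  if (length(q) != 2L || !(0 < q[1L] && q[1L] < q[2L] && q[2L] < 1)) {
    stop("interval_quantiles must satisfy 0 < lo < hi < 1")
  }
  structure(list(
    service_code_prefixes = as.character(service_code_prefixes),
    setting = setting,
    min_age = as.integer(min_age),
    train_max = as.integer(train_max),
    valid_max = as.integer(valid_max),
    mask_threshold = as.integer(mask_threshold),
    max_depth = as.integer(max_depth),
    interval_quantiles = q,
    prune = prune,
    seed = as.integer(seed)
  ), class = "study_config")
}

# Validate and canonicalize a claims data.frame. dx codes are normalized and
# deduplicated within claim (two 5-char codes sharing a 4-char stem count
# once: features are binary presence indicators). Order of dx codes is kept,
# so the first element remains the principal diagnosis.
new_claims <- function(df) {
  req <- c("claim_id", "patient_id", "age", "sex", "setting",
           "service_codes", "dx_codes")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(errorCondition(
      sprintf("claims data is missing required column(s): %s",
              paste(miss, collapse = ", ")),
      class = c("claimdef_schema_error", "error", "condition")))
  }
  df <- df[req]
  df$claim_id <- as.character(df$claim_id)
  if (anyDuplicated(df$claim_id)) {
    stop(errorCondition("duplicate claim_id values in claims data",
                        class = c("claimdef_schema_error", "error", "condition")))
  }
  age <- suppressWarnings(as.integer(df$age))
  bad <- which(is.na(age) | age < 0)
  if (length(bad)) {
    stop(errorCondition(
      sprintf("unparseable or negative age for claim_id %s",
              df$claim_id[bad[1L]]),
      class = c("claimdef_row_error", "error", "condition")))
  }
  df$age <- age
  sex <- toupper(as.character(df$sex))
  bad <- which(!sex %in% c("F", "M"))
  if (length(bad)) {
    stop(errorCondition(
      sprintf("unparseable sex value '%s' for claim_id %s",
              df$sex[bad[1L]], df$claim_id[bad[1L]]),
      class = c("claimdef_row_error", "error", "condition")))
  }
  df$sex <- sex
  df$setting <- as.character(df$setting)
  if (!is.list(df$service_codes)) df$service_codes <- as.list(df$service_codes)
  if (!is.list(df$dx_codes)) df$dx_codes <- as.list(df$dx_codes)
  df$service_codes <- lapply(df$service_codes, function(s) {
    s <- as.character(s)
    s[nzchar(s) & !is.na(s)]
  })
  df$dx_codes <- lapply(df$dx_codes, function(d) {
    d <- as.character(d)
    d <- d[nzchar(d) & !is.na(d)]
    if (!length(d)) return(character())
    unique(normalize_dx_code(d))
  })
  class(df) <- c("claims_df", "data.frame")
  rownames(df) <- NULL
  df
}

#' Number of diagnosis codes on each claim
#' @param claims A `claims_df`.
#' @return Integer vector.
#' @export
dx_count <- function(claims) {
  vapply(claims$dx_codes, length, integer(1L))
}

#' Read claims from a CSV file
#'
#' The canonical schema is one row per claim with columns `claim_id`,
#' `patient_id`, `age`, `sex` (`F`/`M`), `setting`, `service_codes` (a
#' `";"`-delimited list) and `dx_codes` (a `";"`-delimited ordered list, first
#' code = principal diagnosis). A wide variant with columns `dx1..dxK` is also
#' accepted, either auto-detected or named explicitly via `dx_cols`; empty
#' cells are skipped. Codes are normalized ([normalize_dx_code()]) and
#' deduplicated within each claim.
#'
#' @param path CSV file path.
#' @param dx_cols Optional character vector naming wide diagnosis columns.
#' @param delim Delimiter for list-valued cells (default `";"`).
#' @return A `claims_df` data frame with list columns `service_codes` and
#'   `dx_codes`.
#' @export
load_claims <- function(path, dx_cols = NULL, delim = ";") {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  if (is.null(dx_cols)) {
    wide <- grep("^dx[0-9]+$", names(raw), value = TRUE)
    if (!"dx_codes" %in% names(raw) && length(wide)) dx_cols <- wide
  }
  if (!is.null(dx_cols)) {
    miss <- setdiff(dx_cols, names(raw))
    if (length(miss)) {
      stop(errorCondition(
        sprintf("claims data is missing required column(s): %s",
                paste(miss, collapse = ", ")),
        class = c("claimdef_schema_error", "error", "condition")))
    }
    dxm <- as.matrix(raw[dx_cols])
    dx <- lapply(seq_len(nrow(raw)), function(i) {
      v <- dxm[i, ]
      v[nzchar(v)]
    })
    raw$dx_codes <- NULL
  } else {
    if (!"dx_codes" %in% names(raw)) {
      stop(errorCondition(
        "claims data is missing required column(s): dx_codes (or dx1..dxK)",
        class = c("claimdef_schema_error", "error", "condition")))
    }
    dx <- strsplit(raw$dx_codes, delim, fixed = TRUE)
  }
  if (!"service_codes" %in% names(raw)) raw$service_codes <- ""
  svc <- strsplit(raw$service_codes, delim, fixed = TRUE)
  keep <- intersect(c("claim_id", "patient_id", "age", "sex", "setting"),
                    names(raw))
  df <- raw[keep]
  df$service_codes <- svc
  df$dx_codes <- dx
  new_claims(df)
}

#' Write claims to CSV
#'
#' Inverse of [load_claims()]: list columns are serialized as `";"`-delimited
#' strings, so `load_claims(write_claims(x, f))` round-trips.
#'
#' @param claims A `claims_df`.
#' @param path Output CSV path.
#' @param delim List delimiter.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path, delim = ";") {
  out <- data.frame(
    claim_id = claims$claim_id,
    patient_id = claims$patient_id,
    age = claims$age,
    sex = claims$sex,
    setting = claims$setting,
    service_codes = vapply(claims$service_codes, paste, "", collapse = delim),
    dx_codes = vapply(claims$dx_codes, paste, "", collapse = delim),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Does a claim carry the configured service?
#'
#' A claim has the service if any of its service/procedure codes starts with
#' any configured prefix. Prefix matching implements the "any approach,
#' device or qualifier" wildcard convention for procedure-code stems (e.g.
#' prefix `"0SG0"` matches `"0SG00AJ"`).
#'
#' @param claims A `claims_df`.
#' @param config A [study_config()].
#' @return Logical vector, one element per claim.
#' @export
has_service <- function(claims, config) {
  prefixes <- config$service_code_prefixes
  if (!length(prefixes)) return(rep(FALSE, nrow(claims)))
  vapply(claims$service_codes, function(s) {
    if (!length(s)) return(FALSE)
    any(vapply(prefixes, function(p) any(startsWith(s, p)), logical(1L)))
  }, logical(1L))
}

# Evaluate `code` with a private RNG state: seeded, and the caller's
# .Random.seed restored afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# round-half-up at `digits` decimals; base round() is round-half-even, which
# does not match how percentages in claim summaries are conventionally shown
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
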