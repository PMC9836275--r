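#' A cohort definition: per-code selections and labels
#'
#' A definition assigns each diagnosis code one status — `unset`, `include`,
#' `exclude` or `dropped` — and optionally a free-text label (e.g. grouping
#' several codes under "Cancer"). Dropped codes carry no inclusion or
#' exclusion meaning; they are merely hidden from consideration.
#'
#' @param codes Character vector of codes.
#' @param statuses Character vector of statuses, recycled to `codes`.
#' @param labels Optional character vector of labels, recycled likewise.
#' @return An object of class `definition_state`: data.frame with columns
#'   `code`, `status`, `label`, one row per code, lexicographic order.
#' @export
definition_state <- function(codes = character(), statuses = "unset",
                             labels = "") {
  statuses <- rep_len(as.character(statuses), length(codes))
  labels <- rep_len(as.character(labels), length(codes))
  bad <- !statuses %in% c("unset", "include", "exclude", "dropped")
  if (any(bad)) {
    stop(errorCondition(
      sprintf("invalid status '%s' (must be unset/include/exclude/dropped)",
              statuses[which(bad)[1L]]),
      class = c("claimdef_parse_error", "error", "condition")))
  }
  codes <- as.character(codes)
  if (anyDuplicated(codes)) {
    dup <- codes[duplicated(codes)][1L]
    stop(errorCondition(
      sprintf("code %s appears more than once in the definition", dup),
      class = c("claimdef_conflict_error", "error", "condition")))
  }
  ord <- order(codes, method = "radix")
  structure(data.frame(code = codes[ord], status = statuses[ord],
                       label = labels[ord], stringsAsFactors = FALSE),
            class = c("definition_state", "data.frame"))
}

#' Set the status (and optionally the label) of codes in a definition
#'
#' @param state A `definition_state`.
#' @param codes Codes to update (added to the definition if absent).
#' @param status New status for all of `codes`.
#' @param label Optional new label.
#' @return The updated `definition_state`.
#' @export
set_selection <- function(state, codes, status, label = NULL) {
  for (code in codes) {
    i <- match(code, state$code)
    if (is.na(i)) {
      state <- definition_state(c(state$code, code),
                                c(state$status, status),
                                c(state$label, if (is.null(label)) "" else label))
    } else {
      state$status[i] <- status
      if (!is.null(label)) state$label[i] <- label
    }
  }
  definition_state(state$code, state$status, state$label)
}

#' Apply a definition to a masked summary table
#'
#' The count engine. Writing `[I_lo, I_hi]` for the interval sum of
#' [total_code_range()] over the included codes and `[E_lo, E_hi]` over the
#' excluded codes, the engine reports
#' \itemize{
#'   \item `included = [max(0, I_lo - E_hi), max(0, I_hi - E_lo)]` — the
#'     possible count of cohort claims: at most, every included masked cell
#'     is 10 and every excluded one is 1; at least, the reverse, floored at
#'     zero;
#'   \item `excluded = [E_lo, E_hi]`;
#'   \item `maybe` — the claims whose status the masking leaves unresolvable:
#'     the sum of the two interval widths.
#' }
#' Counts are straight sums over the selected codes' total ranges, so a claim
#' carrying two selected codes is counted once per code; the output is an
#' estimated claim count, not a deduplicated cohort size. Dropped and unset
#' codes contribute nothing.
#'
#' @param state A `definition_state`.
#' @param masked A `masked_group_table`.
#' @return An object of class `count_summary`: list with `included`
#'   (`c(lo, hi)`), `excluded` (`c(lo, hi)`), `maybe`, `sample_n`, and
#'   whole-percent strings `included_pct`, `excluded_pct`.
#' @export
apply_selection <- function(state, masked) {
  sel <- state[state$status %in% c("include", "exclude"), , drop = FALSE]
  missing <- setdiff(sel$code, masked$cells$code)
  if (length(missing)) {
    stop(errorCondition(
      sprintf("selected code(s) not present in the summary table: %s",
              paste(missing, collapse = ", ")),
      class = c("claimdef_lookup_error", "error", "condition")))
  }
  range_sum <- function(codes) {
    if (!length(codes)) return(c(lo = 0, hi = 0))
    rowSums(vapply(codes, total_code_range, numeric(2L), masked = masked))
  }
  inc <- range_sum(sel$code[sel$status == "include"])
  exc <- range_sum(sel$code[sel$status == "exclude"])
  included <- c(lo = as.integer(max(0, inc[["lo"]] - exc[["hi"]])),
                hi = as.integer(max(0, inc[["hi"]] - exc[["lo"]])))
  excluded <- c(lo = as.integer(exc[["lo"]]), hi = as.integer(exc[["hi"]]))
  structure(list(
    included = included, excluded = excluded,
    maybe = (included[["hi"]] - included[["lo"]]) +
      (excluded[["hi"]] - excluded[["lo"]]),
    sample_n = masked$sample_n,
    included_pct = pct_range(included, masked$sample_n),
    excluded_pct = pct_range(excluded, masked$sample_n)
  ), class = "count_summary")
}

# whole-percent range string, half-up, as summaries conventionally print it
pct_range <- function(r, n) {
  sprintf("%d to %d%%", as.integer(round_half_up(100 * r[["lo"]] / n, 0L)),
          as.integer(round_half_up(100 * r[["hi"]] / n, 0L)))
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("estimated claim counts out of %d sampled claims:\n", x$sample_n))
  cat(sprintf("  included: %d to %d (%s)\n", x$included[["lo"]],
              x$included[["hi"]], x$included_pct))
  cat(sprintf("  excluded: %d to %d (%s)\n", x$excluded[["lo"]],
              x$excluded[["hi"]], x$excluded_pct))
  cat(sprintf("  maybe (masking indeterminacy): %d\n", x$maybe))
  invisible(x)
}

#' Save / load a definition as a shareable CSV
#'
#' Three columns — `code`, `status`, `label` — in lexicographic code order,
#' so the artifact is deterministic and diff-friendly. Loading restores the
#' state; codes absent from the current summary table are kept (a definition
#' built on one sample can be applied to another) but reported in a warning.
#'
#' @param state A `definition_state`.
#' @param path CSV path.
#' @return `save_definition()` returns `path` invisibly.
#' @export
save_definition <- function(state, path) {
  utils::write.csv(as.data.frame(state)[c("code", "status", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_definition
#' @param masked Optional `masked_group_table` to check codes against.
#' @return `load_definition()` returns a `definition_state`.
#' @export
load_definition <- function(path, masked = NULL) {
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("code", "status")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(errorCondition(
      sprintf("definition file is missing column(s): %s",
              paste(miss, collapse = ", ")),
      class = c("claimdef_schema_error", "error", "condition")))
  }
  bad <- !raw$status %in% c("unset", "include", "exclude", "dropped")
  if (any(bad)) {
    stop(errorCondition(
      sprintf("invalid status '%s' at row %d of %s",
              raw$status[which(bad)[1L]], which(bad)[1L], path),
      class = c("claimdef_parse_error", "error", "condition")))
  }
  if (!"label" %in% names(raw)) raw$label <- ""
  state <- definition_state(raw$code, raw$status, raw$label)
  if (!is.null(masked)) {
    unknown <- setdiff(state$code, masked$cells$code)
    if (length(unknown)) {
      warning(sprintf("definition contains code(s) not in the summary table: %s",
                      paste(unknown, collapse = ", ")))
    }
  }
  state
}
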