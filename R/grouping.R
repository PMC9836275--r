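#' Partition service claims into groups by descending code importance
#'
#' Mirrors the tree's branching logic on the service sample alone: the first
#' group is every claim carrying the top-ranked code; the second group is
#' every remaining claim carrying the second code; and so on until no ranked
#' codes (or no claims) remain. A ranked code whose remaining-claim set is
#' empty produces no group. For every ranked code, the table also records how
#' many claims in each group carry it — the overlap structure a definition
#' builder needs. Claims carrying none of the ranked codes stay unassigned.
#'
#' @param service_claims A `claims_df` (the tabulated service sample).
#' @param ranked_codes Character vector of retained codes, importance
#'   descending (ties already broken lexicographically upstream).
#' @return An object of class `group_table`: list with `sample_n`, `groups`
#'   (data.frame `rank`, `group_code`, `member_count`), `cells` (data.frame
#'   `rank`, `group_code`, `code`, `count`; zero cells omitted),
#'   `unassigned` (count), and `assignment` (claim_id to rank, `NA` when
#'   unassigned).
#' @export
assign_groups <- function(service_claims, ranked_codes) {
  n <- nrow(service_claims)
  dx <- service_claims$dx_codes
  remaining <- rep(TRUE, n)
  rank_of <- rep(NA_integer_, n)
  groups <- list()
  g <- 0L
  for (code in ranked_codes) {
    if (!any(remaining)) break
    carrier <- vapply(dx, function(d) code %in% d, logical(1L))
    members <- remaining & carrier
    if (!any(members)) next
    g <- g + 1L
    rank_of[members] <- g
    remaining[members] <- FALSE
    groups[[g]] <- data.frame(rank = g, group_code = code,
                              member_count = sum(members),
                              stringsAsFactors = FALSE)
  }
  groups <- if (g > 0L) do.call(rbind, groups) else
    data.frame(rank = integer(), group_code = character(),
               member_count = integer(), stringsAsFactors = FALSE)

  cells <- list()
  for (r in seq_len(g)) {
    in_g <- which(rank_of == r)
    cnt <- table(factor(unlist(dx[in_g], use.names = FALSE),
                        levels = ranked_codes))
    nz <- cnt > 0L
    if (any(nz)) {
      cells[[r]] <- data.frame(rank = r, group_code = groups$group_code[r],
                               code = names(cnt)[nz],
                               count = as.integer(cnt[nz]),
                               stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(rank = integer(), group_code = character(),
               code = character(), count = integer(), stringsAsFactors = FALSE)
  rownames(groups) <- rownames(cells) <- NULL
  structure(list(sample_n = n, groups = groups, cells = cells,
                 unassigned = sum(is.na(rank_of)),
                 assignment = data.frame(claim_id = service_claims$claim_id,
                                         rank = rank_of,
                                         stringsAsFactors = FALSE)),
            class = "group_table")
}

#' Coverage of the grouped sample
#'
#' How many tabulated service claims carry at least one of the ranked codes
#' (i.e. fell into some group), as a count and a percentage of the sample
#' (half-up, 2 decimals).
#'
#' @param table A `group_table`.
#' @return List with `count` and `percent`.
#' @export
coverage <- function(table) {
  count <- table$sample_n - table$unassigned
  list(count = count,
       percent = round_half_up(100 * count / table$sample_n, 2L))
}

#' Mask small counts in a group table
#'
#' Disclosure control for summaries leaving a secure data environment: every
#' count `c` with `0 < c < mask_threshold` — cell counts, group member
#' counts, and the unassigned count alike — is replaced by the range
#' `[1, mask_threshold - 1]`; counts at or above the threshold pass through
#' exactly; zero cells are omitted entirely (already absent from the cell
#' table), since masking them as `[1, threshold-1]` would claim at least one
#' carrier that does not exist. Group percentages are only reported for
#' unmasked member counts.
#'
#' @param table A `group_table` with exact counts.
#' @param mask_threshold Masking threshold (default 11: counts of 10 or less
#'   are suppressed).
#' @return An object of class `masked_group_table`: list with `sample_n`,
#'   `mask_threshold`, `groups` (data.frame `rank`, `group_code`,
#'   `member_lo`, `member_hi`, `pct`), `cells` (data.frame `rank`,
#'   `group_code`, `code`, `cell_lo`, `cell_hi`), `unassigned_lo`,
#'   `unassigned_hi`.
#' @export
mask_table <- function(table, mask_threshold = 11L) {
  t <- as.integer(mask_threshold)
  rng <- function(c) {
    lo <- ifelse(c > 0L & c < t, 1L, c)
    hi <- ifelse(c > 0L & c < t, t - 1L, c)
    list(lo = as.integer(lo), hi = as.integer(hi))
  }
  gm <- rng(table$groups$member_count)
  groups <- data.frame(
    rank = table$groups$rank, group_code = table$groups$group_code,
    member_lo = gm$lo, member_hi = gm$hi,
    pct = ifelse(gm$lo == gm$hi,
                 round_half_up(100 * table$groups$member_count /
                                 table$sample_n, 2L),
                 NA_real_),
    stringsAsFactors = FALSE
  )
  cm <- rng(table$cells$count)
  cells <- data.frame(
    rank = table$cells$rank, group_code = table$cells$group_code,
    code = table$cells$code, cell_lo = cm$lo, cell_hi = cm$hi,
    stringsAsFactors = FALSE
  )
  um <- rng(table$unassigned)
  structure(list(sample_n = table$sample_n, mask_threshold = t,
                 groups = groups, cells = cells,
                 unassigned_lo = um$lo, unassigned_hi = um$hi),
            class = "masked_group_table")
}

#' Possible range of the total claim count for one code
#'
#' Interval sum of the code's per-group cells: the lower bound adds every
#' cell's lower bound, the upper bound every upper bound. With threshold 11
#' each masked cell contributes exactly 9 to the width, so the width of the
#' total equals 9 times the number of masked cells summed.
#'
#' @param masked A `masked_group_table`.
#' @param code A diagnosis code appearing in at least one cell.
#' @return Named numeric `c(lo, hi)`.
#' @export
total_code_range <- function(masked, code) {
  rows <- masked$cells$code == code
  if (!any(rows)) {
    stop(errorCondition(sprintf("code %s does not appear in any cell", code),
                        class = c("claimdef_lookup_error", "error", "condition")))
  }
  c(lo = sum(masked$cells$cell_lo[rows]),
    hi = sum(masked$cells$cell_hi[rows]))
}

#' Write / read the masked summary table as CSV
#'
#' The summary CSV is the contract between the secure-environment pipeline
#' and the definition builder: one row per (group, code) cell with columns
#' `rank`, `group_code`, `code`, `description`, `cell_lo`, `cell_hi`,
#' `group_lo`, `group_hi`, `pct`, `total_lo`, `total_hi`, `sample_n`, plus a
#' final rank-0 pseudo-row for unassigned claims. The pair of functions
#' round-trips bit-exactly.
#'
#' @param masked A `masked_group_table`.
#' @param path CSV path.
#' @param descriptions Optional named character vector of code descriptions.
#' @return `write_summary_table()` returns `path` invisibly;
#'   `read_summary_table()` returns a `masked_group_table`.
#' @export
write_summary_table <- function(masked, path, descriptions = character()) {
  cells <- masked$cells
  gi <- match(cells$rank, masked$groups$rank)
  totals <- do.call(rbind, lapply(cells$code, total_code_range, masked = masked))
  out <- data.frame(
    rank = cells$rank, group_code = cells$group_code, code = cells$code,
    description = ifelse(cells$code %in% names(descriptions),
                         descriptions[cells$code], ""),
    cell_lo = cells$cell_lo, cell_hi = cells$cell_hi,
    group_lo = masked$groups$member_lo[gi],
    group_hi = masked$groups$member_hi[gi],
    pct = masked$groups$pct[gi],
    total_lo = totals[, "lo"], total_hi = totals[, "hi"],
    sample_n = masked$sample_n,
    stringsAsFactors = FALSE
  )
  out <- rbind(out, data.frame(
    rank = 0L, group_code = "", code = "", description = "",
    cell_lo = masked$unassigned_lo, cell_hi = masked$unassigned_hi,
    group_lo = masked$unassigned_lo, group_hi = masked$unassigned_hi,
    pct = NA_real_, total_lo = NA_integer_, total_hi = NA_integer_,
    sample_n = masked$sample_n
  ))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = c(
    rank = "integer", group_code = "character", code = "character",
    description = "character", cell_lo = "integer", cell_hi = "integer",
    group_lo = "integer", group_hi = "integer", pct = "numeric",
    total_lo = "integer", total_hi = "integer", sample_n = "integer"))
  un <- raw[raw$rank == 0L, , drop = FALSE]
  cells_raw <- raw[raw$rank != 0L, , drop = FALSE]
  groups <- unique(cells_raw[c("rank", "group_code", "group_lo", "group_hi",
                               "pct")])
  names(groups)[3:4] <- c("member_lo", "member_hi")
  groups <- groups[order(groups$rank), , drop = FALSE]
  rownames(groups) <- NULL
  cells <- cells_raw[c("rank", "group_code", "code", "cell_lo", "cell_hi")]
  rownames(cells) <- NULL
  # a masked range is [1, threshold - 1], so the threshold is recoverable
  # from any masked bound; default 11 when nothing in the table was masked
  masked_hi <- c(cells$cell_hi[cells$cell_lo != cells$cell_hi],
                 groups$member_hi[groups$member_lo != groups$member_hi],
                 if (nrow(un) && un$cell_lo != un$cell_hi) un$cell_hi)
  t_guess <- if (length(masked_hi)) max(masked_hi) + 1L else 11L
  structure(list(sample_n = raw$sample_n[1L], mask_threshold = t_guess,
                 groups = groups, cells = cells,
                 unassigned_lo = if (nrow(un)) un$cell_lo else 0L,
                 unassigned_hi = if (nrow(un)) un$cell_hi else 0L),
            class = "masked_group_table")
}

#' @export
print.masked_group_table <- function(x, ...) {
  cat(sprintf("masked_group_table: %d groups over %d claims (unassigned %d to %d), threshold %d\n",
              nrow(x$groups), x$sample_n, x$unassigned_lo, x$unassigned_hi,
              x$mask_threshold))
  invisible(x)
}
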