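test_that("groups form by rank with overlap cells recording shared codes", {
  g <- assign_groups(grouping_fixture(), c("S832", "M942"))
  expect_equal(g$groups$member_count, c(1906L, 1012L))
  expect_equal(g$groups$group_code, c("S832", "M942"))
  # group 1 contains 532 claims that also carry the rank-2 code
  cell <- g$cells[g$cells$rank == 1L & g$cells$code == "M942", ]
  expect_equal(cell$count, 532L)
  # total count of the rank-2 code across all groups is its sample total
  expect_equal(sum(g$cells$count[g$cells$code == "M942"]), 1544L)
  expect_equal(g$unassigned, 5000L - 1906L - 1012L)
})

test_that("a code carried by every claim forms a single full group", {
  cl <- mk_claims(rep(list(c("S832", "I10")), 40L))
  g <- assign_groups(cl, c("S832", "I10"))
  expect_equal(nrow(g$groups), 1L)  # I10 has no remaining claims, no group
  expect_equal(g$groups$member_count, 40L)
  expect_equal(g$unassigned, 0L)
  expect_equal(coverage(g)$percent, 100)
})

test_that("an empty code list leaves every claim unassigned", {
  cl <- mk_claims(rep(list("S832"), 7L))
  g <- assign_groups(cl, character())
  expect_equal(nrow(g$groups), 0L)
  expect_equal(g$unassigned, 7L)
})

test_that("grouping equals brute-force set subtraction on small fixtures", {
  codes <- c("A001", "B001", "C001")
  for (rep_i in 1:25) {
    set.seed(2000L + rep_i)
    dx <- replicate(12L, codes[rbinom(3L, 1L, 0.4) == 1L], simplify = FALSE)
    cl <- mk_claims(dx)
    g <- assign_groups(cl, codes)
    bf <- brute_force_groups(dx, codes)
    expect_equal(nrow(g$groups), length(bf$groups))
    for (r in seq_along(bf$groups)) {
      expect_equal(g$groups$group_code[r], bf$groups[[r]]$code)
      expect_equal(g$groups$member_count[r], length(bf$groups[[r]]$members))
      expect_equal(which(g$assignment$rank == r), bf$groups[[r]]$members)
    }
    expect_equal(g$unassigned, length(bf$unassigned))
    # partition: every claim in exactly one group or unassigned
    expect_equal(sum(g$groups$member_count) + g$unassigned, 12L)
  }
})

test_that("coverage is the grouped fraction at two decimals", {
  fake <- structure(list(sample_n = 5000L, unassigned = 416L),
                    class = "group_table")
  expect_equal(coverage(fake), list(count = 4584L, percent = 91.68))
  fake$unassigned <- 5000L - 3787L
  expect_equal(coverage(fake)$percent, 75.74)
  fake <- structure(list(sample_n = 1364L, unassigned = 11L),
                    class = "group_table")
  expect_equal(coverage(fake), list(count = 1353L, percent = 99.19))
})

test_that("masking suppresses counts under the threshold to [1, threshold-1]", {
  cl <- mk_claims(c(rep(list(c("A001", "B001")), 10L),
                    rep(list("A001"), 15L),
                    rep(list("B001"), 11L)))
  g <- assign_groups(cl, c("A001", "B001"))
  m <- mask_table(g, 11L)
  # cell of 10 is masked, member counts of 25 and 11 pass through
  cell <- m$cells[m$cells$rank == 1L & m$cells$code == "B001", ]
  expect_equal(c(cell$cell_lo, cell$cell_hi), c(1L, 10L))
  expect_equal(m$groups$member_lo, c(25L, 11L))
  expect_equal(m$groups$member_hi, c(25L, 11L))
  expect_equal(m$groups$pct, round(100 * c(25, 11) / 36, 2))
  # zero cells are omitted rather than masked
  expect_false(any(m$cells$cell_lo == 0L))
  # a small group's member count is itself masked and loses its percentage
  g2 <- assign_groups(mk_claims(rep(list("A001"), 5L)), "A001")
  m2 <- mask_table(g2, 11L)
  expect_equal(c(m2$groups$member_lo, m2$groups$member_hi), c(1L, 10L))
  expect_true(is.na(m2$groups$pct))
})

test_that("true counts always lie inside emitted ranges, widths follow the mask", {
  truth <- small_truth(n_claims = 1200L)
  cl <- generate_population(truth, 13L)
  svc <- cl[has_service(cl, study_config("29877")), ]
  ranked <- c("S832", "M942", "M224", "M171", "I10")
  g <- assign_groups(svc, ranked)
  m <- mask_table(g, 11L)
  key <- paste(g$cells$rank, g$cells$code)
  for (i in seq_len(nrow(m$cells))) {
    true_count <- g$cells$count[match(paste(m$cells$rank[i], m$cells$code[i]),
                                      key)]
    expect_gte(true_count, m$cells$cell_lo[i])
    expect_lte(true_count, m$cells$cell_hi[i])
  }
  # interval sums: width = 9 x number of masked cells at threshold 11,
  # and the true total always lies inside
  for (code in ranked) {
    rows <- m$cells$code == code
    if (!any(rows)) next
    rng <- total_code_range(m, code)
    n_masked <- sum(m$cells$cell_lo[rows] != m$cells$cell_hi[rows])
    expect_equal(unname(rng["hi"] - rng["lo"]), 9L * n_masked)
    true_total <- sum(g$cells$count[g$cells$code == code])
    expect_gte(true_total, unname(rng["lo"]))
    expect_lte(true_total, unname(rng["hi"]))
  }
})

test_that("interval sums over a code's cells follow interval arithmetic", {
  masked <- structure(list(
    sample_n = 5000L, mask_threshold = 11L,
    groups = data.frame(rank = 1:4, group_code = c("S832", "M942", "M224", "M233"),
                        member_lo = c(1906L, 1012L, 578L, 66L),
                        member_hi = c(1906L, 1012L, 578L, 66L),
                        pct = c(38.12, 20.24, 11.56, 1.32)),
    cells = data.frame(
      rank = c(1L, 2L, 3L, 4L, 1L, 2L),
      group_code = c("S832", "M942", "M224", "M233", "S832", "M942"),
      code = c("M233", "M233", "M233", "M233", "Q000", "Q000"),
      cell_lo = c(66L, 235L, 1L, 1L, 12L, 1L),
      cell_hi = c(66L, 235L, 10L, 10L, 12L, 10L)),
    unassigned_lo = 0L, unassigned_hi = 0L), class = "masked_group_table")
  expect_equal(total_code_range(masked, "M233"), c(lo = 303L, hi = 321L))
  expect_equal(total_code_range(masked, "Q000"), c(lo = 13L, hi = 22L))
  expect_error(total_code_range(masked, "ZZZZ"),
               class = "claimdef_lookup_error")
  all_exact <- masked
  all_exact$cells <- data.frame(rank = 1:2, group_code = c("A", "B"),
                                code = "M233", cell_lo = c(66L, 100L),
                                cell_hi = c(66L, 100L))
  expect_equal(total_code_range(all_exact, "M233"), c(lo = 166L, hi = 166L))
})

test_that("the summary-table CSV round-trips bit-exactly", {
  truth <- small_truth(n_claims = 1500L)
  cl <- generate_population(truth, 23L)
  svc <- cl[has_service(cl, study_config("29877")), ]
  g <- assign_groups(svc, c("S832", "M942", "M224", "I10", "E785"))
  m <- mask_table(g, 11L)
  f <- tempfile(fileext = ".csv")
  write_summary_table(m, f)
  back <- read_summary_table(f)
  expect_identical(back$cells, m$cells)
  expect_identical(back$groups, m$groups)
  expect_identical(back$sample_n, m$sample_n)
  expect_identical(back$mask_threshold, m$mask_threshold)
  expect_identical(c(back$unassigned_lo, back$unassigned_hi),
                   c(m$unassigned_lo, m$unassigned_hi))
})
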