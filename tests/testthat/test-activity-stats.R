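test_that("contingency counts follow the group x activity layout", {
  act <- matrix(c(1, 1, 0, 0), nrow = 1,
                dimnames = list("r1", c("s1", "s2", "s3", "s4")))
  labels <- c(s1 = "AD", s2 = "AD", s3 = "CN", s4 = "CN")
  expect_equal(activity_contingency(act, labels, "r1",
                                    group_order = c("AD", "CN")),
               c(a = 2, b = 0, c = 0, d = 2))
  # all active
  act1 <- matrix(1L, 1, 4, dimnames = dimnames(act))
  expect_equal(activity_contingency(act1, labels, "r1",
                                    group_order = c("AD", "CN")),
               c(a = 2, b = 0, c = 2, d = 0))
  # permuting sample order leaves counts unchanged
  perm <- c("s3", "s1", "s4", "s2")
  expect_equal(activity_contingency(act[, perm, drop = FALSE], labels, "r1",
                                    group_order = c("AD", "CN")),
               activity_contingency(act, labels, "r1",
                                    group_order = c("AD", "CN")))
  expect_error(activity_contingency(act, labels[-1], "r1"), "unlabeled")
  labels3 <- labels
  labels3["s4"] <- "PD"
  expect_error(activity_contingency(act, labels3, "r1"), "two groups")
})

test_that("fisher_p reproduces hand-enumerated hypergeometric sums", {
  # margins (2,2 | 2,2): three tables, observed and its mirror each 1/6
  expect_equal(fisher_p(2, 0, 0, 2), 1 / 3)
  # the balanced table is the most probable one
  expect_equal(fisher_p(5, 5, 5, 5), 1)
  # degenerate margins
  expect_equal(fisher_p(0, 0, 3, 4), 1)
  expect_equal(fisher_p(3, 0, 4, 0), 1)
  expect_error(fisher_p(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_p(1.5, 2, 3, 4), "nonnegative")
})

test_that("fisher_p equals the enumeration oracle and fisher.test on a grid", {
  set.seed(12)
  for (i in 1:200) {
    tb <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    p <- fisher_p(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12, info = paste(tb, collapse = ","))
    expect_equal(p, stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9, info = paste(tb, collapse = ","))
  }
  # invariant under simultaneous row and column swaps
  expect_equal(fisher_p(8, 2, 2, 8), fisher_p(8, 2, 2, 8)[1])
  expect_equal(fisher_p(8, 2, 2, 8), fisher_p(2, 8, 8, 2))
})

test_that("doubling rule is a valid alternative two-sided rule", {
  p_mass <- fisher_p(8, 2, 2, 8)
  p_double <- fisher_p(8, 2, 2, 8, rule = "doubling")
  expect_gte(p_double, p_mass - 1e-12)
  expect_lte(p_double, 1)
})

test_that("odds ratios follow the zero-cell conventions", {
  expect_equal(odds_ratio_convention(8, 2, 2, 8), 16)
  expect_identical(odds_ratio_convention(3, 0, 2, 5), Inf)
  expect_identical(format_odds_ratio(odds_ratio_convention(3, 0, 2, 5)), "Inf")
  expect_true(is.na(odds_ratio_convention(0, 4, 0, 6)))
  expect_identical(format_odds_ratio(odds_ratio_convention(0, 4, 0, 6)), "NA")
  expect_equal(odds_ratio_convention(0, 4, 2, 6), 0)
  expect_identical(format_odds_ratio(odds_ratio_convention(0, 4, 2, 6)), "0.000")
  # reciprocal identity when finite and nonzero
  set.seed(3)
  for (i in 1:50) {
    tb <- as.integer(sample(0:9, 4, replace = TRUE))
    or1 <- odds_ratio_convention(tb[1], tb[2], tb[3], tb[4])
    or2 <- odds_ratio_convention(tb[2], tb[1], tb[4], tb[3])
    if (is.finite(or1) && !is.na(or1) && or1 > 0) {
      expect_equal(or1 * or2, 1)
    }
  }
})

test_that("group comparison flags strong activity differences", {
  set.seed(5)
  act <- rbind(
    r_diff = c(rep(1L, 9), 0L, rep(0L, 9), 1L),   # 9/10 vs 1/10 active
    r_same = rep(1L, 20),
    r_null = sample(0:1, 20, replace = TRUE))
  colnames(act) <- sprintf("s%02d", 1:20)
  labels <- setNames(rep(c("AD", "CN"), each = 10), colnames(act))
  cmp <- compare_groups(act, labels, group_order = c("AD", "CN"))
  expect_identical(cmp$reaction, sort(rownames(act)))
  row <- cmp[cmp$reaction == "r_diff", ]
  expect_lt(row$p, 0.05)
  expect_true(row$significant)
  # hand enumeration: tables x in {0, 1, 9, 10} are no more probable than
  # the observed one, giving (1 + 100 + 100 + 1) / C(20, 10)
  expect_equal(row$p, 202 / 184756, tolerance = 1e-12)
  expect_equal(row$p, fisher_oracle(9, 1, 1, 9), tolerance = 1e-12)
  same <- cmp[cmp$reaction == "r_same", ]
  expect_true(is.na(same$odds_ratio))
  expect_false(same$significant)
  # swapping group labels inverts finite ORs and keeps p
  cmp2 <- compare_groups(act, labels, group_order = c("CN", "AD"))
  expect_equal(cmp2$p, cmp$p)
  finite <- is.finite(cmp$odds_ratio) & cmp$odds_ratio > 0
  expect_equal(cmp2$odds_ratio[finite], 1 / cmp$odds_ratio[finite])
  # restriction to a subset keeps only those rows
  sub <- compare_groups(act, labels, reactions = "r_diff",
                        group_order = c("AD", "CN"))
  expect_identical(sub$reaction, "r_diff")
  expect_error(compare_groups(act, labels, reactions = "r_ghost"), "unknown")
})

test_that("null activity comparisons are calibrated", {
  set.seed(42)
  flags <- integer(0)
  for (rep in 1:200) {
    act <- matrix(rbinom(5 * 24, 1, 0.5), nrow = 5,
                  dimnames = list(sprintf("r%d", 1:5), sprintf("s%d", 1:24)))
    labels <- setNames(rep(c("AD", "CN"), each = 12), colnames(act))
    cmp <- compare_groups(act, labels, group_order = c("AD", "CN"))
    flags <- c(flags, cmp$significant)
  }
  expect_lte(mean(flags), 0.07)
})
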