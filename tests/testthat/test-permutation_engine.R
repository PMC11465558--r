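test_that("whole-plot permutations enumerate the within-block plot group", {
  des <- make_design(2L, days = c(0L, 1L, 3L))
  ps <- whole_plot_permutations(des, perm_scheme("whole_plot"))
  expect_true(ps$exhaustive)
  expect_identical(length(ps$perms), 36L)   # (3!)^2
  expect_equal(ps$group_size, 36)
  expect_true(all(vapply(ps$perms, check_permutation, logical(1),
                         design = des, level = "whole_plot")))
  ## identity is an element of the exhaustive set
  expect_true(any(vapply(ps$perms, function(p) all(p == seq_len(nrow(des))),
                         logical(1))))

  ## product formula at study scale forces Monte Carlo
  big <- make_design(8L, days = c(0L, 1L))
  sch <- perm_scheme("whole_plot", n_permutations = 25L, seed = 3)
  ps8 <- whole_plot_permutations(big, sch)
  expect_false(ps8$exhaustive)
  expect_equal(ps8$group_size, factorial(3)^8)  # 1,679,616
  expect_true(all(vapply(ps8$perms, check_permutation, logical(1),
                         design = big, level = "whole_plot")))
})

test_that("a one-block two-plot design gives exactly two whole-plot permutations", {
  des <- make_design(1L, days = c(0L, 1L), treatments = c("control", "novel"))
  ps <- whole_plot_permutations(des, perm_scheme("whole_plot"))
  expect_identical(length(ps$perms), 2L)
  expect_true(ps$exhaustive)
})

test_that("within-plot permutations shuffle days but never exchange plots", {
  des <- make_design(1L, days = c(0L, 1L, 3L),
                     treatments = c("control", "novel"))
  ps <- within_plot_permutations(des, perm_scheme("within_plot"))
  expect_identical(length(ps$perms), 36L)  # 3! * 3!
  expect_true(all(vapply(ps$perms, check_permutation, logical(1),
                         design = des, level = "within_plot")))
  ## a single-sample plot is a fixed point everywhere
  des1 <- study_design(rbind(as.data.frame(des),
    data.frame(sample_id = "lone", plot = "B9_rep", block = "B9",
               treatment = "repeated", day = 0L)))
  ps1 <- within_plot_permutations(des1, perm_scheme("within_plot"))
  lone <- which(des1$sample_id == "lone")
  expect_true(all(vapply(ps1$perms, function(p) p[lone] == lone, logical(1))))
})

test_that("Monte-Carlo within-plot draws are uniform over the group", {
  des <- make_design(1L, days = c(0L, 1L, 3L),
                     treatments = c("control", "novel"))
  sch <- perm_scheme("within_plot", n_permutations = 10000L,
                     exhaustive_threshold = 1L, seed = 42)
  ps <- within_plot_permutations(des, sch)
  expect_false(ps$exhaustive)
  keys <- vapply(ps$perms, paste, character(1), collapse = ",")
  tab <- table(keys)
  expect_identical(length(tab), 36L)
  gof <- chisq.test(as.vector(tab), p = rep(1 / 36, 36))
  expect_gt(gof$p.value, 0.01)
})

test_that("paired within-plot permutations form the 2^m swap group", {
  des <- make_design(4L, days = c(0L, 3L))  # 12 plots, but one treatment at a time
  sub <- study_design(as.data.frame(des[des$treatment == "novel", ]))
  ps <- paired_within_plot_permutations(sub, perm_scheme("paired_within_plot"))
  expect_identical(length(ps$perms), 16L)  # 2^4
  expect_true(all(vapply(ps$perms, check_permutation, logical(1),
                         design = sub, level = "paired_within_plot")))

  ## m = 1: identity and the swap
  one <- study_design(as.data.frame(sub[sub$plot == sub$plot[1], ]))
  ps1 <- paired_within_plot_permutations(one, perm_scheme("paired_within_plot"))
  expect_identical(length(ps1$perms), 2L)

  ## plots missing a day are excluded and reported
  broken <- study_design(as.data.frame(sub)[-1, ])
  expect_message(
    ps2 <- paired_within_plot_permutations(broken,
                                           perm_scheme("paired_within_plot")),
    "excluding")
  expect_identical(length(ps2$perms), 8L)  # 2^3
  expect_identical(length(attr(ps2, "excluded_plots")), 1L)

  expect_error(paired_within_plot_permutations(make_design(2L),
    perm_scheme("paired_within_plot")), "two days")
})

test_that("the smallest attainable paired p-value is 1/2^m", {
  des <- make_design(8L, days = c(0L, 1L))
  sub <- study_design(as.data.frame(des[des$treatment == "repeated", ]))
  ps <- paired_within_plot_permutations(sub, perm_scheme("paired_within_plot"))
  expect_equal(ps$group_size, 256)
  ## statistic maximal at the identity only
  f <- c(10, rep(1, length(ps$perms) - 1L))
  expect_equal(perm_pvalue(10, f, exhaustive = TRUE), 1 / 256)
})

test_that("free-within-block permutations never cross blocks", {
  des <- make_design(2L, days = 0L)
  ps <- free_within_block_permutations(des, perm_scheme("free_within_block"))
  expect_identical(length(ps$perms), 36L)  # 3! * 3!
  expect_true(all(vapply(ps$perms, check_permutation, logical(1),
                         design = des, level = "free_within_block")))
  expect_true(all(vapply(ps$perms, function(p)
    all(des$block[p] == des$block), logical(1))))

  ## one sample per block: identity only
  solo <- study_design(data.frame(sample_id = c("a", "b"),
                                  plot = c("p1", "p2"),
                                  block = c("b1", "b2"),
                                  treatment = c("control", "novel"),
                                  day = 0L))
  ps1 <- free_within_block_permutations(solo, perm_scheme("free_within_block"))
  expect_identical(ps1$perms, list(1:2))

  expect_error(free_within_block_permutations(make_design(1L),
    perm_scheme("free_within_block")), "single-day")
})

test_that("p-value conventions follow the exhaustive and Monte-Carlo forms", {
  ## exhaustive: identity in the reference set, plain proportion
  expect_equal(perm_pvalue(2, c(2, 1, 3, 0), exhaustive = TRUE), 2 / 4)
  ## Monte Carlo: add-one on both counts
  expect_equal(perm_pvalue(2, c(1, 3, 0), exhaustive = FALSE), 2 / 4)
  ## ties count as >=
  expect_equal(perm_pvalue(1, rep(1, 10), exhaustive = TRUE), 1)
})
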