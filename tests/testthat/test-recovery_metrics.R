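# reference implementations of the resistance/resilience rules, written
# as plain loops, used to check the packaged rules over every pattern
ref_first_change <- function(days, p, alpha) {
  for (i in seq_along(days)) if (!is.na(p[i]) && p[i] < alpha) return(days[i])
  NA_integer_
}
ref_recovery <- function(days, p, alpha) {
  fc <- ref_first_change(days, p, alpha)
  for (i in seq_along(days))
    if (days[i] > fc && !is.na(p[i]) && p[i] >= alpha) return(days[i])
  NA_integer_
}

test_that("change/recovery rules are exact over all p patterns on 5 days", {
  days <- c(1L, 3L, 6L, 8L, 14L)
  vals <- c(0.01, 0.9)
  grid <- expand.grid(rep(list(vals), 5))
  for (r in seq_len(nrow(grid))) {
    p <- as.numeric(grid[r, ])
    rep_df <- data.frame(day = days, p = p)
    fc <- first_change_day(rep_df, 0.05)
    expect_identical(fc, ref_first_change(days, p, 0.05))
    if (!is.na(fc))
      expect_identical(recovery_day(rep_df, 0.05),
                       ref_recovery(days, p, 0.05))
  }
  expect_error(recovery_day(data.frame(day = days, p = rep(0.9, 5))),
               "undefined")
})

test_that("rules reproduce the canonical day-grid patterns", {
  ## change on day 3, recovered by day 6
  rep_p <- data.frame(day = c(1L, 3L, 6L, 8L), p = c(0.64, 0.015, 0.70, 0.40))
  expect_identical(first_change_day(rep_p), 3L)
  expect_identical(recovery_day(rep_p), 6L)
  ## change on day 1
  nov_p <- data.frame(day = c(1L, 3L), p = c(0.0078, 0.63))
  expect_identical(first_change_day(nov_p), 1L)
  ## never significant
  expect_identical(first_change_day(data.frame(day = 1:3,
                                               p = c(0.2, 0.9, 0.4))),
                   NA_integer_)
  ## re-excursion after recovery: recovery day is the first return
  rex <- data.frame(day = c(1L, 3L, 28L), p = c(0.01, 0.6, 0.01))
  expect_identical(first_change_day(rex), 1L)
  expect_identical(recovery_day(rex), 3L)
  ## still significant through the end
  expect_identical(recovery_day(data.frame(day = c(1L, 3L),
                                           p = c(0.01, 0.02))), NA_integer_)
})

test_that("baseline dissimilarity series pulls each plot's own day-0 distances", {
  sim <- simulate_study(sim_params(n_blocks = 2L, days = c(0L, 1L, 3L),
                                   n_taxa = 30L, seed = 41))
  d <- bray_curtis(sim$counts)
  ser <- baseline_dissimilarity_series(d, sim$design)
  expect_true(all(ser$dissimilarity[ser$day == 0L] == 0))
  expect_true(all(ser$dissimilarity >= 0 & ser$dissimilarity <= 1))
  one <- ser[ser$plot == "B1_novel" & ser$day == 3L, ]
  expect_equal(one$dissimilarity,
               unclass(d)["B1_novel_d0", "B1_novel_d3"])
  ## plots without a baseline are skipped and reported
  des2 <- study_design(as.data.frame(sim$design)[
    sim$design$sample_id != "B1_novel_d0", ])
  keep <- des2$sample_id
  ser2 <- baseline_dissimilarity_series(
    dist_matrix(unclass(d)[keep, keep], "bray"), des2)
  expect_identical(attr(ser2, "missing_baseline"), "B1_novel")
})

test_that("a strong constructed pulse is detected at its onset day", {
  sim <- simulate_study(sim_params(n_taxa = 60L, days = c(0L, 1L, 3L, 6L),
                                   pulse_depth_novel = 3,
                                   recovery_halflife_novel = 1, seed = 47))
  d <- bray_curtis(sim$counts)
  tests <- pairwise_day_tests(d, sim$design, "novel")
  expect_identical(tests$day, c(1L, 3L, 6L))
  expect_true(all(tests$group_size == 256))
  expect_true(all(abs(tests$p * 256 - round(tests$p * 256)) < 1e-9))
  expect_identical(which.min(tests$p), 1L)
  expect_lt(tests$p[1], 0.05)
})

test_that("cross-treatment dissimilarity contrasts detect a mean shift", {
  ## identical distributions: permutation p is not extreme
  des <- make_design(8L, days = c(0L, 1L))
  mk_series <- function(shift) {
    pb <- unique(as.data.frame(des)[, c("plot", "block", "treatment")])
    withr::with_seed(13, data.frame(
      plot = pb$plot, block = pb$block, treatment = pb$treatment, day = 1L,
      dissimilarity = rnorm(nrow(pb), sd = 0.05) +
        ifelse(pb$treatment == "novel", shift, 0.3)))
  }
  null_cmp <- compare_dissimilarity(mk_series(0.3), day = 1L, seed = 1)
  expect_true(all(null_cmp$p > 0.05))
  shift_cmp <- compare_dissimilarity(mk_series(0.45), day = 1L, seed = 1)
  nov <- shift_cmp$treatment_a == "novel" | shift_cmp$treatment_b == "novel"
  expect_true(all(shift_cmp$p[nov] < 0.05))
  expect_true(all(shift_cmp$p_holm >= shift_cmp$p))
})

test_that("heatmap matrix is log-transformed, centered, scaled and ordered", {
  des <- make_design(2L, days = c(0L, 1L))
  rel <- to_relative_abundance(random_counts(des, 10L, seed = 3))
  hm <- heatmap_matrix(rel, colnames(rel)[1:5], des)
  expect_identical(dim(hm), c(5L, nrow(des)))
  expect_lt(max(abs(rowMeans(hm))), 1e-9)
  expect_equal(unname(apply(unclass(hm), 1, sd)), rep(1, 5), tolerance = 1e-9)
  ## columns: treatment panels, chronological days inside
  trt_order <- des$treatment[match(attr(hm, "column_order"), des$sample_id)]
  expect_identical(trt_order, rep(c("control", "novel", "repeated"), each = 4))

  ## constant rows are centered, flagged, not scaled
  m <- unclass(rel)
  m[, 1] <- 0.1
  hm2 <- heatmap_matrix(
    structure(m, class = class(rel)), colnames(m)[1:2], des)
  expect_identical(attr(hm2, "constant_rows"), colnames(m)[1])
  expect_true(all(hm2[1, ] == 0))

  ## pseudocount: a zero abundance maps to log10(pseudocount) before scaling
  expect_equal(log10(0 + 1e-6), -6)
  expect_error(heatmap_matrix(rel, "nope", des), "not present")
})

test_that("the full trajectory report combines tests, rules and series", {
  sim <- simulate_study(sim_params(n_blocks = 4L, days = c(0L, 1L, 3L),
                                   n_taxa = 40L, pulse_depth_novel = 3,
                                   seed = 53))
  d <- bray_curtis(sim$counts)
  tr <- trajectory_report(d, sim$design)
  expect_setequal(intersect(names(tr), valid_treatments()),
                  valid_treatments())
  expect_identical(tr$alpha, 0.05)
  expect_s3_class(tr$novel$day_tests, "data.frame")
  expect_true(is.data.frame(tr$series))
})
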