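test_that("projectors are idempotent with the term-set rank", {
  des <- make_design(2L, days = c(0L, 1L))
  p0 <- projector(des)
  expect_equal(p0$rank, 1L)
  expect_lt(max(abs(p0$H - matrix(1 / nrow(des), nrow(des), nrow(des)))),
            1e-12)
  pt <- projector(des, "Treatment")
  expect_equal(pt$rank, 3L)  # intercept + 2 of 3 levels
  expect_lt(max(abs(pt$H %*% pt$H - pt$H)), 1e-10)
  expect_lt(max(abs(pt$H - t(pt$H))), 1e-12)
  ## one factor, 2 balanced groups of 3
  des2 <- study_design(data.frame(sample_id = paste0("s", 1:6),
    plot = paste0("p", 1:6), block = "b1",
    treatment = rep(c("control", "novel"), each = 3), day = 0L))
  expect_equal(projector(des2, "Treatment")$rank, 2L)
})

test_that("sequential SS reproduces classical one-way ANOVA on 1-D data", {
  y <- c(1, 2, 3, 4, 5, 6)
  des <- study_design(data.frame(sample_id = paste0("s", 1:6),
    plot = paste0("p", 1:6), block = "b1",
    treatment = rep(c("control", "novel"), each = 3), day = 0L))
  tab <- sequential_ss(gower_center(euclid_dist(matrix(y), paste0("s", 1:6))),
                       "Treatment", des)
  expect_equal(tab["Treatment", "SS"], 13.5)
  expect_equal(tab["Residual", "SS"], 4)
  expect_equal(tab["Treatment", "df"], 1L)
  expect_equal(pseudo_f(tab, "Treatment", "residual"), 13.5)
  expect_equal(tab["Treatment", "R2"], 13.5 / 17.5)
})

test_that("sequential SS matches adonis2 term-by-term on Bray-Curtis data", {
  sim <- simulate_study(sim_params(n_blocks = 2L, days = c(0L, 1L, 3L),
                                   n_taxa = 30L, seed = 7))
  d <- bray_curtis(sim$counts)
  g <- gower_center(d)
  df <- as.data.frame(sim$design)
  df$day_f <- factor(df$day)
  for (terms in list(c("Treatment", "Plot"), c("Plot", "Day"))) {
    tab <- sequential_ss(g, terms, sim$design)
    rhs <- paste(c(Treatment = "treatment", Plot = "plot",
                   Day = "day_f")[terms], collapse = " + ")
    a2 <- vegan::adonis2(stats::as.formula(paste("as.dist(unclass(d)) ~", rhs)),
                         data = df, permutations = 2, by = "terms")
    expect_equal(tab[terms, "SS"], a2$SumOfSqs[1:2], tolerance = 1e-8)
    expect_equal(tab["Residual", "SS"], a2$SumOfSqs[3], tolerance = 1e-8)
    expect_equal(tab[terms, "df"], a2$Df[1:2])
  }
})

test_that("SS additivity holds on random distance models", {
  des <- make_design(2L, days = c(0L, 1L))
  d <- bray_curtis(random_counts(des, 15L, seed = 5))
  g <- gower_center(d)
  for (terms in list("Treatment", c("Treatment", "Plot"),
                     c("Plot", "Day", "Day:Treatment"))) {
    tab <- sequential_ss(g, terms, des)
    expect_equal(sum(tab[setdiff(rownames(tab), "Total"), "SS"]),
                 tab["Total", "SS"], tolerance = 1e-8)
    expect_equal(sum(tab[setdiff(rownames(tab), "Total"), "df"]),
                 nrow(des) - 1L)
  }
})

test_that("a term fitted after one that spans it is flagged aliased", {
  des <- make_design(2L, days = c(0L, 1L))
  g <- gower_center(bray_curtis(random_counts(des, 10L, seed = 2)))
  tab <- sequential_ss(g, c("Plot", "Treatment"), des)
  expect_identical(tab["Treatment", "df"], 0L)
  expect_true(tab["Treatment", "aliased"])
  expect_lt(abs(tab["Treatment", "SS"]), 1e-8)
  expect_true(is.na(pseudo_f(tab, "Treatment", "residual")))
})

test_that("pseudo-F handles zero numerators and denominators without crashing", {
  des <- make_design(2L, days = c(0L, 1L))
  same <- euclid_dist(matrix(1, nrow(des), 2), des$sample_id)
  tab <- sequential_ss(gower_center(same), c("Treatment", "Plot"), des)
  expect_equal(pseudo_f(tab, "Treatment", "whole_plot"), 0)
})

test_that("whole-plot denominator reduces to residual when plots hold one sample", {
  des <- make_design(2L, days = 0L)
  d <- bray_curtis(random_counts(des, 12L, seed = 6))
  g <- gower_center(d)
  split_tab <- sequential_ss(g, c("Treatment", "Plot"), des)
  flat_tab <- sequential_ss(g, "Treatment", des)
  expect_equal(pseudo_f(split_tab, "Treatment", "whole_plot"),
               pseudo_f(flat_tab, "Treatment", "residual"),
               tolerance = 1e-10)
})

test_that("the exhaustive whole-plot p equals a brute-force relabeling rank", {
  sim <- simulate_study(sim_params(n_blocks = 2L, days = c(0L, 1L, 3L),
                                   n_taxa = 25L, seed = 13))
  d <- bray_curtis(sim$counts)
  des <- sim$design
  tab <- permutation_test(d, des, c("Treatment", "Plot"), "Treatment",
                          perm_scheme("whole_plot"), "whole_plot")
  expect_true(attr(tab, "exhaustive"))
  expect_identical(attr(tab, "n_perm"), 36L)

  ## oracle: relabel plot treatments within blocks explicitly and
  ## recompute the split-plot F by the sequential-SS definition each time
  g <- gower_center(d)
  f_of_assign <- function(des2) {
    t2 <- sequential_ss(g, c("Treatment", "Plot"), des2)
    (t2["Treatment", "SS"] / t2["Treatment", "df"]) /
      (t2["Plot", "SS"] / t2["Plot", "df"])
  }
  pb <- unique(as.data.frame(des)[, c("plot", "block", "treatment")])
  blocks <- split(pb$plot, pb$block)
  ords <- expand.grid(a = 1:6, b = 1:6)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  f_all <- numeric(36)
  for (r in seq_len(36)) {
    des2 <- as.data.frame(des)
    for (bi in seq_along(blocks)) {
      ps <- blocks[[bi]]
      ord <- perms3[[ords[r, bi]]]
      trts <- pb$treatment[match(ps, pb$plot)]
      relab <- stats::setNames(trts[ord], ps)
      des2$treatment <- ifelse(des2$plot %in% ps,
                               relab[des2$plot], des2$treatment)
    }
    f_all[r] <- f_of_assign(study_design(des2))
  }
  f_obs <- f_of_assign(study_design(as.data.frame(des)))
  expect_equal(tab["Treatment", "F"], f_obs, tolerance = 1e-10)
  expect_equal(tab["Treatment", "p"], mean(f_all >= f_obs - 1e-12))
})

test_that("consistent relabeling of samples leaves the test invariant", {
  sim <- simulate_study(sim_params(n_blocks = 2L, days = c(0L, 1L),
                                   n_taxa = 20L, seed = 4))
  d <- sim$counts
  des <- sim$design
  run <- function(tab, design) {
    permutation_test(bray_curtis(tab), design, c("Treatment", "Plot"),
                     "Treatment", perm_scheme("whole_plot"), "whole_plot")
  }
  t1 <- run(d, des)
  o <- withr::with_seed(1, sample.int(nrow(des)))
  des2 <- study_design(as.data.frame(des)[o, ])
  d2 <- count_table(unclass(d)[o, ])
  t2 <- run(d2, des2)
  expect_equal(t1["Treatment", "F"], t2["Treatment", "F"], tolerance = 1e-10)
  expect_equal(t1["Treatment", "p"], t2["Treatment", "p"])
})

test_that("scheme/term mismatches are configuration errors", {
  des <- make_design(2L, days = c(0L, 1L))
  d <- bray_curtis(random_counts(des, 10L, seed = 1))
  expect_error(permutation_test(d, des, c("Treatment", "Plot"), "Treatment",
                                perm_scheme("within_plot"), "whole_plot"),
               "not a valid randomization")
  expect_error(permutation_test(d, des, c("Plot", "Day"), "Day",
                                perm_scheme("free_within_block")),
               "not a valid randomization")
  expect_error(permutation_test(d, des, c("Treatment", "Plot"), "Treatment",
                                perm_scheme("free_within_block")),
               "single-day")
})
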