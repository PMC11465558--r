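#' Pairwise day-versus-baseline PERMANOVAs within one treatment
#'
#' For each post-baseline day, the treatment's samples on day 0 and that
#' day are compared with a one-factor (Day) PERMANOVA whose p-value
#' comes from the paired within-plot permutation group (each plot either
#' swaps its two samples or not; with m complete plots the group has
#' 2^m elements and attainable p-values are multiples of 1/2^m). A
#' dispersion contrast (day-0 vs day distances to center) is computed
#' alongside on the same subset.
#'
#' @param d a [dist_matrix()] over all samples
#' @param design the matching [study_design()]
#' @param treatment treatment level analysed
#' @param scheme a [perm_scheme()] with level `"paired_within_plot"`
#' @param center dispersion center (see [distances_to_center()])
#' @return data.frame: `day`, `p` (composition), `dispersion_p`,
#'   `n_plots` (plots with both days), `group_size`
#' @export
pairwise_day_tests <- function(d, design, treatment,
                               scheme = perm_scheme("paired_within_plot"),
                               center = "spatial_median") {
  if (!treatment %in% design$treatment)
    stop("treatment not in design: ", treatment)
  sub_all <- which(design$treatment == treatment)
  if (!0L %in% design$day[sub_all])
    stop("treatment has no day-0 samples")
  days <- setdiff(sort(unique(design$day[sub_all])), 0L)
  rows <- lapply(days, function(dy) {
    keep <- sub_all[design$day[sub_all] %in% c(0L, dy)]
    des <- design[keep, , drop = FALSE]
    ## drop plots lacking either day
    cnt <- table(des$plot)
    full <- names(cnt)[cnt == 2L]
    if (length(full) == 0L)
      return(data.frame(day = dy, p = NA_real_, dispersion_p = NA_real_,
                        n_plots = 0L, group_size = NA_real_))
    des <- des[des$plot %in% full, , drop = FALSE]
    dd <- dist_matrix(unclass(d)[des$sample_id, des$sample_id],
                      metric = attr(d, "metric"))
    des <- study_design(as.data.frame(des))
    tab <- permutation_test(dd, des, terms = "Day", term = "Day",
                            scheme = scheme, denominator = "residual")
    disp <- tryCatch({
      r <- distances_to_center(pcoa(dd), factor(des$day), center = center)
      dispersion_test(r)$p_parametric
    }, error = function(e) NA_real_)
    data.frame(day = dy, p = tab["Day", "p"], dispersion_p = disp,
               n_plots = length(full), group_size = attr(tab, "group_size"))
  })
  out <- do.call(rbind, rows)
  attr(out, "treatment") <- treatment
  out
}

#' First day of significant compositional change
#'
#' Resistance rule: the earliest day whose day-versus-baseline p falls
#' below alpha; `NA` if composition never changes significantly.
#'
#' @param report data.frame with `day` and `p` (from
#'   [pairwise_day_tests()]), days in increasing order
#' @param alpha significance level (default 0.05)
#' @return day (integer) or `NA`
#' @export
first_change_day <- function(report, alpha = 0.05) {
  ok <- !is.na(report$p)
  hit <- which(ok & report$p < alpha)
  if (length(hit) == 0L) NA_integer_ else as.integer(report$day[min(hit)])
}

#' First day of recovery after a significant change
#'
#' Resilience rule: the earliest day after [first_change_day()] whose p
#' is at least alpha; `NA` if the composition stays significantly
#' shifted through the end. Later re-excursions are not part of the
#' rule; inspect the full p series for them.
#'
#' @inheritParams first_change_day
#' @return day (integer) or `NA`
#' @export
recovery_day <- function(report, alpha = 0.05) {
  fc <- first_change_day(report, alpha)
  if (is.na(fc)) stop("recovery_day is undefined without a change day")
  after <- report[report$day > fc & !is.na(report$p), , drop = FALSE]
  hit <- which(after$p >= alpha)
  if (length(hit) == 0L) NA_integer_ else as.integer(after$day[min(hit)])
}

#' Per-plot Bray-Curtis trajectory from each plot's own baseline
#'
#' value(plot, day) = d(sample(plot, 0), sample(plot, day)).
#'
#' @param d a [dist_matrix()]
#' @param design the matching [study_design()]
#' @return data.frame: `plot`, `block`, `treatment`, `day`,
#'   `dissimilarity`; plots without a day-0 sample are skipped and
#'   reported via attribute `missing_baseline`
#' @export
baseline_dissimilarity_series <- function(d, design) {
  dm <- unclass(d)
  rows <- list()
  missing <- character()
  for (pl in unique(design$plot)) {
    idx <- which(design$plot == pl)
    i0 <- idx[design$day[idx] == 0L]
    if (length(i0) == 0L) {
      missing <- c(missing, pl)
      next
    }
    s0 <- design$sample_id[i0[1L]]
    rows[[pl]] <- data.frame(
      plot = pl,
      block = design$block[idx[1L]],
      treatment = design$treatment[idx[1L]],
      day = design$day[idx],
      dissimilarity = dm[s0, design$sample_id[idx]],
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "missing_baseline") <- missing
  out
}

#' Cross-treatment comparison of baseline dissimilarity at one day
#'
#' Block-restricted permutation test on the per-plot dissimilarities:
#' the statistic is the absolute difference of treatment means, and plot
#' treatment labels are permuted within blocks. All pairwise treatment
#' contrasts are reported with Holm adjustment.
#'
#' @param series output of [baseline_dissimilarity_series()]
#' @param day the day compared
#' @param n_perm Monte-Carlo draws when the within-block label group is
#'   large (default 999)
#' @param exhaustive_threshold enumerate when the group is at most this
#' @param seed integer seed
#' @return data.frame: `treatment_a`, `treatment_b`, `mean_a`, `mean_b`,
#'   `statistic`, `p`, `p_holm`
#' @export
compare_dissimilarity <- function(series, day, n_perm = 999L,
                                  exhaustive_threshold = 10000L, seed = 1L) {
  s <- series[series$day == day, , drop = FALSE]
  trts <- sort(unique(s$treatment))
  if (length(trts) < 2L) stop("need at least 2 treatments at that day")
  pairs <- utils::combn(trts, 2L, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    ss <- s[s$treatment %in% pr, , drop = FALSE]
    val <- ss$dissimilarity
    lab <- ss$treatment
    blk <- ss$block
    stat <- function(lab) {
      abs(mean(val[lab == pr[1L]]) - mean(val[lab == pr[2L]]))
    }
    obs <- stat(lab)
    strata <- split(seq_along(val), blk)
    group_size <- prod(vapply(strata, function(i) factorial(length(i)),
                              numeric(1)))
    if (group_size <= exhaustive_threshold) {
      perms <- combine_strata_perms(length(val), strata,
        lapply(vapply(strata, length, integer(1)), all_perms))
      f_perm <- vapply(perms, function(p) stat(lab[p]), numeric(1))
      p <- perm_pvalue(obs, f_perm, exhaustive = TRUE)
    } else {
      f_perm <- withr::with_seed(as.integer(seed) + k, {
        vapply(seq_len(n_perm), function(i) {
          stat(lab[draw_strata_perm(length(val), strata)])
        }, numeric(1))
      })
      p <- perm_pvalue(obs, f_perm, exhaustive = FALSE)
    }
    data.frame(treatment_a = pr[1L], treatment_b = pr[2L],
               mean_a = mean(val[lab == pr[1L]]),
               mean_b = mean(val[lab == pr[2L]]),
               statistic = obs, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Heatmap-ready matrix of selected taxa
#'
#' log10(relative abundance + pseudocount), rows (taxa) centered and
#' scaled to unit variance, columns ordered by treatment panel then
#' chronological day. Constant rows are centered but left unscaled and
#' flagged.
#'
#' @param table a relative-abundance matrix (samples as rows)
#' @param taxa taxa to keep (subset of the table's taxa)
#' @param design the matching [study_design()]
#' @param pseudocount added before the log (default 1e-6)
#' @return taxa x samples matrix of class `heatmap_matrix` with
#'   attributes `pseudocount`, `constant_rows`, `column_order`
#' @export
heatmap_matrix <- function(table, taxa, design, pseudocount = 1e-6) {
  if (!all(taxa %in% colnames(table)))
    stop("taxa not present in the table: ",
         paste(setdiff(taxa, colnames(table)), collapse = ", "))
  ord <- order(match(design$treatment, valid_treatments()), design$day,
               design$plot)
  samples <- design$sample_id[ord]
  m <- t(unclass(table)[samples, taxa, drop = FALSE])
  m <- log10(m + pseudocount)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  constant <- sdv <= 1e-12
  m <- m - mu
  m[!constant, ] <- m[!constant, , drop = FALSE] / sdv[!constant]
  structure(m, class = c("heatmap_matrix", "matrix", "array"),
            pseudocount = pseudocount,
            constant_rows = rownames(m)[constant],
            column_order = samples)
}

#' Full recovery trajectory report for every treatment
#'
#' Runs [pairwise_day_tests()], [first_change_day()], [recovery_day()]
#' and [baseline_dissimilarity_series()] per treatment.
#'
#' @param d a [dist_matrix()]
#' @param design the matching [study_design()]
#' @param alpha significance level (default 0.05)
#' @param scheme paired scheme passed to [pairwise_day_tests()]
#' @return list of class `trajectory_report`: per treatment a list with
#'   `day_tests`, `first_change_day`, `recovery_day`; plus `series` (the
#'   per-plot dissimilarity trajectories) and `alpha`
#' @export
trajectory_report <- function(d, design, alpha = 0.05,
                              scheme = perm_scheme("paired_within_plot")) {
  trts <- sort(unique(design$treatment))
  per_trt <- lapply(trts, function(tr) {
    tests <- pairwise_day_tests(d, design, tr, scheme = scheme)
    fc <- first_change_day(tests, alpha)
    rc <- if (is.na(fc)) NA_integer_ else recovery_day(tests, alpha)
    list(day_tests = tests, first_change_day = fc, recovery_day = rc)
  })
  names(per_trt) <- trts
  structure(c(per_trt, list(series = baseline_dissimilarity_series(d, design),
                            alpha = alpha)),
            class = "trajectory_report")
}
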