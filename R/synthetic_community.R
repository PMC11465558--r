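#' Simulation parameters for the blocked salinity-pulse design
#'
#' Defaults emulate the field layout the package targets: 8 blocks each
#' holding one plot per treatment (control, novel disturbance, repeated
#' disturbance; 24 plots total), sampled on 10 days spanning two months.
#' Community structure is generated on the log scale: a taxon baseline
#' plus Gaussian block, plot and sample effects, a sustained (press)
#' compositional shift in the repeated-disturbance treatment, and a
#' transient (pulse) shift in both disturbed treatments that decays
#' exponentially after onset. Counts are Dirichlet-multinomial at a
#' negative-binomial sequencing depth.
#'
#' @param n_blocks number of blocks (default 8)
#' @param days sampling days, strictly increasing, starting at 0
#' @param n_taxa number of taxa simulated
#' @param depth_mean,depth_dispersion negative-binomial mean and size of
#'   per-sample sequencing depth
#' @param baseline_sd sd of per-taxon baseline log-abundances
#' @param sigma_block,sigma_plot,sigma_sample sd of log-scale random
#'   effects at block, plot and sample level
#' @param press_shift log-scale sustained displacement applied in the
#'   repeated treatment: +shift for tolerant taxa, -shift for sensitive
#' @param dispersion_shrink multiplier (< 1) on `sigma_plot` in the
#'   repeated treatment, producing its reduced compositional variance
#' @param pulse_depth_novel,pulse_depth_repeated initial log-scale pulse
#'   magnitude per treatment (sensitive taxa down, tolerant up)
#' @param recovery_halflife_novel,recovery_halflife_repeated exponential
#'   decay timescale tau (days) of the pulse per treatment
#' @param pulse_onset_day first day the pulse acts (default 1: the
#'   day-0 baseline is sampled before salinity rises)
#' @param frac_sensitive,frac_tolerant fractions of taxa designated
#'   salt-sensitive / salt-tolerant (the rest are neutral)
#' @param concentration Dirichlet concentration scaling; smaller values
#'   give more count overdispersion
#' @param seed integer seed
#' @return list of class `sim_params`
#' @export
sim_params <- function(n_blocks = 8L,
                       days = c(0L, 1L, 3L, 6L, 8L, 14L, 20L, 28L, 42L, 55L),
                       n_taxa = 300L,
                       depth_mean = 20000, depth_dispersion = 10,
                       baseline_sd = 1,
                       sigma_block = 0.3, sigma_plot = 0.4, sigma_sample = 0.3,
                       press_shift = 1,
                       dispersion_shrink = 0.6,
                       pulse_depth_novel = 2, pulse_depth_repeated = 0.5,
                       recovery_halflife_novel = 6, recovery_halflife_repeated = 2,
                       pulse_onset_day = 1L,
                       frac_sensitive = 0.2, frac_tolerant = 0.2,
                       concentration = 300,
                       seed = 1L) {
  p <- list(n_blocks = as.integer(n_blocks), treatments = valid_treatments(),
            days = as.integer(days), n_taxa = as.integer(n_taxa),
            depth_mean = depth_mean, depth_dispersion = depth_dispersion,
            baseline_sd = baseline_sd,
            sigma_block = sigma_block, sigma_plot = sigma_plot,
            sigma_sample = sigma_sample,
            press_shift = press_shift, dispersion_shrink = dispersion_shrink,
            pulse_depth_novel = pulse_depth_novel,
            pulse_depth_repeated = pulse_depth_repeated,
            recovery_halflife_novel = recovery_halflife_novel,
            recovery_halflife_repeated = recovery_halflife_repeated,
            pulse_onset_day = as.integer(pulse_onset_day),
            frac_sensitive = frac_sensitive, frac_tolerant = frac_tolerant,
            concentration = concentration, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$n_blocks >= 1L, p$n_taxa >= 2L)
  if (length(p$days) < 1L || p$days[1L] != 0L || is.unsorted(p$days, strictly = TRUE))
    stop("days must be strictly increasing with days[1] = 0")
  for (nm in c("sigma_block", "sigma_plot", "sigma_sample", "baseline_sd"))
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  if (p$recovery_halflife_novel <= 0 || p$recovery_halflife_repeated <= 0)
    stop("recovery halflives (tau) must be > 0")
  if (p$frac_sensitive < 0 || p$frac_tolerant < 0 ||
      p$frac_sensitive + p$frac_tolerant > 1)
    stop("taxon role fractions must be in [0,1] and sum to at most 1")
  if (p$dispersion_shrink < 0) stop("dispersion_shrink must be >= 0")
  if (p$concentration <= 0) stop("concentration must be > 0")
  invisible(p)
}

#' Null simulation parameters
#'
#' All treatment effects (press shift, pulse depths) are zero and the
#' repeated treatment keeps the common plot variance, so the three
#' treatments are exchangeable; block/plot/sample variances stay at
#' their defaults. Used for type-I-error calibration.
#'
#' @param ... overrides passed to [sim_params()]
#' @return `sim_params` with no treatment effect
#' @export
null_params <- function(...) {
  sim_params(press_shift = 0, dispersion_shrink = 1,
             pulse_depth_novel = 0, pulse_depth_repeated = 0, ...)
}

#' Exponentially decaying pulse effect
#'
#' Log-scale multiplier of a transient disturbance: 0 before onset,
#' `delta0 * exp(-(day - onset_day)/tau)` from onset on.
#'
#' @param day sampling day (vectorized)
#' @param delta0 initial log-scale shift at onset
#' @param tau decay timescale in days (> 0)
#' @param onset_day first day the disturbance acts
#' @return numeric vector of log-scale shifts
#' @export
pulse_effect <- function(day, delta0, tau, onset_day = 1L) {
  if (tau <= 0) stop("tau must be > 0")
  ifelse(day < onset_day, 0, delta0 * exp(-(day - onset_day) / tau))
}

#' Simulate a blocked salinity-pulse study
#'
#' @param params a [sim_params()]
#' @return list with elements `counts` (a [count_table()]), `design` (a
#'   [study_design()]) and `truth` (taxon roles, realized block/plot
#'   effects, and each sample's expected composition)
#' @export
simulate_study <- function(params = sim_params()) {
  validate_sim_params(params)
  p <- params
  trts <- p$treatments
  n_plots <- p$n_blocks * length(trts)
  blocks <- sprintf("B%d", seq_len(p$n_blocks))
  plots <- as.vector(outer(trts, blocks, function(t, b) paste0(b, "_", t)))
  plot_block <- rep(blocks, each = length(trts))
  plot_trt <- rep(trts, times = p$n_blocks)

  design <- expand.grid(day = p$days, plot = plots,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$block <- plot_block[match(design$plot, plots)]
  design$treatment <- plot_trt[match(design$plot, plots)]
  design$sample_id <- paste0(design$plot, "_d", design$day)
  design <- design[, c("sample_id", "plot", "block", "treatment", "day")]
  n <- nrow(design)

  ## taxon roles: leading indices sensitive, trailing tolerant
  n_sens <- round(p$frac_sensitive * p$n_taxa)
  n_tol <- round(p$frac_tolerant * p$n_taxa)
  role <- rep("neutral", p$n_taxa)
  if (n_sens > 0) role[seq_len(n_sens)] <- "sensitive"
  if (n_tol > 0) role[p$n_taxa - seq_len(n_tol) + 1L] <- "tolerant"
  role_sign <- ifelse(role == "sensitive", -1, ifelse(role == "tolerant", 1, 0))
  taxa <- sprintf("ASV%04d", seq_len(p$n_taxa))

  withr::with_seed(p$seed, {
    base <- stats::rnorm(p$n_taxa, 0, p$baseline_sd)
    block_eff <- matrix(stats::rnorm(p$n_taxa * p$n_blocks, 0, p$sigma_block),
                        p$n_taxa, p$n_blocks, dimnames = list(taxa, blocks))
    plot_sd <- ifelse(plot_trt == "repeated",
                      p$sigma_plot * p$dispersion_shrink, p$sigma_plot)
    plot_eff <- matrix(stats::rnorm(p$n_taxa * n_plots, 0,
                                    rep(plot_sd, each = p$n_taxa)),
                       p$n_taxa, n_plots, dimnames = list(taxa, plots))

    comp <- matrix(0, n, p$n_taxa, dimnames = list(design$sample_id, taxa))
    for (j in seq_len(n)) {
      trt <- design$treatment[j]
      eta <- base +
        block_eff[, design$block[j]] +
        plot_eff[, design$plot[j]] +
        stats::rnorm(p$n_taxa, 0, p$sigma_sample)
      if (trt == "repeated")
        eta <- eta + role_sign * p$press_shift
      if (trt != "control") {
        delta0 <- if (trt == "novel") p$pulse_depth_novel else p$pulse_depth_repeated
        tau <- if (trt == "novel") p$recovery_halflife_novel else p$recovery_halflife_repeated
        eta <- eta + role_sign *
          pulse_effect(design$day[j], delta0, tau, p$pulse_onset_day)
      }
      w <- exp(eta - max(eta))
      comp[j, ] <- w / sum(w)
    }

    depth <- stats::rnbinom(n, mu = p$depth_mean, size = p$depth_dispersion)
    depth <- pmax(depth, 100L)  # guard against degenerate empty samples
    counts <- matrix(0L, n, p$n_taxa, dimnames = list(design$sample_id, taxa))
    for (j in seq_len(n)) {
      g <- stats::rgamma(p$n_taxa, shape = p$concentration * comp[j, ])
      g[is.na(g)] <- 0
      if (sum(g) == 0) g <- comp[j, ]
      counts[j, ] <- stats::rmultinom(1L, depth[j], g / sum(g))[, 1L]
    }
    list(counts = count_table(counts),
         design = study_design(design),
         truth = list(role = stats::setNames(role, taxa),
                      block_effects = block_eff,
                      plot_effects = plot_eff,
                      expected_composition = comp))
  })
}
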