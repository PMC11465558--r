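#' Permutation scheme specification
#'
#' The four exchangeability structures of a blocked split-plot
#' time-series design:
#' * `whole_plot` — plots exchange freely within blocks, each plot's
#'   time series moving as a unit (tests between-plot factors such as
#'   Treatment);
#' * `within_plot` — sampling days shuffle within each plot
#'   independently (tests within-plot factors such as Day);
#' * `paired_within_plot` — with exactly two days per plot, each plot
#'   either swaps its two samples or not (2^m patterns over m plots);
#' * `free_within_block` — single-day data; samples shuffle freely
#'   within their block.
#'
#' @param level one of `"whole_plot"`, `"within_plot"`,
#'   `"paired_within_plot"`, `"free_within_block"`
#' @param n_permutations Monte-Carlo draws when the group is too large
#'   to enumerate (default 999)
#' @param exhaustive_threshold enumerate the full group when its size is
#'   at most this (default 10000)
#' @param seed integer seed for Monte-Carlo draws
#' @return list of class `perm_scheme`
#' @export
perm_scheme <- function(level = c("whole_plot", "within_plot",
                                  "paired_within_plot", "free_within_block"),
                        n_permutations = 999L,
                        exhaustive_threshold = 10000L,
                        seed = 1L) {
  level <- match.arg(level)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  structure(list(level = level, n_permutations = as.integer(n_permutations),
                 exhaustive_threshold = as.integer(exhaustive_threshold),
                 seed = as.integer(seed)),
            class = "perm_scheme")
}

## all permutations of 1..k as a list (k small: used per stratum)
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- vector("list", factorial(k))
  i <- 0L
  for (j in seq_len(k)) {
    for (q in all_perms(k - 1L)) {
      i <- i + 1L
      rest <- seq_len(k)[-j]
      out[[i]] <- c(j, rest[q])
    }
  }
  out
}

## cartesian product of per-stratum permutation lists -> sample-level
## bijections. `strata_idx` gives the sample indices of each stratum;
## `strata_perms[[s]]` permutes positions within stratum s.
combine_strata_perms <- function(n, strata_idx, strata_perms) {
  counts <- vapply(strata_perms, length, integer(1))
  grid <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    p <- seq_len(n)
    for (s in seq_along(strata_idx)) {
      idx <- strata_idx[[s]]
      p[idx] <- idx[strata_perms[[s]][[grid[r, s]]]]
    }
    p
  })
}

## one uniform draw: independent random shuffle inside each stratum
draw_strata_perm <- function(n, strata_idx) {
  p <- seq_len(n)
  for (idx in strata_idx)
    if (length(idx) > 1L) p[idx] <- idx[sample.int(length(idx))]
  p
}

make_perm_set <- function(perms, exhaustive, group_size, level,
                          includes_identity) {
  structure(list(perms = perms, exhaustive = exhaustive,
                 group_size = group_size, level = level,
                 includes_identity = includes_identity),
            class = "perm_set")
}

#' @export
print.perm_set <- function(x, ...) {
  cat(sprintf("perm_set[%s]: %d permutations (%s; group size %.6g)\n",
              x$level, length(x$perms),
              if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$group_size))
  invisible(x)
}

## strata as sample-index lists keyed by a factor
split_indices <- function(design, key) {
  split(seq_len(nrow(design)), design[[key]])
}

#' Whole-plot permutations: plots exchange within blocks
#'
#' Plot labels permute freely within each block; every sample of a plot
#' moves with it (time order untouched). Exchanged plots must have been
#' sampled on the same days, otherwise no sample-level bijection exists.
#' Group size is the product over blocks of (number of plots)!.
#'
#' @param design a [study_design()]
#' @param scheme a [perm_scheme()] with level `"whole_plot"`
#' @return a `perm_set` of sample-index bijections
#' @export
whole_plot_permutations <- function(design, scheme = perm_scheme("whole_plot")) {
  n <- nrow(design)
  blocks <- split(unique(design[, c("plot", "block")])$plot,
                  unique(design[, c("plot", "block")])$block)
  if (any(vapply(blocks, length, integer(1)) == 1L))
    warning("block(s) with a single plot contribute only the identity")
  plot_samples <- split_indices(design, "plot")
  ## day-matched sample lists per plot, and the within-block day check
  plot_days <- lapply(plot_samples, function(idx) design$day[idx])
  for (b in names(blocks)) {
    ds <- lapply(blocks[[b]], function(p) sort(plot_days[[p]]))
    if (length(unique(ds)) > 1L)
      stop("plots within block ", b,
           " have different day sets; whole-plot exchange is undefined")
  }
  ## per-block "stratum permutations" act on plots; expand to samples
  block_perm_lists <- lapply(blocks, function(ps) all_perms(length(ps)))
  group_size <- prod(vapply(blocks, function(ps) factorial(length(ps)),
                            numeric(1)))
  expand_plot_perm <- function(assign_list) {
    ## assign_list: named list block -> permutation of its plot positions
    p <- integer(n)
    for (b in names(blocks)) {
      ps <- blocks[[b]]
      tgt <- ps[assign_list[[b]]]
      for (j in seq_along(ps)) {
        src_idx <- plot_samples[[ps[j]]]
        dst_idx <- plot_samples[[tgt[j]]]
        p[src_idx] <- dst_idx[match(design$day[src_idx], design$day[dst_idx])]
      }
    }
    p
  }
  if (group_size <= scheme$exhaustive_threshold) {
    counts <- vapply(block_perm_lists, length, integer(1))
    grid <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
    perms <- lapply(seq_len(nrow(grid)), function(r) {
      expand_plot_perm(stats::setNames(
        lapply(seq_along(blocks),
               function(s) block_perm_lists[[s]][[grid[r, s]]]),
        names(blocks)))
    })
    make_perm_set(perms, TRUE, group_size, "whole_plot", TRUE)
  } else {
    perms <- withr::with_seed(scheme$seed, {
      lapply(seq_len(scheme$n_permutations), function(i) {
        expand_plot_perm(stats::setNames(
          lapply(blocks, function(ps) sample.int(length(ps))),
          names(blocks)))
      })
    })
    make_perm_set(perms, FALSE, group_size, "whole_plot", FALSE)
  }
}

## Whole-plot randomization as plot-label reassignments: each element is
## a named map plot -> source plot (the plot whose treatment it adopts),
## with sources drawn only from the same block. Well-defined even when
## attrition leaves plots with unequal day sets, where the sample-level
## bijection of whole_plot_permutations() does not exist; on complete
## designs the two formulations induce identical statistics.
whole_plot_assignments <- function(design, scheme) {
  pb <- unique(as.data.frame(design)[, c("plot", "block")])
  blocks <- split(pb$plot, pb$block)
  group_size <- prod(vapply(blocks, function(ps) factorial(length(ps)),
                            numeric(1)))
  assignment <- function(per_block) {
    ## per_block: list block -> permutation of its plot positions
    out <- character(0)
    for (b in names(blocks)) {
      ps <- blocks[[b]]
      out[ps] <- ps[per_block[[b]]]
    }
    out
  }
  if (group_size <= scheme$exhaustive_threshold) {
    lists <- lapply(blocks, function(ps) all_perms(length(ps)))
    grid <- expand.grid(lapply(vapply(lists, length, integer(1)), seq_len),
                        KEEP.OUT.ATTRS = FALSE)
    asg <- lapply(seq_len(nrow(grid)), function(r) {
      assignment(stats::setNames(
        lapply(seq_along(blocks), function(s) lists[[s]][[grid[r, s]]]),
        names(blocks)))
    })
    make_perm_set(asg, TRUE, group_size, "whole_plot", TRUE)
  } else {
    asg <- withr::with_seed(scheme$seed, {
      lapply(seq_len(scheme$n_permutations), function(i) {
        assignment(stats::setNames(
          lapply(blocks, function(ps) sample.int(length(ps))),
          names(blocks)))
      })
    })
    make_perm_set(asg, FALSE, group_size, "whole_plot", FALSE)
  }
}

#' Within-plot permutations: days shuffle inside each plot
#'
#' @inheritParams whole_plot_permutations
#' @param scheme a [perm_scheme()] with level `"within_plot"`
#' @return a `perm_set`
#' @export
within_plot_permutations <- function(design, scheme = perm_scheme("within_plot")) {
  n <- nrow(design)
  strata <- split_indices(design, "plot")
  sizes <- vapply(strata, length, integer(1))
  if (all(sizes < 2L)) stop("no plot holds 2 or more samples")
  group_size <- prod(factorial(sizes))
  if (group_size <= scheme$exhaustive_threshold) {
    perms <- combine_strata_perms(n, strata, lapply(sizes, all_perms))
    make_perm_set(perms, TRUE, group_size, "within_plot", TRUE)
  } else {
    perms <- withr::with_seed(scheme$seed, {
      lapply(seq_len(scheme$n_permutations),
             function(i) draw_strata_perm(n, strata))
    })
    make_perm_set(perms, FALSE, group_size, "within_plot", FALSE)
  }
}

#' Paired within-plot permutations for two-day contrasts
#'
#' For data restricted to two days, each plot holding both days either
#' swaps its two samples or keeps them: 2^m patterns over the m complete
#' plots. Plots missing either day are excluded and reported.
#'
#' @inheritParams whole_plot_permutations
#' @param scheme a [perm_scheme()] with level `"paired_within_plot"`
#' @return a `perm_set` with attribute `excluded_plots`
#' @export
paired_within_plot_permutations <- function(design,
                                            scheme = perm_scheme("paired_within_plot")) {
  days <- sort(unique(design$day))
  if (length(days) != 2L)
    stop("paired scheme needs a design restricted to exactly two days")
  n <- nrow(design)
  strata <- split_indices(design, "plot")
  complete <- vapply(strata, function(idx) {
    length(idx) == 2L && setequal(design$day[idx], days)
  }, logical(1))
  excluded <- names(strata)[!complete]
  if (length(excluded) > 0L)
    message("paired scheme: excluding plot(s) without both days: ",
            paste(excluded, collapse = ", "))
  strata <- strata[complete]
  m <- length(strata)
  if (m == 0L) stop("no plot holds both days; paired test impossible")
  group_size <- 2^m
  if (group_size <= scheme$exhaustive_threshold) {
    swap_lists <- rep(list(list(1:2, 2:1)), m)
    perms <- combine_strata_perms(n, strata, swap_lists)
    ps <- make_perm_set(perms, TRUE, group_size, "paired_within_plot", TRUE)
  } else {
    perms <- withr::with_seed(scheme$seed, {
      lapply(seq_len(scheme$n_permutations), function(i) {
        p <- seq_len(n)
        for (idx in strata) if (stats::runif(1) < 0.5) p[idx] <- rev(idx)
        p
      })
    })
    ps <- make_perm_set(perms, FALSE, group_size, "paired_within_plot", FALSE)
  }
  attr(ps, "excluded_plots") <- excluded
  ps
}

#' Free permutations within blocks (single-day data)
#'
#' @inheritParams whole_plot_permutations
#' @param scheme a [perm_scheme()] with level `"free_within_block"`
#' @return a `perm_set`
#' @export
free_within_block_permutations <- function(design,
                                           scheme = perm_scheme("free_within_block")) {
  if (length(unique(design$day)) > 1L)
    stop("free_within_block applies to single-day data; subset first")
  n <- nrow(design)
  strata <- split_indices(design, "block")
  sizes <- vapply(strata, length, integer(1))
  group_size <- prod(factorial(sizes))
  if (group_size <= scheme$exhaustive_threshold) {
    perms <- combine_strata_perms(n, strata, lapply(sizes, all_perms))
    make_perm_set(perms, TRUE, group_size, "free_within_block", TRUE)
  } else {
    perms <- withr::with_seed(scheme$seed, {
      lapply(seq_len(scheme$n_permutations),
             function(i) draw_strata_perm(n, strata))
    })
    make_perm_set(perms, FALSE, group_size, "free_within_block", FALSE)
  }
}

#' Generate the permutation set for a scheme
#' @param design a [study_design()]
#' @param scheme a [perm_scheme()]
#' @return a `perm_set`
#' @export
generate_permutations <- function(design, scheme) {
  switch(scheme$level,
         whole_plot = whole_plot_permutations(design, scheme),
         within_plot = within_plot_permutations(design, scheme),
         paired_within_plot = paired_within_plot_permutations(design, scheme),
         free_within_block = free_within_block_permutations(design, scheme))
}

#' Check that a permutation respects a scheme's restriction
#'
#' Independent validity audit: verifies bijectivity and the
#' exchangeability restriction of the given level, without reference to
#' how the permutation was generated.
#'
#' @param perm integer vector (sample-index bijection)
#' @param design a [study_design()]
#' @param level a scheme level (see [perm_scheme()])
#' @return TRUE/FALSE
#' @export
check_permutation <- function(perm, design, level) {
  n <- nrow(design)
  if (!setequal(perm, seq_len(n))) return(FALSE)
  switch(level,
    whole_plot = {
      ## same-plot samples must land in a common plot, in a block-mate,
      ## with days preserved sample-wise
      if (!all(design$day[perm] == design$day)) return(FALSE)
      dest <- tapply(design$plot[perm], design$plot, function(x) length(unique(x)))
      if (any(dest != 1L)) return(FALSE)
      all(design$block[perm] == design$block)
    },
    within_plot = all(design$plot[perm] == design$plot),
    paired_within_plot = {
      all(design$plot[perm] == design$plot) &&
        all(perm == seq_len(n) | design$day[perm] != design$day)
    },
    free_within_block = all(design$block[perm] == design$block),
    stop("unknown level: ", level))
}

#' Permutation p-value
#'
#' Exhaustive reference sets (identity included as a group element) use
#' p = #\{F_perm >= F_obs\} / group size; Monte-Carlo sets use
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm), the identity providing
#' the +1. Ties count as >= with tolerance 1e-12.
#'
#' @param f_obs observed statistic
#' @param f_perm statistics of the permutation set (identity included
#'   only when `exhaustive`)
#' @param exhaustive whether `f_perm` is the full group
#' @return p-value in (0, 1]
#' @export
perm_pvalue <- function(f_obs, f_perm, exhaustive) {
  hits <- sum(f_perm >= f_obs - 1e-12)
  if (exhaustive) hits / length(f_perm)
  else (1 + hits) / (1 + length(f_perm))
}
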