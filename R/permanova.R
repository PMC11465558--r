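#' Design-term dummy columns
#'
#' @param design a [study_design()]
#' @param term one of `"Treatment"`, `"Plot"`, `"Day"`, `"Block"`,
#'   `"Day:Treatment"`
#' @return model matrix of indicator columns (no intercept)
#' @keywords internal
term_matrix <- function(design, term) {
  f <- switch(term,
              Treatment = factor(design$treatment),
              Plot = factor(design$plot),
              Block = factor(design$block),
              Day = factor(design$day),
              "Day:Treatment" = interaction(factor(design$day),
                                            factor(design$treatment),
                                            drop = TRUE),
              stop("unknown model term: ", term))
  stats::model.matrix(~ 0 + f)
}

#' Projection (hat) matrix of a term set
#'
#' Symmetric idempotent projector onto the column span of the intercept
#' plus the dummy columns of the given terms, computed from a pivoted QR
#' so rank-deficient (aliased) encodings are handled without a crash.
#'
#' @param design a [study_design()]
#' @param terms character vector of term names (may be empty:
#'   intercept-only averaging projector)
#' @return list with `H` (projection matrix) and `rank`
#' @export
projector <- function(design, terms = character()) {
  X <- cbind(`(Intercept)` = rep(1, nrow(design)))
  for (t in terms) X <- cbind(X, term_matrix(design, t))
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = qx$rank)
}

#' Sequential distance-based sums of squares
#'
#' Partitions trace(G) over an ordered term list: the sum of squares of
#' term t is trace(H_{<=t} G) - trace(H_{<t} G) with H the cumulative
#' projectors, exactly the sequential ("Type I") decomposition used by
#' distance-based ANOVA. Terms left with zero degrees of freedom after
#' earlier terms are reported with df 0 and flagged aliased, never
#' silently dropped.
#'
#' @param G Gower-centered inner-product matrix (see [gower_center()])
#' @param terms ordered character vector of model terms
#' @param design a [study_design()] with rows matching G
#' @return data.frame of class `permanova_table` with one row per term
#'   plus `Residual` and `Total`: columns `df`, `SS`, `MS`, `R2`,
#'   `aliased`
#' @export
sequential_ss <- function(G, terms, design) {
  if (nrow(G) != nrow(design)) stop("G and design differ in sample count")
  n <- nrow(G)
  ss_total <- sum(diag(G))
  tr_prev <- 0  # trace(H_intercept G) = 0 since G is centered
  rank_prev <- 1L
  rows <- list()
  cum <- character()
  for (t in terms) {
    cum <- c(cum, t)
    pj <- projector(design, cum)
    tr_now <- sum(pj$H * G)
    df <- pj$rank - rank_prev
    rows[[t]] <- data.frame(term = t, df = df, SS = tr_now - tr_prev,
                            aliased = df == 0L)
    tr_prev <- tr_now
    rank_prev <- pj$rank
  }
  df_res <- n - rank_prev
  res <- do.call(rbind, c(rows, list(
    data.frame(term = "Residual", df = df_res, SS = ss_total - tr_prev,
               aliased = FALSE),
    data.frame(term = "Total", df = n - 1L, SS = ss_total, aliased = FALSE))))
  rownames(res) <- res$term
  res$MS <- ifelse(res$df > 0, res$SS / res$df, NA_real_)
  res$R2 <- res$SS / ss_total
  class(res) <- c("permanova_table", "data.frame")
  res
}

#' Pseudo-F for a term
#'
#' `denominator = "residual"` forms MS(term)/MS(residual);
#' `denominator = "whole_plot"` forms MS(term)/MS(Plot), the
#' plots-within-treatment (whole-plot error) stratum of a split-plot
#' model in which Treatment is fitted before Plot.
#'
#' @param table a `permanova_table` from [sequential_ss()]
#' @param term tested term name
#' @param denominator `"residual"` or `"whole_plot"`
#' @return pseudo-F value (0 when the term SS is 0; Inf with a warning
#'   when the denominator SS is 0 but the term SS is not)
#' @export
pseudo_f <- function(table, term, denominator = c("residual", "whole_plot")) {
  denominator <- match.arg(denominator)
  if (!term %in% rownames(table)) stop("term not in table: ", term)
  den_row <- if (denominator == "residual") "Residual" else "Plot"
  if (!den_row %in% rownames(table))
    stop("whole_plot denominator requires a Plot term in the model")
  num <- table[term, ]
  den <- table[den_row, ]
  if (num$df == 0L) return(NA_real_)
  if (den$df == 0L || den$SS <= 1e-12) {
    if (num$SS <= 1e-12) return(0)
    warning("zero denominator sum of squares; pseudo-F is infinite")
    return(Inf)
  }
  (num$SS / num$df) / (den$SS / den$df)
}

scheme_term_compatible <- function(term, level, design) {
  single_day <- length(unique(design$day)) == 1L
  ok <- switch(term,
               Treatment = level == "whole_plot" ||
                 (level == "free_within_block" && single_day),
               Day = level %in% c("within_plot", "paired_within_plot"),
               "Day:Treatment" = level == "whole_plot",
               FALSE)
  if (!ok)
    stop("scheme level '", level, "' is not a valid randomization for term '",
         term, "'", if (term == "Treatment" && !single_day)
           " (free_within_block needs single-day data)" else "")
  invisible(TRUE)
}

#' Distance-based PERMANOVA with restricted permutations
#'
#' Fits the ordered term list by sequential distance-based sums of
#' squares, forms the pseudo-F of `term` against the chosen error
#' stratum, and recomputes the full statistic for every permutation of
#' the restricted scheme (sample rows of the distance structure are
#' permuted; the design stays fixed, which is equivalent to permuting
#' labels under the scheme's exchangeability group).
#'
#' For the split-plot Treatment test use
#' `terms = c("Treatment", "Plot")`, `denominator = "whole_plot"`,
#' and a `whole_plot` scheme: fitting Treatment before Plot makes the
#' Plot row the plots-within-treatment (whole-plot error) stratum. For
#' the Day test use `terms = c("Plot", "Day")` with a `within_plot`
#' scheme; for the interaction, `terms = c("Plot", "Day",
#' "Day:Treatment")` with a `whole_plot` scheme.
#'
#' @param d a [dist_matrix()]
#' @param design a [study_design()] with one row per distance row, same
#'   order
#' @param terms ordered model terms
#' @param term the tested term (must be in `terms`)
#' @param scheme a [perm_scheme()] (level checked against the term)
#' @param denominator `"residual"` or `"whole_plot"`
#' @return `permanova_table` with columns `F` and `p` filled in for the
#'   tested term, and attributes `scheme`, `n_perm`, `exhaustive`,
#'   `denominator`, `term`
#' @export
permutation_test <- function(d, design, terms, term,
                             scheme = perm_scheme("whole_plot"),
                             denominator = c("residual", "whole_plot")) {
  denominator <- match.arg(denominator)
  if (!term %in% terms) stop("tested term must appear in the model terms")
  scheme_term_compatible(term, scheme$level, design)
  if (denominator == "whole_plot" && !"Plot" %in% terms)
    stop("whole_plot denominator requires Plot in the model")
  ids <- rownames(d)
  if (!is.null(ids) && !identical(ids, design$sample_id))
    stop("distance matrix rows and design rows do not match")
  G <- gower_center(d)
  tab <- sequential_ss(G, terms, design)
  f_obs <- pseudo_f(tab, term, denominator)

  ## cumulative projectors reused across permutations (design fixed,
  ## G permuted): trace(H G[p,p]) per cumulative term set
  cum_pjs <- list()
  cum <- character()
  for (t in terms) {
    cum <- c(cum, t)
    cum_pjs[[t]] <- projector(design, cum)$H
  }
  pos <- match(term, terms)
  H_at <- cum_pjs[[terms[pos]]]
  H_before <- if (pos == 1L) NULL else cum_pjs[[terms[pos - 1L]]]
  ss_total <- sum(diag(G))
  if (denominator == "residual") {
    H_last <- cum_pjs[[terms[length(terms)]]]
  } else {
    ppos <- match("Plot", terms)
    H_plot_at <- cum_pjs[[terms[ppos]]]
    H_plot_before <- if (ppos == 1L) NULL else cum_pjs[[terms[ppos - 1L]]]
  }
  num_df <- tab[term, "df"]
  den_df <- if (denominator == "residual") tab["Residual", "df"]
            else tab["Plot", "df"]

  f_of_traces <- function(tr_at, tr_before, tr_den_at, tr_den_before) {
    ss_num <- tr_at - tr_before
    ss_den <- if (denominator == "residual") ss_total - tr_den_at
              else tr_den_at - tr_den_before
    if (ss_den <= 1e-12) return(if (ss_num <= 1e-12) 0 else Inf)
    (ss_num / num_df) / (ss_den / den_df)
  }
  if (scheme$level == "whole_plot") {
    ## randomize treatment labels at the plot level (valid under sample
    ## attrition); only cumulative spans that genuinely depend on the
    ## treatment assignment need recomputing, since Treatment is
    ## plot-constant and therefore absorbed by any span containing Plot
    pset <- whole_plot_assignments(design, scheme)
    plot_trt <- stats::setNames(design$treatment,
                                design$plot)[!duplicated(design$plot)]
    depends <- function(set) {
      ("Treatment" %in% set && !"Plot" %in% set) || "Day:Treatment" %in% set
    }
    cum_sets <- lapply(seq_along(terms), function(k) terms[seq_len(k)])
    fixed_tr <- vapply(seq_along(terms), function(k) {
      if (depends(cum_sets[[k]])) NA_real_ else sum(cum_pjs[[terms[k]]] * G)
    }, numeric(1))
    trace_k <- function(k, des2) {
      if (!is.na(fixed_tr[k])) return(fixed_tr[k])
      sum(projector(des2, cum_sets[[k]])$H * G)
    }
    tr0 <- function(k, des2) if (k == 0L) 0 else trace_k(k, des2)
    ppos <- if (denominator == "whole_plot") match("Plot", terms) else NA
    f_perm <- vapply(pset$perms, function(a) {
      des2 <- design
      des2$treatment <- unname(plot_trt[a[des2$plot]])
      f_of_traces(tr0(pos, des2), tr0(pos - 1L, des2),
                  if (denominator == "residual")
                    tr0(length(terms), des2) else tr0(ppos, des2),
                  if (denominator == "residual") 0 else tr0(ppos - 1L, des2))
    }, numeric(1))
  } else {
    pset <- generate_permutations(design, scheme)
    f_of <- function(Gp) {
      ss_num <- sum(H_at * Gp) -
        if (is.null(H_before)) 0 else sum(H_before * Gp)
      ss_den <- if (denominator == "residual") {
        ss_total - sum(H_last * Gp)
      } else {
        sum(H_plot_at * Gp) -
          if (is.null(H_plot_before)) 0 else sum(H_plot_before * Gp)
      }
      if (ss_den <= 1e-12) return(if (ss_num <= 1e-12) 0 else Inf)
      (ss_num / num_df) / (ss_den / den_df)
    }
    f_perm <- vapply(pset$perms, function(p) f_of(G[p, p]), numeric(1))
  }
  p_val <- perm_pvalue(f_obs, f_perm, pset$exhaustive)

  tab$F <- NA_real_
  tab$p <- NA_real_
  tab[term, "F"] <- f_obs
  tab[term, "p"] <- p_val
  attr(tab, "scheme") <- scheme$level
  attr(tab, "n_perm") <- length(pset$perms)
  attr(tab, "exhaustive") <- pset$exhaustive
  attr(tab, "group_size") <- pset$group_size
  attr(tab, "denominator") <- denominator
  attr(tab, "term") <- term
  tab
}
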