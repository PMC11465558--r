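#' Per-taxon contributions to one pair's Bray-Curtis dissimilarity
#'
#' c_i = |x_i - y_i| / sum_k (x_k + y_k); the contributions sum exactly
#' to the Bray-Curtis dissimilarity of the pair.
#'
#' @param x,y abundance vectors over the same taxa
#' @return numeric vector of contributions
#' @export
pair_contributions <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must cover the same taxa")
  tot <- sum(x) + sum(y)
  if (tot == 0) {
    warning("both samples are all-zero; contributions set to 0")
    return(rep(0, length(x)))
  }
  abs(x - y) / tot
}

#' Similarity-percentage (SIMPER) analysis for one group pair
#'
#' The mean contribution of each taxon to the between-group Bray-Curtis
#' dissimilarity, averaged over all between-group sample pairs, with a
#' free group-label permutation p per taxon: the fraction of relabelings
#' whose mean contribution is at least the observed one.
#'
#' @param table relative-abundance (or count) matrix, samples as rows
#' @param groups group label per sample
#' @param pair character vector of the two group labels compared
#' @param n_perm number of label permutations (default 999)
#' @param seed integer seed
#' @return data.frame of class `simper_table`, ordered by decreasing
#'   mean contribution: `taxon`, `mean_contribution`, `sd_contribution`,
#'   `cumulative` (cumulative proportion of the summed contributions),
#'   `p`; attribute `comparison`
#' @export
simper_pair <- function(table, groups, pair, n_perm = 999L, seed = 1L) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("groups length must match sample count")
  if (length(pair) != 2L || !all(pair %in% groups))
    stop("pair must name two group labels present in groups")
  ia <- which(groups == pair[1L])
  ib <- which(groups == pair[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need at least 2 samples")

  ## vectorized over the second group: one row sweep per first-group
  ## sample, algebraically identical to averaging pair_contributions()
  tot <- rowSums(m)
  mean_contrib <- function(ia, ib) {
    acc <- numeric(ncol(m))
    acc_sq <- numeric(ncol(m))
    B <- m[ib, , drop = FALSE]
    for (i in ia) {
      w <- 1 / (tot[i] + tot[ib])
      w[!is.finite(w)] <- 0  # all-zero pair: contribution 0
      cij <- abs(sweep(B, 2L, m[i, ], "-")) * w
      acc <- acc + colSums(cij)
      acc_sq <- acc_sq + colSums(cij^2)
    }
    np <- length(ia) * length(ib)
    list(mean = acc / np,
         sd = sqrt(pmax(acc_sq / np - (acc / np)^2, 0)))
  }
  obs <- mean_contrib(ia, ib)
  pool <- c(ia, ib)
  na <- length(ia)
  exceed <- numeric(ncol(m))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_perm)) {
      sh <- sample(pool)
      mp <- mean_contrib(sh[seq_len(na)], sh[-seq_len(na)])$mean
      exceed <- exceed + (mp >= obs$mean - 1e-12)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  ord <- order(obs$mean, decreasing = TRUE)
  out <- data.frame(taxon = colnames(m)[ord],
                    mean_contribution = obs$mean[ord],
                    sd_contribution = obs$sd[ord],
                    cumulative = cumsum(obs$mean[ord]) / sum(obs$mean),
                    p = p[ord],
                    row.names = NULL)
  class(out) <- c("simper_table", "data.frame")
  attr(out, "comparison") <- paste(pair, collapse = "-")
  out
}

#' SIMPER over all three treatment comparisons
#'
#' @param table relative-abundance matrix, samples as rows
#' @param groups group label per sample
#' @param n_perm,seed see [simper_pair()]
#' @return named list of `simper_table`s, one per unordered group pair
#' @export
simper_all_pairs <- function(table, groups, n_perm = 999L, seed = 1L) {
  gl <- sort(unique(as.character(groups)))
  pairs <- utils::combn(gl, 2L, simplify = FALSE)
  out <- lapply(seq_along(pairs), function(k) {
    simper_pair(table, groups, pairs[[k]], n_perm = n_perm,
                seed = seed + k)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "-")
  out
}

#' Union of the top contributing taxa across comparisons
#'
#' Takes the `k` most significantly contributing taxa of each SIMPER
#' comparison (ranked by ascending permutation p, ties broken by
#' descending mean contribution), unions them and deduplicates
#' preserving first occurrence.
#'
#' @param tables list of `simper_table`s (e.g. [simper_all_pairs()])
#' @param k taxa kept per comparison (default 100)
#' @return character vector of taxon ids; attribute `n_before_dedup`
#' @export
top_contributors <- function(tables, k = 100L) {
  picks <- lapply(tables, function(tb) {
    if (k > nrow(tb)) stop("k exceeds the number of taxa in a comparison")
    ord <- order(tb$p, -tb$mean_contribution)
    tb$taxon[ord][seq_len(k)]
  })
  all_taxa <- unlist(picks, use.names = FALSE)
  out <- all_taxa[!duplicated(all_taxa)]
  attr(out, "n_before_dedup") <- length(all_taxa)
  out
}
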