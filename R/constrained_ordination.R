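#' Partial distance-based redundancy analysis
#'
#' Principal coordinates of the dissimilarity matrix (positive
#' eigenvalue axes only; the magnitude of discarded negative inertia is
#' reported), optionally residualized on conditioning factors, then
#' regressed on the constraint factors; the constrained axes are the
#' eigenvectors of the fitted-value cross-product. Eigenvalues are on
#' the sum-of-squares scale, so with Euclidean input and no conditions
#' they equal classical RDA eigenvalues times (n - 1).
#'
#' @param d a [dist_matrix()]
#' @param constraints data.frame of factors (constraint terms)
#' @param conditions data.frame of factors partialled out first, or NULL
#' @return list of class `dbrda_result`: `eigenvalues` (constrained,
#'   descending, >= 0), `scores` (site scores on constrained axes),
#'   `axis_vectors`, `conditioned_inertia`, `constrained_inertia`,
#'   `residual_inertia`, `negative_inertia` (discarded), `collinear`
#'   (TRUE when the constraints add nothing beyond the conditions)
#' @export
partial_dbrda <- function(d, constraints, conditions = NULL) {
  pc <- pcoa(d)
  Y <- pc$points
  n <- nrow(Y)
  total <- sum(Y^2)
  mm <- function(df) {
    X <- cbind(rep(1, n))
    for (j in seq_along(df)) {
      f <- factor(df[[j]])
      X <- cbind(X, stats::model.matrix(~ 0 + f))
    }
    X
  }
  hat <- function(X) {
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    list(H = tcrossprod(Q), rank = qx$rank)
  }
  if (!is.null(conditions)) {
    Hc <- hat(mm(as.data.frame(conditions)))
    Yr <- Y - Hc$H %*% Y
    cond_inertia <- total - sum(Yr^2)
    Xfull <- cbind(mm(as.data.frame(conditions)),
                   mm(as.data.frame(constraints))[, -1L, drop = FALSE])
    Hf <- hat(Xfull)
    rank_extra <- Hf$rank - Hc$rank
    fitted <- Hf$H %*% Y - Hc$H %*% Y
  } else {
    Yr <- sweep(Y, 2L, colMeans(Y))
    cond_inertia <- 0
    Hx <- hat(mm(as.data.frame(constraints)))
    rank_extra <- Hx$rank - 1L
    fitted <- Hx$H %*% Yr
  }
  collinear <- rank_extra == 0L
  cp <- crossprod(fitted)
  e <- eigen((cp + t(cp)) / 2, symmetric = TRUE)
  keep <- which(e$values > max(e$values[1L], 0) * 1e-10 & e$values > 1e-10)
  keep <- utils::head(keep, rank_extra)
  if (collinear || length(keep) == 0L) {
    eigvals <- numeric(0)
    V <- matrix(0, ncol(Y), 0L)
  } else {
    eigvals <- e$values[keep]
    V <- e$vectors[, keep, drop = FALSE]
    ## sign convention: first nonzero loading positive
    for (j in seq_len(ncol(V))) {
      nz <- which(abs(V[, j]) > 1e-8)[1L]
      if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
    }
  }
  scores <- Yr %*% V
  colnames(scores) <- if (ncol(scores) > 0L)
    paste0("CAP", seq_len(ncol(scores))) else character(0)
  rownames(scores) <- rownames(d)
  structure(list(eigenvalues = eigvals, scores = scores, axis_vectors = V,
                 conditioned_inertia = cond_inertia,
                 constrained_inertia = sum(fitted^2),
                 residual_inertia = sum(Yr^2) - sum(fitted^2),
                 negative_inertia = pc$negative_inertia,
                 collinear = collinear),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf(
    "dbrda_result: %d constrained axes; inertia cond %.4g / constr %.4g / resid %.4g%s\n",
    length(x$eigenvalues), x$conditioned_inertia, x$constrained_inertia,
    x$residual_inertia,
    if (x$collinear) " [constraints collinear with conditions]" else ""))
  invisible(x)
}

#' Group centroids and standard errors on ordination axes
#'
#' @param r a [partial_dbrda()] result (or any matrix of scores)
#' @param groups group label per sample
#' @return data.frame: group, axis, centroid, se, n. The standard error
#'   is sd/sqrt(n); singleton groups get `NA` standard errors.
#' @export
group_centroids <- function(r, groups) {
  scores <- if (inherits(r, "dbrda_result")) r$scores else as.matrix(r)
  groups <- factor(groups)
  if (length(groups) != nrow(scores))
    stop("groups length must match score rows")
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    s <- scores[groups == g, , drop = FALSE]
    n <- nrow(s)
    data.frame(group = g, axis = colnames(scores),
               centroid = colMeans(s),
               se = if (n > 1L) apply(s, 2L, stats::sd) / sqrt(n)
                    else rep(NA_real_, ncol(s)),
               n = n, row.names = NULL)
  }))
  out
}
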