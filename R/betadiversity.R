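#' Construct a distance matrix object
#'
#' @param m symmetric numeric matrix with zero diagonal and sample ids
#'   as dimnames
#' @param metric label recording the dissimilarity used
#' @return matrix of class `dist_matrix`
#' @export
dist_matrix <- function(m, metric = "unknown") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix needs sample ids as dimnames")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 0)) stop("distance matrix must have zero diagonal")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, class = c("dist_matrix", "matrix", "array"), metric = metric)
}

#' Bray-Curtis dissimilarity
#'
#' d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik), computed between
#' all sample pairs of an abundance table (counts or relative
#' abundances). A pair of all-zero samples is given distance 0 with a
#' warning.
#'
#' @param table samples x taxa abundance matrix ([count_table()] or
#'   [to_relative_abundance()] output)
#' @return a [dist_matrix()] with values in `[0, 1]`
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 samples for a dissimilarity matrix")
  ## vegdist warns separately about empty rows; we detect and report the
  ## resulting undefined pairs ourselves below
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (any(is.nan(d))) {
    warning("all-zero sample pair(s): Bray-Curtis undefined, set to 0")
    d[is.nan(d)] <- 0
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  dist_matrix(d, metric = "bray")
}

#' Gower-center a distance matrix
#'
#' G = C (-1/2 D*D) C with C = I - 11'/n the centering projector. G is
#' symmetric with zero row sums, and trace(G) is the total sum of
#' squares partitioned by PERMANOVA.
#'
#' @param d a [dist_matrix()] (or plain symmetric matrix)
#' @return centered inner-product matrix
#' @export
gower_center <- function(d) {
  a <- -0.5 * unclass(d)^2
  n <- nrow(a)
  rm <- rowMeans(a)
  g <- a - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(a)
  dimnames(g) <- dimnames(d)
  (g + t(g)) / 2
}

#' Principal coordinates decomposition
#'
#' Eigendecomposition of the Gower-centered matrix. Negative eigenvalues
#' (possible for semimetric dissimilarities such as Bray-Curtis) are
#' retained and reported, and coordinates on negative-eigenvalue axes
#' are kept separately as "imaginary" coordinates scaled by
#' sqrt(|lambda|); no additive correction is applied.
#'
#' @param d a [dist_matrix()]
#' @param eig_tol eigenvalues within `eig_tol * max(|lambda|)` of zero
#'   are treated as null axes and dropped
#' @return list of class `pcoa_result`: `eigenvalues` (descending),
#'   `points` (coordinates on positive axes), `imaginary_points`
#'   (coordinates on negative axes), `trace` (= trace(G)),
#'   `negative_inertia` (sum of |negative eigenvalues|)
#' @export
pcoa <- function(d, eig_tol = 1e-9) {
  g <- gower_center(d)
  e <- eigen(g, symmetric = TRUE)
  lam <- e$values
  scale0 <- max(abs(lam), .Machine$double.eps)
  pos <- lam > eig_tol * scale0
  neg <- lam < -eig_tol * scale0
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam[pos]), sum(pos))
  ipts <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-lam[neg]), sum(neg))
  rownames(pts) <- rownames(ipts) <- rownames(d)
  structure(list(eigenvalues = lam, points = pts, imaginary_points = ipts,
                 trace = sum(diag(g)),
                 negative_inertia = sum(-lam[neg])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d real axes, %d imaginary axes, trace %.4g\n",
              nrow(x$points), ncol(x$points), ncol(x$imaginary_points), x$trace))
  invisible(x)
}

#' Write / read a distance matrix as square TSV
#' @param d a [dist_matrix()]
#' @param path file path
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @param metric metric tag to attach on read
#' @export
read_dist_matrix <- function(path, metric = "unknown") {
  x <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- as.character(x[[1L]])
  dist_matrix(m, metric = metric)
}
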