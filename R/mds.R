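#' Pairwise Disnet distance matrix over snapshots
#'
#' d_ij is the Disnet distance between the networks of snapshots i and j:
#' symmetric, zero diagonal, entries in [0, 1].
#'
#' @param scns list of \code{\link{scn}} objects on a common node set.
#' @param times_ps optional snapshot times kept as an attribute.
#' @return symmetric numeric matrix.
#' @export
pairwise_disnet_matrix <- function(scns, times_ps = NULL) {
  if (length(scns) < 2) stop("need at least 2 networks")
  mats <- lapply(scns, as_adj)
  for (m in mats[-1]) check_same_nodes(mats[[1]], m)
  n <- nrow(mats[[1]])
  m_links <- n * (n - 1) / 2
  ut <- upper.tri(mats[[1]])
  L <- do.call(rbind, lapply(mats, function(m) m[ut]))
  k <- rowSums(L)
  ham <- outer(k, k, "+") - 2 * tcrossprod(L)
  d <- ham / m_links
  diag(d) <- 0
  if (!is.null(times_ps)) attr(d, "times_ps") <- times_ps
  d
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double centering of the squared distances, B = -(1/2) J P2 J with
#' J = I - (1/n) 11', followed by eigendecomposition; coordinates are the
#' top-k eigenvectors scaled by the square roots of their eigenvalues.
#' Negative eigenvalues (possible when the distances are not Euclidean)
#' are never used; if fewer than k eigenvalues are positive the embedding
#' is padded with zero columns and a warning is raised. The share of total
#' absolute eigenvalue mass captured by the kept components is reported so
#' distortion is visible.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal.
#' @param k embedding dimension, default 3.
#' @return object of class \code{scn_mds}: \code{coords} (n x k),
#'   \code{eigenvalues} (descending), \code{positive_mass_fraction}.
#' @export
classical_mds <- function(d, k = 3) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 points")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  p2 <- d * d
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% p2 %*% j
  b <- (b + t(b)) / 2
  eg <- eigen(b, symmetric = TRUE)   # eigenvalues descending; index ties stable
  pos <- eg$values > max(eg$values, 0) * 1e-12
  kept <- utils::head(which(pos), k)
  if (length(kept) < k)
    warning("only ", length(kept),
            " positive eigenvalue(s); embedding padded with zero columns")
  coords <- matrix(0, n, k)
  if (length(kept))
    coords[, seq_along(kept)] <-
      eg$vectors[, kept, drop = FALSE] %*%
      diag(sqrt(eg$values[kept]), length(kept))
  pmf <- if (sum(abs(eg$values)) > 0)
    sum(eg$values[kept]) / sum(abs(eg$values)) else 0
  structure(list(coords = coords, eigenvalues = eg$values,
                 positive_mass_fraction = pmf,
                 times_ps = attr(d, "times_ps")),
            class = "scn_mds")
}

#' @export
print.scn_mds <- function(x, ...) {
  cat(sprintf("scn_mds: %d points in %d dimensions, %.1f%% of |eigenvalue| mass kept\n",
              nrow(x$coords), ncol(x$coords),
              100 * x$positive_mass_fraction))
  invisible(x)
}

#' @export
plot.scn_mds <- function(x, ...) {
  graphics::plot(x$coords[, 1], x$coords[, 2],
                 xlab = "MDS 1", ylab = "MDS 2",
                 col = if (!is.null(x$times_ps))
                   grDevices::hcl.colors(nrow(x$coords))[
                     rank(x$times_ps, ties.method = "first")] else 1, ...)
  invisible(x)
}
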