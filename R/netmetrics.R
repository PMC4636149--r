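as_adj <- function(x) if (inherits(x, "scn")) x$adjacency else as.matrix(x)

check_same_nodes <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      (!is.null(rownames(a)) && !is.null(rownames(b)) &&
       !identical(rownames(a), rownames(b))))
    stop("networks are defined on different node sets")
}

#' Disnet: normalized distance between two networks
#'
#' The number of links present in exactly one of two same-node binary
#' networks, divided by the maximum possible link count N(N-1)/2. A value
#' of 0.4 means 40 percent of all possible links are unique to one network
#' or the other; it is 0 iff the networks are identical and 1 when the two
#' link sets are disjoint and jointly saturate the core.
#'
#' @param a,b \code{\link{scn}} objects or binary symmetric matrices on the
#'   same ordered node set.
#' @return number in [0, 1].
#' @export
disnet <- function(a, b) {
  a <- as_adj(a); b <- as_adj(b)
  check_same_nodes(a, b)
  n <- nrow(a)
  sum(abs(a - b)) / 2 / (n * (n - 1) / 2)
}

#' Fraction of native contacts or links retained
#'
#' The same operation serves Q (distance contacts against the native
#' contact set) and Q_L (network links against the native link set):
#' the retained fraction |current intersect native| / |native|.
#'
#' @param current character vector of pair keys (see
#'   \code{\link{scn_links}}, \code{\link{native_contacts}}).
#' @param native non-empty character vector of native pair keys.
#' @return number in [0, 1].
#' @export
q_fraction <- function(current, native) {
  if (!length(native)) stop("empty native set")
  length(intersect(unique(current), unique(native))) / length(unique(native))
}

#' Link persistence over an epoch
#'
#' Element-wise mean of the adjacency matrices of the epoch's snapshots:
#' P_ij is the fraction of snapshots in which link i-j is present.
#'
#' @param epoch list of \code{\link{scn}} objects on a common node set.
#' @return numeric matrix in [0, 1] with the node dimnames.
#' @export
persistence_matrix <- function(epoch) {
  if (!length(epoch)) stop("empty epoch")
  mats <- lapply(epoch, as_adj)
  for (m in mats[-1]) check_same_nodes(mats[[1]], m)
  Reduce(`+`, mats) / length(mats)
}

#' Binarize a persistence matrix
#'
#' A link is called locked within the epoch when it persists in at least
#' 40 percent of the snapshots: P'_ij = 1 iff P_ij >= threshold (the
#' boundary is inclusive).
#'
#' @param p persistence matrix.
#' @param threshold persistence threshold, default 0.40.
#' @return binary matrix of the same shape.
#' @export
binarize_persistence <- function(p, threshold = 0.40) {
  out <- (p >= threshold) * 1
  dimnames(out) <- dimnames(p)
  out
}

#' persf: Disnet between binarized persistence matrices
#'
#' Measures how far an epoch's locked-link network has drifted from a
#' baseline locked-link network (conventionally, the persistence matrix of
#' the entire native-temperature trajectory, binarized at 0.40).
#'
#' @param epoch_binary,baseline_binary binarized persistence matrices on
#'   the same node set.
#' @return number in [0, 1].
#' @export
persf <- function(epoch_binary, baseline_binary) {
  if (!all(epoch_binary %in% c(0, 1)) || !all(baseline_binary %in% c(0, 1)))
    stop("persf expects binarized persistence matrices")
  disnet(epoch_binary, baseline_binary)
}

#' dlf: mean pairwise Disnet within an epoch
#'
#' The average Disnet over all unordered pairs of the epoch's snapshots;
#' high dlf marks epochs whose networks fluctuate strongly.
#'
#' @param epoch list of at least two \code{\link{scn}} objects.
#' @return number in [0, 1].
#' @export
dlf <- function(epoch) {
  ns <- length(epoch)
  if (ns < 2) stop("dlf needs at least 2 snapshots")
  mats <- lapply(epoch, as_adj)
  for (m in mats[-1]) check_same_nodes(mats[[1]], m)
  n <- nrow(mats[[1]])
  m_links <- n * (n - 1) / 2
  # upper-triangle link indicators, one row per snapshot
  ut <- upper.tri(mats[[1]])
  L <- do.call(rbind, lapply(mats, function(m) m[ut]))
  k <- rowSums(L)
  g <- tcrossprod(L)                       # shared link counts
  ham <- outer(k, k, "+") - 2 * g          # symmetric-difference counts
  mean(ham[upper.tri(ham)]) / m_links
}

#' Adjacent-averaging smoother
#'
#' Centered moving average with an odd window (45 points by default, the
#' presentation smoothing used for the Disnet/Q time series). Near the
#' edges the window shrinks symmetrically, so output length equals input
#' length and a window of 1 is the identity.
#'
#' @param x numeric series.
#' @param window odd positive integer.
#' @return numeric vector, same length as \code{x}.
#' @export
smooth_adjacent <- function(x, window = 45) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  n <- length(x)
  hw <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  h <- pmin(hw, i - 1, n - i)
  (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
}

ca_coords <- function(snap, selection = NULL) {
  a <- snap$atoms
  sel <- toupper(a$atom_name) == "CA"
  if (!is.null(selection)) {
    keys <- if (inherits(selection, "core_definition")) selection$key
            else as.character(selection)
    sel <- sel & residue_key(a$chain, a$res_seq) %in% keys
  }
  atom_xyz(a[sel, , drop = FALSE])
}

#' C-alpha RMSD after optimal superposition
#'
#' Least-squares rigid-body superposition (rotation + translation) of the
#' snapshot's C-alpha set onto the reference, then the root-mean-square
#' deviation, delegated to bio3d.
#'
#' @param snap,reference \code{\link{snapshot}} objects with matching
#'   C-alpha sets.
#' @param selection optional residue keys or a
#'   \code{\link{core_definition}} restricting the atom set.
#' @return RMSD in angstrom.
#' @export
ca_rmsd <- function(snap, reference, selection = NULL) {
  x <- ca_coords(snap, selection)
  y <- ca_coords(reference, selection)
  if (nrow(x) != nrow(y)) stop("mismatched C-alpha sets")
  if (nrow(x) < 3) stop("need at least 3 atoms for superposition")
  bio3d::rmsd(as.numeric(t(y)), as.numeric(t(x)), fit = TRUE)
}

#' Per-residue C-alpha RMSF
#'
#' Frames are superposed onto the first frame's C-alpha set, then the
#' root-mean-square fluctuation of each C-alpha about its time-average
#' position is returned.
#'
#' @param trajectory list of \code{\link{snapshot}} objects (>= 2 frames).
#' @param selection optional residue keys or \code{\link{core_definition}}.
#' @param superpose superpose each frame onto the first before measuring;
#'   set \code{FALSE} when the frames are already aligned.
#' @return named numeric vector of RMSF values (angstrom) per residue.
#' @export
rmsf <- function(trajectory, selection = NULL, superpose = TRUE) {
  if (length(trajectory) < 2) stop("rmsf needs at least 2 frames")
  coords <- lapply(trajectory, ca_coords, selection = selection)
  n <- nrow(coords[[1]])
  if (any(vapply(coords, nrow, 1L) != n)) stop("mismatched C-alpha sets")
  ref <- as.numeric(t(coords[[1]]))
  fitted <- t(vapply(coords, function(m) {
    if (superpose)
      as.numeric(bio3d::fit.xyz(ref, as.numeric(t(m)),
                                fixed.inds = seq_len(3 * n),
                                mobile.inds = seq_len(3 * n)))
    else as.numeric(t(m))
  }, numeric(3 * n)))
  mean_xyz <- colMeans(fitted)
  dev2 <- sweep(fitted, 2, mean_xyz)^2
  per_atom <- sqrt(rowMeans(matrix(colMeans(dev2), ncol = 3, byrow = TRUE) *
                              3))   # sum of x,y,z variances
  a <- trajectory[[1]]$atoms
  sel <- toupper(a$atom_name) == "CA"
  if (!is.null(selection)) {
    keys <- if (inherits(selection, "core_definition")) selection$key
            else as.character(selection)
    sel <- sel & residue_key(a$chain, a$res_seq) %in% keys
  }
  setNames(per_atom, residue_key(a$chain[sel], a$res_seq[sel]))
}

#' Pearson cross-correlation of two metric series
#'
#' @param x,y numeric series of equal length >= 3 with nonzero variance.
#' @return correlation in [-1, 1].
#' @export
cross_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (var(x) == 0 || var(y) == 0) stop("zero-variance series")
  cor(x, y)
}

#' Split a trajectory into contiguous epochs
#'
#' After discarding a burn-in, the frame times are partitioned into
#' contiguous non-overlapping windows of \code{span_ps} (2 ns by default);
#' a final partial window is dropped, matching fixed-size epochs of
#' span/sample_interval snapshots.
#'
#' @param times_ps frame times in picoseconds (non-decreasing).
#' @param span_ps epoch span, default 2000 ps.
#' @param burn_in_ps leading interval to discard, default 2000 ps.
#' @return list of integer index vectors, one per complete epoch.
#' @export
split_epochs <- function(times_ps, span_ps = 2000, burn_in_ps = 2000) {
  if (is.unsorted(times_ps)) stop("frame times must be non-decreasing")
  keep <- which(times_ps >= burn_in_ps)
  if (!length(keep)) return(list())
  t0 <- burn_in_ps
  bin <- floor((times_ps[keep] - t0) / span_ps)
  per <- split(keep, bin)
  full <- table(bin)
  expected <- max(full)          # complete epochs carry the modal count
  per[vapply(per, length, 1L) == expected]
}

#' Epoch ensemble: per-epoch persistence bookkeeping
#'
#' Bundles an epoch's networks with its persistence matrix and the
#' binarized locked-link matrix.
#'
#' @param scns ordered list of \code{\link{scn}} objects in the epoch.
#' @param threshold persistence binarization threshold, default 0.40.
#' @return list of class \code{epoch_ensemble}.
#' @export
epoch_ensemble <- function(scns, threshold = 0.40) {
  p <- persistence_matrix(scns)
  structure(list(scns = scns, n_snapshots = length(scns),
                 persistence = p,
                 persistence_binary = binarize_persistence(p, threshold)),
            class = "epoch_ensemble")
}

#' @export
print.epoch_ensemble <- function(x, ...) {
  cat(sprintf("epoch_ensemble: %d snapshots, %d locked links\n",
              x$n_snapshots, sum(x$persistence_binary) / 2))
  invisible(x)
}
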