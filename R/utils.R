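## Internal geometry helpers. The contract of every consumer is exactness:
## these prefilters (chunking + bounding boxes) can never drop a true
## neighbor within the stated reach.

# Ordered pairs (i, j), i != j, with |c_i - c_j| < reach_i. reach_i must be
# an upper bound for the interaction radius of atom i with any partner.
neighbor_pairs <- function(centers, reach) {
  n <- nrow(centers)
  reach <- rep_len(reach, n)
  chunk <- max(1L, as.integer(2^22 / n))
  out <- vector("list", ceiling(n / chunk))
  k <- 0L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    idx <- s:e
    d2 <- outer(rowSums(centers[idx, , drop = FALSE]^2),
                rowSums(centers^2), "+") -
      2 * tcrossprod(centers[idx, , drop = FALSE], centers)
    hit <- which(d2 < reach[idx]^2, arr.ind = TRUE)
    if (nrow(hit)) {
      i <- idx[hit[, 1]]
      j <- hit[, 2]
      sel <- i != j
      k <- k + 1L
      out[[k]] <- cbind(i = i[sel], j = j[sel])
    }
  }
  if (k == 0L) return(cbind(i = integer(0), j = integer(0)))
  do.call(rbind, out[seq_len(k)])
}

# Single nearest neighbor in `target` for each row of `query`, within
# `cutoff`. Returns list(idx, dist); idx is NA where no target lies within
# the cutoff. Exact: the bounding-box prefilter keeps every target within
# `cutoff` of any query point in the chunk.
nn1_cross <- function(query, target, cutoff) {
  nq <- nrow(query)
  idx <- rep(NA_integer_, nq)
  dist <- rep(NA_real_, nq)
  if (nq == 0 || nrow(target) == 0) return(list(idx = idx, dist = dist))
  chunk <- 256L
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    q <- query[s:e, , drop = FALSE]
    lo <- apply(q, 2, min) - cutoff
    hi <- apply(q, 2, max) + cutoff
    sel <- which(target[, 1] >= lo[1] & target[, 1] <= hi[1] &
                 target[, 2] >= lo[2] & target[, 2] <= hi[2] &
                 target[, 3] >= lo[3] & target[, 3] <= hi[3])
    if (!length(sel)) next
    tt <- target[sel, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rowSums(tt^2), "+") - 2 * tcrossprod(q, tt)
    d2[d2 < 0] <- 0
    best <- max.col(-d2, ties.method = "first")
    bd <- sqrt(d2[cbind(seq_len(nrow(q)), best)])
    ok <- bd <= cutoff
    idx[(s:e)[ok]] <- sel[best[ok]]
    dist[(s:e)[ok]] <- bd[ok]
  }
  list(idx = idx, dist = dist)
}

# Minimum distance between two point sets (used by contact prescreens).
min_cross_dist <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# Which dots lie outside every sphere (strictly-inside test with tolerance):
# keep dot p when |p - c_j| >= r_j - tol for all j. Spheres are visited in
# order of proximity to the dot cloud so buried clouds empty out early.
dots_outside_spheres <- function(p, centers, radii, tol = 0) {
  n <- nrow(p)
  if (length(radii) == 0 || n == 0) return(rep(TRUE, n))
  ctr <- colMeans(p)
  ord <- order((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2 +
                 (centers[, 3] - ctr[3])^2)
  keep <- rep(TRUE, n)
  active <- seq_len(n)
  for (j in ord) {
    d2 <- (p[active, 1] - centers[j, 1])^2 +
          (p[active, 2] - centers[j, 2])^2 +
          (p[active, 3] - centers[j, 3])^2
    inside <- d2 < (radii[j] - tol)^2
    if (any(inside)) {
      keep[active[inside]] <- FALSE
      active <- active[!inside]
      if (!length(active)) break
    }
  }
  keep
}
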