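## Synthetic fixtures: geometric pseudo-residues with controllable packing,
## stochastic link trajectories with known persistence, and monotone
## unfolding series. Pseudo-residues carry real amino-acid names (LEU) and
## plain carbon side-chain atoms so downstream code needs no special cases.
## All generators are deterministic given (spec, seed).

lattice_xyz <- function(center, e1, e2, n_side, spacing) {
  offs <- (seq_len(n_side) - (n_side + 1) / 2) * spacing
  g <- expand.grid(a = offs, b = offs)
  sweep(outer(g$a, e1) + outer(g$b, e2), 2, center, "+")
}

## One pseudo-residue plate: an n_side x n_side side-chain lattice framed by
## a one-atom backbone border and backed by a backbone layer behind it. As
## in a real protein, the main-chain surface bounds the side-chain patch:
## the exposed side-chain sub-surface is exactly the face pointing along
## `normal`, which gives the complementarity examples their closed forms.
plate_atoms <- function(center, normal, e1, e2, n_side, spacing) {
  face <- lattice_xyz(center, e1, e2, n_side, spacing)
  frame <- lattice_xyz(center, e1, e2, n_side + 2, spacing)
  # border = frame atoms not coinciding with a face atom
  keep <- !duplicated(rbind(round(face, 6), round(frame, 6)))[
    nrow(face) + seq_len(nrow(frame))]
  border <- frame[keep, , drop = FALSE]
  backing <- sweep(lattice_xyz(center, e1, e2, n_side + 2, spacing),
                   2, spacing * normal, "-")
  list(sidechain = face, backbone = rbind(border, backing))
}

pseudo_residue_atoms <- function(plates, chain, res_seq) {
  sc <- do.call(rbind, lapply(plates, `[[`, "sidechain"))
  bb <- do.call(rbind, lapply(plates, `[[`, "backbone"))
  data.frame(chain = chain, res_seq = res_seq, res_name = "LEU",
             atom_name = c(sprintf("CG%d", seq_len(nrow(sc))),
                           rep("C", nrow(bb))),
             element = "C",
             x = c(sc[, 1], bb[, 1]), y = c(sc[, 2], bb[, 2]),
             z = c(sc[, 3], bb[, 3]), stringsAsFactors = FALSE)
}

#' Generate an apposed pair of planar pseudo-residue patches
#'
#' Two flat side-chain lattices of carbon atoms facing each other across a
#' stated surface gap, each framed and backed by backbone atoms the way
#' main-chain surface bounds a real side-chain patch (residues 1 and 2 of
#' one chain). Because the lattice spacing is much smaller than the atom
#' radius the exposed side-chain surfaces are nearly flat with
#' anti-parallel normals, so the complementarity score has a closed form:
#' S_m ~ exp(-w gap^2) for ideally apposed patches.
#'
#' @param gap inter-patch surface separation in angstrom (>= 0).
#' @param n_side side-chain atoms per lattice edge.
#' @param atom_radius van der Waals radius assigned to every atom.
#' @param spacing lattice spacing in angstrom.
#' @param jitter standard deviation of Gaussian positional noise.
#' @param seed RNG seed (used only when jitter > 0).
#' @return a \code{\link{snapshot}} with radii assigned.
#' @export
make_patch_pair <- function(gap = 0, n_side = 7, atom_radius = 1.7,
                            spacing = 0.5, jitter = 0, seed = 1) {
  stopifnot(gap >= 0, jitter >= 0, spacing > 0)
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); nz <- c(0, 0, 1)
  a <- plate_atoms(c(0, 0, 0), nz, e1, e2, n_side, spacing)
  b <- plate_atoms(c(0, 0, 2 * atom_radius + gap), -nz, e1, e2, n_side,
                   spacing)
  atoms <- rbind(pseudo_residue_atoms(list(a), "A", 1),
                 pseudo_residue_atoms(list(b), "A", 2))
  if (jitter > 0) {
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
  }
  atoms$vdw_radius <- atom_radius
  snapshot(atoms)
}

#' Generate two coincident dot patches with opposed normals
#'
#' The idealized scoring fixture: two flat lattices of dot points owned by
#' pseudo-residues 1 and 2, separated by \code{gap} along z, with exactly
#' anti-parallel unit normals (+z on patch 1, -z on patch 2). At gap 0 the
#' positions coincide and every dot pair scores the ceiling S = 1; the
#' patch-to-patch overlap is 1 because every dot of one patch has its
#' nearest neighbor on the other.
#'
#' @param gap separation along the normal, angstrom.
#' @param n_side dots per lattice edge.
#' @param spacing lattice spacing, angstrom (defines the dot density).
#' @return a \code{\link{dot_surface}}.
#' @export
make_dot_patch_pair <- function(gap = 0, n_side = 10, spacing = 0.316) {
  offs <- (seq_len(n_side) - (n_side + 1) / 2) * spacing
  g <- expand.grid(x = offs, y = offs)
  n <- nrow(g)
  dots <- rbind(
    data.frame(x = g$x, y = g$y, z = 0, nx = 0, ny = 0, nz = 1,
               atom = 1L, residue = residue_key("A", 1),
               is_sidechain = TRUE),
    data.frame(x = g$x, y = g$y, z = gap, nx = 0, ny = 0, nz = -1,
               atom = 2L, residue = residue_key("A", 2),
               is_sidechain = TRUE))
  dot_surface(dots, density = 1 / spacing^2)
}

#' Generate an interlocked ring core of pseudo-residues
#'
#' n pseudo-residues arranged on a ring, each contacting its two ring
#' neighbors through parallel plate interfaces separated by
#' \code{packing_gap}: residue k owns one plate on each of its two ring
#' edges, and the two plates meeting at an edge face each other across the
#' gap. At tight packing the surface contact network is the n-cycle; once
#' the gap exceeds the dot-neighbor cutoff the network is empty.
#'
#' Each residue additionally carries one fully solvent-exposed side-chain
#' knob atom pointing out of the ring, too far from every interface to take
#' part in scoring; it gives the buried core a small, strictly positive
#' solvent accessibility (as in a real, imperfectly sealed hydrophobic
#' core) so accessibility-normalized metrics are well defined.
#'
#' @param n_residues number of residues (>= 3).
#' @param packing_gap inter-plate surface separation, angstrom.
#' @param seed RNG seed (used only when jitter > 0).
#' @param n_side side-chain atoms per plate edge.
#' @param atom_radius atom radius, angstrom.
#' @param spacing plate lattice spacing, angstrom.
#' @param jitter Gaussian positional noise, angstrom.
#' @return list with \code{snapshot} (radii assigned) and \code{core}
#'   (a \code{\link{core_definition}}).
#' @export
make_interlocked_core <- function(n_residues = 6, packing_gap = 0.3,
                                  seed = 1, n_side = 5, atom_radius = 1.7,
                                  spacing = 0.5, jitter = 0) {
  stopifnot(n_residues >= 3, packing_gap >= 0)
  half_extent <- (n_side - 1) / 2 * spacing + atom_radius
  # vertices far enough apart that only edge-sharing plates can interact
  need <- 2 * half_extent + 4.5 + packing_gap
  R <- need / sin(2 * pi / n_residues) + 2
  theta <- 2 * pi * (seq_len(n_residues) - 1) / n_residues
  vert <- cbind(R * cos(theta), R * sin(theta), 0)

  plates <- vector("list", n_residues)
  for (k in seq_len(n_residues)) plates[[k]] <- list()
  for (k in seq_len(n_residues)) {
    k2 <- if (k == n_residues) 1L else k + 1L
    u <- vert[k2, ] - vert[k, ]
    u <- u / sqrt(sum(u^2))
    m <- (vert[k, ] + vert[k2, ]) / 2
    e1 <- c(0, 0, 1)
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])  # u x e1, in-plane
    off <- packing_gap / 2 + atom_radius
    plates[[k]][[length(plates[[k]]) + 1L]] <-
      plate_atoms(m - off * u, u, e1, e2, n_side, spacing)
    plates[[k2]][[length(plates[[k2]]) + 1L]] <-
      plate_atoms(m + off * u, -u, e1, e2, n_side, spacing)
  }
  half_diag <- sqrt(2) * ((n_side + 1) / 2 * spacing) + atom_radius
  # the knob is a hydrogen: small enough not to dominate the residue's
  # side-chain dot count (O_v denominator), and its radius survives a PDB
  # round trip because it comes from the element fallback table
  knob_radius <- unname(radii_table()$elements[["H"]])
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(k) {
    a <- pseudo_residue_atoms(plates[[k]], "A", k)
    knob <- vert[k, ] * (1 + (half_diag + 5) / R)  # radially clear of plates
    rbind(a, data.frame(chain = "A", res_seq = k, res_name = "LEU",
                        atom_name = "HD1", element = "H",
                        x = knob[1], y = knob[2], z = knob[3],
                        stringsAsFactors = FALSE))
  }))
  if (jitter > 0) {
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
  }
  atoms$vdw_radius <- ifelse(atoms$element == "H", knob_radius, atom_radius)
  list(snapshot = snapshot(atoms),
       core = core_definition("A", seq_len(n_residues), "LEU", "loop"))
}

#' Simulate binary link trajectories with known persistence
#'
#' Each link i-j is sampled independently as Bernoulli(p_ij) in every
#' snapshot, so the expected persistence of a link is exactly p_ij and the
#' expected per-link pair disagreement is 2 p (1 - p). Reproducible by
#' seed.
#'
#' @param p symmetric link-probability matrix in [0, 1] with zero
#'   diagonal; dimnames, if any, become the node names.
#' @param n_snapshots number of snapshots to draw.
#' @param seed RNG seed.
#' @param sample_interval_ps time spacing of the snapshots.
#' @return list of \code{\link{scn}} objects.
#' @export
simulate_link_trajectory <- function(p, n_snapshots = 200, seed = 1,
                                     sample_interval_ps = 10) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (any(p < 0 | p > 1) || any(diag(p) != 0) || any(p != t(p)))
    stop("p must be symmetric in [0,1] with zero diagonal")
  if (is.null(rownames(p)))
    dimnames(p) <- list(paste0("A:", seq_len(n)), paste0("A:", seq_len(n)))
  ut <- which(upper.tri(p))
  set.seed(seed)
  lapply(seq_len(n_snapshots), function(s) {
    m <- matrix(0, n, n, dimnames = dimnames(p))
    m[ut] <- (stats::runif(length(ut)) < p[ut]) * 1
    m <- m + t(m)
    scn(m, time_ps = (s - 1) * sample_interval_ps)
  })
}

#' Generate a monotone unfolding series by core dilation
#'
#' Frame t rescales all inter-residue centroid distances by
#' 1 + t (max_expansion - 1) / (n_frames - 1) about the global centroid,
#' preserving intra-residue geometry, so inter-residue gaps grow
#' monotonically: native links break, never form, and side-chain
#' accessibility can only grow. Waters, when requested, are sprinkled
#' uniformly in a shell around the structure at a fixed count per frame.
#'
#' @param core_snapshot starting \code{\link{snapshot}} (radii assigned).
#' @param n_frames number of frames (frame 0 is the input).
#' @param max_expansion final centroid-distance scale factor (> 1).
#' @param seed RNG seed for the optional waters.
#' @param n_waters waters per frame (0 for none).
#' @param sample_interval_ps time spacing of the frames.
#' @return list of \code{\link{snapshot}} objects.
#' @export
make_unfolding_series <- function(core_snapshot, n_frames = 8,
                                  max_expansion = 1.6, seed = 1,
                                  n_waters = 0, sample_interval_ps = 10) {
  stopifnot(inherits(core_snapshot, "snapshot"), max_expansion > 1,
            n_frames >= 2)
  a <- core_snapshot$atoms
  key <- residue_key(a$chain, a$res_seq)
  xyz <- atom_xyz(a)
  cent <- apply(xyz, 2, function(v) tapply(v, key, mean))
  g <- colMeans(xyz)
  shift0 <- cent[key, , drop = FALSE]   # residue centroid per atom
  set.seed(seed)
  lapply(seq_len(n_frames) - 1L, function(t) {
    f <- 1 + t * (max_expansion - 1) / (n_frames - 1)
    new_xyz <- xyz + (f - 1) * sweep(shift0, 2, g)
    at <- a
    at$x <- new_xyz[, 1]; at$y <- new_xyz[, 2]; at$z <- new_xyz[, 3]
    waters <- NULL
    if (n_waters > 0) {
      rad <- max(sqrt(rowSums(sweep(new_xyz, 2, g)^2))) + 6
      u <- matrix(stats::rnorm(3 * n_waters), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      waters <- sweep(u * rad * stats::runif(n_waters)^(1 / 3), 2, g, "+")
    }
    snapshot(at, waters = waters, frame_index = t,
             time_ps = t * sample_interval_ps)
  })
}
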