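#' Solvation configuration
#'
#' @param probe_radius solvent probe radius in angstrom (1.4 by default).
#' @param water_cutoff water-core interaction distance in angstrom (5.0).
#' @param sasa_density dot sampling density for accessibility, dots per
#'   square angstrom.
#' @return object of class \code{solvation_config}.
#' @export
solvation_config <- function(probe_radius = 1.4, water_cutoff = 5.0,
                             sasa_density = 10) {
  stopifnot(probe_radius > 0, water_cutoff > 0, sasa_density > 0)
  structure(list(probe_radius = probe_radius, water_cutoff = water_cutoff,
                 sasa_density = sasa_density),
            class = "solvation_config")
}

#' Per-residue side-chain solvent accessible surface area
#'
#' Shrake-Rupley-style dot sampling: each atom's sphere is expanded by the
#' probe radius and sampled on the deterministic spiral; a dot is accessible
#' iff it lies outside every other atom's expanded sphere. An atom's
#' accessible area is its accessible dot fraction times the expanded-sphere
#' area; a residue's value sums its side-chain atoms. Waters take no part
#' in either surface or occlusion.
#'
#' @param snap a \code{\link{snapshot}} with radii assigned.
#' @param cfg a \code{\link{solvation_config}}.
#' @return named numeric vector, area per residue key in square angstrom.
#' @export
sidechain_sasa <- function(snap, cfg = solvation_config()) {
  stopifnot(inherits(snap, "snapshot"))
  a <- snap$atoms
  if (anyNA(a$vdw_radius)) stop("unassigned radii; call assign_radii() first")
  centers <- atom_xyz(a)
  re <- a$vdw_radius + cfg$probe_radius
  n <- nrow(a)

  nb <- neighbor_pairs(centers, re + max(re))
  dd2 <- rowSums((centers[nb[, 1], , drop = FALSE] -
                  centers[nb[, 2], , drop = FALSE])^2)
  nb <- nb[dd2 < (re[nb[, 1]] + re[nb[, 2]])^2, , drop = FALSE]
  occ_list <- split(nb[, 2], factor(nb[, 1], levels = seq_len(n)))

  area <- numeric(n)
  for (i in seq_len(n)) {
    ndot <- max(1L, as.integer(round(4 * pi * re[i]^2 * cfg$sasa_density)))
    p <- sweep(fibonacci_sphere(ndot) * re[i], 2, centers[i, ], "+")
    occ <- occ_list[[i]]
    keep <- dots_outside_spheres(p, centers[occ, , drop = FALSE], re[occ])
    area[i] <- 4 * pi * re[i]^2 * sum(keep) / ndot
  }
  key <- residue_key(a$chain, a$res_seq)
  sc_area <- area * (!a$is_backbone)
  out <- tapply(sc_area, key, sum)
  setNames(as.numeric(out), names(out))[unique(key)]
}

#' Summed core side-chain accessibility (SASC)
#'
#' @param snap a \code{\link{snapshot}} with radii assigned.
#' @param core a \code{\link{core_definition}}.
#' @param cfg a \code{\link{solvation_config}}.
#' @return SASC in square angstrom.
#' @export
sasc <- function(snap, core, cfg = solvation_config()) {
  per_res <- sidechain_sasa(snap, cfg)
  missing <- setdiff(core$key, names(per_res))
  if (length(missing)) stop("core residues absent: ",
                            paste(missing, collapse = ", "))
  sum(per_res[core$key])
}

#' Normalized core accessibility (SASCN)
#'
#' SASC of a snapshot divided by the mean SASC of the baseline
#' (native-temperature) ensemble. By construction the baseline ensemble's
#' mean SASCN is exactly 1.
#'
#' @param snapshot_sasc SASC of the snapshot, square angstrom.
#' @param baseline_mean_sasc positive baseline mean SASC.
#' @return dimensionless ratio.
#' @export
sascn <- function(snapshot_sasc, baseline_mean_sasc) {
  if (any(baseline_mean_sasc <= 0)) stop("baseline mean SASC must be > 0")
  snapshot_sasc / baseline_mean_sasc
}

#' Count waters interacting with the core
#'
#' Number of distinct water molecules (by oxygen) whose oxygen lies within
#' the cutoff (5.0 angstrom by default) of any side-chain atom of any core
#' residue.
#'
#' @param snap a \code{\link{snapshot}} (waters may be absent).
#' @param core a \code{\link{core_definition}}.
#' @param cfg a \code{\link{solvation_config}}.
#' @return integer count.
#' @export
count_core_waters <- function(snap, core, cfg = solvation_config()) {
  stopifnot(inherits(snap, "snapshot"))
  w <- snap$waters
  if (is.null(w) || nrow(w) == 0) return(0L)
  sc <- do.call(rbind, lapply(core$key, function(k)
    atom_xyz(select_sidechain(snap, k))))
  if (is.null(sc) || nrow(sc) == 0) return(0L)
  cut2 <- cfg$water_cutoff^2
  hit <- logical(nrow(w))
  chunk <- max(1L, as.integer(2^22 / nrow(sc)))
  for (s in seq(1L, nrow(w), by = chunk)) {
    e <- min(nrow(w), s + chunk - 1L)
    d2 <- outer(rowSums(w[s:e, , drop = FALSE]^2), rowSums(sc^2), "+") -
      2 * tcrossprod(w[s:e, , drop = FALSE], sc)
    hit[s:e] <- apply(d2 <= cut2, 1, any)
  }
  sum(hit)
}

#' Fractional secondary-structural content of an epoch
#'
#' Per snapshot, the fraction of the native secondary-structure residues
#' whose current label class (helix or strand) matches their native class;
#' the epoch value averages this fraction over the epoch's snapshots.
#' Labels come from an external assignment (e.g. STRIDE output parsed by
#' \code{\link{read_sse_labels}}).
#'
#' @param per_snapshot_sse list of named label vectors (values
#'   \code{"helix"/"strand"/"other"}), one per snapshot.
#' @param native_sse named character vector of native classes
#'   (\code{"helix"} or \code{"strand"}) for the tracked residues.
#' @return number in [0, 1].
#' @export
ssc_epoch <- function(per_snapshot_sse, native_sse) {
  if (!length(native_sse)) stop("empty native secondary-structure set")
  keys <- names(native_sse)
  fr <- vapply(per_snapshot_sse, function(lab) {
    missing <- setdiff(keys, names(lab))
    if (length(missing))
      stop("residue missing from snapshot labels: ",
           paste(missing, collapse = ", "))
    mean(lab[keys] == native_sse)
  }, numeric(1))
  mean(fr)
}
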