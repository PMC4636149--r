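#' Scoring configuration for surface contact networks
#'
#' Collects every tunable of the contact definition: the nearest-neighbor
#' search radius between dot points (3.5 angstrom), the Gaussian distance
#' scaling \code{w} (0.5 per square angstrom) in the complementarity score,
#' the mutual contact thresholds S_m >= 0.40 and O_v >= 0.08, the surface
#' sampling density, and the 3.8 angstrom heavy-atom cutoff that defines
#' native distance contacts.
#'
#' @param neighbor_cutoff dot nearest-neighbor search radius, angstrom.
#' @param w distance scaling factor of the complementarity score.
#' @param sm_threshold,ov_threshold mutual contact thresholds in [0, 1].
#' @param density surface sampling density, dots per square angstrom.
#' @param native_contact_cutoff side-chain heavy-atom distance defining a
#'   native contact, angstrom.
#' @return object of class \code{scoring_config}.
#' @export
scoring_config <- function(neighbor_cutoff = 3.5, w = 0.5,
                           sm_threshold = 0.40, ov_threshold = 0.08,
                           density = 10, native_contact_cutoff = 3.8) {
  stopifnot(neighbor_cutoff > 0, w > 0, density > 0,
            native_contact_cutoff > 0,
            sm_threshold >= 0, sm_threshold <= 1,
            ov_threshold >= 0, ov_threshold <= 1)
  structure(list(neighbor_cutoff = neighbor_cutoff, w = w,
                 sm_threshold = sm_threshold, ov_threshold = ov_threshold,
                 density = density,
                 native_contact_cutoff = native_contact_cutoff),
            class = "scoring_config")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

## Per-dot scores for one residue A against the rest of the chain.
## For every side-chain dot of A, its single nearest dot among ALL dots not
## owned by A (side chain and backbone of every other residue) within the
## cutoff is located. The complementarity of the pair is
## S = -(n_a . n_b) exp(-w d^2): one normal is inverted so ideally apposed
## anti-parallel surfaces score +1.
residue_dot_scores <- function(surface, akey, cfg) {
  d <- surface$dots
  qa <- d[d$residue == akey & d$is_sidechain, , drop = FALSE]
  tg <- d[d$residue != akey, , drop = FALSE]
  n_a <- nrow(qa)
  if (n_a == 0)
    return(list(n_a = 0L, owner = character(0), owner_sc = logical(0),
                s = numeric(0)))
  nn <- nn1_cross(as.matrix(qa[, c("x", "y", "z")]),
                  as.matrix(tg[, c("x", "y", "z")]),
                  cfg$neighbor_cutoff)
  hit <- !is.na(nn$idx)
  j <- nn$idx[hit]
  ndot <- qa$nx[hit] * tg$nx[j] + qa$ny[hit] * tg$ny[j] +
          qa$nz[hit] * tg$nz[j]
  s <- -ndot * exp(-cfg$w * nn$dist[hit]^2)
  list(n_a = n_a, owner = tg$residue[j], owner_sc = tg$is_sidechain[j],
       s = s)
}

score_from_dots <- function(sc, bkey) {
  contrib <- sc$owner == bkey & sc$owner_sc
  n_ab <- sum(contrib)
  list(sm = if (n_ab > 0) median(sc$s[contrib]) else 0,
       ov = if (sc$n_a > 0) n_ab / sc$n_a else 0,
       n = sc$n_a, n_ab = n_ab)
}

#' Surface complementarity and overlap of a residue pair
#'
#' Scores both directions A->B and B->A. For each side-chain dot of A its
#' nearest surrounding dot (from any other residue, side chain or backbone,
#' within the neighbor cutoff) is found; the dot contributes to the A->B
#' score only when that nearest dot lies on B's side chain. S_m is the
#' median of the contributing per-dot complementarities and O_v the
#' contributing fraction N_AB / N_A. A residue with no side-chain dots
#' (glycine) scores 0 and is flagged.
#'
#' @param surface a \code{\link{dot_surface}} covering both residues.
#' @param a,b residues as \code{c(chain, res_seq)} or residue keys.
#' @param cfg a \code{\link{scoring_config}}.
#' @return list of class \code{pair_surface_score} with elements
#'   \code{sm_ab, sm_ba, ov_ab, ov_ba, n_a, n_b, n_ab, n_ba, flagged}.
#' @export
score_pair <- function(surface, a, b, cfg = scoring_config()) {
  stopifnot(inherits(surface, "dot_surface"))
  akey <- if (length(a) == 2) residue_key(a[1], a[2]) else as.character(a)
  bkey <- if (length(b) == 2) residue_key(b[1], b[2]) else as.character(b)
  for (k in c(akey, bkey))
    if (!k %in% surface$dots$residue) stop("residue not on surface: ", k)
  sa <- residue_dot_scores(surface, akey, cfg)
  sb <- residue_dot_scores(surface, bkey, cfg)
  ab <- score_from_dots(sa, bkey)
  ba <- score_from_dots(sb, akey)
  structure(list(residue_a = akey, residue_b = bkey,
                 sm_ab = ab$sm, sm_ba = ba$sm,
                 ov_ab = ab$ov, ov_ba = ba$ov,
                 n_a = ab$n, n_b = ba$n, n_ab = ab$n_ab, n_ba = ba$n_ab,
                 flagged = ab$n == 0 || ba$n == 0),
            class = "pair_surface_score")
}

#' @export
print.pair_surface_score <- function(x, ...) {
  cat(sprintf("%s ~ %s: Sm %.3f / %.3f, Ov %.3f / %.3f (N %d/%d)%s\n",
              x$residue_a, x$residue_b, x$sm_ab, x$sm_ba, x$ov_ab, x$ov_ba,
              x$n_a, x$n_b, if (x$flagged) " [no side-chain dots]" else ""))
  invisible(x)
}

#' Surface contact network container
#'
#' A labeled symmetric binary adjacency matrix over the ordered core
#' residues of one snapshot.
#'
#' @param adjacency square binary matrix with zero diagonal; dimnames are
#'   the residue keys in core order.
#' @param time_ps snapshot time.
#' @param edges optional data.frame of scored edges (kept as an attribute).
#' @return object of class \code{scn}.
#' @export
scn <- function(adjacency, time_ps = 0, edges = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  structure(list(nodes = rownames(adjacency), adjacency = adjacency,
                 time_ps = time_ps, edges = edges),
            class = "scn")
}

#' @export
print.scn <- function(x, ...) {
  cat(sprintf("scn: %d nodes, %d links (t = %g ps)\n",
              length(x$nodes), sum(x$adjacency) / 2, x$time_ps))
  invisible(x)
}

#' Build the surface contact network of a snapshot
#'
#' Generates the dot surface of the whole chain, scores every candidate
#' core pair in both directions and places a link where all four
#' quantities pass their thresholds simultaneously:
#' S_m(A->B) >= 0.40, S_m(B->A) >= 0.40, O_v(A->B) >= 0.08 and
#' O_v(B->A) >= 0.08 (defaults; see \code{\link{scoring_config}}).
#' Candidate pairs are prescreened by side-chain heavy-atom distance at
#' \code{neighbor_cutoff + 2 max(radius)}, which provably cannot exclude a
#' true contact.
#'
#' @param snap a \code{\link{snapshot}} with radii assigned.
#' @param core a \code{\link{core_definition}}.
#' @param cfg a \code{\link{scoring_config}}.
#' @param surface optionally, a precomputed \code{\link{dot_surface}}.
#' @return an \code{\link{scn}} with the scored edge table in \code{$edges}.
#' @export
build_scn <- function(snap, core, cfg = scoring_config(), surface = NULL) {
  stopifnot(inherits(core, "core_definition"))
  if (nrow(core) == 0) stop("empty core")
  if (is.null(surface)) {
    stopifnot(inherits(snap, "snapshot"))
    akey <- residue_key(snap$atoms$chain, snap$atoms$res_seq)
    missing <- setdiff(core$key, akey)
    if (length(missing))
      stop("core residues absent from snapshot: ",
           paste(missing, collapse = ", "))
    surface <- generate_dot_surface(snap, cfg$density)
  }
  n <- nrow(core)
  adj <- matrix(0, n, n, dimnames = list(core$key, core$key))

  # prescreen by side-chain heavy-atom separation
  sc_xyz <- if (!is.null(snap)) {
    lapply(core$key, function(k) {
      sc <- select_sidechain(snap, k)
      atom_xyz(sc[!sc$is_hydrogen, , drop = FALSE])
    })
  } else {
    lapply(core$key, function(k) {
      d <- surface$dots[surface$dots$residue == k, , drop = FALSE]
      as.matrix(d[, c("x", "y", "z")])
    })
  }
  max_r <- if (!is.null(snap)) max(snap$atoms$vdw_radius) else 0
  screen <- cfg$neighbor_cutoff + 2 * max_r

  cand <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (min_cross_dist(sc_xyz[[i]], sc_xyz[[j]]) <= screen)
      cand[[length(cand) + 1L]] <- c(i, j)
  if (!length(cand))
    return(scn(adj, time_ps = if (!is.null(snap)) snap$time_ps else 0,
               edges = empty_edge_table()))

  active <- sort(unique(unlist(cand)))
  sc_dots <- setNames(vector("list", length(active)), core$key[active])
  for (i in active)
    sc_dots[[core$key[i]]] <- residue_dot_scores(surface, core$key[i], cfg)

  rows <- list()
  for (p in cand) {
    i <- p[1]; j <- p[2]
    ab <- score_from_dots(sc_dots[[core$key[i]]], core$key[j])
    ba <- score_from_dots(sc_dots[[core$key[j]]], core$key[i])
    linked <- ab$sm >= cfg$sm_threshold && ba$sm >= cfg$sm_threshold &&
              ab$ov >= cfg$ov_threshold && ba$ov >= cfg$ov_threshold
    if (linked) adj[i, j] <- adj[j, i] <- 1
    rows[[length(rows) + 1L]] <-
      data.frame(residue_a = core$key[i], residue_b = core$key[j],
                 sm_ab = ab$sm, sm_ba = ba$sm, ov_ab = ab$ov, ov_ba = ba$ov,
                 linked = linked, stringsAsFactors = FALSE)
  }
  scn(adj, time_ps = if (!is.null(snap)) snap$time_ps else 0,
      edges = do.call(rbind, rows))
}

empty_edge_table <- function() {
  data.frame(residue_a = character(0), residue_b = character(0),
             sm_ab = numeric(0), sm_ba = numeric(0), ov_ab = numeric(0),
             ov_ba = numeric(0), linked = logical(0))
}

#' Link set of a network
#'
#' @param x an \code{\link{scn}} or a symmetric binary matrix with residue
#'   dimnames.
#' @return character vector of canonical pair keys \code{"a|b"}.
#' @export
scn_links <- function(x) {
  m <- if (inherits(x, "scn")) x$adjacency else as.matrix(x)
  idx <- which(upper.tri(m) & m == 1, arr.ind = TRUE)
  if (!nrow(idx)) return(character(0))
  pair_key(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]])
}

#' Native distance contacts of the core
#'
#' A pair of core residues is a native contact when the minimum distance
#' between their side-chain heavy atoms is at most the native-contact
#' cutoff (3.8 angstrom by default); hydrogens are excluded from the
#' distance criterion.
#'
#' @param snap a \code{\link{snapshot}} (the reference structure).
#' @param core a \code{\link{core_definition}}.
#' @param cfg a \code{\link{scoring_config}}.
#' @return character vector of canonical pair keys.
#' @export
native_contacts <- function(snap, core, cfg = scoring_config()) {
  stopifnot(inherits(snap, "snapshot"), inherits(core, "core_definition"))
  xyz <- lapply(core$key, function(k) {
    sc <- select_sidechain(snap, k)
    atom_xyz(sc[!sc$is_hydrogen, , drop = FALSE])
  })
  n <- nrow(core)
  out <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (min_cross_dist(xyz[[i]], xyz[[j]]) <= cfg$native_contact_cutoff)
      out <- c(out, pair_key(core$key[i], core$key[j]))
  out
}

#' Partition network links by secondary-structure class
#'
#' Links are parsed into the sets S1 (core-core: neither end helical),
#' S2 (helix H1 - core), S3 (helix H2 - core) and intra-helix (both ends on
#' the same helix). A link bridging H1 and H2 does not occur in the native
#' structure; it is assigned to S2 by H1 precedence with a warning.
#'
#' @param net an \code{\link{scn}}.
#' @param core the \code{\link{core_definition}} carrying \code{sse_class}.
#' @return named character vector, names are pair keys, values in
#'   \code{c("S1","S2","S3","intra-helix")}.
#' @export
partition_links <- function(net, core) {
  stopifnot(inherits(net, "scn"), inherits(core, "core_definition"))
  links <- scn_links(net)
  if (!length(links)) return(setNames(character(0), character(0)))
  ends <- strsplit(links, "|", fixed = TRUE)
  cls <- setNames(core$sse_class, core$key)
  out <- vapply(ends, function(e) {
    a <- cls[[e[1]]]; b <- cls[[e[2]]]
    if ((a == "H1" && b == "H1") || (a == "H2" && b == "H2")) "intra-helix"
    else if (a == "H1" && b == "H2" || a == "H2" && b == "H1") {
      warning("H1-H2 cross link ", e[1], "|", e[2],
              "; assigned to S2 by H1 precedence")
      "S2"
    }
    else if (a == "H1" || b == "H1") "S2"
    else if (a == "H2" || b == "H2") "S3"
    else "S1"
  }, character(1))
  setNames(out, links)
}

#' Native reference of a trajectory analysis
#'
#' Bundles everything downstream metrics compare against: the reference
#' structure's surface contact network and its link set, the native
#' distance-contact set, and the link partition.
#'
#' @param snap reference \code{\link{snapshot}} (crystal structure).
#' @param core a \code{\link{core_definition}}.
#' @param cfg a \code{\link{scoring_config}}.
#' @return list of class \code{native_reference}.
#' @export
native_reference <- function(snap, core, cfg = scoring_config()) {
  net <- build_scn(snap, core, cfg)
  structure(list(native_scn = net,
                 native_links = scn_links(net),
                 native_contacts = native_contacts(snap, core, cfg),
                 link_partition = partition_links(net, core),
                 core = core, cfg = cfg, snapshot = snap),
            class = "native_reference")
}

#' @export
print.native_reference <- function(x, ...) {
  tab <- table(factor(x$link_partition,
                      levels = c("S1", "S2", "S3", "intra-helix")))
  cat(sprintf("native reference: %d contacts (%.1f A rule), %d links [%s]\n",
              length(x$native_contacts), x$cfg$native_contact_cutoff,
              length(x$native_links),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Reproduce the crystal-structure reference numbers
#'
#' Given a protonated copy of the deposited cyclophilin structure (PDB id
#' 2HAQ) and the full 24-residue core, recomputes the published reference
#' quantities: the native contact count (3.8 angstrom rule), the native SCN
#' link count, the S1/S2/S3 link partition sizes and the summed side-chain
#' solvent accessibility of the core. Exact counts are sensitive to the
#' protonation protocol and radii table, so callers should compare with
#' tolerance rather than byte equality.
#'
#' @param pdb_path path to a protonated PDB file.
#' @param core the full core \code{\link{core_definition}}.
#' @param cfg a \code{\link{scoring_config}}.
#' @param solv_cfg a \code{\link{solvation_config}}.
#' @param allow_missing_hydrogens accept an unprotonated file (reduced
#'   fidelity).
#' @return list with \code{n_contacts}, \code{n_links}, \code{partition},
#'   \code{core_sasa}.
#' @export
crystal_reference <- function(pdb_path, core,
                              cfg = scoring_config(),
                              solv_cfg = solvation_config(),
                              allow_missing_hydrogens = FALSE) {
  snap <- read_snapshots(pdb_path,
                         allow_missing_hydrogens = allow_missing_hydrogens)[[1]]
  snap <- assign_radii(snap)
  ref <- native_reference(snap, core, cfg)
  sasa <- sidechain_sasa(snap, solv_cfg)
  list(n_contacts = length(ref$native_contacts),
       n_links = length(ref$native_links),
       partition = table(factor(ref$link_partition,
                                levels = c("S1", "S2", "S3", "intra-helix"))),
       core_sasa = sum(sasa[core$key]),
       reference = ref)
}

#' Write a network edge list
#'
#' Tab-separated table, one row per scored candidate pair:
#' chain/res_seq/res_name of both residues, the four directional scores and
#' the link flag. Importable by common graph viewers.
#'
#' @param net an \code{\link{scn}} built by \code{\link{build_scn}}.
#' @param core the \code{\link{core_definition}} (for residue names).
#' @param path output file.
#' @param linked_only write only rows that form links.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, core, path, linked_only = FALSE) {
  e <- net$edges
  if (is.null(e)) e <- empty_edge_table()
  if (linked_only) e <- e[e$linked, , drop = FALSE]
  split_key <- function(k) do.call(rbind, strsplit(k, ":", fixed = TRUE))
  nm <- setNames(core$res_name, core$key)
  if (nrow(e)) {
    a <- split_key(e$residue_a); b <- split_key(e$residue_b)
    out <- data.frame(chainA = a[, 1], resseqA = a[, 2],
                      resnameA = nm[e$residue_a],
                      chainB = b[, 1], resseqB = b[, 2],
                      resnameB = nm[e$residue_b],
                      sm_ab = e$sm_ab, sm_ba = e$sm_ba,
                      ov_ab = e$ov_ab, ov_ba = e$ov_ba,
                      linked = as.integer(e$linked))
  } else {
    out <- data.frame(chainA = character(0), resseqA = character(0),
                      resnameA = character(0), chainB = character(0),
                      resseqB = character(0), resnameB = character(0),
                      sm_ab = numeric(0), sm_ba = numeric(0),
                      ov_ab = numeric(0), ov_ba = numeric(0),
                      linked = integer(0))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an adjacency matrix
#'
#' @param net an \code{\link{scn}}.
#' @param path output TSV with residue-labeled rows and columns.
#' @return \code{path}, invisibly.
#' @export
write_adjacency <- function(net, path) {
  write.table(net$adjacency, path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}
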