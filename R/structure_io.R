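#' @importFrom stats median sd var cor aggregate setNames
#' @importFrom utils head tail read.table write.csv write.table
NULL

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SPC", "SOL")

## Backbone convention: N, CA, C, O, OXT plus the hydrogens riding on them
## (H, H1-H3, HA, HA2/HA3 and PDBv2 spellings). Everything else, CB included,
## is side chain; glycine therefore has no side-chain atoms.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HN",
                    "HA", "HA1", "HA2", "HA3",
                    "1H", "2H", "3H", "1HA", "2HA", "3HA")

#' Residue identity keys
#'
#' Residues are identified throughout the package by the pair
#' (chain, residue sequence number), rendered as the string
#' \code{"<chain>:<res_seq>"}. PDB numbering is kept verbatim; nothing is
#' renumbered.
#'
#' @param chain chain identifier(s).
#' @param res_seq residue sequence number(s).
#' @return character vector of keys.
#' @export
residue_key <- function(chain, res_seq) paste(chain, res_seq, sep = ":")

guess_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE"),
               two, substr(nm, 1, 1))
  # digit-led hydrogen names like 1HB1 reduce to "HB" -> "H"
  el[substr(el, 1, 1) %in% c("H", "D")] <- "H"
  el
}

#' Construct a coordinate snapshot
#'
#' A snapshot is one frame of protein coordinates: an atom table plus an
#' optional matrix of water-oxygen positions. The atom table mirrors PDB
#' ATOM records with per-atom van der Waals radii, a backbone flag (see
#' \code{\link{select_sidechain}} for the convention) and a hydrogen flag.
#'
#' @param atoms data.frame with columns \code{chain}, \code{res_seq},
#'   \code{res_name}, \code{atom_name}, \code{element}, \code{x}, \code{y},
#'   \code{z} and optionally \code{vdw_radius}.
#' @param waters numeric matrix (n x 3) of water oxygen coordinates, or NULL.
#' @param frame_index integer frame number (0-based across a trajectory).
#' @param time_ps simulation time of the frame in picoseconds.
#' @return object of class \code{snapshot}.
#' @export
snapshot <- function(atoms, waters = NULL, frame_index = 0L, time_ps = 0) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("chain", "res_seq", "res_name", "atom_name", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("snapshot atoms lack columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom_name)
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- NA_real_
  atoms$is_hydrogen <- atoms$element == "H"
  atoms$is_backbone <- toupper(atoms$atom_name) %in% BACKBONE_ATOMS
  if (!is.null(waters)) {
    waters <- as.matrix(waters)
    if (ncol(waters) != 3) stop("waters must be an n x 3 matrix")
  }
  structure(list(frame_index = as.integer(frame_index),
                 time_ps = as.numeric(time_ps),
                 atoms = atoms, waters = waters),
            class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  nres <- length(unique(residue_key(x$atoms$chain, x$atoms$res_seq)))
  cat(sprintf("snapshot: frame %d (t = %g ps), %d atoms / %d residues, %d waters\n",
              x$frame_index, x$time_ps, nrow(x$atoms), nres,
              if (is.null(x$waters)) 0L else nrow(x$waters)))
  invisible(x)
}

#' Read snapshots from a PDB file
#'
#' Single-model files yield one snapshot; MODEL/ENDMDL records delimit the
#' frames of a multi-model trajectory. Water residues (HOH/WAT/TIP3/...) are
#' separated into the \code{waters} slot (oxygen positions); other
#' heteroatoms are dropped. Alternate locations keep the highest-occupancy
#' conformer. Because the surface method scores hydrogen atoms too, files
#' without hydrogens are rejected unless
#' \code{allow_missing_hydrogens = TRUE}.
#'
#' @param path PDB file path.
#' @param time_step_ps time spacing assigned to successive models.
#' @param allow_missing_hydrogens accept coordinates without hydrogens
#'   (reduced fidelity; typically raw crystal structures).
#' @return list of \code{\link{snapshot}} objects.
#' @export
read_snapshots <- function(path, time_step_ps = 10,
                           allow_missing_hydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms parsed from ", path)

  # highest-occupancy alternate conformer only
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    o <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(o[i])]
    }), use.names = FALSE)
    keep <- sort(keep)
  } else keep <- seq_len(nrow(at))

  is_water <- at$resid %in% WATER_RESNAMES
  is_het <- at$type == "HETATM" & !is_water
  prot_rows <- intersect(keep, which(!is_water & !is_het))
  wat_rows <- intersect(keep, which(is_water))
  if (length(prot_rows) == 0) stop("no protein atoms in ", path)

  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  el <- ifelse(is.na(el) | el == "", guess_element(at$elety), toupper(trimws(el)))

  if (!any(el[prot_rows] == "H") && !allow_missing_hydrogens)
    stop("no hydrogen atoms found in ", path, "; the surface method expects ",
         "protonated coordinates. Pass allow_missing_hydrogens = TRUE to ",
         "proceed at reduced fidelity.")

  # water oxygens only
  wat_rows <- wat_rows[el[wat_rows] == "O"]

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nmodel <- nrow(xyz)

  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  lapply(seq_len(nmodel), function(m) {
    cm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(chain = chain[prot_rows],
                        res_seq = at$resno[prot_rows],
                        res_name = at$resid[prot_rows],
                        atom_name = at$elety[prot_rows],
                        element = el[prot_rows],
                        x = cm[prot_rows, 1], y = cm[prot_rows, 2],
                        z = cm[prot_rows, 3],
                        stringsAsFactors = FALSE)
    waters <- if (length(wat_rows)) cm[wat_rows, , drop = FALSE] else NULL
    snapshot(atoms, waters = waters, frame_index = m - 1L,
             time_ps = (m - 1) * time_step_ps)
  })
}

#' Write a snapshot as a PDB file
#'
#' Protein atoms are written as ATOM records, waters as HETATM oxygens, at
#' standard PDB coordinate precision (1e-3 angstrom).
#'
#' @param snap a \code{\link{snapshot}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_snapshot <- function(snap, path) {
  stopifnot(inherits(snap, "snapshot"))
  a <- snap$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  n <- nrow(a)
  if (!is.null(snap$waters) && nrow(snap$waters) > 0) {
    w <- snap$waters
    nw <- nrow(w)
    bio3d::write.pdb(file = path,
                     xyz = c(xyz, as.numeric(t(w))),
                     type = c(rep("ATOM", n), rep("HETATM", nw)),
                     resno = c(a$res_seq, seq_len(nw) + max(a$res_seq)),
                     resid = c(a$res_name, rep("HOH", nw)),
                     elety = c(a$atom_name, rep("O", nw)),
                     chain = c(a$chain, rep("W", nw)),
                     o = rep(1, n + nw), b = rep(0, n + nw))
  } else {
    bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                     resno = a$res_seq, resid = a$res_name,
                     elety = a$atom_name, chain = a$chain,
                     o = rep(1, n), b = rep(0, n))
  }
  invisible(path)
}

#' Default van der Waals radii
#'
#' A configurable radii table: specific entries keyed by
#' (residue name, atom name) override per-element fallbacks. The shipped
#' defaults are a standard all-atom set (C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, H 1.10 angstrom); any force-field table can be substituted.
#'
#' @param specific optional data.frame with columns \code{res_name},
#'   \code{atom_name}, \code{radius} overriding the element fallback.
#' @param elements named numeric vector of per-element fallback radii.
#' @return object of class \code{radii_table}.
#' @export
radii_table <- function(specific = NULL,
                        elements = c(H = 1.10, C = 1.70, N = 1.55,
                                     O = 1.52, S = 1.80, P = 1.80,
                                     SE = 1.90)) {
  if (any(elements <= 0.2 | elements >= 3.0))
    stop("element radii must lie in (0.2, 3.0) angstrom")
  if (!is.null(specific)) {
    stopifnot(all(c("res_name", "atom_name", "radius") %in% names(specific)))
    if (any(specific$radius <= 0.2 | specific$radius >= 3.0))
      stop("specific radii must lie in (0.2, 3.0) angstrom")
  }
  structure(list(specific = specific, elements = elements),
            class = "radii_table")
}

#' Assign van der Waals radii to every atom
#'
#' Looks each atom up in the specific (residue, atom) table first, then
#' falls back to its element radius. Atoms resolvable by neither route are
#' an error naming the offenders.
#'
#' @param snap a \code{\link{snapshot}}.
#' @param table a \code{\link{radii_table}}.
#' @return the snapshot with all \code{vdw_radius} fields set.
#' @export
assign_radii <- function(snap, table = radii_table()) {
  stopifnot(inherits(snap, "snapshot"), inherits(table, "radii_table"))
  a <- snap$atoms
  r <- unname(table$elements[a$element])
  if (!is.null(table$specific)) {
    key <- paste(a$res_name, toupper(a$atom_name))
    skey <- paste(table$specific$res_name, toupper(table$specific$atom_name))
    hit <- match(key, skey)
    r[!is.na(hit)] <- table$specific$radius[hit[!is.na(hit)]]
  }
  if (anyNA(r)) {
    bad <- unique(paste0(a$res_name[is.na(r)], " ", a$res_seq[is.na(r)], "/",
                         a$atom_name[is.na(r)], " (element ",
                         a$element[is.na(r)], ")"))
    stop("no radius for atom(s): ", paste(head(bad, 5), collapse = "; "))
  }
  snap$atoms$vdw_radius <- r
  snap
}

#' Side-chain atoms of one residue
#'
#' Backbone is N, CA, C, O, OXT and their riding hydrogens; everything else
#' (CB included) is side chain, so glycine returns zero rows.
#'
#' @param snap a \code{\link{snapshot}}.
#' @param residue length-2 vector \code{c(chain, res_seq)} or a residue key.
#' @return data.frame of side-chain atom rows.
#' @export
select_sidechain <- function(snap, residue) {
  stopifnot(inherits(snap, "snapshot"))
  key <- if (length(residue) == 2) residue_key(residue[1], residue[2])
         else as.character(residue)
  akey <- residue_key(snap$atoms$chain, snap$atoms$res_seq)
  if (!key %in% akey) stop("residue not found: ", key)
  snap$atoms[akey == key & !snap$atoms$is_backbone, , drop = FALSE]
}

#' Define the residue core tracked by the networks
#'
#' @param chain,res_seq,res_name vectors describing the core residues, in a
#'   fixed order that is preserved as the node order of every network.
#' @param sse_class secondary-structure class per residue, one of
#'   \code{"H1"}, \code{"H2"}, \code{"strand"}, \code{"loop"}.
#' @return object of class \code{core_definition}.
#' @export
core_definition <- function(chain, res_seq, res_name = NULL,
                            sse_class = NULL) {
  n <- length(res_seq)
  if (n < 2) stop("a core needs at least 2 residues")
  chain <- rep_len(chain, n)
  key <- residue_key(chain, res_seq)
  if (anyDuplicated(key)) stop("duplicate residues in core definition")
  if (is.null(res_name)) res_name <- rep(NA_character_, n)
  if (is.null(sse_class)) sse_class <- rep("loop", n)
  sse_class <- match.arg(sse_class, c("H1", "H2", "strand", "loop"),
                         several.ok = TRUE)
  sse_class <- rep_len(sse_class, n)
  structure(data.frame(chain = chain, res_seq = res_seq,
                       res_name = res_name, sse_class = sse_class,
                       key = key, stringsAsFactors = FALSE),
            class = c("core_definition", "data.frame"))
}

#' The 21 named hydrophobic-core residues of L. donovani cyclophilin
#'
#' The cyclophilin core comprises 24 residues; 21 are named in the main
#' analyses (the remaining three appear only in supplementary material), so
#' this shipped default is documented as partial. Users reproducing the
#' crystal-structure numbers must supply the full 24-residue list.
#'
#' @param chain chain identifier of the deposited structure.
#' @return a \code{\link{core_definition}}.
#' @export
ldcyp_core_partial <- function(chain = "A") {
  res <- c(29, 31, 33, 45, 47, 55, 58, 59, 62, 63, 71, 76, 85, 120, 122,
           134, 151, 161, 164, 179, 181)
  nm <- c("VAL", "PHE", "VAL", "ILE", "LEU", "THR", "ASN", "PHE", "LEU",
          "CYS", "TYR", "PHE", "ILE", "LEU", "MET", "PHE", "PHE", "VAL",
          "ILE", "VAL", "ILE")
  sse <- c("strand", "strand", "strand", "strand", "strand", "H1", "H1",
           "H1", "H1", "H1", "loop", "loop", "strand", "strand", "strand",
           "strand", "strand", "H2", "H2", "strand", "strand")
  core_definition(chain, res, nm, sse)
}

#' Parse STRIDE-style secondary structure labels
#'
#' Reads STRIDE \code{ASG} records (one line per residue) or a minimal
#' two-column \code{res_seq code} dialect, and collapses the one-letter
#' codes H/G/I to \code{"helix"}, E/B/b to \code{"strand"} and everything
#' else to \code{"other"}.
#'
#' @param path label file.
#' @return named character vector, names \code{"<chain>:<res_seq>"}.
#' @export
read_sse_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty secondary-structure label file: ", path)
    return(setNames(character(0), character(0)))
  }
  collapse <- function(code) {
    code <- toupper(code)
    ifelse(code %in% c("H", "G", "I"), "helix",
           ifelse(code %in% c("E", "B"), "strand", "other"))
  }
  asg <- grepl("^ASG", lines)
  out <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^(REM|HDR|CHN|SEQ|STR|LOC)", ln)) next
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (asg[i]) {
      # ASG  ALA A    1    1    H  AlphaHelix  ...
      if (length(f) < 6)
        stop("unparseable STRIDE ASG record at line ", i, ": ", ln)
      out[residue_key(f[3], as.integer(f[4]))] <- collapse(f[6])
    } else {
      if (length(f) < 2 || is.na(suppressWarnings(as.integer(f[1]))))
        stop("unparseable label line ", i, ": ", ln)
      out[residue_key("A", as.integer(f[1]))] <- collapse(f[2])
    }
  }
  out
}
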