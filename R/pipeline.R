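## Pipeline orchestration: the run_* functions wrap the per-module
## operations over whole trajectories and write the CSV/TSV outputs the
## command-line interface (inst/cli/scnet) exposes. Every output directory
## gets a manifest echoing the configuration and input hashes.

#' Per-snapshot trajectory metrics
#'
#' Computes, for every frame, the network metrics against the native
#' reference (Disnet to the native network, Q over native distance
#' contacts, Q_L over native links), the solvation metrics (SASC, SASCN,
#' water-core contacts) and the core C-alpha RMSD.
#'
#' @param snapshots list of \code{\link{snapshot}} objects (radii assigned).
#' @param core a \code{\link{core_definition}}.
#' @param reference a \code{\link{native_reference}} built from the
#'   reference structure.
#' @param cfg a \code{\link{scoring_config}}.
#' @param solv_cfg a \code{\link{solvation_config}}.
#' @param baseline_mean_sasc baseline mean SASC for SASCN; NA leaves SASCN
#'   unnormalized (NA column).
#' @return data.frame with one row per frame and the networks as the
#'   \code{"scns"} attribute.
#' @export
analyze_trajectory <- function(snapshots, core, reference,
                               cfg = scoring_config(),
                               solv_cfg = solvation_config(),
                               baseline_mean_sasc = NA) {
  stopifnot(inherits(reference, "native_reference"))
  if (!length(snapshots)) stop("empty trajectory")
  nets <- vector("list", length(snapshots))
  rows <- vector("list", length(snapshots))
  # C-alpha RMSD only when both sides carry comparable C-alpha sets
  ref_ca <- sum(toupper(reference$snapshot$atoms$atom_name) == "CA")
  for (i in seq_along(snapshots)) {
    sn <- snapshots[[i]]
    nets[[i]] <- build_scn(sn, core, cfg)
    sasc_i <- sasc(sn, core, solv_cfg)
    rmsd_i <- if (ref_ca >= 3 &&
                  sum(toupper(sn$atoms$atom_name) == "CA") == ref_ca)
      ca_rmsd(sn, reference$snapshot) else NA_real_
    rows[[i]] <- data.frame(
      frame = sn$frame_index, time_ps = sn$time_ps,
      disnet = disnet(nets[[i]], reference$native_scn),
      q = q_fraction(native_contacts(sn, core, cfg),
                     reference$native_contacts),
      ql = q_fraction(scn_links(nets[[i]]), reference$native_links),
      n_links = length(scn_links(nets[[i]])),
      sasc = sasc_i,
      sascn = if (is.na(baseline_mean_sasc)) NA_real_
              else sascn(sasc_i, baseline_mean_sasc),
      n_waters = count_core_waters(sn, core, solv_cfg),
      rmsd = rmsd_i)
  }
  out <- do.call(rbind, rows)
  attr(out, "scns") <- nets
  out
}

#' Per-epoch fluctuation metrics
#'
#' Splits a network series into epochs and reports, per epoch, the
#' persistence-derived persf (distance of the epoch's binarized
#' persistence matrix from the baseline's) and dlf (mean pairwise Disnet
#' within the epoch).
#'
#' @param scns list of \code{\link{scn}} objects for the whole series.
#' @param times_ps frame times.
#' @param baseline_binary binarized baseline persistence matrix; NULL
#'   derives it from the whole input series (self-baseline).
#' @param span_ps,burn_in_ps epoch span and burn-in, picoseconds.
#' @param threshold persistence binarization threshold.
#' @return data.frame with epoch index, mid-time, persf, dlf and the
#'   per-epoch ensembles as the \code{"epochs"} attribute.
#' @export
epoch_metrics <- function(scns, times_ps, baseline_binary = NULL,
                          span_ps = 2000, burn_in_ps = 2000,
                          threshold = 0.40) {
  idx <- split_epochs(times_ps, span_ps, burn_in_ps)
  if (!length(idx)) stop("no complete epoch after burn-in")
  if (is.null(baseline_binary)) {
    pooled <- persistence_matrix(scns[unlist(idx)])
    baseline_binary <- binarize_persistence(pooled, threshold)
  }
  ens <- lapply(idx, function(i) epoch_ensemble(scns[i], threshold))
  out <- data.frame(
    epoch = seq_along(ens),
    time_mid_ps = vapply(idx, function(i) mean(times_ps[i]), numeric(1)),
    persf = vapply(ens, function(e)
      persf(e$persistence_binary, baseline_binary), numeric(1)),
    dlf = vapply(ens, function(e) dlf(e$scns), numeric(1)))
  attr(out, "epochs") <- ens
  out
}

write_manifest <- function(dir, params, inputs = character(0)) {
  lines <- c(sprintf("generated\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("scnet_version\t%s",
                     as.character(utils::packageVersion("scnet"))))
  for (nm in names(params))
    lines <- c(lines, sprintf("%s\t%s", nm,
                              paste(format(params[[nm]]), collapse = ",")))
  for (f in inputs)
    if (file.exists(f))
      lines <- c(lines, sprintf("md5:%s\t%s", basename(f),
                                unname(tools::md5sum(f))))
  writeLines(lines, file.path(dir, "manifest.tsv"))
  invisible(lines)
}

core_from_config <- function(conf) {
  core_definition(chain = conf$core$chain %||% "A",
                  res_seq = as.integer(conf$core$res_seq),
                  res_name = conf$core$res_name,
                  sse_class = conf$core$sse_class %||% "loop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build networks for every frame of a trajectory
#'
#' Reads a (multi-model) PDB, builds the surface contact network of each
#' frame and writes per-frame adjacency TSVs and edge lists plus a
#' manifest into \code{output_dir}.
#'
#' @param input PDB path.
#' @param core a \code{\link{core_definition}}.
#' @param output_dir output directory (created if absent).
#' @param cfg a \code{\link{scoring_config}}.
#' @param radii a \code{\link{radii_table}}.
#' @param allow_missing_hydrogens forwarded to
#'   \code{\link{read_snapshots}}.
#' @return list of \code{\link{scn}} objects, invisibly.
#' @export
run_build_network <- function(input, core, output_dir,
                              cfg = scoring_config(),
                              radii = radii_table(),
                              allow_missing_hydrogens = FALSE) {
  snaps <- read_snapshots(input,
                          allow_missing_hydrogens = allow_missing_hydrogens)
  if (!length(snaps)) stop("empty trajectory: ", input)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  nets <- vector("list", length(snaps))
  for (i in seq_along(snaps)) {
    sn <- assign_radii(snaps[[i]], radii)
    nets[[i]] <- build_scn(sn, core, cfg)
    tag <- sprintf("frame%04d", sn$frame_index)
    write_adjacency(nets[[i]], file.path(output_dir,
                                         paste0(tag, "_adjacency.tsv")))
    write_edge_list(nets[[i]], core,
                    file.path(output_dir, paste0(tag, "_edges.tsv")))
  }
  write_manifest(output_dir,
                 list(command = "build-network", input = input,
                      n_frames = length(snaps),
                      sm_threshold = cfg$sm_threshold,
                      ov_threshold = cfg$ov_threshold,
                      neighbor_cutoff = cfg$neighbor_cutoff, w = cfg$w,
                      density = cfg$density,
                      core = paste(core$key, collapse = " ")),
                 inputs = input)
  invisible(nets)
}

#' Run the full metric pipeline over a trajectory
#'
#' Per-frame metrics (Disnet, Q, Q_L, SASC, SASCN, water counts) and
#' per-epoch metrics (persf, dlf) are written as CSVs (raw plus smoothed
#' columns for the per-frame series) together with persistence matrices
#' per epoch and a manifest.
#'
#' @param input trajectory PDB path.
#' @param reference_pdb reference structure PDB; NULL uses the first frame.
#' @param core a \code{\link{core_definition}}.
#' @param output_dir output directory.
#' @param cfg,solv_cfg,radii configuration objects.
#' @param baseline_mean_sasc baseline mean SASC (NA: use this trajectory's
#'   mean, making it the designated baseline run).
#' @param span_ps,burn_in_ps,smooth_window epoch span, burn-in and the
#'   adjacent-averaging window for the presentation columns.
#' @param sse_dir optional directory of per-frame secondary-structure label
#'   files (STRIDE-style, one file per frame in lexical order; see
#'   \code{\link{read_sse_labels}}); enables the SSC output.
#' @param native_sse_path reference label file defining the native
#'   secondary-structure classes; defaults to the first frame's file.
#' @param allow_missing_hydrogens forwarded to the PDB reader.
#' @return the per-frame metric data.frame, invisibly.
#' @export
run_metrics <- function(input, core, output_dir, reference_pdb = NULL,
                        cfg = scoring_config(),
                        solv_cfg = solvation_config(),
                        radii = radii_table(),
                        baseline_mean_sasc = NA,
                        span_ps = 2000, burn_in_ps = 2000,
                        smooth_window = 45,
                        sse_dir = NULL, native_sse_path = NULL,
                        allow_missing_hydrogens = FALSE) {
  snaps <- lapply(read_snapshots(input,
                                 allow_missing_hydrogens = allow_missing_hydrogens),
                  assign_radii, table = radii)
  if (!length(snaps)) stop("empty trajectory: ", input)
  ref_snap <- if (is.null(reference_pdb)) snaps[[1]]
              else assign_radii(read_snapshots(
                reference_pdb,
                allow_missing_hydrogens = allow_missing_hydrogens)[[1]],
                radii)
  ref <- native_reference(ref_snap, core, cfg)
  if (is.na(baseline_mean_sasc)) {
    baseline_mean_sasc <- mean(vapply(snaps, sasc, numeric(1),
                                      core = core, cfg = solv_cfg))
  }
  met <- analyze_trajectory(snaps, core, ref, cfg, solv_cfg,
                            baseline_mean_sasc)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  win <- min(smooth_window, nrow(met) - (1 - nrow(met) %% 2))
  if (win %% 2 == 0) win <- win - 1
  win <- max(win, 1)
  for (m in c("disnet", "q", "ql", "sasc", "sascn", "n_waters", "rmsd")) {
    if (all(is.na(met[[m]]))) next
    df <- data.frame(time_ps = met$time_ps, value = met[[m]],
                     smoothed = smooth_adjacent(met[[m]], win))
    write.csv(df, file.path(output_dir, paste0(m, ".csv")),
              row.names = FALSE)
  }
  if (length(snaps) >= 2 && !all(is.na(met$rmsd))) {
    fluct <- rmsf(snaps)
    write.csv(data.frame(residue = names(fluct), rmsf = fluct),
              file.path(output_dir, "rmsf.csv"), row.names = FALSE)
  }
  if (!is.null(sse_dir)) {
    files <- sort(list.files(sse_dir, full.names = TRUE))
    if (length(files) < length(snaps))
      stop("sse_dir holds ", length(files), " label files for ",
           length(snaps), " frames")
    labels <- lapply(files[seq_along(snaps)], read_sse_labels)
    native_lab <- if (is.null(native_sse_path)) labels[[1]]
                  else read_sse_labels(native_sse_path)
    native_sse <- native_lab[native_lab %in% c("helix", "strand")]
    ssc <- vapply(labels, function(l) ssc_epoch(list(l), native_sse),
                  numeric(1))
    write.csv(data.frame(time_ps = met$time_ps, value = ssc,
                         smoothed = smooth_adjacent(ssc, win)),
              file.path(output_dir, "ssc.csv"), row.names = FALSE)
  }
  nets <- attr(met, "scns")
  ep <- tryCatch(epoch_metrics(nets, met$time_ps, baseline_binary = NULL,
                               span_ps = span_ps, burn_in_ps = burn_in_ps),
                 error = function(e) NULL)
  if (!is.null(ep)) {
    write.csv(ep, file.path(output_dir, "epochs.csv"), row.names = FALSE)
    ens <- attr(ep, "epochs")
    for (i in seq_along(ens))
      write.table(ens[[i]]$persistence,
                  file.path(output_dir,
                            sprintf("persistence_epoch%03d.tsv", i)),
                  sep = "\t", quote = FALSE, col.names = NA)
  }
  write_manifest(output_dir,
                 list(command = "metrics", input = input,
                      reference = reference_pdb %||% "first frame",
                      n_frames = length(snaps),
                      baseline_mean_sasc = baseline_mean_sasc,
                      span_ps = span_ps, burn_in_ps = burn_in_ps,
                      smooth_window = win),
                 inputs = c(input, reference_pdb))
  invisible(met)
}

#' Free-energy landscape over two metric columns
#'
#' @param metrics data.frame from \code{\link{run_metrics}} /
#'   \code{\link{analyze_trajectory}} (or a CSV path with the same
#'   columns).
#' @param output_dir output directory.
#' @param x_metric column for the x axis (\code{"ql"} or \code{"disnet"}).
#' @param y_metric column for the y axis (default \code{"sascn"}).
#' @param lcfg a \code{\link{landscape_config}}.
#' @return the \code{\link{free_energy_grid}}, invisibly.
#' @export
run_landscape <- function(metrics, output_dir, x_metric = "ql",
                          y_metric = "sascn",
                          lcfg = landscape_config()) {
  if (is.character(metrics)) metrics <- utils::read.csv(metrics)
  counts <- bin_counts(metrics[[x_metric]], metrics[[y_metric]], lcfg)
  grid <- free_energy(counts, lcfg)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_landscape(grid, file.path(output_dir, "landscape.csv"))
  write_manifest(output_dir,
                 list(command = "landscape", x_metric = x_metric,
                      y_metric = y_metric, nbins_x = lcfg$nbins_x,
                      nbins_y = lcfg$nbins_y,
                      temperature = lcfg$temperature))
  invisible(grid)
}

#' Classify snapshots into unfolding states
#'
#' @param metrics data.frame or CSV path with the metric columns.
#' @param output_dir output directory.
#' @param x_metric \code{"ql"} or \code{"disnet"}; selects the matching
#'   region table.
#' @param regions optional region-table override
#'   (see \code{\link{state_regions}}).
#' @return data.frame time_ps, x, y, label, invisibly.
#' @export
run_classify <- function(metrics, output_dir, x_metric = "ql",
                         regions = NULL) {
  if (is.character(metrics)) metrics <- utils::read.csv(metrics)
  if (is.null(regions))
    regions <- state_regions(if (x_metric == "ql") "QL" else "Disnet")
  lab <- classify_state(metrics[[x_metric]], metrics$sascn, regions)
  out <- data.frame(time_ps = metrics$time_ps, x = metrics[[x_metric]],
                    y = metrics$sascn, label = lab)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out, file.path(output_dir, "states.csv"), row.names = FALSE)
  occ <- region_occupancy(lab)
  write.csv(data.frame(label = names(occ), fraction = occ),
            file.path(output_dir, "occupancy.csv"), row.names = FALSE)
  write_manifest(output_dir, list(command = "classify",
                                  x_metric = x_metric))
  invisible(out)
}

#' Embed a network series by classical MDS
#'
#' @param scns list of \code{\link{scn}} objects (e.g. the \code{"scns"}
#'   attribute of \code{\link{analyze_trajectory}}).
#' @param times_ps frame times.
#' @param output_dir output directory.
#' @param k embedding dimension.
#' @param stride keep every \code{stride}-th network before embedding.
#' @return the \code{\link{classical_mds}} result, invisibly.
#' @export
run_mds <- function(scns, times_ps, output_dir, k = 3, stride = 1) {
  sel <- seq(1, length(scns), by = stride)
  d <- pairwise_disnet_matrix(scns[sel], times_ps[sel])
  emb <- classical_mds(d, k)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  co <- data.frame(time_ps = times_ps[sel], emb$coords)
  names(co) <- c("time_ps", paste0("mds", seq_len(k)))
  write.csv(co, file.path(output_dir, "mds_coords.csv"), row.names = FALSE)
  write.csv(data.frame(index = seq_along(emb$eigenvalues),
                       eigenvalue = emb$eigenvalues),
            file.path(output_dir, "mds_eigenvalues.csv"), row.names = FALSE)
  write_manifest(output_dir, list(command = "mds", k = k, stride = stride,
                                  positive_mass_fraction =
                                    emb$positive_mass_fraction))
  invisible(emb)
}

#' Write a synthetic fixture trajectory
#'
#' Generates an interlocked ring core, dilates it into an unfolding series
#' and writes the frames as a multi-model PDB plus a matching core config
#' (YAML when available, TSV otherwise).
#'
#' @param output_dir output directory.
#' @param n_residues,packing_gap,n_frames,max_expansion,seed,n_side
#'   generator parameters (see \code{\link{make_interlocked_core}},
#'   \code{\link{make_unfolding_series}}). The atom radius stays at the
#'   generator default (standard carbon) so the written PDB scores
#'   identically after radii are reassigned from the default table.
#' @return path of the written PDB, invisibly.
#' @export
run_simulate <- function(output_dir, n_residues = 6, packing_gap = 0.3,
                         n_frames = 8, max_expansion = 1.6, seed = 1,
                         n_side = 5) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ic <- make_interlocked_core(n_residues, packing_gap, seed = seed,
                              n_side = n_side)
  frames <- make_unfolding_series(ic$snapshot, n_frames = n_frames,
                                  max_expansion = max_expansion,
                                  seed = seed)
  pdb <- file.path(output_dir, "synthetic_trajectory.pdb")
  # multi-model PDB written frame by frame
  con <- file(pdb, "w")
  for (i in seq_along(frames)) {
    tmp <- tempfile(fileext = ".pdb")
    write_snapshot(frames[[i]], tmp)
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(grep("^(ATOM|HETATM|TER)",
                    readLines(tmp, warn = FALSE), value = TRUE), con)
    writeLines("ENDMDL", con)
    unlink(tmp)
  }
  close(con)
  core_df <- data.frame(chain = ic$core$chain, res_seq = ic$core$res_seq,
                        res_name = ic$core$res_name,
                        sse_class = ic$core$sse_class)
  write.table(core_df, file.path(output_dir, "core.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(output_dir,
                 list(command = "simulate", n_residues = n_residues,
                      packing_gap = packing_gap, n_frames = n_frames,
                      max_expansion = max_expansion, seed = seed))
  invisible(pdb)
}
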