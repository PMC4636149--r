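GAS_CONSTANT_KCAL <- 1.9872e-3  # kcal / (mol K)

#' Landscape configuration
#'
#' @param nbins_x,nbins_y number of equal-width bins per axis (20 x 20).
#' @param temperature simulation temperature in kelvin.
#' @param gas_constant in energy units per mol kelvin; the default yields
#'   free energies in kcal/mol.
#' @param x_range,y_range axis ranges; NULL takes the data range.
#' @return object of class \code{landscape_config}.
#' @export
landscape_config <- function(nbins_x = 20, nbins_y = 20, temperature = 310,
                             gas_constant = GAS_CONSTANT_KCAL,
                             x_range = NULL, y_range = NULL) {
  stopifnot(nbins_x >= 2, nbins_y >= 2, temperature > 0, gas_constant > 0)
  structure(list(nbins_x = nbins_x, nbins_y = nbins_y,
                 temperature = temperature, gas_constant = gas_constant,
                 x_range = x_range, y_range = y_range),
            class = "landscape_config")
}

bin_index <- function(v, lo, hi, nbins) {
  # left-closed right-open, last bin closed; out-of-range -> NA
  idx <- floor((v - lo) / (hi - lo) * nbins) + 1
  idx[v == hi] <- nbins
  idx[v < lo | v > hi] <- NA
  as.integer(idx)
}

#' 2-D histogram of snapshot order parameters
#'
#' Equal-width bins, left-closed right-open except the final bin which is
#' closed. Points outside the configured ranges are dropped with a message
#' recording the count.
#'
#' @param x,y order-parameter values per snapshot (equal length).
#' @param cfg a \code{\link{landscape_config}}.
#' @return matrix of counts (rows = x bins), with the bin edges attached as
#'   attributes \code{xedges}, \code{yedges}.
#' @export
bin_counts <- function(x, y, cfg = landscape_config()) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (!length(x)) stop("no points to bin")
  xr <- if (is.null(cfg$x_range)) range(x) else cfg$x_range
  yr <- if (is.null(cfg$y_range)) range(y) else cfg$y_range
  if (diff(xr) <= 0 || diff(yr) <= 0)
    stop("degenerate axis range (min = max)")
  ix <- bin_index(x, xr[1], xr[2], cfg$nbins_x)
  iy <- bin_index(y, yr[1], yr[2], cfg$nbins_y)
  drop <- is.na(ix) | is.na(iy)
  if (any(drop)) message(sum(drop), " point(s) outside range dropped")
  counts <- matrix(0L, cfg$nbins_x, cfg$nbins_y)
  for (k in which(!drop)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  attr(counts, "xedges") <- seq(xr[1], xr[2], length.out = cfg$nbins_x + 1)
  attr(counts, "yedges") <- seq(yr[1], yr[2], length.out = cfg$nbins_y + 1)
  counts
}

#' Helmholtz free-energy surface from a count grid
#'
#' Bin probabilities P_i = N_i / N_tot; the reference cell is the
#' maximum-count cell (ties broken by lowest flat index). Relative free
#' energies are dA_i = -RT ln(P_i / P_ref), zero at the reference and
#' non-negative elsewhere; absolute values add
#' A_ref = -RT ln(N_ref / N_tot). Zero-count cells are masked (NA), not
#' assigned infinite energies.
#'
#' @param counts count grid from \code{\link{bin_counts}}.
#' @param cfg a \code{\link{landscape_config}} (temperature and gas
#'   constant).
#' @return object of class \code{free_energy_grid} with elements
#'   \code{counts, probabilities, deltaA, A_abs, ref_cell, xedges, yedges}.
#' @export
free_energy <- function(counts, cfg = landscape_config()) {
  ntot <- sum(counts)
  if (ntot <= 0) stop("all-zero count grid")
  p <- counts / ntot
  ref <- which.max(counts)  # lowest flat index on ties
  rt <- cfg$gas_constant * cfg$temperature
  da <- -rt * log(p / p[ref])
  da[counts == 0] <- NA
  a_ref <- -rt * log(counts[ref] / ntot)
  structure(list(counts = counts, probabilities = p, deltaA = da,
                 A_abs = a_ref + da, ref_cell = ref,
                 temperature = cfg$temperature,
                 gas_constant = cfg$gas_constant,
                 xedges = attr(counts, "xedges"),
                 yedges = attr(counts, "yedges")),
            class = "free_energy_grid")
}

#' @export
print.free_energy_grid <- function(x, ...) {
  cat(sprintf("free_energy_grid: %d x %d bins, %d snapshots, T = %g K\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$temperature))
  cat(sprintf("  reference cell %d (count %d), max dA = %.3f\n",
              x$ref_cell, x$counts[x$ref_cell], max(x$deltaA, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.free_energy_grid <- function(x, xlab = "x", ylab = "y", ...) {
  xm <- (head(x$xedges, -1) + tail(x$xedges, -1)) / 2
  ym <- (head(x$yedges, -1) + tail(x$yedges, -1)) / 2
  graphics::filled.contour(xm, ym, x$deltaA, xlab = xlab, ylab = ylab,
                           color.palette = grDevices::terrain.colors, ...)
  invisible(x)
}

#' Conformational state regions in order-parameter space
#'
#' Rectangular regions marking Native-like, dry molten globule (DMG), wet
#' molten globule (WMG), transition-state (TS) and Unfolded ensembles in
#' (Q_L, SASCN) or (Disnet, SASCN) space. Bounds are open intervals except
#' where a bound coincides with the metric's attainable extreme (Q_L = 1,
#' SASCN = 0), which is closed so that an exactly native snapshot is
#' Native. Regions overlap by design; classification applies them in
#' decreasing precedence Unfolded > TS > WMG > DMG > Native.
#'
#' @param space \code{"QL"} for Q_L-SASCN regions, \code{"Disnet"} for
#'   Disnet-SASCN regions.
#' @return data.frame with columns \code{name, xmin, xmax, ymin, ymax,
#'   closed_xmax, closed_ymin, precedence}.
#' @export
state_regions <- function(space = c("QL", "Disnet")) {
  space <- match.arg(space)
  if (space == "QL") {
    data.frame(
      name = c("Unfolded", "TS", "WMG", "DMG", "Native"),
      xmin = c(-Inf, 0.2, 0.4, 0.5, 0.5),
      xmax = c(0.10, 0.4, 0.6, 0.7, 1.0),
      ymin = c(25, 7.5, 5, 1, 0),
      ymax = c(Inf, 20, 10, 5, 5),
      closed_xmax = c(FALSE, FALSE, FALSE, FALSE, TRUE),  # Q_L = 1 attainable
      closed_ymin = c(FALSE, FALSE, FALSE, FALSE, TRUE),  # SASCN = 0
      precedence = 1:5, stringsAsFactors = FALSE)
  } else {
    data.frame(
      name = c("Unfolded", "TS", "WMG", "DMG", "Native"),
      xmin = c(0.9, 0.8, 0.7, 0.5, 0.3),
      xmax = c(Inf, 0.9, 0.9, 0.7, 0.5),
      ymin = c(25, 7.5, 5, 1, 0),
      ymax = c(Inf, 20, 10, 5, 5),
      closed_xmax = FALSE,
      closed_ymin = c(FALSE, FALSE, FALSE, FALSE, TRUE),
      precedence = 1:5, stringsAsFactors = FALSE)
  }
}

#' Classify snapshots into unfolding states
#'
#' Each (x, y) point is tested against the regions in increasing
#' \code{precedence} rank (Unfolded first); the first region containing the
#' point wins, and points in no region are \code{"unassigned"}.
#'
#' @param x order-parameter values (Q_L or Disnet).
#' @param y SASCN values.
#' @param regions region table from \code{\link{state_regions}} (or a
#'   user-supplied override with the same columns).
#' @return character vector of state labels.
#' @export
classify_state <- function(x, y, regions = state_regions("QL")) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  regions <- regions[order(regions$precedence), , drop = FALSE]
  out <- rep("unassigned", length(x))
  todo <- rep(TRUE, length(x))
  for (r in seq_len(nrow(regions))) {
    rr <- regions[r, ]
    in_x <- x > rr$xmin &
      (if (isTRUE(rr$closed_xmax)) x <= rr$xmax else x < rr$xmax)
    in_y <- (if (isTRUE(rr$closed_ymin)) y >= rr$ymin else y > rr$ymin) &
      y < rr$ymax
    hit <- todo & in_x & in_y
    out[hit] <- rr$name
    todo <- todo & !hit
  }
  out
}

#' Occupancy fractions of state labels
#'
#' @param labels character vector of state labels (including
#'   \code{"unassigned"}).
#' @return named numeric vector of fractions summing to 1.
#' @export
region_occupancy <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  tab <- table(labels)
  setNames(as.numeric(tab) / length(labels), names(tab))
}

#' Write a free-energy landscape as CSV
#'
#' Columns: x_edge_low, y_edge_low, count, probability, deltaA (empty for
#' masked zero-count cells).
#'
#' @param grid a \code{\link{free_energy_grid}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(grid, path) {
  nx <- nrow(grid$counts); ny <- ncol(grid$counts)
  out <- data.frame(
    x_edge_low = rep(head(grid$xedges, -1), times = ny),
    y_edge_low = rep(head(grid$yedges, -1), each = nx),
    count = as.vector(grid$counts),
    probability = as.vector(grid$probabilities),
    deltaA = as.vector(grid$deltaA))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
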