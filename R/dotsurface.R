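## Deterministic Fibonacci-spiral unit sphere sampling. Reproducible without
## a seed and near-uniform in area, so dot count x (1/density) estimates
## surface area.
fibonacci_sphere <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    if (n < 1) n <- 1
    key <- as.character(n)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    i <- seq_len(n) - 0.5
    phi <- pi * (sqrt(5) - 1)        # golden angle
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z * z))
    th <- phi * (seq_len(n) - 1)
    out <- cbind(x = r * cos(th), y = r * sin(th), z = z)
    cache[[key]] <- out
    out
  }
})

OCCLUSION_TOL <- 1e-6  # a dot exactly on another sphere's surface survives

#' Construct a dot surface directly from dot points
#'
#' Low-level constructor used by the synthetic generators and the surface
#' sampler. Each dot carries a position, an outward unit normal (direction
#' cosines), the owning atom and residue, and a side-chain flag.
#'
#' @param dots data.frame with columns \code{x,y,z,nx,ny,nz,atom,residue,
#'   is_sidechain}.
#' @param density sampling density in dots per square angstrom.
#' @return object of class \code{dot_surface}.
#' @export
dot_surface <- function(dots, density = 10) {
  need <- c("x", "y", "z", "nx", "ny", "nz", "atom", "residue",
            "is_sidechain")
  miss <- setdiff(need, names(dots))
  if (length(miss)) stop("dot table lacks columns: ",
                         paste(miss, collapse = ", "))
  nn <- sqrt(dots$nx^2 + dots$ny^2 + dots$nz^2)
  if (any(abs(nn - 1) > 1e-6)) stop("dot normals must be unit vectors")
  if (density <= 0) stop("density must be positive")
  structure(list(dots = dots, density = density,
                 area_per_dot = 1 / density),
            class = "dot_surface")
}

#' @export
print.dot_surface <- function(x, ...) {
  cat(sprintf("dot_surface: %d dots (%.0f/A^2), %d residues, %d side-chain dots\n",
              nrow(x$dots), x$density, length(unique(x$dots$residue)),
              sum(x$dots$is_sidechain)))
  invisible(x)
}

#' Generate the sampled van der Waals dot surface of a snapshot
#'
#' Every protein atom sphere is sampled at \code{density} dots per square
#' angstrom on a deterministic Fibonacci spiral; normals point radially
#' outward from the owner atom. Dots falling strictly inside any other
#' atom's sphere (tolerance 1e-6 angstrom) are removed, leaving the exposed
#' van der Waals surface of the whole polypeptide chain. Waters never
#' contribute to, nor occlude, the surface.
#'
#' @param snap a \code{\link{snapshot}} with radii assigned
#'   (\code{\link{assign_radii}}).
#' @param density dots per square angstrom, in [1, 100]; 10 by default.
#' @return a \code{\link{dot_surface}}.
#' @export
generate_dot_surface <- function(snap, density = 10) {
  stopifnot(inherits(snap, "snapshot"))
  if (density < 1 || density > 100) stop("density must lie in [1, 100]")
  a <- snap$atoms
  if (anyNA(a$vdw_radius)) stop("unassigned radii; call assign_radii() first")
  centers <- as.matrix(a[, c("x", "y", "z")])
  r <- a$vdw_radius
  n <- nrow(a)

  nb <- neighbor_pairs(centers, r + max(r))  # superset of occluding pairs
  dd <- sqrt(rowSums((centers[nb[, 1], , drop = FALSE] -
                      centers[nb[, 2], , drop = FALSE])^2))
  if (any(dd < 1e-9)) {
    i <- which(dd < 1e-9)[1]
    stop("degenerate geometry: atoms ", nb[i, 1], " and ", nb[i, 2],
         " have identical centers")
  }
  occl <- nb[dd < r[nb[, 1]] + r[nb[, 2]], , drop = FALSE]
  occ_list <- split(occl[, 2], factor(occl[, 1], levels = seq_len(n)))

  res <- residue_key(a$chain, a$res_seq)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ndot <- max(1L, as.integer(round(4 * pi * r[i]^2 * density)))
    u <- fibonacci_sphere(ndot)
    p <- sweep(u * r[i], 2, centers[i, ], "+")
    occ <- occ_list[[i]]
    keep <- dots_outside_spheres(p, centers[occ, , drop = FALSE], r[occ],
                                 tol = OCCLUSION_TOL)
    if (!any(keep)) next
    out[[i]] <- data.frame(x = p[keep, 1], y = p[keep, 2], z = p[keep, 3],
                           nx = u[keep, 1], ny = u[keep, 2], nz = u[keep, 3],
                           atom = i, residue = res[i],
                           is_sidechain = !a$is_backbone[i])
  }
  dots <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(dots)) stop("all dots occluded; degenerate input")
  rownames(dots) <- NULL
  dot_surface(dots, density)
}

#' Side-chain dots of one residue
#'
#' @param surface a \code{\link{dot_surface}}.
#' @param residue length-2 vector \code{c(chain, res_seq)} or a residue key.
#' @return data.frame of dot rows (possibly empty, e.g. glycine).
#' @export
sidechain_dots <- function(surface, residue) {
  stopifnot(inherits(surface, "dot_surface"))
  key <- if (length(residue) == 2) residue_key(residue[1], residue[2])
         else as.character(residue)
  if (!key %in% surface$dots$residue) stop("residue not on surface: ", key)
  surface$dots[surface$dots$residue == key & surface$dots$is_sidechain, ,
               drop = FALSE]
}

#' Write a dot surface dump
#'
#' One line per dot: \code{x y z dl dm dn chain resseq atom sidechain_flag},
#' for debugging and cross-checks against other surface generators.
#'
#' @param surface a \code{\link{dot_surface}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dot_surface <- function(surface, path) {
  d <- surface$dots
  ck <- do.call(rbind, strsplit(d$residue, ":", fixed = TRUE))
  out <- data.frame(d$x, d$y, d$z, d$nx, d$ny, d$nz, ck[, 1], ck[, 2],
                    d$atom, as.integer(d$is_sidechain))
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
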