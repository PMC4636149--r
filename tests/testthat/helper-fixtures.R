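# Shared fixtures, computed lazily and cached so each expensive geometry is
# built once per test run.

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    hit <- cache[[name]]
    if (!is.null(hit)) return(hit)
    val <- switch(name,
      ring = make_interlocked_core(6, 0.3),
      ring_net = build_scn(fx("ring")$snapshot, fx("ring")$core),
      ring_loose = make_interlocked_core(6, 5),
      series = make_unfolding_series(fx("ring")$snapshot, n_frames = 6,
                                     max_expansion = 1.6),
      series_nets = lapply(fx("series"), build_scn, core = fx("ring")$core),
      series_sasc = vapply(fx("series"), sasc, numeric(1),
                           core = fx("ring")$core),
      stop("unknown fixture: ", name))
    cache[[name]] <- val
    val
  }
})

# a tiny protonated peptide-like snapshot: ALA-GLY-PHE with backbone,
# side-chain and hydrogen atoms at made-up but finite coordinates
make_tripeptide <- function() {
  at <- function(res_seq, res_name, atom_name, element, x, y, z)
    data.frame(chain = "A", res_seq = res_seq, res_name = res_name,
               atom_name = atom_name, element = element,
               x = x, y = y, z = z, stringsAsFactors = FALSE)
  atoms <- rbind(
    at(1, "ALA", "N", "N", 0.0, 0.0, 0.0),
    at(1, "ALA", "CA", "C", 1.4, 0.0, 0.0),
    at(1, "ALA", "C", "C", 2.1, 1.3, 0.0),
    at(1, "ALA", "O", "O", 1.5, 2.4, 0.0),
    at(1, "ALA", "CB", "C", 2.2, -1.2, 0.6),
    at(1, "ALA", "H", "H", -0.5, -0.8, 0.3),
    at(1, "ALA", "HA", "H", 1.6, 0.3, -1.0),
    at(1, "ALA", "HB1", "H", 3.2, -1.0, 0.9),
    at(2, "GLY", "N", "N", 3.4, 1.4, 0.1),
    at(2, "GLY", "CA", "C", 4.2, 2.6, 0.1),
    at(2, "GLY", "C", "C", 5.6, 2.4, 0.6),
    at(2, "GLY", "O", "O", 6.1, 1.3, 0.7),
    at(2, "GLY", "H", "H", 3.8, 0.6, -0.1),
    at(3, "PHE", "N", "N", 6.3, 3.5, 0.9),
    at(3, "PHE", "CA", "C", 7.7, 3.5, 1.4),
    at(3, "PHE", "C", "C", 8.5, 4.7, 0.9),
    at(3, "PHE", "O", "O", 8.0, 5.8, 0.8),
    at(3, "PHE", "CB", "C", 7.8, 3.5, 2.9),
    at(3, "PHE", "CG", "C", 9.2, 3.4, 3.5),
    at(3, "PHE", "CD1", "C", 9.9, 2.2, 3.5),
    at(3, "PHE", "CD2", "C", 9.8, 4.5, 4.1),
    at(3, "PHE", "CE1", "C", 11.2, 2.1, 4.1),
    at(3, "PHE", "CE2", "C", 11.1, 4.4, 4.7),
    at(3, "PHE", "CZ", "C", 11.8, 3.2, 4.7),
    at(3, "PHE", "H", "H", 5.9, 4.4, 0.9),
    at(3, "PHE", "HB2", "H", 7.3, 4.4, 3.3))
  snapshot(atoms)
}

# brute-force nearest-neighbor scorer used as the independent oracle for
# score_pair: full distance matrix, no spatial prefilter
naive_score_pair <- function(surface, akey, bkey, cfg = scoring_config()) {
  d <- surface$dots
  qa <- d[d$residue == akey & d$is_sidechain, , drop = FALSE]
  tg <- d[d$residue != akey, , drop = FALSE]
  n_a <- nrow(qa)
  s_vals <- numeric(0)
  n_ab <- 0L
  for (i in seq_len(n_a)) {
    dd <- sqrt((tg$x - qa$x[i])^2 + (tg$y - qa$y[i])^2 + (tg$z - qa$z[i])^2)
    j <- which.min(dd)
    if (dd[j] > cfg$neighbor_cutoff) next
    if (tg$residue[j] == bkey && tg$is_sidechain[j]) {
      n_ab <- n_ab + 1L
      ndot <- qa$nx[i] * tg$nx[j] + qa$ny[i] * tg$ny[j] +
        qa$nz[i] * tg$nz[j]
      s_vals <- c(s_vals, -ndot * exp(-cfg$w * dd[j]^2))
    }
  }
  list(sm = if (n_ab > 0) median(s_vals) else 0, ov = n_ab / n_a)
}
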