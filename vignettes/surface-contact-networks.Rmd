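---
title: "Surface contact networks and their unfolding metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface contact networks and their unfolding metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The model

Tightly packed side chains in a protein core behave like the pieces of a
three-dimensional jigsaw puzzle: each buried side chain presents a surface
patch that is geometrically complementary to the patches of its neighbors.
`scnet` represents this packing as a **surface contact network (SCN)**.
Nodes are the side chains of a user-defined set of core residues; an edge
("link") between residues A and B asserts that their surfaces are mutually
locked.

The surface is the van der Waals surface of the whole polypeptide chain,
hydrogens included, sampled as discrete dots (10 dots/Å² by default). Each
dot carries its position and the direction cosines of its outward normal.
For every side-chain dot *a* of residue A, the nearest dot *b* within
3.5 Å among the dots of all *other* residues (side chain and backbone) is
located, and the pair is scored

$$ S_{ab} = -(\mathbf{n}_a \cdot \mathbf{n}_b)\, e^{-w\, d_{ab}^2}, \qquad w = 0.5\ \text{Å}^{-2}. $$

The sign convention inverts one normal, so ideally apposed anti-parallel
surfaces at zero separation score +1, the maximum. Dots whose nearest
neighbor lies on B's side chain form the set $N_{AB}$; the **surface
complementarity** $S_m^{A \to B}$ is the median of their scores, and the
**overlap** $O_v^{A \to B} = N_{AB}/N_A$ is the fraction of A's side-chain
dots engaged with B. Both quantities are directional. Two residues are in
contact when all four of $S_m^{A\to B}, S_m^{B \to A} \ge 0.40$ and
$O_v^{A\to B}, O_v^{B\to A} \ge 0.08$ hold simultaneously; the thresholds
are the published calibration at which inter-residue geometries become
strongly constrained, and they are configurable (`scoring_config()`).

## Metrics over a trajectory

Given one SCN per trajectory snapshot (adjacency matrices $A_{ij}$ over N
core residues), the package provides:

* **Disnet** — the network distance: links present in exactly one of two
  networks, divided by $N(N-1)/2$. It is a true metric on fixed-node
  binary networks (the test suite verifies the axioms exhaustively on all
  3-node networks). A value of 0.4 means 40% of all possible links
  distinguish the two networks.
* **Q and Q_L** — fractions of native distance contacts (side-chain heavy
  atoms within 3.8 Å in the reference structure) and of native SCN links
  retained by a snapshot.
* **Persistence** — per 2-ns epoch (200 snapshots at 10 ps), $P_{ij}$ is
  the fraction of snapshots containing link $ij$; the locked-link matrix
  binarizes it at $P_{ij} \ge 0.40$ (inclusive).
* **persf** — Disnet between an epoch's locked-link matrix and a baseline
  locked-link matrix (by convention, the whole native-temperature run
  pooled and binarized).
* **dlf** — the mean Disnet over all unordered snapshot pairs inside an
  epoch: a network-fluctuation measure with expectation $2p(1-p)$ per link
  under independent Bernoulli links.
* **SASC / SASCN** — summed side-chain solvent accessibility of the core
  (Shrake–Rupley-style dot sampling, probe 1.4 Å), normalized by the mean
  SASC of the baseline ensemble, whose own mean SASCN is exactly 1 by
  construction.
* **water counts** — distinct waters with an oxygen within 5.0 Å of any
  core side-chain atom.
* **SSC** — the fraction of natively helical/strand residues whose
  externally assigned label (STRIDE-style files, parsed not computed)
  still matches, averaged per epoch.
* Conventional comparators: Cα RMSD after least-squares superposition,
  per-residue RMSF, and Pearson cross-correlation between metric series.

Presentation time series use a 45-point adjacent-averaging smoother. Near
the series edges the window shrinks symmetrically — our choice, since no
edge rule is standard — and smoothing is never applied before epoch
statistics are computed.

## Free-energy landscapes and state classification

Snapshots are histogrammed on a 20×20 grid over two order parameters
(Q_L–SASCN or Disnet–SASCN; bins left-closed, right-open, last bin
closed). With bin probabilities $P_i$ and the maximum-count cell as
reference (ties: lowest flat index),

$$ \Delta A_i = -RT \ln (P_i / P_\mathrm{ref}), \qquad
   A_\mathrm{ref} = -RT \ln (N_\mathrm{ref}/N_\mathrm{tot}), $$

with $R$ defaulting to kcal/(mol·K). Zero-count cells are masked rather
than assigned infinite energies.

Conformational states are rectangular regions in order-parameter space:
Native (0.5 < Q_L ≤ 1.0, 0 ≤ SASCN < 5), DMG-like (0.5–0.7 × 1–5),
WMG-like (0.4–0.6 × 5–10), transition state (0.2–0.4 × 7.5–20) and
Unfolded (Q_L < 0.1, SASCN > 25), with analogous Disnet-space boxes.
Three design choices were genuinely open and are resolved as follows:

* **Precedence.** The printed regions overlap (every DMG point is also in
  the Native box; the Disnet-space TS and WMG boxes share 0.8–0.9×7.5–10).
  Classification tests regions in the order Unfolded > TS > WMG > DMG >
  Native, on the rationale that the narrative of unfolding moves outward:
  the more-unfolded label wins where boxes overlap. The full region table
  is an argument, so users can override it.
* **Boundary closure.** Bounds are open as printed, except where a bound
  coincides with a metric's attainable extreme: Q_L = 1.0 and SASCN = 0
  are closed into the Native box. Without this, a snapshot identical to
  the reference (Q_L exactly 1) would be unclassifiable, which contradicts
  the intent of a "Native" region.
* **Out-of-range points** in the histogram are dropped with a logged
  count, not clipped; the classifier itself has no range limit.

## Classical MDS of network distances

The matrix of pairwise Disnet distances between snapshots is embedded by
classical multidimensional scaling: square the distances, double-center
($B = -\tfrac12 J P^{(2)} J$, $J = I - \mathbf{1}\mathbf{1}^\top/n$),
eigendecompose, and scale the top three eigenvectors by the square roots
of their eigenvalues. Disnet matrices need not be Euclidean, so negative
eigenvalues can occur; they are never used, and the reported
`positive_mass_fraction` (kept eigenvalue mass over total absolute mass)
makes the distortion visible. If fewer than k eigenvalues are positive the
embedding is zero-padded with a warning. Tests compare embedded distance
matrices, never raw coordinates, since the embedding is unique only up to
orthogonal transformation.

## What the synthetic generators emulate

All tests run without molecular dynamics, on generators whose statistical
and geometric properties are known exactly:

* `make_dot_patch_pair()` builds two flat dot lattices with exactly
  anti-parallel normals — the idealized geometry in which the scoring
  ceiling $S_m = O_v = 1.00$ and the closed form $S_m = e^{-w\,\mathrm{gap}^2}$
  are attained exactly.
* `make_patch_pair()` builds the same interface from actual atoms: a
  side-chain lattice framed and backed by backbone atoms, the way
  main-chain surface bounds a real side-chain patch. At 10 dots/Å² the
  nearest partner dot sits ~0.15 Å off ideal apposition, biasing the
  median score a few percent below the closed form; tests therefore allow
  a documented sampling tolerance (±0.06) here, while exact assertions
  live on the dot-lattice construct.
* `make_interlocked_core()` arranges n such residues on a ring, each pair
  of neighbors apposed across a controllable packing gap, so the expected
  network is the n-cycle when packed (gap ≤ 0.5 Å) and empty beyond the
  3.5 Å dot cutoff. Each residue carries one solvent-exposed hydrogen
  "knob" pointing out of the ring: it takes no part in scoring but gives
  the buried core a small positive accessibility, as in a real,
  imperfectly sealed hydrophobic core, so SASCN normalization is well
  defined. Plate sizes of 5×5 atoms at 0.5 Å spacing and standard carbon
  radii keep all four contact quantities comfortably above threshold
  (minimum O_v ≈ 0.10–0.18 across ring sizes) while a written-and-reread
  PDB reproduces the same network from the default radii table.
* `simulate_link_trajectory()` draws each link independently as
  Bernoulli($p_{ij}$) per snapshot, so persistence estimates have exact
  binomial errors and dlf has expectation $2p(1-p)$.
* `make_unfolding_series()` dilates inter-residue centroid distances
  linearly while preserving intra-residue geometry: Q_L is non-increasing,
  SASC non-decreasing, and the state classification leaves the Native
  region and never returns from Unfolded.

What these fixtures do **not** emulate: force-field energetics, realistic
rotamer packing, cooperative breakage order among heterogeneous links,
or solvent structure. Passing tests certify the correctness of the
computational machinery — scoring, network construction, metric algebra,
normalizations, classification logic — not the biophysical realism of any
particular trajectory.

## Numerical choices

* Dot sampling uses a deterministic Fibonacci spiral per atom, so surfaces
  are reproducible without a seed; per-atom dot counts are
  $\mathrm{round}(4\pi r^2 \cdot \mathrm{density})$.
* Occlusion tolerance is 1e-6 Å and a dot exactly on another sphere's
  surface survives. Spatial prefilters (neighbor lists, bounding boxes,
  candidate-pair screens at `neighbor_cutoff + 2 max(radius)`) are exact:
  they can never change a result, only skip impossible pairs.
* Median with an even count averages the two central values; a residue
  with no contributing dots scores $S_m = 0$ (it cannot reach the 0.40
  threshold, so no contact) and is flagged.
* Native contacts use side-chain heavy atoms with a minimum-distance
  criterion at 3.8 Å inclusive — a heavy-atom-scale cutoff consistent
  with a study of side-chain packing; hydrogens are excluded.
* Epochs are contiguous non-overlapping windows after a configurable
  burn-in (defaults 2 ns span, 2 ns burn-in, 10 ps sampling); a trailing
  partial epoch is dropped.
* Unprotonated input is rejected unless explicitly allowed, since the
  surface method scores hydrogens; protonation itself is out of scope.
* Alternate locations keep the highest-occupancy conformer; residue
  numbering is taken verbatim from the PDB records.

## Problem sizes used by the test suite

The suite exercises full pipelines at deliberately small scale: ring cores
of 3–6 pseudo-residues (≈300–1200 atoms), trajectories of 2–8 frames,
Bernoulli ensembles of 200 snapshots over 45–435 links, and a 100-frame
jittered ensemble for the SASCN normalization identity. These sizes make
every property checkable in seconds while leaving the code paths identical
to production use on real trajectories.

## Known limitations

* The shipped cyclophilin core list contains the 21 residues named in the
  main analyses; the full 24-residue core must be supplied by the user to
  reproduce crystal-structure counts, and two table entries in the source
  material print conflicting residue names (85 PHE/ILE, 164 PHE/ILE), so
  residue identity should always be taken from the structure.
* Exact reproduction of the published native counts (35 contacts,
  25 links, 11/9/3 partition, 7.81 Å² core SASA) depends on the
  protonation protocol and radii table, neither fully specified; the
  `crystal_reference()` checker therefore compares within 10%.
* Only multi-model PDB trajectories are read natively; other formats must
  be converted upstream.
* No secondary-structure assignment, protonation engine, or MD engine is
  included, by design.
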