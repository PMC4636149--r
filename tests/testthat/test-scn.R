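test_that("coincident anti-parallel dot patches score the ceiling 1.00", {
  surf <- make_dot_patch_pair(gap = 0)
  ps <- score_pair(surf, c("A", 1), c("A", 2))
  expect_equal(ps$sm_ab, 1.0)
  expect_equal(ps$sm_ba, 1.0)
  expect_equal(ps$ov_ab, 1.0)
  expect_equal(ps$ov_ba, 1.0)
})

test_that("separated dot patches follow the closed form exp(-w d^2)", {
  ps <- score_pair(make_dot_patch_pair(gap = 1), c("A", 1), c("A", 2))
  expect_equal(ps$sm_ab, exp(-0.5), tolerance = 1e-12)
  expect_equal(ps$ov_ab, 1.0)
  # beyond the 3.5 A neighbor cutoff nothing contributes
  far <- score_pair(make_dot_patch_pair(gap = 4), c("A", 1), c("A", 2))
  expect_equal(far$sm_ab, 0)
  expect_equal(far$ov_ab, 0)
  expect_equal(far$n_ab, 0L)
})

test_that("perpendicular normals give zero complementarity", {
  g <- expand.grid(x = seq(-1, 1, 0.25), y = seq(-1, 1, 0.25))
  dots <- rbind(
    data.frame(x = g$x, y = g$y, z = 0, nx = 0, ny = 0, nz = 1,
               atom = 1L, residue = "A:1", is_sidechain = TRUE),
    data.frame(x = g$x, y = g$y, z = 0, nx = 1, ny = 0, nz = 0,
               atom = 2L, residue = "A:2", is_sidechain = TRUE))
  surf <- dot_surface(dots, density = 16)
  ps <- score_pair(surf, "A:1", "A:2")
  expect_equal(ps$sm_ab, 0)
  expect_equal(ps$ov_ab, 1.0)
})

test_that("score_pair agrees with the naive all-pairs oracle", {
  surf <- make_dot_patch_pair(gap = 0.8, n_side = 7)
  ps <- score_pair(surf, "A:1", "A:2")
  oracle <- naive_score_pair(surf, "A:1", "A:2")
  expect_equal(ps$sm_ab, oracle$sm, tolerance = 1e-12)
  expect_equal(ps$ov_ab, oracle$ov, tolerance = 1e-12)

  snap <- make_patch_pair(gap = 0.6, n_side = 5)
  asurf <- generate_dot_surface(snap, density = 10)
  ps2 <- score_pair(asurf, "A:1", "A:2")
  oracle2 <- naive_score_pair(asurf, "A:1", "A:2")
  expect_equal(ps2$sm_ab, oracle2$sm, tolerance = 1e-12)
  expect_equal(ps2$ov_ab, oracle2$ov, tolerance = 1e-12)
})

test_that("a residue without side-chain dots is flagged, not an error", {
  snap <- assign_radii(make_tripeptide())
  surf <- generate_dot_surface(snap, density = 10)
  ps <- score_pair(surf, c("A", 2), c("A", 3))  # glycine
  expect_true(ps$flagged)
  expect_equal(ps$sm_ab, 0)
  expect_equal(ps$ov_ab, 0)
})

test_that("tightly packed ring cores form the cycle network", {
  net <- fx("ring_net")
  expect_s3_class(net, "scn")
  links <- scn_links(net)
  expect_length(links, 6)
  expect_setequal(links, c("A:1|A:2", "A:2|A:3", "A:3|A:4",
                           "A:4|A:5", "A:5|A:6", "A:1|A:6"))
  # adjacency is symmetric binary with zero diagonal
  m <- net$adjacency
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
})

test_that("well-separated residues give an empty network", {
  loose <- fx("ring_loose")
  net <- build_scn(loose$snapshot, loose$core)
  expect_length(scn_links(net), 0)
})

test_that("raising a threshold never adds an edge", {
  net <- fx("ring_net")
  e <- net$edges
  base <- e$linked
  for (sm_thr in c(0.5, 0.8, 0.95)) {
    harder <- e$sm_ab >= sm_thr & e$sm_ba >= sm_thr &
      e$ov_ab >= 0.08 & e$ov_ba >= 0.08
    expect_true(all(!harder | base))
  }
  for (ov_thr in c(0.15, 0.3, 0.6)) {
    harder <- e$sm_ab >= 0.40 & e$sm_ba >= 0.40 &
      e$ov_ab >= ov_thr & e$ov_ba >= ov_thr
    expect_true(all(!harder | base))
  }
})

test_that("network construction is invariant under core permutation", {
  ring <- fx("ring")
  perm <- c(4, 2, 6, 1, 3, 5)
  core_p <- core_definition("A", ring$core$res_seq[perm],
                            ring$core$res_name[perm],
                            ring$core$sse_class[perm])
  net_p <- build_scn(ring$snapshot, core_p)
  expect_setequal(scn_links(net_p), scn_links(fx("ring_net")))
})

test_that("surface complementarity decays monotonically with the gap", {
  gaps <- seq(0, 3.5, by = 0.25)
  sm <- vapply(gaps, function(g) {
    surf <- generate_dot_surface(make_patch_pair(gap = g, n_side = 5),
                                 density = 10)
    score_pair(surf, "A:1", "A:2")$sm_ab
  }, numeric(1))
  expect_true(all(diff(sm) <= 1e-9))
  expect_gt(sm[1], 0.9)
  expect_equal(sm[length(gaps)], 0)
})

test_that("native contacts follow the 3.8 A side-chain heavy-atom rule", {
  mk <- function(d) {
    atoms <- rbind(
      data.frame(chain = "A", res_seq = 1, res_name = "ALA",
                 atom_name = "CB", element = "C", x = 0, y = 0, z = 0),
      data.frame(chain = "A", res_seq = 1, res_name = "ALA",
                 atom_name = "HB1", element = "H", x = d / 2, y = 0, z = 0),
      data.frame(chain = "A", res_seq = 2, res_name = "ALA",
                 atom_name = "CB", element = "C", x = d, y = 0, z = 0))
    snapshot(atoms)
  }
  core <- core_definition("A", 1:2)
  # hydrogens are excluded: the heavy-heavy distance decides
  expect_length(native_contacts(mk(3.9), core), 0)
  expect_equal(native_contacts(mk(3.7), core), "A:1|A:2")
  expect_equal(native_contacts(mk(3.8), core), "A:1|A:2")  # <= is inclusive
})

test_that("native contacts equal the brute-force double loop on a toy core", {
  set.seed(42)
  n <- 8
  rows <- do.call(rbind, lapply(seq_len(n), function(k) {
    m <- 3
    data.frame(chain = "A", res_seq = k, res_name = "VAL",
               atom_name = paste0("CG", seq_len(m)), element = "C",
               x = rnorm(m, k * 2.2), y = rnorm(m), z = rnorm(m))
  }))
  snap <- snapshot(rows)
  core <- core_definition("A", seq_len(n))
  got <- native_contacts(snap, core)
  # oracle: exhaustive O(N^2 atoms^2) scan
  want <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    xi <- atom_xyz(rows[rows$res_seq == i, ])
    xj <- atom_xyz(rows[rows$res_seq == j, ])
    dmin <- Inf
    for (a in seq_len(nrow(xi))) for (b in seq_len(nrow(xj)))
      dmin <- min(dmin, sqrt(sum((xi[a, ] - xj[b, ])^2)))
    if (dmin <= 3.8)
      want <- c(want, paste0("A:", i, "|A:", j))
  }
  expect_setequal(got, want)
})

test_that("link partition respects helix classes with H1 precedence", {
  adj <- matrix(0, 4, 4,
                dimnames = list(c("A:1", "A:2", "A:3", "A:4"),
                                c("A:1", "A:2", "A:3", "A:4")))
  adj["A:1", "A:2"] <- adj["A:2", "A:1"] <- 1   # H1 - strand
  adj["A:2", "A:3"] <- adj["A:3", "A:2"] <- 1   # strand - H2
  adj["A:3", "A:4"] <- adj["A:4", "A:3"] <- 1   # H2 - H1 (cross)
  adj["A:2", "A:4"] <- adj["A:4", "A:2"] <- 1   # strand - H1
  net <- scn(adj)
  core <- core_definition("A", 1:4, sse_class = c("H1", "strand", "H2", "H1"))
  expect_warning(part <- partition_links(net, core), "H1-H2")
  expect_equal(part[["A:1|A:2"]], "S2")
  expect_equal(part[["A:2|A:3"]], "S3")
  expect_equal(part[["A:3|A:4"]], "S2")   # cross link, H1 precedence
  expect_equal(part[["A:2|A:4"]], "S2")

  # no helix nodes: everything is S1; same-helix pairs are intra-helix
  core_flat <- core_definition("A", 1:4, sse_class = "loop")
  expect_true(all(partition_links(net, core_flat) == "S1"))
  core_h <- core_definition("A", 1:4, sse_class = c("H1", "H1", "H2", "H2"))
  part_h <- suppressWarnings(partition_links(net, core_h))
  expect_equal(part_h[["A:1|A:2"]], "intra-helix")
  expect_equal(part_h[["A:3|A:4"]], "intra-helix")
})

test_that("edge lists and adjacency matrices are written faithfully", {
  net <- fx("ring_net")
  core <- fx("ring")$core
  ef <- withr::local_tempfile(fileext = ".tsv")
  af <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, core, ef)
  write_adjacency(net, af)
  edges <- read.table(ef, header = TRUE, sep = "\t")
  expect_equal(sum(edges$linked), 6)
  expect_true(all(c("sm_ab", "ov_ba", "resnameA") %in% names(edges)))
  adj <- as.matrix(read.table(af, header = TRUE, row.names = 1,
                              check.names = FALSE))
  expect_equal(unname(adj), unname(net$adjacency))
  # the round-tripped matrix rebuilds the same network object
  expect_setequal(scn_links(scn(adj)), scn_links(net))
})
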