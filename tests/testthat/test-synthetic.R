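test_that("dot patch pairs realize the scoring ceiling and closed forms", {
  ps0 <- score_pair(make_dot_patch_pair(gap = 0), "A:1", "A:2")
  expect_equal(ps0$sm_ab, 1.0)
  expect_equal(ps0$ov_ab, 1.0)
  ps1 <- score_pair(make_dot_patch_pair(gap = 1), "A:1", "A:2")
  expect_equal(ps1$sm_ab, exp(-0.5), tolerance = 1e-12)
})

test_that("atom patch pairs track exp(-w gap^2) within sampling tolerance", {
  # at 10 dots/A^2 the nearest partner dot sits ~0.15 A off the ideal
  # apposition, biasing the median a few percent below the closed form
  for (g in c(0, 0.5, 1)) {
    surf <- generate_dot_surface(make_patch_pair(gap = g), density = 10)
    ps <- score_pair(surf, "A:1", "A:2")
    expect_equal(ps$sm_ab, exp(-0.5 * g^2), tolerance = 0.06)
    expect_gt(ps$ov_ab, 0.5)
  }
  far <- generate_dot_surface(make_patch_pair(gap = 4), density = 10)
  expect_equal(score_pair(far, "A:1", "A:2")$ov_ab, 0)
})

test_that("patch pairs are reproducible and jitter is seed-controlled", {
  a <- make_patch_pair(gap = 0.5, jitter = 0.05, seed = 7)
  b <- make_patch_pair(gap = 0.5, jitter = 0.05, seed = 7)
  c <- make_patch_pair(gap = 0.5, jitter = 0.05, seed = 8)
  expect_identical(a$atoms, b$atoms)
  expect_false(identical(a$atoms$x, c$atoms$x))
})

test_that("the interlocked ring yields the cycle graph only when packed", {
  links <- scn_links(fx("ring_net"))
  n <- nrow(fx("ring")$core)
  expect_length(links, n)
  deg <- table(unlist(strsplit(links, "|", fixed = TRUE)))
  expect_true(all(deg == 2))                       # a single n-cycle
  loose <- fx("ring_loose")
  expect_length(scn_links(build_scn(loose$snapshot, loose$core)), 0)
  # Q_L of the tight structure against itself as native
  expect_equal(q_fraction(links, links), 1.0)
  # reproducibility
  again <- make_interlocked_core(6, 0.3)
  expect_identical(again$snapshot$atoms, fx("ring")$snapshot$atoms)
})

test_that("link trajectories honor their Bernoulli spec", {
  n <- 6
  p <- matrix(0, n, n)
  p[1, 2] <- p[2, 1] <- 1
  p[3, 4] <- p[4, 3] <- 1
  traj <- simulate_link_trajectory(p, n_snapshots = 50, seed = 2)
  pm <- persistence_matrix(traj)
  expect_equal(pm[1, 2], 1.0)
  expect_equal(pm[3, 4], 1.0)
  expect_true(all(pm[p == 0] == 0))
  # reproducible by seed
  t2 <- simulate_link_trajectory(p, n_snapshots = 50, seed = 2)
  expect_identical(lapply(traj, `[[`, "adjacency"),
                   lapply(t2, `[[`, "adjacency"))
  expect_error(simulate_link_trajectory(matrix(2, 2, 2)), "symmetric")
})

test_that("the unfolding series dilates monotonically from the input frame", {
  series <- fx("series")
  ring <- fx("ring")
  expect_equal(series[[1]]$atoms, ring$snapshot$atoms, ignore_attr = TRUE)

  # intra-residue geometry is preserved while centroid distances scale
  a0 <- series[[1]]$atoms; a5 <- series[[6]]$atoms
  r1 <- a0$res_seq == 1
  expect_equal(as.numeric(dist(atom_xyz(a5[r1, ]))),
               as.numeric(dist(atom_xyz(a0[r1, ]))), tolerance = 1e-9)
  cent <- function(a, k) colMeans(atom_xyz(a[a$res_seq == k, ]))
  d0 <- sqrt(sum((cent(a0, 1) - cent(a0, 4))^2))
  d5 <- sqrt(sum((cent(a5, 1) - cent(a5, 4))^2))
  expect_equal(d5 / d0, 1.6, tolerance = 1e-9)

  # generators are bit-reproducible
  again <- make_unfolding_series(ring$snapshot, n_frames = 6,
                                 max_expansion = 1.6)
  expect_identical(lapply(again, `[[`, "atoms"),
                   lapply(series, `[[`, "atoms"))
})

test_that("unfolding degrades Q_L monotonically and exposes the core", {
  nets <- fx("series_nets")
  native <- scn_links(nets[[1]])
  ql <- vapply(nets, function(n) q_fraction(scn_links(n), native),
               numeric(1))
  expect_equal(ql[1], 1)
  expect_true(all(diff(ql) <= 1e-12))
  expect_lt(ql[length(ql)], 0.5)

  sas <- fx("series_sasc")
  expect_true(all(diff(sas) >= -1e-9))
  expect_gt(sas[1], 0)
  expect_gt(sas[length(sas)], sas[1])
})

test_that("the expanded pipeline traverses states from Native outward", {
  nets <- fx("series_nets")
  native <- scn_links(nets[[1]])
  ql <- vapply(nets, function(n) q_fraction(scn_links(n), native),
               numeric(1))
  sas <- fx("series_sasc")
  sn <- sascn(sas, sas[1])          # first-frame conditions as baseline
  labels <- classify_state(ql, sn, state_regions("QL"))
  expect_equal(labels[1], "Native")
  expect_false(labels[length(labels)] == "Native")
  # a monotone expansion never returns from the Unfolded region
  after_unfolded <- cumsum(labels == "Unfolded") > 0
  expect_true(all(labels[after_unfolded] == "Unfolded" |
                    !any(labels == "Unfolded")))
  # Disnet-based classification agrees on the native end
  dn <- vapply(nets, function(n) disnet(n, nets[[1]]), numeric(1))
  expect_equal(dn[1], 0)
  expect_true(all(diff(dn) >= -1e-12))
})

test_that("waters are sprinkled reproducibly when requested", {
  ring <- fx("ring")
  fr <- make_unfolding_series(ring$snapshot, n_frames = 3,
                              max_expansion = 1.2, n_waters = 25, seed = 5)
  expect_true(all(vapply(fr, function(s) nrow(s$waters), 1L) == 25))
  fr2 <- make_unfolding_series(ring$snapshot, n_frames = 3,
                               max_expansion = 1.2, n_waters = 25, seed = 5)
  expect_identical(fr[[2]]$waters, fr2[[2]]$waters)
  expect_gte(count_core_waters(fr[[1]], ring$core), 0)
})
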