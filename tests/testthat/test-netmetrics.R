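nodes6 <- paste0("A:", 1:6)

adj_from_links <- function(nodes, links) {
  m <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (l in links) m[l[1], l[2]] <- m[l[2], l[1]] <- 1
  m
}

random_adj <- function(nodes, p = 0.5) {
  n <- length(nodes)
  m <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ut <- upper.tri(m)
  m[ut] <- (runif(sum(ut)) < p) * 1
  m + t(m)
}

test_that("Disnet matches its worked example and the XOR oracle", {
  a <- adj_from_links(nodes6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  b <- adj_from_links(nodes6, list(c(1, 6), c(5, 6)))
  expect_equal(sum(a) / 2, 4)
  expect_equal(sum(b) / 2, 2)
  expect_equal(disnet(a, b), 0.4)    # 6 unique links / 15 possible
  expect_equal(disnet(a, a), 0)
  expect_equal(disnet(a, b), disnet(b, a))

  set.seed(7)
  nodes10 <- paste0("A:", 1:10)
  for (rep in 1:20) {
    x <- random_adj(nodes10); y <- random_adj(nodes10)
    xor_count <- sum(xor(x[upper.tri(x)] == 1, y[upper.tri(y)] == 1))
    expect_equal(disnet(x, y), xor_count / 45)
  }
  expect_error(disnet(a, random_adj(paste0("A:", 1:5))), "node sets")
})

test_that("Disnet is a metric on all 3-node network triples", {
  nodes <- paste0("A:", 1:3)
  all_nets <- lapply(0:7, function(bits) {
    adj_from_links(nodes, list(c(1, 2), c(1, 3), c(2, 3))[
      which(bitwAnd(bits, c(1, 2, 4)) > 0)])
  })
  for (i in seq_along(all_nets)) for (j in seq_along(all_nets)) {
    dij <- disnet(all_nets[[i]], all_nets[[j]])
    expect_gte(dij, 0)
    expect_equal(dij, disnet(all_nets[[j]], all_nets[[i]]))
    expect_equal(dij == 0, i == j)
    for (k in seq_along(all_nets))
      expect_lte(dij,
                 disnet(all_nets[[i]], all_nets[[k]]) +
                   disnet(all_nets[[k]], all_nets[[j]]) + 1e-15)
  }
})

test_that("q_fraction covers retention, loss and the worked ratio", {
  native <- paste0("A:1|A:", 2:36)   # 35 native pairs
  expect_equal(q_fraction(native, native), 1)
  expect_equal(q_fraction(character(0), native), 0)
  expect_equal(q_fraction(paste0("B:1|B:", 2:10), native), 0)
  expect_equal(q_fraction(native[1:21], native), 0.6)
  expect_error(q_fraction(native, character(0)), "empty native")
  # Q_L of any network against itself as native is 1
  net <- fx("ring_net")
  expect_equal(q_fraction(scn_links(net), scn_links(net)), 1)
})

test_that("persistence is the exact link frequency with inclusive binarization", {
  nodes <- paste0("A:", 1:3)
  present <- adj_from_links(nodes, list(c(1, 2)))
  absent <- adj_from_links(nodes, list())
  for (k in c(200, 80, 79)) {
    epoch <- c(rep(list(present), k), rep(list(absent), 200 - k))
    p <- persistence_matrix(epoch)
    expect_equal(p["A:1", "A:2"], k / 200)
    pb <- binarize_persistence(p)
    expect_equal(pb["A:1", "A:2"], as.numeric(k / 200 >= 0.40))
  }
  # the boundary cases stated explicitly
  p80 <- persistence_matrix(c(rep(list(present), 80),
                              rep(list(absent), 120)))
  expect_equal(p80["A:1", "A:2"], 0.40)
  expect_equal(binarize_persistence(p80)["A:1", "A:2"], 1)
  p79 <- persistence_matrix(c(rep(list(present), 79),
                              rep(list(absent), 121)))
  expect_equal(p79["A:1", "A:2"], 0.395)
  expect_equal(binarize_persistence(p79)["A:1", "A:2"], 0)
  expect_error(persistence_matrix(list()), "empty epoch")
})

test_that("persf measures baseline drift of locked links", {
  nodes <- paste0("A:", 1:6)
  base <- adj_from_links(nodes, list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(persf(base, base), 0)
  none <- adj_from_links(nodes, list())
  expect_equal(persf(none, base), 3 / 15)
  expect_error(persf(base * 0.5, base), "binarized")

  # links held at p = 1 on the baseline links reproduce the baseline
  p <- base * 1
  traj <- simulate_link_trajectory(p, n_snapshots = 200, seed = 3)
  pb <- binarize_persistence(persistence_matrix(traj))
  expect_equal(persf(pb, base), 0)
})

test_that("dlf matches enumeration and the Bernoulli expectation", {
  nodes <- paste0("A:", 1:6)
  a <- adj_from_links(nodes, list(c(1, 2), c(3, 4)))
  b <- adj_from_links(nodes, list(c(1, 2), c(5, 6), c(2, 3)))
  expect_equal(dlf(list(a, a, a)), 0)
  k <- sum(abs(a - b)) / 2
  # ABAB: 4 of the 6 unordered pairs differ
  expect_equal(dlf(list(a, b, a, b)), (k / 15) * (4 / 6))
  expect_error(dlf(list(a)), "at least 2")

  # iid Bernoulli(0.5) links: E[dlf] = 2 p (1 - p) = 0.5; the estimator's
  # sampling sd at Ns = 200, M = 45 is far below 0.01 (second order in
  # p-hat around 0.5)
  n <- 10
  p <- matrix(0.5, n, n); diag(p) <- 0
  traj <- simulate_link_trajectory(p, n_snapshots = 200, seed = 11)
  expect_lt(abs(dlf(traj) - 0.5), 0.01)
})

test_that("dlf and persf are invariant under node relabeling", {
  set.seed(5)
  nodes <- paste0("A:", 1:6)
  epoch <- lapply(1:10, function(i) random_adj(nodes))
  base <- binarize_persistence(persistence_matrix(epoch))
  perm <- sample(6)
  relab <- lapply(epoch, function(m) {
    m2 <- m[perm, perm]
    dimnames(m2) <- list(nodes, nodes)
    m2
  })
  base2 <- binarize_persistence(persistence_matrix(relab))
  expect_equal(dlf(epoch), dlf(relab))
  expect_equal(persf(base, base), persf(base2, base2))
})

test_that("adjacent averaging shrinks symmetrically at the edges", {
  x <- rep(3.2, 50)
  expect_equal(smooth_adjacent(x, 45), x)
  y <- rnorm(30)
  expect_equal(smooth_adjacent(y, 1), y)
  ramp <- seq(0, 10, length.out = 101)
  sm <- smooth_adjacent(ramp, 45)
  expect_equal(sm, ramp)   # symmetric windows preserve a line everywhere
  z <- c(1, 5, 2, 8, 4)
  expect_equal(smooth_adjacent(z, 3),
               c(1, mean(z[1:3]), mean(z[2:4]), mean(z[3:5]), 4))
  expect_error(smooth_adjacent(z, 4), "odd")
})

test_that("C-alpha RMSD removes rigid-body motion", {
  snap <- assign_radii(make_tripeptide())
  expect_equal(ca_rmsd(snap, snap), 0, tolerance = 1e-9)

  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  a2 <- snap$atoms
  xyz <- atom_xyz(a2) %*% rot
  a2$x <- xyz[, 1] + 5; a2$y <- xyz[, 2] - 2; a2$z <- xyz[, 3] + 1
  moved <- snapshot(a2)
  expect_lt(ca_rmsd(moved, snap), 1e-6)
  expect_error(ca_rmsd(snap, snap, selection = c("A:1", "A:2")),
               "at least 3")
})

test_that("C-alpha RMSD matches an exhaustive rotation-grid oracle", {
  snap <- assign_radii(make_tripeptide())
  a2 <- snap$atoms
  set.seed(9)
  a2$x <- a2$x + rnorm(nrow(a2), 0, 0.4)
  a2$y <- a2$y + rnorm(nrow(a2), 0, 0.4)
  a2$z <- a2$z + rnorm(nrow(a2), 0, 0.4)
  conf2 <- snapshot(a2)
  got <- ca_rmsd(conf2, snap)

  x <- scale(ca_coords(snap <- snap), scale = FALSE)
  y <- scale(ca_coords(conf2), scale = FALSE)
  rot_z <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                                0, 0, 1), 3, 3)
  rot_y <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                                -sin(t), 0, cos(t)), 3, 3)
  best <- Inf
  grid <- seq(0, 2 * pi, length.out = 73)[-73]
  half <- seq(0, pi, length.out = 37)
  for (a in grid) for (b in half) for (g in grid) {
    r <- rot_z(a) %*% rot_y(b) %*% rot_z(g)
    best <- min(best, sqrt(mean(rowSums((y %*% r - x)^2))))
  }
  expect_lt(got, best + 1e-9)       # the optimum beats every grid point
  expect_lt(best - got, 1e-3)       # and the grid comes close to it
})

test_that("RMSF recovers per-atom fluctuation amplitudes", {
  snap <- assign_radii(make_tripeptide())
  frames <- list(snap, snap, snap)
  expect_true(all(rmsf(frames, superpose = FALSE) == 0))

  d <- 0.8
  mk <- function(dx) {
    a <- snap$atoms
    a$x[a$atom_name == "CA" & a$res_seq == 2] <-
      a$x[a$atom_name == "CA" & a$res_seq == 2] + dx
    snapshot(a)
  }
  osc <- list(mk(d), mk(-d), mk(d), mk(-d))
  r <- rmsf(osc, superpose = FALSE)
  expect_equal(unname(r["A:2"]), d)
  expect_equal(unname(r["A:1"]), 0)

  # random-walk fixture against the direct variance computation
  set.seed(21)
  walk <- lapply(1:12, function(i) {
    a <- snap$atoms
    a$x <- a$x + rnorm(nrow(a), 0, 0.1)
    snapshot(a)
  })
  r2 <- rmsf(walk, superpose = FALSE)
  ca <- t(vapply(walk, function(s)
    s$atoms$x[toupper(s$atoms$atom_name) == "CA"], numeric(3)))
  manual <- sqrt(colMeans(sweep(ca, 2, colMeans(ca))^2))
  expect_equal(unname(r2), manual, tolerance = 1e-12)
  expect_error(rmsf(list(snap)), "at least 2")
})

test_that("cross-correlation is plain Pearson correlation", {
  x <- c(0.1, 0.5, 0.3, 0.9, 0.7)
  expect_equal(cross_correlation(x, x), 1)
  expect_equal(cross_correlation(x, -x), -1)
  set.seed(2)
  y <- rnorm(5)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cross_correlation(x, y), manual, tolerance = 1e-12)
  expect_error(cross_correlation(x, rep(1, 5)), "variance")
  expect_error(cross_correlation(x, y[1:4]), "lengths")
})

test_that("epoch splitting drops burn-in and partial epochs", {
  times <- seq(0, 9990, by = 10)           # 1000 frames
  idx <- split_epochs(times, span_ps = 2000, burn_in_ps = 2000)
  expect_length(idx, 4)                    # 2-4, 4-6, 6-8, 8-10 ns
  expect_true(all(vapply(idx, length, 1L) == 200))
  expect_true(all(times[idx[[1]]] >= 2000 & times[idx[[1]]] < 4000))

  # a trailing partial window is dropped
  idx2 <- split_epochs(seq(0, 8990, by = 10), 2000, 2000)
  expect_length(idx2, 3)

  ep <- epoch_ensemble(fx("series_nets"))
  expect_equal(ep$n_snapshots, 6)
  expect_true(all(ep$persistence >= 0 & ep$persistence <= 1))
})

test_that("persistence recovers Bernoulli link probabilities", {
  # p away from 0/1 so the 3-sigma normal approximation to the binomial
  # holds; 435 links make the 99% coverage check meaningful
  set.seed(13)
  n <- 30
  p <- matrix(0, n, n)
  ut <- upper.tri(p)
  p[ut] <- runif(sum(ut), 0.1, 0.9)
  p <- p + t(p)
  traj <- simulate_link_trajectory(p, n_snapshots = 200, seed = 17)
  phat <- persistence_matrix(traj)
  err <- abs(phat - p)[ut]
  tol <- (3 * sqrt(p * (1 - p) / 200))[ut]
  expect_gte(mean(err <= pmax(tol, 1e-12) + 1e-12), 0.99)
})
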