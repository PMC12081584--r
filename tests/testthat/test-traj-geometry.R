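test_that("Kabsch superposition is exact on rigid motions and symmetric", {
  set.seed(10)
  x <- matrix(stats::rnorm(15, sd = 4), ncol = 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-12)

  R <- random_rotation(37 * pi / 180)
  y <- sweep(x %*% t(R), 2, c(3, -2, 7), "+")
  expect_lt(kabsch_superpose(y, x)$rmsd, 1e-8)
  expect_equal(det(R), 1, tolerance = 1e-12)

  a <- matrix(stats::rnorm(15), ncol = 3)
  b <- matrix(stats::rnorm(15), ncol = 3)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_superpose(a[1:2, ], b[1:2, ]), "3 atoms")
  expect_error(kabsch_superpose(a[1:4, ], b), "counts differ")
})

test_that("Kabsch RMSD equals the brute-force rotational minimum", {
  set.seed(22)
  for (i in 1:3) {
    a <- matrix(stats::rnorm(15, sd = 3), ncol = 3)
    b <- matrix(stats::rnorm(15, sd = 3), ncol = 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, bruteforce_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("RMSD series vanishes on rigid-motion trajectories", {
  tet <- std_tetramer()
  base <- coords(tet)
  set.seed(5)
  frames <- lapply(1:8, function(i)
    sweep(base %*% t(random_rotation()), 2, stats::rnorm(3, sd = 5), "+"))
  traj <- trajectory_ensemble(frames, seq_len(8) - 1, tet)
  rs <- rmsd_series(traj, tet, selection = "CA")
  expect_true(all(rs$rmsd < 1e-8))
  expect_error(rmsd_series(traj, tet, selection = "XX"), "no atoms")
})

test_that("single displaced atom gives RMSD ~ d/sqrt(N)", {
  n <- 200
  set.seed(6)
  xyz <- matrix(stats::rnorm(3 * n, sd = 10), ncol = 3)
  big <- structure_model(1:n, "CA", "ALA", 1:n, "A", xyz, radius = 1.9)
  d <- 3
  moved <- xyz
  moved[1, 1] <- moved[1, 1] + d
  traj <- trajectory_ensemble(list(moved), 0, big)
  r <- rmsd_series(traj, big)$rmsd
  expect_equal(r, d / sqrt(n), tolerance = 0.02)
})

test_that("GROMOS clustering matches its contract and an independent oracle", {
  tet <- std_tetramer()
  one <- trajectory_ensemble(list(coords(tet)), 0, tet)
  cl <- cluster_gromos(one, cutoff = 2)
  expect_equal(cl$labels, 1L)
  expect_equal(cl$centers, 1L)
  expect_equal(cl$populations, 1L)

  traj <- gen_trajectory(tet, aperture_drift_spec(n_frames = 10, volatility = 3,
                                                  jitter_sd = 0.3, seed = 2))
  all_in <- cluster_gromos(traj, cutoff = 1e3)
  expect_equal(all_in$populations, 10L)

  # three planted conformers + jitter: recover the planted membership
  set.seed(31)
  nv <- 3 * nrow(tet)
  conf <- lapply(1:3, function(i) coords(tet) +
                   matrix(stats::rnorm(nv, sd = 4), ncol = 3))
  frames <- lapply(rep(1:3, times = c(5, 4, 3)), function(i)
    conf[[i]] + matrix(stats::rnorm(nv, sd = 0.05), ncol = 3))
  ptraj <- trajectory_ensemble(frames, 0:11, tet)
  cl <- cluster_gromos(ptraj, cutoff = 1.0)
  expect_equal(cl$populations, c(5L, 4L, 3L))
  expect_equal(cl$labels, rep(1:3, times = c(5, 4, 3)))

  orc <- oracle_gromos(ptraj, cutoff = 1.0)
  expect_equal(cl$labels, orc$labels)
  expect_equal(cl$centers, orc$centers)
  expect_equal(cl$populations, orc$populations)

  # partition and ordering invariants
  expect_equal(sum(cl$populations), length(ptraj$frames))
  expect_true(all(diff(cl$populations) <= 0))
  expect_true(all(cl$labels[cl$centers] == seq_along(cl$centers)))
  expect_error(cluster_gromos(ptraj, cutoff = 0), "cutoff")
})

test_that("RMSF vanishes for static trajectories and recovers oscillations", {
  tet <- std_tetramer()
  static <- trajectory_ensemble(replicate(6, coords(tet), simplify = FALSE),
                                0:5, tet)
  r <- rmsf(static, reference_frame_index = 1)
  expect_true(all(r$rmsf < 1e-12))

  # one residue oscillating +/- d along x among many static anchors
  n <- 400
  set.seed(8)
  xyz <- matrix(stats::rnorm(3 * n, sd = 12), ncol = 3)
  big <- structure_model(1:n, "CA", "ALA", 1:n, "A", xyz, radius = 1.9)
  d <- 2
  frames <- lapply(1:20, function(i) {
    f <- xyz
    f[7, 1] <- f[7, 1] + d * (-1)^i
    f
  })
  traj <- trajectory_ensemble(frames, seq_len(20) - 1, big)
  r <- rmsf(traj, reference_frame_index = NULL, cluster_cutoff = 5)
  osc <- r$rmsf[r$residue_id == 7]
  anchors <- r$rmsf[r$residue_id != 7]
  # reference frame itself has the residue displaced by d on one side, so the
  # per-frame deviation alternates between ~0 and ~2d; RMS ~ d * sqrt(2)
  expect_gt(osc, d * 0.9)
  expect_lt(max(anchors), 0.1)

  # chain-averaged RMSF of a symmetric tetramer is equal across chains
  # (within sampling noise of the isotropic jitter)
  jtraj <- gen_trajectory(tet, aperture_drift_spec(n_frames = 60, volatility = 0,
                                                   jitter_sd = 0.2, seed = 3))
  rj <- rmsf(jtraj, reference_frame_index = 1)
  per_chain <- tapply(rj$rmsf, rj$chain_id, mean)
  expect_lt((max(per_chain) - min(per_chain)) / mean(per_chain), 0.15)
})

test_that("gate perimeter is geometric and motion-invariant", {
  tet <- std_tetramer(side = 15.51)
  one <- trajectory_ensemble(list(coords(tet)), 0, tet)
  ap <- gate_perimeter(one, 6, "CA")
  expect_equal(ap$perimeter[1], 62.04, tolerance = 1e-9)
  expect_equal(rowSums(ap$pair_distances), ap$perimeter)

  traj <- gen_trajectory(tet, aperture_drift_spec(mean_perimeter = 60,
                                                  n_frames = 30, seed = 4))
  ap1 <- gate_perimeter(traj, 6, "CA")
  set.seed(13)
  moved <- lapply(traj$frames, function(f)
    sweep(f %*% t(random_rotation()), 2, c(10, -4, 2), "+"))
  ap2 <- gate_perimeter(trajectory_ensemble(moved, traj$times, tet), 6, "CA")
  expect_equal(ap2$perimeter, ap1$perimeter, tolerance = 1e-9)

  expect_error(gate_perimeter(one, 999, "CA"), "4 gate atoms")
})

test_that("window summaries select the requested frames", {
  s <- list(times = 1:5, perimeter = c(10, 20, 30, 40, 50))
  w <- window_summary(s, 2, 4)
  expect_equal(w$median, 30)
  expect_equal(w$n, 3L)
  const <- list(times = 0:9, perimeter = rep(7, 10))
  wc <- window_summary(const, 0, 9)
  expect_equal(wc$median, 7)
  expect_equal(wc$sd, 0)
  expect_error(window_summary(s, 99, 100), "no frames")

  tet <- std_tetramer()
  traj <- gen_trajectory(tet, aperture_drift_spec(n_frames = 500, seed = 6))
  ap <- gate_perimeter(traj, 6, "CA")
  lw <- last_window_summary(ap, 2)
  keep <- ap$times >= max(ap$times) - 2
  expect_equal(lw$median, sort(ap$perimeter[keep])[
    ceiling(sum(keep) / 2):ceiling((sum(keep) + 1) / 2)] |> mean())
  expect_equal(lw$n, sum(keep))
})
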