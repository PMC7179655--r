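# RMSD/2D-RMSD, B-factors, hydrogen bonds, and center-of-mass
# distances.

test_that("RMSD vanishes for identical and rigidly moved copies", {
  set.seed(14)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(a, a), 0)
  th <- 0.9
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- sweep(a %*% rot, 2, c(4, -1, 2), "+")
  expect_lt(rmsd(b, a), 1e-8)
  # cross-check the Kabsch fit against the bio3d implementation
  c2 <- a + matrix(rnorm(30, sd = 0.3), 10, 3)
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(c2)), fit = TRUE)
  expect_equal(rmsd(c2, a), ref, tolerance = 5e-4) # bio3d rounds to 3 dp
})

test_that("raw RMSD matches hand arithmetic on centered 2-point sets", {
  a <- rbind(c(-1, 0, 0), c(1, 0, 0))
  b <- rbind(c(-2, 0, 0), c(2, 0, 0))
  expect_equal(rmsd(a, b, superpose = FALSE), 1.0)
  expect_error(rmsd(a, b, superpose = TRUE), ">= 3")
})

test_that("2D-RMSD is symmetric with a zero diagonal", {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 2, n_frames = 5,
                                   jitter = 0.2), seed = 7)
  m <- rmsd_matrix(toy$trajectory)
  expect_equal(diag(m), rep(0, 5), ignore_attr = TRUE)
  expect_equal(m, t(m))
  # per-cell oracle
  for (i in 1:3) for (j in 1:3) {
    expect_equal(m[i, j], rmsd(get_frame(toy$trajectory, i),
                               get_frame(toy$trajectory, j)),
                 tolerance = 1e-10)
  }
  st <- static_traj(toy$system$coords, 4)
  expect_true(all(rmsd_matrix(st) < 1e-10))
})

test_that("B-factors recover the analytic isotropic variance", {
  expect_error(bfactor(static_traj(matrix(0, 4, 3), 1)), "frames")
  st <- static_traj(matrix(rnorm(12), 4, 3), 6)
  expect_num_eq(bfactor(st, align = FALSE), rep(0, 4), 1e-12)
  # Gaussian jitter s = 0.5 A per coordinate: B = 8 pi^2 s^2
  set.seed(15)
  n <- 4; nf <- 1e5; s <- 0.5
  base <- matrix(rnorm(n * 3, sd = 5), n, 3)
  arr <- array(rep(base, nf), dim = c(n, 3, nf)) +
    array(rnorm(n * 3 * nf, sd = s), dim = c(n, 3, nf))
  b <- bfactor(trajectory(arr), align = FALSE)
  expect_num_eq(b, rep(8 * pi^2 * s^2, n), 0.02 * 8 * pi^2 * s^2)
  # rigid translation is removed by alignment
  drift <- array(rep(base, 20), dim = c(n, 3, 20))
  for (f in 1:20) drift[, 1, f] <- drift[, 1, f] + 0.5 * f
  expect_num_eq(bfactor(trajectory(drift), align = TRUE), rep(0, n), 1e-8)
})

test_that("hydrogen-bond detection applies inclusive cutoffs", {
  mk <- function(d, ang) {
    cs <- cos((180 - ang) * pi / 180)
    len <- -cs + sqrt(cs^2 + d^2 - 1)
    rbind(c(0, 0, 0), c(1, 0, 0),
          c(1, 0, 0) + len * c(cs, sin((180 - ang) * pi / 180), 0))
  }
  donors <- data.frame(heavy = 1L, hydrogen = 2L)
  expect_equal(nrow(detect_hbonds(mk(3.4, 150), donors, 3L)), 1L)
  expect_equal(nrow(detect_hbonds(mk(3.6, 170), donors, 3L)), 0L)
  expect_equal(nrow(detect_hbonds(mk(3.4, 110), donors, 3L)), 0L)
  # boundary: exactly 3.5 A and 120 degrees is detected
  expect_equal(nrow(detect_hbonds(mk(3.5, 120), donors, 3L)), 1L)
  expect_error(detect_hbonds(mk(3, 150),
                             data.frame(heavy = 1L, hydrogen = NA), 3L),
               "hydrogen")
})

test_that("occupancy counts bonded frames and averages all frames", {
  h100 <- planted_hbond_trajectory(100, 50, seed = 1)
  expect_equal(hbond_occupancy(h100$trajectory, 1, 2, 3)$occupancy, 100)
  h0 <- planted_hbond_trajectory(0, 50, seed = 1)
  expect_equal(hbond_occupancy(h0$trajectory, 1, 2, 3)$occupancy, 0)
  h54 <- planted_hbond_trajectory(54.31, 1e4, seed = 2)
  rec <- hbond_occupancy(h54$trajectory, 1, 2, 3)
  expect_equal(rec$occupancy, 54.31, tolerance = 1.5 / 54.31 * 54.31)
  expect_equal(rec$occupancy, 100 * mean(h54$bonded))
  # mean distance mixes bonded and broken geometry
  p <- mean(h54$bonded)
  expect_equal(rec$mean_distance, p * 3.0 + (1 - p) * 4.5,
               tolerance = 1e-9)
  # occupancy of disjoint-frame events adds
  half1 <- hbond_occupancy(subset_trajectory(h54$trajectory,
                                             frames = 1:5000), 1, 2, 3)
  half2 <- hbond_occupancy(subset_trajectory(h54$trajectory,
                                             frames = 5001:10000), 1, 2, 3)
  expect_equal((half1$occupancy + half2$occupancy) / 2, rec$occupancy,
               tolerance = 1e-9)
})

test_that("center-of-mass distances follow centroid arithmetic", {
  co <- rbind(c(0, 0, 0), c(4.18, 0, 0))
  tr <- static_traj(co, 3)
  expect_equal(com_distance(tr, 1L, 2L)$mean, 4.18)
  # two identical rings shifted by 5 A
  ring <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  co2 <- rbind(ring, sweep(ring, 2, c(0, 0, 5), "+"))
  tr2 <- static_traj(co2, 2)
  expect_equal(com_distance(tr2, 1:6, 7:12)$mean, 5.0, tolerance = 1e-12)
  # equal-mass pair straddling the origin vs a point at (3,0,0)
  co3 <- rbind(c(0, 1, 0), c(0, -1, 0), c(3, 0, 0))
  expect_equal(com_distance(static_traj(co3, 2), 1:2, 3L)$mean, 3.0)
  expect_error(com_distance(tr, integer(0), 2L), "non-empty")
  expect_error(com_distance(tr, 1L, 2L, masses = c(0, 1)), "mass")
})
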