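# Gas-phase Coulomb / Lennard-Jones energetics against closed forms
# and brute-force oracles.

test_that("Coulomb matches the k_e/r closed form and 1/eps scaling", {
  co <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  q <- c(1, -1)
  expect_equal(coulomb_energy(co, q, 1, 2, 1), -100, tolerance = 1e-10)
  expect_equal(coulomb_energy(co, q, 1, 2, 10), -10, tolerance = 1e-10)
  expect_equal(coulomb_energy(co, c(0, 0), 1, 2), 0)
  expect_error(coulomb_energy(co, q, 1, 1), "disjoint")
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), q, 1, 2),
               "overlap")
})

test_that("LJ minimum, asymptotic decay, and combination rules hold", {
  co <- rbind(c(0, 0, 0), c(3.7, 0, 0)) # r = Rmin = 1.9 + 1.8
  rh <- c(1.9, 1.8)
  ep <- c(0.16, 0.09)
  expect_equal(lj_energy(co, rh, ep, 1, 2), -sqrt(0.16 * 0.09),
               tolerance = 1e-12)
  far <- rbind(c(0, 0, 0), c(1e4, 0, 0))
  expect_lt(abs(lj_energy(far, rh, ep, 1, 2)), 1e-12)
})

test_that("group energies equal brute-force double loops", {
  set.seed(101)
  for (rep in 1:5) {
    co <- matrix(runif(18, -4, 4), 6, 3)
    co <- co + outer(rep(1:6, 1), c(8, 0, 0))[, c(1, 1, 1)] * 0 # keep
    q <- runif(6, -1, 1)
    rh <- runif(6, 1.2, 2.1)
    ep <- runif(6, 0.01, 0.3)
    ga <- 1:3; gb <- 4:6
    d <- min(iescan:::.cross_dist(co[ga, ], co[gb, ]))
    if (d < 0.5) next
    expect_num_eq(coulomb_energy(co, q, ga, gb, 2),
                  coulomb_bf(co, q, ga, gb, 2), 1e-10)
    expect_num_eq(lj_energy(co, rh, ep, ga, gb),
                  lj_bf(co, rh, ep, ga, gb), 1e-8)
    # symmetry and additivity
    expect_num_eq(coulomb_energy(co, q, ga, gb), coulomb_energy(co, q, gb, ga))
    expect_num_eq(lj_energy(co, rh, ep, ga, gb), lj_energy(co, rh, ep, gb, ga))
    expect_num_eq(coulomb_energy(co, q, ga, gb),
                  coulomb_energy(co, q, 1:2, gb) + coulomb_energy(co, q, 3, gb),
                  1e-10)
    # Coulomb linear in charges, LJ independent of them
    q2 <- q; q2[ga] <- 2 * q2[ga]
    expect_num_eq(coulomb_energy(co, q2, ga, gb),
                  2 * coulomb_energy(co, q, ga, gb), 1e-9)
    expect_num_eq(lj_energy(co, rh, ep, ga, gb),
                  lj_energy(co, rh, ep, ga, gb))
  }
})

test_that("interaction energy series is exact per frame", {
  # static trajectory: all frames equal, SD 0
  co <- rbind(c(0, 0, 0), c(4, 0, 0))
  sys <- bare_system(co, charge = c(0.3, -0.5), groups = list(1L, 2L),
                     res_names = c("ALA", "LIG"))
  tr <- static_traj(co, n = 10)
  es <- interaction_energy_series(tr, sys, 1)
  expect_equal(stats::sd(es$e_total), 0)
  expect_num_eq(es$e_total, es$e_vdw + es$e_ele, 1e-12)

  # LJ-only dimer pulled from Rmin to 2 Rmin: strictly increasing energy
  rmin <- 3.6
  frames <- lapply(seq(rmin, 2 * rmin, length.out = 8), function(d) {
    rbind(c(0, 0, 0), c(d, 0, 0))
  })
  sys0 <- bare_system(frames[[1]], charge = c(0, 0), groups = list(1L, 2L),
                      res_names = c("ALA", "LIG"))
  es2 <- interaction_energy_series(trajectory(frames), sys0, 1)
  expect_true(all(diff(es2$e_total) > 0))

  # random frames against a frame-by-frame oracle
  set.seed(7)
  fr <- lapply(1:4, function(i) rbind(c(0, 0, 0), c(3 + i, 0.3, -0.2)))
  sysr <- bare_system(fr[[1]], charge = c(0.4, -0.8),
                      rmin_half = c(1.7, 1.9), epsilon = c(0.2, 0.05),
                      groups = list(1L, 2L), res_names = c("SER", "LIG"))
  esr <- interaction_energy_series(trajectory(fr), sysr, 1)
  eps_used <- sqrt(dielectric_for("polar"))
  for (i in 1:4) {
    expect_num_eq(esr$e_ele[i],
                  coulomb_bf(fr[[i]], c(0.4, -0.8), 1, 2, eps_used), 1e-10)
    expect_num_eq(esr$e_vdw[i],
                  lj_bf(fr[[i]], c(1.7, 1.9), c(0.2, 0.05), 1, 2), 1e-10)
  }
  expect_error(interaction_energy_series(trajectory(fr), sysr, 2),
               "ligand")
})
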