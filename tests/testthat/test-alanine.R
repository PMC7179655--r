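# Sidechain-truncation mutants and ddG assembly.

test_that("identity mutation leaves the system untouched", {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 2,
                                   residue_names = "ALA", n_frames = 5),
                          seed = 1)
  m <- mutate_to_alanine(toy$system, toy$trajectory, 1)
  expect_identical(m$system$atoms, toy$system$atoms)
  expect_identical(m$trajectory$coords, toy$trajectory$coords)
})

test_that("TYR truncates to the 10-atom alanine template", {
  sys <- tyr_system()
  m <- mutate_to_alanine(sys, NULL, 1)
  mres <- residue_atoms(m$system, 1)
  expect_length(mres, 10L)
  expect_setequal(m$system$atoms$name[mres],
                  c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3",
                    "C", "O"))
  expect_equal(m$system$residues$name[1], "ALA")
  expect_equal(m$label, "Y907A")
  # mutant residue is exactly neutral
  expect_num_eq(sum(m$system$atoms$charge[mres]), 0, 1e-12)
  # HB1 sits 1.09 A from CB along the old CB->CG direction
  cb <- m$system$coords[match("CB", m$system$atoms$name[mres]), ]
  hb1 <- m$system$coords[match("HB1", m$system$atoms$name[mres]), ]
  expect_equal(sqrt(sum((hb1 - cb)^2)), 1.09, tolerance = 1e-9)
})

test_that("GLY is rejected and backbone/frames are preserved", {
  sys <- tyr_system()
  sys$residues$name[1] <- "GLY"
  expect_error(mutate_to_alanine(sys, NULL, 1), "GLY")

  toy <- make_toy_complex(toy_spec(n_pocket_residues = 3, n_frames = 7),
                          seed = 2)
  m <- mutate_to_alanine(toy$system, toy$trajectory, 2)
  expect_equal(n_frames(m$trajectory), 7L)
  # backbone coordinates bit-exact in every frame
  bb_old <- which(toy$system$atoms$name %in% c("N", "CA", "C", "O"))
  bb_new <- which(m$system$atoms$name %in% c("N", "CA", "C", "O"))
  expect_identical(m$trajectory$coords[bb_new, , ],
                   toy$trajectory$coords[bb_old, , ])
})

test_that("ddG components follow the mutant-minus-wild convention", {
  mk <- function(vals) list(energy = energy_series(seq_along(vals),
                                                   rep(0, length(vals)),
                                                   vals))
  # mutant identical to wild: every column zero
  x <- gaussian_energy_series(-3, 0.5, 200, seed = 4)
  z <- ddg_components(mk(x), mk(x))
  expect_true(all(abs(unlist(z)) < 1e-12))
  # constants -2 (wild) vs -1 (mutant): ddH = +1, -TddS = 0
  c2 <- ddg_components(mk(rep(-2, 100)), mk(rep(-1, 100)))
  expect_equal(c2$dd_h, 1)
  expect_equal(c2$minus_t_dd_s, 0)
  expect_equal(c2$dd_g, 1)
  # Gaussian wild (sigma 1) vs constant mutant at the same mean:
  # ddH = 0, -TddS = -sigma^2/(2kT) = -0.839 at 300 K
  g <- gaussian_energy_series(-5, 1, 1e6, seed = 10)
  c3 <- ddg_components(mk(g), mk(rep(mean(g), 1e6)), temperature = 300,
                       filter_sd = NULL)
  expect_equal(c3$dd_h, 0, tolerance = 1e-9)
  expect_equal(c3$minus_t_dd_s, -1 / (2 * KB * 300), tolerance = 0.012)
  expect_error(ddg_components(mk(rep(1, 5)), mk(rep(1, 6))), "aligned")
})

test_that("ddH and ddG columns are internally consistent", {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 3, n_frames = 20),
                          seed = 3)
  w <- data.frame(start = c(1, 11), end = c(10, 20))
  sc <- alanine_scan(toy$system, toy$trajectory, w, residues = 1:3,
                     enthalpy_frames = 4, n_points = 120)
  r <- sc$records
  expect_num_eq(r$dd_h,
                r$dd_e_vdw + r$dd_e_ele + r$dd_g_gb + r$dd_g_np, 1e-9)
  expect_num_eq(r$dd_g, r$dd_h + r$minus_t_dd_s, 1e-9)
  expect_true(all(diff(r$dd_g) <= 0)) # sorted descending
})

test_that("deleting an attractive residue destabilizes binding", {
  # Glu-like residue against the +1 ligand: ddG > 0
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 3,
                                   residue_names = c("GLU", "SER", "SER"),
                                   n_frames = 16),
                          seed = 5)
  w <- data.frame(start = c(1, 9), end = c(8, 16))
  sr <- scan_residue(toy$system, toy$trajectory, w, 1,
                     enthalpy_frames = 4, n_points = 120)
  expect_gt(sr$record$dd_g, 0)
})

test_that("total binding energy is the negated sum with stable arithmetic", {
  expect_equal(total_binding_energy(c(1, 2)), -3)
  expect_equal(total_binding_energy(rep(0, 7)), 0)
  expect_error(total_binding_energy(numeric(0)), "empty")
  # published per-residue columns: residue-sum totals
  p1 <- published_ddg("PARP-1")
  p2 <- published_ddg("PARP-2")
  expect_equal(total_binding_energy(p1), -sum(p1$dd_g))
  expect_equal(total_binding_energy(p1), -19.73, tolerance = 1e-9)
  expect_equal(total_binding_energy(p2), -17.11, tolerance = 1e-9)
  # Kahan-vs-naive accumulation agreement
  set.seed(6)
  v <- rnorm(1000) * 1e3
  kahan <- local({
    s <- 0; c <- 0
    for (x in v) {
      y <- x - c; t <- s + y; c <- (t - s) - y; s <- t
    }
    s
  })
  expect_num_eq(total_binding_energy(v), -kahan, 1e-9)
})

test_that("hot-spot classification thresholds and orders correctly", {
  r <- data.frame(mutation = c("A1A", "B2A", "C3A"),
                  dd_g = c(0.5, 2.0, 1.2))
  hs <- classify_hotspots(r, 1.0)
  expect_equal(hs$mutation, c("B2A", "C3A"))
  expect_equal(nrow(classify_hotspots(r, 10)), 0L)
  expect_error(classify_hotspots(r, -1), "positive")
})

test_that("Kd-ratio selectivity converts through kT ln", {
  expect_equal(ddg_from_kd_ratio(154, 300), 3.00, tolerance = 0.005)
  expect_equal(ddg_from_kd_ratio(1), 0)
})
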