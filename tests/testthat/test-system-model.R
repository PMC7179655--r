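# Structure parsing, residue classification, parameter attachment,
# and pocket selection.

test_that("PDB text parses into the expected atoms and residues", {
  sys <- read_structure(toy_pdb_text())
  expect_equal(nrow(sys$atoms), 5L)
  expect_equal(nrow(sys$residues), 3L)
  expect_equal(sys$residues$name, c("ALA", "SER", "LIG"))
  expect_equal(sys$residues$is_ligand, c(FALSE, FALSE, TRUE))
  expect_equal(sys$coords[2, 1], 1.458, tolerance = 1e-6)
})

test_that("ligand-only HETATM input yields one flagged residue", {
  txt <- paste(
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  N1  LIG A   1       1.400   0.000   0.000  1.00  0.00           N",
    sep = "\n")
  sys <- read_structure(txt)
  expect_equal(nrow(sys$residues), 1L)
  expect_true(sys$residues$is_ligand[1])
})

test_that("malformed and empty inputs are rejected with diagnostics", {
  bad <- sub("0.000   0.000   0.000", "0.000   xxx     0.000",
             toy_pdb_text())
  expect_error(read_structure(bad), "line 1")
  expect_error(read_structure("REMARK nothing here"), "empty")
})

test_that("highest-occupancy altloc is retained without changing counts", {
  txt <- paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  sys <- read_structure(txt)
  expect_equal(nrow(sys$atoms), 3L)
  # the B altloc (occupancy 0.60) wins
  expect_equal(sys$coords[2, 1], 1.600, tolerance = 1e-6)
})

test_that("writing frame 0 and re-reading round-trips the system", {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 3, n_frames = 2),
                          seed = 5)
  txt <- write_structure(toy$system)
  back <- read_structure(paste(txt, collapse = "\n"))
  expect_equal(back$atoms$name, toy$system$atoms$name)
  expect_equal(nrow(back$residues), nrow(toy$system$residues))
  expect_equal(back$residues$is_ligand, toy$system$residues$is_ligand)
  expect_num_eq(back$coords, toy$system$coords, tol = 1e-3)
})

test_that("multi-model PDB round-trips as a trajectory", {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 2, n_frames = 4),
                          seed = 2)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_trajectory(toy$system, toy$trajectory, tf)
  back <- read_pdb_trajectory(tf)
  expect_equal(n_frames(back$trajectory), 4L)
  expect_num_eq(back$trajectory$coords, toy$trajectory$coords, tol = 1e-3)
})

test_that("trajectory CSV container round-trips exactly", {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 2, n_frames = 3),
                          seed = 3)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(toy$trajectory, tf)
  back <- read_trajectory_csv(tf)
  expect_equal(back$frame_interval, toy$trajectory$frame_interval)
  expect_num_eq(back$coords, toy$trajectory$coords, tol = 1e-12)
})

test_that("residue classification covers the canonical table", {
  expect_equal(classify_residue("LEU"), "nonpolar")
  expect_equal(classify_residue("GLU"), "charged")
  expect_equal(classify_residue("SER"), "polar")
  canon <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
             "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
             "THR", "TRP", "TYR", "VAL")
  cls <- classify_residue(canon)
  expect_true(all(cls %in% c("nonpolar", "polar", "charged")))
  expect_length(cls, 20L)
  expect_error(classify_residue("XYZ"), "classify")
  expect_equal(dielectric_for(c("nonpolar", "polar", "charged")),
               c(1, 3, 10))
})

test_that("parameter attachment matches, reports misses, rejects dupes", {
  sys <- read_structure(toy_pdb_text())
  tab <- data.frame(
    residue = c("ALA", "ALA", "ALA", "SER", "LIG"),
    atom = c("N", "CA", "C", "N", "C1"),
    charge_e = c(-0.4, 0.03, 0.6, -0.4, 0.1),
    rmin_half_A = 1.8, epsilon_kcal = 0.1)
  full <- attach_parameters(sys, tab)
  expect_false(anyNA(full$atoms$charge))
  expect_false(anyNA(full$atoms$gb_radius)) # element defaults filled
  expect_error(attach_parameters(sys, tab[-4, ]), "SER/N")
  expect_error(attach_parameters(sys, rbind(tab, tab[1, ])), "duplicate")
})

test_that("pocket selection honors the cutoff and is monotone", {
  # one residue at 4 A, one at 8 A from a single-atom ligand
  co <- rbind(c(4, 0, 0), c(8, 0, 0), c(0, 0, 0))
  sys <- bare_system(co, groups = list(1L, 2L, 3L),
                     res_names = c("ALA", "ALA", "LIG"))
  expect_equal(select_pocket(sys, cutoff = 5), 1L)
  expect_length(select_pocket(sys, cutoff = 0), 0L)
  for (c1 in c(2, 4, 6, 10)) {
    p1 <- select_pocket(sys, cutoff = c1)
    p2 <- select_pocket(sys, cutoff = c1 + 2)
    expect_true(all(p1 %in% p2))
  }
  # hydrogens are excluded from the distance test
  co_h <- rbind(c(4, 0, 0), c(0.5, 0, 0), c(0, 0, 0))
  sys_h <- bare_system(co_h, groups = list(1:2, 3L),
                       elements = c("C", "H", "C"),
                       res_names = c("ALA", "LIG"))
  expect_length(select_pocket(sys_h, cutoff = 2), 0L)
})
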