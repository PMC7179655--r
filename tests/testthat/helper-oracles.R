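# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles are deliberately naive (double loops,
# quadrature) and never call the implementation paths they check.

KB <- 1.9872041e-3
KE <- 332.0636

# -- brute-force pair energies ---------------------------------------------

coulomb_bf <- function(coords, q, ga, gb, eps = 1) {
  e <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    e <- e + KE * q[i] * q[j] / (eps * r)
  }
  e
}

lj_bf <- function(coords, rh, ep, ga, gb) {
  e <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    rmin <- rh[i] + rh[j]
    eij <- sqrt(ep[i] * ep[j])
    e <- e + eij * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  e
}

gb_bf <- function(coords, q, radii, eps_in, eps_out = 80) {
  n <- length(q)
  if (length(eps_in) == 1L) eps_in <- rep(eps_in, n)
  e <- 0
  for (i in 1:n) for (j in 1:n) {
    r2 <- sum((coords[i, ] - coords[j, ])^2)
    rr <- radii[i] * radii[j]
    f <- sqrt(r2 + rr * exp(-r2 / (4 * rr)))
    e <- e - (KE / 2) * (1 / sqrt(eps_in[i] * eps_in[j]) - 1 / eps_out) *
      q[i] * q[j] / f
  }
  e
}

# -- quadrature descreening oracle (two-atom Born radii) -------------------

# Volume integral of r^-4 over the scaled neighbor sphere (radius sk at
# distance d), excluding points inside the reduced self sphere oi.
quad_descreen <- function(d, oi, sk) {
  f <- function(ct) {
    disc <- d^2 * ct^2 - (d^2 - sk^2)
    out <- numeric(length(ct))
    for (k in seq_along(ct)) {
      if (disc[k] < 0) next
      rlo <- d * ct[k] - sqrt(disc[k])
      rhi <- d * ct[k] + sqrt(disc[k])
      rlo <- max(rlo, oi)
      if (rhi <= rlo) next
      out[k] <- 1 / rlo - 1 / rhi
    }
    out
  }
  0.5 * stats::integrate(f, -1, 1, subdivisions = 2000,
                         rel.tol = 1e-10)$value
}

# OBC radii for a two-atom system driven by the quadrature integral.
born_radii_quad <- function(coords, rho, screen, offset = 0.09,
                            a = 1.0, b = 0.8, g = 4.85) {
  rt <- rho - offset
  d <- sqrt(sum((coords[1, ] - coords[2, ])^2))
  vapply(1:2, function(i) {
    j <- 3 - i
    I <- quad_descreen(d, rt[i], screen[j] * rt[j])
    psi <- I * rt[i]
    1 / (1 / rt[i] - tanh(a * psi - b * psi^2 + g * psi^3) / rho[i])
  }, numeric(1))
}

# Analytic accessible area of sphere 1 overlapped by sphere 2
# (extended radii r1, r2, centers distance d apart): spherical cap cut.
two_sphere_sasa1 <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  # height of the cap of sphere 1 inside sphere 2
  h <- (r2^2 - (d - r1)^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# -- small fixture builders -------------------------------------------------

# Bare n-atom system: one "residue" per group in `groups` (list of
# atom counts), last group optionally the ligand.
bare_system <- function(coords, charge = NULL, rmin_half = NULL,
                        epsilon = NULL, gb_radius = NULL,
                        gb_screen = NULL, groups = NULL,
                        ligand_last = TRUE, res_names = NULL,
                        elements = NULL) {
  n <- nrow(coords)
  if (is.null(groups)) groups <- list(seq_len(n))
  if (is.null(charge)) charge <- rep(0, n)
  if (is.null(rmin_half)) rmin_half <- rep(1.8, n)
  if (is.null(epsilon)) epsilon <- rep(0.1, n)
  if (is.null(gb_radius)) gb_radius <- rep(1.5, n)
  if (is.null(gb_screen)) gb_screen <- rep(0.8, n)
  if (is.null(elements)) elements <- rep("C", n)
  ng <- length(groups)
  if (is.null(res_names)) {
    res_names <- c(rep("ALA", ng - 1), if (ligand_last) "LIG" else "ALA")
  }
  ridx <- rep(seq_len(ng), lengths(groups))
  atoms <- data.frame(
    serial = seq_len(n),
    name = paste0("X", seq_len(n)), element = elements,
    residue_index = ridx, charge = charge, rmin_half = rmin_half,
    epsilon = epsilon, gb_radius = gb_radius, gb_screen = gb_screen,
    stringsAsFactors = FALSE)
  first <- match(seq_len(ng), ridx)
  last <- c(first[-1] - 1L, n)
  residues <- data.frame(
    index = seq_len(ng), name = res_names, chain = "A",
    resno = seq_len(ng), first_atom = first, last_atom = last,
    polarity_class = vapply(res_names, function(rn) {
      if (rn == "LIG") NA_character_ else classify_residue(rn)
    }, character(1), USE.NAMES = FALSE),
    is_ligand = res_names == "LIG", stringsAsFactors = FALSE)
  param_system(atoms, residues, coords = coords)
}

# Minimal two-residue, five-atom PDB text.
toy_pdb_text <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  N   SER A   2       3.300   1.500   0.000  1.00  0.00           N",
    "HETATM    5  C1  LIG B   3       6.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
}

# Full-hydrogen TYR + ligand system for mutation atom-count checks.
tyr_system <- function() {
  nm <- c("N", "H", "CA", "HA", "CB", "HB2", "HB3", "CG", "CD1", "HD1",
          "CD2", "HD2", "CE1", "HE1", "CE2", "HE2", "CZ", "OH", "HH",
          "C", "O")
  el <- substr(nm, 1, 1)
  n <- length(nm)
  set.seed(11)
  co <- matrix(rnorm(n * 3, sd = 2), n, 3)
  co <- rbind(co, c(20, 0, 0)) # ligand atom far away
  atoms <- data.frame(
    serial = 1:(n + 1), name = c(nm, "C1"), element = c(el, "C"),
    residue_index = c(rep(1L, n), 2L),
    charge = 0, rmin_half = 1.8, epsilon = 0.1,
    gb_radius = 1.5, gb_screen = 0.8, stringsAsFactors = FALSE)
  residues <- data.frame(
    index = 1:2, name = c("TYR", "LIG"), chain = "A", resno = c(907L, 1L),
    first_atom = c(1L, n + 1L), last_atom = c(n, n + 1L),
    polarity_class = c("polar", NA), is_ligand = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  param_system(atoms, residues, coords = co)
}

# Static trajectory repeating one frame.
static_traj <- function(coords, n = 10, dt = 1) {
  trajectory(replicate(n, coords, simplify = FALSE), frame_interval = dt)
}

expect_num_eq <- function(x, y, tol = 1e-10) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max |diff| = %g", max(abs(x - y))))
}
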