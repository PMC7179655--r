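# Seeded synthetic fixtures: toy host-guest complexes with planted
# per-residue interaction strengths, Gaussian interaction-energy
# series, and trajectories with planted hydrogen-bond geometry. All
# generators are pure functions of (spec, seed).

# Heavy-atom residue templates for the toy protein. Local geometry:
# +u points from the residue toward the ligand (sidechain direction),
# t is the backbone tangent, z the out-of-plane axis. Charges are
# template values uniformly shifted to hit the formal net charge.
.toy_templates <- list(
  ALA = list(
    atoms = c("N", "CA", "CB", "C", "O"),
    elements = c("N", "C", "C", "C", "O"),
    offsets = rbind(c(0, 1.45, 0), c(0, 0, 0), c(1.53, 0, 0),
                    c(0, -1.52, 0), c(0.6, -2.2, 0.8)),
    charges = c(-0.35, 0.10, -0.05, 0.55, -0.45),
    net = 0
  ),
  SER = list(
    atoms = c("N", "CA", "CB", "OG", "C", "O"),
    elements = c("N", "C", "C", "O", "C", "O"),
    offsets = rbind(c(0, 1.45, 0), c(0, 0, 0), c(1.53, 0, 0),
                    c(2.96, 0, 0), c(0, -1.52, 0), c(0.6, -2.2, 0.8)),
    charges = c(-0.35, 0.10, 0.25, -0.55, 0.55, -0.45),
    net = 0
  ),
  GLU = list(
    atoms = c("N", "CA", "CB", "CG", "CD", "OE1", "OE2", "C", "O"),
    elements = c("N", "C", "C", "C", "C", "O", "O", "C", "O"),
    offsets = rbind(c(0, 1.45, 0), c(0, 0, 0), c(1.53, 0, 0),
                    c(3.05, 0, 0), c(4.57, 0, 0),
                    c(5.3, 0.6, 0.8), c(5.3, -0.6, -0.8),
                    c(0, -1.52, 0), c(0.6, -2.2, 0.8)),
    charges = c(-0.35, 0.05, -0.05, -0.05, 0.70, -0.75, -0.75,
                0.55, -0.45),
    net = -1
  )
)

.toy_lj <- list(C = c(1.9080, 0.1094), N = c(1.8240, 0.1700),
                O = c(1.6612, 0.2100), H = c(1.4870, 0.0157))

#' Toy complex specification
#'
#' @param n_pocket_residues number of pocket residues (>= 1).
#' @param residue_names 3-letter codes drawn from ALA/SER/GLU templates
#'   (recycled; default alternates SER and GLU).
#' @param strengths planted per-residue interaction strengths
#'   (dimensionless multipliers of the sidechain Lennard-Jones well
#'   depths; default 1).
#' @param ligand_charge formal ligand charge in e (default +1, on the
#'   central atom).
#' @param n_frames trajectory length in frames.
#' @param jitter Gaussian coordinate jitter SD in Angstrom.
#' @param radius clearance from the ligand center to each residue's
#'   sidechain tip (Angstrom); residues are placed radially so that
#'   short and long sidechains make comparable contacts.
#' @param frame_interval ps between frames.
#' @return list of class `ToySpec`.
#' @export
toy_spec <- function(n_pocket_residues = 5, residue_names = NULL,
                     strengths = NULL, ligand_charge = 1,
                     n_frames = 100, jitter = 0.05, radius = 4.8,
                     frame_interval = 1) {
  stopifnot(n_pocket_residues >= 1)
  if (is.null(residue_names)) {
    residue_names <- rep(c("SER", "GLU"),
                         length.out = n_pocket_residues)
  } else {
    residue_names <- rep(residue_names, length.out = n_pocket_residues)
  }
  if (is.null(strengths)) strengths <- rep(1, n_pocket_residues)
  strengths <- rep(strengths, length.out = n_pocket_residues)
  stopifnot(all(residue_names %in% names(.toy_templates)),
            all(strengths > 0))
  structure(list(n_pocket_residues = n_pocket_residues,
                 residue_names = residue_names, strengths = strengths,
                 ligand_charge = ligand_charge, n_frames = n_frames,
                 jitter = jitter, radius = radius,
                 frame_interval = frame_interval),
            class = "ToySpec")
}

#' Build a toy host-guest complex and jittered trajectory
#'
#' A miniature "protein" of 5-9-atom residues arranged on a ring
#' around a 5-atom charged ligand, fully parameterized (charges,
#' Lennard-Jones, GB radii/screens), with frames generated as the
#' reference geometry plus seeded Gaussian jitter. Sidechain
#' Lennard-Jones well depths beyond Cbeta are scaled by the planted
#' per-residue strengths, so a full alanine scan recovers the planted
#' ranking.
#'
#' @param spec a [toy_spec()].
#' @param seed integer seed; the construction is a pure function of
#'   (spec, seed).
#' @return list with `system` (ParamSystem) and `trajectory`.
#' @export
make_toy_complex <- function(spec = toy_spec(), seed = 1) {
  nres <- spec$n_pocket_residues
  atoms <- list(); coords <- list(); residues <- list()
  serial <- 0L
  for (k in seq_len(nres)) {
    tpl <- .toy_templates[[spec$residue_names[k]]]
    th <- 2 * pi * (k - 1) / nres
    u <- c(-cos(th), -sin(th), 0)      # toward the ligand at the origin
    tv <- c(-sin(th), cos(th), 0)      # backbone tangent
    zv <- c(0, 0, 1)
    tip <- max(tpl$offsets[, 1])       # sidechain extent along u
    base <- -(spec$radius + tip) * u   # CA position
    off <- tpl$offsets
    co <- t(apply(off, 1, function(o) base + o[1] * u + o[2] * tv +
                    o[3] * zv))
    q <- tpl$charges + (tpl$net - sum(tpl$charges)) / length(tpl$charges)
    lj <- t(vapply(tpl$elements, function(e) .toy_lj[[e]], numeric(2)))
    eps <- lj[, 2]
    beyond <- !(tpl$atoms %in% c(.backbone_names, "CB"))
    eps[beyond] <- eps[beyond] * spec$strengths[k]
    gb <- t(vapply(seq_along(tpl$atoms), function(i) {
      g <- default_gb_params(tpl$elements[i], tpl$atoms[i])
      c(g$gb_radius, g$gb_screen)
    }, numeric(2)))
    atoms[[k]] <- data.frame(
      serial = serial + seq_along(tpl$atoms),
      name = tpl$atoms, element = tpl$elements, residue_index = k,
      charge = q, rmin_half = lj[, 1], epsilon = eps,
      gb_radius = gb[, 1], gb_screen = gb[, 2],
      stringsAsFactors = FALSE)
    coords[[k]] <- co
    residues[[k]] <- data.frame(
      index = k, name = spec$residue_names[k], chain = "A", resno = k,
      first_atom = serial + 1L, last_atom = serial + length(tpl$atoms),
      polarity_class = classify_residue(spec$residue_names[k]),
      is_ligand = FALSE, stringsAsFactors = FALSE)
    serial <- serial + length(tpl$atoms)
  }
  # 5-atom tetrahedral-ish ligand, formal charge on the central atom
  lig_names <- c("N1", "C1", "C2", "C3", "C4")
  lig_el <- c("N", "C", "C", "C", "C")
  lig_co <- rbind(c(0, 0, 0),
                  c(1.5, 0, 0), c(-0.5, 1.41, 0),
                  c(-0.5, -0.71, 1.22), c(-0.5, -0.71, -1.22))
  lig_q <- c(spec$ligand_charge - 4 * 0.05, rep(0.05, 4))
  lig_lj <- t(vapply(lig_el, function(e) .toy_lj[[e]], numeric(2)))
  lig_gb <- t(vapply(seq_along(lig_names), function(i) {
    g <- default_gb_params(lig_el[i], lig_names[i])
    c(g$gb_radius, g$gb_screen)
  }, numeric(2)))
  atoms[[nres + 1L]] <- data.frame(
    serial = serial + seq_along(lig_names),
    name = lig_names, element = lig_el, residue_index = nres + 1L,
    charge = lig_q, rmin_half = lig_lj[, 1], epsilon = lig_lj[, 2],
    gb_radius = lig_gb[, 1], gb_screen = lig_gb[, 2],
    stringsAsFactors = FALSE)
  coords[[nres + 1L]] <- lig_co
  residues[[nres + 1L]] <- data.frame(
    index = nres + 1L, name = "LIG", chain = "B", resno = nres + 1L,
    first_atom = serial + 1L, last_atom = serial + length(lig_names),
    polarity_class = NA_character_, is_ligand = TRUE,
    stringsAsFactors = FALSE)

  ref <- do.call(rbind, coords)
  sys <- param_system(do.call(rbind, atoms), do.call(rbind, residues),
                      coords = ref)
  na <- nrow(ref)
  arr <- withr::with_seed(seed, {
    jit <- array(stats::rnorm(na * 3 * spec$n_frames, 0, spec$jitter),
                 dim = c(na, 3L, spec$n_frames))
    array(rep(ref, spec$n_frames), dim = c(na, 3L, spec$n_frames)) + jit
  })
  list(system = sys,
       trajectory = trajectory(arr, frame_interval = spec$frame_interval))
}

#' Seeded Gaussian interaction-energy series
#'
#' @param mu mean (kcal/mol).
#' @param sigma SD (kcal/mol, >= 0).
#' @param n length (>= 1).
#' @param seed integer seed.
#' @return numeric vector.
#' @export
gaussian_energy_series <- function(mu, sigma, n, seed = 1) {
  stopifnot(sigma >= 0, n >= 1)
  if (sigma == 0) return(rep(mu, n))
  withr::with_seed(seed, stats::rnorm(n, mu, sigma))
}

#' Trajectory with planted hydrogen-bond geometry at a target occupancy
#'
#' A donor-H-acceptor triad toggles per frame between a bonded geometry
#' (donor-acceptor 3.0 Angstrom, donor-H-acceptor angle 165 degrees)
#' and a broken geometry (4.5 Angstrom, 100 degrees), with i.i.d.
#' Bernoulli(occupancy_target/100) draws.
#'
#' @param occupancy_target percent, in [0, 100].
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return list with `trajectory` (3 atoms: donor heavy, hydrogen,
#'   acceptor), `donor`, `hydrogen`, `acceptor` indices, and `bonded`
#'   (the planted per-frame indicator).
#' @export
planted_hbond_trajectory <- function(occupancy_target, n_frames,
                                     seed = 1) {
  stopifnot(occupancy_target >= 0, occupancy_target <= 100,
            n_frames >= 1)
  triad <- function(dist, angle_deg) {
    # donor at origin, H at (1,0,0); acceptor placed so that the
    # D-A distance is `dist` and the D-H-A angle is `angle_deg`
    cs <- cos((180 - angle_deg) * pi / 180)
    len <- -cs + sqrt(cs^2 + dist^2 - 1)
    a <- c(1, 0, 0) + len * c(cs, sin((180 - angle_deg) * pi / 180), 0)
    rbind(c(0, 0, 0), c(1, 0, 0), a)
  }
  bonded_geo <- triad(3.0, 165)
  broken_geo <- triad(4.5, 100)
  bonded <- withr::with_seed(seed, stats::runif(n_frames) <
                               occupancy_target / 100)
  arr <- array(NA_real_, dim = c(3L, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    arr[, , f] <- if (bonded[f]) bonded_geo else broken_geo
  }
  list(trajectory = trajectory(arr), donor = 1L, hydrogen = 2L,
       acceptor = 3L, bonded = bonded)
}

#' Write toy fixtures (PDB + trajectory + parameter CSV) to a directory
#'
#' Convenience emitter used by the analysis scripts: the reference
#' frame as PDB, the trajectory as multi-MODEL PDB and long CSV, and
#' the per-atom parameter table as CSV keyed by serial.
#'
#' @param toy result of [make_toy_complex()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_toy_fixtures <- function(toy, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "toy_complex.pdb")
  p2 <- file.path(dir, "toy_trajectory.pdb")
  p3 <- file.path(dir, "toy_trajectory.csv")
  p4 <- file.path(dir, "toy_parameters.csv")
  write_structure(toy$system, file = p1)
  write_pdb_trajectory(toy$system, toy$trajectory, p2)
  write_trajectory_csv(toy$trajectory, p3)
  a <- toy$system$atoms
  utils::write.csv(data.frame(
    serial = a$serial,
    residue = toy$system$residues$name[a$residue_index],
    atom = a$name, charge_e = a$charge, rmin_half_A = a$rmin_half,
    epsilon_kcal = a$epsilon, gb_radius_A = a$gb_radius,
    gb_screen = a$gb_screen), p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
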