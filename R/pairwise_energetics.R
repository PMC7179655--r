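# Gas-phase molecular-mechanics interaction energies between two atom
# groups: Coulomb (with an interior-dielectric divisor) and
# Lennard-Jones 12-6 with Lorentz-Berthelot combination. No nonbonded
# cutoff: end-state post-processing evaluates every cross pair.

.check_groups <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("atom groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("atom groups must be disjoint")
  }
}

.group_dist <- function(coords, group_a, group_b) {
  d <- .cross_dist(coords[group_a, , drop = FALSE],
                   coords[group_b, , drop = FALSE])
  if (any(d < 1e-6)) stop("overlapping atoms between groups (r < 1e-6 A)")
  d
}

#' Coulomb interaction energy between two atom groups
#'
#' Sum over cross pairs of `k_e q_i q_j / (eps_in r_ij)` with
#' `k_e = 332.0636` kcal A / (mol e^2).
#'
#' @param coords n_atoms x 3 coordinate matrix (Angstrom).
#' @param charges per-atom partial charges (e).
#' @param group_a,group_b disjoint atom index vectors.
#' @param eps_in interior dielectric divisor (>= 1).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(coords, charges, group_a, group_b, eps_in = 1) {
  .check_groups(group_a, group_b)
  if (eps_in < 1) stop("eps_in must be >= 1")
  d <- .group_dist(coords, group_a, group_b)
  qa <- charges[group_a]
  qb <- charges[group_b]
  KCOUL / eps_in * sum(outer(qa, qb) / d)
}

#' Lennard-Jones interaction energy between two atom groups
#'
#' Sum over cross pairs of
#' `eps_ij [(Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6]` with Lorentz-Berthelot
#' combination `Rmin_ij = rmin_half_i + rmin_half_j`,
#' `eps_ij = sqrt(eps_i eps_j)`.
#'
#' @inheritParams coulomb_energy
#' @param rmin_half per-atom Rmin/2 (Angstrom).
#' @param epsilon per-atom well depth (kcal/mol).
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(coords, rmin_half, epsilon, group_a, group_b) {
  .check_groups(group_a, group_b)
  d <- .group_dist(coords, group_a, group_b)
  rmin <- outer(rmin_half[group_a], rmin_half[group_b], "+")
  eps <- sqrt(outer(epsilon[group_a], epsilon[group_b]))
  sr6 <- (rmin / d)^6
  sum(eps * (sr6^2 - 2 * sr6))
}

#' Per-frame residue-ligand interaction energy series
#'
#' Evaluates the Coulomb and Lennard-Jones interaction between one
#' residue's atoms and the ligand atoms in every frame. The dielectric
#' divisor for the Coulomb term defaults to the geometric-mean pair
#' dielectric between the residue's polarity-class value (1/3/10) and
#' the ligand's (1), i.e. `sqrt(eps_class)` — the same mixing rule the
#' GB term uses, so the direct and reaction-field electrostatics of a
#' scanned residue are screened consistently.
#'
#' @param traj Trajectory.
#' @param sys parameterized ParamSystem.
#' @param residue residue index (must not be the ligand).
#' @param eps_in Coulomb dielectric divisor; default from the residue's
#'   polarity class.
#' @param frames optional frame subset.
#' @param group_b optional atom group to interact with (default: the
#'   ligand atoms).
#' @param dielectrics class-to-dielectric table used for the default
#'   `eps_in`.
#' @return an `EnergySeries`: list with `frame_times`, `e_vdw`, `e_ele`,
#'   `e_total`, `group_a`, `group_b`.
#' @export
interaction_energy_series <- function(traj, sys, residue, eps_in = NULL,
                                      frames = NULL, group_b = NULL,
                                      dielectrics = .default_dielectrics) {
  if (n_frames(traj) == 0L) stop("empty trajectory")
  if (is.null(group_b)) group_b <- ligand_atoms(sys)
  group_a <- residue_atoms(sys, residue)
  if (sys$residues$is_ligand[residue]) stop("residue must not be the ligand")
  if (is.null(eps_in)) {
    eps_in <- sqrt(dielectric_for(sys$residues$polarity_class[residue],
                                  dielectrics))
  }
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  q <- sys$atoms$charge
  rh <- sys$atoms$rmin_half
  ep <- sys$atoms$epsilon
  ev <- numeric(length(frames))
  ee <- numeric(length(frames))
  for (k in seq_along(frames)) {
    co <- traj$coords[, , frames[k], drop = TRUE]
    ev[k] <- lj_energy(co, rh, ep, group_a, group_b)
    ee[k] <- coulomb_energy(co, q, group_a, group_b, eps_in)
  }
  energy_series(traj$times[frames], ev, ee, group_a, group_b)
}

#' Construct an EnergySeries
#'
#' @param frame_times times in ps.
#' @param e_vdw,e_ele per-frame energies (kcal/mol).
#' @param group_a,group_b atom index sets the series refers to.
#' @return object of class `EnergySeries` (`e_total = e_vdw + e_ele`).
#' @export
energy_series <- function(frame_times, e_vdw, e_ele,
                          group_a = integer(), group_b = integer()) {
  stopifnot(length(e_vdw) == length(e_ele),
            length(frame_times) == length(e_vdw))
  structure(list(frame_times = frame_times, e_vdw = e_vdw, e_ele = e_ele,
                 e_total = e_vdw + e_ele,
                 group_a = group_a, group_b = group_b),
            class = "EnergySeries")
}

#' @export
print.EnergySeries <- function(x, ...) {
  cat(sprintf(
    "EnergySeries: %d frames, <E_vdw>=%.3f <E_ele>=%.3f <E_tot>=%.3f kcal/mol\n",
    length(x$e_total), mean(x$e_vdw), mean(x$e_ele), mean(x$e_total)))
  invisible(x)
}
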