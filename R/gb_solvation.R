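# Generalized-Born polar solvation: OBC effective radii (igb = 2
# parameterization) and the pairwise GB energy with residue-class
# interior dielectrics.

#' GB context: dielectrics and OBC shape constants
#'
#' Defaults are the igb = 2 (OBC-II) parameterization: offset 0.09 A,
#' alpha 1.0, beta 0.8, gamma 4.85, exterior dielectric 80, zero salt.
#'
#' @param eps_out exterior (solvent) dielectric.
#' @param offset intrinsic-radius offset in Angstrom.
#' @param alpha,beta,gamma_obc dimensionless OBC tanh coefficients.
#' @return list of class `GBContext`.
#' @export
gb_context <- function(eps_out = 80.0, offset = 0.09,
                       alpha = 1.0, beta = 0.8, gamma_obc = 4.85) {
  stopifnot(eps_out > 1, offset >= 0)
  structure(list(eps_out = eps_out, offset = offset, alpha = alpha,
                 beta = beta, gamma_obc = gamma_obc),
            class = "GBContext")
}

#' Effective Born radii by the OBC (igb = 2) model
#'
#' Pairwise Hawkins-Cramer-Truhlar descreening integrals (closed form,
#' screened neighbor radii) rescaled through the OBC tanh function:
#' `1/R_i = 1/rho_i' - tanh(alpha*Psi - beta*Psi^2 + gamma*Psi^3)/rho_i`
#' with `rho_i' = rho_i - offset` and `Psi = I_i * rho_i'`.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param gb_radius intrinsic Born radii rho (Angstrom), all > offset.
#' @param gb_screen dimensionless descreening scale factors.
#' @param context a [gb_context()].
#' @return per-atom effective radii (Angstrom).
#' @export
effective_born_radii <- function(coords, gb_radius, gb_screen,
                                 context = gb_context()) {
  n <- length(gb_radius)
  stopifnot(nrow(coords) == n, length(gb_screen) == n)
  if (any(gb_radius <= context$offset)) {
    stop("all intrinsic radii must exceed the offset")
  }
  rho_t <- gb_radius - context$offset
  if (n == 1L) {
    psi <- 0
  } else {
    d <- .cross_dist(coords, coords)
    if (any(d[upper.tri(d)] < 1e-6)) {
      stop("overlapping atoms: descreening integral not finite")
    }
    diag(d) <- 1 # dummy, masked below
    oi <- matrix(rho_t, n, n)                       # rho_i' by row
    sk <- matrix(gb_screen * rho_t, n, n, byrow = TRUE) # s_j rho_j' by col
    u <- d + sk
    l <- pmax(oi, abs(d - sk))
    term <- 0.5 * (1 / l - 1 / u +
                   0.25 * (d - sk^2 / d) * (1 / u^2 - 1 / l^2) +
                   0.5 * log(l / u) / d)
    inside <- sk > d + oi # atom i engulfed by neighbor's scaled sphere
    term[inside] <- term[inside] + (1 / oi[inside] - 1 / l[inside])
    mask <- (u > oi)
    diag(mask) <- FALSE
    term[!mask] <- 0
    integral <- rowSums(term)
    psi <- integral * rho_t
  }
  arg <- context$alpha * psi - context$beta * psi^2 +
    context$gamma_obc * psi^3
  rinv <- 1 / rho_t - tanh(arg) / gb_radius
  if (any(!is.finite(rinv)) || any(rinv <= 0)) {
    stop("non-finite or non-positive effective Born radius")
  }
  1 / rinv
}

#' Generalized-Born polar solvation energy
#'
#' `E = -(k_e/2) sum_{i,j} (1/eps_in_ij - 1/eps_out) q_i q_j /
#' f_GB(r_ij, R_i, R_j)` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`; the i = j self
#' terms reduce to `f_GB = R_i`. Mixed interior dielectrics combine as
#' the geometric mean `eps_ij = sqrt(eps_i eps_j)` (symmetric, reduces
#' to the pure case).
#'
#' @param coords n x 3 coordinate matrix.
#' @param charges per-atom charges (e).
#' @param born_radii per-atom effective Born radii (Angstrom).
#' @param eps_in scalar or per-atom interior dielectric(s).
#' @param context a [gb_context()].
#' @return energy in kcal/mol.
#' @export
gb_energy <- function(coords, charges, born_radii, eps_in = 1,
                      context = gb_context()) {
  n <- length(charges)
  stopifnot(length(born_radii) == n, all(born_radii > 0))
  d <- .cross_dist(coords, coords)
  rr <- outer(born_radii, born_radii)
  fgb <- sqrt(d^2 + rr * exp(-d^2 / (4 * rr)))
  pref <- if (length(eps_in) == 1L) {
    (1 / eps_in - 1 / context$eps_out)
  } else {
    stopifnot(length(eps_in) == n)
    (1 / sqrt(outer(eps_in, eps_in)) - 1 / context$eps_out)
  }
  -(KCOUL / 2) * sum(pref * outer(charges, charges) / fgb)
}

#' GB solvation energy of a species (atom subset) of a system
#'
#' Recomputes effective Born radii for the given atom subset in
#' isolation (descreening only by atoms of that species), then
#' evaluates [gb_energy()] with per-atom class dielectrics.
#'
#' @param sys parameterized ParamSystem.
#' @param coords full-system frame (n_atoms x 3).
#' @param atoms atom indices of the species.
#' @param context a [gb_context()].
#' @param eps_in per-atom dielectric vector over all system atoms
#'   (default from [atom_dielectrics()]).
#' @return list with `energy` (kcal/mol) and `radii`.
#' @export
gb_species_energy <- function(sys, coords, atoms, context = gb_context(),
                              eps_in = NULL) {
  if (is.null(eps_in)) eps_in <- atom_dielectrics(sys)
  co <- coords[atoms, , drop = FALSE]
  r <- effective_born_radii(co, sys$atoms$gb_radius[atoms],
                            sys$atoms$gb_screen[atoms], context)
  e <- gb_energy(co, sys$atoms$charge[atoms], r, eps_in[atoms], context)
  list(energy = e, radii = r)
}

#' GB component of the complexation solvation energy for one frame
#'
#' `dG_gb = G_gb(complex) - G_gb(protein) - G_gb(ligand)`, each species
#' evaluated with Born radii recomputed for its own atom set.
#'
#' @inheritParams gb_species_energy
#' @return list with per-species energies and `delta`.
#' @export
gb_delta_solvation <- function(sys, coords, context = gb_context(),
                               eps_in = NULL) {
  if (is.null(eps_in)) eps_in <- atom_dielectrics(sys)
  lig <- ligand_atoms(sys)
  all_at <- seq_len(nrow(sys$atoms))
  prot <- setdiff(all_at, lig)
  ec <- gb_species_energy(sys, coords, all_at, context, eps_in)$energy
  ep <- gb_species_energy(sys, coords, prot, context, eps_in)$energy
  el <- gb_species_energy(sys, coords, lig, context, eps_in)$energy
  list(complex = ec, protein = ep, ligand = el, delta = ec - ep - el)
}
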