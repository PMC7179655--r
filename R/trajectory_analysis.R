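# Structural trajectory analytics: Kabsch superposition, RMSD and
# 2D-RMSD, isotropic B-factors, hydrogen-bond detection/occupancy,
# and center-of-mass distances.

#' Kabsch least-squares superposition
#'
#' Returns the rigid transform (rotation + translation) that best maps
#' `mobile` onto `ref`, and the transformed coordinates.
#'
#' @param mobile,ref n x 3 coordinate matrices (same n, n >= 3).
#' @return list with `xyz` (transformed mobile), `rotation`,
#'   `translation`.
#' @export
kabsch_superpose <- function(mobile, ref) {
  if (nrow(mobile) < 3L) stop("superposition needs >= 3 atoms")
  stopifnot(nrow(mobile) == nrow(ref))
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  xm <- sweep(mobile, 2, cm)
  xr <- sweep(ref, 2, cr)
  s <- svd(crossprod(xm, xr)) # t(xm) %*% xr
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(xyz = sweep(xm %*% rot, 2, cr, "+"), rotation = rot,
       translation = cr - c(cm %*% rot))
}

#' Root-mean-square deviation between two frames
#'
#' With `superpose = TRUE` (default) an optimal Kabsch superposition on
#' the selection is applied first.
#'
#' @param a,b n x 3 coordinate matrices.
#' @param selection atom indices to compare (default all).
#' @param superpose apply least-squares superposition first.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL, superpose = TRUE) {
  if (!is.null(selection)) {
    a <- a[selection, , drop = FALSE]
    b <- b[selection, , drop = FALSE]
  }
  stopifnot(nrow(a) == nrow(b))
  if (superpose) a <- kabsch_superpose(a, b)$xyz
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD series against a reference frame
#'
#' @param traj Trajectory.
#' @param ref reference frame (n_atoms x 3).
#' @inheritParams rmsd
#' @return numeric vector over frames (Angstrom).
#' @export
rmsd_series <- function(traj, ref, selection = NULL, superpose = TRUE) {
  vapply(seq_len(n_frames(traj)), function(f) {
    rmsd(get_frame(traj, f), ref, selection, superpose)
  }, numeric(1))
}

#' 2D-RMSD matrix between two trajectories
#'
#' `M[i, j] = rmsd(frame i of a, frame j of b)` with superposition;
#' symmetric when both arguments are the same trajectory. Selections
#' must map atom-to-atom between the two systems.
#'
#' @param traj_a,traj_b Trajectories (`traj_b` defaults to `traj_a`).
#' @param sel_a,sel_b equal-length atom selections.
#' @param stride frame stride (default 1).
#' @param superpose apply Kabsch superposition per cell.
#' @return matrix of RMSD values (Angstrom) with frame indices as
#'   dimnames.
#' @export
rmsd_matrix <- function(traj_a, traj_b = NULL, sel_a = NULL, sel_b = sel_a,
                        stride = 1, superpose = TRUE) {
  self <- is.null(traj_b)
  if (self) traj_b <- traj_a
  if (!is.null(sel_a) && !is.null(sel_b) &&
      length(sel_a) != length(sel_b)) {
    stop("selections must have equal length")
  }
  fa <- seq(1, n_frames(traj_a), by = stride)
  fb <- seq(1, n_frames(traj_b), by = stride)
  m <- matrix(NA_real_, length(fa), length(fb),
              dimnames = list(fa, fb))
  for (i in seq_along(fa)) {
    ca <- get_frame(traj_a, fa[i])
    if (!is.null(sel_a)) ca <- ca[sel_a, , drop = FALSE]
    jseq <- if (self) i:length(fb) else seq_along(fb)
    for (j in jseq) {
      cb <- get_frame(traj_b, fb[j])
      if (!is.null(sel_b)) cb <- cb[sel_b, , drop = FALSE]
      m[i, j] <- rmsd(ca, cb, superpose = superpose)
      if (self) m[j, i] <- m[i, j]
    }
  }
  m
}

#' Isotropic B-factors from a trajectory
#'
#' `B_i = (8 pi^2 / 3) <|r_i - <r_i>|^2>` after (optionally) aligning
#' every frame to the first frame on `fit_selection`.
#'
#' @param traj Trajectory (>= 2 frames).
#' @param selection atoms to report (default all).
#' @param align superpose frames before computing fluctuations.
#' @param fit_selection atoms used for the superposition (default: the
#'   reported selection, or all atoms).
#' @return numeric vector of B-factors (Angstrom^2).
#' @export
bfactor <- function(traj, selection = NULL, align = TRUE,
                    fit_selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("B-factor needs >= 2 frames")
  na <- dim(traj$coords)[1]
  if (is.null(selection)) selection <- seq_len(na)
  if (is.null(fit_selection)) fit_selection <- selection
  co <- traj$coords
  if (align) {
    ref <- co[fit_selection, , 1, drop = TRUE]
    co2 <- co
    for (f in 2:nf) {
      fit <- kabsch_superpose(co[fit_selection, , f, drop = TRUE], ref)
      co2[, , f] <- sweep(co[, , f, drop = TRUE] %*% fit$rotation,
                          2, fit$translation, "+")
    }
    co <- co2
  }
  co <- co[selection, , , drop = FALSE]
  mu <- apply(co, c(1, 2), mean)
  msf <- numeric(length(selection))
  for (f in seq_len(nf)) {
    dev <- co[, , f, drop = TRUE] - mu
    if (is.null(dim(dev))) dev <- matrix(dev, ncol = 3)
    msf <- msf + rowSums(dev^2)
  }
  msf <- msf / nf
  (8 * pi^2 / 3) * msf
}

# Angle (degrees) at vertex b of points a-b-c.
.angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' A donor/acceptor pair is reported when the donor-heavy-atom to
#' acceptor distance is `<= d_cut` AND the donor-H-acceptor angle is
#' `>= a_cut` (both cutoffs inclusive). Carbon donors are allowed: weak
#' CA-HA / CB-HB hydrogen bonds are part of the analysis.
#'
#' @param coords n x 3 frame.
#' @param donors data.frame with columns `heavy` and `hydrogen` (atom
#'   indices; every donor must carry an attached hydrogen).
#' @param acceptors vector of acceptor atom indices.
#' @param d_cut distance cutoff in Angstrom (default 3.5).
#' @param a_cut angle cutoff in degrees (default 120).
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` (one row per detected bond).
#' @export
detect_hbonds <- function(coords, donors, acceptors, d_cut = 3.5,
                          a_cut = 120) {
  if (anyNA(donors$hydrogen)) stop("donor without an attached hydrogen")
  out <- list()
  for (k in seq_len(nrow(donors))) {
    dh <- donors$heavy[k]
    hh <- donors$hydrogen[k]
    for (ac in setdiff(acceptors, c(dh, hh))) {
      dist <- sqrt(sum((coords[dh, ] - coords[ac, ])^2))
      if (dist > d_cut) next
      ang <- .angle_deg(coords[dh, ], coords[hh, ], coords[ac, ])
      if (ang >= a_cut) {
        out[[length(out) + 1L]] <- data.frame(
          donor = dh, hydrogen = hh, acceptor = ac,
          distance = dist, angle = ang)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  }
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Occupancy is the percentage of frames in which the geometric
#' criteria hold; the mean distance and angle are averaged over ALL
#' frames (so the mean distance can exceed the cutoff and the mean
#' angle can fall below it while the occupancy stays nonzero).
#'
#' @param traj Trajectory.
#' @param donor,hydrogen,acceptor atom indices of the triad.
#' @inheritParams detect_hbonds
#' @return `HBondRecord`: one-row data.frame with `donor`, `hydrogen`,
#'   `acceptor`, `mean_distance`, `mean_angle`, `occupancy` (percent),
#'   `n_frames`.
#' @export
hbond_occupancy <- function(traj, donor, hydrogen, acceptor, d_cut = 3.5,
                            a_cut = 120) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("need >= 1 frame")
  dist <- numeric(nf)
  ang <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- get_frame(traj, f)
    dist[f] <- sqrt(sum((co[donor, ] - co[acceptor, ])^2))
    ang[f] <- .angle_deg(co[donor, ], co[hydrogen, ], co[acceptor, ])
  }
  bonded <- dist <= d_cut & ang >= a_cut
  data.frame(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
             mean_distance = mean(dist), mean_angle = mean(ang),
             occupancy = 100 * mean(bonded), n_frames = nf)
}

#' Center-of-mass distance series between two atom groups
#'
#' @param traj Trajectory.
#' @param group_a,group_b non-empty atom index vectors.
#' @param masses per-atom masses over all atoms; defaults to standard
#'   atomic masses from `sys`, or unit weights (geometric centroid)
#'   when neither is given.
#' @param sys optional ParamSystem supplying elements for the mass
#'   lookup.
#' @return list with `series` (per-frame distances, Angstrom) and
#'   `mean`.
#' @export
com_distance <- function(traj, group_a, group_b, masses = NULL,
                         sys = NULL) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("groups must be non-empty")
  }
  na <- dim(traj$coords)[1]
  if (is.null(masses)) {
    masses <- if (!is.null(sys)) atomic_mass(sys$atoms$element)
              else rep(1, na)
  }
  ma <- masses[group_a]
  mb <- masses[group_b]
  if (sum(ma) <= 0 || sum(mb) <= 0) stop("zero total mass in a group")
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- get_frame(traj, f)
    ca <- colSums(co[group_a, , drop = FALSE] * ma) / sum(ma)
    cb <- colSums(co[group_b, , drop = FALSE] * mb) / sum(mb)
    out[f] <- sqrt(sum((ca - cb)^2))
  }
  list(series = out, mean = mean(out))
}
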