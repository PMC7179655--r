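# Single-trajectory computational alanine scanning: sidechain
# truncation beyond Cbeta, per-window ddG component assembly
# (MM + GB + SASA enthalpy, interaction-entropy term), totals and
# hot-spot classification.

.backbone_names <- c("N", "H", "H1", "H2", "H3", "HN", "CA", "HA",
                     "HA2", "HA3", "C", "O", "OXT")
.beta_names <- c("CB", "HB", "HB1", "HB2", "HB3")
.gamma_heavy <- c("CG", "CG1", "OG", "OG1", "SG")

.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            HIE = "H", HID = "H", HIP = "H", ASH = "D", GLH = "E",
            LYN = "K", CYX = "C")

#' Mutation label for a residue (e.g. "Y907A")
#'
#' @param sys ParamSystem.
#' @param residue residue index.
#' @return character label: one-letter wild-type code, residue number,
#'   "A".
#' @export
mutation_label <- function(sys, residue) {
  r <- sys$residues[residue, ]
  one <- .aa321[toupper(r$name)]
  if (is.na(one)) one <- "X"
  paste0(one, r$resno, "A")
}

#' Truncate a residue's sidechain to alanine
#'
#' Single-trajectory mutant generation: every sidechain atom beyond
#' Cbeta is deleted in every frame; the gamma heavy atom (or first
#' gamma hydrogen) is retained as a methyl hydrogen HB1 repositioned at
#' 1.09 Angstrom along the original Cbeta-gamma bond vector. The methyl
#' group receives standard alanine charges and Lennard-Jones/GB
#' parameters, with the residual charge placed on HB1 so the mutant
#' residue's net charge is exactly alanine's (0). Backbone atoms and
#' coordinates are untouched. An ALA target is the identity mutation.
#'
#' @param sys parameterized ParamSystem.
#' @param traj Trajectory over the same atoms (optional).
#' @param residue residue index; must have a Cbeta (GLY unsupported).
#' @return list with `system`, `trajectory` (NULL if none supplied),
#'   `label`, and `kept` (original atom indices of the mutant's atoms;
#'   the repositioned HB1 keeps the gamma atom's index).
#' @export
mutate_to_alanine <- function(sys, traj = NULL, residue) {
  res <- sys$residues[residue, ]
  if (res$is_ligand) stop("cannot mutate the ligand")
  if (toupper(res$name) == "GLY") {
    stop("unsupported mutation: GLY has no Cbeta to truncate to")
  }
  at <- residue_atoms(sys, residue)
  names_r <- sys$atoms$name[at]
  if (!"CB" %in% names_r) {
    stop("topology error: residue ", mutation_label(sys, residue),
         " has no CB atom")
  }
  keep_local <- names_r %in% c(.backbone_names, .beta_names)
  beyond <- at[!keep_local]
  if (length(beyond) == 0L) {
    # ALA (or already-truncated residue): identity mutation
    return(list(system = sys, trajectory = traj,
                label = mutation_label(sys, residue),
                kept = seq_len(nrow(sys$atoms))))
  }
  gsel <- intersect(.gamma_heavy, names_r)
  if (length(gsel) == 0L) {
    gh <- grep("^HG", names_r, value = TRUE)
    if (length(gh) == 0L) {
      stop("topology error: no gamma atom to retain as HB1 in ",
           mutation_label(sys, residue))
    }
    gsel <- gh[1]
  }
  gamma <- at[match(gsel[1], names_r)]
  cb <- at[match("CB", names_r)]

  removed <- setdiff(beyond, gamma)
  kept <- setdiff(seq_len(nrow(sys$atoms)), removed)

  a <- sys$atoms[kept, , drop = FALSE]
  rownames(a) <- NULL
  gi <- match(gamma, kept) # gamma row in the mutant table
  hb1_name <- if ("HB1" %in% names_r) "HB4" else "HB1"
  a$name[gi] <- hb1_name
  a$element[gi] <- "H"
  hb <- .ala_methyl$hb
  cbp <- .ala_methyl$cb
  a$charge[gi] <- hb$charge
  a$rmin_half[gi] <- hb$rmin_half
  a$epsilon[gi] <- hb$epsilon
  a$gb_radius[gi] <- hb$gb_radius
  a$gb_screen[gi] <- hb$gb_screen
  ci <- match(cb, kept)
  a$charge[ci] <- cbp$charge
  a$rmin_half[ci] <- cbp$rmin_half
  a$epsilon[ci] <- cbp$epsilon
  a$gb_radius[ci] <- cbp$gb_radius
  a$gb_screen[ci] <- cbp$gb_screen
  # existing beta hydrogens get standard methyl parameters
  res_rows <- which(a$residue_index[seq_len(nrow(a))] == residue &
                    a$name %in% c("HB", "HB1", "HB2", "HB3", "HB4") &
                    seq_len(nrow(a)) != gi)
  for (ri in res_rows) {
    a$charge[ri] <- hb$charge
    a$rmin_half[ri] <- hb$rmin_half
    a$epsilon[ri] <- hb$epsilon
    a$gb_radius[ri] <- hb$gb_radius
    a$gb_screen[ri] <- hb$gb_screen
  }
  # neutralize the mutant residue exactly (alanine formal charge 0)
  mres <- which(a$residue_index == residue)
  a$charge[gi] <- a$charge[gi] - sum(a$charge[mres])

  # rebuild residue ranges (contiguity preserved by subsetting)
  r <- sys$residues
  ridx <- a$residue_index
  first <- match(unique(ridx), ridx)
  last <- c(first[-1] - 1L, nrow(a))
  r <- r[unique(ridx), , drop = FALSE]
  r$first_atom <- first
  r$last_atom <- last
  rownames(r) <- NULL
  mi <- match(residue, unique(ridx))
  r$name[mi] <- "ALA"
  r$polarity_class[mi] <- "nonpolar"

  reposition <- function(co_full) {
    co <- co_full[kept, , drop = FALSE]
    v <- co_full[gamma, ] - co_full[cb, ]
    vn <- sqrt(sum(v^2))
    if (vn < 1e-9) stop("degenerate CB-gamma bond vector")
    co[gi, ] <- co_full[cb, ] + 1.09 * v / vn
    co
  }

  coords <- if (!is.null(sys$coords)) reposition(sys$coords) else NULL
  msys <- param_system(a, r, coords = coords)

  mtraj <- NULL
  if (!is.null(traj)) {
    nf <- n_frames(traj)
    arr <- array(NA_real_, dim = c(nrow(a), 3L, nf))
    for (f in seq_len(nf)) arr[, , f] <- reposition(get_frame(traj, f))
    mtraj <- trajectory(arr, times = traj$times,
                        frame_interval = traj$frame_interval)
  }
  list(system = msys, trajectory = mtraj,
       label = mutation_label(sys, residue), kept = kept)
}

#' Assemble single-window ddG components from wild and mutant inputs
#'
#' Signs follow the mutant-minus-wild convention: a positive ddG means
#' the wild-type residue stabilizes binding. Components:
#' `ddE = <E^a> - <E^x>` per MM term over the enthalpy frames;
#' `ddG_gb`/`ddG_np` as means of per-frame complexation solvation
#' differences; `-T ddS` as the difference of interaction entropies of
#' the (independently filtered) mutant and wild energy series.
#'
#' @param wild,mutant lists with elements `energy` (an
#'   [energy_series()]), optional `gb` and `np` (per-enthalpy-frame
#'   complexation solvation terms, kcal/mol), optional `enthalpy`
#'   (indices into the series used for the MM means; default all).
#' @param temperature K.
#' @param filter_sd outlier cutoff applied inside the entropy
#'   estimator (default 3; NULL disables).
#' @return one-row data.frame with `dd_e_vdw`, `dd_e_ele`, `dd_g_gb`,
#'   `dd_g_np`, `dd_h`, `minus_t_dd_s`, `dd_g`.
#' @export
ddg_components <- function(wild, mutant, temperature = 300,
                           filter_sd = 3) {
  if (length(wild$energy$e_total) != length(mutant$energy$e_total)) {
    stop("wild and mutant series must be frame-aligned (equal lengths)")
  }
  enth_w <- if (is.null(wild$enthalpy))
    seq_along(wild$energy$e_total) else wild$enthalpy
  enth_m <- if (is.null(mutant$enthalpy))
    seq_along(mutant$energy$e_total) else mutant$enthalpy
  dd_vdw <- mean(mutant$energy$e_vdw[enth_m]) - mean(wild$energy$e_vdw[enth_w])
  dd_ele <- mean(mutant$energy$e_ele[enth_m]) - mean(wild$energy$e_ele[enth_w])
  dd_gb <- if (is.null(wild$gb)) 0 else mean(mutant$gb) - mean(wild$gb)
  dd_np <- if (is.null(wild$np)) 0 else mean(mutant$np) - mean(wild$np)
  ie_w <- interaction_entropy(wild$energy$e_total, temperature, filter_sd)
  ie_m <- interaction_entropy(mutant$energy$e_total, temperature, filter_sd)
  mtdds <- ie_m$minus_t_ds - ie_w$minus_t_ds
  dd_h <- dd_vdw + dd_ele + dd_gb + dd_np
  data.frame(dd_e_vdw = dd_vdw, dd_e_ele = dd_ele, dd_g_gb = dd_gb,
             dd_g_np = dd_np, dd_h = dd_h, minus_t_dd_s = mtdds,
             dd_g = dd_h + mtdds)
}

# Per-frame solvation components (GB + nonpolar complexation deltas)
# for a system over a set of frames.
.solvation_deltas <- function(sys, traj, frames, context, eps_atoms,
                              probe, n_points, gamma, beta) {
  gb <- numeric(length(frames))
  np <- numeric(length(frames))
  for (k in seq_along(frames)) {
    co <- get_frame(traj, frames[k])
    gb[k] <- gb_delta_solvation(sys, co, context, eps_atoms)$delta
    np[k] <- np_delta_solvation(sys, co, probe, n_points, gamma, beta)$delta
  }
  list(gb = gb, np = np)
}

#' Scan one residue over a set of analysis windows
#'
#' Generates the truncated-sidechain mutant once, then assembles
#' per-window ddG components (MM terms and solvation on the equally
#' spaced enthalpy frames, interaction entropy on all window frames)
#' and aggregates mean and SD across windows.
#'
#' @param sys parameterized ParamSystem.
#' @param traj Trajectory.
#' @param windows data.frame with `start`, `end` (from
#'   [plan_windows()]); may span multiple replicates if frame indices
#'   refer to `traj`.
#' @param residue residue index to scan.
#' @param temperature K.
#' @param enthalpy_frames frames per window for the enthalpy terms.
#' @param filter_sd entropy outlier cutoff.
#' @param context [gb_context()].
#' @param dielectrics polarity-class dielectric table.
#' @param probe,n_points SASA parameters.
#' @param gamma,beta nonpolar model constants.
#' @return list with `record` (one-row aggregated data.frame) and
#'   `per_window` (per-window component data.frame).
#' @export
scan_residue <- function(sys, traj, windows, residue, temperature = 300,
                         enthalpy_frames = 100, filter_sd = 3,
                         context = gb_context(),
                         dielectrics = .default_dielectrics,
                         probe = 1.4, n_points = 960,
                         gamma = 0.00542, beta = 0.92) {
  mut <- mutate_to_alanine(sys, traj, residue)
  msys <- mut$system
  mtraj <- if (is.null(mut$trajectory)) traj else mut$trajectory
  mresidue <- match(residue, sort(unique(sys$atoms$residue_index[mut$kept])))
  eps_w <- atom_dielectrics(sys, dielectrics)
  # the mutant keeps the wild position's dielectric environment
  eps_m <- eps_w[mut$kept]
  eps_res <- sqrt(dielectric_for(sys$residues$polarity_class[residue],
                                 dielectrics))

  rows <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    fr <- windows$start[w]:windows$end[w]
    enth_rel <- match(enthalpy_frame_indices(windows$start[w],
                                             windows$end[w],
                                             enthalpy_frames), fr)
    es_w <- interaction_energy_series(traj, sys, residue, eps_in = eps_res,
                                      frames = fr,
                                      dielectrics = dielectrics)
    es_m <- interaction_energy_series(mtraj, msys, mresidue,
                                      eps_in = eps_res, frames = fr,
                                      dielectrics = dielectrics)
    sol_w <- .solvation_deltas(sys, traj, fr[enth_rel], context, eps_w,
                               probe, n_points, gamma, beta)
    sol_m <- .solvation_deltas(msys, mtraj, fr[enth_rel], context, eps_m,
                               probe, n_points, gamma, beta)
    rows[[w]] <- ddg_components(
      list(energy = es_w, gb = sol_w$gb, np = sol_w$np,
           enthalpy = enth_rel),
      list(energy = es_m, gb = sol_m$gb, np = sol_m$np,
           enthalpy = enth_rel),
      temperature, filter_sd)
  }
  per_window <- do.call(rbind, rows)
  per_window$window <- seq_len(nrow(windows))
  comp <- c("dd_e_vdw", "dd_e_ele", "dd_g_gb", "dd_g_np", "dd_h",
            "minus_t_dd_s", "dd_g")
  rec <- data.frame(mutation = mut$label, stringsAsFactors = FALSE)
  for (cn in comp) {
    if (nrow(per_window) >= 2L) {
      ag <- aggregate_windows(per_window[[cn]])
    } else {
      ag <- list(mean = per_window[[cn]][1], sd = NA_real_)
    }
    rec[[cn]] <- ag$mean
    rec[[paste0(cn, "_sd")]] <- ag$sd
  }
  rec$n_windows <- nrow(windows)
  list(record = rec, per_window = per_window)
}

#' Alanine-scan a set of residues
#'
#' @inheritParams scan_residue
#' @param residues residue indices (default: the 5-Angstrom pocket from
#'   [select_pocket()]); GLY targets are skipped with a message.
#' @param ... passed to [scan_residue()].
#' @return list with `records` (one row per mutation, sorted by `dd_g`
#'   descending) and `per_window` (long data.frame with a `mutation`
#'   column).
#' @export
alanine_scan <- function(sys, traj, windows, residues = NULL, ...) {
  if (is.null(residues)) residues <- select_pocket(sys)
  if (length(residues) == 0L) stop("no residues to scan")
  recs <- list()
  pw <- list()
  for (ri in residues) {
    if (toupper(sys$residues$name[ri]) == "GLY") {
      message("skipping GLY residue ", ri, " (no Cbeta)")
      next
    }
    sr <- scan_residue(sys, traj, windows, ri, ...)
    sr$per_window$mutation <- sr$record$mutation
    recs[[length(recs) + 1L]] <- sr$record
    pw[[length(pw) + 1L]] <- sr$per_window
  }
  records <- do.call(rbind, recs)
  records <- records[order(-records$dd_g), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, per_window = do.call(rbind, pw))
}

#' Total binding free energy from per-residue contributions
#'
#' `dG_bind = - sum_x ddG(x -> a)` over the pocket residues.
#'
#' @param records data.frame with a `dd_g` column (or a numeric vector
#'   of ddG values).
#' @return kcal/mol.
#' @export
total_binding_energy <- function(records) {
  v <- if (is.data.frame(records)) records$dd_g else records
  if (length(v) == 0L) stop("empty record list")
  -sum(v)
}

#' Classify hot-spot residues
#'
#' Residues whose ddG contribution exceeds the threshold (default
#' 1 kcal/mol), in descending ddG order.
#'
#' @param records data.frame with `mutation` and `dd_g` columns.
#' @param threshold kcal/mol (> 0).
#' @return data.frame subset in descending `dd_g` order; the residue
#'   part of the labels is in `residue` (mutation label minus the
#'   trailing "A").
#' @export
classify_hotspots <- function(records, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be positive")
  hs <- records[records$dd_g > threshold, , drop = FALSE]
  hs <- hs[order(-hs$dd_g), , drop = FALSE]
  hs$residue <- sub("A$", "", hs$mutation)
  rownames(hs) <- NULL
  hs
}

#' Whole-complex binding summary from window-level residue sums
#'
#' For each analysis window, sums the per-residue contributions with
#' the residue-sum sign convention (`dG_w = - sum_x ddG_{x,w}`, likewise for
#' the enthalpic and entropic parts) and reports mean and SD across
#' windows.
#'
#' @param scan result of [alanine_scan()] (uses `$per_window`).
#' @return `BindingSummary`: one-row data.frame with `dh_mean`,
#'   `dh_sd`, `minus_tds_mean`, `minus_tds_sd`, `dg_mean`, `dg_sd`,
#'   `n_windows`.
#' @export
binding_summary <- function(scan) {
  pw <- scan$per_window
  dh <- -tapply(pw$dd_h, pw$window, sum)
  tds <- -tapply(pw$minus_t_dd_s, pw$window, sum)
  dg <- -tapply(pw$dd_g, pw$window, sum)
  agg <- function(x) {
    if (length(x) >= 2L) aggregate_windows(x) else list(mean = x[1],
                                                        sd = NA_real_)
  }
  ah <- agg(as.numeric(dh)); at <- agg(as.numeric(tds))
  ag <- agg(as.numeric(dg))
  data.frame(dh_mean = ah$mean, dh_sd = ah$sd,
             minus_tds_mean = at$mean, minus_tds_sd = at$sd,
             dg_mean = ag$mean, dg_sd = ag$sd,
             n_windows = length(dh))
}

#' Binding free-energy difference implied by a Kd ratio
#'
#' `ddG = kT ln(ratio)`; e.g. a 154-fold Kd selectivity at 300 K is
#' 3.00 kcal/mol.
#'
#' @param ratio Kd ratio (> 0).
#' @param temperature K.
#' @return kcal/mol.
#' @export
ddg_from_kd_ratio <- function(ratio, temperature = 300) {
  if (ratio <= 0) stop("ratio must be positive")
  KBOLTZ * temperature * log(ratio)
}
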