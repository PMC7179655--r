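# Pipeline orchestration: configuration, end-to-end scan over replicate
# trajectories, report emission, run comparison, and loaders for the
# published reference tables shipped with the package.

#' Scan configuration with protocol defaults
#'
#' Defaults mirror the production protocol: 300 K, 5-Angstrom pocket,
#' five 5-ns windows per replicate, 100 enthalpy frames and all frames
#' for entropy per window, 3-SD outlier filter, 1 kcal/mol hot-spot
#' threshold, 1/3/10 residue-class dielectrics.
#'
#' @param temperature K.
#' @param pocket_cutoff Angstrom.
#' @param window_ps window length in ps.
#' @param n_windows windows per replicate.
#' @param enthalpy_frames enthalpy frames per window.
#' @param filter_sd outlier cutoff in SD units.
#' @param hotspot_threshold kcal/mol.
#' @param dielectrics named class-dielectric vector.
#' @param eps_out exterior dielectric.
#' @param probe SASA probe radius, Angstrom.
#' @param sasa_points SASA sphere points per atom.
#' @param gamma,beta nonpolar model constants.
#' @param rmsd_stride frame stride for the 2D-RMSD matrix.
#' @param seed integer seed recorded in the run log.
#' @return list of class `RunConfig`.
#' @export
scan_config <- function(temperature = 300, pocket_cutoff = 5.0,
                        window_ps = 5000, n_windows = 5,
                        enthalpy_frames = 100, filter_sd = 3,
                        hotspot_threshold = 1.0,
                        dielectrics = c(nonpolar = 1, polar = 3,
                                        charged = 10),
                        eps_out = 80, probe = 1.4, sasa_points = 960,
                        gamma = 0.00542, beta = 0.92,
                        rmsd_stride = NULL, seed = NULL) {
  stopifnot(temperature > 0, pocket_cutoff > 0, window_ps > 0)
  structure(list(temperature = temperature,
                 pocket_cutoff = pocket_cutoff, window_ps = window_ps,
                 n_windows = n_windows,
                 enthalpy_frames = enthalpy_frames,
                 filter_sd = filter_sd,
                 hotspot_threshold = hotspot_threshold,
                 dielectrics = dielectrics, eps_out = eps_out,
                 probe = probe, sasa_points = sasa_points,
                 gamma = gamma, beta = beta, rmsd_stride = rmsd_stride,
                 seed = seed),
            class = "RunConfig")
}

#' Read a RunConfig from a YAML file
#'
#' Unknown keys error; missing keys take the [scan_config()] defaults.
#'
#' @param path YAML file path.
#' @return `RunConfig`.
#' @export
read_scan_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scan_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(vals$dielectrics)) {
    vals$dielectrics <- unlist(vals$dielectrics)
  }
  do.call(scan_config, vals)
}

#' Run the full alanine-scanning pipeline
#'
#' For each replicate trajectory: computes the ligand heavy-atom RMSD
#' stability series against the reference frame, selects stable
#' analysis windows, and scans every pocket residue. Records are
#' aggregated across all windows of all replicates. Also emits the
#' trajectory analytics (backbone RMSD series, C-alpha B-factors,
#' pocket-backbone 2D-RMSD) and, if hydrogen-bond triads are supplied,
#' a Table-of-occupancies report.
#'
#' @param sys parameterized ParamSystem with a flagged ligand.
#' @param trajectories a `Trajectory` or list of replicate
#'   trajectories.
#' @param config a [scan_config()].
#' @param reference reference frame for pocket selection and RMSD
#'   (default `sys$coords`).
#' @param hbonds optional data.frame with columns `donor`, `hydrogen`,
#'   `acceptor` (atom indices) for the occupancy report.
#' @param output_dir if non-NULL, write the report bundle there via
#'   [write_bundle()].
#' @return report bundle: list with `records`, `per_window`, `summary`,
#'   `total_residue_sum`, `hotspots`, `pocket`, `windows`,
#'   `stability`, `rmsd_backbone`, `bfactor_ca`, `rmsd2d`, `hbonds`,
#'   `config`, `log`.
#' @export
run_scan <- function(sys, trajectories, config = scan_config(),
                     reference = NULL, hbonds = NULL,
                     output_dir = NULL) {
  t0 <- Sys.time()
  if (inherits(trajectories, "Trajectory")) {
    trajectories <- list(trajectories)
  }
  if (length(trajectories) == 0L) stop("stage config: no trajectories")
  if (is.null(reference)) reference <- sys$coords
  if (is.null(reference)) {
    stop("stage config: no reference coordinates available")
  }
  na <- nrow(sys$atoms)
  for (tr in trajectories) {
    if (dim(tr$coords)[1] != na) {
      stop("stage config: trajectory atom count does not match system")
    }
  }

  pocket <- select_pocket(sys, reference, config$pocket_cutoff)
  if (length(pocket) == 0L) stop("stage pocket: no residues within cutoff")

  lig_h <- heavy_atoms(sys, ligand_atoms(sys))
  bb <- which(sys$atoms$name %in% c("N", "CA", "C", "O") &
              !sys$residues$is_ligand[sys$atoms$residue_index])

  # stability + windows per replicate; frames re-indexed per replicate
  stability <- list(); windows <- list(); records_pw <- list()
  all_records <- NULL
  for (r in seq_along(trajectories)) {
    traj <- trajectories[[r]]
    st <- rmsd_series(traj, reference, lig_h,
                      superpose = length(lig_h) >= 3L)
    stability[[r]] <- st
    w <- plan_windows(st, traj$frame_interval, config$window_ps,
                      config$n_windows)
    w$replicate <- r
    windows[[r]] <- w
  }

  # scan each residue across replicates, pooling window-level rows
  scan_one <- function(ri) {
    pw <- list()
    lab <- NULL
    for (r in seq_along(trajectories)) {
      sr <- scan_residue(sys, trajectories[[r]],
                         windows[[r]][, c("start", "end")], ri,
                         temperature = config$temperature,
                         enthalpy_frames = config$enthalpy_frames,
                         filter_sd = config$filter_sd,
                         context = gb_context(eps_out = config$eps_out),
                         dielectrics = config$dielectrics,
                         probe = config$probe,
                         n_points = config$sasa_points,
                         gamma = config$gamma, beta = config$beta)
      sr$per_window$replicate <- r
      pw[[r]] <- sr$per_window
      lab <- sr$record$mutation
    }
    pw <- do.call(rbind, pw)
    pw$window <- seq_len(nrow(pw))
    pw$mutation <- lab
    comp <- c("dd_e_vdw", "dd_e_ele", "dd_g_gb", "dd_g_np", "dd_h",
              "minus_t_dd_s", "dd_g")
    rec <- data.frame(mutation = lab, stringsAsFactors = FALSE)
    for (cn in comp) {
      ag <- if (nrow(pw) >= 2L) aggregate_windows(pw[[cn]])
            else list(mean = pw[[cn]][1], sd = NA_real_)
      rec[[cn]] <- ag$mean
      rec[[paste0(cn, "_sd")]] <- ag$sd
    }
    rec$n_windows <- nrow(pw)
    list(record = rec, per_window = pw)
  }
  for (ri in pocket) {
    if (toupper(sys$residues$name[ri]) == "GLY") next
    res <- scan_one(ri)
    all_records <- rbind(all_records, res$record)
    records_pw[[length(records_pw) + 1L]] <- res$per_window
  }
  if (is.null(all_records)) stop("stage scan: no scannable pocket residues")
  all_records <- all_records[order(-all_records$dd_g), , drop = FALSE]
  rownames(all_records) <- NULL
  scan <- list(records = all_records,
               per_window = do.call(rbind, records_pw))
  summ <- binding_summary(scan)
  hots <- classify_hotspots(all_records, config$hotspot_threshold)

  # trajectory analytics on replicate 1
  traj1 <- trajectories[[1]]
  rb <- rmsd_series(traj1, reference, bb)
  ca <- which(sys$atoms$name == "CA")
  bf <- if (n_frames(traj1) >= 2L && length(ca) > 0L) {
    bfactor(traj1, ca, align = TRUE, fit_selection = bb)
  } else NULL
  pocket_bb <- intersect(bb, unlist(lapply(pocket, residue_atoms,
                                           sys = sys)))
  stride <- config$rmsd_stride
  if (is.null(stride)) stride <- max(1L, n_frames(traj1) %/% 50L)
  r2d <- rmsd_matrix(traj1, sel_a = pocket_bb, stride = stride)

  hb_report <- NULL
  if (!is.null(hbonds)) {
    hb_report <- do.call(rbind, lapply(seq_len(nrow(hbonds)), function(k) {
      hbond_occupancy(traj1, hbonds$donor[k], hbonds$hydrogen[k],
                      hbonds$acceptor[k])
    }))
  }

  bundle <- list(
    records = all_records, per_window = scan$per_window,
    summary = summ,
    total_residue_sum = total_binding_energy(all_records),
    hotspots = hots, pocket = pocket,
    windows = do.call(rbind, windows), stability = stability,
    rmsd_backbone = rb, bfactor_ca = bf, rmsd2d = r2d,
    hbonds = hb_report, config = config,
    log = list(n_replicates = length(trajectories),
               n_frames = vapply(trajectories, n_frames, numeric(1)),
               n_windows = nrow(do.call(rbind, windows)),
               n_pocket = length(pocket),
               seed = config$seed,
               package_version = as.character(
                 utils::packageVersion("iescan")),
               elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")))
  )
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

#' Format "mean +/- sd" strings
#'
#' @param mean,sd numeric vectors.
#' @param digits decimal places (default 2).
#' @return character vector.
#' @export
format_pm <- function(mean, sd, digits = 2) {
  sprintf(paste0("%.", digits, "f±%.", digits, "f"), mean, sd)
}

#' Write a report bundle to a directory
#'
#' Emits the per-residue CSV (descending ddG, "mean+/-sd" columns),
#' the binding summary, hot-spot list, RMSD/B-factor/2D-RMSD series,
#' the per-window long table, and a JSON-lines run log.
#'
#' @param bundle result of [run_scan()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- bundle$records
  pretty <- data.frame(
    Mutation = r$mutation,
    ddEvdw = format_pm(r$dd_e_vdw, r$dd_e_vdw_sd),
    ddEele = format_pm(r$dd_e_ele, r$dd_e_ele_sd),
    ddGgb = format_pm(r$dd_g_gb, r$dd_g_gb_sd),
    ddGnp = format_pm(r$dd_g_np, r$dd_g_np_sd),
    ddH = format_pm(r$dd_h, r$dd_h_sd),
    `-TddS` = format_pm(r$minus_t_dd_s, r$minus_t_dd_s_sd),
    ddG = format_pm(r$dd_g, r$dd_g_sd),
    check.names = FALSE)
  utils::write.csv(pretty, file.path(dir, "ddg_per_residue.csv"),
                   row.names = FALSE)
  utils::write.csv(r, file.path(dir, "ddg_per_residue_raw.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$per_window,
                   file.path(dir, "ddg_per_window.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$summary, file.path(dir, "binding_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$hotspots, file.path(dir, "hotspots.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_along(bundle$rmsd_backbone),
                              rmsd_backbone = bundle$rmsd_backbone),
                   file.path(dir, "rmsd_backbone.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$bfactor_ca)) {
    utils::write.csv(data.frame(atom = seq_along(bundle$bfactor_ca),
                                bfactor = bundle$bfactor_ca),
                     file.path(dir, "bfactor_ca.csv"), row.names = FALSE)
  }
  utils::write.csv(bundle$rmsd2d, file.path(dir, "rmsd2d.csv"),
                   row.names = TRUE)
  if (!is.null(bundle$hbonds)) {
    utils::write.csv(bundle$hbonds, file.path(dir, "hbonds.csv"),
                     row.names = FALSE)
  }
  log_line <- jsonlite::toJSON(
    c(bundle$log, list(config = unclass(bundle$config))),
    auto_unbox = TRUE, null = "null")
  writeLines(as.character(log_line), file.path(dir, "run_log.jsonl"))
  invisible(dir)
}

#' Compare per-residue ddG tables between two runs
#'
#' Pairs residues via an explicit map, reports the ddG difference with
#' propagated SD `sqrt(s1^2 + s2^2)` and a Welch two-sample t-test
#' p-value computed from the window-level summary statistics
#' (mean, SD, n windows). Unpaired residues are dropped with a
#' warning.
#'
#' @param a,b data.frames with `mutation`, `dd_g`, `dd_g_sd` and
#'   optionally `n_windows` columns (run records or published tables).
#' @param pairs data.frame with columns `a` and `b` giving paired
#'   mutation labels.
#' @param alpha significance level for flagging (default 0.01).
#' @return data.frame with `mutation_a`, `mutation_b`, `dd_g_a`,
#'   `dd_g_b`, `difference`, `sd`, `t`, `df`, `p_value`,
#'   `significant`.
#' @export
compare_ddg <- function(a, b, pairs, alpha = 0.01) {
  ia <- match(pairs$a, a$mutation)
  ib <- match(pairs$b, b$mutation)
  drop <- is.na(ia) | is.na(ib)
  if (any(drop)) {
    warning("unpaired residue(s) excluded: ",
            paste(ifelse(is.na(ia[drop]), pairs$a[drop],
                         pairs$b[drop]), collapse = ", "))
    ia <- ia[!drop]; ib <- ib[!drop]
    pairs <- pairs[!drop, , drop = FALSE]
  }
  na_ <- if ("n_windows" %in% names(a)) a$n_windows[ia] else 15
  nb_ <- if ("n_windows" %in% names(b)) b$n_windows[ib] else 15
  sa <- a$dd_g_sd[ia]; sb <- b$dd_g_sd[ib]
  d <- a$dd_g[ia] - b$dd_g[ib]
  se2a <- sa^2 / na_; se2b <- sb^2 / nb_
  tval <- d / sqrt(se2a + se2b)
  dfree <- (se2a + se2b)^2 /
    (se2a^2 / (na_ - 1) + se2b^2 / (nb_ - 1))
  p <- 2 * stats::pt(-abs(tval), dfree)
  data.frame(mutation_a = pairs$a, mutation_b = pairs$b,
             dd_g_a = a$dd_g[ia], dd_g_b = b$dd_g[ib],
             difference = d, sd = sqrt(sa^2 + sb^2),
             t = tval, df = dfree, p_value = p,
             significant = p < alpha)
}

# ---------------------------------------------------------------------------
# Published reference tables (per-residue alanine-scanning results,
# whole-complex totals, and hydrogen-bond occupancies for the
# PARP-1/NMS-P118 and PARP-2/NMS-P118 complexes).

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "iescan")
  if (path == "") {
    # during in-source development
    path <- file.path("inst", "extdata", name)
  }
  path
}

#' Published per-residue alanine-scanning reference table
#'
#' Reference ddG decompositions (mean and SD over 15 analysis windows)
#' for every pocket mutation of the PARP-1/NMS-P118 and PARP-2/NMS-P118
#' complexes, as reported by the published MM/GBSA +
#' interaction-entropy study these methods reproduce. Used as input for
#' hot-spot classification and cross-protein comparisons.
#'
#' @param protein "PARP-1" or "PARP-2" (NULL returns both).
#' @return data.frame with `protein`, `mutation`, component means and
#'   `_sd` columns, `n_windows`.
#' @export
published_ddg <- function(protein = NULL) {
  df <- utils::read.csv(.extdata("parp_ddg_published.csv"),
                        stringsAsFactors = FALSE)
  df$n_windows <- 15L
  if (!is.null(protein)) {
    stopifnot(protein %in% df$protein)
    df <- df[df$protein == protein, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Published whole-complex binding summary
#'
#' Reference dH, -TdS, dG (mean, SD) and experimental dG for the two
#' complexes.
#'
#' @return data.frame with one row per protein.
#' @export
published_binding_summary <- function() {
  utils::read.csv(.extdata("parp_summary_published.csv"),
                  stringsAsFactors = FALSE)
}

#' Published hydrogen-bond occupancy table
#'
#' Reference mean distances, mean angles and occupancies for the
#' ligand hydrogen bonds of the two complexes.
#'
#' @return data.frame.
#' @export
published_hbonds <- function() {
  utils::read.csv(.extdata("parp_hbonds_published.csv"),
                  stringsAsFactors = FALSE)
}
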