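# Molecular data model: atoms + residues + per-atom force-field
# parameters (ParamSystem), and multi-frame coordinate sets (Trajectory).

#' Construct a ParamSystem
#'
#' A ParamSystem fuses topology (atoms grouped into residues, optional
#' bonds) with per-atom force-field parameters (partial charge,
#' Lennard-Jones Rmin/2 and epsilon, intrinsic Born radius and GB
#' screening factor). Parameters may be `NA` until
#' [attach_parameters()] is called.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `residue_index`, `charge`, `rmin_half`, `epsilon`, `gb_radius`,
#'   `gb_screen`.
#' @param residues data.frame with columns `index`, `name`, `chain`,
#'   `resno`, `first_atom`, `last_atom`, `polarity_class`, `is_ligand`.
#' @param coords optional n_atoms x 3 reference coordinate matrix
#'   (Angstrom), typically the crystal frame.
#' @param bonds optional 2-column integer matrix of bonded atom pairs.
#' @return an object of class `ParamSystem`.
#' @export
param_system <- function(atoms, residues, coords = NULL, bonds = NULL) {
  sys <- structure(
    list(atoms = atoms, residues = residues, coords = coords, bonds = bonds),
    class = "ParamSystem"
  )
  validate_param_system(sys)
  sys
}

#' @rdname param_system
#' @param sys a `ParamSystem`.
#' @export
validate_param_system <- function(sys) {
  a <- sys$atoms; r <- sys$residues
  if (nrow(a) == 0L) stop("ParamSystem has zero atoms")
  need_a <- c("serial", "name", "element", "residue_index", "charge",
              "rmin_half", "epsilon", "gb_radius", "gb_screen")
  if (!all(need_a %in% names(a))) {
    stop("atoms table missing columns: ",
         paste(setdiff(need_a, names(a)), collapse = ", "))
  }
  need_r <- c("index", "name", "chain", "resno", "first_atom", "last_atom",
              "polarity_class", "is_ligand")
  if (!all(need_r %in% names(r))) {
    stop("residues table missing columns: ",
         paste(setdiff(need_r, names(r)), collapse = ", "))
  }
  if (any(r$first_atom > r$last_atom)) stop("empty residue atom range")
  # ranges must be contiguous, non-overlapping, and cover all atoms
  if (r$first_atom[1] != 1L || r$last_atom[nrow(r)] != nrow(a) ||
      (nrow(r) > 1L && any(r$first_atom[-1] != r$last_atom[-nrow(r)] + 1L))) {
    stop("residue atom ranges must partition the atom table")
  }
  if (sum(r$is_ligand) > 1L) stop("more than one residue flagged as ligand")
  if (!is.null(sys$coords) &&
      (!is.matrix(sys$coords) || nrow(sys$coords) != nrow(a) ||
       ncol(sys$coords) != 3L)) {
    stop("coords must be an n_atoms x 3 matrix")
  }
  if (!is.null(sys$bonds)) {
    b <- sys$bonds
    if (any(b < 1L) || any(b > nrow(a))) stop("bond indices out of range")
  }
  ok <- !is.na(a$gb_radius) & a$gb_radius <= 0
  if (any(ok)) stop("gb_radius must be positive")
  if (any(!is.na(a$epsilon) & a$epsilon < 0)) stop("epsilon must be >= 0")
  invisible(sys)
}

#' @export
print.ParamSystem <- function(x, ...) {
  lig <- which(x$residues$is_ligand)
  cat(sprintf("ParamSystem: %d atoms, %d residues%s\n",
              nrow(x$atoms), nrow(x$residues),
              if (length(lig)) sprintf(", ligand %s%d",
                                       x$residues$name[lig],
                                       x$residues$resno[lig]) else ""))
  invisible(x)
}

#' Atom indices of a residue
#' @param sys ParamSystem.
#' @param residue residue index (row of the residues table).
#' @return integer vector of atom indices.
#' @export
residue_atoms <- function(sys, residue) {
  r <- sys$residues[residue, ]
  seq.int(r$first_atom, r$last_atom)
}

#' Atom indices of the flagged ligand residue
#' @param sys ParamSystem.
#' @return integer vector of atom indices.
#' @export
ligand_atoms <- function(sys) {
  lig <- which(sys$residues$is_ligand)
  if (length(lig) != 1L) stop("system has no ligand residue flagged")
  residue_atoms(sys, lig)
}

#' Heavy-atom (non-hydrogen) subset of atom indices
#' @param sys ParamSystem.
#' @param atoms atom indices (default: all).
#' @return integer vector.
#' @export
heavy_atoms <- function(sys, atoms = seq_len(nrow(sys$atoms))) {
  atoms[toupper(sys$atoms$element[atoms]) != "H"]
}

# ---------------------------------------------------------------------------
# Trajectory

#' Construct a Trajectory
#'
#' Ordered frames of Cartesian coordinates with equally spaced time
#' stamps. Stored as an `n_atoms x 3 x n_frames` array.
#'
#' @param coords either an `n_atoms x 3 x n_frames` array or a list of
#'   `n_atoms x 3` matrices.
#' @param times frame times in ps; default `frame_interval * (0:(n-1))`.
#' @param frame_interval recording interval in ps (default 1).
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(coords, times = NULL, frame_interval = 1) {
  if (is.list(coords)) {
    n <- nrow(coords[[1]])
    arr <- array(NA_real_, dim = c(n, 3L, length(coords)))
    for (i in seq_along(coords)) arr[, , i] <- coords[[i]]
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nf <- dim(coords)[3]
  if (is.null(times)) times <- frame_interval * (seq_len(nf) - 1)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(abs(dt - dt[1])) > 1e-6) stop("frame times must be equally spaced")
    frame_interval <- dt[1]
  }
  structure(list(coords = coords, times = times,
                 frame_interval = frame_interval),
            class = "Trajectory")
}

#' Number of frames in a Trajectory
#' @param traj Trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an n_atoms x 3 matrix
#' @param traj Trajectory.
#' @param i frame index.
#' @export
get_frame <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames, %.6g ps interval\n",
              dim(x$coords)[1], n_frames(x), x$frame_interval))
  invisible(x)
}

#' Subset a Trajectory by atoms and/or frames
#' @param traj Trajectory.
#' @param atoms atom indices to keep (default all).
#' @param frames frame indices to keep (default all).
#' @export
subset_trajectory <- function(traj, atoms = NULL, frames = NULL) {
  co <- traj$coords
  if (!is.null(atoms)) co <- co[atoms, , , drop = FALSE]
  tm <- traj$times
  if (!is.null(frames)) {
    co <- co[, , frames, drop = FALSE]
    tm <- tm[frames]
  }
  structure(list(coords = co, times = tm,
                 frame_interval = traj$frame_interval),
            class = "Trajectory")
}

# ---------------------------------------------------------------------------
# PDB input

.water_names <- c("HOH", "WAT", "TIP3", "SOL")

.pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
}

# Pre-scan ATOM/HETATM records so malformed lines are reported with
# their line number before delegating to the bio3d reader.
.check_pdb_records <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(idx) == 0L) stop("no ATOM/HETATM records found (empty input)")
  for (i in idx) {
    ln <- lines[i]
    bad <- nchar(ln) < 54
    if (!bad) {
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      bad <- anyNA(xyz)
    }
    if (bad) stop(sprintf("malformed ATOM/HETATM record at line %d: %s",
                          i, trimws(ln)))
  }
  idx
}

.element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  # two-letter elements that actually occur in protein/ligand PDBs
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
  el <- substr(nm, 1, 1)
  el[substr(nm, 1, 2) %in% two] <- substr(nm, 1, 2)[substr(nm, 1, 2) %in% two]
  el
}

#' Read a PDB structure into a ParamSystem
#'
#' Parses ATOM/HETATM records (via the bio3d reader), groups atoms into
#' residues in file order, filters alternate locations (keeping the
#' highest-occupancy altloc per atom), drops waters, and flags the
#' ligand residue. Coordinates of the first MODEL become the reference
#' frame (`$coords`); multi-MODEL files can be read as trajectories with
#' [read_pdb_trajectory()]. Force-field parameters are `NA` until
#' [attach_parameters()] is called.
#'
#' @param pdb path to a PDB file, or PDB text (single string or vector
#'   of lines).
#' @param ligand residue name (e.g. "LIG") or residue number identifying
#'   the ligand among HETATM groups; by default the single non-water
#'   HETATM residue is used (error if ambiguous).
#' @param keep_water keep water residues (default FALSE).
#' @return a `ParamSystem` with `$coords` set to the first model.
#' @export
read_structure <- function(pdb, ligand = NULL, keep_water = FALSE) {
  parsed <- .parse_pdb(pdb)
  .build_system(parsed$atom, parsed$xyz[1, ], ligand, keep_water)
}

#' Read a multi-MODEL PDB as a system plus trajectory
#'
#' @inheritParams read_structure
#' @param frame_interval recording interval in ps (default 1).
#' @return list with `system` (ParamSystem) and `trajectory`.
#' @export
read_pdb_trajectory <- function(pdb, ligand = NULL, keep_water = FALSE,
                                frame_interval = 1) {
  parsed <- .parse_pdb(pdb)
  sys <- .build_system(parsed$atom, parsed$xyz[1, ], ligand, keep_water)
  keep <- attr(sys, "kept_rows")
  nf <- nrow(parsed$xyz)
  arr <- array(NA_real_, dim = c(nrow(sys$atoms), 3L, nf))
  for (f in seq_len(nf)) {
    m <- matrix(parsed$xyz[f, ], ncol = 3L, byrow = TRUE)
    arr[, , f] <- m[keep, , drop = FALSE]
  }
  list(system = sys,
       trajectory = trajectory(arr, frame_interval = frame_interval))
}

.parse_pdb <- function(pdb) {
  lines <- .pdb_lines(pdb)
  .check_pdb_records(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  list(atom = p$atom, xyz = xyz)
}

.build_system <- function(atom, xyz0, ligand, keep_water) {
  n0 <- nrow(atom)
  keep <- rep(TRUE, n0)
  if (!keep_water) keep <- keep & !(atom$resid %in% .water_names)
  # altloc: keep blank-altloc atoms plus, per duplicated atom id, the
  # highest-occupancy alternate (first wins ties)
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  has_alt <- alt != ""
  if (any(has_alt)) {
    for (k in unique(key[has_alt])) {
      rows <- which(key == k & keep)
      if (length(rows) > 1L) {
        best <- rows[which.max(occ[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
    }
  }
  keep_rows <- which(keep)
  atom <- atom[keep_rows, , drop = FALSE]
  if (nrow(atom) == 0L) stop("no atoms left after filtering (empty input)")
  co <- matrix(xyz0, ncol = 3L, byrow = TRUE)[keep_rows, , drop = FALSE]

  el <- atom$elesy
  miss <- is.na(el) | trimws(el) == ""
  el[miss] <- .element_from_name(atom$elety[miss])
  el <- trimws(el)

  rkey <- paste(atom$chain, atom$resno, atom$insert, atom$resid, sep = "|")
  n <- length(rkey)
  res_id <- cumsum(c(TRUE, rkey[-1] != rkey[-n]))
  first <- match(unique(res_id), res_id)
  last <- c(first[-1] - 1L, n)

  rname <- atom$resid[first]
  rtype <- atom$type[first]
  het <- rtype == "HETATM"
  is_lig <- rep(FALSE, length(first))
  if (is.null(ligand)) {
    cand <- which(het)
    if (length(cand) == 1L) {
      is_lig[cand] <- TRUE
    } else if (length(cand) > 1L) {
      stop("multiple HETATM residues (",
           paste(unique(rname[cand]), collapse = ", "),
           "); specify `ligand`")
    }
  } else if (is.character(ligand)) {
    hit <- which(rname == ligand)
    if (length(hit) != 1L) stop("ligand residue name '", ligand,
                                "' matches ", length(hit), " residues")
    is_lig[hit] <- TRUE
  } else {
    hit <- which(atom$resno[first] == ligand)
    if (length(hit) != 1L) stop("ligand residue number ", ligand,
                                " matches ", length(hit), " residues")
    is_lig[hit] <- TRUE
  }

  pol <- rep(NA_character_, length(first))
  known <- rname %in% names(.polarity_table)
  pol[known] <- unname(.polarity_table[rname[known]])

  atoms <- data.frame(
    serial = atom$eleno,
    name = trimws(atom$elety),
    element = el,
    residue_index = res_id,
    charge = NA_real_, rmin_half = NA_real_, epsilon = NA_real_,
    gb_radius = NA_real_, gb_screen = NA_real_,
    stringsAsFactors = FALSE
  )
  residues <- data.frame(
    index = seq_along(first),
    name = rname,
    chain = ifelse(is.na(atom$chain[first]), "", atom$chain[first]),
    resno = atom$resno[first],
    first_atom = first,
    last_atom = last,
    polarity_class = pol,
    is_ligand = is_lig,
    stringsAsFactors = FALSE
  )
  sys <- param_system(atoms, residues, coords = co)
  attr(sys, "kept_rows") <- keep_rows
  sys
}

# ---------------------------------------------------------------------------
# PDB output

.pdb_atom_line <- function(rec, serial, name, resname, chain, resno, x, y, z,
                           element) {
  nm <- if (nchar(name) < 4L && nchar(element) == 1L) {
    formatC(paste0(" ", name), width = -4)
  } else {
    formatC(name, width = -4)
  }
  sprintf("%-6s%5d %s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000L, nm, "", resname, substr(chain, 1, 1),
          resno %% 10000L, x, y, z, 1.0, 0.0, element)
}

.frame_pdb_lines <- function(sys, coords) {
  a <- sys$atoms
  r <- sys$residues
  rec <- ifelse(r$is_ligand[a$residue_index], "HETATM", "ATOM")
  vapply(seq_len(nrow(a)), function(i) {
    ri <- a$residue_index[i]
    .pdb_atom_line(rec[i], a$serial[i], a$name[i], r$name[ri], r$chain[ri],
                   r$resno[ri], coords[i, 1], coords[i, 2], coords[i, 3],
                   a$element[i])
  }, character(1))
}

#' Write a ParamSystem (one frame) to PDB text
#'
#' @param sys ParamSystem.
#' @param coords n_atoms x 3 matrix; defaults to `sys$coords`.
#' @param file optional path; if NULL the PDB text is returned invisibly.
#' @return character vector of PDB lines (invisibly when writing).
#' @export
write_structure <- function(sys, coords = sys$coords, file = NULL) {
  if (is.null(coords)) stop("no coordinates to write")
  lines <- c(.frame_pdb_lines(sys, coords), "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Write a Trajectory as a multi-MODEL PDB
#'
#' @param sys ParamSystem.
#' @param traj Trajectory over the same atoms.
#' @param file output path.
#' @export
write_pdb_trajectory <- function(sys, traj, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(.frame_pdb_lines(sys, get_frame(traj, f)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Write/read a trajectory as a plain-text long-format CSV
#'
#' Columns: frame, atom, x, y, z. A `# frame_interval_ps=` comment line
#' records the frame spacing.
#'
#' @param traj Trajectory.
#' @param file path.
#' @export
write_trajectory_csv <- function(traj, file) {
  nf <- n_frames(traj)
  na <- dim(traj$coords)[1]
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    atom = rep(seq_len(na), times = nf),
    x = as.vector(traj$coords[, 1, ]),
    y = as.vector(traj$coords[, 2, ]),
    z = as.vector(traj$coords[, 3, ])
  )
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_ps=%.10g", traj$frame_interval), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  first <- readLines(file, n = 1L)
  dt <- 1
  if (startsWith(first, "#")) {
    dt <- as.numeric(sub(".*frame_interval_ps=", "", first))
  }
  df <- utils::read.csv(file, comment.char = "#")
  nf <- max(df$frame)
  na <- max(df$atom)
  arr <- array(NA_real_, dim = c(na, 3L, nf))
  ord <- order(df$frame, df$atom)
  df <- df[ord, ]
  arr[cbind(df$atom, 1L, df$frame)] <- df$x
  arr[cbind(df$atom, 2L, df$frame)] <- df$y
  arr[cbind(df$atom, 3L, df$frame)] <- df$z
  trajectory(arr, frame_interval = dt)
}

# ---------------------------------------------------------------------------
# Parameters

#' Attach force-field parameters to a ParamSystem
#'
#' The parameter table is keyed either by `(residue, atom)` name pair or
#' by atom `serial`, with columns `charge_e`, `rmin_half_A`,
#' `epsilon_kcal`, and optionally `gb_radius_A`, `gb_screen` (filled
#' from the element-default table when absent).
#'
#' @param sys ParamSystem.
#' @param params data.frame or path to a CSV file.
#' @return ParamSystem with all atoms parameterized.
#' @export
attach_parameters <- function(sys, params) {
  if (is.character(params)) params <- utils::read.csv(params)
  need <- c("charge_e", "rmin_half_A", "epsilon_kcal")
  if (!all(need %in% names(params))) {
    stop("parameter table missing columns: ",
         paste(setdiff(need, names(params)), collapse = ", "))
  }
  a <- sys$atoms
  if ("serial" %in% names(params)) {
    if (anyDuplicated(params$serial)) {
      stop("duplicate serial key(s) in parameter table: ",
           paste(unique(params$serial[duplicated(params$serial)]),
                 collapse = ", "))
    }
    idx <- match(a$serial, params$serial)
    label <- paste0("serial ", a$serial)
  } else {
    if (!all(c("residue", "atom") %in% names(params))) {
      stop("parameter table must have (residue, atom) or serial key columns")
    }
    pkey <- paste(params$residue, params$atom, sep = "/")
    if (anyDuplicated(pkey)) {
      stop("duplicate (residue, atom) key(s) in parameter table: ",
           paste(unique(pkey[duplicated(pkey)]), collapse = ", "))
    }
    akey <- paste(sys$residues$name[a$residue_index], a$name, sep = "/")
    idx <- match(akey, pkey)
    label <- akey
  }
  if (anyNA(idx)) {
    stop("missing parameters for atom(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  a$charge <- params$charge_e[idx]
  a$rmin_half <- params$rmin_half_A[idx]
  a$epsilon <- params$epsilon_kcal[idx]
  if ("gb_radius_A" %in% names(params)) {
    a$gb_radius <- params$gb_radius_A[idx]
    a$gb_screen <- params$gb_screen[idx]
  }
  fill <- is.na(a$gb_radius)
  if (any(fill)) {
    gp <- mapply(default_gb_params, a$element[fill], a$name[fill],
                 SIMPLIFY = FALSE)
    a$gb_radius[fill] <- vapply(gp, `[[`, numeric(1), "gb_radius")
    a$gb_screen[fill] <- vapply(gp, `[[`, numeric(1), "gb_screen")
  }
  sys$atoms <- a
  validate_param_system(sys)
  sys
}

# ---------------------------------------------------------------------------
# Residue classification and pocket selection

#' Classify residues into polarity classes
#'
#' Deterministic mapping of 3-letter residue codes (including common
#' protonation variants HIE/HID/HIP, ASH, GLH, LYN, CYX) into
#' `nonpolar`, `polar`, or `charged`. The class selects the interior
#' dielectric used for that residue's electrostatics (1/3/10 by
#' default). TYR and TRP sit in the polar class by default; override via
#' the `table` argument if a different placement is preferred.
#'
#' @param name character vector of 3-letter codes.
#' @param table named class lookup (default: the package table).
#' @return character vector of classes.
#' @export
classify_residue <- function(name, table = .polarity_table) {
  cl <- table[toupper(name)]
  if (anyNA(cl)) {
    stop("cannot classify residue(s): ",
         paste(unique(name[is.na(cl)]), collapse = ", "))
  }
  unname(cl)
}

#' Interior dielectric constant for a polarity class
#'
#' @param class character vector of classes (`nonpolar`, `polar`,
#'   `charged`).
#' @param dielectrics named numeric vector, default `c(nonpolar = 1,
#'   polar = 3, charged = 10)`.
#' @return numeric vector of dielectric constants.
#' @export
dielectric_for <- function(class, dielectrics = .default_dielectrics) {
  d <- dielectrics[class]
  if (anyNA(d)) stop("unknown polarity class: ",
                     paste(unique(class[is.na(d)]), collapse = ", "))
  unname(d)
}

#' Per-atom interior dielectric for a system
#'
#' Protein atoms inherit their residue's class dielectric; ligand atoms
#' use `ligand_eps` (default 1).
#'
#' @param sys ParamSystem (residues must be classified).
#' @param dielectrics class-to-dielectric table.
#' @param ligand_eps dielectric for ligand atoms.
#' @return numeric vector over atoms.
#' @export
atom_dielectrics <- function(sys, dielectrics = .default_dielectrics,
                             ligand_eps = 1) {
  r <- sys$residues
  eps_res <- numeric(nrow(r))
  prot <- !r$is_ligand
  eps_res[prot] <- dielectric_for(r$polarity_class[prot], dielectrics)
  eps_res[!prot] <- ligand_eps
  eps_res[sys$atoms$residue_index]
}

#' Select binding-pocket residues within a distance cutoff of the ligand
#'
#' A protein residue is in the pocket when at least one of its heavy
#' atoms lies within `cutoff` Angstrom of any ligand heavy atom in the
#' reference frame (hydrogens excluded: crystal structures typically
#' lack them).
#'
#' @param sys ParamSystem with a flagged ligand.
#' @param coords reference frame (default `sys$coords`).
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return integer vector of residue indices, ascending.
#' @export
select_pocket <- function(sys, coords = sys$coords, cutoff = 5.0) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  if (is.null(coords)) stop("no reference coordinates")
  lig <- ligand_atoms(sys)
  lig_h <- heavy_atoms(sys, lig)
  prot_res <- which(!sys$residues$is_ligand)
  hit <- vapply(prot_res, function(ri) {
    at <- heavy_atoms(sys, residue_atoms(sys, ri))
    if (length(at) == 0L) return(FALSE)
    d <- .cross_dist(coords[at, , drop = FALSE],
                     coords[lig_h, , drop = FALSE])
    any(d <= cutoff)
  }, logical(1))
  prot_res[hit]
}

# Cross distance matrix between two coordinate sets (rows = points).
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
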