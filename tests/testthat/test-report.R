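# End-to-end orchestration, report emission, and run comparison.

toy_bundle <- function(seed = 1, n_frames = 24, hb = NULL) {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 3,
                                   n_frames = n_frames), seed = seed)
  cfg <- scan_config(window_ps = 8, n_windows = 2, enthalpy_frames = 4,
                     sasa_points = 120, seed = seed)
  run_scan(toy$system, toy$trajectory, cfg, hbonds = hb)
}

test_that("run_scan emits a complete, deterministic bundle", {
  b1 <- toy_bundle(1)
  expect_true(all(c("records", "summary", "hotspots", "windows",
                    "rmsd_backbone", "rmsd2d", "log") %in% names(b1)))
  expect_equal(nrow(b1$windows), 2L)
  expect_s3_class(b1$records, "data.frame")
  expect_equal(b1$summary$n_windows, 2L)
  # summary equals the negated window-level residue sums
  expect_num_eq(b1$summary$dg_mean,
                mean(-tapply(b1$per_window$dd_g, b1$per_window$window,
                             sum)), 1e-9)
  b2 <- toy_bundle(1)
  b1$log <- b2$log <- NULL
  expect_equal(b1, b2)
})

test_that("run_scan validates configuration before computing", {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 2, n_frames = 6),
                          seed = 2)
  short <- subset_trajectory(toy$trajectory, frames = 1:2)
  expect_error(run_scan(toy$system, short,
                        scan_config(window_ps = 8, n_windows = 2)),
               "short")
  wrong <- subset_trajectory(toy$trajectory, atoms = 1:5)
  expect_error(run_scan(toy$system, wrong, scan_config()),
               "atom count")
})

test_that("replicate trajectories multiply the window count", {
  toy <- make_toy_complex(toy_spec(n_pocket_residues = 2, n_frames = 24),
                          seed = 3)
  reps <- list(toy$trajectory, toy$trajectory, toy$trajectory)
  cfg <- scan_config(window_ps = 8, n_windows = 2, enthalpy_frames = 3,
                     sasa_points = 120)
  b <- run_scan(toy$system, reps, cfg)
  expect_equal(nrow(b$windows), 6L)
  expect_equal(unique(b$records$n_windows), 6L)
})

test_that("bundle writer produces the tabular report files", {
  hb <- data.frame(donor = 1L, hydrogen = 2L, acceptor = 3L)
  b <- toy_bundle(4, hb = hb)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(
    dir, c("ddg_per_residue.csv", "ddg_per_window.csv",
           "binding_summary.csv", "hotspots.csv", "rmsd_backbone.csv",
           "rmsd2d.csv", "hbonds.csv", "run_log.jsonl")))))
  pretty <- utils::read.csv(file.path(dir, "ddg_per_residue.csv"),
                            check.names = FALSE)
  expect_true(all(grepl("±", pretty$ddG)))
  log <- jsonlite::fromJSON(readLines(file.path(dir, "run_log.jsonl")))
  expect_equal(log$n_windows, 2L)
})

test_that("comparison of identical tables is all-zero and insignificant", {
  p1 <- published_ddg("PARP-1")
  pairs <- data.frame(a = p1$mutation, b = p1$mutation)
  cmp <- compare_ddg(p1, p1, pairs)
  expect_num_eq(cmp$difference, rep(0, nrow(cmp)), 1e-12)
  expect_false(any(cmp$significant, na.rm = TRUE))
})

test_that("published cross-protein pairs reproduce the reported gaps", {
  p1 <- published_ddg("PARP-1")
  p2 <- published_ddg("PARP-2")
  pairs <- data.frame(a = c("Y889A", "H862A", "E763A", "Q759A"),
                      b = c("Y455A", "H428A", "Q332A", "S328A"))
  cmp <- compare_ddg(p1, p2, pairs)
  expect_equal(cmp$difference, c(0.55, 0.25, 0.95, 0.35),
               tolerance = 1e-9)
  expect_num_eq(cmp$sd,
                sqrt(p1$dd_g_sd[match(pairs$a, p1$mutation)]^2 +
                     p2$dd_g_sd[match(pairs$b, p2$mutation)]^2), 1e-12)
  expect_warning(
    compare_ddg(p1, p2, data.frame(a = "Y889A", b = "NOPE")),
    "unpaired")
})

test_that("YAML configuration round-trips through the loader", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("temperature: 310", "n_windows: 4",
               "dielectrics:", "  nonpolar: 1", "  polar: 2",
               "  charged: 8"), tf)
  cfg <- read_scan_config(tf)
  expect_equal(cfg$temperature, 310)
  expect_equal(cfg$n_windows, 4)
  expect_equal(cfg$dielectrics[["polar"]], 2)
  expect_equal(cfg$pocket_cutoff, 5.0) # default preserved
  writeLines("not_a_key: 1", tf)
  expect_error(read_scan_config(tf), "unknown config key")
})
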