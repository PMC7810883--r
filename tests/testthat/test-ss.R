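test_that("ideal constructs get the expected class labels", {
  h <- ideal_helix(15)
  lab_h <- assign_ss(h$coords_nm, h$topology)
  expect_true(all(lab_h[3:13] == "H"))
  e <- ideal_extended(10)
  expect_true(all(assign_ss(e$coords_nm, e$topology) == "C"))
  s <- ideal_sheet(8)
  lab_s <- assign_ss(s$coords_nm, s$topology)
  expect_true(all(lab_s[c(3:6, 11:14)] == "E"))
})

test_that("assignments match the mdtraj DSSP 3-class reduction exactly", {
  reduce <- function(lab) {
    out <- ifelse(lab %in% c("H", "G"), "H", ifelse(lab == "E", "E", "C"))
    paste(out, collapse = "")
  }
  cases <- list(helix = ideal_helix(15), ext = ideal_extended(10),
                sheet = ideal_sheet(8))
  pdbs <- character(0)
  ours <- character(0)
  for (nm in names(cases)) {
    p <- tempfile(fileext = ".pdb")
    write_topology(cases[[nm]]$topology, cases[[nm]]$coords_nm, p)
    pdbs <- c(pdbs, p)
    ours <- c(ours, reduce(assign_ss(cases[[nm]]$coords_nm,
                                     cases[[nm]]$topology)))
  }
  script <- paste(
    "import sys, mdtraj as md",
    "for f in sys.argv[1:]:",
    "    print(''.join(md.compute_dssp(md.load(f), simplified=True)[0]))",
    sep = "\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  ref <- system2("python", c(sf, pdbs), stdout = TRUE)
  ref <- gsub(" ", "C", ref)  # mdtraj prints blank/NA for non-protein only
  expect_equal(ours, ref)
})

test_that("assignment is invariant under global rotation/translation", {
  h <- ideal_helix(12)
  lab0 <- assign_ss(h$coords_nm, h$topology)
  set.seed(19)
  co <- h$coords_nm %*% t(random_rotation())
  co <- sweep(co, 2, c(5, -3, 2), "+")
  expect_equal(assign_ss(co, h$topology), lab0)
})

test_that("residues missing backbone atoms are labelled C with a warning", {
  h <- ideal_helix(10)
  keep <- !(h$topology$atoms$residue_number == 5 &
            h$topology$atoms$atom_name == "O")
  at <- h$topology$atoms[keep, c("atom_name", "residue_number",
                                 "residue_name", "chain_id", "element")]
  top <- topology(at)
  expect_warning(lab <- assign_ss(h$coords_nm[keep, ], top), "backbone")
  expect_equal(unname(lab[names(lab) == "A:5"]), "C")
})

test_that("ss time series tracks a scheduled helix-coil transition", {
  spec <- synthetic_spec(seed = 20, n_frames = 200, dt_ns = 5,
                         sigma_nm = 0.008,
    unfolding_schedules = list(list(region = 287:296, t_start_ns = 500,
                                    t_end_ns = 520)))
  tr <- generate_trajectory(spec)$trajectory
  ss <- ss_timeseries(tr, stride = 2)
  hf <- helix_fraction(ss, 289:296)
  expect_gt(mean(hf$helix_fraction[hf$time_ns < 480]), 0.8)
  expect_lt(mean(hf$helix_fraction[hf$time_ns > 540]), 0.2)
  # strided assignment equals the full series sampled at the same frames
  ss_full <- ss_timeseries(subset_frames(tr, seq(1, 200, by = 2)))
  expect_equal(ss$labels, ss_full$labels)
})

test_that("helix fraction is exact on degenerate regions", {
  h <- ideal_helix(15)
  tr <- trajectory(h$topology,
                   array(h$coords_nm, c(1, nrow(h$coords_nm), 3)), 0)
  ss <- ss_timeseries(tr)
  expect_equal(helix_fraction(ss, 5:10)$helix_fraction, 1.0)
  e <- ideal_extended(10)
  tre <- trajectory(e$topology,
                    array(e$coords_nm, c(1, nrow(e$coords_nm), 3)), 0)
  expect_equal(helix_fraction(ss_timeseries(tre), 3:8)$helix_fraction, 0.0)
  expect_error(helix_fraction(ss, 500:510), "no residues")
})

test_that("folding events: constant series give none, steps give one", {
  times <- seq(0, 999)
  expect_equal(nrow(detect_folding_events(rep(1, 1000), times,
                                          min_dwell_ns = 10)), 0L)
  frac <- c(rep(1, 500), rep(0, 500))
  ev <- detect_folding_events(frac, times, min_dwell_ns = 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "unfolding")
  expect_equal(ev$start_ns, 500, tolerance = 20)
})

test_that("square-wave series yield alternating event pairs per period", {
  times <- seq(0, by = 1, length.out = 1000)
  frac <- rep(c(rep(1, 50), rep(0, 50)), 10)
  ev <- detect_folding_events(frac, times, min_dwell_ns = 10)
  expect_equal(sum(ev$kind == "unfolding"), 10L)
  expect_equal(sum(ev$kind == "refolding"), 9L)
  expect_true(all(ev$kind[seq(1, nrow(ev), by = 2)] == "unfolding"))
  # strict alternation
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  # time-shift invariance of the event count
  ev2 <- detect_folding_events(frac, times + 123, min_dwell_ns = 10)
  expect_equal(nrow(ev2), nrow(ev))
  expect_error(detect_folding_events(frac, times, low_thresh = 0.8,
                                     high_thresh = 0.3), "low")
})
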