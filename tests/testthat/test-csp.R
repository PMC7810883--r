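test_that("the weighted shift formula evaluates exactly", {
  expect_equal(compute_csp(0, 0), 0)
  expect_equal(compute_csp(0.1, 0), 0.1)
  # direct evaluation: sqrt(0.03^2 + (0.12/6)^2)
  expect_equal(compute_csp(0.03, 0.12), 0.03605551, tolerance = 1e-6)
})

test_that("compute_csp is a norm on (d1H, d15N/6)", {
  set.seed(24)
  for (i in 1:50) {
    a <- rnorm(2, sd = 0.1); b <- rnorm(2, sd = 0.1)
    # sign symmetry
    expect_equal(compute_csp(a[1], a[2]), compute_csp(-a[1], a[2]))
    expect_equal(compute_csp(a[1], a[2]), compute_csp(a[1], -a[2]))
    # triangle inequality
    expect_lte(compute_csp(a[1] + b[1], a[2] + b[2]),
               compute_csp(a[1], a[2]) + compute_csp(b[1], b[2]) + 1e-12)
  }
})

test_that("titration series validate ratio ordering and peak tables", {
  pk <- function(int) data.frame(residue_number = 1L, d1H_ppm = 8,
                                 d15N_ppm = 115, intensity = int)
  expect_s3_class(titration_series("wt", list(
    list(ligand_ratio = 0, peaks = pk(100)),
    list(ligand_ratio = 1, peaks = pk(50)))), "titration_series")
  expect_error(titration_series("wt", list(
    list(ligand_ratio = 1, peaks = pk(100)))), "from 0")
  expect_error(titration_series("wt", list(
    list(ligand_ratio = 0, peaks = pk(100)),
    list(ligand_ratio = 0, peaks = pk(50)))), "increasing")
  expect_error(titration_series("wt", list(
    list(ligand_ratio = 0, peaks = pk(-1)),
    list(ligand_ratio = 1, peaks = pk(1)))), "negative")
})

test_that("intensity profiles normalize and flag vanished peaks", {
  pk <- function(res, int) data.frame(residue_number = res, d1H_ppm = 8,
                                      d15N_ppm = 115, intensity = int)
  s <- titration_series("wt", list(
    list(ligand_ratio = 0, peaks = pk(1:2, c(100, 80))),
    list(ligand_ratio = 1, peaks = pk(1:2, c(50, 80))),
    list(ligand_ratio = 2, peaks = pk(2, 80)),       # residue 1 vanished
    list(ligand_ratio = 4, peaks = pk(1:2, c(25, 80)))))
  ip <- intensity_profile(s, 1)
  expect_equal(ip$rel_intensity, c(1, 0.5, 0, 0))  # stays 0 once vanished
  expect_equal(ip$beyond_detection, c(FALSE, FALSE, TRUE, TRUE))
  ip2 <- intensity_profile(s, 2)
  expect_equal(ip2$rel_intensity, rep(1, 4))
  expect_error(intensity_profile(s, 99), "absent")
})

test_that("csp profiles are zero at reference and track shift changes", {
  pk <- function(d1h) data.frame(residue_number = 1L, d1H_ppm = d1h,
                                 d15N_ppm = 115, intensity = 1)
  s <- titration_series("wt", list(
    list(ligand_ratio = 0, peaks = pk(8.00)),
    list(ligand_ratio = 2, peaks = pk(8.10))))
  prof <- csp_profile(s)
  expect_equal(prof$delta_obs_ppm, c(0, 0.1), tolerance = 1e-12)
})

test_that("ranking orders a decaying variant above a flat one; ties declared", {
  pk <- function(int) data.frame(residue_number = c(260L, 261L, 279L, 285L),
                                 d1H_ppm = 8, d15N_ppm = 115, intensity = int)
  mkseries <- function(lab, ints) titration_series(lab, lapply(
    seq_along(ints), function(i) list(ligand_ratio = c(0, 1, 2, 4)[i],
                                      peaks = pk(ints[i]))))
  decay <- mkseries("decay", c(100, 50, 25, 12))
  flat <- mkseries("flat", c(100, 100, 100, 100))
  rk <- rank_affinity(list(flat, decay))
  expect_equal(rk$variant, c("decay", "flat"))
  expect_equal(rk$score[2], 0, tolerance = 1e-12)
  # direct arithmetic for the decay score: 1 - AUC/span
  auc <- (0.75 + 0.375 + 2 * 0.185) / 4
  expect_equal(rk$score[1], 1 - auc, tolerance = 1e-9)
  # identical series tie
  rk2 <- rank_affinity(list(decay, mkseries("decay2", c(100, 50, 25, 12))))
  expect_equal(rk2$rank, c(1L, 1L))
  expect_error(rank_affinity(list(mkseries("bad", c(1, 1, 1, 1))),
                             reporter_residues = 999), "reporter")
})

test_that("peak lists round-trip through CSV, order-independently", {
  spec <- synthetic_spec(seed = 25)
  g <- generate_titration(spec, "wt")
  p <- tempfile(fileext = ".csv")
  write_peaklist(g$series, p)
  s2 <- read_peaklist(p)
  expect_equal(s2$variant_label, "wt")
  expect_equal(length(s2$points), length(g$series$points))
  for (i in seq_along(s2$points)) {
    a <- s2$points[[i]]$peaks
    b <- g$series$points[[i]]$peaks
    b <- b[order(b$residue_number), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-10)
  }
  # shuffled rows parse to the identical series
  d <- utils::read.csv(p)
  set.seed(26)
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(d[sample(nrow(d)), ], p2, row.names = FALSE)
  s3 <- read_peaklist(p2)
  expect_equal(s3$points[[2]]$peaks, s2$points[[2]]$peaks, tolerance = 1e-10)
  # duplicate rows are rejected
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(rbind(d, d[1, ]), p3, row.names = FALSE)
  expect_error(read_peaklist(p3), "duplicate")
})

test_that("planted Kd ordering is recovered from synthetic titrations", {
  spec <- synthetic_spec(seed = 27)
  series <- lapply(names(spec$titration),
                   function(v) generate_titration(spec, v)$series)
  rk <- rank_affinity(series)
  expect_equal(rk$variant, c("wt", "S280E", "S263E"))
  # no-binding limit: enormous Kd gives near-zero CSP and flat intensities
  spec2 <- synthetic_spec(seed = 28,
                          titration = list(none = list(Kd_uM = 1e9)))
  g <- generate_titration(spec2, "none", noise_sd = 0)
  ip <- intensity_profile(g$series, 260)
  expect_true(all(abs(ip$rel_intensity - 1) < 1e-3))
  prof <- csp_profile(g$series, 260)
  expect_true(all(prof$delta_obs_ppm < 1e-3))
  # stoichiometric limit: tiny Kd saturates the CSP by ratio 1
  spec3 <- synthetic_spec(seed = 29,
                          titration = list(tight = list(Kd_uM = 1e-4)))
  g3 <- generate_titration(spec3, "tight", noise_sd = 0, beta = 0)
  prof3 <- csp_profile(g3$series, 260)
  at1 <- prof3$delta_obs_ppm[prof3$ligand_ratio == 1]
  at4 <- prof3$delta_obs_ppm[prof3$ligand_ratio == 4]
  expect_equal(at1, at4, tolerance = 0.05)
})
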