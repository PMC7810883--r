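test_that("static and two-point trajectories give exact RMSF values", {
  spec <- synthetic_spec(seed = 1, n_frames = 6, dt_ns = 1, sigma_nm = 0)
  tr <- generate_trajectory(spec)$trajectory
  tr$aligned <- TRUE
  prof <- compute_rmsf(tr)
  expect_true(all(prof$rmsf_nm == 0))
  # one atom alternating x = +d / -d about its mean has RMSF exactly d
  d <- 0.07
  co <- tr$coords
  ca1 <- resolve_selection("name CA", tr$topology)[1] + 1L
  co[, ca1, 1] <- co[, ca1, 1] + rep(c(d, -d), 3)
  tr2 <- trajectory(tr$topology, co, tr$times_ns, aligned = TRUE)
  prof2 <- compute_rmsf(tr2)
  expect_equal(prof2$rmsf_nm[1], d, tolerance = 1e-12)
})

test_that("unaligned trajectories are refused without the explicit override", {
  spec <- synthetic_spec(seed = 1, n_frames = 4, dt_ns = 1, sigma_nm = 0.02)
  tr <- generate_trajectory(spec)$trajectory
  expect_error(compute_rmsf(tr), "not aligned")
  expect_s3_class(compute_rmsf(tr, allow_unaligned = TRUE), "rmsf_profile")
})

test_that("OU fluctuations recover the planted sqrt(3)*sigma amplitude", {
  spec <- synthetic_spec(seed = 8, n_frames = 20000, dt_ns = 0.1,
                         atoms = "ca", sigma_nm = 0.05)
  tr <- generate_trajectory(spec)$trajectory
  prof <- compute_rmsf(align_trajectory(tr))
  expect_lt(max(abs(prof$rmsf_nm / (sqrt(3) * 0.05) - 1)), 0.10)
})

test_that("RMSF is invariant under a global rigid-body transform", {
  spec <- synthetic_spec(seed = 9, n_frames = 300, dt_ns = 1, atoms = "ca",
                         sigma_nm = 0.05)
  tr <- generate_trajectory(spec)$trajectory
  set.seed(10)
  moved <- transform_trajectory(tr, random_rotation(), rnorm(3))
  p1 <- compute_rmsf(align_trajectory(tr))
  p2 <- compute_rmsf(align_trajectory(moved))
  expect_equal(p1$rmsf_nm, p2$rmsf_nm, tolerance = 1e-8)
})

test_that("replica combination gives elementwise mean and n-1 sd", {
  a <- rmsf_profile(1:3, c(0.1, 0.2, 0.3))
  b <- rmsf_profile(1:3, c(0.3, 0.2, 0.1))
  comb <- combine_replicas(list(a, b))
  expect_equal(comb$rmsf_nm, c(0.2, 0.2, 0.2))
  # hand arithmetic, n-1 convention: sd(0.1, 0.3) = 0.1414214
  expect_equal(comb$std_nm, c(0.1414214, 0, 0.1414214), tolerance = 1e-6)
  expect_equal(comb$n_replicas, 2L)
  # k identical replicas: mean equals input, sd 0
  comb3 <- combine_replicas(list(a, a, a))
  expect_equal(comb3$rmsf_nm, a$rmsf_nm)
  expect_true(all(comb3$std_nm == 0))
  expect_error(combine_replicas(list(a, rmsf_profile(2:4, c(1, 1, 1)))),
               "grids differ")
})

test_that("delta-RMSF is zero on identity, antisymmetric, intersection-based", {
  wt <- rmsf_profile(245:250, seq(0.1, 0.2, length.out = 6))
  expect_true(all(delta_rmsf(wt, wt)$delta_nm == 0))
  var <- rmsf_profile(247:252, seq(0.3, 0.2, length.out = 6))
  d1 <- delta_rmsf(var, wt)
  d2 <- delta_rmsf(wt, var)
  expect_equal(d1$residue_numbers, 247:250)
  expect_equal(d1$delta_nm, -d2$delta_nm)
  expect_error(delta_rmsf(wt, rmsf_profile(300:305, rep(0.1, 6))),
               "overlap")
})

test_that("a planted loop-amplitude increase is recovered in delta-RMSF", {
  loop <- 266:277
  sig <- c(default = 0.04)
  sig_var <- c(sig, stats::setNames(rep(0.08, length(loop)), loop))
  n <- 8000
  wt_tr <- generate_trajectory(synthetic_spec(seed = 11, n_frames = n,
                                              dt_ns = 0.1, atoms = "ca",
                                              sigma_nm = sig))$trajectory
  var_tr <- generate_trajectory(synthetic_spec(seed = 12, n_frames = n,
                                               dt_ns = 0.1, atoms = "ca",
                                               sigma_nm = sig_var))$trajectory
  d <- delta_rmsf(compute_rmsf(align_trajectory(var_tr)),
                  compute_rmsf(align_trajectory(wt_tr)), "loop2x")
  in_loop <- d$residue_numbers %in% loop
  expect_true(all(d$delta_nm[in_loop] > 0))
  # planted effect ~ sqrt(3)*(0.08-0.04); recovered within 25%
  expect_equal(mean(d$delta_nm[in_loop]), sqrt(3) * 0.04, tolerance = 0.25)
  expect_lt(max(abs(d$delta_nm[!in_loop])), 0.02)
})

test_that("convergence summary behaves on identical and anticorrelated profiles", {
  a <- rmsf_profile(1:2, c(0.1, 0.2))
  expect_equal(convergence_check(list(a, a)),
               list(max_abs_diff_nm = 0, pearson_r = 1))
  b <- rmsf_profile(1:2, c(0.2, 0.1))
  cc <- convergence_check(list(a, b))
  expect_equal(cc$pearson_r, -1)
  expect_equal(cc$max_abs_diff_nm, 0.1)
})

test_that("independent OU replicas converge to each other at long runs", {
  prof_of <- function(seed, n) {
    spec <- synthetic_spec(seed = seed, n_frames = n, dt_ns = 0.1,
                           atoms = "ca", sigma_nm = 0.05)
    compute_rmsf(align_trajectory(generate_trajectory(spec)$trajectory))
  }
  short <- convergence_check(list(prof_of(21, 1000), prof_of(22, 1000)))
  long <- convergence_check(list(prof_of(21, 20000), prof_of(22, 20000)))
  expect_lt(long$max_abs_diff_nm, short$max_abs_diff_nm)
  expect_lt(long$max_abs_diff_nm, 0.012)
})
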