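mini_two_atom_traj <- function(dists, box_nm = NULL) {
  at <- data.frame(atom_name = c("P", "CZ"), residue_number = c(263L, 320L),
                   residue_name = c("SEP", "ARG"), chain_id = "A",
                   element = c("P", "C"))
  top <- topology(at)
  nf <- length(dists)
  co <- array(0, c(nf, 2L, 3L))
  co[, 2, 1] <- dists
  trajectory(top, co, seq(0, by = 1, length.out = nf),
             box_nm = if (!is.null(box_nm)) matrix(box_nm, nf, 3, byrow = TRUE))
}

test_that("distance series reproduces planted separations", {
  tr <- mini_two_atom_traj(c(1, 0.5, 2))
  ds <- distance_series(tr, "resid 320 and name CZ", "resid 263 and name P")
  expect_equal(ds$distance_nm, c(1, 0.5, 2))
  # A = B gives identically zero
  ds0 <- distance_series(tr, "name CZ", "name CZ")
  expect_true(all(ds0$distance_nm == 0))
  expect_error(distance_series(tr, "resid 999", "name P"), "empty selection")
})

test_that("minimum-image distances match a brute-force 27-image scan", {
  tr <- mini_two_atom_traj(6.9, box_nm = c(7, 7, 7))
  ds <- distance_series(tr, "name CZ", "name P")
  expect_equal(ds$distance_nm, 0.1, tolerance = 1e-12)
  # brute force over all 27 periodic images
  set.seed(13)
  for (rep in 1:20) {
    a <- runif(3, 0, 7); b <- runif(3, 0, 7)
    imgs <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * 7
    brute <- min(sqrt(rowSums((matrix(b - a, 27, 3, byrow = TRUE) + imgs)^2)))
    tr2 <- mini_two_atom_traj(0, box_nm = c(7, 7, 7))
    tr2$coords[1, 1, ] <- a
    tr2$coords[1, 2, ] <- b
    ds2 <- distance_series(tr2, "name CZ", "name P")
    expect_equal(ds2$distance_nm, brute, tolerance = 1e-10)
  }
})

test_that("contact states use the inclusive 1 nm boundary", {
  crit <- occurrence_criteria()
  tr <- mini_two_atom_traj(c(0.5, 1.5, 0.5, 1.5, 1.0))
  st <- contact_states(distance_series(tr, "name CZ", "name P"), crit)
  expect_equal(st, c(TRUE, FALSE, TRUE, FALSE, TRUE))  # d == 1.0 is a contact
  expect_equal(mean(st[1:4]), 0.5)
})

test_that("event extraction merges gaps per the tolerance", {
  times <- 0:4
  st <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  ev0 <- contact_events(st, times, gap_tolerance_ns = 0)
  expect_equal(nrow(ev0), 2L)
  expect_equal(ev0$duration_ns, c(2, 2))
  ev1 <- contact_events(st, times, gap_tolerance_ns = 1)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$duration_ns, 5)
})

test_that("event lists match the brute-force run-length oracle on 1000 series", {
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(20:120, 1)
    st <- runif(n) < runif(1, 0.2, 0.8)
    times <- seq(0, by = 1, length.out = n)
    gap <- sample(c(0, 1, 2), 1)
    ours <- contact_events(st, times, gap)
    oracle <- brute_events(st, times, gap)
    expect_equal(ours$start_frame, oracle$start_frame)
    expect_equal(ours$end_frame, oracle$end_frame)
    expect_equal(ours$duration_ns, oracle$duration_ns)
  }
})

test_that("occurrence criteria require both a 20 ns dwell and >25% occupancy", {
  times <- seq(0.5, 1000, by = 0.5)
  mk <- function(idx) {
    s <- rep(FALSE, 2000)
    s[idx] <- TRUE
    s
  }
  # one contiguous 300 ns event: both clauses pass
  d1 <- occurrence_decision(mk(1:600), times)
  expect_equal(d1$occupancy, 0.30)
  expect_equal(d1$max_event_ns, 300)
  expect_true(d1$counted)
  # thirty 10 ns events, same 30% occupancy: dwell clause fails
  d2 <- occurrence_decision(mk(unlist(lapply(0:29, function(k) k * 66 + 1:20))),
                            times)
  expect_equal(d2$occupancy, 0.30)
  expect_equal(d2$max_event_ns, 10)
  expect_false(d2$counted)
  # a single 20 ns event: occupancy clause fails
  d3 <- occurrence_decision(mk(1:40), times)
  expect_equal(d3$occupancy, 0.02)
  expect_equal(d3$max_event_ns, 20)
  expect_false(d3$counted)
  # the occupancy comparison is strict: exactly 25% is not counted
  d4 <- occurrence_decision(mk(1:500), times)
  expect_equal(d4$occupancy, 0.25)
  expect_false(d4$counted)
})

test_that("occupancy equals summed event durations over the window (no gaps)", {
  set.seed(15)
  for (i in 1:50) {
    n <- 200
    st <- runif(n) < 0.4
    times <- seq(0.5, by = 0.5, length.out = n)
    d <- occurrence_decision(st, times)
    expect_equal(d$occupancy, sum(d$events$duration_ns) / (n * 0.5))
  }
})

test_that("adding contact frames never flips counted to not-counted", {
  set.seed(16)
  times <- seq(1, 100)
  for (i in 1:30) {
    st <- runif(100) < 0.3
    d0 <- occurrence_decision(st, times)
    st2 <- st | (runif(100) < 0.3)
    d2 <- occurrence_decision(st2, times)
    expect_true(!d0$counted || d2$counted)
  }
})

test_that("occurrence ratios aggregate replicas as k/n", {
  mk_dec <- function(counted) list(occupancy = 0.5, max_event_ns = 50,
                                   counted = counted)
  expect_equal(occurrence_ratio(list(mk_dec(TRUE), mk_dec(FALSE)))$ratio, "1/2")
  expect_equal(occurrence_ratio(list(mk_dec(TRUE), mk_dec(TRUE),
                                     mk_dec(TRUE)))$ratio, "3/3")
})

test_that("telegraph statistics match the planted rates", {
  # k_on = k_off -> stationary occupancy 1/2; mean on-dwell 1/k_off
  set.seed(17)
  k <- 0.01; dt <- 0.01; nf <- 1e5
  occs <- dwells <- numeric(10)
  counted <- logical(10)
  crit <- occurrence_criteria()
  for (r in 1:10) {
    s <- telegraph_states(nf, dt, k, k)
    times <- seq(dt, by = dt, length.out = nf)
    occs[r] <- mean(s)
    ev <- contact_events(s, times)
    dwells[r] <- mean(ev$duration_ns)
    counted[r] <- occurrence_decision(s, times, crit)$counted
  }
  tau_c <- 1 / (2 * k)                      # correlation time, ns
  se_occ <- sqrt(0.25 * 2 * tau_c / (nf * dt) / 10)
  expect_lt(abs(mean(occs) - 0.5), 3 * se_occ)
  expect_equal(mean(dwells), 1 / k, tolerance = 0.3)
  # planted occupancy 0.5 with 100 ns dwells: nearly all replicas counted
  expect_gte(sum(counted), 8)
})

test_that("saltbridge_monitor composes the full chain per pair", {
  crit <- occurrence_criteria()
  tr_on <- mini_two_atom_traj(rep(0.4, 100))
  mon <- saltbridge_monitor(tr_on, list(D290_R292 = c("name CZ", "name P")),
                            crit)
  expect_equal(mon$D290_R292$occurrence$ratio, "1/1")
  expect_equal(mon$D290_R292$occurrence$per_replica$occupancy, 1.0)
  # planted break at half time
  tr_break <- mini_two_atom_traj(c(rep(0.4, 50), rep(1.6, 50)))
  mon2 <- saltbridge_monitor(tr_break, list(pair = c("name CZ", "name P")),
                             crit)
  expect_equal(mon2$pair$occurrence$per_replica$occupancy, 0.5)
  expect_true(mon2$pair$occurrence$per_replica$counted)
  # never in contact -> 0/n
  tr_off <- mini_two_atom_traj(rep(1.8, 100))
  mon3 <- saltbridge_monitor(list(tr_off, tr_off),
                             list(pair = c("name CZ", "name P")), crit)
  expect_equal(mon3$pair$occurrence$ratio, "0/2")
})

test_that("scripted ions are classified stable vs diffuse", {
  spec <- synthetic_spec(seed = 18, n_frames = 200, dt_ns = 1,
                         sigma_nm = 0.02, n_ions = 2,
    ion_schedules = list(
      list(ion = 1, siteA = "resid 263 and name P",
           siteB = "resid 280 and name P",
           intervals = data.frame(start_ns = 0, end_ns = 160)),
      list(ion = 2, siteA = "resid 263 and name P",
           siteB = "resid 280 and name P",
           intervals = data.frame(start_ns = 170, end_ns = 180))))
  tr <- generate_trajectory(spec)$trajectory
  br <- ion_bridges(tr, "resid 263 and name P", "resid 280 and name P",
                    "resname NA")
  expect_length(br, 2L)
  expect_equal(br[[1]]$residence_fraction, 0.80, tolerance = 0.02)
  expect_equal(br[[1]]$classification, "stable")
  expect_equal(br[[2]]$residence_fraction, 0.05, tolerance = 0.02)
  expect_equal(br[[2]]$classification, "diffuse")
})

test_that("an ion near only one site does not bridge", {
  at <- data.frame(atom_name = c("P", "P", "NA"),
                   residue_number = c(263L, 280L, 901L),
                   residue_name = c("SEP", "SEP", "NA"),
                   chain_id = c("A", "A", "I"), element = c("P", "P", "Na"))
  top <- topology(at)
  co <- array(0, c(1, 3, 3))
  co[1, 2, 1] <- 1.8   # site B far away
  co[1, 3, 1] <- 0.3   # ion next to site A only
  tr <- trajectory(top, co, 0)
  expect_length(ion_bridges(tr, "resid 263", "resid 280", "resname NA",
                            cutoff_nm = 0.4), 0L)
  # ion at the midpoint of two nearby sites bridges
  co[1, 2, 1] <- 0.6
  co[1, 3, 1] <- 0.3
  tr2 <- trajectory(top, co, 0)
  br <- ion_bridges(tr2, "resid 263", "resid 280", "resname NA",
                    cutoff_nm = 0.4)
  expect_length(br, 1L)
  expect_true(br[[1]]$bridging[1])
})
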