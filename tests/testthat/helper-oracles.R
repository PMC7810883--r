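# Independent oracles used across the suite.

# brute-force run-length scan: events as maximal runs of TRUE, optional
# gap merging, duration (last - first + 1) * dt
brute_events <- function(states, times, gap_tolerance_ns = 0) {
  n <- length(states)
  dt <- if (n > 1) stats::median(diff(times)) else 1
  runs <- list()
  i <- 1
  while (i <= n) {
    if (states[i]) {
      j <- i
      while (j < n && states[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(runs)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_ns = numeric(0)))
  }
  ev <- do.call(rbind, runs)
  merged <- list(ev[1, ])
  if (nrow(ev) > 1) {
    for (r in 2:nrow(ev)) {
      last <- merged[[length(merged)]]
      gap <- (ev[r, 1] - last[2] - 1) * dt
      if (gap <= gap_tolerance_ns) {
        merged[[length(merged)]][2] <- ev[r, 2]
      } else {
        merged[[length(merged) + 1]] <- ev[r, ]
      }
    }
  }
  ev <- do.call(rbind, merged)
  data.frame(start_frame = ev[, 1], end_frame = ev[, 2],
             duration_ns = (ev[, 2] - ev[, 1] + 1) * dt)
}

# numerical-minimization superposition oracle: minimize RMSD over Euler
# angles + translation, independent of the SVD route
oracle_superpose_rmsd <- function(mobile, reference) {
  rotmat <- function(a) {
    Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])),
                 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3])),
                 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    R <- rotmat(p[1:3])
    moved <- mobile %*% t(R)
    moved <- sweep(moved, 2, p[4:6], "+")
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(pi / 2, 0, 0, 0, 0, 0), c(0, pi / 2, pi / 2, 0, 0, 0))) {
    f <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    f <- stats::optim(f$par, obj, method = "BFGS", control = list(maxit = 1000))
    best <- min(best, f$value)
  }
  best
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply one rigid transform to every frame of a trajectory
transform_trajectory <- function(traj, R, t) {
  co <- traj$coords
  for (f in seq_len(dim(co)[1])) {
    co[f, , ] <- co[f, , ] %*% t(R) +
      matrix(t, nrow = dim(co)[2], ncol = 3, byrow = TRUE)
  }
  trajectory(traj$topology, co, traj$times_ns, aligned = FALSE)
}

# tiny hand-written 3-residue PDB fixture
write_mini_pdb <- function(path, insert_code = FALSE, altloc = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A 243      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A 243      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A 243      10.729   6.768  -4.123  1.00  0.00           C",
    "ATOM      4  O   ALA A 243      10.934   6.641  -2.915  1.00  0.00           O",
    "ATOM      5  N   SER A 244       9.722   7.485  -4.630  1.00  0.00           N",
    "ATOM      6  CA  SER A 244       8.740   8.219  -3.821  1.00  0.00           C",
    "ATOM      7  C   SER A 244       7.481   7.374  -3.597  1.00  0.00           C",
    "ATOM      8  O   SER A 244       6.861   7.443  -2.531  1.00  0.00           O",
    "HETATM    9  N   SEP A 245       7.093   6.565  -4.583  1.00  0.00           N",
    "HETATM   10  CA  SEP A 245       5.903   5.705  -4.493  1.00  0.00           C",
    "HETATM   11  P   SEP A 245       4.618   6.395  -5.384  1.00  0.00           P",
    "END")
  if (insert_code) {
    substr(lines[5], 27, 27) <- "A"
  }
  if (altloc) {
    l <- lines[2]
    substr(l, 17, 17) <- "B"
    substr(l, 7, 11) <- "   99"
    lines <- append(lines, l, after = 2)
  }
  writeLines(lines, path)
  path
}
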