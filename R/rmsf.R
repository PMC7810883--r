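#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its
#' time-averaged position, RMSF_i = sqrt( <|r_i(t) - <r_i>|^2> ), computed
#' on an aligned trajectory. Per residue the C-alpha value is reported by
#' default (the field convention for per-residue profiles); a mass-less
#' heavy-atom average is available via `per_residue = "heavy"`.
#'
#' @param traj an aligned [trajectory] (see [align_trajectory()]). Passing
#'   an unaligned trajectory is an error unless `allow_unaligned = TRUE`.
#' @param selection atom selection, default `"name CA"`.
#' @param per_residue `"ca"` (default) reports one value per residue taken
#'   from its C-alpha; `"heavy"` averages squared fluctuations over the
#'   selected atoms of each residue; `"atom"` reports per-atom values.
#' @param allow_unaligned explicit override of the alignment check.
#' @return An `rmsf_profile`: data.frame-backed list with
#'   `residue_numbers`, `rmsf_nm`, optional `std_nm`, `n_replicas`,
#'   `selection`.
#' @export
compute_rmsf <- function(traj, selection = "name CA",
                         per_residue = c("ca", "heavy", "atom"),
                         allow_unaligned = FALSE) {
  per_residue <- match.arg(per_residue)
  if (!traj$aligned && !allow_unaligned) {
    stop("compute_rmsf: trajectory is not aligned; run align_trajectory() ",
         "or set allow_unaligned = TRUE")
  }
  sel0 <- resolve_selection(selection, traj$topology)
  if (per_residue == "ca") {
    ca <- resolve_selection("name CA", traj$topology)
    sel0 <- intersect(sel0, ca)
  }
  if (length(sel0) == 0L) stop("compute_rmsf: empty selection")
  idx <- sel0 + 1L
  # per-atom mean squared displacement about the time mean, summed over xyz
  msd <- numeric(length(idx))
  for (k in 1:3) {
    x <- matrix(traj$coords[, idx, k], nrow = n_frames(traj))
    mu <- colMeans(x)
    msd <- msd + colMeans(x^2) - mu^2
  }
  atom_rmsf <- sqrt(pmax(msd, 0))
  resno <- traj$topology$atoms$residue_number[idx]
  if (per_residue == "atom") {
    prof <- data.frame(residue_number = resno, rmsf_nm = atom_rmsf)
  } else if (per_residue == "ca") {
    prof <- data.frame(residue_number = resno, rmsf_nm = atom_rmsf)
    prof <- prof[order(prof$residue_number), ]
  } else {
    agg <- tapply(atom_rmsf^2, resno, mean)
    prof <- data.frame(residue_number = as.integer(names(agg)),
                       rmsf_nm = sqrt(as.numeric(agg)))
  }
  rownames(prof) <- NULL
  rmsf_profile(prof$residue_number, prof$rmsf_nm, n_replicas = 1L,
               selection = if (inherits(selection, "atom_selection"))
                 selection$expression else selection)
}

#' Construct an RMSF profile object
#' @param residue_numbers integer residue grid.
#' @param rmsf_nm nonnegative fluctuation values, nm.
#' @param std_nm optional across-replica standard deviation (present iff
#'   `n_replicas >= 2`).
#' @param n_replicas number of replicas combined.
#' @param selection selection expression the profile was computed on.
#' @export
rmsf_profile <- function(residue_numbers, rmsf_nm, std_nm = NULL,
                         n_replicas = 1L, selection = "name CA") {
  stopifnot(length(residue_numbers) == length(rmsf_nm), all(rmsf_nm >= 0))
  if (!is.null(std_nm)) {
    stopifnot(length(std_nm) == length(rmsf_nm), all(std_nm >= 0))
  }
  if (n_replicas >= 2L && is.null(std_nm)) {
    stop("rmsf_profile: std_nm required when n_replicas >= 2")
  }
  structure(list(residue_numbers = as.integer(residue_numbers),
                 rmsf_nm = as.numeric(rmsf_nm),
                 std_nm = if (!is.null(std_nm)) as.numeric(std_nm),
                 n_replicas = as.integer(n_replicas),
                 selection = selection),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("<rmsf_profile> %d residues, %d replica(s), mean RMSF %.4f nm\n",
              length(x$residue_numbers), x$n_replicas, mean(x$rmsf_nm)))
  invisible(x)
}

#' @export
as.data.frame.rmsf_profile <- function(x, ...) {
  data.frame(residue_number = x$residue_numbers, rmsf_nm = x$rmsf_nm,
             std_nm = if (is.null(x$std_nm)) NA_real_ else x$std_nm)
}

#' Combine replica RMSF profiles into mean +/- standard deviation
#'
#' Element-wise mean and sample (n-1) standard deviation across replicas,
#' as displayed for the two independent 1-us wild-type runs.
#'
#' @param profiles list of >= 2 `rmsf_profile` objects on identical
#'   residue grids.
#' @return An `rmsf_profile` with `std_nm` set.
#' @export
combine_replicas <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  grid <- profiles[[1]]$residue_numbers
  for (p in profiles) {
    if (!identical(p$residue_numbers, grid)) {
      stop("combine_replicas: residue grids differ between replicas")
    }
  }
  m <- vapply(profiles, function(p) p$rmsf_nm, numeric(length(grid)))
  rmsf_profile(grid, rowMeans(m), std_nm = apply(m, 1, stats::sd),
               n_replicas = length(profiles),
               selection = profiles[[1]]$selection)
}

#' Per-residue RMSF difference (variant minus wild type)
#'
#' Positive values mean increased fluctuation in the variant relative to
#' the wild type; defined on the intersection of the two residue grids.
#'
#' @param variant,wt `rmsf_profile` objects.
#' @param variant_label label stored with the result.
#' @return A `delta_rmsf` object (data.frame-backed).
#' @export
delta_rmsf <- function(variant, wt, variant_label = "variant") {
  common <- intersect(variant$residue_numbers, wt$residue_numbers)
  if (length(common) == 0L) stop("delta_rmsf: residue grids do not overlap")
  iv <- match(common, variant$residue_numbers)
  iw <- match(common, wt$residue_numbers)
  structure(list(residue_numbers = as.integer(common),
                 delta_nm = variant$rmsf_nm[iv] - wt$rmsf_nm[iw],
                 variant_label = variant_label),
            class = "delta_rmsf")
}

#' @export
as.data.frame.delta_rmsf <- function(x, ...) {
  data.frame(residue_number = x$residue_numbers, delta_rmsf_nm = x$delta_nm,
             variant = x$variant_label)
}

#' Replica convergence summary
#'
#' Maximum per-residue absolute difference and Pearson correlation between
#' replica RMSF profiles; both replicas must be on the same residue grid.
#' For a converged pair of runs the difference tends to zero and the
#' correlation to one.
#'
#' @param profiles list of >= 2 `rmsf_profile` objects.
#' @return list with `max_abs_diff_nm` and `pearson_r` (for > 2 replicas,
#'   the maximum pairwise difference and the minimum pairwise correlation).
#' @export
convergence_check <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  grid <- profiles[[1]]$residue_numbers
  for (p in profiles) {
    if (!identical(p$residue_numbers, grid)) {
      stop("convergence_check: residue grids differ")
    }
  }
  maxd <- 0; minr <- 1
  np <- length(profiles)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    a <- profiles[[i]]$rmsf_nm; b <- profiles[[j]]$rmsf_nm
    maxd <- max(maxd, max(abs(a - b)))
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      if (max(abs(a - b)) == 0) 1 else NA_real_
    } else {
      stats::cor(a, b)
    }
    minr <- min(minr, r, na.rm = TRUE)
  }
  list(max_abs_diff_nm = maxd, pearson_r = minr)
}
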