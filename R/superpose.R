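#' Kabsch superposition
#'
#' Least-squares rigid-body superposition of `mobile` onto `reference` via
#' SVD of the weighted covariance matrix. The returned rotation is always
#' proper (det = +1); degenerate (collinear) point sets are an error
#' rather than a silent reflection.
#'
#' @param mobile,reference `n x 3` matrices (nm), n >= 3.
#' @param weights optional nonnegative weights, length n.
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% rotation + translation` superposes onto `reference`, and
#'   the residual `rmsd_nm`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("kabsch_superpose: point counts differ")
  if (n < 3L) stop("kabsch_superpose: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  # collinear/degenerate sets have a (near-)zero second singular value and
  # no unique rotation
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    stop("kabsch_superpose: degenerate (collinear) configuration")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  tr <- cr - as.numeric(cm %*% R)
  fitted <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  list(rotation = R, translation = tr, rmsd_nm = rmsd)
}

rmsd_points <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Align every frame of a trajectory onto a reference
#'
#' Each frame is Kabsch-superposed onto the reference on the fit-selection
#' atoms (all C-alpha by default); all other atoms are co-transformed. The
#' result carries an `aligned` flag consumed by [compute_rmsf()].
#'
#' @param traj a [trajectory].
#' @param reference_frame frame index (1-based) used as reference, or an
#'   `n_atoms x 3` coordinate matrix (nm).
#' @param fit_selection an `atom_selection` or expression; must resolve to
#'   >= 3 atoms.
#' @return The aligned [trajectory].
#' @export
align_trajectory <- function(traj, reference_frame = 1L,
                             fit_selection = "name CA") {
  sel <- resolve_selection(fit_selection, traj$topology)
  if (length(sel) < 3L) {
    stop(sprintf("align_trajectory: fit selection resolves to %d atoms (need >= 3)",
                 length(sel)))
  }
  idx <- sel + 1L
  ref <- if (is.matrix(reference_frame)) {
    stopifnot(nrow(reference_frame) == dim(traj$coords)[2])
    reference_frame[idx, , drop = FALSE]
  } else {
    traj$coords[reference_frame, idx, , drop = TRUE]
  }
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3L)
  co <- traj$coords
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    fr <- co[f, , ]
    fit <- kabsch_superpose(fr[idx, , drop = FALSE], ref)
    co[f, , ] <- fr %*% fit$rotation +
      matrix(fit$translation, nrow = dim(co)[2], ncol = 3L, byrow = TRUE)
  }
  trajectory(traj$topology, co, traj$times_ns, box_nm = traj$box_nm,
             aligned = TRUE)
}

#' Per-frame RMSD time series
#'
#' RMSD of the selection atoms against a reference frame, one value per
#' frame. With `superpose = TRUE` (default) each frame is pairwise
#' superposed on the selection before measuring, so the series reflects
#' internal motion only.
#'
#' @param traj a [trajectory].
#' @param reference frame index (1-based) or `n_atoms x 3` matrix.
#' @param selection atoms to measure (and fit on), default all C-alpha.
#' @param superpose pairwise-superpose each frame before measuring.
#' @return data.frame with `time_ns`, `rmsd_nm`.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = "name CA",
                        superpose = TRUE) {
  sel <- resolve_selection(selection, traj$topology)
  if (length(sel) == 0L) stop("rmsd_series: empty selection")
  idx <- sel + 1L
  ref <- if (is.matrix(reference)) reference[idx, , drop = FALSE]
         else traj$coords[reference, idx, , drop = TRUE]
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3L)
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- traj$coords[f, idx, , drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3L)
    out[f] <- if (superpose && length(idx) >= 3L) {
      kabsch_superpose(fr, ref)$rmsd_nm
    } else {
      rmsd_points(fr, ref)
    }
  }
  data.frame(time_ns = traj$times_ns, rmsd_nm = out)
}
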