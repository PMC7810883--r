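#' Ion-mediated bridge detection
#'
#' Detects frames in which an ion simultaneously coordinates two anionic
#' sites (e.g. the phosphates of pS263 and pS280, which interact through
#' Na+ rather than directly): an ion bridges at a frame iff it is within
#' `cutoff_nm` of at least one atom of site A AND at least one atom of
#' site B. Each ion's residence fraction is its bridging fraction over all
#' analyzed frames; ions with residence >= `stable_threshold` are
#' classified `"stable"`, bridging ions below it `"diffuse"`.
#'
#' @param traj a [trajectory].
#' @param siteA,siteB atom selections for the two anionic sites.
#' @param ions selection resolving to the candidate ions (one atom each),
#'   e.g. `"resname NA"`.
#' @param cutoff_nm coordination cutoff, default 0.35 nm (typical Na+-O
#'   coordination distance).
#' @param stable_threshold residence fraction separating stable from
#'   diffuse ions, default 0.5.
#' @return list of `ion_bridge_record`s (one per ion that ever bridges):
#'   `ion_id` (atom_index), `bridging` (logical per frame),
#'   `residence_fraction`, `classification`.
#' @export
ion_bridges <- function(traj, siteA, siteB, ions, cutoff_nm = 0.35,
                        stable_threshold = 0.5) {
  sa <- resolve_selection(siteA, traj$topology)
  sb <- resolve_selection(siteB, traj$topology)
  si <- resolve_selection(ions, traj$topology)
  if (length(sa) == 0L || length(sb) == 0L) {
    stop("ion_bridges: empty site selection")
  }
  if (length(si) == 0L) stop("ion_bridges: empty ion selection")
  nf <- n_frames(traj)
  records <- list()
  for (ion in si) {
    bridging <- logical(nf)
    for (f in seq_len(nf)) {
      p <- traj$coords[f, ion + 1L, ]
      box <- if (!is.null(traj$box_nm)) traj$box_nm[f, ]
      dA <- set_min_distance(matrix(p, 1L), coords_of(traj, sa + 1L, f), box)
      if (dA > cutoff_nm) next
      dB <- set_min_distance(matrix(p, 1L), coords_of(traj, sb + 1L, f), box)
      bridging[f] <- dB <= cutoff_nm
    }
    if (!any(bridging)) next
    res <- mean(bridging)
    records[[length(records) + 1L]] <- structure(
      list(ion_id = ion, bridging = bridging, residence_fraction = res,
           classification = if (res >= stable_threshold) "stable" else "diffuse"),
      class = "ion_bridge_record")
  }
  records
}

#' @export
print.ion_bridge_record <- function(x, ...) {
  cat(sprintf("<ion_bridge_record> ion %d: residence %.3f (%s)\n",
              x$ion_id, x$residence_fraction, x$classification))
  invisible(x)
}
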