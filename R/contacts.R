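#' Contact-occurrence criteria
#'
#' Houses the thresholds under which a monitored interaction is "counted":
#' atoms within `distance_cutoff_nm` (1 nm) are in contact; the
#' interaction counts only when at least one contiguous contact event
#' lasts `min_event_ns` (20 ns) or longer AND the contact is present in
#' strictly more than `min_occupancy` (25%) of the analyzed simulation
#' time.
#'
#' @param distance_cutoff_nm contact distance cutoff, default 1.0 nm
#'   (boundary inclusive: d <= cutoff is a contact).
#' @param min_event_ns minimum contiguous event duration, default 20 ns.
#' @param min_occupancy minimum occupancy fraction, default 0.25; the
#'   comparison is strict (`occupancy > min_occupancy`).
#' @param gap_tolerance_ns contact interruptions up to this long are
#'   bridged when building events; default 0 (no merging).
#' @return An `occurrence_criteria` object.
#' @export
occurrence_criteria <- function(distance_cutoff_nm = 1.0, min_event_ns = 20,
                                min_occupancy = 0.25, gap_tolerance_ns = 0) {
  stopifnot(distance_cutoff_nm > 0, min_event_ns > 0,
            min_occupancy > 0, min_occupancy < 1, gap_tolerance_ns >= 0)
  structure(list(distance_cutoff_nm = distance_cutoff_nm,
                 min_event_ns = min_event_ns,
                 min_occupancy = min_occupancy,
                 gap_tolerance_ns = gap_tolerance_ns),
            class = "occurrence_criteria")
}

coords_of <- function(traj, idx1, frame) {
  m <- traj$coords[frame, idx1, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
  m
}

min_image_delta <- function(d, box) {
  # orthorhombic minimum-image convention per coordinate
  d - box * round(d / box)
}

set_min_distance <- function(A, B, box = NULL) {
  # minimum inter-set distance; sets are small (a handful of atoms)
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d <- sweep(B, 2, A[i, ])
    if (!is.null(box)) d <- t(apply(d, 1, min_image_delta, box = box))
    best <- min(best, sqrt(min(rowSums(d^2))))
  }
  best
}

#' Distance time series between two atom selections
#'
#' Per-frame Euclidean distance (minimum-image if the trajectory has a
#' periodic box). Selections resolving to several atoms are reduced to the
#' minimum inter-set distance per frame — the natural reading of "distance
#' to the phosphate group"; pass a single-atom selection (e.g.
#' `"... and name P"`) to use one named atom instead.
#'
#' @param traj a [trajectory].
#' @param atomA,atomB atom selections (expression or `atom_selection`).
#' @param pair_label label stored with the series (defaults to the two
#'   expressions).
#' @return A `distance_series`: data.frame with `time_ns`, `distance_nm`,
#'   plus attribute `pair_label`.
#' @export
distance_series <- function(traj, atomA, atomB, pair_label = NULL) {
  sa <- resolve_selection(atomA, traj$topology)
  sb <- resolve_selection(atomB, traj$topology)
  if (length(sa) == 0L || length(sb) == 0L) {
    stop("distance_series: empty selection (A: ", length(sa),
         " atoms, B: ", length(sb), " atoms)")
  }
  ia <- sa + 1L; ib <- sb + 1L
  nf <- n_frames(traj)
  out <- numeric(nf)
  if (length(ia) == 1L && length(ib) == 1L) {
    d <- traj$coords[, ib, , drop = FALSE] - traj$coords[, ia, , drop = FALSE]
    d <- matrix(d, nrow = nf, ncol = 3L)
    if (!is.null(traj$box_nm)) d <- d - traj$box_nm * round(d / traj$box_nm)
    out <- sqrt(rowSums(d^2))
  } else {
    for (f in seq_len(nf)) {
      out[f] <- set_min_distance(coords_of(traj, ia, f), coords_of(traj, ib, f),
                                 box = if (!is.null(traj$box_nm)) traj$box_nm[f, ])
    }
  }
  if (is.null(pair_label)) {
    lab_of <- function(s) if (inherits(s, "atom_selection")) s$expression else s
    pair_label <- paste(lab_of(atomA), lab_of(atomB), sep = " -- ")
  }
  structure(data.frame(time_ns = traj$times_ns, distance_nm = out),
            pair_label = pair_label, class = c("distance_series", "data.frame"))
}

#' Boolean contact states from a distance series
#'
#' A frame is in contact iff distance <= cutoff (boundary inclusive).
#'
#' @param series a `distance_series` (or data.frame with `distance_nm`).
#' @param criteria an [occurrence_criteria].
#' @return Logical vector, one element per frame.
#' @export
contact_states <- function(series, criteria = occurrence_criteria()) {
  stopifnot(!is.null(series$distance_nm), all(series$distance_nm >= 0))
  series$distance_nm <= criteria$distance_cutoff_nm
}

#' Contiguous contact events
#'
#' Maximal runs of in-contact frames; runs separated by out-of-contact
#' gaps no longer than `gap_tolerance_ns` are merged. An event's duration
#' counts its frames inclusively: (last - first + 1) * dt.
#'
#' @param states logical per-frame contact vector.
#' @param times frame times, ns.
#' @param gap_tolerance_ns merge tolerance, default 0.
#' @return data.frame with `start_ns`, `end_ns`, `duration_ns`,
#'   `start_frame`, `end_frame` (1-based), sorted and disjoint.
#' @export
contact_events <- function(states, times, gap_tolerance_ns = 0) {
  stopifnot(length(states) == length(times), gap_tolerance_ns >= 0)
  n <- length(states)
  empty <- data.frame(start_ns = numeric(0), end_ns = numeric(0),
                      duration_ns = numeric(0), start_frame = integer(0),
                      end_frame = integer(0))
  if (n == 0L || !any(states)) return(empty)
  dt <- if (n > 1L) stats::median(diff(times)) else 1
  r <- rle(as.logical(states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start_frame = starts[r$values], end_frame = ends[r$values])
  if (gap_tolerance_ns > 0 && nrow(ev) > 1L) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      gap_frames <- ev$start_frame[i] - merged$end_frame[nrow(merged)] - 1L
      if (gap_frames * dt <= gap_tolerance_ns) {
        merged$end_frame[nrow(merged)] <- ev$end_frame[i]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  data.frame(start_ns = times[ev$start_frame],
             end_ns = times[ev$end_frame],
             duration_ns = (ev$end_frame - ev$start_frame + 1L) * dt,
             start_frame = ev$start_frame,
             end_frame = ev$end_frame)
}

#' Apply the occurrence criteria to one contact series
#'
#' `counted` requires both clauses: at least one contiguous event of
#' `min_event_ns` or longer, and occupancy strictly above `min_occupancy`.
#' Occupancy is the fraction of all analyzed frames in contact (the full
#' window is the denominator).
#'
#' @param states logical contact vector.
#' @param times frame times, ns.
#' @param criteria an [occurrence_criteria].
#' @return list with `occupancy`, `max_event_ns`, `counted`, `events`.
#' @export
occurrence_decision <- function(states, times, criteria = occurrence_criteria()) {
  stopifnot(length(states) > 0L)
  ev <- contact_events(states, times, criteria$gap_tolerance_ns)
  occupancy <- mean(states)
  max_event <- if (nrow(ev)) max(ev$duration_ns) else 0
  list(occupancy = occupancy,
       max_event_ns = max_event,
       counted = (max_event >= criteria$min_event_ns) &&
                 (occupancy > criteria$min_occupancy),
       events = ev)
}

#' Occurrence ratio across replicas
#'
#' The per-interaction summary reported as "k/n": the number of replicas
#' in which the interaction met the occurrence criteria over the number of
#' replicas simulated.
#'
#' @param decisions list of [occurrence_decision()] results (one per
#'   replica).
#' @return An `occurrence_result`: list with `per_replica` data.frame
#'   (`replica_id`, `occupancy`, `max_event_ns`, `counted`), `k`, `n`, and
#'   the `ratio` string.
#' @export
occurrence_ratio <- function(decisions) {
  stopifnot(is.list(decisions), length(decisions) >= 1L)
  per <- data.frame(
    replica_id = seq_along(decisions),
    occupancy = vapply(decisions, `[[`, numeric(1), "occupancy"),
    max_event_ns = vapply(decisions, `[[`, numeric(1), "max_event_ns"),
    counted = vapply(decisions, `[[`, logical(1), "counted")
  )
  k <- sum(per$counted)
  structure(list(per_replica = per, k = k, n = nrow(per),
                 ratio = sprintf("%d/%d", k, nrow(per))),
            class = "occurrence_result")
}

#' @export
print.occurrence_result <- function(x, ...) {
  cat(sprintf("<occurrence_result> %s replicas counted (occupancies: %s)\n",
              x$ratio, paste(sprintf("%.2f", x$per_replica$occupancy),
                             collapse = ", ")))
  invisible(x)
}

#' Monitor salt-bridge (or any atom-pair) contacts across replicas
#'
#' Convenience composite: for each replica trajectory and each pair,
#' distance series -> contact states -> occurrence decision; results per
#' pair are aggregated into an occurrence ratio. Used e.g. for the
#' D290-R292 salt bridge that stabilizes the short loop after helix a1.
#'
#' @param trajs a [trajectory] or list of replica trajectories.
#' @param pairs list of 2-element lists/character vectors
#'   `(selectionA, selectionB)`, optionally named.
#' @param criteria an [occurrence_criteria].
#' @return Named list per pair: `occurrence` (an `occurrence_result`) and
#'   `series` (list of per-replica `distance_series`).
#' @export
saltbridge_monitor <- function(trajs, pairs, criteria = occurrence_criteria()) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(pairs) >= 1L)
  nm <- names(pairs)
  if (is.null(nm)) nm <- rep("", length(pairs))
  out <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    stopifnot(length(p) == 2L)
    series <- lapply(trajs, distance_series, atomA = p[[1]], atomB = p[[2]])
    decisions <- lapply(series, function(s) {
      occurrence_decision(contact_states(s, criteria), s$time_ns, criteria)
    })
    label <- if (nzchar(nm[i])) nm[i] else attr(series[[1]], "pair_label")
    out[[label]] <- list(occurrence = occurrence_ratio(decisions),
                         series = series)
  }
  out
}
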