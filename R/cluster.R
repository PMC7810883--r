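#' Leader-style RMSD clustering of conformations
#'
#' Daura neighbor-counting clustering, the standard algorithm for counting
#' MD conformers: compute all pairwise RMSDs on the selection (with
#' pairwise superposition), then iteratively take the frame with the most
#' neighbors within the cutoff as the next cluster center (medoid), assign
#' it and its neighbors, remove them, and repeat. Ties are broken
#' deterministically by lowest frame index. Cluster ids are 0-based and
#' ordered by descending cluster size (cluster 0 is the largest; equal
#' sizes ordered by medoid frame index).
#'
#' Used here to count conformations of the long beta2-beta3 loop, which
#' falls into three distinct conformers in the wild-type domain.
#'
#' @param traj a [trajectory].
#' @param selection atoms clustered on (e.g. `"resid 266-277 and name CA"`).
#' @param cutoff_nm neighbor cutoff, default 0.15 nm.
#' @param superpose pairwise-superpose before measuring each pairwise RMSD.
#' @return A `cluster_result`: list with `frame_labels` (0-based, one per
#'   frame), `n_clusters`, `cutoff_nm`, `medoid_frames` (1-based frame
#'   index per cluster), `cluster_sizes`.
#' @export
cluster_conformations <- function(traj, selection = "name CA",
                                  cutoff_nm = 0.15, superpose = TRUE) {
  stopifnot(cutoff_nm > 0)
  nf <- n_frames(traj)
  if (nf < 1L) stop("cluster_conformations: empty trajectory")
  sel <- resolve_selection(selection, traj$topology)
  if (length(sel) == 0L) stop("cluster_conformations: empty selection")
  idx <- sel + 1L
  pts <- lapply(seq_len(nf), function(f) {
    m <- traj$coords[f, idx, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
    m
  })
  # pairwise RMSD matrix
  D <- matrix(0, nf, nf)
  if (nf > 1L) {
    for (i in seq_len(nf - 1L)) {
      for (j in (i + 1L):nf) {
        D[i, j] <- D[j, i] <- if (superpose && length(idx) >= 3L) {
          kabsch_superpose(pts[[j]], pts[[i]])$rmsd_nm
        } else {
          rmsd_points(pts[[j]], pts[[i]])
        }
      }
    }
  }
  neigh <- D <= cutoff_nm   # includes self
  labels <- rep(NA_integer_, nf)
  medoids <- integer(0)
  sizes <- integer(0)
  remaining <- rep(TRUE, nf)
  k <- 0L
  while (any(remaining)) {
    counts <- colSums(neigh & remaining)  # neighbors among remaining frames
    counts[!remaining] <- -1L
    center <- which.max(counts)           # which.max -> lowest index on ties
    members <- which(remaining & neigh[, center])
    labels[members] <- k
    medoids <- c(medoids, center)
    sizes <- c(sizes, length(members))
    remaining[members] <- FALSE
    k <- k + 1L
  }
  # relabel by descending size (stable: ties keep medoid-index order)
  ord <- order(-sizes, medoids)
  relab <- integer(k)
  relab[ord] <- seq_len(k) - 1L
  structure(list(frame_labels = relab[labels + 1L],
                 n_clusters = k,
                 cutoff_nm = cutoff_nm,
                 medoid_frames = medoids[ord],
                 cluster_sizes = sizes[ord]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters (cutoff %.3g nm); sizes: %s\n",
              x$n_clusters, x$cutoff_nm,
              paste(x$cluster_sizes, collapse = ", ")))
  invisible(x)
}
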