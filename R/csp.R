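#' Weighted chemical-shift perturbation
#'
#' Combined amide shift change upon titration,
#' `delta_obs = sqrt(d1H^2 + (d15N/6)^2)` — the nitrogen change is
#' down-weighted by exactly 1/6 (not the also-common 0.14 or 0.2
#' variants).
#'
#' @param d1H_ppm change in 1H shift vs the reference point, ppm.
#' @param d15N_ppm change in 15N shift vs the reference point, ppm.
#' @return Nonnegative combined shift change, ppm (vectorized).
#' @examples
#' compute_csp(0.03, 0.12)  # 0.036056
#' @export
compute_csp <- function(d1H_ppm, d15N_ppm) {
  sqrt(d1H_ppm^2 + (d15N_ppm / 6)^2)
}

#' Construct a titration series
#'
#' @param variant_label variant name (`"wt"`, `"S263E"`, `"S280E"`, ...).
#' @param points list of `list(ligand_ratio =, peaks =)` where `peaks` is
#'   a data.frame with `residue_number`, `d1H_ppm`, `d15N_ppm`,
#'   `intensity`. Ratios must be strictly increasing from 0; point 1
#'   (ratio 0) is the no-peptide reference.
#' @return A `titration_series`.
#' @export
titration_series <- function(variant_label, points) {
  ratios <- vapply(points, `[[`, numeric(1), "ligand_ratio")
  if (length(ratios) < 2L || ratios[1] != 0 || any(diff(ratios) <= 0)) {
    stop("titration_series: ligand ratios must be strictly increasing from 0")
  }
  for (p in points) {
    pk <- p$peaks
    need <- c("residue_number", "d1H_ppm", "d15N_ppm", "intensity")
    if (!all(need %in% names(pk))) {
      stop("titration_series: peaks need columns ", paste(need, collapse = ","))
    }
    if (any(pk$intensity < 0)) stop("titration_series: negative intensity")
    if (anyDuplicated(pk$residue_number)) {
      stop("titration_series: duplicate residue at ratio ", p$ligand_ratio)
    }
  }
  structure(list(variant_label = variant_label, points = points),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s: %d points, ratios %s\n",
              x$variant_label, length(x$points),
              paste(vapply(x$points, `[[`, numeric(1), "ligand_ratio"),
                    collapse = ", ")))
  invisible(x)
}

ratios_of <- function(series) {
  vapply(series$points, `[[`, numeric(1), "ligand_ratio")
}

peak_of <- function(point, residue) {
  pk <- point$peaks
  pk[pk$residue_number == residue, , drop = FALSE]
}

#' Per-residue CSP across a titration
#'
#' @param series a [titration_series()].
#' @param residues residue numbers; default all residues of the reference
#'   point.
#' @return data.frame with `residue_number`, `ligand_ratio`,
#'   `delta_obs_ppm` (NA where the peak has broadened beyond detection).
#' @export
csp_profile <- function(series, residues = NULL) {
  ref <- series$points[[1]]$peaks
  if (is.null(residues)) residues <- ref$residue_number
  out <- list()
  for (r in residues) {
    p0 <- peak_of(series$points[[1]], r)
    if (nrow(p0) == 0L) stop("csp_profile: residue ", r, " absent at reference")
    for (pt in series$points) {
      p <- peak_of(pt, r)
      out[[length(out) + 1L]] <- data.frame(
        residue_number = r, ligand_ratio = pt$ligand_ratio,
        delta_obs_ppm = if (nrow(p)) {
          compute_csp(p$d1H_ppm - p0$d1H_ppm, p$d15N_ppm - p0$d15N_ppm)
        } else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Normalized intensity decay of one residue
#'
#' Intensities divided by the reference (no-peptide) intensity. A peak
#' missing at some point has broadened beyond detection: it is reported as
#' 0 with `beyond_detection = TRUE`, and stays 0 from the first missing
#' point onward.
#'
#' @param series a [titration_series()].
#' @param residue residue number (must exist at the reference with
#'   intensity > 0).
#' @return data.frame with `ligand_ratio`, `rel_intensity`,
#'   `beyond_detection`.
#' @export
intensity_profile <- function(series, residue) {
  p0 <- peak_of(series$points[[1]], residue)
  if (nrow(p0) == 0L || p0$intensity <= 0) {
    stop("intensity_profile: residue ", residue,
         " absent (or zero intensity) at reference")
  }
  ratios <- ratios_of(series)
  rel <- numeric(length(ratios)); gone <- logical(length(ratios))
  vanished <- FALSE
  for (i in seq_along(ratios)) {
    p <- peak_of(series$points[[i]], residue)
    if (vanished || nrow(p) == 0L) {
      vanished <- TRUE
      rel[i] <- 0; gone[i] <- TRUE
    } else {
      rel[i] <- p$intensity / p0$intensity
    }
  }
  data.frame(ligand_ratio = ratios, rel_intensity = rel,
             beyond_detection = gone)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Qualitative affinity ranking from intensity broadening
#'
#' Operationalizes the broadening readout of an HSQC titration: for each
#' variant, the score is the mean over reporter residues of one minus the
#' normalized area under the intensity-decay curve (trapezoid over the
#' ligand-ratio axis, peaks broadened beyond detection contributing 0).
#' Faster/deeper broadening gives a larger score, i.e. stronger apparent
#' binding. The output is an ordering, not a Kd: ties (score difference
#' below `tie_tol`) are reported, not broken.
#'
#' @param series_set list of [titration_series()], all sharing the
#'   reporter residues.
#' @param reporter_residues reporter residue numbers; default
#'   `c(260, 261, 279, 285)` (carboxylate-binding loop L260/G261 and
#'   groove-adjacent G279/G285).
#' @param tie_tol score difference below which two variants tie.
#' @return data.frame sorted by descending score with `variant`, `score`,
#'   `rank` (ties share a rank).
#' @export
rank_affinity <- function(series_set, reporter_residues = c(260, 261, 279, 285),
                          tie_tol = 1e-9) {
  stopifnot(length(series_set) >= 1L)
  scores <- vapply(series_set, function(s) {
    ref_res <- s$points[[1]]$peaks$residue_number
    miss <- setdiff(reporter_residues, ref_res)
    if (length(miss)) {
      stop("rank_affinity: variant ", s$variant_label,
           " lacks reporter residue(s) ", paste(miss, collapse = ","))
    }
    ratios <- ratios_of(s)
    span <- diff(range(ratios))
    mean(vapply(reporter_residues, function(r) {
      ip <- intensity_profile(s, r)
      1 - trapz(ip$ligand_ratio, ip$rel_intensity) / span
    }, numeric(1)))
  }, numeric(1))
  variants <- vapply(series_set, `[[`, character(1), "variant_label")
  ord <- order(-scores)
  out <- data.frame(variant = variants[ord], score = scores[ord])
  # shared ranks for ties
  rank <- integer(nrow(out))
  rank[1] <- 1L
  if (nrow(out) > 1L) {
    for (i in 2:nrow(out)) {
      rank[i] <- if (out$score[i - 1] - out$score[i] < tie_tol) rank[i - 1] else i
    }
  }
  out$rank <- rank
  out
}

#' Read a titration peak list from CSV
#'
#' Expected columns: `variant, ligand_ratio, residue, d1H, d15N,
#' intensity`. Rows may be in any order; one series per file.
#'
#' @param path CSV file.
#' @return A [titration_series()].
#' @export
read_peaklist <- function(path) {
  d <- utils::read.csv(path)
  need <- c("variant", "ligand_ratio", "residue", "d1H", "d15N", "intensity")
  if (!all(need %in% names(d))) {
    stop("read_peaklist: need columns ", paste(need, collapse = ","))
  }
  if (length(unique(d$variant)) != 1L) {
    stop("read_peaklist: one variant per file expected")
  }
  if (anyDuplicated(d[, c("ligand_ratio", "residue")])) {
    stop("read_peaklist: duplicate (ligand_ratio, residue) row")
  }
  ratios <- sort(unique(d$ligand_ratio))
  points <- lapply(ratios, function(rt) {
    pk <- d[d$ligand_ratio == rt, , drop = FALSE]
    pk <- pk[order(pk$residue), ]
    list(ligand_ratio = rt,
         peaks = data.frame(residue_number = pk$residue, d1H_ppm = pk$d1H,
                            d15N_ppm = pk$d15N, intensity = pk$intensity))
  })
  titration_series(d$variant[1], points)
}

#' Write a titration series to CSV (inverse of [read_peaklist()])
#' @param series a [titration_series()].
#' @param path output CSV file.
#' @export
write_peaklist <- function(series, path) {
  rows <- lapply(series$points, function(pt) {
    data.frame(variant = series$variant_label,
               ligand_ratio = pt$ligand_ratio,
               residue = pt$peaks$residue_number,
               d1H = pt$peaks$d1H_ppm, d15N = pt$peaks$d15N_ppm,
               intensity = pt$peaks$intensity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
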