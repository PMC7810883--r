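# Secondary-structure assignment, Kabsch-Sander style, reduced to the
# four classes the analysis uses: H (alpha helix), G (3-10 helix),
# E (strand), C (coil/other). Pi helices, bends and turns collapse into C.

KS_Q1Q2_F <- 0.42 * 0.20 * 332  # = 27.888 kcal/mol * Angstrom

ss_residue_table <- function(top) {
  a <- top$atoms
  key <- paste(a$chain_id, a$residue_number)
  res <- a[!duplicated(key), c("chain_id", "residue_number", "residue_name")]
  rownames(res) <- NULL
  find <- function(ch, rn, nm) {
    i <- which(a$chain_id == ch & a$residue_number == rn & a$atom_name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  for (nm in c("N", "CA", "C", "O")) {
    res[[paste0("i", nm)]] <- mapply(find, res$chain_id, res$residue_number,
                                     MoreArgs = list(nm = nm))
  }
  res$iH <- mapply(find, res$chain_id, res$residue_number,
                   MoreArgs = list(nm = "H"))
  res$is_pro <- res$residue_name == "PRO"
  res$complete <- !is.na(res$iN) & !is.na(res$iCA) & !is.na(res$iC) & !is.na(res$iO)
  # peptide residues with a partial backbone deserve a warning; ions/hetero
  # groups with no backbone at all are silently coil
  res$warn_incomplete <- !res$complete & (!is.na(res$iCA) | !is.na(res$iN))
  n <- nrow(res)
  # sequence neighbors within a chain (used for H placement, turns, bridges)
  res$prev <- c(NA_integer_, seq_len(n - 1L))
  res$next_ <- c(seq_len(n)[-1], NA_integer_)
  res$prev[c(TRUE, res$chain_id[-1] != res$chain_id[-n])] <- NA_integer_
  res$next_[c(res$chain_id[-1] != res$chain_id[-n], TRUE)] <- NA_integer_
  res
}

ks_hbond_matrix <- function(coords, res) {
  # hb[d, a] TRUE iff the backbone NH of residue d donates to the CO of
  # residue a with Kabsch-Sander energy below -0.5 kcal/mol
  n <- nrow(res)
  # amide H: explicit if present, else 1.01 A from N anti to the preceding
  # carbonyl (H = N + 0.101 * unit(Cprev - Oprev))
  Hpos <- matrix(NA_real_, n, 3L)
  for (d in seq_len(n)) {
    if (!res$complete[d] || res$is_pro[d]) next
    if (!is.na(res$iH[d])) {
      Hpos[d, ] <- coords[res$iH[d], ]
      next
    }
    p <- res$prev[d]
    if (is.na(p) || !res$complete[p]) next  # chain start: no donor
    v <- coords[res$iC[p], ] - coords[res$iO[p], ]
    Hpos[d, ] <- coords[res$iN[d], ] + 0.101 * unit3(v)
  }
  ca <- matrix(NA_real_, n, 3L)
  ok <- res$complete
  ca[ok, ] <- coords[res$iCA[ok], , drop = FALSE]
  hb <- matrix(FALSE, n, n)
  donors <- which(ok & !is.na(Hpos[, 1]))
  acceptors <- which(ok)
  for (d in donors) {
    dca <- sqrt(rowSums((ca - matrix(ca[d, ], n, 3L, byrow = TRUE))^2))
    for (a in acceptors) {
      if (a == d || is.na(dca[a]) || dca[a] > 0.9) next
      # donors cannot bond their own or an adjacent peptide unit
      if (res$chain_id[a] == res$chain_id[d] && abs(a - d) < 2L) next
      E <- ks_pair_energy(coords, res, d, a, Hpos = Hpos[d, ])
      if (E < -0.5) hb[d, a] <- TRUE
    }
  }
  hb
}

ks_pair_energy <- function(coords, res, d, a, Hpos = NULL) {
  # Kabsch-Sander electrostatic H-bond energy (kcal/mol), clamped at -9.9
  if (is.null(Hpos)) {
    p <- res$prev[d]
    if (is.na(p) || !res$complete[p] || !res$complete[d] || !res$complete[a] ||
        res$is_pro[d]) {
      return(0)
    }
    Hpos <- coords[res$iN[d], ] +
      0.101 * unit3(coords[res$iC[p], ] - coords[res$iO[p], ])
  }
  Npos <- coords[res$iN[d], ]; Cpos <- coords[res$iC[a], ]
  Opos <- coords[res$iO[a], ]
  rON <- sqrt(sum((Opos - Npos)^2)) * 10
  rCH <- sqrt(sum((Cpos - Hpos)^2)) * 10
  rOH <- sqrt(sum((Opos - Hpos)^2)) * 10
  rCN <- sqrt(sum((Cpos - Npos)^2)) * 10
  max(KS_Q1Q2_F * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN), -9.9)
}

#' Assign secondary structure for one frame
#'
#' DSSP-style assignment from backbone hydrogen-bond patterns: the amide H
#' is placed geometrically when absent, the Kabsch-Sander electrostatic
#' energy defines H-bonds (E < -0.5 kcal/mol), runs of i->i+4 turns give H,
#' i->i+3 runs give G, ladder bridges give E, and everything else is C.
#' Proline never donates; residues lacking backbone atoms are labelled C
#' with a warning.
#'
#' @param coords_nm `n_atoms x 3` coordinate matrix, nm.
#' @param top the matching [topology].
#' @return character vector of labels in {"H","G","E","C"}, one per
#'   residue, named by `chain:residue_number`.
#' @export
assign_ss <- function(coords_nm, top) {
  res <- ss_residue_table(top)
  if (any(res$warn_incomplete)) {
    warning(sprintf("assign_ss: %d residue(s) lack backbone atoms; labelled C",
                    sum(res$warn_incomplete)))
  }
  labels <- ss_labels_from_table(coords_nm, res)
  names(labels) <- paste(res$chain_id, res$residue_number, sep = ":")
  labels
}

ss_labels_from_table <- function(coords, res) {
  n <- nrow(res)
  hb <- ks_hbond_matrix(coords, res)
  seq_next <- function(i, k) {
    # k-th sequence successor of residue i within its chain, NA past a break
    for (s in seq_len(k)) {
      i <- res$next_[i]
      if (is.na(i)) return(NA_integer_)
    }
    i
  }
  turn <- function(k) {
    t <- logical(n)
    for (i in seq_len(n)) {
      j <- seq_next(i, k)
      if (!is.na(j) && hb[j, i]) t[i] <- TRUE  # CO(i) <- NH(i+k)
    }
    t
  }
  t4 <- turn(4L); t3 <- turn(3L)
  labels <- rep("C", n)
  # alpha helix: two consecutive 4-turns at i, i+1 mark residues i+1..i+4
  for (i in seq_len(n)) {
    i2 <- res$next_[i]
    if (!is.na(i2) && t4[i] && t4[i2]) {
      j <- i
      for (s in 1:4) {
        j <- seq_next(i, s)
        if (!is.na(j)) labels[j] <- "H"
      }
    }
  }
  # strand: Kabsch-Sander parallel/antiparallel bridges between
  # non-neighboring residues
  in_bridge <- logical(n)
  HBond <- function(i, j) {  # CO(i) accepts from NH(j)
    if (is.na(i) || is.na(j)) return(FALSE)
    hb[j, i]
  }
  for (i in seq_len(n)) {
    im1 <- res$prev[i]; ip1 <- res$next_[i]
    for (j in seq_len(n)) {
      if (res$chain_id[j] == res$chain_id[i] && abs(j - i) < 3L) next
      if (j == i) next
      jm1 <- res$prev[j]; jp1 <- res$next_[j]
      par <- (HBond(im1, j) && HBond(j, ip1)) || (HBond(jm1, i) && HBond(i, jp1))
      anti <- (HBond(i, j) && HBond(j, i)) || (HBond(im1, jp1) && HBond(jm1, ip1))
      if (par || anti) {
        in_bridge[i] <- TRUE
        in_bridge[j] <- TRUE
      }
    }
  }
  labels[in_bridge & labels != "H"] <- "E"
  # 3-10 helix on what is left
  for (i in seq_len(n)) {
    i2 <- res$next_[i]
    if (!is.na(i2) && t3[i] && t3[i2]) {
      for (s in 1:3) {
        j <- seq_next(i, s)
        if (!is.na(j) && labels[j] == "C") labels[j] <- "G"
      }
    }
  }
  labels[!res$complete] <- "C"
  labels
}

#' Secondary-structure time series
#'
#' [assign_ss()] applied per frame (optionally strided).
#'
#' @param traj a [trajectory].
#' @param stride keep every `stride`-th frame, default 1.
#' @return An `ss_assignment`: list with `times_ns` and `labels`
#'   (frames x residues character matrix, columns named
#'   `chain:residue_number`).
#' @export
ss_timeseries <- function(traj, stride = 1L) {
  stopifnot(stride >= 1L)
  frames <- seq(1L, n_frames(traj), by = stride)
  res <- ss_residue_table(traj$topology)
  if (any(res$warn_incomplete)) {
    warning(sprintf("ss_timeseries: %d residue(s) lack backbone atoms; labelled C",
                    sum(res$warn_incomplete)))
  }
  lab <- matrix(NA_character_, length(frames), nrow(res))
  for (k in seq_along(frames)) {
    lab[k, ] <- ss_labels_from_table(traj$coords[frames[k], , ], res)
  }
  colnames(lab) <- paste(res$chain_id, res$residue_number, sep = ":")
  structure(list(times_ns = traj$times_ns[frames], labels = lab,
                 residue_numbers = res$residue_number,
                 chain_ids = res$chain_id),
            class = "ss_assignment")
}

#' Helical fraction of a residue range over time
#'
#' Per frame, the fraction of the region's residues labelled H or G.
#'
#' @param ss an `ss_assignment` from [ss_timeseries()].
#' @param region integer residue numbers (e.g. `289:296` for helix a1).
#' @param chain chain id, default the first.
#' @return data.frame with `time_ns`, `helix_fraction`.
#' @export
helix_fraction <- function(ss, region, chain = NULL) {
  stopifnot(length(region) > 0L)
  if (is.null(chain)) chain <- ss$chain_ids[1]
  cols <- which(ss$chain_ids == chain & ss$residue_numbers %in% region)
  if (length(cols) == 0L) stop("helix_fraction: region matches no residues")
  m <- matrix(ss$labels[, cols, drop = FALSE] %in% c("H", "G"),
              nrow = nrow(ss$labels))
  data.frame(time_ns = ss$times_ns, helix_fraction = rowMeans(m))
}

#' Detect helix unfolding / refolding events
#'
#' Hysteresis thresholding of a helix-fraction series: an unfolding event
#' is recorded when the fraction drops below `low_thresh` and stays there
#' for at least `min_dwell_ns`; a refolding event when it rises above
#' `high_thresh` for at least `min_dwell_ns`. The two thresholds prevent
#' chatter around a single boundary. Event kinds strictly alternate.
#'
#' @param fraction numeric helix-fraction series in `[0,1]`.
#' @param times frame times, ns.
#' @param low_thresh,high_thresh hysteresis thresholds, defaults 0.3/0.7
#'   (must satisfy low < high).
#' @param min_dwell_ns minimum time beyond a threshold for a confirmed
#'   transition, default 5 ns.
#' @param region optional residue range recorded with the events.
#' @return data.frame with `kind` ("unfolding"/"refolding"), `start_ns`
#'   (threshold crossing), `end_ns` (dwell confirmed), `region`.
#' @export
detect_folding_events <- function(fraction, times, low_thresh = 0.3,
                                  high_thresh = 0.7, min_dwell_ns = 5,
                                  region = NA_character_) {
  stopifnot(length(fraction) == length(times), low_thresh < high_thresh,
            min_dwell_ns >= 0)
  n <- length(fraction)
  state <- ifelse(fraction <= low_thresh, "unfolded",
                  ifelse(fraction >= high_thresh, "folded", NA_character_))
  # confirmed runs: contiguous beyond-threshold stretches of >= min_dwell
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(state = r$values, start = starts, end = ends)
  runs <- runs[!is.na(runs$state), , drop = FALSE]
  if (nrow(runs)) {
    dur <- times[runs$end] - times[runs$start]
    single_ok <- runs$start == runs$end & n == 1L
    runs <- runs[dur >= min_dwell_ns | single_ok, , drop = FALSE]
  }
  out <- data.frame(kind = character(0), start_ns = numeric(0),
                    end_ns = numeric(0), region = character(0))
  if (nrow(runs) < 2L) return(out)
  cur <- runs$state[1]
  region <- as.character(region)
  for (i in 2:nrow(runs)) {
    if (runs$state[i] != cur) {
      cur <- runs$state[i]
      t0 <- times[runs$start[i]]
      out <- rbind(out, data.frame(
        kind = if (cur == "unfolded") "unfolding" else "refolding",
        start_ns = t0, end_ns = t0 + min_dwell_ns, region = region))
    }
  }
  out
}
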