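#' Specification for the synthetic-data generator
#'
#' The generator emulates the statistical structure of the phenomena the
#' analysis pipeline measures — stationary per-residue Gaussian (OU)
#' fluctuations, two-state telegraph contacts with known on/off rates,
#' scheduled helix unfolding, ions scripted to bridge two anionic sites,
#' and two-state-binding titration peak lists — with no attempt at
#' physical realism (no excluded volume, no force field). Every random
#' draw is fixed by `seed`.
#'
#' The default blueprint mirrors the architecture of the hDVL3 PDZ
#' construct (residues 245-338, 94 residues): a beta2-like strand
#' (260-265), the long beta2-beta3 loop (266-277), a beta3-like strand
#' (278-283), helix a1 (287-296), helix a2 (317-327), and pseudo
#' side-chain atoms for the residues the contact analyses name (phospho
#' sites S263/S268/S280/S311 as SEP with a P atom; R320 CZ, K283 NZ,
#' Q267 CD, D290 CG, R292 CZ).
#'
#' @param seed integer; fixes every random draw.
#' @param n_frames number of frames, default 2000.
#' @param dt_ns frame spacing, default 0.5 ns (a 1-us run at 2000 frames).
#' @param atoms `"backbone"` (N/CA/C/O + pseudo side chains; supports
#'   secondary structure) or `"ca"` (C-alpha trace only; cheap, for
#'   fluctuation statistics at large frame counts).
#' @param sigma_nm stationary per-coordinate OU amplitude, nm; default
#'   0.05. May be a single value or a named vector of per-residue
#'   overrides (names = residue numbers).
#' @param tau_ns OU relaxation time, default 1 ns.
#' @param contact_schedules list of schedules:
#'   `list(pairA =, pairB = <selection strings>, mode = "telegraph",
#'   k_on_per_ns =, k_off_per_ns =)` or `mode = "intervals"` with
#'   `intervals = data.frame(start_ns, end_ns)`; optional
#'   `contact_distance_nm` (default 0.45), `apart_distance_nm` (default
#'   1.8), `jitter_nm` (default 0.01).
#' @param unfolding_schedules list of
#'   `list(region = <residue numbers>, t_start_ns =, t_end_ns =)`;
#'   dihedrals of the region interpolate helix -> extended across the
#'   window.
#' @param ion_schedules list of `list(ion = <1-based ion number>,
#'   siteA =, siteB = <selections>, intervals = data.frame(start_ns,
#'   end_ns))`; during an interval the two sites are pinned
#'   `site_distance_nm` apart (default 0.5) and the ion sits at their
#'   midpoint.
#' @param n_ions number of Na-like ions appended to the topology.
#' @param titration per-variant truth for [generate_titration()]: a named
#'   list of `list(Kd_uM =)`; defaults plant the affinity order
#'   wt > S280E > S263E with Kd = 1, 10, 100 uM.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed = 1L, n_frames = 2000L, dt_ns = 0.5,
                           atoms = c("backbone", "ca"), sigma_nm = 0.05,
                           tau_ns = 1, contact_schedules = list(),
                           unfolding_schedules = list(),
                           ion_schedules = list(), n_ions = 0L,
                           titration = list(wt = list(Kd_uM = 1),
                                            S280E = list(Kd_uM = 10),
                                            S263E = list(Kd_uM = 100))) {
  atoms <- match.arg(atoms)
  stopifnot(n_frames >= 1L, dt_ns > 0, all(sigma_nm >= 0), tau_ns > 0)
  t_end <- n_frames * dt_ns
  for (s in c(contact_schedules, ion_schedules)) {
    iv <- s$intervals
    if (!is.null(iv) && any(iv$start_ns < 0 | iv$end_ns > t_end)) {
      stop("synthetic_spec: schedule interval outside [0, ", t_end, "] ns")
    }
  }
  for (s in unfolding_schedules) {
    if (s$t_start_ns < 0 || s$t_end_ns > t_end || s$t_start_ns >= s$t_end_ns) {
      stop("synthetic_spec: invalid unfolding window")
    }
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 dt_ns = dt_ns, atoms = atoms, sigma_nm = sigma_nm,
                 tau_ns = tau_ns, contact_schedules = contact_schedules,
                 unfolding_schedules = unfolding_schedules,
                 ion_schedules = ion_schedules, n_ions = as.integer(n_ions),
                 titration = titration),
            class = "synthetic_spec")
}

toy_blueprint <- function() {
  list(residue_start = 245L, residue_end = 338L,
       segments = list(strand_b2 = 260:265, loop = 266:277,
                       strand_b3 = 278:283, helix_a1 = 287:296,
                       helix_a2 = 317:327),
       sc_atoms = data.frame(
         residue_number = c(263L, 268L, 280L, 311L, 320L, 283L, 267L, 290L, 292L),
         atom_name = c("P", "P", "P", "P", "CZ", "NZ", "CD", "CG", "CZ"),
         residue_name = c("SEP", "SEP", "SEP", "SEP", "ARG", "LYS", "GLN",
                          "ASP", "ARG"),
         stringsAsFactors = FALSE))
}

toy_dihedrals <- function(bp) {
  resnos <- bp$residue_start:bp$residue_end
  n <- length(resnos)
  phi <- rep(180, n); psi <- rep(180, n)
  for (nm in names(bp$segments)) {
    idx <- which(resnos %in% bp$segments[[nm]])
    if (startsWith(nm, "helix")) {
      phi[idx] <- -57; psi[idx] <- -47
    } else if (startsWith(nm, "strand")) {
      phi[idx] <- -139.9; psi[idx] <- 135.2
    }
    # loop/coil stay extended
  }
  list(resnos = resnos, phi = phi, psi = psi)
}

toy_coords_backbone <- function(bp, phi, psi) {
  bb <- build_backbone(phi, psi, cb = TRUE)
  backbone_to_topology(bb, bp$residue_start:bp$residue_end,
                       chain_id = "A", resname = "ALA",
                       sc_atoms = bp$sc_atoms)
}

#' Build the toy topology and its reference coordinates
#'
#' Ideal-geometry chain per the blueprint (helices at helical dihedrals,
#' strands extended-beta, loop/coil fully extended), one pseudo
#' side-chain atom for each designated residue, plus `n_ions` Na-like
#' ions parked away from the chain. Deterministic: no random draws.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `topology`, `coords_nm` (n_atoms x 3 reference), and
#'   the blueprint used.
#' @export
build_toy_topology <- function(spec) {
  bp <- toy_blueprint()
  dih <- toy_dihedrals(bp)
  if (spec$atoms == "ca") {
    bb <- build_backbone(dih$phi, dih$psi)
    atoms <- data.frame(atom_name = "CA",
                        residue_number = dih$resnos,
                        residue_name = "ALA", chain_id = "A", element = "C",
                        stringsAsFactors = FALSE)
    coords <- bb$CA
  } else {
    parts <- toy_coords_backbone(bp, dih$phi, dih$psi)
    atoms <- parts$atoms
    coords <- parts$coords
  }
  if (spec$n_ions > 0L) {
    span <- apply(coords, 2, max)
    for (i in seq_len(spec$n_ions)) {
      atoms <- rbind(atoms, data.frame(
        atom_name = "NA", residue_number = 900L + i, residue_name = "NA",
        chain_id = "I", element = "Na", stringsAsFactors = FALSE))
      coords <- rbind(coords, span + c(2 + 0.5 * i, 2, 2))
    }
  }
  list(topology = topology(atoms), coords_nm = coords, blueprint = bp,
       phi = dih$phi, psi = dih$psi)
}

#' Two-state telegraph (random-telegraph) state series
#'
#' Continuous-time two-state Markov switch sampled at `dt_ns`:
#' per-frame switching probabilities `1 - exp(-k dt)`. The initial state
#' is drawn from the stationary distribution, so long-run occupancy tends
#' to `k_on / (k_on + k_off)` and mean on-dwell to `1 / k_off`.
#' Uses the current RNG stream (seed it for reproducibility).
#'
#' @param n_frames series length.
#' @param dt_ns frame spacing, ns.
#' @param k_on_per_ns,k_off_per_ns transition rates, 1/ns.
#' @return logical vector (TRUE = on/in contact).
#' @export
telegraph_states <- function(n_frames, dt_ns, k_on_per_ns, k_off_per_ns) {
  stopifnot(n_frames >= 1L, dt_ns > 0, k_on_per_ns > 0, k_off_per_ns > 0)
  p_on <- 1 - exp(-k_on_per_ns * dt_ns)
  p_off <- 1 - exp(-k_off_per_ns * dt_ns)
  u <- stats::runif(n_frames)
  s <- logical(n_frames)
  s[1] <- u[1] < k_on_per_ns / (k_on_per_ns + k_off_per_ns)
  for (t in 2:n_frames) {
    s[t] <- if (s[t - 1L]) u[t] >= p_off else u[t] < p_on
  }
  s
}

intervals_to_states <- function(intervals, times) {
  s <- logical(length(times))
  for (i in seq_len(nrow(intervals))) {
    s <- s | (times >= intervals$start_ns[i] & times < intervals$end_ns[i])
  }
  s
}

#' Generate a synthetic trajectory with planted structure
#'
#' Per-atom positions are the blueprint reference plus isotropic
#' Ornstein-Uhlenbeck noise of stationary per-coordinate amplitude
#' `sigma_nm` and relaxation time `tau_ns`. Contact-schedule pairs then
#' have the B atom repositioned along the reference A->B direction at the
#' contact or apart distance (plus jitter); unfolding regions interpolate
#' their dihedrals helix -> extended across the scheduled window; ions are
#' placed at the midpoint of their two sites during bridging intervals.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `trajectory` and `truth` (planted states and
#'   schedules: per contact schedule the logical state series, per ion the
#'   bridging series, per-residue sigma).
#' @export
generate_trajectory <- function(spec) {
  set.seed(spec$seed)
  built <- build_toy_topology(spec)
  top <- built$topology
  ref <- built$coords_nm
  na <- nrow(ref)
  nf <- spec$n_frames
  times <- seq(0, by = spec$dt_ns, length.out = nf)
  # per-atom sigma from per-residue sigma
  sig_res <- spec$sigma_nm
  sigma_atom <- rep(if (length(sig_res) == 1L) sig_res else 0.05, na)
  if (!is.null(names(sig_res))) {
    base <- if ("default" %in% names(sig_res)) sig_res[["default"]] else 0.05
    sigma_atom <- rep(base, na)
    for (nm in setdiff(names(sig_res), "default")) {
      sigma_atom[top$atoms$residue_number == as.integer(nm)] <- sig_res[[nm]]
    }
  }
  phi_ar <- exp(-spec$dt_ns / spec$tau_ns)
  co <- array(NA_real_, c(nf, na, 3L))
  if (nf == 1L) {
    co[1, , ] <- ref
  } else {
    innov_sd <- sigma_atom * sqrt(1 - phi_ar^2)
    for (k in 1:3) {
      x <- matrix(0, nf, na)
      x[1, ] <- stats::rnorm(na, sd = sigma_atom)
      if (any(sigma_atom > 0)) {
        for (t in 2:nf) {
          x[t, ] <- phi_ar * x[t - 1L, ] + stats::rnorm(na, sd = innov_sd)
        }
      }
      co[, , k] <- matrix(ref[, k], nf, na, byrow = TRUE) + x
    }
  }
  truth <- list(sigma_atom_nm = sigma_atom, times_ns = times,
                contacts = list(), ions = list())
  # scheduled unfolding: rebuild backbone with interpolated dihedrals
  if (length(spec$unfolding_schedules)) {
    if (spec$atoms != "backbone") {
      stop("generate_trajectory: unfolding schedules need atoms = 'backbone'")
    }
    bp <- built$blueprint
    resnos <- bp$residue_start:bp$residue_end
    for (s in spec$unfolding_schedules) {
      idx <- which(resnos %in% s$region)
      if (!length(idx)) stop("generate_trajectory: empty unfolding region")
      a_of_t <- pmin(1, pmax(0, (times - s$t_start_ns) /
                                  (s$t_end_ns - s$t_start_ns)))
      parts_end <- NULL
      for (f in seq_len(nf)) {
        a <- a_of_t[f]
        if (a == 0) next
        if (a == 1 && !is.null(parts_end)) {
          co[f, , ] <- co[f, , ] - ref + parts_end
          next
        }
        phi <- built$phi; psi <- built$psi
        phi[idx] <- (1 - a) * phi[idx] + a * 180
        psi[idx] <- (1 - a) * psi[idx] + a * 180
        parts <- toy_coords_backbone(bp, phi, psi)$coords
        if (nrow(parts) < na) parts <- rbind(parts, ref[(nrow(parts) + 1L):na, ])
        if (a == 1) parts_end <- parts
        co[f, , ] <- co[f, , ] - ref + parts
      }
      truth$unfolding <- c(truth$unfolding, list(s))
    }
  }
  # contact schedules: override pair distances
  for (si in seq_along(spec$contact_schedules)) {
    s <- spec$contact_schedules[[si]]
    ia <- resolve_selection(s$pairA, top) + 1L
    ib <- resolve_selection(s$pairB, top) + 1L
    if (length(ia) != 1L || length(ib) != 1L) {
      stop("generate_trajectory: contact schedules need single-atom selections")
    }
    states <- if (identical(s$mode, "telegraph")) {
      telegraph_states(nf, spec$dt_ns, s$k_on_per_ns, s$k_off_per_ns)
    } else {
      intervals_to_states(s$intervals, times)
    }
    dc <- if (is.null(s$contact_distance_nm)) 0.45 else s$contact_distance_nm
    da <- if (is.null(s$apart_distance_nm)) 1.8 else s$apart_distance_nm
    jit <- if (is.null(s$jitter_nm)) 0.01 else s$jitter_nm
    u <- unit3(ref[ib, ] - ref[ia, ])
    d <- ifelse(states, dc, da) + stats::rnorm(nf, sd = jit)
    d <- pmax(d, 0.05)
    co[, ib, ] <- co[, ia, ] + outer(d, u)
    truth$contacts[[si]] <- list(pairA = s$pairA, pairB = s$pairB,
                                 states = states,
                                 occupancy = mean(states),
                                 contact_distance_nm = dc,
                                 apart_distance_nm = da)
  }
  # ion schedules: pin the two sites together and park the ion between them
  for (si in seq_along(spec$ion_schedules)) {
    s <- spec$ion_schedules[[si]]
    ion_row <- which(top$atoms$residue_number == 900L + s$ion &
                     top$atoms$atom_name == "NA")
    if (!length(ion_row)) stop("generate_trajectory: no ion #", s$ion)
    ia <- resolve_selection(s$siteA, top) + 1L
    ib <- resolve_selection(s$siteB, top) + 1L
    stopifnot(length(ia) == 1L, length(ib) == 1L)
    states <- intervals_to_states(s$intervals, times)
    dsite <- if (is.null(s$site_distance_nm)) 0.5 else s$site_distance_nm
    u <- unit3(ref[ib, ] - ref[ia, ])
    jit <- matrix(stats::rnorm(3L * nf, sd = 0.01), nf, 3L)
    for (f in which(states)) {
      co[f, ib, ] <- co[f, ia, ] + dsite * u
      co[f, ion_row, ] <- co[f, ia, ] + (dsite / 2) * u + jit[f, ]
    }
    truth$ions[[si]] <- list(ion = s$ion, states = states,
                             residence = mean(states))
  }
  list(trajectory = trajectory(top, co, times), truth = truth)
}

binding_fraction <- function(P_uM, L_uM, Kd_uM) {
  b <- P_uM + L_uM + Kd_uM
  (b - sqrt(b^2 - 4 * P_uM * L_uM)) / (2 * P_uM)
}

#' Generate a synthetic NMR titration peak list
#'
#' Two-state binding in fast exchange: the bound fraction f at each
#' titration point comes from the quadratic binding equation at protein
#' concentration `P_uM` and ligand `ratio * P_uM`; the observed shift is
#' `f * delta_max` per residue. Intensities follow the phenomenological
#' exchange-broadening law `I = I0 * exp(-beta * f * (1 - f) / Kd_rel)`
#' (Kd_rel = Kd in uM): broadening peaks at half saturation and is
#' stronger for slower-dissociating (stronger) binders, reproducing the
#' fast-vs-intermediate exchange phenomenology of the titrations. Peaks
#' whose relative intensity falls below `detection` vanish from the list
#' (and stay vanished at higher ratios).
#'
#' @param spec a [synthetic_spec()] (uses `seed` and `titration`).
#' @param variant variant name present in `spec$titration`.
#' @param ratios ligand:protein ratios, default `c(0, 0.25, 0.5, 1, 2, 4)`.
#' @param P_uM protein concentration, default 100 uM.
#' @param beta broadening strength, default 20.
#' @param detection relative-intensity detection floor, default 0.05.
#' @param noise_sd relative intensity noise, default 0.02 (shift noise
#'   0.002 ppm 1H / 0.02 ppm 15N).
#' @return list with `series` (a [titration_series()]) and `truth`
#'   (Kd, bound fractions, per-residue delta_max).
#' @export
generate_titration <- function(spec, variant, ratios = c(0, 0.25, 0.5, 1, 2, 4),
                               P_uM = 100, beta = 20, detection = 0.05,
                               noise_sd = 0.02) {
  tr <- spec$titration[[variant]]
  if (is.null(tr)) stop("generate_titration: unknown variant ", variant)
  stopifnot(tr$Kd_uM > 0, ratios[1] == 0)
  set.seed(spec$seed + match(variant, names(spec$titration)) * 1000L)
  reporters <- c(260L, 261L, 279L, 285L)
  bystanders <- c(250L, 270L, 300L, 320L, 330L)
  residues <- sort(c(reporters, bystanders))
  dmax_1H <- ifelse(residues %in% reporters,
                    0.08 + 0.04 * seq_along(residues) %% 2, 0.004)
  dmax_15N <- ifelse(residues %in% reporters, 0.8, 0.03)
  f <- binding_fraction(P_uM, ratios * P_uM, tr$Kd_uM)
  points <- list()
  vanished <- rep(FALSE, length(residues))
  for (i in seq_along(ratios)) {
    broad <- exp(-beta * f[i] * (1 - f[i]) / tr$Kd_uM)
    rel <- broad * (1 + stats::rnorm(length(residues), sd = noise_sd))
    # bystander peaks broaden marginally regardless of variant
    rel[!(residues %in% reporters)] <- 1 + stats::rnorm(sum(!(residues %in% reporters)),
                                                        sd = noise_sd)
    vanished <- vanished | (rel < detection & residues %in% reporters)
    keep <- !vanished
    pk <- data.frame(
      residue_number = residues,
      d1H_ppm = 8 + 0.01 * residues %% 7 + f[i] * dmax_1H +
        stats::rnorm(length(residues), sd = noise_sd / 10),
      d15N_ppm = 115 + 0.1 * residues %% 13 + f[i] * dmax_15N +
        stats::rnorm(length(residues), sd = noise_sd),
      intensity = pmax(rel * 100, 0)
    )[keep, , drop = FALSE]
    points[[i]] <- list(ligand_ratio = ratios[i], peaks = pk)
  }
  list(series = titration_series(variant, points),
       truth = list(Kd_uM = tr$Kd_uM, bound_fraction = f, ratios = ratios,
                    reporters = reporters))
}

#' Emit the canonical synthetic fixture bundle
#'
#' Writes a toy topology PDB, a wild-type-like and a phospho-like
#' trajectory (DCD), titration peak lists for every variant in
#' `spec$titration`,
#' and `manifest.json` recording all planted truths. Re-running with the
#' same seed reproduces identical content.
#'
#' @param spec a [synthetic_spec()].
#' @param outdir output directory (created if needed).
#' @return Invisible list of written paths + the manifest.
#' @export
emit_fixture_set <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  manifest <- list(seed = spec$seed, n_frames = spec$n_frames,
                   dt_ns = spec$dt_ns)
  # wild-type-like: permanent D290-R292 salt bridge, no phospho contact
  wt_spec <- spec
  wt_spec$contact_schedules <- list(list(
    pairA = "resid 290 and name CG", pairB = "resid 292 and name CZ",
    mode = "intervals",
    intervals = data.frame(start_ns = 0, end_ns = spec$n_frames * spec$dt_ns),
    contact_distance_nm = 0.35, apart_distance_nm = 1.5))
  gen <- generate_trajectory(wt_spec)
  paths$topology <- file.path(outdir, "toy_synthetic.pdb")
  write_topology(gen$trajectory$topology,
                 build_toy_topology(spec)$coords_nm, paths$topology)
  paths$wt_traj <- file.path(outdir, "wt.dcd")
  write_trajectory(gen$trajectory, paths$wt_traj)
  manifest$wt <- list(saltbridge_occupancy = gen$truth$contacts[[1]]$occupancy)
  # phospho-like: R320 CZ -- pS263 P telegraph contact
  ps_spec <- spec
  ps_spec$seed <- spec$seed + 1L
  ps_spec$contact_schedules <- list(list(
    pairA = "resid 320 and name CZ", pairB = "resid 263 and name P",
    mode = "telegraph", k_on_per_ns = 0.02, k_off_per_ns = 0.01))
  gen2 <- generate_trajectory(ps_spec)
  paths$ps263_traj <- file.path(outdir, "pS263.dcd")
  write_trajectory(gen2$trajectory, paths$ps263_traj)
  manifest$pS263 <- list(
    contact_occupancy = gen2$truth$contacts[[1]]$occupancy,
    k_on_per_ns = 0.02, k_off_per_ns = 0.01)
  # titrations
  manifest$titration <- list()
  for (v in names(spec$titration)) {
    g <- generate_titration(spec, v)
    p <- file.path(outdir, sprintf("titration_%s.csv", v))
    write_peaklist(g$series, p)
    paths[[paste0("titration_", v)]] <- p
    manifest$titration[[v]] <- list(Kd_uM = g$truth$Kd_uM)
  }
  paths$manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(manifest = manifest)))
}
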