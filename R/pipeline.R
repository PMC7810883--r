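#' Run the variant-comparison workflow from a single config
#'
#' Orchestrates the full wt-vs-variant analysis: per-variant replica RMSF
#' (mean +/- sd), delta-RMSF vs wt, per-pair contact occurrence with the
#' 1 nm / 20 ns / 25% criteria and "k/n" ratios across replicas,
#' secondary-structure timelines with helix-fraction event detection,
#' loop-conformation clustering, and CSP/affinity tables from titration
#' peak lists. Every threshold in force is echoed into the run log and
#' the JSON output for provenance.
#'
#' @param config an R list or path to a JSON file with entries:
#'   `outdir`; `variants` (named list; each
#'   `list(topology =, trajectories = c(paths), dt_ns =)`); optional
#'   blocks `rmsf` (`selection`, `fit`), `contacts` (`pairs` = list of
#'   `list(name =, a =, b =)`, `criteria` = occurrence_criteria fields),
#'   `ss` (`regions` = named list of residue ranges "289-296",
#'   `min_dwell_ns`), `cluster` (`selection`, `cutoff_nm`), `csp`
#'   (`peaklists` = paths, `reporters`); `equilibration_frac`
#'   (default 0.1); `stride` (default 1).
#' @return Invisible list of results (also written under `outdir`):
#'   `rmsf`, `delta_rmsf`, `occurrence`, `ss_events`, `clusters`,
#'   `affinity`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$outdir), !is.null(config$variants))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run_log.txt")
  logcon <- file(logfile, "w")
  on.exit(close(logcon))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  eq <- if (is.null(config$equilibration_frac)) 0.1 else config$equilibration_frac
  stride <- if (is.null(config$stride)) 1L else as.integer(config$stride)
  say("pdzdyn pipeline: equilibration discard %.0f%%, stride %d", 100 * eq, stride)

  # --- load trajectories -----------------------------------------------
  vnames <- names(config$variants)
  trajs <- stage("load", {
    lapply(config$variants, function(v) {
      top <- read_topology(v$topology)
      dt <- if (is.null(v$dt_ns)) 1 else v$dt_ns
      lapply(v$trajectories, function(p) {
        tr <- read_trajectory(p, top, dt_ns = dt)
        tr <- discard_equilibration(tr, eq)
        if (stride > 1L) tr <- subset_frames(tr, seq(1L, n_frames(tr), by = stride))
        tr
      })
    })
  })
  results <- list()

  # --- RMSF / delta-RMSF ----------------------------------------------
  rc <- config$rmsf
  fitsel <- if (is.null(rc$fit)) "name CA" else rc$fit
  rsel <- if (is.null(rc$selection)) "name CA" else rc$selection
  results$rmsf <- stage("rmsf", {
    out <- list()
    for (v in vnames) {
      profs <- lapply(trajs[[v]], function(tr) {
        compute_rmsf(align_trajectory(tr, fit_selection = fitsel), rsel)
      })
      prof <- if (length(profs) >= 2L) combine_replicas(profs) else profs[[1]]
      utils::write.csv(as.data.frame(prof),
                       file.path(outdir, sprintf("rmsf_%s.csv", v)),
                       row.names = FALSE)
      out[[v]] <- prof
      say("rmsf: %s, %d replica(s), mean %.4f nm", v, length(profs),
          mean(prof$rmsf_nm))
    }
    out
  })
  results$delta_rmsf <- stage("delta_rmsf", {
    if (!"wt" %in% vnames || length(vnames) < 2L) {
      say("delta_rmsf: skipped (need a 'wt' variant plus at least one other)")
      NULL
    } else {
      out <- list()
      for (v in setdiff(vnames, "wt")) {
        d <- delta_rmsf(results$rmsf[[v]], results$rmsf[["wt"]], v)
        utils::write.csv(as.data.frame(d),
                         file.path(outdir, sprintf("delta_rmsf_%s.csv", v)),
                         row.names = FALSE)
        out[[v]] <- d
      }
      out
    }
  })

  # --- contact occurrence ---------------------------------------------
  if (!is.null(config$contacts)) {
    results$occurrence <- stage("contacts", {
      cc <- config$contacts$criteria
      crit <- occurrence_criteria(
        distance_cutoff_nm = if (is.null(cc$distance_cutoff_nm)) 1.0 else cc$distance_cutoff_nm,
        min_event_ns = if (is.null(cc$min_event_ns)) 20 else cc$min_event_ns,
        min_occupancy = if (is.null(cc$min_occupancy)) 0.25 else cc$min_occupancy,
        gap_tolerance_ns = if (is.null(cc$gap_tolerance_ns)) 0 else cc$gap_tolerance_ns)
      say("contacts: cutoff %.2f nm, min event %g ns, occupancy > %g, gap %g ns",
          crit$distance_cutoff_nm, crit$min_event_ns, crit$min_occupancy,
          crit$gap_tolerance_ns)
      occ <- list(criteria = unclass(crit))
      for (v in vnames) {
        pairs <- lapply(config$contacts$pairs, function(p) list(p$a, p$b))
        names(pairs) <- vapply(config$contacts$pairs, function(p)
          if (is.null(p$name)) paste(p$a, p$b, sep = " -- ") else p$name,
          character(1))
        mon <- saltbridge_monitor(trajs[[v]], pairs, crit)
        occ[[v]] <- lapply(mon, function(m) {
          list(ratio = m$occurrence$ratio,
               per_replica = m$occurrence$per_replica)
        })
        for (nm in names(mon)) {
          say("contacts: %s / %s -> %s", v, nm, mon[[nm]]$occurrence$ratio)
        }
      }
      jsonlite::write_json(occ, file.path(outdir, "occurrence.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows",
                           pretty = TRUE)
      occ
    })
  }

  # --- secondary structure --------------------------------------------
  if (!is.null(config$ss)) {
    results$ss_events <- stage("secondary_structure", {
      dwell <- if (is.null(config$ss$min_dwell_ns)) 5 else config$ss$min_dwell_ns
      evs <- list()
      for (v in vnames) {
        for (ri in seq_along(trajs[[v]])) {
          ss <- ss_timeseries(trajs[[v]][[ri]])
          lab <- data.frame(time_ns = rep(ss$times_ns, ncol(ss$labels)),
                            residue = rep(colnames(ss$labels),
                                          each = nrow(ss$labels)),
                            label = as.vector(ss$labels))
          utils::write.csv(lab,
                           file.path(outdir, sprintf("ss_%s_rep%d.csv", v, ri)),
                           row.names = FALSE)
          for (rn in names(config$ss$regions)) {
            rng <- config$ss$regions[[rn]]
            if (is.character(rng)) {
              b <- as.integer(strsplit(rng, "-")[[1]])
              rng <- b[1]:b[2]
            }
            hf <- helix_fraction(ss, rng)
            ev <- detect_folding_events(hf$helix_fraction, hf$time_ns,
                                        min_dwell_ns = dwell, region = rn)
            if (nrow(ev)) {
              ev$variant <- v; ev$replica <- ri
              evs[[length(evs) + 1L]] <- ev
            }
            say("ss: %s rep%d region %s: mean helix fraction %.2f, %d event(s)",
                v, ri, rn, mean(hf$helix_fraction), nrow(ev))
          }
        }
      }
      evs <- if (length(evs)) do.call(rbind, evs) else
        data.frame(kind = character(0), start_ns = numeric(0),
                   end_ns = numeric(0), region = character(0))
      utils::write.csv(evs, file.path(outdir, "folding_events.csv"),
                       row.names = FALSE)
      evs
    })
  }

  # --- clustering ------------------------------------------------------
  if (!is.null(config$cluster)) {
    results$clusters <- stage("cluster", {
      sel <- config$cluster$selection
      cut <- if (is.null(config$cluster$cutoff_nm)) 0.15 else config$cluster$cutoff_nm
      out <- list()
      for (v in vnames) {
        cl <- cluster_conformations(trajs[[v]][[1]], sel, cut)
        utils::write.csv(
          data.frame(frame = seq_along(cl$frame_labels), cluster = cl$frame_labels),
          file.path(outdir, sprintf("clusters_%s.csv", v)), row.names = FALSE)
        say("cluster: %s -> %d cluster(s), sizes %s (cutoff %.3g nm)",
            v, cl$n_clusters, paste(cl$cluster_sizes, collapse = ","), cut)
        out[[v]] <- cl
      }
      out
    })
  }

  # --- CSP / affinity ranking -----------------------------------------
  if (!is.null(config$csp)) {
    results$affinity <- stage("csp", {
      series <- lapply(config$csp$peaklists, read_peaklist)
      reps <- if (is.null(config$csp$reporters)) c(260, 261, 279, 285)
              else config$csp$reporters
      for (s in series) {
        prof <- csp_profile(s)
        utils::write.csv(prof, file.path(outdir,
                                         sprintf("csp_%s.csv", s$variant_label)),
                         row.names = FALSE)
      }
      rank <- rank_affinity(series, reps)
      utils::write.csv(rank, file.path(outdir, "affinity_rank.csv"),
                       row.names = FALSE)
      say("csp: affinity order %s", paste(rank$variant, collapse = " > "))
      rank
    })
  }
  say("pipeline complete: outputs in %s", outdir)
  invisible(results)
}
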