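#!/usr/bin/env Rscript
# Helix a1 unfolding: assign per-frame secondary structure (Kabsch-Sander
# H-bond patterns reduced to H/G/E/C), track the helical fraction of the
# a1 region, and detect unfolding/refolding events with hysteresis
# thresholds. The generator schedules an unfolding at 500 ns; the
# detector should recover it.

library(pdzdyn)
dir.create("results", showWarnings = FALSE)

spec <- synthetic_spec(seed = 404, n_frames = 200, dt_ns = 5,
                       sigma_nm = 0.008,
  unfolding_schedules = list(list(region = 287:296, t_start_ns = 500,
                                  t_end_ns = 520)))
tr <- generate_trajectory(spec)$trajectory
ss <- ss_timeseries(tr, stride = 2)
hf <- helix_fraction(ss, 289:296)
ev <- detect_folding_events(hf$helix_fraction, hf$time_ns,
                            min_dwell_ns = 10, region = "a1")

write.csv(hf, "results/helix_fraction_a1.csv", row.names = FALSE)
write.csv(ev, "results/folding_events.csv", row.names = FALSE)

cat(sprintf("a1 helix fraction: %.2f before 480 ns, %.2f after 540 ns\n",
            mean(hf$helix_fraction[hf$time_ns < 480]),
            mean(hf$helix_fraction[hf$time_ns > 540])))
cat(sprintf("Detected %d event(s); first: %s at %.0f ns (scheduled 500 ns)\n",
            nrow(ev), ev$kind[1], ev$start_ns[1]))
cat("Wrote results/helix_fraction_a1.csv and results/folding_events.csv\n")
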