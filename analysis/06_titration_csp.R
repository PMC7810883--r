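#!/usr/bin/env Rscript
# NMR titration analysis: weighted chemical-shift perturbations
# (sqrt(d1H^2 + (d15N/6)^2)) and reporter-residue intensity broadening
# across synthetic two-state titrations with planted Kd = 1 / 10 / 100 uM
# for wt / S280E / S263E. The broadening score must rank the variants
# wt > S280E > S263E.

library(pdzdyn)
dir.create("results", showWarnings = FALSE)

spec <- synthetic_spec(seed = 606)
series <- lapply(names(spec$titration),
                 function(v) generate_titration(spec, v)$series)

csp_all <- do.call(rbind, lapply(series, function(s) {
  prof <- csp_profile(s, c(260, 261, 279, 285))
  prof$variant <- s$variant_label
  prof
}))
write.csv(csp_all, "results/csp_reporters.csv", row.names = FALSE)

rk <- rank_affinity(series)
write.csv(rk, "results/affinity_rank.csv", row.names = FALSE)

cat("Reporter-residue CSP at the final titration point (4:1 ligand):\n")
final <- subset(csp_all, ligand_ratio == 4)
print(aggregate(delta_obs_ppm ~ variant, final, mean, na.action = stats::na.pass))
cat("\nBroadening-based affinity ranking (larger score = stronger binding):\n")
print(rk)
cat(sprintf("\nRecovered order: %s (planted Kd %s uM)\n",
            paste(rk$variant, collapse = " > "),
            paste(vapply(spec$titration[rk$variant], `[[`, numeric(1), "Kd_uM"),
                  collapse = " < ")))
cat("Wrote results/csp_reporters.csv and results/affinity_rank.csv\n")
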