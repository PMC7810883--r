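#!/usr/bin/env Rscript
# Per-residue flexibility: two independent replicas of the wild-type-like
# generator are aligned on all C-alpha, their RMSF profiles combined as
# mean +/- sd, and replica convergence summarized. A variant with doubled
# beta2-beta3-loop amplitude is then compared against wt as delta-RMSF,
# recovering the planted loop-softening.

library(pdzdyn)
dir.create("results", showWarnings = FALSE)

rmsf_of <- function(seed, sigma) {
  spec <- synthetic_spec(seed = seed, n_frames = 20000, dt_ns = 0.1,
                         atoms = "ca", sigma_nm = sigma)
  compute_rmsf(align_trajectory(generate_trajectory(spec)$trajectory))
}

loop <- 266:277
sig_wt <- c(default = 0.04)
sig_var <- c(sig_wt, stats::setNames(rep(0.08, length(loop)), loop))

wt_reps <- list(rmsf_of(101, sig_wt), rmsf_of(102, sig_wt))
wt <- combine_replicas(wt_reps)
conv <- convergence_check(wt_reps)
cat(sprintf("wt replicas: max |dRMSF| %.4f nm, r = %.3f\n",
            conv$max_abs_diff_nm, conv$pearson_r))

variant <- rmsf_of(103, sig_var)
d <- delta_rmsf(variant, wt, "loop-softened")

write.csv(as.data.frame(wt), "results/rmsf_wt.csv", row.names = FALSE)
write.csv(as.data.frame(d), "results/delta_rmsf_loop_softened.csv",
          row.names = FALSE)

in_loop <- d$residue_numbers %in% loop
cat(sprintf("delta-RMSF in the loop: %.4f nm (planted sqrt(3)*0.04 = %.4f)\n",
            mean(d$delta_nm[in_loop]), sqrt(3) * 0.04))
cat(sprintf("delta-RMSF elsewhere:   %.4f nm (expected ~0)\n",
            mean(d$delta_nm[!in_loop])))
cat("Wrote results/rmsf_wt.csv and results/delta_rmsf_loop_softened.csv\n")
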