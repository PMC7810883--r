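#!/usr/bin/env Rscript
# Build the synthetic study bundle every downstream analysis consumes:
# a toy PDZ-like topology (residues 245-338 with pseudo side-chain atoms
# for the phospho sites and their interaction partners), a wild-type-like
# trajectory with a permanent D290-R292 salt bridge, a phospho-like
# trajectory with a telegraph R320-pS263 contact, and titration peak
# lists for wt / S280E / S263E with planted Kd = 1 / 10 / 100 uM.

library(pdzdyn)

spec <- synthetic_spec(seed = 20260924L, n_frames = 1000, dt_ns = 1,
                       sigma_nm = 0.02)
fx <- emit_fixture_set(spec, "scratch/fixtures")

cat("Fixture bundle written to scratch/fixtures:\n")
cat(" - topology:", fx$topology, "\n")
cat(" - wt trajectory (1000 frames, 1 ns spacing):", fx$wt_traj, "\n")
cat(" - pS263-like trajectory:", fx$ps263_traj, "\n")
cat(" - titrations:", fx$titration_wt, fx$titration_S280E, fx$titration_S263E, "\n")
cat(" - planted truths:", fx$manifest_path, "\n")
cat(sprintf("Planted pS263 contact occupancy: %.3f (telegraph k_on=0.02, k_off=0.01 /ns)\n",
            fx$manifest$pS263$contact_occupancy))
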