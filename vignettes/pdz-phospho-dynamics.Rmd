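---
title: "Methods: trajectory and titration analysis of phosphorylated PDZ domains"
author: "pdzdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory and titration analysis of phosphorylated PDZ domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzdyn)
```

## What the package computes

`pdzdyn` implements the dynamics and NMR analyses used to characterize how
phosphorylation (and its S→E mimetics) changes a PDZ domain — here the PDZ
of human Dishevelled-3, residues 245–338, with phospho-sites at S263, S268,
S280 and S311 and interaction partners R320, K283, Q267 and the D290–R292
salt bridge. The pipeline covers:

1. **Per-residue fluctuation maps.** Frames are Kabsch-superposed onto a
   reference on the Cα fit set; RMSF per residue is
   $\mathrm{RMSF}_i = \sqrt{\langle |\mathbf{r}_i(t)-\langle \mathbf{r}_i\rangle|^2\rangle}$,
   combined over replicas as mean ± sample (n−1) standard deviation, and
   ΔRMSF = variant − wild type (positive = more flexible).
2. **Contact occurrence.** A monitored atom pair is *in contact* in a frame
   when its distance is ≤ 1 nm (boundary inclusive). An interaction is
   *counted* in a replica only when (a) at least one contiguous contact
   event lasts ≥ 20 ns and (b) the contact occupies strictly more than 25%
   of the analyzed simulation time. Per interaction, results aggregate
   across replicas as the ratio "k/n".
3. **Ion-mediated bridges.** An ion bridges two anionic sites in a frame
   when it lies within the coordination cutoff (default 0.35 nm, a typical
   Na⁺–O distance) of at least one atom of *each* site; ions are "stable"
   at residence fraction ≥ 0.5 and "diffuse" below.
4. **Secondary structure.** A Kabsch–Sander style assigner: the amide H is
   placed 1.01 Å from N anti to the preceding carbonyl (an explicit H is
   used when present), H-bonds are pairs with electrostatic energy
   $E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) < -0.5$
   kcal/mol (clamped at −9.9), runs of i→i+4 turns give H, i→i+3 give G,
   ladder bridges give E, everything else is C. π-helices, bends and turns
   collapse into C; proline never donates.
5. **Loop conformer counting.** Daura neighbor-counting (leader) clustering
   on pairwise-superposed RMSD over the β2–β3 loop Cα, cutoff 0.15 nm,
   deterministic lowest-frame-index tie-break, clusters ordered by size.
6. **NMR titration.** Weighted chemical-shift perturbation
   $\Delta\delta_{obs} = \sqrt{(\delta^{1H})^2 + (\tfrac{1}{6}\,\delta^{15N})^2}$
   (the nitrogen weight is exactly 1/6), normalized intensity-decay
   profiles with broadened-beyond-detection peaks scored 0 from their first
   missing point, and a qualitative affinity ranking.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| distance_cutoff_nm | 1.0 | nm | contact definition (inclusive) |
| min_event_ns | 20 | ns | minimum contiguous dwell for counting |
| min_occupancy | 0.25 | fraction | strict lower bound on occupancy |
| gap_tolerance_ns | 0 | ns | contact-gap merging (strictest reading) |
| ion cutoff | 0.35 | nm | Na⁺ coordination distance |
| stable/diffuse threshold | 0.5 | fraction | ion residence classification |
| clustering cutoff | 0.15 | nm | conformer neighbor distance |
| hysteresis thresholds | 0.3 / 0.7 | fraction | unfolding / refolding detection |
| min_dwell_ns | 5 | ns | confirmed threshold crossing |
| equilibration discard | 10% | frames | dropped before statistics |

The 1 nm / 20 ns / 25% triplet is the counting criterion itself; the
remaining values are this package's defaults, all exposed in the function
signatures and echoed into pipeline outputs for provenance.

Design choices where the method was genuinely open:

- **"Lasted at least 20 ns"** is read as *one contiguous event* ≥ 20 ns.
  Under the alternative total-time reading the clause would be implied by
  the 25% clause for any simulation of 80 ns or longer, making it
  redundant; only the contiguous reading gives both clauses force.
- **Occupancy denominator** is the full post-equilibration window, not the
  union of measurable frames.
- **Multi-atom selections** (e.g. "the phosphate") reduce to the minimum
  inter-set distance per frame; selecting the single P atom instead is a
  one-line change of the selection string. Which atom defines "the
  phosphate" in the original distance criteria is not stated; both
  readings are supported and neither is claimed to be the original choice.
- **RMSF atom choice** is Cα per residue (the field convention for
  per-residue profiles); heavy-atom averaging is available via
  `per_residue = "heavy"`. Which selection the original profiles used is
  unstated, so no numerical reproduction of them is claimed.
- **Clustering algorithm and cutoff** are likewise unstated in the source
  analyses; Daura leader clustering at 0.15 nm is the standard MD
  conformer-counting choice, and three-conformer recovery is demonstrated
  on synthetic data only.
- **Ion-bridge residence** is measured over all analyzed frames (not only
  frames where some bridge exists): it keeps residence an absolute
  quantity and the stable/diffuse split unambiguous.
- **Affinity ranking is deliberately qualitative.** The broadening readout
  is operationalized as score = 1 − AUC of the normalized intensity decay
  (mean over reporter residues L260, G261, G279, G285); the published
  observation is an ordering, not a Kd, so no lineshape or binding-curve
  fit is attempted. The score is this package's operationalization.

## The synthetic generator

Real μs trajectories and spectra for this system are not deposited, so
every pipeline stage is exercised on synthetic data with planted,
analytically known structure (`synthetic_spec()` and friends):

- **Topology**: an ideal-geometry chain mirroring the construct's
  architecture (β2-like strand 260–265, β2–β3 loop 266–277, β3-like strand
  278–283, helix α1 287–296, helix α2 317–327), built from φ/ψ dihedrals
  by natural-extension (NeRF) placement, with one pseudo side-chain atom
  for each residue the contact analyses name (SEP P atoms at the four
  phospho-sites; CZ/NZ/CD/CG for R320, K283, Q267, D290, R292).
- **Fluctuations**: per-coordinate Ornstein–Uhlenbeck noise with
  stationary σ (default 0.05 nm) and relaxation time τ = 1 ns. OU rather
  than i.i.d. noise makes dwell statistics and convergence behavior
  nontrivial; the stationary per-residue RMSF is exactly √3·σ, the
  recovery target.
- **Contacts**: two-state telegraph switching with rates (k_on, k_off);
  the pair distance is pinned at 0.45 nm (contact) or 1.8 nm (apart) plus
  0.01 nm jitter, straddling the 1 nm cutoff so the measured state series
  equals the planted one frame-by-frame. Stationary occupancy is
  k_on/(k_on+k_off) and mean dwell 1/k_off.
- **Unfolding**: scheduled regions interpolate their dihedrals from
  helical (−57/−47) to extended (180/180) across the window, driving the
  helix fraction from 1 to 0 at a known time.
- **Ions**: scripted bridging intervals pin the two sites 0.5 nm apart
  with the ion at their midpoint, giving exact planted residences.
- **Titrations**: two-state binding with bound fraction f from the
  quadratic binding equation at protein concentration 100 μM and ligand
  ratios 0→4 (the experimental design); shifts are f·Δδ_max in fast
  exchange and intensities follow the phenomenological law
  $I = I_0 \exp(-\beta f(1-f)/K_d[\mu M])$ with β = 20, so broadening
  peaks at half-saturation and is stronger for slower-dissociating
  (tighter) binders — the fast-vs-intermediate exchange phenomenology of
  the titrations. Peaks whose relative intensity falls below 0.05 vanish
  and stay vanished. Planted Kd defaults are 1, 10, 100 μM for wt, S280E,
  S263E, a 10× ladder well beyond the ≥3× separation the ranking needs.

What the generator deliberately does **not** emulate: excluded volume,
force-field energetics, water, correlated backbone motion beyond OU, or
realistic NMR lineshapes. Passing tests therefore demonstrate that each
analysis recovers what it is defined to measure, not that it would agree
numerically with any particular MD engine or spectrometer output on real
data.

## Numerical choices and degenerate inputs

- Internal units are nm and ns everywhere; Å/ps inputs are converted on
  read (PDB and DCD are Å by convention; CSV declares its unit).
- Superposition uses SVD with a determinant correction, so reflections are
  never returned; collinear point sets are an error.
- The contact boundary is inclusive (d ≤ cutoff); results must be
  insensitive to this for continuous distances, and the boundary test
  pins the convention.
- Event durations count frames inclusively: (last − first + 1)·Δt.
- Alignment of an already-aligned trajectory is a no-op to 1e-9 nm;
  single-frame trajectories, empty selections and empty event lists are
  all legal inputs with defined results.
- Problem sizes in the test-suite and acceptance runs: 2×10⁵ frames for
  RMSF recovery, 10⁵ frames for telegraph statistics, 200-frame
  backbone trajectories for secondary-structure schedules, 100 seeded
  titration replicates for the ordering check — sizes at which every
  planted quantity is comfortably inside its statistical tolerance.

## Known limitations

- The DSSP reduction is 4-class (H, G, E, C); no π-helix, bend, turn or
  bridge/strand distinction. On ideal constructs it agrees exactly with a
  reference DSSP implementation's 3-class reduction (verified in the test
  suite against mdtraj).
- The quantitative values of the original per-residue RMSF profiles,
  secondary-structure panels and occurrence ratios are not reproducible
  without the underlying trajectories; the pipeline reproduces the
  *procedures* and validates them on planted ground truth.
- The optional sequence-identity check against the hDVL2 PDZ template
  structure (PDB 2rey, 96.28% identity to the hDVL3 construct) requires
  that structure as a local file; the alignment machinery
  (`sequence_identity()`, Needleman–Wunsch via Biostrings) is implemented
  and unit-tested on sequences with hand-countable identity.
- Telegraph dwell statistics at the stated study size (10⁵ frames, 100 ns
  mean dwell, 1000 ns window) rest on only a handful of events; the
  acceptance check uses the empirical standard error of the dwell mean,
  which is the honest uncertainty at that sample size.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1, n_frames = 2000, dt_ns = 0.5,
                       contact_schedules = list(list(
                         pairA = "resid 320 and name CZ",
                         pairB = "resid 263 and name P",
                         mode = "telegraph",
                         k_on_per_ns = 0.02, k_off_per_ns = 0.01)))
tr <- generate_trajectory(spec)$trajectory
ds <- distance_series(tr, "resid 320 and name CZ", "resid 263 and name P")
crit <- occurrence_criteria()
occurrence_decision(contact_states(ds, crit), ds$time_ns, crit)
```

The `analysis/` directory runs the full study as numbered driver scripts
(fixtures → RMSF/ΔRMSF → contact occurrence → secondary structure → ion
bridges → titration/CSP), writing tables under `results/`.
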