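# tndyn

Post-simulation analysis of molecular dynamics trajectories of the cardiac
troponin core — the Ca²⁺-sensing switch of heart muscle formed by troponin C
(TnC), troponin I (TnI) and troponin T (TnT). Phosphorylation of TnI
Ser22/Ser23 and disease-linked mutations such as TnC G159D shift the
equilibrium of troponin's large-scale domain motion; `tndyn` quantifies that
shift from trajectory output. It is aimed at structural
biologists/biophysicists who have MD trajectories of troponin (or any
two-domain articulated protein) and want the standard interdomain metrics,
interaction fingerprints and distribution statistics without stitching
together ad-hoc scripts.

## What it computes

**Geometric domain metrics**, per frame:

* *Interdomain hinge angle* θ — the angle at the hinge centroid **H**
  (Cα of TnC 94–157) between the vectors to the regulatory head **P**
  (Cα of TnC 3–85) and to the end of the IT arm **A** (pooled Cα of
  TnT 241–251 and TnI 69–76):
  θ = arccos[(**P**−**H**)·(**A**−**H**) / |**P**−**H**||**A**−**H**|].
* *Helix A/B interhelical angle* — 180° − arccos(**â**·**b̂**), where each
  N→C helix axis joins the centroids of the first and last 10 Cα of
  helix A (TnC 14–25) and helix B (TnC 38–47); angles above 110° label the
  "open" hydrophobic-patch conformation.
* *NTnC–CTnC distance* — the distance between the TnC 3–85 and TnC 94–157
  Cα centroids.

**Fluctuation metrics**: per-residue RMSF about an iterated mean structure,
all-heavy-atom pairwise RMSD matrices (Kabsch superposition per pair), and
the representative structure = the conformation with the lowest summed RMSD
to all others.

**Interaction profiling**: per-frame classification of hydrogen-bond, ionic,
aromatic and van der Waals contacts from atom types and positions,
deduplicated to residue-pair presence per frame, aggregated to percentages
of all frames, with state-comparison delta tables and heat-map matrices.

**Distribution statistics**: mean/sd, Gaussian-KDE mode (Scott bandwidth),
full width at half maximum (FWHM), threshold fractions, Cohen's
d = (m_B − m_A)/s_pooled, and binding free-energy deltas
ΔΔG = ΔG_B − ΔG_A on externally supplied (e.g. MMPBSA) summaries.

**Synthetic trajectories**: a generator that builds a toy two-domain
articulated protein and plants hinge-angle distributions, interhelical
angles, contact occupancies and positional jitter *exactly*, recording every
draw, so each pipeline stage can be validated against ground truth.

## Worked example

Two synthetic "systems" emulating an unphosphorylated and a phosphorylated
state (hinge means 121.6° vs 123.3°, sd 7.2° vs 5.9°), analyzed end to end:

```r
library(tndyn)

spec_uP <- synthetic_spec(n_runs = 2, frames_per_run = 500, seed = 1,
                          hinge = hinge_gaussian(121.6, 7.2))
spec_P  <- synthetic_spec(n_runs = 2, frames_per_run = 500, seed = 2,
                          hinge = hinge_gaussian(123.3, 5.9))
traj_uP <- generate_trajectory(spec_uP)$trajectory
traj_P  <- generate_trajectory(spec_P)$trajectory

b_uP <- run_system(analysis_config(traj_uP$topology, traj_uP, name = "wt-uP"),
                   "wt_uP")
b_P  <- run_system(analysis_config(traj_P$topology, traj_P, name = "wt-P"),
                   "wt_P")
report <- compare_systems(b_uP, b_P, out_dir = "wt_compare")
report$metrics[, c("metric", "mean_a", "mean_b", "delta_mean",
                   "fwhm_pct_change", "cohens_d")]
#>             metric mean_a mean_b delta_mean fwhm_pct_change cohens_d
#> 1            hinge 121.52 123.67       2.15             -15    0.318
#> 2         ab_angle 101.80 101.80       0.00              NA       NA
#> 3 ntc_ctc_distance  30.00  30.00       0.00              NA       NA
```

The hinge row recovers the planted story: the mean shifts by about +2°
(sampling error at n = 1000 frames per state), the distribution narrows
(negative FWHM change), and the effect size is small-positive. The A/B
angle and interdomain distance are planted constant in this toy, so their
deltas are exactly zero and their FWHM/effect size are flagged undefined
rather than reported as noise. The interaction delta table singles out the
planted ionic contact (TnC 100 – TnC 140, 80.6% → 78.4% here since both
states planted it at 80%):

```r
ion <- report$interaction_delta
ion[ion$type == "ionic" & abs(ion$delta) > 1, ]
#>    sub_a res_a sub_b res_b  type percent_a percent_b delta
#> 24   TnC   100   TnC   140 ionic      80.6      78.4  -2.2
```

Each `run_system()` call also writes per-frame series CSVs, a per-residue
RMSF CSV, the interaction frequency table, the representative structure as
a PDB, and JSON summaries/manifests into its output directory.

Real trajectories enter through `read_topology()` (PDB, with a
chain→subunit map) and `read_trajectory()` (multi-model PDB or DCD, one
file per run); published per-state summary statistics for the four troponin
systems are available via `troponin_reference_stats()` for comparison
arithmetic.

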