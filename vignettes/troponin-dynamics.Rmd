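---
title: "Measuring interdomain dynamics of cardiac troponin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interdomain dynamics of cardiac troponin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tndyn)
```

# The measurement model

Cardiac troponin behaves, to a good approximation, as two quasi-rigid
bodies — the regulatory N-lobe of troponin C (NcTnC) and the "ITC arm"
(the C-lobe of TnC plus the coiled helices of TnI and TnT) — connected by a
flexible linker. Phosphorylation of TnI Ser22/Ser23 and mutations such as
TnC G159D act by shifting the *population* of conformations rather than by
creating a single new structure. Everything in this package is therefore
distribution-first: metrics are evaluated per frame, and states are
compared through summary statistics of the resulting distributions.

## Geometric observables

**Hinge angle.** Three anchor points are defined as unweighted Cα
centroids: head = TnC 3–85, hinge = TnC 94–157, arm end = the *pooled*
union of TnT 241–251 and TnI 69–76. The hinge angle is the angle at the
hinge centroid between the two outgoing vectors. Two details are fixed
deliberately:

* the arm-end centroid averages the pooled atom set, not the mean of two
  per-range sub-centroids. With 11 + 8 atoms the two conventions differ
  slightly; the pooled average is the literal reading of "the average of
  the Cα coordinates of TnT 241–251, TnI 69–76" and is what we implement;
* angles are computed with `atan2(|u×v|, u·v)`, which is numerically stable
  at both ends of [0°, 180°], where the arccos form loses precision. This
  is what lets the rigid-body invariance tests demand 1e-9 degrees.

No superposition is applied before angle computation: internal angles and
distances are invariant under global rigid-body motion, and the test suite
enforces that invariance explicitly.

**Interhelical (A/B) angle.** Each helix axis runs from the centroid of the
first *w* Cα to the centroid of the last *w* Cα (N→C), with *w* = 10 by
default, and the reported angle is the supplement
180° − arccos(**â**·**b̂**). Helix A (TnC 14–25) has 12 residues and helix B
(TnC 38–47) has 10, so a 10-residue window cannot fit twice into either.
How the original endpoint-window convention handled this is not documented
anywhere we could find, so the package makes its own rule explicit:
the window is clamped to `length − 1` with a warning (for helix B, 9-Cα
windows sharing 8 atoms), and the axis is an error only if the two window
centroids actually coincide. Users who prefer a hard failure can pass
`clamp = FALSE` to `helix_definition()`. The supplement convention means
parallel axes read 180° and antiparallel axes 0°; values above 110° label
the "open" hydrophobic-patch conformation, and the fraction above that
threshold is reported alongside the distribution summary.

A subtlety worth recording: for a finite ideal helix the centroid of a
*w*-residue window is radially offset from the geometric axis, and the two
endpoint windows are offset in different directions unless the twist
accumulated between the window centers is a multiple of 360°. The endpoint
axis is therefore *not* the cylinder axis in general — it is its own,
well-defined convention, and both the synthetic generator and the tests
treat it as such (the generator orients its helices so the
endpoint-convention angle equals the planted value exactly; the
"axis along +z" test uses a 28-residue helix, for which the offsets cancel).

## Fluctuation metrics

**Superposition** is least-squares rigid-body fitting (Kabsch, via SVD with
determinant correction). The tests cross-check it against two independent
routes: Horn's quaternion method implemented in the test helpers, and
`bio3d::rmsd(fit = TRUE)`.

**RMSF** needs a reference. The convention used here is the iterated mean
structure: align all frames to the first frame, average, re-align to the
average, average again (two iterations), then report the per-residue RMS
deviation of each Cα from its mean position. Reporting is Cα-per-residue.
For isotropic per-coordinate jitter of amplitude σ the expected RMSF is
σ√3, which is the closed form the validation tests use.

**Pairwise RMSD / representative structure.** The matrix is computed over
all heavy atoms; entry (i, j) is the RMSD after optimally superposing frame
j on frame i (computed via the trace identity from the singular values, so
no rotated copy is materialized). The representative structure is the frame
minimizing the row sum, with ties — which arise to float precision whenever
conformations repeat — broken by the lowest (run, frame) label. A full
37,500-frame matrix is not desk-scale, so the matrix is strided: the
default budget is 2,000 frames in `pairwise_rmsd()` (with a hard 20,000
guard), and the orchestrated pipeline uses a 500-frame budget. Striding
changes the sampling of the estimator, not its definition; the stride used
is recorded in the run manifest.

## Interaction profiling

The profiler is a clean-room, geometry-only contact typer. Criteria
(defaults; all are configuration keys logged into every output):

| type | criterion |
|------|-----------|
| hydrogen bond | donor heavy atom–acceptor ≤ 3.5 Å, plus D–H···A ≥ 120° when explicit hydrogens exist; distance-only in "no-H" mode |
| ionic | any atom of a +1 group within 4.0 Å of any atom of a −1 group |
| aromatic | ring-centroid distance ≤ 5.0 Å |
| van der Waals | heavy-atom distance ≤ r₁ + r₂ + 0.5 Å |

Charge groups follow physiological protonation: Arg (NE/NH1/NH2)⁺,
Lys (NZ)⁺, His⁺ only when named HIP, Asp/Glu carboxylates⁻, the
phosphoserine (SEP) phosphate treated as one anionic group (net charge −2
at physiological pH), and charged termini. Rings are the Phe/Tyr/His/Trp
ring systems. Presence is boolean per residue pair per type per frame —
however many atom pairs qualify, a frame contributes at most one count —
and frequencies are percentages of all frames. Intra-residue pairs and
backbone–backbone pairs of sequence neighbours are excluded for the
hydrogen-bond and ionic classes (they would be trivially constant), and a
residue pair already counted as hydrogen-bonded or ionic in a frame is not
additionally counted as van der Waals. The published analysis delegated
its geometric criteria to an external fingerprinting tool whose cutoffs
are not printed; numeric agreement with published percentages is therefore
not claimed — the validation surface is scale and sign behaviour on
synthetic data with planted occupancies.

## Distribution statistics

KDE uses a Gaussian kernel with Scott's bandwidth h = sd·n^(−1/5) (the
default of the plotting stacks commonly used for such figures — "default
parameters" is all that is documented, so the rule is pinned here for
reproducibility), evaluated on a 1,024-point grid padded 3 bandwidths
beyond the data range. The KDE mode is the grid argmax; the FWHM is the
distance between the outermost half-peak crossings, located by linear
interpolation between grid points. "Outermost" makes the statistic
well-defined for bimodal distributions (low FWHM values often flag
bimodality); per-mode widths are additionally available as
`fwhm_segments`. For Gaussian data the KDE of the sample is itself
approximately Gaussian with variance σ² + h², so FWHM ≈ 2.3548·√(σ² + h²) —
the closed form used in validation. A constant (or numerically constant)
series is flagged `degenerate` with FWHM `NA`, never silently 0.

Standard deviations use the n−1 denominator. Cohen's d uses the classical
pooled standard deviation; the summary-statistics form
`cohens_d_stats()` is exactly equivalent on raw samples and is what allows
effect sizes to be recomputed from published per-state tables. Percent
changes are rounded half-away-from-zero to integer percent in formatted
reports only; raw values are never rounded internally. ΔΔG is plain
mean(B) − mean(A) on supplied binding free-energy summaries — energy
evaluation itself (MMPBSA or otherwise) is out of scope, only the
comparison arithmetic is provided.

Distributions are pooled across runs before summarizing, matching the
practice of combining all runs once metrics are seen to be stationary.
Whether published KDE/FWHM values were pooled or averaged per run is not
documented; pooling is the choice here.

# The synthetic generator

`generate_trajectory()` builds a toy articulated protein (TnC 1–161,
TnI 1–80, TnT 200–260; ~318 atoms) whose *measured* observables equal
planted values exactly:

* per frame, a hinge angle is drawn from the planted distribution
  (Gaussian or two-component mixture) and realized by rigidly rotating the
  head domain about the axis through the hinge centroid perpendicular to
  the head and arm vectors — so the measured series equals the recorded
  draws to float precision, and geometry tests can be tolerance-tight
  rather than statistical;
* the two ideal helices (1.5 Å rise, 100°/residue twist, 2.3 Å radius) are
  oriented so the endpoint-convention interhelical angle equals the planted
  value exactly; the head-to-hinge centroid distance is planted exactly by
  construction;
* each planted contact (an Arg/Glu ionic pair, a Ser/Asn hydrogen bond, a
  Phe/Phe ring stack) is switched on — side-chain atoms placed at 0.8–0.95×
  their cutoff — in an independent Bernoulli(f) subset of frames and parked
  at 1.6× the cutoff otherwise, with every draw recorded;
* i.i.d. Gaussian jitter is added to a designated flexible tail (TnI 1–33),
  emulating the disordered N-terminal extension.

Defaults mirror the study conditions where those are documented: 5
independent runs; hinge Gaussian(121.6°, 7.2°) at the wild-type
unphosphorylated scale; A/B angle 101.8°; 30 Å NTnC–CTnC separation;
planted occupancies 0.80/0.25/0.05 spanning the strong-to-rare range seen
in interaction heat maps. Where no value is documented the package makes a
one-time realistic choice: 1,000 frames per run (enough that a planted
mean is recovered to ~0.2° while a five-run generation stays in seconds)
and 0.5 Å tail jitter (disordered-loop scale). All of it is overridable
per spec, and one seeded PRNG stream drives every draw.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: autocorrelation in time (frames are i.i.d.;
real MD frames are strongly correlated, so real-data error bars are wider
than √n suggests), coupling between metrics (hinge, A/B angle and contacts
are planted independently; in real troponin they co-vary — indeed that
coupling is the scientific point), internal deformation of the domains,
solvent, and any physical energetics. The generator validates the
*measurement machinery*, not the biology.

# Problem sizes and numerical choices

The shipped validation runs at deliberate desk scales: planted-distribution
recovery at n = 5,000 frames (mean within 0.3°, sd within 10%), contact
occupancy at n = 1,000 frames against exact binomial 99% intervals, RMSF
convergence at n = 2,000 frames (within 5% of σ√3), medoid recovery on
100-frame fixtures against a brute-force quaternion-method matrix, and a
full four-system pipeline at 2 runs × 1,000 frames per system. Tolerances
are derived, not tuned: 3σ/√n bounds for means, exact binomial quantiles
for occupancies, closed forms for FWHM and RMSF, and 1e-6°/1e-9°
tolerances where the quantity is exact by construction.

Other numerical decisions, collected: selections resolve 1-based inclusive
author-numbered residue ranges and are order-stable and idempotent; frames
failing a metric (e.g. coincident centroids) are excluded and counted, with
a hard error past 10% failures; `read_trajectory()` assigns one run per
input file in path order; multi-model PDB is the canonical human-readable
dialect and DCD (read via bio3d; written by a minimal internal X-PLOR
writer, since no installed R package writes DCD) covers the binary format,
with round-trips verified to writer precision (3 decimals for PDB, float32
for DCD); comparison of two bundles refuses configurations whose
fingerprints (MD5 of the canonicalized manifest/cutoffs/stats) differ.

# Known limitations

* The interaction typer covers the 20 standard residues plus SEP and the
  His protonation-state names; other hetero-groups degrade to
  van-der-Waals-only with a warning. There are no weak-hydrogen-bond,
  CH–π or halogen categories.
* The hydrogen-bond angle term requires explicit hydrogens; hydrogen-free
  topologies silently use the distance-only criterion (logged as "no-H"
  behaviour in the cutoffs documentation).
* The published reference table embeds one internal inconsistency (the
  wild-type NTnC–CTnC KDE modes 31.1 → 29.6 Å are printed alongside a
  delta of −0.5 Å, which matches an unphosphorylated mode of 30.1 Å, the
  value also suggested by the printed mean 30.18 Å). `state_delta()`
  always reports exact B − A arithmetic on the values it is given.
* `pairwise_rmsd()` is O(n²) in strided frames with an R-level loop; the
  2,000-frame default budget keeps it in tens of seconds, but full
  37,500-frame matrices are out of scope on one CPU.
* Per-run (as opposed to pooled) distribution summaries, time-lagged
  analyses and clustering beyond medoid selection are intentionally not
  provided.
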