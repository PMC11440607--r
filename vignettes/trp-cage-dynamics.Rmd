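---
title: "Rigid-body segmentation and fold-stability descriptors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body segmentation and fold-stability descriptors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcagedyn)
```

# The problem

Exenatide-class peptide agonists of the GLP-1 receptor can be rigidified by a
C-terminal Trp-cage (Tc) motif — a compact miniprotein fold in which a
polyproline-II tail and a 3~10~ helix encase a central tryptophan (W25 in
exenatide numbering).  Assessing what that rigidification does to the
peptide's fold stability and to the receptor complex's internal dynamics
requires a set of quantitative descriptors computed from heterogeneous data:
molecular-dynamics trajectories of the receptor complexes, NMR chemical
shifts and NOESY cross-peak volumes of the free peptides, and CD melting
series.  This package implements those descriptors as one tested pipeline,
together with synthetic-data generators that plant known ground truth, so
that every stage can be validated end to end without any external download.

# Rigid-body segmentation (RBS)

## Model

A group of residues that moves as one quasi-rigid body keeps its internal
C&alpha;–C&alpha; distances nearly constant along a trajectory.  RBS
therefore reduces a trajectory to its **distance standard-deviation
matrix**: entry $(i, j)$ is the population standard deviation (divide by
$N$) of the C&alpha;$_i$–C&alpha;$_j$ Euclidean distance over the sampled
frames.  The matrix is then clustered with DBSCAN, using the matrix itself
as the precomputed metric: residue $i$ is a *core* point if at least `cln`
residues lie within `clr` of it, clusters grow over core–core connectivity,
non-core residues within `clr` of a core attach as border points, and
everything else is `UNASSIGNED` — those residues move freely.

Defaults are `clr = 2.5` Å, `cln = 5`, frames sampled at 100 ps intervals.

## Numerical and convention choices

* **Population standard deviation.**  With hundreds of frames the $N$ vs
  $N-1$ choice is immaterial, but it must be pinned down for exact
  reproducibility; the divide-by-$N$ form matches the "standard deviation"
  reading most directly and makes the two-frame case exact
  ($\sigma(\{3,5\}) = 1$).
* **Neighbor counting.**  Whether a point counts itself among its `cln`
  neighbors differs between DBSCAN conventions.  The default here requires
  `cln` *other* residues within `clr` (a "neighbor count" reads most
  naturally as excluding the point); `include_self` is exposed as a
  parameter because some library implementations count the point itself.
* **Deterministic border rule.**  DBSCAN border assignment is famously
  order-dependent.  Here a border point joins the cluster of the
  *lowest-index* core point whose neighborhood covers it.  This rule is
  order-free, deterministic, and is what the label-for-label oracle tests
  assert.
* **Segment numbering.**  Ids run `0..K-1` ordered by each segment's first
  residue, so output is stable under re-runs.
* **Striding.**  Frames are taken at times $0, s, 2s, \dots$; when the
  stride is not a multiple of the frame interval the nearest earlier frame
  is used and a warning is emitted.
* **Equilibration.**  All provided frames are used by default; discarding an
  initial fraction is available in the descriptor layer
  (`equilibration_discard`) because no universal burn-in fraction exists.

# The synthetic trajectory generator

`generate_hinge_trajectory()` plants a known rigid-body decomposition: one
C&alpha; per residue on an ideal &alpha;-helical template (rise 1.5 Å, 100°
per residue, radius 2.3 Å), bodies rigidly rotated about inter-body hinges
by angles drawn from $N(0, \text{amplitude})$, plus isotropic per-atom
Gaussian jitter.  Its defaults are the study conditions used throughout the
tests: body jitter 0.2 Å, hinge amplitude 30°, linker jitter 3 Å, 200
frames at 100 ps.

Two geometric choices deserve explanation because naive alternatives make
the planted ground truth unrecoverable *in principle*, not merely noisy:

* **Off-axis hinge pivot.**  A rotation preserves every distance to its
  pivot, so a pivot placed *on* the chain axis between two bodies leaves
  near-hinge inter-body distances invariant to second order in the hinge
  angle — no amplitude makes those pairs fluctuate, and a single
  low-fluctuation core–core pair merges the two bodies in DBSCAN.  The
  generator therefore displaces the pivot laterally off the chain axis
  (default 12 Å, direction random per joint per seed) with the rotation
  axis perpendicular to both the chain and the offset.  This is also the
  physically sensible picture: real domain hinges pivot about contact
  points at the interface periphery, so the moving domain sweeps a
  lever arm.  With this geometry every cross-body distance fluctuates in
  proportion to amplitude × offset (≈ 4 Å standard deviation at the
  defaults, safely above `clr`).
* **Chord-sweep linkers.**  A flexible linker pinned to a static template
  with isotropic jitter σ has *folded* distance distributions to its
  sequence neighbors: at separations comparable to σ the distance standard
  deviation saturates near $0.67\sigma$ (≈ 2.0 Å at σ = 3 Å), i.e. *below*
  the default `clr` — border attachment of linker residues would then be a
  coin flip across seeds rather than a property of the motion.  Linker
  residues bracketed by two bodies are instead placed, per frame and per
  residue, at a uniform random fraction along the chord between the two
  flanking body anchor atoms (plus their jitter): a floppy tether sweeps
  the whole inter-domain gap.  When a joint's amplitude is zero, the tether
  rests at fixed fractional positions so that the zero-motion degenerate
  case yields bit-identical frames.

Jitter is drawn as standard normals in a fixed order and scaled by each
atom's σ, so sweeping jitter at a fixed seed produces coupled trajectories —
the monotone-degradation property (raising body jitter never shrinks the
unassigned set) is then a property of the model rather than of sampling
luck.

What the generator does **not** emulate: force-field energetics, solvent and
membrane contacts, correlated loop motions, anisotropic B-factor structure,
side chains (only C&alpha; traces are generated for segmentation work).
Passing the recovery tests therefore shows that the segmentation machinery
is correct and well-conditioned under the stated motion model — not that
`clr = 2.5` Å/`cln = 5` are optimal for any particular real system.

# Trajectory descriptors

* **Ring-centroid distances** (`centroid_distance_series`): unweighted mean
  of the ring atoms per frame (default: the 9-atom Trp indole), Euclidean
  distance between the two centroids.  Distributions are summarized with a
  midpoint-rule median and a histogram mode; bins are left-closed and
  *centered* on multiples of the bin width (default 0.1 Å, the reporting
  granularity typical for such distances), ties resolving to the lowest
  bin.
* **χ1 rotamers** (`dihedral_series`, `classify_rotamer`): standard IUPAC
  signed torsion in $(-180°, 180°]$ (cross-checked against an independent
  implementation to 10⁻⁸ degrees in the tests); classes are fixed 120°
  sectors centered on −60° (gauche(−)), +60° (gauche(+)) and 180°
  (antiperiplanar), since the class names fix the centers but not the
  boundaries.  Frames with collinear atoms have no defined torsion and are
  reported as missing.
* **Contact occupancies** (`contact_occupancy`, `count_multiple_hbonds`):
  fraction of retained frames where any donor–acceptor pair meets the
  criterion.  Hydrogen bonds use heavy-atom distance ≤ 3.5 Å *and*
  D–H···A angle ≥ 120° (angle at the hydrogen); when no hydrogen is listed
  the criterion downgrades to distance-only with a message.  Salt bridges
  use any cation-group N to anion-group O distance ≤ 4.0 Å.  These cutoffs
  are the common MD-analysis conventions; occupancy percentages in the
  literature rarely state theirs, so both are parameters.
* **Segment RMSD vs a reference ensemble**
  (`segment_rmsd_vs_reference`): the reference frames are mutually
  superposed on the fit selection and averaged; each analyzed frame is then
  least-squares fitted to that average on the fit selection, and the RMSD
  is taken over the measure selection and averaged over frames.  A
  mean-structure reference is deterministic and cheap; "distance to the
  nearest reference frame" is a different statistic and intentionally not
  the default.
* **Cluster counts** (`cluster_coverage_count`): leader-style (gromos)
  clustering on pairwise fitted C&alpha; RMSD — repeatedly take the frame
  with the most neighbors within the cutoff (ties to the earliest frame) as
  a center and remove its cluster — then report how many clusters, largest
  first, are needed to cover 95% of frames.  The clustering algorithm
  behind published cluster counts is usually unstated; gromos-style
  clustering is the documented stand-in here.

# NMR fold descriptors and melting-curve normalization

Secondary chemical shifts are `SCS = δ_obs − δ_rc` per proton.  Two summed
descriptors quantify the fold:

* `scs_helix`: Σ|SCS| of H&alpha; protons over the helical window (default
  residues 16–27 in exenatide numbering — the same window as residues 2–13
  of the truncated 25-mer constructs, related by the fixed +14 offset;
  `renumber_residues()` converts between the schemes).
* `scs_tc`: Σ|SCS| over the nine unique ring-current-sensitive protons
  around the central Trp (W25 Hε1, L21 Hα, G30 Hα2, P31 Hβ2, R35 Hα,
  P37 Hα, P37 Hβ2, P38 Hδ1, P38 Hδ2).  Absolute-value summation is the
  default so that the two descriptors share one convention; a signed mode
  exists because ring-current shifts have physically meaningful signs
  (upfield above/below the indole plane, downfield in it).  After
  normalization the two modes differ only when signs are mixed.

Random-coil references are an *input* (a small approximate 1H reference
table ships with the package for tests and examples); random-coil
prediction and CD spectrum deconvolution are upstream tools, and their
outputs (random-coil shifts, folded fractions) enter this pipeline as data.

To compare melting curves recorded by different techniques
([Θ]~222nm~, folded fraction, SCS~helix~, SCS~Tc~), each series is divided
by the *reference variant's value at its lowest temperature*
(`normalize_series`), which maps that reference point to exactly 1 and puts
all four descriptors on one dimensionless scale.  Each method anchors at
its own lowest temperature (4 °C for the NMR grid, 5 °C for CD) because
the acquisition grids differ; the anchor is recorded in the result's
metadata.  Comparison temperatures are then read off by linear
interpolation: `crossing_temperature` returns the lowest temperature at
which a series reaches a level (exact grid hits returned as-is), and
`value_at_temperature` interpolates within the grid, rejecting
extrapolation.

# NOE calibration

NOESY cross-peak volume scales approximately as the inverse sixth power of
the interproton distance.  `calibrate` assigns the arithmetic mean volume
to the reference distance (3.2 Å), and `volumes_to_restraints` applies

$$ d_i = d_\mathrm{ref} \left( \frac{V_\mathrm{ref}}{V_i} \right)^{1/6}, $$

clipping targets into [1.72, 8.00] Å and setting the restraint bounds to
those policy limits.  The arithmetic mean is the documented default reading
of "average of the volume intensities"; a geometric-mean alternative is one
flag away because the exporting software's exact convention is not public.
Duplicate proton pairs (symmetric-peak exports) merge by volume summation
with a warning, or can be rejected strictly.

Long-range peaks are those with sequence separation $|i - j| \ge 5$ — the
contacts that pin the tertiary Tc motif — and thermal unfolding is
quantified by the loss fraction $1 - N/N_\mathrm{ref}$ against a reference
(lowest-temperature) peak list.

A note on the round-trip check (`restraint_roundtrip_check`): calibration
estimates $V_\mathrm{ref}$ as the mean volume of the list at hand, so an
exact noise-free inverse requires the generator's reference distance to be
*volume-mean consistent* — the −6 power mean $(\overline{d^{-6}})^{-1/6}$
of the true distances.  That value is the default; with it, recovery is
exact to machine precision inside the clipping bounds, and first-order
error propagation $|\Delta d / d| \approx |\Delta V / V| / 6$ holds for
small volume noise.

# Problem sizes

The test-suite and acceptance-script workloads are sized for a desk run:
synthetic rigid-body systems of 1–4 bodies × 30 residues with 5-residue
linkers at 200 frames (10 seeds per condition), 200 random matrices up to
n = 60 for the clustering oracle, 10⁴ random quadruples for the torsion
oracle, 10³ peaks for noise propagation, and 100 seeds for the shift-noise
bias check.  These sizes were chosen so the full validation runs in about a
minute while keeping every statistical margin (worst-case fluctuation
distances vs `clr`, bias vs 3·SEM) several sampling standard deviations
wide.

# Known limitations

* Occupancy percentages, rotamer-class fractions and cluster counts from
  published μs-scale membrane-GPCR simulations cannot be reproduced without
  those trajectories; the pipeline validates the *operators* on synthetic
  ground truth and accepts real trajectories through the same interfaces.
* The multi-model PDB reader requires consistent topology across models and
  does not unwrap periodic images; inputs are assumed whole.
* mmCIF and NMR-STAR are not parsed; tables enter as TSV/CSV.
* Binary trajectory formats (XTC/DCD) are not read in this R
  implementation; multi-model PDB is the portable interchange format.
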