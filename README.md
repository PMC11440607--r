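# tcagedyn

Quantitative descriptors for the dynamics and fold stability of
Trp-cage-stabilized peptide agonists and their GLP-1 receptor complexes.

Rigidifying a peptide hormone mimetic with a C-terminal Trp-cage (Tc) — a
miniprotein fold in which a polyproline-II tail and a 3₁₀ helix encase a
central tryptophan — changes both the peptide's thermal stability and the
internal dynamics of its receptor complex. Judging those changes requires
descriptors computed from several kinds of data. This package implements
that analysis pipeline for R users working at the interface of molecular
simulation and biomolecular NMR:

* **Rigid-body segmentation (RBS)** of MD trajectories: the Cα–Cα distance
  standard-deviation matrix (entry *(i,j)* = population σ of the
  Cα*ᵢ*–Cα*ⱼ* distance over frames) is clustered with DBSCAN (defaults:
  cluster radius `clr = 2.5` Å, neighbor count `cln = 5`, 100 ps frame
  sampling) into quasi-rigid segments; residues reachable from no core
  point are `UNASSIGNED` and move freely.
* **Trajectory descriptors**: Trp-indole centroid distance series with
  median/mode summaries, χ1 rotamer classification (gauche(−)/gauche(+)/
  antiperiplanar), hydrogen-bond and salt-bridge occupancies, backbone RMSD
  of a segment against a reference ensemble, and gromos-style
  95%-coverage conformational cluster counts.
* **NMR fold descriptors**: secondary chemical shifts SCS = δ_obs − δ_rc;
  SCS_helix = Σ|SCS(Hα)| over the helical window (residues 16–27, Ex4
  numbering) and SCS_Tc = Σ|SCS| over the nine ring-current-sensitive
  protons around W25; melting series from different techniques normalized
  to a reference variant's lowest-temperature point and compared via
  interpolated crossing temperatures.
* **NOE calibration**: NOESY cross-peak volumes converted to distance
  restraints via *d = d_ref (V_ref / V)^(1/6)* with V_ref the mean volume
  at d_ref = 3.2 Å, clipped to [1.72, 8.00] Å; long-range (≥ *i*+5) peak
  counting and thermal peak-loss fractions.
* **Synthetic-data generators** with planted ground truth for all of the
  above (hinged rigid-body trajectories, shift tables, peak lists, melting
  sigmoids), so every stage is testable without downloads.

## Worked example

Plant a two-body hinge system with a flexible linker, recover it, and
calibrate a synthetic NOESY peak list:

```r
library(tcagedyn)

spec <- rigid_body_spec(bodies = list(1:30, 36:65), linkers = list(31:35))
traj <- generate_hinge_trajectory(spec, sim_spec(n_frames = 200, seed = 1))
seg <- segment_trajectory(traj)
seg
#> rigid-body segmentation: 2 segment(s), 5 of 65 residues unassigned
#>   clr = 2.5 A, cln = 5 (exclude_self), frames analyzed: 200
summary(seg)
#>     segment residues n_residues   fraction
#>           0   A:1-30         30 0.46153846
#>           1  A:36-65         30 0.46153846
#>  unassigned  A:31-35         5 0.07692308
```

The two planted 30-residue bodies come back as segments 0 and 1 with exact
membership, and the 5-residue flexible linker is unassigned — it moves
freely, so it belongs to no rigid segment. `write_labeled_pdb(traj, seg,
"colored.pdb")` encodes the segment ids in the B-factor column for
visualization.

```r
pl <- generate_peak_list(c(2.5, 3.2, 4.1, 5.8), v_ref = 100, d_ref = 3.2)
cal <- calibrate(pl)
cal
#> NOE calibration: d_ref = 3.20 A at V_ref = 141.3 (mean of 4 volumes)
round(volumes_to_restraints(pl, cal)$distance, 3)
#> [1] 2.648 3.390 4.343 6.144
```

The recovered distances differ from the planted ones only through the
reference-volume estimate (the mean volume of the list at hand); see the
methods vignette (`vignettes/trp-cage-dynamics.Rmd`) for the exact-inverse
condition and the noise-propagation bound |Δd/d| ≈ |ΔV/V|/6.

A thin command-line front end ships in `inst/exec/tcagedyn`
(`simulate | segment | describe | scs | calibrate`), e.g.:

```sh
Rscript inst/exec/tcagedyn segment --traj ensemble.pdb --clr 2.5 --cln 5 \
    --out labels.tsv --pdb-out colored.pdb
```

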