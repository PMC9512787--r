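# augminr

Integrative structural analysis of coiled-coil multiprotein assemblies,
built around the workflow used to establish the architecture of the
augmin (HAUS) complex — the octameric factor that recruits the
γ-tubulin ring complex to spindle microtubules for branched
nucleation. The package is aimed at structural bioinformaticians who
need to validate and compare predicted or fitted models of large,
flexible complexes with orthogonal experimental restraints.

## What it computes

* **Ensemble flexibility profiling.** Members of a model ensemble are
  superposed on a core selection by least-squares (Kabsch/SVD)
  superposition; per-residue Cα deviation is reported either between
  the two most extreme conformations (max over all pairwise global
  RMSDs) or as the per-residue ensemble RMSD about the mean.
* **Crosslinking-MS validation.** Residue-pair tables are
  deduplicated per unordered pair (best aggregate score wins,
  score = Σ −ln E over spectra), filtered at score > 250, mapped to
  Cα–Cα distances *d* on a model, and classified satisfied iff
  *d* ≤ 30 Å. Reports include the integer-rounded percent satisfied,
  per-subunit-pair count tables, and a permutation test for the
  association between violated links and flexible residues.
* **Density docking.** Maps are simulated from models as Gaussian
  atoms with σ = resolution × 1/(π√2); rigid-body fits are scored by
  masked Pearson cross-correlation, searched over a deterministic
  axis-angle grid plus local refinement. MRC/CCP4 2014 map I/O is
  included.
* **Composite modelling and hinge measurement.** Complementary residue
  ranges of overlapping models are spliced (with deletions and rigid
  placements) into one composite; the rotation relating a mobile
  domain between two conformations is extracted as an axis-angle pair,
  θ = atan2(‖skew(R)‖/2, (tr R − 1)/2), after superposition on a
  reference selection (or after centroid centering for globular-domain
  comparisons).
* **Synthetic studies.** Seeded generators build helix bundles,
  two-state hinge ensembles with known rotation, flexible ensembles
  with planted per-residue amplitudes, and crosslink tables with
  planted satisfied/violated pairs and duplicate rows — every pipeline
  stage is testable against exact ground truth, offline.

## Worked example

Measure a clamp-opening rotation on a synthetic two-state hinge and
validate a planted crosslink study:

```r
library(augminr)

hinge  <- make_hinge_ensemble(23, axis = c(0, 1, 0), split_residue = 50)
fixed  <- parse_selection("S1 1-50; S2 1-50; S3 1-50; S4 1-50")
mobile <- parse_selection("S1 51-100; S2 51-100; S3 51-100; S4 51-100")
rotation_between(hinge$ensemble[[1]], hinge$ensemble[[2]], fixed, mobile)
#> <hinge_measurement> 23.00 deg about (0.000, 1.000, -0.000)
#>   reference fit rmsd: 0.000 A, mobile residual rmsd: 0.000 A

bundle <- make_bundle(n_chains = 4, n_res = 100)
xl  <- make_crosslinks(bundle, n_satisfied = 90, n_violated = 10,
                       n_duplicates = 15, seed = 1)
links <- dedup_and_filter(xl$table, score_min = 0)
validate_crosslinks(map_crosslinks(links, bundle), d_max = 30)
#> <xl_validation> 100 links: 90 satisfied, 10 violated, 0 unmapped (d_max 30.0 A)
#>   90% of mapped links satisfied
```

The hinge measurement recovers the generator's planted 23° rotation
and its axis exactly; the 115-row table (100 planted pairs + 15
injected duplicates) collapses back to 100 unique links, of which the
planted 90% fall within the 30 Å BS3-compatible bound. `tidy()` and
`glance()` return the same results as tibbles, `autoplot()` draws the
per-residue flexibility profile and the satisfied/violated distance
bars, and `run_analysis()` chains all stages from one (YAML-able)
configuration.

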