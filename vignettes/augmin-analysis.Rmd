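---
title: "Integrative validation of coiled-coil complex models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative validation of coiled-coil complex models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augminr)
```

## The problem

The augmin (HAUS) complex is an octameric, largely coiled-coil assembly
that recruits the γ-tubulin ring complex to spindle microtubules for
branched nucleation. It splits into two tetramers: TII (HAUS2/6/7/8),
the microtubule-binding module, and TIII (HAUS1/3/4/5), the γ-TuRC
binding module. Complexes of this kind — elongated, flexible, hard to
resolve to high resolution — are typically characterised by an
*integrative* strategy: ensembles of predicted models are profiled for
internal (dis)agreement, crosslinking mass-spectrometry restraints are
mapped onto candidate models and scored against a distance threshold,
models are docked as rigid bodies into low-resolution EM densities and
ranked by cross-correlation, and composite models of the full assembly
are spliced from overlapping subcomplex models. `augminr` implements
that workflow as a reusable, tested pipeline, together with seeded
synthetic generators so that every stage can be exercised — and its
statistical behaviour verified against planted ground truth — without
any external downloads.

## Structures, selections and chain maps

Atomic models are tibbles of atom records (`atom_tbl`), keeping the
author residue numbering of the source file as the only addressing
scheme; all residue ranges used in the analysis (clamp halves, arm
segments, hinge deletions) are expressed in that numbering, so no
renumbering ever happens on read. PDB and mmCIF reading and PDB writing
are delegated to `bio3d`. Alternate locations keep the
highest-occupancy copy (ties: first encountered). Because the PDB chain
field is a single character, multi-character chain names (the synthetic
generators use subunit-style `S1`, `S2`, ...) are remapped
deterministically to single letters on write, with a warning.

Selections are tibbles of `(subunit, start, end)` ranges; a chain map
connects subunit names to model chains (many-to-one allowed, for
subunits present in more than one copy). Resolution of a selection is
deterministic (ordered by chain, residue number, insertion code, atom
name) and *always* reports requested residues absent from the model
rather than silently dropping them: downstream superpositions require
identical residue sets, and silent drops would corrupt the pairing.
`augmin_selections()` ships the fixed ranges used in the augmin
analysis (N-clamp, C-clamp, H3/H5-arm, rigid N-clamp body, hinge
deletions, HAUS6 tail).

## Superposition and ensemble flexibility

All superpositions minimise least-squares RMSD over paired Cα atoms via
the SVD (Kabsch) solution with the determinant correction, so a proper
rotation is always returned, also for degenerate (rank-deficient) point
sets. Cα-only superposition is the package default: at the resolutions
involved (≈ 8 Å simulated density, ~2 Å model uncertainty) side-chain
atoms add no information, and Cα-only keeps every operation well-defined
on the Cα-only synthetic models.

Ensemble analysis aligns every member onto a reference member
(member 1 by convention — ensembles are expected sorted by prediction
confidence, and the highest-confidence model is the natural reference)
over a stated core selection. Two flexibility summaries are provided:

* **extreme pair** — per-residue Cα deviation between the two members
  with the largest global Cα RMSD (found exhaustively over all pairs,
  ties broken lexicographically). This mirrors the common "colour by
  RMSD between the two most extreme conformations" display, usually
  shown on a 0–10 Å scale.
* **ensemble RMSD** — per-residue root-mean-square deviation from the
  per-residue ensemble mean, over all members. This is the estimator the
  synthetic tests check quantitatively: for the generator's displacement
  model (isotropic random direction, `N(0, σ)` magnitude) its
  expectation is σ per residue.

Residues missing from some members are intersected away before
profiling and reported; a residue present in some members but not
others within the *core* is an error naming the offending members,
because a partial core silently changes the superposition.

## Hinge (axis-angle) measurement

The rotation relating a mobile domain between two conformations is
measured by first superposing the conformations on a fixed reference
selection, then extracting the least-squares rotation of the mobile
selection and decomposing it into axis and angle. Angles are reported
in degrees in [0, 180] with a right-handed unit axis; opening versus
closing is carried by the axis direction, not by a signed angle. The
angle is computed as `atan2(‖skew(R)‖/2, (trace(R)−1)/2)`, which keeps
full floating-point precision at both ends of the range (the plain
`acos` form loses half the significant digits near 0° and 180°); near
180° the axis is taken from the eigenvector of `R` for eigenvalue +1.
A `centroid` mode skips the reference superposition and instead
translates both mobile domains to a common centroid — the convention
for comparing the orientation of two globular domains (e.g. tandem
calponin-homology domains) independently of their position.

Synthetic two-state hinge ensembles with a known rotation are the
ground truth here: the tests require exact recovery (to 1e-6 degrees)
at 0°, 23°, 90° and 180°, 23° being the clamp-opening magnitude
relevant to the augmin TII hinge.

## Crosslink validation

The pipeline starts from the residue-pair table exported by the MS
search software; spectral search and FDR control happen upstream and
are out of scope. Processing follows the field's standard recipe:

1. **Deduplication** — one record per unordered residue pair, keeping
   the copy with the highest aggregate score (sum of −ln(E) spectrum
   scores); ties keep the first record in file order, which makes the
   operation deterministic and idempotent.
2. **Score filter** — strictly greater than `score_min` (default 250);
   a link scoring exactly 250 is excluded. The strict reading follows
   the usual "higher than" phrasing of such thresholds.
3. **Mapping** — Euclidean Cα–Cα distance on the target model; a
   subunit mapped to several chains takes the minimum over chain
   combinations; links with an endpoint outside the modelled range are
   flagged `unmapped`, kept in the report, and excluded from the
   percentage denominator.
4. **Validation** — satisfied iff distance ≤ `d_max` (inclusive;
   default 30 Å, the conventional BS3 Cα–Cα bound). The headline
   percentage is rounded to an integer, as conventionally reported;
   full precision is retained in the tables. Export scores are divided
   by `score_norm_factor` (default 10) for downstream visualisation
   tools.

Cα–Cα (rather than lysine Nζ–Nζ) distance is the standard convention
when only a threshold is stated; it is also the only choice available
on Cα-only models.

The **violation–flexibility association** asks whether violated links
preferentially touch flexible residues. A residue is "flexible" when
its profile deviation exceeds the q = 0.8 quantile of the profile; the
observed statistic is the fraction of violated links with at least one
flexible endpoint; the null permutes satisfied/violated labels over the
mapped links with fixed counts, and the p-value uses the standard
add-one estimator. Both the quantile and the permutation null are this
package's formalisation of what is usually a qualitative claim, and the
report labels the statistic as exploratory.

## Density simulation, correlation and rigid fitting

Maps are simulated as sums of per-atom isotropic Gaussians with
σ = resolution × `sigma_factor` and amplitude proportional to atomic
number (uniform on Cα-only models). The default
`sigma_factor = 1/(π√2) ≈ 0.225` matches the convention of the widely
used visualisation tools; correlation values are only comparable
between implementations that agree on this width. Grid defaults:
voxel = resolution/3, padding = 2 × resolution. The sampling
precondition resolution > 2 × voxel is enforced.

Cross-correlation is a Pearson correlation about the mean after
trilinear resampling of one map onto the other's grid. The default
mask keeps voxels where the resampled model map exceeds 1% of its
maximum, so empty box volume cannot dilute the coefficient; a full
`overlap` mask is available. Pearson-about-mean makes the score
invariant to affine rescaling of either map, which the tests assert.

Rigid fitting scores a pose by simulating a map from the posed model
and correlating it against the target. Interactive docking is not
reproducible, so the search is a deterministic two-stage procedure: an
exhaustive coarse stage over a uniform axis-angle rotation grid
(default 15° step; area-weighted axis grid) and a translation grid,
ranked by a fast proxy (mean interpolated target density at the posed
Cα positions), followed by Nelder–Mead refinement of the best
candidates against the full cross-correlation. The identity placement
is always evaluated, so the reported fit can never score below it.
MRC/CCP4 2014 map I/O is implemented directly (mode-2 float,
axis-order normalisation, origin handling, voxel-size override for
recalibrated pixel sizes); no R package in the supported stack reads
MRC. Coverage — the fraction of Cα atoms inside density at a contour —
links the map view of flexibility back to the per-residue profile.

## The synthetic generators

The generators define the study conditions for everything above and
emit their ground truth alongside the data:

* `make_bundle()` — ideal α-helical Cα traces (rise 1.5 Å, twist
  100°/residue — the textbook α-helix — helix radius 2.3 Å), chains on
  a circle at 12 Å spacing; 4 chains × 100 residues by default, the
  scale of one augmin tetramer's core. Deterministic, no RNG.
* `make_hinge_ensemble()` — a two-state pair with everything past a
  split residue rotated by a stated angle about a stated axis; the
  default study angle is 23°, the experimentally observed clamp
  opening.
* `make_flex_ensemble()` — per-atom displacements along an isotropic
  random direction with `N(0, σ_residue)` magnitude. This convention
  (rather than per-coordinate noise) makes the recovered per-residue
  ensemble RMSD equal σ in expectation, so planted step profiles with
  σ = 3 Å are recovered in the 1.5–4.5 Å band at 25 models.
* `make_crosslinks()` — satisfied pairs sampled at ≤ 30 Å, violated
  beyond it, log-normal scores centred at 250 (`meanlog = log 250`,
  `sdlog = 0.5`) so the strict filter is exercised on both sides,
  optional duplicate rows with strictly lower scores, and K/KSTY
  residue-type labels emulating BS3 chemistry in the table only. The
  default 90/10 planted split makes the expected satisfaction 90%,
  adjacent to the ~91% regime reported for well-validated models.

All randomness uses R's Mersenne–Twister via `set.seed`, which is
platform-stable; generators save and restore the caller's RNG state.

What the generators do *not* emulate: real coiled-coil supercoiling,
side chains, correlated (domain-like) flexibility, distance-dependent
crosslink detectability, and search-engine score distributions. Tests
passing on synthetic data therefore demonstrate correctness of the
*computations* (exact recovery of planted rotations, rates, counts and
profiles), not the biological accuracy of any particular model.

## Numerical choices and edge cases

* Satisfied threshold inclusive (≤ 30 Å); score filter strictly
  exclusive (> 250); both asserted at the boundary in the tests.
* Dedup tie-break: first record in input order.
* Percentages rounded to integers only in headline fields; tables keep
  full precision. Angles report to 0.1°, distances to 0.01 Å in the
  JSON report.
* Zero mapped links yields an `NA` percentage, not a division error;
  zero violated links yields an undefined association statistic with a
  message.
* Trace of a near-degenerate rotation is clamped within 1e-6 before
  the angle is taken; anything farther out of range errors.
* The ensemble-RMSD profile is invariant under any global rigid motion
  of the aligned ensemble (asserted as a property test).

## Reproduction scope and problem sizes

The quantitative claims about the deposited augmin data (190
high-confidence crosslinks of which 88 intramolecular and 102
intermolecular; 91% satisfaction on the fitted TIII model; the 23°
clamp rotation between the open and closed holocomplex conformations;
the ~180° relative rotation of the HAUS6/HAUS7 CH domains) require the
deposited accession files (PDB 8AT2/8AT3/8AT4, PDB 3IZ0, and the
exported crosslink tables). The reproduction tests in
`tests/testthat/test-acceptance.R` run against those files when placed
under the directory named by `options(augminr.reference_dir = ...)`
(default `~/augmin-reference`) and fail with an explanatory message
when the files are absent. The download-free battery runs on synthetic
studies sized to execute quickly while keeping estimates stable: 25
models for profile recovery, 2 × 40-residue bundles for fitting
searches, 4 × 100-residue bundles for crosslink studies, 999
permutations for the association null. These sizes are the package's
chosen defaults for its own verification; all are parameters the user
can raise.

## Limitations

* No flexible fitting, energy minimisation, or morphing; flexible-fit
  models are inputs, not outputs.
* mmCIF is read-only; writing is PDB-only, with the single-character
  chain restriction noted above.
* The rigid-fit search is exhaustive-plus-local, not globally optimal;
  its guarantees are the ones tested (self-fit identity, recovery of
  moderate displacements, never below the identity placement).
* The association statistic is exploratory by construction and should
  be read as descriptive, not confirmatory.
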