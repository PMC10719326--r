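---
title: "Membrane anchorage metrics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane anchorage metrics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`memanchor` measures how strongly a small molecule anchors to the surface
of a lipid bilayer in a molecular dynamics trajectory. This vignette is
the package's methods account: the models behind each metric, the
parameters that matter and their defaults, what the synthetic generator
does and does not emulate, the numerical choices, and the limitations a
user should know about.

Units are fixed package-wide: coordinates in nm, times in ps, masses in
amu, charges in elementary-charge units, energies in kT. Boxes are
orthorhombic; triclinic input is rejected explicitly rather than silently
mishandled. The membrane normal is z, the upper leaflet sits at z above
the mid-plane, and leaflet assignment is a static annotation from the
topology sidecar — bilayers do not flip-flop on the timescales this
package targets, so per-frame re-assignment would add noise, not
information.

## The data model

A system is a `topology` (one row per atom: element, mass, partial
charge, residue class, leaflet label, hydrogen-bond role) plus a
`trajectory` (time-ordered frames of positions with per-frame box
lengths). Structures are read from fixed-column GRO files; annotations
from a sidecar CSV; trajectories from extended-XYZ text whose comment
line carries `time=<ps> box=<Lx>,<Ly>,<Lz>`. All readers reject
truncated or malformed files outright — a partially read trajectory is a
silent source of biased averages.

The bilayer **mid-plane** is defined as the mass-weighted mean z of all
lipid atoms. The choice is genuinely open (phosphate-plane definitions
are equally defensible); the mass-weighted all-atom mean is adopted
because it is well defined for any lipid selection, including the
single-bead lipids of the synthetic generator, and it degrades gracefully
for asymmetric compositions. A custom atom selection can be passed to
`assign_midplane()` when a phosphate-plane convention is wanted.

## The four anchorage metrics

**Residence time** (`residence_time`). The fraction of frames, as a
percentage, in which the shortest minimum-image atom-pair distance
between the molecule and the leaflet selection is at or below the cutoff.
The default cutoff of 0.3 nm is the average length of a biological salt
bridge; the boundary is inclusive ("0.3 nm or less"). "Atom on the
surface" is interpreted as *any* atom of a lipid assigned to that
leaflet; the selection argument lets a user restrict to head groups.

**Hydrogen bonds** (`hbond_count`). A bond exists when a donor carrying a
polar hydrogen and an acceptor lie at r(Do,A) ≤ 0.35 nm while the
hydrogen–donor–acceptor angle is ≤ 30°, both boundaries inclusive. The
angle is measured **at the donor**, between the donor→hydrogen and
donor→acceptor vectors, following the criterion's wording; the more
common donor–H···A linearity convention is available via
`angle_at = "hydrogen"` (implemented as 180° minus the Do–H–A angle, so
the same "≤ 30°" semantics apply). Both donor-in-A/acceptor-in-B
directions are scanned, and each bond is attributed to the residue class
of the membrane-side partner, which yields the per-phospholipid
attribution table.

**Diffusion** (`msd`, `diffusion_coefficient`, `diffusivity_ratio`). The
MSD is averaged over all time origins (sliding window), per axis and in
total, for the drug's centre of mass; D is the least-squares slope over
the fit window divided by 2·dim. The default fit window is 10–50 % of
the maximum lag — the standard bias/variance compromise: shorter lags are
better sampled, longer lags are noisier and, in a finite box, biased by
confinement. Because x and y are stored wrapped, per-frame displacements
are healed by the minimum-image convention before accumulating
(`unwrap = TRUE`); this is exact whenever true per-frame displacements
are below half the box, which the generator's stability limit guarantees.
With `unwrap = FALSE` a wrapped jump raises an error instead. Negative
fitted slopes are clamped to zero with a warning rather than reported as
unphysical negative diffusivities. The immobilization ratio is
D_membrane/D_bulk × 100 from a paired bulk run of the same molecule.
Inside the pipeline the ratio is fitted at deliberately short lags: in a
10 nm box the bulk z-MSD saturates within ~30 ns, so long-lag fits
measure confinement, not mobility, while at short lags the adsorbed
drug's suppressed z displacement shows up cleanly.

**Mid-plane proximity** (`midplane_location`). Frames are partitioned by
the sign of the drug's centre-of-mass z relative to the mid-plane, and
the mean |z| is reported separately for the two sides. Frames with the
drug between the head-group planes still partition by sign — molecules
can be simultaneously near both layers, so introducing a third category
would fragment exactly the interesting frames. An empty side reports an
absent value flagged `"absent"`, never a fabricated zero.

**Uncertainties** (`block_std`). Every metric reports the sample standard
deviation of the metric recomputed on 4 consecutive blocks. The pipeline
convention discards the first third of each trajectory as equilibration
and blocks the remainder — the generalization of "split the tail of the
run into 4 blocks" to runs of any length. `block_std` itself takes any
per-frame series and any per-block statistic, so metrics with non-mean
aggregation (percentages, counts) block correctly.

**Profiles.** `density_profile` histograms mass in z-bins relative to the
per-frame mid-plane and converts amu/nm³ to kg/m³ (factor
1.66053906660); bins align to multiples of the bin width so that sharp
structural boundaries fall on bin edges, and the binning conserves group
mass to floating-point accuracy (this identity is a test).
`free_energy_profile` is the Boltzmann inversion F(z) =
−ln p(z)/max p(z) in kT; empty bins give NA, never ±Inf, and an all-zero
histogram is an error. Boltzmann inversion is the only reading compatible
with unbiased equilibrium data — no reweighting or biased-sampling
machinery is implied.

**Dipole moment** (`dipole_moment`): μ = |Σ qᵢ rᵢ|, converted at
1 e·nm = 48.0321 D. For non-neutral species the moment is
origin-dependent; it is then reported about the centre of mass with a
warning, but rank-correlation analyses should use neutral forms only.

## The ranking rubric

`rubric_config()` encodes the four category bands (residence > 20 % /
12–20 %; hydrogen bonds > 0.1 / 0.05–0.1 per frame; mid-plane < 2.6 nm /
2.6–4.16 nm; diffusivity ratio < 25 % / 25–35 %). Boundary inclusivity
is deliberately explicit and configurable: prose thresholds like "more
than 20 %" and "between 12 and 20 %" are ambiguous exactly at the
boundary, so the package fixes a reading (strict first-band bounds,
closed second bands) and exposes every inclusivity flag through
`make_band()`. Values in neither band are "neither"; a missing metric
marks the criterion unavailable and is excluded from counts with a
warning rather than silently treated as zero.

`rank_drugs` orders by first-category count, then second-category count,
then layer breadth on residence (anchoring to both layers beats one),
then a criterion-priority comparison (residence > hydrogen bonds >
mid-plane > diffusivity). The chain beyond the two counts is an artifact
convention chosen for deterministic, reproducible output — it is
documented as such and not claimed to be a scientific ordering. Drugs
equal under every rule are reported as an explicit tie group and listed
alphabetically.

## The synthetic generator

The generator exists so that every estimator can be validated against
known ground truth: real drug–membrane MD data is typically not
redistributable, and no estimator should be trusted on data with unknown
answers only.

`build_membrane_topology` places one head bead per lipid on jittered
square lattices at ±z_surface around the box centre, with head-group
identities shuffled within each leaflet under a seed. The default
composition is the asymmetric myocardial model (upper: 40 PC, 17 PE,
7 SM; lower: 35 PC, 21 PE, 8 PS — 128 lipids, 64 per leaflet), whose
percentage bookkeeping (62.5 % PC upper, 12.5 % PS lower, 11 % SM upper
after rounding) is asserted in tests. Head beads carry realistic head
masses, a −1 charge on PS, and acceptor roles.

`simulate_adsorption` moves the drug centre by overdamped Brownian
dynamics: per step a Gaussian displacement of variance 2·D_bulk·dt per
axis, plus the square-well adsorption energy U(z) (depth `well_depth` kT
over [z_surface − well_width, z_surface] and its mirror image below)
applied through a Metropolis acceptance factor min(1, e^−ΔU/kT). For a
piecewise-constant well the deterministic drift −(D/kT)·dU/dz vanishes
almost everywhere and the entire Boltzmann weight lives at the well
edges; the acceptance factor implements exactly that weight, so long runs
sample e^−U(z)/kT exactly — a property the test suite checks by
chi-square. z-boundaries are reflective at the excluded core slab
(|z| < core_halfwidth) and at the box faces, preserving the
above/below-membrane distinction that mid-plane analysis needs; x and y
are free and periodically wrapped; stored z is never wrapped. The rms
step must not exceed the well width (a step that can jump the well
unresolved is a discretization failure), enforced as a stability error.
With the well switched off every move is accepted and the path is
generated in closed vectorized form — the same process, computed faster.

The closed-form two-state occupancy p = w·e^ε / (w·e^ε + L_free), with w
the well width and L_free the accessible width outside the well on the
drug's side of the core, is exported as
`equilibrium_well_occupancy()` and is the oracle for occupancy tests.

Defaults are chosen to be physically plausible for a drug-sized solute at
a bilayer: D_bulk = 4×10⁻⁴ nm²/ps (≈ 0.4×10⁻⁵ cm²/s, anthracycline-like),
z_surface = 2.5 nm (head-group plane offset of a fully hydrated
bilayer), well_width = 0.5 nm (head-group interaction region),
core_halfwidth = 1.5 nm (the tail core an unbiased run does not
penetrate), well_depth = 3 kT, box 6.4 × 6.4 × 10 nm, dt = 50 ps (rms
step 0.2 nm), temperature 310 K.

What the generator does **not** emulate: lipid dynamics (beads are
static), explicit water and ions, electrostatics in the dynamics,
lateral drug–lipid coupling, anisotropic friction, and membrane crossing
(the core is impenetrable by design). Consequently, passing tests
demonstrate that the *estimators* are correct on data with known
structure — not that any particular real drug behaves a particular way.
Drug–water hydrogen-bond counting is exercised with static site clouds,
since counting machinery, not solvent dynamics, is what needs testing.
For the same reason, the drug is one bead for dynamics but may carry
rigidly co-moving satellite donor/hydrogen/acceptor/charge sites
(`add_drug_bead`), decoupling integrator simplicity from metric
coverage.

`make_hbond_fixture` constructs donor–hydrogen–acceptor triads on a
2 nm grid (far beyond the 0.35 nm cutoff, so triads cannot cross-bond):
a requested number of true bonds (r in [0.28, 0.34] nm, angle in
[0, 25]°), distance near-misses at exactly 0.36 nm, and angle
near-misses at exactly 35° — the construction, not the detector, fixes
the expected count. `make_residence_fixture` places the drug at 0.25 nm
from the lower leaflet in a prescribed fraction of frames and at 1.5 nm
otherwise, making the residence percentage exact by construction.

## Validation problem sizes

The test suite validates estimators at sizes chosen to make sampling
error small relative to the asserted tolerances while keeping a full run
comfortable on one CPU:

* bulk-diffusivity recovery: 30 independent seeds × 16 000 steps of free
  diffusion, lateral MSD fitted at 0.4–2 % of the window (short lags:
  unbiased and well-averaged); the seed-mean lands within 5 % of truth.
* well-depth recovery: a 10 µs-equivalent run (200 000 × 50 ps) gives
  ~130 well-escape events at 3 kT; Boltzmann inversion of the z
  histogram recovers the depth within 0.3 kT.
* occupancy: a 50 µs-equivalent run at 6 kT is compared with the
  closed-form occupancy within three block standard errors.
* oracle equivalences are exact: minimum-image distances against
  27-image enumeration (10⁴ random pairs drawn inside the primary cell,
  where the 27-image enumeration is the complete image set), and
  hydrogen-bond counts against a brute-force triple loop.

The quickstart pipeline uses well depths 0, 1.5 and 5 kT. These are
chosen from the closed-form occupancy so the three drugs land in
distinct rubric signatures (no marks / second-category marks /
first-category marks on residence and mid-plane proximity), making the
demonstration ranking strict rather than resting on tie-breaks.

## Degenerate inputs and numerical conventions

Empty atom groups are errors naming the offending group, except where a
zero is meaningful: a group with no donors or acceptors yields a zero
bond count with a warning (an analysis question, not a malformed input).
Density and occupancy bins align to multiples of the bin width; the
rightmost bin edge is closed. MSD(0) is identically zero. Spearman rank
correlations use average ranks under ties and require at least three
paired drugs. All randomness flows from explicit seeds; the pipeline
derives a named substream per stage from one root seed, and a rerun with
the same config and seed is bitwise identical.

## Limitations

The rubric is categorical and saturates: two strongly anchored drugs can
tie even when their raw metrics differ, which is faithful to
category-table reasoning but loses resolution — the tidy metrics CSV
retains the raw values for finer comparisons. Hydrogen-bond lifetimes
and kinetics, potential-of-mean-force via biased sampling, and membrane
surface tension are out of scope. Binary trajectory formats (XTC/TRR/
DCD) are not read; convert externally to extended-XYZ. The generator's
validation scope is estimator correctness, as discussed above; no
numeric per-drug value from any real MD study is reproduced or implied.
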