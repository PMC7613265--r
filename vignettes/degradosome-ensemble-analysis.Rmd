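---
title: "Ensemble analysis of flexible membrane-associated assemblies with saxsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis of flexible membrane-associated assemblies with saxsemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsemble)
```

## The scientific problem

The bacterial RNA degradosome is the archetype of an assembly that resists
conventional structure determination: a tetrameric catalytic core (the
N-terminal half of RNase E) from which four long, intrinsically disordered
scaffold tails emanate, each carrying folded partner enzymes (the DEAD-box
helicase RhlB, enolase, and in the full-length complex PNPase) at defined
recruitment microdomains. In solution such a particle is not one structure
but a broad conformational ensemble; bound to a lipid vesicle it forms a
protein shell whose radial extent and stand-off from the membrane are the
measurable quantities. saxsemble implements the quantitative workflow for
characterising this kind of assembly:

1. **Conformer-pool generation** — rigid folded domains joined by sampled
   random-coil linkers, partner enzymes docked as rigid ligands, four
   protomers combined onto a symmetric core (module `conformers`).
2. **Coarse-grained SAXS** — Debye scattering curves per model, plus the
   curve-level analyses: Guinier fit, pair-distance distribution P(r) in
   both directions, normalized Kratky transform, and concentration-series
   merging (module `scattering`).
3. **Ensemble selection** — a genetic algorithm that picks sub-ensembles of
   pool models whose average curve fits a target curve, with the
   entropy-based flexibility metric Rflex and the size-dispersion ratio
   Rsigma (module `ensemble_selection`).
4. **1-D radial density profiles** — shell-averaged density of
   protein-coated vesicles from tomographic volumes, with membrane-peak,
   gap and extension metrics (module `radial_profile`).
5. **Sequence charge analysis** — isoelectric point, charged-residue
   fractions and the Das–Pappu charge-patterning parameter kappa for
   arbitrary sequence regions (module `charge_analysis`).
6. **Synthetic data with planted ground truth** for every stage
   (module `synthetic_data`), which is what makes the whole pipeline
   testable without access to beamline or microscope data.

## Conformer pools

### Model representation

Models are coarse-grained to one bead per residue at the C-alpha position
with unit scattering weight. This keeps a 7,000-bead tetramer pool
desk-scale while preserving everything the downstream ensemble analysis
uses: pairwise distance spectra, radii of gyration, and mutual
distinguishability of conformers. All-atom detail (side chains, hydration
shell, atomic form factors) is deliberately out of scope; because the pool
curves and the synthetic "experimental" curves share the same forward
model, ensemble selection is internally consistent, which is the property
the method actually requires.

### Linker sampling

Flexible segments are grown bead by bead with

* fixed virtual bonds of 3.8 Å (the C-alpha–C-alpha distance of an
  extended peptide),
* bond angles uniform in [75°, 155°] and dihedrals uniform in [−180°, 180°),
* a hard excluded-volume distance of 4.0 Å against every non-adjacent
  linker bead and every previously placed bead of the model,
* whole-linker restarts on dead ends, with an error after 500 restarts.

This is a standard self-avoiding coarse coil model. The bond-angle window
and excluded-volume radius are generic C-alpha-level choices; nothing
downstream is sensitive to their exact values because pool and target
curves always come from the same sampler. The sampler draws from R's RNG,
so `set.seed()` makes pools bit-reproducible; the test suite additionally
checks the mean squared end-to-end distance of a 50-residue linker against
an independent re-implementation of the same rules.

### Clash filtering and tetramer combination

The clash score counts non-adjacent bead pairs closer than 3.0 Å, scaled
per 1000 beads; pairs bonded along a chain are exempt. The default
filtering cutoff of 60 follows the conventional all-atom clashscore
threshold used for pool curation; at the bead level the score plays the
same role (discarding self-intersecting conformers) without claiming
numerical equivalence to an all-atom metric.

Tetramers are assembled by drawing one protomer per pool (uniformly, with
replacement) and docking each onto one of four core transforms — by
default the identity plus the three 2-fold rotations of an idealized D2
core. Combinations whose *inter*-protomer clash score exceeds the cutoff
are resampled, and a rejection rate above 99% is an error rather than an
endless loop. Source indices are recorded per tetramer so every pool
member is traceable to its protomers.

## Scattering

### Debye curves

`debye_intensity()` evaluates `I(q) = sum_ij w_i w_j sinc(q r_ij)`. The
default path bins pair distances into a 0.5 Å histogram and evaluates the
sinc at the *weighted mean distance of each bin*, not the bin center; this
keeps the acceleration second-order accurate in the bin width and within
the 0.5% agreement bound against the exact double sum that the tests
enforce. `I(0) = (sum w)^2` holds exactly by construction. The default
q-grid spans 0–0.3 Å⁻¹ in 101 points, covering the Guinier and Kratky
features of 100–450 Å particles.

### Guinier fitting

The automated fit regresses `ln I` on `q²`, growing the window from the
lowest q and iterating (at most 20 times) until the window is the largest
prefix satisfying `q·Rg <= 1.3`. Points are weighted by `(I/sigma)²` when
uncertainties are present. Two numerical realities are worth knowing:

* For a **solid sphere** the `qRg <= 1.3` window itself biases Rg upward
  by ~1.8% relative to `sqrt(3/5) R` — that is a property of the Guinier
  approximation, not of the fit. The closed-form tests therefore use
  20,000-bead spheres so that Monte Carlo error does not stack on top of
  this intrinsic bias.
* A rising low-q curve (aggregation-like) raises a "no Guinier region"
  error instead of returning a number.

### P(r) in both directions

From a model, `pdist_from_model()` is a unit-area weighted histogram of
pair distances. From a curve, `pdist_from_curve()` solves the regularized
indirect transform: non-negative least squares (Lawson–Hanson, via
pracma) on the sinc design matrix with `p(0) = p(Dmax) = 0` and a
second-difference smoothness penalty. The smoothing weight `alpha`
(default 1) multiplies a penalty block scaled to the Frobenius norm of the
weighted design matrix, so its meaning is stable across problem sizes; no
automatic L-curve search is attempted. The round trip
model → curve → P(r) agrees with the direct histogram to an L1 distance
of 0.05 on noiseless data in the tests.

### Kratky and merging

`normalized_kratky()` is the pointwise transform
`(qRg)² I(q)/I(0)` vs `qRg`; globules peak near `(sqrt(3), 3/e)` and
flexible chains plateau. `merge_curves()` scales every curve of a
concentration series onto the lowest-concentration reference, finds the
crossover q above which all scaled curves agree with the reference within
3 combined sigma, and returns reference data below the crossover with the
inverse-variance average above it — removing low-q structure-factor
distortion while keeping the concentrated samples' high-q statistics.

## Ensemble selection

The genetic algorithm encodes an ensemble as a fixed-length list of L = 20
pool indices with repetition, so multiplicity encodes weight. Each of 10
independent repeats runs 500 generations of: elitism (2 chromosomes),
parent selection, one-point crossover (rate 0.5), and per-slot mutation to
a uniformly random pool index (rate 0.1); fitness is `-chi2` with the
analytic least-squares scale factor. Parent selection draws uniformly from
the **top quartile** of the population: on planted-data landscapes, where
one exact model must be found among hundreds, tournament-of-2 selection
converged an order of magnitude more slowly in our experiments while
truncation selection reaches the noise floor within the default budget.
Ties are broken by stable ordering, and elitism guarantees the best
chi-square is non-increasing within a repeat (asserted in tests every
generation).

Two statistical points shaped the test design:

* With K grid points, the reduced chi-square of the *generating truth
  itself* scatters with standard deviation `sqrt(2/K)` around 1, so no
  fitter can promise `chi2 <= 1.05` on every noise draw. The
  planted-recovery tests therefore require the fit to reach
  `max(1.05, chi2_truth)` — the noise floor of that realization.
* Index-level weight recovery is only meaningful when every pool curve is
  distinguishable at the noise level. The mixture-recovery experiment
  uses a 120-tetramer pool at 0.2% relative noise for exactly that
  reason; the distribution-level check (selected Rg distributions move
  toward the planted one in Wasserstein distance) runs on a 400-tetramer
  pool at 1% noise over 20 seeds.

`rflex()` is the Shannon entropy of the Rg histogram relative to the
maximal entropy, as a percentage: 0% for a single-valued pool, 100% for
equal occupancy of every bin. The default binning (100 bins over the
pool's Rg range) matters for intermediate values but not for the
definitional endpoints, which is why the endpoints are what the package
treats as reference quantities. `rsigma()` is the plain ratio of Rg
standard deviations, ensemble over pool.

## Radial density profiles

`radial_profile()` samples each spherical shell (spacing = one voxel, out
to half the box) at `max(100, 4*pi*r²/voxel²)` deterministic Fibonacci
points with trilinear interpolation, dropping points outside the grid.
`icosahedral_average()` averages over the 60 rotations of the icosahedral
group (generated once by closure from a 2-fold and a 5-fold generator and
memoized), and `axis_rotational_average()` adds fine averaging about
coordinate axes; both leave smooth spherically symmetric volumes unchanged
to ≈1% RMS, the trilinear interpolation error at 8.8 Å voxels. Sharp
voxel-scale edges smear under any interpolating rotation — the tests use
smooth fixtures for the fixed-point checks for that reason.

`profile_metrics()` measures the quantities of interest:

* **baseline**: median of the outer 20% of the radial range (solvent);
* **membrane peak**: first local maximum above half the dynamic range;
* **membrane subtraction**: an asymmetric Gaussian (inner and outer widths
  estimated from the two half-maximum crossings) is fitted to the peak and
  subtracted, because at realistic membrane thicknesses (~40 Å FWHM) the
  membrane tail otherwise bleeds into the protein shell;
* **protein shell**: the residual's outer maximum must reach `frac`
  (default 0.1) of the membrane height to count as present; its edges are
  the interpolated half-maximum crossings of the residual, which locate
  shell boundaries to sub-voxel accuracy;
* **gap** = inner protein edge minus membrane peak radius;
  **extension** = outer minus inner protein edge; **bimodal** is flagged
  when the shell holds two maxima separated by a ≥10% dip.

The gap is measured from the membrane *peak* rather than from a
low-threshold outer edge of the membrane: with a 40 Å-thick membrane the
10% outer edge sits 20–35 Å beyond the peak, which would reduce any
realistic gap to nearly zero and make the metric uninterpretable; the
peak-to-shell convention recovers the generative geometry of the synthetic
volumes within one voxel, which is the recovery the tests demand.
`average_profiles()` aligns profiles on their membrane peaks (at the mean
peak radius) before the pointwise mean and standard deviation, mirroring
the three-vesicle averaging the analysis is designed for; how real
different-radius vesicles are best aligned is genuinely open, and
peak alignment is this package's choice.

## Charge analysis

`net_charge()` and `isoelectric_point()` implement the
Henderson–Hasselbalch sum with the Bjellqvist pKa set, including the
residue-specific N-terminal values and the shifted C-terminal pKas for
aspartate/glutamate — the same constants the ProtParam tool uses, which
the tests pin against frozen ProtParam reference values. One consequence
worth noting: because terminal residues carry their own pKas, the pI of a
two-residue sequence is *not* invariant under swapping the termini;
composition-only invariance holds once the termini are fixed.

`charge_fractions()` counts K/R as positive and D/E as negative, excluding
histidine — the convention of the charge-patterning literature — while
histidine remains ionizable for the pI. `kappa_metrics()` computes the
Das–Pappu patterning parameter over blob sizes 5 and 6 (windows fully
inside the sequence, zero-charge windows contributing zero asymmetry). The
normalizing `delta_max` is found by a deterministic search over
block-segregated arrangements of the same composition: all neutral-spacer
splits around contiguous charge blocks, *plus* arrangements that split one
charge species across both sequence ends. The end-split family matters:
for short sequences the window average under-samples the termini and the
true maximum is often attained by, for example, `+0000+` rather than
`++0000`. With it, the deterministic search matches exhaustive enumeration
over every composition up to length 10 exactly (verified to 1e-12), which
is the basis of the exhaustive-oracle tests.

`region_report()` tabulates all metrics per region and classifies each on
the (f+, f−) diagram of states (weak polyampholyte, boundary, strong
polyampholyte, strong polyelectrolytes). Region bounds beyond the sequence
are clamped with a warning rather than rejected, since published region
tables occasionally overrun the true sequence length by a residue or two.

## Synthetic data: what it emulates and what it does not

`make_domain_templates("core_tetramer")` builds a desk-scale protomer: an
off-center core ball (so the four D2 copies form a compact tetramer), a
~320-residue scaffold of four linkers interrupted by three small rigid
microdomains (a membrane-anchor rod and the helicase- and enolase-binding
sites), and two ligand balls docked at the binding microdomains. The
scaffold length matches the layout scale of the RNase E C-terminal half;
the bead counts (60-bead core, 20-bead ligands by default) are an order of
magnitude below residue-true sizes to keep pool generation fast. Ball
templates place beads with a 3.5 Å minimum separation so the templates
are clash-free by construction.

`make_planted_experiment()` mixes chosen pool curves and adds Gaussian
noise with `sigma(q) = noise * sqrt(I(q) I(0))` — the shape of counting
statistics, with `sigma/I = noise` at q = 0 (default 1%, a typical
good-quality SEC-SAXS level). At `noise = 0` the target is the exact
mixture with a nominal uncertainty column, so a zero-noise chi-square is
exactly zero. `make_liposome_volume()` builds a Gaussian membrane shell
(default radius 100 Å, 40 Å FWHM — a typical bilayer) plus a uniform
protein shell from gap (30 Å) to gap + extent (140 Å), in an 80³ box of
8.8 Å voxels (leaving a generous solvent margin for baseline estimation),
with optional sub-unity angular occupancy (Bernoulli voxel mask — a crude
granularity model, not a particle model) and white noise.

What passing these tests shows: the estimators recover the parameters of
data generated by their own forward models, at realistic noise, and agree
with independent brute-force implementations where those exist. What they
cannot show: fidelity to hydration-layer scattering, detector effects,
missing-wedge and CTF artifacts of real tomograms, or the torsional
statistics of any specific disordered sequence. Real-data conclusions
inherit those caveats.

## Problem sizes and runtimes

The test suite and reference scripts run at deliberately desk-scale sizes:
protomer pools of 40 models per component, tetramer pools of 120–400
models, GA budgets of 100 × 500 × 10 (population × generations ×
repeats), 20,000-bead spheres for closed-form checks, 80³ volumes, and 50
noise seeds for the recovery studies. The paper-scale numbers (20,000
protomers per pool, 10⁶ tetramers) are reachable with the same calls —
pool generation and curve computation scale linearly in models and
quadratically in beads per model — but are not exercised by the tests.

## Known limitations

* Ligand orientations are fixed by their dock transforms, not re-sampled
  per conformer; rigid-domain orientations after a linker are sampled but
  only lightly clash-screened (the pool filter does the real curation).
* The indirect P(r) transform uses a fixed default smoothing weight; no
  automatic regularization selection.
* The clash score is a bead-overlap count, not an all-atom clashscore;
  the shared threshold of 60 is a convention, not an equivalence.
* Rflex values between the endpoints depend on the binning choice (100
  bins over the pool range by default); comparisons are only meaningful
  at fixed binning.
* `kappa` follows the blob-window definition with deterministic
  `delta_max` search; other published implementations differ in terminal
  window handling at the ~0.01 level.
* The CLI (`run_cli()`, `inst/scripts/saxsemble`) is a thin wrapper for
  scripting convenience; the R functions are the primary interface.
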