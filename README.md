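# saxsemble

Ensemble analysis of flexible multidomain assemblies: conformer-pool
generation, coarse-grained SAXS, genetic-algorithm ensemble selection,
tomographic radial density profiles, and sequence charge patterning — with
a synthetic-data module that plants known ground truth into every stage.

## Who this is for

Structural biologists working on assemblies that are ensembles rather than
structures: a folded oligomeric core with long intrinsically disordered
tails carrying partner proteins, of which the *E. coli* RNA degradosome
(tetrameric RNase E core + disordered C-terminal scaffold binding RhlB,
enolase and PNPase) is the motivating example. For such particles the
informative quantities are distributions and profiles, not coordinates:

* the **pair-distance distribution** P(r) and **Dmax** from SAXS;
* the **normalized Kratky plot** `(qRg)^2 I(q)/I(0)` vs `qRg`, which
  separates globules (peak near `(sqrt(3), 3/e)`) from flexible chains
  (rising plateau);
* **ensemble optimization**: a genetic algorithm selecting L-member
  sub-ensembles of a random conformer pool whose average Debye curve
  `I(q) = sum_ij w_i w_j sinc(q r_ij)` fits the measured curve, scored by
  `chi2 = sum_k ((mu I_t - I_e)/sigma)^2 / (K-1)` with the analytic scale
  `mu`;
* flexibility metrics **Rflex** (entropy of the Rg histogram relative to
  maximal entropy, 0% rigid to 100% maximally flexible) and **Rsigma**
  (ensemble/pool Rg standard-deviation ratio);
* the **1-D radial density profile** of protein-coated vesicles, with
  membrane peak, membrane-to-protein **gap** and protein **extension**;
* charge metrics per sequence region: **pI** (Bjellqvist/ProtParam pKa
  set), **FCR/NCPR** and the Das–Pappu patterning parameter
  **kappa = delta/delta_max** over 5–6-residue blobs.

## Worked example

Build a desk-scale tetramer pool (rigid cores and ligand balls, sampled
random-coil linkers), plant a 50/50 compact/extended mixture with 0.2%
noise, and ask the genetic algorithm to recover it:

```r
library(saxsemble)

tpl   <- make_domain_templates("core_tetramer", radius = 12, n_beads = 60, seed = 3)
pools <- lapply(1:4, function(k)
  generate_pool(tpl$blueprint, tpl$domains, n = 40, seed = 100 + k))
tet   <- combine_tetramers(pools, tpl$tetramer, n = 120, seed = 7)
tet   <- compute_pool_curves(tet)
tet
#> conformer_pool: 120 models, Rg 63.3-135.8 A, Dmax 219.9-430.6 A, curves computed

compact  <- which.min(tet$rg)
extended <- which.max(tet$rg)
exp1 <- make_planted_experiment(tet, setNames(c(0.5, 0.5), c(compact, extended)),
                                noise = 0.002, seed = 42)
fit <- gajoe(tet, exp1$target, ga_config(repeats = 10, seed = 43))
fit
#> ensemble_fit: chi2 = 1.072, mu = 1.001, 2 distinct models over 20 slots (10 repeats)
fit$distinct_models
#>   index weight
#> 1    25    0.5
#> 2    88    0.5
flex_metrics(tet, fit)
#> flex_metrics: Rflex(ensemble) = 26.37%, Rflex(pool) = 85.79%, Rsigma = 2.396
```

The fit lands on the two planted models (88 is the most compact conformer,
25 the most extended) at exactly half weight each, with chi-square at the
noise floor. The ensemble Rflex far below the pool Rflex says the selected
ensemble is much narrower than the random pool — as it should be for a
two-state truth — while Rsigma > 1 reflects that the two survivors sit at
the extreme ends of the pool's size range.

The same pattern holds for the other stages — every generator returns its
ground truth alongside the data:

```r
lip <- make_liposome_volume(noise_sd = 0.5, seed = 11)   # truth: 100 / 30 / 140 A
profile_metrics(radial_profile(lip$vol, "auto"))
#> profile_metrics: membrane peak 96.8 A, gap 35.2 A, extension 137.3 A

s <- make_patterned_sequence(60, fplus = 0.25, fminus = 0.15, "random", seed = 1)
kappa_metrics(s)
#> charge_metrics: kappa = 0.175 (delta 0.06083 / delta_max 0.3475), FCR 0.400, NCPR +0.100
```

All three vesicle metrics are recovered within one 8.8 Å voxel of the
construction, and the charge fractions are exact by construction.

A thin command-line layer (`inst/scripts/saxsemble`, or `run_cli()` from
R) exposes the stages as subcommands (`simulate`, `generate-pool`,
`guinier`, `pofr`, `kratky`, `merge`, `fit-ensemble`, `rdp`, `charge`) and
writes a JSON manifest per run. See
`vignettes/degradosome-ensemble-analysis.Rmd` for the models, parameter
choices and limitations.

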