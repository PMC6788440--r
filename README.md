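# elevdiv

Analysis of small non-volant mammal communities live-trapped along
tropical elevational gradients, built around the two-mountain survey of
Mt. Kinabalu (trapped 503–3,466 m) and Mt. Tambuyukon (331–2,509 m) in
Borneo. The package is for community ecologists who have capture-level
trap data (one row per animal: species, mountain, trapping location,
elevation, trap class, recapture flag) plus per-location trap-night
totals and per-species endemic status, and who want the standard
gradient analyses as tested, reproducible code:

* **Survey accounting** — filtering to the ground-trap community of
  first captures, trap success (captures per 100 trap nights), species
  accumulation curves, camera-trap relative abundance.
* **Alpha diversity** — per site: richness *S*, Shannon
  *H′* = −Σ pᵢ ln pᵢ, Simpson *D* = 1 − Σ pᵢ², Pielou *J′* = *H′*/ln *S*.
* **Mid-domain-effect (MDE) null model** — species ranges discretized
  into 50 m elevational bands and shuffled (soft or hard boundaries,
  5,000 reps) to get the richness envelope expected from geometric
  constraints alone, against which observed richness is classified.
* **Beta diversity** — Sorensen dissimilarity partitioned into turnover
  and nestedness, pairwise (β_sim = min(b,c)/(a+min(b,c)),
  β_sor = (b+c)/(2a+b+c), β_sne = β_sor − β_sim) and multiple-site
  (β_SIM, β_SNE, β_SOR), with neighbor-joining clustering of sites and
  Newick export.
* **Endemism** — per-site endemic proportions (species and captures)
  with 1,000-rep bootstrap envelopes, and a 5,000-rep endemic-removal
  permutation test: are endemics the species driving turnover?
* **Synthetic surveys** — a generator with known ground truth
  (declining richness, elevation-correlated endemism, uneven abundances,
  Bernoulli detection over trap nights) so every stage is testable
  without field data, plus an end-to-end pipeline (`runPipeline()`) with
  seeds, tidy outputs and a manifest.

## Worked example

Trap-success accounting over the published per-location totals:

```r
library(elevdiv)
ds <- filterRecords(studySurveyFromTables())   # drop arboreal/pitfall
trapSuccess(ds, groupBy = "mountain")
#>        group   mountain n_captures trap_nights percent percent_raw
#> 1   Kinabalu   Kinabalu        209        2022    10.3   10.336301
#> 2 Tambuyukon Tambuyukon        295        5957     5.0    4.952157
```

209 animals over 2,022 ground-trap nights is a 10.3% trap success on
Mt. Kinabalu — roughly twice Mt. Tambuyukon's 5.0%.

A full synthetic analysis with known truth:

```r
sim <- simulateSurvey(paperlikePreset())       # 2 mountains, 23 species
fds <- filterRecords(sim$dataset)
cm  <- buildAbundanceMatrix(fds)
diversityProfile(cm)[1:6, c("site", "elevation", "S", "H", "D", "J")]
#>            site elevation  S        H         D         J
#> 1  MountA / 500       500 12 2.266706 0.8777701 0.9121894
#> 2 MountA / 1040      1040 10 2.153025 0.8727778 0.9350469
#> 3 MountA / 1580      1580  7 1.853859 0.8316127 0.9526949
#> 4 MountA / 2120      2120  6 1.508360 0.7277051 0.8418319
#> 5 MountA / 2660      2660  5 1.507306 0.7530864 0.9365421
#> 6 MountA / 3200      3200  5 1.459482 0.7377778 0.9068271

multisitePartition(subsetMountain(cm, "MountA"))
#> BetaPartition (multisite, 6 sites): sor = 0.7734 = sim 0.6974 + sne 0.0760

endemicRemovalTest(subsetMountain(cm, "MountA"), speciesMeta(fds),
                   reps = 5000, seed = 20120602)
#> EndemicRemovalResult 'MountA': 12-species null subsets, 5000 reps
#>   observed (endemics removed): sim = 0.222, sne = 0.389, sor = 0.611
#>   p_sim = 0.0002 (le), p_sne = 0.0007998 (ge)
```

Richness declines monotonically with elevation (12 → 5 species); most
of the mountain's beta diversity (β_SOR = 0.77) is turnover
(β_SIM = 0.70), and removing the endemic species collapses turnover to
0.22 — far below any of 5,000 equal-size random species subsets
(p = 0.0002, `le` = decrease) — so the high-elevation endemics are the
species being replaced along the gradient.

A command-line wrapper with verbs `simulate`, `summarize`, `alpha`,
`mde`, `beta`, `endemism`, `all` ships at `inst/scripts/elevdiv.R`.

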