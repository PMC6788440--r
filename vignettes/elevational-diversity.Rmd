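---
title: "Methods: small-mammal diversity along elevational gradients"
author: "elevdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-mammal diversity along elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevdiv)
```

## The problem

Tropical mountains compress large environmental gradients into small
spatial scales, which makes them natural experiments for biogeography.
For small non-volant mammals (treeshrews, rats, squirrels, gymnures)
surveyed by live-trapping along two neighbouring Bornean peaks
(Mt. Kinabalu, 4,095 m, trapped 503–3,466 m; Mt. Tambuyukon, 2,579 m,
trapped 331–2,509 m), three questions structure the analysis this package
implements:

1. **Alpha diversity.** How do species richness *S*, Shannon *H′*,
   Simpson *D* and Pielou *J′* change with elevation, and does the
   richness profile depart from the *mid-domain effect* (MDE) — the null
   expectation that randomly placed ranges inside a bounded domain
   overlap most at its centre?
2. **Beta diversity.** Is compositional change between trapping locations
   driven by species *turnover* (replacement) or by *nestedness*
   (poorer assemblages being subsets of richer ones)?
3. **Endemism.** Does the proportion of Borneo-endemic species (and of
   captures belonging to them) rise with elevation, and are endemics the
   species responsible for the turnover signal?

## Survey data model

A `SurveyDataset` couples capture-level records (species, mountain,
trapping location, elevation in metres, trap class, recapture flag,
optional capture day) with per-location trap-night totals by trap class
and per-species metadata carrying the endemic status
(`endemic`/`non_endemic`/`unknown`). Analyses run on the *ground-trap
community of first captures*: `filterRecords()` drops arboreal (traps
above ~3 m) and pitfall captures together with their trap nights, and
recaptured individuals, recording every filter in a provenance log.
Species identified only to genus (shrews such as *Suncus* sp.) are legal
species entries with endemic status `unknown`; they take part in
diversity calculations but are excluded — from numerator *and*
denominator — everywhere endemism is quantified.

Trap success, the survey's relative-abundance proxy, is
`100 × captures / trap nights`, reported rounded half-up to one decimal
(the unrounded value is retained); camera rates use two decimals per 100
camera nights. Reported percentages must recompute exactly from their own
printed numerator and denominator, and the test suite enforces this
internal consistency on every output row.

`buildAbundanceMatrix()` cross-tabulates records into a `CommunityMatrix`
(sites × species counts). Sites are ordered by mountain, then nominal
elevation ascending, then label, which makes every downstream output
deterministic. The nominal site elevation is the numeric trapping-location
label where one exists, otherwise the median capture elevation.

## Alpha diversity

For a site with relative abundances \(p_i\):
\[H' = -\sum_i p_i \ln p_i, \qquad D = 1 - \sum_i p_i^2, \qquad
J' = H'/\ln S .\]
Natural logarithms are the default (a config option), matching the
community-ecology convention; \(0\ln 0 \equiv 0\). Simpson's index is the
complement ("diversity") form rising with evenness — the inverse form
\(1/\sum p_i^2\) sits behind a flag. *J′* is undefined for \(S \le 1\)
and the package signals this rather than returning a silent 0; an empty
site is flagged with `NA` indices. These conventions were genuinely open
(neither the log base nor the Simpson variant is forced by the survey
outputs); both choices are recorded here as assumptions and both
alternatives remain callable.

## The mid-domain-effect null

`discretizeRanges()` tiles each mountain's trapped extent into 50 m bands
(band *k* covers `[min + (k−1)·50, min + k·50)`, 1-based, top band
closed) and assigns each species the contiguous band run from its lowest
to its highest capture — interpolation justified by the survey's design,
in which species were recorded at essentially all sites between their
extreme occurrences. `rangeShuffle()` then builds the null: each of
`reps` replicates (default 5,000) keeps every observed range *size* and
draws a uniformly random position:

* **soft boundaries** (default): the midpoint band is uniform over all
  bands; the range extends half its size each way and is truncated where
  it overshoots the domain, so a species may occupy fewer bands than its
  size near an edge. For even sizes the odd band goes uphill or downhill
  by a fair coin per placement.
* **hard boundaries**: the whole range must fit; its start band is
  uniform over the feasible positions, and a range wider than the domain
  is an error.

One consequence worth stating: under soft boundaries even a species whose
range size equals the whole domain does *not* occupy every band in every
replicate (an edge-hugging midpoint truncates it), so the degenerate
"full-domain range ⇒ flat envelope of 1" identity holds under hard
boundaries only. This follows directly from the truncation semantics
above and is asserted that way in the tests.

Envelopes are per-band means with 2.5%/97.5% percentiles (linear
interpolation between order statistics). `compareObserved()` maps each
site's nominal elevation to its band and classifies observed richness
against the **closed** envelope interval — a value exactly on a
percentile is `"within"`. The mapping from six trapping locations onto
50 m band expectations is thereby explicit rather than implicit in a
plotting routine. Monte-Carlo band means are validated against exact
enumeration over all placements on small domains, and hard-boundary
placement conserves total band-incidences exactly (the summed mean
richness equals the summed range sizes).

## Beta diversity

With `a` species shared by two sites and `b`, `c` exclusive to each,
the Sorensen-family pairwise partition is
\[\beta_{sim} = \frac{\min(b,c)}{a+\min(b,c)}, \qquad
\beta_{sor} = \frac{b+c}{2a+b+c}, \qquad
\beta_{sne} = \beta_{sor}-\beta_{sim},\]
and the multiple-site version, with \(S_i\) site richness, \(S_T\) pooled
richness and \(b_{ij}\) the species of site *i* absent from *j*:
\[\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
 {\sum_i S_i - S_T + \sum_{i<j}\min(b_{ij},b_{ji})},\qquad
\beta_{SOR} = \frac{\sum\min + \sum\max}
 {2(\sum_i S_i - S_T) + \sum\min + \sum\max}.\]
Additivity \(\beta_{sor} = \beta_{sim} + \beta_{sne}\) holds to
\(10^{-12}\) and is property-tested on random incidence matrices; for two
sites the multiple-site and pairwise forms coincide. A pair of two empty
sites is *undefined* and reported `NA`, never 0 — a silent zero would
corrupt the clustering input. Empty sites are excluded from the
multiple-site computation with a warning.

Sites are clustered by neighbor-joining on the pairwise \(\beta_{sor}\)
matrix (any component is selectable; the survey outputs do not pin down
which distance fed the original clustering, so the total dissimilarity is
the default). The NJ implementation minimizes the standard Q criterion
with deterministic tie-breaking by the lexicographic order of the joined
clusters' smallest leaf labels — equidistant inputs therefore yield
label-ordered cherries — and clamps negative branch lengths to zero with
a warning, retaining the raw tree in an attribute. On additive inputs it
recovers the generating topology and branch lengths exactly (tested
against random 4–8 leaf trees and against an independent implementation).

## Endemism

`endemismProfile()` reports, per site, the proportion of endemic species
and the proportion of captures belonging to endemics, over classified
species only. `bootstrapEnvelope()` resamples — with replacement, at the
original size — either the site's classified species list (default, the
unit used for the published envelope) or its classified capture records
(the resampling unit for the capture proportion is not pinned down by the
survey outputs, so it is configurable and logged), and reports 2.5%/97.5%
percentile envelopes; 1,000 replicates by default. Exact-coverage
calculations for binomial sites put the percentile envelope's coverage
near 95% (≈ 0.96 at 40 classified species), and the Monte-Carlo coverage
is tested against that oracle.

`endemicRemovalTest()` asks whether endemics drive the partition:
the observed statistic is the multiple-site partition of the non-endemic
submatrix; the null re-draws, 5,000 times without replacement, a species
subset of the same size from the mountain's classified pool and
recomputes the partition. Unknown-status species can never enter a null
subset; mountains are tested independently, each subset drawn from that
mountain's own species (the plausible reading of the original design —
the alternative, a pooled cross-mountain pool, would mix communities the
test is meant to keep apart). Empirical p-values carry the add-one
correction \(p = (\#\{\text{null} \le \text{obs}\}+1)/(R+1)\), one-tailed
with the tail chosen by the sign of (observed − full-matrix component);
two-tailed doubling is a flag away.

A calibration subtlety: the *sign-adaptive* p-value just described is not
uniform under a label-randomized null — choosing the tail from the data
folds both tails onto small values. The p-value for a *pre-specified*
direction (e.g., "turnover decreases when endemics are removed", the
direction of scientific interest) is uniform, and `permutationP()`
extracts it from the stored null distribution. The calibration tests
(Kolmogorov–Smirnov over 200 label-randomized simulations) therefore
check the fixed-direction p-value; the threshold combines the KS critical
value at α = 0.01 with the lattice width of the add-one support.

## The synthetic generator

`simulateSurvey()` provides ground truth for every pipeline stage.
Species niches are contiguous elevational intervals on the *biological*
domain — sea level to the highest summit, not merely the trapped extent,
so lowland species can (as in reality) centre their ranges below the
lowest transect. Range sizes are truncated-normal in 50 m bands (mean 26,
sd 10 ≈ 1,300 ± 500 m). Midpoints are drawn with exponentially
elevation-decaying weight whose decay rate is solved numerically so that
the least-squares slope of the analytic expected-richness profile across
the trapped extent equals `richnessSlope` (default −4 species per
1,000 m, echoing the observed decline from ~19 lowland species to ~7 at
the top); `richnessSlope = 0` recovers uniform midpoints. A species is
endemic with logit-linear probability in its range midpoint (intercept
−5.5, slope 4.5 per 1,000 m: P(endemic) ≈ 0.04 at 500 m and ≈ 0.92 at
2,000 m, matching high-elevation communities composed mainly of
endemics).

Abundances combine geometric dominance weights (ratio 0.92 across the
23-species pool) with log-normal site effects (sd 0.25); available
individuals per in-range species are Poisson (mean 34 before weights).
Detection is a per-trap-night Bernoulli per available individual —
40 traps over 10 nights per location (400 trap nights, near the real
per-location effort) with per-trap-night probability 0.001 — simple, but
sufficient to produce realistic saturation in accumulation curves, and
captured individuals may yield one later recapture record so the
recapture filter is exercised. Under these defaults total captures per
mountain fall in roughly 150–450 across seeds (a 100-seed calibration run
gave 153–422, mean 270), bracketing the real surveys' 209–299.

What the generator does **not** emulate: spatially explicit trap
placement and micro-habitat heterogeneity; inter-annual or seasonal
effects; a single hyper-dominant species (the real survey's most-caught
species took 35.7% of captures — the geometric weights are milder);
identification uncertainty (all synthetic species are classified);
camera traps. Tests passing on synthetic surveys therefore validate the
statistical machinery and its calibration, not robustness to those
field realities.

## Numerical choices

* Percent rounding half-up (1 decimal trap success, 2 decimals camera
  rates); unrounded values retained alongside.
* Percentiles everywhere by linear interpolation between order statistics
  (R type 7).
* Bands are 1-based half-open intervals; the domain maximum falls in the
  top band.
* Every stochastic operation takes a mandatory seed and is reproducible
  from it; the pipeline derives per-stage seeds from one base seed and
  writes them to its manifest.
* NJ ties break by label order; envelope classification uses closed
  intervals; `0·ln 0 ≡ 0`.

## Problem sizes in the test suite

The suite exercises: additivity on 1,000 random incidence matrices;
NJ recovery on random 4–8 leaf trees; MDE enumeration oracles on ≤ 8-band
domains at 6,000–8,000 replicates; permutation-p uniformity over 200
label-randomized datasets at 99 permutations; bootstrap coverage over 200
binomial sites at 400–500 replicates; and parameter recovery over 50
generator seeds at 499 permutations per mountain — sizes chosen so the
Monte-Carlo error of each check sits well inside its assertion tolerance.

## Known limitations

* The mixed-effects model fits relating richness and endemism to
  elevation (LME with spatial autocorrelation; binomial GLMM with a
  mountain random intercept) are deliberately out of scope: the package
  exports tidy per-site tables (`diversityProfile()`,
  `endemismProfile()`) ready for `nlme`/`lme4`.
* LOWESS smoothing and figure rendering are left to the caller.
* Rarefaction/extrapolation richness estimators are not provided; raw
  accumulation curves are.
* The camera-2/3 night totals in the published camera table are
  ambiguous; their recomputed rates are not treated as ground truth.
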