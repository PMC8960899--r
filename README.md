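# dialectscope

Zebra finch song is famously individual-specific, and for decades the
consensus was that this individuality precludes population-level "dialects".
Yet when captive populations that have been isolated for many generations are
mixed, birds pair assortatively by the population they were *reared* in —
as if they can hear a group signature that standard acoustic measurements
miss. `dialectscope` is a simulation-and-analysis toolkit for studying this
phenomenon end to end:

* a **synthetic colony generator** — populations with divergent
  syllable-prototype pools, cultural transmission of motifs from foster
  fathers with per-syllable innovation, cross-fostering designs that decouple
  genetic origin from rearing culture, rendered WAV song recordings,
  automated-tracking fixes, and dyadic interaction counts, all with known
  ground truth;
* a **dialect classifier** — spectral summary features on 1-s sliding windows
  (50% overlap), a ridge-regularized logistic discriminant, recording-level
  confidence averaging over a 4.5-s trim, with generation-crossed train/test
  splits and a negative control;
* a **motif-similarity surrogate** — per-frame feature trajectories aligned
  by banded dynamic time warping, mapped to a 0–100 score, with "super-motif"
  concatenation for group references;
* **proximity-network analysis** — daily mean dyadic distances from tracking
  fixes, nearest-opposite-sex assignment, weighted categorical assortativity
  with a node-label permutation test, and daily assortment series;
* **pair-bond calling** — a zero-truncated Poisson background model with a
  tail-ratio "clear deviation" cutoff rule (and the fixed cutoff of 5 used as
  the headline rule), plus exact binomial assortment tests;
* **hypothesis comparison** — expected 4×4 pair-type matrices under innate
  preference (H1), morphotype imprinting (H2), song imprinting (H3), and a
  wild-prefers-domesticated pattern (H1W); Pearson correlations with observed
  matrices; simplex-grid mixtures; and a crossed-random-effects model of
  daily dyadic distances.

## The statistics at the core

Categorical (Newman) assortativity of a weighted network with mixing matrix
`e` (undirected edges counted once in each orientation, margins `a`):

    r = (Σ_i e_ii − Σ_i a_i²) / (1 − Σ_i a_i²)

with significance from permuting node labels (p = proportion of permuted
coefficients larger than observed; the add-one conservative variant is
co-reported). Pair bonds are counts `c ≥ cutoff`, where the background is
zero-truncated Poisson, `P(X = k) = e^{−λ} λ^k / (k!(1 − e^{−λ}))`, fitted by
solving the mean equation `m = λ/(1 − e^{−λ})`. Assortment proportions are
tested against a 50:50 null with the exact two-tailed (minimum-likelihood)
binomial test.

## Worked example

A desk-scale run of the full chain — one 80-bird cross-fostered aviary,
15 tracking days of 0.5 h each, pure song-imprinting (H3) mate choice
ramping in over the experiment:

```r
library(dialectscope)
res <- run_pipeline(pipeline_config(
  seed = 11, stages = c("world", "tracking", "distances", "pairs",
                        "hypotheses")))

res$assortment
#> 41/43 pairs assortative by rearing_pop (95%), exact binomial p = 2.153e-10
res$assort_perm
#> assortativity r = 0.051 (rearing_pop), p_perm = 0 (conservative 9.999e-05,
#> 10000 permutations)
round(res$hyp_correlations, 2)
#>    H1    H2    H3   H1W
#> -0.07 -0.10  0.97  0.07
res$distance_model$fixed[term == "H3"]
#>    term   estimate         se         t   ci_lower   ci_upper            p
#> 1:   H3 -0.2434585 0.03881337 -6.272543 -0.3195313 -0.1673857 3.551991e-10
```

Reading the output: 95% of called pair bonds share the rearing population
(binomial p ≪ 0.001 against 50:50); the proximity network is significantly
assortative by rearing culture; the observed 4×4 pairing matrix correlates
almost perfectly with the song-imprinting expectation (and with no other
hypothesis); and daily male–female distances are shorter for dyads sharing a
song dialect (negative H3 coefficient, in standardized ln-mm units). The
daily series in `res$series_between` shows the assortment rising from ~0 to
~0.26 as the preference ramps in, while same-sex networks stay mixed —
the signature of mate choice rather than general gregariousness.

## Scope notes

Song synthesis aims at spectral fidelity to latent syllable parameters, not
acoustic realism; similarity scores are comparable within this package only;
and the headline numbers of the original study (pairwise classification
successes of 0.85–0.97, observed matrix correlations, fitted coefficients)
depend on its deposited recordings and tracking data, which this package does
not consume. See the methods vignette (`vignettes/cryptic-dialects.Rmd`) for
the model, parameter choices, and limitations.
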