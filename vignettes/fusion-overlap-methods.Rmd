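---
title: "Search overlap and precision in fused virtual screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Search overlap and precision in fused virtual screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionoverlap)
library(dplyr)
```

## The question the package addresses

Ligand-based virtual screening ranks a database of molecules by fingerprint
similarity to one or more known actives and keeps the top of the ranking.
Practitioners rarely trust a single ranking: *similarity fusion* (SF) searches
one reference structure with many similarity measures, and *group fusion*
(GF) searches many reference structures with one measure. Either way, every
database molecule ends up with an integer count — how many of the `n`
searches retrieved it — and two statistics summarize the battery:

- **search overlap** `O_s`: the number of distinct molecules retrieved by
  exactly `s` of the `n` searches, and
- **search precision** `P_s`: the percentage of molecules retrieved exactly
  `s` times that belong to the target activity class.

Empirically, `O_s` falls off as a power law in `s` — most molecules are found
by a single search, very few by many — while `P_s` rises with `s` (SF) or
rises to a peak and falls again (GF). The package implements the machinery to
measure these profiles, to compare them against a binomial
"retrieval-at-random" null, to fit power-law and competing trends, and to
explain the power law with a preferential-attachment generative model.

## Similarity searching

Molecules are binary fingerprints of fixed length `L`. For two fingerprints
the contingency counts `a` (on in both), `b`, `c` (on in one only) and `d`
(off in both) define the five supported coefficients: Tanimoto `a/(a+b+c)`,
Cosine `a/sqrt((a+b)(a+c))`, Forbes `n·a/((a+b)(a+c))`, Russell–Rao `a/n` and
Simple Match `(a+d)/n`. Scores are used for ranking only. Two numerical
conventions are fixed here because batch searches must never crash on
degenerate inputs: an all-zero pair has Tanimoto 0, and Cosine/Forbes are 0
whenever either fingerprint is empty — empty fingerprints rank last. Ties at
the cutoff boundary are broken by ascending molecule id, making every
ranking a deterministic total order; the top fraction keeps
`floor(fraction · M)` molecules (at least one). References stay in the
database and may retrieve themselves; self-retrieval inflates every method
equally and so cancels from all comparisons between methods.

## The synthetic database generator

The analyses were designed against large proprietary screening databases
that cannot be redistributed, so the package generates synthetic databases
with the three structural features the statistics actually depend on:

1. **Activity classes of controllable homogeneity.** Each class has a random
   centroid; each member corrupts centroid bits with probability
   `noise_rate`, a corrupted bit being redrawn from the background density.
   Corruption (rather than symmetric bit-flipping) keeps the expected on-bit
   density constant across noise levels, so the class homogeneity — the mean
   pairwise Tanimoto over all member pairs — decreases cleanly as
   `noise_rate` grows instead of being confounded by a density shift.
2. **Scaffold clusters.** Each class is partitioned into `n_scaffolds`
   clusters; a cluster shares a sub-centroid drawn at half the class noise
   rate, so scaffold structure is coarser than molecule structure and
   scaffold-level overlap profiles fall off faster than molecule-level ones.
   Inactives carry singleton scaffold ids.
3. **Correlated fingerprint views.** Each molecule has `V` fingerprint
   views standing in for distinct fingerprint types. A view copies a
   `view_correlation` fraction of bit positions from the molecule's master
   fingerprint and redraws the remaining positions from the molecule's own
   latent bit model under a per-view stream. A pure per-view permutation of
   bit positions would be useless here: applying the same permutation to
   every molecule leaves all pairwise contingency tables — and therefore all
   rankings — exactly unchanged, and the search battery would degenerate to
   `n` copies of one search. Redrawing from the latent model keeps each
   view's class structure intact while making the views rank molecules
   genuinely differently, which is the property the fusion experiments need.

Inactive on-bit densities are drawn per molecule from a Beta distribution
with mean `background_density` and concentration `background_concentration`
(`Inf` recovers a fixed density). The spread matters: real molecules vary
widely in fingerprint bit count, and dense molecules are mildly similar to
everything, acting as promiscuous retrievers that recur across searches —
the population that keeps high-agreement buckets from being trivially pure.
An optional `scaffold_spread` parameter decouples the scaffold sub-centroid
distance from the member noise (its default stays at half the noise rate),
allowing multi-chemotype classes with no common core.

The default specification (`default_database_spec()`) uses 20,000 molecules,
five 512-bit views at correlation 0.6, background density 0.1 at
concentration 40, and eleven classes of 100–600 actives whose noise rates
span 0.15–0.45. These sizes keep one class at 0.5–3% of the database — the
sparse-actives regime of real screening files — while staying desk-scale;
the view correlation of 0.6 encodes the premise that the fused measures are
"similar but not identical". The noise span was chosen, after exploring the
generator's regimes, so that class homogeneities (roughly 0.13–0.35 mean
pairwise Tanimoto) sit modestly above the background similarity level
(about 0.05): that is the regime in which a top-1%/top-5% cutoff retrieves
classes *partially* — the precondition for any precision-vs-agreement
structure. Much tighter classes are retrieved wholesale by every search and
all profiles degenerate to 0-or-100 precision. The class homogeneities of
the source databases were never published numerically (only their rank
order), so the levels are free parameters chosen once here. All randomness
derives from one master seed with fixed substream offsets per stage, class
and view; classes are generated in sorted id order so a reordered
specification yields the identical database.

What the generator does **not** emulate: real fingerprint bit correlations
(substructure bits co-occur), heavy-tailed molecule "popularity" (some
scaffolds dominate real files), and chemically meaningful scaffold overlap
across classes. Tests passing on synthetic data therefore validate the
*statistical machinery* — counting, profiling, fitting, the null, the
generative model — not any claim about a particular chemistry space.

## Experiment drivers

`run_similarity_fusion()` searches one reference with a battery of
(view, coefficient) measures — the full crossing of 5 views and 5
coefficients gives the classical 25-measure SF battery.
`run_group_fusion()` searches many references with one measure.
`run_replicated_experiment()` repeats either protocol with fresh random
reference draws (without replacement within a replicate, independent across
replicates) and profiles are averaged element-wise across replicates;
precision is averaged only over replicates where the bucket is defined,
because a 0/0 bucket is missing information, not zero precision.

Two identities hold by construction and are asserted throughout the tests:
`sum(s · O_s) = n · cutoff_count` (conservation of retrieval instances) and
invariance of the counts under permutation of the searches.

## The binomial null

If each search retrieved uniformly at random with per-molecule probability
`p`, the expected overlap profile would be
`E[O_s] = M · choose(n, s) · p^s (1−p)^(n−s)`, summing to `M` exactly over
`s = 0..n`. Two readings of a "top-1%" probability are supported: the
nominal `p = 0.01` and the realized `p = floor(0.01·M)/M` after the integer
cutoff. At `M = 138,127` and `n = 25` the two give `E[O_1]` of 27,130.8 and
27,126.8 — a 0.015% spread that brackets the commonly quoted 27,128; the
package exposes `p` explicitly rather than committing to one convention.
Real searches overlap far more than the null in the tail, which is the
empirical signature the generative model explains.

## The preferential-attachment model

Searches are modelled sequentially: each of `n` searches returns `m`
molecules; a pick duplicates an already-retrieved molecule with probability
`γ` (chosen proportionally to its current retrieval count) and otherwise
draws a fresh molecule uniformly. Writing `X_s(t)` for the number of
molecules retrieved exactly `s` times after `t` searches, the expected flows
give a steady state `X_s(t) = O_s · m · t` with

- `O_1 = (1−γ)/(1+γ)`, and
- `O_s = γ(s−1) · O_{s−1} / (1 + γs)` for `s ≥ 2`.

The `O_1` closed form is obtained by applying the same steady-state argument
to the `(1−γ)m` inflow of never-retrieved molecules. For large `s` the
recurrence behaves as `O_s ∝ s^b` with `b = −(1 + 1/γ)`, which is ≤ −2 on
all of `γ ∈ (0,1]` with equality at `γ = 1` — the classical Lotka slope. At
finite `n`, however, the fitted log-log slope is shallower: fitting ordinary
least squares over `s = 1..25` gives −1.923 at `γ = 0.9` and −1.845 at
`γ = 0.99` (`effective_slope()`). The fit range `1..n` is the package
default and is exposed as a parameter; it matches how empirical overlap
plots are drawn (they start at `s = 1`) and it is the range under which the
two quoted finite-`n` slopes arise.

Three numerical points deserve care:

- **Normalization.** `sum(s · O_s) = 1` holds only in the infinite-`s`
  limit, and the tail converges slowly: `s · O_s ~ s^(−1/γ)` decays with
  exponent barely above 1 for γ near 1, so at γ = 0.9 the partial sum at
  `s = 10^5` is still only ≈ 0.79. The property tests therefore check the
  partial sum plus the analytic tail integral
  `a · S^(1−1/γ)/(1/γ − 1)` against 1 (to 2%), not the bare partial sum.
- **Steady state vs transient.** The Monte-Carlo simulator
  (`simulate_pa_process()`) reproduces the recurrence bucket-for-bucket in
  the long-time regime — e.g. thousands of draw-level steps (`m = 1`) —
  where the self-similar steady state applies. A short batched run
  (`n = 25` searches of `m = 500`) is dominated by its transient: the first
  search alone seeds `m` once-retrieved molecules, and the relaxation toward
  `X_s ∝ t` is itself power-law slow, so simulated batch profiles sit
  systematically above the recurrence in the tail. This is a property of
  the model, not an artifact; the two regimes are both exercised in the
  test suite, with the batch-regime comparison recorded at the study's
  parameterization.
- **γ estimation.** `estimate_gamma()` fits the recurrence to the log shape
  of an observed profile with a free scale (so counts or fractions work
  alike), by golden-section search over γ; an alternative route inverts the
  asymptotic exponent, `γ = −1/(b+1)`, which is valid only for fitted
  slopes `b < −2` — shallower slopes are flagged as outside the model
  rather than silently inverted. Because the estimator assumes the steady
  state, it must be fed profiles from the long-time regime; batch-regime
  profiles bias it toward 1.

## Trend fitting

All fits are ordinary least squares in base-10 log space (slope and `r²` are
base-invariant; intercepts are reported base-10). `loglog_fit()` regresses
`log10 y_s` on `log10 s` (power law), `loglinear_fit()` on `s`
(exponential), and `cubic_loglog_fit()` fits a cubic polynomial in
`log10 s`, the smooth trend used for precision profiles; `compare_trends()`
ranks the candidates by `r²`. Zero and undefined buckets are dropped before
taking logs and the number dropped is reported on the fit object. Constant
data would make `r²` 0/0, so flat inputs return slope 0 and `r² = 0` with a
`flat` flag instead of `NaN`. Maximum-likelihood power-law estimation is
deliberately out of scope: the analyses this package reproduces use simple
log-log regression, and comparability matters more than estimator
efficiency here.

## Worked defaults and sizes

The bundled tests and the study pipeline run at reduced sizes chosen so the
statistical signal is unambiguous while a full run stays within a few
minutes on one CPU: study-level property checks use databases of 2,000–3,000
molecules with 120-active classes, recurrence-vs-simulation checks use 200
Monte-Carlo replicates, and γ-recovery uses draw-level runs matching the
study's total of 12,500 retrieval instances. The headline quantities —
the binomial null at `M = 138,127`, the finite-`n` slopes −1.923/−1.845 and
the asymptotic bound −2 — are closed-form or deterministic and are computed
at full scale.

## Known limitations

- The "common molecules" intersection table is order-dependent by
  definition (the intersection of the *first* `k` outputs in declared
  order); a count-threshold variant (`method = "threshold"`) is provided
  because the two readings genuinely differ and the choice matters when
  comparing against published tables.
- Precision is not modelled by the generative framework; the model speaks
  only to overlap.
- The falling tail of group-fusion precision on heterogeneous classes is
  reproduced only partially: synthetic profiles rise to an interior peak
  (and the heterogeneous class peaks earlier than the homogeneous one), but
  the full-consensus bucket stays essentially pure. With a centroid-based
  class model, the molecules ranked highly by *every* reference are always
  class-core actives; a genuine terminal decline would need
  consensus-dominating inactives — e.g. unlabeled near-class analogues,
  which real screening databases contain and this generator deliberately
  does not.
- Synthetic homogeneity levels are free parameters; only their ordering,
  not their values, is anchored to published observations.
- The package does not produce fused output rankings (MAX/SUM rules): the
  object of study is the *disagreement between* search outputs, not a
  combined ranking.

## A short worked example

```{r example, eval = FALSE}
db <- generate_database(default_database_spec(seed = 1))

sf <- run_replicated_experiment(db, "class01", mode = "SF",
                                n_replicates = 10, fraction = 0.01, seed = 1)
overlap <- average_profiles(lapply(sf$counts, overlap_profile))
loglog_fit(overlap)

precision <- average_profiles(
  lapply(sf$counts, precision_profile, db = db, target_class = "class01")
)
argmax_precision(precision)
autoplot(overlap)

# the generative model's account of the decay
effective_slope(0.9, n = 25)   # -1.923
asymptotic_exponent(1)         # -2
```
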