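# fusionoverlap

When several similarity searches are fused in ligand-based virtual
screening — one reference structure searched with many similarity measures
(*similarity fusion*, SF), or many reference structures searched with one
measure (*group fusion*, GF) — the different searches retrieve strikingly
different molecules. `fusionoverlap` is an R package for studying that
disagreement quantitatively. It is aimed at cheminformaticians and
information scientists who want to measure, on their own or on synthetic
data, how search outputs overlap, how precision depends on inter-search
agreement, and why the overlap follows a power law.

The package implements:

- **Fingerprint similarity**: binary fingerprints with hex serialization,
  contingency counts, and the Tanimoto, Cosine, Forbes, Russell–Rao and
  Simple Match coefficients, with fixed degenerate-input conventions.
- **Synthetic screening databases**: activity classes of controllable
  homogeneity (mean pairwise Tanimoto), scaffold clusters, and `V`
  correlated fingerprint "views" per molecule standing in for distinct
  fingerprint types (`generate_database()`).
- **Search batteries**: ranked similarity search with top-fraction cutoffs,
  SF/GF drivers and replicated experiments producing per-molecule retrieval
  counts (`run_similarity_fusion()`, `run_group_fusion()`,
  `run_replicated_experiment()`).
- **Overlap statistics**: the overlap profile `O_s` (distinct molecules
  retrieved by exactly `s` of `n` searches) at molecule and scaffold level,
  the precision profile `P_s` (% active among molecules retrieved `s`
  times), common-molecule tables, and the binomial random-retrieval null
  `E[O_s] = M · C(n,s) p^s (1−p)^(n−s)`.
- **Trend fitting**: least-squares power-law fits on log-log axes
  (`O = a·s^b`), log-linear comparison fits, and cubic log-log trends for
  precision profiles, with broom-style `tidy()`/`glance()` and ggplot2
  `autoplot()` methods.
- **A preferential-attachment generative model**: each search re-retrieves
  an already-found molecule with probability γ in proportion to its current
  retrieval count. Its steady state obeys `O_1 = (1−γ)/(1+γ)`,
  `O_s = γ(s−1)O_{s−1}/(1+γs)`, giving a power law with asymptotic exponent
  `b = −(1+1/γ) ≤ −2`; finite-`n` fitted slopes, a Monte-Carlo simulator
  and a γ estimator are included.

## Worked example

```r
library(fusionoverlap)

# a 20,000-molecule database: 5 correlated 512-bit views, 11 activity
# classes spanning tight to diffuse homogeneity
db <- generate_database(default_database_spec(seed = 1))

# similarity fusion on a diffuse 100-active class: 10 replicates,
# 25 measures (5 views x 5 coefficients), top-1% cutoff
sf <- run_replicated_experiment(db, "class11", mode = "SF",
                                n_replicates = 10, fraction = 0.01, seed = 1)
overlap <- average_profiles(lapply(sf$counts, overlap_profile))
loglog_fit(overlap)
#> <power fit>  r^2 = 0.8709  (25 points used, 0 dropped)
#> intercept     slope 
#>  3.165730 -2.095772 

precision <- average_profiles(
  lapply(sf$counts, precision_profile, db = db, target_class = "class11")
)
argmax_precision(precision)
#> [1] 14

# the binomial null for retrieval at random, top-1% of 138,127 molecules
nul <- binomial_null(M = 138127, p = 0.01, n = 25)
nul$expected[nul$s == 1]
#> [1] 27130.84

# the generative model's account of the decay
effective_slope(0.9, n = 25)
#> [1] -1.923084
asymptotic_exponent(1)
#> [1] -2
```

The fitted SF slope sits near the classical Lotka value of −2: the number
of molecules on which `s` searches agree collapses roughly as `s^−2`
(here, from hundreds of molecules found by one search to a handful found by
ten). Meanwhile precision climbs from under 1% at `s = 1` to 100% by
`s = 14`: agreement across searches is strong evidence of activity. Under
random retrieval neither structure exists — the null expects under one
molecule at `s = 5` and none beyond. The preferential-attachment model
reproduces exactly this finite-`n` slope regime for γ just below 1.

An end-to-end study (database → SF/GF per class → averaged profiles →
fits → null → generative model, all written to TSV/JSON) runs from one
configuration via `run_screening_study(config, out_dir)`.

See the vignette `vignettes/fusion-overlap-methods.Rmd` for the models,
parameter choices, numerical conventions and limitations.

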