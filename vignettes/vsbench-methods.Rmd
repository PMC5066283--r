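---
title: "Benchmark metrics and bias auditing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark metrics and bias auditing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsbench)
```

## The problem

A structure-based virtual screen ranks a chemical library against a protein
target; a good program places the known actives at the very top, because only
a handful of compounds can be tested experimentally. Benchmarks measure this
"early recognition" over many targets, each with a library of actives diluted
about 1:50 in property-matched decoys. The difficulty is that measured
performance confounds two things: the program's docking quality and the way
the active/decoy libraries were constructed. `vsbench` separates them — it
computes the ranking metrics, quantifies the residual library biases, and
recomputes success rates after removing biased targets.

## Ranking metrics

**Docking enrichment.** `DE_x%` is the percentage of all actives recovered in
the top fraction `x` of the ranking. With a 2% active ratio the ceiling is
100% at `x = 2%` and 25% at `x = 0.5%` (the top 0.5% can physically hold only
a quarter of the actives). The top-`k` cut is `round(x·N)` with round-half-up
and a floor of one compound; no rounding convention is canonical here, and
half-up keeps `k` integral and monotone in `x`.

**BEDROC.** The Boltzmann-enhanced discrimination of ROC weights each active
at rank `r_i` by `e^(−α·r_i/N)` and min–max rescales so that the perfect
ranking scores 1 and the inverted ranking 0. The score depends only on the
ranks — any strictly monotone transform of the raw scores leaves it unchanged
— and `α` sets the effective percentile of interest: the share of total
weight in the top fraction `x` is `(1−e^(−αx))/(1−e^(−α))`
(`weight_fraction()`), so α = 80.5 focuses 80% of the score on the top 2%,
α = 321.9 on the top 0.5% and α = 20.0 on the top 8%. `alpha_for_fraction()`
inverts this relation by bracketed root finding to relative tolerance 1e-8
(the conventional α = 20.0 is a round value; exact inversion of the 8%/80%
condition gives ≈ 20.1, an inherited discrepancy we do not resolve). When
`α·R_a ≥ 1` the classical probabilistic reading of BEDROC degrades and the
function warns — note this fires for the standard α = 80.5 at a 2% active
ratio, so the warning marks an interpretation caveat, not an input error.

Numerics: evaluating the closed form at extreme rankings can overshoot the
bounds by sub-epsilon amounts (about −3e−50 at the worst ranking, +2e−16 at
the perfect one); the implementation clamps to [0, 1]. `cosh(α/2)` overflows
for α beyond roughly 1400, far above any useful weighting.

**Net balance.** `Δp(a/b)` compares two programs target by target: wins minus
losses over the number of targets compared. Exact score ties are counted for
neither side (both-excluded), a choice we document because printed usage
never specifies it. The restricted variant keeps only targets where at least
one program succeeds (score > 0.5), and divides by that subset's size.

**Ties and orientation.** Docking scores do tie in practice. Ranking uses a
stable sort by default (input order preserved inside a tie block) with
`pessimistic`/`optimistic` policies that place actives last/first inside the
block — running both brackets the metric uncertainty that ties introduce.
Higher-score-is-better is the default; `ascending = TRUE` handles
energy-like scores. Success is the strict comparison `BEDROC > 0.5`.

## Library bias statistics

For each of nine properties (MW, AlogP, E-state, PSA, HBA, HBD, ring count,
rotatable-bond count, embranchment count) the per-target normalized
difference is

> ΔP = (P̄_actives − P̄_decoys) / (max_t P̄_actives − min_t P̄_actives),

where the denominator is the range of the per-target *actives* means across
the analyzed collection — recomputed for every collection, never hard-coded
from any reference dataset. The overall bias statistic is `S = Σ|ΔP_i|`. The
unbiased subset keeps targets with `S` strictly below a threshold defaulting
to the collection's own mean `S` (a fixed value such as 0.87 can be passed
when comparing against an external collection) and crystal-ligand similarity
`Sim2D_cryst-act` strictly below 0.1. That similarity threshold is
fingerprint-dialect dependent and therefore configurable.

The embranchment count (EC) counts atoms with three or more bonds to
heavy-atom neighbours, restricted by default to C, N, Se and Sn (the atom
types that define the descriptor; the tertiary-CH type shows the attached
hydrogen does not count towards the three bonds). An all-heavy-elements
variant is exposed.

Correlations between per-target scores and covariates use the Pearson
coefficient with the Student t test (`t = r√(n−2)/√(1−r²)`, two-sided p from
the t distribution; two-sided reproduces the reference case p = 3e−3 for
r = 0.29 at n = 102). Tiers are `significant` when p ≤ 1e−4, `questionable`
up to 1e−2, `none` above — closed upper bounds. No multiple-testing
correction is applied across the screen; the stringent 1e−4 tier is the
stand-in, and users should treat `questionable` accordingly. Leave-one-group
-out re-screening uses the reduced `n` in the t test, which is statistically
correct even where historical reports may have kept the full `n`.

## Descriptors, fingerprints, cavities

MW, HBA, HBD, ring count and rotatable bonds follow standard graph
definitions (N/O acceptors; N–H/O–H donors; cyclomatic ring count, which
equals the smallest-set-of-smallest-rings size; non-ring single bonds between
non-terminal heavy atoms). AlogP and PSA belong to external parameterized
method families and are either delegated to the Open Babel engine (Crippen
logP, topological PSA) or ingested from a table; E-state is ingest-only.
Values are engine-dependent; the contract is consistency within one run.
Implicit hydrogens come from default valences; formal charges are not
modelled, so charged species (e.g. carboxylates) get neutral-form hydrogen
counts. Salts reduce to the largest fragment with a message.

The 2D fingerprint is this package's own hashed linear-path dialect: all
simple paths of up to 7 bonds, written as element/bond-order strings, read in
the lexicographically canonical direction, hashed by 32-bit FNV-1a into 1024
bits by default. The dialect tag travels with every fingerprint and file, and
Tanimoto comparisons refuse mixed dialects, because absolute similarity
values are only meaningful within one dialect. Two all-empty fingerprints
compare as 1 with a `both_empty` flag.

Cavity hydrophobicity (FCA) is the carbon fraction among protein heavy atoms
strictly within 4 Å (configurable) of any probe point of a surface cloud such
as a docking protomol; "strictly" follows the defining phrase "less than
4 Å", and the same strict rule is used for the surface atom count. Distances
are brute-force; cavities are small enough that no spatial index is needed.
Binding-site exposure is accepted as an externally supplied column only — its
reference implementation is proprietary and is not re-derived here.

## The synthetic-data generators

The generators exist so every downstream stage is testable with known ground
truth; they emulate the *structure* of a large docking benchmark, not its
chemistry.

- **Screens.** A target's active ranks are drawn without replacement from a
  discretized truncated-exponential law with weight `e^(−λk/N)` on rank `k`,
  mirroring BEDROC's weighting: λ = 0 is the uniform null, larger λ means
  stronger early enrichment. Sampling uses the Gumbel top-n construction
  (keys `−λk/N + Gumbel noise`, take the n largest), which is exact for this
  law, stable in log space for any λ, and degenerates cleanly to ranks
  `1..n` as λ → ∞ — naive rejection sampling cannot terminate there because
  the tail probability underflows. The default library shape is 510
  compounds with 10 actives (50 decoys per active, the benchmark-database
  convention, ≈ 2% actives).
- **Property tables.** Actives are `Normal(base + drift, σ)`, decoys
  `Normal(base, σ)`, independent across properties by default with an
  optional correlation-matrix hook. Per-target base means vary across a
  collection so the ΔP denominator is a genuine range.
- **Fingerprint families.** Shared random core XOR per-bit noise; the
  crystal fingerprint comes from the same core. Noise 0 gives pairwise
  Tanimoto 1; noise 0.5 is indistinguishable from independent fingerprints.
- **Cavities.** Probe cloud plus atoms placed strictly inside/outside the
  cutoff; surface atoms are carbon with a set probability, so FCA is a
  binomial proportion with known mean.
- **Coupled collections.** `gen_benchmark_collection()` ties it together:
  biased targets get property drift (on PSA, HBD and EC), a tight
  fingerprint family, and higher enrichment λ for every simulated program —
  one program couples mainly to crystal similarity, the others to property
  drift. Its fingerprint families are sparse (core density 0.025, noise
  0.03) so the similarity summaries land on the 0–0.4 scale at which the 0.1
  crystal-similarity threshold is meaningful; dense random bit vectors would
  all be ≈ 0.3 similar to each other. Seeds derive per target and per
  generator from one master seed, so adding targets never perturbs earlier
  ones and every run is reproducible.

What the generators do *not* emulate: real score distributions of docking
programs, property correlations between actives and decoys of the same
target, chemical series structure, or any 3D realism. Passing tests therefore
demonstrate that the statistics recover injected effects of realistic size
under Gaussian/Bernoulli noise — not that any particular docking program is
biased.

## Problem sizes used by the test suite

The suite favours many small deterministic cases plus a few calibrated
simulations: BEDROC is checked against an independent direct-summation oracle
on 1,000 random screens of up to 500 compounds (agreement ≤ 1e−12); drift
recovery uses 200 replicate collections of 4 targets with 1,000 actives and
1,000 decoys each; the type-I rate of the `significant` tier is estimated
from 10,000 null correlations at n = 102; FCA recovery averages 200 cavities
of 100 surface atoms; the end-to-end bias-removal property uses 20 replicate
collections of 16 targets. These sizes give stable verdicts for the effect
sizes tested while keeping a full run around twenty seconds.

## Known limitations

- The fingerprint dialect is package-specific; absolute Sim2D values are not
  comparable to other toolkits' fingerprints, only rankings and thresholds
  calibrated within the dialect are.
- Descriptor values for AlogP/PSA depend on the delegated engine version.
- No formal charges, stereochemistry or aromaticity perception beyond bond
  orders in the molecule model.
- The correlation screen is descriptive: tiers control the per-test error
  rate, not the family-wise one.
- Exposure (site openness) is never computed, only ingested; analyses that
  need it silently reduce to the covariates present.
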