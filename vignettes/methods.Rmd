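---
title: "Methods: serum pharmacochemistry and network pharmacology in serumnetpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum pharmacochemistry and network pharmacology in serumnetpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumnetpharm)
```

## The analytical problem

A multi-herb decoction delivers dozens of constituents into serum —
prototypes and metabolites. The workflow this package implements treats
those absorbed constituents as the candidate actives and asks three
questions in sequence: which library compounds explain the observed MS1
features; which protein targets each constituent plausibly binds; and what
network- and pathway-level structure the resulting compound–target map
carries. Each stage is an established computation; the package's
contribution is a tested, seeded, fully reproducible implementation with a
synthetic benchmark whose ground truth is planted by construction.

## MS1 annotation

Peaks are matched to library compounds through singly charged
proton-transfer quasimolecular ions. The theoretical m/z of `[M+H]+` is
`M + 1.007276466` Da and of `[M−H]−` is `M − 1.007276466` Da; the proton
mass constant is fixed and the electron mass is absorbed into this
convention, which is standard for ±H adducts and keeps the arithmetic
bit-reproducible. A (compound, adduct) pair annotates a peak when the
adduct polarity matches the peak's ion mode and the relative mass error
`|m_obs − m_theo| / m_theo × 10⁶` does not exceed the tolerance. The
tolerance is **inclusive at the boundary** and defaults to **5.0 ppm**.
Matching is mass-only: retention-time comparison in the original workflow
relies on physical reference standards that a computational library does
not carry, so the match table is explicitly flagged as RT-unchecked.

Unmatched peaks can be assigned elemental compositions by exhaustive
search over a bounded CHNOS grid (monoisotopic masses embedded: C 12.0,
H 1.007825032, N 14.003074005, O 15.994914620, S 31.972071174 Da). A
candidate is kept when its neutralized mass error is within tolerance and
its ring-and-double-bond equivalents, `RDBE = C − H/2 + N/2 + 1`, is a
non-negative **integer** — the half-integer case is rejected (nitrogen
parity rule for even-electron neutral molecules). Candidates are ranked by
|ppm| with ties broken by formula string; any chemical prioritisation
beyond that (isotope patterns, MS2) is out of scope.

## Target prediction

Compounds and reference ligands are compared as fixed-length binary
structural fingerprints with the Tanimoto coefficient
`T = c / (a + b − c)`. Two conventions are fixed by design:

- `T` of two all-zero fingerprints is **0**, not 1 or undefined — an empty
  fingerprint can never pass a positive threshold.
- A target backed by several ligands is scored by the **maximum** ligand
  similarity, the similarity-ensemble convention; it preserves the
  threshold semantics (a target passes iff some ligand passes).

The decision threshold is **T ≥ 0.4, inclusive**. Similarity predictions
can be merged with precomputed database prediction tables by union, the
score of a pair present in both being the maximum and its source labelled
`both`; database rows without scores default to 1.0. Union rather than
intersection is the deliberate choice here: how the original workflow
combined its database and fingerprint predictions is not documented, and
union is the conservative option for a hypothesis-generating screen. All
outputs are sorted by descending score with lexicographic tie-breaks so
repeated runs are byte-identical.

## Networks and core-constituent selection

The compound–target (C-T) network is bipartite: deduplicated
(compound, target) pairs, with compound/target/category namespaces kept
distinct internally (`C:`, `T:`, `D:` prefixes, stripped on export).
Degree tables satisfy the handshake identity (compound degrees, target
degrees, and edges all sum consistently; enforced by tests on random
networks). Core constituents are the compounds of **degree ≥ 17,
inclusive** — at the study scale this keeps exactly 19 of 60 constituents.
Degree counts **distinct targets**, not prediction records with
multiplicity: the prediction table is deduplicated before the network is
built, which is the only reading under which the published node/edge
arithmetic is self-consistent.

The compound–target–disease (C-T-D) network adds one category edge per
mapped target. One-category-per-target is the default because the eight
published per-pathology counts (111, 79, 46, 41, 27, 18, 9, 7) sum exactly
to 338, the number of targets — a multi-label map could not reproduce that
identity. A `multi = TRUE` mode exists for databases that genuinely
multi-label.

The study-scale constructor `paper_scale_predictions()` realizes this
arithmetic exactly and deterministically: the 19 published core degrees
(75, 56, 52, …, 17; sum 667) plus 41 sub-threshold filler compounds whose
degrees sum to 318 (31 compounds of degree 8, 10 of degree 7), giving 985
distinct pairs over 338 targets assigned by a least-loaded greedy rule
that guarantees full target coverage.

## PPI topology and the permutation enrichment test

PPI graphs are simple undirected `igraph` objects; STRING-style TSV ingest
collapses reversed duplicates (keeping the best score) and drops
self-loops with a warning. Average node degree is `2E/N`, displayed at two
decimals (matching the precision convention of such reports) with full
precision retained in machine-readable output.

The online database's analytical subnetwork-enrichment p-value depends on
a proprietary background model, so the package substitutes a **seeded
permutation test**, clearly labelled in every report: draw `n_perm`
uniform node subsets of the same size, count within-subset edges, and
report `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`. The add-one correction
makes the statistic valid (super-uniform under the null — verified over
500 seeded replicates at a reduced `n_perm` of 199) and bounds the
smallest attainable p at `1/(n_perm + 1)`.

## Over-representation analysis

Term enrichment is the standard one-sided hypergeometric upper tail
`P(X ≥ k)` for overlap `k`, term size `K`, study size `n`, universe `N`,
evaluated through the log-space survival function so extreme tails keep
precision. Multiplicity is controlled by Benjamini–Hochberg by default
(Bonferroni available); the original workflow names its annotation tool
but not its test or correction, so the field-standard pair is used and
echoed in the run metadata. Terms with zero overlap are excluded from the
testing family by default, matching common ORA-tool behaviour. Group
shares are `100 × (significant terms in group) / (total significant
terms)`, reported at two decimals and summing to 100 within rounding.
The enrichment universe defaults to the term database's universe; an
explicit background can override it.

## The synthetic benchmark: what it emulates and what it does not

Every generator flows from one integer seed; each stage derives a fixed
sub-seed, so a dataset, or any single stage, is bit-reproducible.

- **Compound library** — neutral masses uniform on [50, 1500] Da (the
  instrument scan range) with herb-source labels; fingerprints are
  independent Bernoulli bit vectors (default length 1024, density 0.1).
  This deliberately decouples the statistics from any chemistry toolkit:
  real structural-key fingerprints are sparse and correlated, synthetic
  ones are not, so passing benchmarks here demonstrates recovery of
  planted similarity structure, not chemical realism.
- **Reference panel** — each target has a random prototype; its ligands
  are per-bit mutated copies, making within-target similarity high and
  between-target similarity background-level.
- **Planted associations** — selected compounds receive a mutated copy of
  a random ligand's fingerprint (flip probability = `mutation_rate`,
  default 0.02, validated < 0.5 beyond which similarity is unrecoverable).
  At the defaults, prediction at the 0.4 cutoff recovers planted pairs
  with precision and recall ≥ 0.95 averaged over 20 seeds (tested).
- **Peak lists** — every compound emits both default adducts with
  multiplicative Gaussian ppm noise (default SD 1 ppm, so essentially all
  planted peaks fall inside a 5 ppm window); decoys are rejection-sampled
  at least 20 ppm from every library adduct mass so they are unassignable
  by construction. No retention modelling, isotope envelopes, or MS2.
- **PPI graphs** — Erdős–Rényi background plus a planted module topped up
  to a target internal density; defaults (100 nodes, p = 0.02, module of
  15 at density 0.5) give a module the permutation test flags at
  p ≤ 0.01 across seeds.
- **Term database** — random gene sets over a universe (default 1000)
  with one planted term drawn entirely from the designated study set, so
  ORA must rank it first. The study set defaults to a seeded random
  subset of roughly a tenth of the universe capped at 50 — its size is a
  package choice, documented here, not an inference from data.

The `paper_scale` preset pins the study's scale: 60 compounds, 338
targets, a 91-node PPI graph whose edge probability targets 448 expected
edges, and 84 terms over 8 functional groups.

## Numerical and reproducibility choices

- All thresholds are inclusive at their boundary (T ≥ 0.4, degree ≥ 17,
  ppm ≤ 5.0), matching the printed conventions they implement.
- Every ranking has a total order: descending score or degree, then
  lexicographic id.
- Formula search windows are computed in Da from the neutralized mass and
  widened by a small margin before the exact ppm filter decides inclusion,
  so no boundary candidate is lost to the denominator asymmetry between
  observed and theoretical mass.
- The pipeline report omits wall-clock timestamps so that identical
  configuration and seed give byte-identical output directories
  (timestamps go to the stderr log instead).

## Problem sizes used by the test suite

The suite runs the planted-recovery benchmark at 30 compounds x 20
targets x 1024 bits over 20 seeds, the permutation-null calibration at
500 replicates with `n_perm = 199` on a 60-node graph, the ORA type-I
check at 200 null replicates of 25 terms, and brute-force oracle
comparisons (Tanimoto, hypergeometric enumeration, CHNOS grid search) at
sizes where exhaustive computation is exact. These sizes are chosen so the
whole suite exercises every statistical guarantee while remaining quick to
run routinely.

## Known limitations

- Synthetic fingerprints are uncorrelated Bernoulli bits; real MACCS-style
  keys have strong bit correlations, so real-data precision/recall will
  differ from the planted benchmark.
- Formula enumeration covers C, H, N, O, S only and ranks by |ppm| alone.
- The permutation enrichment p-value is a surrogate for, not a
  reimplementation of, the online database's analytical statistic.
- Identifier normalization (gene symbol vs. protein id, species mapping)
  is out of scope; ids are opaque strings.
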