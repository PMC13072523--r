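---
title: "Influence-matrix stratification of re-identification risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Influence-matrix stratification of re-identification risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimeda)
```

## The problem and the modelling stance

A data controller deciding whether to release a pseudonymised or anonymised
medical dataset needs a *holistic* risk judgement: record-level uniqueness
matters, but so do the linkable knowledge available to an adversary, the
adversary's capabilities, and the releasing organisation's technical and
organisational safeguards. `rimeda` treats re-identification risk as a
complex system of 13 interacting risk entities grouped into four
perspectives (data, knowledge, attacker, technical/organisational) and
analyses it with a cross-impact **influence matrix**, a classic instrument
of "networked thinking" system analysis.

Two modelling layers are deliberately separated:

1. **System dynamics** — the influence matrix `M`, fixed per model: signed
   integers in `[-3, 3]`, zero diagonal, `m(i,j)` scoring how strongly
   entity *i* drives entity *j* (sign = parallel vs opposing development).
2. **Case assessment** — the controller's weight vector `w`, one integer
   per entity from that entity's admissible domain, graded against
   free-text rubric criteria carried on each entity definition.

## Indices and their interpretation

With per-entity doubling factors `δ` (2 for D1 uniqueness and TO2
anonymisation methods, else 1) and the default `row` strategy, the weighted
matrix is `W(i,j) = w_i δ_i |m(i,j)|`. Row sums give the **active sum**
(influence exerted), column sums the **passive sum** (influence received),
their product the **Q-value** (cross-linkage; the lever indicator), and
`Σ AS + Σ PS = 2 Σ W` the **total risk score**. All stored values are exact
integer arithmetic; the ceiling-rounding used "for presentability" is
applied in the chart renderers only, never to stored indices.

Factor **categories** follow the four classic system roles — active
(impulsive), reactive (passive), critical (dynamic), inert (buffering).
The qualitative definitions ("pronounced" vs "rather low" sums) need a
concrete cut; the default compares `|AS|` and `|PS|` against their
across-entity means, with ties (`|AS|` exactly equal to the mean) counting
as pronounced, and an all-zero system classified inert throughout. Median
and fixed cut-off schemes are available (`classify_factors(scheme = )`)
because the category boundary is a presentation choice, not part of the
arithmetic.

### Weighting strategies

The published description — cell moduli multiplied by the entities'
weighting scores — does not pin down whether the *influenced* entity's
weight also scales a cell, and the printed extreme index values of the
original prototype suggest a finer-grained formula than pure row scaling.
The strategy is therefore pluggable:

* `row` (default): `W(i,j) = w_i δ_i |m(i,j)|` — the direct reading of the
  verbal definition; the score is linear in each weight with nonnegative
  coefficient `2 δ_i Σ_j |m(i,j)|`.
* `row_col`: additionally scaled by `w_j δ_j` — the natural "both ends"
  alternative.

Without the original prototype workbook to calibrate against (see *The
canonical model's matrix* below) no further strategies are guessed; the
shipped canonical model pins `row`.

### The Q-value sign convention

The stated interpretation is that positive Q means risk-increasing and
negative Q risk-reducing. A raw product `AS · PS` violates this when both
sums are negative (a strongly inhibiting safeguard would flip to
"risk-increasing"). The default convention `active_sign` therefore takes
`|AS · PS|` with the sign of the active sum, which preserves the reading on
every admissible assessment; the raw `product` convention is kept for
strict-formula comparison and is selectable per model. The report names the
convention used.

### Negative weights

Technical/organisational entities admit `-3` alongside `1..3`: a
high-quality safeguard is not merely absent risk but an active inhibitor.
The signed weight carries through to the cells (the modulus in the
definitions applies to the raw matrix entries, not to the weights), which
is what makes negative active/passive sums — and a below-"basic" score
reduction — representable.

## The canonical model's matrix is a synthetic stand-in

The canonical model ships the published *structure* exactly: 13 entities,
4 perspectives, weight domains (D1–D3: 0–3; W1, W2, W4, A1–A3: 1–3;
W3: 0–3; TO1–TO3: −3 or 1–3), and the D1/TO2 doubling. The *cell values*
of the original influence matrix, however, exist only in a figure and a
prototype spreadsheet that cannot be redistributed with this package. The
shipped matrix (`rimeda_matrix_synthetic.csv` — the filename labels it) was
therefore curated once from the published qualitative descriptions of the
inter-entity relationships: the uniqueness entity's full row is described
verbatim (strong links to similarity, vulnerable quasi-identifiers and the
linkage-knowledge entities, a somewhat weaker one to inference, strong
motivation effects, weaker skill/resource effects, medium effects on the
organisational entities), metadata is described as exceptionally
cross-linked, and the technical/organisational rows act as inhibitors
(negative signs toward the risk entities, positive mutual reinforcement).

Consequences, stated plainly:

* **Structure-level results are faithful**: the qualitative lever
  behaviour — uniqueness (D1) and metadata (W3) among the strongest risk
  factors at the maximum configuration, method quality (TO2) the strongest
  inhibitor at the minimum — is encoded by the curation and verified by
  tests and the acceptance script.
* **Absolute score values are illustrative**: the stand-in yields
  achievable bounds (−226, 1632) and index ranges (AS −114..174,
  PS −19..90), which are *not* the originally published scale. Replacing
  `matrix: csv:` in a copy of the model file with a faithful transcription
  restores the original scale without code changes; all arithmetic is
  matrix-agnostic.
* Every engine property that the test suite relies on (oracle equivalence,
  linearity, monotonicity, the `2 × Σ cells` identity, zero-weight
  annihilation, sign behaviour, enumeration-vs-analytic bounds) is
  established on generated models independent of any transcription.

## Exact sensitivity analysis

Because the diagonal is zero, the total score is *multilinear* in the
per-entity signed weights under both strategies, so its extremes over the
admissible weight box occur with every entity at a domain endpoint:

* `row`: closed-form bounds (linear, nonnegative coefficients) — the
  minimum/maximum configuration is each entity at its domain
  minimum/maximum.
* `row_col`: exact bounds by enumerating the `2^n` endpoint corners
  (8192 for 13 entities) rather than the full admissible product
  (`4^7 · 3^6 = 11,943,936` for the canonical domains).

Index ranges under `row` are computed exactly without enumeration: an
entity's active sum is separable (`w_i δ_i Σ_j |m(i,j)|`), its passive sum
is a sum of independent per-entity terms, and its Q-value couples its own
weight with the *other* entities' achievable passive-sum values, whose
exact set is built by dynamic programming over Minkowski sums of the tiny
per-entity value sets. Under `row_col` the Q-values are not separable, so
ranges fall back to exhaustive enumeration below a hard cap of `10^6`
combinations and are refused above it.

`sweep_assessments()` explores the weight space either exhaustively (below
the same cap; the canonical model exceeds it and is refused with guidance)
or by Monte-Carlo sampling, per-entity uniform and independent — no
empirical distribution over assessor behaviour is available, so uniformity
is the declared neutral choice. A single integer seed governs a sweep;
generators save and restore the caller's RNG state. Leverage is reported
per entity: under `row` it is exactly
`2 δ_i Σ_j |m(i,j)| · (max domain − min domain)` independent of context;
under `row_col` it is evaluated with the other entities at their domain
maxima (a documented, deliberately pessimistic context).

## Stratification, charts, and hints

Risk classes are not defined numerically in the source system, so the
default band scheme is four equal-width bands over the *achievable* range
(low / moderate / high / critical), mirroring the equal-size subdivisions
of the system grid; custom ascending edges are accepted and validated.
Bands are half-open with a closed top band, making the band function total
and monotone on the achievable range; a score outside the bounds raises an
error, since it can only arise from mismatched model/assessment pairs.

The three renderers (gauge, Q-chart ordered by |Q|, and the (AS, PS)
Cartesian grid with equal subdivisions and category colouring) write SVG
(canonical, diffable, byte-deterministic for fixed input) and PNG. The
system grid always shows the origin and spans all four quadrants whenever
any sum is negative. The subdivision count defaults to 4 per axis — a
choice, not a published fact — and is a parameter.

Countermeasure hints operationalise the lever reading: controllable
entities (data and technical/organisational by default; world knowledge
and attackers cannot be acted upon by a controller — configurable per
model file) are partitioned into risk-increasing levers (descending Q,
paired with the model's free-text countermeasure hints) and protective
levers to maintain (negative Q, strongest first); the partition is total
and duplicate-free by construction.

## The generators and what passing tests mean

`toy3_model()` is a fixed three-entity system small enough that every
published-style index can be hand-computed and every admissible assessment
(48) enumerated; it anchors the hand oracles in the test suite.
`random_model()` / `random_assessment()` generate admissible systems
(zero diagonal, cells in `[-3, 3]`, domains from a palette) as pure
functions of their configuration and seed; tests verify engine arithmetic
against naive scalar-loop oracles on over a thousand such systems and
exhaustive enumerations on the small ones (problem sizes: 2–6 entities for
oracle sweeps, 8192-corner enumerations for the canonical model — all
chosen to keep the full suite comfortably within an interactive run).

The generators emulate admissible *model structures and assessments*, not
patient data: no quasi-identifier distributions, attack frequencies or
assessor behaviour are simulated. Passing tests therefore establish the
correctness of the arithmetic, the exactness of the sensitivity analysis,
and the internal consistency of the shipped model — not the external
validity of any particular matrix transcription, which remains a curation
input.

## Known limitations

* The shipped matrix is a synthetic stand-in (above); absolute scores are
  comparable *within* a model file, not across differently curated ones.
* The weighting itself is expert judgement; the package checks
  admissibility, not inter-rater reliability.
* Only the two stated weighting strategies are implemented; finer-grained
  normalisations would need a reference to calibrate against.
* Image and signal data are outside the system's scope by design; the
  entities address tabular/relational releases.
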