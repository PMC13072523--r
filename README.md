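# rimeda

Quantify and stratify the **re-identification (deanonymisation) risk of a
medical dataset** before release. `rimeda` is aimed at data controllers and
data stewards who must judge whether a pseudonymised or anonymised dataset
can be shared, where the residual risk concentrates, and which
countermeasures (generalisation, suppression, randomisation, organisational
safeguards) would move it most.

Re-identification is not mono-causal: it emerges from the interplay of the
**data** itself (uniqueness, similarity, vulnerable quasi-identifiers), the
**knowledge** an adversary can link against (external data sources,
background information, metadata, inference potential), the **attacker**
(motivation, skills, resources), and the **technical/organisational**
environment (awareness, anonymisation methods, data security). `rimeda`
models these 13 entities as a cross-impact system in the "networked
thinking" tradition of system analysis.

## The model

The system is a signed integer **influence matrix** `M` with zero diagonal:
cell `m(i,j) ∈ [−3, 3]` scores how strongly entity *i* drives entity *j*
(|1| weak, |2| medium, |3| strong; the sign distinguishes parallel from
opposing development). A data controller grades each entity with an integer
weight `w_i` from its admissible domain (e.g. 0–3 for data entities, 1–3
for knowledge/attacker entities, and −3 or 1–3 for technical/organisational
entities, where −3 expresses an actively risk-reducing safeguard). Entities
D1 (uniqueness) and TO2 (anonymisation methods) count double (`δ_i = 2`).

With the default `row` weighting strategy, the weighted matrix is
`W(i,j) = w_i · δ_i · |m(i,j)|`, and per entity:

- **active sum** `AS_i = Σ_j W(i,j)` — influence exerted on the system;
- **passive sum** `PS_i = Σ_j W(j,i)` — influence received from it;
- **Q-value** `Q_i = sign(AS_i) · |AS_i · PS_i|` — cross-linkage; positive Q
  is risk-increasing, negative Q risk-reducing, and high |Q| marks a
  candidate *lever* for risk control;
- **category** — active / reactive / critical / inert, by comparing |AS|
  and |PS| to their across-entity means.

The **total risk score** is `Σ_i AS_i + Σ_i PS_i = 2 · Σ_{i,j} W(i,j)`,
stratified into equal-width risk bands (low / moderate / high / critical by
default) over the model's exactly computed achievable score range.

The shipped 13-entity model (`canonical_model()`) carries the published
perspectives, weight domains and doubling flags; its matrix cell values are
a clearly labelled **synthetic stand-in**
(`inst/extdata/rimeda_matrix_synthetic.csv`) curated from the published
qualitative relationship descriptions — see the vignette for what that does
and does not imply about absolute scores.

## Worked example

```r
library(rimeda)

model  <- canonical_model()
assess <- random_assessment(model, seed = 42, label = "demo release")
result <- compute_risk(model, assess)
result
#> <rimeda_result for model 'rimeda-canonical-synthetic'>
#>   total risk score: 746 of [-226, 1632]  ->  band 'high'
#>  entity perspective weight active_sum passive_sum q_value category
#>      D1           D      0          0          31       0 reactive
#>      ...
#>      W3           W      3         78          29    2262 critical
#>      ...
#>     TO2          TO      2         76          24    1824   active
```

The score 746 falls in the third of four equal-width bands over the
achievable range [−226, 1632]: a *high*-risk release. The indices say why:
metadata (W3, weighted 3) is the most cross-linked risk driver
(Q = 2262, *critical*), while the data entities contribute nothing here
(weighted 0). The lever analysis ranks what the controller can act on:

```r
countermeasure_hints(result, model)$risk_levers[, 1:4]
#>   entity          name q_value category
#> 1    TO2       Methods    1824   active
#> 2    TO3 Data security     924   active
#> 3    TO1     Awareness     819   active
```

Improving the anonymisation methods (TO2, currently weighted 2 = mediocre)
is the strongest available lever; `what_if()` quantifies it:

```r
what_if(model, assess, c(TO2 = -3))$delta   # high-quality methods
#> [1] -380
```

Charts mirror the three standard evaluation views:

```r
render_gauge(result, "gauge.svg")        # score on the banded scale
render_q_chart(result, "qchart.svg")     # Q-values, ordered by |Q|
render_system_grid(result, "grid.svg")   # (AS, PS) Cartesian grid
```

A command-line front end wraps the same functions
(`validate`, `assess`, `whatif`, `sweep`, `demo`):

```sh
Rscript inst/exec/rimeda demo --out demo
Rscript inst/exec/rimeda assess demo/toy3_model.yaml demo/toy3_assessment.yaml --out demo/report
```

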