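---
title: "Information-exchange networks in practice teams: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-exchange networks in practice teams: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(praxnet)
```

This vignette documents the statistical model behind `praxnet`, the
conventions and tunable parameters of each pipeline stage, what the
synthetic-cohort generator does and does not emulate, and the design
decisions taken where the methodology left room.

## 1. Data model

A *cohort* is a list of *practices*; a practice is a roster of *members*
(physicians and practice assistants — the closed vocabulary of German
primary-care teams; other role strings are rejected at parse time rather
than silently coerced, since the analysis is defined for these two roles
only). Each responding member carries, per condition (DM, CHD, CHF, in that
fixed order), the set of colleagues they nominate as weekly
information-exchange partners, the external occupational groups they mark
(a closed list of 13), and monthly cardiologist contact counts (CHD and CHF
only, 0–5). Non-respondents by definition carry no outgoing data but remain
nodes: their incoming nominations are observable and are the raw material
for reconstruction.

Cohorts serialize to a canonical nested JSON schema and to a flat CSV pair
(`members.csv` with one row per member and practice metadata repeated;
`nominations.csv` as a `practice_id, source_id, target_id, condition` edge
list). Both round-trip exactly, which the test suite checks property-style
on randomly generated cohorts.

## 2. From nominations to analysable networks

**Directed networks.** One per practice × condition. Nodes are *all*
members; ties originate only from respondents. An empty nomination set is
information (an isolated-out node), not missingness.

**Reciprocity gate.** Reciprocity is the edge-wise ratio: reciprocated
directed ties / assessable directed ties, where a tie is assessable only if
both endpoints responded — a non-respondent cannot return a nomination by
design, and counting such ties as unreciprocated would bias the measure
downward. The gate pools numerator and denominator over all conditions and
all practices admitted by the inclusion filter (the all-practice value is
also reported for transparency; the gated quantity is the one the analysis
itself will use). The pipeline proceeds to undirected networks only when
pooled reciprocity is *strictly* above the threshold (default 0.6); an
undefined value (no assessable ties) is an error, never a silent pass.

**Symmetrization.** The union (weak) rule: edge {a, b} iff a→b or b→a.
Two reasons. First, with reciprocity validated above the gate, a single
report is considered sufficient evidence of exchange. Second, union
symmetrization *is* the standard reconstruction for a single non-respondent:
their edges are exactly their incoming nominations. The intersection
(strong) rule is available (`symmetrize(net, "intersection")`,
`cmd_analyze(..., rule = "intersection")`) for sensitivity analyses; it is
not the default because it would erase every edge at a non-respondent.

**Inclusion filter.** At least three members and at most one non-respondent;
otherwise the reconstructed network would not represent the practice.
Inclusion is practice-level, since team size and response do not vary by
condition. When a practice violates both rules it is reported as
`too_few_members`: size is the more fundamental defect, and the two reasons
must be disjoint for exclusion bookkeeping to add up.

## 3. Network metrics

All four metrics are implemented natively on the package's own edge-list
representation (and cross-checked in the tests against brute-force
adjacency-matrix oracles and against igraph):

* *number of connections*: undirected edge count after symmetrization;
* *density*: |E| / (n(n−1)/2), defined for n ≥ 2;
* *degree centralization* (Freeman): Σᵢ(d_max − dᵢ) / ((n−1)(n−2)),
  defined for n ≥ 3; equals 1 exactly on a star and 0 whenever all degrees
  are equal — in particular density 1 forces centralization 0, the analytic
  identity that anchors the acceptance script;
* *reciprocity*: as in Section 2, per directed network; undefined (`NA`)
  when no tie is assessable.

Degenerate networks (n < 2 or n < 3 respectively) raise errors rather than
returning 0: a silent zero would let excluded practices leak into
summaries. The empty network returns density 0 and centralization 0 — both
well-defined, since all degrees are equal.

## 4. Typology

Density and centralization are banded low ≤ 0.33 < medium ≤ 0.67 < high,
with an absolute tolerance of 1e-9 at the thresholds so that rational
values such as 2/3 = 0.666… fall in the intended band. Bands are applied to
raw (unrounded) metric values. The four types are A = high density with low
centralization (fully connected networks flagged as the special case),
B = medium/medium, C = medium/low, D = low density (its centralization is
low as a practical consequence in observed teams, but the label does not
require it — a sparse star is still "hardly a network"). Two combinations
are deliberately *unmapped* rather than forced: medium density with high
centralization, and high density with medium centralization. The latter is
logically possible in small teams (a 4-member team missing one edge has
density 5/6 but centralization 1/3) and occurs regularly in
Erdős–Rényi-style simulations; forcing it into A would misstate the
hierarchy of such teams.

## 5. Cohort statistics

* Summaries use the sample SD (n−1), and median/IQR with the 25th–75th
  percentiles under linear interpolation (R's default type-7 quantile); the
  IQR convention is stated because the quantile rule is otherwise
  ambiguous. Reciprocity summaries skip undefined values and report the
  effective n.
* The *Friedman rank test* compares a metric across the three conditions
  within practices: mid-ranks per practice, statistic
  χ² = [12/(nk(k+1))]·ΣRⱼ² − 3n(k+1) divided by the tie-correction factor
  1 − Σ(t³−t)/(nk(k²−1)), with asymptotic χ²(k−1) p-values at α = 0.05.
  The tie correction matters here: density values tie often (many exactly
  1.0), and the uncorrected statistic would be systematically deflated.
  When all rows tie completely the statistic is 0 and p = 1. Asymptotic
  rather than exact p-values are used; at the cohort sizes in scope
  (n ≈ 25 practices) the null rejection rate at α = 0.05 is calibrated to
  0.05 within Monte-Carlo error, which the test suite verifies over 2,000
  simulated null cohorts. Practices missing a condition value are dropped
  with a warning.
* The density–centralization association is reported as the *Spearman*
  correlation (mid-ranks, product-moment on ranks, two-sided t
  approximation for p). Pearson is deliberately not offered for this
  output: the relationship is monotone but not linear, being bounded by the
  analytic identity at density 1.
* External-exchange percentages use responding *individuals* as the
  denominator (overall and stratified by role); cardiologist counts
  aggregate both at practice level (mean of member means) and by role.

## 6. The synthetic-cohort generator

No roster data of this kind are published, so the generator is the
package's testbed and stands in for a study cohort. Its defaults encode the
conditions the pipeline is designed for:

* 40 practices of 3–7 members, 1–2 physicians (a second physician with
  probability 0.32);
* directed DM nominations per ordered pair with base probability
  p = 0.6, one-way dyads returned with boost r = 0.2. Per unordered dyad
  this gives a mutual probability B = p² + 2p(1−p)r and one-way probability
  O = 2p(1−p)(1−r), hence an expected undirected density
  1 − (1−p)² = 0.84 and an expected tie reciprocity
  2B/(2B + O) ≈ 0.70 — a cohort that passes the 0.6 gate but not
  trivially;
* CHD ties as a Bernoulli(0.95) thinning of DM ties and CHF of CHD
  (expected connection totals decline by ~5% per step, and tie sets are
  nested CHF ⊆ CHD ⊆ DM by construction, so per-practice densities are
  ordered DM ≥ CHD ≥ CHF). Thinning reflects the view that
  disease-management programmes make diabetes the most widely shared
  condition, with heart-failure exchange a subset of the same channels.
  `retention = "independent"` switches nesting off for sensitivity checks;
* member non-response 0.1, roughly the non-response seen in analysable
  teams; non-respondents are generated like everyone else and their
  outgoing data then erased, so their incoming nominations survive exactly
  as in a real roster study;
* external-group marks concentrated on pharmacists and the two nursing
  groups (probability 0.5 each), rare elsewhere, never for occupational
  health physicians; cardiologist counts Binomial(5, p) with higher p for
  physicians (0.79/0.73 for CHD/CHF) than assistants (0.44/0.40), matching
  the observation that physicians hold most external specialist contacts.

Randomness is disciplined: each practice draws from its own sub-seed (an
affine function of the master seed and the practice index, kept below
2³¹), with a fixed draw order inside the practice (size, roles, hub,
metadata, DM dyads in row order — forward, backward, boost —, thinning,
non-response, externals, cardiologists). Consequently cohorts are exactly
reproducible and enlarging `n_practices` never perturbs earlier practices.

`expected_edge_probability()` gives the closed form of the undirected edge
probability implied by this draw order (the boost converts one-way dyads to
mutual ones and therefore cancels from the union; thinning maps a dyad
state (B, O) to (Bq², 2Bq(1−q) + Oq)). It is defined only without hub bias
and non-response, and the tests verify the generator against it within
three Monte-Carlo standard errors.

**Calibration to the four types** (`calibrate_to_bands()`): pilot Monte
Carlo fixed tie probability 0.95 for type A and 0.05 for type D, which
place well over 90% of practices of sizes 3–7 in the target type. The
medium-density types cannot be hit at that rate: the density and
centralization of 3–7-node graphs take few discrete values that straddle
the 0.33/0.67 boundaries, so no configuration concentrates 90% of mass in
a medium band. The calibration therefore targets the band *medians* for B
and C — B uses a low base tie probability (0.20) with one strong hub
(bias 3.5) to lift centralization into the medium band; C uses tie
probability 0.35 with larger teams (9–12 members, inside the overall
observed 2–15 range), whose relative degree variance, and hence
centralization, is naturally low. The tests assert ≥ 90% recovery for A
and D and median-band placement (plus modal-type) for B and C.

**What the generator does not emulate.** Real teams are more
degree-regular than an Erdős–Rényi-style tie model: everyone talks to the
practice's physician and to the assistant at the front desk, so observed
centralization at high density is lower than simulated. Two visible
consequences: simulated cohorts put a sizeable minority of high-density
networks into the unmapped high/medium cell that real data rarely occupy,
and mean centralization runs higher than in the study setting. Passing
tests on synthetic cohorts therefore demonstrate correctness of the
pipeline's bookkeeping and estimators, not that the generator reproduces
field data distributions. Role structure is also simplified (no "other"
staff categories), external marks are independent across members of a
practice, and metadata are drawn independently of network structure.

## 7. Numerical conventions and problem sizes

* Band boundaries: absolute tolerance 1e-9; `fully_connected` means
  density ≥ 1 − 1e-9.
* Undefined metrics raise errors (n < 2 / n < 3) or return `NA`
  (reciprocity with no assessable ties); downstream summaries and gates
  treat `NA` explicitly and never coerce it to 0.
* Ties in ranks: mid-ranks everywhere (Friedman, Spearman).
* The test suite runs its oracle comparison over 10⁴ random graphs on up
  to 6 nodes, the Friedman null calibration over 2,000 cohorts of 25
  practices, and generator checks on cohorts of 100–1,500 practices —
  sizes chosen so the whole suite completes in well under a minute while
  keeping Monte-Carlo error far below the asserted margins.

## 8. Known limitations

* The typology is threshold-based by design (no clustering alternative is
  offered), and band membership of values near 0.33/0.67 is sensitive to
  single edges in very small teams.
* Reconstruction handles exactly one non-respondent; practices with more
  are excluded rather than imputed — with 3–7 members there is too little
  signal to impute a second missing row defensibly.
* Asymptotic Friedman p-values are slightly conservative for n well below
  ~15 practices; an exact permutation variant is not implemented.
* The external-exchange and cardiologist modules are descriptive only; no
  inferential subgroup comparisons are attached to them.
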