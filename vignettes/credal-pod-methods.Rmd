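---
title: "Methods: credal networks, impact analysis and the place-of-death model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: credal networks, impact analysis and the place-of-death model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Most terminally ill cancer patients say they would prefer to die at
home, yet most die in institutions.  Understanding which factors drive
the place of death (POD) — treatment decisions, end-of-life
communication, patient and family awareness and preferences, the
family's capacity for home care, the professional home-care network —
is a causal question: one wants to know what would happen *if* a factor
were changed, not merely how factors co-occur.  Cohorts in this setting
are small (around a hundred charts), so a model estimated from data
alone would be hopelessly underdetermined.  The approach implemented
here combines a small amount of chart-review data with structured
expert knowledge, and is deliberately honest about how much the experts
actually know.

`credalpod` implements the two analysis tools this calls for:

1. a **discrete credal network** — a directed acyclic graph over
   categorical variables whose conditional tables are *sets* of
   distributions (specified by probability intervals and qualitative
   comparisons) rather than single distributions; and
2. a **naive Bayes classifier** predicting POD from chart features,
   used to sanity-check the causal model and to compare machine
   predictions with the care team's recorded expectations.

## Credal sets and their geometry

For one variable with states $1,\dots,k$ (given one configuration of
its parents), an expert provides intervals $[l_i, u_i]$ and optionally
comparative statements $p_a \ge p_b$.  The credal set is the polytope

$$K = \{\, p \in \Delta^{k-1} : l \le p \le u,\ p_a \ge p_b \,\}.$$

Three operations underpin everything else:

* **Coherence** (`check_coherence`): $K$ is non-empty for interval-only
  constraints iff $0 \le l_i \le u_i \le 1$ and
  $\sum_i l_i \le 1 \le \sum_i u_i$.
* **Reachability** (`normalize_reachable`): elicited bounds are
  tightened to $l_i' = \max(l_i,\, 1 - \sum_{j \ne i} u_j)$ and
  $u_i' = \min(u_i,\, 1 - \sum_{j \ne i} l_j)$, the exact per-coordinate
  min/max over $K$.  This changes no inference result but guarantees
  every printed bound is attainable, and it is idempotent.
* **Vertex enumeration** (`enumerate_vertices`): every vertex of $K$
  lies on $k-1$ linearly independent facets besides the simplex
  hyperplane, so all $\binom{m}{k-1}$ active sets are solved and
  feasibility-filtered.  This is combinatorial in $k$, which is why the
  number of states per credal set is capped (default 6, a deliberate
  hard error rather than silent truncation; the POD model's largest
  variable has 4 states).  Duplicate solutions are merged at an
  absolute tolerance of `1e-9` — far above double-precision noise for
  $k \le 6$, far below any elicitable difference.  Coordinates within
  the same tolerance of 0 or 1 are snapped before renormalisation so
  that point masses are exact and zero-probability evidence is detected
  exactly.

Feasibility of a credal set is decided by the enumeration itself: a
non-empty bounded polytope always has a vertex, so "no vertex found" is
a proof of emptiness.  This avoids carrying a linear-programming
dependency for a question the enumerator already answers exactly; an
empty credal set is always an error, never an empty vertex list.

## Elicitation

Experts rarely produce numbers directly.  The package translates three
judgment kinds into constraints: numeric intervals, verbal terms, and
comparatives.  The shipped verbal scale (a JSON config, editable
without touching code) is

| term | interval |
|---|---|
| impossible | [0, 0] |
| very improbable | [0, 0.10] |
| improbable | [0.05, 0.35] |
| as probable as not | [0.45, 0.55] |
| probable | [0.65, 0.95] |
| very probable | [0.80, 1.00] |
| certain | [1, 1] |

The calibration is a package default, chosen symmetric and overlapping;
any study using its own scale should ship its own config.  States with
no judgment get the vacuous interval $[0,1]$: imprecision, not an
invented uniform.  Compiled judgment sets are reachability-tightened,
and contradictions are rejected with the conflicting constraints named.
Judgments apply per parent configuration; cross-row constraints are out
of scope.

## Inference: the strong extension

A credal network induces its *strong extension*: every (variable,
parent configuration) picks one distribution from its credal set,
independently, giving an ordinary Bayesian network; a query
$P(T = t \mid e)$ is answered by the interval
$[\underline{P}, \overline{P}]$ of min and max posteriors over all such
selections.  The posterior is a ratio of multilinear functions of each
table's choice, so the extrema are attained at credal-set vertices;
optimisation therefore runs over one vertex per table (and a test
verifies this empirically against interior sampling rather than taking
it on faith).

Each candidate selection is evaluated by exact variable elimination.
Because the optimiser evaluates thousands of selections on a fixed
query, the elimination schedule is *compiled once per query* into
integer gather-index vectors; an evaluation is then pure vectorised
arithmetic (about 3 ms on the full 20-variable POD model, versus ~40 ms
for a naive factor-algebra walk-through).

Two regimes:

* **Exact**: if the product of per-table vertex counts is at most
  `exact_budget` (default 10,000), all combinations are enumerated and
  the result is flagged `exact = TRUE`.  The default is sized so that
  an exact query stays in the seconds range on one core; it is a
  configuration knob, not a truth parameter — raising it never changes
  a result, only how often enumeration is chosen over search.
* **Local search**: beyond the budget, seeded greedy coordinate descent
  over single-vertex swaps (each coordinate moves to its best
  alternative immediately; sweeps repeat until no swap improves), with
  8 random restarts by default.  Descent of this kind converges in 2–3
  sweeps on the POD model; restarts guard against local optima, and
  results are flagged `exact = FALSE` and are *inner* approximations —
  the true interval can only be wider, never narrower, so containment
  guarantees are preserved.  All randomness flows from the single
  configured seed; two runs with the same seed are bit-identical.

Coordinates that cannot matter are pruned before search: barren
descendants of the query variables are removed, and a table row whose
parent configuration contradicts an evidence- or do-fixed parent is
sliced away by conditioning and never enters the computation.

**Zero-probability evidence.**  If the evidence has probability zero
for *every* selection, conditioning is an error.  If only *some*
selections kill the evidence, the bounds are taken over selections that
give it positive probability — regular-extension behaviour — and the
result is flagged.  The alternative (vacuous $[0,1]$) would silently
destroy every query touching a rare state, such as conditioning on a
nursing-home preference that one table vertex assigns probability zero.

**Interventions.**  `do`-assignments mutilate the graph: the intervened
variable loses its parents and receives a point mass.  For root
variables with no upstream evidence this provably coincides with plain
conditioning, and a property test holds the engine to that to 1e-12.
Whether a manipulation should be modelled as `do` or as observation is
a genuine modelling choice; both are exposed, each packaged scenario
records its mode, and intervention is the default because policy
questions ("what if a palliative home-care service were involved?") are
interventional.

## The impact statistic

The effect measure reported throughout is the *impact* of a manipulated
variable $A$ on a target state: for every ordered state pair
$(a, a')$,

$$\Delta(a, a') = \underline{P}(T = t \mid A = a) -
  \underline{P}(T = t \mid A = a'),$$

computed on **lower** bounds (a rise in the guaranteed probability is
the conservative reading of an effect under imprecision), with the
headline impact $\max_{a,a'} |\Delta(a,a')|$ expressed in percentage
points.  The max-over-pairs aggregation is this package's declared
definition of a single-number impact; per-pair breakdowns are always
returned alongside.  Display rounds to whole points; the raw float is
kept.

## The packaged place-of-death model

`load_reference_model()` ships a 20-variable network wired as the study
narrative describes: cancer treatment drives end-of-life communication,
which drives patient and family awareness; awareness drives whether
preferences are assessed at all; treatment and symptom burden drive
hospital days; family structure, awareness, dependence, symptoms and
economic resources drive the family's conditions for home care, which
drive the family's preference; five service variables aggregate into a
home-care-network strength; and place of death depends on family
preference, patient preference, hospital days, the care network and
the area of residence.

Two things matter about its numbers:

* **Every table is labelled `"illustrative"`.**  The study's elicited
  tables were never published; the shipped intervals are
  package-authored values chosen to be qualitatively consistent with
  the published narrative (family preference dominant, ongoing
  treatment suppressing communication, and so on).  They are data
  files, not code: replacing them with real elicited values requires no
  code change.  Published effect sizes appear only as `reported`
  annotations printed *beside* computed values, never asserted.
* **"Not assessed" is a state, not a missing marker, in the network.**
  Unknown preferences are a clinically meaningful condition — the
  study reasons about patients whose preferences were never elicited —
  so `patient_preference`, `family_preference`, both awareness
  variables and `family_conditions` carry an explicit `not_assessed`
  state matching the cohort vocabulary.

The network file uses partial-row defaults (a `{}` row plus
increasingly specific exceptions, last match wins), which keeps a
341-configuration model hand-auditable in ~12 kB; parsing expands rows,
and serialisation writes the expanded form, so round trips are
semantically loss-free.

## The classifier

`fit_naive_bayes` is a categorical naive Bayes with smoothing weight
$\alpha$ (default 1, Laplace; recorded in the serialized model):
priors $(n_c + \alpha)/(n + \alpha K)$ and conditionals
$(n_{fc} + \alpha)/(n_c + \alpha K_f)$.  For the *classifier*,
"not assessed"/"not available" are treated as missing and skipped —
a record missing a feature still contributes its other features, and
prediction multiplies conditionals over present features only, so a
fully missing record falls back on the prior.  (The credal network
treats the same labels as states; the two tools model missingness
differently on purpose, and the model-driven recovery tests fit with an
empty missing-marker list because sampled cohorts are fully observed.)
Day-count columns are pre-binned by a config: hospital days 0 / 1–14 /
>14 — aligning with the network's `hospital_days` variable — and the
assessment interval at sample tertiles.  Ties in the posterior argmax
break by canonical class order.  Because the study does not state its
validation protocol, evaluation reports both in-sample and
leave-one-out accuracy, beside the care-team baseline column; LOOCV
refits share the full model's level vocabulary so a singleton level
(one nursing-home preference in 116 records) cannot crash a fold.

## The synthetic cohort generator

The study deposited no data, so the generator is the package's ground
truth substrate, in two modes:

* **Marginal-faithful** (`generate_marginal_cohort`): reproduces the
  published per-column summary *exactly* — exact categorical counts,
  exact integer means with ranges.  Integer columns are constructed
  deterministically: fill with the floor of the mean, pin the printed
  min and max once each, spread the residual in ±1 layers, then
  shuffle.  Columns are shuffled independently, so **cross-column
  joints are random by design**: the published table gives no joint
  distribution, and any cross-tabulated claim in prose is deliberately
  untestable in this mode.  Consequently, passing classifier runs on
  marginal cohorts exercise the machinery (missing handling, LOOCV,
  baselines), not real signal — feature–label associations are noise.
  Columns whose printed range is an observation window rather than an
  observed extreme (the 0–60 place-of-care day counts) do not pin the
  extremes; a mean of 0 cannot attain a maximum of 60.  The published
  tumour-site counts sum to 115 of 116; the remaining record is
  generated as missing rather than inflating a printed count.
* **Model-driven** (`generate_model_cohort`): picks one distribution
  per table from the reference model (vertex rules: lower/upper corner,
  random vertex, or the vertex centroid as a midpoint) and ancestrally
  samples records, returning the chosen Bayesian network alongside so
  recovery tests can compare fitted against true parameters.  These
  cohorts *do* carry dependence structure.

Both modes are bit-reproducible from their seed, and cohorts embed
their generation metadata (mode, seed, spec hash).

## Problem sizes and numerical choices in the test suite

The suite checks geometry against an independent bound-assignment
vertex oracle on 500 random interval specs ($k \le 4$); inference
against full joint-outcome × vertex-combination brute force on 100
random networks of up to 5 nodes (vertex products capped near 2,500 to
keep the oracle exhaustive), with 1,000 sampled Bayesian-vertex
posteriors per query contained in the reported interval; Bayesian
reduction and root do/observe equivalence at 1e-12 on 100 point
networks; classifier recovery on a 10,000-record model-driven cohort;
and bit-identical double runs of every packaged scenario.  These sizes
were chosen to exercise each guarantee at full strength while a
complete run stays in the minutes range on one core.

## Known limitations

* The shipped POD tables are illustrative; no numeric agreement with
  the study's published interval results is claimed or tested, and the
  printed `reported` annotations exist precisely to keep that
  comparison visible and honest.
* Approximate bounds are inner approximations; for decisions that
  hinge on an interval endpoint, rerun with a larger `exact_budget` or
  more restarts.
* Credal sets are intervals plus pairwise orderings; general linear
  constraints, continuous variables, and imprecise-Dirichlet ("naive
  credal") classification are out of scope.
* The impact statistic compares lower bounds only; upper-bound or
  width-based effect measures would be easy to add but are not what the
  analysis reports.
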