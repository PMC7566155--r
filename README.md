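# credalpod

Credal networks and naive Bayes classification for exploring the
determinants of cancer patients' place of death (POD).

Most terminally ill cancer patients would prefer to die at home; most
die in institutions.  Asking *why* — and what a care system could
change — is a causal question posed with very little data: a regional
cohort of ~116 chart reviews cannot identify a twenty-variable joint
distribution.  `credalpod` implements the analysis stack for this
setting: a **discrete credal network** built from expert-elicited
probability intervals and qualitative judgments, queried for
interval-valued posteriors, interventions and effect sizes, plus a
**naive Bayes classifier** learned from the chart-review features, and
a **synthetic cohort generator** that reproduces a published summary
table exactly so the whole pipeline is testable without any private
data.

## The model in brief

A credal network is a DAG over discrete variables where each
(variable, parent-configuration) carries a *credal set*
`K = {p : sum(p)=1, l ≤ p ≤ u, p_a ≥ p_b}` — probability intervals
plus optional comparative judgments — instead of one distribution.
Queries are answered under the **strong extension**: one distribution
is chosen per table, independently, and the reported interval

    [ min P(T=t | e),  max P(T=t | e) ]

is taken over all such choices.  Extrema occur at credal-set vertices
(the posterior is a ratio of multilinear forms), so the engine
enumerates vertices exactly (`enumerate_vertices`), combines them
exhaustively when the combination count is within budget, and
otherwise runs seeded coordinate-descent over single-vertex swaps,
flagged as an inner approximation.  Interventions use graph mutilation
(`do`-calculus); conditioning on evidence that only some vertex
choices make impossible follows the regular extension and is flagged.
The headline effect measure is the **impact** of a manipulated
variable: the largest pairwise difference in *lower* posterior
probability of the target state, in percentage points.

## Worked example

```r
library(credalpod)

net <- load_reference_model()   # packaged POD network (illustrative tables)
net
#> Credal network: 20 variables, 22 arcs, 341 conditional credal sets
#> Interval-valued tables present

## How much does a family's preference for home move the home-death bound?
posterior_bounds(net, c(place_of_death = "home"),
                 evidence = c(family_preference = "home"),
                 control = bounds_control(seed = 1))
#> P(place_of_death = home | family_preference=home) in [0.3870, 0.4448] (inner approximation)

## Interventional effect of treatment status on open end-of-life communication
impact(net, c(eol_communication = "open"), "cancer_treatment", mode = "do")
#> Impact of cancer_treatment on P(eol_communication = open) [do mode]: 40 percentage points
#> lower bounds by state:
#>   ongoing          0.2000
#>   discontinued     0.6000

## A cohort reproducing the published 116-patient summary, and a classifier
co <- generate_marginal_cohort(table1_spec(), seed = 1)
sum(co$place_of_death == "home")          # 21, exactly as printed
mean(co$assessment_to_death_days)         # 38, exactly as printed
nb <- fit_naive_bayes(discretize_cohort(co), "place_of_death",
                      c("symptom_burden", "family_preference", "hospital_days"))
predict(nb, data.frame(symptom_burden = "none_low",
                       family_preference = "home"), type = "prob")
#>           home  hospital nursing_home
#> [1,] 0.2043718 0.5949722     0.200656
```

The first interval says: under every distribution the elicited
constraints allow, a family preference for home puts the probability
of a home death between 0.39 and 0.44 under the packaged illustrative
tables — the width is what the model honestly does not know.  The
impact line reads the same way: moving treatment from ongoing to
discontinued raises the guaranteed probability of open end-of-life
communication by 40 percentage points.  The classifier's posterior is
learned from a marginal-faithful cohort whose cross-column joints are
random by construction, so it demonstrates the machinery, not clinical
signal (see the methods vignette).

Packaged scenario decks mirror the study's query classes and print
computed bounds beside the study's published figures as annotations:

```r
run_scenario(net, "family-preference-pod", control = bounds_control(seed = 1))
```

A command-line interface wraps the same functions
(`inst/cli/credalpod`): subcommands `validate`, `infer`, `intervene`,
`impact`, `run-scenario`, `fit-nb`, `predict`, `evaluate`, `simulate`,
`summarize`.

**Important**: the shipped POD network's tables are *illustrative*
values, labelled as such in the model file — the study's elicited
tables were never published.  Structure and vocabularies follow the
study; the numbers are qualitatively consistent stand-ins stored as
data so real elicited values can be dropped in without code changes.

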