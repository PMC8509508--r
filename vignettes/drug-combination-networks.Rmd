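---
title: "Drug co-reporting networks from spontaneous case reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug co-reporting networks from spontaneous case reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icsrnet)
```

## The problem

Spontaneous-reporting pharmacovigilance databases collect individual case
safety reports (ICSRs): one report lists a patient's demographics and the
drugs they were taking when an adverse event occurred. Classical signal
detection screens one drug at a time, which is blind to combination effects.
`icsrnet` analyses *combinations*: which drug pairs and triads are
co-reported more often than chance, and which groups of drugs form densely
connected co-prescription communities in the co-reporting network. The
motivating application is acute generalized exanthematous pustulosis (AGEP),
a rare severe cutaneous drug reaction for which polypharmacy, particularly
cardiovascular drugs combined with antibiotics, is a candidate risk pattern.

## The inclusion cascade

`apply_exclusions()` reproduces the standard report-inclusion flowchart, in
this order:

1. drop reports flagged as possible duplicates;
2. drop drug entries whose name is unknown or cannot be assigned an ATC
   code, and collapse repeated ingredients within a report to a set;
3. keep only reports with at least two distinct mapped drugs.

The counters of each stage are kept on the returned `icsr_set` (`flow_table()`).
Two deliberately simple conventions: within-report drug lists are *sets*, so
a pair can contribute at most once per report (the only reading under which
pair prevalences are coherent with marginal prevalences); and the drug role
(suspected / interacting / concomitant) is carried as metadata but never
filtered on, since restricting to suspect drugs would discard most of the
combination signal. When one ingredient maps to several ATC codes the
lexicographically smallest code is chosen, deterministically and with a
warning — any fixed rule would do, but this one needs no external priority
list.

## Observed-to-expected ratios

For a pair or triad of drugs with marginal report counts $n_1, \dots, n_k$
in a cohort of $N$ reports, the observed prevalence is $n_{obs}/N$ and the
expected prevalence under independence is the product of marginal
prevalences $\prod_i n_i/N$, giving

$$\mathrm{O/E} \;=\; \frac{n_{obs}/N}{\prod_{i} n_i/N}
  \;=\; \frac{n_{obs}\,N^{k-1}}{\prod_i n_i}.$$

All quantities share the *same* denominator $N$, the retained ($\geq 2$
drugs) cohort — this is the only convention under which observed, expected
and O/E columns of a summary table stay mutually consistent. O/E is reported
as a raw point estimate: no confidence interval, no shrinkage, no
multiple-testing correction. This matches its exploratory,
hypothesis-generating role; `oe_permutation_null()` offers an optional
permutation check of the null spread. Ratios are computed on unrounded
values; `round_half_up()` is applied only for display (exact halves round
away from zero, so 2.285 prints as 2.29).

A structural caveat that the test suite makes explicit: in any cohort where
every report must contain drugs (there is no such thing as an empty report),
prevalences are implicitly conditioned on report non-emptiness. For two
therapy blocks that jointly cover the cohort, the cross-block O/E converges
not to 1 but to $P(\text{report activates} \geq 1 \text{ block})$, which is
strictly below 1. O/E ratios of drugs from unrelated regimens should
therefore be expected to sit slightly *below* 1 even without any protective
effect.

## The co-reporting network

`build_graph()` returns an undirected weighted `igraph`: nodes are drugs
(attributes: report count, prevalence, ATC-1 anatomical main group), an edge
joins two drugs co-listed in at least one report, and the edge weight is the
pair count. Node identity is the normalized ingredient name, not the ATC
code (distinct drugs share ATC groups); ATC-1 is carried as the colour key
for external viewers. Edge weights are raw co-report counts — O/E is
attached as an extra edge attribute but never drives the topology. Exports
(`export_graph()`) cover GraphML, GEXF 1.2 and an edge-list CSV; layout and
rendering are left to dedicated tools such as Gephi. No edge pruning is
applied by default; `filter_graph()` exposes thresholds for display
purposes.

## Community detection

Both clustering methods are implemented in the package rather than
delegated, because their behaviour is the analytical core; the igraph
implementations serve as independent cross-checks in the tests.

**Modularity.** For weighted adjacency $A$, weighted degrees $k_i$, total
edge weight $m$ and resolution $\gamma$:
$$Q = \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \gamma\frac{k_ik_j}{2m}\Big]
  \delta(c_i, c_j).$$
Self-loops (which appear in aggregated super-graphs) count twice on the
diagonal, keeping $Q$ consistent across aggregation levels.

**Louvain** (`louvain_communities()`): the classic two-phase greedy scheme —
local moves of single nodes to the neighbouring community with the largest
gain $w_{i\to C} - \gamma k_i \Sigma_{tot}(C)/2m$, then aggregation of
communities into a weighted super-graph with self-loops, repeated until no
further $Q$ gain. Ties between equal-gain moves go to the smallest community
label; the node visiting order is shuffled once per pass from a caller
seed, so a run is fully reproducible. The resolution parameter defaults to 1
(classic modularity) and is exposed only for exploration.

**Leading eigenvector** (`leading_eigen_communities()`): recursive spectral
bisection of the (generalized) modularity matrix
$B^{(g)}_{ij} = B_{ij} - \delta_{ij}\sum_{k \in g} B_{ik}$, splitting each
group by the sign pattern of the dominant eigenvector, followed by the
method's Kernighan-Lin-style fine-tuning sweep (greedy single-vertex flips,
keeping the best intermediate state). A split is kept only if the leading
eigenvalue exceeds the solver tolerance (`1e-9`) *and* the split increases
total $Q$ (by more than `1e-12`); otherwise the group is declared
indivisible. The eigenvector sign is fixed by making its largest-magnitude
component positive, so the method is deterministic, and negating the vector
yields the same bipartition. Without the fine-tuning stage, sign-splitting
alone routinely lands a few percent below the attainable optimum on small
graphs — the package's oracle tests (exhaustive maximization over all
partitions of up to 8 nodes) measure both methods against the true maximum.

Disconnected graphs need no special handling: components separate naturally
under both schemes. Stratified reruns (`stratified_analysis()`) split by sex
or by age at 65. The age boundary is a documented choice: strata are
"< 65" versus "$\geq$ 65", so a 65-year-old belongs to the older group;
reports with unknown sex or age are excluded from their stratification only.

## Descriptive tables

`demographics_table()` produces the cohort summary: counts and percentages
for categorical characteristics, mean (SD) and median (IQR) for age and
drugs per report, with Pearson chi-squared tests for categorical
comparisons and Welch two-sample t-tests for numeric ones. Welch is used
because the equal-variance assumption buys nothing here and the conservative
default is preferable; for degenerate constant inputs with equal means the
p-value is defined as 1. Percentage denominators are per characteristic:
reporter-type percentages use the known-reporter total (reporter is missing
frequently and non-randomly), other categorical rows use the stratum size.
Tests always run on raw counts; rounding is display-only.

## The synthetic cohort generator

Real spontaneous-report data cannot be redistributed, so validation uses
`simulate_icsr()`. Its mechanism mirrors what the analysis assumes about
such data:

- **Therapy profiles** (`therapy_profile()`): blocks of co-prescribed drugs.
  A report activates each profile independently; an active profile includes
  each member drug with its inclusion probability. Profiles are the planted
  communities.
- **Background noise**: every universe drug can additionally enter any
  report with a small `background_rate`, which is the only source of
  cross-profile pairs when profiles are disjoint.
- **Polypharmacy frailty**: a per-report gamma multiplier (mean 1) on
  activation odds. This produces the overdispersed, heavy-tailed
  drugs-per-report distribution that real cohorts show (median 3 but mean
  above 4); independent profile draws alone are too Poisson-like.
- **Non-empty reports**: drug sets are redrawn until non-empty (capped at
  100 attempts, then one uniformly chosen profile is forced). An empty
  "report" is not an observable object in spontaneous reporting.
- **Noise for the filters**: a configured fraction of reports are flagged
  near-copies (duplicates), and a configured fraction of drug entries have
  their name replaced by an unmappable token. The ground-truth object keeps
  the marks so tests can verify the filters undo exactly the noise.

All draws flow from one seed in a documented order, so output is
byte-reproducible.

`default_agep_config()` is the package's standing cohort: 66 drugs with
real ATC codes, eight overlapping profiles (acute infection, hospital
antibiotics, cardiovascular, gastroprotection, neuropsychiatric, metabolic,
oncology, analgesia), demographics matching a large international
severe-cutaneous-reaction cohort (59.3% female, mean age 57.3, ~92% serious,
2.5% fatal), 2% duplicates and 2% unmappable names. The drug-load knobs were
fixed once, by pilot calibration (`calibrate_inclusion()` bisection plus a
grid over the frailty shape), so that the *retained* cohort shows median 3
(IQR 2-5) drugs per report and roughly 44% of extracted reports survive the
cascade; the selected values are an inclusion scale of 1.70 and a frailty
shape of 0.28, baked into the defaults and not revisited. What the generator
does *not* emulate: reporting trends over time, country-level reporting
heterogeneity, MedDRA coding, or correlation between demographics and
specific regimens (an optional age-dependent fatality rate is available but
off by default). Passing tests on synthetic cohorts therefore validate the
*pipeline arithmetic and the recoverability of planted structure*, not any
clinical claim about real data.

## Validation design and problem sizes

The test suite exercises, among others:

- every checkable row of the published pair/triad summary-table arithmetic
  (printed marginal counts as inputs, 2-decimal agreement of observed,
  expected and O/E columns);
- exhaustive-oracle tests: on random weighted graphs of up to 8 nodes
  (Bell(8) = 4140 partitions), both clustering methods must reach at least
  95% of the true maximum modularity, and the two-triangle bridge graph must
  yield exactly $Q = 5/14$;
- planted-community recovery on a 5000-report two-profile cohort
  (inclusion 0.8, activation 0.5, background 0.005): both methods must
  recover the planted drug partition with adjusted Rand index $\geq 0.9$,
  and within-profile pair O/E must exceed 1. The companion cross-profile
  assertion (mean O/E within three standard errors of 1) documents the
  non-emptiness conditioning described above: the measured mean sits near
  $P(\geq 1\ \text{profile}) \approx 0.78$, and the test records that gap
  rather than widening the tolerance;
- a brute-force double-loop pair/triad counter as an independent oracle on a
  200-report cohort, and an independence-null calibration on a 50,000-report
  profile-free cohort of common drugs;
- a 20-report hand-built cascade fixture with known per-stage exclusions.

Simulation sizes (500-5983 reports for pipeline tests, 50,000 for
convergence checks) were chosen to keep the default test run fast while
leaving Monte-Carlo noise well inside the asserted tolerances.

## Known limitations

- O/E point estimates carry no uncertainty statement; with hundreds of
  pairs, some large ratios among rare combinations are expected by chance.
- Modularity methods inherit modularity's resolution limit; very small
  regimens attached to a large cluster may not separate.
- The ATC tie-break (smallest code) is arbitrary where a true
  indication-specific code would be preferable.
- The generator's demographics are independent of its drug profiles, so
  stratified analyses on synthetic data differ between strata only by
  sampling noise.
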