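---
title: "Methods: evolutionary decision lists for two-class expression data"
author: "rulemine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary decision lists for two-class expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two-class gene-expression studies (tumour vs. control, one disease subtype
vs. another) routinely need three things at once: a classifier whose
decisions a biologist can read, a compact set of genes worth following up,
and an honest estimate of how well either generalizes. `rulemine` addresses
all three with *decision lists over expression intervals*: ordered rules of
the form

```
Exp(HPN) in [210.5, 297.3] AND Exp(NELL2) in [17.2, 132.8] -> tumour
...
DEFAULT -> control
```

evaluated by first match and closed by a default rule, so every sample
receives a prediction. Interval predicates are closed on both ends; a value
exactly on a bound matches. A conjunctive rule points to a potential joint
pattern between genes, a one-predicate rule to up-/down-regulation of a
single gene, and the relative width of an interval indicates how robust a
class assignment is.

## The two learners

**Iterative rule learning (`biohel_learn`).** Separate-and-conquer: starting
from the full training set, a generational genetic algorithm evolves the
single best rule for the examples not yet covered; the rule is appended, the
examples it matches are removed, and the loop repeats until the remainder is
empty or single-class or no usable rule can be found (accuracy below
`min_rule_accuracy`, default 0.5, or zero coverage). The list is closed by a
default rule predicting the majority class of the remaining examples. Each
accepted rule covers at least one example, so the loop terminates within
`n` iterations.

The fitness of a candidate rule on the current example set combines the
three desiderata of accuracy, coverage and simplicity. With coverage
`cov` (fraction of examples matched) and accuracy `acc` (fraction of matched
examples with the rule's class),

```
CT(cov)  = cov / CB                  if cov <  CB
         = 1 + w * (cov - CB)       if cov >= CB
fitness  = acc * CT - lambda * (number of predicates)
```

The coverage term rises steeply up to the breakpoint `CB` (default 0.25) and
only gently beyond it (slope `w`, default 0.1, continuous at `CB`): a rule is
strongly rewarded for covering a minimum share of the examples, but extra
coverage beyond the breakpoint cannot compensate for lost accuracy. The
complexity penalty `lambda` (default 0.001) breaks ties toward shorter
rules. The breakpoint form honours the published behaviour of
minimum-description-length-based rule fitness in this family of learners;
the exact constants are deliberately configurable because the precise
published formula lives in a separate technical reference.

**Pittsburgh-style evolution (`gassist_learn`).** Here each GA individual is
a complete decision list (1 to `max_rules` rules plus the default, which is
fixed to the training majority class). Fitness is training accuracy minus
`lambda` times the total predicate count; crossover exchanges contiguous
rule blocks between two parents; mutation edits a random rule, inserts a
freshly seeded rule, or deletes one. This learner tends to shine on smaller
problems, the iterative learner on larger ones.

**Shared GA machinery.** Tournament selection (size 4), one-point crossover
on predicate collections (probability 0.6), mutation (probability 0.6) that
first perturbs a random bound by a tenth of the gene's observed range and
then either *generalizes* (drops a predicate or widens a bound to the
observed extreme) or *specializes* (adds a predicate centred on a matched
example, or narrows a bound toward the interval midpoint), each with
probability 0.5; elitism of one. Initial rules are seeded from randomly
drawn training examples: up to `max_init_predicates` (default 3) predicates
whose intervals span `init_fraction` (default 0.5) of the gene's observed
range around the example's value, predicting the example's class. Seeding
from examples guarantees the initial population already matches data, which
is what makes small GA budgets workable. All randomness flows through R's
RNG, so every learner is a pure function of (data, parameters, seed).

**Ensembles.** Because the GA is stochastic, `train_ensemble` repeats
learning with consecutive seeds (default 100 members) and
`ensemble_predict` takes a majority vote. An exact vote tie goes to the
class with higher training prevalence, then to the lexicographically first
class — ties must be broken somehow and this rule is deterministic and
favours the prior. `attribute_frequency` turns trained ensembles into a gene
ranking: the percentage of non-default rules (across members and CV cycles)
carrying a predicate on each gene. The denominator is the total number of
non-default rules; the published tables do not pin this choice down, and
rules-as-denominator makes scores comparable across ensembles of different
sizes.

## Feature selection

All selectors cap subsets at 30 genes (`max_size`), the usual upper bound
for the number of informative probes in microarray studies, and may return
fewer.

* **`plss_rank`** ranks genes by the two-group ANOVA F statistic (equal to
  the squared pooled-variance t). This ordering is provably equivalent to
  ordering by the absolute first-component weights of a partial-least-squares
  fit on standardized predictors — the origin of the PLSS name. We compute
  the F statistic directly and enforce the equivalence in a test against an
  independent PLS (SIMPLS) implementation rather than implementing PLS
  twice. A constant gene scores 0; a perfect separator scores `Inf` and
  ranks first; all ties break by gene identifier.
* **`cfs_select`** scores subsets by the CFS merit
  `k * r_cf / sqrt(k + k(k-1) * r_ff)` and explores them with greedy
  best-first search (stop after 5 consecutive non-improving expansions —
  the classic default; the source material is silent). The original CFS
  discretizes data and uses symmetrical uncertainty; since expression values
  are continuous we use absolute Pearson correlation (point-biserial against
  a 0/1 class code) for `r_cf` and absolute Pearson for `r_ff`. With
  `r_ff = 0` the merit grows as `sqrt(k)`; with `r_ff = 1` it is flat in
  `k`, which is exactly the redundancy penalty the redundant blocks of the
  synthetic generator exercise.
* **`rfs_rank`** ranks genes by mean decrease in Gini impurity from a
  `randomForest` fit (500 trees, `sqrt(p)` candidate split variables —
  package defaults, the source material states neither). The companion
  `select_top_k` takes the top `k`, conventionally matched to the CFS subset
  size on the same fold.

`consensus_selection` implements the "Ensemble FS" idea: per method, rank
genes by the number of CV folds in which they were selected, keep the
`top_k` most frequent, and return genes appearing in at least
`min_methods` (default 2) of those lists, annotated with their method count.

## Evaluation protocol

`external_cv` runs *two-level external cross-validation*: the selector is
re-fit on every training fold (external level), and plugin classifiers can
tune hyperparameters by a nested stratified grid search on the training fold
only (`nested_param_search`, inner 5-fold by default — the inner fold count
is our choice). The harness API only ever passes training rows to the
selector and the classifier, so test-fold leakage cannot be expressed
through it. Fold plans are seeded and stratified (per-class fold sizes
differ by at most one); one plan is shared across all method combinations
of a comparison so that splits are consistent. Accuracies are reported as
AVG (mean per-fold accuracy, percent) and STDDEV (sample SD over folds);
leave-one-out folds score 0 or 100, which is why LOOCV standard deviations
are large by construction.

`friedman_average_ranks` compares methods across blocks (dataset × selector
or dataset × classifier combinations): within each block methods are ranked
by decreasing accuracy with mid-ranks for ties (rank 1 = best; both choices
are required to reproduce the published rank tables), and the tie-corrected
Friedman chi-square is reported. `holm_adjust` applies the Holm step-down to
pairwise post-hoc p-values. The package ships the published benchmark
accuracy tables for three cancer microarray datasets
(`benchmark_accuracies`) as worked input; the 10-fold CFS selector cell of
the published selector comparison is internally inconsistent (the printed
row sums to 6.1, while three average ranks must sum to 6.0) and our
recomputation of that single cell yields 2.2, so it is not used as a
reference value.

## Literature-mining prioritization

For a gene set and a disease term, `pmi` computes pointwise mutual
information `log2( f(x,y) / (f(x) f(y)) )` over document relative
frequencies from a counts table (`corpus_counts`); base 2 is cosmetic since
set scores scale by a positive constant and permutation p-values are
invariant to the base. A zero frequency anywhere makes the association
undefined; the sentinel, like a negative PMI, contributes 0 to
`gene_set_pmi_score` — the magnitude of rare negative associations is
dominated by sampling noise, so they are treated as irrelevant rather than
as evidence against. No smoothing is applied by default.
`permutation_pvalue` compares the observed positive-PMI sum with 100
matched-size gene sets drawn uniformly without replacement from the
platform universe; the p-value is the fraction of random sets scoring
*strictly* higher, which makes an exact 0.00 possible at 100 permutations
(the `(r+1)/(n+1)` estimator is easy to apply downstream if preferred, but
the strict-proportion convention is what the reported significance grids
use).

## The synthetic generator

`generate_expression` emulates the *structure* of two-class microarray
data: Gaussian background of SD `noise_sd`, a planted set of informative
genes shifted by `effect` noise-SD units in the case class, optional
redundant blocks correlated with an informative parent at `block_rho`
(specifically there to test the CFS redundancy penalty), and an optional
perfectly separable marker. Defaults — 50 + 50 samples, 200 genes, 10
informative at effect 2 — are the desk-scale analogue of the benchmark
datasets (roughly a hundred samples, thousands of genes, a small
informative core): large enough that selectors and learners behave
qualitatively like on real data, small enough for routine testing. The
generator does **not** emulate probe-level artifacts, heavy-tailed or
platform-specific intensity distributions, batch effects, or
normalization — passing tests demonstrate correct algorithmic behaviour
under the planted-signal model, not performance on any particular real
dataset.

`generate_corpus` simulates documents independently: every term occurs at
`base_rate` per document, and planted gene–disease pairs have their joint
probability lifted by `assoc_lift` (capped at a valid probability with a
warning) while preserving marginals. Counts are document counts, so the
relative frequencies entering the PMI are exactly `count / n_docs`.

## Numerical and scale choices

* Rule-text serialization writes bounds with 17 significant digits so
  write/read round trips are bit-exact.
* Learner defaults follow the published setup where stated: 500 GA
  iterations, generalize/specialize probabilities 0.5, 100-member
  ensembles, at most 30 genes per rule set. Population size, tournament
  size and operator probabilities are unstated there; the defaults above
  were chosen for robustness and all live in `learner_params`.
* The package's own tests and the acceptance script run the desk-scale
  configuration (population 100, 100 generations, 25-member ensembles, 10
  replicates of 10-fold CV on the default generator) — sizes chosen so the
  whole suite completes in minutes on a single core while leaving the
  evolutionary search enough budget to solve the planted problems reliably.
* Degenerate inputs: constant genes get F = 0 and zero CFS correlation;
  single-class training data yields a default-only list with a warning; an
  empty consensus or an ensemble without non-default rules warns and
  returns an empty result.

## Known limitations

Two-class problems only (the benchmark studies are all two-class);
multi-class would need one-vs-rest voting and a different default-rule
policy. The GA searches axis-aligned interval conjunctions; oblique
combinations of genes are expressible only via rule stacking. CFS here is
the continuous-correlation variant; the discretized symmetrical-uncertainty
variant would change selections on strongly non-linear gene–class
relationships. Literature-mining results depend entirely on the supplied
count tables; the package neither queries PubMed nor maps probe identifiers
to gene symbols.
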