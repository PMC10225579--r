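---
title: "Differential co-expression analysis with dcnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression analysis with dcnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

## The problem

Two groups of bulk RNA-seq samples — typically cases and controls — can
differ not only in which genes are expressed but in how genes co-vary.
`dcnet` implements the full chain of a two-condition differential
co-expression study: count preprocessing, per-group weighted co-expression
networks with module and hub detection, a differential network built from
per-pair correlation differences, chance-corrected comparison of such
networks across datasets, over-representation analysis of the resulting
gene lists, and expression-based prediction of the condition label. A
synthetic-data generator with planted structure makes every stage testable
for recovery, which is how the package validates itself.

## Preprocessing

Counts are normalised to counts per million (`cpm_normalize()`), so every
sample has library size $10^6$. Three filters mirror standard practice:

* `filter_transcripts_global_average()` removes transcripts whose total
  count across samples falls strictly below the global mean of those
  totals. The "average of reads" is interpreted as the mean over
  transcripts of their totals (grand total / number of transcripts); the
  per-sample variant of that reading would drop the same genes up to the
  constant factor and is not separately implemented. Note this filter is
  deliberately *not* idempotent: removing below-average transcripts raises
  the average, so a second application can remove more. Provenance records
  the cutoff used.
* `filter_samples_by_depth()` drops samples under a read floor (default
  $10^7$, the usual recommendation for co-expression work). It acts on raw
  counts — CPM columns are constant by construction.
* `filter_by_biotype()` restricts to annotated biotypes (default
  protein-coding); unannotated genes resolve to a sentinel and are dropped.

`vst()` is `log2(CPM + 1)`: correlation-based networks assume roughly
homoskedastic inputs, and this is the standard variance stabiliser for
count data. The transform is tagged in provenance so an alternative
stabiliser can be swapped in without touching downstream code.

Every filter recomputes CPM from the current matrix, so library sizes
always reflect the retained genes. All operations return new matrices; a
`provenance()` trail records each step with its parameters.

## Per-group co-expression networks

The co-expression chain (`coexpression_analysis()`) follows the weighted
network construction that WGCNA-style tools use:

1. **Variance filter.** `filter_genes_invgamma()` fits an inverse-gamma
   distribution to per-gene sample variances by maximum likelihood (via the
   exact duality $V \sim \mathrm{InvGamma}(a, b) \iff 1/V \sim
   \Gamma(a, \text{rate} = b)$, fitted with `fitdistrplus`) and keeps genes
   in the upper tail ($p \le 0.1$ by default). On the package's synthetic
   data this filter is uninformative — the latent-factor construction gives
   module and background genes identical marginal variances — so recovery
   analyses run the chain with `filter_p = NULL` and the filter is
   validated on its own calibration fixtures (variances drawn from an
   inverse-gamma, where the kept fraction must match the threshold by the
   probability integral transform).
2. **Soft threshold.** `adjacency_matrix()` uses the unsigned convention
   $a_{gh} = |\mathrm{cor}(g,h)|^\beta$. `select_soft_threshold()` scans
   $\beta = 1..20$ and, for each, regresses $\log_{10} p(k)$ on
   $\log_{10} k$ over 10 connectivity bins; the signed fit $R^2$ (negated
   for positive slopes) must reach 0.8. Two guards matter in practice:
   positive slopes can never satisfy the criterion, and a fit is only
   valid when at least 6 of the 10 bins are occupied — a connectivity
   histogram collapsed onto a few clusters (all module genes at one $k$,
   all background at another) yields a meaninglessly high $R^2$ through
   3–4 points and, if trusted, selects a low $\beta$ at which weak global
   correlations glue all modules together. When no power qualifies, the
   power with the best valid fit is used and `criterion_met = FALSE` is
   reported; block-modular data with equal-size planted modules is a case
   in point, since its connectivity distribution is bimodal rather than
   scale-free.
3. **Topological overlap.** `tom_similarity()` computes
   $\mathrm{TOM}_{gh} = (\ell_{gh} + a_{gh}) / (\min(k_g, k_h) + 1 -
   a_{gh})$ with $\ell_{gh} = \sum_{u \ne g,h} a_{gu} a_{uh}$, the shared
   neighbourhood strengthening direct adjacency. Matrix algebra is used
   internally; tests pin it to a brute-force triple loop to $10^{-12}$.
4. **Modules.** `detect_modules()` clusters $1 - \mathrm{TOM}$ with
   average linkage and cuts the dendrogram deterministically: among all cut
   positions at or below a ceiling of 0.99 (branches joining above it are
   effectively uncorrelated), the cut yielding the most branches of at
   least `min_module_size = 30` genes is used, ties resolving to the
   highest cut. This is the package's own variant of dynamic branch
   cutting: a single fixed height is brittle because compositional
   correlation (below) moves merge heights with $\beta$, whereas the
   adaptive cut finds the level at which tight branches separate. Labels
   are 1..K by decreasing size, 0 meaning "not correlated"; the assignment
   is a pure function of the TOM and the two parameters.
5. **Hubs.** `find_hubs()` ranks genes within each module by intramodular
   connectivity $k^{\mathrm{in}}_g = \sum_{h \in m, h \ne g} a_{gh}$ and
   returns the top 5 per module (a configurable convention; ties break
   lexicographically so results are reproducible).

**Stability.** `module_stability()` reruns the whole chain on 100 random
subsets of 70% of samples, drawn *without* replacement — "bootstrapping
70% of samples" describes subsampling, not the classical with-replacement
bootstrap. It reports the distribution of the module count, the frequency
of the modal count (the "accuracy" in the field's usage), per-rank module
sizes and per-gene hub recovery.

## The differential network

`conditioned_expression()` splits a transformed matrix by condition (both
groups need $n \ge 4$ because Fisher's variance is $1/(n-3)$). The stages:

* **Gating.** `coexpressed_pairs()` computes all pairwise Pearson
  correlations per condition with $t$-based p-values, BH-adjusts each
  condition's full set of pair p-values, and retains pairs co-expressed in
  at least one condition: $|r| \ge 0.5$ and $q \le 0.1$. Only retained
  pairs are tested downstream. The thresholds are conventions (the field
  states none canonically) and are all configurable.
* **DCLs.** `fisher_z_diff_test()` compares correlations through
  $z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2) /
  \sqrt{1/(n_1 - 3) + 1/(n_2 - 3)}$ with a two-sided normal p-value.
  Correlations of exactly $\pm 1$ are clamped to $\pm(1 - 10^{-15})$,
  keeping the statistic finite without disturbing order. `call_dcls()`
  BH-adjusts over the retained pairs only — that is the tested family —
  and calls differential co-expressed links at $q \le 0.1$, classified as
  same-signed, switched-opposite (both conditions co-expressed), or
  diff-signed (one condition only).
* **DCGs.** `call_dcgs()` uses a global-rate binomial model: with
  $\hat p$ = total DCLs / total retained pairs, a gene with $n$ incident
  retained pairs and $d$ incident DCLs gets
  $P(X \ge d),\ X \sim \mathrm{Binomial}(n, \hat p)$, BH-adjusted across
  genes with at least one link. The per-gene-rate variant would absorb the
  very signal being tested; the global rate matches the "number of links"
  description of the upstream method.
* **Stability.** `dcg_stability()` subsamples each condition independently
  (preserving the group ratio; a `joint` option exists) at 70%, 100 times,
  and reports per-gene DCG recovery fractions.

## Comparing differential networks

`pairwise_ami()` quantifies agreement between differential networks from
different datasets by adjusted mutual information,
$\mathrm{AMI} = (\mathrm{MI} - E[\mathrm{MI}]) / (\tfrac{1}{2}(H_a + H_b)
- E[\mathrm{MI}])$, with the expected MI computed exactly under the
permutation model of the contingency table (no sampling). Two views are
offered because the comparison the field reports leaves the clustering
implicit: the default labels every pair in the union of tested pairs
(restricted to shared genes) as DCL / not-DCL per network; the alternative
(`mode = "communities"`) labels shared genes by connected components of
each DCL graph. Identical networks give 1, independent ones about 0, and
the measure is invariant to label renaming. Shared DCL genes — genes
incident to at least one DCL in both networks of a pair — are reported
alongside; note this reads "common genes" as incident-in-both, not as
sharing the same partner.

## Over-representation analysis

`ora_hypergeom()` is a generic hypergeometric upper-tail test of a query
list against GMT gene sets, BH-corrected across sets with significance at
$q \le 0.05$. The universe is the gene set entering the stage that
produced the query (e.g. genes surviving co-expression filtering), not the
whole genome — the ORA-on-module semantics. Any GMT file works; no pathway
database content ships with the package.

## Prediction

`cross_validated_boosting()` fits gradient-boosted decision trees
(`xgboost`, binary logistic objective) on the expression of a feature gene
set and evaluates by ten rounds of stratified 5-fold cross-validation,
each round drawing a fresh seeded partition. Metrics are the mean AUC
(Mann–Whitney formulation, ties one half — `auc()` is pinned to an
exhaustive pair-count oracle in tests) and the mean held-out
misclassification rate at probability 0.5. Stratification matters because
case/control studies are often imbalanced (e.g. 219 vs 70); unstratified
folds risk single-class test sets. Hyperparameters are fixed at moderate
values — 100 trees, depth 4, learning rate 0.1, single thread — favouring
determinism and desk-scale runtime over tuning; they are arguments, not
constants.

## The synthetic-data generator

`generate_dataset()` emulates the moments of a two-group bulk RNA-seq
design:

* **Modules** come from latent factors: gene $g$ in module $m$ has
  log-scale signal $x_{gs} = \sqrt{\rho} f_{ms} + \sqrt{1-\rho}\,
  \epsilon_{gs}$, giving every within-module pair true correlation
  $\rho$. The same module structure holds in both conditions (factors are
  redrawn per condition).
* **Planted differential pairs** override the background: the second gene
  of a pair is rebuilt as $r_c x_i + \sqrt{1 - r_c^2}\, \epsilon_j$ with
  condition-specific $r_c$; stars (`planted_star()`) chain this to give
  one hub many differential links — the planted analogue of a DCG. Pairs
  are carved out of background genes by default so module recovery and
  differential recovery stay independent tests.
* **Counts** are negative binomial, $\mathrm{NB}(\mu = L_s e^{\beta_0 +
  x_{gs}},\ \alpha = 0.1)$ with log-normal library-size factors $L_s$
  (log-sd 0.2) and baseline $\beta_0 = 6$ on the natural-log scale
  (roughly 400 counts per gene); $\alpha = 0.1$ is a typical bulk RNA-seq
  dispersion. `n_unexpressed` adds decoy genes 6 log-units lower —
  near-zero transcripts that give abundance filtering its real-data
  target; without them, equal expected expression would make the
  global-average filter remove a quasi-random half of the genes.
* **Calibration.** The targets `within_module_cor` and the planted $r$'s
  refer to the *observed* log-CPM scale. Two mechanisms attenuate latent
  correlations in count data: measurement noise (log-scale variance
  $\tau^2 = \psi_1(1/\alpha) + e^{-\beta_0}$, with $\psi_1$ the trigamma
  function) and the CPM compositional effect — module factors move the
  library depth, and dividing by depth both dampens within-module
  correlation and induces negative correlation between modules. The
  generator solves the first-order log-linear second-moment equations
  (one root-find per module, iterated because the depth variance couples
  modules) so that realized correlations hit their targets; empirically a
  target of 0.85 realizes within about 0.01. Latent correlations are
  capped at 0.995, so configurations whose modules dominate the library
  can fall slightly short. A corollary worth knowing: because the
  calibration depends on the gene roster, adding genes changes module and
  planted genes' emitted values even though every underlying random draw
  (per-gene, per-module, per-condition named sub-streams of one master
  seed) is roster-invariant.
* **Null harness.** `generate_null_correlation_pairs()` draws sample
  correlation pairs under a shared true correlation, the calibration
  input for type-I error checks of the Fisher-Z test.

What the generator does **not** emulate: batch effects and covariates,
read-level artefacts, mean-expression differences between conditions
(labels differ only through correlation structure, so prediction tests
plant an explicit mean-shift gene), heavy-tailed hub connectivity (its
block-modular networks are not scale-free — the soft-threshold criterion
legitimately reports `criterion_met = FALSE` on them), and dependence
between gene-level dispersions and means. Passing recovery tests on this
data therefore demonstrates the statistical machinery, not robustness to
real-data artefacts.

## Pipeline orchestration

`run_pipeline()` chains the stages: preprocessing; co-expression per
condition and pooled (the pooled run ignores labels by construction);
condition-exclusive module genes and hubs (`exclusive_elements()`);
the differential network; optional stability stages; optional ORA and
prediction. One master seed feeds named per-stage sub-streams. With an
output directory, every table is written (TSV/JSON/SIF) and the manifest
records the config snapshot and MD5 hashes — reruns with identical inputs
and config produce identical hashes, which the test suite asserts.

Two orchestration choices are deliberate. The differential stage defaults
to the genes assembled from either condition's modules (the procedure the
per-group design implies); `diffcoexp_genes = "all"` evaluates every
preprocessed gene instead, which is what the synthetic evaluation uses
since planted differential pairs live outside modules. Stability stages
default to off in the orchestrator (`coexpr_stability_reps = 0`,
`dcg_stability_reps = 0`) because they multiply runtime a hundredfold;
the dedicated functions keep the 100-replicate, 70% defaults and the
evaluation scripts run them explicitly. A warning cites the best-practice
floor of 20 or more samples per group when a group is smaller.

## Problem sizes and numerical conventions

The test suite and `scripts/acceptance.R` run at desk scale, chosen as the
smallest sizes at which each property is sharply testable: 10,000
replicate pairs for type-I calibration at $n_1 = n_2 = 100$; 200 runs for
DCL power at group sizes 70 vs 200; module recovery and 100-replicate
stability on two 50-gene modules ($\rho = 0.85$) among 100 background
genes with 100 samples per condition; an end-to-end run on 220 genes (60
of them decoys) with two planted 10-partner differential stars. Numerical
conventions worth restating: BH is used wherever an FDR is mentioned;
TOM and AMI are pinned to independent oracles ($10^{-12}$ and $10^{-8}$);
correlation clamping at $1 - 10^{-15}$; all tie-breaks (hub ranking,
module ordering, cut selection) are deterministic.

## Known limitations

Spearman correlation is available throughout but its p-values reuse the
$t$ approximation. The adaptive cut has no PAM-like reassignment stage, so
genes weakly attached to a module stay unassigned rather than being
rescued. The binomial DCG model treats incident links as independent,
which planted stars mildly violate (partners correlate through the hub).
AMI between networks of very different density is dominated by the larger
network's tested universe. None of these affect the package's contracts,
but they are the places a maintainer would look first.
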