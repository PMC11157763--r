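---
title: "Inferring altered glia-neuron communication: methods and design"
author: "gliaCCC maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring altered glia-neuron communication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaCCC)
```

# The problem

Glia (astrocytes, microglia, oligodendrocytes, OPCs) support neurons through
ligand-receptor signaling, and this communication is remodeled in
neurodegeneration. Given annotated single-nucleus RNA-seq count matrices from
case and control donors, `gliaCCC` asks: *which glia-to-neuron
ligand-receptor-target (LRT) interactions differ between conditions, do they
replicate across independent cohorts, how cell-type-specific are they, which
intracellular mediators relay them, and what do they imply for TF and pathway
activity in the receiving neurons?*

The pipeline operates downstream of standard preprocessing: alignment, QC,
integration and cell-type annotation are deliberately out of scope. The input
contract is a genes × cells integer matrix with per-cell `sample_id`,
`condition` (`case`/`control`), `cell_type` and `sex`.

# The model, stage by stage

## Pseudobulk and differential expression

Counts are summed per (sample, cell type) unit; units backed by fewer than 5
cells are dropped (inclusive threshold: 5 cells is kept — "minimum of 5"
reads as inclusive). Per cell type, each gene's `log2(CPM + 1)` is regressed
by ordinary least squares on an intercept, a case indicator and (by default)
a sex indicator:

$$ y_{gs} = \beta_0 + \beta_1\,\mathrm{case}_s + \beta_2\,\mathrm{male}_s + \varepsilon_{gs} $$

The reported `log2fc` is $\hat\beta_1$, the Wald statistic
$\hat\beta_1/\mathrm{se}(\hat\beta_1)$, p-values are two-sided t with the
residual degrees of freedom, and adjustment is Benjamini–Hochberg within the
table. This OLS Wald test replaces a negative-binomial engine with shrinkage:
the only quantities consumed downstream are the Wald statistic and the
fold-change sign/threshold semantics, which the linear model preserves while
keeping the implementation self-contained and exactly checkable against
closed-form normal equations. The CPM denominator is the unit's pseudobulk
library size with pseudocount 1; genes with zero counts across a cell type's
units are dropped (their fold changes are undefined). A gene constant across
all units gets `log2fc = 0`, `p = 1`.

On null simulations (no planted effects; 2,000 genes, 8+8 units) the
empirical fraction of p < 0.05 sits near the nominal 5% — the calibration is
asserted by the test suite.

## Candidate interactions and direction

A candidate requires ligand DE in a sender and receptor DE in a receiver,
both at |log2fc| ≥ 0.5 and unadjusted p ≤ 0.05, with *concordant* signs: both
positive defines `up_in_case`, both negative `up_in_control`, mixed signs are
discarded. Swapping the condition labels of the input exactly exchanges the
two direction sets and negates every DE statistic (asserted by a test).

## Ligand activity and targets

For each ligand, activity is the Pearson correlation over the receiver's
tested genes between (i) the ligand's regulatory-potential row restricted to
its top-250 genes (zero elsewhere) and (ii) the binary indicator of receiver
DE. Genes with zero regulatory potential are not target candidates: the
top-250 is taken within the row's positive support, ranked descending with
lexicographic tie-breaks. Predicted targets are the intersection of that top
set with the receiver's DE genes.

## Prioritization

Eight metrics are computed per candidate: ligand and receptor DE strength
(−log10 p), the fraction of samples expressing both pair members, ligand and
receptor mean expression in the direction's condition, min-max-scaled ligand
activity, and sender/receiver abundance (mean per-sample nuclei fraction) in
the direction's condition. Each metric is min-max scaled to [0, 1] across
candidates, and the priority score is their weighted mean. Weights default to
equal — the upstream tool's defaults are not published, and equal weights are
the neutral, documented choice; they are fully configurable. A metric
constant across candidates scales to 0 for everyone (it carries no
discrimination and this avoids 0/0). Scores are therefore invariant to any
increasing affine transform of a raw metric. Ordering is by descending score
with a full lexicographic tie-break, so output order is deterministic.

## Correlation filter

For each LRT, over samples shared by the sender and receiver units, the pair
signal is the elementwise product of min-max-scaled ligand (sender) and
receptor (receiver) pseudobulk expression; the filter keeps the LRT only when
both |Pearson| > 0.33 *and* |Spearman| > 0.33 (strict, mirroring "greater
than") between pair signal and target expression. Whether the original
analysis correlated the pair jointly or ligand and receptor separately is not
derivable from its description; both are implemented
(`correlationSignal = "separate"` requires each to pass and reports the
weaker), with the product signal as default because the correlation is
described pair-to-target. Fewer than 4 shared samples makes the coefficient
unstable; such LRTs are dropped with a warning.

## Cross-cohort high confidence

Cohorts are intersected on (sender, receiver, ligand, receptor, direction)
for shared pairs and additionally on target for high-confidence LRTs — a
replicated interaction must match in cell types *and* direction. Per-cohort
priority scores are reported side by side, never averaged. Three or more
cohorts reduce by repeated pairwise intersection.

## Signaling mediators

Per high-confidence LRT, a weighted directed subnetwork is induced on the
anchors plus the top-2 regulators, scored by being downstream of the ligand
and upstream of the target (each role contributes the mean edge weight of its
best path; ties lexicographic). Edge costs are $1 - w + \varepsilon$ with
$\varepsilon = 10^{-6}$: bounded (unlike $-\log w$), strictly positive, and
stable for comparing direct vs mediated routes when weights are small.
Candidate mediators are receptor out-neighbors (anchors excluded); top
mediators are the union of interior nodes over *all* cost-minimal
receptor→target Dijkstra paths, lexicographically ordered — reporting the
union on ties is the deterministic faithful choice when several relays are
equally supported. An interaction is "direct" only when the single
receptor→target edge is the unique minimal path. Because distances accumulate
edge-by-edge along paths, tie detection agrees exactly with brute-force path
enumeration; the suite asserts exact equivalence on a thousand random graphs,
with `igraph` as an additional independent cross-check of minimal costs.

## TF and pathway activity

Per receiver, Wald statistics are outer-joined across cohorts on the gene
union; entries missing in a cohort become 0 (counted and logged), because the
cohorts do not test identical gene sets and the joint model cannot take NAs.
The design matrix holds all regulators simultaneously (signed ±1 regulon
modes for TFs; signature weights of the top-500 most responsive genes by
p-rank for pathways; regulators with fewer than 5 represented targets are
dropped, inclusive). One joint OLS fit per contrast column — the "multivariate
linear model" semantics require the joint fit, which correctly separates
correlated regulons where one-at-a-time fits misattribute signal (shown in a
guarded test). The per-regulator t-values are the activities: positive =
activator/increased, negative = repressor/decreased. Fitting is per column;
columns are independent responses. Finally TF activities are subset to TFs
appearing among the mediators of the high-confidence LRTs.

# The synthetic-data generator

Real postmortem snRNA-seq inputs are access-restricted, so the package ships
a first-class generator whose defaults *are* the validation conditions: two
cohorts sharing one prior and ground truth; 8 case + 8 control samples each;
four glial senders and two neuronal receivers; 1,200 genes; negative-binomial
counts (shared dispersion 2) with log-normal library-size factors
(sdlog 0.3); 10 planted ligand-receptor pairs at |log2fc| = 2 with 5
downstream targets each; 50 TF regulons of 20 signed targets, 10 of them
shifted by ±1; a sex effect (log2fc 1) on a random 5% gene subset with sex
alternating within condition; and a cohort-wide batch shift (sd 0.25 log2).

Design choices that matter:

* **Planted receptors are shifted too.** A triple is only recoverable if its
  receptor is differentially expressed in the receiver, so the planted effect
  covers ligand (sender), receptor and targets (receiver) in the direction's
  condition.
* **A per-sample latent signaling factor** (sd 0.3 log2) is shared by the
  ligand, receptor and targets of each planted interaction: subjects signal
  with different strength, which is exactly the within-condition covariation
  the correlation filter is designed to detect.
* **Identifiability by construction.** Ligand, receptor, TF, mediator, LRT
  target, potential-support and TF-target gene pools are mutually disjoint,
  and each ligand's regulatory potential is sparse (~60 genes from a
  dedicated pool, planted targets drawn in the row's top decile). A validation
  instrument must let every planted signal class be attributed to its own
  ground truth; with dense random potential, TF-driven DE genes would appear
  as (correct, but unattributable) communication targets.
* **Two cohorts differ by seed-driven noise and an additive batch shift**
  common to all genes — the simplest confound that cross-cohort intersection
  must tolerate. Cohort sequencing-depth ratios are left to the library-size
  model.

What the generator does **not** emulate: ambient RNA, doublets, UMI
saturation, realistic marker-gene structure, or empirically calibrated brain
cell-type proportions. Passing recovery tests therefore demonstrates the
pipeline's correctness and statistical behavior under its stated model, not
performance on real tissue.

# Validation and problem sizes

The suite asserts, among others: exact Jaccard equivalence with brute-force
set algebra (1,000 random pairs); exact Dijkstra/enumeration equivalence on
1,000 random digraphs of up to 8 nodes; activity t-values equal to
normal-equation statistics to 1e-8 on 50 random designs; null DE calibration
(p < 0.05 fraction within [0.035, 0.065] at 2,000 genes, 8+8 units);
end-to-end planted-LRT sensitivity and precision ≥ 0.8 on the default
two-cohort study; TF sign recovery with planted |t| above the 95th percentile
of null TFs; exact direction-set exchange under label swap; and conservation
plus [0, 1] bounds on all scores. These sizes were chosen so the full suite
runs in about a minute on a laptop while keeping Monte-Carlo assertions
stable across seeds.

# Known limitations

* The OLS Wald test is not a negative-binomial model; very low counts make it
  slightly conservative, and no shrinkage is applied to fold changes.
* Ligand activity is a documented stand-in (Pearson on a thresholded
  indicator) for proprietary regulatory-potential scoring; absolute activity
  values are not comparable across priors.
* Equal prioritization weights are a neutral default, not a reproduction of
  any published weighting.
* Mediator extraction reflects the prior's signaling graph; it cannot recover
  relays absent from the prior, and "direct" means direct *in the prior*.
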