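---
title: "Methods: screening candidate lncRNA biomarkers with ceRNA networks and weighted co-expression modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening candidate lncRNA biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The screening chain

`cernascreen` implements an integrated inference chain that nominates
candidate long non-coding RNA (lncRNA) biomarkers from a paired
tumor/normal transcriptomic cohort, of the kind studied in
hepatocellular carcinoma. The chain combines five layers of evidence:

1. **Differential expression.** Counts are TMM-normalized and
   transformed to log2-CPM; each gene gets a paired two-sided t-test on
   per-pair (tumor − normal) log2 differences. mRNAs and lncRNAs are
   screened at BH-FDR < 0.01 and |log2FC| > 1 (both strict, matching
   the printed rules); miRNAs by the top-10 / bottom-10 fold-change
   rule, on the premise that the largest expression swings mark the
   regulators most likely to matter.
2. **ceRNA pair inference.** Competing endogenous RNA logic: a lncRNA
   and an mRNA that share binding sites for the same miRNAs compete for
   the same miRNA pool, so their expression should rise and fall
   together. For each (DE lncRNA, DE mRNA) combination sharing at least
   one DE miRNA in a predicted target table, the shared count `m` is
   tested against the upper-tail hypergeometric distribution with
   universe `N` = DE miRNAs present in the table, margins `K` and `n` =
   the two genes' universe out-degrees. A pair passes with
   hypergeometric p < 0.05, tumor-sample Pearson correlation > 0, and
   correlation p < 0.05 — all strict, all three independently
   toggleable.
3. **Signed weighted co-expression modules.** Signed adjacency
   `a_ij = ((1 + cor_ij)/2)^β`, topological overlap
   `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij)`,
   average-linkage clustering of `1 − TOM`, a static cut, eigengene
   merging, and kME pruning. Module eigengenes (first principal
   component of the standardized member expression, unit variance,
   sign-aligned with mean expression) are correlated with per-stage
   TNM indicators on tumor samples.
4. **Candidate selection.** A candidate lncRNA must be (i) in the top
   20% of ceRNA pair-graph degree (ties at the boundary included), (ii)
   a member of a TNM-significant module (any stage column with
   p < 0.05), and (iii) incident to at least one co-expression edge at
   PCC ≥ 0.7 (inclusive). Its reported target set is the union of its
   ceRNA partners and its lncRNA–mRNA co-expression partners, labeled
   by evidence so either definition can be recovered.
5. **Validation.** Per candidate, patients are median-split on tumor
   expression (ties to "low") and compared with the two-group log-rank
   test; a candidate is flagged when high expression carries worse
   survival (smaller restricted mean) at p < 0.05. Candidate-linked
   mRNAs are tested for over-representation against user-supplied
   (GMT) gene sets by the same hypergeometric tail, BH-corrected across
   sets.

# The synthetic cohort and what it emulates

Real cohorts carry no ground truth against which recovery can be
scored, so the package ships a generator (`generate_cohort()`) whose
defaults define the study conditions used throughout the tests:

* 50 tumor/normal pairs; 2,000 mRNAs, 500 lncRNAs, 150 miRNAs.
* Negative-binomial counts (dispersion 0.05) around log-normal
  baselines (log2 mean 6, sd 1.2, clamped to [3, 12]), with mild
  per-sample library effects (log2 sd 0.15).
* 10% of each role planted differentially expressed at |log2FC| = 2.
* Five lncRNA modules of 40 genes following per-sample latent factors
  (residual log2 noise sd 0.3); the first module's factor tracks
  standardized TNM stage (assigned uniformly over I–III on tumors) with
  correlation 0.7.
* 80 planted ceRNA lncRNA–mRNA pairs. Eight "candidate" lncRNAs sit in
  the trait module and carry five pairs each; 40 background lncRNAs
  carry one pair each. Each lncRNA sponges a dedicated duo of miRNAs
  shared by all of its partners: with a top/bottom-10 miRNA universe of
  N = 20, a single shared miRNA gives an upper-tail p of exactly
  1/20 = 0.05, which the strict p < 0.05 filter rejects — one shared
  regulator is indistinguishable from chance at this universe size, so
  detectable planted pairs share two. Candidate duos are distinct
  across candidates to keep cross-candidate false pairs rare. The
  partner mRNA loads the same latent factor as its lncRNA (+1), the
  sponged miRNAs load the negative mean of their pairs' factors, giving
  the positive lncRNA–mRNA and negative miRNA–mRNA tumor correlations
  that ceRNA competition predicts.
* The 90% of the target table that is not planted is uniform random
  decoy edges (~20 edges per miRNA), giving the hypergeometric test a
  non-degenerate null.
* Two candidates are survival risks: patients in the top half of their
  tumor expression draw exponential survival with a 2.5× hazard over a
  1,000-day median, censored uniformly at 1–6.8 years.

These defaults are chosen for testability, not biological realism: real
cohorts have heavier dispersion, correlated library composition, batch
effects, overlapping modules, and much weaker planted effects. Passing
the recovery tests therefore demonstrates that the chain's wiring and
statistics are correct, not that it would achieve the same sensitivity
on real tumor data.

# Numerical and design choices

**Differential test.** The DE stage is deliberately a paired t-test on
TMM-normalized log2-CPM rather than a negative-binomial exact test: the
chain treats DE as a screening filter with thresholds, and the paired
design exploits the cohort's tumor/normal pairing directly. An unpaired
Welch variant sits behind `paired = FALSE`, with no default
recommendation, since the original design is not recorded. TMM is
implemented as specified for the normalization stage (30% M-trim and 5%
A-trim per tail, precision-weighted mean M, factors rescaled to
geometric mean 1) and cross-checked against the reference
implementation in the tests. The pseudo-count is 0.5; zero-variance
genes get p = 1 with a warning rather than an error.

**Hypergeometric universe.** `N` counts DE miRNAs present in the target
table, not the genome: the network is built from differentially
expressed regulators, which makes the DE miRNA set the natural sampling
frame. No multiple-testing correction is applied across pairs (raw
p < 0.05), matching the stated pair rule; a BH option exists and is off
by default.

**Tumor-only correlations.** Both the ceRNA PCC filter and the module /
co-expression stages correlate over tumor samples. Competition for a
shared miRNA pool is asserted in tumors, TNM stage exists only for
tumors, and pooling tumor with normal columns would let the shared
tumor/normal mean shift of *every* DE gene masquerade as co-expression,
fusing unrelated DE genes into one apparent module.

**Soft threshold.** The fit index is the signed scale-free criterion
`−sign(slope)·R²` of the log-binned connectivity regression, with the
smallest power reaching `r2_min = 0.85` chosen, else the argmax with a
warning. The pipeline's candidate grid is `c(6:10, 12, 14, 16)`: in a
signed network a power below ~6 leaves two uncorrelated genes with
adjacency `(1/2)^β` large enough to wash out all topological-overlap
contrast, and when no power reaches the threshold (module-structured
data is not scale-free) an argmax over the low powers can pick such a
degenerate value. Restricting the grid matches standard signed-network
power recommendations.

**Module detection.** Average linkage with a static cut at 0.985,
minimum module size 30, eigengene merging below dissimilarity 0.25, and
kME pruning at 0.3. The cut height sits just below the plateau where
background (uncorrelated) genes chain together (~0.99 on these TOM
dendrograms); a cut above that plateau returns a single giant module.
Static cutting still attaches a few stray background leaves to each
module, so genes whose correlation with their module eigengene falls
below 0.3 (the conventional kME floor) are returned to "unassigned".
Labels are deterministic: M1, M2, … by decreasing size, ties broken by
smallest member id; color names carry no meaning here.

**Ties and boundaries.** All stated thresholds are strict except the
co-expression PCC cutoff (≥ 0.7, inclusive, since no strictness is
printed for it) and the top-degree rule (at least ⌈fraction × count⌉
nodes, boundary ties all included — determinism without arbitrary
dropping). The miRNA top/bottom-k rule breaks fold-change ties
lexicographically and always returns 2k genes. Median splits send ties
to "low"; the split quantile is configurable.

**Degenerate inputs.** Empty passing-pair sets propagate as empty but
valid tables through network construction, selection, survival and
enrichment; an all-censored or constant-expression candidate yields an
"untestable" row rather than an error; a stage with no samples is
dropped from the module–trait matrix with a warning.

# Problem sizes and runtime

The default test and acceptance configuration uses the full synthetic
cohort (50 pairs, 2,650 genes) over seeds 1–3, plus null calibrations
(200 module–trait replicates; 500 two-group log-rank null datasets of
40 patients — the log-rank null needs only survival draws, so full
cohorts are not re-simulated for it). A complete seven-stage run takes
a few seconds on one core; the entire suite, including the exhaustive
combinatorial oracles (every hypergeometric margin with N ≤ 12, 1,000
BH vectors, 100 random graphs vs. path enumeration), runs in well under
a minute.

# Known limitations

* The generator plants clean block modules and exact fold changes;
  detection parameters tuned here (cut height, kME floor) are sensible
  defaults, not universal constants, and real data may need the usual
  dendrogram inspection.
* The miRNA stage keeps exactly 2k regulators regardless of effect
  size, as specified by the top/bottom-k rule; with fewer than 2k
  expressed miRNAs it refuses to run.
* Survival validation is an unadjusted two-group comparison; no Cox
  model, staging covariates or competing risks.
* Enrichment is a plain hypergeometric over-representation test against
  user-supplied sets; no annotation databases ship with the package,
  and fuzzy-clustering enrichment scores of hosted tools are out of
  scope.
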