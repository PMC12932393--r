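---
title: "Discovering and replicating DNA methylation disease subtypes across cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and replicating DNA methylation disease subtypes across cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsubtypes)
```

## The problem

Late-onset Alzheimer's disease (LOAD) is clinically and molecularly
heterogeneous. One way to resolve that heterogeneity is to ask whether the
cortical DNA methylation (DNAm) profiles of LOAD brains fall into
reproducible subgroups: clusters of donors that share a methylomic
signature, recur across independent brain-bank cohorts, and differ
downstream in their epigenome-wide association signals, regulatory context,
transcriptomes and microglial phenotypes.

`methsubtypes` implements that full analytical arc as a reusable pipeline:

1. **Pre-clustering adjustment** — per-probe covariate residualization and a
   robust variability filter.
2. **Per-cohort dual clustering** — Ward-D2 hierarchical and k-means
   clustering of LOAD samples with data-driven selection of the cluster
   number, consensus labeling, and batch-association diagnostics.
3. **Cross-cohort replication** — median-profile correlation block matching
   plus convex-hull projection tests in a sparse PLS-DA latent space, with a
   strict all-rotations confirmation rule.
4. **Subtype characterization** — per-cohort EWAS with surrogate variables,
   empirical-Bayes bias/inflation correction, inverse-variance
   meta-analysis, set-overlap and regulatory/cell-type enrichment,
   colocalization with GWAS signals, bulk transcriptomic consensus DEGs,
   CpG-gene window correlations, microglial-state statistics and morphology
   comparisons.
5. **A synthetic multi-cohort generator** with a truth registry, so every
   stage is testable end to end without access to restricted human data.

## Input model and pre-clustering transformation

Methylation enters as per-cohort beta matrices (probes x samples, values in
(0,1)). Each probe is regressed by ordinary least squares on the sample
covariates (age, sex, cell-type proportions, technical batch; an intercept
is always included) and the residuals are carried forward
(`residualize()`). Working on beta values directly matches the clustering
input used downstream; an M-value (logit) option exists but is off by
default.

Non-variant probes are removed by a robust spread statistic: the 90th
percentile of absolute deviations from the probe median across samples
(`filter_most_variable()`). The retention cutoff is a quantile of that
statistic's distribution across probes, default 0.5. The published retained
counts for this kind of data (hundreds of thousands of probes reduced to a
~40% subset) are not reproducible from a text description alone, so the
cutoff is exposed as a parameter; filtering is monotone in the cutoff, so
sensitivity analyses are cheap. Percentiles interpolate linearly between
order statistics.

Cross-platform work (EPIC-like discovery arrays vs a 450K-like cohort) is a
row intersection (`intersect_platform()`): the 450K probe set must be a
subset of the EPIC set, and all cross-cohort stages operate on the shared
probes.

## Cluster discovery and the number of clusters

LOAD samples of each cohort are clustered twice: agglomerative hierarchical
clustering with the Ward-D2 criterion on Euclidean distances (distances are
*not* pre-squared; the Lance-Williams recurrence squares internally), and
k-means with 25 seeded restarts. Using two methods of different character is
deliberate: their agreement, measured by normalized mutual information
(NMI), is the model-selection signal.

Two practical points deserve emphasis because they are easy to get wrong:

* **NMI ties.** On cleanly separated data, NMI between the two methods is
  exactly 1 for *every* candidate k up to the true cluster count (both
  methods merge the same clusters). "Pick the k with the highest NMI"
  therefore needs a tie-break. We break ties by elbow strength — the second
  forward difference of the hierarchical **log**-WCSS curve, extended one k
  below and above the candidate range — and only then by the smallest k.
* **Why log-WCSS.** On the raw WCSS curve the largest second difference
  always sits at the largest absolute drop, which for well-separated
  clusters is the first split (k = 2) regardless of the true k. Relative
  (log-scale) drops put the knee where the marginal gain collapses, which is
  the true cluster count in our simulations and the standard reading of an
  elbow plot.

Consensus labels (`consensus_labels()`) are assigned only to samples on
which the two methods agree after the k-means clusters are matched
one-to-one to the hierarchical clusters. The matching maximizes total
overlap on the contingency table by exhaustive search over permutations
(k <= 8), which is exact and deterministic — a greedy matching can depend on
tie order. Cluster labels are checked against technical variables
(`batch_association()`): Spearman correlation for continuous variables, NMI
with a seeded permutation p-value for discrete ones.

## Sparse PLS-DA

`fit_splsda()` implements sparse partial least squares discriminant
analysis. Labels are dummy-coded, features centered and scaled; per
component the weight vector is the dominant left singular vector of
\(X^\top Y\) (the direction power iteration on \(X^\top Y Y^\top X\)
converges to), soft-thresholded so exactly `keep_per_component`
largest-magnitude entries survive, and renormalized. Scores are \(Xw\); X
and Y are deflated by regression on the scores, which makes the component
scores mutually orthogonal. A regression-form rotation
\(R = W (P^\top W)^{-1}\) is stored so that projecting the training data
reproduces the training scores exactly; new cohorts are scaled with the
*training* means and standard deviations before projection (self-consistent
with the rotation). When a replication platform lacks some features, the
rotation rows are dropped and each component column renormalized; if fewer
than half the selected features are available the projection refuses to run.

The conventional operating point at full array scale is 6 components with
2,000 features kept per component (12,000 features in total when supports
are disjoint). The label-randomization robustness procedure
(`randomization_robustness()`) permutes the labels of a random fraction of
samples (grid 1.00, 0.75, 0.50, 0.25, 0.10, 0.05, 0.01 by default; the
published description fixes only the endpoints), refits, and records the
overlap of the selected-feature union with the reference model. On real
signal the overlap decays monotonically with the randomized fraction.

## Cross-cohort replication

Replication is two-pronged and intentionally strict.

**Probe level.** Per (cohort, consensus cluster), the per-probe median of
the adjusted values is the cluster's profile; cross-cohort Pearson
correlations of these profiles are computed on shared probes, and a *block*
is a cluster triple (one per cohort) in which every pair is a mutual best
match — row and column maximum of its correlation matrix. Mutual best
matching is deterministic; weaker schemes (best-match chains) are not.
Profiles are computed on residualized values, not raw betas: raw medians are
dominated by the shared per-CpG baseline, which would make *every* cluster
pair correlate near 1.

**Sample level.** For every ordered (discovery, replication) cohort pair and
both clustering methods, a sPLS-DA model is fitted to the discovery cohort,
2-D convex hulls are drawn around each discovery cluster in components 1-2,
the replication cohort is projected, and each (replication cluster,
discovery hull) pair is tested by a one-sided hypergeometric test for
over-representation of the cluster inside the hull. Boundary points count as
inside; collinear clusters degrade to zero-width polygons rather than
failing. p-values are BH-adjusted within each rotation (the source
description names no multiplicity rule; BH within rotation is the declared
default, threshold 0.05).

**Confirmation.** A block becomes a subtype only if it is a correlation
block *and* every matched hull test in every rotation is significant under
*both* clustering methods. Samples outside confirmed blocks — including
entire cohort-specific clusters — are called `Unassigned`; controls stay
`Control`.

Two numerical safeguards matter at reduced simulation scale:

* **Control anchoring.** Per-cohort residualization centers each probe on
  the cohort's full sample mean, which depends on the cohort's cluster
  composition: a cluster present in only one cohort contaminates that
  cohort's centering and rigidly shifts its projections relative to other
  cohorts. Before any cross-cohort comparison the pipeline therefore
  re-anchors each cohort's residuals to its own *control* samples, whose
  composition is stable across cohorts. Per-probe shifts do not change
  within-cohort sample distances, so clustering is unaffected.
* **Scale-adaptive sparsity.** The hull stage defaults to
  `min(2000, max(50, 0.015 * shared probes))` features per component. At
  array scale this reproduces the conventional 2,000; at simulation scale
  (about 1,300 shared probes) a dense fit overfits noise features, inflating
  discovery-score separation and shrinking projected replication clouds off
  the hulls.

## Subtype EWAS, correction and meta-analysis

Each cohort's EWAS (`run_ewas()`) is per-CpG OLS of methylation on the
subtype contrast plus covariates and surrogate variables. Surrogates
(`estimate_svs()`) come from permutation parallel analysis: singular values
of the outcome/covariate-residualized matrix are compared, as fractions of
the trace, against row-permuted matrices that are re-residualized by the
same design (both normalizations matter — without them the observed top
eigenvalue systematically exceeds the null and phantom surrogates appear).
The reported z is the exact normal quantile of the t-based p-value and the
standard error is rescaled so `estimate/se = z`; this keeps normal-theory
pooling calibrated at moderate sample sizes.

Test-statistic bias and inflation are handled by a three-component normal
mixture fitted by constrained EM (`bacon_correct()`): the central component
(largest weight) models the null — its mean is the bias, its standard
deviation the inflation — while the side components absorb true signals.
The side means are constrained to sit at least four central standard
deviations away; without that floor the side components nibble the null
tails and the inflation estimate is biased low at moderate test counts. The
EM is deterministic (moment-based initialization). Corrected statistics are
`z' = (z - bias)/inflation` with estimates rescaled consistently at
unchanged standard errors; `only_if_inflated = TRUE` floors the applied
inflation divisor at 1, the assess-then-correct-if-needed workflow, which
is what the null-calibration analyses use.

`meta_analyze()` pools by fixed-effect inverse variance (weights `1/se^2`);
DerSimonian-Laird random effects (tau² from Cochran's Q) are available. The
default is fixed-effect because the random-effects alternative is offered
without an extra optimizer; both match `metafor::rma.uni` on the same
inputs in the test suite. The Bonferroni family is the set of CpGs entering
the meta-analysis; a differentially methylated position (DMP) requires a
Bonferroni-adjusted p below 0.05.

## Enrichment statistics

Set overlaps (`fisher_overlap()`, `fisher_overlap_counts()`) report the
*conditional maximum-likelihood* odds ratio of the noncentral
hypergeometric model — the value classical Fisher-test implementations
print — rather than the sample odds ratio. The score equation
\(E_\psi[X] = x\) is solved on the same bounded parametrization and at the
same root tolerance as the classical implementation, so published values
are reproduced digit for digit; the enrichment p-value is the exact
hypergeometric upper tail. Regulatory enrichment places CpGs into 0-based
half-open intervals via `GenomicRanges` and BH-adjusts across features
within each CpG set; cell-type panel enrichment does the same across
(cell type, specificity level) panels.

## Colocalization

`coloc_abf()` computes per-SNP Wakefield log approximate Bayes factors
(`wakefield_labf()`, prior effect sd `W = 0.15` for quantitative traits —
the conventional default; the source analysis states none) and sums the
five hypothesis configurations in log space, obtaining the two-distinct-
variants term as the cross-product sum minus the shared-SNP diagonal.
Default priors are p1 = p2 = 1e-4, p12 = 1e-5. The decision rule is
PP3 + PP4 > 0.90 — implemented verbatim even though H4-only is the common
convention, which is available via `rule = "h4"`. Inputs may be effect/se
pairs or p + MAF + N (standard-error reconstruction for a standardized
quantitative trait), with a cis-mQTL suggestive-p flag (p < 1e-5) for
upstream filtering. Note that posteriors are invariant to a common
rescaling of effects and standard errors only when `W` is expressed in the
same rescaled units; `W` is a unit-bearing quantity.

## Transcriptomics

Counts are filtered by the strict rule "below 10 in more than 80% of
samples", TMM-normalized and converted to logCPM via edgeR (prior count
0.5, scaled with library size so a pure depth change leaves logCPM exactly
invariant). Differential expression uses a moderated t: per-gene OLS with
empirical-Bayes variance shrinkage, with prior df and scale estimated by
method of moments on the log residual variances (the trigamma-matching
construction); fold changes match limma's exactly, the moderated statistics
agree closely. The cross-cohort consensus filter retains a gene only with a
consistent direction in all cohorts, |FC| > 1.5 (linear scale — the log
scale is not specified in the source and linear is the stricter reading)
in at least one, p < 0.05 in all, and FDR < 0.05 in at least one.
CpG-gene candidate pairs live within TSS +/- 10 kb (inclusive boundary);
Spearman correlations (midranks under ties) are computed per cohort and
subtype stratum, BH-adjusted within each (cohort, subtype) family, and a
pair replicates when FDR < 0.1 in at least two cohorts.

## Microglial states and morphology

State proportions use per-sample fractions of total microglia, excluding
any state with fewer than 100 cells summed within any group, then one-way
ANOVA with Tukey HSD. The global-shift analysis is a control-anchored PCA
(`control_pca_projection()`): TMM/logCPM with the reference sample chosen
among controls and a fixed prior count (so control values never depend on
disease samples), outlier screening in the initial control PCA over the
components explaining >= 80% variance (median + 3.5 x MAD on distances from
the median score vector; MAD uses the 1.4826 consistency constant), refit
on cleaned controls, and projection of all samples with control means, sds
and rotation. Group separation in PC1-2 is tested by permutation
(`permutation_separation_test()`, default 10,000 permutations): the
statistic is the median over all cross-group pairwise distances (centroid
distance is available), the empirical p is `(1 + #{null >= obs})/(1 + B)` —
never zero — the reported interval is the 2.5/97.5 percentile band of the
null, and BH runs across the tested group pairs.

Activation scores are PC1 of the marker-gene logCPM matrix, sign-oriented
to correlate positively with mean marker expression, standardized against
controls, and compared between subtypes by a two-sided Welch t-test.
Pseudobulk DEA aggregates cells by summation per (state, sample), drops
zero-library pseudobulk samples, and applies the lenient dual rule: a gene
is flagged when p < 0.05 between subtypes *and* p < 0.05 versus controls in
at least one subtype. Morphology tables (proportions of activated
microglia, stage-3 burden) are compared per region by Welch t-tests with
Satterthwaite degrees of freedom, Cohen's d on the pooled standard
deviation, and BH across all comparisons within each measure.

## The synthetic study

`sim_config()` / `simulate_study()` generate the multi-cohort data the
pipeline assumes. Methylation is additive on the logit scale — per-CpG
baseline (shared across cohorts) + covariate terms + cohort offset +
planted effects + Gaussian noise — so betas stay strictly inside (0,1)
without clipping. The default conditions, chosen once to mirror a
three-cohort brain-bank study at reduced scale:

* 3 cohorts, 150 samples each (50 controls, 50 + 50 planted subtypes);
  cohort 1 carries an extra 25-sample cohort-specific cluster, and the last
  cohort exposes only a random 60% probe subset (the 450K-like platform),
  with at least half of every signature retained so replication stays
  detectable.
* 5,000 CpGs; disjoint signatures of 150 (S1), 150 (S2), 100 (shared LOAD),
  150 (cohort-specific) and 150 (tangle-like, shifted in all LOAD) CpGs;
  logit effects 1.2 for the subtypes, 1.4 for the cohort-specific cluster,
  0.6 for the shared signatures; effect signs drawn once per CpG and reused
  in every cohort. Per-CpG noise sd 0.3; 20% of probes are near-constant
  (sd 0.02) to exercise the variability filter.
* Covariate coefficients per CpG drawn with sds 0.01 (age), 0.15 (sex),
  0.8 (neuronal proportion) and 0.25 (batch).
* Expression: 2,000 genes, negative-binomial with dispersion 0.1 and
  log-normal library sizes; 50 planted DEGs per subtype at fold change 2
  (random direction); 20 CpG-linked genes whose expected expression rises
  monotonically with the linked planted CpG's beta across LOAD-S2 samples,
  placed within the promoter window of their CpG.
* Microglia: 4 states x 20 markers (disjoint), multinomial cell counts with
  one state made rare (< 100 cells) in one group, log-normal pseudobulk
  scaled by cell counts, and a +1 marker shift of state MG2 in LOAD-S1.
* Morphology: four regions, logit-normal PAM with a wider spread for
  LOAD-S1.

One global seed streams per-component seeds, so a fixed seed gives
byte-identical output and the components can be regenerated independently.

What the generator does **not** emulate: probe-probe correlation structure
(neighbouring CpGs; this mainly affects how conservative Bonferroni is),
cell-type deconvolution error, array normalization artifacts, genotype
structure, and realistic single-cell sampling. Passing tests therefore
demonstrate the pipeline's statistical machinery under its stated
assumptions, not performance on raw array data.

## Problem sizes and determinism

The packaged analyses run at deliberately reduced scale: the planted-study
pipeline uses 5,000 CpGs and ~150 samples per cohort; replication-validity
null studies use 400 CpGs and 60 samples per cohort over 50 replicates;
EWAS calibration uses 1,000 CpGs x 60 samples x 3 cohorts; the
permutation-test calibration uses 1,000 replicates at 500 permutations;
bias/inflation recovery uses 50,000 z-scores. Every stochastic step takes
an explicit seed; k-means restarts, permutation tests and the robustness
grid derive per-task seeds from it. Degenerate inputs are handled
explicitly rather than by chance: constant features are dropped with a
warning, collinear designs raise errors naming the offending columns,
degenerate hulls become zero-width polygons, empty consensus sets and empty
block sets are valid outcomes, and permutation p-values are floored at
`1/(B+1)`.

## Known limitations

* The simplified co-methylation detector (signed adjacency, average
  linkage, fixed cut height; defaults soft power 6, cut height 0.35,
  minimum size 10) captures block structure but is not a topological-
  overlap network method; the cross-platform *preservation test* — ANOVA
  significance on both platforms plus per-cluster paired t-tests between
  platform versions — is the faithful part.
* The EM bias/inflation model recovers parameters of the null component; it
  is not a posterior-sampling reimplementation, and extremely asymmetric
  signal distributions can bias the bias estimate.
* Convex-hull replication is sensitive to projection shrinkage when the
  feature selection is too dense relative to the signal; the scale-adaptive
  sparsity default addresses this, but very small replication cohorts will
  still yield weak hypergeometric tests.
* The confirmation rule is strict (every rotation, both methods); with many
  cohorts it becomes conservative, and the interface generalizes to "all
  pairs" rather than relaxing.
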