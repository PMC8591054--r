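---
title: "Methods: immune cell infiltration subtyping and ICI scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune cell infiltration subtyping and ICI scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`iciscore` implements a complete analysis chain for characterising the
immune cell infiltration (ICI) landscape of a bulk tumor expression cohort
and deriving a transferable per-sample prognostic score:

1. **Deconvolution** of 22 immune-cell fractions per sample against an
   LM22-style signature matrix.
2. **Consensus clustering** of the fractions into ICI subtypes.
3. **Immunophenoscore (IPS) stratification**: a survival-optimal IPS
   cutpoint splits the cohort, and moderated-t differential expression
   between the groups defines an IPS-associated gene panel.
4. **Gene types A/B**: consensus clustering of samples on the DEG panel,
   then each gene is typed by the sign of its association with the
   reference (immunogenicity-high) cluster.
5. **Boruta reduction** of each gene type, then the **ICI score**
   `ici_score = PC1(A) - PC1(B)`: the difference of first-principal-
   component projections on the two reduced gene sets.
6. **Downstream integration**: survival cutpoints and Kaplan-Meier /
   log-rank contrasts, tumor mutation burden (TMB), enrichment analyses,
   and validation on an immunotherapy cohort via responder rates.

Every stage is an exported function; `run_pipeline()` wires them together
and the numbered scripts under `analysis/` present the same flow as a
staged, narrated analysis.

# The score model and its assumptions

For a gene set $G$ with training expression $X$ (samples × genes), the
model stores the per-gene training means $\mu$ and the unit-norm first
eigenvector $v$ of the covariance of the centered data. A sample $x$ is
scored by the projection $(x - \mu)^\top v$, and

$$\mathrm{ICI} = (x-\mu_A)^\top v_A \;-\; (x-\mu_B)^\top v_B.$$

The summation sign sometimes written in front of "PC1" in this family of
scores is read as the sum over the set's genes *inside* the projection —
a single inner product per set — which is the only dimensionally
consistent interpretation and matches the TME-score construction this
design follows.

Assumptions worth making explicit:

* **PC1 captures the program.** The score is meaningful when the dominant
  axis of variation within each gene set is the coordinated immune
  program, not a technical artefact. On the synthetic cohorts PC1
  explains ~80% of each set's variance; on real cohorts this should be
  checked (`model$A$var_explained`).
* **Sign convention.** An eigenvector is defined up to sign. The loading
  sign is fixed so that the per-sample PC1 scores correlate positively
  with the mean expression of the set's genes. This both makes refitting
  bit-reproducible and orients `score_A` upward when A genes are high,
  so the ICI score is high in immune-hot samples.
* **Genes are centered, not standardised,** before PCA (a
  `scale_genes` switch exists). With log2 expression the gene variances
  are comparable, and centering-only keeps the external-cohort scoring
  rule a pure inner product with the training means.
* **External scoring** requires ≥ 80% of each gene list; missing genes
  are imputed at their training mean (i.e. contribute zero after
  centering) with a warning. Below the threshold the mismatch is too
  severe to patch silently and scoring errors out.

# Deconvolution

`deconvolve()` re-implements signature-based deconvolution with two
solvers behind one contract: ν-SVR (linear kernel, ν ∈ {0.25, 0.5, 0.75},
lowest-RMSE fit kept, negative weights clipped, renormalised) and a
deterministic NNLS default. Design choices:

* Expression is de-logged (`2^x`) first: the mixing model is linear in
  intensity space.
* One **shared affine z-normalisation** (mean/sd of the signature
  submatrix) is applied to both signature and mixture. Because the same
  transform is applied to both sides, a convex mixture of basis columns
  remains an exact solution — the noiseless-recovery error is at machine
  precision rather than merely small.
* The NNLS design includes a free intercept (a +/− column pair), which
  additionally makes fractions exactly invariant to per-sample positive
  rescaling of the mixture.
* The per-sample permutation p-value shuffles the mixture over marker
  genes and asks how often a shuffled mixture fits as well (Pearson r);
  the +1-corrected estimate lives in `[1/(n_perm+1), 1]`.

The packaged `synthetic_signature_matrix()` is a synthetic LM22-shaped
basis (22 cell types, 5 private markers each over a low shared
background). It shares LM22's dimensions and cell-type names only; real
analyses should supply the real LM22 as TSV.

# Consensus clustering and model selection

`consensus_cluster()` follows the standard resampling recipe: for each
candidate k, 1,000 (default; 200 in the bundled analyses, see "Problem
sizes") subsamples of 80% of samples are clustered with PAM on Euclidean
distance, co-clustering counts are normalised by co-sampling counts, and
final labels cut an average-linkage tree of `1 - consensus`. Feature
columns are standardised by default (switchable), since cell fractions
live on very different scales.

The phrase "PAM according to Euclidean and Ward linkages" that motivates
this module is internally contradictory; the resolution here is PAM on
Euclidean distance as the resampled base learner, with Ward-linkage
hierarchical clustering available via `base_method = "ward"`.

k is selected by minimising PAC (the proportion of consensus entries in
(0.1, 0.9)), with ties going to the smaller k; `select_k(..., "delta_area")`
implements the CDF delta-area alternative, and manual override is always
possible since every per-k result is returned. PAC has a known
degeneracy: when two planted clusters are much closer to each other than
to the rest, the merged solution can be exactly as stable as the true
one (both PAC = 0) and the tie rule then under-clusters. The tests
exercise both regimes.

# Differential expression

`differential_expression()` implements the empirical-Bayes moderated
t-statistic: per-gene pooled variances $s_g^2$ are shrunk as
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ with p-values on
$d_0 + d_g$ df. The prior $(d_0, s_0^2)$ is fitted by method of moments
under the scaled-F sampling model ($s^2 \sim s_0^2 F(d_g, d_0)$), matching
the first two moments of the observed $s_g^2$. Setting `d0 = 0` recovers
the ordinary t-test, and supplying limma's fitted prior reproduces
limma's moderated t exactly (this is a test). Genes with zero pooled
variance are reported with p = 1 and logged. Thresholds are BH-adjusted
p < 0.05 and |log2FC| > 1.

# Gene types A and B

The defining phrase — genes "positively related" to the consensus
classification — is ambiguous: with a per-gene *best-matching* cluster,
the maximal one-vs-rest correlation is almost never negative, so every
DEG would land in type A. `assign_gene_types()` therefore computes each
gene's point-biserial correlation with a **reference cluster** indicator:
positive association → type A, remainder → type B. The pipeline chooses
the highest-mean-IPS cluster as reference (the immunogenicity-high
subtype), which makes type A the immune-activation-associated panel; the
per-gene best-matching cluster is still reported for diagnostics.

# Boruta reduction

`boruta_select()` implements the shadow-feature scheme: per iteration,
every feature gets a column-shuffled shadow copy, a random forest
(`ranger`, permutation importance, 100 trees) is fitted on the joint
matrix, and a feature scores a hit when it outranks the best shadow. A
two-sided binomial test (α/2 per tail) confirms or rejects features
across iterations, with early stopping once all are decided; leftover
tentative features are resolved against the median shadow importance of
the final iteration. The target variable is the IPS-derived high/low
label in the pipeline (the source analysis names only the algorithm, not
the target; cluster labels or survival status are drop-in alternatives).

# Survival machinery

Kaplan-Meier and log-rank computations delegate to the survival package;
the reported median is the earliest time with $S(t) \le 0.5$.
`optimal_cutpoint()` implements maximally selected rank statistics
directly: every midpoint of consecutive distinct score values is a
candidate, candidates violating `minprop = 0.1` on either side are
discarded, and the candidate maximising the absolute standardized
two-group log-rank statistic wins (ties to the smallest threshold;
samples strictly above the threshold are "high"). This is exactly
equivalent to brute force by construction and is verified against a
brute-force oracle on random fixtures. No selection-corrected p-value is
attached to the chosen split; the log-rank p after an optimal split is
optimistic and should be read descriptively.

# Mutation burden

TMB = nonsilent variants / 38 Mb (configurable). The nonsilent set is
the MAF-standard list (missense, nonsense, nonstop, frame-shift ins/del,
in-frame ins/del, splice site, translation start site); Silent and
non-coding classes are excluded, unknown classes are excluded with a
warning. Driver contrasts keep the top-30 genes by pooled mutated-sample
frequency (a sample counts once per gene), Fisher-exact per gene with BH
across the kept genes. The waterfall export resolves multi-hit cells by
a documented severity order and memo-sorts samples lexicographically on
the gene-ordered mutation pattern.

# Enrichment

`preranked_gsea()` is the classic weighted running-sum statistic (hit
steps ∝ |score|^weight, miss steps 1/(N−Nh)); the null permutes gene
labels — phenotype permutation would need per-sample recomputation the
source analysis does not specify — with NES = ES / mean(|same-sign null
ES|), +1-corrected nominal p and the standard pooled positive/negative
FDR. The ranking metric between score groups is the moderated-t log2
fold change. `ora_hypergeometric()` is the upper-tail hypergeometric
test with BH adjustment and per-namespace top-k reporting. No licensed
gene-set content ships with the package; tests and analyses build tiny
synthetic GMT collections.

# The synthetic cohort generator

`simulate_cohort()` provides the ground truth every stage is tested
against. Per sample: a phenotype (3 by default, equal prior) sets the
mean of a continuous latent immune score z (means −1.5/0/+1.5, sd 0.6,
then standardised); fractions come from a per-phenotype Dirichlet (block
design: five boosted cell types per phenotype, concentration 6 vs 0.6,
giving cleanly separable but overlapping mixtures); marker expression is
`log2(1 + S f)` plus Gaussian noise (sd 0.5); 200 type-A genes rise and
200 type-B genes fall by 1 log2 unit per unit z (the A panel starts with
the six checkpoint and nine activation symbols so panel stages see
realistic names); IPS = 5.5 + 2 tanh(z) + noise clipped to [0, 10], so
the high-IPS regime sits near the upper third of the scale; survival is
exponential with log-hazard −0.8·z around a 2000-day baseline median,
censored uniformly with the bound calibrated by root-finding so the
expected censoring rate hits 90%; nonsilent mutation counts are Poisson
(8/16/32 by phenotype, BRAF-heavy gene pool) realised as MAF records
plus 20% silent variants; and response is 4-level CR/PR/SD/PD with
responder probability logistic in z (coefficient 2, base rate 25%).

All randomness flows from the single config seed through
`withr::with_seed()`, so cohorts are bitwise reproducible and the
caller's RNG state is untouched.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: gene-gene correlation beyond the shared
latent factor, batch and platform effects, realistic censoring patterns,
subclonal mutations, and any nonlinearity in the IPS-expression
relationship. The generator exists to verify that each stage recovers a
truth it is in-principle able to recover, not to imitate TCGA.

# Numerical choices and degenerate inputs

* Duplicate gene symbols collapse by per-sample median; rows with any
  missing value are dropped and counted.
* Consensus entries for never-co-drawn pairs are 0 and logged;
  `n_resample = 1` therefore yields a 0/1 matrix.
* PAC ties and cutpoint-statistic ties resolve to the smaller k /
  smaller threshold deterministically.
* Wilcoxon uses exact enumeration for combined n ≤ 10 without ties,
  midrank + normal approximation otherwise; Spearman uses the
  tie-corrected test; the 2×k chi-square is Pearson without continuity
  correction.
* Zero-sum NNLS solutions (a pathological all-background mixture) fall
  back to the uniform fraction vector rather than NaN.
* The variance-prior fit guards the method-of-moments solution: when
  the observed variance dispersion is at or below its sampling floor the
  prior df is infinite (complete shrinkage), and finite solutions are
  kept above 4 df so the prior variance exists.

# Problem sizes used in the bundled runs

The packaged analyses and checks run at the generator's default cohort
size (n = 300, 2,000 genes) with 200 consensus resamples per k, 20-100
GSEA/deconvolution permutations, Boruta capped at 20-30 iterations, and
500 replicates for the null-calibration study at n = 100 with more
informative censoring (30%) so each replicate carries enough events for
the log-rank approximation to be meaningful. These sizes were chosen so
each stage's statistical behaviour is measurable while a full run stays
comfortably interactive; all are plain arguments, and the 1,000-resample
/ 1,000-permutation settings match the defaults of the corresponding
functions.

# Known limitations

* The ν-SVR solver follows the published recipe but is not a numerical
  clone of any particular deconvolution service; NNLS is the tested
  reference path.
* PAC-based k selection inherits the degeneracy described above;
  inspect the PAC table and CDFs rather than trusting `chosen_k` blindly.
* The optimal-cutpoint p-value is not corrected for threshold selection.
* Gene-label permutation GSEA understates inter-gene correlation; its
  p-values are anti-conservative on strongly co-expressed sets.
* The A/B typing rule depends on the reference-cluster choice; with a
  poorly separated DEG clustering the assignment is unstable, which is
  why the association statistic is exported per gene.
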