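---
title: "Methods: neoantigen immunogenicity and clonality-aware landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoantigen immunogenicity and clonality-aware landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented by `neoscape`: the
T-cell-recognition model and its assumptions, the patient-level landscape
layer, the parameters that matter, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was open.

## Why model recognition, not just presentation

Burden metrics (TMB) and presentation metrics (neoantigen burden filtered on
MHC binding) ignore whether a T-cell receptor can actually distinguish the
mutant peptide from its wild-type self. Central tolerance removes T cells
recognizing self peptides, so a mutant that is *cross-reactive* with its
wild-type counterpart — recognized by the same TCRs — is unlikely to be
immunogenic, while a mutant pushed far from the wild-type in recognition
space can engage the surviving repertoire. The model therefore scores the
*difference* between the wild-type and mutant 9-mer binding cores, not the
mutant sequence alone, and conditions that difference on the MHC allele's
binding motif, because the groove's residue preferences reshape which
substitutions matter for TCR contact.

## The recognition network

For aligned 9-mer cores the forward pass is: one-hot residues → BLOSUM62
rows → affine embedding into `d_a = 2` dimensions (the same map embeds the
allele motif's frequency rows, so motifs live in the same residue space);
`K = 8` convolution kernels modulated by the motif embedding and applied
position-wise; projection to `d_p = 2`; position-weighted pooling with
learnable per-position weights (separate for MHC-I and MHC-II, initialized
uniform at 1/9); then a geometric representation (origin = wild-type
embedding, unit direction of the mutation, Euclidean distance `d`), a
two-layer tanh scaling network producing `CRD = d * sigmoid(s)`, and a
logistic classifier on `[CRD; binding covariate]`.

Assumptions worth stating:

- **Hamming-1 pairs.** Only single-substitution neoantigens are modelled;
  indels and frameshifts have no aligned wild-type core. For class II,
  15-mers are reduced to their 9-mer cores first (flanking-region effects
  are not modelled).
- **Register pairing.** The binding predictor is run on the *mutant*
  peptide and its reported core register is imposed on the wild-type, which
  guarantees the pair differs at one core position at most. (Predicting
  both independently can produce incompatible registers.)
- **Binding covariate.** The classifier's presentation input is
  `1 - min(rank, R)/R` with `R` the class binder threshold (2 / 10), a
  bounded "binding strength" that is 0 at or beyond the threshold. A raw
  rank percentile would make the logistic layer sensitive to the predictor's
  heavy right tail.

Training: stage 1 minimizes the triplet loss
`max(0, CRD(seed, cross-reactive) - CRD(seed, non-cross-reactive) + margin)`
with margin 1; stage 2 minimizes binary cross-entropy on assay labels with
every representation layer frozen (only the scaling network and classifier
move), selecting the epoch with the lowest validation loss. Both stages use
AdamW at learning rate 0.005 for 100 epochs by default; batches are
full-batch up to 4,096 samples, then mini-batches of 512. Where the
architecture was underspecified we chose: affine `f_embed` (weights + bias),
scaling-network hidden width 8 with tanh, free (unnormalized) position
weights — reported position factors are normalized only for display.
Gradients are hand-derived; the test suite checks them against central
finite differences at 30 random coordinates and checks the whole forward
pass against an explicit loop-based transcription of the defining equations
to 1e-10.

## Curation rules

TCR–pMHC binding records need complete CDR3β / peptide / allele annotation;
peptides failing the class rank filter (2% MHC-I, 10% MHC-II) are removed;
records are grouped by (allele, CDR3) and singleton groups dropped. All
ordered within-group pairs at Hamming distance exactly 1 become
cross-reactive pairs (ordered, because the geometric representation is
asymmetric in wild-type vs mutant). Each pair is completed by 10
non-cross-reactive peptides drawn uniformly without replacement from the
single-substitution variants of the seed (any position) whose substitution
has a strictly negative BLOSUM62 score and which lie outside the seed's
cross-reactive set; pairs with no valid candidate are skipped with a
warning. Labelled epitope sets drop mismatched-length pairs and rank-filter
failures, then split 75/10/15 stratified by label.

Motifs are position-specific amino-acid frequency matrices over the 9-mer
cores of predicted binders from a peptidome sample; no pseudocounts are
added, so frequencies can be exactly zero. The default self-contained
peptidome is uniform random peptides (100,000 in production, small samples
in tests); a FASTA-derived peptidome can be supplied instead.

## Interpretation layer

Motif enrichment acts position-wise and linearly on the residue embedding,
so for each allele and core position the map from the 20 raw residue
embeddings to their motif-enriched counterparts is exactly affine. We fit
`E_m ≈ E_r A + t` by least squares (row-vector convention; the fit is exact
here, residual 0) and decompose `A = U Σ V'`; the axis scaling factors are
`S_x = |V11 σ1| + |V12 σ2|`, `S_y = |V21 σ1| + |V22 σ2|` (absolute values
make them invariant to singular-vector sign flips; the `diag(3, 2) → (3, 2)`
oracle pins the V-indexing convention). The allele benefit score is the
mean over the 9 positions of `sqrt(S_x S_y)`; patient scores are geometric
means within each MHC class, `dual = sqrt(I * II)`, and
`combined = log10(TMB + 1) * dual` (base-10 with +1 pseudocount; the log
base was unspecified and is recorded in output metadata). The affine map is
fit on all 20 residues — which residue cloud to use was an open choice; all
20 keeps the map independent of any binder threshold.

## Mutation metrics and aggregation

PHBR is the harmonic mean over genotype copies of each allele's best rank
(homozygous alleles counted twice, the convention of the PHBR literature);
robustness counts binding alleles; agretopicity is the mutant/wild-type
binding-*score* ratio (a rank-based variant is available); expression
quartiles are right-closed per-patient ECDF bins, invariant to monotone
transforms of TPM. Allele aggregation of recognition scores supports
mean / harmonic mean / weighted average / best-binding / maximum, each with
optional masking to binding alleles; the package default is the masked
maximum. A masked aggregation with an empty survivor set returns
(0, not-presented) rather than falling back to unmasked: a mutation no
allele can present cannot be recognized. The integrated model is a
standardized logistic regression after recursive feature elimination
(drop the smallest standardized |coefficient| one step at a time, scoring
every subset by 4-fold cross-validated AUROC, keep exactly 5 features);
training-set means and standard deviations are stored and reused at
prediction time.

## Landscape layer

With `dual` the product (default; sum and max available) of the MHC-I and
MHC-II recognition scores:

- `np_sum  = log10(1 + Σ_m dual_m)`
- `np_ccf  = log10(1 + Σ_m ccf_m · dual_m)` (never exceeds `np_sum`)
- `np_clone`: class-wise sums within each clone cluster, integrated per
  cluster, then a prevalence-weighted mean over clusters inside the same
  log transform. Prevalences are not assumed to sum to 1; the weighted mean
  normalizes by their total. Mutations lacking a cluster go to singleton
  pseudo-clusters at their own CCF, with a warning.

The `log10(1 + x)` transform (an open choice) keeps empty tumors at 0.
Burdens: TMB counts all mutations, TNB those with PHBR ≤ 2, the
immunogenicity burden those with dual score ≥ 0.16 (0.4², the square of the
roughly-median per-class score). Benchmarks: CSiN with rank cutoffs
{0.375, 0.5, 0.625, 0.75, 1.25, 1.75, 2}, VAF ≥ 0.05 filter and a
500-mutation cap (natural log inside; cutoffs with no qualifying mutation
are skipped and the divisor reduced, with a warning), and ioTNL summing
`L_j · CCF_j` over clusters with elimination score `L_j/S_j < 1.4`, where
`L_j` counts class-I pMHC pairs at rank ≤ 2 (the presentation-burden
convention; the load definition is inherited, not restated, by the source
method). Inequality strictness follows the printed forms exactly: `q < c`
and `L/S < e` strict, `PHBR ≤ 2`, `CCF ≥ 0.85`, `dual ≥ 0.16` non-strict.
Heterogeneity: Gini indices of cluster prevalences and sizes
(`Σ|xi − xj| / (2n Σxi)`), quadrant-classified against cohort medians —
both at-or-below = heterogeneous, both above = homogeneous, off-quadrant =
mixed (mixed patients are excluded from two-group comparisons).

## What the synthetic data emulate — and what they do not

The generators produce every input with known structure: Dirichlet PWM
alleles with sharp anchor positions (class I anchors 2 and 9; class II 1,
4, 6, 9), TCR groups holding a PWM-sampled seed binder plus conservative
(BLOSUM62-positive, non-anchor) variants — the planted cross-reactive
pairs; labelled substitutions whose Bernoulli labels follow a logistic
model on a ground-truth distance defined in the BLOSUM62 PCA plane (not the
model's own embedding, so recovery tests cannot be circular), with both
covariates centered so prevalence stays near 1/2 at any effect size (the
uncentered form saturates to all-positive labels because distances are
strictly positive); and cohorts with a clonal cluster at prevalence 1,
Beta(2, 3) subclones, negative-binomial cluster sizes (patients floored at
4 mutations so per-patient quartiles are defined),
`VAF = 0.5 · CCF · purity` plus Beta noise, and a per-tumor antigen quality
`q ~ U(0.2, 0.8)` driving per-mutation Beta(4q, 4(1−q)) recognition scores.
The quality factor matters: with i.i.d. scores the summed landscape is a
near-monotone transform of the mutation count and a planted
response-follows-quality signal would be unrecoverable by construction.

They do **not** emulate: mutational signatures, immunoediting dynamics,
linkage between binding strength and expression, germline variation, or
realistic HLA allele frequencies. Passing recovery tests therefore shows
the estimators recover the structure they target under a faithful noise
model — not that real cohorts carry that structure.

## Problem sizes and reproducibility

Tests run on deliberately small instances (peptidome samples of ~1,200–
4,000, 25 TCR groups ≈ 1,700 triplets, 15–60 training epochs, cohorts of
4–60 patients); `scripts/acceptance.R` uses the generator defaults
(60 groups, 40 epochs, 60 patients) and completes in about a minute. All
generators and both training stages consume explicit seeds through a
private RNG stream that never disturbs the caller's `.Random.seed`; fixed
seeds give bit-identical parameters, triplet lists and output tables. Model
checkpoints are single JSON files with a versioned schema.

## Known limitations

Single-substitution neoantigens only; 9-mer cores only (no class II
flanking regions); the binding predictor is an interface — production use
requires an external predictor behind the adapter, and the shipped PWM mock
is deterministic test tooling, not a binding model; foreignness is carried
as an optional pass-through column, never computed; the PMBEC matrix is not
bundled (any symmetric 20×20 substitution matrix can be supplied to
`pca_embedding()`); survival analysis and cohort batch-effect evaluation
consume the landscape tables downstream and are out of scope.
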