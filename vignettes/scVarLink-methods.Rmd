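---
title: "scVarLink: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scVarLink: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

scVarLink chains six statistical stages that together connect common
genetic variation to cell-type-resolved expression and on to
donor-level traits in single-nucleus RNA-seq cohorts. This vignette
records the model behind each stage, the tunable parameters and their
defaults, the numerical choices made where the method definition left
room, what the synthetic-data generators do and do not emulate, and
the known limitations. Every empirical statement here is one the test
suite or `scripts/acceptance.R` computes.

## Cell-level quality control

Nuclei are filtered on six rules, applied in a fixed attribution order
(gene count, mitochondrial, ribosomal, hemoglobin, genes-per-UMI, UMI
window) so the per-rule removal counts partition the removed set:

* detected genes < `minGenes` (default 200);
* mitochondrial / ribosomal count fraction > 0.05;
* hemoglobin count fraction > 0.001;
* `log10(genes detected) / log10(total UMI)` < 0.8 — the standard
  definition of the log10GenesPerUMI complexity metric;
* log10 total UMI outside a window derived from a sigmoid fit.

**The sigmoid window.** A logistic CDF
$F(x) = 1/(1+e^{-(x-\mu)/s})$ is fitted to the empirical CDF of
per-cell log10 total UMI by least squares (Nelder–Mead from a
median/IQR start), and cells outside $\mu \pm \ln 4 \cdot s$ are
removed; at those cutoffs the fitted CDF equals exactly 1/5 and 4/5.
Fitting the CDF rather than the density makes the inflection point the
fitted median and keeps the objective smooth and stable; the
alternative (fitting a sigmoid to a histogram) depends on binning. The
fit is declared failed when the optimizer does not converge or the
RMSE against the empirical CDF exceeds 0.1, in which case the cutoffs
fall back to the 1st/99th percentiles and `converged = FALSE` is
recorded. Both cutoffs are applied symmetrically (removal of "either
too high or low" totals). The multiplier $\ln 4$ is a config field
(`sigmoidScaleMultiplier`); tests that need a QC fixture where only
planted violations fail use a wide multiplier, since for a roughly
Gaussian log10-UMI distribution the $\ln 4$ window is aggressive (a
logistic matched to a Gaussian has $s \approx 0.55\sigma$, so the
window is about $\pm 0.76\sigma$).

The thresholds assume a transcriptome-wide gene panel. On the small
synthetic panels used in tests and the demo pipeline the
genes-per-UMI ratio is structurally lower (about 0.7 for a 60-gene
panel), so the demo configuration rescales `minGenes`,
`minLog10GenesPerUmi` and the hemoglobin threshold; this is a
property of panel size, not of the data quality.

Doublet detection is out of scope (an external tool in practice); the
filter report carries a pass-through `doublet` column for externally
supplied flags.

## Normalization and pseudobulk

Per-cell size factors are total counts divided by the mean total
count (unit mean), and the normalized value is
$\log(1 + \mathrm{count}/\mathrm{factor})$. This deliberately simple,
fully specified scheme replaces pooling-deconvolution normalization:
pseudobulk means are dominated by library-size correction, and a
closed-form substitute is testable. The factors are invariant to a
global rescaling of all counts (the ratio definition makes this
automatic). Pseudobulk for one cell type is the per-donor mean of
normalized values over that donor's cells of the type; donors without
such cells are excluded and listed, never imputed.

One consequence documented by the generator tests: a planted
single-gene multiplicative cis effect inflates the carrying cell's
library, and library-size normalization reabsorbs roughly the gene's
library share of the fold. The normalized-scale slope therefore sits
predictably below the planted log-fold (by about
$\beta \cdot \mathrm{share}$); the recovery test asserts the planted
slope up to this compositional attenuation. This is a real property
of library-normalized readouts, not an implementation artifact.

## Variant QC, LD pruning and cis-eQTL mapping

Variants are dropped for minor allele frequency < 0.05, missing call
rate > 0.1, or a Hardy–Weinberg exact test p < 1e-6. The HWE test is
the exact conditional test: given allele counts, the p-value sums the
conditional probabilities of all heterozygote counts (of matching
parity) no more probable than the observed one; probabilities are
computed in log space and renormalized, and the suite checks equality
with a direct enumeration oracle for every genotype configuration up
to 30 donors.

LD pruning is a greedy position-ordered scan: a variant is dropped if
its dosage r² with any already-kept variant within the window exceeds
the threshold (default 0.8 — the threshold is a config field since
only the procedure, not its parameter, is standard); the kept list is
deterministic, and with perfectly correlated pairs the first by
position survives.

Association testing is OLS of pseudobulk expression on alt-allele
dosage plus fixed covariates and the top expression principal
components (default 20, computed from the gene-scaled donor matrix
with a deterministic sign convention: the largest-magnitude loading
of each component is positive). Only fixed covariates are described
for this design, so no random-effect/kinship structure is fitted.
Missing dosages are handled per-pair by complete-case analysis, and
pairs with singular designs (e.g. constant dosage) are skipped with a
reason code. The cis window is inclusive: a variant is tested when
its position is within 250,000 bp of either end of the 1-based
transcribed span, so a variant exactly 250,000 bp away is tested and
one at 250,001 bp is not. Expression PCs are used (rather than
genotype PCs); a `pcs` argument lets callers supply externally
computed components instead. The diagnosis-by-dosage interaction test
fits `expression ~ dosage * diagnosis + covariates` and reports the
interaction coefficient.

## Conditional FDR

For each aligned (gene, variant) pair with primary p-value $p_i$ and
auxiliary (external-study) p-value $a_i$:

$$\widehat{\mathrm{cFDR}}_i = p_i \cdot
  \frac{\#\{j : a_j \le a_i\}}{\#\{j : p_j \le p_i \wedge a_j \le a_i\}}$$

clipped at 1 and monotonized so the estimate is non-decreasing in the
primary p (tied p share their group maximum, keeping the estimator
permutation-invariant). The null proportion is conservatively set
to 1. With an uninformative auxiliary track this reduces exactly to
$p/\widehat{F}(p)$, the unconditional analog. Pairs without an
auxiliary value get cFDR 1 and a flag. Under a global null the
fraction of cFDR ≤ 0.05 calls is far below 0.05 (the suite measures
about 0.001 over 500 replicates), and with shared signals the true
pairs receive smaller values than Benjamini–Hochberg gives them —
the power gain the conditioning is for.

## Colocalization

Per-variant log approximate Bayes factors use the Wakefield form with
$z = \beta/\mathrm{se}$ (or $|z|$ back-computed from a two-sided p
when only p, MAF and n are available), $V = \mathrm{se}^2$ or the
sample-size approximation $1/(2\,n\,f(1-f))$ — divided by $s(1-s)$
for case-control tracks — and prior effect variance $W = 0.15^2$
(quantitative) or $0.2^2$ (case-control), the cited method's
defaults. When both (beta, se) and (p, MAF, n) are present, se wins.
A `mafOverride` argument supports estimating MAF from a cohort rather
than the track. The five hypothesis weights
$(1,\; p_1 S_1,\; p_2 S_2,\; p_1 p_2 (S_1 S_2 - S_{12}),\; p_{12} S_{12})$
are accumulated entirely in log space with log-sum-exp, so regions of
a thousand variants with $|z|$ in the tens (lABFs of several hundred)
normalize without overflow; the suite checks agreement with a naive
direct-summation oracle to 1e-10 and handles a 1122-variant region
with an lABF of 700. The $S_1 S_2 - S_{12}$ difference is computed as
`log1p`-style complement in log space and clipped at zero if rounding
makes it negative (warning at material magnitude). Per-variant H4
posteriors are the softmax of $lABF_1 + lABF_2$.

A note from the simulation design: the case-control track is analysed
by per-variant logistic regression of liability-threshold case status.
Very large liability effects push the causal variant's logistic Wald z
*down* (Hauck–Donner effect under quasi-separation) until LD
neighbors outscore it; the generator therefore plants moderate
liability effects, which is also the realistic regime.

## Causal inference test

For a trio (L, G, T) the four conditions are: L–G association, L–T
association, L–G association given T, and L independent of T
given G. The first three are partial F-tests of L in the obvious OLS
models (covariates included when present; L is numeric dosage with
1 df by default, with a 2-df genotype-factor option). The fourth is
an equivalence-type test: the observed F for L in
`T ~ covariates + G + L` is referred to a noncentral F representing
the hypothesis that the marginal L–T association is a *direct*
effect. Its noncentrality is the marginal F deflated by
$1 - r^2(L, G)$: under a direct effect, conditioning on G inflates
the sampling variance of the L coefficient by exactly
$1/(1 - r^2(L,G))$, so the conditional F of a direct effect is
attenuated by that factor, and using the undeflated marginal F would
reject the direct model too easily (in simulation, an independent
L→G, L→T scenario was falsely called causal 19% of the time with the
undeflated bound and 0% with the deflated one). Small
$p_4 = \Pr(F_{ncp} \le F_{obs})$ means the conditional association
is significantly smaller than a direct effect would produce. The
omnibus p is the maximum of the four (intersection–union: all
conditions must hold).

**Permutation FDR.** T is permuted across donors within each trio —
preserving the L–G backbone while destroying mediation — and the
omnibus p recomputed B = 1000 times;
$q(p) = \mathrm{mean}_b \#\{p^*_b \le p\} / \max(1, \#\{p_{obs} \le p\})$,
clipped and monotonized, with calls at q < 0.05. One subtlety is
load-bearing: the condition-4 equivalence bound (the direct-effect
noncentrality) is part of the test's definition and is therefore held
at its observed value across permutation replicates. Re-estimating it
from permuted data collapses the bound together with the conditional
F, so permuted $p_4^*$ can never be small, the permuted omnibus loses
its entire left tail, and q degenerates to 0 for any observed p below
about 0.25 — in simulation that called 24% of reactive (L→T→G) trios
causal. With the fixed bound the permuted omnibus behaves like a
proper null and, at the suite's study conditions (200 trios per
scenario, n = 500, standardized effects 0.5, B = 1000), causal recall
is 0.80 with reactive and independent false-call rates of 0.

For a no-covariate numeric-L trio every component test reduces to a
(partial) correlation F statistic, so the permutation stream is
computed for all B replicates at once from two crossproducts; the
suite checks this fast path against the lm-based path to 1e-10.

`buildDownstreamNetwork()` prescreens candidate downstream genes by
absolute correlation with the mediator (default 0.3 — the original
screening rule is unreported, so this is a config field), CIT-tests
each survivor and computes the permutation FDR across candidates;
candidates collinear with the mediator (including the mediator
itself) are rejected by the degeneracy guard.

## Differential abundance

For each cell and each neighborhood size k in the grid (default
100–4000 in steps of 500; the reduced preset 100–1000 step 100 for
large data, which the test fixtures use since k must stay below the
cell count), the score is the fraction of the cell's k nearest
Euclidean neighbors carrying condition A, with the cell itself
excluded and distance ties broken by cell index for determinism. The
embedding (top 40 PCs upstream) is taken as given; scores are
invariant to rigid rotations.

The DA measure is the classifier-prediction construction: an
L2-penalized logistic model predicts the condition from the score
vector, and the measure is $2\hat q - 1 \in [-1, 1]$. The ridge
penalty default is deliberately tiny (1e-4): it stabilizes the fit
numerically without shrinking predictions away from the local
condition composition. At a conventional penalty (0.01) the
predictions are shrunk so far toward the base rate that a clearly
enriched subpopulation cannot pass any threshold preset; at 1e-4 the
measure tracks the composition, and the random-label null still stays
far below the selection thresholds (99th percentile of |measure|
around 0.2 in the suite's null runs).

Selection keeps cells with measure ≥ 0.8 or ≤ -0.8 (preset ±0.5),
recording direction by sign. Note the measure has a composition
ceiling: if a subpopulation has condition fractions $f_A$ vs $f_B$,
a perfectly recovered member cell's calibrated measure approaches
$2 f_A/(f_A + f_B) - 1$ — for the 0.3 vs 0.05 planted fixture that is
about 0.71, which is why the recovery analyses use the ±0.5 preset
while the ±0.8 default is exercised by the null (where nothing should
pass). Selected cells are clustered by Louvain on a k = 20 kNN graph
at resolution 0.01; "clustering parameter 0.01" is interpreted as the
Louvain resolution (the most natural reading for a community-detection
step; the original tool's parameter semantics are not stated), and
singleton communities are merged into the nearest community by
centroid distance. Cluster labels are deterministic given the seed.

## Donor-level trait enrichment

Cells are collapsed to donors: a donor belongs to a cluster iff at
least `minCells` (default 1) of its cells carry the label. Categorical
traits use a two-sided Fisher exact test on the membership-by-trait
2×2 table, the sample odds ratio with a Haldane 0.5 correction when a
cell is zero, and BH correction across the clusters of one call.
Quantitative traits use subset resampling: the observed statistic is
the member mean; the null is the mean over random same-size donor
subsets (membership is permuted, not trait values, matching the
donor-level null construction); z is the deviation over the
*population* standard deviation of the null (so the exhaustive
four-donor worked example gives exactly z = 0.7746); the empirical
two-sided p uses the add-one estimator to avoid zeros, and a z-derived
normal p is emitted alongside it since which one the original analysis
reported is unstated. When the subset space has at most `nPerm`
elements, exhaustive enumeration replaces sampling; the suite checks
the two paths agree in distribution (KS statistic < 0.05 on a fixture
where both run).

Antemortem measurement series are reduced per donor to the value with
the smallest days-before-death among those within the window (1095
days, inclusive at the boundary since "within three years" states no
boundary rule); donors with no qualifying entry are missing, never
imputed. Genotype–trait association is OLS with covariates, an
optional pathology main effect and dosage-by-pathology interaction;
quantitative pathology burdens are log(x+1)-transformed when requested
(the +1 accommodates zero burdens), and semiquantitative stages are
treated as numeric. Dosage is used as supplied, with a `flipDosage`
switch between major- and minor-allele counting.

## The synthetic-data generators

The generators provide every input with the statistical structure the
chain assumes; they are first-class, tested code.

* **Genotypes** — haplotypes are a first-order Markov chain: a latent
  Gaussian AR(1) with per-step correlation `ldDecay`, thresholded at
  each variant's frequency quantile. A literal
  copy-previous-allele-with-probability chain distorts marginal
  frequencies whenever adjacent MAFs differ; the latent-threshold
  construction preserves the drawn MAFs exactly while correlation
  still decays geometrically with panel distance. MAFs are uniform on
  `mafRange` ⊆ [0.05, 0.5], mirroring the retained spectrum after
  variant QC; positions increase monotonically along one chromosome
  with 1–5 kb gaps.
* **Cells** — negative-binomial counts with log-normal gene
  dispersions and log-normal per-cell size factors; a designated
  subpopulation with a 4-fold marker-block shift and
  condition-dependent frequency; optional planted QC violations (low
  gene count or inflated mitochondrial share) and optional planted
  cis effects multiplying per-donor gene means by
  $e^{\beta \cdot \mathrm{dosage}}$.
* **Trios** — structural equations per scenario (causal L→G→T,
  reactive L→T→G, independent, confounded) with Gaussian noise;
  scenario constructors enforce the structural zeros (no direct L→T
  slope under "causal", no G–T edge under "independent").
* **Summary-track pairs** — marginal OLS for a quantitative trait and
  per-variant logistic regression of liability-threshold case status
  (case fraction default 0.087) on one shared panel, with one or two
  causal variants.
* **Donor traits** — covariates (age, sex, education) with small
  fixed slopes, a lognormal or staged pathology burden, genotype main
  and interaction effects, plus a timestamped repeated-measurement
  series for the windowing rule.

Everything is deterministic given (config, seed); the pipeline fans a
single global seed out to fixed per-stage offsets so a stage rerun in
isolation reproduces its in-pipeline stream. Since no effect-size
distribution is reported for the real detected eQTL, simulation
defaults (standardized effects around 0.5, unit noise) are chosen for
test power, not realism. What the generators do *not* emulate —
ambient RNA, doublets, transcriptome-wide co-expression structure,
batch effects, imputation uncertainty — bounds what passing tests
show: the chain's estimators are correct and calibrated under the
stated models, not robust to every artifact of real data.

## Problem sizes and numerical conventions

The test and acceptance runs use desk-scale sizes chosen as the
smallest at which each property is statistically decidable: 200 trios
per CIT scenario at n = 500 with B = 1000; ~3000 cells with planted
condition fractions 0.3 vs 0.05 for DA; 2000 GWAS samples over 50
variants for colocalization; 500-replicate null calibrations for the
cFDR; exhaustive enumeration fixtures wherever a closed count exists
(HWE, quantitative enrichment, Fisher). The demo pipeline runs 60
donors, 30 variants, 60 genes and ~50 cells per donor end to end in
well under a minute.

Conventions worth knowing: dosage matrices are donors × variants with
alt-allele dosage 0/1/2 and `NA` for missing; coordinates are 1-based
inclusive; all tables are tab-separated UTF-8 with one header row;
VCF output is v4.2 with GT fields (gzip-compressed); kNN distance
ties break by cell index; PCA signs follow the largest-loading
convention; and every stochastic routine takes an explicit seed.

## Limitations

The eQTL model has no kinship or repeated-measures structure;
trans-eQTL, stepwise conditional eQTL discovery and genotype
imputation are out of scope. Colocalization assumes at most one
causal variant per trait in the region (no multi-signal
decomposition). The CIT cannot distinguish mediation from certain
confounding topologies and its condition-4 calibration is verified by
simulation rather than by equivalence to any particular existing
implementation. The DA measure inherits the composition ceiling
described above, so fixed thresholds should be read against the
plausible enrichment ratios of the study. The sigmoid-window QC rule
is aggressive for unimodal log-UMI distributions; the multiplier is
exposed for that reason.
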