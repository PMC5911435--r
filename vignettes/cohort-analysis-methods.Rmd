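---
title: "Methods: variant-aware outlier calling, dual-analysis DE, and co-expression networks in case/control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-aware outlier calling, dual-analysis DE, and co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cohortex` implements a complete analysis path for a case/control RNA-seq
cohort assayed in patient-derived cell lines (for example lymphoblastoid
cell lines from a cerebral palsy cohort with whole-exome data): gene-level
counts go in, and out come variant-stratified expression outliers with
"resolved" cases, dual-analysis differential expression, hypergeometric
gene-list overlaps with representation factors, and an unsigned weighted
co-expression network with module--trait association and permutation
module preservation. A synthetic cohort generator with planted ground
truth makes every stage testable without access to patient data.

This vignette records the models, the parameters that matter, and the
design decisions taken where the workflow left genuine freedom.

# Preprocessing

**Normalisation and filtering.** Counts are scaled to counts per million
(CPM), with the library size defined as the *total* column sum before any
filtering, so the robust-expression filter remains a pure per-gene
predicate. A gene is retained when its CPM strictly exceeds `min_cpm = 5`
in at least `min_samples` samples; the default sample requirement is the
fraction 120/302 of the cohort, so the rule scales to other cohort sizes
while reproducing the canonical "more than five CPM in at least 120 of
302 samples" behaviour at the reference size. The CPM comparison is
strict (a gene at exactly 5 CPM everywhere is removed) and the sample
count is inclusive.

**Log transform.** `log2(x + pseudocount)` with `pseudocount = 1` by
default. The pseudocount is not dictated by the workflow we emulate; 1 is
the common choice for log2(CPM + 1) and is recorded in the matrix's
provenance.

**Order of operations.** The empirical-Bayes batch adjustment assumes
approximately normal per-gene data, which favours adjusting *logged*
values; the workflow we emulate describes adjusting first and
log-transforming afterwards. The default is log2 then adjustment;
`paper_order = TRUE` in `pipeline_config()` applies the adjustment to
un-logged CPM first. Both paths are exercised by the same code.

**Batch adjustment.** `combat_adjust()` is a from-scratch implementation
of the parametric empirical-Bayes location/scale model: per-gene
standardisation removing covariate effects and pooled variance; per-batch
location (gamma) and scale (delta^2) estimates shrunk toward batch-level
priors (normal on gamma, inverse-gamma on delta^2, hyper-parameters by
method of moments); iterative posterior solve until the maximum relative
change falls below 1e-4; reconstruction without batch terms. The
relative-change stopping rule matches the reference implementation in the
sva package, against which the function is tested for numerical
agreement. Batches confounded with a protected covariate and singleton
batches are hard errors.

The pipeline protects **group and sex** during adjustment. With every
case concentrated in one batch (the cohort design: cases plus in-house
controls in one batch, external controls in the other), protecting only
sex lets the batch term absorb most of the case/control difference —
on synthetic data a planted log2 fold change of 1.0 shrinks to about
0.25 — so the biological contrast must be in the protected design. Users
who want the sex-only behaviour can call `combat_adjust()` directly.

**MDS check.** Classical metric MDS on the (1 − Pearson) sample distance
with the mean silhouette width of a label partition in the 2-D embedding
as the separation score. Inside the pipeline the check is computed on
control samples (in-house vs external) whenever both batches contain
controls: the protected case/control biology would otherwise masquerade
as residual batch separation, and the question the check answers is
precisely whether the two control sets co-locate after adjustment.

# Variant-stratified outlier analysis

For each gene, `Z = (x − mean_ref) / sd_ref` with the sample SD (n − 1
denominator). The default reference is `within_group` — means and SDs
computed for cases and controls separately, each sample referenced
against its own group — with `all_samples` available because both
phrasings of the rule exist in the source workflow; neither is asserted
as the only intent. Genes with zero reference SD are flagged degenerate
and receive Z = 0: they can never be outliers and are reported for QC
rather than crashing the division.

A (sample, gene) pair in a case sample is called an outlier when

* |Z| ≥ 2 and that sample carries *any* annotated variant in that gene
  ("variant-supported"), or
* |Z| ≥ 4 regardless of variant status ("expression-only").

Thresholds are inclusive ("at least k SD") and the variant-supported tier
takes precedence, so each pair yields at most one call. A case is
**resolved** when at least one of its outlier calls is supported by a
same-gene deletion, stop-gain or frameshift variant — the conservative
loss-of-function reading — and each case counts once. The summary reports
`round(100 * resolved / n_cases)`, so nine resolved cases in a cohort of
182 print as 5%.

# Differential expression

Two arms, intersected:

* **primary** — all samples on batch-adjusted log2 CPM, model
  `~ group`;
* **secondary** — cases and in-house controls only (controls sharing a
  batch with cases), model `~ group + age + sex`, on unadjusted log2 CPM
  (no external batch is present in this subset).

Each arm fits per-gene ordinary least squares (via limma's `lmFit`) and
moderates the residual variances with the scaled-inverse-chi-squared
empirical-Bayes model: `s2_post = (d0·s02 + d·s2) / (d0 + d)`, moderated
t with `d0 + d` degrees of freedom, hyper-parameters estimated by moment
matching on the log variances (limma's `squeezeVar`). `ebayes_moderate()`
accepts explicit `d0`/`s02` so the closed-form limits (`d0 = 0` ordinary
t, `d0 = Inf` fully pooled) are directly checkable. P values are
Bonferroni-corrected over the filtered genes.

A gene is reported when |log2FC| > 0.5 in both arms with agreeing sign,
Bonferroni p < 0.001 in the primary arm, and p < 0.05 in the secondary
arm. The secondary threshold applies to the *unadjusted* p value by
default: in the workflow this package reproduces, "corrected" is attached
only to the primary arm's threshold. `secondary_adjusted = TRUE` switches
to the stricter reading. Genes that pass every magnitude threshold but
disagree in sign between the arms are excluded and recorded.

Calibration note: the moderated test's type-I error is checked on
2000-gene replicate null sets (20 + 20 samples). With very small gene
sets (tens of genes) the prior-df estimate is noisy and the realised
type-I error rises slightly above the nominal level; that is a property
of variance moderation, not of this implementation.

# Gene-list overlap

`hypergeom_overlap()` intersects both lists with the background universe
(by default the robustly expressed genes, mirroring a background of
~9884 genes in the reference workflow), then computes the exact
hypergeometric tails `P(X ≥ k)` and `P(X ≤ k)` and the representation
factor `k / (|A||B|/N)`. Both tails are always reported; the headline p
value is the over-representation tail unless the representation factor is
below 1 (so under-representation, e.g. of intellectual-disability genes,
is reported on its own tail). Exactness is verified against exhaustive
enumeration of all draws for N ≤ 12 and against shuffle estimates.

# Co-expression network

All parameters are pinned to the reference workflow: unsigned adjacency
`|cor|^6`, topological overlap

```
TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),   l_ij = Σ_u a_iu a_uj
```

average-linkage clustering of `1 − TOM`, minimum module size 40,
eigengene merge height 0.1, kME merge parameters threshPercent = 50,
mergePercent = 25, reassignScale = 0.6, final assignment at kME > 0.7
(strict) with a grey fallback, and preservation judged at Z-summary > 10.
The implementation is self-contained (matrix algebra for TOM, checked
against a cubic-time reference to 1e-12).

**Dynamic branch cutting.** The published "hybrid" tree-cut algorithm is
intricate; `detect_modules()` implements a documented approximation: a
static cut at `cut_height = 0.995` on the TOM dissimilarity scale,
recursive branch splitting while both children hold ≥ 40 genes and are
separated from their parent merge by at least `min_gap = 0.02`, and
PAM-like rescue of stray genes by mean dissimilarity capped at the cut
height. The cut height is *absolute* deliberately: TOM dissimilarity
lives in [0, 1], and in featureless (pure-noise) data every merge sits
above 0.995, so no modules are reported instead of one spurious
all-gene module. Module labels are colour names assigned by decreasing
size from the conventional palette; grey is reserved for unassigned
genes. Recovery of planted structure — not label-for-label equality with
any particular implementation — is the contract, and is what the test
suite scores.

**Eigengenes and kME.** The module eigengene is the first principal
component of the gene-standardised module submatrix, unit-norm,
sign-aligned so its mean correlation with members is positive. kME is the
Pearson correlation of a gene with a module eigengene; genes may belong
to every module whose kME exceeds 0.7, and to none (grey).

**kME-based merging.** For each ordered module pair (smaller first), the
top 50% of the smaller module's genes by own-module kME are examined; if
more than 25% of them have higher kME to the other module, the modules
merge. The own-module kME used in this comparison carries a rank-one
leave-one-out correction (the gene's own contribution to the eigengene
score is subtracted before correlating): without it the eigengene
overfits its members and even two modules driven by the same latent
factor fail the comparison. After merging, any gene whose best foreign
kME exceeds `reassign_scale` (0.6) times its home kME moves to its
maximal-kME module; eigengenes are recomputed and the procedure iterates
to a fixed point, bounded by twice the initial module count.

**Module--trait association.** Binary traits use Welch's t-test on
eigengene values; continuous traits use Pearson correlation with the
Student asymptotic p value; Bonferroni correction spans all module ×
trait tests. The pipeline tests case status, age, sex, gestation, and
comorbidity/risk-factor flags when present.

**Preservation.** For each module, the density statistic is the mean
intramodular adjacency in the test data and the connectivity statistic is
the correlation of intramodular connectivities (kIM) between reference
and test data. The null re-scores `n_perm = 100` equal-sized random gene
sets drawn from the shared universe *excluding all modules of the tested
set*: random sets that straddle other strong modules carry genuine shared
connectivity and would make the null almost impossible to beat, so the
null deliberately measures unstructured background. Z-summary is the
mean of the two Z scores. On synthetic data the background adjacency is
nearly zero, so permutation nulls are extremely tight and Z-summary
magnitudes are far larger than the values seen in real cohorts; only the
qualitative bars (> 10 for preserved, |Z| ≤ 2 for destroyed structure)
are meaningful. The permutation seed is mandatory and recorded in the
output.

Inside the pipeline the network is built on control samples, eigengenes
are then computed for all samples with modules as defined on controls,
and preservation is evaluated with controls as reference and cases as
test — the cohort-analysis convention this package follows. Module
counts on synthetic data depend on the planted structure and are not
expected to match any particular published count.

# The synthetic cohort generator

`simulation_spec()` defaults describe the study conditions end to end:
182 cases, 20 in-house controls (same batch as cases) and 100 external
controls (second batch); ~2000 genes with baseline abundance log-normal
on the log2-CPM scale (mean 4, SD 2); per-gene NB dispersion log-normal
around 0.1 (biological CV ≈ 0.3, typical for cohorts of unrelated
individuals); library sizes log-normal around 10^7 with CV 0.3 so the
CPM filter has realistic bite; per-gene additive batch shifts (SD 0.5
log2 units) and mild batch dispersion inflation; 50 planted DE genes at
|log2FC| = 1; planted case outliers — 9 loss-of-function-supported and 6
missense-supported at 2.5--4 SD, 10 variant-free at 4.5--6 SD — each on
its own case sample and mid-abundance gene; 200 benign background
variant rows; and three planted 80-gene modules at loading 0.8, the
first with a latent factor correlated 0.5 with case status.

Design choices worth knowing:

* **Outliers are planted in the caller's units.** The target sample's
  log2 expression is shifted by the requested number of within-case SDs
  and rounded back to counts, so a planted 3-SD shift is directly
  comparable with the 2-SD/4-SD rule. The realised Z differs slightly
  because the shifted sample re-enters the reference mean and SD.
* **Modules have hub structure.** Planted module members receive
  per-gene loadings jittered ±0.15 around the module loading. With one
  common loading the intramodular connectivity ranking is pure noise and
  connectivity preservation of a perfectly preserved module would be
  undetectable; real modules always mix hubs and peripheral genes.
  `inject_module()` itself defaults to a common loading so its
  correlation contract (expected pairwise correlation = loading²) is
  exact.
* **What the generator does not emulate:** count-level gene--gene
  correlation outside planted modules, GC/length biases, sample quality
  gradients, relatedness, or any real expression distribution. Passing
  recovery tests on this generator demonstrates that the machinery is
  correct under its stated model, not that any particular biological
  result would replicate.

Every draw is a pure function of the spec (the caller's RNG state is
saved and restored), and the returned GroundTruth object locates every
planted signal exactly.

# Numerical and engineering choices

* Problem sizes in the test-suite: the default cohort (302 samples ×
  2000 genes) for pipeline-level scoring; 2000-gene null sets × 200
  replicates for calibration; 360-gene × 150-sample fixtures across ten
  seeds for module recovery; 400-gene × 120-sample pairs at 100
  permutations for preservation. These sizes were chosen so each
  property is measured with comfortable Monte-Carlo margin.
* Pearson correlation throughout, pairwise-complete for missing data.
* The posterior iteration in `combat_adjust` stops at relative change
  < 1e-4; `squeezeVar`'s moment matching handles the prior fit for
  moderation; ties in module naming are broken by size then input
  order.
* Determinism: with a fixed seed the full pipeline is reproducible; the
  summary carries a checksum over the stage outputs, the config hash,
  seed and package versions, and every written table is prefixed with
  the config hash that produced it.

# Known limitations

* The dynamic tree cut and the kME merge are documented approximations
  of their namesakes; they honour the published parameters but are not
  bit-compatible with any external implementation.
* The secondary DE arm assumes the in-house controls share a batch with
  the cases; cohorts with other layouts should pass their own subset.
* Preservation Z-summary magnitudes are meaningful only relative to the
  qualitative bars; see above.
* No count-model (GLM) differential expression path is provided; the
  moderated-t path on log2 CPM is the one implemented.
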