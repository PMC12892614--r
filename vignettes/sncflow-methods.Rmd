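---
title: "Profiling noncanonical small RNAs in blood: models and methods"
author: "sncflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling noncanonical small RNAs in blood: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncflow)
```

`sncflow` analyses tRNA-, rRNA- and Y RNA-derived small RNA fragments
(tsRNA/rsRNA/ysRNA) in blood small-RNA sequencing, from collapsed reads to a
cross-validated diagnostic risk score. This vignette is the package's own
account of the underlying models: what each stage assumes, which parameters
matter, what the synthetic-cohort generator does and does not emulate, and
where the numerical and design choices were genuinely open.

## Annotation model

The unit of observation is a *species* — a unique read sequence — and the
unit of analysis is a *family*: the anticodon family for tRNA fragments
(e.g. `GtsRNA-Arg-ACG` from nuclear, `MtsRNA-His-GTG` from mitochondrial
tRNAs), the parental subunit for rRNA fragments (`rsRNA-12S`), the RNY gene
for Y RNA fragments (`ysRNA-RNY3`), and the miRNA name for miRNAs.

Species of 15–45 nt are retained and assigned by **exact substring matching**
(zero mismatches, forward strand) against mature parental sense sequences.
Nuclear tRNA references carry the 3' CCA of the mature form, so the
restriction to fragments of mature tRNAs is inherent in the reference set:
a fragment spanning a pre-tRNA boundary simply does not match. When a
species matches references of several classes, a configurable **precedence**
decides (default `miRNA > GtRNA > MtRNA > YRNA > rRNA`): rRNA is by far the
longest and most promiscuous matcher, so it absorbs reads only when nothing
else explains them. Within the winning class, a species matching parents of
different families is flagged ambiguous and assigned to the
lexicographically first family, so that assignment is total and
deterministic. Multi-locus species count **once** toward family expression
(no double counting) but contribute to **every** matched position in
cleavage profiles, where the positional signal is the point.

Family expression is reads per million:
`RPM = count × 10⁶ / denominator`, with the denominator the per-sample
total of retained reads by default (`annotated_total` is available; the
choice changes all RPMs by a common per-sample factor and is therefore
mostly neutral for rank-based and contrast-based statistics).

RPM is **compositional**: the per-sample values sum to at most 10⁶, so any
multiplier applied to every species cancels exactly, and pushing one
family up necessarily pushes the others down. Several design choices below
follow from this.

## Differential families and the signature

For each family and each case contrast (HC vs UC, HC vs CD), the model is
ordinary least squares of **raw RPM** on an intercept, a case indicator, age
in years, and sex (male = 1, female = 0 — the coefficient sign depends on
this encoding, hence it is fixed and documented). Only the two groups of
the contrast enter the fit. The group coefficient's two-sided P comes from
the t distribution with n − 4 degrees of freedom. Within one contrast, P
values are Bonferroni-adjusted over the m families tested (`p.adjust`);
the adjustment is per contrast, and the **signature** is the intersection:
families with adjusted P < α (default 0.05) in *both* contrasts *and* the
same direction of effect. The direction of every signature family is
recorded; callers may restrict to upregulated families, but the default
admits both directions, with downregulated families entering the risk
score with weight −1.

Two caveats worth knowing. First, fitting raw RPM (not log RPM) means the
case-group variance grows with the fold change, so detection power scales
with family abundance; a `log_transform` flag provides the variant on
log2(RPM + 1) for robustness studies. Second, because RPM is compositional,
planting a strong upregulation on some families creates a real, concordant
*downregulation* of the remainder; seeing "down" families co-selected with
planted "up" families in simulations is correct behaviour, not a false
positive in the usual sense.

A numerical corner: families whose residual variance is at rounding-error
level (constant or exactly interpolated data) are detected explicitly and
reported with t = 0, P = 1 (zero coefficient) or P = 0 (exact nonzero
effect), rather than letting floating-point noise produce arbitrary t
statistics.

## The z-sum risk score and its validation

The score of a sample is the signed sum of per-family z-scores of
log2(RPM + 1):

$$\mathrm{score} = \sum_i d_i\,\frac{e_i - \mu_i}{\tau_i}$$

with μᵢ and τᵢ the mean and (n−1)-denominator SD of family *i* over a
stated reference population, and dᵢ = +1 (up) or −1 (down). Zero-variance
families are dropped with a warning. A higher score means a higher
likelihood or severity of disease.

AUC is computed by the rank (Mann–Whitney) identity — the concordant-pair
fraction with ties counted ½ — with no automatic orientation flip: a score
that ranks cases *below* controls honestly reports AUC < 0.5. DeLong's
test compares two correlated AUCs through placement-value covariances.
Both are implemented in the package (they sit inside the cross-validation
loop) and are cross-checked in the test suite against exhaustive pair
enumeration and against pROC.

**Cross-validation** repeats, for each of `rounds` rounds, a stratified
split of the HC/UC/CD samples into k = 5 folds (per group, remainder
samples go one per fold, largest folds first, deterministically given the
seed). For every fold the *entire* signature-derivation procedure is re-run
on the training folds, baselines μ/τ are computed on training samples only
(the leakage-free choice; a full-cohort mode exists behind
`baseline_population = "cohort"` since the reference-population convention
is ambiguous in practice), the held-out fold is scored, and AUC(HC vs UC)
and AUC(HC vs CD) are recorded; the round value is the mean over folds.
Folds whose training split yields an empty signature are excluded from the
round mean and counted. Permuting validation-fold labels cannot change the
trained signature — training never sees them.

### Calibration design

Two properties are checked under the generator's fixed study conditions
(group sizes 30/65/58/52, 300 families; see below):

- **Null calibration.** Under the null generator with Bonferroni α = 0.05,
  essentially every training split yields an *empty* signature — which is
  the correct behaviour but leaves nothing to calibrate. The calibration
  run therefore opens the selection threshold (α = 1), so the score is
  built from pure-noise families and any systematic deviation of the AUC
  from 0.5 would expose bias in the scoring/CV machinery. One further
  subtlety: round-mean AUCs *within* one cohort are strongly correlated,
  because the summed noise score behaves like a single common factor (the
  compositional coupling again) and the whole-cohort AUC is itself a random
  variable with SD ≈ 0.1 under the null. A median over many rounds of one
  cohort therefore estimates that cohort's realized AUC, not 0.5. The
  calibration consequently draws its 100 round-mean AUCs one per replicate
  null cohort; the pooled medians land within a few points of 0.5
  (0.45–0.50 across master seeds, both contrasts), with the residual
  deviation attributable to the mild right skew of the null AUC
  distribution (its mean is exactly 0.5; its median sits just below).
- **Power.** With 20 families planted at 2 residual SDs the median
  round-mean AUC is 1.0 for both contrasts at rounds = 100.

## Co-expression and pathway scoring

Family–gene association uses Spearman's rank correlation (average ranks for
ties) with the t-approximation P, `t = ρ√((n−2)/(1−ρ²))` on n − 2 df, and
**joint** BH adjustment across all family × gene pairs. Genes are called
co-expressed when at least 20 families associate at adjusted P < 0.05 with
a consistent sign; a gene can qualify in both directions (it is then
reported in both sets and flagged — under compositional coupling a gene
tracking the latent factor genuinely correlates positively with loaded
families and negatively with the rest).

Gene-set enrichment is a local one-sided hypergeometric upper-tail test
(overlap ≥ observed) with BH across sets — a self-contained replacement
for web-service KEGG enrichment; the user supplies gene sets as GMT.

Per-sample pathway scores are rank-based: within each sample genes are
ranked by expression descending (rank 1 = highest, average ranks for
ties), weighted `w = exp(−rank/(0.1 N))`, and the set score is
`mean(w in set) − mean(w in complement)`. The exponential-rank weight —
emphasising highly expressed genes, invariant under any strictly monotone
per-sample transform — is this package's fixed contract for the
rank-based single-sample scoring scheme; published variants of such
scores differ in the decay constant, so the 0.1 decay fraction is exposed
as a parameter. Group comparisons of pathway scores use Welch t-tests,
as do all mean comparisons in the package (the unequal-variance form is
the R default and the safer choice for RPM-scale data).

## Cohort divergence

Baseline stability of healthy controls between two cohorts is measured per
family as `log2FC = log2((mean_B + ε)/(mean_A + ε))` on the intersection of
family universes (A is the first-listed cohort; the convention is fixed
and documented since swapping cohorts simply negates the values). The
miRNA-vs-noncanonical comparison applies the two-sample Kolmogorov–Smirnov
test to |log2FC| with the asymptotic P (at ≥ 100 families per class the
exact small-sample correction is immaterial), and baseline linearity is
the R² between log10-transformed mean RPMs — computed as the squared
Pearson correlation, which for simple regression is identical in either
direction.

The pseudocount ε = 0.01 RPM is shared with the fold-change computations;
it only matters for families near zero and its value is exposed in the
configuration.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
study conditions under which the statistical guarantees are measured.

**References.** 48 nuclear tRNA anticodon families (mature, 3'-CCA), the 22
human mitochondrial tRNAs, 8 rRNAs, 4 Y RNAs (RNY1/3/4/5) and 50 miRNA
hairpins by default, as random A/C/G/T sequences of realistic lengths;
rejection sampling guarantees no reference contains another.

**Species.** Each parental RNA gets cleavage hotspots — (offset, length,
weight) triples with weights summing to 1 — whose lengths reproduce the
multi-peak fragment-length distributions seen in blood: tRNA fragments at
17/22 nt, Y RNA fragments at 27/32 nt, rRNA fragments at 15/17/23/26/33 nt,
miRNAs a single 22 nt mature arm. Species sequences are exact substrings of
their parents at the hotspot loci.

**Counts.** Per-sample species counts follow a Gamma–Poisson (negative
binomial) hierarchy *conditioned on the drawn library size*: each species'
rate is `library_size × family weight × hotspot weight × 2^(planted log2
effects)` perturbed by Gamma(shape = dispersion) mixing noise, and the
library total (uniform in `library_size_range`, ≥ 10⁴) is allocated
multinomially to those rates. Conditioning on the total is what a
sequencing run actually does, keeps overdispersion controllable through
the same dispersion parameter (per-species CV ≈ 1/√dispersion; default 10,
CV ≈ 0.32), and makes count conservation exact: annotatable counts sum to
the drawn library size, with a configurable fraction of unannotatable
random species added on top.

**Structure vs draw.** Cleavage hotspots and per-family abundance weights
(log-normal, SD 1 log unit) are drawn under a separate `structure_seed`,
so two cohorts generated from the same references share the same species
universe and baseline abundances — as two sequencing cohorts of one
organism would — while samples, counts and covariates vary with the cohort
seed.

**Planted log2 effects** enter the rate exponent: group effects on chosen
families (the symptomatic-control group receives half of each UC/CD effect
by default, reflecting an intermediate phenotype; the ratio is a free
parameter), an age slope (0.004 log2/year, centred at 49) and a sex offset
(0.08 log2 for males) on the noncanonical compartment, a single latent
factor z ~ N(0,1) per sample whose per-family loadings couple fragment
abundance to a gene module, and a per-miRNA cohort shift
(N(0, `mirna_cohort_shift_sd` log2)) that emulates cohort-specific miRNA
baseline divergence while leaving noncanonical families untouched.
Covariate and latent multipliers act on the noncanonical compartment, not
on every species: a multiplier common to all species cancels exactly under
RPM normalisation, so a "global" covariate effect would be unobservable by
construction. For the same reason the co-expression scenario loads the
latent factor on a *subset* (40 of 82) of noncanonical families.

**Gene matrix.** Gene g in sample j is
`baseline_g + loading_g × z_j + N(0, noise)`; positively and negatively
loaded genes form the `POS_PATH` and `NEG_PATH` sets, plus random decoy
sets, written as GMT.

**Effect sizes in residual-SD units.** `effect_for_sd(k, dispersion)`
returns `log2(1 + k/√dispersion)` — the log2 fold change whose induced
mean shift equals k times the count-model CV, the dominant residual term.
Two caveats are documented rather than hidden: planted mass deflates the
compositional denominator (attenuating realized ratios when the planted
families are many or abundant), and on the raw-RPM scale the case-group SD
grows with the fold change; both make the realized standardized effect
somewhat smaller than k for large k.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequencing error and quality scores, adapter
artefacts, RNA modifications that block or bias reverse transcription
(a major factor in real tRNA-fragment quantification), pre-tRNA species,
genome multimapping beyond the supplied references, batch effects other
than the one planted miRNA cohort shift, and any nonlinearity between
disease severity and expression. Recovery rates measured here are
best-case figures for a correctly specified pipeline, not estimates of
clinical performance.

## Study conditions used by the acceptance checks

The fixed scenarios (exported as `simulate_signature_cohort`,
`simulate_coexpression_study`, `simulate_divergence_pair`) use the
four-group design 30 HC / 65 SC / 58 UC / 52 CD with libraries of 1–2×10⁵
reads. The signature scenario extends the miRNA panel to reach 300
families total (the multiple-testing burden at which recovery is
measured) and plants 20 common-up families at 1.5 residual SDs, with
latent loadings zeroed so the planted group effect is the only structured
signal; the divergence scenario uses a 100-noncanonical / 120-miRNA
reference set (≥ 100 families per class for the distributional KS
comparison) with a 0.5-SD per-miRNA shift; the null-calibration and
error-control checks run 100–200 replicate cohorts. These sizes keep the
full acceptance run at about 1.5 minutes on a single CPU while leaving
every check's sampling error well inside its decision band.

## Pipeline and reproducibility

`run_pipeline()` executes the stages simulate → annotate → profile → diff →
score → cv → coexpress → diverge. Stages communicate **only** through
declared output files (TSV/JSON) in the run directory; missing optional
inputs skip dependent stages with explicit log lines. All randomness
derives from one master seed via named substreams
(`substream_seed(seed, "cohortA")` etc.), so adding a stage never perturbs
earlier streams, and a rerun with the same configuration and seed is
byte-identical — verified by the MD5 manifest the pipeline writes. With
`cache = TRUE`, a stage whose configuration fields and upstream output
hashes are unchanged is not recomputed, so changing, say, α re-runs only
the signature-dependent stages.

## Known limitations

- Exact matching only: no mismatch or indel tolerance, no genome
  alignment, no pre-tRNA (flanked) matching, no modification-aware
  handling.
- The per-family OLS on raw RPM is the deliberate primary model; it is
  heteroscedastic under multiplicative effects and abundance-dependent in
  power (see above).
- The hypergeometric enrichment and the rank-based pathway score are
  self-contained stand-ins for curated-database tooling; no pathway
  content ships with the package.
- The divergence module measures cross-cohort divergence; it does not
  correct for it.
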