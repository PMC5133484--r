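---
title: "Methods: simulating familial blood-pressure phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating familial blood-pressure phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpsimr)
```

## Purpose and scope

`bpsimr` generates replicated systolic/diastolic blood-pressure (SBP/DBP)
phenotypes with a fully known genetic architecture over real or synthetic
genotype data, so that association, linkage and heritability methods can be
scored against ground truth. This vignette documents the model, every
consequential parameter, the numerical choices, and what the validation
results do and do not demonstrate.

## The trait model

For individual $i$ at exam $t$, each trait is

$$y_{it} = \mu + \beta_{age}(age_{it} - 40) + \beta_{sex}\,male_i +
  \sum_j \beta_j g_{ij} + a_i + e_{it}$$

with the following components.

**Variant effects.** Functional variants come in two classes. Deleterious
coding variants of a selected gene receive per-allele effects

$$\beta = \mathrm{percentile}(PP2S) \times PP2S^2 \times \rho_g \times k
  \times l,$$

where $PP2S \in [0,1]$ is the PolyPhen-2 deleteriousness score,
the percentile is its average-tie rank percentile among the selected coding
variants, $\rho_g$ is the genetic correlation between the gene's expression
level and the trait (carrying the sign), $k$ is an overall scale and $l$ a
gene-specific scale. Non-coding variants qualify when they are eQTLs for a
selected gene and lie within 5 kb of its boundaries; their effect is taken
proportional to the observed mRNA–trait correlation,
$\beta = corr \times k \times l$. The proportional form is a design choice:
the two pipelines stay symmetric and the non-coding effect inherits its sign
and magnitude from the observed correlation; any monotone alternative could
be substituted by supplying effects directly to `run_replicates()`.

Under Hardy–Weinberg proportions, variant $j$ contributes variance
$2p_j(1-p_j)\beta_j^2$, assuming linkage equilibrium between functional
variants. That assumption is a documented limitation: variants inside one
gene are in fact correlated, so the summed single-variant "variance
explained" slightly overstates a gene's joint contribution when its variants
are in LD. `calibrate_gene_constant()` solves for $l$ so a gene's summed VE
hits a target exactly (the relation is quadratic in $l$, so the solution is
closed-form).

**Polygenic residual.** $a$ is multivariate normal with covariance
$2\Phi\,\sigma^2_a$, where $\Phi$ is the kinship matrix. So that *total*
heritability equals the configured $h^2$ regardless of how many variant
effects are attached, the residual variance is set to
$\sigma^2_a = h^2\sigma^2 - \sum_j 2p_j(1-p_j)\beta_j^2$, floored at zero
with a warning if the variants alone exceed the genetic budget. The
cross-trait genetic covariance is treated the same way: the target
$\rho_g^{SBP,DBP}\sqrt{h^2_S\sigma^2_S\,h^2_D\sigma^2_D}$ minus the variant
cross-term, clamped so the residual $2\times 2$ matrix stays positive
semi-definite.

**Environmental deviations.** $(e_{SBP}, e_{DBP})$ have variances
$(1-h^2)\sigma^2$ and correlation $\rho_e$. Across exams the environmental
part follows an exchangeable correlation $\rho_{e,time}$ by default (a full
exam-by-exam matrix is accepted); the genetic part is identical at every
exam, so with independent environments the exam-to-exam trait correlation
equals $h^2$ — a property the test-suite verifies at $n = 20{,}000$.

**Medication.** Treated individuals are reduced by fixed amounts, except
carriers of deleterious variants in a designated non-responder gene
(default *CYP3A43*), giving a genotype-by-medication interaction with an
exact truth table. Hypertension is `SBP > 140 | DBP > 90 | medicated`,
strict inequalities. In the family design, medication status is expected as
an observed per-exam indicator held fixed across replicates (mirroring usage
taken from real data); when none is supplied, and always in the unrelated
design, status is Bernoulli per replicate.

**The null trait Q1.** $q_1 = a + e$ with $a \sim MVN(0, 2\Phi h^2\sigma^2)$
and i.i.d. $e$; no sequence variant ever enters, making Q1 a clean type-I
benchmark. Its total variance is configurable and defaults to 1.

## Parameter defaults and their rationale

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mu_sbp`, `mu_dbp` | 125, 74 | mmHg | typical adult cohort means |
| `sigma2_sbp`, `sigma2_dbp` | 238.6, 88.4 | mmHg² | the totals implied by the bundled top-effect table (`implied_trait_variances()`) |
| `h2_sbp`, `h2_dbp` | 0.30 | — | usual family-study BP heritability range |
| `rho_g_traits`, `rho_e_traits` | 0.65, 0.35 | — | strong genetic, moderate environmental SBP–DBP sharing |
| `beta_age` | 0.5 / 0.2 | mmHg/yr | BP rises with age; SBP faster |
| `beta_sex` | 4 / 3 | mmHg | male–female difference, non-negative by construction |
| `med_effect` | 10 / 5 | mmHg | conventional treatment-response magnitudes; no published value exists, so these are deliberate, documented choices |
| `med_proportion` | 0.18 | — | first-exam treatment frequency of an aging cohort |
| `n_exams`, `exam_interval_years` | 3, 5 | — | three exams at 5-year spacing |
| `rho_e_time` | 0.5 | — | moderately persistent environment |
| `q1_h2`, `q1_var` | 0.68, 1 | — | the null trait's defining heritability |
| `window_bp` | 5000 | bp | non-coding eligibility window |
| `pp2s_deleterious` | 0.85 | — | "probably damaging" region of the PolyPhen-2 scale |
| `n_replicates` | 200 | — | replicate count of the distributed design |

These were chosen once as the simulation's study conditions and are not
tuned against any validation outcome.

## Kinship

`pedigree_kinship()` implements the standard recursion
($\phi_{ii} = \tfrac12(1+\phi_{fm})$,
$\phi_{ij} = \tfrac12(\phi_{fj}+\phi_{mj})$) over a topological
(parents-before-children) order, founders taken as non-inbred and mutually
unrelated, families kept as dense blocks of a block-diagonal structure. It is
validated against an exhaustive inheritance-vector oracle that enumerates
every transmission pattern on pedigrees of up to 8 members.

`empirical_kinship()` is the allele-frequency-standardized GRM divided by
two:
$\hat\phi_{ij} = \frac{1}{2M}\sum_m \frac{(g_{im}-2p_m)(g_{jm}-2p_m)}{2p_m(1-p_m)}$,
with missing calls imputed to $2p_m$ and an MAF filter excluding
monomorphic (and optionally rare) sites. No LD weighting is applied — the
estimator is the field's plain GRM; its frequency reference is the sample
itself, so duplicates and relatives are recovered accurately only when
embedded in a reasonably large panel (the tests use 150–200 individuals and
5,000–20,000 variants, recovering pedigree kinship within ±0.03).

## Numerical choices

* **Factorizations.** $2\Phi$ blocks are factored by Cholesky, falling back
  to an eigendecomposition that clamps eigenvalues in $[-10^{-8}, 0)$ to
  zero; anything more negative is an error. Trait-pair covariance matrices
  get a $10^{-12}$ diagonal jitter so the comonotone limit
  ($\rho = 1$) remains factorable.
* **Random streams.** Every draw derives its seed as a hash of
  `(seed, replicate, component)` (and per-variant counters in
  `gene_drop()`), so adding a variant, an individual or a replicate never
  perturbs other draws, and replicate $r$ is reproducible in isolation. All
  arithmetic stays below $2^{31}$.
* **Exact tests.** The Hardy–Weinberg test enumerates the conditional
  distribution of heterozygote counts in log space and sums probabilities no
  larger than the observed one (with a $1+10^{-7}$ slack against ties); it
  matches a term-by-term enumeration oracle to $10^{-12}$ for $n \le 200$.
  The probe-detection test is the exact binomial upper tail at a null rate
  of 0.05 — one-sided, since the question is enrichment of detectable
  expression above the chip's false-call rate.
* **Ties and bins.** PP2S percentiles use average ranks; quantile
  normalization assigns tied entries the average of their tied quantile
  means (via `limma::normalizeQuantiles`); MAF bins close on the upper
  bound, so MAF = 0.01 falls in the rarest bin.
* **Degenerate inputs.** Monomorphic variants give HWE $p = 1$; variants
  with every call missing yield `NA` frequency with a warning; a
  constant-signal expression sample has undefined correlations, treated as
  0 (and therefore dropped by any positive correlation threshold); empty
  matrices pass through normalization unchanged.

## The synthetic fixture generator

`make_fixture()` emulates the structural features the engine needs:
multi-family two-generation pedigrees, founder genotypes in Hardy–Weinberg
proportions at configurable frequencies with Mendelian transmission, genes
with flanking non-coding eQTL candidates, PolyPhen-2-like scores (with
highly deleterious variants scoring 0.9–1), ages around 45 and log-normal
expression signals with a configurable detection rate. It deliberately does
*not* emulate linkage disequilibrium between variants, genotyping error,
missingness patterns, population structure beyond family blocks, deeper
pedigrees, or non-normal trait tails. Validation results on fixtures
therefore demonstrate correctness of the simulation machinery under its own
model assumptions — not robustness of downstream methods to the
complications of real data.

## Validation scales

The routine test-suite exercises Monte-Carlo checks at the smallest sizes
that keep sampling error well inside the asserted bands: 10,000–40,000
unrelated individuals for marginal variances and correlations, 10,000 pairs
for polygenic correlation recovery, 20,000 gene-dropped variants for
empirical-kinship recovery, 100 six-member pedigrees for routine
heritability recovery, and the full published design — 200 replicates on 200
ten-member pedigrees, plus cohorts of 100,000 unrelateds — in the
acceptance checks. `haseman_elston()` regresses trait cross-products on
$2\phi$ over related pairs without an intercept (after standardization,
unrelated pairs have expected cross-product zero); the grand-mean
standardization attenuates the estimate slightly in small, strongly related
samples, which is why heritability recovery is quoted on 200-family
collections.

For the type-I-error property of Q1, naive OLS on related individuals is
anticonservative by construction (both genotype and trait correlate within
families), so the check uses a kinship-aware test: whitening trait and
genotype by the true per-family trait covariance and t-testing the
transformed regression — exact under the model — in the family design, and
plain OLS in the unrelated design where it is already exact.

## Known limitations

* Linkage equilibrium is assumed when accounting variance across a gene's
  variants (see above).
* The non-coding effect-size rule is a modeling convention, not an estimate.
* Founders are treated as unrelated and non-inbred; X-linked kinship and
  identity states beyond $\phi$ are out of scope.
* Year-of-examination effects and tobacco use are not part of the
  generative model.
* Multi-allelic VCF records are split per alternate allele for `GT` and
  dropped for the scalar numeric fields (`DOS`, `NALTT`), with warnings.
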