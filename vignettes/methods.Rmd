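---
title: "Person-centered decomposition of phenotype cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-centered decomposition of phenotype cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Broad-phenotype cohorts of autistic children collect hundreds of item-level
and composite measures per individual — binary questionnaire items, 0–3
ordinal items, standardized t-scores, and parent-reported milestone ages in
months — alongside matched genetic data. Trait-centric analyses associate
one measure at a time with genetic variation and marginalize everything
else. `mixphen` takes the person-centered alternative: model the joint
distribution of all features, infer latent classes of individuals with
coherent phenotype profiles, and only then stratify the genetic analyses by
class.

# The mixture model

## Likelihood

For individual $i$ with feature vector $x_i$ and covariates
$z_i = (1, \mathrm{sex}_i, \mathrm{age}_i)$, the general finite mixture
model (GFMM) with $K$ classes is

$$
p(x_i \mid z_i) \;=\; \sum_{k=1}^{K} \pi_k(z_i) \prod_{j=1}^{d} f_{kj}(x_{ij}),
$$

where each feature's class-conditional density $f_{kj}$ is chosen by type:
Gaussian $(\mu_{kj}, \sigma^2_{kj})$ for continuous features, Bernoulli
$p_{kj}$ for binary items, and multinomial over $L_j$ levels for categorical
items. Features are conditionally independent given class — the usual
latent-class assumption; what the model buys over independent per-trait
analyses is exactly the latent $k$ that ties them together.

Class priors are covariate-dependent through a multinomial logit,
$\pi_k(z) \propto \exp(z^\top \beta_k)$ with $\beta_1 \equiv 0$ for
identifiability (the "1-step with covariates" configuration). Covariates
enter **only** the prior, never the feature densities: sex and age shift how
likely a class is, not what the class looks like. Age is used in years as-is
and sex as 0/1; the intercept absorbs scale, so covariates are not
standardized.

## Estimation

Parameters are estimated by EM:

* **E-step.** Posterior responsibilities
  $\gamma_{ik} \propto \pi_k(z_i)\prod_j f_{kj}(x_{ij})$, computed in log
  space with a log-sum-exp reduction, so densities far below
  $\exp(-700)$ cannot underflow.
* **M-step.** Feature parameters are $\gamma$-weighted maximum-likelihood
  updates (weighted means/variances, proportions, level frequencies). The
  prior coefficients maximize the $\gamma$-weighted multinomial-logit
  likelihood by damped Newton iterations, warm-started from the previous
  M-step and run to gradient max-norm $< 10^{-8}$; the step-halving guard
  keeps each M-step an ascent step, which preserves EM's monotonicity.

Each fit runs `n_init` independent chains from random soft
responsibilities (rows drawn Dirichlet$(1,\dots,1)$ — the least-assumption
multi-start scheme) and keeps the chain with the highest final
log-likelihood. Defaults: `tol = 1e-6` on the log-likelihood gain,
`max_iter = 500`, and a variance floor of $10^{-4}$ *relative to each
feature's overall variance* (features arrive on native scales — months,
t-scores — so an absolute floor would be meaningless; the relative floor
prevents singular Gaussians on duplicated points). Categorical level
probabilities carry $10^{-10}$ pseudo-mass so unseen levels at predict time
score finitely rather than $-\infty$. Prediction is a frozen-parameter
E-step plus arg-max, with posterior ties broken deterministically toward
the lowest class index.

The free-parameter count used by the information criteria is
$3(K-1)$ prior coefficients plus, per class, 2 per continuous feature, 1
per binary, and $L_j - 1$ per categorical.

# Choosing the number of classes

`enumerate_models()` produces, per candidate $K$: the log-likelihood; AIC,
BIC, CAIC ($= \mathrm{BIC} + p$), and SABIC ($\ln n$ replaced by
$\ln\frac{n+2}{24}$); 3-fold cross-validated held-out log-likelihood
(simple random folds, each individual held out once per repetition, summed
across individuals); relative entropy
$1 - \sum_{ik}(-\gamma_{ik}\ln\gamma_{ik})/(n \ln K)$; average posterior
probability per class; and the smallest class's size and proportion.

Consecutive models are compared with a **naive** likelihood-ratio test:
$2(\mathrm{LL}_K - \mathrm{LL}_{K-1})$ clipped at zero against a
$\chi^2$ with the parameter-count difference as degrees of freedom. This is
the plain chi-square comparison, *not* the Lo–Mendell–Rubin adjusted
distribution; mixture-order testing violates the classical regularity
conditions and the naive test is anti-conservative under the null. The
package therefore flags it `naive = TRUE`, and the test suite documents an
empirical null rejection bound of 0.15 at $\alpha = 0.05$ rather than
nominal coverage. Final model choice is deliberately left to the analyst
reading the table — the intended workflow combines statistical fit with
interpretability, and no automatic selector is provided.

# Category affinity profiles

Each feature is assigned to one of seven phenotype categories (limited
social/communication, restricted/repetitive behavior, attention, disruptive
behavior, anxiety/mood, developmental delay, self-injury). After fitting:

1. **Completeness filter** — drop features under 90% complete across
   probands, then probands with any missing surviving feature.
2. **Per-feature tests** — each class against the pooled other classes:
   exact binomial tails (via the binomial CDF, not a normal approximation)
   for binary features against the pooled-other rate; one-sided independent
   t-tests in both directions for continuous and categorical features
   (categoricals scored by level index — they are ordinal 0–3 items in the
   emulated instruments). Pooled-variance t by default with a Welch toggle.
   Benjamini–Hochberg correction runs within each (class, direction) family
   across features.
3. **Exclusion rules** — a feature is contributory unless (1) it is never
   significant ($q \ge 0.05$ in every class and direction), (2) it is
   continuous/categorical with $|d| < 0.2$ (pooled-SD Cohen's d) in every
   class, or (3) it is binary with fold enrichment $< 1.5$ in every class.
4. **Affinity** — for class $c$ and category $g$:
   (enriched contributory features $-$ depleted contributory features)
   $/$ (contributory features in $g$), a signed proportion in $[-1, 1]$.
   Categories with no contributory features yield flagged `NA` cells; the
   null-calibration suites score those cells as 0 (no evidence = no
   affinity) when averaging.

The significance threshold everywhere is BH-adjusted $q < 0.05$ — the
prevailing convention of the analyses this pipeline reproduces, which state
"significant" without restating a level. External validation reuses the
same machinery with siblings as the background (exact binomial for binary
diagnoses; one-sided t with normal-approximation 95% CIs for
sibling-observed features), with the background population exposed as a
parameter since different analyses legitimately use different references.

# Replication across cohorts

`transfer_model()` refits the mixture on the training cohort restricted to
the features shared with the replication cohort and predicts test-cohort
labels with frozen parameters. Contributory-feature exclusion is computed
from the training data only. Both cohorts' affinity matrices are compared by
Pearson correlation per category (over the $K$ class values) and overall on
the flattened $K \times 7$ matrix — flattening is the only construction
that yields a single permutable scalar alongside the per-category values.

Significance comes from a label-permutation null: the test-cohort label
vector is shuffled (size-preserving permutation) `n_perm` times, the
test-cohort affinity matrix recomputed each time *with the contributory set
frozen* from the unpermuted analysis, and the overall correlation
recorded. Freezing tests label assignment only; recomputing exclusion per
shuffle would conflate feature selection with labeling. The p-value uses
the add-one convention $(1 + \#\{r_{\mathrm{perm}} \ge r_{\mathrm{obs}}\})
/ (1 + n_{\mathrm{perm}})$, so zero exceedances report
$p < 1/n_{\mathrm{perm}}$, never 0.

Two subtleties of a threshold-count statistic: a permutation can yield a
constant (all-zero) affinity matrix, where a correlation is undefined — the
permutation statistic scores such matrices $r = 0$ (no affinity signal, no
similarity evidence) so observed and permuted values remain exchangeable;
and the statistic is discrete, so the add-one p is valid but
super-uniform under ties. `permutation_test()` therefore also returns a
tie-randomized p-value — the standard construction that is exactly
U(0,1) under exchangeability for any discrete statistic — which the
calibration suites use to verify the machinery; the add-one value remains
the one to report.

# Genetic analyses

* **Variant classes.** High-confidence LoF = one of the seven LoF
  consequence terms (stop gained, frameshift, splice acceptor/donor,
  start/stop lost, transcript ablation) *and* LOFTEE-style `HC`; damaging
  missense = one of four missense-class terms *and* a `likely_pathogenic`
  prediction; `synonymous_variant` maps to synonymous; anything else
  (including unknown strings, warned once each) is `other`.
* **De novo QC**, in order: individuals above the roster mean + 3 SD of
  total de novo count are excluded (computed once on the pre-filter roster,
  zero-call individuals included, not iterated); variants whose identity
  key appears in more than one family are removed from all of them (the key
  is `chrom:pos:ref:alt` when positional fields exist, else a
  gene/consequence surrogate in TSV-only mode); per-individual counts are
  emitted with explicit zeros for every roster member.
* **Rare inherited** = allele frequency below 1%; records with missing AF
  are kept and flagged `rare_by_absence` (absence from the population
  reference is read as rarity) with the flagged count reported.
* **Burden tests**: per class, mean count per offspring, SE
  ($s/\sqrt{n}$), fold enrichment of means versus siblings, one-sided
  pooled-variance t (proband-exceeds-sibling direction; Welch toggle), BH
  across classes within each (gene set, variant class) family.
* **Odds ratios**: carrier = at least one qualifying variant in the gene
  set; $\mathrm{OR} = (a/b)/(c/d)$ with Haldane–Anscombe $+0.5$ on all
  cells when any cell is zero; one-sided Fisher exact p (the standard 2×2
  exact choice); BH per (gene set, variant class).
* **Constraint bins**: pLI $\ge 0.995$ high, $[0.5, 0.995)$ intermediate.
* **devDEG enrichment**: the burden machinery per (trend × cell type) gene
  set, for each class and the pooled proband group, BH within each set.
* **pLI median comparison**: one-tailed Mood's median test — grand median
  of the pooled pLI values, 2×2 of above/at-or-below by group (ties to the
  at-or-below cell), one-sided Fisher exact p in a pre-declared direction.
* **Hypergeometric term enrichment**: for a term with $K_t$ background
  genes, $k$ overlapping the $n$ impacted genes of $N$ background:
  $\mathrm{FE} = (k/n)/(K_t/N)$, $p = P(X \ge k)$, BH across terms, sorted
  by q then FE. Term databases are plain input gene sets (GMT).
* **PGS contrasts**: per trait, least-squares residualization on
  (intercept, sex, 6 ancestry PCs) over all individuals, then centering on
  the sibling mean and scaling by the sibling SD (center-only available via
  `scale_by_sibling_sd = FALSE` — the normalization description admits
  both readings, and scaling makes shifts interpretable in sibling-SD
  units). Class-versus-sibling comparisons are **two-sided** with BH
  across (class, trait): depletion signals (e.g. educational attainment)
  are as meaningful as enrichments, and the source sidedness is unstated.

# The synthetic-data generator

The generator draws cohorts from exactly the model family the GFMM fits —
Gaussian/Bernoulli/multinomial class-conditionals with a mixing vector or
covariate-logit priors — so parameter recovery is exactly testable. A
`separation` knob scales all class effects; `separation = 0` produces the
null (identical classes) used by every type-I-error suite. The demo spec
emulates a school-age autism cohort: mean age 8.56 y (SD 3.15, truncated to
4–18), 77.4% male, class mixing (0.37, 0.10, 0.34, 0.19), milestone-like
months-scale features, t-score-like scales, binary social/communication
items, and 0–3 ordinal items across the seven categories; siblings draw
from the reference distribution and are observed only on the
social/communication and developmental-delay instruments, mirroring the
limited sibling questionnaire coverage of the emulated cohorts. Variant
tables use per-(group, channel, set) Poisson rates; the default channel
rates give siblings ~2.7 de novo calls per exome with a modest proband
excess concentrated in damaging classes, and 4.5% of offspring are forced
to zero de novo calls so the zero-backfill path is always exercised.
Missingness is MCAR only — the completeness filter is the pipeline's only
missing-data mechanism, and nothing richer is claimed. Milestone truncation
at 0 is available as an explicit misspecification toggle, off by default.

What passing tests on generator data do **not** show: robustness to
model misspecification (real questionnaire items are over-dispersed,
skewed, and locally dependent within instruments), informative
missingness, batch effects across cohorts, or genetic architecture beyond
set-level Poisson rates (no LD, no realistic allele-frequency spectrum).
The generator validates the *machinery*, not the clinical conclusions.

# Numerical and design choices

* EM monotonicity is asserted to $10^{-8}$ per iteration in every test.
* Exact tests (binomial, Fisher, hypergeometric) are exercised against
  direct-summation oracles on all small-margin tables.
* The parameter-recovery suite aligns estimated to true classes by best
  label agreement over all $K!$ permutations and checks continuous means
  per-parameter at 3 posterior SE with a multiplicity-aware joint rule: 80
  simultaneous checks put the expected maximum $|z|$ near 3.2 under
  *correct* estimation, so the joint assertion allows the 99.9% binomial
  quantile of 3-SE exceedances and caps all deviations at 4 SE.
* Desk-scale study sizes (chosen once as the package's validation
  conditions): recovery cohorts $n = 2000$ with 60 mixed features at
  separation 3 SD and 20 restarts; enumeration replicates reuse that
  design with 4 restarts per candidate $K$ (at this separation the
  likelihood surface is effectively unimodal and further restarts are
  redundant); permutation calibration uses 200 replicate runs at
  `n_perm = 200`; burden/median calibration uses 1000 null replicates at
  $n = 500$ per side.
* All randomness flows through explicit integer seeds; generators restore
  the caller's RNG state, so library calls never perturb user code.

# Known limitations

* Missing-data EM is out of scope by design; fit requires complete cases.
* The naive LRT's p-values are descriptive, not calibrated (see above).
* Categorical features are scored by level index in t-tests and Cohen's d,
  which treats them as equally spaced ordinal scales.
* `permutation_test` recomputes enrichment under each shuffle with the
  *observed* class sizes; labels are permuted, never resampled, so the
  null preserves class sizes exactly.
* The minimal VCF reader handles the narrow annotated-call interchange
  format documented in `read_minimal_vcf()` — it is not a general VCF
  parser, and standard multi-sample VCFs should be converted upstream.
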