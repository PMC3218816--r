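---
title: "Combined main-effect and genotype-by-intervention testing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined main-effect and genotype-by-intervention testing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescan)
```

## The model

`gxescan` tests, for each SNP in a nested case-control sample drawn from a
partial factorial randomized trial, the joint null hypothesis of *no
overall association and no interaction with any randomized intervention*.
The alternative it is powered against is deliberately broad: a SNP may
matter only because an intervention's effect depends on it.

Five score statistics are computed per SNP.

**Main effect.** With case indicator $y_i$, dosage $g_i \in \{0,1,2\}$ and
confounders $x_i$, the null logistic model $\mathrm{logit}\,P(y_i=1) =
x_i'\gamma$ is fit once per scan; the score for the genotype coefficient is
$U_M = \sum_i (y_i - \hat p_i)\, g_i^\*$, where $g^\*$ is the genotype
residual after weighted-least-squares projection onto the confounders at
the null fit (the efficient score). Its variance is the expected (Fisher)
information $V_M = \sum_i \hat w_i {g_i^\*}^2$ with $\hat w_i = \hat
p_i(1-\hat p_i)$. Using $g^\*$ rather than raw $g$ leaves $U_M$ unchanged
(the residual $y-\hat p$ is orthogonal to the confounders at the MLE) but
yields per-subject contributions whose cross-products consistently estimate
covariances with other components — needed if the structural zero between
the main-effect and case-only scores is ever disabled.

**Case-only interaction, one per component.** Among cases belonging to a
component with randomization fraction $q$, the model is
$$\mathrm{logit}\,P(\text{active}) = \log\tfrac{q}{1-q} + \alpha + \beta g,$$
and the component statistic is the score for $\beta = 0$ with $\alpha$
profiled. Because $\alpha$ is free, the profiled fitted probability is the
observed active fraction among those cases, and the offset merely centers
$\alpha$ at zero under no intervention effect. This is the essential design
choice: were the intercept *fixed* at $\mathrm{logit}\,q$, an intervention
main effect (which shifts the active fraction among cases away from $q$)
would masquerade as interaction. With the free intercept, the score reduces
to $U_C = \sum_i (a_i - \bar a)(g_i - \bar g)$ with variance $\bar a(1-\bar
a)\sum_i (g_i-\bar g)^2$ — a centered covariance between assignment and
genotype among cases, which randomization guarantees is mean-zero under the
null. The size simulation in the test suite verifies specifically that
intervention main effects do not inflate the combined test.

Component case sets follow the trial design: the two hormone trials are
disjoint (split by hysterectomy status); the dietary component is tested in
the upper baseline fat quartile of its participants, where the intervention
contrast is largest; the calcium/vitamin D component uses only cases arising
after its year-one randomization.

**Covariance and the combined test.** The five scores are assembled into
$U$ and covariance $V$: diagonal entries are the component informations;
the main-effect score is asymptotically independent of each case-only score
(case-control contrast versus within-case assignment contrast), and the two
hormone-trial scores are independent by disjointness — these entries are
exact zeros. The remaining case-only pairs share cases, and their entries
are estimated empirically as $\sum_{i \in A \cap B} c_i^A c_i^B$ over
shared per-subject contributions (a sandwich cross term). Arms of different
components are independently randomized, so these true covariances are
small, but the empirical estimate protects against design quirks. The
combined statistic is $U' V^- U$ with the Moore–Penrose pseudo-inverse
(relative eigenvalue tolerance $10^{-10}$), referred to a chi-square whose
degrees of freedom equal the rank of the retained block — five in the
regular case. Components degenerate for a given SNP (monomorphic among a
component's cases, or a single-arm case set) are dropped and the degrees of
freedom reduced, keeping genome-wide scans total.

## Ranking and the FDR estimate

SNPs are ranked by combined-test p-value and annotated with the rank-based
false discovery rate estimate $\widehat{\mathrm{FDR}}_i = p_i N / i$ for
rank $i$ among $N$ tests. This estimate is intentionally **not**
monotonized: it is the expected null count at $p_i$ divided by the observed
rank, so it can decrease from rank 1 to rank 2 when the top p-value is
relatively less extreme. The monotonized Benjamini–Hochberg step-up value
(cumulative minimum from the bottom, capped at one) is available as an
extra column via `step_up = TRUE`; it is what `p.adjust(method = "BH")`
returns and is never larger at rank 1. Ties in p break by SNP id so ranks
are deterministic.

## Interaction profiles

For descriptive follow-up, intervention odds ratios are estimated
separately at zero, one and two minor alleles by the case-only estimator
$\widehat{OR}_g = (n_{a,g}/n_{c,g}) / (q/(1-q))$, with Wald 95% intervals
on the log scale, $\exp(\log \widehat{OR}_g \pm 1.96\sqrt{1/n_{a,g} +
1/n_{c,g}})$. A zero cell triggers the Haldane–Anscombe +0.5 correction
with an explicit flag rather than silent adjustment; a genotype with both
cells empty reports a missing OR. Interaction per component is tested by a
2-df likelihood ratio test comparing the offset logistic model with
genotype-level indicators (zero copies as reference, so each genotype's
intervention effect is estimated separately) against the
intercept-only offset model; absent genotype levels reduce the degrees of
freedom. Joint models for several SNPs regress assignment on all selected
dosages at once, with collinear pairs rejected by name.

## Discrimination analysis

Three nested logistic risk models are compared in-sample: confounders plus
the four assignment indicators (M0); plus per-SNP indicators for one and two
minor alleles (M1); plus SNP-indicator-by-assignment products (M2). AUC is
the tie-corrected Mann–Whitney concordance probability computed from
mid-ranks. The significance of the interaction terms' AUC contribution is
assessed by resampling *matched pairs* with replacement (pair-level
resampling respects the dependence matching induces), refitting both models
per replicate, and applying a two-sided normal-approximation test of zero
AUC difference with the bootstrap standard error; per-model intervals are
bootstrap percentiles. In-sample AUC without cross-validation is the
reported procedure; separation in any refit falls back to a lightly
ridge-penalized fit ($\lambda = 10^{-4}$ on non-intercept terms), flagged
in the result.

## The synthetic cohort generator

No genotype or phenotype data from the motivating trial are deposited
anywhere, so the package carries a generator whose defaults emulate the
design it targets: roughly 40% of enrollees in a hormone component (split
by hysterectomy into estrogen-alone and estrogen-plus-progestin), 72% in
the dietary component with an 11.8% overlap, calcium/vitamin D
randomization at the one-year anniversary among volunteers then event-free,
assignment fractions $q$ of 0.5/0.5/0.4/0.5, a per-year discrete-time
logistic hazard of 0.004 at baseline over eight years of follow-up
(yielding a realistic ~3% cumulative incidence), and a high-fat subset
comprising the top quartile of dietary participants by baseline percent
energy from fat.

The discrete-time hazard was chosen over full survival machinery because
every published quantity the package targets is an odds ratio: intervention
and genotype effects enter the per-year logit directly as log odds ratios,
and interaction enters as a genotype-specific intervention log odds ratio,
so generator presets can be read off published tables without
transformation.

Genotypes come from Gaussian-copula haplotypes: within an LD block a latent
AR(1) Gaussian sequence is thresholded at each SNP's allele frequency, with
the latent correlation solved numerically (tetrachoric inversion) so
adjacent alleles hit the target allelic correlation exactly; two
independent haplotypes are summed, giving Hardy–Weinberg genotypes whose
adjacent dosage $r^2$ matches the squared target. One base frequency is
drawn per block — variants in strong LD carry near-equal allele frequencies,
and equal frequencies make every allelic correlation in $[0,1)$ attainable.
Ancestry groups (86% / 9% / 5% by default, mirroring a
majority-European-ancestry cohort) apply additive frequency shifts,
producing exactly the stratification structure genotype principal
components detect; simulations in the test suite confirm that PC adjustment
removes the induced confounding inflation.

Matching is greedy risk-set matching: cases in event-time order, exact
match on ethnicity, hysterectomy and per-component participation, nearest
age within a ±2-year caliper, sampling without replacement, unmatched cases
flagged rather than fatal. The matching factors follow the motivating
study; the algorithm itself is a design choice here — greedy nearest-age
risk-set matching is the standard construction for nested case-control
samples — and the caliper is configurable. The Gail-type risk score is a log-normal stand-in (median
five-year risk 1.2%, log-SD 0.4) — a distributional placeholder, since only
its role as an adjustment covariate matters here. Tumor receptor status is
assigned to cases independently of genotype; the label exists to exercise
subtype filters, not to encode biology.

For operating-characteristic studies the package also draws the matched
case-control sample directly from its implied marginal distribution
(`simulate_case_control`): case arm assignments follow odds $q/(1-q)$ times
the intervention odds ratio at the case's genotype — the rare-disease limit
of the cohort model — and controls follow the randomization fractions.
This is what makes 2,000 replicate samples of 2,000 pairs, or single
samples of 50,000 cases, tractable on one CPU; the full cohort path is
validated against it at moderate size in the test suite.

What the generator does **not** emulate: accrual dynamics, adherence,
drop-in, competing risks, early trial stopping, age effects on the hazard,
and any genotype-covariate dependence. Passing tests therefore demonstrate
the statistical machinery under a clean randomized design, not robustness
to those real-data complications.

## Numerical choices and degenerate inputs

* Pseudo-inverse tolerance: eigenvalues below $10^{-10}$ of the largest are
  treated as null directions; the quadratic form's df follow the retained
  rank.
* Monomorphic genotype columns: flagged degenerate (score variance zero)
  and dropped from the combined statistic; in PCA they are removed with a
  warning since they carry no information and break binomial scaling.
* MAF ties at 0.5: the lexicographically smaller allele label is declared
  minor, making dosage orientation deterministic.
* LD $r^2$ uses pairwise-complete genotype dosage correlation (composite
  LD) — the case-control sample is unphased. Constant vectors yield a
  flagged missing value rather than zero.
* Locus binning compares each SNP to the *first* SNP of the current locus
  (anchor-based greedy scan); a fixed anchor makes the convention that
  adjacent regions in low LD open a new locus deterministic. Chromosome
  changes always open a locus.
* PCA standardizes by the binomial standard deviation
  $\sqrt{2f(1-f)}$ with per-SNP mean imputation of missing genotypes — the
  standard construction when the purpose is stratification adjustment. The
  components are computed on cases and controls jointly.
* The case-only score and LRT keep the offset in fitted models so reported
  intercepts translate directly into intervention odds ratios, even though
  the free intercept makes the offset immaterial to the test statistics.
* All simulation functions take a master seed, derive any internal stage
  seeds deterministically from it, and restore the caller's RNG state on
  exit, so a run is reproducible end to end and reordering module calls
  does not silently change results.

## Validation problem sizes

The shipped test suite validates size and power by simulation at sizes
chosen to give adequate Monte-Carlo precision while remaining comfortable
on a single CPU: 2,000 replicate samples of 2,000 matched pairs for the
null size of the combined test (99% binomial band around the nominal 0.05),
50,000-case single samples for genotype-specific odds ratio recovery
(sampling error well inside the 10% acceptance margin), 150 replicates of
800 pairs for the power comparison against the main-effect-only scan, and
1,500 replicates for the sandwich covariance against the empirical score
covariance. Oracle agreements (trend test, iterative maximum likelihood,
brute-force concordance, full eigendecomposition) are exact to stated
numerical tolerances and run in seconds.

## Known limitations

* The main-effect test uses unconditional logistic regression with the
  matching factors as covariates, not conditional (matched-pair)
  likelihood; this mirrors the analysis the statistic was designed for but
  is mildly inefficient under fine matching.
* In-sample AUC is optimistic for SNPs selected by the same scan; the
  cross-validation flag exists but is off by default to match the reported
  procedure.
* The sandwich cross terms are estimated per SNP from the shared-case
  sums; with very small overlapping components the combined statistic can
  be slightly conservative.
* Real-data reuse expects dosage or VCF genotypes with unambiguous allele
  orientation; no strand resolution or palindromic-SNP handling is
  attempted (single-source genotype data).
* The generator leaves ages out of the hazard model, so the documented
  tendency of age-matched designs to depress AUC is not reproducible
  in-simulation; AUC levels here reflect the configured covariate shifts
  only.
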