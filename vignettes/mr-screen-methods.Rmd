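---
title: "Methods: metabolome-wide two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolome-wide two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem and the model

`mrscreen` implements a hypothesis-free two-sample Mendelian randomisation
(MR) screen: many exposures (for example, hundreds of circulating
metabolite concentrations) are each tested for a causal effect on one
binary outcome (disease liability), using only GWAS summary statistics
from two non-overlapping samples.

For exposure *X* and outcome *Y*, each instrument SNP *j* carries an
estimated per-allele effect on the exposure, $\hat\gamma_j$ with standard
error $\sigma_{X_j}$, and on the outcome, $\hat\Gamma_j$ (log-odds) with
standard error $\sigma_{Y_j}$. Under the instrumental-variable
assumptions (relevance, independence from confounders, and effect on the
outcome only through the exposure), $\Gamma_j = \beta\,\gamma_j$, and
$\beta$ — the log-odds of the outcome per SD of exposure — is estimable
from the per-SNP ratios $\hat\Gamma_j/\hat\gamma_j$.

Real instruments violate the exclusion restriction through horizontal
pleiotropy, so a single estimator is never trusted alone. The package
computes a five-estimator battery per exposure:

* **Wald ratio** (single instrument): $\hat\beta = \hat\Gamma_1/\hat\gamma_1$,
  first-order delta-method SE $\sigma_{Y_1}/|\hat\gamma_1|$.
* **IVW**, the weighted regression of $\hat\Gamma$ on $\hat\gamma$ through
  the origin with weights $w_j = \sigma_{Y_j}^{-2}$. The fixed-effect SE is
  $(\sum_j w_j \hat\gamma_j^2)^{-1/2}$; the **multiplicative
  random-effects** variant — the screen's primary significance test, the
  most powerful member of the battery — scales it by
  $\sqrt{\max(1, Q/(J-1))}$ with $Q$ Cochran's heterogeneity statistic.
  Truncation at 1 means underdispersion never shrinks the standard error;
  an untruncated variant sits behind `phi_truncate = FALSE`.
* **MR-Egger**: the same regression with an unconstrained intercept after
  orienting all pairs to $\hat\gamma_j \ge 0$ (without orientation the
  intercept is not identified). The slope is a pleiotropy-robust estimate
  under InSIDE (direct effects independent of instrument strength); the
  intercept estimates the mean direct effect and its *t*-test
  ($J-2$ df, SEs scaled by $\sqrt{\max(1, Q_E/(J-2))}$) flags directional
  pleiotropy.
* **Weighted median** of the per-SNP ratios (weights
  $\mathrm{se}(r_j)^{-2}$, linear interpolation through midpoint
  cumulative weights): consistent while at least half the weight is valid.
* **Weighted mode**: argmax of a Gaussian-kernel weighted density of the
  ratios, bandwidth = `bandwidth_factor` times the modified Silverman rule
  $0.9\,\min(\mathrm{sd}, \mathrm{mad})\,J^{-1/5}$: consistent while the
  largest cluster of instruments is valid. Median and mode standard
  errors come from a seeded parametric bootstrap (default 1000 draws) of
  the summary statistics; normal two-sided p-values.

## The per-exposure pipeline

`runSingle()` fixes the stage order:

1. **Instrument selection** (`selectInstruments`): a p-value ladder from
   5e-8 to 5e-6 (defaults `5e-8, 1e-7, 5e-7, 1e-6, 5e-6`; the published
   screen states only the endpoints) is walked from stringent to lenient,
   and the first rung whose post-clump count reaches `min_instruments = 5`
   wins. Exposures that never reach 5 independent instruments are
   reported not-analysable — a small-J test gives excessive weight to
   single SNPs. Greedy LD clumping retains the lowest-p SNP and discards
   neighbours with $r^2 \ge 0.001$ within 10,000 kb (the published
   "R < 0.001" cutoff is read as $r^2$, the conventional clumping
   parameter — at a 10,000-kb window only that reading matches standard
   stringent practice); ties in p break by (chromosome, position, id) so
   output never depends on input order, and pairwise independence of the
   retained set is certified against the LD reference on every run.
2. **Harmonisation** (`harmoniseSet`): outcome effects are aligned to the
   exposure's effect allele, flipping signs and frequencies for swapped
   alleles and complementing strand-flipped ones. Palindromic variants
   (A/T, C/G) carry no strand information in their letters, so they are
   aligned by matching minor alleles across the traits and excluded as
   ambiguous when the minor-allele frequency exceeds `maf_limit = 0.42`
   on either side — or when either frequency is missing (the conservative
   choice; the flag trail records every decision per variant). Instruments
   absent from the outcome GWAS are replaced by their best LD proxy with
   $r^2 > 0.9$ (strict), multiplying the proxy's outcome effect by the
   sign of the LD correlation; proxy search requires a signed-r LD table
   and is refused for unsigned $r^2$ input. No qualifying proxy means the
   instrument is excluded. Instruments always reconcile:
   pairs + exclusions = instruments selected.
3. **Pleiotropy p-filter** (`pleiotropyFilter`): pairs whose outcome
   p-value is strictly below their exposure p-value are removed — an
   instrument more strongly associated with the outcome than with its
   exposure is suspected of acting through another pathway. The filter
   runs before radial outlier removal (the publication order is not
   stated; both removal lists are kept separately so either order can be
   audited).
4. **Radial MR** (`radialOutliers`): regressing
   $\hat\Gamma_j/\sigma_{Y_j}$ on $\hat\gamma_j/\sigma_{Y_j}$ through the
   origin makes each SNP's contribution to Cochran's Q a
   $\chi^2_1$ statistic; SNPs with upper-tail p below
   `radial_alpha = 0.05` are removed and the fit repeats until no outlier
   remains or fewer than three SNPs would survive. A per-set Bonferroni
   option (`radial_bonferroni`) divides alpha by the current J. First-order
   weights only (outcome SEs); modified second-order weights are out of
   scope.
5. **Estimation and diagnostics** on the surviving set: the battery above
   plus mean F-statistic ($F_j = (\hat\gamma_j/\sigma_{X_j})^2$, weak-flag
   at mean $F \le 10$), Cochran's Q with df and p,
   $I^2_{GX}$ (precision of the instrument-exposure effects relative to
   their spread; low values warn of regression dilution in MR-Egger),
   leave-one-out IVW refits with the count of refits losing significance,
   and the Egger intercept test.

`runScreen()` maps this over an exposure panel, controls multiplicity
over the number of exposures *attempted* (not merely analysable — the
published screen divides by the full panel size: $0.05/575 =
8.7\times10^{-5}$), computes Benjamini–Hochberg adjusted p-values as the
alternative correction, and measures q-q inflation of the primary
p-values as $\lambda = \mathrm{median}(\chi^2_1(p))/0.4549$, flagged above
1.1. Every bootstrap seed derives from the configuration seed and the
exposure id (`deriveSeed`), so results are byte-identical under panel
permutation.

## The synthetic-data generator

`simulatePair()` draws two-sample summary statistics from the linear IV
model the estimators presume, so every pipeline stage is verifiable at
desk scale with known ground truth:

$$\hat\gamma_j \sim N(\gamma_j, \sigma_{X_j}^2), \qquad
  \hat\Gamma_j \sim N(\beta\gamma_j + \alpha_j, \sigma_{Y_j}^2)$$

with maf $\sim U(0.05, 0.5)$,
$\sigma_{X_j} = (2\,\mathrm{maf}(1-\mathrm{maf})\,n_X)^{-1/2}$ for the
standardised exposure (the small-per-SNP-variance regime: the variance
explained by one SNP is ignored), and
$\sigma_{Y_j} = 2(2\,\mathrm{maf}(1-\mathrm{maf})\,n_\mathrm{eff})^{-1/2}$
on the log-odds scale with $n_\mathrm{eff} = 4/(1/\mathrm{cases} +
1/\mathrm{controls})$. The factor 2 in $\sigma_{Y_j}$ is the standard
logistic-regression scaling (verified against a logistic oracle during
development); effects are generated directly on the log-odds scale rather
than through individual-level case-control sampling, keeping the
generator closed-form and fast.

Instrument effects are drawn as $\gamma_j = |N(0, \texttt{gamma\_sd}^2)|$
— the trait-increasing-allele coding conventional in MR simulation
studies. This matters: with symmetric $\gamma_j$, a constant-mean direct
effect would cancel out of IVW and of the Egger intercept after
orientation, and directional pleiotropy would be untestable. Direct
effects $\alpha_j$ are nonzero with probability `prop_invalid`, with mean
`pleiotropy_mean`, spread `pleiotropy_sd`, and correlation
`inside_correlation` with standardised instrument strength (0 = InSIDE
holds). Harmonisation stressors (allele swaps at 25%, strand flips at
10%, palindromic assignment at 10%, outcome deletion with a planted
$|r| = 0.95$ proxy at 5%) recode the emitted records without touching the
latent truth, because all randomness flows from one seed through named
substreams (effects, noise, stressors).

Defaults pin the generator to the observed regime of a metabolome-
against-disease screen: exposure GWAS n = 8000, outcome 29,612 cases and
122,656 controls, and `gamma_sd = 0.115` so that the mean F-statistic is
about 40, inside the 22–51 band such screens report
($E[F] \approx 1 + n_X E[2\,\mathrm{maf}(1-\mathrm{maf})]\,
\texttt{gamma\_sd}^2$). `simulateScreenPanel()` scales this to a panel:
causal exposures draw $|\beta| \in [0.2, 0.7]$ with mixed signs (the
effect band such screens report significant), and each exposure
contributes 25 candidate SNPs so the post-ladder instrument count lands
in the 5–9 range observed in practice. `simulateLDReference()` adds AR-1
LD blocks ($r = \rho^{|i-j|}$ within a block) with lead-SNP signals
propagated through the LD, for exercising clumping and proxy search.

## Numerical choices and degenerate inputs

* Two-sided normal p-values are clamped at $10^{-300}$ so extreme
  z-scores stay inside (0, 1].
* `ratioEstimates` refuses $\hat\gamma_j = 0$ by name; a second-order
  delta option exists and agrees with first-order within 1% whenever the
  outcome z-score is small relative to the exposure z-score, the regime
  instruments live in.
* The weighted mode falls back to the highest-weight ratio when the
  bandwidth degenerates (all ratios numerically identical); ties in the
  gridded density argmax resolve to the lowest grid point, and the grid
  spans the ratio range ± 3 bandwidths at 512 points.
* Egger requires $J \ge 3$ and a non-degenerate design
  ($\det(X^TWX) > 0$); failures are typed "unavailable" results, never
  errors, so a battery always reports every method or its reason.
* p/z consistency of read records is checked within 10% relative error on
  the z scale — published GWAS round p-values — and only warns.
* Validation reruns with other exposure panels need no new machinery:
  they are configuration variants (different files, possibly a relaxed
  `min_instruments`, which the published validation tables suggest).

## What the simulations do and do not show

Problem sizes used by the test-suite experiments (the package's choices
for desk-scale verification): 1000 replicates for null calibration of the
primary test at J = 20, 500 for effect recovery (J = 9), Egger intercept
recovery, and the weighted-median robustness comparison, 400 for radial
calibration/detection at J = 10, and 20 replicate screens of 40 exposures
(4 causal) for end-to-end sensitivity and family-wise error.

The generator emulates: two-sample designs with a binary outcome,
realistic instrument strength, balanced and directional pleiotropy with
optional InSIDE violation, LD structure, and the harmonisation
pathologies of real GWAS files. It does not emulate: sample overlap
between the two GWAS, winner's-curse inflation of selected instrument
effects, fine-scale LD mismatch between the reference panel and either
GWAS, allele-frequency estimation error (palindrome resolution uses exact
frequencies), or non-collapsibility subtleties of odds ratios. Green
simulations therefore certify the estimators and plumbing, not the
epidemiological validity of any particular real-data screen.

Known limitations surfaced by the package's own experiments:

* The truncated multiplicative random-effects IVW is mildly conservative
  under the null (rejection rate ≈ 0.04 at nominal 0.05, J = 20) — the
  price of never letting $\hat\phi < 1$ shrink the SE.
* The MR-Egger intercept is attenuated (by roughly a fifth at these
  settings) when the
  instrument-effect distribution puts mass near zero: sampling noise
  flips the $\hat\gamma_j \ge 0$ orientation of exactly the weak SNPs
  that dominate the intercept, shrinking its mean toward zero. This is a
  property of MR-Egger under weak-instrument contamination, not of this
  implementation (which matches the WLS oracle to machine precision); it
  is why $I^2_{GX}$ is reported alongside the intercept.
* With a much larger effective outcome sample than exposure sample, the
  outcome-vs-exposure p-value filter begins to strip *valid* instruments
  of strong causal exposures once $|\beta| > 2\sqrt{n_X/n_\mathrm{eff}}$;
  at the default sizes that is $|\beta| \gtrsim 0.63$. The filter is kept
  as published, and the removal list makes the behaviour auditable.
* The per-screen family-wise false-positive probability under Bonferroni
  is by construction about $\alpha$ (4–5% for 36 null exposures at
  0.05/40), so individual screens occasionally contain one false
  positive; control is in expectation across screens.

## A worked desk-scale example

```{r example}
cfg <- simConfig(n_snps = 9, true_beta = 0.2, seed = 11)
sim <- simulatePair(cfg)
battery <- runSingle(sim$exposure, sim$outcome, sim$ld, mrConfig(seed = 3))
battery
```

The battery prints the five estimates with their standard errors and
p-values, instrument accounting (selected, excluded, p-filtered, radial
outliers), and the diagnostics row. A panel-level screen is one call:

```{r screen}
panel <- simulateScreenPanel(simConfig(seed = 42), n_exposures = 12,
                             n_causal = 2, n_candidates = 15)
screen <- runScreen(panel$exposures, panel$outcome, panel$ld,
                    mrConfig(seed = 42))
screen
panel$truth[panel$truth$causal, ]
```
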