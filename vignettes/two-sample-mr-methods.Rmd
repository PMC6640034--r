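---
title: "Methods: two-sample Mendelian randomization in mrinflame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrinflame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Two-sample MR treats each genetic instrument $j$ as a natural experiment.
Write $\gamma_j$ for the per-allele effect of SNP $j$ on the exposure (a
serum biomarker, in SD units), $\Gamma_j$ for its effect on the outcome
(Alzheimer's disease, in log-odds), and $\theta$ for the causal effect of
one SD of exposure on the outcome. Allowing a direct (horizontally
pleiotropic) effect $\alpha_j$,

$$\Gamma_j = \theta\,\gamma_j + \alpha_j .$$

The package's estimators are exactly the estimators this identity suggests:

- **Wald ratio** (one SNP): $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ with
  first-order delta-method standard error
  $\mathrm{se}(\hat\Gamma_j)/|\hat\gamma_j|$. The exposure-side sampling
  error is ignored, as is standard in two-sample practice; it enters only at
  second order and its consequences are discussed under *Limitations*.
- **IVW**: the fixed-effect weighted regression of $\hat\Gamma$ on
  $\hat\gamma$ through the origin with weights
  $w_j = 1/\mathrm{se}(\hat\Gamma_j)^2$,
  $$\hat\theta = \frac{\sum_j w_j \hat\gamma_j \hat\Gamma_j}
                      {\sum_j w_j \hat\gamma_j^2},\qquad
    \mathrm{se} = \Big(\sum_j w_j \hat\gamma_j^2\Big)^{-1/2},$$
  algebraically the inverse-variance-weighted mean of the Wald ratios, and
  identical to the single Wald ratio when only one instrument survives.
  Unbiased only when all $\alpha_j$ average out.
- **MR-Egger**: the same weighted regression with a free intercept. The
  slope estimates $\theta$ and the intercept the average directional
  pleiotropy $\bar\alpha$, provided instrument strength is independent of
  the direct effects (InSIDE). Identification needs spread in $\gamma$, so
  the fit is refused below three instruments.

Inference uses the normal reference distribution for Wald and IVW and
$t_{n-2}$ for both Egger coefficients, two-tailed throughout; these match
the dominant published implementations of each estimator. Results are
reported on the log-odds scale and, for presentation alongside case-control
effect sizes, as odds ratios per SD with exponentiated interval bounds.

Because the regression with an intercept is not invariant to reflecting a
point through the origin, MR-Egger requires a fixed orientation: all
exposure effects are made non-negative, flipping the paired outcome effects.
Orientation changes the intercept's sign, never its magnitude, and is
recorded on the returned object.

Three deliberate defaults deserve mention. The IVW estimator is
fixed-effect: with the 2–4 instruments available per cytokine, a
multiplicative random-effects scale is essentially unestimable, so the
option exists but is off. The confidence level defaults to 95%. And an
instrument set with exactly one SNP still yields an estimate (the Wald
ratio), while Egger is skipped with a logged reason rather than an error so
that a pipeline run always produces its IVW row.

## Instrument selection

Candidates are filtered on genome-wide significance
($p \le 5\times10^{-8}$) and on folded minor-allele frequency
$\min(f, 1-f)$ strictly above a floor (default 0.3, configurable — the
packaged instrument table itself contains index SNPs with folded MAF as low
as 0.066, so reproducing it requires relaxing the floor). Variance explained
per SNP uses the standard biallelic formula for a unit-variance trait,
$R^2 = 2\beta^2 f(1-f)$, on folded frequency; this is the only formula
exposed. It is symmetric in $f \leftrightarrow 1-f$, maximal at $f=0.5$,
and consistent with the packaged table's magnitudes
($\beta \approx 0.24$ SD at $f = 0.34$ gives 2.65%).

Clumping builds a graph over candidates with edges where *known* pairwise
$r^2$ exceeds the threshold (default 0.2), takes connected components
(transitive closure), and keeps the record with the greatest $|\beta|$ per
component — $|\beta|$, not $\beta$, because effect sign depends on arbitrary
allele coding. Ties break to the smaller p-value, then the lexicographically
smaller rsID, making the result deterministic and order-invariant. A pair
absent from the LD table is treated as independent with a logged note, never
as linked: absence of LD evidence is not evidence of independence, but the
selection rule only acts on known linkage.

A note on frequency columns: instrument tables in the literature sometimes
label a frequency column "minor allele frequency" while containing values
above 0.5. The package stores such columns as effect-allele frequency —
the only reading under which values like 0.934 are coherent — and folds
internally wherever a MAF is required.

## Harmonization

Each exposure index SNP is aligned to the outcome dataset on the exposure's
effect allele:

1. same allele pair, same order — kept;
2. same pair, reversed — outcome $\beta$ negated, frequency complemented;
3. reverse-complementary pair (strand difference, non-palindromic) —
   complemented, then rule 1 or 2;
4. palindromic pair (A/T or C/G) — allele labels cannot distinguish a strand
   flip from an allele swap, so orientation is decided by frequency: if the
   effect-allele frequencies fall on the same side of 0.5 in both datasets
   the reported orientation is kept, otherwise it is flipped. If the folded
   frequency lies within $w$ of 0.5 in either dataset the comparison is
   unsafe and the SNP is dropped. The default $w = 0.08$ is a conventional
   safety margin; $w = 0$ trusts any frequency difference, reproducing the
   permissive behaviour implied when palindromic SNPs with near-balanced
   frequencies are retained in published analyses.
5. absent from the outcome — the LD table is searched for the highest-$r^2$
   partner with $r^2$ strictly above 0.8 present in *both* datasets; the
   proxy's own statistics replace the original's (exposure statistics must
   come from the supplied exposure pool; a proxy absent from it drops the
   original). Otherwise the SNP is dropped as unmatched.

An outcome record with an unknown other allele makes strand resolution
impossible and is dropped with a logged reason. Every decision — kept,
flipped, strand-swapped, palindromic-aligned, palindromic-dropped, proxied,
dropped — is recorded per SNP, and `audit_report()` returns the lossless
decision table; harmonization choices are the scientifically sensitive part
of any summary-statistic MR and must be auditable.

## Power

For a binary outcome the Wald statistic of the causal log-odds ratio has
approximate noncentrality $\sqrt\lambda$ with
$\lambda = n\,R^2 \log(\mathrm{OR})^2 K(1-K)$, where $R^2$ is the exposure
variance explained by the instruments, $n$ the outcome-study size, and $K$
its case fraction (default 0.314, the composition of a 17008-case /
37154-control AD meta-analysis). Two-sided power at level $\alpha$ is
$\Phi(-z_{1-\alpha/2}+\sqrt\lambda)+\Phi(-z_{1-\alpha/2}-\sqrt\lambda)$,
which equals $\alpha$ at the null OR and is monotone in $n$, $R^2$, and
$|\log \mathrm{OR}|$. `min_sample_size()` inverts this numerically and
returns the smallest integer $n$ reaching the target (default 0.8),
erroring at the null OR where no sample size suffices.

## The synthetic-data generator

`simulate_mr()` emulates the summary statistics a two-sample MR consumes —
not the individual-level studies behind them. Per SNP: effect-allele
frequency $f_j \sim U(0.1, 0.9)$; true exposure effects
$\gamma_j \propto U(0.5, 1.5)$, rescaled so
$\sum_j 2\gamma_j^2 f_j(1-f_j)$ equals the target total $R^2$ (default
0.03, the order of the per-biomarker totals 3.15%, 1.95%, 3.23%, 2.99%);
pleiotropy $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$, given a chosen
correlation with instrument strength (0 preserves InSIDE); and exactly
$\Gamma_j = \theta\gamma_j + \alpha_j$. Observed effects are drawn normal
around the truth with $\mathrm{se}(\hat\gamma_j) = (2 n_x f_j(1-f_j))^{-1/2}$
and $\mathrm{se}(\hat\Gamma_j) = (2 n_y K(1-K) f_j(1-f_j))^{-1/2}$ — the
large-sample approximations for a standardized trait and a log-odds score
test. Default sample sizes mirror the motivating studies: $n_x = 12\,736$
(the largest cytokine GWAS) and $n_y = 54\,162$ with $K = 0.314$.

Two generator choices matter and are deliberate. First, outcome statistics
are generated directly on the log-odds scale from the linear approximation;
no case-control sampling is simulated, because the estimators consume only
summary statistics and the approximation error is irrelevant to testing
estimator algebra. Second, the $\gamma_j$ are positive and bounded away from
zero with a roughly 3-fold spread — the shape of a genuine index-SNP table,
where the significance filter guarantees no near-zero effects and published
per-SNP $R^2$ values span about an order of magnitude. Positivity also fixes
the orientation relative to which "directional" pleiotropy is defined; with
sign-symmetric effects a constant $\alpha$ would cancel under Egger's
orientation convention and the intercept would estimate zero by
construction.

Corruptions are applied to the outcome *after* observation, with the clean
coding retained in the truth record: allele-order swaps
(EA↔OA, $\beta \to -\beta$, $f \to 1-f$), strand flips (non-palindromic SNPs
only; a strand flip of a palindromic SNP is invisible by definition),
missing-in-outcome deletions, and LD twins — high-$r^2$ companions present
in both datasets that give clumping something to prune and proxy search
something to find. Because corruption is purely representational,
harmonization must (and, by test, does) restore the original effect pairs
bit-for-bit. All draws consume one RNG stream seeded from the configuration
in a fixed documented order, so any seed is exactly reproducible.

What the generator does **not** emulate: realistic LD beyond injected
twins, winner's-curse inflation of the exposure effects (instruments are
not selected on the simulated data unless the pipeline's filter is run),
sample overlap between the two studies, and population stratification.
Passing tests therefore validate the pipeline's algebra and bookkeeping
under the stated model, not robustness to these additional features of real
data.

## Validation design and numerical choices

The test suite validates each estimator against an independent
normal-equations weighted-least-squares oracle to $10^{-10}$ on randomized
instances (200 instances, 3–6 SNPs), checks the single-SNP degeneracy
(IVW ≡ Wald, exact) and the collapse of zero-intercept Egger onto IVW,
and checks clumping against exhaustive connected-component enumeration on
small graphs. Monte-Carlo suites (1000 replicates) verify IVW's null
behaviour — unbiasedness at $\theta = 0$ and empirical size 5% at
$\alpha = 0.05$ — and a 100-seed sweep verifies that swap/flip corruptions
are exactly undone. The Egger-vs-IVW contrast under directional pleiotropy
(intercept recovers $\bar\alpha$, slope stays on $\theta$, IVW departs from
it) is asserted at $m = 50$ with $n_x = 2\times10^6$: consistency of the
Egger slope is an asymptotic property in instrument precision, so it is
tested in a regime where exposure-side measurement error is negligible.

Numerical conventions: strict inequalities where thresholds are phrased as
"greater than" (MAF floor, clump $r^2$, proxy $r^2$); exact summation for
total variance explained; `uniroot` on the noncentrality followed by an
integer walk for minimum sample size; and TSV output written with 17
significant digits so write-then-read round trips are lossless.

## Limitations

The dominant one is weak-instrument bias. With noisy exposure effects the
IVW estimate is attenuated by approximately
$R^2/(R^2 + m/n_x)$ — about 2.5% attenuation at $m = 10$, $R^2 = 0.03$,
$n_x = 12\,736$ (mean per-SNP $F \approx 38$). The MR-Egger slope is diluted
more severely, by roughly
$\mathrm{var}(\gamma)/(\mathrm{var}(\gamma) + \overline{se_x^2})$
(the $I^2_{GX}$ statistic), because it is identified from the *spread* of
instrument strengths; at realistic cytokine-instrument strengths this
factor can be 0.6–0.85, and the intercept absorbs the complementary bias.
Neither estimator corrects for this (no SIMEX), matching the analyses the
package models; the consequence is that strict mean-recovery checks at
study-scale sample sizes detectably fail while null behaviour and size are
preserved, and the recovery tests at those scales document this expected
attenuation. Other limitations: the Wald SE omits the second-order
exposure-variance term; palindromic orientation by frequency is fallible
when both datasets sit near 0.5 even outside the ambiguity window; proxy
substitution does not re-orient the proxy to the original SNP's alleles
(the proxy is harmonized on its own coding); and the power formula is an
approximation that ignores instrument-estimation uncertainty in $R^2$.
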