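---
title: "The similarity-based weighted U test: model, null distribution, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The similarity-based weighted U test: model, null distribution, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wujoint)
```

## The problem

Sequencing studies yield many rare single-nucleotide variants (SNVs) per
gene, each too infrequent for single-marker tests.  Set-based tests
aggregate a gene region's variants into one statistic.  When expression
data for the same samples exist, a joint test can borrow strength from
both molecular levels: a regulatory signal that is weak in genotypes
alone and weak in expression alone may be clear in combination.
`wujoint` implements a similarity-based weighted U statistic for this
joint analysis, with genotype-only (G), expression-only (T), and joint
(G+T) modes, a genome-screen driver, and a synthetic-data generator for
validation.

## The statistic

For a gene region with $K$ SNVs, let $p_k$ be the minor allele
frequency (MAF) of SNV $k$ and $v_{jk} \in \{0,1,2\}$ the minor-allele
dosage of sample $j$.  The per-sample burden score is the weighted sum

$$a_j = \frac{\sum_k w_k v_{jk}}{2 \sum_k w_k}, \qquad
  w_k = \frac{1}{\sqrt{p_k (1 - p_k)}},$$

which lives in $[0,1]$ and up-weights rare variants.  With $t_j$ the
expression value of the matched probe and $y_j$ the (tie-averaged) rank
of sample $j$'s phenotype, the statistic is

$$U = \sum_{i \ne j} f(a_i, a_j)\, g(t_i, t_j)\, h(y_i, y_j),$$

where the phenotype kernel
$h(y_i,y_j) = (y_i - \bar y)(y_j - \bar y)/\widehat{\mathrm{Var}}(Y)$
is the outer product of standardized centered ranks, and the genotype
and expression similarities are Gaussian,
$f(a_i,a_j) = \exp\{-(a_i-a_j)^2/d\}$ and likewise for $g$, with a
shared denominator $d = 2N$ ($N$ = sample count) by default.  Fixing
$g \equiv 1$ gives the G mode, $f \equiv 1$ the T mode.  Sample pairs
that are similar in genotype and expression receive large weights; if
their phenotypes also co-vary, positive $h$ values are up-weighted and
$U$ grows.

Two conventions matter and are fixed here deliberately:

* **Rank variance.**  $\widehat{\mathrm{Var}}$ is the sample variance
  (denominator $n-1$) of the realized, tie-adjusted rank vector.  This
  makes $\sum_{i \ne j} h(y_i,y_j) = -(n-1)$ an exact identity (the
  centered ranks sum to zero), so $U = -(n-1)$ exactly under unit
  similarity weights — a convenient anchor used throughout the tests.
* **Binary phenotypes.**  Case/control traits pass through the same
  rank kernel: all cases share one averaged rank, all controls another.
  No separate machinery is needed, and the permutation oracle validates
  the calibration for this case exactly as for quantitative traits.

### The bandwidth

With burden scores in $[0,1]$ and $d = 2N$, the genotype similarity is
confined to $[e^{-1/2N}, 1]$ — numerically close to 1.  That is not the
defect it may appear to be: subtracting the permutation-constant part
of the kernel leaves a statistic proportional to the kernel's
*variation*, and the null distribution is scaled by exactly the same
factor, so the test is essentially invariant to the overall bandwidth
scale.  What the bandwidth does control is the *shape* of the kernel's
dependence on distance (how quickly similarity decays, hence how much
weight tail pairs carry).  The printed default is kept, and
`kernel_config(bandwidth_denominator=)` exposes the choice.  Expression
values are standardized before the kernel by default
(`standardize_expression = TRUE`) because expression units are
arbitrary while the shared denominator is scale-sensitive; burden
scores are already on $[0,1]$ and are left unstandardized by default.

One visible consequence of these conventions: in the joint mode the
expression kernel (standardized values, range several units) varies far
more than the genotype kernel (burden differences below 1), so the G+T
statistic is numerically dominated by the expression channel and
`p_gt` typically tracks `p_t` closely under the defaults.  Because an
eQTL-coupled gene expresses its genetic signal through expression as
well, the joint test still captures genotype-driven associations; users
who want the two channels on an equal numerical footing can set
`standardize_burden = TRUE`, which puts burden distances on the same
scale as expression distances.

## The null distribution

Under no association, the phenotype ranks are exchangeable across
samples, so the exact null of $U$ is its permutation distribution with
the similarity matrix $M = f \circ g$ (zero diagonal) held fixed.  $U$
is a quadratic form $z' M z$ in the standardized centered rank scores
$z$, and the classical large-sample treatment approximates it by a
linear combination of independent $\chi^2_1$ variables with weights
from the spectrum of the doubly-centered kernel $PMP$,
$P = I - \tfrac{1}{n} J$ (see `mixture_weights()`).

Two finite-sample facts break the naive version of that approximation
in exactly the regime this test occupies, and the package's null
construction addresses both:

1. **The rank vector has fixed norm, not just fixed sum.**  $\sum_i
   z_i = 0$ *and* $\sum_i z_i^2 = n - 1$ hold for every permutation.
   The spectrum of $PMP$ respects the first constraint only.  When the
   kernel is nearly constant (the default bandwidth), almost all of the
   spectral mass of $PMP$ sits on the fixed-norm direction — variance
   the permutation distribution does not actually have.  The
   construction removes the trace component (subtracting
   $\mathrm{tr}(PMP)/(n-1)$ from the support spectrum), after which the
   adjusted eigenvalues sum to zero and the mixture is automatically
   centered.
2. **The bulk spectrum is not independent chi-squares.**  Projections
   of a permuted fixed vector onto the many near-zero eigen-directions
   are strongly negatively dependent; treating them as independent
   $\chi^2_1$ overstates the remainder variance by orders of magnitude
   and smears the distribution's support edge.  The package therefore
   keeps only the few dominant eigen-components explicitly and handles
   the rest as a Gaussian remainder whose size is fixed by *exact*
   moments.

The exact moments come from closed-form permutation moment formulas for
Mantel-type statistics: the mean and variance of $\sum_{i \ne j} M_{ij}
z_{\sigma(i)} z_{\sigma(j)}$ (and of any auxiliary quadratic form, with
diagonal terms handled separately), plus the third central moment via
sums over the eight isomorphism classes of three-edge multigraphs
(`perm_cumulants()`).  All formulas are verified against full
enumeration of permutations at small $n$ in the test suite, and the
computation splits off the constant part of the kernel first so that
near-constant kernels do not cause catastrophic cancellation.

Each retained eigen-component $\lambda_j w_j^2$ (with
$w_j = u_j' z_\sigma$, unit permutation variance) is modeled as a gamma
variable with unit mean and that component's exact permutation variance
$\mathrm{Var}(w_j^2)$.  The gamma family is chosen over a scaled
$\chi^2_1$ for one reason: permuted rank projections have a fourth
moment slightly below the Gaussian value, and matching their variance
by *scaling* a $\chi^2$ would move the hard support edge at
$w_j^2 \ge 0$ — precisely where the null density spikes — while the
gamma shape absorbs the moment deficit with the edge intact.  The
covariance between each component and the remainder (an approximately
linear-in-$w_j^2$ coupling) is folded into an effective eigenvalue, so
the edge also sits at the correct *conditional* location, and the
Gaussian remainder is sized so the total exact permutation variance is
matched.

This construction was selected against the built-in permutation oracle
(`permutation_pvalue()`): p-values are uniform under permutation
*conditionally on a gene* (Kolmogorov–Smirnov at thousands of permuted
phenotypes), rejection rates sit inside the binomial band at
$\alpha = 0.05$ for all three modes at $n = 142$, and asymptotic and
permutation $-\log_{10} p$ agree with correlation above $0.99$.  The
classical unadjusted construction is retained behind
`mixture_weights(norm_adjust = FALSE)` for the case of genuinely
independent (non-permutation) scores.

## Tail probabilities

`davies_pvalue()` computes $\Pr\{\sum_i \lambda_i (\chi^2_{1,i} - 1)
\ge q\}$ by numerical inversion of the characteristic function, the
approach of Davies, generalized internally to gamma mixtures plus a
Gaussian component.  Numerical choices:

* adaptive quadrature of the Gil–Pelaez integrand on $[0, U]$ with
  absolute target $10^{-8}$ and two truncation rules: an envelope bound
  when the integrand's modulus decays fast enough, otherwise an
  integration-by-parts correction for the oscillatory tail with its
  remainder added to the error estimate;
* a reported fault when the certified error exceeds $10^{-6}$, in which
  case the result falls back to a shifted-gamma (Pearson III) tail
  matched to the first three cumulants, with `method =
  "moment_fallback"` recorded;
* eigenvalues below $10^{-10}$ of the largest are truncated after the
  trace identity is checked;
* p-values are clamped to $[10^{-14}, 1]$ so integrator underflow never
  reports an exact zero.

Accuracy is verified against chi-square closed forms (unit-weight
mixtures, absolute error below $10^{-6}$ across the distribution
including far tails) and Monte Carlo for mixed-sign mixtures.

## Screen mechanics

* **Regions.**  Gene coordinates (GFF3 or BED; BED's half-open
  convention converted at parse time) are expanded by a flank of 5,000
  bp on both ends, strand ignored.  An SNV belongs to a region iff
  $\mathrm{start} - \mathrm{flank} \le \mathrm{pos} \le \mathrm{end} +
  \mathrm{flank}$ — a closed interval; the boundary base itself is in.
  SNVs may belong to several overlapping regions.  Monomorphic SNVs
  (MAF = 0 in the analysis sample) are dropped, then regions left with
  no SNVs, and regions without an expression probe; `region_report()`
  reconciles every input region into retained or one drop reason.
* **Probes.**  One test per (region, probe) pair: a gene matched by
  several probes yields several records flagged by probe id, rather
  than a collapsed composite, keeping provenance explicit.
* **Covariates and ancestry.**  The phenotype is residualized on an
  intercept, covariates, and optional genotype principal components by
  ordinary least squares, and the *residuals* are ranked.  This is the
  simplest mechanism consistent with a rank kernel; binary phenotypes
  use the identical path (linear-probability residuals), validated
  against the permutation oracle.  Residuals smaller than $10^{-8}$
  standard deviations collapse to exact ties so a perfectly explained
  phenotype degenerates cleanly instead of rank-ordering round-off
  noise.  `genotype_pca()` provides EIGENSTRAT-style scores (columns
  standardized by $\sqrt{\hat p(1-\hat p)}$) when precomputed PCs are
  not supplied.
* **Multiple testing.**  Benjamini–Hochberg q-values are computed per
  phenotype and per mode across all regions (the stratification is
  recorded in output metadata).  Per-region failures — for example a
  degenerate kernel when every sample carries the same burden — are
  logged and reported as missing p-values; they never abort a screen.
* **Alignment.**  All joins across genotype, expression, and phenotype
  sources go through a single sample alignment in phenotype-table
  order.  Mismatched identifiers are a hard error; nothing is ever
  reordered silently.

## The synthetic-data generator

`simulate_study()` produces data with the statistical structure the
test assumes, at the scale the tool targets: $n = 142$ unrelated
samples by default; per-gene SNV counts uniform on 115–411 (spanning the
interquartile range typical of flanked gene regions in whole-genome
sequencing); MAFs from a rare-heavy mixture (80% uniform on
0.001–0.01, 20% uniform on 0.01–0.5, so most SNVs are rare); expression
$t = \gamma \cdot \tilde a + \varepsilon$ driven by the standardized
burden $\tilde a$ (an eQTL link); phenotype $y = \beta_G \tilde a +
\beta_T t + $ covariate effects $+\ N(0,1)$, with an age-like and a
sex-like covariate and a binary trait thresholded at a configured
prevalence (0.3).  Effects act through the standardized burden rather
than per-SNV coefficients, aligning the generative model with the
statistic under test so power calibrations are interpretable.  A second
quantitative trait shares the structural signal with independent noise,
giving the correlated-trait trio (two quantitative, one binary) typical
of blood-pressure phenotypes.

Default effect sizes ($\beta_G = \beta_T = 0.1$, $\gamma = 0.7$) were
calibrated once to give causal genes moderate power (about 0.5 at
$\alpha = 0.05$, $n = 142$), so mode comparisons remain informative;
rare SNVs that realize zero carriers are redrawn, which keeps every
emitted SNV polymorphic and slightly favors the common stratum (the
accepted rare fraction is ~0.76 rather than 0.80).

What the generator does *not* emulate — and what passing tests
therefore cannot certify about real data: linkage disequilibrium and
haplotype structure (SNVs are independent given their MAFs), population
stratification (beyond a two-subpopulation scenario used to test the
PCA), family relatedness, genotyping error, and expression batch
structure.  Calibration results transfer to real data only to the
extent that phenotype exchangeability after covariate residualization
holds.

## Validation protocol and problem sizes

The test suite validates, at sizes chosen to balance Monte Carlo
resolution against runtime on a single CPU: exact finite-sample
identities of the statistic (against a double-loop oracle, $10^{-12}$);
inversion accuracy against chi-square closed forms ($10^{-6}$) and
$10^6$-draw Monte Carlo; agreement between asymptotic and permutation
p-values over 50 genes with 10,000 permutations each (Pearson $r$ of
$-\log_{10} p$ above 0.95); type-I calibration over 2,000 all-null
replicates per mode at $n = 142$ (rejection rate in the binomial 99%
band around 0.05 and KS uniformity); the joint test's power dominance
over single-source modes at 200 replicates; exact filter-rule
reconciliation on a committed 5-gene fixture; and a 1,000-gene,
three-phenotype screen as a throughput exercise.

## Known limitations

* The asymptotic null is an approximation to the permutation law;
  for very small samples ($n \lesssim 30$) or extremely sparse burden
  distributions, use `wu_test(..., n_perm = )` to attach the
  permutation oracle.
* Kernels other than Gaussian and SNV weights other than
  $1/\sqrt{p(1-p)}$ are out of scope, as are family data (samples must
  be unrelated) and multivariate phenotype combinations.
* Multiallelic VCF records are skipped, not split; split them upstream
  if they matter.
* The test statistic directs power at positive association between
  similarity in the molecular data and similarity in phenotype; the
  one-sided tail is the intended use.
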