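---
title: "Models and methods behind globalepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind globalepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globalepi)
```

## The phenomenon

A combinatorial fitness landscape assigns a scalar fitness (or any other
function value, in caller-defined units) to every combination of $N$
binary loci — mutations, gene knockouts, species in a consortium, drugs
in a cocktail. *Global epistasis* is the observation that the fitness
effect of a mutation, $\Delta F_i(B) = F_{B+i} - F_B$, is often
well-predicted by a linear regression on the fitness $F_B$ of the
background it is added to. A negative slope for a beneficial mutation is
*diminishing returns*; for a deleterious one, *increasing costs*; the
positive-slope counterparts are *increasing returns* and
*decreasing costs*.

The package quantifies these patterns (`ge_scatter()`, `ols_fit()`,
`ge_fit()`, `classify_pattern()`), explains them from microscopic
interaction structure (`to_walsh()`, `decompose_slope()`,
`decompose_report()`), and simulates the landscape regimes in which each
explanation is exact (`simulate_additive()`, `simulate_hoc()`,
`simulate_pairwise()`, `simulate_latent()`).

## Interaction expansion

Writing $x_i = 2 p_i - 1 \in \{-1, +1\}$ for presence $p_i \in \{0,1\}$,
any complete landscape has a unique expansion

$$F = \bar F + \sum_i f_i x_i + \sum_{j>i} f_{ij} x_i x_j
      + \sum_{k>j>i} f_{ijk} x_i x_j x_k + \cdots$$

`to_walsh()` uses the uniform-measure orthonormal basis on
$\{-1,+1\}^N$: the coefficient of a subset $S$ is the plain mean of
$F(g)\prod_{i \in S} x_i(g)$ over all $2^N$ genotypes. This
normalization was chosen deliberately: it makes the transform involutive
(`from_walsh()` is the exact inverse), it satisfies the Parseval
identity (the population variance of fitness equals the sum of squared
non-mean coefficients), and it is the unique scaling under which the
background-averaged identities used below,

$$f_{ij} = \tfrac14 \langle \varepsilon_{ij} \rangle,
\qquad
f_j - f_{ij} = \tfrac12 \langle \delta F_j \rangle_{B(i)},$$

hold without stray factors. Files and the data model store genotypes as
$\{0,1\}$ presence columns; the $\pm 1$ encoding exists only inside the
transform, so no sign convention can leak between modules. On the
$\{0,1\}$ scale an additive effect $\delta_i$ corresponds to $2 f_i$
plus interaction adjustments; the test suite asserts this conversion
numerically rather than assuming a formula.

The transform is computed with the in-place fast Walsh–Hadamard
butterfly ($O(N 2^N)$); the direct signed sum ($O(4^N)$) is kept in the
test suite as the independent oracle. For incomplete landscapes the
exact transform is undefined; `to_walsh(estimate = TRUE)` instead fits
coefficients up to `max_order` by least squares over the measured
genotypes and labels the result an estimate. Truncation
(`truncate_walsh()`) keeps the mean term and drops every subset above
the requested order; it is lossy exactly when higher-order structure
exists.

## Regression and classification

`ols_fit()` computes the simple-regression slope and intercept in
closed form from centred sums, and reports $R^2$ as the squared Pearson
correlation (identical to the coefficient of determination here). Two
degenerate inputs are handled explicitly rather than erroring:

* constant $\Delta F$ (an additive mutation): slope 0 and $R^2$
  reported as 0, since no variation is explained;
* zero variance in $F_B$: no slope exists; the fit is returned with a
  `degenerate` flag and classification falls back to `flat`.

Fits require at least 3 points; `ge_fit()` reports loci with fewer
usable backgrounds as flagged `NA` rows instead of dropping them.

`classify_pattern()` needs a *beneficial/deleterious* call and a
*nonzero-slope* call. The mutation is called beneficial (deleterious)
when every $\Delta F$ is $\ge 0$ ($\le 0$) with at least one strict;
otherwise it is `mixed-sign`, since a single returns/costs label would
misdescribe it. The slope is called nonzero by the standard t-test on
the OLS slope at a caller-supplied `alpha` (default 0.05); no flatness
criterion is standard for these regressions, so the test and level are
surfaced in the output rather than hidden. Classification is
per-mutation, and no multiple-testing correction is applied by default;
`ge_fit(bonferroni = TRUE)` divides `alpha` by the number of loci for
users who want the family-wise version.

## Slope decomposition

For a focal mutation $i$, the slope of its global epistasis regression
can be predicted from pairwise quantities:

$$b_i \approx
  \frac{\sum_{j \neq i} \langle \varepsilon_{ij} \rangle
        \langle \delta F_j \rangle_{B(i)}}
       {\sum_{j \neq i} \langle \delta F_j \rangle_{B(i)}^2}
  = \sum_{j \neq i} \omega_{ij} \beta_{ij},
\qquad
a_i = \langle \Delta F \rangle - b_i \langle F_B \rangle .$$

Here $\langle \varepsilon_{ij} \rangle$ is the mean four-corner
epistasis $F_{B+i+j} - F_{B+i} - F_{B+j} + F_B$ over the backgrounds
lacking both $i$ and $j$ (the average *vertical* shift that carrying
$j$ induces in $\Delta F_i$), and
$\langle \delta F_j \rangle_{B(i)}$ is the mean effect of $j$ over
those same backgrounds (the average *horizontal* shift it induces in
$F_B$). The weight
$\omega_{ij} = \langle \delta F_j \rangle^2 / \sum_k \langle \delta F_k \rangle^2$
sums to one, and $\beta_{ij} = \langle \varepsilon_{ij} \rangle /
\langle \delta F_j \rangle$ is partner $j$'s individual slope
contribution. A partner whose signs align (synergistic epistasis with a
beneficial background mutation, or antagonistic with a deleterious one)
pushes the slope up; misaligned signs push it down.

Design choices that the formulas leave open:

* **Background set.** $\langle \delta F_j \rangle_{B(i)}$ is averaged
  over backgrounds lacking *both* $i$ and $j$ — the only reading under
  which adding $j$ is well-defined on $B(i)$ — with uniform weight per
  background. The choice is validated by the identity
  $\langle \delta F_j \rangle_{B(i)} = 2(f_j - f_{ij})$, which the test
  suite checks against the Walsh module.
* **Intercept averages.** $\langle \Delta F \rangle$ and
  $\langle F_B \rangle$ are taken over the focal mutation's own
  scatter, which makes $a_i$ the exact OLS intercept whenever $b_i$ is
  the exact OLS slope.
* **Zero-effect partners.** If $\langle \delta F_j \rangle = 0$ but
  $\langle \varepsilon_{ij} \rangle \neq 0$, $\beta_{ij}$ diverges; the
  partner's $\beta$ is reported `NA` while its (zero) product term
  stays in the authoritative sum form. If *every* partner's average
  effect is zero the slope is undefined and the decomposition is
  flagged degenerate.
* **Two modes.** `mode = "averages"` computes the background averages
  directly (and therefore works, with reported `n_used` counts, on
  incomplete landscapes); `mode = "walsh"` uses
  $b_i = 2\sum_j f_{ij}(f_j - f_{ij}) / \sum_j (f_j - f_{ij})^2$ from
  order-$\le 2$ coefficients and requires completeness. On complete
  landscapes the two agree to rounding error — the background averages
  annihilate every character above order two, so the identities are
  exact there, not merely for pairwise-truncated landscapes — and the
  tests assert the agreement on pairwise landscapes, where the claim
  is unambiguous.

The prediction is *exact* (machine precision, verified against a
brute-force OLS oracle) when every interaction involves the focal
locus, because then $F_B$ is additive in the background loci. With
background–background epistasis it is an approximation whose error
shrinks with the ratio of interaction to additive magnitudes; a test
sweeps that ratio and checks the convergence.

## Simulated regimes and what they emulate

* **Additive** (`simulate_additive()`): $F = \text{baseline} +
  \sum_i \delta_i p_i$. Every scatter is constant; slopes are zero to
  summation roundoff ($\sim 10^{-16}$) and classified flat. The
  six-locus fixture with effects $\pm 0.3, \pm 0.2, \pm 0.1$ (three
  beneficial, three deleterious; magnitudes are arbitrary, chosen to be
  distinct and order-one) is used throughout the tests.
* **House of cards** (`simulate_hoc()`): each of the $2^N$ fitnesses is
  iid Normal(mean, sd), the maximally idiosyncratic limit. Defaults are
  mean 1, sd 0.2 — the regime used for the package's calibration
  checks. Regression to the mean forces every mutation towards slope
  $-1$, $R^2 = 1/2$ (since
  $\mathrm{corr}(F_B, \Delta F) = -1/\sqrt2$ for iid corners) and
  intercept at the distribution mean; the checks use 500 replicate
  6-locus landscapes, enough to pin the grand means to well within
  $\pm 0.05$ while running in seconds.
* **Sparse pairwise** (`simulate_pairwise()`): additive plus
  $\varepsilon_{ij} p_i p_j$ terms. With a single interaction the focal
  scatter splits into two clusters offset vertically by
  $\varepsilon_{12}$ and horizontally by $\delta_2$, and the slope is
  proportional to $\varepsilon_{12}/\delta_2$ — the geometric picture
  the decomposition generalizes.
* **Latent nonlinear** (`simulate_latent()`): mutations act additively
  on a latent trait $\lambda$ (fitness potential) and
  $F = e^\lambda$ (convex) or $F = 1 - e^{-\lambda}$ (concave). Both
  transforms make $\Delta F$ *exactly* linear in $F_B$:
  $\Delta F = (e^{\delta\lambda} - 1) F_B$ for the convex case and
  $\Delta F = (1 - e^{-\delta\lambda})(1 - F_B)$ for the concave one
  (`latent_closed_form_slope()`), so simulated $R^2$ is 1 to machine
  precision and the four classification labels follow from the sign of
  $\delta\lambda$ and the curvature.

All simulators are deterministic given a seed; `simulate_hoc()` draws
inside `withr::with_seed()` so a seeded call never perturbs the
caller's RNG stream. What the simulators do *not* emulate: measurement
noise, multi-allelic loci, NK/Rough-Mount-Fuji correlation structure,
non-exponential latent transforms, and partial sampling designs.
Passing tests on these regimes therefore show that the estimators are
correct under their own generative assumptions, not that any empirical
landscape satisfies those assumptions — on real data, measurement error
alone can bias slopes negative, and undersampling can mimic global
trends.

## Applying the decomposition to an empirical table

Any combinatorially complete empirical landscape can be analysed by
writing it in the wide TSV dialect (one 0/1 column per mutation plus
`fitness`, in whatever units the study reports — the package is
unit-agnostic and applies no log or relative-fitness conversion) and
running:

```r
L <- read_landscape("landscape.tsv")
ge_fit(L)                       # slopes, R^2, classifications
decompose_report(L)             # per-partner products vs OLS slopes
```

A classic use case is a five-mutation bacterial landscape from an
evolution experiment: each mutation's predicted slope decomposes into
four partner products, and the sign of the dominant product explains
which mutations show diminishing versus increasing returns. No such
table ships with the package; the recipe is the two calls above on the
user-supplied file.

## Numerical and testing notes

* Landscape files are written at 17 significant digits and parsed with
  base R's `strtod`, so write/read round trips are bit-exact; the CLI
  writes analysis tables at 6 significant digits unless
  `--full-precision` is given.
* Genotype lookup is by integer index ($\sum_i p_i 2^{i-1}$, exact in
  doubles far beyond any practical $N$); row order never affects
  results.
* Exactness tolerances in the tests are $10^{-12}$ (closed-form
  agreements), $10^{-9}$ (round trips and identities over random
  landscapes); stochastic calibrations use $\pm 0.05$ bands. Round-trip
  checks cover 1000 random landscapes up to $N = 10$; identity checks
  100 random pairwise landscapes with $N = 4$–$8$. These sizes keep the
  whole suite under a minute while leaving the stochastic bands
  comfortably narrower than the sampling noise of smaller designs.
* Known limitations: the exact Walsh transform materializes all $2^N$
  coefficients (practical to $N \approx 20$); the decomposition's
  approximation error for strong background–background epistasis is
  not quantified beyond the convergence property; and residual
  structure around the fitted line — which can distinguish microscopic
  interactions from latent nonlinearity — is deliberately out of
  scope.
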