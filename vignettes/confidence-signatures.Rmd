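---
title: "Objective confidence and its statistical signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective confidence and its statistical signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confsig)
```

## The generative models

`confsig` simulates two-alternative forced-choice trials under a signal
detection account and computes *objective confidence*: the Bayesian
posterior probability that the choice was correct given the evidence the
observer has. Each trial is generated as

- identity $I \in \{-1, 1\}$, balanced exactly across the experiment (the
  first half of trials has $I = 1$, the second half $I = -1$; every
  analysis in the package is exchangeable over trial order, so no shuffling
  is needed);
- discriminability $d \ge 0$, drawn i.i.d. from a prior $p(d)$;
- identity evidence $e_I \sim N(d \cdot I,\ \sigma_I)$;
- in the *general model* only, discriminability evidence
  $e_d \sim N(d,\ \sigma_d)$, independent of $I$ given $d$;
- a deterministic choice $\vartheta = \operatorname{sign}(e_I)$, with the
  probability-zero tie $e_I = 0$ mapped to $\vartheta = 1$ so the rule is
  total;
- accuracy $A = \mathbf{1}[\vartheta = I]$.

The observer knows the generative parameters (the prior, $\sigma_I$, and
$\sigma_d$ where applicable); model mismatch is out of scope. Confidence is

$$
c \;=\; p(I = \vartheta \mid e_I, e_d, \vartheta)
\;=\; \frac{\sum_k p(d_k)\, N(e_I;\, d_k \vartheta,\ \sigma_I)\, N(e_d;\, d_k,\ \sigma_d)}
       {\sum_{i \in \{-1,1\}} \sum_k p(d_k)\, N(e_I;\, d_k i,\ \sigma_I)\, N(e_d;\, d_k,\ \sigma_d)}.
$$

The *standard model* — confidence from $e_I$ and $\vartheta$ alone — is the
same computation with the $N(e_d; d_k, \sigma_d)$ factor identically 1;
the package implements it as exactly that reduction rather than a separate
code path, which also realizes the limit argument: as
$\sigma_d \to \infty$ the $e_d$ factor becomes constant across $d_k$ and
the general model collapses onto the standard model (tested at
$\sigma_d = 10^9$ against the standard engine).

Because the choice is the sign of $e_I$ and the identity prior is
symmetric, confidence never falls below $0.5$, and it is *calibrated by
construction*: among trials assigned confidence $c$, the long-run fraction
correct is $c$. This is the strongest correctness check in the test suite —
it holds only if the posterior is exactly right — and is verified for both
models under all nine canonical priors by binning scored trials into 20
equal-count confidence bins and comparing per-bin accuracy with per-bin
mean confidence.

## Discriminability priors and quadrature

Nine canonical priors are built in (`methods_priors()`): discrete uniform
on $\{0,1\}$, $\{0,1,2\}$, $\{0,\dots,4\}$; continuous uniform on $[0,1]$,
$[0,2]$, $[0,4]$; and gamma with (shape, rate) of $(1,2)$, $(1.5,1.5)$,
$(2,1)$ — gamma parameters whose means and variances line up with the
discrete uniform grids; the three listed parameter pairs are taken as
given rather than re-derived, since the intended pairing is not unique.

The posterior sums over $d_k$ are exact for discrete priors. For continuous
priors the marginalization is a quadrature sum: fixed-order Gauss–Legendre
(256 nodes by default) over the support, with gamma support truncated at
the $1 - 10^{-10}$ quantile so the domain is bounded at negligible mass
loss, and weights multiplied by the prior density and renormalized to sum
to one. Gauss–Legendre was chosen because the integrands here — Gaussian
likelihoods times a smooth density — are smooth, so a deterministic
spectral rule is both accurate (relative error below $10^{-6}$ on smooth
moments, verified against closed-form gamma moments) and reproducible,
unlike Monte Carlo integration. Discrete support values are stored exactly
as the grid rationals realized in floating point, and downstream grouping
uses exact float equality, which is safe because the values are assigned,
never computed.

## Numerical choices

At $d = 10$ and $\sigma_I = 1$ a raw Gaussian density underflows double
precision, so all likelihood products are accumulated in log space and
combined with a max-subtraction log-sum-exp. The posterior is returned as
`plogis(log-odds)`, which keeps the $[0.5, 1]$ confidence range exact at
both ends. Scoring is vectorized and chunked so the trial-by-node
likelihood matrix stays around $4 \times 10^6$ cells per block; a
full-scale $4 \times 10^6$-trial experiment with a 256-node prior scores in
minutes on one CPU, and the desk-scale runs below in seconds.

## Result summaries

`confidence_curve()` averages confidence by discriminability level and
accuracy. Discrete priors group by exact support value. Continuous priors
use 10 equal-width bins over $[0, \max d]$ labelled by midpoints — a
granularity comparable to plotting practice for such curves; the bin count
is a parameter, and results are insensitive to it at these trial counts.
Cells with no trials of a given accuracy are `NA`, never zero.

`classify_pattern()` fits count-weighted least-squares slopes of mean
confidence on level, separately for correct and incorrect trials, and
labels the curve `folded_X` (correct slope $> \tau$, incorrect $< -\tau$),
`double_increase` (both $> \tau$) or `flat`. The threshold
$\tau = 0.005$ confidence units per discriminability unit separates real
flatness from Monte Carlo noise: at $10^5$ trials per experiment the true
slopes of interest are an order of magnitude larger, while the standard
error of a binned mean is around $10^{-3}$. Empty cells are dropped from
the fit with a warning; when fewer than two populated levels remain for a
class (e.g. a $\{0, 10\}$ prior, where errors at $d = 10$ have probability
$\Phi(-10)$), the label is `NA` rather than a guess.

`accuracy_entropy()` implements
$H(A|c) = -\tfrac1n \sum_j \log\!\big(A_j c_j + (1 - A_j)(1 - c_j)\big)$
in natural log units (nats); the base only rescales the comparison, and
the choice is recorded in the campaign output metadata. The comparison of
interest scores *the same trials* twice — once with the general engine
($e_I$ and $e_d$) and once with a standard engine over the same prior and
$\sigma_I$ ($e_I$ only) — so the Monte Carlo error of the difference is the
paired standard error of the per-trial log-score differences, which the
package reports as `se_diff`.

`neutral_confidence()` evaluates the $d = 0$ point of the curves by direct
conditioning: $d$ is held at zero while the scoring engine keeps the full
experiment prior. This avoids binning artifacts and is the only correct
reading for continuous priors, where exactly-neutral trials have
probability zero in a simulated experiment.

## Campaigns, seeds, and problem sizes

`campaign()` enumerates the study grids: nine standard-model experiments
(one per canonical prior), the discrete level-grid and two-value sets, and
the $9 \times 4$ general-model grid with
$\sigma_d \in \{1/10, 1/3, 1, 10\}$. Full scale is $4 \times 10^6$ trials
per experiment with identity balanced $2 \times 10^6 / 2 \times 10^6$ and
$\sigma_I = 1$; those are the package defaults. The analysis scripts and
test suite run at scale $0.025$ ($10^5$ trials per experiment, the
package's desk-scale choice), at which every qualitative conclusion —
pattern labels, neutral-evidence values, entropy ordering — is already
stable well beyond its Monte Carlo error; `scale = 1` reproduces the full
campaigns.

Each simulated experiment consumes one seeded RNG stream; draws occur in
the fixed order $d$, $e_I$, $e_d$, so runs are bit-reproducible from the
config. Per-config seeds derive from the campaign seed by a stable string
hash of the config name, so adding or removing one config does not shift
the streams of the others.

## What the generator does and does not emulate

The simulator reproduces the generative structure the models assume:
balanced identities, i.i.d. discriminability, Gaussian evidence,
deterministic sign choice, an observer who knows the true parameters. It
deliberately omits features of real psychophysics: lapses, response bias,
probabilistic choice, sequential evidence accumulation and response times,
asymmetric identity priors, and observer misestimation of $\sigma_I$ or
$\sigma_d$. Passing tests therefore show that the *models imply* the
simulated patterns — folded X under the standard model, double increase
under the general model with reliable $e_d$, entropy dominance of
$e_d$-informed confidence — not that human confidence behaves this way in
any given task; fitting these models to empirical data is out of scope.

## Known limitations

- Continuous-prior posteriors are quadrature approximations; 256
  Gauss–Legendre nodes leave errors far below every tolerance used here,
  but pathological priors (heavy tails far beyond the truncation point)
  are not supported.
- The pattern classifier is a three-way threshold on two slopes; it is
  meant to reproduce qualitative claims, not to be a statistical test with
  controlled error rates.
- `H(A|c)` diverges if a scorer assigns probability zero to a realized
  outcome; the package raises a domain error identifying the offending
  trial rather than clamping, since under the exact posteriors used here
  this cannot occur.
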