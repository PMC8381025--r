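---
title: "Strand mastery classification: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand mastery classification: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Licensing examinations report a single scaled score, but educators want to
know which content strands (cardiology, trauma, obstetrics, ...) a given
examinee has or has not mastered. `dcmastery` implements and compares three
engines that turn a binary persons-by-items response matrix plus a
simple-structure Q-matrix (each item assigned to exactly one strand) into a
binary persons-by-strands mastery matrix:

* **CTT**: the strand subscore is the proportion correct among the strand's
  items; an examinee masters the strand when that proportion is *strictly*
  above a cut (default 0.5).
* **Rasch, per strand**: for each strand a unidimensional Rasch model
  \(P(X_{ij}=1\mid\theta_j, b_i) = \operatorname{logit}^{-1}(\theta_j - b_i)\)
  is fitted by marginal maximum likelihood with \(\theta \sim N(0,1)\);
  persons are scored by the posterior mode (MAP) and master the strand when
  \(\hat\theta_j > 0\), the population median under the identification.
* **DINA, jointly**: the deterministic-inputs noisy "and"-gate model over
  all items at once. With mastery profile \(\alpha_j \in \{0,1\}^K\) and
  ideal response \(\eta_{ij} = \prod_k \alpha_{jk}^{q_{ik}}\), the item
  response function is
  \(P(X_{ij}=1\mid\eta_{ij}) = g_i^{1-\eta_{ij}} (1-s_i)^{\eta_{ij}}\),
  where \(g_i\) is the guess and \(s_i\) the slip probability. All \(2^K\)
  profiles form the latent-class space; EM estimates \(g, s\) and the class
  weights; each examinee gets the profile with the largest posterior.

Accuracy is the per-strand proportion of examinees whose estimated mastery
matches the simulated truth (the diagonal share of the 2x2 truth-by-estimate
table); consistency is the same exact-match proportion between two engines;
person-score correlations compare CTT proportions, Rasch MAP thetas and the
DINA per-attribute marginal posterior mastery probabilities.

## The synthetic-data generator

The simulator emulates the structure of a large multi-strand licensing
examination. Responses come from a simple-structure multidimensional IRT
model with unit slopes: item \(i\) measuring strand \(k(i)\) has
\(P(X_{ij}=1) = \operatorname{logit}^{-1}(\theta_{j,k(i)} - b_i)\).
Abilities are multivariate normal with zero means, unit variances and a
common pairwise correlation \(\rho\) (compound symmetry); difficulties are
uniform on \([-3, 3]\); one generated form carries all strands at once
(default 5/10/15/20 items, so 50 items), with 1,000 examinees per form and
50 replicate forms per condition. These defaults *are* the study design;
`sim_condition()` exposes them but the accuracy study is defined at these
values.

True mastery is \(\theta_{jk} > 0\), strictly. The generating model never
states an observable truth — any cut is a definition — and the population
median mirrors the Rasch estimation rule, making the three engines'
accuracies comparable on one scale. Ties at exactly zero (probability zero
in the continuous model) count as non-mastery, as do CTT subscores landing
exactly on the cut: "above" is read literally everywhere.

Two structural consequences are worth knowing when reading results:

* A strand's CTT subscore and its per-strand Rasch fit use only that
  strand's items, and each strand's ability marginal is \(N(0,1)\) at every
  \(\rho\); those two engines' accuracies are therefore invariant in
  \(\rho\) by construction, up to Monte-Carlo noise. Only the joint DINA
  fit can react to the correlation, which it does through the estimated
  class weights: at high \(\rho\), weight concentrates near the all-zero
  and all-one profiles and short strands borrow strength from the rest of
  the form.
* Because the generator is logistic in a continuous ability while DINA is a
  two-level latent-class model, the DINA fit is deliberately misspecified —
  exactly the situation the comparison is about.

What the generator does **not** emulate: local item dependence, speededness,
differential guessing on multiple-choice items, complex (multi-attribute)
Q-matrix entries, missing responses (loading rejects them), and polytomous
items. Passing tests say nothing about robustness to those features.

The licensing-shaped variant (`simulate_kmle_like()`) reproduces only the
*dimensions* of a real examination — 3,265 examinees, 360 items, 8 strands
of 45/45/45/25/154/20/20/6 items — with \(\rho = 0.7\) as a realistic
default for strongly related clinical domains. It is a synthetic stand-in:
published real-data deviances, flag counts and consistency values are not
reproduction targets, because the real responses are not public.

## Estimation details

**Rasch MML-EM.** The latent density is fixed at \(N(0,1)\) (the
identification that makes \(\theta > 0\) a meaningful cut) and discretised
on 61 equally spaced nodes on \([-6, 6]\) with renormalised normal weights —
fine enough that the quadrature error is orders of magnitude below the
Monte-Carlo noise the study cares about. The M-step solves each item's
score equation by Newton steps (clamped to \(\pm 2\) logits per step).
Convergence: max \(|\Delta b| < 10^{-5}\), at most 1,000 iterations;
non-convergence warns with the trace rather than failing. Items answered
all-correct or all-incorrect carry no difficulty information and are
excluded with a warning (`NA` difficulty), never silently.

**MAP scoring.** The log-posterior is strictly concave, so a Newton
iteration with step-halving against the posterior value converges for every
response pattern; all-correct and all-zero patterns stay finite thanks to
the proper prior. Tolerance \(10^{-6}\) logits.

**DINA EM.** Saturated structural model: all \(2^K\) class weights free
(simplex-constrained), initial values \(g = s = 0.2\) and uniform weights;
person-by-class likelihoods are accumulated in log space so 360-item data
do not underflow; closed-form M-step ratios are clipped to
\([10^{-4}, 1-10^{-4}]\). The monotonicity condition \(g_i < 1 - s_i\) is
*warned about* but not imposed — imposing it would hide exactly the reversed
items the fit statistics should flag. Convergence: max parameter change
\(< 10^{-5}\), at most 1,000 iterations. \(K \le 16\) is enforced before
any allocation. Posterior ties at the MAP step break toward the lowest
class index, with a warning, so runs are deterministic.

**Fit statistics.** Outfit is the unweighted mean-square standardised
residual \(\frac{1}{N}\sum_j (X_{ij}-P_{ij})^2 / (P_{ij}(1-P_{ij}))\),
acceptable in \([0.6, 1.4]\). Its expectation is 1 when \(P_{ij}\) is
evaluated at the generating parameters; computed from MAP-scored thetas it
runs somewhat below 1 on short tests (shrinkage plus fitting the same
responses being diagnosed), which is why the calibration test evaluates it
at the generating values while the misfit-flagging tests run the full
fit-then-score pipeline. The DINA item fit is an RMSEA-type index: the
root of the class-weighted mean squared gap between the model-implied
success probability and the posterior-weighted observed proportion correct
per class, flagged above 0.08. The class-conditional observed proportions
are not printed in closed form anywhere authoritative; the
posterior-weighted form used here is the standard construction in the
diagnostic-classification literature. Classes with essentially no posterior
mass are skipped and the weights renormalised, with a message.

## Reproducibility machinery

Every study takes one master seed; each form uses a substream seed derived
deterministically from (seed, form index) by a fixed affine map modulo
\(2^{31}-1\), so any single form can be regenerated in isolation and a
one-form study equals a direct `run_condition()` call. Fits are
deterministic given data, so two runs of a writer with the same
configuration and seed produce byte-identical CSVs and logs (run logs
record settings and versions, never timestamps).

## Problem sizes in the test suite

The test suite runs the factorial study at 10 forms per correlation level
(the study's fast mode; across-form standard errors enter the tolerances as
\(3\,\mathrm{SE}\)), parameter-recovery checks at \(n = 5{,}000\) (Rasch)
and \(n = 2{,}000\) (DINA), fit-statistic calibration at \(n = 5{,}000\),
and the licensing-shaped pipeline at 500 examinees over 73 items with all
8 strands (256 latent classes). `scripts/acceptance.R` and the
`analysis/` drivers run the full 50-form, 1,000-examinee design; the
full-scale 3,265 x 360 pipeline lives in `analysis/02_consistency_analysis.R`.

## Known limitations

* Simple structure only: multi-attribute items are validated against, not
  modelled; the generator refuses non-simple Q-matrices.
* The compound-symmetric ability correlation is the only dependence
  structure offered.
* No standard errors on item parameters, no infit, no 2PL/3PL, no
  DINO/G-DINA variants, no Q-matrix estimation: the package implements the
  comparison it was built for, not a general DCM toolkit.
* The DINA EM likelihood surface is multimodal in principle; the fixed
  initialisation makes runs reproducible but a pathological dataset could
  converge to a local optimum. The EM-ascent and oracle-equivalence tests
  guard the computation, not global optimality.
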