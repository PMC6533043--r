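---
title: "Estimating causal effects of emotions and network position on dropout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects of emotions and network position on dropout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attritioniv)
```

## The problem

In an online peer community observed at two time points, some members stop
posting between the observations.  Observed associations between a member's
attributes (emotional tone of their posts, their position in the follow
network) and this dropout cannot be read causally: unobserved circumstances
(for example, undergoing treatment) can move both a member's emotions and
their platform use, and platform use itself feeds back on emotions.  In
regression terms the main explanatory variable is *endogenous* — correlated
with the error term — so ordinary least squares is biased.

This package implements an instrumental-variables (IV) analysis of that
problem.  The structural model for the binary dropout decision is the
linear-probability equation

$$Y_i = \beta_1 X_{1i} + \beta_2' X_{2i} + u_i,$$

with $X_1$ the endogenous attribute (emotion), $X_2$ exogenous controls, and
$u$ the error.  The instrument $Z_i$ is the mean attribute of the accounts
user $i$ follows (the *followees*).  $Z$ is relevant because peers'
expressed emotions influence a user's own ($\mathrm{cov}(Z, X_1) \neq 0$,
testable in the first stage) and plausibly excluded because followees'
emotions should affect a user's dropout only through the user's own state —
except for one known alternative channel, followees' *own* dropout, which is
controlled explicitly by covariates (share of followees still active, and
their mean active duration) and further hardened by a single-way instrument
variant that drops reciprocated follows.

For time to dropout the package uses Aalen's additive hazards model, in
which the hazard is a sum of time-varying covariate effects
$\lambda_i(t) = \beta_0(t) + \sum_k \beta_k(t) x_{ik}$, estimated through
least-squares increments of the cumulative coefficients
$B_k(t) = \int_0^t \beta_k(s)\,ds$ at each event time.  The IV version is a
control-function estimator: each endogenous covariate is regressed on the
instruments plus exogenous covariates, and the first-stage residuals are
added to the hazard model as extra covariates with time-varying effects.
The coefficients on the endogenous covariates are then the causal
estimates.

## Measurement layer

* **Emotion.** Each post is scored on a $[-4, 4]$ integer scale by a
  pluggable lexicon scorer: the positive strength is the maximum positive
  lexicon value among the tokens (default 1 = neutral), the negative
  strength the minimum negative value (default $-1$), and the post score is
  their sum.  One detail worth flagging: the dual scales are collapsed by
  *summation*; other collapse rules (sign of the stronger scale) would
  also fit the $[-4,4]$ output contract, and the scorer is
  deliberately minimal — no negation or booster handling — because the
  estimators, not the NLP, are the contribution.  A user's emotion is the
  mean score over their own (non-retweet) posts in the first observation
  window; users with at most 10 usable posts or at most 50 tokens are
  excluded ("words" = tokens after preprocessing, which strips mentions,
  hashtags and URLs, lower-cases, and splits on whitespace).
* **Centrality.** In-coreness on the directed who-follows-whom graph: the
  largest $k$ such that the user sits in a subgraph where everyone has
  in-degree at least $k$.  Computed via igraph's peeling implementation;
  tests pin it to a brute-force peeling oracle.
* **Outcomes.** Binary dropout = no post strictly after the first
  observation.  Survival outcomes use interval censoring: a user has
  dropped out if their last-post gap before the second observation strictly
  exceeds a threshold — a fixed $\pi$ (identical censoring) or
  $\lambda\pi + (1-\lambda) I_i$ with $I_i$ the user's mean inter-post
  interval (personalized censoring).  Dropouts get survival time = last
  post − obs1; others are censored at the full window.  $(\pi, \lambda)$
  can be tuned by maximizing agreement between first-window predictions and
  observed statuses over a grid (defaults $\pi \in \{7, 14, 30, 60, 90,
  180\}$ days, $\lambda \in \{0, .25, .5, .75, 1\}$; ties break to smaller
  $\pi$, then larger $\lambda$).  All boundaries are strict
  inequalities.

## The synthetic community generator

Real panels of this kind cannot be redistributed, so the package ships a
generator that reproduces exactly the statistical structure the estimators
assume, with every piece tunable:

1. **Graph.** Users carry a latent binary trait; follows are drawn with a
   within-group preference `homophily_strength` ($h$), so the planted
   Newman assortativity on the trait is approximately $h$.  The two groups
   differ in mean out-degree by `degree_ratio`, which makes in-coreness
   heterogeneous; combined with homophily this is what gives the
   followee-mean centrality instrument its first-stage strength.
2. **Traits.** Emotions are peer-coupled in *two passes*: an i.i.d.
   first-pass draw $e^0_i$ (group shift + confounder loading + noise), then
   one update $e_i = \text{peer\_weight}\cdot \overline{e^0}_{F(i)} +
   e^0_i$, clamped to $[-4,4]$.  A fixed point over the network would also
   work but the one-step form guarantees existence and keeps the relevance
   channel explicit.  The confounder is i.i.d. normal and unobserved by the
   estimators.
3. **Dropout.** A per-user constant hazard $h_i = b_0 + h_e e_i +
   h_c (c_i - \bar c) + h_u U_i$, floored at zero with a warning when the
   floor binds.  Centrality enters centered so $b_0$ describes a
   typical-centrality user; the intercept's time-varying coefficient
   absorbs the shift, so estimates are unaffected.  Binary dropout is
   derived from the same latent time (dropout time < obs2), keeping the
   linear and survival analyses mutually consistent; a separate pure
   linear-probability outcome generator exists for estimator validation.
4. **Posts.** Poisson streams at log-normal user rates, truncated at
   min(dropout, obs2).  Each post emits one sentiment-bearing token whose
   strength is the user's emotion plus rounding noise, plus neutral filler;
   this makes measured emotion a noisy but consistent proxy of the planted
   one (correlation > 0.95 at 50+ posts).  Hashtags come from two disjoint
   Zipf-weighted topic vocabularies mixed according to the user's emotion
   tercile and dropout status.

Followee attributes never enter a user's outcome directly — only through
the user's own emotion (the peer pass) — so the exclusion restriction holds
by construction and IV recovery is a meaningful test.

### Default study conditions

Defaults were fixed once, by a small design study run before the test suite
was written, to give the planted effects enough power to be detectable at
desk scale while keeping the panel qualitatively plausible (dropout rates
around 50–85% depending on the window, median account lifetime around 7
months, dropout-state homophily clearly positive):
`n_users = 2000` (3000 in the shipped analysis), `mean_out_degree = 10`,
`degree_ratio = 2.5`, `homophily_strength = 0.55`, `trait_shift = -0.8`
(the high-degree core group skews negative, so central users express more
negative emotion — the direction the motivating literature reports),
`peer_weight = 0.9`, confounder s.d. 1 with loading 0.8 on emotion,
hazard $b_0 = 0.0055$/day, $h_e = +0.0025$, $h_c = -0.0018$,
$h_u = -0.0045$ per unit.  The confounder raises emotion but lowers the
hazard, i.e. *attenuating* confounding: OLS underestimates the positive
effect of emotion on dropout and the IV estimate is larger in magnitude,
the package's qualitative headline.  No distributional details of any real
population are encoded; the generator is a test instrument, not a
population model, and passing tests show estimator correctness under its
assumptions (linear additive effects, constant per-user hazards,
exclusion by construction) — not that those assumptions hold in any real
community.

## Estimation choices

* **Robust covariance.** HC1 sandwich throughout the linear layer;
  p-values from the normal approximation.
* **2SLS variance.** Second-stage residuals are recomputed with the
  original (not fitted) endogenous regressors — the proper IV sandwich,
  not the naive two-step one.
* **First-stage F.** Robust Wald F of the excluded instruments only
  (squared robust t for a single instrument; joint F per endogenous
  variable when both emotion and centrality are instrumented).
* **Wu-Hausman.** Regression-based control-function form (augment the
  outcome equation with first-stage residuals, robust Wald on their
  coefficients); a classic contrast-form variant is exposed for
  cross-checks.
* **Cross-specification Wald.** The all-followee and single-way IV samples
  overlap almost completely, so the default equality test is a paired case
  bootstrap (refit both specifications per replicate, test the mean paired
  difference); an analytic no-overlap variant (sum of squared SEs) is also
  available.
* **Aalen increments.** At each distinct event time $t_k$,
  $\Delta \hat B(t_k) = (X_R'X_R)^{-1} X_R'\,\Delta N(t_k)$ over the at-risk
  set, ties processed together, implemented as an O($np^2 + Kp^3$)
  downdating sweep in compiled code.  Columns are RMS-equilibrated before
  solving so the conditioning check is unit-free; estimation truncates at
  the first event time whose (scaled) at-risk design has condition number
  above `1e8` — the standard tail truncation, recorded in the fit.
* **Mean coefficients.** Table-style summaries are the least-squares slope
  of $B_k(t)$ on $t$ over the reliable window (robust to early-time noise);
  the terminal ratio $B_k(\tau)/\tau$ is exposed as an alternative.  The
  package reports hazard-scale coefficients; "effect on survival time" is
  the negated sign.
* **Bootstrap.** Case (user-level) resampling; IV first stages re-run
  inside every replicate; percentile 95% intervals; failed replicates are
  dropped and counted with a warning above 10%.  The shipped analysis uses
  500 replicates (reference analyses would use 1000); tests use 100–200.
* **Missing data.** Listwise deletion with logged sample sizes at every
  filter step (eligibility → linear sample → survival sample → single-way
  sample), mirroring how per-model n's shrink in real analyses.
* **Interests.** Each group's pooled hashtags form one document; tf is the
  within-group count, idf $= \log(1 + G/g_t)$ over the comparison set with
  add-one smoothing (the output contract fixes only that absent tags score
  0; smoothing keeps ubiquitous tags at a small positive score).
  Spearman correlations are computed on the union vocabulary with zeros
  for absent tags, average ranks for ties, t-approximation p-values (exact
  permutation enumerated for unions of at most 8 tags — full enumeration
  beyond that is not computable at desk scale).
* **Terciles.** Users ranked by emotion, split into thirds; remainders go
  to the lower-score groups (10 users split 4/3/3); ties break by stable
  user id.

## Numerical and degenerate-input conventions

Strict thresholds everywhere a boundary appears (gap exactly $\pi$ is not a
dropout; a last post exactly at obs1 is).  A permutation null with zero
variance maps to $z = 0$.  A perfect first stage (zero residual variance)
gives an infinite first-stage F, and its residual columns are dropped from
the control-function design rather than poisoning it.  Rank-deficient
designs error out naming the collinear columns.  Users with no posts, no
usable posts, no followees, or no single-way followees are flagged and
excluded from exactly the affected samples, never silently imputed.

## Problem sizes used in the shipped studies

Simulation studies in the test suite and analysis scripts use: 200
replicates at n = 2000 for linear recovery; 500/200 replicates at n = 1000
for diagnostic size/power; n = 10000 draws for closed-form survival checks;
100 recovery replicates and 200 coverage panels (200 bootstrap replicates
each) at n = 1000 for the survival IV; 50 panels at n = 3000 for the
qualitative sign study.  These sizes were chosen so each study has clear
statistical resolution for the property it checks.

## Known limitations

The generator's hazards are constant per user; time-varying covariates and
hazards are out of scope.  The emotion scorer is intentionally naive.
Single accounts are assumed to be single individuals.  The hazard floor at
zero introduces a mild nonlinearity at extreme covariate values, which
slightly attenuates recovered hazard coefficients on heavily floored
configurations (kept rare under the defaults).  Proportional-hazards (Cox)
models are deliberately not offered: the additive model is the one whose
IV extension is implemented.
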