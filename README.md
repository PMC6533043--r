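# attritioniv

Causal estimation of why members drop out of an online peer community, for
researchers studying attrition in social-media health communities and for
methodologists who want a tested reference implementation of
instrumental-variables (IV) estimators for both binary and time-to-event
attrition outcomes.

Observed associations between a member's attributes and their later dropout
are confounded: unobserved circumstances move both a person's emotional
state and their platform use, and platform use feeds back on emotions.  The
package addresses this with followee-based instruments: the average
attribute of the accounts a user follows is correlated with the user's own
attribute (homophily and peer influence) but plausibly affects the user's
dropout only through it.

Two estimators sit at the core:

* **Linear probability / 2SLS.** Structural model
  `Y = β₁X₁ + β₂'X₂ + u` with endogenous emotion `X₁`, followee-mean
  emotion as instrument `Z`, HC1 robust inference, first-stage relevance F,
  a control-function Wu-Hausman endogeneity test, and a paired-bootstrap
  Wald test of coefficient equality across instrument definitions
  (all followees vs single-way followees, i.e. not-followed-back).
* **Additive hazards / control-function IV.** Aalen's model
  `λᵢ(t) = β₀(t) + Σₖ βₖ(t)xᵢₖ` estimated by least-squares increments of
  the cumulative coefficients `Bₖ(t)` at event times; the IV version adds
  first-stage residuals as extra time-varying-effect covariates, giving
  causal estimates for emotion and in-coreness centrality, with case
  bootstrap percentile CIs for the time-averaged ("mean") coefficients.

Around them: a lexicon sentiment scorer on the [−4, 4] per-tweet scale with
per-user averaging and a >10 tweets / >50 words eligibility filter;
in-coreness centrality and Newman assortativity with a permutation null on
the who-follows-whom graph; identical and personalized interval censoring
of dropout (`λπ + (1−λ)Iᵢ` thresholds, tunable by agreement maximization);
Table-style covariates; and TF-IDF hashtag-interest profiles compared by
zero-for-absent-tag Spearman correlations.

Because the original platform data cannot be redistributed, the package
ships a **synthetic community generator** that plants exactly the structure
the estimators assume — homophilous directed follow graph, peer-coupled
emotions (instrument relevance), an unobserved confounder loading on both
emotion and dropout (endogeneity), hazard-driven dropout, Poisson posting
streams, topic-conditioned hashtags — so the entire pipeline is exercised
and validated end-to-end with known ground truth.  See
`vignettes/attrition-iv-methods.Rmd` for the model, the generator's
assumptions, and every numerical convention.

## Worked example

```r
library(attritioniv)
cfg <- sim_config(n_users = 1000, seed = 42)
res <- run_pipeline(cfg, n_boot = 200)
```

Printed summaries from this run:

```
eligible users: 787 of 1000; dropout rate: 0.44
KM median lifetime: 272 days
OLS emotion beta: 0.017 | 2SLS: 0.062 (first-stage F = 70)
Aalen IV emotion: 0.00042 [-0.00044, 0.00095] per day
Aalen IV centrality: -0.00152 [-0.00313, -0.00069] per day
```

Reading the numbers: 787 of 1000 simulated users pass the measurement
filter and 44% stop posting before the second observation; half of all
accounts fall silent within ~9 months of creation.  The 2SLS effect of
emotion on dropout probability (0.062 per score unit) is several times the
OLS estimate (0.017) — the planted confounder raises emotion while
lowering dropout, so OLS is attenuated, and the strong first stage
(F = 70 ≫ 10) says the followee-mean instrument has the relevance the
design needs.  In the survival model, the centrality coefficient is
negative on the hazard scale with a CI excluding zero: core community
members drop out more slowly.  The emotion hazard coefficient is positive
(shorter survival for positive emotion) but not significant at this small
panel size; `analysis/05_survival_models.R` runs the same model at n = 3000
where it is.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study on a simulated
community of 3000 users and write all tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # panel -> results/panel/ (plain text)
Rscript analysis/02_measure.R         # emotions, coreness, instruments
Rscript analysis/03_outcomes.R        # dropout, lifetimes, homophily, tuning
Rscript analysis/04_linear_models.R   # OLS + 2SLS + diagnostics
Rscript analysis/05_survival_models.R # Aalen standard + IV, both censorings
Rscript analysis/06_interests.R       # TF-IDF profiles + Spearman matrix
```

Each script prints what it found; the estimation scripts recompute their
stages through `run_pipeline()`, the same function the tests exercise.

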