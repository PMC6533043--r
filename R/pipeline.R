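## End-to-end orchestration: simulate (or load) a panel, measure emotions and
## centrality, build instruments and covariates, construct outcomes, fit the
## linear and survival models (standard and IV, both instrument definitions
## and both censoring schemes), profile interests, and collect a manifest of
## sample sizes at every filter step.

log_stage <- function(manifest, stage, n_in, n_out, t0) {
  message(sprintf("[%s] n_in=%d n_out=%d (%.1fs)", stage, n_in, n_out,
                  as.numeric(Sys.time()) - t0))
  manifest$stages[[stage]] <- list(n_in = n_in, n_out = n_out)
  manifest
}

covariate_names <- c("n_followees", "n_posts", "n_followers", "active_days",
                     "followees_per_day", "posts_per_day",
                     "followers_per_day", "n_tweets_in_use",
                     "n_followees_in_use", "pct_active_followees",
                     "avg_duration_followees")

#' Run the full dropout analysis pipeline
#'
#' Stages: simulate (or take a supplied panel), sentiment measurement,
#' eligibility filtering, centrality and instruments, covariates, binary
#' dropout outcomes with OLS and 2SLS (all-followee and single-way
#' instruments), censored survival outcomes with standard and
#' control-function IV Aalen fits (identical and personalized censoring),
#' and hashtag-interest profiles with their correlation matrix.  All tables
#' can be written under `out_dir`.
#'
#' The linear models instrument emotion only (centrality's binary-outcome
#' effect is not identified when many users dropped out long before the
#' first observation); the survival models treat emotion and centrality as
#' endogenous with followee-mean emotion and centrality as the two
#' instruments.
#'
#' @param config a [sim_config()] used to simulate, ignored when `panel` is
#'   given.
#' @param panel optional pre-built `community_panel`.
#' @param pi_days,lambda censoring parameters; when `tune = TRUE` they are
#'   chosen by [tune_censoring()] instead.
#' @param tune logical; tune (pi, lambda) against observed statuses.
#' @param n_boot bootstrap replicates for the survival CIs (default 200 at
#'   desk scale; the reference analysis uses 1000).  `n_boot = 0` skips the
#'   survival bootstrap and switches the cross-specification Wald test to
#'   its analytic variant (point estimates only, for sign / recovery
#'   studies).
#' @param out_dir optional output directory for CSV/TSV tables and the JSON
#'   manifest.
#' @param lexicon sentiment lexicon (default [default_lexicon()]).
#' @return list with elements `panel`, `measured`, `eligible`,
#'   `instruments` (all + single-way), `covariates`, `linear` (ols, iv_all,
#'   iv_single, wu_hausman, wald), `survival` (km, fits + CIs per scheme),
#'   `interests`, `descriptives` (KM median lifetime, assortativity), and
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), panel = NULL,
                         pi_days = 30, lambda = 0.5, tune = FALSE,
                         n_boot = 200, out_dir = NULL,
                         lexicon = default_lexicon()) {
  t0 <- as.numeric(Sys.time())
  manifest <- list(seed = if (is.null(panel)) config$seed else NA,
                   stages = list())

  if (is.null(panel)) panel <- simulate_community(config)
  manifest <- log_stage(manifest, "simulate", nrow(panel$users),
                        nrow(panel$users), t0)

  ## --- measurement -------------------------------------------------------
  measured <- user_emotion(panel$posts, lexicon, obs1_time = panel$obs1_time)
  elig <- eligible_users(panel$posts, obs1_time = panel$obs1_time)
  manifest <- log_stage(manifest, "eligibility", nrow(panel$users),
                        length(elig), t0)

  centrality <- in_coreness(panel$graph)
  emo_attr <- stats::setNames(measured$emotion, measured$user_id)
  all_ids <- as.character(panel$users$user_id)
  emo_attr <- emo_attr[all_ids]
  names(emo_attr) <- all_ids
  cent_attr <- as.numeric(centrality[all_ids])
  names(cent_attr) <- all_ids

  inst <- list(
    all = list(emotion = build_instruments(panel$graph, emo_attr),
               centrality = build_instruments(panel$graph, cent_attr)),
    single = list(
      emotion = build_instruments(panel$graph, emo_attr, single_way = TRUE),
      centrality = build_instruments(panel$graph, cent_attr,
                                     single_way = TRUE)))

  covariates <- compute_covariates(panel, measured, inst$all$emotion)
  act <- activity_summary(panel$posts, panel$obs1_time, panel$obs2_time)
  status <- dropout_status(act, panel$obs1_time)

  ## --- descriptives ------------------------------------------------------
  created <- panel$users$created_at[match(act$user_id, panel$users$user_id)]
  lt <- user_lifetime(act, created)
  km_life <- kaplan_meier(lt, rep(1L, length(lt)))
  status_named <- stats::setNames(status, act$user_id)
  lab <- rep("dropout", length(panel$users$user_id))
  lab[match(act$user_id[status == 0], panel$users$user_id)] <- "nondropout"
  names(lab) <- all_ids
  assort <- tryCatch(
    assortativity_null_z(panel$graph, lab, n_perm = 200,
                         seed = config$seed + 11L),
    error = function(e) list(r_obs = NA, z = NA, p = NA))
  descriptives <- list(km_lifetime = km_life,
                       median_lifetime = km_life$median,
                       assortativity = assort,
                       dropout_rate = mean(status))

  ## --- linear models -----------------------------------------------------
  frame <- data.frame(user_id = act$user_id, status = status)
  frame <- merge(frame, measured[, c("user_id", "emotion")], by = "user_id")
  frame <- merge(frame, covariates, by = "user_id")
  frame$z_emotion_all <-
    inst$all$emotion$value[match(frame$user_id, inst$all$emotion$user_id)]
  frame$z_emotion_single <-
    inst$single$emotion$value[match(frame$user_id,
                                    inst$single$emotion$user_id)]
  frame <- frame[frame$user_id %in% elig, ]

  lin_all <- stats::complete.cases(
    frame[, c("status", "emotion", covariate_names, "z_emotion_all")])
  lin_single <- lin_all & !is.na(frame$z_emotion_single)
  manifest <- log_stage(manifest, "linear_sample_all", length(elig),
                        sum(lin_all), t0)
  manifest <- log_stage(manifest, "linear_sample_single", sum(lin_all),
                        sum(lin_single), t0)

  design <- function(rows, zcol) {
    d <- frame[rows, ]
    list(y = d$status, X1 = as.matrix(d[, "emotion", drop = FALSE]),
         X2 = add_intercept(as.matrix(d[, covariate_names])),
         Z = as.matrix(d[, zcol, drop = FALSE]), d = d)
  }
  da <- design(lin_all, "z_emotion_all")
  ds <- design(lin_single, "z_emotion_single")
  linear <- list(
    ols = ols_fit(da$y, cbind(da$X1, da$X2)),
    iv_all = tsls_fit(da$y, da$X1, da$X2, da$Z),
    iv_single = tsls_fit(ds$y, ds$X1, ds$X2, ds$Z),
    wu_hausman = wu_hausman(da$y, da$X1, da$X2, da$Z))
  refit <- function(zcol) {
    dd <- design(lin_single, zcol)
    function(idx) tsls_fit(dd$y[idx], dd$X1[idx, , drop = FALSE],
                           dd$X2[idx, , drop = FALSE],
                           dd$Z[idx, , drop = FALSE])$coefficients
  }
  linear$wald <- if (n_boot > 0) wald_equality(
    linear$iv_all, linear$iv_single, "emotion",
    refit_a = refit("z_emotion_all"), refit_b = refit("z_emotion_single"),
    n_index = sum(lin_single), n_boot = max(100, min(200, n_boot * 2)),
    seed = config$seed + 21L)
  else wald_equality(linear$iv_all, linear$iv_single, "emotion",
                     method = "analytic")
  manifest$linear_n <- c(all = sum(lin_all), single = sum(lin_single))

  ## --- survival models ---------------------------------------------------
  surv_act <- survival_sample(act, panel$obs1_time)
  sframe <- frame[frame$user_id %in% surv_act$user_id, ]
  sact <- surv_act[match(sframe$user_id, surv_act$user_id), ]
  sframe$centrality <- cent_attr[as.character(sframe$user_id)]
  sframe$z_centrality_all <-
    inst$all$centrality$value[match(sframe$user_id,
                                    inst$all$centrality$user_id)]
  sframe$z_centrality_single <-
    inst$single$centrality$value[match(sframe$user_id,
                                       inst$single$centrality$user_id)]
  if (tune) {
    tuned <- tune_censoring(act, status, panel$obs1_time)
    pi_days <- tuned$pi; lambda <- tuned$lambda
    manifest$tuned <- tuned[c("pi", "lambda", "agreement")]
  }
  manifest$censoring <- list(pi = pi_days, lambda = lambda)
  keep <- stats::complete.cases(
    sframe[, c("emotion", "centrality", covariate_names, "z_emotion_all",
               "z_centrality_all")])
  sframe <- sframe[keep, ]; sact <- sact[keep, ]
  manifest <- log_stage(manifest, "survival_sample", nrow(surv_act),
                        nrow(sframe), t0)

  outcomes <- list(
    identical = censor_identical(sact, pi_days, panel$obs1_time,
                                 panel$obs2_time),
    personalized = censor_personalized(sact, pi_days, lambda,
                                       panel$obs1_time, panel$obs2_time))
  X1s <- as.matrix(sframe[, c("emotion", "centrality")])
  X2s <- add_intercept(as.matrix(sframe[, covariate_names]))
  Zs <- as.matrix(sframe[, c("z_emotion_all", "z_centrality_all")])
  survival_res <- list()
  for (scheme in names(outcomes)) {
    oc <- outcomes[[scheme]]
    std <- aalen_fit(oc$time, oc$event, cbind(X1s, X2s))
    iv <- aalen_iv_fit(oc$time, oc$event, X1s, X2s, Zs)
    if (n_boot == 0) {
      survival_res[[scheme]] <- list(outcomes = oc, standard = std, iv = iv,
                                     km = kaplan_meier(oc$time, oc$event),
                                     ci_standard = NULL, ci_iv = NULL)
      next
    }
    ci_std <- bootstrap_ci(function(idx)
      mean_coefficient(aalen_fit(oc$time[idx], oc$event[idx],
                                 cbind(X1s, X2s)[idx, , drop = FALSE])),
      n = nrow(sframe), n_boot = n_boot, seed = config$seed + 31L)
    ci_iv <- bootstrap_ci(function(idx)
      mean_coefficient(aalen_iv_fit(oc$time[idx], oc$event[idx],
                                    X1s[idx, , drop = FALSE],
                                    X2s[idx, , drop = FALSE],
                                    Zs[idx, , drop = FALSE])),
      n = nrow(sframe), n_boot = n_boot, seed = config$seed + 32L)
    survival_res[[scheme]] <- list(
      outcomes = oc, standard = std, iv = iv,
      km = kaplan_meier(oc$time, oc$event),
      ci_standard = ci_std, ci_iv = ci_iv)
  }

  ## --- interests ---------------------------------------------------------
  interests <- tryCatch(
    interest_analysis(panel, measured, status_named),
    error = function(e) NULL)
  manifest$runtime_s <- as.numeric(Sys.time()) - t0

  result <- list(panel = panel, measured = measured, eligible = elig,
                 instruments = inst, covariates = covariates,
                 linear = linear, survival = survival_res,
                 interests = interests, descriptives = descriptives,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_tables(result, out_dir)
  invisible(result)
}

# group hashtag corpora by dropout state and emotion tercile, build TF-IDF
# profiles and their pairwise Spearman matrix
interest_analysis <- function(panel, measured, status_named) {
  posts <- panel$posts
  has_emo <- measured[!is.na(measured$emotion), ]
  terc <- emotion_terciles(stats::setNames(has_emo$emotion,
                                           has_emo$user_id))
  terc_lab <- stats::setNames(as.character(terc$tercile), terc$user_id)
  tag_user <- rep(posts$user_id, lengths(posts$hashtags))
  tags <- unlist(posts$hashtags, use.names = FALSE)
  by_status <- split(tags, ifelse(
    status_named[as.character(tag_user)] == 1, "dropout", "nondropout"))
  by_terc <- split(tags, terc_lab[as.character(tag_user)])
  status_prof <- build_profiles(by_status)
  terc_prof <- build_profiles(by_terc)
  list(status_profiles = status_prof, tercile_profiles = terc_prof,
       correlations = profile_correlations(status_prof, terc_prof))
}

write_pipeline_tables <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  lin_tab <- do.call(rbind, lapply(
    c(ols = "ols", iv_all = "iv_all", iv_single = "iv_single"),
    function(m) {
      f <- result$linear[[m]]
      data.frame(model = m, term = names(f$coefficients),
                 beta = unname(f$coefficients),
                 robust_se = unname(f$robust_se),
                 p_value = unname(f$p_values))
    }))
  w(lin_tab, "linear_models.csv")
  surv_tab <- do.call(rbind, lapply(names(result$survival), function(s) {
    r <- result$survival[[s]]
    do.call(rbind, lapply(c("standard", "iv"), function(m) {
      mc <- mean_coefficient(r[[m]])
      ci <- r[[paste0("ci_", if (m == "iv") "iv" else "standard")]]
      data.frame(scheme = s, model = m, term = names(mc),
                 mean_coef = unname(mc),
                 survival_direction = -unname(mc),
                 ci_lower = if (is.null(ci)) NA_real_ else
                   unname(ci$lower[names(mc)]),
                 ci_upper = if (is.null(ci)) NA_real_ else
                   unname(ci$upper[names(mc)]))
    }))
  }))
  w(surv_tab, "survival_models.csv")
  w(result$covariates, "covariates.csv")
  if (!is.null(result$interests)) {
    rho <- result$interests$correlations$rho
    w(data.frame(group = rownames(rho), rho), "interest_correlations.csv")
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
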