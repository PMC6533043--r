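## Dropout outcome construction: binary status, identical and personalized
## interval censoring, survival times, lifetimes, and the estimation
## covariates.  All boundary conventions are strict ">" (a gap exactly equal
## to the threshold is not a dropout; a last post exactly at obs1 counts as
## dropout for the binary status).

#' Per-user activity summary
#'
#' Collapses a post stream into the per-user quantities every outcome rule
#' needs: overall last post, first/last post and post count within the first
#' observation window, and the mean inter-post interval in that window.
#'
#' @param posts data frame with `user_id` and `time`.
#' @param obs1_time,obs2_time observation timestamps (days).
#' @return data frame keyed by `user_id` with columns `n_posts`,
#'   `last_post`, `first_obs1`, `last_obs1`, `n_obs1`, `mean_interval_obs1`
#'   (NA when fewer than 2 obs1 posts).
#' @export
activity_summary <- function(posts, obs1_time, obs2_time) {
  stopifnot(obs1_time < obs2_time)
  ids <- sort(unique(posts$user_id))
  if (length(ids) == 0)
    return(data.frame(user_id = numeric(0), n_posts = integer(0),
                      last_post = numeric(0), first_obs1 = numeric(0),
                      last_obs1 = numeric(0), n_obs1 = integer(0),
                      mean_interval_obs1 = numeric(0)))
  out <- data.frame(user_id = ids,
                    n_posts = as.integer(tapply(posts$time, posts$user_id,
                                                length)[as.character(ids)]),
                    last_post = as.numeric(tapply(posts$time, posts$user_id,
                                                  max)[as.character(ids)]))
  p1 <- posts[posts$time <= obs1_time, ]
  out$first_obs1 <- NA_real_; out$last_obs1 <- NA_real_; out$n_obs1 <- 0L
  if (nrow(p1) > 0) {
    f <- tapply(p1$time, p1$user_id, min)
    l <- tapply(p1$time, p1$user_id, max)
    n <- tapply(p1$time, p1$user_id, length)
    idx <- match(as.numeric(names(f)), out$user_id)
    out$first_obs1[idx] <- as.numeric(f)
    out$last_obs1[idx] <- as.numeric(l)
    out$n_obs1[idx] <- as.integer(n)
  }
  out$mean_interval_obs1 <- ifelse(
    out$n_obs1 >= 2, (out$last_obs1 - out$first_obs1) / (out$n_obs1 - 1),
    NA_real_)
  out
}

#' Binary dropout status
#'
#' A user is a non-dropout (0) iff they posted within the follow-up window,
#' i.e. the last post is strictly later than the first observation; a last
#' post at or before obs1 is a dropout (1).
#'
#' @param activity output of [activity_summary()] (users with no posts ever
#'   are expected to have been removed upstream by the eligibility filter).
#' @param obs1_time first observation time.
#' @return integer vector of 0/1 statuses aligned with `activity$user_id`.
#' @export
dropout_status <- function(activity, obs1_time) {
  as.integer(!(activity$last_post > obs1_time))
}

#' Identical interval censoring
#'
#' A user drops out iff the gap between their last post and the second
#' observation strictly exceeds the fixed threshold `pi_days`.  Dropouts get
#' survival time = last post - obs1 (duration from first observation to last
#' posting); non-dropouts are censored at obs2 - obs1 (the whole window).
#' Only survival-eligible users (last post strictly after obs1, see
#' [survival_sample()]) may be passed in.
#'
#' @param activity per-user activity summary rows for the survival sample.
#' @param pi_days fixed threshold, days (> 0).
#' @param obs1_time,obs2_time observation timestamps.
#' @return data frame `user_id`, `event`, `time`, `scheme`,
#'   `threshold_used`.
#' @export
censor_identical <- function(activity, pi_days, obs1_time, obs2_time) {
  stopifnot(pi_days > 0)
  check_survival_sample(activity, obs1_time)
  event <- as.integer((obs2_time - activity$last_post) > pi_days)
  data.frame(user_id = activity$user_id, event = event,
             time = ifelse(event == 1, activity$last_post - obs1_time,
                           obs2_time - obs1_time),
             scheme = "identical", threshold_used = pi_days)
}

#' Personalized interval censoring
#'
#' Per-user threshold lambda * pi + (1 - lambda) * I_i, where I_i is the
#' user's mean inter-post interval in the first observation window.  Users
#' with fewer than 2 obs1 posts (I_i undefined) fall back to the identical
#' threshold and are flagged.  With `lambda = 1` this reduces exactly to
#' [censor_identical()].
#'
#' @param activity per-user activity summary rows for the survival sample.
#' @param pi_days fixed threshold component (> 0).
#' @param lambda blend weight in `[0, 1]`.
#' @param obs1_time,obs2_time observation timestamps.
#' @return data frame as [censor_identical()] plus `fallback` (logical).
#' @export
censor_personalized <- function(activity, pi_days, lambda, obs1_time,
                                obs2_time) {
  stopifnot(pi_days > 0, lambda >= 0, lambda <= 1)
  check_survival_sample(activity, obs1_time)
  fallback <- is.na(activity$mean_interval_obs1)
  thr <- lambda * pi_days +
    (1 - lambda) * ifelse(fallback, pi_days, activity$mean_interval_obs1)
  event <- as.integer((obs2_time - activity$last_post) > thr)
  data.frame(user_id = activity$user_id, event = event,
             time = ifelse(event == 1, activity$last_post - obs1_time,
                           obs2_time - obs1_time),
             scheme = "personalized", threshold_used = thr,
             fallback = fallback)
}

check_survival_sample <- function(activity, obs1_time) {
  if (any(activity$last_post <= obs1_time))
    stop("censoring: users inactive past obs1 are not in the survival ",
         "sample; filter with survival_sample() first", call. = FALSE)
  invisible(activity)
}

#' Survival-eligible users
#'
#' Keeps users who were active past the first observation (last post
#' strictly after obs1); only these enter the survival models.
#'
#' @param activity per-user activity summary.
#' @param obs1_time first observation time.
#' @return the filtered activity data frame.
#' @export
survival_sample <- function(activity, obs1_time) {
  activity[activity$last_post > obs1_time, , drop = FALSE]
}

#' Tune censoring parameters against observed second-period statuses
#'
#' For each (pi, lambda) grid point, predicts dropout from first-observation
#' activity alone -- a user is predicted to drop out if the gap between obs1
#' and their last obs1 post strictly exceeds the (personalized) threshold --
#' and measures agreement with the observed binary statuses.  Returns the
#' grid point maximizing fraction-agreement; ties break toward smaller pi,
#' then larger lambda.
#'
#' @param activity per-user activity summary (users with at least one obs1
#'   post).
#' @param observed integer vector of observed dropout statuses aligned with
#'   `activity$user_id`.
#' @param pi_grid,lambda_grid candidate values (non-empty); defaults are
#'   pi in {7, 14, 30, 60, 90, 180} days and lambda in {0, .25, .5, .75, 1}.
#' @param obs1_time first observation time.
#' @return list `pi`, `lambda`, `agreement`, and `grid` (the full evaluated
#'   grid, one row per point).
#' @export
tune_censoring <- function(activity, observed, obs1_time,
                           pi_grid = c(7, 14, 30, 60, 90, 180),
                           lambda_grid = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(length(pi_grid) > 0, length(lambda_grid) > 0,
            length(observed) == nrow(activity))
  if (length(unique(observed)) < 2)
    warning("tune_censoring: observed statuses are constant; ",
            "agreement is degenerate")
  gap <- obs1_time - activity$last_obs1
  gap[is.na(gap)] <- Inf   # no obs1 activity: predicted dropout at any pi
  ii <- activity$mean_interval_obs1
  grid <- expand.grid(pi = pi_grid, lambda = lambda_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$agreement <- vapply(seq_len(nrow(grid)), function(k) {
    thr <- grid$lambda[k] * grid$pi[k] +
      (1 - grid$lambda[k]) * ifelse(is.na(ii), grid$pi[k], ii)
    mean(as.integer(gap > thr) == observed)
  }, numeric(1))
  best <- grid[order(-grid$agreement, grid$pi, -grid$lambda), ][1, ]
  list(pi = best$pi, lambda = best$lambda, agreement = best$agreement,
       grid = grid)
}

#' Account lifetime
#'
#' Days from account creation to last posting, the quantity whose
#' Kaplan-Meier median summarizes how long accounts stay active.
#'
#' @param activity per-user activity summary (>= 1 post each).
#' @param created_at per-user creation times aligned with
#'   `activity$user_id`.
#' @return numeric vector of lifetimes in days.
#' @export
user_lifetime <- function(activity, created_at) {
  activity$last_post - created_at
}

#' Estimation covariates
#'
#' Builds the covariate table used by every model: social capital (followee,
#' post, follower counts), activity level (active days and per-day rates),
#' observational-bias controls (tweets and followees actually used in
#' measurement), and the alternative-channel controls (share of the
#' instrument followee set active between the observations and their mean
#' active duration).  Counts are measured in the first observation window;
#' rates use active days (creation to last obs1 post) as denominator and are
#' NA-flagged when active days is zero.
#'
#' @param panel a `community_panel`.
#' @param measured output of [user_emotion()] (for `n_tweets_in_use`).
#' @param instruments output of [build_instruments()] (for
#'   `n_followees_in_use` and the followee set used for the
#'   alternative-channel controls).
#' @param single_way logical; must match the instrument set.
#' @return data frame keyed by `user_id` with the Table-style covariate
#'   columns.
#' @export
compute_covariates <- function(panel, measured, instruments,
                               single_way = FALSE) {
  act <- activity_summary(panel$posts, panel$obs1_time, panel$obs2_time)
  obs1 <- panel$obs1_time; obs2 <- panel$obs2_time
  p1 <- panel$posts[panel$posts$time <= obs1, ]
  ids <- act$user_id
  n_posts <- as.integer(tapply(p1$time, p1$user_id, length)[as.character(ids)])
  n_posts[is.na(n_posts)] <- 0L
  out_deg <- table(factor(panel$edges$follower, levels = ids))
  in_deg <- table(factor(panel$edges$followee, levels = ids))
  created <- panel$users$created_at[match(ids, panel$users$user_id)]
  active_days <- act$last_obs1 - created
  zero_span <- is.na(active_days) | active_days <= 0
  rate <- function(x) ifelse(zero_span, NA_real_, x / active_days)
  # alternative-channel controls over the instrument followee set
  status_all <- as.integer(!(act$last_post > obs1))
  dur_all <- pmax(0, pmin(act$last_post, obs2) - obs1)
  fsets <- followee_sets(panel$graph, single_way = single_way)
  pct_active <- avg_dur <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    fs <- match(fsets[[as.character(ids[i])]], ids)
    fs <- fs[!is.na(fs)]
    if (length(fs) > 0) {
      pct_active[i] <- mean(status_all[fs] == 0L)
      avg_dur[i] <- mean(dur_all[fs])
    }
  }
  cov <- data.frame(
    user_id = ids,
    n_followees = as.integer(out_deg),
    n_posts = n_posts,
    n_followers = as.integer(in_deg),
    active_days = active_days,
    followees_per_day = rate(as.integer(out_deg)),
    posts_per_day = rate(n_posts),
    followers_per_day = rate(as.integer(in_deg)),
    n_tweets_in_use = measured$n_tweets_in_use[match(ids, measured$user_id)],
    n_followees_in_use =
      instruments$n_followees_used[match(ids, instruments$user_id)],
    pct_active_followees = pct_active,
    avg_duration_followees = avg_dur
  )
  attr(cov, "flagged_zero_active_days") <- ids[zero_span]
  cov
}
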