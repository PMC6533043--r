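## Synthetic community generator.
##
## The generator is the package's test bed: it produces panels with exactly
## the statistical structure the estimators assume -- a homophilous directed
## follow graph, emotions coupled to followee emotions (instrument relevance),
## an unobserved confounder loading on both emotion and dropout (endogeneity),
## dropout driven by an additive hazard, Poisson posting streams truncated at
## dropout, and topic-conditioned hashtag usage.  Followee attributes never
## enter a user's dropout mechanism directly: the exclusion restriction holds
## by construction.
##
## Stage functions draw their own substream as seed + fixed offset so each is
## individually reproducible; simulate_community() chains them.

seed_offset <- c(graph = 1L, traits = 2L, activity = 3L, hashtags = 4L,
                 linear = 5L)

stage_seed <- function(cfg, stage) {
  (cfg$seed + seed_offset[[stage]]) %% .Machine$integer.max
}

#' Generate a homophilous directed follow graph
#'
#' Each user carries a latent binary trait group.  In out-degree mode
#' (default) every user draws a Poisson number of followees; each follow goes
#' to a same-group target with probability (1 + h)/2 and to the other group
#' with probability (1 - h)/2, where h is `homophily_strength`, so the
#' planted Newman assortativity on the trait is approximately h.  In density
#' mode (when `edge_density` is set) every ordered pair is an edge
#' independently with probability density * (1 + h) within group and
#' density * (1 - h) across groups (capped at 1).
#'
#' @param config a [sim_config()].
#' @return a [follow_graph()] with an extra element `group` (integer 1/2 per
#'   node, the latent homophily trait).
#' @export
generate_follow_graph <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "graph"))
  n <- config$n_users
  h <- config$homophily_strength
  group <- sample(rep_len(1:2, n))
  if (!is.null(config$edge_density)) {
    p0 <- config$edge_density
    from <- rep(seq_len(n), each = n)
    to <- rep(seq_len(n), times = n)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    p <- ifelse(group[from] == group[to], pmin(1, p0 * (1 + h)),
                pmax(0, p0 * (1 - h)))
    sel <- stats::runif(length(p)) < p
    edges <- data.frame(follower = from[sel], followee = to[sel])
  } else {
    r <- if (is.null(config$degree_ratio)) 1 else config$degree_ratio
    d_g <- ifelse(group == 1L, config$mean_out_degree * r,
                  config$mean_out_degree / r)
    k_out <- pmin(stats::rpois(n, d_g), n - 1L)
    from <- rep(seq_len(n), k_out)
    same <- stats::runif(length(from)) < (1 + h) / 2
    members <- split(seq_len(n), group)
    to <- integer(length(from))
    for (g in 1:2) {
      own <- members[[g]]; other <- members[[3 - g]]
      sel_same <- which(group[from] == g & same)
      sel_cross <- which(group[from] == g & !same)
      to[sel_same] <- own[sample.int(length(own), length(sel_same),
                                     replace = TRUE)]
      to[sel_cross] <- other[sample.int(length(other), length(sel_cross),
                                        replace = TRUE)]
    }
    keep <- from != to & !duplicated(paste(from, to, sep = "\r"))
    edges <- data.frame(follower = from[keep], followee = to[keep])
  }
  g <- follow_graph(edges, nodes = seq_len(n))
  g$group <- group
  g
}

#' Generate per-user traits: emotion, confounder, covariate primitives
#'
#' Emotions are peer-coupled in two passes: a first-pass baseline emotion
#' e0_i = trait_shift_i + loading * confounder_i + noise_i is drawn i.i.d.,
#' then the final emotion adds `peer_weight` times the mean first-pass
#' emotion of the user's followees (grand mean for users with no followees)
#' and is clamped to `[-4, 4]`.  The confounder is i.i.d. normal(0,
#' confounder_sd) and is never observed by the estimators.  Centrality is the
#' in-coreness of the generated graph.  Account-creation times and posting
#' rates are drawn independently.
#'
#' @param graph output of [generate_follow_graph()].
#' @param config the same [sim_config()].
#' @return data frame with one row per user: `user_id`, `group`,
#'   `confounder`, `emotion` (true emotion), `centrality`, `posting_rate`,
#'   `created_at`, plus `emotion_base` (the first-pass draw, kept for
#'   diagnostics).
#' @export
generate_traits <- function(graph, config) {
  set.seed(stage_seed(config, "traits"))
  n <- length(graph$nodes)
  confounder <- stats::rnorm(n, 0, config$confounder_sd)
  shift <- config$trait_shift * ifelse(graph$group == 1L, 1, -1)
  own <- shift + config$confounder_loading * confounder +
    stats::rnorm(n, 0, config$emotion_noise_sd)
  # mean first-pass emotion over followees, fast path via rowsum on edges
  e <- graph$edges
  peer_mean <- rep(mean(own), n)
  if (nrow(e) > 0) {
    s <- rowsum(own[e$followee], e$follower)
    k <- rowsum(rep(1, nrow(e)), e$follower)
    idx <- as.integer(rownames(s))
    peer_mean[idx] <- s[, 1] / k[, 1]
  }
  emotion <- pmin(4, pmax(-4, config$peer_weight * peer_mean + own))
  data.frame(
    user_id = seq_len(n),
    group = graph$group,
    confounder = confounder,
    emotion_base = own,
    emotion = emotion,
    centrality = as.numeric(in_coreness(graph)),
    posting_rate = stats::rlnorm(
      n, log(config$posting_rate_mean) - config$posting_rate_sdlog^2 / 2,
      config$posting_rate_sdlog),
    created_at = stats::runif(n, 0, 0.9 * config$obs1_time)
  )
}

#' Draw true dropout times from the additive hazard
#'
#' Each user's dropout hazard is piecewise-constant from account creation:
#' h_i = baseline + he * emotion_i + hc * (centrality_i - mean centrality) +
#' hu * confounder_i, floored at zero (a warning reports how many users were
#' floored; floored users never drop out).  Centrality enters centered so the
#' baseline refers to a typical-centrality, neutral-emotion user.
#'
#' @param traits output of [generate_traits()].
#' @param config the [sim_config()].
#' @param seed optional override of the stage seed.
#' @return numeric vector of absolute dropout times (days; `Inf` for
#'   zero-hazard users), aligned with `traits$user_id`.
#' @export
sim_dropout_times <- function(traits, config, seed = NULL) {
  set.seed(if (is.null(seed)) stage_seed(config, "activity") else seed)
  h <- config$hazard_baseline +
    config$hazard_emotion * traits$emotion +
    config$hazard_centrality * (traits$centrality - mean(traits$centrality)) +
    config$hazard_confounder * traits$confounder
  n_floor <- sum(h < 0)
  if (n_floor > 0)
    warning("sim_dropout_times: hazard floored at 0 for ", n_floor, " users")
  h <- pmax(h, 0)
  wait <- ifelse(h > 0, stats::rexp(length(h)) / ifelse(h > 0, h, 1), Inf)
  traits$created_at + wait
}

#' Generate posting streams truncated at dropout
#'
#' Dropout times come from [sim_dropout_times()]; each user then posts as a
#' Poisson process at their posting rate from account creation until
#' min(dropout time, obs2).  Post tokens are emitted from the default
#' sentiment lexicon so that the expected per-post score equals the user's
#' true emotion (plus noise), which is what lets the sentiment module recover
#' true emotions from text.  A fraction of posts are flagged as retweets.
#'
#' @param graph,traits,config generator state.
#' @param lexicon sentiment lexicon used for token emission (default
#'   [default_lexicon()]).
#' @return list with `posts` (data frame: `user_id`, `time`, `tokens`
#'   (list column), `hashtags` (list column, filled by
#'   [generate_hashtags()]), `is_retweet`) and `dropout_time` (per-user
#'   vector).
#' @export
generate_activity <- function(graph, traits, config,
                              lexicon = default_lexicon()) {
  dropout_time <- sim_dropout_times(traits, config)
  # continue in the same stream (sim_dropout_times seeded it)
  n <- nrow(traits)
  end <- pmin(dropout_time, config$obs2_time)
  span <- pmax(0, end - traits$created_at)
  n_posts <- stats::rpois(n, traits$posting_rate * span)
  uid <- rep(traits$user_id, n_posts)
  t_post <- traits$created_at[uid] +
    stats::runif(length(uid)) * span[uid]
  ord <- order(uid, t_post)
  uid <- uid[ord]; t_post <- t_post[ord]
  is_rt <- stats::runif(length(uid)) < config$retweet_prob
  tokens <- emit_tokens(traits$emotion[uid], config$token_noise_sd, lexicon)
  posts <- data.frame(user_id = uid, time = t_post, is_retweet = is_rt)
  posts$tokens <- tokens
  posts$hashtags <- rep(list(character(0)), nrow(posts))
  list(posts = posts, dropout_time = dropout_time)
}

# one sentiment-bearing token per post at a strength level centred on the
# user's true emotion, plus neutral filler tokens
emit_tokens <- function(emotion, noise_sd, lexicon) {
  m <- length(emotion)
  level <- pmin(4, pmax(-4, round(emotion + stats::rnorm(m, 0, noise_sd))))
  filler <- c("today", "really", "just", "want", "going", "think", "time",
              "day", "people", "still")
  n_fill <- 1L + stats::rpois(m, 4)
  signal <- signal_token(level, lexicon)
  fill_pool <- sample(filler, sum(n_fill), replace = TRUE)
  stops <- cumsum(n_fill)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  lapply(seq_len(m), function(i) {
    tk <- fill_pool[starts[i]:stops[i]]
    if (!is.na(signal[i])) tk <- c(signal[i], tk)
    tk
  })
}

# map a score level in [-4, 4] to a lexicon term of matching strength
signal_token <- function(level, lexicon) {
  strength <- ifelse(level > 0, level + 1L, ifelse(level < 0, level - 1L, NA))
  idx <- match(strength, lexicon$strength)
  ifelse(is.na(idx), NA_character_, lexicon$term[idx])
}

#' Generate topic-conditioned hashtags
#'
#' Each post carries hashtags with probability `tag_prob`; tags are drawn
#' from a mixture of the topic distributions in `config$topic_params`, with
#' mixture weights combining the user's emotion tercile and dropout status,
#' so matched groups (negative tercile with non-dropouts, positive tercile
#' with dropouts under the defaults) share topic distributions.
#'
#' @param posts post data frame from [generate_activity()].
#' @param traits trait data frame (for emotion terciles).
#' @param dropout logical/0-1 vector per user: dropped out before obs2.
#' @param config the [sim_config()].
#' @return `posts` with the `hashtags` list column filled.
#' @export
generate_hashtags <- function(posts, traits, dropout, config) {
  tp <- config$topic_params
  if (is.null(tp) || length(tp$topics) == 0)
    stop("invalid config: empty topic_params", call. = FALSE)
  set.seed(stage_seed(config, "hashtags"))
  terc <- emotion_terciles(stats::setNames(traits$emotion, traits$user_id))
  terc_lab <- stats::setNames(terc$tercile, terc$user_id)
  # P(lifestyle topic) per user
  p_life <- tp$mix_weight * tp$tercile_pref[terc_lab[as.character(traits$user_id)]] +
    (1 - tp$mix_weight) * tp$status_pref[ifelse(dropout > 0, "dropout",
                                                "nondropout")]
  p_life <- stats::setNames(as.numeric(p_life), traits$user_id)
  m <- nrow(posts)
  has_tag <- stats::runif(m) < tp$tag_prob
  n_tags <- ifelse(has_tag, 1L + stats::rbinom(m, 1L, 0.3), 0L)
  topics <- tp$topics
  tag_rows <- which(n_tags > 0)
  tags <- rep(list(character(0)), m)
  if (length(tag_rows) > 0) {
    u <- as.character(posts$user_id[tag_rows])
    is_life <- stats::runif(length(tag_rows)) < p_life[u]
    for (topic_id in 1:2) {
      rows <- tag_rows[if (topic_id == 1) is_life else !is_life]
      if (length(rows) == 0) next
      topic <- topics[[topic_id]]
      k <- n_tags[rows]
      drawn <- sample(names(topic), sum(k), replace = TRUE, prob = topic)
      tags[rows] <- split(drawn, factor(rep(seq_along(rows), k),
                                        levels = seq_along(rows)))
    }
  }
  posts$hashtags <- tags
  posts
}

#' Linear-probability dropout outcome
#'
#' Draws the continuous dropout propensity y* = intercept + beta_e * emotion
#' + beta_c * centrality + gamma * confounder + eps and a Bernoulli indicator
#' at the propensity clamped to `[0, 1]`.  This is the pure linear structural
#' equation used in estimator-validation studies; panel-level binary dropout
#' is instead derived from the hazard mechanism (dropout time < obs2) so the
#' linear and survival outcomes stay mutually consistent.
#'
#' @param traits trait data frame.
#' @param config the [sim_config()].
#' @param seed optional stage-seed override.
#' @return data frame `user_id`, `propensity`, `dropout_bin`.
#' @export
generate_linear_outcome <- function(traits, config, seed = NULL) {
  set.seed(if (is.null(seed)) stage_seed(config, "linear") else seed)
  y_star <- config$lp_intercept +
    config$beta_emotion * traits$emotion +
    config$beta_centrality * traits$centrality +
    config$gamma_linear * traits$confounder +
    stats::rnorm(nrow(traits), 0, config$lp_noise_sd)
  p <- pmin(1, pmax(0, y_star))
  data.frame(user_id = traits$user_id, propensity = y_star,
             dropout_bin = stats::rbinom(nrow(traits), 1, p))
}

#' Simulate a complete community panel
#'
#' Chains graph, trait, activity and hashtag generation and bundles the
#' result with the observation timestamps and the hidden truth table
#' (confounder, true emotion, true dropout time -- retained only so recovery
#' tests can compare estimates against the planted values).
#'
#' @param config a [sim_config()].
#' @return an object of class `community_panel`: list with `users` (user_id,
#'   created_at), `edges`, `posts`, `obs1_time`, `obs2_time`, `truth`,
#'   `config`.
#' @export
simulate_community <- function(config = sim_config()) {
  validate_sim_config(config)
  graph <- generate_follow_graph(config)
  traits <- generate_traits(graph, config)
  act <- generate_activity(graph, traits, config)
  dropout <- as.integer(act$dropout_time < config$obs2_time)
  posts <- generate_hashtags(act$posts, traits, dropout, config)
  truth <- traits
  truth$dropout_time <- act$dropout_time
  panel <- list(
    users = data.frame(user_id = traits$user_id,
                       created_at = traits$created_at),
    edges = graph$edges,
    graph = graph,
    posts = posts,
    obs1_time = config$obs1_time,
    obs2_time = config$obs2_time,
    truth = truth,
    config = config
  )
  class(panel) <- "community_panel"
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "community_panel"))
  with(panel, {
    stopifnot(all(c(edges$follower, edges$followee) %in% users$user_id))
    if (nrow(posts) > 0) {
      created <- users$created_at[match(posts$user_id, users$user_id)]
      stopifnot(all(posts$time >= created - 1e-9),
                all(posts$time <= obs2_time + 1e-9))
      stopifnot(!is.unsorted(order(posts$user_id, posts$time)))
    }
  })
  invisible(panel)
}

#' @export
print.community_panel <- function(x, ...) {
  cat("community_panel:", nrow(x$users), "users,", nrow(x$edges), "edges,",
      nrow(x$posts), "posts; obs1 =", x$obs1_time, "obs2 =", x$obs2_time,
      "\n")
  invisible(x)
}
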