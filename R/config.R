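#' Simulation configuration for a synthetic community
#'
#' Bundles every knob of the synthetic-data generator: network size and
#' homophily, the peer channel that makes followee averages relevant
#' instruments, the unobserved confounder that makes a user's own emotion
#' endogenous, the dropout mechanisms (linear-probability and additive-hazard),
#' the posting process, the two observation timestamps, and the
#' hashtag-topic parameters.
#'
#' Timestamps are real-valued days since simulation start.  Defaults describe
#' a mid-sized community observed for one year before the first observation
#' and followed up 1.5 years later, with a median account lifetime of roughly
#' six months; they are held fixed across the package's simulation studies.
#'
#' @param n_users number of accounts (>= 2).
#' @param mean_out_degree expected number of followees per user; ignored when
#'   `edge_density` is supplied.
#' @param degree_ratio multiplicative out-degree contrast between the two
#'   latent groups (group 1 posts at `mean_out_degree * r`, group 2 at
#'   `mean_out_degree / r`); > 1 makes coreness heterogeneous across groups,
#'   which combined with homophily is what makes followee-mean centrality an
#'   informative instrument.  1 = homogeneous degrees.
#' @param edge_density optional per-ordered-pair edge probability; when given,
#'   edges are drawn independently per ordered pair (used for small, dense
#'   test graphs, e.g. `edge_density = 1` yields the complete directed graph).
#' @param homophily_strength in `[0, 1)`: relative excess probability of a
#'   within-group edge over a cross-group edge on the latent binary trait.
#'   0 means trait-independent wiring; the planted Newman assortativity is
#'   approximately equal to this value.
#' @param trait_shift additive shift of baseline emotion by latent group
#'   (+shift for group 1, -shift for group 2); links the wiring trait to
#'   emotions so dropout states inherit network homophily.
#' @param peer_weight coefficient of the followee-mean baseline emotion in a
#'   user's emotion (the instrument-relevance channel).
#' @param confounder_sd standard deviation of the unobserved i.i.d. normal
#'   confounder; 0 switches endogeneity off.
#' @param confounder_loading loading of the confounder on emotion.
#' @param emotion_noise_sd idiosyncratic emotion noise s.d.
#' @param beta_emotion,beta_centrality true causal effects on the
#'   linear-probability dropout scale.
#' @param gamma_linear confounder effect on the linear dropout propensity.
#' @param lp_intercept,lp_noise_sd intercept and noise s.d. of the linear
#'   propensity equation.
#' @param hazard_baseline baseline dropout hazard, events/day.
#' @param hazard_emotion,hazard_centrality,hazard_confounder additive hazard
#'   effects per unit of each attribute, events/day; the aggregate hazard is
#'   floored at zero (with a warning when the floor binds).
#' @param posting_rate_mean mean posting rate, posts/day (log-normal across
#'   users).
#' @param posting_rate_sdlog log-scale s.d. of the posting rate.
#' @param retweet_prob probability that a post is a retweet.
#' @param token_noise_sd s.d. of the per-post sentiment-level noise around the
#'   user's true emotion, in score units.
#' @param obs1_time,obs2_time first and second observation timestamps, days.
#' @param topic_params hashtag-topic parameters, see [default_topic_params()].
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   panel.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_community()]
#' @export
sim_config <- function(n_users = 2000,
                       mean_out_degree = 10,
                       degree_ratio = 2.5,
                       edge_density = NULL,
                       homophily_strength = 0.55,
                       trait_shift = -0.8,
                       peer_weight = 0.9,
                       confounder_sd = 1,
                       confounder_loading = 0.8,
                       emotion_noise_sd = 1,
                       beta_emotion = 0.3,
                       beta_centrality = 0,
                       gamma_linear = -1,
                       lp_intercept = 0,
                       lp_noise_sd = 1,
                       hazard_baseline = 0.0055,
                       hazard_emotion = 0.0025,
                       hazard_centrality = -0.0018,
                       hazard_confounder = -0.0045,
                       posting_rate_mean = 0.5,
                       posting_rate_sdlog = 0.6,
                       retweet_prob = 0.2,
                       token_noise_sd = 1.2,
                       obs1_time = 365,
                       obs2_time = 912,
                       topic_params = default_topic_params(),
                       seed = 1L) {
  cfg <- list(
    n_users = as.integer(n_users), mean_out_degree = mean_out_degree,
    degree_ratio = degree_ratio,
    edge_density = edge_density, homophily_strength = homophily_strength,
    trait_shift = trait_shift, peer_weight = peer_weight,
    confounder_sd = confounder_sd, confounder_loading = confounder_loading,
    emotion_noise_sd = emotion_noise_sd, beta_emotion = beta_emotion,
    beta_centrality = beta_centrality, gamma_linear = gamma_linear,
    lp_intercept = lp_intercept, lp_noise_sd = lp_noise_sd,
    hazard_baseline = hazard_baseline, hazard_emotion = hazard_emotion,
    hazard_centrality = hazard_centrality,
    hazard_confounder = hazard_confounder,
    posting_rate_mean = posting_rate_mean,
    posting_rate_sdlog = posting_rate_sdlog,
    retweet_prob = retweet_prob, token_noise_sd = token_noise_sd,
    obs1_time = obs1_time, obs2_time = obs2_time,
    topic_params = topic_params, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$n_users) || cfg$n_users < 2L)
    stop("invalid config: n_users must be >= 2", call. = FALSE)
  if (!is.null(cfg$edge_density) &&
      (cfg$edge_density < 0 || cfg$edge_density > 1))
    stop("invalid config: edge_density must lie in [0, 1]", call. = FALSE)
  if (cfg$obs1_time >= cfg$obs2_time)
    stop("invalid config: obs1_time must precede obs2_time", call. = FALSE)
  rates <- c(cfg$hazard_baseline, cfg$posting_rate_mean, cfg$mean_out_degree)
  if (any(rates < 0))
    stop("invalid config: rates must be non-negative", call. = FALSE)
  if (cfg$homophily_strength < 0 || cfg$homophily_strength >= 1)
    stop("invalid config: homophily_strength must lie in [0, 1)", call. = FALSE)
  if (cfg$confounder_sd < 0 || cfg$emotion_noise_sd < 0)
    stop("invalid config: standard deviations must be non-negative",
         call. = FALSE)
  invisible(cfg)
}

#' Default hashtag-topic parameters
#'
#' Two disjoint synthetic tag vocabularies ("lifestyle" vs "recovery") with
#' Zipf-weighted tag frequencies.  A user's posts draw tags from a mixture of
#' the two topics; mixture weights come half from the user's emotion tercile
#' and half from the user's dropout status, so that the negative-emotion
#' tercile and the non-dropout group share a topic (and likewise positive /
#' dropout), reproducing the matched-interest structure the interests module
#' is designed to detect.
#'
#' @param n_tags tags per topic.
#' @param tag_prob probability that a post carries hashtags at all.
#' @param mix_weight weight on the emotion-tercile preference (the remainder
#'   goes to the dropout-status preference).
#' @return a list with elements `topics` (named list of named probability
#'   vectors), `tercile_pref`, `status_pref`, `tag_prob`, `mix_weight`.
#' @export
default_topic_params <- function(n_tags = 25, tag_prob = 0.3,
                                 mix_weight = 0.5) {
  zipf <- function(prefix) {
    w <- 1 / seq_len(n_tags)
    stats::setNames(w / sum(w), sprintf("%s%02d", prefix, seq_len(n_tags)))
  }
  list(
    topics = list(lifestyle = zipf("lifestyle"), recovery = zipf("recovery")),
    # P(topic = lifestyle) contribution by emotion tercile and dropout status
    tercile_pref = c(negative = 1, neutral = 0.5, positive = 0),
    status_pref = c(nondropout = 1, dropout = 0),
    tag_prob = tag_prob,
    mix_weight = mix_weight
  )
}

#' Read / write a simulation config as YAML
#' @param path file path.
#' @param cfg a `sim_config` object.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tp <- raw$topic_params
  raw$topic_params <- NULL
  cfg <- do.call(sim_config, raw)
  if (!is.null(tp)) {
    tp$topics <- lapply(tp$topics, unlist)
    tp$tercile_pref <- unlist(tp$tercile_pref)
    tp$status_pref <- unlist(tp$status_pref)
    cfg$topic_params <- tp
  }
  cfg
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  out <- unclass(cfg)
  out$topic_params$topics <- lapply(out$topic_params$topics, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
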