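test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_users = 1), "n_users")
  expect_error(sim_config(obs1_time = 10, obs2_time = 5), "obs1_time")
  expect_error(sim_config(homophily_strength = 1.2), "homophily")
  expect_error(sim_config(posting_rate_mean = -1), "rates")
  cfg_bad <- sim_config()
  cfg_bad$topic_params <- list(topics = list())
  expect_error(generate_hashtags(data.frame(), data.frame(), integer(0),
                                 cfg_bad),
               "topic_params")
})

test_that("follow-graph generation respects homophily settings", {
  # independence case: assortativity near zero
  cfg0 <- sim_config(n_users = 2000, homophily_strength = 0,
                     degree_ratio = 1, mean_out_degree = 10, seed = 2)
  g0 <- generate_follow_graph(cfg0)
  r0 <- newman_assortativity(g0, stats::setNames(g0$group, g0$nodes))
  expect_lt(abs(r0), 0.05)
  # strong homophily: assortativity well above 0.3
  cfg1 <- sim_config(n_users = 2000, homophily_strength = 0.6,
                     degree_ratio = 1, seed = 2)
  g1 <- generate_follow_graph(cfg1)
  r1 <- newman_assortativity(g1, stats::setNames(g1$group, g1$nodes))
  expect_gt(r1, 0.3)
  expect_lt(abs(r1 - 0.6), 0.1)   # planted r is approximately h
  # graphs are simple
  expect_false(any(g1$edges$follower == g1$edges$followee))
  expect_false(anyDuplicated(paste(g1$edges$follower, g1$edges$followee)) > 0)
})

test_that("density mode: two users at density 1 give both directed edges", {
  cfg <- sim_config(n_users = 2, edge_density = 1, homophily_strength = 0,
                    seed = 1)
  g <- generate_follow_graph(cfg)
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$follower, g$edges$followee),
                  c("1 2", "2 1"))
})

test_that("traits: no coupling means emotions independent of followee means", {
  cfg <- sim_config(n_users = 2000, peer_weight = 0, confounder_sd = 0,
                    trait_shift = 0, degree_ratio = 1,
                    homophily_strength = 0, seed = 6)
  g <- generate_follow_graph(cfg)
  tr <- generate_traits(g, cfg)
  inst <- build_instruments(g, stats::setNames(tr$emotion, tr$user_id))
  idx <- match(inst$user_id, tr$user_id)
  ok <- !is.na(inst$value)
  expect_lt(abs(stats::cor(tr$emotion[idx][ok], inst$value[ok])), 0.05)
})

test_that("peer coupling produces a strong first stage", {
  cfg <- sim_config(n_users = 2000, peer_weight = 0.6, seed = 7)
  g <- generate_follow_graph(cfg)
  tr <- generate_traits(g, cfg)
  inst <- build_instruments(g, stats::setNames(tr$emotion, tr$user_id))
  idx <- match(inst$user_id, tr$user_id)
  ok <- !is.na(inst$value)
  fs <- first_stage(X1 = cbind(emotion = tr$emotion[idx][ok]),
                    X2 = matrix(1, sum(ok), 1,
                                dimnames = list(NULL, "(Intercept)")),
                    Z = cbind(z = inst$value[ok]))
  expect_gt(fs$F, 10)
})

test_that("emotions stay in [-4, 4] and confounder endogeneity is planted", {
  cfg <- sim_config(n_users = 1500, seed = 8)
  g <- generate_follow_graph(cfg)
  tr <- generate_traits(g, cfg)
  expect_true(all(tr$emotion >= -4 & tr$emotion <= 4))
  out <- generate_linear_outcome(tr, cfg)
  # error term of the structural equation contains gamma * confounder:
  # emotion correlates with it when confounder_sd > 0
  err <- out$propensity - cfg$beta_emotion * tr$emotion
  expect_gt(abs(stats::cor(tr$emotion, err)), 0.1)
  cfg0 <- sim_config(n_users = 1500, confounder_sd = 0, seed = 8)
  tr0 <- generate_traits(g, cfg0)
  out0 <- generate_linear_outcome(tr0, cfg0)
  err0 <- out0$propensity - cfg0$beta_emotion * tr0$emotion
  expect_lt(abs(stats::cor(tr0$emotion, err0)), 0.08)
})

test_that("dropout times follow the planted additive hazard", {
  # all modifiers zero: exponential with the baseline rate
  cfg <- sim_config(n_users = 10000, hazard_baseline = 0.01,
                    hazard_emotion = 0, hazard_centrality = 0,
                    hazard_confounder = 0, obs1_time = 5000,
                    obs2_time = 10000, seed = 9)
  g <- generate_follow_graph(cfg)
  tr <- generate_traits(g, cfg)
  tt <- sim_dropout_times(tr, cfg) - tr$created_at
  expect_lt(abs(stats::median(tt) - log(2) / 0.01) / (log(2) / 0.01), 0.05)
  # negative aggregate hazard triggers the floor warning
  cfg2 <- sim_config(n_users = 500, hazard_baseline = 0.001,
                     hazard_emotion = 0.05, seed = 10)
  tr2 <- generate_traits(generate_follow_graph(cfg2), cfg2)
  expect_warning(sim_dropout_times(tr2, cfg2), "floored")
})

test_that("KM curves stratified by emotion tercile are hazard-ordered", {
  cfg <- sim_config(n_users = 6000, hazard_baseline = 0.006,
                    hazard_emotion = 0.004, hazard_centrality = 0,
                    hazard_confounder = 0, trait_shift = -1.2,
                    obs1_time = 365, obs2_time = 912, seed = 11)
  g <- generate_follow_graph(cfg)
  tr <- generate_traits(g, cfg)
  tt <- suppressWarnings(sim_dropout_times(tr, cfg)) - tr$created_at
  terc <- emotion_terciles(stats::setNames(tr$emotion, tr$user_id))
  med <- vapply(split(tt[match(terc$user_id, tr$user_id)], terc$tercile),
                stats::median, numeric(1))
  # positive emotion = higher hazard = shorter time to dropout
  expect_gt(med[["negative"]], med[["neutral"]])
  expect_gt(med[["neutral"]], med[["positive"]])
})

test_that("posting streams respect dropout truncation and zero rates", {
  cfg <- sim_config(n_users = 200, posting_rate_mean = 0, seed = 12)
  g <- generate_follow_graph(cfg)
  tr <- generate_traits(g, cfg)
  act <- suppressWarnings(generate_activity(g, tr, cfg))
  expect_equal(nrow(act$posts), 0L)
  expect_length(eligible_users(act$posts), 0)
  cfg2 <- sim_config(n_users = 200, seed = 12)
  tr2 <- generate_traits(g, cfg2)
  act2 <- suppressWarnings(generate_activity(g, tr2, cfg2))
  end <- pmin(act2$dropout_time, cfg2$obs2_time)
  expect_true(all(act2$posts$time <=
                  end[act2$posts$user_id] + 1e-9))
  expect_true(all(act2$posts$time >=
                  tr2$created_at[act2$posts$user_id] - 1e-9))
})

test_that("panels are deterministic given config + seed, including on disk", {
  cfg <- sim_config(n_users = 150, seed = 99)
  p1 <- suppressWarnings(simulate_community(cfg))
  p2 <- suppressWarnings(simulate_community(cfg))
  expect_identical(p1$posts, p2$posts)
  expect_identical(p1$edges, p2$edges)
  expect_identical(p1$truth, p2$truth)
  d1 <- file.path(tempdir(), "panel_a"); d2 <- file.path(tempdir(), "panel_b")
  write_panel(p1, d1); write_panel(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # different seed changes the panel
  p3 <- suppressWarnings(simulate_community(sim_config(n_users = 150,
                                                       seed = 100)))
  expect_false(identical(p1$posts, p3$posts))
})

test_that("panels round-trip through the plain-text serialization", {
  cfg <- sim_config(n_users = 80, seed = 13)
  p <- suppressWarnings(simulate_community(cfg))
  dir <- file.path(tempdir(), "roundtrip")
  write_panel(p, dir)
  q <- read_panel(dir)
  expect_equal(q$users$user_id, p$users$user_id)
  expect_equal(q$users$created_at, p$users$created_at, tolerance = 1e-12)
  expect_equal(q$edges, p$edges)
  expect_equal(nrow(q$posts), nrow(p$posts))
  expect_identical(q$posts$tokens, p$posts$tokens)
  expect_identical(q$posts$hashtags, p$posts$hashtags)
  expect_equal(q$obs1_time, p$obs1_time)
  expect_equal(q$config$seed, p$config$seed)
})

test_that("hashtag topics separate matched groups from disjoint ones", {
  tp <- default_topic_params()
  expect_named(tp$topics, c("lifestyle", "recovery"))
  expect_length(intersect(names(tp$topics$lifestyle),
                          names(tp$topics$recovery)), 0)
  cfg <- sim_config(n_users = 400, seed = 14)
  p <- suppressWarnings(simulate_community(cfg))
  expect_gt(sum(lengths(p$posts$hashtags)), 0)
  # identical generating law: two halves of one group correlate strongly
  tags <- unlist(p$posts$hashtags)
  half <- seq_along(tags) %% 2 == 0
  prof <- build_profiles(list(a = tags[half], b = tags[!half]))
  expect_gt(rank_correlation(prof$a, prof$b)$rho, 0.8)
})
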