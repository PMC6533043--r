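#!/usr/bin/env Rscript
# Stage 2: measurement.  Scores per-tweet sentiment on the [-4, 4] scale,
# averages it into per-user emotions (first-observation posts only,
# retweets excluded), applies the >10 tweets / >50 words eligibility
# filter, computes in-coreness centrality, and builds the followee-mean
# instruments (all-followee and single-way variants).  Writes
# results/measures.csv and results/instruments.csv.

suppressPackageStartupMessages(library(attritioniv))

panel <- read_panel("results/panel")
measured <- user_emotion(panel$posts, obs1_time = panel$obs1_time)
elig <- eligible_users(panel$posts, obs1_time = panel$obs1_time)
cat(sprintf("eligible users: %d of %d\n", length(elig),
            nrow(panel$users)))

centrality <- in_coreness(panel$graph)
ids <- as.character(panel$users$user_id)
emo <- stats::setNames(measured$emotion, measured$user_id)[ids]
names(emo) <- ids
cent <- stats::setNames(as.numeric(centrality[ids]), ids)

inst <- list(
  emotion_all = build_instruments(panel$graph, emo),
  emotion_sw = build_instruments(panel$graph, emo, single_way = TRUE),
  centrality_all = build_instruments(panel$graph, cent),
  centrality_sw = build_instruments(panel$graph, cent, single_way = TRUE))

measures <- data.frame(user_id = ids,
                       emotion = as.numeric(emo),
                       centrality = as.numeric(cent),
                       eligible = panel$users$user_id %in% elig)
utils::write.csv(measures, "results/measures.csv", row.names = FALSE)

inst_tab <- Reduce(function(a, b) merge(a, b, by = "user_id"), Map(
  function(d, nm) stats::setNames(
    d[, c("user_id", "value", "n_followees_used")],
    c("user_id", paste0("z_", nm), paste0("n_", nm))),
  inst, names(inst)))
utils::write.csv(inst_tab, "results/instruments.csv", row.names = FALSE)

no_sw <- sum(inst$emotion_sw$n_followees_used == 0)
cat(sprintf("users with no single-way followees (excluded from that IV spec): %d\n",
            no_sw))
tr <- panel$truth
cc <- stats::cor(measures$emotion,
                 tr$emotion[match(measures$user_id, tr$user_id)],
                 use = "complete.obs")
cat(sprintf("measured emotion vs planted emotion: r = %.3f\n", cc))
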