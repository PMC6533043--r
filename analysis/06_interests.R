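#!/usr/bin/env Rscript
# Stage 6: hashtag interests.  Pools hashtags by dropout state and by
# emotion tercile, ranks tags by TF-IDF within each group (absent tags
# score 0), and computes the pairwise Spearman correlations between the
# dropout-state and tercile profiles.  A positive correlation means the
# two groups rank the same tags highly, i.e. share posting interests.
# Writes results/interest_profiles.tsv and
# results/interest_correlations.csv.

suppressPackageStartupMessages(library(attritioniv))

panel <- read_panel("results/panel")
measured <- user_emotion(panel$posts, obs1_time = panel$obs1_time)
act <- activity_summary(panel$posts, panel$obs1_time, panel$obs2_time)
status <- stats::setNames(dropout_status(act, panel$obs1_time),
                          act$user_id)

ia <- attritioniv:::interest_analysis(panel, measured, status)
rho <- ia$correlations$rho
p <- ia$correlations$p
cat("Spearman rho between dropout-state and emotion-tercile tag profiles\n")
print(round(rho, 3))
cat("\np-values\n")
print(signif(p, 2))

profs <- c(ia$status_profiles, ia$tercile_profiles)
tab <- do.call(rbind, Map(function(pr, nm) {
  if (nrow(pr) == 0) return(NULL)
  data.frame(group = nm, tag = pr$tag, tf = pr$tf, idf = pr$idf,
             score = pr$score, rank = seq_len(nrow(pr)))
}, profs, names(profs)))
utils::write.table(tab, "results/interest_profiles.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.csv(data.frame(group = rownames(rho), rho),
                 "results/interest_correlations.csv", row.names = FALSE)
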