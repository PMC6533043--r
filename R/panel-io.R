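## Panel serialization: edges as two-column TSV, posts as JSON-lines, users
## and the (simulation-only) truth table as CSV, config as YAML.

#' Write / read a community panel to a directory of plain-text files
#'
#' Files written: `users.csv` (user_id, created_at), `edges.tsv`
#' (follower, followee), `posts.jsonl` (one JSON record per post: user_id,
#' time, tokens, hashtags, is_retweet), `meta.yaml` (obs1/obs2 times),
#' `truth.csv` and `config.yaml` when the panel is simulated.  Reading the
#' files back reproduces the panel byte-for-byte up to numeric text
#' round-trip.
#'
#' @param panel a `community_panel`.
#' @param dir directory (created if missing).
#' @return `write_panel` returns `dir` invisibly; `read_panel` returns a
#'   `community_panel`.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "community_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(panel$users, file.path(dir, "users.csv"),
                   row.names = FALSE)
  utils::write.table(panel$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  con <- file(file.path(dir, "posts.jsonl"), "w")
  on.exit(close(con))
  if (nrow(panel$posts) > 0) {
    recs <- lapply(seq_len(nrow(panel$posts)), function(i) {
      jsonlite::toJSON(list(user_id = panel$posts$user_id[i],
                            time = panel$posts$time[i],
                            tokens = panel$posts$tokens[[i]],
                            hashtags = panel$posts$hashtags[[i]],
                            is_retweet = panel$posts$is_retweet[i]),
                       auto_unbox = TRUE, digits = NA)
    })
    writeLines(unlist(recs), con)
  }
  yaml::write_yaml(list(obs1_time = panel$obs1_time,
                        obs2_time = panel$obs2_time),
                   file.path(dir, "meta.yaml"))
  if (!is.null(panel$truth))
    utils::write.csv(panel$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  if (!is.null(panel$config))
    write_sim_config(panel$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  users <- utils::read.csv(file.path(dir, "users.csv"))
  edges <- utils::read.delim(file.path(dir, "edges.tsv"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  lines <- readLines(file.path(dir, "posts.jsonl"))
  if (length(lines) > 0) {
    recs <- lapply(lines, jsonlite::fromJSON)
    posts <- data.frame(
      user_id = vapply(recs, `[[`, numeric(1), "user_id"),
      time = vapply(recs, `[[`, numeric(1), "time"),
      is_retweet = vapply(recs, `[[`, logical(1), "is_retweet"))
    posts$tokens <- lapply(recs, function(r) as.character(r$tokens))
    posts$hashtags <- lapply(recs, function(r) as.character(r$hashtags))
  } else {
    posts <- data.frame(user_id = numeric(0), time = numeric(0),
                        is_retweet = logical(0))
    posts$tokens <- list(); posts$hashtags <- list()
  }
  truth_path <- file.path(dir, "truth.csv")
  cfg_path <- file.path(dir, "config.yaml")
  panel <- list(users = users, edges = edges,
                graph = follow_graph(edges, nodes = users$user_id),
                posts = posts,
                obs1_time = meta$obs1_time, obs2_time = meta$obs2_time,
                truth = if (file.exists(truth_path))
                  utils::read.csv(truth_path) else NULL,
                config = if (file.exists(cfg_path))
                  read_sim_config(cfg_path) else NULL)
  class(panel) <- "community_panel"
  validate_panel(panel)
  panel
}
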