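## Lexicon-based sentiment scoring on a dual positive/negative scale.
##
## Each tweet gets a positive strength P (max positive lexicon value over its
## tokens, default 1 = neutral) and a negative strength N (min negative value,
## default -1), and a single scaled score P + N in [-4, 4].  The lexicon is
## pluggable; the default is a small synthetic lexicon whose strengths span
## the full dual scale.  The scorer deliberately has no negation, booster or
## emoticon handling: the estimators downstream, not the NLP, are the point,
## and the text contract (a score per tweet in [-4, 4], retweets excluded,
## user emotion = mean score) is what matters.

#' Build a sentiment lexicon
#'
#' @param terms character vector (lower-cased, unique).
#' @param strengths integer strengths: positive terms in `[2, 5]` (meaning +1
#'   to +4 above neutral), negative terms in `[-5, -2]`; no term may map to
#'   a neutral strength.
#' @return data frame of class `sentiment_lexicon` with columns `term`,
#'   `strength`.
#' @export
sentiment_lexicon <- function(terms, strengths) {
  terms <- tolower(terms)
  stopifnot(length(terms) == length(strengths))
  if (anyDuplicated(terms))
    stop("lexicon terms must be unique", call. = FALSE)
  ok <- (strengths >= 2 & strengths <= 5) | (strengths >= -5 & strengths <= -2)
  if (!all(ok))
    stop("lexicon strengths must lie in [2,5] or [-5,-2]", call. = FALSE)
  structure(data.frame(term = terms, strength = as.integer(strengths),
                       stringsAsFactors = FALSE),
            class = c("sentiment_lexicon", "data.frame"))
}

#' Default synthetic lexicon
#'
#' Eight signal words covering every strength level of the dual scale; the
#' generator emits these words at rates tied to true emotion, which is what
#' makes measured emotions recover planted ones in simulation studies.
#'
#' @return a [sentiment_lexicon()].
#' @export
default_lexicon <- function() {
  sentiment_lexicon(
    c("glad", "happy", "joyful", "ecstatic",
      "down", "sad", "miserable", "devastated"),
    c(2L, 3L, 4L, 5L, -2L, -3L, -4L, -5L))
}

#' Read / write a lexicon as two-column TSV (term, strength)
#' @param path file path; `lexicon` a [sentiment_lexicon()].
#' @param lexicon a [sentiment_lexicon()].
#' @return `read_lexicon` returns a lexicon; `write_lexicon` returns `path`
#'   invisibly.
#' @export
read_lexicon <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  sentiment_lexicon(d[[1]], d[[2]])
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(lexicon, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Preprocess raw tweet text into tokens
#'
#' Removes @-mentions, #-hashtags and URLs, lower-cases the remainder, and
#' splits on whitespace.  Empty input gives an empty token list.
#'
#' @param text character vector of raw texts.
#' @return list of character token vectors, one per input text.
#' @export
preprocess_text <- function(text) {
  cleaned <- gsub("(https?://\\S+|www\\.\\S+|@\\S+|#\\S+)", " ", text,
                  perl = TRUE)
  cleaned <- tolower(cleaned)
  toks <- strsplit(trimws(cleaned), "\\s+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Score one tweet
#'
#' Positive strength P = max positive lexicon value over the tokens (default
#' 1), negative strength N = min negative value (default -1); the tweet score
#' is P + N, an integer in `[-4, 4]` (0 = neutral).  Tokens absent from the
#' lexicon contribute nothing.
#'
#' @param tokens character vector of tokens (already preprocessed).
#' @param lexicon a [sentiment_lexicon()].
#' @return list with `value` (integer score), `n_tokens`, `P`, `N`.
#' @export
score_tweet <- function(tokens, lexicon = default_lexicon()) {
  s <- lexicon$strength[match(tokens, lexicon$term)]
  s <- s[!is.na(s)]
  P <- if (any(s > 0)) max(s[s > 0]) else 1L
  N <- if (any(s < 0)) min(s[s < 0]) else -1L
  list(value = as.integer(P + N), n_tokens = length(tokens),
       P = as.integer(P), N = as.integer(N))
}

# vectorized scorer over a list of token vectors
score_posts <- function(tokens_list, lexicon = default_lexicon()) {
  m <- length(tokens_list)
  if (m == 0) return(integer(0))
  n_tok <- lengths(tokens_list)
  flat <- unlist(tokens_list, use.names = FALSE)
  post_id <- rep.int(seq_len(m), n_tok)
  s <- lexicon$strength[match(flat, lexicon$term)]
  keep <- !is.na(s)
  s <- s[keep]; post_id <- post_id[keep]
  P <- rep(1L, m); N <- rep(-1L, m)
  if (length(s) > 0) {
    pos <- s > 0
    if (any(pos)) {
      mx <- tapply(s[pos], post_id[pos], max)
      P[as.integer(names(mx))] <- as.integer(mx)
    }
    if (any(!pos)) {
      mn <- tapply(s[!pos], post_id[!pos], min)
      N[as.integer(names(mn))] <- as.integer(mn)
    }
  }
  P + N
}

#' Per-user emotion from post scores
#'
#' A user's emotional state is the arithmetic mean tweet score over usable
#' posts: retweets and empty-token posts are excluded.  Users with no usable
#' posts get `NA` and are flagged.
#'
#' @param posts data frame with columns `user_id`, `tokens` (list column)
#'   and `is_retweet`; typically `panel$posts`.
#' @param lexicon a [sentiment_lexicon()].
#' @param obs1_time optional cutoff: only posts at or before this time are
#'   used (emotions are measured in the first observation period).
#' @return data frame `user_id`, `emotion` (mean score, NA if no usable
#'   posts), `n_tweets_in_use`.
#' @export
user_emotion <- function(posts, lexicon = default_lexicon(),
                         obs1_time = NULL) {
  if (!is.null(obs1_time)) posts <- posts[posts$time <= obs1_time, ]
  usable <- !posts$is_retweet & lengths(posts$tokens) > 0
  use <- posts[usable, ]
  all_ids <- sort(unique(posts$user_id))
  out <- data.frame(user_id = all_ids, emotion = NA_real_,
                    n_tweets_in_use = 0L)
  if (nrow(use) > 0) {
    sc <- score_posts(use$tokens, lexicon)
    agg_m <- tapply(sc, use$user_id, mean)
    agg_n <- tapply(sc, use$user_id, length)
    idx <- match(as.numeric(names(agg_m)), out$user_id)
    out$emotion[idx] <- as.numeric(agg_m)
    out$n_tweets_in_use[idx] <- as.integer(agg_n)
  }
  out
}

#' Eligibility filter for emotion measurement
#'
#' Keeps users with more than `min_tweets` non-retweet posts and more than
#' `min_words` tokens summed over those posts (both strict inequalities),
#' counted after retweet exclusion -- the robustness filter for
#' lexicon-based scoring.
#'
#' @param posts post data frame (`user_id`, `tokens`, `is_retweet`).
#' @param min_tweets,min_words strict lower bounds (defaults 10 and 50).
#' @param obs1_time optional first-observation cutoff.
#' @return vector of eligible user ids.
#' @export
eligible_users <- function(posts, min_tweets = 10, min_words = 50,
                           obs1_time = NULL) {
  if (!is.null(obs1_time)) posts <- posts[posts$time <= obs1_time, ]
  own <- posts[!posts$is_retweet, ]
  if (nrow(own) == 0) return(own$user_id[0])
  n_tweets <- tapply(rep(1L, nrow(own)), own$user_id, sum)
  n_words <- tapply(lengths(own$tokens), own$user_id, sum)
  ids <- as.numeric(names(n_tweets))
  sort(ids[n_tweets > min_tweets & n_words > min_words])
}
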