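## Hashtag-interest profiling: emotion-tercile splits, per-group TF-IDF tag
## profiles, and zero-for-absent-tag Spearman correlations between groups.

#' Split users into emotion terciles
#'
#' Ranks users by emotion and splits them into negative / neutral / positive
#' thirds whose sizes differ by at most one; when the size is not divisible
#' by 3 the lower-score groups absorb the remainder (10 users give sizes
#' 4/3/3).  Ties are broken by stable user-id order; an all-equal input is
#' split by that order with a warning.
#'
#' @param emotions named numeric vector (names = user ids) with no missing
#'   values, or a data frame with columns `user_id` and `emotion`.
#' @return data frame `user_id`, `emotion`, `tercile` (factor negative <
#'   neutral < positive).
#' @export
emotion_terciles <- function(emotions) {
  if (is.data.frame(emotions))
    emotions <- stats::setNames(emotions$emotion, emotions$user_id)
  emotions <- emotions[!is.na(emotions)]
  n <- length(emotions)
  if (n < 3) stop("emotion_terciles: need at least 3 users", call. = FALSE)
  if (length(unique(emotions)) == 1)
    warning("emotion_terciles: all scores equal; split by stable id order")
  ord <- order(emotions, names(emotions))
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- base + as.integer(seq_len(3) <= rem)
  lab <- rep(c("negative", "neutral", "positive"), times = sizes)
  out <- data.frame(user_id = names(emotions)[ord],
                    emotion = as.numeric(emotions[ord]),
                    tercile = factor(lab, levels = c("negative", "neutral",
                                                     "positive")),
                    stringsAsFactors = FALSE)
  out[order(match(out$user_id, names(emotions))), ]
}

#' TF-IDF tag profiles for a set of groups
#'
#' Treats each group's pooled hashtags as one document.  tf(t, g) is the
#' count of tag t in group g; idf(t) = log(1 + G / g_t) with G the number of
#' groups in the comparison set and g_t the number of groups containing t
#' (add-one smoothing keeps ubiquitous tags at a small positive score);
#' score = tf * idf, and a tag absent from a group scores 0 by contract.
#' Tags are lower-cased and compared exactly.
#'
#' @param corpora named list: one character vector of hashtags (with
#'   repetitions) per group.
#' @return named list of `tag_profile` objects (data frames `tag`, `tf`,
#'   `idf`, `score` sorted by decreasing score, with attribute `n_tags`);
#'   groups with no hashtags get an empty, flagged profile.
#' @export
build_profiles <- function(corpora) {
  stopifnot(is.list(corpora), length(corpora) > 0)
  corpora <- lapply(corpora, tolower)
  G <- length(corpora)
  counts <- lapply(corpora, function(x) table(x))
  vocab <- sort(unique(unlist(lapply(counts, names))))
  present <- lapply(counts, names)
  g_t <- vapply(vocab, function(t)
    sum(vapply(present, function(p) t %in% p, logical(1))), numeric(1))
  idf <- stats::setNames(log(1 + G / g_t), vocab)
  out <- lapply(counts, function(ct) {
    if (length(ct) == 0) {
      prof <- data.frame(tag = character(0), tf = numeric(0),
                         idf = numeric(0), score = numeric(0))
      attr(prof, "empty") <- TRUE
    } else {
      prof <- data.frame(tag = names(ct), tf = as.numeric(ct),
                         idf = as.numeric(idf[names(ct)]),
                         stringsAsFactors = FALSE)
      prof$score <- prof$tf * prof$idf
      prof <- prof[order(-prof$score, prof$tag), ]
      rownames(prof) <- NULL
      attr(prof, "empty") <- FALSE
    }
    attr(prof, "n_tags") <- nrow(prof)
    class(prof) <- c("tag_profile", "data.frame")
    prof
  })
  out
}

#' Spearman rank correlation between two tag profiles
#'
#' Scores every tag in the union of the two profiles (0 when absent), ranks
#' with average ranks for ties, and returns Spearman's rho with a two-sided
#' p-value from the large-sample t approximation; for small unions
#' (<= `exact_max` tags) an exact permutation p-value is available.
#' Symmetric in its arguments.  At least 3 union tags and rank variation in
#' both score vectors are required.
#'
#' @param profile_i,profile_j `tag_profile` objects from [build_profiles()].
#' @param method `"t"` (default) or `"permutation"`.
#' @param exact_max largest union size for which the permutation p-value is
#'   enumerated exactly (default 8).
#' @return list `rho`, `p`, `n_tags` (union size), `method`.
#' @export
rank_correlation <- function(profile_i, profile_j,
                             method = c("t", "permutation"),
                             exact_max = 8) {
  method <- match.arg(method)
  tags <- sort(unique(c(profile_i$tag, profile_j$tag)))
  n <- length(tags)
  if (n < 3)
    stop("degenerate input: union vocabulary has fewer than 3 tags",
         call. = FALSE)
  si <- stats::setNames(rep(0, n), tags)
  sj <- si
  si[profile_i$tag] <- profile_i$score
  sj[profile_j$tag] <- profile_j$score
  if (length(unique(si)) == 1 || length(unique(sj)) == 1)
    stop("degenerate input: no rank variation in at least one list",
         call. = FALSE)
  ri <- rank(si); rj <- rank(sj)
  rho <- stats::cor(ri, rj)
  if (method == "permutation" && n <= exact_max) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(ri[p], rj))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (method == "permutation")
      message("rank_correlation: union too large for exact permutation; ",
              "using t approximation")
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t"
  }
  list(rho = rho, p = min(1, p), n_tags = n, method = method)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Pairwise profile correlation matrix
#'
#' Convenience wrapper: Spearman rho (and p) for every pair of one list of
#' profiles against another, mirroring a dropout-state by emotion-tercile
#' comparison table.
#'
#' @param profiles_rows,profiles_cols named lists of `tag_profile`s.
#' @return list of matrices `rho` and `p`.
#' @export
profile_correlations <- function(profiles_rows, profiles_cols) {
  rho <- matrix(NA_real_, length(profiles_rows), length(profiles_cols),
                dimnames = list(names(profiles_rows), names(profiles_cols)))
  p <- rho
  for (i in seq_along(profiles_rows)) {
    for (j in seq_along(profiles_cols)) {
      rc <- tryCatch(rank_correlation(profiles_rows[[i]],
                                      profiles_cols[[j]]),
                     error = function(e) NULL)
      if (!is.null(rc)) { rho[i, j] <- rc$rho; p[i, j] <- rc$p }
    }
  }
  list(rho = rho, p = p)
}
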