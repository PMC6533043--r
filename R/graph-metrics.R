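#' Directed follow graph
#'
#' A minimal container for a who-follows-whom network: an edge (A, B) means
#' "A follows B".  The edge set is validated to be simple (no self-loops, no
#' duplicates) and closed over the node set.
#'
#' @param edges a two-column data frame or matrix (follower, followee).
#' @param nodes vector of node ids; defaults to the ids appearing in `edges`.
#' @return an object of class `follow_graph` with elements `nodes` (integer
#'   or character vector) and `edges` (data frame with columns `follower`,
#'   `followee`).
#' @export
follow_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("edges must have two columns", call. = FALSE)
  names(edges)[1:2] <- c("follower", "followee")
  edges <- edges[, 1:2]
  if (is.null(nodes)) nodes <- sort(unique(c(edges$follower, edges$followee)))
  if (nrow(edges) > 0) {
    if (any(edges$follower == edges$followee))
      stop("follow_graph: self-loops are not allowed", call. = FALSE)
    key <- paste(edges$follower, edges$followee, sep = "\r")
    if (anyDuplicated(key))
      stop("follow_graph: duplicate edges are not allowed", call. = FALSE)
    if (!all(c(edges$follower, edges$followee) %in% nodes))
      stop("follow_graph: edge endpoint not in node set", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "follow_graph")
}

#' @export
print.follow_graph <- function(x, ...) {
  cat("follow_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges\n")
  invisible(x)
}

as_igraph <- function(graph) {
  stopifnot(inherits(graph, "follow_graph"))
  igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$follower),
               to = as.character(graph$edges$followee)),
    directed = TRUE, vertices = as.character(graph$nodes))
}

#' In-coreness centrality
#'
#' The in-coreness of a node is the largest k such that the node belongs to a
#' maximal subgraph in which every node has in-degree at least k (iterative
#' peeling on in-degree).  Core members of a community score high; peripheral
#' accounts score 0.
#'
#' @param graph a [follow_graph()].
#' @return named integer vector of coreness values, one per node (names are
#'   node ids); empty graph gives an empty result.
#' @export
in_coreness <- function(graph) {
  stopifnot(inherits(graph, "follow_graph"))
  if (length(graph$nodes) == 0) return(stats::setNames(integer(0), character(0)))
  g <- as_igraph(graph)
  k <- igraph::coreness(g, mode = "in")
  stats::setNames(as.integer(k), igraph::V(g)$name)
}

#' Followee sets
#'
#' The followees of a user are the accounts the user follows.  In single-way
#' mode, mutual follows are excluded: only followees who do not follow the
#' user back are kept (used to harden instrument exogeneity against feedback
#' from the user to the followee).
#'
#' @param graph a [follow_graph()].
#' @param single_way logical; drop reciprocated follows.
#' @return named list mapping each node id to a vector of followee ids
#'   (possibly empty).
#' @export
followee_sets <- function(graph, single_way = FALSE) {
  stopifnot(inherits(graph, "follow_graph"))
  ids <- as.character(graph$nodes)
  out <- stats::setNames(vector("list", length(ids)), ids)
  e <- graph$edges
  if (nrow(e) > 0) {
    if (single_way) {
      fwd <- paste(e$follower, e$followee, sep = "\r")
      rev <- paste(e$followee, e$follower, sep = "\r")
      e <- e[!(rev %in% fwd), , drop = FALSE]
    }
    if (nrow(e) > 0) {
      sets <- split(e$followee, as.character(e$follower))
      out[names(sets)] <- sets
    }
  }
  out[vapply(out, is.null, logical(1))] <- list(
    if (is.character(graph$nodes)) character(0) else integer(0))
  out
}

#' Followee-aggregated instruments
#'
#' For each user, the unweighted mean of an attribute (emotion or centrality)
#' over the user's followees, used as an instrument for the user's own
#' attribute.  Users with no (single-way) followees get a missing value and
#' are flagged for exclusion from the corresponding estimation sample;
#' followees with a missing attribute are omitted from the mean and counted.
#'
#' @param graph a [follow_graph()].
#' @param attributes named numeric vector, names are node ids; must cover
#'   every followee that is referenced (possibly with NA values).
#' @param single_way logical; use single-way followees only.
#' @return data frame with columns `user_id`, `value` (mean attribute, NA if
#'   no usable followees), `n_followees_used`, and attribute `n_excluded`
#'   (total followee references dropped for missing attribute values, also
#'   reported via a message when positive).
#' @export
build_instruments <- function(graph, attributes, single_way = FALSE) {
  sets <- followee_sets(graph, single_way = single_way)
  ids <- names(sets)
  miss <- setdiff(unique(unlist(lapply(sets, as.character))), names(attributes))
  if (length(miss) > 0)
    stop("build_instruments: attribute not defined for followee(s) ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  excluded <- 0L
  value <- numeric(length(ids))
  n_used <- integer(length(ids))
  for (i in seq_along(sets)) {
    a <- attributes[as.character(sets[[i]])]
    ok <- !is.na(a)
    excluded <- excluded + sum(!ok)
    n_used[i] <- sum(ok)
    value[i] <- if (n_used[i] > 0) mean(a[ok]) else NA_real_
  }
  if (excluded > 0)
    message("build_instruments: omitted ", excluded,
            " followee references with missing attribute values")
  out <- data.frame(user_id = ids, value = value,
                    n_followees_used = n_used,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- excluded
  attr(out, "mode") <- if (single_way) "single-way" else "all-followees"
  out
}

#' Newman assortativity coefficient for categorical labels
#'
#' Directed mixing-matrix statistic r = (sum_i e_ii - sum_i a_i b_i) /
#' (1 - sum_i a_i b_i), where e_ij is the fraction of edges running from a
#' node with label i to a node with label j, a are row sums and b column
#' sums.  r = 1 iff every edge joins same-label nodes; r near 0 indicates
#' label-independent wiring.  Each directed edge is counted once.
#'
#' @param graph a [follow_graph()].
#' @param labels named vector of node labels (names are node ids), or an
#'   unnamed vector ordered as `graph$nodes`.
#' @return scalar r in `[-1, 1]`.
#' @export
newman_assortativity <- function(graph, labels) {
  stopifnot(inherits(graph, "follow_graph"))
  if (nrow(graph$edges) < 1)
    stop("newman_assortativity: graph has no edges", call. = FALSE)
  labels <- align_labels(graph, labels)
  if (length(unique(labels)) < 2)
    stop("degenerate input: a single label is present (denominator 0)",
         call. = FALSE)
  lf <- labels[as.character(graph$edges$follower)]
  lt <- labels[as.character(graph$edges$followee)]
  mixing_r(lf, lt)
}

align_labels <- function(graph, labels) {
  ids <- as.character(graph$nodes)
  if (is.null(names(labels))) {
    stopifnot(length(labels) == length(ids))
    names(labels) <- ids
  }
  if (!all(ids %in% names(labels)))
    stop("labels must cover every node", call. = FALSE)
  labels[ids]
}

# r from the label pairs of each directed edge (used once per edge)
mixing_r <- function(lf, lt) {
  cats <- sort(unique(c(lf, lt)))
  e <- table(factor(lf, cats), factor(lt, cats)) / length(lf)
  s_eii <- sum(diag(e))
  s_ab <- sum(rowSums(e) * colSums(e))
  if (isTRUE(all.equal(s_ab, 1))) return(NaN)
  (s_eii - s_ab) / (1 - s_ab)
}

#' Permutation null for the assortativity coefficient
#'
#' Compares the observed assortativity with its distribution under random
#' label permutations (label counts and graph held fixed), the minimal
#' exchangeability null.  The z score is (r_obs - mean_null) / sd_null, with
#' the 0/0 -> 0 convention when the null distribution is degenerate; the
#' p-value is the two-sided permutation p with add-one smoothing.
#'
#' @param graph a [follow_graph()].
#' @param labels node labels as in [newman_assortativity()].
#' @param n_perm number of permutations (default 1000; below 100 a warning is
#'   emitted because z is unstable).
#' @param seed integer seed for the permutations.
#' @return list with `r_obs`, `z`, `p`, `null_mean`, `null_sd`, `n_perm`.
#' @export
assortativity_null_z <- function(graph, labels, n_perm = 1000, seed = 1L) {
  if (n_perm < 100)
    warning("assortativity_null_z: n_perm < 100 gives an unstable z")
  labels <- align_labels(graph, labels)
  r_obs <- newman_assortativity(graph, labels)
  idx_f <- match(as.character(graph$edges$follower), as.character(graph$nodes))
  idx_t <- match(as.character(graph$edges$followee), as.character(graph$nodes))
  lab <- unname(labels)
  set.seed(seed)
  r_null <- vapply(seq_len(n_perm), function(i) {
    p <- sample(lab)
    mixing_r(p[idx_f], p[idx_t])
  }, numeric(1))
  m <- mean(r_null); s <- stats::sd(r_null)
  z <- if (is.na(s) || s == 0) {
    if (isTRUE(all.equal(r_obs, m))) 0 else sign(r_obs - m) * Inf
  } else (r_obs - m) / s
  p <- (1 + sum(abs(r_null - m) >= abs(r_obs - m))) / (n_perm + 1)
  list(r_obs = r_obs, z = z, p = p, null_mean = m, null_sd = s,
       n_perm = n_perm)
}

#' Read / write an edge list as two-column TSV
#' @param graph a [follow_graph()]; `path` a file path.
#' @param path file path.
#' @return `read_edges` returns a `follow_graph`; `write_edges` returns
#'   `path` invisibly.
#' @export
write_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @param nodes optional node set (to preserve isolated nodes).
#' @export
read_edges <- function(path, nodes = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  follow_graph(e, nodes = nodes)
}
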