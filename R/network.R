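#' Construct a nomination matrix
#'
#' A nomination matrix is the directed binary record of a roster-based
#' friendship survey: entry `[i, j] = 1` when subject `i` named subject
#' `j`. Self-nominations are disallowed.
#'
#' @param entries square binary matrix (row = nominator, column =
#'   nominee).
#' @param subject_ids character identifiers, one per row.
#' @return an object of class `nomination_matrix`.
#' @export
nomination_matrix <- function(entries, subject_ids = NULL) {
  m <- as.matrix(entries)
  n <- nrow(m)
  if (ncol(m) != n) stop("nomination matrix must be square", call. = FALSE)
  if (!all(m %in% c(0, 1))) {
    stop("nomination entries must be 0 or 1", call. = FALSE)
  }
  if (any(diag(m) != 0)) {
    stop("self-nominations are not allowed (nonzero diagonal)",
         call. = FALSE)
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(m) %||% sprintf("S%03d", seq_len(n))
  }
  stopifnot(length(subject_ids) == n, !anyDuplicated(subject_ids))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(subject_ids, subject_ids)
  structure(list(entries = m, subject_ids = as.character(subject_ids)),
            class = "nomination_matrix")
}

#' @export
print.nomination_matrix <- function(x, ...) {
  cat(sprintf(
    "Nomination matrix: %d subjects, %d directed nominations\n",
    length(x$subject_ids), sum(x$entries)
  ))
  invisible(x)
}

#' Build an undirected social graph from nominations
#'
#' Under the `reciprocal` rule an edge joins `i` and `j` only when each
#' nominated the other; under `any` a single directed nomination
#' suffices.
#'
#' @param nominations a [nomination_matrix()].
#' @param tie_rule `"reciprocal"` (default) or `"any"`.
#' @return a `social_graph`: list with an [igraph::graph_from_adjacency_matrix()]
#'   graph, the tie rule and the subject ids.
#' @export
build_graph <- function(nominations, tie_rule = c("reciprocal", "any")) {
  stopifnot(inherits(nominations, "nomination_matrix"))
  tie_rule <- match.arg(tie_rule)
  m <- nominations$entries
  adj <- if (tie_rule == "reciprocal") m * t(m) else pmin(m + t(m), 1L)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  structure(
    list(graph = g, tie_rule = tie_rule,
         subject_ids = nominations$subject_ids),
    class = "social_graph"
  )
}

#' @export
print.social_graph <- function(x, ...) {
  cat(sprintf(
    "Social graph (%s ties): %d nodes, %d edges\n",
    x$tie_rule, igraph::vcount(x$graph), igraph::ecount(x$graph)
  ))
  invisible(x)
}

#' Geodesic social distances
#'
#' All-pairs shortest-path lengths on a social graph. Unreachable pairs
#' keep `Inf` in `distances`; `capped_category` collapses every distance
#' at or above `cap` (including unreachable) into the top category, the
#' "cap+" bucket used throughout the dyadic analyses.
#'
#' @param graph a `social_graph` from [build_graph()].
#' @param cap top distance category (default 4).
#' @return a `distance_result`: list with `distances` (numeric, `Inf` for
#'   unreachable), `capped_category` (integer in `1..cap`, diagonal 0)
#'   and `cap`.
#' @export
geodesic_distances <- function(graph, cap = 4) {
  stopifnot(inherits(graph, "social_graph"), cap >= 1)
  d <- igraph::distances(graph$graph)
  dimnames(d) <- list(graph$subject_ids, graph$subject_ids)
  capped <- pmin(d, cap)
  storage.mode(capped) <- "integer"
  structure(list(distances = d, capped_category = capped,
                 cap = as.integer(cap)),
            class = "distance_result")
}

#' Descriptive statistics of a nomination network
#'
#' Computes the standard survey-network summaries: density of the
#' reciprocal-tie and any-tie graphs, total (edge-level) reciprocity,
#' dyad-level reciprocity, the diameter of the reciprocal graph (maximum
#' finite geodesic distance, flagged when the graph is disconnected), and
#' in-/out-degree summaries of the directed matrix.
#'
#' Total reciprocity is the probability that a directed nomination is
#' returned: `2 * mutual dyads / directed edges`. Dyad reciprocity is the
#' probability that a tied dyad is mutual: `mutual dyads / tied dyads`,
#' which equals `density(reciprocal) / density(any)` identically.
#'
#' @param nominations a [nomination_matrix()].
#' @return a `network_stats` list.
#' @export
network_stats <- function(nominations) {
  stopifnot(inherits(nominations, "nomination_matrix"))
  m <- nominations$entries
  n <- nrow(m)
  nd <- choose(n, 2)
  mutual <- sum(m * t(m)) / 2
  any_tie <- sum(pmin(m + t(m), 1)) / 2
  directed <- sum(m)
  g_rec <- build_graph(nominations, "reciprocal")
  d <- igraph::distances(g_rec$graph)
  finite <- d[is.finite(d) & d > 0]
  deg_stats <- function(x) {
    list(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
         min = min(x), max = max(x))
  }
  structure(list(
    n = n,
    density_reciprocal = mutual / nd,
    density_any = any_tie / nd,
    total_reciprocity = if (directed == 0) NA_real_ else
      2 * mutual / directed,
    dyad_reciprocity = if (any_tie == 0) NA_real_ else mutual / any_tie,
    diameter = if (length(finite) == 0) 0L else as.integer(max(finite)),
    connected = all(is.finite(d)),
    out_degree_stats = deg_stats(rowSums(m)),
    in_degree_stats = deg_stats(colSums(m))
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("Network of %d subjects\n", x$n))
  cat(sprintf("  density: reciprocal %.4f, any %.4f\n",
              x$density_reciprocal, x$density_any))
  cat(sprintf("  reciprocity: total %.3f, dyad-level %.3f\n",
              x$total_reciprocity, x$dyad_reciprocity))
  cat(sprintf("  diameter (reciprocal graph): %d%s\n", x$diameter,
              if (x$connected) "" else " [disconnected: max finite]"))
  cat(sprintf("  out-degree: mean %.2f sd %.2f median %g range [%g, %g]\n",
              x$out_degree_stats$mean, x$out_degree_stats$sd,
              x$out_degree_stats$median, x$out_degree_stats$min,
              x$out_degree_stats$max))
  cat(sprintf("  in-degree:  mean %.2f sd %.2f median %g range [%g, %g]\n",
              x$in_degree_stats$mean, x$in_degree_stats$sd,
              x$in_degree_stats$median, x$in_degree_stats$min,
              x$in_degree_stats$max))
  invisible(x)
}

#' Reciprocity identities from graph densities
#'
#' On any nomination matrix, dyad-level reciprocity equals the ratio of
#' the reciprocal-tie density to the any-tie density, and total (edge
#' level) reciprocity equals `2 d_rec / (d_rec + d_any)`. This helper
#' evaluates both identities from a pair of densities, e.g. to check a
#' published summary for internal consistency.
#'
#' @param density_reciprocal density of the mutual-tie graph.
#' @param density_any density of the any-tie graph.
#' @return list with `dyad_reciprocity` and `total_reciprocity`.
#' @export
reciprocity_from_densities <- function(density_reciprocal, density_any) {
  stopifnot(density_any > 0, density_reciprocal >= 0,
            density_reciprocal <= density_any)
  list(
    dyad_reciprocity = density_reciprocal / density_any,
    total_reciprocity = 2 * density_reciprocal /
      (density_reciprocal + density_any)
  )
}
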