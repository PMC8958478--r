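#' Density of an undirected network
#'
#' The quotient of the number of existing connections and the number of
#' possible connections, \eqn{|E| / (n(n-1)/2)}.
#'
#' @param net A `praxnet_undirected` network.
#' @return Fraction in \[0, 1\].
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "praxnet_undirected"))
  n <- nrow(net$nodes)
  if (n < 2L) {
    stop("density undefined for practice '", net$practice_id, "' (", net$condition,
         "): fewer than 2 nodes", call. = FALSE)
  }
  nrow(net$edges) / (n * (n - 1) / 2)
}

node_degrees <- function(net) {
  ids <- net$nodes$member_id
  d <- integer(length(ids)); names(d) <- ids
  if (nrow(net$edges)) {
    ta <- table(factor(net$edges$a, levels = ids))
    tb <- table(factor(net$edges$b, levels = ids))
    d <- as.integer(ta + tb); names(d) <- ids
  }
  d
}

#' Freeman degree centralization of an undirected network
#'
#' How strongly the network is centred on a single person:
#' \eqn{\sum_i (d_{max} - d_i) / ((n-1)(n-2))}. The star attains 1, and any
#' degree-regular network (including the complete and the empty network)
#' attains 0.
#'
#' @param net A `praxnet_undirected` network.
#' @return Fraction in \[0, 1\].
#' @export
degree_centralization <- function(net) {
  stopifnot(inherits(net, "praxnet_undirected"))
  n <- nrow(net$nodes)
  if (n < 3L) {
    stop("centralization undefined for practice '", net$practice_id, "' (",
         net$condition, "): fewer than 3 nodes", call. = FALSE)
  }
  d <- node_degrees(net)
  sum(max(d) - d) / ((n - 1) * (n - 2))
}

reciprocity_counts <- function(net) {
  resp <- net$nodes$member_id[net$nodes$responded]
  t <- net$ties
  assess <- t$from %in% resp & t$to %in% resp
  t <- t[assess, , drop = FALSE]
  if (nrow(t) == 0L) return(list(n_assessable = 0L, n_reciprocated = 0L))
  fwd <- paste(t$from, t$to, sep = "\r")
  rev <- paste(t$to, t$from, sep = "\r")
  list(n_assessable = nrow(t), n_reciprocated = sum(fwd %in% rev))
}

#' Reciprocity of a directed nomination network
#'
#' Fraction of directed ties between two respondents whose reverse tie also
#' exists. Ties pointing at non-respondents are unassessable (the reverse
#' nomination could not be observed) and are excluded from numerator and
#' denominator. Returns `NA` when no assessable tie exists.
#'
#' @param net A `praxnet_directed` network.
#' @return Fraction in \[0, 1\], or `NA_real_` when undefined.
#' @export
network_reciprocity <- function(net) {
  stopifnot(inherits(net, "praxnet_directed"))
  r <- reciprocity_counts(net)
  if (r$n_assessable == 0L) return(NA_real_)
  r$n_reciprocated / r$n_assessable
}

#' Assemble the metric record of one practice-condition network
#'
#' Bundles the four network properties — number of connections (undirected
#' edge count), density, Freeman degree centralization, and reciprocity of
#' the underlying directed network — into a one-row data frame.
#'
#' @param directed A `praxnet_directed` network.
#' @param undirected The matching `praxnet_undirected` network (same practice
#'   and condition).
#' @return One-row data frame: `practice_id`, `condition`, `n_nodes`,
#'   `n_edges`, `density`, `centralization`, `reciprocity` (`NA` when
#'   undefined).
#' @export
metrics_bundle <- function(directed, undirected) {
  stopifnot(inherits(directed, "praxnet_directed"),
            inherits(undirected, "praxnet_undirected"))
  if (!identical(directed$practice_id, undirected$practice_id) ||
      !identical(directed$condition, undirected$condition)) {
    stop("directed and undirected networks must describe the same practice ",
         "and condition", call. = FALSE)
  }
  data.frame(
    practice_id = directed$practice_id,
    condition = directed$condition,
    n_nodes = nrow(undirected$nodes),
    n_edges = nrow(undirected$edges),
    density = network_density(undirected),
    centralization = degree_centralization(undirected),
    reciprocity = network_reciprocity(directed),
    stringsAsFactors = FALSE
  )
}

#' Per-network metrics for all included practices of a cohort
#'
#' Applies the inclusion filter, builds the directed and symmetrized network
#' for every included practice and condition, and stacks the
#' [metrics_bundle()] rows.
#'
#' @param coh A validated [cohort()].
#' @param rule Symmetrization rule passed to [symmetrize()].
#' @return Data frame of metric rows, 3 per included practice, ordered by
#'   practice then condition (DM, CHD, CHF).
#' @export
cohort_metrics <- function(coh, rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  dec <- apply_inclusion_filter(coh)
  prs <- coh$practices[dec$included]
  rows <- list()
  for (pr in prs) {
    for (cn in CONDITIONS) {
      dn <- build_directed_network(pr, cn)
      un <- symmetrize(dn, rule = rule)
      rows[[length(rows) + 1L]] <- metrics_bundle(dn, un)
    }
  }
  if (!length(rows)) {
    return(data.frame(practice_id = character(0), condition = character(0),
                      n_nodes = integer(0), n_edges = integer(0),
                      density = numeric(0), centralization = numeric(0),
                      reciprocity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an undirected practice network as GraphML
#'
#' Writes the network with node attributes `role` and `responded` so it can
#' be laid out and rendered in external tools.
#'
#' @param net A `praxnet_undirected` or `praxnet_directed` network.
#' @param path Output file path (.graphml).
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(net, path) {
  if (inherits(net, "praxnet_undirected")) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
  } else if (inherits(net, "praxnet_directed")) {
    g <- igraph::graph_from_data_frame(net$ties, directed = TRUE,
                                       vertices = net$nodes)
  } else {
    stop("not a praxnet network object", call. = FALSE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
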