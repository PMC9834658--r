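#' Highest threshold keeping the IBS graph connected
#'
#' The largest value t such that the graph with an edge for every pair with
#' IBS >= t is connected. This is the bottleneck (minimum edge weight) of a
#' maximum spanning tree of the complete IBS graph, computed exactly.
#'
#' @param ibs an [ibs_matrix()].
#' @param node_subset optional character vector of sample ids to restrict to.
#' @return The threshold (a single IBS value present in the matrix).
#' @export
connectivity_threshold <- function(ibs, node_subset = NULL) {
  ids <- if (is.null(node_subset)) ibs$samples else node_subset
  if (length(ids) < 2) {
    stop("need at least two nodes")
  }
  m <- ibs$ibs[ids, ids, drop = FALSE]
  if (anyNA(m[upper.tri(m)])) {
    stop("missing IBS entries within the node subset")
  }
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
  min(igraph::E(mst)$weight)
}

#' Build a thresholded similarity network
#'
#' Nodes are all samples of the IBS matrix (or the subset); edges are exactly
#' the pairs whose IBS satisfies the rule (`>=` or `>`) against the
#' threshold, weighted by IBS. Isolated nodes are retained.
#'
#' @param ibs an [ibs_matrix()].
#' @param threshold edge-inclusion threshold between 0 and 1.
#' @param rule `"ge"` (default, IBS >= threshold) or `"gt"` (strictly above).
#' @param node_subset optional character vector of sample ids.
#' @return An object of class `similarity_network`: list with `graph` (an
#'   igraph), `threshold`, `rule`.
#' @export
build_network <- function(ibs, threshold, rule = c("ge", "gt"),
                          node_subset = NULL) {
  rule <- match.arg(rule)
  stopifnot(threshold >= 0, threshold <= 1)
  ids <- if (is.null(node_subset)) ibs$samples else node_subset
  m <- ibs$ibs[ids, ids, drop = FALSE]
  keep <- if (rule == "ge") m >= threshold else m > threshold
  keep[is.na(keep)] <- FALSE
  sel <- which(keep & upper.tri(m), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(sel) > 0) {
    g <- igraph::add_edges(g, rbind(sel[, 1], sel[, 2]),
                           weight = m[sel])
  }
  structure(list(graph = g, threshold = threshold, rule = rule),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges (IBS %s %.4g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (x$rule == "ge") ">=" else ">", x$threshold))
  invisible(x)
}

#' Summarize a similarity network
#'
#' Betweenness centrality uses unweighted shortest paths (every edge counts
#' 1), excludes endpoints, and is normalized by `(n-1)(n-2)/2`, computed on
#' the full graph. The diameter is the largest unweighted shortest-path
#' distance within the largest connected component (`NA` for a single-node
#' component).
#'
#' @param net a [build_network()] result.
#' @param top_k how many top-betweenness nodes to list.
#' @return An object of class `network_summary`: list with `n_nodes`,
#'   `n_edges`, `average_degree` (2E/N), `diameter`, `betweenness` (tibble
#'   `id`, `betweenness` sorted descending, ties by id), `top` (first
#'   `top_k` rows), `largest_component` (node ids).
#' @export
summarize_network <- function(net, top_k = 5) {
  stopifnot(inherits(net, "similarity_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0) {
    stop("empty network")
  }
  e <- igraph::ecount(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = TRUE)
  bt <- tibble::tibble(id = igraph::V(g)$name, betweenness = as.numeric(btw))
  bt <- dplyr::arrange(bt, dplyr::desc(.data$betweenness), .data$id)

  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  comp_ids <- igraph::V(g)$name[comp$membership == big]
  diam <- if (length(comp_ids) < 2) {
    NA_real_
  } else {
    sub <- igraph::induced_subgraph(g, comp_ids)
    as.numeric(igraph::diameter(sub, directed = FALSE, weights = NA))
  }
  structure(list(
    n_nodes = n,
    n_edges = e,
    average_degree = 2 * e / n,
    diameter = diam,
    betweenness = bt,
    top = utils::head(bt, top_k),
    largest_component = comp_ids
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d nodes, %d edges, average degree %.3f, diameter %s\n",
              x$n_nodes, x$n_edges, x$average_degree,
              ifelse(is.na(x$diameter), "NA", format(x$diameter))))
  cat("  top betweenness:\n")
  top <- utils::head(x$top, 5)
  cat(paste0("    ", top$id, ": ", sprintf("%.3f", top$betweenness),
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
#' @rdname tidiers
tidy.network_summary <- function(x, ...) x$betweenness

#' @export
#' @rdname tidiers
glance.network_summary <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes, n_edges = x$n_edges,
    average_degree = x$average_degree, diameter = x$diameter,
    max_betweenness = if (nrow(x$betweenness)) x$betweenness$betweenness[1] else NA_real_,
    largest_component_size = length(x$largest_component)
  )
}

#' Remove the top-betweenness hubs and re-analyse
#'
#' Removes the `k` nodes of highest betweenness centrality (ties broken by
#' sample id), then summarizes the largest connected component of the
#' remaining graph. This probes the "spoked wheel" topology that heavy use of
#' one sire induces: deleting the hub fragments the network and exposes the
#' structure behind it.
#'
#' @param net a [build_network()] result.
#' @param k number of hubs to remove (default 1), `k < n_nodes`.
#' @param top_k how many top-betweenness nodes to report afterwards.
#' @return A list with `removed` (ids), `before` and `after`
#'   ([summarize_network()] objects; `after` is restricted to the largest
#'   remaining component).
#' @export
hub_removal_analysis <- function(net, k = 1, top_k = 5) {
  stopifnot(inherits(net, "similarity_network"))
  n <- igraph::vcount(net$graph)
  if (k >= n) {
    stop("k must be smaller than the number of nodes")
  }
  before <- summarize_network(net, top_k = top_k)
  removed <- before$betweenness$id[seq_len(k)]
  g2 <- igraph::delete_vertices(net$graph, removed)
  comp <- igraph::components(g2)
  keep <- igraph::V(g2)$name[comp$membership == which.max(comp$csize)]
  sub <- igraph::induced_subgraph(g2, keep)
  after_net <- structure(list(graph = sub, threshold = net$threshold,
                              rule = net$rule),
                         class = "similarity_network")
  list(removed = removed, before = before,
       after = summarize_network(after_net, top_k = top_k))
}

#' Nearest-rank percentile
#'
#' The smallest sorted value whose rank is at least `ceiling(p/100 * n)`.
#' Used for the edge-weight highlight cut, so a constant sample returns that
#' constant.
#'
#' @param x numeric vector.
#' @param p percentile in (0, 100].
#' @return A single value of `x`.
#' @export
nearest_rank_percentile <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 100)
  xs <- sort(x)
  xs[max(1L, ceiling(p / 100 * length(xs)))]
}

#' Export a similarity network to GraphML
#'
#' Nodes carry their betweenness centrality; edges carry the IBS weight and a
#' `highlight` flag marking edges at or above the given nearest-rank
#' percentile of the retained edge weights (the convention used to draw the
#' strongest relationships as thick lines).
#'
#' @param net a [build_network()] result.
#' @param path output `.graphml` path.
#' @param highlight_percentile percentile of retained edge weights at or
#'   above which an edge is highlighted. Default 85.
#' @return Invisibly, the path.
#' @export
export_graph <- function(net, path, highlight_percentile = 85) {
  stopifnot(inherits(net, "similarity_network"))
  g <- net$graph
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = TRUE)
  igraph::V(g)$betweenness <- as.numeric(btw)
  if (igraph::ecount(g) > 0) {
    cut <- nearest_rank_percentile(igraph::E(g)$weight, highlight_percentile)
    igraph::E(g)$highlight <- igraph::E(g)$weight >= cut
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Edge list of a similarity network
#'
#' @param net a [build_network()] result.
#' @param highlight_percentile percentile for the `highlight` flag.
#' @return A tibble `id1`, `id2`, `ibs`, `highlight`.
#' @export
network_edges <- function(net, highlight_percentile = 85) {
  stopifnot(inherits(net, "similarity_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0) {
    return(tibble::tibble(id1 = character(), id2 = character(),
                          ibs = numeric(), highlight = logical()))
  }
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  cut <- nearest_rank_percentile(w, highlight_percentile)
  tibble::tibble(id1 = el[, 1], id2 = el[, 2], ibs = w, highlight = w >= cut)
}

#' Plot a similarity network
#'
#' Fruchterman-Reingold layout; node size scales with betweenness centrality
#' and edges above the highlight percentile are drawn darker and thicker.
#'
#' @param object a [build_network()] result.
#' @param highlight_percentile percentile for thick-edge highlighting.
#' @param seed layout seed.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.similarity_network <- function(object, highlight_percentile = 85,
                                        seed = 1, ...) {
  g <- object$graph
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  xy <- withr_seed(igraph::layout_with_fr(g))
  nodes <- tibble::tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = TRUE)
  nodes$betweenness <- as.numeric(btw)
  edges <- network_edges(object, highlight_percentile)
  edges <- dplyr::left_join(edges, nodes[, c("id", "x", "y")],
                            by = c(id1 = "id"))
  edges <- dplyr::left_join(edges, nodes[, c("id", "x", "y")],
                            by = c(id2 = "id"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend,
                   linewidth = .data$highlight, alpha = .data$highlight),
      colour = "grey20"
    ) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.2, `TRUE` = 0.8),
                                    guide = "none") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 0.9),
                                guide = "none") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$betweenness),
      colour = "firebrick"
    ) +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::theme_void()
}
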