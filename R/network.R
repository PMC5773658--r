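#' Confidence-thresholded induced subnetwork
#'
#' Keeps edges with confidence at or above the threshold (inclusive, as in
#' selecting interactions at high confidence 0.7), induces the subgraph on
#' the requested node set, and computes connected components.  Nodes with
#' no surviving edge are retained as isolated vertices.
#'
#' @param edges An `edge_list` (see [read_edges()]).
#' @param nodes Character vector of node ids to induce on.
#' @param threshold Confidence threshold in `[0, 1]` (default 0.7).
#' @param annotations Optional named character vector of per-node
#'   annotations (e.g. the state transition "K4->K27") carried along.
#' @return Object of class `tf_network`: `graph` (igraph), `nodes`,
#'   `threshold`, `membership` (named component ids), `components`
#'   (list of node-id vectors, largest first), `annotations`.
#' @export
filter_and_induce <- function(edges, nodes, threshold = 0.7,
                              annotations = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  nodes <- unique(as.character(nodes))
  keep <- edges$confidence >= threshold &
    edges$node_a %in% nodes & edges$node_b %in% nodes
  e <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[c("node_a", "node_b", "confidence", "channel")],
    directed = FALSE, vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  membership <- comp$membership
  comps <- split(names(membership), membership)
  comps <- comps[order(-lengths(comps))]
  names(comps) <- NULL
  structure(list(graph = g, nodes = nodes, threshold = threshold,
                 membership = membership, components = comps,
                 annotations = annotations),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  sizes <- lengths(x$components)
  cat(sprintf(
    "tf_network: %d nodes, %d edges (confidence >= %.2f), %d components (largest %d)\n",
    length(x$nodes), igraph::ecount(x$graph), x$threshold,
    length(sizes), if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

# Number of `core` nodes inside the largest component (by that count) of
# the confidence-filtered graph induced on `nodes`.
largest_core_component <- function(edges, nodes, core, threshold) {
  net <- filter_and_induce(edges, nodes, threshold)
  sizes <- vapply(net$components, function(cc) sum(cc %in% core), 0L)
  if (length(sizes)) max(sizes) else 0L
}

#' Greedy seed augmentation of a subnetwork
#'
#' Models the manual step of adding a few supplementary factors to
#' maximize network connectivity: candidates are added one at a time,
#' each step choosing the candidate that most increases the number of
#' original nodes in the largest connected component of the thresholded
#' induced graph.  Ties are broken lexicographically by id; the loop stops
#' at `max_added` additions or when no candidate improves the objective.
#' Greedy search is the documented behaviour; optimality is not claimed.
#'
#' @param net A `tf_network` from [filter_and_induce()].
#' @param candidates Character vector of candidate node ids.
#' @param edges The full `edge_list` (candidate edges need not have been
#'   present when `net` was built).
#' @param max_added Maximum number of candidates to add (default 3).
#' @return A list: `network` (the augmented `tf_network`) and `added`
#'   (candidate ids in addition order).
#' @export
augment_network <- function(net, candidates, edges, max_added = 3L) {
  stopifnot(max_added >= 0)
  core <- net$nodes
  current <- core
  pool <- sort(setdiff(unique(as.character(candidates)), core))
  added <- character()
  best_now <- largest_core_component(edges, current, core, net$threshold)
  while (length(added) < max_added && length(pool)) {
    gains <- vapply(pool, function(cand) {
      largest_core_component(edges, c(current, cand), core, net$threshold)
    }, 0L)
    if (max(gains) <= best_now) break
    pick <- pool[which.max(gains)]  # pool sorted => lexicographic ties
    current <- c(current, pick)
    added <- c(added, pick)
    pool <- setdiff(pool, pick)
    best_now <- max(gains)
  }
  list(network = filter_and_induce(edges, current, net$threshold,
                                   annotations = net$annotations),
       added = added)
}
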