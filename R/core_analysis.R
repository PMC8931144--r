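#' Extract the core network of strongest links
#'
#' Keeps only the strongest fraction of links (by standardized weight;
#' default the strongest 5%) and removes every node not incident to a
#' retained link. The target count is `k = ceiling(fraction * E)`. With
#' `tie_policy = "include_ties"` (default) all edges whose weight equals
#' the k-th largest are retained, so ties at the cutoff never depend on
#' arbitrary edge order; `"strict_count"` retains exactly `k` edges,
#' breaking weight ties lexicographically by (source, target).
#'
#' Because both standardization modes preserve rank order, the extracted
#' core is invariant to the choice of standardization.
#'
#' @param network A standardized network (see [standardize_weights()]).
#' @param fraction Fraction of edges to retain, in (0, 1].
#' @param tie_policy `"include_ties"` (default) or `"strict_count"`.
#' @return The core subgraph, with graph attributes `core_fraction`,
#'   `cutoff_weight`, `n_edges_kept`, `n_edges_total`, `tie_policy` and
#'   `realized_fraction`.
#' @export
extract_core <- function(network, fraction = 0.05,
                         tie_policy = c("include_ties", "strict_count")) {
  tie_policy <- match.arg(tie_policy)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
        fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]", call. = FALSE)
  }
  if (!"std_weight" %in% igraph::edge_attr_names(network)) {
    stop("network has no std_weight: run standardize_weights() first",
         call. = FALSE)
  }
  ne <- igraph::ecount(network)
  if (ne == 0) stop("network has no edges", call. = FALSE)
  w <- igraph::E(network)$std_weight
  k <- ceiling(fraction * ne)
  cutoff <- sort(w, decreasing = TRUE)[k]
  if (tie_policy == "include_ties") {
    keep <- which(w >= cutoff)
  } else {
    ends <- igraph::ends(network, igraph::E(network), names = TRUE)
    ord <- order(-w, ends[, 1], ends[, 2])
    keep <- ord[seq_len(k)]
  }
  core <- igraph::subgraph_from_edges(network, igraph::E(network)[keep],
                                      delete.vertices = TRUE)
  core <- igraph::set_graph_attr(core, "core_fraction", fraction)
  core <- igraph::set_graph_attr(core, "cutoff_weight", cutoff)
  core <- igraph::set_graph_attr(core, "n_edges_kept", length(keep))
  core <- igraph::set_graph_attr(core, "n_edges_total", ne)
  core <- igraph::set_graph_attr(core, "tie_policy", tie_policy)
  core <- igraph::set_graph_attr(core, "realized_fraction",
                                 length(keep) / ne)
  core
}

check_ego <- function(network, ego) {
  if (!ego %in% igraph::V(network)$name) {
    stop("ego node '", ego, "' not present in the network", call. = FALSE)
  }
  cls <- igraph::V(network)$class[match(ego, igraph::V(network)$name)]
  if (!identical(cls, "biophysical")) {
    stop("ego must be biophysical, but '", ego, "' has class '", cls, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Ego network of a biophysical element
#'
#' The induced subgraph on the ego plus every node reachable from it by a
#' directed path of length at most `k`. Reachability follows edge
#' direction out of the ego: a biophysical-to-value edge means the value
#' depends on the element, so `k = 1` captures values directly dependent
#' on the element and `k = 2` adds the values one further dependency step
#' away — the cascading disturbance pathway. Set `mode = "all"` to ignore
#' direction as a sensitivity check.
#'
#' When `std_weight` is present each edge carries a logical `strong`
#' attribute (`std_weight > 0.5`), the display rule for the strongest
#' core connections.
#'
#' @param network A network or core network with a `class` vertex
#'   attribute.
#' @param ego A biophysical node name.
#' @param k Path length (non-negative integer; the analyses use 1 or 2).
#' @param mode `"out"` (directed, default) or `"all"` (undirected).
#' @return The induced subgraph, with graph attributes `ego` and `ego_k`.
#' @export
ego_network <- function(network, ego, k, mode = c("out", "all")) {
  mode <- match.arg(mode)
  check_ego(network, ego)
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, k == round(k))
  nodes <- igraph::ego(network, order = k, nodes = ego, mode = mode)[[1]]
  sub <- igraph::induced_subgraph(network, nodes)
  if ("std_weight" %in% igraph::edge_attr_names(sub)) {
    sub <- igraph::set_edge_attr(sub, "strong",
                                 value = igraph::E(sub)$std_weight > 0.5)
  }
  sub <- igraph::set_graph_attr(sub, "ego", ego)
  igraph::set_graph_attr(sub, "ego_k", as.integer(k))
}

#' Values reachable from a biophysical element
#'
#' The set of value codes reachable from `ego` by a directed path of
#' length at most `k` (excluding the ego itself). `k = 0` returns the
#' empty set; the result is non-decreasing in `k`.
#'
#' @inheritParams ego_network
#' @return Sorted character vector of value codes.
#' @export
reachable_values <- function(network, ego, k, mode = c("out", "all")) {
  mode <- match.arg(mode)
  check_ego(network, ego)
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, k == round(k))
  if (k == 0) return(character(0))
  nodes <- igraph::ego(network, order = k, nodes = ego, mode = mode)[[1]]
  nm <- nodes$name
  cls <- nodes$class
  sort(nm[cls == "value" & nm != ego])
}

#' Direct biophysical support of core values
#'
#' For each value node, the number of distinct biophysical elements with
#' an incoming edge to it (biophysical -> value: the value receives
#' direct support from the element). Values with no biophysical
#' in-neighbours are listed with 0.
#'
#' @param core A core network (or any network with a `class` vertex
#'   attribute).
#' @return A tibble `value`, `n_biophysical`, sorted by descending count
#'   with alphabetical tie-break.
#' @export
direct_biophysical_support <- function(core) {
  nm <- igraph::V(core)$name
  cls <- igraph::V(core)$class
  values <- sort(nm[cls == "value"])
  if (igraph::ecount(core) > 0) {
    ends <- igraph::ends(core, igraph::E(core), names = TRUE)
    src_cls <- cls[match(ends[, 1], nm)]
    tgt_cls <- cls[match(ends[, 2], nm)]
    bv <- unique(ends[src_cls == "biophysical" & tgt_cls == "value", ,
                      drop = FALSE])
    counts <- table(factor(bv[, 2], levels = values))
  } else {
    counts <- table(factor(character(0), levels = values))
  }
  out <- tibble::tibble(value = values,
                        n_biophysical = as.integer(counts[values]))
  dplyr::arrange(out, dplyr::desc(.data$n_biophysical), .data$value)
}

#' Average shortest path length
#'
#' Mean unweighted shortest-path length over all node pairs with a
#' finite path — ordered pairs when `direction = "directed"` (default),
#' unordered pairs when `"undirected"`. Unreachable pairs are counted and
#' reported, never imputed.
#'
#' @param network A network with at least two nodes.
#' @param direction `"directed"` (default) or `"undirected"`.
#' @return A list: `average`, `n_pairs`, `n_finite_pairs`,
#'   `n_unreachable_pairs`, `direction`.
#' @export
average_path_length <- function(network,
                                direction = c("directed", "undirected")) {
  direction <- match.arg(direction)
  n <- igraph::vcount(network)
  if (n < 2) {
    stop("average path length needs at least 2 nodes", call. = FALSE)
  }
  d <- igraph::distances(network,
                         mode = if (direction == "directed") "out" else "all",
                         weights = NA)
  if (direction == "directed") {
    vals <- d[row(d) != col(d)]
  } else {
    vals <- d[upper.tri(d)]
  }
  finite <- is.finite(vals)
  list(
    average = if (any(finite)) mean(vals[finite]) else NaN,
    n_pairs = length(vals),
    n_finite_pairs = sum(finite),
    n_unreachable_pairs = sum(!finite),
    direction = direction
  )
}

#' Ego-network summary table
#'
#' One row per biophysical node of the core: the number of nodes in its
#' ego network at path lengths 1 and 2, and the number of values reached
#' at each path length. Node counts include the ego itself when
#' `include_ego = TRUE` (the default, matching the convention of counting
#' the biophysical node); values-reached counts never include the ego.
#'
#' @param core A core network with at least one biophysical node.
#' @param include_ego Include the ego in the node counts (default
#'   `TRUE`).
#' @param mode Reachability mode, as in [ego_network()].
#' @return A tibble `element`, `k1_nodes`, `k2_nodes`, `k1_values`,
#'   `k2_values`, sorted by descending `k1_nodes` with alphabetical
#'   tie-break.
#' @export
ego_table <- function(core, include_ego = TRUE, mode = c("out", "all")) {
  mode <- match.arg(mode)
  els <- sort(igraph::V(core)$name[igraph::V(core)$class == "biophysical"])
  if (length(els) == 0) {
    stop("core network has no biophysical nodes", call. = FALSE)
  }
  rows <- lapply(els, function(el) {
    n1 <- length(igraph::ego(core, order = 1, nodes = el, mode = mode)[[1]])
    n2 <- length(igraph::ego(core, order = 2, nodes = el, mode = mode)[[1]])
    if (!include_ego) {
      n1 <- n1 - 1L
      n2 <- n2 - 1L
    }
    tibble::tibble(element = el, k1_nodes = as.integer(n1),
                   k2_nodes = as.integer(n2),
                   k1_values = length(reachable_values(core, el, 1,
                                                       mode = mode)),
                   k2_values = length(reachable_values(core, el, 2,
                                                       mode = mode)))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$k1_nodes), .data$element)
}
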