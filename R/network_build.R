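#' Build the directed, weighted biocultural values network
#'
#' The weight of a directed edge (a, b) is the number of segments whose
#' mention set contains the mention a -> b: the frequency with which the
#' two codes were discussed together, with the narrative segment as the
#' unit of co-occurrence. Pairs never mentioned carry no edge.
#'
#' @param corpus A [bcv_corpus][corpus].
#' @param keep_isolated Keep vocabulary codes with no mentions as
#'   isolated nodes (default `FALSE`).
#' @return An [igraph][igraph::igraph-package] directed graph with vertex
#'   attributes `name` and `class` (`"value"`/`"biophysical"`) and edge
#'   attribute `raw_weight` (positive integer count). Counting metadata
#'   is stored as graph attributes.
#' @examples
#' voc <- as_vocabulary(data.frame(
#'   code = c("PTP", "STE", "SEA"), label = c("people", "stewardship", "sea"),
#'   class = c("value", "value", "biophysical")))
#' m <- data.frame(interview_id = "I1", segment_id = c("S1", "S1", "S2"),
#'                 source = c("SEA", "PTP", "SEA"),
#'                 target = c("PTP", "STE", "PTP"))
#' g <- build_network(corpus(m, voc))
#' igraph::E(g)$raw_weight
#' @export
build_network <- function(corpus, keep_isolated = FALSE) {
  stopifnot(inherits(corpus, "bcv_corpus"))
  if (nrow(corpus$mentions) == 0) {
    stop("no co-occurrence data: corpus contains no mentions", call. = FALSE)
  }
  # mentions are already deduplicated per segment (set semantics), so the
  # per-pair row count equals the number of segments containing the pair
  edges <- dplyr::count(corpus$mentions, .data$source, .data$target,
                        name = "raw_weight")
  edges <- dplyr::arrange(edges, .data$source, .data$target)

  cls <- code_class(corpus$vocabulary)
  if (keep_isolated) {
    verts <- tibble::tibble(name = corpus$vocabulary$code,
                            class = corpus$vocabulary$class)
  } else {
    nodes <- sort(unique(c(edges$source, edges$target)))
    verts <- tibble::tibble(name = nodes, class = unname(cls[nodes]))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = verts)
  g <- igraph::set_graph_attr(g, "counting", "segment_cooccurrence")
  g <- igraph::set_graph_attr(g, "n_segments", nrow(corpus$segments))
  g <- igraph::set_graph_attr(g, "n_mentions", nrow(corpus$mentions))
  assert_no_biophysical_edge(g)
  g
}

# invariant asserted on every build: no biophysical -> biophysical edge
assert_no_biophysical_edge <- function(g) {
  if (igraph::ecount(g) == 0) return(invisible(g))
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  cls <- igraph::V(g)$class
  bad <- cls[ends[, 1]] == "biophysical" & cls[ends[, 2]] == "biophysical"
  if (any(bad)) {
    stop("internal error: biophysical-to-biophysical edge in network",
         call. = FALSE)
  }
  invisible(g)
}

#' Build a network from a weighted adjacency matrix
#'
#' Entry point for data shared as an adjacency matrix rather than as
#' coded segments: rows are sources, columns targets, entries the raw
#' co-occurrence counts (0 = no edge). Node classes are supplied
#' alongside; biophysical-to-biophysical entries must be zero.
#'
#' @param mat Square numeric matrix with identical row and column names.
#' @param classes Named character vector mapping every node name to
#'   `"value"` or `"biophysical"`.
#' @return A directed network as from [build_network()].
#' @export
network_from_adjacency <- function(mat, classes) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (is.null(rownames(mat)) ||
        !identical(rownames(mat), colnames(mat))) {
    stop("adjacency matrix needs identical row and column names",
         call. = FALSE)
  }
  missing <- setdiff(rownames(mat), names(classes))
  if (length(missing) > 0) {
    stop("no class given for node: ", missing[1], call. = FALSE)
  }
  if (any(mat < 0) || any(mat != round(mat))) {
    stop("adjacency entries must be non-negative integer counts",
         call. = FALSE)
  }
  idx <- which(mat > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no co-occurrence data: empty matrix",
                           call. = FALSE)
  edges <- tibble::tibble(source = rownames(mat)[idx[, 1]],
                          target = colnames(mat)[idx[, 2]],
                          raw_weight = mat[idx])
  edges <- dplyr::arrange(edges, .data$source, .data$target)
  if (any(edges$source == edges$target)) {
    stop("adjacency matrix has a non-zero diagonal", call. = FALSE)
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = tibble::tibble(name = nodes,
                              class = unname(classes[nodes])))
  g <- igraph::set_graph_attr(g, "counting", "adjacency_matrix")
  assert_no_biophysical_edge(g)
  g
}

#' Standardize edge weights to [0, 1]
#'
#' Adds a `std_weight` edge attribute alongside the raw counts. The
#' default, `divide_by_max`, maps each weight to `raw_weight / max`,
#' giving range (0, 1]: every observed link keeps a positive weight.
#' `min_max` maps to `(w - min) / (max - min)`, range [0, 1]; when all
#' weights are equal every edge maps to 1. Both modes preserve the rank
#' order of weights.
#'
#' @param network A directed network from [build_network()].
#' @param mode `"divide_by_max"` (default) or `"min_max"`.
#' @return The network with edge attribute `std_weight` and graph
#'   attribute `standardization`.
#' @export
standardize_weights <- function(network,
                                mode = c("divide_by_max", "min_max")) {
  mode <- match.arg(mode)
  w <- igraph::E(network)$raw_weight
  if (length(w) == 0) {
    stop("cannot standardize an edgeless network", call. = FALSE)
  }
  std <- switch(mode,
    divide_by_max = w / max(w),
    min_max = if (max(w) == min(w)) rep(1, length(w)) else
      (w - min(w)) / (max(w) - min(w))
  )
  network <- igraph::set_edge_attr(network, "std_weight", value = std)
  igraph::set_graph_attr(network, "standardization", mode)
}

#' Value frequency table
#'
#' How often each value code occurs in the corpus — the most direct
#' indicator of which values are most recurrently associated with the
#' study area. With `unit = "segment"` (default, matching the
#' co-occurrence unit) a value counts once per segment in which it
#' appears at either end of any mention; with `unit = "mention"` every
#' mention endpoint occurrence counts. Relative frequencies are fractions
#' of all value occurrences and sum to 1.
#'
#' @param corpus A [bcv_corpus][corpus].
#' @param unit `"segment"` (default) or `"mention"`.
#' @return A tibble `value`, `count`, `rel_freq`, sorted by descending
#'   count with alphabetical tie-break. All vocabulary values are listed,
#'   including zero-count ones.
#' @export
value_frequencies <- function(corpus, unit = c("segment", "mention")) {
  unit <- match.arg(unit)
  stopifnot(inherits(corpus, "bcv_corpus"))
  cls <- code_class(corpus$vocabulary)
  m <- corpus$mentions
  long <- dplyr::bind_rows(
    tibble::tibble(interview_id = m$interview_id, segment_id = m$segment_id,
                   value = m$source),
    tibble::tibble(interview_id = m$interview_id, segment_id = m$segment_id,
                   value = m$target))
  long <- long[unname(cls[long$value]) == "value", , drop = FALSE]
  if (unit == "segment") {
    long <- dplyr::distinct(long, .data$interview_id, .data$segment_id,
                            .data$value)
  }
  counts <- dplyr::count(long, .data$value, name = "count")
  all_values <- tibble::tibble(value = sort(
    corpus$vocabulary$code[corpus$vocabulary$class == "value"]))
  counts <- dplyr::left_join(all_values, counts, by = "value")
  counts$count[is.na(counts$count)] <- 0L
  total <- sum(counts$count)
  counts$rel_freq <- if (total > 0) counts$count / total else 0
  dplyr::arrange(counts, dplyr::desc(.data$count), .data$value)
}

#' Connectivity summary of the full network
#'
#' Counts, for each value, the number of distinct biophysical elements it
#' is connected to, and for each biophysical element the number of
#' distinct values. "Connected" ignores edge direction: the counts
#' describe associations, not dependencies. Aggregates report the mean
#' number of elements per value, the mean number of values per element,
#' how many elements reach at least `values_threshold` values, how many
#' elements are associated with every value, and how many values reach
#' more than `elements_threshold` elements.
#'
#' @param network A network from [build_network()].
#' @param values_threshold Count elements connected to at least this many
#'   values (default 10).
#' @param elements_threshold Count values connected to more than this
#'   many elements (default 20).
#' @return A `bcv_connectivity` list: `nodes`, a tibble `node`, `class`,
#'   `n_connected`; and `aggregates`, a named list.
#' @export
connectivity_summary <- function(network, values_threshold = 10,
                                 elements_threshold = 20) {
  cls <- igraph::V(network)$class
  names(cls) <- igraph::V(network)$name
  if (igraph::ecount(network) > 0) {
    ends <- igraph::ends(network, igraph::E(network), names = TRUE)
    pairs <- tibble::tibble(a = ends[, 1], b = ends[, 2])
    # undirected cross-class association pairs (value, element)
    cross <- pairs[unname(cls[pairs$a]) != unname(cls[pairs$b]), ,
                   drop = FALSE]
    val_el <- tibble::tibble(
      value = ifelse(unname(cls[cross$a]) == "value", cross$a, cross$b),
      element = ifelse(unname(cls[cross$a]) == "biophysical", cross$a,
                       cross$b))
    val_el <- dplyr::distinct(val_el)
  } else {
    val_el <- tibble::tibble(value = character(), element = character())
  }
  nodes <- tibble::tibble(node = names(cls), class = unname(cls))
  per_value <- dplyr::count(val_el, node = .data$value, name = "n_connected")
  per_element <- dplyr::count(val_el, node = .data$element,
                              name = "n_connected")
  nodes <- dplyr::left_join(nodes, dplyr::bind_rows(per_value, per_element),
                            by = "node")
  nodes$n_connected[is.na(nodes$n_connected)] <- 0L
  nodes <- dplyr::arrange(nodes, .data$class,
                          dplyr::desc(.data$n_connected), .data$node)

  vals <- nodes[nodes$class == "value", , drop = FALSE]
  els <- nodes[nodes$class == "biophysical", , drop = FALSE]
  n_values <- nrow(vals)
  aggregates <- list(
    mean_elements_per_value = mean(vals$n_connected),
    mean_values_per_element = mean(els$n_connected),
    n_elements_with_min_values = sum(els$n_connected >= values_threshold),
    n_elements_connected_to_all_values = sum(els$n_connected == n_values),
    n_values_above_elements_threshold =
      sum(vals$n_connected > elements_threshold),
    values_threshold = values_threshold,
    elements_threshold = elements_threshold
  )
  structure(list(nodes = nodes, aggregates = aggregates),
            class = "bcv_connectivity")
}

#' @export
print.bcv_connectivity <- function(x, ...) {
  a <- x$aggregates
  cat("<bcv_connectivity>\n")
  cat(sprintf("  mean biophysical elements per value: %.2f\n",
              a$mean_elements_per_value))
  cat(sprintf("  mean values per biophysical element: %.2f\n",
              a$mean_values_per_element))
  cat(sprintf("  elements with >= %d values: %d\n", a$values_threshold,
              a$n_elements_with_min_values))
  cat(sprintf("  elements connected to all values: %d\n",
              a$n_elements_connected_to_all_values))
  invisible(x)
}

#' Network exports
#'
#' `write_network_graphml()` writes the network as GraphML (vertex
#' attribute `class`; edge attributes `raw_weight` and, when present,
#' `std_weight`). `as_edge_list()` returns (and `write_edge_list()`
#' writes as CSV) the deterministic edge table
#' `source,target,raw_weight,std_weight`.
#'
#' @param network A network from [build_network()].
#' @param path Output path.
#' @return The path (writers, invisibly) or a tibble (`as_edge_list`).
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
as_edge_list <- function(network) {
  ends <- igraph::ends(network, igraph::E(network), names = TRUE)
  out <- tibble::tibble(
    source = ends[, 1], target = ends[, 2],
    raw_weight = igraph::E(network)$raw_weight,
    std_weight = if ("std_weight" %in%
                       igraph::edge_attr_names(network))
      igraph::E(network)$std_weight else NA_real_)
  dplyr::arrange(out, .data$source, .data$target)
}

#' @rdname write_network_graphml
#' @export
write_edge_list <- function(network, path) {
  readr::write_csv(as_edge_list(network), path, progress = FALSE)
  invisible(path)
}
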