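# Shared fixtures and brute-force oracles. The oracles deliberately use
# plain loops and base R so they stay independent of the package's
# igraph/dplyr implementation paths.

toy_vocab <- function() {
  as_vocabulary(data.frame(
    code = c("PTP", "PTL", "STE", "SEA", "ROCKS"),
    label = c("people to people", "people to location", "stewardship",
              "sea", "rocky shore"),
    class = c("value", "value", "value", "biophysical", "biophysical")))
}

# three-segment example: SEA->PTP appears in all three segments
toy_mentions <- function() {
  data.frame(
    interview_id = "I1",
    segment_id = c("S1", "S1", "S2", "S2", "S3"),
    source = c("SEA", "PTP", "SEA", "SEA", "SEA"),
    target = c("PTP", "STE", "PTP", "PTL", "PTP"))
}

toy_corpus <- function() corpus(toy_mentions(), toy_vocab())

# brute-force co-occurrence counts: nested loop over segments and the
# ordered pairs mentioned in each (set semantics within a segment)
oracle_cooccurrence <- function(mentions) {
  counts <- new.env(parent = emptyenv())
  segs <- unique(paste(mentions$interview_id, mentions$segment_id,
                       sep = "\r"))
  for (s in segs) {
    rows <- which(paste(mentions$interview_id, mentions$segment_id,
                        sep = "\r") == s)
    pairs <- unique(paste(mentions$source[rows], mentions$target[rows],
                          sep = "\r"))
    for (p in pairs) {
      counts[[p]] <- (if (is.null(counts[[p]])) 0L else counts[[p]]) + 1L
    }
  }
  keys <- ls(counts)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    source = vapply(parts, `[`, "", 1),
    target = vapply(parts, `[`, "", 2),
    count = vapply(keys, function(k) counts[[k]], integer(1)),
    row.names = NULL)
}

# breadth-first search by hand on an edge table; returns all nodes within
# max_steps of start (start included), following direction unless
# directed = FALSE
oracle_reach <- function(edges, start, max_steps, directed = TRUE) {
  seen <- start
  frontier <- start
  steps <- 0
  while (length(frontier) > 0 && steps < max_steps) {
    nxt <- edges$target[edges$source %in% frontier]
    if (!directed) {
      nxt <- c(nxt, edges$source[edges$target %in% frontier])
    }
    frontier <- setdiff(unique(nxt), seen)
    seen <- c(seen, frontier)
    steps <- steps + 1
  }
  sort(seen)
}

# all-pairs shortest path lengths by repeated BFS; mean over finite
# ordered pairs plus unreachable count
oracle_apl <- function(edges, nodes, directed = TRUE) {
  dists <- c()
  unreachable <- 0L
  for (a in nodes) {
    depth <- stats::setNames(rep(Inf, length(nodes)), nodes)
    depth[a] <- 0
    frontier <- a
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- edges$target[edges$source %in% frontier]
      if (!directed) nxt <- c(nxt, edges$source[edges$target %in% frontier])
      nxt <- unique(nxt[is.infinite(depth[nxt])])
      depth[nxt] <- d
      frontier <- nxt
    }
    others <- depth[names(depth) != a]
    dists <- c(dists, others[is.finite(others)])
    unreachable <- unreachable + sum(is.infinite(others))
  }
  if (!directed) {
    # every unordered pair was counted twice, symmetrically
    return(list(average = mean(dists), n_unreachable = unreachable / 2L))
  }
  list(average = mean(dists), n_unreachable = unreachable)
}

# random valid corpus over a small vocabulary (3 values, 3 elements)
random_corpus <- function(n_segments = NULL) {
  voc <- as_vocabulary(data.frame(
    code = c("A", "B", "C", "X", "Y", "Z"),
    label = paste("code", c("A", "B", "C", "X", "Y", "Z")),
    class = rep(c("value", "biophysical"), each = 3)))
  values <- c("A", "B", "C")
  elements <- c("X", "Y", "Z")
  vv <- expand.grid(source = values, target = values,
                    stringsAsFactors = FALSE)
  vv <- vv[vv$source != vv$target, ]
  bv <- expand.grid(source = elements, target = values,
                    stringsAsFactors = FALSE)
  pairs <- rbind(vv, bv)
  if (is.null(n_segments)) n_segments <- sample(1:20, 1)
  mentions <- do.call(rbind, lapply(seq_len(n_segments), function(s) {
    n <- sample(1:6, 1)
    idx <- sample(nrow(pairs), n, replace = FALSE)
    data.frame(interview_id = sprintf("I%d", 1 + s %% 4),
               segment_id = sprintf("S%03d", s),
               source = pairs$source[idx], target = pairs$target[idx])
  }))
  corpus(mentions, voc)
}

# random directed graph with a 'class' vertex attribute; node n1 is the
# single biophysical node so no biophysical-biophysical edge can exist
random_digraph <- function(n_nodes = NULL, p = 0.2) {
  if (is.null(n_nodes)) n_nodes <- sample(4:15, 1)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  all_pairs <- expand.grid(source = nodes, target = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  keep <- runif(nrow(all_pairs)) < p
  edges <- all_pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = nodes,
                          class = c("biophysical",
                                    rep("value", n_nodes - 1))))
  if (igraph::ecount(g) > 0) {
    w <- sample(1:10, igraph::ecount(g), replace = TRUE)
    g <- igraph::set_edge_attr(g, "raw_weight", value = w)
    g <- igraph::set_edge_attr(g, "std_weight", value = w / max(w))
  }
  list(graph = g, edges = edges, nodes = nodes)
}

shipped_vocabulary_path <- function() {
  system.file("extdata", "vocabulary_synthetic.csv", package = "biocnet")
}
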