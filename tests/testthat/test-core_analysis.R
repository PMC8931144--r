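# toy standardized network: SEA->PTP (1.0), PTP->STE (1/3), SEA->PTL (1/3)
toy_network <- function() standardize_weights(build_network(toy_corpus()))

# directed chain SEA -> PTP -> STE
chain_network <- function() {
  m <- data.frame(interview_id = "I1", segment_id = c("S1", "S2"),
                  source = c("SEA", "PTP"), target = c("PTP", "STE"))
  standardize_weights(build_network(corpus(m, toy_vocab())))
}

test_that("core extraction keeps the strongest fraction of links", {
  core <- extract_core(toy_network(), fraction = 0.05)
  # k = ceiling(0.05 * 3) = 1: only the SEA->PTP edge survives
  expect_equal(igraph::ecount(core), 1)
  expect_setequal(igraph::V(core)$name, c("SEA", "PTP"))
  expect_equal(igraph::graph_attr(core, "cutoff_weight"), 1)

  # fraction 1 returns the full network minus isolated nodes
  full <- extract_core(toy_network(), fraction = 1)
  expect_equal(igraph::ecount(full), 3)
  expect_equal(igraph::vcount(full), 4)

  expect_error(extract_core(toy_network(), fraction = 0), "fraction")
  expect_error(extract_core(toy_network(), fraction = 1.2), "fraction")
  expect_error(extract_core(build_network(toy_corpus()), 0.05),
               "std_weight")
})

test_that("boundary ties are included or cut according to the tie policy", {
  # 40 edges; a 3-way tie at the k = 2 boundary
  voc <- as_vocabulary(data.frame(
    code = c(sprintf("V%02d", 1:41), "E1"), label = "x",
    class = c(rep("value", 41), "biophysical")))
  w <- c(10, 9, 9, 9, sample(1:5, 36, replace = TRUE))
  m <- do.call(rbind, lapply(seq_along(w), function(i) {
    data.frame(interview_id = "I1", segment_id = sprintf("S%03d", seq_len(w[i])),
               source = sprintf("V%02d", i), target = sprintf("V%02d", i + 1))
  }))
  g <- standardize_weights(build_network(corpus(m, voc)))
  expect_equal(igraph::ecount(g), 40)
  # fraction 0.05 of 40 edges: k = 2, the second-largest weight is the
  # three-way tied 9
  incl <- extract_core(g, 0.05, tie_policy = "include_ties")
  expect_equal(igraph::ecount(incl), 4)
  strict <- extract_core(g, 0.05, tie_policy = "strict_count")
  expect_equal(igraph::ecount(strict), 2)
  # strict tie-break is lexicographic: V01->V02 (10) then V02->V03 (9)
  expect_setequal(as_edge_list(strict)$source, c("V01", "V02"))
})

test_that("threshold correctness holds for random networks and fractions", {
  withr::local_seed(23)
  for (i in 1:25) {
    g <- random_digraph()$graph
    if (igraph::ecount(g) < 2) next
    for (f in c(0.01, 0.05, 0.5, 1.0)) {
      for (policy in c("include_ties", "strict_count")) {
        core <- extract_core(g, f, tie_policy = policy)
        all_el <- as_edge_list(g)
        all_key <- paste(all_el$source, all_el$target)
        kept_el <- as_edge_list(core)
        kept_key <- paste(kept_el$source, kept_el$target)
        kept_w <- all_el$std_weight[all_key %in% kept_key]
        dropped_w <- all_el$std_weight[!all_key %in% kept_key]
        if (length(dropped_w) > 0) {
          expect_true(min(kept_w) >= max(dropped_w))
        }
        k <- ceiling(f * igraph::ecount(g))
        if (policy == "include_ties") {
          expect_true(igraph::ecount(core) >= k)
        } else {
          expect_equal(igraph::ecount(core), min(k, igraph::ecount(g)))
        }
        # no isolated nodes
        expect_true(all(igraph::degree(core, mode = "all") >= 1))
      }
    }
  }
})

test_that("ego networks follow directed reachability from the ego", {
  g <- chain_network()
  e1 <- ego_network(g, "SEA", 1)
  expect_setequal(igraph::V(e1)$name, c("SEA", "PTP"))
  e2 <- ego_network(g, "SEA", 2)
  expect_setequal(igraph::V(e2)$name, c("SEA", "PTP", "STE"))
  expect_equal(igraph::graph_attr(e2, "ego"), "SEA")

  # strong-edge display flag: both chain weights standardize to 1 > 0.5
  expect_type(igraph::E(e2)$strong, "logical")
  expect_equal(sum(igraph::E(e2)$strong), 2)
})

test_that("strong flag marks std_weight above 0.5", {
  e <- ego_network(toy_network(), "SEA", 2)
  expect_equal(igraph::E(e)$strong, igraph::E(e)$std_weight > 0.5)
})

test_that("ego validation rejects absent or value-class egos", {
  g <- chain_network()
  expect_error(ego_network(g, "NOPE", 1), "not present")
  expect_error(ego_network(g, "PTP", 1), "must be biophysical")
  expect_error(reachable_values(g, "PTP", 1), "must be biophysical")
})

test_that("an ego with no out-edges is alone in its ego network", {
  m <- data.frame(interview_id = "I1", segment_id = "S1",
                  source = c("SEA", "PTP"), target = c("PTP", "STE"))
  # ROCKS has no mentions: keep_isolated retains it as an edge-free ego
  g2 <- standardize_weights(build_network(
    corpus(m, toy_vocab()), keep_isolated = TRUE))
  e <- ego_network(g2, "ROCKS", 1)
  expect_equal(igraph::V(e)$name, "ROCKS")
  expect_equal(igraph::ecount(e), 0)
})

test_that("reachable value sets grow with k and match BFS by hand", {
  g <- chain_network()
  expect_equal(reachable_values(g, "SEA", 0), character(0))
  expect_equal(reachable_values(g, "SEA", 1), "PTP")
  expect_equal(reachable_values(g, "SEA", 2), c("PTP", "STE"))

  # two parallel 2-chains from the ego: union of both branches
  voc <- as_vocabulary(data.frame(
    code = c("A", "B", "C", "D", "X"), label = "x",
    class = c(rep("value", 4), "biophysical")))
  m <- data.frame(interview_id = "I1", segment_id = "S1",
                  source = c("X", "A", "X", "C"),
                  target = c("A", "B", "C", "D"))
  g2 <- standardize_weights(build_network(corpus(m, voc)))
  expect_equal(reachable_values(g2, "X", 2), c("A", "B", "C", "D"))
  expect_equal(reachable_values(g2, "X", 1), c("A", "C"))
})

test_that("ego node sets equal a brute-force BFS oracle on random digraphs", {
  withr::local_seed(29)
  for (i in 1:100) {
    rd <- random_digraph()
    ego <- "n01"  # the biophysical node
    for (k in 0:3) {
      nodes <- igraph::ego(rd$graph, order = k, nodes = ego,
                           mode = "out")[[1]]$name
      expect_equal(sort(nodes), oracle_reach(rd$edges, ego, k))
    }
    e2 <- ego_network(rd$graph, ego, 2)
    expect_equal(sort(igraph::V(e2)$name), oracle_reach(rd$edges, ego, 2))
    # monotonicity in k
    n1 <- igraph::V(ego_network(rd$graph, ego, 1))$name
    expect_true(all(n1 %in% igraph::V(e2)$name))
    expect_true(length(reachable_values(rd$graph, ego, 1)) <=
                  length(reachable_values(rd$graph, ego, 2)))
  }
})

test_that("direct biophysical support counts distinct in-neighbours", {
  voc <- toy_vocab()
  m <- data.frame(interview_id = "I1", segment_id = "S1",
                  source = c("SEA", "ROCKS", "SEA"),
                  target = c("PTP", "PTP", "STE"))
  core <- standardize_weights(build_network(corpus(m, voc)))
  tab <- direct_biophysical_support(core)
  expect_equal(tab$n_biophysical[tab$value == "PTP"], 2)
  expect_equal(tab$n_biophysical[tab$value == "STE"], 1)
  expect_equal(tab$value[1], "PTP")  # sorted by count descending

  # values-only network: all counts zero but every value listed
  vv <- data.frame(interview_id = "I1", segment_id = "S1",
                   source = "PTP", target = "STE")
  tab0 <- direct_biophysical_support(build_network(corpus(vv, voc)))
  expect_equal(tab0$n_biophysical, c(0, 0))
})

test_that("average path length matches hand computation and the oracle", {
  g <- chain_network()
  apl <- average_path_length(g)
  # finite ordered pairs: SEA->PTP 1, SEA->STE 2, PTP->STE 1
  expect_equal(apl$average, 4 / 3)
  expect_equal(apl$n_finite_pairs, 3)
  expect_equal(apl$n_unreachable_pairs, 3)

  # complete directed graph: every pair at distance 1
  full <- igraph::make_full_graph(5, directed = TRUE)
  igraph::V(full)$name <- paste0("v", 1:5)
  igraph::V(full)$class <- "value"
  expect_equal(average_path_length(full)$average, 1)

  expect_error(
    average_path_length(igraph::make_empty_graph(1, directed = TRUE)),
    "at least 2")
})

test_that("average path length equals the all-pairs BFS oracle", {
  withr::local_seed(31)
  for (i in 1:100) {
    rd <- random_digraph()
    if (nrow(rd$edges) == 0) next
    got <- average_path_length(rd$graph)
    want <- oracle_apl(rd$edges, rd$nodes)
    expect_equal(got$average, want$average)
    expect_equal(got$n_unreachable_pairs, want$n_unreachable)
    gu <- average_path_length(rd$graph, "undirected")
    wu <- oracle_apl(rd$edges, rd$nodes, directed = FALSE)
    expect_equal(gu$average, wu$average)
    expect_equal(gu$n_unreachable_pairs, wu$n_unreachable)
  }
})

test_that("directed average path length is invariant under edge reversal", {
  withr::local_seed(37)
  for (i in 1:20) {
    rd <- random_digraph()
    if (nrow(rd$edges) == 0) next
    rev <- igraph::reverse_edges(rd$graph)
    expect_equal(average_path_length(rd$graph)$average,
                 average_path_length(rev)$average)
  }
})

test_that("the ego summary table reports node and value counts at k = 1, 2", {
  core <- chain_network()
  tab <- ego_table(core)
  sea <- tab[tab$element == "SEA", ]
  expect_equal(sea$k1_nodes, 2)  # SEA + PTP, ego included
  expect_equal(sea$k2_nodes, 3)
  expect_equal(sea$k1_values, 1)
  expect_equal(sea$k2_values, 2)

  no_ego <- ego_table(core, include_ego = FALSE)
  expect_equal(no_ego$k1_nodes, tab$k1_nodes - 1L)
  expect_equal(no_ego$k2_nodes, tab$k2_nodes - 1L)
  expect_equal(no_ego$k1_values, tab$k1_values)  # value counts unchanged

  expect_true(all(tab$k2_nodes >= tab$k1_nodes))
  values_only <- standardize_weights(build_network(corpus(
    data.frame(interview_id = "I1", segment_id = "S1",
               source = "PTP", target = "STE"), toy_vocab())))
  expect_error(ego_table(values_only), "no biophysical")
})
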