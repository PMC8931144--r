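---
title: "Biocultural values networks: model, parameters and design choices"
author: "biocnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biocultural values networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocnet)
```

## The model

`biocnet` analyses how a community's cultural values depend on its local
environment, starting from qualitatively coded interviews. The raw unit
is the **coded segment**: a section of interview narrative to which
coders assigned an assemblage of value codes and biophysical element
codes, together with directed **dependency mentions** between them
(`source -> target` meaning the target depends on the source — e.g.
`PETRELS -> HAR`: customary harvesting depends on petrels). Direction is
assigned by the coder during coding; the pipeline never infers it.

From a corpus of coded segments the pipeline builds a **directed,
weighted co-occurrence network**:

* nodes are value codes and biophysical element codes (two node
  classes);
* the weight of edge (a, b) is the number of segments whose mention set
  contains a -> b — the frequency with which the two codes were
  discussed together, with the segment as the counting unit (mentions
  have set semantics within a segment, so repeating an utterance inside
  one segment does not inflate the weight);
* biophysical-to-biophysical edges are excluded by construction: the
  network describes the value system and its environmental supports,
  not ecological interactions among elements.

Weights are standardized to [0, 1], and the **core network** is the
subgraph of the strongest 5% of links together with only the nodes
incident to them. Vulnerability is then read off the core:

* the **ego network** of a biophysical element at path length k is the
  induced subgraph on the element plus every node reachable from it in
  at most k directed steps. k = 1 captures values directly dependent on
  the element; k = 2 adds values one dependency step further — the
  cascading pathway by which loss of access to one element can reach
  values never directly coded against it;
* `direct_biophysical_support()` counts, per core value, the distinct
  biophysical elements with an edge into it (incoming support);
* `average_path_length()` summarizes how quickly a perturbation can
  traverse the core: the mean unweighted shortest-path length over
  ordered node pairs that are connected by a directed path, with the
  number of unreachable pairs reported alongside (never imputed).

### Assumptions

* The segment is the exchangeable unit of evidence. All segments weigh
  equally, including segments from interviews with several
  participants; nothing in the data model records participant counts,
  and down-weighting multi-participant interviews would need exactly
  that information.
* Co-occurrence frequency is a meaningful proxy for the strength of a
  dependency, and coder-assigned direction is reliable.
* Dependency propagates along edge direction: if value v depends on
  element b, and value w depends on v, a perturbation of b can reach w.
  Reachability therefore follows out-edges of the ego. An undirected
  mode (`mode = "all"`) is available as a sensitivity check.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| `mode` | `standardize_weights()` | `divide_by_max` | `std = w / max(w)`, range (0, 1] |
| `fraction` | `extract_core()` | 0.05 | fraction of edges retained, k = ⌈fraction·E⌉ |
| `tie_policy` | `extract_core()` | `include_ties` | keep all edges tied with the k-th largest weight |
| `unit` | `value_frequencies()` | `segment` | a value counts once per segment it appears in |
| `include_ego` | `ego_table()` | `TRUE` | ego counted in the k = 1, 2 node counts |
| `direction` | `average_path_length()` | `directed` | mean over ordered reachable pairs |
| strong-edge cutoff | `ego_network()`, pipeline | 0.5 | `std_weight > 0.5` flags the strongest links for display |

Design choices that were genuinely open, and how they were resolved:

* **Standardization.** "Standardized to 0–1" admits at least two
  readings. The default divides by the maximum weight, so the weakest
  observed link keeps a small positive weight (1/max) rather than being
  mapped to exactly 0, which would misrepresent a real observed
  co-occurrence as absent. Min–max scaling is provided as an
  alternative; in the degenerate all-equal case it maps every edge to 1.
  Core extraction is invariant to the choice because both are
  rank-preserving, and the mode used is recorded in the graph's
  provenance attributes.
* **Tie policy at the threshold.** With integer counts, ties at the 5%
  boundary are common. The default keeps all edges tied with the k-th
  largest weight, so the result never depends on arbitrary edge
  ordering; the realized fraction is recorded. `strict_count` retains
  exactly k edges with a deterministic lexicographic tie-break for
  workflows that need an exact count.
* **Frequency denominator.** Published frequency percentages of this
  kind rarely state their denominator. The default counts a value once
  per segment (consistent with the co-occurrence unit); per-mention
  counting is available, and both report relative frequencies that sum
  to 1.
* **Ego-count conventions.** Summary tables of ego-network sizes are
  ambiguous about whether the focal element itself is counted. Rather
  than resolving the ambiguity, `ego_table()` reports node counts with
  the ego included by default (`include_ego = FALSE` subtracts exactly
  1) *and* values-reached counts separately, which never include the
  ego. Readers can reconcile either convention from one table.
* **Permissive input, conservative analysis.** Value-to-biophysical
  mentions are accepted by the data model (with a warning) but no core
  analysis interprets them; the support direction is fixed as
  biophysical -> value.

## The synthetic-corpus generator

Real corpora of this kind are commonly restricted — interview data
belong to the community that provided them. So the package's testbed is
a generator, `generate_corpus()`, whose defaults emulate the structure
such a study reports:

* 24 interviews; segments per interview ~ 1 + NegBin(mean 11,
  dispersion 5); mentions per segment ~ NegBin(mean 8, dispersion 4)
  (zero-mention segments are legal and exercised);
* a closed vocabulary of 22 values and 41 biophysical elements (the
  shipped `vocabulary_synthetic.csv`);
* admissible mention pairs are value-value and biophysical-value only;
  a mention is value-value with probability 0.55;
* background pairs are sampled from a rank-based power law: a random
  permutation assigns each admissible pair a rank r and sampling weight
  r^(-α), α = 1 by default. This produces the strongly skewed,
  heavy-tailed co-occurrence counts (maxima around 100–130 from roughly
  2000 mentions under the defaults) that motivate thresholding in the
  first place;
* a **planted core**: ten designated pairs are sampled at `multiplier`
  (default 20) times the *mean* background pair weight of their pool.
  Anchoring the multiplier to the pool mean, rather than to the pair's
  own rank-dependent base weight, gives the multiplier one meaning for
  every planted pair — and makes multiplier 1 an exchangeable null in
  which planted pairs behave like ordinary background pairs.

α and the value-value probability were fixed once so that the generated
networks sit in the intended regime — maximum raw weights in the
heavy-tailed range of order 10² and a 20× planted core that thresholding
recovers reliably — and are exposed as configuration knobs
(`background_concentration`, `p_value_value`) rather than constants.

`planted_core_recovery()` closes the loop: over seeded replicates it
generates, builds, standardizes and thresholds, then scores the recall
(planted pairs retained in the core) and precision (core edges that are
planted) of core extraction. Recall rises monotonically with the
multiplier; at 20× the planted pairs are count leaders with high
probability and mean recall exceeds 0.9.

What the generator does **not** emulate: narrative text and coder
behaviour (it samples coded mentions directly), inter-coder
disagreement, participant counts per interview, any clustering of
topics within interviews (segments are i.i.d. given the pair
distribution), and any calibrated correspondence to a real community's
value frequencies. Passing tests on synthetic corpora therefore
demonstrate that the *pipeline machinery* is correct under realistic
statistical structure — not that any substantive conclusion about a real
community would be reproduced.

## Numerical and degenerate-case choices

* All orderings are deterministic: tables sort by descending count with
  alphabetical tie-breaks; corpus files are written sorted by
  (interview, segment, source, target); re-running the pipeline on
  identical inputs reproduces byte-identical outputs.
* Relative frequencies are exact ratios of integer counts; tests check
  they sum to 1 within 1e-12.
* `extract_core()` on an edgeless network, `standardize_weights()` on
  an edgeless network, `average_path_length()` on fewer than 2 nodes,
  and `ego_table()` on a core without biophysical nodes are errors, not
  silent empties.
* `reachable_values(..., k = 0)` is the empty set; ego networks at
  k = 0 contain only the ego.
* Unreachable pairs never enter the path-length mean; their count is a
  first-class output.
* Duplicate mention rows collapse with a warning that reports how many
  were collapsed; unknown codes are reported with the offending row
  number.

## Problem sizes used by the test suite

Property-style tests run the implementation against independent
brute-force oracles (hand-rolled loops and breadth-first search) on 100
random corpora of at most 20 segments over 6 codes, and 100 random
digraphs of at most 15 nodes; threshold correctness is checked across
fractions {0.01, 0.05, 0.5, 1} under both tie policies; planted-core
recovery runs 20 seeded replicates at the default configuration
(~2000 mentions each) plus a 3-replicate multiplier sweep over
{1, 5, 20, 100}. These sizes keep the full suite under a minute on a
single CPU while leaving the oracle comparisons exact, not sampled.

## Known limitations

* Co-occurrence is evidence of association, not a causal dependency
  estimate; the dependency reading rests entirely on the coders'
  directed assignments.
* The 5% threshold is a conventional backbone choice, not a
  significance filter; no null-model correction of co-occurrence counts
  is attempted (deliberately out of scope).
* k-step reachability treats all paths as equally conductive;
  there is no weighted spreading or percolation model.
* The average path length is unweighted and reported only over
  reachable pairs; on sparse cores with many unreachable pairs it
  summarizes the connected portion only, which is why the unreachable
  count is always reported next to it.
* With a single-linkage-style threshold on heavily tied integer
  weights, `include_ties` can retain noticeably more than 5% of edges
  on small networks; the realized fraction is recorded in the core's
  metadata.
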