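#' Default planted core pairs
#'
#' Ten dependency pairs, oversampled twenty-fold, that seed the intended
#' core of the default synthetic corpus: strong support links from the
#' sea, petrels and land birds into harvesting, place- and
#' people-connection and governance values, plus strong value-value
#' dependencies among the governance cluster.
#'
#' @return A tibble `source`, `target`, `multiplier`.
#' @export
default_planted_pairs <- function() {
  tibble::tibble(
    source = c("PETRELS", "SEA", "SEA", "LANDBIRDS", "SEA",
               "PRE", "PTP", "PTL", "GOV", "PTP"),
    target = c("HAR", "PTL", "PTP", "GOV", "STE",
               "STE", "PTL", "PTA", "STE", "STE"),
    multiplier = rep(20, 10)
  )
}

#' Configuration for the synthetic corpus generator
#'
#' Defines the study conditions the generator emulates: a small interview
#' corpus (24 interviews by default) over a closed vocabulary of 22 value
#' codes and 41 biophysical element codes, with heavy-tailed
#' co-occurrence counts and a small planted set of very strong links.
#' Segment and mention counts are drawn from negative binomial
#' distributions; admissible mention pairs (value-value and
#' biophysical-value only) are sampled from a rank-based power-law
#' ("Zipf-like") distribution whose exponent is
#' `background_concentration`. Planted pairs are sampled at `multiplier`
#' times the mean background pair weight of their pool, so the multiplier
#' has the same meaning for every planted pair regardless of where the
#' pair falls in the background ranking.
#'
#' @param n_values,n_biophysical Vocabulary sizes (defaults 22 and 41;
#'   with these defaults and no `vocabulary`, the shipped synthetic
#'   vocabulary is used, otherwise codes `VAL01...`/`ELEM01...` are
#'   generated).
#' @param n_interviews Number of interviews (default 24).
#' @param segments_per_interview,mentions_per_segment Lists with `mean`
#'   and `dispersion` (negative binomial size). Segments per interview
#'   are truncated at 1; mention counts may be 0 (a segment with no coded
#'   dependency).
#' @param planted_pairs Tibble `source`, `target`, `multiplier`
#'   (multipliers >= 1) defining the intended core.
#' @param background_concentration Power-law exponent for background pair
#'   weights (default 1; larger = heavier tail).
#' @param p_value_value Probability a sampled mention is value-value
#'   rather than biophysical-value (default 0.55).
#' @param seed Random seed.
#' @param vocabulary Optional [bcv_vocabulary][read_vocabulary] to draw
#'   codes from.
#' @return A validated `bcv_synth_config` list.
#' @export
synth_config <- function(n_values = 22, n_biophysical = 41,
                         n_interviews = 24,
                         segments_per_interview = list(mean = 12,
                                                       dispersion = 5),
                         mentions_per_segment = list(mean = 8,
                                                     dispersion = 4),
                         planted_pairs = default_planted_pairs(),
                         background_concentration = 1,
                         p_value_value = 0.55,
                         seed = 1,
                         vocabulary = NULL) {
  counts <- c(n_values = n_values, n_biophysical = n_biophysical,
              n_interviews = n_interviews)
  if (any(!is.finite(counts)) || any(counts < 1) ||
        any(counts != round(counts))) {
    stop("config error: n_values, n_biophysical and n_interviews must be ",
         "positive integers", call. = FALSE)
  }
  for (d in list(segments_per_interview, mentions_per_segment)) {
    if (!is.list(d) || !all(c("mean", "dispersion") %in% names(d)) ||
          d$mean <= 0 || d$dispersion <= 0) {
      stop("config error: count distributions need positive mean and ",
           "dispersion", call. = FALSE)
    }
  }
  if (!is.numeric(p_value_value) || p_value_value < 0 || p_value_value > 1) {
    stop("config error: p_value_value must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(background_concentration) || background_concentration < 0) {
    stop("config error: background_concentration must be >= 0",
         call. = FALSE)
  }
  if (is.null(vocabulary)) {
    if (n_values == 22 && n_biophysical == 41) {
      vocabulary <- read_vocabulary(
        system.file("extdata", "vocabulary_synthetic.csv",
                    package = "biocnet"))
    } else {
      vocabulary <- as_vocabulary(tibble::tibble(
        code = c(sprintf("VAL%02d", seq_len(n_values)),
                 sprintf("ELEM%02d", seq_len(n_biophysical))),
        label = c(sprintf("synthetic value %d", seq_len(n_values)),
                  sprintf("synthetic element %d", seq_len(n_biophysical))),
        class = rep(c("value", "biophysical"),
                    c(n_values, n_biophysical))))
    }
  }
  if (sum(vocabulary$class == "value") != n_values ||
        sum(vocabulary$class == "biophysical") != n_biophysical) {
    stop("config error: vocabulary sizes do not match n_values / ",
         "n_biophysical", call. = FALSE)
  }
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble::tibble(source = character(),
                                    target = character(),
                                    multiplier = numeric())
  }
  planted_pairs <- tibble::as_tibble(planted_pairs)
  if (nrow(planted_pairs) > 0) {
    if (!all(c("source", "target", "multiplier") %in%
               names(planted_pairs))) {
      stop("config error: planted_pairs needs columns source, target, ",
           "multiplier", call. = FALSE)
    }
    if (any(planted_pairs$multiplier < 1)) {
      stop("config error: planted multipliers must be >= 1", call. = FALSE)
    }
    cls <- code_class(vocabulary)
    s <- unname(cls[planted_pairs$source])
    t <- unname(cls[planted_pairs$target])
    if (any(is.na(s)) || any(is.na(t))) {
      bad <- c(planted_pairs$source[is.na(s)], planted_pairs$target[is.na(t)])
      stop("config error: planted pair code not in vocabulary: ", bad[1],
           call. = FALSE)
    }
    if (any(t != "value") || any(planted_pairs$source ==
                                   planted_pairs$target)) {
      stop("config error: planted pairs must be value-value or ",
           "biophysical-value, source != target", call. = FALSE)
    }
  }
  structure(
    list(n_values = as.integer(n_values),
         n_biophysical = as.integer(n_biophysical),
         n_interviews = as.integer(n_interviews),
         segments_per_interview = segments_per_interview,
         mentions_per_segment = mentions_per_segment,
         planted_pairs = planted_pairs,
         background_concentration = background_concentration,
         p_value_value = p_value_value,
         seed = as.integer(seed),
         vocabulary = vocabulary),
    class = "bcv_synth_config")
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file mirroring the [synth_config()] fields
#'   (`planted_pairs` as a list of `{source, target, multiplier}`).
#' @param seed Optional seed overriding the file's value.
#' @return A `bcv_synth_config`.
#' @export
read_synth_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    stop("config file does not exist: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_values", "n_biophysical", "n_interviews",
              "background_concentration", "p_value_value", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  for (f in c("segments_per_interview", "mentions_per_segment")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$planted_pairs)) {
    args$planted_pairs <- dplyr::bind_rows(lapply(y$planted_pairs,
                                                  tibble::as_tibble))
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(synth_config, args)
}

# admissible ordered pairs of one pool, with deterministic base weights:
# a random permutation assigns power-law ranks; planted pairs get
# multiplier x mean background weight
pool_pairs <- function(sources, targets, alpha, planted, no_self = FALSE) {
  pairs <- expand.grid(source = sources, target = targets,
                       stringsAsFactors = FALSE)
  if (no_self) pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  n <- nrow(pairs)
  rank <- sample.int(n)
  w <- rank^(-alpha)
  key <- paste(pairs$source, pairs$target, sep = "\r")
  if (nrow(planted) > 0) {
    pkey <- paste(planted$source, planted$target, sep = "\r")
    idx <- match(pkey, key)
    idx_ok <- idx[!is.na(idx)]
    base_mean <- mean(w)
    w[idx_ok] <- planted$multiplier[!is.na(idx)] * base_mean
  }
  list(pairs = pairs, w = w)
}

#' Generate a synthetic coded corpus with a planted core
#'
#' Draws a corpus under the configured study conditions and returns it
#' together with the ground truth needed to score core recovery: the
#' planted pairs and the realized per-pair segment counts (which equal
#' the raw weights [build_network()] produces on the emitted corpus).
#' Identical configurations (including the seed) yield identical corpora.
#'
#' @param config A [synth_config()].
#' @return A list: `corpus` (a [bcv_corpus][corpus]) and `truth` (list
#'   with `planted` and `realized_counts`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "bcv_synth_config"))
  voc <- config$vocabulary
  values <- sort(voc$code[voc$class == "value"])
  elements <- sort(voc$code[voc$class == "biophysical"])
  cls <- code_class(voc)
  planted <- config$planted_pairs
  p_vv <- if (nrow(planted) > 0)
    planted[unname(cls[planted$source]) == "value", , drop = FALSE]
  else planted
  p_bv <- if (nrow(planted) > 0)
    planted[unname(cls[planted$source]) == "biophysical", , drop = FALSE]
  else planted

  withr::with_seed(config$seed, {
    vv <- pool_pairs(values, values, config$background_concentration,
                     p_vv, no_self = TRUE)
    bv <- pool_pairs(elements, values, config$background_concentration,
                     p_bv)

    spi <- config$segments_per_interview
    n_seg <- 1L + rnbinom(config$n_interviews,
                          mu = max(spi$mean - 1, 0.01),
                          size = spi$dispersion)
    interview_id <- rep(sprintf("I%02d", seq_len(config$n_interviews)),
                        n_seg)
    segment_id <- unlist(lapply(n_seg, function(k) sprintf("S%03d",
                                                           seq_len(k))),
                         use.names = FALSE)
    manifest <- tibble::tibble(interview_id = interview_id,
                               segment_id = segment_id)

    mps <- config$mentions_per_segment
    n_men <- rnbinom(nrow(manifest), mu = mps$mean, size = mps$dispersion)
    seg_idx <- rep(seq_len(nrow(manifest)), n_men)
    n_total <- length(seg_idx)
    from_vv <- runif(n_total) < config$p_value_value
    pick <- integer(n_total)
    if (any(from_vv)) {
      pick[from_vv] <- sample.int(nrow(vv$pairs), sum(from_vv),
                                  replace = TRUE, prob = vv$w)
    }
    if (any(!from_vv)) {
      pick[!from_vv] <- sample.int(nrow(bv$pairs), sum(!from_vv),
                                   replace = TRUE, prob = bv$w)
    }
    mentions <- tibble::tibble(
      interview_id = manifest$interview_id[seg_idx],
      segment_id = manifest$segment_id[seg_idx],
      source = ifelse(from_vv, vv$pairs$source[pick], bv$pairs$source[pick]),
      target = ifelse(from_vv, vv$pairs$target[pick], bv$pairs$target[pick]))
    mentions <- dplyr::distinct(mentions)  # set semantics within a segment
  })

  corp <- corpus(mentions, voc, segments = manifest,
                 metadata = list(generator = "biocnet::generate_corpus",
                                 seed = config$seed))
  realized <- dplyr::arrange(
    dplyr::count(corp$mentions, .data$source, .data$target, name = "count"),
    dplyr::desc(.data$count), .data$source, .data$target)
  list(corpus = corp,
       truth = list(planted = planted, realized_counts = realized))
}

#' Score planted-core recovery over replicates
#'
#' Runs the full pipeline — generate, build, standardize, extract the
#' core — on `n_replicates` corpora drawn with seeds `seed, seed + 1,
#' ...`, and scores how well core extraction recovers the planted pairs:
#' recall is the fraction of planted pairs retained in the core,
#' precision the fraction of core edges that are planted.
#'
#' @param config A [synth_config()] with at least one planted pair.
#' @param n_replicates Number of replicates (>= 1).
#' @param fraction Core fraction passed to [extract_core()] (default
#'   0.05).
#' @return A `bcv_recovery` list: `replicates` (tibble with per-replicate
#'   `seed`, `recall`, `precision`, `n_core_edges`), `mean_recall`,
#'   `mean_precision`.
#' @export
planted_core_recovery <- function(config, n_replicates = 20,
                                  fraction = 0.05) {
  stopifnot(inherits(config, "bcv_synth_config"))
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  if (nrow(config$planted_pairs) == 0) {
    stop("config has no planted pairs to recover", call. = FALSE)
  }
  planted_key <- paste(config$planted_pairs$source,
                       config$planted_pairs$target)
  rows <- lapply(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sim <- generate_corpus(cfg)
    g <- standardize_weights(build_network(sim$corpus))
    core <- extract_core(g, fraction = fraction)
    ends <- igraph::ends(core, igraph::E(core), names = TRUE)
    core_key <- paste(ends[, 1], ends[, 2])
    tibble::tibble(
      replicate = i, seed = cfg$seed,
      recall = mean(planted_key %in% core_key),
      precision = mean(core_key %in% planted_key),
      n_core_edges = length(core_key))
  })
  reps <- dplyr::bind_rows(rows)
  structure(list(replicates = reps,
                 mean_recall = mean(reps$recall),
                 mean_precision = mean(reps$precision)),
            class = "bcv_recovery")
}

#' @export
print.bcv_recovery <- function(x, ...) {
  cat(sprintf(
    "<bcv_recovery> %d replicates: mean recall %.3f, mean precision %.3f\n",
    nrow(x$replicates), x$mean_recall, x$mean_precision))
  invisible(x)
}
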