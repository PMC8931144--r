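#' Pipeline configuration
#'
#' All defaults encode the reference analysis: divide-by-max weight
#' standardization, a 5% core with boundary ties included, directed
#' reachability and path lengths, ego counts including the biophysical
#' node, per-segment frequency counting and a strong-edge display cutoff
#' of 0.5. Every field can be overridden and is recorded in the run
#' manifest.
#'
#' @param standardization `"divide_by_max"` or `"min_max"`.
#' @param core_fraction Fraction of edges kept in the core, in (0, 1].
#' @param tie_policy `"include_ties"` or `"strict_count"`.
#' @param path_direction `"directed"` or `"undirected"`.
#' @param include_ego Logical; include the ego in ego-table node counts.
#' @param frequency_unit `"segment"` or `"mention"`.
#' @param strong_cutoff Standardized weight above which an edge is
#'   flagged strong.
#' @return A validated `bcv_pipeline_config` list.
#' @export
pipeline_config <- function(standardization = "divide_by_max",
                            core_fraction = 0.05,
                            tie_policy = "include_ties",
                            path_direction = "directed",
                            include_ego = TRUE,
                            frequency_unit = "segment",
                            strong_cutoff = 0.5) {
  standardization <- match.arg(standardization,
                               c("divide_by_max", "min_max"))
  tie_policy <- match.arg(tie_policy, c("include_ties", "strict_count"))
  path_direction <- match.arg(path_direction, c("directed", "undirected"))
  frequency_unit <- match.arg(frequency_unit, c("segment", "mention"))
  if (!is.numeric(core_fraction) || core_fraction <= 0 ||
        core_fraction > 1) {
    stop("core_fraction must be in (0, 1]", call. = FALSE)
  }
  stopifnot(is.logical(include_ego), length(include_ego) == 1,
            is.numeric(strong_cutoff))
  structure(list(standardization = standardization,
                 core_fraction = core_fraction,
                 tie_policy = tie_policy,
                 path_direction = path_direction,
                 include_ego = include_ego,
                 frequency_unit = frequency_unit,
                 strong_cutoff = strong_cutoff),
            class = "bcv_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file does not exist: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown pipeline config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, y)
}

#' Validate a corpus file against a vocabulary
#'
#' Unlike [read_corpus()], which stops at the first invalid record, this
#' collects and reports every violation, for use as the `validate`
#' subcommand of the pipeline script.
#'
#' @param corpus_path,vocabulary_path Input files.
#' @param quiet Suppress the printed report.
#' @return A list with `status` (0 valid, 1 invalid, 2 unreadable input)
#'   and `report` (tibble `row`, `severity`, `problem`), invisibly
#'   returned and printed unless `quiet`.
#' @export
cmd_validate <- function(corpus_path, vocabulary_path, quiet = FALSE) {
  say <- function(...) if (!quiet) cat(..., "\n", sep = "")
  vocab <- tryCatch(read_vocabulary(vocabulary_path), error = function(e) e)
  if (inherits(vocab, "error")) {
    say("ERROR reading vocabulary: ", conditionMessage(vocab))
    return(invisible(list(status = 2L, report = NULL)))
  }
  mentions <- tryCatch({
    df <- readr::read_csv(corpus_path,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    required <- c("interview_id", "segment_id", "source", "target")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("corpus file is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    empty <- (is.na(df$source) | df$source == "") &
      (is.na(df$target) | df$target == "")
    df[!empty, required]
  }, error = function(e) e)
  if (inherits(mentions, "error")) {
    say("ERROR reading corpus: ", conditionMessage(mentions))
    return(invisible(list(status = 2L, report = NULL)))
  }
  report <- corpus_violations(mentions, vocab)
  errs <- report[report$severity == "error", , drop = FALSE]
  if (!quiet) {
    if (nrow(report) == 0) {
      say("corpus valid: ", nrow(mentions), " mention rows, no violations")
    } else {
      for (i in seq_len(nrow(report))) {
        say(sprintf("%s row %d: %s", toupper(report$severity[i]),
                    report$row[i], report$problem[i]))
      }
      say(sprintf("%d error(s), %d warning(s)", nrow(errs),
                  nrow(report) - nrow(errs)))
    }
  }
  invisible(list(status = if (nrow(errs) > 0) 1L else 0L, report = report))
}

#' Run the full analysis pipeline
#'
#' Reads a coded corpus, builds and standardizes the network, extracts
#' the core, and writes all outputs to `out_dir`: `network.graphml`,
#' `core.graphml`, `frequencies.csv`, `connectivity.csv`,
#' `support_table.csv`, `ego_table.csv`, one `ego_<element>.graphml` per
#' biophysical core node, `metrics.json` and `manifest.json` (config,
#' package version, input checksums). Outputs are deterministic:
#' re-running on identical inputs reproduces identical files.
#'
#' @param corpus_path,vocabulary_path Input files.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()] (or path to a YAML one).
#' @return `out_dir`, invisibly.
#' @export
cmd_run <- function(corpus_path, vocabulary_path, out_dir,
                    config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "bcv_pipeline_config"))
  vocab <- read_vocabulary(vocabulary_path)
  corp <- read_corpus(corpus_path, vocab)

  g <- build_network(corp)
  g <- standardize_weights(g, mode = config$standardization)
  core <- extract_core(g, fraction = config$core_fraction,
                       tie_policy = config$tie_policy)
  freqs <- value_frequencies(corp, unit = config$frequency_unit)
  conn <- connectivity_summary(g)
  support <- direct_biophysical_support(core)
  etab <- ego_table(core, include_ego = config$include_ego)
  apl <- average_path_length(core, direction = config$path_direction)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_network_graphml(g, p("network.graphml"))
  write_network_graphml(core, p("core.graphml"))
  readr::write_csv(freqs, p("frequencies.csv"), progress = FALSE)
  readr::write_csv(conn$nodes, p("connectivity.csv"), progress = FALSE)
  names(support) <- c("value", "n_biophysical")
  readr::write_csv(support, p("support_table.csv"), progress = FALSE)
  readr::write_csv(etab, p("ego_table.csv"), progress = FALSE)
  core_els <- sort(igraph::V(core)$name[
    igraph::V(core)$class == "biophysical"])
  for (el in core_els) {
    eg <- ego_network(core, el, k = 1)
    write_network_graphml(eg, p(sprintf("ego_%s.graphml", el)))
  }
  metrics <- list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    max_raw_weight = max(igraph::E(g)$raw_weight),
    n_core_nodes = igraph::vcount(core),
    n_core_values = sum(igraph::V(core)$class == "value"),
    n_core_biophysical = sum(igraph::V(core)$class == "biophysical"),
    n_core_edges = igraph::ecount(core),
    cutoff = igraph::graph_attr(core, "cutoff_weight"),
    realized_core_fraction = igraph::graph_attr(core, "realized_fraction"),
    avg_path_length = apl$average,
    n_unreachable_pairs = apl$n_unreachable_pairs,
    connectivity = conn$aggregates
  )
  jsonlite::write_json(metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "biocnet",
    version = as.character(utils::packageVersion("biocnet")),
    config = unclass(config),
    inputs = list(
      corpus = list(path = basename(corpus_path),
                    md5 = unname(tools::md5sum(corpus_path))),
      vocabulary = list(path = basename(vocabulary_path),
                        md5 = unname(tools::md5sum(vocabulary_path)))),
    outputs = sort(c("network.graphml", "core.graphml", "frequencies.csv",
                     "connectivity.csv", "support_table.csv",
                     "ego_table.csv", "metrics.json",
                     sprintf("ego_%s.graphml", core_els))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate a corpus to files
#'
#' Delegates to [generate_corpus()] and writes the corpus (CSV) and the
#' ground truth (JSON: planted pairs, multipliers, realized counts).
#'
#' @param config A [synth_config()] or path to a YAML one.
#' @param out Corpus output path (CSV).
#' @param truth_out Ground-truth output path (JSON); `NULL` to skip.
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, a list with the output paths.
#' @export
cmd_simulate <- function(config, out, truth_out = NULL, seed = NULL) {
  if (is.character(config)) {
    config <- read_synth_config(config, seed = seed)
  } else if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  stopifnot(inherits(config, "bcv_synth_config"))
  sim <- generate_corpus(config)
  write_corpus(sim$corpus, out)
  if (!is.null(truth_out)) {
    jsonlite::write_json(
      list(planted = sim$truth$planted,
           realized_counts = sim$truth$realized_counts,
           seed = config$seed),
      truth_out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(corpus = out, truth = truth_out))
}
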