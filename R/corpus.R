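#' Construct a coded corpus
#'
#' A corpus holds directed dependency mentions grouped into coded
#' segments: one segment is the section of interview narrative to which a
#' coder assigned an assemblage of codes, and is the unit of
#' co-occurrence counting. Mentions have set semantics within a segment —
#' duplicate rows collapse to one, with a warning giving the number
#' collapsed.
#'
#' Direction encodes dependency (`source -> target` means the target
#' depends on the source) and is supplied by the coder, never inferred.
#' Biophysical-to-biophysical mentions are rejected: connections between
#' biophysical nodes are excluded from the network by design.
#' Value-to-biophysical mentions are accepted but flagged with a warning,
#' since the analyses only interpret biophysical-to-value and
#' value-to-value edges.
#'
#' @param mentions A data frame with columns `interview_id`, `segment_id`,
#'   `source`, `target`; one row per dependency mention.
#' @param vocabulary A [bcv_vocabulary][read_vocabulary] resolving every
#'   code.
#' @param segments Optional segment manifest (`interview_id`,
#'   `segment_id`), allowing segments with no mentions; defaults to the
#'   segments present in `mentions`.
#' @param metadata Free-form provenance list.
#' @return A `bcv_corpus` object: list with elements `vocabulary`,
#'   `segments`, `mentions`, `metadata`.
#' @export
corpus <- function(mentions, vocabulary, segments = NULL, metadata = list()) {
  if (!inherits(vocabulary, "bcv_vocabulary")) {
    vocabulary <- as_vocabulary(vocabulary)
  }
  mentions <- tibble::as_tibble(mentions)
  required <- c("interview_id", "segment_id", "source", "target")
  missing <- setdiff(required, names(mentions))
  if (length(missing) > 0) {
    stop("mentions table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mentions <- mentions[, required]
  for (col in required) mentions[[col]] <- as.character(mentions[[col]])

  viol <- corpus_violations(mentions, vocabulary)
  err <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(err) > 0) {
    stop(sprintf("invalid corpus (row %d): %s", err$row[1], err$problem[1]),
         call. = FALSE)
  }

  n_dup <- sum(duplicated(mentions))
  if (n_dup > 0) {
    warning(sprintf(
      "collapsed %d duplicate mention row(s) within segments (set semantics)",
      n_dup), call. = FALSE)
    mentions <- mentions[!duplicated(mentions), , drop = FALSE]
  }

  vb <- viol[viol$severity == "warning", , drop = FALSE]
  if (nrow(vb) > 0) {
    warning(sprintf(
      "%d value-to-biophysical mention(s) accepted but not used by the core analyses (first at row %d)",
      nrow(vb), vb$row[1]), call. = FALSE)
  }

  manifest <- unique(mentions[, c("interview_id", "segment_id")])
  if (!is.null(segments)) {
    segments <- tibble::as_tibble(segments)[, c("interview_id", "segment_id")]
    segments$interview_id <- as.character(segments$interview_id)
    segments$segment_id <- as.character(segments$segment_id)
    if (anyDuplicated(segments) > 0) {
      d <- segments[duplicated(segments), ]
      stop("duplicate (interview_id, segment_id) in segment manifest: (",
           d$interview_id[1], ", ", d$segment_id[1], ")", call. = FALSE)
    }
    orphan <- dplyr::anti_join(manifest, segments,
                               by = c("interview_id", "segment_id"))
    if (nrow(orphan) > 0) {
      stop("mentions reference segment absent from manifest: (",
           orphan$interview_id[1], ", ", orphan$segment_id[1], ")",
           call. = FALSE)
    }
    manifest <- segments
  }
  manifest <- dplyr::arrange(manifest, .data$interview_id, .data$segment_id)
  mentions <- dplyr::arrange(mentions, .data$interview_id, .data$segment_id,
                             .data$source, .data$target)

  structure(
    list(vocabulary = vocabulary, segments = manifest, mentions = mentions,
         metadata = metadata),
    class = "bcv_corpus"
  )
}

# All invariant violations in a mentions table, one row per offence.
# Used both by corpus() (stop at first error) and cmd_validate() (report all).
corpus_violations <- function(mentions, vocabulary) {
  cls <- code_class(vocabulary)
  src_cls <- unname(cls[mentions$source])
  tgt_cls <- unname(cls[mentions$target])
  out <- list()
  add <- function(rows, severity, problem) {
    if (length(rows) > 0) {
      out[[length(out) + 1]] <<- tibble::tibble(
        row = rows, severity = severity,
        problem = problem)
    }
  }
  bad_src <- which(is.na(src_cls))
  add(bad_src, "error",
      sprintf("source code '%s' not in vocabulary", mentions$source[bad_src]))
  bad_tgt <- which(is.na(tgt_cls))
  add(bad_tgt, "error",
      sprintf("target code '%s' not in vocabulary", mentions$target[bad_tgt]))
  self <- which(!is.na(src_cls) & !is.na(tgt_cls) &
                  mentions$source == mentions$target)
  add(self, "error",
      sprintf("self-dependency '%s' -> itself", mentions$source[self]))
  bb <- which(!is.na(src_cls) & !is.na(tgt_cls) &
                src_cls == "biophysical" & tgt_cls == "biophysical")
  add(bb, "error",
      sprintf(
        "biophysical-to-biophysical mention '%s' -> '%s' (connections between biophysical nodes are excluded)",
        mentions$source[bb], mentions$target[bb]))
  vb <- which(!is.na(src_cls) & !is.na(tgt_cls) &
                src_cls == "value" & tgt_cls == "biophysical")
  add(vb, "warning",
      sprintf("value-to-biophysical mention '%s' -> '%s' (accepted, unused by core analyses)",
              mentions$source[vb], mentions$target[vb]))
  if (length(out) == 0) {
    return(tibble::tibble(row = integer(), severity = character(),
                          problem = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row)
}

#' @export
print.bcv_corpus <- function(x, ...) {
  cat(sprintf(
    "<bcv_corpus> %d interviews, %d segments, %d mentions (%d value / %d biophysical codes)\n",
    length(unique(x$segments$interview_id)), nrow(x$segments),
    nrow(x$mentions), sum(x$vocabulary$class == "value"),
    sum(x$vocabulary$class == "biophysical")))
  invisible(x)
}

#' Read a coded corpus from file
#'
#' The long CSV format has columns `interview_id`, `segment_id`,
#' `source`, `target`, one row per mention; a row with empty `source` and
#' `target` declares a segment with no coded dependency (preserved in the
#' segment manifest). The JSON mirror is an array of
#' `{interview_id, segment_id, mentions: [{source, target}, ...]}`.
#'
#' @param path Path to a corpus file.
#' @param vocabulary A [bcv_vocabulary][read_vocabulary]; every code in
#'   the file must resolve in it.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A [bcv_corpus][corpus].
#' @export
read_corpus <- function(path, vocabulary, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) {
    stop("corpus file does not exist: ", path, call. = FALSE)
  }
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    required <- c("interview_id", "segment_id", "source", "target")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("corpus file is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    empty <- (is.na(df$source) | df$source == "") &
      (is.na(df$target) | df$target == "")
    manifest <- unique(df[, c("interview_id", "segment_id")])
    mentions <- df[!empty, required]
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    manifest <- tibble::tibble(
      interview_id = vapply(recs, function(r) as.character(r$interview_id),
                            character(1)),
      segment_id = vapply(recs, function(r) as.character(r$segment_id),
                          character(1)))
    mentions <- dplyr::bind_rows(lapply(recs, function(r) {
      if (length(r$mentions) == 0) return(NULL)
      tibble::tibble(
        interview_id = as.character(r$interview_id),
        segment_id = as.character(r$segment_id),
        source = vapply(r$mentions, function(m) as.character(m$source),
                        character(1)),
        target = vapply(r$mentions, function(m) as.character(m$target),
                        character(1)))
    }))
    if (nrow(mentions) == 0) {
      mentions <- tibble::tibble(interview_id = character(),
                                 segment_id = character(),
                                 source = character(), target = character())
    }
  }
  corpus(mentions, vocabulary, segments = manifest)
}

#' Write a coded corpus to file
#'
#' Rows are emitted in a deterministic order (interview, segment, source,
#' target); segments without mentions are preserved (as an empty-mention
#' row in CSV, an empty `mentions` array in JSON), so that
#' `read_corpus(write_corpus(c))` reproduces `c`'s segments and mentions
#' exactly.
#'
#' @param corpus A [bcv_corpus][corpus].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(corpus, "bcv_corpus"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  m <- dplyr::arrange(corpus$mentions, .data$interview_id, .data$segment_id,
                      .data$source, .data$target)
  empty_segs <- dplyr::anti_join(corpus$segments,
                                 unique(m[, c("interview_id", "segment_id")]),
                                 by = c("interview_id", "segment_id"))
  if (format == "csv") {
    if (nrow(empty_segs) > 0) {
      empty_segs$source <- ""
      empty_segs$target <- ""
      m <- dplyr::arrange(dplyr::bind_rows(m, empty_segs),
                          .data$interview_id, .data$segment_id,
                          .data$source, .data$target)
    }
    readr::write_csv(m, path, progress = FALSE)
  } else {
    segs <- dplyr::arrange(corpus$segments, .data$interview_id,
                           .data$segment_id)
    recs <- lapply(seq_len(nrow(segs)), function(i) {
      mi <- m[m$interview_id == segs$interview_id[i] &
                m$segment_id == segs$segment_id[i], , drop = FALSE]
      list(interview_id = segs$interview_id[i],
           segment_id = segs$segment_id[i],
           mentions = if (nrow(mi) == 0) list() else
             lapply(seq_len(nrow(mi)), function(j) {
               list(source = mi$source[j], target = mi$target[j])
             }))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
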