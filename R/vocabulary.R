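#' Read a code vocabulary
#'
#' A vocabulary is the closed set of codes the coders may assign: cultural
#' value codes (e.g. `PTP`, "people to people") and biophysical element
#' codes (e.g. `SEA`). The two code namespaces must be disjoint and both
#' non-empty.
#'
#' The CSV format has a header row and columns `code`, `label`, `class`
#' (`value` or `biophysical`), plus optional `tier` and `description`.
#' The JSON format mirrors the same records as an array of objects.
#'
#' @param path Path to a vocabulary file.
#' @param format `"auto"` (by file extension), `"csv"` or `"json"`.
#' @return A `bcv_vocabulary`: a tibble with columns `code`, `label`,
#'   `class`, `tier`, `description`.
#' @examples
#' voc <- read_vocabulary(system.file("extdata", "vocabulary_synthetic.csv",
#'                                    package = "biocnet"))
#' table(voc$class)
#' @export
read_vocabulary <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) {
    stop("vocabulary file does not exist: ", path, call. = FALSE)
  }
  df <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    json = tibble::as_tibble(jsonlite::fromJSON(path))
  )
  as_vocabulary(df)
}

#' Coerce and validate a vocabulary table
#'
#' @param df A data frame with columns `code`, `label`, `class` and
#'   optionally `tier`, `description`.
#' @return A validated `bcv_vocabulary` tibble.
#' @export
as_vocabulary <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("code", "label", "class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("vocabulary is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("tier", "description")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df <- df[, c("code", "label", "class", "tier", "description")]
  df$code <- as.character(df$code)
  df$label <- as.character(df$label)
  df$class <- as.character(df$class)

  bad_class <- setdiff(unique(df$class), c("value", "biophysical"))
  if (length(bad_class) > 0) {
    stop("unknown class token(s) in vocabulary: ",
         paste(bad_class, collapse = ", "),
         " (expected 'value' or 'biophysical')", call. = FALSE)
  }
  if (any(is.na(df$code) | df$code == "")) {
    stop("vocabulary contains an empty code", call. = FALSE)
  }
  if (any(is.na(df$label) | df$label == "")) {
    stop("vocabulary label is empty for code: ",
         df$code[which(is.na(df$label) | df$label == "")[1]], call. = FALSE)
  }
  dup <- df$code[duplicated(df$code)]
  if (length(dup) > 0) {
    stop("duplicate vocabulary code: ", dup[1],
         " (codes must be unique across value and biophysical classes)",
         call. = FALSE)
  }
  if (!any(df$class == "value") || !any(df$class == "biophysical")) {
    stop("vocabulary must contain at least one value code and one ",
         "biophysical code", call. = FALSE)
  }
  class(df) <- c("bcv_vocabulary", class(df))
  df
}

#' @export
print.bcv_vocabulary <- function(x, ...) {
  cat(sprintf("<bcv_vocabulary> %d value codes, %d biophysical codes\n",
              sum(x$class == "value"), sum(x$class == "biophysical")))
  NextMethod()
}

# named chr vector code -> class
code_class <- function(vocabulary) {
  stats::setNames(vocabulary$class, vocabulary$code)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json")) "json" else "csv"
}
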