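#' Read and write the long per-window table
#'
#' The individual-level layout is a delimited text table with one row per
#' participant per assessment window: identifier and window columns, the
#' symptom columns (`phq9_total`, `gad7_total`, `item9`,
#' `panic_attacks`), blog activity (`n_posts`, `post_word_counts` as a
#' `;`-separated list) and one numeric column per linguistic feature.
#' Blank cells are missing values.  Unknown columns are preserved as
#' passthrough.  Distinct validation errors are raised for duplicate
#' (participant, window) keys, rows whose feature vector is only
#' partially filled, and non-numeric symptom cells.
#'
#' @param path file path.
#' @param feature_names names of the feature columns; if `NULL`, all
#'   columns matching `feature_regex` are taken as features.
#' @param feature_regex pattern identifying feature columns when
#'   `feature_names` is `NULL`.
#' @param delim field delimiter (default comma).
#' @return `read_individual_data()`: a [new_cohort()] object.
#' @export
read_individual_data <- function(path, feature_names = NULL,
                                 feature_regex = "^feat", delim = ",") {
  raw <- utils::read.csv(path, sep = delim, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("participant_id", "window_index")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    lm_stop("header", paste("missing required columns:",
                            paste(missing_cols, collapse = ", ")))
  if (is.null(feature_names))
    feature_names <- grep(feature_regex, names(raw), value = TRUE)
  if (!length(feature_names))
    lm_stop("feature_names", "no feature columns found")

  num <- function(col, nm, integer = FALSE) {
    if (is.null(col)) return(rep(NA_real_, nrow(raw)))
    col[!nzchar(col)] <- NA_character_
    out <- suppressWarnings(as.numeric(col))
    bad <- is.na(out) & !is.na(col)
    if (any(bad))
      lm_stop(nm, sprintf("non-numeric cell(s), e.g. '%s'", col[bad][1]),
              class = "lingmark_nonnumeric_error")
    if (integer) as.integer(out) else out
  }
  d <- data.frame(participant_id = raw$participant_id,
                  window_index = num(raw$window_index, "window_index", TRUE),
                  phq9_total = num(raw$phq9_total, "phq9_total", TRUE),
                  gad7_total = num(raw$gad7_total, "gad7_total", TRUE),
                  item9 = num(raw$item9, "item9", TRUE),
                  panic_attacks = num(raw$panic_attacks, "panic_attacks", TRUE),
                  stringsAsFactors = FALSE)
  fm <- vapply(feature_names, function(nm) num(raw[[nm]], nm), numeric(nrow(raw)))
  fm <- matrix(fm, nrow = nrow(raw),
               dimnames = list(NULL, feature_names))
  has_feat <- rowSums(!is.na(fm)) > 0
  d$n_posts <- if ("n_posts" %in% names(raw))
    num(raw$n_posts, "n_posts", TRUE) else as.integer(has_feat)
  pwc <- if ("post_word_counts" %in% names(raw)) {
    v <- raw$post_word_counts; v[!nzchar(v)] <- NA_character_; v
  } else rep(NA_character_, nrow(raw))
  d$post_word_counts <- pwc
  d <- cbind(d, as.data.frame(fm))
  passthrough <- setdiff(names(raw), c(names(d), feature_names))
  for (nm in passthrough) d[[nm]] <- raw[[nm]]
  new_cohort(d, feature_names)
}

#' @rdname read_individual_data
#' @param x a `lingmark_cohort`.
#' @return `write_individual_data()`: the path, invisibly.  A JSON
#'   sidecar of the generating config (if attached) is written next to
#'   the table as `<path>.config.json`.
#' @export
write_individual_data <- function(x, path, delim = ",") {
  utils::write.table(x$data, path, sep = delim, na = "", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE)
  cfg <- attr(x, "config")
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write the per-participant mean table
#'
#' The cross-sectional layout holds one row per participant with mean
#' symptom and feature scores over matched windows (see
#' [cross_section()]).
#'
#' @param table data.frame as returned by [cross_section()].
#' @param path file path.
#' @param delim field delimiter.
#' @export
write_mean_data <- function(table, path, delim = ",") {
  utils::write.table(table, path, sep = delim, na = "", row.names = FALSE,
                     col.names = TRUE, quote = TRUE)
  invisible(path)
}

#' @rdname write_mean_data
#' @export
read_mean_data <- function(path, delim = ",") {
  utils::read.csv(path, sep = delim, check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Export an activity summary as JSON
#'
#' @param summary a `lingmark_activity` from [summarize_activity()].
#' @param path output path.
#' @export
write_activity_json <- function(summary, path) {
  jsonlite::write_json(list(per_participant = summary$per_participant,
                            cohort = summary$cohort),
                       path, dataframe = "rows", digits = NA, na = "null")
  invisible(path)
}
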