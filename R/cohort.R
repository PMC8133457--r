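#' Longitudinal blog-and-symptom cohort
#'
#' A `lingmark_cohort` holds one row per participant per fortnightly
#' assessment window: bounded integer symptom totals (PHQ-9 0--27, GAD-7
#' 0--21, PHQ-9 item 9 0--3, panic-attack count), blog activity for the
#' window (number of posts, per-post word counts) and the window-averaged
#' linguistic feature vector.  Missing assessments and windows without
#' blog posts are represented explicitly as `NA`; a feature vector is
#' missing exactly when the window has no posts.
#'
#' @param data data.frame in the long per-window layout.  Required
#'   columns: `participant_id`, `window_index`, `phq9_total`,
#'   `gad7_total`, `item9`, `panic_attacks`, `n_posts`,
#'   `post_word_counts` (a `;`-separated string of per-post word counts),
#'   plus one numeric column per linguistic feature.
#' @param feature_names character vector naming the feature columns, in
#'   order.
#' @param validate check invariants (unique keys, scale bounds,
#'   `phq9_total >= item9`, features missing iff `n_posts == 0`).
#' @return An object of class `lingmark_cohort`: a list with elements
#'   `data` (the long table) and `feature_names`.
#' @export
new_cohort <- function(data, feature_names, validate = TRUE) {
  if (!is.data.frame(data)) lm_stop("data", "must be a data.frame")
  missing_cols <- setdiff(lm_reserved_cols, names(data))
  if (length(missing_cols))
    lm_stop("data", paste("missing required columns:",
                          paste(missing_cols, collapse = ", ")))
  if (!all(feature_names %in% names(data)))
    lm_stop("feature_names", "not all feature columns present in data")
  obj <- structure(list(data = data,
                        feature_names = as.character(feature_names)),
                   class = "lingmark_cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' @rdname new_cohort
#' @param x a `lingmark_cohort`
#' @export
validate_cohort <- function(x) {
  d <- x$data
  key <- paste(d$participant_id, d$window_index, sep = "\r")
  if (anyDuplicated(key))
    lm_stop("participant_id/window_index",
            "duplicate (participant, window) keys",
            class = "lingmark_duplicate_key_error")
  check_scale <- function(v, lo, hi, nm) {
    v <- v[!is.na(v)]
    if (length(v) && (any(v < lo | v > hi) || any(v != round(v))))
      lm_stop(nm, sprintf("values must be integers in %d..%d", lo, hi))
  }
  check_scale(d$phq9_total, 0L, 27L, "phq9_total")
  check_scale(d$gad7_total, 0L, 21L, "gad7_total")
  check_scale(d$item9, 0L, 3L, "item9")
  both <- !is.na(d$phq9_total) & !is.na(d$item9)
  if (any(d$phq9_total[both] < d$item9[both]))
    lm_stop("item9", "item 9 exceeds the PHQ-9 total it belongs to")
  if (any(d$n_posts < 0, na.rm = TRUE))
    lm_stop("n_posts", "post counts must be non-negative")
  fm <- as.matrix(d[, x$feature_names, drop = FALSE])
  n_na <- rowSums(is.na(fm))
  partial <- n_na > 0 & n_na < length(x$feature_names)
  if (any(partial))
    lm_stop("features", "feature vector incomplete in some rows",
            class = "lingmark_feature_mismatch_error")
  all_na <- n_na == length(x$feature_names)
  if (any(all_na != (d$n_posts == 0)))
    lm_stop("features",
            "features must be missing exactly when n_posts is 0")
  invisible(x)
}

#' @export
print.lingmark_cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("<lingmark_cohort> %d participants, %d window records, %d features\n",
              length(unique(d$participant_id)), nrow(d),
              length(x$feature_names)))
  cat(sprintf("  assessments completed: %d;  windows with blog data: %d\n",
              sum(!is.na(d$phq9_total)), sum(d$n_posts > 0)))
  invisible(x)
}

# Feature matrix of a cohort (rows aligned with x$data).
feature_matrix <- function(x) {
  as.matrix(x$data[, x$feature_names, drop = FALSE])
}

#' Average post-level linguistic scores into a window-level vector
#'
#' Windows with more than one blog post carry one LIWC score vector per
#' post; the window-level score is their unweighted element-wise
#' arithmetic mean.  An empty list signals a window without posts and
#' yields `NULL` (the missing-window signal), not an error.
#'
#' @param post_level_scores list of equal-length numeric vectors, one per
#'   post.
#' @return numeric vector, or `NULL` when no posts were made.
#' @export
average_window_features <- function(post_level_scores) {
  if (length(post_level_scores) == 0L) return(NULL)
  lens <- lengths(post_level_scores)
  if (length(unique(lens)) != 1L)
    lm_stop("post_level_scores", "post vectors differ in length",
            class = "lingmark_feature_mismatch_error")
  colMeans(do.call(rbind, post_level_scores))
}

#' Symptom severity bands
#'
#' Total scores on the PHQ-9 (0--27) and GAD-7 (0--21) are classified as
#' nil-minimal (0--4), mild (5--9), moderate (10--14), moderately-severe
#' (15--19) or severe (20 up to the scale maximum).  The bands partition
#' the full scale range.
#'
#' @param total integer vector of scale totals.
#' @param scale `"PHQ9"` or `"GAD7"`.
#' @return `severity_band()`: character vector of band labels.
#'   `severity_bands()`: data.frame of labels and inclusive bounds.
#' @export
severity_band <- function(total, scale = c("PHQ9", "GAD7")) {
  scale <- match.arg(scale)
  bands <- severity_bands(scale)
  max_ok <- bands$upper[nrow(bands)]
  if (any(is.na(total)) || any(total < 0 | total > max_ok) ||
      any(total != round(total)))
    lm_stop("total", sprintf("must be integers in 0..%d for %s", max_ok, scale))
  idx <- findInterval(total, bands$lower)
  bands$label[idx]
}

#' @rdname severity_band
#' @export
severity_bands <- function(scale = c("PHQ9", "GAD7")) {
  scale <- match.arg(scale)
  top <- if (scale == "PHQ9") 27L else 21L
  data.frame(label = c("nil-minimal", "mild", "moderate",
                       "moderately-severe", "severe"),
             lower = c(0L, 5L, 10L, 15L, 20L),
             upper = c(4L, 9L, 14L, 19L, top),
             stringsAsFactors = FALSE)
}

#' Suicidal-ideation flag from PHQ-9 item 9
#'
#' Participants scoring item 9 ("thoughts that you would be better off
#' dead, or of hurting yourself") above 0 -- i.e. reporting such thoughts
#' for more than several days -- are flagged.  The raw 0--3 score is kept
#' as the continuous suicidality target elsewhere.
#'
#' @param item9 integer vector, values in 0..3.
#' @return logical vector.
#' @export
suicidal_flag <- function(item9) {
  if (any(is.na(item9)) || any(item9 < 0 | item9 > 3) ||
      any(item9 != round(item9)))
    lm_stop("item9", "must be integers in 0..3")
  item9 > 0
}

#' Restrict a cohort to the analysable final sample
#'
#' Retains participants with at least one window in which a completed
#' assessment (either symptom scale) and a non-missing feature vector
#' co-occur.  All windows of retained participants are kept; analysis
#' tables built downstream ([cross_section()]) use only matched windows.
#'
#' @param x a `lingmark_cohort`.
#' @param quiet suppress the message reporting removed participants.
#' @return filtered `lingmark_cohort`; attribute `n_removed` counts
#'   dropped participants.
#' @export
filter_final_sample <- function(x, quiet = FALSE) {
  d <- x$data
  matched <- (!is.na(d$phq9_total) | !is.na(d$gad7_total)) & d$n_posts > 0
  keep_ids <- unique(d$participant_id[matched])
  n_removed <- length(unique(d$participant_id)) - length(keep_ids)
  if (!quiet && n_removed > 0)
    message(sprintf("filter_final_sample: removed %d participant(s) with no matched window", n_removed))
  out <- new_cohort(d[d$participant_id %in% keep_ids, , drop = FALSE],
                    x$feature_names, validate = FALSE)
  attr(out, "n_removed") <- n_removed
  out
}

#' Per-participant cross-sectional table of mean scores
#'
#' Averages each participant's linguistic features and symptom scores
#' across assessment windows, using only windows in which a feature
#' vector and the respective assessment co-occur.  This is the
#' between-subject analysis table (one row per participant).
#'
#' @param x a `lingmark_cohort` (typically after [filter_final_sample()]).
#' @return data.frame with columns `participant_id`, `n_windows_used`,
#'   `depression`, `anxiety`, `suicidality` (mean PHQ-9 / GAD-7 / item-9
#'   over matched windows) and one mean column per feature.
#' @export
cross_section <- function(x) {
  d <- x$data
  ids <- unique(d$participant_id)
  if (!length(ids)) lm_stop("cohort", "empty cohort",
                            class = "lingmark_empty_cohort_error")
  fm <- feature_matrix(x)
  has_feat <- d$n_posts > 0
  rows <- lapply(ids, function(id) {
    sel <- d$participant_id == id
    any_assess <- !is.na(d$phq9_total[sel]) | !is.na(d$gad7_total[sel])
    used <- has_feat[sel] & any_assess
    tmeans <- vapply(lm_targets, function(col) {
      w <- has_feat[sel] & !is.na(d[[col]][sel])
      if (any(w)) mean(d[[col]][sel][w]) else NA_real_
    }, numeric(1))
    fmeans <- if (any(used)) colMeans(fm[sel, , drop = FALSE][used, , drop = FALSE])
              else rep(NA_real_, ncol(fm))
    c(n_windows_used = sum(used), tmeans, fmeans)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("n_windows_used", names(lm_targets), x$feature_names)
  cbind(participant_id = ids, out)
}

#' Blog-activity and assessment-completion summary
#'
#' Per-participant totals (assessments completed per scale, total posts,
#' total word count, mean words per post) together with cohort-level
#' mean, sample SD (n - 1), minimum and maximum of each column.
#'
#' @param x a `lingmark_cohort`.
#' @return object of class `lingmark_activity`: list with
#'   `per_participant` and `cohort` data.frames.
#' @export
summarize_activity <- function(x) {
  d <- x$data
  ids <- unique(d$participant_id)
  if (!length(ids)) lm_stop("cohort", "empty cohort",
                            class = "lingmark_empty_cohort_error")
  word_tot <- vapply(strsplit(ifelse(is.na(d$post_word_counts), "",
                                     d$post_word_counts), ";", fixed = TRUE),
                     function(w) sum(as.numeric(w[nzchar(w)])), numeric(1))
  per <- do.call(rbind, lapply(ids, function(id) {
    sel <- d$participant_id == id
    tp <- sum(d$n_posts[sel])
    tw <- sum(word_tot[sel])
    data.frame(participant_id = id,
               phq9_completed = sum(!is.na(d$phq9_total[sel])),
               gad7_completed = sum(!is.na(d$gad7_total[sel])),
               total_posts = tp,
               total_words = tw,
               mean_words_per_post = if (tp > 0) tw / tp else NA_real_)
  }))
  aggregate_activity(per)
}

#' @rdname summarize_activity
#' @param per_participant data.frame of per-participant totals with
#'   columns `phq9_completed`, `gad7_completed`, `total_posts`,
#'   `total_words`, `mean_words_per_post` (e.g. a published activity
#'   table).
#' @export
aggregate_activity <- function(per_participant) {
  cols <- c("phq9_completed", "gad7_completed", "total_posts",
            "total_words", "mean_words_per_post")
  missing_cols <- setdiff(cols, names(per_participant))
  if (length(missing_cols))
    lm_stop("per_participant", paste("missing columns:",
                                     paste(missing_cols, collapse = ", ")))
  stats <- do.call(rbind, lapply(cols, function(cl) {
    v <- per_participant[[cl]]
    v <- v[!is.na(v)]
    data.frame(variable = cl, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v))
  }))
  structure(list(per_participant = per_participant, cohort = stats),
            class = "lingmark_activity")
}

#' @export
print.lingmark_activity <- function(x, ...) {
  cat(sprintf("<lingmark_activity> %d participants\n",
              nrow(x$per_participant)))
  print(x$cohort, row.names = FALSE)
  invisible(x)
}
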