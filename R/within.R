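#' Predicted and observed symptom series for one participant
#'
#' Applies a group-level model to every window of a participant in which
#' both a feature vector and the target assessment are available,
#' returning the original-scale predictions paired with the observed
#' scores.
#'
#' @param model fitted `lingmark_pls`.
#' @param x a `lingmark_cohort`.
#' @param participant_id participant to extract.
#' @param target one of `"depression"`, `"anxiety"`, `"suicidality"`.
#' @return data.frame with `window_index`, `predicted`, `observed`
#'   (possibly zero rows).
#' @export
predict_trajectory <- function(model, x, participant_id,
                               target = c("depression", "anxiety",
                                          "suicidality")) {
  target <- match.arg(target)
  d <- x$data
  sel <- d$participant_id == participant_id
  if (!any(sel)) lm_stop("participant_id", "participant not in cohort")
  col <- lm_targets[[target]]
  use <- sel & d$n_posts > 0 & !is.na(d[[col]])
  if (!any(use))
    return(data.frame(window_index = integer(0), predicted = numeric(0),
                      observed = numeric(0)))
  Xw <- as.matrix(d[use, model$feature_names, drop = FALSE])
  pred <- predict(model, Xw)
  k <- if (target %in% model$target_names) match(target, model$target_names)
       else 1L
  data.frame(window_index = d$window_index[use],
             predicted = as.numeric(pred[, k]),
             observed = as.numeric(d[[col]][use]))
}

#' Within-participant correlation of predicted and observed scores
#'
#' Pearson correlation over a participant's time points (a rank variant
#' is available).  Undefined when fewer than 3 paired points exist or
#' either series is constant; signalled as `NA`, and such participants
#' are excluded from aggregation (clamping would bias the mean Fisher
#' z).
#'
#' @param pred,obs paired numeric series.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation, or `NA` when undefined.
#' @export
per_participant_correlation <- function(pred, obs,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(pred) & !is.na(obs)
  if (sum(ok) < 3L) return(NA_real_)
  pred <- pred[ok]; obs <- obs[ok]
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs, method = method)
}

#' Fisher z transformation
#'
#' `atanh(r)`, approximately variance-stabilizing for correlation
#' coefficients, enabling one-sample t-tests on mean correlations.
#' `|r| = 1` maps to an infinite value; such participants are excluded
#' from aggregation and counted.
#'
#' @param r correlation in \[-1, 1\].
#' @return z value (infinite at the boundary).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) lm_stop("r", "|r| must not exceed 1")
  atanh(r)
}

#' Group-to-individual generalizability analysis
#'
#' Applies a group-level model to each participant's time series,
#' correlates predicted and observed scores over time, Fisher-z
#' transforms the per-participant correlations, and tests the mean z
#' against zero with a one-sample t-test across a sweep of
#' minimum-assessment thresholds.  Under an ergodic regime (the
#' within-subject relation mirrors the between-subject one) the mean z
#' is positive; when group-level structure does not generalise the
#' distribution of z straddles zero.
#'
#' @param model fitted `lingmark_pls` (typically the restricted model).
#' @param x a `lingmark_cohort`.
#' @param target symptom target.
#' @param method correlation type, see [per_participant_correlation()].
#' @param n_min_range minimum-assessment thresholds to sweep (default
#'   3:18).
#' @return object of class `lingmark_within`: `per_participant`
#'   (`participant_id`, `n_timepoints`, `r_time`, `fisher_z`,
#'   `usable`), `aggregates` (one row per threshold: `n_min`,
#'   `n_participants`, `mean_z`, `ci_low`, `ci_high`, `t`, `p`,
#'   `available`), `n_excluded`, `target`.
#' @export
within_subject_analysis <- function(model, x, target = "depression",
                                    method = "pearson",
                                    n_min_range = 3:18) {
  ids <- unique(x$data$participant_id)
  per <- do.call(rbind, lapply(ids, function(id) {
    tr <- predict_trajectory(model, x, id, target)
    r <- per_participant_correlation(tr$predicted, tr$observed, method)
    z <- if (is.na(r)) NA_real_ else fisher_z(r)
    data.frame(participant_id = id, n_timepoints = nrow(tr),
               r_time = r, fisher_z = z,
               usable = !is.na(z) && is.finite(z),
               stringsAsFactors = FALSE)
  }))
  agg <- threshold_sweep(per, n_min_range)
  structure(list(per_participant = per, aggregates = agg,
                 n_excluded = sum(!per$usable), target = target),
            class = "lingmark_within")
}

#' @rdname within_subject_analysis
#' @param per_participant data.frame with columns `n_timepoints`,
#'   `fisher_z`, `usable`.
#' @export
threshold_sweep <- function(per_participant, n_min_range = 3:18) {
  do.call(rbind, lapply(n_min_range, function(nm) {
    z <- per_participant$fisher_z[per_participant$usable &
                                    per_participant$n_timepoints >= nm]
    n <- length(z)
    if (n < 2L)
      return(data.frame(n_min = nm, n_participants = n, mean_z = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, t = NA_real_,
                        p = NA_real_, available = FALSE))
    m <- mean(z); s <- stats::sd(z)
    se <- s / sqrt(n)
    if (s == 0) {               # all equal: t is 0 at 0, infinite otherwise
      tval <- if (m == 0) 0 else sign(m) * Inf
      pval <- if (m == 0) 1 else 0
      ci <- c(m, m)
    } else {
      tval <- m / se
      pval <- 2 * stats::pt(-abs(tval), df = n - 1L)
      hw <- stats::qt(0.975, df = n - 1L) * se
      ci <- c(m - hw, m + hw)
    }
    data.frame(n_min = nm, n_participants = n, mean_z = m,
               ci_low = ci[1], ci_high = ci[2], t = tval, p = pval,
               available = TRUE)
  }))
}

#' @export
print.lingmark_within <- function(x, ...) {
  cat(sprintf("<lingmark_within> target: %s; %d participants (%d excluded: undefined correlation)\n",
              x$target, nrow(x$per_participant), x$n_excluded))
  print(utils::head(x$aggregates, 4), row.names = FALSE)
  cat("  ...\n")
  invisible(x)
}
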