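#' Spearman rank correlation with explicit missing-data handling
#'
#' Pairwise-deletes missing entries, then computes the Pearson
#' correlation of the midrank-transformed vectors.  A constant vector
#' (after deletion) makes the correlation undefined; this is signalled
#' as `NA`, not an error, so it can propagate as a missing result.
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho, or `NA` when undefined.  Attribute `n_pairs`
#'   reports the number of complete pairs used.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) lm_stop("x/y", "lengths differ")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) lm_stop("x/y", "fewer than 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, n_pairs = sum(ok)))
  structure(stats::cor(x, y, method = "spearman"), n_pairs = sum(ok))
}

# Uncorrected p-value for Spearman's rho: exact permutation null for
# n <= 10 (via cor.test; falls back to the t approximation under ties),
# t approximation otherwise.
spearman_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 10L)$p.value)
}

#' Mass bivariate Spearman screening
#'
#' Correlates every linguistic feature with every symptom target across
#' participants of a cross-sectional table, yielding one result per
#' (feature, target) pair -- `n_features x 3` tests for the standard
#' three targets.  Uncorrected p-values use the exact Spearman null for
#' n <= 10 and the t approximation above; family-wise corrected
#' p-values are added by [max_stat_permutation()].  Optional percentile
#' bootstrap confidence intervals resample participants.
#'
#' @param table data.frame from [cross_section()] (or any table with the
#'   target and feature columns).
#' @param feature_names feature columns to test.
#' @param targets target columns (default depression, anxiety,
#'   suicidality).
#' @param n_boot bootstrap resamples for the CI; 0 skips CIs.
#' @param level CI level.
#' @param seed seed for the bootstrap.
#' @return data.frame with columns `feature`, `target`, `rho`, `ci_low`,
#'   `ci_high`, `p_uncorr`, `p_corr` (NA until permutation), `n_pairs`.
#' @export
mass_correlations <- function(table, feature_names,
                              targets = names(lm_targets),
                              n_boot = 0L, level = 0.95, seed = 1L) {
  if (!length(feature_names)) lm_stop("feature_names", "empty feature set")
  missing_cols <- setdiff(c(feature_names, targets), names(table))
  if (length(missing_cols))
    lm_stop("table", paste("missing columns:",
                           paste(missing_cols, collapse = ", ")))
  if (nrow(table) < 3L) lm_stop("table", "fewer than 3 participants")
  grid <- expand.grid(feature = feature_names, target = targets,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- table[[grid$feature[i]]]
    y <- table[[grid$target[i]]]
    rho <- spearman_rho(x, y)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0L && !is.na(rho))
      ci <- bootstrap_ci(x, y, n_boot = n_boot, level = level,
                         seed = derive_seed(seed, i))
    data.frame(feature = grid$feature[i], target = grid$target[i],
               rho = as.numeric(rho), ci_low = ci[1], ci_high = ci[2],
               p_uncorr = spearman_p(x, y), p_corr = NA_real_,
               n_pairs = attr(rho, "n_pairs"), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Max-statistic permutation control of the family-wise error rate
#'
#' For each permutation the symptom rows are shuffled jointly across
#' participants (feature rows fixed), every correlation of the family is
#' recomputed, and the most extreme statistic -- the maximum absolute rho
#' over the whole family -- is recorded.  The corrected p-value of a
#' pair compares its observed |rho| against this null distribution of
#' extremes, which automatically adapts to the number of comparisons;
#' the (1 - alpha) quantile of the extremes is the family significance
#' threshold on the |rho| scale.
#'
#' By default all targets are permuted with a single permutation per
#' iteration, preserving their mutual association; `joint = FALSE`
#' permutes each target separately.  With `exhaustive = TRUE` all `n!`
#' distinct permutations (including the identity) are enumerated instead
#' of sampled, and p-values are exact proportions.
#'
#' @param table cross-sectional data.frame (no missing cells in the fast
#'   path; pairwise deletion is applied otherwise).
#' @param feature_names,targets columns defining the family.
#' @param n_perm number of random permutations (default 10000).
#' @param alpha family-wise error level for the threshold.
#' @param seed RNG seed.
#' @param joint permute all targets with one permutation per iteration.
#' @param exhaustive enumerate all permutations (n <= 8 only).
#' @return list with `results` (the [mass_correlations()] table with
#'   `p_corr` filled in, add-one convention `(1 + #{max >= |rho|}) /
#'   (n_perm + 1)` for sampled permutations) and `null` (class
#'   `lingmark_permnull`: `n_perm`, `max_abs_stat`, `alpha`,
#'   `threshold`, `seed`).
#' @export
max_stat_permutation <- function(table, feature_names,
                                 targets = names(lm_targets),
                                 n_perm = 10000L, alpha = 0.05, seed = 1L,
                                 joint = TRUE, exhaustive = FALSE,
                                 results = NULL) {
  n <- nrow(table)
  if (n < 3L) lm_stop("table", "fewer than 3 participants")
  if (!exhaustive) n_perm <- check_count(n_perm, "n_perm")
  if (is.null(results))
    results <- mass_correlations(table, feature_names, targets)
  X <- as.matrix(table[, feature_names, drop = FALSE])
  Y <- as.matrix(table[, targets, drop = FALSE])
  complete <- !anyNA(X) && !anyNA(Y)

  perms <- if (exhaustive) all_permutations(n) else NULL
  n_iter <- if (exhaustive) nrow(perms) else n_perm

  max_abs <- numeric(n_iter)
  if (complete) {
    # rank-transform once; correlation reduces to a cross-product
    Xr <- scale(apply(X, 2, midranks))
    Yr <- scale(apply(Y, 2, midranks))
    const_x <- attr(Xr, "scaled:scale") == 0
    const_y <- attr(Yr, "scaled:scale") == 0
    Xr[, const_x] <- 0
    Yr[, const_y] <- 0
    compute <- function(perm_rows) {
      if (joint) {
        max(abs(crossprod(Xr, Yr[perm_rows, , drop = FALSE])) / (n - 1))
      } else {
        m <- 0
        for (k in seq_along(targets)) {
          pr <- if (is.matrix(perm_rows)) perm_rows[, k] else perm_rows
          m <- max(m, abs(crossprod(Xr, Yr[pr, k])) / (n - 1))
        }
        m
      }
    }
    with_seed(seed, {
      for (b in seq_len(n_iter)) {
        pr <- if (exhaustive) perms[b, ]
              else if (joint) sample.int(n)
              else matrix(replicate(length(targets), sample.int(n)), ncol = length(targets))
        max_abs[b] <- compute(pr)
      }
    })
  } else {
    # missing data: recompute each pair with pairwise deletion
    with_seed(seed, {
      for (b in seq_len(n_iter)) {
        m <- 0
        pr_joint <- if (exhaustive) perms[b, ] else sample.int(n)
        for (k in seq_along(targets)) {
          pr <- if (joint) pr_joint else sample.int(n)
          yk <- Y[pr, k]
          for (j in seq_along(feature_names)) {
            ok <- !is.na(X[, j]) & !is.na(yk)
            if (sum(ok) >= 3L && stats::sd(X[ok, j]) > 0 &&
                stats::sd(yk[ok]) > 0)
              m <- max(m, abs(stats::cor(X[ok, j], yk[ok],
                                         method = "spearman")))
          }
        }
        max_abs[b] <- m
      }
    })
  }

  obs <- abs(results$rho)
  eps <- 1e-12
  results$p_corr <- vapply(obs, function(r) {
    if (is.na(r)) return(NA_real_)
    hits <- sum(max_abs >= r - eps)
    if (exhaustive) hits / n_iter else (1 + hits) / (n_iter + 1)
  }, numeric(1))
  null <- structure(list(n_perm = n_iter, max_abs_stat = max_abs,
                         alpha = alpha,
                         threshold = as.numeric(
                           stats::quantile(max_abs, 1 - alpha, type = 1)),
                         seed = seed, joint = joint,
                         exhaustive = exhaustive),
                    class = "lingmark_permnull")
  list(results = results, null = null)
}

#' @export
print.lingmark_permnull <- function(x, ...) {
  cat(sprintf("<lingmark_permnull> %d permutations%s; alpha = %g; |rho| threshold = %.3f\n",
              x$n_perm, if (x$exhaustive) " (exhaustive)" else "",
              x$alpha, x$threshold))
  invisible(x)
}

#' Percentile bootstrap confidence interval for Spearman's rho
#'
#' Resamples participants with replacement and takes percentile bounds
#' of the resampled rank correlations.  Resamples in which the
#' correlation is undefined (a constant vector) are redrawn and counted.
#'
#' @param x,y paired numeric vectors.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return numeric `c(ci_low, ci_high)`; attribute `n_redrawn` counts
#'   redrawn degenerate resamples.
#' @export
bootstrap_ci <- function(x, y, n_boot = 1000L, level = 0.95, seed = 1L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) lm_stop("x/y", "fewer than 3 complete pairs")
  n_boot <- check_count(n_boot, "n_boot")
  rhos <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    b <- 1L
    guard <- 0L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (stats::sd(xb) == 0 || stats::sd(yb) == 0) {
        n_redrawn <- n_redrawn + 1L
        guard <- guard + 1L
        if (guard > 100L * n_boot)
          lm_stop("x/y", "bootstrap degenerate: resamples persistently constant")
        next
      }
      rhos[b] <- stats::cor(xb, yb, method = "spearman")
      b <- b + 1L
    }
  })
  qs <- stats::quantile(rhos, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(qs, n_redrawn = n_redrawn)
}

#' Arrange screening results like a published correlation table
#'
#' Sorts within each target by decreasing |rho|, breaking ties by
#' feature label so the ordering is deterministic.
#'
#' @param results data.frame from [mass_correlations()] /
#'   [max_stat_permutation()].
#' @return the sorted data.frame.
#' @export
format_table3 <- function(results) {
  ord <- order(match(results$target, unique(results$target)),
               -abs(results$rho), results$feature)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
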