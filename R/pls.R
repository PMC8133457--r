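#' Column standardization with stored parameters
#'
#' z-transforms each column to mean 0 and sample SD 1 (n - 1
#' denominator).  Constant columns carry no information and are dropped
#' with a warning; an all-constant matrix is rejected.
#'
#' @param x numeric matrix.
#' @return list with `x` (standardized matrix of kept columns), `center`,
#'   `scale` (named by kept columns) and `kept` (column names retained).
#' @export
zscore_fit_apply <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ctr <- colMeans(x)
  scl <- col_sds(x, ctr)
  keep <- scl > 0
  if (!any(keep)) lm_stop("x", "all columns are constant")
  if (!all(keep))
    warning(sprintf("dropping %d constant column(s): %s", sum(!keep),
                    paste(colnames(x)[!keep], collapse = ", ")))
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  list(x = xs, center = ctr[keep], scale = scl[keep],
       kept = colnames(x)[keep])
}

# Apply stored standardization parameters to new data.
zscore_apply <- function(x, center, scale) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) == length(center))
    colnames(x) <- names(center)
  x <- x[, names(center), drop = FALSE]
  sweep(sweep(x, 2, center), 2, scale, "/")
}

# SIMPLS on already-standardized matrices.  Returns projection weights R
# (T = Xs %*% R), x-loadings P, y-loadings Q and the sequence of
# coefficient matrices.  Deterministic; each weight vector's
# largest-magnitude entry is made positive (flipping t, p, q jointly, so
# predictions are unaffected).
simpls <- function(Xs, Ys, ncomp) {
  p <- ncol(Xs); t_ <- ncol(Ys)
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, t_, ncomp); V <- matrix(0, p, ncomp)
  S <- crossprod(Xs, Ys)
  for (a in seq_len(ncomp)) {
    r <- svd(S, nu = 1, nv = 0)$u[, 1]
    tt <- Xs %*% r
    normt <- sqrt(sum(tt^2))
    if (normt < 1e-12)
      lm_stop("n_components", "exceeds the rank of the feature matrix")
    tt <- tt / normt; r <- r / normt
    pp <- crossprod(Xs, tt)
    qq <- crossprod(Ys, tt)
    if (r[which.max(abs(r))] < 0) {      # sign convention
      r <- -r; tt <- -tt; pp <- -pp; qq <- -qq
    }
    vv <- pp
    if (a > 1L) vv <- vv - V[, 1:(a - 1L), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1L), drop = FALSE], pp)
    vv <- vv / sqrt(sum(vv^2))
    S <- S - vv %*% crossprod(vv, S)
    R[, a] <- r; P[, a] <- pp; Q[, a] <- qq; V[, a] <- vv
  }
  list(weights = R, x_loadings = P, y_loadings = Q)
}

#' Fit a partial least squares regression model
#'
#' Extracts latent components from the feature--target covariance
#' structure by the deterministic SIMPLS deflation scheme.  Features and
#' targets are z-transformed internally and the standardization
#' parameters stored, so prediction on the original scale is
#' self-contained.  With `n_components` equal to the rank of the feature
#' matrix the coefficients coincide with the least-squares solution.
#'
#' @param X feature matrix (participants x features), original scale.
#' @param Y target matrix or vector, original scale.
#' @param n_components number of latent components (>= 1, at most the
#'   rank of the standardized feature matrix).
#' @param restricted marks a model refit on a selected feature subset.
#' @return object of class `lingmark_pls` with weights, loadings,
#'   standardized-scale coefficients (`coef_std`, features x targets),
#'   centers/scales and bookkeeping fields.
#' @export
fit_pls <- function(X, Y, n_components, restricted = FALSE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  n_components <- check_count(n_components, "n_components")
  zx <- zscore_fit_apply(X)
  zy <- zscore_fit_apply(Y)
  rk <- qr(zx$x)$rank
  if (n_components > rk)
    lm_stop("n_components", sprintf("exceeds rank %d of the feature matrix", rk))
  fit <- simpls(zx$x, zy$x, n_components)
  coef_std <- fit$weights %*% t(fit$y_loadings)
  dimnames(coef_std) <- list(zx$kept, zy$kept)
  structure(list(feature_names = zx$kept, target_names = zy$kept,
                 n_components = n_components,
                 x_center = zx$center, x_scale = zx$scale,
                 y_center = zy$center, y_scale = zy$scale,
                 weights = fit$weights, x_loadings = fit$x_loadings,
                 y_loadings = fit$y_loadings, coef_std = coef_std,
                 intercept_std = rep(0, length(zy$kept)),
                 restricted = restricted),
            class = "lingmark_pls")
}

#' @rdname fit_pls
#' @param object a fitted `lingmark_pls`.
#' @param newdata feature matrix (original scale) with the model's
#'   feature columns.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return `predict()`: matrix of predictions on the original target
#'   scale.
#' @export
predict.lingmark_pls <- function(object, newdata, ncomp = object$n_components, ...) {
  ncomp <- check_count(ncomp, "ncomp")
  if (ncomp > object$n_components)
    lm_stop("ncomp", "exceeds fitted components")
  Xs <- zscore_apply(newdata, object$x_center, object$x_scale)
  B <- object$weights[, seq_len(ncomp), drop = FALSE] %*%
       t(object$y_loadings[, seq_len(ncomp), drop = FALSE])
  Ys <- Xs %*% B
  sweep(sweep(Ys, 2, object$y_scale, "*"), 2, object$y_center, "+")
}

#' @export
print.lingmark_pls <- function(x, ...) {
  cat(sprintf("<lingmark_pls> %d feature(s) -> %d target(s), %d component(s)%s\n",
              length(x$feature_names), length(x$target_names),
              x$n_components, if (x$restricted) " [restricted]" else ""))
  invisible(x)
}

#' Cross-validated selection of the number of PLS components
#'
#' Participants are partitioned into seeded folds; standardization is
#' refit on each training fold and applied to its held-out fold (no
#' leakage; set `scope = "global"` to standardize once on the full data
#' for comparison with pipelines that z-transform up front).  Prediction
#' error is the mean squared error on the standardized target scale, so
#' zero components (the train-fold mean predictor) gives an MSE near 1.
#' Components are added until the cross-validated MSE stops decreasing:
#' the selected count is the smallest m with `mse[m+1] >= mse[m]`, or
#' `max_ncomp` if the curve is strictly decreasing throughout.
#'
#' @param X,Y original-scale matrices.
#' @param k_folds number of folds (default 5).
#' @param max_ncomp largest candidate component count (default 10,
#'   capped by rank and fold size).
#' @param seed seed for the fold assignment.
#' @param scope `"fold"` (standardize within training folds) or
#'   `"global"`.
#' @return object of class `lingmark_cv`: `mse_by_ncomp` (named "0",
#'   "1", ...), `selected_ncomp`, `relative_change_vs_zero` (percent,
#'   negative = improvement), `k_folds`, `seed`.
#' @export
cv_select_ncomp <- function(X, Y, k_folds = 5L, max_ncomp = 10L, seed = 1L,
                            scope = c("fold", "global")) {
  scope <- match.arg(scope)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  n <- nrow(X)
  k_folds <- check_count(k_folds, "k_folds", min = 2L)
  if (n < k_folds) lm_stop("k_folds", "more folds than participants")
  folds <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  if (min(table(folds)) < 2L)
    lm_stop("k_folds", "a fold has fewer than 2 participants")
  if (scope == "global") {
    zx <- zscore_fit_apply(X); zy <- zscore_fit_apply(Y)
    Xg <- zx$x; Yg <- zy$x
  }
  max_ncomp <- check_count(max_ncomp, "max_ncomp")
  M <- min(max_ncomp, ncol(X), min(table(folds)) * (k_folds - 1L) - 1L)
  if (M < 1L) lm_stop("max_ncomp", "no admissible component count for this fold layout")
  sse <- matrix(0, k_folds, M + 1L)
  n_test <- integer(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    if (scope == "fold") {
      zx <- zscore_fit_apply(X[tr, , drop = FALSE])
      zy <- zscore_fit_apply(Y[tr, , drop = FALSE])
      Xtr <- zx$x; Ytr <- zy$x
      Xte <- zscore_apply(X[!tr, , drop = FALSE], zx$center, zx$scale)
      Yte <- zscore_apply(Y[!tr, colnames(Y) %in% zy$kept, drop = FALSE],
                          zy$center, zy$scale)
    } else {
      Xtr <- Xg[tr, , drop = FALSE]; Ytr <- Yg[tr, , drop = FALSE]
      Xte <- Xg[!tr, , drop = FALSE]; Yte <- Yg[!tr, , drop = FALSE]
    }
    Mf <- min(M, qr(Xtr)$rank)
    fit <- simpls(Xtr, Ytr, Mf)
    n_test[f] <- nrow(Xte)
    sse[f, 1L] <- sum(Yte^2)                 # mean-only predictor (std scale)
    for (m in seq_len(M)) {
      mm <- min(m, Mf)
      B <- fit$weights[, seq_len(mm), drop = FALSE] %*%
           t(fit$y_loadings[, seq_len(mm), drop = FALSE])
      sse[f, m + 1L] <- sum((Yte - Xte %*% B)^2)
    }
  }
  n_y <- ncol(Y)
  mse <- colSums(sse) / (sum(n_test) * n_y)
  names(mse) <- as.character(0:M)
  sel <- M
  for (m in 0:(M - 1L)) {
    if (mse[m + 2L] >= mse[m + 1L]) { sel <- m; break }
  }
  structure(list(mse_by_ncomp = mse, selected_ncomp = sel,
                 relative_change_vs_zero =
                   100 * (mse[as.character(sel)] - mse["0"]) / mse["0"],
                 k_folds = k_folds, seed = seed, scope = scope),
            class = "lingmark_cv")
}

#' @export
print.lingmark_cv <- function(x, ...) {
  cat(sprintf("<lingmark_cv> %d-fold CV; selected %d component(s); MSE change vs 0: %+.1f%%\n",
              x$k_folds, x$selected_ncomp, x$relative_change_vs_zero))
  invisible(x)
}

#' Bootstrap-z feature selection for a restricted PLS model
#'
#' Resamples participants with replacement, refits a one-component PLS
#' model per resample, and scores each feature by
#' `z = mean(loading) / SD(loading)` across resamples.  One-component
#' loadings are taken as the (normalized) feature weights; each
#' resample's weight vector is sign-aligned with the full-sample fit
#' before accumulation, since the latent component's sign is otherwise
#' arbitrary and would corrupt the bootstrap SDs.  The `k` features with
#' the largest |z| are selected, ties broken by feature label.
#' Degenerate resamples (constant target) are redrawn and counted.
#'
#' @param X feature matrix, original scale.
#' @param y single target vector.
#' @param n_boot bootstrap resamples (default 10000).
#' @param k number of features to select (default 4).
#' @param seed RNG seed.
#' @return object of class `lingmark_featsel`: `z_by_feature` (named),
#'   `selected`, `k`, `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_select_features <- function(X, y, n_boot = 10000L, k = 4L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 10L) lm_stop("X", "fewer than 10 participants")
  n_boot <- check_count(n_boot, "n_boot")
  k <- check_count(k, "k")
  if (k > p) lm_stop("k", "cannot select more features than available")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  # full-sample one-component direction for sign alignment
  zx <- zscore_fit_apply(X); zy0 <- (y - mean(y)) / stats::sd(y)
  w0 <- crossprod(zx$x, zy0)
  w0 <- w0 / sqrt(sum(w0^2))
  kept_idx <- match(zx$kept, colnames(X))
  W <- matrix(NA_real_, p, n_boot, dimnames = list(colnames(X), NULL))
  n_redrawn <- 0L
  with_seed(seed, {
    b <- 1L; guard <- 0L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      sy <- stats::sd(yb)
      if (sy == 0) {
        n_redrawn <- n_redrawn + 1L; guard <- guard + 1L
        if (guard > 100L * n_boot)
          lm_stop("y", "bootstrap degenerate: target persistently constant")
        next
      }
      Xb <- X[idx, , drop = FALSE]
      ctr <- colMeans(Xb)
      scl <- col_sds(Xb, ctr)
      ybs <- (yb - mean(yb)) / sy
      wb <- crossprod(Xb, ybs) - ctr * sum(ybs)   # = crossprod(centered Xb, ybs)
      ok <- scl > 0
      wb[ok] <- wb[ok] / scl[ok]
      wb[!ok] <- 0
      nrm <- sqrt(sum(wb^2))
      if (nrm == 0) {
        n_redrawn <- n_redrawn + 1L; guard <- guard + 1L; next
      }
      wb <- wb / nrm
      if (sum(wb[kept_idx] * w0) < 0) wb <- -wb   # sign alignment
      W[, b] <- wb
      b <- b + 1L
    }
  })
  mu <- rowMeans(W)
  sdv <- apply(W, 1, stats::sd)
  z <- ifelse(sdv > 0, mu / sdv, 0)
  names(z) <- colnames(X)
  ord <- order(-abs(z), names(z))
  structure(list(z_by_feature = z, selected = names(z)[ord[seq_len(k)]],
                 k = k, n_boot = n_boot, n_redrawn = n_redrawn, seed = seed),
            class = "lingmark_featsel")
}

#' @export
print.lingmark_featsel <- function(x, ...) {
  cat(sprintf("<lingmark_featsel> top %d of %d features (%d bootstrap resamples):\n  %s\n",
              x$k, length(x$z_by_feature), x$n_boot,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Correlation between model predictions and observations
#'
#' Pearson correlation (and its square) per target between the model's
#' predictions and the observed scores, with a percentile bootstrap
#' confidence interval over participants.  Constant predictions make
#' the correlation undefined (`NA`).
#'
#' @param model fitted `lingmark_pls`.
#' @param X,Y original-scale data.
#' @param n_boot bootstrap resamples for the CI (0 skips it).
#' @param level CI level.
#' @param seed RNG seed.
#' @return data.frame with `target`, `r`, `r_squared`, `ci_low`,
#'   `ci_high`.
#' @export
predicted_vs_observed <- function(model, X, Y, n_boot = 1000L, level = 0.95,
                                  seed = 1L) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- model$target_names
  pred <- predict(model, X)
  out <- lapply(seq_along(model$target_names), function(k) {
    tn <- model$target_names[k]
    obs <- Y[, tn]
    pk <- pred[, k]
    r <- if (stats::sd(pk) == 0 || stats::sd(obs) == 0) NA_real_
         else stats::cor(pk, obs)
    ci <- c(NA_real_, NA_real_)
    if (!is.na(r) && n_boot > 0L) {
      n <- length(obs)
      rs <- with_seed(derive_seed(seed, k), {
        replicate(n_boot, {
          idx <- sample.int(n, n, replace = TRUE)
          if (stats::sd(pk[idx]) == 0 || stats::sd(obs[idx]) == 0) NA_real_
          else stats::cor(pk[idx], obs[idx])
        })
      })
      ci <- stats::quantile(rs, c((1 - level) / 2, 1 - (1 - level) / 2),
                            na.rm = TRUE, names = FALSE)
    }
    data.frame(target = tn, r = r, r_squared = r^2,
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit a combined model for all three symptom targets
#'
#' Runs the cross-validated component selection and fits a PLS model
#' with the three targets jointly (depression, anxiety, suicidality),
#' exploiting their mutual correlation.
#'
#' @param X feature matrix, original scale.
#' @param Y three-column target matrix.
#' @inheritParams cv_select_ncomp
#' @return list with elements `cv` (a `lingmark_cv`) and `model` (a
#'   `lingmark_pls` fitted with the selected component count, at least
#'   one).
#' @export
fit_multitarget <- function(X, Y, k_folds = 5L, max_ncomp = 10L, seed = 1L,
                            scope = "fold") {
  cv <- cv_select_ncomp(X, Y, k_folds = k_folds, max_ncomp = max_ncomp,
                        seed = seed, scope = scope)
  model <- fit_pls(X, Y, n_components = max(cv$selected_ncomp, 1L))
  list(cv = cv, model = model)
}

#' Serialize a PLS model as a versioned JSON document
#'
#' @param model fitted `lingmark_pls`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  doc <- list(format_version = 1L,
              feature_names = model$feature_names,
              target_names = model$target_names,
              n_components = model$n_components,
              x_center = as.list(model$x_center),
              x_scale = as.list(model$x_scale),
              y_center = as.list(model$y_center),
              y_scale = as.list(model$y_scale),
              coef_std = model$coef_std,
              weights = model$weights,
              restricted = model$restricted)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
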