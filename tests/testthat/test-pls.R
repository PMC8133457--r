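make_regression_data <- function(n = 40, p = 6, t_ = 1, noise = 1, seed = 55) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  B <- matrix(rnorm(p * t_), p, t_)
  Y <- X %*% B + noise * matrix(rnorm(n * t_), n, t_)
  list(X = X, Y = Y)
}

test_that("z-transform produces unit-variance columns and stores its parameters", {
  expect_equal(as.numeric(zscore_fit_apply(cbind(c(2, 4, 6)))$x), c(-1, 0, 1))
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  z <- zscore_fit_apply(X)
  expect_equal(unname(colMeans(z$x)), rep(0, 3))
  expect_equal(unname(apply(z$x, 2, sd)), rep(1, 3))
  # stored transform reproduces the standardized matrix
  again <- sweep(sweep(X, 2, z$center), 2, z$scale, "/")
  expect_equal(unname(again), unname(z$x))
  Xc <- cbind(X, 7)
  expect_warning(z2 <- zscore_fit_apply(Xc), "constant")
  expect_identical(ncol(z2$x), 3L)
  expect_error(suppressWarnings(zscore_fit_apply(matrix(1, 5, 2))), "constant")
})

test_that("the first PLS direction is the feature-target covariance direction", {
  d <- make_regression_data(p = 5)
  m <- fit_pls(d$X, d$Y, n_components = 1)
  w <- m$weights[, 1]
  cv <- cov(scale(d$X), scale(d$Y))[, 1]
  cosine <- sum(w * cv) / sqrt(sum(w^2) * sum(cv^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-10)
})

test_that("a full-rank PLS fit reproduces the least-squares oracle", {
  d <- make_regression_data(n = 50, p = 7, t_ = 2)
  m <- fit_pls(d$X, d$Y, n_components = 7)
  pred <- predict(m, d$X)
  # independent oracle: normal equations on the raw data
  XtX <- crossprod(cbind(1, d$X))
  beta <- solve(XtX, crossprod(cbind(1, d$X), d$Y))
  expect_lt(max(abs(pred - cbind(1, d$X) %*% beta)), 1e-8)
  expect_error(fit_pls(d$X, d$Y, n_components = 8), "rank")
})

test_that("a target equal to a feature column is recovered exactly", {
  # with mutually orthogonal features one component suffices (the first
  # direction is the covariance vector, here a coordinate axis)
  set.seed(20)
  M <- scale(matrix(rnorm(30 * 4), 30, 4), scale = FALSE)
  Xo <- qr.Q(qr(M))               # centered, mutually orthogonal columns
  colnames(Xo) <- paste0("x", 1:4)
  y <- Xo[, 2]
  m1 <- fit_pls(Xo, y, n_components = 1)
  expect_lt(max(abs(predict(m1, Xo) - y)), 1e-8)
  # with correlated features the full-rank fit recovers it
  d <- make_regression_data(n = 30, p = 4)
  m4 <- fit_pls(d$X, d$X[, 2], n_components = 4)
  expect_lt(max(abs(predict(m4, d$X) - d$X[, 2])), 1e-8)
})

test_that("training error is non-increasing in the number of components", {
  d <- make_regression_data(n = 40, p = 8)
  m <- fit_pls(d$X, d$Y, n_components = 8)
  errs <- vapply(1:8, function(k)
    mean((predict(m, d$X, ncomp = k) - d$Y)^2), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("standardized predictions are scale-equivariant", {
  d <- make_regression_data(n = 30, p = 5)
  m1 <- fit_pls(d$X, d$Y, n_components = 2)
  X2 <- d$X
  X2[, 3] <- X2[, 3] * 100        # positive rescaling of a raw feature
  m2 <- fit_pls(X2, d$Y, n_components = 2)
  expect_equal(predict(m1, d$X), predict(m2, X2), tolerance = 1e-10)
})

test_that("the one-target fit matches an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_regression_data(n = 35, p = 6)
  m <- fit_pls(d$X, d$Y, n_components = 2)
  ref <- mixOmics::pls(d$X, d$Y, ncomp = 2, scale = TRUE, mode = "regression")
  pred_ref <- predict(ref, d$X)$predict[, 1, 2]
  expect_equal(unname(predict(m, d$X)[, 1]), unname(pred_ref),
               tolerance = 1e-6)
})

test_that("cross-validation selects components by the stopping rule", {
  # noiseless single-component structure: selected = 1, mse[1] ~ 0
  set.seed(42)
  n <- 60
  lat <- rnorm(n)
  X <- outer(lat, c(1, -1, 0.5, 2)) # rank-1 feature matrix + tiny jitter
  X <- X + 1e-6 * matrix(rnorm(length(X)), n)
  y <- 2 * lat
  cv <- cv_select_ncomp(X, y, k_folds = 5, max_ncomp = 3, seed = 7)
  expect_identical(cv$selected_ncomp, 1L)
  expect_lt(cv$mse_by_ncomp["1"], 1e-6)
  # zero components corresponds to the mean-only predictor: MSE near 1
  expect_lt(abs(cv$mse_by_ncomp["0"] - 1), 0.25)
  expect_lt(cv$relative_change_vs_zero, -99)

  # pure-noise target: zero components selected in most seeded runs
  sel0 <- vapply(1:40, function(s) {
    set.seed(s + 500)
    Xn <- matrix(rnorm(40 * 10), 40, 10)
    yn <- rnorm(40)
    cv_select_ncomp(Xn, yn, k_folds = 5, max_ncomp = 4, seed = s)$selected_ncomp
  }, integer(1))
  expect_gt(mean(sel0 == 0L), 0.5)
})

test_that("cross-validation is deterministic under a fixed seed", {
  d <- make_regression_data(n = 45, p = 6)
  a <- cv_select_ncomp(d$X, d$Y, seed = 3)
  b <- cv_select_ncomp(d$X, d$Y, seed = 3)
  expect_identical(a$mse_by_ncomp, b$mse_by_ncomp)
  c_ <- cv_select_ncomp(d$X, d$Y, seed = 4)
  expect_false(identical(a$mse_by_ncomp, c_$mse_by_ncomp))
})

test_that("bootstrap feature selection recovers planted features and is seeded", {
  set.seed(11)
  n <- 120; p <- 12
  u <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("x%02d", 1:p)))
  X[, 1:3] <- X[, 1:3] + outer(u, c(2, -2, 1.5))
  y <- u + 0.3 * rnorm(n)
  sel <- bootstrap_select_features(X, y, n_boot = 400, k = 3, seed = 2)
  expect_setequal(sel$selected, c("x01", "x02", "x03"))
  sel2 <- bootstrap_select_features(X, y, n_boot = 400, k = 3, seed = 2)
  expect_identical(sel$z_by_feature, sel2$z_by_feature)
  # k = p selects everything
  selp <- bootstrap_select_features(X, y, n_boot = 50, k = p, seed = 1)
  expect_setequal(selp$selected, colnames(X))
  expect_error(bootstrap_select_features(X, y, k = p + 1), "k")
  expect_error(bootstrap_select_features(X[1:5, ], y[1:5]), "participants")
})

test_that("pure-noise features yield no stable selection across seeds", {
  counts <- table(unlist(lapply(1:20, function(s) {
    set.seed(s + 900)
    X <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(NULL, sprintf("x%02d", 1:10)))
    y <- rnorm(40)
    bootstrap_select_features(X, y, n_boot = 150, k = 2, seed = s)$selected
  })))
  expect_true(all(counts <= 10))  # no feature selected in > 50% of runs
})

test_that("predicted-vs-observed report has correlation identities", {
  d <- make_regression_data(n = 50, p = 5, noise = 0.8)
  m <- fit_pls(d$X, d$Y, n_components = 2)
  rep_ <- predicted_vs_observed(m, d$X, d$Y, n_boot = 200, seed = 6)
  expect_equal(rep_$r_squared, rep_$r^2)
  expect_true(rep_$ci_low <= rep_$r && rep_$r <= rep_$ci_high)
  # target equal to its prediction: r = 1
  pred <- predict(m, d$X)
  rep2 <- predicted_vs_observed(m, d$X, pred, n_boot = 0)
  expect_equal(rep2$r, 1)
})

test_that("multi-target fits are symmetric and equivariant", {
  d <- make_regression_data(n = 40, p = 6)
  Y3 <- cbind(a = d$Y[, 1], b = d$Y[, 1], c = d$Y[, 1])
  m <- fit_pls(d$X, Y3, n_components = 2)
  expect_equal(m$coef_std[, "a"], m$coef_std[, "b"])
  expect_equal(m$coef_std[, "a"], m$coef_std[, "c"])

  set.seed(8)
  Ym <- cbind(p = d$Y[, 1], q = rnorm(40), r = d$Y[, 1] + rnorm(40))
  m1 <- fit_pls(d$X, Ym, n_components = 2)
  m2 <- fit_pls(d$X, Ym[, c("r", "p", "q")], n_components = 2)
  expect_equal(m1$coef_std[, c("r", "p", "q")], m2$coef_std,
               tolerance = 1e-10)

  mt <- fit_multitarget(d$X, Ym, seed = 4)
  expect_s3_class(mt$cv, "lingmark_cv")
  expect_identical(mt$model$n_components, max(mt$cv$selected_ncomp, 1L))
})

test_that("PLS models serialize to a versioned JSON document", {
  d <- make_regression_data(n = 30, p = 4)
  m <- fit_pls(d$X, d$Y, n_components = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  doc <- jsonlite::read_json(path)
  expect_identical(doc$format_version, 1L)
  expect_identical(unlist(doc$feature_names), m$feature_names)
  expect_equal(doc$n_components, 2L)
})
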