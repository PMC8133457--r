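test_that("spearman_rho has rank-correlation semantics", {
  x <- c(0.5, 1, 2, 3, 4)
  expect_equal(as.numeric(spearman_rho(x, x^2)), 1)   # monotone invariance
  expect_equal(as.numeric(spearman_rho(x, rev(x))), -1)
  # frozen value from the independent midrank-then-Pearson oracle
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(3, 1, 2, 5, 4)
  expect_equal(as.numeric(spearman_rho(x5, y5)), oracle_spearman(x5, y5))
  expect_equal(as.numeric(spearman_rho(x5, y5)), 0.6)
  # ties handled by midranks, matching the oracle
  xt <- c(1, 1, 2, 3, 3, 4); yt <- c(2, 1, 1, 3, 4, 4)
  expect_equal(as.numeric(spearman_rho(xt, yt)), oracle_spearman(xt, yt))
})

test_that("spearman_rho pairwise-deletes and signals undefined cases", {
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, NA, 3, 8, 10, 12)
  r <- spearman_rho(x, y)
  expect_identical(attr(r, "n_pairs"), 4L)
  expect_equal(as.numeric(r), oracle_spearman(c(1, 4, 5, 6), c(2, 8, 10, 12)))
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))    # constant: NA, no error
  expect_error(spearman_rho(1:2, 1:2), "pairs")
})

test_that("mass screening produces one calibrated result per pair", {
  coh <- make_complete_cohort(n = 15, n_features = 6)
  xs <- cross_section(coh)
  mc <- mass_correlations(xs, coh$feature_names)
  expect_identical(nrow(mc), 18L)
  expect_error(mass_correlations(xs, character(0)), "feature")

  # a feature identical to the target correlates perfectly
  xs$feat_dup <- xs$depression
  mc2 <- mass_correlations(xs, c(coh$feature_names, "feat_dup"))
  expect_equal(mc2$rho[mc2$feature == "feat_dup" &
                         mc2$target == "depression"], 1)

  # null calibration: fraction of p_uncorr < 0.05 near 0.05
  set.seed(77)
  tab <- as.data.frame(matrix(rnorm(200 * 40), 200, 40))
  names(tab) <- c(sprintf("feat_%02d", 1:37), "depression", "anxiety",
                  "suicidality")
  mc3 <- mass_correlations(tab, sprintf("feat_%02d", 1:37))
  frac <- mean(mc3$p_uncorr < 0.05)
  expect_lt(abs(frac - 0.05), 0.03)
})

test_that("max-statistic correction dominates the uncorrected p-value", {
  coh <- make_complete_cohort(n = 15, n_features = 6)
  xs <- cross_section(coh)
  out <- max_stat_permutation(xs, coh$feature_names, n_perm = 500, seed = 5)
  ok <- !is.na(out$results$p_corr)
  # max-statistic dominance (the permutation p has a 1/(n_perm+1) floor)
  expect_true(all(out$results$p_corr[ok] + 1e-12 >=
                    pmin(out$results$p_uncorr[ok], 1 / 501)))
  expect_true(mean(out$results$p_corr[ok] >= out$results$p_uncorr[ok]) > 0.9)
  expect_gte(out$null$threshold, 0)
  expect_identical(length(out$null$max_abs_stat), 500L)
})

test_that("exhaustive permutation p-values equal a full-enumeration oracle", {
  set.seed(13)
  n <- 5
  tab <- data.frame(feat_a = rnorm(n), feat_b = rnorm(n),
                    depression = rnorm(n))
  out <- max_stat_permutation(tab, c("feat_a", "feat_b"),
                              targets = "depression", exhaustive = TRUE)
  expect_identical(out$null$n_perm, 120L)

  # independent oracle: enumerate all 120 orderings by hand
  perms <- expand.grid(rep(list(1:n), n))
  perms <- as.matrix(perms[apply(perms, 1, function(r)
    length(unique(r)) == n), ])
  expect_identical(nrow(perms), 120L)
  maxs <- apply(perms, 1, function(pr) {
    max(abs(cor(tab$feat_a, tab$depression[pr], method = "spearman")),
        abs(cor(tab$feat_b, tab$depression[pr], method = "spearman")))
  })
  for (j in 1:2) {
    obs <- abs(out$results$rho[j])
    expect_equal(out$results$p_corr[j], mean(maxs >= obs - 1e-12))
  }
})

test_that("corrected p-values are invariant to monotone feature transforms", {
  coh <- make_complete_cohort(n = 12, n_features = 4)
  xs <- cross_section(coh)
  out1 <- max_stat_permutation(xs, coh$feature_names, n_perm = 300, seed = 8)
  xs2 <- xs
  xs2$feat_01 <- exp(3 * xs2$feat_01)      # strictly monotone
  xs2$feat_02 <- xs2$feat_02^3 + 5
  out2 <- max_stat_permutation(xs2, coh$feature_names, n_perm = 300, seed = 8)
  expect_equal(out1$results$rho, out2$results$rho)
  expect_equal(out1$results$p_corr, out2$results$p_corr)
})

test_that("joint permutation preserves the targets' mutual association", {
  # separate permutation must break the target correlation; joint keeps it.
  # checked indirectly: with strongly correlated targets the joint null has
  # heavier-tailed max statistics than the separate null on average
  coh <- make_complete_cohort(n = 20, n_features = 4)
  xs <- cross_section(coh)
  joint <- max_stat_permutation(xs, coh$feature_names, n_perm = 300,
                                seed = 9, joint = TRUE)
  sep <- max_stat_permutation(xs, coh$feature_names, n_perm = 300,
                              seed = 9, joint = FALSE)
  # both are valid nulls of the same family; thresholds should be close
  expect_lt(abs(joint$null$threshold - sep$null$threshold), 0.25)
})

test_that("permutation handles missing cells by pairwise deletion", {
  coh <- make_complete_cohort(n = 14, n_features = 3)
  xs <- cross_section(coh)
  xs$depression[c(2, 5)] <- NA
  out <- max_stat_permutation(xs, coh$feature_names, n_perm = 100, seed = 10)
  expect_true(all(is.finite(out$null$max_abs_stat)))
  expect_true(all(out$results$n_pairs[out$results$target == "depression"] == 12))
})

test_that("bootstrap CI behaves at the degenerate and generic cases", {
  x <- 1:20
  ci <- bootstrap_ci(x, x, n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci), c(1, 1))          # y = x exactly
  set.seed(3)
  y <- rnorm(20)
  ci2 <- bootstrap_ci(x, y, n_boot = 400, seed = 2)
  expect_true(all(ci2 >= -1 & ci2 <= 1))
  expect_lt(ci2[1], ci2[2])
  expect_error(bootstrap_ci(1:2, 1:2), "pairs")
})

test_that("bootstrap CI coverage is near nominal for bivariate-normal data", {
  # population rho_s ~ 0.48 (Pearson 0.5); 400 replicates at n = 50
  reps <- 400
  rho_s <- (6 / pi) * asin(0.25)
  covered <- logical(reps)
  set.seed(99)
  for (i in seq_len(reps)) {
    u <- rnorm(50)
    x <- u + rnorm(50, sd = 1)
    y <- u + rnorm(50, sd = 1)     # Pearson corr 0.5
    ci <- bootstrap_ci(x, y, n_boot = 300, seed = i)
    covered[i] <- ci[1] <= rho_s && rho_s <= ci[2]
  }
  expect_lt(abs(mean(covered) - 0.95), 0.03)
})

test_that("published-style table ordering is deterministic", {
  coh <- make_complete_cohort(n = 12, n_features = 5)
  xs <- cross_section(coh)
  mc <- mass_correlations(xs, coh$feature_names)
  t1 <- format_table3(mc)
  t2 <- format_table3(mc[sample(nrow(mc)), ])
  expect_equal(t1, t2)
  # |rho| non-increasing within target
  for (tg in unique(t1$target)) {
    v <- abs(t1$rho[t1$target == tg])
    expect_true(all(diff(v) <= 1e-12))
  }
})
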