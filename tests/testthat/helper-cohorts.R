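# Shared fixture builders; everything is generated in code.

# Small fully-observed cohort with planted effects.
make_complete_cohort <- function(n = 20, n_features = 6, seed = 101,
                                 within_coupling = 1, n_windows = 6) {
  cfg <- synthetic_config(
    n_participants = n, n_windows = n_windows, n_features = n_features,
    between_loadings = default_loadings(n_features),
    within_coupling = within_coupling,
    p_missing_assessment = 0, p_missing_blog = 0, seed = seed)
  generate_cohort(cfg)
}

# Hand-built 2-participant cohort for arithmetic checks.
make_tiny_cohort <- function() {
  d <- data.frame(
    participant_id = c("A", "A", "B"),
    window_index = c(0L, 1L, 0L),
    phq9_total = c(10L, 14L, NA),
    gad7_total = c(8L, 12L, 5L),
    item9 = c(1L, 2L, NA),
    panic_attacks = c(0L, 3L, NA),
    n_posts = c(2L, 0L, 1L),
    post_word_counts = c("10;30", NA, "40"),
    f_a = c(1, NA, 3),
    f_b = c(2, NA, 6),
    stringsAsFactors = FALSE)
  new_cohort(d, c("f_a", "f_b"))
}

# Independent oracle: Spearman rho as Pearson on midranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# The published per-participant activity profile bundled with the package.
activity_fixture <- function() {
  utils::read.csv(system.file("extdata", "blog_activity_totals.csv",
                              package = "lingmark"))
}
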