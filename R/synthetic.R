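#' Configuration of a synthetic longitudinal cohort
#'
#' Defines the generative model used by [generate_cohort()].  Each
#' participant carries a latent severity trait `u ~ N(0, 1)`; each
#' fortnightly window adds a shared mood deviation with SD
#' `symptom_noise_sd`, giving a latent state `s = u + noise`.  Continuous
#' symptom scores are affine in `s` (anchored to realistic PHQ-9 / GAD-7
#' means and spreads), then rounded and clipped to the bounded integer
#' scales.  Feature `j` couples to the cohort via
#' `between_loadings[j] * (within_coupling * s + (1 - within_coupling) * u)`
#' plus per-window feature noise, shifted to the non-negative
#' percent-of-words scale LIWC produces.  `within_coupling = 1` makes the
#' within-subject feature--symptom relation identical to the
#' between-subject one (an ergodic regime); `within_coupling = 0` makes
#' the systematic feature signal time-invariant per subject while
#' symptoms still fluctuate, so group-level models carry no information
#' about individual change.
#'
#' @param n_participants number of participants.
#' @param n_windows fortnightly windows per participant (default 18,
#'   i.e. 36 weeks).
#' @param n_features number of linguistic features (default 68).
#' @param feature_names feature labels.
#' @param between_loadings numeric vector (length `n_features`) mapping
#'   the latent severity signal to feature means.  Default plants four
#'   informative features (two positive, two negative) among nulls.
#' @param within_coupling real in \[0, 1\]; see Details above.
#' @param symptom_noise_sd SD of the per-window mood deviation on the
#'   latent (unit-trait) scale.
#' @param feature_noise_sd SD of per-window feature measurement noise.
#' @param feature_baseline non-negative baseline level per feature
#'   (percent-of-words scale); features are truncated at 0 after the
#'   correlation structure is imposed, a mild attenuation when the
#'   baseline is large relative to the feature SD.
#' @param p_missing_assessment probability a window's assessment is
#'   skipped (default 0.58, matching a mean of about 7.5 completions out
#'   of 18).
#' @param p_missing_blog probability a window has no blog posts.
#' @param posts_per_window_mean mean posts per active window.
#' @param words_per_post_mean mean words per post.
#' @param phq9_mean,phq9_scale,gad7_mean,gad7_scale affine anchors of the
#'   continuous symptom scores (defaults give cohort means/SDs near 14.5
#'   / 5.6 for PHQ-9 and 11.6 / 4.9 for GAD-7).
#' @param seed integer RNG seed; identical config + seed reproduces a
#'   bit-identical dataset.
#' @return validated list of class `lingmark_synth_config`.
#' @export
synthetic_config <- function(n_participants,
                             n_windows = 18L,
                             n_features = 68L,
                             feature_names = sprintf("feat_%02d", seq_len(n_features)),
                             between_loadings = default_loadings(n_features),
                             within_coupling = 1,
                             symptom_noise_sd = 0.6,
                             feature_noise_sd = 1,
                             feature_baseline = default_baseline(n_features),
                             p_missing_assessment = 0.58,
                             p_missing_blog = 0.5,
                             posts_per_window_mean = 1.8,
                             words_per_post_mean = 193,
                             phq9_mean = 14.5, phq9_scale = 4.8,
                             gad7_mean = 11.6, gad7_scale = 4.2,
                             seed = 1L) {
  cfg <- list(
    n_participants = check_count(n_participants, "n_participants"),
    n_windows = check_count(n_windows, "n_windows"),
    n_features = check_count(n_features, "n_features"),
    feature_names = as.character(feature_names),
    between_loadings = as.numeric(between_loadings),
    within_coupling = check_prob(within_coupling, "within_coupling"),
    symptom_noise_sd = check_nonneg(symptom_noise_sd, "symptom_noise_sd"),
    feature_noise_sd = check_nonneg(feature_noise_sd, "feature_noise_sd"),
    feature_baseline = as.numeric(feature_baseline),
    p_missing_assessment = check_prob(p_missing_assessment, "p_missing_assessment"),
    p_missing_blog = check_prob(p_missing_blog, "p_missing_blog"),
    posts_per_window_mean = check_nonneg(posts_per_window_mean, "posts_per_window_mean"),
    words_per_post_mean = check_nonneg(words_per_post_mean, "words_per_post_mean"),
    phq9_mean = phq9_mean, phq9_scale = check_nonneg(phq9_scale, "phq9_scale"),
    gad7_mean = gad7_mean, gad7_scale = check_nonneg(gad7_scale, "gad7_scale"),
    seed = check_count(seed, "seed", min = 0L))
  if (length(cfg$feature_names) != cfg$n_features)
    lm_stop("feature_names", "length must equal n_features")
  if (length(cfg$between_loadings) != cfg$n_features)
    lm_stop("between_loadings", "length must equal n_features")
  if (length(cfg$feature_baseline) != cfg$n_features ||
      any(cfg$feature_baseline < 0))
    lm_stop("feature_baseline", "must be n_features non-negative levels")
  if (cfg$posts_per_window_mean <= 0)
    lm_stop("posts_per_window_mean", "must be positive")
  if (cfg$words_per_post_mean <= 0)
    lm_stop("words_per_post_mean", "must be positive")
  structure(cfg, class = "lingmark_synth_config")
}

#' @rdname synthetic_config
#' @export
default_loadings <- function(n_features) {
  if (n_features < 4L) return(rep(0.8, n_features))
  c(0.8, -0.8, 0.6, -0.6, rep(0, n_features - 4L))
}

#' @rdname synthetic_config
#' @export
default_baseline <- function(n_features) {
  # baseline percent-of-words levels: LIWC categories span roughly
  # 0.3 -- 8 percent; cycled deterministically across features
  rep(c(0.5, 1, 2, 4, 8), length.out = n_features)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort from the generative model described in
#' [synthetic_config()].  Assessments and blog windows are deleted
#' independently with the configured probabilities; post counts and
#' per-post word counts come from over-dispersed (negative-binomial)
#' distributions, matching the heavy-tailed posting activity seen in
#' blogging cohorts.  PHQ-9 item 9 is a coarsened monotone function of
#' the continuous depression score, so `phq9_total >= item9` always
#' holds.
#'
#' @param config a `lingmark_synth_config`.
#' @return a [new_cohort()] object; the generating config is attached as
#'   attribute `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "lingmark_synth_config"))
    lm_stop("config", "must be created by synthetic_config()")
  cfg <- config
  n <- cfg$n_participants; W <- cfg$n_windows; p <- cfg$n_features
  with_seed(cfg$seed, {
    u <- stats::rnorm(n)                                    # latent trait
    mood <- matrix(stats::rnorm(n * W, sd = cfg$symptom_noise_sd), n, W)
    state <- u + mood                                       # latent window state

    phq_cont <- cfg$phq9_mean + cfg$phq9_scale * state
    gad_cont <- cfg$gad7_mean + cfg$gad7_scale * state
    phq <- pmin(pmax(round(phq_cont), 0L), 27L)
    gad <- pmin(pmax(round(gad_cont), 0L), 21L)
    it9 <- pmin(pmax(floor((phq_cont - 2) / 7), 0L), 3L)
    it9 <- pmin(it9, phq)                                   # item is part of total
    panic <- matrix(stats::rnbinom(n * W, size = 1,
                                   mu = pmin(exp(0.3 + 0.25 * state), 60)),
                    n, W)

    # feature signal: ergodicity knob mixes window state and trait
    sig <- cfg$within_coupling * state + (1 - cfg$within_coupling) * u
    base <- cfg$feature_baseline
    feats <- array(stats::rnorm(n * W * p, sd = cfg$feature_noise_sd),
                   dim = c(n, W, p))
    for (j in seq_len(p))
      feats[, , j] <- pmax(0, base[j] + cfg$between_loadings[j] * sig +
                              feats[, , j])

    miss_assess <- matrix(stats::runif(n * W) < cfg$p_missing_assessment, n, W)
    miss_blog <- matrix(stats::runif(n * W) < cfg$p_missing_blog, n, W)
    n_posts <- matrix(0L, n, W)
    active <- !miss_blog
    n_posts[active] <- 1L + stats::rnbinom(sum(active), size = 0.7,
                                           mu = max(cfg$posts_per_window_mean - 1, 0.01))
    wc <- matrix("", n, W)
    idx_active <- which(active)
    for (k in idx_active) {
      counts <- 1L + stats::rnbinom(n_posts[k], size = 0.5,
                                    mu = max(cfg$words_per_post_mean - 1, 1))
      wc[k] <- paste(counts, collapse = ";")
    }

    d <- data.frame(
      participant_id = rep(sprintf("P%03d", seq_len(n)), each = W),
      window_index = rep(0:(W - 1L), times = n),
      phq9_total = as.integer(t(phq)),
      gad7_total = as.integer(t(gad)),
      item9 = as.integer(t(it9)),
      panic_attacks = as.integer(t(panic)),
      n_posts = as.integer(t(n_posts)),
      post_word_counts = as.vector(t(wc)),
      stringsAsFactors = FALSE)
    ma <- as.vector(t(miss_assess))
    d$phq9_total[ma] <- NA_integer_
    d$gad7_total[ma] <- NA_integer_
    d$item9[ma] <- NA_integer_
    d$panic_attacks[ma] <- NA_integer_
    fm <- matrix(NA_real_, n * W, p,
                 dimnames = list(NULL, cfg$feature_names))
    keep <- as.vector(t(active))
    for (j in seq_len(p)) fm[keep, j] <- as.vector(t(feats[, , j]))[keep]
    d$post_word_counts[!keep] <- NA_character_
    d <- cbind(d, as.data.frame(fm))
    out <- new_cohort(d, cfg$feature_names)
    attr(out, "config") <- cfg
    out
  })
}

#' Impose an observed assessment-completion profile on a cohort
#'
#' Reduces each participant's completed assessments to exactly the
#' requested count by deleting a random (seeded) subset, reproducing the
#' unbalanced completion profiles seen in real longitudinal cohorts.
#'
#' @param x a `lingmark_cohort`.
#' @param completion_counts integer vector, one count per participant (in
#'   the order participants first appear); each must not exceed the
#'   number of that participant's completed assessments.
#' @param seed integer seed for the random subset.
#' @return a `lingmark_cohort` in which participant `i` has exactly
#'   `completion_counts[i]` completed assessments.
#' @export
degrade_to_study_profile <- function(x, completion_counts, seed = 1L) {
  d <- x$data
  ids <- unique(d$participant_id)
  if (length(completion_counts) != length(ids))
    lm_stop("completion_counts", "length must equal number of participants")
  n_windows <- max(d$window_index) + 1L
  if (any(completion_counts > n_windows))
    lm_stop("completion_counts",
            sprintf("counts exceed the %d available windows", n_windows))
  with_seed(seed, {
    for (i in seq_along(ids)) {
      sel <- which(d$participant_id == ids[i])
      done <- sel[!is.na(d$phq9_total[sel])]
      k <- completion_counts[i]
      if (k > length(done))
        lm_stop("completion_counts",
                sprintf("participant %s has only %d completed assessments (%d requested)",
                        ids[i], length(done), k))
      drop <- if (length(done) > k)
        done[sample.int(length(done), length(done) - k)] else integer(0)
      d$phq9_total[drop] <- NA_integer_
      d$gad7_total[drop] <- NA_integer_
      d$item9[drop] <- NA_integer_
      d$panic_attacks[drop] <- NA_integer_
    }
  })
  out <- new_cohort(d, x$feature_names, validate = FALSE)
  attr(out, "config") <- attr(x, "config")
  out
}
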