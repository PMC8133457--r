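# Internal helpers shared across modules.

# Canonical mapping from analysis target names to symptom columns.
lm_targets <- c(depression = "phq9_total",
                anxiety    = "gad7_total",
                suicidality = "item9")

# Reserved (non-feature) columns of the long per-window layout.
lm_reserved_cols <- c("participant_id", "window_index", "phq9_total",
                      "gad7_total", "item9", "panic_attacks", "n_posts",
                      "post_word_counts")

#' @keywords internal
lm_stop <- function(field, msg, class = "lingmark_validation_error") {
  stop(structure(class = c(class, "lingmark_error", "error", "condition"),
                 list(message = sprintf("%s: %s", field, msg),
                      call = sys.call(-1), field = field)))
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream.  All stochastic operations in the package route through this.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a master seed; stays below 2^31.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1103L + offset * 7919) %% 2147483647)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    lm_stop(field, "must be a single probability in [0, 1]")
  x
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    lm_stop(field, "must be a single non-negative number")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    lm_stop(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

# Sample standard deviation per column of a matrix (n - 1 denominator),
# without the copy overhead of apply(x, 2, sd).
col_sds <- function(x, center = colMeans(x)) {
  n <- nrow(x)
  sqrt(colSums((x - rep(center, each = n))^2) / (n - 1))
}

# Midranks of a numeric vector (ties averaged); NA kept as NA.
midranks <- function(x) rank(x, na.last = "keep", ties.method = "average")

# All permutations of 1..n, one per row.  Guarded: exhaustive enumeration
# is only meant for tiny samples.
all_permutations <- function(n) {
  if (n > 8L) lm_stop("n", "exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
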