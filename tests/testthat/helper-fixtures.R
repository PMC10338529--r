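# Shared fixtures, generated in code and cached for the duration of a test
# run.  All cohorts here are deliberately small; the full study design
# (30 x 4 x 10) is exercised only where a test is about its counts.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 4 subjects x 4 conditions x 3 trials, default effect scales.
tiny_dataset <- function() {
  cached("tiny_dataset",
         generate_dataset(cohort_config(n_subjects = 4, n_trials = 3,
                                        rng_seed = 42)))
}

tiny_prep <- function() {
  cached("tiny_prep", preprocess_dataset(tiny_dataset()))
}

# A cheap footwear-task CV on the tiny cohort, reused by several tests.
tiny_cv_footwear <- function() {
  cached("tiny_cv_footwear", {
    prep <- tiny_prep()
    run_task("footwear", prep$features, prep$metadata, seed = 3,
             grid = c_grid(by = 5))
  })
}

# Linearly separable 3-class toy problem in 2-D with well-separated means.
toy_three_class <- function(n_per = 8, seed = 1) {
  with_seed_local(seed, {
    centers <- rbind(a = c(0, 0), b = c(6, 0), c = c(0, 6))
    x <- do.call(rbind, lapply(rownames(centers), function(cl)
      sweep(matrix(rnorm(2 * n_per, 0, 0.3), ncol = 2), 2,
            centers[cl, ], "+")))
    list(x = x, y = factor(rep(rownames(centers), each = n_per)))
  })
}

# Seed helper local to the tests (the package's with_seed is internal).
with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# Analytic magnitude response of the bidirectional (two-pass) digital
# Butterworth low-pass of order `ord`, including the bilinear-transform
# frequency prewarping: |H(f)|^2 with Omega = tan(pi f / fs) / tan(pi fc / fs).
butter2_bidir_gain <- function(f, fs, fc, ord = 2) {
  omega <- tan(pi * f / fs) / tan(pi * fc / fs)
  1 / (1 + omega^(2 * ord))
}
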