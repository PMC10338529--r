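# Filtering, stance detection, time normalisation, body-weight scaling,
# feature assembly and training-scoped min-max scaling.

test_that("zero-phase filter has unit DC gain and keeps zeros", {
  x <- rep(3.7, 200)
  expect_equal(lowpass_filter(x, 1000), x, tolerance = 1e-8)
  expect_equal(lowpass_filter(rep(0, 100), 1000), rep(0, 100))
})

test_that("filter attenuation matches the analytic Butterworth response", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  mid <- 301:700      # steady state; an integer number of cycles for all f
  for (f in c(10, 80, 200)) {
    y <- lowpass_filter(sin(2 * pi * f * t), fs)
    gain <- sqrt(2 * mean(y[mid]^2))    # RMS amplitude of the sinusoid
    expect_equal(gain, butter2_bidir_gain(f, fs, 50), tolerance = 2e-3)
  }
})

test_that("filter is linear and validates its input", {
  set.seed(1)
  a <- rnorm(150); b <- rnorm(150)
  lhs <- lowpass_filter(2 * a - 3 * b, 1000)
  rhs <- 2 * lowpass_filter(a, 1000) - 3 * lowpass_filter(b, 1000)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(lowpass_filter(rnorm(5), 1000), "need >= 7")
  expect_error(lowpass_filter(rnorm(100), 90), "twice the cutoff")
})

test_that("stance detection finds the longest supra-threshold run", {
  # same samples as the 0-based half-open window (2, 5)
  expect_equal(unname(detect_stance(c(0, 0, 12, 50, 12, 0))), c(3, 5))
  expect_error(detect_stance(rep(5, 10)), "no stance detected")
  # longest run wins over an earlier shorter one
  v <- c(0, 20, 0, 15, 30, 40, 12, 0)
  expect_equal(unname(detect_stance(v)), c(4, 7))
  # strict comparison: a sample exactly at the threshold is outside
  expect_equal(unname(detect_stance(c(10, 11, 10))), c(2, 2))
})

test_that("detected stance length matches the configured duration", {
  cohort <- generate_cohort(cohort_config(n_subjects = 1, rng_seed = 21))
  subj <- cohort$subjects[[1]]
  subj$signature[["stance_ms"]] <- 250
  fw <- footwear_effect("neutral")           # no offsets
  rec <- generate_recording(subj, fw, noise_scale = 0, seed = 2)
  filt <- lowpass_filter(rec$samples, rec$sampling_rate)
  win <- detect_stance(filt[, "V"])
  expect_lt(abs((win["end"] - win["start"] + 1) - 250), 10)
})

test_that("time normalisation interpolates linearly onto 101 points", {
  x <- sin(seq(0, 3, length.out = 101))
  expect_equal(time_normalize(x), x, tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = 57)
  expect_equal(time_normalize(ramp), seq(0, 1, length.out = 101),
               tolerance = 1e-12)
  tt <- seq(0, 1, length.out = 250)
  out <- time_normalize(sin(pi * tt))
  expect_lt(max(abs(out - sin(pi * seq(0, 1, length.out = 101)))), 1e-3)
  # endpoints are preserved exactly
  y <- rnorm(30)
  expect_equal(time_normalize(y)[c(1, 101)], y[c(1, 30)])
  expect_error(time_normalize(1), "at least 2")
})

test_that("body-weight normalisation scales to %BW", {
  expect_equal(normalize_body_weight(800, 800), 100)
  expect_equal(normalize_body_weight(rep(0, 5), 700), rep(0, 5))
  expect_error(normalize_body_weight(1, 0), "positive")
  expect_error(normalize_body_weight(1, -3), "positive")
})

test_that("configured active peak survives the full preprocessing chain", {
  cohort <- generate_cohort(cohort_config(n_subjects = 1, rng_seed = 31))
  subj <- cohort$subjects[[1]]
  subj$signature[["act_mag"]] <- 250
  rec <- generate_recording(subj, footwear_effect("neutral"),
                            noise_scale = 0, seed = 9)
  sc <- stance_curves(rec)
  expect_length(sc$v, 101)
  expect_lt(abs(max(sc$v) - 250), 5)
})

test_that("feature vectors concatenate ML, AP, V in fixed order", {
  sc <- structure(list(ml = rep(1, 101), ap = rep(2, 101), v = rep(3, 101),
                       stance_duration_ms = 250, subject_id = 1,
                       footwear_id = "barefoot", trial_id = 1),
                  class = "stance_curves")
  fv <- build_feature_vector(sc)
  expect_length(fv, 303)
  expect_equal(unique(fv[1:101]), 1)
  expect_equal(unique(fv[102:202]), 2)
  expect_equal(unique(fv[203:303]), 3)
  # slicing recovers the curves exactly
  expect_identical(fv[1:101], sc$ml)
  expect_identical(fv[203:303], sc$v)
  sc$ap <- sc$ap[-1]
  expect_error(build_feature_vector(sc), "unequal")
})

test_that("min-max scaling is fitted on training data only", {
  x <- rbind(c(0, 5, 7), c(10, 5, 9))
  sc <- fit_minmax(x)
  expect_equal(unname(apply_minmax(sc, x)[, 1]), c(0, 1))
  # test values outside the training range are not clipped
  expect_equal(unname(apply_minmax(sc, c(12, 5, 8))), c(1.2, 0, 0.5))
  # degenerate (constant) training inputs map every value to 0
  expect_equal(unname(apply_minmax(sc, c(0, 99, 7))[2]), 0)
  expect_error(apply_minmax(list(), 1:3), "not been fitted")
  expect_error(fit_minmax(matrix(1, 1, 3)), "at least 2")
})

test_that("scaler parameters are untouched by test-set perturbations", {
  prep <- tiny_prep()
  train <- 1:30
  s1 <- fit_minmax(prep$features[train, ])
  perturbed <- prep$features
  perturbed[-train, ] <- perturbed[-train, ] * 5 + 100
  s2 <- fit_minmax(perturbed[train, ])
  expect_identical(s1, s2)
})

test_that("preprocessing yields 101 x 3 values for every recording", {
  prep <- tiny_prep()
  expect_equal(dim(prep$features), c(48, 303))
  expect_true(all(is.finite(prep$features)))
  expect_true(all(vapply(prep$curves, function(s)
    length(s$ml) == 101 && length(s$ap) == 101 && length(s$v) == 101,
    logical(1))))
})
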