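# Time-continuous SPM ANOVA and the time-discrete variable machinery.

test_that("pointwise F equals t^2 for two groups", {
  set.seed(4)
  y <- matrix(rnorm(20 * 101), 20, 101)
  g <- rep(c("a", "b"), each = 10)
  res <- spm_anova(y, g, n_perm = 10, seed = 1)
  t2 <- vapply(seq_len(101), function(j)
    unname(t.test(y[g == "a", j], y[g == "b", j],
                  var.equal = TRUE)$statistic)^2, numeric(1))
  expect_equal(res$F, t2, tolerance = 1e-10)
})

test_that("near-identical groups rarely produce significant clusters", {
  # under the exchangeable null the FWER is ~5%, so over 10 datasets the
  # number of rejections should stay at binomial-noise level (P(X > 2) ~ 1%)
  rejections <- 0
  base <- sin(seq(0, pi, length.out = 101))
  for (s in 1:10) {
    set.seed(100 + s)
    y <- t(replicate(24, base + rnorm(101, 0, 1e-3)))
    res <- spm_anova(y, rep(1:4, each = 6), n_perm = 200, seed = s)
    rejections <- rejections + (nrow(res$clusters) > 0)
  }
  expect_lte(rejections, 2)
})

test_that("a localised group shift is detected where it was injected", {
  set.seed(11)
  base <- 100 * sin(seq(0, pi, length.out = 101))
  y <- t(replicate(40, base + rnorm(101, 0, 2)))
  g <- rep(1:4, each = 10)
  window <- 41:60                     # 40-59 %stance
  y[g == 4, window] <- y[g == 4, window] + 15
  res <- spm_anova(y, g, n_perm = 500, seed = 2)
  expect_gt(nrow(res$clusters), 0)
  expect_true(any(res$clusters$start <= 59 & res$clusters$end >= 40))
  # clusters are exactly the maximal supra-threshold runs
  r <- rle(res$F > res$f_crit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  expect_equal(res$clusters$start, starts[r$values] - 1)
  expect_equal(res$clusters$end, ends[r$values] - 1)
  expect_error(spm_anova(y, rep(1, 40)), "2 groups")
  expect_error(spm_anova(y[1:4, ], c(1, 1, 2, 3)), "2 curves per group")
})

test_that("discrete variables are located by the window rules", {
  t_pct <- 0:100
  # AP = -sin(2 pi t / 100): braking minimum at 25%, propulsion max at 75%
  ap <- -sin(2 * pi * t_pct / 100) * 30
  v <- 240 * sin(pi * t_pct / 100)    # single mid-stance maximum, no impact
  ml <- cos(2 * pi * t_pct / 100) * 5
  sc <- structure(list(ml = ml, ap = ap, v = v, stance_duration_ms = 250,
                       subject_id = 1, footwear_id = "a", trial_id = 1),
                  class = "stance_curves")
  d <- extract_discrete(sc)
  expect_true(is.na(d$v_impact_bw))   # no early local maximum
  expect_equal(d$v_active_t, 50)
  expect_equal(d$ap_brake_t, 25)
  expect_equal(d$ap_brake_bw, -30)
  expect_equal(d$ap_prop_t, 75)
  expect_equal(d$ap_prop_bw, 30)
  expect_equal(d$ml_max_t, 0)         # earliest of the tied maxima
  expect_true(d$ap_brake_bw <= 0 && d$ap_prop_bw >= 0)
})

test_that("impact and active peaks separate on a two-peak curve", {
  t_pct <- 0:100
  v <- 150 * exp(-0.5 * ((t_pct - 15) / 4)^2) +
    250 * exp(-0.5 * ((t_pct - 45) / 12)^2)
  sc <- structure(list(ml = t_pct * 0, ap = t_pct * 0, v = v,
                       stance_duration_ms = 250, subject_id = 1,
                       footwear_id = "a", trial_id = 1),
                  class = "stance_curves")
  d <- extract_discrete(sc)
  expect_equal(d$v_impact_t, 15, tolerance = 0.15)
  expect_equal(d$v_active_t, 45)
  expect_gt(d$v_active_t, d$v_impact_t)
  expect_equal(d$v_active_bw, max(v))
})

test_that("degenerate zero curves fall back to first-index ties", {
  z <- rep(0, 101)
  sc <- structure(list(ml = z, ap = z, v = z, stance_duration_ms = 250,
                       subject_id = 1, footwear_id = "a", trial_id = 1),
                  class = "stance_curves")
  d <- extract_discrete(sc)
  expect_true(is.na(d$v_impact_bw))
  expect_equal(d$v_active_bw, 0)
  expect_equal(d$ap_brake_bw, 0)
  expect_equal(d$ml_max_t, 0)
  expect_equal(d$ml_min_t, 0)
})

test_that("Kruskal-Wallis matches the hand-ranked oracle", {
  # groups {1,2,3}, {4,5,6}, {7,8,9}: ranks are the values themselves;
  # H = 12/(N(N+1)) * sum n_g (rbar_g - rbar)^2 = 12/90 * 3*((2-5)^2+(8-5)^2) = 7.2
  kw <- kruskal_wallis(1:9, rep(1:3, each = 3))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))
  expect_equal(kruskal_wallis(rep(5, 12), rep(1:3, 4))$H, 0)
  expect_error(kruskal_wallis(1:5, rep(1, 5)), "2 groups")
})

test_that("rank separation increases the two-group H statistic", {
  h1 <- kruskal_wallis(c(1, 3, 5, 2, 4, 6), rep(1:2, each = 3))$H
  h2 <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))$H
  expect_gt(h2, h1)
})

test_that("DSCF post-hoc table is symmetric with sensible p-values", {
  set.seed(6)
  vals <- c(rnorm(10), rnorm(10), rnorm(10), rnorm(10) + 10)
  grp <- rep(letters[1:4], each = 10)
  res <- dscf_posthoc(vals, grp)
  expect_true(isSymmetric(res$p))
  expect_true(all(is.na(diag(res$p))))
  # the shifted group's three comparisons are the three smallest p-values
  pd <- res$p["d", c("a", "b", "c")]
  others <- res$p[upper.tri(res$p)]
  expect_lte(max(pd), min(others[others > 0 & !others %in% pd], na.rm = TRUE))
  expect_true(all(pd < 0.05))
  # near-identical groups give p ~ 1
  same <- dscf_posthoc(c(rnorm(15), rnorm(15)), rep(1:2, each = 15))
  expect_gt(same$p[1, 2], 0.05)
  # untestable pair is NA
  tiny <- dscf_posthoc(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c"))
  expect_true(is.na(tiny$p["a", "c"]))
  expect_false(is.na(tiny$p["a", "b"]))
})

test_that("identical groups give an exactly degenerate DSCF statistic", {
  res <- dscf_posthoc(rep(c(1, 2, 3), 4), rep(1:2, each = 6))
  expect_equal(res$W[1, 2], 0)
  expect_equal(res$p[1, 2], 1, tolerance = 1e-6)
})
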