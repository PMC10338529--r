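# Statistical evaluation of footwear effects on the normalised curves:
# time-continuous SPM-style one-way ANOVA with permutation-based
# family-wise control, and the classical time-discrete variables with
# Kruskal-Wallis and Dwass-Steel-Critchlow-Fligner post-hoc tests.

#' SPM-style one-way ANOVA over 1-D curves
#'
#' Computes the pointwise one-way ANOVA F statistic at every time point of
#' the curves and controls the family-wise error across the whole stance
#' phase with the permutation distribution of the maximum F: group labels
#' are permuted `n_perm` times, the maximum F over all time points is
#' recorded, and the critical threshold `F*` is its `1 - alpha` quantile.
#' Significant regions are the maximal contiguous runs with `F > F*`.
#'
#' @param curves numeric matrix, rows = curves (one channel), columns =
#'   time points (e.g. 101 = 0-100 %stance).
#' @param groups group labels (factor; >= 2 groups, >= 2 curves each).
#' @param alpha family-wise significance level (default 0.05).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return an object of class `spm_result`: the F trajectory, critical
#'   threshold `f_crit`, a data.frame of significant `clusters`
#'   (start/end in %stance, assuming columns span 0-100%), `alpha` and
#'   `n_perm`.
#' @export
spm_anova <- function(curves, groups, alpha = 0.05, n_perm = 1000,
                      seed = 1) {
  curves <- as.matrix(curves)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    stop("spm_anova needs at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("spm_anova needs at least 2 curves per group", call. = FALSE)
  g0 <- as.integer(groups) - 1L
  K <- nlevels(groups)
  f_obs <- pointwise_f(curves, g0, K)
  max_f <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    max(pointwise_f(curves, sample(g0), K))
  }, numeric(1)))
  f_crit <- as.numeric(quantile(max_f, 1 - alpha, type = 1))
  above <- f_obs > f_crit
  clusters <- if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    pct <- 100 / (ncol(curves) - 1)
    data.frame(start = (starts[keep] - 1L) * pct,
               end = (ends[keep] - 1L) * pct)
  } else data.frame(start = numeric(0), end = numeric(0))
  structure(list(F = f_obs, f_crit = f_crit, clusters = clusters,
                 alpha = alpha, n_perm = n_perm,
                 df = c(K - 1L, nrow(curves) - K)),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(
    "SPM one-way ANOVA: F(%d, %d), permutation F* = %.2f (alpha = %g, %d permutations)\n",
    x$df[1], x$df[2], x$f_crit, x$alpha, x$n_perm))
  if (nrow(x$clusters) == 0) cat("  no significant clusters\n")
  else for (i in seq_len(nrow(x$clusters)))
    cat(sprintf("  significant cluster: %.0f-%.0f %%stance\n",
                x$clusters$start[i], x$clusters$end[i]))
  invisible(x)
}

#' Extract the time-discrete GRF variables from stance curves
#'
#' Locates the classical discrete variables on 101-point curves: vertical
#' impact peak (first local maximum within the first third of stance;
#' marked missing if there is none) and active peak (global maximum after
#' the impact peak), anteroposterior braking peak (global minimum in the
#' first half) and propulsion peak (global maximum in the second half), and
#' the mediolateral extrema over the whole stance.  Magnitudes are in %BW,
#' times in %stance; ties go to the earliest time point.
#'
#' @param stance a `stance_curves` object.
#' @return a one-row data.frame with value/time columns for each variable
#'   (`v_impact`, `v_active`, `ap_brake`, `ap_prop`, `ml_max`, `ml_min`).
#' @export
extract_discrete <- function(stance) {
  stopifnot(inherits(stance, "stance_curves"))
  n <- length(stance$v)
  t_pct <- seq(0, 100, length.out = n)
  v <- stance$v; ap <- stance$ap; ml <- stance$ml

  # first strict-left local maximum with 0 < t <= 33 %stance
  interior <- 2:(n - 1)
  is_lmax <- v[interior] > v[interior - 1] & v[interior] >= v[interior + 1]
  cand <- interior[is_lmax & t_pct[interior] > 0 & t_pct[interior] <= 100 / 3]
  imp_i <- if (length(cand)) cand[1] else NA_integer_

  act_win <- if (!is.na(imp_i)) which(t_pct > t_pct[imp_i]) else seq_len(n)
  act_i <- act_win[which.max(v[act_win])]

  br_win <- which(t_pct > 0 & t_pct <= 50)
  br_i <- br_win[which.min(ap[br_win])]
  pr_win <- which(t_pct > 50 & t_pct < 100)
  pr_i <- pr_win[which.max(ap[pr_win])]

  mlmax_i <- which.max(ml)
  mlmin_i <- which.min(ml)

  data.frame(
    subject_id = stance$subject_id, footwear_id = stance$footwear_id,
    trial_id = stance$trial_id,
    v_impact_bw = if (is.na(imp_i)) NA_real_ else v[imp_i],
    v_impact_t = if (is.na(imp_i)) NA_real_ else t_pct[imp_i],
    v_active_bw = v[act_i], v_active_t = t_pct[act_i],
    ap_brake_bw = ap[br_i], ap_brake_t = t_pct[br_i],
    ap_prop_bw = ap[pr_i], ap_prop_t = t_pct[pr_i],
    ml_max_bw = ml[mlmax_i], ml_max_t = t_pct[mlmax_i],
    ml_min_bw = ml[mlmin_i], ml_min_t = t_pct[mlmin_i],
    stringsAsFactors = FALSE
  )
}

#' Discrete-variable table for a list of stance curves
#'
#' @param curves list of `stance_curves`.
#' @return data.frame with one row per recording, see [extract_discrete()].
#' @export
discrete_variables <- function(curves) {
  do.call(rbind, lapply(curves, extract_discrete))
}

#' Kruskal-Wallis test between footwear conditions
#'
#' Rank-based H statistic with tie correction and the chi-squared
#' approximation on `groups - 1` degrees of freedom (via
#' [stats::kruskal.test()]).  A fully degenerate input (all values
#' identical) returns `H = 0`, `p = 1`.
#'
#' @param values numeric observations of one discrete variable.
#' @param groups group labels.
#' @return list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2)
    stop("kruskal_wallis needs at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dwass-Steel-Critchlow-Fligner pairwise post-hoc test
#'
#' For every pair of groups, ranks are computed on that pair only; the
#' standardised (tie-corrected) rank-sum statistic `W` is referred to the
#' studentised-range distribution with `k` groups (infinite degrees of
#' freedom), i.e. `p = P(q_k > sqrt(2) |W|)`.  Pairs involving a group with
#' fewer than 2 observations are marked untestable (`NA`).
#'
#' @param values numeric observations.
#' @param groups group labels (k >= 2 groups).
#' @return list with symmetric matrices `p` and `W` (diagonal `NA`).
#' @export
dscf_posthoc <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2) stop("dscf_posthoc needs at least 2 groups", call. = FALSE)
  lev <- levels(groups)
  P <- W <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    vi <- values[groups == lev[i]]
    vj <- values[groups == lev[j]]
    ni <- length(vi); nj <- length(vj)
    if (ni < 2 || nj < 2) next
    m <- ni + nj
    r <- rank(c(vi, vj))
    Rj <- sum(r[(ni + 1):m])
    ties <- table(c(vi, vj))
    tie_term <- sum(ties^3 - ties) / (m * (m - 1))
    v <- (ni * nj / 24) * (m + 1 - tie_term)
    if (v <= 0) { W[i, j] <- W[j, i] <- 0; P[i, j] <- P[j, i] <- 1; next }
    w <- (Rj - nj * (m + 1) / 2) / sqrt(v)
    W[i, j] <- W[j, i] <- w
    P[i, j] <- P[j, i] <- ptukey(sqrt(2) * abs(w), nmeans = k, df = Inf,
                                 lower.tail = FALSE)
  }
  list(p = P, W = W)
}
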