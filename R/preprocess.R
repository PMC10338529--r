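# Raw recording -> 101-point, body-weight-normalised stance curves ->
# 303-value feature vectors with training-scoped min-max scaling.

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth design applied forward and backward
#' (bidirectional), giving zero phase shift and a doubled effective order;
#' no cutoff correction is applied, so the -3 dB point of a single pass sits
#' at `cutoff`.  Edges are handled by odd (point-symmetric) reflective
#' padding before the forward pass; the pad length, `5 * sampling_rate /
#' cutoff` samples (capped at the signal length), is chosen long enough for
#' the filter's zero-state startup transient to decay to numerical noise
#' within the pad.
#'
#' @param x numeric vector or T x k matrix of force samples; channels
#'   (columns) are filtered independently.
#' @param sampling_rate sampling rate in Hz; must exceed `2 * cutoff`.
#' @param cutoff low-pass cutoff frequency in Hz (default 50).
#' @param order filter order of a single pass (default 2).
#' @return filtered data with the same shape as `x`.
#' @export
lowpass_filter <- function(x, sampling_rate, cutoff = 50, order = 2) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  min_len <- 3 * order + 1
  if (n < min_len)
    stop(sprintf("input too short for filtering: %d samples, need >= %d",
                 n, min_len), call. = FALSE)
  if (sampling_rate <= 2 * cutoff)
    stop("sampling_rate must exceed twice the cutoff frequency",
         call. = FALSE)
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  pad <- min(n - 1, max(3 * order, ceiling(5 * sampling_rate / cutoff)))
  out <- apply(xm, 2, function(ch) {
    head_pad <- 2 * ch[1] - ch[(pad + 1):2]
    tail_pad <- 2 * ch[n] - ch[(n - 1):(n - pad)]
    padded <- c(head_pad, ch, tail_pad)
    fwd <- signal::filter(bf, padded)
    bwd <- rev(signal::filter(bf, rev(fwd)))
    as.numeric(bwd)[(pad + 1):(pad + n)]
  })
  if (vec) as.numeric(out) else {
    colnames(out) <- colnames(xm)
    out
  }
}

#' Detect the stance phase from the filtered vertical force
#'
#' The stance phase is the longest maximal contiguous run of samples
#' strictly above `threshold` (default 10 N); ties go to the earliest run.
#'
#' @param v_filtered filtered vertical force in newtons.
#' @param threshold detection threshold in newtons.
#' @return integer vector `c(start, end)`: first and last sample of the
#'   stance phase (1-based, inclusive).
#' @export
detect_stance <- function(v_filtered, threshold = 10) {
  above <- v_filtered > threshold
  if (!any(above))
    stop("no stance detected: no sample above ", threshold, " N",
         call. = FALSE)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(start = starts[best], end = ends[best])
}

#' Time-normalise a stance segment
#'
#' Piecewise-linear interpolation of a segment onto `n_points` evenly
#' spaced abscissae spanning the first to the last sample (so 101 points
#' correspond to 0-100% stance in 1% steps).
#'
#' @param segment numeric vector (length >= 2).
#' @param n_points number of output points (default 101).
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(segment, n_points = 101) {
  n <- length(segment)
  if (n < 2) stop("segment must contain at least 2 samples", call. = FALSE)
  approx(seq(0, 1, length.out = n), segment,
         xout = seq(0, 1, length.out = n_points))$y
}

#' Normalise forces to body weight
#'
#' @param x forces in newtons (any shape).
#' @param body_weight body weight in newtons for the recording's footwear
#'   condition; must be positive.
#' @return forces in %BW (`x * 100 / body_weight`).
#' @export
normalize_body_weight <- function(x, body_weight) {
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a single positive number", call. = FALSE)
  x * 100 / body_weight
}

#' Preprocess one raw recording into stance curves
#'
#' Applies the full processing chain of a single trial: zero-phase low-pass
#' filtering of all three channels, stance detection on the filtered
#' vertical force, cropping, time normalisation to `n_points` and body
#' weight scaling.
#'
#' @param recording a `grf_recording`.
#' @param cutoff filter cutoff in Hz.
#' @param threshold stance threshold in N.
#' @param n_points points per normalised curve (default 101).
#' @return an object of class `stance_curves` with elements `ml`, `ap`,
#'   `v` (each `n_points` values in %BW), `stance_duration_ms` and the
#'   recording's identifiers.
#' @export
stance_curves <- function(recording, cutoff = 50, threshold = 10,
                          n_points = 101) {
  stopifnot(inherits(recording, "grf_recording"))
  filt <- lowpass_filter(recording$samples, recording$sampling_rate,
                         cutoff = cutoff)
  win <- detect_stance(filt[, "V"], threshold = threshold)
  idx <- win["start"]:win["end"]
  crop <- filt[idx, , drop = FALSE]
  bw <- recording$body_weight
  structure(list(
    ml = normalize_body_weight(time_normalize(crop[, "ML"], n_points), bw),
    ap = normalize_body_weight(time_normalize(crop[, "AP"], n_points), bw),
    v  = normalize_body_weight(time_normalize(crop[, "V"], n_points), bw),
    stance_duration_ms = length(idx) * 1000 / recording$sampling_rate,
    subject_id = recording$subject_id, footwear_id = recording$footwear_id,
    trial_id = recording$trial_id
  ), class = "stance_curves")
}

#' Concatenate stance curves into a feature vector
#'
#' Fixed order ML, AP, V: positions 1-101 hold the mediolateral curve,
#' 102-202 the anteroposterior curve and 203-303 the vertical curve
#' (for the default 101-point normalisation).
#'
#' @param stance a `stance_curves` object.
#' @return numeric vector of length `3 * n_points`.
#' @export
build_feature_vector <- function(stance) {
  stopifnot(inherits(stance, "stance_curves"))
  n <- length(stance$ml)
  if (length(stance$ap) != n || length(stance$v) != n)
    stop("stance curves have unequal lengths", call. = FALSE)
  out <- c(stance$ml, stance$ap, stance$v)
  if (!all(is.finite(out)))
    stop("non-finite values in stance curves", call. = FALSE)
  out
}

#' Preprocess a whole dataset
#'
#' Runs [stance_curves()] and [build_feature_vector()] over every recording
#' of a dataset.
#'
#' @inheritParams stance_curves
#' @param dataset a `grf_dataset`.
#' @return a list with `features` (n x 3`n_points` matrix, unscaled),
#'   `curves` (list of `stance_curves`) and `metadata`.
#' @export
preprocess_dataset <- function(dataset, cutoff = 50, threshold = 10,
                               n_points = 101) {
  stopifnot(inherits(dataset, "grf_dataset"))
  curves <- lapply(dataset$recordings, stance_curves, cutoff = cutoff,
                   threshold = threshold, n_points = n_points)
  features <- t(vapply(curves, build_feature_vector,
                       numeric(3 * n_points)))
  list(features = features, curves = curves, metadata = dataset$metadata)
}

#' Per-input min-max scaler fitted on training data only
#'
#' `fit_minmax()` records the per-column minimum and maximum of the
#' training feature matrix; `apply_minmax()` maps values through
#' `(v - min) / (max - min)`.  Training values therefore land in \[0, 1\];
#' test values outside the training range are NOT clipped.  Degenerate
#' inputs (constant across the training set) map to 0.
#'
#' @param x training feature matrix (>= 2 rows) for `fit_minmax()`; any
#'   matrix or single vector with matching width for `apply_minmax()`.
#' @param scaler a fitted `minmax_scaler`.
#' @return `fit_minmax()` returns a `minmax_scaler`; `apply_minmax()`
#'   returns the scaled data with the shape of its input.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop("min-max scaling needs at least 2 training vectors", call. = FALSE)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 fitted = TRUE), class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @export
apply_minmax <- function(scaler, x) {
  if (!inherits(scaler, "minmax_scaler") || !isTRUE(scaler$fitted))
    stop("scaler has not been fitted", call. = FALSE)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(xm) != length(scaler$min))
    stop("feature width does not match the fitted scaler", call. = FALSE)
  rng <- scaler$max - scaler$min
  out <- sweep(xm, 2, scaler$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  if (vec) as.numeric(out) else out
}
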