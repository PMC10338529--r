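# Parametric GRF cohort generator.
#
# Every stance curve is built from a 9-parameter "signature":
#   imp_mag   vertical impact-peak magnitude   (%BW)
#   imp_t     impact-peak timing               (%stance)
#   act_mag   vertical active-peak magnitude   (%BW)
#   act_t     active-peak timing               (%stance)
#   br_mag    anteroposterior braking-peak magnitude   (%BW, stored positive)
#   pr_mag    anteroposterior propulsion-peak magnitude (%BW)
#   ml_amp    mediolateral oscillation amplitude (%BW)
#   ml_phase  mediolateral phase offset (rad)
#   stance_ms stance duration (ms)
#
# Sign convention (the axes themselves carry no canonical sign): vertical
# force is non-negative, anteroposterior is negative during braking and
# positive during propulsion, mediolateral oscillates with a positive
# (lateral) mean.

# Population distribution of the signature: mean, between-subject SD and
# within-subject (trial-to-trial) SD.  Values are typical of rearfoot
# running at self-selected speed: active peak ~2.5 BW, impact peak ~1.6 BW,
# AP peaks ~0.35 BW, ML ~0.1 BW, ground contact ~250 ms.
.sig_population <- function() {
  data.frame(
    param    = c("imp_mag", "imp_t", "act_mag", "act_t", "br_mag",
                 "pr_mag", "ml_amp", "ml_phase", "stance_ms"),
    mean     = c(160, 13, 250, 45, 35, 35, 8, 0, 250),
    sd_subj  = c(25, 2, 20, 3, 6, 6, 2.5, 0.6, 20),
    sd_trial = c(4, 1, 5, 1, 2, 2, 1, 0.15, 8),
    stringsAsFactors = FALSE
  )
}

# Default footwear conditions and their additive signature offsets.
# Barefoot: higher, earlier impact peak and shorter contact; cushioned shoes
# damp the impact transient and lengthen contact, with small shifts in the
# propulsion phase that differ between shoe constructions.
.footwear_defaults <- function() {
  off <- rbind(
    barefoot = c(30, -2, -5, -2,  3,  2,  1.0,  0.15, -15),
    shoe_A   = c(-10, 1,  5,  1, -2, -1, -1.0, -0.10,   8),
    shoe_B   = c(  8, 0,  8,  0,  4,  5,  0.5,  0.00,   4),
    shoe_C   = c( -5, 2, -6,  2, -4, -4, -0.5, -0.20,  12)
  )
  colnames(off) <- .sig_population()$param
  list(offsets = off, bw_delta = c(barefoot = 0, shoe_A = 3,
                                   shoe_B = 3.5, shoe_C = 4))
}

#' Configuration of a synthetic GRF cohort
#'
#' Bundles the design of a simulated running study: cohort size, number of
#' footwear conditions and trials, sampling rate, effect scales and the seed.
#' The default design is 30 subjects x 4 footwear conditions x 10 trials =
#' 1,200 recordings sampled at 1,000 Hz.
#'
#' @param n_subjects number of subjects (default 30).
#' @param n_conditions number of footwear conditions, at most 4 of the
#'   built-in conditions (barefoot plus three standardised shoes).
#' @param n_trials trials per subject x condition cell (default 10).
#' @param sampling_rate sampling rate in Hz (default 1000).
#' @param trial_noise_scale multiplier on trial-to-trial variability
#'   (signature jitter and smooth curve noise); 0 gives noise-free trials.
#' @param between_subject_scale multiplier on the between-subject SD of the
#'   signature parameters; 0 makes all subjects identical.
#' @param between_footwear_scale multiplier on the footwear offsets; 0
#'   removes all footwear effects.
#' @param rng_seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 30L, n_conditions = 4L,
                          n_trials = 10L, sampling_rate = 1000,
                          trial_noise_scale = 1,
                          between_subject_scale = 1,
                          between_footwear_scale = 1,
                          rng_seed = 1L) {
  if (n_subjects < 1 || n_conditions < 1 || n_trials < 1)
    stop("all cohort counts must be >= 1", call. = FALSE)
  if (n_conditions > 4)
    stop("at most 4 built-in footwear conditions are available",
         call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (trial_noise_scale < 0 || between_subject_scale < 0 ||
      between_footwear_scale < 0)
    stop("effect scales must be >= 0", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_conditions = as.integer(n_conditions),
    n_trials = as.integer(n_trials),
    sampling_rate = sampling_rate,
    trial_noise_scale = trial_noise_scale,
    between_subject_scale = between_subject_scale,
    between_footwear_scale = between_footwear_scale,
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

#' Draw subject signatures and footwear effects for a cohort
#'
#' Samples per-subject signature parameters from the population
#' distribution (SDs scaled by `between_subject_scale`) and builds the
#' footwear conditions (offsets scaled by `between_footwear_scale`).
#' Fully reproducible from `config$rng_seed`.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `subjects` (list of per-subject parameter
#'   sets) and `footwear` (list of footwear effects).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pop <- .sig_population()
  fw <- .footwear_defaults()
  with_seed(config$rng_seed, {
    subjects <- lapply(seq_len(config$n_subjects), function(s) {
      mass <- min(max(rnorm(1, 85.7, 7), 71.4), 100)
      sig <- rnorm(nrow(pop), pop$mean,
                   config$between_subject_scale * pop$sd_subj)
      names(sig) <- pop$param
      sig <- .constrain_signature(sig)
      structure(list(subject_id = s, body_mass = mass, signature = sig),
                class = "subject_params")
    })
    footwear <- lapply(seq_len(config$n_conditions), function(f) {
      structure(list(
        footwear_id = rownames(fw$offsets)[f],
        offsets = fw$offsets[f, ] * config$between_footwear_scale,
        bw_delta = unname(fw$bw_delta[f])
      ), class = "footwear_effect")
    })
    list(subjects = subjects, footwear = footwear)
  })
}

#' Construct a custom footwear effect
#'
#' A footwear condition is an additive offset on each signature parameter
#' plus a body-weight delta (shoe mass).  Useful for designing cohorts
#' where a footwear effect is confined to chosen curve parameters (e.g.
#' only the anteroposterior peaks).
#'
#' @param footwear_id condition label.
#' @param offsets named numeric vector of signature offsets; omitted
#'   parameters default to 0.  Valid names: `imp_mag`, `imp_t`, `act_mag`,
#'   `act_t`, `br_mag`, `pr_mag`, `ml_amp`, `ml_phase`, `stance_ms`.
#' @param bw_delta additive change of the measured body weight in newtons.
#' @return an object of class `footwear_effect`.
#' @export
footwear_effect <- function(footwear_id, offsets = numeric(0),
                            bw_delta = 0) {
  params <- .sig_population()$param
  full <- setNames(numeric(length(params)), params)
  if (length(offsets)) {
    bad <- setdiff(names(offsets), params)
    if (length(bad))
      stop("unknown signature parameters: ", paste(bad, collapse = ", "),
           call. = FALSE)
    full[names(offsets)] <- offsets
  }
  if (!all(is.finite(full)) || !is.finite(bw_delta))
    stop("footwear offsets must be finite", call. = FALSE)
  structure(list(footwear_id = as.character(footwear_id), offsets = full,
                 bw_delta = bw_delta), class = "footwear_effect")
}

# Keep a (possibly jittered) signature inside its physical domain.
.constrain_signature <- function(sig) {
  sig["imp_mag"] <- max(sig["imp_mag"], 20)
  sig["act_mag"] <- max(sig["act_mag"], 120)
  sig["br_mag"] <- max(sig["br_mag"], 5)
  sig["pr_mag"] <- max(sig["pr_mag"], 5)
  sig["ml_amp"] <- max(sig["ml_amp"], 0.5)
  sig["imp_t"] <- min(max(sig["imp_t"], 5), 30)
  sig["act_t"] <- min(max(sig["act_t"], sig["imp_t"] + 10), 70)
  sig["stance_ms"] <- min(max(sig["stance_ms"], 150), 400)
  sig
}

# Evaluate the stance-phase template at relative times tau in [0, 1].
# Returns a length(tau) x 3 matrix (%BW, columns ML, AP, V).
#
# V: a broad support hump (steep sin^0.5 shoulders, so the 10 N threshold is
# crossed within ~1 ms of nominal foot strike / toe-off) plus two Gaussian
# lobes (impact, active).  AP: negative braking lobe then positive
# propulsion lobe.  ML: tapered oscillation with a positive bias.  Lobe
# amplitudes are calibrated (2x2 linear solve) so the template attains the
# configured peak magnitudes exactly at the configured peak times.
grf_template <- function(p, tau) {
  t <- 100 * tau
  taper <- sin(pi * pmin(pmax(tau, 0), 1))
  taper[taper < 0] <- 0
  tap25 <- taper^0.25
  base_v <- 15 * taper^0.5
  g <- function(t, c, s) exp(-0.5 * ((t - c) / s)^2)

  lobes_v <- cbind(tap25 * g(t, p[["imp_t"]], 4),
                   tap25 * g(t, p[["act_t"]], 13))
  amp_v <- .calibrate_lobes(
    times = c(p[["imp_t"]], p[["act_t"]]),
    centers = c(p[["imp_t"]], p[["act_t"]]), sigmas = c(4, 13),
    targets = c(p[["imp_mag"]], p[["act_mag"]]) -
      15 * sin(pi * c(p[["imp_t"]], p[["act_t"]]) / 100)^0.5
  )
  v <- base_v + as.vector(lobes_v %*% amp_v)
  v[v < 0] <- 0

  # braking/propulsion lobes mirrored about mid-stance, so equal peak
  # magnitudes give a (numerically) zero net AP impulse
  lobes_ap <- cbind(tap25 * g(t, 25, 9), tap25 * g(t, 75, 9))
  amp_ap <- .calibrate_lobes(
    times = c(25, 75), centers = c(25, 75), sigmas = c(9, 9),
    targets = c(-p[["br_mag"]], p[["pr_mag"]])
  )
  ap <- as.vector(lobes_ap %*% amp_ap)

  ml <- p[["ml_amp"]] * tap25 *
    (sin(2 * pi * tau + p[["ml_phase"]]) + 0.3 * sin(pi * tau))

  cbind(ML = ml, AP = ap, V = v)
}

# Solve for two lobe amplitudes so the tapered Gaussian sum hits `targets`
# at `times`.
.calibrate_lobes <- function(times, centers, sigmas, targets) {
  tp <- sin(pi * times / 100)^0.25
  G <- outer(seq_along(times), seq_along(centers), function(i, j)
    tp[i] * exp(-0.5 * ((times[i] - centers[j]) / sigmas[j])^2))
  solve(G, targets)
}

#' Generate one raw GRF recording
#'
#' Builds a raw tri-axial force trace (in newtons, 1 kHz by default) for one
#' running trial: sub-threshold lead-in and lead-out noise flanking a single
#' stance phase drawn from the subject's signature plus the footwear
#' offsets.  Trial noise jitters the signature parameters (including stance
#' duration) and adds a smooth, edge-tapered perturbation to each channel.
#'
#' @param subject a subject parameter set from [generate_cohort()].
#' @param footwear a footwear effect from [generate_cohort()].
#' @param trial_id integer trial index.
#' @param noise_scale trial noise multiplier (0 = deterministic template).
#' @param seed integer seed for this trial.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `grf_recording`: a `samples` matrix (columns
#'   `ML`, `AP`, `V`, newtons), the sampling rate, identifiers and the
#'   per-condition body weight in newtons.
#' @export
generate_recording <- function(subject, footwear, trial_id = 1L,
                               noise_scale = 1, seed = 1L,
                               sampling_rate = 1000) {
  stopifnot(inherits(subject, "subject_params"),
            inherits(footwear, "footwear_effect"))
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  pop <- .sig_population()
  body_weight <- subject$body_mass * 9.81 + footwear$bw_delta

  with_seed(seed, {
    p <- subject$signature + footwear$offsets
    if (noise_scale > 0)
      p <- p + rnorm(length(p), 0, noise_scale * pop$sd_trial)
    p <- .constrain_signature(p)

    n_st <- max(2L, as.integer(round(p[["stance_ms"]] * sampling_rate / 1000)))
    tau <- seq(0, 1, length.out = n_st)
    curves <- grf_template(p, tau)                       # %BW

    if (noise_scale > 0) {
      knots <- seq(0, 1, length.out = 15)
      amp <- c(ML = 0.8, AP = 1.2, V = 2.5)              # %BW at scale 1
      envelope <- sin(pi * tau)^0.5
      for (ch in 1:3) {
        sm <- spline(knots, rnorm(15), xout = tau)$y
        curves[, ch] <- curves[, ch] + noise_scale * amp[ch] * envelope * sm
      }
      curves[, "V"] <- pmax(curves[, "V"], 0)
    }

    n_pad <- as.integer(round(0.1 * sampling_rate))
    pad_noise <- function(n) pmin(pmax(rnorm(n, 0, 0.8), -4), 4)
    lead_in <- cbind(pad_noise(n_pad), pad_noise(n_pad), abs(pad_noise(n_pad)))
    lead_out <- cbind(pad_noise(n_pad), pad_noise(n_pad), abs(pad_noise(n_pad)))
    samples <- rbind(lead_in, curves * body_weight / 100, lead_out)
    colnames(samples) <- c("ML", "AP", "V")

    structure(list(
      samples = samples, sampling_rate = sampling_rate,
      subject_id = subject$subject_id, footwear_id = footwear$footwear_id,
      trial_id = as.integer(trial_id), body_weight = body_weight,
      params = p
    ), class = "grf_recording")
  })
}

#' Generate a full synthetic GRF dataset
#'
#' Expands a [cohort_config()] into `n_subjects x n_conditions x n_trials`
#' raw recordings plus a metadata table (one row per recording).  Cohort
#' parameters are drawn once from `rng_seed`; each trial uses its own seed
#' derived deterministically from (seed, subject, footwear, trial), so any
#' subset of the dataset can be regenerated independently.
#'
#' @param config a [cohort_config()].
#' @param cohort optionally, a (possibly modified) cohort from
#'   [generate_cohort()] to expand instead of drawing a fresh one; its
#'   `footwear` list may hold custom [footwear_effect()]s.
#' @return an object of class `grf_dataset`: `recordings` (list of
#'   [generate_recording()] outputs), `metadata` (data.frame with columns
#'   `recording`, `subject_id`, `footwear_id`, `trial_id`,
#'   `body_weight_N`), `cohort` and `config`.
#' @export
generate_dataset <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config)
  stopifnot(length(cohort$subjects) == config$n_subjects,
            length(cohort$footwear) == config$n_conditions)
  recs <- vector("list", config$n_subjects * config$n_conditions *
                   config$n_trials)
  meta <- vector("list", length(recs))
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (f in seq_len(config$n_conditions)) {
      for (tr in seq_len(config$n_trials)) {
        i <- i + 1L
        rec <- generate_recording(
          cohort$subjects[[s]], cohort$footwear[[f]], trial_id = tr,
          noise_scale = config$trial_noise_scale,
          seed = trial_seed(config$rng_seed, s, f, tr),
          sampling_rate = config$sampling_rate
        )
        recs[[i]] <- rec
        meta[[i]] <- data.frame(
          recording = i, subject_id = rec$subject_id,
          footwear_id = rec$footwear_id, trial_id = rec$trial_id,
          body_weight_N = rec$body_weight, stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(recordings = recs, metadata = do.call(rbind, meta),
                 cohort = cohort, config = config),
            class = "grf_dataset")
}

#' @export
print.grf_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic GRF dataset: %d recordings (%d subjects x %d conditions x %d trials) at %g Hz\n",
    nrow(x$metadata), cfg$n_subjects, cfg$n_conditions, cfg$n_trials,
    cfg$sampling_rate))
  invisible(x)
}

#' Write / read a GRF dataset as delimited text
#'
#' `write_grf_dataset()` stores one CSV per recording (columns `ML`, `AP`,
#' `V` in newtons) plus `metadata.csv` (recording path, subject, footwear,
#' trial, body weight, sampling rate).  `read_grf_dataset()` reads that
#' layout back.
#'
#' @param dataset a `grf_dataset`.
#' @param dir output (input) directory.
#' @return `write_grf_dataset()` returns the metadata file path invisibly;
#'   `read_grf_dataset()` returns a `grf_dataset` (without cohort
#'   parameters, which are not serialised).
#' @export
write_grf_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "grf_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dataset$metadata
  meta$path <- sprintf("rec_%04d.csv", meta$recording)
  meta$sampling_rate_hz <- vapply(dataset$recordings, `[[`, 0, "sampling_rate")
  for (i in seq_along(dataset$recordings))
    write.csv(as.data.frame(dataset$recordings[[i]]$samples),
              file.path(dir, meta$path[i]), row.names = FALSE)
  mf <- file.path(dir, "metadata.csv")
  write.csv(meta, mf, row.names = FALSE)
  invisible(mf)
}

#' @rdname write_grf_dataset
#' @export
read_grf_dataset <- function(dir) {
  mf <- file.path(dir, "metadata.csv")
  if (!file.exists(mf))
    stop("metadata file not found: ", mf, call. = FALSE)
  meta <- read.csv(mf, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    samples <- as.matrix(read.csv(file.path(dir, meta$path[i])))
    structure(list(
      samples = samples, sampling_rate = meta$sampling_rate_hz[i],
      subject_id = meta$subject_id[i], footwear_id = meta$footwear_id[i],
      trial_id = meta$trial_id[i], body_weight = meta$body_weight_N[i]
    ), class = "grf_recording")
  })
  structure(list(recordings = recs,
                 metadata = meta[, c("recording", "subject_id", "footwear_id",
                                     "trial_id", "body_weight_N")],
                 cohort = NULL, config = NULL),
            class = "grf_dataset")
}
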