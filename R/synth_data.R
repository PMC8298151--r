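#' Synthesis specification for a dysphonic sustained vowel
#'
#' Describes a sustained /a/-like vowel as a formant-filtered glottal pulse
#' train with controlled cycle-to-cycle perturbations: `jitter_pct` is the
#' target mean absolute cycle-to-cycle period difference relative to the mean
#' period (in percent), `shimmer_db` the target mean absolute cycle-to-cycle
#' peak-amplitude difference in dB, and `hnr_db` the target ratio of periodic
#' to aperiodic power in dB (use `Inf` for a noiseless vowel).
#'
#' @param f0 Fundamental frequency in Hz (60-400).
#' @param jitter_pct Target percent jitter (>= 0).
#' @param shimmer_db Target shimmer in dB (>= 0).
#' @param hnr_db Target harmonics-to-noise ratio in dB (may be `Inf`).
#' @param formants List of `c(center_hz, bandwidth_hz)` pairs; defaults to
#'   standard male /a/ values (700/130, 1220/170, 2600/250 Hz).
#' @param duration_s Duration in seconds.
#' @param rate Sample rate in Hz.
#' @param seed Integer seed controlling all randomness in the vowel.
#' @return An object of class `SynthesisSpec`.
#' @export
synthesis_spec <- function(f0 = 150, jitter_pct = 0.5, shimmer_db = 0.3,
                           hnr_db = 20,
                           formants = list(c(700, 130), c(1220, 170),
                                           c(2600, 250)),
                           duration_s = 2.0, rate = 44100, seed = 1L) {
  if (f0 < 60 || f0 > 400) stop("f0 must lie in [60, 400] Hz", call. = FALSE)
  if (jitter_pct < 0) stop("jitter_pct must be >= 0", call. = FALSE)
  if (shimmer_db < 0) stop("shimmer_db must be >= 0", call. = FALSE)
  if (is.na(hnr_db)) stop("hnr_db must be finite or Inf", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  structure(list(f0 = f0, jitter_pct = jitter_pct, shimmer_db = shimmer_db,
                 hnr_db = hnr_db, formants = formants,
                 duration_s = duration_s, rate = rate,
                 seed = as.integer(seed)),
            class = "SynthesisSpec")
}

# Rescale a zero-ish mean perturbation series so the realized mean |diff|
# equals `target` (two fixed-point passes suffice; |diff| scales linearly).
rescale_to_target <- function(x, target, realized_fun) {
  if (target == 0) return(numeric(length(x)))
  for (i in 1:2) {
    r <- realized_fun(x)
    if (r > 0) x <- x * target / r
  }
  x
}

# Windowed-sinc band-limited impulse train at fractional sample positions.
pulse_train <- function(positions, amplitudes, n, cutoff = 0.45,
                        half_width = 32L) {
  x <- numeric(n + 2L * half_width)
  k <- -half_width:half_width
  for (i in seq_along(positions)) {
    p <- positions[i]
    base <- floor(p)
    frac <- p - base
    t <- k - frac
    h <- 2 * cutoff * sinc(2 * cutoff * t) * hann_taper(t, half_width)
    idx <- base + k + half_width + 1L
    ok <- idx >= 1L & idx <= length(x)
    x[idx[ok]] <- x[idx[ok]] + amplitudes[i] * h[ok]
  }
  x[(half_width + 1L):(half_width + n)]
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
hann_taper <- function(t, hw) ifelse(abs(t) <= hw, 0.5 + 0.5 * cos(pi * t / hw), 0)

# Second-order resonator cascade (center, bandwidth pairs in Hz).
formant_filter <- function(x, formants, fs) {
  for (fm in formants) {
    r <- exp(-pi * fm[2] / fs)
    theta <- 2 * pi * fm[1] / fs
    a <- c(1, -2 * r * cos(theta), r^2)
    b <- sum(a)                      # unity gain at DC
    x <- as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
  }
  x
}

# Ideal FFT brickwall lowpass.
brickwall_lowpass <- function(x, fs, cutoff) {
  N <- length(x)
  X <- stats::fft(x)
  f <- (0:(N - 1)) * fs / N
  f <- pmin(f, fs - f)
  X[f > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / N
}

#' Synthesize a dysphonic sustained vowel
#'
#' Generates a formant-filtered glottal pulse train. Per-cycle periods are
#' `T0 * (1 + e_i)` with Gaussian `e_i` rescaled so the realized percent
#' jitter matches `spec$jitter_pct`; per-cycle amplitudes are perturbed in dB
#' analogously for shimmer. The glottal source has a -12 dB/octave spectral
#' rolloff (two one-pole lowpasses at f0). Formant-filtered Gaussian noise,
#' band-limited to 7.2 kHz (as is the harmonic part, so later decimation to
#' 16 kHz leaves the ratio untouched), is scaled so the realized
#' periodic-to-aperiodic power ratio equals `spec$hnr_db` exactly.
#'
#' @param spec A [synthesis_spec()].
#' @return A list with `rec` (the `Recording`), `marks` (ground-truth
#'   `CycleMarks`: realized per-cycle periods in seconds and relative
#'   per-cycle amplitudes), and `components` (the harmonic and noise parts
#'   before peak normalization, for power-calibration checks).
#' @export
synth_vowel <- function(spec) {
  if (!inherits(spec, "SynthesisSpec")) spec <- do.call(synthesis_spec, spec)
  fs <- spec$rate
  T0 <- 1 / spec$f0
  n_cycles <- ceiling(spec$duration_s / T0) + 4L
  withr::with_seed(spec$seed, {
    eps <- stats::rnorm(n_cycles, 0, (spec$jitter_pct / 100) / 1.1284)
    eps <- rescale_to_target(eps, spec$jitter_pct / 100,
      function(e) mean(abs(diff(e))) / mean(1 + e))
    if (any(1 + eps < 0.05))
      stop("jitter_pct too large: cycle periods collapse", call. = FALSE)
    periods <- T0 * (1 + eps)
    ddb <- stats::rnorm(n_cycles, 0, spec$shimmer_db / 1.1284)
    ddb <- rescale_to_target(ddb, spec$shimmer_db,
      function(d) mean(abs(diff(d))))
    amps <- 10^(ddb / 20)
    noise <- stats::rnorm(round(spec$duration_s * fs) + 1024L)
  })
  positions <- cumsum(periods) * fs          # first pulse after one period
  n <- round(spec$duration_s * fs)
  src <- pulse_train(positions, amps, n)
  # -12 dB/octave glottal rolloff: two one-pole lowpasses with cutoff at f0
  a1 <- exp(-2 * pi * spec$f0 / fs)
  for (i in 1:2)
    src <- as.numeric(signal::filter(signal::Arma(b = 1 - a1, a = c(1, -a1)),
                                     src))
  harm <- brickwall_lowpass(formant_filter(src, spec$formants, fs), fs, 7200)
  harm <- harm - mean(harm)   # no DC: mics are AC-coupled, and DC is not
                              # harmonic power for HNR purposes
  if (is.finite(spec$hnr_db)) {
    nz <- brickwall_lowpass(formant_filter(noise[seq_len(n)], spec$formants,
                                           fs), fs, 7200)
    nz <- nz - mean(nz)
    p_h <- mean(harm^2); p_n <- mean(nz^2)
    nz <- nz * sqrt(p_h / (p_n * 10^(spec$hnr_db / 10)))
    x <- harm + nz
  } else {
    nz <- numeric(n)
    x <- harm
  }
  x <- 0.5 * x / max(abs(x))
  marks <- cycle_marks(periods = periods, amplitudes = amps,
                       voiced_fraction = 1)
  list(rec = recording(x, fs, sprintf("synth_f0%g_seed%d", spec$f0,
                                      spec$seed)),
       marks = marks,
       components = list(harmonic = harm, noise = nz))
}

#' Generate a cohort of synthetic vowels with known ground truth
#'
#' Draws `n` synthesis parameter sets uniformly from `param_ranges` and
#' synthesizes one vowel per set. The default ranges span mild to severe
#' dysphonia: f0 100-220 Hz, jitter 0.1-2 %, shimmer 0.1-1.5 dB,
#' HNR 5-30 dB.
#'
#' @param n Number of recordings (>= 2).
#' @param param_ranges Named list of `c(lo, hi)` ranges for `f0`,
#'   `jitter_pct`, `shimmer_db`, `hnr_db`.
#' @param seed Integer seed.
#' @param duration_s,rate Passed to each [synthesis_spec()].
#' @return A list with `recordings` (list of `Recording`) and `truth`
#'   (data.frame: source_id and the drawn parameters), aligned by row.
#' @export
synth_cohort <- function(n, param_ranges = list(), seed = 1L,
                         duration_s = 2.0, rate = 44100) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  ranges <- utils::modifyList(list(f0 = c(100, 220), jitter_pct = c(0.1, 2),
                                   shimmer_db = c(0.1, 1.5),
                                   hnr_db = c(5, 30)),
                              param_ranges)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[2] < rg[1])
      stop(sprintf("invalid range for '%s'", nm), call. = FALSE)
  }
  draws <- withr::with_seed(seed, {
    d <- data.frame(
      f0         = stats::runif(n, ranges$f0[1], ranges$f0[2]),
      jitter_pct = stats::runif(n, ranges$jitter_pct[1], ranges$jitter_pct[2]),
      shimmer_db = stats::runif(n, ranges$shimmer_db[1], ranges$shimmer_db[2]),
      hnr_db     = stats::runif(n, ranges$hnr_db[1], ranges$hnr_db[2]))
    d$vowel_seed <- sample.int(.Machine$integer.max - 1L, n)
    d
  })
  recs <- vector("list", n)
  ids <- sprintf("v%03d", seq_len(n))
  for (i in seq_len(n)) {
    sp <- synthesis_spec(f0 = draws$f0[i], jitter_pct = draws$jitter_pct[i],
                         shimmer_db = draws$shimmer_db[i],
                         hnr_db = draws$hnr_db[i], duration_s = duration_s,
                         rate = rate, seed = draws$vowel_seed[i])
    recs[[i]] <- synth_vowel(sp)$rec
    recs[[i]]$source_id <- ids[i]
  }
  truth <- cbind(data.frame(source_id = ids, stringsAsFactors = FALSE),
                 draws[c("f0", "jitter_pct", "shimmer_db", "hnr_db")])
  list(recordings = recs, truth = truth)
}

#' Simulated VAS rater panel
#'
#' Defines a panel of raters scoring perceived vowel quality on a 0-100
#' visual-analogue scale (mm on a 10-cm line). Each rater's score is
#' `clip(quality_map(params) + bias_r + N(0, rater_noise_sd), 0, 100)`. The
#' default `quality_map` is a logistic function of the synthesis parameters,
#' `100 * plogis(0.09 * (hnr_db - 1.5) - 0.675 * jitter_pct -
#' 0.5625 * shimmer_db)`, calibrated so the default cohort's consensus
#' ratings have mean near 55 and SD near 18 VAS units.
#'
#' @param n_raters Number of raters (>= 1).
#' @param rater_bias Per-rater additive bias in VAS units (recycled).
#' @param rater_noise_sd Per-rating Gaussian noise SD in VAS units.
#' @param quality_map Function `(hnr_db, jitter_pct, shimmer_db) -> mean VAS`.
#' @param seed Integer seed.
#' @return An object of class `RaterPanelSpec`.
#' @export
rater_panel_spec <- function(n_raters = 3L, rater_bias = c(-5, 0, 5),
                             rater_noise_sd = 8,
                             quality_map = default_quality_map,
                             seed = 1L) {
  if (n_raters < 1) stop("n_raters must be >= 1", call. = FALSE)
  if (rater_noise_sd < 0) stop("rater_noise_sd must be >= 0", call. = FALSE)
  structure(list(n_raters = as.integer(n_raters),
                 rater_bias = rep_len(rater_bias, n_raters),
                 rater_noise_sd = rater_noise_sd,
                 quality_map = quality_map, seed = as.integer(seed)),
            class = "RaterPanelSpec")
}

#' @rdname rater_panel_spec
#' @param hnr_db,jitter_pct,shimmer_db Synthesis ground-truth parameters.
#' @export
default_quality_map <- function(hnr_db, jitter_pct, shimmer_db) {
  100 * stats::plogis(0.09 * (hnr_db - 1.5) - 0.675 * jitter_pct -
                        0.5625 * shimmer_db)
}

#' Simulate VAS ratings for a synthetic cohort
#'
#' @param truth Ground-truth data.frame from [synth_cohort()] (columns
#'   `source_id`, `hnr_db`, `jitter_pct`, `shimmer_db`).
#' @param panel A [rater_panel_spec()].
#' @return A `RatingSet`: list with `source_id`, `per_rater` (m x k matrix),
#'   and `y` (consensus mean across raters).
#' @export
synth_ratings <- function(truth, panel = rater_panel_spec()) {
  if (!inherits(panel, "RaterPanelSpec")) stop("panel must be a RaterPanelSpec",
                                               call. = FALSE)
  m <- nrow(truth)
  if (is.null(m) || m < 1) stop("truth table is empty", call. = FALSE)
  base <- panel$quality_map(truth$hnr_db, truth$jitter_pct, truth$shimmer_db)
  per_rater <- withr::with_seed(panel$seed, {
    noise <- matrix(stats::rnorm(m * panel$n_raters, 0, panel$rater_noise_sd),
                    m, panel$n_raters)
    sweep(noise, 2, panel$rater_bias, "+") + base
  })
  per_rater <- pmin(pmax(per_rater, 0), 100)
  colnames(per_rater) <- sprintf("rater_%d", seq_len(panel$n_raters))
  rating_set(truth$source_id, per_rater)
}

#' Rating sets
#'
#' Container for per-recording, per-rater VAS scores; the consensus score `y`
#' is the row mean across raters.
#'
#' @param source_id Character vector of recording labels.
#' @param per_rater m x k numeric matrix of VAS scores.
#' @return An object of class `RatingSet`.
#' @export
rating_set <- function(source_id, per_rater) {
  per_rater <- as.matrix(per_rater)
  if (length(source_id) != nrow(per_rater))
    stop("source_id length must match per_rater rows", call. = FALSE)
  structure(list(source_id = as.character(source_id), per_rater = per_rater,
                 y = rowMeans(per_rater)),
            class = "RatingSet")
}

#' @export
print.RatingSet <- function(x, ...) {
  cat(sprintf("<RatingSet: %d recordings x %d raters, consensus mean %.1f (SD %.1f)>\n",
              nrow(x$per_rater), ncol(x$per_rater), mean(x$y),
              stats::sd(x$y)))
  invisible(x)
}
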