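# Analytic (Hilbert) band signals by frequency-domain filtering: the signal
# spectrum is weighted per channel, negative frequencies zeroed and positive
# doubled, and the result inverse-transformed. Returns the magnitude
# envelopes, one column per channel.
band_envelopes <- function(x, fs, weights) {
  N <- length(x)
  X <- stats::fft(x)
  pos <- 2:(ceiling(N / 2))                    # strictly positive frequencies
  mask <- numeric(N)
  mask[pos] <- 2
  mask[1] <- 1
  if (N %% 2 == 0) mask[N / 2 + 1] <- 1
  Xa <- X * mask
  Y <- weights * 0i
  for (j in seq_len(ncol(weights))) Y[, j] <- Xa * weights[, j]
  Mod(stats::mvfft(Y, inverse = TRUE)) / N
}

# Squared magnitude response of a 2nd-order resonant bandpass on a grid.
bandpass2_response <- function(f, fc, q = 2) {
  num <- (f * fc / q)^2
  den <- (fc^2 - f^2)^2 + num
  num / pmax(den, 1e-300)
}

#' Speech-to-reverberation modulation energy ratio (SRMR)
#'
#' The recording is decomposed by a 23-channel Gammatone filterbank with
#' ERB-spaced centers from 125 Hz to half the sampling rate; each channel's
#' temporal envelope (analytic-signal magnitude, resampled to 256 Hz) is
#' analysed by 8 overlapping second-order modulation bandpasses with centers
#' log-spaced from 4 to 128 Hz. SRMR is the total envelope-modulation energy
#' in modulation bands 1-4 divided by that in bands 5-8 (denominator floored
#' at 1e-10).
#'
#' @param rec A 16 kHz [recording()] of at least 1 s.
#' @param config A [pvq_config()].
#' @return Dimensionless non-negative ratio.
#' @export
srmr <- function(rec, config = pvq_config()) {
  stopifnot_recording(rec, min_dur = 1)
  grid <- modulation_energy_grid_srmr(rec, config)
  if (is.null(grid)) return(0)
  lo <- seq_len(config$srmr_n_mod / 2)
  sum(grid[, lo]) / max(sum(grid[, -lo]), 1e-10)
}

# 23 x 8 acoustic-by-modulation energy grid backing SRMR; NULL for silence.
modulation_energy_grid_srmr <- function(rec, config = pvq_config()) {
  x <- rec$samples
  if (all(x == 0)) {
    warning("silent input: SRMR undefined, returning 0")
    return(NULL)
  }
  fs <- rec$rate
  N <- length(x)
  f <- (0:(N - 1)) * fs / N
  f <- pmin(f, fs - f)
  cf <- erb_to_hz(seq(hz_to_erb(config$srmr_cf_min), hz_to_erb(fs / 2),
                      length.out = config$srmr_n_channels))
  W <- vapply(cf, function(c) sqrt(gammatone_response(f, c)), numeric(N))
  env <- band_envelopes(x, fs, W)
  env_ds <- apply(env, 2, fft_resample, fs_in = fs,
                  fs_out = config$srmr_env_rate)
  env_ds <- sweep(env_ds, 2, colMeans(env_ds))   # modulation = AC component
  Ne <- nrow(env_ds)
  Ef <- Mod(stats::mvfft(env_ds))^2
  fe <- (0:(Ne - 1)) * config$srmr_env_rate / Ne
  fe <- pmin(fe, config$srmr_env_rate - fe)
  mod_cf <- exp(seq(log(config$srmr_mod_lo), log(config$srmr_mod_hi),
                    length.out = config$srmr_n_mod))
  grid <- vapply(mod_cf, function(c)
    colSums(Ef * bandpass2_response(fe, c)), numeric(ncol(Ef)))
  pmax(grid, 0)
}

#' Modulation area (ModA)
#'
#' The recording is decomposed into 4 octave-wide acoustic bands (edges
#' 300-600-1200-2400-4800 Hz); each band's envelope (analytic-signal
#' magnitude, normalized by the band's RMS so the metric reflects modulation
#' shape rather than loudness) is lowpassed and downsampled to 20 Hz and
#' analysed by a 1/3-octave modulation filterbank with centers
#' `0.5 * 2^(k/3)` Hz up to 8 Hz. Per acoustic band, the area under the
#' modulation energy across centers is computed by trapezoidal integration
#' on a log-frequency axis; ModA is the mean of the 4 areas.
#'
#' @param rec A 16 kHz [recording()] of at least 1 s.
#' @param config A [pvq_config()].
#' @return Dimensionless non-negative area.
#' @export
moda <- function(rec, config = pvq_config()) {
  stopifnot_recording(rec, min_dur = 1)
  x <- rec$samples
  if (all(x == 0)) {
    warning("silent input: ModA undefined, returning 0")
    return(0)
  }
  fs <- rec$rate
  N <- length(x)
  f <- (0:(N - 1)) * fs / N
  f <- pmin(f, fs - f)
  edges <- config$moda_band_edges
  nb <- length(edges) - 1L
  W <- vapply(seq_len(nb), function(b)
    as.numeric(f >= edges[b] & f < edges[b + 1]), numeric(N))
  env <- band_envelopes(x, fs, W)
  rms <- sqrt(colMeans(env^2))
  ok <- rms > 0
  env <- sweep(env[, ok, drop = FALSE], 2, rms[ok], "/")
  er <- config$moda_env_rate
  env_ds <- apply(env, 2, fft_resample, fs_in = fs, fs_out = er)
  env_ds <- sweep(env_ds, 2, colMeans(env_ds))
  # zero-pad for a fine modulation-frequency grid before 1/3-octave sums
  Ne <- nrow(env_ds)
  pad <- 2^ceiling(log2(max(1024, Ne)))
  env_pad <- rbind(env_ds, matrix(0, pad - Ne, ncol(env_ds)))
  Ef <- Mod(stats::mvfft(env_pad))^2 / Ne
  fe <- (0:(pad - 1)) * er / pad
  centers <- config$moda_mod_lo * 2^((0:12) / 3)
  centers <- centers[centers <= config$moda_mod_hi + 1e-9]
  third <- 2^(1 / 6)
  E <- vapply(centers, function(c)
    colSums(Ef[fe >= c / third & fe < c * third, , drop = FALSE]),
    numeric(ncol(Ef)))
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  lf <- log2(centers)
  areas <- apply(E, 1, function(e)
    sum(0.5 * (e[-1] + e[-length(e)]) * diff(lf)))
  mean(areas)
}
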