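#' @useDynLib pvq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ERB-rate scale (Glasberg & Moore) and its inverse.
hz_to_erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

# Magnitude response of a 4th-order gammatone filter on a frequency grid,
# peak-normalized. Bandwidth is 1.019 x ERB(fc).
gammatone_response <- function(f, fc) {
  erb <- 24.7 * (4.37 * fc / 1000 + 1)
  b <- 1.019 * erb
  g <- (1 + ((f - fc) / b)^2)^(-2)   # |H|^2 of a 4th-order gammatone approx
  g / max(g)
}

# n_filters x n_bins matrix of squared magnitude responses with ERB-spaced
# center frequencies in [fmin, fmax].
gammatone_filterbank <- function(freqs, n_filters, fmin, fmax) {
  cf <- erb_to_hz(seq(hz_to_erb(fmin), hz_to_erb(fmax),
                      length.out = n_filters))
  t(vapply(cf, function(c) gammatone_response(freqs, c), numeric(length(freqs))))
}

# Orthonormal DCT-II matrix (k x n), rows = basis functions.
dct_matrix <- function(n, k = n) {
  m <- outer(0:(k - 1), 0:(n - 1),
             function(i, j) cos(pi * i * (2 * j + 1) / (2 * n)))
  m[1, ] <- m[1, ] * sqrt(1 / n)
  if (k > 1) m[2:k, ] <- m[2:k, ] * sqrt(2 / n)
  m
}

#' Gammatone-filterbank cepstral features (GFCC)
#'
#' Frames of 256 samples (hop 156 = 256 - 100 overlap) are Hamming-windowed
#' and their power spectra weighted by a 128-channel ERB-spaced Gammatone
#' filterbank (50 Hz - 8 kHz). Log filterbank energies are decorrelated by an
#' orthonormal DCT-II; coefficients 1-30 (c0, the frame energy, excluded)
#' and their first-order frame differences are averaged across frames to
#' give 60 named features `gfcc_01..gfcc_30`, `dgfcc_01..dgfcc_30`.
#'
#' @param rec A 16 kHz [recording()] of at least 1 s.
#' @param config A [pvq_config()].
#' @return Named numeric vector of length 60.
#' @export
gfcc_features <- function(rec, config = pvq_config()) {
  stopifnot_recording(rec, min_dur = 1)
  if (rec$rate != config$target_rate)
    stop("gfcc_features expects a 16 kHz recording; decimate first",
         call. = FALSE)
  fl <- config$gfcc_frame_len
  hop <- fl - config$gfcc_overlap
  fseq <- frame_signal(rec, fl, hop, config$gfcc_window)
  spec <- Mod(stats::mvfft(fseq$frames))^2
  half <- fl %/% 2 + 1L
  spec <- spec[seq_len(half), , drop = FALSE]
  freqs <- (seq_len(half) - 1) * rec$rate / fl
  fb <- gammatone_filterbank(freqs, config$gfcc_n_filters,
                             config$gfcc_fmin, config$gfcc_fmax)
  fbe <- fb %*% spec
  if (all(fbe < 1e-10))
    warning("silent input: log filterbank energies floored")
  logE <- log(pmax(fbe, 1e-10))
  D <- dct_matrix(config$gfcc_n_filters)
  keep <- if (config$gfcc_include_c0) seq_len(config$gfcc_n_coef) else
    1L + seq_len(config$gfcc_n_coef)
  cc <- D[keep, , drop = FALSE] %*% logE
  deltas <- cc[, -1L, drop = FALSE] - cc[, -ncol(cc), drop = FALSE]
  out <- c(rowMeans(cc), rowMeans(deltas))
  names(out) <- c(sprintf("gfcc_%02d", seq_len(config$gfcc_n_coef)),
                  sprintf("dgfcc_%02d", seq_len(config$gfcc_n_coef)))
  out
}

# Levinson-Durbin recursion: autocorrelation -> LP coefficients and
# prediction-error (excitation) variance.
levinson_durbin <- function(r, order) {
  a <- numeric(order)
  e <- r[1]
  if (e <= 0) return(list(a = a, err = 0))
  for (i in seq_len(order)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[seq_len(i - 1)] * r[i:2])
    k <- acc / e
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[seq_len(i - 1)] <- a[seq_len(i - 1)] - k * a[(i - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) { e <- max(e, 0); break }
  }
  list(a = a, err = e)
}

#' Linear-prediction quality-assessment features (LCQA)
#'
#' The recording is cut into 20 ms non-overlapping frames; each frame gets an
#' 18th-order LP model (autocorrelation method, Levinson-Durbin). From the
#' LP spectrum on a 512-bin grid, five per-frame descriptors are computed --
#' spectral flatness, excitation variance, signal variance, spectral
#' centroid, spectral dynamics (mean squared difference of consecutive
#' frames' log LP spectra, assigned to the later frame) -- plus the first
#' time-difference of each, 10 per-frame values in all. Their mean, variance,
#' skewness and kurtosis across frames form the 40 named features
#' `lcqa_01..lcqa_40` (descriptor-major order: 4 statistics for flatness,
#' then excitation variance, and so on).
#'
#' @param rec A 16 kHz [recording()] of at least 1 s.
#' @param config A [pvq_config()].
#' @return Named numeric vector of length 40.
#' @export
lcqa_features <- function(rec, config = pvq_config()) {
  stopifnot_recording(rec, min_dur = 1)
  if (rec$rate != config$target_rate)
    stop("lcqa_features expects a 16 kHz recording; decimate first",
         call. = FALSE)
  fs <- rec$rate
  fl <- round(config$lcqa_frame_ms / 1000 * fs)
  p <- config$lcqa_lp_order
  nb <- config$lcqa_n_spectrum
  fseq <- frame_signal(rec, fl, fl, "rectangular")
  X <- fseq$frames
  energies <- colSums(X^2)
  usable <- energies > 0
  if (sum(usable) < 10)
    stop("fewer than 10 usable frames", call. = FALSE)
  if (any(!usable)) warning(sprintf("%d zero-energy frame(s) skipped",
                                    sum(!usable)))
  X <- X[, usable, drop = FALSE]
  nf <- ncol(X)
  freqs <- (0:(nb - 1)) * (fs / 2) / nb
  omega <- outer(0:p, 2 * pi * freqs / fs)   # (p+1) x nb phase grid
  cosm <- cos(omega); sinm <- sin(omega)
  flat <- cent <- sigv <- excv <- numeric(nf)
  logS <- matrix(0, nb, nf)
  for (j in seq_len(nf)) {
    x <- X[, j]
    r <- as.numeric(stats::convolve(x, x, conj = TRUE, type = "open"))[fl:(fl + p)]
    ld <- levinson_durbin(r, p)
    sigv[j] <- r[1] / fl                       # frame power
    excv[j] <- ld$err / fl                     # LP residual power
    aa <- c(1, -ld$a)
    denom <- (colSums(aa * cosm))^2 + (colSums(aa * sinm))^2
    S <- pmax(excv[j], 1e-30) / pmax(denom, 1e-30)
    logS[, j] <- log(S)
    flat[j] <- exp(mean(log(S))) / mean(S)
    cent[j] <- sum(freqs * S) / sum(S)
  }
  dyn <- c(0, colMeans((logS[, -1L, drop = FALSE] -
                          logS[, -nf, drop = FALSE])^2))
  base <- cbind(flat, excv, sigv, cent, dyn)
  deltas <- rbind(0, diff(base))
  desc <- cbind(base, deltas)
  stats4 <- function(v) {
    m <- mean(v); va <- mean((v - m)^2)
    s <- if (va > 0) mean((v - m)^3) / va^1.5 else 0
    k <- if (va > 0) mean((v - m)^4) / va^2 - 3 else 0
    c(m, va, s, k)
  }
  out <- as.numeric(apply(desc, 2, stats4))
  names(out) <- sprintf("lcqa_%02d", seq_along(out))
  out
}
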