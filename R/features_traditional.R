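#' Cycle marks
#'
#' Per-glottal-cycle period and peak-amplitude series, the raw material of
#' jitter and shimmer. `periods` are seconds per cycle, `amplitudes` the peak
#' absolute amplitude of each cycle (dimensionless), and `voiced_fraction`
#' the proportion of analysis frames judged voiced.
#'
#' @param periods Positive numeric vector, seconds per cycle.
#' @param amplitudes Non-negative numeric vector, same length as `periods`.
#' @param voiced_fraction Proportion of voiced frames in \[0, 1\].
#' @return An object of class `CycleMarks`.
#' @export
cycle_marks <- function(periods, amplitudes, voiced_fraction) {
  if (length(periods) != length(amplitudes))
    stop("periods and amplitudes must have equal length", call. = FALSE)
  if (length(periods) && (any(periods <= 0) || any(amplitudes < 0)))
    stop("periods must be positive and amplitudes non-negative",
         call. = FALSE)
  structure(list(periods = as.numeric(periods),
                 amplitudes = as.numeric(amplitudes),
                 voiced_fraction = voiced_fraction),
            class = "CycleMarks")
}

#' @export
print.CycleMarks <- function(x, ...) {
  cat(sprintf("<CycleMarks: %d cycles, voiced fraction %.2f>\n",
              length(x$periods), x$voiced_fraction))
  invisible(x)
}

# Frame-wise normalized cross-correlation against the signal's own future,
# r(l) = sum_{t=1..L} x_{s+t} x_{s+t+l} / sqrt(E1 E2(l)), with the second
# segment allowed to extend past the frame so the overlap is always the full
# frame length (truncated-overlap within-frame autocorrelation is biased for
# pulse-train signals). The raw cross-correlation is band-limited in the lag,
# so it is interpolated EXACTLY to fractional lags by FFT zero-padding
# (factor `up`); vowel correlation peaks are sharp on the sample grid and
# 3-point parabolas misestimate them badly. A small octave penalty (0.02 per
# doubling) applied to the peak score avoids period-doubling at near-tied
# subharmonic peaks. Returns, per frame, the refined peak correlation and
# its fractional lag.
frame_autocorr <- function(x, fs, frame_len, hop, lag_min, lag_max, up = 8L) {
  # remove DC once, globally: per-frame demeaning of a pitch-pulse signal
  # (whose window mean depends on the partial cycle included) decorrelates
  # period-shifted segments and biases r, hence HNR, downward
  x <- x - mean(x)
  N <- length(x)
  L <- as.integer(frame_len)
  ext <- L + as.integer(lag_max)
  nf <- (N - ext) %/% hop + 1L
  if (nf < 1L) stop("recording too short for correlation analysis",
                    call. = FALSE)
  starts <- (seq_len(nf) - 1L) * hop          # 0-based frame starts
  G1 <- matrix(x[outer(seq_len(L), starts, "+")], L)
  G2 <- matrix(x[outer(seq_len(ext), starts, "+")], ext)
  nfft <- 2^ceiling(log2(ext))
  F1 <- stats::mvfft(rbind(G1, matrix(0, nfft - L, nf)))
  F2 <- stats::mvfft(rbind(G2, matrix(0, nfft - ext, nf)))
  P <- Conj(F1) * F2                          # cross-spectrum (Hermitian)
  half <- nfft %/% 2
  Pup <- rbind(P[1:half, , drop = FALSE],
               P[half + 1, , drop = FALSE] / 2,
               matrix(0, (up - 1L) * nfft - 1L, nf),
               Conj(P[half + 1, , drop = FALSE]) / 2,
               P[(half + 2):nfft, , drop = FALSE])
  Cf <- Re(stats::mvfft(Pup, inverse = TRUE)) / nfft
  # energy terms from a global cumulative sum; E2 interpolated at fractional lags
  cs <- cumsum(c(0, x^2))
  E1 <- cs[starts + L + 1L] - cs[starts + 1L]
  tau <- seq(lag_min, lag_max, by = 1 / up)
  fl_lo <- floor(tau); fr <- tau - fl_lo
  pos_lo <- outer(fl_lo, starts, "+")
  E2 <- (cs[pos_lo + L + 1L] * (1 - fr) + cs[pos_lo + L + 2L] * fr) -
    (cs[pos_lo + 1L] * (1 - fr) + cs[pos_lo + 2L] * fr)
  dim(E2) <- c(length(tau), nf)
  num <- Cf[round(tau * up) + 1L, , drop = FALSE]
  R <- num / sqrt(pmax(outer(rep(1, length(tau)), E1) * E2, 1e-300))
  score <- R - 0.02 * log2(tau / lag_min)
  i_star <- max.col(t(score), ties.method = "first")
  cols <- seq_len(nf)
  r_peak <- R[cbind(i_star, cols)]
  lag_star <- tau[i_star]
  # parabolic touch-up on the fine grid
  ok <- i_star > 1L & i_star < length(tau)
  if (any(ok)) {
    y1 <- R[cbind(i_star[ok] - 1L, which(ok))]
    y2 <- r_peak[ok]
    y3 <- R[cbind(i_star[ok] + 1L, which(ok))]
    d2 <- y1 - 2 * y2 + y3
    better <- is.finite(d2) & d2 < 0
    adj <- ifelse(better, y2 - (y1 - y3)^2 / (8 * d2), y2)
    r_peak[ok] <- pmax(adj, y2)
    lag_star[ok] <- lag_star[ok] +
      ifelse(better, 0.5 * (y1 - y3) / d2 / up, 0)
  }
  list(r_max = r_peak, r_refined = r_peak, lag = lag_star, n_frames = nf)
}

# Band-limited (sinc) interpolation of a sampled cross-correlation around its
# coarse maximum: y holds values at consecutive integer offsets, j indexes the
# coarse peak. Returns the refined offset (in index units) and peak value.
sinc_refine <- function(y, j, step = 1 / 16, span = 1.5) {
  n <- length(y)
  taus <- seq(max(1, j - span), min(n, j + span), by = step)
  i <- seq_len(n)
  vals <- vapply(taus, function(tau) sum(y * sinc(tau - i)), numeric(1))
  k <- which.max(vals)
  pos <- taus[k]; val <- vals[k]
  if (k > 1 && k < length(vals)) {
    d2 <- vals[k - 1] - 2 * vals[k] + vals[k + 1]
    if (is.finite(d2) && d2 < 0) {
      pos <- pos + 0.5 * (vals[k - 1] - vals[k + 1]) / d2 * step
      val <- parabolic_peak_value(vals[k - 1], vals[k], vals[k + 1])
    }
  }
  list(pos = pos, val = val)
}

# Parabolic vertex value through three equally spaced points.
parabolic_peak_value <- function(y1, y2, y3) {
  d2 <- y1 - 2 * y2 + y3
  if (!is.finite(d2) || d2 >= 0) return(y2)
  y2 - (y1 - y3)^2 / (8 * d2)
}

#' Track glottal cycles
#'
#' Frame-wise f0 by normalized autocorrelation in the `[1/f0_max, 1/f0_min]`
#' lag range establishes voicing and a median period; cycle anchors are then
#' found by picking one waveform peak per estimated period, and each
#' cycle-to-cycle period is refined to sub-sample precision by parabolic
#' interpolation of the local waveform cross-correlation. Recordings with
#' fewer than half their frames voiced return empty marks with
#' `voiced_fraction < 0.5`.
#'
#' @param rec A [recording()] of at least 0.5 s.
#' @param f0_min,f0_max f0 search range in Hz.
#' @return A [cycle_marks()] object.
#' @export
track_cycles <- function(rec, f0_min = 60, f0_max = 400) {
  stopifnot_recording(rec, min_dur = 0.5)
  x <- rec$samples; fs <- rec$rate
  frame_len <- round(0.04 * fs); hop <- round(0.01 * fs)
  lag_min <- max(2L, floor(fs / f0_max)); lag_max <- ceiling(fs / f0_min)
  ac <- frame_autocorr(x, fs, frame_len, hop, lag_min, lag_max)
  voiced <- ac$r_max > 0.45
  vf <- mean(voiced)
  if (vf < 0.5 || sum(voiced) < 3)
    return(cycle_marks(numeric(0), numeric(0), vf))
  T0 <- stats::median(ac$lag[voiced])

  # anchor peaks: start from the strongest extremum in the central third,
  # then march one period at a time in both directions
  mid <- seq.int(floor(length(x) / 3), ceiling(2 * length(x) / 3))
  p0 <- mid[which.max(abs(x[mid]))]
  s <- sign(x[p0]); if (s == 0) s <- 1
  xs <- s * x
  lo_f <- floor(0.65 * T0); hi_f <- ceiling(1.45 * T0)
  peaks_fwd <- integer(0); p <- p0
  repeat {
    w <- (p + lo_f):min(p + hi_f, length(x))
    if (length(w) < 3 || w[1] > length(x) - 2) break
    p <- w[which.max(xs[w])]
    peaks_fwd <- c(peaks_fwd, p)
  }
  peaks_bwd <- integer(0); p <- p0
  repeat {
    w <- max(p - hi_f, 1L):(p - lo_f)
    if (length(w) < 3 || w[length(w)] < 3) break
    p <- w[which.max(xs[w])]
    peaks_bwd <- c(peaks_bwd, p)
  }
  peaks <- c(rev(peaks_bwd), p0, peaks_fwd)
  # drop edge cycles whose correlation/amplitude windows would be clipped
  margin <- round(0.45 * T0) + 26L
  peaks <- peaks[peaks > margin & peaks <= length(x) - margin]
  K <- length(peaks)
  if (K < 4) return(cycle_marks(numeric(0), numeric(0), vf))

  # sub-sample periods via sinc-interpolated local cross-correlation around
  # adjacent anchors (the raw cross-correlation is band-limited, so values at
  # integer lags determine it at fractional lags)
  hw <- max(8L, round(0.45 * T0))
  half_lags <- 24L   # wide support keeps sinc-interpolation truncation low
  periods <- numeric(K - 1)
  for (i in seq_len(K - 1)) {
    a <- peaks[i]
    lag0 <- peaks[i + 1] - a
    i1 <- max(1L, a - hw); i2 <- min(length(x), a + hw)
    seg <- x[i1:i2]
    lags <- (lag0 - half_lags):(lag0 + half_lags)
    lags <- lags[i1 + lags >= 1 & i2 + lags <= length(x) & lags > 0]
    if (length(lags) < 5) { periods[i] <- lag0; next }
    e0 <- sum(seg^2)
    cc <- vapply(lags, function(l) {
      seg2 <- x[(i1 + l):(i2 + l)]
      sum(seg * seg2) / sqrt(e0 * sum(seg2^2) + 1e-300)
    }, numeric(1))
    ref <- sinc_refine(cc, which.max(cc))
    periods[i] <- lags[1] + ref$pos - 1
  }

  # per-cycle amplitudes as energy-equivalent peak (sqrt(2) x cycle RMS):
  # raw waveform peaks of formant-filtered voices are contaminated by
  # ringing from neighbouring cycles, which inflates shimmer by ~30%. The
  # energy window starts 0.2 T before each anchor peak so it contains one
  # whole glottal event (excitation precedes the waveform peak slightly).
  off <- round(0.2 * T0)
  amps <- vapply(seq_len(K - 1), function(i) {
    seg <- x[(peaks[i] - off):(peaks[i + 1] - off - 1L)]
    sqrt(2 * mean(seg^2))
  }, numeric(1))

  cycle_marks(periods / fs, amps, vf)
}

#' Percent jitter
#'
#' Mean absolute cycle-to-cycle period difference relative to the mean
#' period: `100 * mean(|T_i - T_(i-1)|) / mean(T)`.
#'
#' @param marks A [cycle_marks()] object with at least 3 cycles.
#' @return Percent jitter.
#' @export
jitter_percent <- function(marks) {
  if (length(marks$periods) < 3)
    stop("insufficient voicing: need at least 3 cycles", call. = FALSE)
  100 * mean(abs(diff(marks$periods))) / mean(marks$periods)
}

#' Shimmer in dB
#'
#' Mean absolute cycle-to-cycle peak-amplitude ratio in decibels:
#' `mean(|20 log10(A_(i+1) / A_i)|)`. Cycle pairs containing a zero
#' amplitude are excluded with a warning.
#'
#' @param marks A [cycle_marks()] object with at least 3 cycles.
#' @return Shimmer in dB.
#' @export
shimmer_db <- function(marks) {
  A <- marks$amplitudes
  if (length(A) < 3)
    stop("insufficient voicing: need at least 3 cycles", call. = FALSE)
  ratio <- A[-1] / A[-length(A)]
  bad <- !is.finite(ratio) | ratio <= 0
  if (any(bad)) {
    warning(sprintf("%d cycle pair(s) with zero amplitude excluded",
                    sum(bad)))
    ratio <- ratio[!bad]
  }
  if (!length(ratio))
    stop("no usable amplitude pairs", call. = FALSE)
  mean(abs(20 * log10(ratio)))
}

#' Harmonics-to-noise ratio in dB
#'
#' Frame-wise normalized autocorrelation: with `r` the (fractional-lag
#' refined) autocorrelation maximum in the f0 lag range, the frame HNR is
#' `10 log10(r / (1 - r))`; the recording HNR is the mean over voiced frames,
#' clamped to \[-10, 40\] dB.
#'
#' @param rec A [recording()].
#' @param f0_min,f0_max f0 search range in Hz.
#' @param config A [pvq_config()] supplying frame/hop durations and clamp.
#' @return HNR in dB.
#' @export
hnr_db <- function(rec, f0_min = 60, f0_max = 400, config = pvq_config()) {
  stopifnot_recording(rec, min_dur = 0.5)
  fs <- rec$rate
  frame_len <- round(config$hnr_frame_s * fs)
  hop <- round(config$hnr_hop_s * fs)
  lag_min <- max(2L, floor(fs / f0_max)); lag_max <- ceiling(fs / f0_min)
  ac <- frame_autocorr(rec$samples, fs, frame_len, hop, lag_min, lag_max)
  voiced <- ac$r_max > 0.45
  if (!any(voiced))
    stop("insufficient voicing: no voiced frames", call. = FALSE)
  r <- pmin(pmax(ac$r_refined[voiced], 1e-6), 1 - 1e-6)
  clamp <- config$hnr_clamp
  h <- pmin(pmax(10 * log10(r / (1 - r)), clamp[1]), clamp[2])
  min(max(mean(h), clamp[1]), clamp[2])
}

#' Smoothed cepstral peak prominence (CPPS) in dB
#'
#' Frame-wise real cepstra of the dB log-magnitude spectrum (1024-sample
#' frames, 2 ms hop) are smoothed by moving averages across time (10 frames)
#' and quefrency (10 bins); for each smoothed frame the cepstral peak in the
#' `[1/f0_max, 1/f0_min]` quefrency band is measured against a least-squares
#' line fit over quefrencies from 1 ms to the top of the search band, and
#' CPPS is the mean peak-minus-regression value across frames.
#'
#' @param rec A [recording()] of at least 1 s.
#' @param f0_min,f0_max f0 search range in Hz.
#' @param config A [pvq_config()].
#' @return CPPS in dB.
#' @export
cpps_db <- function(rec, f0_min = 60, f0_max = 400, config = pvq_config()) {
  stopifnot_recording(rec, min_dur = 1)
  fs <- rec$rate
  frame_len <- config$cpps_frame_len
  hop <- max(1L, round(config$cpps_hop_s * fs))
  fseq <- frame_signal(rec, frame_len, hop, "hamming")
  S <- log(Mod(stats::mvfft(fseq$frames))^2 + 1e-300)
  P <- Mod(stats::mvfft(S))^2                 # power cepstrum
  # moving-average smoothing in the linear power-cepstrum domain:
  # time (columns) then quefrency (rows)
  P <- t(apply(P, 1, running_mean, k = config$cpps_time_smooth))
  P <- apply(P, 2, running_mean, k = config$cpps_quef_smooth)
  cep <- 10 * log10(P + 1e-300)
  q <- (0:(frame_len - 1)) / fs
  band <- which(q >= 1 / f0_max & q <= 1 / f0_min)
  trend <- which(q >= 0.001 & q <= 1 / f0_min)
  qt <- q[trend]
  cpp <- vapply(seq_len(ncol(cep)), function(j) {
    fit <- stats::lm.fit(cbind(1, qt), cep[trend, j])
    i <- band[which.max(cep[band, j])]
    cep[i, j] - sum(fit$coefficients * c(1, q[i]))
  }, numeric(1))
  mean(cpp)
}

# Centered running mean with edge truncation (window k).
running_mean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half_lo <- (k - 1) %/% 2; half_hi <- k %/% 2
  cs <- cumsum(c(0, x))
  i1 <- pmax(seq_len(n) - half_lo, 1)
  i2 <- pmin(seq_len(n) + half_hi, n)
  (cs[i2 + 1] - cs[i1]) / (i2 - i1 + 1)
}
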