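test_that("WAV write/read round-trips within 16-bit quantization", {
  t <- (0:8819) / 44100
  x <- 0.7 * sin(2 * pi * 220 * t)
  rec <- recording(x, 44100, "rt")
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, path)
  back <- read_wav(path)
  expect_equal(back$rate, 44100)
  expect_equal(length(back$samples), length(x))
  expect_lt(max(abs(back$samples - x)), 2^-15)
  expect_identical(back$source_id, sub("\\.wav$", "", basename(path)))
})

test_that("full-scale PCM maps to 32767/32768 and empty files error", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(recording(c(1, -1, 0.5), 16000), path)
  back <- read_wav(path)
  expect_equal(back$samples[1], 32767 / 32768, tolerance = 1e-12)
  expect_equal(back$samples[2], -1)
  empty <- withr::local_tempfile(fileext = ".wav")
  file.create(empty)
  expect_error(read_wav(empty), "missing or empty")
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "missing or empty")
})

test_that("multichannel WAVs fall back to channel 1 with a warning", {
  # hand-assemble a 2-channel 16-bit PCM file
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  ch1 <- as.integer(c(1000, 2000, 3000)); ch2 <- as.integer(c(-1, -2, -3))
  inter <- as.integer(rbind(ch1, ch2))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(inter)), con, size = 4,
           endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(c(8000L, 32000L), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(inter)), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  expect_warning(rec <- read_wav(path), "channel 1")
  expect_equal(rec$samples * 32768, c(1000, 2000, 3000))
})

test_that("decimation produces exact 16 kHz output of the right length", {
  t <- (0:88199) / 44100
  rec <- recording(sin(2 * pi * 1000 * t), 44100)
  out <- decimate_to_16k(rec)
  expect_equal(out$rate, 16000)
  expect_equal(length(out$samples), 32000)
  same <- recording(sin(2 * pi * 100 * (0:15999) / 16000), 16000)
  expect_identical(decimate_to_16k(same), same)
  expect_error(decimate_to_16k(recording(rnorm(100), 8000)), "upsample")
})

test_that("decimation preserves band-limited content", {
  t <- (0:88199) / 44100
  x <- sin(2 * pi * 1000 * t)
  out <- decimate_to_16k(recording(x, 44100))
  spec <- Mod(fft(out$samples)) / length(out$samples) * 2
  f <- (0:(length(out$samples) - 1)) * 16000 / length(out$samples)
  peak <- max(spec[f > 990 & f < 1010])
  expect_lt(abs(peak - 1), 0.01)                       # amplitude within 1%
  # RMS of a <7 kHz band-limited mixture changes by < 1%
  x2 <- sin(2 * pi * 500 * t) + 0.5 * sin(2 * pi * 4000 * t) +
    0.25 * sin(2 * pi * 6500 * t)
  out2 <- decimate_to_16k(recording(x2, 44100))
  expect_lt(abs(sd(out2$samples) / sd(x2) - 1), 0.01)
})

test_that("central segment extraction is centered and guarded", {
  rec <- recording(seq_len(5 * 1000) / 5000, 1000)      # 5 s ramp at 1 kHz
  seg <- extract_central_segment(rec, 2)
  expect_equal(length(seg$samples), 2000)
  expect_equal(seg$samples[1], rec$samples[1501])       # starts at 1.5 s
  exact <- recording(rnorm(2000), 1000)
  expect_equal(extract_central_segment(exact, 2)$samples, exact$samples)
  expect_error(extract_central_segment(recording(rnorm(900), 1000), 2),
               "shorter")
})

test_that("frame counts follow floor((N - L)/hop) + 1 and windows apply", {
  rec <- recording(rnorm(32000), 16000)
  fs <- frame_signal(rec, 256, 156, "hamming")
  expect_equal(ncol(fs$frames), (32000 - 256) %/% 156 + 1)   # 204
  expect_equal(ncol(fs$frames), 204)
  one <- frame_signal(recording(rnorm(256), 16000), 256, 99)
  expect_equal(ncol(one$frames), 1)
  const <- frame_signal(recording(rep(1, 1000), 1000), 100, 50,
                        "rectangular")
  expect_true(all(const$frames == 1))
  expect_error(frame_signal(recording(rnorm(100), 1000), 200, 50), "exceeds")
  # fuzz the count formula
  withr::with_seed(42, {
    for (i in 1:100) {
      N <- sample(500:5000, 1)
      L <- sample(10:N, 1)
      hop <- sample(1:300, 1)
      fr <- frame_signal(recording(numeric(N), 1000), L, hop, "rectangular")
      expect_equal(ncol(fr$frames), (N - L) %/% hop + 1)
    }
  })
})
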