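test_that("cycle tracking recovers exact periods on clean vowels", {
  v <- test_vowel(f0 = 150, seed = 3)
  m <- track_cycles(v$rec16)
  expect_gt(m$voiced_fraction, 0.9)
  expect_true(all(abs(m$periods - 1 / 150) < 1 / 16000))   # within 1 sample
  # 100 Hz with 2% jitter: mean period 10 ms within 2%
  v2 <- test_vowel(f0 = 100, jitter = 2, shimmer = 0.3, hnr = 25, seed = 4)
  m2 <- track_cycles(v2$rec16)
  expect_lt(abs(mean(m2$periods) - 0.010) / 0.010, 0.02)
})

test_that("unvoiced input yields empty marks, not an error", {
  m <- track_cycles(test_noise(2))
  expect_lt(m$voiced_fraction, 0.5)
  expect_length(m$periods, 0)
  expect_error(jitter_percent(m), "insufficient")
  expect_error(shimmer_db(m), "insufficient")
})

test_that("jitter follows its defining arithmetic", {
  const <- cycle_marks(rep(0.01, 20), rep(1, 20), 1)
  expect_equal(jitter_percent(const), 0)
  alt <- cycle_marks(rep(c(0.0100, 0.0102), 10), rep(1, 20), 1)
  expect_equal(jitter_percent(alt), 100 * mean(abs(diff(rep(c(10, 10.2),
                                                            10)))) / 10.1,
               tolerance = 1e-9)
  expect_equal(round(jitter_percent(alt), 2), 1.98)
})

test_that("shimmer follows its defining arithmetic and skips zero cycles", {
  const <- cycle_marks(rep(0.01, 10), rep(0.5, 10), 1)
  expect_equal(shimmer_db(const), 0)
  alt <- cycle_marks(rep(0.01, 10), rep(c(1, 1.122), 5), 1)
  expect_equal(shimmer_db(alt), 20 * log10(1.122), tolerance = 1e-9)
  withz <- cycle_marks(rep(0.01, 5), c(1, 0, 1, 1, 1), 1)
  expect_warning(s <- shimmer_db(withz), "zero amplitude")
  expect_true(is.finite(s))
})

test_that("perturbation measures are invariant to global amplitude scaling", {
  v <- test_vowel(f0 = 130, jitter = 1, shimmer = 0.5, hnr = 20, seed = 6)
  scaled <- recording(3 * v$rec16$samples, 16000)
  m1 <- track_cycles(v$rec16); m2 <- track_cycles(scaled)
  expect_equal(jitter_percent(m1), jitter_percent(m2), tolerance = 1e-9)
  expect_equal(shimmer_db(m1), shimmer_db(m2), tolerance = 1e-9)
  expect_lt(abs(hnr_db(v$rec16) - hnr_db(scaled)), 0.2)
  expect_lt(abs(cpps_db(v$rec16) - cpps_db(recording(
    0.5 * v$rec16$samples, 16000))), 0.1)
})

test_that("HNR estimates are clamped and need voicing", {
  v <- test_vowel(f0 = 150, seed = 3)                    # noiseless
  h <- hnr_db(v$rec16)
  expect_gte(h, 35)
  expect_lte(h, 40)
  expect_error(hnr_db(test_noise(3)), "insufficient voicing")
})

test_that("all four traditional measures are deterministic", {
  v <- test_vowel(f0 = 150, jitter = 0.5, shimmer = 0.5, hnr = 15, seed = 8)
  expect_identical(jitter_percent(track_cycles(v$rec16)),
                   jitter_percent(track_cycles(v$rec16)))
  expect_identical(hnr_db(v$rec16), hnr_db(v$rec16))
  expect_identical(cpps_db(v$rec16), cpps_db(v$rec16))
})

test_that("CPPS separates periodic vowels from noise", {
  v <- test_vowel(f0 = 150, jitter = 0.3, shimmer = 0.3, hnr = 25, seed = 14)
  expect_gt(cpps_db(v$rec16) - cpps_db(test_noise(5)), 5)
  expect_error(cpps_db(recording(rnorm(4000), 16000)), "at least 1")
})
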