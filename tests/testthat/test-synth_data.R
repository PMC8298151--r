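test_that("noiseless jitter-free vowels are exactly periodic", {
  v <- test_vowel(f0 = 150, seed = 3)
  # use the central portion; the first cycles carry the filter ring-in
  x <- v$raw$rec$samples[8821:79380]
  T0 <- round(44100 / 150)
  num <- sum(x[1:(length(x) - T0)] * x[(T0 + 1):length(x)])
  den <- sqrt(sum(x[1:(length(x) - T0)]^2) * sum(x[(T0 + 1):length(x)]^2))
  expect_gt(num / den, 1 - 1e-3)
})

test_that("noise calibration hits the HNR target exactly at mixing time", {
  for (h in c(0, 10)) {
    v <- synth_vowel(synthesis_spec(f0 = 140, jitter_pct = 0.3,
                                    shimmer_db = 0.3, hnr_db = h, seed = 5,
                                    duration_s = 1))
    ratio <- 10 * log10(mean(v$components$harmonic^2) /
                          mean(v$components$noise^2))
    expect_lt(abs(ratio - h), 1)
  }
})

test_that("synthesis is deterministic and validates its spec", {
  a <- synth_vowel(synthesis_spec(seed = 7, duration_s = 0.6))
  b <- synth_vowel(synthesis_spec(seed = 7, duration_s = 0.6))
  expect_identical(a$rec$samples, b$rec$samples)
  expect_identical(a$marks$periods, b$marks$periods)
  expect_error(synthesis_spec(f0 = 30), "f0")
  expect_error(synthesis_spec(jitter_pct = -1), "jitter")
  expect_error(synth_vowel(synthesis_spec(jitter_pct = 80, seed = 1,
                                          duration_s = 0.6)),
               "collapse")
})

test_that("realized ground-truth perturbations match the spec values", {
  v <- synth_vowel(synthesis_spec(f0 = 150, jitter_pct = 1, shimmer_db = 0.8,
                                  hnr_db = 20, seed = 11, duration_s = 1))
  p <- v$marks$periods
  expect_lt(abs(100 * mean(abs(diff(p))) / mean(p) - 1) / 1, 0.10)
  a <- 20 * log10(v$marks$amplitudes)
  expect_lt(abs(mean(abs(diff(a))) - 0.8) / 0.8, 0.10)
})

test_that("cohorts have aligned truth tables and honour seeds and ranges", {
  co <- synth_cohort(5, seed = 2, duration_s = 0.6)
  expect_length(co$recordings, 5)
  expect_equal(nrow(co$truth), 5)
  expect_identical(vapply(co$recordings, function(r) r$source_id, ""),
                   co$truth$source_id)
  co2 <- synth_cohort(5, seed = 2, duration_s = 0.6)
  expect_identical(co$truth, co2$truth)
  # degenerate single-point ranges: recordings differ only by noise seed
  cd <- synth_cohort(2, param_ranges = list(f0 = c(150, 150),
                                            jitter_pct = c(0.5, 0.5),
                                            shimmer_db = c(0.3, 0.3),
                                            hnr_db = c(20, 20)),
                     seed = 3, duration_s = 0.6)
  expect_equal(cd$truth$f0, c(150, 150))
  expect_false(identical(cd$recordings[[1]]$samples,
                         cd$recordings[[2]]$samples))
  expect_error(synth_cohort(1), "n must be")
  expect_error(synth_cohort(3, param_ranges = list(hnr_db = c(30, 5))),
               "invalid range")
})

test_that("a noiseless panel reproduces the quality map exactly", {
  truth <- data.frame(source_id = sprintf("s%d", 1:8),
                      hnr_db = seq(5, 30, length.out = 8),
                      jitter_pct = rep(0.5, 8), shimmer_db = rep(0.3, 8))
  panel <- rater_panel_spec(rater_bias = 0, rater_noise_sd = 0, seed = 1)
  rs <- synth_ratings(truth, panel)
  expect_equal(rs$per_rater[, 1], rs$per_rater[, 2])
  expect_equal(icc(rs$per_rater + cbind(rnorm(8, 0, 1e-9), 0, 0),
                   "consistency_random"), 1, tolerance = 1e-6)
  # monotone map in hnr_db -> ratings rank-identical with hnr_db
  expect_identical(order(rs$y), order(truth$hnr_db))
})

test_that("the default rater panel gives good interrater reliability", {
  truth <- study_cohort()$truth
  rs <- synth_ratings(truth, rater_panel_spec(seed = 101))
  ic <- icc(rs$per_rater, "consistency_random")
  expect_gte(ic, 0.75)
  expect_lte(ic, 0.95)
  # consensus ratings span most of the VAS line
  expect_gte(diff(range(rs$y)), 60)
})
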