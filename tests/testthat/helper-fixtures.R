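# Shared, lazily built fixtures. Everything is generated in code; the cache
# avoids re-synthesizing the same vowel across test files.

.pvq_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.pvq_cache[[key]])) .pvq_cache[[key]] <- force(expr)
  .pvq_cache[[key]]
}

# A decimated 16 kHz synthetic vowel with the given perturbations.
test_vowel <- function(f0 = 150, jitter = 0, shimmer = 0, hnr = Inf,
                       seed = 1, duration = 2) {
  key <- paste("v", f0, jitter, shimmer, hnr, seed, duration, sep = "_")
  cached(key, {
    v <- synth_vowel(synthesis_spec(f0 = f0, jitter_pct = jitter,
                                    shimmer_db = shimmer, hnr_db = hnr,
                                    duration_s = duration, seed = seed))
    list(rec16 = decimate_to_16k(v$rec), raw = v)
  })
}

# Gaussian white noise recording at 16 kHz.
test_noise <- function(seed = 1, n = 32000) {
  cached(paste("nz", seed, n, sep = "_"),
         recording(withr::with_seed(seed, stats::rnorm(n)) * 0.1, 16000,
                   paste0("noise", seed)))
}

# The default 113-vowel study cohort with simulated ratings: used by the
# end-to-end ordering checks. Built once (about half a minute).
study_cohort <- function() {
  cached("cohort113", {
    co <- synth_cohort(113, seed = 101)
    tab <- extract_features(co$recordings,
                            features = c("traditional", "lcqa", "srmr",
                                         "moda", "rpde"))
    ratings <- synth_ratings(co$truth, rater_panel_spec(seed = 101))
    keep <- match(tab$source_ids, ratings$source_id)
    list(truth = co$truth, table = tab,
         ratings = rating_set(ratings$source_id[keep],
                              ratings$per_rater[keep, , drop = FALSE]))
  })
}

# Small planted-signal regression dataset for modeling tests.
planted_data <- function(m = 200, n_decoy = 17, noise = 0.1, seed = 9) {
  cached(paste("planted", m, n_decoy, noise, seed, sep = "_"), {
    withr::with_seed(seed, {
      X <- matrix(stats::rnorm(m * (3 + n_decoy)), m,
                  dimnames = list(NULL, sprintf("f%02d", seq_len(3 + n_decoy))))
      sig <- 2 * X[, 1] - X[, 2] + X[, 3]
      y <- sig + stats::rnorm(m, 0, noise * stats::sd(sig))
      list(X = X, y = y)
    })
  })
}
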