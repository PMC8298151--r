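test_that("Pearson correlation handles exact and degenerate cases", {
  a <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(a, a)$rho, 1)
  expect_equal(pearson_r(a, -a + 7)$rho, -1)
  withr::with_seed(2, {
    x <- rnorm(1000); y <- rnorm(1000)
  })
  expect_lt(abs(pearson_r(x, y)$rho), 0.1)
  expect_error(pearson_r(a, rep(1, 5)), "zero variance")
  expect_error(pearson_r(a, a[1:4]), "lengths")
  # p-value matches the t transform
  pr <- pearson_r(x, x + rnorm(1000))
  tstat <- pr$rho * sqrt(998 / (1 - pr$rho^2))
  expect_equal(pr$p_value, 2 * pt(-abs(tstat), 998), tolerance = 1e-12)
})

test_that("SDPE follows its closed form", {
  expect_equal(sdpe(18, 0), 18)
  expect_equal(sdpe(18, 1), 0)
  expect_equal(sdpe(18, -1), 0)
  sigma <- 17.26 / sqrt(1 - 0.28^2)
  expect_equal(round(sdpe(sigma, 0.80), 2), 10.79)
  expect_error(sdpe(-1, 0.5), "sigma_s")
  expect_error(sdpe(10, 1.5), "rho")
})

# Independent coding of the dependent-correlation Z test, written directly
# from the Fisher/Pearson-Filon algebra (kept deliberately separate from the
# package implementation).
steiger_oracle <- function(r1, r2, r12, n) {
  fz <- function(r) 0.5 * log((1 + r) / (1 - r))
  rm <- mean(c(r1, r2))
  num <- r12 * (1 - rm^2 - rm^2) - 0.5 * rm * rm * (1 - rm^2 - rm^2 - r12^2)
  cov_term <- num / ((1 - rm^2) * (1 - rm^2))
  (fz(r1) - fz(r2)) * sqrt((n - 3) / (2 - 2 * cov_term))
}

test_that("Steiger's Z is symmetric, antisymmetric, and matches an oracle", {
  expect_equal(steiger_z(0.6, 0.6, 0.3, 50)$Z, 0)
  expect_equal(steiger_z(0.6, 0.6, 0.3, 50)$p_value, 1)
  a <- steiger_z(0.8, 0.65, 0.5, 80)
  b <- steiger_z(0.65, 0.8, 0.5, 80)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$p_value, b$p_value)
  withr::with_seed(13, {
    for (i in 1:50) {
      r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
      r12 <- runif(1, -0.9, 0.9); n <- sample(10:500, 1)
      expect_equal(steiger_z(r1, r2, r12, n)$Z,
                   steiger_oracle(r1, r2, r12, n), tolerance = 1e-8)
    }
  })
  expect_error(steiger_z(1, 1, 0.5, 30), "degenerate")
  expect_error(steiger_z(0.5, 0.4, 0.3, 3), "n >= 4")
})

test_that("ICC distinguishes agreement from consistency", {
  M <- cbind(1:10, 1:10, 1:10)
  expect_equal(icc(M + 0, "consistency_random"), 1)
  expect_equal(icc(M + 0, "agreement_mixed"), 1)
  offset <- cbind(1:10, (1:10) + 5, (1:10) - 2)
  expect_equal(icc(offset, "consistency_random"), 1)
  expect_lt(icc(offset, "agreement_mixed"), 1)
  expect_error(icc(matrix(3, 4, 3)), "constant")
})

test_that("ICC matches the variance-component closed form on simulation", {
  withr::with_seed(8, {
    m <- 400; k <- 3
    sigma_t <- 15; sigma_e <- 6
    target <- rnorm(m, 0, sigma_t)
    M <- target + matrix(rnorm(m * k, 0, sigma_e), m, k)
  })
  expected <- sigma_t^2 / (sigma_t^2 + sigma_e^2 / k)
  expect_lt(abs(icc(M, "consistency_random") - expected), 0.05)
  expect_lt(abs(icc(M, "agreement_mixed") - expected), 0.05)
})

test_that("paired t-tests behave at the edges and have power", {
  x <- c(10, 12, 14, 11, 9)
  res <- paired_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  expect_error(paired_t(x, x + 2), "zero-variance")
  withr::with_seed(9, {
    hits <- 0
    for (i in 1:200) {
      d <- rnorm(51, 0, 4)
      off <- rnorm(51, 50, 10)
      if (paired_t(off, off + d + 4)$p_value < 0.01) hits <- hits + 1
    }
  })
  expect_gte(hits / 200, 0.95)
})

test_that("evaluation reports satisfy the SDPE identity", {
  withr::with_seed(3, {
    y <- runif(40, 20, 80)
    pred <- y + rnorm(40, 0, 8)
  })
  ev <- eval_report(y, pred, "test")
  expect_equal(ev$sdpe, ev$sigma_s * sqrt(1 - ev$rho^2), tolerance = 1e-12)
  expect_lte(ev$sdpe, ev$sigma_s)
  expect_equal(ev$n, 40)
})

test_that("a single repeated split equals the manual pipeline", {
  withr::with_seed(12, {
    X <- matrix(rnorm(60 * 3), 60, dimnames = list(NULL, c("u", "v", "w")))
    y <- 50 + 5 * X[, 1] + rnorm(60)
  })
  tab <- feature_table(X, sprintf("q%02d", 1:60))
  rs <- rating_set(tab$source_ids, cbind(y, y, y))
  res <- repeated_split_eval(tab, rs, list(mapper = "lr", reduce = "none"),
                             n_repeats = 1, base_seed = 41)
  sp <- split_dataset(tab, rs, 0.2, seed = 42)
  mod <- fit_quality_model(sp$train$table, sp$train$ratings, mapper = "lr")
  expect_equal(res$per_repeat$test_r,
               pearson_r(sp$test$ratings$y,
                         predict(mod, sp$test$table$X))$rho)
})
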