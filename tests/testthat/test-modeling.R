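make_table <- function(m = 20, n = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(m * n), m, dimnames = list(NULL, sprintf("c%d", 1:n)))
    feature_table(X, sprintf("r%03d", seq_len(m)))
  })
}
make_ratings <- function(y, ids) rating_set(ids, cbind(y, y, y))

test_that("dataset splits are disjoint, exhaustive, and seeded", {
  tab <- make_table(10)
  rs <- make_ratings(rnorm(10) + 50, tab$source_ids)
  sp <- split_dataset(tab, rs, 0.2, seed = 4)
  expect_equal(nrow(sp$train$table$X), 8)
  expect_equal(nrow(sp$test$table$X), 2)
  expect_length(intersect(sp$train$table$source_ids,
                          sp$test$table$source_ids), 0)
  expect_setequal(c(sp$train$table$source_ids, sp$test$table$source_ids),
                  tab$source_ids)
  sp2 <- split_dataset(tab, rs, 0.2, seed = 4)
  expect_identical(sp$test$table$source_ids, sp2$test$table$source_ids)
  expect_error(split_dataset(tab, rs, 0.01, seed = 1), "empty")
})

test_that("feature ranking orders by |r| with stable tie-breaks", {
  tab <- make_table(50, 6, seed = 2)
  y <- tab$X[, 3]
  rk <- rank_features(tab$X, y)
  expect_equal(rk$ranked_indices[1], 3)
  expect_equal(abs(rk$correlations[3]), 1)
  # invariance to column rescaling
  rk2 <- rank_features(sweep(tab$X, 2, c(10, 0.1, 3, 7, 2, 5), "*"), y)
  expect_identical(rk$ranked_indices, rk2$ranked_indices)
  Xz <- cbind(tab$X, zv = rep(1, 50))
  expect_warning(rk3 <- rank_features(Xz, y), "zero-variance")
  expect_equal(rk3$correlations[7], 0)
})

test_that("spurious correlations stay small with independent noise", {
  withr::with_seed(31, {
    X <- matrix(rnorm(200 * 20), 200)
    y <- rnorm(200)
  })
  rk <- rank_features(X, y)
  expect_lt(max(abs(rk$correlations)), 0.3)
})

test_that("Monte Carlo selection recovers planted features compactly", {
  pd <- planted_data()
  rk <- rank_features(pd$X, pd$y)
  sel <- monte_carlo_select(pd$X, pd$y, rk, n_iter = 2000, seed = 7)
  expect_true(all(c(1, 2, 3) %in% sel$chosen))
  expect_lte(length(sel$chosen), 8)
  sel2 <- monte_carlo_select(pd$X, pd$y, rk, n_iter = 2000, seed = 7)
  expect_identical(sel$chosen, sel2$chosen)
  expect_identical(sel$cv_mse, sel2$cv_mse)
  # single-column input short-circuits
  one <- monte_carlo_select(pd$X[, 1, drop = FALSE], pd$y, n_iter = 50,
                            seed = 1)
  expect_equal(one$chosen, 1L)
  expect_error(monte_carlo_select(pd$X, pd$y, rk, n_iter = 0), "n_iter")
})

test_that("PCA reduction keeps the minimal component count", {
  withr::with_seed(5, {
    basis <- matrix(rnorm(10), 2, 5)
    Z <- matrix(rnorm(100 * 2), 100, 2) %*% basis +
      matrix(rnorm(500), 100, 5) * 1e-8
  })
  colnames(Z) <- sprintf("z%d", 1:5)
  expect_equal(pca_reduce(Z, 0.95)$n_kept, 2)
  full <- make_table(30, 4, seed = 6)
  expect_equal(pca_reduce(full$X, 1.0)$n_kept, 4)
  expect_equal(pca_reduce(full$X[, 1, drop = FALSE], 0.5)$n_kept, 1)
  expect_error(pca_reduce(full$X, 0), "threshold")
  expect_error(pca_reduce(full$X, 1.2), "threshold")
})

test_that("LR interpolates exact affine responses and handles constants", {
  tab <- make_table(40, 3, seed = 7)
  y <- 2 + 3 * tab$X[, 1] - tab$X[, 2]
  mod <- fit_mapper(tab$X, y, "lr")
  expect_lt(sqrt(mean(mod$b^2)), 1e-8)
  expect_equal(pearson_r(predict(mod, tab$X), y)$rho, 1, tolerance = 1e-9)
  ymu <- rep(50, 40)
  modc <- fit_mapper(tab$X, ymu, "lr")
  expect_equal(unname(predict(modc, tab$X)), ymu, tolerance = 1e-9)
})

test_that("predictions reproduce fit-time values and honour preprocessing", {
  tab <- make_table(60, 4, seed = 8)
  y <- 50 + 10 * tab$X[, 1] + rnorm(60)
  for (kind in c("lr", "svr")) {
    mod <- fit_mapper(tab$X, y, kind)
    expect_equal(predict(mod, tab$X), mod$fitted, tolerance = 1e-12)
    expect_error(predict(mod, tab$X[, 1:2]), "lacks required")
  }
  mod <- fit_mapper(tab$X, y, "lr")
  at_mean <- matrix(mod$preprocessing$center, 1,
                    dimnames = list(NULL, colnames(tab$X)))
  expect_equal(unname(predict(mod, at_mean)), unname(mod$theta$coef[1]),
               tolerance = 1e-9)
  # clipping for reporting only
  expect_true(all(predict(mod, tab$X, clip = TRUE) >= 0))
})

test_that("models survive JSON serialization bit-faithfully", {
  tab <- make_table(60, 4, seed = 9)
  y <- 50 + 8 * tab$X[, 2] + rnorm(60, 0, 2)
  for (kind in c("lr", "svr")) {
    mod <- fit_mapper(tab$X, y, kind)
    path <- withr::local_tempfile(fileext = ".json")
    save_model_json(mod, path)
    back <- load_model_json(path)
    expect_lt(max(abs(predict(back, tab$X) - predict(mod, tab$X))), 1e-10)
  }
})

test_that("the composite table has exactly 42 canonical columns", {
  st <- study_cohort()
  comp <- assemble_composite(st$table)
  expect_equal(ncol(comp$X), 42)
  expect_identical(comp$feature_names,
                   c(sprintf("lcqa_%02d", 1:40), "hnr_db", "cpps_db"))
  # column order is canonical regardless of input order
  shuffled <- feature_table(st$table$X[, rev(st$table$feature_names)],
                            st$table$source_ids)
  expect_identical(assemble_composite(shuffled)$X, comp$X)
  dropped <- feature_table(
    st$table$X[, setdiff(st$table$feature_names, "cpps_db")],
    st$table$source_ids)
  expect_error(assemble_composite(dropped), "cpps_db")
})

test_that("planted linear cohorts are recovered across repeated splits", {
  withr::with_seed(77, {
    X <- matrix(rnorm(113 * 3), 113,
                dimnames = list(NULL, c("a", "b", "c")))
    sig <- 55 + 12 * X[, 1] - 6 * X[, 2] + 4 * X[, 3]
    y <- sig + rnorm(113, 0, 0.3 * sd(sig))
  })
  tab <- feature_table(X, sprintf("p%03d", 1:113))
  rs <- make_ratings(y, tab$source_ids)
  res <- repeated_split_eval(tab, rs, list(mapper = "lr", reduce = "none"),
                             n_repeats = 20, base_seed = 3)
  expect_gte(res$mean_test_r, 0.9)
  expect_lt(abs(res$mean_test_r - res$mean_train_r), 0.05)
  res2 <- repeated_split_eval(tab, rs, list(mapper = "lr", reduce = "none"),
                              n_repeats = 20, base_seed = 3)
  expect_identical(res$per_repeat, res2$per_repeat)
})
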