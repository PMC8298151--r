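#' Pearson correlation with significance
#'
#' Sample Pearson correlation and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length (n >= 3), each with non-zero
#'   variance.
#' @return List with `rho` and `p_value`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("lengths differ", call. = FALSE)
  if (length(a) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Standard deviation of prediction error (SDPE)
#'
#' `sigma_s * sqrt(1 - rho^2)`, where `sigma_s` is the standard deviation of
#' the subjective quality scores and `rho` the correlation between true and
#' predicted scores.
#'
#' @param sigma_s SD of subjective scores, VAS units (>= 0).
#' @param rho Correlation coefficient in \[-1, 1\].
#' @return SDPE in VAS units.
#' @export
sdpe <- function(sigma_s, rho) {
  if (sigma_s < 0) stop("sigma_s must be >= 0", call. = FALSE)
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  sigma_s * sqrt(1 - rho^2)
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests whether `corr(metric1, y)` and `corr(metric2, y)` differ, given the
#' correlation between the two metrics. Uses the Fisher-transform Z1*-bar
#' statistic: `Z = (z1 - z2) * sqrt((n - 3) / (2 * (1 - s)))` with `s` the
#' Pearson-Filon covariance term evaluated at the mean of the two
#' correlations.
#'
#' @param r_1y,r_2y Correlations of the two metrics with the shared
#'   variable.
#' @param r_12 Correlation between the two metrics.
#' @param n Sample size (>= 4).
#' @return List with `Z` and two-sided `p_value`.
#' @export
steiger_z <- function(r_1y, r_2y, r_12, n) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (any(abs(c(r_1y, r_2y, r_12)) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (abs(r_1y) == 1 && abs(r_2y) == 1)
    stop("degenerate case: both correlations are +-1", call. = FALSE)
  z1 <- atanh(r_1y); z2 <- atanh(r_2y)
  rbar <- (r_1y + r_2y) / 2
  s <- (r_12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
          (1 - 2 * rbar^2 - r_12^2)) / (1 - rbar^2)^2
  Z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(Z = Z, p_value = 2 * stats::pnorm(-abs(Z)))
}

#' Intraclass correlation (two-way, average measures)
#'
#' Two-way ANOVA decomposition of an m-targets by k-raters score matrix.
#' `flavor = "agreement_mixed"` gives average-measures absolute agreement,
#' ICC(A,k): `(MS_R - MS_E) / (MS_R + (MS_C - MS_E) / m)`;
#' `flavor = "consistency_random"` gives average-measures consistency,
#' ICC(C,k): `(MS_R - MS_E) / MS_R`.
#'
#' @param per_rater m x k numeric matrix (m >= 2 targets, k >= 2 raters).
#' @param flavor `"agreement_mixed"` or `"consistency_random"`.
#' @return The ICC value.
#' @export
icc <- function(per_rater, flavor = c("agreement_mixed",
                                      "consistency_random")) {
  flavor <- match.arg(flavor)
  M <- as.matrix(per_rater)
  m <- nrow(M); k <- ncol(M)
  if (m < 2 || k < 2) stop("need >= 2 targets and >= 2 raters",
                           call. = FALSE)
  if (stats::sd(as.numeric(M)) == 0)
    stop("constant matrix: ICC undefined", call. = FALSE)
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- m * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  ms_r <- ss_row / (m - 1)
  ms_c <- ss_col / (k - 1)
  ms_e <- ss_err / ((m - 1) * (k - 1))
  if (flavor == "consistency_random") (ms_r - ms_e) / ms_r
  else (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / m)
}

#' Paired-sample t-test
#'
#' Standard paired t statistic with two-sided p on n - 1 degrees of freedom,
#' as used to compare vowel quality off and on medication.
#'
#' @param off,on Paired score vectors of equal length (n >= 3).
#' @return List with `t` and `p_value`.
#' @export
paired_t <- function(off, on) {
  if (length(off) != length(on)) stop("lengths differ", call. = FALSE)
  if (length(off) < 3) stop("need n >= 3", call. = FALSE)
  d <- off - on
  if (stats::sd(d) == 0 && any(d != 0))
    stop("zero-variance differences: t undefined", call. = FALSE)
  if (all(d == 0)) return(list(t = 0, p_value = 1))
  tt <- stats::t.test(off, on, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value)
}

#' Evaluation report for one metric on one partition
#'
#' Bundles the Pearson correlation between subjective and predicted scores
#' with the subjective-score SD and the implied SDPE, asserting the SDPE
#' identity `sdpe = sigma_s * sqrt(1 - rho^2)`.
#'
#' @param y_true Subjective (consensus VAS) scores.
#' @param y_pred Predicted scores.
#' @param partition Label: `"train"`, `"test"`, or `"full"`.
#' @return An `EvalReport`: list with `rho`, `p_value`, `sigma_s`, `sdpe`,
#'   `partition`, `n`.
#' @export
eval_report <- function(y_true, y_pred, partition = "full") {
  pr <- pearson_r(y_true, y_pred)
  sigma_s <- stats::sd(y_true) * sqrt((length(y_true) - 1) / length(y_true))
  out <- list(rho = pr$rho, p_value = pr$p_value, sigma_s = sigma_s,
              sdpe = sdpe(sigma_s, pr$rho), partition = partition,
              n = length(y_true))
  stopifnot(abs(out$sdpe - out$sigma_s * sqrt(1 - out$rho^2)) < 1e-10)
  structure(out, class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  stars <- if (x$p_value < 0.01) "**" else if (x$p_value < 0.05) "*" else ""
  cat(sprintf("<EvalReport [%s, n=%d]: rho = %.2f%s, SDPE = %.2f>\n",
              x$partition, x$n, x$rho, stars, x$sdpe))
  invisible(x)
}

#' Repeated random-split evaluation
#'
#' Repeats the whole pipeline -- a fresh seeded 80/20 split, a full fit on
#' the training partition (including any selection or PCA), evaluation on
#' both partitions -- and averages the correlations. Per-repeat values are
#' returned alongside the means.
#'
#' @param table A [feature_table()].
#' @param ratings A [rating_set()] aligned with `table`.
#' @param pipeline List with elements `columns` (feature names, or NULL for
#'   all), `mapper` (`"lr"`/`"svr"`), `reduce` (`"none"`/`"pca"`/`"mc"`).
#' @param n_repeats Number of repeated splits.
#' @param base_seed Base seed; repeat i uses `base_seed + i`.
#' @param config A [pvq_config()].
#' @return List with `mean_train_r`, `mean_test_r`, and a data.frame
#'   `per_repeat`.
#' @export
repeated_split_eval <- function(table, ratings, pipeline, n_repeats = 20L,
                                base_seed = 1L, config = pvq_config()) {
  pipeline <- utils::modifyList(list(columns = NULL, mapper = "lr",
                                     reduce = "none"), pipeline)
  rows <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    seed_i <- base_seed + i
    sp <- split_dataset(table, ratings, config$test_frac, seed_i)
    model <- fit_quality_model(sp$train$table, sp$train$ratings,
                               columns = pipeline$columns,
                               mapper = pipeline$mapper,
                               reduce = pipeline$reduce,
                               config = config, seed = seed_i)
    # guard: selection and fitting must never have seen held-out rows
    stopifnot(!any(sp$test$table$source_ids %in% sp$train$table$source_ids))
    r_tr <- pearson_r(sp$train$ratings$y,
                      predict(model, sp$train$table$X))$rho
    r_te <- pearson_r(sp$test$ratings$y,
                      predict(model, sp$test$table$X))$rho
    rows[[i]] <- data.frame(repeat_i = i, seed = seed_i,
                            train_r = r_tr, test_r = r_te)
  }
  per <- do.call(rbind, rows)
  list(mean_train_r = mean(per$train_r), mean_test_r = mean(per$test_r),
       per_repeat = per)
}
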