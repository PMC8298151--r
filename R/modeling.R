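#' Feature tables
#'
#' An m-recordings by n-features matrix with unique feature names and
#' per-row source labels; the `X` of the quality-mapping model.
#'
#' @param X Numeric matrix (or data.frame) with named columns.
#' @param source_ids Character vector of row labels.
#' @return An object of class `FeatureTable`.
#' @export
feature_table <- function(X, source_ids) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("X must have unique column names", call. = FALSE)
  if (nrow(X) != length(source_ids))
    stop("source_ids length must match rows of X", call. = FALSE)
  if (anyNA(X)) stop("feature table contains missing values", call. = FALSE)
  rownames(X) <- source_ids
  structure(list(X = X, feature_names = colnames(X),
                 source_ids = as.character(source_ids)),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("<FeatureTable: %d recordings x %d features>\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Extract acoustic features from a set of recordings
#'
#' Runs the requested feature families on each recording after the standard
#' front end (central-segment extraction when the recording is longer than
#' the configured 2 s, then decimation to 16 kHz). Families: `traditional`
#' (jitter_pct, shimmer_db, hnr_db, cpps_db), `gfcc` (60), `lcqa` (40),
#' `srmr`, `moda`, `rpde` -- the full set gives 107 columns. Recordings on
#' which any feature fails are dropped with a warning; the dropped ids are
#' kept in the `dropped` attribute.
#'
#' @param recordings List of [recording()] objects.
#' @param features Character vector of family names (see above).
#' @param config A [pvq_config()].
#' @return A [feature_table()].
#' @export
extract_features <- function(recordings,
                             features = c("traditional", "gfcc", "lcqa",
                                          "srmr", "moda", "rpde"),
                             config = pvq_config()) {
  features <- match.arg(features, several.ok = TRUE)
  if (!length(recordings)) stop("no recordings given", call. = FALSE)
  rows <- list(); dropped <- character(0)
  for (rec in recordings) {
    row <- tryCatch(extract_one(rec, features, config), error = function(e) {
      warning(sprintf("dropping '%s': %s", rec$source_id, conditionMessage(e)))
      NULL
    })
    if (is.null(row)) dropped <- c(dropped, rec$source_id)
    else rows[[rec$source_id]] <- row
  }
  if (!length(rows)) stop("all recordings failed feature extraction",
                          call. = FALSE)
  tab <- feature_table(do.call(rbind, rows), names(rows))
  attr(tab, "dropped") <- dropped
  tab
}

extract_one <- function(rec, features, config) {
  if (duration_s(rec) > config$segment_s)
    rec <- extract_central_segment(rec, config$segment_s)
  if (rec$rate != config$target_rate) rec <- decimate_to_16k(rec)
  out <- numeric(0)
  if ("traditional" %in% features) {
    marks <- track_cycles(rec, config$f0_min, config$f0_max)
    out <- c(out, jitter_pct = jitter_percent(marks),
             shimmer_db = shimmer_db(marks),
             hnr_db = hnr_db(rec, config$f0_min, config$f0_max, config),
             cpps_db = cpps_db(rec, config$f0_min, config$f0_max, config))
  }
  if ("gfcc" %in% features) out <- c(out, gfcc_features(rec, config))
  if ("lcqa" %in% features) out <- c(out, lcqa_features(rec, config))
  if ("srmr" %in% features) out <- c(out, srmr = srmr(rec, config))
  if ("moda" %in% features) out <- c(out, moda = moda(rec, config))
  if ("rpde" %in% features)
    out <- c(out, rpde = rpde(rec, config$rpde_embed_dim, config$rpde_delay,
                              config$rpde_radius, config$rpde_t_max,
                              config)$H_norm)
  out
}

#' Split a dataset into training and test partitions
#'
#' Rows are shuffled by a seeded permutation; the first `floor(test_frac*m)`
#' go to the test partition and the remainder to training (113 recordings at
#' the default 0.2 give the canonical 91/22 split).
#'
#' @param table A [feature_table()].
#' @param ratings A [rating_set()] aligned with `table` by source_id.
#' @param test_frac Fraction of rows held out.
#' @param seed Integer seed.
#' @return List with `train` and `test`, each a list of `table`, `ratings`.
#' @export
split_dataset <- function(table, ratings, test_frac = 0.2, seed = 1L) {
  m <- nrow(table$X)
  if (m < 5) stop("need at least 5 rows to split", call. = FALSE)
  if (!identical(table$source_ids, ratings$source_id))
    stop("table and ratings are not aligned by source_id", call. = FALSE)
  n_test <- floor(test_frac * m)
  if (n_test < 1) stop("test partition would be empty", call. = FALSE)
  perm <- withr::with_seed(seed, sample.int(m))
  take <- function(idx) list(
    table = feature_table(table$X[idx, , drop = FALSE],
                          table$source_ids[idx]),
    ratings = rating_set(ratings$source_id[idx],
                         ratings$per_rater[idx, , drop = FALSE]))
  list(test = take(perm[seq_len(n_test)]),
       train = take(perm[(n_test + 1):m]))
}

#' Rank features by absolute correlation with the subjective scores
#'
#' Pearson correlation of each column with `y`; columns are ordered by |r|
#' descending, ties broken by original column index. Zero-variance columns
#' get r = 0 with a warning.
#'
#' @param X Numeric matrix with named columns.
#' @param y Numeric response (consensus VAS scores).
#' @return A `SelectionResult` with `ranked_indices`, `correlations`
#'   (in original column order), `chosen = NULL`.
#' @export
rank_features <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) warning(sprintf(
    "%d zero-variance column(s); correlation set to 0", sum(sds == 0)))
  r <- rep(0, ncol(X))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], y))
  ord <- order(-abs(r), seq_along(r))
  structure(list(ranked_indices = ord, correlations = r, chosen = NULL,
                 cv_mse = NA_real_, n_iterations = 0L, seed = NA_integer_),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("<SelectionResult: %d features ranked%s>\n",
              length(x$ranked_indices),
              if (is.null(x$chosen)) "" else
                sprintf(", %d chosen (cv MSE %.3f)", length(x$chosen),
                        x$cv_mse)))
  invisible(x)
}

#' Monte Carlo feature-subset selection
#'
#' Each iteration draws a candidate subset (size uniform on 1..n, members
#' sampled without replacement with probability proportional to
#' `n - rank + 1`, biasing toward high-ranked features) and scores it by
#' ordinary-least-squares validation MSE averaged over a fixed, seeded pool
#' of inner train/validation splits of the supplied (training) rows; the
#' shared split pool makes subset scores directly comparable and the whole
#' procedure deterministic given `seed`. The subset with the lowest mean
#' validation MSE wins. Selection never sees held-out test rows; validation
#' happens inside the training partition only.
#'
#' @param X Numeric matrix of training-row features (named columns).
#' @param y Training-row responses.
#' @param ranking A `SelectionResult` from [rank_features()] (or NULL to
#'   rank internally).
#' @param n_iter Number of Monte Carlo iterations.
#' @param inner_val_frac Fraction of rows used for inner validation.
#' @param seed Integer seed; results are deterministic given it.
#' @param n_splits Size of the shared inner split pool.
#' @return A `SelectionResult` with `chosen` (original column indices, sorted
#'   by rank), `cv_mse`, `n_iterations`, `seed`.
#' @export
monte_carlo_select <- function(X, y, ranking = NULL, n_iter = 2000L,
                               inner_val_frac = 0.25, seed = 1L,
                               n_splits = 40L) {
  X <- as.matrix(X)
  m <- nrow(X); n <- ncol(X)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (m < 10) stop("need at least 10 rows for inner validation",
                   call. = FALSE)
  if (is.null(ranking)) ranking <- rank_features(X, y)
  ord <- ranking$ranked_indices
  if (n == 1L)
    return(structure(list(ranked_indices = ord, correlations =
                            ranking$correlations, chosen = 1L,
                          cv_mse = NA_real_, n_iterations = as.integer(n_iter),
                          seed = as.integer(seed)),
                     class = "SelectionResult"))
  n_val <- max(2L, round(inner_val_frac * m))
  w <- (n:1)                      # rank-proportional inclusion weights
  scores <- new.env(parent = emptyenv())
  withr::with_seed(seed, {
    val_pool <- replicate(n_splits, sample.int(m, n_val), simplify = FALSE)
    for (it in seq_len(n_iter)) {
      s <- sample.int(n, 1L)
      sub_rank <- sort(sample.int(n, s, prob = w))
      key <- paste(sub_rank, collapse = ",")
      if (!is.null(scores[[key]])) next      # already scored on the pool
      cols <- ord[sub_rank]
      scores[[key]] <- mean(vapply(val_pool, function(val)
        subset_val_mse(X, y, cols, val), numeric(1)))
    }
  })
  keys <- ls(scores)
  mean_mse <- vapply(keys, function(k) scores[[k]], numeric(1))
  best <- keys[which.min(mean_mse)]
  sub_rank <- as.integer(strsplit(best, ",")[[1]])
  structure(list(ranked_indices = ord, correlations = ranking$correlations,
                 chosen = ord[sub_rank], cv_mse = min(mean_mse),
                 n_iterations = as.integer(n_iter), seed = as.integer(seed)),
            class = "SelectionResult")
}

# Validation MSE of OLS fit on the complement of `val`, evaluated on `val`.
subset_val_mse <- function(X, y, cols, val) {
  Xtr <- cbind(1, X[-val, cols, drop = FALSE])
  fit <- tryCatch(stats::.lm.fit(Xtr, y[-val]), error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  pred <- cbind(1, X[val, cols, drop = FALSE]) %*% fit$coefficients
  mean((y[val] - pred)^2)
}

#' PCA dimensionality reduction
#'
#' Columns are standardized (zero mean, unit variance) before the
#' eigendecomposition; the transform keeps the smallest number of components
#' whose cumulative explained-variance fraction reaches `variance_threshold`.
#'
#' @param X Numeric matrix.
#' @param variance_threshold Target cumulative explained variance in (0, 1].
#' @return A `PcaTransform` with `rotation`, `center`, `scale`,
#'   `explained_variance_fractions`, `n_kept`.
#' @export
pca_reduce <- function(X, variance_threshold = 0.95) {
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
        variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]", call. = FALSE)
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  pc <- stats::prcomp(X, center = TRUE, scale. = sds)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  n_kept <- which(cumsum(fr) >= variance_threshold - 1e-12)[1]
  structure(list(rotation = pc$rotation[, seq_len(n_kept), drop = FALSE],
                 center = pc$center, scale = pc$scale,
                 explained_variance_fractions = fr, n_kept = n_kept),
            class = "PcaTransform")
}

#' @export
print.PcaTransform <- function(x, ...) {
  cat(sprintf("<PcaTransform: %d of %d components (%.1f%% variance)>\n",
              x$n_kept, length(x$explained_variance_fractions),
              100 * sum(x$explained_variance_fractions[seq_len(x$n_kept)])))
  invisible(x)
}

apply_pca <- function(transform, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, transform$center), 2, transform$scale,
              "/")
  Xs %*% transform$rotation
}

#' Fit a feature-to-quality mapper
#'
#' `kind = "lr"` fits ordinary least squares with intercept (falling back to
#' a small ridge penalty, with a warning, when there are at least as many
#' features as rows); `kind = "svr"` fits epsilon-insensitive support vector
#' regression with an RBF kernel (C = 10, epsilon = 1 VAS unit, kernel width
#' 1/n_features -- constants from [pvq_config()]). Columns are standardized
#' internally with training-row constants that are stored in the model and
#' re-applied verbatim at prediction time.
#'
#' @param X Training feature matrix (named columns).
#' @param y Training responses (consensus VAS).
#' @param kind `"lr"` or `"svr"`.
#' @param config A [pvq_config()].
#' @return A `MappingModel`.
#' @export
fit_mapper <- function(X, y, kind = c("lr", "svr"), config = pvq_config()) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("X rows must match length(y)", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (all(scl == 0)) stop("degenerate X: all columns constant", call. = FALSE)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (kind == "lr") {
    if (nrow(Xs) > ncol(Xs) + 1) {
      fit <- stats::lm.fit(cbind(1, Xs), y)
      theta <- list(coef = fit$coefficients)
    } else {
      warning("m <= n: ridge fallback (lambda = 1e-6 * n)")
      lam <- 1e-6 * ncol(Xs)
      A <- crossprod(cbind(1, Xs)) + diag(lam, ncol(Xs) + 1)
      theta <- list(coef = as.numeric(solve(A, crossprod(cbind(1, Xs), y))))
    }
    fitted <- as.numeric(cbind(1, Xs) %*% theta$coef)
  } else {
    sv <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                     cost = config$svr_cost, epsilon = config$svr_epsilon,
                     gamma = 1 / ncol(Xs), scale = FALSE)
    theta <- list(sv = unname(as.matrix(sv$SV)),
                  coefs = as.numeric(sv$coefs),
                  rho = sv$rho, gamma = 1 / ncol(Xs))
    fitted <- svr_eval(theta, Xs)
  }
  structure(list(kind = kind, theta = theta, b = y - fitted,
                 fitted = fitted,
                 preprocessing = list(center = ctr, scale = scl,
                                      feature_names = colnames(X),
                                      pca = NULL)),
            class = "MappingModel")
}

svr_eval <- function(theta, Xs) {
  d2 <- outer(rowSums(Xs^2), rowSums(theta$sv^2), "+") -
    2 * Xs %*% t(theta$sv)
  as.numeric(exp(-theta$gamma * d2) %*% theta$coefs - theta$rho)
}

#' @export
print.MappingModel <- function(x, ...) {
  cat(sprintf("<MappingModel (%s): %d features, train residual SD %.2f>\n",
              toupper(x$kind), length(x$preprocessing$feature_names),
              stats::sd(x$b)))
  invisible(x)
}

#' Predict VAS quality scores from a fitted mapper
#'
#' Applies the stored preprocessing (column selection by name,
#' standardization, optional PCA) verbatim, never re-estimating it, then
#' evaluates the mapper. Scores are returned unclipped (as used for
#' correlation computations); set `clip = TRUE` to clip to the 0-100 VAS
#' range for reporting.
#'
#' @param object A `MappingModel`.
#' @param X_new Matrix (or data.frame) containing at least the model's
#'   feature columns, identified by name.
#' @param clip Clip predictions into \[0, 100\]?
#' @param ... Unused.
#' @return Numeric vector of predicted scores, one per row.
#' @export
predict.MappingModel <- function(object, X_new, clip = FALSE, ...) {
  X_new <- as.matrix(X_new)
  need <- object$preprocessing$feature_names
  miss <- setdiff(need, colnames(X_new))
  if (length(miss))
    stop(sprintf("X_new lacks required columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  Xs <- sweep(sweep(X_new[, need, drop = FALSE], 2,
                    object$preprocessing$center),
              2, object$preprocessing$scale, "/")
  if (!is.null(object$preprocessing$pca))
    Xs <- Xs %*% object$preprocessing$pca$rotation
  out <- if (object$kind == "lr")
    as.numeric(cbind(1, Xs) %*% object$theta$coef)
  else svr_eval(object$theta, Xs)
  if (clip) out <- pmin(pmax(out, 0), 100)
  out
}

#' Assemble the composite feature table
#'
#' The composite quality metric augments the 40 LCQA features with HNR and
#' smoothed CPP: exactly 42 columns in canonical order
#' (`lcqa_01..lcqa_40`, `hnr_db`, `cpps_db`), independent of input column
#' order.
#'
#' @param table A [feature_table()] containing the required columns.
#' @return A `FeatureTable` with 42 columns.
#' @export
assemble_composite <- function(table) {
  want <- c(sprintf("lcqa_%02d", 1:40), "hnr_db", "cpps_db")
  miss <- setdiff(want, table$feature_names)
  if (length(miss))
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  feature_table(table$X[, want, drop = FALSE], table$source_ids)
}

#' Fit a full quality-estimation pipeline on a training partition
#'
#' Convenience wrapper tying the pieces together the way the study grid
#' does: optional feature-subset column selection, then `reduce` --
#' `"none"`, `"pca"` (components covering the configured variance
#' threshold), or `"mc"` (correlation-ranked Monte Carlo subset selection)
#' -- then an LR or SVR mapper. All constants estimated on the training
#' rows only and stored in the returned model.
#'
#' @param table Training [feature_table()].
#' @param ratings Training [rating_set()].
#' @param columns Character vector of feature columns to consider (default
#'   all).
#' @param mapper `"lr"` or `"svr"`.
#' @param reduce `"none"`, `"pca"`, or `"mc"`.
#' @param config A [pvq_config()].
#' @param seed Seed for the Monte Carlo selection.
#' @return A `MappingModel` (with PCA/selection metadata in
#'   `preprocessing`).
#' @export
fit_quality_model <- function(table, ratings, columns = NULL,
                              mapper = c("lr", "svr"),
                              reduce = c("none", "pca", "mc"),
                              config = pvq_config(), seed = 1L) {
  mapper <- match.arg(mapper); reduce <- match.arg(reduce)
  X <- table$X
  if (!is.null(columns)) {
    miss <- setdiff(columns, colnames(X))
    if (length(miss)) stop(sprintf("unknown column(s): %s",
                                   paste(miss, collapse = ", ")),
                           call. = FALSE)
    X <- X[, columns, drop = FALSE]
  }
  y <- ratings$y
  selection <- NULL
  if (reduce == "mc") {
    selection <- monte_carlo_select(X, y, rank_features(X, y),
                                    n_iter = config$mc_n_iter,
                                    inner_val_frac = config$mc_val_frac,
                                    seed = seed)
    X <- X[, selection$chosen, drop = FALSE]
  }
  if (reduce == "pca") {
    pca <- pca_reduce(X, config$pca_threshold)
    model <- fit_pca_model(pca, X, y, mapper, config)
  } else {
    model <- fit_mapper(X, y, mapper, config)
  }
  model$selection <- selection
  model
}

# PCA path: fit the mapper directly on PCA scores (already standardized by
# the PCA's center/scale), storing the PCA as the whole preprocessing chain.
fit_pca_model <- function(pca, X, y, mapper, config) {
  scores <- apply_pca(pca, X)
  if (mapper == "lr") {
    fit <- stats::lm.fit(cbind(1, scores), y)
    theta <- list(coef = fit$coefficients)
    fitted <- as.numeric(cbind(1, scores) %*% theta$coef)
  } else {
    sv <- e1071::svm(scores, y, type = "eps-regression", kernel = "radial",
                     cost = config$svr_cost, epsilon = config$svr_epsilon,
                     gamma = 1 / ncol(scores), scale = FALSE)
    theta <- list(sv = unname(as.matrix(sv$SV)), coefs = as.numeric(sv$coefs),
                  rho = sv$rho, gamma = 1 / ncol(scores))
    fitted <- svr_eval(theta, scores)
  }
  structure(list(kind = mapper, theta = theta, b = y - fitted,
                 fitted = fitted,
                 preprocessing = list(center = pca$center, scale = pca$scale,
                                      feature_names = colnames(X),
                                      pca = pca)),
            class = "MappingModel")
}
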