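#' Read and write pipeline interchange files
#'
#' Feature tables and rating sets travel as plain CSV: feature tables have a
#' `source_id` column plus one column per feature; rating sets have
#' `source_id`, `rater_1..k`, and `mean_vas` (recomputed, not trusted, on
#' read). Models are stored as a single JSON document carrying the mapper
#' parameters, the preprocessing constants, and the selection metadata.
#'
#' @param table A [feature_table()].
#' @param path File path.
#' @return The read functions return the corresponding object; the write
#'   functions return `path` invisibly.
#' @name interchange
NULL

#' @rdname interchange
#' @export
write_feature_csv <- function(table, path) {
  df <- data.frame(source_id = table$source_ids, table$X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname interchange
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"source_id" %in% names(df)) stop("missing source_id column",
                                        call. = FALSE)
  feature_table(as.matrix(df[setdiff(names(df), "source_id")]),
                df$source_id)
}

#' @rdname interchange
#' @param ratings A [rating_set()].
#' @export
write_ratings_csv <- function(ratings, path) {
  df <- data.frame(source_id = ratings$source_id, ratings$per_rater,
                   mean_vas = ratings$y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname interchange
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rater_cols <- grep("^rater_", names(df), value = TRUE)
  if (!"source_id" %in% names(df) || !length(rater_cols))
    stop("ratings CSV needs source_id and rater_* columns", call. = FALSE)
  rating_set(df$source_id, as.matrix(df[rater_cols]))
}

#' @rdname interchange
#' @param model A `MappingModel`.
#' @export
save_model_json <- function(model, path) {
  pp <- model$preprocessing
  doc <- list(
    kind = model$kind,
    theta = model$theta,
    preprocessing = list(
      center = as.list(stats::setNames(pp$center, pp$feature_names)),
      scale = as.list(stats::setNames(pp$scale, pp$feature_names)),
      feature_names = pp$feature_names,
      pca_rotation = if (!is.null(pp$pca)) unclass(pp$pca$rotation) else NULL),
    selection = if (!is.null(model$selection))
      list(chosen = model$selection$chosen,
           cv_mse = model$selection$cv_mse,
           n_iterations = model$selection$n_iterations,
           seed = model$selection$seed) else NULL)
  doc$preprocessing <- Filter(Negate(is.null), doc$preprocessing)
  doc <- Filter(Negate(is.null), doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname interchange
#' @export
load_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nms <- doc$preprocessing$feature_names
  theta <- doc$theta
  if (doc$kind == "lr") theta$coef <- as.numeric(theta$coef)
  else {
    theta$sv <- matrix(unlist(theta$sv), nrow = length(theta$coefs),
                       byrow = FALSE)
    if (is.list(theta$sv)) theta$sv <- do.call(rbind, theta$sv)
    theta$coefs <- as.numeric(theta$coefs)
  }
  pca <- NULL
  if (length(doc$preprocessing$pca_rotation)) {
    rot <- doc$preprocessing$pca_rotation
    if (is.list(rot)) rot <- do.call(rbind, rot)
    pca <- list(rotation = rot)
  }
  structure(list(kind = doc$kind, theta = theta, b = NULL, fitted = NULL,
                 preprocessing = list(
                   center = unlist(doc$preprocessing$center)[nms],
                   scale = unlist(doc$preprocessing$scale)[nms],
                   feature_names = nms, pca = pca),
                 selection = doc$selection),
            class = "MappingModel")
}

study_metric_rows <- function() {
  list(
    list(label = "SRMR",         columns = "srmr",    mapper = "lr",
         single = TRUE),
    list(label = "ModA",         columns = "moda",    mapper = "lr",
         single = TRUE),
    list(label = "CPP",          columns = "cpps_db", mapper = "lr",
         single = TRUE),
    list(label = "HNR",          columns = "hnr_db",  mapper = "lr",
         single = TRUE),
    list(label = "RPDE",         columns = "rpde",    mapper = "lr",
         single = TRUE),
    list(label = "GFCC-LR",      columns = "gfcc",    mapper = "lr",
         single = FALSE),
    list(label = "GFCC-SVR",     columns = "gfcc",    mapper = "svr",
         single = FALSE),
    list(label = "LCQA-LR",      columns = "lcqa",    mapper = "lr",
         single = FALSE),
    list(label = "LCQA-SVR",     columns = "lcqa",    mapper = "svr",
         single = FALSE),
    list(label = "Combined-LR",  columns = "combined", mapper = "lr",
         single = FALSE),
    list(label = "Combined-SVR", columns = "combined", mapper = "svr",
         single = FALSE))
}

resolve_columns <- function(spec, feature_names) {
  switch(spec,
    gfcc = grep("^d?gfcc_", feature_names, value = TRUE),
    lcqa = grep("^lcqa_", feature_names, value = TRUE),
    combined = c(sprintf("lcqa_%02d", 1:40), "hnr_db", "cpps_db"),
    spec)
}

#' Run the full objective-metric study grid
#'
#' Reproduces the benchmark structure of the quality-estimation experiment
#' on the given data: the five single scalar features (SRMR, ModA, CPP,
#' HNR, RPDE) under linear regression, and the multi-feature sets (GFCC,
#' LCQA, and the 42-feature combined set) under LR and SVR, each with no
#' reduction, PCA reduction, and correlation-ranked Monte Carlo reduction.
#' One seeded 80/20 split is used throughout; every metric/variant reports
#' training- and test-partition correlation and SDPE.
#'
#' @param table A [feature_table()] holding the full 107-column extraction.
#' @param ratings A [rating_set()] aligned with `table`.
#' @param seed Integer seed for the split and the selection.
#' @param metrics Optional character vector restricting the metric labels
#'   (e.g. `"RPDE"`).
#' @param out_dir Optional directory; when given, the report CSV and a
#'   provenance JSON (config, seed, package version) are written there.
#' @param config A [pvq_config()].
#' @return A data.frame with columns `metric`, `variant`, `n_features`,
#'   `train_r`, `train_p`, `train_sdpe`, `test_r`, `test_p`, `test_sdpe`.
#' @export
run_study <- function(table, ratings, seed = 1L, metrics = NULL,
                      out_dir = NULL, config = pvq_config()) {
  sp <- split_dataset(table, ratings, config$test_frac, seed)
  rows <- study_metric_rows()
  if (!is.null(metrics)) {
    rows <- Filter(function(r) r$label %in% metrics, rows)
    if (!length(rows)) stop("no matching metric labels", call. = FALSE)
  }
  out <- list()
  for (row in rows) {
    cols <- resolve_columns(row$columns, table$feature_names)
    variants <- if (row$single) "full" else c("full", "pca", "reduced")
    for (variant in variants) {
      reduce <- switch(variant, full = "none", pca = "pca", reduced = "mc")
      model <- fit_quality_model(sp$train$table, sp$train$ratings,
                                 columns = cols, mapper = row$mapper,
                                 reduce = reduce, config = config,
                                 seed = seed)
      ev_tr <- eval_report(sp$train$ratings$y,
                           predict(model, sp$train$table$X), "train")
      ev_te <- eval_report(sp$test$ratings$y,
                           predict(model, sp$test$table$X), "test")
      nf <- if (reduce == "mc") length(model$selection$chosen)
      else if (reduce == "pca") model$preprocessing$pca$n_kept
      else length(cols)
      out[[length(out) + 1]] <- data.frame(
        metric = row$label, variant = variant, n_features = nf,
        train_r = ev_tr$rho, train_p = ev_tr$p_value,
        train_sdpe = ev_tr$sdpe,
        test_r = ev_te$rho, test_p = ev_te$p_value, test_sdpe = ev_te$sdpe)
    }
  }
  report <- do.call(rbind, out)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "study_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, package_version = as.character(
        utils::packageVersion("pvq")), config = unclass(config)),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
    writeLines(format_study_report(report),
               file.path(out_dir, "study_report.txt"))
  }
  report
}

#' Format a study report as an aligned text table
#'
#' Correlations carry the conventional significance stars (* p < 0.05,
#' ** p < 0.01).
#'
#' @param report Data.frame from [run_study()].
#' @return Character vector of lines.
#' @export
format_study_report <- function(report) {
  star <- function(r, p) sprintf("%5.2f%-2s", r,
                                 ifelse(p < 0.01, "**",
                                        ifelse(p < 0.05, "*", "")))
  body <- sprintf("%-14s %-8s %4d   %s %6.2f   %s %6.2f",
                  report$metric, report$variant, report$n_features,
                  star(report$train_r, report$train_p), report$train_sdpe,
                  star(report$test_r, report$test_p), report$test_sdpe)
  c(sprintf("%-14s %-8s %4s   %-8s %6s   %-8s %6s",
            "metric", "variant", "n", "r(train)", "SDPE",
            "r(test)", "SDPE"), body)
}
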