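# Pipeline orchestration: generate -> extract -> select -> evaluate,
# reproducing the analysis artifacts (ranking tables, incremental curve,
# forward subset search) from one configuration.

#' Extract features for a whole run
#'
#' Thin wrapper around \code{\link{extract_feature_table}} that accepts a
#' manifest path or an in-memory \code{synthetic_dataset} and applies the
#' run configuration.
#'
#' @param x Manifest path or \code{synthetic_dataset}.
#' @param config An \code{\link{analysis_config}}.
#' @return A \code{\link{feature_table}}.
#' @export
run_extraction <- function(x, config = analysis_config()) {
  extract_feature_table(x, config)
}

#' Compare the four filter selection methods at top-k
#'
#' Ranks the features with Relief-F, Pearson correlation, NCA and term
#' variance, then evaluates each method's top-k subset with the
#' configured k-NN variant under repeated stratified CV.
#'
#' @param table A \code{\link{feature_table}}.
#' @param config An \code{\link{analysis_config}}.
#' @return List with \code{rankings} (named list of
#'   \code{feature_ranking}) and \code{results} (data frame of mean
#'   metrics per method).
#' @export
run_selection_comparison <- function(table, config = analysis_config()) {
  methods <- c("relief_f", "pearson", "nca", "term_variance")
  cfg <- knn_preset(config$knn_preset)
  rankings <- lapply(methods, rank_features, table = table, config = config)
  names(rankings) <- methods
  results <- do.call(rbind, lapply(methods, function(m) {
    top <- select_top_k(rankings[[m]], config$top_k)
    cv <- repeated_stratified_cv(table, features = top, cfg = cfg,
                                 folds = config$folds,
                                 repeats = config$repeats,
                                 seed = config$cv_seed)
    data.frame(method = m, top_k = config$top_k,
               accuracy = cv$mean[["accuracy"]],
               sensitivity = cv$mean[["sensitivity"]],
               specificity = cv$mean[["specificity"]])
  }))
  list(rankings = rankings, results = results)
}

#' Incremental curve for a run configuration
#'
#' @param table A \code{\link{feature_table}}.
#' @param ranking A \code{feature_ranking} over the table's features.
#' @param config An \code{\link{analysis_config}}.
#' @return Data frame (see \code{\link{incremental_curve}}).
#' @export
run_incremental_curve <- function(table, ranking,
                                  config = analysis_config()) {
  incremental_curve(table, ranking = ranking,
                    cfg = knn_preset(config$knn_preset),
                    max_size = config$top_k, folds = config$folds,
                    repeats = config$repeats, seed = config$cv_seed)
}

#' Run the full analysis from one configuration
#'
#' Executes the complete pipeline on the synthetic benchmark: dataset
#' generation, 125-feature extraction, full-feature-set CV baseline,
#' four-method selection comparison at top-k, the incremental feature
#' curve for the configured selection method, and the greedy forward
#' subset search over that method's top-k candidates. Every randomized
#' stage consumes seeds derived from the configuration, so reruns are
#' numerically identical.
#'
#' @param config An \code{\link{analysis_config}}.
#' @param table Optional pre-extracted \code{\link{feature_table}}
#'   (skips generation/extraction).
#' @param verbose Print progress messages.
#' @return An object of class \code{mass_analysis}.
#' @export
run_full_analysis <- function(config = analysis_config(), table = NULL,
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(table)) {
    say("generating synthetic dataset (",
        config$n_benign, " benign / ", config$n_malignant, " malignant)")
    presets <- config$presets %||% default_presets()
    dataset <- generate_dataset(config$n_benign, config$n_malignant,
                                presets, config$master_seed)
    say("extracting 125-feature table")
    table <- extract_feature_table(dataset, config)
  }
  cfg <- knn_preset(config$knn_preset)
  if (min(table(table$label)) < config$folds) {
    stop("smallest class (", min(table(table$label)),
         " samples) is below the fold count ", config$folds,
         "; reduce folds")
  }
  say("evaluating all-125-feature baseline")
  cv_full <- repeated_stratified_cv(table, cfg = cfg,
                                    folds = config$folds,
                                    repeats = config$repeats,
                                    seed = config$cv_seed)
  say("running four-method selection comparison")
  sel <- run_selection_comparison(table, config)
  ranking <- sel$rankings[[config$selection_method]]
  top <- select_top_k(ranking, config$top_k)
  cv_top <- repeated_stratified_cv(table, features = top, cfg = cfg,
                                   folds = config$folds,
                                   repeats = config$repeats,
                                   seed = config$cv_seed)
  say("computing incremental feature curve")
  curve <- run_incremental_curve(table, ranking, config)
  say("forward subset search (max size ", config$search_max_size, ")")
  search <- forward_subset_search(table, candidates = top, cfg = cfg,
                                  max_size = config$search_max_size,
                                  folds = config$folds,
                                  repeats = config$repeats,
                                  seed = config$cv_seed)
  out <- structure(list(config = config, table = table,
                        cv_full = cv_full,
                        selection = sel,
                        ranking = ranking,
                        top_features = top,
                        cv_top = cv_top,
                        curve = curve,
                        search = search),
                   class = "mass_analysis")
  if (!is.null(config$output_dir)) {
    write_analysis(out, config$output_dir)
  }
  out
}

# Persist the analysis artifacts as delimited text files.
write_analysis <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(x$table, file.path(dir, "features.csv"))
  for (m in names(x$selection$rankings)) {
    write_ranking(x$selection$rankings[[m]],
                  file.path(dir, paste0("ranking_", m, ".csv")))
  }
  utils::write.csv(x$selection$results,
                   file.path(dir, "selection_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(x$curve, file.path(dir, "incremental_curve.csv"),
                   row.names = FALSE)
  summary_df <- data.frame(
    feature_set = c("all_125",
                    paste0("top_", x$config$top_k, "_",
                           x$config$selection_method),
                    "compact_subset"),
    n_features = c(125L, length(x$top_features), length(x$search$subset)),
    accuracy = c(x$cv_full$mean[["accuracy"]],
                 x$cv_top$mean[["accuracy"]],
                 x$search$cv$mean[["accuracy"]]),
    sensitivity = c(x$cv_full$mean[["sensitivity"]],
                    x$cv_top$mean[["sensitivity"]],
                    x$search$cv$mean[["sensitivity"]]),
    specificity = c(x$cv_full$mean[["specificity"]],
                    x$cv_top$mean[["specificity"]],
                    x$search$cv$mean[["specificity"]]))
  utils::write.csv(summary_df, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  cat125 <- feature_catalog()
  writeLines(cat125$column[x$search$subset],
             file.path(dir, "compact_subset.txt"))
  invisible(dir)
}

#' @export
print.mass_analysis <- function(x, ...) {
  cat("Breast-mass classification analysis (synthetic benchmark)\n")
  cat(sprintf("  samples: %d (%s)\n", nrow(x$table),
              paste(names(table(x$table$label)), table(x$table$label),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  all 125 features:    accuracy %.1f%%\n",
              x$cv_full$mean[["accuracy"]]))
  cat(sprintf("  top %d (%s):    accuracy %.1f%%\n", x$config$top_k,
              x$config$selection_method, x$cv_top$mean[["accuracy"]]))
  cat(sprintf("  compact subset (%d): accuracy %.1f%% [%s]\n",
              length(x$search$subset), x$search$cv$mean[["accuracy"]],
              paste(feature_catalog()$feature[x$search$subset],
                    collapse = " ")))
  invisible(x)
}

#' @export
summary.mass_analysis <- function(object, ...) {
  cat125 <- feature_catalog()
  res <- rbind(
    data.frame(feature_set = "all_125", n = 125L,
               t(object$cv_full$mean)),
    data.frame(feature_set = paste0("top_", object$config$top_k),
               n = length(object$top_features), t(object$cv_top$mean)),
    data.frame(feature_set = "compact_subset",
               n = length(object$search$subset),
               t(object$search$cv$mean)))
  list(results = res,
       selection_comparison = object$selection$results,
       compact_subset = cat125$column[object$search$subset],
       curve = object$curve)
}

#' Plot the incremental feature curve of an analysis
#' @param x A \code{mass_analysis}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.mass_analysis <- function(x, ...) {
  graphics::matplot(x$curve$size,
                    x$curve[, c("accuracy", "sensitivity", "specificity")],
                    type = "b", pch = 1:3, lty = 1,
                    xlab = "number of selected features",
                    ylab = "metric (%)", ...)
  graphics::legend("bottomright",
                   legend = c("accuracy", "sensitivity", "specificity"),
                   pch = 1:3, col = 1:3, lty = 1, bty = "n")
  invisible(x)
}
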