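# Repeated stratified 10-fold cross-validation and the greedy forward
# subset search over a candidate feature list.

# Stratified fold assignment: within each class, indices are shuffled
# under the repeat seed and dealt round-robin across folds.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Repeated stratified k-fold cross-validation of a k-NN classifier
#'
#' Per repeat, a stratified fold assignment is drawn from that repeat's
#' seed (master seed + repeat index). Per fold, features are standardized
#' with the training-fold statistics, the k-NN variant predicts the held
#' out fold, and fold predictions are pooled; accuracy, sensitivity and
#' specificity are computed on the pooled predictions and averaged over
#' repeats.
#'
#' @param x Feature matrix (rows = samples) or \code{feature_table}.
#' @param y Class labels (ignored when \code{x} is a feature table).
#' @param features Optional column indices to use (default all).
#' @param cfg A \code{\link{knn_config}}.
#' @param folds,repeats CV layout (default 10 x 10).
#' @param seed Master seed; repeat r uses seed + r.
#' @return A list of class \code{cv_result} with per-repeat metrics and
#'   their means (percent).
#' @export
repeated_stratified_cv <- function(x, y = NULL, features = NULL,
                                   cfg = knn_preset("weighted_cosine"),
                                   folds = 10L, repeats = 10L,
                                   seed = 11L) {
  if (inherits(x, "feature_table")) {
    y <- x$label
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- as.character(y)
  counts <- table(y)
  if (length(counts) < 2) stop("need two classes")
  if (min(counts) < folds) {
    stop("smallest class has ", min(counts), " samples; use folds <= ",
         min(counts))
  }
  per_repeat <- matrix(NA_real_, nrow = repeats, ncol = 3,
                       dimnames = list(NULL, c("accuracy", "sensitivity",
                                               "specificity")))
  seeds <- seed + seq_len(repeats)
  for (r in seq_len(repeats)) {
    fold_of <- stratified_folds(y, folds, seeds[r])
    pred <- character(length(y))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      ctr <- colMeans(x[!test, , drop = FALSE])
      scl <- apply(x[!test, , drop = FALSE], 2, stats::sd)
      scl[!is.finite(scl) | scl == 0] <- 1
      xtr <- standardize_columns(x[!test, , drop = FALSE], ctr, scl)
      xte <- standardize_columns(x[test, , drop = FALSE], ctr, scl)
      pred[test] <- knn_predict(xtr, y[!test], xte, cfg)
    }
    per_repeat[r, ] <- confusion_metrics(y, pred)
  }
  structure(list(folds = folds, repeats = repeats, seeds = seeds,
                 per_repeat = per_repeat,
                 mean = colMeans(per_repeat),
                 config = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV, %d repeats: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$folds, x$repeats, x$mean[["accuracy"]], x$mean[["sensitivity"]],
    x$mean[["specificity"]]))
  invisible(x)
}

#' Greedy forward subset search over candidate features
#'
#' Sequential forward selection: starting empty, repeatedly add the
#' candidate feature whose addition maximizes mean CV accuracy under fixed
#' seeds, breaking ties by higher sensitivity and then lower feature
#' index; stop at \code{max_size} or when no addition improves accuracy.
#' The full candidate set is also evaluated, and the best subset seen
#' overall is returned — so the result is never worse (on these seeds)
#' than using all candidates.
#'
#' @inheritParams repeated_stratified_cv
#' @param candidates Candidate feature indices (e.g. a top-20 list).
#' @param max_size Largest subset size to grow to.
#' @return List with \code{subset} (feature indices), \code{cv} (its
#'   \code{cv_result}) and \code{trace} (per-step accuracy).
#' @export
forward_subset_search <- function(x, y = NULL, candidates,
                                  cfg = knn_preset("weighted_cosine"),
                                  max_size = 9L, folds = 10L,
                                  repeats = 10L, seed = 11L) {
  if (inherits(x, "feature_table")) {
    y <- x$label
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  stopifnot(length(candidates) >= 1)
  eval_subset <- function(fs) {
    repeated_stratified_cv(x, y, features = fs, cfg = cfg, folds = folds,
                           repeats = repeats, seed = seed)
  }
  chosen <- integer(0)
  best_acc <- -Inf
  best <- NULL
  trace <- data.frame(size = integer(0), added = integer(0),
                      accuracy = numeric(0))
  repeat {
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining) || length(chosen) >= max_size) break
    step_best <- NULL
    for (f in sort(remaining)) {
      cv <- eval_subset(c(chosen, f))
      cand <- list(f = f, cv = cv,
                   acc = cv$mean[["accuracy"]],
                   sens = cv$mean[["sensitivity"]])
      if (is.null(step_best) ||
          cand$acc > step_best$acc ||
          (cand$acc == step_best$acc && cand$sens > step_best$sens)) {
        step_best <- cand
      }
    }
    if (step_best$acc <= best_acc) break  # no improvement
    chosen <- c(chosen, step_best$f)
    best_acc <- step_best$acc
    best <- list(subset = chosen, cv = step_best$cv)
    trace <- rbind(trace, data.frame(size = length(chosen),
                                     added = step_best$f,
                                     accuracy = step_best$acc))
  }
  full_cv <- eval_subset(candidates)
  if (is.null(best) || full_cv$mean[["accuracy"]] > best_acc) {
    best <- list(subset = sort(candidates), cv = full_cv)
  }
  best$trace <- trace
  best$full_candidates_cv <- full_cv
  best
}

#' Incremental feature curve
#'
#' Evaluates the prefix subsets of a ranking (sizes 1..\code{max_size})
#' under fixed seeds, yielding the accuracy / sensitivity / specificity
#' curve versus the number of selected features.
#'
#' @inheritParams repeated_stratified_cv
#' @param ranking A \code{feature_ranking}.
#' @param max_size Largest prefix evaluated (default 20).
#' @return Data frame with one row per subset size.
#' @export
incremental_curve <- function(x, y = NULL, ranking,
                              cfg = knn_preset("weighted_cosine"),
                              max_size = 20L, folds = 10L, repeats = 10L,
                              seed = 11L) {
  if (inherits(x, "feature_table")) {
    y <- x$label
    x <- feature_matrix(x)
  }
  stopifnot(inherits(ranking, "feature_ranking"))
  max_size <- min(max_size, length(ranking$order))
  rows <- lapply(seq_len(max_size), function(s) {
    fs <- ranking$order[seq_len(s)]
    cv <- repeated_stratified_cv(x, y, features = fs, cfg = cfg,
                                 folds = folds, repeats = repeats,
                                 seed = seed)
    data.frame(size = s, feature_added = ranking$order[s],
               accuracy = cv$mean[["accuracy"]],
               sensitivity = cv$mean[["sensitivity"]],
               specificity = cv$mean[["specificity"]])
  })
  do.call(rbind, rows)
}
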