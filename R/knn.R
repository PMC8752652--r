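# k-nearest-neighbor classification with the metric / distance-weighting
# variants used in the evaluation, plus confusion-matrix metrics.

#' k-NN configuration and named variant presets
#'
#' \code{knn_config} builds a configuration; \code{knn_preset} returns one
#' of the conventional variant presets: \code{fine} (k = 1, Euclidean,
#' uniform), \code{medium} (k = 10, Euclidean, uniform), \code{cosine}
#' (k = 10, cosine, uniform), \code{cubic} (k = 10, Minkowski order 3,
#' uniform), \code{weighted} (k = 10, Euclidean, squared inverse
#' distance) and \code{weighted_cosine} (k = 5, cosine, squared inverse
#' distance) — the last being the best-performing variant of the study
#' design this package implements.
#'
#' @param k Neighbor count (>= 1).
#' @param metric \code{"euclidean"}, \code{"cosine"} or \code{"cubic"}
#'   (Minkowski order 3).
#' @param weighting \code{"uniform"} or \code{"squared_inverse"}.
#' @return A list of class \code{knn_config}.
#' @export
knn_config <- function(k = 5L, metric = c("euclidean", "cosine", "cubic"),
                       weighting = c("uniform", "squared_inverse")) {
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), metric = match.arg(metric),
                 weighting = match.arg(weighting)),
            class = "knn_config")
}

#' @rdname knn_config
#' @param name Preset name.
#' @export
knn_preset <- function(name = c("weighted_cosine", "fine", "medium",
                                "cosine", "cubic", "weighted")) {
  switch(match.arg(name),
         fine = knn_config(1L, "euclidean", "uniform"),
         medium = knn_config(10L, "euclidean", "uniform"),
         cosine = knn_config(10L, "cosine", "uniform"),
         cubic = knn_config(10L, "cubic", "uniform"),
         weighted = knn_config(10L, "euclidean", "squared_inverse"),
         weighted_cosine = knn_config(5L, "cosine", "squared_inverse"))
}

# query x train distance matrix for the three supported metrics.
# Cosine distance involving a zero-norm vector is defined as 1.
knn_distances <- function(train, query, metric) {
  train <- as.matrix(train); query <- as.matrix(query)
  switch(metric,
    euclidean = {
      cross <- query %*% t(train)
      d2 <- outer(rowSums(query^2), rowSums(train^2), "+") - 2 * cross
      sqrt(pmax(d2, 0))
    },
    cubic = {
      d <- matrix(0, nrow(query), nrow(train))
      for (i in seq_len(nrow(query))) {
        d[i, ] <- (colSums(abs(t(train) - query[i, ])^3))^(1 / 3)
      }
      d
    },
    cosine = {
      qn <- sqrt(rowSums(query^2))
      tn <- sqrt(rowSums(train^2))
      d <- 1 - (query %*% t(train)) / outer(qn, tn)
      d[!is.finite(d)] <- 1
      d
    })
}

#' Predict labels with a k-NN classifier
#'
#' Uniform weighting takes the majority vote among the k nearest training
#' instances; squared-inverse weighting scores each class by the sum of
#' 1/(d^2 + 1e-12) over its neighbors, so exact-coincidence neighbors
#' dominate. Neighbor distance ties are broken by smallest training index,
#' vote ties by the class of the single nearest neighbor.
#'
#' @param train Numeric matrix of training feature vectors (rows).
#' @param labels Training class labels.
#' @param query Numeric matrix of query vectors (rows).
#' @param cfg A \code{\link{knn_config}}.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train, labels, query, cfg = knn_config()) {
  train <- as.matrix(train)
  query <- matrix(as.numeric(query), ncol = ncol(train))
  stopifnot(nrow(train) >= 1, length(labels) == nrow(train))
  k <- cfg$k
  if (k > nrow(train)) {
    warning("k = ", k, " exceeds training size ", nrow(train),
            "; clamping")
    k <- nrow(train)
  }
  d <- knn_distances(train, query, cfg$metric)
  eps <- 1e-12
  labels <- as.character(labels)
  vapply(seq_len(nrow(query)), function(i) {
    nb <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
    if (cfg$weighting == "uniform") {
      votes <- table(labels[nb])
      top <- names(votes)[votes == max(votes)]
      if (length(top) == 1) top else labels[nb[1]]
    } else {
      wts <- 1 / (d[i, nb]^2 + eps)
      scores <- tapply(wts, labels[nb], sum)
      top <- names(scores)[scores == max(scores)]
      if (length(top) == 1) top else labels[nb[1]]
    }
  }, character(1))
}

#' Confusion-matrix metrics (accuracy, sensitivity, specificity)
#'
#' Malignant is the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n, all in percent.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive Positive class (default \code{"malignant"}).
#' @return Named numeric vector (percentages).
#' @export
confusion_metrics <- function(truth, predicted, positive = "malignant") {
  stopifnot(length(truth) == length(predicted))
  pos <- truth == positive
  if (!any(pos)) stop("no positive-class instances in truth; stratify folds")
  if (all(pos)) stop("no negative-class instances in truth; stratify folds")
  tp <- sum(pos & predicted == positive)
  fn <- sum(pos & predicted != positive)
  tn <- sum(!pos & predicted != positive)
  fp <- sum(!pos & predicted == positive)
  c(accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}
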