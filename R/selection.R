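# Filter feature selection: Relief-F, Pearson correlation, neighborhood
# component analysis, term variance. All rankings sort scores descending
# and are deterministic under a fixed seed.

new_ranking <- function(method, scores) {
  scores <- unname(scores)
  order <- order(-scores, seq_along(scores))
  structure(list(method = method, order = order, scores = scores),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat("Feature ranking (", x$method, "), ", length(x$order),
      " features. Top ", n, ":\n", sep = "")
  cols <- catalog_columns()
  top <- utils::head(x$order, n)
  nm <- if (length(x$scores) == length(cols)) cols[top] else
    paste0("f", top)
  print(data.frame(rank = seq_along(top), feature = nm,
                   score = signif(x$scores[top], 4)), row.names = FALSE)
  invisible(x)
}

# label coding used by Pearson / NCA: benign = 0, malignant = 1
label01 <- function(labels) {
  as.numeric(labels == "malignant")
}

resolve_xy <- function(table) {
  if (inherits(table, "feature_table")) {
    list(x = feature_matrix(table), y = table$label)
  } else {
    stop("expected a feature_table")
  }
}

#' Relief-F feature ranking
#'
#' Two-class Relief-F: for each of m target instances, the relief_k
#' nearest hits (same class) and relief_k nearest misses (other class) are
#' located by Euclidean distance on standardized features, and each
#' feature's weight accumulates (miss differences - hit differences) /
#' (m * relief_k), with per-feature differences normalized by the
#' feature's range. Weights lie in [-1, 1]; constant features score
#' exactly 0. With m = n every instance is a target once, so no sampling
#' randomness remains.
#'
#' @param table A \code{\link{feature_table}} (or list with x, y).
#' @param relief_k Number of nearest hits and misses (default 10).
#' @param m Number of target instances (default all, the stable choice).
#' @param standardize Standardize features before neighbor search.
#' @param seed Seed for target sampling when m < n.
#' @return A \code{feature_ranking}.
#' @export
relief_f_rank <- function(table, relief_k = 10L, m = NULL,
                          standardize = TRUE, seed = 1L) {
  d <- resolve_xy(table)
  x <- d$x; y <- d$y
  n <- nrow(x); p <- ncol(x)
  classes <- unique(y)
  stopifnot(length(classes) == 2)
  if (any(tabulate(factor(y)) < 2)) stop("need >= 2 samples per class")
  if (is.null(m)) m <- n
  stopifnot(m >= 1, m <= n)
  xs <- if (standardize) standardize_columns(x) else x
  rng <- apply(xs, 2, function(v) diff(range(v)))
  denom <- ifelse(rng > 0, rng, 1)  # constant features contribute diff 0
  targets <- if (m == n) seq_len(n) else
    with_seed(seed, sample.int(n, m))
  dist2 <- as.matrix(stats::dist(xs))^2
  w <- numeric(p)
  for (t in targets) {
    for (cls in classes) {
      same <- y == cls
      cand <- which(same & seq_len(n) != t)
      k_eff <- min(relief_k, length(cand))
      if (k_eff == 0) next
      nb <- cand[order(dist2[t, cand], cand)][seq_len(k_eff)]
      diffs <- abs(sweep(xs[nb, , drop = FALSE], 2, xs[t, ], "-"))
      diffs <- sweep(diffs, 2, denom, "/")
      diffs[, rng == 0] <- 0
      contrib <- colSums(diffs) * (relief_k / k_eff)
      if (cls == y[t]) w <- w - contrib else w <- w + contrib
    }
  }
  w <- w / (m * relief_k)
  new_ranking("relief_f", w)
}

#' Pearson correlation feature ranking
#'
#' Scores each feature by the absolute Pearson correlation with the
#' numeric class coding (benign = 0, malignant = 1). Zero-variance
#' features score 0.
#'
#' @inheritParams relief_f_rank
#' @return A \code{feature_ranking}.
#' @export
pearson_rank <- function(table) {
  d <- resolve_xy(table)
  y <- label01(d$y)
  if (stats::sd(y) == 0) stop("need both classes present")
  scores <- apply(d$x, 2, function(v) {
    if (stats::sd(v) == 0) 0 else abs(stats::cor(v, y))
  })
  new_ranking("pearson", scores)
}

#' Neighborhood component analysis feature ranking
#'
#' Diagonal NCA: learns one weight per feature by gradient ascent on the
#' expected leave-one-out same-class assignment probability under the
#' soft-neighbor kernel exp(-d_w), where d_w(a, b) = sum_f w_f^2
#' (a_f - b_f)^2, with an L2 penalty lambda * sum w_f^2. Scores are the
#' final squared weights at the iteration cap (non-convergence is not an
#' error).
#'
#' @inheritParams relief_f_rank
#' @param lambda Regularization strength (default 1/n).
#' @param rate Gradient-ascent learning rate.
#' @param iterations Fixed iteration count.
#' @return A \code{feature_ranking}.
#' @export
nca_rank <- function(table, lambda = NULL, rate = 0.1,
                     iterations = 200L, standardize = TRUE) {
  d <- resolve_xy(table)
  x <- if (standardize) standardize_columns(d$x) else d$x
  y <- d$y
  n <- nrow(x); p <- ncol(x)
  if (any(tabulate(factor(y)) < 2)) stop("need >= 2 samples per class")
  if (is.null(lambda)) lambda <- 1 / n
  hit <- outer(y, y, "==")
  diag(hit) <- FALSE
  # per-feature squared difference matrices (precomputed once)
  D <- lapply(seq_len(p), function(f) {
    df <- outer(x[, f], x[, f], "-")
    df * df
  })
  w <- rep(1, p)
  for (it in seq_len(iterations)) {
    dw <- matrix(0, n, n)
    for (f in seq_len(p)) dw <- dw + w[f]^2 * D[[f]]
    K <- exp(-dw)
    diag(K) <- 0
    rs <- rowSums(K)
    rs[rs == 0] <- 1
    P <- K / rs
    p_i <- rowSums(P * hit)
    grad <- numeric(p)
    for (f in seq_len(p)) {
      A <- P * D[[f]]
      grad[f] <- 2 * w[f] * (sum(p_i * rowSums(A)) - sum(A[hit]))
    }
    # ascent on the data term, proximal (implicit) step for the L2
    # penalty: stable for arbitrarily large lambda
    w <- (w + rate * grad) / (1 + 2 * rate * lambda)
  }
  new_ranking("nca", w^2)
}

#' Term variance feature ranking
#'
#' Scores each feature by its sample variance after min-max scaling to
#' [0, 1], making the ranking invariant to per-feature affine rescaling of
#' the raw inputs. Constant features score 0.
#'
#' @inheritParams relief_f_rank
#' @return A \code{feature_ranking}.
#' @export
variance_rank <- function(table) {
  d <- resolve_xy(table)
  scores <- apply(d$x, 2, function(v) {
    r <- diff(range(v))
    if (r == 0) return(0)
    stats::var((v - min(v)) / r)
  })
  new_ranking("term_variance", scores)
}

#' Rank features with a named method
#'
#' @inheritParams relief_f_rank
#' @param method One of \code{"relief_f"}, \code{"pearson"},
#'   \code{"nca"}, \code{"term_variance"}.
#' @param config An \code{\link{analysis_config}} supplying
#'   hyperparameters.
#' @return A \code{feature_ranking}.
#' @export
rank_features <- function(table, method = c("relief_f", "pearson", "nca",
                                            "term_variance"),
                          config = analysis_config()) {
  method <- match.arg(method)
  switch(method,
         relief_f = relief_f_rank(table, relief_k = config$relief_k,
                                  standardize = config$standardize),
         pearson = pearson_rank(table),
         nca = nca_rank(table, lambda = config$nca_lambda,
                        rate = config$nca_rate,
                        iterations = config$nca_iterations,
                        standardize = config$standardize),
         term_variance = variance_rank(table))
}

#' Take the top-k features of a ranking
#'
#' @param ranking A \code{feature_ranking}.
#' @param k Number of features, 1 <= k <= length(order).
#' @return Integer vector of the first k feature indices (stable).
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k < 1 || k > length(ranking$order)) {
    stop("k must be between 1 and ", length(ranking$order))
  }
  ranking$order[seq_len(k)]
}
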