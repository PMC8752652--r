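# Repeated stratified cross-validation and the forward subset search.

gauss_table <- function(n_per_class = 60, informative = 4, sep = 3,
                        seed = 30) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("benign", "malignant"), each = n_per_class)
  x <- matrix(rnorm(n * 125), n, 125)
  x[labels == "malignant", seq_len(informative)] <-
    x[labels == "malignant", seq_len(informative)] + sep
  feature_table(x, labels)
}

test_that("stratified folds preserve class counts and seeds reproduce them", {
  labels <- rep(c("benign", "malignant"), c(52, 63))
  f1 <- mammotex:::stratified_folds(labels, 10, 99)
  f2 <- mammotex:::stratified_folds(labels, 10, 99)
  expect_identical(f1, f2)
  per_fold <- table(f1[labels == "benign"])
  expect_true(all(per_fold %in% c(5, 6)))  # 52 benign over 10 folds
  expect_equal(length(unique(f1)), 10)
})

test_that("well-separated classes reach high CV accuracy; permuted labels sit at chance", {
  for (seed in c(1, 2, 3)) {
    tab <- gauss_table(seed = seed + 100)
    cv <- repeated_stratified_cv(tab, features = 1:4,
                                 cfg = knn_preset("weighted_cosine"),
                                 repeats = 3, seed = seed)
    expect_gte(cv$mean[["accuracy"]], 95)
  }
  tab <- gauss_table(seed = 31)
  set.seed(32)
  perm <- tab
  perm$label <- sample(perm$label)
  cvp <- repeated_stratified_cv(perm, features = 1:4, repeats = 5,
                                seed = 7)
  expect_gte(cvp$mean[["accuracy"]], 40)
  expect_lte(cvp$mean[["accuracy"]], 60)
})

test_that("CV results are deterministic and expose their layout", {
  tab <- gauss_table(20, seed = 33)
  a <- repeated_stratified_cv(tab, features = 1:6, repeats = 4, seed = 5)
  b <- repeated_stratified_cv(tab, features = 1:6, repeats = 4, seed = 5)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_equal(a$mean, colMeans(a$per_repeat))
  expect_equal(a$seeds, 5 + 1:4)
  expect_true(all(a$per_repeat >= 0 & a$per_repeat <= 100))
  expect_error(repeated_stratified_cv(tab[1:25, ], folds = 10),
               "folds")
})

test_that("forward search finds a planted label feature first", {
  set.seed(34)
  n <- 60
  labels <- rep(c("benign", "malignant"), each = n / 2)
  x <- matrix(rnorm(n * 125), n, 125)
  x[, 17] <- as.numeric(labels == "malignant") + rnorm(n, sd = 0.05)
  tab <- feature_table(x, labels)
  res <- forward_subset_search(tab, candidates = c(3, 17, 40, 88),
                               max_size = 3, repeats = 2, seed = 9)
  expect_equal(res$subset[1], 17)
  expect_gte(res$cv$mean[["accuracy"]], 95)
})

test_that("duplicated informative features enter the subset only once", {
  set.seed(35)
  n <- 60
  labels <- rep(c("benign", "malignant"), each = n / 2)
  x <- matrix(rnorm(n * 125), n, 125)
  sig <- as.numeric(labels == "malignant") * 2 + rnorm(n, sd = 0.3)
  x[, 5] <- sig
  x[, 6] <- sig  # exact duplicate
  tab <- feature_table(x, labels)
  res <- forward_subset_search(tab, candidates = c(5, 6),
                               max_size = 2, repeats = 2, seed = 4)
  expect_length(intersect(res$subset, c(5, 6)), 1)
  expect_equal(res$subset, 5)  # tie broken by lower index
})

test_that("the returned subset is at least as accurate as the full candidate set", {
  tab <- gauss_table(30, informative = 3, sep = 2, seed = 36)
  cands <- c(1:3, 50:56)  # 3 signal + 7 noise
  res <- forward_subset_search(tab, candidates = cands, max_size = 5,
                               repeats = 2, seed = 6)
  expect_gte(res$cv$mean[["accuracy"]],
             res$full_candidates_cv$mean[["accuracy"]])
})

test_that("the incremental curve is consistent with direct evaluation", {
  tab <- gauss_table(25, informative = 5, sep = 1.5, seed = 37)
  rk <- relief_f_rank(tab)
  curve <- incremental_curve(tab, ranking = rk, max_size = 5,
                             repeats = 2, seed = 8)
  expect_equal(nrow(curve), 5)
  direct <- repeated_stratified_cv(tab, features = rk$order[1:5],
                                   repeats = 2, seed = 8)
  expect_equal(curve$accuracy[5], direct$mean[["accuracy"]])
  direct1 <- repeated_stratified_cv(tab, features = rk$order[1],
                                    repeats = 2, seed = 8)
  expect_equal(curve$accuracy[1], direct1$mean[["accuracy"]])
})
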