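# Filter feature selection: worked oracles, degenerate features, and
# recovery of planted signal.

make_table <- function(x, labels) {
  full <- matrix(0, nrow(x), 125)
  full[, seq_len(ncol(x))] <- x
  feature_table(full, labels)
}

test_that("Relief-F ranks a label-copy feature first and constants score 0", {
  set.seed(10)
  n <- 40
  labels <- rep(c("benign", "malignant"), each = n / 2)
  x <- cbind(as.numeric(labels == "malignant"), rnorm(n))
  tab <- make_table(x, labels)
  rk <- relief_f_rank(tab, relief_k = 3)
  expect_equal(rk$order[1], 1L)
  expect_gt(rk$scores[1], rk$scores[2])
  # all padding features are constant -> weight exactly 0
  expect_true(all(rk$scores[3:125] == 0))
  expect_true(all(rk$scores >= -1 & rk$scores <= 1))
})

test_that("Relief-F weights equal a hand-traced run on a 4-sample dataset", {
  # 2 features, 4 samples, relief_k = 1, m = 4, no standardization
  x <- rbind(c(0, 0), c(1, 0.5), c(0.2, 1), c(0.9, 0.4))
  labels <- c("benign", "malignant", "benign", "malignant")
  tab <- make_table(x, labels)
  rk <- relief_f_rank(tab, relief_k = 1, standardize = FALSE)
  # hand trace: ranges f1 = 1, f2 = 1; Euclidean nearest hit/miss per target
  # t1 (0,0):      hit t3 d2=1.04; miss t4 d2=.97  -> miss t4, hit t3
  # t2 (1,.5):     hit t4 d2=.02;  miss t3 d2=.89  -> hit t4, miss t3
  # t3 (.2,1):     hit t1;         miss t2 d2=.89 < t4 .85 -> miss t4
  # t4 (.9,.4):    hit t2;         miss t1 .97 vs t3 .85 -> miss t3
  w1 <- ((0.9 - 0) + (1 - 0.2) + (0.9 - 0.2) + (0.9 - 0.2)) / 4 -
    ((0.2 - 0) + (1 - 0.9) + (0.2 - 0) + (1 - 0.9)) / 4
  w2 <- ((0.4 - 0) + (1 - 0.5) + (1 - 0.4) + (1 - 0.4)) / 4 -
    ((1 - 0) + (0.5 - 0.4) + (1 - 0) + (0.5 - 0.4)) / 4
  expect_equal(rk$scores[1], w1)
  expect_equal(rk$scores[2], w2)
})

test_that("Pearson ranking is sign-invariant and matches the textbook formula", {
  labels <- rep(c("benign", "malignant"), each = 10)
  y <- as.numeric(labels == "malignant")
  set.seed(11)
  x <- cbind(y, -y, rnorm(20))
  tab <- make_table(x, labels)
  rk <- pearson_rank(tab)
  expect_equal(rk$scores[1], 1)
  expect_equal(rk$scores[2], 1)  # negated coding, absolute value
  expect_true(all(rk$order[1:2] %in% c(1L, 2L)))
  # six-point hand check
  f <- c(1.2, 0.5, 2.2, 3.1, 2.9, 4.0)
  lab6 <- c("benign", "benign", "benign", "malignant", "malignant",
            "malignant")
  y6 <- as.numeric(lab6 == "malignant")
  r_hand <- sum((f - mean(f)) * (y6 - mean(y6))) /
    sqrt(sum((f - mean(f))^2) * sum((y6 - mean(y6))^2))
  tab6 <- make_table(cbind(f, rnorm(6)), lab6)
  expect_equal(pearson_rank(tab6)$scores[1], abs(r_hand))
})

test_that("NCA upweights a separating feature and shrinks under heavy regularization", {
  first_hits <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 60
    labels <- rep(c("benign", "malignant"), each = n / 2)
    x <- cbind(as.numeric(labels == "malignant") * 3 + rnorm(n, sd = 0.3),
               rnorm(n), rnorm(n))
    tab <- make_table(x, labels)
    rk <- nca_rank(tab, iterations = 60)
    rk$order[1] == 1L && rk$scores[1] > max(rk$scores[-1])
  }, logical(1))
  expect_true(all(first_hits))

  set.seed(3)
  labels <- rep(c("benign", "malignant"), each = 15)
  x <- cbind(as.numeric(labels == "malignant"), rnorm(30))
  rk_reg <- nca_rank(make_table(x, labels), lambda = 1e4, iterations = 60)
  expect_lt(max(rk_reg$scores), 1e-3)
})

test_that("NCA signal ordering is preserved when dataset rows are duplicated", {
  set.seed(12)
  labels <- rep(c("benign", "malignant"), each = 12)
  x <- cbind(as.numeric(labels == "malignant") * 2 + rnorm(24, sd = 0.3),
             as.numeric(labels == "malignant") * 0.8 + rnorm(24, sd = 0.3),
             rnorm(24))
  tab1 <- make_table(x, labels)
  tab2 <- make_table(rbind(x, x), c(labels, labels))
  r1 <- nca_rank(tab1, lambda = 0, iterations = 40)
  r2 <- nca_rank(tab2, lambda = 0, iterations = 40)
  expect_equal(utils::head(r1$order, 2), c(1L, 2L))
  expect_equal(utils::head(r2$order, 2), c(1L, 2L))
})

test_that("term variance ranks by min-max-scaled spread, affine-invariantly", {
  n <- 20
  labels <- rep(c("benign", "malignant"), each = n / 2)
  bal <- rep(c(0, 1), n / 2)
  set.seed(13)
  narrow <- runif(n, 0.4, 0.6)
  x <- cbind(bal, narrow)
  rk <- variance_rank(make_table(x, labels))
  expect_equal(rk$scores[1], 0.25 * n / (n - 1))
  expect_equal(rk$order[1], 1L)
  # constant features (padding) rank last with score exactly 0
  expect_true(all(rk$scores[3:125] == 0))
  # affine rescaling of a raw feature leaves the ranking unchanged
  x2 <- cbind(bal * 1000 - 37, narrow)
  rk2 <- variance_rank(make_table(x2, labels))
  expect_equal(rk2$order, rk$order)
  expect_equal(rk2$scores, rk$scores)
})

test_that("top-k selection is stable and validates k", {
  tab <- signal_table(20, s = 4, seed = 5)
  rk <- relief_f_rank(tab)
  expect_length(select_top_k(rk, 20), 20)
  expect_equal(select_top_k(rk, 125), rk$order)
  expect_error(select_top_k(rk, 0), "between 1 and")
  expect_error(select_top_k(rk, 126), "between 1 and")
})

test_that("rankings are permutations and reproducible", {
  tab <- signal_table(25, s = 5, seed = 7)
  for (m in c("relief_f", "pearson", "nca", "term_variance")) {
    cfg <- analysis_config(nca_iterations = 30L)
    r1 <- rank_features(tab, m, cfg)
    r2 <- rank_features(tab, m, cfg)
    expect_equal(sort(r1$order), 1:125)
    expect_identical(r1$scores, r2$scores)
  }
})
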