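# Shared fixtures built in code at test time.

# Rasterized disk mask: pixel centers within radius r of the center.
disk_mask <- function(n = 64, r = n / 3) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  d <= r
}

# Irregular star-shaped blob mask (deterministic given seed).
blob_mask <- function(n = 64, seed = 1) {
  set.seed(seed)
  m <- 90
  theta <- seq(0, 2 * pi, length.out = m + 1)[1:m]
  r <- (n / 3.2) * (1 + 0.25 * sin(4 * theta + runif(1, 0, 2 * pi)) +
                      0.1 * sin(7 * theta + runif(1, 0, 2 * pi)))
  ctr <- (n - 1) / 2
  contour_to_mask(cbind(ctr + r * cos(theta), ctr + r * sin(theta)),
                  c(n, n))
}

# Small two-class feature table with `s` signal columns (shifted means in
# the malignant class) among 125 columns of noise.
signal_table <- function(n_per_class = 30, s = 5, effect = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * 125), n, 125)
  labels <- rep(c("benign", "malignant"), each = n_per_class)
  x[labels == "malignant", seq_len(s)] <-
    x[labels == "malignant", seq_len(s)] + effect
  colnames(x) <- feature_catalog()$column
  feature_table(x, labels)
}

# Brute-force k-NN oracle: naive per-query loops, all metrics/weights.
knn_oracle <- function(train, labels, query, k, metric, weighting) {
  n <- nrow(train)
  dist1 <- function(a, b) {
    switch(metric,
           euclidean = sqrt(sum((a - b)^2)),
           cubic = sum(abs(a - b)^3)^(1 / 3),
           cosine = {
             na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
             if (na == 0 || nb == 0) 1 else 1 - sum(a * b) / (na * nb)
           })
  }
  apply(query, 1, function(qv) {
    d <- vapply(seq_len(n), function(j) dist1(qv, train[j, ]), numeric(1))
    nb <- order(d, seq_len(n))[seq_len(min(k, n))]
    if (weighting == "uniform") {
      votes <- table(labels[nb])
      top <- names(votes)[votes == max(votes)]
      if (length(top) == 1) top else labels[nb[1]]
    } else {
      w <- 1 / (d[nb]^2 + 1e-12)
      sc <- tapply(w, labels[nb], sum)
      top <- names(sc)[sc == max(sc)]
      if (length(top) == 1) top else labels[nb[1]]
    }
  })
}
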