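# Texture models: worked examples with independent oracles, degenerate
# (constant-image) fallbacks, and definitional invariances.

test_that("constant ROI gives the degenerate values across all texture models", {
  flat <- matrix(7, 16, 16)
  g <- compute_sglcm_features(flat)
  expect_equal(g[["ASM"]], 1)
  expect_equal(g[["Entropy"]], 0)
  expect_equal(g[["Contrast"]], 0)
  expect_equal(g[["Inverse_Diff_Moment"]], 1)
  expect_equal(g[["Correlation"]], 0)  # zero-variance fallback
  expect_equal(g[["Max_Corr_Coff"]], 0)

  d <- compute_glds_features(flat)
  expect_equal(unname(d[c("Mean", "Contrast", "Entropy")]), c(0, 0, 0))
  expect_equal(d[["Energy"]], 1)
  expect_equal(d[["Homogeneity"]], 1)

  f <- compute_fos_features(flat)
  expect_equal(unname(f), c(7, 0, 0, 0))

  s <- compute_sfm_features(flat)
  expect_equal(s[["Contrast"]], 0)

  expect_equal(unname(compute_ltem_features(flat)), rep(0, 14))
  expect_equal(unname(compute_fractal_features(flat)), c(0, 0))
  expect_equal(unname(compute_fps_features(flat)), c(0, 0))
})

test_that("co-occurrence counts match a hand count on the 4x4 worked image", {
  img <- matrix(c(0, 0, 1, 1,
                  0, 0, 1, 1,
                  0, 2, 2, 2,
                  2, 2, 3, 3), 4, 4, byrow = TRUE)
  mats <- mammotex:::glcm_matrices(mammotex:::quantize_gray(img, 4L), 4L)
  # 12 horizontal adjacent pairs, symmetric accumulation doubles them
  counts <- mats$h * 24
  expect_equal(counts[1, 1], 4)   # (0,0) pairs: hand count = 4
  expect_equal(counts[2, 2], 4)   # (1,1)
  expect_equal(counts[3, 3], 6)   # (2,2)
  expect_equal(counts[4, 4], 2)   # (3,3)
  expect_equal(sum(counts), 24)
})

test_that("checkerboard contrast equals (G-1)^2 for the horizontal matrix", {
  G <- 32L
  cell <- matrix(c(0, G - 1, G - 1, 0), 2, 2)
  board <- cell[rep(1:2, 4), rep(1:2, 4)]  # 8x8 tiling
  mats <- mammotex:::glcm_matrices(mammotex:::quantize_gray(board, G), G)
  st <- mammotex:::haralick_statistics(mats$h)
  expect_equal(st[["Contrast"]], (G - 1)^2)
})

test_that("gray-level difference statistics match pair enumeration on a checkerboard", {
  board <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
  d <- compute_glds_features(board, deltas = list(c(0L, 1L)))
  # every horizontal pair differs by exactly 1
  expect_equal(unname(d), c(0.5, 1, 1, 1, 0),
               tolerance = 1e-12)  # homog, contrast, mean, energy, entropy
  # probability axioms on an arbitrary image
  set.seed(1)
  img <- matrix(sample(0:255, 15 * 17, replace = TRUE), 15, 17)
  q <- mammotex:::quantize_gray(img, 32L)
  p <- tabulate(abs(q[, -1] - q[, -17]) + 1L, nbins = 32L) / (15 * 16)
  expect_equal(sum(p), 1)
  expect_gte(mammotex:::shannon_entropy(p), 0)
})

test_that("first-order moments agree with the pixelwise oracle", {
  v <- c(1, 1, 3, 3)
  f <- compute_fos_features(matrix(v, 2, 2))
  expect_equal(unname(f), c(2, 1, 0, 1))
  set.seed(2)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  f2 <- compute_fos_features(img)
  mu <- mean(img)
  expect_equal(f2[["Mean"]], mu)
  expect_equal(f2[["Variance"]], sum((img - mu)^2) / length(img))
  expect_equal(f2[["Skewness"]],
               mean((img - mu)^3) / f2[["Variance"]]^1.5)
})

test_that("SFM dissimilarity is zero at zero displacement and periodicity detects stripes", {
  set.seed(3)
  img <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
  m <- mammotex:::sfm_dissimilarity(mammotex:::quantize_gray(img, 32L),
                                    4L, 4L)
  expect_equal(m$dss[1, 1], 0)
  # vertically striped period-2 image vs white noise of equal variance
  stripes <- matrix(rep(c(0, 200), length.out = 20), 20, 20, byrow = TRUE)
  per_stripe <- compute_sfm_features(stripes)[["Periodicity"]]
  per_noise <- vapply(1:20, function(s) {
    set.seed(s)
    noise <- matrix(sample(c(0, 200), 400, replace = TRUE), 20, 20)
    compute_sfm_features(noise)[["Periodicity"]]
  }, numeric(1))
  expect_gt(per_stripe, max(per_noise))
})

test_that("the Laws bank has 14 valid masks and energies match a direct convolution", {
  masks <- laws_masks()
  expect_length(masks, 14)
  expect_named(masks, c("EE", "SS", "WW", "RR", "EL", "SL", "WL", "RL",
                        "SE", "WE", "RE", "WS", "RS", "RW"))
  v <- mammotex:::laws_vectors()
  for (nm in names(masks)) {
    a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
    expect_equal(masks[[nm]], outer(v[[a]], v[[b]]))
    expect_equal(sum(masks[[nm]]), 0)  # every mask has an E/S/W/R factor
  }
  # horizontal ramp: compare EL energy with a brute-force convolution
  ramp <- outer(rep(1, 12), 1:12)
  brute <- function(img, k) {
    nr <- nrow(img) - 4; nc <- ncol(img) - 4
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      out[i, j] <- sum(img[i:(i + 4), j:(j + 4)] * k)
    }
    mean(abs(out))
  }
  expected <- (brute(ramp, outer(v$E, v$L)) + brute(ramp, outer(v$L, v$E))) / 2
  got <- compute_ltem_features(ramp)
  expect_equal(got[["EL"]], expected)
  # and the separable closed form: E5 on a unit ramp gives sum(w*k) = 8,
  # L5 across the constant direction sums to 16
  expect_equal(brute(ramp, outer(v$L, v$E)), 8 * 16)
})

test_that("Hurst estimates order correctly on synthetic fractional Brownian fields", {
  h_est <- function(h, seeds) {
    vapply(seeds, function(s) {
      estimate_hurst(30 * fbm_texture(64, h, seed = s), 8L)
    }, numeric(1))
  }
  lo <- mean(h_est(0.2, 1:8))
  hi <- mean(h_est(0.8, 1:8))
  expect_lt(lo, hi)
  expect_true(all(h_est(0.5, 1:4) >= 0 & h_est(0.5, 1:4) <= 1))
})

test_that("power spectrum features isolate a sinusoid and obey Parseval", {
  n <- 32
  sinus <- outer(rep(1, n), sin(2 * pi * 6 * (0:(n - 1)) / n))
  f <- compute_fps_features(sinus)
  expect_gte(f[["Sr"]], 0.99)      # 6/32 cycles/px is inside the annulus
  expect_gte(f[["Stheta"]], 0.99)  # horizontal pattern, wedge at 0 deg
  set.seed(4)
  img <- matrix(rnorm(n * n), n, n)
  phi_total <- sum(Mod(stats::fft(img))^2)
  expect_equal(phi_total, length(img) * sum(img^2),
               tolerance = 1e-6)
})

test_that("gray-offset invariance holds exactly where definitions imply it", {
  set.seed(5)
  img <- matrix(sample(40:200, 24 * 24, replace = TRUE), 24, 24)
  shifted <- img + 17
  expect_equal(compute_glds_features(shifted), compute_glds_features(img))
  expect_equal(compute_sfm_features(shifted), compute_sfm_features(img))
  expect_equal(compute_ltem_features(shifted), compute_ltem_features(img))
  expect_equal(compute_fractal_features(shifted),
               compute_fractal_features(img))
  # FOS mean is not offset-invariant
  expect_equal(compute_fos_features(shifted)[["Mean"]],
               compute_fos_features(img)[["Mean"]] + 17)
})

test_that("the texture block emits exactly 45 values in catalog order", {
  set.seed(6)
  img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  v <- compute_texture_features(lesion_sample(img, matrix(TRUE, 32, 32)))
  expect_length(v, 45)
  expect_equal(names(v), feature_catalog()$column[1:45])
  g <- compute_sglcm_features(img)
  expect_gt(g[["ASM"]], 0)
  expect_lte(g[["ASM"]], 1)
  expect_gte(g[["Entropy"]], 0)
})
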