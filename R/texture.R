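# Texture feature models F1-F45. All operate on the rectangular
# bounding-box ROI of a lesion sample (matrix/convolution operators need a
# regular grid); gray-level statistics (GLCM, GLDS, SFM) run on the image
# requantized to G levels.

# ---- gray-level co-occurrence (Haralick) ------------------------------

# Four symmetric normalized co-occurrence matrices at displacement 1 for
# the directions 0, 90, 45 and 135 degrees.
glcm_matrices <- function(q, G) {
  offsets <- list(h = c(0L, 1L), v = c(1L, 0L),
                  rd = c(1L, 1L), ld = c(1L, -1L))
  nr <- nrow(q); nc <- ncol(q)
  lapply(offsets, function(off) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    counts <- tabulate(as.vector(a) * G + as.vector(b) + 1L, nbins = G * G)
    m <- matrix(counts, G, G, byrow = TRUE)
    m <- m + t(m)
    m / sum(m)
  })
}

# The 14 Haralick statistics of one normalized symmetric GLCM.
# Levels are indexed 1..G. Degenerate marginals (zero variance) give
# correlation = 0 and maximal correlation coefficient = 0.
haralick_statistics <- function(P) {
  G <- nrow(P)
  lev <- seq_len(G)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  ii <- row(P); jj <- col(P)
  # diagonal sums: p_{x+y}(k), k = 2..2G and p_{x-y}(k), k = 0..G-1
  p_sum <- as.vector(tapply(P, ii + jj, sum))
  k_sum <- sort(unique(as.vector(ii + jj)))
  p_dif <- as.vector(tapply(P, abs(ii - jj), sum))
  k_dif <- sort(unique(as.vector(abs(ii - jj))))

  asm <- sum(P^2)
  contrast <- sum(k_dif^2 * p_dif)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (sum(ii * jj * P) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  sum_squares <- sum((ii - mu_x)^2 * P)
  idm <- sum(P / (1 + (ii - jj)^2))
  sum_average <- sum(k_sum * p_sum)
  sum_variance <- sum((k_sum - sum_average)^2 * p_sum)
  sum_entropy <- shannon_entropy(p_sum)
  entropy <- shannon_entropy(as.vector(P))
  dif_mean <- sum(k_dif * p_dif)
  dif_variance <- sum((k_dif - dif_mean)^2 * p_dif)
  dif_entropy <- shannon_entropy(p_dif)
  hx <- shannon_entropy(px); hy <- shannon_entropy(py)
  pq <- outer(px, py)
  pos <- P > 0 & pq > 0
  hxy1 <- -sum(P[pos] * log(pq[pos]))
  hxy2 <- shannon_entropy(as.vector(pq))
  info1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  info2 <- sqrt(1 - exp(-2 * max(hxy2 - entropy, 0)))
  # maximal correlation coefficient: sqrt of 2nd largest eigenvalue of Q
  keep <- px > 0
  mcc <- 0
  if (sum(keep) >= 2) {
    Pk <- P[keep, keep, drop = FALSE]
    Q <- (Pk / px[keep]) %*% t(Pk / py[keep])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(min(ev[2], 1), 0))
  }
  c(ASM = asm, Contrast = contrast, Correlation = correlation,
    Sum_Squares = sum_squares, Inverse_Diff_Moment = idm,
    Sum_Average = sum_average, Sum_Variance = sum_variance,
    Sum_Entropy = sum_entropy, Entropy = entropy,
    Diff_Variance = dif_variance, Diff_Entropy = dif_entropy,
    Info_Measure1 = info1, Info_Measure2 = info2, Max_Corr_Coff = mcc)
}

#' Co-occurrence (Haralick) texture features F1-F14
#'
#' Computes the 14 Haralick statistics on each of four symmetric
#' co-occurrence matrices (0, 90, 45, 135 degrees, displacement 1) of the
#' G-level requantized ROI, averaged over the four directions.
#'
#' @param sample A \code{\link{lesion_sample}} (or plain matrix).
#' @param G Number of quantized gray levels (default 32).
#' @return Named numeric vector of 14 features.
#' @export
compute_sglcm_features <- function(sample, G = 32L) {
  roi <- if (inherits(sample, "lesion_sample")) sample$roi else
    as.matrix(sample)
  stopifnot(nrow(roi) >= 2, ncol(roi) >= 2, G >= 2)
  q <- quantize_gray(roi, G)
  mats <- glcm_matrices(q, G)
  rowMeans(sapply(mats, haralick_statistics))
}

# ---- gray-level difference statistics ---------------------------------

#' Gray-level difference statistics F15-F19
#'
#' Features of the probability density of absolute gray-level differences
#' \eqn{|I(x,y) - I(x+\Delta x, y+\Delta y)|}, averaged over the
#' displacement set.
#'
#' @inheritParams compute_sglcm_features
#' @param deltas List of (row, col) displacements; default the four unit
#'   displacements (0,1), (1,0), (1,1), (1,-1).
#' @return Named vector: homogeneity, contrast, mean, energy, entropy.
#' @export
compute_glds_features <- function(sample,
                                  deltas = list(c(0L, 1L), c(1L, 0L),
                                                c(1L, 1L), c(1L, -1L)),
                                  G = 32L) {
  roi <- if (inherits(sample, "lesion_sample")) sample$roi else
    as.matrix(sample)
  stopifnot(nrow(roi) >= 2, ncol(roi) >= 2)
  q <- quantize_gray(roi, G)
  nr <- nrow(q); nc <- ncol(q)
  feats <- sapply(deltas, function(off) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - abs(dr))
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    d <- abs(q[r1, c1, drop = FALSE] -
               q[r1 + abs(dr), c1 + dc, drop = FALSE])
    p <- tabulate(as.vector(d) + 1L, nbins = G) / length(d)
    i <- 0:(G - 1)
    c(Homogeneity = sum(p / (1 + i)),
      Contrast = sum(i^2 * p),
      Mean = sum(i * p),
      Energy = sum(p^2),
      Entropy = shannon_entropy(p))
  })
  rowMeans(feats)
}

# ---- first-order statistics -------------------------------------------

#' First-order (histogram) statistics F20-F23
#'
#' Population moments of the gray-level histogram: mean, variance,
#' skewness and kurtosis (non-excess). A constant ROI has zero variance;
#' skewness and kurtosis then fall back to 0.
#'
#' @inheritParams compute_sglcm_features
#' @return Named vector: mean, variance, skewness, kurtosis.
#' @export
compute_fos_features <- function(sample) {
  roi <- if (inherits(sample, "lesion_sample")) sample$roi else
    as.matrix(sample)
  v <- as.vector(roi)
  stopifnot(length(v) >= 1)
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  if (s2 == 0) {
    return(c(Mean = mu, Variance = 0, Skewness = 0, Kurtosis = 0))
  }
  c(Mean = mu, Variance = s2,
    Skewness = mean((v - mu)^3) / s2^1.5,
    Kurtosis = mean((v - mu)^4) / s2^2)
}

# ---- statistical feature matrix ---------------------------------------

# Mean absolute (DSS) and mean squared difference over displacement (i,j).
sfm_dissimilarity <- function(q, Lr, Lc) {
  nr <- nrow(q); nc <- ncol(q)
  dss <- matrix(0, Lr + 1, Lc + 1)
  sq <- matrix(0, Lr + 1, Lc + 1)
  for (i in 0:Lr) for (j in 0:Lc) {
    if (i == 0 && j == 0) next
    d <- q[seq_len(nr - i), seq_len(nc - j), drop = FALSE] -
      q[seq_len(nr - i) + i, seq_len(nc - j) + j, drop = FALSE]
    dss[i + 1, j + 1] <- mean(abs(d))
    sq[i + 1, j + 1] <- mean(d^2)
  }
  list(dss = dss, sq = sq)
}

#' Statistical feature matrix texture features F24-F27
#'
#' Builds the dissimilarity matrix \eqn{DSS(i,j) = E|I(x,y) -
#' I(x+i,y+j)|} over the displacement lattice \eqn{0 \le i \le L_r},
#' \eqn{0 \le j \le L_c} on the requantized ROI and derives four scalars:
#' coarseness (inverse mean dissimilarity, scaled by 100), contrast (RMS
#' of the unit-displacement squared differences), periodicity (relative
#' depth of the deepest dissimilarity valley) and roughness (mean of the
#' directional fractal dimensions \eqn{3 - H} fitted from the log-log
#' dissimilarity decay along rows and columns).
#'
#' @inheritParams compute_sglcm_features
#' @param Lr,Lc Maximum inter-sample spacings (default 4).
#' @return Named vector: coarseness, contrast, periodicity, roughness.
#' @export
compute_sfm_features <- function(sample, Lr = 4L, Lc = 4L, G = 32L) {
  roi <- if (inherits(sample, "lesion_sample")) sample$roi else
    as.matrix(sample)
  stopifnot(nrow(roi) > Lr + 1, ncol(roi) > Lc + 1)
  q <- quantize_gray(roi, G)
  m <- sfm_dissimilarity(q, Lr, Lc)
  nz <- as.vector(m$dss)[-1]  # drop the (0,0) entry (index 1, column-major)
  mean_dss <- mean(nz)
  coarseness <- if (mean_dss > 0) 100 / mean_dss else 0
  contrast <- sqrt((m$sq[1, 2] + m$sq[2, 1]) / 2)
  periodicity <- if (mean_dss > 0) (mean_dss - min(nz)) / mean_dss else 0
  dir_dim <- function(vals) {
    d <- seq_along(vals)
    ok <- vals > 0
    if (sum(ok) < 2) return(NA_real_)
    h <- stats::coef(stats::lm(log(vals[ok]) ~ log(d[ok])))[[2]]
    3 - min(max(h, 0), 1)
  }
  dh <- dir_dim(m$dss[1, -1])
  dv <- dir_dim(m$dss[-1, 1])
  roughness <- mean(c(dh, dv), na.rm = TRUE)
  if (!is.finite(roughness)) roughness <- 0
  c(Coarseness = coarseness, Contrast = contrast,
    Periodicity = periodicity, Roughness = roughness)
}

# ---- Laws texture energy ----------------------------------------------

laws_vectors <- function() {
  list(L = c(1, 4, 6, 4, 1),
       E = c(-1, -2, 0, 2, 1),
       S = c(-1, 0, 2, 0, -1),
       W = c(-1, 2, 0, -2, 1),
       R = c(1, -4, 6, -4, 1))
}

#' The 14 Laws 5x5 texture energy masks
#'
#' Each mask is the outer product of a column vector and a row vector from
#' the level/edge/spot/wave/ripple bank L5, E5, S5, W5, R5. The 14 named
#' masks are the four symmetric pairs EE, SS, WW, RR and the ten mixed
#' pairs EL, SL, WL, RL, SE, WE, RE, WS, RS, RW.
#'
#' @return Named list of 14 5x5 matrices.
#' @export
laws_masks <- function() {
  v <- laws_vectors()
  names14 <- c("EE", "SS", "WW", "RR", "EL", "SL", "WL", "RL",
               "SE", "WE", "RE", "WS", "RS", "RW")
  masks <- lapply(names14, function(nm) {
    a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
    outer(v[[a]], v[[b]])
  })
  names(masks) <- names14
  masks
}

# valid-region 2-D correlation with a small kernel
conv2_valid <- function(img, k) {
  nr <- nrow(img) - nrow(k) + 1
  nc <- ncol(img) - ncol(k) + 1
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      if (k[a, b] == 0) next
      out <- out + k[a, b] *
        img[a:(a + nr - 1), b:(b + nc - 1), drop = FALSE]
    }
  }
  out
}

#' Laws texture energy measures F28-F41
#'
#' Convolves the ROI with each 5x5 Laws mask and reports the mean absolute
#' response over fully-overlapping positions. The two orientations of each
#' mixed mask (XY and YX) are averaged into one feature, giving 14 values
#' in the mask order EE, SS, WW, RR, EL, SL, WL, RL, SE, WE, RE, WS, RS,
#' RW.
#'
#' @inheritParams compute_sglcm_features
#' @return Named numeric vector of 14 energies.
#' @export
compute_ltem_features <- function(sample) {
  roi <- if (inherits(sample, "lesion_sample")) sample$roi else
    as.matrix(sample)
  if (nrow(roi) < 5 || ncol(roi) < 5) {
    stop("LTEM requires an ROI of at least 5x5 pixels")
  }
  v <- laws_vectors()
  masks <- laws_masks()
  energy <- function(a, b) mean(abs(conv2_valid(roi, outer(v[[a]], v[[b]]))))
  vapply(names(masks), function(nm) {
    a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
    if (a == b) energy(a, b) else (energy(a, b) + energy(b, a)) / 2
  }, numeric(1))
}

# ---- fractal (Hurst) --------------------------------------------------

#' Estimate the Hurst exponent of an image patch
#'
#' Fits the slope of \eqn{\log E|I(p) - I(q)|} against \eqn{\log \|p-q\|}
#' over all pixel pairs grouped by rounded Euclidean distance 1..max_dist
#' (fractional-Brownian-motion increment scaling). The estimate is clipped
#' to [0, 1]; a constant patch returns 0.
#'
#' @param img Numeric matrix.
#' @param max_dist Largest pair distance used (default 8).
#' @return Scalar Hurst estimate in [0, 1].
#' @export
estimate_hurst <- function(img, max_dist = 8L) {
  img <- as.matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  sums <- numeric(max_dist)
  counts <- numeric(max_dist)
  for (di in 0:max_dist) {
    for (dj in (-max_dist):max_dist) {
      if (di == 0 && dj <= 0) next
      rd <- as.integer(round(sqrt(di^2 + dj^2)))
      if (rd < 1 || rd > max_dist) next
      if (di >= nr || abs(dj) >= nc) next
      r1 <- seq_len(nr - di)
      c1 <- if (dj >= 0) seq_len(nc - dj) else seq(1 - dj, nc)
      d <- abs(img[r1, c1, drop = FALSE] -
                 img[r1 + di, c1 + dj, drop = FALSE])
      sums[rd] <- sums[rd] + sum(d)
      counts[rd] <- counts[rd] + length(d)
    }
  }
  mad <- ifelse(counts > 0, sums / counts, 0)
  ok <- mad > 0
  if (sum(ok) < 2) return(0)
  slope <- stats::coef(stats::lm(log(mad[ok]) ~ log(seq_len(max_dist)[ok])))[[2]]
  min(max(slope, 0), 1)
}

#' Fractal texture features F42-F43 (Hurst coefficients at two resolutions)
#'
#' H1 is estimated on the full-resolution ROI (pair distances 1..8); H2 on
#' the ROI downsampled 2x by 2x2 block averaging (distances 1..4).
#'
#' @inheritParams compute_sglcm_features
#' @return Named vector \code{c(H1, H2)}.
#' @export
compute_fractal_features <- function(sample) {
  roi <- if (inherits(sample, "lesion_sample")) sample$roi else
    as.matrix(sample)
  stopifnot(nrow(roi) >= 8, ncol(roi) >= 8)
  h1 <- estimate_hurst(roi, 8L)
  nr2 <- floor(nrow(roi) / 2); nc2 <- floor(ncol(roi) / 2)
  r <- roi[seq_len(2 * nr2), seq_len(2 * nc2), drop = FALSE]
  ds <- (r[seq(1, 2 * nr2, 2), seq(1, 2 * nc2, 2)] +
           r[seq(2, 2 * nr2, 2), seq(1, 2 * nc2, 2)] +
           r[seq(1, 2 * nr2, 2), seq(2, 2 * nc2, 2)] +
           r[seq(2, 2 * nr2, 2), seq(2, 2 * nc2, 2)]) / 4
  h2 <- estimate_hurst(ds, 4L)
  c(H1 = h1, H2 = h2)
}

# ---- Fourier power spectrum -------------------------------------------

#' Fourier power spectrum features F44-F45
#'
#' Computes the sample power spectrum \eqn{\phi(u,v) = |F(u,v)|^2} of the
#' ROI and reports the fraction of non-DC power in a radial annulus
#' (default quarter to half Nyquist) and in an angular wedge (default
#' +/- 22.5 degrees about the horizontal frequency axis).
#'
#' @inheritParams compute_sglcm_features
#' @param annulus Radial band in cycles/pixel (Nyquist = 0.5).
#' @param wedge_half_angle Half-angle of the wedge in degrees.
#' @return Named vector \code{c(Sr, Stheta)}.
#' @export
compute_fps_features <- function(sample, annulus = c(0.125, 0.25),
                                 wedge_half_angle = 22.5) {
  roi <- if (inherits(sample, "lesion_sample")) sample$roi else
    as.matrix(sample)
  nr <- nrow(roi); nc <- ncol(roi)
  stopifnot(nr >= 4, nc >= 4)
  phi <- Mod(stats::fft(roi))^2
  fr <- (seq_len(nr) - 1) / nr; fr[fr >= 0.5] <- fr[fr >= 0.5] - 1
  fc <- (seq_len(nc) - 1) / nc; fc[fc >= 0.5] <- fc[fc >= 0.5] - 1
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  nondc <- rad > 0
  total <- sum(phi[nondc])
  if (total == 0) return(c(Sr = 0, Stheta = 0))
  in_annulus <- nondc & rad >= annulus[1] & rad < annulus[2]
  ang <- atan2(outer(fr, rep(1, nc)), outer(rep(1, nr), fc)) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90  # fold to (-90, 90], horizontal = 0
  in_wedge <- nondc & abs(ang) <= wedge_half_angle
  c(Sr = sum(phi[in_annulus]) / total,
    Stheta = sum(phi[in_wedge]) / total)
}

#' All 45 texture features (F1-F45) in catalog order
#'
#' @inheritParams compute_sglcm_features
#' @param config An \code{\link{analysis_config}} supplying tunables
#'   (quantization levels).
#' @return Named numeric vector of length 45 (catalog column names).
#' @export
compute_texture_features <- function(sample, config = analysis_config()) {
  G <- config$glcm_levels
  vals <- c(compute_sglcm_features(sample, G),
            compute_glds_features(sample, G = G),
            compute_fos_features(sample),
            compute_sfm_features(sample, G = G),
            compute_ltem_features(sample),
            compute_fractal_features(sample),
            compute_fps_features(sample))
  names(vals) <- catalog_columns()[1:45]
  vals
}
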