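#' Lesion generator parameters
#'
#' Parameter bundle for one synthetic mass lesion. The phantom emulates the
#' two radiological archetypes the classifier must separate: benign masses
#' are round/oval with well-circumscribed smooth boundaries and relatively
#' homogeneous interior texture; malignant masses are irregular with rough,
#' spiculated boundaries and heterogeneous (rougher, lower-Hurst) texture.
#'
#' @param label \code{"benign"} or \code{"malignant"}.
#' @param base_radius Mean mass radius in pixels.
#' @param spiculation_amplitude Radial perturbation amplitude as a fraction
#'   of the radius, in [0, 1).
#' @param spiculation_count Number of spicule lobes (dominant angular
#'   harmonic of the boundary perturbation), integer >= 0.
#' @param boundary_smoothness Low-pass cutoff (highest angular harmonic
#'   retained) of the radial perturbation; lower = smoother outline.
#' @param texture_hurst Target Hurst exponent of the interior fractional
#'   Brownian texture, in (0, 1); lower = rougher.
#' @param texture_contrast Gray-level standard deviation inside the mass.
#' @param background_level Mean gray level of surrounding tissue.
#' @param patch_size Side of the square patch in pixels; must hold the mass
#'   plus a margin of at least 5 px.
#' @param seed Integer RNG seed for this lesion.
#' @return A list of class \code{lesion_params}.
#' @export
lesion_params <- function(label,
                          base_radius = 22,
                          spiculation_amplitude = if (label == "benign")
                            0.06 else 0.35,
                          spiculation_count = if (label == "benign") 5L
                            else 11L,
                          boundary_smoothness = if (label == "benign") 8L
                            else 24L,
                          texture_hurst = if (label == "benign") 0.65
                            else 0.35,
                          texture_contrast = if (label == "benign") 10
                            else 22,
                          background_level = 90,
                          patch_size = 96L,
                          seed = 1L) {
  stopifnot(label %in% c("benign", "malignant"),
            spiculation_amplitude >= 0, spiculation_amplitude < 1,
            spiculation_count >= 0,
            texture_hurst > 0, texture_hurst < 1,
            base_radius > 0, patch_size >= 16)
  structure(list(label = label, base_radius = base_radius,
                 spiculation_amplitude = spiculation_amplitude,
                 spiculation_count = as.integer(spiculation_count),
                 boundary_smoothness = as.integer(boundary_smoothness),
                 texture_hurst = texture_hurst,
                 texture_contrast = texture_contrast,
                 background_level = background_level,
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "lesion_params")
}

#' Default benign / malignant presets
#' @return Named list with \code{benign} and \code{malignant}
#'   \code{\link{lesion_params}}.
#' @export
default_presets <- function() {
  list(benign = lesion_params("benign"),
       malignant = lesion_params("malignant"))
}

#' Synthesize isotropic fractional-Brownian-motion-like texture
#'
#' Spectral synthesis: complex Gaussian white noise is shaped by an
#' amplitude spectrum proportional to \eqn{f^{-(H+1)}} (power
#' \eqn{f^{-(2H+2)}}), the 2-D exponent for which mean absolute increments
#' scale as \eqn{d^{H}}. The field is normalized to zero mean, unit
#' standard deviation.
#'
#' @param n Side of the square field in pixels.
#' @param hurst Target Hurst exponent in (0, 1).
#' @param seed Integer seed.
#' @return n x n numeric matrix.
#' @export
fbm_texture <- function(n, hurst, seed = 1L) {
  stopifnot(hurst > 0, hurst < 1, n >= 4)
  with_seed(seed, {
    w <- matrix(stats::rnorm(n * n), n, n) +
      1i * matrix(stats::rnorm(n * n), n, n)
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    f2 <- outer(k^2, k^2, "+")
    amp <- f2^(-(hurst + 1) / 2)
    amp[1, 1] <- 0
    field <- Re(stats::fft(w * amp, inverse = TRUE)) / (n * n)
    field <- field - mean(field)
    s <- stats::sd(field)
    if (s > 0) field <- field / s
    field
  })
}

# Smoothed periodic radial perturbation with `count` dominant lobes,
# band-limited at `cutoff`, normalized to max|s| = 1.
radial_perturbation <- function(theta, count, cutoff) {
  if (count == 0) return(rep(0, length(theta)))
  harmonics <- 2:max(cutoff, 2)
  width <- max(count / 3, 1)
  w <- exp(-((harmonics - count)^2) / (2 * width^2))
  w[harmonics > cutoff] <- 0
  if (all(w == 0)) w[which.min(abs(harmonics - count))] <- 1
  a <- stats::rnorm(length(harmonics)) * w
  phi <- stats::runif(length(harmonics), 0, 2 * pi)
  s <- rowSums(sapply(seq_along(harmonics), function(i) {
    a[i] * cos(harmonics[i] * theta + phi[i])
  }))
  m <- max(abs(s))
  if (m > 0) s / m else s
}

#' Generate one synthetic mass lesion
#'
#' The boundary is the radial curve \eqn{r(\theta) = R (1 + a\, s(\theta))}
#' with \eqn{s} a smoothed periodic perturbation having
#' \code{spiculation_count} lobes; the interior is filled with correlated
#' fractional-Brownian noise at the target Hurst exponent, brighter than
#' the background tissue by a fixed 60 gray-level offset.
#'
#' @param params A \code{\link{lesion_params}}.
#' @return List with \code{image} (8-bit gray matrix), \code{boundary}
#'   (m x 2 (x, y) points, open polygon), \code{mask} (logical matrix) and
#'   \code{label}.
#' @export
generate_lesion <- function(params) {
  stopifnot(inherits(params, "lesion_params"))
  S <- params$patch_size
  cx <- (S - 1) / 2
  rmax_possible <- params$base_radius * (1 + params$spiculation_amplitude)
  if (rmax_possible + 5 > (S - 1) / 2) {
    stop("mass (radius ", round(rmax_possible, 1),
         ") exceeds patch bounds for patch_size ", S,
         " with a 5 px margin")
  }
  with_seed(params$seed, {
    m <- 180L
    theta <- seq(0, 2 * pi, length.out = m + 1)[1:m]
    s <- radial_perturbation(theta, params$spiculation_count,
                             params$boundary_smoothness)
    r <- params$base_radius * (1 + params$spiculation_amplitude * s)
    boundary <- cbind(x = cx + r * cos(theta), y = cx + r * sin(theta))
    mask <- contour_to_mask(boundary, c(S, S))
    bg <- params$background_level +
      6 * fbm_texture(S, 0.6, seed = stats::runif(1, 1, 2^30))
    interior <- (params$background_level + 60) +
      params$texture_contrast *
        fbm_texture(S, params$texture_hurst,
                    seed = stats::runif(1, 1, 2^30))
    img <- bg
    img[mask] <- interior[mask]
    img <- matrix(pmin(pmax(round(img), 0), 255), S, S)
    list(image = img, boundary = unname(boundary), mask = mask,
         label = params$label)
  })
}

#' Generate a labeled synthetic lesion dataset
#'
#' Draws \code{n_benign + n_malignant} lesions from the class presets.
#' Per-sample seeds are derived deterministically from \code{master_seed}
#' and the sample index, so regeneration is bit-identical and independent
#' of generation order. Mass size and lobe count are jittered per sample
#' (radius uniform in ±25%, lobe count ±2) to emulate natural variability.
#'
#' @param n_benign,n_malignant Class sample counts (>= 0).
#' @param presets Named list with \code{benign} and \code{malignant}
#'   \code{\link{lesion_params}}; default \code{\link{default_presets}()}.
#' @param master_seed Integer master seed.
#' @details Per-sample morphology is jittered around the class preset
#'   (radius uniform in ±25%, lobe count ±2, spiculation amplitude scaled
#'   by U(0.2, 1.8) capped at 0.5, Hurst exponent shifted by U(-0.2, 0.2),
#'   texture contrast scaled by U(0.6, 1.5)). The class parameter
#'   distributions deliberately overlap: benign and malignant masses in
#'   real mammograms are not cleanly separated in any single morphological
#'   axis, and a phantom without overlap would make the classification
#'   task trivially saturated.
#' @return A list of class \code{synthetic_dataset} with \code{samples}
#'   (each: sample_id, image, boundary, mask, label), \code{class_counts}
#'   and \code{master_seed}.
#' @export
generate_dataset <- function(n_benign, n_malignant,
                             presets = default_presets(),
                             master_seed = 7L) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  samples <- lapply(seq_along(labels), function(i) {
    p <- presets[[labels[[i]]]]
    jit <- with_seed(derive_seed(master_seed, i + 500000L), {
      list(radius = stats::runif(1, 0.75, 1.25),
           lobes = sample(-2:2, 1),
           amp = stats::runif(1, 0.2, 1.8),
           hurst = stats::runif(1, -0.2, 0.2),
           contrast = stats::runif(1, 0.6, 1.5))
    })
    p$base_radius <- p$base_radius * jit$radius
    if (p$spiculation_count > 0) {
      p$spiculation_count <-
        max(1L, p$spiculation_count + as.integer(jit$lobes))
    }
    p$spiculation_amplitude <- min(p$spiculation_amplitude * jit$amp, 0.5)
    p$texture_hurst <- min(max(p$texture_hurst + jit$hurst, 0.1), 0.9)
    p$texture_contrast <- p$texture_contrast * jit$contrast
    p$seed <- derive_seed(master_seed, i)
    les <- generate_lesion(p)
    les$sample_id <- sprintf("%s%03d", substr(labels[[i]], 1, 1), i)
    les
  })
  structure(list(samples = samples,
                 class_counts = c(n_benign = n_benign,
                                  n_malignant = n_malignant),
                 master_seed = as.integer(master_seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic lesion dataset:", length(x$samples), "samples (",
      x$class_counts[["n_benign"]], "benign /",
      x$class_counts[["n_malignant"]], "malignant ), master seed",
      x$master_seed, "\n")
  invisible(x)
}
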