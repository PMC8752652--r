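# Geometry feature models F46-F125: 13 shape descriptors, 15 Zernike
# moment magnitudes, 52 generic Fourier descriptors. All operate on the
# binary lesion mask.

# ---- binary-morphology helpers ----------------------------------------

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

neighbor_offsets <- function(conn) {
  if (conn == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
}

# Connected-component labeling by iterative minimum-label propagation.
label_components <- function(mask, conn = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  offs <- neighbor_offsets(conn)
  big <- .Machine$integer.max
  repeat {
    prev <- lab
    work <- ifelse(mask, lab, big)
    for (off in offs) {
      work <- pmin(work, shift_mat(work, off[1], off[2], fill = big))
    }
    lab[mask] <- work[mask]
    if (identical(lab, prev)) break
  }
  u <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], u)
  lab
}

# Background pixels 4-connected to the image border (outside region).
outer_background <- function(mask) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(mask)] <- bg[, ncol(mask)]
  offs <- neighbor_offsets(4)
  repeat {
    prev <- reach
    for (off in offs) {
      reach <- reach | (bg & shift_mat(reach, off[1], off[2]))
    }
    if (identical(reach, prev)) break
  }
  reach
}

# Moore boundary trace of one 8-connected component containing `start`
# (matrix index, column-major: leftmost foreground column, topmost pixel).
# Maintains (current, backtrack) pixel state; terminates when the initial
# state recurs. Returns the ordered (row, col) path.
trace_boundary <- function(mask, start) {
  nr <- nrow(mask)
  dirs <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                 ncol = 2, byrow = TRUE)  # N NE E SE S SW W NW (clockwise)
  at <- function(r, c) {
    r >= 1 && r <= nr && c >= 1 && c <= ncol(mask) && mask[r, c]
  }
  sr <- ((start - 1) %% nr) + 1
  sc <- ((start - 1) %/% nr) + 1
  # backtrack starts due west of the start pixel: background, because the
  # start is in the leftmost foreground column
  cr <- sr; cc <- sc
  br <- sr; bc <- sc - 1
  path <- matrix(c(sr, sc), ncol = 2)
  state0 <- c(sr, sc, br, bc)
  steps <- 0L
  max_steps <- 4L * length(mask) + 8L
  repeat {
    # index of the direction current -> backtrack
    d0 <- which(dirs[, 1] == br - cr & dirs[, 2] == bc - cc)
    found <- FALSE
    lr <- br; lc <- bc  # last background cell visited in the scan
    for (k in seq_len(8)) {
      d <- ((d0 - 1L + k) %% 8L) + 1L  # clockwise, starting after d0
      rr <- cr + dirs[d, 1]; rc <- cc + dirs[d, 2]
      if (at(rr, rc)) {
        br <- lr; bc <- lc
        cr <- rr; cc <- rc
        found <- TRUE
        break
      }
      lr <- rr; lc <- rc
    }
    if (!found) break  # isolated pixel
    if (identical(c(cr, cc, br, bc), state0)) break
    path <- rbind(path, c(cr, cc))
    steps <- steps + 1L
    if (steps > max_steps) break
  }
  # drop the duplicated start if the trace closed on it
  n <- nrow(path)
  if (n > 1 && all(path[n, ] == path[1, ])) path <- path[-n, , drop = FALSE]
  path
}

# Polygonal length of the 8-connected boundary trace(s) of a mask.
boundary_perimeter <- function(mask) {
  lab <- label_components(mask, 8)
  total <- 0
  for (comp in seq_len(max(lab))) {
    inmask <- lab == comp
    start <- which(inmask)[1]
    p <- trace_boundary(inmask, start)
    if (nrow(p) < 2) next
    closed <- rbind(p, p[1, ])
    d <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                         closed[-nrow(closed), , drop = FALSE])^2))
    total <- total + sum(d)
  }
  total
}

# ---- shape descriptors -------------------------------------------------

#' Shape descriptors F46-F58
#'
#' Region properties of the binary lesion mask: area (foreground pixel
#' count), major/minor axis lengths, eccentricity and orientation of the
#' equivalent second-moment ellipse (with the 1/12 per-pixel moment
#' correction), convex area (pixel centers inside the convex hull), filled
#' area (after hole filling), Euler number (8-connected components minus
#' holes), equivalent diameter, solidity, extent, perimeter (polygonal
#' length of the 8-connected boundary trace) and the circularity ratio
#' perimeter^2 / (4 pi area).
#'
#' Orientation is reported in degrees in (-90, 90], measured from the row
#' axis toward increasing columns.
#'
#' @param mask Logical matrix (or \code{\link{lesion_sample}}).
#' @return Named numeric vector of 13 shape features.
#' @export
compute_shape_features <- function(mask) {
  if (inherits(mask, "lesion_sample")) mask <- mask$mask
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (!any(mask)) stop("empty mask")
  area <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  rbar <- mean(r); cbar <- mean(c)
  # normalized second central moments, pixel treated as a unit square
  urr <- mean((r - rbar)^2) + 1 / 12
  ucc <- mean((c - cbar)^2) + 1 / 12
  urc <- mean((r - rbar) * (c - cbar))
  common <- sqrt((urr - ucc)^2 + 4 * urc^2)
  l1 <- (urr + ucc + common) / 2
  l2 <- (urr + ucc - common) / 2
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
  orient <- 0.5 * atan2(2 * urc, urr - ucc) * 180 / pi
  if (orient <= -90) orient <- orient + 180
  if (orient > 90) orient <- orient - 180
  # convex area: pixel centers inside / on the hull of foreground centers
  convex_area <- area
  pts <- cbind(x = c, y = r)
  upts <- unique(pts)
  if (nrow(upts) >= 3) {
    h <- grDevices::chull(upts[, 1], upts[, 2])
    hull <- upts[h, , drop = FALSE]
    if (abs(polygon_area(hull[, 1], hull[, 2])) > 0) {
      # hull coordinates are 1-based (x=col, y=row); mask rasterizer is
      # 0-based, so shift
      hm <- contour_to_mask(cbind(hull[, 1] - 1, hull[, 2] - 1), dim(mask))
      convex_area <- sum(hm)
    }
  }
  holes_mask <- !mask & !outer_background(mask)
  filled_area <- area + sum(holes_mask)
  n_comp <- max(label_components(mask, 8))
  n_holes <- if (any(holes_mask)) max(label_components(holes_mask, 4)) else 0
  euler <- n_comp - n_holes
  equiv_diam <- sqrt(4 * area / pi)
  extent <- area / length(mask)
  perim <- boundary_perimeter(mask)
  cirratio <- perim^2 / (4 * pi * area)
  c(Area = area, Major_Axis_Length = major, Minor_Axis_Length = minor,
    Eccentricity = ecc, Orientation = orient, Convex_Area = convex_area,
    Filled_Area = filled_area, Euler_Number = euler,
    Equiv_Diameter = equiv_diam, Solidity = area / convex_area,
    Extent = extent, Perimeter = perim, Perimeter_Cirratio = cirratio)
}

# ---- Zernike moments ---------------------------------------------------

#' Zernike order/repetition pairs used by the battery
#'
#' The 15 pairs (n, m) with n = 0..4, |m| <= n and n - |m| even, signed m
#' (negative repetitions included), in order of increasing n then m. The
#' pair names (ZM00, ZM1-1, ZM11, ...) match the catalog.
#'
#' @return Data frame with columns \code{n} and \code{m} (15 rows).
#' @export
zernike_spec <- function() {
  rows <- do.call(rbind, lapply(0:4, function(n) {
    m <- seq(-n, n, by = 2)
    cbind(n = rep(n, length(m)), m = m)
  }))
  as.data.frame(rows)
}

# Radial polynomial R_nm(rho) for |m| <= n, n - |m| even.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  s_max <- (n - m) / 2
  out <- numeric(length(rho))
  for (s in 0:s_max) {
    coefs <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s))
    out <- out + coefs * rho^(n - 2 * s)
  }
  out
}

#' Zernike moment magnitudes F59-F73
#'
#' Computes \eqn{Z_{nm} = \frac{n+1}{\pi} \sum_x \sum_y f(x,y)
#' V_{nm}^*(x,y)} over the binary mask mapped onto the closed unit disk
#' (centroid-centered, radius = maximum centroid-to-foreground-pixel
#' distance) and reports the magnitudes \eqn{|Z_{nm}|} for the 15
#' order/repetition pairs of \code{\link{zernike_spec}}. Magnitudes are
#' rotation-invariant, and conjugate pairs (\eqn{\pm m}) are exactly equal
#' for a real-valued image.
#'
#' @param mask Logical matrix or \code{\link{lesion_sample}}.
#' @return Named numeric vector of 15 moment magnitudes.
#' @export
compute_zernike_moments <- function(mask) {
  if (inherits(mask, "lesion_sample")) mask <- mask$mask
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1] - mean(idx[, 1])
  x <- idx[, 2] - mean(idx[, 2])
  rmax <- max(sqrt(x^2 + y^2))
  if (rmax == 0) rmax <- 1
  rho <- sqrt(x^2 + y^2) / rmax
  theta <- atan2(y, x)
  spec <- zernike_spec()
  vals <- vapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n[i]; m <- spec$m[i]
    v <- zernike_radial(n, m, rho) * exp(-1i * m * theta)
    Mod((n + 1) / pi * sum(v))
  }, numeric(1))
  names(vals) <- catalog_columns()[59:73]
  vals
}

# ---- generic Fourier descriptors --------------------------------------

#' Generic Fourier descriptors F74-F125
#'
#' Modified polar Fourier transform of the binary mask about its centroid:
#' each foreground pixel contributes \eqn{\exp[-j(2\pi \rho r + \phi
#' \theta)]} with radius \eqn{r} normalized by the maximum centroid
#' distance, evaluated on the frequency grid \eqn{0 \le \rho < R = 4},
#' \eqn{0 \le \phi < T = 13}. The 52 descriptors are the normalized
#' magnitudes: \eqn{|PF(0,0)|/area} for the DC term and
#' \eqn{|PF(\rho,\phi)|/|PF(0,0)|} otherwise, ordered by FD index
#' \eqn{\rho T + \phi + 1}. Centroid centering makes them
#' translation-invariant; magnitudes make them rotation-invariant.
#'
#' @param mask Logical matrix or \code{\link{lesion_sample}}.
#' @param R,T Radial and angular frequency resolutions (4 x 13 = 52).
#' @return Named numeric vector FD1..FD52.
#' @export
compute_gfd <- function(mask, R = 4L, T = 13L) {
  if (inherits(mask, "lesion_sample")) mask <- mask$mask
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1] - mean(idx[, 1])
  x <- idx[, 2] - mean(idx[, 2])
  rmax <- max(sqrt(x^2 + y^2))
  if (rmax == 0) rmax <- 1
  rad <- sqrt(x^2 + y^2) / rmax
  theta <- atan2(y, x)
  area <- length(x)
  fd <- numeric(R * T)
  pf00 <- NULL
  for (rho in 0:(R - 1)) {
    for (phi in 0:(T - 1)) {
      pf <- sum(exp(-1i * (2 * pi * rad * rho + theta * phi)))
      k <- rho * T + phi + 1
      if (rho == 0 && phi == 0) {
        pf00 <- Mod(pf)
        fd[k] <- pf00 / area
      } else {
        fd[k] <- if (pf00 > 0) Mod(pf) / pf00 else 0
      }
    }
  }
  names(fd) <- catalog_columns()[74:125]
  fd
}

#' All 80 geometry features (F46-F125) in catalog order
#'
#' @param sample A \code{\link{lesion_sample}} (its mask is used).
#' @return Named numeric vector of length 80.
#' @export
compute_geometry_features <- function(sample) {
  mask <- if (inherits(sample, "lesion_sample")) sample$mask else
    as.matrix(sample)
  vals <- c(compute_shape_features(mask),
            compute_zernike_moments(mask),
            compute_gfd(mask))
  names(vals) <- catalog_columns()[46:125]
  vals
}
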