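#' Rasterize a lesion boundary polygon into a binary mask
#'
#' A pixel belongs to the mask when its center lies inside or on the
#' polygon (even-odd rule with an explicit on-boundary test). Coordinates
#' follow the annotation convention: boundary points are (x, y) =
#' (column, row), 0-based, with pixel centers at integer coordinates; the
#' returned mask is indexed (row, column).
#'
#' @param boundary n x 2 matrix of (x, y) vertices; the closing point may
#'   be present or implicit.
#' @param image_shape Integer (rows, cols) of the target image.
#' @return Logical matrix of dimension \code{image_shape}.
#' @export
contour_to_mask <- function(boundary, image_shape) {
  boundary <- as.matrix(boundary)
  n <- nrow(boundary)
  if (n >= 2 && all(boundary[n, ] == boundary[1, ])) {
    boundary <- boundary[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) stop("polygon must have at least 3 distinct points")
  xs <- boundary[, 1]; ys <- boundary[, 2]
  if (abs(polygon_area(xs, ys)) < .Machine$double.eps) {
    stop("degenerate polygon with zero area")
  }
  nr <- image_shape[[1]]; nc <- image_shape[[2]]
  px <- rep(0:(nc - 1), each = nr)   # x = column, column-major order
  py <- rep(0:(nr - 1), times = nc)  # y = row
  inside <- rep(FALSE, nr * nc)
  on_edge <- rep(FALSE, nr * nc)
  x2v <- c(xs[-1], xs[1]); y2v <- c(ys[-1], ys[1])
  for (e in seq_len(n)) {
    x1 <- xs[e]; y1 <- ys[e]; x2 <- x2v[e]; y2 <- y2v[e]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- px[crosses] < xi
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      on_edge <- on_edge | d2 < 1e-18
    } else {
      on_edge <- on_edge | ((px - x1)^2 + (py - y1)^2 < 1e-18)
    }
  }
  mask <- matrix(inside | on_edge, nrow = nr, ncol = nc)
  mask
}

# Signed shoelace area of a polygon.
polygon_area <- function(xs, ys) {
  n <- length(xs)
  j <- c(2:n, 1)
  sum(xs * ys[j] - xs[j] * ys) / 2
}

#' Construct a lesion sample (ROI patch + mask + label)
#'
#' @param roi 2-D grayscale matrix (8-bit range values).
#' @param mask Logical matrix, same shape, at least one foreground pixel,
#'   touching all four sides of its bounding box.
#' @param offset (row, col) of the ROI within the source image, 0-based.
#' @param label Class label or NA.
#' @return A list of class \code{lesion_sample}.
#' @export
lesion_sample <- function(roi, mask, offset = c(0L, 0L),
                          label = NA_character_) {
  roi <- as.matrix(roi); mask <- matrix(as.logical(mask), nrow = nrow(roi))
  if (!identical(dim(roi), dim(mask))) stop("roi and mask shapes differ")
  if (!any(mask)) stop("mask has no foreground pixels")
  structure(list(roi = roi, mask = mask, offset = as.integer(offset),
                 label = as.character(label)),
            class = "lesion_sample")
}

#' Crop the tight lesion ROI from an image and mask
#'
#' Crops image and mask to the bounding box of the mask foreground. Pixels
#' outside the mask but inside the box are retained in the ROI; individual
#' feature models decide whether to use them.
#'
#' @param image Grayscale matrix.
#' @param mask Logical matrix, same shape.
#' @param label Optional class label carried on the sample.
#' @return A \code{\link{lesion_sample}} with 0-based \code{offset}.
#' @export
crop_roi <- function(image, mask, label = NA_character_) {
  image <- as.matrix(image)
  mask <- matrix(as.logical(mask), nrow = nrow(image))
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  if (!any(mask)) stop("empty mask")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  lesion_sample(image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
                mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
                offset = c(rr[1] - 1L, cc[1] - 1L),
                label = label)
}
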