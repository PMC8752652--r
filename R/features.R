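#' Extract the full 125-feature vector for one lesion
#'
#' Runs the seven texture models on the rectangular ROI and the three
#' geometry models on the binary mask, returning the fixed catalog order
#' F1-F125.
#'
#' @param sample A \code{\link{lesion_sample}}.
#' @param config An \code{\link{analysis_config}} with extraction tunables.
#' @return Named numeric vector of length 125.
#' @export
extract_features <- function(sample, config = analysis_config()) {
  stopifnot(inherits(sample, "lesion_sample"))
  vals <- c(compute_texture_features(sample, config),
            compute_geometry_features(sample))
  names(vals) <- catalog_columns()
  vals
}

#' Extract a feature table from a dataset or manifest
#'
#' Accepts either a \code{synthetic_dataset} from
#' \code{\link{generate_dataset}} or the path to a manifest CSV whose rows
#' reference image and annotation files. Each lesion contributes one row
#' of the 125 catalog features. Any per-sample failure aborts the run with
#' the offending sample id (no silent drops).
#'
#' @param x A \code{synthetic_dataset} or manifest path.
#' @param config An \code{\link{analysis_config}}.
#' @return A \code{\link{feature_table}}.
#' @export
extract_feature_table <- function(x, config = analysis_config()) {
  samples <- if (inherits(x, "synthetic_dataset")) {
    lapply(x$samples, function(s) {
      list(sample_id = s$sample_id,
           sample = crop_roi(s$image, s$mask, s$label))
    })
  } else {
    manifest <- read_manifest(x)
    base <- attr(manifest, "base_dir")
    lapply(seq_len(nrow(manifest)), function(i) {
      row <- manifest[i, ]
      img_path <- file.path(base, row$image)
      ann_path <- file.path(base, row$annotation)
      if (!file.exists(img_path)) {
        stop("sample '", row$sample_id, "': missing image file ", img_path)
      }
      if (!file.exists(ann_path)) {
        stop("sample '", row$sample_id, "': missing annotation file ",
             ann_path)
      }
      img <- read_gray_png(img_path)
      ann <- read_annotation(ann_path, sample_id = row$sample_id,
                             label = row$label)
      mask <- contour_to_mask(ann$boundary, dim(img))
      list(sample_id = row$sample_id,
           sample = crop_roi(img, mask, row$label))
    })
  }
  if (!length(samples)) {
    empty <- matrix(numeric(0), nrow = 0, ncol = 125,
                    dimnames = list(NULL, catalog_columns()))
    return(feature_table(empty, character(0), character(0)))
  }
  rows <- lapply(samples, function(s) {
    tryCatch(extract_features(s$sample, config),
             error = function(e) {
               stop("feature extraction failed for sample '", s$sample_id,
                    "': ", conditionMessage(e), call. = FALSE)
             })
  })
  feature_table(do.call(rbind, rows),
                labels = vapply(samples, function(s) s$sample$label,
                                character(1)),
                sample_ids = vapply(samples, function(s) s$sample_id,
                                    character(1)))
}
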