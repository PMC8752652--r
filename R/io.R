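#' Read a lesion boundary annotation
#'
#' Annotation files carry one \code{"x,y"} pixel coordinate per line, with
#' the final point equal to the first (closed polygon). Optional leading
#' comment lines of the form \code{# sample_id: s001} and
#' \code{# label: benign} carry metadata so a record round-trips through a
#' single file.
#'
#' @param path Path to the annotation file.
#' @param sample_id,label Overrides for metadata absent from the file.
#' @return An \code{annotation_record}: list with \code{sample_id},
#'   \code{boundary} (n x 2 matrix of x, y coordinates, not repeating the
#'   closing point) and \code{label}.
#' @export
read_annotation <- function(path, sample_id = NULL, label = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  coord_lines <- character()
  coord_lineno <- integer()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*(\\w+)\\s*:\\s*(.+)$", ln))[[1]]
      if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
    } else {
      coord_lines <- c(coord_lines, ln)
      coord_lineno <- c(coord_lineno, i)
    }
  }
  pts <- matrix(NA_real_, nrow = length(coord_lines), ncol = 2)
  for (i in seq_along(coord_lines)) {
    parts <- strsplit(coord_lines[[i]], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(trimws(parts)))
    if (length(vals) != 2 || anyNA(vals)) {
      stop("malformed annotation line ", coord_lineno[[i]], " in ", path,
           ": '", coord_lines[[i]], "'")
    }
    pts[i, ] <- vals
  }
  # drop explicit closing point
  n <- nrow(pts)
  if (n >= 2 && all(pts[n, ] == pts[1, ])) pts <- pts[-n, , drop = FALSE]
  annotation_record(
    sample_id = sample_id %||% meta$sample_id %||%
      sub("\\.[^.]*$", "", basename(path)),
    boundary = pts,
    label = label %||% meta$label %||% NA_character_
  )
}

#' Construct and validate an annotation record
#'
#' @param sample_id Character identifier.
#' @param boundary n x 2 matrix of (x, y) pixel coordinates, open polygon.
#' @param label \code{"benign"}, \code{"malignant"} or \code{NA}.
#' @return An \code{annotation_record} list.
#' @export
annotation_record <- function(sample_id, boundary, label = NA_character_) {
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3) {
    stop("annotation must have at least 3 boundary points, got ",
         nrow(boundary))
  }
  if (!is.na(label) && !label %in% c("benign", "malignant")) {
    stop("label must be 'benign', 'malignant' or NA, got '", label, "'")
  }
  structure(list(sample_id = as.character(sample_id),
                 boundary = unname(boundary),
                 label = as.character(label)),
            class = "annotation_record")
}

#' @rdname read_annotation
#' @param record An \code{annotation_record}.
#' @export
write_annotation <- function(record, path) {
  stopifnot(inherits(record, "annotation_record"))
  b <- record$boundary
  lines <- c(
    paste0("# sample_id: ", record$sample_id),
    if (!is.na(record$label)) paste0("# label: ", record$label),
    sprintf("%s,%s", format(b[, 1], trim = TRUE, scientific = FALSE),
            format(b[, 2], trim = TRUE, scientific = FALSE)),
    sprintf("%s,%s", format(b[1, 1], trim = TRUE, scientific = FALSE),
            format(b[1, 2], trim = TRUE, scientific = FALSE))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct a feature table
#'
#' A feature table is a data frame with \code{sample_id}, \code{label} and
#' the 125 catalog feature columns in fixed order.
#'
#' @param values Numeric matrix (samples x 125) with catalog column names,
#'   or already-named data frame of feature values.
#' @param labels Character vector of class labels per row.
#' @param sample_ids Optional identifiers (default \code{s1, s2, ...}).
#' @return A data frame of class \code{feature_table}.
#' @export
feature_table <- function(values, labels, sample_ids = NULL) {
  values <- as.matrix(values)
  cols <- catalog_columns()
  if (ncol(values) != length(cols)) {
    stop("feature table must have ", length(cols), " feature columns, got ",
         ncol(values))
  }
  if (!is.null(colnames(values)) && !identical(colnames(values), cols)) {
    stop("feature columns do not match the catalog header")
  }
  colnames(values) <- cols
  n <- nrow(values)
  if (length(labels) != n) stop("labels length must equal row count")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(n))
  out <- data.frame(sample_id = as.character(sample_ids),
                    label = as.character(labels),
                    values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Extract the numeric feature matrix from a feature table
#' @param table A \code{feature_table}.
#' @return Numeric matrix, rows named by sample id.
#' @export
feature_matrix <- function(table) {
  m <- as.matrix(table[, catalog_columns(), drop = FALSE])
  rownames(m) <- table$sample_id
  storage.mode(m) <- "double"
  m
}

#' Read / write a feature table as CSV
#'
#' The header must carry the full 125-column catalog; anything else is a
#' schema error.
#'
#' @param path CSV path.
#' @return \code{read_feature_table}: a \code{feature_table}.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- catalog_columns()
  expected <- c("sample_id", "label", cols)
  if (!identical(names(df), expected)) {
    stop("feature table schema mismatch: expected ", length(expected),
         " catalog columns, got ", ncol(df))
  }
  feature_table(as.matrix(df[, cols, drop = FALSE]), df$label, df$sample_id)
}

#' @rdname read_feature_table
#' @param table A \code{feature_table}.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a feature ranking as CSV
#'
#' Columns: rank, feature index, feature name, score, method — mirroring a
#' rank-wise selection listing.
#'
#' @param ranking A \code{feature_ranking} (see \code{\link{rank_features}}).
#' @param path CSV path.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "feature_ranking"))
  cat125 <- feature_catalog()
  df <- data.frame(rank = seq_along(ranking$order),
                   index = ranking$order,
                   feature = cat125$feature[ranking$order],
                   name = cat125$name[ranking$order],
                   score = ranking$scores[ranking$order],
                   method = ranking$method)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rank", "index", "feature", "name", "score", "method")
  if (!all(need %in% names(df))) stop("ranking file missing columns")
  scores <- numeric(max(df$index))
  scores[df$index] <- df$score
  structure(list(method = df$method[[1]], order = df$index, scores = scores),
            class = "feature_ranking")
}

#' Write an 8-bit grayscale image as PNG
#' @param img Numeric matrix with values in [0, 255].
#' @param path Output path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(round(img), 0), 255) / 255, target = path)
  invisible(path)
}

#' @rdname write_gray_png
#' @return \code{read_gray_png}: numeric matrix with values in 0..255.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  round(a * 255)
}

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with columns \code{sample_id}, \code{image},
#' \code{annotation}, \code{label}; paths are interpreted relative to the
#' manifest's directory.
#'
#' @param path Manifest path.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "image", "annotation", "label")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  attr(df, "base_dir") <- dirname(normalizePath(path))
  df
}

#' Write a synthetic dataset to disk (images, annotations, manifest)
#'
#' @param dataset A \code{synthetic_dataset} from
#'   \code{\link{generate_dataset}}.
#' @param dir Output directory (created if absent).
#' @return Path to the written manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    img_file <- sprintf("%s.png", s$sample_id)
    ann_file <- sprintf("%s.txt", s$sample_id)
    write_gray_png(s$image, file.path(dir, img_file))
    write_annotation(
      annotation_record(s$sample_id, s$boundary, s$label),
      file.path(dir, ann_file))
    data.frame(sample_id = s$sample_id, image = img_file,
               annotation = ann_file, label = s$label)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), image = character(0),
               annotation = character(0), label = character(0))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Default analysis configuration
#'
#' Collects every tunable of the pipeline in one list: generator presets,
#' gray-level quantization, selection settings, k-NN settings and
#' cross-validation layout. Values can be overridden via \code{...} or read
#' from a YAML file with \code{\link{read_config}}.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class \code{run_config}.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    n_benign = 52L,
    n_malignant = 63L,
    master_seed = 7L,
    presets = NULL,          # NULL -> default_presets()
    glcm_levels = 32L,
    selection_method = "relief_f",
    top_k = 20L,
    relief_k = 10L,
    nca_lambda = NULL,       # NULL -> 1/n
    nca_rate = 0.1,
    nca_iterations = 200L,
    standardize = TRUE,
    knn_preset = "weighted_cosine",
    folds = 10L,
    repeats = 10L,
    cv_seed = 11L,
    search_max_size = 9L,
    output_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (cfg$folds < 2) stop("folds must be >= 2")
  if (cfg$repeats < 1) stop("repeats must be >= 1")
  if (!cfg$selection_method %in%
      c("relief_f", "pearson", "nca", "term_variance")) {
    stop("unknown selection method: ", cfg$selection_method)
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname analysis_config
#' @param path YAML config file.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}
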