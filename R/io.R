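# Dataset ingestion and run configuration. Datasets are folder-per-class
# trees (the layout of the public sperm-head benchmarks); run configs are
# YAML (JSON accepted) and are copied into every run's output directory.

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = if (requireNamespace("jpeg", quietly = TRUE))
      jpeg::readJPEG(path) else NULL,
    tif = , tiff = if (requireNamespace("EBImage", quietly = TRUE)) {
      a <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(a)) >= 2) aperm(a, c(2, 1, seq_along(dim(a))[-(1:2)]))
      else a
    } else NULL,
    NULL)
  if (is.null(img)) return(NULL)
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3]
  } else if (length(dim(img)) == 3) {
    img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))
  } else {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  img
}

#' Read a folder-per-class image dataset
#'
#' Classes are the sub-directory names, sorted lexicographically, so label
#' ids are stable across platforms. Supported extensions: PNG and JPEG
#' (TIFF when EBImage is installed). Unreadable files are skipped with a
#' warning and counted.
#'
#' @param path dataset root with one sub-directory per class (>= 2).
#' @return a `labeled_image_set` with an extra attribute `skipped`.
#' @export
read_image_folder <- function(path) {
  if (!dir.exists(path)) stop("dataset path does not exist: ", path,
                              call. = FALSE)
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) < 2) {
    stop(sprintf("need at least 2 class sub-directories, found %d",
                 length(classes)), call. = FALSE)
  }
  exts <- "\\.(png|jpg|jpeg|tif|tiff|bmp)$"
  images <- list(); labels <- integer(0); skipped <- 0L
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(path, classes[ci]),
                             pattern = exts, ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("class directory is empty: ", classes[ci],
                             call. = FALSE)
    for (f in files) {
      img <- tryCatch(read_one_image(f), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable image: ", f)
        skipped <- skipped + 1L
        next
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, ci)
    }
  }
  structure(list(images = images, labels = labels, class_names = classes),
            class = "labeled_image_set", skipped = skipped)
}

#' Load / save a run configuration
#'
#' A run config bundles the synthetic spec or dataset path, preprocessing,
#' backbone, training, grid preset, CV folds, seed and output directory.
#' YAML and JSON files are both accepted.
#'
#' @param path config file path.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg a run configuration list.
#' @export
write_run_config <- function(cfg, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

#' Hash of a configuration for artifact provenance
#'
#' @param cfg any serializable list.
#' @return short hex digest string.
#' @export
config_hash <- function(cfg) {
  raw <- as.integer(serialize(unclass(cfg), NULL, version = 2))
  # polynomial rolling hash; provenance tag, not cryptographic
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
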