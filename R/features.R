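# Deep feature extraction from a frozen trained network. Four extraction
# sites: the flattened final CBAM-refined map ("cbam"), global average and
# global max pooling of that map ("gap", "gmp"), their concatenation
# ("combined"), the post-batch-norm descriptor just before the classifier
# ("prefinal"), and the pooled pre-CBAM final-stage output ("backbone").

FEATURE_TAGS <- c("cbam", "gap", "gmp", "combined", "prefinal", "backbone")

new_feature_matrix <- function(data, layer_tag, sample_ids, class_names) {
  structure(data, layer_tag = layer_tag, sample_ids = sample_ids,
            class_names = class_names, class = c("feature_matrix", "matrix"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d samples x %d features\n",
              attr(x, "layer_tag"), nrow(x), ncol(x)))
  invisible(x)
}

# flatten one H x W x C map channel-major (w fastest, then h, then c)
flatten_cmajor <- function(map3) {
  as.vector(aperm(map3, c(2, 1, 3)))
}

#' Extract deep features from a trained network
#'
#' Runs the network in inference mode (deterministic: dropout off,
#' batch-norm on running statistics) and returns the requested
#' representation as an N x D matrix. `cbam` flattens the final refined
#' map channel-major; `gap`/`gmp` are its spatial mean/max per channel;
#' `combined` concatenates gap then gmp columns; `prefinal` is the
#' combined descriptor after the head's inference-mode batch-norm;
#' `backbone` is the pooled (gap) pre-CBAM final-stage output.
#'
#' @param net a trained `cbam_resnet`.
#' @param images list of preprocessed images or a `labeled_image_set`.
#' @param layer_tag one of `"cbam"`, `"gap"`, `"gmp"`, `"combined"`,
#'   `"prefinal"`, `"backbone"`.
#' @param batch_size forward batch size.
#' @return a `feature_matrix` (N x D) tagged with the layer.
#' @export
extract_features <- function(net, images, layer_tag = "gap",
                             batch_size = 16) {
  if (!(layer_tag %in% FEATURE_TAGS)) {
    stop(sprintf("unknown layer tag '%s'; valid tags: %s", layer_tag,
                 paste(FEATURE_TAGS, collapse = ", ")), call. = FALSE)
  }
  if (inherits(images, "labeled_image_set")) images <- images$images
  n <- length(images)
  dims <- feature_dims(net$cfg)
  D <- unname(dims[[if (layer_tag %in% c("combined", "prefinal"))
                      layer_tag else layer_tag]])
  out <- matrix(0, n, D)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    X <- images_to_tensor(images[b], net$cfg$input_size)
    fw <- forward_net(net, X, training = FALSE)
    f <- fw$features
    rows <- switch(layer_tag,
      gap = f$gap,
      gmp = f$gmp,
      combined = f$combined,
      prefinal = f$prefinal,
      backbone = nn_gap_forward(f$backbone_map)$out,
      cbam = {
        d <- dim(f$final_map)
        t(vapply(seq_along(b), function(i)
          flatten_cmajor(array(f$final_map[, , , i], d[1:3])),
          numeric(d[1] * d[2] * d[3])))
      })
    out[b, ] <- rows
  }
  new_feature_matrix(out, layer_tag, sample_ids = seq_len(n),
                     class_names = net$class_names)
}

#' Concatenate GAP and GMP feature matrices
#'
#' Column-wise concatenation with gap columns first; both inputs must hold
#' the same samples in the same order.
#'
#' @param Fgap,Fgmp `feature_matrix` objects with matching rows.
#' @return a `feature_matrix` tagged `combined`.
#' @export
combine_gap_gmp <- function(Fgap, Fgmp) {
  if (nrow(Fgap) != nrow(Fgmp)) {
    stop(sprintf("row mismatch: gap has %d rows, gmp has %d",
                 nrow(Fgap), nrow(Fgmp)), call. = FALSE)
  }
  if (!identical(attr(Fgap, "sample_ids"), attr(Fgmp, "sample_ids"))) {
    stop("sample_ids of gap and gmp matrices differ", call. = FALSE)
  }
  new_feature_matrix(cbind(unclass(Fgap), unclass(Fgmp)), "combined",
                     attr(Fgap, "sample_ids"), attr(Fgap, "class_names"))
}

#' Write / read a feature store
#'
#' A feature store is a serialized matrix plus a JSON sidecar recording
#' the layer tag, shape and class names.
#'
#' @param fm a `feature_matrix`.
#' @param path file path (`.rds`; sidecar `.json`).
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_store <- function(fm, path) {
  saveRDS(unclass(fm), path)
  jsonlite::write_json(list(layer_tag = attr(fm, "layer_tag"),
                            shape = dim(fm),
                            class_names = attr(fm, "class_names")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- readRDS(path)
  new_feature_matrix(m, side$layer_tag, seq_len(nrow(m)), side$class_names)
}
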