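#' Aligned multimodal dataset
#'
#' Container for an aligned set of per-modality feature matrices, a categorical
#' label vector, and an optional train/test split assignment. All matrices
#' must share the same number of rows, in the same sample order.
#'
#' @param modalities Named list of numeric matrices (samples x features). List
#'   names are the modality names.
#' @param labels Factor (or vector coercible to factor) of class labels, one
#'   per sample.
#' @param split Optional character/factor vector with values `"train"` /
#'   `"test"` per sample.
#' @param meta Optional list of generator or provenance metadata.
#' @return An object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(modalities, labels, split = NULL, meta = list()) {
  if (!is.list(modalities) || length(modalities) == 0L ||
      is.null(names(modalities)) || any(names(modalities) == "")) {
    stop("modalities must be a non-empty named list of matrices", call. = FALSE)
  }
  modalities <- lapply(modalities, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n <- unique(vapply(modalities, nrow, integer(1)))
  if (length(n) != 1L) stop("all modalities must have the same row count", call. = FALSE)
  if (any(vapply(modalities, function(m) any(!is.finite(m)), logical(1)))) {
    stop("modality features must be finite", call. = FALSE)
  }
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels length must equal the row count", call. = FALSE)
  if (!is.null(split)) {
    split <- as.character(split)
    if (length(split) != n || !all(split %in% c("train", "test"))) {
      stop("split must be 'train'/'test' per sample", call. = FALSE)
    }
  }
  structure(list(modalities = modalities, labels = labels, split = split,
                 meta = meta),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  dims <- vapply(x$modalities, ncol, integer(1))
  cat("<multimodal_dataset> n =", length(x$labels),
      "| classes =", nlevels(x$labels), "\n")
  cat("  modalities:",
      paste(sprintf("%s (d=%d)", names(dims), dims), collapse = ", "), "\n")
  if (!is.null(x$split)) {
    cat("  split: train =", sum(x$split == "train"),
        ", test =", sum(x$split == "test"), "\n")
  }
  invisible(x)
}

#' Number of samples in a multimodal dataset
#' @param data A [multimodal_dataset()].
#' @return Integer sample count.
#' @export
n_samples <- function(data) length(data$labels)

#' Subset a multimodal dataset by sample index
#' @param data A [multimodal_dataset()].
#' @param idx Integer or logical row index.
#' @return A [multimodal_dataset()] restricted to `idx`.
#' @export
subset_samples <- function(data, idx) {
  multimodal_dataset(lapply(data$modalities, function(m) m[idx, , drop = FALSE]),
                     droplevels(data$labels[idx]),
                     split = if (!is.null(data$split)) data$split[idx],
                     meta = data$meta)
}

split_indices <- function(data, which = c("train", "test")) {
  which <- match.arg(which)
  if (is.null(data$split)) seq_along(data$labels) else which(data$split == which)
}

#' Concatenate a subset of modalities into one feature matrix
#'
#' Unobserved modalities can be zero-masked rather than removed, so the result
#' keeps the column layout expected by models trained on all modalities.
#'
#' @param data A [multimodal_dataset()].
#' @param subset Character vector of modality names to keep (default all).
#' @param mask_missing If `TRUE`, modalities outside `subset` are included as
#'   all-zero blocks; if `FALSE` they are dropped.
#' @return Numeric matrix.
#' @export
concat_modalities <- function(data, subset = names(data$modalities),
                              mask_missing = FALSE) {
  unknown <- setdiff(subset, names(data$modalities))
  if (length(unknown) > 0L) {
    stop("unknown modality: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (mask_missing) {
    blocks <- lapply(names(data$modalities), function(nm) {
      m <- data$modalities[[nm]]
      if (nm %in% subset) m else m * 0
    })
  } else {
    blocks <- data$modalities[subset]
  }
  do.call(cbind, blocks)
}
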