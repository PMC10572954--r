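#' Labeled RGB image record
#'
#' The atomic unit flowing through the dataset pipeline: one RGB image with
#' its class label and a provenance tag recording how it entered the dataset
#' (`"original"`, `"flipped_copy"` for oversampled mirror copies, or
#' `"augmented"`).
#'
#' @param id Unique character identifier.
#' @param pixels H x W x 3 integer array with values in [0, 255].
#' @param label Integer class index in `[0, K)`.
#' @param provenance One of `"original"`, `"flipped_copy"`, `"augmented"`.
#' @param source_id For derived records, the id of the record they were
#'   derived from; `NA` for originals.
#'
#' @return An object of class `image_record`.
#' @export
image_record <- function(id, pixels, label,
                         provenance = c("original", "flipped_copy", "augmented"),
                         source_id = NA_character_) {
  provenance <- match.arg(provenance)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L ||
      any(dim(pixels)[1:2] < 1L)) {
    stop("`pixels` must be a non-empty H x W x 3 array", call. = FALSE)
  }
  if (any(pixels < 0 | pixels > 255)) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  label <- as.integer(label)
  if (is.na(label) || label < 0L) stop("`label` must be a non-negative class index", call. = FALSE)
  structure(
    list(id = id, pixels = pixels, label = label,
         provenance = provenance, source_id = source_id),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_record %s: %dx%dx%d, label %d, %s>\n",
              x$id, d[1], d[2], d[3], x$label, x$provenance))
  invisible(x)
}

#' Extract labels from a list of image records
#' @param records List of [image_record()] objects.
#' @return Integer vector of class indices.
#' @export
record_labels <- function(records) {
  vapply(records, function(r) r$label, integer(1))
}

#' Per-class record counts
#' @param records List of [image_record()] objects.
#' @param n_classes Number of classes `K`; counts are reported for classes
#'   `0..K-1` even when a class is absent.
#' @return Named integer vector of length `n_classes`.
#' @export
class_counts <- function(records, n_classes = max(record_labels(records)) + 1L) {
  labs <- record_labels(records)
  counts <- tabulate(labs + 1L, nbins = n_classes)
  names(counts) <- as.character(seq_len(n_classes) - 1L)
  counts
}

#' Mirror an image horizontally
#'
#' Reverses the column order of an H x W x 3 pixel array; bit-exact and an
#' involution (flipping twice restores the original).
#'
#' @param pixels H x W x 3 array.
#' @return Array of the same shape.
#' @export
flip_horizontal <- function(pixels) {
  pixels[, dim(pixels)[2]:1, , drop = FALSE]
}

#' Mirror an image vertically
#' @param pixels H x W x 3 array.
#' @return Array of the same shape.
#' @export
flip_vertical <- function(pixels) {
  pixels[dim(pixels)[1]:1, , , drop = FALSE]
}
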