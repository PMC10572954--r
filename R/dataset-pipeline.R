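#' Read a directory-per-class image dataset
#'
#' Reads PNG/JPEG images from `<root>/<class_name>/*.{png,jpg,jpeg}`. Class
#' indices are assigned either from `class_order` (a character vector of
#' folder names in class order) or alphabetically.
#'
#' @param root Dataset root directory.
#' @param class_order Optional character vector fixing the class-index order;
#'   for the osteosarcoma layout this is
#'   `c("Non-Tumor", "Necrotic-Tumor", "Viable-Tumor")`.
#' @return List of [image_record()] objects with provenance `"original"`.
#' @export
read_image_dataset <- function(root, class_order = NULL) {
  if (!dir.exists(root)) stop("data root does not exist: ", root, call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (length(dirs) == 0) stop("no class folders under ", root, call. = FALSE)
  if (is.null(class_order)) class_order <- sort(dirs)
  if (!all(class_order %in% dirs)) {
    stop("class folders missing: ",
         paste(setdiff(class_order, dirs), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (k in seq_along(class_order)) {
    files <- list.files(file.path(root, class_order[k]),
                        pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    for (f in sort(files)) {
      px <- png::readPNG(f)
      if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
      if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
      if (dim(px)[3] == 1L) px <- px[, , c(1, 1, 1), drop = FALSE]
      px <- array(as.integer(round(px * 255)), dim = dim(px))
      out[[length(out) + 1L]] <- image_record(
        id = tools::file_path_sans_ext(basename(f)),
        pixels = px, label = k - 1L
      )
    }
  }
  out
}

#' Split a dataset into training and test sets
#'
#' Uniform random split with `floor(train_frac * n)` records in the training
#' set. The default is a global (non-stratified) shuffle; with
#' `stratified = TRUE` the floor rule is applied within each class. On the
#' 1144-image osteosarcoma composition the 80/20 global rule yields 915
#' training and 229 test images.
#'
#' @param records Non-empty list of [image_record()] objects.
#' @param train_frac Training fraction in `(0, 1]`.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratified Apply the floor rule per class instead of globally.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(records, train_frac = 0.8, seed = 1L,
                          stratified = FALSE) {
  if (length(records) == 0) stop("`records` must be non-empty", call. = FALSE)
  if (train_frac <= 0 || train_frac > 1) {
    stop("`train_frac` must lie in (0, 1]", call. = FALSE)
  }
  with_local_seed(seed, {
    if (stratified) {
      labs <- record_labels(records)
      tr_idx <- integer(0)
      for (k in sort(unique(labs))) {
        ki <- which(labs == k)
        tr_idx <- c(tr_idx, ki[sample.int(length(ki),
                                          floor(train_frac * length(ki)))])
      }
    } else {
      n_train <- floor(train_frac * length(records))
      tr_idx <- sample(seq_along(records), n_train)
    }
    list(train = records[sort(tr_idx)],
         test = records[setdiff(seq_along(records), tr_idx)])
  })
}

#' Carve a validation set out of a training set
#'
#' Removes `floor(val_frac * n)` uniformly sampled records from the training
#' set to serve as a validation set.
#'
#' @param train List of [image_record()] objects.
#' @param val_frac Validation fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with elements `train` and `validation`.
#' @export
carve_validation <- function(train, val_frac = 0.1, seed = 1L) {
  if (val_frac < 0 || val_frac >= 1) {
    stop("`val_frac` must lie in [0, 1)", call. = FALSE)
  }
  with_local_seed(seed, {
    n_val <- floor(val_frac * length(train))
    val_idx <- if (n_val > 0) sample(seq_along(train), n_val) else integer(0)
    list(train = train[setdiff(seq_along(train), val_idx)],
         validation = train[sort(val_idx)])
  })
}

#' Oversample minority classes to the majority count by horizontal flipping
#'
#' Every class is brought up to the pre-balance maximum class count by adding
#' horizontally mirrored copies of a without-replacement random subset of
#' that class's images, sized to the deficit. Added records carry provenance
#' `"flipped_copy"` and reference their source; originals are untouched.
#' On the osteosarcoma training composition \{422, 208, 285\} this yields
#' 422 images per class (214 + 137 flipped copies added); note that case
#' needs `allow_duplicates = TRUE`, since 214 copies cannot all come from
#' distinct images in a 208-image class.
#'
#' @param train List of [image_record()] objects; every class of the dataset
#'   must be present.
#' @param seed Integer seed for the source-image sampling.
#' @param allow_duplicates If a class's deficit exceeds its size, flipping
#'   distinct images cannot supply enough copies and an error is raised
#'   unless this flag is set. When set, sources are drawn in whole passes
#'   over the class plus a without-replacement remainder, so duplication is
#'   the minimum the deficit forces (none when the deficit fits the class).
#' @return List of records, originals first, balanced per class.
#' @export
balance_by_flip <- function(train, seed = 1L, allow_duplicates = FALSE) {
  labs <- record_labels(train)
  counts <- table(labs)
  max_count <- max(counts)
  with_local_seed(seed, {
    added <- list()
    for (k in as.integer(names(counts))) {
      deficit <- max_count - counts[[as.character(k)]]
      if (deficit == 0) next
      ki <- which(labs == k)
      if (deficit > length(ki) && !allow_duplicates) {
        stop(sprintf(
          "class %d deficit (%d) exceeds its %d source images; flipping cannot supply enough distinct copies (set allow_duplicates = TRUE to sample with replacement)",
          k, deficit, length(ki)), call. = FALSE)
      }
      # whole passes over the class (each image flipped once per pass), then
      # a without-replacement remainder — minimal duplication when the
      # deficit exceeds the class size, none otherwise
      n_k <- length(ki)
      src <- c(rep(ki, deficit %/% n_k),
               ki[sample.int(n_k, deficit %% n_k)])
      copy_n <- 0L
      for (i in src) {
        copy_n <- copy_n + 1L
        r <- train[[i]]
        added[[length(added) + 1L]] <- image_record(
          id = sprintf("%s_flip%d", r$id, copy_n),
          pixels = flip_horizontal(r$pixels),
          label = r$label, provenance = "flipped_copy", source_id = r$id
        )
      }
    }
    c(train, added)
  })
}

#' Preprocess an image for the network
#'
#' Bilinear resize to the target spatial size followed by scaling of the
#' pixel intensities into `[0, 1]` (division by 255).
#'
#' @param record An [image_record()] (or a bare H x W x 3 pixel array).
#' @param target_size `(height, width)`; default `c(224, 224)`, the input
#'   size of the proposed network.
#' @return Numeric H x W x 3 array with values in `[0, 1]`.
#' @export
preprocess_image <- function(record, target_size = c(224, 224)) {
  pixels <- if (inherits(record, "image_record")) record$pixels else record
  target_size <- as.integer(target_size)
  if (length(target_size) != 2L || any(target_size < 1L)) {
    stop("`target_size` must be two positive integers", call. = FALSE)
  }
  d <- dim(pixels)
  if (!all(d[1:2] == target_size)) {
    # EBImage stores images as (x = width, y = height, channel)
    img <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)), colormode = "Color")
    img <- EBImage::resize(img, w = target_size[2], h = target_size[1])
    out <- aperm(as.array(img), c(2, 1, 3))
  } else {
    out <- pixels / 255
  }
  pmin(pmax(out, 0), 1)
}

#' Augmentation configuration
#'
#' The training-time augmentation stack: vertical flip, small random
#' rotation with reflect padding, and multiplicative brightness jitter,
#' applied in that order.
#'
#' @param vertical_flip_prob Probability of a vertical flip.
#' @param rotation_range_deg Rotation drawn uniformly in plus/minus this many
#'   degrees.
#' @param brightness_delta Brightness factor drawn uniformly in
#'   `[1 - delta, 1 + delta]`; `delta` in `[0, 1]`.
#' @param seed Integer seed used when a whole-dataset augmentation pass is
#'   seeded externally.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(vertical_flip_prob = 0.5, rotation_range_deg = 20,
                           brightness_delta = 0.2, seed = 1L) {
  stopifnot(vertical_flip_prob >= 0, vertical_flip_prob <= 1,
            rotation_range_deg >= 0,
            brightness_delta >= 0, brightness_delta <= 1)
  structure(
    list(vertical_flip_prob = vertical_flip_prob,
         rotation_range_deg = rotation_range_deg,
         brightness_delta = brightness_delta, seed = as.integer(seed)),
    class = "augment_config"
  )
}

# Rotate an H x W x C numeric array by `deg` degrees about its centre using
# inverse-mapped bilinear interpolation with mirror (reflect) padding.
rotate_reflect <- function(x, deg) {
  if (deg == 0) return(x)
  d <- dim(x); h <- d[1]; w <- d[2]
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- matrix(seq_len(h), h, w) - cy
  gx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse rotation: where did each output pixel come from
  sy <- cy + gy * cos(th) - gx * sin(th)
  sx <- cx + gy * sin(th) + gx * cos(th)
  reflect <- function(v, n) {
    # mirror coordinates into [1, n] (period 2(n-1))
    if (n == 1) return(rep(1, length(v)))
    v <- abs(v - 1) %% (2 * (n - 1))
    ifelse(v > (n - 1), 2 * (n - 1) - v, v) + 1
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  iy0 <- reflect(y0, h); iy1 <- reflect(y0 + 1, h)
  ix0 <- reflect(x0, w); ix1 <- reflect(x0 + 1, w)
  out <- x
  for (ch in seq_len(d[3])) {
    plane <- x[, , ch]
    out[, , ch] <-
      plane[cbind(c(iy0), c(ix0))] * (1 - fy) * (1 - fx) +
      plane[cbind(c(iy1), c(ix0))] * fy * (1 - fx) +
      plane[cbind(c(iy0), c(ix1))] * (1 - fy) * fx +
      plane[cbind(c(iy1), c(ix1))] * fy * fx
  }
  out
}

# Core augmentation on a numeric pixel array in [0, max_val]; draws from the
# current RNG stream so epoch-wise generators see fresh transforms.
augment_pixels <- function(pixels, config, max_val = 255) {
  if (config$vertical_flip_prob > 0 &&
      stats::runif(1) < config$vertical_flip_prob) {
    pixels <- flip_vertical(pixels)
  }
  if (config$rotation_range_deg > 0) {
    ang <- stats::runif(1, -config$rotation_range_deg, config$rotation_range_deg)
    pixels <- rotate_reflect(pixels, ang)
  }
  if (config$brightness_delta > 0) {
    f <- stats::runif(1, 1 - config$brightness_delta, 1 + config$brightness_delta)
    pixels <- pixels * f
  }
  pmin(pmax(pixels, 0), max_val)
}

#' Randomly augment an image record
#'
#' Applies, in order: vertical flip with the configured probability, rotation
#' by a uniform angle in the configured range (bilinear, reflect padding at
#' the borders), and multiplicative brightness jitter with clipping to
#' `[0, 255]`. Draws come from the current RNG stream, so the result is
#' deterministic given the RNG state — seed once per epoch to emulate
#' generator-style augmentation that shows the model novel variants of each
#' image every epoch.
#'
#' @param record An [image_record()].
#' @param config An [augment_config()].
#' @return A new [image_record()] with provenance `"augmented"`.
#' @export
augment_record <- function(record, config) {
  px <- augment_pixels(record$pixels, config, max_val = 255)
  image_record(
    id = paste0(record$id, "_aug"),
    pixels = array(as.integer(round(px)), dim = dim(px)),
    label = record$label, provenance = "augmented", source_id = record$id
  )
}

#' Write a split manifest CSV
#'
#' One row per record with columns id, class_index, subset, provenance,
#' source_id — the on-disk record of a split/balance run.
#'
#' @param splits Named list of record lists (e.g. train/validation/test).
#' @param path Output CSV path.
#' @return Invisibly, the manifest data frame.
#' @export
write_split_manifest <- function(splits, path) {
  rows <- lapply(names(splits), function(s) {
    if (length(splits[[s]]) == 0) return(NULL)
    do.call(rbind, lapply(splits[[s]], function(r) {
      data.frame(id = r$id, class_index = r$label, subset = s,
                 provenance = r$provenance,
                 source_id = ifelse(is.na(r$source_id), "", r$source_id),
                 stringsAsFactors = FALSE)
    }))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}
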