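#' Class specification for the synthetic image generator
#'
#' Describes one tissue class of the generative model: a base RGB colour,
#' a density of elliptical "cell cluster" blobs, and additive Gaussian pixel
#' noise. The defaults emulate the three osteosarcoma H&E categories
#' (Non-Tumor, Necrotic-Tumor, Viable-Tumor) as colour-separable classes.
#'
#' @param label_index Integer class index in `[0, K)`.
#' @param label_name Class name used for output folders.
#' @param base_color RGB triple in `[0, 255]`.
#' @param blob_density Expected blob count per 10^4 pixels (>= 0).
#' @param noise_sd Pixel-intensity standard deviation (>= 0).
#'
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label_index, label_name, base_color,
                       blob_density = 8, noise_sd = 12) {
  stopifnot(length(base_color) == 3L, all(base_color >= 0), all(base_color <= 255),
            blob_density >= 0, noise_sd >= 0, label_index >= 0)
  structure(
    list(label_index = as.integer(label_index), label_name = label_name,
         base_color = as.numeric(base_color), blob_density = blob_density,
         noise_sd = noise_sd),
    class = "class_spec"
  )
}

#' Default three-class specifications
#'
#' Base colours are chosen to mimic the palette of H&E-stained bone tissue
#' (light pink stroma, brownish necrotic debris, dense purple viable tumor)
#' while keeping the class means separated by far more than the pixel noise,
#' so the classes are learnable by construction.
#'
#' @return List of three [class_spec()] objects in the fixed class order
#'   Non-Tumor = 0, Necrotic-Tumor = 1, Viable-Tumor = 2.
#' @export
default_class_specs <- function() {
  list(
    class_spec(0L, "Non-Tumor",      c(215, 175, 210)),
    class_spec(1L, "Necrotic-Tumor", c(140,  95,  70)),
    class_spec(2L, "Viable-Tumor",   c(150,  60, 140))
  )
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Draw one synthetic image for a class: base colour + random filled ellipses
# in shifted shades + Gaussian noise, clipped to [0, 255].
synth_one_image <- function(spec, height, width) {
  img <- array(rep(spec$base_color, each = height * width),
               dim = c(height, width, 3L))
  n_blobs <- stats::rpois(1L, spec$blob_density * height * width / 1e4)
  if (n_blobs > 0) {
    row_grid <- matrix(seq_len(height), height, width)
    col_grid <- matrix(seq_len(width), height, width, byrow = TRUE)
    min_dim <- min(height, width)
    for (b in seq_len(n_blobs)) {
      cy <- stats::runif(1, 1, height)
      cx <- stats::runif(1, 1, width)
      a  <- stats::runif(1, 0.04, 0.15) * min_dim
      bb <- stats::runif(1, 0.04, 0.15) * min_dim
      th <- stats::runif(1, 0, pi)
      shade <- spec$base_color + stats::runif(3, -45, 45)
      dy <- row_grid - cy
      dx <- col_grid - cx
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / bb
      mask <- u * u + v * v <= 1
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- shade[ch]
        img[, , ch] <- plane
      }
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  }
  array(as.integer(round(pmin(pmax(img, 0), 255))), dim = dim(img))
}

#' Generate a class-separable synthetic image dataset
#'
#' Draws RGB images from a class-conditional model (per-class base colour,
#' random elliptical blobs, Gaussian pixel noise clipped to `[0, 255]`) so
#' that every downstream stage — splitting, balancing, training, evaluation,
#' ensembling — can be exercised without the external histology dataset.
#' Output is bit-identical for identical arguments.
#'
#' @param counts Named or unnamed vector/list mapping class index to the
#'   number of images to generate (name `"0"` or position 1 is class 0).
#' @param image_size `(height, width)` in pixels.
#' @param class_specs List of [class_spec()]; defaults to
#'   [default_class_specs()].
#' @param seed Integer seed; the caller's RNG state is left untouched.
#'
#' @return List of [image_record()] objects, grouped by class in class order.
#' @export
#' @examples
#' recs <- generate_image_dataset(c(5, 5, 5), image_size = c(32, 32), seed = 7)
#' class_counts(recs)
generate_image_dataset <- function(counts, image_size = c(96, 96),
                                   class_specs = default_class_specs(),
                                   seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 1L)) {
    stop("`image_size` must be two positive integers (height, width)", call. = FALSE)
  }
  counts <- unlist(counts)
  idx <- if (is.null(names(counts))) seq_along(counts) - 1L else as.integer(names(counts))
  known <- vapply(class_specs, function(s) s$label_index, integer(1))
  if (!all(idx %in% known)) {
    stop("counts refer to unknown class index: ",
         paste(setdiff(idx, known), collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  with_local_seed(seed, {
    out <- list()
    for (k in seq_along(idx)) {
      spec <- class_specs[[which(known == idx[k])]]
      n <- counts[[k]]
      if (n == 0) next
      recs <- vector("list", n)
      for (i in seq_len(n)) {
        recs[[i]] <- image_record(
          id = sprintf("%s_%04d", spec$label_name, i),
          pixels = synth_one_image(spec, image_size[1], image_size[2]),
          label = spec$label_index
        )
      }
      out <- c(out, recs)
    }
    out
  })
}

#' Synthetic dataset matching the osteosarcoma collection's composition
#'
#' Generates a dataset whose per-class counts are `round(scale * c(536, 263,
#' 345))` — the Non-Tumor / Necrotic-Tumor / Viable-Tumor composition of the
#' public "Osteosarcoma Tumor Assessment" collection (UT Southwestern / UT
#' Dallas) — at a configurable scale, so imbalance-handling code can be
#' exercised on realistically skewed class ratios.
#'
#' @param scale Positive scale factor; scaled counts must round to >= 1 per
#'   class.
#' @param image_size,class_specs,seed Passed to [generate_image_dataset()].
#' @return List of [image_record()] objects.
#' @export
make_count_fixture <- function(scale = 1, image_size = c(96, 96),
                               class_specs = default_class_specs(), seed = 1L) {
  base_counts <- c(536L, 263L, 345L)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("`scale` must be a positive number", call. = FALSE)
  }
  counts <- floor(scale * base_counts + 0.5)   # round half up
  if (any(counts < 1)) stop("scaled counts must round to >= 1 per class", call. = FALSE)
  names(counts) <- c("0", "1", "2")
  generate_image_dataset(counts, image_size = image_size,
                         class_specs = class_specs, seed = seed)
}

#' Generate synthetic base-learner probability matrices
#'
#' Emulates the softmax outputs of a bank of trained classifiers with known
#' accuracies. For each learner and sample, the predicted label equals the
#' true label with probability equal to the learner's accuracy (a Bernoulli
#' draw per sample; wrong labels are uniform over the remaining classes), and
#' the probability row is a Dirichlet-style draw sharply peaked on the chosen
#' label. The argmax of each row is guaranteed to equal the chosen label.
#'
#' @param n_learners Number of learners (>= 1).
#' @param true_labels Integer vector of true class indices in `[0, K)`.
#' @param n_classes Number of classes `K >= 2`.
#' @param per_learner_accuracy Vector of length `n_learners`, each in [0, 1].
#' @param concentration Positive sharpness of the peaked Dirichlet draw
#'   (Dirichlet weight on the chosen class, against weight 1 elsewhere);
#'   the default 20 yields confident rows resembling trained softmax output.
#' @param seed Integer seed.
#' @param learner_ids Optional character ids; default `"L1".."Ln"`.
#'
#' @return Named list of [probability_matrix()] objects, one per learner;
#'   every row sums to 1 within 1e-9.
#' @export
generate_prediction_matrices <- function(n_learners, true_labels, n_classes,
                                         per_learner_accuracy,
                                         concentration = 20, seed = 1L,
                                         learner_ids = NULL) {
  stopifnot(n_learners >= 1, n_classes >= 2, concentration > 0)
  if (length(per_learner_accuracy) != n_learners) {
    stop("`per_learner_accuracy` must have length `n_learners`", call. = FALSE)
  }
  if (any(per_learner_accuracy < 0 | per_learner_accuracy > 1)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  true_labels <- as.integer(true_labels)
  if (any(true_labels < 0 | true_labels >= n_classes)) {
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  }
  if (is.null(learner_ids)) learner_ids <- paste0("L", seq_len(n_learners))
  n <- length(true_labels)
  with_local_seed(seed, {
    out <- vector("list", n_learners)
    for (l in seq_len(n_learners)) {
      correct <- stats::runif(n) < per_learner_accuracy[l]
      chosen <- true_labels
      wrong <- which(!correct)
      if (length(wrong) > 0) {
        # uniform over the K-1 labels other than the true one
        shift <- sample.int(n_classes - 1L, length(wrong), replace = TRUE)
        chosen[wrong] <- (true_labels[wrong] + shift) %% n_classes
      }
      g <- matrix(stats::rgamma(n * n_classes, shape = 1), n, n_classes)
      g[cbind(seq_len(n), chosen + 1L)] <-
        stats::rgamma(n, shape = concentration)
      p <- g / rowSums(g)
      # enforce the argmax contract: swap the peak onto the chosen class
      amax <- max.col(p, ties.method = "first")
      swap <- which(amax != chosen + 1L)
      if (length(swap) > 0) {
        for (i in swap) {
          j <- amax[i]; k <- chosen[i] + 1L
          tmp <- p[i, j]; p[i, j] <- p[i, k]; p[i, k] <- tmp
        }
      }
      out[[l]] <- probability_matrix(p, learner_id = learner_ids[l])
    }
    names(out) <- learner_ids
    out
  })
}

#' Write an image dataset as a directory-per-class PNG tree
#'
#' Writes each record to `<root>/<class_name>/<id>.png` and a manifest CSV
#' (`manifest.csv` under `root`) with columns id, class_name, class_index,
#' provenance.
#'
#' @param records List of [image_record()] objects.
#' @param root Output directory (created if missing).
#' @param class_specs List of [class_spec()] supplying class names.
#' @return Invisibly, the manifest data frame.
#' @export
write_image_dataset <- function(records, root,
                                class_specs = default_class_specs()) {
  idx <- vapply(class_specs, function(s) s$label_index, integer(1))
  nm <- vapply(class_specs, function(s) s$label_name, character(1))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    cname <- nm[match(r$label, idx)]
    dir.create(file.path(root, cname), showWarnings = FALSE)
    png::writePNG(r$pixels / 255, file.path(root, cname, paste0(r$id, ".png")))
    data.frame(id = r$id, class_name = cname, class_index = r$label,
               provenance = r$provenance, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
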