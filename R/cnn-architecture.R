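#' Layer specifications
#'
#' Constructors for the layer kinds understood by the architecture
#' specification and the training engine: batch normalization, 2-D
#' convolution (same padding), max pooling (stride = pool size), flatten,
#' dense, and dropout.
#'
#' @param filters,units Output channels / units (>= 1).
#' @param filter_size Square filter/pool side length `f` (>= 1).
#' @param activation One of `"relu"`, `"softmax"`, `"none"`.
#' @param rate Dropout rate in `[0, 1)`.
#' @return A `layer_spec` list with fields kind, filter_size, depth_or_units,
#'   activation, dropout_rate.
#' @name layer_spec
NULL

new_layer <- function(kind, filter_size = NA_integer_, depth_or_units = NA_integer_,
                      activation = "none", dropout_rate = NA_real_) {
  structure(
    list(kind = kind, filter_size = filter_size,
         depth_or_units = depth_or_units, activation = activation,
         dropout_rate = dropout_rate),
    class = "layer_spec"
  )
}

#' @rdname layer_spec
#' @export
layer_batch_norm <- function() new_layer("batch_norm")

#' @rdname layer_spec
#' @export
layer_conv2d <- function(filters, filter_size = 3L, activation = "relu") {
  stopifnot(filters >= 1, filter_size >= 1)
  new_layer("conv2d", as.integer(filter_size), as.integer(filters),
            match.arg(activation, c("relu", "softmax", "none")))
}

#' @rdname layer_spec
#' @export
layer_max_pool <- function(filter_size = 2L) {
  stopifnot(filter_size >= 1)
  new_layer("max_pool", as.integer(filter_size))
}

#' @rdname layer_spec
#' @export
layer_flatten <- function() new_layer("flatten")

#' @rdname layer_spec
#' @export
layer_dense <- function(units, activation = "relu") {
  stopifnot(units >= 1)
  new_layer("dense", depth_or_units = as.integer(units),
            activation = match.arg(activation, c("relu", "softmax", "none")))
}

#' @rdname layer_spec
#' @export
layer_dropout <- function(rate = 0.5) {
  stopifnot(rate >= 0, rate < 1)
  new_layer("dropout", dropout_rate = rate)
}

#' Architecture specification
#'
#' An ordered stack of layers with a fixed input shape. Output shapes and
#' parameter counts are derived on construction via [infer_shapes()] and
#' [count_parameters()], so a spec is always internally consistent.
#'
#' @param layers List of layer specs (see [layer_spec]).
#' @param input_shape `(height, width, channels)`.
#' @return An object of class `architecture_spec` with fields `input_shape`,
#'   `layers`, `output_shapes`, `per_layer_params`, `total_params`.
#' @export
architecture_spec <- function(layers, input_shape = c(224, 224, 3)) {
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1))
  spec <- structure(
    list(input_shape = as.integer(input_shape), layers = layers),
    class = "architecture_spec"
  )
  spec$output_shapes <- infer_shapes(spec)
  pc <- count_parameters(spec)
  spec$per_layer_params <- pc$per_layer
  spec$total_params <- pc$total
  spec
}

#' The proposed compact CNN architecture
#'
#' The 19-layer stack classifying 224 x 224 x 3 histology tiles into three
#' classes: input batch normalization; seven conv/max-pool pairs with channel
#' progression 32, 32, 64, 64, 128, 128, 256 (all convolutions 3 x 3 with
#' same padding and ReLU, all pools 2 x 2); flatten; a 512-unit ReLU dense
#' layer; dropout; and a 3-unit softmax head. Spatial size halves at every
#' pool: 224 -> 112 -> 56 -> 28 -> 14 -> 7 -> 3 -> 1. Total parameter count
#' is 715,311 (batch normalization contributes 4 parameters per channel,
#' counting the non-trainable moving statistics).
#'
#' @param dropout_rate Dropout rate before the softmax head; does not affect
#'   the parameter count.
#' @param n_classes Output classes; 3 for the osteosarcoma task.
#' @return An [architecture_spec()].
#' @export
#' @examples
#' spec <- proposed_architecture()
#' spec$total_params  # 715311
proposed_architecture <- function(dropout_rate = 0.5, n_classes = 3L) {
  channels <- c(32L, 32L, 64L, 64L, 128L, 128L, 256L)
  layers <- list(layer_batch_norm())
  for (ch in channels) {
    layers <- c(layers, list(layer_conv2d(ch, 3L, "relu"), layer_max_pool(2L)))
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(512L, "relu"),
    layer_dropout(dropout_rate),
    layer_dense(as.integer(n_classes), "softmax")
  ))
  architecture_spec(layers, input_shape = c(224L, 224L, 3L))
}

#' Infer per-layer output shapes
#'
#' Chains shapes through the stack: convolutions use same padding (spatial
#' size preserved, channel count set by the layer); max pooling divides the
#' spatial size by the pool size with floor division; flatten multiplies the
#' dimensions; dense and dropout carry their unit count through.
#'
#' @param spec An `architecture_spec` (the derived fields may be absent).
#' @return List of integer output shapes, one per layer.
#' @export
infer_shapes <- function(spec) {
  shape <- as.integer(spec$input_shape)
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    shape <- switch(ly$kind,
      batch_norm = shape,
      conv2d = c(shape[1], shape[2], ly$depth_or_units),
      max_pool = {
        if (length(shape) != 3L) stop("max_pool requires a spatial input", call. = FALSE)
        sp <- shape[1:2] %/% ly$filter_size
        if (any(sp < 1L)) {
          stop(sprintf("layer %d: pooling a %dx%d map underflows to zero size",
                       i, shape[1], shape[2]), call. = FALSE)
        }
        c(sp, shape[3])
      },
      flatten = prod(shape),
      dense = ly$depth_or_units,
      dropout = shape,
      stop("unknown layer kind: ", ly$kind, call. = FALSE)
    )
    out[[i]] <- as.integer(shape)
  }
  out
}

#' Count parameters layer by layer
#'
#' Closed-form accounting: a convolution holds `(f^2 * C_in + 1) * C_out`
#' parameters (weights plus one bias per output channel); a dense layer
#' `(n_in + 1) * n_out`; batch normalization `4 * C` (scale, shift, moving
#' mean, moving variance — all counted); pooling, flatten and dropout hold
#' none.
#'
#' @param spec An `architecture_spec`.
#' @return List with `per_layer` (integer vector) and `total`.
#' @export
count_parameters <- function(spec) {
  shapes <- spec$output_shapes
  if (is.null(shapes)) shapes <- infer_shapes(spec)
  per <- integer(length(spec$layers))
  in_shape <- as.integer(spec$input_shape)
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    per[i] <- switch(ly$kind,
      batch_norm = 4L * in_shape[length(in_shape)],
      conv2d = (ly$filter_size^2 * in_shape[3] + 1L) * ly$depth_or_units,
      dense = (in_shape[1] + 1L) * ly$depth_or_units,
      0L
    )
    in_shape <- shapes[[i]]
  }
  list(per_layer = per, total = sum(per))
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec: input %s, %d layers, %s parameters>\n",
              paste(x$input_shape, collapse = "x"), length(x$layers),
              format(x$total_params, big.mark = ",")))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    cat(sprintf("  %2d %-10s %-8s -> %-12s %8d params\n", i, ly$kind,
                ifelse(is.na(ly$depth_or_units), "", ly$depth_or_units),
                paste(x$output_shapes[[i]], collapse = "x"),
                x$per_layer_params[i]))
  }
  invisible(x)
}

#' Serialize an architecture specification to JSON
#'
#' @param spec An `architecture_spec`.
#' @param path Output file path.
#' @return Invisibly, the JSON string.
#' @export
write_architecture_json <- function(spec, path) {
  obj <- list(
    input_shape = spec$input_shape,
    layers = lapply(seq_along(spec$layers), function(i) {
      ly <- spec$layers[[i]]
      list(kind = ly$kind,
           filter_size = if (!is.na(ly$filter_size)) ly$filter_size,
           depth_or_units = if (!is.na(ly$depth_or_units)) ly$depth_or_units,
           activation = ly$activation,
           dropout_rate = if (!is.na(ly$dropout_rate)) ly$dropout_rate,
           output_shape = spec$output_shapes[[i]],
           parameters = spec$per_layer_params[i])
    }),
    total_params = spec$total_params
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(js, path)
  invisible(as.character(js))
}
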