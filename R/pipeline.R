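#' Compact sibling of the proposed architecture for desk-scale runs
#'
#' Same layer grammar as [proposed_architecture()] (input batch norm,
#' conv/pool pairs, flatten, dense, dropout, softmax head) with a reduced
#' channel progression and input size, so a full pipeline run trains in
#' seconds on one CPU.
#'
#' @param input_shape `(height, width, 3)`.
#' @param channels Channel progression, one conv/pool pair per entry.
#' @param dense_units Units of the penultimate dense layer.
#' @param dropout_rate Dropout before the softmax head.
#' @param n_classes Output classes.
#' @return An [architecture_spec()].
#' @export
compact_architecture <- function(input_shape = c(32, 32, 3),
                                 channels = c(8L, 16L), dense_units = 32L,
                                 dropout_rate = 0.25, n_classes = 3L) {
  layers <- list(layer_batch_norm())
  for (ch in channels) {
    layers <- c(layers, list(layer_conv2d(as.integer(ch), 3L, "relu"),
                             layer_max_pool(2L)))
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(as.integer(dense_units), "relu"),
    layer_dropout(dropout_rate),
    layer_dense(as.integer(n_classes), "softmax")
  ))
  architecture_spec(layers, input_shape = as.integer(input_shape))
}

#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end pipeline: data source (a
#' directory-per-class tree, or the synthetic generator when `data_root` is
#' `NULL`), split fractions and seed, balancing, augmentation, architecture
#' and training settings, simulated transfer-learning base learners for the
#' ensemble stage, and the ensemble selection criterion.
#'
#' @param data_root Directory-per-class image tree, or `NULL` to generate a
#'   synthetic dataset.
#' @param output_dir Run directory for artifacts.
#' @param seed Master seed; stage seeds are derived from it.
#' @param train_frac,val_frac Split fractions (defaults 0.8 / 0.1).
#' @param stratified Stratified train/test split.
#' @param balance Oversample minority classes by horizontal flipping.
#' @param synth_counts Per-class image counts for the synthetic source.
#' @param image_size Generated image size `(H, W)`; images are
#'   bilinearly resized to `architecture$input_shape` during preprocessing.
#' @param architecture An [architecture_spec()]; default
#'   [compact_architecture()] sized to `image_size`.
#' @param training A [training_config()]; default 10 epochs at the standard
#'   optimizer settings.
#' @param augment An [augment_config()] or `NULL` to disable augmentation.
#' @param simulated_learners Named accuracies of simulated base learners
#'   joining the ensemble alongside the trained CNN (stand-ins for
#'   transfer-learning backbones, which plug in through the same
#'   probability-matrix interface).
#' @param criterion Ensemble selection criterion (see
#'   [brute_force_search()]).
#' @param class_names Class-name ordering (fixed class-index order).
#' @return An object of class `run_config`.
#' @export
run_config <- function(data_root = NULL, output_dir = tempfile("osteovote_run_"),
                       seed = 1L, train_frac = 0.8, val_frac = 0.1,
                       stratified = FALSE, balance = TRUE,
                       synth_counts = c(80L, 40L, 55L),
                       image_size = c(32L, 32L),
                       architecture = NULL,
                       training = training_config(epochs = 10L),
                       augment = augment_config(),
                       simulated_learners = c(NasNetMobile = 0.9,
                                              EfficientNetV2B0 = 0.92),
                       criterion = "accuracy",
                       class_names = c("Non-Tumor", "Necrotic-Tumor",
                                       "Viable-Tumor")) {
  if (is.null(architecture)) {
    architecture <- compact_architecture(c(as.integer(image_size), 3L),
                                         n_classes = length(class_names))
  }
  stopifnot(train_frac > 0, train_frac <= 1, val_frac >= 0, val_frac < 1)
  structure(
    list(data_root = data_root, output_dir = output_dir,
         seed = as.integer(seed), train_frac = train_frac,
         val_frac = val_frac, stratified = stratified, balance = balance,
         synth_counts = synth_counts, image_size = as.integer(image_size),
         architecture = architecture, training = training, augment = augment,
         simulated_learners = simulated_learners, criterion = criterion,
         class_names = class_names),
    class = "run_config"
  )
}

stage_logger <- function(log_path) {
  con_open <- !is.null(log_path)
  function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    message(line)
    if (con_open) cat(line, "\n", file = log_path, append = TRUE)
  }
}

#' Stack image records into a model-ready array
#'
#' Preprocesses each record (bilinear resize, scaling to `[0, 1]`) and
#' stacks the results into the `(n, H, W, 3)` array consumed by
#' [train_learner()] and [predict_proba()].
#'
#' @param records List of [image_record()] objects.
#' @param target_size `(height, width)`.
#' @return Numeric array `(n, H, W, 3)`.
#' @export
records_to_array <- function(records, target_size) {
  n <- length(records)
  x <- array(0, c(n, target_size[1], target_size[2], 3L))
  for (i in seq_len(n)) {
    x[i, , , ] <- preprocess_image(records[[i]], target_size)
  }
  x
}

#' Run the full pipeline end to end
#'
#' Executes ingest (or synthesis) -> split -> balance -> validation carve ->
#' preprocess -> CNN training -> prediction -> metric reporting -> ensemble
#' brute-force search, writing every artifact into the run directory:
#' `manifest.csv` (split membership), `architecture.json`, `history.csv`,
#' `predictions.csv`, `metrics.json` / `metrics.csv`, `confusion.csv`,
#' `search.json` / `search.csv`, `config.txt` and `run.log`. Fully
#' reproducible from the configuration and its seed. Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the run directory, the trained learner,
#'   the CNN `metric_report`, and the `combination_search`.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$data_root) && !dir.exists(config$data_root)) {
    stop("configuration error: data root does not exist: ", config$data_root,
         call. = FALSE)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- stage_logger(file.path(config$output_dir, "run.log"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log(name, sprintf("done in %.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  k <- length(config$class_names)

  records <- stage("ingest", {
    if (is.null(config$data_root)) {
      generate_image_dataset(config$synth_counts,
                             image_size = config$image_size,
                             seed = config$seed)
    } else {
      read_image_dataset(config$data_root, class_order = config$class_names)
    }
  })

  splits <- stage("split", {
    sp <- split_dataset(records, config$train_frac, seed = config$seed,
                        stratified = config$stratified)
    train <- sp$train
    # allow_duplicates: after a random split a minority class's deficit can
    # exceed its size, and the reference composition itself requires it
    if (config$balance) train <- balance_by_flip(train, seed = config$seed + 1L,
                                                 allow_duplicates = TRUE)
    cv <- carve_validation(train, config$val_frac, seed = config$seed + 2L)
    list(train = cv$train, validation = cv$validation, test = sp$test)
  })
  write_split_manifest(splits, file.path(config$output_dir, "manifest.csv"))

  arch <- config$architecture
  target <- arch$input_shape[1:2]
  data <- stage("preprocess", {
    list(
      x_train = records_to_array(splits$train, target),
      y_train = record_labels(splits$train),
      x_val = if (length(splits$validation) > 0)
        records_to_array(splits$validation, target) else NULL,
      y_val = if (length(splits$validation) > 0)
        record_labels(splits$validation) else NULL,
      x_test = records_to_array(splits$test, target),
      y_test = record_labels(splits$test)
    )
  })
  write_architecture_json(arch, file.path(config$output_dir, "architecture.json"))

  learner <- stage("train", {
    train_learner(arch, config$training, data$x_train, data$y_train,
                  data$x_val, data$y_val, augment = config$augment,
                  seed = config$seed + 3L, learner_id = "CNN")
  })
  write_history_csv(learner, file.path(config$output_dir, "history.csv"))

  predictions <- stage("predict", {
    cnn <- predict_proba(learner, data$x_test)
    preds <- list(CNN = cnn)
    if (length(config$simulated_learners) > 0) {
      sim <- generate_prediction_matrices(
        n_learners = length(config$simulated_learners),
        true_labels = data$y_test, n_classes = k,
        per_learner_accuracy = unname(config$simulated_learners),
        seed = config$seed + 4L,
        learner_ids = names(config$simulated_learners)
      )
      preds <- c(preds, sim)
    }
    preds
  })
  write_probability_csv(predictions, file.path(config$output_dir, "predictions.csv"))

  cnn_report <- stage("evaluate", {
    metric_report(data$y_test, probs = predictions$CNN,
                  class_names = config$class_names)
  })
  write_metric_report(cnn_report,
                      json_path = file.path(config$output_dir, "metrics.json"),
                      csv_path = file.path(config$output_dir, "metrics.csv"))
  write_confusion_csv(cnn_report$confusion,
                      file.path(config$output_dir, "confusion.csv"),
                      class_names = config$class_names)

  search <- stage("search", {
    brute_force_search(predictions, data$y_test, criterion = config$criterion,
                       class_names = config$class_names)
  })
  write_search_results(search,
                       json_path = file.path(config$output_dir, "search.json"),
                       csv_path = file.path(config$output_dir, "search.csv"))

  write_run_config(config, file.path(config$output_dir, "config.txt"))
  log("run", sprintf("complete; artifacts under %s", config$output_dir))
  invisible(list(run_dir = config$output_dir, learner = learner,
                 cnn_report = cnn_report, search = search))
}

#' Render consolidated tables from a completed run
#'
#' Re-derives, without recomputation drift, the class-wise metric table from
#' the stored confusion matrix and the ensemble combination table from the
#' stored search results. Idempotent across invocations.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return List with `class_table` (class-wise integer-percent metrics) and
#'   `combination_table` (ranked ensemble combinations).
#' @export
report_run <- function(run_dir) {
  needed <- c("confusion.csv", "search.csv")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing) > 0) {
    stop("incomplete run; missing artifacts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cm <- read_confusion_csv(file.path(run_dir, "confusion.csv"))
  k <- nrow(cm)
  per <- lapply(seq_len(k) - 1L, function(kk) {
    bc <- one_vs_rest_counts(cm, kk)
    data.frame(class = rownames(cm)[kk + 1L],
               accuracy = percent2(class_accuracy(bc)),
               precision = percent0(precision(bc)),
               recall = percent0(recall(bc)),
               f1 = percent0(f1_score(bc)))
  })
  class_table <- do.call(rbind, per)
  combination_table <- utils::read.csv(file.path(run_dir, "search.csv"))
  list(class_table = class_table, combination_table = combination_table)
}

#' Write / read the plain-text key-value configuration format
#'
#' One `key = value` pair per line; vectors comma-separated; nested
#' architecture/training/augmentation settings are stored under dotted keys.
#' Only scalar-representable fields round-trip; the architecture itself is
#' regenerated from its stored dimensions.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) paste(v, collapse = ", ")
  lines <- c(
    paste("data_root =", ifelse(is.null(config$data_root), "", config$data_root)),
    paste("seed =", config$seed),
    paste("train_frac =", config$train_frac),
    paste("val_frac =", config$val_frac),
    paste("stratified =", config$stratified),
    paste("balance =", config$balance),
    paste("synth_counts =", fmt(config$synth_counts)),
    paste("image_size =", fmt(config$image_size)),
    paste("criterion =", config$criterion),
    paste("class_names =", fmt(config$class_names)),
    paste("training.learning_rate =", config$training$learning_rate),
    paste("training.batch_size =", config$training$batch_size),
    paste("training.epochs =", config$training$epochs),
    if (!is.null(config$augment)) c(
      paste("augment.vertical_flip_prob =", config$augment$vertical_flip_prob),
      paste("augment.rotation_range_deg =", config$augment$rotation_range_deg),
      paste("augment.brightness_delta =", config$augment$brightness_delta)
    ),
    paste("simulated_learners =",
          paste(sprintf("%s:%s", names(config$simulated_learners),
                        config$simulated_learners), collapse = ", "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @param overrides Named list applied over the file's values (the CLI's
#'   flag-override mechanism).
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    kv[[key]] <- trimws(paste(parts[-1], collapse = "="))
  }
  kv[names(overrides)] <- lapply(overrides, as.character)
  num <- function(key, default) if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  lgl <- function(key, default) if (is.null(kv[[key]])) default else as.logical(kv[[key]])
  vec <- function(key, default, cast = as.numeric) {
    if (is.null(kv[[key]]) || !nzchar(kv[[key]])) return(default)
    cast(trimws(strsplit(kv[[key]], ",")[[1]]))
  }
  sim <- kv[["simulated_learners"]]
  simulated <- if (is.null(sim) || !nzchar(sim)) {
    c(NasNetMobile = 0.9, EfficientNetV2B0 = 0.92)
  } else {
    parts <- trimws(strsplit(sim, ",")[[1]])
    vals <- vapply(parts, function(p) as.numeric(sub(".*:", "", p)), numeric(1))
    names(vals) <- sub(":.*", "", parts)
    vals
  }
  image_size <- as.integer(vec("image_size", c(32, 32)))
  class_names <- vec("class_names",
                     c("Non-Tumor", "Necrotic-Tumor", "Viable-Tumor"),
                     as.character)
  aug <- if (!is.null(kv[["augment.vertical_flip_prob"]])) {
    augment_config(num("augment.vertical_flip_prob", 0.5),
                   num("augment.rotation_range_deg", 20),
                   num("augment.brightness_delta", 0.2))
  } else augment_config()
  run_config(
    data_root = if (is.null(kv[["data_root"]]) || !nzchar(kv[["data_root"]]))
      NULL else kv[["data_root"]],
    output_dir = if (is.null(kv[["output_dir"]]))
      tempfile("osteovote_run_") else kv[["output_dir"]],
    seed = as.integer(num("seed", 1)),
    train_frac = num("train_frac", 0.8),
    val_frac = num("val_frac", 0.1),
    stratified = lgl("stratified", FALSE),
    balance = lgl("balance", TRUE),
    synth_counts = as.integer(vec("synth_counts", c(80, 40, 55))),
    image_size = image_size,
    training = training_config(
      learning_rate = num("training.learning_rate", 0.001),
      batch_size = as.integer(num("training.batch_size", 16)),
      epochs = as.integer(num("training.epochs", 10))),
    augment = aug,
    simulated_learners = simulated,
    criterion = if (is.null(kv[["criterion"]])) "accuracy" else kv[["criterion"]],
    class_names = class_names
  )
}
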