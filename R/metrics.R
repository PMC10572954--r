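#' Build a confusion matrix
#'
#' `counts[i, j]` is the number of samples with true class `i - 1` predicted
#' as class `j - 1`: rows are true classes, columns predicted classes, in
#' fixed class-index order.
#'
#' @param y_true,y_pred Equal-length integer label vectors in `[0, K)`.
#' @param n_classes Class count `K`.
#' @param class_names Optional dimnames.
#' @return A `confusion_matrix`: K x K integer matrix.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
confusion_matrix <- function(y_true, y_pred,
                             n_classes = max(y_true, y_pred) + 1L,
                             class_names = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(c(y_true, y_pred) < 0L | c(y_true, y_pred) >= n_classes)) {
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (t in seq_along(y_true)) {
    cm[y_true[t] + 1L, y_pred[t] + 1L] <- cm[y_true[t] + 1L, y_pred[t] + 1L] + 1L
  }
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Wrap an existing count matrix as a confusion matrix
#' @param counts K x K non-negative integer matrix (rows = true classes).
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0)) {
    stop("`counts` must be a square non-negative matrix", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' One-vs-rest binary counts for a class
#'
#' Decomposes a multiclass confusion matrix into the binary counts for one
#' class treated as positive: TPOS is the diagonal cell, FNG the rest of its
#' row, FPOS the rest of its column, and TNG everything else.
#'
#' @param cm A `confusion_matrix`.
#' @param class_index Class in `[0, K)`.
#' @return List with tpos, tng, fpos, fng.
#' @export
one_vs_rest_counts <- function(cm, class_index) {
  k <- class_index + 1L
  if (class_index < 0 || k > nrow(cm)) {
    stop("`class_index` out of range", call. = FALSE)
  }
  tpos <- cm[k, k]
  fng <- sum(cm[k, ]) - tpos
  fpos <- sum(cm[, k]) - tpos
  tng <- sum(cm) - tpos - fng - fpos
  list(tpos = tpos, tng = tng, fpos = fpos, fng = fng)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s has zero denominator; returning 0", what), call. = FALSE)
    return(0)
  }
  num / den
}

#' Overall accuracy
#' @param cm A `confusion_matrix`.
#' @return Fraction of correctly classified samples (trace / N).
#' @export
accuracy <- function(cm) {
  safe_ratio(sum(diag(cm)), sum(cm), "accuracy")
}

#' Precision, recall, F1 and class accuracy from binary counts
#'
#' Precision = TPOS / (TPOS + FPOS); recall = TPOS / (TPOS + FNG);
#' F1 = harmonic mean of the two; class accuracy = (TPOS + TNG) / N.
#' Zero denominators yield 0 with a warning rather than an error.
#'
#' @param bc Binary counts from [one_vs_rest_counts()].
#' @return A fraction in `[0, 1]`.
#' @name binary_metrics
NULL

#' @rdname binary_metrics
#' @export
precision <- function(bc) safe_ratio(bc$tpos, bc$tpos + bc$fpos, "precision")

#' @rdname binary_metrics
#' @export
recall <- function(bc) safe_ratio(bc$tpos, bc$tpos + bc$fng, "recall")

#' @rdname binary_metrics
#' @export
f1_score <- function(bc) {
  pn <- precision(bc); rl <- recall(bc)
  if (pn + rl == 0) {
    warning("f1 has zero denominator; returning 0", call. = FALSE)
    return(0)
  }
  2 * pn * rl / (pn + rl)
}

#' @rdname binary_metrics
#' @export
class_accuracy <- function(bc) {
  safe_ratio(bc$tpos + bc$tng, bc$tpos + bc$tng + bc$fpos + bc$fng,
             "class accuracy")
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, where `p_o` is the
#' observed accuracy and the random accuracy `p_e` is the marginal-product
#' expectation `sum_i(row_i * col_i) / N^2`.
#'
#' @param cm A `confusion_matrix`.
#' @return Value in `[-1, 1]`.
#' @export
kappa_score <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (p_e == 1) {
    warning("chance agreement is 1; kappa undefined, returning 0", call. = FALSE)
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Multiclass logarithmic loss
#'
#' Mean negative log predicted probability of the true class,
#' `-(1/N) sum_i log p_i(true_i)`, with probabilities clipped away from 0.
#' For two classes this reduces to the familiar binary cross-entropy; uniform
#' predictions over `K` classes give `log(K)`.
#'
#' @param y_true Integer labels in `[0, K)`.
#' @param probs `N x K` probability matrix, rows summing to 1 within 1e-6.
#' @param clip_eps Clipping floor for predicted probabilities.
#' @return Non-negative real.
#' @export
multiclass_log_loss <- function(y_true, probs, clip_eps = 1e-15) {
  probs <- unclass_probability(probs)
  y_true <- as.integer(y_true)
  if (nrow(probs) != length(y_true)) {
    stop("`probs` rows must align with `y_true`", call. = FALSE)
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1 within 1e-6", call. = FALSE)
  }
  p <- pmin(pmax(probs[cbind(seq_along(y_true), y_true + 1L)], clip_eps),
            1 - clip_eps)
  -mean(log(p))
}

# Mann-Whitney AUC for one score vector: ties count 1/2.
rank_auc <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest ROC-AUC with micro and macro averaging
#'
#' Per-class AUC via the rank (Mann-Whitney) formulation with ties counted
#' one half. The macro average is the unweighted mean over classes with at
#' least one positive and one negative; the micro average is the AUC over
#' the flattened one-vs-rest label/score pairs.
#'
#' @param y_true Integer labels in `[0, K)`.
#' @param probs `N x K` score matrix (column `k` scores class `k - 1`).
#' @return List with `per_class` (NA for degenerate classes), `macro`,
#'   `micro`.
#' @export
ovr_auc <- function(y_true, probs) {
  probs <- unclass_probability(probs)
  y_true <- as.integer(y_true)
  k <- ncol(probs)
  per_class <- vapply(seq_len(k), function(j) {
    rank_auc(probs[, j], y_true == j - 1L)
  }, numeric(1))
  defined <- !is.na(per_class)
  if (!all(defined)) {
    warning("AUC undefined for class(es) without positives or negatives: ",
            paste(which(!defined) - 1L, collapse = ", "), call. = FALSE)
  }
  micro <- rank_auc(as.vector(probs),
                    as.vector(outer(y_true, seq_len(k) - 1L, "==")))
  list(per_class = per_class,
       macro = mean(per_class[defined]),
       micro = micro)
}

#' Assemble a full metric report
#'
#' Computes the complete evaluation suite for one classifier: overall
#' accuracy, per-class precision/recall/F1/class-accuracy/AUC, macro and
#' support-weighted aggregates, Cohen's kappa, and multiclass log-loss.
#' Predictions may be given as a probability matrix (labels are its row-wise
#' argmax) or as hard labels (probability-based metrics are then `NA`).
#'
#' @param y_true Integer labels in `[0, K)`.
#' @param probs Optional `N x K` probability matrix.
#' @param y_pred Optional hard labels (ignored when `probs` is given).
#' @param n_classes Class count `K`.
#' @param class_names Optional class names for presentation.
#' @return An object of class `metric_report`.
#' @export
metric_report <- function(y_true, probs = NULL, y_pred = NULL,
                          n_classes = NULL, class_names = NULL) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (is.null(probs) && is.null(y_pred)) {
    stop("supply `probs` or `y_pred`", call. = FALSE)
  }
  if (!is.null(probs)) {
    probs <- unclass_probability(probs)
    y_pred <- max.col(probs, ties.method = "first") - 1L
    if (is.null(n_classes)) n_classes <- ncol(probs)
  }
  if (is.null(n_classes)) n_classes <- max(y_true, y_pred) + 1L
  cm <- confusion_matrix(y_true, y_pred, n_classes, class_names)
  per <- lapply(seq_len(n_classes) - 1L, function(k) {
    bc <- one_vs_rest_counts(cm, k)
    list(precision = precision(bc), recall = recall(bc), f1 = f1_score(bc),
         class_accuracy = class_accuracy(bc), support = bc$tpos + bc$fng)
  })
  auc <- if (!is.null(probs)) ovr_auc(y_true, probs) else
    list(per_class = rep(NA_real_, n_classes), macro = NA_real_,
         micro = NA_real_)
  support <- vapply(per, `[[`, numeric(1), "support")
  w <- support / sum(support)
  agg <- function(field) {
    v <- vapply(per, `[[`, numeric(1), field)
    c(macro = mean(v), weighted = sum(w * v))
  }
  structure(
    list(
      confusion = cm,
      n = sum(cm),
      accuracy = accuracy(cm),
      per_class = per,
      per_class_auc = auc$per_class,
      macro = c(precision = agg("precision")[["macro"]],
                recall = agg("recall")[["macro"]],
                f1 = agg("f1")[["macro"]],
                auc = auc$macro),
      weighted = c(precision = agg("precision")[["weighted"]],
                   recall = agg("recall")[["weighted"]],
                   f1 = agg("f1")[["weighted"]]),
      micro_auc = auc$micro,
      kappa = kappa_score(cm),
      log_loss = if (!is.null(probs)) multiclass_log_loss(y_true, probs)
                 else NA_real_,
      class_names = class_names
    ),
    class = "metric_report"
  )
}

#' Presentation rounding helpers
#'
#' Reported tables mix two conventions: two-decimal percentages for overall
#' metrics (e.g. accuracy 95.63) and integer percentages for class-wise
#' tables (e.g. precision 99).
#'
#' @param x Fraction in `[0, 1]`.
#' @return Percentage, rounded.
#' @export
percent2 <- function(x) round(100 * x, 2)

#' @rdname percent2
#' @export
percent0 <- function(x) round(100 * x)

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: n = %d, accuracy %.2f%%, kappa %.2f%%%s>\n",
              x$n, percent2(x$accuracy), percent2(x$kappa),
              if (!is.na(x$log_loss))
                sprintf(", log-loss %.3f", x$log_loss) else ""))
  print(class_wise_table(x))
  invisible(x)
}

#' Class-wise metric table (integer-percent presentation)
#'
#' @param report A `metric_report`.
#' @return Data frame with one row per class: class accuracy (2-decimal
#'   percent), precision/recall/F1 (integer percent), AUC (2 decimals).
#' @export
class_wise_table <- function(report) {
  k <- length(report$per_class)
  nm <- report$class_names
  if (is.null(nm)) nm <- paste0("class_", seq_len(k) - 1L)
  data.frame(
    class = nm,
    accuracy = vapply(report$per_class,
                      function(p) percent2(p$class_accuracy), numeric(1)),
    precision = vapply(report$per_class,
                       function(p) percent0(p$precision), numeric(1)),
    recall = vapply(report$per_class,
                    function(p) percent0(p$recall), numeric(1)),
    f1 = vapply(report$per_class, function(p) percent0(p$f1), numeric(1)),
    auc = round(report$per_class_auc, 2),
    stringsAsFactors = FALSE
  )
}

#' Overall metric row (two-decimal-percent presentation)
#'
#' @param report A `metric_report`.
#' @param aggregate `"macro"` or `"weighted"` for precision/recall/F1.
#' @return One-row data frame in the column order accuracy, precision,
#'   recall, f1, auc, kappa, log_loss.
#' @export
overall_table <- function(report, aggregate = c("macro", "weighted")) {
  aggregate <- match.arg(aggregate)
  v <- if (aggregate == "macro") report$macro else
    c(report$weighted, auc = report$macro[["auc"]])
  data.frame(
    accuracy = percent2(report$accuracy),
    precision = percent0(v[["precision"]]),
    recall = percent0(v[["recall"]]),
    f1 = percent0(v[["f1"]]),
    auc = round(report$macro[["auc"]], 3),
    kappa = percent2(report$kappa),
    log_loss = round(report$log_loss, 3)
  )
}

#' Write a metric report as JSON (full precision) and CSV (rounded)
#'
#' @param report A `metric_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_metric_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      n = report$n,
      accuracy = report$accuracy,
      kappa = report$kappa,
      log_loss = report$log_loss,
      macro = as.list(report$macro),
      weighted = as.list(report$weighted),
      micro_auc = report$micro_auc,
      per_class = lapply(seq_along(report$per_class), function(i) {
        c(report$per_class[[i]], list(auc = report$per_class_auc[i]))
      }),
      confusion = unclass(report$confusion)
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null"), json_path)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(cbind(overall_table(report),
                           overall_weighted = percent0(report$weighted[["f1"]])),
                     csv_path, row.names = FALSE)
  }
  invisible(report)
}

#' Write a confusion matrix CSV with class-name headers
#' @param cm A `confusion_matrix`.
#' @param path Output path.
#' @param class_names Optional names; defaults to existing dimnames or
#'   `class_0..`.
#' @return Invisibly, `cm`.
#' @export
write_confusion_csv <- function(cm, path, class_names = NULL) {
  if (is.null(class_names)) {
    class_names <- rownames(cm)
    if (is.null(class_names)) class_names <- paste0("class_", seq_len(nrow(cm)) - 1L)
  }
  m <- as.data.frame(unclass(cm))
  names(m) <- class_names
  utils::write.csv(cbind(true_class = class_names, m), path, row.names = FALSE)
  invisible(cm)
}

#' Read back a confusion matrix CSV written by [write_confusion_csv()]
#' @param path CSV path.
#' @return A `confusion_matrix` with dimnames.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cm <- as.matrix(df[, -1, drop = FALSE])
  dimnames(cm) <- list(true = df[[1]], predicted = colnames(cm))
  as_confusion_matrix(cm)
}
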