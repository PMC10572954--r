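#' Per-learner class-probability matrix
#'
#' `n_samples x K` class probabilities from one base learner; every row must
#' sum to 1 within 1e-6. Carries the learner's id as an attribute.
#'
#' @param values Numeric matrix with entries in `[0, 1]`.
#' @param learner_id Identifier of the emitting learner.
#' @return An object of class `probability_matrix`.
#' @export
probability_matrix <- function(values, learner_id = "learner") {
  values <- as.matrix(values)
  if (any(values < -1e-12 | values > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(values) - 1) > 1e-6)) {
    stop("every probability row must sum to 1 within 1e-6", call. = FALSE)
  }
  structure(values, learner_id = learner_id,
            class = c("probability_matrix", "matrix", "array"))
}

# Strip the class so plain matrix algebra applies.
unclass_probability <- function(p) {
  m <- unclass(p)
  attr(m, "learner_id") <- NULL
  m
}

#' @export
print.probability_matrix <- function(x, ...) {
  cat(sprintf("<probability_matrix %s: %d samples x %d classes>\n",
              attr(x, "learner_id"), nrow(x), ncol(x)))
  invisible(x)
}

check_prediction_set <- function(predictions) {
  if (length(predictions) < 2L) {
    stop("at least 2 base learners are required", call. = FALSE)
  }
  dims <- vapply(predictions, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all probability matrices must share the same dimensions", call. = FALSE)
  }
  invisible(dims[, 1])
}

#' Tally hard votes across base learners
#'
#' Each learner casts one vote per sample for its argmax class (lowest index
#' on within-learner argmax ties). Row sums equal the number of
#' participating learners.
#'
#' @param predictions List of >= 2 [probability_matrix()] objects with
#'   identical dimensions.
#' @return `n_samples x K` integer vote-count matrix of class `vote_tally`.
#' @export
tally_votes <- function(predictions) {
  d <- check_prediction_set(predictions)
  n <- d[1]; k <- d[2]
  tally <- matrix(0L, n, k)
  for (p in predictions) {
    vote <- max.col(unclass_probability(p), ties.method = "first")
    tally[cbind(seq_len(n), vote)] <- tally[cbind(seq_len(n), vote)] + 1L
  }
  structure(tally, class = c("vote_tally", "matrix", "array"))
}

#' Adapted majority vote with probability tie-breaking
#'
#' Per sample, the predicted class is the one with the highest vote count.
#' When two or more classes tie for the highest count, the tie is resolved
#' by the summed predicted probability of the tied classes across the
#' participating learners; a residual exact tie falls back to the lowest
#' class index. A strict vote majority can never be overturned by
#' probabilities.
#'
#' @param predictions List of >= 2 [probability_matrix()] objects.
#' @return List with `labels` (integer class indices) and `tie_flags`
#'   (logical; `TRUE` where the probability rule decided the sample).
#' @export
#' @examples
#' a <- probability_matrix(matrix(c(0.8, 0.1, 0.1), 1), "A")
#' b <- probability_matrix(matrix(c(0.2, 0.5, 0.3), 1), "B")
#' adapted_majority_vote(list(a, b))
adapted_majority_vote <- function(predictions) {
  tally <- tally_votes(predictions)
  n <- nrow(tally); k <- ncol(tally)
  prob_sum <- Reduce(`+`, lapply(predictions, unclass_probability))
  labels <- integer(n)
  tie_flags <- logical(n)
  row_max <- do.call(pmax, lapply(seq_len(k), function(j) tally[, j]))
  for (i in seq_len(n)) {
    tied <- which(tally[i, ] == row_max[i])
    if (length(tied) == 1L) {
      labels[i] <- tied - 1L
    } else {
      tie_flags[i] <- TRUE
      ps <- prob_sum[i, tied]
      labels[i] <- tied[which.max(ps)] - 1L   # which.max -> lowest index on ties
    }
  }
  list(labels = labels, tie_flags = tie_flags)
}

#' Enumerate all base-learner combinations of size two or more
#'
#' A combination comprises at least two learners, so for `k` learners there
#' are `2^k - k - 1` combinations. Order is deterministic: by size, then
#' lexicographically within size over sorted ids.
#'
#' @param learner_ids Character vector of >= 2 distinct ids.
#' @return List of character vectors.
#' @export
enumerate_combinations <- function(learner_ids) {
  learner_ids <- sort(unique(as.character(learner_ids)))
  k <- length(learner_ids)
  if (k < 2L) stop("need at least 2 distinct learner ids", call. = FALSE)
  out <- list()
  for (size in 2:k) {
    cmb <- utils::combn(learner_ids, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Brute-force search over all ensemble combinations
#'
#' Evaluates the adapted majority vote for every combination of base
#' learners (size >= 2) against a labeled evaluation split and ranks the
#' combinations by the chosen criterion, descending. Ranking ties are broken
#' by fewer learners, then higher kappa, then lexicographic ids. To avoid
#' selection leakage, prefer a validation split as `y_eval`; evaluating on
#' the test split reproduces the protocol that reports test-set rankings.
#'
#' @param predictions Named list of >= 2 [probability_matrix()] objects
#'   (names or `learner_id` attributes identify learners).
#' @param y_eval Integer labels aligned with the matrices' rows.
#' @param criterion `"accuracy"` (default), `"kappa"` or `"f1"` (macro F1).
#' @param class_names Optional class names for the per-combination reports.
#' @return An object of class `combination_search` with `ranking` (data
#'   frame), `reports` (per-combination `metric_report`s in ranked order),
#'   `selected` (best combination's ids), `criterion`.
#' @export
brute_force_search <- function(predictions, y_eval,
                               criterion = c("accuracy", "kappa", "f1"),
                               class_names = NULL) {
  criterion <- match.arg(criterion)
  ids <- names(predictions)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(predictions, attr, character(1), "learner_id")
    names(predictions) <- ids
  }
  if (anyDuplicated(ids)) stop("learner ids must be distinct", call. = FALSE)
  d <- check_prediction_set(predictions)
  if (d[1] != length(y_eval)) {
    stop("`y_eval` must align with the prediction rows", call. = FALSE)
  }
  combos <- enumerate_combinations(ids)
  reports <- vector("list", length(combos))
  rows <- vector("list", length(combos))
  for (ci in seq_along(combos)) {
    members <- combos[[ci]]
    vote <- adapted_majority_vote(predictions[members])
    rep_i <- metric_report(y_eval, y_pred = vote$labels, n_classes = d[2],
                           class_names = class_names)
    reports[[ci]] <- rep_i
    score <- switch(criterion,
                    accuracy = rep_i$accuracy,
                    kappa = rep_i$kappa,
                    f1 = rep_i$macro[["f1"]])
    rows[[ci]] <- data.frame(
      combination = paste(members, collapse = "+"),
      size = length(members),
      accuracy = rep_i$accuracy,
      precision = rep_i$weighted[["precision"]],
      recall = rep_i$weighted[["recall"]],
      f1 = rep_i$weighted[["f1"]],
      kappa = rep_i$kappa,
      score = score,
      ties_broken = sum(vote$tie_flags),
      stringsAsFactors = FALSE
    )
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$score, ranking$size, -ranking$kappa,
               ranking$combination)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(
    list(ranking = ranking, reports = reports[ord],
         selected = combos[[ord[1]]], criterion = criterion),
    class = "combination_search"
  )
}

#' @export
print.combination_search <- function(x, ...) {
  cat(sprintf("<combination_search: %d combinations ranked by %s; best = %s>\n",
              nrow(x$ranking), x$criterion,
              paste(x$selected, collapse = "+")))
  top <- utils::head(x$ranking[, c("rank", "combination", "accuracy", "kappa")], 5)
  top$accuracy <- percent2(top$accuracy); top$kappa <- percent2(top$kappa)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Write search results as JSON and a combination-table CSV
#'
#' The CSV mirrors the reported ensemble comparison: combination members,
#' accuracy (2-decimal percent), precision/recall/F1 (fractions), kappa
#' (2-decimal percent).
#'
#' @param search A `combination_search`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the search object.
#' @export
write_search_results <- function(search, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      criterion = search$criterion,
      selected = search$selected,
      ranking = search$ranking
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"), json_path)
  }
  if (!is.null(csv_path)) {
    r <- search$ranking
    utils::write.csv(data.frame(
      rank = r$rank, models = r$combination,
      accuracy = percent2(r$accuracy),
      precision = round(r$precision, 4),
      recall = round(r$recall, 4),
      f1 = round(r$f1, 4),
      kappa = percent2(r$kappa)
    ), csv_path, row.names = FALSE)
  }
  invisible(search)
}

#' Write probability matrices in the interchange CSV dialect
#'
#' Long-format CSV with columns learner_id, sample_id, `p_0..p_{K-1}`.
#'
#' @param predictions Named list of [probability_matrix()] objects.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_probability_csv <- function(predictions, path) {
  rows <- lapply(predictions, function(p) {
    m <- unclass_probability(p)
    df <- as.data.frame(m)
    names(df) <- paste0("p_", seq_len(ncol(m)) - 1L)
    cbind(data.frame(learner_id = attr(p, "learner_id"),
                     sample_id = seq_len(nrow(m))), df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read probability matrices written by [write_probability_csv()]
#' @param path CSV path.
#' @return Named list of [probability_matrix()] objects.
#' @export
read_probability_csv <- function(path) {
  df <- utils::read.csv(path)
  pcols <- grep("^p_", names(df), value = TRUE)
  pcols <- pcols[order(as.integer(sub("^p_", "", pcols)))]
  out <- lapply(split(df, df$learner_id), function(sub) {
    sub <- sub[order(sub$sample_id), , drop = FALSE]
    probability_matrix(as.matrix(sub[, pcols, drop = FALSE]),
                       learner_id = as.character(sub$learner_id[1]))
  })
  out[unique(as.character(df$learner_id))]
}
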