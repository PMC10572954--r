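test_that("confusion matrices count true/predicted pairs in fixed class order", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unclass(cm)[1:2, 1:2], matrix(c(1L, 0L, 1L, 1L), 2),
               ignore_attr = TRUE)
  diag_cm <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(sum(diag(diag_cm)), 3)
  expect_equal(sum(diag_cm) - sum(diag(diag_cm)), 0)
  expect_error(confusion_matrix(c(0, 1), c(0), 2), "equal length")
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 2), "\\[0, n_classes\\)")
})

test_that("one-vs-rest decomposition recovers the binary counts", {
  cm <- cnn_test_confusion()
  viable <- one_vs_rest_counts(cm, 2)
  expect_equal(viable, list(tpos = 57L, tng = 168L, fpos = 1L, fng = 3L))
  d <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  for (k in 0:2) {
    bc <- one_vs_rest_counts(d, k)
    expect_equal(bc$fpos, 0L)
    expect_equal(bc$fng, 0L)
  }
  one_class <- as_confusion_matrix(matrix(5L, 1, 1))
  expect_equal(one_vs_rest_counts(one_class, 0)$tng, 0L)
})

test_that("the published test-split metrics are recomputed exactly", {
  cm <- cnn_test_confusion()
  expect_equal(percent2(accuracy(cm)), 95.63)
  expect_equal(percent2(kappa_score(cm)), 93.09)
  # class-wise table: accuracy / precision / recall / F1
  expected <- data.frame(
    accuracy = c(96.94, 96.07, 98.25),
    precision = c(99, 87, 98),
    recall = c(95, 98, 95),
    f1 = c(97, 92, 97)
  )
  for (k in 0:2) {
    bc <- one_vs_rest_counts(cm, k)
    expect_equal(percent2(class_accuracy(bc)), expected$accuracy[k + 1])
    expect_equal(percent0(precision(bc)), expected$precision[k + 1])
    expect_equal(percent0(recall(bc)), expected$recall[k + 1])
    expect_equal(percent0(f1_score(bc)), expected$f1[k + 1])
  }
})

test_that("the voting-ensemble test-split metrics are recomputed exactly", {
  cm <- enl_cne_confusion()
  expect_equal(percent2(accuracy(cm)), 96.51)
  expect_equal(percent0(recall(one_vs_rest_counts(cm, 2))), 100)
})

test_that("kappa has the expected closed-form limits and invariances", {
  perfect <- confusion_matrix(rep(0:2, 5), rep(0:2, 5), 3)
  expect_equal(kappa_score(perfect), 1)
  chance <- as_confusion_matrix(matrix(5L, 2, 2))
  expect_equal(kappa_score(chance), 0)
  # independent oracle: e1071's classAgreement on random matrices
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    cm <- as_confusion_matrix(matrix(rpois(k * k, 8), k, k))
    expect_equal(kappa_score(cm), e1071::classAgreement(unclass(cm))$kappa,
                 tolerance = 1e-12)
    # invariant under simultaneous row/column permutation
    p <- sample(k)
    expect_equal(kappa_score(as_confusion_matrix(unclass(cm)[p, p])),
                 kappa_score(cm))
    # kappa <= accuracy for above-chance classifiers
    if (kappa_score(cm) > 0) expect_lte(kappa_score(cm), accuracy(cm))
  }
})

test_that("metrics from matrices agree with direct counting on random instances", {
  set.seed(23)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    n <- sample(10:60, 1)
    y <- sample(0:(k - 1), n, replace = TRUE)
    p <- sample(0:(k - 1), n, replace = TRUE)
    cm <- confusion_matrix(y, p, k)
    expect_equal(accuracy(cm), mean(y == p))
    kk <- sample(0:(k - 1), 1)
    bc <- one_vs_rest_counts(cm, kk)
    expect_equal(bc$tpos, sum(y == kk & p == kk))
    expect_equal(bc$fpos, sum(y != kk & p == kk))
    expect_equal(bc$fng, sum(y == kk & p != kk))
    expect_equal(bc$tng, sum(y != kk & p != kk))
  }
})

test_that("zero-denominator metrics warn and return 0 instead of crashing", {
  cm <- as_confusion_matrix(matrix(c(0L, 0L, 5L, 5L), 2))
  bc <- one_vs_rest_counts(cm, 0)
  expect_warning(p <- precision(bc), "zero denominator")
  expect_equal(p, 0)
  bc2 <- one_vs_rest_counts(as_confusion_matrix(matrix(c(0L, 0L, 0L, 10L), 2)), 0)
  expect_warning(r <- recall(bc2), "zero denominator")
  expect_equal(r, 0)
})

test_that("multiclass log-loss matches closed forms and validates rows", {
  expect_equal(multiclass_log_loss(c(0, 1, 2), matrix(1 / 3, 3, 3)), log(3))
  expect_equal(multiclass_log_loss(0, matrix(c(0.5, 0.3, 0.2), 1)), -log(0.5))
  onehot <- diag(3)
  expect_lte(multiclass_log_loss(0:2, onehot), 3.5e-15)
  expect_error(multiclass_log_loss(c(0, 1), matrix(c(0.5, 0.5, 0.4, 0.4), 2)),
               "sum to 1")
  # binary case reduces to binary cross-entropy
  p1 <- c(0.9, 0.2, 0.7)
  y <- c(1, 0, 1)
  expect_equal(multiclass_log_loss(y, cbind(1 - p1, p1)),
               -mean(y * log(p1) + (1 - y) * log(1 - p1)))
})

test_that("rank-based AUC matches hand cases, handles ties, survives transforms", {
  y <- c(1, 1, 0, 0)
  scores <- cbind(1 - c(0.9, 0.4, 0.6, 0.1), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(ovr_auc(y, scores)$per_class[2], 0.75)
  sep <- cbind(1 - c(0.9, 0.8, 0.2, 0.1), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(ovr_auc(y, sep)$per_class[2], 1)
  ties <- cbind(rep(0.5, 4), rep(0.5, 4))
  expect_equal(ovr_auc(y, ties)$per_class[2], 0.5)
  # invariance under strictly monotone transforms of the scores
  set.seed(5)
  s <- runif(30); yy <- rbinom(30, 1, 0.5)
  a1 <- ovr_auc(yy, cbind(1 - s, s))$per_class[2]
  a2 <- osteovote:::rank_auc(exp(3 * s), yy == 1)
  expect_equal(a1, a2)
  # independent oracle: pROC on random scores
  for (i in 1:10) {
    s <- runif(40); yy <- rbinom(40, 1, 0.4)
    if (length(unique(yy)) < 2) next
    expect_equal(osteovote:::rank_auc(s, yy == 1),
                 as.numeric(pROC::auc(pROC::roc(yy, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("degenerate AUC classes are flagged and excluded from the macro mean", {
  y <- c(0, 0, 1, 1)          # class 2 never appears
  p <- matrix(c(0.5, 0.3, 0.2,
                0.6, 0.2, 0.2,
                0.2, 0.6, 0.2,
                0.1, 0.7, 0.2), 4, 3, byrow = TRUE)
  expect_warning(auc <- ovr_auc(y, p), "undefined")
  expect_true(is.na(auc$per_class[3]))
  expect_equal(auc$macro, mean(auc$per_class[1:2]))
})

test_that("micro-precision equals accuracy for single-label multiclass", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    n <- sample(20:80, 1)
    y <- sample(0:(k - 1), n, replace = TRUE)
    p <- sample(0:(k - 1), n, replace = TRUE)
    cm <- confusion_matrix(y, p, k)
    tp <- sum(vapply(0:(k - 1), function(kk) one_vs_rest_counts(cm, kk)$tpos,
                     integer(1)))
    fp <- sum(vapply(0:(k - 1), function(kk) one_vs_rest_counts(cm, kk)$fpos,
                     integer(1)))
    fn <- sum(vapply(0:(k - 1), function(kk) one_vs_rest_counts(cm, kk)$fng,
                     integer(1)))
    expect_equal(tp / (tp + fp), accuracy(cm))  # micro-precision
    expect_equal(tp / (tp + fn), accuracy(cm))  # micro-recall
  }
})

test_that("metric reports assemble, round per table conventions, and serialize", {
  cm <- cnn_test_confusion()
  y <- rep(0:2, times = c(114, 55, 60))
  pred <- unlist(lapply(1:3, function(i) rep(0:2, times = unclass(cm)[i, ])))
  # confident probabilities consistent with the predictions
  k <- 3
  probs <- matrix(0.05, length(pred), k)
  probs[cbind(seq_along(pred), pred + 1L)] <- 0.9
  rep <- metric_report(y, probs = probs,
                       class_names = c("Non-Tumor", "Necrotic-Tumor", "Viable"))
  expect_equal(percent2(rep$accuracy), 95.63)
  expect_equal(percent2(rep$kappa), 93.09)
  tab <- class_wise_table(rep)
  expect_equal(tab$recall[2], 98)       # Necrotic-Tumor recall, integer percent
  expect_equal(tab$accuracy[3], 98.25)  # Viable class accuracy
  ov <- overall_table(rep)
  expect_equal(ov$accuracy, 95.63)
  expect_equal(ov$kappa, 93.09)
  expect_error(metric_report(integer(0), y_pred = integer(0)), "empty")
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, json, csv)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$accuracy, rep$accuracy, tolerance = 1e-12)
  expect_equal(back$kappa, rep$kappa, tolerance = 1e-12)
  expect_equal(utils::read.csv(csv)$accuracy, 95.63)
})

test_that("confusion matrices round-trip through their CSV format", {
  cm <- cnn_test_confusion()
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, path,
                      class_names = c("Non-Tumor", "Necrotic-Tumor", "Viable"))
  back <- read_confusion_csv(path)
  expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE)
  expect_equal(rownames(back), c("Non-Tumor", "Necrotic-Tumor", "Viable"))
})
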