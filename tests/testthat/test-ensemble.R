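pm <- function(rows, id = "L") probability_matrix(matrix(rows, ncol = 3,
                                                         byrow = TRUE), id)

test_that("vote tallies count argmax votes and respect learner-order invariance", {
  a <- pm(c(0.8, 0.1, 0.1), "A")       # votes class 0
  b <- pm(c(0.2, 0.5, 0.3), "B")       # votes class 1
  c3 <- pm(c(0.1, 0.6, 0.3), "C")      # votes class 1
  tal <- tally_votes(list(a, b, c3))
  expect_equal(unclass(tal)[1, ], c(1L, 2L, 0L), ignore_attr = TRUE)
  expect_equal(sum(tal[1, ]), 3)
  unan <- tally_votes(list(pm(c(0, 0.1, 0.9)), pm(c(0.2, 0.1, 0.7)),
                           pm(c(0.1, 0.2, 0.7))))
  expect_equal(unclass(unan)[1, ], c(0L, 0L, 3L), ignore_attr = TRUE)
  expect_equal(unclass(tally_votes(list(c3, a, b))), unclass(tal))
  expect_error(tally_votes(list(a)), "at least 2")
  expect_error(tally_votes(list(a, probability_matrix(matrix(c(0.5, 0.5), 1)))),
               "same dimensions")
})

test_that("majority wins outright; vote ties fall to summed probability", {
  a <- pm(c(0.8, 0.1, 0.1), "A")
  b <- pm(c(0.2, 0.5, 0.3), "B")
  c3 <- pm(c(0.1, 0.6, 0.3), "C")
  v <- adapted_majority_vote(list(a, b, c3))
  expect_equal(v$labels, 1L)
  expect_false(v$tie_flags)
  # three-way tie: summed probabilities (1.3, 0.9, 0.8) pick class 0
  t1 <- pm(c(0.8, 0.1, 0.1), "A")
  t2 <- pm(c(0.2, 0.5, 0.3), "B")
  t3 <- pm(c(0.3, 0.3, 0.4), "C")
  v <- adapted_majority_vote(list(t1, t2, t3))
  expect_equal(v$labels, 0L)
  expect_true(v$tie_flags)
  # identical learners reduce to the single learner's argmax
  same <- list(pm(c(0.2, 0.3, 0.5), "A"), pm(c(0.2, 0.3, 0.5), "B"))
  expect_equal(adapted_majority_vote(same)$labels, 2L)
})

test_that("a strict vote majority cannot be overturned by probabilities", {
  # two confident votes for class 1 beat one extreme probability for class 0
  a <- pm(c(0.05, 0.55, 0.40), "A")
  b <- pm(c(0.05, 0.50, 0.45), "B")
  c3 <- pm(c(0.99, 0.01, 0.00), "C")
  v <- adapted_majority_vote(list(a, b, c3))
  expect_equal(v$labels, 1L)
  expect_false(v$tie_flags)
})

test_that("residual exact probability ties fall back to the lowest class index", {
  a <- pm(c(0.6, 0.2, 0.2), "A")
  b <- pm(c(0.2, 0.6, 0.2), "B")
  v <- adapted_majority_vote(list(a, b))   # summed probs (0.8, 0.8, 0.4)
  expect_equal(v$labels, 0L)
  expect_true(v$tie_flags)
})

test_that("vote resolution agrees with a brute-force oracle on random instances", {
  set.seed(97)
  for (trial in 1:1000) {
    k <- sample(2:5, 1)
    L <- sample(2:6, 1)
    n <- sample(1:4, 1)
    first <- matrix(stats::rexp(n * k), n, k)
    first <- first / rowSums(first)
    preds <- lapply(seq_len(L), function(l) {
      # occasional exact duplicates of the first learner force vote and
      # probability ties
      m <- if (l > 1 && stats::runif(1) < 0.3) first else {
        mm <- matrix(stats::rexp(n * k), n, k)
        mm / rowSums(mm)
      }
      probability_matrix(m, paste0("L", l))
    })
    got <- adapted_majority_vote(preds)
    want <- reference_vote(preds)
    expect_identical(got$labels, want$labels)
    expect_identical(got$tie_flags, want$tie_flags)
  }
})

test_that("vote output is invariant under learner permutation", {
  set.seed(13)
  preds <- random_predictions(4, 25, 3)
  base <- adapted_majority_vote(preds)
  for (i in 1:5) {
    perm <- adapted_majority_vote(preds[sample(4)])
    expect_identical(perm$labels, base$labels)
  }
})

test_that("combination enumeration yields 2^k - k - 1 subsets in sorted order", {
  expect_length(enumerate_combinations(c("A", "B")), 1)
  c3 <- enumerate_combinations(c("C", "A", "B"))
  expect_length(c3, 4)
  expect_equal(c3, list(c("A", "B"), c("A", "C"), c("B", "C"),
                        c("A", "B", "C")))
  expect_length(enumerate_combinations(letters[1:5]), 26)
  expect_length(enumerate_combinations(letters[1:6]), 2^6 - 6 - 1)
  expect_error(enumerate_combinations("A"), "at least 2")
})

test_that("brute-force search finds the constructed best pair", {
  y <- rep(0:2, each = 10)
  onehot <- function(lab, k = 3) {
    m <- matrix(1e-4, length(lab), k)
    m[cbind(seq_along(lab), lab + 1L)] <- 1 - (k - 1) * 1e-4
    m
  }
  A <- probability_matrix(onehot(y), "A")
  B <- probability_matrix(onehot(y), "B")
  C <- probability_matrix(onehot((y + 1L) %% 3L), "C")   # adversarial
  # combinations dominated by C never predict some class, so the per-class
  # metrics legitimately warn about zero denominators
  w <- capture_warnings(res <- brute_force_search(list(A = A, B = B, C = C), y))
  expect_true(all(grepl("zero denominator", w)))
  expect_equal(res$selected, c("A", "B"))
  expect_equal(res$ranking$accuracy[1], 1)
  expect_equal(nrow(res$ranking), 4)
  # ranking equals an independent exhaustive re-evaluation
  indep <- vapply(enumerate_combinations(c("A", "B", "C")), function(members) {
    v <- reference_vote(list(A = A, B = B, C = C)[members])
    mean(v$labels == y)
  }, numeric(1))
  names(indep) <- vapply(enumerate_combinations(c("A", "B", "C")),
                         paste, character(1), collapse = "+")
  for (r in seq_len(nrow(res$ranking))) {
    expect_equal(res$ranking$accuracy[r],
                 unname(indep[res$ranking$combination[r]]))
  }
})

test_that("rank ties prefer fewer learners and the tie rule is deterministic", {
  y <- rep(0:1, each = 5)
  perfect <- function(id) {
    m <- matrix(0.01, 10, 2)
    m[cbind(1:10, y + 1L)] <- 0.99
    probability_matrix(m, id)
  }
  res <- brute_force_search(list(A = perfect("A"), B = perfect("B"),
                                 C = perfect("C")), y)
  expect_true(all(res$ranking$accuracy == 1))
  expect_equal(res$ranking$size[1], 2)
  expect_equal(res$selected, c("A", "B"))   # lexicographic among size-2 ties
})

test_that("ensembling conditionally independent learners beats their mean accuracy", {
  set.seed(2024)
  y <- sample(0:2, 2000, replace = TRUE)
  preds <- generate_prediction_matrices(5, y, 3, rep(0.8, 5),
                                        seed = 2024)
  single <- vapply(preds, function(p)
    mean(max.col(p, ties.method = "first") - 1L == y), numeric(1))
  ens <- mean(adapted_majority_vote(preds)$labels == y)
  se <- sqrt(0.8 * 0.2 / length(y))
  expect_gte(ens, mean(single) - 3 * se)
  # with 5 independent learners at 0.8 the ensemble should in fact be better
  expect_gt(ens, mean(single))
})

test_that("search results and probability matrices round-trip their CSV formats", {
  set.seed(3)
  y <- sample(0:2, 40, replace = TRUE)
  preds <- generate_prediction_matrices(3, y, 3, c(0.9, 0.8, 0.7), seed = 4)
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_probability_csv(preds, ppath)
  back <- read_probability_csv(ppath)
  expect_equal(names(back), names(preds))
  expect_equal(unclass(back[[2]]), unclass(preds[[2]]), tolerance = 1e-12,
               ignore_attr = TRUE)
  res <- brute_force_search(preds, y)
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_search_results(res, jpath, cpath)
  jback <- jsonlite::fromJSON(jpath)
  expect_equal(jback$selected, res$selected)
  cback <- utils::read.csv(cpath)
  expect_equal(nrow(cback), 4)
  expect_equal(cback$accuracy, percent2(res$ranking$accuracy))
})
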