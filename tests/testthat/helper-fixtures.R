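# Shared fixtures for the suite. Everything is generated in code at test
# time; nothing is read from disk.

# The published confusion matrix of the compact CNN on the balanced test
# split (rows = true Non-Tumor / Necrotic-Tumor / Viable-Tumor).
cnn_test_confusion <- function() {
  as_confusion_matrix(matrix(
    c(108, 5, 1,
      1, 54, 0,
      0, 3, 57), nrow = 3, byrow = TRUE))
}

# The voting ensemble's per-class correct counts on the same test split:
# 110/114 non-tumor, 51/55 necrotic, 60/60 viable. Off-diagonal placement is
# unreported; errors are placed arbitrarily (diagonal + row totals determine
# accuracy and recall, which is all that is asserted).
enl_cne_confusion <- function() {
  as_confusion_matrix(matrix(
    c(110, 3, 1,
      2, 51, 2,
      0, 0, 60), nrow = 3, byrow = TRUE))
}

# Small flat-colour records for pipeline bookkeeping tests (split, balance,
# manifest round-trips) where pixel content is irrelevant.
flat_records <- function(counts, size = 8L, seed = 1L) {
  set.seed(seed)
  recs <- list()
  for (k in seq_along(counts)) {
    for (i in seq_len(counts[k])) {
      px <- array(as.integer(sample(0:255, size * size * 3, replace = TRUE)),
                  dim = c(size, size, 3L))
      recs[[length(recs) + 1L]] <-
        image_record(sprintf("c%d_%03d", k - 1L, i), px, k - 1L)
    }
  }
  recs
}

# Independent brute-force reference for the adapted majority vote: count
# argmax votes by explicit loops, then resolve ties by summed probability,
# then by lowest index.
reference_vote <- function(predictions) {
  n <- nrow(predictions[[1]])
  k <- ncol(predictions[[1]])
  labels <- integer(n)
  flags <- logical(n)
  for (i in seq_len(n)) {
    counts <- rep(0L, k)
    psum <- rep(0, k)
    for (p in predictions) {
      row <- as.numeric(p[i, ])
      v <- which(row == max(row))[1]
      counts[v] <- counts[v] + 1L
      psum <- psum + row
    }
    tied <- which(counts == max(counts))
    if (length(tied) > 1L) {
      flags[i] <- TRUE
      best <- tied[psum[tied] == max(psum[tied])]
      labels[i] <- min(best) - 1L
    } else {
      labels[i] <- tied - 1L
    }
  }
  list(labels = labels, tie_flags = flags)
}

# Random probability matrices (no structure) for property tests.
random_predictions <- function(n_learners, n, k) {
  lapply(seq_len(n_learners), function(l) {
    m <- matrix(stats::rexp(n * k), n, k)
    probability_matrix(m / rowSums(m), learner_id = paste0("L", l))
  })
}
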