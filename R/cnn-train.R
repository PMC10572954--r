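#' Training configuration
#'
#' Optimizer and schedule settings shared by all networks in the pipeline.
#' Defaults follow the study protocol: Adam, learning rate 0.001, batch size
#' 16, sparse categorical cross-entropy. The full protocol trains for 200
#' epochs; desk-scale runs use far fewer.
#'
#' @param optimizer_name Only `"adam"` is implemented.
#' @param learning_rate Positive step size.
#' @param batch_size Positive mini-batch size.
#' @param epochs Non-negative epoch count (0 returns an untrained learner
#'   that still emits valid probability rows).
#' @param loss_name Only `"sparse_categorical_crossentropy"` is implemented.
#' @return An object of class `training_config`.
#' @export
training_config <- function(optimizer_name = "adam", learning_rate = 0.001,
                            batch_size = 16L, epochs = 200L,
                            loss_name = "sparse_categorical_crossentropy") {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0)
  optimizer_name <- match.arg(optimizer_name, "adam")
  loss_name <- match.arg(loss_name, "sparse_categorical_crossentropy")
  structure(
    list(optimizer_name = optimizer_name, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         loss_name = loss_name),
    class = "training_config"
  )
}

# ---- layer state construction -----------------------------------------------

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# im2col index matrix: rows = output positions (column-major over H x W),
# cols = patch elements (di, dj, channel); values are linear indices into the
# zero-padded input array of dim (H + 2p, W + 2p, C).
conv_index <- function(h, w, c_in, f) {
  p <- (f - 1L) %/% 2L
  hp <- h + 2L * p
  pos_i <- rep(seq_len(h), times = w)
  pos_j <- rep(seq_len(w), each = h)
  off <- expand.grid(di = 0:(f - 1L), dj = 0:(f - 1L), ch = 0:(c_in - 1L))
  idx <- matrix(0L, h * w, f * f * c_in)
  for (k in seq_len(nrow(off))) {
    idx[, k] <- (pos_i + off$di[k]) +
      (pos_j + off$dj[k] - 1L) * hp +
      off$ch[k] * hp * (w + 2L * p)
  }
  idx
}

# Per-(di,dj) linear index arrays used by max-pool argmax tracking.
pool_index <- function(h, w, c_in, f) {
  ho <- h %/% f; wo <- w %/% f
  out <- vector("list", f * f)
  k <- 0L
  for (dj in seq_len(f)) {
    for (di in seq_len(f)) {
      k <- k + 1L
      rows <- seq(di, ho * f, by = f)
      cols <- seq(dj, wo * f, by = f)
      lin <- outer(rows, (cols - 1L) * h, "+")          # ho x wo within a plane
      out[[k]] <- as.vector(outer(as.vector(lin), (seq_len(c_in) - 1L) * h * w, "+"))
    }
  }
  list(idx = out, ho = ho, wo = wo)
}

# Instantiate weights and cached geometry for every layer of a spec.
build_model <- function(spec, seed = 1L) {
  shapes <- spec$output_shapes
  with_local_seed(seed, {
    layers <- vector("list", length(spec$layers))
    in_shape <- spec$input_shape
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      st <- list(kind = ly$kind, activation = ly$activation)
      if (ly$kind == "conv2d") {
        if (ly$filter_size %% 2L == 0L) {
          stop("the training engine supports odd filter sizes only", call. = FALSE)
        }
        f <- ly$filter_size; c_in <- in_shape[3]; c_out <- ly$depth_or_units
        st$f <- f; st$c_in <- c_in; st$c_out <- c_out
        st$h <- in_shape[1]; st$w <- in_shape[2]
        st$pad <- (f - 1L) %/% 2L
        st$idx <- conv_index(st$h, st$w, c_in, f)
        st$W <- matrix(glorot_uniform(f * f * c_in, f * f * c_out,
                                      f * f * c_in * c_out),
                       f * f * c_in, c_out)
        st$b <- numeric(c_out)
      } else if (ly$kind == "dense") {
        n_in <- in_shape[1]; n_out <- ly$depth_or_units
        st$W <- matrix(glorot_uniform(n_in, n_out, n_in * n_out), n_in, n_out)
        st$b <- numeric(n_out)
      } else if (ly$kind == "batch_norm") {
        c_in <- in_shape[length(in_shape)]
        st$gamma <- rep(1, c_in); st$beta <- numeric(c_in)
        st$moving_mean <- numeric(c_in); st$moving_var <- rep(1, c_in)
        # moving stats are seeded from the first training batch (see
        # forward_pass), then tracked with momentum 0.9 so short desk-scale
        # runs reach usable inference statistics
        st$momentum <- 0.9; st$eps <- 1e-3; st$initialized <- FALSE
        st$spatial <- length(in_shape) == 3L
      } else if (ly$kind == "max_pool") {
        st$pool <- pool_index(in_shape[1], in_shape[2], in_shape[3], ly$filter_size)
        st$f <- ly$filter_size
        st$in_shape <- in_shape
      } else if (ly$kind == "dropout") {
        st$rate <- ly$dropout_rate
      } else if (ly$kind == "flatten") {
        st$in_shape <- in_shape
      }
      st$out_shape <- shapes[[i]]
      layers[[i]] <- st
      in_shape <- shapes[[i]]
    }
    list(layers = layers, input_shape = spec$input_shape)
  })
}

# Total length of every instantiated weight tensor (including batch-norm
# moving statistics) — the brute-force counterpart of count_parameters().
model_parameter_count <- function(model) {
  sum(vapply(model$layers, function(st) {
    length(st[["W"]]) + length(st[["b"]]) + length(st[["gamma"]]) +
      length(st[["beta"]]) + length(st[["moving_mean"]]) +
      length(st[["moving_var"]])
  }, numeric(1)))
}

# ---- forward / backward -----------------------------------------------------

# x: array (H, W, C, B) for spatial input. Returns list(logits = K x B
# matrix, caches) where caches hold what backward needs. Training mode uses
# batch statistics and dropout; inference uses moving statistics.
forward_pass <- function(model, x, train = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    st <- model$layers[[i]]
    cache <- list()
    if (st$kind == "batch_norm") {
      cdim <- length(st$gamma)
      if (train) {
        d <- dim(x)
        n_per_c <- prod(d) / cdim / if (st$spatial) 1 else 1
        # per-channel mean/var over all non-channel dims
        xm <- if (st$spatial) matrix(aperm(x, c(1, 2, 4, 3)), ncol = cdim)
              else t(x)
        mu <- colMeans(xm)
        va <- colMeans(xm^2) - mu^2
        if (!st$initialized) {
          st$moving_mean <- mu; st$moving_var <- va; st$initialized <- TRUE
        } else {
          st$moving_mean <- st$momentum * st$moving_mean + (1 - st$momentum) * mu
          st$moving_var  <- st$momentum * st$moving_var  + (1 - st$momentum) * va
        }
        model$layers[[i]] <- st
      } else {
        mu <- st$moving_mean; va <- st$moving_var
      }
      inv <- 1 / sqrt(va + st$eps)
      if (st$spatial) {
        d <- dim(x)
        hw <- d[1] * d[2]
        mu_e <- rep(mu, each = hw); inv_e <- rep(inv, each = hw)
        g_e <- rep(st$gamma, each = hw); b_e <- rep(st$beta, each = hw)
        xhat <- (x - mu_e) * inv_e      # recycles over batch dim
        x <- g_e * xhat + b_e
      } else {
        xhat <- (x - mu) * inv
        x <- st$gamma * xhat + st$beta
      }
      cache <- list(xhat = xhat, inv = inv)
    } else if (st$kind == "conv2d") {
      d <- dim(x); b_n <- d[4]
      hp <- st$h + 2L * st$pad; wp <- st$w + 2L * st$pad
      out <- array(0, c(st$h, st$w, st$c_out, b_n))
      patches_list <- vector("list", b_n)
      for (bb in seq_len(b_n)) {
        padded <- array(0, c(hp, wp, st$c_in))
        padded[st$pad + seq_len(st$h), st$pad + seq_len(st$w), ] <- x[, , , bb]
        patches <- matrix(padded[st$idx], nrow(st$idx), ncol(st$idx))
        o <- patches %*% st$W
        o <- sweep(o, 2L, st$b, "+")
        out[, , , bb] <- o
        patches_list[[bb]] <- patches
      }
      if (st$activation == "relu") {
        mask <- out > 0
        out <- out * mask
        cache$mask <- mask
      }
      cache$patches <- patches_list
      x <- out
    } else if (st$kind == "max_pool") {
      d <- dim(x); b_n <- d[4]
      ho <- st$pool$ho; wo <- st$pool$wo; c_in <- d[3]
      out <- array(0, c(ho, wo, c_in, b_n))
      src <- array(0L, c(ho, wo, c_in, b_n))
      for (bb in seq_len(b_n)) {
        plane <- x[, , , bb]
        best <- plane[st$pool$idx[[1]]]
        best_src <- st$pool$idx[[1]]
        for (k in seq_along(st$pool$idx)[-1]) {
          cand <- plane[st$pool$idx[[k]]]
          take <- cand > best
          best[take] <- cand[take]
          best_src[take] <- st$pool$idx[[k]][take]
        }
        out[, , , bb] <- best
        src[, , , bb] <- best_src
      }
      cache$src <- src
      cache$in_dim <- d
      x <- out
    } else if (st$kind == "flatten") {
      d <- dim(x)
      cache$in_dim <- d
      x <- matrix(x, prod(d[1:3]), d[4])
    } else if (st$kind == "dense") {
      cache$x_in <- x
      x <- crossprod(st$W, x) + st$b
      if (st$activation == "relu") {
        mask <- x > 0
        x <- x * mask
        cache$mask <- mask
      }
      # softmax (if any) is applied by the caller / loss
    } else if (st$kind == "dropout") {
      if (train && st$rate > 0) {
        mask <- (stats::runif(length(x)) >= st$rate) / (1 - st$rate)
        dim(mask) <- dim(x)
        x <- x * mask
        cache$mask <- mask
      }
    }
    caches[[i]] <- cache
  }
  list(out = x, caches = caches, model = model)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Backward pass from d_logits (K x B); returns per-layer gradient list.
backward_pass <- function(model, caches, grad) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    st <- model$layers[[i]]
    cache <- caches[[i]]
    g <- list()
    if (st$kind == "dense") {
      if (!is.null(cache$mask)) grad <- grad * cache$mask
      g$W <- cache$x_in %*% t(grad)
      g$b <- rowSums(grad)
      grad <- st$W %*% grad
    } else if (st$kind == "dropout") {
      if (!is.null(cache$mask)) grad <- grad * cache$mask
    } else if (st$kind == "flatten") {
      dim(grad) <- cache$in_dim
    } else if (st$kind == "max_pool") {
      d <- cache$in_dim
      b_n <- d[4]
      dx <- array(0, d)
      plane_len <- prod(d[1:3])
      for (bb in seq_len(b_n)) {
        v <- numeric(plane_len)
        v[cache$src[, , , bb]] <- grad[, , , bb]
        dx[, , , bb] <- v
      }
      grad <- dx
    } else if (st$kind == "conv2d") {
      if (!is.null(cache$mask)) grad <- grad * cache$mask
      d <- dim(grad); b_n <- d[4]
      hw <- st$h * st$w
      gW <- matrix(0, nrow(st$W), ncol(st$W))
      gb <- numeric(st$c_out)
      hp <- st$h + 2L * st$pad; wp <- st$w + 2L * st$pad
      dx <- array(0, c(st$h, st$w, st$c_in, b_n))
      idxv <- as.vector(st$idx)
      for (bb in seq_len(b_n)) {
        dout <- matrix(grad[, , , bb], hw, st$c_out)
        gW <- gW + crossprod(cache$patches[[bb]], dout)
        gb <- gb + colSums(dout)
        dpatch <- dout %*% t(st$W)
        acc <- rowsum(as.vector(dpatch), group = idxv)
        dpad <- numeric(hp * wp * st$c_in)
        dpad[as.integer(rownames(acc))] <- acc
        dim(dpad) <- c(hp, wp, st$c_in)
        dx[, , , bb] <- dpad[st$pad + seq_len(st$h), st$pad + seq_len(st$w), ]
      }
      g$W <- gW; g$b <- gb
      grad <- dx
    } else if (st$kind == "batch_norm") {
      cdim <- length(st$gamma)
      if (st$spatial) {
        hw <- prod(dim(grad)[1:2])
        gm <- matrix(aperm(grad, c(1, 2, 4, 3)), ncol = cdim)
        xh <- matrix(aperm(cache$xhat, c(1, 2, 4, 3)), ncol = cdim)
        g$gamma <- colSums(gm * xh)
        g$beta <- colSums(gm)
        m_d <- colMeans(gm)
        m_dx <- colMeans(gm * xh)
        scale <- st$gamma * cache$inv
        s_e <- rep(scale, each = hw)
        md_e <- rep(m_d, each = hw)
        mdx_e <- rep(m_dx, each = hw)
        grad <- s_e * (grad - md_e - cache$xhat * mdx_e)
      } else {
        g$gamma <- rowSums(grad * cache$xhat)
        g$beta <- rowSums(grad)
        m_d <- rowMeans(grad)
        m_dx <- rowMeans(grad * cache$xhat)
        grad <- (st$gamma * cache$inv) * (grad - m_d - cache$xhat * m_dx)
      }
    }
    grads[[i]] <- g
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(st) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(st))
    stt <- list()
    for (p in nm) stt[[p]] <- list(m = st[[p]] * 0, v = st[[p]] * 0)
    stt
  })
}

adam_step <- function(model, grads, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  corr <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (i in seq_along(model$layers)) {
    for (p in names(opt$state[[i]])) {
      gp <- grads[[i]][[p]]
      if (is.null(gp)) next
      s <- opt$state[[i]][[p]]
      s$m <- beta1 * s$m + (1 - beta1) * gp
      s$v <- beta2 * s$v + (1 - beta2) * gp^2
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] -
        corr * s$m / (sqrt(s$v) + eps)
      opt$state[[i]][[p]] <- s
    }
  }
  list(model = model, opt = opt)
}

# ---- training ---------------------------------------------------------------

batch_to_engine <- function(x, sel) {
  aperm(x[sel, , , , drop = FALSE], c(2, 3, 4, 1))
}

model_predict_proba <- function(model, x, batch_size = 64L) {
  n <- dim(x)[1]
  k <- model$layers[[length(model$layers)]]$out_shape[1]
  out <- matrix(0, n, k)
  i <- 1L
  while (i <= n) {
    sel <- i:min(i + batch_size - 1L, n)
    fw <- forward_pass(model, batch_to_engine(x, sel), train = FALSE)
    out[sel, ] <- t(softmax_cols(fw$out))
    i <- i + batch_size
  }
  out
}

#' Train a CNN base learner
#'
#' Mini-batch training of an [architecture_spec()] with the Adam optimizer
#' and sparse categorical cross-entropy, implemented in vectorized R
#' (im2col convolutions, batch normalization with moving statistics, max
#' pooling, inverted dropout). Per-epoch training and validation loss and
#' accuracy are logged.
#'
#' @param spec An [architecture_spec()].
#' @param config A [training_config()].
#' @param x_train Numeric array `(n, H, W, C)` preprocessed to `[0, 1]` and
#'   matching `spec$input_shape`.
#' @param y_train Integer labels in `[0, K)`.
#' @param x_val,y_val Optional validation data in the same format.
#' @param augment Optional [augment_config()]; when supplied, each training
#'   image is freshly transformed every epoch (generator-style augmentation).
#' @param seed Integer seed covering initialization, shuffling, dropout and
#'   augmentation.
#' @param learner_id Identifier carried into the learner's probability
#'   matrices.
#' @param mode Training mode tag: `"complete_training"` for networks trained
#'   from scratch; `"frozen"` / `"fine_tuned"` tag externally supplied
#'   transfer-learning learners.
#' @return An object of class `base_learner` with fields `learner_id`,
#'   `mode`, `spec`, `model`, `config`, `history` (data frame with epoch,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train_learner <- function(spec, config, x_train, y_train,
                          x_val = NULL, y_val = NULL, augment = NULL,
                          seed = 1L, learner_id = "CNN",
                          mode = "complete_training") {
  k <- spec$output_shapes[[length(spec$layers)]][1]
  y_train <- as.integer(y_train)
  if (any(y_train < 0 | y_train >= k)) {
    stop("labels must lie in [0, K)", call. = FALSE)
  }
  d <- dim(x_train)
  if (length(d) != 4L || !all(d[2:4] == spec$input_shape)) {
    stop("`x_train` must be (n, ", paste(spec$input_shape, collapse = ", "),
         ")", call. = FALSE)
  }
  if (d[1] != length(y_train)) stop("x/y length mismatch", call. = FALSE)
  model <- build_model(spec, seed = seed)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  if (config$epochs > 0) {
    with_local_seed(seed + 1L, {
      opt <- list(state = adam_init(model))
      t_step <- 0L
      n <- d[1]
      for (epoch in seq_len(config$epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0; ep_correct <- 0L
        i <- 1L
        while (i <= n) {
          sel <- ord[i:min(i + config$batch_size - 1L, n)]
          xb <- batch_to_engine(x_train, sel)
          if (!is.null(augment)) {
            for (bb in seq_along(sel)) {
              xb[, , , bb] <- augment_pixels(xb[, , , bb, drop = FALSE][, , , 1],
                                             augment, max_val = 1)
            }
          }
          yb <- y_train[sel]
          fw <- forward_pass(model, xb, train = TRUE)
          model <- fw$model            # updated moving statistics
          p <- softmax_cols(fw$out)
          picked <- p[cbind(yb + 1L, seq_along(sel))]
          ep_loss <- ep_loss - sum(log(pmax(picked, 1e-12)))
          ep_correct <- ep_correct +
            sum(max.col(t(p), ties.method = "first") == yb + 1L)
          grad <- p
          grad[cbind(yb + 1L, seq_along(sel))] <-
            grad[cbind(yb + 1L, seq_along(sel))] - 1
          grad <- grad / length(sel)
          grads <- backward_pass(model, fw$caches, grad)
          t_step <- t_step + 1L
          upd <- adam_step(model, grads, opt, config$learning_rate, t_step)
          model <- upd$model; opt <- upd$opt
          i <- i + config$batch_size
        }
        val_loss <- NA_real_; val_acc <- NA_real_
        if (!is.null(x_val) && dim(x_val)[1] > 0) {
          pv <- model_predict_proba(model, x_val)
          yv <- as.integer(y_val)
          val_loss <- -mean(log(pmax(pv[cbind(seq_along(yv), yv + 1L)], 1e-12)))
          val_acc <- mean(max.col(pv, ties.method = "first") == yv + 1L)
        }
        history[nrow(history) + 1L, ] <-
          list(epoch, ep_loss / n, ep_correct / n, val_loss, val_acc)
      }
    })
  }
  structure(
    list(learner_id = learner_id, mode = mode, spec = spec, model = model,
         config = config, history = history),
    class = "base_learner"
  )
}

#' Predict class probabilities
#'
#' @param learner A `base_learner` from [train_learner()].
#' @param x Numeric array `(n, H, W, C)` preprocessed like the training data.
#' @return A [probability_matrix()] (`n` x `K`, rows summing to 1).
#' @export
predict_proba <- function(learner, x) {
  probability_matrix(model_predict_proba(learner$model, x),
                     learner_id = learner$learner_id)
}

#' @export
print.base_learner <- function(x, ...) {
  cat(sprintf("<base_learner %s (%s): %s params, %d epochs trained>\n",
              x$learner_id, x$mode,
              format(x$spec$total_params, big.mark = ","),
              nrow(x$history)))
  invisible(x)
}

#' Actual parameter count of an instantiated learner
#'
#' Sums the lengths of every weight tensor held by the training engine
#' (convolution and dense weights and biases, batch-norm scale/shift and
#' moving statistics). Serves as a brute-force check of the closed-form
#' [count_parameters()] accounting.
#'
#' @param learner A `base_learner`.
#' @return Integer total.
#' @export
learner_parameter_count <- function(learner) {
  model_parameter_count(learner$model)
}

#' Write a training history CSV
#'
#' @param learner A `base_learner`.
#' @param path Output path; columns epoch, train_loss, train_acc, val_loss,
#'   val_acc.
#' @return Invisibly, the history data frame.
#' @export
write_history_csv <- function(learner, path) {
  utils::write.csv(learner$history, path, row.names = FALSE)
  invisible(learner$history)
}
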