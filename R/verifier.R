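## Feedforward speaker verifier: input 60-d LFCC, hidden blocks of
## affine -> batch normalization -> ReLU, output affine -> softmax over
## (target, non_target). Trained with mini-batch backpropagation,
## cross-entropy loss and Adam. Written in plain matrix algebra so the
## analytic gradients can be checked against finite differences.

CLASS_ORDER <- c("target", "non_target")
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

init_network <- function(input_dim, hidden, n_classes = 2L) {
  widths <- c(input_dim, hidden)
  layers <- lapply(seq_along(hidden), function(l) {
    d_in <- widths[l]; d_out <- widths[l + 1]
    list(W = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
         b = numeric(d_out),
         gamma = rep(1, d_out), beta = numeric(d_out),
         run_mean = numeric(d_out), run_var = rep(1, d_out))
  })
  d_last <- widths[length(widths)]
  out <- list(W = matrix(stats::rnorm(d_last * n_classes, 0, sqrt(2 / d_last)),
                         d_last, n_classes),
              b = numeric(n_classes))
  list(hidden = layers, out = out)
}

softmax_rows <- function(z) {
  mx <- z[, 1]
  for (j in 2:ncol(z)) mx <- pmax(mx, z[, j])
  e <- exp(z - mx)
  e / rowSums(e)
}

## Row-recycled column-vector arithmetic (fast replacements for sweep()
## with MARGIN = 2 in the training hot loop; matrices are column-major, so
## rep(v, each = n) aligns v[j] with column j).
add_row <- function(m, v) m + rep(v, each = nrow(m))
sub_row <- function(m, v) m - rep(v, each = nrow(m))
mul_row <- function(m, v) m * rep(v, each = nrow(m))

## Forward pass. In training mode batch statistics are used (and returned in
## the cache for the backward pass); in inference mode the frozen running
## statistics are used and the network state never changes.
forward_pass <- function(net, x, training = FALSE) {
  caches <- list()
  a <- x
  for (l in seq_along(net$hidden)) {
    ly <- net$hidden[[l]]
    z <- add_row(a %*% ly$W, ly$b)
    if (training) {
      mu <- colMeans(z)
      va <- colMeans(z^2) - mu^2
    } else {
      mu <- ly$run_mean
      va <- ly$run_var
    }
    inv_sd <- 1 / sqrt(va + BN_EPS)
    zhat <- mul_row(sub_row(z, mu), inv_sd)
    h <- add_row(mul_row(zhat, ly$gamma), ly$beta)
    a_next <- h
    a_next[a_next < 0] <- 0
    caches[[l]] <- list(a_in = a, zhat = zhat, inv_sd = inv_sd, h = h,
                        mu = mu, va = va)
    a <- a_next
  }
  scores <- add_row(a %*% net$out$W, net$out$b)
  probs <- softmax_rows(scores)
  list(probs = probs, a_last = a, caches = caches)
}

## Backward pass for mean cross-entropy over the batch. `y_onehot` is
## n x 2. Returns gradients with the same shape as the network parameters.
backward_pass <- function(net, fwd, y_onehot) {
  n <- nrow(y_onehot)
  grads <- list(hidden = vector("list", length(net$hidden)), out = NULL)
  d_scores <- (fwd$probs - y_onehot) / n
  grads$out <- list(W = crossprod(fwd$a_last, d_scores), b = colSums(d_scores))
  d_a <- tcrossprod(d_scores, net$out$W)
  for (l in rev(seq_along(net$hidden))) {
    ly <- net$hidden[[l]]
    ca <- fwd$caches[[l]]
    d_h <- d_a * (ca$h > 0)
    d_gamma <- colSums(d_h * ca$zhat)
    d_beta <- colSums(d_h)
    d_zhat <- mul_row(d_h, ly$gamma)
    m <- nrow(d_h)
    ## standard batch-norm backward, vectorized per feature column
    sum_dz <- colSums(d_zhat)
    sum_dz_zhat <- colSums(d_zhat * ca$zhat)
    d_z <- sub_row(d_zhat, sum_dz / m) - mul_row(ca$zhat, sum_dz_zhat / m)
    d_z <- mul_row(d_z, ca$inv_sd)
    grads$hidden[[l]] <- list(W = crossprod(ca$a_in, d_z), b = colSums(d_z),
                              gamma = d_gamma, beta = d_beta)
    d_a <- tcrossprod(d_z, ly$W)
  }
  grads
}

cross_entropy <- function(probs, y_onehot) {
  -mean(log(pmax(rowSums(probs * y_onehot), 1e-12)))
}

## Flat views of parameters/gradients (used by Adam and the gradient check).
param_names <- function(net) {
  c(unlist(lapply(seq_along(net$hidden), function(l)
    paste0("h", l, ".", c("W", "b", "gamma", "beta")))),
    "out.W", "out.b")
}

get_param <- function(net, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "out") net$out[[parts[2]]]
  else net$hidden[[as.integer(sub("h", "", parts[1]))]][[parts[2]]]
}

set_param <- function(net, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "out") net$out[[parts[2]]] <- value
  else net$hidden[[as.integer(sub("h", "", parts[1]))]][[parts[2]]] <- value
  net
}

get_grad <- function(grads, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "out") grads$out[[parts[2]]]
  else grads$hidden[[as.integer(sub("h", "", parts[1]))]][[parts[2]]]
}

labels_to_onehot <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_ORDER)
  if (length(bad)) {
    stop_invalid("labels must be 'target' or 'non_target' (got: ",
                 paste(bad, collapse = ", "), ")")
  }
  cbind(target = as.numeric(labels == "target"),
        non_target = as.numeric(labels == "non_target"))
}

#' Fit the speaker verification network
#'
#' Trains a feedforward network (hidden blocks of affine, batch
#' normalization and ReLU; softmax output over target/non-target) on LFCC
#' feature rows by mini-batch backpropagation with cross-entropy loss and
#' Adam. The seed controls both the weight initialization and the
#' mini-batch shuffling, and the fit is a pure function of its arguments.
#'
#' @param x numeric matrix of features, 60 columns, one row per voice
#'   sample.
#' @param y labels, `"target"` or `"non_target"`, one per row; both classes
#'   must be present.
#' @param hidden widths of the hidden blocks.
#' @param epochs full passes over the training data.
#' @param batch_size mini-batch size (trailing batches of fewer than 2 rows
#'   are skipped, since batch normalization needs a batch variance).
#' @param learning_rate Adam step size; `beta1`, `beta2`, `adam_eps` are the
#'   usual Adam moment decays and stabilizer.
#' @param beta1,beta2,adam_eps Adam hyperparameters.
#' @param seed integer seed.
#' @return an object of class `voice_verifier` with `predict`, `print`,
#'   `summary` and `coef` methods. `$loss_history` holds the mean training
#'   loss per epoch; `$final_loss` its last entry.
#' @export
voice_verifier <- function(x, y, hidden = c(128L, 64L, 32L), epochs = 300L,
                           batch_size = 32L, learning_rate = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                           seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) != N_BANDS) {
    stop_invalid("feature width must be ", N_BANDS, " (got ", ncol(x), ")")
  }
  if (nrow(x) != length(y)) stop_invalid("nrow(x) must equal length(y)")
  y_onehot <- labels_to_onehot(y)
  if (length(unique(as.character(y))) < 2) {
    stop_invalid("both classes must be present in the training labels")
  }
  if (!is_count(epochs) || epochs < 1) stop_invalid("'epochs' must be >= 1")
  if (!is_count(batch_size) || batch_size < 1) stop_invalid("'batch_size' must be >= 1")
  n <- nrow(x)
  net <- NULL
  loss_history <- numeric(epochs)
  with_seed(seed, {
    net <- init_network(ncol(x), as.integer(hidden))
    zero_like <- function(part, fields) lapply(part[fields], function(p) p * 0)
    hidden_fields <- c("W", "b", "gamma", "beta")
    adam <- list(
      hidden = lapply(net$hidden, zero_like, fields = hidden_fields),
      out = zero_like(net$out, c("W", "b")))
    m_state <- v_state <- adam
    t_step <- 0
    bc1 <- bc2 <- 1
    step_one <- function(param, grad, m, v) {
      m <- beta1 * m + (1 - beta1) * grad
      v <- beta2 * v + (1 - beta2) * grad^2
      list(param = param - learning_rate * (m / bc1) / (sqrt(v / bc2) + adam_eps),
           m = m, v = v)
    }
    batch_starts <- seq(1, n, by = batch_size)
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(n)
      batch_losses <- numeric(length(batch_starts))
      n_used <- 0L
      for (start in batch_starts) {
        idx <- perm[start:min(start + batch_size - 1, n)]
        if (length(idx) < 2) next
        xb <- x[idx, , drop = FALSE]
        yb <- y_onehot[idx, , drop = FALSE]
        fwd <- forward_pass(net, xb, training = TRUE)
        n_used <- n_used + 1L
        batch_losses[n_used] <- cross_entropy(fwd$probs, yb)
        grads <- backward_pass(net, fwd, yb)
        t_step <- t_step + 1
        bc1 <- 1 - beta1^t_step
        bc2 <- 1 - beta2^t_step
        for (l in seq_along(net$hidden)) {
          for (f in hidden_fields) {
            st <- step_one(net$hidden[[l]][[f]], grads$hidden[[l]][[f]],
                           m_state$hidden[[l]][[f]], v_state$hidden[[l]][[f]])
            net$hidden[[l]][[f]] <- st$param
            m_state$hidden[[l]][[f]] <- st$m
            v_state$hidden[[l]][[f]] <- st$v
          }
          ## update frozen inference statistics
          ca <- fwd$caches[[l]]
          net$hidden[[l]]$run_mean <- BN_MOMENTUM * net$hidden[[l]]$run_mean +
            (1 - BN_MOMENTUM) * ca$mu
          net$hidden[[l]]$run_var <- BN_MOMENTUM * net$hidden[[l]]$run_var +
            (1 - BN_MOMENTUM) * ca$va
        }
        for (f in c("W", "b")) {
          st <- step_one(net$out[[f]], grads$out[[f]],
                         m_state$out[[f]], v_state$out[[f]])
          net$out[[f]] <- st$param
          m_state$out[[f]] <- st$m
          v_state$out[[f]] <- st$v
        }
      }
      loss_history[epoch] <- mean(batch_losses[seq_len(n_used)])
    }
    net
  })
  structure(list(net = net, hidden = as.integer(hidden),
                 class_order = CLASS_ORDER,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 n_train = n, loss_history = loss_history,
                 final_loss = loss_history[epochs]),
            class = "voice_verifier")
}

#' Predict target/non-target probabilities
#'
#' Inference is side-effect-free: batch normalization uses the running
#' statistics frozen at training time, so predictions are a pure function
#' of the model and the input.
#'
#' @param object a fitted `voice_verifier`.
#' @param newdata feature matrix with 60 columns.
#' @param ... unused.
#' @return data.frame with columns `p_target` and `p_non_target`; each row
#'   sums to 1.
#' @export
predict.voice_verifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != N_BANDS) {
    stop_invalid("feature width must be ", N_BANDS, " (got ", ncol(newdata), ")")
  }
  probs <- forward_pass(object$net, newdata, training = FALSE)$probs
  data.frame(p_target = probs[, 1], p_non_target = probs[, 2])
}

#' @export
print.voice_verifier <- function(x, ...) {
  cat(sprintf("<voice_verifier: 60 -> %s -> 2 (softmax)>\n",
              paste(x$hidden, collapse = " -> ")))
  cat(sprintf("  trained %d epochs, batch %d, seed %d; final loss %.4f\n",
              x$epochs, x$batch_size, x$seed, x$final_loss))
  invisible(x)
}

#' @export
summary.voice_verifier <- function(object, ...) {
  n_par <- sum(vapply(param_names(object$net),
                      function(p) length(get_param(object$net, p)), numeric(1)))
  out <- list(hidden = object$hidden, n_parameters = n_par,
              epochs = object$epochs, batch_size = object$batch_size,
              seed = object$seed, n_train = object$n_train,
              final_loss = object$final_loss)
  class(out) <- "summary.voice_verifier"
  out
}

#' @export
print.summary.voice_verifier <- function(x, ...) {
  cat("Speaker verification network\n")
  cat(sprintf("  architecture : 60 -> %s -> 2\n", paste(x$hidden, collapse = " -> ")))
  cat(sprintf("  parameters   : %d\n", x$n_parameters))
  cat(sprintf("  training     : %d epochs, batch %d, %d samples, seed %d\n",
              x$epochs, x$batch_size, x$n_train, x$seed))
  cat(sprintf("  final loss   : %.5f\n", x$final_loss))
  invisible(x)
}

#' @export
coef.voice_verifier <- function(object, ...) {
  nm <- param_names(object$net)
  out <- lapply(nm, function(p) get_param(object$net, p))
  names(out) <- nm
  out
}

#' Train an ensemble of verification models
#'
#' Fits `n_models` networks on the same data with distinct seeds derived
#' from `seed` (different weight initializations and mini-batch orders);
#' downstream accuracy is averaged over the ensemble.
#'
#' @inheritParams voice_verifier
#' @param n_models ensemble size.
#' @param ... further arguments passed to [voice_verifier()].
#' @return list of `voice_verifier` objects, class `verifier_ensemble`.
#' @export
train_ensemble <- function(x, y, n_models = 5L, seed = 1L, ...) {
  if (!is_count(n_models) || n_models < 1) {
    stop_invalid("'n_models' must be a positive integer")
  }
  models <- lapply(seq_len(n_models), function(i) {
    voice_verifier(x, y, seed = derive_seed(seed, "ensemble", i), ...)
  })
  structure(models, class = "verifier_ensemble")
}

#' @export
print.verifier_ensemble <- function(x, ...) {
  cat(sprintf("<verifier_ensemble of %d models (seeds %s)>\n", length(x),
              paste(vapply(x, function(m) m$seed, integer(1)), collapse = ", ")))
  invisible(x)
}
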