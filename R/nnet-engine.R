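# Minimal dense feed-forward classifier: ReLU hidden layers, softmax output,
# cross-entropy loss, mini-batch gradient descent with momentum. Pure R
# matrix arithmetic, single-threaded, fully deterministic under a seed --
# small tabular problems (a few thousand samples, tens of inputs) train in
# well under a second.

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    # He initialization suits the ReLU layers
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                 sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

mlp_forward <- function(params, x) {
  acts <- list(x)
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% params[[l]]$W +
      matrix(params[[l]]$b, nrow(acts[[l]]), length(params[[l]]$b),
             byrow = TRUE)
    acts[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else softmax_rows(z)
  }
  acts
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_train <- function(x, y_onehot, hidden = c(32L, 16L), epochs = 200L,
                      batch_size = 32L, learning_rate = 0.01,
                      momentum = 0.9) {
  n <- nrow(x)
  params <- mlp_init(ncol(x), hidden, ncol(y_onehot))
  vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  n_layers <- length(params)
  for (epoch in seq_len(epochs)) {
    order <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- order[s:min(s + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y_onehot[idx, , drop = FALSE]
      acts <- mlp_forward(params, xb)
      # softmax + cross-entropy gradient at the output
      delta <- (acts[[n_layers + 1L]] - yb) / nrow(xb)
      for (l in rev(seq_len(n_layers))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
        }
        vel[[l]]$W <- momentum * vel[[l]]$W - learning_rate * gW
        vel[[l]]$b <- momentum * vel[[l]]$b - learning_rate * gb
        params[[l]]$W <- params[[l]]$W + vel[[l]]$W
        params[[l]]$b <- params[[l]]$b + vel[[l]]$b
      }
    }
  }
  params
}

mlp_predict_class <- function(params, x) {
  probs <- mlp_forward(params, x)[[length(params) + 1L]]
  max.col(probs, ties.method = "first")
}
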