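# Minimal fully connected regression network (tanh hidden layers, linear
# output) trained with Adam on minibatches. Kept deliberately small and
# dependency-free: inference must be vectorizable over whole images and
# training must be bit-reproducible from a seed.

mlp_init <- function(n_in, hidden, seed) {
  sizes <- c(n_in, hidden, 1L)
  with_seed(seed, {
    w <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(w)) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))   # Glorot uniform
      w[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      b[[l]] <- rep(0, fan_out)
    }
    list(w = w, b = b)
  })
}

# forward pass; returns activations per layer (needed for backprop)
mlp_forward <- function(par, X) {
  L <- length(par$w)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  a <- X
  for (l in seq_len(L)) {
    z <- a %*% par$w[[l]]
    z <- sweep(z, 2L, par$b[[l]], `+`)
    a <- if (l < L) tanh(z) else z
    acts[[l + 1L]] <- a
  }
  acts
}

# gradients of mean squared error 0.5 * mean((yhat - y)^2)
mlp_grad <- function(par, acts, y) {
  L <- length(par$w)
  n <- length(y)
  gw <- vector("list", L); gb <- vector("list", L)
  delta <- (acts[[L + 1L]] - y) / n            # n x 1
  for (l in rev(seq_len(L))) {
    gw[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$w[[l]])) * (1 - acts[[l]]^2)
    }
  }
  list(w = gw, b = gb)
}

mlp_loss <- function(par, X, y) {
  yhat <- mlp_forward(par, X)[[length(par$w) + 1L]]
  0.5 * mean((yhat - y)^2)
}

mlp_train <- function(par, X, y, epochs, batch_size, lr, seed,
                      Xval = NULL, yval = NULL, lr_decay = 1) {
  n <- nrow(X)
  L <- length(par$w)
  m <- lapply(c(par$w, par$b), function(p) p * 0)
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  history <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      # geometric learning-rate decay over epochs for tight convergence
      lr_ep <- lr * lr_decay^(ep - 1L)
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        acts <- mlp_forward(par, X[idx, , drop = FALSE])
        g <- mlp_grad(par, acts, y[idx])
        flat <- c(g$w, g$b)
        t <- t + 1L
        lr_t <- lr_ep * sqrt(1 - beta2^t) / (1 - beta1^t)
        for (k in seq_along(flat)) {
          m[[k]] <- beta1 * m[[k]] + (1 - beta1) * flat[[k]]
          v[[k]] <- beta2 * v[[k]] + (1 - beta2) * flat[[k]]^2
          upd <- lr_t * m[[k]] / (sqrt(v[[k]]) + eps)
          if (k <= L) par$w[[k]] <- par$w[[k]] - upd
          else par$b[[k - L]] <- par$b[[k - L]] - upd
        }
      }
      l_ep <- if (!is.null(Xval)) mlp_loss(par, Xval, yval)
              else mlp_loss(par, X, y)
      if (!is.finite(l_ep)) {
        stop(sprintf("network training diverged at epoch %d (loss %g); ",
                     ep, l_ep),
             "reduce the learning rate or inspect the training targets")
      }
      history <- c(history, l_ep)
    }
  })
  list(par = par, history = history)
}
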