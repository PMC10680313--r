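# Minimal feed-forward network engine: dense / batch-norm / ReLU / dropout
# layers with explicit forward caches, analytic backward passes and an Adam
# optimizer. All randomness (initialization, dropout masks, batching) draws
# from R's global RNG so callers control determinism with a single seed.
# Networks are plain lists, so snapshots for early stopping are free copies.

nn_dense <- function(n_in, n_out) {
  # He weights for the ReLU layers that follow; a small positive bias keeps
  # ReLU units initially active (narrow code layers die otherwise)
  list(kind = "dense",
       W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0.01, n_out))
}

nn_bn <- function(n, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn", gamma = rep(1, n), beta = numeric(n),
       rmean = numeric(n), rvar = rep(1, n), momentum = momentum, eps = eps)
}

nn_relu <- function() list(kind = "relu")

nn_dropout <- function(rate) list(kind = "dropout", rate = rate)

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "dense") {
      caches[[i]] <- list(x = x)
      x <- sweep(x %*% l$W, 2, l$b, "+")
    } else if (l$kind == "bn") {
      if (training) {
        n <- nrow(x)
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu, "-")
        v <- colMeans(xc * xc)  # population variance, standard for batch norm
        ivar <- 1 / sqrt(v + l$eps)
        xhat <- sweep(xc, 2, ivar, "*")
        layers[[i]]$rmean <- (1 - l$momentum) * l$rmean + l$momentum * mu
        layers[[i]]$rvar <- (1 - l$momentum) * l$rvar + l$momentum * v
        caches[[i]] <- list(xhat = xhat, ivar = ivar)
        x <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      } else {
        xhat <- sweep(sweep(x, 2, l$rmean, "-"), 2, sqrt(l$rvar + l$eps), "/")
        x <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      }
    } else if (l$kind == "relu") {
      mask <- x > 0
      caches[[i]] <- list(mask = mask)
      x <- x * mask
    } else if (l$kind == "dropout") {
      if (training && l$rate > 0) {
        keep <- matrix(stats::runif(length(x)) >= l$rate, nrow(x), ncol(x)) / (1 - l$rate)
        caches[[i]] <- list(keep = keep)
        x <- x * keep
      } else {
        caches[[i]] <- list(keep = NULL)
      }
    } else {
      abort(sprintf("unknown layer kind '%s'", l$kind))
    }
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    c_i <- caches[[i]]
    if (l$kind == "dense") {
      grads[[i]] <- list(W = crossprod(c_i$x, dout), b = colSums(dout))
      dout <- tcrossprod(dout, l$W)
    } else if (l$kind == "bn") {
      n <- nrow(c_i$xhat)
      dgamma <- colSums(dout * c_i$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2, l$gamma, "*")
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * c_i$xhat)
      dout <- sweep(
        sweep(dxhat, 2, s1 / n, "-") - sweep(c_i$xhat, 2, s2 / n, "*"),
        2, c_i$ivar, "*"
      )
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (l$kind == "relu") {
      dout <- dout * c_i$mask
    } else if (l$kind == "dropout") {
      if (!is.null(c_i$keep)) dout <- dout * c_i$keep
    }
  }
  list(dx = dout, grads = grads)
}

nn_add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (i in seq_along(g1)) {
    if (!is.null(g1[[i]])) {
      for (p in names(g1[[i]])) g1[[i]][[p]] <- g1[[i]][[p]] + g2[[i]][[p]]
    }
  }
  g1
}

adam_init <- function(layers) {
  st <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "dense") {
      st[[i]] <- list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else if (l$kind == "bn") {
      st[[i]] <- list(mg = l$gamma * 0, vg = l$gamma * 0, mb = l$beta * 0, vb = l$beta * 0)
    }
  }
  list(t = 0L, layers = st)
}

adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    list(m = m, v = v, step = lr * (m / bc1) / (sqrt(v / bc2) + eps))
  }
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]
    s <- state$layers[[i]]
    if (l$kind == "dense") {
      u <- upd(s$mW, s$vW, g$W); s$mW <- u$m; s$vW <- u$v; l$W <- l$W - u$step
      u <- upd(s$mb, s$vb, g$b); s$mb <- u$m; s$vb <- u$v; l$b <- l$b - u$step
    } else if (l$kind == "bn") {
      u <- upd(s$mg, s$vg, g$gamma); s$mg <- u$m; s$vg <- u$v; l$gamma <- l$gamma - u$step
      u <- upd(s$mb, s$vb, g$beta); s$mb <- u$m; s$vb <- u$v; l$beta <- l$beta - u$step
    }
    state$layers[[i]] <- s
    layers[[i]] <- l
  }
  list(layers = layers, state = state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
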