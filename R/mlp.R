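# Minimal two-hidden-layer multilayer perceptron for classification,
# trained with Adam on the softmax cross-entropy, with early stopping on a
# held-out fraction of the training data. Inputs are expected to be
# standardized (here: principal-component scores).

mlp_fit <- function(X, y, hidden = c(64L, 32L), lr = 1e-3, epochs = 300L,
                    batch = 64L, val_frac = 0.15, patience = 20L, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  classes <- levels(y)
  K <- length(classes)
  set.seed(seed)
  n <- nrow(X)
  vi <- sample(n, max(1L, round(val_frac * n)))
  Xv <- X[vi, , drop = FALSE]; yv <- as.integer(y)[vi]
  Xt <- X[-vi, , drop = FALSE]; yt <- as.integer(y)[-vi]
  sizes <- c(ncol(X), hidden, K)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; epsb <- 1e-8
  step <- 0L
  forward <- function(x) {
    a <- list(x)
    for (l in seq_along(W)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1L]] <- if (l < length(W)) pmax(z, 0) else z
    }
    a
  }
  softmax <- function(z) {
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  }
  val_loss <- function() {
    p <- softmax(forward(Xv)[[length(sizes)]])
    -mean(log(pmax(p[cbind(seq_along(yv), yv)], 1e-12)))
  }
  best <- list(W = W, b = b, loss = val_loss())
  bad <- 0L
  nt <- nrow(Xt)
  for (ep in seq_len(epochs)) {
    ord <- sample(nt)
    for (s in seq(1L, nt, by = batch)) {
      ii <- ord[s:min(s + batch - 1L, nt)]
      a <- forward(Xt[ii, , drop = FALSE])
      p <- softmax(a[[length(sizes)]])
      m <- length(ii)
      delta <- p
      delta[cbind(seq_len(m), yt[ii])] <- delta[cbind(seq_len(m), yt[ii])] - 1
      delta <- delta / m
      step <- step + 1L
      for (l in rev(seq_along(W))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^step; cor2 <- 1 - beta2^step
        W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + epsb)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + epsb)
      }
    }
    vl <- val_loss()
    if (vl < best$loss - 1e-5) {
      best <- list(W = W, b = b, loss = vl)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  structure(list(W = best$W, b = best$b, classes = classes, sizes = sizes),
            class = "chromatin_mlp")
}

mlp_predict_prob <- function(model, X) {
  a <- as.matrix(X)
  for (l in seq_along(model$W)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- if (l < length(model$W)) pmax(z, 0) else z
  }
  z <- a - apply(a, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  colnames(p) <- model$classes
  p
}
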