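# Minimal 1-D convolutional network engine (internal).
#
# No deep-learning framework is available, so the scorer networks are built
# directly on BLAS matrix products. Feature maps of length L with C channels
# are stored as n x (L*C) matrices in position-fastest order, i.e. column
# (p, c) sits at index p + (c-1)*L. That layout lets an n x (L*C) matrix be
# reinterpreted as an (n*L) x C matrix by a plain dim<- change, which is what
# makes im2col-free convolution via k matrix products possible.
#
# Gradient correctness is pinned by a finite-difference test.

nn_build <- function(conv_blocks, n_channels, fcl_size, dropout_rate,
                     n_out = 1L, output = c("sigmoid", "softmax"),
                     seed = 0L) {
  output <- match.arg(output)
  set.seed(seed)
  layers <- list()
  L <- as.integer(n_channels); C <- 1L
  for (blk in conv_blocks) {
    k <- as.integer(blk$kernel); f <- as.integer(blk$filters)
    m <- as.integer(blk$pool)
    Lout <- L - k + 1L
    if (Lout < 1L) stop("spectrum too short for this architecture")
    layers[[length(layers) + 1L]] <- list(
      kind = "conv", k = k, Cin = C, Cout = f, L = L, Lout = Lout,
      W = matrix(rnorm(k * C * f, 0, sqrt(2 / (k * C))), k * C, f),
      b = numeric(f))
    layers[[length(layers) + 1L]] <- list(kind = "relu")
    Lm <- Lout %/% m
    if (Lm < 1L) stop("spectrum too short for this architecture")
    layers[[length(layers) + 1L]] <- list(
      kind = "pool", m = m, L = Lout, C = f, Lm = Lm)
    L <- Lm; C <- f
  }
  flat <- L * C
  if (dropout_rate > 0)
    layers[[length(layers) + 1L]] <- list(kind = "dropout",
                                          rate = dropout_rate)
  if (fcl_size > 0) {
    layers[[length(layers) + 1L]] <- list(
      kind = "dense", W = matrix(rnorm(flat * fcl_size, 0, sqrt(2 / flat)),
                                 flat, fcl_size),
      b = numeric(fcl_size))
    layers[[length(layers) + 1L]] <- list(kind = "relu")
    flat <- fcl_size
  }
  layers[[length(layers) + 1L]] <- list(
    kind = "dense", W = matrix(rnorm(flat * n_out, 0, sqrt(1 / flat)),
                               flat, n_out),
    b = numeric(n_out))
  list(layers = layers, n_in = as.integer(n_channels),
       n_out = as.integer(n_out), output = output)
}

conv_fwd <- function(ly, X) {
  conv_fwd_cpp(X, ly$W, ly$b, ly$L, ly$Cin, ly$k)
}

conv_bwd <- function(ly, X, dY) {
  conv_bwd_cpp(X, ly$W, dY, ly$L, ly$Cin, ly$k)
}

pool_fwd <- function(ly, X) {
  pool_fwd_cpp(X, ly$L, ly$C, ly$m)
}

pool_bwd <- function(ly, cache, dY) {
  pool_bwd_cpp(dY, cache$take, ly$L, ly$C, ly$m)
}

nn_forward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$kind == "conv") {
      caches[[i]] <- list(X = X)
      X <- conv_fwd(ly, X)
    } else if (ly$kind == "relu") {
      mask <- X > 0
      X <- X * mask
      caches[[i]] <- list(mask = mask)
    } else if (ly$kind == "pool") {
      res <- pool_fwd(ly, X)
      caches[[i]] <- res
      X <- res$out
    } else if (ly$kind == "dropout") {
      if (training && ly$rate > 0) {
        mask <- matrix((runif(length(X)) >= ly$rate) / (1 - ly$rate),
                       nrow(X), ncol(X))
        X <- X * mask
        caches[[i]] <- list(mask = mask)
      } else caches[[i]] <- list(mask = NULL)
    } else if (ly$kind == "dense") {
      caches[[i]] <- list(X = X)
      X <- X %*% ly$W + rep(ly$b, each = nrow(X))
    }
  }
  p <- if (net$output == "sigmoid") plogis(X) else softmax_rows(X)
  list(z = X, p = p, caches = caches)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Backward pass from the output pre-activation gradient dZ; returns a list of
# per-layer gradients (NULL for parameter-free layers).
nn_backward <- function(net, caches, dZ) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$kind == "dense") {
      grads[[i]] <- list(dW = crossprod(caches[[i]]$X, dZ), db = colSums(dZ))
      dZ <- dZ %*% t(ly$W)
    } else if (ly$kind == "relu") {
      dZ <- dZ * caches[[i]]$mask
    } else if (ly$kind == "dropout") {
      if (!is.null(caches[[i]]$mask)) dZ <- dZ * caches[[i]]$mask
    } else if (ly$kind == "pool") {
      dZ <- pool_bwd(ly, caches[[i]], dZ)
    } else if (ly$kind == "conv") {
      res <- conv_bwd(ly, caches[[i]]$X, dZ)
      grads[[i]] <- list(dW = res$dW, db = res$db)
      dZ <- res$dX
    }
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    if (ly$kind %in% c("conv", "dense"))
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    else NULL
  })
}

adam_update <- function(net, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  corr <- sqrt(1 - b2^t) / (1 - b1^t)
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- net$layers[[i]]
    s <- state[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * g$dW
    s$vW <- b2 * s$vW + (1 - b2) * g$dW^2
    ly$W <- ly$W - lr * corr * s$mW / (sqrt(s$vW) + eps)
    s$mb <- b1 * s$mb + (1 - b1) * g$db
    s$vb <- b2 * s$vb + (1 - b2) * g$db^2
    ly$b <- ly$b - lr * corr * s$mb / (sqrt(s$vb) + eps)
    net$layers[[i]] <- ly
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# Stratified index split: returns validation indices.
stratified_val_idx <- function(labels, fraction) {
  unlist(lapply(split(seq_along(labels), labels), function(ix) {
    nv <- max(1L, floor(fraction * length(ix)))
    if (length(ix) <= 1L) return(integer(0))
    sample(ix, min(nv, length(ix) - 1L))
  }), use.names = FALSE)
}

# Train a network with mini-batch Adam on (X, y).
# y: 0/1 vector (sigmoid) or integer class vector 1..n_out (softmax).
# weights: per-sample loss weights.
nn_train <- function(net, X, y, epochs, batch_size, lr,
                     validation_fraction = 0.2, weights = NULL, seed = 0L) {
  set.seed(seed)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  val <- if (validation_fraction > 0 && n >= 5L)
    stratified_val_idx(y, validation_fraction) else integer(0)
  tr <- setdiff(seq_len(n), val)
  state <- adam_init(net)
  step <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  softmax <- net$output == "softmax"
  Y_onehot <- if (softmax)
    diag(net$n_out)[y, , drop = FALSE] else NULL
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    bl <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0; ep_correct <- 0; ep_w <- 0
    for (bix in bl) {
      Xb <- X[bix, , drop = FALSE]
      wb <- weights[bix]
      fw <- nn_forward(net, Xb, training = TRUE)
      if (softmax) {
        Yb <- Y_onehot[bix, , drop = FALSE]
        eps <- 1e-12
        loss <- -sum(wb * log(rowSums(fw$p * Yb) + eps)) / sum(wb)
        dZ <- (fw$p - Yb) * (wb / sum(wb))
        correct <- sum(max.col(fw$p, "first") == y[bix])
      } else {
        yb <- y[bix]
        p <- pmin(pmax(fw$p[, 1L], 1e-12), 1 - 1e-12)
        loss <- -sum(wb * (yb * log(p) + (1 - yb) * log(1 - p))) / sum(wb)
        dZ <- matrix((p - yb) * (wb / sum(wb)), ncol = 1L)
        correct <- sum((p > 0.5) == yb)
      }
      grads <- nn_backward(net, fw$caches, dZ)
      step <- step + 1L
      upd <- adam_update(net, grads, state, lr, step)
      net <- upd$net; state <- upd$state
      ep_loss <- ep_loss + loss * length(bix)
      ep_correct <- ep_correct + correct
      ep_w <- ep_w + length(bix)
    }
    vm <- if (length(val)) {
      pv <- nn_predict(net, X[val, , drop = FALSE])
      if (softmax) {
        c(-mean(log(pv[cbind(seq_along(val), y[val])] + 1e-12)),
          mean(max.col(pv, "first") == y[val]))
      } else {
        pvv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
        c(-mean(y[val] * log(pvv) + (1 - y[val]) * log(1 - pvv)),
          mean((pv > 0.5) == y[val]))
      }
    } else c(NA_real_, NA_real_)
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = ep_loss / ep_w, train_acc = ep_correct / ep_w,
      val_loss = vm[1L], val_acc = vm[2L]))
  }
  list(net = net, history = hist)
}

nn_predict <- function(net, X, chunk = 512L) {
  n <- nrow(X)
  if (n == 0L)
    return(if (net$n_out == 1L) numeric(0)
           else matrix(numeric(0), 0L, net$n_out))
  out <- matrix(0, n, net$n_out)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- nn_forward(net, X[s:e, , drop = FALSE])$p
  }
  if (net$n_out == 1L) out[, 1L] else out
}
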