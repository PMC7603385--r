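# Internal feed-forward network engine: Glorot-initialised dense layers,
# tanh/relu/linear/softmax activations, inverted dropout, Adadelta updates,
# softmax cross-entropy or mean-squared-error losses, optional penalty on
# the first weight matrix. Plain matrix arithmetic; one RNG stream per
# training run so results are reproducible from the seed.

.glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# layer_sizes includes input and output; returns weight/bias lists.
# Consumes RNG state (caller sets the seed).
mlp_init <- function(layer_sizes) {
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  L <- length(layer_sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- .glorot(layer_sizes[l], layer_sizes[l + 1L])
    b[[l]] <- numeric(layer_sizes[l + 1L])
  }
  list(W = W, b = b, sizes = as.integer(layer_sizes))
}

.mlp_act <- function(Z, kind) {
  switch(kind,
    tanh = tanh(Z),
    relu = pmax(Z, 0),
    linear = Z,
    softmax = {
      E <- exp(Z - apply(Z, 1L, max))
      E / rowSums(E)
    },
    stop("unknown activation: ", kind)
  )
}

# derivative of the activation wrt its pre-activation, elementwise
# (softmax handled jointly with the cross-entropy loss, never here)
.mlp_act_grad <- function(A, Z, kind) {
  switch(kind,
    tanh = 1 - A^2,
    relu = (Z > 0) + 0,
    linear = array(1, dim(Z)),
    stop("no elementwise gradient for activation: ", kind)
  )
}

# Forward pass. X is m x sizes[1]. activations: one name per layer (length
# L). dropout: per-layer rate applied to that layer's *output* (only for
# hidden layers; entries for the last layer are ignored). When training,
# inverted-dropout masks are drawn from the current RNG stream and returned.
mlp_forward <- function(net, X, activations, dropout = NULL, training = FALSE) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  M <- vector("list", L) # dropout masks
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- .mlp_act(Z[[l]], activations[l])
    rate <- if (is.null(dropout)) 0 else dropout[l]
    if (training && l < L && rate > 0) {
      keep <- matrix(stats::runif(length(Z[[l]])) >= rate, nrow(Z[[l]]))
      M[[l]] <- keep / (1 - rate)
      A[[l + 1L]] <- A[[l + 1L]] * M[[l]]
    }
  }
  list(A = A, Z = Z, M = M)
}

.mlp_loss <- function(Yhat, Y, loss) {
  switch(loss,
    softmax_ce = -mean(rowSums(Y * log(Yhat + 1e-12))),
    mse = mean((Yhat - Y)^2),
    stop("unknown loss: ", loss)
  )
}

# Gradient of the loss wrt the output pre-activation.
.mlp_out_grad <- function(Yhat, Y, loss) {
  m <- nrow(Y)
  switch(loss,
    softmax_ce = (Yhat - Y) / m,                 # softmax + CE jointly
    mse = 2 * (Yhat - Y) / (m * ncol(Y)),        # linear output
    stop("unknown loss: ", loss)
  )
}

# Backpropagation for one batch; returns gradient lists dW, db.
mlp_backprop <- function(net, fwd, Y, activations, loss,
                         reg = NULL) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  dZ <- .mlp_out_grad(fwd$A[[L + 1L]], Y, loss)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fwd$A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, net$W[[l]])
      if (!is.null(fwd$M[[l - 1L]])) dA <- dA * fwd$M[[l - 1L]]
      dZ <- dA * .mlp_act_grad(fwd$A[[l]], fwd$Z[[l - 1L]], activations[l - 1L])
    }
  }
  if (!is.null(reg) && reg$type != "none" && reg$strength > 0) {
    dW[[1L]] <- dW[[1L]] + .reg_grad(net$W[[1L]], reg)
  }
  list(dW = dW, db = db)
}

# Penalties on the input weight matrix (feature rows).
.reg_penalty <- function(W, reg) {
  switch(reg$type,
    none = 0,
    l1 = reg$strength * sum(abs(W)),
    group_row_l2 = reg$strength * sum(sqrt(rowSums(W^2))),
    stop("unknown regularizer: ", reg$type)
  )
}

.reg_grad <- function(W, reg) {
  switch(reg$type,
    l1 = reg$strength * sign(W),
    group_row_l2 = {
      nrm <- sqrt(rowSums(W^2))
      nrm[nrm == 0] <- 1 # subgradient 0 at the origin
      reg$strength * W / nrm
    }
  )
}

.adadelta_state <- function(net) {
  zero_like <- function(p) lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  list(
    Eg_W = zero_like(net$W), Ed_W = zero_like(net$W),
    Eg_b = zero_like(net$b), Ed_b = zero_like(net$b)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adadelta update: accumulate squared gradients, scale by the RMS of
# past updates, accumulate squared updates. lr is a multiplier on the
# native Adadelta step.
.adadelta_step <- function(p, g, Eg, Ed, lr, rho, eps) {
  Eg <- rho * Eg + (1 - rho) * g^2
  dx <- -sqrt(Ed + eps) / sqrt(Eg + eps) * g
  Ed <- rho * Ed + (1 - rho) * dx^2
  list(p = p + lr * dx, Eg = Eg, Ed = Ed)
}

# Mini-batch training loop. Returns the trained net and the per-epoch mean
# data loss (regularization penalty excluded from the history).
mlp_train <- function(net, X, Y, activations, loss,
                      epochs, batch_size, lr,
                      rho = 0.95, eps = 1e-6,
                      dropout = NULL, reg = NULL) {
  m <- nrow(X)
  st <- .adadelta_state(net)
  history <- numeric(epochs)
  if (epochs == 0L) return(list(net = net, history = numeric(0)))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(m)
    starts <- seq(1L, m, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, m)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fwd <- mlp_forward(net, Xb, activations, dropout, training = TRUE)
      gr <- mlp_backprop(net, fwd, Yb, activations, loss, reg)
      for (l in seq_along(net$W)) {
        up <- .adadelta_step(net$W[[l]], gr$dW[[l]], st$Eg_W[[l]], st$Ed_W[[l]], lr, rho, eps)
        net$W[[l]] <- up$p; st$Eg_W[[l]] <- up$Eg; st$Ed_W[[l]] <- up$Ed
        up <- .adadelta_step(net$b[[l]], gr$db[[l]], st$Eg_b[[l]], st$Ed_b[[l]], lr, rho, eps)
        net$b[[l]] <- up$p; st$Eg_b[[l]] <- up$Eg; st$Ed_b[[l]] <- up$Ed
      }
      ep_loss <- ep_loss + .mlp_loss(fwd$A[[length(fwd$A)]], Yb, loss) * length(idx)
    }
    history[ep] <- ep_loss / m
  }
  list(net = net, history = history)
}

# Inference-time forward pass returning the final activation only.
mlp_predict <- function(net, X, activations) {
  fwd <- mlp_forward(net, X, activations, dropout = NULL, training = FALSE)
  fwd$A[[length(fwd$A)]]
}
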