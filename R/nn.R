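# Minimal dense neural-network machinery: hand-written forward/backward
# passes and first-order optimizers, enough for the small MLPs, the VAE and
# the graph-convolutional model in this package. Everything operates on
# plain matrices; a "net" is a list of layers, each list(W, b, act) with
# act one of "relu", "linear", "softmax".

nn_init_layer <- function(n_in, n_out, act, scheme = c("he", "xavier")) {
  scheme <- match.arg(scheme)
  sd <- if (scheme == "he") sqrt(2 / n_in) else sqrt(2 / (n_in + n_out))
  list(W = matrix(stats::rnorm(n_in * n_out, 0, sd), n_in, n_out),
       b = rep(0, n_out), act = act)
}

nn_init <- function(dims, acts, scheme = "he") {
  lapply(seq_along(acts), function(l)
    nn_init_layer(dims[l], dims[l + 1], acts[l], scheme))
}

nn_act <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         linear = z,
         softmax = {
           z <- z - apply(z, 1, max)
           e <- exp(z)
           e / rowSums(e)
         })
}

# Forward pass; returns output and per-layer caches (input, preactivation,
# activation) for the backward pass.
nn_forward <- function(net, X) {
  caches <- vector("list", length(net))
  h <- X
  for (l in seq_along(net)) {
    z <- sweep(h %*% net[[l]]$W, 2, net[[l]]$b, "+")
    a <- nn_act(z, net[[l]]$act)
    caches[[l]] <- list(input = h, z = z, a = a)
    h <- a
  }
  list(out = h, caches = caches)
}

# Backward pass from dOut = dLoss/d(output activations). For softmax layers
# the Jacobian is applied row-wise. `extra_dA` optionally injects additional
# gradient wrt a hidden layer's activation (extra_dA[[l]] added when layer l
# is reached), for losses attached to intermediate layers. Returns per-layer
# gradients and dX.
nn_backward <- function(net, caches, dOut, extra_dA = NULL) {
  grads <- vector("list", length(net))
  dA <- dOut
  for (l in rev(seq_along(net))) {
    cache <- caches[[l]]
    if (!is.null(extra_dA) && l <= length(extra_dA) &&
        !is.null(extra_dA[[l]])) {
      dA <- dA + extra_dA[[l]]
    }
    dZ <- switch(net[[l]]$act,
                 relu = dA * (cache$z > 0),
                 linear = dA,
                 softmax = {
                   p <- cache$a
                   p * (dA - rowSums(dA * p))
                 })
    grads[[l]] <- list(W = crossprod(cache$input, dZ), b = colSums(dZ))
    dA <- dZ %*% t(net[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

# Flatten/restore parameter lists so one optimizer state covers a model.
nn_get_params <- function(net) {
  unlist(lapply(net, function(l) c(l$W, l$b)))
}

nn_set_params <- function(net, theta) {
  pos <- 1L
  for (l in seq_along(net)) {
    nw <- length(net[[l]]$W); nb <- length(net[[l]]$b)
    net[[l]]$W[] <- theta[pos:(pos + nw - 1)]
    net[[l]]$b[] <- theta[(pos + nw):(pos + nw + nb - 1)]
    pos <- pos + nw + nb
  }
  net
}

nn_flatten_grads <- function(grads) {
  unlist(lapply(grads, function(g) c(g$W, g$b)))
}

# Adam optimizer over a flat parameter vector.
adam_init <- function(n, lr = 3e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = numeric(n), v = numeric(n), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(theta, grad, st) {
  st$t <- st$t + 1L
  st$m <- st$beta1 * st$m + (1 - st$beta1) * grad
  st$v <- st$beta2 * st$v + (1 - st$beta2) * grad^2
  mhat <- st$m / (1 - st$beta1^st$t)
  vhat <- st$v / (1 - st$beta2^st$t)
  list(theta = theta - st$lr * mhat / (sqrt(vhat) + st$eps), state = st)
}

# RMSProp optimizer over a flat parameter vector.
rmsprop_init <- function(n, lr = 1e-3, rho = 0.9, eps = 1e-8) {
  list(v = numeric(n), lr = lr, rho = rho, eps = eps)
}

rmsprop_step <- function(theta, grad, st) {
  st$v <- st$rho * st$v + (1 - st$rho) * grad^2
  list(theta = theta - st$lr * grad / (sqrt(st$v) + st$eps), state = st)
}

# Row-wise (1 - cosine similarity) loss and its gradient wrt A.
cosine_loss <- function(A, B, eps = 1e-12) {
  na <- sqrt(rowSums(A^2)) + eps
  nb <- sqrt(rowSums(B^2)) + eps
  dot <- rowSums(A * B)
  cosv <- dot / (na * nb)
  grad <- -(B / (na * nb) - A * (dot / (na^3 * nb))) / nrow(A)
  list(value = mean(1 - cosv), grad = grad)
}

# Global gradient-norm clipping.
clip_grad <- function(g, max_norm) {
  nr <- sqrt(sum(g^2))
  if (is.finite(nr) && nr > max_norm) g * (max_norm / nr) else g
}
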