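#' Squared maximum mean discrepancy between two samples
#'
#' MMD^2(U, V) = (1/n^2) sum k(u, u') - (2/nm) sum k(u, v) +
#' (1/m^2) sum k(v, v'), with the Gaussian kernel
#' k(u, v) = exp(-|u - v|^2 / sigma). Symmetric, non-negative up to kernel
#' bias, and zero when the two samples coincide. Used to pull the embeddings
#' of simulated and real spots onto a common distribution.
#'
#' @param U,V n x d and m x d sample matrices.
#' @param sigma kernel bandwidth; by convention the dimension of the hidden
#'   layer the embeddings come from.
#' @return A scalar.
#' @export
mmd2 <- function(U, V, sigma) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (nrow(U) == 0 || nrow(V) == 0) stop("empty sample")
  stopifnot(sigma > 0, ncol(U) == ncol(V))
  kmat <- function(A, B) exp(-cross_dist2(A, B) / sigma)
  mean(kmat(U, U)) - 2 * mean(kmat(U, V)) + mean(kmat(V, V))
}

# MMD^2 value plus gradients wrt U and V (for training).
mmd2_grad <- function(U, V, sigma) {
  n <- nrow(U); m <- nrow(V)
  Kuu <- exp(-cross_dist2(U, U) / sigma)
  Kuv <- exp(-cross_dist2(U, V) / sigma)
  Kvv <- exp(-cross_dist2(V, V) / sigma)
  val <- mean(Kuu) - 2 * mean(Kuv) + mean(Kvv)
  dU <- (-4 / (sigma * n^2)) * (rowSums(Kuu) * U - Kuu %*% U) +
    (4 / (sigma * n * m)) * (rowSums(Kuv) * U - Kuv %*% V)
  dV <- (-4 / (sigma * m^2)) * (rowSums(Kvv) * V - Kvv %*% V) +
    (4 / (sigma * n * m)) * (colSums(Kuv) * V - t(Kuv) %*% U)
  list(value = val, dU = dU, dV = dV)
}

#' Proportion prediction loss
#'
#' Per-row (1 - cosine similarity) plus KL(truth || pred), averaged over
#' rows; zero exactly when prediction equals truth row-wise. Both arguments
#' are floored at `eps` inside the KL term (natural log).
#'
#' @param pred,truth matching matrices with rows on the simplex.
#' @param eps floor for the KL term.
#' @return A scalar >= 0.
#' @export
proportion_loss <- function(pred, truth, eps = 1e-8) {
  stopifnot(all(dim(pred) == dim(truth)))
  p <- pmax(pred, eps)
  t2 <- pmax(truth, eps)
  kl <- mean(rowSums(t2 * log(t2 / p)))
  cosine_loss(pred, truth)$value + kl
}

# Loss value + gradient wrt pred.
proportion_loss_grad <- function(pred, truth, eps = 1e-8) {
  p <- pmax(pred, eps)
  t2 <- pmax(truth, eps)
  kl <- mean(rowSums(t2 * log(t2 / p)))
  # denominator floored but gradient kept: through a softmax this bounds the
  # pull at -t and lets saturated outputs recover
  dkl <- -(t2 / p) / nrow(pred)
  cl <- cosine_loss(pred, truth)
  list(value = cl$value + kl, grad = cl$grad + dkl)
}

# --- variational autoencoder -------------------------------------------

vae_init <- function(n_genes, hidden = 128, latent = 64) {
  list(enc = nn_init(c(n_genes, hidden), "relu"),
       mu = nn_init(c(hidden, latent), "linear"),
       lv = nn_init(c(hidden, latent), "linear"),
       dec = nn_init(c(latent, hidden, n_genes), c("relu", "linear")),
       latent = latent)
}

vae_params <- function(v) {
  c(nn_get_params(v$enc), nn_get_params(v$mu), nn_get_params(v$lv),
    nn_get_params(v$dec))
}

vae_set_params <- function(v, theta) {
  sizes <- c(length(nn_get_params(v$enc)), length(nn_get_params(v$mu)),
             length(nn_get_params(v$lv)), length(nn_get_params(v$dec)))
  ends <- cumsum(sizes)
  v$enc <- nn_set_params(v$enc, theta[1:ends[1]])
  v$mu <- nn_set_params(v$mu, theta[(ends[1] + 1):ends[2]])
  v$lv <- nn_set_params(v$lv, theta[(ends[2] + 1):ends[3]])
  v$dec <- nn_set_params(v$dec, theta[(ends[3] + 1):ends[4]])
  v
}

vae_encode <- function(v, X) {
  h <- nn_forward(v$enc, X)
  nn_forward(v$mu, h$out)$out
}

# One evidence-lower-bound evaluation with gradients (Gaussian latent
# prior, mean-squared reconstruction on log-normalized expression).
vae_loss_grad <- function(v, X, eps_draw, beta = 1e-3) {
  n <- nrow(X); g <- ncol(X); d <- v$latent
  fe <- nn_forward(v$enc, X)
  fmu <- nn_forward(v$mu, fe$out)
  flv <- nn_forward(v$lv, fe$out)
  mu <- fmu$out
  lv <- pmin(pmax(flv$out, -10), 10)
  z <- mu + exp(0.5 * lv) * eps_draw
  fd <- nn_forward(v$dec, z)
  recon <- fd$out
  mse <- mean((recon - X)^2)
  kl <- mean(rowSums(0.5 * (mu^2 + exp(lv) - 1 - lv))) / d
  dRecon <- 2 * (recon - X) / (n * g)
  bd <- nn_backward(v$dec, fd$caches, dRecon)
  dz <- bd$dX
  dmu <- dz + beta * mu / (n * d)
  dlv <- dz * eps_draw * 0.5 * exp(0.5 * lv) +
    beta * 0.5 * (exp(lv) - 1) / (n * d)
  bmu <- nn_backward(v$mu, fmu$caches, dmu)
  blv <- nn_backward(v$lv, flv$caches, dlv)
  be <- nn_backward(v$enc, fe$caches, bmu$dX + blv$dX)
  list(value = mse + beta * kl,
       grad = c(nn_flatten_grads(be$grads), nn_flatten_grads(bmu$grads),
                nn_flatten_grads(blv$grads), nn_flatten_grads(bd$grads)))
}

# --- marker selection ---------------------------------------------------

#' Rank reference marker genes per cell type
#'
#' Vectorized two-sided Wilcoxon rank-sum statistic of each gene, one type
#' against the rest, on log-normalized counts; the top `n_markers` genes per
#' type (largest standardized statistic in favour of the type) define the
#' model gene space.
#'
#' @param ref an [sc_reference].
#' @param n_markers markers kept per type.
#' @return Character vector: the union of per-type marker genes.
#' @export
select_markers <- function(ref, n_markers = 200) {
  X <- normalize_counts(ref$counts)
  types <- levels(ref$cell_types)
  n <- nrow(X)
  ranks <- apply(X, 2, rank)
  out <- character(0)
  for (t in types) {
    grp <- ref$cell_types == t
    n1 <- sum(grp); n2 <- n - n1
    rs <- colSums(ranks[grp, , drop = FALSE])
    # standardized rank-sum, large positive = up in this type
    zs <- (rs - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
    out <- union(out, colnames(X)[order(zs, decreasing = TRUE)[
      seq_len(min(n_markers, ncol(X)))]])
  }
  out
}

#' Deconvolute spot cell-type proportions against a single-cell reference
#'
#' Fits the three-model deconvolution: a variational autoencoder embeds
#' simulated pseudo-spots and real spots in a common latent space; a
#' predictor MLP maps latents to cell-type proportions (softmax output);
#' a recovery head maps predicted proportions back toward the latent so the
#' proportions retain the information in the expression; and the maximum
#' mean discrepancy between simulated and real embeddings of the
#' predictor's last hidden layer aligns the two distributions. Training
#' alternates (1) a predictor update on the proportion loss over simulated
#' spots with known truth, and (2) a joint predictor + recovery update on
#' the recovery loss plus the MMD term, until the proportion loss changes by
#' less than `conv_tol` between epochs.
#'
#' @param ref an [sc_reference]; pseudo-spots are simulated from it.
#' @param slice a [slice_data] with the real spots to deconvolute.
#' @param n_sim_spots number of simulated training spots.
#' @param n_markers_per_type reference markers per type defining the gene
#'   space (intersected with the slice's genes).
#' @param vae_hidden,vae_latent VAE hidden width and latent dimension.
#' @param predictor_hidden width of the three predictor/recovery hidden
#'   layers; also the MMD kernel bandwidth.
#' @param lr Adam learning rate for the alternating phase; gradients are
#'   clipped to global norm `clip` for stability.
#' @param max_epochs,min_epochs epoch bounds for the alternating phase.
#' @param vae_epochs,vae_lr,vae_beta VAE pretraining epochs, learning rate
#'   and KL weight.
#' @param clip gradient-norm clip.
#' @param conv_tol convergence threshold on the proportion-loss change;
#'   training stops once the change stays below it for `conv_patience`
#'   consecutive epochs (a single small step on a transient plateau is not
#'   convergence).
#' @param conv_patience consecutive sub-threshold epochs required.
#' @param mu_c,delta_c pseudo-spot cells-per-spot parameters (see
#'   [simulate_pseudospots]).
#' @param seed integer seed; fixed seed gives a bit-identical fit.
#' @return An object of class `deconv_fit` with elements `proportions`
#'   (spots x types for `slice`), `history` (per-epoch losses), `genes`,
#'   `types`, and the fitted networks. Methods: [predict.deconv_fit],
#'   `print`, `coef` (the proportions).
#' @export
deconvolute <- function(ref, slice, n_sim_spots = 1000, n_markers_per_type = 200,
                   vae_hidden = 128, vae_latent = 64, predictor_hidden = 512,
                   lr = 1e-3, max_epochs = 300, min_epochs = 40,
                   vae_epochs = 1200, vae_lr = 3e-3, vae_beta = 1e-4,
                   clip = 5, conv_tol = 1e-3, conv_patience = 5,
                   mu_c = 10, delta_c = 5, seed = 1L) {
  stopifnot(inherits(ref, "sc_reference"), inherits(slice, "slice_data"))
  set.seed(derive_seed(seed, 10L))
  h <- harmonize_genes(ref, slice)
  markers <- select_markers(h$ref, n_markers_per_type)
  genes <- intersect(markers, colnames(h$slices[[1]]$counts))
  ref2 <- h$ref; ref2$counts <- ref2$counts[, genes, drop = FALSE]
  real_counts <- h$slices[[1]]$counts[, genes, drop = FALSE]

  depth <- estimate_depth_target(h$slices[[1]])
  sim <- simulate_pseudospots(ref2, n_sim_spots, mu_c = mu_c,
                              delta_c = delta_c, depth_target = depth,
                              seed = derive_seed(seed, 11L))
  types <- colnames(sim$proportions)
  n_types <- length(types)

  scale_to <- stats::median(rowSums(real_counts))
  Xs <- normalize_counts(sim$counts, scale_to = scale_to)
  Xr <- normalize_counts(real_counts, scale_to = scale_to)

  # VAE pretraining on the union of simulated and real spots
  vae <- vae_init(length(genes), vae_hidden, vae_latent)
  Xall <- rbind(Xs, Xr)
  theta <- vae_params(vae)
  st <- adam_init(length(theta), lr = vae_lr)
  for (e in seq_len(vae_epochs)) {
    eps_draw <- matrix(stats::rnorm(nrow(Xall) * vae_latent),
                       nrow(Xall), vae_latent)
    lg <- vae_loss_grad(vae_set_params(vae, theta), Xall, eps_draw,
                        beta = vae_beta)
    upd <- adam_step(theta, clip_grad(lg$grad, 2 * clip), st)
    theta <- upd$theta; st <- upd$state
  }
  vae <- vae_set_params(vae, theta)
  Zs <- vae_encode(vae, Xs)
  Zr <- vae_encode(vae, Xr)

  ph <- predictor_hidden
  E <- nn_init(c(vae_latent, ph, ph, ph, n_types),
               c("relu", "relu", "relu", "softmax"))
  R <- nn_init(c(n_types, ph, ph, ph, vae_latent),
               c("relu", "relu", "relu", "linear"))
  thE <- nn_get_params(E); thR <- nn_get_params(R)
  stE <- adam_init(length(thE), lr = lr)
  stJ <- adam_init(length(thE) + length(thR), lr = lr)
  hist <- data.frame(epoch = integer(), loss_E = numeric(),
                     loss_R = numeric(), loss_M = numeric())
  prev <- Inf
  flat <- 0L
  n_s <- nrow(Zs)
  Zall <- rbind(Zs, Zr)
  for (e in seq_len(max_epochs)) {
    # step 1: predictor on simulated spots with known proportions
    E <- nn_set_params(E, thE)
    fE <- nn_forward(E, Zs)
    plg <- proportion_loss_grad(fE$out, sim$proportions)
    bE <- nn_backward(E, fE$caches, plg$grad)
    upd <- adam_step(thE, clip_grad(nn_flatten_grads(bE$grads), clip), stE)
    thE <- upd$theta; stE <- upd$state
    loss_E <- plg$value

    # step 2: joint recovery + MMD update of E and R
    E <- nn_set_params(E, thE); R <- nn_set_params(R, thR)
    fA <- nn_forward(E, Zall)
    H2 <- fA$caches[[3]]$a
    mg <- mmd2_grad(H2[seq_len(n_s), , drop = FALSE],
                    H2[-seq_len(n_s), , drop = FALSE], sigma = ph)
    extra <- vector("list", 4)
    extra[[3]] <- rbind(mg$dU, mg$dV)
    fR <- nn_forward(R, fA$out)
    cl <- cosine_loss(fR$out, Zall)
    mseg <- 2 * (fR$out - Zall) / length(Zall)
    loss_R <- cl$value + mean((fR$out - Zall)^2)
    bR <- nn_backward(R, fR$caches, cl$grad + mseg)
    bE2 <- nn_backward(E, fA$caches, bR$dX, extra_dA = extra)
    gj <- clip_grad(c(nn_flatten_grads(bE2$grads), nn_flatten_grads(bR$grads)),
                    clip)
    updj <- adam_step(c(thE, thR), gj, stJ)
    thE <- updj$theta[seq_along(thE)]
    thR <- updj$theta[-seq_along(thE)]
    stJ <- updj$state

    hist <- rbind(hist, data.frame(epoch = e, loss_E = loss_E,
                                   loss_R = loss_R, loss_M = mg$value))
    if (!is.finite(loss_E)) stop("non-finite loss at epoch ", e)
    flat <- if (abs(prev - loss_E) < conv_tol) flat + 1L else 0L
    if (e >= min_epochs && flat >= conv_patience) break
    prev <- loss_E
  }
  if (e == max_epochs && flat < conv_patience) {
    warning("no convergence by max_epochs; returning best-so-far model")
  }
  E <- nn_set_params(E, thE); R <- nn_set_params(R, thR)
  fit <- structure(list(vae = vae, E = E, R = R, genes = genes,
                        types = types, scale_to = scale_to,
                        history = hist, seed = seed),
                   class = "deconv_fit")
  fit$proportions <- predict(fit, slice)
  fit
}

#' Predict cell-type proportions for a slice
#'
#' @param object a `deconv_fit`.
#' @param newdata a [slice_data] sharing the training gene space.
#' @param ... unused.
#' @return Spots x types matrix; each row on the simplex.
#' @export
predict.deconv_fit <- function(object, newdata, ...) {
  missing_g <- setdiff(object$genes, colnames(newdata$counts))
  if (length(missing_g)) {
    stop("slice lacks model genes: ", paste(utils::head(missing_g, 5),
                                            collapse = ", "))
  }
  X <- normalize_counts(newdata$counts[, object$genes, drop = FALSE],
                        scale_to = object$scale_to)
  Z <- vae_encode(object$vae, X)
  P <- nn_forward(object$E, Z)$out
  dimnames(P) <- list(rownames(newdata$counts), object$types)
  P
}

#' @exportS3Method base::print
print.deconv_fit <- function(x, ...) {
  cat(sprintf("<deconv_fit> %d genes, %d cell types, %d training epochs\n",
              length(x$genes), length(x$types), nrow(x$history)))
  cat(sprintf("  final losses: E = %.4f, R = %.4f, MMD = %.4g\n",
              utils::tail(x$history$loss_E, 1),
              utils::tail(x$history$loss_R, 1),
              utils::tail(x$history$loss_M, 1)))
  invisible(x)
}

#' @export
coef.deconv_fit <- function(object, ...) object$proportions
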