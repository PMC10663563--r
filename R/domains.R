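#' Build a k-nearest-neighbour spatial graph
#'
#' A_uv = 1 when v is among the k nearest Euclidean neighbours of u, then
#' symmetrized with max(A, t(A)). The self-looped adjacency Ahat = A + I,
#' its degree diagonal, the normalized Laplacian
#' L = I - D^{-1/2} A D^{-1/2} and the scaled Laplacian
#' Ltilde = 2 L / lambda_max - I (eigenvalues in [-1, 1]) are derived.
#' Duplicate coordinates are handled deterministically: ties are broken by
#' spot index.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k neighbour count (default 6, the hexagonal neighbourhood of a
#'   Visium spot; use ~25 for single-cell-resolution data).
#' @return An object of class `spatial_graph` with elements `A`, `A_hat`,
#'   `D_hat`, `L`, `L_tilde`, `lambda_max`, `k`.
#' @export
build_graph <- function(coords, k = 6) {
  n <- nrow(coords)
  stopifnot(n > k)
  d2 <- cross_dist2(as.matrix(coords), as.matrix(coords))
  diag(d2) <- Inf
  A <- matrix(0, n, n)
  for (u in seq_len(n)) {
    A[u, order(d2[u, ])[seq_len(k)]] <- 1
  }
  A <- pmax(A, t(A))
  diag(A) <- 0
  A_hat <- A + diag(n)
  deg <- rowSums(A)
  dinv <- 1 / sqrt(pmax(deg, 1e-12))
  L <- diag(n) - t(A * dinv) * dinv  # D^-1/2 A D^-1/2 symmetric form
  L <- (L + t(L)) / 2
  lambda_max <- power_iteration_lmax(L)
  L_tilde <- 2 * L / lambda_max - diag(n)
  structure(list(A = A, A_hat = A_hat, D_hat = diag(rowSums(A_hat)),
                 L = L, L_tilde = L_tilde, lambda_max = lambda_max, k = k),
            class = "spatial_graph")
}

# Largest eigenvalue of a symmetric PSD matrix by power iteration, stopped
# on the residual |Mv - lam v| (a rigorous eigenvalue error bound for
# symmetric matrices); the residual is added to the estimate so the scaled
# Laplacian's spectrum cannot overshoot [-1, 1].
power_iteration_lmax <- function(M, tol = 1e-8, max_iter = 2000) {
  v <- rep(1 / sqrt(nrow(M)), nrow(M))
  lam <- 0
  res <- Inf
  for (i in seq_len(max_iter)) {
    w <- as.numeric(M %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    Mv <- as.numeric(M %*% v)
    lam <- sum(v * Mv)
    res <- sqrt(sum((Mv - lam * v)^2))
    if (res < tol * max(1, lam)) break
  }
  lam + res
}

#' Chebyshev polynomial graph filter
#'
#' Evaluates y = sum_{k=0}^{K-1} Tk(Ltilde) X theta_k with the recurrence
#' xbar_k = 2 Ltilde xbar_{k-1} - xbar_{k-2}, xbar_0 = X,
#' xbar_1 = Ltilde X. Equivalent to spectral filtering in the graph Fourier
#' basis; order K controls the receptive field (K = 2 mixes first- and
#' second-order neighbourhoods).
#'
#' @param graph a [spatial_graph] (its `L_tilde` is used) or a matrix taken
#'   as the scaled Laplacian directly.
#' @param X n x d signal matrix.
#' @param theta list of K coefficient matrices (d x d').
#' @return n x d' filtered signal.
#' @export
cheb_filter <- function(graph, X, theta) {
  Lt <- if (inherits(graph, "spatial_graph")) graph$L_tilde else graph
  X <- as.matrix(X)
  K <- length(theta)
  stopifnot(K >= 1)
  xb_prev2 <- X
  out <- X %*% theta[[1]]
  if (K >= 2) {
    xb_prev1 <- Lt %*% X
    out <- out + xb_prev1 %*% theta[[2]]
    if (K >= 3) {
      for (k in 3:K) {
        xb <- 2 * Lt %*% xb_prev1 - xb_prev2
        out <- out + xb %*% theta[[k]]
        xb_prev2 <- xb_prev1
        xb_prev1 <- xb
      }
    }
  }
  out
}

# Chebyshev basis stack: list of Tk(Ltilde) X for k = 0..K-1.
cheb_basis <- function(Lt, X, K) {
  out <- vector("list", K)
  out[[1]] <- X
  if (K >= 2) out[[2]] <- Lt %*% X
  if (K >= 3) {
    for (k in 3:K) out[[k]] <- 2 * Lt %*% out[[k - 1]] - out[[k - 2]]
  }
  out
}

# --- Chebyshev GCN ------------------------------------------------------

# Layer weights: per layer a list of K matrices plus a bias.
gcn_init <- function(dims, K, acts) {
  lapply(seq_along(acts), function(l) {
    sdv <- sqrt(2 / (dims[l] + dims[l + 1]))  # Xavier
    list(W = lapply(seq_len(K), function(k)
      matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sdv),
             dims[l], dims[l + 1])),
      b = rep(0, dims[l + 1]), act = acts[l])
  })
}

gcn_get_params <- function(net) {
  unlist(lapply(net, function(l) c(unlist(l$W), l$b)))
}

gcn_set_params <- function(net, theta) {
  pos <- 1L
  for (l in seq_along(net)) {
    for (k in seq_along(net[[l]]$W)) {
      nw <- length(net[[l]]$W[[k]])
      net[[l]]$W[[k]][] <- theta[pos:(pos + nw - 1)]
      pos <- pos + nw
    }
    nb <- length(net[[l]]$b)
    net[[l]]$b[] <- theta[pos:(pos + nb - 1)]
    pos <- pos + nb
  }
  net
}

# Forward through all layers for one slice (one Ltilde block).
gcn_forward <- function(net, Lt, X, K) {
  caches <- vector("list", length(net))
  h <- X
  for (l in seq_along(net)) {
    basis <- cheb_basis(Lt, h, K)
    z <- Reduce(`+`, Map(`%*%`, basis, net[[l]]$W))
    z <- sweep(z, 2, net[[l]]$b, "+")
    a <- nn_act(z, net[[l]]$act)
    caches[[l]] <- list(basis = basis, z = z, a = a)
    h <- a
  }
  list(out = h, caches = caches)
}

gcn_backward <- function(net, Lt, caches, dOut, K, extra_dA = NULL) {
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
    gW <- lapply(seq_len(K), function(k) crossprod(cache$basis[[k]], dZ))
    grads[[l]] <- list(W = gW, b = colSums(dZ))
    # dX = sum_k Tk(Lt) (dZ W_k'); Tk symmetric, reuse the recurrence
    tmp <- lapply(seq_len(K), function(k) dZ %*% t(net[[l]]$W[[k]]))
    dX <- tmp[[1]]
    if (K >= 2) dX <- dX + Lt %*% tmp[[2]]
    if (K >= 3) {
      # apply Tk to tmp[[k]] via the recurrence on each
      for (k in 3:K) {
        t0 <- tmp[[k]]
        t_prev2 <- t0
        t_prev1 <- Lt %*% t0
        for (kk in 3:k) {
          t_cur <- 2 * Lt %*% t_prev1 - t_prev2
          t_prev2 <- t_prev1
          t_prev1 <- t_cur
        }
        dX <- dX + t_prev1
      }
    }
    dA <- dX
  }
  list(grads = grads, dA0 = dA)
}

gcn_flatten_grads <- function(grads) {
  unlist(lapply(grads, function(g) c(unlist(g$W), g$b)))
}

# Davies-Bouldin score of a clustering (lower = crisper clusters).
davies_bouldin <- function(X, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  if (k < 2) return(NA_real_)
  cent <- t(vapply(labs, function(l) colMeans(X[labels == l, , drop = FALSE]),
                   numeric(ncol(X))))
  disp <- vapply(seq_len(k), function(i) {
    pts <- X[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  cd <- sqrt(cross_dist2(cent, cent))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (disp[i] + disp[j]) / max(cd[i, j], 1e-12), numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Identify spatial domains jointly across slices
#'
#' Fits a five-layer Chebyshev-filter graph convolutional network to the
#' per-spot cell-type compositions of one or more slices (block-diagonal
#' graphs, no cross-slice edges): the outer layers reconstruct the
#' composition (cosine reconstruction loss), the middle latent layer is
#' smoothed toward each spot's graph neighbours, and an adversarial slice
#' discriminator on the latent removes slice-level batch effects (the
#' network is trained to fool it, weight `alpha_D`). Training uses RMSProp
#' and stops when the total loss change falls below `conv_tol` and the
#' Davies-Bouldin score of a K-means clustering of the latent stops
#' improving within a patience window. Spots of all slices are then
#' clustered by K-means on the shared latent into `n_domains` domains.
#'
#' @param slices list of [slice_data]; each must carry a `$compositions`
#'   matrix (spots x cell types, shared type vocabulary), e.g. from
#'   [predict.deconv_fit] or [generate_stack3d].
#' @param n_domains number of spatial domains.
#' @param k spatial-graph neighbour count (see [build_graph]).
#' @param K Chebyshev order.
#' @param latent_dim latent layer width.
#' @param hidden_dim width of the two intermediate layers.
#' @param alpha_C,alpha_S,alpha_D loss weights (reconstruction, smoothness,
#'   adversarial); defaults 1, 1, 0.5. With a single slice the adversarial
#'   branch is disabled automatically.
#' @param lr RMSProp learning rate.
#' @param disc_steps discriminator updates per epoch; a few keep the
#'   discriminator near its optimum so its gradient on the network is
#'   informative.
#' @param max_epochs,min_epochs epoch bounds.
#' @param conv_tol threshold on the total-loss change.
#' @param patience epochs without Davies-Bouldin improvement tolerated.
#' @param seed integer seed.
#' @return An object of class `domain_fit`: `latent` (spots x latent_dim),
#'   `domains` (per-spot labels, shared vocabulary), `slice_of_spot`,
#'   `history` (losses, discriminator accuracy, DBS per epoch), the fitted
#'   networks, and the inputs' graphs.
#' @export
spatial_domains <- function(slices, n_domains, k = 6, K = 2, latent_dim = 16,
                            hidden_dim = 64, alpha_C = 1, alpha_S = 1,
                            alpha_D = 0.5, lr = 1e-3, disc_steps = 3,
                            max_epochs = 300,
                            min_epochs = 30, conv_tol = 1e-4, patience = 10,
                            seed = 1L) {
  stopifnot(n_domains >= 2, K >= 1)
  if (inherits(slices, "slice_data")) slices <- list(slices)
  comps <- lapply(slices, function(s) {
    if (is.null(s$compositions)) stop("each slice needs a $compositions matrix")
    s$compositions
  })
  n_types <- ncol(comps[[1]])
  for (cm in comps) stopifnot(ncol(cm) == n_types)
  n_slices <- length(slices)
  if (n_slices == 1 && alpha_D != 0) {
    message("single slice: adversarial branch disabled (alpha_D = 0)")
    alpha_D <- 0
  }
  set.seed(derive_seed(seed, 20L))
  graphs <- lapply(slices, function(s) build_graph(s$coords, k = k))
  ns <- vapply(comps, nrow, integer(1))
  slice_of_spot <- rep(seq_len(n_slices), ns)
  N <- sum(ns)

  dims <- c(n_types, hidden_dim, latent_dim, hidden_dim, n_types)
  acts <- c("relu", "linear", "relu", "softmax")
  net <- gcn_init(dims, K, acts)
  disc <- nn_init(c(latent_dim, 64, 64, n_slices),
                  c("relu", "relu", "softmax"), scheme = "xavier")
  thG <- gcn_get_params(net)
  thD <- nn_get_params(disc)
  stG <- rmsprop_init(length(thG), lr = lr)
  stD <- rmsprop_init(length(thD), lr = lr)
  Y <- diag(n_slices)[slice_of_spot, , drop = FALSE]  # one-hot slice labels

  # row-normalized neighbour operator per slice (for the smoothness loss)
  Anorm <- lapply(graphs, function(g) {
    rs <- pmax(rowSums(g$A), 1)
    g$A / rs
  })

  hist <- data.frame(epoch = integer(), loss_C = numeric(),
                     loss_S = numeric(), loss_D = numeric(),
                     total = numeric(), disc_acc = numeric(),
                     dbs = numeric())
  prev_total <- Inf
  best_dbs <- Inf
  stale <- 0L
  H2_pool <- NULL
  for (e in seq_len(max_epochs)) {
    net <- gcn_set_params(net, thG)
    fw <- lapply(seq_len(n_slices), function(s)
      gcn_forward(net, graphs[[s]]$L_tilde, comps[[s]], K))
    H2_pool <- do.call(rbind, lapply(fw, function(f) f$caches[[2]]$a))

    # discriminator steps on detached latent
    disc <- nn_set_params(disc, thD)
    fd <- nn_forward(disc, H2_pool)
    p_corr <- rowSums(fd$out * Y)
    loss_D <- -mean(log(pmax(p_corr, 1e-12)))
    disc_acc <- mean(max.col(fd$out, ties.method = "first") == slice_of_spot)
    if (alpha_D > 0) {
      for (ds in seq_len(disc_steps)) {
        fd <- nn_forward(disc, H2_pool)
        dP <- -(Y / pmax(fd$out, 1e-12)) / N
        bD <- nn_backward(disc, fd$caches, dP)
        updD <- rmsprop_step(thD, nn_flatten_grads(bD$grads), stD)
        thD <- updD$theta; stD <- updD$state
        disc <- nn_set_params(disc, thD)
      }
    }

    # network step: alpha_C Loss_C + alpha_S Loss_S - alpha_D Loss_D(disc)
    loss_C <- 0; loss_S <- 0
    gacc <- NULL
    # adversarial gradient wrt pooled latent (discriminator frozen)
    dH2_adv <- matrix(0, N, latent_dim)
    if (alpha_D > 0) {
      fd2 <- nn_forward(disc, H2_pool)
      dP2 <- -(Y / pmax(fd2$out, 1e-12)) / N
      bD2 <- nn_backward(disc, fd2$caches, dP2)
      dH2_adv <- -alpha_D * bD2$dX  # ascend the discriminator loss
    }
    off <- 0L
    for (s in seq_len(n_slices)) {
      f <- fw[[s]]
      Q <- comps[[s]]
      cl <- cosine_loss(f$out, Q)
      loss_C <- loss_C + cl$value * ns[s] / N
      H2 <- f$caches[[2]]$a
      Dm <- H2 - Anorm[[s]] %*% H2
      loss_S <- loss_S + sum(abs(Dm)) / (N * latent_dim)
      sg <- sign(Dm) / (N * latent_dim)
      dH2 <- alpha_S * (sg - t(Anorm[[s]]) %*% sg) +
        dH2_adv[(off + 1):(off + ns[s]), , drop = FALSE]
      extra <- vector("list", 4)
      extra[[2]] <- dH2
      bb <- gcn_backward(net, graphs[[s]]$L_tilde, f$caches,
                         alpha_C * cl$grad * (ns[s] / N) / 1, K,
                         extra_dA = extra)
      g <- gcn_flatten_grads(bb$grads)
      gacc <- if (is.null(gacc)) g else gacc + g
      off <- off + ns[s]
    }
    updG <- rmsprop_step(thG, gacc, stG)
    thG <- updG$theta; stG <- updG$state
    total <- alpha_C * loss_C + alpha_S * loss_S - alpha_D * loss_D

    km <- stats::kmeans(H2_pool, centers = min(n_domains, N - 1),
                        nstart = 5, iter.max = 50)
    dbs <- davies_bouldin(H2_pool, km$cluster)
    hist <- rbind(hist, data.frame(epoch = e, loss_C = loss_C,
                                   loss_S = loss_S, loss_D = loss_D,
                                   total = total, disc_acc = disc_acc,
                                   dbs = dbs))
    improved <- is.finite(dbs) && dbs < best_dbs - 1e-9
    if (improved) { best_dbs <- dbs; stale <- 0L } else stale <- stale + 1L
    if (e >= min_epochs && abs(prev_total - total) < conv_tol &&
        stale >= patience) break
    prev_total <- total
  }
  net <- gcn_set_params(net, thG)
  fit <- structure(list(net = net, disc = nn_set_params(disc, thD),
                        graphs = graphs, latent = H2_pool,
                        slice_of_spot = slice_of_spot, n_domains = n_domains,
                        history = hist, K = K, seed = seed,
                        slice_ids = vapply(slices, function(s) s$slice_id,
                                           character(1))),
                   class = "domain_fit")
  fit$domains <- assign_domains(fit, n_domains, seed = seed)
  fit
}

#' Cluster the shared latent into spatial domains
#'
#' K-means (10 restarts) on the pooled latent features of all slices; one
#' label vocabulary shared across slices. Cluster labels are relabelled by
#' decreasing cluster size so that the labelling is stable.
#'
#' @param fit a `domain_fit`.
#' @param n_domains number of domains.
#' @param seed integer seed for the K-means restarts.
#' @return Integer vector of per-spot domain labels in `1..n_domains`.
#' @export
assign_domains <- function(fit, n_domains = fit$n_domains, seed = fit$seed) {
  if (n_domains > nrow(fit$latent)) stop("more domains than spots")
  set.seed(derive_seed(seed, 21L))
  km <- stats::kmeans(fit$latent, centers = n_domains, nstart = 10,
                      iter.max = 100)
  relab <- match(km$cluster, order(tabulate(km$cluster), decreasing = TRUE))
  as.integer(relab)
}

#' @exportS3Method base::print
print.domain_fit <- function(x, ...) {
  cat(sprintf("<domain_fit> %d spots across %d slices, %d domains, %d epochs\n",
              nrow(x$latent), length(unique(x$slice_of_spot)),
              x$n_domains, nrow(x$history)))
  h <- utils::tail(x$history, 1)
  cat(sprintf("  final: Loss_C = %.4f, Loss_S = %.4f, Loss_D = %.4f, DBS = %.3f\n",
              h$loss_C, h$loss_S, h$loss_D, h$dbs))
  invisible(x)
}
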