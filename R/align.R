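#' Rigid 2D transform (mirror, rotation, translation)
#'
#' S' = R M S + T, with R the rotation by `theta`, M = diag(flip, 1) the
#' mirror (flip = -1 mirrors the x axis), and T the translation. Pairwise
#' distances are preserved; orientation is reversed when flip = -1.
#'
#' @param theta rotation angle in radians.
#' @param flip -1 or +1.
#' @param dx,dy translation in micrometres.
#' @return An object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(theta = 0, flip = 1, dx = 0, dy = 0) {
  stopifnot(flip %in% c(-1, 1))
  structure(list(theta = theta, flip = flip, dx = dx, dy = dy),
            class = "rigid_transform2d")
}

#' @exportS3Method base::print
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> theta = %.4f rad, flip = %+d, t = (%.1f, %.1f) um\n",
              x$theta, x$flip, x$dx, x$dy))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 2 matrix of (x, y) positions.
#' @param t a [rigid_transform2d].
#' @return The transformed n x 2 matrix.
#' @export
apply_transform <- function(coords, t) {
  coords <- as.matrix(coords)
  R <- matrix(c(cos(t$theta), sin(t$theta), -sin(t$theta), cos(t$theta)), 2, 2)
  M <- diag(c(t$flip, 1))
  out <- coords %*% t(R %*% M)
  out[, 1] <- out[, 1] + t$dx
  out[, 2] <- out[, 2] + t$dy
  colnames(out) <- c("x", "y")
  out
}

#' Invert a rigid transform
#'
#' `apply_transform(apply_transform(x, t), invert_transform(t))` returns `x`
#' to floating-point precision.
#'
#' @param t a [rigid_transform2d].
#' @return The inverse transform as a function of coordinates.
#' @export
invert_transform <- function(t) {
  function(coords) {
    coords <- as.matrix(coords)
    coords[, 1] <- coords[, 1] - t$dx
    coords[, 2] <- coords[, 2] - t$dy
    R <- matrix(c(cos(t$theta), sin(t$theta), -sin(t$theta), cos(t$theta)), 2, 2)
    M <- diag(c(t$flip, 1))
    out <- coords %*% t(solve(R %*% M))
    colnames(out) <- c("x", "y")
    out
  }
}

#' Centre slices at the origin
#'
#' Translates each slice so its coordinate centroid is (0, 0); the
#' initialization step before alignment so that rotation and translation
#' search ranges are comparable across slices.
#'
#' @param slices list of [slice_data].
#' @return The list with centred coordinates.
#' @export
center_slices <- function(slices) {
  lapply(slices, function(s) {
    s$coords <- sweep(s$coords, 2, colMeans(s$coords))
    s
  })
}

# Squared cross-distance matrix, rows of A vs rows of B.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

# Index matrix (n x k) of the k nearest rows of B for each row of A,
# ties broken by index order.
knn_index <- function(A, B, k) {
  d2 <- cross_dist2(A, B)
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

#' Mutual-nearest-neighbour overlap between two slices
#'
#' A source spot and a target spot are mutual neighbours when each lies in
#' the other's k-nearest-neighbour set across slices. Mutual pairs farther
#' apart than `max_dist` are discarded; a source spot belongs to the overlap
#' set when at least one mutual neighbour survives. By default `max_dist` is
#' the median distance of target spots to their 2k-th nearest neighbour
#' within the target slice.
#'
#' @param source_coords,target_coords n x 2 coordinate matrices.
#' @param k_mnn neighbourhood size k.
#' @param max_dist distance cut-off; `NULL` for the default rule.
#' @return A list: `overlap` (source indices), `neighbors` (per-source list
#'   of surviving mutual target indices), `max_dist`.
#' @export
overlap_set <- function(source_coords, target_coords, k_mnn = 10,
                        max_dist = NULL) {
  ns <- nrow(source_coords); nt <- nrow(target_coords)
  k <- min(k_mnn, nt, ns)
  if (is.null(max_dist)) max_dist <- default_max_dist(target_coords, k_mnn)
  d2 <- cross_dist2(source_coords, target_coords)
  kn_s <- matrix(apply(d2, 1, function(r) order(r)[seq_len(k)]),
                 ncol = k, byrow = TRUE)
  kn_t <- matrix(apply(d2, 2, function(r) order(r)[seq_len(k)]),
                 ncol = k, byrow = TRUE)
  neigh <- vector("list", ns)
  md2 <- max_dist^2
  for (i in seq_len(ns)) {
    cand <- kn_s[i, ]
    mutual <- cand[vapply(cand, function(j) i %in% kn_t[j, ], logical(1))]
    mutual <- mutual[d2[i, mutual] <= md2]
    neigh[[i]] <- mutual
  }
  ov <- which(lengths(neigh) > 0)
  list(overlap = ov, neighbors = neigh, max_dist = max_dist)
}

# Median distance to the 2k-th nearest neighbour within a slice.
default_max_dist <- function(coords, k_mnn) {
  n <- nrow(coords)
  kk <- min(2 * k_mnn, n - 1)
  d2 <- cross_dist2(coords, coords)
  diag(d2) <- Inf
  kd <- apply(d2, 1, function(r) sort(r, partial = kk)[kk])
  stats::median(sqrt(kd))
}

#' Alignment objective function between two slices
#'
#' Measures how well the (already transformed) source slice sits on the
#' target slice: the mean, over overlapped source spots, of the fraction of
#' their mutual nearest neighbours in the target sharing the same spatial
#' domain, plus the penalty f(n_o/n_j) = -|n_o/n_j - 1|^p on the
#' non-overlapping fraction (the absolute value keeps the penalty a penalty
#' for every exponent p >= 1). Bounded above by 1, attained when every
#' mutual neighbour agrees and all source spots overlap.
#'
#' @param source_coords,source_domains transformed source slice.
#' @param target_coords,target_domains target slice.
#' @param k_mnn mutual-neighbourhood size.
#' @param p penalty exponent (>= 1).
#' @param max_dist overlap cut-off; `NULL` for the default rule.
#' @return A scalar, at most 1.
#' @export
aof <- function(source_coords, source_domains, target_coords, target_domains,
                k_mnn = 10, p = 2, max_dist = NULL) {
  if (is.null(max_dist)) max_dist <- default_max_dist(target_coords, k_mnn)
  aof_cpp(as.matrix(source_coords), as.integer(source_domains),
          as.matrix(target_coords), as.integer(target_domains),
          as.integer(k_mnn), p, max_dist)
}

# Differential evolution (rand/1/bin), maximizing fn over box bounds.
# Deterministic given the ambient RNG state.
de_maximize <- function(fn, lower, upper, n_pop = 30, max_gen = 60,
                        F = 0.8, CR = 0.9, tol = 1e-8) {
  d <- length(lower)
  pop <- matrix(stats::runif(n_pop * d, lower, upper), n_pop, d, byrow = TRUE)
  fit <- apply(pop, 1, fn)
  for (gen in seq_len(max_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3)
      v <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      jr <- sample.int(d, 1)
      cross <- stats::runif(d) < CR
      cross[jr] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      fu <- fn(u)
      if (fu >= fit[i]) { pop[i, ] <- u; fit[i] <- fu }
    }
    if (max(fit) - min(fit) < tol) break
  }
  best <- which.max(fit)
  list(par = pop[best, ], value = fit[best])
}

#' Align one slice to a target slice
#'
#' Searches flip, rotation and translation maximizing the [aof] of the
#' transformed source against the target by differential evolution; the
#' mutual-nearest-neighbour overlap is recomputed from the adjusted
#' coordinates at every candidate evaluation. The continuous search runs
#' separately for flip = +1 and flip = -1 and the better optimum is kept.
#' Translation bounds are the sum of the two slices' bounding-box
#' half-diagonals, which guarantees any overlap is reachable.
#'
#' @param source_coords,source_domains source slice (centred).
#' @param target_coords,target_domains target slice (already in its final
#'   frame).
#' @param k_mnn,p see [aof].
#' @param n_pop,max_gen differential-evolution population and generations.
#' @param seed integer seed (the search is stochastic).
#' @return A list: `transform` (a [rigid_transform2d]), `aof` at the
#'   optimum, and `coords` (transformed source coordinates).
#' @export
align_pair <- function(source_coords, source_domains, target_coords,
                       target_domains, k_mnn = 10, p = 2,
                       n_pop = 30, max_gen = 60, seed = 1L) {
  if (nrow(source_coords) < k_mnn + 1 || nrow(target_coords) < k_mnn + 1) {
    stop("degenerate slice: fewer spots than k_mnn + 1")
  }
  set.seed(derive_seed(seed, 5L))
  md <- default_max_dist(target_coords, k_mnn)
  half_diag <- function(x) sqrt(sum((apply(x, 2, max) - apply(x, 2, min))^2)) / 2
  tb <- half_diag(source_coords) + half_diag(target_coords)
  lower <- c(0, -tb, -tb); upper <- c(2 * pi, tb, tb)
  best <- NULL
  for (flip in c(1, -1)) {
    obj <- function(par) {
      tr <- rigid_transform2d(par[1], flip, par[2], par[3])
      aof(apply_transform(source_coords, tr), source_domains,
          target_coords, target_domains, k_mnn, p, max_dist = md)
    }
    res <- de_maximize(obj, lower, upper, n_pop = n_pop, max_gen = max_gen)
    if (is.null(best) || res$value > best$value) {
      best <- res; best$flip <- flip
    }
  }
  tr <- rigid_transform2d(best$par[1], best$flip, best$par[2], best$par[3])
  list(transform = tr, aof = best$value,
       coords = apply_transform(source_coords, tr))
}

#' Rigidly align a stack of consecutive slices
#'
#' Centres all slices, keeps the first fixed, and aligns each subsequent
#' slice to the already-transformed previous slice with [align_pair]. The
#' aligned slices are stacked along z at `z_spacing` intervals to give a 3D
#' reconstruction.
#'
#' @param slices list of [slice_data], each carrying `$domains` labels from
#'   a shared vocabulary (e.g. [spatial_domains] output).
#' @param z_spacing slice-to-slice distance in micrometres.
#' @inheritParams align_pair
#' @return An object of class `aligned_stack`: `slices` (aligned, with
#'   updated coords and z), `transforms` (per-slice [rigid_transform2d]),
#'   `aof` (per-pair optimum), `z_spacing`.
#' @export
align_stack <- function(slices, z_spacing = 10, k_mnn = 10, p = 2,
                        n_pop = 30, max_gen = 60, seed = 1L) {
  stopifnot(length(slices) >= 2)
  for (s in slices) {
    if (is.null(s$domains)) stop("every slice needs domain labels")
  }
  slices <- center_slices(slices)
  transforms <- vector("list", length(slices))
  transforms[[1]] <- rigid_transform2d(0, 1, 0, 0)
  aofs <- rep(NA_real_, length(slices))
  for (j in 2:length(slices)) {
    res <- tryCatch(
      align_pair(slices[[j]]$coords, slices[[j]]$domains,
                 slices[[j - 1]]$coords, slices[[j - 1]]$domains,
                 k_mnn = k_mnn, p = p, n_pop = n_pop, max_gen = max_gen,
                 seed = derive_seed(seed, 100L + j)),
      error = function(e) stop(sprintf("slice %d: %s", j, conditionMessage(e))))
    slices[[j]]$coords <- res$coords
    transforms[[j]] <- res$transform
    aofs[j] <- res$aof
  }
  for (j in seq_along(slices)) slices[[j]]$z <- (j - 1) * z_spacing
  structure(list(slices = slices, transforms = transforms, aof = aofs,
                 z_spacing = z_spacing),
            class = "aligned_stack")
}

#' @exportS3Method base::print
print.aligned_stack <- function(x, ...) {
  cat(sprintf("<aligned_stack> %d aligned slices, z spacing %g um\n",
              length(x$slices), x$z_spacing))
  for (j in seq_along(x$slices)) {
    tr <- x$transforms[[j]]
    cat(sprintf("  %s: theta = %6.3f, flip = %+d, t = (%7.1f, %7.1f)%s\n",
                x$slices[[j]]$slice_id, tr$theta, tr$flip, tr$dx, tr$dy,
                if (is.na(x$aof[j])) "" else sprintf(", AOF = %.3f", x$aof[j])))
  }
  invisible(x)
}

#' 3D coordinates of an aligned stack
#'
#' @param x a `aligned_stack`.
#' @return n x 3 matrix of (x, y, z) over all slices.
#' @export
stack_coords3d <- function(x) {
  do.call(rbind, lapply(x$slices, function(s)
    cbind(s$coords, z = s$z)))
}
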