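# Evaluation statistics for every stage: deconvolution metrics and the
# accuracy-score ranking, domain metrics (Jaccard index, shifting distance,
# ARI), batch-mixing ASW, overlap percentage, spatially-variable-gene
# calling, and grid-based alignment similarity.

ssim_scalar <- function(x, y, C1 = 0.01, C2 = 0.03) {
  # min-max scale both vectors to [0, 1]: the SSIM constants assume a unit
  # dynamic range
  rng <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }
  x <- rng(x); y <- rng(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  cv <- stats::cov(x, y)
  ((2 * mx * my + C1^2) * (2 * cv + C2^2)) /
    ((mx^2 + my^2 + C1^2) * (vx + vy + C2^2))
}

jsd_vec <- function(p, q, eps = 1e-12) {
  p <- pmax(p, eps); p <- p / sum(p)
  q <- pmax(q, eps); q <- q / sum(q)
  m <- (p + q) / 2
  0.5 * sum(p * log(p / m)) + 0.5 * sum(q * log(q / m))
}

#' Per-cell-type deconvolution metrics
#'
#' Columnwise comparison of predicted and true composition matrices: Pearson
#' correlation, structural similarity (on min-max-scaled columns, constants
#' C1 = 0.01, C2 = 0.03), root-mean-square error, and Jensen-Shannon
#' divergence between the spatial distributions of each type (columns
#' renormalized over spots; natural log, so bounded by log 2).
#'
#' @param pred,truth spots x types matrices with matching type order.
#' @return data.frame with one row per type and columns `type`, `pcc`,
#'   `ssim`, `rmse`, `jsd`. PCC is `NA` for zero-variance truth columns.
#' @export
deconv_metrics <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  types <- colnames(truth)
  if (is.null(types)) types <- paste0("type", seq_len(ncol(truth)))
  out <- data.frame(type = types, pcc = NA_real_, ssim = NA_real_,
                    rmse = NA_real_, jsd = NA_real_)
  for (i in seq_len(ncol(truth))) {
    x <- truth[, i]; xh <- pred[, i]
    out$pcc[i] <- if (stats::sd(x) == 0 || stats::sd(xh) == 0) NA_real_
    else stats::cor(xh, x)
    out$ssim[i] <- ssim_scalar(xh, x)
    out$rmse[i] <- sqrt(mean((xh - x)^2))
    out$jsd[i] <- jsd_vec(xh, x)
  }
  out
}

#' Accuracy score across competing methods
#'
#' Ranks methods by their average PCC, SSIM, RMSE and JSD (PCC/SSIM
#' ascending so that the best method has the largest rank; RMSE/JSD
#' descending), averages the four ranks and normalizes by the number of
#' methods, so the best attainable score is 1. Ties receive average ranks.
#'
#' @param per_method named list of data frames as returned by
#'   [deconv_metrics] (>= 2 entries).
#' @param normalize divide mean ranks by the method count (default); set
#'   `FALSE` for raw mean ranks.
#' @return Named numeric vector of accuracy scores.
#' @export
accuracy_score <- function(per_method, normalize = TRUE) {
  stopifnot(length(per_method) >= 2)
  avg <- t(vapply(per_method, function(df)
    c(pcc = mean(df$pcc, na.rm = TRUE), ssim = mean(df$ssim, na.rm = TRUE),
      rmse = mean(df$rmse, na.rm = TRUE), jsd = mean(df$jsd, na.rm = TRUE)),
    numeric(4)))
  r_pcc <- rank(avg[, "pcc"])
  r_ssim <- rank(avg[, "ssim"])
  r_rmse <- rank(-avg[, "rmse"])
  r_jsd <- rank(-avg[, "jsd"])
  as_raw <- (r_pcc + r_ssim + r_rmse + r_jsd) / 4
  if (normalize) as_raw / length(per_method) else as_raw
}

#' Adjusted Rand index (pair-counting formula)
#'
#' @param a,b two label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(0)
  (sij - expected) / (maxi - expected)
}

#' Domain-identification metrics
#'
#' For each predicted domain d, the Jaccard index JI(d, l) =
#' |P_d intersect P_l| / |P_d union P_l| against every true layer l; the
#' layer with the largest JI is the corresponding layer, and JI(d, l_d)
#' scores the domain. The shifting distance of a spot is its distance to
#' the nearest spot of the corresponding layer (zero when it lies in it),
#' averaged per domain. ARI is computed over all spots.
#'
#' @param pred integer vector of predicted domain labels.
#' @param truth integer/character vector of true layer labels.
#' @param coords n x 2 (or n x 3) spot coordinates for the shifting
#'   distance; `NULL` skips it.
#' @return List with `per_domain` (data.frame: domain, layer, ji, sd) and
#'   `ari`.
#' @export
domain_metrics <- function(pred, truth, coords = NULL) {
  stopifnot(length(pred) == length(truth))
  doms <- sort(unique(pred))
  layers <- sort(unique(truth))
  res <- data.frame(domain = doms, layer = NA, ji = NA_real_, sd = NA_real_)
  for (i in seq_along(doms)) {
    Pd <- which(pred == doms[i])
    if (length(Pd) == 0) { warning("empty domain skipped"); next }
    ji <- vapply(layers, function(l) {
      Pl <- which(truth == l)
      length(intersect(Pd, Pl)) / length(union(Pd, Pl))
    }, numeric(1))
    best <- which.max(ji)
    res$layer[i] <- as.character(layers[best])
    res$ji[i] <- ji[best]
    if (!is.null(coords)) {
      Pl <- which(truth == layers[best])
      d2 <- cross_dist2(as.matrix(coords)[Pd, , drop = FALSE],
                        as.matrix(coords)[Pl, , drop = FALSE])
      res$sd[i] <- mean(sqrt(apply(d2, 1, min)))
    }
  }
  list(per_domain = res, ari = adjusted_rand(pred, truth))
}

#' Batch-mixing average silhouette width
#'
#' Within each cluster (domain), the silhouette of every spot is computed
#' over the *batch* (slice) labels — a(i) the mean distance to spots of the
#' same batch, b(i) the smallest mean distance to another batch — and the
#' score is the mean over clusters of mean(1 - |silhouette|). Near 1 when
#' batches are indistinguishable inside every cluster (well mixed), near 0
#' when batches separate.
#'
#' @param features n x d feature matrix (e.g. latent embeddings or raw
#'   compositions).
#' @param batch per-spot batch/slice labels (>= 2 distinct).
#' @param cluster per-spot cluster/domain labels; a single cluster by
#'   default.
#' @return Scalar ASW in `[0, 1]`.
#' @export
asw_batch <- function(features, batch, cluster = rep(1L, nrow(features))) {
  stopifnot(length(unique(batch)) >= 2)
  features <- as.matrix(features)
  ks <- unique(cluster)
  per_k <- vapply(ks, function(kk) {
    idx <- which(cluster == kk)
    bt <- batch[idx]
    if (length(unique(bt)) < 2) return(NA_real_)
    D <- sqrt(cross_dist2(features[idx, , drop = FALSE],
                          features[idx, , drop = FALSE]))
    sil <- vapply(seq_along(idx), function(i) {
      same <- which(bt == bt[i]); same <- setdiff(same, i)
      if (length(same) == 0) return(NA_real_)
      a <- mean(D[i, same])
      b <- min(vapply(setdiff(unique(bt), bt[i]), function(o)
        mean(D[i, bt == o]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(1 - abs(sil), na.rm = TRUE)
  }, numeric(1))
  mean(per_k, na.rm = TRUE)
}

#' Percentage overlap of a domain with an annotation
#'
#' PO_d = |annotated intersect domain| / |domain|.
#'
#' @param annotated_spots,domain_spots spot identifier sets.
#' @return Scalar in `[0, 1]`.
#' @export
percentage_overlap <- function(annotated_spots, domain_spots) {
  if (length(domain_spots) == 0) stop("empty domain")
  length(intersect(annotated_spots, domain_spots)) / length(domain_spots)
}

# Vectorized two-sided Wilcoxon rank-sum p-values, group vs rest, all genes
# at once (normal approximation with tie correction).
ranksum_test <- function(X, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  ranks <- apply(X, 2, rank)
  rs <- colSums(ranks[in_group, , drop = FALSE])
  mu <- n1 * (n + 1) / 2
  tie_term <- apply(X, 2, function(v) {
    t <- table(v); sum(t^3 - t)
  })
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (rs - mu) / sqrt(pmax(sig2, 1e-300))
  p <- 2 * stats::pnorm(-abs(z))
  list(p = p, z = z)
}

#' Spatially variable genes per domain
#'
#' For each domain, a two-sided Wilcoxon rank-sum test of every gene
#' (domain vs all other spots) on normalized expression, with a
#' log fold-change filter: genes with log(fold-change) > `lfc_cut` and
#' p < `p_cut` make the domain's list. The per-gene p-value ranking (best
#' across domains) supports ROC construction against a known gene set.
#'
#' @param expr spots x genes normalized expression matrix.
#' @param domains per-spot domain labels; domains with < 3 spots are
#'   skipped.
#' @param lfc_cut natural-log fold-change threshold (default 0.5).
#' @param p_cut p-value threshold (default 0.01).
#' @return List with `per_domain` (named list of gene vectors) and
#'   `p_values` (gene x domain matrix).
#' @export
find_svgs <- function(expr, domains, lfc_cut = 0.5, p_cut = 0.01) {
  expr <- as.matrix(expr)
  doms <- sort(unique(domains))
  pv <- matrix(NA_real_, ncol(expr), length(doms),
               dimnames = list(colnames(expr), as.character(doms)))
  lists <- stats::setNames(vector("list", length(doms)), as.character(doms))
  for (i in seq_along(doms)) {
    grp <- domains == doms[i]
    if (sum(grp) < 3) { lists[[i]] <- character(0); next }
    rt <- ranksum_test(expr, grp)
    pv[, i] <- rt$p
    m1 <- colMeans(expr[grp, , drop = FALSE])
    m0 <- colMeans(expr[!grp, , drop = FALSE])
    lfc <- log((m1 + 1e-9) / (m0 + 1e-9))
    lists[[i]] <- colnames(expr)[lfc > lfc_cut & rt$p < p_cut]
  }
  list(per_domain = lists, p_values = pv)
}

#' Grid-based similarity of two aligned slices
#'
#' Divides the common bounding-box area of the two slices into
#' `grid` x `grid` cells, averages the cell-type composition of the spots
#' in each cell, and compares the two gridded composition fields per type
#' by SSIM and Pearson correlation (cells empty in either slice are
#' dropped). Returns the mean over types.
#'
#' @param coords_a,comp_a,coords_b,comp_b coordinates and spots x types
#'   compositions of the two slices.
#' @param grid cells per axis (default 10).
#' @return List with `ssim` and `pcc`.
#' @export
grid_similarity <- function(coords_a, comp_a, coords_b, comp_b, grid = 10) {
  lo <- pmax(apply(coords_a, 2, min), apply(coords_b, 2, min))
  hi <- pmin(apply(coords_a, 2, max), apply(coords_b, 2, max))
  if (any(hi <= lo)) stop("slices share no common area")
  cell_means <- function(coords, comp) {
    ix <- findInterval(coords[, 1], seq(lo[1], hi[1], length.out = grid + 1),
                       rightmost.closed = TRUE)
    iy <- findInterval(coords[, 2], seq(lo[2], hi[2], length.out = grid + 1),
                       rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= grid & iy >= 1 & iy <= grid
    cell <- (ix - 1) * grid + iy
    out <- matrix(NA_real_, grid * grid, ncol(comp))
    for (cc in unique(cell[ok])) {
      out[cc, ] <- colMeans(comp[ok & cell == cc, , drop = FALSE])
    }
    out
  }
  ga <- cell_means(coords_a, comp_a)
  gb <- cell_means(coords_b, comp_b)
  shared <- stats::complete.cases(ga) & stats::complete.cases(gb)
  if (sum(shared) < 3) stop("too few shared grid cells")
  per_type <- vapply(seq_len(ncol(ga)), function(t) {
    x <- ga[shared, t]; y <- gb[shared, t]
    c(ssim = ssim_scalar(x, y),
      pcc = if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
      else stats::cor(x, y))
  }, numeric(2))
  list(ssim = mean(per_type["ssim", ], na.rm = TRUE),
       pcc = mean(per_type["pcc", ], na.rm = TRUE))
}

#' Least-squares affine registration to ground truth
#'
#' Fits the affine map sending ground-truth coordinates to aligned
#' coordinates over shared spots (>= 3, non-collinear) and returns it so
#' the *next* aligned slice can be carried into the ground-truth frame
#' before grid comparison (the registration absorbs the global frame
#' ambiguity of a stack alignment).
#'
#' @param aligned n x 2 aligned coordinates.
#' @param truth n x 2 ground-truth coordinates of the same spots.
#' @return List with `M` (2 x 3 affine matrix, truth -> aligned),
#'   `inverse` (function mapping aligned-frame points into the truth
#'   frame), and `residual` (RMS fit error).
#' @export
register_to_truth <- function(aligned, truth) {
  aligned <- as.matrix(aligned); truth <- as.matrix(truth)
  stopifnot(nrow(aligned) == nrow(truth), nrow(aligned) >= 3)
  X <- cbind(truth, 1)
  if (qr(X)$rank < 3) stop("rank-deficient registration (collinear points)")
  B <- qr.solve(X, aligned)        # 3 x 2: truth -> aligned
  fitted <- X %*% B
  resid <- sqrt(mean((fitted - aligned)^2))
  Maff <- t(B)                     # 2 x 3
  A <- Maff[, 1:2]; tvec <- Maff[, 3]
  inv <- function(pts) {
    sweep(as.matrix(pts), 2, tvec) %*% t(solve(A))
  }
  list(M = Maff, inverse = inv, residual = resid)
}
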