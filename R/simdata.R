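#' Per-spot cell-type sampling probabilities
#'
#' Maps the reference type frequencies f_t to the sampling distribution used
#' for one pseudo-spot, chosen by a uniform draw r_c: the frequencies
#' themselves (r_c < 1/3), their normalized reciprocals (1/3 <= r_c < 2/3,
#' over-sampling rare types), or their normalized square roots
#' (2/3 <= r_c < 1, a compromise between the two). Types with f_t = 0 are
#' excluded before reciprocal normalization rather than dividing by zero.
#'
#' @param f per-type frequency vector on the simplex.
#' @param r_c scalar in `[0, 1)`.
#' @return A probability vector of the same length as `f`, summing to 1.
#' @export
sampling_probs <- function(f, r_c) {
  stopifnot(length(r_c) == 1, r_c >= 0, r_c < 1, all(f >= 0))
  if (abs(sum(f) - 1) > 1e-8) stop("f must lie on the simplex")
  if (r_c < 1 / 3) {
    p <- f
  } else if (r_c < 2 / 3) {
    p <- numeric(length(f))
    pos <- f > 0
    p[pos] <- (1 / f[pos]) / sum(1 / f[pos])
  } else {
    p <- sqrt(f) / sum(sqrt(f))
  }
  names(p) <- names(f)
  p
}

#' Exact count thinning to a target total
#'
#' Draws a multivariate-hypergeometric subsample of the molecules in one
#' spot: `target_total` molecules are kept without replacement, so expected
#' gene proportions are preserved, no count increases, and the output total
#' equals the target exactly. Implemented as sequential conditional
#' hypergeometric draws per gene.
#'
#' @param counts_row non-negative integer vector.
#' @param target_total integer; if it exceeds `sum(counts_row)` the row is
#'   returned unchanged with a warning.
#' @return Integer vector of the same length with total `target_total`.
#' @export
downsample_counts <- function(counts_row, target_total) {
  counts_row <- as.integer(round(counts_row))
  total <- sum(counts_row)
  target_total <- as.integer(round(target_total))
  if (target_total > total) {
    warning("target total exceeds available counts; row returned unchanged")
    return(counts_row)
  }
  if (target_total == total) return(counts_row)
  out <- integer(length(counts_row))
  remaining <- total
  need <- target_total
  for (g in seq_along(counts_row)) {
    if (need == 0L) break
    cg <- counts_row[g]
    if (cg == 0L) { remaining <- remaining - cg; next }
    x <- stats::rhyper(1, m = cg, n = remaining - cg, k = need)
    out[g] <- x
    need <- need - x
    remaining <- remaining - cg
  }
  out
}

#' Estimate a downsampling target from a real slice
#'
#' @param slice a [slice_data]; per-spot totals give the mean and sd of the
#'   sequencing-depth distribution that simulated spots should match.
#' @return A list with `mu_L` and `sigma_L`.
#' @export
estimate_depth_target <- function(slice) {
  tot <- rowSums(slice$counts)
  list(mu_L = mean(tot), sigma_L = stats::sd(tot))
}

#' Simulate pseudo-spots from a single-cell reference
#'
#' Builds the training set for spot deconvolution. For each pseudo-spot the
#' number of cells N_c and of cell types N_t are drawn from normal
#' distributions (defaults mu_c = 10, delta_c = 5, mu_t = mu_c/2,
#' delta_t = delta_c/2), rounded and clamped to N_c >= 1 and
#' 1 <= N_t <= min(N_c, n types). A per-spot draw r_c selects the type
#' sampling law (see [sampling_probs]); N_t types are drawn without
#' replacement by that law, the law is renormalized over the chosen types,
#' and N_c cells are sampled with replacement from those types. Their counts
#' are summed into an "original spot" and the sampled type counts divided by
#' N_c are the ground-truth proportions. Finally each spot is thinned to a
#' depth drawn from N(mu_L, sigma_L) (see [downsample_counts]) so simulated
#' depths match the target slice.
#'
#' @param ref an [sc_reference].
#' @param n_spots number of pseudo-spots.
#' @param mu_c,delta_c,mu_t,delta_t normal parameters for cells/types per
#'   spot; `mu_t`/`delta_t` default to half of `mu_c`/`delta_c`.
#' @param depth_target optional list `(mu_L, sigma_L)` from
#'   [estimate_depth_target]; `NULL` skips downsampling.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A list with `counts` (n_spots x genes), `proportions` (n_spots x
#'   types, rows sum to 1), and `n_cells` (per-spot N_c).
#' @export
simulate_pseudospots <- function(ref, n_spots, mu_c = 10, delta_c = 5,
                                 mu_t = mu_c / 2, delta_t = delta_c / 2,
                                 depth_target = NULL, seed = 1L) {
  stopifnot(inherits(ref, "sc_reference"), n_spots >= 1, mu_c > 0)
  set.seed(derive_seed(seed, 1L))
  types <- levels(ref$cell_types)
  n_types <- length(types)
  cells_by_type <- split(seq_len(nrow(ref$counts)), ref$cell_types)
  f <- ref$type_freq
  counts <- matrix(0, n_spots, ncol(ref$counts),
                   dimnames = list(paste0("spot", seq_len(n_spots)),
                                   colnames(ref$counts)))
  props <- matrix(0, n_spots, n_types,
                  dimnames = list(rownames(counts), types))
  n_cells <- integer(n_spots)
  warned <- FALSE
  for (i in seq_len(n_spots)) {
    N_c <- max(1L, as.integer(round(stats::rnorm(1, mu_c, delta_c))))
    N_t <- as.integer(round(stats::rnorm(1, mu_t, delta_t)))
    if (N_t > min(N_c, n_types) && n_types < N_t && !warned) {
      warning("requested more types per spot than available; clamped")
      warned <- TRUE
    }
    N_t <- min(max(1L, N_t), N_c, n_types)
    r_c <- stats::runif(1)
    P_t <- sampling_probs(f, r_c)
    avail <- which(P_t > 0)
    N_t <- min(N_t, length(avail))
    chosen <- if (length(avail) == 1) avail else
      sample(avail, N_t, prob = P_t[avail])
    p_sub <- P_t[chosen] / sum(P_t[chosen])
    type_draw <- if (length(chosen) == 1) rep(chosen, N_c) else
      sample(chosen, N_c, replace = TRUE, prob = p_sub)
    cell_idx <- vapply(type_draw, function(t) {
      pool <- cells_by_type[[types[t]]]
      pool[sample.int(length(pool), 1)]
    }, integer(1))
    counts[i, ] <- colSums(ref$counts[cell_idx, , drop = FALSE])
    tc <- tabulate(type_draw, nbins = n_types)
    props[i, ] <- tc / N_c
    n_cells[i] <- N_c
  }
  if (!is.null(depth_target)) {
    for (i in seq_len(n_spots)) {
      tot <- sum(counts[i, ])
      tgt <- as.integer(round(stats::rnorm(1, depth_target$mu_L,
                                           depth_target$sigma_L)))
      tgt <- min(max(1L, tgt), tot)
      counts[i, ] <- downsample_counts(counts[i, ], tgt)
    }
  }
  list(counts = counts, proportions = props, n_cells = n_cells)
}

#' Generate a synthetic single-cell reference with planted markers
#'
#' Counts follow a negative-binomial model with lognormal baseline gene
#' means shared across types; each type over-expresses its own disjoint
#' marker block by `marker_logfc` (log2 fold-change). Useful as a fixture
#' whose marker structure and composition are known exactly.
#'
#' @param n_types,n_genes,n_cells dimensions; cells are split evenly across
#'   types (remainder to the first types).
#' @param marker_genes_per_type size of each disjoint marker block; requires
#'   `n_types * marker_genes_per_type <= n_genes`.
#' @param marker_logfc log2 fold-change of markers in their own type.
#' @param nb_size negative-binomial size (inverse dispersion).
#' @param seed integer seed.
#' @return An [sc_reference] with attribute `"markers"`, a list of marker
#'   gene names per type.
#' @export
generate_reference <- function(n_types = 5, n_genes = 200, n_cells = 500,
                               marker_genes_per_type = 10, marker_logfc = 2,
                               nb_size = 2, seed = 1L) {
  stopifnot(n_types * marker_genes_per_type <= n_genes)
  set.seed(derive_seed(seed, 2L))
  base_mu <- exp(stats::rnorm(n_genes, log(2), 0.6))
  genes <- paste0("g", seq_len(n_genes))
  markers <- lapply(seq_len(n_types), function(t)
    genes[((t - 1) * marker_genes_per_type + 1):(t * marker_genes_per_type)])
  names(markers) <- paste0("type", seq_len(n_types))
  per <- diff(round(seq(0, n_cells, length.out = n_types + 1)))
  labels <- rep(names(markers), per)
  counts <- matrix(0L, n_cells, n_genes, dimnames = list(
    paste0("cell", seq_len(n_cells)), genes))
  row <- 1L
  for (t in seq_len(n_types)) {
    mu <- base_mu
    idx <- ((t - 1) * marker_genes_per_type + 1):(t * marker_genes_per_type)
    mu[idx] <- mu[idx] * 2^marker_logfc
    for (i in seq_len(per[t])) {
      counts[row, ] <- stats::rnbinom(n_genes, mu = mu, size = nb_size)
      row <- row + 1L
    }
  }
  ref <- sc_reference(counts, labels)
  attr(ref, "markers") <- markers
  ref
}

# Fixed, distinct per-domain composition profiles: domain d concentrates
# mass on type d with a smooth tail over the others.
domain_profiles <- function(n_domains, n_types) {
  P <- matrix(0, n_domains, n_types)
  for (d in seq_len(n_domains)) {
    w <- exp(-0.9 * abs(seq_len(n_types) - d))
    P[d, ] <- w / sum(w)
  }
  rownames(P) <- paste0("domain", seq_len(n_domains))
  colnames(P) <- paste0("type", seq_len(n_types))
  P
}

#' Generate a 3D stack of slices with planted spatial domains
#'
#' Emulates serial sections of a tissue block: spots lie on a jittered grid
#' inside a rectangle (default 1400 x 1700 um), domains are spatially
#' contiguous regions whose boundaries drift smoothly with z (parallel bands
#' plus, for `layout = "bands_disc"`, an off-centre disc that breaks mirror
#' and rotational symmetry), and each spot carries a cell-type composition
#' drawn around its domain profile in logit space. An optional slice-level
#' batch shift perturbs compositions of whole slices, for testing batch-
#' effect removal.
#'
#' @param n_slices number of consecutive slices.
#' @param spots_per_slice approximate spots per slice.
#' @param n_domains number of planted domains (>= 2).
#' @param n_types number of cell types in the composition vectors.
#' @param extent_um c(width, height) of the tissue rectangle in um.
#' @param thickness_um z spacing between consecutive slices in um.
#' @param layout `"bands_disc"` (default) or `"bands"`.
#' @param noise_sd sd of logit-space composition noise within a domain.
#' @param batch_shift sd of the per-slice logit-space shift (0 = none).
#' @param seed integer seed.
#' @return A list of [slice_data] objects; each has `$domains` truth and an
#'   extra `$compositions` matrix (spots x types, rows on the simplex).
#' @export
generate_stack3d <- function(n_slices = 3, spots_per_slice = 300,
                             n_domains = 3, n_types = n_domains + 2,
                             extent_um = c(1400, 1700), thickness_um = 10,
                             layout = c("bands_disc", "bands"),
                             noise_sd = 0.15, batch_shift = 0, seed = 1L) {
  stopifnot(n_domains >= 2, n_slices >= 1)
  layout <- match.arg(layout)
  set.seed(derive_seed(seed, 3L))
  prof <- domain_profiles(n_domains, n_types)
  nx <- max(2L, round(sqrt(spots_per_slice * extent_um[1] / extent_um[2])))
  ny <- max(2L, ceiling(spots_per_slice / nx))
  step <- c(extent_um[1] / nx, extent_um[2] / ny)
  slices <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    gx <- rep(seq_len(nx), ny) - 0.5
    gy <- rep(seq_len(ny), each = nx) - 0.5
    x <- gx * step[1] + stats::rnorm(nx * ny, 0, step[1] * 0.15)
    y <- gy * step[2] + stats::rnorm(nx * ny, 0, step[2] * 0.15)
    keep <- sample.int(nx * ny, min(spots_per_slice, nx * ny))
    x <- x[keep]; y <- y[keep]
    zfrac <- if (n_slices == 1) 0 else (s - 1) / (n_slices - 1)
    # curved laminae: band boundaries follow a gentle sine in x (real
    # cortical layers are curved, not straight) and drift smoothly with depth
    shift <- 0.12 * extent_um[2] * zfrac
    wave <- 0.08 * extent_um[2] *
      sin(2 * pi * x / extent_um[1] + 0.8 + 0.5 * zfrac)
    yb <- y - wave
    edges <- seq(0, extent_um[2], length.out = n_domains + 1) + shift
    dom <- findInterval(yb, edges[-c(1, length(edges))]) + 1L
    dom[dom < 1L] <- 1L; dom[dom > n_domains] <- n_domains
    if (layout == "bands_disc") {
      cx <- 0.30 * extent_um[1] + 0.1 * extent_um[1] * zfrac
      cy <- 0.65 * extent_um[2]
      r <- 0.18 * min(extent_um) * (1 - 0.3 * zfrac)
      dom[(x - cx)^2 + (y - cy)^2 < r^2] <- n_domains
    }
    shift_vec <- if (batch_shift > 0)
      stats::rnorm(n_types, 0, batch_shift) else numeric(n_types)
    logit <- log(prof[dom, , drop = FALSE]) +
      matrix(stats::rnorm(length(dom) * n_types, 0, noise_sd),
             ncol = n_types) +
      matrix(shift_vec, length(dom), n_types, byrow = TRUE)
    comp <- exp(logit)
    comp <- comp / rowSums(comp)
    colnames(comp) <- colnames(prof)
    counts <- matrix(0L, length(dom), 1, dimnames = list(NULL, "dummy"))
    sl <- slice_data(counts, cbind(x, y),
                     slice_id = sprintf("slice%02d", s),
                     z = (s - 1) * thickness_um, domains = dom)
    sl$compositions <- comp
    slices[[s]] <- sl
  }
  slices
}

#' Perturb a slice stack by known rigid transforms and edge crops
#'
#' Emulates what tissue sectioning does to consecutive slices: every slice
#' except the first is randomly mirrored (probability 1/2), rotated by a
#' uniform angle in `[0, 2*pi)`, translated by 300-2000 um (random sign) per
#' axis, and cropped from its edge by removing the `crop_ratio` fraction of
#' spots with the largest projection onto a random direction. True
#' transforms and retained-spot indices are recorded so the perturbation is
#' exactly invertible on retained spots.
#'
#' @param stack list of [slice_data] (e.g. from [generate_stack3d]).
#' @param crop_ratio fraction of spots removed per slice, in `[0, 0.25]`.
#' @param seed integer seed.
#' @return A list with `slices` (perturbed) and `record`: per-slice list of
#'   `transform` (a [rigid_transform2d]) and `kept` (retained spot indices).
#' @export
perturb_stack <- function(stack, crop_ratio = 0, seed = 1L) {
  stopifnot(crop_ratio >= 0, crop_ratio <= 0.25)
  set.seed(derive_seed(seed, 4L))
  out <- vector("list", length(stack))
  rec <- vector("list", length(stack))
  for (j in seq_along(stack)) {
    sl <- stack[[j]]
    n <- nrow(sl$coords)
    if (j == 1) {
      tr <- rigid_transform2d(0, 1, 0, 0)
      kept <- seq_len(n)
    } else {
      flip <- sample(c(-1, 1), 1)
      theta <- stats::runif(1, 0, 2 * pi)
      tmag <- stats::runif(2, 300, 2000) * sample(c(-1, 1), 2, replace = TRUE)
      tr <- rigid_transform2d(theta, flip, tmag[1], tmag[2])
      ang <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(ang), sin(ang))
      proj <- sl$coords %*% u
      n_drop <- round(crop_ratio * n)
      kept <- if (n_drop > 0)
        order(proj, decreasing = TRUE)[-seq_len(n_drop)] else seq_len(n)
      kept <- sort(kept)
    }
    sl$counts <- sl$counts[kept, , drop = FALSE]
    sl$coords <- apply_transform(sl$coords[kept, , drop = FALSE], tr)
    if (!is.null(sl$domains)) sl$domains <- sl$domains[kept]
    if (!is.null(sl$compositions))
      sl$compositions <- sl$compositions[kept, , drop = FALSE]
    out[[j]] <- sl
    rec[[j]] <- list(transform = tr, kept = kept)
  }
  list(slices = out, record = rec)
}
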