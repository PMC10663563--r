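test_that("sampling probabilities follow the three frequency branches", {
  f <- c(0.5, 0.3, 0.2)
  expect_equal(sampling_probs(f, 0.1), f)
  expect_equal(sampling_probs(f, 0.5), (1 / f) / sum(1 / f), tolerance = 1e-12)
  expect_equal(sampling_probs(f, 0.5), c(0.1935484, 0.3225806, 0.4838710),
               tolerance = 1e-6)
  expect_equal(sampling_probs(f, 0.9), sqrt(f) / sum(sqrt(f)),
               tolerance = 1e-12)
  expect_equal(sampling_probs(f, 0.9), c(0.4154459, 0.3218030, 0.2627511),
               tolerance = 1e-6)
  # zero-frequency types are excluded before inversion, not divided by
  f0 <- c(0.6, 0.4, 0)
  p <- sampling_probs(f0, 0.5)
  expect_equal(p[3], 0)
  expect_equal(sum(p), 1)
  expect_true(all(is.finite(p)))
})

test_that("count thinning is exact, monotone, and unbiased", {
  expect_identical(downsample_counts(c(10L, 0L, 30L), 40), c(10L, 0L, 30L))
  set.seed(1)
  expect_equal(sum(downsample_counts(c(7L, 3L, 12L), 0)), 0)
  x <- c(40L, 0L, 25L, 100L)
  for (i in 1:20) {
    y <- downsample_counts(x, 60)
    expect_true(all(y <= x))
    expect_equal(sum(y), 60)
  }
  expect_warning(z <- downsample_counts(c(5L, 5L), 20), "unchanged")
  expect_identical(z, c(5L, 5L))
  # thinning expectation: (1000, 1000) to 1000 gives per-gene mean ~500
  set.seed(42)
  reps <- t(replicate(500, downsample_counts(c(1000L, 1000L), 1000)))
  se <- sd(reps[, 1]) / sqrt(500)
  expect_lt(abs(mean(reps[, 1]) - 500), 3 * se + 1e-9)
})

test_that("pseudo-spot simulation honours its sampling scheme", {
  ref <- tiny_reference(n_types = 5, n_genes = 100, n_cells = 250)
  sim <- suppressWarnings(simulate_pseudospots(ref, 1000, seed = 3))
  expect_equal(unname(rowSums(sim$proportions)), rep(1, 1000),
               tolerance = 1e-12)
  expect_lt(abs(mean(sim$n_cells) - 10), 0.5)
  # proportions are exact multiples of 1/N_c
  i <- which(sim$n_cells == sim$n_cells[1])[1]
  expect_equal(sim$proportions[i, ] * sim$n_cells[i],
               round(sim$proportions[i, ] * sim$n_cells[i]),
               tolerance = 1e-9)

  sim2 <- suppressWarnings(simulate_pseudospots(ref, 1000, seed = 3))
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$proportions, sim2$proportions)

  # degenerate single-type reference
  ref1 <- sc_reference(matrix(rpois(40, 4), 10, 4), rep("only", 10))
  s1 <- suppressWarnings(simulate_pseudospots(ref1, 20, seed = 4))
  expect_equal(unname(s1$proportions[, 1]), rep(1, 20))

  # depth targets are matched after thinning
  tgt <- list(mu_L = 80, sigma_L = 5)
  s2 <- suppressWarnings(simulate_pseudospots(ref, 200, depth_target = tgt,
                                              seed = 5))
  expect_lt(abs(mean(rowSums(s2$counts)) - 80), 5)
})

test_that("reference generator plants recoverable markers", {
  ref <- generate_reference(n_types = 5, n_genes = 150, n_cells = 400,
                            marker_genes_per_type = 10, marker_logfc = 2,
                            seed = 8)
  planted <- attr(ref, "markers")
  found <- select_markers(ref, n_markers = 10)
  hit <- mean(unlist(planted) %in% found)
  expect_gte(hit, 0.9)
  ref2 <- generate_reference(n_types = 5, n_genes = 150, n_cells = 400,
                             marker_genes_per_type = 10, marker_logfc = 2,
                             seed = 8)
  expect_identical(ref$counts, ref2$counts)
})

test_that("null reference (zero fold-change) has exchangeable types", {
  # planted "markers" with no effect should rarely reach rank-sum
  # significance at alpha = 0.01
  pvals <- replicate(10, {
    ref <- generate_reference(n_types = 2, n_genes = 30, n_cells = 80,
                              marker_genes_per_type = 5, marker_logfc = 0,
                              seed = sample.int(1e6, 1))
    g <- attr(ref, "markers")[[1]][1]
    suppressWarnings(stats::wilcox.test(
      ref$counts[ref$cell_types == "type1", g],
      ref$counts[ref$cell_types == "type2", g])$p.value)
  })
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("3D stacks carry contiguous domains and batch structure", {
  stack <- generate_stack3d(n_slices = 3, spots_per_slice = 200,
                            n_domains = 3, seed = 9)
  expect_length(stack, 3)
  for (s in stack) {
    expect_equal(sort(unique(s$domains)), 1:3)
    expect_equal(unname(rowSums(s$compositions)),
                 rep(1, nrow(s$compositions)), tolerance = 1e-9)
  }
  # spatial contiguity: most spots of each band sit in one graph component
  s <- stack[[1]]
  g <- build_graph(s$coords, k = 8)
  for (d in 1:3) {
    idx <- which(s$domains == d)
    A <- g$A[idx, idx]
    # BFS from the first spot of the domain
    seen <- rep(FALSE, length(idx)); seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    expect_gte(mean(seen), 0.9)
  }
  # batch shift lowers raw-composition mixing
  st0 <- generate_stack3d(n_slices = 2, spots_per_slice = 150, batch_shift = 0,
                          seed = 10)
  st1 <- generate_stack3d(n_slices = 2, spots_per_slice = 150,
                          batch_shift = 0.6, seed = 10)
  batch <- rep(1:2, each = 150)
  comp0 <- do.call(rbind, lapply(st0, `[[`, "compositions"))
  comp1 <- do.call(rbind, lapply(st1, `[[`, "compositions"))
  dom0 <- unlist(lapply(st0, `[[`, "domains"))
  dom1 <- unlist(lapply(st1, `[[`, "domains"))
  expect_gt(asw_batch(comp0, batch, dom0), asw_batch(comp1, batch, dom1))
})

test_that("stack perturbation is recorded exactly and crops as stated", {
  stack <- generate_stack3d(n_slices = 3, spots_per_slice = 100, seed = 13)
  pert <- perturb_stack(stack, crop_ratio = 0.25, seed = 14)
  expect_equal(pert$slices[[1]]$coords, stack[[1]]$coords)
  for (j in 2:3) {
    rec <- pert$record[[j]]
    expect_lte(abs(length(rec$kept) - 75), 1)
    back <- invert_transform(rec$transform)(pert$slices[[j]]$coords)
    expect_lt(max(abs(back - stack[[j]]$coords[rec$kept, ])), 1e-9)
  }
  pert2 <- perturb_stack(stack, crop_ratio = 0.25, seed = 14)
  expect_equal(pert$slices[[2]]$coords, pert2$slices[[2]]$coords)
})
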