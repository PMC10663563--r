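test_that("squared MMD matches hand and brute-force evaluation", {
  expect_error(mmd2(matrix(numeric(0), 0, 1), matrix(1, 1, 1), 1), "empty")
  u <- matrix(0, 1, 1); v <- matrix(1, 1, 1)
  expect_equal(mmd2(u, v, 1), 2 - 2 * exp(-1), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:5) {
    U <- matrix(rnorm(sample(2:5, 1) * 3), ncol = 3)
    V <- matrix(rnorm(sample(2:5, 1) * 3), ncol = 3)
    expect_equal(mmd2(U, V, 2.5), mmd2_brute(U, V, 2.5), tolerance = 1e-10)
    expect_equal(mmd2(U, V, 2.5), mmd2(V, U, 2.5), tolerance = 1e-12)
  }
  W <- matrix(rnorm(12), 4, 3)
  expect_lt(abs(mmd2(W, W, 3)), 1e-12)
})

test_that("proportion loss is a divergence with the stated form", {
  t2 <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, byrow = TRUE)
  expect_lt(proportion_loss(t2, t2), 1e-10)
  # direct evaluation for pred (1,0) vs truth (.5,.5) with the 1e-8 floor
  pred <- matrix(c(1, 0), 1)
  tr <- matrix(c(0.5, 0.5), 1)
  cos_term <- 1 - 0.5 / (1 * sqrt(0.5))
  kl_term <- 0.5 * log(0.5 / 1) + 0.5 * log(0.5 / 1e-8)
  expect_equal(proportion_loss(pred, tr), cos_term + kl_term,
               tolerance = 1e-6)
  # joint row permutation leaves the average unchanged
  set.seed(6)
  P <- matrix(runif(12), 4); P <- P / rowSums(P)
  Q <- matrix(runif(12), 4); Q <- Q / rowSums(Q)
  perm <- c(3, 1, 4, 2)
  expect_equal(proportion_loss(P, Q), proportion_loss(P[perm, ], Q[perm, ]))
  expect_gte(proportion_loss(P, Q), 0)
})

test_that("marker selection returns the union of per-type top genes", {
  ref <- tiny_reference(n_types = 3, n_genes = 60, n_cells = 120)
  mk <- select_markers(ref, n_markers = 5)
  expect_lte(length(mk), 15)
  planted <- unlist(attr(ref, "markers"))
  expect_gte(mean(planted %in% mk), 0.8)
})

test_that("deconvolution collapses to the only type in a degenerate reference", {
  set.seed(7)
  counts <- matrix(rpois(60 * 40, 3), 60, 40,
                   dimnames = list(NULL, paste0("g", 1:40)))
  ref <- sc_reference(counts, rep("only", 60))
  sl <- slice_data(matrix(rpois(10 * 40, 30), 10, 40,
                          dimnames = list(NULL, paste0("g", 1:40))),
                   cbind(1:10, 1:10))
  fit <- suppressWarnings(
    deconvolute(ref, sl, n_sim_spots = 50, n_markers_per_type = 10,
           predictor_hidden = 16, vae_hidden = 16, vae_latent = 8,
           vae_epochs = 5, max_epochs = 5, min_epochs = 1, seed = 1))
  expect_equal(unname(fit$proportions[, 1]), rep(1, 10), tolerance = 1e-6)
})

test_that("fits are bit-reproducible under a fixed seed", {
  ref <- tiny_reference(n_types = 3, n_genes = 60, n_cells = 120)
  sim <- suppressWarnings(simulate_pseudospots(ref, 40, seed = 2))
  sl <- slice_data(sim$counts, cbind(seq_len(40), seq_len(40)))
  args <- list(ref = ref, slice = sl, n_sim_spots = 60,
               n_markers_per_type = 8, predictor_hidden = 32,
               vae_hidden = 16, vae_latent = 8, vae_epochs = 10,
               max_epochs = 12, min_epochs = 12, seed = 99)
  f1 <- suppressWarnings(do.call(deconvolute, args))
  f2 <- suppressWarnings(do.call(deconvolute, args))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$proportions, f2$proportions)
})

test_that("predictions respect the softmax contract and gene checks", {
  ref <- tiny_reference(n_types = 3, n_genes = 60, n_cells = 120)
  sim <- suppressWarnings(simulate_pseudospots(ref, 30, seed = 3))
  counts <- sim$counts
  counts[2, ] <- counts[1, ]  # duplicate spot
  sl <- slice_data(counts, cbind(seq_len(30), seq_len(30)))
  fit <- suppressWarnings(
    deconvolute(ref, sl, n_sim_spots = 60, n_markers_per_type = 8,
           predictor_hidden = 32, vae_hidden = 16, vae_latent = 8,
           vae_epochs = 10, max_epochs = 10, min_epochs = 10, seed = 4))
  P <- fit$proportions
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(P[1, ], P[2, ], tolerance = 1e-12, ignore_attr = TRUE)
  bad <- slice_data(matrix(1, 3, 2, dimnames = list(NULL, c("zz1", "zz2"))),
                    matrix(0, 3, 2))
  expect_error(predict(fit, bad), "lacks model genes")
})
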