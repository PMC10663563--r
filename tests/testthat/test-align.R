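test_that("rigid transforms follow the rotation/mirror/translation algebra", {
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(apply_transform(x, rigid_transform2d()), x,
               ignore_attr = TRUE)
  expect_equal(apply_transform(matrix(c(1, 0), 1), rigid_transform2d(pi / 2)),
               matrix(c(0, 1), 1), tolerance = 1e-12, ignore_attr = TRUE)
  fl <- apply_transform(x, rigid_transform2d(0, flip = -1))
  expect_equal(fl[, 1], -x[, 1])
  expect_equal(fl[, 2], x[, 2])
  tr <- rigid_transform2d(1.1, -1, 40, -17)
  expect_lt(max(abs(invert_transform(tr)(apply_transform(x, tr)) - x)), 1e-9)
  # distances preserved
  expect_equal(dist(apply_transform(x, tr)), dist(x), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("slice centring subtracts the centroid exactly", {
  sl <- tiny_slice(n = 20)
  sl$coords <- sl$coords + 37
  out <- center_slices(list(sl, tiny_slice(n = 15, seed = 3)))
  for (s in out) {
    expect_equal(colMeans(s$coords), c(x = 0, y = 0), tolerance = 1e-10)
  }
  again <- center_slices(out)
  expect_equal(again[[1]]$coords, out[[1]]$coords, tolerance = 1e-12)
})

test_that("mutual-NN overlap matches a brute-force enumeration", {
  set.seed(31)
  S <- matrix(runif(40, 0, 10), 20, 2)
  ov <- overlap_set(S, S, k_mnn = 3)
  expect_equal(ov$overlap, 1:20)
  far <- overlap_set(S + 10 * ov$max_dist, S, k_mnn = 3)
  expect_length(far$overlap, 0)
  T2 <- matrix(runif(30, 0, 10), 15, 2)
  for (k in c(1, 3)) {
    got <- overlap_set(S, T2, k_mnn = k, max_dist = 4)
    want <- overlap_brute(S, T2, k, 4)
    expect_equal(lapply(got$neighbors, sort), want)
  }
})

test_that("alignment objective matches its definition and bounds", {
  set.seed(32)
  co <- matrix(runif(100, 0, 100), 50, 2)
  # domain-pure slice aligned with itself: agreement 1, penalty 0
  expect_equal(aof(co, rep(1L, 50), co, rep(1L, 50)), 1, tolerance = 1e-12)
  # same coordinates, disjoint domain labels: agreement 0, penalty 0
  expect_equal(aof(co, rep(1L, 50), co, rep(2L, 50)), 0, tolerance = 1e-12)
  # complete separation with p = 2: f(0) = -1
  expect_equal(aof(co + 1e5, rep(1L, 50), co, rep(1L, 50), p = 2), -1)
  # random configurations agree with the brute-force definition
  for (i in 1:5) {
    S <- matrix(runif(60, 0, 50), 30, 2)
    T2 <- matrix(runif(60, 0, 50), 30, 2)
    sd_ <- sample(1:3, 30, replace = TRUE)
    td_ <- sample(1:3, 30, replace = TRUE)
    expect_equal(aof(S, sd_, T2, td_, k_mnn = 4, p = 2, max_dist = 12),
                 aof_brute(S, sd_, T2, td_, 4, 2, 12), tolerance = 1e-12)
    expect_lte(aof(S, sd_, T2, td_, k_mnn = 4, p = 2, max_dist = 12), 1)
  }
})

test_that("the objective is invariant under a common rigid motion", {
  set.seed(33)
  S <- matrix(runif(80, 0, 60), 40, 2)
  T2 <- S + matrix(rnorm(80, 0, 2), 40, 2)
  sd_ <- sample(1:2, 40, replace = TRUE)
  td_ <- sample(1:2, 40, replace = TRUE)
  a0 <- aof(S, sd_, T2, td_, k_mnn = 4, p = 2)
  tr <- rigid_transform2d(0.8, 1, 12, -5)
  a1 <- aof(apply_transform(S, tr), sd_, apply_transform(T2, tr), td_,
            k_mnn = 4, p = 2)
  expect_equal(a0, a1, tolerance = 1e-9)
})

test_that("pairwise alignment recovers a known rigid perturbation", {
  stack <- generate_stack3d(n_slices = 2, spots_per_slice = 150,
                            n_domains = 4, seed = 34)
  # duplicate slice 1 so source and target share geometry exactly
  src <- stack[[1]]
  tgt <- stack[[1]]
  true_tr <- rigid_transform2d(40 * pi / 180, 1, 500, -300)
  csrc <- sweep(src$coords, 2, colMeans(src$coords))
  ctgt <- sweep(tgt$coords, 2, colMeans(tgt$coords))
  moved <- apply_transform(csrc, true_tr)
  moved <- sweep(moved, 2, colMeans(moved))
  res <- align_pair(moved, src$domains, ctgt, tgt$domains,
                    n_pop = 30, max_gen = 60, seed = 11)
  rmsd <- sqrt(mean(rowSums((res$coords - ctgt)^2)))
  nnsp <- median(apply(as.matrix(dist(ctgt)) + diag(Inf, nrow(ctgt)), 1, min))
  expect_lt(rmsd, nnsp)
  # self-alignment of a domain-pure slice reaches the AOF upper bound
  pure <- ctgt
  res2 <- align_pair(pure, rep(1L, nrow(pure)), pure, rep(1L, nrow(pure)),
                     n_pop = 15, max_gen = 25, seed = 12)
  expect_gte(res2$aof, 1 - 1e-6)
  expect_error(align_pair(pure[1:5, ], rep(1L, 5), pure, rep(1L, nrow(pure))),
               "degenerate")
})

test_that("stack alignment records transforms, AOFs and z spacing", {
  stack <- generate_stack3d(n_slices = 3, spots_per_slice = 120,
                            n_domains = 4, seed = 35)
  st <- align_stack(stack, z_spacing = 10, n_pop = 15, max_gen = 25, seed = 13)
  expect_s3_class(st, "aligned_stack")
  expect_equal(st$transforms[[1]]$theta, 0)
  expect_equal(vapply(st$slices, `[[`, numeric(1), "z"), c(0, 10, 20))
  expect_true(all(is.finite(st$aof[-1])))
  xyz <- stack_coords3d(st)
  expect_equal(ncol(xyz), 3)
  expect_equal(nrow(xyz), 360)
  expect_output(print(st), "aligned slices")
})
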