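test_that("deconvolution metrics hit their closed-form anchors", {
  set.seed(51)
  P <- matrix(runif(40), 10, 4); P <- P / rowSums(P)
  m <- deconv_metrics(P, P)
  expect_equal(m$pcc, rep(1, 4), tolerance = 1e-12)
  expect_equal(m$ssim, rep(1, 4), tolerance = 1e-12)
  expect_equal(m$rmse, rep(0, 4))
  expect_equal(m$jsd, rep(0, 4), tolerance = 1e-12)
  # two-spot reversal gives perfect anticorrelation
  tr <- cbind(c(0.2, 0.8), c(0.8, 0.2))
  pr <- tr[2:1, ]
  expect_equal(deconv_metrics(pr, tr)$pcc, c(-1, -1), tolerance = 1e-12)
  # zero-variance truth column: PCC undefined
  t0 <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_true(is.na(deconv_metrics(tr, t0)$pcc[1]))
})

test_that("Jensen-Shannon divergence matches its printed formula", {
  p <- c(0.2, 0.5, 0.3); q <- c(0.4, 0.4, 0.2)
  m <- (p + q) / 2
  brute <- 0.5 * sum(p * log(p / m)) + 0.5 * sum(q * log(q / m))
  got <- deconv_metrics(matrix(q, 3), matrix(p, 3))$jsd
  expect_equal(got, brute, tolerance = 1e-10)
  expect_lte(brute, log(2))
})

test_that("structural similarity follows the constant-augmented covariance form", {
  x <- c(0.1, 0.5, 0.9, 0.3); y <- c(0.2, 0.4, 0.8, 0.1)
  rng <- function(v) (v - min(v)) / diff(range(v))
  xs <- rng(x); ys <- rng(y)
  direct <- ((2 * mean(xs) * mean(ys) + 0.01^2) *
               (2 * cov(xs, ys) + 0.03^2)) /
    ((mean(xs)^2 + mean(ys)^2 + 0.01^2) * (var(xs) + var(ys) + 0.03^2))
  got <- deconv_metrics(matrix(y, 4), matrix(x, 4))$ssim
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("accuracy scores rank methods on the 0-1 scale", {
  mk <- function(pcc, ssim, rmse, jsd)
    data.frame(type = "t", pcc = pcc, ssim = ssim, rmse = rmse, jsd = jsd)
  two <- list(A = mk(0.9, 0.9, 0.1, 0.1), B = mk(0.5, 0.5, 0.3, 0.3))
  expect_equal(accuracy_score(two), c(A = 1, B = 0.5))
  tied <- list(A = mk(0.7, 0.7, 0.2, 0.2), B = mk(0.7, 0.7, 0.2, 0.2))
  expect_equal(unname(accuracy_score(tied)), c(0.75, 0.75))
  three <- list(A = mk(0.9, 0.9, 0.1, 0.1), B = mk(0.7, 0.7, 0.2, 0.2),
                C = mk(0.5, 0.5, 0.3, 0.3))
  expect_equal(accuracy_score(three), c(A = 1, B = 2 / 3, C = 1 / 3))
  # monotone rescaling of the metrics leaves the ordering intact
  resc <- lapply(three, function(df) {
    df$pcc <- tanh(3 * df$pcc); df$ssim <- df$ssim^2
    df$rmse <- exp(df$rmse); df$jsd <- 10 * df$jsd
    df
  })
  expect_equal(accuracy_score(resc), accuracy_score(three))
  expect_error(accuracy_score(three[1]), "length")
})

test_that("domain metrics score identity, toys, and random labels correctly", {
  set.seed(52)
  co <- matrix(runif(40), 20, 2)
  truth <- rep(1:2, each = 10)
  dm <- domain_metrics(truth, truth, co)
  expect_equal(dm$per_domain$ji, c(1, 1))
  expect_equal(dm$per_domain$sd, c(0, 0))
  expect_equal(dm$ari, 1)
  # P_d = {1,2,3}, P_l = {2,3,4} -> JI = 0.5
  pred <- c(1, 1, 1, 2, 2, 2)
  tru <- c(2, 1, 1, 1, 2, 2)
  ji <- domain_metrics(pred, tru)$per_domain$ji[1]
  expect_equal(ji, 0.5)
  # random labels: ARI concentrates near zero
  aris <- replicate(20, {
    a <- sample(1:4, 400, replace = TRUE)
    b <- sample(1:4, 400, replace = TRUE)
    adjusted_rand(a, b)
  })
  expect_lt(median(abs(aris)), 0.05)
})

test_that("pair-counting ARI agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(53)
  for (i in 1:10) {
    a <- sample(1:3, 60, replace = TRUE)
    b <- sample(1:4, 60, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("batch ASW separates mixed from split batches", {
  set.seed(54)
  mixed <- matrix(rnorm(200), 100, 2)
  batch <- rep(1:2, 50)
  expect_gt(asw_batch(mixed, batch), 0.8)
  split <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100) + 50, 50, 2))
  batch2 <- rep(1:2, each = 50)
  expect_lt(asw_batch(split, batch2), 0.2)
  # brute-force silhouette on 10 points, one cluster
  X <- matrix(rnorm(20), 10, 2)
  b <- rep(1:2, 5)
  D <- as.matrix(dist(X))
  sil <- sapply(1:10, function(i) {
    a <- mean(D[i, setdiff(which(b == b[i]), i)])
    bb <- mean(D[i, b != b[i]])
    (bb - a) / max(a, bb)
  })
  expect_equal(asw_batch(X, b), mean(1 - abs(sil)), tolerance = 1e-10)
})

test_that("percentage overlap is plain set arithmetic", {
  expect_equal(percentage_overlap(1:5, 1:5), 1)
  expect_equal(percentage_overlap(1:5, 6:10), 0)
  expect_equal(percentage_overlap(c(2, 3, 4), 1:10), 0.3)
  expect_error(percentage_overlap(1:3, integer(0)), "empty")
})

test_that("spatially variable genes are found where planted and calibrated under the null", {
  set.seed(55)
  n <- 90; g <- 40
  dom <- rep(1:3, each = 30)
  expr <- matrix(rnorm(n * g), n, g, dimnames = list(NULL, paste0("g", 1:g)))
  expr[dom == 2, "g7"] <- expr[dom == 2, "g7"] + 3
  res <- find_svgs(exp(expr), dom, lfc_cut = 0.5, p_cut = 0.01)
  expect_true("g7" %in% res$per_domain[["2"]])
  expect_length(find_svgs(exp(expr), dom, lfc_cut = Inf)$per_domain[["1"]], 0)
  sizes <- replicate(20, {
    r <- find_svgs(exp(expr), sample(dom), lfc_cut = 0, p_cut = 0.01)
    mean(lengths(r$per_domain)) / g
  })
  expect_lte(median(sizes), 0.05)
  # domains with < 3 spots are skipped
  small <- find_svgs(exp(expr), c(rep(1, 88), 2, 2), p_cut = 0.01)
  expect_length(small$per_domain[["2"]], 0)
})

test_that("gridded composition similarity matches direct computation", {
  set.seed(56)
  co <- as.matrix(expand.grid(seq(5, 95, 10), seq(5, 95, 10)))
  comp <- cbind(co[, 1] / 100, 1 - co[, 1] / 100)
  self <- grid_similarity(co, comp, co, comp)
  expect_equal(self$ssim, 1, tolerance = 1e-12)
  expect_equal(self$pcc, 1, tolerance = 1e-12)
  # an asymmetric field compared with its half-turn is strictly worse
  rot <- apply_transform(sweep(co, 2, c(50, 50)), rigid_transform2d(pi))
  rot <- sweep(rot, 2, c(-50, -50))
  half <- grid_similarity(co, comp, rot, comp)
  expect_lt(half$ssim, self$ssim)
  expect_lt(half$pcc, self$pcc)
  # 2 x 2 toy with known cell means
  co2 <- rbind(c(1, 1), c(3, 1), c(1, 3), c(3, 3))
  ca <- cbind(c(0.1, 0.2, 0.3, 0.4), c(0.9, 0.8, 0.7, 0.6))
  cb <- cbind(c(0.2, 0.1, 0.4, 0.3), c(0.8, 0.9, 0.6, 0.7))
  got <- grid_similarity(co2, ca, co2, cb, grid = 2)
  expect_equal(got$pcc,
               mean(c(cor(ca[, 1], cb[, 1]), cor(ca[, 2], cb[, 2]))),
               tolerance = 1e-10)
})

test_that("affine registration recovers exact and least-squares maps", {
  set.seed(57)
  truth <- matrix(runif(40, 0, 100), 20, 2)
  reg0 <- register_to_truth(truth, truth)
  expect_equal(reg0$M, cbind(diag(2), c(0, 0)), tolerance = 1e-9)
  expect_equal(reg0$residual, 0, tolerance = 1e-9)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  aligned <- truth %*% t(R) + matrix(c(12, -7), 20, 2, byrow = TRUE)
  reg <- register_to_truth(aligned, truth)
  expect_lt(reg$residual, 1e-6)
  expect_equal(reg$inverse(aligned), truth, tolerance = 1e-6,
               ignore_attr = TRUE)
  # three non-collinear points are interpolated exactly
  t3 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  a3 <- rbind(c(2, 2), c(5, 3), c(1, 7))
  reg3 <- register_to_truth(a3, t3)
  expect_lt(reg3$residual, 1e-10)
  expect_error(register_to_truth(rbind(c(1, 1), c(2, 2), c(3, 3)),
                                 rbind(c(0, 0), c(1, 1), c(2, 2))),
               "rank-deficient")
})
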