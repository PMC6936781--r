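test_that("zero-noise model data are recovered exactly", {
  sim <- simulate_dataset(n_samples = 40, noise_sd = 0, seed = 11)
  m <- o2pls(sim$truth$X_latent, sim$truth$Y_latent, K = 2, nx = 1, ny = 1,
             scaling = "center_only")
  expect_equal(m$R2Y, 1, tolerance = 1e-6)
  expect_lt(max(principal_angles(m$W, sim$truth$W_true)), 1e-6)
  expect_lt(max(principal_angles(m$C, sim$truth$C_true)), 1e-6)
  # prediction from X reproduces the predictable part of Y exactly: the
  # Y-orthogonal component is block-specific and cannot be predicted from X
  pred <- predict(m, sim$truth$X_latent)
  y_pred_part <- sim$truth$Y_latent -
    tcrossprod(sim$truth$U_orth, sim$truth$P_yorth)
  expect_equal(pred, y_pred_part, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("K=1 without orthogonal parts reduces to the SVD of X'Y", {
  set.seed(21)
  x <- matrix(rnorm(20 * 8), 20, 8)
  y <- matrix(rnorm(20 * 6), 20, 6)
  m <- o2pls(x, y, K = 1, nx = 0, ny = 0, scaling = "center_only")
  s <- svd(crossprod(scale(x, scale = FALSE), scale(y, scale = FALSE)),
           nu = 1, nv = 1)
  w_ref <- s$u * sign(s$u[which.max(abs(s$u))])
  c_ref <- s$v * sign(s$v[which.max(abs(s$v))])
  expect_equal(unname(m$W[, 1]), as.vector(w_ref), tolerance = 1e-10)
  expect_equal(unname(m$C[, 1]), as.vector(c_ref), tolerance = 1e-10)
})

test_that("the fit is equivariant under taxon permutation", {
  sim <- simulate_dataset(n_samples = 30, seed = 31)
  x <- sim$abundance$values
  y <- sim$flavor$values
  m1 <- o2pls(x, y, K = 2, nx = 1, ny = 1)
  perm <- sample(ncol(x))
  m2 <- o2pls(x[, perm], y, K = 2, nx = 1, ny = 1)
  expect_equal(m2$W, m1$W[perm, ], tolerance = 1e-8)
  expect_equal(m2$R2Y, m1$R2Y, tolerance = 1e-10)
  v1 <- vip_pred(m1); v2 <- vip_pred(m2)
  expect_equal(v2[names(v1)], v1, tolerance = 1e-8)
})

test_that("fitted models satisfy the structural identities", {
  for (seed in c(1, 7, 13)) {
    sim <- simulate_dataset(n_samples = 25, seed = seed)
    m <- o2pls(sim$abundance, sim$flavor, K = 2, nx = 1, ny = 1)
    # weight orthonormality
    expect_equal(crossprod(m$W), diag(2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(crossprod(m$C), diag(2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # VIP normalisation
    v <- vip_pred(m)
    expect_equal(sum(v^2), length(v), tolerance = 1e-6)
    expect_true(all(v >= 0))
  }
})

test_that("cross-block scores decouple exactly on exact-model data", {
  # the deflation estimates the orthogonal structure exactly at zero noise,
  # where T_orth'U and U_orth'T vanish; on noisy data the decoupling is
  # only approximate (the estimator has no structural cross-block zero)
  sim <- simulate_dataset(n_samples = 30, noise_sd = 0, seed = 17)
  m <- o2pls(sim$truth$X_latent, sim$truth$Y_latent, K = 2, nx = 1, ny = 1,
             scaling = "center_only")
  expect_lt(max(abs(crossprod(m$T_orth, m$U))), 1e-8)
  expect_lt(max(abs(crossprod(m$U_orth, m$T))), 1e-8)
})

test_that("VIP collapses correctly for a single active taxon", {
  # X built so the only Y-relevant direction is taxon 3
  set.seed(41)
  n <- 30; p <- 6
  t1 <- scale(rnorm(n), scale = FALSE)
  x <- matrix(rnorm(n * p, 0, 1e-4), n, p)
  x[, 3] <- t1
  y <- cbind(t1 + rnorm(n, 0, 1e-4), -t1 + rnorm(n, 0, 1e-4))
  m <- o2pls(x, y, K = 1, nx = 0, ny = 0, scaling = "center_only")
  v <- vip_pred(m)
  expect_equal(unname(v[3]), sqrt(p), tolerance = 1e-2)
  expect_lt(max(v[-3]), 0.1)
})

test_that("training R2Y does not decrease with more joint components", {
  sim <- simulate_dataset(n_samples = 30, K = 3, nx = 1, ny = 1,
                          score_sd = c(2, 1, 0.5), seed = 51)
  r2 <- vapply(1:3, function(k) {
    o2pls(sim$abundance, sim$flavor, K = k, nx = 0, ny = 0)$R2Y
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-9))
})

test_that("predict matches R2Y_pred on training data and maps pointwise", {
  sim <- simulate_dataset(n_samples = 30, seed = 61)
  m <- o2pls(sim$abundance, sim$flavor, K = 2, nx = 1, ny = 1)
  yv <- sim$flavor$values
  pred <- predict(m, sim$abundance)
  ys <- scale(yv)
  ps <- sweep(sweep(pred, 2, m$scaling$y_center), 2, m$scaling$y_scale, "/")
  expect_equal(1 - sum((ys - ps)^2) / sum(ys^2), m$R2Y_pred,
               tolerance = 1e-8)
  # duplicated rows give duplicated predictions
  x2 <- sim$abundance$values[c(1, 1, 5), ]
  rownames(x2) <- c("a", "b", "c")
  p2 <- predict(m, x2)
  expect_equal(unname(p2[1, ]), unname(p2[2, ]))
  # unknown taxa are rejected by name
  xbad <- sim$abundance$values
  colnames(xbad)[1] <- "mystery"
  expect_error(predict(m, xbad), "mystery")
})

test_that("rank violations and misaligned blocks are rejected", {
  sim <- simulate_dataset(n_samples = 8, seed = 71)
  expect_error(o2pls(sim$abundance, sim$flavor, K = 5, nx = 3), "rank")
  expect_error(o2pls(sim$abundance$values[1:7, ], sim$flavor$values),
               "same samples")
})

test_that("cross-validation selects the planted component triple", {
  picks <- vapply(1:20, function(seed) {
    sim <- simulate_dataset(n_samples = 60, seed = 500 + seed)
    cv <- o2pls_cv(sim$abundance, sim$flavor, K_range = 1:3,
                   nx_range = 0:2, ny_range = 0:2, seed = seed)
    paste(cv$best$K, cv$best$nx, cv$best$ny)
  }, character(1))
  modal <- names(sort(table(picks), decreasing = TRUE))[1]
  expect_equal(modal, "2 1 1")
  # Q2 never exceeds training R2Y for the selected model
  sim <- simulate_dataset(n_samples = 60, seed = 999)
  cv <- o2pls_cv(sim$abundance, sim$flavor, K_range = 2, nx_range = 1,
                 ny_range = 1, seed = 1)
  expect_lte(cv$model$Q2, cv$model$R2Y_pred + 0.05)
})

test_that("null data yield no spuriously high cross-validated Q2", {
  good <- 0
  for (seed in 1:100) {
    set.seed(seed + 3000)
    x <- matrix(rnorm(20 * 10), 20, 10)
    y <- matrix(rnorm(20 * 8), 20, 8)
    cv <- o2pls_cv(x, y, K_range = 1:2, nx_range = 0:1, ny_range = 0:1,
                   seed = seed)
    if (max(cv$table$Q2, na.rm = TRUE) <= 0.1) good <- good + 1
  }
  expect_gte(good, 90)
})

test_that("VIP separates planted core taxa from the rest", {
  aucs <- numeric(20)
  all_above <- TRUE
  for (seed in 1:20) {
    sim <- simulate_dataset(n_samples = 60, seed = 700 + seed)
    m <- o2pls(sim$abundance, sim$flavor, K = 2, nx = 1, ny = 1)
    v <- vip_pred(m)
    core <- names(v) %in% sim$truth$planted_core
    if (any(v[core] <= 1)) all_above <- FALSE
    # rank-sum AUC
    r <- rank(v)
    n1 <- sum(core); n0 <- sum(!core)
    aucs[seed] <- (sum(r[core]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  expect_true(all_above)
  expect_gt(mean(aucs), 0.95)
})
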