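test_that("cross-task correlations report rho/p and mask same-task or insignificant", {
  set.seed(43)
  n <- 60
  x <- rnorm(n)
  X <- cbind(t1.a = x, t1.b = x + rnorm(n, 0, 0.1), t2.c = -x, t2.d = rnorm(n))
  tasks <- c(t1.a = "t1", t1.b = "t1", t2.c = "t2", t2.d = "t2")
  res <- cross_task_correlations(X, tasks)
  r_ab <- res[res$metric1 == "t1.a" & res$metric2 == "t1.b", ]
  expect_gt(r_ab$rho, 0.9)
  expect_true(r_ab$masked)  # same task
  r_ac <- res[res$metric1 == "t1.a" & res$metric2 == "t2.c", ]
  expect_equal(r_ac$rho, -1, tolerance = 1e-12)
  expect_false(r_ac$masked)
  # constant column: correlation missing and masked
  X2 <- cbind(X, t3.e = rep(1, n))
  res2 <- cross_task_correlations(X2, c(tasks, t3.e = "t3"))
  expect_true(all(is.na(res2$rho[res2$metric2 == "t3.e"])))
  expect_true(all(res2$masked[res2$metric2 == "t3.e"]))
})

test_that("independent metrics are masked at the nominal 5% rate", {
  set.seed(47)
  masked <- vapply(1:200, function(i) {
    X <- cbind(t1.a = rnorm(200), t2.b = rnorm(200))
    cross_task_correlations(X, c(t1.a = "t1", t2.b = "t2"))$masked
  }, TRUE)
  expect_gt(mean(masked), 0.90)
  expect_lt(mean(masked), 0.99)
})

test_that("PCA explains all variance for duplicated metrics and stays orthonormal", {
  set.seed(53)
  x <- rnorm(50)
  two <- cbind(a = x, b = 2 * x + 3)
  p <- pca_scores(two, k = 1)
  expect_equal(p$explained_ratio[1], 1, tolerance = 1e-12)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("m", 1:4)))
  p4 <- pca_scores(X, k = 4)
  expect_equal(crossprod(p4$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p4$explained_variance) <= 1e-12))
  expect_error(pca_scores(two, k = 2), "rank")
})

test_that("orthogonal latent factors give near-orthogonal loading directions", {
  set.seed(59)
  f1 <- rnorm(300); f2 <- rnorm(300)
  X <- cbind(a = f1 + rnorm(300, 0, 0.05), b = f1 + rnorm(300, 0, 0.05),
             c = f2 + rnorm(300, 0, 0.05), d = f2 + rnorm(300, 0, 0.05))
  p <- pca_scores(X, k = 2)
  ab <- p$loadings[c("a", "b"), 1:2]; cd <- p$loadings[c("c", "d"), 1:2]
  cosang <- sum(colMeans(ab) * colMeans(cd)) /
    sqrt(sum(colMeans(ab)^2) * sum(colMeans(cd)^2))
  expect_lt(abs(cosang), 0.2)
})

test_that("CCA on an identical pair of views yields unit correlations", {
  set.seed(61)
  X <- matrix(rnorm(300), 100, 3)
  m <- cca_fit(X, X, k = 3, ridge = 1e-10)
  expect_true(all(m$correlations > 1 - 1e-5))
  expect_true(all(diff(m$correlations) <= 1e-8))
})

test_that("CCA recovers a shared latent factor from noisy views", {
  set.seed(67)
  n <- 1000
  z <- rnorm(n)
  a1 <- runif(5, 0.5, 1.5); a2 <- runif(4, 0.5, 1.5)
  v1 <- outer(z, a1) + matrix(rnorm(n * 5, 0, 0.1), n, 5)
  v2 <- outer(z, a2) + matrix(rnorm(n * 4, 0, 0.1), n, 4)
  m <- cca_fit(v1, v2, k = 2, ridge = 1e-3)
  expect_gt(m$correlations[1], 0.9)
  variate <- predict(m, v1, view = 1)[, 1]
  expect_gt(abs(cor(variate, z)), 0.9)
})

test_that("canonical correlations are invariant to invertible view transforms", {
  set.seed(71)
  n <- 200
  v1 <- matrix(rnorm(n * 3), n, 3)
  v2 <- v1 %*% matrix(runif(9), 3, 3) + matrix(rnorm(n * 3, 0, 0.5), n, 3)
  base <- cca_fit(v1, v2, k = 3, ridge = 0)$correlations
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3, 3); while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    B <- matrix(rnorm(9), 3, 3); while (abs(det(B)) < 0.1) B <- matrix(rnorm(9), 3, 3)
    tr <- cca_fit(v1 %*% A, v2 %*% B, k = 3, ridge = 0)$correlations
    expect_equal(tr, base, tolerance = 1e-6)
  }
})

test_that("the 2x2 case matches the small-dimension eigen oracle and cancor", {
  set.seed(73)
  n <- 500
  v1 <- matrix(rnorm(n * 2), n, 2)
  v2 <- 0.6 * v1 + matrix(rnorm(n * 2), n, 2)
  got <- cca_fit(v1, v2, k = 2, ridge = 0)$correlations
  # eigen oracle on raw covariances: eigvals of S11^-1 S12 S22^-1 S21
  S11 <- cov(scale(v1)); S22 <- cov(scale(v2)); S12 <- cov(scale(v1), scale(v2))
  ev <- eigen(solve(S11) %*% S12 %*% solve(S22) %*% t(S12))$values
  expect_equal(got, sqrt(sort(Re(ev), decreasing = TRUE)), tolerance = 1e-6)
  expect_equal(got, stats::cancor(scale(v1), scale(v2))$cor, tolerance = 1e-6)
})

test_that("rank-deficient views are rejected without ridge, accepted with it", {
  set.seed(79)
  v <- matrix(rnorm(100), 50, 2)
  v1 <- cbind(v, v[, 1])  # exact collinearity
  v2 <- matrix(rnorm(150), 50, 3)
  expect_error(cca_fit(v1, v2, k = 2, ridge = 0), "ridge")
  m <- cca_fit(v1, v2, k = 2, ridge = 1e-3)
  expect_true(all(m$correlations >= 0 & m$correlations <= 1))
})

test_that("augmentation projects externals consistently and concatenates widths", {
  set.seed(83)
  n <- 60
  v1 <- matrix(rnorm(n * 25), n, 25)
  v2 <- v1[, 1:22] + matrix(rnorm(n * 22, 0, 0.5), n, 22)
  m <- cca_fit(v1, v2, k = 20, ridge = 1e-3)
  expect_equal(m$k, 20L)
  sel <- matrix(rnorm(10 * 50), 10, 50)
  ext <- matrix(rnorm(10 * 25), 10, 25)
  aug <- cca_augment(m, ext, sel)
  expect_equal(dim(aug), c(10L, 70L))
  # training projection reproduces training embeddings
  emb_train <- predict(m, v1, view = 1)
  expect_equal(cca_augment(m, v1, matrix(0, n, 1))[, 1:20], emb_train,
               ignore_attr = TRUE)
  expect_error(predict(m, matrix(0, 3, 7)), "expects")
  # zero-variance external column is handled by stored standardization
  ext0 <- ext; ext0[, 1] <- 5
  expect_true(all(is.finite(cca_augment(m, ext0, sel))))
})
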