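test_that("pilot GLM weights recover exact coefficients and ignore sign", {
  x <- matrix(seq(-2, 2, length.out = 20), ncol = 1,
              dimnames = list(NULL, "f1"))
  expect_equal(glm_weights(x, 3 * x[, 1]), c(f1 = 3), tolerance = 1e-10)
  # sign flip of a column leaves the weight unchanged
  withr::with_seed(4, {
    X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- X[, 1] - 2 * X[, 2] + rnorm(40, sd = 0.1)
    w1 <- glm_weights(X, y)
    X2 <- X; X2[, 2] <- -X2[, 2]
    expect_equal(glm_weights(X2, y), w1, tolerance = 1e-12)
  })
  # a feature independent of y has a near-zero (floored, positive) weight
  withr::with_seed(6, {
    X <- matrix(rnorm(1000 * 2), 1000, 2, dimnames = list(NULL, c("s", "n")))
    y <- 2 * X[, 1] + rnorm(1000)
    w <- glm_weights(X, y)
    expect_lt(w[["n"]], 3 / sqrt(1000) + 1e-6)  # within ~3 SE of zero
    expect_gt(w[["n"]], 0)
  })
  # wide systems fall back to ridge with a warning
  expect_warning(glm_weights(matrix(rnorm(12), 3, 4), rnorm(3)), "ridge")
})

test_that("unit weights reduce the adaptive LASSO to plain LASSO
           (coordinate-descent oracle)", {
  withr::with_seed(14, {
    for (trial in 1:10) {
      n <- 30; p <- 6
      X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
      beta_true <- c(2, -1, rep(0, p - 2))
      y <- as.numeric(X %*% beta_true + rnorm(n, sd = 0.3))
      y <- y - mean(y)
      lambda <- runif(1, 1, 20)
      w <- rep(1, p)
      got <- adaptive_lasso(X, y, w, lambda = lambda)$beta
      want <- cd_adaptive_lasso(X, y, w, lambda)
      expect_equal(unname(got), want, tolerance = 1e-6)
    }
  })
})

test_that("orthonormal designs match the soft-threshold closed form", {
  withr::with_seed(15, {
    for (trial in 1:5) {
      n <- 40; p <- 5
      Q <- rand_orthonormal(n, p)
      colnames(Q) <- paste0("q", 1:p)
      y <- rnorm(n, sd = 2)
      w <- runif(p, 0.5, 3)
      lambda <- runif(1, 0.5, 4)
      got <- adaptive_lasso(Q, y, w, lambda = lambda)$beta
      z <- as.numeric(crossprod(Q, y))
      want <- sign(z) * pmax(abs(z) - lambda * w / 2, 0)
      expect_equal(unname(got), want, tolerance = 1e-6)
    }
  })
})

test_that("the penalty-free limit recovers ordinary least squares", {
  withr::with_seed(16, {
    n <- 50; p <- 4
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- as.numeric(X %*% c(1, -2, 0.5, 0) + rnorm(n, sd = 0.2))
    y <- y - mean(y)
    w <- runif(p, 0.5, 2)
    got <- adaptive_lasso(X, y, w, lambda = 0)$beta
    ols <- as.numeric(qr.coef(qr(X), y))
    expect_equal(unname(got), ols, tolerance = 1e-6)
  })
})

test_that("CV solutions satisfy the KKT conditions of the weighted
           objective", {
  withr::with_seed(17, {
    for (trial in 1:5) {
      n <- 60; p <- 8
      X <- suppressWarnings(autoscale(matrix(rnorm(n * p), n, p)))
      colnames(X) <- paste0("v", 1:p)
      y <- as.numeric(X %*% c(3, -2, rep(0, p - 2)) + rnorm(n, sd = 0.5))
      y <- y - mean(y)
      w <- glm_weights(X, y)
      fit <- adaptive_lasso(X, y, w, k_folds = 5, seed = trial)
      # refit at the returned lambda with the tight-convergence path
      fit2 <- adaptive_lasso(X, y, w, lambda = fit$lambda)
      expect_lt(kkt_violation(X, y, fit2$beta, w, fit$lambda), 1e-5)
      expect_error(adaptive_lasso(X, y, w, k_folds = 1), "k_folds")
    }
  })
})

test_that("cluster scores distribute to features through the loadings", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 3, 3.9), c = c(9, 1, 5, 2))
  asg <- dbscan_features(suppressWarnings(autoscale(x)), eps = 0.5)
  cm <- collapse_clusters(suppressWarnings(autoscale(x)), asg)
  expect_equal(sort(cm$provenance$cluster_1), c("a", "b"))
  fake <- c(cluster_1 = 2, c = 5)
  fs <- feature_scores(fake, cm)
  expect_equal(fs$feature_score[fs$feature == "a"],
               2 * cm$loadings$cluster_1[["a"]])
  expect_equal(fs$feature_score[fs$feature == "c"], 5)  # singleton
  expect_equal(nrow(fs), 3L)
  # zero cluster score zeroes all members
  fs0 <- feature_scores(c(cluster_1 = 0, c = 1), cm)
  expect_equal(fs0$feature_score[fs0$collapsed == "cluster_1"], c(0, 0))
  expect_error(feature_scores(c(cluster_1 = 1), cm), "named")

  # worked arithmetic: score 2 with loadings (0.6, 0.8)
  cm2 <- cm
  cm2$loadings$cluster_1 <- c(a = 0.6, b = 0.8)
  fs2 <- feature_scores(fake, cm2)
  expect_equal(fs2$feature_score[match(c("a", "b"), fs2$feature)],
               c(1.2, 1.6))
})

test_that("score summaries use non-excess moment conventions", {
  s <- score_summary(c(-1, 0, 1))
  expect_equal(s$skewness, 0)
  expect_gt(score_summary(c(0, 0, 0, 10))$skewness, 0)
  # m2 = 1, m4 = 1 for (-1, 1, -1, 1): kurtosis 1 under m4 / m2^2
  expect_equal(score_summary(c(-1, 1, -1, 1))$kurtosis, 1)
  expect_warning(sc <- score_summary(c(2, 2, 2)), "constant")
  expect_equal(sc$skewness, 0)
  expect_error(score_summary(c(1, 2)), "at least 3")
})

test_that("the cluster that drives the response gets the largest score", {
  hits <- 0L
  for (s in 1:20) {
    res <- withr::with_seed(100 + s, {
      n <- 120
      driver <- rnorm(n)
      x <- cbind(d1 = driver + rnorm(n, sd = 0.02),
                 d2 = driver + rnorm(n, sd = 0.02),
                 n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
      y <- 2 * driver + rnorm(n, sd = 0.3)
      xs <- suppressWarnings(autoscale(x))
      asg <- dbscan_features(xs, eps = 1)
      cm <- collapse_clusters(xs, asg)
      suppressWarnings(score_features(cm, y, k_folds = 5, seed = s))
    })
    top <- res$feature[which.max(abs(res$feature_score))]
    if (top %in% c("d1", "d2")) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
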