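# Independent oracle: best single-atom least-squares fit by exhaustive search.
best_single_atom <- function(y, D) {
  corr <- drop(crossprod(D, y))
  j <- which.max(abs(corr))
  resid <- y - D[, j] * corr[j]
  list(atom = j, coef = corr[j], residual = sqrt(sum(resid^2)))
}

test_that("OMP recovers an exact atom and honors L = 0", {
  D <- qr.Q(qr(random_dictionary(8, 8, seed = 1)))[, 1:4]
  oc <- omp_code(D[, 3], D, L = 3)
  expect_equal(oc$support, 3)
  expect_equal(oc$coef[3], 1)
  expect_lt(oc$residual_norm, 1e-10)

  y <- rnorm(8)
  z <- omp_code(y, D, L = 0)
  expect_true(all(z$coef == 0))
  expect_equal(z$residual_norm, sqrt(sum(y^2)))
})

test_that("OMP at L = 1 equals exhaustive single-atom search", {
  withr::with_seed(11, {
    for (rep in 1:200) {
      D <- random_dictionary(8, 4, seed = rep)
      y <- rnorm(8)
      got <- omp_code(y, D, L = 1)
      want <- best_single_atom(y, D)
      expect_equal(got$support, want$atom)
      expect_equal(got$coef[want$atom], want$coef, tolerance = 1e-12)
      expect_equal(got$residual_norm, want$residual, tolerance = 1e-12)
    }
  })
})

test_that("OMP codes never exceed the sparsity budget", {
  withr::with_seed(12, {
    D <- random_dictionary(30, 20)
    Y <- matrix(rnorm(30 * 40), 30)
    for (L in c(1, 3, 7)) {
      S <- mifdict:::sparse_encode(D, Y, L)
      expect_true(all(colSums(S != 0) <= L))
    }
  })
})

test_that("a non-unit-norm dictionary is rejected", {
  D <- random_dictionary(10, 5)
  D[, 2] <- D[, 2] * 2
  expect_error(omp_code(rnorm(10), D, 2), "unit")
})

test_that("objective value matches its definition and is affine in rho", {
  withr::with_seed(13, {
    D <- random_dictionary(20, 6)
    Y <- matrix(rnorm(20 * 15), 20)
    Yb <- matrix(rnorm(20 * 9), 20)
  })
  # rho = 0: mean in-class squared residual, non-negative
  v0 <- objective_value(D, Y, Yb, L = 2, rho = 0)
  S <- mifdict:::sparse_encode(D, Y, 2)
  expect_equal(v0, sum((Y - D %*% S)^2) / ncol(Y))
  expect_gte(v0, 0)

  # affine and decreasing in rho
  vals <- vapply(c(0, 0.5, 1, 2), function(r) {
    objective_value(D, Y, Yb, L = 2, rho = r)
  }, numeric(1))
  slopes <- diff(vals) / diff(c(0, 0.5, 1, 2))
  expect_lt(max(abs(slopes - slopes[1])), 1e-10)
  expect_lt(slopes[1], 0)

  # own-N normalization divides the out-class term by its own count
  vo <- objective_value(D, Y, Yb, L = 2, rho = 1, normalize_by_own_N = TRUE)
  Sb <- mifdict:::sparse_encode(D, Yb, 2)
  expect_equal(vo, v0 + 0 - sum((Yb - D %*% Sb)^2) / ncol(Yb))

  expect_error(objective_value(D, Y[1:10, ], Yb, 2, 0.1), "mismatch")
})

test_that("trained atoms are unit norm and training is deterministic", {
  cls <- disjoint_channel_classes(d = 60, active = 25, n = 40, seed = 14)
  cfg <- dfdl_config(k_atoms = 8, L = 2, max_iters = 8, seed = 2)
  fit1 <- train_dfdl(cls$Y1, cls$Y2, cfg)
  fit2 <- train_dfdl(cls$Y1, cls$Y2, cfg)
  expect_identical(fit1$atoms, fit2$atoms)
  expect_lt(max(abs(sqrt(colSums(fit1$atoms^2)) - 1)), 1e-10)
})

test_that("with rho = 0, N = k = L the dictionary memorizes its class", {
  withr::with_seed(15, {
    Y <- matrix(rnorm(30 * 8), 30)
    Yb <- matrix(rnorm(30 * 8), 30)
  })
  cfg <- dfdl_config(k_atoms = 8, L = 8, rho = 0, max_iters = 5, seed = 1)
  d <- train_dfdl(Y, Yb, cfg)
  S <- mifdict:::sparse_encode(d$atoms, Y, 8)
  expect_lt(mean(colSums((Y - d$atoms %*% S)^2)), 1e-6)
})

test_that("with rho = 0 the alternation does not increase the objective", {
  for (seed in 1:4) {
    cls <- disjoint_channel_classes(d = 50, active = 20, n = 30, seed = seed)
    cfg <- dfdl_config(k_atoms = 6, L = 2, rho = 0, max_iters = 10,
                       seed = seed)
    d <- train_dfdl(cls$Y1, cls$Y2, cfg)
    tr <- d$objective_trace
    expect_lte(tr[length(tr)], tr[1] + 1e-12)
  }
})

test_that("class dictionaries discriminate held-out disjoint-support patches", {
  accs <- vapply(1:5, function(seed) {
    tr <- disjoint_channel_classes(d = 200, active = 80, n = 100, seed = seed)
    te <- disjoint_channel_classes(d = 200, active = 80, n = 50,
                                   seed = 100 + seed)
    cfg <- dfdl_config(k_atoms = 10, L = 3, max_iters = 10, seed = seed)
    fit <- train_pair(tr$Y1, tr$Y2, cfg)
    pred <- classify_patches(cbind(te$Y1, te$Y2), fit)
    mean(pred$label == rep(1:2, each = 50))
  }, numeric(1))
  expect_true(all(accs >= 0.9))
})

test_that("train_pair concatenates and swapping inputs swaps the halves", {
  cls <- disjoint_channel_classes(d = 60, active = 25, n = 40, seed = 16)
  cfg <- dfdl_config(k_atoms = 7, L = 2, max_iters = 6, seed = 3)
  fit <- train_pair(cls$Y1, cls$Y2, cfg)
  expect_equal(ncol(fit$D_combined), 14)
  expect_identical(fit$D_combined[, 1:7], fit$D1$atoms)
  expect_identical(fit$D_combined[, 8:14], fit$D2$atoms)

  swapped <- train_pair(cls$Y2, cls$Y1, cfg)
  expect_identical(swapped$D1$atoms, fit$D2$atoms)
  expect_identical(swapped$D2$atoms, fit$D1$atoms)
})

test_that("training requires at least k in-class patches", {
  cls <- disjoint_channel_classes(d = 30, active = 10, n = 5, seed = 17)
  expect_error(train_dfdl(cls$Y1, cls$Y2,
                          dfdl_config(k_atoms = 10, L = 2)),
               "at least k")
})

test_that("discriminability grows with class separation", {
  # separation = fraction of active coordinates unique to each class
  acc_at <- function(sep, seed) {
    withr::with_seed(seed, {
      d <- 100; n <- 60; act <- 40
      shift <- round(sep * act)  # 0 = identical support, act = disjoint
      mk <- function(start, n) {
        M <- matrix(0, d, n)
        M[start:(start + act - 1), ] <- abs(rnorm(act * n))
        M
      }
      Y1 <- mk(1, n); Y2 <- mk(1 + shift, n)
      T1 <- mk(1, 25); T2 <- mk(1 + shift, 25)
    })
    cfg <- dfdl_config(k_atoms = 8, L = 2, max_iters = 8, seed = seed)
    fit <- train_pair(Y1, Y2, cfg)
    pred <- classify_patches(cbind(T1, T2), fit)
    mean(pred$label == rep(1:2, each = 25))
  }
  seps <- c(0.05, 0.25, 0.5, 0.75, 1)
  accs <- sapply(1:5, function(s) vapply(seps, acc_at, numeric(1), seed = s))
  mean_acc <- rowMeans(accs)
  expect_gt(cor(seps, mean_acc, method = "spearman"), 0.8)
})
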