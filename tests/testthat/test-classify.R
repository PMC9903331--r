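test_that("residual rule assigns the class of the reconstructing half", {
  # orthonormal halves: D1 spans coords 1..3, D2 spans coords 4..6
  D1 <- diag(8)[, 1:3]
  D2 <- diag(8)[, 4:6]
  fit <- structure(
    list(D1 = list(atoms = D1), D2 = list(atoms = D2),
         D_combined = cbind(D1, D2), k = 3,
         config = dfdl_config(k_atoms = 3, L = 2)),
    class = "dfdl_fit")
  pred <- classify_patches(cbind(D1[, 2], D2[, 3]), fit)
  expect_equal(pred$label, c(1L, 2L))
  expect_equal(pred$eps1[1], 0)
  expect_gt(pred$eps2[1], 0)

  # exact tie breaks to class 1
  y <- (D1[, 1] + D2[, 1])
  tie <- classify_patches(matrix(y), fit, L = 2)
  expect_equal(tie$eps1, tie$eps2)
  expect_equal(tie$label, 1L)
})

test_that("theta is the class-1 patch fraction", {
  mk <- function(labels, entity = "img1") {
    tibble::tibble(image_id = entity, subject_id = "s1", class = 1L,
                   label = labels)
  }
  # 24 patches, 3 labeled class 1 -> theta = 0.125
  th <- aggregate_theta(mk(rep(c(1L, 2L), c(3, 21))), by = "image")
  expect_equal(th$theta, 0.125)
  expect_equal(th$n_patches, 24L)
  expect_equal(aggregate_theta(mk(rep(1L, 10)))$theta, 1.0)
  expect_equal(aggregate_theta(mk(rep(2L, 10)))$theta, 0.0)

  # subject level pools patches across the subject's images
  pred <- tibble::tibble(
    image_id = c("i1", "i1", "i2", "i2"),
    subject_id = "s1", class = 2L,
    label = c(1L, 1L, 2L, 2L))
  expect_equal(aggregate_theta(pred, by = "subject")$theta, 0.5)
  expect_equal(aggregate_theta(pred, by = "image")$theta, c(1, 0))
})

test_that("AUC matches brute-force pair counting", {
  # worked example: ties credited 0.5
  theta <- c(0.9, 0.8, 0.8, 0.1)
  cls <- c(1, 1, 2, 2)
  expect_equal(auc_score(theta, cls), (1 + 0.5 + 1 + 1) / 4)

  brute_auc <- function(theta, cls) {
    pos <- theta[cls == 1]; neg <- theta[cls == 2]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  withr::with_seed(21, {
    for (rep in 1:20) {
      th <- round(runif(30), 1)  # coarse values force ties
      cl <- sample(1:2, 30, replace = TRUE, prob = c(0.6, 0.4))
      if (length(unique(cl)) < 2) next
      expect_equal(auc_score(th, cl), brute_auc(th, cl))
    }
  })
  expect_equal(auc_score(c(1, 0.9, 0.2, 0.1), c(1, 1, 2, 2)), 1.0)
  expect_error(auc_score(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("AUC agrees with pROC and is near 0.5 under label shuffling", {
  withr::with_seed(22, {
    th <- runif(200)
    cl <- sample(1:2, 200, replace = TRUE)
  })
  ours <- auc_score(th, cl)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = cl, predictor = th, levels = c(2, 1),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)

  withr::with_seed(23, {
    th <- runif(2000)
    cl <- sample(rep(1:2, 1000))
  })
  expect_lt(abs(auc_score(th, cl) - 0.5), 0.05)
})

test_that("sensitivity/specificity follow the theta threshold", {
  th <- c(1.0, 0.6, 0.4, 0.0)
  cl <- c(1, 1, 2, 2)
  ss <- sens_spec(th, cl, threshold = 0.5)
  expect_equal(ss$sensitivity, 1.0)
  expect_equal(ss$specificity, 1.0)

  expect_equal(sens_spec(th, cl, threshold = 0)$sensitivity, 1.0)
  hi <- sens_spec(th, cl, threshold = 1.01)
  expect_equal(hi$sensitivity, 0.0)
  expect_equal(hi$specificity, 1.0)

  # Youden point on a separable configuration is perfect
  expect_equal(ss$sensitivity_youden + ss$specificity_youden, 2)
})

test_that("swapping class roles mirrors AUC and swaps the error types", {
  withr::with_seed(24, {
    th <- runif(40)
    cl <- sample(1:2, 40, replace = TRUE)
  })
  expect_equal(auc_score(th, 3 - cl), 1 - auc_score(th, cl))
  thr <- 0.437  # interior, not attained by any score
  a <- sens_spec(th, cl, thr)
  b <- sens_spec(1 - th, 3 - cl, 1 - thr)
  expect_equal(b$sensitivity, a$specificity)
  expect_equal(b$specificity, a$sensitivity)
})

test_that("grouped cross-validation respects subjects and stratification", {
  cells <- small_cohort(n_subjects = 6, seed = 31)
  cfg <- dfdl_config(k_atoms = 8, L = 2, max_iters = 5, seed = 1)
  cv <- cross_validate(cells, grid = small_grid(),
                       pspec = patch_spec(n = 6, stride = 3),
                       config = cfg, mode = "subject", k = 3, seed = 9)
  expect_s3_class(cv, "dfdl_cv")
  expect_equal(nrow(tidy(cv)), 3)
  expect_true(all(tidy(cv)$auc >= 0 & tidy(cv)$auc <= 1))

  # every subject scored exactly once, folds partition subjects evenly
  expect_setequal(cv$scores$entity, unique(cells$subject_id))
  fold_sizes <- cv$scores |>
    dplyr::count(fold, class) |>
    dplyr::pull(n)
  expect_lte(diff(range(fold_sizes)), 1)
  expect_true(all(cv$scores$theta >= 0 & cv$scores$theta <= 1))

  # deterministic under the same seed
  cv2 <- cross_validate(cells, grid = small_grid(),
                        pspec = patch_spec(n = 6, stride = 3),
                        config = cfg, mode = "subject", k = 3, seed = 9)
  expect_identical(cv$folds, cv2$folds)

  # image mode treats images as entities
  cvi <- cross_validate(cells, grid = small_grid(),
                        pspec = patch_spec(n = 6, stride = 3),
                        config = cfg, mode = "image", k = 3, seed = 9)
  expect_setequal(cvi$scores$entity, unique(cells$image_id))

  # too many folds for the entities per class
  expect_error(
    cross_validate(cells, grid = small_grid(),
                   pspec = patch_spec(n = 6, stride = 3),
                   config = cfg, mode = "subject", k = 7, seed = 9),
    "smaller k")
})
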