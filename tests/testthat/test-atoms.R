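make_activity_fixture <- function() {
  # tiny fit: 4 + 4 orthonormal atoms in an 8-dim signal space
  D1 <- diag(8)[, 1:4]
  D2 <- diag(8)[, 5:8]
  fit <- structure(
    list(D1 = list(atoms = D1), D2 = list(atoms = D2),
         D_combined = cbind(D1, D2), k = 4,
         config = dfdl_config(k_atoms = 4, L = 2), patch_dim = c(2, 2, 2)),
    class = "dfdl_fit")
  fit
}

test_that("binarized activity follows the positive-code rule", {
  fit <- make_activity_fixture()
  # class-1 patches load atom 1 positively, atom 2 negatively; class-2
  # patches load atom 5 (first atom of D2)
  Y <- cbind(fit$D_combined[, 1] * 0.3,
             -fit$D_combined[, 2] * 2,
             fit$D_combined[, 5] * 1.5)
  meta <- tibble::tibble(image_id = c("a", "a", "b"),
                         subject_id = c("sa", "sa", "sb"),
                         class = c(1L, 1L, 2L))
  pm <- structure(list(Y = Y, meta = meta, patch_dim = c(2, 2, 2)),
                  class = "patch_matrix")
  act <- compute_activity(pm, fit)

  expect_equal(act$A_i[1, 1], 1L)  # positive code (0.3 before normalization)
  expect_equal(act$A_i[2, 2], 0L)  # negative code excluded
  expect_equal(act$A_i[3, 5], 1L)
  expect_true(all(act$A_i %in% c(0L, 1L)))
  # zero codes are not active
  expect_equal(act$A_i[1, 3], 0L)
  # an atom with only non-positive codes has an all-zero activity column
  expect_true(all(act$A_i[, 2] == 0))
  # per-atom normalization is sign-preserving with unit max magnitude
  expect_equal(max(abs(act$A_o[, 2])), 1)
  expect_lt(act$A_o[2, 2], 0)
  # binarization is idempotent
  expect_identical(((act$A_i > 0) * 1L), act$A_i)

  # a class without patches is an error
  pm1 <- structure(list(Y = Y[, 1:2], meta = meta[1:2, ],
                        patch_dim = c(2, 2, 2)), class = "patch_matrix")
  expect_error(compute_activity(pm1, fit), "class 2")
})

test_that("atom selection finds planted activation differences", {
  fit <- make_activity_fixture()
  n_img <- 20; per_img <- 10
  withr::with_seed(41, {
    meta <- tibble::tibble(
      image_id = rep(sprintf("c%d_i%02d", rep(1:2, each = n_img),
                             rep(seq_len(n_img), 2)), each = per_img),
      subject_id = "s", class = rep(1:2, each = n_img * per_img))
    N <- nrow(meta)
    # atom 1 (class 1): active in 90% of class-1 patches, 5% of class-2
    # atoms 2..8: equally active everywhere
    act1 <- ifelse(meta$class == 1, rbinom(N, 1, 0.9), rbinom(N, 1, 0.05))
    rest <- matrix(rbinom(N * 7, 1, 0.5), N, 7)
    A <- cbind(act1, rest)
  })
  activity <- structure(
    list(A_o = A, A_i = A, meta = meta, k = 4,
         atom_class = rep(1:2, each = 4)),
    class = "atom_activity")

  sig <- select_significant_atoms(activity, alpha = 0.05)
  expect_true(sig$selected[1])
  expect_gt(sig$t_value[1], 0)
  expect_equal(sum(sig$selected[2:8]), 0)

  # identical activation proportions select nothing
  same <- activity
  same$A_i <- matrix(rep(rep(c(1L, 0L), length.out = per_img), 8 * 2 * n_img),
                     ncol = 8)
  expect_equal(sum(select_significant_atoms(same, 0.05)$selected), 0)

  # alpha = 0 selects nothing
  expect_equal(sum(select_significant_atoms(activity, alpha = 0)$selected), 0)
})

test_that("atom reshaping inverts vectorization", {
  fit <- make_activity_fixture()
  fit$D_combined[, 1] <- seq(0.1, 0.8, by = 0.1)
  block <- atom_to_patch(fit, 1)
  expect_identical(vectorize_patch(block), fit$D_combined[, 1])

  # one-hot column maps to the documented cell: position 2 is row 1, col 2
  v <- rep(0, 8); v[2] <- 1
  b <- unvectorize_patch(v, c(2, 2, 2))
  expect_equal(b[1, 2, 1], 1)
  expect_equal(sum(b != 0), 1)

  expect_error(atom_to_patch(matrix(1:6, 3), 1, dim = c(2, 2, 2)),
               "does not match")
})

test_that("c = 2 partial correlation equals weighted Pearson", {
  cfg <- wpcor_config(n_permutations = 1, seed = 1)
  withr::with_seed(42, {
    for (rep in 1:50) {
      n <- sample(4:8, 1)
      block <- array(rnorm(n * n * 2), c(n, n, 2))
      wp <- weighted_partial_correlation(block, cfg)
      w <- dense_lattice_weights(n, n, n / 2)
      ref <- weighted_pearson(as.vector(block[, , 1]),
                              as.vector(block[, , 2]), w)
      expect_equal(wp$pcor[1, 2], ref, tolerance = 1e-10)
    }
  })
})

test_that("partial correlation matrix is symmetric with unit diagonal", {
  withr::with_seed(43, {
    block <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  })
  wp <- weighted_partial_correlation(block, wpcor_config(n_permutations = 19))
  expect_equal(wp$pcor, t(wp$pcor))
  expect_equal(diag(wp$pcor), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(wp$pcor) <= 1 + 1e-8))
})

test_that("a duplicated channel is near-perfectly partially correlated", {
  withr::with_seed(44, {
    a <- matrix(rnorm(64), 8, 8)
    b <- matrix(rnorm(64), 8, 8)
  })
  block <- array(c(a, a, b), c(8, 8, 3))
  wp <- weighted_partial_correlation(block,
                                     wpcor_config(n_permutations = 9,
                                                  shrinkage = TRUE))
  expect_gte(wp$pcor[1, 2], 0.99)
})

test_that("constant channels are undefined sentinels, not errors", {
  withr::with_seed(45, {
    block <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  })
  block[, , 2] <- 7
  wp <- weighted_partial_correlation(block, wpcor_config(n_permutations = 9))
  expect_equal(wp$undefined, "2")
  expect_true(all(is.na(wp$pcor[2, ])))
  expect_false(anyNA(wp$pcor[c(1, 3), c(1, 3)]))
  td <- tidy(wp)
  expect_true(all(is.na(td$p_value[td$channel_a == "2" | td$channel_b == "2"])))
})

test_that("null channels are rarely flagged", {
  cfg <- wpcor_config(n_permutations = 99, alpha = 0.05)
  flagged <- withr::with_seed(46, {
    vapply(1:30, function(rep) {
      block <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
      c2 <- cfg; c2$seed <- rep
      wp <- weighted_partial_correlation(block, c2)
      td <- tidy(wp)
      mean(td$p_value < 0.05)
    }, numeric(1))
  })
  expect_lte(mean(flagged), 0.10)
})

test_that("pair proportions hit the boundary cases", {
  # fit whose class-1 atoms all duplicate channels 1 and 2, while class-2
  # atoms have independent channels
  n <- 6
  d <- n * n * 3
  mk_dup <- function(seed) {
    withr::with_seed(seed, {
      a <- matrix(rnorm(n * n), n, n)
      b <- matrix(rnorm(n * n), n, n)
    })
    v <- vectorize_patch(array(c(a, a + 1e-3 * b, b), c(n, n, 3)))
    v / sqrt(sum(v^2))
  }
  mk_ind <- function(seed) {
    withr::with_seed(seed, v <- rnorm(d))
    v / sqrt(sum(v^2))
  }
  D1 <- vapply(1:4, mk_dup, numeric(d))
  D2 <- vapply(5:8, mk_ind, numeric(d))
  fit <- structure(
    list(D1 = list(atoms = D1), D2 = list(atoms = D2),
         D_combined = cbind(D1, D2), k = 4,
         config = dfdl_config(k_atoms = 4, L = 2), patch_dim = c(n, n, 3)),
    class = "dfdl_fit")
  sig <- tibble::tibble(atom = 1:8, class = rep(1:2, each = 4),
                        t_value = 1, p_value = 0.01,
                        own_mean = 1, other_mean = 0, selected = TRUE)
  prop <- pair_proportions(fit, sig, wpcor_config(n_permutations = 49, seed = 2))
  p12 <- prop |> dplyr::filter(pair_a == "1", pair_b == "2")
  expect_equal(p12$proportion[p12$class == 1], 1.0)
  expect_equal(p12$n_atoms, c(4L, 4L))

  comp <- compare_pair_proportions(prop)
  z12 <- comp |> dplyr::filter(pair_a == "1", pair_b == "2")
  expect_gt(z12$proportion_1, z12$proportion_2)
})

test_that("two-proportion z matches the pooled closed form and prop.test", {
  # worked example: 0.8 of 32 vs 0.5 of 30 (counts 26 and 15)
  z <- mifdict:::two_proportion_z(26, 32, 15, 30)
  p1 <- 26 / 32; p2 <- 15 / 30; pp <- (26 + 15) / 62
  z_ref <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 32 + 1 / 30))
  expect_equal(z, z_ref)
  pt <- prop.test(c(26, 15), c(32, 30), correct = FALSE)
  expect_equal(z^2, unname(pt$statistic))

  expect_equal(mifdict:::two_proportion_z(10, 20, 10, 20), 0)
  # 1.0 vs 0.0 with n = 30 each: overwhelming evidence
  z3 <- mifdict:::two_proportion_z(30, 30, 0, 30)
  expect_lt(2 * pnorm(-abs(z3)), 0.001)
  # degenerate pooled proportion
  expect_equal(mifdict:::two_proportion_z(20, 20, 20, 20), 0)
})

test_that("comparison skips pairs missing a class with a warning", {
  tab <- tibble::tibble(
    pair_a = c("A", "A", "B"), pair_b = c("B", "C", "C"),
    class = c(1L, 1L, 2L),
    n_atoms = c(10L, 10L, 8L), n_correlated = c(5L, 2L, 4L),
    proportion = c(0.5, 0.2, 0.5))
  expect_warning(out <- compare_pair_proportions(tab), "skipped")
  expect_equal(nrow(out), 0)

  both <- tibble::tibble(
    pair_a = rep("A", 2), pair_b = rep("B", 2), class = 1:2,
    n_atoms = c(10L, 10L), n_correlated = c(5L, 5L),
    proportion = c(0.5, 0.5))
  out2 <- compare_pair_proportions(both)
  expect_equal(out2$z, 0)
  expect_equal(out2$p_value, 1)
})
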