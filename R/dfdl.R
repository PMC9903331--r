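# Discriminative dictionary learning.
#
# For each class a dictionary D (d x k, unit-norm atoms) is learned to
# minimize
#
#   (1/N) min_{||S||_0 <= L} ||Y - D S||_F^2
#     - (rho/N) min_{||Sbar||_0 <= L} ||Ybar - D Sbar||_F^2
#
# by alternating (i) OMP sparse coding of both classes against the current D
# and (ii) a block-coordinate atom update on the quadratic surrogate with the
# codes held fixed.  The discriminative term makes the surrogate's curvature
# possibly indefinite, so atoms with non-positive curvature are left
# untouched, and atoms no in-class code ever selects are re-seeded from the
# worst reconstructed in-class patch.

#' Configure discriminative dictionary training
#'
#' @param k_atoms Atoms per class dictionary (default 50).
#' @param L Maximum nonzeros per sparse code (default 5).
#' @param rho Discrimination trade-off, >= 0 (default 0.1).  Low `rho` favors
#'   own-class reconstruction; high `rho` favors explaining the other class
#'   poorly at the expense of own-class fit.
#' @param max_iters Maximum alternations (default 30).
#' @param rel_tol Relative objective-change stopping tolerance (default 1e-4).
#' @param delta Curvature floor below which an atom update is skipped.
#' @param normalize_by_own_N If `TRUE`, the out-class term is divided by its
#'   own column count instead of N (the original DFDL convention); default
#'   `FALSE`, matching the printed objective.
#' @param coder `"omp"` (default) or `"lasso"` (experimental l1 coder via
#'   glmnet, refit on its support).
#' @param seed Integer seed driving initialization and any sampling.
#' @return A `dfdl_config` object.
#' @export
dfdl_config <- function(k_atoms = 50, L = 5, rho = 0.1, max_iters = 30,
                        rel_tol = 1e-4, delta = 1e-8,
                        normalize_by_own_N = FALSE,
                        coder = c("omp", "lasso"), seed = 1L) {
  coder <- match.arg(coder)
  if (k_atoms < 1) abort("k_atoms must be >= 1")
  if (L < 1) abort("L must be >= 1")
  if (L > k_atoms) abort("L must not exceed k_atoms")
  if (rho < 0) abort("rho must be >= 0")
  if (max_iters < 1) abort("max_iters must be >= 1")
  structure(
    list(k_atoms = as.integer(k_atoms), L = as.integer(L), rho = rho,
         max_iters = as.integer(max_iters), rel_tol = rel_tol, delta = delta,
         normalize_by_own_N = normalize_by_own_N, coder = coder,
         seed = as.integer(seed)),
    class = "dfdl_config"
  )
}

check_unit_norm <- function(D, tol = 1e-8) {
  nrm <- sqrt(colSums(D^2))
  if (any(abs(nrm - 1) > tol)) {
    abort("dictionary columns must have unit l2 norm")
  }
  invisible(nrm)
}

#' Sparse-code one signal by orthogonal matching pursuit
#'
#' Greedy OMP: repeatedly select the atom with the largest absolute inner
#' product with the residual, refit least squares on the selected support,
#' and stop at `L` atoms or when the residual l2 norm falls below
#' `resid_tol`.
#'
#' @param y Signal vector (length d).
#' @param D Dictionary, d x k with unit-norm columns.
#' @param L Maximum number of selected atoms (`L = 0` gives the zero code).
#' @param resid_tol Residual norm for early exit.
#' @return List with `coef` (length-k vector, at most `L` nonzeros),
#'   `support` (selected column indices) and `residual_norm`.
#' @export
omp_code <- function(y, D, L, resid_tol = 1e-10) {
  check_unit_norm(D)
  if (L < 0) abort("L must be >= 0")
  s <- drop(.omp_encode_cpp(D, matrix(y, ncol = 1), as.integer(L),
                            resid_tol^2))
  r <- y - D %*% s
  list(coef = s, support = which(s != 0), residual_norm = sqrt(sum(r^2)))
}

# Batch coder used internally: returns k x N coefficient matrix.
sparse_encode <- function(D, Y, L, coder = "omp", resid_tol = 1e-10) {
  if (coder == "omp") {
    return(.omp_encode_cpp(D, Y, as.integer(L), resid_tol^2))
  }
  lasso_encode(D, Y, L)
}

# Experimental l1 coder: glmnet lasso path per column, take the densest
# solution with at most L nonzeros and refit least squares on its support.
lasso_encode <- function(D, Y, L) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    abort("the lasso coder requires the glmnet package")
  }
  k <- ncol(D)
  S <- matrix(0, k, ncol(Y))
  for (i in seq_len(ncol(Y))) {
    fit <- glmnet::glmnet(D, Y[, i], intercept = FALSE, standardize = FALSE,
                          nlambda = 50)
    ok <- which(fit$df <= L)
    if (!length(ok)) next
    b <- as.numeric(fit$beta[, ok[length(ok)]])
    supp <- which(b != 0)
    if (length(supp)) {
      b[supp] <- qr.coef(qr(D[, supp, drop = FALSE]), Y[, i])
      S[, i] <- b
    }
  }
  S
}

#' Evaluate the discriminative objective
#'
#' `(1/N) ||Y - D S||_F^2 - (rho/Nden) ||Ybar - D Sbar||_F^2` with the inner
#' minimizations approximated by OMP at sparsity `L`; `Nden` is `N` by
#' default, or the out-class count under `normalize_by_own_N`.
#'
#' @param D Dictionary (unit-norm columns).
#' @param Y,Ybar In-class / out-class signal matrices (d x N, d x Nbar).
#' @param L Sparsity level.
#' @param rho Trade-off parameter.
#' @param normalize_by_own_N See [dfdl_config()].
#' @return Scalar objective value.
#' @export
objective_value <- function(D, Y, Ybar, L, rho, normalize_by_own_N = FALSE) {
  if (nrow(Y) != nrow(D) || nrow(Ybar) != nrow(D)) {
    abort("dimension mismatch between dictionary and signals")
  }
  S <- sparse_encode(D, Y, L)
  Sb <- sparse_encode(D, Ybar, L)
  nden <- if (normalize_by_own_N) ncol(Ybar) else ncol(Y)
  sum((Y - D %*% S)^2) / ncol(Y) - rho * sum((Ybar - D %*% Sb)^2) / nden
}

#' Train one class's discriminative dictionary
#'
#' Alternates OMP coding of both classes with a block-coordinate atom update
#' on the surrogate statistics
#' `E = (1/N) Y S' - (rho/Nden) Ybar Sbar'` and
#' `F = (1/N) S S' - (rho/Nden) Sbar Sbar'`; atom j moves to
#' `(e_j - D f_j + d_j F_jj) / F_jj` (then renormalized) only when
#' `F_jj > delta`.  Initialization takes `k_atoms` distinct in-class columns
#' chosen by the config seed.  Deterministic given inputs and config.
#'
#' @param Y In-class patch matrix (d x N) or a `patch_matrix`.
#' @param Ybar Out-class patch matrix (d x Nbar) or a `patch_matrix`.
#' @param config A [dfdl_config()].
#' @param class_id Class this dictionary represents (1 or 2).
#' @return A `class_dictionary`: list with `atoms` (d x k, unit-norm
#'   columns), `class_id`, `config`, `objective_trace`, `n_iters`.
#' @export
train_dfdl <- function(Y, Ybar, config = dfdl_config(), class_id = 1L) {
  if (inherits(Y, "patch_matrix")) Y <- Y$Y
  if (inherits(Ybar, "patch_matrix")) Ybar <- Ybar$Y
  if (ncol(Y) == 0 || ncol(Ybar) == 0) abort("both classes must be non-empty")
  if (nrow(Y) != nrow(Ybar)) abort("Y and Ybar must share signal dimension d")
  k <- config$k_atoms
  if (ncol(Y) < k) {
    abort(sprintf("need at least k = %d in-class patches, got %d", k, ncol(Y)))
  }

  N <- ncol(Y)
  nden <- if (config$normalize_by_own_N) ncol(Ybar) else N
  rho <- config$rho

  init_idx <- withr::with_seed(derive_seed(config$seed, 101L),
                               sample.int(N, k))
  D <- Y[, init_idx, drop = FALSE]
  nrm <- sqrt(colSums(D^2))
  nrm[nrm < 1e-12] <- 1
  D <- sweep(D, 2, nrm, "/")
  # degenerate (all-zero) initial columns get a random unit vector
  zero <- which(colSums(D^2) < 1e-20)
  if (length(zero)) {
    D[, zero] <- withr::with_seed(derive_seed(config$seed, 131L), {
      m <- matrix(rnorm(nrow(D) * length(zero)), nrow(D))
      sweep(m, 2, sqrt(colSums(m^2)), "/")
    })
  }

  trace <- numeric(0)
  prev <- Inf
  iters <- 0L
  for (it in seq_len(config$max_iters)) {
    iters <- it
    S <- sparse_encode(D, Y, config$L, config$coder)
    Sb <- sparse_encode(D, Ybar, config$L, config$coder)
    obj <- sum((Y - D %*% S)^2) / N - rho * sum((Ybar - D %*% Sb)^2) / nden
    trace <- c(trace, obj)

    E <- (Y %*% t(S)) / N - rho * (Ybar %*% t(Sb)) / nden
    Fm <- (S %*% t(S)) / N - rho * (Sb %*% t(Sb)) / nden
    for (j in seq_len(k)) {
      fjj <- Fm[j, j]
      if (fjj <= config$delta) next
      dj <- (E[, j] - D %*% Fm[, j] + D[, j] * fjj) / fjj
      nj <- sqrt(sum(dj^2))
      if (nj > 1e-12) D[, j] <- dj / nj
    }

    # re-seed atoms never used by an in-class code
    unused <- which(rowSums(S != 0) == 0)
    if (length(unused)) {
      resid2 <- colSums((Y - D %*% S)^2)
      worst <- order(resid2, decreasing = TRUE)
      for (q in seq_along(unused)) {
        cand <- Y[, worst[q]]
        nc <- sqrt(sum(cand^2))
        if (nc > 1e-12) D[, unused[q]] <- cand / nc
      }
    }

    if (is.finite(prev) &&
        abs(obj - prev) <= config$rel_tol * max(1, abs(prev))) break
    prev <- obj
  }

  structure(
    list(atoms = D, class_id = as.integer(class_id), config = config,
         objective_trace = trace, n_iters = iters),
    class = "class_dictionary"
  )
}

#' Train the pair of class dictionaries and concatenate them
#'
#' Runs [train_dfdl()] with class roles swapped, then forms the combined
#' dictionary `[D1 | D2]` used for residual classification and the atom
#' interpretability stage.
#'
#' @param Y1,Y2 Patch matrices (d x N) for class 1 and class 2, or
#'   `patch_matrix` objects.
#' @param config A [dfdl_config()].
#' @param patch_dim Optional `c(n, n, c)` patch shape carried along for atom
#'   reshaping and plots (taken from `patch_matrix` inputs automatically).
#' @return A `dfdl_fit`: list with `D1`, `D2` (class dictionaries),
#'   `D_combined` (d x 2k), `k`, `config`, `patch_dim`.
#' @export
train_pair <- function(Y1, Y2, config = dfdl_config(), patch_dim = NULL) {
  if (inherits(Y1, "patch_matrix")) {
    patch_dim <- patch_dim %||% Y1$patch_dim
    Y1 <- Y1$Y
  }
  if (inherits(Y2, "patch_matrix")) {
    patch_dim <- patch_dim %||% Y2$patch_dim
    Y2 <- Y2$Y
  }
  d1 <- train_dfdl(Y1, Y2, config, class_id = 1L)
  d2 <- train_dfdl(Y2, Y1, config, class_id = 2L)
  structure(
    list(D1 = d1, D2 = d2,
         D_combined = cbind(d1$atoms, d2$atoms),
         k = config$k_atoms, config = config, patch_dim = patch_dim),
    class = "dfdl_fit"
  )
}

#' @export
print.dfdl_fit <- function(x, ...) {
  cat(sprintf(
    "<dfdl_fit: %d + %d atoms of dimension %d (L = %d, rho = %g)>\n",
    ncol(x$D1$atoms), ncol(x$D2$atoms), nrow(x$D_combined),
    x$config$L, x$config$rho))
  invisible(x)
}

#' @rdname train_pair
#' @param x A `dfdl_fit`.
#' @param ... Unused.
#' @export
tidy.dfdl_fit <- function(x, ...) {
  k <- x$k
  tibble(
    atom = seq_len(2 * k),
    class = rep(1:2, each = k),
    within_class_index = rep(seq_len(k), 2),
    norm = sqrt(colSums(x$D_combined^2))
  )
}

#' @rdname train_pair
#' @export
glance.dfdl_fit <- function(x, ...) {
  tibble(
    d = nrow(x$D_combined),
    k_per_class = x$k,
    n_atoms = ncol(x$D_combined),
    L = x$config$L,
    rho = x$config$rho,
    iters_class1 = x$D1$n_iters,
    iters_class2 = x$D2$n_iters,
    objective_class1 = tail(x$D1$objective_trace, 1),
    objective_class2 = tail(x$D2$objective_trace, 1)
  )
}

#' Mosaic plot of learned atoms
#'
#' Reshapes dictionary atoms back to n x n x c blocks and shows each
#' requested atom's channels as intensity rasters.
#'
#' @param object A `dfdl_fit` with a known `patch_dim`.
#' @param atoms Which combined-dictionary columns to show (default first 4
#'   of each class).
#' @param channels Channel labels (defaults to channel indices).
#' @param ... Unused.
#' @return A ggplot faceted by atom and channel.
#' @export
autoplot.dfdl_fit <- function(object, atoms = NULL,
                              channels = NULL, ...) {
  if (is.null(object$patch_dim)) {
    abort("fit has no patch_dim; pass patch_dim to train_pair()")
  }
  k <- object$k
  atoms <- atoms %||% c(seq_len(min(4, k)), k + seq_len(min(4, k)))
  pd <- object$patch_dim
  channels <- channels %||% as.character(seq_len(pd[3]))
  df <- purrr::map(atoms, function(a) {
    bl <- unvectorize_patch(object$D_combined[, a], pd)
    purrr::map(seq_len(pd[3]), function(ch) {
      tibble(atom = sprintf("atom %d (class %d)", a, if (a <= k) 1L else 2L),
             channel = channels[ch],
             row = rep(seq_len(pd[1]), times = pd[2]),
             col = rep(seq_len(pd[2]), each = pd[1]),
             value = as.vector(bl[, , ch]))
    }) |> list_rbind()
  }) |> list_rbind()
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    facet_grid(atom ~ channel) +
    scale_fill_viridis_c(name = NULL) +
    coord_fixed() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}
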