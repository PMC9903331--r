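# Spatially weighted partial correlation between the channels of a patch.
#
# Pixels of the n x n lattice receive weights from a uniformly varying
# Gaussian kernel k(x_i, x_j) = exp(-||x_i - x_j||^2 / sigma^2): each pixel's
# weight is its kernel row sum, so central pixels count more than border
# pixels.  A weighted channel covariance is inverted to partial correlations
# (correlation between two channels given the rest); significance comes from
# seeded permutations of pixel assignments per channel, since the effective
# sample size under spatial weighting is not the pixel count.

#' Configure the weighted partial-correlation analysis
#'
#' @param sigma_px Kernel bandwidth in patch cells; `NULL` (default) means
#'   half the patch side.
#' @param n_permutations Permutations for the two-sided p-values (default 999).
#' @param shrinkage Shrink the covariance toward its diagonal when
#'   near-singular (default `TRUE`).
#' @param alpha Significance level used downstream (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return A `wpcor_config` object.
#' @export
wpcor_config <- function(sigma_px = NULL, n_permutations = 999,
                         shrinkage = TRUE, alpha = 0.05, seed = 1L) {
  if (!is.null(sigma_px) && sigma_px <= 0) abort("sigma_px must be > 0")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  structure(
    list(sigma_px = sigma_px, n_permutations = as.integer(n_permutations),
         shrinkage = shrinkage, alpha = alpha, seed = as.integer(seed)),
    class = "wpcor_config"
  )
}

# Pixel weights: row sums of the Gaussian kernel matrix over the lattice,
# normalized to sum 1.  Separable, so computed without the N x N matrix.
lattice_weights <- function(n_rows, n_cols, sigma) {
  rows <- seq_len(n_rows)
  cols <- seq_len(n_cols)
  kr <- exp(-outer(rows, rows, "-")^2 / sigma^2)
  kc <- exp(-outer(cols, cols, "-")^2 / sigma^2)
  # sum_j exp(-(dr^2+dc^2)/s^2) factorizes into row and column sums
  w <- outer(rowSums(kr), rowSums(kc))
  as.vector(w / sum(w))
}

# Weighted covariance (biased, weights sum to 1) and partial correlations.
# Returns NULL if the (possibly shrunk) covariance is still not invertible.
weighted_pcor <- function(Z, w, shrinkage = TRUE) {
  mu <- colSums(Z * w)
  Zc <- sweep(Z, 2, mu)
  Sigma <- crossprod(Zc * sqrt(w))
  lambdas <- if (shrinkage) c(0, 1e-4, 1e-3, 1e-2, 1e-1) else 0
  for (lam in lambdas) {
    Sl <- (1 - lam) * Sigma + lam * diag(diag(Sigma), nrow(Sigma))
    Om <- tryCatch(solve(Sl), error = function(e) NULL)
    if (!is.null(Om) && all(is.finite(Om))) {
      dd <- sqrt(diag(Om))
      P <- -Om / outer(dd, dd)
      diag(P) <- 1
      return(P)
    }
  }
  NULL
}

#' Spatially weighted partial correlations of a patch block
#'
#' @param block An `n x n x c` array (a patch or a reshaped dictionary atom).
#' @param config A [wpcor_config()].
#' @return A `wpcor` object: list with `pcor` and `p_value` (c x c matrices;
#'   `NA` rows/columns for constant channels, which are flagged in
#'   `undefined`), `sigma_px`, `n_permutations`.
#' @export
weighted_partial_correlation <- function(block, config = wpcor_config()) {
  d <- dim(block)
  if (length(d) != 3 || d[3] < 2) abort("block must be n x n x c with c >= 2")
  if (!all(is.finite(block))) abort("block must be finite")
  nch <- d[3]
  labs <- dimnames(block)[[3]] %||% as.character(seq_len(nch))
  sigma <- config$sigma_px %||% (d[1] / 2)
  w <- lattice_weights(d[1], d[2], sigma)
  Z <- matrix(block, nrow = d[1] * d[2], ncol = nch)

  mu <- colSums(Z * w)
  v <- colSums(sweep(Z, 2, mu)^2 * w)
  defined <- v > 1e-18
  pcor <- matrix(NA_real_, nch, nch, dimnames = list(labs, labs))
  pval <- matrix(NA_real_, nch, nch, dimnames = list(labs, labs))

  if (sum(defined) >= 2) {
    Zd <- Z[, defined, drop = FALSE]
    P <- weighted_pcor(Zd, w, config$shrinkage)
    if (!is.null(P)) {
      pcor[defined, defined] <- P
      B <- config$n_permutations
      npx <- nrow(Zd)
      exceed <- matrix(0, ncol(Zd), ncol(Zd))
      n_ok <- 0
      withr::with_seed(derive_seed(config$seed, 907L), {
        for (b in seq_len(B)) {
          Zp <- apply(Zd, 2, function(col) col[sample.int(npx)])
          Pp <- weighted_pcor(Zp, w, config$shrinkage)
          if (is.null(Pp)) next
          n_ok <- n_ok + 1
          exceed <- exceed + (abs(Pp) >= abs(P) - 1e-12)
        }
      })
      pv <- (exceed + 1) / (n_ok + 1)
      diag(pv) <- NA_real_
      pval[defined, defined] <- pv
    }
  }

  structure(
    list(pcor = pcor, p_value = pval, sigma_px = sigma,
         n_permutations = config$n_permutations,
         undefined = labs[!defined]),
    class = "wpcor"
  )
}

#' @export
print.wpcor <- function(x, ...) {
  cat(sprintf("<wpcor: %d channels, sigma = %g px, %d permutations>\n",
              nrow(x$pcor), x$sigma_px, x$n_permutations))
  print(round(x$pcor, 3))
  invisible(x)
}

#' @rdname weighted_partial_correlation
#' @param x A `wpcor` object.
#' @param ... Unused.
#' @return `tidy()`: one row per unordered channel pair with `pcor` and
#'   `p_value`.
#' @export
tidy.wpcor <- function(x, ...) {
  labs <- rownames(x$pcor)
  pairs <- utils::combn(seq_along(labs), 2)
  tibble(
    channel_a = labs[pairs[1, ]],
    channel_b = labs[pairs[2, ]],
    pcor = x$pcor[t(pairs)],
    p_value = x$p_value[t(pairs)]
  )
}
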