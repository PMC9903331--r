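# Patch extraction, low-intensity filtering and vectorization.
#
# Patches are n x n x c sub-blocks of a composite image, taken on a stride
# lattice so none straddles the border.  Near-empty patches (more than
# `low_frac` of values below `low_tol`) are discarded before any training or
# scoring.  Vectorization order is fixed: channel slowest, row-major within a
# channel; classification is invariant to the choice, but the inverse reshape
# must match for atom visualization and the correlation stage.

#' Specify patch extraction and filtering
#'
#' @param n Patch side in grid cells (patches are `n x n x c`).
#' @param stride Lattice step between patch origins, in cells (default 10,
#'   i.e. 50% overlap at the default `n = 20`).
#' @param low_frac A patch is dropped iff strictly more than this fraction of
#'   its values is below `low_tol` (default 0.70).
#' @param low_tol Intensity threshold for "empty" values (default 1e-15).
#' @return A `patch_spec` object.
#' @export
patch_spec <- function(n = 20, stride = 10, low_frac = 0.70, low_tol = 1e-15) {
  if (n < 1) abort("patch side `n` must be >= 1")
  if (stride < 1 || stride > n) abort("`stride` must lie in 1..n")
  if (low_frac <= 0 || low_frac >= 1) abort("`low_frac` must lie in (0, 1)")
  if (low_tol <= 0) abort("`low_tol` must be > 0")
  structure(list(n = as.integer(n), stride = as.integer(stride),
                 low_frac = low_frac, low_tol = low_tol),
            class = "patch_spec")
}

# Closed-form number of lattice origins along an axis.
n_origins <- function(extent, n, stride) {
  if (n > extent) 0L else as.integer((extent - n) %/% stride + 1L)
}

#' Extract overlapping patches from a composite image
#'
#' All patches whose top-left (low-row, low-col) origin lies on the stride
#' lattice and that fit entirely inside the image, in raster order (row-major
#' over origins).
#'
#' @param img A `composite_image`.
#' @param spec A [patch_spec()].
#' @return Tibble with `origin_row`, `origin_col`, `image_id`, `subject_id`,
#'   `class` and a `block` list-column of n x n x c arrays.
#' @export
extract_patches <- function(img, spec = patch_spec()) {
  d <- dim(img$stack)
  if (spec$n > d[1] || spec$n > d[2]) {
    abort(sprintf("patch side %d exceeds image dimensions %d x %d",
                  spec$n, d[1], d[2]))
  }
  row0 <- seq(1L, d[1] - spec$n + 1L, by = spec$stride)
  col0 <- seq(1L, d[2] - spec$n + 1L, by = spec$stride)
  grid <- expand.grid(origin_col = col0, origin_row = row0)  # row-major order
  blocks <- purrr::map2(grid$origin_row, grid$origin_col, function(r, cl) {
    img$stack[r:(r + spec$n - 1L), cl:(cl + spec$n - 1L), , drop = FALSE]
  })
  tibble(
    origin_row = grid$origin_row,
    origin_col = grid$origin_col,
    image_id = img$image_id,
    subject_id = img$subject_id,
    class = img$class_label,
    block = blocks
  )
}

#' Drop near-empty patches
#'
#' A patch is removed iff strictly more than `low_frac` of its `n^2 * c`
#' values is below `low_tol`; survivor order is preserved.  Idempotent.
#'
#' @param patches Tibble from [extract_patches()] (rows from several images
#'   may be concatenated).
#' @param spec A [patch_spec()] providing the thresholds.
#' @return The surviving rows of `patches`.
#' @export
filter_low_intensity <- function(patches, spec = patch_spec()) {
  keep <- map_dbl(patches$block, ~ mean(.x < spec$low_tol)) <= spec$low_frac
  patches[keep, , drop = FALSE]
}

#' Vectorize a patch block
#'
#' Fixed order: channel slowest, row-major within each channel.
#'
#' @param block An n x n x c array.
#' @return Numeric vector of length `n^2 * c`.
#' @seealso [unvectorize_patch()]
#' @export
vectorize_patch <- function(block) {
  as.vector(aperm(block, c(2, 1, 3)))
}

#' Invert [vectorize_patch()]
#'
#' @param v Numeric vector of length `prod(dim)`.
#' @param dim Target dimensions `c(n_rows, n_cols, c)`.
#' @return The original array, bit-exactly.
#' @export
unvectorize_patch <- function(v, dim) {
  if (length(v) != prod(dim)) {
    abort(sprintf("vector length %d does not match dim %s",
                  length(v), paste(dim, collapse = " x ")))
  }
  aperm(array(v, dim = dim[c(2, 1, 3)]), c(2, 1, 3))
}

#' Column-stack patches into a learner matrix
#'
#' @param patches Tibble with a `block` list-column and per-patch metadata.
#' @return A `patch_matrix`: list with `Y` (d x N matrix of vectorized
#'   patches) and `meta` (tibble of per-column metadata), plus `patch_dim`.
#' @export
patch_matrix <- function(patches) {
  if (nrow(patches) == 0) abort("no patches to stack")
  dim0 <- dim(patches$block[[1]])
  Y <- vapply(patches$block, vectorize_patch, numeric(prod(dim0)))
  structure(
    list(Y = Y,
         meta = patches |> select(-"block"),
         patch_dim = dim0),
    class = "patch_matrix"
  )
}

#' Assemble class-split training matrices
#'
#' Splits filtered patches into the two class matrices `Y` (class 1) and
#' `Ybar` (class 2).  With `proportional = TRUE` and a total budget, per-class
#' patch counts are proportional to class sizes measured in subjects, sampled
#' without replacement under `seed`.
#'
#' @param patches Filtered patch tibble covering both classes.
#' @param proportional Sample patches proportionally to class subject counts?
#' @param n_total Total patch budget when `proportional = TRUE`.
#' @param seed Integer seed for the sampling.
#' @return List with `Y`, `Ybar` (`patch_matrix` objects for class 1 and 2).
#' @export
assemble_training <- function(patches, proportional = FALSE, n_total = NULL,
                              seed = 1L) {
  for (cl in 1:2) {
    if (!any(patches$class == cl)) {
      abort(sprintf("class %d has zero surviving patches", cl))
    }
  }
  split <- list(patches[patches$class == 1, ], patches[patches$class == 2, ])
  if (proportional) {
    if (is.null(n_total)) abort("`n_total` is required when proportional = TRUE")
    sizes <- vapply(split, function(p) n_distinct(p$subject_id), integer(1))
    quota <- round(n_total * sizes / sum(sizes))
    quota[1] <- n_total - quota[2]  # keep the total exact
    quota <- pmin(quota, vapply(split, nrow, integer(1)))
    withr::with_seed(derive_seed(seed, 17L), {
      split <- purrr::map2(split, quota, function(p, q) {
        p[sort(sample.int(nrow(p), q)), ]
      })
    })
  }
  list(Y = patch_matrix(split[[1]]), Ybar = patch_matrix(split[[2]]))
}
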