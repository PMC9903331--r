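# Kernel-smoothed intensity surfaces and multi-channel composite images.
#
# Each phenotype's point pattern becomes a gridded isotropic-Gaussian kernel
# intensity estimate (points per um^2), optionally edge-corrected; the
# per-phenotype surfaces are stacked into an l x m x c composite, the
# pseudocolor representation fed to the dictionary learner.

#' Specify the evaluation grid for intensity surfaces
#'
#' The grid is row-major with row index running along y (row 1 at the bottom
#' edge of the window) and column index along x; values are sampled at cell
#' centers.  The grid implies the observation window: width =
#' `n_cols * cell_size_um`, height = `n_rows * cell_size_um` from `origin`.
#'
#' @param n_rows,n_cols Grid dimensions `l` and `m` (default 70 x 50).
#' @param cell_size_um Side of a square grid cell in microns.
#' @param origin Window lower-left corner `c(x, y)` in microns.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(n_rows = 70, n_cols = 50, cell_size_um = 20,
                      origin = c(0, 0)) {
  if (n_rows < 1 || n_cols < 1) abort("grid dimensions must be >= 1")
  if (cell_size_um <= 0) abort("cell_size_um must be > 0")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_um = cell_size_um, origin = as.numeric(origin)),
    class = "grid_spec"
  )
}

#' Build the default grid for a cohort's window
#'
#' Keeps the default 70 x 50 cell layout and picks the cell size from the
#' window so that the grid covers it, aspect preserved within one cell.
#'
#' @param window Named `c(width, height)` in microns.
#' @param n_rows,n_cols Grid dimensions.
#' @return A [grid_spec()].
#' @export
grid_for_window <- function(window, n_rows = 70, n_cols = 50) {
  cs_x <- window[["width"]] / n_cols
  cs_y <- window[["height"]] / n_rows
  if (abs(cs_x - cs_y) > min(cs_x, cs_y) * 1e-6) {
    warn(sprintf(
      "window aspect (%.3g) differs from grid aspect; using cell size %.4g um (x-derived)",
      window[["width"]] / window[["height"]], cs_x))
  }
  grid_spec(n_rows = n_rows, n_cols = n_cols, cell_size_um = cs_x)
}

grid_x_centers <- function(grid) {
  grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_um
}

grid_y_centers <- function(grid) {
  grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size_um
}

grid_window <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + grid$n_cols * grid$cell_size_um,
    ymin = grid$origin[2],
    ymax = grid$origin[2] + grid$n_rows * grid$cell_size_um)
}

#' Kernel intensity estimate of one phenotype's point pattern
#'
#' Isotropic Gaussian kernel (truncated at 4 sigma) evaluated at grid cell
#' centers, in points per um^2.  With `edge_correction = "diggle"` (default)
#' each point's kernel is divided by its in-window mass, which conserves
#' total mass exactly up to grid discretization; `"uniform"` instead divides
#' each cell's estimate by the kernel mass falling inside the window when
#' centered at that cell, and `"none"` applies no correction.  Either
#' correction makes the surface integrate (sum times cell area) to
#' approximately the number of points.
#'
#' @param cells Cell table (at least `phenotype`, `x_um`, `y_um`); typically
#'   one image's rows of [simulate_cohort()] output.
#' @param phenotype Which phenotype to estimate.
#' @param grid A [grid_spec()] covering the window.
#' @param bandwidth_um Gaussian sigma in microns (default 1.5 grid cells).
#' @param edge_correction `"diggle"`, `"uniform"` or `"none"`; `TRUE`/`FALSE`
#'   are accepted as diggle/none.
#' @return A `phenotype_surface`: list with `values` (n_rows x n_cols matrix),
#'   `phenotype`, `bandwidth_um`, `edge_correction`, `grid`.
#' @export
estimate_intensity <- function(cells, phenotype, grid = grid_spec(),
                               bandwidth_um = 1.5 * grid$cell_size_um,
                               edge_correction = "diggle") {
  if (isTRUE(edge_correction)) edge_correction <- "diggle"
  if (isFALSE(edge_correction)) edge_correction <- "none"
  edge_correction <- match.arg(edge_correction, c("diggle", "uniform", "none"))
  if (bandwidth_um <= 0) abort("bandwidth_um must be > 0")
  declared <- attr(cells, "phenotypes")
  if (!is.null(declared) && !phenotype %in% declared) {
    abort(sprintf("phenotype '%s' is not in the declared list", phenotype))
  }
  win <- grid_window(grid)
  pts <- cells[cells$phenotype == phenotype, c("x_um", "y_um")]
  if (nrow(pts) > 0 &&
      (any(pts$x_um < win["xmin"]) || any(pts$x_um > win["xmax"]) ||
       any(pts$y_um < win["ymin"]) || any(pts$y_um > win["ymax"]))) {
    abort("points lie outside the grid's window")
  }

  sig <- bandwidth_um
  xc <- grid_x_centers(grid)
  yc <- grid_y_centers(grid)
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  halo <- 4 * sig  # truncation radius

  for (i in seq_len(nrow(pts))) {
    px <- pts$x_um[i]; py <- pts$y_um[i]
    ci <- which(abs(xc - px) <= halo)
    ri <- which(abs(yc - py) <= halo)
    if (!length(ci) || !length(ri)) next
    kx <- dnorm(xc[ci], px, sig)
    ky <- dnorm(yc[ri], py, sig)
    w <- 1
    if (edge_correction == "diggle") {
      w <- (pnorm(win["xmax"], px, sig) - pnorm(win["xmin"], px, sig)) *
           (pnorm(win["ymax"], py, sig) - pnorm(win["ymin"], py, sig))
    }
    vals[ri, ci] <- vals[ri, ci] + outer(ky, kx) / w
  }

  if (edge_correction == "uniform" && nrow(pts) > 0) {
    ex <- pnorm(win["xmax"], xc, sig) - pnorm(win["xmin"], xc, sig)
    ey <- pnorm(win["ymax"], yc, sig) - pnorm(win["ymin"], yc, sig)
    vals <- vals / outer(ey, ex)
  }

  structure(
    list(values = vals, phenotype = phenotype, bandwidth_um = bandwidth_um,
         edge_correction = edge_correction, grid = grid),
    class = "phenotype_surface"
  )
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("n_rows", "n_cols", "cell_size_um", "origin")],
                   b[c("n_rows", "n_cols", "cell_size_um", "origin")]))
}

#' Stack phenotype surfaces into a composite image
#'
#' @param surfaces List of [estimate_intensity()] results sharing one grid.
#' @param order Phenotype labels giving the channel order; must cover each
#'   surface exactly once.
#' @param image_id,subject_id,class_label Optional metadata to carry along.
#' @return A `composite_image`: list with `stack` (l x m x c array),
#'   `channel_order`, `grid`, and the metadata fields.
#' @export
build_composite <- function(surfaces, order = NULL, image_id = NA_character_,
                            subject_id = NA_character_, class_label = NA_integer_) {
  labs <- vapply(surfaces, function(s) s$phenotype, character(1))
  order <- order %||% labs
  if (anyDuplicated(order) || !setequal(order, labs) ||
      length(order) != length(surfaces)) {
    abort("`order` must cover each surface's phenotype exactly once")
  }
  g <- surfaces[[1]]$grid
  for (s in surfaces[-1]) {
    if (!same_grid(s$grid, g)) abort("surfaces are on different grids")
  }
  stack <- array(0, dim = c(g$n_rows, g$n_cols, length(order)),
                 dimnames = list(NULL, NULL, order))
  for (j in seq_along(order)) {
    stack[, , j] <- surfaces[[which(labs == order[j])]]$values
  }
  structure(
    list(stack = stack, channel_order = order, grid = g,
         image_id = image_id, subject_id = subject_id,
         class_label = class_label),
    class = "composite_image"
  )
}

#' One-call composite for a single image's cells
#'
#' @inheritParams estimate_intensity
#' @param phenotypes Channel order; defaults to the table's declared list.
#' @param normalize_channels If `TRUE`, divide each channel by its maximum
#'   (documented deviation: the raw estimator applies no cross-channel
#'   normalization).
#' @return A `composite_image`.
#' @export
compose_image <- function(cells, grid = grid_spec(),
                          bandwidth_um = 1.5 * grid$cell_size_um,
                          phenotypes = attr(cells, "phenotypes"),
                          edge_correction = "diggle",
                          normalize_channels = FALSE) {
  if (is.null(phenotypes)) phenotypes <- sort(unique(cells$phenotype))
  surfs <- lapply(phenotypes, function(ph) {
    estimate_intensity(cells, ph, grid, bandwidth_um, edge_correction)
  })
  comp <- build_composite(
    surfs, phenotypes,
    image_id = if ("image_id" %in% names(cells)) cells$image_id[1] else NA_character_,
    subject_id = if ("subject_id" %in% names(cells)) cells$subject_id[1] else NA_character_,
    class_label = if ("class" %in% names(cells)) cells$class[1] else NA_integer_)
  if (normalize_channels) {
    for (j in seq_along(phenotypes)) {
      mx <- max(comp$stack[, , j])
      if (mx > 0) comp$stack[, , j] <- comp$stack[, , j] / mx
    }
  }
  comp
}

#' Composites for every image of a cohort
#'
#' @param cells Cohort cell table from [simulate_cohort()] (or read from CSV).
#' @inheritParams compose_image
#' @return Tibble with `image_id`, `subject_id`, `class` and a `composite`
#'   list-column of `composite_image` objects.
#' @export
cohort_composites <- function(cells, grid = grid_for_window(attr(cells, "window")),
                              bandwidth_um = 1.5 * grid$cell_size_um,
                              phenotypes = attr(cells, "phenotypes"),
                              edge_correction = "diggle",
                              normalize_channels = FALSE) {
  cells |>
    tidyr::nest(data = -c("image_id", "subject_id", "class")) |>
    mutate(composite = pmap(
      list(.data$data, .data$image_id, .data$subject_id, .data$class),
      function(d, im, su, cl) {
        attr(d, "phenotypes") <- phenotypes
        comp <- compose_image(d, grid, bandwidth_um, phenotypes,
                              edge_correction, normalize_channels)
        comp$image_id <- im
        comp$subject_id <- su
        comp$class_label <- cl
        comp
      })) |>
    select(-"data")
}

#' @export
print.composite_image <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<composite_image %s: %d x %d x %d [%s]>\n",
              x$image_id, d[1], d[2], d[3],
              paste(x$channel_order, collapse = ", ")))
  invisible(x)
}

#' Plot a composite image's channels
#'
#' @param object A `composite_image`.
#' @param ... Unused.
#' @return A ggplot with one intensity raster facet per phenotype channel.
#' @export
autoplot.composite_image <- function(object, ...) {
  df <- purrr::map(seq_along(object$channel_order), function(j) {
    m <- object$stack[, , j]
    tibble(
      phenotype = object$channel_order[j],
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      intensity = as.vector(m)
    )
  }) |> list_rbind()
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    facet_wrap(~phenotype, nrow = 1) +
    scale_fill_viridis_c(name = "points/um²") +
    coord_fixed() +
    labs(x = "grid column (x)", y = "grid row (y)",
         title = object$image_id) +
    theme_minimal()
}
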