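# Synthetic two-class cohorts of multi-phenotype spatial point patterns.
#
# Each image is a rectangular observation window holding one point pattern per
# cell phenotype.  Class structure is planted in two ways: per-phenotype
# baseline intensity (points per um^2) and cross-phenotype spatial coupling,
# where a fraction of one phenotype's points is relocated to Gaussian offsets
# around parents of another phenotype (a Thomas-process-like displacement).

#' Default mIF phenotype panel
#'
#' The five cell phenotypes used throughout: epithelial/tumor cells (PanCK+),
#' cytotoxic T lymphocytes, helper T cells, regulatory T cells, and antigen
#' presenting cells.
#'
#' @return Character vector of phenotype labels.
#' @export
mif_phenotypes <- function() {
  c("Epithelial", "CTL", "HelperT", "Treg", "APC")
}

#' Default per-phenotype baseline intensities
#'
#' Dense epithelium with a sparser immune infiltrate, in points per square
#' micron.  Phenotypes outside the standard panel default to 1e-3.
#'
#' @param phenotypes Character vector of phenotype labels.
#' @return Named numeric vector of intensities (points/um^2).
#' @export
default_base_intensity <- function(phenotypes = mif_phenotypes()) {
  known <- c(Epithelial = 2e-3, CTL = 8e-4, HelperT = 8e-4,
             Treg = 4e-4, APC = 6e-4)
  out <- ifelse(phenotypes %in% names(known), known[phenotypes], 1e-3)
  setNames(as.numeric(out), phenotypes)
}

#' Specify a synthetic two-class cohort
#'
#' Collects every knob of the simulator into a validated specification.
#'
#' @param n_subjects_per_class Subjects in each of the two classes.
#' @param images_per_subject Either a single count or a `c(min, max)` range;
#'   with a range, each subject's image count is drawn uniformly.
#' @param window_width_um,window_height_um Observation window extent in
#'   microns (x and y respectively).
#' @param phenotypes Ordered, duplicate-free phenotype labels.
#' @param base_intensity Baseline intensities, points/um^2.  Either a named
#'   numeric vector applied to both classes, or a list
#'   `list(\`1\` = ..., \`2\` = ...)` of two such vectors.
#' @param coupling Cross-phenotype coupling: a data frame with columns
#'   `class` (1 or 2), `parent`, `offspring`, `frac`, where `frac` in \[0,1\]
#'   is the fraction of `offspring` points relocated next to uniformly chosen
#'   `parent` points.  `NULL` means no coupling anywhere.
#' @param offspring_dispersion_um Standard deviation (um) of the isotropic
#'   Gaussian offset of relocated offspring around their parent.
#' @param subject_sd Standard deviation, on the log scale, of an optional
#'   per-subject log-normal intensity multiplier (0 disables it).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return A `cohort_spec` object (validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_subjects_per_class = 20,
                        images_per_subject = c(1, 3),
                        window_width_um = 1000,
                        window_height_um = 1400,
                        phenotypes = mif_phenotypes(),
                        base_intensity = default_base_intensity(phenotypes),
                        coupling = NULL,
                        offspring_dispersion_um = 20,
                        subject_sd = 0,
                        seed = 1L) {
  spec <- structure(
    list(
      n_subjects_per_class = n_subjects_per_class,
      images_per_subject = images_per_subject,
      window_width_um = window_width_um,
      window_height_um = window_height_um,
      phenotypes = phenotypes,
      base_intensity = base_intensity,
      coupling = coupling,
      offspring_dispersion_um = offspring_dispersion_um,
      subject_sd = subject_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

# Normalize base_intensity to a 2-element list of named vectors.
intensity_by_class <- function(spec) {
  bi <- spec$base_intensity
  if (is.list(bi)) {
    list(`1` = bi[[1]][spec$phenotypes], `2` = bi[[2]][spec$phenotypes])
  } else {
    v <- bi[spec$phenotypes]
    list(`1` = v, `2` = v)
  }
}

validate_cohort_spec <- function(spec) {
  bad <- function(field, msg) {
    abort(sprintf("invalid cohort_spec: field `%s` %s", field, msg),
          class = "mifdict_spec_error")
  }
  if (!is.numeric(spec$n_subjects_per_class) ||
      spec$n_subjects_per_class < 1) {
    bad("n_subjects_per_class", "must be a positive count")
  }
  ips <- spec$images_per_subject
  if (!is.numeric(ips) || !length(ips) %in% c(1, 2) || any(ips < 1) ||
      (length(ips) == 2 && ips[2] < ips[1]) || any(ips > 20)) {
    bad("images_per_subject", "must be a count or range within 1..20")
  }
  if (spec$window_width_um <= 0) bad("window_width_um", "must be > 0")
  if (spec$window_height_um <= 0) bad("window_height_um", "must be > 0")
  ph <- spec$phenotypes
  if (length(ph) == 0 || anyDuplicated(ph) || !is.character(ph)) {
    bad("phenotypes", "must be a non-empty duplicate-free label list")
  }
  bi <- intensity_by_class(spec)
  for (cl in 1:2) {
    v <- bi[[cl]]
    if (anyNA(v) || any(v < 0)) {
      bad("base_intensity",
          sprintf("must give a non-negative value for every phenotype (class %d)", cl))
    }
  }
  cp <- spec$coupling
  if (!is.null(cp)) {
    need <- c("class", "parent", "offspring", "frac")
    if (!is.data.frame(cp) || !all(need %in% names(cp))) {
      bad("coupling", "must have columns class, parent, offspring, frac")
    }
    if (!all(cp$class %in% 1:2)) bad("coupling", "has class outside {1, 2}")
    if (!all(cp$parent %in% ph) || !all(cp$offspring %in% ph)) {
      bad("coupling", "names a phenotype outside the declared list")
    }
    if (any(cp$frac < 0 | cp$frac > 1)) bad("coupling", "frac must lie in [0, 1]")
  }
  if (spec$offspring_dispersion_um <= 0) {
    bad("offspring_dispersion_um", "must be > 0")
  }
  if (spec$subject_sd < 0) bad("subject_sd", "must be >= 0")
  invisible(spec)
}

#' Simulate a two-class cohort of phenotyped cell tables
#'
#' Baseline points of each phenotype are a homogeneous Poisson process with the
#' class intensity (optionally modulated per subject); for each coupled pair,
#' the configured fraction of offspring points is relocated to Gaussian offsets
#' around uniformly chosen parent points, resampling any offset that falls
#' outside the window so per-phenotype counts are untouched.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per cell: `image_id`, `subject_id`, `class`,
#'   `phenotype`, `x_um`, `y_um`.  Attributes `window` (named width/height),
#'   `phenotypes` and `spec` carry the cohort metadata.
#' @examples
#' cells <- simulate_cohort(cohort_spec(n_subjects_per_class = 2,
#'                                      images_per_subject = 1, seed = 7))
#' dplyr::count(cells, class, phenotype)
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  bi <- intensity_by_class(spec)
  withr::with_seed(spec$seed, {
    rows <- list()
    for (cl in 1:2) {
      for (s in seq_len(spec$n_subjects_per_class)) {
        subject_id <- sprintf("c%d_s%02d", cl, s)
        mult <- if (spec$subject_sd > 0) {
          exp(rnorm(1, 0, spec$subject_sd))
        } else 1
        ips <- spec$images_per_subject
        n_img <- if (length(ips) == 2) {
          sample(seq(ips[1], ips[2]), 1)
        } else as.integer(ips)
        for (im in seq_len(n_img)) {
          image_id <- sprintf("%s_i%d", subject_id, im)
          tab <- simulate_image(spec, bi[[cl]] * mult, cl)
          if (nrow(tab)) {
            tab$image_id <- image_id
            tab$subject_id <- subject_id
            tab$class <- cl
            rows[[length(rows) + 1]] <- tab
          }
        }
      }
    }
    cells <- bind_rows(rows) |>
      select("image_id", "subject_id", "class", "phenotype", "x_um", "y_um")
  })
  attr(cells, "window") <- c(width = spec$window_width_um,
                             height = spec$window_height_um)
  attr(cells, "phenotypes") <- spec$phenotypes
  attr(cells, "spec") <- spec
  cells
}

# One image: baseline Poisson points per phenotype, then coupling relocation.
simulate_image <- function(spec, lambda, cl) {
  W <- spec$window_width_um
  H <- spec$window_height_um
  pts <- lapply(spec$phenotypes, function(ph) {
    n <- rpois(1, lambda[[ph]] * W * H)
    tibble(phenotype = ph, x_um = runif(n, 0, W), y_um = runif(n, 0, H))
  })
  names(pts) <- spec$phenotypes
  cp <- spec$coupling
  if (!is.null(cp)) {
    cp <- cp[cp$class == cl, , drop = FALSE]
    for (r in seq_len(nrow(cp))) {
      par <- pts[[cp$parent[r]]]
      off <- pts[[cp$offspring[r]]]
      n_off <- nrow(off)
      n_move <- round(cp$frac[r] * n_off)
      if (n_move == 0 || nrow(par) == 0) next
      idx <- sample.int(n_off, n_move)
      parent_idx <- sample.int(nrow(par), n_move, replace = TRUE)
      sdisp <- spec$offspring_dispersion_um
      for (q in seq_len(n_move)) {
        px <- par$x_um[parent_idx[q]]
        py <- par$y_um[parent_idx[q]]
        repeat {
          nx <- px + rnorm(1, 0, sdisp)
          ny <- py + rnorm(1, 0, sdisp)
          if (nx >= 0 && nx <= W && ny >= 0 && ny <= H) break
        }
        off$x_um[idx[q]] <- nx
        off$y_um[idx[q]] <- ny
      }
      pts[[cp$offspring[r]]] <- off
    }
  }
  bind_rows(pts)
}

#' Empirical cross-type coupling statistic
#'
#' Mean number of offspring-phenotype points within `radius_um` of each
#' parent-phenotype point, normalized by the expected count under complete
#' spatial randomness (`lambda_b * pi * r^2`).  Approximately 1 when the two
#' patterns are independent, above 1 under attraction.  Border bias is removed
#' by minus-sampling: only parent points at least `radius_um` from every
#' window edge are counted.  Used as the simulator's own oracle that planted
#' coupling is present.
#'
#' @param cells Cell table for a single image (tibble with `phenotype`,
#'   `x_um`, `y_um`).
#' @param pair Character vector `c(parent, offspring)`.
#' @param radius_um Interaction radius in microns.
#' @param window Named `c(width, height)`; defaults to the table's `window`
#'   attribute.
#' @return A single number, or `NA_real_` when either phenotype is absent.
#' @export
empirical_cross_coupling <- function(cells, pair, radius_um,
                                     window = attr(cells, "window")) {
  stopifnot(length(pair) == 2, radius_um > 0)
  if (is.null(window)) {
    abort("`window` is required (no `window` attribute on `cells`)")
  }
  a <- cells[cells$phenotype == pair[1], ]
  b <- cells[cells$phenotype == pair[2], ]
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  area <- window[["width"]] * window[["height"]]
  lambda_b <- nrow(b) / area
  # minus-sampling: keep parents whose disc lies fully inside the window
  a <- a[a$x_um >= radius_um & a$x_um <= window[["width"]] - radius_um &
           a$y_um >= radius_um & a$y_um <= window[["height"]] - radius_um, ]
  if (nrow(a) == 0) return(NA_real_)
  d2 <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
  counts <- rowSums(d2 <= radius_um^2)
  if (identical(pair[1], pair[2])) counts <- counts - 1  # self-pairs
  mean(counts) / (lambda_b * pi * radius_um^2)
}
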