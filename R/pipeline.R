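# Run orchestration, configuration and serialization.
#
# The pipeline stages are: simulate -> train -> evaluate -> atoms -> report.
# Every artifact lands under one run directory; tabular artifacts are CSV,
# structured metadata is JSON, fitted objects are RDS.  One global seed
# deterministically drives every stage, and the run manifest records config,
# version and per-file hashes so identical runs are byte-identical up to
# timestamps.

#' Write / read a cohort cell table
#'
#' Cells go to `cells.csv` (columns image_id, subject_id, class, phenotype,
#' x_um, y_um) and the window/phenotype metadata to `cohort_manifest.json`.
#'
#' @param cells Cohort tibble from [simulate_cohort()].
#' @param dir Directory to write into (created if needed).
#' @return `write_cells()`: the directory, invisibly.  `read_cells()`: the
#'   cohort tibble with `window` and `phenotypes` attributes restored.
#' @export
write_cells <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(cells), file.path(dir, "cells.csv"))
  win <- attr(cells, "window")
  spec <- attr(cells, "spec")
  manifest <- list(
    window = as.list(win),
    phenotypes = attr(cells, "phenotypes"),
    seed = if (!is.null(spec)) spec$seed else NULL,
    spec = if (!is.null(spec)) spec_to_list(spec) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  if (!is.null(out$coupling)) out$coupling <- as.data.frame(out$coupling)
  if (is.list(out$base_intensity)) {
    out$base_intensity <- lapply(out$base_intensity, as.list)
  } else {
    out$base_intensity <- as.list(out$base_intensity)
  }
  out
}

#' @rdname write_cells
#' @export
read_cells <- function(dir) {
  cells <- readr::read_csv(
    file.path(dir, "cells.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      image_id = readr::col_character(),
      subject_id = readr::col_character(),
      class = readr::col_integer(),
      phenotype = readr::col_character(),
      x_um = readr::col_double(),
      y_um = readr::col_double()
    ))
  man <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                             simplifyVector = TRUE)
  attr(cells, "window") <- c(width = man$window$width,
                             height = man$window$height)
  attr(cells, "phenotypes") <- man$phenotypes
  cells
}

#' Assemble a full run configuration
#'
#' Defaults follow the pipeline's standard settings: 70 x 50 grid, 20 x 20
#' patches at stride 10, 50 atoms per class, L = 5, rho = 0.1, 5 folds,
#' alpha = 0.05.
#'
#' @param cohort A [cohort_spec()] (for simulated input) or a directory
#'   containing `cells.csv` from [write_cells()].
#' @param grid `NULL` (fit a 70 x 50 grid to the window) or a [grid_spec()].
#' @param pspec A [patch_spec()].
#' @param dfdl A [dfdl_config()].
#' @param wpcor A [wpcor_config()].
#' @param cv_mode,cv_k,cv_threshold Cross-validation settings.
#' @param alpha Atom-selection significance level.
#' @param seed Global seed; propagates to every stage.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_spec(), grid = NULL,
                       pspec = patch_spec(), dfdl = dfdl_config(),
                       wpcor = wpcor_config(), cv_mode = "subject",
                       cv_k = 5, cv_threshold = 0.5, alpha = 0.05,
                       seed = 1L) {
  structure(
    list(cohort = cohort, grid = grid, pspec = pspec, dfdl = dfdl,
         wpcor = wpcor, cv_mode = cv_mode, cv_k = cv_k,
         cv_threshold = cv_threshold, alpha = alpha,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Any omitted field falls back to the [run_config()] default; nested
#' sections `cohort`, `grid`, `patches`, `dfdl`, `wpcor`, `cv` mirror the
#' constructor arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort_dir)) {
    y$cohort_dir
  } else {
    cargs <- y$cohort %||% list()
    if (!is.null(cargs$coupling)) {
      cargs$coupling <- bind_rows(lapply(cargs$coupling, as_tibble))
    }
    if (!is.null(cargs$base_intensity)) {
      cargs$base_intensity <- unlist(cargs$base_intensity)
    }
    do.call(cohort_spec, cargs)
  }
  grid <- if (is.null(y$grid)) NULL else do.call(grid_spec, y$grid)
  cfg <- run_config(
    cohort = cohort,
    grid = grid,
    pspec = do.call(patch_spec, y$patches %||% list()),
    dfdl = do.call(dfdl_config, y$dfdl %||% list()),
    wpcor = do.call(wpcor_config, y$wpcor %||% list()),
    cv_mode = y$cv$mode %||% "subject",
    cv_k = y$cv$k %||% 5,
    cv_threshold = y$cv$threshold %||% 0.5,
    alpha = y$alpha %||% 0.05,
    seed = y$seed %||% 1L
  )
  cfg
}

pipeline_stages <- function() {
  c("simulate", "train", "evaluate", "atoms", "report")
}

require_artifact <- function(path, stage_needed) {
  if (!file.exists(path)) {
    abort(sprintf("missing artifact '%s'; run stage '%s' first",
                  basename(path), stage_needed),
          class = "mifdict_stage_error")
  }
  path
}

#' Run the pipeline end to end (or a subset of stages)
#'
#' Stages execute in canonical order: `simulate` (cohort CSV + manifest),
#' `train` (dictionary pair on all filtered patches), `evaluate` (grouped
#' cross-validation metrics), `atoms` (interpretability tables), `report`
#' (run manifest with config echo and file hashes).  Each stage reads its
#' inputs from `outdir`, so stages are resumable across calls; a missing
#' upstream artifact raises an error naming the stage to run first.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @param outdir Output directory for all artifacts.
#' @param stages Subset of `c("simulate", "train", "evaluate", "atoms",
#'   "report")`.
#' @param quiet Suppress per-stage messages?
#' @return The run manifest (list), invisibly; written as
#'   `run_manifest.json` by the `report` stage.
#' @export
run_pipeline <- function(config, outdir,
                         stages = pipeline_stages(), quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- intersect(pipeline_stages(), stages)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  load_cohort <- function() {
    if (is.character(config$cohort)) {
      read_cells(config$cohort)
    } else {
      read_cells(outdir)
    }
  }
  get_grid <- function(cells) {
    config$grid %||% grid_for_window(attr(cells, "window"))
  }
  prepared_patches <- function(cells) {
    grid <- get_grid(cells)
    comps <- cohort_composites(cells, grid)
    comps$composite |>
      purrr::map(~ filter_low_intensity(extract_patches(.x, config$pspec),
                                        config$pspec)) |>
      list_rbind()
  }

  if ("simulate" %in% stages) {
    say("stage simulate: generating cohort")
    if (is.character(config$cohort)) {
      cells <- read_cells(config$cohort)
      write_cells(cells, outdir)
    } else {
      spec <- config$cohort
      spec$seed <- derive_seed(config$seed, 1L)
      write_cells(simulate_cohort(spec), outdir)
    }
  }

  if ("train" %in% stages) {
    require_artifact(file.path(outdir, "cells.csv"), "simulate")
    cells <- load_cohort()
    say("stage train: surfaces, patches, dictionary pair")
    patches <- prepared_patches(cells)
    say("  %d patches survive filtering", nrow(patches))
    split <- assemble_training(patches, seed = derive_seed(config$seed, 2L))
    cfg <- config$dfdl
    cfg$seed <- derive_seed(config$seed, 3L)
    fit <- train_pair(split$Y, split$Ybar, cfg)
    saveRDS(fit, file.path(outdir, "fit.rds"))
    readr::write_csv(glance(fit), file.path(outdir, "fit_summary.csv"))
  }

  if ("evaluate" %in% stages) {
    require_artifact(file.path(outdir, "cells.csv"), "simulate")
    cells <- load_cohort()
    say("stage evaluate: %d-fold %s-level cross-validation",
        config$cv_k, config$cv_mode)
    cv <- cross_validate(cells, get_grid(cells), pspec = config$pspec,
                         config = config$dfdl, mode = config$cv_mode,
                         k = config$cv_k, threshold = config$cv_threshold,
                         seed = derive_seed(config$seed, 4L))
    readr::write_csv(tidy(cv), file.path(outdir, "cv_folds.csv"))
    readr::write_csv(cv$scores, file.path(outdir, "predictions.csv"))
    jsonlite::write_json(as.list(glance(cv)),
                         file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("atoms" %in% stages) {
    require_artifact(file.path(outdir, "cells.csv"), "simulate")
    require_artifact(file.path(outdir, "fit.rds"), "train")
    cells <- load_cohort()
    fit <- readRDS(file.path(outdir, "fit.rds"))
    say("stage atoms: activity, significance, pair correlations")
    patches <- prepared_patches(cells)
    wcfg <- config$wpcor
    wcfg$seed <- derive_seed(config$seed, 5L)
    ana <- analyze_atoms(patch_matrix(patches), fit, wcfg,
                         alpha = config$alpha,
                         channels = attr(cells, "phenotypes"))
    readr::write_csv(ana$significance, file.path(outdir, "atom_significance.csv"))
    readr::write_csv(ana$proportions, file.path(outdir, "pair_proportions.csv"))
    readr::write_csv(ana$comparison, file.path(outdir, "pair_comparison.csv"))
  }

  manifest <- NULL
  if ("report" %in% stages) {
    say("stage report: manifest")
    files <- setdiff(list.files(outdir), "run_manifest.json")
    hashes <- tools::md5sum(file.path(outdir, files))
    names(hashes) <- files
    manifest <- list(
      package_version = as.character(packageVersion("mifdict")),
      seed = config$seed,
      config = config_to_list(config),
      files = as.list(hashes),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(manifest)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$cohort <- if (is.character(out$cohort)) out$cohort else spec_to_list(out$cohort)
  for (nm in c("grid", "pspec", "dfdl", "wpcor")) {
    if (!is.null(out[[nm]])) out[[nm]] <- unclass(out[[nm]])
  }
  out
}
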