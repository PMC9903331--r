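# Residual-based classification, theta voting and grouped cross-validation.
#
# A test patch is coded once against the combined dictionary [D1 | D2]; the
# code is split into class halves and the patch takes the class whose half
# reconstructs it with the smaller squared l2 residual (ties to class 1).
# Entity scores theta are the fraction of an image's (or a subject's pooled)
# patches labeled class 1, and feed rank-based AUC plus thresholded
# sensitivity/specificity.

#' Classify patches by class-wise reconstruction residuals
#'
#' @param Y A d x N matrix of vectorized patches, or a `patch_matrix`
#'   (metadata is then carried into the result).
#' @param fit A [train_pair()] fit.
#' @param L Sparsity used for test coding (defaults to the training `L`).
#' @return Tibble with one row per patch: `eps1`, `eps2` (squared residual
#'   norms against each class half), `label` (1 iff `eps1 <= eps2`), plus any
#'   metadata columns.
#' @export
classify_patches <- function(Y, fit, L = fit$config$L) {
  meta <- NULL
  if (inherits(Y, "patch_matrix")) {
    meta <- Y$meta
    Y <- Y$Y
  }
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  if (nrow(Y) != nrow(fit$D_combined)) {
    abort("patch dimension does not match the dictionary")
  }
  k <- fit$k
  S <- sparse_encode(fit$D_combined, Y, L, fit$config$coder)
  R1 <- Y - fit$D1$atoms %*% S[seq_len(k), , drop = FALSE]
  R2 <- Y - fit$D2$atoms %*% S[k + seq_len(k), , drop = FALSE]
  eps1 <- colSums(R1^2)
  eps2 <- colSums(R2^2)
  out <- tibble(eps1 = eps1, eps2 = eps2,
                label = ifelse(eps1 <= eps2, 1L, 2L))
  if (!is.null(meta)) out <- bind_cols(meta, out)
  out
}

#' Aggregate patch labels into entity-level theta scores
#'
#' theta is the fraction of an entity's patches predicted class 1; at the
#' subject level all patches from all of the subject's images are pooled.
#'
#' @param predictions Tibble from [classify_patches()] including metadata.
#' @param by `"image"` or `"subject"`.
#' @return Tibble with `entity`, `class` (true class when available),
#'   `theta`, `n_patches`.
#' @export
aggregate_theta <- function(predictions, by = c("image", "subject")) {
  by <- match.arg(by)
  key <- if (by == "image") "image_id" else "subject_id"
  if (!key %in% names(predictions)) {
    abort(sprintf("predictions lack the `%s` metadata column", key))
  }
  predictions |>
    group_by(entity = .data[[key]]) |>
    summarise(
      class = if ("class" %in% names(predictions)) .data$class[1] else NA_integer_,
      theta = mean(.data$label == 1L),
      n_patches = dplyr::n(),
      .groups = "drop"
    )
}

#' Rank-based AUC of theta scores
#'
#' Mann-Whitney AUC treating theta as the score for class 1 (the reference
#' class); tied score pairs are credited 0.5.
#'
#' @param theta Numeric entity scores.
#' @param class True classes, coded 1 (positive/reference) and 2.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(theta, class) {
  pos <- theta[class == 1]
  neg <- theta[class == 2]
  if (!length(pos) || !length(neg)) {
    abort("both classes must be present to compute AUC")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Thresholded sensitivity and specificity
#'
#' An entity is called class 1 iff `theta >= threshold`.  Sensitivity is
#' recall on class 1; specificity is recall on class 2.  Also reports the
#' Youden-optimal threshold (maximizing sensitivity + specificity - 1 over
#' observed scores) and its operating point.
#'
#' @inheritParams auc_score
#' @param threshold Decision threshold on theta (default 0.5).
#' @return One-row tibble: `sensitivity`, `specificity`,
#'   `youden_threshold`, `sensitivity_youden`, `specificity_youden`.
#' @export
sens_spec <- function(theta, class, threshold = 0.5) {
  if (!any(class == 1) || !any(class == 2)) {
    abort("both classes must be present")
  }
  at <- function(thr) {
    pred1 <- theta >= thr
    c(sens = mean(pred1[class == 1]), spec = mean(!pred1[class == 2]))
  }
  base <- at(threshold)
  cand <- sort(unique(c(theta, 0, 1, 1 + 1e-9)))
  youden <- vapply(cand, function(t) sum(at(t)) - 1, numeric(1))
  best <- cand[which.max(youden)]
  besty <- at(best)
  tibble(sensitivity = base[["sens"]], specificity = base[["spec"]],
         youden_threshold = best,
         sensitivity_youden = besty[["sens"]],
         specificity_youden = besty[["spec"]])
}

# Stratified fold assignment over entities; returns integer fold per entity.
assign_folds <- function(entities, classes, k, seed) {
  fold <- integer(length(entities))
  withr::with_seed(derive_seed(seed, 211L), {
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Grouped cross-validation of the full pipeline
#'
#' Composites and filtered patches are computed once per image (both are
#' strictly per-image operations, so no information crosses folds); folds are
#' stratified over entities — images in image mode, subjects in subject mode,
#' where all of a subject's images travel together.  Each fold trains the
#' dictionary pair on the training entities' patches only and scores the held
#' out entities.
#'
#' @param cells Cohort cell table from [simulate_cohort()] or [read_cells()].
#' @param grid A [grid_spec()]; defaults to a 70 x 50 grid fit to the window.
#' @param bandwidth_um Kernel bandwidth for the intensity surfaces.
#' @param pspec A [patch_spec()].
#' @param config A [dfdl_config()].
#' @param mode `"subject"` (grouped, default) or `"image"`.
#' @param k Number of folds (default 5, i.e. 80-20 splits).
#' @param threshold Theta threshold for sensitivity/specificity.
#' @param proportional,n_total Passed to [assemble_training()].
#' @param seed Integer seed for fold assignment and per-fold training.
#' @param edge_correction,normalize_channels Passed to the surface stage.
#' @return A `dfdl_cv` object: list with `folds` (per-fold metrics tibble),
#'   `scores` (per-entity theta tibble), and the settings.  `tidy()` returns
#'   the per-fold metrics, `glance()` the across-fold summary with min-max
#'   ranges.
#' @export
cross_validate <- function(cells,
                           grid = grid_for_window(attr(cells, "window")),
                           bandwidth_um = 1.5 * grid$cell_size_um,
                           pspec = patch_spec(),
                           config = dfdl_config(),
                           mode = c("subject", "image"),
                           k = 5,
                           threshold = 0.5,
                           proportional = FALSE,
                           n_total = NULL,
                           seed = 1L,
                           edge_correction = "diggle",
                           normalize_channels = FALSE) {
  mode <- match.arg(mode)
  if (k < 2) abort("k must be >= 2")

  comps <- cohort_composites(cells, grid, bandwidth_um,
                             edge_correction = edge_correction,
                             normalize_channels = normalize_channels)
  patches <- comps$composite |>
    purrr::map(~ filter_low_intensity(extract_patches(.x, pspec), pspec)) |>
    list_rbind()

  key <- if (mode == "subject") "subject_id" else "image_id"
  ent <- comps |> distinct(entity = .data[[key]], .data$class)
  if (anyDuplicated(ent$entity)) {
    abort("an entity appears with two different class labels")
  }
  ent$fold <- assign_folds(ent$entity, ent$class, k, seed)
  for (f in seq_len(k)) {
    tr_cls <- ent$class[ent$fold != f]
    te_cls <- ent$class[ent$fold == f]
    if (n_distinct(tr_cls) < 2 || n_distinct(te_cls) < 2) {
      abort(sprintf("fold %d has a single class; use a smaller k", f))
    }
  }

  patches$entity <- patches[[key]]
  folds <- vector("list", k)
  scores <- vector("list", k)
  for (f in seq_len(k)) {
    train_ent <- ent$entity[ent$fold != f]
    test_ent <- ent$entity[ent$fold == f]
    if (mode == "subject") {
      stopifnot(length(intersect(train_ent, test_ent)) == 0)
    }
    tr <- patches[patches$entity %in% train_ent, ]
    te <- patches[patches$entity %in% test_ent, ]
    if (nrow(te) == 0) abort(sprintf("fold %d has no test patches", f))

    split <- assemble_training(tr, proportional = proportional,
                               n_total = n_total,
                               seed = derive_seed(seed, 300L + f))
    cfg <- config
    cfg$seed <- derive_seed(seed, 400L + f)
    fit <- train_pair(split$Y, split$Ybar, cfg)

    pred <- classify_patches(patch_matrix(te), fit)
    th <- aggregate_theta(pred, by = if (mode == "subject") "subject" else "image")
    unscorable <- setdiff(test_ent, th$entity)
    if (length(unscorable)) {
      warn(sprintf("fold %d: %d entit%s had no surviving patches and were excluded",
                   f, length(unscorable),
                   if (length(unscorable) == 1) "y" else "ies"))
    }
    ss <- sens_spec(th$theta, th$class, threshold)
    folds[[f]] <- bind_cols(tibble(fold = f,
                                   auc = auc_score(th$theta, th$class)),
                            ss,
                            tibble(n_train_patches = nrow(tr),
                                   n_test_entities = nrow(th)))
    scores[[f]] <- th |> mutate(fold = f)
  }

  structure(
    list(folds = list_rbind(folds), scores = list_rbind(scores),
         mode = mode, k = as.integer(k), threshold = threshold,
         seed = as.integer(seed), config = config),
    class = "dfdl_cv"
  )
}

#' @export
print.dfdl_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<dfdl_cv: %d-fold, %s mode; AUC %.4f (%.4f-%.4f)>\n",
              x$k, x$mode, g$auc_mean, g$auc_min, g$auc_max))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `dfdl_cv` object.
#' @param ... Unused.
#' @export
tidy.dfdl_cv <- function(x, ...) x$folds

#' @rdname cross_validate
#' @export
glance.dfdl_cv <- function(x, ...) {
  f <- x$folds
  tibble(
    mode = x$mode, k = x$k, threshold = x$threshold,
    auc_mean = mean(f$auc), auc_min = min(f$auc), auc_max = max(f$auc),
    sensitivity_mean = mean(f$sensitivity),
    sensitivity_min = min(f$sensitivity),
    sensitivity_max = max(f$sensitivity),
    specificity_mean = mean(f$specificity),
    specificity_min = min(f$specificity),
    specificity_max = max(f$specificity)
  )
}

#' Plot cross-validated entity scores
#'
#' @param object A `dfdl_cv` object.
#' @param ... Unused.
#' @return A ggplot of theta by true class, one point per entity.
#' @export
autoplot.dfdl_cv <- function(object, ...) {
  ggplot(object$scores,
         aes(x = factor(.data$class), y = .data$theta,
             colour = factor(.data$fold))) +
    geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    labs(x = "true class", y = expression(theta),
         colour = "fold",
         title = sprintf("%s-level scores, %d-fold CV", object$mode, object$k)) +
    theme_minimal()
}
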