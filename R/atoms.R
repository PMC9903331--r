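# Atom interpretability stage.
#
# Every patch is sparse-coded against the combined dictionary; per-atom code
# values are normalized (sign-preserving) and binarized to activity A_i = 1
# iff A_o > 0 — negative codes describe poorly represented bases and are
# excluded.  Atoms whose per-image activation proportion is higher in their
# own class than in the other (two-sample t-test, p < alpha) are deemed
# significant; inside each significant atom, phenotype channels are examined
# for spatially weighted partial correlation, and per-pair proportions of
# correlated atoms are compared between classes with a pooled two-proportion
# z-test.

#' Binarized sparse-code activity of every patch
#'
#' Codes each patch against the combined dictionary at sparsity `L`,
#' normalizes every atom's code values across all patches to unit maximum
#' absolute value (sign-preserving, so the binarization is unaffected), and
#' recodes activity as `A_i = 1` iff `A_o > 0` (zero or negative codes give
#' 0).
#'
#' @param pm A `patch_matrix` covering both classes (with `class`,
#'   `image_id`, `subject_id` metadata).
#' @param fit A [train_pair()] fit.
#' @param L Sparsity for the activity coding (defaults to training `L`).
#' @return An `atom_activity` object: list with `A_o`, `A_i` (N x 2k
#'   matrices), `meta`, `k`, `atom_class` (length-2k half index).
#' @export
compute_activity <- function(pm, fit, L = fit$config$L) {
  stopifnot(inherits(pm, "patch_matrix"))
  for (cl in 1:2) {
    if (!any(pm$meta$class == cl)) {
      abort(sprintf("class %d has zero patches", cl))
    }
  }
  S <- sparse_encode(fit$D_combined, pm$Y, L, fit$config$coder)
  A_o <- t(S)  # patches x atoms
  mx <- apply(abs(A_o), 2, max)
  mx[mx == 0] <- 1
  A_o <- sweep(A_o, 2, mx, "/")
  structure(
    list(A_o = A_o, A_i = (A_o > 0) * 1L, meta = pm$meta, k = fit$k,
         atom_class = rep(1:2, each = fit$k)),
    class = "atom_activity"
  )
}

#' Own-class half of the activity matrix
#'
#' The interpretability view: for each patch only the half of the code
#' matching the patch's true class (S1 for class 1, S2 for class 2).
#'
#' @param activity An [compute_activity()] result.
#' @return Tibble with `image_id`, `subject_id`, `class`, `atom` (index
#'   within the class dictionary), `A_o`, `A_i`.
#' @export
own_class_activity <- function(activity) {
  k <- activity$k
  purrr::map(1:2, function(cl) {
    rows <- which(activity$meta$class == cl)
    cols <- which(activity$atom_class == cl)
    tibble(
      image_id = rep(activity$meta$image_id[rows], times = k),
      subject_id = rep(activity$meta$subject_id[rows], times = k),
      class = cl,
      atom = rep(seq_len(k), each = length(rows)),
      A_o = as.vector(activity$A_o[rows, cols]),
      A_i = as.vector(activity$A_i[rows, cols])
    )
  }) |> list_rbind()
}

#' Select class-discriminant atoms
#'
#' For each atom, per-image activation proportions (fraction of the image's
#' patches with `A_i = 1`) are compared between images of the atom's own
#' class and images of the other class (all patches are coded against the
#' same combined dictionary).  A Welch two-sample t-test gives the t value
#' and p; an atom is selected iff `p < alpha` and its own-class mean
#' activation exceeds the other class's.
#'
#' @param activity An [compute_activity()] result.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `atom` (combined index), `class`, `t_value`,
#'   `p_value`, `own_mean`, `other_mean`, `selected`.
#' @export
select_significant_atoms <- function(activity, alpha = 0.05) {
  meta <- activity$meta
  for (cl in 1:2) {
    if (n_distinct(meta$image_id[meta$class == cl]) < 2) {
      abort(sprintf("need at least 2 images in class %d", cl))
    }
  }
  img <- meta$image_id
  img_class <- meta |>
    distinct(.data$image_id, .data$class)
  # per-image activation proportion for every atom (images x atoms)
  prop <- rowsum(activity$A_i, img) / as.vector(table(img)[sort(unique(img))])
  prop <- prop[img_class$image_id[order(img_class$image_id)], , drop = FALSE]
  cls <- img_class$class[order(img_class$image_id)]

  n_atoms <- ncol(activity$A_i)
  out <- purrr::map(seq_len(n_atoms), function(j) {
    own_cl <- activity$atom_class[j]
    own <- prop[cls == own_cl, j]
    oth <- prop[cls != own_cl, j]
    tt <- tryCatch(t.test(own, oth), error = function(e) NULL)
    tv <- if (is.null(tt)) NA_real_ else unname(tt$statistic)
    pv <- if (is.null(tt)) NA_real_ else tt$p.value
    tibble(atom = j, class = own_cl, t_value = tv, p_value = pv,
           own_mean = mean(own), other_mean = mean(oth))
  }) |> list_rbind()
  out$selected <- !is.na(out$p_value) & out$p_value < alpha &
    out$own_mean > out$other_mean
  out
}

#' Reshape a dictionary atom back into a patch block
#'
#' Exact inverse of [vectorize_patch()] applied to one column of the
#' combined dictionary.
#'
#' @param fit A [train_pair()] fit (or any matrix of atom columns).
#' @param atom Combined-dictionary column index.
#' @param dim Patch dimensions `c(n, n, c)`; defaults to the fit's
#'   `patch_dim`.
#' @return An n x n x c array.
#' @export
atom_to_patch <- function(fit, atom, dim = NULL) {
  col <- if (inherits(fit, "dfdl_fit")) {
    dim <- dim %||% fit$patch_dim
    fit$D_combined[, atom]
  } else fit[, atom]
  if (is.null(dim)) abort("patch dimensions are unknown; supply `dim`")
  unvectorize_patch(col, dim)
}

#' Per-pair proportions of correlated atoms
#'
#' For each class, runs the weighted partial-correlation analysis on every
#' selected atom of that class and reports, per unordered phenotype pair, the
#' proportion of atoms in which the pair is significantly correlated
#' (`p < alpha`).  Atoms where a pair is undefined (constant channel) do not
#' count toward that pair's denominator.
#'
#' @param fit A [train_pair()] fit with known `patch_dim`.
#' @param significance Output of [select_significant_atoms()].
#' @param config A [wpcor_config()].
#' @param channels Channel labels (defaults to the phenotype panel order
#'   stored in `fit$patch_dim` dimnames or channel indices).
#' @return A `pair_proportion_table` tibble: `pair_a`, `pair_b`, `class`,
#'   `n_atoms`, `n_correlated`, `proportion`.
#' @export
pair_proportions <- function(fit, significance, config = wpcor_config(),
                             channels = NULL) {
  if (is.null(fit$patch_dim)) abort("fit has no patch_dim")
  nch <- fit$patch_dim[3]
  channels <- channels %||% as.character(seq_len(nch))
  sel <- significance[significance$selected, ]
  if (nrow(sel) == 0) abort("no selected atoms in either class")

  rows <- purrr::map(seq_len(nrow(sel)), function(i) {
    a <- sel$atom[i]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 1000L + a)
    block <- atom_to_patch(fit, a)
    dimnames(block) <- list(NULL, NULL, channels)
    wp <- weighted_partial_correlation(block, cfg)
    tidy(wp) |> mutate(atom = a, class = sel$class[i])
  }) |> list_rbind()

  out <- rows |>
    filter(!is.na(.data$p_value)) |>
    group_by(pair_a = .data$channel_a, pair_b = .data$channel_b,
             class = .data$class) |>
    summarise(n_atoms = dplyr::n(),
              n_correlated = sum(.data$p_value < config$alpha),
              proportion = .data$n_correlated / .data$n_atoms,
              .groups = "drop")
  class(out) <- c("pair_proportion_table", class(out))
  out
}

#' Pooled two-proportion z-test between the classes' pair proportions
#'
#' For each phenotype pair, compares the proportion of correlated atoms in
#' class 1 against class 2 with the pooled-variance two-proportion z
#' statistic and a two-sided normal p-value.  Pairs with zero selected atoms
#' in a class are skipped with a warning.
#'
#' @param table A [pair_proportions()] result.
#' @return Tibble with `pair_a`, `pair_b`, per-class counts and proportions,
#'   `z`, `p_value`.
#' @export
compare_pair_proportions <- function(table) {
  wide <- table |>
    tidyr::pivot_wider(id_cols = c("pair_a", "pair_b"),
                       names_from = "class",
                       values_from = c("n_atoms", "n_correlated", "proportion"))
  need <- c("n_atoms_1", "n_atoms_2")
  missing_cols <- setdiff(need, names(wide))
  if (length(missing_cols)) {
    abort("both classes' counts are required for the z-test")
  }
  drop <- is.na(wide$n_atoms_1) | is.na(wide$n_atoms_2) |
    wide$n_atoms_1 == 0 | wide$n_atoms_2 == 0
  if (any(drop)) {
    warn(sprintf("%d pair(s) skipped: zero selected atoms in one class",
                 sum(drop)))
    wide <- wide[!drop, ]
  }
  z <- two_proportion_z(wide$n_correlated_1, wide$n_atoms_1,
                        wide$n_correlated_2, wide$n_atoms_2)
  wide |>
    mutate(z = z, p_value = 2 * pnorm(-abs(z))) |>
    select("pair_a", "pair_b",
           n_1 = "n_atoms_1", correlated_1 = "n_correlated_1",
           proportion_1 = "proportion_1",
           n_2 = "n_atoms_2", correlated_2 = "n_correlated_2",
           proportion_2 = "proportion_2",
           "z", "p_value")
}

# Pooled two-proportion z statistic; 0 when the pooled proportion is
# degenerate (both 0 or both 1).
two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  ifelse(se == 0, 0, (p1 - p2) / se)
}

#' Full interpretability analysis of a fitted dictionary pair
#'
#' Chains [compute_activity()], [select_significant_atoms()],
#' [pair_proportions()] and [compare_pair_proportions()].
#'
#' @param pm A `patch_matrix` of all (filtered) patches with metadata.
#' @param fit A [train_pair()] fit.
#' @param config A [wpcor_config()].
#' @param alpha Significance level for atom selection.
#' @param channels Phenotype labels for the channels.
#' @return An `atom_analysis` object: list with `significance`,
#'   `proportions`, `comparison`, `n_selected` (per class).
#' @export
analyze_atoms <- function(pm, fit, config = wpcor_config(), alpha = 0.05,
                          channels = NULL) {
  act <- compute_activity(pm, fit)
  sig <- select_significant_atoms(act, alpha)
  prop <- pair_proportions(fit, sig, config, channels)
  comp <- compare_pair_proportions(prop)
  structure(
    list(significance = sig, proportions = prop, comparison = comp,
         n_selected = c(`1` = sum(sig$selected & sig$class == 1),
                        `2` = sum(sig$selected & sig$class == 2)),
         alpha = alpha),
    class = "atom_analysis"
  )
}

#' @export
print.atom_analysis <- function(x, ...) {
  cat(sprintf("<atom_analysis: %d / %d significant atoms (class 1 / 2) at alpha = %g>\n",
              x$n_selected[1], x$n_selected[2], x$alpha))
  print(x$comparison)
  invisible(x)
}

#' Plot pair-proportion profiles per class
#'
#' @param object An `atom_analysis` or `pair_proportion_table`.
#' @param ... Unused.
#' @return A grouped bar chart of correlated-atom proportions per phenotype
#'   pair and class.
#' @export
autoplot.atom_analysis <- function(object, ...) {
  autoplot.pair_proportion_table(object$proportions, ...)
}

#' @rdname autoplot.atom_analysis
#' @export
autoplot.pair_proportion_table <- function(object, ...) {
  df <- object |>
    mutate(pair = paste(.data$pair_a, .data$pair_b, sep = "-"))
  ggplot(df, aes(x = .data$pair, y = .data$proportion,
                 fill = factor(.data$class))) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 0.5, linetype = 2) +
    labs(x = "phenotype pair", y = "proportion of correlated atoms",
         fill = "class") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
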