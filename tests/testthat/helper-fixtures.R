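# Shared fixture builders; everything is generated in code under fixed seeds.

# Random dictionary with exactly unit-norm columns.
random_dictionary <- function(d, k, seed = 1) {
  withr::with_seed(seed, {
    D <- matrix(rnorm(d * k), d, k)
    sweep(D, 2, sqrt(colSums(D^2)), "/")
  })
}

# Two-class patch matrices living on disjoint coordinate blocks (emulating
# classes whose activity occupies different phenotype channels).
disjoint_channel_classes <- function(d = 200, active = 80, n = 100, seed = 1) {
  withr::with_seed(seed, {
    Y1 <- rbind(matrix(abs(rnorm(active * n)), active),
                matrix(0, d - active, n))
    Y2 <- rbind(matrix(0, d - active, n),
                matrix(abs(rnorm(active * n)), active))
  })
  list(Y1 = Y1, Y2 = Y2)
}

# A small composite image with smooth random channels.
random_composite <- function(n_rows = 20, n_cols = 14, c = 3, seed = 1,
                             image_id = "img1", subject_id = "s1",
                             class_label = 1L) {
  withr::with_seed(seed, {
    stack <- array(abs(rnorm(n_rows * n_cols * c)), c(n_rows, n_cols, c))
  })
  structure(
    list(stack = stack, channel_order = paste0("ch", seq_len(c)),
         grid = grid_spec(n_rows, n_cols, 20),
         image_id = image_id, subject_id = subject_id,
         class_label = class_label),
    class = "composite_image"
  )
}

# Small, quickly separable synthetic cohort: class differences both in one
# phenotype's intensity and in coupling, small window.
small_cohort <- function(n_subjects = 6, seed = 1, coupling_frac = 0.9) {
  coupling <- tibble::tibble(class = 1L, parent = "CTL",
                             offspring = "HelperT", frac = coupling_frac)
  base <- list(
    `1` = c(Epithelial = 2e-3, CTL = 1.2e-3, HelperT = 1.2e-3,
            Treg = 4e-4, APC = 6e-4),
    `2` = c(Epithelial = 2e-3, CTL = 6e-4, HelperT = 6e-4,
            Treg = 4e-4, APC = 6e-4)
  )
  simulate_cohort(cohort_spec(
    n_subjects_per_class = n_subjects, images_per_subject = 1,
    window_width_um = 280, window_height_um = 400,
    base_intensity = base, coupling = coupling, seed = seed
  ))
}

small_grid <- function() grid_spec(n_rows = 20, n_cols = 14, cell_size_um = 20)

# Independent weighted Pearson correlation (oracle for the c = 2 identity).
weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cxy / sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# The package's lattice weights, recomputed independently (dense kernel).
dense_lattice_weights <- function(n_rows, n_cols, sigma) {
  coords <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  # column-major pixel order to match matrix(block) vectorization
  coords <- coords[order(coords$col, coords$row), ]
  d2 <- as.matrix(dist(coords))^2
  W <- exp(-d2 / sigma^2)
  w <- rowSums(W)
  w / sum(w)
}
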