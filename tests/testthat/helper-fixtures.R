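# Shared fixtures: everything is generated in code at test time.

tiny_grid <- c(10L, 12L, 10L)

# desk-scale cohort: 2 scans/session on a 10x12x10 grid
tiny_spec <- function(n_subjects = 4, seed = 1, ...) {
  cohort_spec(
    n_subjects = n_subjects, n_scans_per_session = 2,
    grid_shape = tiny_grid, voxel_size_mm = c(3, 3, 3),
    blobs = default_pain_blobs(tiny_grid), seed = seed, ...
  )
}

# build an asl_features object directly from matrices (bypasses volumes)
make_features <- function(X, labels, subject_ids, grid_shape = NULL) {
  X <- as.matrix(X)
  if (is.null(grid_shape)) grid_shape <- c(ncol(X), 1L, 1L)
  stopifnot(prod(grid_shape) >= ncol(X))
  structure(
    list(X = X, labels = as.numeric(labels), subject_ids = subject_ids,
         voxel_index = seq_len(ncol(X)), grid_shape = as.integer(grid_shape),
         voxel_size_mm = c(3, 3, 3),
         meta = tibble::tibble(subject_id = subject_ids)),
    class = "asl_features"
  )
}

# one +1 and one -1 sample per subject; signal w shared by all subjects
separable_features <- function(n_subjects, p = 6, signal = 4, noise_sd = 0.1,
                               seed = 1) {
  set.seed(seed)
  w <- stats::rnorm(p)
  w <- w / sqrt(sum(w^2))
  X <- matrix(NA_real_, 2 * n_subjects, p)
  labels <- rep(c(1, -1), n_subjects)
  subject_ids <- rep(sprintf("s%02d", seq_len(n_subjects)), each = 2)
  for (i in seq_len(2 * n_subjects)) {
    X[i, ] <- labels[i] * signal * w + stats::rnorm(p, 0, noise_sd)
  }
  make_features(X, labels, subject_ids)
}

# Gauss-Hermite quadrature nodes/weights transformed for N(0,1) expectations
gauss_hermite_std <- function(n = 150) {
  gh <- statmod::gauss.quad(n, "hermite")
  list(nodes = sqrt(2) * gh$nodes, weights = gh$weights / sqrt(pi))
}
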