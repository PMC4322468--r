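# Discrete Gaussian kernel weights for one axis, normalized to sum 1.
# sigma in voxels = (fwhm_mm / voxel_mm) / (2 sqrt(2 ln 2)); support 4 sigma.
gaussian_kernel_weights <- function(fwhm_mm, voxel_mm) {
  if (fwhm_mm == 0) return(1)
  sigma <- (fwhm_mm / voxel_mm) / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# n x n convolution matrix with reflection (mirror) boundary handling; rows
# sum to 1, so constants are preserved exactly.
conv_matrix_reflect <- function(n, w) {
  r <- (length(w) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-r:r)
    # reflect about the edges (1-based, edge voxel not duplicated when n > 1)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    for (k in seq_along(w)) M[i, idx[k]] <- M[i, idx[k]] + w[k]
  }
  M
}

apply_axis <- function(a, M, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- M %*% matrix(ap, nrow = d[axis])
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

#' Smooth a volume with an isotropic Gaussian kernel
#'
#' Separable convolution with per-axis sigma (in voxels) of
#' `(fwhm_mm / voxel_size_mm) / (2 sqrt(2 log 2))`, reflection boundary
#' handling (constants are preserved exactly). `fwhm_mm = 0` is the identity.
#'
#' @param v an [asl_volume()].
#' @param fwhm_mm kernel full width at half maximum, mm (>= 0).
#' @return smoothed [asl_volume()].
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  }
  if (fwhm_mm == 0) return(v)
  vs <- voxel_size(v)
  a <- vol_data(v)
  for (axis in 1:3) {
    w <- gaussian_kernel_weights(fwhm_mm, vs[axis])
    if (length(w) > 1L) a <- apply_axis(a, conv_matrix_reflect(dim(a)[axis], w), axis)
  }
  asl_volume(a, vs)
}

#' Scale a volume so its global median equals a target
#'
#' Removes inter-subject global perfusion differences by scaling every voxel
#' by `target / median`. The median is taken over in-mask voxels by default
#' (a whole-volume median would be dominated by background); pass
#' `use_mask = FALSE` for the whole-volume variant.
#'
#' @param v an [asl_volume()].
#' @param mask logical array matching the grid.
#' @param target target median, default 1000.
#' @param use_mask compute the median over in-mask voxels only (default).
#' @return scaled [asl_volume()] whose (in-mask) median equals `target`.
#' @export
scale_global_median <- function(v, mask, target = 1000, use_mask = TRUE) {
  a <- vol_data(v)
  med <- if (use_mask) {
    if (!identical(dim(mask), dim(a))) stop("mask grid does not match volume grid", call. = FALSE)
    stats::median(a[mask])
  } else {
    stats::median(a)
  }
  if (!is.finite(med) || med <= 0) {
    stop("global median is ", med, "; refusing to scale a degenerate image", call. = FALSE)
  }
  asl_volume(a * (target / med), voxel_size(v))
}

#' Voxelwise average of a list of volumes
#'
#' @param volumes nonempty list of [asl_volume()]s on a common grid.
#' @return the mean [asl_volume()].
#' @export
average_scans <- function(volumes) {
  if (length(volumes) == 0) stop("cannot average an empty scan list", call. = FALSE)
  d <- dim(volumes[[1]])
  acc <- array(0, dim = d)
  for (v in volumes) {
    if (!identical(dim(v), d)) stop("volumes have mismatched grids", call. = FALSE)
    acc <- acc + vol_data(v)
  }
  asl_volume(acc / length(volumes), voxel_size(volumes[[1]]))
}

#' Assemble the samples-by-voxels feature matrix
#'
#' Rows follow the input record order; columns follow the deterministic
#' column-major linear scan of the mask (`which(mask)`). Records whose
#' condition is absent from `label_map` are dropped when `drop_unmapped` is
#' `TRUE`, otherwise they are an error.
#'
#' @param records tibble with `subject_id`, `condition` and a `volume`
#'   list-column (other columns are carried through as metadata).
#' @param mask logical 3-D array.
#' @param label_map named numeric vector mapping conditions to `+1` / `-1`
#'   (e.g. `c(postsurgery = 1, presurgery = -1)`).
#' @param drop_unmapped drop records with unmapped conditions (default FALSE).
#' @return an `asl_features` object: list with `X` (samples x voxels),
#'   `labels` (+1/-1), `subject_ids`, `voxel_index` (linear in-mask indices),
#'   `grid_shape`, `voxel_size_mm` and `meta` (per-row metadata tibble).
#' @export
build_feature_matrix <- function(records, mask, label_map, drop_unmapped = FALSE) {
  stopifnot(is.array(mask), all(unlist(label_map) %in% c(-1, 1)))
  mapped <- records$condition %in% names(label_map)
  if (!all(mapped)) {
    if (!drop_unmapped) {
      stop("conditions without a label mapping: ",
           paste(unique(records$condition[!mapped]), collapse = ", "), call. = FALSE)
    }
    records <- records[mapped, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no records remain after label mapping", call. = FALSE)
  g <- dim(records$volume[[1]])
  if (!identical(dim(mask), g)) stop("mask grid does not match volume grid", call. = FALSE)
  voxel_index <- which(mask)
  X <- matrix(NA_real_, nrow(records), length(voxel_index))
  for (i in seq_len(nrow(records))) X[i, ] <- vol_data(records$volume[[i]])[voxel_index]
  structure(
    list(
      X = X,
      labels = unname(unlist(label_map)[records$condition]),
      subject_ids = records$subject_id,
      voxel_index = voxel_index,
      grid_shape = g,
      voxel_size_mm = voxel_size(records$volume[[1]]),
      meta = dplyr::select(records, -"volume")
    ),
    class = "asl_features"
  )
}

#' @export
print.asl_features <- function(x, ...) {
  cat(sprintf(
    "<asl_features> %d samples x %d in-mask voxels (%d subjects; labels: %s)\n",
    nrow(x$X), ncol(x$X), length(unique(x$subject_ids)),
    paste(sprintf("%+d x %d", c(1, -1), c(sum(x$labels == 1), sum(x$labels == -1))),
          collapse = ", ")
  ))
  invisible(x)
}

#' Smooth and median-scale every scan of a cohort
#'
#' The per-scan half of the preprocessing tail, in its fixed order: smooth
#' each scan with the isotropic Gaussian kernel, then scale each smoothed
#' scan to the common global median. Averaging (the next stage) happens in
#' [average_sessions()]; keeping the two apart lets the scan-reduction
#' analysis preprocess each scan exactly once.
#'
#' @param cohort scan-level tibble from [simulate_cohort()] / [read_dataset()].
#' @param mask logical 3-D array.
#' @param fwhm_mm smoothing kernel FWHM, mm (default 8).
#' @param target_median global median target (default 1000).
#' @param use_mask median over in-mask voxels only (default TRUE).
#' @return the cohort tibble with processed volumes.
#' @export
preprocess_scans <- function(cohort, mask, fwhm_mm = 8, target_median = 1000,
                             use_mask = TRUE) {
  dplyr::mutate(cohort, volume = purrr::map(
    .data$volume,
    ~ scale_global_median(gaussian_smooth(.x, fwhm_mm), mask, target_median, use_mask)
  ))
}

#' Average the kept scans of every subject-session
#'
#' Scan reduction keeps acquisition indices `1..n_scans` (scans are dropped
#' from the end, i.e. in reverse acquisition order) and averages them into a
#' single image per subject-session; VAS scores are averaged alongside.
#'
#' @param processed scan-level tibble (typically from [preprocess_scans()]).
#' @param n_scans number of scans kept per session (default: all).
#' @return tibble with one row per subject-session.
#' @export
average_sessions <- function(processed, n_scans = NULL) {
  if (is.null(n_scans)) n_scans <- max(processed$acquisition_index)
  counts <- processed |>
    dplyr::summarise(k = dplyr::n(), .by = c("subject_id", "session_code"))
  if (any(counts$k < n_scans)) {
    bad <- counts[counts$k < n_scans, ][1, ]
    stop(sprintf("session %s of %s has %d scans; %d requested",
                 bad$session_code, bad$subject_id, bad$k, n_scans), call. = FALSE)
  }
  processed |>
    dplyr::filter(.data$acquisition_index <= n_scans) |>
    dplyr::summarise(
      vas_pain = mean(.data$vas_pain),
      vas_alertness = mean(.data$vas_alertness),
      n_scans = dplyr::n(),
      volume = list(average_scans(.data$volume)),
      .by = c("subject_id", "session_code", "condition", "side")
    )
}

#' Run the preprocessing tail and collapse to one image per subject-session
#'
#' Fixed order, matching the acquisition pipeline: smooth each scan, scale
#' each scan to a common global median, then average the kept scans of every
#' subject-session (composition of [preprocess_scans()] and
#' [average_sessions()]).
#'
#' @param cohort scan-level tibble from [simulate_cohort()] / [read_dataset()].
#' @param mask logical 3-D array.
#' @param fwhm_mm smoothing kernel FWHM, mm (default 8).
#' @param target_median global median target (default 1000).
#' @param n_scans number of scans kept per session (default: all).
#' @param use_mask median over in-mask voxels only (default TRUE).
#' @return tibble with one row per subject-session: metadata, mean VAS scores
#'   and the averaged `volume`.
#' @export
preprocess_cohort <- function(cohort, mask, fwhm_mm = 8, target_median = 1000,
                              n_scans = NULL, use_mask = TRUE) {
  average_sessions(
    preprocess_scans(cohort, mask, fwhm_mm = fwhm_mm,
                     target_median = target_median, use_mask = use_mask),
    n_scans = n_scans
  )
}

#' Build classifier samples for one of the study comparisons
#'
#' Realizes the three decoding analyses on session-averaged records:
#' \describe{
#'   \item{`pre_vs_post`}{postsurgical (+1) vs presurgical (-1) states. With
#'     `samples = "averaged"` (default) each subject contributes one averaged
#'     presurgical and one averaged postsurgical image; with `"per_scan"`
#'     every session image is its own sample.}
#'   \item{`left_vs_right`}{left (+1) vs right (-1) postsurgical sessions.}
#'   \item{`followup_vs_post`}{postsurgical (+1) on the given `side` vs
#'     pain-free follow-up (-1).}
#' }
#'
#' @param prep subject-session tibble from [preprocess_cohort()].
#' @param comparison one of `"pre_vs_post"`, `"left_vs_right"`,
#'   `"followup_vs_post"`.
#' @param side surgery side for `followup_vs_post` (`"left"` or `"right"`).
#' @param samples `"averaged"` or `"per_scan"` (pre_vs_post only).
#' @return list with `records` (tibble incl. `volume`) and `label_map`.
#' @export
assemble_samples <- function(prep, comparison = c("pre_vs_post", "left_vs_right",
                                                  "followup_vs_post"),
                             side = NULL, samples = c("averaged", "per_scan")) {
  comparison <- match.arg(comparison)
  samples <- match.arg(samples)
  if (comparison == "pre_vs_post") {
    rec <- prep |> dplyr::filter(.data$condition %in% c("presurgery", "postsurgery"))
    if (samples == "averaged") {
      rec <- rec |>
        dplyr::summarise(volume = list(average_scans(.data$volume)),
                         .by = c("subject_id", "condition"))
    }
    list(records = rec, label_map = c(postsurgery = 1, presurgery = -1))
  } else if (comparison == "left_vs_right") {
    rec <- prep |>
      dplyr::filter(.data$condition == "postsurgery") |>
      dplyr::mutate(condition = paste0("postsurgery_", .data$side))
    list(records = rec, label_map = c(postsurgery_left = 1, postsurgery_right = -1))
  } else {
    if (is.null(side) || !side %in% c("left", "right")) {
      stop("`side` must be \"left\" or \"right\" for followup_vs_post", call. = FALSE)
    }
    rec <- prep |>
      dplyr::filter(.data$condition == "followup" |
                      (.data$condition == "postsurgery" & .data$side == !!side))
    list(records = rec, label_map = c(postsurgery = 1, followup = -1))
  }
}
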