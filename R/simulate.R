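#' Specify a Gaussian blob of the discriminative perfusion pattern
#'
#' One isotropic Gaussian bump of rCBF change. Positive amplitudes stand in
#' for regions whose perfusion rises in the postsurgical state (thalamus,
#' insula, anterior cingulate in the third-molar-extraction pain model);
#' negative amplitudes for occipito-parietal decreases.
#'
#' @param center integer length 3, 1-based voxel coordinates of the peak.
#' @param fwhm_mm spatial full width at half maximum of the bump, mm (> 0).
#' @param amplitude signed peak rCBF offset, scaled CBF units.
#' @return one-row tibble (`center` is a list-column).
#' @export
blob_spec <- function(center, fwhm_mm, amplitude) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, is.finite(fwhm_mm), is.finite(amplitude))
  if (fwhm_mm <= 0) stop("`fwhm_mm` must be > 0", call. = FALSE)
  tibble::tibble(center = list(center), fwhm_mm = fwhm_mm, amplitude = amplitude)
}

#' Default blob layout emulating the postsurgical pain pattern
#'
#' Schematic stand-ins, positioned in grid fractions so that any grid shape
#' gets bilateral deep "thalamus"-like foci, lateral "insula"-like foci and a
#' midline anterior focus with positive amplitude, plus bilateral posterior
#' ("occipital") foci with negative amplitude.
#'
#' @param grid_shape integer length 3.
#' @return tibble of blob specs.
#' @export
default_pain_blobs <- function(grid_shape = c(24, 32, 24)) {
  g <- as.numeric(grid_shape)
  at <- function(fx, fy, fz) round(c(fx, fy, fz) * g)
  dplyr::bind_rows(
    blob_spec(at(0.38, 0.50, 0.46), 12, 6),   # left thalamus-like
    blob_spec(at(0.62, 0.50, 0.46), 12, 6),   # right thalamus-like
    blob_spec(at(0.22, 0.56, 0.42), 12, 5),   # left insula-like
    blob_spec(at(0.78, 0.56, 0.42), 12, 5),   # right insula-like
    blob_spec(at(0.50, 0.72, 0.54), 14, 5),   # anterior cingulate-like
    blob_spec(at(0.38, 0.16, 0.42), 14, -5),  # left occipito-parietal
    blob_spec(at(0.62, 0.16, 0.42), 14, -5)   # right occipito-parietal
  )
}

#' Build the spatial pattern template from blob specs
#'
#' Sums isotropic Gaussian bumps on the voxel grid. Each bump has value
#' `amplitude` exactly at its centre voxel and half that at distance
#' `fwhm_mm / 2`, i.e. `amplitude * exp(-4 log(2) * r_mm^2 / fwhm_mm^2)`.
#'
#' @param grid_shape integer length 3.
#' @param voxel_size_mm numeric length 1 or 3, mm.
#' @param blobs tibble of [blob_spec()] rows (may be empty).
#' @return an [asl_volume()] with the summed template.
#' @export
generate_pattern_template <- function(grid_shape, voxel_size_mm, blobs) {
  grid_shape <- as.integer(grid_shape)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  tpl <- array(0, dim = grid_shape)
  if (nrow(blobs) > 0) {
    for (b in seq_len(nrow(blobs))) {
      ctr <- blobs$center[[b]]
      if (any(ctr < 1) || any(ctr > grid_shape)) {
        stop(sprintf(
          "blob %d center (%s) lies outside the %s grid",
          b, paste(ctr, collapse = ","), paste(grid_shape, collapse = "x")
        ), call. = FALSE)
      }
      fwhm <- blobs$fwhm_mm[b]
      amp <- blobs$amplitude[b]
      # separable: exp(-4 ln2 (dx^2+dy^2+dz^2)/fwhm^2) factorizes per axis
      ax <- lapply(1:3, function(k) {
        dmm <- (seq_len(grid_shape[k]) - ctr[k]) * voxel_size_mm[k]
        exp(-4 * log(2) * dmm^2 / fwhm^2)
      })
      tpl <- tpl + amp * outer(outer(ax[[1]], ax[[2]]), ax[[3]])
    }
  }
  asl_volume(tpl, voxel_size_mm)
}

default_sessions <- function() {
  tibble::tibble(
    session_code = c("S2", "S3", "S4", "S5", "S6"),
    condition = c("presurgery", "postsurgery", "presurgery", "postsurgery", "followup"),
    surgery = c(NA, 1L, NA, 2L, NA)
  )
}

#' Describe a synthetic ASL cohort
#'
#' Encodes the repeated-measures design being emulated: subjects scanned on
#' five occasions (presurgery, postsurgery for each of two extractions, and a
#' pain-free follow-up), six ASL scans per session. Surgery side order is
#' balanced and pseudorandomized across subjects from the seed.
#'
#' @param n_subjects number of subjects (default 20).
#' @param n_scans_per_session ASL scans per session (default 6).
#' @param sessions tibble with columns `session_code`, `condition`
#'   (`presurgery`/`postsurgery`/`followup`) and `surgery` (1, 2 or `NA`),
#'   in scan order.
#' @param grid_shape,voxel_size_mm volume geometry; default 24 x 32 x 24 at
#'   3 mm isotropic, a desk-scale stand-in for a 48 x 64 x 60 acquisition.
#' @param baseline_cbf mean perfusion level, scaled CBF units.
#' @param subject_global_sd sd of the per-subject lognormal global perfusion
#'   factor (multiplicative inter-subject spread).
#' @param scan_noise_sd additive per-voxel, per-scan Gaussian noise sd.
#' @param effect_scale multiplier on all blob amplitudes (0 = null cohort).
#' @param blobs pattern blob specs, default [default_pain_blobs()].
#' @param vas_pain_presurgery_mean,vas_pain_post_left_delta,vas_pain_post_right_delta
#'   VAS pain model (0-100): presurgical mean and side-specific postsurgical
#'   increments; defaults reproduce mean post-minus-pre differences of 52.41
#'   (left) and 50.779 (right).
#' @param vas_alert_mean VAS alertness mean, identical across conditions.
#' @param vas_sd VAS score sd.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 20, n_scans_per_session = 6,
                        sessions = default_sessions(),
                        grid_shape = c(24, 32, 24), voxel_size_mm = c(3, 3, 3),
                        baseline_cbf = 50, subject_global_sd = 0.15,
                        scan_noise_sd = 8, effect_scale = 1,
                        blobs = default_pain_blobs(grid_shape),
                        vas_pain_presurgery_mean = 15,
                        vas_pain_post_left_delta = 52.41,
                        vas_pain_post_right_delta = 50.779,
                        vas_alert_mean = 70, vas_sd = 8, seed = 1) {
  stopifnot(
    n_subjects >= 1, n_scans_per_session >= 1,
    all(c("session_code", "condition", "surgery") %in% names(sessions)),
    length(grid_shape) == 3L, all(grid_shape >= 1),
    subject_global_sd >= 0, scan_noise_sd >= 0, vas_sd >= 0,
    is.finite(effect_scale),
    is.finite(vas_pain_post_left_delta), is.finite(vas_pain_post_right_delta)
  )
  spec <- list(
    n_subjects = as.integer(n_subjects),
    n_scans_per_session = as.integer(n_scans_per_session),
    sessions = sessions,
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
    baseline_cbf = baseline_cbf,
    subject_global_sd = subject_global_sd,
    scan_noise_sd = scan_noise_sd,
    effect_scale = effect_scale,
    blobs = blobs,
    vas_pain_presurgery_mean = vas_pain_presurgery_mean,
    vas_pain_post_left_delta = vas_pain_post_left_delta,
    vas_pain_post_right_delta = vas_pain_post_right_delta,
    vas_alert_mean = vas_alert_mean,
    vas_sd = vas_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  force(code)
}

#' Simulate a synthetic ASL cohort
#'
#' Generative model per scan:
#' `volume = baseline_cbf * g_s + 1[postsurgery] * effect_scale * template + noise`
#' where `g_s ~ lognormal(0, subject_global_sd)` is fixed per subject
#' (emulating inter-subject global perfusion variability, the motivation for
#' median-1000 scaling), the template is [generate_pattern_template()] over
#' the spec's blobs, and noise is i.i.d. `N(0, scan_noise_sd)` per voxel and
#' scan. VAS pain is `N(presurgery_mean + side delta * 1[postsurgery],
#' vas_sd)` clipped to `[0, 100]`; VAS alertness has no condition effect.
#' Fully reproducible from `spec$seed`; the caller's RNG state is preserved.
#'
#' @param spec a [cohort_spec()].
#' @return tibble with one row per scan: `subject_id`, `session_code`,
#'   `condition`, `side`, `acquisition_index`, `vas_pain`, `vas_alertness`
#'   and a `volume` list-column of [asl_volume()]s.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- vol_data(generate_pattern_template(spec$grid_shape, spec$voxel_size_mm, spec$blobs))
  with_preserved_rng({
    set.seed(spec$seed)
    n <- spec$n_subjects
    subjects <- sprintf("sub%02d", seq_len(n))
    # balanced first-surgery side, pseudorandomized across the group
    first_side <- rep(c("left", "right"), length.out = n)[sample.int(n)]
    g_subject <- exp(stats::rnorm(n, 0, spec$subject_global_sd))

    rows <- vector("list", n * nrow(spec$sessions) * spec$n_scans_per_session)
    k <- 0L
    for (s in seq_len(n)) {
      sides <- c(first_side[s], setdiff(c("left", "right"), first_side[s]))
      for (j in seq_len(nrow(spec$sessions))) {
        cond <- spec$sessions$condition[j]
        surg <- spec$sessions$surgery[j]
        side <- if (!is.na(surg)) sides[surg] else "none"
        is_post <- cond == "postsurgery"
        delta <- if (!is_post) 0 else if (side == "left") {
          spec$vas_pain_post_left_delta
        } else {
          spec$vas_pain_post_right_delta
        }
        base <- spec$baseline_cbf * g_subject[s] +
          (if (is_post) spec$effect_scale * tpl else 0)
        for (a in seq_len(spec$n_scans_per_session)) {
          noise <- stats::rnorm(length(tpl), 0, spec$scan_noise_sd)
          vol <- asl_volume(array(base + noise, dim = spec$grid_shape),
                            spec$voxel_size_mm)
          vas_pain <- clip01(stats::rnorm(1, spec$vas_pain_presurgery_mean + delta, spec$vas_sd))
          vas_alert <- clip01(stats::rnorm(1, spec$vas_alert_mean, spec$vas_sd))
          k <- k + 1L
          rows[[k]] <- tibble::tibble(
            subject_id = subjects[s], session_code = spec$sessions$session_code[j],
            condition = cond, side = side, acquisition_index = a,
            vas_pain = vas_pain, vas_alertness = vas_alert, volume = list(vol)
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

clip01 <- function(x) pmin(100, pmax(0, x))

#' Analytic contrast-to-noise ratio of a cohort spec
#'
#' CNR of the condition effect in the session-averaged, smoothed image:
#' peak absolute smoothed template amplitude times `effect_scale`, divided by
#' the post-smoothing scan noise sd reduced by `sqrt(n_scans_per_session)`.
#' The smoothed noise sd follows analytically from the separable kernel
#' weights (`sd_out = sd_in * prod_axis sqrt(sum w_axis^2)`).
#'
#' @param spec a [cohort_spec()].
#' @param fwhm_mm preprocessing smoothing kernel FWHM, mm (default 8).
#' @return a single number; `Inf` when `scan_noise_sd = 0`.
#' @export
cohort_cnr <- function(spec, fwhm_mm = 8) {
  tpl <- generate_pattern_template(spec$grid_shape, spec$voxel_size_mm, spec$blobs)
  tpl_sm <- gaussian_smooth(tpl, fwhm_mm)
  peak <- max(abs(tpl_sm)) * abs(spec$effect_scale)
  w2 <- vapply(1:3, function(k) {
    w <- gaussian_kernel_weights(fwhm_mm, spec$voxel_size_mm[k])
    sum(w^2)
  }, numeric(1))
  noise_sd <- spec$scan_noise_sd * sqrt(prod(w2)) / sqrt(spec$n_scans_per_session)
  if (noise_sd == 0) return(Inf)
  peak / noise_sd
}

#' Rescale the condition effect to a target contrast-to-noise ratio
#'
#' CNR is linear in `effect_scale`, so the tuned value is a single ratio.
#'
#' @param spec a [cohort_spec()].
#' @param target_cnr desired [cohort_cnr()] (default 1.5).
#' @param fwhm_mm smoothing kernel assumed by the CNR computation.
#' @return the spec with `effect_scale` replaced.
#' @export
tune_effect_scale <- function(spec, target_cnr = 1.5, fwhm_mm = 8) {
  ref <- spec
  ref$effect_scale <- 1
  base <- cohort_cnr(ref, fwhm_mm)
  if (!is.finite(base) || base <= 0) {
    stop("cannot tune effect scale: base CNR is ", base, call. = FALSE)
  }
  spec$effect_scale <- target_cnr / base
  spec
}

#' Write a cohort to NIfTI volumes plus a CSV metadata table
#'
#' @param cohort tibble from [simulate_cohort()].
#' @param mask logical 3-D array (brain mask), written as `mask.nii`.
#' @param out_dir output directory, created if needed.
#' @return tibble manifest (the metadata table with absolute filenames).
#' @export
write_dataset <- function(cohort, mask, out_dir) {
  stopifnot(nrow(cohort) > 0)
  g <- dim(cohort$volume[[1]])
  if (!identical(dim(mask), g)) {
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match volume grid ", paste(g, collapse = "x"), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  vs <- voxel_size(cohort$volume[[1]])
  write_nifti(asl_volume(array(as.numeric(mask), dim = g), vs),
              file.path(out_dir, "mask.nii"), descrip = "brain mask (nonzero = in-mask)")
  meta <- cohort |>
    dplyr::mutate(filename = sprintf(
      "%s_%s_scan%02d.nii", .data$subject_id, .data$session_code, .data$acquisition_index
    ))
  for (i in seq_len(nrow(meta))) {
    write_nifti(meta$volume[[i]], file.path(out_dir, meta$filename[i]))
  }
  tab <- meta |>
    dplyr::select("subject_id", "session_code", "condition", "side",
                  "acquisition_index", "filename", "vas_pain", "vas_alertness")
  utils::write.csv(tab, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  tab
}

#' Read a cohort written by [write_dataset()]
#'
#' @param dir dataset directory containing `metadata.csv`, `mask.nii` and the
#'   per-scan volumes.
#' @return list with `cohort` (tibble as produced by [simulate_cohort()]) and
#'   `mask` (logical array).
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir, call. = FALSE)
  tab <- tibble::as_tibble(utils::read.csv(meta_path, stringsAsFactors = FALSE))
  mask_vol <- read_nifti(file.path(dir, "mask.nii"))
  cohort <- tab |>
    dplyr::mutate(volume = purrr::map(.data$filename, ~ read_nifti(file.path(dir, .x)))) |>
    dplyr::select(-"filename")
  list(cohort = cohort, mask = array(vol_data(mask_vol) != 0, dim = dim(mask_vol)))
}
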