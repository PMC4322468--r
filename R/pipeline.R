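#' Assemble a full pipeline run configuration
#'
#' Bundles the cohort specification, preprocessing parameters, classifier
#' controls and evaluation settings into one validated object; every field is
#' echoed into the run manifest so a run is reproducible from its config and
#' seed alone.
#'
#' @param cohort a [cohort_spec()] (its `seed` is overridden by `seed`).
#' @param fwhm_mm,target_median preprocessing parameters (defaults 8 mm, 1000).
#' @param comparison `"pre_vs_post"`, `"left_vs_right"` or
#'   `"followup_vs_post"`.
#' @param side side(s) for `followup_vs_post` / the scan-reduction stage.
#' @param samples `"averaged"` or `"per_scan"` (pre_vs_post sample mode).
#' @param classifier a [gpc_control()].
#' @param n_perm permutations for significance testing (default 1000; 0
#'   disables).
#' @param alpha nominal significance level recorded in reports.
#' @param max_scans scan counts for the reduction stage (0 disables).
#' @param seed mandatory top-level RNG seed; every random draw in the run
#'   derives from it.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = cohort_spec(), fwhm_mm = 8, target_median = 1000,
                       comparison = "pre_vs_post", side = "left",
                       samples = "averaged", classifier = gpc_control(),
                       n_perm = 1000, alpha = 0.05, max_scans = 6, seed) {
  if (missing(seed) || !is.finite(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(comparison %in% c("pre_vs_post", "left_vs_right", "followup_vs_post"),
            n_perm >= 0, max_scans >= 0)
  cohort$seed <- as.integer(seed)
  structure(
    list(cohort = cohort, fwhm_mm = fwhm_mm, target_median = target_median,
         comparison = comparison, side = side, samples = samples,
         classifier = classifier, n_perm = n_perm, alpha = alpha,
         max_scans = max_scans, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognized top-level keys: `seed` (mandatory), `comparison`, `side`,
#' `samples`, `fwhm_mm`, `target_median`, `n_perm`, `alpha`, `max_scans`,
#' `optimize`, plus a `cohort:` block whose keys are [cohort_spec()]
#' arguments (blob tables are given as lists of `{center, fwhm_mm,
#' amplitude}`).
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set `seed`", call. = FALSE)
  co <- y$cohort %||% list()
  if (!is.null(co$blobs)) {
    co$blobs <- dplyr::bind_rows(lapply(co$blobs, function(b) {
      blob_spec(unlist(b$center), b$fwhm_mm, b$amplitude)
    }))
  }
  co$seed <- y$seed
  cohort <- do.call(cohort_spec, co)
  args <- y[setdiff(names(y), c("cohort", "optimize"))]
  args$cohort <- cohort
  if (!is.null(y$optimize)) args$classifier <- gpc_control(optimize = isTRUE(y$optimize))
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_digest <- function(config) {
  rlang::hash(config)
}

#' Run the full decoding pipeline
#'
#' Orchestrates simulate, preprocess, classify, permute, reduce-scans and
#' gmap in that fixed order, writing every report under `out_dir`:
#' `metadata.csv` + NIfTI volumes (when `write_volumes`), `report.json`
#' (confusion statistics, AUC, permutation p), `scan_curve.csv` (when
#' `max_scans > 0`), `gmap.nii` + sidecar, and `manifest.json` (config hash,
#' seed, package version, stage artifact list). Re-running with an identical
#' config reproduces identical reports.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if needed.
#' @param mask optional logical mask array; default [ellipsoid_mask()] of the
#'   cohort grid. A character path is read as NIfTI (nonzero = in-mask) and
#'   validated before any computation.
#' @param write_volumes also export the simulated volumes as NIfTI
#'   (default FALSE; the metadata table is always written).
#' @return list with `manifest`, `report` (stats tibble), `curve`
#'   (or NULL), `gmap`.
#' @export
run_pipeline <- function(config, out_dir, mask = NULL, write_volumes = FALSE) {
  stopifnot(inherits(config, "run_config"))
  # validate before any compute
  if (is.character(mask)) {
    if (!file.exists(mask)) stop("mask file not found: ", mask, call. = FALSE)
    mv <- read_nifti(mask)
    mask <- array(vol_data(mv) != 0, dim = dim(mv))
  }
  if (is.null(mask)) mask <- ellipsoid_mask(config$cohort$grid_shape)
  if (!identical(dim(mask), as.integer(config$cohort$grid_shape))) {
    stop("mask grid does not match the cohort grid", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "simulate"
  artifacts <- character(0)
  result <- tryCatch({
    cohort <- simulate_cohort(config$cohort)
    meta <- dplyr::select(cohort, -"volume")
    utils::write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "metadata.csv")
    if (write_volumes) {
      write_dataset(cohort, mask, file.path(out_dir, "volumes"))
      artifacts <- c(artifacts, "volumes/")
    }

    stage <- "preprocess"
    prep <- preprocess_cohort(cohort, mask, fwhm_mm = config$fwhm_mm,
                              target_median = config$target_median)
    smp <- assemble_samples(prep, config$comparison,
                            side = if (config$comparison == "followup_vs_post") {
                              config$side[1]
                            } else {
                              NULL
                            },
                            samples = config$samples)
    fm <- build_feature_matrix(smp$records, mask, smp$label_map)

    stage <- "classify"
    ev <- evaluate_comparison(fm, config$classifier, n_perm = config$n_perm,
                              seed = config$seed + 7L)
    report <- dplyr::bind_cols(
      tibble::tibble(comparison = config$comparison),
      ev$stats,
      tibble::tibble(alpha = config$alpha, seed = config$seed)
    )
    jsonlite::write_json(as.list(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(ev$predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    artifacts <- c(artifacts, "report.json", "predictions.csv")

    curve <- NULL
    if (config$max_scans > 0) {
      stage <- "reduce-scans"
      curve <- scan_reduction_curve(cohort, mask, config$classifier,
                                    side = config$side,
                                    max_scans = config$max_scans,
                                    n_perm = config$n_perm,
                                    seed = config$seed + 11L,
                                    fwhm_mm = config$fwhm_mm,
                                    target_median = config$target_median)
      utils::write.csv(tibble::as_tibble(curve),
                       file.path(out_dir, "scan_curve.csv"), row.names = FALSE)
      artifacts <- c(artifacts, "scan_curve.csv")
    }

    stage <- "gmap"
    model <- gpc_fit(fm$X, fm$labels,
                     hyperparams = config$classifier$hyperparams,
                     optimize = config$classifier$optimize,
                     d_normalize = config$classifier$d_normalize,
                     maxit = config$classifier$maxit)
    gm <- compute_gmap(model, fm)
    write_gmap(gm, file.path(out_dir, "gmap.nii"),
               extra = list(comparison = config$comparison, fit = "all-data"))
    artifacts <- c(artifacts, "gmap.nii", "gmap.json")

    list(report = report, curve = curve, gmap = gm)
  }, error = function(e) {
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    config_hash = config_digest(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("aslgpc")),
    comparison = config$comparison,
    n_perm = config$n_perm,
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  c(list(manifest = manifest), result)
}
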