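#' Compute the discriminative pattern map (g-map)
#'
#' Projects the training data onto the direction of maximal class difference:
#' dual coefficients `a = K^-1 mu` are obtained from the EP posterior latent
#' mean by a jittered solve, and the voxel-space map is `g = Xc' a` over the
#' centered training features — the mean of the posterior distribution in
#' input (voxel) space. The map is defined exactly on in-mask voxels and is
#' never thresholded.
#'
#' Sign convention (recorded in the result and any exported metadata):
#' `"negative_favors_positive"` (default) flips the raw projection so that
#' negative coefficients favor the class coded +1 (postsurgery) and positive
#' coefficients the comparison class; `"positive_favors_positive"` keeps the
#' raw orientation.
#'
#' @param model a `gpc_model` trained on `fm`.
#' @param fm the `asl_features` the model was trained on (supplies the
#'   voxel-to-grid mapping).
#' @param sign_convention `"negative_favors_positive"` or
#'   `"positive_favors_positive"`.
#' @param jitter relative diagonal jitter for the kernel solve.
#' @return an `asl_gmap`: list with `values` (per in-mask voxel), `volume`
#'   (grid array, `NA` outside the mask), `voxel_index`, `sign_convention`,
#'   `hyperparams`.
#' @export
compute_gmap <- function(model, fm,
                         sign_convention = c("negative_favors_positive",
                                             "positive_favors_positive"),
                         jitter = 1e-8) {
  sign_convention <- match.arg(sign_convention)
  if (model$n != nrow(fm$X)) {
    stop("model was not trained on this feature matrix (sample count differs)",
         call. = FALSE)
  }
  K <- model$ep$K
  Kj <- K + diag(jitter * mean(diag(K)), nrow(K))
  a <- tryCatch(solve(Kj, model$ep$mu), error = function(e) {
    stop("kernel matrix is singular even after jitter: ", conditionMessage(e),
         call. = FALSE)
  })
  g <- as.vector(crossprod(model$Xc, a))
  if (sign_convention == "negative_favors_positive") g <- -g
  vol <- array(NA_real_, dim = fm$grid_shape)
  vol[fm$voxel_index] <- g
  structure(
    list(values = g, volume = vol, voxel_index = fm$voxel_index,
         grid_shape = fm$grid_shape, voxel_size_mm = fm$voxel_size_mm,
         sign_convention = sign_convention, hyperparams = model$hyperparams),
    class = "asl_gmap"
  )
}

#' @export
print.asl_gmap <- function(x, ...) {
  cat(sprintf(
    "<asl_gmap> %d in-mask voxels on a %s grid; sign: %s; |g| range [%.3g, %.3g]\n",
    length(x$values), paste(x$grid_shape, collapse = "x"),
    x$sign_convention, min(abs(x$values)), max(abs(x$values))
  ))
  invisible(x)
}

#' Export a g-map as NIfTI plus a JSON sidecar
#'
#' Out-of-mask voxels are written as `NaN` (the background value is recorded
#' in the NIfTI description and the sidecar), never silently zero-filled.
#'
#' @param gmap an `asl_gmap`.
#' @param path output `.nii` path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param extra named list merged into the sidecar (e.g. fold provenance).
#' @return `path`, invisibly.
#' @export
write_gmap <- function(gmap, path, extra = list()) {
  vol <- gmap$volume
  vol[is.na(vol)] <- NaN
  write_nifti(asl_volume(vol, gmap$voxel_size_mm), path,
              descrip = paste0("gmap; background=NaN; ", gmap$sign_convention))
  sidecar <- c(list(
    sign_convention = gmap$sign_convention,
    background_value = "NaN",
    thresholded = FALSE,
    log_signal = gmap$hyperparams$log_signal,
    log_bias = gmap$hyperparams$log_bias,
    n_in_mask_voxels = length(gmap$values)
  ), extra)
  jsonlite::write_json(sidecar, sub("\\.nii$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Tidy a g-map into a per-voxel tibble
#'
#' @param x an `asl_gmap`.
#' @param ... unused.
#' @return tibble with voxel coordinates (`i`, `j`, `k`) and `g`.
#' @export
tidy.asl_gmap <- function(x, ...) {
  coords <- arrayInd(x$voxel_index, x$grid_shape)
  tibble::tibble(i = coords[, 1], j = coords[, 2], k = coords[, 3], g = x$values)
}
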