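#' Classifier configuration for cross-validated analyses
#'
#' @param optimize re-optimize hyperparameters in every training fold by
#'   evidence maximization (default TRUE).
#' @param hyperparams starting / fixed [gp_hyperparams()].
#' @param d_normalize see [linear_kernel()].
#' @param maxit evidence-optimizer iteration cap per fit.
#' @param reoptimize_permutations re-run hyperparameter optimization inside
#'   every permutation replicate (default TRUE; set FALSE to freeze the
#'   hyperparameters for speed — then the observed statistic is computed
#'   under the same frozen configuration so observed and null are comparable).
#' @param ep_tol,ep_max_sweeps EP convergence controls (see [ep_inference()]).
#' @return a `gpc_control` list.
#' @export
gpc_control <- function(optimize = TRUE, hyperparams = gp_hyperparams(),
                        d_normalize = TRUE, maxit = 100,
                        reoptimize_permutations = TRUE,
                        ep_tol = 1e-4, ep_max_sweeps = 60) {
  structure(list(optimize = optimize, hyperparams = hyperparams,
                 d_normalize = d_normalize, maxit = maxit,
                 reoptimize_permutations = reoptimize_permutations,
                 ep_tol = ep_tol, ep_max_sweeps = ep_max_sweeps),
            class = "gpc_control")
}

# raw (uncentered) normalized Gram of the feature matrix; computed once per
# LOOCV pass and shared by all folds — the dual form for n << p data
fm_gram <- function(fm, d_normalize = TRUE) {
  tcrossprod(fm$X) / (if (d_normalize) ncol(fm$X) else 1)
}

# one fold in Gram space: center G by the training-fold mean, fit, predict
fit_predict_fold_gram <- function(G, train_idx, test_idx, y, config) {
  y_tr <- y[train_idx]
  if (length(unique(y_tr)) < 2) {
    stop("training partition excluding sample(s) ",
         paste(utils::head(test_idx, 3), collapse = ","),
         " contains a single class", call. = FALSE)
  }
  Gc <- center_gram(G, train_idx)
  fit <- gpc_fit_gram(Gc[train_idx, train_idx, drop = FALSE], y_tr,
                      hyperparams = config$hyperparams,
                      optimize = config$optimize, maxit = config$maxit,
                      ep_tol = config$ep_tol, ep_max_sweeps = config$ep_max_sweeps)
  predict_gram(fit, Gc[train_idx, test_idx, drop = FALSE],
               diag(Gc)[test_idx])
}

#' Subject-level leave-one-out cross-validation
#'
#' One fold per subject: all of a subject's samples form the test set and
#' every other sample the training set, so no subject contributes to the
#' model that predicts it. The model (including, by default, its
#' hyperparameters) is refitted in every fold.
#'
#' @param fm an `asl_features` object from [build_feature_matrix()].
#' @param config a [gpc_control()].
#' @param labels optional replacement label vector (used by the permutation
#'   test); defaults to `fm$labels`.
#' @return tibble of per-sample held-out predictions: `subject_id`,
#'   `sample` (row index in `fm`), `truth` (+1/-1) and `prob` (probability
#'   of class +1).
#' @export
classify_loocv <- function(fm, config = gpc_control(), labels = fm$labels) {
  loocv_gram(fm_gram(fm, config$d_normalize), fm$subject_ids, labels, config)
}

# LOOCV over subjects on a precomputed raw Gram matrix
loocv_gram <- function(G, subject_ids, labels, config) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 3) stop("need at least 3 subjects for LOOCV", call. = FALSE)
  folds <- lapply(subjects, function(s) {
    test_idx <- which(subject_ids == s)
    train_idx <- which(subject_ids != s)
    if (length(unique(labels[train_idx])) < 2) {
      stop("training partition for held-out subject ", s,
           " contains a single class", call. = FALSE)
    }
    p <- fit_predict_fold_gram(G, train_idx, test_idx, labels, config)
    tibble::tibble(subject_id = s, sample = test_idx,
                   truth = labels[test_idx], prob = p)
  })
  dplyr::bind_rows(folds)
}

#' Confusion statistics at a probability threshold
#'
#' Sensitivity is the fraction of class-(+1) (postsurgical) samples with
#' predicted probability above the threshold; specificity the fraction of
#' class-(-1) samples below it. A sample exactly at the threshold counts as
#' misclassified for either class. Balanced accuracy is their mean.
#'
#' @param preds tibble from [classify_loocv()] (needs `truth`, `prob`).
#' @param threshold decision threshold on the class-(+1) probability.
#' @return one-row tibble: `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `n_pos`, `n_neg`.
#' @export
confusion_stats <- function(preds, threshold = 0.5) {
  stopifnot(nrow(preds) > 0)
  pos <- preds$truth == 1
  neg <- preds$truth == -1
  if (!any(pos) || !any(neg)) {
    stop("a class is absent from the test pool; rates undefined", call. = FALSE)
  }
  sens <- mean(preds$prob[pos] > threshold)
  spec <- mean(preds$prob[neg] < threshold)
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    n_pos = sum(pos), n_neg = sum(neg)
  )
}

#' ROC curve and area under the curve
#'
#' Threshold sweep over the predicted probabilities; the area is the
#' trapezoidal integral of the curve, which with the tie-sharing construction
#' equals the rank (Mann-Whitney) formulation with ties counted 1/2.
#'
#' @param preds tibble with `truth` (+1/-1) and `prob`.
#' @return an `asl_roc`: list with `curve` (tibble `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(preds) {
  pos <- preds$prob[preds$truth == 1]
  neg <- preds$prob[preds$truth == -1]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("ROC requires both classes in the test pool", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(preds$prob), decreasing = TRUE), -Inf)
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1))
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "asl_roc")
}

#' @export
print.asl_roc <- function(x, ...) {
  cat(sprintf("<asl_roc> AUC = %.4f (%d operating points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' Repeated-measures permutation test of the LOOCV balanced accuracy
#'
#' Builds the null by flipping, independently per permutation and with
#' probability 1/2, all condition labels of each subject together (both of a
#' subject's classes swap), respecting the repeated-measures design. The full
#' LOOCV is recomputed per permutation. The p-value uses the plus-one
#' estimator `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, whose smallest
#' attainable value with 1,000 permutations is ~0.001.
#'
#' @param fm an `asl_features` object.
#' @param config a [gpc_control()]; when `reoptimize_permutations = FALSE`
#'   the hyperparameters are optimized once on the unpermuted full data and
#'   frozen for the observed and all null LOOCVs.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the subject flips (mandatory).
#' @param observed optionally, a precomputed observed LOOCV prediction tibble
#'   (must match `fm` and `config`); avoids recomputation.
#' @return an `asl_permtest`: list with `p_value`, `observed` (balanced
#'   accuracy), `null` (numeric vector of null balanced accuracies),
#'   `n_perm` and `seed`.
#' @export
permutation_test <- function(fm, config = gpc_control(), n_perm = 1000, seed,
                             observed = NULL) {
  stopifnot(n_perm >= 1)
  if (missing(seed)) stop("`seed` is required for the permutation test", call. = FALSE)
  if (!isTRUE(config$reoptimize_permutations) && config$optimize) {
    m <- gpc_fit(fm$X, fm$labels, hyperparams = config$hyperparams,
                 optimize = TRUE, d_normalize = config$d_normalize,
                 maxit = config$maxit)
    config$hyperparams <- m$hyperparams
    config$optimize <- FALSE
  }
  G <- fm_gram(fm, config$d_normalize) # label flips never change the kernel
  obs_preds <- if (is.null(observed)) {
    loocv_gram(G, fm$subject_ids, fm$labels, config)
  } else {
    observed
  }
  obs_ba <- confusion_stats(obs_preds)$balanced_accuracy
  subjects <- unique(fm$subject_ids)
  null_ba <- numeric(n_perm)
  with_preserved_rng({
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      flip <- subjects[stats::runif(length(subjects)) < 0.5]
      lab <- fm$labels
      lab[fm$subject_ids %in% flip] <- -lab[fm$subject_ids %in% flip]
      preds <- loocv_gram(G, fm$subject_ids, lab, config)
      null_ba[b] <- confusion_stats(preds)$balanced_accuracy
    }
  })
  structure(
    list(
      p_value = (1 + sum(null_ba >= obs_ba)) / (1 + n_perm),
      observed = obs_ba, observed_preds = obs_preds,
      null = null_ba, n_perm = n_perm, seed = seed
    ),
    class = "asl_permtest"
  )
}

#' @export
print.asl_permtest <- function(x, ...) {
  cat(sprintf(
    "<asl_permtest> observed balanced accuracy = %.3f, p = %.4g (%d subject-level permutations)\n",
    x$observed, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' Holm's step-down multiple-testing correction
#'
#' Sorts the raw p-values ascending, multiplies the k-th smallest by
#' `m - k + 1`, enforces monotonicity by the running maximum and caps at 1;
#' adjusted values are returned in the original order.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
holm_stepdown <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj_sorted <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj_sorted <- cummax(adj_sorted)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Scan-number reduction analysis
#'
#' Repeats the follow-up vs postsurgery decoding while progressively reducing
#' the number of ASL scans per session from `max_scans` down to one, dropping
#' scans in reverse acquisition order; the kept scans are averaged into a
#' single image per subject-session used for both training and testing. Each
#' scan count gets a full subject-level LOOCV, confusion statistics, ROC/AUC
#' and (if `n_perm > 0`) a permutation p-value; Holm's step-down is applied
#' across all tests produced by the one call (both sides together when both
#' are requested).
#'
#' @param cohort scan-level cohort tibble.
#' @param mask logical 3-D array.
#' @param config a [gpc_control()].
#' @param side surgery side(s): `"left"`, `"right"` or both.
#' @param max_scans largest scan count (sessions must have at least this
#'   many scans; default 6).
#' @param n_perm permutations per test (0 skips significance testing).
#' @param seed RNG seed for the permutation tests.
#' @param fwhm_mm,target_median preprocessing parameters.
#' @return an `asl_scan_curve` tibble: one row per (side, n_scans) with
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `auc`, `p_value`,
#'   `p_holm`.
#' @export
scan_reduction_curve <- function(cohort, mask, config = gpc_control(),
                                 side = "left", max_scans = 6, n_perm = 0,
                                 seed = 1, fwhm_mm = 8, target_median = 1000) {
  stopifnot(all(side %in% c("left", "right")), max_scans >= 1)
  n_avail <- min(table(paste(cohort$subject_id, cohort$session_code)))
  if (n_avail < max_scans) {
    stop("sessions provide only ", n_avail, " scans; max_scans = ", max_scans,
         call. = FALSE)
  }
  processed <- preprocess_scans(cohort, mask, fwhm_mm = fwhm_mm,
                                target_median = target_median)
  rows <- list()
  for (n in seq_len(max_scans)) {
    prep <- average_sessions(processed, n_scans = n)
    for (sd_ in side) {
      smp <- assemble_samples(prep, "followup_vs_post", side = sd_)
      fm <- build_feature_matrix(smp$records, mask, smp$label_map)
      if (n_perm > 0) {
        pt <- permutation_test(fm, config, n_perm = n_perm,
                               seed = seed + 1000L * n + (sd_ == "right"))
        preds <- pt$observed_preds
        p <- pt$p_value
      } else {
        preds <- classify_loocv(fm, config)
        p <- NA_real_
      }
      cs <- confusion_stats(preds)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(side = sd_, n_scans = n),
        cs,
        tibble::tibble(auc = roc_auc(preds)$auc, p_value = p)
      )
    }
  }
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$side, .data$n_scans)
  out$p_holm <- if (n_perm > 0) holm_stepdown(out$p_value) else NA_real_
  class(out) <- c("asl_scan_curve", class(out))
  out
}

#' Full evaluation report for one comparison
#'
#' Convenience wrapper: LOOCV, confusion statistics, ROC/AUC and (optional)
#' permutation significance in one tidy object.
#'
#' @param fm an `asl_features` object.
#' @param config a [gpc_control()].
#' @param n_perm permutations (0 skips the test).
#' @param seed permutation RNG seed.
#' @param threshold decision threshold.
#' @return an `asl_eval`: list with `predictions`, `stats` (one-row tibble),
#'   `roc`, `permutation` (or NULL).
#' @export
evaluate_comparison <- function(fm, config = gpc_control(), n_perm = 0,
                                seed = 1, threshold = 0.5) {
  if (n_perm > 0) {
    pt <- permutation_test(fm, config, n_perm = n_perm, seed = seed)
    preds <- pt$observed_preds
  } else {
    pt <- NULL
    preds <- classify_loocv(fm, config)
  }
  cs <- confusion_stats(preds, threshold)
  roc <- roc_auc(preds)
  stats <- dplyr::bind_cols(cs, tibble::tibble(
    auc = roc$auc,
    p_value = if (is.null(pt)) NA_real_ else pt$p_value,
    n_perm = if (is.null(pt)) 0L else pt$n_perm
  ))
  structure(list(predictions = preds, stats = stats, roc = roc, permutation = pt),
            class = "asl_eval")
}

#' @export
print.asl_eval <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<asl_eval> sens %.3f / spec %.3f / balanced acc %.3f / AUC %.3f%s\n",
    s$sensitivity, s$specificity, s$balanced_accuracy, s$auc,
    if (is.na(s$p_value)) "" else sprintf(" / p = %.4g (%d perms)", s$p_value, s$n_perm)
  ))
  invisible(x)
}

#' @export
tidy.asl_eval <- function(x, ...) x$predictions

#' @export
glance.asl_eval <- function(x, ...) x$stats

#' @export
glance.asl_permtest <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p_value, n_perm = x$n_perm)
}

#' @export
tidy.asl_permtest <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null), balanced_accuracy = x$null)
}
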