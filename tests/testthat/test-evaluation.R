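frozen <- function(...) gpc_control(optimize = FALSE, ...)

test_that("LOOCV partitions by subject and is invariant to subject order", {
  fm <- separable_features(8, p = 5, signal = 1, noise_sd = 0.5, seed = 3)
  preds <- classify_loocv(fm, frozen())
  expect_equal(length(unique(preds$subject_id)), 8) # one fold per subject
  expect_equal(sort(preds$sample), seq_len(nrow(fm$X)))
  # the held-out subject contributes no training samples: predictions do not
  # depend on the held-out subject's own labels
  fm_flipped <- fm
  s1 <- fm$subject_ids == "s01"
  fm_flipped$labels[s1] <- -fm_flipped$labels[s1]
  preds_f <- classify_loocv(fm_flipped, frozen())
  expect_equal(preds_f$prob[preds_f$subject_id == "s01"],
               preds$prob[preds$subject_id == "s01"], tolerance = 1e-12)
  # shuffling the sample order leaves every (subject, truth, prob) triple
  # intact (tight EP tolerance so site-visit order cannot matter numerically)
  tight <- frozen(ep_tol = 1e-11, ep_max_sweeps = 1000)
  preds_t <- classify_loocv(fm, tight)
  set.seed(1)
  perm <- sample(nrow(fm$X))
  fm_perm <- make_features(fm$X[perm, ], fm$labels[perm], fm$subject_ids[perm])
  preds_p <- classify_loocv(fm_perm, tight)
  a <- dplyr::arrange(preds_t[c("subject_id", "truth", "prob")],
                      subject_id, truth)
  b <- dplyr::arrange(preds_p[c("subject_id", "truth", "prob")],
                      subject_id, truth)
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("LOOCV separates a strongly separable synthetic cohort perfectly", {
  spec <- tiny_spec(n_subjects = 4, seed = 2, effect_scale = 500,
                    scan_noise_sd = 0.5)
  cohort <- simulate_cohort(spec)
  mask <- ellipsoid_mask(spec$grid_shape)
  prep <- preprocess_cohort(cohort, mask)
  smp <- assemble_samples(prep, "pre_vs_post")
  fm <- build_feature_matrix(smp$records, mask, smp$label_map)
  cs <- confusion_stats(classify_loocv(fm, gpc_control()))
  expect_equal(cs$balanced_accuracy, 1)
})

test_that("a training partition missing a class names the offending subject", {
  X <- matrix(rnorm(12), 6, 2)
  # subject sA holds every positive sample
  fm <- make_features(X, c(1, 1, -1, -1, -1, -1),
                      c("sA", "sA", "sB", "sB", "sC", "sC"))
  expect_error(classify_loocv(fm, frozen()), "sA")
})

test_that("confusion statistics reproduce the published accuracy identities", {
  mk <- function(n_pos, pos_correct, n_neg, neg_correct) {
    tibble::tibble(
      truth = c(rep(1, n_pos), rep(-1, n_neg)),
      prob = c(rep(0.9, pos_correct), rep(0.1, n_pos - pos_correct),
               rep(0.1, neg_correct), rep(0.9, n_neg - neg_correct))
    )
  }
  # 19/20 postsurgical and 15/20 comparison scans correct
  cs <- confusion_stats(mk(20, 19, 20, 15))
  expect_equal(cs$sensitivity, 0.95)
  expect_equal(cs$specificity, 0.75)
  expect_equal(cs$balanced_accuracy, 0.85)
  # 15/20 and 13/20 correct
  cs2 <- confusion_stats(mk(20, 15, 20, 13))
  expect_equal(cs2$sensitivity, 0.75)
  expect_equal(cs2$specificity, 0.65)
  expect_equal(cs2$balanced_accuracy, 0.70)
  # perfect classifier
  cs3 <- confusion_stats(mk(5, 5, 5, 5))
  expect_equal(unlist(cs3[1:3], use.names = FALSE), c(1, 1, 1))
  # a sample exactly at the threshold is misclassified for either class
  tie <- tibble::tibble(truth = c(1, -1), prob = c(0.5, 0.5))
  cst <- confusion_stats(tie)
  expect_equal(cst$balanced_accuracy, 0)
  expect_error(confusion_stats(tibble::tibble(truth = 1, prob = 0.9)), "absent")
})

test_that("balanced accuracy is always the mean of sensitivity and specificity", {
  set.seed(14)
  for (i in 1:20) {
    preds <- tibble::tibble(
      truth = sample(c(-1, 1), 30, replace = TRUE),
      prob = runif(30)
    )
    if (length(unique(preds$truth)) < 2) next
    cs <- confusion_stats(preds)
    expect_equal(cs$balanced_accuracy, (cs$sensitivity + cs$specificity) / 2)
  }
})

test_that("ROC/AUC: perfect ordering, anti-ordering, and the pair-counting oracle", {
  perfect <- tibble::tibble(truth = c(1, 1, -1, -1), prob = c(0.9, 0.8, 0.3, 0.1))
  expect_equal(roc_auc(perfect)$auc, 1)
  reversed <- tibble::tibble(truth = c(-1, -1, 1, 1), prob = c(0.9, 0.8, 0.3, 0.1))
  expect_equal(roc_auc(reversed)$auc, 0)
  mixed <- tibble::tibble(
    truth = c(1, 1, -1, 1, -1, -1),
    prob = c(0.9, 0.7, 0.7, 0.4, 0.3, 0.2) # includes a cross-class tie
  )
  pos <- mixed$prob[mixed$truth == 1]
  neg <- mixed$prob[mixed$truth == -1]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  expect_equal(roc_auc(mixed)$auc, conc / (length(pos) * length(neg)))
  expect_error(roc_auc(tibble::tibble(truth = c(1, 1), prob = c(0.2, 0.4))),
               "both classes")
})

test_that("permutation p is exactly 1 when the observed accuracy cannot beat the null", {
  # each subject's samples are orthogonal to every other subject's; with zero
  # kernel bias every held-out prediction is exactly 1/2, hence (by the strict
  # threshold rule) misclassified: observed and all null accuracies are 0
  n_sub <- 4
  X <- matrix(0, 2 * n_sub, n_sub)
  labels <- rep(c(1, -1), n_sub)
  for (k in seq_len(n_sub)) {
    X[2 * k - 1, k] <- 1
    X[2 * k, k] <- -1
  }
  fm <- make_features(X, labels, rep(sprintf("s%d", 1:n_sub), each = 2))
  cfg <- gpc_control(optimize = FALSE, hyperparams = gp_hyperparams(0, -745))
  pt <- permutation_test(fm, cfg, n_perm = 20, seed = 99)
  expect_equal(pt$observed, 0)
  expect_true(all(pt$null == 0))
  expect_equal(pt$p_value, 1)
})

test_that("a separable cohort attains the smallest attainable p of 1/(n_perm + 1)", {
  fm <- separable_features(16, p = 4, signal = 4, noise_sd = 0.2, seed = 7)
  pt <- permutation_test(fm, frozen(), n_perm = 1000, seed = 42)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p_value, 1 / 1001)
  # internal consistency of the plus-one estimator
  expect_equal(pt$p_value, (1 + sum(pt$null >= pt$observed)) / (1 + pt$n_perm))
})

test_that("null permutation distributions from independent batches agree", {
  fm <- separable_features(8, p = 5, signal = 0, noise_sd = 1, seed = 11)
  a <- permutation_test(fm, frozen(), n_perm = 60, seed = 1)$null
  b <- permutation_test(fm, frozen(), n_perm = 60, seed = 2)$null
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("frozen-hyperparameter mode optimizes once and stays comparable", {
  fm <- separable_features(6, p = 4, signal = 2, noise_sd = 0.5, seed = 5)
  cfg <- gpc_control(optimize = TRUE, reoptimize_permutations = FALSE)
  pt <- permutation_test(fm, cfg, n_perm = 10, seed = 3)
  expect_true(is.finite(pt$p_value))
  expect_equal(length(pt$null), 10)
})

test_that("Holm step-down matches the hand-evaluated formula and p.adjust", {
  expect_equal(holm_stepdown(0.2), 0.2)
  expect_equal(holm_stepdown(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(1:8, 1))
    adj <- holm_stepdown(p)
    expect_equal(adj, stats::p.adjust(p, method = "holm"), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone in sorted order
  }
  expect_error(holm_stepdown(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("scan-reduction curve is complete, ordered, and exact at full scan count", {
  spec <- tiny_spec(n_subjects = 4, seed = 13, effect_scale = 3)
  cohort <- simulate_cohort(spec)
  mask <- ellipsoid_mask(spec$grid_shape)
  curve <- scan_reduction_curve(cohort, mask, frozen(), side = "left",
                                max_scans = 2, n_perm = 0)
  expect_equal(nrow(curve), 2)
  expect_equal(curve$n_scans, 1:2)
  # the full-scan entry reproduces the all-scans averaged analysis exactly
  prep <- preprocess_cohort(cohort, mask)
  smp <- assemble_samples(prep, "followup_vs_post", side = "left")
  fm <- build_feature_matrix(smp$records, mask, smp$label_map)
  direct <- confusion_stats(classify_loocv(fm, frozen()))
  expect_equal(curve$balanced_accuracy[2], direct$balanced_accuracy)
  expect_equal(curve$auc[2], roc_auc(classify_loocv(fm, frozen()))$auc)
  expect_error(
    scan_reduction_curve(cohort, mask, frozen(), max_scans = 3),
    "only 2 scans"
  )
})

test_that("Holm correction spans both sides of one scan-reduction run", {
  spec <- tiny_spec(n_subjects = 4, seed = 17, effect_scale = 3)
  cohort <- simulate_cohort(spec)
  mask <- ellipsoid_mask(spec$grid_shape)
  curve <- scan_reduction_curve(cohort, mask, frozen(),
                                side = c("left", "right"), max_scans = 2,
                                n_perm = 9, seed = 5)
  expect_equal(nrow(curve), 4) # 2 sides x 2 scan counts
  expect_equal(curve$p_holm, holm_stepdown(curve$p_value))
})

test_that("sample assembly realizes the three comparisons", {
  spec <- tiny_spec(n_subjects = 3, seed = 19)
  prep <- preprocess_cohort(simulate_cohort(spec), ellipsoid_mask(spec$grid_shape))
  a <- assemble_samples(prep, "pre_vs_post")
  expect_equal(nrow(a$records), 6) # one pre + one post average per subject
  a2 <- assemble_samples(prep, "pre_vs_post", samples = "per_scan")
  expect_equal(nrow(a2$records), 12) # each session image its own sample
  b <- assemble_samples(prep, "left_vs_right")
  expect_equal(nrow(b$records), 6)
  expect_setequal(unname(b$label_map[b$records$condition]), c(1, -1))
  c3 <- assemble_samples(prep, "followup_vs_post", side = "right")
  expect_equal(nrow(c3$records), 6) # follow-up + right post per subject
  expect_error(assemble_samples(prep, "followup_vs_post"), "side")
})
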