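test_that("rank-based AUC matches hand values and brute-force pair
           enumeration, with ties contributing 1/2", {
  expect_equal(auc(c(0.1, 0.2, 0.9, 0.8), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # scores (0.9, 0.8, 0.4), labels (+,-,+): 1 concordant, 1 discordant pair
  expect_equal(auc(c(0.9, 0.8, 0.4), c(TRUE, FALSE, TRUE)), 0.5)
  expect_error(auc(c(1, 2), c(TRUE, TRUE)), "both classes")
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(pos)) < 2) pos[1:2] <- c(TRUE, FALSE)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc(scores, pos), brute_auc(scores, pos))
  }
})

test_that("cross-validation plans partition labeled profiles and keep each
           compound's groups in a single outer fold", {
  sim <- small_sim()
  pr <- compute_group_profiles(sim$dataset, 14)
  y <- task_labels(pr$info$class_label, "C_vs_NC")
  plan <- make_cv_plan(pr$info, y, seed = 2)
  expect_true(all(is.na(plan$outer_assign) == is.na(y)))
  expect_setequal(unique(stats::na.omit(plan$outer_assign)), 1:3)
  for (cmp in unique(pr$info$compound[!is.na(y)])) {
    folds <- plan$outer_assign[pr$info$compound == cmp]
    expect_length(unique(folds), 1)
  }
  plan_g <- make_cv_plan(pr$info, y, grouping = "by_group", seed = 2)
  expect_setequal(which(!is.na(plan_g$outer_assign)), which(!is.na(y)))
  tiny <- pr$info[1:5, ]
  expect_error(make_cv_plan(tiny, factor(c("a", "a", "a", "a", "b"))),
               "stratify")
})

test_that("fixed signatures are evaluated without Stage 1: planted features
           predict, noise features do not, unknown ids are dropped", {
  sim <- small_sim()
  pr <- compute_group_profiles(sim$dataset, 14)
  y <- task_labels(pr$info$class_label, "C_vs_NC")
  oracle <- relevant_planted(sim$truth, "C_vs_NC")
  rep_o <- evaluate_fixed_signature(pr, y, oracle,
                                    classifiers = "WEIGHTED_VOTING", seed = 3)
  expect_gte(mean(rep_o$mean_auc), 0.9)
  expect_true(all(vapply(seq_len(nrow(pr$fold_changes)), function(i)
    sum(rep_o$predictions$group_id == pr$info$group_id[i]) <= 1,
    logical(1))))  # every profile in exactly one outer test fold
  all_planted <- c(sim$truth$shared, sim$truth$gc, sim$truth$ngc)
  noise <- setdiff(colnames(pr$fold_changes), all_planted)[1:20]
  rep_n <- evaluate_fixed_signature(pr, y, noise,
                                    classifiers = "WEIGHTED_VOTING", seed = 3)
  expect_lt(abs(mean(rep_n$mean_auc) - 0.5), 0.35)
  expect_warning(
    evaluate_fixed_signature(pr, y, c(oracle, "not_a_probeset"),
                             classifiers = "WEIGHTED_VOTING", seed = 3),
    "dropped")
  expect_error(nested_cv(pr, y, signature = c("zz1", "zz2")),
               "no signature probeset")
})

test_that("signature overlap counts pairwise intersections", {
  ov <- signature_overlap(list(a = c("x", "y", "z"), b = c("y", "z", "w"),
                               c = c("q", "r", "s")))
  expect_identical(ov["a", "a"], 3L)
  expect_identical(ov["a", "b"], 2L)
  expect_identical(ov["a", "c"], 0L)
  expect_identical(ov, t(ov))
})

test_that("undefined compounds are called by majority vote with an explicit
           ambiguous outcome on ties", {
  sim <- small_sim()
  pr <- compute_group_profiles(sim$dataset, 14)
  y <- task_labels(pr$info$class_label, "GC_vs_NGC")
  sig <- relevant_planted(sim$truth, "GC_vs_NGC")
  cu <- classify_undefined(pr, y, sig,
                           classifiers = c("SVM", "WEIGHTED_VOTING", "KNN"),
                           seed = 5)
  expect_setequal(cu$calls$compound, names(sim$truth$undef_regime))
  for (cmp in cu$calls$compound)
    expect_identical(cu$calls$call[cu$calls$compound == cmp],
                     unname(sim$truth$undef_regime[cmp]))
  # undefined profiles never enter training: predictions only for UNDEF
  expect_setequal(unique(cu$predictions$compound),
                  names(sim$truth$undef_regime))
  # tie policy
  expect_identical(toxsig:::majority_call(c("GC", "NGC"), c("NGC", "GC")),
                   "ambiguous")
  expect_identical(toxsig:::majority_call(c(NA, NA), c("NGC", "GC")),
                   "ambiguous")
  expect_identical(toxsig:::majority_call(c("GC", "GC", "NGC"),
                                          c("NGC", "GC")), "GC")
})

test_that("PCA projection returns two coordinates per group, separates the
           planted classes, and is stable under feature reordering", {
  sim <- small_sim()
  pr <- compute_group_profiles(sim$dataset, 14)
  sig <- c(sim$truth$shared, sim$truth$gc, sim$truth$ngc)
  proj <- pca_project_groups(pr, sig)
  expect_identical(nrow(proj), nrow(pr$fold_changes))
  expect_true(all(c("PC1", "PC2", "group_id", "class_label") %in% names(proj)))
  lab <- task_labels(proj$class_label, "C_vs_NC")
  keep <- !is.na(lab)
  expect_gt(auc(abs(proj$PC1[keep] - mean(proj$PC1[keep][lab[keep] == "NC"])),
                lab[keep]), 0.9)
  perm <- sample(length(sig))
  proj_p <- pca_project_groups(pr, sig[perm])
  expect_equal(abs(proj_p$PC1), abs(proj$PC1), tolerance = 1e-8)
  expect_error(pca_project_groups(pr, sig[1]), ">= 2")
})

test_that("outer-fold signatures are independent of that fold's test
           profiles (no leakage)", {
  sim <- small_sim()
  pr <- compute_group_profiles(sim$dataset, 14)
  y <- task_labels(pr$info$class_label, "C_vs_NC")
  s1_args <- list(n_bootstraps = 5, consensus_size = 10,
                  evaluate_performance = FALSE, methods = "GOLUB")
  rep <- suppressMessages(nested_cv(pr, y, classifiers = "WEIGHTED_VOTING",
                                    stage1_args = s1_args, seed = 9))
  for (f in 1:3) {
    tr <- which(rep$plan$outer_assign != f & !is.na(y))
    redo <- suppressMessages(do.call(run_stage1, c(list(
      profiles = subset_profiles(pr, tr), y = droplevels(y[tr]),
      seed = 9 + f), s1_args)))
    expect_identical(redo$signature$probeset_ids,
                     rep$signatures[[f]]$probeset_ids)
  }
})
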