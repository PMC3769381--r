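#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive profile
#' scores higher than a random negative one, with ties contributing 1/2.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels two-level factor (second level positive) or logical vector.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2)
      stop("AUC undefined: need both classes present")
    pos <- labels == levels(labels)[2]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: need both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deal shuffled units into n_folds round-robin, per class, so folds stay
# class-balanced; returns integer fold per unit
stratified_fold_assign <- function(unit_class, n_folds) {
  fold <- integer(length(unit_class))
  offset <- 0
  for (cl in levels(droplevels(as.factor(unit_class)))) {
    idx <- which(unit_class == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1 + offset) %% n_folds) + 1
    offset <- offset + length(idx)
  }
  fold
}

#' Build a stratified (nested) cross-validation plan
#'
#' Assigns every labeled profile to one of `outer_folds` test folds,
#' stratified by class. With `grouping = "by_compound"` (the default) all
#' treatment groups of one compound -- both sexes and all dose groups -- are
#' placed in the same outer fold, so no compound can appear on both sides of
#' a split.
#'
#' @param info per-profile metadata data.frame with columns `group_id` and
#'   `compound` (e.g. `profiles$info`).
#' @param y two-level factor; profiles with NA are left out of all folds.
#' @param outer_folds,inner_folds fold counts (defaults 3 and 3).
#' @param grouping "by_compound" or "by_group".
#' @param seed integer seed.
#' @return object of class `CVPlan` with `outer_assign` (fold per profile,
#'   NA for unlabeled profiles).
#' @export
make_cv_plan <- function(info, y, outer_folds = 3, inner_folds = 3,
                         grouping = c("by_compound", "by_group"), seed = 1L) {
  grouping <- match.arg(grouping)
  y <- factor(y)
  lab <- which(!is.na(y))
  if (any(table(droplevels(y[lab])) < outer_folds))
    stop("a class has fewer profiles than outer folds; cannot stratify")
  set.seed(seed)
  outer_assign <- rep(NA_integer_, length(y))
  if (grouping == "by_compound") {
    comp <- info$compound[lab]
    units <- unique(comp)
    unit_class <- vapply(units, function(u)
      as.character(y[lab][comp == u][1]), character(1))
    f <- stratified_fold_assign(unit_class, outer_folds)
    outer_assign[lab] <- f[match(comp, units)]
  } else {
    outer_assign[lab] <- stratified_fold_assign(as.character(y[lab]),
                                                outer_folds)
  }
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 grouping = grouping, seed = seed,
                 outer_assign = outer_assign),
            class = "CVPlan")
}

# expand a classifier's tuning grid into a list of params lists; grids sorted
# ascending so that the first maximum = smallest (most regularized) value
expand_grid_params <- function(kind, grids, X, y) {
  g <- grids[[kind]]
  switch(kind,
    SVM = lapply(sort(g$cost), function(cc) list(cost = cc)),
    KNN = lapply(sort(g$k), function(k) list(k = k)),
    PAM = lapply(pam_delta_grid(X, y, g$n_delta %||% 10),
                 function(d) list(delta = d)),
    RANDOM_FOREST = {
      P <- ncol(X)
      mtry <- sort(unique(pmax(1, c(floor(sqrt(P)), floor(P / 3)))))
      lapply(mtry, function(m) list(mtry = m))
    },
    list(list()))
}

# inner-CV grid search; returns the params list with the best mean inner AUC
tune_classifier <- function(kind, X, y, info, grids, inner_folds, grouping,
                            seed) {
  cand <- expand_grid_params(kind, grids, X, y)
  if (length(cand) == 1) return(cand[[1]])
  inner <- make_cv_plan(info, y, outer_folds = inner_folds,
                        inner_folds = inner_folds, grouping = grouping,
                        seed = seed)
  score <- vapply(cand, function(par) {
    aucs <- c()
    for (f in seq_len(inner_folds)) {
      tr <- which(inner$outer_assign != f)
      te <- which(inner$outer_assign == f)
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) next
      m <- train_classifier(kind, X[tr, , drop = FALSE], y[tr], par,
                            seed = seed)
      aucs <- c(aucs, auc(predict_confidence(m, X[te, , drop = FALSE]),
                          y[te]))
    }
    if (length(aucs)) mean(aucs) else NA_real_
  }, numeric(1))
  if (all(is.na(score))) return(cand[[1]])
  cand[[which.max(round(score, 12))]]
}

#' Nested cross-validated evaluation of signatures and classifiers
#'
#' Outer folds provide independent test sets; within each outer-training set
#' the signature is derived (running the full Stage-1 pipeline when
#' `signature = NULL`, so no test information leaks into feature selection)
#' or a fixed probeset list is applied, features are z-scored with
#' training-set statistics, classifier hyperparameters are tuned by inner
#' cross-validated AUC (ties resolve to the smaller, more regularized
#' value), and out-of-fold confidences are produced.
#'
#' @param profiles a `GroupProfiles` object.
#' @param y two-level factor over profiles (NA = excluded).
#' @param signature NULL to run Stage 1 per outer fold, or a character
#'   vector of probeset ids (probesets absent from the data are dropped with
#'   a warning; zero overlap is an error).
#' @param classifiers classifier kinds to evaluate.
#' @param plan optional [CVPlan][make_cv_plan]; built with defaults
#'   otherwise.
#' @param stage1_args list of arguments passed to [run_stage1()].
#' @param grids hyperparameter grids, see [default_grids()].
#' @param seed integer seed.
#' @return object of class `EvaluationReport`: `predictions` (one row per
#'   group x classifier), `fold_auc`, `mean_auc` (named by classifier),
#'   `signatures` (per outer fold).
#' @export
nested_cv <- function(profiles, y, signature = NULL,
                      classifiers = CLASSIFIER_KINDS, plan = NULL,
                      stage1_args = list(), grids = default_grids(),
                      seed = 1L) {
  classifiers <- match.arg(classifiers, CLASSIFIER_KINDS, several.ok = TRUE)
  X <- as_fc_matrix(profiles)
  info <- profiles$info
  y <- factor(y)
  if (any(table(droplevels(y[!is.na(y)])) < 3))
    stop("need >= 3 profiles per class for nested 3x3 cross-validation")
  if (is.null(plan)) plan <- make_cv_plan(info, y, seed = seed)
  fixed <- !is.null(signature)
  if (fixed) {
    known <- intersect(signature, colnames(X))
    if (!length(known)) stop("no signature probeset is present in the dataset")
    if (length(known) < length(signature))
      warning(length(signature) - length(known),
              " signature probeset(s) absent from the dataset were dropped")
  }
  preds <- NULL
  fold_sig <- vector("list", plan$outer_folds)
  for (f in seq_len(plan$outer_folds)) {
    tr <- which(plan$outer_assign != f & !is.na(y))
    te <- which(plan$outer_assign == f)
    if (fixed) {
      feats <- known
    } else {
      s1 <- do.call(run_stage1, c(list(
        profiles = subset_profiles(profiles, tr), y = droplevels(y[tr]),
        seed = seed + f), stage1_args))
      feats <- s1$signature$probeset_ids
      fold_sig[[f]] <- s1$signature
    }
    if (fixed) fold_sig[[f]] <- feats
    z <- suppressWarnings(zscore_fit_apply(X[tr, , drop = FALSE],
                                           X[te, , drop = FALSE],
                                           features = feats))
    ytr <- droplevels(y[tr])
    for (kind in classifiers) {
      par <- tune_classifier(kind, z$train, ytr,
                             info[tr, , drop = FALSE], grids,
                             plan$inner_folds, plan$grouping,
                             seed = seed + 100 * f)
      m <- train_classifier(kind, z$train, ytr, par, seed = seed + f)
      conf <- predict_confidence(m, z$test)
      preds <- rbind(preds, data.frame(
        group_id = info$group_id[te], classifier = kind, fold = f,
        confidence = conf,
        predicted = ifelse(conf >= 0.5, levels(y)[2], levels(y)[1]),
        truth = as.character(y[te]), stringsAsFactors = FALSE))
    }
  }
  fold_auc <- do.call(rbind, lapply(classifiers, function(kind) {
    do.call(rbind, lapply(seq_len(plan$outer_folds), function(f) {
      p <- preds[preds$classifier == kind & preds$fold == f &
                   !is.na(preds$truth), , drop = FALSE]
      a <- if (length(unique(p$truth)) < 2) NA_real_
           else auc(p$confidence, factor(p$truth, levels = levels(y)))
      data.frame(classifier = kind, fold = f, auc = a)
    }))
  }))
  mean_auc <- vapply(classifiers, function(kind)
    mean(fold_auc$auc[fold_auc$classifier == kind], na.rm = TRUE),
    numeric(1))
  structure(list(predictions = preds, fold_auc = fold_auc,
                 mean_auc = mean_auc, signatures = fold_sig, plan = plan,
                 levels = levels(y)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport:", length(unique(x$predictions$group_id)),
      "groups,", x$plan$outer_folds, "outer folds\n")
  print(round(x$mean_auc, 3))
  invisible(x)
}

#' Evaluate an externally supplied (fixed) signature
#'
#' Skips Stage 1 and runs the nested cross-validated Stage-2 evaluation with
#' the supplied probeset list as features, e.g. to benchmark published
#' signatures against newly derived ones.
#'
#' @inheritParams nested_cv
#' @param signature character vector of probeset ids.
#' @return an [EvaluationReport][nested_cv].
#' @export
evaluate_fixed_signature <- function(profiles, y, signature,
                                     classifiers = CLASSIFIER_KINDS,
                                     plan = NULL, grids = default_grids(),
                                     seed = 1L) {
  nested_cv(profiles, y, signature = signature, classifiers = classifiers,
            plan = plan, grids = grids, seed = seed)
}

#' Pairwise overlap of signatures
#'
#' @param signatures named list of >= 2 probeset-id vectors.
#' @return symmetric integer matrix of pairwise intersection sizes (diagonal
#'   = signature sizes).
#' @export
signature_overlap <- function(signatures) {
  n <- length(signatures)
  if (is.null(names(signatures)))
    names(signatures) <- paste0("sig", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(names(signatures), names(signatures)))
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- length(intersect(unique(signatures[[i]]),
                                unique(signatures[[j]])))
  m
}

#' Classify compounds of undefined carcinogenicity class
#'
#' Trains every classifier on the profiles with defined task labels
#' (undefined compounds never enter training), scores each undefined
#' treatment group, and calls a class per compound by majority vote across
#' classifiers and that compound's groups. Confidences of exactly 0.5 count
#' as abstentions; a tied or empty vote yields the call "ambiguous".
#'
#' @param profiles a `GroupProfiles` object containing both defined and
#'   undefined groups.
#' @param y two-level factor over profiles; NA marks the undefined groups to
#'   classify.
#' @param signature character vector of probeset ids to use as features.
#' @param classifiers classifier kinds.
#' @param grids hyperparameter grids (tuned by inner CV on the training
#'   profiles).
#' @param seed integer seed.
#' @return list with `predictions` (per group x classifier) and `calls`
#'   (per-compound majority call).
#' @export
classify_undefined <- function(profiles, y, signature,
                               classifiers = CLASSIFIER_KINDS,
                               grids = default_grids(), seed = 1L) {
  X <- as_fc_matrix(profiles)
  info <- profiles$info
  y <- factor(y)
  tr <- which(!is.na(y))
  te <- if (!is.null(info$class_label)) which(info$class_label == "UNDEF")
        else which(is.na(y))
  if (!length(te)) stop("no undefined profiles to classify")
  feats <- intersect(signature, colnames(X))
  if (!length(feats)) stop("no signature probeset is present in the dataset")
  z <- suppressWarnings(zscore_fit_apply(X[tr, , drop = FALSE],
                                         X[te, , drop = FALSE],
                                         features = feats))
  ytr <- droplevels(y[tr])
  preds <- NULL
  for (kind in classifiers) {
    par <- tune_classifier(kind, z$train, ytr, info[tr, , drop = FALSE],
                           grids, 3, "by_compound", seed = seed)
    m <- train_classifier(kind, z$train, ytr, par, seed = seed)
    conf <- predict_confidence(m, z$test)
    preds <- rbind(preds, data.frame(
      group_id = info$group_id[te], compound = info$compound[te],
      classifier = kind, confidence = conf,
      vote = ifelse(conf > 0.5, levels(ytr)[2],
                    ifelse(conf < 0.5, levels(ytr)[1], NA_character_)),
      stringsAsFactors = FALSE))
  }
  calls <- do.call(rbind, lapply(unique(preds$compound), function(cmp) {
    v <- preds$vote[preds$compound == cmp]
    data.frame(compound = cmp, call = majority_call(v, levels(ytr)),
               n_votes = sum(!is.na(v)), stringsAsFactors = FALSE)
  }))
  list(predictions = preds, calls = calls)
}

# majority vote over per-classifier/per-group calls; NA = abstention; an
# empty or tied vote is reported as "ambiguous", never silently resolved
majority_call <- function(votes, levels) {
  v <- votes[!is.na(votes)]
  if (!length(v)) return("ambiguous")
  tab <- table(factor(v, levels = levels))
  if (tab[1] == tab[2]) "ambiguous" else names(tab)[which.max(tab)]
}

#' Project treatment-group profiles onto two principal components
#'
#' Restricts the fold-change matrix to the signature probesets, column
#' centers, and returns each group's coordinates on the first two principal
#' axes together with its metadata (for convex-hull / scatter displays of
#' class separation).
#'
#' @param profiles a `GroupProfiles` object (>= 3 groups).
#' @param signature character vector of >= 2 probeset ids.
#' @return data.frame with group metadata, `PC1`, `PC2`; fraction of
#'   variance explained in attribute `"var_explained"`.
#' @export
pca_project_groups <- function(profiles, signature) {
  X <- as_fc_matrix(profiles)
  feats <- intersect(signature, colnames(X))
  if (length(feats) < 2) stop("signature must contain >= 2 probesets present in the data")
  if (nrow(X) < 3) stop("need >= 3 profiles")
  pc <- stats::prcomp(X[, feats, drop = FALSE], center = TRUE, scale. = FALSE)
  out <- cbind(profiles$info,
               PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  rownames(out) <- NULL
  attr(out, "var_explained") <-
    (pc$sdev[1:2]^2) / sum(pc$sdev^2)
  out
}
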