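DEFAULT_SIZE_GRID <- c(2, 5, 10, 15, 20, 30, 40, 60, 80, 100)
DEFAULT_METHODS <- c("GOLUB", "SVM", "SVM_RFE", "PAM")

#' Draw a class-stratified bootstrap (subsampling) plan
#'
#' Each "bootstrap" is a subsample drawn without replacement containing
#' `in_bag_fraction` of the training profiles, stratified by class so that
#' in-bag class proportions stay within one member of the global proportions;
#' the complementary profiles form the out-of-bag set used for ROC
#' evaluation.
#'
#' @param y two-level factor of training labels (one per profile).
#' @param n_bootstraps number of subsamples (default 25).
#' @param in_bag_fraction fraction of profiles in each in-bag set
#'   (default 0.90).
#' @param seed integer seed; plans are reproducible for a fixed seed.
#' @return object of class `BootstrapPlan` with `in_bag` / `out_of_bag`
#'   index lists.
#' @export
draw_bootstraps <- function(y, n_bootstraps = 25, in_bag_fraction = 0.9,
                            seed = 1L) {
  if (length(y) < 10) stop("need >= 10 training profiles, got ", length(y))
  y <- check_binary(y, min_per_class = 2)
  n <- length(y)
  target <- round(in_bag_fraction * n)
  classes <- levels(y)
  nk <- as.numeric(table(y)[classes])
  base <- floor(in_bag_fraction * nk)
  rem <- target - sum(base)
  if (rem > 0) {
    frac <- in_bag_fraction * nk - base
    # distribute the remainder by largest fractional part, preferring
    # classes that still keep an out-of-bag member
    add <- order(-(base + 1 < nk), -frac, seq_along(frac))[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  set.seed(seed)
  in_bag <- vector("list", n_bootstraps)
  for (b in seq_len(n_bootstraps)) {
    idx <- unlist(lapply(seq_along(classes), function(k) {
      pool <- which(y == classes[k])
      sort(sample(pool, base[k]))
    }))
    in_bag[[b]] <- sort(idx)
  }
  oob <- lapply(in_bag, function(i) setdiff(seq_len(n), i))
  one_class <- vapply(oob, function(i) length(unique(y[i])) < 2, logical(1))
  if (any(one_class))
    message(sum(one_class), " bootstrap(s) have a single-class out-of-bag set")
  structure(list(n_bootstraps = n_bootstraps,
                 in_bag_fraction = in_bag_fraction, seed = seed,
                 in_bag = in_bag, out_of_bag = oob, y = y),
            class = "BootstrapPlan")
}

#' Kuncheva stability index of two equal-size feature subsets
#'
#' Chance-corrected set similarity KI = (r*P - k^2) / (k*(P - k)) for two
#' subsets of size k with intersection size r drawn from P features. KI is 1
#' for identical subsets, has expectation 0 for independently drawn subsets,
#' and reaches -1 for disjoint subsets that each contain half of the
#' features.
#'
#' @param A,B feature subsets (vectors of ids or indices) with |A| = |B| = k,
#'   0 < k < P.
#' @param P total number of features.
#' @return KI in [-1, 1].
#' @export
kuncheva_index <- function(A, B, P) {
  A <- unique(A); B <- unique(B)
  k <- length(A)
  if (length(B) != k) stop("subsets must have equal size (got ",
                           k, " and ", length(B), ")")
  if (k == 0 || k >= P) stop("subset size must satisfy 0 < k < P")
  r <- length(intersect(A, B))
  (r * P - k^2) / (k * (P - k))
}

#' Mean pairwise Kuncheva index of several subsets
#'
#' Generalizes the pairwise index to B subsets by averaging KI over all
#' unordered pairs.
#'
#' @param subsets list of >= 2 equal-size feature subsets.
#' @param P total number of features.
#' @return mean KI.
#' @export
mean_kuncheva <- function(subsets, P) {
  if (length(subsets) < 2) stop("need >= 2 subsets")
  sizes <- vapply(subsets, function(s) length(unique(s)), integer(1))
  if (length(unique(sizes)) != 1)
    stop("all subsets must have the same size (got ",
         paste(unique(sizes), collapse = ", "), ")")
  pairs <- utils::combn(length(subsets), 2)
  mean(apply(pairs, 2, function(p)
    kuncheva_index(subsets[[p[1]]], subsets[[p[2]]], P)))
}

# the out-of-bag decision rule paired with each selector
paired_classifier <- function(method) {
  switch(method,
    SVM = "SVM", SVM_RFE = "SVM", PAM = "PAM",
    GOLUB = "WEIGHTED_VOTING", PCA = "WEIGHTED_VOTING",
    PLSDA = "WEIGHTED_VOTING")
}

# one full-feature ranking per bootstrap (features z-scored on in-bag data)
bootstrap_rankings <- function(X, y, plan, method, cost = 1, delta = 0) {
  lapply(seq_len(plan$n_bootstraps), function(b) {
    ib <- plan$in_bag[[b]]
    z <- zscore_quiet(X[ib, , drop = FALSE])
    rank_features(method, z, y[ib], cost = cost, delta = delta)
  })
}

zscore_quiet <- function(X) suppressWarnings(zscore_fit_apply(X)$train)

#' Out-of-bag ROC across signature sizes for one selector
#'
#' For every bootstrap and candidate signature size: rank features on the
#' in-bag profiles, keep the top `size`, train the selector's paired decision
#' rule (linear SVM for SVM/SVM-RFE, shrunken centroids for PAM, weighted
#' voting otherwise) on the in-bag profiles, score the out-of-bag profiles,
#' and compute the rank-based AUC. Bootstraps whose out-of-bag set contains a
#' single class are excluded from the mean.
#'
#' @param X numeric fold-change matrix, profiles x features (not yet
#'   standardized; standardization is fit per bootstrap).
#' @param y two-level factor, second level positive.
#' @param plan a [BootstrapPlan][draw_bootstraps].
#' @param method selector name.
#' @param sizes candidate signature sizes (default 10 values spanning
#'   2..100).
#' @param rankings optional precomputed per-bootstrap rankings.
#' @param cost,delta selector/classifier hyperparameters.
#' @return object of class `SizePerformanceCurve`: `sizes`, `mean_roc`,
#'   `n_valid` (bootstraps contributing per size), `optimum_size` (NULL until
#'   [spline_optimum()] is applied).
#' @export
evaluate_oob <- function(X, y, plan, method, sizes = DEFAULT_SIZE_GRID,
                         rankings = NULL, cost = 1, delta = 0) {
  sizes <- sort(unique(pmin(sizes, ncol(X))))
  if (any(sizes < 2)) stop("signature sizes must be >= 2")
  if (is.null(rankings))
    rankings <- bootstrap_rankings(X, y, plan, method, cost, delta)
  kind <- paired_classifier(method)
  auc_mat <- matrix(NA_real_, plan$n_bootstraps, length(sizes))
  for (b in seq_len(plan$n_bootstraps)) {
    ib <- plan$in_bag[[b]]; ob <- plan$out_of_bag[[b]]
    if (length(unique(y[ob])) < 2) next
    z <- suppressWarnings(
      zscore_fit_apply(X[ib, , drop = FALSE], X[ob, , drop = FALSE]))
    for (s in seq_along(sizes)) {
      feats <- top_features(rankings[[b]], sizes[s])
      m <- train_classifier(kind, z$train[, feats, drop = FALSE], y[ib],
                            params = list(cost = cost, delta = delta),
                            seed = plan$seed + b)
      conf <- predict_confidence(m, z$test[, feats, drop = FALSE])
      auc_mat[b, s] <- auc(conf, y[ob])
    }
  }
  n_valid <- colSums(!is.na(auc_mat))
  structure(list(method = method, sizes = sizes,
                 mean_roc = colMeans(auc_mat, na.rm = TRUE),
                 n_valid = n_valid, optimum_size = NULL),
            class = "SizePerformanceCurve")
}

#' Spline-estimated optimal signature size
#'
#' Fits a cubic smoothing spline (smoothing chosen by generalized
#' cross-validation) to the mean ROC vs size points and returns the argmax of
#' the fitted curve over the integer grid spanning the evaluated sizes. Ties
#' (e.g. a flat curve) resolve to the smallest size; with fewer than 4 points
#' the raw argmax is used.
#'
#' @param curve a `SizePerformanceCurve` from [evaluate_oob()].
#' @return the curve with `optimum_size` filled in.
#' @export
spline_optimum <- function(curve) {
  sizes <- curve$sizes; roc <- curve$mean_roc
  ok <- is.finite(roc)
  if (!any(ok)) {
    # no bootstrap produced a defined out-of-bag AUC; fall back to the
    # smallest (most parsimonious) size
    message("no defined out-of-bag AUC for ", curve$method,
            "; optimum set to the smallest size")
    curve$optimum_size <- min(sizes)
    return(curve)
  }
  grid <- seq(min(sizes), max(sizes))
  fitted <- NULL
  if (sum(ok) >= 4) {
    fitted <- tryCatch({
      sp <- stats::smooth.spline(sizes[ok], roc[ok])
      stats::predict(sp, grid)$y
    }, error = function(e) NULL)
  }
  if (is.null(fitted)) {
    curve$optimum_size <- sizes[ok][which.max(round(roc[ok], 12))]
  } else {
    curve$optimum_size <- grid[which.max(round(fitted, 12))]
  }
  curve
}

#' Per-size signature stability across bootstraps
#'
#' For each candidate size, the mean pairwise Kuncheva index of the top-size
#' feature subsets selected on the different bootstraps.
#'
#' @param rankings list of per-bootstrap `FeatureRanking`s.
#' @param sizes candidate signature sizes.
#' @param P total feature count.
#' @return object of class `StabilityResult`: `sizes`, `per_size_KI`.
#' @export
stability_per_size <- function(rankings, sizes, P) {
  ki <- vapply(sizes, function(s) {
    mean_kuncheva(lapply(rankings, top_features, k = s), P)
  }, numeric(1))
  structure(list(method = rankings[[1]]$method, sizes = sizes,
                 per_size_KI = ki), class = "StabilityResult")
}

#' Rank-sum consensus signature
#'
#' Sums each feature's rank position over all supplied rankings (n
#' bootstraps x m methods), sorts features by ascending rank sum (ties broken
#' by feature index) and keeps the top `size`.
#'
#' @param rankings list of `FeatureRanking`s over the same feature universe.
#' @param size signature size.
#' @param task,duration_days,provenance optional metadata carried along.
#' @return object of class `ConsensusSignature` with ordered `probeset_ids`
#'   and their `rank_sums`.
#' @export
consensus_rank <- function(rankings, size, task = NA, duration_days = NA,
                           provenance = list()) {
  ids <- rankings[[1]]$feature_ids
  P <- length(ids)
  rs <- numeric(P)
  for (r in rankings) {
    if (!identical(r$feature_ids, ids))
      stop("rankings cover different feature universes")
    pos <- integer(P)
    pos[r$ranks] <- seq_len(P)
    rs <- rs + pos
  }
  ord <- order(rs, seq_len(P))
  size <- min(size, P)
  structure(list(task = task, duration_days = duration_days,
                 probeset_ids = ids[ord[seq_len(size)]],
                 rank_sums = rs[ord[seq_len(size)]],
                 size = size, provenance = provenance),
            class = "ConsensusSignature")
}

#' @export
print.ConsensusSignature <- function(x, ...) {
  cat("ConsensusSignature (", if (is.na(x$task)) "?" else x$task, ", ",
      if (is.na(x$duration_days)) "?" else x$duration_days, " d): ",
      x$size, " probesets; top: ",
      paste(utils::head(x$probeset_ids, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Stage 1: bootstrap ensemble signature extraction
#'
#' Orchestrates the full first stage on one binary task: draw a stratified
#' bootstrap plan, compute one full-feature ranking per selector and
#' bootstrap, evaluate out-of-bag ROC across the size grid, estimate each
#' selector's optimal size by spline fitting, quantify per-size stability
#' with the mean Kuncheva index, and aggregate all n x m rankings into a
#' rank-sum consensus signature. The default ensemble uses the four
#' selectors GOLUB, SVM, SVM_RFE and PAM; the reduced {SVM, SVM_RFE} and the
#' {PCA, PLSDA} loading variants are selectable via `methods`.
#'
#' @param profiles a `GroupProfiles` object or fold-change matrix
#'   (profiles x probesets).
#' @param y two-level factor (NAs, e.g. undefined compounds, are dropped).
#' @param methods character vector of selector names.
#' @param n_bootstraps,in_bag_fraction bootstrap plan parameters (defaults
#'   25 and 0.90).
#' @param size_grid candidate signature sizes (default 10 sizes in 2..100).
#' @param consensus_size signature size; NULL (default) uses the rounded
#'   median of the per-method spline optima.
#' @param evaluate_performance set FALSE to skip the out-of-bag ROC / spline
#'   step (requires an explicit `consensus_size`).
#' @param cost,delta selector hyperparameters.
#' @param seed integer seed controlling all randomness.
#' @param task,duration_days metadata recorded in the signature.
#' @return list of class `Stage1Result`: `signature`
#'   ([ConsensusSignature][consensus_rank]), `curves`, `stability`, `plan`,
#'   `rankings`.
#' @export
run_stage1 <- function(profiles, y, methods = DEFAULT_METHODS,
                       n_bootstraps = 25, in_bag_fraction = 0.9,
                       size_grid = DEFAULT_SIZE_GRID, consensus_size = NULL,
                       evaluate_performance = TRUE, cost = 1, delta = 0,
                       seed = 1L, task = NA, duration_days = NA) {
  if (!length(methods)) stop("empty method set")
  methods <- match.arg(methods, RANK_METHODS, several.ok = TRUE)
  X <- as_fc_matrix(profiles)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- droplevels(factor(y[keep]))
  if (!evaluate_performance && is.null(consensus_size))
    stop("'consensus_size' is required when performance evaluation is skipped")
  plan <- draw_bootstraps(y, n_bootstraps, in_bag_fraction, seed)
  sizes <- sort(unique(pmin(size_grid, ncol(X))))
  rankings <- lapply(methods, function(m)
    bootstrap_rankings(X, y, plan, m, cost, delta))
  names(rankings) <- methods
  curves <- stability <- NULL
  if (evaluate_performance) {
    curves <- lapply(methods, function(m)
      spline_optimum(evaluate_oob(X, y, plan, m, sizes,
                                  rankings = rankings[[m]],
                                  cost = cost, delta = delta)))
    names(curves) <- methods
  }
  stability <- lapply(methods, function(m)
    stability_per_size(rankings[[m]], sizes, ncol(X)))
  names(stability) <- methods
  if (is.null(consensus_size)) {
    optima <- vapply(curves, `[[`, numeric(1), "optimum_size")
    consensus_size <- round(stats::median(optima))
  }
  signature <- consensus_rank(unlist(rankings, recursive = FALSE),
                              consensus_size, task = task,
                              duration_days = duration_days,
                              provenance = list(methods = methods,
                                                n_bootstraps = n_bootstraps,
                                                in_bag_fraction = in_bag_fraction,
                                                seed = seed))
  structure(list(signature = signature, curves = curves,
                 stability = stability, plan = plan, rankings = rankings),
            class = "Stage1Result")
}

#' Write a consensus signature as tab-delimited text
#' @param signature a `ConsensusSignature`.
#' @param path output file path.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(
    data.frame(rank = seq_along(signature$probeset_ids),
               probeset_id = signature$probeset_ids,
               rank_sum = signature$rank_sums),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fixed signature (one probeset id per line)
#' @param path text file, one probeset id per line.
#' @return character vector of probeset ids.
#' @export
read_signature <- function(path) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) stop("duplicated probeset ids in signature file")
  ids
}
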