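RANK_METHODS <- c("GOLUB", "SVM", "SVM_RFE", "PAM", "PCA", "PLSDA")

#' Construct a feature ranking
#'
#' A total ordering of all features, best first, with a relevance score per
#' feature (higher = more informative). Ties in score are broken by feature
#' index so every ranker is deterministic.
#'
#' @param method one of GOLUB, SVM, SVM_RFE, PAM, PCA, PLSDA.
#' @param scores numeric vector of relevance scores in feature order.
#' @param feature_ids character vector of feature (probeset) ids.
#' @return object of class `FeatureRanking` with `ranks` (feature indices,
#'   best first), `scores` (feature order) and `feature_ids`.
#' @export
feature_ranking <- function(method, scores, feature_ids = names(scores)) {
  method <- match.arg(method, RANK_METHODS)
  if (is.null(feature_ids)) feature_ids <- as.character(seq_along(scores))
  stopifnot(length(scores) == length(feature_ids), all(is.finite(scores)))
  ranks <- order(-scores, seq_along(scores))
  structure(list(method = method, ranks = ranks, scores = unname(scores),
                 feature_ids = feature_ids),
            class = "FeatureRanking")
}

#' @export
print.FeatureRanking <- function(x, ...) {
  cat("FeatureRanking (", x$method, "): ", length(x$ranks), " features; top: ",
      paste(x$feature_ids[utils::head(x$ranks, 5)], collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Top features of a ranking
#' @param ranking a `FeatureRanking`.
#' @param k number of features.
#' @return character vector of the k best feature ids.
#' @export
top_features <- function(ranking, k) {
  ranking$feature_ids[ranking$ranks[seq_len(min(k, length(ranking$ranks)))]]
}

check_binary <- function(y, min_per_class = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2)
    stop("labels must contain exactly two classes (got ", nlevels(y), ")")
  if (any(table(y) < min_per_class))
    stop("each class needs >= ", min_per_class, " profiles")
  y
}

# signed signal-to-noise per feature: (mu_pos - mu_neg) / (sd_pos + sd_neg),
# second factor level taken as the positive class. Zero denominators are
# replaced by the median positive denominator (or 1), so flat features score 0
# instead of Inf.
signed_s2n <- function(X, y) {
  y <- check_binary(y, min_per_class = 2)
  pos <- X[y == levels(y)[2], , drop = FALSE]
  neg <- X[y == levels(y)[1], , drop = FALSE]
  num <- colMeans(pos) - colMeans(neg)
  den <- apply(pos, 2, stats::sd) + apply(neg, 2, stats::sd)
  zero <- den == 0
  if (any(zero)) {
    fill <- if (all(zero)) 1 else stats::median(den[!zero])
    den[zero] <- fill
    num[zero & abs(num) < .Machine$double.eps] <- 0
  }
  num / den
}

#' Golub signal-to-noise feature ranking
#'
#' Scores each feature by the absolute signal-to-noise ratio
#' |mu_pos - mu_neg| / (sd_pos + sd_neg) between the two classes and ranks by
#' descending score. The ranking is invariant to swapping the class labels.
#'
#' @param X numeric matrix, profiles x features.
#' @param y two-level factor; the second level is the positive class.
#' @return a [FeatureRanking][feature_ranking].
#' @export
golub_rank <- function(X, y) {
  feature_ranking("GOLUB", abs(signed_s2n(X, y)), colnames(X))
}

svm_weights <- function(X, y, cost = 1) {
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  # e1071 orients decision values toward the first label it encounters;
  # flip so positive weight means evidence for the positive (second) level
  if (fit$labels[1] == which(levels(y) == levels(y)[2])) w else -w
}

#' Linear SVM weight feature ranking
#'
#' Fits a soft-margin linear SVM on (typically z-scored) features and ranks
#' features by the absolute value of their weight-vector component.
#'
#' @inheritParams golub_rank
#' @param cost SVM regularization parameter C.
#' @return a [FeatureRanking][feature_ranking].
#' @export
svm_weight_rank <- function(X, y, cost = 1) {
  y <- check_binary(y)
  feature_ranking("SVM", abs(svm_weights(X, y, cost)), colnames(X))
}

#' SVM recursive feature elimination ranking
#'
#' Iteratively refits a linear SVM and eliminates the features with the
#' smallest absolute weights: half of the remaining features per iteration
#' while more than `halve_until` remain, then one at a time. The reversed
#' elimination order is the ranking (survivors outrank all eliminated
#' features); within one eliminated batch, features are ordered by their
#' weights at elimination time.
#'
#' @inheritParams svm_weight_rank
#' @param halve_until switch from halving to single elimination at this many
#'   remaining features.
#' @return a [FeatureRanking][feature_ranking].
#' @export
svm_rfe_rank <- function(X, y, cost = 1, halve_until = 10) {
  y <- check_binary(y)
  P <- ncol(X)
  if (halve_until < 1) stop("'halve_until' must be >= 1")
  surv <- seq_len(P)
  pos <- integer(P)        # rank position per feature, 1 = best
  worst <- P
  while (length(surv) > 1) {
    w <- abs(svm_weights(X[, surv, drop = FALSE], y, cost))
    n <- length(surv)
    keep_n <- if (n > halve_until) max(ceiling(n / 2), halve_until)
              else n - 1
    drop_n <- n - keep_n
    ord <- order(w, -seq_len(n))       # worst first; ties drop higher index
    dropped <- surv[ord[seq_len(drop_n)]]
    pos[dropped] <- worst:(worst - drop_n + 1)
    worst <- worst - drop_n
    surv <- setdiff(surv, dropped)
  }
  pos[surv] <- 1L
  # score decreasing in rank position so the ranking round-trips
  feature_ranking("SVM_RFE", as.numeric(P - pos + 1), colnames(X))
}

# Sizes of the surviving feature set over SVM-RFE iterations (first entry P).
rfe_schedule <- function(P, halve_until = 10) {
  sizes <- P
  n <- P
  while (n > 1) {
    n <- if (n > halve_until) max(ceiling(n / 2), halve_until) else n - 1
    sizes <- c(sizes, n)
  }
  sizes
}

# Nearest-shrunken-centroids sufficient statistics shared by the PAM ranker
# and the PAM classifier. s0 is the median of per-feature pooled SDs.
pam_stats <- function(X, y) {
  y <- check_binary(y)
  n <- nrow(X); K <- nlevels(y)
  classes <- levels(y)
  overall <- colMeans(X)
  cent <- do.call(rbind, lapply(classes, function(k)
    colMeans(X[y == k, , drop = FALSE])))
  rownames(cent) <- classes
  ss <- 0
  for (k in classes) {
    Xi <- X[y == k, , drop = FALSE]
    ss <- ss + colSums((Xi - matrix(cent[k, ], nrow(Xi), ncol(Xi),
                                    byrow = TRUE))^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  # degenerate pooled SDs (e.g. perfectly separated toy data): keep the
  # offset positive so discriminant scores stay finite
  if (s0 == 0) s0 <- if (any(s > 0)) min(s[s > 0]) else 1
  nk <- table(y)[classes]
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  d <- sweep(sweep(cent, 2, overall, "-"), 2, s + s0, "/") / mk
  list(y = y, classes = classes, n = n, nk = as.numeric(nk), overall = overall,
       centroids = cent, s = s, s0 = s0, mk = mk, d = d)
}

shrink_d <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

#' Nearest-shrunken-centroid (PAM) feature ranking
#'
#' Computes per-feature, per-class standardized centroid distances d_kj,
#' soft-thresholds them by `delta`, and scores each feature by
#' max_k |d'_kj|. At `delta = 0` this ranks by the unshrunken distances; as
#' `delta` grows all scores shrink to 0.
#'
#' @inheritParams golub_rank
#' @param delta shrinkage threshold (>= 0).
#' @return a [FeatureRanking][feature_ranking].
#' @export
pam_rank <- function(X, y, delta = 0) {
  st <- pam_stats(X, y)
  ds <- shrink_d(st$d, delta)
  feature_ranking("PAM", apply(abs(ds), 2, max), colnames(X))
}

#' PCA loading feature ranking
#'
#' Unsupervised variant: ranks features by the absolute loading on the first
#' principal component of the column-centered matrix.
#'
#' @inheritParams golub_rank
#' @return a [FeatureRanking][feature_ranking].
#' @export
pca_loading_rank <- function(X) {
  if (nrow(X) < 2) stop("need >= 2 profiles")
  vars <- apply(X, 2, stats::var)
  if (all(vars == 0)) stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  feature_ranking("PCA", abs(pc$rotation[, 1]), colnames(X))
}

#' PLS-DA loading feature ranking
#'
#' Ranks features by the absolute weight on the first partial-least-squares
#' component against the +/-1 coded class label. For a single response the
#' first PLS weight vector is proportional to the feature/label covariance
#' X_c' y_c, which is computed directly.
#'
#' @inheritParams golub_rank
#' @return a [FeatureRanking][feature_ranking].
#' @export
plsda_loading_rank <- function(X, y) {
  y <- check_binary(y)
  if (nrow(X) < 2) stop("need >= 2 profiles")
  yv <- ifelse(y == levels(y)[2], 1, -1)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  w <- drop(crossprod(Xc, yv - mean(yv)))
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("degenerate input: zero covariance with the label")
  feature_ranking("PLSDA", abs(w / nrm), colnames(X))
}

#' Run one feature selector by name
#'
#' @inheritParams golub_rank
#' @param method one of GOLUB, SVM, SVM_RFE, PAM, PCA, PLSDA.
#' @param cost SVM regularization (SVM and SVM_RFE).
#' @param delta PAM shrinkage threshold.
#' @return a [FeatureRanking][feature_ranking].
#' @export
rank_features <- function(method, X, y = NULL, cost = 1, delta = 0) {
  method <- match.arg(method, RANK_METHODS)
  switch(method,
    GOLUB   = golub_rank(X, y),
    SVM     = svm_weight_rank(X, y, cost),
    SVM_RFE = svm_rfe_rank(X, y, cost),
    PAM     = pam_rank(X, y, delta),
    PCA     = pca_loading_rank(X),
    PLSDA   = plsda_loading_rank(X, y))
}

#' Write a feature ranking as tab-delimited text
#' @param ranking a `FeatureRanking`.
#' @param path output file path.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$ranks),
                   probeset_id = ranking$feature_ids[ranking$ranks],
                   method = ranking$method,
                   score = ranking$scores[ranking$ranks])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
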