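CLASSIFIER_KINDS <- c("SVM", "KNN", "PAM", "NAIVE_BAYES", "RANDOM_FOREST",
                      "WEIGHTED_VOTING")

#' Default hyperparameter grids for the six classifiers
#'
#' SVM: cost C; KNN: neighbor count k; PAM: number of evenly spaced shrinkage
#' thresholds on the data-driven path; Random Forest: candidate
#' features-per-split (resolved against the signature size at train time).
#' Naive Bayes and Weighted Voting have no tuned parameters.
#'
#' @return named list of grids, one entry per classifier kind.
#' @export
default_grids <- function() {
  list(SVM = list(cost = c(0.01, 0.1, 1, 10, 100)),
       KNN = list(k = c(1, 3, 5)),
       PAM = list(n_delta = 10),
       NAIVE_BAYES = list(),
       RANDOM_FOREST = list(mtry_rule = c("sqrt", "third")),
       WEIGHTED_VOTING = list())
}

#' Train one classifier on standardized signature features
#'
#' All six kinds consume a numeric matrix of z-scored fold changes restricted
#' to a signature (profiles x features) and a two-level factor whose second
#' level is the positive class. Training is deterministic for a fixed seed.
#'
#' @param kind one of SVM, KNN, PAM, NAIVE_BAYES, RANDOM_FOREST,
#'   WEIGHTED_VOTING.
#' @param X standardized numeric matrix, profiles x signature features.
#' @param y two-level factor; second level = positive class.
#' @param params named list of hyperparameters (`cost`, `k`, `delta`,
#'   `mtry`, `ntree`, `prior`). Missing entries take defaults.
#' @param seed integer seed for the stochastic kinds (Random Forest).
#' @return object of class `toxsig_model`.
#' @export
train_classifier <- function(kind, X, y, params = list(), seed = 1L) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  if (!is.matrix(X) || ncol(X) < 1) stop("X must be a matrix with >= 1 signature feature")
  y <- check_binary(y)
  fit <- switch(kind,
    SVM = {
      cost <- params$cost %||% 1
      list(svm = e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
                            scale = FALSE), cost = cost)
    },
    KNN = list(X = X, y = y, k = params$k %||% 3),
    PAM = {
      st <- pam_stats(X, y)
      prior <- params$prior %||% "class"
      pi_k <- if (identical(prior, "uniform")) rep(0.5, 2) else st$nk / st$n
      list(stats = st, delta = params$delta %||% 0, prior = pi_k)
    },
    NAIVE_BAYES = list(nb = e1071::naiveBayes(x = as.data.frame(X), y = y)),
    RANDOM_FOREST = {
      ntree <- params$ntree %||% 500
      mtry <- params$mtry %||% max(1, floor(sqrt(ncol(X))))
      set.seed(seed)
      list(rf = randomForest::randomForest(x = X, y = y, ntree = ntree,
                                           mtry = min(mtry, ncol(X))))
    },
    WEIGHTED_VOTING = {
      pos <- X[y == levels(y)[2], , drop = FALSE]
      neg <- X[y == levels(y)[1], , drop = FALSE]
      list(weights = signed_s2n(X, y),
           midpoint = (colMeans(pos) + colMeans(neg)) / 2)
    })
  structure(list(kind = kind, fit = fit, levels = levels(y),
                 features = colnames(X), seed = seed, params = params),
            class = "toxsig_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict positive-class confidences in [0,1]
#'
#' Every classifier's raw output is rescaled to a confidence for the positive
#' class: SVM decision values pass through the logistic map 1/(1+exp(-d));
#' Weighted-Voting prediction strengths v in [-1,1] through (v+1)/2; KNN
#' confidence is the fraction of positively labeled nearest neighbors; PAM,
#' Naive Bayes and Random Forest emit native posteriors / vote fractions.
#'
#' @param model a `toxsig_model` from [train_classifier()].
#' @param X_new matrix of profiles x features, standardized with the
#'   training-set statistics; columns must cover the model's signature.
#' @return numeric vector of confidences in [0,1], one per row of `X_new`.
#' @export
predict_confidence <- function(model, X_new) {
  stopifnot(inherits(model, "toxsig_model"))
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1,
                                           dimnames = list(NULL, model$features))
  miss <- setdiff(model$features, colnames(X_new))
  if (length(miss))
    stop("input lacks signature features: ",
         paste(utils::head(miss, 5), collapse = ", "))
  X_new <- X_new[, model$features, drop = FALSE]
  pos <- model$levels[2]
  conf <- switch(model$kind,
    SVM = {
      pr <- stats::predict(model$fit$svm, X_new, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      d <- drop(dv[, 1])
      # e1071 names the column "A/B" with positive values favoring A
      if (strsplit(colnames(dv)[1], "/")[[1]][1] != pos) d <- -d
      plogis_map(d)
    },
    KNN = knn_confidence(model$fit$X, model$fit$y, X_new, model$fit$k, pos),
    PAM = pam_posterior(model$fit$stats, model$fit$delta, model$fit$prior,
                        X_new)[, pos],
    NAIVE_BAYES = stats::predict(model$fit$nb, as.data.frame(X_new),
                                 type = "raw")[, pos],
    RANDOM_FOREST = stats::predict(model$fit$rf, X_new, type = "prob")[, pos],
    WEIGHTED_VOTING = (weighted_voting_strength(model$fit, X_new) + 1) / 2)
  unname(pmin(pmax(as.numeric(conf), 0), 1))
}

plogis_map <- function(d) 1 / (1 + exp(-d))

# fraction of positively labeled neighbors among the k nearest (Euclidean);
# distance ties broken by training-sample index for determinism
knn_confidence <- function(Xtr, ytr, Xte, k, pos) {
  k <- min(k, nrow(Xtr))
  apply(Xte, 1, function(x) {
    d <- sqrt(colSums((t(Xtr) - x)^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    mean(ytr[nb] == pos)
  })
}

# class posteriors from shrunken-centroid discriminant scores with priors
pam_posterior <- function(st, delta, prior, X_new) {
  ds <- shrink_d(st$d, delta)
  cent <- sweep(sweep(ds, 1, st$mk, "*"), 2, st$s + st$s0, "*") +
    matrix(st$overall, nrow(ds), ncol(ds), byrow = TRUE)
  denom <- (st$s + st$s0)^2
  delta_k <- vapply(seq_along(st$classes), function(k) {
    rowSums(sweep((X_new - matrix(cent[k, ], nrow(X_new), ncol(X_new),
                                  byrow = TRUE))^2, 2, denom, "/")) -
      2 * log(prior[k])
  }, numeric(nrow(X_new)))
  if (is.null(dim(delta_k))) delta_k <- matrix(delta_k, nrow = 1)
  delta_k <- delta_k - apply(delta_k, 1, min)
  post <- exp(-delta_k / 2)
  post <- post / rowSums(post)
  colnames(post) <- st$classes
  post
}

# signed prediction strength in [-1,1]: each feature votes
# weight * (x - midpoint); strength = (V_pos - V_neg)/(V_pos + V_neg),
# 0 (abstention) when all votes are zero
weighted_voting_strength <- function(fit, X_new) {
  apply(X_new, 1, function(x) {
    v <- fit$weights * (x - fit$midpoint)
    vp <- sum(pmax(v, 0)); vn <- sum(pmax(-v, 0))
    if (vp + vn == 0) 0 else (vp - vn) / (vp + vn)
  })
}

#' Weighted-Voting classifier: fit and predict in one call
#'
#' Golub-style weighted voting: per feature, the weight is the signed
#' signal-to-noise ratio on the training data and the decision boundary is
#' the midpoint of the class means; a test profile's prediction strength in
#' [-1,1] is rescaled to a confidence via (v+1)/2.
#'
#' @param X training matrix (profiles x features).
#' @param y two-level factor, second level positive.
#' @param X_new matrix of profiles to score.
#' @return numeric vector of confidences in [0,1].
#' @export
weighted_voting_fit_predict <- function(X, y, X_new) {
  m <- train_classifier("WEIGHTED_VOTING", X, y)
  predict_confidence(m, X_new)
}

#' Nearest-shrunken-centroid classifier: fit and predict in one call
#'
#' @inheritParams weighted_voting_fit_predict
#' @param delta shrinkage threshold.
#' @param prior "class" (training proportions) or "uniform".
#' @return numeric vector of positive-class posteriors in [0,1].
#' @export
pam_classify <- function(X, y, X_new, delta = 0, prior = "class") {
  m <- train_classifier("PAM", X, y, params = list(delta = delta, prior = prior))
  predict_confidence(m, X_new)
}

# candidate deltas spanning the shrinkage path of the training data
pam_delta_grid <- function(X, y, n_delta = 10) {
  st <- pam_stats(X, y)
  dmax <- max(abs(st$d))
  seq(0, dmax, length.out = n_delta)
}

#' Tabulate prediction results
#'
#' @param group_id character vector of treatment-group ids.
#' @param classifier classifier kind.
#' @param confidence numeric confidences in [0,1].
#' @param truth optional true labels.
#' @param positive name of the positive class (used for `predicted`).
#' @param negative name of the negative class.
#' @return data.frame with columns group_id, classifier, confidence,
#'   predicted, truth.
#' @export
prediction_results <- function(group_id, classifier, confidence,
                               truth = NA, positive = "pos",
                               negative = "neg") {
  data.frame(group_id = group_id, classifier = classifier,
             confidence = confidence,
             predicted = ifelse(confidence >= 0.5, positive, negative),
             truth = as.character(truth), stringsAsFactors = FALSE)
}
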