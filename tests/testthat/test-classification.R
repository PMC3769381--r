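test_that("all six classifiers put separable training data on the correct
           side of 0.5 and are deterministic under a fixed seed", {
  toy <- separable_toy()
  z <- zscore_fit_apply(toy$X)$train
  for (kind in c("SVM", "KNN", "PAM", "NAIVE_BAYES", "RANDOM_FOREST",
                 "WEIGHTED_VOTING")) {
    m <- train_classifier(kind, z, toy$y, seed = 7)
    conf <- predict_confidence(m, z)
    expect_true(all(conf[toy$y == "pos"] > 0.5), info = kind)
    expect_true(all(conf[toy$y == "neg"] < 0.5), info = kind)
    m2 <- train_classifier(kind, z, toy$y, seed = 7)
    expect_identical(conf, predict_confidence(m2, z), info = kind)
  }
  expect_error(train_classifier("SVM", z[, 0, drop = FALSE], toy$y),
               "signature feature")
  expect_error(train_classifier("SVM", z, factor(rep("pos", nrow(z)))),
               "two classes")
})

test_that("score rescaling maps the documented anchor points", {
  # SVM: symmetric single-feature data -> decision value 0 at the midpoint
  X <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  m <- train_classifier("SVM", X, y)
  expect_equal(predict_confidence(m, matrix(0, 1, 1,
                                            dimnames = list(NULL, "f"))),
               0.5, tolerance = 1e-6)
  # weighted voting: unanimous votes hit the [0,1] endpoints exactly
  mwv <- train_classifier("WEIGHTED_VOTING", X, y)
  expect_identical(predict_confidence(mwv, matrix(5, 1, 1,
                                                  dimnames = list(NULL, "f"))), 1)
  expect_identical(predict_confidence(mwv, matrix(-5, 1, 1,
                                                  dimnames = list(NULL, "f"))), 0)
  # balanced votes abstain at 0.5
  expect_equal(predict_confidence(mwv, matrix(0, 1, 1,
                                              dimnames = list(NULL, "f"))), 0.5)
  # KNN: 3 of 5 positive nearest neighbors -> 0.6
  Xk <- matrix(c(0, 0.1, 0.2, 0.3, 0.4, 10), ncol = 1,
               dimnames = list(NULL, "f"))
  yk <- factor(c("pos", "pos", "pos", "neg", "neg", "neg"),
               levels = c("neg", "pos"))
  mk <- train_classifier("KNN", Xk, yk, params = list(k = 5))
  expect_equal(predict_confidence(mk, matrix(0, 1, 1,
                                             dimnames = list(NULL, "f"))), 0.6)
})

test_that("weighted voting strength matches a two-feature hand computation", {
  # feature A: neg {0,2} (mean 1, sd sqrt(2)), pos {4,6} (mean 5, sd sqrt(2))
  #   weight = 4 / (2*sqrt(2)) = sqrt(2); midpoint = 3
  # feature B: neg {1,3} , pos {3,5} -> weight = 2/(2*sqrt(2)) = 1/sqrt(2);
  #   midpoint = 3
  X <- cbind(A = c(0, 2, 4, 6), B = c(1, 3, 3, 5))
  y <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  m <- train_classifier("WEIGHTED_VOTING", X, y)
  x_new <- matrix(c(4, 2), 1, dimnames = list(NULL, c("A", "B")))
  # votes: A: sqrt(2)*(4-3) = sqrt(2); B: (1/sqrt(2))*(2-3) = -1/sqrt(2)
  # strength = (sqrt(2) - 1/sqrt(2)) / (sqrt(2) + 1/sqrt(2)) = 1/3
  expect_equal(predict_confidence(m, x_new), (1 / 3 + 1) / 2)
})

test_that("PAM classification reduces to nearest centroids at zero
           shrinkage and to the priors under complete shrinkage", {
  toy <- separable_toy(n_per_class = 5)
  z <- zscore_fit_apply(toy$X)$train
  conf <- pam_classify(z, toy$y, z, delta = 0)
  expect_true(all((conf > 0.5) == (toy$y == "pos")))
  # complete shrinkage: posteriors equal the class priors for any input
  yu <- factor(c(rep("neg", 6), rep("pos", 4)), levels = c("neg", "pos"))
  set.seed(4)
  Xu <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  probe <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  conf_inf <- pam_classify(Xu, yu, probe, delta = 1e9)
  expect_equal(conf_inf, rep(0.4, 5))
  # equidistant point with equal priors scores exactly 0.5
  Xe <- matrix(c(-1, -1, 1, 1), 4, 1, dimnames = list(NULL, "f"))
  ye <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  expect_equal(pam_classify(Xe, ye, matrix(0, 1, 1,
                                           dimnames = list(NULL, "f")),
                            prior = "uniform"), 0.5)
})

test_that("swapping the class labels flips confidences to 1 - c", {
  toy <- separable_toy(n_per_class = 5, gap = 2)
  z <- zscore_fit_apply(toy$X)$train
  y_sw <- factor(toy$y, levels = c("pos", "neg"))  # positive class now "neg"
  probe <- z + 0.3
  for (kind in c("KNN", "WEIGHTED_VOTING")) {
    c1 <- predict_confidence(train_classifier(kind, z, toy$y), probe)
    c2 <- predict_confidence(train_classifier(kind, z, y_sw), probe)
    expect_equal(c1, 1 - c2, tolerance = 1e-9, info = kind)
  }
  c1 <- predict_confidence(
    train_classifier("PAM", z, toy$y, params = list(prior = "uniform")), probe)
  c2 <- predict_confidence(
    train_classifier("PAM", z, y_sw, params = list(prior = "uniform")), probe)
  expect_equal(c1, 1 - c2, tolerance = 1e-9)
  c1 <- predict_confidence(train_classifier("SVM", z, toy$y), probe)
  c2 <- predict_confidence(train_classifier("SVM", z, y_sw), probe)
  expect_equal(c1, 1 - c2, tolerance = 1e-6)
})

test_that("confidences stay in [0,1] for arbitrary finite inputs", {
  set.seed(21)
  toy <- separable_toy()
  z <- zscore_fit_apply(toy$X)$train
  extreme <- matrix(runif(200 * 2, -1e3, 1e3), ncol = 2,
                    dimnames = list(NULL, colnames(z)))
  for (kind in c("SVM", "KNN", "PAM", "NAIVE_BAYES", "RANDOM_FOREST",
                 "WEIGHTED_VOTING")) {
    m <- train_classifier(kind, z, toy$y, seed = 2)
    conf <- predict_confidence(m, extreme)
    expect_true(all(is.finite(conf) & conf >= 0 & conf <= 1), info = kind)
  }
  m <- train_classifier("SVM", z, toy$y)
  expect_error(predict_confidence(m, matrix(0, 1, 1,
                                            dimnames = list(NULL, "zz"))),
               "signature features")
})
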