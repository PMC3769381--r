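test_that("bootstrap plans are stratified 90% subsamples with complementary
           out-of-bag sets", {
  y <- factor(rep(c("neg", "pos"), each = 20), levels = c("neg", "pos"))
  plan <- draw_bootstraps(y, seed = 11)
  expect_identical(plan$n_bootstraps, 25)
  expect_true(all(vapply(plan$in_bag, length, integer(1)) == 36L))
  glob <- 0.5
  for (b in seq_len(plan$n_bootstraps)) {
    ib <- plan$in_bag[[b]]; ob <- plan$out_of_bag[[b]]
    expect_length(intersect(ib, ob), 0)
    expect_setequal(c(ib, ob), seq_along(y))
    expect_identical(anyDuplicated(ib), 0L)           # without replacement
    # in-bag class proportions within one member of the global proportions
    expect_lte(abs(sum(y[ib] == "pos") - glob * 36), 1)
  }
  plan2 <- draw_bootstraps(y, seed = 11)
  expect_identical(plan$in_bag, plan2$in_bag)
  expect_error(draw_bootstraps(y[1:8]), ">= 10")
})

test_that("Kuncheva index reproduces its analytic anchors and hand values", {
  A <- paste0("f", 1:10)
  expect_identical(kuncheva_index(A, A, 100), 1)
  expect_identical(kuncheva_index(1:50, 51:100, 100), -1)
  expect_equal(kuncheva_index(1:3, 3:5, 10), 1 / 21)  # P=10, k=3, r=1
  expect_error(kuncheva_index(1:3, 1:4, 10), "equal size")
  expect_error(kuncheva_index(1:10, 1:10, 10), "0 < k < P")
  expect_error(kuncheva_index(integer(0), integer(0), 10))
})

test_that("Kuncheva index is bounded and strictly increasing in the
           intersection size over exhaustive small grids", {
  for (P in 4:12) for (k in 1:(P - 1)) {
    r_max <- k
    r_min <- max(0, 2 * k - P)
    kis <- vapply(r_min:r_max, function(r) {
      A <- seq_len(k)
      B <- c(seq_len(r), setdiff(seq_len(P), seq_len(k)))[seq_len(k)]
      stopifnot(length(intersect(A, B)) == r)
      kuncheva_index(A, B, P)
    }, numeric(1))
    expect_true(all(kis >= -1 - 1e-12 & kis <= 1 + 1e-12))
    if (length(kis) > 1) expect_true(all(diff(kis) > 0))
  }
})

test_that("multi-set stability is the mean over all unordered pairs", {
  subs <- list(1:4, 1:4, 1:4)
  expect_equal(mean_kuncheva(subs, 20), 1)
  subs2 <- list(1:4, 3:6, c(1, 2, 5, 6))
  manual <- mean(c(kuncheva_index(subs2[[1]], subs2[[2]], 20),
                   kuncheva_index(subs2[[1]], subs2[[3]], 20),
                   kuncheva_index(subs2[[2]], subs2[[3]], 20)))
  expect_equal(mean_kuncheva(subs2, 20), manual)
  expect_error(mean_kuncheva(list(1:3, 1:4), 20), "same size")
  expect_error(mean_kuncheva(list(1:3), 20), ">= 2")
})

test_that("spline size optimisation handles monotone, unimodal and flat
           curves", {
  sizes <- c(2, 5, 10, 15, 20, 30, 40, 60, 80, 100)
  mk <- function(roc) structure(list(method = "GOLUB", sizes = sizes,
                                     mean_roc = roc, optimum_size = NULL),
                                class = "SizePerformanceCurve")
  expect_identical(spline_optimum(mk(seq(0.5, 0.95, length.out = 10)))$optimum_size,
                   100L)
  peaked <- 1 - ((sizes - 40) / 100)^2
  opt <- spline_optimum(mk(peaked))$optimum_size
  expect_true(opt >= 30 && opt <= 60)   # within one grid step of 40
  expect_identical(spline_optimum(mk(rep(0.8, 10)))$optimum_size, 2L)
  # fewer than 4 points: raw argmax fallback
  few <- structure(list(method = "GOLUB", sizes = c(2, 10, 50),
                        mean_roc = c(0.6, 0.9, 0.7), optimum_size = NULL),
                   class = "SizePerformanceCurve")
  expect_identical(spline_optimum(few)$optimum_size, 10)
})

test_that("rank-sum consensus aggregates rankings with index tie-breaks", {
  mkrank <- function(ord, ids = c("a", "b", "c")) {
    scores <- numeric(3); scores[ord] <- 3:1
    feature_ranking("GOLUB", scores, ids)
  }
  same <- list(mkrank(c(1, 2, 3)), mkrank(c(1, 2, 3)))
  cs <- consensus_rank(same, 2)
  expect_identical(cs$probeset_ids, c("a", "b"))
  # rankings (a,b,c) and (b,a,c): rank sums a=3, b=3, c=6; a first by index
  mixed <- list(mkrank(c(1, 2, 3)), mkrank(c(2, 1, 3)))
  cs2 <- consensus_rank(mixed, 3)
  expect_identical(cs2$probeset_ids, c("a", "b", "c"))
  expect_equal(cs2$rank_sums, c(3, 3, 6))
  # exact reverses: all rank sums equal, order fully from the tie-break
  rev2 <- list(mkrank(c(1, 2, 3)), mkrank(c(3, 2, 1)))
  cs3 <- consensus_rank(rev2, 3)
  expect_identical(cs3$probeset_ids, c("a", "b", "c"))
  expect_true(length(unique(cs3$rank_sums)) == 1)
  other <- list(mkrank(c(1, 2, 3), ids = c("x", "y", "z")))
  expect_error(consensus_rank(c(same, other), 2), "feature universes")
})

test_that("out-of-bag ROC separates planted signal from permuted labels", {
  pm <- planted_matrix(n = 40, P = 200, n_inf = 20, effect = 2, seed = 8)
  plan <- draw_bootstraps(pm$y, n_bootstraps = 25, seed = 5)
  curve <- evaluate_oob(pm$X, pm$y, plan, "GOLUB", sizes = c(2, 10, 20, 50))
  expect_identical(curve$sizes, c(2, 10, 20, 50))
  expect_true(all(curve$mean_roc >= 0 & curve$mean_roc <= 1))
  expect_gt(curve$mean_roc[curve$sizes == 10], 0.9)

  set.seed(9); yp <- sample(pm$y)
  curve_null <- evaluate_oob(pm$X, yp, plan, "GOLUB", sizes = c(10, 50))
  expect_true(all(abs(curve_null$mean_roc - 0.5) < 0.25))
})

test_that("the default size grid has 10 entries spanning 2..100", {
  grid <- toxsig:::DEFAULT_SIZE_GRID
  expect_length(grid, 10)
  expect_identical(range(grid), c(2, 100))
  expect_true(all(diff(grid) > 0))
})

test_that("Stage 1 is reproducible, supports the reduced ensembles, and
           recovers planted signatures", {
  sim <- small_sim()
  pr <- compute_group_profiles(sim$dataset, 14)
  y <- task_labels(pr$info$class_label, "C_vs_NC")
  args <- list(profiles = pr, y = y, n_bootstraps = 10, consensus_size = 15,
               evaluate_performance = FALSE, seed = 42)
  s1 <- suppressMessages(do.call(run_stage1, args))
  s2 <- suppressMessages(do.call(run_stage1, args))
  expect_identical(s1$signature$probeset_ids, s2$signature$probeset_ids)
  expect_identical(s1$signature$rank_sums, s2$signature$rank_sums)
  expect_named(s1$rankings, c("GOLUB", "SVM", "SVM_RFE", "PAM"))
  expect_length(s1$rankings$SVM, 10)
  # consensus is dominated by planted carcinogen-shared probesets
  expect_gte(recovery_score(s1$signature, sim$truth, "C_vs_NC"), 0.8)

  red <- suppressMessages(run_stage1(pr, y, methods = c("SVM", "SVM_RFE"),
                                     n_bootstraps = 5, consensus_size = 10,
                                     evaluate_performance = FALSE, seed = 1))
  expect_named(red$rankings, c("SVM", "SVM_RFE"))
  expect_identical(red$signature$size, 10)
  expect_error(run_stage1(pr, y, methods = character(0)), "empty method")

  mv <- suppressMessages(run_stage1(pr, y, methods = c("PCA", "PLSDA"),
                                    n_bootstraps = 5, consensus_size = 10,
                                    evaluate_performance = FALSE, seed = 1))
  expect_identical(mv$signature$size, 10)
})

test_that("signatures round-trip through their text serialization", {
  sig <- structure(list(task = "C_vs_NC", duration_days = 14,
                        probeset_ids = c("p3", "p1", "p2"),
                        rank_sums = c(4, 9, 11), size = 3,
                        provenance = list()),
                   class = "ConsensusSignature")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  tab <- read.delim(path)
  expect_identical(tab$probeset_id, sig$probeset_ids)
  idpath <- withr::local_tempfile(fileext = ".txt")
  writeLines(sig$probeset_ids, idpath)
  expect_identical(read_signature(idpath), sig$probeset_ids)
  writeLines(c("p1", "p1"), idpath)
  expect_error(read_signature(idpath), "duplicated")
})
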