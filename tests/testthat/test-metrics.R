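test_that("confusion counts match exhaustive enumeration", {
  cc <- confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(unname(cc$matrix), matrix(c(1, 0, 1, 2), 2, 2))
  # class-1 one-vs-rest collapse of the 4 samples
  expect_equal(unname(cc$per_class["1", ]), c(2, 1, 0, 1))  # TP FP FN TN
  expect_equal(sum(cc$matrix), 4)
  # identity prediction gives a diagonal matrix
  cc2 <- confusion_counts(c(2, 0, 1, 2), c(2, 0, 1, 2))
  expect_true(all(cc2$matrix[upper.tri(cc2$matrix) | lower.tri(cc2$matrix)] == 0))
  expect_true(all(cc2$per_class[, c("FP", "FN")] == 0))
  # per-class counts always sum to m
  withr::local_seed(1)
  y1 <- random_labels(37, 4); y2 <- random_labels(37, 4)
  cc3 <- confusion_counts(y1, y2)
  expect_true(all(rowSums(cc3$per_class) == 37))
})

test_that("external metrics reproduce the hand-evaluated binary example", {
  y_true <- c(0, 0, 1, 1)
  y_pred <- c(0, 1, 1, 1)
  em <- external_metrics(y_true, y_pred)
  expect_equal(em$accuracy, 0.75)
  expect_equal(em$precision, (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(em$recall, (0.5 + 1) / 2, tolerance = 1e-12)
  expect_equal(em$mcc, 2 / sqrt(12), tolerance = 1e-12)
  # perfect prediction
  em1 <- external_metrics(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(unname(unlist(em1)), rep(1, 6), tolerance = 1e-12)
  # constant single-class prediction: degenerate MCC convention -> 0
  expect_warning(em0 <- external_metrics(c(0, 0, 1, 1), c(0, 0, 0, 0)),
                 "degenerate")
  expect_equal(em0$mcc, 0)
})

test_that("external metrics and multiclass MCC agree with the independent oracle", {
  withr::local_seed(99)
  for (i in 1:60) {
    m <- sample(5:60, 1)
    k <- sample(2:5, 1)
    y1 <- random_labels(m, k)
    y2 <- if (i %% 3 == 0) y1 else random_labels(m, k)
    em <- suppressWarnings(external_metrics(y1, y2))
    oe <- oracle_external(y1, y2)
    for (f in names(oe)) {
      expect_equal(em[[f]], oe[[f]], tolerance = 1e-10, label = f)
    }
    expect_true(em$accuracy >= 0 && em$accuracy <= 1)
    expect_true(em$mcc >= -1 && em$mcc <= 1 + 1e-12)
  }
  # for F=2 the multiclass MCC equals the literal binary formula exactly
  withr::local_seed(5)
  for (i in 1:40) {
    y1 <- random_labels(20, 2); y2 <- random_labels(20, 2)
    tp <- sum(y1 == 2 & y2 == 2); tn <- sum(y1 == 1 & y2 == 1)
    fp <- sum(y1 == 1 & y2 == 2); fn <- sum(y1 == 2 & y2 == 1)
    em <- suppressWarnings(external_metrics(y1, y2))
    expect_equal(em$mcc, oracle_mcc_binary(tp, tn, fp, fn), tolerance = 1e-12)
  }
})

test_that("pair counts match exhaustive pair enumeration", {
  pc <- pair_counts(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(pc[c("TP", "FP", "FN", "TN")],
               list(TP = 2L, FP = 0L, FN = 0L, TN = 4L))
  pc2 <- pair_counts(c(0, 0, 1, 1), c(0, 0, 0, 1))
  expect_equal(pc2[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 2L, FN = 1L, TN = 2L))
  withr::local_seed(3)
  for (i in 1:30) {
    m <- sample(4:40, 1)
    y1 <- random_labels(m, sample(2:4, 1))
    y2 <- random_labels(m, sample(2:4, 1))
    pc <- pair_counts(y1, y2)
    o <- oracle_pair_counts(y1, y2)
    expect_identical(pc[c("TP", "FP", "FN", "TN")], o)
    expect_equal(pc$TP + pc$FP + pc$FN + pc$TN, m * (m - 1) / 2)
  }
})

test_that("both adjusted Rand formulas behave as documented", {
  # identical partitions: 1 under both
  y <- c(0, 0, 1, 1, 2)
  expect_equal(adjusted_rand(y, y), 1)
  expect_equal(adjusted_rand(y, y, formula = "eq10"), 1)
  # frozen pair-count case: standard gives 0, the literal chain goes negative
  pc <- structure(list(TP = 1, FP = 2, FN = 1, TN = 2, total = 6),
                  class = "pair_counts")
  expect_equal(adjusted_rand(pc), 0)
  expect_equal(adjusted_rand(pc, formula = "eq10"), (0.5 - 1.5) / (3 - 1.5))
  # standard formula agrees with an established independent implementation
  skip_if_not_installed("mclust")
  withr::local_seed(21)
  for (i in 1:50) {
    y1 <- random_labels(30, 3); y2 <- random_labels(30, 4)
    expect_equal(adjusted_rand(y1, y2),
                 mclust::adjustedRandIndex(y1, y2), tolerance = 1e-10)
  }
})

test_that("standard ARI is centered at zero under independent partitions", {
  withr::local_seed(77)
  aris <- replicate(200, adjusted_rand(random_labels(60, 3),
                                       random_labels(60, 3)))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("silhouette reproduces the 4-point hand computation and the oracle", {
  feat <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c(1, 1, 2, 2)
  b <- (sqrt(100) + sqrt(101)) / 2
  expect_equal(silhouette_width(feat, lab), (b - 1) / b, tolerance = 1e-12)
  # two singleton clusters: 0 by convention
  expect_equal(silhouette_width(rbind(c(0, 0), c(5, 5)), c(1, 2)), 0)
  expect_error(silhouette_width(feat, rep(1, 4)), "2 clusters")
  withr::local_seed(10)
  for (i in 1:25) {
    m <- sample(6:40, 1)
    feat <- matrix(rnorm(m * 3), m, 3)
    lab <- random_labels(m, sample(2:4, 1))
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_width(feat, lab), oracle_silhouette(feat, lab),
                 tolerance = 1e-10)
  }
  # agreement with the established cluster-package implementation
  skip_if_not_installed("cluster")
  withr::local_seed(11)
  feat <- matrix(rnorm(30 * 4), 30, 4)
  lab <- random_labels(30, 3)
  sil <- cluster::silhouette(lab, dist(feat))
  expect_equal(silhouette_width(feat, lab), mean(sil[, "sil_width"]),
               tolerance = 1e-10)
})

test_that("Davies-Bouldin reproduces the hand computation and the oracle", {
  feat <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin(feat, lab), 0.1, tolerance = 1e-12)
  # zero-spread clusters at distinct points reach the lower limit 0
  feat0 <- rbind(c(0, 0), c(0, 0), c(3, 3), c(3, 3))
  expect_equal(davies_bouldin(feat0, lab), 0)
  expect_error(davies_bouldin(rbind(feat0, feat0), rep(1, 8)), "2 clusters")
  expect_error(davies_bouldin(rbind(c(0, 0), c(0, 0)), c(1, 2)), "coincident")
  withr::local_seed(13)
  for (i in 1:25) {
    m <- sample(6:40, 1)
    feat <- matrix(rnorm(m * 3), m, 3)
    lab <- random_labels(m, sample(2:4, 1))
    if (length(unique(lab)) < 2) next
    expect_equal(davies_bouldin(feat, lab), oracle_dbi(feat, lab),
                 tolerance = 1e-10)
  }
})

test_that("evaluate_predictions bundles metrics within their ranges", {
  withr::local_seed(19)
  feat <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
  y <- rep(c("a", "b"), each = 10)
  rep1 <- evaluate_predictions(y, y, features = feat,
                               metadata = list(fold = 1))
  expect_equal(rep1$accuracy, 1)
  expect_gt(rep1$silhouette, 0)
  expect_gte(rep1$dbi, 0)
  expect_identical(rep1$metadata$fold, 1)
  # degenerate single-class prediction: internal metrics become NA, not errors
  warns <- capture_warnings(
    rep2 <- evaluate_predictions(y, rep("a", 20), features = feat))
  expect_true(any(grepl("silhouette|degenerate", warns)))
  expect_true(is.na(rep2$silhouette))
  expect_true(rep2$accuracy >= 0 && rep2$accuracy <= 1)
})
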