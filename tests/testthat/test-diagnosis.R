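test_that("yield discretization with at-cutoff ties going high", {
  expect_equal(as.character(discretize_yield(c(50, 70), 60)), c("low", "high"))
  expect_equal(as.character(discretize_yield(60, 60)), "high")
  expect_true(all(discretize_yield(c(10, 20, 30), 60) == "low"))
  expect_error(discretize_yield(c(-1, 5), 60), ">= 0")
  expect_error(discretize_yield(c(1, 5), 0))
})

make_clusters <- function(n_per, d = 7, sep = 4, seed = 5) {
  set.seed(seed)
  mu <- c(sep / sqrt(d) * rep(1, d))
  x <- rbind(matrix(rnorm(n_per * d), ncol = d),
             sweep(matrix(rnorm(n_per * d), ncol = d), 2, mu, `+`))
  list(x = x, cl = factor(rep(c("low", "high"), each = n_per),
                          levels = c("low", "high")))
}

test_that("knn classification: trivial cases and separated clusters", {
  # one training specimen dominates everything
  one <- matrix(0, 1, 3)
  q <- matrix(rnorm(15), 5, 3)
  expect_true(all(knn_classify(one, "low", q, k = 1) == "low"))
  # k = 1 self-prediction is perfect
  cl2 <- make_clusters(30)
  expect_equal(knn_classify(cl2$x, cl2$cl, cl2$x, k = 1), cl2$cl)
  # two clusters 4 pooled SDs apart: high accuracy under every kernel
  cl <- make_clusters(100)
  for (kern in c("rectangular", "triangular", "optimal")) {
    pred <- knn_classify(cl$x, cl$cl, cl$x, k = 10, kernel = kern)
    expect_gte(mean(pred == cl$cl), 0.95)
  }
  expect_error(knn_classify(cl$x, cl$cl, cl$x, k = 300), "training size")
  expect_error(knn_classify(cl$x, cl$cl, cl$x[, 1:3], k = 5), "dimension")
})

test_that("knn agrees with an exact nearest-neighbour oracle", {
  skip_if_not_installed("class")
  cl <- make_clusters(60, seed = 9)
  q <- make_clusters(40, seed = 10)$x
  # rectangular kernel, Euclidean distance, odd k: plain majority vote
  ours <- knn_classify(cl$x, cl$cl, q, k = 5, p = 2, kernel = "rectangular")
  oracle <- class::knn(cl$x, q, cl$cl, k = 5)
  expect_equal(as.character(ours), as.character(oracle))
})

test_that("knn predictions are invariant to coordinate permutation", {
  cl <- make_clusters(40, seed = 21)
  q <- matrix(rnorm(10 * 7), 10, 7)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  for (kern in c("rectangular", "triangular", "optimal")) {
    p1 <- knn_classify(cl$x, cl$cl, q, k = 7, p = 4, kernel = kern)
    p2 <- knn_classify(cl$x[, perm], cl$cl, q[, perm], k = 7, p = 4, kernel = kern)
    expect_equal(p1, p2)
  }
})

test_that("Minkowski exponent is honoured", {
  tr <- rbind(c(2.2, 2.2), c(3, 0.5))
  # from the origin: ||(3,.5)||_2 = 3.04 < ||(2.2,2.2)||_2 = 3.11,
  # but ||(3,.5)||_4 = 3.00 > ||(2.2,2.2)||_4 = 2.62
  q <- matrix(c(0, 0), 1)
  expect_equal(as.character(knn_classify(tr, c("a", "b"), q, k = 1, p = 2)), "b")
  expect_equal(as.character(knn_classify(tr, c("a", "b"), q, k = 1, p = 4)), "a")
})

test_that("cross-validated tuning is reproducible and sane", {
  cl <- make_clusters(60, seed = 33)
  g1 <- knn_grid(k = 7, p = 2)
  t1 <- tune_knn(cl$x, cl$cl, grid = g1, folds = 5, seed = 3)
  expect_equal(t1$best$k, 7)  # single-config grid returns that config
  # perfectly separable data: k = 1 reaches CV accuracy 1
  far <- make_clusters(30, sep = 40, seed = 34)
  tf <- tune_knn(far$x, far$cl, grid = knn_grid(k = 1, p = 2), folds = 5, seed = 3)
  expect_equal(tf$cv_accuracy, 1.0)
  # identical seed, identical selection; tie-break toward smaller k then p
  g <- knn_grid(k = c(5, 10), p = c(2, 4))
  a <- tune_knn(cl$x, cl$cl, grid = g, folds = 5, seed = 11)
  b <- tune_knn(cl$x, cl$cl, grid = g, folds = 5, seed = 11)
  expect_identical(a, b)
  expect_error(tune_knn(cl$x[1:8, ], cl$cl[1:8], folds = 10), "fewer specimens")
  one_low <- factor(c("low", rep("high", 59)), levels = c("low", "high"))
  expect_error(tune_knn(cl$x[1:60, ], one_low, folds = 5, seed = 1), "absent")
})

test_that("confusion partition crosses truth with prediction", {
  hh <- partition_confusion(rep(c("high", "low"), each = 4),
                            rep(c("high", "low"), each = 4))
  expect_equal(unname(hh$counts), c(4, 0, 4, 0))  # TN, FN, TP, FP
  inv <- partition_confusion(rep(c("high", "low"), each = 4),
                             rep(c("low", "high"), each = 4))
  expect_equal(unname(inv$counts[c("TN", "TP")]), c(0, 0))
  four <- partition_confusion(c("high", "high", "low", "low"),
                              c("high", "low", "high", "low"))
  expect_equal(four$counts, c(TN = 1L, FN = 1L, TP = 1L, FP = 1L))
  expect_equal(sum(four$counts), 4)
  expect_equal(four$category, c("TN", "FP", "FN", "TP"))
  expect_error(partition_confusion(c("high"), c("high", "low")), "length")
})

test_that("diagnostic metrics: published counts and identities", {
  m <- diagnostic_metrics(confusion_counts(TN = 96, FN = 4, TP = 85, FP = 10))
  expect_equal(unname(m["accuracy"]), 181 / 195, tolerance = 1e-12)
  expect_equal(round(unname(m["accuracy"]), 2), 0.93)
  expect_equal(unname(m["npv"]), 0.96, tolerance = 1e-12)
  expect_equal(unname(round(m["ppv"], 3)), 0.895)  # prints 0.89 at 2 dp
  expect_equal(unname(round(m["sensitivity"], 3)), 0.955)
  expect_equal(unname(round(m["specificity"], 3)), 0.906)

  expect_true(all(diagnostic_metrics(confusion_counts(10, 0, 10, 0)) == 1))
  expect_equal(unname(diagnostic_metrics(confusion_counts(0, 5, 0, 5))["accuracy"]), 0)

  # identities over random nonnegative quadruples; NA (not 0) on empty ratios
  set.seed(2)
  for (i in 1:50) {
    ct <- rpois(4, 5)
    if (sum(ct) == 0) ct[1] <- 1
    m <- diagnostic_metrics(confusion_counts(ct[1], ct[2], ct[3], ct[4]))
    expect_equal(unname(m["accuracy"]), (ct[1] + ct[3]) / sum(ct))
    expect_true(all(is.na(m) | (m >= 0 & m <= 1)))
  }
  nb <- diagnostic_metrics(confusion_counts(TN = 5, FN = 0, TP = 0, FP = 0))
  expect_true(is.na(nb[["sensitivity"]]))
  expect_error(diagnostic_metrics(confusion_counts(0, 0, 0, 0)), "empty")
})
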