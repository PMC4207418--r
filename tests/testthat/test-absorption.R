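test_that("ellipse threshold equals the chi-square(2 df) quantile", {
  pts <- cbind(c(0, 1, 0, 2, -1), c(0, 0, 1, 1, -1))
  m95 <- fitEllipse(pts, confidence = 0.95)
  expect_equal(m95@threshold, -2 * log(0.05), tolerance = 1e-9)
  m50 <- fitEllipse(pts, confidence = 0.50)
  expect_equal(m50@threshold, -2 * log(0.5), tolerance = 1e-9)
})

test_that("ellipse fit recovers mean and covariance of a normal cloud", {
  cl <- simulateAbsorptionClouds(nWell = 4000, nPoor = 0, seed = 1)
  m <- fitEllipse(cl[, c("alogp", "psa")])
  expect_equal(m@mean, c(2.5, 60), tolerance = 0.05)
  expect_equal(m@covariance[1, 1], 1.5^2, tolerance = 0.1)
  expect_equal(m@covariance[2, 2], 25^2, tolerance = 0.1)
  expect_equal(m@covariance[1, 2] / (1.5 * 25), -0.3, tolerance = 0.15)
})

test_that("ellipse classification: centre, far point, inclusive boundary", {
  pts <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(0.5, 0.5), c(-0.5, -0.5))
  m <- fitEllipse(pts, confidence = 0.95)
  expect_equal(ellipseClassify(m, m@mean), "well")
  far <- m@mean + c(10 * sqrt(m@covariance[1, 1]), 0)
  expect_equal(ellipseClassify(m, far), "poor")
  # boundary point at exactly the threshold distance is well
  ev <- eigen(m@covariance)
  dir1 <- ev$vectors[, 1]
  boundary <- m@mean + sqrt(m@threshold * ev$values[1]) * dir1
  expect_equal(ellipseClassify(m, boundary), "well")
  expect_equal(
    unname(stats::mahalanobis(rbind(boundary), m@mean, m@covariance)),
    m@threshold,
    tolerance = 1e-9
  )
})

test_that("ellipse classification is affine invariant", {
  cl <- simulateAbsorptionClouds(nWell = 300, nPoor = 300, seed = 4)
  P <- as.matrix(cl[, c("alogp", "psa")])
  train <- P[cl$class == "well", ]
  A <- matrix(c(2, 0.5, -1, 3), 2, 2)
  b <- c(10, -5)
  m1 <- fitEllipse(train)
  m2 <- fitEllipse(t(A %*% t(train) + b))
  q1 <- ellipseClassify(m1, P)
  q2 <- ellipseClassify(m2, t(A %*% t(P) + b))
  expect_identical(q1, q2)
})

test_that("misclassification rate: exact cases and label-flip complement", {
  pts <- rbind(c(0, 0), c(0.1, 0.1), c(-0.1, 0), c(50, 50))
  m <- fitEllipse(pts[1:3, ] + matrix(rnorm(6, 0, 1e-3), 3, 2))
  labels <- c("well", "well", "well", "poor")
  pred <- ellipseClassify(m, pts)
  rate <- misclassificationRate(m, pts, labels)
  expect_equal(rate, mean(pred != labels))
  flipped <- ifelse(labels == "well", "poor", "well")
  expect_equal(misclassificationRate(m, pts, flipped), 1 - rate)
  hand <- fitEllipse(rbind(c(-1, 0), c(1, 0), c(0, 1), c(0, -1)))
  handPts <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(9, 9))
  expect_equal(
    misclassificationRate(hand, handPts, c("well", "well", "well", "well")),
    0.25
  )
  expect_error(misclassificationRate(m, pts[0, ], character()), "empty")
})

test_that("fresh draws from the fitted normal fall inside at ~95%", {
  cl <- simulateAbsorptionClouds(nWell = 3000, nPoor = 0, seed = 11)
  m <- fitEllipse(cl[, c("alogp", "psa")])
  fresh <- simulateAbsorptionClouds(nWell = 3000, nPoor = 0, seed = 12)
  inside <- mean(ellipseClassify(m, fresh[, c("alogp", "psa")]) == "well")
  expect_equal(inside, 0.95, tolerance = 0.015)
})

test_that("tree handles one-class input with a single majority leaf", {
  pts <- cbind(runif(20), runif(20))
  tr <- fitTree(pts, rep("well", 20))
  expect_equal(BioavailQSPR:::.treeDepth(tr@nodes), 0L)
  expect_true(all(treeClassify(tr, pts) == "well"))
})

test_that("tree separates an axis-aligned PSA split at depth 1", {
  set.seed(21)
  well <- cbind(rnorm(40, 2, 1), runif(40, 20, 120))
  poor <- cbind(rnorm(40, 2, 1), runif(40, 160, 250))
  P <- rbind(well, poor)
  colnames(P) <- c("alogp", "psa")
  lab <- rep(c("well", "poor"), each = 40)
  tr <- fitTree(P, lab)
  expect_equal(BioavailQSPR:::.treeDepth(tr@nodes), 1L)
  expect_equal(tr@nodes$feature, 2) # split on psa
  expect_gt(tr@nodes$threshold, 120)
  expect_lt(tr@nodes$threshold, 160)
  expect_equal(misclassificationRate(tr, P, lab), 0)
})

test_that("XOR-arranged clusters need depth at least 2", {
  # deterministic XOR grid: within each column the two classes share
  # identical coordinate multisets, so interior cuts carry no Gini
  # gain and the greedy splitter must take the between-column cut;
  # the class imbalance (15 vs 6 per corner) makes that cut's gain
  # positive (a perfectly balanced XOR stalls any greedy splitter)
  blk <- function(xs, ys) as.matrix(expand.grid(xs, ys))
  xs <- c(0, 0.1, 0.2)
  yb <- seq(0, 0.2, length.out = 5)
  yt <- c(1, 1.2)
  P <- rbind(blk(xs, yb), blk(1 + xs, 1 + yt),
             blk(xs, 1 + yt), blk(1 + xs, yb))
  colnames(P) <- c("alogp", "psa")
  lab <- rep(c("well", "well", "poor", "poor"), times = c(15, 6, 6, 15))
  shallow <- fitTree(P, lab, maxDepth = 1)
  expect_gt(misclassificationRate(shallow, P, lab), 0)
  deep <- fitTree(P, lab, maxDepth = 2)
  expect_equal(misclassificationRate(deep, P, lab), 0)
})

test_that("training error is non-increasing in tree depth", {
  cl <- simulateAbsorptionClouds(nWell = 150, nPoor = 150, seed = 31)
  P <- as.matrix(cl[, c("alogp", "psa")])
  errs <- vapply(0:5, function(d) {
    misclassificationRate(fitTree(P, cl$class, maxDepth = d), P, cl$class)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("tree accuracy is comparable to rpart on the same cloud", {
  skip_if_not_installed("rpart")
  cl <- simulateAbsorptionClouds(nWell = 200, nPoor = 200, seed = 41)
  P <- data.frame(alogp = cl$alogp, psa = cl$psa)
  tr <- fitTree(as.matrix(P), cl$class, maxDepth = 4, minLeaf = 5)
  ours <- 1 - misclassificationRate(tr, as.matrix(P), cl$class)
  rp <- rpart::rpart(
    cls ~ alogp + psa, data = cbind(P, cls = factor(cl$class)),
    method = "class",
    control = rpart::rpart.control(maxdepth = 4, minbucket = 5, cp = 0.001)
  )
  theirs <- mean(predict(rp, P, type = "class") == cl$class)
  expect_lt(abs(ours - theirs), 0.05)
})
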