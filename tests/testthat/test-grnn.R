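# Naive kernel-regression oracle: direct double loop, no
# stabilization, raw feature space.
bruteKernelRegression <- function(X, y, Q, sigma) {
  vapply(seq_len(nrow(Q)), function(i) {
    w <- vapply(seq_len(nrow(X)), function(j) {
      exp(-sum((Q[i, ] - X[j, ])^2) / (2 * sigma^2))
    }, numeric(1))
    sum(w * y) / sum(w)
  }, numeric(1))
}

test_that("midpoint symmetry: equal kernel weights average the targets", {
  m <- grnnModel(matrix(c(0, 1), ncol = 1), c(0, 10), sigma = 1, scale = FALSE)
  expect_equal(grnnPredict(m, 0.5), 5, tolerance = 1e-12)
})

test_that("sigma limits: exact interpolation and global-mean convergence", {
  set.seed(5)
  X <- matrix(rnorm(100), ncol = 2)
  y <- runif(50, 0, 100)
  tiny <- grnnModel(X, y, sigma = 1e-4, scale = FALSE)
  for (i in c(1, 17, 50)) {
    expect_equal(grnnPredict(tiny, X[i, ]), y[i], tolerance = 1e-6)
  }
  huge <- grnnModel(X, y, sigma = 1e6, scale = FALSE)
  expect_equal(grnnPredict(huge, c(0.3, -0.8)), mean(y), tolerance = 1e-6)
  expect_equal(grnnPredict(huge, X[9, ]), mean(y), tolerance = 1e-6)
})

test_that("predictions are convex combinations of the training targets", {
  set.seed(6)
  X <- matrix(rnorm(300), ncol = 3)
  y <- runif(100, 0, 100)
  for (sigma in c(0.05, 0.5, 2, 20)) {
    m <- grnnModel(X, y, sigma = sigma, scale = FALSE)
    q <- matrix(rnorm(60, sd = 2), ncol = 3)
    p <- grnnPredictBatch(m, as.data.frame(`colnames<-`(q, m@columns)))
    expect_true(all(p$predicted >= min(y) - 1e-9))
    expect_true(all(p$predicted <= max(y) + 1e-9))
  }
})

test_that("batch prediction equals looped single prediction", {
  tab <- simulateDescriptorTable(n = 40, seed = 2)
  m <- grnnModel(tab[, descriptorNames("model")], tab$F, sigma = 0.8)
  batch <- grnnPredictBatch(m, tab)
  single <- vapply(seq_len(nrow(tab)), function(i) {
    grnnPredict(m, as.numeric(tab[i, m@columns]))
  }, numeric(1))
  expect_equal(batch$predicted, single, tolerance = 1e-12)
  # permuting rows permutes predictions with them
  perm <- sample(nrow(tab))
  shuffled <- grnnPredictBatch(m, tab[perm, ])
  expect_equal(shuffled$predicted, batch$predicted[perm], tolerance = 1e-12)
})

test_that("stabilized prediction matches the naive kernel oracle", {
  set.seed(8)
  X <- matrix(rnorm(60), ncol = 2)
  y <- runif(30, 0, 100)
  Q <- matrix(rnorm(24), ncol = 2)
  for (sigma in c(0.7, 1.5, 4)) {
    m <- grnnModel(X, y, sigma = sigma, scale = FALSE)
    got <- grnnPredictBatch(m, as.data.frame(`colnames<-`(Q, m@columns)))
    expect_equal(got$predicted, bruteKernelRegression(X, y, Q, sigma),
                 tolerance = 1e-10)
  }
})

test_that("bandwidth selection minimizes test RMSE over the bracket", {
  tab <- simulateDescriptorTable(n = 240, seed = 13)
  train <- tab[1:160, ]
  test <- tab[161:240, ]
  m <- fitGRNN(train, test)
  tr <- m@trace
  expect_gt(nrow(tr), 10)
  obj <- function(sigma) {
    mm <- grnnModel(train[, m@columns], train$F, sigma = sigma)
    p <- grnnPredictBatch(mm, test)
    sqrt(mean((test$F - p$predicted)^2))
  }
  atSelected <- obj(m@sigma)
  expect_lte(atSelected, obj(10^-3) + 1e-9)
  expect_lte(atSelected, obj(10^2) + 1e-9)
  expect_lte(atSelected, min(tr$test_rmse) + 1e-6)
})

test_that("noisy smooth signal: selected sigma beats the noise floor x2", {
  tab <- simulateDescriptorTable(n = 600, seed = 17, noiseSd = 5)
  m <- fitGRNN(tab[1:400, ], tab[401:600, ])
  expect_lt(min(m@trace$test_rmse), 2 * 5 + 2.5)
})

test_that("empty test set falls back to leave-one-out selection", {
  tab <- simulateDescriptorTable(n = 80, seed = 19)
  m <- fitGRNN(tab, test = NULL)
  expect_s4_class(m, "GRNNModel")
  expect_gt(m@sigma, 10^-3)
  expect_lt(m@sigma, 10^2)
})

test_that("a training row duplicated into test is interpolated exactly", {
  tab <- simulateDescriptorTable(n = 50, seed = 23)
  m <- grnnModel(tab[, descriptorNames("model")], tab$F, sigma = 0.01)
  dup <- tab[7, ]
  p <- grnnPredictBatch(m, dup)
  expect_equal(p$predicted, tab$F[7], tolerance = 1e-6)
})

test_that("column mismatches are reported by name", {
  tab <- simulateDescriptorTable(n = 30, seed = 29)
  m <- grnnModel(tab[, descriptorNames("model")], tab$F, sigma = 1)
  broken <- tab[, setdiff(names(tab), "hasa2")]
  expect_error(grnnPredictBatch(m, broken), "hasa2")
})
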