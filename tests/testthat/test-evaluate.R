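test_that("a perfect estimate scores perfectly", {
  adj <- matrix(FALSE, 3, 3)
  adj[3, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  m <- scoreNetwork(fakeEstimate(adj), fakeTruth(adj))
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$fdr, 0)
  expect_equal(m$tp + m$fp + m$fn + m$tn, 6)  # p(p-1) pairs
})

test_that("confusion counts give the textbook metric values", {
  truth <- matrix(FALSE, 3, 3); truth[3, 1] <- truth[2, 3] <- truth[3, 2] <- TRUE
  est <- matrix(FALSE, 3, 3);  est[3, 1] <- est[2, 3] <- est[1, 2] <- TRUE
  m <- scoreNetwork(fakeEstimate(est), fakeTruth(truth))
  expect_equal(m[, c("tp", "fp", "fn")], data.frame(tp = 2, fp = 1, fn = 1))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$fdr, 1 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
})

test_that("empty predictions use the stated conventions", {
  truth <- matrix(FALSE, 3, 3); truth[1, 2] <- TRUE
  m <- scoreNetwork(fakeEstimate(matrix(FALSE, 3, 3)), fakeTruth(truth))
  expect_equal(m$precision, 0)
  expect_equal(m$fdr, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
})

test_that("scoring identities hold for arbitrary estimate/truth pairs", {
  set.seed(61)
  for (r in 1:30) {
    p <- sample(3:6, 1)
    est <- matrix(runif(p * p) < 0.4, p, p)
    tru <- matrix(runif(p * p) < 0.3, p, p); diag(tru) <- FALSE
    m <- scoreNetwork(fakeEstimate(est), fakeTruth(tru))
    expect_equal(m$tp + m$fp + m$fn + m$tn, p * (p - 1))
    if (m$tp + m$fp > 0) expect_equal(m$fdr, 1 - m$precision)
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  }
})

test_that("self edges enter the score only on request", {
  est <- diag(TRUE, 3)
  truth <- fakeTruth(matrix(FALSE, 3, 3), self = c(TRUE, TRUE, FALSE))
  mOff <- scoreNetwork(fakeEstimate(est), truth)
  expect_equal(mOff$tp + mOff$fp, 0)  # diagonal ignored
  mOn <- scoreNetwork(fakeEstimate(est), truth, includeSelf = TRUE)
  expect_equal(mOn$tp, 2)
  expect_equal(mOn$fp, 1)
  expect_equal(mOn$tp + mOn$fp + mOn$fn + mOn$tn, 9)
})

test_that("shape mismatches are rejected", {
  expect_error(scoreNetwork(fakeEstimate(matrix(FALSE, 3, 3)),
                            fakeTruth(matrix(FALSE, 4, 4))), "different")
})

test_that("a single-replicate benchmark equals one scored inference run", {
  res <- runBenchmark("dataset1", TGrid = 60, replicates = 1, baseSeed = 100,
                      methods = "elastic_net_copula")
  sim <- simulateDataset1(60, seed = 101)   # baseSeed + r with r = 1
  one <- scoreNetwork(inferNetwork(sim$series, L = 2), sim$truth)
  expect_equal(res$precision, one$precision)
  expect_equal(res$recall, one$recall)
  expect_equal(res$fdr, one$fdr)
  expect_equal(res$f1, one$f1)
})

test_that("benchmark rows carry the requested methods and averages of F1", {
  res <- runBenchmark("dataset1", TGrid = 50, replicates = 4, baseSeed = 7)
  expect_setequal(unique(res$method), c("elastic_net_copula", "lasso_copula"))
  # mean of per-replicate F1, not F1 of mean precision/recall
  f1s <- vapply(1:4, function(r) {
    sim <- simulateDataset1(50, seed = 7 + r)
    scoreNetwork(inferNetwork(sim$series, L = 2), sim$truth)$f1
  }, numeric(1))
  expect_equal(res$f1[res$method == "elastic_net_copula"], mean(f1s))
  expect_true(all(res$failures == 0))
})

test_that("the LASSO-copula harness is the alpha = 1 slice of the machinery", {
  res <- runBenchmark("dataset1", TGrid = 40, replicates = 2, baseSeed = 3,
                      methods = "lasso_copula")
  sim <- simulateDataset1(40, seed = 4)
  direct <- scoreNetwork(inferNetwork(sim$series, L = 2,
                                      config = penaltyConfig(alphaGrid = 1)),
                         sim$truth)
  sim2 <- simulateDataset1(40, seed = 5)
  direct2 <- scoreNetwork(inferNetwork(sim2$series, L = 2,
                                       config = penaltyConfig(alphaGrid = 1)),
                          sim2$truth)
  expect_equal(res$recall, mean(c(direct$recall, direct2$recall)))
})
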