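test_that("lambda = 0 reproduces ordinary least squares", {
  set.seed(31)
  X <- standardizeCols(matrix(rnorm(200), 40, 5))
  y <- rnorm(40); y <- y - mean(y)
  for (a in c(0.3, 1)) {
    expect_equal(unname(elasticNetFit(X, y, 0, a)),
                 unname(qr.coef(qr(X), y)), tolerance = 1e-7)
  }
})

test_that("lambda at or above lambda_max shrinks everything to zero", {
  set.seed(32)
  X <- standardizeCols(matrix(rnorm(300), 50, 6))
  y <- X[, 2] + rnorm(50); y <- y - mean(y)
  n <- nrow(X)
  for (a in c(0.4, 1)) {
    lamMax <- max(abs(crossprod(X, y))) / (n * a)
    expect_true(all(elasticNetFit(X, y, lamMax, a) == 0))
    expect_true(all(elasticNetFit(X, y, lamMax * 2, a) == 0))
  }
})

test_that("orthonormal design matches the soft-threshold closed form", {
  set.seed(33)
  n <- 32; m <- 5
  Q <- qr.Q(qr(matrix(rnorm(n * m), n, m)))
  X <- sqrt(n) * Q                      # X'X / n = I
  y <- rnorm(n, sd = 2)
  b <- crossprod(X, y)[, 1] / n
  for (a in c(0.25, 0.6, 1)) {
    for (lam in c(0.05, 0.5)) {
      closed <- sign(b) * pmax(abs(b) - lam * a, 0) / (1 + lam * (1 - a))
      expect_equal(unname(elasticNetFit(X, y, lam, a)), closed,
                   tolerance = 1e-7)
    }
  }
})

test_that("coordinate descent matches an independent convex solver", {
  set.seed(34)
  for (r in 1:5) {
    X <- standardizeCols(matrix(rnorm(20 * 10), 20, 10))
    y <- X %*% rnorm(10, sd = 0.5) + rnorm(20)
    y <- as.numeric(y - mean(y))
    a <- sample(c(0.2, 0.5, 0.8, 1), 1)
    lam <- runif(1, 0.02, 0.4)
    mine <- elasticNetFit(X, y, lam, a)
    oracle <- fistaEnet(X, y, lam, a)
    expect_lt(max(abs(mine - oracle)), 1e-5)
    expect_lte(enetObjective(X, y, mine, lam, a),
               enetObjective(X, y, oracle, lam, a) + 1e-10)
  }
})

test_that("coordinate descent agrees with glmnet once response scaling is aligned", {
  set.seed(35)
  for (r in 1:5) {
    X <- standardizeCols(matrix(rnorm(50 * 8), 50, 8))
    y <- X[, 1] * 1.5 - X[, 3] + rnorm(50)
    y <- y - mean(y)
    y <- y / sqrt(mean(y^2))  # glmnet standardizes the response internally
    a <- sample(c(0.2, 0.5, 1), 1)
    lam <- runif(1, 0.01, 0.5)
    g <- glmnet::glmnet(X, y, alpha = a, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(elasticNetFit(X, y, lam, a) -
                        as.numeric(stats::coef(g))[-1])), 1e-5)
  }
})

test_that("AIC has its closed Gaussian form and prefers sparser fits at equal RSS", {
  expect_equal(aicScore(rss = 50, df = 0, n = 50), 0)
  expect_lt(aicScore(10, df = 2, n = 30), aicScore(10, df = 5, n = 30))
  # 50*ln(10/9) = 5.268 < 2*(5-2) = 6: the rss=10/df=2 fit wins
  expect_lt(aicScore(10, 2, 50), aicScore(9, 5, 50))
  expect_error(aicScore(-1, 0, 10), "rss")
  expect_equal(aicScore(0, 0, 10), 10 * log(1e-12 / 10))  # log(0) guard
})

test_that("path selection stays empty on pure noise", {
  set.seed(36)
  dfs <- replicate(60, {
    v <- matrix(rnorm(201 * 1), 201, 1)
    d <- buildLaggedDesign(cbind(v, matrix(rnorm(201 * 10), 201)), 1, 1)
    # response is column 1's future, predictors include 10 noise series
    fitPath(d)@df
  })
  expect_equal(median(dfs), 0)
})

test_that("path selection finds a strong single predictor", {
  set.seed(37)
  hits <- replicate(100, {
    n <- 200
    X <- matrix(rnorm(n * 10), n, 10)
    y <- 0.9 * X[, 4] + rnorm(n, sd = 0.1)
    d <- new("LaggedDesign", target = 1L, response = y, predictors = X,
             columnMap = data.frame(source = 1:10, lag = rep(1L, 10)),
             L = 1L)
    abs(fitPath(d)@coefficients[4]) > 1e-8
  })
  expect_gte(mean(hits), 0.95)
})

test_that("alpha grid of {1} is the LASSO baseline's selection problem", {
  sim <- simulateDataset1(150, seed = 5)
  d <- buildLaggedDesign(copulaTransform(sim$series), 2, 2)
  f <- fitPath(d, penaltyConfig(alphaGrid = 1))
  expect_equal(f@alpha, 1)
  # identical to the alpha = 1 slice of the full grid machinery
  fFull <- fitPath(d, penaltyConfig(alphaGrid = c(0.5, 1)))
  if (fFull@alpha == 1) expect_equal(f@coefficients, fFull@coefficients)
})

test_that("zero-variance predictor columns are dropped as exact zeros", {
  set.seed(38)
  X <- cbind(matrix(rnorm(60), 30, 2), 0)
  y <- X[, 1] + rnorm(30, sd = 0.2)
  d <- new("LaggedDesign", target = 1L, response = y, predictors = X,
           columnMap = data.frame(source = 1:3, lag = rep(1L, 3)), L = 1L)
  expect_warning(f <- fitPath(d), "zero-variance")
  expect_identical(f@coefficients[3], 0)
  expect_gt(abs(f@coefficients[1]), 0)
})

test_that("df trends downward in lambda along a fixed-alpha path", {
  set.seed(39)
  # statistical check: average Spearman correlation between lambda and df
  # over random instances is strongly negative
  rho <- replicate(20, {
    X <- standardizeCols(matrix(rnorm(60 * 8), 60, 8))
    y <- X %*% rnorm(8) + rnorm(60)
    y <- as.numeric(y - mean(y))
    n <- nrow(X)
    lamMax <- max(abs(crossprod(X, y))) / n
    lams <- exp(seq(log(lamMax), log(lamMax * 0.01), length.out = 20))
    dfs <- vapply(lams, function(l) sum(abs(elasticNetFit(X, y, l, 1)) > 1e-8),
                  numeric(1))
    suppressWarnings(cor(lams, dfs, method = "spearman"))
  })
  expect_lt(mean(rho, na.rm = TRUE), -0.8)
})

test_that("invalid solver inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(elasticNetFit(X, rnorm(10), -0.1, 1), "lambda")
  expect_error(elasticNetFit(X, rnorm(10), 0.1, 0), "alpha")
  X[1, 1] <- Inf
  expect_error(elasticNetFit(X, rnorm(10), 0.1, 1), "finite")
})
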