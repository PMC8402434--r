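test_that("PLS1 fits a rank-one problem exactly with one component", {
  set.seed(1)
  t <- rnorm(25)
  p <- rnorm(8)
  x <- tcrossprod(t, p)
  y <- 2 * t + 3
  m <- fitPLS1(x, y, nLV = 1L)
  expect_lt(max(abs(predict(m, x) - y)), 1e-10)
})

test_that("PLS1 beta matches independent oracles on random problems", {
  skip_if_not_installed("mixOmics")
  set.seed(2)
  for (rep in 1:20) {
    n <- 30L; p <- 20L; F <- 5L
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("V", seq_len(p))))
    y <- rnorm(n)
    m <- fitPLS1(x, y, nLV = F)
    # oracle 1: Krylov-subspace closed form
    expect_equal(m@coefficients, plsKrylovBeta(x, y, F), tolerance = 1e-8)
    # oracle 2: reference library predictions (every 5th replicate)
    if (rep %% 5L == 0L) {
      ref <- mixOmics::pls(x, y, ncomp = F, mode = "regression",
                           scale = FALSE)
      pref <- predict(ref, x)$predict[, 1L, F]
      expect_equal(unname(predict(m, x)), unname(pref), tolerance = 1e-8)
    }
  }
})

test_that("PLS1 at full rank reproduces the least-squares solution", {
  set.seed(3)
  n <- 40L; p <- 6L
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  m <- fitPLS1(x, y, nLV = p)
  xc <- sweep(x, 2L, colMeans(x))
  betaOLS <- as.vector(solve(crossprod(xc), crossprod(xc, y - mean(y))))
  expect_equal(m@coefficients, betaOLS, tolerance = 1e-8)
})

test_that("model internals satisfy the PLS1 identities", {
  set.seed(4)
  x <- matrix(rnorm(35 * 12), 35, 12)
  y <- x[, 2] - 0.5 * x[, 7] + rnorm(35, 0, 0.2)
  m <- fitPLS1(x, y, nLV = 6L)
  # factorization-path prediction equals the beta path
  xc <- sweep(x, 2L, m@xMean)
  Wstar <- m@weights %*% solve(crossprod(m@loadings, m@weights))
  predFact <- as.vector(xc %*% Wstar %*% m@yLoadings + m@yMean)
  expect_equal(predict(m, x), predFact, tolerance = 1e-10)
  # centring: prediction at the training mean is the response mean
  expect_equal(predict(m, matrix(m@xMean, 1L)), m@yMean, tolerance = 1e-10)
  # linearity: prediction of a mean spectrum = mean of predictions
  sub <- x[1:7, ]
  expect_equal(predict(m, matrix(colMeans(sub), 1L)),
               mean(predict(m, sub)), tolerance = 1e-10)
  # explained-Y bookkeeping
  expect_true(all(m@ssyF >= 0))
  expect_lte(sum(m@ssyF), m@ssyTotal + 1e-8)
  # monotone training fit in the component count
  rss <- vapply(1:6, function(f)
    sum((predict(fitPLS1(x, y, f), x) - y)^2), numeric(1L))
  expect_true(all(diff(rss) <= 1e-10))

  expect_error(fitPLS1(x, rep(1, 35), 2L), "variance")
  expect_error(fitPLS1(x, y, 40L), "nLV")
  expect_error(predict(m, x[, 1:5]), "band axis")
})

test_that("cross-validated component choice finds planted dimensionality", {
  hits <- vapply(1:20, function(s) {
    set.seed(s + 40L)
    n <- 60L; p <- 20L
    scoresT <- matrix(rnorm(n * 3L), n, 3L)
    load <- matrix(rnorm(3L * p), 3L, p)
    x <- scoresT %*% load + matrix(rnorm(n * p, 0, 0.05), n, p)
    y <- scoresT %*% c(1, -2, 1.5) + rnorm(n, 0, 0.05)
    chooseNLV(x, as.vector(y), maxLV = 10L, folds = 5L, seed = s)
  }, integer(1L))
  expect_gte(sum(hits %in% 3:4), 18L)
})

test_that("component choice degenerate cases", {
  set.seed(5)
  x <- matrix(rnorm(30 * 8), 30, 8)
  y <- x[, 1] + rnorm(30, 0, 0.1)
  expect_identical(as.integer(chooseNLV(x, y, maxLV = 1L, seed = 1L)), 1L)
  # duplicating every sample does not change the choice
  a <- chooseNLV(x, y, maxLV = 6L, folds = 3L, seed = 7L)
  b <- chooseNLV(rbind(x, x), c(y, y), maxLV = 6L, folds = 3L, seed = 7L)
  expect_identical(as.integer(a), as.integer(b))
  expect_error(chooseNLV(x, y, folds = 1L, seed = 1L), "folds")
})

test_that("nearest-code classification honours ties and affine maps", {
  enc <- encodeGroupsSPRI(c("BH", "AR", "AS"))
  expect_identical(classifyScores(c(-10, 49, 95), enc),
                   c("BH", "AR", "AS"))
  # tie at the midpoint goes to the lower code
  two <- encodeGroupsSPRI(c("BH", "AS"))
  expect_identical(classifyScores(50, two), "BH")
  expect_identical(classifyScores(25, encodeGroupsSPRI(c("BH", "AS"))), "BH")

  # joint strictly-increasing affine maps leave assignments unchanged
  set.seed(6)
  for (rep in 1:10) {
    sc <- runif(40, -30, 130)
    a <- runif(1, 0.2, 4); b <- runif(1, -50, 50)
    # nearest-code assignment under the jointly mapped scores and codes
    codes2 <- a * groupCodes(enc)[enc@groupOrder] + b
    got <- vapply(a * sc + b, function(s)
      enc@groupOrder[which.min(abs(s - codes2))], character(1L))
    expect_identical(classifyScores(sc, enc), got)
  }
})

test_that("accuracy accounting reproduces the published worked examples", {
  # validation row with totals (126, 64, 48) and correct (110, 57, 22)
  at <- accuracyFromCounts(c(BH = 126L, AR = 64L, AS = 48L),
                           c(BH = 110L, AR = 57L, AS = 22L))
  d <- displayAccuracy(at)
  expect_equal(unname(d$perGroup), c(87.3, 89.1, 45.8))
  expect_equal(d$overall, 74.1)

  at2 <- accuracyFromCounts(c(126L, 42L, 56L), c(125L, 41L, 56L))
  d2 <- displayAccuracy(at2)
  expect_equal(unname(d2$perGroup), c(99.2, 97.6, 100.0))
  expect_equal(d2$overall, 98.9)

  all100 <- accuracyFromCounts(c(10L, 5L), c(10L, 5L))
  expect_equal(unname(displayAccuracy(all100)$perGroup), c(100, 100))
  expect_equal(displayAccuracy(all100)$overall, 100)

  # label-based path agrees with the count-based path
  truth <- rep(c("BH", "AS"), c(4L, 4L))
  pred <- c("BH", "BH", "BH", "AS", "AS", "AS", "AS", "BH")
  at3 <- accuracyTable(pred, truth, c("BH", "AS"))
  expect_equal(at3@counts$correct, c(3L, 3L))
  expect_equal(at3@overall, 75)
  expect_error(accuracyTable(pred[1:3], truth, c("BH", "AS")), "length")
})

test_that("the macro overall is the unweighted mean, not the pooled rate", {
  at <- accuracyFromCounts(c(126L, 64L, 48L), c(110L, 57L, 22L))
  pooled <- 100 * (110 + 57 + 22) / (126 + 64 + 48)
  expect_equal(displayAccuracy(at)$overall, 74.1)
  expect_gt(abs(pooled - at@overall), 4)   # pooled would print 79.4
})

test_that("VIP satisfies the mean-square identity and flags relevant bands", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(20:40, 1L); p <- sample(8:25, 1L)
    x <- matrix(rnorm(n * p), n, p)
    y <- x %*% rnorm(p) + rnorm(n, 0, 0.3)
    m <- fitPLS1(x, as.vector(y), nLV = sample(2:5, 1L))
    v <- vipScores(m)
    expect_true(all(v >= 0))
    expect_equal(mean(v^2), 1, tolerance = 1e-10)
  }

  # single relevant band dominates on a 5-band toy
  set.seed(8)
  x <- matrix(rnorm(50 * 5), 50, 5)
  y <- x[, 3]
  m <- fitPLS1(x, y, nLV = 2L)
  expect_identical(which.max(vipScores(m)), 3L)

  # one component: VIP proportional to |w|, scaled to mean square 1
  m1 <- fitPLS1(x, y, nLV = 1L)
  w <- m1@weights[, 1L]
  expect_equal(vipScores(m1), sqrt(5) * abs(w) / sqrt(sum(w^2)),
               tolerance = 1e-10)
})

test_that("noise-free synthetic spectra classify perfectly with two components", {
  arch <- makeArchetypes("visnir", nBands = 48L, seed = 9L)
  st <- simulateSpectra(arch, c(BH = 20L, AR = 20L, AS = 20L),
                        noiseConfig(0, 0, 0, 1, 0, 0, seed = 1L))
  enc <- encodeGroupsSPRI(c("BH", "AR", "AS"))
  y <- codesFor(enc, sampleGroups(st))
  m <- fitPLS1(spectra(st), y, nLV = 2L)
  pred <- classifyScores(predict(m, spectra(st)), enc)
  expect_identical(pred, sampleGroups(st))
})
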