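test_that("LDA recovers the obvious axis in one dimension", {
  set.seed(1)
  x <- matrix(c(rnorm(30, -3, 0.5), rnorm(30, 3, 0.5)), ncol = 1L)
  g <- rep(c("BH", "AS"), each = 30L)
  m <- fitLDA(x, g, shrinkage = 0)
  expect_equal(abs(m@axes[1L, 1L]), 1)
  expect_lt(m@groupCenters1D[["BH"]], m@groupCenters1D[["AS"]])
})

test_that("projected group centres match a brute-force oracle", {
  tab <- makeToyTable(n = 12L, p = 8L, sep = 1.5, seed = 2L)
  m <- fitLDA(tab, shrinkage = 0.1)
  x <- spectra(tab)
  g <- sampleGroups(tab)
  proj <- sweep(x, 2L, m@centering) %*% m@axes[, m@chosenAxis]
  for (grp in unique(g))
    expect_equal(m@groupCenters1D[[grp]], mean(proj[g == grp]),
                 tolerance = 1e-10)
})

test_that("full shrinkage reduces to the standardized mean difference", {
  set.seed(3)
  n <- 40L; p <- 6L
  x <- matrix(rnorm(2 * n * p), 2L * n, p)
  shift <- c(2, -1, 0.5, 0, 0, 1)
  x[(n + 1):(2 * n), ] <- x[(n + 1):(2 * n), ] +
    matrix(shift, n, p, byrow = TRUE)
  g <- rep(c("A", "B"), each = n)
  m <- fitLDA(x, g, shrinkage = 1, referenceGroup = "A")
  # closed form in the diagonal limit: axis ~ diag(Sw)^{-1} (m2 - m1)
  m1 <- colMeans(x[g == "A", ]); m2 <- colMeans(x[g == "B", ])
  Sw <- matrix(0, p, p)
  for (gg in c("A", "B")) {
    xc <- sweep(x[g == gg, ], 2L, colMeans(x[g == gg, ]))
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / (2L * n - 2L)
  ref <- (m2 - m1) / diag(Sw)
  ref <- ref / sqrt(sum(ref^2))
  got <- m@axes[, 1L]
  expect_equal(abs(sum(got * ref)), 1, tolerance = 1e-8)
})

test_that("singular within-class scatter demands shrinkage", {
  set.seed(4)
  x <- matrix(rnorm(10 * 30), 10, 30)       # p > n: singular scatter
  g <- rep(c("A", "B"), each = 5L)
  expect_error(fitLDA(x, g, shrinkage = 0), "shrinkage")
  expect_s4_class(fitLDA(x, g, shrinkage = 0.2), "LDAModel")
})

test_that("best projection values centre, translate and variance-ratio correctly", {
  tab <- makeToyTable(n = 10L, p = 6L, sep = 2, seed = 5L)
  m <- fitLDA(tab, shrinkage = 0.1)
  x <- spectra(tab)

  # sample at the global mean projects to exactly zero
  expect_equal(bestProjectionValues(m, matrix(m@centering, 1L)), 0,
               tolerance = 1e-12)

  # translation invariance: a constant shift of every spectrum is
  # absorbed by the centring, so refitting on shifted data reproduces
  # the projection values
  bpv <- bestProjectionValues(m, x)
  xs <- sweep(x, 2L, rep(-0.37, 6L))
  ms <- fitLDA(xs, sampleGroups(tab), shrinkage = 0.1)
  expect_equal(bestProjectionValues(ms, xs), bpv, tolerance = 1e-8)

  # between/within variance ratio along the axis equals the eigenvalue
  g <- sampleGroups(tab)
  glev <- sort(unique(g))
  p <- ncol(x)
  xc <- sweep(x, 2L, colMeans(x))
  means <- do.call(rbind, lapply(glev, function(gg)
    colMeans(xc[g == gg, , drop = FALSE])))
  Sw <- matrix(0, p, p)
  for (i in seq_along(glev)) {
    xg <- sweep(xc[g == glev[i], , drop = FALSE], 2L, means[i, ])
    Sw <- Sw + crossprod(xg)
  }
  Sw <- Sw / (nrow(x) - length(glev))
  SwReg <- (1 - 0.1) * Sw + 0.1 * diag(diag(Sw), p)
  Sb <- matrix(0, p, p)
  for (i in seq_along(glev))
    Sb <- Sb + sum(g == glev[i]) * tcrossprod(means[i, ])
  Sb <- Sb / (length(glev) - 1L)
  a <- m@axes[, m@chosenAxis]
  ratio <- as.numeric((a %*% Sb %*% a) / (a %*% SwReg %*% a))
  expect_equal(ratio, m@eigenvalues[m@chosenAxis], tolerance = 1e-8)

  expect_error(bestProjectionValues(m, x[, 1:3]), "band axis")
})

test_that("BPV encoding rescales histogram centres to 0..100 codes", {
  # three crisp groups at centres (-2, 1, 2): codes 0 / 75 / 100
  set.seed(6)
  bpv <- c(rnorm(50, -2, 1e-3), rnorm(50, 1, 1e-3), rnorm(50, 2, 1e-3))
  g <- rep(c("BH", "AR", "AS"), each = 50L)
  enc <- encodeGroupsBPV(bpv, g, referenceGroup = "BH")
  expect_equal(unname(enc@codes[c("BH", "AR", "AS")]), c(0, 75, 100))
  expect_identical(enc@groupOrder, c("BH", "AR", "AS"))

  # the reference study's Vis/NIR geometry: centres (0, 0.74, 1.0)
  bpv2 <- c(rnorm(50, 0, 1e-4), rnorm(50, 0.74, 1e-4), rnorm(50, 1, 1e-4))
  enc2 <- encodeGroupsBPV(bpv2, g, referenceGroup = "BH")
  expect_equal(unname(enc2@codes[c("BH", "AR", "AS")]), c(0, 74, 100))

  # permutation invariance
  perm <- sample(length(bpv))
  enc3 <- encodeGroupsBPV(bpv[perm], g[perm], referenceGroup = "BH")
  expect_identical(enc3@codes, enc@codes)

  # degenerate centres are refused
  g3 <- rep(c("BH", "AR", "AS"), each = 5L)
  expect_error(encodeGroupsBPV(c(rep(0, 5), rep(0, 5), rep(1, 5)), g3),
               "degenerate|coincide")
})

test_that("SPRI encoding places codes at regular intervals in given order", {
  enc <- encodeGroupsSPRI(c("BH", "AR", "AS"))
  expect_equal(unname(groupCodes(enc)[c("BH", "AR", "AS")]), c(0, 50, 100))
  # the SWIR ordering swaps the two stressed groups
  encS <- encodeGroupsSPRI(c("BH", "AS", "AR"))
  expect_equal(unname(groupCodes(encS)[c("BH", "AS", "AR")]), c(0, 50, 100))
  two <- encodeGroupsSPRI(c("BH", "AS"))
  expect_equal(unname(groupCodes(two)), c(0, 100))
  expect_error(encodeGroupsSPRI(c("BH", "BH", "AS")), "duplicate")
})

test_that("encoding order matches the BPV centre order and is affine-invariant", {
  for (s in 1:5) {
    tab <- makeToyTable(n = 10L, p = 8L, sep = 1.2, seed = s)
    m <- fitLDA(tab, shrinkage = 0.1)
    bpv <- bestProjectionValues(m, tab)
    g <- sampleGroups(tab)
    enc <- encodeGroupsBPV(bpv, g, referenceGroup = "BH")
    centers <- vapply(enc@groupOrder, function(gg)
      mean(bpv[g == gg]), numeric(1L))
    expect_false(is.unsorted(centers * sign(centers[3L] - centers[1L])))
    # affine transform of the projection scale leaves codes unchanged
    enc2 <- encodeGroupsBPV(3.7 * bpv + 11, g, referenceGroup = "BH")
    expect_identical(enc2@codes, enc@codes)
  }
})

test_that("equidistant archetypes encode near (0, 50, 100) across seeds", {
  codes <- matrix(0, 20L, 3L)
  for (s in 1:20) {
    arch <- makeArchetypes("visnir", nBands = 64L, seed = s,
                           groupPositions = c(BH = 0, AR = 0.5, AS = 1))
    st <- simulateSpectra(arch, c(BH = 120L, AR = 120L, AS = 120L),
                          noiseConfig(seed = s + 500L))
    m <- fitLDA(st, shrinkage = 0.1)
    enc <- encodeGroupsBPV(bestProjectionValues(m, st), sampleGroups(st))
    codes[s, ] <- sort(enc@codes)
  }
  expect_true(all(abs(colMeans(codes) - c(0, 50, 100)) <= 5))
})
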