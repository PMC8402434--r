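test_that("archetypes respect the region grid, ordering and zero-effect limit", {
  arch <- makeArchetypes("visnir", nBands = 128L, effectSize = 0.05,
                         seed = 3L)
  wl <- arch$BH@wavelengths
  expect_equal(range(wl), c(400, 1000))
  expect_equal(diff(wl), rep(diff(wl)[1L], 127L), tolerance = 1e-12)
  # one shared informative set, monotone group means there (visnir order)
  info <- arch$BH@informativeBands
  expect_identical(info, arch$AR@informativeBands)
  expect_identical(info, arch$AS@informativeBands)
  expect_true(all(arch$BH@meanSpectrum[info] < arch$AR@meanSpectrum[info]))
  expect_true(all(arch$AR@meanSpectrum[info] < arch$AS@meanSpectrum[info]))
  # differences confined to the informative set
  outside <- setdiff(seq_along(wl), info)
  expect_equal(arch$BH@meanSpectrum[outside], arch$AS@meanSpectrum[outside])

  swir <- makeArchetypes("swir", nBands = 64L, seed = 1L)
  expect_equal(range(swir$BH@wavelengths), c(1000, 1800))
  sinfo <- swir$BH@informativeBands
  # SWIR convention: the resistant group moves farthest
  expect_true(all(swir$AS@meanSpectrum[sinfo] < swir$AR@meanSpectrum[sinfo]))

  zero <- makeArchetypes("visnir", effectSize = 0)
  expect_identical(zero$BH@meanSpectrum, zero$AS@meanSpectrum)
  expect_length(zero$BH@informativeBands, 0L)

  expect_identical(makeArchetypes("visnir", seed = 11L),
                   makeArchetypes("visnir", seed = 11L))
  expect_error(makeArchetypes("mwir"), "region")
  expect_error(makeArchetypes("visnir", nBands = 8L), ">= 16")
})

test_that("simulated samples equal their archetype in the noise-free limit", {
  arch <- makeArchetypes("visnir", nBands = 32L, seed = 2L,
                         nInformative = 6L)
  silent <- noiseConfig(0, 0, 0, 1, 0, 0, seed = 9L)
  st <- simulateSpectra(arch, c(BH = 3L, AR = 3L, AS = 3L), silent)
  sp <- spectra(st)
  for (g in c("BH", "AR", "AS")) {
    rows <- sp[sampleGroups(st) == g, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      expect_equal(unname(rows[i, ]), arch[[g]]@meanSpectrum)
  }
  # no group difference outside the informative set
  info <- arch$BH@informativeBands
  outside <- setdiff(seq_len(32L), info)
  expect_equal(unname(sp[1L, outside]), unname(sp[7L, outside]))
})

test_that("group sizes, labels and determinism behave as configured", {
  arch <- makeArchetypes("visnir", nBands = 32L, seed = 1L)
  one <- simulateSpectra(arch, c(BH = 377L, AR = 0L, AS = 0L),
                         noiseConfig(seed = 5L))
  expect_equal(ncol(one), 377L)
  expect_true(all(sampleGroups(one) == "BH"))

  a <- simulateSpectra(arch, c(BH = 10L, AR = 10L, AS = 10L),
                       noiseConfig(seed = 7L))
  b <- simulateSpectra(arch, c(BH = 10L, AR = 10L, AS = 10L),
                       noiseConfig(seed = 7L))
  expect_identical(spectra(a), spectra(b))
  expect_error(simulateSpectra(arch, c(BH = 0L, AR = 0L, AS = 0L)))
})

test_that("per-group sample means track the archetype over repeated seeds", {
  # Monte-Carlo: mean at an informative band within 3 standard errors
  arch <- makeArchetypes("visnir", nBands = 32L, seed = 4L,
                         nInformative = 6L)
  band <- arch$BH@informativeBands[1L]
  n <- 60L
  noise <- noiseConfig()
  for (g in c("BH", "AS")) {
    hits <- vapply(1:20, function(s) {
      st <- simulateSpectra(arch, stats::setNames(
        as.integer(c(g == "BH", g == "AR", g == "AS")) * n,
        c("BH", "AR", "AS")), noiseConfig(seed = s))
      m <- mean(spectra(st)[, band])
      # marginal SD at an informative band from the configured generator
      mu <- arch[[g]]@meanSpectrum
      dir <- arch$AS@meanSpectrum - arch$BH@meanSpectrum
      sdBand <- sqrt((noise@scatterSlopeSD * mu[band])^2 +
                     noise@scatterOffsetSD^2 + noise@correlatedNoiseSD^2 +
                     (noise@groupJitterSD * dir[band])^2)
      abs(m - mu[band]) <= 3 * sdBand / sqrt(n)
    }, logical(1L))
    expect_gte(sum(hits), 19L)
  }
})

test_that("Fisher ratio at informative bands grows with the effect size", {
  fisher <- function(effect) {
    arch <- makeArchetypes("visnir", nBands = 32L, effectSize = effect,
                           seed = 6L, nInformative = 6L,
                           groupPositions = c(BH = 0, AR = 0.5, AS = 1))
    st <- simulateSpectra(arch, c(BH = 80L, AR = 80L, AS = 80L),
                          noiseConfig(seed = 8L))
    band <- if (effect > 0) arch$BH@informativeBands[1L] else 10L
    v <- spectra(st)[, band]
    g <- sampleGroups(st)
    means <- tapply(v, g, mean)
    wthn <- mean(tapply(v, g, var))
    var(means) / wthn
  }
  ratios <- vapply(c(0.02, 0.06, 0.12), fisher, numeric(1L))
  expect_true(all(diff(ratios) > 0))
})

test_that("simulated cubes carry the archetype inside an exact ellipse mask", {
  arch <- makeArchetypes("visnir", nBands = 24L, seed = 2L)
  geom <- list(center = c(12, 14), semiAxes = c(6, 8), angle = 0)
  sim <- simulateCube(arch$AS, shape = c(24L, 28L), leafGeometry = geom,
                      noise = noiseConfig(pixelNoiseSD = 0, seed = 3L))
  # independent rasterization oracle for the ellipse pixel count
  cnt <- 0L
  for (i in 1:24) for (j in 1:28)
    if (((i - 12) / 6)^2 + ((j - 14) / 8)^2 <= 1) cnt <- cnt + 1L
  expect_identical(sum(sim$mask), cnt)
  # noise-free: every leaf pixel equals the archetype
  flat <- matrix(sim$cube@data, ncol = 24L)
  for (px in which(sim$mask)[c(1L, cnt)])
    expect_equal(unname(flat[px, ]), arch$AS@meanSpectrum)
  # background is low and flat at every band
  expect_true(all(flat[!sim$mask, ] <= 0.05))

  expect_error(simulateCube(arch$AS, shape = c(16L, 16L),
                            leafGeometry = list(center = c(8, 8),
                                                semiAxes = c(10, 4))),
               "fit")
})

test_that("spectrum tables survive a CSV round-trip", {
  arch <- makeArchetypes("visnir", nBands = 20L, seed = 1L)
  st <- simulateSpectra(arch, c(BH = 4L, AR = 3L, AS = 2L),
                        noiseConfig(seed = 2L))
  path <- tempfile(fileext = ".csv")
  writeSpectrumTable(st, path)
  back <- readSpectrumTable(path)
  expect_equal(spectra(back), spectra(st), tolerance = 1e-10)
  expect_identical(sampleGroups(back), sampleGroups(st))
  expect_identical(pixelCounts(back), pixelCounts(st))
  expect_equal(wavelengths(back), wavelengths(st))
})
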