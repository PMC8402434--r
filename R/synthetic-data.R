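# Synthetic leaf reflectance: class archetypes, sample tables and cubes
# with known ground truth. The generator stands in for unreleased plant
# data; its defaults define the study conditions used throughout the
# test-suite (see the methods vignette).

#' Region presets for the synthetic generator
#'
#' @param region \code{"visnir"} (400-1000 nm) or \code{"swir"}
#'   (1000-1800 nm).
#' @return list with the wavelength range, the window (nm) in which
#'   group-informative bands are placed, and the default group positions
#'   along the stress axis.
#' @keywords internal
regionPreset <- function(region) {
  switch(region,
    visnir = list(
      range = c(400, 1000), window = c(500, 760),
      positions = c(BH = 0, AR = 0.5, AS = 1)
    ),
    swir = list(
      range = c(1000, 1800), window = c(1150, 1620),
      positions = c(BH = 0, AS = 0.5, AR = 1)
    ),
    stop("unknown region tag: ", region, " (use 'visnir' or 'swir')")
  )
}

# Smooth noise-free leaf baseline for a region, reflectance in [0.01,0.99].
leafBaseline <- function(region, lambda) {
  if (region == "visnir") {
    # green peak near 550 nm, chlorophyll trough near 680 nm, red edge
    0.05 +
      0.45 * stats::plogis((lambda - 730) / 16) +
      0.10 * exp(-((lambda - 550) / 30)^2) -
      0.02 * exp(-((lambda - 680) / 25)^2)
  } else {
    # water absorption trough near 1450 nm, weaker dip near 1200 nm
    0.48 -
      0.20 * exp(-((lambda - 1450) / 55)^2) -
      0.06 * exp(-((lambda - 1200) / 90)^2) -
      0.05 * stats::plogis((lambda - 1750) / 25)
  }
}

#' Build the three group archetypes of one simulation
#'
#' Constructs smooth noise-free mean spectra for the three heat-stress
#' groups (\code{BH} before stress, \code{AR} resistant after stress,
#' \code{AS} susceptible after stress) on a uniform wavelength grid.
#' Group differences of magnitude \code{effectSize} are planted at
#' \code{nInformative} randomly placed bands inside the region's
#' biologically active window; outside those bands the three spectra are
#' identical. Group means at the informative bands are ordered by the
#' group's position along the stress axis (default: BH < AR < AS for
#' Vis/NIR; BH < AS < AR for SWIR, where the resistant group moves
#' farthest).
#'
#' @param region \code{"visnir"} or \code{"swir"}.
#' @param nBands number of bands on the uniform grid (>= 16, default 128).
#' @param effectSize reflectance difference between the reference group
#'   and the farthest group at each informative band (>= 0; 0 yields three
#'   identical archetypes and an empty informative set).
#' @param seed integer seed governing informative-band placement.
#' @param nInformative number of informative bands to plant; the default
#'   is 12, reduced to the number of grid bands inside the feature window
#'   on coarse grids.
#' @param groupPositions optional named numeric in [0, 1] giving each
#'   group's position along the stress axis (reference at 0, farthest at
#'   1); defaults to the region preset.
#' @return named list of three \linkS4class{ClassArchetype} objects
#'   (\code{BH}, \code{AR}, \code{AS}) sharing one wavelength grid and one
#'   informative-band set.
#' @examples
#' arch <- makeArchetypes("visnir", nBands = 64, effectSize = 0.05, seed = 1)
#' arch$BH
#' @export
makeArchetypes <- function(region, nBands = 128L, effectSize = 0.10,
                           seed = 1L, nInformative = NULL,
                           groupPositions = NULL) {
  preset <- regionPreset(region)
  nBands <- as.integer(nBands)
  if (nBands < 16L) stop("nBands must be >= 16")
  if (effectSize < 0) stop("effectSize must be >= 0")
  lambda <- seq(preset$range[1L], preset$range[2L], length.out = nBands)
  base <- leafBaseline(region, lambda)
  if (is.null(groupPositions)) groupPositions <- preset$positions
  if (!all(c("BH", "AR", "AS") %in% names(groupPositions)))
    stop("groupPositions must name BH, AR and AS")

  if (effectSize > 0) {
    window <- which(lambda >= preset$window[1L] &
                    lambda <= preset$window[2L])
    if (is.null(nInformative))
      nInformative <- min(12L, length(window))
    if (length(window) < nInformative)
      stop("nBands too small to place ", nInformative,
           " informative bands in the ", region, " feature window")
    info <- withSeed(seed, sort(sample(window, nInformative)))
  } else {
    info <- integer(0)
  }

  lapply(stats::setNames(nm = c("BH", "AR", "AS")), function(g) {
    spec <- base
    if (length(info))
      spec[info] <- spec[info] + groupPositions[[g]] * effectSize
    new("ClassArchetype", group = g, wavelengths = lambda,
        meanSpectrum = pmin(0.99, pmax(0.01, spec)),
        informativeBands = as.integer(info))
  })
}

#' Simulate a labelled table of leaf-mean spectra
#'
#' Each simulated sample is
#' \code{a * (archetype + z * stressDirection) + b + smooth noise} with
#' per-sample multiplicative scatter slope \code{a ~ N(1, scatterSlopeSD)},
#' additive offset \code{b ~ N(0, scatterOffsetSD)}, band-correlated
#' noise obtained by Gaussian-smoothing white noise over
#' \code{correlationLength} bands (marginal SD \code{correlatedNoiseSD}),
#' and a biological-heterogeneity term: \code{z ~ N(0, groupJitterSD)}
#' displaces the sample along the stress direction (the spectral
#' difference between the farthest group's archetype and the reference
#' archetype), emulating plants whose stress response is stronger or
#' weaker than their group's average. Default group sizes
#' (377/192/144) reproduce
#' the 251/128/96 calibration split of the reference experiment at a 2/3
#' calibration fraction.
#'
#' @param archetypes named list of \linkS4class{ClassArchetype} as built by
#'   \code{\link{makeArchetypes}}.
#' @param nPerGroup named integer vector of samples per group; zero is
#'   allowed for absent groups.
#' @param noise a \linkS4class{NoiseConfig}.
#' @return A \linkS4class{SpectrumTable}; reproducible for a fixed
#'   \code{noise@seed}.
#' @examples
#' arch <- makeArchetypes("visnir", nBands = 32, seed = 1)
#' st <- simulateSpectra(arch, c(BH = 5, AR = 5, AS = 5), noiseConfig(seed = 7))
#' table(sampleGroups(st))
#' @export
simulateSpectra <- function(archetypes,
                            nPerGroup = c(BH = 377L, AR = 192L, AS = 144L),
                            noise = noiseConfig()) {
  wl <- archetypes[[1L]]@wavelengths
  same <- vapply(archetypes, function(a)
    identical(a@wavelengths, wl), logical(1L))
  if (!all(same)) stop("archetypes must share one wavelength grid")
  if (is.null(names(nPerGroup)))
    names(nPerGroup) <- names(archetypes)[seq_along(nPerGroup)]
  if (any(nPerGroup < 0) || sum(nPerGroup) < 1L)
    stop("nPerGroup must be non-negative with at least one sample")
  p <- length(wl)

  # per-sample heterogeneity acts along the reference -> farthest-group
  # spectral direction (zero when all archetypes coincide)
  ref <- if ("BH" %in% names(archetypes)) "BH" else names(archetypes)[1L]
  dists <- vapply(archetypes, function(a)
    sqrt(sum((a@meanSpectrum - archetypes[[ref]]@meanSpectrum)^2)),
    numeric(1L))
  stressDir <- archetypes[[names(which.max(dists))]]@meanSpectrum -
    archetypes[[ref]]@meanSpectrum

  varietyFor <- function(g, n) {
    pool <- switch(g,
      BH = c("Chunpoong", "Sunmyoung", "Sunil"),
      AR = c("Sunmyoung", "Sunil"),
      AS = "Chunpoong",
      "unknown")
    rep_len(pool, n)
  }

  withSeed(noise@seed, {
    rows <- list(); grp <- character(0); vty <- character(0)
    for (g in names(nPerGroup)) {
      n <- nPerGroup[[g]]
      if (n == 0L) next
      mu <- archetypes[[g]]@meanSpectrum
      a <- stats::rnorm(n, 1, noise@scatterSlopeSD)
      b <- stats::rnorm(n, 0, noise@scatterOffsetSD)
      z <- stats::rnorm(n, 0, noise@groupJitterSD)
      m <- matrix(0, n, p)
      for (i in seq_len(n)) {
        eps <- if (noise@correlatedNoiseSD > 0)
          gaussianSmooth(stats::rnorm(p), noise@correlationLength) *
            noise@correlatedNoiseSD
        else rep(0, p)
        m[i, ] <- a[i] * (mu + z[i] * stressDir) + b[i] + eps
      }
      rows[[g]] <- m
      grp <- c(grp, rep(g, n))
      vty <- c(vty, varietyFor(g, n))
    }
    X <- do.call(rbind, rows)
    px <- sample(20000:48000, nrow(X), replace = TRUE)
    SpectrumTable(X, wl, group = grp, variety = vty, pixelCount = px)
  })
}

#' Simulate a small hyperspectral leaf cube with ground truth
#'
#' Pixels inside an elliptical leaf mask carry the archetype spectrum plus
#' independent per-pixel Gaussian noise (\code{pixelNoiseSD}); background
#' pixels carry a flat low spectrum (reflectance 0.03).
#'
#' @param archetype a \linkS4class{ClassArchetype}.
#' @param shape integer (lines, samples), both >= 16.
#' @param leafGeometry list with \code{center} (line, sample),
#'   \code{semiAxes} (a, b in pixels) and optional \code{angle} (radians);
#'   defaults to a centred ellipse covering ~30\% of each dimension. The
#'   ellipse must fit inside the frame.
#' @param noise a \linkS4class{NoiseConfig}; only \code{pixelNoiseSD} and
#'   \code{seed} are used.
#' @return list with elements \code{cube} (\linkS4class{HyperCube},
#'   reflectance) and \code{mask} (logical ground-truth leaf mask).
#' @examples
#' arch <- makeArchetypes("visnir", nBands = 32, seed = 1)
#' sim <- simulateCube(arch$BH, shape = c(24, 24), noise = noiseConfig(seed = 3))
#' sum(sim$mask)
#' @export
simulateCube <- function(archetype, shape = c(48L, 48L),
                         leafGeometry = NULL, noise = noiseConfig()) {
  shape <- as.integer(shape)
  if (any(shape < 16L)) stop("shape must be at least 16 x 16")
  if (is.null(leafGeometry))
    leafGeometry <- list(center = (shape + 1) / 2,
                         semiAxes = floor(shape * 0.3), angle = 0)
  ctr <- leafGeometry$center
  ax <- leafGeometry$semiAxes
  ang <- if (is.null(leafGeometry$angle)) 0 else leafGeometry$angle
  ext <- sqrt((ax[1L] * cos(ang))^2 + (ax[2L] * sin(ang))^2)
  eyt <- sqrt((ax[1L] * sin(ang))^2 + (ax[2L] * cos(ang))^2)
  if (ctr[1L] - ext < 1 || ctr[1L] + ext > shape[1L] ||
      ctr[2L] - eyt < 1 || ctr[2L] + eyt > shape[2L])
    stop("leaf ellipse does not fit inside the frame")

  ii <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  jj <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  u <- (ii - ctr[1L]) * cos(ang) + (jj - ctr[2L]) * sin(ang)
  v <- -(ii - ctr[1L]) * sin(ang) + (jj - ctr[2L]) * cos(ang)
  mask <- (u / ax[1L])^2 + (v / ax[2L])^2 <= 1

  p <- length(archetype@wavelengths)
  cube <- array(0.03, c(shape, p))
  leaf <- which(mask)
  withSeed(noise@seed, {
    for (b in seq_len(p)) {
      plane <- cube[, , b]
      val <- archetype@meanSpectrum[b]
      if (noise@pixelNoiseSD > 0)
        plane[leaf] <- val + stats::rnorm(length(leaf), 0, noise@pixelNoiseSD)
      else plane[leaf] <- val
      cube[, , b] <- plane
    }
  })
  cube <- pmax(cube, 0)
  list(
    cube = HyperCube(cube, archetype@wavelengths, units = "reflectance",
                     metadata = list(source = "synthetic",
                                     group = archetype@group)),
    mask = mask
  )
}

#' Write / read a SpectrumTable as CSV
#'
#' Plain-text interchange format: columns \code{sample_id}, \code{group},
#' \code{variety}, \code{pixel_count}, then one reflectance column per
#' wavelength (column name = wavelength in nm).
#'
#' @param table a \linkS4class{SpectrumTable}.
#' @param path output CSV path.
#' @return \code{writeSpectrumTable}: the path, invisibly;
#'   \code{readSpectrumTable}: a \linkS4class{SpectrumTable}.
#' @export
writeSpectrumTable <- function(table, path) {
  df <- data.frame(
    sample_id = colnames(table),
    group = sampleGroups(table),
    variety = sampleVariety(table),
    pixel_count = pixelCounts(table),
    check.names = FALSE
  )
  sp <- spectra(table)
  colnames(sp) <- format(wavelengths(table), digits = 15, trim = TRUE,
                         scientific = FALSE)
  utils::write.csv(cbind(df, sp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTable
#' @export
readSpectrumTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("sample_id", "group", "variety", "pixel_count")
  wlcols <- setdiff(colnames(df), meta)
  SpectrumTable(as.matrix(df[, wlcols]), as.numeric(wlcols),
                group = df$group, variety = df$variety,
                pixelCount = df$pixel_count, sampleIds = df$sample_id)
}
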