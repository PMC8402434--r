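# Leaf segmentation, per-leaf mean spectra and stratified
# calibration/validation splits.

# 8-connected component labelling of a logical matrix by BFS flood fill.
# Returns an integer matrix with 0 on background and 1..L on components.
labelComponents <- function(mask) {
  nl <- nrow(mask); ns <- ncol(mask)
  labels <- matrix(0L, nl, ns)
  lab <- 0L
  offs <- cbind(
    di = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dj = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      idx <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((idx - 1L) %% nl) + 1L
      j <- ((idx - 1L) %/% nl) + 1L
      ni <- i + offs[, 1L]; nj <- j + offs[, 2L]
      ok <- ni >= 1L & ni <= nl & nj >= 1L & nj <= ns
      nidx <- (nj[ok] - 1L) * nl + ni[ok]
      nidx <- nidx[mask[nidx] & labels[nidx] == 0L]
      if (length(nidx)) {
        labels[nidx] <- lab
        queue <- c(queue, nidx)
      }
    }
  }
  labels
}

# Renumber labels to 1..L after dropping small components.
compactLabels <- function(labels, minPixels) {
  sizes <- tabulate(labels)
  keep <- which(sizes >= minPixels)
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(keep)) out[labels == keep[k]] <- k
  out
}

#' Segment leaf pixels in a reflectance cube
#'
#' Two strategies are provided. The default, \code{method = "index"},
#' thresholds a normalized-difference vegetation index
#' \eqn{(R_{nir} - R_{red}) / (R_{nir} + R_{red})} computed from the
#' nearest grid bands to the two index wavelengths; it suits Vis/NIR
#' cubes. \code{method = "intensity"} thresholds the plain reflectance at
#' one wavelength (default 1100 nm) and suits SWIR cubes, where both index
#' wavelengths fall outside the range. Retained pixels are labelled by
#' 8-connected components and components smaller than \code{minPixels}
#' are dropped.
#'
#' @param cube a reflectance \linkS4class{HyperCube}.
#' @param indexBands numeric (nir, red) wavelengths in nm for the index
#'   method; both must lie within the cube's range.
#' @param threshold index (or reflectance) value above which a pixel is
#'   kept; default 0.3 for \code{"index"}, 0.2 for \code{"intensity"}.
#' @param method \code{"index"} or \code{"intensity"}.
#' @param intensityBand wavelength (nm) used by the intensity method.
#' @param minPixels smallest component kept (default 50; full-resolution
#'   leaves run to tens of thousands of pixels, synthetic ones far fewer).
#' @return A \linkS4class{LeafMask}.
#' @export
segmentLeaf <- function(cube, indexBands = c(nir = 800, red = 670),
                        threshold = NULL,
                        method = c("index", "intensity"),
                        intensityBand = 1100, minPixels = 50L) {
  method <- match.arg(method)
  wl <- cube@wavelengths
  if (method == "index") {
    if (is.null(threshold)) threshold <- 0.3
    if (any(indexBands < min(wl)) || any(indexBands > max(wl)))
      stop("index wavelengths lie outside the cube's spectral range")
    bnir <- nearestBand(wl, indexBands[[1L]])
    bred <- nearestBand(wl, indexBands[[2L]])
    nir <- cube@data[, , bnir]
    red <- cube@data[, , bred]
    ndvi <- (nir - red) / (nir + red)
    keep <- ndvi > threshold
  } else {
    if (is.null(threshold)) threshold <- 0.2
    if (intensityBand < min(wl) || intensityBand > max(wl))
      stop("intensity wavelength lies outside the cube's spectral range")
    keep <- cube@data[, , nearestBand(wl, intensityBand)] > threshold
  }
  keep[is.na(keep)] <- FALSE
  labels <- compactLabels(labelComponents(keep), minPixels)
  if (!any(labels > 0L))
    stop("segmentation produced an empty mask; lower 'threshold' or ",
         "'minPixels'")
  new("LeafMask", mask = labels > 0L, labels = labels)
}

#' Reduce each segmented leaf to one mean spectrum
#'
#' Band-wise arithmetic mean over every pixel of each labelled leaf; the
#' per-leaf pixel count is recorded.
#'
#' @param cube a reflectance \linkS4class{HyperCube}.
#' @param mask a \linkS4class{LeafMask} (or logical matrix, treated as one
#'   leaf).
#' @param group,variety labels attached to every extracted row (defaults
#'   \code{"unknown"}/\code{NA}: cube pixels carry no class information).
#' @return A \linkS4class{SpectrumTable} with one row per labelled leaf.
#' @export
meanSpectra <- function(cube, mask, group = "unknown", variety = NA) {
  labels <- if (is(mask, "LeafMask")) mask@labels
            else { m <- as.matrix(mask); matrix(as.integer(m), nrow(m)) }
  if (!identical(dim(labels), dim(cube@data)[1:2]))
    stop("mask shape does not match the cube")
  L <- max(labels)
  if (L < 1L) stop("mask is empty")
  p <- length(cube@wavelengths)
  flat <- matrix(cube@data, ncol = p)
  means <- matrix(0, L, p)
  counts <- integer(L)
  for (k in seq_len(L)) {
    px <- which(labels == k)
    counts[k] <- length(px)
    means[k, ] <- colMeans(flat[px, , drop = FALSE])
  }
  SpectrumTable(means, cube@wavelengths,
                group = rep_len(group, L), variety = rep_len(variety, L),
                pixelCount = counts,
                sampleIds = sprintf("leaf%02d", seq_len(L)))
}

#' Stratified calibration/validation split
#'
#' Randomly splits the samples within each stratum (by default the group
#' label) at \code{calFraction}; the calibration count per stratum is
#' \code{round(calFraction * n)} with the remainder going to validation.
#' The default 2/3 fraction reproduces a 251/128/96 vs 126/64/48 split of
#' 377/192/144 samples.
#'
#' @param table a \linkS4class{SpectrumTable}.
#' @param calFraction calibration fraction, in (0, 1); default 2/3.
#' @param seed integer seed making the split reproducible.
#' @param stratifyBy column of \code{colData} used as stratum (default
#'   \code{"group"}).
#' @return list with elements \code{cal} and \code{val}, two disjoint and
#'   exhaustive \linkS4class{SpectrumTable}s.
#' @export
splitCalVal <- function(table, calFraction = 2 / 3, seed = 1L,
                        stratifyBy = "group") {
  if (calFraction <= 0 || calFraction >= 1)
    stop("calFraction must lie strictly between 0 and 1")
  strata <- SummarizedExperiment::colData(table)[[stratifyBy]]
  calIdx <- withSeed(seed, {
    unlist(lapply(unique(strata), function(s) {
      idx <- which(strata == s)
      if (length(idx) < 2L)
        stop("stratum '", s, "' has fewer than 2 samples")
      nCal <- as.integer(roundHalfUp(calFraction * length(idx)))
      nCal <- max(1L, min(nCal, length(idx) - 1L))
      sample(idx, nCal)
    }), use.names = FALSE)
  })
  list(cal = table[, sort(calIdx)],
       val = table[, sort(setdiff(seq_len(ncol(table)), calIdx))])
}

#' Write a leaf mask as a PNG for visual inspection
#'
#' Background is written as 0, leaf pixels as 255.
#'
#' @param mask a \linkS4class{LeafMask} or logical matrix.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  m <- if (is(mask, "LeafMask")) mask@mask else mask
  png::writePNG(matrix(as.numeric(m), nrow(m)), path)
  invisible(path)
}
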