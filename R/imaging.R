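# Pixel-wise chemical imaging: apply a selected-band PLS-DA model to
# every leaf pixel of a cube, producing a stress-code map.

#' Pixel-wise prediction map
#'
#' Applies a PLS1 model trained on the selected bands to every leaf pixel:
#' \eqn{\hat y = (x_{sel} - \bar x)\beta + \bar y}. Selected wavelengths
#' are mapped onto the cube grid by nearest-band lookup (no
#' interpolation). Predicted codes are clipped to [-20, 120] so extreme
#' noise pixels stay visible but bounded; background pixels are no-data
#' (NA).
#'
#' @param cube a reflectance \linkS4class{HyperCube} covering all selected
#'   wavelengths.
#' @param mask a \linkS4class{LeafMask} or logical matrix marking leaf
#'   pixels.
#' @param model a \linkS4class{PLSModel} trained on exactly the selected
#'   bands.
#' @param selection a \linkS4class{BandSelection}; its wavelengths define
#'   the model's band axis.
#' @param colormapRange (lo, hi) code units for later rendering (default
#'   0-100, the SPRI code span).
#' @param clipRange (lo, hi) clamp applied to the predicted codes, or
#'   NULL for the raw linear predictions (default c(-20, 120)).
#' @return A \linkS4class{PredictionMap}.
#' @export
predictMap <- function(cube, mask, model, selection,
                       colormapRange = c(0, 100),
                       clipRange = c(-20, 120)) {
  m <- if (is(mask, "LeafMask")) mask@mask else as.matrix(mask)
  if (!identical(dim(m), dim(cube@data)[1:2]))
    stop("mask shape does not match the cube")
  wl <- selection@selectedWavelengths
  if (length(wl) != length(model@xMean))
    stop("model was not trained on the selection's bands")
  tol <- max(diff(cube@wavelengths)) / 2 + 1e-9
  bands <- nearestBand(cube@wavelengths, wl)
  off <- abs(cube@wavelengths[bands] - wl)
  if (any(off > tol))
    stop("cube lacks a band near ", format(wl[which.max(off)]), " nm")
  flat <- matrix(cube@data, ncol = dim(cube@data)[3L])
  leaf <- which(m)
  x <- flat[leaf, bands, drop = FALSE]
  yhat <- as.vector(sweep(x, 2L, model@xMean) %*% model@coefficients +
                      model@yMean)
  if (!is.null(clipRange))
    yhat <- pmin(pmax(yhat, clipRange[1L]), clipRange[2L])
  values <- matrix(NA_real_, nrow(m), ncol(m))
  values[leaf] <- yhat
  new("PredictionMap", values = values, mask = m,
      colormapRange = as.numeric(colormapRange))
}

#' Render a prediction map to a PNG image
#'
#' 8-bit color rendering with a vertical colorbar spanning the map's
#' colormap range appended on the right; values outside the range render
#' as the endpoint colors and no-data pixels as neutral gray. Identical
#' inputs produce byte-identical files.
#'
#' @param map a \linkS4class{PredictionMap}.
#' @param path output PNG path.
#' @param colormapName an \code{\link[grDevices]{hcl.colors}} palette name
#'   (default \code{"Viridis"}).
#' @param barWidth colorbar width in pixels (0 suppresses the bar).
#' @return the path, invisibly.
#' @export
renderMap <- function(map, path, colormapName = "Viridis",
                      barWidth = 8L) {
  pal <- grDevices::hcl.colors(256L, colormapName)
  rgbPal <- grDevices::col2rgb(pal) / 255
  lo <- map@colormapRange[1L]; hi <- map@colormapRange[2L]
  v <- pmin(pmax(map@values, lo), hi)
  idx <- 1L + as.integer(round(255 * (v - lo) / (hi - lo)))
  nl <- nrow(v); ns <- ncol(v)
  img <- array(0.85, c(nl, ns, 3L))        # neutral gray background
  leaf <- which(map@mask)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[leaf] <- rgbPal[ch, idx[leaf]]
    img[, , ch] <- plane
  }
  if (barWidth > 0L) {
    barIdx <- 1L + as.integer(round(255 * rev(seq_len(nl) - 1) / (nl - 1)))
    bar <- array(0, c(nl, barWidth + 2L, 3L))
    for (ch in 1:3) {
      bar[, , ch] <- 0.85                  # gutter
      bar[, 3:(barWidth + 2L), ch] <- matrix(rgbPal[ch, barIdx], nl,
                                             barWidth)
    }
    out <- array(0, c(nl, ns + barWidth + 2L, 3L))
    out[, seq_len(ns), ] <- img
    out[, ns + seq_len(barWidth + 2L), ] <- bar
    img <- out
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write the raw score map as a single-band float ENVI cube
#'
#' No-data (background) pixels are written as the fill value.
#'
#' @param map a \linkS4class{PredictionMap}.
#' @param headerPath output ENVI header path.
#' @param fill background fill value (default -999).
#' @return invisibly, the written paths.
#' @export
writeScoreMapENVI <- function(map, headerPath, fill = -999) {
  v <- map@values
  v[is.na(v)] <- fill
  cube <- HyperCube(array(v, c(dim(v), 1L)), wavelengths = 0,
                    units = "score",
                    metadata = list(content = "plsda score map",
                                    fill = as.character(fill)))
  writeENVI(cube, headerPath, interleave = "bsq")
}
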