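# Ensemble waveband selection: a VIP threshold filter over the
# full-spectrum PLS-DA model picks candidate wavebands, then the
# successive projections algorithm (SPA) extracts a minimally collinear
# subset, capped below 20 bands, scored by validation misclassification.

#' VIP threshold filter
#'
#' Keeps the bands whose VIP score is greater than or equal to the
#' threshold, in wavelength order. Since the mean squared VIP over bands
#' is 1, a threshold of 1.0 keeps the above-average contributors.
#'
#' @param vip numeric vector of per-band VIP scores.
#' @param threshold positive cutoff (default 1.0), inclusive.
#' @return integer vector of candidate band indices.
#' @export
vipFilter <- function(vip, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be > 0")
  idx <- which(vip >= threshold)
  if (!length(idx))
    stop("no band reaches VIP >= ", threshold, "; lower the threshold")
  idx
}

#' Successive projections chain
#'
#' Greedy anti-collinearity recursion: starting from \code{startIndex},
#' repeatedly project every unselected column onto the orthogonal
#' complement of the span of the selected columns and append the column
#' with the largest projected norm, stopping at \code{mMax} columns. When
#' every remaining projected norm falls below 1e-12 (the matrix rank is
#' exhausted) the chain is returned truncated with attribute
#' \code{truncated = TRUE}.
#'
#' @param x numeric matrix of centred candidate columns.
#' @param startIndex column starting the chain.
#' @param mMax chain length, at most \code{min(n_rows, n_cols)}.
#' @return integer vector of column indices in selection order, with a
#'   logical attribute \code{"truncated"}.
#' @export
spaChain <- function(x, startIndex, mMax) {
  x <- as.matrix(x)
  nc <- ncol(x)
  mMax <- as.integer(mMax)
  if (mMax < 1L || mMax > min(nrow(x), nc))
    stop("mMax must lie in 1..min(n_rows, n_cols)")
  if (startIndex < 1L || startIndex > nc) stop("startIndex out of range")
  chain <- integer(0)
  resid <- x                      # columns projected off the selected span
  current <- as.integer(startIndex)
  truncated <- FALSE
  for (m in seq_len(mMax)) {
    chain <- c(chain, current)
    v <- resid[, current]
    nv2 <- sum(v^2)
    if (nv2 < 1e-24) break
    # deflate every column by its projection onto v
    coef <- crossprod(resid, v) / nv2
    resid <- resid - tcrossprod(v, coef)
    if (m == mMax) break
    norms <- sqrt(colSums(resid^2))
    norms[chain] <- -Inf
    if (max(norms) < 1e-12) { truncated <- TRUE; break }
    current <- which.max(norms)
  }
  structure(chain, truncated = truncated)
}

#' SPA selection scored by validation misclassification
#'
#' For every start column and every chain length \code{m} in
#' \code{[mMin, mMax]}, fits a PLS1 model on the chain's bands
#' (calibration set), classifies the validation set by nearest class code
#' and records the misclassification rate. Returns the
#' (start, m) combination minimizing the validation error, ties broken by
#' smaller \code{m} then smaller start index.
#'
#' @param xcal,ycal calibration spectra (samples x candidate bands) and
#'   class codes.
#' @param xval,yval validation spectra and class codes.
#' @param encoding the active \linkS4class{GroupEncoding} (decides the
#'   nearest-code classes).
#' @param mMin,mMax smallest / largest subset size tried (defaults 8 and
#'   20; both are clamped to the candidate count).
#' @param nLVCap latent variables used for the subset fits, capped at the
#'   subset size (default 10).
#' @param wavelengths wavelengths of the candidate bands (for reporting).
#' @param indices original band indices of the candidate columns (for
#'   reporting; defaults to column positions).
#' @param vip full-length VIP scores to store with the result.
#' @return A \linkS4class{BandSelection}.
#' @export
spaSelect <- function(xcal, ycal, xval, yval, encoding,
                      mMin = 8L, mMax = 20L, nLVCap = 10L,
                      wavelengths = NULL, indices = NULL,
                      vip = numeric(0)) {
  xcal <- as.matrix(xcal); xval <- as.matrix(xval)
  nc <- ncol(xcal)
  if (is.null(indices)) indices <- seq_len(nc)
  if (is.null(wavelengths)) wavelengths <- as.numeric(indices)
  mMax <- min(as.integer(mMax), 20L, nc, nrow(xcal) - 1L)
  mMin <- max(2L, min(as.integer(mMin), mMax))
  truthVal <- classifyScores(yval, encoding)

  xcalC <- sweep(xcal, 2L, colMeans(xcal))
  best <- NULL
  trace <- vector("list", nc)
  for (s in seq_len(nc)) {
    chain <- spaChain(xcalC, s, mMax)
    ms <- seq.int(mMin, length(chain))
    if (!length(ms) || mMin > length(chain)) next
    errs <- vapply(ms, function(m) {
      bands <- chain[seq_len(m)]
      fit <- fitPLS1(xcal[, bands, drop = FALSE], ycal,
                     nLV = min(nLVCap, m, nrow(xcal) - 1L))
      pred <- predict(fit, xval[, bands, drop = FALSE])
      mean(classifyScores(pred, encoding) != truthVal)
    }, numeric(1L))
    trace[[s]] <- data.frame(start = s, m = ms, error = errs)
    for (k in seq_along(ms)) {
      cand <- list(error = errs[k], m = ms[k], start = s,
                   bands = chain[seq_len(ms[k])],
                   truncated = attr(chain, "truncated"))
      if (is.null(best) ||
          cand$error < best$error - 1e-15 ||
          (abs(cand$error - best$error) <= 1e-15 &&
           (cand$m < best$m ||
            (cand$m == best$m && cand$start < best$start))))
        best <- cand
    }
  }
  if (is.null(best))
    stop("no SPA chain of length >= ", mMin, " could be built")
  new("BandSelection",
      selectedIndices = as.integer(indices[best$bands]),
      selectedWavelengths = as.numeric(wavelengths[best$bands]),
      vipScores = vip,
      candidates = as.integer(indices),
      criterionTrace = do.call(rbind, trace[!vapply(trace, is.null,
                                                    logical(1L))]),
      scheme = encoding@scheme,
      truncated = isTRUE(best$truncated))
}

#' Ensemble waveband selection (VIP filter then SPA)
#'
#' Fits a full-spectrum PLS1 model on the calibration set (component
#' count chosen by cross-validation), scores every band by VIP, keeps the
#' bands at or above \code{vipThreshold}, and runs
#' \code{\link{spaSelect}} restricted to those candidates. The result
#' records both stages: the candidate set and the final chain.
#'
#' @param xcal,ycal calibration spectra (samples x all bands) and class
#'   codes.
#' @param xval,yval validation spectra and class codes.
#' @param encoding the active \linkS4class{GroupEncoding}.
#' @param wavelengths band wavelengths in nm (one per column of
#'   \code{xcal}).
#' @param vipThreshold VIP cutoff (default 1.0).
#' @param mMin,mMax subset size range handed to \code{\link{spaSelect}}
#'   (defaults 8 and 20; clamped to the candidate count).
#' @param maxLV,folds,seed cross-validation settings for the
#'   full-spectrum component count.
#' @param nLVCap latent-variable cap for the subset fits.
#' @return A \linkS4class{BandSelection} whose indices refer to the full
#'   band grid.
#' @export
ensembleSelect <- function(xcal, ycal, xval, yval, encoding,
                           wavelengths = NULL, vipThreshold = 1.0,
                           mMin = 8L, mMax = 20L, maxLV = 15L,
                           folds = 5L, seed = 1L, nLVCap = 10L) {
  if (is(xcal, "SpectrumTable")) xcal <- spectra(xcal)
  if (is(xval, "SpectrumTable")) xval <- spectra(xval)
  xcal <- as.matrix(xcal); xval <- as.matrix(xval)
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(xcal))
  nLV <- chooseNLV(xcal, ycal, maxLV = maxLV, folds = folds, seed = seed)
  full <- fitPLS1(xcal, ycal, nLV = nLV)
  vip <- vipScores(full)
  cand <- vipFilter(vip, vipThreshold)
  spaSelect(xcal[, cand, drop = FALSE], ycal,
            xval[, cand, drop = FALSE], yval, encoding,
            mMin = mMin, mMax = mMax, nLVCap = nLVCap,
            wavelengths = wavelengths[cand], indices = cand, vip = vip)
}

#' Serialize a BandSelection
#'
#' \code{writeSelectionJSON} emits the full record (selected indices and
#' wavelengths, VIP candidates, criterion trace, scheme);
#' \code{writeWavelengthList} writes the selected wavelengths as a plain
#' text list, one value (nm) per line.
#'
#' @param selection a \linkS4class{BandSelection}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSelectionJSON <- function(selection, path) {
  jsonlite::write_json(list(
    scheme = selection@scheme,
    selected_indices = selection@selectedIndices,
    selected_wavelengths = selection@selectedWavelengths,
    vip_candidates = selection@candidates,
    vip_scores = selection@vipScores,
    truncated = selection@truncated,
    criterion_trace = selection@criterionTrace
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSelectionJSON
#' @export
writeWavelengthList <- function(selection, path) {
  writeLines(format(sort(selection@selectedWavelengths),
                    digits = 10, trim = TRUE), path)
  invisible(path)
}
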