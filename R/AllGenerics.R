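#' Wavelength grid accessor
#' @param x an object carrying a wavelength axis.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Spectra matrix accessor (samples x bands)
#' @param x an object holding per-sample spectra.
#' @return numeric matrix, samples in rows, bands in columns.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' Group label accessor
#' @param x an object holding per-sample group labels.
#' @return character vector of group labels.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Variety label accessor
#' @param x an object holding per-sample variety labels.
#' @return character vector of variety labels.
#' @export
setGeneric("sampleVariety", function(x) standardGeneric("sampleVariety"))

#' Pixel count accessor
#' @param x an object recording the number of pixels averaged per sample.
#' @return integer vector.
#' @export
setGeneric("pixelCounts", function(x) standardGeneric("pixelCounts"))

#' Class code accessor
#' @param x a \linkS4class{GroupEncoding}.
#' @return named numeric vector of class codes.
#' @export
setGeneric("groupCodes", function(x) standardGeneric("groupCodes"))

#' Selected band index accessor
#' @param x a \linkS4class{BandSelection}.
#' @return integer vector of selected band indices in selection order.
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))

#' Per-band VIP score accessor
#' @param x a \linkS4class{PLSModel} or \linkS4class{BandSelection}.
#' @return numeric vector of VIP scores, one per band.
#' @export
setGeneric("vipScores", function(x) standardGeneric("vipScores"))

# ---- straightforward accessor methods -------------------------------------

#' @describeIn HyperCube wavelength grid of the cube.
#' @param x a HyperCube.
#' @export
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

#' @describeIn HyperCube cube dimensions (lines, samples, bands).
#' @export
setMethod("dim", "HyperCube", function(x) dim(x@data))

#' @describeIn SpectrumTable wavelength grid shared by all rows.
#' @param x a SpectrumTable.
#' @export
setMethod("wavelengths", "SpectrumTable", function(x)
  SummarizedExperiment::rowData(x)$wavelength)

#' @describeIn SpectrumTable samples x bands reflectance matrix.
#' @export
setMethod("spectra", "SpectrumTable", function(x) {
  m <- t(SummarizedExperiment::assay(x, "reflectance"))
  colnames(m) <- as.character(wavelengths(x))
  m
})

#' @describeIn SpectrumTable per-sample group labels.
#' @export
setMethod("sampleGroups", "SpectrumTable", function(x)
  SummarizedExperiment::colData(x)$group)

#' @describeIn SpectrumTable per-sample variety labels.
#' @export
setMethod("sampleVariety", "SpectrumTable", function(x)
  SummarizedExperiment::colData(x)$variety)

#' @describeIn SpectrumTable per-sample leaf pixel counts.
#' @export
setMethod("pixelCounts", "SpectrumTable", function(x)
  SummarizedExperiment::colData(x)$pixel_count)

#' @describeIn GroupEncoding named class codes.
#' @param x a GroupEncoding.
#' @export
setMethod("groupCodes", "GroupEncoding", function(x) x@codes)

#' @describeIn BandSelection selected band indices.
#' @param x a BandSelection.
#' @export
setMethod("selectedBands", "BandSelection", function(x) x@selectedIndices)

#' @describeIn BandSelection wavelengths of the selected bands.
#' @export
setMethod("wavelengths", "BandSelection", function(x) x@selectedWavelengths)

#' @describeIn BandSelection full-length VIP scores from the filtering
#'   stage.
#' @export
setMethod("vipScores", "BandSelection", function(x) x@vipScores)

# ---- show methods ----------------------------------------------------------

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube: %d lines x %d samples x %d bands [%s]\n",
              d[1L], d[2L], d[3L], object@units))
  cat(sprintf("  wavelengths: %.1f - %.1f nm\n",
              min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "GroupEncoding", function(object) {
  cat(sprintf("GroupEncoding [%s], reference %s\n",
              object@scheme, object@referenceGroup))
  print(round(object@codes[object@groupOrder], 1))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d bands, %d latent variables\n",
              nrow(object@weights), ncol(object@weights)))
  cat(sprintf("  explained Y variance: %.1f%%\n",
              100 * sum(object@ssyF) / object@ssyTotal))
})

setMethod("show", "BandSelection", function(object) {
  cat(sprintf("BandSelection [%s]: %d of %d VIP candidates\n",
              object@scheme, length(object@selectedIndices),
              length(object@candidates)))
  if (length(object@selectedWavelengths))
    cat("  wavelengths (nm):",
        paste(round(sort(object@selectedWavelengths)), collapse = ", "),
        "\n")
})

setMethod("show", "AccuracyTable", function(object) {
  cts <- object@counts
  cts$accuracy <- roundHalfUp(cts$accuracy, 1L)
  print(cts, row.names = FALSE)
  cat(sprintf("Overall (macro): %.1f%%\n",
              roundHalfUp(object@overall, 1L)))
})
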