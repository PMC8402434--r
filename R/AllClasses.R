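#' @import methods
#' @importFrom stats predict
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' HyperCube: a hyperspectral reflectance cube
#'
#' A three-dimensional raster of spectral measurements ordered
#' lines x samples x bands, together with the wavelength (nm) of every
#' band and free-form acquisition metadata. Cubes are either raw detector
#' counts (\code{units == "raw"}) or calibrated reflectance
#' (\code{units == "reflectance"}).
#'
#' @slot data numeric 3-D array, lines x samples x bands.
#' @slot wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per band.
#' @slot units either \code{"raw"} or \code{"reflectance"}.
#' @slot metadata named list of free-form key/value metadata.
#'
#' @export
setClass("HyperCube",
  representation(
    data = "array",
    wavelengths = "numeric",
    units = "character",
    metadata = "list"
  ),
  prototype(units = "raw", metadata = list())
)

setValidity("HyperCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-D array (lines x samples x bands)")
  if (length(object@wavelengths) != d[3L])
    return("length(wavelengths) must equal the band dimension")
  if (anyNA(object@wavelengths) || any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing with no NA")
  if (!(object@units %in% c("raw", "reflectance", "score")))
    return("units must be 'raw', 'reflectance' or 'score'")
  if (object@units == "reflectance" &&
      (anyNA(object@data) || min(object@data) < 0))
    return("reflectance cubes must be NA-free and non-negative")
  TRUE
})

#' Construct a HyperCube
#'
#' @param data numeric 3-D array, lines x samples x bands.
#' @param wavelengths numeric vector of wavelengths in nm (strictly
#'   increasing), one per band.
#' @param units \code{"raw"} or \code{"reflectance"}.
#' @param metadata named list of acquisition metadata.
#' @return A \linkS4class{HyperCube}.
#' @examples
#' cube <- HyperCube(array(runif(4 * 4 * 3), c(4, 4, 3)),
#'                   wavelengths = c(500, 600, 700),
#'                   units = "reflectance")
#' dim(cube)
#' @export
HyperCube <- function(data, wavelengths, units = "raw", metadata = list()) {
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      units = units, metadata = metadata)
}

#' SpectrumTable: per-sample mean spectra with class labels
#'
#' A \linkS4class{SummarizedExperiment} holding one mean reflectance
#' spectrum per sample (bands as rows, samples as columns). Row metadata
#' carries the wavelength grid; column metadata carries the heat-stress
#' group (\code{BH}/\code{AR}/\code{AS}), the variety label and the number
#' of leaf pixels averaged into each spectrum.
#'
#' @export
setClass("SpectrumTable", contains = "SummarizedExperiment")

setValidity("SpectrumTable", function(object) {
  if (!("reflectance" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'reflectance' is required")
  a <- SummarizedExperiment::assay(object, "reflectance")
  if (anyNA(a)) return("reflectance values must not contain NA")
  rd <- SummarizedExperiment::rowData(object)
  if (!("wavelength" %in% colnames(rd)))
    return("rowData column 'wavelength' is required")
  wl <- rd$wavelength
  if (anyNA(wl) || any(diff(wl) <= 0))
    return("wavelengths must be strictly increasing with no NA")
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "variety", "pixel_count")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (any(cd$pixel_count < 1L))
    return("pixel_count must be >= 1 for every sample")
  TRUE
})

#' Construct a SpectrumTable
#'
#' @param spectra numeric matrix, samples x bands, of mean reflectance.
#' @param wavelengths numeric vector of wavelengths in nm, one per band.
#' @param group character/factor vector of group labels, one per sample.
#' @param variety optional character vector of variety labels.
#' @param pixelCount optional integer vector: leaf pixels averaged per
#'   sample (defaults to 1).
#' @param sampleIds optional sample identifiers.
#' @return A \linkS4class{SpectrumTable}.
#' @examples
#' st <- SpectrumTable(matrix(runif(6), 2, 3), c(500, 600, 700),
#'                     group = c("BH", "AS"))
#' spectra(st)
#' @export
SpectrumTable <- function(spectra, wavelengths, group,
                          variety = NULL, pixelCount = NULL,
                          sampleIds = NULL) {
  spectra <- as.matrix(spectra)
  dimnames(spectra) <- NULL
  n <- nrow(spectra)
  if (length(group) != n)
    stop("'group' must supply one label per row of 'spectra'")
  if (is.null(variety)) variety <- rep(NA_character_, n)
  if (is.null(pixelCount)) pixelCount <- rep(1L, n)
  if (is.null(sampleIds)) sampleIds <- sprintf("S%04d", seq_len(n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = t(spectra)),
    rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelengths)),
    colData = S4Vectors::DataFrame(
      group = as.character(group),
      variety = as.character(variety),
      pixel_count = as.integer(pixelCount),
      row.names = sampleIds
    )
  )
  new("SpectrumTable", se)
}

#' ClassArchetype: the noise-free mean spectrum of one group
#'
#' @slot group group label (\code{BH}, \code{AR} or \code{AS}).
#' @slot wavelengths wavelength grid in nm.
#' @slot meanSpectrum reflectance in [0.01, 0.99], one value per band.
#' @slot informativeBands integer indices of the bands at which the three
#'   groups differ by construction (identical across the archetypes of one
#'   simulation).
#' @export
setClass("ClassArchetype",
  representation(
    group = "character",
    wavelengths = "numeric",
    meanSpectrum = "numeric",
    informativeBands = "integer"
  )
)

setValidity("ClassArchetype", function(object) {
  if (length(object@meanSpectrum) != length(object@wavelengths))
    return("meanSpectrum and wavelengths must have equal length")
  if (any(object@meanSpectrum < 0.01 - 1e-12) ||
      any(object@meanSpectrum > 0.99 + 1e-12))
    return("meanSpectrum values must lie in [0.01, 0.99]")
  if (length(object@informativeBands) &&
      (min(object@informativeBands) < 1L ||
       max(object@informativeBands) > length(object@wavelengths)))
    return("informativeBands out of range")
  TRUE
})

#' NoiseConfig: sample- and pixel-level noise for the simulator
#'
#' @slot scatterSlopeSD SD of the per-sample multiplicative scatter slope
#'   (unitless, around 1).
#' @slot scatterOffsetSD SD of the per-sample additive offset (reflectance).
#' @slot correlatedNoiseSD marginal SD of smooth (band-correlated)
#'   per-sample noise (reflectance).
#' @slot correlationLength Gaussian smoothing kernel width, in bands.
#' @slot groupJitterSD SD of the per-sample position jitter along the
#'   stress axis, in group-position units (the reference group sits at 0,
#'   the farthest group at 1). Models biological heterogeneity of the
#'   stress response; it acts in the signal direction, so no linear model
#'   can remove it.
#' @slot pixelNoiseSD SD of independent per-pixel noise in cubes
#'   (reflectance).
#' @slot seed integer random seed.
#' @export
setClass("NoiseConfig",
  representation(
    scatterSlopeSD = "numeric",
    scatterOffsetSD = "numeric",
    correlatedNoiseSD = "numeric",
    correlationLength = "numeric",
    groupJitterSD = "numeric",
    pixelNoiseSD = "numeric",
    seed = "integer"
  )
)

setValidity("NoiseConfig", function(object) {
  sds <- c(object@scatterSlopeSD, object@scatterOffsetSD,
           object@correlatedNoiseSD, object@groupJitterSD,
           object@pixelNoiseSD)
  if (any(sds < 0)) return("all standard deviations must be >= 0")
  if (object@correlationLength < 1) return("correlationLength must be >= 1")
  TRUE
})

#' Construct a NoiseConfig
#'
#' Defaults emulate moderate sample-to-sample scatter and smooth spectral
#' noise typical of leaf-mean reflectance spectra; see the package
#' vignette for the rationale behind the magnitudes.
#'
#' @param scatterSlopeSD,scatterOffsetSD,correlatedNoiseSD,correlationLength,groupJitterSD,pixelNoiseSD
#'   see the corresponding slots of \linkS4class{NoiseConfig}.
#' @param seed integer random seed.
#' @return A \linkS4class{NoiseConfig}.
#' @export
noiseConfig <- function(scatterSlopeSD = 0.02, scatterOffsetSD = 0.005,
                        correlatedNoiseSD = 0.008, correlationLength = 8,
                        groupJitterSD = 0.2, pixelNoiseSD = 0.02,
                        seed = 1L) {
  new("NoiseConfig",
      scatterSlopeSD = scatterSlopeSD, scatterOffsetSD = scatterOffsetSD,
      correlatedNoiseSD = correlatedNoiseSD,
      correlationLength = correlationLength,
      groupJitterSD = groupJitterSD,
      pixelNoiseSD = pixelNoiseSD, seed = as.integer(seed))
}

#' LeafMask: segmented leaf pixels
#'
#' @slot mask logical matrix (lines x samples), TRUE on leaf pixels.
#' @slot labels integer matrix of the same shape; 0 on background,
#'   1..L on the L connected leaves (8-connectivity, no gaps).
#' @export
setClass("LeafMask",
  representation(mask = "matrix", labels = "matrix")
)

setValidity("LeafMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!identical(dim(object@mask), dim(object@labels)))
    return("mask and labels must share the same shape")
  lab <- sort(unique(as.integer(object@labels[object@labels > 0L])))
  if (length(lab) && !identical(lab, seq_along(lab)))
    return("labels must be 1..L with no gaps")
  if (any((object@labels > 0L) != object@mask))
    return("labels must be positive exactly on mask pixels")
  TRUE
})

#' LDAModel: shrinkage-regularized linear discriminant axes
#'
#' @slot axes matrix n_bands x n_axes of unit-norm discriminant
#'   directions, sorted by decreasing eigenvalue.
#' @slot eigenvalues between/within variance ratio along each axis.
#' @slot groupCenters1D named per-group centre on the chosen axis.
#' @slot chosenAxis index of the axis used for best projection values.
#' @slot centering per-band global mean removed before projection.
#' @slot shrinkage shrinkage intensity in [0, 1] applied to the
#'   within-class scatter.
#' @slot referenceGroup label of the baseline (unstressed) group.
#' @export
setClass("LDAModel",
  representation(
    axes = "matrix",
    eigenvalues = "numeric",
    groupCenters1D = "numeric",
    chosenAxis = "integer",
    centering = "numeric",
    shrinkage = "numeric",
    referenceGroup = "character"
  )
)

setValidity("LDAModel", function(object) {
  nrm <- sqrt(colSums(object@axes^2))
  if (any(abs(nrm - 1) > 1e-8)) return("axes must have unit norm")
  if (object@chosenAxis < 1L || object@chosenAxis > ncol(object@axes))
    return("chosenAxis out of range")
  if (object@shrinkage < 0 || object@shrinkage > 1)
    return("shrinkage must lie in [0, 1]")
  TRUE
})

#' GroupEncoding: continuous class codes for multi-group PLS-DA
#'
#' Maps the group labels to scalar reference codes in [0, 100]: either
#' best-projection-value (BPV) codes derived from LDA histogram centres,
#' or sequential placement at regular intervals (SPRI).
#'
#' @slot scheme \code{"BPV"} or \code{"SPRI"}.
#' @slot codes named numeric vector of class codes; the reference group
#'   has code 0 and the farthest group code 100.
#' @slot referenceGroup label of the code-0 group.
#' @slot groupOrder group labels sorted by increasing code.
#' @slot centers named numeric of the underlying axis centres (BPV only;
#'   empty for SPRI).
#' @export
setClass("GroupEncoding",
  representation(
    scheme = "character",
    codes = "numeric",
    referenceGroup = "character",
    groupOrder = "character",
    centers = "numeric"
  )
)

setValidity("GroupEncoding", function(object) {
  if (!(object@scheme %in% c("BPV", "SPRI")))
    return("scheme must be 'BPV' or 'SPRI'")
  cd <- object@codes
  if (is.null(names(cd))) return("codes must be named by group")
  if (anyDuplicated(cd)) return("codes must be distinct")
  if (abs(cd[[object@referenceGroup]]) > 1e-12)
    return("reference group code must be 0")
  if (abs(max(cd) - 100) > 1e-12) return("maximum code must be 100")
  if (!identical(sort(names(cd)), sort(object@groupOrder)))
    return("groupOrder must contain exactly the coded groups")
  if (is.unsorted(cd[object@groupOrder]))
    return("groupOrder must sort the groups by increasing code")
  TRUE
})

#' PLSModel: a centred NIPALS PLS1 regression model
#'
#' @slot weights n_bands x F weight matrix W, columns unit norm.
#' @slot loadings n_bands x F X-loading matrix P.
#' @slot yLoadings length-F y-loading vector q.
#' @slot scores n_samples x F score matrix T (mutually orthogonal columns).
#' @slot coefficients length-n_bands regression coefficient vector beta.
#' @slot xMean per-band centring vector.
#' @slot yMean scalar y centring value.
#' @slot ssyF per-component explained sum of squares of Y.
#' @slot ssyTotal total centred sum of squares of Y.
#' @slot wavelengths wavelengths (nm) of the modelled bands (may be empty
#'   when the model was fitted on a plain matrix).
#' @export
setClass("PLSModel",
  representation(
    weights = "matrix",
    loadings = "matrix",
    yLoadings = "numeric",
    scores = "matrix",
    coefficients = "numeric",
    xMean = "numeric",
    yMean = "numeric",
    ssyF = "numeric",
    ssyTotal = "numeric",
    wavelengths = "numeric"
  )
)

setValidity("PLSModel", function(object) {
  Fc <- ncol(object@weights)
  if (ncol(object@loadings) != Fc || length(object@yLoadings) != Fc ||
      ncol(object@scores) != Fc || length(object@ssyF) != Fc)
    return("component dimensions are inconsistent")
  if (length(object@coefficients) != nrow(object@weights) ||
      length(object@xMean) != nrow(object@weights))
    return("band dimensions are inconsistent")
  G <- crossprod(object@scores)
  nrm <- sqrt(pmax(diag(G), 1e-300))
  C <- G / tcrossprod(nrm)
  if (max(abs(C - diag(ncol(C)))) > 1e-8)
    return("score columns must be mutually orthogonal")
  if (any(object@ssyF < -1e-10))
    return("per-component explained Y sums of squares must be >= 0")
  if (sum(object@ssyF) > object@ssyTotal * (1 + 1e-8) + 1e-10)
    return("explained Y sum of squares cannot exceed the total")
  TRUE
})

#' BandSelection: result of VIP-filtered SPA waveband selection
#'
#' @slot selectedIndices ordered band indices (into the full grid) in SPA
#'   selection order; no duplicates; at most 20.
#' @slot selectedWavelengths wavelengths (nm) of the selected bands.
#' @slot vipScores full-length per-band VIP scores of the full-spectrum
#'   model.
#' @slot candidates band indices that passed the VIP threshold filter.
#' @slot criterionTrace data.frame with one row per evaluated
#'   (start, size) SPA candidate: columns \code{start}, \code{m},
#'   \code{error} (validation misclassification rate).
#' @slot scheme encoding scheme the selection was evaluated under.
#' @slot truncated TRUE when the SPA chain exhausted the matrix rank
#'   before reaching the requested length.
#' @export
setClass("BandSelection",
  representation(
    selectedIndices = "integer",
    selectedWavelengths = "numeric",
    vipScores = "numeric",
    candidates = "integer",
    criterionTrace = "data.frame",
    scheme = "character",
    truncated = "logical"
  ),
  prototype(truncated = FALSE)
)

setValidity("BandSelection", function(object) {
  if (anyDuplicated(object@selectedIndices))
    return("selected indices must not contain duplicates")
  if (length(object@selectedIndices) > 20L)
    return("at most 20 bands may be selected")
  if (length(object@selectedWavelengths) != length(object@selectedIndices))
    return("selectedWavelengths must match selectedIndices")
  if (length(object@candidates) &&
      !all(object@selectedIndices %in% object@candidates))
    return("every selected band must have passed the VIP filter")
  TRUE
})

#' AccuracyTable: per-group and macro-averaged classification accuracy
#'
#' Mirrors the usual calibration/validation accounting for discriminant
#' models: per-group totals, correct counts, per-group accuracy in %, and
#' an overall accuracy defined as the unweighted (macro) mean of the
#' per-group accuracies.
#'
#' @slot counts data.frame with columns \code{group}, \code{total},
#'   \code{correct}, \code{accuracy} (exact, unrounded percent).
#' @slot overall exact macro-averaged accuracy in percent.
#' @export
setClass("AccuracyTable",
  representation(counts = "data.frame", overall = "numeric")
)

setValidity("AccuracyTable", function(object) {
  cts <- object@counts
  need <- c("group", "total", "correct", "accuracy")
  if (!all(need %in% colnames(cts)))
    return(paste("counts must contain", paste(need, collapse = ", ")))
  if (any(cts$correct < 0) || any(cts$correct > cts$total))
    return("0 <= correct <= total must hold per group")
  TRUE
})

#' PredictionMap: pixel-wise predicted class-code image
#'
#' @slot values numeric matrix (lines x samples) of predicted class
#'   codes; NA outside the leaf mask.
#' @slot mask logical leaf mask of the same shape.
#' @slot colormapRange length-2 numeric (lo, hi) in code units.
#' @export
setClass("PredictionMap",
  representation(values = "matrix", mask = "matrix",
                 colormapRange = "numeric")
)

setValidity("PredictionMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must share the same shape")
  if (any(!is.na(object@values[!object@mask])))
    return("values must be NA outside the mask")
  if (any(is.na(object@values[object@mask])))
    return("values must be defined on every mask pixel")
  r <- object@colormapRange
  if (length(r) != 2L || r[1L] >= r[2L])
    return("colormapRange must be (lo, hi) with lo < hi")
  TRUE
})
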