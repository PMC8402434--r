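# ENVI raster + header I/O, white/dark reflectance calibration and
# spectral cropping. The ENVI convention stores a cube as a raw binary
# file plus a small text header declaring samples/lines/bands, the byte
# interleave (bil/bip/bsq), the data type and the wavelength list.

# ENVI numeric data-type codes we support.
.enviTypes <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

# Parse an ENVI header file into a named list of strings / string vectors.
parseEnviHeader <- function(headerPath) {
  lines <- readLines(headerPath, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln, fixed = TRUE)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("\\}", val) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
      val <- val[nzchar(val)]
    }
    out[[key]] <- val
    i <- i + 1L
  }
  out
}

#' Read an ENVI header/raster pair into a HyperCube
#'
#' Materializes the cube in lines x samples x bands order regardless of
#' the file's interleave, and parses the wavelength list (nm) from the
#' header.
#'
#' @param headerPath path to the ENVI text header (.hdr).
#' @param dataPath path to the raw binary file; defaults to
#'   \code{headerPath} with the .hdr extension removed (or .dat appended).
#' @return A \linkS4class{HyperCube}. The \code{units} tag is taken from
#'   the optional header key \code{reflectance units}; otherwise cubes of
#'   integer data type are tagged \code{raw} and floating-point cubes
#'   \code{reflectance}.
#' @seealso \code{\link{writeENVI}}
#' @export
readENVI <- function(headerPath, dataPath = NULL) {
  if (is.null(dataPath)) {
    dataPath <- sub("\\.hdr$", "", headerPath)
    if (identical(dataPath, headerPath))
      dataPath <- paste0(headerPath, ".dat")
  }
  h <- parseEnviHeader(headerPath)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  missing <- setdiff(need, names(h))
  if (length(missing))
    stop("ENVI header is missing: ", paste(missing, collapse = ", "))
  if (!("wavelength" %in% names(h)))
    stop("ENVI header declares no wavelength list")
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  wl <- as.numeric(h$wavelength)
  if (length(wl) != nb)
    stop("header declares ", nb, " bands but lists ", length(wl),
         " wavelengths")
  interleave <- tolower(h$interleave)
  if (!(interleave %in% c("bil", "bip", "bsq")))
    stop("unsupported interleave: ", interleave)
  tp <- .enviTypes[[as.character(as.integer(h$`data type`))]]
  if (is.null(tp)) stop("unsupported ENVI data type: ", h$`data type`)

  nVal <- as.numeric(ns) * nl * nb
  expect <- nVal * tp$size
  actual <- file.size(dataPath)
  if (is.na(actual) || actual != expect)
    stop("declared dimensions imply ", expect, " bytes but the data file ",
         "has ", actual)
  con <- file(dataPath, "rb")
  on.exit(close(con))
  v <- readBin(con, what = tp$what, n = nVal, size = tp$size,
               signed = tp$signed, endian = "little")
  data <- switch(interleave,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3L, 2L, 1L))
  )
  units <- if (!is.null(h$`reflectance units`)) h$`reflectance units`
           else if (tp$what == "integer") "raw" else "reflectance"
  meta <- h[setdiff(names(h), c(need, "wavelength", "byte order",
                                "header offset", "file type",
                                "reflectance units", "wavelength units"))]
  HyperCube(data, wl, units = units, metadata = meta)
}

#' Write a HyperCube as an ENVI header/raster pair
#'
#' Raw-count cubes are written as little-endian unsigned 16-bit integers
#' (ENVI data type 12) and reflectance cubes as 32-bit floats (type 4).
#' The wavelength block is written to full double precision so it
#' re-parses exactly.
#'
#' @param cube a \linkS4class{HyperCube}.
#' @param headerPath output header path.
#' @param dataPath output binary path (default: header path minus .hdr).
#' @param interleave one of \code{"bil"}, \code{"bip"}, \code{"bsq"}.
#' @return invisibly, a list with the two paths written.
#' @export
writeENVI <- function(cube, headerPath, dataPath = NULL,
                      interleave = c("bil", "bip", "bsq")) {
  interleave <- match.arg(interleave)
  if (is.null(dataPath)) {
    dataPath <- sub("\\.hdr$", "", headerPath)
    if (identical(dataPath, headerPath))
      dataPath <- paste0(headerPath, ".dat")
  }
  d <- dim(cube@data)
  nl <- d[1L]; ns <- d[2L]; nb <- d[3L]
  raw <- cube@units == "raw"
  dtype <- if (raw) 12L else 4L
  size <- if (raw) 2L else 4L

  v <- switch(interleave,
    bsq = as.vector(aperm(cube@data, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube@data, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube@data, c(3L, 2L, 1L)))
  )
  con <- file(dataPath, "wb")
  if (raw) writeBin(as.integer(v), con, size = size, endian = "little")
  else writeBin(as.numeric(v), con, size = size, endian = "little")
  close(con)

  wlBlock <- paste(format(cube@wavelengths, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   collapse = ",\n ")
  extra <- ""
  if (length(cube@metadata)) {
    kv <- vapply(names(cube@metadata), function(k)
      sprintf("%s = %s", k, paste(cube@metadata[[k]], collapse = ", ")),
      character(1L))
    extra <- paste0(paste(kv, collapse = "\n"), "\n")
  }
  hdr <- sprintf(paste0(
    "ENVI\nsamples = %d\nlines = %d\nbands = %d\nheader offset = 0\n",
    "file type = ENVI Standard\ndata type = %d\ninterleave = %s\n",
    "byte order = 0\nreflectance units = %s\n%s",
    "wavelength units = Nanometers\nwavelength = {\n %s\n}\n"),
    ns, nl, nb, dtype, interleave, cube@units, extra, wlBlock)
  writeLines(hdr, headerPath, sep = "")
  invisible(list(header = headerPath, data = dataPath))
}

#' White/dark reflectance calibration
#'
#' Converts raw counts to reflectance with the standard two-point
#' correction \eqn{R = (S - D) / (W - D)} per pixel and band, where the
#' white and dark reference cubes are first averaged over their spatial
#' extent band-wise (references may be single-line scans or full cubes).
#' The result is clamped to \code{[0, clipMax]}: detector noise can push
#' the sample signal below the dark reference.
#'
#' @param raw sample \linkS4class{HyperCube} (counts).
#' @param white,dark reference \linkS4class{HyperCube}s on the identical
#'   band axis.
#' @param clipMax upper clamp for the reflectance values (default 2).
#' @return A reflectance-tagged \linkS4class{HyperCube} with the shape of
#'   \code{raw}.
#' @examples
#' wl <- c(500, 600)
#' S <- HyperCube(array(50, c(2, 2, 2)), wl)
#' W <- HyperCube(array(100, c(1, 2, 2)), wl)
#' D <- HyperCube(array(0, c(1, 2, 2)), wl)
#' range(calibrateReflectance(S, W, D)@data)   # 0.5 everywhere
#' @export
calibrateReflectance <- function(raw, white, dark, clipMax = 2) {
  if (!isTRUE(all.equal(raw@wavelengths, white@wavelengths)) ||
      !isTRUE(all.equal(raw@wavelengths, dark@wavelengths)))
    stop("sample and reference cubes must share one band axis")
  w <- apply(white@data, 3L, mean)
  d <- apply(dark@data, 3L, mean)
  bad <- which(w - d <= 0)
  if (length(bad))
    stop("white minus dark reference is not positive at band ", bad[1L],
         " (", format(raw@wavelengths[bad[1L]]), " nm)")
  dd <- dim(raw@data)
  denom <- aperm(array(w - d, c(dd[3L], dd[1L], dd[2L])), c(2L, 3L, 1L))
  darkA <- aperm(array(d, c(dd[3L], dd[1L], dd[2L])), c(2L, 3L, 1L))
  refl <- (raw@data - darkA) / denom
  refl <- pmin(pmax(refl, 0), clipMax)
  HyperCube(refl, raw@wavelengths, units = "reflectance",
            metadata = raw@metadata)
}

#' Crop a cube to a wavelength range
#'
#' Retains the bands with \code{lambdaMin <= wavelength <= lambdaMax};
#' spectral ranges with low signal (e.g. beyond 1800 nm on SWIR sensors)
#' are typically discarded this way before analysis.
#'
#' @param cube a \linkS4class{HyperCube}.
#' @param lambdaMin,lambdaMax inclusive wavelength limits in nm.
#' @return the cropped \linkS4class{HyperCube}.
#' @export
cropBands <- function(cube, lambdaMin, lambdaMax) {
  if (lambdaMin > lambdaMax) stop("lambdaMin must be <= lambdaMax")
  keep <- which(cube@wavelengths >= lambdaMin &
                cube@wavelengths <= lambdaMax)
  if (!length(keep))
    stop("no bands lie within [", lambdaMin, ", ", lambdaMax, "] nm")
  HyperCube(cube@data[, , keep, drop = FALSE], cube@wavelengths[keep],
            units = cube@units, metadata = cube@metadata)
}
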