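# Internal numeric helpers shared across modules.

# Round half away from zero to `digits` decimals (display convention for
# accuracy tables; base round() is round-half-even).
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Index of the grid band nearest to each requested wavelength (nm).
nearestBand <- function(grid, lambda) {
  vapply(lambda, function(l) which.min(abs(grid - l)), integer(1L))
}

# Smooth a white-noise vector with a normalized Gaussian kernel of width
# `len` bands, rescaled so the marginal SD is preserved. Uses reflected
# padding so edge bands keep the same variance.
gaussianSmooth <- function(x, len) {
  if (len <= 1) return(x)
  half <- ceiling(3 * len)
  k <- exp(-0.5 * ((-half:half) / len)^2)
  k <- k / sum(k)
  k <- k / sqrt(sum(k^2))      # restore unit marginal variance
  n <- length(x)
  pad <- c(rev(x[seq_len(min(half, n))]), x,
           rev(x[seq.int(to = n, length.out = min(half, n))]))
  if (length(pad) < n + 2L * half)   # very short inputs: tile the padding
    pad <- rep_len(pad, n + 2L * half)
  out <- stats::convolve(pad, rev(k), type = "filter")
  # convolve(type="filter") returns length(pad) - 2*half values, aligned
  # with the unpadded vector when pad has exactly `half` on each side
  out[seq_len(n)]
}

# Derive a named substream seed from a root seed, kept below 2^31.
subSeed <- function(seed, stream) {
  offs <- c(simulate = 11L, split = 23L, cv = 37L, cube = 51L, spa = 67L)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 101 + offs[[stream]]) %% 2147483587)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
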