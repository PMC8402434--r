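# Shared fixture builders for the test-suite. Everything is generated in
# code; no binary fixtures are stored.

# Small labelled spectrum table with well-separated groups (no simulator
# involvement), for LDA / PLS unit tests.
makeToyTable <- function(n = 15L, p = 10L, sep = 2, seed = 1L,
                         groups = c("BH", "AR", "AS")) {
  set.seed(seed)
  shift <- seq(0, sep, length.out = length(groups))
  rows <- lapply(seq_along(groups), function(g)
    matrix(rnorm(n * p, 0, 0.3), n, p) +
      matrix(shift[g] * c(rep(1, 3), rep(0, p - 3)), n, p, byrow = TRUE))
  SpectrumTable(do.call(rbind, rows), seq(400, 700, length.out = p),
                group = rep(groups, each = n))
}

# Deterministic dyadic-rational cube values so float32 ENVI round-trips
# are exact.
makeDyadicCube <- function(lines = 8L, samples = 8L, bands = 16L,
                           seed = 1L, units = "reflectance") {
  set.seed(seed)
  v <- sample.int(1024L, lines * samples * bands, replace = TRUE) / 1024
  HyperCube(array(v, c(lines, samples, bands)),
            wavelengths = seq(400, 1000, length.out = bands),
            units = units)
}

# Independent brute-force SPA oracle: exhaustive Gram-Schmidt recursion.
spaOracle <- function(x, start, mMax) {
  chain <- start
  basis <- matrix(x[, start] / sqrt(sum(x[, start]^2)), ncol = 1L)
  for (step in seq_len(mMax - 1L)) {
    norms <- vapply(seq_len(ncol(x)), function(j) {
      if (j %in% chain) return(-Inf)
      v <- x[, j]
      for (k in seq_len(ncol(basis))) v <- v - sum(v * basis[, k]) * basis[, k]
      sqrt(sum(v^2))
    }, numeric(1L))
    if (max(norms) < 1e-12) break
    nxt <- which.max(norms)
    chain <- c(chain, nxt)
    v <- x[, nxt]
    for (k in seq_len(ncol(basis))) v <- v - sum(v * basis[, k]) * basis[, k]
    basis <- cbind(basis, v / sqrt(sum(v^2)))
  }
  chain
}

# Independent PLS1 oracle via the Krylov-subspace closed form:
# beta_F = K (K' X'X K)^{-1} K' X'y with K spanning {s, As, ..., A^{F-1}s}.
plsKrylovBeta <- function(x, y, nLV) {
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2L, xm); yc <- y - ym
  A <- crossprod(xc); s <- crossprod(xc, yc)
  K <- matrix(0, ncol(x), nLV)
  v <- s
  for (f in seq_len(nLV)) { K[, f] <- v; v <- A %*% v }
  K <- qr.Q(qr(K))
  as.vector(K %*% solve(crossprod(K, A %*% K), crossprod(K, s)))
}

# All 16 printed rows of the reference study's accuracy accounting
# (region, scheme, band set, split, per-group totals and correct counts
# in BH/AR/AS order, printed per-group accuracies and printed overall).
referenceAccuracyRows <- function() {
  rows <- list(
    list("visnir", "BPV", "full", "cal", c(251, 128, 96), c(231, 113, 59),
         c(92.0, 88.3, 61.5), 80.6),
    list("visnir", "BPV", "full", "val", c(126, 64, 48), c(110, 57, 22),
         c(87.3, 89.1, 45.8), 74.1),
    list("visnir", "BPV", "main", "cal", c(251, 128, 96), c(229, 113, 57),
         c(91.2, 88.3, 59.4), 79.6),
    list("visnir", "BPV", "main", "val", c(126, 64, 48), c(108, 57, 24),
         c(85.7, 89.1, 50.0), 74.9),
    list("visnir", "SPRI", "full", "cal", c(251, 128, 96), c(218, 118, 68),
         c(86.9, 92.2, 70.8), 83.3),
    list("visnir", "SPRI", "full", "val", c(126, 64, 48), c(105, 58, 27),
         c(83.3, 90.6, 56.3), 76.7),
    list("visnir", "SPRI", "main", "cal", c(251, 128, 96), c(230, 115, 60),
         c(91.6, 89.8, 62.5), 81.3),
    list("visnir", "SPRI", "main", "val", c(126, 64, 48), c(117, 58, 26),
         c(92.9, 90.6, 54.2), 79.2),
    list("swir", "BPV", "full", "cal", c(251, 85, 113), c(251, 81, 97),
         c(100.0, 95.3, 85.8), 93.7),
    list("swir", "BPV", "full", "val", c(126, 42, 56), c(126, 38, 51),
         c(100.0, 90.5, 91.1), 93.8),
    list("swir", "BPV", "main", "cal", c(251, 85, 113), c(251, 75, 84),
         c(100.0, 88.2, 74.3), 87.5),
    list("swir", "BPV", "main", "val", c(126, 42, 56), c(126, 33, 47),
         c(100.0, 78.6, 83.9), 87.5),
    list("swir", "SPRI", "full", "cal", c(251, 85, 113), c(250, 85, 113),
         c(99.6, 100.0, 100.0), 99.9),
    list("swir", "SPRI", "full", "val", c(126, 42, 56), c(126, 42, 56),
         c(100.0, 100.0, 100.0), 100.0),
    list("swir", "SPRI", "main", "cal", c(251, 85, 113), c(250, 85, 112),
         c(99.6, 100.0, 99.1), 99.6),
    list("swir", "SPRI", "main", "val", c(126, 42, 56), c(125, 41, 56),
         c(99.2, 97.6, 100.0), 98.9)
  )
  do.call(rbind, lapply(rows, function(r)
    data.frame(region = r[[1]], scheme = r[[2]], bands = r[[3]],
               split = r[[4]],
               total_BH = r[[5]][1], total_AR = r[[5]][2],
               total_AS = r[[5]][3],
               correct_BH = r[[6]][1], correct_AR = r[[6]][2],
               correct_AS = r[[6]][3],
               acc_BH = r[[7]][1], acc_AR = r[[7]][2], acc_AS = r[[7]][3],
               overall = r[[8]])))
}
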