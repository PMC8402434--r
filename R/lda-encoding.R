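# Continuous class codes for multi-group PLS-DA. Two schemes:
#   BPV  - each group's code is derived from the centre of its histogram
#          of best projection values on the leading LDA axis, rescaled so
#          the reference group maps to 0 and the farthest group to 100;
#   SPRI - sequential placement at regular intervals (0, 50, 100 for
#          three groups) in the LDA-derived group order.

#' Fit a shrinkage-regularized linear discriminant model
#'
#' Solves the generalized eigenproblem for between- versus within-class
#' scatter on the mean-centred spectra. The within-class scatter is
#' regularized as \eqn{(1 - s) S_W + s\,\mathrm{diag}(S_W)} with shrinkage
#' intensity \eqn{s}; with a hundred-plus strongly correlated bands the
#' unregularized \eqn{S_W} is ill-conditioned, hence the 0.1 default.
#' Axes are unit-norm, sorted by decreasing eigenvalue and sign-fixed so
#' the reference group's centre lies at the low end of each axis.
#'
#' @param x a \linkS4class{SpectrumTable}, or a samples x bands matrix.
#' @param groups group labels (ignored when \code{x} is a SpectrumTable).
#' @param shrinkage shrinkage intensity in [0, 1] (default 0.1).
#' @param referenceGroup baseline group label; defaults to \code{"BH"}
#'   when present, else the first sorted label.
#' @param chosenAxis index of the discriminant axis used for best
#'   projection values (default 1, the largest-eigenvalue axis).
#' @return An \linkS4class{LDAModel}.
#' @export
fitLDA <- function(x, groups = NULL, shrinkage = 0.1,
                   referenceGroup = NULL, chosenAxis = 1L) {
  if (is(x, "SpectrumTable")) {
    groups <- sampleGroups(x)
    x <- spectra(x)
  }
  x <- as.matrix(x)
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  G <- length(glev)
  if (G < 2L) stop("at least 2 groups are required")
  cnt <- table(groups)
  if (any(cnt < 2L)) stop("every group needs at least 2 samples")
  n <- nrow(x); p <- ncol(x)
  if (n <= G) stop("more samples than groups are required")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must lie in [0, 1]")

  centering <- colMeans(x)
  xc <- sweep(x, 2L, centering)
  means <- do.call(rbind, lapply(glev, function(g)
    colMeans(xc[groups == g, , drop = FALSE])))
  rownames(means) <- glev

  Sw <- matrix(0, p, p)
  for (g in glev) {
    xg <- sweep(xc[groups == g, , drop = FALSE], 2L, means[g, ])
    Sw <- Sw + crossprod(xg)
  }
  Sw <- Sw / (n - G)
  Sb <- matrix(0, p, p)
  for (g in glev)
    Sb <- Sb + cnt[[g]] * tcrossprod(means[g, ])
  Sb <- Sb / (G - 1)

  SwReg <- (1 - shrinkage) * Sw + shrinkage * diag(diag(Sw), p)
  R <- tryCatch(chol(SwReg), error = function(e) NULL)
  if (is.null(R))
    stop("within-class scatter is singular",
         if (shrinkage == 0) "; increase 'shrinkage'" else "")
  # whiten: R'^{-1} Sb R^{-1} is symmetric with the same eigenvalues
  M <- backsolve(R, t(backsolve(R, t(Sb), transpose = TRUE)),
                 transpose = TRUE)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  K <- min(G - 1L, p)
  axes <- backsolve(R, eig$vectors[, seq_len(K), drop = FALSE])
  axes <- sweep(axes, 2L, sqrt(colSums(axes^2)), "/")

  if (is.null(referenceGroup))
    referenceGroup <- if ("BH" %in% glev) "BH" else glev[1L]
  proj <- means %*% axes
  for (k in seq_len(K)) {
    others <- proj[setdiff(glev, referenceGroup), k]
    if (proj[referenceGroup, k] > mean(others)) {
      axes[, k] <- -axes[, k]
      proj[, k] <- -proj[, k]
    }
  }
  chosenAxis <- as.integer(chosenAxis)
  if (chosenAxis < 1L || chosenAxis > K)
    stop("chosenAxis must lie in 1..", K)
  new("LDAModel", axes = axes,
      eigenvalues = pmax(eig$values[seq_len(K)], 0),
      groupCenters1D = stats::setNames(proj[, chosenAxis], glev),
      chosenAxis = chosenAxis, centering = centering,
      shrinkage = shrinkage, referenceGroup = referenceGroup)
}

#' Best projection values
#'
#' Projects mean-centred spectra onto the model's chosen discriminant
#' axis, yielding one scalar (the BPV) per sample.
#'
#' @param model an \linkS4class{LDAModel}.
#' @param x a \linkS4class{SpectrumTable} or samples x bands matrix on the
#'   training band axis.
#' @return numeric vector of projection values.
#' @export
bestProjectionValues <- function(model, x) {
  if (is(x, "SpectrumTable")) x <- spectra(x)
  x <- as.matrix(x)
  if (ncol(x) != length(model@centering))
    stop("band axis does not match the fitted model")
  as.vector(sweep(x, 2L, model@centering) %*%
              model@axes[, model@chosenAxis])
}

#' Encode groups by best-projection-value histogram centres
#'
#' Each group's centre is the mean of a Gaussian fit to its BPVs (for a
#' normal histogram the fitted centre equals the sample mean). Codes are
#' the centres rescaled affinely so the reference group maps to 0 and the
#' group farthest from it maps to 100, rounded to the nearest integer.
#'
#' @param bpv numeric vector of best projection values.
#' @param groups group label per value.
#' @param referenceGroup label of the code-0 group (default \code{"BH"}).
#' @return A \linkS4class{GroupEncoding} with scheme \code{"BPV"}.
#' @examples
#' bpv <- c(rnorm(20, -2), rnorm(20, 1), rnorm(20, 2))
#' g <- rep(c("BH", "AR", "AS"), each = 20)
#' encodeGroupsBPV(bpv, g)
#' @export
encodeGroupsBPV <- function(bpv, groups, referenceGroup = "BH") {
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  if (!(referenceGroup %in% glev))
    stop("referenceGroup not present in 'groups'")
  if (any(table(groups) < 3L))
    stop("every group needs at least 3 samples for a histogram centre")
  centers <- vapply(glev, function(g) mean(bpv[groups == g]), numeric(1L))
  d <- abs(centers - centers[[referenceGroup]])
  if (any(stats::dist(centers) < 1e-9))
    stop("two group centres coincide; the encoding is degenerate")
  far <- names(which.max(d))
  codes <- 100 * (centers - centers[[referenceGroup]]) /
    (centers[[far]] - centers[[referenceGroup]])
  codes <- roundHalfUp(codes)
  new("GroupEncoding", scheme = "BPV", codes = codes,
      referenceGroup = referenceGroup,
      groupOrder = names(sort(codes)), centers = centers)
}

#' Encode groups at regular intervals (SPRI)
#'
#' Places class codes at equal spacing 0, 100/(G-1), ..., 100 along a
#' given group order (reference group first). For three groups the codes
#' are exactly 0, 50 and 100.
#'
#' @param groupOrder character vector of group labels, reference first;
#'   typically the centre order of a BPV encoding so that either spectral
#'   region's empirical ordering is preserved.
#' @return A \linkS4class{GroupEncoding} with scheme \code{"SPRI"}.
#' @examples
#' groupCodes(encodeGroupsSPRI(c("BH", "AR", "AS")))
#' @export
encodeGroupsSPRI <- function(groupOrder) {
  groupOrder <- as.character(groupOrder)
  if (anyDuplicated(groupOrder)) stop("duplicate group labels")
  G <- length(groupOrder)
  if (G < 2L) stop("at least 2 groups are required")
  codes <- stats::setNames(seq(0, 100, length.out = G), groupOrder)
  new("GroupEncoding", scheme = "SPRI", codes = codes,
      referenceGroup = groupOrder[1L], groupOrder = groupOrder,
      centers = numeric(0))
}

#' Class codes for a vector of group labels
#'
#' @param encoding a \linkS4class{GroupEncoding}.
#' @param groups character vector of group labels.
#' @return numeric vector of codes, one per label.
#' @export
codesFor <- function(encoding, groups) {
  groups <- as.character(groups)
  unknown <- setdiff(unique(groups), names(encoding@codes))
  if (length(unknown))
    stop("labels without a code: ", paste(unknown, collapse = ", "))
  unname(encoding@codes[groups])
}

#' Serialize a GroupEncoding to JSON
#'
#' @param encoding a \linkS4class{GroupEncoding}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEncodingJSON <- function(encoding, path) {
  jsonlite::write_json(list(
    scheme = encoding@scheme,
    reference_group = encoding@referenceGroup,
    codes = as.list(encoding@codes),
    group_order = encoding@groupOrder,
    centers = as.list(encoding@centers)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
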