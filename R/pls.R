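# Single-response (PLS1) partial least squares regression against the
# continuous class codes, latent-variable selection by cross-validation,
# nearest-code classification, per-group accuracy accounting and
# variable-importance-in-projection (VIP) scoring.

#' Fit a centred NIPALS PLS1 model
#'
#' Classical PLS1 with deflation on the mean-centred predictor matrix and
#' response: at each component the weight vector is
#' \eqn{w_f = X'y / \|X'y\|}, scores \eqn{t_f = X w_f}, X-loading
#' \eqn{p_f = X't_f / t_f't_f}, y-loading \eqn{q_f = y't_f / t_f't_f},
#' followed by rank-one deflation of both X and y. The per-component
#' explained response sum of squares is \eqn{SSY_f = q_f^2\, t_f't_f}.
#'
#' @param x samples x bands numeric matrix (or
#'   \linkS4class{SpectrumTable}).
#' @param y numeric response (class codes), non-constant.
#' @param nLV number of latent variables F, with
#'   \code{nLV <= min(n - 1, n_bands)}.
#' @param wavelengths optional band wavelengths stored with the model
#'   (taken from \code{x} when it is a SpectrumTable).
#' @return A \linkS4class{PLSModel}.
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' y <- x[, 1] - x[, 5] + rnorm(20, 0, 0.1)
#' m <- fitPLS1(x, y, nLV = 3)
#' m
#' @export
fitPLS1 <- function(x, y, nLV, wavelengths = numeric(0)) {
  if (is(x, "SpectrumTable")) {
    wavelengths <- wavelengths(x)
    x <- spectra(x)
  }
  x <- unname(as.matrix(x))
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y dimensions disagree")
  if (stats::var(y) == 0) stop("y has zero variance")
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > min(n - 1L, p))
    stop("nLV must lie in 1..min(n - 1, n_bands) = ", min(n - 1L, p))

  xMean <- colMeans(x); yMean <- mean(y)
  Xd <- sweep(x, 2L, xMean); yd <- y - yMean
  ssyTotal <- sum(yd^2)
  W <- P <- matrix(0, p, nLV)
  Tm <- matrix(0, n, nLV)
  q <- ssy <- numeric(nLV)
  for (f in seq_len(nLV)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {           # response fully deflated: trim components
      nLV <- f - 1L
      if (nLV == 0L) stop("y carries no covariance with x")
      W <- W[, seq_len(nLV), drop = FALSE]
      P <- P[, seq_len(nLV), drop = FALSE]
      Tm <- Tm[, seq_len(nLV), drop = FALSE]
      q <- q[seq_len(nLV)]; ssy <- ssy[seq_len(nLV)]
      break
    }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pv <- crossprod(Xd, t) / tt
    qf <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pv)
    yd <- yd - qf * t
    W[, f] <- w; P[, f] <- pv; Tm[, f] <- t
    q[f] <- qf; ssy[f] <- qf^2 * tt
  }
  beta <- as.vector(W %*% solve(crossprod(P, W), q))
  new("PLSModel", weights = W, loadings = P, yLoadings = q, scores = Tm,
      coefficients = beta, xMean = xMean, yMean = yMean, ssyF = ssy,
      ssyTotal = ssyTotal, wavelengths = as.numeric(wavelengths))
}

#' @describeIn fitPLS1 predict continuous class-code scores:
#'   \eqn{\hat y = (x - \bar x)\beta + \bar y} per row.
#' @param object a fitted \linkS4class{PLSModel}.
#' @param newdata samples x bands matrix (or SpectrumTable) on the
#'   training band axis.
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
  if (is(newdata, "SpectrumTable")) newdata <- spectra(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@xMean))
    stop("band axis does not match the fitted model")
  as.vector(sweep(newdata, 2L, object@xMean) %*% object@coefficients +
              object@yMean)
})

# Nested predictions: one column per component count 1..F, computed by
# sequential deflation of the new data (used by cross-validation).
predictNested <- function(model, x) {
  x <- as.matrix(x)
  Fc <- ncol(model@weights)
  Xd <- sweep(x, 2L, model@xMean)
  out <- matrix(model@yMean, nrow(x), Fc)
  acc <- rep(model@yMean, nrow(x))
  for (f in seq_len(Fc)) {
    t <- Xd %*% model@weights[, f]
    Xd <- Xd - t %*% t(model@loadings[, f])
    acc <- acc + model@yLoadings[f] * t
    out[, f] <- acc
  }
  out
}

#' Choose the number of latent variables by cross-validation
#'
#' k-fold cross-validation of the root-mean-square error of prediction
#' (RMSEP); returns the smallest component count whose RMSEP is within 2\%
#' of the global minimum (one-sided parsimony rule).
#'
#' @param x samples x bands matrix (or \linkS4class{SpectrumTable}).
#' @param y numeric response.
#' @param maxLV largest component count examined (capped at
#'   \code{min(n_train - 1, n_bands)}).
#' @param folds number of folds (>= 2, default 5).
#' @param seed integer seed for the fold assignment.
#' @return the chosen integer component count, with the per-count RMSEP in
#'   attribute \code{"rmsep"}.
#' @export
chooseNLV <- function(x, y, maxLV = 15L, folds = 5L, seed = 1L) {
  if (is(x, "SpectrumTable")) x <- spectra(x)
  x <- as.matrix(x); y <- as.numeric(y)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  n <- nrow(x)
  maxLV <- min(as.integer(maxLV), n - ceiling(n / folds) - 1L, ncol(x))
  if (maxLV < 1L) stop("too few samples for cross-validation")
  # content-based fold assignment: identical samples share a fold, so
  # duplicating the data leaves the cross-validation curve unchanged
  key <- do.call(paste, c(as.data.frame(x), list(y)))
  uk <- unique(key)
  foldU <- withSeed(seed, sample(rep_len(seq_len(folds), length(uk))))
  fold <- foldU[match(key, uk)]
  sse <- numeric(maxLV)
  for (k in seq_len(folds)) {
    test <- fold == k
    m <- fitPLS1(x[!test, , drop = FALSE], y[!test], maxLV)
    pred <- predictNested(m, x[test, , drop = FALSE])
    if (ncol(pred) < maxLV)   # deflation exhausted early: extend last col
      pred <- cbind(pred, pred[, rep(ncol(pred), maxLV - ncol(pred)),
                               drop = FALSE])
    sse <- sse + colSums((pred - y[test])^2)
  }
  rmsep <- sqrt(sse / n)
  best <- which(rmsep <= min(rmsep) * 1.02)[1L]
  structure(as.integer(best), rmsep = rmsep)
}

#' Nearest-code classification of predicted scores
#'
#' Assigns each continuous predicted score to the group whose class code
#' is nearest; ties break toward the lower code.
#'
#' @param scores numeric vector of predicted class-code scores.
#' @param encoding a \linkS4class{GroupEncoding}.
#' @return character vector of group labels.
#' @examples
#' enc <- encodeGroupsSPRI(c("BH", "AR", "AS"))
#' classifyScores(c(-10, 49, 95), enc)
#' @export
classifyScores <- function(scores, encoding) {
  codes <- sort(encoding@codes)          # ascending: ties pick lower code
  labs <- names(codes)
  labs[vapply(scores, function(s) which.min(abs(s - codes)), integer(1L))]
}

#' Per-group and macro-averaged accuracy accounting
#'
#' Computes, per group, the total, the number of correct assignments and
#' the accuracy \code{100 * correct / total}; the overall accuracy is the
#' unweighted (macro) mean of the per-group accuracies. Display rounding
#' is half-up to one decimal.
#'
#' @param predicted predicted group labels.
#' @param truth true group labels (every group must be non-empty).
#' @param groupOrder row order of the output (default: sorted labels).
#' @return An \linkS4class{AccuracyTable}.
#' @examples
#' at <- accuracyTable(c("BH", "BH", "AS"), c("BH", "AS", "AS"),
#'                     c("BH", "AS"))
#' at
#' @export
accuracyTable <- function(predicted, truth,
                          groupOrder = sort(unique(truth))) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!all(truth %in% groupOrder))
    stop("truth contains labels outside groupOrder")
  rows <- lapply(groupOrder, function(g) {
    idx <- truth == g
    if (!any(idx)) stop("group '", g, "' is empty in truth")
    data.frame(group = g, total = sum(idx),
               correct = sum(predicted[idx] == g))
  })
  cts <- do.call(rbind, rows)
  cts$accuracy <- 100 * cts$correct / cts$total
  new("AccuracyTable", counts = cts, overall = mean(cts$accuracy))
}

#' @describeIn accuracyTable build the table directly from per-group
#'   totals and correct counts (e.g. when checking published accuracy
#'   accounting).
#' @param total,correct named integer vectors of per-group totals and
#'   correct counts.
#' @export
accuracyFromCounts <- function(total, correct) {
  stopifnot(length(total) == length(correct))
  cts <- data.frame(group = if (is.null(names(total)))
                      paste0("G", seq_along(total)) else names(total),
                    total = as.integer(total),
                    correct = as.integer(correct))
  if (any(cts$correct < 0 | cts$correct > cts$total))
    stop("correct counts must lie in [0, total]")
  cts$accuracy <- 100 * cts$correct / cts$total
  new("AccuracyTable", counts = cts, overall = mean(cts$accuracy))
}

#' Displayed accuracy values (half-up, one decimal)
#'
#' @param x an \linkS4class{AccuracyTable}.
#' @return list with \code{perGroup} (named, percent) and \code{overall}.
#' @export
displayAccuracy <- function(x) {
  list(perGroup = stats::setNames(roundHalfUp(x@counts$accuracy, 1L),
                                  x@counts$group),
       overall = roundHalfUp(x@overall, 1L))
}

#' Variable importance in projection
#'
#' VIP score of band \eqn{j} over the F components of a fitted PLS1
#' model:
#' \deqn{VIP_j = \sqrt{ J \sum_f w_{jf}^2\, SSY_f \; / \; \sum_f SSY_f }}
#' with unit-norm weight vectors \eqn{w_f}, \eqn{J} the number of bands
#' and \eqn{SSY_f} the response sum of squares explained by component
#' \eqn{f}. With this normalization the mean squared VIP over bands is
#' exactly 1, so 1.0 is the natural filter threshold.
#'
#' @param x a fitted \linkS4class{PLSModel}.
#' @return numeric vector of per-band VIP scores (all >= 0).
#' @export
setMethod("vipScores", "PLSModel", function(x) {
  ssy <- x@ssyF
  if (sum(ssy) <= 0) stop("model explains no response variance")
  W <- x@weights
  wn <- sqrt(colSums(W^2))
  Wn <- sweep(W, 2L, pmax(wn, 1e-300), "/")
  J <- nrow(W)
  sqrt(J * as.vector(Wn^2 %*% ssy) / sum(ssy))
})

#' Serialize an AccuracyTable to CSV / JSON
#'
#' Emits the Total / Correct / Accuracy / Overall layout with display
#' rounding (half-up, one decimal) applied to the accuracy columns.
#'
#' @param x an \linkS4class{AccuracyTable}.
#' @param path output path (extension decides nothing; pick the writer).
#' @return the path, invisibly.
#' @export
writeAccuracyCSV <- function(x, path) {
  cts <- x@counts
  cts$accuracy <- roundHalfUp(cts$accuracy, 1L)
  cts <- rbind(cts, data.frame(group = "Overall", total = sum(cts$total),
                               correct = sum(cts$correct),
                               accuracy = roundHalfUp(x@overall, 1L)))
  utils::write.csv(cts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAccuracyCSV
#' @export
writeAccuracyJSON <- function(x, path) {
  d <- displayAccuracy(x)
  jsonlite::write_json(list(
    total = as.list(stats::setNames(x@counts$total, x@counts$group)),
    correct = as.list(stats::setNames(x@counts$correct, x@counts$group)),
    accuracy = as.list(d$perGroup),
    overall = d$overall
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
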