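# FastICA (symmetric orthogonalization, tanh contrast) and ocular-artifact
# removal by EOG correlation. The removal contract is defined by the
# correlation criterion, not the decomposition algorithm: any component whose
# absolute correlation with an EOG channel reaches the threshold is zeroed
# before back-projection.

# X: rows = signals. Returns sources S, mixing A (X ~ A %*% S + rowMeans),
# deterministic (fixed internal init seed).
fastICADecompose <- function(X, nComp = nrow(X), maxIter = 500, tol = 1e-6) {
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  C <- tcrossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-9)
  nComp <- min(nComp, length(keep))
  keep <- keep[seq_len(nComp)]
  D <- eg$values[keep]
  E <- eg$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(D), nComp) %*% t(E)      # whitening: Z = K Xc
  Z <- K %*% Xc

  symDecor <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), nComp) %*%
      t(s$vectors) %*% W
  }
  W <- withSeed(987654321L, matrix(rnorm(nComp * nComp), nComp))
  W <- symDecor(W)
  for (it in seq_len(maxIter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gPrime <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n - diag(gPrime, nComp) %*% W
    W1 <- symDecor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- E %*% diag(sqrt(D), nComp) %*% t(W)    # X ~ A S + mu
  list(S = S, A = A, mean = mu, nComp = nComp, iterations = it)
}

# Core removal on a scalp-channel matrix given EOG time courses.
icaCleanMatrix <- function(scalpX, eogX, threshold, maxIter = 500) {
  dec <- fastICADecompose(scalpX, maxIter = maxIter)
  corMat <- matrix(0, dec$nComp, nrow(eogX),
                   dimnames = list(NULL, rownames(eogX)))
  for (j in seq_len(nrow(eogX))) {
    e <- eogX[j, ]
    if (sd(e) == 0) next
    for (i in seq_len(dec$nComp)) {
      s <- dec$S[i, ]
      corMat[i, j] <- if (sd(s) == 0) 0 else cor(s, e)
    }
  }
  removed <- which(apply(abs(corMat), 1, max) >= threshold)
  if (length(removed)) {
    Skeep <- dec$S
    Skeep[removed, ] <- 0
    cleaned <- dec$A %*% Skeep + dec$mean
  } else {
    cleaned <- scalpX   # exact round-trip identity when nothing is removed
  }
  list(cleaned = cleaned,
       report = list(removed = removed,
                     correlations = corMat,
                     nComponents = dec$nComp,
                     iterations = dec$iterations,
                     threshold = threshold))
}

#' Remove ocular artifacts by ICA
#'
#' Decomposes the scalp channels (EOG channels are excluded from the
#' decomposition) with FastICA, zeroes every component whose absolute
#' correlation with any EOG channel reaches \code{threshold} (default 0.8),
#' and back-projects. When no component reaches the threshold, the data are
#' returned unchanged (exact round-trip identity). Works on a continuous
#' \code{\linkS4class{EEGRecording}} or, following the study's stated order,
#' on an already-epoched \code{\linkS4class{EEGEpochs}} (epochs are
#' concatenated for decomposition and split back afterwards).
#'
#' @param x an \code{EEGRecording} or \code{EEGEpochs} with at least one EOG
#'   channel.
#' @param threshold absolute EOG correlation at which a component is removed.
#' @param minSec minimum data length in seconds required for a stable
#'   decomposition (default 60).
#' @param maxIter FastICA iteration cap.
#' @return list with elements \code{recording} (or \code{epochs}) — the
#'   cleaned object — and \code{report} (removed component indices, the
#'   component x EOG correlation matrix, component count).
#' @export
setGeneric("removeOcularICA",
           function(x, threshold = 0.8, minSec = 60, maxIter = 500)
             standardGeneric("removeOcularICA"))

#' @rdname removeOcularICA
#' @export
setMethod("removeOcularICA", "EEGRecording",
  function(x, threshold = 0.8, minSec = 60, maxIter = 500) {
    if (!length(x@eogLabels))
      stop("no EOG channel present: skip ICA or supply a blink regressor channel")
    if (ncol(x@data) / x@fs < minSec)
      stop(sprintf("recording shorter than %g s; too little data for ICA", minSec))
    scalp <- setdiff(x@channelLabels, x@eogLabels)
    res <- icaCleanMatrix(x@data[scalp, , drop = FALSE],
                          x@data[x@eogLabels, , drop = FALSE],
                          threshold, maxIter)
    out <- x
    out@data[scalp, ] <- res$cleaned
    out <- addProvenance(out, "ica",
                         list(threshold = threshold,
                              removed = res$report$removed,
                              nComponents = res$report$nComponents))
    list(recording = out, report = res$report)
  })

#' @rdname removeOcularICA
#' @export
setMethod("removeOcularICA", "EEGEpochs",
  function(x, threshold = 0.8, minSec = 60, maxIter = 500) {
    if (!length(x@eogLabels))
      stop("no EOG channel present: skip ICA or supply a blink regressor channel")
    d <- dim(x@data)
    if (d[1] * d[3] / x@fs < minSec)
      stop(sprintf("epochs total less than %g s; too little data for ICA", minSec))
    scalp <- which(!(x@channelLabels %in% x@eogLabels))
    eog <- which(x@channelLabels %in% x@eogLabels)
    # concatenate trials: channels x (trials * samples)
    flat <- matrix(aperm(x@data, c(2, 3, 1)), nrow = d[2])
    rownames(flat) <- x@channelLabels
    res <- icaCleanMatrix(flat[scalp, , drop = FALSE],
                          flat[eog, , drop = FALSE], threshold, maxIter)
    flat[scalp, ] <- res$cleaned
    out <- x
    out@data <- aperm(array(flat, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
    out@provenance <- c(out@provenance,
                        list(list(op = "ica",
                                  params = list(threshold = threshold,
                                                removed = res$report$removed,
                                                nComponents = res$report$nComponents))))
    list(epochs = out, report = res$report)
  })
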