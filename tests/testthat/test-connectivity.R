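# WPLI estimator: analytic cases, symmetry, invariances, and the bias /
# volume-conduction behavior that motivates the index.

toneEpochs <- function(fs = 128, dur = 30, freq = 10, phases = c(0, pi / 2),
                       amps = rep(1, length(phases)), noise = 0) {
  tt <- seq_len(fs * dur) / fs
  mat <- t(vapply(seq_along(phases), function(i)
    amps[i] * sin(2 * pi * freq * tt + phases[i]) + noise * rnorm(length(tt)),
    numeric(length(tt))))
  matrixEpochs(mat, fs)
}

test_that("cross-spectra: zero-lag pairs are purely real, quarter-cycle lag has constant-sign imaginary part", {
  ep <- toneEpochs(phases = c(0, 0))
  cs <- crossSpectra(ep, "alpha")
  s <- pairSamples(cs, 1, 2)
  expect_lt(max(abs(Im(s))) / max(abs(Re(s))), 1e-8)

  ep2 <- toneEpochs(phases = c(0, pi / 2))
  cs2 <- crossSpectra(ep2, "alpha")
  bin10 <- which.min(abs(cs2@freqs - 10))
  im10 <- Im(pairSamples(cs2, 1, 2)[bin10, ])
  expect_true(all(im10 > 0) || all(im10 < 0))
})

test_that("cross-spectra are Hermitian on random data", {
  set.seed(42)
  ep <- matrixEpochs(matrix(rnorm(3 * 128 * 10), nrow = 3), fs = 128)
  cs <- crossSpectra(ep, "alpha")
  expect_equal(pairSamples(cs, 1, 2), Conj(pairSamples(cs, 2, 1)))
  expect_equal(pairSamples(cs, 2, 3), Conj(pairSamples(cs, 3, 2)))
})

test_that("WPLI estimator: hand sample, perfect lag, zero-lag convention", {
  # |1 + 2 - 1| / (1 + 2 + 1)
  expect_identical(wpliEstimate(c(1, 2, -1)), 0.5)
  expect_identical(wpliEstimate(numeric(3)), 0)   # 0/0 -> 0

  ep <- toneEpochs(phases = c(0, pi / 2))
  cs <- crossSpectra(ep, "alpha")
  bin10 <- which.min(abs(cs@freqs - 10))
  perBin <- vapply(seq_along(cs@freqs), function(f)
    wpliEstimate(Im(pairSamples(cs, 1, 2)[f, ])), 0)
  expect_equal(perBin[bin10], 1)

  ep0 <- toneEpochs(phases = c(0, 0))
  W0 <- connMatrix(wpli(crossSpectra(ep0, "alpha")))
  expect_equal(W0[1, 2], 0)
})

test_that("connectivity matrix is symmetric, zero-diagonal, in [0,1]", {
  set.seed(7)
  ep <- matrixEpochs(matrix(rnorm(4 * 128 * 8), nrow = 4), fs = 128)
  cm <- wpli(crossSpectra(ep, "alpha"))
  W <- connMatrix(cm)
  expect_equal(W, t(W))
  expect_equal(diag(W), setNames(rep(0, 4), rownames(W)))
  expect_true(all(W >= 0 & W <= 1))
  expect_true(validObject(cm))
})

test_that("WPLI is exactly invariant to positive channel rescaling", {
  set.seed(11)
  mat <- matrix(rnorm(3 * 128 * 8), nrow = 3)
  W1 <- connMatrix(wpli(crossSpectra(matrixEpochs(mat, 128), "alpha")))
  mat2 <- mat
  mat2[2, ] <- 7.3 * mat2[2, ]
  W2 <- connMatrix(wpli(crossSpectra(matrixEpochs(mat2, 128), "alpha")))
  expect_equal(W1, W2, tolerance = 1e-12)
})

test_that("a common zero-lag source does not increase expected null WPLI", {
  set.seed(23)
  fs <- 128
  wpliPair <- function(mat) {
    connMatrix(wpli(crossSpectra(matrixEpochs(mat, fs), "alpha")))[1, 2]
  }
  indep <- common <- numeric(50)
  for (r in seq_len(50)) {
    x <- rnorm(fs * 8); y <- rnorm(fs * 8)
    s <- rnorm(fs * 8)
    indep[r] <- wpliPair(rbind(x, y))
    common[r] <- wpliPair(rbind(x + 2 * s, y + 2 * s))
  }
  # one-sided: volume conduction must not inflate connectivity
  expect_lte(mean(common), mean(indep) + 0.03)
})

test_that("null WPLI bias decreases with the number of segments", {
  set.seed(31)
  fs <- 128
  biasAt <- function(nSeg) {
    # 1 s segments, no overlap -> nSeg segments
    mean(replicate(30, {
      mat <- rbind(rnorm(fs * nSeg), rnorm(fs * nSeg))
      connMatrix(wpli(crossSpectra(matrixEpochs(mat, fs), "alpha",
                                   segSec = 1, overlap = 0)))[1, 2]
    }))
  }
  b <- c(biasAt(4), biasAt(16), biasAt(64))
  expect_gt(b[1], b[2])
  expect_gt(b[2], b[3])
})

test_that("group connectivity averages element-wise and preserves validity", {
  set.seed(5)
  mk <- function(W) new("ConnectivityMatrix", W = W,
                        band = canonicalBands()[3, ],
                        condition = c(musicType = "nostalgic"),
                        subject = "0", meta = list())
  lab <- c("a", "b", "c")
  W1 <- matrix(0.4, 3, 3, dimnames = list(lab, lab)); diag(W1) <- 0
  W2 <- matrix(0.6, 3, 3, dimnames = list(lab, lab)); diag(W2) <- 0
  expect_equal(connMatrix(groupConnectivity(list(mk(W1)))), W1)
  g <- groupConnectivity(list(mk(W1), mk(W2)))
  expect_equal(unname(connMatrix(g)[1, 2]), 0.5)
  expect_equal(g@meta$n, 2)

  for (r in seq_len(20)) {
    mats <- lapply(1:3, function(i) {
      W <- randomWeightMatrix(4, sparsity = 0)
      W <- W / max(W)
      dimnames(W) <- list(letters[1:4], letters[1:4])
      mk(W)
    })
    Wm <- connMatrix(groupConnectivity(mats))
    expect_equal(Wm, t(Wm))
    expect_true(all(diag(Wm) == 0) && all(Wm >= 0 & Wm <= 1))
  }
  bad <- mk(W1); bad@W <- W1[c(2, 1, 3), c(2, 1, 3)]
  expect_error(groupConnectivity(list(mk(W1), bad)), "montage")
})

test_that("degenerate inputs are rejected with clear errors", {
  ep <- toneEpochs(dur = 3)
  expect_error(crossSpectra(ep, "alpha", segSec = 3, overlap = 0), "2 segments")
  expect_error(crossSpectra(ep, data.frame(name = "x", lo = 70, hi = 80),
                            segSec = 1), "no frequency bins")
  expect_error(crossSpectra(ep, "nosuchband"), "unknown band")
})
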