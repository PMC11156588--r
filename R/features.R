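#' Build a triangular filterbank around a principal frequency
#'
#' Places \code{M} triangular filters between \code{fAHz} and \code{fBHz}
#' with center density maximal near the principal frequency of interest
#' \code{FHz}: centers are uniform in the warped coordinate
#' \code{u(f) = sign(f - F) * log(1 + |f - F| / w)}, so inter-center spacing
#' grows geometrically with distance from \code{F} symmetrically on both
#' sides. Each triangle spans its two neighboring centers with peak 1, hence
#' adjacent filters cross at 50\% height; the first and last centers sit at
#' the band edges. With \code{M = 1} the single triangle spans the whole
#' band and peaks at \code{FHz}.
#'
#' @param M number of filters; default 7.
#' @param FHz principal frequency of interest (Hz); default 2.5.
#' @param fAHz low band edge (Hz); default 1.
#' @param fBHz high band edge (Hz); default 10 (per-subject configurable up
#'   to about 13).
#' @param gridHz PSD grid spacing the weights are sampled on; default 0.25.
#' @param warpWHz warp length scale w (Hz); default 1.
#' @return a \linkS4class{FilterBank}.
#' @examples
#' fb <- buildFilterbank()
#' filterCenters(fb)
#' @export
buildFilterbank <- function(M = 7L, FHz = 2.5, fAHz = 1, fBHz = 10,
                            gridHz = 0.25, warpWHz = 1) {
  M <- as.integer(M)
  if (!(fAHz < FHz && FHz < fBHz)) stop("need fA < F < fB")
  if (M < 1L) stop("M must be >= 1")
  freqs <- seq(0, fBHz, by = gridHz)
  freqs <- freqs[freqs >= fAHz - 1e-9]
  if (M > length(freqs))
    stop("M = ", M, " exceeds the ", length(freqs),
         " grid points in [", fAHz, ", ", fBHz, "] Hz")
  if (M == 1L) {
    centers <- FHz
    left <- fAHz
    right <- fBHz
  } else {
    u <- function(f) sign(f - FHz) * log1p(abs(f - FHz) / warpWHz)
    uinv <- function(v) FHz + sign(v) * warpWHz * expm1(abs(v))
    uu <- seq(u(fAHz), u(fBHz), length.out = M)
    centers <- vapply(uu, uinv, numeric(1))
    centers[1L] <- fAHz
    centers[M] <- fBHz
    left <- c(centers[1L], centers[-M])
    right <- c(centers[-1L], centers[M])
  }
  W <- matrix(0, nrow = M, ncol = length(freqs))
  for (m in seq_len(M)) {
    cm <- centers[m]
    up <- freqs >= left[m] & freqs <= cm
    if (cm > left[m]) {
      W[m, up] <- (freqs[up] - left[m]) / (cm - left[m])
    } else W[m, up] <- 1
    dn <- freqs > cm & freqs <= right[m]
    if (right[m] > cm)
      W[m, dn] <- (right[m] - freqs[dn]) / (right[m] - cm)
    # peak-normalize the sampled response (centers need not sit on the grid)
    if (max(W[m, ]) > 0) W[m, ] <- W[m, ] / max(W[m, ])
  }
  new("FilterBank", M = M, FHz = FHz, fAHz = fAHz, fBHz = fBHz,
      centersHz = centers, freqsHz = freqs, weights = W, gridHz = gridHz)
}

#' Apply a filterbank to a spectral estimate
#'
#' Computes the per-filter (log) energies
#' \code{e_m = log(sum_f weight_m(f) * power(f) + eps)}. The PSD grid must
#' contain the filterbank grid (same spacing, matching frequencies).
#'
#' @param psd a \linkS4class{SpectralEstimate}.
#' @param fb a \linkS4class{FilterBank}.
#' @param logEnergies take the log (default TRUE, cepstral-style; makes the
#'   subsequent coefficients amplitude-scale robust).
#' @param eps floor inside the log; default 1e-12.
#' @return numeric vector of length \code{M}.
#' @export
applyFilterbank <- function(psd, fb, logEnergies = TRUE, eps = 1e-12) {
  stopifnot(is(psd, "SpectralEstimate"), is(fb, "FilterBank"))
  idx <- match(round(fb@freqsHz / fb@gridHz),
               round(psd@freqsHz / fb@gridHz))
  if (anyNA(idx) ||
      max(abs(psd@freqsHz[idx] - fb@freqsHz)) > 1e-6)
    stop("grid mismatch: PSD grid does not contain the filterbank grid")
  e <- as.numeric(fb@weights %*% psd@power[idx])
  if (logEnergies) log(e + eps) else e
}

# orthonormal DCT-II matrix
.dctMatrix <- function(M) {
  k <- seq_len(M) - 1L
  n <- seq_len(M) - 1L
  D <- sqrt(2 / M) * cos(pi * outer(k, 2 * n + 1) / (2 * M))
  D[1L, ] <- D[1L, ] / sqrt(2)
  D
}

#' Decorrelate filter energies with the orthonormal cosine transform
#'
#' Orthonormal type-II discrete cosine transform of the energy vector;
#' \code{decorrelateInverse} is its exact inverse.
#'
#' @param x numeric vector of (log) filter energies.
#' @return numeric vector of decorrelated coefficients (same length).
#' @examples
#' x <- rnorm(7)
#' max(abs(decorrelateInverse(decorrelate(x)) - x)) < 1e-12
#' @export
decorrelate <- function(x) {
  stopifnot(all(is.finite(x)))
  as.numeric(.dctMatrix(length(x)) %*% x)
}

#' @param y numeric vector of decorrelated coefficients.
#' @rdname decorrelate
#' @export
decorrelateInverse <- function(y) {
  as.numeric(t(.dctMatrix(length(y))) %*% y)
}

# Vectorized per-channel coefficient extraction: decorrelated filter-energy
# coefficients (M x nEnds) for many 1-s windows of one channel. Window ends
# are given in session time; the recording may start at t0 < 0 (pre-roll).
.windowCoefficients <- function(x, rate, endsS, t0, fb, windowS = 1,
                                logEnergies = TRUE, eps = 1e-12,
                                chunk = 512L) {
  nW <- round(windowS * rate)
  ends <- round((endsS - t0) * rate)
  starts <- ends - nW + 1L
  if (any(starts < 1L) || any(ends > length(x)))
    stop("window(s) outside the recorded signal")
  nfft <- max(nW, round(rate / fb@gridHz))
  w <- .hann(nW)
  scale <- 1 / (rate * sum(w^2))
  binIdx <- round(fb@freqsHz * nfft / rate) + 1L
  mult <- ifelse(fb@freqsHz > 0 & binIdx - 1L < nfft / 2, 2, 1)
  D <- .dctMatrix(fb@M)
  out <- matrix(0, nrow = fb@M, ncol = length(endsS))
  for (lo in seq(1L, length(endsS), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(endsS))
    cols <- lo:hi
    idx <- outer(0:(nW - 1L), starts[cols], "+")
    Xw <- matrix(x[idx], nrow = nW)
    Xw <- (Xw - rep(colMeans(Xw), each = nW)) * w
    Xp <- rbind(Xw, matrix(0, nrow = nfft - nW, ncol = length(cols)))
    P <- (Mod(stats::mvfft(Xp)[binIdx, , drop = FALSE])^2) * scale * mult
    E <- fb@weights %*% P
    if (logEnergies) E <- log(E + eps)
    out[, cols] <- D %*% E
  }
  out
}

#' Feature matrix for one electrode at one decision time
#'
#' Builds the M x P matrix of decorrelated coefficients for a decision at
#' \code{tDecision}: P analysis windows of \code{windowS} seconds ending at
#' \code{tDecision}, \code{tDecision - shiftS}, ...,
#' \code{tDecision - (P-1) * shiftS} (1.8 s of history at the defaults),
#' each reduced to M coefficients. Columns are ordered oldest window first.
#' If the buffer does not yet hold the full history, \code{NULL} is returned
#' (warmup; no decision is emitted).
#'
#' @param x numeric vector: the signal buffer of one electrode.
#' @param rate sampling rate (Hz).
#' @param tDecision decision time (s, session clock).
#' @param fb a \linkS4class{FilterBank}.
#' @param P number of temporal iterations; default 5.
#' @param windowS analysis window (s); default 1.
#' @param shiftS sliding shift (s); default 0.2.
#' @param t0 buffer start time (s); default 0.
#' @param logEnergies see \code{\link{applyFilterbank}}.
#' @return an M x P numeric matrix (attributes \code{decision_time_s},
#'   \code{M}, \code{P}), or \code{NULL} during warmup.
#' @export
featureMatrix <- function(x, rate, tDecision, fb, P = 5L, windowS = 1,
                          shiftS = 0.2, t0 = 0, logEnergies = TRUE) {
  P <- as.integer(P)
  ends <- tDecision - (P:1 - 1L) * shiftS  # oldest first
  if (min(ends) - windowS < t0 - 1e-9 ||
      tDecision > t0 + length(x) / rate + 1e-9)
    return(NULL)
  fm <- .windowCoefficients(x, rate, ends, t0, fb, windowS,
                            logEnergies = logEnergies)
  structure(fm, decision_time_s = tDecision, M = fb@M, P = P)
}

#' Flatten a feature matrix to the classifier input vector
#'
#' Fixed filter-major order: all P temporal values of filter 1 first, then
#' filter 2, and so on (M * P = 35 features at the defaults).
#'
#' @param fm an M x P feature matrix from \code{\link{featureMatrix}}.
#' @return numeric vector of length M * P.
#' @export
flattenFeatures <- function(fm) as.numeric(t(fm))

#' Dimensionality reduction ratio of the feature stage
#'
#' Percent reduction of \code{nFeatures} model inputs relative to one
#' analysis window of raw multi-channel samples:
#' \code{100 * (1 - nFeatures / (nChannels * rateHz * windowS))}. At the
#' nominal acquisition settings (32 channels, 20 kHz, 1 s, 35 features) the
#' reduction exceeds 99.99\%.
#'
#' @param nChannels,rateHz,windowS,nFeatures positive scalars.
#' @return percent reduction.
#' @export
reductionRatio <- function(nChannels = 32, rateHz = 20000, windowS = 1,
                           nFeatures = 35) {
  stopifnot(nChannels > 0, rateHz > 0, windowS > 0, nFeatures > 0)
  100 * (1 - nFeatures / (nChannels * rateHz * windowS))
}
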