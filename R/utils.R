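#' @importFrom stats fft rnorm runif rgamma rlnorm rexp rbinom ks.test
#'   na.omit sd
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# periodic Hann taper
.hann <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
}

# snap times to an integer grid index (guards against float drift on the
# 200-ms decision grid)
.gridIndex <- function(t, stepS) as.integer(round(t / stepS))

.isWhole <- function(x, tol = 1e-8) abs(x - round(x)) < tol

# half-open interval membership: any interval [start, end) containing t
.inIntervals <- function(t, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(t)))
  out <- logical(length(t))
  for (i in seq_along(starts))
    out <- out | (t >= starts[i] & t < ends[i])
  out
}

# derive a reproducible child seed (kept below 2^31)
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + k * 12345) %% 2147483647L)
}
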