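#' Fractional Gaussian noise
#'
#' Draws a stationary fractional Gaussian noise (fGn) sequence — the
#' increment process of fractional Brownian motion — by Davies–Harte
#' circulant embedding of the fGn autocovariance.  A sequence of `n` unit
#' variance increments with Hurst index `hurst` has autocovariance
#' `g(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2`; partial sums of the
#' returned vector form an fBm path whose mean-squared displacement grows
#' as `tau^{2H}`.
#'
#' @param n number of increments (>= 1).
#' @param hurst Hurst index in (0, 1); 0.5 gives independent Gaussian steps.
#' @param sd marginal standard deviation of each increment.
#' @return numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' x <- rfgn(512, hurst = 0.8)
#' var(x)      # ~ 1
#' @export
rfgn <- function(n, hurst, sd = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer")
  n <- as.integer(n)
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("'hurst' must lie strictly in (0, 1)")
  if (hurst == 0.5) return(stats::rnorm(n, sd = sd))
  if (n == 1L) return(stats::rnorm(1L, sd = sd))

  h2 <- 2 * hurst
  k <- 0:n
  acov <- 0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  m <- 2L * n
  circ <- c(acov, acov[n:2])           # circulant first row, length 2n
  lam <- Re(stats::fft(circ))
  # eigenvalues are non-negative for fGn; clip tiny fp noise
  if (min(lam) < -1e-8 * max(lam))
    stop("circulant embedding failed: negative eigenvalue")
  lam[lam < 0] <- 0

  z <- complex(length.out = m)
  z[1L] <- sqrt(lam[1L]) * stats::rnorm(1L)
  z[n + 1L] <- sqrt(lam[n + 1L]) * stats::rnorm(1L)
  a <- stats::rnorm(n - 1L)
  b <- stats::rnorm(n - 1L)
  idx <- 2:n
  z[idx] <- sqrt(lam[idx] / 2) * complex(real = a, imaginary = b)
  z[m - idx + 2L] <- Conj(z[idx])
  x <- Re(stats::fft(z)) / sqrt(m)
  sd * x[seq_len(n)]
}
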