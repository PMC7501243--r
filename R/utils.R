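# Small numerical helpers shared across modules.

#' Generate RFC-4122 version-4 UUID strings
#'
#' UUIDs are drawn from R's current RNG stream, so archives built under
#' `set.seed()` (or by the seeded simulator) get reproducible identifiers.
#'
#' @param n Number of UUIDs.
#' @return Character vector of lowercase v4 UUIDs.
#' @export
fmt_uuid <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    b <- sample.int(256L, 16L, replace = TRUE) - 1L
    b[7] <- bitwOr(bitwAnd(b[7], 0x0FL), 0x40L)  # version 4
    b[9] <- bitwOr(bitwAnd(b[9], 0x3FL), 0x80L)  # variant 10xx
    h <- sprintf("%02x", b)
    paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""),
           "-", paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""),
           "-", paste(h[11:16], collapse = ""))
  }, character(1))
}

# Ordinary least squares line fit returning slope, intercept, residual sd.
# Centered formulation for numerical stability.
ols_line <- function(t, y) {
  n <- length(t)
  stopifnot(n >= 2, length(y) == n)
  tm <- mean(t)
  ym <- mean(y)
  tc <- t - tm
  sxx <- sum(tc^2)
  if (sxx == 0) {
    return(list(slope = 0, intercept = ym, resid_sd = stats::sd(y), sse = sum((y - ym)^2)))
  }
  slope <- sum(tc * (y - ym)) / sxx
  intercept <- ym - slope * tm
  resid <- y - (intercept + slope * t)
  sse <- sum(resid^2)
  list(slope = slope, intercept = intercept,
       resid_sd = if (n > 2) sqrt(sse / (n - 2)) else 0, sse = sse)
}

# Rolling OLS slope over contiguous windows of `nw` samples.
# Returns a vector of length n - nw + 1; entry i is the slope of the
# regression of y[i:(i+nw-1)] on t[i:(i+nw-1)]. O(n) via prefix sums.
rolling_slope <- function(t, y, nw) {
  n <- length(t)
  stopifnot(nw >= 2, n >= nw, length(y) == n)
  # shift for stability
  t0 <- t - t[1]
  y0 <- y - mean(y)
  ct <- c(0, cumsum(t0))
  cy <- c(0, cumsum(y0))
  ctt <- c(0, cumsum(t0^2))
  cty <- c(0, cumsum(t0 * y0))
  i <- seq_len(n - nw + 1)
  j <- i + nw - 1
  st <- ct[j + 1] - ct[i]
  sy <- cy[j + 1] - cy[i]
  stt <- ctt[j + 1] - ctt[i]
  sty <- cty[j + 1] - cty[i]
  denom <- stt - st^2 / nw
  num <- sty - st * sy / nw
  out <- num / denom
  out[denom <= 0] <- 0
  out
}

# Point-noise standard deviation estimate insensitive to piecewise-linear
# trends: MAD of second differences / sqrt(6) (second differences of any
# linear segment vanish; white noise has Var(d2) = 6 sigma^2).
point_noise_sd <- function(y) {
  if (length(y) < 3) return(0)
  d2 <- diff(y, differences = 2)
  stats::mad(d2) / sqrt(6)
}
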