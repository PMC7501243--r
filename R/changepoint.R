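# Kinetic change-point segmentation of piecewise-linear time series.
# The single change point is located by exhaustive minimization of the total
# SSE of two independent least-squares lines over all admissible split
# indices; a split is accepted when an F-test rejects the single-line null.

#' Fit a single kinetic change point
#'
#' Scans every admissible split index `k` (left segment `1..k`, right
#' segment `k+1..n`, each with at least `min_pts` points), fitting an
#' ordinary least-squares line to each side, and returns the split with the
#' smallest total sum of squared errors (ties broken by the earliest
#' index). The change-point time `t_star` is the intersection of the two
#' fitted lines when that falls between the bracketing samples, otherwise
#' their midpoint. Significance is the p-value of an F-test comparing the
#' two-line model (4 parameters) against a single line (2 parameters).
#'
#' @param t Numeric vector of abscissae (time, flow rate, ...), increasing.
#' @param y Numeric response, same length.
#' @param min_pts Minimum points per segment (default 3).
#' @return List of class `changepoint_result` with fields `t_star`, `index`
#'   (last point of the left segment), `left`, `right` (each
#'   slope/intercept/resid_sd), `significance`, `sse_two`, `sse_one`.
#' @export
fit_single_changepoint <- function(t, y, min_pts = 3) {
  n <- length(t)
  stopifnot(length(y) == n, min_pts >= 2)
  if (n < 2 * min_pts) {
    stop(sprintf("fit_single_changepoint: need >= %d points, got %d",
                 2 * min_pts, n))
  }
  # prefix/suffix SSE of an OLS line via cumulative sums (centered input
  # for numerical stability)
  t0 <- t - mean(t)
  y0 <- y - mean(y)
  seg_sse <- function(ct, cy, ctt, cty, cyy, i, j) {
    m <- j - i + 1
    st <- ct[j + 1] - ct[i]
    sy <- cy[j + 1] - cy[i]
    stt <- ctt[j + 1] - ctt[i]
    sty <- cty[j + 1] - cty[i]
    syy <- cyy[j + 1] - cyy[i]
    sxx <- stt - st^2 / m
    sxy <- sty - st * sy / m
    syy_c <- syy - sy^2 / m
    sse <- syy_c - ifelse(sxx > 0, sxy^2 / sxx, 0)
    pmax(sse, 0)
  }
  ct <- c(0, cumsum(t0)); cy <- c(0, cumsum(y0))
  ctt <- c(0, cumsum(t0^2)); cty <- c(0, cumsum(t0 * y0))
  cyy <- c(0, cumsum(y0^2))
  ks <- min_pts:(n - min_pts)
  sse_left <- seg_sse(ct, cy, ctt, cty, cyy, rep(1L, length(ks)), ks)
  sse_right <- seg_sse(ct, cy, ctt, cty, cyy, ks + 1L, rep(n, length(ks)))
  total <- sse_left + sse_right
  k <- ks[which.min(total)]          # which.min takes the earliest tie
  sse_two <- min(total)
  left <- ols_line(t[1:k], y[1:k])
  right <- ols_line(t[(k + 1):n], y[(k + 1):n])
  one <- ols_line(t, y)
  sse_one <- one$sse
  # t_star: intersection of the two lines inside the bracketing interval
  t_star <- (t[k] + t[k + 1]) / 2
  dslope <- right$slope - left$slope
  if (dslope != 0) {
    t_int <- (left$intercept - right$intercept) / dslope
    lo <- min(t[k], t[k + 1]); hi <- max(t[k], t[k + 1])
    if (t_int >= lo && t_int <= hi) t_star <- t_int
  }
  eps <- .Machine$double.eps * max(1, sse_one)
  if (sse_one <= eps) {
    p <- 1  # a single line already fits perfectly
  } else if (sse_two <= eps) {
    p <- 0
  } else {
    Fstat <- ((sse_one - sse_two) / 2) / (sse_two / (n - 4))
    p <- stats::pf(Fstat, 2, n - 4, lower.tail = FALSE)
    # the split index was chosen as the best of length(ks) candidates, so
    # the naive p-value is anti-conservative; Bonferroni-correct it
    p <- min(1, p * length(ks))
  }
  structure(list(t_star = t_star, index = k,
                 left = left[c("slope", "intercept", "resid_sd")],
                 right = right[c("slope", "intercept", "resid_sd")],
                 significance = p, sse_two = sse_two, sse_one = sse_one),
            class = "changepoint_result")
}

#' Segment a trace by recursive change-point splitting
#'
#' Applies [fit_single_changepoint()] recursively: a split is accepted when
#' its significance is below `1 - confidence`, and each accepted side is
#' segmented further. The returned segments tile the series.
#'
#' Binary splitting can place an early split inside a longer true segment
#' (the two halves then carry the same line); a final bottom-up pass merges
#' adjacent segments whose joint data do not support a split, so the
#' returned boundaries coincide with the true kinks on clean input.
#'
#' @param t,y Numeric vectors.
#' @param confidence Split acceptance confidence (default 0.99, i.e. accept
#'   when p < 0.01).
#' @param min_pts Minimum points per segment.
#' @return A segment table: data frame with columns `t_start`, `t_end`,
#'   `slope`, `intercept`, `resid_sd`, ordered and non-overlapping.
#' @export
segment_trace <- function(t, y, confidence = 0.99, min_pts = 3) {
  n <- length(t)
  stopifnot(length(y) == n)
  alpha <- 1 - confidence
  recurse <- function(i, j) {
    m <- j - i + 1
    if (m < 2 * min_pts) return(data.frame(i = i, j = j))
    cp <- fit_single_changepoint(t[i:j], y[i:j], min_pts = min_pts)
    if (cp$significance < alpha) {
      k <- i + cp$index - 1
      rbind(recurse(i, k), recurse(k + 1, j))
    } else {
      data.frame(i = i, j = j)
    }
  }
  seg <- recurse(1, n)
  # merge adjacent segments whose union shows no significant change point
  repeat {
    merged <- FALSE
    r <- 1
    while (r < nrow(seg)) {
      i <- seg$i[r]; j <- seg$j[r + 1]
      cp <- if (j - i + 1 >= 2 * min_pts) {
        fit_single_changepoint(t[i:j], y[i:j], min_pts = min_pts)
      } else NULL
      if (is.null(cp) || cp$significance >= alpha) {
        seg <- rbind(seg[seq_len(r - 1), , drop = FALSE],
                     data.frame(i = i, j = j),
                     seg[-seq_len(r + 1), , drop = FALSE])
        merged <- TRUE
      } else {
        r <- r + 1
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(seq_len(nrow(seg)), function(r) {
    i <- seg$i[r]; j <- seg$j[r]
    fit <- ols_line(t[i:j], y[i:j])
    data.frame(t_start = t[i], t_end = t[j], slope = fit$slope,
               intercept = fit$intercept, resid_sd = fit$resid_sd)
  }))
  rownames(out) <- NULL
  out
}
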