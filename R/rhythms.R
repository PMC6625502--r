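# Lomb periodogram rhythm detection for (possibly unevenly sampled)
# activity series, with analytic peak significance.

#' Lomb normalised periodogram of an activity series
#'
#' Least-squares spectral power for arbitrary sampling: at angular frequency
#' w the power is
#' P(w) = (1 / 2 s^2) ( \[sum (x - xbar) cos w(t - tau)\]^2 / sum cos^2 w(t - tau)
#'        + \[sum (x - xbar) sin w(t - tau)\]^2 / sum sin^2 w(t - tau) )
#' with tan(2 w tau) = sum sin 2wt / sum cos 2wt and s^2 the sample variance.
#' Power is invariant to mean shifts and positive rescaling of the series.
#'
#' The frequency grid runs from 1/(oversampling * span) up to
#' `max_freq_factor` times the pseudo-Nyquist frequency 1/(2 * median
#' spacing), in steps of 1/(oversampling * span).
#'
#' @param times_h Sample times in hours, strictly increasing (gaps allowed).
#' @param values Series values; must not be constant.
#' @param oversampling Frequency oversampling factor (default 4).
#' @param max_freq_factor Upper frequency limit as a multiple of the
#'   pseudo-Nyquist frequency (default 1).
#' @param n_independent Number of independent frequencies M used for peak
#'   significance; defaults to the number of samples.
#' @param frequency_grid Optional explicit frequency grid (cycles/hour,
#'   strictly increasing); overrides the automatic grid.
#'
#' @return Object of class `lomb_periodogram`: list with `frequency`
#'   (cycles/hour), `period_h`, `power`, `n`, `m_independent` and
#'   `thresholds` (powers at which a peak reaches p = 0.1, 0.01, 0.001).
#' @export
lomb_periodogram <- function(times_h, values, oversampling = 4,
                             max_freq_factor = 1, n_independent = NULL,
                             frequency_grid = NULL) {
  n <- length(times_h)
  abort_if(length(values) != n, "times and values differ in length")
  abort_if(n < 8, "need at least 8 samples")
  abort_if(any(diff(times_h) <= 0), "times must be strictly increasing")
  s2 <- stats::var(values)
  abort_if(s2 == 0, "constant series has no spectral content")
  span <- times_h[n] - times_h[1]
  dt_med <- stats::median(diff(times_h))
  f_nyq <- 1 / (2 * dt_med)
  df <- 1 / (oversampling * span)
  freqs <- if (is.null(frequency_grid)) {
    seq(df, max_freq_factor * f_nyq, by = df)
  } else {
    abort_if(any(frequency_grid <= 0) || any(diff(frequency_grid) <= 0),
             "frequency_grid must be positive and strictly increasing")
    df <- if (length(frequency_grid) > 1) min(diff(frequency_grid)) else df
    frequency_grid
  }
  abort_if(length(freqs) < 2, "frequency grid is degenerate")

  x <- values - mean(values)
  power <- numeric(length(freqs))
  chunk <- 512L
  for (i0 in seq(1L, length(freqs), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(freqs))
    w <- 2 * pi * freqs[idx]
    wt <- outer(w, times_h)                   # m x n
    tau <- atan2(rowSums(sin(2 * wt)), rowSums(cos(2 * wt))) / (2 * w)
    arg <- wt - w * tau
    Cm <- cos(arg); Sm <- sin(arg)
    power[idx] <- (as.vector(Cm %*% x)^2 / rowSums(Cm^2) +
                   as.vector(Sm %*% x)^2 / rowSums(Sm^2)) / (2 * s2)
  }
  m_ind <- if (is.null(n_independent)) n else n_independent
  thr <- vapply(c(0.1, 0.01, 0.001), function(p) {
    significance_threshold(p, m_ind)
  }, numeric(1))
  names(thr) <- c("p0.1", "p0.01", "p0.001")
  structure(list(frequency = freqs, period_h = 1 / freqs, power = power,
                 n = n, m_independent = m_ind, thresholds = thr,
                 oversampling = oversampling, grid_step = df,
                 resolution = 1 / span),
            class = "lomb_periodogram")
}

#' Analytic p-value of a periodogram peak
#'
#' Probability that pure Gaussian noise produces a maximum normalised power
#' of at least `power` among `m_independent` independent frequencies:
#' p = 1 - (1 - exp(-z))^M.
#'
#' @param power Peak power z (>= 0).
#' @param m_independent Number of independent frequencies M.
#' @return p-value in \[0, 1\].
#' @export
periodogram_significance <- function(power, m_independent) {
  abort_if(any(power < 0), "power must be non-negative")
  abort_if(m_independent < 1, "m_independent must be >= 1")
  ez <- exp(-power)
  p <- -expm1(m_independent * log1p(-ez))
  # log1p(-1) = -Inf for power 0 -> p = 1, handled naturally
  pmin(pmax(p, 0), 1)
}

# Power level whose peak p-value equals `p` for M independent frequencies.
significance_threshold <- function(p, m_independent) {
  -log(-expm1(log1p(-p) / m_independent))
}

#' Extract significant periodogram peaks
#'
#' Local power maxima with analytic p-value at most `alpha`. Maxima within
#' two spectral resolution elements (2/span) of a stronger maximum are
#' merged into it: the first sidelobes of the rectangular spectral window
#' sit about 1.4 resolution elements from a strong line and would otherwise
#' be reported as spurious extra peaks.
#'
#' @param pg A [lomb_periodogram()].
#' @param alpha Significance level (default 0.05).
#' @return Data frame (`period_h`, `frequency`, `power`, `p`) sorted by
#'   power, strongest first; zero rows when nothing is significant.
#' @export
detect_peaks <- function(pg, alpha = 0.05) {
  stopifnot(inherits(pg, "lomb_periodogram"))
  abort_if(alpha <= 0 || alpha > 1, "alpha must be in (0, 1]")
  pw <- pg$power
  m <- length(pw)
  is_max <- vapply(seq_len(m), function(i) {
    left <- if (i > 1) pw[i - 1] else -Inf
    right <- if (i < m) pw[i + 1] else -Inf
    pw[i] > left && pw[i] >= right
  }, logical(1))
  cand <- which(is_max)
  if (length(cand) > 1) {
    # merge maxima within the sidelobe skirt, keeping the stronger
    radius <- 2 * pg$resolution
    ord <- cand[order(-pw[cand])]
    kept <- integer(0)
    for (i in ord) {
      if (!any(abs(pg$frequency[i] - pg$frequency[kept]) <= radius)) {
        kept <- c(kept, i)
      }
    }
    cand <- kept
  }
  p <- periodogram_significance(pw[cand], pg$m_independent)
  sig <- p <= alpha
  out <- data.frame(period_h = pg$period_h[cand][sig],
                    frequency = pg$frequency[cand][sig],
                    power = pw[cand][sig], p = p[sig])
  out[order(-out$power), , drop = FALSE]
}

#' @export
print.lomb_periodogram <- function(x, ...) {
  best <- which.max(x$power)
  cat(sprintf(paste0("<lomb_periodogram> %d frequencies (%.4g-%.4g c/h), ",
                     "n = %d, M = %d\n  top power %.2f at period %.3g h ",
                     "(p = %.3g)\n"),
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$n, x$m_independent, x$power[best], x$period_h[best],
              periodogram_significance(x$power[best], x$m_independent)))
  cat(sprintf("  thresholds: p=0.1 %.2f | p=0.01 %.2f | p=0.001 %.2f\n",
              x$thresholds[1], x$thresholds[2], x$thresholds[3]))
  invisible(x)
}
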