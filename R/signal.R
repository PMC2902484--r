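# Robust cutoffs and FFT low-pass smoothing of a score track.

#' Robust divergence/conservation cutoffs for a score track
#'
#' Cutoffs are placed `k` times a robust spread estimate away from the
#' median score, with k = 1.4826 so that k * MAD estimates one standard
#' deviation under normality. When the sequences are so closely related
#' that the MAD collapses to (numerically) zero — the typical case for
#' DNA, where most columns score exactly alike — the spread falls back to
#' the mean absolute deviation about the mean, `mean(|X - mean(X)|)`,
#' which is not swamped by the overpopulated modal value. In the fallback
#' only the low (divergence) cutoff is kept: with a degenerate score
#' distribution a high cutoff would not flag meaningful conservation.
#'
#' @param x A `score_track` (or bare numeric vector).
#' @param k Scale factor applied to the spread (default 1.4826).
#' @param tol MAD values at or below `tol` trigger the fallback.
#' @return A `cutoff_pair`: list with `low`, `high` (`NA` in the
#'   fallback), `basis` (`"MAD"` or `"MAD_MEAN"`), `center` (median),
#'   `spread`.
#' @examples
#' compute_cutoffs(c(-3, -1, 0, 0, 0, 1, 2))
#' @export
compute_cutoffs <- function(x, k = 1.4826, tol = 1e-12) {
  v <- if (inherits(x, "score_track")) x$values else as.numeric(x)
  if (length(v) == 0L) stop("empty score track", call. = FALSE)
  med <- stats::median(v)
  mad_ <- stats::median(abs(v - med))
  if (mad_ > tol) {
    structure(list(low = med - k * mad_, high = med + k * mad_,
                   basis = "MAD", center = med, spread = mad_),
              class = "cutoff_pair")
  } else {
    mad_mean <- mean(abs(v - mean(v)))
    structure(list(low = med - k * mad_mean, high = NA_real_,
                   basis = "MAD_MEAN", center = med, spread = mad_mean),
              class = "cutoff_pair")
  }
}

#' Low-pass FFT smoothing of a score track
#'
#' Sharp per-column peaks are widened into region-scale signals by
#' discrete-Fourier low-pass filtering: coefficients at frequency index
#' above `ceil(L / (2 * window))` (and their conjugates) are zeroed and
#' the signal is inverse-transformed. The DC component is always kept, so
#' the track mean is preserved exactly; the filter is linear. `window`
#' is the approximate width, in columns, of the narrowest feature meant
#' to survive smoothing.
#'
#' @param x A `score_track` (or bare numeric vector) of length >= 4.
#' @param window Smoothing window in columns (default 10).
#' @return A `smoothed_track`: list with `values` (same length/names as
#'   the input), `window`, `bounds` (when the input was a `score_track`).
#' @export
smooth_fft <- function(x, window = 10) {
  v <- if (inherits(x, "score_track")) x$values else as.numeric(x)
  if (window < 1) stop("smoothing window must be >= 1", call. = FALSE)
  n <- length(v)
  if (n < 4L) stop("track too short to smooth (need >= 4 columns)",
                   call. = FALSE)
  kc <- ceiling(n / (2 * window))
  co <- stats::fft(v)
  freq_index <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))
  co[freq_index > kc] <- 0
  sm <- Re(stats::fft(co, inverse = TRUE)) / n
  structure(list(values = stats::setNames(sm, names(v)),
                 window = window,
                 bounds = if (inherits(x, "score_track")) x$bounds else NULL),
            class = "smoothed_track")
}
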