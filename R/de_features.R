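#' Differential-entropy features from raw multichannel signal
#'
#' Computes the standard DE feature: the raw signal is band-pass filtered
#' per frequency band (zero-phase Butterworth), cut into non-overlapping
#' epochs, and each epoch's DE is taken under the band-limited Gaussian
#' assumption, `DE = 1/2 * log(2 * pi * e * var)` (nats). One value per
#' (epoch, channel, band).
#'
#' @param raw numeric matrix `samples x N` of raw signal.
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param bands list of `c(low, high)` Hz pairs. Defaults to the five
#'   conventional EEG bands delta/theta/alpha/beta/gamma.
#' @param epoch_s epoch length in seconds (default 1, the per-second DE
#'   convention).
#' @param filter_order Butterworth order (applied forward-backward).
#' @param var_floor variance floor; a (near-)constant epoch has DE -Inf, so
#'   variance is floored here with a warning.
#' @return numeric array `n_epochs x N x length(bands)` of DE values (nats).
#' @export
compute_de_features <- function(raw, fs,
                                bands = list(c(1, 4), c(4, 8), c(8, 14),
                                             c(14, 31), c(31, 50)),
                                epoch_s = 1, filter_order = 4,
                                var_floor = 1e-12) {
  raw <- as.matrix(raw)
  stopifnot_finite(raw, "raw signal")
  hi <- max(vapply(bands, max, 0))
  if (fs <= 2 * hi) {
    stop(sprintf("sampling rate %g Hz must exceed twice the highest band edge (%g Hz)",
                 fs, hi), call. = FALSE)
  }
  ep_len <- as.integer(round(epoch_s * fs))
  if (ep_len < 2L) stop("epoch length must span at least 2 samples", call. = FALSE)
  n_ep <- nrow(raw) %/% ep_len
  if (n_ep < 1L) stop("signal shorter than one epoch", call. = FALSE)
  N <- ncol(raw)
  out <- array(NA_real_, dim = c(n_ep, N, length(bands)))
  floored <- FALSE
  for (b in seq_along(bands)) {
    filt <- signal::butter(filter_order,
                           c(bands[[b]][1], bands[[b]][2]) / (fs / 2),
                           type = "pass")
    for (ch in seq_len(N)) {
      x <- signal::filtfilt(filt, raw[, ch])
      for (e in seq_len(n_ep)) {
        seg <- x[((e - 1L) * ep_len + 1L):(e * ep_len)]
        v <- stats::var(seg)
        if (v < var_floor) {
          v <- var_floor
          floored <- TRUE
        }
        out[e, ch, b] <- 0.5 * log(2 * pi * exp(1) * v)
      }
    }
  }
  if (floored) {
    warning("zero-variance epoch(s): variance floored at var_floor; DE of a constant signal is -Inf",
            call. = FALSE)
  }
  out
}
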