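#' Logarithmic Morlet frequency grid
#'
#' Frequencies and wavelet cycle counts increase geometrically and are paired
#' elementwise: `f_k = f1 * (f2/f1)^((k-1)/(n-1))` and likewise for cycles.
#' The default is the 30-step grid from 3 to 80 Hz with cycles from 3 to 10.
#'
#' @param n number of steps.
#' @param freq_range,cycle_range two-element numeric ranges.
#' @return list of class `freq_grid` with `frequencies` and `cycles`.
#' @export
make_freq_grid <- function(n = 30, freq_range = c(3, 80),
                           cycle_range = c(3, 10)) {
  stopifnot(n >= 2, length(freq_range) == 2, length(cycle_range) == 2,
            freq_range[1] > 0, freq_range[1] < freq_range[2],
            cycle_range[1] > 0, cycle_range[1] <= cycle_range[2])
  k <- (seq_len(n) - 1) / (n - 1)
  structure(list(frequencies = freq_range[1] * (freq_range[2] / freq_range[1])^k,
                 cycles = cycle_range[1] * (cycle_range[2] / cycle_range[1])^k),
            class = "freq_grid")
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("<freq_grid> %d steps, %.3g-%.3g Hz, %.3g-%.3g cycles\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              min(x$cycles), max(x$cycles)))
  invisible(x)
}

#' Linear interpolation across the TMS pulse window
#'
#' Replaces, independently for every epoch and channel, all samples strictly
#' inside `(t0, t1)` ms by the straight line through the samples at the window
#' boundaries. Removes residual pulse/decay artifacts that would otherwise
#' leak into the wavelet decomposition.
#'
#' @param epochs an [epoch_set()].
#' @param t0,t1 window edges in ms (defaults -1 and 15).
#' @return an `epoch_set` with the window interpolated.
#' @export
interpolate_pulse_window <- function(epochs, t0 = -1, t1 = 15) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (t0 >= t1) stop("`t0` must be smaller than `t1`")
  tm <- epochs$times
  if (t0 < min(tm) || t1 > max(tm))
    stop("interpolation window [", t0, ", ", t1, "] ms outside the epoch")
  i0 <- max(which(tm <= t0))
  i1 <- min(which(tm >= t1))
  inner <- which(tm > tm[i0] & tm < tm[i1])
  if (!length(inner)) return(epochs)
  w <- (tm[inner] - tm[i0]) / (tm[i1] - tm[i0])
  d <- epochs$data
  a <- d[, , i0, drop = FALSE]
  b <- d[, , i1, drop = FALSE]
  for (j in seq_along(inner))
    d[, , inner[j]] <- (1 - w[j]) * a[, , 1] + w[j] * b[, , 1]
  epochs$data <- d
  epochs
}

# Butterworth-magnitude band-pass gain, squared response of order `ord` at
# each edge. Purely real in the frequency domain, hence exactly zero-phase.
bandpass_gain <- function(f, lo, hi, ord) {
  g <- rep(0, length(f))
  pos <- f > 0
  g[pos] <- 1 / sqrt(1 + (lo / f[pos])^(2 * ord)) /
    sqrt(1 + (f[pos] / hi)^(2 * ord))
  g
}

#' Zero-phase band-pass filter
#'
#' Filters every epoch and channel with a zero-phase spectral filter whose
#' magnitude follows a Butterworth band-pass response (order 8 per edge by
#' default). Being applied as a real gain in the frequency domain the filter
#' introduces no group delay: a passband sinusoid's peak does not move.
#'
#' @param epochs an [epoch_set()].
#' @param lo,hi band edges in Hz (defaults 3 and 100).
#' @param order Butterworth order per edge.
#' @return filtered `epoch_set`.
#' @export
bandpass <- function(epochs, lo = 3, hi = 100, order = 8) {
  stopifnot(inherits(epochs, "epoch_set"), lo > 0, lo < hi)
  if (hi >= epochs$sfreq / 2)
    stop("upper band edge (", hi, " Hz) must be below the Nyquist frequency (",
         epochs$sfreq / 2, " Hz)")
  d <- dim(epochs$data)
  n <- d[3]
  x <- t(matrix(epochs$data, d[1] * d[2], n))      # samples x (epoch*channel)
  fgrid <- fft_frequencies(n, epochs$sfreq)
  g <- bandpass_gain(abs(fgrid), lo, hi, order)
  y <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / n
  epochs$data <- array(t(y), d)
  epochs
}

# Signed FFT bin frequencies for length n at sampling rate sfreq.
fft_frequencies <- function(n, sfreq) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k * sfreq / n
}

# Analytic Morlet wavelet spectrum on the FFT grid: a Gaussian of spectral
# width sigma_f = f/cycles centred at f, amplitude 2 so that a unit real
# sinusoid at f maps to unit analytic amplitude (hence unit power).
morlet_spectrum <- function(nf, sfreq, f, cycles) {
  nu <- fft_frequencies(nf, sfreq)
  w <- numeric(nf)
  pos <- nu > 0
  sf <- f / cycles
  w[pos] <- 2 * exp(-(nu[pos] - f)^2 / (2 * sf^2))
  w
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every epoch and channel with complex Morlet wavelets on the
#' given frequency grid and returns the total oscillatory power: the squared
#' magnitude of each single-epoch convolution, averaged across epochs
#' (trial-average of power, not power of the trial average, so that
#' non-phase-locked activity is retained). Samples closer than three wavelet
#' standard deviations to either epoch edge are flagged as edge-contaminated.
#'
#' @param epochs an [epoch_set()].
#' @param grid a [make_freq_grid()] object.
#' @return object of class `tf_map` with linear-scale `power`
#'   `[frequency, sample, channel]`.
#' @export
morlet_tfr <- function(epochs, grid) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(grid, "freq_grid"))
  d <- dim(epochs$data)
  n <- d[3]
  sfreq <- epochs$sfreq
  sigma_t <- grid$cycles / (2 * pi * grid$frequencies)        # seconds
  half_len <- ceiling(3 * sigma_t * sfreq)
  too_long <- which(2 * half_len + 1 > n)
  if (length(too_long))
    stop(sprintf(
      "epoch too short for the %.3g Hz wavelet (%d cycles, needs %d samples, have %d)",
      grid$frequencies[too_long[1]], round(grid$cycles[too_long[1]]),
      2 * half_len[too_long[1]] + 1, n))
  nf <- stats::nextn(n + max(2 * half_len + 1) - 1, c(2, 3, 5))
  x <- t(matrix(epochs$data, d[1] * d[2], n))
  X <- stats::mvfft(rbind(x, matrix(0, nf - n, ncol(x))))
  nfreq <- length(grid$frequencies)
  power <- array(0, c(nfreq, n, d[2]))
  # epoch-averaging operator: columns are (epoch, channel) pairs, epoch fastest
  avg <- matrix(0, d[1] * d[2], d[2])
  avg[cbind(seq_len(d[1] * d[2]), rep(seq_len(d[2]), each = d[1]))] <- 1 / d[1]
  for (k in seq_len(nfreq)) {
    w <- morlet_spectrum(nf, sfreq, grid$frequencies[k], grid$cycles[k])
    y <- stats::mvfft(X * w, inverse = TRUE)[seq_len(n), , drop = FALSE] / nf
    power[k, , ] <- (Re(y)^2 + Im(y)^2) %*% avg
  }
  edges <- matrix(FALSE, nfreq, n)
  idx <- seq_len(n)
  for (k in seq_len(nfreq))
    edges[k, ] <- idx <= half_len[k] | idx > n - half_len[k]
  tf_map(power, freqs = grid$frequencies, times = epochs$times,
         channels = epochs$channels, scale = "linear",
         n_epochs = d[1], edges = edges,
         subject = epochs$subject, site = epochs$site, group = epochs$group)
}

#' Induced (non-phase-locked) time-frequency decomposition
#'
#' Subtracts the across-epoch mean waveform (the phase-locked ERP) from every
#' epoch per channel before applying [morlet_tfr()], isolating induced from
#' evoked oscillatory activity.
#'
#' @inheritParams morlet_tfr
#' @return a linear-scale `tf_map`.
#' @export
induced_tfr <- function(epochs, grid) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_epochs(epochs) < 2)
    stop("induced activity is undefined for a single epoch")
  erp <- apply(epochs$data, c(2, 3), mean)
  epochs$data <- sweep(epochs$data, c(2, 3), erp, "-")
  morlet_tfr(epochs, grid)
}

# Internal tf_map constructor. power is [freq, time] or [freq, time, channel].
tf_map <- function(power, freqs, times, channels = NULL, scale = "linear",
                   baseline = NULL, n_epochs = NA_integer_, edges = NULL,
                   subject = NA_character_, site = NA_character_,
                   group = NA_character_) {
  if (length(dim(power)) == 2L) power <- array(power, c(dim(power), 1L))
  stopifnot(length(dim(power)) == 3L,
            dim(power)[1] == length(freqs), dim(power)[2] == length(times))
  if (!is.null(channels) && dim(power)[3] != length(channels))
    stop("channel dimension does not match channel labels")
  structure(
    list(power = power, freqs = as.numeric(freqs), times = as.numeric(times),
         channels = channels, scale = scale, baseline = baseline,
         n_epochs = n_epochs, edges = edges, subject = subject, site = site,
         group = group),
    class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tf_map> %d freqs (%.3g-%.3g Hz) x %d times (%g..%g ms) x %d channel(s), %s scale\n",
    d[1], min(x$freqs), max(x$freqs), d[2], min(x$times), max(x$times), d[3],
    x$scale))
  if (!is.null(x$baseline))
    cat(sprintf("  baseline: [%g, %g] ms\n", x$baseline[1], x$baseline[2]))
  invisible(x)
}

#' Decibel baseline normalization
#'
#' Divides the power at every frequency and channel by the mean power over
#' the pre-stimulus baseline window of that same frequency and channel, and
#' takes `10*log10` of the ratio. Performed before temporal binning.
#'
#' @param tf a linear-scale `tf_map`.
#' @param baseline two-element window in ms (default `c(-400, -200)`).
#' @return a dB-scale `tf_map`.
#' @export
db_normalize <- function(tf, baseline = c(-400, -200)) {
  stopifnot(inherits(tf, "tf_map"))
  if (tf$scale != "linear") stop("`tf` must be on the linear scale")
  if (baseline[1] >= baseline[2]) stop("invalid baseline window")
  sel <- tf$times >= baseline[1] & tf$times <= baseline[2]
  if (!any(sel))
    stop("baseline window [", baseline[1], ", ", baseline[2],
         "] ms contains no samples")
  base <- apply(tf$power[, sel, , drop = FALSE], c(1, 3), mean)
  if (any(base <= 0))
    stop("baseline power is zero for at least one frequency/channel")
  ratio <- sweep(tf$power, c(1, 3), base, "/")
  tf$power <- 10 * log10(ratio)
  tf$scale <- "dB"
  tf$baseline <- as.numeric(baseline)
  tf
}

#' Temporal binning of a time-frequency map
#'
#' Averages consecutive non-overlapping bins of `width` ms anchored at the
#' first sample; a trailing partial bin is dropped. Bin times are the bin
#' centers. Edge flags are carried over: a bin is flagged if any of its
#' samples was flagged.
#'
#' @param tf a `tf_map` on the sample grid.
#' @param width bin width in ms, a positive multiple of the sample interval
#'   (default 20).
#' @return a binned `tf_map`.
#' @export
bin_time <- function(tf, width = 20) {
  stopifnot(inherits(tf, "tf_map"))
  dt <- diff(tf$times[1:2])
  if (width < dt)
    stop("bin width (", width, " ms) smaller than the sample interval (",
         dt, " ms)")
  spb <- round(width / dt)
  if (abs(spb * dt - width) > 1e-6 * width)
    stop("bin width must be a multiple of the sample interval")
  n <- length(tf$times)
  nb <- floor(n / spb)
  if (nb < 1) stop("epoch shorter than one bin")
  keep <- seq_len(nb * spb)
  grp <- rep(seq_len(nb), each = spb)
  d <- dim(tf$power)
  p <- tf$power[, keep, , drop = FALSE]
  binned <- array(0, c(d[1], nb, d[3]))
  for (ch in seq_len(d[3]))
    binned[, , ch] <- t(rowsum(t(matrix(p[, , ch], d[1], length(keep))),
                               grp) / spb)
  tf$power <- binned
  tf$times <- as.numeric(rowsum(tf$times[keep], grp) / spb)
  if (!is.null(tf$edges)) {
    e <- tf$edges[, keep, drop = FALSE]
    tf$edges <- t(rowsum(t(e * 1), grp)) > 0
  }
  tf
}

#' Subset a time-frequency map
#'
#' Restricts a `tf_map` to frequency and/or time ranges (closed intervals on
#' the stored grid values).
#'
#' @param tf a `tf_map`.
#' @param freq,time two-element ranges, or NULL to keep all.
#' @return the subset `tf_map`.
#' @export
subset_tf <- function(tf, freq = NULL, time = NULL) {
  stopifnot(inherits(tf, "tf_map"))
  fi <- if (is.null(freq)) seq_along(tf$freqs) else
    which(tf$freqs >= freq[1] & tf$freqs <= freq[2])
  ti <- if (is.null(time)) seq_along(tf$times) else
    which(tf$times >= time[1] & tf$times <= time[2])
  if (!length(fi) || !length(ti)) stop("empty frequency/time selection")
  tf$power <- tf$power[fi, ti, , drop = FALSE]
  tf$freqs <- tf$freqs[fi]
  tf$times <- tf$times[ti]
  if (!is.null(tf$edges)) tf$edges <- tf$edges[fi, ti, drop = FALSE]
  tf
}
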