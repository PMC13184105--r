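#' Frequency-band / time-window definition
#'
#' @param name band label.
#' @param f_lo,f_hi frequency bounds in Hz.
#' @param t_lo,t_hi time-window bounds in ms.
#' @return list of class `band_window`.
#' @export
band_window <- function(name, f_lo, f_hi, t_lo, t_hi) {
  stopifnot(f_lo < f_hi, t_lo < t_hi)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 t_lo = t_lo, t_hi = t_hi),
            class = "band_window")
}

#' @export
print.band_window <- function(x, ...) {
  cat(sprintf("<band_window> %s: %g-%g Hz, %g-%g ms\n",
              x$name, x$f_lo, x$f_hi, x$t_lo, x$t_hi))
  invisible(x)
}

#' Default frequency bands and analysis windows
#'
#' The two bands showing a TMS-related response: theta (4-7.5 Hz, 60-300 ms)
#' and low gamma (30-45 Hz, 20-100 ms). Both are overridable wherever a
#' `band_window` is accepted.
#'
#' @return named list with elements `theta` and `gamma`.
#' @export
default_bands <- function() {
  list(theta = band_window("theta", 4, 7.5, 60, 300),
       gamma = band_window("gamma", 30, 45, 20, 100))
}

#' Fixed fronto-central theta electrodes
#'
#' @return character vector `FC1, FCz, FC2, C1, Cz, C2`.
#' @export
theta_electrodes <- function() c("FC1", "FCz", "FC2", "C1", "Cz", "C2")

# Band membership masks: closed interval on grid frequencies, half-open
# [t_lo, t_hi) on bin centers.
band_freq_mask <- function(freqs, band) freqs >= band$f_lo & freqs <= band$f_hi
band_time_mask <- function(times, band) times >= band$t_lo & times < band$t_hi

#' Average a channel-resolved map over a region of interest
#'
#' Averages a `tf_map` across the given electrodes; errors if any is missing
#' from the map.
#'
#' @param tf a `tf_map` with channel axis.
#' @param electrodes channel labels (default the fixed theta set).
#' @return a `tf_map` without channel axis (single-channel).
#' @export
roi_average <- function(tf, electrodes = theta_electrodes()) {
  stopifnot(inherits(tf, "tf_map"))
  if (is.null(tf$channels)) stop("`tf` has no channel labels")
  miss <- setdiff(electrodes, tf$channels)
  if (length(miss))
    stop("channel(s) missing from map: ", paste(miss, collapse = ", "))
  idx <- match(electrodes, tf$channels)
  tf$power <- array(apply(tf$power[, , idx, drop = FALSE], c(1, 2), mean),
                    c(dim(tf$power)[1:2], 1L))
  tf$channels <- NULL
  tf
}

#' Select the peak-power gamma electrode
#'
#' Returns the channel whose mean dB power over the band's frequencies and
#' time window is largest; ties are broken by montage order (first maximum).
#' Mirrors per-site peak-electrode selection for the spatially variable gamma
#' response.
#'
#' @param tf a dB-scale `tf_map` with channel axis.
#' @param band a [band_window()] (default gamma).
#' @return a channel label.
#' @export
select_gamma_electrode <- function(tf, band = default_bands()$gamma) {
  stopifnot(inherits(tf, "tf_map"), inherits(band, "band_window"))
  if (is.null(tf$channels)) stop("`tf` has no channel labels")
  if (tf$scale != "dB") stop("`tf` must be dB-scaled")
  fm <- band_freq_mask(tf$freqs, band)
  tm <- band_time_mask(tf$times, band)
  if (!any(fm) || !any(tm))
    stop("band/window has empty intersection with the map grid")
  m <- apply(tf$power[fm, tm, , drop = FALSE], 3, mean)
  tf$channels[which.max(m)]
}
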