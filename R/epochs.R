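#' Construct an epoched EEG recording
#'
#' Container for the epoched multi-channel EEG of one subject at one
#' stimulation site, with the time axis in milliseconds relative to the TMS
#' pulse (time 0).
#'
#' @param data numeric array `[epoch, channel, sample]`, microvolts.
#' @param channels character vector of 10-10 channel labels (unique).
#' @param sfreq sampling rate in Hz.
#' @param times numeric vector of sample times in ms, strictly increasing,
#'   uniformly spaced, containing 0.
#' @param subject,site,group identifying labels.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, channels, sfreq, times,
                      subject = NA_character_, site = NA_character_,
                      group = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[2] != length(channels))
    stop("channel dimension (", dim(data)[2], ") does not match ",
         length(channels), " channel labels")
  if (dim(data)[3] != length(times))
    stop("sample dimension does not match length of `times`")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  dt <- diff(times)
  if (any(dt <= 0)) stop("`times` must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("`times` must be uniformly sampled")
  if (abs(mean(dt) - 1000 / sfreq) > 1e-6 * mean(dt))
    stop("`times` spacing inconsistent with `sfreq`")
  if (min(times) > 0 || max(times) < 0)
    stop("epoch must contain time 0 (the TMS pulse)")
  structure(
    list(data = data, channels = as.character(channels), sfreq = sfreq,
         times = as.numeric(times), subject = subject, site = site,
         group = group),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s, site %s, group %s\n",
              x$subject, x$site, x$group))
  cat(sprintf("  %d epochs x %d channels x %d samples @ %g Hz, %g..%g ms\n",
              d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times)))
  invisible(x)
}

n_epochs <- function(epochs) dim(epochs$data)[1]
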