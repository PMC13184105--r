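#' Specification of a synthetic TMS-EEG cohort
#'
#' Parameterizes the generator that emulates the structure of a two-group
#' (healthy control HC vs clinical high-risk CHR-P) single-pulse TMS-EEG
#' study: three stimulation sites, epoched multi-channel EEG with 1/f
#' background noise, a phase-locked ERP, a fronto-central theta burst whose
#' amplitude depends on group and site, a small central gamma burst, and a
#' clinical table whose item scores are coupled to each subject's theta
#' amplitude.
#'
#' Burst amplitudes are specified in decibels and calibrated operationally:
#' the injected burst power is scaled so that the analytic expected dB,
#' `10*log10((P_noise + P_burst)/P_noise)` averaged over the band's
#' region-of-interest cells and electrodes, equals the requested value under
#' the analysis grid stored in the spec.
#'
#' @param n_hc,n_chr subjects per group (study sizes 58 and 44 by default).
#' @param sites ordered site labels.
#' @param epochs_per_site single TMS pulses per site (default 100).
#' @param sfreq sampling rate in Hz (default 2500).
#' @param epoch_window epoch extent in ms around the pulse
#'   (default `c(-1000, 1000)`); must contain the baseline `[-400, -200]` ms
#'   and the theta window `[60, 300]` ms.
#' @param channels montage labels; must include the fixed theta electrodes.
#' @param theta_amp_db,gamma_amp_db group-by-site matrices (rows `HC`,
#'   `CHR`; columns `sites`) of target dB elevations over baseline.
#' @param theta_burst,gamma_burst named vectors `center` (ms), `duration`
#'   (FWHM, ms), `freq` (carrier Hz).
#' @param erp_amp amplitude of the phase-locked N100/P200-like component
#'   (microvolts; identical across trials).
#' @param noise_exponent 1/f spectral slope of the background noise.
#' @param noise_sd broadband RMS of the background noise (microvolts).
#' @param subject_sd_db between-subject SD of burst amplitude (dB), shared
#'   across sites of a subject.
#' @param site_sd_db independent per-subject-per-site amplitude jitter (dB).
#' @param clinical_effect named numeric: per-item slope linking a subject's
#'   theta amplitude deviation (dB) to the item score.
#' @param missing_rate probability of a missing clinical value (CHR rows).
#' @param grid analysis [make_freq_grid()] used for amplitude calibration.
#' @param bands band windows used for calibration (default [default_bands()]).
#' @param band_limits analysis band-pass edges in Hz (used for calibration).
#' @param bin_width,baseline analysis binning (ms) and dB baseline window.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 58, n_chr = 44,
                        sites = c("lDLPFC", "lPPC", "DMPFC"),
                        epochs_per_site = 100,
                        sfreq = 2500,
                        epoch_window = c(-1000, 1000),
                        channels = montage_1010()$label,
                        theta_amp_db = default_theta_map(sites),
                        gamma_amp_db = default_gamma_map(sites),
                        theta_burst = c(center = 180, duration = 240,
                                        freq = 5.5),
                        gamma_burst = c(center = 60, duration = 80,
                                        freq = 38),
                        erp_amp = 5,
                        noise_exponent = 1,
                        noise_sd = 10,
                        subject_sd_db = 1.2,
                        site_sd_db = 0.3,
                        clinical_effect = c(P1 = -0.45, N2 = -0.35,
                                            N4 = -0.5, N6 = -0.55),
                        missing_rate = 0.05,
                        grid = make_freq_grid(),
                        bands = default_bands(),
                        band_limits = c(3, 100),
                        bin_width = 20,
                        baseline = c(-400, -200),
                        seed = 1) {
  if (n_hc < 1 || n_chr < 1) stop("each group needs at least one subject")
  if (epochs_per_site < 1) stop("`epochs_per_site` must be >= 1")
  if (anyDuplicated(sites)) stop("`sites` must be distinct")
  if (epoch_window[1] > baseline[1] || epoch_window[2] < baseline[2])
    stop("epoch window must contain the baseline window [",
         baseline[1], ", ", baseline[2], "] ms")
  theta_w <- bands$theta
  if (epoch_window[1] > theta_w$t_lo || epoch_window[2] < theta_w$t_hi)
    stop("epoch window must contain the theta analysis window [",
         theta_w$t_lo, ", ", theta_w$t_hi, "] ms")
  miss <- setdiff(theta_electrodes(), channels)
  if (length(miss))
    stop("montage missing required theta electrode(s): ",
         paste(miss, collapse = ", "))
  for (m in list(theta_amp_db, gamma_amp_db)) {
    if (!is.matrix(m) || !all(c("HC", "CHR") %in% rownames(m)) ||
        !all(sites %in% colnames(m)))
      stop("amplitude maps must be matrices with rows HC, CHR and one ",
           "column per site")
  }
  structure(
    list(n_hc = n_hc, n_chr = n_chr, sites = sites,
         epochs_per_site = epochs_per_site, sfreq = sfreq,
         epoch_window = epoch_window, channels = channels,
         theta_amp_db = theta_amp_db, gamma_amp_db = gamma_amp_db,
         theta_burst = theta_burst, gamma_burst = gamma_burst,
         erp_amp = erp_amp, noise_exponent = noise_exponent,
         noise_sd = noise_sd, subject_sd_db = subject_sd_db,
         site_sd_db = site_sd_db, clinical_effect = clinical_effect,
         missing_rate = missing_rate, grid = grid, bands = bands,
         band_limits = band_limits, bin_width = bin_width,
         baseline = baseline, seed = seed),
    class = "cohort_spec")
}

# Default group x site theta targets (dB): HC differentiated with the
# strongest response after lDLPFC stimulation (~1 dB site effects), CHR-P
# uniformly elevated ("flattened").
default_theta_map <- function(sites = c("lDLPFC", "lPPC", "DMPFC")) {
  m <- matrix(2.7, 2, length(sites),
              dimnames = list(c("HC", "CHR"), sites))
  if ("lDLPFC" %in% sites) m["HC", "lDLPFC"] <- 2.88
  if ("lPPC" %in% sites) m["HC", "lPPC"] <- 2.88 - 0.92
  if ("DMPFC" %in% sites) m["HC", "DMPFC"] <- 2.88 - 1.03
  m
}

# Gamma: small central burst, no group or site differentiation.
default_gamma_map <- function(sites = c("lDLPFC", "lPPC", "DMPFC")) {
  matrix(0.9, 2, length(sites), dimnames = list(c("HC", "CHR"), sites))
}

# Per-site gamma topography peak: central electrodes so that the
# peak-electrode selector is exercised (C1 for lateral sites, Cz for DMPFC).
gamma_peak_electrode <- function(site) {
  if (grepl("DMPFC", site)) "Cz" else "C1"
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d HC + %d CHR, %d sites x %d epochs, %g Hz, %d channels, seed %d\n",
    x$n_hc, x$n_chr, length(x$sites), x$epochs_per_site, x$sfreq,
    length(x$channels), x$seed))
  invisible(x)
}

# ---- noise / burst primitives -------------------------------------------

# Spectral shaping gains for 1/f^alpha noise on an n-sample FFT grid.
# Flattened below 2 Hz to keep the variance finite; no DC.
noise_gains <- function(n, sfreq, exponent) {
  f <- abs(fft_frequencies(n, sfreq))
  g <- numeric(n)
  g[f > 0] <- pmax(f[f > 0], 2)^(-exponent / 2)
  g
}

# Generate m columns of shaped noise (n samples each) with broadband RMS sd.
shaped_noise <- function(n, m, sfreq, exponent, sd) {
  g <- noise_gains(n, sfreq, exponent)
  scale <- sd / sqrt(mean(g^2))
  w <- matrix(stats::rnorm(n * m), n, m)
  Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n * scale
}

# Expected single-epoch wavelet power of the background noise at each grid
# frequency, including the band-pass response, from the discrete spectral
# densities (stationary approximation; exact up to edge padding).
expected_noise_power <- function(spec, times, band_limits = spec$band_limits) {
  n <- length(times)
  g <- noise_gains(n, spec$sfreq, spec$noise_exponent)
  scale <- spec$noise_sd / sqrt(mean(g^2))
  b <- bandpass_gain(abs(fft_frequencies(n, spec$sfreq)),
                     band_limits[1], band_limits[2], 8)
  gb2 <- (g * b * scale)^2
  vapply(seq_along(spec$grid$frequencies), function(k) {
    w <- morlet_spectrum(n, spec$sfreq, spec$grid$frequencies[k],
                         spec$grid$cycles[k])
    sum(gb2 * w^2) / n
  }, numeric(1))
}

# Gaussian burst envelope; duration is the FWHM in ms.
burst_envelope <- function(times, center, duration) {
  sigma <- duration / (2 * sqrt(2 * log(2)))
  exp(-(times - center)^2 / (2 * sigma^2))
}

# Binned wavelet power of the unit-amplitude burst (phase-averaged over two
# quadratures), after band-pass, on the spec's analysis grid.
unit_burst_power <- function(spec, times, burst,
                             band_limits = spec$band_limits) {
  env <- burst_envelope(times, burst[["center"]], burst[["duration"]])
  ph <- 2 * pi * burst[["freq"]] * (times - burst[["center"]]) / 1000
  x <- cbind(env * cos(ph), env * sin(ph))
  es <- epoch_set(array(t(x), c(2, 1, length(times))), channels = "Cz",
                  sfreq = spec$sfreq, times = times)
  es <- bandpass(es, band_limits[1], band_limits[2])
  # per-phase power, then phase average: morlet_tfr averages across "epochs"
  tf <- morlet_tfr(es, spec$grid)
  tf <- bin_time(tf, spec$bin_width)
  list(power = tf$power[, , 1], times = tf$times)
}

# Solve for the burst scale s so that the ROI-mean expected dB equals
# target_db: mean over ROI cells/channels of 10*log10(1 + s^2 * R) = target.
calibrate_burst_scale <- function(target_db, ratio_unit) {
  if (target_db <= 0 || !length(ratio_unit)) return(0)
  f <- function(s) mean(10 * log10(1 + s^2 * ratio_unit)) - target_db
  hi <- 1
  while (f(hi) < 0) hi <- hi * 4
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}

# Precompute, for one burst type, the unit power ratio over ROI cells and
# electrode weights; returns a vector over (cell, channel).
burst_roi_ratio <- function(spec, times, burst, band, electrodes, weights,
                            noise_power) {
  up <- unit_burst_power(spec, times, burst)
  fm <- band_freq_mask(spec$grid$frequencies, band)
  tm <- band_time_mask(up$times, band)
  if (!any(fm) || !any(tm))
    stop("calibration band has empty intersection with the analysis grid")
  pb <- up$power[fm, tm, drop = FALSE]
  pn <- noise_power[fm]
  ratio_cells <- pb / pn            # recycled per column of the window
  as.numeric(outer(as.numeric(ratio_cells), weights[electrodes]^2))
}

# ---- cohort generation ---------------------------------------------------

#' Simulate a synthetic TMS-EEG cohort
#'
#' Generates one [epoch_set()] per subject and stimulation site (1/f noise +
#' phase-locked ERP + amplitude-calibrated theta and gamma bursts with
#' per-trial random phase) plus a clinical table, fully reproducible from
#' the spec's seed. Per-subject realized burst amplitudes are stored as
#' ground truth.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `tms_cohort`: list with `epochs` (nested list
#'   `[[subject]][[site]]`), `clinical` (data.frame), `truth` (data.frame of
#'   realized per-subject-site amplitudes) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- round((spec$epoch_window[2] - spec$epoch_window[1]) / 1000 *
               spec$sfreq) + 1
  times <- seq(spec$epoch_window[1], spec$epoch_window[2], length.out = n)
  mont <- montage_1010(spec$channels)
  w_theta <- topography_weights(mont, "FCz")
  names(w_theta) <- mont$label
  pn <- expected_noise_power(spec, times)

  theta_ratio <- burst_roi_ratio(spec, times, spec$theta_burst,
                                 spec$bands$theta, theta_electrodes(),
                                 w_theta, pn)
  gamma_peaks <- vapply(spec$sites, gamma_peak_electrode, character(1))
  w_gamma <- lapply(gamma_peaks, function(pk) {
    wg <- topography_weights(mont, pk)
    names(wg) <- mont$label
    wg
  })
  gamma_ratio <- lapply(seq_along(spec$sites), function(i)
    burst_roi_ratio(spec, times, spec$gamma_burst, spec$bands$gamma,
                    gamma_peaks[i], w_gamma[[i]], pn))

  subjects <- c(sprintf("HC%02d", seq_len(spec$n_hc)),
                sprintf("CHR%02d", seq_len(spec$n_chr)))
  groups <- rep(c("HC", "CHR"), c(spec$n_hc, spec$n_chr))
  ns <- length(subjects)
  nsite <- length(spec$sites)

  # subject-level amplitude structure (drawn before epoch noise so that the
  # clinical table is reproducible independent of epoch count)
  th_off <- stats::rnorm(ns, 0, spec$subject_sd_db)
  ga_off <- stats::rnorm(ns, 0, spec$subject_sd_db)
  th_jit <- matrix(stats::rnorm(ns * nsite, 0, spec$site_sd_db), ns, nsite)
  ga_jit <- matrix(stats::rnorm(ns * nsite, 0, spec$site_sd_db), ns, nsite)

  truth <- expand.grid(subject = subjects, site = spec$sites,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$group <- groups[match(truth$subject, subjects)]
  truth$theta_db <- NA_real_
  truth$gamma_db <- NA_real_

  erp <- spec$erp_amp *
    (-burst_envelope(times, 100, 70) + 0.7 * burst_envelope(times, 200, 106))
  env_th <- burst_envelope(times, spec$theta_burst[["center"]],
                           spec$theta_burst[["duration"]])
  env_ga <- burst_envelope(times, spec$gamma_burst[["center"]],
                           spec$gamma_burst[["duration"]])
  tsec <- (times - spec$theta_burst[["center"]]) / 1000
  gsec <- (times - spec$gamma_burst[["center"]]) / 1000
  E <- spec$epochs_per_site
  C <- length(spec$channels)

  epochs <- vector("list", ns)
  names(epochs) <- subjects
  for (si in seq_len(ns)) {
    grp <- groups[si]
    grp_key <- if (grp == "HC") "HC" else "CHR"
    site_list <- vector("list", nsite)
    names(site_list) <- spec$sites
    for (ti in seq_len(nsite)) {
      site <- spec$sites[ti]
      th_target <- max(0, spec$theta_amp_db[grp_key, site] + th_off[si] +
                         th_jit[si, ti])
      ga_target <- max(0, spec$gamma_amp_db[grp_key, site] + ga_off[si] +
                         ga_jit[si, ti])
      s_th <- calibrate_burst_scale(th_target, theta_ratio)
      s_ga <- calibrate_burst_scale(ga_target, gamma_ratio[[ti]])
      row <- truth$subject == subjects[si] & truth$site == site
      truth$theta_db[row] <- th_target
      truth$gamma_db[row] <- ga_target

      x <- shaped_noise(n, E * C, spec$sfreq, spec$noise_exponent,
                        spec$noise_sd)
      ph_th <- stats::runif(E, 0, 2 * pi)
      ph_ga <- stats::runif(E, 0, 2 * pi)
      th_mat <- env_th * cos(outer(2 * pi * spec$theta_burst[["freq"]] * tsec,
                                   ph_th, "+"))
      ga_mat <- env_ga * cos(outer(2 * pi * spec$gamma_burst[["freq"]] * gsec,
                                   ph_ga, "+"))
      wg <- w_gamma[[ti]]
      for (ch in seq_len(C)) {
        cols <- (ch - 1) * E + seq_len(E)
        add <- s_th * w_theta[ch] * th_mat + s_ga * wg[ch] * ga_mat +
          w_theta[ch] * erp
        x[, cols] <- x[, cols] + add
      }
      site_list[[ti]] <- epoch_set(array(t(x), c(E, C, n)),
                                   channels = spec$channels,
                                   sfreq = spec$sfreq, times = times,
                                   subject = subjects[si], site = site,
                                   group = grp_key)
    }
    epochs[[si]] <- site_list
  }

  clinical <- simulate_clinical(spec, subjects, groups, th_off)
  structure(list(epochs = epochs, clinical = clinical, truth = truth,
                 spec = spec),
            class = "tms_cohort")
}

#' Simulate a null cohort (no group or site effects)
#'
#' Same generator with the theta and gamma amplitude maps forced to a single
#' constant (the mean of each map), so that the generative distribution is
#' exchangeable across sites and groups. Used for family-wise error
#' calibration of the permutation tests.
#'
#' @param spec a [cohort_spec()].
#' @return a `tms_cohort`.
#' @export
simulate_null_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  spec$theta_amp_db[, ] <- mean(spec$theta_amp_db)
  spec$gamma_amp_db[, ] <- mean(spec$gamma_amp_db)
  simulate_cohort(spec)
}

#' @export
print.tms_cohort <- function(x, ...) {
  cat(sprintf(
    "<tms_cohort> %d subjects (%d HC, %d CHR) x %d sites, %d epochs/site\n",
    length(x$epochs), x$spec$n_hc, x$spec$n_chr, length(x$spec$sites),
    x$spec$epochs_per_site))
  invisible(x)
}

# ---- clinical table ------------------------------------------------------

# Reference means/SDs of the clinical instruments per group (ordinal SIPS
# items 0-6; negative items not assessed in HC).
clinical_reference <- function() {
  items <- data.frame(
    item = c("P1", "P2", "P3", "P4", "P5",
             "N1", "N2", "N3", "N4", "N5", "N6"),
    chr_mean = c(2.6, 2.4, 0.5, 3.3, 0.8, 1.8, 2.8, 2.0, 3.3, 0.6, 2.5),
    chr_sd = c(1.3, 1.6, 0.9, 1.3, 1.0, 1.6, 1.4, 1.6, 2.0, 1.1, 2.0),
    hc_mean = c(0.09, 0.02, 0, 0.66, 0.09, NA, NA, NA, NA, NA, NA),
    hc_sd = c(0.43, 0.13, 0.1, 0.66, 0.47, NA, NA, NA, NA, NA, NA))
  cont <- data.frame(
    item = c("COPER", "COGDIS", "SOFAS", "AVLT_first", "AVLT_total",
             "AVLT_delay", "DSST"),
    chr_mean = c(11.8, 8.4, 59.7, 46.9, 50.6, 44.7, 10.8),
    chr_sd = c(9.6, 7.7, 10.2, 27.8, 33.7, 32.9, 5.8),
    hc_mean = c(0.1, 0.0, 87.8, 70.9, 74.7, 69.8, 12.6),
    hc_sd = c(0.4, 0.1, 4.8, 21.8, 22.5, 22.0, 2.7))
  list(items = items, continuous = cont)
}

simulate_clinical <- function(spec, subjects, groups, theta_dev) {
  ref <- clinical_reference()
  ns <- length(subjects)
  is_chr <- groups == "CHR"
  out <- data.frame(subject = subjects, group = groups,
                    stringsAsFactors = FALSE)
  out$age <- round(pmin(pmax(stats::rnorm(
    ns, ifelse(is_chr, 19.2, 20.2), ifelse(is_chr, 4.2, 3.6)), 14), 33), 1)
  out$antipsychotic <- is_chr & stats::runif(ns) < 7 / 44
  out$mood_comorbidity <- is_chr & stats::runif(ns) < 0.35
  eff <- spec$clinical_effect
  for (i in seq_len(nrow(ref$items))) {
    it <- ref$items$item[i]
    mu <- ifelse(is_chr, ref$items$chr_mean[i], ref$items$hc_mean[i])
    sd <- ifelse(is_chr, ref$items$chr_sd[i], ref$items$hc_sd[i])
    mu[is.na(mu)] <- 0
    sd[is.na(sd)] <- 0                      # N items: unassessed in HC
    slope <- if (it %in% names(eff)) eff[[it]] else 0
    val <- round(mu + slope * theta_dev + stats::rnorm(ns, 0, sd))
    val <- pmin(pmax(val, 0), 6)
    if (grepl("^N", it)) val[!is_chr] <- NA      # not assessed in HC
    val[is_chr & stats::runif(ns) < spec$missing_rate] <- NA
    out[[it]] <- val
  }
  for (i in seq_len(nrow(ref$continuous))) {
    it <- ref$continuous$item[i]
    mu <- ifelse(is_chr, ref$continuous$chr_mean[i], ref$continuous$hc_mean[i])
    sd <- ifelse(is_chr, ref$continuous$chr_sd[i], ref$continuous$hc_sd[i])
    slope <- if (it %in% names(eff)) eff[[it]] else 0
    val <- mu + slope * theta_dev + stats::rnorm(ns, 0, sd)
    if (it %in% c("COPER", "COGDIS")) val <- pmax(round(val, 1), 0)
    if (it == "SOFAS") val <- pmin(pmax(round(val), 0), 100)
    if (grepl("^AVLT", it)) val <- pmin(pmax(round(val, 1), 0), 100)
    if (it == "DSST") val <- round(val, 1)
    val[is_chr & stats::runif(ns) < spec$missing_rate] <- NA
    out[[it]] <- val
  }
  out
}

#' Write a cohort to disk
#'
#' Clinical and ground-truth tables as CSV; the epoch arrays as an RDS file.
#'
#' @param cohort a `tms_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tms_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(file.path(dir, "clinical.csv"), file.path(dir, "truth.csv"),
             file.path(dir, "epochs.rds"))
  utils::write.csv(cohort$clinical, files[1], row.names = FALSE)
  utils::write.csv(cohort$truth, files[2], row.names = FALSE)
  saveRDS(cohort$epochs, files[3])
  invisible(files)
}
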