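# Shared fixtures: reduced cohort specs and independent oracles.

site3 <- c("lDLPFC", "lPPC", "DMPFC")

amp_map <- function(v) matrix(v, 2, 3, dimnames = list(c("HC", "CHR"), site3))

reduced_grid <- function(n = 15) make_freq_grid(n)

# Desk-scale analysis settings shared by the simulation studies: theta ROI
# channels only, 200 Hz sampling (band-pass top edge 90 Hz, below Nyquist).
reduced_band_limits <- c(3, 90)

reduced_spec <- function(seed, n_hc = 20, n_chr = 1, epochs = 100, ...) {
  cohort_spec(n_hc = n_hc, n_chr = n_chr, epochs_per_site = epochs,
              sfreq = 200, channels = theta_electrodes(),
              grid = reduced_grid(), band_limits = reduced_band_limits,
              seed = seed, ...)
}

# Truly noise-only null spec: zero burst/ERP amplitudes and zero amplitude
# spread, so epochs contain nothing but 1/f noise.
noise_spec <- function(seed, n_hc = 20, epochs = 8) {
  reduced_spec(seed, n_hc = n_hc, n_chr = 1, epochs = epochs,
               theta_amp_db = amp_map(0), gamma_amp_db = amp_map(0),
               erp_amp = 0, subject_sd_db = 0, site_sd_db = 0)
}

reduced_maps <- function(cohort) {
  cohort_tf_maps(cohort, reduced_grid(),
                 band_limits = reduced_band_limits)
}

# A quick single-channel epoch_set from a samples x epochs matrix.
quick_epochs <- function(x, sfreq = 500, t0 = -1000, channel = "Cz") {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  tm <- t0 + (seq_len(nrow(x)) - 1) / sfreq * 1000
  epoch_set(array(t(x), c(ncol(x), 1, nrow(x))), channel, sfreq, tm)
}

# ---- independent oracles -------------------------------------------------

# Exhaustive sign-flip z-map: enumerate all 2^n sign patterns. The complete
# permutation distribution's population SD is the estimand of the
# Monte-Carlo sample SD, so no n-1 correction over the enumeration set.
enum_signflip_z <- function(devm) {
  n <- nrow(devm)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm_means <- (signs %*% devm) / n
  mu <- colMeans(perm_means)
  sd <- sqrt(colMeans(sweep(perm_means, 2, mu)^2))
  (colMeans(devm) - mu) / sd
}

# Exhaustive two-group label-shuffle z-map over all distinct assignments.
enum_labelshuffle_z <- function(devm, na) {
  n <- nrow(devm)
  combos <- utils::combn(n, na)
  perm <- t(apply(combos, 2, function(ia)
    colMeans(devm[ia, , drop = FALSE]) -
      colMeans(devm[-ia, , drop = FALSE])))
  obs <- colMeans(devm[seq_len(na), , drop = FALSE]) -
    colMeans(devm[-seq_len(na), , drop = FALSE])
  mu <- colMeans(perm)
  sd <- sqrt(colMeans(sweep(perm, 2, mu)^2))
  (obs - mu) / sd
}

# Brute-force flood-fill connected-component labeling (queue-based).
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- cur[1] + offs[k, 1]; c <- cur[2] + offs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Equality of labelings up to renumbering.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  cells <- which(a > 0)
  if (!length(cells)) return(TRUE)
  pairs <- unique(cbind(a[cells], b[cells]))
  !(anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
}

# Direct generative model for band-power tables (no EEG simulation):
# mean_power = site effect + group x site interaction + subject intercept +
# residual, for LMM parameter-recovery checks.
simulate_bp_table <- function(n_per_group, beta_site, beta_int,
                              subject_sd, resid_sd, seed,
                              sites = c("lDLPFC", "lPPC", "DMPFC")) {
  set.seed(seed)
  subjects <- c(sprintf("HC%03d", seq_len(n_per_group)),
                sprintf("CHR%03d", seq_len(n_per_group)))
  groups <- rep(c("HC", "CHR"), each = n_per_group)
  u <- rnorm(length(subjects), 0, subject_sd)
  tab <- expand.grid(subject = subjects, site = sites,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$group <- groups[match(tab$subject, subjects)]
  tab$band <- "theta"
  tab$age <- round(rnorm(length(subjects), 20, 4), 1)[
    match(tab$subject, subjects)]
  tab$antipsychotic <- (tab$group == "CHR") &
    (match(tab$subject, subjects) %% 7 == 0)
  eff_site <- ifelse(tab$site == sites[1], 0, beta_site)
  eff_int <- ifelse(tab$site != sites[1] & tab$group == "CHR", beta_int, 0)
  tab$mean_power <- 2.5 + eff_site + eff_int +
    u[match(tab$subject, subjects)] + rnorm(nrow(tab), 0, resid_sd)
  tab
}

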