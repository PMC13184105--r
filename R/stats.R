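#' Select per-site peak gamma electrodes from grand-average maps
#'
#' Averages the dB maps of all subjects per site and applies
#' [select_gamma_electrode()] to the grand average.
#'
#' @param maps nested list `maps[[subject]][[site]]` of binned dB `tf_map`s
#'   with channel axis.
#' @param band a [band_window()] (default gamma).
#' @return named character vector, one electrode per site.
#' @export
select_site_gamma_electrodes <- function(maps, band = default_bands()$gamma) {
  sites <- names(maps[[1]])
  out <- vapply(sites, function(st) {
    ga <- maps[[1]][[st]]
    acc <- ga$power * 0
    for (s in names(maps)) acc <- acc + maps[[s]][[st]]$power
    ga$power <- acc / length(maps)
    select_gamma_electrode(ga, band)
  }, character(1))
  names(out) <- sites
  out
}

#' Extract mean band power per subject and site
#'
#' Scalar per subject and site: the mean of the dB map over the band's
#' frequencies (closed interval on grid frequencies), time window (half-open
#' on bin centers) and electrode set. Electrodes may be one fixed set (the
#' theta convention) or a named per-site vector (the gamma peak-electrode
#' convention).
#'
#' @param maps nested list `maps[[subject]][[site]]` of binned dB `tf_map`s
#'   with channel axis.
#' @param band a [band_window()].
#' @param electrodes character vector of electrodes, or a named character
#'   vector/list keyed by site.
#' @param clinical optional clinical data.frame merged in by `subject`.
#' @return long data.frame (`band_power_table`): one row per subject x site
#'   with `mean_power` in dB.
#' @export
extract_band_power <- function(maps, band, electrodes = theta_electrodes(),
                               clinical = NULL) {
  stopifnot(inherits(band, "band_window"))
  per_site <- (is.list(electrodes) || !is.null(names(electrodes)))
  rows <- list()
  for (s in names(maps)) for (st in names(maps[[s]])) {
    tf <- maps[[s]][[st]]
    el <- if (per_site) electrodes[[st]] else electrodes
    if (is.null(el)) stop("no electrode selection for site ", st)
    fm <- band_freq_mask(tf$freqs, band)
    tm <- band_time_mask(tf$times, band)
    idx <- match(el, tf$channels)
    if (anyNA(idx))
      stop("channel(s) missing from map: ",
           paste(el[is.na(idx)], collapse = ", "))
    if (!any(fm) || !any(tm)) stop("empty band/window selection")
    rows[[length(rows) + 1]] <- data.frame(
      subject = tf$subject, group = tf$group, site = st, band = band$name,
      mean_power = mean(tf$power[fm, tm, idx]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(clinical))
    out <- merge(out, clinical, by = intersect(c("subject", "group"),
                                               names(clinical)),
                 all.x = TRUE, sort = FALSE)
  class(out) <- c("band_power_table", "data.frame")
  out
}

# Shared LMM fitting core: response ~ term * site + age + antipsychotic +
# (1 | subject), with reference levels fixed.
fit_band_lmm <- function(table, band, term, term_ref, site_ref = "lDLPFC") {
  tab <- as.data.frame(table)
  tab <- tab[tab$band == band, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for band ", band)
  needed <- c("mean_power", term, "site", "age", "antipsychotic", "subject")
  miss <- needed[!needed %in% names(tab)]
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  tab$site <- stats::relevel(factor(tab$site), ref = site_ref)
  tv <- tab[[term]]
  if (is.logical(tv)) tv <- factor(tv, c(FALSE, TRUE))
  tv <- factor(tv)
  if (nlevels(droplevels(tv)) < 2)
    stop("`", term, "` has fewer than two levels")
  if (!is.null(term_ref)) tv <- stats::relevel(tv, ref = term_ref)
  tab[[term]] <- tv
  fml <- stats::as.formula(paste(
    "mean_power ~", term, "* site + age + antipsychotic + (1 | subject)"))
  fit <- lmerTest::lmer(fml, data = tab, REML = TRUE)
  singular <- lme4::isSingular(fit)
  coefs <- as.data.frame(summary(fit)$coefficients)
  names(coefs) <- c("estimate", "se", "df", "t", "p")
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  var_fix <- stats::var(as.numeric(lme4::getME(fit, "X") %*%
                                     lme4::fixef(fit)))
  tot <- var_fix + var_re + var_res
  r2c <- if (tot > 0) (var_fix + var_re) / tot else NA_real_
  structure(list(model = fit, coefficients = coefs,
                 r2_conditional = r2c, singular = singular,
                 band = band, term = term, n_subjects =
                   length(unique(tab$subject)), df_method = "Satterthwaite"),
            class = "band_lmm")
}

#' Group-by-site linear mixed model of band power
#'
#' Fits `mean_power ~ group * site + age + antipsychotic + (1 | subject)`
#' with restricted maximum likelihood, reference levels HC and lDLPFC, and
#' Satterthwaite denominator degrees of freedom for the t statistics.
#' Conditional R-squared is the variance explained by fixed plus random
#' effects over the total. Singular random-effect fits are flagged, not
#' fatal.
#'
#' @param table a `band_power_table` from [extract_band_power()].
#' @param band band name to model (e.g. `"theta"`).
#' @return object of class `band_lmm` with `coefficients`,
#'   `r2_conditional`, `singular` and the underlying `lmerMod`.
#' @export
fit_group_site_lmm <- function(table, band = "theta") {
  fit_band_lmm(table, band, term = "group", term_ref = "HC")
}

#' Mood-comorbidity linear mixed model within CHR-P
#'
#' Same structure as [fit_group_site_lmm()] restricted to the CHR-P group,
#' with comorbid mood disorder replacing group.
#'
#' @inheritParams fit_group_site_lmm
#' @return a `band_lmm`.
#' @export
fit_comorbidity_lmm <- function(table, band = "theta") {
  tab <- as.data.frame(table)
  tab <- tab[tab$group == "CHR", , drop = FALSE]
  if (!nrow(tab)) stop("no CHR-P rows in table")
  fit_band_lmm(tab, band, term = "mood_comorbidity", term_ref = "FALSE")
}

#' @export
print.band_lmm <- function(x, digits = 3, ...) {
  cat(sprintf("<band_lmm> %s power ~ %s * site + age + antipsychotic + (1 | subject)\n",
              x$band, x$term))
  cat(sprintf("  %d subjects; df: %s%s\n", x$n_subjects, x$df_method,
              if (x$singular) "; singular random-effects fit" else ""))
  stats::printCoefmat(as.matrix(x$coefficients), digits = digits,
               cs.ind = 1:2, tst.ind = 4, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("  conditional R^2 = %.3f\n", x$r2_conditional))
  invisible(x)
}

#' @export
summary.band_lmm <- function(object, ...) object

#' Spearman correlations with FDR correction
#'
#' Spearman rank correlations (average ranks on ties) between band power per
#' stimulation site and clinical items, within the CHR-P group, with
#' pairwise deletion of missing values. Benjamini-Hochberg correction is
#' applied across the chosen family of tests (all site-by-item tests within
#' one band by default).
#'
#' @param table a `band_power_table` with clinical columns merged in.
#' @param items character vector of item column names.
#' @param group group to analyze (default `"CHR"`).
#' @param family FDR family: `"band"` (default; all site x item tests of one
#'   band), `"band_site"` or `"global"`.
#' @param alpha significance level for the flags (default 0.05).
#' @return data.frame with one row per band x site x item: `n`, `rho`, `p`,
#'   `p_fdr`, `sig_raw` (raw p <= alpha), `sig_fdr` (adjusted p < alpha).
#'   Pairs with fewer than 3 complete observations get `NA` rho and a
#'   `too_few` flag.
#' @export
spearman_fdr <- function(table,
                         items = c("P1", "P2", "P3", "P4", "P5", "N1", "N2",
                                   "N3", "N4", "N5", "N6"),
                         group = "CHR",
                         family = c("band", "band_site", "global"),
                         alpha = 0.05) {
  family <- match.arg(family)
  tab <- as.data.frame(table)
  tab <- tab[tab$group == group, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for group ", group)
  miss <- setdiff(items, names(tab))
  if (length(miss))
    stop("item column(s) not in table: ", paste(miss, collapse = ", "))
  rows <- list()
  for (bd in unique(tab$band)) for (st in unique(tab$site)) {
    sub <- tab[tab$band == bd & tab$site == st, , drop = FALSE]
    for (it in items) {
      x <- sub$mean_power
      y <- sub[[it]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n >= 3) {
        rho <- stats::cor(x[ok], y[ok], method = "spearman")
        p <- suppressWarnings(stats::cor.test(
          x[ok], y[ok], method = "spearman", exact = FALSE)$p.value)
      } else {
        rho <- NA_real_
        p <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        band = bd, site = st, item = it, n = n, rho = rho, p = p,
        too_few = n < 3, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  key <- switch(family,
                band = out$band,
                band_site = paste(out$band, out$site),
                global = rep("all", nrow(out)))
  out$p_fdr <- NA_real_
  for (k in unique(key)) {
    i <- key == k
    out$p_fdr[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out$sig_raw <- !is.na(out$p) & out$p <= alpha
  out$sig_fdr <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out
}
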