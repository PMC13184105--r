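#' Preprocess and decompose one epoch set
#'
#' The standard single-dataset chain: pulse-window linear interpolation,
#' zero-phase band-pass, Morlet decomposition (total or induced power), dB
#' baseline normalization, then temporal binning — in that order.
#'
#' @param epochs an [epoch_set()].
#' @param grid a [make_freq_grid()].
#' @param interp_window pulse interpolation window in ms
#'   (default `c(-1, 15)`).
#' @param band_limits band-pass edges in Hz (default `c(3, 100)`).
#' @param baseline dB baseline window in ms (default `c(-400, -200)`).
#' @param bin_width bin width in ms (default 20).
#' @param induced if TRUE compute induced (ERP-subtracted) power.
#' @return a binned dB `tf_map` with channel axis.
#' @export
process_epochs <- function(epochs, grid = make_freq_grid(),
                           interp_window = c(-1, 15),
                           band_limits = c(3, 100),
                           baseline = c(-400, -200),
                           bin_width = 20, induced = FALSE) {
  epochs <- interpolate_pulse_window(epochs, interp_window[1],
                                     interp_window[2])
  epochs <- bandpass(epochs, band_limits[1], band_limits[2])
  tf <- if (induced) induced_tfr(epochs, grid) else morlet_tfr(epochs, grid)
  tf <- db_normalize(tf, baseline)
  bin_time(tf, bin_width)
}

#' Time-frequency maps for a whole cohort
#'
#' Applies [process_epochs()] to every subject and site.
#'
#' @param cohort a `tms_cohort` (or a compatible nested list of epoch sets).
#' @inheritParams process_epochs
#' @return nested list `maps[[subject]][[site]]` of binned dB `tf_map`s.
#' @export
cohort_tf_maps <- function(cohort, grid = make_freq_grid(),
                           interp_window = c(-1, 15),
                           band_limits = c(3, 100),
                           baseline = c(-400, -200),
                           bin_width = 20, induced = FALSE) {
  epochs <- if (inherits(cohort, "tms_cohort")) cohort$epochs else cohort
  lapply(epochs, function(bysite)
    lapply(bysite, process_epochs, grid = grid,
           interp_window = interp_window, band_limits = band_limits,
           baseline = baseline, bin_width = bin_width, induced = induced))
}

#' ROI-averaged map stacks per group
#'
#' Averages channel maps over the theta electrode set and stacks them per
#' group for the permutation tests.
#'
#' @param maps nested list from [cohort_tf_maps()].
#' @param electrodes ROI electrodes (default [theta_electrodes()]).
#' @return named list of `roi_maps`, one per group present.
#' @export
group_roi_stacks <- function(maps, electrodes = theta_electrodes()) {
  roi <- lapply(maps, function(bysite) lapply(bysite, roi_average,
                                              electrodes = electrodes))
  groups <- vapply(roi, function(m) m[[1]]$group, character(1))
  out <- lapply(unique(groups), function(g) stack_roi_maps(roi[groups == g]))
  names(out) <- unique(groups)
  out
}

#' Default pipeline configuration
#'
#' Returns the full configuration list: cohort spec, analysis grid, band
#' windows, permutation settings (5000 permutations, two-sided cluster
#' forming alpha 0.05, 97.5th percentile size threshold), statistics
#' settings, and output directory. Any element can be overridden before
#' calling [run_pipeline()].
#'
#' @param seed integer master seed (flows to the cohort and all permutation
#'   tests).
#' @param out_dir output directory.
#' @return a named list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1, out_dir = "teposc-output") {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    cohort = list(n_hc = 58, n_chr = 44, epochs_per_site = 100,
                  sfreq = 2500, channels = NULL),
    grid = list(n = 30, freq_range = c(3, 80), cycle_range = c(3, 10)),
    preprocessing = list(interp_window = c(-1, 15), band_limits = c(3, 100),
                         baseline = c(-400, -200), bin_width = 20),
    bands = list(theta = c(4, 7.5, 60, 300), gamma = c(30, 45, 20, 100)),
    permutation = list(n_perm = 5000, alpha_cf = 0.05, percentile = 97.5,
                       test_window = c(0, 600)),
    stats = list(fdr_family = "band",
                 items = c("P1", "P2", "P3", "P4", "P5", "N1", "N2", "N3",
                           "N4", "N5", "N6"))),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [pipeline_config()];
#' everything else keeps its default.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "pipeline_config")
}

config_bands <- function(cfg) {
  list(theta = do.call(band_window, c(list("theta"),
                                      as.list(cfg$bands$theta))),
       gamma = do.call(band_window, c(list("gamma"),
                                      as.list(cfg$bands$gamma))))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, decompose it to binned dB maps, run the
#' within-group and between-group cluster permutation tests on the
#' theta-ROI maps, extract theta and gamma band power, fit the
#' group-by-site and comorbidity mixed models, compute the Spearman/FDR
#' symptom associations, and write all artifacts plus a manifest to the
#' output directory. Fully deterministic given the configuration.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @param cohort optionally a pre-built `tms_cohort`; by default one is
#'   simulated from the config.
#' @return the run manifest (named list), invisibly the same as written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  manifest <- list(package_version = as.character(utils::packageVersion("teposc")),
                   seed = cfg$seed, config = unclass(cfg),
                   config_hash = config_hash(cfg))
  tryCatch({
    grid <- make_freq_grid(cfg$grid$n, cfg$grid$freq_range,
                           cfg$grid$cycle_range)
    bands <- config_bands(cfg)
    if (is.null(cohort)) {
      spec_args <- cfg$cohort[!vapply(cfg$cohort, is.null, logical(1))]
      spec <- do.call(cohort_spec, c(spec_args,
                                     list(grid = grid, bands = bands,
                                          bin_width = cfg$preprocessing$bin_width,
                                          baseline = cfg$preprocessing$baseline,
                                          seed = cfg$seed)))
      cohort <- simulate_cohort(spec)
    }
    utils::write.csv(cohort$clinical,
                     file.path(cfg$out_dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$truth, file.path(cfg$out_dir, "truth.csv"),
                     row.names = FALSE)

    stage <- "time-frequency"
    pp <- cfg$preprocessing
    maps <- cohort_tf_maps(cohort, grid, pp$interp_window, pp$band_limits,
                           pp$baseline, pp$bin_width)
    saveRDS(maps, file.path(cfg$out_dir, "tf_maps.rds"))

    stage <- "permutation tests"
    stacks <- group_roi_stacks(maps)
    pm <- cfg$permutation
    within <- lapply(stacks, within_group_test, n_perm = pm$n_perm,
                     seed = cfg$seed, alpha_cf = pm$alpha_cf,
                     percentile = pm$percentile, time = pm$test_window)
    between <- if (length(stacks) == 2)
      between_group_test(stacks[[1]], stacks[[2]], n_perm = pm$n_perm,
                         seed = cfg$seed, alpha_cf = pm$alpha_cf,
                         percentile = pm$percentile, time = pm$test_window)
    else NULL
    cluster_json <- file.path(cfg$out_dir, "cluster_results.json")
    jsonlite::write_json(
      list(within = lapply(within, cluster_set_summary),
           between = if (!is.null(between)) cluster_set_summary(between),
           settings = pm, seed = cfg$seed),
      cluster_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    saveRDS(list(within = within, between = between),
            file.path(cfg$out_dir, "cluster_results.rds"))

    stage <- "band power"
    theta_bp <- extract_band_power(maps, bands$theta, theta_electrodes(),
                                   cohort$clinical)
    gamma_el <- select_site_gamma_electrodes(maps, bands$gamma)
    gamma_bp <- extract_band_power(maps, bands$gamma, gamma_el,
                                   cohort$clinical)
    bp <- rbind(theta_bp, gamma_bp)
    utils::write.csv(bp, file.path(cfg$out_dir, "band_power.csv"),
                     row.names = FALSE)

    stage <- "mixed models"
    lmms <- list()
    for (bd in c("theta", "gamma")) {
      lmms[[bd]] <- tryCatch(lmm_summary(fit_group_site_lmm(bp, bd)),
                             error = function(e) list(error = conditionMessage(e)))
      lmms[[paste0(bd, "_comorbidity")]] <-
        tryCatch(lmm_summary(fit_comorbidity_lmm(bp, bd)),
                 error = function(e) list(error = conditionMessage(e)))
    }
    jsonlite::write_json(lmms, file.path(cfg$out_dir, "lmm_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "associations"
    assoc <- spearman_fdr(bp, cfg$stats$items, family = cfg$stats$fdr_family)
    utils::write.csv(assoc, file.path(cfg$out_dir, "associations.csv"),
                     row.names = FALSE)

    stage <- "manifest"
    files <- c("clinical.csv", "truth.csv", "tf_maps.rds",
               "cluster_results.json", "cluster_results.rds",
               "band_power.csv", "lmm_results.json", "associations.csv")
    paths <- file.path(cfg$out_dir, files)
    manifest$outputs <- data.frame(
      file = files, md5 = unname(tools::md5sum(paths)),
      stringsAsFactors = FALSE)
    manifest$gamma_electrodes <- as.list(gamma_el)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

# JSON-friendly summary of a cluster_test_set.
cluster_set_summary <- function(set) {
  lapply(set, function(r) list(
    site = r$site, size_threshold = r$size_threshold,
    cluster_sizes = r$cluster_sizes,
    n_significant = length(r$significant),
    peaks = r$peaks))
}

lmm_summary <- function(fit) {
  list(band = fit$band, term = fit$term,
       coefficients = cbind(term = rownames(fit$coefficients),
                            fit$coefficients),
       r2_conditional = fit$r2_conditional, singular = fit$singular,
       df_method = fit$df_method)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Render report figures for a pipeline run
#'
#' Writes lossless PNG panels to the run's output directory: per-group,
#' per-site time-frequency maps and z-maps with significant-cluster
#' outlines, plus a cluster summary table as CSV.
#'
#' @param out_dir the pipeline output directory (must contain the artifacts
#'   written by [run_pipeline()]).
#' @return invisibly, the files written.
#' @export
report_pipeline <- function(out_dir) {
  maps_file <- file.path(out_dir, "tf_maps.rds")
  clus_file <- file.path(out_dir, "cluster_results.rds")
  if (!file.exists(maps_file) || !file.exists(clus_file))
    stop("missing pipeline artifacts in ", out_dir,
         "; run run_pipeline() first")
  maps <- readRDS(maps_file)
  clus <- readRDS(clus_file)
  files <- character(0)

  roi <- group_roi_stacks(maps)
  for (g in names(roi)) {
    f <- file.path(out_dir, paste0("tf_", g, ".png"))
    grDevices::png(f, width = 1500, height = 520, res = 120)
    graphics::par(mfrow = c(1, length(roi[[g]]$sites)),
                  mar = c(4, 4, 3, 1))
    for (st in roi[[g]]$sites) {
      i <- match(st, roi[[g]]$sites)
      m <- apply(roi[[g]]$power[, i, , , drop = FALSE], c(3, 4), mean)
      graphics::image(roi[[g]]$times, seq_along(roi[[g]]$freqs), t(m),
                      col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                      xlab = "time (ms)", ylab = "frequency index",
                      main = paste(g, st))
    }
    grDevices::dev.off()
    files <- c(files, f)
  }

  plot_set <- function(set, tag) {
    f <- file.path(out_dir, paste0("zmap_", tag, ".png"))
    grDevices::png(f, width = 1500, height = 520, res = 120)
    graphics::par(mfrow = c(1, length(set)), mar = c(4, 4, 3, 1))
    for (r in set) {
      graphics::image(r$times, seq_along(r$freqs), t(r$zmap),
                      col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                      xlab = "time (ms)", ylab = "frequency index",
                      main = paste(tag, r$site))
      if (length(r$significant)) {
        sig <- matrix(as.numeric(r$labels %in% r$significant),
                      nrow(r$labels), ncol(r$labels))
        graphics::contour(r$times, seq_along(r$freqs), t(sig),
                          levels = 0.5, add = TRUE, drawlabels = FALSE,
                          lwd = 2)
      }
    }
    grDevices::dev.off()
    f
  }
  for (g in names(clus$within))
    files <- c(files, plot_set(clus$within[[g]], paste0("within_", g)))
  if (!is.null(clus$between))
    files <- c(files, plot_set(clus$between, "between"))

  rows <- list()
  collect <- function(set, analysis) {
    for (r in set)
      if (nrow(r$peaks))
        rows[[length(rows) + 1]] <<- cbind(analysis = analysis,
                                           site = r$site, r$peaks)
  }
  for (g in names(clus$within)) collect(clus$within[[g]],
                                        paste0("within_", g))
  if (!is.null(clus$between)) collect(clus$between, "between")
  summ <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analysis = character(0), site = character(0))
  f <- file.path(out_dir, "significant_clusters.csv")
  utils::write.csv(summ, f, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
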