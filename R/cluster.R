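#' Stack per-subject ROI time-frequency maps
#'
#' Assembles binned, dB-scaled, ROI-averaged maps of all subjects and sites
#' into one array for the permutation machinery.
#'
#' @param maps nested list `maps[[subject]][[site]]` of single-channel
#'   `tf_map` objects on a common frequency/bin grid.
#' @return object of class `roi_maps`: array `[subject, site, freq, bin]`
#'   plus `freqs`, `times`, `subjects`, `sites`, `group`.
#' @export
stack_roi_maps <- function(maps) {
  subjects <- names(maps)
  if (is.null(subjects)) stop("`maps` must be a named list (subjects)")
  sites <- names(maps[[1]])
  missing <- lapply(maps, function(m) setdiff(sites, names(m)))
  bad <- names(missing)[vapply(missing, length, 1L) > 0]
  if (length(bad))
    stop("subject(s) missing a site: ", paste(bad, collapse = ", "))
  ref <- maps[[1]][[1]]
  arr <- array(NA_real_, c(length(subjects), length(sites),
                           length(ref$freqs), length(ref$times)),
               dimnames = list(subjects, sites, NULL, NULL))
  for (s in subjects) for (st in sites) {
    m <- maps[[s]][[st]]
    if (!isTRUE(all.equal(m$freqs, ref$freqs)) ||
        !isTRUE(all.equal(m$times, ref$times)))
      stop("maps do not share a common grid (subject ", s, ", site ", st, ")")
    arr[s, st, , ] <- m$power[, , 1]
  }
  structure(list(power = arr, freqs = ref$freqs, times = ref$times,
                 subjects = subjects, sites = sites,
                 group = ref$group),
            class = "roi_maps")
}

#' Subset a `roi_maps` stack in frequency/time
#'
#' @param x a `roi_maps` object.
#' @param freq,time two-element closed ranges, or NULL to keep all.
#' @return the restricted `roi_maps`.
#' @export
subset_roi_maps <- function(x, freq = NULL, time = NULL) {
  stopifnot(inherits(x, "roi_maps"))
  fi <- if (is.null(freq)) seq_along(x$freqs) else
    which(x$freqs >= freq[1] & x$freqs <= freq[2])
  ti <- if (is.null(time)) seq_along(x$times) else
    which(x$times >= time[1] & x$times <= time[2])
  if (!length(fi) || !length(ti)) stop("empty frequency/time selection")
  x$power <- x$power[, , fi, ti, drop = FALSE]
  x$freqs <- x$freqs[fi]
  x$times <- x$times[ti]
  x
}

#' Mean-center ROI maps per subject across stimulation sites
#'
#' For every subject the across-site mean map is subtracted from each site's
#' map, yielding the per-site deviation from that subject's average response.
#' Deviations of one subject sum to zero across sites by construction.
#'
#' @param roi a `roi_maps` object.
#' @return named list (one per site) of `dev_stack` objects with `dev`
#'   `[subject, freq, bin]`.
#' @export
center_by_subject <- function(roi) {
  stopifnot(inherits(roi, "roi_maps"))
  if (anyNA(roi$power)) {
    bad <- roi$subjects[apply(roi$power, 1, anyNA)]
    stop("missing site map(s) for subject(s): ", paste(bad, collapse = ", "))
  }
  subj_mean <- apply(roi$power, c(1, 3, 4), mean)
  d3 <- dim(roi$power)[c(1, 3, 4)]
  out <- lapply(seq_along(roi$sites), function(i) {
    structure(list(dev = array(roi$power[, i, , , drop = FALSE], d3) -
                     array(subj_mean, d3),
                   subjects = roi$subjects, site = roi$sites[i],
                   freqs = roi$freqs, times = roi$times),
              class = "dev_stack")
  })
  names(out) <- roi$sites
  out
}

# Flatten a dev_stack to a subjects x cells matrix.
dev_matrix <- function(stack) {
  d <- dim(stack$dev)
  matrix(stack$dev, d[1], d[2] * d[3])
}

#' Sign-flip permutation z-map
#'
#' Builds the null by multiplying each subject's entire deviation map by an
#' independent random sign per permutation and recording the across-subject
#' mean map. The z-map is the observed mean map standardized by the mean and
#' standard deviation (n-1 denominator) of the permuted means. Cells with
#' zero permutation spread get z = 0 with a warning.
#'
#' @param stack a `dev_stack` from [center_by_subject()].
#' @param n_perm number of permutations (default 5000).
#' @param seed optional integer seed for the permutation RNG.
#' @return object of class `signflip_z` with `zmap` `[freq, bin]`, the
#'   observed mean map `obs`, and the permutation ensemble.
#' @export
signflip_zmap <- function(stack, n_perm = 5000, seed = NULL) {
  stopifnot(inherits(stack, "dev_stack"), n_perm >= 1)
  S <- dim(stack$dev)[1]
  if (S < 2) stop("sign-flip test requires at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  devm <- dev_matrix(stack)
  signs <- matrix(sample(c(-1, 1), S * n_perm, replace = TRUE), n_perm, S)
  perm_means <- (signs %*% devm) / S
  z <- standardize_by_perms(colMeans(devm), perm_means)
  d <- dim(stack$dev)[2:3]
  structure(list(zmap = matrix(z$z, d[1], d[2]),
                 obs = matrix(z$obs, d[1], d[2]),
                 perm_means = perm_means, perm_mu = z$mu, perm_sd = z$sd,
                 freqs = stack$freqs, times = stack$times,
                 site = stack$site, n_perm = n_perm, seed = seed),
            class = "signflip_z")
}

# Standardize an observed cell vector against the permutation ensemble.
standardize_by_perms <- function(obs, perm_means) {
  n <- nrow(perm_means)
  mu <- colMeans(perm_means)
  sd <- sqrt(pmax(colSums(perm_means^2) - n * mu^2, 0) / (n - 1))
  z <- numeric(length(obs))
  ok <- sd > 0
  if (!all(ok))
    warning("zero permutation spread in ", sum(!ok),
            " cell(s); z set to 0 there")
  z[ok] <- (obs[ok] - mu[ok]) / sd[ok]
  list(z = z, obs = obs, mu = mu, sd = sd)
}

#' Label connected suprathreshold clusters
#'
#' Connected-component labeling of a logical matrix in the frequency-by-time
#' plane, 8-connectivity by default (diagonal neighbors join). Implemented
#' as a union-find merge over neighbor offsets.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 outside clusters, cluster ids
#'   1..k inside.
#' @export
label_clusters <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cells <- which(mask)
  if (!length(cells)) return(lab)
  parent <- seq_along(cells)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx_of <- integer(nr * nc)
  idx_of[cells] <- seq_along(cells)
  pos_r <- (cells - 1L) %% nr + 1L
  pos_c <- (cells - 1L) %/% nr + 1L
  offs <- rbind(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8) offs <- rbind(offs, c(-1L, -1L), c(1L, -1L))
  for (k in seq_len(nrow(offs))) {
    nb_r <- pos_r + offs[k, 1]
    nb_c <- pos_c + offs[k, 2]
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
    nb_lin <- (nb_c - 1L) * nr + nb_r
    ok[ok] <- mask[nb_lin[ok]]
    for (i in which(ok)) {
      a <- find(i)
      b <- find(idx_of[nb_lin[i]])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(cells), find, integer(1))
  lab[cells] <- match(roots, unique(roots))
  lab
}

# Largest cluster size of a logical matrix (0 when empty).
max_cluster_size <- function(mask, connectivity = 8) {
  lab <- label_clusters(mask, connectivity)
  if (!any(lab > 0)) return(0L)
  max(tabulate(lab[lab > 0]))
}

#' Cluster-size correction against a max-cluster-size null
#'
#' Thresholds the z-map two-sided at `qnorm(1 - alpha_cf/2)` (1.96 at the
#' default), labels connected components of the suprathreshold mask
#' (positive and negative cells in the same |z| mask, reported with their
#' signed peaks), and keeps clusters whose size in bins exceeds the given
#' percentile of the null distribution of per-permutation maximum cluster
#' sizes.
#'
#' @param z a `signflip_z` (or comparable) object, or a bare z matrix.
#' @param null_max_sizes numeric vector of per-permutation maximum cluster
#'   sizes, or a function of no arguments producing one. For a `signflip_z`
#'   input the default derives them from the stored permutation ensemble by
#'   applying the identical thresholding/labeling to every permuted mean
#'   map's z-map.
#' @param alpha_cf two-sided cluster-forming alpha (default 0.05).
#' @param percentile percentile of null max sizes used as the size threshold
#'   (default 97.5).
#' @param connectivity 8 (default) or 4.
#' @return object of class `cluster_test`.
#' @export
cluster_correct <- function(z, null_max_sizes = NULL, alpha_cf = 0.05,
                            percentile = 97.5, connectivity = 8) {
  if (inherits(z, "signflip_z") || (is.list(z) && !is.null(z$zmap))) {
    zmap <- z$zmap
    obs <- z$obs
    freqs <- z$freqs
    times <- z$times
    site <- z$site
    if (is.null(null_max_sizes))
      null_max_sizes <- perm_max_sizes(z, alpha_cf, connectivity)
  } else {
    zmap <- as.matrix(z)
    obs <- NULL
    freqs <- seq_len(nrow(zmap))
    times <- seq_len(ncol(zmap))
    site <- NA_character_
  }
  if (is.function(null_max_sizes)) null_max_sizes <- null_max_sizes()
  if (is.null(null_max_sizes) || !length(null_max_sizes))
    stop("no permutations available for the null max-size distribution")
  if (any(!is.finite(zmap))) stop("z-map contains non-finite values")
  cf <- stats::qnorm(1 - alpha_cf / 2)
  mask <- abs(zmap) >= cf
  labels <- label_clusters(mask, connectivity)
  k <- max(labels)
  sizes <- if (k > 0) tabulate(labels[labels > 0], k) else integer(0)
  size_threshold <- as.numeric(stats::quantile(null_max_sizes,
                                               percentile / 100))
  significant <- which(sizes > size_threshold)
  peaks <- cluster_peaks(significant, labels, zmap, obs, freqs, times)
  structure(
    list(site = site, zmap = zmap, obs = obs,
         cluster_forming_threshold = cf, labels = labels,
         cluster_sizes = sizes, null_max_sizes = null_max_sizes,
         size_threshold = size_threshold, significant = significant,
         peaks = peaks, freqs = freqs, times = times,
         alpha_cf = alpha_cf, percentile = percentile,
         connectivity = connectivity),
    class = "cluster_test")
}

# Null max-cluster-size per permutation, from the stored ensemble.
perm_max_sizes <- function(z, alpha_cf, connectivity) {
  cf <- stats::qnorm(1 - alpha_cf / 2)
  ok <- z$perm_sd > 0
  d <- dim(z$zmap)
  vapply(seq_len(nrow(z$perm_means)), function(j) {
    zz <- numeric(length(z$perm_mu))
    zz[ok] <- (z$perm_means[j, ok] - z$perm_mu[ok]) / z$perm_sd[ok]
    max_cluster_size(matrix(abs(zz) >= cf, d[1], d[2]), connectivity)
  }, numeric(1))
}

# Signed peak descriptors for the significant clusters.
cluster_peaks <- function(significant, labels, zmap, obs, freqs, times) {
  rows <- lapply(significant, function(id) {
    cells <- which(labels == id)
    peak <- cells[which.max(abs(zmap[cells]))]
    fr <- (peak - 1L) %% nrow(zmap) + 1L
    tc <- (peak - 1L) %/% nrow(zmap) + 1L
    data.frame(cluster = id, size = sum(labels == id),
               peak_db = if (is.null(obs)) NA_real_ else obs[peak],
               freq = freqs[fr], time = times[tc], z = zmap[peak],
               p = 2 * stats::pnorm(-abs(zmap[peak])))
  })
  if (!length(rows))
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak_db = numeric(0), freq = numeric(0),
                      time = numeric(0), z = numeric(0), p = numeric(0)))
  do.call(rbind, rows)
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> site %s: |z| >= %.2f, %d cluster(s), size threshold %.1f (%gth pct of %d perms)\n",
    x$site, x$cluster_forming_threshold, length(x$cluster_sizes),
    x$size_threshold, x$percentile, length(x$null_max_sizes)))
  if (nrow(x$peaks)) {
    cat("  significant clusters:\n")
    for (i in seq_len(nrow(x$peaks)))
      cat(sprintf(
        "    #%d: %d bins, peak %+.2f dB at %.2f Hz / %g ms (z = %.2f, p = %.3g)\n",
        x$peaks$cluster[i], x$peaks$size[i], x$peaks$peak_db[i],
        x$peaks$freq[i], x$peaks$time[i], x$peaks$z[i], x$peaks$p[i]))
  } else cat("  no significant clusters\n")
  invisible(x)
}

#' Within-group cluster permutation test across stimulation sites
#'
#' Composition of [center_by_subject()], [signflip_zmap()] and
#' [cluster_correct()], run independently per stimulation site. The null
#' max-cluster-size distribution is computed from the same sign-flip
#' permutations as the z-map.
#'
#' @param roi a `roi_maps` object (one group).
#' @param n_perm permutations (default 5000).
#' @param seed integer seed; site tests draw from one stream seeded here.
#' @param alpha_cf,percentile,connectivity see [cluster_correct()].
#' @param freq,time optional closed ranges restricting the tested map.
#' @return named list of `cluster_test`, one per site
#'   (class `cluster_test_set`).
#' @export
within_group_test <- function(roi, n_perm = 5000, seed = NULL,
                              alpha_cf = 0.05, percentile = 97.5,
                              connectivity = 8, freq = NULL, time = NULL) {
  stopifnot(inherits(roi, "roi_maps"))
  roi <- subset_roi_maps(roi, freq, time)
  stacks <- center_by_subject(roi)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(stacks, function(st) {
    z <- signflip_zmap(st, n_perm = n_perm, seed = NULL)
    res <- cluster_correct(z, alpha_cf = alpha_cf, percentile = percentile,
                           connectivity = connectivity)
    res$seed <- seed
    res
  })
  structure(out, class = "cluster_test_set")
}

#' @export
print.cluster_test_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Between-group cluster permutation test
#'
#' Both groups are first mean-centered per subject across sites; the observed
#' statistic at each site is the group difference (A minus B) of the mean
#' deviation maps. The null reassigns subjects to groups at random preserving
#' group sizes; z-maps and cluster correction are as in the within-group
#' test.
#'
#' @param roi_a,roi_b `roi_maps` of the two groups on a common grid.
#' @inheritParams within_group_test
#' @return named list of `cluster_test`, one per site
#'   (class `cluster_test_set`).
#' @export
between_group_test <- function(roi_a, roi_b, n_perm = 5000, seed = NULL,
                               alpha_cf = 0.05, percentile = 97.5,
                               connectivity = 8, freq = NULL, time = NULL) {
  stopifnot(inherits(roi_a, "roi_maps"), inherits(roi_b, "roi_maps"))
  roi_a <- subset_roi_maps(roi_a, freq, time)
  roi_b <- subset_roi_maps(roi_b, freq, time)
  if (!isTRUE(all.equal(roi_a$freqs, roi_b$freqs)) ||
      !isTRUE(all.equal(roi_a$times, roi_b$times)) ||
      !identical(roi_a$sites, roi_b$sites))
    stop("the two groups are not on a common grid / site set")
  na <- length(roi_a$subjects); nb <- length(roi_b$subjects)
  if (na < 2 || nb < 2) stop("each group needs at least 2 subjects")
  stacks_a <- center_by_subject(roi_a)
  stacks_b <- center_by_subject(roi_b)
  if (!is.null(seed)) set.seed(seed)
  d <- c(length(roi_a$freqs), length(roi_a$times))
  # sites are tested independently; shuffles draw from one seeded stream
  out <- lapply(seq_along(roi_a$sites), function(i) {
    devm <- rbind(dev_matrix(stacks_a[[i]]), dev_matrix(stacks_b[[i]]))
    obs <- colMeans(devm[seq_len(na), , drop = FALSE]) -
      colMeans(devm[na + seq_len(nb), , drop = FALSE])
    perm_means <- matrix(0, n_perm, ncol(devm))
    for (j in seq_len(n_perm)) {
      ia <- sample.int(na + nb, na)
      perm_means[j, ] <- colMeans(devm[ia, , drop = FALSE]) -
        colMeans(devm[-ia, , drop = FALSE])
    }
    z <- standardize_by_perms(obs, perm_means)
    zobj <- structure(list(zmap = matrix(z$z, d[1], d[2]),
                           obs = matrix(z$obs, d[1], d[2]),
                           perm_means = perm_means, perm_mu = z$mu,
                           perm_sd = z$sd, freqs = roi_a$freqs,
                           times = roi_a$times, site = roi_a$sites[i],
                           n_perm = n_perm, seed = seed),
                      class = "signflip_z")
    res <- cluster_correct(zobj, alpha_cf = alpha_cf,
                           percentile = percentile,
                           connectivity = connectivity)
    res$seed <- seed
    res
  })
  names(out) <- roi_a$sites
  structure(out, class = "cluster_test_set")
}
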