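make_stack <- function(devm, nf, nt, site = "lDLPFC") {
  structure(list(dev = array(devm, c(nrow(devm), nf, nt)),
                 subjects = paste0("S", seq_len(nrow(devm))),
                 site = site, freqs = seq_len(nf),
                 times = seq(0, by = 20, length.out = nt)),
            class = "dev_stack")
}

test_that("per-subject centering removes the across-site mean exactly", {
  nf <- 3; nt <- 4
  mk_roi <- function(vals) {
    # vals: subjects x sites scalar maps
    arr <- array(0, c(nrow(vals), ncol(vals), nf, nt),
                 dimnames = list(paste0("S", seq_len(nrow(vals))),
                                 paste0("site", seq_len(ncol(vals))),
                                 NULL, NULL))
    for (s in seq_len(nrow(vals))) for (st in seq_len(ncol(vals)))
      arr[s, st, , ] <- vals[s, st]
    structure(list(power = arr, freqs = seq_len(nf),
                   times = seq(0, by = 20, length.out = nt),
                   subjects = rownames(arr), sites = colnames(arr),
                   group = "HC"), class = "roi_maps")
  }
  # identical maps across sites -> zero deviations
  d0 <- center_by_subject(mk_roi(cbind(c(1, 2), c(1, 2), c(1, 2))))
  expect_true(all(vapply(d0, function(s) max(abs(s$dev)), 1) == 0))
  # two sites a, b -> deviations (a-b)/2 and (b-a)/2
  d2 <- center_by_subject(mk_roi(cbind(5, 1)))
  expect_equal(as.numeric(d2[[1]]$dev[1, , ]), rep(2, nf * nt))
  expect_equal(as.numeric(d2[[2]]$dev[1, , ]), rep(-2, nf * nt))
  # three sites (3, 1, -1) -> (2, 0, -2)
  d3 <- center_by_subject(mk_roi(cbind(3, 1, -1)))
  expect_equal(unique(as.numeric(d3[[1]]$dev)), 2)
  expect_equal(unique(as.numeric(d3[[2]]$dev)), 0)
  expect_equal(unique(as.numeric(d3[[3]]$dev)), -2)
  # centering conservation on random maps: site-sum of deviations is zero
  set.seed(4)
  arr <- array(rnorm(5 * 3 * nf * nt), c(5, 3, nf, nt),
               dimnames = list(paste0("S", 1:5), paste0("site", 1:3),
                               NULL, NULL))
  roi <- structure(list(power = arr, freqs = 1:nf,
                        times = seq(0, by = 20, length.out = nt),
                        subjects = rownames(arr), sites = colnames(arr),
                        group = "HC"), class = "roi_maps")
  dd <- center_by_subject(roi)
  total <- Reduce(`+`, lapply(dd, function(s) s$dev))
  expect_lt(max(abs(total)), 1e-12)
})

test_that("sign-flip z matches the exhaustive enumeration oracle", {
  # scalar case n = 3, deviations (1, 2, 3): closed-form enumeration
  devm <- matrix(c(1, 2, 3), 3, 1)
  z_exact <- enum_signflip_z(devm)
  # by hand: the 8 permutation means are (+-1 +-2 +-3)/3 with mean 0 and
  # population sd sqrt(14)/3; observed mean 2 -> z = 6/sqrt(14)
  expect_equal(as.numeric(z_exact), 6 / sqrt(14))
  st <- make_stack(devm, 1, 1)
  z_mc <- signflip_zmap(st, n_perm = 5000, seed = 42)
  se <- sqrt((1 + z_exact^2 / 2) / 5000)
  expect_lt(abs(z_mc$zmap[1, 1] - z_exact), 3 * se)

  # map-valued case, n = 8 subjects, 4x5 maps
  set.seed(77)
  n <- 8
  devm2 <- matrix(rnorm(n * 20, mean = 0.3), n, 20)
  z_exact2 <- enum_signflip_z(devm2)
  st2 <- make_stack(devm2, 4, 5)
  z_mc2 <- signflip_zmap(st2, n_perm = 5000, seed = 7)
  se2 <- sqrt((1 + z_exact2^2 / 2) / 5000)
  expect_true(all(abs(as.numeric(z_mc2$zmap) - z_exact2) < 3 * se2))

  # all-zero deviations -> z all zero via the zero-spread rule
  expect_warning(z0 <- signflip_zmap(make_stack(matrix(0, 4, 1), 1, 1),
                                     n_perm = 50, seed = 1), "zero")
  expect_equal(max(abs(z0$zmap)), 0)
  expect_error(signflip_zmap(make_stack(matrix(1, 1, 1), 1, 1), 10),
               "2 subjects")
})

test_that("z-maps are invariant to positive rescaling of the deviations", {
  set.seed(13)
  devm <- matrix(rnorm(6 * 12), 6, 12)
  z1 <- signflip_zmap(make_stack(devm, 3, 4), n_perm = 400, seed = 5)
  z2 <- signflip_zmap(make_stack(37.5 * devm, 3, 4), n_perm = 400, seed = 5)
  expect_equal(z1$zmap, z2$zmap, tolerance = 1e-10)
})

test_that("cluster labeling matches brute-force flood fill on random masks", {
  set.seed(19)
  for (i in 1:100) {
    mask <- matrix(runif(12 * 15) < 0.35, 12, 15)
    expect_true(same_partition(label_clusters(mask, 8),
                               flood_fill_labels(mask, 8)))
  }
  # 4-connectivity variant agrees too
  for (i in 1:20) {
    mask <- matrix(runif(10 * 10) < 0.4, 10, 10)
    expect_true(same_partition(label_clusters(mask, 4),
                               flood_fill_labels(mask, 4)))
  }
  # diagonal-only pattern: one cluster under 8-, two under 4-connectivity
  m <- matrix(FALSE, 2, 2); m[1, 1] <- m[2, 2] <- TRUE
  expect_equal(max(label_clusters(m, 8)), 1L)
  expect_equal(max(label_clusters(m, 4)), 2L)
})

test_that("cluster correction keeps only clusters beyond the null percentile", {
  # sub-threshold map -> no clusters
  flat <- matrix(1, 6, 8)
  res <- cluster_correct(flat, null_max_sizes = rep(3, 100))
  expect_equal(length(res$cluster_sizes), 0)
  expect_equal(length(res$significant), 0)
  # planted 30-bin blob against a null whose 97.5th percentile is 6
  z <- matrix(0, 10, 12)
  z[3:7, 4:9] <- 3                       # 30 suprathreshold bins
  null <- c(rep(2, 95), rep(6, 5))       # 97.5th pct = 6
  res2 <- cluster_correct(z, null_max_sizes = null)
  expect_equal(length(res2$significant), 1)
  expect_equal(res2$cluster_sizes[res2$significant], 30)
  expect_equal(res2$size_threshold, 6)
  # threshold is exceeded strictly: a size-6 cluster is not significant
  z3 <- matrix(0, 10, 12); z3[1, 1:6] <- 3
  expect_equal(length(cluster_correct(z3, null)$significant), 0)
  expect_error(cluster_correct(z, null_max_sizes = numeric(0)), "permutation")
})

test_that("within-group test recovers injected site differentiation", {
  coh <- simulate_cohort(reduced_spec(
    101, n_hc = 12, n_chr = 1, epochs = 40, erp_amp = 0))
  maps <- reduced_maps(coh)
  stacks <- group_roi_stacks(maps)
  res <- within_group_test(stacks$HC, n_perm = 400, seed = 9,
                           time = c(0, 400))
  expect_named(res, c("lDLPFC", "lPPC", "DMPFC"))
  expect_true(nrow(res$lDLPFC$peaks) >= 1)
  expect_gt(res$lDLPFC$peaks$peak_db[which.max(abs(res$lDLPFC$peaks$z))], 0)
  # determinism: same seed, identical result
  res2 <- within_group_test(stacks$HC, n_perm = 400, seed = 9,
                            time = c(0, 400))
  expect_identical(res, res2)
  # invariants on the result object
  for (r in res) {
    expect_length(r$null_max_sizes, 400)
    expect_true(all(r$cluster_sizes[r$significant] > r$size_threshold))
    expect_true(all(abs(r$zmap[r$labels > 0]) >=
                      r$cluster_forming_threshold))
  }
})

test_that("between-group z is null for identical groups and matches the split oracle", {
  set.seed(23)
  nf <- 2; nt <- 5
  mk_roi <- function(devs, group) {
    n <- dim(devs)[1]
    arr <- array(0, c(n, 3, nf, nt),
                 dimnames = list(paste0(group, seq_len(n)),
                                 c("lDLPFC", "lPPC", "DMPFC"), NULL, NULL))
    base <- array(rnorm(n * nf * nt), c(n, nf, nt))
    for (st in 1:3) arr[, st, , ] <- base + devs[, st] # scalar per site
    structure(list(power = arr, freqs = 1:nf,
                   times = seq(0, by = 20, length.out = nt),
                   subjects = rownames(arr),
                   sites = colnames(arr), group = group),
              class = "roi_maps")
  }
  # identical groups (same subjects duplicated): z ~ 0, no clusters
  devs <- cbind(rnorm(6), rnorm(6), rnorm(6))
  a <- mk_roi(devs, "A")
  b <- a; b$group <- "B"
  res <- between_group_test(a, b, n_perm = 300, seed = 3)
  for (r in res) {
    expect_lt(max(abs(r$zmap)), 1.0)
    expect_equal(length(r$significant), 0)
  }
  # 3 + 3 subjects: Monte-Carlo z within 3 SE of the exhaustive-split z
  roi_a <- mk_roi(cbind(rnorm(3, 1), rnorm(3), rnorm(3, -1)), "A")
  roi_b <- mk_roi(cbind(rnorm(3), rnorm(3), rnorm(3)), "B")
  res2 <- between_group_test(roi_a, roi_b, n_perm = 4000, seed = 31)
  sa <- center_by_subject(roi_a)
  sb <- center_by_subject(roi_b)
  for (i in 1:3) {
    devm <- rbind(teposc:::dev_matrix(sa[[i]]),
                  teposc:::dev_matrix(sb[[i]]))
    z_exact <- enum_labelshuffle_z(devm, 3)
    z_mc <- as.numeric(res2[[i]]$zmap)
    se <- sqrt((1 + z_exact^2 / 2) / 4000)
    expect_true(all(abs(z_mc - z_exact) < 4 * se))
  }
  tiny <- mk_roi(cbind(rnorm(1), rnorm(1), rnorm(1)), "A")
  expect_error(between_group_test(tiny, roi_b), "2 subjects")
})
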