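test_that("frequency grid is the 30-step geometric progression", {
  g <- make_freq_grid()
  expect_length(g$frequencies, 30)
  expect_equal(g$frequencies[1], 3)
  expect_equal(g$frequencies[30], 80)
  expect_equal(g$cycles[1], 3)
  expect_equal(g$cycles[30], 10)
  k <- 0:29
  expect_equal(g$frequencies, 3 * (80 / 3)^(k / 29))
  expect_equal(g$cycles, 3 * (10 / 3)^(k / 29))
  # geometric: constant ratio
  expect_equal(diff(log(g$frequencies)), rep(log(80 / 3) / 29, 29))
  expect_equal(g$frequencies[15], 3 * (80 / 3)^(14 / 29))
})

test_that("pulse-window interpolation draws the boundary line and only that", {
  sr <- 2500
  tm <- seq(-100, 100, by = 1000 / sr)
  # linear signal: interpolation is the identity
  lin <- matrix(rep(2 * tm + 1, 2), ncol = 2)
  es <- quick_epochs(lin, sr, t0 = -100)
  out <- interpolate_pulse_window(es)
  expect_equal(out$data, es$data, tolerance = 1e-12)

  # boundary samples carrying the line value = t + 1 (0 at -1 ms, 16 at
  # 15 ms): interior samples follow that line, e.g. ~8 at ~7 ms
  x <- tm + 1
  inner <- tm > -1 & tm < 15
  xa <- x
  xa[inner] <- 99                   # artifact to be removed
  es2 <- quick_epochs(xa, sr, t0 = -100)
  out2 <- interpolate_pulse_window(es2)
  expect_equal(out2$data[1, 1, inner], tm[inner] + 1, tolerance = 1e-9)
  i7 <- which.min(abs(tm - 7))
  expect_equal(out2$data[1, 1, i7], tm[i7] + 1, tolerance = 1e-9)
  expect_equal(out2$data[1, 1, !inner], x[!inner])

  # a confined step artifact is removed entirely, rest untouched
  y <- sin(2 * pi * 7 * tm / 1000)
  ya <- y
  ya[tm > -1 & tm < 15] <- ya[tm > -1 & tm < 15] + 500
  cleaned <- interpolate_pulse_window(quick_epochs(ya, sr, t0 = -100))
  expect_lt(max(abs(cleaned$data[1, 1, inner])), 1.01)
  expect_equal(cleaned$data[1, 1, !inner], y[!inner])

  expect_error(interpolate_pulse_window(es, 15, -1), "smaller")
  expect_error(interpolate_pulse_window(es, -1, 400), "outside")
})

test_that("band-pass meets its gain/attenuation/latency contract", {
  sr <- 1000
  tm <- seq(-2000, 2000, by = 1000 / sr)
  probe <- function(f) {
    es <- quick_epochs(cos(2 * pi * f * tm / 1000), sr, t0 = -2000)
    out <- bandpass(es)$data[1, 1, ]
    mid <- abs(tm) <= 1000
    max(abs(out[mid]))
  }
  # passband [1.25*lo, 0.8*hi]
  for (f in c(3.75, 10, 50, 80))
    expect_true(probe(f) > 0.95 && probe(f) < 1.05)
  # >= 20 dB attenuation at 0.5*lo and 1.5*hi
  expect_lt(probe(1.5), 0.1)
  expect_lt(probe(150), 0.1)
  # DC essentially removed
  dc <- bandpass(quick_epochs(rep(1, length(tm)), sr, t0 = -2000))
  expect_lt(max(abs(dc$data[1, 1, abs(tm) <= 1000])), 0.1)
  # zero phase: the unique peak of a windowed 50 Hz burst moves <= 1 sample
  burst <- exp(-tm^2 / (2 * 40^2)) * cos(2 * pi * 50 * tm / 1000)
  es <- quick_epochs(burst, sr, t0 = -2000)
  out <- bandpass(es)$data[1, 1, ]
  mid <- which(abs(tm) <= 200)
  expect_lte(abs(which.max(out[mid]) - which.max(burst[mid])), 1)
  expect_error(bandpass(es, 3, 600), "Nyquist")
})

test_that("Morlet decomposition localizes, averages power, and is linear", {
  sr <- 500
  tm <- seq(-1000, 1000, by = 1000 / sr)
  g <- make_freq_grid()
  # all-zero epochs -> all-zero power
  z <- morlet_tfr(quick_epochs(matrix(0, length(tm), 3), sr), g)
  expect_equal(max(abs(z$power)), 0)
  # random-phase 6 Hz sinusoid: argmax at the grid frequency nearest 6 Hz
  set.seed(11)
  x <- sapply(runif(8, 0, 2 * pi),
              function(p) sin(2 * pi * 6 * tm / 1000 + p))
  tf <- morlet_tfr(quick_epochs(x, sr), g)
  mid <- which.min(abs(tf$times))
  best <- tf$freqs[which.max(tf$power[, mid, 1])]
  expect_equal(best, g$frequencies[which.min(abs(g$frequencies - 6))])
  # unit sinusoid -> unit power at the carrier
  expect_equal(max(tf$power[, mid, 1]), 1, tolerance = 0.05)
  # opposite-phase epochs: power averaging, not amplitude averaging
  s <- sin(2 * pi * 8 * tm / 1000)
  both <- morlet_tfr(quick_epochs(cbind(s, -s), sr), g)
  one <- morlet_tfr(quick_epochs(s, sr), g)
  expect_equal(both$power, one$power, tolerance = 1e-10)
  # doubling amplitude quadruples linear power
  twice <- morlet_tfr(quick_epochs(2 * s, sr), g)
  expect_equal(twice$power, 4 * one$power, tolerance = 1e-10)
  # too-short epoch errors naming the violating frequency
  short <- quick_epochs(matrix(0, 200, 1), sr, t0 = -100)
  expect_error(morlet_tfr(short, g), "3 Hz")
})

test_that("induced power removes the ERP but keeps non-phase-locked bursts", {
  sr <- 500
  tm <- seq(-1000, 1000, by = 1000 / sr)
  g <- make_freq_grid(12)
  erp <- 4 * exp(-(tm - 100)^2 / (2 * 30^2))
  env <- exp(-(tm - 180)^2 / (2 * 80^2))
  set.seed(21)
  x <- sapply(runif(40, 0, 2 * pi), function(p)
    erp + env * cos(2 * pi * 5.5 * tm / 1000 + p))
  es <- quick_epochs(x, sr)
  tot <- morlet_tfr(es, g)
  ind <- induced_tfr(es, g)
  # identical epochs (pure ERP): induced ~ 0
  pure <- quick_epochs(matrix(rep(erp, 10), ncol = 10), sr)
  expect_lt(max(induced_tfr(pure, g)$power), 1e-10)
  # the random-phase burst survives ERP subtraction: induced power at the
  # burst locus matches the total power of the burst alone
  burst_only <- morlet_tfr(quick_epochs(
    sapply(runif(40, 0, 2 * pi),
           function(p) env * cos(2 * pi * 5.5 * tm / 1000 + p)), sr), g)
  bi <- which.min(abs(g$frequencies - 5.5))
  ti <- which.min(abs(tm - 180))
  expect_equal(ind$power[bi, ti, 1], burst_only$power[bi, ti, 1],
               tolerance = 0.2)
  # while total power there is inflated by the phase-locked ERP
  expect_lt(ind$power[bi, ti, 1], 0.6 * tot$power[bi, ti, 1])
  # the ERP signature is strongly reduced at its own locus
  lowf <- which.min(abs(g$frequencies - 4))
  t100 <- which.min(abs(tm - 100))
  expect_lt(ind$power[lowf, t100, 1], 0.6 * tot$power[lowf, t100, 1])
  expect_error(induced_tfr(quick_epochs(matrix(0, length(tm), 1), sr), g),
               "single epoch")
})

test_that("dB normalization is exact and conserves the baseline", {
  sr <- 250
  tm <- seq(-1000, 1000, by = 1000 / sr)
  nfreq <- 5
  p <- array(rep(2, nfreq * length(tm) * 2), c(nfreq, length(tm), 2))
  tf <- teposc:::tf_map(p, freqs = 1:nfreq, times = tm,
                        channels = c("A", "B"))
  # constant power map -> all zeros
  expect_equal(max(abs(db_normalize(tf)$power)), 0)
  # P = 10 x baseline mean -> exactly +10 dB
  p2 <- p
  p2[, 300, ] <- 20
  tf2 <- teposc:::tf_map(p2, freqs = 1:nfreq, times = tm,
                         channels = c("A", "B"))
  db <- db_normalize(tf2)
  expect_equal(db$power[, 300, ], matrix(10, nfreq, 2))
  # normalization conservation: baseline mean of linear ratios is exactly 1
  set.seed(5)
  pr <- array(rexp(nfreq * length(tm)), c(nfreq, length(tm), 1))
  tfr <- teposc:::tf_map(pr, freqs = 1:nfreq, times = tm, channels = "A")
  dbn <- db_normalize(tfr)
  sel <- tm >= -400 & tm <= -200
  ratios <- 10^(dbn$power[, sel, 1] / 10)
  expect_equal(rowMeans(ratios), rep(1, nfreq), tolerance = 1e-12)
  # zero baseline errors
  p0 <- pr; p0[1, , ] <- 0
  expect_error(db_normalize(teposc:::tf_map(p0, 1:nfreq, tm,
                                            channels = "A")), "zero")
})

test_that("temporal binning averages fixed windows and drops the remainder", {
  mk <- function(v, sr = 500) teposc:::tf_map(
    array(rep(v, each = 1), c(1, length(v), 1)),
    freqs = 5, times = (seq_along(v) - 1) / sr * 1000, channels = "A")
  b <- bin_time(mk(c(1, 2, 3, 4)), width = 4)   # 2 samples per bin at 500 Hz
  expect_equal(as.numeric(b$power), c(1.5, 3.5))
  # constant map stays constant
  cb <- bin_time(mk(rep(7, 103)), width = 20)
  expect_true(all(cb$power == 7))
  # bin count = floor(n / samples_per_bin) over random lengths
  set.seed(9)
  for (n in sample(30:400, 8)) {
    bb <- bin_time(mk(seq_len(n)), width = 20)  # 10 samples per bin
    expect_equal(dim(bb$power)[2], floor(n / 10))
  }
  expect_error(bin_time(mk(1:10), width = 1), "smaller")
})

test_that("the fixed pipeline order is normalize-then-bin", {
  # binning and dB conversion do not commute (Jensen); pin the order used
  set.seed(3)
  sr <- 250
  tm <- seq(-1000, 1000, by = 1000 / sr)
  p <- array(rexp(2 * length(tm)) + 0.1, c(2, length(tm), 1))
  tf <- teposc:::tf_map(p, freqs = c(5, 10), times = tm, channels = "A")
  norm_then_bin <- bin_time(db_normalize(tf), 20)
  bin_then_norm <- db_normalize(bin_time(tf, 20))
  expect_gt(max(abs(norm_then_bin$power - bin_then_norm$power)), 1e-6)
  es <- quick_epochs(matrix(rnorm(length(tm) * 3), ncol = 3), sr)
  got <- process_epochs(es, make_freq_grid(8))
  ref <- bin_time(db_normalize(morlet_tfr(bandpass(
    interpolate_pulse_window(es)), make_freq_grid(8))), 20)
  expect_equal(got$power, ref$power)
})

test_that("edge flags stay clear of the analysis windows at default extent", {
  sr <- 250
  tm <- seq(-1000, 1000, by = 1000 / sr)
  es <- quick_epochs(matrix(rnorm(length(tm) * 2), ncol = 2), sr)
  tf <- bin_time(morlet_tfr(es, make_freq_grid()), 20)
  sel <- tf$times >= 20 & tf$times <= 300
  expect_false(any(tf$edges[, sel]))
  base <- tf$times >= -400 & tf$times <= -200
  expect_false(any(tf$edges[, base]))
})
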