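fs <- 7.81
n240 <- ceiling(240 * fs)

test_that("Morlet transform localizes a sinusoid and is linear", {
  t <- (0:(n240 - 1)) / fs
  x <- sin(2 * pi * t / 10)                       # 10-s period
  cw <- morlet_cwt(x, fs)
  peak <- cw$periods_s[which.max(rowMeans(Mod(cw$wave)^2))]
  expect_lt(abs(peak - 10) / 10, 0.10)
  expect_true(min(cw$periods_s) <= 2 && max(cw$periods_s) >= 64)
  # linearity: scaling the amplitude scales |W|
  cw3 <- morlet_cwt(3 * x, fs)
  expect_equal(Mod(cw3$wave), 3 * Mod(cw$wave), tolerance = 1e-9)
  # zero series -> zero transform
  expect_true(all(Mod(morlet_cwt(rep(0, 512), fs)$wave) < 1e-12))
  expect_error(morlet_cwt(c(1, NA, 3, 4), fs), "missing")
  expect_error(morlet_cwt(c(1, 2), fs), "too short")
})

test_that("coherence is bounded, symmetric, self-unity and affine invariant", {
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.8), n240))
  y <- as.numeric(arima.sim(list(ar = 0.8), n240))
  w <- wavelet_coherence(x, y, fs)
  expect_true(all(w$coherence >= 0 & w$coherence <= 1))
  expect_true(!is.unsorted(w$periods_s))
  expect_true(all(w$coi_s > 0))
  # symmetry
  wyx <- wavelet_coherence(y, x, fs)
  expect_equal(w$coherence, wyx$coherence, tolerance = 1e-10)
  # affine rescaling of an input leaves coherence unchanged
  waff <- wavelet_coherence(x, -2.5 * y + 7, fs)
  expect_equal(w$coherence, waff$coherence, tolerance = 1e-8)
  # self-coherence inside the COI
  ws <- apply_coi_mask(wavelet_coherence(x, x, fs))
  expect_gte(min(ws$coherence, na.rm = TRUE), 0.999)
  expect_error(wavelet_coherence(x, y[-1], fs), "length mismatch")
})

test_that("a delayed in-band sinusoid keeps high band coherence", {
  set.seed(4)
  t <- (0:(n240 - 1)) / fs
  x <- sin(2 * pi * 0.1 * t) + 0.05 * rnorm(n240)
  y <- sin(2 * pi * 0.1 * (t - 1)) + 0.05 * rnorm(n240)   # 1-s delay
  ep <- band_epoch_average(wavelet_coherence(x, y, fs))
  expect_gt(mean(ep), 0.9)
})

test_that("independent noise stays below the phase-randomized null", {
  set.seed(5)
  n <- 1024
  x <- rnorm(n); y <- rnorm(n)
  plan <- cwt_plan(n, fs, period_range = band_period_range(c(0.06, 0.15)))
  band_mean <- function(a, b) {
    mean(band_epoch_average(wavelet_coherence(a, b, plan = plan),
                            epoch_len_s = n / fs), na.rm = TRUE)
  }
  # several independent pairs: their typical coherence must sit inside the
  # bulk of the phase-randomized null distribution
  obs <- replicate(5, band_mean(rnorm(n), y))
  null <- replicate(200, band_mean(phase_randomize(x), y))
  expect_lt(median(obs), quantile(null, 0.95))
})

test_that("COI masking drops edge cells, keeps the center, idempotent", {
  set.seed(6)
  x <- rnorm(n240); y <- rnorm(n240)
  w <- wavelet_coherence(x, y, fs)
  m <- apply_coi_mask(w)
  i16 <- which.min(abs(w$periods_s - 16))
  expect_true(is.na(m$coherence[i16, 1]))               # edge: COI ~ 0
  expect_false(is.na(m$coherence[i16, round(n240 / 2)])) # center: COI >> 16 s
  expect_identical(apply_coi_mask(m)$coherence, m$coherence)
})

test_that("band-epoch averages equal the brute-force masked mean", {
  set.seed(7)
  x <- rnorm(n240); y <- rnorm(n240)
  w <- wavelet_coherence(x, y, fs)
  got <- band_epoch_average(w)
  expect_length(got, 8L)
  # independent masked mean over the raw spectrum array
  freq <- 1 / w$periods_s
  keep_scale <- freq >= 0.06 & freq <= 0.15
  expected <- numeric(8)
  for (e in 1:8) {
    acc <- c()
    for (s in which(keep_scale)) {
      for (ti in seq_len(n240)) {
        if (floor((ti - 1) / fs / 30) + 1 == e &&
            w$periods_s[s] <= w$coi_s[ti]) {
          acc <- c(acc, w$coherence[s, ti])
        }
      }
    }
    expected[e] <- mean(acc)
  }
  expect_equal(got, expected, tolerance = 1e-12)
  expect_error(band_epoch_average(w, band_hz = c(4, 5)), "band")

  # spectrum identically 1 inside the COI -> every epoch mean is 1
  w1 <- w; w1$coherence[] <- 1
  expect_equal(band_epoch_average(w1), rep(1, 8))
  # monotone under pointwise dominance
  w2 <- w; w2$coherence <- pmin(w$coherence + 0.1, 1)
  expect_true(all(band_epoch_average(w2) >= band_epoch_average(w)))
})

test_that("dyad coherence has the 16 x 8 structure and handles masks", {
  set.seed(8)
  base <- matrix(rnorm(16 * n240), 16)
  hm <- toy_hb(base, montage = build_default_montage(), dyad_id = "dyadX")
  hc <- toy_hb(base + matrix(rnorm(16 * n240, 0, 0.01), 16),
               montage = build_default_montage(), role = "child",
               dyad_id = "dyadX")
  ct <- dyad_coherence(hm, hc)
  expect_equal(dim(ct$values), c(16L, 8L))
  expect_gt(min(ct$values), 0.99)        # near-identical partners
  # masked channel in either partner -> missing row
  hc$channel_mask[5] <- FALSE
  ct2 <- dyad_coherence(hm, hc)
  expect_true(all(is.na(ct2$values[5, ])))
  expect_false(anyNA(ct2$values[6, ]))
  hm2 <- hm; hm2$channel_mask[] <- FALSE
  expect_error(dyad_coherence(hm2, hc), "no channel retained")
  # long format
  df <- coherence_long(ct)
  expect_equal(nrow(df), 16L * 8L)
  expect_equal(df$wtc[df$channel_id == 2 & df$epoch == 3], ct$values[2, 3])
})

test_that("band-restricted scale grid reproduces the full grid in band", {
  set.seed(9)
  x <- rnorm(n240); y <- rnorm(n240)
  full <- band_epoch_average(wavelet_coherence(x, y, fs))
  red <- band_epoch_average(wavelet_coherence(
    x, y, fs, period_range = band_period_range(c(0.06, 0.15))))
  expect_equal(red, full, tolerance = 2e-2)
})

test_that("imposed coupling raises measured coherence (simulation oracle)", {
  mont <- tiny_montage(2)
  n_seeds <- 8
  wins <- 0
  for (s in seq_len(n_seeds)) {
    hi <- simulate_dyad(simulation_spec(coupling_base = 0.9,
                                        coupling_slope = 0, seed = 100 + s),
                        1, level = "hb", montage = mont)
    lo <- simulate_dyad(simulation_spec(coupling_base = 0,
                                        coupling_slope = 0, seed = 100 + s),
                        2, level = "hb", montage = mont)
    m_hi <- mean(dyad_coherence(hi$mother, hi$child)$values, na.rm = TRUE)
    m_lo <- mean(dyad_coherence(lo$mother, lo$child)$values, na.rm = TRUE)
    wins <- wins + (m_hi > m_lo)
  }
  expect_gte(wins, n_seeds - 1)
})
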