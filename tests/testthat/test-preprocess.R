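make_od <- function(series_list, fs = 7.81) {
  # series_list: list of per-channel series (same for both wavelengths)
  nch <- length(series_list); n <- length(series_list[[1]])
  od <- array(NA_real_, c(2, nch, n))
  for (ch in seq_len(nch)) od[, ch, ] <- rbind(series_list[[ch]],
                                               series_list[[ch]])
  dyadsync:::new_od_series(od, fs, tiny_montage(nch), "mother", "dT",
                           c(760, 850))
}

test_that("intensity to OD follows -log(I/mean) and is scale invariant", {
  n <- 6
  intensity <- array(1, c(2, 2, n))
  intensity[1, 1, ] <- c(exp(-1), rep((6 - exp(-1)) / 5, 5))  # mean exactly 1
  rec <- make_recording(intensity, subject_role = "mother",
                        montage = tiny_montage(2))
  od <- intensity_to_od(rec)
  expect_s3_class(od, "od_series")
  expect_equal(od$od[1, 1, 1], 1)                    # -ln(e^-1 / 1)
  expect_equal(od$od[2, 2, ], rep(0, n))             # constant channel
  # doubling a channel's intensity leaves OD unchanged
  rec2 <- rec; rec2$intensity[1, 1, ] <- 2 * rec$intensity[1, 1, ]
  expect_equal(intensity_to_od(rec2)$od, od$od, tolerance = 1e-12)
})

test_that("MODWT is exactly invertible and motion correction despikes", {
  set.seed(7)
  n <- 512
  x <- sin(2 * pi * 0.1 * (0:(n - 1)) / 7.81) + 0.1 * rnorm(n)
  expect_equal(imodwt(modwt(x)), x, tolerance = 1e-10)
  expect_error(modwt(rnorm(8)), "too short")

  t <- (0:(n - 1)) / 7.81
  clean <- sin(2 * pi * 0.08 * t)
  spiky <- clean; spiky[250] <- spiky[250] + 10
  od_clean <- make_od(list(clean))
  od_spiky <- make_od(list(spiky))

  # spike-free low-frequency signal passes nearly unchanged (small RMS
  # change overall; tight agreement away from the series edges)
  out_clean <- wavelet_motion_correct(od_clean)$od[1, 1, ]
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(out_clean - clean) / rms(clean), 0.05)
  interior <- 40:(n - 40)
  expect_lt(max(abs(out_clean - clean)[interior]), 0.05 * max(abs(clean)))

  # 10x spike suppressed by >= 80%
  out_spiky <- wavelet_motion_correct(od_spiky)$od[1, 1, ]
  resid_before <- max(abs(spiky - clean))
  resid_after <- max(abs(out_spiky - clean))
  expect_lt(resid_after, 0.2 * resid_before)

  # infinite threshold is the identity
  expect_equal(wavelet_motion_correct(od_spiky, iqr_alpha = Inf)$od[1, 1, ],
               spiky, tolerance = 1e-12)

  # masked-out channels are untouched
  od2 <- make_od(list(spiky, spiky))
  od2$channel_mask <- c(TRUE, FALSE)
  out2 <- wavelet_motion_correct(od2)
  expect_equal(out2$od[1, 2, ], spiky, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out2$od[1, 1, ], spiky)))
})

test_that("cardiac QC retains pulsatile channels and masks flat ones", {
  fs <- 7.81; n <- 2048
  t <- (0:(n - 1)) / fs
  set.seed(11)
  cardiac <- sin(2 * pi * 1.0 * t)
  drift <- sin(2 * pi * 0.05 * t)
  noise <- rnorm(n)
  od <- make_od(list(cardiac, drift, noise), fs)
  qc <- cardiac_quality_check(od, power_ratio_min = 0.3)
  expect_true(qc$channel_mask[1])
  expect_false(qc$channel_mask[2])
  # white noise: decision must match the independent Welch oracle
  r_ref <- ref_welch_ratio(noise, fs)
  expect_equal(qc$channel_mask[3], r_ref >= 0.3)
  got <- qc$report$cardiac_power_ratio[qc$report$channel_id == 3][1]
  expect_equal(got, r_ref, tolerance = 1e-10)
  expect_error(cardiac_quality_check(od, cardiac_band_hz = c(0.6, 5)),
               "Nyquist")
})

test_that("band-pass matches its analytic frequency response", {
  fs <- 7.81; n <- 8192
  t <- (0:(n - 1)) / fs
  # analytic |H|^2 of the designed digital filter, evaluated from its
  # coefficients at e^{i omega} (zero-phase doubles the magnitude response)
  flt <- signal::butter(2, c(0.01, 0.5) / (fs / 2), type = "pass")
  h2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(flt$b * z^(0:(length(flt$b) - 1))) /
          sum(flt$a * z^(0:(length(flt$a) - 1))))^2
  }
  amp_of <- function(y, f) {
    keep <- seq(round(n * 0.2), round(n * 0.8))   # interior, no edge effects
    basis <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    co <- coef(lm(y[keep] ~ basis[keep, ] - 1))
    sqrt(sum(co^2))
  }
  # constant input is rejected
  od0 <- make_od(list(rep(3, 256)))
  expect_lt(max(abs(bandpass(od0)$od[1, 1, ])), 1e-8)
  # pass band: 0.1 Hz
  x1 <- sin(2 * pi * 0.1 * t)
  g1 <- amp_of(bandpass(make_od(list(x1), fs))$od[1, 1, ], 0.1)
  expect_gt(g1, 0.95); expect_lt(g1, 1.05)
  expect_equal(g1, h2(0.1), tolerance = 0.01)
  # stop band: 1 Hz, one octave above cutoff
  x2 <- sin(2 * pi * 1.0 * t)
  g2 <- amp_of(bandpass(make_od(list(x2), fs))$od[1, 1, ], 1.0)
  expect_lt(20 * log10(g2), -20)
  expect_equal(g2, h2(1.0), tolerance = 0.01 * h2(1.0) + 1e-4)
  # linearity: response to a sum is the sum of responses
  y12 <- bandpass(make_od(list(x1 + x2), fs))$od[1, 1, ]
  y1 <- bandpass(make_od(list(x1), fs))$od[1, 1, ]
  y2 <- bandpass(make_od(list(x2), fs))$od[1, 1, ]
  expect_equal(y12, y1 + y2, tolerance = 1e-10)
  expect_error(bandpass(make_od(list(x1), fs), low_hz = 0.3, high_hz = 0.1),
               "Nyquist|low_hz|require")
})

test_that("Beer-Lambert conversion is exact on the forward model", {
  set.seed(5)
  nch <- 2; n <- 100
  hbo <- matrix(rnorm(nch * n, 0, 0.5), nch)
  hbr <- matrix(rnorm(nch * n, 0, 0.2), nch)
  for (role in c("mother", "child")) {
    dpf <- DEFAULT_DPF[[role]]
    od_arr <- hb_to_od(hbo, hbr, rep(30, nch), dpf)
    od <- dyadsync:::new_od_series(od_arr, 7.81, tiny_montage(nch), role,
                                   "dT", c(760, 850))
    hb <- od_to_hb(od)
    expect_equal(hb$hbo, hbo, tolerance = 1e-10)
    expect_equal(hb$hbr, hbr, tolerance = 1e-10)
  }
  # zero OD -> zero concentrations
  od0 <- dyadsync:::new_od_series(array(0, c(2, nch, n)), 7.81,
                                  tiny_montage(nch), "mother", "dT",
                                  c(760, 850))
  hb0 <- od_to_hb(od0)
  expect_true(all(hb0$hbo == 0) && all(hb0$hbr == 0))
  # doubling DPF halves concentrations
  od_arr <- hb_to_od(hbo, hbr, rep(30, nch), 6)
  od <- dyadsync:::new_od_series(od_arr, 7.81, tiny_montage(nch), "mother",
                                 "dT", c(760, 850))
  hb2 <- od_to_hb(od, dpf_by_role = c(mother = 12, child = 11))
  expect_equal(hb2$hbo, hbo / 2, tolerance = 1e-10)
  expect_error(od_to_hb(od, extinction = matrix(1, 2, 2)), "singular")
})

test_that("full preprocessing runs in the documented order", {
  spec <- simulation_spec(n_dyads = 1, duration_s = 60, seed = 42)
  rec <- simulate_dyad(spec, 1)$mother
  pp <- preprocess_recording(rec)
  expect_identical(pp$hb$provenance,
                   c("intensity_to_od", "wavelet_motion_correct",
                     "cardiac_quality_check", "bandpass", "od_to_hb"))
  expect_true(all(is.finite(pp$hb$hbo)))
  expect_equal(dim(pp$hb$hbo), dim(pp$hb$hbr))
  expect_equal(nrow(pp$qc_report), 32L)   # 16 channels x 2 wavelengths
})
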