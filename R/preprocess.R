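# Preprocessing: raw intensity -> optical density -> motion correction ->
# heart-band channel QC -> zero-phase Butterworth band-pass -> modified
# Beer-Lambert conversion to HbO/HbR. The stage order is recorded in a
# provenance vector carried on the objects.

new_od_series <- function(od, fs, montage, role, dyad_id, wavelengths_nm,
                          channel_mask = NULL, provenance = character()) {
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, dim(od)[2])
  stopifnot(length(channel_mask) == dim(od)[2])
  structure(
    list(od = od, fs = fs, montage = montage, subject_role = role,
         dyad_id = dyad_id, wavelengths_nm = wavelengths_nm,
         channel_mask = channel_mask, provenance = provenance),
    class = "od_series"
  )
}

#' @export
print.od_series <- function(x, ...) {
  d <- dim(x$od)
  cat(sprintf("<od_series> %s/%s: %d wl x %d ch x %d samples, %d/%d channels retained\n",
              x$dyad_id, x$subject_role, d[1], d[2], d[3],
              sum(x$channel_mask), d[2]))
  cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Convert raw intensity to optical density change
#'
#' OD is the negative natural log of intensity relative to its own temporal
#' mean, per wavelength and channel: `od = -ln(I / mean_t(I))`. Scale-free:
#' rescaling a channel's intensity leaves its OD unchanged.
#'
#' @param rec an `fnirs_recording` with strictly positive intensities.
#' @return An `od_series`.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (any(rec$intensity <= 0)) stop("non-positive intensity")
  d <- dim(rec$intensity)
  mu <- apply(rec$intensity, c(1, 2), mean)           # 2 x nch
  od <- -log(rec$intensity / array(mu, d))            # recycles over samples
  new_od_series(od, rec$fs, rec$montage, rec$subject_role, rec$dyad_id,
                rec$wavelengths_nm, provenance = "intensity_to_od")
}

#' Wavelet-based motion artifact correction
#'
#' Per wavelength and retained channel, the OD series is decomposed with a
#' db5 maximal-overlap discrete wavelet transform; detail coefficients
#' further than `iqr_alpha` times the interquartile range from their level
#' median (motion spikes concentrate there) are zeroed and the series is
#' reconstructed. `iqr_alpha = Inf` is the identity. Masked-out channels are
#' left untouched.
#'
#' @param od an `od_series`.
#' @param iqr_alpha outlier threshold in IQR units (default 1.5).
#' @param n_levels decomposition depth (default: deepest fitting level).
#' @return corrected `od_series`.
#' @export
wavelet_motion_correct <- function(od, iqr_alpha = 1.5, n_levels = NULL) {
  stopifnot(inherits(od, "od_series"))
  n <- dim(od$od)[3]
  if (is.finite(iqr_alpha)) {
    if (modwt_max_level(n) < 1L) {
      stop("series too short for wavelet motion correction")
    }
    for (w in 1:2) {
      for (ch in which(od$channel_mask)) {
        od$od[w, ch, ] <- modwt_despike(od$od[w, ch, ], iqr_alpha, n_levels)
      }
    }
  }
  od$provenance <- c(od$provenance, "wavelet_motion_correct")
  od
}

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlap segment-averaged periodogram.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param nperseg segment length (default `min(256, length(x))`).
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = min(256L, length(x))) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  if (nperseg %% 2L == 0L) {
    psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  } else {
    psd[2:nf] <- 2 * psd[2:nf]
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

#' Heart-band channel quality check
#'
#' A channel with good scalp coupling shows a clear cardiac oscillation.
#' For each channel and wavelength the Welch power inside the cardiac band
#' (default 0.6-1.5 Hz) is divided by the total power over 0.01-3 Hz
#' (truncated at Nyquist); a channel whose ratio falls below
#' `power_ratio_min` at either wavelength is masked out.
#'
#' @param od an `od_series` (pre band-pass).
#' @param cardiac_band_hz numeric length-2 band (Hz).
#' @param power_ratio_min retention threshold on the power ratio.
#' @param total_band_hz denominator band (Hz).
#' @return list with `channel_mask` (logical) and `report` (data frame of
#'   per-channel, per-wavelength ratios and retained flags).
#' @export
cardiac_quality_check <- function(od, cardiac_band_hz = c(0.6, 1.5),
                                  power_ratio_min = 0.2,
                                  total_band_hz = c(0.01, 3)) {
  stopifnot(inherits(od, "od_series"))
  nyq <- od$fs / 2
  if (cardiac_band_hz[2] >= nyq || cardiac_band_hz[1] <= 0) {
    stop("cardiac band outside (0, Nyquist)")
  }
  total_band_hz[2] <- min(total_band_hz[2], nyq * 0.999)
  nc <- dim(od$od)[2]
  rows <- list()
  ratio <- matrix(NA_real_, 2, nc)
  for (w in 1:2) {
    for (ch in seq_len(nc)) {
      p <- welch_psd(od$od[w, ch, ], od$fs)
      inb <- p$freq >= cardiac_band_hz[1] & p$freq <= cardiac_band_hz[2]
      tot <- p$freq >= total_band_hz[1] & p$freq <= total_band_hz[2]
      denom <- sum(p$psd[tot])
      ratio[w, ch] <- if (denom > 0) sum(p$psd[inb & tot]) / denom else 0
    }
  }
  keep <- ratio[1, ] >= power_ratio_min & ratio[2, ] >= power_ratio_min
  report <- data.frame(
    channel_id = rep(od$montage$channels$channel_id, each = 2L),
    wavelength = rep(od$wavelengths_nm, nc),
    cardiac_power_ratio = as.vector(ratio),
    retained = rep(keep, each = 2L)
  )
  list(channel_mask = keep & od$channel_mask, report = report)
}

#' Apply a channel mask from QC to an OD series
#'
#' @param od an `od_series`.
#' @param channel_mask logical vector, typically from
#'   [cardiac_quality_check()].
#' @return masked `od_series` (data untouched; mask intersected).
#' @export
apply_channel_mask <- function(od, channel_mask) {
  stopifnot(inherits(od, "od_series"),
            length(channel_mask) == dim(od$od)[2])
  od$channel_mask <- od$channel_mask & channel_mask
  od$provenance <- c(od$provenance, "cardiac_quality_check")
  od
}

#' Zero-phase Butterworth band-pass filter
#'
#' Second-order Butterworth (12 dB/octave roll-off per pass) applied
#' forward and backward (`signal::filtfilt`), so the effective attenuation
#' is doubled and the phase response is zero -- no lag is introduced
#' between the two partners' series. Masked-out channels are untouched.
#'
#' @param od an `od_series`.
#' @param low_hz,high_hz corner frequencies (defaults 0.01 and 0.5 Hz).
#' @param order filter order (default 2).
#' @return filtered `od_series`.
#' @export
bandpass <- function(od, low_hz = 0.01, high_hz = 0.5, order = 2L) {
  stopifnot(inherits(od, "od_series"))
  nyq <- od$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("require 0 < low_hz < high_hz < Nyquist")
  }
  flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  # demean and mirror-extend: the band-pass rejects DC anyway, and the
  # extension suppresses start-up transients of the forward-backward pass
  zp_filter <- function(x) {
    n <- length(x)
    x <- x - mean(x)
    ext <- c(rev(x), x, rev(x))
    signal::filtfilt(flt, ext)[(n + 1):(2 * n)]
  }
  for (w in 1:2) {
    for (ch in which(od$channel_mask)) {
      od$od[w, ch, ] <- zp_filter(od$od[w, ch, ])
    }
  }
  od$provenance <- c(od$provenance, "bandpass")
  od
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Modified Beer-Lambert law: per channel and sample,
#' `c(dHbO, dHbR) = solve(E) %*% (dOD / (d_cm * DPF))` with `E` the
#' 2x2 extinction matrix (wavelength x chromophore, cm^-1/uM), `d_cm` the
#' source-detector separation in cm and DPF the role-specific differential
#' pathlength factor. Output units are uM.
#'
#' @param od an `od_series`.
#' @param dpf_by_role named vector of differential pathlength factors,
#'   default `c(mother = 6, child = 5.5)`.
#' @param extinction 2x2 extinction matrix; default [default_extinction()].
#' @return An `hb_series` with `hbo` and `hbr` matrices
#'   `[n_channels x n_samples]`.
#' @export
od_to_hb <- function(od, dpf_by_role = DEFAULT_DPF,
                     extinction = default_extinction()) {
  stopifnot(inherits(od, "od_series"))
  if (abs(det(extinction)) < 1e-12) stop("singular extinction matrix")
  dpf <- dpf_by_role[[od$subject_role]]
  if (is.null(dpf) || is.na(dpf)) stop("no DPF for role ", od$subject_role)
  einv <- solve(extinction)
  d <- dim(od$od)
  sep_cm <- od$montage$channels$separation_mm / 10
  hbo <- matrix(NA_real_, d[2], d[3])
  hbr <- matrix(NA_real_, d[2], d[3])
  for (ch in seq_len(d[2])) {
    scaled <- rbind(od$od[1, ch, ], od$od[2, ch, ]) / (sep_cm[ch] * dpf)
    conc <- einv %*% scaled
    hbo[ch, ] <- conc[1, ]
    hbr[ch, ] <- conc[2, ]
  }
  structure(
    list(hbo = hbo, hbr = hbr, fs = od$fs, montage = od$montage,
         subject_role = od$subject_role, dyad_id = od$dyad_id,
         channel_mask = od$channel_mask,
         provenance = c(od$provenance, "od_to_hb")),
    class = "hb_series"
  )
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("<hb_series> %s/%s: %d ch x %d samples @ %.2f Hz, %d retained\n",
              x$dyad_id, x$subject_role, nrow(x$hbo), ncol(x$hbo), x$fs,
              sum(x$channel_mask)))
  cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Runs intensity -> OD -> wavelet motion correction -> heart-band QC ->
#' band-pass -> modified Beer-Lambert law, in that order, and records each
#' step in the provenance.
#'
#' @param rec an `fnirs_recording`.
#' @param params list of parameters; recognised entries `iqr_alpha`,
#'   `cardiac_band_hz`, `power_ratio_min`, `low_hz`, `high_hz`,
#'   `dpf_by_role`, `extinction`, `qc` (set `FALSE` to skip channel QC).
#' @return list with `hb` (`hb_series`) and `qc_report` (data frame or NULL).
#' @export
preprocess_recording <- function(rec, params = list()) {
  p <- utils::modifyList(list(
    iqr_alpha = 1.5, cardiac_band_hz = c(0.6, 1.5), power_ratio_min = 0.2,
    low_hz = 0.01, high_hz = 0.5, dpf_by_role = DEFAULT_DPF,
    extinction = default_extinction(), qc = TRUE
  ), params)
  od <- intensity_to_od(rec)
  od <- wavelet_motion_correct(od, iqr_alpha = p$iqr_alpha)
  qc_report <- NULL
  if (isTRUE(p$qc)) {
    qc <- cardiac_quality_check(od, p$cardiac_band_hz, p$power_ratio_min)
    od <- apply_channel_mask(od, qc$channel_mask)
    qc_report <- qc$report
  }
  od <- bandpass(od, p$low_hz, p$high_hz)
  hb <- od_to_hb(od, dpf_by_role = p$dpf_by_role, extinction = p$extinction)
  list(hb = hb, qc_report = qc_report)
}

#' Forward Beer-Lambert model (simulation/round-trip helper)
#'
#' Maps known HbO/HbR concentration changes (uM) to optical density at both
#' wavelengths for a given separation and DPF -- the exact inverse of
#' [od_to_hb()].
#'
#' @param hbo,hbr matrices `[n_channels x n_samples]` (uM).
#' @param separation_mm per-channel separation (mm).
#' @param dpf differential pathlength factor.
#' @param extinction 2x2 extinction matrix.
#' @return array `[2 x n_channels x n_samples]` of OD changes.
#' @export
hb_to_od <- function(hbo, hbr, separation_mm = rep(30, nrow(hbo)),
                     dpf = 6, extinction = default_extinction()) {
  nc <- nrow(hbo); nt <- ncol(hbo)
  od <- array(NA_real_, c(2L, nc, nt))
  sep_cm <- separation_mm / 10
  for (ch in seq_len(nc)) {
    od[, ch, ] <- extinction %*% rbind(hbo[ch, ], hbr[ch, ]) * (sep_cm[ch] * dpf)
  }
  od
}
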