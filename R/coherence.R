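# Morlet wavelet transform coherence (WTC) between the two partners of a
# dyad. Continuous Morlet transform on a dyadic scale grid, smoothing in
# time (scale-matched Gaussian) and scale (boxcar over 0.6 decorrelation
# lengths), squared coherence clipped to [0,1], cone-of-influence
# exclusion, and band-limited averages over consecutive 30-s epochs.
#
# Internals keep time in rows and scale in columns ([n x n_scales]) so the
# FFT-based smoothing runs column-major without transposes; the public
# spectrum object uses the conventional [n_scales x n] layout.

morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Build a reusable wavelet transform plan
#'
#' Precomputes the zero-padded frequency grid, Morlet daughter filters on a
#' dyadic scale grid, the time- and scale-smoothing operators, Fourier
#' periods and the cone of influence for a given series length. Reusing a
#' plan across channels and surrogate draws avoids recomputing filters.
#'
#' @param n series length in samples.
#' @param fs sampling rate (Hz).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @param dj scale resolution in octaves (default 1/12).
#' @param period_range periods (s) the dyadic scale grid must cover
#'   (default 2 samples to 64 s).
#' @return a `cwt_plan` list.
#' @export
cwt_plan <- function(n, fs, omega0 = 6, dj = 1 / 12, period_range = NULL) {
  dt <- 1 / fs
  ff <- morlet_fourier_factor(omega0)
  s0 <- 2 * dt
  if (is.null(period_range)) period_range <- c(ff * s0, 64)
  s_min <- max(s0, period_range[1] / ff)
  s_max <- period_range[2] / ff
  jmax <- ceiling(log2(s_max / s_min) / dj)
  scales <- s_min * 2^(dj * (0:jmax))
  ns <- length(scales)
  npad <- 2^ceiling(log2(n))
  k <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) * (2 * pi / (npad * dt))
  pos <- k > 0                       # analytic wavelet: positive freqs only
  daughters <- matrix(0, npad, ns)
  norm <- sqrt(2 * pi * scales / dt) * pi^(-1 / 4)
  for (j in seq_len(ns)) {
    daughters[pos, j] <- norm[j] * exp(-0.5 * (scales[j] * k[pos] - omega0)^2)
  }
  gauss <- exp(-0.5 * outer(k^2, scales^2))          # time smoother, freq dom
  m <- max(1L, round(0.6 / dj))                      # scale boxcar bins
  half <- m %/% 2L
  boxcar <- NULL
  if (half >= 1L) {
    boxcar <- matrix(0, ns, ns)
    for (i in seq_len(ns)) {
      lo <- max(1L, i - half); hi <- min(ns, i + half)
      boxcar[lo:hi, i] <- 1 / (hi - lo + 1L)
    }
  }
  dist <- pmin(seq_len(n) - 1L, n - seq_len(n))
  structure(list(
    n = n, npad = npad, fs = fs, dt = dt, omega0 = omega0, dj = dj,
    scales = scales, periods_s = ff * scales,
    coi_s = ff / sqrt(2) * dt * pmax(dist, 1e-8),
    daughters = daughters, gauss = gauss, boxcar = boxcar, k = k
  ), class = "cwt_plan")
}

# CWT in the internal [n x n_scales] layout.
cwt_cols <- function(x, plan) {
  xpad <- c(x - mean(x), numeric(plan$npad - plan$n))
  fhat <- stats::fft(xpad)
  wave <- stats::mvfft(plan$daughters * fhat, inverse = TRUE) / plan$npad
  wave[seq_len(plan$n), , drop = FALSE]
}

# Smoothing operator on a [n x n_scales] field (real or complex).
smooth_cols <- function(field, plan) {
  ns <- ncol(field)
  pad <- matrix(if (is.complex(field)) 0i else 0, plan$npad, ns)
  pad[seq_len(plan$n), ] <- field
  sm <- stats::mvfft(stats::mvfft(pad) * plan$gauss, inverse = TRUE) / plan$npad
  out <- sm[seq_len(plan$n), , drop = FALSE]
  if (!is.complex(field)) out <- Re(out)
  if (!is.null(plan$boxcar)) out <- out %*% plan$boxcar
  out
}

# Per-subject reusable pieces: wave and smoothed autospectrum.
wtc_cache <- function(x, plan) {
  wave <- cwt_cols(x, plan)
  inv_s <- rep(1 / plan$scales, each = plan$n)
  list(wave = wave, sxx = smooth_cols(Mod(wave)^2 * inv_s, plan))
}

# Squared coherence [n x n_scales] from two subject caches.
wtc_r2_from_cache <- function(ca, cb, plan) {
  inv_s <- rep(1 / plan$scales, each = plan$n)
  sxy <- smooth_cols(ca$wave * Conj(cb$wave) * inv_s, plan)
  r2 <- Mod(sxy)^2 / pmax(ca$sxx * cb$sxx, .Machine$double.xmin)
  r2[r2 > 1] <- 1
  r2
}

#' Continuous Morlet wavelet transform
#'
#' Transform on a dyadic scale grid (`s0 = 2/fs`, `dj = 1/12` by default)
#' covering at least 2-64 s Fourier periods; the Fourier period of scale
#' `s` is `4*pi*s / (omega0 + sqrt(2 + omega0^2))`.
#'
#' @param x finite numeric series (length >= 4; no missing values --
#'   interpolate upstream).
#' @param fs sampling rate (Hz); ignored when `plan` is given.
#' @param omega0,dj,period_range see [cwt_plan()].
#' @param plan optional precomputed [cwt_plan()].
#' @return list with complex `wave` `[n_scales x n]`, `scales`,
#'   `periods_s`, `coi_s`, `fs`.
#' @export
morlet_cwt <- function(x, fs = NULL, omega0 = 6, dj = 1 / 12,
                       period_range = NULL, plan = NULL) {
  if (anyNA(x) || any(!is.finite(x))) stop("series contains missing/non-finite values")
  if (length(x) < 4L) stop("series too short for a wavelet transform")
  if (is.null(plan)) {
    if (is.null(fs)) stop("provide fs or a plan")
    plan <- cwt_plan(length(x), fs, omega0, dj, period_range)
  }
  stopifnot(length(x) == plan$n)
  list(wave = t(cwt_cols(x, plan)), scales = plan$scales,
       periods_s = plan$periods_s, coi_s = plan$coi_s, fs = plan$fs)
}

#' Wavelet transform coherence of two series
#'
#' Squared cross-wavelet coherence
#' `R2 = |S(Wxy/s)|^2 / (S(|Wx|^2/s) * S(|Wy|^2/s))` where `S` smooths in
#' time with a Gaussian of standard deviation equal to the scale and in
#' scale with a boxcar spanning 0.6 decorrelation lengths; values clipped
#' to `[0, 1]`.
#'
#' @param x,y equal-length numeric series.
#' @param fs sampling rate (Hz).
#' @param omega0,dj,period_range see [cwt_plan()].
#' @param plan optional precomputed plan.
#' @return a `wtc_spectrum`: list with `coherence` `[n_scales x n]`,
#'   `periods_s`, `coi_s`, `fs`.
#' @export
wavelet_coherence <- function(x, y, fs = NULL, omega0 = 6, dj = 1 / 12,
                              period_range = NULL, plan = NULL) {
  if (length(x) != length(y)) stop("series length mismatch")
  if (is.null(plan)) {
    if (is.null(fs)) stop("provide fs or a plan")
    plan <- cwt_plan(length(x), fs, omega0, dj, period_range)
  }
  r2 <- wtc_r2_from_cache(wtc_cache(x, plan), wtc_cache(y, plan), plan)
  structure(list(coherence = t(r2), periods_s = plan$periods_s,
                 coi_s = plan$coi_s, fs = plan$fs),
            class = "wtc_spectrum")
}

#' @export
print.wtc_spectrum <- function(x, ...) {
  cat(sprintf("<wtc_spectrum> %d scales (%.2f-%.2f s) x %d samples @ %.2f Hz\n",
              length(x$periods_s), min(x$periods_s), max(x$periods_s),
              ncol(x$coherence), x$fs))
  invisible(x)
}

#' Exclude cells outside the cone of influence
#'
#' Cells whose Fourier period exceeds the per-sample cone-of-influence
#' period (the edge-effect region) are set to missing. Idempotent.
#'
#' @param w a `wtc_spectrum`.
#' @return the masked `wtc_spectrum`.
#' @export
apply_coi_mask <- function(w) {
  stopifnot(inherits(w, "wtc_spectrum"))
  outside <- outer(w$periods_s, w$coi_s, `>`)
  w$coherence[outside] <- NA_real_
  w
}

#' Band-limited epoch averages of a coherence spectrum
#'
#' Means of retained (in-band, inside-COI) coherence cells within each
#' consecutive non-overlapping epoch. Epochs with no retained cell are
#' missing.
#'
#' @param w a `wtc_spectrum`.
#' @param band_hz frequency band (Hz), default `c(0.06, 0.15)`.
#' @param epoch_len_s epoch length in seconds (default 30).
#' @param apply_coi apply the COI mask before averaging (default TRUE).
#' @return numeric vector of `floor(duration / epoch_len_s)` epoch means.
#' @export
band_epoch_average <- function(w, band_hz = c(0.06, 0.15), epoch_len_s = 30,
                               apply_coi = TRUE) {
  stopifnot(inherits(w, "wtc_spectrum"))
  freq <- 1 / w$periods_s
  in_band <- freq >= band_hz[1] & freq <= band_hz[2]
  if (!any(in_band)) stop("no wavelet scales inside the requested band")
  if (apply_coi) w <- apply_coi_mask(w)
  sub <- w$coherence[in_band, , drop = FALSE]
  n <- ncol(sub)
  n_epochs <- floor(n / w$fs / epoch_len_s)
  if (n_epochs < 1L) stop("recording shorter than one epoch")
  epoch_of <- floor((seq_len(n) - 1L) / w$fs / epoch_len_s) + 1L
  vapply(seq_len(n_epochs), function(e) {
    cells <- sub[, epoch_of == e, drop = FALSE]
    if (all(is.na(cells))) NA_real_ else mean(cells, na.rm = TRUE)
  }, numeric(1))
}

# Fast internal epoch averaging from the column-major r2 field.
band_epoch_from_cols <- function(r2, plan, band_hz, epoch_len_s) {
  freq <- 1 / plan$periods_s
  in_band <- which(freq >= band_hz[1] & freq <= band_hz[2])
  if (!length(in_band)) stop("no wavelet scales inside the requested band")
  n <- plan$n
  n_epochs <- floor(n / plan$fs / epoch_len_s)
  sub <- r2[, in_band, drop = FALSE]
  sub[outer(plan$coi_s, plan$periods_s[in_band], `<`)] <- NA_real_
  epoch_of <- floor((seq_len(n) - 1L) / plan$fs / epoch_len_s) + 1L
  vapply(seq_len(n_epochs), function(e) {
    cells <- sub[epoch_of == e, , drop = FALSE]
    if (all(is.na(cells))) NA_real_ else mean(cells, na.rm = TRUE)
  }, numeric(1))
}

#' Scale-grid period range adapted to an analysis band
#'
#' Returns the period range covering `band_hz` widened by `margin`
#' scale-smoothing bins on each side -- the smallest dyadic grid on which
#' in-band coherence matches a full 2-64 s grid up to boxcar edge effects.
#'
#' @param band_hz analysis band (Hz).
#' @param dj scale resolution in octaves.
#' @param margin scale-smoothing bins of slack on each side.
#' @return length-2 numeric period range in seconds.
#' @export
band_period_range <- function(band_hz, dj = 1 / 12, margin = 6L) {
  fac <- 2^(margin * dj)
  c((1 / band_hz[2]) / fac, (1 / band_hz[1]) * fac)
}

#' Per-dyad channel x epoch coherence table
#'
#' For each homologous channel retained in both partners' masks, computes
#' wavelet coherence of the chosen chromophore series, applies the
#' cone-of-influence mask and averages within the analysis band over
#' consecutive epochs. Channels masked out in either partner yield missing
#' rows.
#'
#' @param mother_hb,child_hb `hb_series` preprocessed with identical
#'   settings.
#' @param chromophore `"HbO"` (default) or `"HbR"`.
#' @param band_hz analysis band (Hz).
#' @param epoch_len_s epoch length (s).
#' @param omega0,dj wavelet parameters.
#' @param period_range scale coverage; default spans the analysis band plus
#'   a scale-smoothing margin so in-band values equal a full 2-64 s grid.
#' @return a `coherence_table`: list with `dyad_id`, `chromophore`,
#'   `values` `[n_channels x n_epochs]`, `band_hz`, `epoch_len_s`,
#'   `channel_mask`, `montage`.
#' @export
dyad_coherence <- function(mother_hb, child_hb, chromophore = c("HbO", "HbR"),
                           band_hz = c(0.06, 0.15), epoch_len_s = 30,
                           omega0 = 6, dj = 1 / 12, period_range = NULL) {
  chromophore <- match.arg(chromophore)
  stopifnot(inherits(mother_hb, "hb_series"), inherits(child_hb, "hb_series"))
  if (!isTRUE(all.equal(mother_hb$fs, child_hb$fs))) stop("sampling rate mismatch")
  field <- if (chromophore == "HbO") "hbo" else "hbr"
  xm <- mother_hb[[field]]; xc <- child_hb[[field]]
  n <- min(ncol(xm), ncol(xc))
  mask <- mother_hb$channel_mask & child_hb$channel_mask
  if (!any(mask)) stop("no channel retained in both partners")
  fs <- mother_hb$fs
  if (is.null(period_range)) period_range <- band_period_range(band_hz, dj)
  plan <- cwt_plan(n, fs, omega0, dj, period_range)
  n_epochs <- floor(n / fs / epoch_len_s)
  nc <- nrow(xm)
  values <- matrix(NA_real_, nc, n_epochs)
  for (ch in which(mask)) {
    r2 <- wtc_r2_from_cache(wtc_cache(xm[ch, seq_len(n)], plan),
                            wtc_cache(xc[ch, seq_len(n)], plan), plan)
    values[ch, ] <- band_epoch_from_cols(r2, plan, band_hz, epoch_len_s)
  }
  structure(list(
    dyad_id = mother_hb$dyad_id, chromophore = chromophore, values = values,
    band_hz = band_hz, epoch_len_s = epoch_len_s, channel_mask = mask,
    montage = mother_hb$montage
  ), class = "coherence_table")
}

#' @export
print.coherence_table <- function(x, ...) {
  cat(sprintf("<coherence_table> %s %s: %d channels x %d epochs, mean WTC %.3f\n",
              x$dyad_id, x$chromophore, nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Long-format data frame of a coherence table (the TSV layout)
#'
#' @param x a `coherence_table`.
#' @return data frame with dyad_id, chromophore, channel_id, roi, epoch, wtc.
#' @export
coherence_long <- function(x) {
  stopifnot(inherits(x, "coherence_table"))
  nc <- nrow(x$values); ne <- ncol(x$values)
  data.frame(
    dyad_id = x$dyad_id, chromophore = x$chromophore,
    channel_id = rep(x$montage$channels$channel_id, ne),
    roi = rep(x$montage$channels$roi, ne),
    epoch = rep(seq_len(ne), each = nc),
    wtc = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}

# Shared fast path for cohorts: coherence of arbitrary mother-child index
# pairs with per-channel subject caching. `pairs` is a data frame with
# columns mother_idx, child_idx. Series are truncated to the cohort-wide
# minimum length. Returns [n_pairs x n_channels x n_epochs].
cohort_pair_coherence <- function(mother_hbs, child_hbs, pairs,
                                  chromophore = "HbO",
                                  band_hz = c(0.06, 0.15), epoch_len_s = 30,
                                  omega0 = 6, dj = 1 / 12,
                                  period_range = NULL) {
  field <- if (chromophore == "HbO") "hbo" else "hbr"
  n <- min(vapply(c(mother_hbs, child_hbs), function(h) ncol(h[[field]]), 1L))
  fs <- mother_hbs[[1]]$fs
  nc <- nrow(mother_hbs[[1]][[field]])
  if (is.null(period_range)) period_range <- band_period_range(band_hz, dj)
  plan <- cwt_plan(n, fs, omega0, dj, period_range)
  n_epochs <- floor(n / fs / epoch_len_s)
  out <- array(NA_real_, c(nrow(pairs), nc, n_epochs))
  for (ch in seq_len(nc)) {
    m_need <- unique(pairs$mother_idx[vapply(
      pairs$mother_idx, function(i) mother_hbs[[i]]$channel_mask[ch], TRUE)])
    c_need <- unique(pairs$child_idx[vapply(
      pairs$child_idx, function(i) child_hbs[[i]]$channel_mask[ch], TRUE)])
    m_cache <- stats::setNames(vector("list", length(m_need)), m_need)
    for (i in m_need) {
      m_cache[[as.character(i)]] <-
        wtc_cache(mother_hbs[[i]][[field]][ch, seq_len(n)], plan)
    }
    c_cache <- stats::setNames(vector("list", length(c_need)), c_need)
    for (i in c_need) {
      c_cache[[as.character(i)]] <-
        wtc_cache(child_hbs[[i]][[field]][ch, seq_len(n)], plan)
    }
    for (p in seq_len(nrow(pairs))) {
      mi <- pairs$mother_idx[p]; ci <- pairs$child_idx[p]
      if (!mother_hbs[[mi]]$channel_mask[ch] ||
          !child_hbs[[ci]]$channel_mask[ch]) next
      r2 <- wtc_r2_from_cache(m_cache[[as.character(mi)]],
                              c_cache[[as.character(ci)]], plan)
      out[p, ch, ] <- band_epoch_from_cols(r2, plan, band_hz, epoch_len_s)
    }
  }
  out
}
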