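# Seeded synthetic dyads with known coupling structure. Each partner's HbO
# mixes a shared narrowband (0.06-0.15 Hz) oscillation -- weighted by an
# epoch-varying coupling kappa -- with private narrowband noise, cardiac
# and respiratory oscillations, slow drift, white noise and sparse motion
# spikes; HbR is anti-correlated with HbO. Intensities come from the
# forward Beer-Lambert model so the whole preprocessing path is exercised.

#' Construct a simulation specification
#'
#' Defaults emulate the study conditions: 4-min dyadic recordings at
#' 7.81 Hz with a coupled hemodynamic component inside 0.06-0.15 Hz,
#' cardiac (~1 Hz mother, ~1.2 Hz child), respiratory (~0.25 Hz, outside
#' the analysis band), drift, white noise and occasional motion spikes.
#' Amplitudes are in uM of HbO equivalent.
#'
#' @param n_dyads number of dyads (cohort-level simulation).
#' @param duration_s recording length in seconds (default 240).
#' @param fs sampling rate (default 7.81 Hz).
#' @param coupling_base baseline shared-signal weight kappa in `[0, 1]`.
#' @param coupling_slope additive change of kappa per epoch (centered on
#'   the mid-epoch).
#' @param behavior_link effect (per SD of the dyad turn-taking target) on
#'   the per-dyad coupling slope; positive values make high-turn-taking
#'   dyads gain coherence over epochs.
#' @param amp named list of component amplitudes (uM): `band`, `cardiac`,
#'   `resp`, `drift`, `white`, `spike`, `hbr_noise`.
#' @param spike_rate_per_min expected motion spikes per minute.
#' @param turn_rate_mean,turn_rate_sd cohort distribution of the per-dyad
#'   turn-taking target (utterance pairs per 4 min).
#' @param epoch_len_s epoch length used for the kappa schedule (default 30).
#' @param seed master seed; all generators are pure functions of
#'   (spec, seed, dyad index).
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_dyads = 20L, duration_s = 240, fs = 7.81,
                            coupling_base = 0.45, coupling_slope = 0.01,
                            behavior_link = 0.02,
                            amp = list(band = 0.3, cardiac = 0.4,
                                       resp = 0.1, drift = 0.2,
                                       white = 0.05, spike = 2,
                                       hbr_noise = 0.05),
                            spike_rate_per_min = 1,
                            turn_rate_mean = 40, turn_rate_sd = 12,
                            epoch_len_s = 30, seed = 1L) {
  amp <- utils::modifyList(list(band = 0.3, cardiac = 0.4, resp = 0.1,
                                drift = 0.2, white = 0.05, spike = 2,
                                hbr_noise = 0.05), amp)
  stopifnot(duration_s > 0, fs > 0,
            coupling_base >= 0, coupling_base <= 1)
  structure(list(
    n_dyads = n_dyads, duration_s = duration_s, fs = fs,
    coupling_base = coupling_base, coupling_slope = coupling_slope,
    behavior_link = behavior_link, amp = amp,
    spike_rate_per_min = spike_rate_per_min,
    turn_rate_mean = turn_rate_mean, turn_rate_sd = turn_rate_sd,
    epoch_len_s = epoch_len_s, seed = as.integer(seed)
  ), class = "simulation_spec")
}

dyad_seed <- function(spec, dyad_index, salt = 0L) {
  as.integer((as.numeric(spec$seed) * 100003 + dyad_index * 257 + salt) %%
               2147483629)
}

# Narrowband noise centered on the analysis band, unit variance.
narrowband_noise <- function(n, fs, band = c(0.06, 0.15)) {
  flt <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(flt, stats::rnorm(n + 400))[201:(n + 200)]
  x / stats::sd(x)
}

kappa_schedule <- function(spec, slope = spec$coupling_slope) {
  ne <- floor(spec$duration_s / spec$epoch_len_s)
  e <- seq_len(ne)
  k <- spec$coupling_base + slope * (e - (ne + 1) / 2)
  if (any(k < 0 | k > 1)) {
    stop("coupling kappa leaves [0,1] after linking; adjust base/slope")
  }
  k
}

#' Simulate one dyad
#'
#' @param spec a `simulation_spec`.
#' @param dyad_index dyad number (enters the derived seed).
#' @param coupling_slope overrides the spec slope (used by
#'   [simulate_cohort()] to impose the behavior link).
#' @param level `"intensity"` returns `fnirs_recording` pairs produced by
#'   the forward Beer-Lambert model; `"hb"` returns the latent `hb_series`
#'   pair directly (fast path for method studies).
#' @param montage probe montage (default [build_default_montage()]).
#' @param global_signal optional numeric series added to every subject's
#'   HbO (a shared exogenous confound, e.g. a cohort-wide 0.1 Hz
#'   component, used to probe the random-pair control).
#' @return list with `mother`, `child` (recordings or `hb_series`) and
#'   `truth` (kappa per epoch, slope, seed).
#' @export
simulate_dyad <- function(spec, dyad_index = 1L,
                          coupling_slope = spec$coupling_slope,
                          level = c("intensity", "hb"),
                          montage = build_default_montage(),
                          global_signal = NULL) {
  level <- match.arg(level)
  kappa <- kappa_schedule(spec, coupling_slope)
  n <- ceiling(spec$duration_s * spec$fs)
  nc <- n_channels(montage)
  fs <- spec$fs
  tt <- (seq_len(n) - 1) / fs
  kap_t <- kappa[pmin(floor(tt / spec$epoch_len_s) + 1L, length(kappa))]
  amp <- spec$amp
  dyad_id <- sprintf("dyad%03d", dyad_index)
  with_seed(dyad_seed(spec, dyad_index), {
    shared <- replicate(nc, narrowband_noise(n, fs))   # n x nc
    make_member <- function(role) {
      f_card <- if (role == "mother") 1.0 else 1.2
      dpf <- DEFAULT_DPF[[role]]
      hbo <- matrix(NA_real_, nc, n)
      hbr <- matrix(NA_real_, nc, n)
      for (ch in seq_len(nc)) {
        private <- narrowband_noise(n, fs)
        band <- amp$band * (kap_t * shared[, ch] +
                              sqrt(pmax(0, 1 - kap_t^2)) * private)
        cardiac <- amp$cardiac * sin(2 * pi * f_card * tt +
                                       stats::runif(1, 0, 2 * pi))
        resp <- amp$resp * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
        rw <- cumsum(stats::rnorm(n))
        drift <- amp$drift * rw / max(stats::sd(rw), 1e-12)
        white <- amp$white * stats::rnorm(n)
        spikes <- numeric(n)
        n_spk <- stats::rpois(1, spec$spike_rate_per_min * spec$duration_s / 60)
        if (n_spk > 0 && amp$spike > 0) {
          pos <- sample.int(n, n_spk, replace = TRUE)
          for (p in pos) {
            len <- min(n - p, round(0.5 * fs))
            if (len < 1) next
            spikes[p:(p + len)] <- spikes[p:(p + len)] +
              amp$spike * sample(c(-1, 1), 1) * exp(-(0:len) / (0.15 * fs))
          }
        }
        hbo[ch, ] <- band + cardiac + resp + drift + white + spikes
        if (!is.null(global_signal)) hbo[ch, ] <- hbo[ch, ] + global_signal
        hbr[ch, ] <- -0.5 * hbo[ch, ] + amp$hbr_noise * stats::rnorm(n)
      }
      if (level == "hb") {
        structure(list(hbo = hbo, hbr = hbr, fs = fs, montage = montage,
                       subject_role = role, dyad_id = dyad_id,
                       channel_mask = rep(TRUE, nc),
                       provenance = "simulated"),
                  class = "hb_series")
      } else {
        od <- hb_to_od(hbo, hbr, montage$channels$separation_mm, dpf)
        make_recording(exp(-od), fs = fs, subject_role = role,
                       dyad_id = dyad_id, montage = montage)
      }
    }
    mother <- make_member("mother")
    child <- make_member("child")
    list(mother = mother, child = child,
         truth = list(dyad_id = dyad_id, kappa = kappa,
                      coupling_slope = coupling_slope,
                      seed = dyad_seed(spec, dyad_index)))
  })
}

#' Simulate a conversation coding log
#'
#' Alternating-renewal utterance process: gaps mostly in the 200-700 ms
#' range with occasional >3000 ms pauses; utterances are coded as
#' alternating or long turns, with relevance/contingency/intrusiveness
#' codes emitted at configured probabilities.
#'
#' @param spec a `simulation_spec`.
#' @param dyad_index dyad number.
#' @param turn_score_target expected turn-taking composite (utterance pairs
#'   per recording); defaults to the spec cohort mean.
#' @param p_codes named probabilities for secondary codes (`relevant`,
#'   `irrelevant`, `contingent`, `noncontingent`, `no_time_for_response`,
#'   `interrupts`, `simultaneous`).
#' @return list with `log` (a `coding_log`) and `scores` (the realized
#'   `dyad_scores`).
#' @export
simulate_conversation <- function(spec, dyad_index = 1L,
                                  turn_score_target = spec$turn_rate_mean,
                                  p_codes = c(relevant = 0.5,
                                              irrelevant = 0.1,
                                              contingent = 0.3,
                                              noncontingent = 0.1,
                                              no_time_for_response = 0.05,
                                              interrupts = 0.08,
                                              simultaneous = 0.04)) {
  dyad_id <- sprintf("dyad%03d", dyad_index)
  with_seed(dyad_seed(spec, dyad_index, salt = 1L), {
    total_ms <- spec$duration_s * 1000
    events <- list()
    if (turn_score_target > 0) {
      # ~2 * target utterances must fit into the recording
      n_utt_target <- max(2, round(2 * turn_score_target))
      cycle <- total_ms / n_utt_target
      t_ms <- stats::runif(1, 0, 300)
      speaker <- sample(c("mother", "child"), 1)
      while (t_ms < total_ms - 300) {
        dur <- max(250, stats::rlnorm(1, log(0.75 * cycle), 0.35))
        dur <- min(dur, total_ms - t_ms - 10)
        alternate <- stats::runif(1) < 0.8
        code <- if (alternate) "alternating_turn" else "long_turn"
        events[[length(events) + 1L]] <-
          data.frame(speaker = speaker, onset_ms = t_ms,
                     offset_ms = t_ms + dur, code = code,
                     stringsAsFactors = FALSE)
        extra <- names(p_codes)[stats::runif(length(p_codes)) < p_codes]
        for (code2 in extra) {
          events[[length(events) + 1L]] <-
            data.frame(speaker = speaker, onset_ms = t_ms,
                       offset_ms = t_ms + dur, code = code2,
                       stringsAsFactors = FALSE)
        }
        gap <- if (stats::runif(1) < 0.05) stats::runif(1, 3200, 6000) else
          stats::runif(1, 200, 700)
        t_ms <- t_ms + dur + gap
        if (alternate) {
          speaker <- if (speaker == "mother") "child" else "mother"
        }
      }
    }
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(speaker = character(), onset_ms = numeric(),
                 offset_ms = numeric(), code = character(),
                 stringsAsFactors = FALSE)
    log <- make_coding_log(dyad_id, ev)
    list(log = log, scores = composite_scores(log))
  })
}

#' Simulate a pipeline-ready cohort
#'
#' Draws each dyad's turn-taking target from the cohort distribution and
#' sets its coupling slope to
#' `coupling_slope + behavior_link * z(turn target)`, so that (for
#' positive `behavior_link`) high-turn-taking dyads gain coherence over
#' epochs. Recordings, coding logs and the ground-truth table are
#' returned together.
#'
#' @param spec a `simulation_spec` with `n_dyads >= 2`.
#' @param level `"intensity"` or `"hb"` (see [simulate_dyad()]).
#' @param global_signal optional shared confound series added to all
#'   subjects (see [simulate_dyad()]).
#' @return list with `dyads` (list of simulate_dyad results), `logs`,
#'   `scores` and `truth` (data frame: dyad_id, turn_target,
#'   realized turn_taking, coupling_slope).
#' @export
simulate_cohort <- function(spec, level = c("intensity", "hb"),
                            global_signal = NULL) {
  level <- match.arg(level)
  if (spec$n_dyads < 2L) stop("cohort needs at least 2 dyads")
  targets <- with_seed(spec$seed, {
    pmax(5, stats::rnorm(spec$n_dyads, spec$turn_rate_mean, spec$turn_rate_sd))
  })
  tz <- zstd(targets)
  slopes <- spec$coupling_slope + spec$behavior_link * tz
  dyads <- vector("list", spec$n_dyads)
  logs <- vector("list", spec$n_dyads)
  scores <- vector("list", spec$n_dyads)
  for (i in seq_len(spec$n_dyads)) {
    dyads[[i]] <- simulate_dyad(spec, i, coupling_slope = slopes[i],
                                level = level, global_signal = global_signal)
    conv <- simulate_conversation(spec, i, turn_score_target = targets[i])
    logs[[i]] <- conv$log
    scores[[i]] <- conv$scores
  }
  truth <- data.frame(
    dyad_id = vapply(dyads, function(d) d$truth$dyad_id, ""),
    turn_target = targets,
    turn_taking = vapply(scores, function(s) s$turn_taking, 1.0),
    coupling_slope = slopes
  )
  list(dyads = dyads, logs = logs, scores = scores, truth = truth,
       spec = spec)
}

#' Simulate an epoch-level model frame from a beta mixed model
#'
#' Generates data directly at the statistical-model level: dyad-level
#' turn-taking scores, linear link-scale predictor with the supplied
#' coefficients, dyad random intercept/slopes, and beta-distributed
#' responses with precision `phi`. Used for parameter-recovery and power
#' studies of the inference module.
#'
#' @param n_dyads,n_channels,n_epochs frame dimensions.
#' @param beta named fixed effects on the logit scale; recognised names
#'   `(Intercept)`, `turn_taking_z`, `time_z`, `turn_taking_z:time_z`.
#' @param phi beta precision.
#' @param sd_intercept dyad random-intercept SD.
#' @param sd_slopes named SDs of uncorrelated dyad slopes (same names as
#'   `beta`, minus the intercept).
#' @param seed integer seed.
#' @return a model frame ready for [fit_beta_mixed()] / [model_ladder()],
#'   with extra ladder columns set to independent noise predictors.
#' @export
simulate_beta_frame <- function(n_dyads = 40L, n_channels = 16L,
                                n_epochs = 8L,
                                beta = c("(Intercept)" = -0.75,
                                         turn_taking_z = 0.05,
                                         time_z = 0.04,
                                         "turn_taking_z:time_z" = 0.10),
                                phi = 30, sd_intercept = 0.3,
                                sd_slopes = c(turn_taking_z = 0.05,
                                              time_z = 0.05,
                                              "turn_taking_z:time_z" = 0.05),
                                seed = 1L) {
  with_seed(seed, {
    tt <- stats::rnorm(n_dyads)
    tt_z <- zstd(tt)
    time_z <- zstd(seq_len(n_epochs))
    b0 <- stats::rnorm(n_dyads, 0, sd_intercept)
    slope <- function(nm) {
      s <- if (nm %in% names(sd_slopes)) sd_slopes[[nm]] else 0
      stats::rnorm(n_dyads, 0, s)
    }
    b_tt <- slope("turn_taking_z"); b_ti <- slope("time_z")
    b_in <- slope("turn_taking_z:time_z")
    g <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
    rows <- expand.grid(channel_id = seq_len(n_channels),
                        epoch = seq_len(n_epochs),
                        dyad = seq_len(n_dyads))
    d <- rows$dyad
    x_tt <- tt_z[d]; x_time <- time_z[rows$epoch]
    eta <- g("(Intercept)") + b0[d] +
      (g("turn_taking_z") + b_tt[d]) * x_tt +
      (g("time_z") + b_ti[d]) * x_time +
      (g("turn_taking_z:time_z") + b_in[d]) * x_tt * x_time
    mu <- stats::plogis(eta)
    y <- stats::rbeta(length(eta), mu * phi, (1 - mu) * phi)
    data.frame(
      dyad_id = sprintf("dyad%03d", d), channel_id = rows$channel_id,
      roi = "sim", epoch = rows$epoch,
      wtc = compress_boundary(pmin(pmax(y, 1e-12), 1 - 1e-12)),
      turn_taking_z = x_tt, time_z = x_time,
      relevance_z = zstd(stats::rnorm(n_dyads))[d],
      contingency_z = zstd(stats::rnorm(n_dyads))[d],
      intrusiveness_z = zstd(stats::rnorm(n_dyads))[d],
      turn_duration_z = zstd(stats::rnorm(n_dyads))[d],
      pairing = "original", stringsAsFactors = FALSE
    )
  })
}
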