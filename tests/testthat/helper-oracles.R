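# Independent reference implementations used as test oracles. These stay
# deliberately naive (single-pass loops, direct formulas, quadrature) and
# share no code with the package internals they check.

# --- events / turns -------------------------------------------------------

toy_log <- function(..., dyad_id = "toy") {
  rows <- list(...)
  ev <- do.call(rbind, lapply(rows, function(r) {
    data.frame(speaker = r[[1]], onset_ms = as.numeric(r[[2]]),
               offset_ms = as.numeric(r[[3]]),
               code = if (length(r) > 3) r[[4]] else "vocalization",
               stringsAsFactors = FALSE)
  }))
  make_coding_log(dyad_id, ev)
}

# Single-pass reference turn segmentation, written directly from the coding
# rules; returns turn count and transition-type counts only.
ref_segment <- function(events, max_gap_ms = 3000, min_gap_ms = 0) {
  if (!nrow(events)) {
    return(list(n_turns = 0L,
                types = c(alternation = 0, overlap = 0,
                          long_pause_break = 0,
                          same_speaker_continuation = 0),
                total_overlap = 0))
  }
  events <- events[order(events$onset_ms, events$offset_ms), ]
  n_turns <- 1L
  types <- c(alternation = 0, overlap = 0, long_pause_break = 0,
             same_speaker_continuation = 0)
  total_overlap <- 0
  spk <- events$speaker[1]; turn_end <- events$offset_ms[1]
  for (i in seq_len(nrow(events))[-1]) {
    gap <- events$onset_ms[i] - turn_end
    if (events$speaker[i] == spk && gap <= max_gap_ms) {
      turn_end <- max(turn_end, events$offset_ms[i])
      next
    }
    n_turns <- n_turns + 1L
    if (events$speaker[i] != spk) {
      if (gap < min_gap_ms) {
        types["overlap"] <- types["overlap"] + 1
        total_overlap <- total_overlap +
          (min(turn_end, events$offset_ms[i]) - events$onset_ms[i])
      } else if (gap <= max_gap_ms) {
        types["alternation"] <- types["alternation"] + 1
      } else {
        types["long_pause_break"] <- types["long_pause_break"] + 1
      }
    } else {
      types["same_speaker_continuation"] <-
        types["same_speaker_continuation"] + 1
    }
    spk <- events$speaker[i]; turn_end <- events$offset_ms[i]
  }
  list(n_turns = n_turns, types = types, total_overlap = total_overlap)
}

# --- beta regression ------------------------------------------------------

# Fixed-effects-only beta regression MLE (logit link), direct optimisation
# of the log-likelihood; the independent check on fit_beta_mixed() when the
# random-effect variance is (near) zero.
ref_beta_mle <- function(y, X) {
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    phi <- exp(par[length(par)])
    mu <- stats::plogis(drop(X %*% beta))
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(rep(0, ncol(X)), log(10))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(beta = opt$par[seq_len(ncol(X))], phi = exp(opt$par[length(opt$par)]),
       loglik = -opt$value)
}

# Intercept-only beta mixed model fit by adaptive Gauss-Hermite quadrature
# over the dyad random intercept (independent of glmmTMB's Laplace path).
ref_beta_agq <- function(y, dyad, n_nodes = 15) {
  gh <- function(n) {   # Hermite nodes/weights via Golub-Welsch
    i <- seq_len(n - 1)
    a <- sqrt(i / 2)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- a; J[cbind(i + 1, i)] <- a
    e <- eigen(J, symmetric = TRUE)
    list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
  }
  q <- gh(n_nodes)
  ids <- unique(dyad)
  logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  nll <- function(par) {
    b0 <- par[1]; phi <- exp(par[2]); sig <- exp(par[3])
    ll <- 0
    for (g in ids) {
      yi <- y[dyad == g]
      lig <- function(u) {   # log integrand: likelihood x N(0, sig^2) prior
        mu <- stats::plogis(b0 + u)
        sum(stats::dbeta(yi, mu * phi, (1 - mu) * phi, log = TRUE)) +
          stats::dnorm(u, 0, sig, log = TRUE)
      }
      # adaptive: recentre/rescale nodes at the per-dyad mode and curvature
      opt <- stats::optimize(lig, c(-5 * sig - 3, 5 * sig + 3), maximum = TRUE)
      u0 <- opt$maximum
      eps <- 1e-4
      h <- -(lig(u0 + eps) - 2 * lig(u0) + lig(u0 - eps)) / eps^2
      h <- max(h, 1e-8)
      sc <- sqrt(2 / h)
      logc <- vapply(seq_along(q$nodes), function(k) {
        u <- u0 + sc * q$nodes[k]
        log(q$weights[k]) + q$nodes[k]^2 + lig(u)
      }, 1.0)
      ll <- ll + log(sc) + logsumexp(logc)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  mu_hat <- mean(y)
  phi_hat <- max(2, mu_hat * (1 - mu_hat) / stats::var(y) - 1)
  sig_hat <- max(0.05, stats::sd(tapply(y, dyad, function(v)
    stats::qlogis(mean(v)))))
  start <- c(stats::qlogis(mu_hat), log(phi_hat), log(sig_hat))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(beta0 = opt$par[1], phi = exp(opt$par[2]), sigma = exp(opt$par[3]),
       loglik = -opt$value)
}

# --- spectra --------------------------------------------------------------

# Direct Welch estimate (Hann, 50% overlap), reimplemented independently.
ref_welch_ratio <- function(x, fs, band = c(0.6, 1.5), total = c(0.01, 3),
                            nperseg = min(256L, length(x))) {
  step <- nperseg %/% 2L
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  nf <- nperseg %/% 2 + 1
  p <- acc[seq_len(nf)]
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  f <- (seq_len(nf) - 1) * fs / nperseg
  total[2] <- min(total[2], fs / 2 * 0.999)
  inb <- f >= band[1] & f <= band[2]
  tot <- f >= total[1] & f <= total[2]
  sum(p[inb & tot]) / sum(p[tot])
}

# --- misc fixtures --------------------------------------------------------

tiny_montage <- function(nch = 2L) {
  make_montage(
    sources = data.frame(source_id = 1:2, label = c("S1", "S2")),
    detectors = data.frame(detector_id = 1:2, label = c("D1", "D2")),
    channels = data.frame(
      channel_id = seq_len(nch),
      source_id = rep_len(1:2, nch), detector_id = rep_len(1:2, nch),
      roi = rep_len(c("dlPFC-L", "TPJ-R"), nch), separation_mm = 30)
  )
}

toy_recording <- function(n = 64, nch = 16, fs = 7.81, role = "mother",
                          dyad_id = "dyadT", seed = 1) {
  set.seed(seed)
  intensity <- array(exp(stats::rnorm(2 * nch * n, 0, 0.01)), c(2, nch, n))
  make_recording(intensity, fs = fs, subject_role = role, dyad_id = dyad_id)
}

# hb_series built directly from matrices (for controlled coherence tests).
toy_hb <- function(hbo, fs = 7.81, role = "mother", dyad_id = "dyadT",
                   montage = NULL, hbr = NULL) {
  nc <- nrow(hbo)
  if (is.null(montage)) montage <- tiny_montage(nc)
  if (is.null(hbr)) hbr <- -0.5 * hbo
  structure(list(hbo = hbo, hbr = hbr, fs = fs, montage = montage,
                 subject_role = role, dyad_id = dyad_id,
                 channel_mask = rep(TRUE, nc), provenance = "test"),
            class = "hb_series")
}
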