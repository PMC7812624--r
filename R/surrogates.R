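# Surrogate null distributions for dyadic coherence: random-pair controls
# (children paired with non-partner mothers) and amplitude-preserving phase
# randomization.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    })
  }
  force(expr)
}

#' Phase-randomized surrogate of a series
#'
#' Replaces the Fourier phases of all positive-frequency bins with i.i.d.
#' uniform(0, 2*pi) draws, enforcing conjugate symmetry; the DC and (for
#' even lengths) Nyquist bins stay real. The amplitude spectrum -- hence
#' mean, variance and autocorrelation -- is preserved exactly.
#'
#' @param x finite numeric series.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return surrogate numeric series of the same length.
#' @export
phase_randomize <- function(x, seed = NULL) {
  if (any(!is.finite(x))) stop("series contains non-finite values")
  with_seed(seed, {
    n <- length(x)
    if (n < 3L) return(x)
    xf <- stats::fft(x)
    half <- if (n %% 2L == 0L) n %/% 2L - 1L else (n - 1L) %/% 2L
    ph <- stats::runif(half, 0, 2 * pi)
    idx <- 2L:(1L + half)
    xf[idx] <- Mod(xf[idx]) * exp(1i * ph)
    xf[n + 2L - idx] <- Conj(xf[idx])
    if (n %% 2L == 0L) {
      k <- n %/% 2L + 1L
      xf[k] <- Mod(xf[k]) * sign(Re(xf[k]) + (Re(xf[k]) == 0))
    }
    Re(stats::fft(xf, inverse = TRUE)) / n
  })
}

new_surrogate_set <- function(kind, values, pairing, n_draws, seed,
                              chromophore, band_hz, epoch_len_s, dyad_ids) {
  child_mean <- NULL
  if (n_draws > 0L) {
    child_mean <- apply(values, c(1, 3, 4), function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  }
  structure(list(
    kind = kind, n_draws = n_draws, seed = seed, values = values,
    pairing = pairing, chromophore = chromophore, band_hz = band_hz,
    epoch_len_s = epoch_len_s, dyad_ids = dyad_ids, child_mean = child_mean
  ), class = "surrogate_set")
}

#' @export
print.surrogate_set <- function(x, ...) {
  cat(sprintf("<surrogate_set> %s: %d dyads x %d draws, mean WTC %.3f (seed %s)\n",
              x$kind, length(x$dyad_ids), x$n_draws,
              if (x$n_draws) mean(x$values, na.rm = TRUE) else NA,
              format(x$seed)))
  invisible(x)
}

#' Random-pair null distribution of dyadic coherence
#'
#' For each child, `n_draws` mothers are sampled uniformly with replacement
#' from the non-matching mothers of the cohort; coherence is computed for
#' every surrogate pairing exactly as for the original dyads. The per-child
#' mean over draws is the chance-synchronization reference level.
#'
#' @param mother_hbs,child_hbs lists of preprocessed `hb_series`, index
#'   i = dyad i (the true partner of child i is mother i).
#' @param n_draws surrogate pairings per child (default 1000).
#' @param seed integer seed for the pairing draw.
#' @param chromophore,band_hz,epoch_len_s,omega0,dj,period_range passed to
#'   the coherence computation (same defaults as [dyad_coherence()]).
#' @return a `surrogate_set` with `values`
#'   `[n_children x n_draws x n_channels x n_epochs]`, the pairing record
#'   and the per-child mean table.
#' @export
random_pair_null <- function(mother_hbs, child_hbs, n_draws = 1000L,
                             seed = 1L, chromophore = "HbO",
                             band_hz = c(0.06, 0.15), epoch_len_s = 30,
                             omega0 = 6, dj = 1 / 12, period_range = NULL) {
  n_m <- length(mother_hbs); n_c <- length(child_hbs)
  if (n_m < 2L) stop("random-pair null needs at least two mothers")
  dyad_ids <- vapply(child_hbs, function(h) h$dyad_id, "")
  if (n_draws == 0L) {
    return(new_surrogate_set("random_pair",
                             array(NA_real_, c(n_c, 0L, 0L, 0L)),
                             data.frame(), 0L, seed, chromophore, band_hz,
                             epoch_len_s, dyad_ids))
  }
  pairing <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_c), function(ci) {
      pool <- setdiff(seq_len(n_m), ci)
      data.frame(child_idx = ci, draw = seq_len(n_draws),
                 mother_idx = sample(pool, n_draws, replace = TRUE))
    }))
  })
  vals <- cohort_pair_coherence(mother_hbs, child_hbs, pairing,
                                chromophore, band_hz, epoch_len_s,
                                omega0, dj, period_range)
  nc <- dim(vals)[2]; ne <- dim(vals)[3]
  values <- array(NA_real_, c(n_c, n_draws, nc, ne))
  for (p in seq_len(nrow(pairing))) {
    values[pairing$child_idx[p], pairing$draw[p], , ] <- vals[p, , ]
  }
  new_surrogate_set("random_pair", values, pairing, n_draws, seed,
                    chromophore, band_hz, epoch_len_s, dyad_ids)
}

#' Phase-randomization null distribution of dyadic coherence
#'
#' Per draw, the mother series of each dyad is replaced by an
#' amplitude-preserving phase-randomized surrogate and coherence with the
#' true child is recomputed. A stricter control than random pairing since
#' each surrogate retains the mother's own spectral content.
#'
#' @param mother_hbs,child_hbs lists of preprocessed `hb_series`.
#' @param n_draws surrogate draws (0 gives an empty, valid set).
#' @param seed integer seed.
#' @param chromophore,band_hz,epoch_len_s,omega0,dj,period_range as in
#'   [random_pair_null()].
#' @return a `surrogate_set` with values
#'   `[n_dyads x n_draws x n_channels x n_epochs]`.
#' @export
phase_randomized_null <- function(mother_hbs, child_hbs, n_draws = 100L,
                                  seed = 1L, chromophore = "HbO",
                                  band_hz = c(0.06, 0.15), epoch_len_s = 30,
                                  omega0 = 6, dj = 1 / 12,
                                  period_range = NULL) {
  n_d <- length(mother_hbs)
  stopifnot(length(child_hbs) == n_d)
  dyad_ids <- vapply(child_hbs, function(h) h$dyad_id, "")
  field <- if (chromophore == "HbO") "hbo" else "hbr"
  if (n_draws == 0L) {
    return(new_surrogate_set("phase_randomized",
                             array(NA_real_, c(n_d, 0L, 0L, 0L)),
                             data.frame(), 0L, seed, chromophore, band_hz,
                             epoch_len_s, dyad_ids))
  }
  n <- min(vapply(c(mother_hbs, child_hbs), function(h) ncol(h[[field]]), 1L))
  fs <- mother_hbs[[1]]$fs
  nc <- nrow(mother_hbs[[1]][[field]])
  if (is.null(period_range)) period_range <- band_period_range(band_hz, dj)
  plan <- cwt_plan(n, fs, omega0, dj, period_range)
  ne <- floor(n / fs / epoch_len_s)
  values <- array(NA_real_, c(n_d, n_draws, nc, ne))
  with_seed(seed, {
    for (ch in seq_len(nc)) {
      c_cache <- vector("list", n_d)
      for (i in seq_len(n_d)) {
        if (mother_hbs[[i]]$channel_mask[ch] &&
            child_hbs[[i]]$channel_mask[ch]) {
          c_cache[[i]] <- wtc_cache(child_hbs[[i]][[field]][ch, seq_len(n)], plan)
        }
      }
      for (d in seq_len(n_draws)) {
        for (i in seq_len(n_d)) {
          if (is.null(c_cache[[i]])) next
          xm <- phase_randomize(mother_hbs[[i]][[field]][ch, seq_len(n)])
          r2 <- wtc_r2_from_cache(wtc_cache(xm, plan), c_cache[[i]], plan)
          values[i, d, ch, ] <- band_epoch_from_cols(r2, plan, band_hz,
                                                     epoch_len_s)
        }
      }
    }
  })
  new_surrogate_set("phase_randomized", values, data.frame(), n_draws, seed,
                    chromophore, band_hz, epoch_len_s, dyad_ids)
}

#' Long-format summary of a surrogate set (the TSV layout)
#'
#' @param s a `surrogate_set`.
#' @return data frame with dyad_id, channel_id, epoch, surrogate_mean,
#'   surrogate_sd, n_draws, kind, seed.
#' @export
surrogate_summary <- function(s) {
  stopifnot(inherits(s, "surrogate_set"))
  if (s$n_draws == 0L) {
    return(data.frame(dyad_id = character(), channel_id = integer(),
                      epoch = integer(), surrogate_mean = numeric(),
                      surrogate_sd = numeric(), n_draws = integer(),
                      kind = character(), seed = integer()))
  }
  d <- dim(s$values)
  sds <- apply(s$values, c(1, 3, 4), function(v) {
    if (sum(!is.na(v)) < 2L) NA_real_ else stats::sd(v, na.rm = TRUE)
  })
  data.frame(
    dyad_id = rep(s$dyad_ids, times = d[3] * d[4]),
    channel_id = rep(rep(seq_len(d[3]), each = d[1]), times = d[4]),
    epoch = rep(seq_len(d[4]), each = d[1] * d[3]),
    surrogate_mean = as.vector(s$child_mean),
    surrogate_sd = as.vector(sds),
    n_draws = s$n_draws, kind = s$kind, seed = s$seed,
    stringsAsFactors = FALSE
  )
}
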