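# Maximal-overlap discrete wavelet transform (MODWT), Daubechies db5,
# circular boundary. Used by the motion-correction step; kept minimal and
# exactly invertible (pyramid algorithm, Percival & Walden style).

# db5 scaling filter (sum = sqrt(2), unit energy)
DB5_SCALING <- c(
  0.1601023979741929, 0.6038292697971896, 0.7243085284377729,
  0.1384281459013207, -0.2422948870663820, -0.0322448695846384,
  0.0775714938400457, -0.0062414902127983, -0.0125807519990820,
  0.0033357252854738
)

modwt_filters <- function() {
  g <- DB5_SCALING
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1) * rev(g)   # quadrature mirror wavelet filter
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)
}

# circularly filter v with filter f upsampled by 2^(j-1):
# out[t] = sum_l f[l] * v[(t - 2^(j-1) * (l-1)) mod N]
circ_filt_down <- function(v, f, j) {
  n <- length(v)
  out <- numeric(n)
  step <- 2^(j - 1)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    out <- out + f[l] * v[((idx0 - step * (l - 1L)) %% n) + 1L]
  }
  out
}

# adjoint direction used by the inverse transform:
# out[t] = sum_l f[l] * v[(t + 2^(j-1) * (l-1)) mod N]
circ_filt_up <- function(v, f, j) {
  n <- length(v)
  out <- numeric(n)
  step <- 2^(j - 1)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    out <- out + f[l] * v[((idx0 + step * (l - 1L)) %% n) + 1L]
  }
  out
}

# Maximum level for which the (upsampled) filter still fits in the series.
modwt_max_level <- function(n, L = 10L) {
  if (n < 2L * L) return(0L)
  floor(log2((n - 1) / (L - 1) + 1))
}

#' MODWT decomposition (db5, circular)
#'
#' @param x numeric series.
#' @param n_levels decomposition depth; default the deepest level whose
#'   equivalent filter fits inside the series.
#' @return list with `W` (list of wavelet/detail coefficient vectors, level
#'   1..J), `V` (level-J scaling coefficients) and `n_levels`.
#' @export
modwt <- function(x, n_levels = NULL) {
  flt <- modwt_filters()
  n <- length(x)
  jmax <- modwt_max_level(n, flt$L)
  if (is.null(n_levels)) n_levels <- jmax
  if (jmax < 1L || n_levels < 1L) {
    stop("series too short for a single wavelet decomposition level")
  }
  n_levels <- min(n_levels, jmax)
  W <- vector("list", n_levels)
  v <- x
  for (j in seq_len(n_levels)) {
    W[[j]] <- circ_filt_down(v, flt$h, j)
    v <- circ_filt_down(v, flt$g, j)
  }
  list(W = W, V = v, n_levels = n_levels)
}

#' Inverse MODWT
#'
#' @param dec decomposition produced by [modwt()].
#' @return reconstructed numeric series.
#' @export
imodwt <- function(dec) {
  flt <- modwt_filters()
  v <- dec$V
  for (j in rev(seq_len(dec$n_levels))) {
    v <- circ_filt_up(dec$W[[j]], flt$h, j) + circ_filt_up(v, flt$g, j)
  }
  v
}

# Per-level outlier shrinkage: detail coefficients further than
# iqr_alpha * IQR from their level median are zeroed; scaling coefficients
# (slow trend) are left untouched. The series is mirror-extended before the
# circular transform so that the wrap-around discontinuity does not itself
# look like an artifact.
modwt_despike <- function(x, iqr_alpha = 1.5, n_levels = NULL) {
  if (!is.finite(iqr_alpha)) return(x)
  n <- length(x)
  ext <- c(x, rev(x))
  dec <- modwt(ext, n_levels)
  for (j in seq_len(dec$n_levels)) {
    w <- dec$W[[j]]
    spread <- stats::IQR(w)
    if (spread > 0) {
      out <- abs(w - stats::median(w)) > iqr_alpha * spread
      w[out] <- 0
      dec$W[[j]] <- w
    }
  }
  imodwt(dec)[seq_len(n)]
}
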