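# Beta-response mixed-effects inference on epoch-level coherence: model
# frame construction, glmmTMB beta-family fits (logit link, ML/Laplace)
# with dyad random intercepts and uncorrelated random slopes, likelihood
# ratio model ladder, link-scale marginal trend contrasts, and the
# original-vs-random-pair comparison.

zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Boundary compression for beta responses: values exactly 0 or 1 are pulled
# inside the open interval by (y*(n-1)+0.5)/n.
compress_boundary <- function(y) {
  n <- length(y)
  at <- y <= 0 | y >= 1
  y[at] <- (y[at] * (n - 1) + 0.5) / n
  y
}

#' Build the epoch-level model frame
#'
#' Joins coherence tables to per-dyad conversation scores, drops missing
#' coherence cells (count recorded in the `n_dropped` attribute),
#' z-standardizes every continuous predictor over the included rows and
#' compresses boundary responses into (0,1).
#'
#' @param coh_list list of `coherence_table` objects (one per dyad).
#' @param scores_list list of `dyad_scores` objects; matched by `dyad_id`.
#' @return data frame with columns dyad_id, channel_id, roi, epoch, wtc,
#'   turn_taking_z, relevance_z, contingency_z, intrusiveness_z,
#'   turn_duration_z, time_z, pairing.
#' @export
build_model_frame <- function(coh_list, scores_list) {
  stopifnot(length(coh_list) >= 1)
  sc_ids <- vapply(scores_list, function(s) s$dyad_id, "")
  rows <- lapply(coh_list, function(ct) {
    df <- coherence_long(ct)
    i <- match(ct$dyad_id, sc_ids)
    if (is.na(i)) stop("no dyad scores for ", ct$dyad_id)
    s <- scores_list[[i]]
    df$turn_taking <- s$turn_taking
    df$relevance <- s$relevance
    df$contingency <- s$contingency
    df$intrusiveness <- s$intrusiveness
    df$turn_duration <- s$mean_turn_duration_ms
    df
  })
  frame <- do.call(rbind, rows)
  n_dropped <- sum(is.na(frame$wtc))
  frame <- frame[!is.na(frame$wtc), , drop = FALSE]
  if (!nrow(frame)) stop("empty join: no non-missing coherence values")
  frame$wtc <- compress_boundary(frame$wtc)
  frame$turn_taking_z <- zstd(frame$turn_taking)
  frame$relevance_z <- zstd(frame$relevance)
  frame$contingency_z <- zstd(frame$contingency)
  frame$intrusiveness_z <- zstd(frame$intrusiveness)
  frame$turn_duration_z <- zstd(frame$turn_duration)
  frame$time_z <- zstd(frame$epoch)
  frame$pairing <- "original"
  rownames(frame) <- NULL
  attr(frame, "n_dropped") <- n_dropped
  frame
}

#' Fit a beta-response mixed model
#'
#' Logit-link beta regression estimated by maximum likelihood (Laplace
#' approximation, via glmmTMB) with a dyad-level random intercept and one
#' uncorrelated dyad-level random slope per requested term.
#'
#' @param frame model frame (response in `(0,1)` in column `wtc`).
#' @param fixed character vector of fixed-effect terms (may include `a:b`
#'   interactions); empty for the intercept-only model.
#' @param random_slopes character vector of terms receiving uncorrelated
#'   dyad-level random slopes (defaults to `fixed`).
#' @param group grouping column for the random effects (default
#'   `"dyad_id"`).
#' @param response response column name (default `"wtc"`).
#' @param random_intercept include the group random intercept (default
#'   TRUE; FALSE gives a plain fixed-effects beta regression, useful at
#'   reduced simulation scales).
#' @return a `beta_mixed_fit`: list with `fixef` (term/estimate/se table),
#'   `vcov`, `phi`, `loglik`, `df`, `n_obs`, `converged`, random-effect
#'   variances `ranef_var`, and the underlying glmmTMB `fit`.
#' @export
fit_beta_mixed <- function(frame, fixed = character(),
                           random_slopes = fixed, group = "dyad_id",
                           response = "wtc", random_intercept = TRUE) {
  needed <- unique(c(unlist(strsplit(c(fixed, random_slopes), ":", fixed = TRUE)),
                     group, response))
  missing_cols <- setdiff(needed, names(frame))
  if (length(missing_cols)) {
    stop("model frame lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  y <- frame[[response]]
  if (any(y <= 0 | y >= 1)) stop("response must lie strictly inside (0,1)")
  rhs <- c("1", fixed,
           if (random_intercept) sprintf("(1 | %s)", group),
           if (length(random_slopes))
             sprintf("(0 + %s | %s)", random_slopes, group))
  form <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(glmmTMB::glmmTMB(
    form, data = frame, family = glmmTMB::beta_family(link = "logit"),
    REML = FALSE
  ))
  est <- glmmTMB::fixef(fit)$cond
  vc <- stats::vcov(fit)$cond
  se <- sqrt(diag(vc))
  ll_obj <- stats::logLik(fit)
  ll <- as.numeric(ll_obj)
  df <- attr(ll_obj, "df")
  # variance components on the boundary make the Hessian non-PD and logLik
  # NA even though the ML objective was attained; fall back to it
  if (!is.finite(ll)) ll <- -as.numeric(fit$fit$objective)
  if (is.null(df) || !is.finite(df)) df <- length(fit$fit$par)
  vcr <- glmmTMB::VarCorr(fit)$cond
  ranef_var <- vapply(vcr, function(m) as.numeric(m[1, 1]), 1.0)
  conv <- isTRUE(fit$fit$convergence == 0)
  pd_hess <- !isTRUE(fit$sdr$pdHess == FALSE)
  structure(list(
    fixef = data.frame(term = names(est), estimate = as.numeric(est),
                       se = as.numeric(se), stringsAsFactors = FALSE),
    vcov = vc, phi = glmmTMB::sigma(fit),
    loglik = ll, df = df,
    n_obs = nrow(frame), converged = conv, pd_hess = pd_hess,
    ranef_var = ranef_var,
    fixed = fixed, random_slopes = random_slopes, group = group,
    frame = frame, fit = fit
  ), class = "beta_mixed_fit")
}

#' @export
print.beta_mixed_fit <- function(x, ...) {
  cat(sprintf("<beta_mixed_fit> logLik %.2f (df %d), phi %.1f, n %d%s\n",
              x$loglik, x$df, x$phi, x$n_obs,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$fixef, row.names = FALSE)
  invisible(x)
}

#' Likelihood ratio test between nested ML fits
#'
#' @param fit_null,fit_full `beta_mixed_fit` objects fit on identical rows,
#'   `fit_null` nested in `fit_full`.
#' @return list with `chi2`, `df` and `p`.
#' @export
lrt <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "beta_mixed_fit"),
            inherits(fit_full, "beta_mixed_fit"))
  if (fit_null$n_obs != fit_full$n_obs) {
    stop("models were fit on different data (n_obs differ)")
  }
  if (fit_full$df < fit_null$df) stop("models are not nested as given")
  chi2 <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  df <- fit_full$df - fit_null$df
  p <- if (df == 0) as.numeric(chi2 < 1e-6) else
    stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

LADDER_TERMS <- list(
  m1 = "turn_taking_z", m2 = "time_z", m3 = "turn_taking_z:time_z",
  m4 = "turn_duration_z", m5 = "relevance_z", m6 = "intrusiveness_z",
  m7 = "contingency_z"
)

#' Sequential model ladder for epoch-level coherence
#'
#' Fits the null (intercept + dyad random intercept) model, then adds in
#' order: turn-taking (Model 1), time (Model 2), their interaction
#' (Model 3), and -- each added to Model 3 -- turn duration (Model 4),
#' relevance (Model 5), intrusiveness (Model 6) and contingency (Model 7).
#' Every added fixed effect brings an uncorrelated dyad-level random slope.
#' Models 1-3 are compared to their predecessor, Models 4-7 to Model 3.
#'
#' @param frame model frame from [build_model_frame()].
#' @param through last model to fit, 0-7 (default 7).
#' @return list with `fits` (named list m0..m7) and `lrts` (data frame:
#'   comparison, chi2, df, p).
#' @export
model_ladder <- function(frame, through = 7L) {
  need <- unique(unlist(strsplit(unlist(LADDER_TERMS[seq_len(through)]),
                                 ":", fixed = TRUE)))
  missing_cols <- setdiff(need, names(frame))
  if (length(missing_cols)) {
    stop("model frame lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  fits <- list(m0 = fit_beta_mixed(frame))
  lrts <- data.frame(comparison = character(), chi2 = numeric(),
                     df = integer(), p = numeric(), stringsAsFactors = FALSE)
  base3 <- c("turn_taking_z", "time_z", "turn_taking_z:time_z")
  for (k in seq_len(through)) {
    name <- paste0("m", k)
    terms_k <- if (k <= 3) unlist(LADDER_TERMS[seq_len(k)]) else
      c(base3, LADDER_TERMS[[k]])
    fits[[name]] <- fit_beta_mixed(frame, fixed = unname(terms_k))
    ref <- if (k <= 3) paste0("m", k - 1) else "m3"
    if (!is.null(fits[[ref]])) {
      t <- lrt(fits[[ref]], fits[[name]])
      lrts[nrow(lrts) + 1L, ] <- list(paste(name, "vs", ref),
                                      t$chi2, t$df, t$p)
    }
  }
  list(fits = fits, lrts = lrts)
}

find_term <- function(fixef, term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  cand <- c(term, if (length(parts) == 2) paste(rev(parts), collapse = ":"))
  i <- which(fixef$term %in% cand)
  if (!length(i)) NA_integer_ else i[1]
}

#' Link-scale marginal trend of a focal predictor at moderator levels
#'
#' For a fit containing `focal`, `moderator` and their interaction, the
#' marginal slope of `focal` at moderator value `m` is
#' `beta_focal + beta_int * m` on the link scale; its standard error comes
#' from the delta method (exact here, the trend being linear in the
#' coefficients). Also returns the between-level difference contrast.
#'
#' @param fit a `beta_mixed_fit`.
#' @param focal focal predictor name (default `"turn_taking_z"`).
#' @param moderator moderator name (default `"time_z"`).
#' @param at named numeric vector of moderator values; default the
#'   early/late means of the fit frame's `time_z` split at the epoch
#'   midpoint.
#' @param level confidence level (default 0.95).
#' @return list with `trends` (data frame: level, moderator_value, trend,
#'   se, lower, upper) and `difference` (last minus first level).
#' @export
trend_contrast <- function(fit, focal = "turn_taking_z",
                           moderator = "time_z", at = NULL, level = 0.95) {
  stopifnot(inherits(fit, "beta_mixed_fit"))
  fe <- fit$fixef
  i_f <- find_term(fe, focal)
  i_x <- find_term(fe, paste(focal, moderator, sep = ":"))
  if (is.na(i_f)) stop("fit lacks focal term ", focal)
  if (is.na(i_x)) stop("fit lacks the ", focal, ":", moderator,
                       " interaction term")
  if (is.null(at)) {
    ep <- fit$frame$epoch
    tz <- fit$frame$time_z
    cut <- stats::median(unique(ep))
    at <- c(early = mean(tz[ep <= cut]), late = mean(tz[ep > cut]))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  V <- fit$vcov
  rows <- lapply(seq_along(at), function(j) {
    m <- at[[j]]
    cvec <- numeric(nrow(fe)); cvec[i_f] <- 1; cvec[i_x] <- m
    tr <- sum(cvec * fe$estimate)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(level = names(at)[j], moderator_value = m, trend = tr,
               se = se, lower = tr - z * se, upper = tr + z * se,
               stringsAsFactors = FALSE)
  })
  trends <- do.call(rbind, rows)
  dm <- at[[length(at)]] - at[[1]]
  dse <- abs(dm) * fe$se[i_x]
  difference <- data.frame(
    contrast = paste(names(at)[length(at)], "-", names(at)[1]),
    estimate = dm * fe$estimate[i_x], se = dse,
    lower = dm * fe$estimate[i_x] - z * dse,
    upper = dm * fe$estimate[i_x] + z * dse, stringsAsFactors = FALSE)
  list(trends = trends, difference = difference)
}

#' Compare original dyads against their random-pair null
#'
#' Stacks the original coherence rows with the per-child surrogate means
#' (pairing indicator: original = 1, random = 0), shares one random
#' intercept per child, and builds the model ladder pairing -> time ->
#' pairing x time with sequential likelihood ratio tests, plus the
#' per-pairing time trends.
#'
#' @param coh_list list of original `coherence_table` objects.
#' @param surrogate a `surrogate_set` with `n_draws > 0` on the same epoch
#'   grid.
#' @return list with `fits` (p0..p3), `lrts`, `trends` (time trend within
#'   each pairing level) and the stacked `frame`.
#' @export
pairing_comparison <- function(coh_list, surrogate) {
  stopifnot(inherits(surrogate, "surrogate_set"))
  if (surrogate$n_draws == 0L) stop("surrogate set contains no draws")
  orig <- do.call(rbind, lapply(coh_list, coherence_long))
  orig$pairing <- "original"
  sm <- surrogate_summary(surrogate)
  surr <- data.frame(dyad_id = sm$dyad_id, chromophore = orig$chromophore[1],
                     channel_id = sm$channel_id, roi = NA_character_,
                     epoch = sm$epoch, wtc = sm$surrogate_mean,
                     pairing = "random", stringsAsFactors = FALSE)
  frame <- rbind(orig[names(surr)], surr)
  frame <- frame[!is.na(frame$wtc), , drop = FALSE]
  if (!nrow(frame)) stop("no non-missing rows to compare")
  frame$wtc <- compress_boundary(frame$wtc)
  frame$pairing_orig <- as.numeric(frame$pairing == "original")
  frame$time_z <- zstd(frame$epoch)
  fits <- list(p0 = fit_beta_mixed(frame))
  steps <- list(p1 = "pairing_orig", p2 = "time_z",
                p3 = "pairing_orig:time_z")
  lrts <- data.frame(comparison = character(), chi2 = numeric(),
                     df = integer(), p = numeric(), stringsAsFactors = FALSE)
  acc <- character()
  prev <- "p0"
  for (nm in names(steps)) {
    acc <- c(acc, steps[[nm]])
    fits[[nm]] <- fit_beta_mixed(frame, fixed = acc)
    t <- lrt(fits[[prev]], fits[[nm]])
    lrts[nrow(lrts) + 1L, ] <- list(paste(nm, "vs", prev), t$chi2, t$df, t$p)
    prev <- nm
  }
  trends <- trend_contrast(fits$p3, focal = "time_z",
                           moderator = "pairing_orig",
                           at = c(random = 0, original = 1))
  list(fits = fits, lrts = lrts, trends = trends, frame = frame)
}
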