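test_that("model frame standardizes, compresses boundaries and counts rows", {
  co <- list()
  sc <- list()
  set.seed(51)
  for (i in 1:3) {
    vals <- matrix(runif(16 * 8, 0.05, 0.95), 16, 8)
    co[[i]] <- structure(list(
      dyad_id = paste0("d", i), chromophore = "HbO", values = vals,
      band_hz = c(0.06, 0.15), epoch_len_s = 30,
      channel_mask = rep(TRUE, 16), montage = build_default_montage()),
      class = "coherence_table")
    log <- toy_log(list("mother", 0, 900), list("child", 1100, 2000),
                   dyad_id = paste0("d", i))
    log$events$code <- "alternating_turn"
    sc[[i]] <- composite_scores(log)
    sc[[i]]$turn_taking <- i * 3   # distinct dyad scores
  }
  fr <- build_model_frame(co, sc)
  expect_equal(nrow(fr), 3 * 16 * 8)
  for (col in c("turn_taking_z", "time_z")) {
    expect_lt(abs(mean(fr[[col]])), 1e-10)
    expect_lt(abs(sd(fr[[col]]) - 1), 1e-10)
  }
  expect_equal(attr(fr, "n_dropped"), 0L)
  # boundary compression
  co[[1]]$values[1, 1] <- 1; co[[1]]$values[2, 1] <- 0
  co[[2]]$values[3, 4] <- NA
  fr2 <- build_model_frame(co, sc)
  n <- nrow(fr2)
  expect_equal(max(fr2$wtc), (1 * (n - 1) + 0.5) / n)
  expect_equal(min(fr2$wtc), 0.5 / n)
  expect_equal(attr(fr2, "n_dropped"), 1L)
  expect_equal(nrow(fr2), 3 * 16 * 8 - 1)
  # y = 1 with n = 100 -> 0.995 (compression formula)
  expect_equal(dyadsync:::compress_boundary(c(rep(0.5, 99), 1))[100], 0.995)
})

test_that("beta mixed fit matches the plain MLE when variance is zero", {
  set.seed(52)
  n_dyads <- 12; n_obs <- 30
  d <- rep(seq_len(n_dyads), each = n_obs)
  x <- rnorm(n_dyads * n_obs)
  mu <- plogis(-0.5 + 0.3 * x)          # no dyad effect at all
  y <- rbeta(length(mu), mu * 40, (1 - mu) * 40)
  fr <- data.frame(dyad_id = paste0("d", d), wtc = y, x = x)
  fit <- fit_beta_mixed(fr, fixed = "x")
  ref <- ref_beta_mle(y, cbind(1, x))
  expect_equal(fit$fixef$estimate, ref$beta, tolerance = 1e-3)
  expect_equal(fit$phi, ref$phi, tolerance = 0.02 * ref$phi)
  expect_true(fit$converged)
  expect_gt(fit$phi, 0)
  expect_true(all(is.finite(fit$fixef$se)))
})

test_that("Laplace fit agrees with adaptive Gauss-Hermite quadrature", {
  set.seed(53)
  n_dyads <- 16; n_obs <- 80
  d <- rep(seq_len(n_dyads), each = n_obs)
  b0 <- rnorm(n_dyads, 0, 0.4)
  mu <- plogis(-0.6 + b0[d])
  y <- rbeta(length(mu), mu * 30, (1 - mu) * 30)
  fr <- data.frame(dyad_id = paste0("d", d), wtc = y)
  fit <- fit_beta_mixed(fr)
  ref <- suppressWarnings(ref_beta_agq(y, d))
  expect_equal(fit$fixef$estimate[1], ref$beta0, tolerance = 1e-2)
  expect_equal(log(fit$phi), log(ref$phi), tolerance = 1e-2)
  expect_equal(sqrt(fit$ranef_var[[1]]), ref$sigma, tolerance = 1e-2)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("constant response at 0.5 gives a null intercept", {
  fr <- data.frame(dyad_id = rep(c("a", "b"), each = 50), wtc = 0.5)
  fit <- fit_beta_mixed(fr)
  expect_lt(abs(fit$fixef$estimate[1]), 1e-6)
  expect_equal(plogis(fit$fixef$estimate[1]), 0.5, tolerance = 1e-6)
})

test_that("likelihood ratio test arithmetic and guards", {
  fr <- simulate_beta_frame(n_dyads = 8, n_channels = 2, n_epochs = 8,
                            seed = 3)
  f0 <- fit_beta_mixed(fr)
  expect_equal(lrt(f0, f0), list(chi2 = 0, df = 0L, p = 1))
  f1 <- fit_beta_mixed(fr, fixed = "turn_taking_z")
  t1 <- lrt(f0, f1)
  expect_gte(t1$chi2, 0)                   # ll never decreases with params
  expect_equal(t1$df, 2L)                  # fixed effect + slope variance
  expect_equal(t1$p, pchisq(t1$chi2, 2, lower.tail = FALSE))
  # the reported chi2(2) = 19.54 corresponds to p < 0.001
  expect_lt(pchisq(19.54, 2, lower.tail = FALSE), 0.001)
  fr2 <- fr[-(1:16), ]
  f2 <- fit_beta_mixed(fr2)
  expect_error(lrt(f2, f1), "different data")
})

test_that("the model ladder runs, is monotone in logLik, names gaps", {
  fr <- simulate_beta_frame(n_dyads = 10, n_channels = 2, n_epochs = 8,
                            seed = 4)
  lad <- model_ladder(fr, through = 3L)
  expect_named(lad$fits, c("m0", "m1", "m2", "m3"))
  lls <- vapply(lad$fits, `[[`, 1.0, "loglik")
  expect_true(all(diff(lls) >= -1e-6))
  expect_equal(lad$lrts$comparison,
               c("m1 vs m0", "m2 vs m1", "m3 vs m2"))
  expect_true(all(lad$lrts$df == 2))
  # fitted means stay inside (0,1)
  mu <- predict(lad$fits$m3$fit, type = "response")
  expect_true(all(mu > 0 & mu < 1))
  fr_bad <- fr; fr_bad$contingency_z <- NULL
  expect_error(model_ladder(fr_bad, through = 7L), "contingency_z")
})

test_that("trend contrasts are the exact link-scale linear identity", {
  fr <- simulate_beta_frame(n_dyads = 12, n_channels = 2, n_epochs = 8,
                            seed = 5)
  fit <- fit_beta_mixed(fr, fixed = c("turn_taking_z", "time_z",
                                      "turn_taking_z:time_z"))
  fe <- setNames(fit$fixef$estimate, fit$fixef$term)
  tc <- trend_contrast(fit, at = c(early = -0.8, late = 0.8))
  expect_equal(tc$trends$trend[1],
               fe[["turn_taking_z"]] - 0.8 * fe[["turn_taking_z:time_z"]])
  expect_equal(tc$trends$trend[2],
               fe[["turn_taking_z"]] + 0.8 * fe[["turn_taking_z:time_z"]])
  # symmetric moderator coding -> trends equidistant from the main effect
  expect_equal(mean(tc$trends$trend), unname(fe[["turn_taking_z"]]),
               tolerance = 1e-12)
  expect_equal(tc$difference$estimate, 1.6 * fe[["turn_taking_z:time_z"]],
               tolerance = 1e-12)
  # cross-check trends and SEs against emtrends (the conventional tool)
  skip_if_not_installed("emmeans")
  em <- as.data.frame(emmeans::emtrends(
    fit$fit, ~ time_z, var = "turn_taking_z",
    at = list(time_z = c(-0.8, 0.8))))
  expect_equal(tc$trends$trend, em$turn_taking_z.trend, tolerance = 1e-8)
  expect_equal(tc$trends$se, em$SE, tolerance = 1e-6)
  # default moderator levels: early/late epoch means
  tc2 <- trend_contrast(fit)
  expect_equal(tc2$trends$level, c("early", "late"))
  expect_equal(tc2$trends$moderator_value[1],
               mean(unique(fr$time_z)[1:4]), tolerance = 1e-12)
  fit_noint <- fit_beta_mixed(fr, fixed = c("turn_taking_z", "time_z"))
  expect_error(trend_contrast(fit_noint), "interaction")
})

test_that("pairing comparison separates coupled originals from their null", {
  co <- list()
  set.seed(54)
  # construct original tables clearly above the surrogate level
  mont <- tiny_montage(2)
  for (i in 1:6) {
    co[[i]] <- structure(list(
      dyad_id = paste0("d", i), chromophore = "HbO",
      values = matrix(plogis(rnorm(16, 0.3 + 0.05 * (1:8), 0.3)), 2,
                      byrow = TRUE),
      band_hz = c(0.06, 0.15), epoch_len_s = 30,
      channel_mask = rep(TRUE, 2), montage = mont),
      class = "coherence_table")
  }
  surr_vals <- array(runif(6 * 3 * 2 * 8, 0.2, 0.4), c(6, 3, 2, 8))
  surr <- dyadsync:::new_surrogate_set(
    "random_pair", surr_vals, data.frame(), 3L, 1L, "HbO",
    c(0.06, 0.15), 30, paste0("d", 1:6))
  pc <- pairing_comparison(co, surr)
  expect_named(pc$fits, c("p0", "p1", "p2", "p3"))
  expect_equal(nrow(pc$frame), 6 * 2 * 8 * 2)
  i_p <- match("pairing_orig", pc$fits$p1$fixef$term)
  expect_gt(pc$fits$p1$fixef$estimate[i_p], 0)   # original > random
  expect_equal(pc$trends$trends$level, c("random", "original"))
  surr0 <- dyadsync:::new_surrogate_set(
    "random_pair", array(NA_real_, c(6, 0, 0, 0)), data.frame(), 0L, 1L,
    "HbO", c(0.06, 0.15), 30, paste0("d", 1:6))
  expect_error(pairing_comparison(co, surr0), "no draws")
})
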