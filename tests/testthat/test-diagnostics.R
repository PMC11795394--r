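test_that("DIC decomposition follows the textbook identities", {
  d <- dic_stats(c(95, 105), 90)
  expect_equal(d$D_bar, 100)
  expect_equal(d$p_D, 10)
  expect_equal(d$DIC, 110)
  # degenerate posterior: p_D = 0
  d0 <- dic_stats(c(100, 100), 100)
  expect_equal(d0$p_D, 0)
  expect_equal(d0$DIC, d0$D_bar)
  expect_warning(dic_stats(c(80, 82), 95), "p_D")
  expect_error(dic_stats(100, 90), "at least 2")
})

test_that("WAIC matches hand-computed values and degenerates correctly", {
  # identical draws: no pointwise variance
  w0 <- waic_stats(matrix(c(-1, -1, -2, -2), 2))
  expect_equal(w0$p_waic, 0)
  # 2 cells x 2 draws, arithmetic done by hand:
  # cell1 lpd {-1, -1.5}: log mean exp = log((e^-1 + e^-1.5)/2)
  # cell2 lpd {-2, -1}:   log mean exp = log((e^-2 + e^-1)/2)
  lpd <- matrix(c(-1, -1.5, -2, -1), 2)
  w <- waic_stats(lpd)
  lppd_hand <- log((exp(-1) + exp(-1.5)) / 2) + log((exp(-2) + exp(-1)) / 2)
  p_hand <- var(c(-1, -1.5)) + var(c(-2, -1))
  expect_equal(w$lppd, lppd_hand, tolerance = 1e-12)
  expect_equal(w$p_waic, p_hand, tolerance = 1e-12)
  expect_equal(w$WAIC, -2 * (lppd_hand - p_hand), tolerance = 1e-12)
  expect_error(waic_stats(matrix(-1, 1, 3)), "one posterior draw")
})

test_that("draw-based DIC satisfies its identity and p_D is sensible", {
  sim <- toy_panel(T = 3, k = 1, seed = 131)
  fit <- fit_st(sim$panel, sim$graph,
                st_model(effects = c("v", "u", "gamma"), interaction = "none",
                         hyper_grid = "eb"), seed = 1)
  d <- dic(fit, n_draws = 300)
  expect_equal(d$DIC, d$D_bar + d$p_D, tolerance = 1e-12)
  expect_gt(d$p_D, 0)
  # p_D is close to a long-MCMC estimate on the same toy
  mc <- mcmc_st(sim$panel, sim$graph,
                st_model(effects = c("v", "u", "gamma"), interaction = "none"),
                n_iter = 8000, seed = 1)
  devs <- apply(mc$eta, 1, function(h) {
    -2 * stdismap:::loglik_eta(fit$internals$int, h)
  })
  d_mc <- dic_stats(devs, -2 * stdismap:::loglik_eta(fit$internals$int,
                                                     colMeans(mc$eta)))
  expect_lt(abs(d$p_D - d_mc$p_D) / d_mc$p_D, 0.5)
})

test_that("DIC and WAIC rank a signal model above a null model", {
  sim <- simulate_panel(lattice_graph(c(5L, 4L)), n_periods = 4, k = 1,
                        beta = 0.6, seed = 141)
  m_full <- st_model(effects = c("v", "u", "gamma"), interaction = "none",
                     hyper_grid = "eb")
  fit_with <- fit_st(sim$panel, sim$graph, m_full, seed = 1)
  no_cov <- dplyr::select(sim$panel, -"pct_nourished")
  fit_null <- fit_st(no_cov, sim$graph, m_full, seed = 1)
  d1 <- dic(fit_with, n_draws = 300); d0 <- dic(fit_null, n_draws = 300)
  w1 <- waic(fit_with, n_draws = 300); w0 <- waic(fit_null, n_draws = 300)
  expect_lt(d1$DIC, d0$DIC)
  expect_lt(w1$WAIC, w0$WAIC)
})

test_that("model comparison flags Delta DIC > 3 and rejects mismatched data", {
  sim <- simulate_panel(lattice_graph(c(5L, 4L)), n_periods = 4, k = 1,
                        seed = 151)
  m1 <- st_model(effects = c("v", "u", "gamma", "phi", "psi"),
                 interaction = "IV", hyper_grid = "eb")
  m0 <- st_model(effects = c("v", "u", "gamma", "phi"), interaction = "none",
                 hyper_grid = "eb")
  f1 <- fit_st(sim$panel, sim$graph, m1, seed = 1)
  f0 <- fit_st(sim$panel, sim$graph, m0, seed = 1)
  cmp <- compare_st(interaction = f1, none = f0, n_draws = 300)
  expect_equal(min(cmp$delta_DIC), 0)
  expect_equal(cmp$significant, cmp$delta_DIC > 3)

  other <- simulate_panel(lattice_graph(c(5L, 4L)), n_periods = 4, k = 1,
                          seed = 152)
  f2 <- fit_st(other$panel, other$graph, m0, seed = 1)
  expect_error(compare_st(a = f1, b = f2), "identical data")
})

test_that("variance partition attributes all variability to the only active family", {
  sim <- simulate_panel(lattice_graph(c(5L, 4L)), n_periods = 4, k = 0,
                        variances = list(v = 0, u = 0, gamma = 0.5, phi = 0,
                                         psi = 0),
                        interaction = "none", seed = 161)
  fit <- fit_st(sim$panel, sim$graph,
                st_model(effects = "gamma", interaction = "none",
                         hyper_grid = "eb"), seed = 1)
  vp <- variance_partition(fit)
  expect_equal(sum(vp$proportion), 1, tolerance = 1e-9)
  expect_true(all(vp$proportion >= 0))
  expect_equal(vp$proportion[vp$family == "temporal"], 1, tolerance = 1e-9)
})

test_that("relative-risk transforms reproduce reported percent changes", {
  expect_equal(rr_percent_change(0), 0)
  expect_equal(round(rr_percent_change(-0.90)), -59)
  expect_equal(round(rr_percent_change(0.51)), 67)
  expect_equal(rr_change_label(c(-0.90, 0.51, 0)),
               c("59% decrease", "67% increase", "0%"))
  # reciprocal identity
  b <- c(0.3, -1.2, 0.51)
  p_plus <- rr_percent_change(b); p_minus <- rr_percent_change(-b)
  expect_equal((1 + p_plus / 100) * (1 + p_minus / 100), rep(1, 3),
               tolerance = 1e-12)
})

test_that("rr_table exposes coefficient risk changes from a fit", {
  sim <- toy_panel(T = 3, k = 1, seed = 171)
  fit <- fit_st(sim$panel, sim$graph,
                st_model(effects = c("v", "u"), interaction = "none",
                         hyper_grid = "eb"), seed = 1)
  rr <- rr_table(fit)
  expect_false(any(grepl("Intercept", rr$term)))
  expect_equal(rr$rr_change, rr_percent_change(rr$estimate))
})
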