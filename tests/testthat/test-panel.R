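test_that("expected counts pool the global rate and conserve totals", {
  p <- tibble::tibble(area_id = c("a", "b"), time = 1L,
                      deaths = c(10, 20), at_risk = c(100, 300))
  out <- add_expected_counts(p)
  expect_equal(out$expected, c(7.5, 22.5))       # pooled rate 30/400 = 0.075
  expect_identical(sum(out$expected), sum(out$deaths))

  # everyone dies: e = N
  p2 <- tibble::tibble(area_id = c("a", "b"), time = 1L,
                       deaths = c(5, 9), at_risk = c(5, 9))
  expect_equal(add_expected_counts(p2)$expected, c(5, 9))

  # zero exposure cell gets zero expected
  p3 <- tibble::tibble(area_id = c("a", "b"), time = 1L,
                       deaths = c(0, 10), at_risk = c(0, 100))
  expect_equal(add_expected_counts(p3)$expected[1], 0)

  expect_error(add_expected_counts(
    tibble::tibble(area_id = "a", time = 1L, deaths = 0, at_risk = 0)),
    "zero")

  # per-period standardization conserves within period
  p4 <- tibble::tibble(area_id = rep(c("a", "b"), 2), time = rep(1:2, each = 2),
                       deaths = c(1, 3, 10, 2), at_risk = c(10, 10, 20, 20))
  out4 <- add_expected_counts(p4, by = "time")
  expect_equal(tapply(out4$expected, out4$time, sum),
               tapply(out4$deaths, out4$time, sum))
})

test_that("SMR is O/e with NA for undefined cells", {
  p <- tibble::tibble(area_id = c("a", "b"), time = 1L,
                      deaths = c(10, 20), at_risk = c(100, 300))
  out <- add_smr(add_expected_counts(p))
  expect_equal(out$smr, c(10 / 7.5, 20 / 22.5))
  p0 <- tibble::tibble(area_id = "a", time = 1L, deaths = 0,
                       at_risk = 10, expected = 2.5)
  expect_equal(add_smr(p0)$smr, 0)
  pbad <- tibble::tibble(area_id = "a", time = 1L, deaths = 3,
                         at_risk = 10, expected = 0)
  expect_warning(res <- add_smr(pbad), "undefined")
  expect_true(is.na(res$smr))
})

test_that("covariate standardization uses the population convention and is invertible", {
  p <- tibble::tibble(area_id = c("a", "b"), time = 1L, deaths = 0,
                      at_risk = 1, x = c(0, 1))
  out <- standardize_covariates(p, "x")
  expect_equal(out$x, c(-1, 1))   # population sd of {0,1} is 0.5
  sc <- attr(out, "covariate_scaling")
  expect_equal(sc$mean, 0.5); expect_equal(sc$sd, 0.5)

  # already standardized column is unchanged
  out2 <- standardize_covariates(out, "x")
  expect_equal(out2$x, out$x)

  expect_error(standardize_covariates(
    dplyr::mutate(p, x = 1), "x"), "'x' is constant")

  # 16 survey-style covariates: all means/sds exact after standardization
  sim <- simulate_panel(lattice_graph(c(5L, 4L)), n_periods = 3, k = 16,
                        seed = 8)
  X <- as.matrix(sim$panel[, survey_covariate_names()])
  expect_lt(max(abs(colMeans(X))), 1e-12)
  expect_equal(unname(apply(X, 2, stdismap:::pop_sd)), rep(1, 16),
               tolerance = 1e-10)
})

test_that("design maps reproduce the elementwise linear predictor", {
  # hand cases, time-major layout
  eta <- assemble_eta(2, 2, v = c(1, -1))
  expect_equal(eta, c(1, -1, 1, -1))
  eta2 <- assemble_eta(2, 2, gamma = c(2, -2))
  expect_equal(eta2, c(2, 2, -2, -2))

  # oracle: direct loop over Eq-style elementwise sum
  withr::local_seed(21)
  for (rep in 1:25) {
    S <- sample(2:5, 1); T <- sample(2:5, 1); k <- sample(0:3, 1)
    X <- if (k) matrix(rnorm(S * T * k), S * T, k) else NULL
    beta <- if (k) rnorm(k) else NULL
    b0 <- rnorm(1); v <- rnorm(S); u <- rnorm(S)
    gam <- rnorm(T); phi <- rnorm(T); psi <- rnorm(S * T)
    eta <- assemble_eta(S, T, b0, X, beta, v, u, gam, phi, psi)
    direct <- numeric(S * T)
    for (t in seq_len(T)) for (i in seq_len(S)) {
      cell <- (t - 1) * S + i
      direct[cell] <- b0 + (if (k) sum(X[cell, ] * beta) else 0) +
        v[i] + u[i] + gam[t] + phi[t] + psi[cell]
    }
    expect_equal(eta, direct, tolerance = 1e-12)
  }
})

test_that("latent layout slices are disjoint and exhaustive", {
  lay <- latent_layout(S = 5, T = 3, k = 2, n_components = 2,
                       split_intercept = TRUE)
  slices <- lay[setdiff(names(lay), "total")]
  all_idx <- sort(unname(unlist(slices)))
  expect_equal(all_idx, seq_len(lay$total))
  expect_equal(lay$total, 2 + 2 + 2 * 5 + 2 * 3 + 15)
})

test_that("Poisson log-likelihood matches hand arithmetic and is maximized at log(O/e)", {
  expect_equal(poisson_loglik(2, 1, 0), 2 * 0 - 1 - log(2), tolerance = 1e-10)
  # saturated at omega = 1 when O = e
  O <- c(3, 7); ll <- poisson_loglik(O, O, c(0, 0))
  expect_equal(ll, sum(O * log(O) - O - lfactorial(O)))
  # monotone decreasing tail
  expect_lt(poisson_loglik(2, 1, -20), poisson_loglik(2, 1, -5))
  # score zero at eta = log(O/e) per cell
  O <- c(4, 9); e <- c(2, 3)
  eta_hat <- log(O / e)
  for (j in 1:2) {
    bump <- replace(numeric(2), j, 1e-4)
    expect_lt(poisson_loglik(O, e, eta_hat + bump),
              poisson_loglik(O, e, eta_hat))
    expect_lt(poisson_loglik(O, e, eta_hat - bump),
              poisson_loglik(O, e, eta_hat))
  }
  expect_error(poisson_loglik(1.5, 1, 0), "integers")
})

test_that("panel CSV round trip validates columns", {
  sim <- simulate_panel(lattice_graph(c(4L, 3L)), n_periods = 2, k = 1, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel(sim$panel, tmp)
  back <- read_panel(tmp)
  expect_equal(back$deaths, sim$panel$deaths)
  expect_equal(back$pct_nourished, sim$panel$pct_nourished, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(sim$panel, -"at_risk"), bad)
  expect_error(read_panel(bad), "at_risk")
})

test_that("smr_table writes the expected columns", {
  sim <- simulate_panel(lattice_graph(4L), n_periods = 2, k = 0, seed = 5)
  tab <- smr_table(sim$panel)
  expect_named(tab, c("area_id", "time", "deaths", "at_risk", "expected", "smr"))
  expect_equal(sum(tab$expected), sum(tab$deaths))
})
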