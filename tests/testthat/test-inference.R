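test_that("single-cell mode matches a 1-D optimization oracle", {
  g <- areal_graph(data.frame(from = character(0), to = character(0)), "a")
  panel <- tibble::tibble(area_id = "a", time = 1L, deaths = 2L,
                          at_risk = 10L, expected = 1)
  model <- st_model(effects = character(0), interaction = "none")
  ga <- gaussian_approximation(panel, g, model)
  oracle <- stats::optimize(function(b) 2 * b - exp(b) - 0.5e-4 * b^2,
                            c(-3, 3), maximum = TRUE)$maximum
  expect_lt(abs(ga$x[["(Intercept)"]] - log(2)), 1e-3)
  expect_equal(unname(ga$x[["(Intercept)"]]), oracle, tolerance = 1e-5)
})

test_that("null data give a null fit with constraints enforced", {
  g <- lattice_graph(c(5L, 4L))
  T <- 3
  panel <- tidyr::expand_grid(time = seq_len(T), area_id = g$area_ids)
  panel$at_risk <- 1000L
  panel$deaths <- 100L      # exactly the pooled rate everywhere: O = e
  fit <- fit_st(panel, g, st_model(hyper_grid = "eb"), seed = 1)
  expect_lt(abs(fit$fixed$estimate[1]), 1e-4)
  eff <- fit$effects
  expect_lt(max(abs(eff$mean[eff$block != "fixed"])), 1e-4)
  expect_true(all(fit$cells$rr > 0.99 & fit$cells$rr < 1.01))

  # constraint residuals
  vhat <- eff$mean[eff$block == "v"]
  for (c in seq_len(g$n_components)) {
    expect_lt(abs(sum(vhat[g$component == c])), 1e-8)
  }
  expect_lt(abs(sum(eff$mean[eff$block == "gamma"])), 1e-8)
  ist <- interaction_structure("IV", T, g)
  expect_lt(max(abs(crossprod(ist$null_basis, eff$mean[eff$block == "psi"]))),
            1e-8)
})

test_that("hyper-grid weights normalize and the fit is deterministic", {
  sim <- toy_panel(T = 3, k = 1, seed = 51)
  fit1 <- fit_st(sim$panel, sim$graph, st_model(), seed = 2)
  expect_equal(sum(fit1$grid$weights), 1, tolerance = 1e-12)
  fit2 <- fit_st(sim$panel, sim$graph, st_model(), seed = 2)
  expect_identical(fit1$fixed, fit2$fixed)
  expect_identical(fit1$cells, fit2$cells)
})

test_that("one-hyperparameter posterior matches a nested-quadrature oracle", {
  # 3 areas, 1 period, intercept + iid heterogeneity only: the exact
  # hyperposterior factorizes into nested 1-D integrals.
  g <- areal_graph(data.frame(from = character(0), to = character(0)),
                   c("a", "b", "c"))
  panel <- tibble::tibble(area_id = c("a", "b", "c"), time = 1L,
                          deaths = c(30L, 55L, 20L), at_risk = 1000L)
  panel <- add_expected_counts(panel)
  model <- st_model(effects = "u", interaction = "none", grid_points = 15)
  fit <- fit_st(panel, g, model, seed = 1)

  lambda <- -log(model$pc_alpha) / model$pc_u
  oracle_lp <- function(theta) {
    sigma <- exp(-theta / 2)
    cell_lik <- function(b0) {
      out <- 1
      for (i in 1:3) {
        f <- function(u) {
          stats::dpois(panel$deaths[i],
                       panel$expected[i] * exp(b0 + u)) * stats::dnorm(u, 0, sigma)
        }
        out <- out * stats::integrate(f, -8 * sigma, 8 * sigma)$value
      }
      out
    }
    b0s <- seq(-0.5, 0.5, length.out = 201)
    like <- vapply(b0s, cell_lik, numeric(1))
    log(sum(like) * diff(b0s[1:2])) + (-lambda * sigma - theta / 2)
  }
  thetas <- seq(min(fit$grid$theta), max(fit$grid$theta), length.out = 41)
  lp_oracle <- vapply(thetas, oracle_lp, numeric(1))
  mode_oracle <- thetas[which.max(lp_oracle)]
  mode_fit <- fit$grid$theta[which.max(fit$grid$lp), 1]
  step <- diff(sort(unique(fit$grid$theta[, 1])))[1]
  expect_lt(abs(mode_fit - mode_oracle), step + 0.2)

  # grid refinement self-consistency: posterior mean log-precision moves < 2%
  fit2 <- fit_st(panel, g, st_model(effects = "u", interaction = "none",
                                    grid_points = 29), seed = 1)
  m1 <- drop(fit$grid$weights %*% fit$grid$theta)
  m2 <- drop(fit2$grid$weights %*% fit2$grid$theta)
  expect_lt(abs(m2 - m1) / max(abs(m1), 0.5), 0.02)
})

test_that("fixed effects are recovered across synthetic replicates", {
  g <- lattice_graph(rep(9L, 4))
  hits <- c()
  for (s in 1:5) {
    sim <- simulate_panel(g, n_periods = 4, k = 3, seed = 300 + s)
    fit <- fit_st(sim$panel, sim$graph, st_model(hyper_grid = "eb"), seed = s)
    fx <- fit$fixed[-1, ]
    hits <- c(hits, abs(fx$estimate - sim$truth$beta) <= 2 * fx$std.error)
  }
  expect_gte(mean(hits), 0.8)
})

test_that("raising one cell's count does not lower its fitted risk", {
  sim <- toy_panel(T = 3, k = 1, seed = 61)
  panel <- sim$panel  # expected already attached; held fixed across versions
  fit0 <- fit_st(panel, sim$graph, st_model(hyper_grid = "eb"), seed = 1)
  bump <- panel
  j <- 4L
  bump$deaths[j] <- bump$deaths[j] + max(20L, bump$deaths[j])
  fit1 <- fit_st(bump, sim$graph, st_model(hyper_grid = "eb"), seed = 1)
  expect_gt(fit1$cells$rr[j], fit0$cells$rr[j])
})

test_that("orthogonalization enforces covariate-orthogonal fields and shifts beta", {
  # spatially confounded setup: the covariate is a noisy copy of the true
  # spatial field and has no effect of its own
  g <- lattice_graph(c(8L, 8L))
  S <- g$n_areas; T <- 3L
  withr::local_seed(71)
  v_true <- sample_gmrf(icar_structure(g), variance = 0.4)
  x_area <- as.numeric(scale(v_true + rnorm(S, 0, 0.2)))
  panel <- tidyr::expand_grid(time = seq_len(T), area_id = g$area_ids)
  panel$confounded_x <- rep(x_area, times = T)
  panel$at_risk <- 3000L
  eta <- rep(v_true, times = T)
  panel$deaths <- rpois(S * T, panel$at_risk * 0.1 * exp(eta))
  panel <- standardize_covariates(add_expected_counts(panel), "confounded_x")
  X <- matrix(panel$confounded_x)

  m_plain <- st_model(effects = c("v", "gamma"), interaction = "none",
                      hyper_grid = "eb")
  m_orth <- st_model(effects = c("v", "gamma"), interaction = "none",
                     orthogonalize = TRUE, hyper_grid = "eb")
  fit_p <- fit_st(panel, g, m_plain, seed = 1)
  fit_o <- fit_st(panel, g, m_orth, seed = 1)
  maps <- design_maps(S, T)
  vp <- fit_p$effects$mean[fit_p$effects$block == "v"]
  vo <- fit_o$effects$mean[fit_o$effects$block == "v"]
  expect_lt(max(abs(crossprod(X, as.matrix(maps$spatial %*% vo)))), 1e-8)
  expect_gt(max(abs(crossprod(X, as.matrix(maps$spatial %*% vp)))), 1e-6)

  glm_fit <- stats::glm(deaths ~ confounded_x + offset(log(expected)),
                        family = stats::poisson(), data = panel)
  b_glm <- unname(coef(glm_fit)["confounded_x"])
  b_o <- fit_o$fixed$estimate[2]
  b_p <- fit_p$fixed$estimate[2]
  # the smoothing prior pulls the plain fit's coefficient off the GLM value;
  # forcing the field orthogonal to X restores it
  expect_lt(abs(b_o - b_glm), abs(b_p - b_glm))
})

test_that("component splits give per-country intercepts and variances", {
  sim <- simulate_panel(lattice_graph(c(6L, 5L)), n_periods = 3, k = 1,
                        seed = 81)
  model <- st_model(split_intercept = TRUE, split_spatial_variance = TRUE,
                    interaction = "none",
                    effects = c("v", "u", "gamma", "phi"), hyper_grid = "eb")
  fit <- fit_st(sim$panel, sim$graph, model, seed = 1)
  expect_equal(sum(grepl("^\\(Intercept\\):c", fit$fixed$term)), 2L)
  expect_equal(sum(grepl("^v_c", fit$hyper$name)), 2L)
})

test_that("unknown hyperparameter names are rejected", {
  sim <- toy_panel(T = 3, k = 0, seed = 91)
  expect_error(
    gaussian_approximation(sim$panel, sim$graph,
                           st_model(effects = "u", interaction = "none"),
                           variances = list(bogus = 1)),
    "Unknown hyperparameter"
  )
})
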