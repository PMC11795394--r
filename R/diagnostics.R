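#' Deviance information criterion from deviance evaluations
#'
#' The textbook decomposition: `D_bar` is the posterior mean deviance,
#' `p_D = D_bar - D(posterior mean)` the effective number of parameters, and
#' `DIC = D_bar + p_D`.
#'
#' @param deviances Numeric vector of deviance evaluations under the
#'   posterior (at least 2).
#' @param deviance_at_mean Deviance evaluated at the posterior mean of the
#'   latent field.
#' @return A tibble with `D_bar`, `p_D`, `DIC`.
#' @export
dic_stats <- function(deviances, deviance_at_mean) {
  if (length(deviances) < 2L) abort("Need at least 2 deviance evaluations.")
  D_bar <- mean(deviances)
  p_D <- D_bar - deviance_at_mean
  if (p_D < 0) warn("Negative effective number of parameters (p_D < 0).")
  tibble::tibble(D_bar = D_bar, p_D = p_D, DIC = D_bar + p_D)
}

#' Widely applicable information criterion from pointwise log densities
#'
#' `lppd` is the sum over cells of the log posterior-mean predictive
#' density, `p_WAIC` the summed posterior variance of the pointwise log
#' density, and `WAIC = -2 (lppd - p_WAIC)`.
#'
#' @param lpd A `draws x cells` matrix of pointwise log predictive
#'   densities.
#' @return A tibble with `lppd`, `p_waic`, `WAIC`.
#' @export
waic_stats <- function(lpd) {
  lpd <- as.matrix(lpd)
  if (nrow(lpd) < 2L) abort("WAIC needs more than one posterior draw.")
  # log mean exp per cell, stabilized
  mx <- apply(lpd, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(lpd, 2, mx)))))
  p_waic <- sum(apply(lpd, 2, var))
  tibble::tibble(lppd = lppd, p_waic = p_waic, WAIC = -2 * (lppd - p_waic))
}

# Deviance (-2 Poisson log-likelihood, unsaturated) of a linear-predictor
# draw; constants cancel in model comparisons.
deviance_of_eta <- function(int, eta) {
  -2 * loglik_eta(int, eta)
}

#' Model-comparison criteria for a fitted model
#'
#' Draw-based DIC and WAIC for an [fit_st()] (or [mcmc_st()]) result.
#'
#' @param fit An `st_fit` or `st_mcmc` object.
#' @param n_draws Posterior draws used (ignored for `st_mcmc`, which uses
#'   its stored draws).
#' @param seed Seed for the posterior draws (defaults to the fit's seed).
#' @return [dic()]: tibble `D_bar`, `p_D`, `DIC`. [waic()]: tibble `lppd`,
#'   `p_waic`, `WAIC`.
#' @export
dic <- function(fit, n_draws = 400L, seed = NULL) {
  eta_info <- fit_eta_draws(fit, n_draws, seed)
  devs <- apply(eta_info$eta, 1, function(h) deviance_of_eta(eta_info$int, h))
  dic_stats(devs, deviance_of_eta(eta_info$int, eta_info$eta_mean))
}

#' @rdname dic
#' @export
waic <- function(fit, n_draws = 400L, seed = NULL) {
  eta_info <- fit_eta_draws(fit, n_draws, seed)
  int <- eta_info$int
  inc <- which(int$include)
  lpd <- t(apply(eta_info$eta, 1, function(h) {
    dpois(int$O[inc], int$e[inc] * exp(pmin(h[inc], 40)), log = TRUE)
  }))
  waic_stats(lpd)
}

fit_eta_draws <- function(fit, n_draws, seed) {
  if (inherits(fit, "st_fit")) {
    pd <- posterior_draws(fit, n_draws = n_draws, seed = seed)
    list(int = fit$internals$int, eta = pd$eta, eta_mean = fit$cells$eta_mean)
  } else if (inherits(fit, "st_mcmc")) {
    list(int = fit$internals$int, eta = fit$eta, eta_mean = colMeans(fit$eta))
  } else {
    abort("Expected an `st_fit` or `st_mcmc` object.")
  }
}

#' Compare fitted models by DIC and WAIC
#'
#' All fits must be on identical data (checked). A DIC difference greater
#' than 3 relative to the best model is flagged as meaningful.
#'
#' @param ... Named `st_fit` objects, or a single (named) list of them.
#' @param n_draws Posterior draws per fit for the criteria.
#' @param seed Common seed for the criterion draws.
#' @return A tibble of class `st_compare`: `model`, `D_bar`, `p_D`, `DIC`,
#'   `WAIC`, `delta_DIC`, `significant` (`delta_DIC > 3`).
#' @export
compare_st <- function(..., n_draws = 400L, seed = 1L) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "st_fit")) fits <- fits[[1]]
  if (length(fits) < 2L) abort("Need at least two fits to compare.")
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  keys <- purrr::map_chr(fits, function(f) {
    rlang::hash(list(f$internals$int$O, f$internals$int$e))
  })
  if (length(unique(keys)) != 1L) {
    abort("Fits were not computed on identical data; comparison is invalid.")
  }
  rows <- purrr::imap_dfr(fits, function(f, nm) {
    d <- dic(f, n_draws = n_draws, seed = seed)
    w <- waic(f, n_draws = n_draws, seed = seed)
    tibble::tibble(model = nm, D_bar = d$D_bar, p_D = d$p_D, DIC = d$DIC,
                   WAIC = w$WAIC)
  })
  rows$delta_DIC <- rows$DIC - min(rows$DIC)
  rows$significant <- rows$delta_DIC > 3
  class(rows) <- c("st_compare", class(rows))
  rows
}

#' Variance partition across random-effect families
#'
#' Attributes the variability of the fitted latent log relative risk to the
#' spatial (ICAR), heterogeneity (iid area), temporal (trend + unstructured)
#' and space-time interaction fields: each family's posterior-mean effect
#' vector is mapped onto the area-period grid and its empirical variance
#' taken; proportions are normalized to sum to one. (Empirical variances of
#' the fields, not hyperparameter values — intrinsic-prior variance
#' parameters are conditional, not marginal, variances.)
#'
#' @param fit An [fit_st()] result.
#' @return A tibble `family`, `variance`, `proportion` (proportions sum
#'   to 1).
#' @export
variance_partition <- function(fit) {
  if (!inherits(fit, "st_fit")) abort("Expected an `st_fit`.")
  int <- fit$internals$int
  S <- int$pm$S; T <- int$pm$T
  eff <- fit$effects
  field <- function(block) {
    m <- eff$mean[eff$block == block]
    if (!length(m)) return(rep(0, S * T))
    switch(block,
      v = , u = rep(m, times = T),
      gamma = , phi = rep(m, each = S),
      psi = m
    )
  }
  temporal <- field("gamma") + field("phi")
  fields <- list(
    spatial = field("v"),
    heterogeneity = field("u"),
    temporal = temporal,
    interaction = field("psi")
  )
  vars <- vapply(fields, pop_var, numeric(1))
  if (sum(vars) <= 0) {
    warn("All fitted random-effect fields are zero; reporting a uniform partition.")
    props <- rep(1 / length(vars), length(vars))
  } else {
    props <- vars / sum(vars)
  }
  tibble::tibble(family = names(fields), variance = unname(vars),
                 proportion = unname(props))
}

#' Percent change in relative risk per unit covariate increase
#'
#' Converts a coefficient on a standardized covariate to the signed percent
#' change in relative risk per one-unit (one standard deviation) increase:
#' `100 * (exp(beta) - 1)`.
#'
#' @param beta Numeric vector of coefficients (log relative-risk scale).
#' @return Numeric vector of signed percent changes.
#' @examples
#' rr_percent_change(-0.90) # about -59: a 59% decrease in relative risk
#' @export
rr_percent_change <- function(beta) {
  if (any(!is.finite(beta))) abort("`beta` must be finite.")
  100 * (exp(beta) - 1)
}

#' @rdname rr_percent_change
#' @return `rr_change_label()`: character labels like `"59% decrease"`,
#'   rounded to whole percent for report parity.
#' @export
rr_change_label <- function(beta) {
  pc <- rr_percent_change(beta)
  dplyr::case_when(
    round(abs(pc)) == 0 ~ "0%",
    pc > 0 ~ sprintf("%d%% increase", round(pc)),
    TRUE ~ sprintf("%d%% decrease", round(-pc))
  )
}

#' Relative-risk table of fixed effects
#'
#' The fitted coefficients of an [fit_st()] with their percent relative-risk
#' changes and interval.
#'
#' @param fit An `st_fit`.
#' @return Tibble `term`, `estimate`, `conf.low`, `conf.high`,
#'   `rr_change` (numeric percent), `rr_label`.
#' @export
rr_table <- function(fit) {
  if (!inherits(fit, "st_fit")) abort("Expected an `st_fit`.")
  fx <- fit$fixed
  fx <- fx[!grepl("^\\(Intercept\\)", fx$term), , drop = FALSE]
  tibble::tibble(
    term = fx$term,
    estimate = fx$estimate,
    conf.low = fx$conf.low,
    conf.high = fx$conf.high,
    rr_change = rr_percent_change(fx$estimate),
    rr_label = rr_change_label(fx$estimate)
  )
}
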