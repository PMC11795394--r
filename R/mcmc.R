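#' Metropolis-within-Gibbs sampler (validation oracle)
#'
#' Exact-posterior MCMC for the same model fitted by [fit_st()], intended as
#' an independent check of the approximate inference on small instances.
#' The latent field is updated in one block with an independence proposal
#' from the Gaussian approximation at the current hyperparameters; each log
#' variance gets a random-walk update (scales adapted during burn-in toward
#' ~40% acceptance). Constraints hold exactly: the chain runs in the reduced
#' (constraint-free) coordinates.
#'
#' @inheritParams fit_st
#' @param n_iter Total sweeps.
#' @param burnin Discarded sweeps (default a quarter of `n_iter`).
#' @param thin Keep every `thin`-th sweep.
#' @param seed Integer seed; the chain is reproducible.
#' @return An object of class `st_mcmc`: `fixed` (draws matrix), `theta`
#'   (log-precision draws), `eta` (thinned linear-predictor draws),
#'   `acceptance` (rates), and posterior-mean tibbles `fixed_summary`,
#'   `hyper_summary`.
#' @export
mcmc_st <- function(panel, graph, model = st_model(), n_iter = 20000L,
                    burnin = NULL, thin = 10L, seed = 1L) {
  int <- build_internals(panel, graph, model)
  n_iter <- as.integer(n_iter)
  burnin <- as.integer(burnin %||% floor(n_iter / 4))
  thin <- as.integer(thin)
  n_h <- nrow(int$hyper)
  n <- int$n_z

  loglik_z <- function(z) {
    h <- drop(int$A_inc %*% z)
    sum(int$O_inc * (log(int$e_inc) + h) - int$e_inc * exp(pmin(h, 40)))
  }
  lp_theta_prior <- function(theta) hyper_log_prior(model, theta)

  run <- function() {
    theta <- numeric(n_h)
    qq <- build_Q(int, theta)
    ga <- newton_mode(int, qq$Q)
    z <- ga$z
    ll <- loglik_z(z)
    quad <- 0.5 * sum(z * (qq$Q %*% z))
    logq <- function(z, ga) {
      r <- drop(ga$L %*% (z - ga$z))
      -0.5 * sum(r^2) + sum(log(diag(ga$L)))
    }
    lq <- logq(z, ga)

    step <- rep(0.6, n_h)
    acc_z <- 0L; try_z <- 0L
    acc_t <- numeric(n_h); try_t <- numeric(n_h)
    batch_acc <- numeric(n_h); batch_try <- numeric(n_h)

    keep <- seq.int(burnin + thin, n_iter, by = thin)
    n_keep <- length(keep)
    nfix <- int$blocks$fixed$n_x
    fixed_draws <- matrix(0, n_keep, nfix)
    theta_draws <- matrix(0, n_keep, n_h)
    eta_draws <- matrix(0, n_keep, nrow(int$A_red))
    kidx <- 0L

    for (it in seq_len(n_iter)) {
      # latent block: independence proposal from the Gaussian approximation
      zp <- ga$z + backsolve(ga$L, rnorm(n))
      llp <- loglik_z(zp)
      quadp <- 0.5 * sum(zp * (qq$Q %*% zp))
      lqp <- logq(zp, ga)
      try_z <- try_z + 1L
      if (log(runif(1)) < (llp - quadp - lqp) - (ll - quad - lq)) {
        z <- zp; ll <- llp; quad <- quadp; lq <- lqp
        acc_z <- acc_z + 1L
      }

      # hyperparameters: random-walk on each log precision
      if (n_h > 0L) {
        changed <- FALSE
        for (j in seq_len(n_h)) {
          thp <- theta
          thp[j] <- thp[j] + rnorm(1, 0, step[j])
          qqp <- build_Q(int, thp)
          quadp <- 0.5 * sum(z * (qqp$Q %*% z))
          num <- -quadp + 0.5 * qqp$logdet + lp_theta_prior(thp)
          den <- -quad + 0.5 * qq$logdet + lp_theta_prior(theta)
          try_t[j] <- try_t[j] + 1; batch_try[j] <- batch_try[j] + 1
          if (log(runif(1)) < num - den) {
            theta <- thp; qq <- qqp; quad <- quadp
            acc_t[j] <- acc_t[j] + 1; batch_acc[j] <- batch_acc[j] + 1
            changed <- TRUE
          }
        }
        if (changed) {
          ga <- newton_mode(int, qq$Q, z0 = ga$z)
          lq <- logq(z, ga)
        }
        if (it <= burnin && it %% 50L == 0L) {
          rate <- ifelse(batch_try > 0, batch_acc / batch_try, 0.44)
          step <- step * exp((rate - 0.44))
          step <- pmin(pmax(step, 0.05), 5)
          batch_acc[] <- 0; batch_try[] <- 0
        }
      }

      if (kidx < n_keep && it == keep[kidx + 1L]) {
        kidx <- kidx + 1L
        fixed_draws[kidx, ] <- z[int$idx$fixed]
        if (n_h) theta_draws[kidx, ] <- theta
        eta_draws[kidx, ] <- drop(int$A_red %*% z)
      }
    }
    list(fixed = fixed_draws, theta = theta_draws, eta = eta_draws,
         acc_z = acc_z / max(try_z, 1),
         acc_t = ifelse(try_t > 0, acc_t / try_t, NA_real_))
  }

  out <- with_seed(seed, run())
  # independence proposals: only LOW acceptance signals a bad approximation
  if (out$acc_z < 0.05) {
    warn(sprintf("Latent-block acceptance rate %.1f%% below 5%%; the Gaussian proposal fits the posterior poorly.",
                 100 * out$acc_z))
  }
  bad_t <- !is.na(out$acc_t) & (out$acc_t < 0.05 | out$acc_t > 0.95)
  if (any(bad_t)) {
    warn(sprintf("Random-walk acceptance outside (5%%, 95%%) after adaptation for: %s",
                 paste(int$hyper$name[bad_t], collapse = ", ")))
  }
  colnames(out$fixed) <- int$blocks$fixed$x_names
  if (n_h) colnames(out$theta) <- int$hyper$name
  fixed_summary <- tibble::tibble(
    term = colnames(out$fixed),
    estimate = colMeans(out$fixed),
    std.error = apply(out$fixed, 2, sd),
    conf.low = apply(out$fixed, 2, quantile, 0.025),
    conf.high = apply(out$fixed, 2, quantile, 0.975)
  )
  hyper_summary <- if (n_h) {
    tibble::tibble(
      name = int$hyper$name,
      family = int$hyper$family,
      variance = colMeans(exp(-out$theta)),
      var.low = apply(exp(-out$theta), 2, quantile, 0.025),
      var.high = apply(exp(-out$theta), 2, quantile, 0.975)
    )
  } else {
    tibble::tibble(name = character(0), family = character(0),
                   variance = numeric(0))
  }
  structure(
    list(fixed = out$fixed, theta = out$theta, eta = out$eta,
         acceptance = list(latent = out$acc_z, hyper = out$acc_t),
         fixed_summary = fixed_summary, hyper_summary = hyper_summary,
         model = model, seed = as.integer(seed),
         internals = list(int = int)),
    class = "st_mcmc"
  )
}

#' @export
print.st_mcmc <- function(x, ...) {
  cat(sprintf("<st_mcmc> %d kept draws; latent acceptance %.1f%%\n",
              nrow(x$fixed), 100 * x$acceptance$latent))
  print(as.data.frame(x$fixed_summary), digits = 3)
  invisible(x)
}
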