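# Internal model assembly ----------------------------------------------------
#
# The latent field x = (intercepts, beta, v, u, gamma, phi, psi) is handled
# in a reduced coordinate system: every intrinsic block is reparameterized
# onto an orthonormal basis Z_b of the subspace satisfying its sum-to-zero
# (and optional covariate-orthogonality) constraints. The reduced prior
# precision Z' Q Z is full rank, so the Gaussian approximation, the Laplace
# evidence and the MCMC oracle all operate on an ordinary unconstrained
# latent Gaussian model while the constraints hold exactly by construction.

build_internals <- function(panel, graph, model) {
  pm <- panel_matrices(panel, graph)
  S <- pm$S; T <- pm$T
  C <- graph$n_components
  comp <- graph$component
  comp_cell <- rep(comp, times = T)
  X <- pm$X
  k <- ncol(X)
  maps <- design_maps(S, T)
  A_sp <- as.matrix(maps$spatial)
  A_tm <- as.matrix(maps$temporal)

  eig_range <- function(W) {
    ev <- eigen(W, symmetric = TRUE)
    tol <- max(ev$values, 1e-12) * 1e-9
    keep <- ev$values > tol
    list(Z = ev$vectors[, keep, drop = FALSE], values = ev$values[keep])
  }

  blocks <- list()
  hyper <- tibble::tibble(name = character(0), family = character(0))

  add_block <- function(name, A, Z, M_list, hyper_names = NULL,
                        family = NULL, fixed_prec = NULL, x_names = NULL) {
    blocks[[name]] <<- list(
      name = name, A = A, Z = Z, M = M_list,
      hyper = hyper_names, fixed_prec = fixed_prec,
      n_x = nrow(Z), n_z = ncol(Z), x_names = x_names
    )
    if (!is.null(hyper_names)) {
      hyper <<- dplyr::bind_rows(hyper, tibble::tibble(name = hyper_names,
                                                       family = family))
    }
  }

  # fixed-effect block (vague ridge prior, no hyperparameter)
  if (model$split_intercept) {
    Ai <- sapply(seq_len(C), function(c) as.numeric(comp_cell == c))
    int_names <- sprintf("(Intercept):c%d", seq_len(C))
  } else {
    Ai <- matrix(1, T * S, 1)
    int_names <- "(Intercept)"
  }
  if (k > 0) {
    if (model$split_covariates) {
      Ax <- do.call(cbind, lapply(seq_len(C), function(c) {
        X * (comp_cell == c)
      }))
      bnames <- as.vector(outer(pm$covariates, sprintf(":c%d", seq_len(C)),
                                paste0))
    } else {
      Ax <- X
      bnames <- pm$covariates
    }
  } else {
    Ax <- matrix(0, T * S, 0)
    bnames <- character(0)
  }
  A_fix <- cbind(Ai, Ax)
  nf <- ncol(A_fix)
  add_block("fixed", A_fix, diag(nf), list(diag(nf)),
            fixed_prec = model$fixed_prec,
            x_names = c(int_names, bnames))

  orth_rows <- function(map) {
    if (model$orthogonalize && k > 0) orthogonality_constraints(X, map) else NULL
  }

  if ("v" %in% model$effects) {
    icar <- icar_structure(graph)
    W <- icar$matrix
    if (model$scale_gmrf) W <- scale_structure_matrix(W)
    er <- eig_range(W)
    Z <- restrict_basis(er$Z, orth_rows(A_sp))
    if (model$split_spatial_variance) {
      M_list <- lapply(seq_len(C), function(c) {
        Wc <- W * outer(comp == c, comp == c)
        crossprod(Z, Wc %*% Z)
      })
      hn <- sprintf("v_c%d", seq_len(C))
    } else {
      M_list <- list(crossprod(Z, W %*% Z))
      hn <- "v"
    }
    add_block("v", A_sp, Z, M_list, hyper_names = hn, family = "spatial",
              x_names = paste0("v[", graph$area_ids, "]"))
  }
  if ("u" %in% model$effects) {
    add_block("u", A_sp, diag(S), list(diag(S)), hyper_names = "u",
              family = "heterogeneity",
              x_names = paste0("u[", graph$area_ids, "]"))
  }
  if ("gamma" %in% model$effects) {
    W <- rw1_structure(T)$matrix
    if (model$scale_gmrf) W <- scale_structure_matrix(W)
    er <- eig_range(W)
    add_block("gamma", A_tm, er$Z, list(crossprod(er$Z, W %*% er$Z)),
              hyper_names = "gamma", family = "temporal_trend",
              x_names = paste0("gamma[", pm$times, "]"))
  }
  if ("phi" %in% model$effects) {
    add_block("phi", A_tm, diag(T), list(diag(T)), hyper_names = "phi",
              family = "temporal_iid",
              x_names = paste0("phi[", pm$times, "]"))
  }
  if ("psi" %in% model$effects && model$interaction != "none") {
    istr <- interaction_structure(model$interaction, T, graph)
    W <- istr$matrix
    if (model$scale_gmrf && model$interaction != "I") W <- scale_structure_matrix(W)
    er <- eig_range(W)
    Z <- restrict_basis(er$Z, orth_rows(diag(T * S)))
    split_psi <- model$split_interaction_variance &&
      model$interaction %in% c("III", "IV")
    if (split_psi) {
      M_list <- lapply(seq_len(C), function(c) {
        mask <- outer(comp_cell == c, comp_cell == c)
        crossprod(Z, (W * mask) %*% Z)
      })
      hn <- sprintf("psi_c%d", seq_len(C))
    } else {
      M_list <- list(crossprod(Z, W %*% Z))
      hn <- "psi"
    }
    cell_names <- paste0("psi[", rep(graph$area_ids, times = T), ",",
                         rep(pm$times, each = S), "]")
    add_block("psi", diag(T * S), Z, M_list, hyper_names = hn,
              family = "interaction", x_names = cell_names)
  }

  n_z <- sum(vapply(blocks, function(b) b$n_z, integer(1)))
  idx <- list()
  pos <- 0L
  A_red <- matrix(0, T * S, n_z)
  for (b in blocks) {
    if (b$n_z == 0L) { idx[[b$name]] <- integer(0); next }
    cols <- pos + seq_len(b$n_z)
    idx[[b$name]] <- cols
    A_red[, cols] <- if (identical(dim(b$Z), dim(diag(b$n_x))) &&
                         all(b$Z == diag(b$n_x))) b$A else b$A %*% b$Z
    pos <- pos + b$n_z
  }

  list(
    pm = pm, graph = graph, model = model,
    blocks = blocks, idx = idx, hyper = hyper,
    n_z = n_z, A_red = A_red,
    O = pm$O, e = pm$e, include = pm$include,
    A_inc = A_red[pm$include, , drop = FALSE],
    O_inc = pm$O[pm$include], e_inc = pm$e[pm$include]
  )
}

# Reduced prior precision Q(theta) and its log determinant.
build_Q <- function(int, theta) {
  n <- int$n_z
  Q <- matrix(0, n, n)
  logdet <- 0
  for (b in int$blocks) {
    if (b$n_z == 0L) next
    cols <- int$idx[[b$name]]
    if (!is.null(b$fixed_prec)) {
      Qb <- b$M[[1]] * b$fixed_prec
      logdet <- logdet + b$n_z * log(b$fixed_prec)
    } else {
      taus <- exp(theta[match(b$hyper, int$hyper$name)])
      Qb <- matrix(0, b$n_z, b$n_z)
      for (g in seq_along(b$M)) Qb <- Qb + taus[[g]] * b$M[[g]]
      Lb <- chol(Qb)
      logdet <- logdet + 2 * sum(log(diag(Lb)))
    }
    Q[cols, cols] <- Qb
  }
  list(Q = Q, logdet = logdet)
}

loglik_eta <- function(int, eta) {
  h <- eta[int$include]
  sum(int$O_inc * (log(int$e_inc) + h) - int$e_inc * exp(pmin(h, 40)) -
        lfactorial(int$O_inc))
}

# Newton-Raphson Gaussian approximation to p(z | y, theta) in the reduced
# coordinates. Latent start at 0 (or a warm start); step-halving on
# objective decrease; converges when the max step falls below `tol`.
newton_mode <- function(int, Q, z0 = NULL, tol = 1e-6, maxit = 50L) {
  n <- int$n_z
  z <- if (is.null(z0)) numeric(n) else z0
  A <- int$A_inc
  O <- int$O_inc; e <- int$e_inc
  obj <- function(z, eta_inc) {
    sum(O * (log(e) + eta_inc) - e * exp(pmin(eta_inc, 40))) -
      0.5 * sum(z * (Q %*% z))
  }
  eta_inc <- drop(A %*% z)
  f <- obj(z, eta_inc)
  trace <- numeric(0)
  L <- NULL
  for (it in seq_len(maxit)) {
    mu <- e * exp(pmin(eta_inc, 40))
    grad <- drop(crossprod(A, O - mu)) - drop(Q %*% z)
    H <- Q + crossprod(A * sqrt(mu))
    L <- tryCatch(chol(H), error = function(err) NULL)
    if (is.null(L)) {
      H <- H + diag(1e-8 * max(diag(H)), n)
      L <- chol(H)
    }
    step <- backsolve(L, forwardsolve(t(L), grad))
    alpha <- 1
    repeat {
      z_new <- z + alpha * step
      eta_new <- drop(A %*% z_new)
      f_new <- obj(z_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { z_new <- z; eta_new <- eta_inc; f_new <- f; break }
    }
    delta <- max(abs(z_new - z))
    trace <- c(trace, delta)
    z <- z_new; eta_inc <- eta_new; f <- f_new
    if (delta < tol) {
      # refresh curvature at the accepted mode
      mu <- e * exp(pmin(eta_inc, 40))
      H <- Q + crossprod(A * sqrt(mu))
      L <- tryCatch(chol(H), error = function(err) chol(H + diag(1e-8 * max(diag(H)), n)))
      return(list(z = z, L = L, iterations = it, converged = TRUE,
                  loglik = sum(O * (log(e) + eta_inc) -
                                 e * exp(pmin(eta_inc, 40)) - lfactorial(O)),
                  quad = 0.5 * sum(z * (Q %*% z))))
    }
  }
  abort(sprintf(
    "Gaussian approximation did not converge in %d iterations (step trace tail: %s).",
    maxit, paste(signif(utils::tail(trace, 5), 3), collapse = ", ")))
}

# Log posterior density of theta up to a constant (Laplace approximation):
# log p(y | z*) + log p(z* | theta) + log p(theta) - log p~_G(z* | y, theta).
log_post_theta <- function(int, theta, z0 = NULL) {
  qq <- build_Q(int, theta)
  nm <- newton_mode(int, qq$Q, z0 = z0)
  lp <- nm$loglik - nm$quad + 0.5 * qq$logdet - sum(log(diag(nm$L))) +
    hyper_log_prior(int$model, theta)
  list(lp = lp, mode = nm, Q = qq$Q)
}

# Log hyperprior density of the log precisions theta (up to a constant),
# Jacobians included.
hyper_log_prior <- function(model, theta) {
  if (!length(theta)) return(0)
  if (model$hyper_prior == "pc") {
    lambda <- -log(model$pc_alpha) / model$pc_u
    sum(-lambda * exp(-theta / 2) - theta / 2)
  } else {
    sum(model$hyper_shape * theta - model$hyper_rate * exp(theta))
  }
}

#' Gaussian approximation at fixed hyperparameters
#'
#' Computes the mode and curvature of the latent field given the data and a
#' fixed set of random-effect variances — the inner step of the approximate
#' inference scheme. Constraints (per-component sum-to-zero, overall
#' sum-to-zero, interaction constraints) hold exactly: the optimization runs
#' on an orthonormal basis of the constraint subspace.
#'
#' @param panel A panel tibble (long format; see [read_panel()]).
#' @param graph An [areal_graph()].
#' @param model An [st_model()].
#' @param variances Named list/vector of variances for the active
#'   hyperparameters (names as in the fit's hyperparameter table, e.g.
#'   `v`, `u`, `gamma`, `phi`, `psi`).
#' @return A list with `x` (named full-space latent mode), `eta` (linear
#'   predictor), `loglik`, `iterations`, and `logdet_posterior`.
#' @export
gaussian_approximation <- function(panel, graph, model = st_model(),
                                   variances = list()) {
  int <- build_internals(panel, graph, model)
  theta <- numeric(nrow(int$hyper))
  names(theta) <- int$hyper$name
  for (nm in names(variances)) {
    if (!nm %in% names(theta)) {
      abort(sprintf("Unknown hyperparameter '%s' (active: %s).", nm,
                    paste(names(theta), collapse = ", ")))
    }
    stopifnot_positive(variances[[nm]], sprintf("variance '%s'", nm))
    theta[[nm]] <- -log(variances[[nm]])
  }
  qq <- build_Q(int, theta)
  nm_fit <- newton_mode(int, qq$Q)
  x <- z_to_x(int, nm_fit$z)
  list(
    x = x,
    eta = drop(int$A_red %*% nm_fit$z),
    loglik = nm_fit$loglik,
    iterations = nm_fit$iterations,
    logdet_posterior = 2 * sum(log(diag(nm_fit$L)))
  )
}

# Map reduced coordinates back to the full named latent vector.
z_to_x <- function(int, z) {
  out <- list()
  for (b in int$blocks) {
    cols <- int$idx[[b$name]]
    xb <- if (b$n_z == 0L) rep(0, b$n_x) else drop(b$Z %*% z[cols])
    names(xb) <- b$x_names
    out[[b$name]] <- xb
  }
  unlist(unname(out))
}

# Hyperparameter exploration: mode search, then a grid (<= 2 dims) or a
# CCD-style axial design, weighted by the Laplace-approximate posterior.
explore_hyper <- function(int) {
  model <- int$model
  n_h <- nrow(int$hyper)
  warm <- new.env(parent = emptyenv())
  warm$z <- NULL
  eval_lp <- function(theta) {
    res <- log_post_theta(int, theta, z0 = warm$z)
    warm$z <- res$mode$z
    res
  }
  if (n_h == 0L) {
    res <- eval_lp(numeric(0))
    return(list(theta = matrix(numeric(0), 1, 0), lp = res$lp, weights = 1,
                modes = list(res$mode), Qs = list(res$Q),
                theta_mode = numeric(0), theta_sd = numeric(0)))
  }
  nll <- function(theta) -eval_lp(theta)$lp
  opt <- tryCatch(
    optim(rep(0, n_h), nll, method = "BFGS",
          control = list(maxit = model$optim_maxit, reltol = 1e-10)),
    error = function(err) NULL
  )
  if (is.null(opt)) {
    opt <- optim(rep(0, n_h), nll, method = "Nelder-Mead",
                 control = list(maxit = 10L * model$optim_maxit, reltol = 1e-9))
  }
  theta_mode <- opt$par
  # numerical curvature (central differences) for grid scaling
  h <- 0.15
  Hm <- matrix(0, n_h, n_h)
  f0 <- -opt$value
  lp_at <- function(th) eval_lp(th)$lp
  for (i in seq_len(n_h)) {
    ei <- replace(numeric(n_h), i, h)
    fpp <- lp_at(theta_mode + ei); fmm <- lp_at(theta_mode - ei)
    Hm[i, i] <- (fpp - 2 * f0 + fmm) / h^2
    if (n_h > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(n_h), j, h)
      fpq <- lp_at(theta_mode + ei + ej); fmq <- lp_at(theta_mode - ei - ej)
      fpm <- lp_at(theta_mode + ei - ej); fmp <- lp_at(theta_mode - ei + ej)
      Hm[i, j] <- Hm[j, i] <- (fpq + fmq - fpm - fmp) / (4 * h^2)
    }
  }
  sds <- rep(0.5, n_h)
  ok <- tryCatch({
    Cv <- solve(-Hm)
    d <- diag(Cv)
    all(d > 0)
  }, error = function(err) FALSE)
  if (isTRUE(ok)) {
    sds <- sqrt(diag(solve(-Hm)))
  } else if (all(diag(Hm) < 0)) {
    sds <- sqrt(-1 / diag(Hm))  # diagonal curvature when cross terms misbehave
  }
  sds <- pmin(pmax(sds, 0.05), 2)

  strategy <- model$hyper_grid
  if (strategy == "auto") strategy <- if (n_h <= 2L) "grid" else "ccd"
  pts <- switch(strategy,
    eb = matrix(theta_mode, 1, n_h, byrow = TRUE),
    grid = {
      axes <- lapply(seq_len(n_h), function(i) {
        theta_mode[i] + seq(-2.5, 2.5, length.out = model$grid_points) * sds[i]
      })
      as.matrix(expand.grid(axes))
    },
    ccd = {
      p <- matrix(theta_mode, 1, n_h, byrow = TRUE)
      for (i in seq_len(n_h)) {
        for (s in c(-1.2, 1.2)) {
          row <- theta_mode
          row[i] <- row[i] + s * sds[i]
          p <- rbind(p, row)
        }
      }
      p
    }
  )
  modes <- vector("list", nrow(pts))
  Qs <- vector("list", nrow(pts))
  lp <- numeric(nrow(pts))
  for (g in seq_len(nrow(pts))) {
    res <- log_post_theta(int, pts[g, ], z0 = warm$z)
    lp[g] <- res$lp
    modes[[g]] <- res$mode
    Qs[[g]] <- res$Q
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  if (all(w == 0) || any(!is.finite(w))) abort("Hyper-grid weights degenerate (grid misplaced).")
  list(theta = pts, lp = lp, weights = w, modes = modes, Qs = Qs,
       theta_mode = theta_mode, theta_sd = sds, strategy = strategy)
}

#' Fit the spatiotemporal areal count model
#'
#' Approximate Bayesian inference for the hierarchical Poisson model: a
#' Gaussian approximation to the latent field combined with numerical
#' integration over the random-effect variance parameters (a simplified
#' integrated-nested-Laplace scheme). Latent posterior marginals are
#' Gaussian mixtures over the hyperparameter design points; fitted relative
#' risks come with credible intervals. The fit is deterministic given the
#' inputs.
#'
#' @inheritParams gaussian_approximation
#' @param seed Integer stored with the fit and used as the default seed for
#'   downstream posterior draws ([dic()], [waic()]).
#' @return An object of class `st_fit` with tibbles `fixed` (term, estimate,
#'   std.error, conf.low, conf.high), `hyper` (one row per variance
#'   parameter), `cells` (per area-period: counts, expected, SMR, posterior
#'   mean/sd of the log relative risk and interval for the relative risk),
#'   `effects` (posterior mean/sd per latent element), plus diagnostics.
#'   Supports [tidy()], [glance()], [autoplot()], [dic()], [waic()],
#'   [variance_partition()].
#' @examples
#' sim <- simulate_panel(lattice_graph(c(4, 4)), n_periods = 3, k = 1, seed = 2)
#' fit <- fit_st(sim$panel, sim$graph,
#'               st_model(effects = c("v", "u"), interaction = "none",
#'                        hyper_grid = "eb"))
#' tidy(fit)
#' @export
fit_st <- function(panel, graph, model = st_model(), seed = 1L) {
  int <- build_internals(panel, graph, model)
  hg <- explore_hyper(int)
  G <- nrow(hg$theta)
  n <- int$n_z

  # per-point latent moments (x-space, plus linear predictor)
  x_mean_g <- vector("list", G)
  x_sd_g <- vector("list", G)
  eta_mean_g <- vector("list", G)
  eta_sd_g <- vector("list", G)
  for (g in seq_len(G)) {
    nm <- hg$modes[[g]]
    Sigma <- chol2inv(nm$L)
    xm <- z_to_x(int, nm$z)
    xv <- numeric(length(xm))
    pos <- 0L
    for (b in int$blocks) {
      cols <- int$idx[[b$name]]
      rows <- pos + seq_len(b$n_x)
      if (b$n_z > 0L) {
        Sb <- Sigma[cols, cols, drop = FALSE]
        ZS <- b$Z %*% Sb
        xv[rows] <- rowSums(ZS * b$Z)
      }
      pos <- pos + b$n_x
    }
    em <- drop(int$A_red %*% nm$z)
    AS <- int$A_red %*% Sigma
    ev <- rowSums(AS * int$A_red)
    x_mean_g[[g]] <- xm
    x_sd_g[[g]] <- sqrt(pmax(xv, 0))
    eta_mean_g[[g]] <- em
    eta_sd_g[[g]] <- sqrt(pmax(ev, 0))
  }
  w <- hg$weights
  mix <- function(means, sds) {
    m <- Reduce(`+`, purrr::map2(means, w, `*`))
    s2 <- Reduce(`+`, purrr::map2(purrr::map2(sds, means,
                                              function(s, mu) s^2 + mu^2),
                                  w, `*`)) - m^2
    list(mean = m, sd = sqrt(pmax(s2, 0)))
  }
  xs <- mix(x_mean_g, x_sd_g)
  es <- mix(eta_mean_g, eta_sd_g)

  x_names <- names(x_mean_g[[1]])
  block_of <- rep(vapply(int$blocks, function(b) b$name, character(1)),
                  times = vapply(int$blocks, function(b) b$n_x, integer(1)))
  effects_tbl <- tibble::tibble(
    block = block_of, term = x_names,
    mean = unname(xs$mean), sd = unname(xs$sd)
  )

  nfix <- int$blocks$fixed$n_x
  fixed_tbl <- tibble::tibble(
    term = int$blocks$fixed$x_names,
    estimate = unname(xs$mean[seq_len(nfix)]),
    std.error = unname(xs$sd[seq_len(nfix)])
  )
  fixed_tbl$conf.low <- fixed_tbl$estimate - 1.96 * fixed_tbl$std.error
  fixed_tbl$conf.high <- fixed_tbl$estimate + 1.96 * fixed_tbl$std.error

  # hyperparameters: mixture moments of the log-precision, reported as
  # variances via lognormal mapping
  hyper_tbl <- NULL
  if (nrow(int$hyper) > 0L) {
    mth <- drop(w %*% hg$theta)
    vth <- drop(w %*% (hg$theta^2)) - mth^2
    if (nrow(hg$theta) == 1L) vth <- hg$theta_sd^2
    sdth <- sqrt(pmax(vth, 1e-12))
    hyper_tbl <- tibble::tibble(
      name = int$hyper$name,
      family = int$hyper$family,
      variance = exp(-mth + vth / 2),
      var.low = exp(-(mth + 1.96 * sdth)),
      var.high = exp(-(mth - 1.96 * sdth)),
      log_precision = mth,
      log_precision_sd = sdth
    )
  } else {
    hyper_tbl <- tibble::tibble(name = character(0), family = character(0),
                                variance = numeric(0), var.low = numeric(0),
                                var.high = numeric(0),
                                log_precision = numeric(0),
                                log_precision_sd = numeric(0))
  }

  p <- int$pm$panel
  cells_tbl <- tibble::tibble(
    area_id = p$area_id, time = p$time,
    deaths = p$deaths, at_risk = p$at_risk, expected = p$expected,
    smr = ifelse(p$expected > 0, p$deaths / p$expected, NA_real_),
    eta_mean = es$mean, eta_sd = es$sd,
    rr = exp(es$mean),
    rr.low = exp(es$mean - 1.96 * es$sd),
    rr.high = exp(es$mean + 1.96 * es$sd)
  )

  res <- structure(
    list(
      model = model, graph = graph,
      fixed = fixed_tbl, hyper = hyper_tbl, cells = cells_tbl,
      effects = effects_tbl,
      grid = list(theta = hg$theta, lp = hg$lp, weights = w,
                  strategy = hg$strategy %||% "none",
                  theta_mode = hg$theta_mode, theta_sd = hg$theta_sd),
      log_evidence = max(hg$lp) + log(sum(exp(hg$lp - max(hg$lp)))),
      iterations = vapply(hg$modes, function(m) m$iterations, integer(1)),
      seed = as.integer(seed),
      internals = list(int = int, modes = hg$modes)
    ),
    class = "st_fit"
  )
  res
}

#' @export
print.st_fit <- function(x, ...) {
  cat(sprintf("<st_fit> %d areas x %d periods; interaction %s; %d hyper point(s) [%s]\n",
              x$internals$int$pm$S, x$internals$int$pm$T,
              x$model$interaction, nrow(x$grid$theta), x$grid$strategy))
  cat("Fixed effects:\n")
  print(as.data.frame(x$fixed), digits = 3)
  if (nrow(x$hyper)) {
    cat("Random-effect variances (posterior mean, 95% interval):\n")
    print(as.data.frame(x$hyper[, c("name", "family", "variance",
                                    "var.low", "var.high")]), digits = 3)
  }
  invisible(x)
}

#' Posterior draws from a fitted model
#'
#' Samples latent configurations from the mixture-of-Gaussians posterior
#' (a hyperparameter design point drawn by its weight, then the latent field
#' from that point's Gaussian approximation). Used by [dic()] and [waic()].
#'
#' @param fit An [fit_st()] result.
#' @param n_draws Number of draws.
#' @param seed Integer seed (defaults to the fit's stored seed).
#' @return A list with `eta` (`n_draws x (T*S)` matrix of linear predictors),
#'   `theta` (`n_draws x n_hyper`), and `fixed` (`n_draws x n_fixed`).
#' @export
posterior_draws <- function(fit, n_draws = 400L, seed = NULL) {
  if (!inherits(fit, "st_fit")) abort("Expected an `st_fit`.")
  seed <- seed %||% fit$seed
  int <- fit$internals$int
  modes <- fit$internals$modes
  G <- nrow(fit$grid$theta)
  n <- int$n_z
  nfix <- int$blocks$fixed$n_x
  with_seed(seed, {
    gs <- sample.int(G, n_draws, replace = TRUE, prob = fit$grid$weights)
    eta <- matrix(0, n_draws, nrow(int$A_red))
    fixed <- matrix(0, n_draws, nfix)
    theta <- matrix(0, n_draws, ncol(fit$grid$theta))
    for (d in seq_len(n_draws)) {
      g <- gs[[d]]
      z <- modes[[g]]$z + backsolve(modes[[g]]$L, rnorm(n))
      eta[d, ] <- drop(int$A_red %*% z)
      fixed[d, ] <- z[int$idx$fixed]
      if (ncol(theta)) theta[d, ] <- fit$grid$theta[g, ]
    }
    colnames(fixed) <- int$blocks$fixed$x_names
    list(eta = eta, theta = theta, fixed = fixed)
  })
}
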