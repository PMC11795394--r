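#' Specify a spatiotemporal areal count model
#'
#' Configuration object for the hierarchical Poisson model of log relative
#' risk: intercept + standardized covariates + structured spatial field
#' (ICAR, `v`) + spatial heterogeneity (iid, `u`) + structured temporal
#' trend (RW1, `gamma`) + unstructured temporal effect (iid, `phi`) +
#' Knorr-Held space-time interaction (`psi`).
#'
#' @param effects Which random-effect families are active; any subset of
#'   `c("v", "u", "gamma", "phi", "psi")`.
#' @param interaction Interaction type: `"none"`, `"I"`, `"II"`, `"III"`,
#'   `"IV"` (default). `"none"` removes `psi` regardless of `effects`.
#' @param split_intercept,split_covariates Estimate a separate intercept /
#'   coefficient vector per connected component (country), implemented as
#'   component-indicator interactions. The non-split fit is the pooled
#'   model.
#' @param split_spatial_variance One ICAR variance per connected component
#'   instead of a common one.
#' @param split_interaction_variance One interaction variance per component
#'   (types III/IV only).
#' @param orthogonalize Add constraints making the structured spatial and
#'   interaction fields orthogonal to the covariate span (restricted spatial
#'   regression, a guard against spatial confounding). Default off.
#' @param hyper_prior Hyperprior family on each random-effect variance:
#'   `"pc"` (default) is a penalized-complexity prior — exponential on the
#'   standard deviation with `P(sd > pc_u) = pc_alpha` — which shrinks
#'   toward the base model without the variance-collapse pathology of vague
#'   gamma priors under weak identifiability; `"gamma"` is the classical
#'   Gamma(`hyper_shape`, `hyper_rate`) prior on each precision.
#' @param pc_u,pc_alpha Scaling of the PC prior (defaults: `P(sd > 1) = 0.01`,
#'   i.e. rate 4.6 on the log-relative-risk sd).
#' @param hyper_shape,hyper_rate Gamma(shape, rate) prior on each precision
#'   when `hyper_prior = "gamma"` (defaults `1` and `5e-4`).
#' @param fixed_prec Gaussian ridge precision on intercept and coefficients
#'   (default `1e-4`, i.e. a vague proper prior).
#' @param scale_gmrf Rescale each intrinsic structure matrix to unit
#'   generalized variance (geometric mean of nonzero eigenvalues = 1) so
#'   variance parameters are comparable across structures. Default off.
#' @param hyper_grid Hyperparameter integration strategy: `"auto"` (grid for
#'   up to 2 variance parameters, CCD-style axial design otherwise),
#'   `"grid"`, `"ccd"`, or `"eb"` (empirical Bayes: posterior mode only).
#' @param grid_points Points per dimension for the full grid (default 7).
#' @param optim_maxit Iteration cap for the hyperparameter mode search.
#' @return An object of class `st_model`.
#' @export
st_model <- function(effects = c("v", "u", "gamma", "phi", "psi"),
                     interaction = "IV",
                     split_intercept = FALSE,
                     split_covariates = FALSE,
                     split_spatial_variance = FALSE,
                     split_interaction_variance = FALSE,
                     orthogonalize = FALSE,
                     hyper_prior = c("pc", "gamma"),
                     pc_u = 1,
                     pc_alpha = 0.01,
                     hyper_shape = 1,
                     hyper_rate = 5e-4,
                     fixed_prec = 1e-4,
                     scale_gmrf = FALSE,
                     hyper_grid = c("auto", "grid", "ccd", "eb"),
                     grid_points = 7L,
                     optim_maxit = 300L) {
  effects <- if (length(effects)) {
    match.arg(effects, c("v", "u", "gamma", "phi", "psi"), several.ok = TRUE)
  } else {
    character(0)
  }
  interaction <- as.character(interaction)
  if (!interaction %in% c("none", "I", "II", "III", "IV")) {
    abort("`interaction` must be one of none, I, II, III, IV.")
  }
  if (interaction == "none") effects <- setdiff(effects, "psi")
  if ("psi" %in% effects && interaction == "none") {
    abort("An interaction effect requires an interaction type.")
  }
  structure(
    list(
      effects = effects,
      interaction = interaction,
      split_intercept = isTRUE(split_intercept),
      split_covariates = isTRUE(split_covariates),
      split_spatial_variance = isTRUE(split_spatial_variance),
      split_interaction_variance = isTRUE(split_interaction_variance),
      orthogonalize = isTRUE(orthogonalize),
      hyper_prior = match.arg(hyper_prior),
      pc_u = pc_u,
      pc_alpha = pc_alpha,
      hyper_shape = hyper_shape,
      hyper_rate = hyper_rate,
      fixed_prec = fixed_prec,
      scale_gmrf = isTRUE(scale_gmrf),
      hyper_grid = match.arg(hyper_grid),
      grid_points = as.integer(grid_points),
      optim_maxit = as.integer(optim_maxit)
    ),
    class = "st_model"
  )
}

#' @export
print.st_model <- function(x, ...) {
  cat("<st_model>\n")
  cat("  effects:", paste(x$effects, collapse = ", "),
      if (length(x$effects) == 0) "(none)", "\n")
  cat("  interaction type:", x$interaction, "\n")
  splits <- c("intercept", "covariates", "spatial variance",
              "interaction variance")[c(x$split_intercept, x$split_covariates,
                                        x$split_spatial_variance,
                                        x$split_interaction_variance)]
  if (length(splits)) cat("  split by component:", paste(splits, collapse = ", "), "\n")
  if (x$orthogonalize) cat("  restricted (covariate-orthogonal) spatial fields\n")
  if (x$hyper_prior == "pc") {
    cat(sprintf("  hyperprior: PC, P(sd > %g) = %g; grid: %s\n",
                x$pc_u, x$pc_alpha, x$hyper_grid))
  } else {
    cat(sprintf("  hyperprior: Gamma(%g, %g) on precisions; grid: %s\n",
                x$hyper_shape, x$hyper_rate, x$hyper_grid))
  }
  invisible(x)
}

# Rescale an intrinsic structure matrix to unit generalized variance.
scale_structure_matrix <- function(W) {
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev[ev > max(ev, 1e-12) * 1e-9]
  gv <- exp(mean(log(1 / pos)))  # generalized variance of the intrinsic GMRF
  W * gv
}

#' Orthogonality (restricted regression) constraint rows
#'
#' Rows `t(X) %*% A_b` constraining an effect block `b` with design map
#' `A_b` so that its mapped field is orthogonal to the covariate span:
#' `t(X) %*% (A_b %*% effect) = 0`.
#'
#' @param X `(T*S) x k` covariate matrix (full column rank).
#' @param map `(T*S) x n_b` design map of the effect block.
#' @return A `k x n_b` constraint matrix.
#' @export
orthogonality_constraints <- function(X, map) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) abort("`X` has no columns.")
  if (qr(X)$rank < ncol(X)) abort("`X` is rank deficient; cannot orthogonalize.")
  crossprod(X, as.matrix(map))
}
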