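#' District-style covariate names
#'
#' Sixteen household-survey covariate labels (proportions per district) used
#' by the synthetic generator, echoing the kind of child-, maternal- and
#' household-level aggregates a demographic survey reports.
#'
#' @return Character vector of length 16.
#' @export
survey_covariate_names <- function() {
  c("pct_nourished", "pct_female", "pct_min_diet_diversity", "pct_first_born",
    "pct_women_literate", "pct_mothers_below_median_age",
    "pct_women_high_autonomy", "pct_basic_sanitation", "pct_improved_water",
    "pct_clean_fuel", "pct_media_exposure", "pct_mother_working",
    "pct_father_working", "pct_rural", "pct_facility_delivery",
    "pct_poor_wealth")
}

#' Disconnected grid-lattice areal graph
#'
#' Builds a multi-component areal map from disjoint rook-contiguity grid
#' lattices — a stand-in for several countries with no shared borders. Each
#' component of size `m` is laid out row-major on a near-square grid
#' (`ceiling(sqrt(m))` columns) truncated to `m` cells. The default sizes
#' `c(11, 10, 9, 7)` give 37 areas in 4 components, mirroring a four-country,
#' 37-district map.
#'
#' @param sizes Integer vector of component sizes.
#' @return An [areal_graph()] whose `area_ids` are `"c<comp>_a<index>"`. Grid
#'   coordinates are attached as attribute `"coords"` (tibble `area_id`,
#'   `row`, `col`, `component`) for plotting.
#' @export
lattice_graph <- function(sizes = c(11L, 10L, 9L, 7L)) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(sizes < 1L)) {
    abort("`sizes` must be positive component sizes.")
  }
  ids <- character(0)
  edges <- list()
  coords <- list()
  col_offset <- 0L
  for (cidx in seq_along(sizes)) {
    m <- sizes[[cidx]]
    ncols <- ceiling(sqrt(m))
    cid <- sprintf("c%d_a%d", cidx, seq_len(m))
    ids <- c(ids, cid)
    rows <- (seq_len(m) - 1L) %/% ncols + 1L
    cols <- (seq_len(m) - 1L) %% ncols + 1L
    coords[[cidx]] <- tibble::tibble(area_id = cid, row = rows,
                                     col = cols + col_offset,
                                     component = cidx)
    for (a in seq_len(m)) {
      # right neighbour
      if (cols[a] < ncols && a + 1L <= m) {
        edges[[length(edges) + 1L]] <- c(cid[a], cid[a + 1L])
      }
      # down neighbour
      if (a + ncols <= m) {
        edges[[length(edges) + 1L]] <- c(cid[a], cid[a + ncols])
      }
    }
    col_offset <- col_offset + ncols + 1L  # visual gap between components
  }
  edf <- if (length(edges)) {
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0))
  }
  g <- areal_graph(edf, area_ids = ids)
  attr(g, "coords") <- dplyr::bind_rows(coords)
  g
}

#' Simulate a spatiotemporal areal count panel with known truth
#'
#' Generates a survey-style district panel on a (possibly disconnected)
#' areal graph under the full spatiotemporal model: standardized covariates
#' with fixed effects, an ICAR spatial field, iid spatial heterogeneity, an
#' RW1 temporal trend, iid temporal noise, and a Knorr-Held space-time
#' interaction of the chosen type. Counts are Poisson with internally
#' standardized expected counts as offset; a two-pass scheme (a provisional
#' draw fixes the pooled rate) makes the generator's expected-count
#' definition identical to the analysis side's.
#'
#' Covariates are generated with AR(1) temporal autocorrelation and
#' component-level mean shifts, so they are confounded with the spatial
#' structure the way real district covariates are; raw values are logistic
#' proportions, then standardized to mean 0 / sd 1.
#'
#' @param graph An [areal_graph()]; default the 37-area four-component
#'   lattice of [lattice_graph()].
#' @param n_periods Number of survey periods `T` (default 4).
#' @param k Number of covariates (<= 16; named by [survey_covariate_names()]).
#' @param beta0 True intercept (log relative-risk scale).
#' @param beta True coefficient vector (length `k`) on the standardized
#'   covariates.
#' @param variances Named list of true random-effect variances
#'   (`v`, `u`, `gamma`, `phi`, `psi`); set an entry to 0 to switch the
#'   effect off.
#' @param interaction Interaction type `"I"`..`"IV"` or `"none"`.
#' @param n_range Range (min, max) of per-cell at-risk totals, drawn
#'   uniformly (default 500-8000, echoing district survey denominators).
#' @param baseline_rate Pooled event rate used for the provisional draw
#'   (default 0.09, a typical under-five mortality proportion).
#' @param rho AR(1) coefficient of the covariate process (default 0.7).
#' @param seed Integer seed; the same seed reproduces the panel bit for bit.
#' @return A list of class `st_sim`: `panel` (tibble with `area_id`, `time`,
#'   `deaths`, `at_risk`, `expected`, standardized covariates), `graph`, and
#'   `truth` (all effect vectors, parameters and the seed).
#' @export
simulate_panel <- function(graph = lattice_graph(),
                           n_periods = 4L,
                           k = 3L,
                           beta0 = 0,
                           beta = NULL,
                           variances = list(v = 0.3, u = 0.05, gamma = 0.36,
                                            phi = 0.02, psi = 0.1),
                           interaction = "IV",
                           n_range = c(500L, 8000L),
                           baseline_rate = 0.09,
                           rho = 0.7,
                           seed = 1L) {
  check_areal_graph(graph)
  T <- as.integer(n_periods)
  if (T < 2L) abort("`n_periods` must be at least 2 (RW1 needs T >= 2).")
  S <- graph$n_areas
  k <- as.integer(k)
  if (k < 0L || k > 16L) abort("`k` must be between 0 and 16.")
  if (is.null(beta)) {
    beta <- if (k > 0) c(-0.4, 0.25, 0.15, rep(0.1, max(0, k - 3)))[seq_len(k)]
    else numeric(0)
  }
  if (length(beta) != k) abort("`beta` must have length `k`.")
  vdef <- list(v = 0.3, u = 0.05, gamma = 0.36, phi = 0.02, psi = 0.1)
  variances <- modifyList(vdef, as.list(variances))
  if (any(unlist(variances) < 0)) abort("Variances must be nonnegative.")
  itype <- as.character(interaction)
  if (!itype %in% c("I", "II", "III", "IV", "none")) {
    abort("`interaction` must be one of I, II, III, IV, none.")
  }

  cov_names <- survey_covariate_names()[seq_len(k)]
  comp <- graph$component

  gen <- function() {
    # covariates: component shift + area level + AR(1) in time, on the
    # logistic scale so raw values are proportions
    X_raw <- matrix(0, T * S, k)
    if (k > 0) {
      for (j in seq_len(k)) {
        shift <- rnorm(graph$n_components, 0, 0.7)
        a_lev <- rnorm(S, shift[comp], 0.4)
        z <- matrix(0, S, T)
        z[, 1] <- rnorm(S)
        if (T > 1) for (t in 2:T) z[, t] <- rho * z[, t - 1] + sqrt(1 - rho^2) * rnorm(S)
        lat <- a_lev[row(z)] + 0.6 * z
        X_raw[, j] <- as.vector(lat)  # time-major: T blocks of S
      }
      X_raw <- stats::plogis(X_raw)
    }

    # random effects, each on its constrained range space
    v <- if (variances$v > 0) {
      sample_gmrf(icar_structure(graph), variances$v)
    } else rep(0, S)
    u <- if (variances$u > 0) rnorm(S, 0, sqrt(variances$u)) else rep(0, S)
    gam <- if (variances$gamma > 0) {
      sample_gmrf(rw1_structure(T), variances$gamma)
    } else rep(0, T)
    phi <- if (variances$phi > 0) {
      x <- rnorm(T, 0, sqrt(variances$phi)); x
    } else rep(0, T)
    psi <- if (itype != "none" && variances$psi > 0) {
      sample_gmrf(interaction_structure(itype, T, graph), variances$psi)
    } else rep(0, T * S)

    N <- matrix(sample(seq.int(n_range[[1]], n_range[[2]]), S * T, replace = TRUE),
                S, T)

    panel <- tidyr::expand_grid(time = seq_len(T), area_id = graph$area_ids)
    if (k > 0) {
      Xs <- X_raw
      colnames(Xs) <- cov_names
      panel <- dplyr::bind_cols(panel, tibble::as_tibble(Xs))
      panel <- standardize_covariates(panel, cov_names)
      Xstd <- as.matrix(panel[, cov_names, drop = FALSE])
    } else {
      Xstd <- matrix(0, T * S, 0)
    }

    eta <- assemble_eta(S, T, intercept = beta0, X = Xstd, beta = beta,
                        v = v, u = u, gamma = gam, phi = phi, psi = psi)

    # two-pass expected counts: a provisional draw at the configured pooled
    # rate fixes the internal-standardization rate, then final counts are
    # drawn from e * exp(eta)
    Nvec <- as.vector(N)  # time-major (S rows per time block)
    O_prov <- rpois(T * S, Nvec * baseline_rate * exp(eta))
    e <- Nvec * (sum(O_prov) / sum(Nvec))
    O <- rpois(T * S, e * exp(eta))

    panel$deaths <- O
    panel$at_risk <- Nvec
    panel <- add_expected_counts(panel)

    truth <- list(
      beta0 = beta0, beta = setNames(beta, cov_names),
      v = v, u = u, gamma = gam, phi = phi, psi = psi,
      variances = variances, interaction = itype,
      S = S, T = T, k = k, seed = as.integer(seed)
    )
    list(panel = panel, graph = graph, truth = truth)
  }

  out <- with_seed(seed, gen())
  class(out) <- "st_sim"
  out
}

#' @export
print.st_sim <- function(x, ...) {
  cat(sprintf("<st_sim> %d areas x %d periods, %d covariates, interaction %s, seed %d\n",
              x$truth$S, x$truth$T, x$truth$k, x$truth$interaction,
              x$truth$seed))
  cat(sprintf("  total deaths %d / at-risk %d\n",
              sum(x$panel$deaths), sum(x$panel$at_risk)))
  invisible(x)
}
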