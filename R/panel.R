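#' Internally standardized expected counts
#'
#' Adds the expected count `expected = at_risk * (sum(deaths) / sum(at_risk))`
#' to an areal panel: the pooled event rate over all areas and periods,
#' allocated to each cell's exposure (internal standardization). By
#' construction `sum(expected) == sum(deaths)` exactly. Cells with zero
#' exposure get `expected = 0` and are excluded from any likelihood.
#'
#' @param panel A data frame with one row per area-period, containing the
#'   count and exposure columns.
#' @param deaths,at_risk Column names (strings) of the event counts and
#'   at-risk totals.
#' @param by Optional column name to standardize within (e.g. `"time"` for
#'   per-period standardization); default pools over the whole panel.
#' @return The panel as a tibble with an `expected` column added.
#' @examples
#' p <- tibble::tibble(area_id = c("a", "b"), time = 1L,
#'                     deaths = c(10, 20), at_risk = c(100, 300))
#' add_expected_counts(p)$expected # 7.5, 22.5
#' @export
add_expected_counts <- function(panel, deaths = "deaths", at_risk = "at_risk",
                                by = NULL) {
  panel <- tibble::as_tibble(panel)
  O <- panel[[deaths]]
  N <- panel[[at_risk]]
  if (is.null(O) || is.null(N)) abort("`deaths` / `at_risk` columns not found.")
  if (any(N < 0) || any(O < 0)) abort("Counts and exposures must be nonnegative.")
  if (sum(N) <= 0) abort("All at-risk totals are zero; cannot standardize.")
  if (is.null(by)) {
    panel$expected <- N * (sum(O) / sum(N))
  } else {
    g <- panel[[by]]
    rate <- tapply(O, g, sum) / tapply(N, g, sum)
    panel$expected <- N * as.numeric(rate[as.character(g)])
  }
  panel
}

#' Standardized mortality ratios
#'
#' Adds `smr = deaths / expected` per cell. Cells with `expected == 0` are
#' reported as `NA`; if such a cell has positive deaths a warning is raised
#' (the ratio is undefined there).
#'
#' @param panel A panel tibble with `deaths` and `expected` columns (see
#'   [add_expected_counts()]).
#' @param deaths,expected Column names.
#' @return The panel with an `smr` column added.
#' @export
add_smr <- function(panel, deaths = "deaths", expected = "expected") {
  panel <- tibble::as_tibble(panel)
  O <- panel[[deaths]]
  e <- panel[[expected]]
  if (is.null(e)) abort("No `expected` column; call add_expected_counts() first.")
  smr <- ifelse(e > 0, O / e, NA_real_)
  if (any(e == 0 & O > 0)) {
    warn("SMR undefined for cells with zero expected count but positive deaths; set to NA.")
  }
  panel$smr <- smr
  panel
}

#' Standardize covariate columns
#'
#' Centres and scales covariate columns to mean 0, sd 1 using the population
#' convention (divide by `n`). The transform parameters are stored in the
#' `"covariate_scaling"` attribute so fitted coefficients can be mapped back
#' to the raw proportion scale.
#'
#' @param panel A panel tibble.
#' @param cols Character vector of covariate column names. Defaults to every
#'   numeric column other than the reserved panel columns
#'   (`time`, `deaths`, `at_risk`, `expected`, `smr`).
#' @return The panel with standardized covariates and a `covariate_scaling`
#'   attribute (tibble: `column`, `mean`, `sd`).
#' @export
standardize_covariates <- function(panel, cols = NULL) {
  panel <- tibble::as_tibble(panel)
  reserved <- c("area_id", "time", "time_index", "deaths", "at_risk",
                "expected", "smr", "component")
  if (is.null(cols)) {
    cols <- setdiff(names(panel)[vapply(panel, is.numeric, logical(1))], reserved)
  }
  if (length(cols) == 0L) abort("No covariate columns to standardize.")
  sc <- purrr::map_dfr(cols, function(cn) {
    x <- panel[[cn]]
    s <- pop_sd(x)
    if (!is.finite(s) || s <= 0) {
      abort(sprintf("Covariate column '%s' is constant; cannot standardize.", cn))
    }
    tibble::tibble(column = cn, mean = mean(x), sd = s)
  })
  for (r in seq_len(nrow(sc))) {
    cn <- sc$column[[r]]
    panel[[cn]] <- (panel[[cn]] - sc$mean[[r]]) / sc$sd[[r]]
  }
  attr(panel, "covariate_scaling") <- sc
  panel
}

#' Poisson log-likelihood of an areal panel
#'
#' The log-likelihood of counts `O` under mean `expected * exp(eta)`, i.e.
#' `sum(O * (log(expected) + eta) - expected * exp(eta) - log(O!))` over cells
#' with positive exposure. `eta` is the log relative risk (linear predictor);
#' `log(expected)` enters as the offset.
#'
#' @param deaths Nonnegative integer counts.
#' @param expected Positive expected counts (cells with 0 are excluded).
#' @param eta Linear predictor, same length.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(deaths, expected, eta) {
  if (length(deaths) != length(expected) || length(deaths) != length(eta)) {
    abort("`deaths`, `expected` and `eta` must have equal length.")
  }
  if (any(deaths < 0) || any(abs(deaths - round(deaths)) > 1e-8)) {
    abort("`deaths` must be nonnegative integers.")
  }
  keep <- expected > 0
  O <- deaths[keep]; e <- expected[keep]; h <- eta[keep]
  sum(O * (log(e) + h) - e * exp(h) - lfactorial(O))
}

#' Layout of the stacked latent effect vector
#'
#' Index slices for each block of the latent field of the spatiotemporal
#' model: intercept(s), covariate coefficients, structured spatial (`v`),
#' spatial heterogeneity (`u`), temporal trend (`gamma`), unstructured
#' temporal (`phi`) and space-time interaction (`psi`). With component
#' splitting the intercept and/or coefficients are replicated per connected
#' component.
#'
#' @param S,T Number of areas and periods.
#' @param k Number of covariates.
#' @param n_components Number of connected components `C`.
#' @param split_intercept,split_covariates Replicate per component?
#' @param effects Character vector of active random effects among
#'   `c("v", "u", "gamma", "phi", "psi")`.
#' @return A list of class `latent_layout` with an index vector per block and
#'   `total` length.
#' @export
latent_layout <- function(S, T, k = 0L, n_components = 1L,
                          split_intercept = FALSE, split_covariates = FALSE,
                          effects = c("v", "u", "gamma", "phi", "psi")) {
  sizes <- c(
    intercept = if (split_intercept) n_components else 1L,
    beta = if (split_covariates) k * n_components else k,
    v = if ("v" %in% effects) S else 0L,
    u = if ("u" %in% effects) S else 0L,
    gamma = if ("gamma" %in% effects) T else 0L,
    phi = if ("phi" %in% effects) T else 0L,
    psi = if ("psi" %in% effects) T * S else 0L
  )
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  slices <- purrr::map2(unname(starts), unname(ends),
                        function(a, b) if (b >= a) seq.int(a, b) else integer(0))
  names(slices) <- names(sizes)
  structure(c(slices, list(total = sum(sizes))), class = "latent_layout")
}

#' Sparse design maps of the spatiotemporal linear predictor
#'
#' The matrices that map each stacked effect block onto the length-`T*S`
#' linear predictor, in time-major cell order (`T` blocks of `S` areas):
#' the intercept column of ones, `1_T (x) I_S` for the spatial blocks,
#' `I_T (x) 1_S` for the temporal blocks and `I_TS` for the interaction.
#' Multiplying each map by its effect and summing reproduces the elementwise
#' linear predictor `eta[i, t]`.
#'
#' @param S,T Number of areas and periods.
#' @return Named list of `Matrix` sparse matrices:
#'   `intercept`, `spatial`, `temporal`, `interaction`.
#' @export
design_maps <- function(S, T) {
  IS <- Matrix::Diagonal(S)
  IT <- Matrix::Diagonal(T)
  list(
    intercept = Matrix::Matrix(1, T * S, 1),
    spatial = Matrix::kronecker(Matrix::Matrix(1, T, 1), IS),
    temporal = Matrix::kronecker(IT, Matrix::Matrix(1, S, 1)),
    interaction = Matrix::Diagonal(T * S)
  )
}

#' Assemble a linear predictor from effect blocks
#'
#' @param S,T Dimensions.
#' @param intercept Scalar overall level, or per-component values with
#'   `component` supplied.
#' @param X Optional `(T*S) x k` covariate matrix (time-major rows).
#' @param beta Coefficient vector matching `X`.
#' @param v,u Length-`S` spatial effects.
#' @param gamma,phi Length-`T` temporal effects.
#' @param psi Length-`T*S` interaction effect (time-major).
#' @param component Optional per-area component labels for a split intercept.
#' @return Length-`T*S` numeric `eta` in time-major order.
#' @export
assemble_eta <- function(S, T, intercept = 0, X = NULL, beta = NULL,
                         v = NULL, u = NULL, gamma = NULL, phi = NULL,
                         psi = NULL, component = NULL) {
  maps <- design_maps(S, T)
  eta <- numeric(T * S)
  if (length(intercept) == 1L) {
    eta <- eta + intercept
  } else {
    if (is.null(component)) abort("Per-component intercept needs `component` labels.")
    eta <- eta + rep(intercept[component], times = T)
  }
  if (!is.null(X)) {
    if (is.null(beta) || ncol(X) != length(beta)) abort("`beta` must match `X` columns.")
    eta <- eta + drop(as.matrix(X) %*% beta)
  }
  if (!is.null(v)) eta <- eta + drop(as.matrix(maps$spatial %*% v))
  if (!is.null(u)) eta <- eta + drop(as.matrix(maps$spatial %*% u))
  if (!is.null(gamma)) eta <- eta + drop(as.matrix(maps$temporal %*% gamma))
  if (!is.null(phi)) eta <- eta + drop(as.matrix(maps$temporal %*% phi))
  if (!is.null(psi)) eta <- eta + psi
  eta
}

# Validate a long panel against a graph and return dense matrices in
# time-major order. Covariate columns are taken from `covariates` (names).
panel_matrices <- function(panel, graph, covariates = NULL) {
  check_areal_graph(graph)
  panel <- tibble::as_tibble(panel)
  need <- c("area_id", "time", "deaths", "at_risk")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    abort(sprintf("Panel is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  times <- sort(unique(panel$time))
  T <- length(times)
  S <- graph$n_areas
  if (nrow(panel) != S * T) {
    abort(sprintf("Panel must be complete: expected %d rows (%d areas x %d periods), got %d.",
                  S * T, S, T, nrow(panel)))
  }
  if (!all(panel$area_id %in% graph$area_ids)) {
    abort("Panel contains area ids absent from the graph.")
  }
  key <- order(match(panel$time, times), match(panel$area_id, graph$area_ids))
  panel <- panel[key, ]
  if (is.null(covariates)) {
    reserved <- c("area_id", "time", "time_index", "deaths", "at_risk",
                  "expected", "smr", "component")
    covariates <- setdiff(names(panel)[vapply(panel, is.numeric, logical(1))],
                          reserved)
  }
  if (!"expected" %in% names(panel)) panel <- add_expected_counts(panel)
  X <- if (length(covariates)) as.matrix(panel[, covariates, drop = FALSE]) else
    matrix(0, S * T, 0)
  list(
    panel = panel,
    S = S, T = T, times = times,
    O = panel$deaths,
    N = panel$at_risk,
    e = panel$expected,
    X = X,
    covariates = covariates,
    include = panel$expected > 0
  )
}

#' Read / write a long-format areal panel CSV
#'
#' The canonical exchange format: columns `area_id`, `time` (or
#' `time_index`), `deaths`, `at_risk`, plus covariate columns. Validated on
#' load with explicit error messages.
#'
#' @param path File path.
#' @return A panel tibble.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  if ("time_index" %in% names(panel) && !"time" %in% names(panel)) {
    panel <- dplyr::rename(panel, time = "time_index")
  }
  need <- c("area_id", "time", "deaths", "at_risk")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    abort(sprintf("Panel file %s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(panel$deaths < 0) || any(panel$at_risk < 0)) {
    abort("Negative counts/exposures in panel file.")
  }
  panel
}

#' @rdname read_panel
#' @param panel A panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(panel), path)
  invisible(path)
}

#' SMR table
#'
#' Convenience wrapper producing (and optionally writing) the per-cell table
#' of observed, at-risk, expected counts and SMR.
#'
#' @param panel A panel tibble.
#' @param path Optional CSV output path.
#' @return Tibble with `area_id`, `time`, `deaths`, `at_risk`, `expected`,
#'   `smr`.
#' @export
smr_table <- function(panel, path = NULL) {
  panel <- tibble::as_tibble(panel)
  if (!"expected" %in% names(panel)) panel <- add_expected_counts(panel)
  if (!"smr" %in% names(panel)) panel <- add_smr(panel)
  out <- dplyr::select(panel, dplyr::all_of(c("area_id", "time", "deaths",
                                              "at_risk", "expected", "smr")))
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
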