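#' GMRF structure matrices
#'
#' A `gmrf_structure` packages the (scaled-precision) structure matrix of a
#' Gaussian Markov random field together with its rank and an orthonormal
#' basis of its null space. Intrinsic priors — ICAR in space, first-order
#' random walk (RW1) in time, and their Kronecker-product space-time
#' interactions — are rank-deficient; the null basis defines the sum-to-zero
#' constraints that make the corresponding effects identifiable.
#'
#' @name gmrf_structure
#' @return All constructors return a list of class `gmrf_structure` with
#'   elements `matrix` (dense symmetric PSD), `rank`, `null_basis`
#'   (n x nullity, orthonormal columns), `label`, and (for graph-based
#'   structures) `component` labels per coordinate.
NULL

new_gmrf_structure <- function(matrix, rank, null_basis, label,
                               component = NULL, isolated = NULL) {
  structure(
    list(
      matrix = matrix,
      rank = as.integer(rank),
      null_basis = null_basis,
      label = label,
      component = component,
      isolated = isolated
    ),
    class = "gmrf_structure"
  )
}

#' @export
print.gmrf_structure <- function(x, ...) {
  n <- nrow(x$matrix)
  cat(sprintf("<gmrf_structure: %s> %d x %d, rank %d, nullity %d\n",
              x$label, n, n, x$rank, n - x$rank))
  invisible(x)
}

#' Intrinsic CAR (ICAR) spatial structure matrix
#'
#' Builds the joint ICAR structure `W = D - A`, where `D` is the diagonal
#' matrix of neighbour counts and `A` the 0/1 adjacency. Conditionally, each
#' area's effect is Gaussian around the mean of its neighbours with variance
#' inversely proportional to its neighbour count — the joint `D - A` form
#' reproduces both. On a graph with `C` connected components the matrix has
#' rank `S - C`; the null space is spanned by the per-component indicator
#' vectors, so identification requires one sum-to-zero constraint per
#' component. Isolated areas contribute an all-zero row: their structured
#' spatial effect is pinned to zero by the constraint and any residual area
#' heterogeneity is absorbed by the iid term.
#'
#' @param graph An [areal_graph()].
#' @return A [gmrf_structure] labelled `"icar"`.
#' @examples
#' g <- areal_graph(data.frame(from = c("a", "b"), to = c("b", "c")),
#'                  area_ids = c("a", "b", "c"))
#' icar_structure(g)$matrix
#' @export
icar_structure <- function(graph) {
  check_areal_graph(graph)
  S <- graph$n_areas
  A <- adjacency_matrix(graph)
  W <- diag(rowSums(A), S) - A
  dimnames(W) <- list(graph$area_ids, graph$area_ids)
  comp <- graph$component
  C <- graph$n_components
  nb <- matrix(0, S, C)
  for (c in seq_len(C)) {
    idx <- comp == c
    nb[idx, c] <- 1 / sqrt(sum(idx))
  }
  new_gmrf_structure(
    W, rank = S - C, null_basis = nb, label = "icar",
    component = comp, isolated = unname(which(rowSums(A) == 0))
  )
}

#' First-order random-walk (RW1) temporal structure matrix
#'
#' The intrinsic prior penalizing squared first differences of a time
#' effect: tridiagonal with 1 on the two corner diagonals entries and 2 on
#' the interior diagonal, -1 off-diagonal. Rank `T - 1`; null space the
#' constant vector, giving the usual overall sum-to-zero constraint.
#'
#' @param n_periods Number of time points `T` (>= 2).
#' @return A [gmrf_structure] labelled `"rw1"`.
#' @export
rw1_structure <- function(n_periods) {
  T <- as.integer(n_periods)
  if (is.na(T) || T < 2L) abort("RW1 needs at least 2 time periods.")
  D <- diff(diag(T))        # (T-1) x T first-difference operator
  W <- crossprod(D)
  nb <- matrix(1 / sqrt(T), T, 1)
  new_gmrf_structure(W, rank = T - 1L, null_basis = nb, label = "rw1")
}

#' Exchangeable (iid) structure matrix
#'
#' Identity structure for unstructured heterogeneity: full rank, no
#' constraints.
#'
#' @param n Dimension (>= 1).
#' @return A [gmrf_structure] labelled `"iid"`.
#' @export
iid_structure <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be a positive integer.")
  new_gmrf_structure(diag(n), rank = n, null_basis = matrix(0, n, 0),
                     label = "iid")
}

#' Knorr-Held space-time interaction structure
#'
#' The four canonical interaction priors arise as Kronecker products of a
#' temporal factor (identity or RW1) and a spatial factor (identity or ICAR),
#' in time-major order (the length-`T*S` interaction vector is laid out as
#' `T` blocks of `S` areas):
#'
#' * type I:  `I_T (x) I_S`  — fully unstructured; rank `T*S`
#' * type II: `W_rw1 (x) I_S` — each area has its own random walk; rank `(T-1)*S`
#' * type III: `I_T (x) W_icar` — each period has its own spatial field; rank `T*(S-C)`
#' * type IV: `W_rw1 (x) W_icar` — spatially and temporally structured; rank `(T-1)*(S-C)`
#'
#' The null basis is assembled from Kronecker products of the factors'
#' eigenvectors, hence orthonormal; its dimension equals the number of
#' sum-to-zero constraints the interaction needs.
#'
#' @param type One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param n_periods Number of time points `T` (>= 2).
#' @param graph An [areal_graph()] with `S` areas.
#' @return A [gmrf_structure] labelled `"interaction-<type>"`, carrying the
#'   per-cell component label (the component of the cell's area).
#' @export
interaction_structure <- function(type, n_periods, graph) {
  type <- toupper(as.character(type))
  if (!type %in% c("I", "II", "III", "IV")) {
    abort(sprintf("Unknown interaction type '%s' (use I, II, III or IV).", type))
  }
  check_areal_graph(graph)
  T <- as.integer(n_periods)
  if (is.na(T) || T < 2L) abort("Interactions need at least 2 time periods.")
  S <- graph$n_areas
  C <- graph$n_components
  Wt <- switch(type, I = diag(T), II = rw1_structure(T)$matrix,
               III = diag(T), IV = rw1_structure(T)$matrix)
  icar <- if (type %in% c("III", "IV")) icar_structure(graph) else NULL
  Ws <- if (is.null(icar)) diag(S) else icar$matrix
  W <- kronecker(Wt, Ws)
  # Orthonormal null basis from the factors' eigenpairs: a Kronecker
  # eigenvalue is zero iff either factor eigenvalue is zero.
  et <- eigen(Wt, symmetric = TRUE)
  es <- eigen(Ws, symmetric = TRUE)
  tol_t <- max(et$values, 1e-12) * 1e-9
  tol_s <- max(es$values, 1e-12) * 1e-9
  zt <- which(abs(et$values) <= tol_t)
  zs <- which(abs(es$values) <= tol_s)
  cols <- list()
  for (i in zt) cols <- c(cols, lapply(seq_len(S), function(j)
    kronecker(et$vectors[, i], es$vectors[, j])))
  for (j in zs) for (i in setdiff(seq_len(T), zt)) {
    cols <- c(cols, list(kronecker(et$vectors[, i], es$vectors[, j])))
  }
  nb <- if (length(cols)) do.call(cbind, cols) else matrix(0, T * S, 0)
  rank <- switch(type,
    I = T * S,
    II = (T - 1L) * S,
    III = T * (S - C),
    IV = (T - 1L) * (S - C)
  )
  stopifnot(ncol(nb) == T * S - rank)
  new_gmrf_structure(
    W, rank = rank, null_basis = nb,
    label = paste0("interaction-", type),
    component = rep(graph$component, times = T)
  )
}

#' Sum-to-zero constraint set of an intrinsic structure
#'
#' One linear constraint per null-basis vector: for the ICAR these are
#' per-component sum-to-zero constraints, for the RW1 the overall
#' sum-to-zero constraint, and for the structured interactions the standard
#' Knorr-Held constraint sets arising from the Kronecker null space.
#'
#' @param structure A [gmrf_structure].
#' @return A list of class `gmrf_constraints` with `matrix` (m x n constraint
#'   rows) and `rhs` (zeros).
#' @export
constraint_set <- function(structure) {
  if (!inherits(structure, "gmrf_structure")) {
    abort("Expected a `gmrf_structure`.")
  }
  A <- t(structure$null_basis)
  structure(list(matrix = A, rhs = rep(0, nrow(A))), class = "gmrf_constraints")
}

#' Sample a (constrained) Gaussian Markov random field
#'
#' Draws from the density proportional to `exp(-x' W x / (2 * variance))`
#' restricted to the subspace where all constraints hold. Sampling is
#' spectral: only the range-space eigendirections (positive eigenvalues)
#' receive mass, which enforces the structure's intrinsic sum-to-zero
#' constraints exactly; any additional constraint rows are imposed by
#' conditioning by kriging (mean/covariance correction).
#'
#' @param structure A [gmrf_structure].
#' @param variance Scalar variance parameter (> 0).
#' @param constraints Optional extra constraint rows (matrix with `n`
#'   columns, or a `gmrf_constraints` object) beyond the structure's own
#'   null-space constraints.
#' @param seed Optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param n_samples Number of draws.
#' @return A length-`n` vector, or an `n x n_samples` matrix if
#'   `n_samples > 1`.
#' @export
sample_gmrf <- function(structure, variance, constraints = NULL, seed = NULL,
                        n_samples = 1L) {
  if (!inherits(structure, "gmrf_structure")) abort("Expected a `gmrf_structure`.")
  stopifnot_positive(variance, "`variance`")
  W <- structure$matrix
  n <- nrow(W)
  ev <- eigen(W, symmetric = TRUE)
  tol <- max(ev$values, 1e-12) * 1e-9
  keep <- ev$values > tol
  Vr <- ev$vectors[, keep, drop = FALSE]
  lam <- ev$values[keep]
  draw <- function() {
    z <- rnorm(sum(keep))
    x <- Vr %*% (z * sqrt(variance / lam))
    drop(x)
  }
  do_draws <- function() {
    X <- matrix(0, n, n_samples)
    for (s in seq_len(n_samples)) X[, s] <- draw()
    X
  }
  X <- if (is.null(seed)) do_draws() else with_seed(seed, do_draws())
  Cm <- constraints
  if (inherits(Cm, "gmrf_constraints")) Cm <- Cm$matrix
  if (!is.null(Cm) && nrow(Cm) > 0L) {
    # Conditioning by kriging on the range-space covariance
    # Sigma = Vr diag(variance / lam) Vr'.
    SigAt <- Vr %*% (t(Cm %*% Vr) * (variance / lam))   # n x m
    M <- Cm %*% SigAt                                    # m x m
    X <- X - SigAt %*% solve(M, Cm %*% X)
  }
  if (n_samples == 1L) drop(X) else X
}

#' Export a structure matrix in Matrix Market format
#'
#' @param structure A [gmrf_structure].
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_structure_mm <- function(structure, path) {
  if (!inherits(structure, "gmrf_structure")) abort("Expected a `gmrf_structure`.")
  M <- methods::as(methods::as(Matrix::Matrix(structure$matrix, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(M, path)
  invisible(path)
}
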