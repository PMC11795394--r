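#' @importFrom rlang abort warn inform %||%
#' @importFrom stats dpois optim rnorm runif rpois var sd setNames dgamma quantile
#' @importFrom utils head modifyList
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103L + as.double(stream) * 12347L) %% 2147483587)
}

# Population-convention standard deviation (divide by n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

pop_var <- function(x) mean((x - mean(x))^2)

# Orthonormal basis of the null space of a set of constraint rows applied to
# the columns of Z (i.e. vectors z with C %*% Z %*% v = 0), returned as the
# restricted basis Z %*% V.
restrict_basis <- function(Z, C_rows, tol = 1e-10) {
  if (is.null(C_rows) || nrow(C_rows) == 0L) return(Z)
  B <- C_rows %*% Z
  sv <- svd(B, nu = 0, nv = ncol(Z))
  keep <- sv$d <= tol * max(sv$d, 1)
  n_zero <- ncol(Z) - sum(sv$d > tol * max(sv$d, 1))
  if (n_zero == 0L) {
    return(Z[, 0, drop = FALSE])
  }
  V <- sv$v[, (ncol(Z) - n_zero + 1L):ncol(Z), drop = FALSE]
  Z %*% V
}

stopifnot_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("%s must be strictly positive and finite.", what))
  }
  invisible(x)
}
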