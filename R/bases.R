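#' Natural cubic spline basis over age
#'
#' Natural cubic spline basis (linear beyond the boundary knots, zero second
#' derivative at the boundaries) evaluated at age-band midpoints, without an
#' intercept column. With fewer than 3 distinct ages the basis falls back to
#' a single centered linear column, with a warning.
#'
#' @param ages ages (band midpoints) at which to evaluate.
#' @param knots interior knot locations (default 42.5, 55, 67.5).
#' @param boundary boundary knots (default 32.5 and 77.5, the extreme band
#'   midpoints).
#' @return matrix with one row per age; attribute `"knots"`/`"boundary"`
#'   record the configuration so new ages evaluate consistently.
#' @export
age_spline_basis <- function(ages, knots = c(42.5, 55, 67.5),
                             boundary = c(32.5, 77.5)) {
  stopifnot(!is.unsorted(knots, strictly = TRUE),
            all(knots > boundary[1]), all(knots < boundary[2]))
  if (length(unique(ages)) < 3) {
    warning("fewer than 3 distinct ages: falling back to a linear age term")
    b <- matrix(ages - mean(boundary), ncol = 1,
                dimnames = list(NULL, "age_lin"))
    attr(b, "knots") <- numeric(0)
    attr(b, "boundary") <- boundary
    return(b)
  }
  b <- splines::ns(ages, knots = knots, Boundary.knots = boundary)
  m <- unclass(b)
  attributes(m) <- list(dim = dim(b),
                        dimnames = list(NULL, paste0("age", seq_len(ncol(b)))),
                        knots = knots, boundary = boundary)
  m
}

# second-difference matrix for a length-n series
second_diff_matrix <- function(n) {
  stopifnot(n >= 3)
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

#' Spectral basis of the second-order random-walk (RW2) penalty
#'
#' The RW2 prior over `n_years` time points has precision proportional to
#' `t(D) %*% D` with `D` the second-difference matrix; its null space is the
#' set of linear trends. The walk is parameterised as `u = B %*% coef` where
#' the columns of `B` are the penalty's eigenvectors with nonzero eigenvalue
#' (orthonormal, and exactly orthogonal to constant and linear sequences, so
#' the walk never competes with the intercept and slope terms), and the prior
#' on `coef` is independent Gaussian with variances `sigma_rw^2 / lambda`.
#' By default the basis is truncated to the `k` smoothest modes; modes beyond
#' those are penalised so heavily that their prior contribution is
#' negligible at the smoothness scales used here.
#'
#' @param n_years number of time points.
#' @param k number of retained modes (default `min(n_years - 2, 12)`).
#' @return list with `B` (n_years x k, orthonormal columns), `lambda`
#'   (eigenvalues, ascending), and `D` (the full second-difference matrix).
#' @export
rw2_basis <- function(n_years, k = min(n_years - 2L, 12L)) {
  stopifnot(n_years >= 4, k >= 1, k <= n_years - 2)
  D <- second_diff_matrix(n_years)
  e <- eigen(crossprod(D), symmetric = TRUE)
  ord <- order(e$values)          # ascending: 2 null modes first
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  keep <- 3:(2 + k)               # drop the 2-dim null space {1, t}
  list(B = vecs[, keep, drop = FALSE], lambda = vals[keep], D = D)
}

#' RW2 roughness penalty of a time series
#'
#' Sum of squared second differences; zero exactly for any linear sequence.
#'
#' @param u numeric series.
#' @return non-negative scalar.
#' @export
rw2_penalty <- function(u) sum(diff(u, differences = 2)^2)
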