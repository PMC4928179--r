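# Form factor of a homogeneous sphere, parameterized by its radius of
# gyration.  For a uniform solid sphere of radius R the relation
# R^2 = (5/3) Rg^2 holds, so the amplitude is evaluated at x = q * sqrt(5/3) * Rg.

# amplitude 3 (sin x - x cos x) / x^3 with a series fallback near x = 0:
# the direct expression suffers catastrophic cancellation at small x (the
# numerator is O(x^3)), while below x = 1e-2 the truncated series
# 1 - x^2/10 + x^4/280 is exact to < 1e-16 (next term x^6/15120), so the
# switch keeps the amplitude in [0, 1] to full precision on both sides.
.sphere_amplitude <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Scattering intensity of a homogeneous sphere
#'
#' Normalized scattering intensity `I_S(q, Rg)` of a sphere with uniform
#' (homogeneous) scattering density and radius of gyration `rg`:
#' `[3 (sin x - x cos x) / x^3]^2` with `x = q R` and `R = sqrt(5/3) rg`.
#' The intensity is normalized so that `I_S(0, rg) = 1` exactly; values lie
#' in `[0, 1]`.  In the Guinier limit (`q * rg` small) it agrees with
#' `exp(-q^2 rg^2 / 3)`.
#'
#' @param q numeric vector of momentum transfers, 1/Angstrom, all `>= 0`.
#' @param rg positive scalar radius of gyration, Angstrom.
#' @return Numeric vector of normalized intensities, same length as `q`.
#' @examples
#' sphere_intensity(0, 25)                      # exactly 1
#' sphere_intensity(c(0.01, 0.1, 0.3), rg = 25)
#' @export
sphere_intensity <- function(q, rg) {
  if (!is.numeric(rg) || length(rg) != 1L || !is.finite(rg) || rg <= 0)
    stop("`rg` must be a positive finite scalar")
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q < 0))
    stop("`q` must be finite and non-negative")
  .sphere_amplitude(q * sqrt(5 / 3) * rg)^2
}

#' Precompute a sphere-intensity lookup matrix
#'
#' Evaluates [sphere_intensity()] on the outer product of a `q` grid and an
#' `Rg` grid.  The result is identical to element-wise calls; the matrix
#' form exists so the ensemble-average quadrature inside the fit can be a
#' single matrix-vector product.
#'
#' @param q strictly increasing grid of momentum transfers (may start at 0).
#' @param rg_grid strictly increasing grid of positive radii of gyration.
#' @return Object of class `"sphere_grid"`: list with `q`, `rg_grid` and
#'   `values`, a `length(q) x length(rg_grid)` matrix with entries in
#'   `[0, 1]`.
#' @export
sphere_grid <- function(q, rg_grid) {
  q <- as.numeric(q); rg_grid <- as.numeric(rg_grid)
  if (length(q) == 0L || length(rg_grid) == 0L)
    stop("grids must be non-empty")
  if (any(!is.finite(q)) || any(q < 0) ||
      (length(q) > 1L && is.unsorted(q, strictly = TRUE)))
    stop("`q` must be non-negative and strictly increasing")
  if (any(!is.finite(rg_grid)) || any(rg_grid <= 0) ||
      (length(rg_grid) > 1L && is.unsorted(rg_grid, strictly = TRUE)))
    stop("`rg_grid` must be positive and strictly increasing")
  x <- outer(q * sqrt(5 / 3), rg_grid)
  values <- matrix(.sphere_amplitude(as.vector(x))^2,
                   nrow = length(q), ncol = length(rg_grid))
  structure(list(q = q, rg_grid = rg_grid, values = values),
            class = "sphere_grid")
}

#' @export
print.sphere_grid <- function(x, ...) {
  cat(sprintf("sphere intensity grid: %d q-points x %d Rg-points\n",
              length(x$q), length(x$rg_grid)))
  invisible(x)
}
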