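#' Construct a SAXS scattering profile
#'
#' A scattering profile holds a one-dimensional SAXS curve: the momentum
#' transfer grid `q` (in inverse Angstrom), the rotationally averaged
#' intensity `I(q)` in arbitrary units, and optionally the per-point
#' standard error of the intensity.
#'
#' Validation enforces the physical invariants of a usable profile:
#' `q` strictly increasing and positive, intensities finite and positive,
#' and `sigma` (when present) finite, non-negative and of matching length.
#'
#' @param q numeric vector of momentum-transfer magnitudes, 1/Angstrom.
#' @param intensity numeric vector of scattering intensities, arbitrary
#'   units, same length as `q`.
#' @param sigma optional numeric vector of per-point standard errors of the
#'   intensity, same units and length as `intensity`.
#' @param label free-text identifier carried through I/O round trips.
#' @return An object of class `"saxs_profile"`: a list with elements `q`,
#'   `intensity`, `sigma` (possibly `NULL`) and `label`.
#' @examples
#' q <- seq(0.01, 0.3, by = 0.01)
#' p <- saxs_profile(q, exp(-q^2 * 20^2 / 3), label = "guinier-toy")
#' p
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("`q` and `intensity` must have the same length")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("`q` must be finite and strictly positive")
  if (is.unsorted(q, strictly = TRUE))
    stop("`q` must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("`intensity` must be finite and strictly positive")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("`sigma` must have the same length as `q`")
    if (any(!is.finite(sigma)) || any(sigma < 0))
      stop("`sigma` must be finite and non-negative")
  }
  structure(
    list(q = q, intensity = intensity, sigma = sigma,
         label = as.character(label)[1]),
    class = "saxs_profile"
  )
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat("SAXS scattering profile",
      if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  cat(sprintf("  %d points, q in [%.4g, %.4g] 1/Angstrom\n",
              length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  I(q_min) = %.4g, I(q_max) = %.4g%s\n",
              x$intensity[1], x$intensity[length(x$intensity)],
              if (is.null(x$sigma)) ", no errors" else ", with errors"))
  invisible(x)
}

#' @export
as.data.frame.saxs_profile <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' @export
plot.saxs_profile <- function(x, log = "y", ...) {
  graphics::plot(x$q, x$intensity, log = log, type = "l",
                 xlab = expression(q ~ (ring(A)^-1)),
                 ylab = "I(q) (a.u.)", main = x$label, ...)
  invisible(x)
}

#' Read a three-column SAXS .dat file
#'
#' Parses the whitespace-delimited text dialect used by ATSAS, BIOISIS and
#' SASBDB deposits: lines starting with `#`, and any line whose first token
#' is not numeric, are treated as header/comment and skipped.  The first two
#' numeric columns are `q` and `I(q)`; a numeric third column, when present
#' on every data row, becomes the per-point error.  Columns beyond the third
#' are ignored.
#'
#' Rows with non-finite or non-positive `q` or `I` are dropped with a
#' message reporting the count (zero-angle points are unphysical in SAXS and
#' are never used as `I(0)`).
#'
#' @param path path to a readable text file.
#' @param units `"angstrom"` (default) if `q` is in 1/Angstrom, `"nm"` if in
#'   1/nm; nm input is converted by multiplying `q` by 0.1.
#' @param label profile label; defaults to the file name.
#' @return A [saxs_profile] object.
#' @seealso [write_dat()]
#' @export
read_dat <- function(path, units = c("angstrom", "nm"), label = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t,]+")
  num1 <- vapply(toks, function(tk)
    suppressWarnings(as.numeric(tk[1])), numeric(1))
  data_rows <- toks[is.finite(num1)]
  if (length(data_rows) == 0L)
    stop("no numeric data rows in ", path)
  parse_col <- function(i) vapply(data_rows, function(tk) {
    if (length(tk) < i) return(NA_real_)
    suppressWarnings(as.numeric(tk[i]))
  }, numeric(1))
  q <- parse_col(1)
  intens <- parse_col(2)
  sig <- parse_col(3)
  if (any(!is.finite(intens[is.finite(q)])) && all(!is.finite(sig)))
    stop("fewer than 2 numeric columns in ", path)
  keep <- is.finite(q) & is.finite(intens) & q > 0 & intens > 0
  if (!is.null(sig) && all(is.finite(sig[keep]))) {
    keep <- keep & sig >= 0
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_dat: dropped ", n_dropped,
            " row(s) with non-positive or non-finite q/I")
  q <- q[keep]; intens <- intens[keep]; sig <- sig[keep]
  if (length(q) < 5L)
    stop("malformed profile: fewer than 5 valid points in ", path)
  sigma <- if (all(is.finite(sig))) sig else NULL
  if (units == "nm") q <- q * 0.1
  ord <- order(q)
  saxs_profile(q[ord], intens[ord],
               sigma = if (is.null(sigma)) NULL else sigma[ord],
               label = if (is.null(label)) basename(path) else label)
}

#' Write a SAXS profile to a three-column .dat file
#'
#' Writes whitespace-delimited text with a `#`-prefixed header carrying the
#' label.  A [read_dat()] of the result reproduces the profile to at least
#' six significant digits.
#'
#' @param profile a [saxs_profile].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_dat <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  hdr <- c(paste0("# ", profile$label),
           if (is.null(profile$sigma)) "# q intensity"
           else "# q intensity sigma")
  body <- if (is.null(profile$sigma)) {
    sprintf("%.9e %.9e", profile$q, profile$intensity)
  } else {
    sprintf("%.9e %.9e %.9e", profile$q, profile$intensity, profile$sigma)
  }
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write file: ", path)
  invisible(path)
}

#' Divide a profile by a zero-angle intensity
#'
#' Rescales the intensity (and error, when present) by `1 / i0`, leaving
#' `q` untouched.  Used to put profiles on the normalized `I(q)/I(0)` scale
#' required by dimensionless Kratky and Porod-Debye plots.
#'
#' @param profile a [saxs_profile].
#' @param i0 positive scalar, typically the Guinier-extrapolated `I(0)`.
#' @return A new [saxs_profile].
#' @export
normalize_profile <- function(profile, i0) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (!is.numeric(i0) || length(i0) != 1L || !is.finite(i0) || i0 <= 0)
    stop("`i0` must be a positive finite scalar")
  saxs_profile(profile$q, profile$intensity / i0,
               sigma = if (is.null(profile$sigma)) NULL
                       else profile$sigma / i0,
               label = profile$label)
}

#' Guinier analysis: radius of gyration and zero-angle intensity
#'
#' Fits `ln I = ln I(0) - q^2 Rg^2 / 3` by linear regression over the
#' largest low-q window satisfying `q * Rg <= qrg_max`.  Because the window
#' depends on the unknown `Rg`, the window is found by fixed-point
#' iteration: fit, update `Rg`, re-select the window, repeat until `Rg`
#' changes by less than `tol` (relative) or `max_iter` is reached.
#'
#' @param profile a [saxs_profile].
#' @param qrg_max upper limit of `q * Rg` in the fitted window; 1.3 is the
#'   standard validity limit of the Guinier approximation for globular
#'   particles.
#' @param min_points minimum number of points required in the window.
#' @param max_iter,tol fixed-point iteration controls.
#' @return An object of class `"guinier"`: list with `rg` (Angstrom), `i0`,
#'   `q_window` (range actually fitted), `r2` and `n_points`.
#' @examples
#' q <- seq(0.005, 0.05, length.out = 60)
#' p <- saxs_profile(q, 7 * exp(-q^2 * 20^2 / 3))
#' guinier_fit(p)  # recovers rg = 20, i0 = 7
#' @export
guinier_fit <- function(profile, qrg_max = 1.3, min_points = 5L,
                        max_iter = 50L, tol = 1e-6) {
  stopifnot(inherits(profile, "saxs_profile"))
  q <- profile$q
  y <- log(profile$intensity)
  n <- length(q)
  if (n < min_points) stop("insufficient data: fewer than ", min_points,
                           " points")
  q2 <- q^2

  fit_window <- function(idx) {
    fi <- stats::lm.fit(cbind(1, q2[idx]), y[idx])
    slope <- fi$coefficients[2]
    list(slope = slope, intercept = fi$coefficients[1],
         r2 = 1 - sum(fi$residuals^2) /
           max(sum((y[idx] - mean(y[idx]))^2), .Machine$double.eps))
  }

  # seed the iteration from a small leading window
  idx <- seq_len(max(min_points, min(n, 20L)))
  f <- fit_window(idx)
  if (!is.finite(f$slope) || f$slope >= 0)
    stop("no Guinier region: intensity does not decay at low q")
  rg <- sqrt(-3 * f$slope)

  for (iter in seq_len(max_iter)) {
    q_hi <- qrg_max / rg
    idx <- which(q <= q_hi)
    if (length(idx) < min_points)
      stop("insufficient data: fewer than ", min_points,
           " points with q*Rg <= ", qrg_max)
    f <- fit_window(idx)
    if (!is.finite(f$slope) || f$slope >= 0)
      stop("no Guinier region: intensity does not decay at low q")
    rg_new <- sqrt(-3 * f$slope)
    if (abs(rg_new - rg) <= tol * rg) {
      rg <- rg_new
      break
    }
    rg <- rg_new
  }

  structure(
    list(rg = unname(rg), i0 = unname(exp(f$intercept)),
         q_window = c(q[idx[1]], q[idx[length(idx)]]),
         r2 = unname(f$r2), n_points = length(idx), qrg_max = qrg_max),
    class = "guinier"
  )
}

#' @export
print.guinier <- function(x, ...) {
  cat("Guinier analysis\n")
  cat(sprintf("  Rg   = %.4g Angstrom\n", x$rg))
  cat(sprintf("  I(0) = %.6g\n", x$i0))
  cat(sprintf("  window q in [%.4g, %.4g] (%d points, q*Rg <= %.3g), R2 = %.5f\n",
              x$q_window[1], x$q_window[2], x$n_points, x$qrg_max, x$r2))
  invisible(x)
}
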