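# Classical SAXS diagnostics used alongside the RgD entropy: Kratky,
# dimensionless Kratky, Porod and Porod-Debye transforms, plateau
# detection, and the entropy-quartile flexibility classifier.

.transform_kinds <- c("kratky", "dimensionless_kratky", "porod",
                      "porod_debye", "q3_debye")

new_transformed_curve <- function(x, y, kind, xlab, ylab, label = "") {
  kind <- match.arg(kind, .transform_kinds)
  structure(list(x = x, y = y, kind = kind, xlab = xlab, ylab = ylab,
                 label = label),
            class = "saxs_transform")
}

#' @export
print.saxs_transform <- function(x, ...) {
  cat(sprintf("SAXS transform '%s' (%d points), x in [%.4g, %.4g]\n",
              x$kind, length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' @export
as.data.frame.saxs_transform <- function(x, ...) {
  data.frame(x = x$x, y = x$y)
}

#' @export
plot.saxs_transform <- function(x, guides = TRUE, ...) {
  graphics::plot(x$x, x$y, type = "l", xlab = x$xlab, ylab = x$ylab,
                 main = if (nzchar(x$label)) x$label else x$kind, ...)
  if (guides && x$kind == "dimensionless_kratky") {
    graphics::abline(v = sqrt(3), lty = 3)
    graphics::abline(h = 3 * exp(-1), lty = 3)
  }
  invisible(x)
}

#' Kratky transform
#'
#' `q^2 I(q)` versus `q`.  Compact particles produce a bell that returns to
#' baseline at high `q`; flexible chains plateau or rise (an ideal Gaussian
#' chain with `I ~ 1/q^2` gives a flat plateau).
#'
#' @param profile a [saxs_profile].
#' @return A `"saxs_transform"` object with `x = q`, `y = q^2 I(q)`.
#' @export
kratky <- function(profile) {
  stopifnot(inherits(profile, "saxs_profile"))
  new_transformed_curve(profile$q, profile$q^2 * profile$intensity,
                        "kratky", "q (1/A)", "q^2 I(q)", profile$label)
}

#' Dimensionless Kratky transform
#'
#' `(q Rg)^2 I(q) / I(0)` versus `q Rg`.  Both axes are dimensionless, so
#' curves from particles of different size and molecular weight are
#' directly comparable.  An ideally compact (Guinier-like) particle has a
#' local maximum at `x = sqrt(3)` of height `3/e = 1.104`; deviation from
#' that landmark signals conformational flexibility.
#'
#' @param profile a [saxs_profile].
#' @param rg,i0 radius of gyration (Angstrom) and zero-angle intensity used
#'   for the normalization; by default both are estimated by
#'   [guinier_fit()].
#' @return A `"saxs_transform"` object.
#' @export
dimensionless_kratky <- function(profile, rg = NULL, i0 = NULL) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (is.null(rg) || is.null(i0)) {
    g <- guinier_fit(profile)
    if (is.null(rg)) rg <- g$rg
    if (is.null(i0)) i0 <- g$i0
  }
  if (!is.finite(rg) || rg <= 0) stop("`rg` must be a positive scalar")
  if (!is.finite(i0) || i0 <= 0) stop("`i0` must be a positive scalar")
  x <- profile$q * rg
  new_transformed_curve(x, x^2 * profile$intensity / i0,
                        "dimensionless_kratky", "q Rg",
                        "(q Rg)^2 I(q)/I(0)", profile$label)
}

#' Porod transform
#'
#' `q^4 I(q)` versus `q`.  The position of the first peak marks the onset
#' of the Porod-Debye region.
#'
#' @param profile a [saxs_profile].
#' @return A `"saxs_transform"` object.
#' @export
porod <- function(profile) {
  stopifnot(inherits(profile, "saxs_profile"))
  new_transformed_curve(profile$q, profile$q^4 * profile$intensity,
                        "porod", "q (1/A)", "q^4 I(q)", profile$label)
}

#' Porod-Debye transform
#'
#' `q^4 I(q) / I(0)` versus `q^4` (default exponent 4).  For a compact
#' particle the intensity decays as `q^-4` and the curve reaches a plateau
#' over the Porod-Debye region; flexible particles decay more slowly and
#' never plateau.  The exponent-3 variant (`q^3 I(q)/I(0)` versus `q^3`)
#' diagnoses an intermediate `q^-3` decay.
#'
#' @param profile a [saxs_profile].
#' @param i0 positive zero-angle intensity used to normalize the ordinate;
#'   estimated by [guinier_fit()] when omitted.
#' @param exponent 4 (Porod-Debye, default) or 3.
#' @return A `"saxs_transform"` object of kind `"porod_debye"` or
#'   `"q3_debye"`.
#' @export
porod_debye <- function(profile, i0 = NULL, exponent = 4) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (is.null(i0)) i0 <- guinier_fit(profile)$i0
  if (!is.finite(i0) || i0 <= 0) stop("`i0` must be a positive scalar")
  if (!exponent %in% c(3, 4)) stop("`exponent` must be 3 or 4")
  kind <- if (exponent == 4) "porod_debye" else "q3_debye"
  new_transformed_curve(profile$q^exponent,
                        profile$q^exponent * profile$intensity / i0,
                        kind, sprintf("q^%d (1/A^%d)", exponent, exponent),
                        sprintf("q^%d I(q)/I(0)", exponent), profile$label)
}

#' Detect a Porod-Debye plateau
#'
#' Locates the onset of the Porod-Debye region as the first local maximum
#' of the corresponding Porod ordinate (lightly median-smoothed for peak
#' finding only), then scans candidate windows of width `window_fraction`
#' of the full x-range beyond that onset and asks whether any is flat: the
#' normalized slope — the fitted linear slope times the window width,
#' divided by the mean level in the window, i.e. the relative change of
#' the ordinate across the window — must stay within `slope_tol`.  The
#' flattest window found is reported.  The criterion is a heuristic
#' stand-in for the visual judgement usually applied to these plots; both
#' thresholds are exposed.
#'
#' @param curve a `"saxs_transform"` of kind `"porod_debye"` or
#'   `"q3_debye"` with at least 20 points.
#' @param window_fraction fraction of the x-range a flat window must span
#'   (default 0.25).
#' @param slope_tol maximum absolute normalized slope accepted as flat
#'   (default 0.1).
#' @return A list of class `"plateau_report"`: `present` (logical),
#'   `x_range` of the flattest window, `level` (mean ordinate there),
#'   `slope_norm`, and `onset_x`.
#' @export
detect_plateau <- function(curve, window_fraction = 0.25, slope_tol = 0.1) {
  stopifnot(inherits(curve, "saxs_transform"))
  if (!curve$kind %in% c("porod_debye", "q3_debye"))
    stop("plateau detection applies to porod_debye / q3_debye curves")
  n <- length(curve$x)
  if (n < 20L) stop("insufficient data: need at least 20 points")
  x <- curve$x
  y <- curve$y
  ys <- stats::runmed(y, 3)
  peaks <- which(diff(sign(diff(ys))) < 0) + 1L
  onset_i <- if (length(peaks)) peaks[1] else 1L
  x0 <- x[onset_i]
  width <- window_fraction * (x[n] - x[1])
  best <- Inf; best_sel <- onset_i:min(n, onset_i + 4L)
  for (i in onset_i:n) {
    sel <- which(x >= x[i] & x <= x[i] + width)
    if (length(sel) < 5L || x[sel[length(sel)]] - x[i] < 0.8 * width)
      next
    fit <- stats::lm.fit(cbind(1, x[sel]), y[sel])
    s <- fit$coefficients[2] * width / mean(y[sel])
    if (is.finite(s) && abs(s) < abs(best)) {
      best <- s
      best_sel <- sel
    }
  }
  level <- mean(y[best_sel])
  structure(list(present = is.finite(best) && abs(best) <= slope_tol,
                 x_range = range(x[best_sel]), level = level,
                 slope_norm = unname(best), onset_x = x0,
                 window_fraction = window_fraction,
                 slope_tol = slope_tol),
            class = "plateau_report")
}

#' @export
print.plateau_report <- function(x, ...) {
  cat(sprintf("Porod-Debye plateau: %s\n",
              if (x$present) "PRESENT" else "absent"))
  cat(sprintf("  onset x = %.4g; tested x in [%.4g, %.4g]\n",
              x$onset_x, x$x_range[1], x$x_range[2]))
  cat(sprintf("  level = %.4g, normalized slope = %.3g (tol %.3g)\n",
              x$level, x$slope_norm, x$slope_tol))
  invisible(x)
}

#' Flexibility class from the RgD entropy
#'
#' Maps an entropy value onto the four empirical flexibility quartiles of
#' the deposited-dataset survey, with cut-points 3.37, 3.86 and 4.26 nats
#' (left-inclusive): `S <= 3.37` is compact/folded, `S > 4.26` is
#' disordered, and the two middle classes show intermediate and relatively
#' increased flexibility.
#'
#' @param s numeric vector of entropies (nats); must be finite.
#' @return A factor with levels `Q1_compact`, `Q2_intermediate`,
#'   `Q3_flexible`, `Q4_disordered` and attribute `cutpoints`.
#' @examples
#' classify_entropy(c(2.58, 3.36, 4.41))
#' @export
classify_entropy <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("`s` must be finite numeric")
  cutpoints <- c(3.37, 3.86, 4.26)
  labels <- c("Q1_compact", "Q2_intermediate", "Q3_flexible",
              "Q4_disordered")
  out <- cut(s, breaks = c(-Inf, cutpoints, Inf), labels = labels,
             right = TRUE)
  attr(out, "cutpoints") <- cutpoints
  out
}
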