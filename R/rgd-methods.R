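#' @export
print.rgd <- function(x, digits = 4, ...) {
  cat("Rg-distribution (RgD) fit\n")
  if (nzchar(x$profile$label)) cat("  profile:", x$profile$label, "\n")
  cat(sprintf("  mu = %.*g   sigma = %.*g   scale = %.*g\n",
              digits, x$mu, digits, x$sigma, digits, x$scale))
  err <- if (is.finite(x$entropy_err))
    sprintf(" +/- %.2g", x$entropy_err) else ""
  cat(sprintf("  entropy S = %.*g nats%s  [%s]\n",
              digits, x$entropy, err,
              as.character(classify_entropy(x$entropy))))
  cat(sprintf("  misfit (%s) = %.3g over q in [%.4g, %.4g]\n",
              x$objective, x$misfit, x$q_window[1], x$q_window[2]))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.rgd <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, scale = object$scale)
}

#' @export
summary.rgd <- function(object, ...) {
  med <- exp(object$mu)
  s2 <- object$sigma^2
  out <- list(
    fit = object,
    rg_median = med,
    rg_mean = exp(object$mu + s2 / 2),
    rg_mode = exp(object$mu - s2),
    rg_sd = sqrt((exp(s2) - 1)) * exp(object$mu + s2 / 2),
    class = classify_entropy(object$entropy),
    n_fit = sum(object$profile$q >= object$q_window[1] &
                  object$profile$q <= object$q_window[2]))
  class(out) <- "summary.rgd"
  out
}

#' @export
print.summary.rgd <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nFitted Rg distribution (Angstrom):\n")
  cat(sprintf("  median %.4g, mean %.4g, mode %.4g, sd %.4g\n",
              x$rg_median, x$rg_mean, x$rg_mode, x$rg_sd))
  cat(sprintf("  flexibility class: %s\n", as.character(x$class)))
  cat(sprintf("  %d points fitted; %d/%d starts converged\n",
              x$n_fit, sum(x$fit$starts$converged), nrow(x$fit$starts)))
  if (!is.null(x$fit$guinier))
    cat(sprintf("  Guinier: Rg = %.4g A, I(0) = %.4g (R2 = %.4f)\n",
                x$fit$guinier$rg, x$fit$guinier$i0, x$fit$guinier$r2))
  invisible(x)
}

#' Predict model intensity from an RgD fit
#'
#' @param object an [rgd()] fit.
#' @param q momentum transfers at which to evaluate; defaults to the
#'   profile's grid.
#' @param type `"intensity"` for the fitted curve on the data scale
#'   (`scale * I_model`), `"normalized"` for the unit-`I(0)` model.
#' @param ... unused.
#' @return Numeric vector of intensities.
#' @export
predict.rgd <- function(object, q = object$profile$q,
                        type = c("intensity", "normalized"), ...) {
  type <- match.arg(type)
  im <- model_intensity(q, object$mu, object$sigma,
                        n_nodes = object$n_nodes)
  if (type == "intensity") object$scale * im else im
}

#' @export
fitted.rgd <- function(object, ...) {
  sel <- object$profile$q >= object$q_window[1] &
    object$profile$q <= object$q_window[2]
  predict(object, q = object$profile$q[sel])
}

#' Residuals of an RgD fit
#'
#' @param object an [rgd()] fit.
#' @param type `"log"` (default): difference of log-intensities, the scale
#'   the default objective minimizes; `"raw"`: intensity difference;
#'   `"pearson"`: raw residuals divided by the reported errors (requires
#'   `sigma`).
#' @param ... unused.
#' @return Numeric vector over the fitted window.
#' @export
residuals.rgd <- function(object, type = c("log", "raw", "pearson"), ...) {
  type <- match.arg(type)
  sel <- object$profile$q >= object$q_window[1] &
    object$profile$q <= object$q_window[2]
  ie <- object$profile$intensity[sel]
  im <- fitted(object)
  switch(type,
         log = log(ie) - log(im),
         raw = ie - im,
         pearson = {
           if (is.null(object$profile$sigma))
             stop("pearson residuals require profile errors")
           (ie - im) / object$profile$sigma[sel]
         })
}

#' Plot an RgD fit
#'
#' Two panels: the measured intensity with the fitted model curve over the
#' fit window (log intensity scale), and the fitted log-normal probability
#' density over the radius of gyration.
#'
#' @param x an [rgd()] fit.
#' @param which subset of `1:2` selecting the panels.
#' @param ... further arguments passed to the base plotting calls.
#' @export
plot.rgd <- function(x, which = 1:2, ...) {
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if (1 %in% which) {
    graphics::plot(x$profile$q, x$profile$intensity, log = "y",
                   col = "grey40", pch = 16, cex = 0.4,
                   xlab = expression(q ~ (ring(A)^-1)),
                   ylab = "I(q) (a.u.)", main = x$profile$label, ...)
    qq <- seq(x$q_window[1], x$q_window[2], length.out = 200)
    graphics::lines(qq, predict(x, q = qq), col = "red3", lwd = 2)
    graphics::abline(v = x$q_window, lty = 3)
  }
  if (2 %in% which) {
    rr <- .rg_nodes(x$mu, x$sigma, 300L, p_tail = 1e-4)
    graphics::plot(rr, rg_lognormal_pdf(rr, x$mu, x$sigma), type = "l",
                   lwd = 2, col = "red3",
                   xlab = expression(R[g] ~ (ring(A))),
                   ylab = expression(p(R[g])),
                   main = sprintf("S = %.3g nats", x$entropy), ...)
  }
  invisible(x)
}

#' Simulate noisy profiles from a fitted RgD model
#'
#' Draws synthetic profiles on the fitted model curve with multiplicative
#' Gaussian noise.  The noise level defaults to the profile's median
#' relative error when errors are present, otherwise 1\%.
#'
#' @param object an [rgd()] fit.
#' @param nsim number of profiles to simulate.
#' @param seed integer seed (optional).
#' @param noise_level relative noise level (per-point sd as a fraction of
#'   the intensity).
#' @param ... unused.
#' @return A list of [saxs_profile] objects of length `nsim`.
#' @export
simulate.rgd <- function(object, nsim = 1, seed = NULL,
                         noise_level = NULL, ...) {
  if (!is.null(seed)) {
    old_seed <- .save_seed()
    on.exit(.restore_seed(old_seed))
    set.seed(as.integer(seed))
  }
  if (is.null(noise_level)) {
    noise_level <- if (!is.null(object$profile$sigma))
      stats::median(object$profile$sigma / object$profile$intensity)
    else 0.01
  }
  q <- object$profile$q
  iclean <- predict(object, q = q)
  lapply(seq_len(nsim), function(b) {
    inoisy <- iclean * (1 + noise_level * stats::rnorm(length(q)))
    keep <- inoisy > 0
    saxs_profile(q[keep], inoisy[keep],
                 sigma = (noise_level * iclean)[keep],
                 label = sprintf("%s [sim %d]", object$profile$label, b))
  })
}
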