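#' Log-normal probability density over the radius of gyration
#'
#' Density of the log-normal distribution used to describe the diversity of
#' radii of gyration a biomolecule samples in solution:
#' `p(Rg) = 1 / (Rg sigma sqrt(2 pi)) * exp(-(ln Rg - mu)^2 / (2 sigma^2))`.
#' The density is only supported on positive `Rg`; by convention
#' `p(0) = 0`, so a grid that includes zero is handled gracefully.
#'
#' @param rg numeric vector of radii of gyration, Angstrom, all `>= 0`.
#' @param mu log-scale location (the log of the median Rg in Angstrom).
#' @param sigma log-scale standard deviation, `> 0`.
#' @return Densities (per Angstrom), same length as `rg`.
#' @export
rg_lognormal_pdf <- function(rg, mu, sigma) {
  .check_mu_sigma(mu, sigma)
  rg <- as.numeric(rg)
  if (any(!is.finite(rg)) || any(rg < 0))
    stop("`rg` must be finite and non-negative")
  out <- stats::dlnorm(rg, meanlog = mu, sdlog = sigma)
  out[rg == 0] <- 0
  out
}

.check_mu_sigma <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop("`mu` must be a finite scalar")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a positive finite scalar")
  invisible(TRUE)
}

#' Differential entropy of the fitted Rg distribution
#'
#' The flexibility metric: the differential entropy
#' `S = -Integral p ln p dRg` of a log-normal density over the radius of
#' gyration, in closed form `S = mu + 1/2 + ln(sigma sqrt(2 pi))` (nats).
#' Unlike a discrete Shannon entropy, the differential entropy is unbounded
#' below: `S -> -Inf` as `sigma -> 0` (a delta-like, perfectly rigid
#' ensemble).  Larger `S` means a broader diversity of sampled sizes, i.e.
#' a more flexible molecule.
#'
#' @param mu,sigma log-normal parameters; both may be vectors (recycled).
#' @return Entropy in nats.
#' @examples
#' rgd_entropy(0, 1)              # 0.5 + log(sqrt(2*pi))
#' rgd_entropy(3, c(0.1, 0.5))    # increases with sigma
#' @export
rgd_entropy <- function(mu, sigma) {
  if (any(!is.finite(mu))) stop("`mu` must be finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be positive and finite")
  mu + 0.5 + log(sigma * sqrt(2 * pi))
}

# log-spaced quadrature nodes spanning the [p, 1-p] quantiles of the
# current log-normal; log spacing makes the node density follow the
# distribution's natural scale.
.rg_nodes <- function(mu, sigma, n_nodes = 400L, p_tail = 1e-6) {
  lo <- stats::qlnorm(p_tail, mu, sigma)
  hi <- stats::qlnorm(1 - p_tail, mu, sigma)
  exp(seq(log(lo), log(hi), length.out = n_nodes))
}

# trapezoid weights for an arbitrary strictly increasing grid
.trap_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

#' Ensemble-averaged model intensity
#'
#' The forward model of the Rg-distribution (RgD) method: the normalized
#' scattering intensity of an ensemble whose radii of gyration follow a
#' log-normal distribution,
#' `I(q) = Integral p(Rg) I_S(q, Rg) dRg`,
#' where `I_S` is the homogeneous-sphere intensity ([sphere_intensity()]).
#' The integral is evaluated by trapezoid quadrature on a log-spaced `Rg`
#' grid spanning the `[1e-6, 1 - 1e-6]` quantiles of the current
#' distribution, so `I(0) = 1` within quadrature tolerance.
#'
#' @param q numeric vector of momentum transfers, 1/Angstrom, `>= 0`.
#' @param mu,sigma log-normal parameters of the Rg distribution.
#' @param n_nodes number of quadrature nodes (default 400).
#' @param rg_grid optional explicit quadrature grid; it must carry at least
#'   99.99\% of the distribution's mass or a coverage error is raised.
#' @return Normalized model intensities, same length as `q`.
#' @examples
#' q <- seq(0, 0.2, by = 0.01)
#' model_intensity(q, mu = 3, sigma = 0.3)
#' @export
model_intensity <- function(q, mu, sigma, n_nodes = 400L, rg_grid = NULL) {
  .check_mu_sigma(mu, sigma)
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q < 0))
    stop("`q` must be finite and non-negative")
  if (is.null(rg_grid)) {
    rg_grid <- .rg_nodes(mu, sigma, n_nodes)
  } else {
    rg_grid <- sort(as.numeric(rg_grid))
    if (any(rg_grid <= 0)) stop("`rg_grid` must be positive")
    mass <- stats::plnorm(rg_grid[length(rg_grid)], mu, sigma) -
      stats::plnorm(rg_grid[1], mu, sigma)
    if (mass < 1 - 1e-4)
      stop(sprintf(
        "quadrature grid covers only %.6f of the Rg distribution mass",
        mass))
  }
  w <- .trap_weights(rg_grid) * rg_lognormal_pdf(rg_grid, mu, sigma)
  x <- outer(q * sqrt(5 / 3), rg_grid)
  m <- matrix(.sphere_amplitude(as.vector(x))^2, nrow = length(q))
  as.vector(m %*% w)
}

#' Misfit between a measured profile and the RgD forward model
#'
#' @param profile a [saxs_profile].
#' @param mu,sigma log-normal Rg-distribution parameters.
#' @param scale positive overall intensity scale multiplying the normalized
#'   model.
#' @param q_window numeric length-2 interval of `q` actually compared;
#'   defaults to the full profile range.
#' @param weighting `"logls"` (default): mean squared difference of
#'   log-intensities, appropriate over the ~1 decade of low-q falloff;
#'   `"chi2"`: error-weighted mean squared difference, requires the profile
#'   to carry `sigma`.
#' @param n_nodes quadrature nodes for the forward model.
#' @return Non-negative scalar misfit.
#' @export
rgd_misfit <- function(profile, mu, sigma, scale,
                       q_window = NULL, weighting = c("logls", "chi2"),
                       n_nodes = 400L) {
  stopifnot(inherits(profile, "saxs_profile"))
  weighting <- match.arg(weighting)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("`scale` must be a positive finite scalar")
  if (is.null(q_window)) q_window <- range(profile$q)
  sel <- profile$q >= q_window[1] & profile$q <= q_window[2]
  if (sum(sel) < 10L)
    stop("fewer than 10 profile points inside the q window")
  qe <- profile$q[sel]
  ie <- profile$intensity[sel]
  im <- scale * model_intensity(qe, mu, sigma, n_nodes = n_nodes)
  if (weighting == "logls") {
    if (any(ie <= 0)) stop("log objective requires positive intensities")
    mean((log(pmax(im, 1e-300)) - log(ie))^2)
  } else {
    if (is.null(profile$sigma))
      stop("chi2 weighting requires a profile with errors")
    se <- profile$sigma[sel]
    if (any(se <= 0)) stop("chi2 weighting requires strictly positive sigma")
    mean(((im - ie) / se)^2)
  }
}

# default fit window: from q_min to the first q at which the (lightly
# smoothed) intensity has fallen to I(0)/10, capped at q_cap.  This is the
# low-q decade where the sphere approximation is the stated validity regime.
.default_q_window <- function(profile, i0, q_cap = 0.3, min_points = 10L) {
  q <- profile$q
  ii <- profile$intensity
  k <- min(5L, length(ii))
  ism <- as.numeric(stats::filter(ii, rep(1 / k, k), sides = 2))
  ism[is.na(ism)] <- ii[is.na(ism)]
  below <- which(ism <= i0 / 10)
  q_hi <- if (length(below)) min(q[below[1]], q_cap) else min(max(q), q_cap)
  if (sum(q <= q_hi) < min_points) {
    if (length(q) < min_points)
      stop("insufficient data: fewer than ", min_points, " points")
    q_hi <- q[min_points]
  }
  c(q[1], q_hi)
}

# profiled objective over (mu, sigma): the intensity scale has a closed-form
# optimum for both weighting schemes, so the search is two-dimensional.
.make_objective <- function(qe, ie, se, weighting, n_nodes) {
  log_ie <- log(ie)
  function(par) {
    mu <- par[1]; sigma <- par[2]
    im <- model_intensity(qe, mu, sigma, n_nodes = n_nodes)
    im <- pmax(im, 1e-300)
    if (weighting == "logls") {
      r <- log_ie - log(im)
      ls <- mean(r)
      list(value = mean((r - ls)^2), scale = exp(ls))
    } else {
      s <- sum(im * ie / se^2) / sum(im^2 / se^2)
      s <- max(s, 1e-300)
      list(value = mean(((s * im - ie) / se)^2), scale = s)
    }
  }
}

#' Fit the Rg-distribution model to a SAXS profile
#'
#' The main fitting routine.  A log-normal distribution over the radius of
#' gyration, convolved with the homogeneous-sphere form factor
#' ([model_intensity()]), is fitted to the measured low-angle intensity by
#' minimizing a misfit over `(mu, sigma)` with the overall intensity scale
#' profiled out in closed form.  The differential entropy of the fitted
#' distribution ([rgd_entropy()]) is the flexibility estimate.
#'
#' The objective is multimodal in `sigma` (the sphere form factor
#' oscillates), so a deterministic multi-start strategy is used: bounded
#' quasi-Newton (`L-BFGS-B`) from a lattice of starts with `mu` at
#' `ln(Rg_Guinier) - 1` and `ln(Rg_Guinier) + 1` crossed with
#' `sigma` in `{0.05, 0.2, 0.5, 1.0}`.  Bounds are
#' `mu` in `[ln 2, ln 500]` (median Rg between 2 and 500 Angstrom) and
#' `sigma` in `[1e-3, 2]`.
#'
#' The default fit window is the low-q decade: from `q_min` to the first
#' `q` at which the smoothed intensity has fallen to `I(0)/10` (with `I(0)`
#' from Guinier analysis), capped at 0.3 1/Angstrom.  This is the regime in
#' which intensity depends mainly on particle size, the model's stated
#' domain of validity.
#'
#' @param profile a [saxs_profile].
#' @param q_window optional numeric length-2 fit window in `q`; overrides
#'   the default low-q-decade window.
#' @param objective `"logls"` (default; log-intensity least squares, which
#'   equalizes the decade of dynamic range) or `"chi2"` (error-weighted,
#'   requires profile errors).
#' @param n_starts number of multi-starts actually used (taken from the
#'   head of the 8-point deterministic lattice).
#' @param starts optional matrix/list of explicit `(mu, sigma)` starts,
#'   replacing the lattice.
#' @param resamples if `> 0` and the profile carries errors, the entropy
#'   error is estimated by [entropy_error()] with this many noise refits.
#' @param seed integer seed governing the (optional) noise resampling;
#'   the fit itself is deterministic.
#' @param n_nodes quadrature nodes for the forward model (default 400).
#' @param q_cap upper cap of the automatic fit window, 1/Angstrom.
#' @param mu_bounds,sigma_bounds optimizer box constraints.
#' @param qrg_max Guinier window limit used for the initial size estimate.
#' @return An object of class `"rgd"` with components `mu`, `sigma`,
#'   `scale`, `entropy` (nats), `entropy_err` (or `NA`), `misfit`,
#'   `q_window`, `objective`, `n_starts`, `converged`, `starts`
#'   (per-start diagnostics), `guinier`, `profile`, and `call`.  Standard
#'   methods are provided: [print.rgd()], `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' spec <- ensemble_spec(list(list(weight = 1, kind = "lognormal",
#'                                 mu = 3, sigma = 0.25)))
#' fit <- rgd(generate_profile(spec))
#' coef(fit)
#' fit$entropy
#' @export
rgd <- function(profile, q_window = NULL,
                objective = c("logls", "chi2"),
                n_starts = 8L, starts = NULL, resamples = 0L, seed = 1L,
                n_nodes = 400L, q_cap = 0.3,
                mu_bounds = log(c(2, 500)), sigma_bounds = c(1e-3, 2),
                qrg_max = 1.3) {
  stopifnot(inherits(profile, "saxs_profile"))
  objective <- match.arg(objective)
  cl <- match.call()
  if (length(profile$q) < 10L)
    stop("insufficient data: need at least 10 points to fit")

  gui <- tryCatch(guinier_fit(profile, qrg_max = qrg_max),
                  error = function(e) NULL)
  rg0 <- if (!is.null(gui)) gui$rg else 20
  i0 <- if (!is.null(gui)) gui$i0 else max(profile$intensity)

  if (is.null(q_window))
    q_window <- .default_q_window(profile, i0, q_cap = q_cap)
  sel <- profile$q >= q_window[1] & profile$q <= q_window[2]
  if (sum(sel) < 10L)
    stop("fewer than 10 profile points inside the q window")
  qe <- profile$q[sel]
  ie <- profile$intensity[sel]
  se <- profile$sigma[sel]
  if (objective == "logls" && any(ie <= 0))
    stop("log objective requires positive intensities in the window")
  if (objective == "chi2" && (is.null(se) || any(se <= 0)))
    stop("chi2 objective requires strictly positive profile errors")

  if (is.null(starts)) {
    mu0 <- log(rg0)
    mus <- pmin(pmax(mu0 + c(-1, 1), mu_bounds[1]), mu_bounds[2])
    sig0 <- c(0.05, 0.2, 0.5, 1.0)
    lattice <- as.matrix(expand.grid(mu = mus, sigma = sig0))
    starts <- lattice[seq_len(min(n_starts, nrow(lattice))), , drop = FALSE]
  } else {
    starts <- matrix(unlist(starts), ncol = 2, byrow = is.list(starts),
                     dimnames = list(NULL, c("mu", "sigma")))
  }

  obj <- .make_objective(qe, ie, se, objective, n_nodes)
  fn <- function(par) obj(par)$value

  runs <- vector("list", nrow(starts))
  for (k in seq_len(nrow(starts))) {
    runs[[k]] <- tryCatch(
      stats::optim(par = as.numeric(starts[k, ]), fn = fn,
                   method = "L-BFGS-B",
                   lower = c(mu_bounds[1], sigma_bounds[1]),
                   upper = c(mu_bounds[2], sigma_bounds[2]),
                   control = list(maxit = 200L)),
      error = function(e) list(par = as.numeric(starts[k, ]), value = Inf,
                               convergence = 99L, message = conditionMessage(e)))
    # the objective is non-negative, so an essentially exact fit cannot be
    # improved by the remaining starts
    if (runs[[k]]$convergence == 0L && runs[[k]]$value < 1e-12) {
      runs <- runs[seq_len(k)]
      starts <- starts[seq_len(k), , drop = FALSE]
      break
    }
  }
  values <- vapply(runs, function(r) r$value, numeric(1))
  conv <- vapply(runs, function(r) r$convergence == 0L, logical(1))
  if (!any(is.finite(values)))
    stop("fit failure: no start produced a finite objective; diagnostics: ",
         paste(vapply(runs, function(r)
           if (is.null(r$message)) "?" else r$message, character(1)),
           collapse = "; "))
  best <- runs[[which.min(values)]]
  fin <- obj(best$par)

  start_diag <- data.frame(
    mu_start = starts[, 1], sigma_start = starts[, 2],
    mu_end = vapply(runs, function(r) r$par[1], numeric(1)),
    sigma_end = vapply(runs, function(r) r$par[2], numeric(1)),
    misfit = values, converged = conv)

  out <- structure(list(
    mu = best$par[1], sigma = best$par[2], scale = fin$scale,
    entropy = rgd_entropy(best$par[1], best$par[2]),
    entropy_err = NA_real_,
    misfit = fin$value, q_window = q_window, objective = objective,
    n_starts = nrow(starts), starts = start_diag,
    converged = any(conv), guinier = gui,
    n_nodes = n_nodes, seed = as.integer(seed),
    mu_bounds = mu_bounds, sigma_bounds = sigma_bounds,
    profile = profile, call = cl), class = "rgd")

  if (resamples > 0 && !is.null(profile$sigma))
    out$entropy_err <- entropy_error(profile, out,
                                     n_resamples = resamples, seed = seed)
  out
}

#' Monte-Carlo error of the RgD entropy
#'
#' Propagates the reported per-point intensity errors into the entropy by
#' noise resampling: the profile's intensities are perturbed by independent
#' additive Gaussian noise with the reported standard deviations, the model
#' is refitted, and the standard deviation of the entropy across refits is
#' returned.  Refits start from the original optimum (with bracketing
#' `sigma` starts), since the perturbations are small.
#'
#' @param profile a [saxs_profile] carrying `sigma`.
#' @param fit an [rgd()] fit of that profile.
#' @param n_resamples number of noise refits, at least 2.
#' @param seed integer seed; results are reproducible given the seed.
#' @return Non-negative scalar: sd of the entropy over refits.
#' @export
entropy_error <- function(profile, fit, n_resamples = 100L, seed = 1L) {
  stopifnot(inherits(profile, "saxs_profile"), inherits(fit, "rgd"))
  if (is.null(profile$sigma))
    stop("entropy_error requires a profile with reported errors")
  if (!isTRUE(fit$converged))
    stop("entropy_error requires a converged fit")
  if (n_resamples < 2L)
    stop("`n_resamples` must be at least 2")
  sb <- fit$sigma_bounds
  warm <- rbind(c(fit$mu, fit$sigma),
                c(fit$mu, max(fit$sigma / 2, sb[1])),
                c(fit$mu, min(fit$sigma * 2, sb[2])))
  old_seed <- .save_seed()
  on.exit(.restore_seed(old_seed))
  set.seed(as.integer(seed))
  ent <- numeric(n_resamples)
  n <- length(profile$q)
  for (b in seq_len(n_resamples)) {
    inoisy <- profile$intensity + stats::rnorm(n, 0, profile$sigma)
    keep <- inoisy > 0
    p_b <- saxs_profile(profile$q[keep], inoisy[keep],
                        sigma = profile$sigma[keep], label = profile$label)
    f_b <- rgd(p_b, q_window = fit$q_window, objective = fit$objective,
               starts = warm, n_nodes = fit$n_nodes,
               mu_bounds = fit$mu_bounds, sigma_bounds = sb)
    ent[b] <- f_b$entropy
  }
  stats::sd(ent)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
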