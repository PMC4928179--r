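# Synthetic SAXS profiles from specified Rg ensembles.  These emulate the
# statistical structure of deposited solution-scattering data — a monotone
# low-q decay of about one order of magnitude, q extending to at least
# 0.3 1/Angstrom, and multiplicative noise growing toward high q — and
# serve as ground-truth test beds for the RgD fit.

#' Specify a synthetic Rg ensemble
#'
#' An ensemble is a finite mixture of components, each either a `delta`
#' (a single conformation with a fixed radius of gyration) or a
#' `lognormal` (a continuum of sizes with parameters `mu`, `sigma`).
#' Mixtures of deltas emulate discrete open/closed two-state systems;
#' a single log-normal matches the model the fit assumes.
#'
#' @param components list of components; each a list with `weight`
#'   (positive, weights must sum to 1) and `kind` (`"delta"` with `rg` in
#'   Angstrom, or `"lognormal"` with `mu`, `sigma`).
#' @param q_grid strictly increasing q grid, 1/Angstrom.  The default —
#'   400 linear points on \[0.005, 0.35\] — extends past 0.3 1/Angstrom, the
#'   usual minimum coverage required for a meaningful Kratky analysis.
#' @param noise `"none"` or `"multiplicative_gaussian"` (per-point sd equal
#'   to `noise_level` times the clean intensity, the crude counting-noise
#'   model).
#' @param noise_level relative noise level (fraction).
#' @param seed integer seed used when noise is drawn.
#' @param scale overall intensity scale (arbitrary units).
#' @return Object of class `"ensemble_spec"`.
#' @examples
#' ensemble_spec(list(list(weight = 1, kind = "delta", rg = 20)))
#' ensemble_spec(list(
#'   list(weight = 0.5, kind = "delta", rg = 18),
#'   list(weight = 0.5, kind = "delta", rg = 35)),
#'   noise = "multiplicative_gaussian", noise_level = 0.01)
#' @export
ensemble_spec <- function(components,
                          q_grid = seq(0.005, 0.35, length.out = 400),
                          noise = c("none", "multiplicative_gaussian"),
                          noise_level = 0.01, seed = 1L, scale = 1) {
  noise <- match.arg(noise)
  if (!is.list(components) || length(components) == 0L)
    stop("`components` must be a non-empty list")
  w <- vapply(components, function(cp) as.numeric(cp$weight), numeric(1))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("component weights must be positive")
  if (abs(sum(w) - 1) > 1e-8)
    stop("component weights must sum to 1 (got ", sum(w), ")")
  for (cp in components) {
    kind <- match.arg(cp$kind, c("delta", "lognormal"))
    if (kind == "delta") {
      if (is.null(cp$rg) || cp$rg <= 0)
        stop("delta component requires positive `rg`")
    } else {
      .check_mu_sigma(cp$mu, cp$sigma)
    }
  }
  q_grid <- as.numeric(q_grid)
  if (any(q_grid <= 0) || is.unsorted(q_grid, strictly = TRUE))
    stop("`q_grid` must be positive and strictly increasing")
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be positive")
  if (noise != "none" && (!is.finite(noise_level) || noise_level < 0))
    stop("`noise_level` must be non-negative")
  structure(list(components = components, q_grid = q_grid, noise = noise,
                 noise_level = noise_level, seed = as.integer(seed),
                 scale = scale),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("Rg ensemble: %d component(s), %d q-points, noise = %s\n",
              length(x$components), length(x$q_grid), x$noise))
  for (cp in x$components) {
    if (cp$kind == "delta")
      cat(sprintf("  %.3g x delta(Rg = %.4g A)\n", cp$weight, cp$rg))
    else
      cat(sprintf("  %.3g x lognormal(mu = %.4g, sigma = %.4g)  [S = %.4g]\n",
                  cp$weight, cp$mu, cp$sigma,
                  rgd_entropy(cp$mu, cp$sigma)))
  }
  invisible(x)
}

#' Generate a synthetic SAXS profile from an Rg ensemble
#'
#' The clean intensity is the weighted ensemble average of
#' homogeneous-sphere intensities — exact for delta components,
#' quadrature ([model_intensity()]) for log-normal components — times the
#' overall scale.  Multiplicative Gaussian noise, when requested, is drawn
#' with the spec's seed; the profile then carries `sigma = level * I_clean`
#' as its per-point error, mirroring how deposited files report errors.
#'
#' @param spec an [ensemble_spec()].
#' @param label profile label.
#' @return A [saxs_profile].  The generating truth is attached as attribute
#'   `"truth"`: the spec itself plus, for a single log-normal component,
#'   the true `mu`, `sigma` and entropy.
#' @export
generate_profile <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "ensemble_spec"))
  q <- spec$q_grid
  iclean <- numeric(length(q))
  for (cp in spec$components) {
    comp <- if (cp$kind == "delta") sphere_intensity(q, cp$rg)
            else model_intensity(q, cp$mu, cp$sigma)
    iclean <- iclean + cp$weight * comp
  }
  iclean <- spec$scale * iclean
  if (spec$noise == "none") {
    prof <- saxs_profile(q, iclean, label = label)
  } else {
    old_seed <- .save_seed()
    on.exit(.restore_seed(old_seed))
    set.seed(spec$seed)
    sig <- spec$noise_level * iclean
    inoisy <- iclean + sig * stats::rnorm(length(q))
    keep <- inoisy > 0
    prof <- saxs_profile(q[keep], inoisy[keep], sigma = sig[keep],
                         label = label)
  }
  truth <- list(spec = spec)
  if (length(spec$components) == 1L &&
      spec$components[[1]]$kind == "lognormal") {
    truth$mu <- spec$components[[1]]$mu
    truth$sigma <- spec$components[[1]]$sigma
    truth$entropy <- rgd_entropy(truth$mu, truth$sigma)
  }
  attr(prof, "truth") <- truth
  prof
}

# default parameters of the three-member demonstration suite: a compact
# folded protein, a partially disordered protein, and an IDP, with
# increasing median size and increasing relative Rg spread
.suite_params <- function() {
  data.frame(
    name = c("folded", "partial", "disordered"),
    mu = c(log(16), log(22), log(35)),
    sigma = c(0.06, 0.20, 0.45),
    stringsAsFactors = FALSE)
}

#' Generate a folded / partially disordered / IDP fixture suite
#'
#' Writes three synthetic `.dat` profiles with increasing true Rg spread —
#' a compact folded protein (narrow log-normal), a partially disordered
#' protein (intermediate) and an intrinsically disordered protein (broad)
#' — plus a JSON sidecar recording the generating truth.  Fitted entropies
#' over the suite are strictly increasing, the qualitative ordering
#' expected across these structural classes.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the noise draws.
#' @param noise_level relative noise level (default 1\%).
#' @param q_grid q grid passed to [ensemble_spec()].
#' @return Invisibly, a data frame with columns `name`, `file`, `mu`,
#'   `sigma`, `entropy` (the true values).
#' @export
generate_suite <- function(dir, seed = 1L, noise_level = 0.01,
                           q_grid = seq(0.005, 0.35, length.out = 400)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pars <- .suite_params()
  pars$file <- file.path(dir, paste0(pars$name, ".dat"))
  pars$entropy <- rgd_entropy(pars$mu, pars$sigma)
  for (i in seq_len(nrow(pars))) {
    spec <- ensemble_spec(
      list(list(weight = 1, kind = "lognormal",
                mu = pars$mu[i], sigma = pars$sigma[i])),
      q_grid = q_grid, noise = "multiplicative_gaussian",
      noise_level = noise_level, seed = as.integer(seed) + i)
    prof <- generate_profile(spec, label = pars$name[i])
    write_dat(prof, pars$file[i])
  }
  sidecar <- lapply(seq_len(nrow(pars)), function(i) list(
    name = pars$name[i], file = basename(pars$file[i]),
    mu = pars$mu[i], sigma = pars$sigma[i], entropy = pars$entropy[i],
    noise_level = noise_level, seed = as.integer(seed) + i))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(pars[, c("name", "file", "mu", "sigma", "entropy")])
}
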