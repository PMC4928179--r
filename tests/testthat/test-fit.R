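test_that("the fitted optimum matches an independent coarse grid search", {
  prof <- make_lognormal_profile(mu = 3, sigma = 0.25)
  # oracle: profile-scale log-LS misfit evaluated on a parameter lattice
  qw <- c(min(prof$q), 0.1)
  sel <- prof$q <= qw[2]
  qe <- prof$q[sel]; le <- log(prof$intensity[sel])
  grid_misfit <- function(mu, sigma) {
    r <- le - log(model_intensity(qe, mu, sigma))
    mean((r - mean(r))^2)
  }
  mus <- seq(2.8, 3.2, by = 0.02)
  sigmas <- seq(0.15, 0.35, by = 0.01)
  vals <- outer(mus, sigmas, Vectorize(grid_misfit))
  ij <- which(vals == min(vals), arr.ind = TRUE)
  expect_equal(mus[ij[1]], 3, tolerance = 0.021)
  expect_equal(sigmas[ij[1, 2]], 0.25, tolerance = 0.011)

  fit <- rgd(prof, q_window = qw)
  expect_true(fit$converged)
  expect_equal(fit$mu, 3, tolerance = 1e-3)
  expect_equal(fit$sigma, 0.25, tolerance = 1e-3)
  # at least as good as the lattice, up to quadrature-noise resolution
  expect_lte(fit$misfit, min(vals) + 1e-10)
  expect_identical(fit$entropy, rgd_entropy(fit$mu, fit$sigma))
  expect_gte(fit$q_window[1], min(prof$q))
  expect_lte(fit$q_window[2], max(prof$q))
})

test_that("1% multiplicative noise perturbs the estimates only slightly", {
  prof <- make_lognormal_profile(mu = 3, sigma = 0.25, noise_level = 0.01,
                                 seed = 1)
  fit <- rgd(prof, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$mu, 3, tolerance = 0.05)
  expect_equal(fit$sigma, 0.25, tolerance = 0.05)
})

test_that("the chi2 objective agrees with log-LS on well-behaved data", {
  prof <- make_lognormal_profile(mu = 3, sigma = 0.3, noise_level = 0.01,
                                 seed = 5)
  f1 <- rgd(prof, objective = "logls")
  f2 <- rgd(prof, objective = "chi2")
  expect_equal(f1$mu, f2$mu, tolerance = 0.02)
  expect_equal(f1$sigma, f2$sigma, tolerance = 0.02)
})

test_that("degenerate inputs raise fit errors", {
  q <- c(0.01, 0.02)
  expect_error(rgd(saxs_profile(q, c(2, 1))), "insufficient|fewer")
  p9 <- make_guinier_profile(q = seq(0.005, 0.02, length.out = 9))
  expect_error(rgd(p9), "insufficient|fewer")
})

test_that("rescaling the intensities changes only the fitted scale", {
  prof <- make_lognormal_profile(mu = 3.2, sigma = 0.35)
  f0 <- rgd(prof)
  for (cc in c(1e-3, 7, 1e4)) {
    pc <- saxs_profile(prof$q, cc * prof$intensity, label = prof$label)
    fc <- rgd(pc)
    expect_equal(fc$mu, f0$mu, tolerance = 1e-6)
    expect_equal(fc$sigma, f0$sigma, tolerance = 1e-6)
    expect_equal(fc$entropy, f0$entropy, tolerance = 1e-6)
    expect_equal(fc$scale / f0$scale, cc, tolerance = 1e-4)
  }
})

test_that("larger true sigma yields larger fitted entropy at fixed mu", {
  ents <- vapply(c(0.1, 0.3, 0.6), function(s)
    rgd(make_lognormal_profile(mu = 3, sigma = s))$entropy, numeric(1))
  expect_true(all(diff(ents) > 0))
})

test_that("entropy_error propagates reported noise reproducibly", {
  prof <- make_lognormal_profile(mu = 3, sigma = 0.25, noise_level = 0.01,
                                 seed = 3)
  fit <- rgd(prof)
  e1 <- entropy_error(prof, fit, n_resamples = 10, seed = 101)
  e2 <- entropy_error(prof, fit, n_resamples = 10, seed = 101)
  expect_identical(e1, e2)               # same seed, same answer
  expect_gt(e1, 0)
  e3 <- entropy_error(prof, fit, n_resamples = 10, seed = 202)
  expect_gt(e3, 0)
  expect_lt(abs(e3 - e1) / e1, 1)        # same order of magnitude

  # degenerate reported errors: refits are identical, spread is exactly 0
  p0 <- saxs_profile(prof$q, prof$intensity,
                     sigma = numeric(length(prof$q)))
  f0 <- rgd(p0)
  expect_identical(entropy_error(p0, f0, n_resamples = 3, seed = 1), 0)

  expect_error(entropy_error(prof, fit, n_resamples = 1), "at least 2")
  pf <- make_lognormal_profile(mu = 3, sigma = 0.25)   # no sigma column
  expect_error(entropy_error(pf, rgd(pf), n_resamples = 5),
               "reported errors")
})

test_that("fit methods expose the model consistently", {
  prof <- make_lognormal_profile(mu = 3, sigma = 0.25, noise_level = 0.01,
                                 seed = 2)
  fit <- rgd(prof)
  expect_named(coef(fit), c("mu", "sigma", "scale"))
  expect_equal(unname(coef(fit)[1:2]), c(fit$mu, fit$sigma))
  # predict on the fitted window equals fitted()
  sel <- prof$q >= fit$q_window[1] & prof$q <= fit$q_window[2]
  expect_equal(fitted(fit), predict(fit, q = prof$q[sel]))
  expect_equal(predict(fit, q = 0, type = "normalized"), 1,
               tolerance = 2e-4)        # quadrature-level normalization
  # residuals: log residuals are log(data) - log(fit)
  r <- residuals(fit)
  expect_equal(r, log(prof$intensity[sel]) - log(fitted(fit)))
  expect_lt(sd(r), 0.02)                 # 1% noise scale
  rp <- residuals(fit, type = "pearson")
  expect_lt(mean(abs(rp)), 3)
  # simulate returns valid profiles on the same grid
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "saxs_profile")
  expect_identical(simulate(fit, nsim = 1, seed = 9)[[1]]$intensity,
                   sims[[1]]$intensity)
  s <- summary(fit)
  expect_s3_class(s, "summary.rgd")
  expect_equal(s$rg_median, exp(fit$mu))
  expect_output(print(s), "flexibility class")
})
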