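# shared fixture builders; everything is generated in code, no stored data

# ideal Guinier curve I(q) = i0 * exp(-q^2 rg^2 / 3)
make_guinier_profile <- function(rg = 20, i0 = 7, q = seq(0.005, 0.05,
                                                          length.out = 60),
                                 label = "guinier") {
  saxs_profile(q, i0 * exp(-q^2 * rg^2 / 3), label = label)
}

# noiseless single-log-normal ensemble profile with attached truth
make_lognormal_profile <- function(mu = 3, sigma = 0.25, scale = 1,
                                   q = seq(0.005, 0.35, length.out = 400),
                                   noise_level = 0, seed = 1L) {
  spec <- ensemble_spec(
    list(list(weight = 1, kind = "lognormal", mu = mu, sigma = sigma)),
    q_grid = q, scale = scale,
    noise = if (noise_level > 0) "multiplicative_gaussian" else "none",
    noise_level = noise_level, seed = seed)
  generate_profile(spec)
}

expect_profile_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$q, b$q, tolerance = tol)
  expect_equal(a$intensity, b$intensity, tolerance = tol)
  expect_equal(is.null(a$sigma), is.null(b$sigma))
  if (!is.null(a$sigma)) expect_equal(a$sigma, b$sigma, tolerance = tol)
}
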