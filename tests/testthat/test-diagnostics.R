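test_that("kratky transform: closed forms and invertibility", {
  q <- seq(0.01, 0.4, length.out = 100)
  # ideal Gaussian-chain signature: I ~ 1/q^2 gives a flat plateau
  k <- kratky(saxs_profile(q, 1 / q^2))
  expect_equal(k$y, rep(1, length(q)), tolerance = 1e-12)
  expect_equal(k$x, q)
  # compact particle: interior maximum
  kg <- kratky(make_guinier_profile(rg = 20, q = seq(0.01, 0.3,
                                                     length.out = 200)))
  imax <- which.max(kg$y)
  expect_gt(imax, 1)
  expect_lt(imax, length(kg$y))
  # pointwise inverse recovers I(q)
  p <- make_lognormal_profile()
  kk <- kratky(p)
  expect_equal(kk$y / kk$x^2, p$intensity, tolerance = 1e-14)
})

test_that("dimensionless Kratky peaks at sqrt(3) with height 3/e", {
  rg <- 20; i0 <- 7
  q <- seq(0.001, 0.2, length.out = 4000)
  p <- saxs_profile(q, i0 * exp(-q^2 * rg^2 / 3))
  dk <- dimensionless_kratky(p, rg = rg, i0 = i0)
  imax <- which.max(dk$y)
  expect_equal(dk$x[imax], sqrt(3), tolerance = 1e-3)
  expect_equal(dk$y[imax], 3 * exp(-1), tolerance = 1e-4)
})

test_that("dimensionless Kratky is size-invariant", {
  # two Guinier particles probed on q grids chosen so the dimensionless
  # abscissae q*Rg coincide exactly: the curves must be identical
  x <- seq(0.05, 3, length.out = 300)
  mk <- function(rg) {
    q <- x / rg
    p <- saxs_profile(q, 4 * exp(-q^2 * rg^2 / 3))
    dimensionless_kratky(p, rg = rg, i0 = 4)
  }
  a <- mk(15); b <- mk(45)
  expect_equal(a$x, b$x, tolerance = 1e-12)
  expect_equal(a$y, b$y, tolerance = 1e-12)
  p <- make_guinier_profile()
  expect_error(dimensionless_kratky(p, rg = 20, i0 = 0), "positive")
  expect_error(dimensionless_kratky(p, rg = -2, i0 = 1), "positive")
})

test_that("Porod-Debye transform: closed forms, exponent-3 variant, inverse", {
  q <- seq(0.05, 0.4, length.out = 120)
  cc <- 3.7; i0 <- 2
  pd4 <- porod_debye(saxs_profile(q, cc / q^4), i0 = i0)
  expect_equal(pd4$x, q^4)
  expect_equal(pd4$y, rep(cc / i0, length(q)), tolerance = 1e-12)
  pd2 <- porod_debye(saxs_profile(q, cc / q^2), i0 = i0)
  expect_equal(pd2$y, sqrt(pd2$x) * cc / i0, tolerance = 1e-10)
  expect_true(all(diff(pd2$y) > 0))
  pd3 <- porod_debye(saxs_profile(q, cc / q^3), i0 = i0, exponent = 3)
  expect_identical(pd3$kind, "q3_debye")
  expect_equal(pd3$y, rep(cc / i0, length(q)), tolerance = 1e-12)
  # inverse: I = y * i0 / x
  p <- make_lognormal_profile()
  pdm <- porod_debye(p, i0 = 1)
  expect_equal(pdm$y / pdm$x, p$intensity, tolerance = 1e-14)
  expect_error(porod_debye(p, i0 = -1), "positive")
  expect_error(porod_debye(p, i0 = 1, exponent = 5), "3 or 4")
})

test_that("plateau detection separates compact from flexible decays", {
  q <- seq(0.005, 0.35, length.out = 400)
  x60 <- seq(0.001, 1, length.out = 60)
  const <- rgdflex:::new_transformed_curve(x60, rep(2.5, 60),
                                           "porod_debye", "x", "y")
  rc <- detect_plateau(const)
  expect_true(rc$present)
  expect_equal(rc$level, 2.5, tolerance = 1e-12)

  rising <- rgdflex:::new_transformed_curve(x60, x60^0.5,
                                            "porod_debye", "x", "y")
  expect_false(detect_plateau(rising)$present)

  # polydisperse sphere ensemble: noiseless oracle, then 1% noise
  iclean <- model_intensity(q, log(20), 0.2)
  r0 <- detect_plateau(porod_debye(saxs_profile(q, iclean), i0 = 1))
  expect_true(r0$present)
  set.seed(4)
  pn <- saxs_profile(q, iclean * (1 + 0.01 * rnorm(length(q))))
  rn <- detect_plateau(porod_debye(pn, i0 = 1))
  expect_true(rn$present)
  expect_equal(rn$level, r0$level, tolerance = 0.05)

  # chain-like q^-2 decay never flattens on the q^4 axis
  pflex <- saxs_profile(q, 1 / (1 + (q * 30)^2))
  expect_false(detect_plateau(porod_debye(pflex, i0 = 1))$present)

  expect_error(detect_plateau(kratky(pflex)), "porod_debye")
  short <- rgdflex:::new_transformed_curve(x60[1:10], x60[1:10],
                                           "porod_debye", "x", "y")
  expect_error(detect_plateau(short), "insufficient|20 points")
})

test_that("entropy quartile classification follows the cut-point rules", {
  expect_identical(as.character(classify_entropy(2.58)), "Q1_compact")
  expect_identical(as.character(classify_entropy(4.41)), "Q4_disordered")
  # boundaries are inclusive on the left class
  expect_identical(as.character(classify_entropy(3.37)), "Q1_compact")
  expect_identical(as.character(classify_entropy(3.86)), "Q2_intermediate")
  expect_identical(as.character(classify_entropy(4.26)), "Q3_flexible")
  expect_identical(as.character(classify_entropy(3.38)), "Q2_intermediate")
  # monotone non-decreasing and exhaustive over finite s
  s <- sort(c(runif(50, -2, 7), 3.37, 3.86, 4.26))
  cls <- as.integer(classify_entropy(s))
  expect_true(all(diff(cls) >= 0))
  expect_false(anyNA(cls))
  expect_error(classify_entropy(NaN), "finite")
  expect_error(classify_entropy(Inf), "finite")
})
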