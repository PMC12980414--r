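# Relaxation, amide-I deconvolution, cumulant fits and diameter conversion.

test_that("inversion-recovery fit recovers noiseless planted parameters", {
  d <- synthRelaxation(100, 2, "inversion_recovery", snr = Inf)
  f <- fitInversionRecovery(d$t, d$I)
  expect_equal(f@i0, 100, tolerance = 1e-6)
  expect_equal(f@rate, 2, tolerance = 1e-6)
  # model value at t = 0 is -I0
  expect_equal(f@i0 * (1 - 2 * exp(-f@rate * 0)), -f@i0)
  expect_error(fitInversionRecovery(1:3, c(1, 2, 3)), "at least 4")
})

test_that("CPMG fit matches the log-linear oracle and the half-life identity", {
  d <- synthRelaxation(50, 30, "cpmg_decay", snr = Inf)
  f <- fitCpmgDecay(d$t, d$I)
  expect_equal(f@i0, 50, tolerance = 1e-6)
  expect_equal(f@rate, 30, tolerance = 1e-6)
  ll <- stats::lm(log(d$I) ~ d$t)
  expect_equal(unname(-stats::coef(ll)[2]), f@rate, tolerance = 1e-6)
  # halving time ln2 / R2
  I_of <- function(t) f@i0 * exp(-f@rate * t)
  expect_equal(I_of(0.05 + log(2) / f@rate), I_of(0.05) / 2,
               tolerance = 1e-9)
})

test_that("relaxation errors are SNR-calibrated against Monte-Carlo truth", {
  res <- vapply(1:200, function(k) {
    d <- synthRelaxation(100, 2, "inversion_recovery", snr = 50, seed = k)
    f <- fitInversionRecovery(d$t, d$I, snr = 50)
    c(f@rate, f@stderrRate)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) / 2 - 1), 0.01)
  ratio <- stats::sd(res[1, ]) / mean(res[2, ])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("a single synthetic Voigt band is recovered to high accuracy", {
  ir <- synthIR(centers = 1650, areas = 50, gaussian_sd = 6,
                lorentzian_hwhm = 3, noise_sd = 0)
  dec <- deconvolveAmideI(ir$wavenumber, ir$absorbance,
                          init_centers = 1650)
  cmp <- dec@components
  expect_equal(cmp$center, 1650, tolerance = 1e-4)
  expect_equal(cmp$gaussianWidth, 6, tolerance = 1e-3)
  expect_equal(cmp$lorentzianWidth, 3, tolerance = 1e-3)
  expect_equal(cmp$area, 50, tolerance = 1e-4)
})

test_that("the Voigt profile equals a numerical Gauss-Lorentz convolution", {
  xs <- c(-5, -1.2, 0, 0.8, 2.5, 7)
  for (par in list(c(1.3, 0.7), c(2.5, 0.05), c(0.6, 2.0))) {
    got <- voigtProfile(xs, 0, par[1], par[2])
    want <- vapply(xs, function(x0) stats::integrate(function(u)
      stats::dnorm(u, 0, par[1]) * (par[2] / pi) /
        ((x0 - u)^2 + par[2]^2), -Inf, Inf, rel.tol = 1e-10)$value,
      numeric(1))
    expect_equal(got, want, tolerance = 1e-4)
  }
  # unit area (wide bounds: the Lorentzian wing decays only as 1/x^2)
  expect_equal(stats::integrate(function(x) voigtProfile(x, 0, 2, 1),
                                -2e4, 2e4)$value, 1, tolerance = 1e-3)
})

test_that("two overlapping bands give area fractions within 2% and bounded residuals", {
  noise <- 0.01
  ir <- synthIR(centers = c(1650, 1635), areas = c(60, 40),
                gaussian_sd = 5, lorentzian_hwhm = 2,
                noise_sd = noise, seed = 4)
  dec <- deconvolveAmideI(ir$wavenumber, ir$absorbance,
                          init_centers = c(1650, 1635))
  fr <- dec@components$area / sum(dec@components$area)
  expect_equal(fr[order(-dec@components$center)], c(0.6, 0.4),
               tolerance = 0.02 / 0.4)
  resid <- ir$absorbance[ir$wavenumber >= 1600 & ir$wavenumber <= 1700] -
    dec@fitted
  expect_lt(sqrt(mean(resid^2)), noise * 1.2)
})

test_that("structure fractions pool beta-sheet bands, sum to 100 and ignore order", {
  one <- data.frame(center = 1670, area = 12)
  r1 <- structureFractions(one)
  expect_equal(unname(r1@fractions["alpha_helix"]), 100)
  planted <- data.frame(center = c(1682, 1670, 1649, 1637, 1622),
                        area = c(3, 11, 34, 30, 22))
  rp <- structureFractions(planted)
  expect_equal(unname(rp@fractions),
               c(3, 11, 34, 52), tolerance = 1e-9)
  expect_equal(sum(rp@fractions), 100, tolerance = 1e-4)
  shuf <- planted[c(4, 1, 5, 2, 3), ]
  expect_equal(structureFractions(shuf)@fractions, rp@fractions)
  expect_error(structureFractions(data.frame(center = 1700, area = 1)),
               "outside all")
})

test_that("cumulant fit recovers monodisperse and polydisperse planted truths", {
  d <- synthDLS(dh = 72.3, pdi = 0, counts = Inf)
  f <- fitCumulants(d$tau, d$g2, sigma = d$sigma)
  expect_equal(f@gamma, d$truth$gamma, tolerance = 1e-3)
  expect_lt(f@pdi, 1e-3)
  expect_equal(f@baseline, 1, tolerance = 1e-6)
  # long-time asymptote equals the baseline
  expect_equal(d$g2[length(d$g2)], f@baseline, tolerance = 1e-3)
  pdis <- vapply(1:200, function(k)
    fitCumulants(synthDLS(pdi = 0.1, counts = 1e7, seed = k)$tau,
                 synthDLS(pdi = 0.1, counts = 1e7, seed = k)$g2,
                 counts = 1e7)@pdi, numeric(1))
  expect_lt(abs(mean(pdis) / 0.1 - 1), 0.15)
  expect_error(fitCumulants(d$tau, rev(d$g2)), "decay")
})

test_that("hydrodynamic diameter follows Stokes-Einstein and inverts the generator", {
  # doubling Gamma halves Dh
  d1 <- hydrodynamicDiameter(1000)
  d2 <- hydrodynamicDiameter(2000)
  expect_equal(d1 / d2, 2, tolerance = 1e-12)
  # hand Stokes-Einstein: D = 1e-11 m^2/s at 293 K in water
  D <- 1e-11
  q <- 4 * pi * 1.33 * sin(pi / 4) / 633e-9
  dh_hand <- 2 * 1.380649e-23 * 293 / (6 * pi * 1.002e-3 * D) * 1e10
  expect_equal(hydrodynamicDiameter(D * q^2), dh_hand, tolerance = 1e-9)
  # round trip against the planted generator value
  d <- synthDLS(dh = 72, counts = 1e6, seed = 2)
  f <- hydrodynamicDiameter(fitCumulants(d$tau, d$g2, counts = 1e6))
  expect_equal(f@dh, 72, tolerance = 0.02)
})

test_that("fitters are estimator-consistent as noise vanishes", {
  rates <- vapply(c(100, 1000, 1e5), function(snr) {
    d <- synthRelaxation(80, 5, "cpmg_decay", snr = snr, seed = 1)
    abs(fitCpmgDecay(d$t, d$I, snr = snr)@rate - 5)
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_lt(rates[3], 1e-3)
})
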