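# Debye profiles, chi-square fitting, curve averaging, Guinier and P(r).

test_that("q/angle conversion matches the closed form and round-trips", {
  expect_equal(qFromAngle(0), 0)
  expect_equal(qFromAngle(pi, 1.548), 4 * pi / 1.548)
  tt <- seq(0.001, 0.3, length.out = 50)
  expect_equal(angleFromQ(qFromAngle(tt)), tt, tolerance = 1e-12)
})

test_that("Debye profile has the closed forms and brute-force oracle agreement", {
  q <- seq(0.01, 0.5, length.out = 30)
  one <- debyeProfile(matrix(0, 1, 3), q, form_factor = "unit")
  expect_equal(one@I, rep(1, 30))
  d <- 6.2
  two <- debyeProfile(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE), q,
                      form_factor = "unit")
  expect_equal(two@I, 2 + 2 * sin(q * d) / (q * d), tolerance = 1e-12)
  for (seed in 1:3) {
    set.seed(seed)
    xyz <- matrix(stats::rnorm(60, sd = 8), 20, 3)
    got <- debyeProfile(xyz, q)@I
    want <- debye_oracle(xyz, q, f = rep(6, 20))
    expect_lt(max(abs(got - want) / want), 1e-10)
  }
  expect_error(debyeProfile(matrix(0, 0, 3)), "empty")
})

test_that("Debye profile is rigid-motion invariant, positive, and peaks at I(0)", {
  s <- fix_two_domain()$s
  q <- c(1e-9, seq(0.01, 0.4, length.out = 40))
  base <- debyeProfile(s, q)@I
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- coords(s) %*% R + matrix(c(5, -3, 11), nAtoms(s), 3, byrow = TRUE)
  rot <- debyeProfile(moved, q, form_factor = "unit")
  rot2 <- debyeProfile(coords(s), q, form_factor = "unit")
  expect_lt(max(abs(rot@I - rot2@I) / rot2@I), 1e-10)
  expect_true(all(base > 0))
  expect_equal(which.max(base), 1)
  expect_equal(base[1], sum(sbmsaxs:::.f0_table[s@atoms$element])^2,
               tolerance = 1e-6)
})

test_that("chi-square is exact on perfect and rescaled data and calibrates on noise", {
  s <- fix_two_domain()$s
  th <- debyeProfile(s)
  perfect <- ScatteringCurve(th@q, th@I, sigma = 0.01 * th@I)
  f <- chiSquare(perfect, th)
  expect_equal(f@scale, 1)
  expect_equal(f@chi2, 0)
  tripled <- ScatteringCurve(th@q, 3 * th@I, sigma = 0.01 * th@I)
  f3 <- chiSquare(tripled, th)
  expect_equal(f3@scale, 3)
  expect_equal(f3@chi2, 0, tolerance = 1e-20)
  # equivariance/invariance under rescaling
  th_scaled <- ScatteringCurve(th@q, 7 * th@I)
  expect_equal(chiSquare(tripled, th_scaled)@chi2, f3@chi2, tolerance = 1e-12)
  expect_equal(chiSquare(tripled, th_scaled)@scale, 3 / 7, tolerance = 1e-12)
  # simulation with known truth
  cs <- vapply(1:100, function(sd) {
    e <- synthSAXS(s, mean_counts = 1e4, seed = sd)
    ft <- chiSquare(e, th)
    c(ft@chi2, ft@scale)
  }, numeric(2))
  expect_gt(mean(cs[1, ]), 0.85)
  expect_lt(mean(cs[1, ]), 1.15)
  # generator emits the curve on the model scale, so the true scale is 1
  expect_lt(abs(mean(cs[2, ]) - 1), 3 * stats::sd(cs[2, ]) / sqrt(100))
  expect_error(chiSquare(th, th), "sigma")
})

test_that("residual diagnostics flag systematic offsets and pass pure noise", {
  s <- fix_two_domain()$s
  th <- debyeProfile(s)
  perfect <- ScatteringCurve(th@q, th@I, sigma = 0.01 * th@I)
  rc <- residualCurve(chiSquare(perfect, th))
  expect_true(all(rc$residuals == 0))
  # constant additive offset -> one-signed residual pattern
  off <- ScatteringCurve(th@q, th@I + 0.2 * min(th@I),
                         sigma = 0.001 * th@I)
  rc_off <- residualCurve(chiSquare(off, th))
  expect_true(rc_off$systematic)
  set.seed(11)
  noise <- ScatteringCurve(th@q, th@I * (1 + stats::rnorm(40, 0, 0.01)),
                           sigma = 0.01 * th@I)
  rc_n <- residualCurve(chiSquare(noise, th))
  expect_lt(abs(rc_n$mean), 3 / sqrt(40))
})

test_that("weighted averaging pools curves with propagated uncertainty", {
  q <- seq(0.01, 0.2, length.out = 15)
  a <- ScatteringCurve(q, rep(2, 15), sigma = rep(0.5, 15))
  avg3 <- averageCurves(list(a, a, a))
  expect_equal(avg3@I, a@I)
  expect_equal(avg3@sigma, a@sigma / sqrt(3))
  b <- ScatteringCurve(q, rep(10, 15), sigma = rep(1e9, 15))
  avg_w <- averageCurves(list(a, b))
  expect_equal(avg_w@I, a@I, tolerance = 1e-9)
  two <- averageCurves(list(ScatteringCurve(0.1, 0, sigma = 1),
                            ScatteringCurve(0.1, 2, sigma = 1)))
  expect_equal(two@I, 1)
  expect_equal(two@sigma, 1 / sqrt(2))
  expect_error(averageCurves(list(a, ScatteringCurve(q + 1, a@I, a@sigma))),
               "common q grid")
})

test_that("Guinier fit recovers exact Gaussian, sphere-oracle and noisy radii", {
  q <- seq(0.004, 0.2, by = 0.002)
  exact <- ScatteringCurve(q, 5 * exp(-q^2 * 20^2 / 3))
  g <- guinierFit(exact)
  expect_equal(g@rg, 20, tolerance = 1e-6)
  expect_equal(g@i0, 5, tolerance = 1e-6)
  R <- 30
  x <- q * R
  sph <- ScatteringCurve(q, (3 * (sin(x) - x * cos(x)) / x^3)^2)
  gs <- guinierFit(sph)
  expect_equal(gs@rg, sqrt(3 / 5) * R, tolerance = 0.01)
  errs <- vapply(1:50, function(sd) {
    set.seed(sd)
    noisy <- ScatteringCurve(q, pmax(5 * exp(-q^2 * 400 / 3) *
                                       (1 + stats::rnorm(length(q), 0, 0.02)),
                                     1e-12))
    abs(guinierFit(noisy)@rg - 20) / 20
  }, numeric(1))
  expect_lt(max(errs), 0.05)
  rising <- ScatteringCurve(q, exp(q^2 * 10))
  expect_error(guinierFit(rising), "no Guinier region")
})

test_that("P(r) from coordinates matches direct pairwise-distance facts", {
  two <- two_atom_structure(d = 10)
  pd <- prFromStructure(two, bin_width = 1)
  expect_equal(pd@dmax, 10)
  expect_equal(sum(pd@p > 0), 1)
  expect_equal(pd@r[which(pd@p > 0)], 9.5)  # bin centre holding 10 A
  s <- fix_two_domain()$s
  pd2 <- prFromStructure(s, bin_width = 0.5)
  expect_equal(pd2@dmax, max(stats::dist(coords(s))))
  expect_equal(pd2@p[1], 0)
  # second-moment Rg vs coordinate Rg with unit weights
  pd3 <- prFromStructure(s, bin_width = 0.25, form_factor = "unit")
  expect_equal(pd3@rg, radiusOfGyration(s), tolerance = 0.02)
})

test_that("indirect transform inverts synthetic curves from a known P(r)", {
  # forward model from a two-Gaussian P(r)
  r <- seq(0, 40, length.out = 200)
  p_true <- dnorm(r, 12, 3) + 0.5 * dnorm(r, 25, 4)
  p_true[1] <- 0
  q <- seq(0.01, 0.45, length.out = 120)
  A <- outer(q, r, function(qq, rr) ifelse(qq * rr < 1e-12, 1,
                                           sin(qq * rr) / (qq * rr)))
  I <- as.numeric(A %*% p_true) * (r[2] - r[1])
  cv <- ScatteringCurve(q, I, sigma = pmax(I, max(I) * 1e-3) * 0.01)
  pd <- prFromCurve(cv, dmax_guess = 50, n_r = 80)
  p_interp <- stats::approx(pd@r, pd@p, xout = r, rule = 2)$y
  expect_gt(stats::cor(p_interp, p_true), 0.99)
  # sphere: support bounded by the diameter
  R <- 15
  x <- pmax(q * R, 1e-9)
  sph <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  cs <- ScatteringCurve(q, sph, sigma = pmax(sph, 1e-6) * 0.01 + 1e-9)
  ps <- prFromCurve(cs, dmax_guess = 60, n_r = 80)
  beyond <- ps@r > 2 * R * 1.15
  expect_lt(max(ps@p[beyond]) , 0.05 * max(ps@p))
  # structure round trip within 5% on Rg
  s <- fix_two_domain()$s
  e <- synthSAXS(s, q_grid = seq(0.01, 0.35, length.out = 80),
                 mean_counts = 1e5, seed = 5)
  rt <- prFromCurve(e, dmax_guess = 40)
  expect_equal(rt@rg, prFromStructure(s)@rg, tolerance = 0.05)
})

test_that("SAXS text I/O round-trips curves including comments and commas", {
  f <- withr::local_tempfile(fileext = ".dat")
  cv <- ScatteringCurve(c(0.01, 0.02, 0.05), c(100, 80, 30), c(1, 0.9, 0.4))
  writeScatteringCurve(cv, f)
  back <- readScatteringCurve(f)
  expect_equal(back@q, cv@q)
  expect_equal(back@I, cv@I, tolerance = 1e-7)
  expect_equal(back@sigma, cv@sigma, tolerance = 1e-7)
  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# comment", "0.01, 5.0, 0.1", "0.02, 4.0, 0.1"), f2)
  expect_equal(readScatteringCurve(f2)@I, c(5, 4))
})
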