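#' Scattering curve constructor
#'
#' @param q scattering vector modulus, 1/Angstrom, strictly increasing.
#' @param I intensity.
#' @param sigma optional 1-sigma uncertainties.
#' @return A [ScatteringCurve-class].
#' @export
ScatteringCurve <- function(q, I, sigma = numeric(0)) {
  new("ScatteringCurve", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma))
}

#' @describeIn qValues q grid of a scattering curve.
#' @param x object.
#' @export
setMethod("qValues", "ScatteringCurve", function(x) x@q)

#' @describeIn intensities Intensities of a scattering curve.
#' @param x object.
#' @export
setMethod("intensities", "ScatteringCurve", function(x) x@I)

#' @describeIn uncertainties Per-point uncertainties (length 0 if absent).
#' @param x object.
#' @export
setMethod("uncertainties", "ScatteringCurve", function(x) x@sigma)

setMethod("show", "ScatteringCurve", function(object) {
  cat("ScatteringCurve:", length(object@q), "points, q in [",
      format(min(object@q), digits = 3), ",",
      format(max(object@q), digits = 3), "] 1/A",
      if (length(object@sigma)) "with uncertainties" else "(theoretical)",
      "\n")
})

#' Scattering vector modulus from scattering angle
#'
#' `q = 4 pi sin(theta) / lambda` with `2 theta` the scattering angle.
#'
#' @param two_theta scattering angle 2-theta, rad.
#' @param wavelength X-ray wavelength, Angstrom (1.548 A for a Cu anode).
#' @return q in 1/Angstrom.
#' @export
qFromAngle <- function(two_theta, wavelength = 1.548) {
  stopifnot(wavelength > 0)
  4 * pi * sin(two_theta / 2) / wavelength
}

#' @rdname qFromAngle
#' @param q scattering vector modulus, 1/Angstrom.
#' @export
angleFromQ <- function(q, wavelength = 1.548) {
  2 * asin(q * wavelength / (4 * pi))
}

# per-element f(0): electron counts (vacuum, q-independent default)
.f0_table <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

# 4-Gaussian (Cromer-Mann) coefficients a1..a4, b1..b4, c for common elements
.cromer_mann <- list(
  H = c(0.489918, 0.262003, 0.196767, 0.049879,
        20.6593, 7.74039, 49.5519, 2.20159, 0.001305),
  C = c(2.31000, 1.02000, 1.58860, 0.865000,
        20.8439, 10.2075, 0.568700, 51.6512, 0.215600),
  N = c(12.2126, 3.13220, 2.01250, 1.16630,
        0.005700, 9.89330, 28.9975, 0.582600, -11.529),
  O = c(3.04850, 2.28680, 1.54630, 0.867000,
        13.2771, 5.70110, 0.323900, 32.9089, 0.250800),
  P = c(6.43450, 4.17910, 1.78000, 1.49080,
        1.90670, 27.1570, 0.526000, 68.1645, 1.11490),
  S = c(6.90530, 5.20340, 1.43790, 1.58630,
        1.46790, 22.2151, 0.253600, 56.1720, 0.866900))

.form_factors <- function(elements, q, model = c("constant", "cromer-mann",
                                                 "unit")) {
  model <- match.arg(model)
  n <- length(elements)
  if (model == "unit") return(matrix(1, n, length(q)))
  if (model == "constant") {
    f0 <- .f0_table[elements]
    f0[is.na(f0)] <- 6
    return(matrix(f0, n, length(q)))
  }
  s2 <- (q / (4 * pi))^2  # (sin theta / lambda)^2
  f <- matrix(0, n, length(q))
  for (e in unique(elements)) {
    cm <- .cromer_mann[[e]]
    if (is.null(cm)) cm <- .cromer_mann[["C"]]
    fe <- cm[9] + cm[1] * exp(-cm[5] * s2) + cm[2] * exp(-cm[6] * s2) +
      cm[3] * exp(-cm[7] * s2) + cm[4] * exp(-cm[8] * s2)
    f[elements == e, ] <- matrix(fe, sum(elements == e), length(q),
                                 byrow = TRUE)
  }
  f
}

#' Theoretical scattering profile by the Debye formula
#'
#' `I(q) = sum_ij f_i(q) f_j(q) sin(q r_ij) / (q r_ij)`. Invariant under
#' rigid rotation/translation; `I(0) = (sum f_i(0))^2`.
#'
#' @param s [MolecularStructure-class] or N x 3 coordinate matrix.
#' @param q_grid q values, 1/Angstrom (default: the 0.013-0.26 range typical
#'   of a laboratory camera).
#' @param form_factor `"constant"` per-element electron counts (default),
#'   `"cromer-mann"` 4-Gaussian analytic form factors, or `"unit"`.
#' @return A theoretical [ScatteringCurve-class] (no sigma).
#' @export
debyeProfile <- function(s, q_grid = seq(0.013, 0.26, length.out = 40),
                         form_factor = "constant") {
  if (is(s, "MolecularStructure")) {
    el <- s@atoms$element
    xyz <- coords(s)
  } else {
    xyz <- s
    el <- rep("C", nrow(xyz))
  }
  if (nrow(xyz) < 1) stop("empty structure")
  f <- .form_factors(el, q_grid, form_factor)
  ScatteringCurve(q_grid, cpp_debye(xyz, f, q_grid))
}

#' Scale-optimized chi-square between experimental and theoretical curves
#'
#' Finds the multiplicative scale c (and optionally an additive background)
#' minimizing `sum[ (I_exp - c I_th - b)^2 / sigma^2 ]` in closed form, and
#' reports `chi2 = minimum / n_points`, so a fit within noise gives
#' chi2 ~ 1. The theoretical curve is cubic-spline interpolated onto the
#' experimental grid; extrapolation is refused.
#'
#' @param exp experimental [ScatteringCurve-class] (must carry sigma).
#' @param th theoretical [ScatteringCurve-class].
#' @param q_window optional (qmin, qmax) restriction, e.g. `c(0.1, Inf)` to
#'   fit the high-q region first and extrapolate the fit to low q.
#' @param offset also fit a constant background.
#' @param normalization divide the minimized sum by `"n"` (default) or
#'   `"n-1"`.
#' @return A [ChiSquareFit-class].
#' @export
chiSquare <- function(exp, th, q_window = NULL, offset = FALSE,
                      normalization = c("n", "n-1")) {
  normalization <- match.arg(normalization)
  if (length(exp@sigma) == 0) stop("experimental curve must carry sigma")
  if (any(exp@sigma == 0)) stop("zero sigma in experimental curve")
  keep <- rep(TRUE, length(exp@q))
  if (!is.null(q_window))
    keep <- exp@q >= q_window[1] & exp@q <= q_window[2]
  qe <- exp@q[keep]
  if (length(qe) < 2) stop("q window leaves fewer than 2 points")
  if (min(qe) < min(th@q) - 1e-9 || max(qe) > max(th@q) + 1e-9)
    stop("theoretical curve does not cover the experimental q range (",
         "no extrapolation)")
  It <- if (length(th@q) == length(qe) && all(abs(th@q - qe) < 1e-12))
    th@I else stats::spline(th@q, th@I, xout = qe)$y
  Ie <- exp@I[keep]
  w <- 1 / exp@sigma[keep]^2
  if (offset) {
    # linear least squares in (c, b)
    X <- cbind(It, 1)
    A <- t(X * w) %*% X
    rhs <- t(X * w) %*% Ie
    cb <- solve(A, rhs)
    cc <- cb[1]; bb <- cb[2]
  } else {
    cc <- sum(w * Ie * It) / sum(w * It^2)
    bb <- 0
  }
  res <- (Ie - cc * It - bb) * sqrt(w)
  nn <- length(qe)
  denom <- if (normalization == "n") nn else nn - 1
  new("ChiSquareFit", scale = as.numeric(cc), chi2 = sum(res^2) / denom,
      residuals = as.numeric(res), q = qe, nPoints = as.integer(nn),
      offset = as.numeric(bb))
}

setMethod("show", "ChiSquareFit", function(object) {
  cat(sprintf("ChiSquareFit: chi2 = %.4g (scale %.4g, %d points)\n",
              object@chi2, object@scale, object@nPoints))
})

#' Residual curve and randomness diagnostic of a chi-square fit
#'
#' Returns the per-q residuals `(I_exp - c I_th)/sigma` plus a mean and a
#' sign-runs statistic: for residuals randomly scattered around zero the
#' standardized runs statistic is approximately standard normal; large
#' negative values indicate systematic one-signed deviations.
#'
#' @param fit a [ChiSquareFit-class].
#' @return list with `q`, `residuals`, `mean`, `runs_z` (standardized runs
#'   statistic) and `systematic` (TRUE when |runs_z| > 3 or the mean is more
#'   than 3 standard errors from 0).
#' @export
residualCurve <- function(fit) {
  r <- fit@residuals
  n <- length(r)
  s <- sign(r)
  s[s == 0] <- 1
  runs <- 1 + sum(diff(s) != 0)
  np <- sum(s > 0); nm <- sum(s < 0)
  mu <- 1 + 2 * np * nm / n
  v <- if (n > 1) (mu - 1) * (mu - 2) / (n - 1) else 0
  z <- if (v > 0) (runs - mu) / sqrt(v) else 0
  m <- mean(r)
  list(q = fit@q, residuals = r, mean = m, runs_z = z,
       systematic = abs(z) > 3 || abs(m) > 3 / sqrt(n))
}

#' Inverse-variance weighted average of scattering curves
#'
#' `I = sum(I_i / s_i^2) / sum(1 / s_i^2)` per q with propagated uncertainty
#' `sigma = (sum s_i^-2)^(-1/2)`.
#'
#' @param curves list of [ScatteringCurve-class] on a common q grid, all
#'   with sigma.
#' @return The averaged [ScatteringCurve-class].
#' @export
averageCurves <- function(curves) {
  stopifnot(length(curves) >= 1)
  q <- curves[[1]]@q
  for (cv in curves) {
    if (length(cv@q) != length(q) || any(abs(cv@q - q) > 1e-9))
      stop("curves must share a common q grid")
    if (length(cv@sigma) == 0) stop("all curves must carry sigma")
  }
  W <- vapply(curves, function(cv) 1 / cv@sigma^2, numeric(length(q)))
  IW <- vapply(curves, function(cv) cv@I / cv@sigma^2, numeric(length(q)))
  if (length(q) == 1) { W <- matrix(W, 1); IW <- matrix(IW, 1) }
  sw <- rowSums(W)
  ScatteringCurve(q, rowSums(IW) / sw, 1 / sqrt(sw))
}

#' Guinier fit for the radius of gyration
#'
#' Linear fit of `ln I` vs `q^2` on the largest low-q window that (a)
#' satisfies `q_max * Rg <= qmax_rg_limit` (default 1.3, the globular
#' convention; reported, not enforced, for elongated particles) and (b)
#' shows no statistically significant curvature (a quadratic term in q^2
#' with |t| > 4 marks departure from Guinier linearity, so exact non-Gaussian
#' curves are fit only where the approximation truly holds). `Rg =
#' sqrt(-3 slope)`.
#'
#' @param curve a [ScatteringCurve-class].
#' @param qmax_rg_limit window limit on q*Rg.
#' @param min_points smallest window considered.
#' @return A [GuinierResult-class].
#' @export
guinierFit <- function(curve, qmax_rg_limit = 1.3, min_points = 5) {
  q <- curve@q; I <- curve@I
  pos <- I > 0
  q <- q[pos]; I <- I[pos]
  if (length(q) < min_points) stop("too few positive low-q points")
  best <- NULL
  for (m in seq(min_points, length(q))) {
    x <- q[1:m]^2
    y <- log(I[1:m])
    fitlm <- stats::lm.fit(cbind(1, x), y)
    slope <- fitlm$coefficients[2]
    # a noise-dominated window can have slope >= 0; keep extending
    if (!is.finite(slope) || slope >= 0) next
    rg <- sqrt(-3 * slope)
    if (q[m] * rg > qmax_rg_limit) {
      if (!is.null(best)) break else next
    }
    tq <- tryCatch(suppressWarnings(
      stats::summary.lm(stats::lm(y ~ x + I(x^2)))$coefficients[3, 3]),
      error = function(e) 0)
    if (!is.finite(tq)) tq <- 0
    ssr <- sum(fitlm$residuals^2)
    sst <- sum((y - mean(y))^2)
    cand <- list(m = m, rg = rg, i0 = exp(fitlm$coefficients[1]),
                 r2 = if (sst > 0) 1 - ssr / sst else 1)
    if (abs(tq) <= 4 || is.null(best)) best <- cand
  }
  if (is.null(best))
    stop("no Guinier region: low-q slope not negative within the limit")
  new("GuinierResult", rg = as.numeric(best$rg), i0 = as.numeric(best$i0),
      fitRange = c(q[1], q[best$m]),
      qmaxRg = as.numeric(q[best$m] * best$rg), r2 = as.numeric(best$r2),
      nPoints = as.integer(best$m))
}

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf("GuinierResult: Rg = %.2f A, I0 = %.4g, qmax*Rg = %.2f%s\n",
              object@rg, object@i0, object@qmaxRg,
              if (object@qmaxRg > 1.3) " (beyond globular limit)" else ""))
})

#' Pair-distance distribution from coordinates
#'
#' Histogram of all pairwise distances weighted by form-factor products;
#' `dmax` is the maximum pairwise distance and `rg` comes from the second
#' moment of P(r) (with the self-term correction so that unit weights
#' reproduce the coordinate-based Rg exactly up to binning).
#'
#' @param s [MolecularStructure-class] or coordinate matrix.
#' @param bin_width histogram bin width, Angstrom.
#' @param form_factor as in [debyeProfile()].
#' @return A [PairDistribution-class].
#' @export
prFromStructure <- function(s, bin_width = 1.0, form_factor = "constant") {
  if (is(s, "MolecularStructure")) {
    el <- s@atoms$element
    xyz <- coords(s)
  } else {
    xyz <- s
    el <- rep("C", nrow(xyz))
  }
  if (nrow(xyz) < 2) stop("need at least two atoms")
  f0 <- .form_factors(el, 0, form_factor)[, 1]
  dm <- max(stats::dist(xyz))
  nb <- max(1L, ceiling(dm / bin_width))
  h <- cpp_pair_histogram(xyz, f0, bin_width, nb)
  r <- (seq_len(nb) - 0.5) * bin_width
  # second moment with self-term (r = 0) weight included in the denominator
  rg <- sqrt(sum(h * r^2) / (2 * (sum(h) + sum(f0^2))))
  new("PairDistribution", r = c(0, r), p = c(0, h), dmax = dm, rg = rg)
}

setMethod("show", "PairDistribution", function(object) {
  cat(sprintf("PairDistribution: Dmax = %.1f A, Rg = %.2f A (%d bins)\n",
              object@dmax, object@rg, length(object@r)))
})

#' Indirect Fourier transform: P(r) from a scattering curve
#'
#' Smoothness-regularized least squares on a linear-interpolation P(r)
#' basis with P(0) = P(dmax) = 0 and P >= 0 (box-constrained BFGS). The
#' regularization weight is chosen by a deterministic L-curve criterion.
#' Dmax is refined as the end of the support of the recovered P(r).
#'
#' @param curve experimental [ScatteringCurve-class] with sigma.
#' @param dmax_guess upper bound for the particle dimension, Angstrom.
#' @param n_r number of P(r) grid points.
#' @param alphas candidate regularization weights (log-spaced scan).
#' @return A [PairDistribution-class].
#' @export
prFromCurve <- function(curve, dmax_guess, n_r = 60,
                        alphas = 10^seq(-6, 4, length.out = 21)) {
  stopifnot(dmax_guess > 0)
  q <- curve@q; I <- curve@I
  sg <- if (length(curve@sigma)) curve@sigma else
    rep(stats::sd(I) * 0.01 + 1e-12, length(I))
  if (length(q) < 10) stop("too few points for an indirect transform")
  r <- seq(0, dmax_guess, length.out = n_r)
  dr <- r[2] - r[1]
  # forward design matrix: I(q) = sum_j p_j sinc(q r_j) dr  (free j: 2..n-1)
  Sinc <- outer(q, r, function(qq, rr) {
    x <- qq * rr
    ifelse(abs(x) < 1e-9, 1, sin(x) / x)
  })
  A <- Sinc[, 2:(n_r - 1), drop = FALSE] * dr / sg
  b <- I / sg
  m <- ncol(A)
  D2 <- diff(diag(m), differences = 2)  # curvature penalty
  AtA <- crossprod(A); Atb <- crossprod(A, b); DtD <- crossprod(D2)
  fn_of <- function(alpha) function(p) {
    rv <- A %*% p - b
    sum(rv^2) + alpha * sum((D2 %*% p)^2)
  }
  gr_of <- function(alpha) function(p)
    2 * (AtA %*% p - Atb + alpha * (DtD %*% p))
  # continuation: solve from the largest alpha down, warm-starting each
  # fit from the previous solution (first start: well-conditioned ridge)
  ord <- order(alphas, decreasing = TRUE)
  a_max <- alphas[ord[1]]
  p_prev <- tryCatch(
    pmax(as.numeric(solve(AtA + a_max * DtD + 1e-8 * max(diag(AtA)) *
                            diag(m), Atb)), 0),
    error = function(e) rep(mean(abs(b)) / max(1, mean(A)), m))
  resnorm <- pennorm <- numeric(length(alphas))
  sols <- vector("list", length(alphas))
  for (i in ord) {
    p <- stats::optim(p_prev, fn_of(alphas[i]), gr_of(alphas[i]),
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = 1000, factr = 1e4))$par
    p_prev <- p
    sols[[i]] <- p
    resnorm[i] <- sqrt(sum((A %*% p - b)^2))
    pennorm[i] <- sqrt(sum((D2 %*% p)^2))
  }
  # L-curve corner: maximum curvature of (log resnorm, log pennorm)
  lx <- log(pmax(resnorm, 1e-300)); ly <- log(pmax(pennorm, 1e-300))
  k <- rep(-Inf, length(alphas))
  for (i in 2:(length(alphas) - 1)) {
    d1x <- (lx[i + 1] - lx[i - 1]) / 2; d1y <- (ly[i + 1] - ly[i - 1]) / 2
    d2x <- lx[i + 1] - 2 * lx[i] + lx[i - 1]
    d2y <- ly[i + 1] - 2 * ly[i] + ly[i - 1]
    den <- (d1x^2 + d1y^2)^1.5
    if (den > 0) k[i] <- (d1x * d2y - d1y * d2x) / den
  }
  pick <- which.max(k)
  p <- c(0, sols[[pick]], 0)
  # refined dmax: end of support (last r where P exceeds 0.5% of its peak)
  thr <- 0.005 * max(p)
  last <- max(which(p > thr), 2)
  dmax <- r[min(last + 1, n_r)]
  rg <- sqrt(sum(p * r^2) / (2 * sum(p)))
  new("PairDistribution", r = r, p = pmax(p, 0), dmax = dmax, rg = rg)
}

#' Read a 3-column SAXS curve (q, I, sigma)
#'
#' Whitespace- or comma-separated text with `#` comments (ATSAS-style .dat
#' accepted); a third column, when present, is taken as sigma.
#'
#' @param path input file.
#' @return A [ScatteringCurve-class].
#' @export
readScatteringCurve <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  ln <- gsub(",", " ", ln)
  parts <- strsplit(trimws(ln), "\\s+")
  parts <- parts[vapply(parts, function(p)
    length(p) >= 2 && !anyNA(suppressWarnings(as.numeric(p[1:2]))),
    logical(1))]
  if (length(parts) == 0) stop("no numeric data rows in ", path)
  m <- t(vapply(parts, function(p)
    suppressWarnings(as.numeric(p[1:3])), numeric(3)))
  sg <- m[, 3]
  if (anyNA(sg)) sg <- numeric(0)
  ScatteringCurve(m[, 1], m[, 2], sg)
}

#' Write a scattering curve as 3-column text
#'
#' @param curve a [ScatteringCurve-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScatteringCurve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q(1/A) I sigma", con)
  sg <- if (length(curve@sigma)) curve@sigma else rep(NA_real_,
                                                      length(curve@q))
  writeLines(sprintf("%.8g %.8g %s", curve@q, curve@I,
                     ifelse(is.na(sg), "", sprintf("%.8g", sg))), con)
  invisible(path)
}
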