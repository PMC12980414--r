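#' Fit an inversion-recovery decay for R1
#'
#' Nonlinear least squares of `I(t) = I0 (1 - 2 exp(-R1 t))` (so the model
#' value at t = 0 is -I0). Initialization is derivative-free: I0 from the
#' long-time plateau and R1 from a log-linear prefit of `(I0 - I)/ (2 I0)`.
#' Standard errors use the signal-to-noise-based intensity noise
#' `sigma_I = I0 / snr` (SNR referenced to the peak intensity) and the
#' known-sigma covariance `sigma^2 (J'J)^-1`.
#'
#' @param t time, s.
#' @param I intensities (any units).
#' @param snr signal-to-noise ratio of the spectra (defines sigma_I); when
#'   `NULL` sigma_I is estimated from the fit residuals.
#' @return A [RelaxationResult-class].
#' @export
fitInversionRecovery <- function(t, I, snr = NULL) {
  .check_series(t, I)
  i0_start <- max(abs(I))
  y <- (i0_start - I) / (2 * i0_start)
  ok <- y > 1e-12
  r_start <- if (sum(ok) >= 2)
    max(1e-6, -unname(stats::lm.fit(cbind(1, t[ok]),
                                    log(y[ok]))$coefficients)[2])
  else 1 / max(t[t > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ i0 * (1 - 2 * exp(-r * t)),
                      start = list(i0 = i0_start, r = r_start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("inversion-recovery fit failed (start: I0 = ",
           signif(i0_start, 4), ", R1 = ", signif(r_start, 4), "): ",
           conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- .exp_fit_stderr(t, I, cf["i0"], cf["r"], model = "ir", snr = snr)
  new("RelaxationResult", i0 = unname(cf["i0"]), rate = unname(cf["r"]),
      stderrRate = se$rate, stderrI0 = se$i0, model = "inversion_recovery",
      sigmaI = se$sigma)
}

#' Fit a CPMG mono-exponential decay for R2
#'
#' Nonlinear least squares of `I(t) = I0 exp(-R2 t)`; the intensity halves
#' every `ln 2 / R2` seconds. Same initialization and SNR-based error
#' conventions as [fitInversionRecovery()].
#'
#' @inheritParams fitInversionRecovery
#' @return A [RelaxationResult-class].
#' @export
fitCpmgDecay <- function(t, I, snr = NULL) {
  .check_series(t, I)
  ok <- I > 0
  if (sum(ok) < 2) stop("need positive intensities for the log-linear start")
  pre <- unname(stats::lm.fit(cbind(1, t[ok]), log(I[ok]))$coefficients)
  i0_start <- exp(pre[1])
  r_start <- max(1e-6, -pre[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ i0 * exp(-r * t),
                      start = list(i0 = i0_start, r = r_start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("CPMG decay fit failed (start: I0 = ", signif(i0_start, 4),
           ", R2 = ", signif(r_start, 4), "): ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- .exp_fit_stderr(t, I, cf["i0"], cf["r"], model = "cpmg", snr = snr)
  new("RelaxationResult", i0 = unname(cf["i0"]), rate = unname(cf["r"]),
      stderrRate = se$rate, stderrI0 = se$i0, model = "cpmg_decay",
      sigmaI = se$sigma)
}

.check_series <- function(t, I) {
  stopifnot(length(t) == length(I))
  if (length(t) < 4) stop("need at least 4 points to fit a decay")
  if (any(t < 0) || any(diff(t) <= 0))
    stop("times must be >= 0 and strictly increasing")
}

.exp_fit_stderr <- function(t, I, i0, r, model, snr) {
  if (model == "ir") {
    fitted <- i0 * (1 - 2 * exp(-r * t))
    J <- cbind(1 - 2 * exp(-r * t), 2 * i0 * t * exp(-r * t))
  } else {
    fitted <- i0 * exp(-r * t)
    J <- cbind(exp(-r * t), -i0 * t * exp(-r * t))
  }
  # SNR referenced to the peak (initial) intensity I0
  sigma <- if (!is.null(snr)) abs(i0) / snr else {
    sqrt(sum((I - fitted)^2) / max(1, length(I) - 2))
  }
  cv <- tryCatch(solve(crossprod(J)) * sigma^2, error = function(e)
    matrix(NA_real_, 2, 2))
  list(i0 = sqrt(cv[1, 1]), rate = sqrt(cv[2, 2]), sigma = sigma)
}

setMethod("show", "RelaxationResult", function(object) {
  cat(sprintf("RelaxationResult (%s): rate = %.4g +/- %.2g 1/s, I0 = %.4g\n",
              object@model, object@rate, object@stderrRate, object@i0))
})

#' Area-normalized Voigt profile
#'
#' Convolution of a Gaussian (standard deviation `sigma`) and a Lorentzian
#' (half-width `gamma`), evaluated through the real Faddeeva function.
#' Integrates to 1 over the real line.
#'
#' @param x evaluation points (e.g. wavenumber, 1/cm).
#' @param center band center.
#' @param sigma Gaussian standard deviation (> 0).
#' @param gamma Lorentzian half-width at half-maximum (>= 0).
#' @return Profile values.
#' @export
voigtProfile <- function(x, center, sigma, gamma) {
  stopifnot(sigma > 0, gamma >= 0)
  cpp_voigt(as.numeric(x), center, sigma, gamma)
}

.amideI_assignments <- data.frame(
  center = c(1682, 1670, 1649, 1637, 1622),
  assignment = c("beta_turn", "alpha_helix", "disordered", "beta_sheet",
                 "beta_sheet"),
  stringsAsFactors = FALSE)

.assign_center <- function(center, tolerance = 8) {
  d <- abs(.amideI_assignments$center - center)
  i <- which.min(d)
  if (d[i] > tolerance)
    stop("component center ", round(center, 1), " 1/cm falls outside all ",
         "assignment windows (+/-", tolerance, " of ",
         paste(.amideI_assignments$center, collapse = ", "), ")")
  .amideI_assignments$assignment[i]
}

#' Fourier self-deconvolution preprocessing (optional)
#'
#' Lorentzian line-narrowing filter applied in the Fourier domain:
#' multiplies the interferogram by `exp(2 pi w |x|)` (inverse of a
#' Lorentzian of half-width `w`) and a Bessel apodization window, narrowing
#' overlapped bands before deconvolution. Off by default in
#' [deconvolveAmideI()].
#'
#' @param wavenumber equally spaced grid, 1/cm.
#' @param absorbance spectrum values.
#' @param halfwidth assumed Lorentzian half-width w, 1/cm.
#' @param narrowing band-narrowing factor K (apodization cutoff).
#' @return Filtered absorbance values.
#' @export
fsdFilter <- function(wavenumber, absorbance, halfwidth = 8, narrowing = 2) {
  n <- length(absorbance)
  dv <- mean(diff(wavenumber))
  ft <- stats::fft(absorbance)
  x <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * dv)
  lmax <- narrowing / (2 * pi * halfwidth)
  w <- exp(2 * pi * halfwidth * pmin(abs(x), lmax))
  apod <- (1 - pmin(abs(x) / lmax, 1)^2)^2
  Re(stats::fft(ft * w * apod, inverse = TRUE)) / n
}

#' Deconvolve the amide-I band into Voigt components
#'
#' Nonlinear least-squares fit of a sum of area-parameterized Voigt bands to
#' the amide-I region (1,600-1,700 1/cm). Component centers are bounded to
#' `init_centers +/- center_tolerance` (default 8 1/cm, the assignment
#' window width). Standard errors come from the parameter covariance matrix
#' `sigma_hat^2 (J'J)^-1`; areas equal the amplitude parameters exactly
#' because the profile is area-normalized.
#'
#' @param wavenumber grid, 1/cm (restricted internally to 1,600-1,700).
#' @param absorbance spectrum values.
#' @param init_centers starting band centers, 1/cm.
#' @param center_tolerance allowed center shift, 1/cm.
#' @param fsd apply [fsdFilter()] preprocessing first (default off).
#' @return A [VoigtDeconvolution-class] with per-band assignment from the
#'   amide-I map (1,682 beta-turn; 1,670 alpha-helix; 1,649 disordered;
#'   1,637 and 1,622 beta-sheet).
#' @export
deconvolveAmideI <- function(wavenumber, absorbance,
                             init_centers = c(1682, 1670, 1649, 1637, 1622),
                             center_tolerance = 8, fsd = FALSE) {
  keep <- wavenumber >= 1600 & wavenumber <= 1700
  wn <- wavenumber[keep]; ab <- absorbance[keep]
  if (length(wn) < 3 * length(init_centers) + 2)
    stop("too few spectral points for ", length(init_centers), " components")
  if (fsd) ab <- fsdFilter(wn, ab)
  nc <- length(init_centers)
  # linear least-squares amplitude start: areas are linear in the profile
  # once centers and widths are fixed, which lands the nonlinear fit in the
  # right basin for strongly overlapped bands
  B0 <- vapply(init_centers, function(cc) cpp_voigt(wn, cc, 6, 2),
               numeric(length(wn)))
  a0 <- tryCatch(pmax(qr.solve(B0, ab), max(ab) * 1e-3),
                 error = function(e) rep(max(ab) * 10 / nc, nc))
  # parameters per band: center, log sigma, log gamma, log area
  p0 <- c(init_centers, rep(log(6), nc), rep(log(2), nc), log(a0))
  lower <- c(init_centers - center_tolerance, rep(log(0.5), nc),
             rep(log(0.05), nc), rep(-30, nc))
  upper <- c(init_centers + center_tolerance, rep(log(25), nc),
             rep(log(25), nc), rep(30, nc))
  model <- function(p) {
    y <- 0
    for (b in seq_len(nc))
      y <- y + exp(p[3 * nc + b]) *
        cpp_voigt(wn, p[b], exp(p[nc + b]), exp(p[2 * nc + b]))
    y
  }
  res_fn <- function(p) ab - model(p)
  fit <- minpack.lm::nls.lm(p0, lower, upper, res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 400))
  p <- fit$par
  J <- .num_jacobian(model, p)
  dof <- length(wn) - length(p)
  sig2 <- sum(fit$fvec^2) / max(1, dof)
  JtJ <- crossprod(J)
  cv <- tryCatch(solve(JtJ) * sig2, error = function(e) NULL)
  if (is.null(cv)) {
    ev <- eigen(JtJ, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev))
      stop("component set not resolvable (singular covariance); ",
           "try fewer components")
    cv <- MASS::ginv(JtJ) * sig2
  }
  areas <- exp(p[3 * nc + seq_len(nc)])
  # delta method: sd(area) = area * sd(log area)
  area_se <- areas * sqrt(pmax(0, diag(cv)[3 * nc + seq_len(nc)]))
  comp <- data.frame(
    center = p[seq_len(nc)],
    gaussianWidth = exp(p[nc + seq_len(nc)]),
    lorentzianWidth = exp(p[2 * nc + seq_len(nc)]),
    amplitude = areas, area = areas, areaStderr = area_se,
    assignment = vapply(p[seq_len(nc)], .assign_center, character(1),
                        tolerance = center_tolerance + 1e-9),
    stringsAsFactors = FALSE)
  new("VoigtDeconvolution", components = comp, fitted = model(p),
      wavenumber = wn, sigmaNoise = sqrt(sig2), covariance = cv)
}

.num_jacobian <- function(f, p, h = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (k in seq_along(p)) {
    ph <- p; ph[k] <- ph[k] + h
    pm <- p; pm[k] <- pm[k] - h
    J[, k] <- (f(ph) - f(pm)) / (2 * h)
  }
  J
}

setMethod("show", "VoigtDeconvolution", function(object) {
  cat("VoigtDeconvolution:", nrow(object@components), "bands\n")
  print(object@components[, c("center", "area", "assignment")])
})

#' Secondary-structure fractions from deconvolved band areas
#'
#' The percentage of each class is the area of its bands relative to the
#' total area; the two beta-sheet bands are pooled. Percentages sum to 100
#' and the result is invariant to component order.
#'
#' @param x a [VoigtDeconvolution-class] or its `components` data.frame
#'   (columns `center`, `area`, optionally `assignment`).
#' @param center_tolerance assignment window when centers must be mapped.
#' @return A [SecondaryStructureReport-class].
#' @export
structureFractions <- function(x, center_tolerance = 8) {
  comp <- if (is(x, "VoigtDeconvolution")) x@components else
    as.data.frame(x)
  if (is.null(comp$assignment))
    comp$assignment <- vapply(comp$center, .assign_center, character(1),
                              tolerance = center_tolerance)
  tot <- sum(comp$area)
  cls <- c("beta_turn", "alpha_helix", "disordered", "beta_sheet")
  fr <- vapply(cls, function(cl)
    100 * sum(comp$area[comp$assignment == cl]) / tot, numeric(1))
  new("SecondaryStructureReport", fractions = fr, byComponent = comp)
}

setMethod("show", "SecondaryStructureReport", function(object) {
  cat("Secondary-structure fractions (%):\n")
  print(round(object@fractions, 1))
})

#' DLS second-order cumulant fit
#'
#' Weighted nonlinear least squares of
#' `g2(tau) = B + beta exp(-2 Gamma tau) (1 + (mu2/2) tau^2)^2`, each point
#' weighted by its experimental variance under the Poisson photon-count
#' noise model (Gaussian under acquisition averaging). The polydispersity
#' index is `mu2 / Gamma^2`; uncertainties are propagated from the
#' parameter covariance.
#'
#' @param tau delay times, s, strictly increasing.
#' @param g2 intensity autocorrelation values.
#' @param sigma per-point standard deviations; `NULL` derives them from the
#'   Poisson count model with `counts` mean photon counts.
#' @param counts mean photon counts per correlation point for the Poisson
#'   noise model (used when `sigma` is NULL).
#' @return A [CumulantResult-class] (diameter slots NA until
#'   [hydrodynamicDiameter()] is applied).
#' @export
fitCumulants <- function(tau, g2, sigma = NULL, counts = 1e6) {
  stopifnot(length(tau) == length(g2), all(tau > 0), all(diff(tau) > 0))
  if (g2[1] <= g2[length(g2)] + 1e-12 ||
      stats::cor(tau, g2) > 0)
    stop("autocorrelation does not decay; cannot fit cumulants")
  if (is.null(sigma)) sigma <- sqrt(pmax(g2, 1e-12) / counts)
  if (!any(is.finite(sigma) & sigma > 0)) sigma <- rep(1, length(g2))
  sigma[!is.finite(sigma) | sigma <= 0] <- min(sigma[is.finite(sigma) &
                                                     sigma > 0])
  B0 <- min(g2)
  beta0 <- max(g2) - B0
  yy <- (g2 - B0) / beta0
  ok <- yy > 1e-6
  g0 <- max(1e-3, -0.5 * stats::lm.fit(cbind(1, tau[ok]),
                                       log(yy[ok]))$coefficients[2])
  model <- function(p) {
    # p = (B, beta, log Gamma, mu2n) with mu2 = mu2n * Gamma^2
    G <- exp(p[3])
    p[1] + p[2] * exp(-2 * G * tau) * (1 + 0.5 * p[4] * G^2 * tau^2)^2
  }
  res_fn <- function(p) (g2 - model(p)) / sigma
  fit <- minpack.lm::nls.lm(c(B0, beta0, log(g0), 0),
                            lower = c(-Inf, 1e-12, -30, -0.5),
                            upper = c(Inf, Inf, 30, 5),
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 400))
  p <- fit$par
  G <- exp(p[3]); mu2 <- p[4] * G^2
  J <- .num_jacobian(model, p) / sigma
  cv <- tryCatch(solve(crossprod(J)), error = function(e)
    MASS::ginv(crossprod(J)))
  seG <- G * sqrt(pmax(0, cv[3, 3]))  # delta method on log Gamma
  sePdi <- sqrt(pmax(0, cv[4, 4]))    # pdi = mu2/Gamma^2 is p[4] itself
  new("CumulantResult", gamma = G, mu2 = mu2, pdi = max(0, p[4]),
      baseline = p[1], intercept = p[2], stderrGamma = seG,
      stderrPdi = sePdi)
}

setMethod("show", "CumulantResult", function(object) {
  cat(sprintf(
    "CumulantResult: Gamma = %.4g 1/s, PDI = %.3g, baseline = %.4g%s\n",
    object@gamma, object@pdi, object@baseline,
    if (!is.na(object@dh)) sprintf(", Dh = %.1f A", object@dh) else ""))
})

#' Hydrodynamic diameter from a DLS decay rate
#'
#' `q = 4 pi n sin(angle/2) / lambda`, `D = Gamma / q^2`, and the
#' Stokes-Einstein relation `Dh = 2 kB T / (6 pi eta D)`, returned in
#' Angstrom. Defaults follow a 90-degree, 633 nm instrument at 293 K in
#' water.
#'
#' @param x a [CumulantResult-class] (filled in and returned) or a decay
#'   rate Gamma in 1/s.
#' @param wavelength laser wavelength, Angstrom (6330 A = 633 nm).
#' @param angle scattering angle, rad.
#' @param refractive_index solvent refractive index.
#' @param temperature K.
#' @param viscosity Pa s.
#' @return Updated [CumulantResult-class], or the diameter in Angstrom when
#'   `x` is numeric.
#' @export
hydrodynamicDiameter <- function(x, wavelength = 6330, angle = pi / 2,
                                 refractive_index = 1.33,
                                 temperature = 293, viscosity = 1.002e-3) {
  stopifnot(wavelength > 0, refractive_index > 0, temperature > 0,
            viscosity > 0)
  gam <- if (is(x, "CumulantResult")) x@gamma else as.numeric(x)
  q <- 4 * pi * refractive_index * sin(angle / 2) / (wavelength * 1e-10) # 1/m
  D <- gam / q^2                                                # m^2/s
  kB <- 1.380649e-23
  rh <- kB * temperature / (6 * pi * viscosity * D)              # m
  dh <- 2 * rh * 1e10                                            # Angstrom
  if (is(x, "CumulantResult")) {
    x@dh <- dh
    # Dh is inversely proportional to Gamma
    x@stderrDh <- if (is.finite(x@stderrGamma)) dh * x@stderrGamma / gam
                  else NA_real_
    validObject(x)
    return(x)
  }
  dh
}

#' Read a two-column delimited series (t, I) or (wavenumber, absorbance)
#'
#' Accepts comma-, tab- or whitespace-separated text with `#` comments and
#' an optional header line.
#'
#' @param path input file.
#' @return data.frame with columns `x` and `y`.
#' @export
readSeries <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  ln <- gsub("[,\t]", " ", ln)
  parts <- strsplit(trimws(ln), "\\s+")
  num <- vapply(parts, function(p)
    length(p) >= 2 && !anyNA(suppressWarnings(as.numeric(p[1:2]))),
    logical(1))
  m <- t(vapply(parts[num], function(p)
    suppressWarnings(as.numeric(p[1:2])), numeric(2)))
  if (nrow(m) == 0) stop("no numeric rows in ", path)
  data.frame(x = m[, 1], y = m[, 2])
}
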