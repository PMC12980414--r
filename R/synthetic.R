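## Seeded generators for every input the pipeline consumes, each a pure
## function of (parameters, seed), with planted ground truth for recovery
## tests. Toy residues carry 3 pseudo-atoms (N, CA backbone; CB sidechain)
## so every bonded term type is exercised without full residue templates.

.toy_bond <- list(n_ca = 1.46, ca_cb = 1.53, ca_n = 1.47)

# self-avoiding compact globule of CA positions: random walk inside a
# confinement sphere with a minimum-distance acceptance threshold against
# all non-consecutive residues. CA spacing 2.93 A so the bridging N
# pseudo-atom sits a bond length (~1.47 A) from both flanking CAs; the
# 4.5 A clearance leaves room for the N/CB substituents of a 3-atom
# residue without inter-segment clashes.
.globule_walk <- function(n, step = 2.93, min_dist = 4.5,
                          center = c(0, 0, 0),
                          avoid = matrix(0, 0, 3)) {
  conf_r <- step * max(2, n^(1 / 3)) * 1.2
  pos <- matrix(0, n, 3)
  pos[1, ] <- center
  for (i in seq(2, length.out = n - 1)) {
    placed <- FALSE
    for (try in 1:500) {
      u <- stats::rnorm(3)
      cand <- pos[i - 1, ] + step * u / sqrt(sum(u^2))
      if (sqrt(sum((cand - center)^2)) > conf_r) next
      prev <- rbind(pos[seq_len(max(0, i - 2)), , drop = FALSE], avoid)
      if (nrow(prev) == 0) { placed <- TRUE; break }
      d2 <- rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2)
      if (min(d2) >= min_dist^2) { placed <- TRUE; break }
    }
    if (!placed) stop("globule generator failed to place residue ", i)
    pos[i, ] <- cand
  }
  pos
}

.unit <- function(v) v / sqrt(sum(v^2))

.perp_basis <- function(dirv) {
  ref <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- .unit(ref - sum(ref * dirv) * dirv)
  b2 <- c(dirv[2] * b1[3] - dirv[3] * b1[2],
          dirv[3] * b1[1] - dirv[1] * b1[3],
          dirv[1] * b1[2] - dirv[2] * b1[1])
  list(b1 = b1, b2 = b2)
}

.angle3 <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

# expand the CA trace into N/CA/CB pseudo-atoms. Substituent positions
# are chosen from a ring of candidate directions around the local chain
# axis, scored by clearance from all non-bonded atoms and by the margin of
# every bond angle from the 0/pi singularities of the harmonic angle
# gradient; a greedy pass is followed by coordinate-descent repair sweeps.
# Deterministic given the CA trace.
.decorate_residues <- function(ca, resid_start = 1, chain = "A") {
  n <- nrow(ca)
  phis <- seq(0, 2 * pi, length.out = 25)[-25]
  npos <- cbpos <- matrix(NA_real_, n, 3)
  ang_lo <- 0.6; ang_hi <- 2.6
  dirs <- t(vapply(seq_len(n), function(i)
    if (i > 1) .unit(ca[i, ] - ca[i - 1, ]) else c(1, 0, 0), numeric(3)))
  score_cand <- function(cand, angles, others) {
    clear <- if (nrow(others) == 0) 5 else
      min(sqrt(rowSums((others - matrix(cand, nrow(others), 3,
                                        byrow = TRUE))^2)))
    margin <- if (length(angles) == 0) 0.45 else
      min(c(angles - ang_lo, ang_hi - angles))
    # clearance saturates at 2 A (bond rule 1.8 plus margin); angle
    # violations are penalized so they occur only when nothing is feasible
    min(clear, 2) + min(margin, 0.45) + 10 * min(margin, 0)
  }
  others_for <- function(i, kind) {
    keep <- rbind(ca[-c(i, if (kind == "n" && i > 1) i - 1), , drop = FALSE],
                  npos[if (kind == "n") -i else TRUE, , drop = FALSE],
                  cbpos[if (kind == "cb") -i else TRUE, , drop = FALSE])
    keep[stats::complete.cases(keep), , drop = FALSE]
  }
  place_n <- function(i) {
    pb <- .perp_basis(dirs[i, ])
    others <- others_for(i, "n")
    best <- NULL
    for (phi in phis) {
      noff <- cos(phi) * pb$b1 + sin(phi) * pb$b2
      cand <- ca[i, ] - dirs[i, ] * 1.45 + noff * 0.9
      angs <- numeric(0)
      if (i > 1) {
        angs <- c(angs, .angle3(ca[i - 1, ], cand, ca[i, ]),
                  .angle3(npos[i - 1, ], ca[i - 1, ], cand),
                  .angle3(cbpos[i - 1, ], ca[i - 1, ], cand))
        angs <- angs[!is.na(angs)]
      }
      if (!anyNA(cbpos[i, ]))
        angs <- c(angs, .angle3(cand, ca[i, ], cbpos[i, ]))
      sc <- score_cand(cand, angs, others)
      if (is.null(best) || sc > best$sc) best <- list(p = cand, sc = sc)
    }
    best$p
  }
  place_cb <- function(i) {
    pb <- .perp_basis(dirs[i, ])
    others <- others_for(i, "cb")
    best <- NULL
    for (phi in phis) {
      soff <- cos(phi) * pb$b1 + sin(phi) * pb$b2
      cand <- ca[i, ] + soff * .toy_bond$ca_cb
      angs <- .angle3(npos[i, ], ca[i, ], cand)
      if (i < n && !anyNA(npos[i + 1, ]))
        angs <- c(angs, .angle3(cand, ca[i, ], npos[i + 1, ]))
      sc <- score_cand(cand, angs, others)
      if (is.null(best) || sc > best$sc) best <- list(p = cand, sc = sc)
    }
    best$p
  }
  for (i in seq_len(n)) {
    npos[i, ] <- place_n(i)
    cbpos[i, ] <- place_cb(i)
  }
  for (sweep in 1:3) {
    for (i in seq_len(n)) {
      npos[i, ] <- place_n(i)
      cbpos[i, ] <- place_cb(i)
    }
  }
  atoms <- lapply(seq_len(n), function(i) data.frame(
    name = c("N", "CA", "CB"), element = c("N", "C", "C"),
    resid = resid_start + i - 1, resname = "GLY", chain = chain,
    x = c(npos[i, 1], ca[i, 1], cbpos[i, 1]),
    y = c(npos[i, 2], ca[i, 2], cbpos[i, 2]),
    z = c(npos[i, 3], ca[i, 3], cbpos[i, 3]), stringsAsFactors = FALSE))
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  a
}

# geometric sanity of a decorated toy chain: the 1.8 A distance rule must
# recover exactly the intended template bonds (so no spurious bonds and no
# unmodeled angle terms), and every template bond angle must stay clear of
# the 0/pi gradient singularities
.toy_geometry_ok <- function(a, ang_lo = 0.5, ang_hi = 2.75) {
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n_res <- nrow(a) / 3
  at_i <- function(i, name) (i - 1) * 3 + match(name, c("N", "CA", "CB"))
  at <- function(i, name) xyz[at_i(i, name), ]
  bonds <- NULL
  for (i in seq_len(n_res)) {
    bonds <- rbind(bonds, c(at_i(i, "N"), at_i(i, "CA")),
                   c(at_i(i, "CA"), at_i(i, "CB")))
    if (i < n_res) bonds <- rbind(bonds, c(at_i(i, "CA"), at_i(i + 1, "N")))
  }
  blen <- sqrt(rowSums((xyz[bonds[, 1], ] - xyz[bonds[, 2], ])^2))
  if (any(blen > 1.78)) return(FALSE)
  D <- as.matrix(stats::dist(xyz))
  D[cbind(bonds[, 1], bonds[, 2])] <- Inf
  D[cbind(bonds[, 2], bonds[, 1])] <- Inf
  diag(D) <- Inf
  if (min(D) < 1.85) return(FALSE)  # anything else under the bond rule
  angs <- c()
  for (i in seq_len(n_res)) {
    angs <- c(angs, .angle3(at(i, "N"), at(i, "CA"), at(i, "CB")))
    if (i < n_res) {
      angs <- c(angs, .angle3(at(i, "CA"), at(i + 1, "N"), at(i + 1, "CA")),
                .angle3(at(i, "N"), at(i, "CA"), at(i + 1, "N")),
                .angle3(at(i, "CB"), at(i, "CA"), at(i + 1, "N")))
    }
  }
  all(angs >= ang_lo & angs <= ang_hi)
}

#' Generate a toy single-globule chain
#'
#' @param n_res residues (3 pseudo-atoms each).
#' @param seed RNG seed.
#' @return A [MolecularStructure-class].
#' @export
makeToyChain <- function(n_res = 10, seed = 1) {
  set.seed(seed)
  for (try in 1:50) {
    a <- tryCatch({
      ca <- .globule_walk(n_res)
      .decorate_residues(ca)
    }, error = function(e) NULL)
    if (!is.null(a) && .toy_geometry_ok(a))
      return(MolecularStructure(a, title = "toy chain"))
  }
  stop("could not generate a clash-free toy chain; try another seed")
}

#' Generate a two-domain toy monomer with a flexible linker
#'
#' Two compact self-avoiding globules joined by an extended linker: the
#' synthetic analogue of a multidomain protein with a rigid core and a
#' flexible domain. Also returns the domain map and linker residues the
#' topology builder needs.
#'
#' @param n_res_per_domain residues per globular domain (>= 3).
#' @param linker_len linker residues (>= 1).
#' @param seed RNG seed.
#' @return list with `structure` ([MolecularStructure-class]),
#'   `domain_map` (list of residue vectors) and `linker_residues`.
#' @export
makeTwoDomain <- function(n_res_per_domain = 10, linker_len = 5, seed = 1) {
  stopifnot(n_res_per_domain >= 3, linker_len >= 1)
  set.seed(seed)
  n1 <- n_res_per_domain
  s <- NULL
  for (try in 1:50) {
    a <- tryCatch({
      g1 <- .globule_walk(n1)
      # extended linker leaves the first domain along +x
      exit <- g1[n1, ]
      step <- 2.9
      linker <- t(vapply(seq_len(linker_len), function(i)
        exit + c(step * i, 0.3 * sin(i), 0.3 * cos(i)), numeric(3)))
      start2 <- linker[linker_len, ] + c(step, 0, 0)
      g2 <- .globule_walk(n_res_per_domain, center = start2,
                          avoid = rbind(g1, linker))
      ca <- rbind(g1, linker, g2)
      .decorate_residues(ca)
    }, error = function(e) NULL)
    if (!is.null(a) && .toy_geometry_ok(a)) {
      s <- MolecularStructure(a, title = "two-domain toy")
      break
    }
  }
  if (is.null(s))
    stop("could not generate a clash-free two-domain toy; try another seed")
  nres <- nrow(ca)
  list(structure = s,
       domain_map = list(d1 = seq_len(n1),
                         d2 = seq(n1 + linker_len + 1, nres)),
       linker_residues = seq(n1 + 1, n1 + linker_len))
}

#' Build a compact dimer from a monomer
#'
#' Two copies related by a rigid transform (180-degree rotation) brought
#' together so the minimum inter-chain atom distance equals
#' `contact_offset`; chains labeled A and B. `extractChain(dimer, "A")`
#' recovers the input monomer exactly.
#'
#' @param monomer a [MolecularStructure-class] (single chain).
#' @param contact_offset target interface gap, Angstrom.
#' @param seed seed for the random rotation axis.
#' @return The dimer [MolecularStructure-class].
#' @export
makeDimer <- function(monomer, contact_offset = 3.0, seed = 1) {
  set.seed(seed)
  a <- monomer@atoms
  a$chain <- "A"
  xyz <- coords(monomer)
  ctr <- colMeans(xyz)
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  # Rodrigues rotation by pi about axis u
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + 2 * K %*% K  # sin(pi) K + (1-cos(pi)) K^2
  rot <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  dirv <- c(1, 0, 0)
  mind <- function(shift) {
    b <- sweep(rot, 2, shift * dirv, "+")
    min(sqrt(outer(rowSums(xyz^2), rowSums(b^2), "+") - 2 * xyz %*% t(b)))
  }
  lo <- 0; hi <- 2 * (max(xyz[, 1]) - min(xyz[, 1])) + 50
  while (mind(hi) < contact_offset) hi <- hi * 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mind(mid) < contact_offset) lo <- mid else hi <- mid
  }
  b <- a
  b$chain <- "B"
  b$serial <- b$serial + max(a$serial)
  shifted <- sweep(rot, 2, hi * dirv, "+")
  b$x <- shifted[, 1]; b$y <- shifted[, 2]; b$z <- shifted[, 3]
  MolecularStructure(rbind(a, b), title = "synthetic dimer")
}

#' Synthesize a noisy experimental SAXS curve from a structure
#'
#' Computes the Debye profile, scales it so the peak intensity corresponds
#' to `mean_counts` detector counts, draws per-point Poisson counts, and
#' maps counts and `sqrt(counts)` uncertainties back to the intensity
#' scale — the count-statistics analogue of the propagated experimental
#' error bars.
#'
#' @param s [MolecularStructure-class].
#' @param q_grid q values, 1/Angstrom.
#' @param mean_counts expected counts at the curve peak.
#' @param seed RNG seed.
#' @param form_factor as in [debyeProfile()].
#' @return A [ScatteringCurve-class] with sigma.
#' @export
synthSAXS <- function(s, q_grid = seq(0.013, 0.26, length.out = 40),
                      mean_counts = 1e4, seed = 1,
                      form_factor = "constant") {
  set.seed(seed)
  th <- debyeProfile(s, q_grid, form_factor)
  scale <- mean_counts / max(th@I)
  lam <- th@I * scale
  counts <- stats::rpois(length(lam), lam)
  counts <- pmax(counts, 1)  # guard: zero counts carry no usable sigma
  ScatteringCurve(q_grid, counts / scale, sqrt(counts) / scale)
}

#' Planted two-mode conformational ensemble
#'
#' Draws frames from labeled perturbation modes around a base structure:
#' each mode scales the conformation about its centroid (`swell`) and adds
#' isotropic Gaussian jitter (`jitter_sd`). Mode labels are returned for
#' recovery scoring. Mode 1 defaults to near-native, mode 2 to a swollen
#' decoy.
#'
#' @param base [MolecularStructure-class].
#' @param n_frames frames to draw.
#' @param weights mixture weights (normalized internally).
#' @param swell per-mode mean expansion factors about the centroid.
#' @param swell_sd per-mode spread of the per-frame expansion factor, so the
#'   ensemble carries a continuum of compactness (and hence of chi-square
#'   against a fixed curve) rather than a single degenerate value.
#' @param jitter_sd per-mode Gaussian jitter, Angstrom.
#' @param seed RNG seed.
#' @return list with `frames` (list of matrices), `labels` (mode index per
#'   frame), `swell` (per-frame factor) and `structure` (the base).
#' @export
plantedEnsemble <- function(base, n_frames = 100, weights = c(0.8, 0.2),
                            swell = c(1.0, 1.35),
                            swell_sd = c(0.03, 0.03),
                            jitter_sd = c(0.15, 0.3), seed = 1) {
  stopifnot(length(weights) == length(swell),
            length(weights) == length(jitter_sd),
            length(weights) == length(swell_sd))
  set.seed(seed)
  xyz <- coords(base)
  ctr <- colMeans(xyz)
  labels <- sample.int(length(weights), n_frames, replace = TRUE,
                       prob = weights / sum(weights))
  sw <- stats::rnorm(n_frames, swell[labels], swell_sd[labels])
  frames <- lapply(seq_len(n_frames), function(i) {
    f <- sweep(sweep(xyz, 2, ctr) * sw[i], 2, ctr, "+")
    f + matrix(stats::rnorm(length(f), sd = jitter_sd[labels[i]]),
               nrow(f), 3)
  })
  list(frames = frames, labels = labels, swell = sw, structure = base)
}

#' Synthetic relaxation decay series with planted parameters
#'
#' Exact forward model of the inversion-recovery or CPMG decay plus
#' Gaussian noise of width `i0 / snr`.
#'
#' @param i0 planted initial intensity.
#' @param rate planted relaxation rate, 1/s.
#' @param model "inversion_recovery" or "cpmg_decay".
#' @param t sampling times, s.
#' @param snr signal-to-noise ratio (Inf for noiseless).
#' @param seed RNG seed.
#' @return list with `t`, `I` and the planted `truth`.
#' @export
synthRelaxation <- function(i0 = 100, rate = 2,
                            model = c("inversion_recovery", "cpmg_decay"),
                            t = NULL, snr = Inf, seed = 1) {
  model <- match.arg(model)
  if (is.null(t))
    t <- seq(0.01, 2.5 / rate, length.out = 10)
  set.seed(seed)
  I <- if (model == "inversion_recovery") i0 * (1 - 2 * exp(-rate * t))
       else i0 * exp(-rate * t)
  if (is.finite(snr)) I <- I + stats::rnorm(length(t), sd = i0 / snr)
  list(t = t, I = I, truth = list(i0 = i0, rate = rate, model = model,
                                  snr = snr))
}

#' Synthetic amide-I spectrum from planted Voigt bands
#'
#' @param centers band centers, 1/cm.
#' @param areas band areas (arbitrary units).
#' @param gaussian_sd,lorentzian_hwhm band widths, 1/cm (recycled).
#' @param wavenumber grid (default 1,600-1,700 at 1 1/cm).
#' @param noise_sd additive Gaussian noise.
#' @param seed RNG seed.
#' @return list with `wavenumber`, `absorbance` and planted `truth`.
#' @export
synthIR <- function(centers = c(1682, 1670, 1649, 1637, 1622),
                    areas = c(3, 11, 34, 30, 22),
                    gaussian_sd = 5, lorentzian_hwhm = 2,
                    wavenumber = seq(1600, 1700, by = 1),
                    noise_sd = 0, seed = 1) {
  stopifnot(length(centers) == length(areas))
  gaussian_sd <- rep_len(gaussian_sd, length(centers))
  lorentzian_hwhm <- rep_len(lorentzian_hwhm, length(centers))
  set.seed(seed)
  ab <- 0
  for (b in seq_along(centers))
    ab <- ab + areas[b] * cpp_voigt(wavenumber, centers[b], gaussian_sd[b],
                                    lorentzian_hwhm[b])
  if (noise_sd > 0) ab <- ab + stats::rnorm(length(wavenumber), sd = noise_sd)
  list(wavenumber = wavenumber, absorbance = ab,
       truth = list(centers = centers, areas = areas,
                    gaussian_sd = gaussian_sd,
                    lorentzian_hwhm = lorentzian_hwhm, noise_sd = noise_sd))
}

#' Synthetic DLS autocorrelation with planted hydrodynamic diameter
#'
#' Forward model of the second-order cumulant expansion
#' `g2 = B + beta exp(-2 Gamma tau) (1 + (mu2/2) tau^2)^2` with
#' Poisson-count noise (Gaussian approximation, `sigma = sqrt(g2/counts)`).
#' Gamma is derived from the planted diameter via Stokes-Einstein and
#' `Gamma = D q^2` for the given optics.
#'
#' @param dh planted hydrodynamic diameter, Angstrom.
#' @param pdi planted polydispersity index (mu2 = pdi * Gamma^2).
#' @param tau delay grid, s.
#' @param baseline,intercept planted B and beta.
#' @param counts mean photon counts (noise scale); Inf for noiseless.
#' @param seed RNG seed.
#' @param wavelength,angle,refractive_index,temperature,viscosity optics and
#'   solvent, as in [hydrodynamicDiameter()].
#' @return list with `tau`, `g2`, `sigma` and planted `truth` (including
#'   Gamma).
#' @export
synthDLS <- function(dh = 72.3, pdi = 0, tau = NULL, baseline = 1,
                     intercept = 0.9, counts = 1e6, seed = 1,
                     wavelength = 6330, angle = pi / 2,
                     refractive_index = 1.33, temperature = 293,
                     viscosity = 1.002e-3) {
  q <- 4 * pi * refractive_index * sin(angle / 2) / (wavelength * 1e-10)
  kB <- 1.380649e-23
  D <- kB * temperature / (3 * pi * viscosity * dh * 1e-10)
  gamma <- D * q^2
  if (is.null(tau)) tau <- 10^seq(-6, -2, length.out = 60)
  set.seed(seed)
  mu2 <- pdi * gamma^2
  g2 <- baseline + intercept * exp(-2 * gamma * tau) *
    (1 + 0.5 * mu2 * tau^2)^2
  sigma <- sqrt(pmax(g2, 1e-12) / counts)
  if (is.finite(counts)) g2 <- g2 + stats::rnorm(length(tau), sd = sigma)
  list(tau = tau, g2 = g2, sigma = sigma,
       truth = list(dh = dh, pdi = pdi, gamma = gamma, baseline = baseline,
                    intercept = intercept, counts = counts))
}
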