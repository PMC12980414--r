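#' @useDynLib sbmsaxs, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Molecular structure container
#'
#' Holds heavy-atom coordinates of one model: the native reference used to
#' build the structure-based topology, or any sampled/experimental
#' conformation. Coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (residue index), `resname`, `chain`, `x`, `y`, `z`.
#' @slot title free-text description.
#' @export
setClass("MolecularStructure",
  representation(atoms = "data.frame", title = "character"),
  prototype(title = ""))

setValidity("MolecularStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resid", "resname", "chain",
            "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return(TRUE)
  if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
    return("all coordinates must be finite")
  if (anyDuplicated(a$serial)) return("atom serials must be unique")
  for (ch in unique(a$chain)) {
    r <- unique(a$resid[a$chain == ch])
    if (any(diff(sort(r)) < 1)) return("residue indices must increase per chain")
  }
  TRUE
})

#' Force-field prefactors of the structure-based potential
#'
#' The epsilon prefactors of the all-atom structure-based model. Defaults
#' follow the printed convention: bond 100 per Angstrom^2, angle 20 per
#' rad^2, planar dihedral 10 per rad^2, excluded-volume 0.01 with
#' sigma_NC = 2.5 Angstrom. Contact and proper-dihedral weights are resolved
#' by [defaultWeights()] from the topology unless supplied.
#'
#' @slot epsR energy/Angstrom^2 bond prefactor.
#' @slot epsTheta energy/rad^2 angle prefactor.
#' @slot epsXi energy/rad^2 planar-dihedral prefactor.
#' @slot epsPhiBB,epsPhiSC per-dihedral weights (backbone, sidechain).
#' @slot epsContact energy per native contact.
#' @slot epsNC excluded-volume prefactor.
#' @slot sigmaNC excluded-volume radius, Angstrom.
#' @export
setClass("ForceFieldParameters",
  representation(epsR = "numeric", epsTheta = "numeric", epsXi = "numeric",
                 epsPhiBB = "numeric", epsPhiSC = "numeric",
                 epsContact = "numeric", epsNC = "numeric",
                 sigmaNC = "numeric"),
  prototype(epsR = 100, epsTheta = 20, epsXi = 10, epsPhiBB = 1,
            epsPhiSC = 0.5, epsContact = 1, epsNC = 0.01, sigmaNC = 2.5))

setValidity("ForceFieldParameters", function(object) {
  eps <- c(object@epsR, object@epsTheta, object@epsXi, object@epsPhiBB,
           object@epsPhiSC, object@epsContact, object@epsNC)
  if (any(eps < 0)) return("all epsilon prefactors must be >= 0")
  if (object@sigmaNC <= 0) return("sigmaNC must be > 0")
  TRUE
})

#' Structure-based-model topology
#'
#' Bonded terms with native values measured on the reference structure,
#' shadow-map contacts, and the exclusion list for the excluded-volume term.
#' Atom indices are 1-based into the structure the topology was built from.
#'
#' @slot nAtoms number of atoms.
#' @slot bonds data.frame (i, j, r0 Angstrom).
#' @slot angles data.frame (i, j, k, theta0 rad).
#' @slot planarDihedrals data.frame (i, j, k, l, xi0 rad).
#' @slot properDihedrals data.frame (i, j, k, l, phi0 rad,
#'   class in backbone/sidechain, constrained flag).
#' @slot contacts data.frame (i, j, sigma Angstrom).
#' @slot exclusions 2-column integer matrix of bonded/1-3/1-4 pairs removed
#'   from the excluded-volume sum (contact pairs are excluded implicitly).
#' @export
setClass("SBMTopology",
  representation(nAtoms = "integer", bonds = "data.frame",
                 angles = "data.frame", planarDihedrals = "data.frame",
                 properDihedrals = "data.frame", contacts = "data.frame",
                 exclusions = "matrix"))

setValidity("SBMTopology", function(object) {
  ct <- object@contacts
  if (nrow(ct) > 0) {
    if (any(ct$i >= ct$j)) return("contacts must be canonicalized with i < j")
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    bad <- intersect(key(cbind(ct$i, ct$j)), key(object@exclusions))
    if (length(bad) > 0)
      return("contact pairs must not also be bonded/1-3/1-4 pairs")
  }
  TRUE
})

#' Simulation configuration (reduced units)
#'
#' Langevin dynamics settings. One reduced time unit maps approximately to
#' 1 ps; the default time step is 0.0005 reduced time units and frames are
#' recorded every 1,000 steps.
#'
#' @slot temperature reduced temperature (kB = 1).
#' @slot dt time step, reduced time units.
#' @slot friction Langevin friction, 1/rtu.
#' @slot nSteps total integration steps.
#' @slot recordEvery recording cadence in steps.
#' @slot seed RNG seed.
#' @slot thermostat logical; FALSE gives velocity-Verlet NVE.
#' @slot guard coordinate magnitude triggering a divergence abort.
#' @export
setClass("SimulationConfig",
  representation(temperature = "numeric", dt = "numeric", friction = "numeric",
                 nSteps = "integer", recordEvery = "integer", seed = "integer",
                 thermostat = "logical", guard = "numeric"),
  prototype(temperature = 0.5, dt = 0.0005, friction = 1.0, nSteps = 100000L,
            recordEvery = 1000L, seed = 1L, thermostat = TRUE, guard = 1e4))

setValidity("SimulationConfig", function(object) {
  if (object@dt <= 0) return("dt must be > 0")
  if (object@nSteps < object@recordEvery)
    return("nSteps must be >= recordEvery")
  TRUE
})

#' Recorded trajectory
#'
#' @slot frames list of N x 3 coordinate matrices (Angstrom).
#' @slot energies data.frame of per-frame energy components, kinetic energy
#'   and step index.
#' @slot config the [SimulationConfig-class] that produced it.
#' @slot nativeId identifier of the native reference.
#' @export
setClass("Trajectory",
  representation(frames = "list", energies = "data.frame",
                 config = "SimulationConfig", nativeId = "character"),
  prototype(nativeId = ""))

setValidity("Trajectory", function(object) {
  if (length(object@frames) != nrow(object@energies))
    return("one energy row per recorded frame required")
  if (!all(vapply(object@frames, function(f) all(is.finite(f)), logical(1))))
    return("all frame coordinates must be finite")
  TRUE
})

#' Scattering curve (q, I, sigma)
#'
#' @slot q scattering vector modulus, 1/Angstrom, strictly increasing.
#' @slot I intensity (arbitrary units).
#' @slot sigma 1-sigma uncertainty; length 0 for theoretical curves.
#' @export
setClass("ScatteringCurve",
  representation(q = "numeric", I = "numeric", sigma = "numeric"),
  prototype(sigma = numeric(0)))

setValidity("ScatteringCurve", function(object) {
  if (length(object@q) != length(object@I)) return("q and I lengths differ")
  if (any(diff(object@q) <= 0)) return("q must be strictly increasing")
  if (!all(is.finite(object@I))) return("I must be finite")
  if (length(object@sigma) > 0) {
    if (length(object@sigma) != length(object@q))
      return("sigma length must match q")
    if (any(object@sigma <= 0)) return("sigma must be > 0 where present")
  }
  TRUE
})

#' Scale-optimized chi-square fit of a theoretical to an experimental curve
#'
#' @slot scale fitted multiplicative scale c.
#' @slot chi2 mean of squared sigma-weighted residuals.
#' @slot residuals per-point (I_exp - c I_th) / sigma.
#' @slot q q values used (after any window restriction).
#' @slot nPoints number of points fitted.
#' @slot offset fitted additive background (0 unless requested).
#' @export
setClass("ChiSquareFit",
  representation(scale = "numeric", chi2 = "numeric", residuals = "numeric",
                 q = "numeric", nPoints = "integer", offset = "numeric"),
  prototype(offset = 0))

#' Pair-distance distribution P(r)
#'
#' @slot r distance grid, Angstrom.
#' @slot p P(r) values, >= 0, with p(0) = 0 and p = 0 beyond dmax.
#' @slot dmax maximum particle dimension, Angstrom.
#' @slot rg radius of gyration from the second moment of P(r), Angstrom.
#' @export
setClass("PairDistribution",
  representation(r = "numeric", p = "numeric", dmax = "numeric",
                 rg = "numeric"))

setValidity("PairDistribution", function(object) {
  if (any(object@p < -1e-9)) return("P(r) must be non-negative")
  if (sum(object@p) <= 0) return("P(r) must have positive mass")
  TRUE
})

#' Guinier analysis result
#'
#' @slot rg radius of gyration, Angstrom.
#' @slot i0 extrapolated forward scattering.
#' @slot fitRange (q_min, q_max) of the fitted window.
#' @slot qmaxRg q_max * Rg of the window (flagged if > limit).
#' @slot r2 linearity diagnostic (R^2 of ln I vs q^2).
#' @slot nPoints points in the window.
#' @export
setClass("GuinierResult",
  representation(rg = "numeric", i0 = "numeric", fitRange = "numeric",
                 qmaxRg = "numeric", r2 = "numeric", nPoints = "integer"))

#' Condensed inter-conformation dissimilarity matrix
#'
#' @slot values condensed lower-triangle dissimilarities (as in [stats::dist]).
#' @slot nFrames number of conformations.
#' @export
setClass("DissimilarityMatrix",
  representation(values = "numeric", nFrames = "integer"))

setValidity("DissimilarityMatrix", function(object) {
  n <- object@nFrames
  if (length(object@values) != n * (n - 1) / 2)
    return("condensed length must be n(n-1)/2")
  if (any(object@values < 0)) return("dissimilarities must be >= 0")
  TRUE
})

#' Planar projection of a conformational ensemble
#'
#' @slot coords n x 2 matrix of projection coordinates (dimensionless).
#' @slot stress final normalized stress.
#' @slot stressTrace per-iteration stress values.
#' @slot seed seed used for initialization.
#' @slot converged logical convergence flag.
#' @export
setClass("Projection2D",
  representation(coords = "matrix", stress = "numeric",
                 stressTrace = "numeric", seed = "integer",
                 converged = "logical"))

#' Representative-ensemble selection
#'
#' @slot band inclusive (chi2_lo, chi2_hi) filter.
#' @slot members frame indices inside the band.
#' @slot clusterMembers member frames inside the density-peak cluster.
#' @slot densityPeak (x, y) of the highest-density point.
#' @slot representatives k frames nearest the peak.
#' @slot chi2 per-frame chi-square (all frames).
#' @slot density per-frame density (NA outside the band).
#' @slot peaks data.frame of all local density maxima found on the grid.
#' @slot note warning note (e.g., k exceeded cluster size).
#' @export
setClass("EnsembleSelection",
  representation(band = "numeric", members = "integer",
                 clusterMembers = "integer", densityPeak = "numeric",
                 representatives = "integer", chi2 = "numeric",
                 density = "numeric", peaks = "data.frame", note = "character"),
  prototype(note = ""))

setValidity("EnsembleSelection", function(object) {
  if (!all(object@representatives %in% object@members))
    return("representatives must be a subset of band members")
  cx <- object@chi2[object@members]
  if (any(cx < object@band[1] - 1e-12 | cx > object@band[2] + 1e-12))
    return("all member chi2 must lie within the band")
  TRUE
})

#' Exponential relaxation fit (inversion recovery R1 or CPMG R2)
#'
#' @slot i0 fitted initial intensity.
#' @slot rate fitted relaxation rate, 1/s.
#' @slot stderrRate standard error of the rate (SNR-based sigma).
#' @slot stderrI0 standard error of I0.
#' @slot model "inversion_recovery" or "cpmg_decay".
#' @slot sigmaI intensity noise level used for the errors.
#' @export
setClass("RelaxationResult",
  representation(i0 = "numeric", rate = "numeric", stderrRate = "numeric",
                 stderrI0 = "numeric", model = "character",
                 sigmaI = "numeric"))

setValidity("RelaxationResult", function(object) {
  if (object@rate <= 0) return("rate must be > 0")
  if (object@stderrRate < 0) return("stderr must be >= 0")
  TRUE
})

#' Amide-I Voigt deconvolution result
#'
#' @slot components data.frame with center, gaussianWidth, lorentzianWidth,
#'   amplitude (= area, the profile is area-normalized), area, areaStderr and
#'   assignment per band.
#' @slot fitted fitted absorbance on the input wavenumber grid.
#' @slot wavenumber input grid, 1/cm.
#' @slot sigmaNoise residual noise estimate.
#' @slot covariance parameter covariance matrix.
#' @export
setClass("VoigtDeconvolution",
  representation(components = "data.frame", fitted = "numeric",
                 wavenumber = "numeric", sigmaNoise = "numeric",
                 covariance = "matrix"))

#' Secondary-structure fractions from pooled band areas
#'
#' @slot fractions named percentages per class, summing to 100.
#' @slot byComponent per-component areas and assignments.
#' @export
setClass("SecondaryStructureReport",
  representation(fractions = "numeric", byComponent = "data.frame"))

#' DLS second-order cumulant fit
#'
#' @slot gamma mean decay rate, 1/s.
#' @slot mu2 second cumulant, 1/s^2.
#' @slot pdi polydispersity index mu2 / gamma^2.
#' @slot baseline fitted baseline B.
#' @slot intercept fitted coherence amplitude beta.
#' @slot dh hydrodynamic diameter, Angstrom (NA until converted).
#' @slot stderrGamma,stderrPdi,stderrDh propagated standard errors.
#' @export
setClass("CumulantResult",
  representation(gamma = "numeric", mu2 = "numeric", pdi = "numeric",
                 baseline = "numeric", intercept = "numeric", dh = "numeric",
                 stderrGamma = "numeric", stderrPdi = "numeric",
                 stderrDh = "numeric"),
  prototype(dh = NA_real_, stderrDh = NA_real_))

setValidity("CumulantResult", function(object) {
  if (object@gamma <= 0) return("decay rate must be > 0")
  if (object@pdi < -1e-6) return("polydispersity index must be >= 0")
  TRUE
})
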