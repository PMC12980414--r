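#' Dihedral restraint function
#'
#' `Fd(phi) = [1 - cos(phi - phi0)] + (1/2)[1 - cos(3(phi - phi0))]`:
#' periodic with period 2 pi, minimum 0 at `phi = phi0`.
#'
#' @param phi dihedral angle, rad (vectorized).
#' @param phi0 native dihedral angle, rad.
#' @return Restraint energy (dimensionless; multiply by the dihedral weight).
#' @export
dihedralRestraint <- function(phi, phi0) {
  d <- phi - phi0
  (1 - cos(d)) + 0.5 * (1 - cos(3 * d))
}

.topo_to_cpp <- function(topo) {
  pd <- topo@properDihedrals
  list(n_atoms = topo@nAtoms,
       bonds = as.matrix(topo@bonds[, c("i", "j")]),
       r0 = topo@bonds$r0,
       angles = if (nrow(topo@angles)) as.matrix(topo@angles[, c("i", "j", "k")])
                else matrix(integer(0), 0, 3),
       theta0 = topo@angles$theta0,
       planars = if (nrow(topo@planarDihedrals))
                   as.matrix(topo@planarDihedrals[, c("i", "j", "k", "l")])
                 else matrix(integer(0), 0, 4),
       xi0 = topo@planarDihedrals$xi0,
       dihedrals = if (nrow(pd)) as.matrix(pd[, c("i", "j", "k", "l")])
                   else matrix(integer(0), 0, 4),
       phi0 = pd$phi0,
       dihedral_bb = as.integer(pd$class == "backbone"),
       dihedral_on = as.integer(pd$constrained),
       contacts = if (nrow(topo@contacts))
                    as.matrix(topo@contacts[, c("i", "j")])
                  else matrix(integer(0), 0, 2),
       sigma = topo@contacts$sigma,
       exclusions = topo@exclusions)
}

.params_to_cpp <- function(p) {
  list(eps_r = p@epsR, eps_theta = p@epsTheta, eps_xi = p@epsXi,
       eps_phi_bb = p@epsPhiBB, eps_phi_sc = p@epsPhiSC,
       eps_contact = p@epsContact, eps_nc = p@epsNC, sigma_nc = p@sigmaNC)
}

#' Evaluate the structure-based potential
#'
#' Term-by-term breakdown of the potential: harmonic bonds, angles and
#' planar dihedrals, Fd restraints on backbone/sidechain proper dihedrals,
#' the 12-6 native-contact attraction `epsC [(sigma/r)^12 - 2 (sigma/r)^6]`
#' (exactly -epsC per contact at the native distance) and the
#' `epsNC (sigmaNC/r)^12` excluded-volume repulsion over non-excluded pairs.
#'
#' @param conf N x 3 coordinate matrix or [MolecularStructure-class].
#' @param topo [SBMTopology-class] built for the same atoms.
#' @param params [ForceFieldParameters-class].
#' @return Named numeric vector with components `bond`, `angle`, `planar`,
#'   `dihedral_bb`, `dihedral_sc`, `contact`, `noncontact`, `total`.
#' @export
sbmEnergy <- function(conf, topo, params = ForceFieldParameters()) {
  if (is(conf, "MolecularStructure")) conf <- coords(conf)
  if (nrow(conf) != topo@nAtoms)
    stop("conformation has ", nrow(conf), " atoms but topology expects ",
         topo@nAtoms)
  cpp_sbm_energy(conf, .topo_to_cpp(topo), .params_to_cpp(params))
}

#' Analytic forces of the structure-based potential
#'
#' Returns `-grad V` per atom. Net force on an isolated molecule is zero.
#'
#' @inheritParams sbmEnergy
#' @return N x 3 matrix of force components.
#' @export
sbmForces <- function(conf, topo, params = ForceFieldParameters()) {
  if (is(conf, "MolecularStructure")) conf <- coords(conf)
  if (nrow(conf) != topo@nAtoms)
    stop("conformation has ", nrow(conf), " atoms but topology expects ",
         topo@nAtoms)
  cpp_sbm_forces(conf, .topo_to_cpp(topo), .params_to_cpp(params))
}

#' Simulation configuration constructor
#'
#' @param temperature reduced temperature (kB = 1).
#' @param dt time step in reduced time units (default 0.0005).
#' @param friction Langevin friction, 1/rtu (default 1).
#' @param nSteps total steps.
#' @param recordEvery recording cadence (default 1000 steps).
#' @param seed RNG seed.
#' @param thermostat `FALSE` switches to velocity-Verlet NVE integration.
#' @param guard coordinate magnitude treated as divergence.
#' @return A [SimulationConfig-class].
#' @export
SimulationConfig <- function(temperature = 0.5, dt = 0.0005, friction = 1.0,
                             nSteps = 100000L, recordEvery = 1000L, seed = 1L,
                             thermostat = TRUE, guard = 1e4) {
  new("SimulationConfig", temperature = temperature, dt = dt,
      friction = friction, nSteps = as.integer(nSteps),
      recordEvery = as.integer(recordEvery), seed = as.integer(seed),
      thermostat = thermostat, guard = guard)
}

#' Run Langevin dynamics on the structure-based potential
#'
#' BAOAB-split Langevin integration in reduced units (uniform unit masses,
#' kB = 1; one reduced time unit maps approximately to 1 ps). With
#' `thermostat = FALSE` (or zero friction) the integrator reduces exactly to
#' velocity Verlet. Reproducible: the trajectory is a pure function of the
#' seed in the configuration.
#'
#' @param start starting conformation (matrix or
#'   [MolecularStructure-class]).
#' @param topo [SBMTopology-class].
#' @param params [ForceFieldParameters-class].
#' @param cfg [SimulationConfig-class].
#' @param init_velocities draw Maxwell-Boltzmann initial velocities.
#' @return A [Trajectory-class]; frames recorded every `recordEvery` steps.
#' @export
runLangevin <- function(start, topo, params = ForceFieldParameters(),
                        cfg = SimulationConfig(), init_velocities = TRUE) {
  native_id <- ""
  if (is(start, "MolecularStructure")) {
    native_id <- start@title
    start <- coords(start)
  }
  stopifnot(all(is.finite(start)))
  set.seed(cfg@seed)
  res <- cpp_run_langevin(start, .topo_to_cpp(topo), .params_to_cpp(params),
                          cfg@temperature, cfg@dt, cfg@friction, cfg@nSteps,
                          cfg@recordEvery, cfg@thermostat, cfg@guard,
                          init_velocities)
  en <- as.data.frame(res$energies)
  names(en) <- c("bond", "angle", "planar", "dihedral_bb", "dihedral_sc",
                 "contact", "noncontact", "total", "kinetic", "step")
  new("Trajectory", frames = res$frames, energies = en, config = cfg,
      nativeId = native_id)
}

#' @describeIn nFrames Number of recorded frames in a trajectory.
#' @param x object.
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@frames))

#' @describeIn frames List of recorded coordinate matrices.
#' @param x object.
#' @export
setMethod("frames", "Trajectory", function(x) x@frames)

#' @describeIn energies Per-frame energy breakdown table.
#' @param x object.
#' @export
setMethod("energies", "Trajectory", function(x) x@energies)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@frames), "frames of",
      if (length(object@frames)) nrow(object@frames[[1]]) else 0, "atoms\n")
  cat("  T =", object@config@temperature, "(reduced), dt =",
      object@config@dt, "rtu (~1 rtu per ps), recorded every",
      object@config@recordEvery, "steps\n")
})

#' Root-mean-square deviation between two coordinate sets
#'
#' Optimal-superposition RMSD (Kabsch alignment) unless `fit = FALSE`.
#'
#' @param a,b N x 3 matrices or [MolecularStructure-class] objects.
#' @param fit superpose before measuring.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, fit = TRUE) {
  if (is(a, "MolecularStructure")) a <- coords(a)
  if (is(b, "MolecularStructure")) b <- coords(b)
  stopifnot(nrow(a) == nrow(b))
  if (fit) {
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    s <- svd(t(ac) %*% bc)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    ac <- ac %*% t(R)
    sqrt(mean(rowSums((ac - bc)^2)))
  } else {
    sqrt(mean(rowSums((a - b)^2)))
  }
}

#' Write trajectory energies as CSV and metadata as a JSON sidecar
#'
#' @param traj a [Trajectory-class].
#' @param prefix output path prefix; writes `<prefix>_energies.csv` and
#'   `<prefix>_meta.json`.
#' @return Invisibly, the two paths.
#' @export
writeTrajectoryData <- function(traj, prefix) {
  ecsv <- paste0(prefix, "_energies.csv")
  mjs <- paste0(prefix, "_meta.json")
  utils::write.csv(traj@energies, ecsv, row.names = FALSE)
  cfg <- traj@config
  jsonlite::write_json(
    list(units = list(time = "reduced (1 rtu ~ 1 ps)", length = "angstrom",
                      energy = "reduced"),
         temperature = cfg@temperature, dt = cfg@dt, friction = cfg@friction,
         n_steps = cfg@nSteps, record_every = cfg@recordEvery,
         seed = cfg@seed, thermostat = cfg@thermostat,
         n_frames = length(traj@frames), native_id = traj@nativeId),
    mjs, auto_unbox = TRUE, digits = NA)
  invisible(c(ecsv, mjs))
}
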