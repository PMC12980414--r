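#' Force-field parameter constructor
#'
#' @param epsR,epsTheta,epsXi harmonic prefactors (energy per Angstrom^2 or
#'   rad^2); defaults 100, 20, 10.
#' @param epsPhiBB,epsPhiSC backbone/sidechain proper-dihedral weights; if
#'   `NULL` resolve them with [defaultWeights()] when a topology is at hand.
#' @param epsContact energy per native contact.
#' @param epsNC,sigmaNC excluded-volume prefactor (0.01) and radius (2.5 A).
#' @return A [ForceFieldParameters-class].
#' @export
ForceFieldParameters <- function(epsR = 100, epsTheta = 20, epsXi = 10,
                                 epsPhiBB = 1, epsPhiSC = 0.5,
                                 epsContact = 1, epsNC = 0.01,
                                 sigmaNC = 2.5) {
  new("ForceFieldParameters", epsR = epsR, epsTheta = epsTheta, epsXi = epsXi,
      epsPhiBB = epsPhiBB, epsPhiSC = epsPhiSC, epsContact = epsContact,
      epsNC = epsNC, sigmaNC = sigmaNC)
}

#' Resolve contact and dihedral weights from a topology
#'
#' Distributes the stabilizing energy following the usual all-atom
#' structure-based-model convention: the summed contact energy and summed
#' dihedral energy are in ratio `rCD` (default 2), their total equals the
#' number of atoms, and backbone dihedrals carry `rBBSC` (default 2) times
#' the sidechain weight.
#'
#' @param topo an [SBMTopology-class].
#' @param rCD contact-to-dihedral energy ratio.
#' @param rBBSC backbone-to-sidechain dihedral weight ratio.
#' @param ... other arguments passed to [ForceFieldParameters()].
#' @return A [ForceFieldParameters-class] with resolved weights.
#' @export
defaultWeights <- function(topo, rCD = 2, rBBSC = 2, ...) {
  nc <- nrow(topo@contacts)
  dh <- topo@properDihedrals
  dh <- dh[dh$constrained, , drop = FALSE]
  nbb <- sum(dh$class == "backbone")
  nsc <- sum(dh$class == "sidechain")
  etot <- topo@nAtoms
  if (nc == 0 && nbb + nsc == 0) return(ForceFieldParameters(...))
  ec <- if (nc > 0) etot * rCD / (1 + rCD) / nc else 0
  ed <- if (nbb + nsc > 0) etot / (1 + rCD) else 0
  esc <- if (nbb + nsc > 0) ed / (rBBSC * nbb + nsc) else 0
  ForceFieldParameters(epsContact = ec, epsPhiBB = rBBSC * esc,
                       epsPhiSC = esc, ...)
}

.backbone_atoms <- c("N", "CA", "C", "O")

.measure_angle <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

.measure_dihedral <- function(xyz, i, j, k, l)
  cpp_dihedral_angle(xyz[c(i, j, k, l), , drop = FALSE])

.bond_connectivity <- function(s, bond_cutoff = 1.8, break_threshold = 2.0) {
  a <- s@atoms
  xyz <- coords(s)
  n <- nrow(a)
  pairs <- list()
  # intra- and inter-residue bonds by a distance rule over nearby residues
  for (i in seq_len(n - 1)) {
    js <- which(a$resid[(i + 1):n] - a$resid[i] <= 1) + i
    if (length(js) == 0) next
    d <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
    hit <- js[d < bond_cutoff]
    if (length(hit) > 0) pairs[[length(pairs) + 1]] <- cbind(i, hit)
  }
  B <- do.call(rbind, pairs)
  if (is.null(B)) stop("no bonds found; structure is not a connected chain")
  # chain-break check: consecutive residues must be linked within threshold
  res <- sort(unique(a$resid))
  linked <- paste(a$resid[B[, 1]], a$resid[B[, 2]])
  for (k in seq_len(length(res) - 1)) {
    if (res[k + 1] - res[k] != 1) next
    if (!(paste(res[k], res[k + 1]) %in% linked)) {
      ii <- which(a$resid == res[k]); jj <- which(a$resid == res[k + 1])
      dmin <- min(sqrt(outer(rowSums(xyz[ii, , drop = FALSE]^2),
                             rowSums(xyz[jj, , drop = FALSE]^2), "+") -
                       2 * xyz[ii, , drop = FALSE] %*%
                           t(xyz[jj, , drop = FALSE])))
      if (dmin > break_threshold)
        stop("chain break between residues ", res[k], " and ", res[k + 1],
             " (closest linking atoms ", round(dmin, 2), " A > ",
             break_threshold, " A)")
      best <- which.min(as.vector(sqrt(outer(
        rowSums(xyz[ii, , drop = FALSE]^2),
        rowSums(xyz[jj, , drop = FALSE]^2), "+") -
        2 * xyz[ii, , drop = FALSE] %*% t(xyz[jj, , drop = FALSE]))))
      B <- rbind(B, c(ii[(best - 1) %% length(ii) + 1],
                      jj[(best - 1) %/% length(ii) + 1]))
    }
  }
  B
}

#' Build a structure-based-model topology from a native structure
#'
#' Enumerates bonds (distance rule), angles and proper dihedrals (paths in
#' the bond graph), and planar dihedrals (impropers at atoms with three or
#' more bonded neighbors), measuring every native value (r0, theta0, xi0,
#' phi0) on the input structure. Proper dihedrals whose central bond lies in
#' a linker residue are released (constrained = FALSE), and the dihedral
#' class is backbone when all four atoms are backbone atoms (N, CA, C, O).
#'
#' @param s single-chain [MolecularStructure-class] (the native reference).
#' @param linker_residues integer vector of linker residue indices whose
#'   non-rigid proper dihedrals are released.
#' @param domain_map named list mapping domain id -> integer residue vector;
#'   contacts across different domains are excluded (residues outside any
#'   domain, e.g. linkers, are unrestricted).
#' @param contact_cutoff,shadow_radius,min_res_sep shadow-map settings
#'   (defaults 6.0 A, 1.0 A, 3 residues).
#' @param bond_cutoff distance rule for covalent bonds, Angstrom.
#' @return An [SBMTopology-class].
#' @export
buildTopology <- function(s, linker_residues = integer(0),
                          domain_map = list(), contact_cutoff = 6.0,
                          shadow_radius = 1.0, min_res_sep = 3,
                          bond_cutoff = 1.8) {
  if (length(chains(s)) != 1)
    stop("topology requires a single chain; extract one first")
  a <- s@atoms
  xyz <- coords(s)
  n <- nrow(a)
  B <- .bond_connectivity(s, bond_cutoff)
  adj <- vector("list", n)
  for (k in seq_len(nrow(B))) {
    i <- B[k, 1]; j <- B[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  bonds <- data.frame(i = B[, 1], j = B[, 2],
                      r0 = sqrt(rowSums((xyz[B[, 1], , drop = FALSE] -
                                         xyz[B[, 2], , drop = FALSE])^2)))
  # angles: i - j - k over bonded neighbors of each central atom
  ang <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    ang[[length(ang) + 1]] <- cbind(cmb[1, ], j, cmb[2, ])
  }
  A <- do.call(rbind, ang)
  angles <- if (is.null(A)) {
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               theta0 = numeric(0))
  } else {
    data.frame(i = A[, 1], j = A[, 2], k = A[, 3],
               theta0 = vapply(seq_len(nrow(A)), function(r)
                 .measure_angle(xyz, A[r, 1], A[r, 2], A[r, 3]), numeric(1)))
  }
  # proper dihedrals: i - j - k - l paths over central bonds j-k
  dih <- list()
  for (k in seq_len(nrow(B))) {
    j <- B[k, 1]; kk <- B[k, 2]
    for (i in setdiff(adj[[j]], kk))
      for (l in setdiff(adj[[kk]], j))
        if (i != l) dih[[length(dih) + 1]] <- c(i, j, kk, l)
  }
  D <- unique(do.call(rbind, dih))
  if (is.null(D)) D <- matrix(integer(0), 0, 4)
  is_bb <- function(idx) all(a$name[idx] %in% .backbone_atoms)
  properDihedrals <- data.frame(
    i = D[, 1], j = D[, 2], k = D[, 3], l = D[, 4],
    phi0 = vapply(seq_len(nrow(D)), function(r)
      .measure_dihedral(xyz, D[r, 1], D[r, 2], D[r, 3], D[r, 4]), numeric(1)),
    class = vapply(seq_len(nrow(D)), function(r)
      if (is_bb(D[r, ])) "backbone" else "sidechain", character(1)),
    constrained = vapply(seq_len(nrow(D)), function(r)
      !any(a$resid[D[r, 2:3]] %in% linker_residues), logical(1)),
    stringsAsFactors = FALSE)
  # planar dihedrals (impropers): center j with >= 3 neighbors
  imp <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 3) next
    imp[[length(imp) + 1]] <- c(nb[1], j, nb[2], nb[3])
  }
  P <- do.call(rbind, imp)
  planarDihedrals <- if (is.null(P)) {
    data.frame(i = integer(0), j = integer(0), k = integer(0), l = integer(0),
               xi0 = numeric(0))
  } else {
    data.frame(i = P[, 1], j = P[, 2], k = P[, 3], l = P[, 4],
               xi0 = vapply(seq_len(nrow(P)), function(r)
                 .measure_dihedral(xyz, P[r, 1], P[r, 2], P[r, 3], P[r, 4]),
                 numeric(1)))
  }
  # exclusions: 1-2, 1-3, 1-4 pairs
  excl <- rbind(as.matrix(bonds[, c("i", "j")]),
                as.matrix(angles[, c("i", "k")]),
                as.matrix(properDihedrals[, c("i", "l")]))
  excl <- unique(cbind(pmin(excl[, 1], excl[, 2]),
                       pmax(excl[, 1], excl[, 2])))
  colnames(excl) <- NULL
  domain <- integer(n)
  if (length(domain_map) > 0)
    for (d in seq_along(domain_map))
      domain[a$resid %in% domain_map[[d]]] <- d
  sc <- cpp_shadow_contacts(xyz, as.integer(a$resid), domain, excl,
                            contact_cutoff, shadow_radius,
                            as.integer(min_res_sep))
  contacts <- data.frame(i = sc$pairs[, 1], j = sc$pairs[, 2],
                         sigma = sc$sigma)
  if (nrow(contacts) == 0)
    contacts <- data.frame(i = integer(0), j = integer(0), sigma = numeric(0))
  new("SBMTopology", nAtoms = as.integer(n), bonds = bonds, angles = angles,
      planarDihedrals = planarDihedrals, properDihedrals = properDihedrals,
      contacts = contacts, exclusions = excl)
}

#' Shadow-map contacts of a structure
#'
#' Atom pairs within `cutoff`, separated by at least `min_res_sep` residues,
#' not bonded/1-3/1-4, in the same domain (or involving unassigned residues),
#' and with an unoccluded line of sight: a pair is removed when any third
#' atom, modeled as a sphere of `shadow_radius`, intersects the segment
#' between them. `sigma` is the native pair distance.
#'
#' @inheritParams buildTopology
#' @param cutoff contact cutoff, Angstrom.
#' @param excluded 2-column matrix of pairs to skip (bonded/1-3/1-4).
#' @return data.frame (i, j, sigma).
#' @export
shadowContacts <- function(s, cutoff = 6.0, shadow_radius = 1.0,
                           domain_map = list(), min_res_sep = 3,
                           excluded = matrix(integer(0), 0, 2)) {
  a <- s@atoms
  domain <- integer(nrow(a))
  if (length(domain_map) > 0)
    for (d in seq_along(domain_map))
      domain[a$resid %in% domain_map[[d]]] <- d
  sc <- cpp_shadow_contacts(coords(s), as.integer(a$resid), domain,
                            excluded, cutoff, shadow_radius,
                            as.integer(min_res_sep))
  data.frame(i = as.integer(sc$pairs[, 1]), j = as.integer(sc$pairs[, 2]),
             sigma = as.numeric(sc$sigma))
}

#' @describeIn contacts Native contact table of a topology.
#' @param x object.
#' @export
setMethod("contacts", "SBMTopology", function(x) x@contacts)

setMethod("show", "SBMTopology", function(object) {
  cat("SBMTopology:", object@nAtoms, "atoms\n")
  cat(" ", nrow(object@bonds), "bonds,", nrow(object@angles), "angles,",
      nrow(object@planarDihedrals), "planar and",
      nrow(object@properDihedrals), "proper dihedrals (",
      sum(object@properDihedrals$constrained), "restrained ),",
      nrow(object@contacts), "contacts\n")
})

#' Serialize a topology to JSON (units: Angstrom, radian)
#'
#' @param topo an [SBMTopology-class].
#' @param path output file; `NULL` returns the JSON string.
#' @return The JSON string, invisibly if written to file.
#' @export
writeTopologyJSON <- function(topo, path = NULL) {
  obj <- list(units = list(length = "angstrom", angle = "radian"),
              n_atoms = topo@nAtoms, bonds = topo@bonds,
              angles = topo@angles, planar_dihedrals = topo@planarDihedrals,
              proper_dihedrals = topo@properDihedrals,
              contacts = topo@contacts,
              exclusions = as.data.frame(topo@exclusions))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
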