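# Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fix_two_domain <- function() {
  if (is.null(.fixture_env$td)) {
    td <- makeTwoDomain(10, 5, seed = 1)
    topo <- buildTopology(td$structure, td$linker_residues, td$domain_map)
    .fixture_env$td <- list(s = td$structure, td = td, topo = topo,
                            params = defaultWeights(topo))
  }
  .fixture_env$td
}

# minimal hand-built topology: a single harmonic bond between two atoms
bond_only_topology <- function(r0 = 1.5) {
  new("SBMTopology", nAtoms = 2L,
      bonds = data.frame(i = 1L, j = 2L, r0 = r0),
      angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                          theta0 = numeric(0)),
      planarDihedrals = data.frame(i = integer(0), j = integer(0),
                                   k = integer(0), l = integer(0),
                                   xi0 = numeric(0)),
      properDihedrals = data.frame(i = integer(0), j = integer(0),
                                   k = integer(0), l = integer(0),
                                   phi0 = numeric(0), class = character(0),
                                   constrained = logical(0)),
      contacts = data.frame(i = integer(0), j = integer(0),
                            sigma = numeric(0)),
      exclusions = matrix(c(1L, 2L), 1, 2))
}

two_atom_structure <- function(d = 1.5) {
  MolecularStructure(data.frame(
    serial = 1:2, name = c("CA", "CA"), element = "C", resid = 1:2,
    resname = "GLY", chain = "A", x = c(0, d), y = 0, z = 0))
}

# O(N^2) pure-R Debye oracle, independent of the production C++ path
debye_oracle <- function(xyz, q, f = rep(1, nrow(xyz))) {
  D <- as.matrix(stats::dist(xyz))
  vapply(q, function(qq) {
    S <- outer(f, f) * ifelse(qq * D < 1e-12, 1, sin(qq * D) / (qq * D))
    diag(S) <- f^2
    sum(S)
  }, numeric(1))
}

# O(N^3) brute-force shadow-contact oracle (triple loop, pure R)
shadow_oracle <- function(xyz, resid, domain, excl, cutoff, radius,
                         min_sep) {
  n <- nrow(xyz)
  key <- function(i, j) paste(min(i, j), max(i, j))
  ex <- character(0)
  if (nrow(excl) > 0)
    ex <- apply(excl, 1, function(p) key(p[1], p[2]))
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    sqrt(sum((a + t * ab - p)^2))
  }
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(resid[i] - resid[j]) < min_sep) next
    if (domain[i] != 0 && domain[j] != 0 && domain[i] != domain[j]) next
    if (key(i, j) %in% ex) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > cutoff) next
    occ <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (seg_dist(xyz[k, ], xyz[i, ], xyz[j, ]) < radius) {
        occ <- TRUE
        break
      }
    }
    if (!occ) out <- rbind(out, c(i, j))
  }
  out
}

# finite-difference gradient of the total SBM energy (4th-order stencil:
# the r^-12 repulsion has third derivatives large enough that a plain
# central difference at h = 1e-5 is itself wrong by > 1e-4 near contact)
fd_forces <- function(x, topo, params, h = 1e-5) {
  g <- matrix(0, nrow(x), 3)
  e_at <- function(x) sbmEnergy(x, topo, params)[["total"]]
  for (i in seq_len(nrow(x))) for (j in 1:3) {
    ev <- vapply(c(h, -h, 2 * h, -2 * h), function(dd) {
      xd <- x; xd[i, j] <- xd[i, j] + dd; e_at(xd)
    }, numeric(1))
    g[i, j] <- -(8 * (ev[1] - ev[2]) - (ev[3] - ev[4])) / (12 * h)
  }
  g
}

expand_about_centroid <- function(xyz, factor) {
  ctr <- colMeans(xyz)
  sweep(sweep(xyz, 2, ctr) * factor, 2, ctr, "+")
}
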