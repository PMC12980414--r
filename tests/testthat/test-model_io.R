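# Structure I/O, chain extraction, topology construction, shadow contacts.

test_that("PDB writing and reading round-trips coordinates at PDB precision", {
  s <- makeToyChain(5, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_equal(nAtoms(s2), nAtoms(s))
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)  # PDB %.3f precision
  expect_equal(s2@atoms$resid, s@atoms$resid)
})

test_that("hand-written two-atom PDB is parsed verbatim", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "END"), f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 2)
  expect_equal(coords(s), matrix(1:6, 2, 3, byrow = TRUE))
  expect_error(readStructure(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("chain extraction halves a symmetric dimer, is idempotent, and merging restores it", {
  mono <- fix_two_domain()$s
  dimer <- makeDimer(mono, contact_offset = 3, seed = 2)
  expect_setequal(chains(dimer), c("A", "B"))
  a <- extractChain(dimer, "A")
  expect_equal(nAtoms(a), nAtoms(dimer) / 2)
  expect_equal(extractChain(a, "A"), a)
  expect_equal(coords(a), coords(mono))
  b <- extractChain(dimer, "B")
  back <- mergeStructures(a, b)
  expect_setequal(back@atoms$serial, dimer@atoms$serial)
  expect_equal(coords(back), coords(dimer))
  expect_error(extractChain(mono, "Z"), "available")
})

test_that("a 4-atom linear chain yields path-graph combinatorics", {
  s <- MolecularStructure(data.frame(
    serial = 1:4, name = "CA", element = "C", resid = 1:4, resname = "GLY",
    chain = "A",
    x = c(0, 1.4, 2.6, 4.0), y = c(0, 0.4, -0.3, 0.2), z = 0))
  topo <- buildTopology(s, contact_cutoff = 0.1)
  expect_equal(nrow(topo@bonds), 3)
  expect_equal(nrow(topo@angles), 2)
  expect_equal(nrow(topo@properDihedrals), 1)
  expect_equal(nrow(topo@planarDihedrals), 0)
})

test_that("native topology values reproduce independent geometric measurements", {
  fx <- fix_two_domain()
  xyz <- coords(fx$s)
  b <- fx$topo@bonds
  d <- sqrt(rowSums((xyz[b$i, ] - xyz[b$j, ])^2))
  expect_lt(max(abs(d - b$r0)), 1e-6)
  a <- fx$topo@angles
  th <- vapply(seq_len(nrow(a)), function(r) {
    u <- xyz[a$i[r], ] - xyz[a$j[r], ]
    v <- xyz[a$k[r], ] - xyz[a$j[r], ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }, numeric(1))
  expect_lt(max(abs(th - a$theta0)), 1e-6)
  ct <- contacts(fx$topo)
  sg <- sqrt(rowSums((xyz[ct$i, ] - xyz[ct$j, ])^2))
  expect_lt(max(abs(sg - ct$sigma)), 1e-6)
})

test_that("linker residues release their proper dihedrals", {
  fx <- fix_two_domain()
  td <- fx$td
  resid <- fx$s@atoms$resid
  pd <- fx$topo@properDihedrals
  in_linker <- resid[pd$j] %in% td$linker_residues |
    resid[pd$k] %in% td$linker_residues
  expect_true(all(!pd$constrained[in_linker]))
  expect_true(all(pd$constrained[!in_linker]))
  # all residues marked linker -> everything released
  topo_all <- buildTopology(fx$s, linker_residues = unique(resid))
  expect_true(all(!topo_all@properDihedrals$constrained))
})

test_that("topology construction is deterministic", {
  fx <- fix_two_domain()
  t2 <- buildTopology(fx$s, fx$td$linker_residues, fx$td$domain_map)
  expect_identical(as.character(writeTopologyJSON(fx$topo)),
                   as.character(writeTopologyJSON(t2)))
})

test_that("chain breaks are reported with the offending residues", {
  s <- MolecularStructure(data.frame(
    serial = 1:4, name = "CA", element = "C", resid = 1:4, resname = "GLY",
    chain = "A", x = c(0, 1.4, 6.0, 7.4), y = 0, z = 0))
  expect_error(buildTopology(s), "chain break between residues 2 and 3")
})

test_that("occlusion removes shadowed pairs: collinear triple has no outer contact", {
  s <- MolecularStructure(data.frame(
    serial = 1:3, name = "CA", element = "C", resid = c(1, 5, 9),
    resname = "GLY", chain = "A", x = c(0, 2.5, 5), y = 0, z = 0))
  ct <- shadowContacts(s, cutoff = 6, shadow_radius = 1, min_res_sep = 3)
  # 0-5 A pair is occluded by the middle atom; the 2.5 A pairs survive
  expect_false(any(ct$i == 1 & ct$j == 3))
  expect_true(all(ct$sigma <= 2.5 + 1e-9))
})

test_that("inter-domain pairs are excluded from contacts", {
  fx <- fix_two_domain()
  resid <- fx$s@atoms$resid
  ct <- contacts(fx$topo)
  dm <- fx$td$domain_map
  d_of <- function(idx) {
    r <- resid[idx]
    ifelse(r %in% dm$d1, 1L, ifelse(r %in% dm$d2, 2L, 0L))
  }
  di <- d_of(ct$i); dj <- d_of(ct$j)
  expect_false(any(di != 0 & dj != 0 & di != dj))
  # one domain per residue: every eligible pair is trans-domain -> 0 contacts
  per_res <- as.list(seq_len(max(resid)))
  ct2 <- shadowContacts(fx$s, domain_map = per_res,
                        excluded = fx$topo@exclusions)
  expect_equal(nrow(ct2), 0)
})

test_that("shadow contacts agree with a brute-force O(N^3) oracle on random clouds", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 30
    xyz <- matrix(stats::runif(3 * n, 0, 12), n, 3)
    resid <- seq_len(n)
    dom <- integer(n)
    s <- MolecularStructure(data.frame(
      serial = seq_len(n), name = "CA", element = "C", resid = resid,
      resname = "GLY", chain = "A", x = xyz[, 1], y = xyz[, 2],
      z = xyz[, 3]))
    got <- shadowContacts(s, cutoff = 6, shadow_radius = 1, min_res_sep = 3)
    want <- shadow_oracle(xyz, resid, dom, matrix(integer(0), 0, 2),
                         6, 1, 3)
    got_keys <- paste(got$i, got$j)
    want_keys <- if (is.null(want)) character(0) else
      paste(want[, 1], want[, 2])
    expect_setequal(got_keys, want_keys)
  }
})
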