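# Internal-distance features, projection, chi-square annotation, selection.

test_that("internal-distance features are rigid-motion invariant and seeded", {
  set.seed(4)
  f1 <- matrix(stats::rnorm(30), 10, 3)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  f2 <- f1 %*% R + matrix(c(3, 4, 5), 10, 3, byrow = TRUE)
  ft <- internalDistanceFeatures(list(f1, f2), pair_sample = 20, seed = 9)
  expect_lt(max(abs(ft[1, ] - ft[2, ])), 1e-9)
  # 3-atom frame, all pairs -> length 3
  tri <- matrix(stats::rnorm(9), 3, 3)
  expect_equal(ncol(internalDistanceFeatures(list(tri, tri))), 3)
  # same seed -> same pair subsample
  big <- replicate(3, matrix(stats::rnorm(150), 50, 3), simplify = FALSE)
  a <- internalDistanceFeatures(big, pair_sample = 40, seed = 2)
  b <- internalDistanceFeatures(big, pair_sample = 40, seed = 2)
  expect_identical(a, b)
  expect_error(internalDistanceFeatures(list(f1, tri)), "inconsistent")
})

test_that("dissimilarities equal the brute-force double loop and respect permutation", {
  set.seed(8)
  feats <- matrix(stats::rnorm(10 * 6), 10, 6)
  dm <- dissimilarityMatrix(feats)
  M <- dissimilarityAsMatrix(dm)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(M[i, j], sqrt(sum((feats[i, ] - feats[j, ])^2) / 6),
                 tolerance = 1e-12)
  expect_equal(diag(M), rep(0, 10))
  perm <- sample(10)
  Mp <- dissimilarityAsMatrix(dissimilarityMatrix(feats[perm, ]))
  expect_equal(Mp, M[perm, perm], tolerance = 1e-12)
  expect_equal(dissimilarityAsMatrix(
    dissimilarityMatrix(feats[c(1, 1), ]))[1, 2], 0)
})

test_that("projection embeds symmetric and planar-Euclidean data faithfully", {
  # three mutually equidistant frames -> equilateral triangle
  eq <- new("DissimilarityMatrix", values = rep(2, 3), nFrames = 3L)
  pr <- project2D(eq, seed = 1)
  d <- as.numeric(stats::dist(pr@coords))
  expect_lt(diff(range(d)) / mean(d), 0.01)
  # planted planar geometry recovered with tiny stress
  set.seed(3)
  pts <- matrix(stats::rnorm(2 * 40, sd = 3), 40, 2)
  dm <- new("DissimilarityMatrix", values = as.numeric(stats::dist(pts)),
            nFrames = 40L)
  pr2 <- project2D(dm, seed = 5)
  expect_lt(pr2@stress, 1e-3)
  D0 <- as.matrix(stats::dist(pts))
  D1 <- as.matrix(stats::dist(pr2@coords))
  off <- upper.tri(D0)
  expect_lt(max(abs(D1[off] - D0[off]) / D0[off]), 0.01)
  # duplicates stay coincident
  pts3 <- rbind(pts[1:5, ], pts[1, ])
  dm3 <- new("DissimilarityMatrix", values = as.numeric(stats::dist(pts3)),
             nFrames = 6L)
  pr3 <- project2D(dm3, seed = 2)
  expect_lt(sqrt(sum((pr3@coords[1, ] - pr3@coords[6, ])^2)), 1e-6)
})

test_that("projection stress is non-increasing and seed-reproducible", {
  set.seed(10)
  feats <- matrix(stats::rnorm(30 * 8), 30, 8)
  dm <- dissimilarityMatrix(feats)
  p1 <- project2D(dm, seed = 4)
  p2 <- project2D(dm, seed = 4)
  expect_identical(p1@coords, p2@coords)
  expect_true(all(diff(p1@stressTrace) <= 1e-12))
})

test_that("chi-square annotation aligns with frames and separates planted clusters", {
  s <- fix_two_domain()$s
  th <- debyeProfile(s)
  exact_exp <- ScatteringCurve(th@q, th@I, sigma = rep(mean(th@I) * 0.01,
                                                       length(th@q)))
  c0 <- annotateChi2(list(coords(s), coords(s)), exact_exp,
                     elements = s@atoms$element)
  expect_equal(c0, c(0, 0), tolerance = 1e-16)
  pe <- plantedEnsemble(s, n_frames = 60, seed = 3)
  e <- synthSAXS(s, seed = 3)
  c2 <- annotateChi2(pe$frames, e, elements = s@atoms$element)
  expect_length(c2, 60)
  expect_lt(stats::median(c2[pe$labels == 1]),
            stats::median(c2[pe$labels == 2]))
  # order contract: permuting frames permutes the output
  ord <- rev(seq_len(60))
  expect_equal(annotateChi2(pe$frames[ord], e,
                            elements = s@atoms$element), c2[ord])
})

test_that("band + density selection obeys its contracts on constructed inputs", {
  set.seed(6)
  # single tight cluster, all in band
  n <- 40
  xy <- matrix(stats::rnorm(2 * n, sd = 0.2), n, 2)
  proj <- new("Projection2D", coords = xy, stress = 0,
              stressTrace = 0, seed = 1L, converged = TRUE)
  chi2 <- stats::runif(n, 0.92, 1.08)
  sel <- selectEnsemble(proj, chi2, k = 5)
  expect_equal(sort(sel@members), 1:n)
  expect_lt(sqrt(sum((sel@densityPeak - colMeans(xy))^2)), 0.5)
  expect_length(sel@representatives, 5)
  # band filter is inclusive and excludes out-of-band frames
  chi2b <- chi2
  chi2b[1:10] <- 5
  selb <- selectEnsemble(proj, chi2b, k = 3)
  expect_false(any(1:10 %in% selb@members))
  # empty band errors with advice
  expect_error(selectEnsemble(proj, rep(3, n)), "widen")
  # k larger than cluster: whole cluster with warning
  expect_warning(sel_all <- selectEnsemble(proj, chi2, k = n + 5),
                 "exceeds cluster size")
  expect_setequal(sel_all@representatives, sel_all@clusterMembers)
})

test_that("planted 80/20 mixture puts the peak and all representatives in the majority mode", {
  wins <- vapply(1:20, function(sd) {
    set.seed(sd)
    na <- 48; nb <- 12
    a <- matrix(stats::rnorm(2 * na, mean = 0, sd = 0.4), na, 2)
    b <- matrix(stats::rnorm(2 * nb, mean = 6, sd = 0.4), nb, 2)
    proj <- new("Projection2D", coords = rbind(a, b), stress = 0,
                stressTrace = 0, seed = 1L, converged = TRUE)
    chi2 <- stats::runif(na + nb, 0.9, 1.1)
    sel <- selectEnsemble(proj, chi2, k = 5)
    all(sel@representatives <= na)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("band filtering commutes with frame order permutation", {
  set.seed(12)
  n <- 50
  xy <- matrix(stats::rnorm(2 * n), n, 2)
  chi2 <- stats::runif(n, 0.7, 1.3)
  proj <- new("Projection2D", coords = xy, stress = 0, stressTrace = 0,
              seed = 1L, converged = TRUE)
  sel <- selectEnsemble(proj, chi2, k = 3)
  perm <- sample(n)
  proj_p <- new("Projection2D", coords = xy[perm, ], stress = 0,
                stressTrace = 0, seed = 1L, converged = TRUE)
  sel_p <- selectEnsemble(proj_p, chi2[perm], k = 3)
  expect_setequal(perm[sel_p@members], sel@members)
})
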