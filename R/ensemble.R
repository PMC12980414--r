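#' Internal-distance feature vectors of trajectory frames
#'
#' Maps each conformation to a vector of intramolecular pairwise distances
#' over a seeded subsample of atom pairs (all pairs when few), which makes
#' the representation rotation/translation invariant.
#'
#' @param frames list of N x 3 coordinate matrices or a
#'   [Trajectory-class].
#' @param pair_sample number of atom pairs to sample (all pairs if the total
#'   is smaller).
#' @param seed seed controlling the pair subsample.
#' @return n_frames x n_pairs matrix of distances.
#' @export
internalDistanceFeatures <- function(frames, pair_sample = 500, seed = 1) {
  if (is(frames, "Trajectory")) frames <- frames@frames
  stopifnot(length(frames) >= 2)
  n <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, integer(1)) == n))
    stop("frames have inconsistent atom counts")
  all_pairs <- utils::combn(n, 2)
  np <- ncol(all_pairs)
  if (np > pair_sample) {
    set.seed(seed)
    all_pairs <- all_pairs[, sort(sample.int(np, pair_sample)), drop = FALSE]
  }
  i <- all_pairs[1, ]; j <- all_pairs[2, ]
  t(vapply(frames, function(f)
    sqrt(rowSums((f[i, , drop = FALSE] - f[j, , drop = FALSE])^2)),
    numeric(length(i))))
}

#' Pairwise dissimilarity between feature vectors
#'
#' Euclidean distance between internal-distance feature vectors, normalized
#' by the square root of the vector length (so values are per-pair RMS
#' differences in Angstrom). The triangle inequality holds for this metric
#' but is not assumed downstream.
#'
#' @param features matrix from [internalDistanceFeatures()].
#' @return A [DissimilarityMatrix-class].
#' @export
dissimilarityMatrix <- function(features) {
  d <- stats::dist(features) / sqrt(ncol(features))
  new("DissimilarityMatrix", values = as.numeric(d),
      nFrames = as.integer(nrow(features)))
}

#' @export
#' @describeIn dissimilarityMatrix Full symmetric matrix form.
#' @param x a [DissimilarityMatrix-class].
dissimilarityAsMatrix <- function(x) {
  n <- x@nFrames
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- x@values
  m + t(m)
}

#' Planar projection of conformations by stress majorization
#'
#' Metric MDS of the inter-conformation dissimilarities into the plane:
#' initialized from classical scaling (plus a small seeded jitter to break
#' ties), then refined by SMACOF majorization, which guarantees a
#' non-increasing stress sequence. Stress is reported in normalized form
#' `sqrt(sum (d - delta)^2 / sum delta^2)`.
#'
#' @param d a [DissimilarityMatrix-class].
#' @param seed seed for the initialization jitter.
#' @param max_iter iteration cap.
#' @param tol relative stress-change convergence threshold.
#' @return A [Projection2D-class].
#' @export
project2D <- function(d, seed = 1, max_iter = 300, tol = 1e-5) {
  n <- d@nFrames
  stopifnot(n >= 3)
  Delta <- dissimilarityAsMatrix(d)
  set.seed(seed)
  X <- tryCatch(stats::cmdscale(Delta, k = 2), error = function(e) NULL)
  if (is.null(X) || ncol(X) < 2 || anyNA(X))
    X <- matrix(stats::rnorm(2 * n), n, 2)
  X <- X + matrix(stats::rnorm(2 * n, sd = 1e-8 * (max(Delta) + 1)), n, 2)
  res <- cpp_smacof(Delta, X, as.integer(max_iter), tol)
  if (!res$converged)
    warning("projection did not converge in ", max_iter,
            " iterations; returning best-so-far")
  new("Projection2D", coords = res$X, stress = res$stress,
      stressTrace = res$trace, seed = as.integer(seed),
      converged = res$converged)
}

setMethod("show", "Projection2D", function(object) {
  cat(sprintf("Projection2D: %d points, normalized stress %.3g%s\n",
              nrow(object@coords), object@stress,
              if (!object@converged) " (not converged)" else ""))
})

#' Per-frame chi-square against an experimental curve
#'
#' Computes a Debye profile for every frame and its scale-optimized
#' chi-square against the experimental curve; output order matches frame
#' order.
#'
#' @param frames list of coordinate matrices, a [Trajectory-class], or a
#'   list of [MolecularStructure-class] objects.
#' @param exp experimental [ScatteringCurve-class] with sigma.
#' @param elements element vector for the form factors (default all carbon
#'   when frames are bare matrices).
#' @param form_factor as in [debyeProfile()].
#' @param q_window optional chi-square window.
#' @param bin_width when non-NULL, accelerate the per-frame Debye sums with
#'   a pair-distance histogram at this bin width (Angstrom); relative error
#'   is of order `(q bin_width)^2`, far below typical noise at 0.02 A. NULL
#'   (default) computes the exact pair sum.
#' @return Numeric vector of chi-square values, one per frame.
#' @export
annotateChi2 <- function(frames, exp, elements = NULL,
                         form_factor = "constant", q_window = NULL,
                         bin_width = NULL) {
  if (is(frames, "Trajectory")) frames <- frames@frames
  qg <- exp@q
  # batched fast path: bare matrices, histogram Debye, full q range
  if (!is.null(bin_width) && is.null(q_window) &&
      length(exp@sigma) == length(qg) &&
      all(vapply(frames, is.matrix, logical(1)))) {
    if (any(exp@sigma == 0)) stop("zero sigma in experimental curve")
    el <- if (is.null(elements)) rep("C", nrow(frames[[1]])) else elements
    f0 <- .form_factors(el, 0, form_factor)[, 1]
    return(cpp_chi2_frames(frames, f0, qg, exp@I, exp@sigma, bin_width))
  }
  vapply(frames, function(f) {
    if (is(f, "MolecularStructure")) {
      el <- f@atoms$element
      f <- coords(f)
    } else {
      el <- if (is.null(elements)) rep("C", nrow(f)) else elements
    }
    th <- if (!is.null(bin_width)) {
      f0 <- .form_factors(el, 0, form_factor)[, 1]
      ScatteringCurve(qg, cpp_debye_hist(f, f0, qg, bin_width))
    } else {
      fq <- .form_factors(el, qg, form_factor)
      ScatteringCurve(qg, cpp_debye(f, fq, qg))
    }
    chiSquare(exp, th, q_window = q_window)@chi2
  }, numeric(1))
}

# Gaussian KDE with Scott's-rule bandwidth, evaluated at arbitrary points
.kde2d_at <- function(pts, at, bandwidth = NULL) {
  n <- nrow(pts)
  if (is.null(bandwidth)) {
    # Scott's rule per dimension
    bandwidth <- apply(pts, 2, stats::sd) * n^(-1 / 6)
    bandwidth[bandwidth <= 0 | !is.finite(bandwidth)] <-
      max(bandwidth[is.finite(bandwidth) & bandwidth > 0], 1e-6)
  }
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  u <- outer(at[, 1], pts[, 1], "-") / bandwidth[1]
  v <- outer(at[, 2], pts[, 2], "-") / bandwidth[2]
  rowSums(exp(-0.5 * (u^2 + v^2))) /
    (n * 2 * pi * bandwidth[1] * bandwidth[2])
}

#' Select the representative ensemble by the chi-square band + density rule
#'
#' Frames with chi-square inside the inclusive band are kept; a Gaussian
#' kernel density (Scott's-rule bandwidth by default) over their projection
#' coordinates locates the global density peak; the cluster is the connected
#' grid region above `level` (default 50%) of the peak density; and the `k`
#' members nearest the peak (ties broken by lower chi-square, then lower
#' frame index) are returned as representatives. All local density maxima
#' found on the grid are reported as well.
#'
#' @param proj a [Projection2D-class].
#' @param chi2 per-frame chi-square aligned with the projection.
#' @param band inclusive (lo, hi) chi-square filter (default 0.9-1.1).
#' @param bandwidth KDE bandwidth (scalar or per-axis); `NULL` for Scott's
#'   rule.
#' @param k number of representatives (default 5).
#' @param level cluster contour as a fraction of the peak density.
#' @param grid_n KDE grid resolution per axis.
#' @return An [EnsembleSelection-class].
#' @export
selectEnsemble <- function(proj, chi2, band = c(0.9, 1.1), bandwidth = NULL,
                           k = 5, level = 0.5, grid_n = 64) {
  stopifnot(nrow(proj@coords) == length(chi2))
  members <- which(chi2 >= band[1] & chi2 <= band[2])
  if (length(members) == 0)
    stop("no frames with chi-square inside [", band[1], ", ", band[2],
         "]; widen the band")
  pts <- proj@coords[members, , drop = FALSE]
  if (length(members) < 3) {
    dens <- rep(1, length(members))
    peak <- colMeans(pts)
    cluster <- members
    peaks <- data.frame(x = peak[1], y = peak[2],
                        density = 1)
  } else {
    gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = grid_n)
    gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = grid_n)
    if (gx[1] == gx[grid_n]) gx <- gx[1] + seq(-1, 1, length.out = grid_n) * 1e-6
    if (gy[1] == gy[grid_n]) gy <- gy[1] + seq(-1, 1, length.out = grid_n) * 1e-6
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    gd <- matrix(.kde2d_at(pts, grid, bandwidth), grid_n, grid_n)
    pk <- which(gd == max(gd), arr.ind = TRUE)[1, ]
    peak <- c(gx[pk[1]], gy[pk[2]])
    # connected region above level * peak density (4-neighbour flood fill)
    above <- gd >= level * max(gd)
    lab <- matrix(FALSE, grid_n, grid_n)
    stack <- list(pk)
    lab[pk[1], pk[2]] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- cur[1] + dd[1]; nj <- cur[2] + dd[2]
        if (ni >= 1 && ni <= grid_n && nj >= 1 && nj <= grid_n &&
            above[ni, nj] && !lab[ni, nj]) {
          lab[ni, nj] <- TRUE
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
    ix <- pmin(pmax(findInterval(pts[, 1], gx, all.inside = TRUE), 1),
               grid_n - 1)
    iy <- pmin(pmax(findInterval(pts[, 2], gy, all.inside = TRUE), 1),
               grid_n - 1)
    nearest_i <- ifelse(abs(pts[, 1] - gx[ix]) <= abs(pts[, 1] - gx[ix + 1]),
                        ix, ix + 1)
    nearest_j <- ifelse(abs(pts[, 2] - gy[iy]) <= abs(pts[, 2] - gy[iy + 1]),
                        iy, iy + 1)
    inside <- lab[cbind(nearest_i, nearest_j)]
    cluster <- members[inside]
    if (length(cluster) == 0) cluster <- members
    dens <- .kde2d_at(pts, pts, bandwidth)
    # all local maxima on the grid (8-neighbourhood)
    loc <- list()
    for (i in 2:(grid_n - 1))
      for (j in 2:(grid_n - 1))
        if (gd[i, j] == max(gd[(i - 1):(i + 1), (j - 1):(j + 1)]) &&
            gd[i, j] > 0.05 * max(gd))
          loc[[length(loc) + 1]] <- c(gx[i], gy[j], gd[i, j])
    peaks <- if (length(loc)) {
      m <- do.call(rbind, loc)
      data.frame(x = m[, 1], y = m[, 2], density = m[, 3])
    } else data.frame(x = peak[1], y = peak[2], density = max(gd))
  }
  note <- ""
  cand <- cluster
  dpk <- sqrt(rowSums(sweep(proj@coords[cand, , drop = FALSE], 2, peak)^2))
  ord <- order(dpk, chi2[cand], cand)
  if (k > length(cand)) {
    note <- sprintf("k = %d exceeds cluster size %d; returning whole cluster",
                    k, length(cand))
    warning(note)
    reps <- cand[ord]
  } else {
    reps <- cand[ord][seq_len(k)]
  }
  dens_all <- rep(NA_real_, length(chi2))
  dens_all[members] <- dens
  new("EnsembleSelection", band = as.numeric(band),
      members = as.integer(members), clusterMembers = as.integer(cluster),
      densityPeak = as.numeric(peak), representatives = as.integer(reps),
      chi2 = as.numeric(chi2), density = dens_all, peaks = peaks,
      note = note)
}

#' @describeIn representatives Representative frame indices of a selection.
#' @param x object.
#' @export
setMethod("representatives", "EnsembleSelection",
          function(x) x@representatives)

setMethod("show", "EnsembleSelection", function(object) {
  cat(sprintf(
    "EnsembleSelection: %d/%d frames in chi2 band [%.3g, %.3g]\n",
    length(object@members), length(object@chi2), object@band[1],
    object@band[2]))
  cat(sprintf("  density peak at (%.3g, %.3g); cluster %d; representatives: %s\n",
              object@densityPeak[1], object@densityPeak[2],
              length(object@clusterMembers),
              paste(object@representatives, collapse = " ")))
})

#' Write an ensemble selection as CSV plus a JSON report
#'
#' @param sel an [EnsembleSelection-class].
#' @param proj the matching [Projection2D-class].
#' @param prefix output prefix (`<prefix>_frames.csv`,
#'   `<prefix>_selection.json`).
#' @return Invisibly, the two paths.
#' @export
writeSelection <- function(sel, proj, prefix) {
  csv <- paste0(prefix, "_frames.csv")
  js <- paste0(prefix, "_selection.json")
  df <- data.frame(frame = seq_along(sel@chi2), x = proj@coords[, 1],
                   y = proj@coords[, 2], chi2 = sel@chi2,
                   density = sel@density,
                   member = seq_along(sel@chi2) %in% sel@members,
                   representative = seq_along(sel@chi2) %in%
                     sel@representatives)
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(band = sel@band, n_members = length(sel@members),
         density_peak = sel@densityPeak,
         representatives = sel@representatives,
         cluster_size = length(sel@clusterMembers),
         peaks = sel@peaks, note = sel@note,
         projection_stress = proj@stress),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
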