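#' Construct a MolecularStructure from an atom table
#'
#' @param atoms data.frame with columns serial, name, element, resid,
#'   resname, chain, x, y, z.
#' @param title free-text title.
#' @return A [MolecularStructure-class].
#' @export
MolecularStructure <- function(atoms, title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  new("MolecularStructure", atoms = atoms, title = as.character(title)[1])
}

.guess_element <- function(name) {
  e <- sub("^[0-9 ]*", "", name)
  e <- substr(e, 1, 1)
  ifelse(e %in% c("C", "N", "O", "S", "P", "H"), e, "C")
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d. By default hydrogens are stripped
#' (the structure-based model operates on heavy atoms), waters and ligand
#' HETATM records are dropped, and only the first alternate location is kept.
#'
#' @param path PDB file.
#' @param model which MODEL to return (default 1).
#' @param keep_hydrogens keep hydrogen atoms.
#' @param keep_hetatm keep non-water HETATM records.
#' @return A [MolecularStructure-class].
#' @export
readStructure <- function(path, model = 1, keep_hydrogens = FALSE,
                          keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (nrow(a) == 0) stop("no ATOM/HETATM records in ", path)
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) >= model) {
    m <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
    a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
  } else if (model != 1) {
    stop("model ", model, " not present in ", path)
  }
  keep <- rep(TRUE, nrow(a))
  if (!keep_hetatm) keep <- keep & (a$type == "ATOM")
  keep <- keep & !(a$resid %in% c("HOH", "WAT"))
  if (!keep_hydrogens) {
    elt <- a$elesy
    elt[is.na(elt) | elt == ""] <- .guess_element(a$elety[is.na(elt) | elt == ""])
    keep <- keep & toupper(trimws(elt)) != "H"
  }
  keep <- keep & (is.na(a$alt) | a$alt %in% c("", "A"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms left after filtering in ", path)
  elt <- toupper(trimws(a$elesy))
  bad <- is.na(elt) | elt == ""
  elt[bad] <- .guess_element(a$elety[bad])
  ch <- a$chain
  ch[is.na(ch) | ch == ""] <- "A"
  MolecularStructure(
    data.frame(serial = seq_len(nrow(a)), name = a$elety, element = elt,
               resid = a$resno, resname = a$resid, chain = ch,
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE),
    title = basename(path))
}

.format_atom_record <- function(a) {
  nm <- substr(a$name, 1, 4)
  nm <- ifelse(nchar(nm) < 4, formatC(paste0(" ", nm), width = -4), nm)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          a$serial %% 100000, nm, substr(a$resname, 1, 3),
          substr(a$chain, 1, 1), a$resid %% 10000, a$x, a$y, a$z, a$element)
}

#' Write one or more structures to a PDB file
#'
#' A list of structures (or a [Trajectory-class]) is written as a
#' multi-model PDB with MODEL/ENDMDL records.
#'
#' @param x a [MolecularStructure-class], a list of them, or a
#'   [Trajectory-class] (frames take atom metadata from `template`).
#' @param path output file.
#' @param template structure providing atom metadata for trajectory frames.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path, template = NULL) {
  if (is(x, "Trajectory")) {
    stopifnot(!is.null(template))
    x <- lapply(x@frames, function(f) setCoords(template, f))
  }
  if (is(x, "MolecularStructure")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(x) > 0 && nzchar(x[[1]]@title))
    writeLines(sprintf("TITLE     %s", x[[1]]@title), con)
  multi <- length(x) > 1
  for (m in seq_along(x)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- x[[m]]@atoms
    writeLines(.format_atom_record(a), con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @describeIn coords Coordinates of a structure as an N x 3 matrix.
#' @param x object.
#' @param ... unused.
#' @export
setMethod("coords", "MolecularStructure", function(x, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' Replace the coordinates of a structure
#'
#' @param s a [MolecularStructure-class].
#' @param xyz N x 3 matrix.
#' @return The structure with new coordinates.
#' @export
setCoords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s@atoms))
  s@atoms$x <- xyz[, 1]; s@atoms$y <- xyz[, 2]; s@atoms$z <- xyz[, 3]
  s
}

#' @describeIn nAtoms Number of atoms in a structure.
#' @param x object.
#' @export
setMethod("nAtoms", "MolecularStructure", function(x) nrow(x@atoms))

#' @describeIn chains Chain identifiers present in a structure.
#' @param x object.
#' @export
setMethod("chains", "MolecularStructure",
          function(x) unique(x@atoms$chain))

#' @describeIn extractChain Subset a structure to one chain; coordinates are
#'   unchanged and the operation is idempotent.
#' @param x object.
#' @param chain chain identifier.
#' @export
setMethod("extractChain", "MolecularStructure", function(x, chain) {
  av <- unique(x@atoms$chain)
  if (!chain %in% av)
    stop("chain '", chain, "' not present; available: ",
         paste(av, collapse = ", "))
  MolecularStructure(x@atoms[x@atoms$chain == chain, , drop = FALSE],
                     title = x@title)
})

#' Merge structures into one (e.g., re-assemble extracted chains)
#'
#' @param ... [MolecularStructure-class] objects.
#' @return The combined structure, atoms ordered by serial.
#' @export
mergeStructures <- function(...) {
  parts <- list(...)
  a <- do.call(rbind, lapply(parts, function(p) p@atoms))
  a <- a[order(a$serial), , drop = FALSE]
  MolecularStructure(a, title = parts[[1]]@title)
}

#' Radius of gyration of a coordinate set
#'
#' @param x matrix of coordinates or a [MolecularStructure-class].
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(x) {
  if (is(x, "MolecularStructure")) x <- coords(x)
  c <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, c)^2)))
}

setMethod("show", "MolecularStructure", function(object) {
  cat("MolecularStructure:", object@title, "\n")
  cat(" ", nrow(object@atoms), "atoms,",
      length(unique(paste(object@atoms$chain, object@atoms$resid))),
      "residues, chains:", paste(unique(object@atoms$chain), collapse = " "),
      "\n")
})
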