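#' Molecular geometry container
#'
#' Atoms with element symbols, per-atom masses (Da), Cartesian coordinates
#' (\enc{Å}{Angstrom}) and chain/residue labels, plus an ordered list of
#' amide units (one atom group per peptide bond) used by the fragmentation
#' machinery.
#'
#' @param elements character vector of element symbols.
#' @param xyz numeric N x 3 matrix of coordinates in \enc{Å}{Angstrom}.
#' @param masses per-atom masses in Da; defaults to monoisotopic masses
#'   looked up by element.
#' @param labels data.frame with columns \code{chain}, \code{resno}
#'   (0-based residue index), \code{resid} (residue code), \code{atom}
#'   (atom name); one row per atom. Optional.
#' @param amide_units list, one entry per peptide bond in chain order; each
#'   entry a list with \code{atoms} (1-based atom indices of the amide
#'   group), \code{chain}, and \code{resno} (0-based index of the residue
#'   donating the carbonyl). Optional.
#' @param check if TRUE, enforce the minimum interatomic distance of 0.5
#'   \enc{Å}{Angstrom}.
#' @return object of class \code{geometry}.
#' @export
geometry <- function(elements, xyz, masses = NULL, labels = NULL,
                     amide_units = list(), check = TRUE) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(elements)
  stopifnot(nrow(xyz) == n, ncol(xyz) == 3)
  if (is.null(masses)) {
    unknown <- setdiff(unique(elements), names(.monoisotopic))
    if (length(unknown))
      stop("no mass tabulated for element(s): ", paste(unknown, collapse = ", "))
    masses <- unname(.monoisotopic[elements])
  }
  stopifnot(length(masses) == n)
  if (!is.null(labels)) {
    stopifnot(is.data.frame(labels), nrow(labels) == n,
              all(c("chain", "resno", "resid", "atom") %in% names(labels)))
  }
  g <- structure(
    list(elements = as.character(elements), masses = as.numeric(masses),
         xyz = xyz, labels = labels, amide_units = amide_units),
    class = "geometry")
  if (check && n > 1) {
    dmin <- min_pair_distance(g)
    if (dmin < 0.5)
      stop(sprintf("steric clash: minimum interatomic distance %.3f A < 0.5 A",
                   dmin))
  }
  g
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %d atoms", n_atoms(x)))
  if (!is.null(x$labels))
    cat(sprintf(", %d chain(s), %d residues",
                length(unique(x$labels$chain)),
                nrow(unique(x$labels[, c("chain", "resno")]))))
  if (length(x$amide_units))
    cat(sprintf(", %d amide units", length(x$amide_units)))
  cat("\n")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param g a [geometry()].
#' @export
n_atoms <- function(g) length(g$elements)

#' Minimum interatomic distance
#' @param g a [geometry()].
#' @return smallest pairwise distance in \enc{Å}{Angstrom}.
#' @export
min_pair_distance <- function(g) {
  min(stats::dist(g$xyz))
}

#' Center of mass
#' @param g a [geometry()].
#' @return length-3 numeric vector.
#' @export
center_of_mass <- function(g) {
  colSums(g$xyz * g$masses) / sum(g$masses)
}

#' Apply a rigid (or improper) transformation to a geometry
#'
#' @param g a [geometry()].
#' @param R 3 x 3 orthogonal matrix (may be improper).
#' @param t length-3 translation, applied after rotation.
#' @return transformed [geometry()].
#' @export
transform_geometry <- function(g, R = diag(3), t = c(0, 0, 0)) {
  g$xyz <- g$xyz %*% t(R) + matrix(t, n_atoms(g), 3, byrow = TRUE)
  g
}

## ---- XYZ I/O (single and multi-frame, standard element-x-y-z layout) ----

#' Write geometries to an XYZ file
#'
#' Writes standard XYZ: atom count, comment line, then one
#' \code{element x y z} row per atom. A list of geometries is written as a
#' concatenated multi-frame trajectory file.
#'
#' @param g a [geometry()] or a list of them.
#' @param file output path.
#' @param comment comment line(s), recycled over frames.
#' @param digits coordinate decimals (default 6, preserving 1e-4
#'   \enc{Å}{Angstrom} round trips).
#' @export
write_xyz <- function(g, file, comment = "", digits = 6) {
  frames <- if (inherits(g, "geometry")) list(g) else g
  comment <- rep_len(comment, length(frames))
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(c(as.character(n_atoms(fr)), comment[k]), con)
    fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df", digits + 6, digits,
                   digits + 6, digits, digits + 6, digits)
    writeLines(sprintf(fmt, fr$elements, fr$xyz[, 1], fr$xyz[, 2],
                       fr$xyz[, 3]), con)
  }
  invisible(file)
}

#' Read an XYZ file
#'
#' @param file path to a single- or multi-frame XYZ file.
#' @param multi if TRUE always return a list of frames; otherwise a single
#'   frame is unwrapped.
#' @return a [geometry()] (labels absent) or a list of them.
#' @export
read_xyz <- function(file, multi = FALSE) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- geometry(el, xyz, check = FALSE)
    i <- i + 2L + n
  }
  if (!multi && length(frames) == 1L) frames[[1L]] else frames
}

## ---- PDB I/O (delegated to bio3d) ----

#' Write a labeled geometry to PDB
#'
#' Uses standard residue names (PRO/HYP/GLY/ALA) and chain identifiers from
#' the geometry labels; residue numbering converts from the internal 0-based
#' convention to 1-based PDB numbering. A list of geometries is written as a
#' multi-model PDB.
#'
#' @param g labeled [geometry()] or list of them (identical labels assumed).
#' @param file output path.
#' @export
write_pdb_geometry <- function(g, file) {
  frames <- if (inherits(g, "geometry")) list(g) else g
  g1 <- frames[[1L]]
  if (is.null(g1$labels)) stop("geometry has no labels; cannot write PDB")
  resid3 <- toupper(g1$labels$resid)
  xyz <- do.call(rbind, lapply(frames, function(fr) as.vector(t(fr$xyz))))
  bio3d::write.pdb(
    file = file,
    xyz = xyz,
    resno = g1$labels$resno + 1L,
    resid = resid3,
    chain = g1$labels$chain,
    elety = g1$labels$atom,
    eleno = seq_len(n_atoms(g1)))
  invisible(file)
}

#' Read a (multi-model) PDB file into labeled geometries
#'
#' @param file path to a PDB file.
#' @param multi if TRUE always return a list of frames.
#' @return labeled [geometry()] or list of them; amide units are detected
#'   from the backbone labels via [detect_amide_units()].
#' @export
read_pdb_geometry <- function(file, multi = FALSE) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || any(!nzchar(el)) || anyNA(el))
    el <- substr(trimws(at$elety), 1, 1)
  labels <- data.frame(chain = at$chain, resno = at$resno - 1L,
                       resid = .pdb_resid_to_code(at$resid),
                       atom = at$elety, stringsAsFactors = FALSE)
  nfr <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nfr), function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    g <- geometry(el, xyz, labels = labels, check = FALSE)
    g$amide_units <- detect_amide_units(g)
    g
  })
  if (!multi && length(frames) == 1L) frames[[1L]] else frames
}

.pdb_resid_to_code <- function(resid) {
  map <- c(PRO = "Pro", HYP = "Hyp", GLY = "Gly", ALA = "Ala")
  out <- map[toupper(trimws(resid))]
  ifelse(is.na(out), trimws(resid), out)
}

#' Detect amide units from backbone labels
#'
#' One amide unit per peptide bond: the carbonyl C and O of residue i plus
#' the N of residue i+1 in the same chain.
#'
#' @param g labeled [geometry()].
#' @return list of amide-unit records (\code{atoms}, \code{chain},
#'   \code{resno}).
#' @export
detect_amide_units <- function(g) {
  if (is.null(g$labels)) stop("geometry has no labels")
  lb <- g$labels
  units <- list()
  for (ch in unique(lb$chain)) {
    resnos <- sort(unique(lb$resno[lb$chain == ch]))
    for (r in resnos[-length(resnos)]) {
      iC <- which(lb$chain == ch & lb$resno == r & lb$atom == "C")
      iO <- which(lb$chain == ch & lb$resno == r & lb$atom == "O")
      iN <- which(lb$chain == ch & lb$resno == r + 1L & lb$atom == "N")
      if (length(iC) == 1L && length(iN) == 1L)
        units[[length(units) + 1L]] <-
          list(atoms = c(iC, iO, iN), chain = ch, resno = r)
    }
  }
  units
}
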