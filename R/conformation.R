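## Backbone conformational analysis: torsions, Ramachandran free-energy
## surfaces, and triplet segment-length histograms.

#' Signed dihedral (torsion) angle of four points
#'
#' Standard atan2 construction with the IUPAC sign convention: looking from
#' p2 to p3, a clockwise rotation of the far bond is positive.
#'
#' @param p1,p2,p3,p4 length-3 numeric vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (any(c(sum(b1^2), sum(b2^2), sum(b3^2)) < 1e-12))
    stop("degenerate geometry: coincident consecutive points")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("degenerate geometry: collinear points")
  ang <- atan2(sum(.cross3(n1, n2) * .unit(b2)), sum(n1 * n2)) / .deg2rad
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals of a labeled geometry
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Terminal residues lacking a dihedral get NA (flagged absent, not zero).
#'
#' @param g labeled [geometry()].
#' @return data.frame with columns \code{chain}, \code{resno}, \code{resid},
#'   \code{phi}, \code{psi} (degrees).
#' @export
backbone_dihedrals <- function(g) {
  if (is.null(g$labels)) stop("geometry has no labels")
  lb <- g$labels
  out <- NULL
  for (ch in unique(lb$chain)) {
    resnos <- sort(unique(lb$resno[lb$chain == ch]))
    idx <- function(r, a) which(lb$chain == ch & lb$resno == r & lb$atom == a)
    at <- function(r, a) g$xyz[idx(r, a), ]
    for (r in resnos) {
      phi <- psi <- NA_real_
      if ((r - 1L) %in% resnos)
        phi <- dihedral_angle(at(r - 1L, "C"), at(r, "N"), at(r, "CA"),
                              at(r, "C"))
      if ((r + 1L) %in% resnos)
        psi <- dihedral_angle(at(r, "N"), at(r, "CA"), at(r, "C"),
                              at(r + 1L, "N"))
      out <- rbind(out, data.frame(
        chain = ch, resno = r,
        resid = lb$resid[idx(r, "CA")][1], phi = phi, psi = psi,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Dihedral time series over a trajectory
#'
#' @param trajectory list of labeled [geometry()] frames with identical
#'   labels.
#' @return object of class \code{dihedral_series}: list with \code{phi} and
#'   \code{psi} matrices (snapshots x residues, degrees, NA for absent
#'   terminal dihedrals) and a \code{residues} data.frame.
#' @export
dihedral_series <- function(trajectory) {
  stopifnot(length(trajectory) >= 1)
  tabs <- lapply(trajectory, backbone_dihedrals)
  phi <- t(vapply(tabs, `[[`, numeric(nrow(tabs[[1]])), "phi"))
  psi <- t(vapply(tabs, `[[`, numeric(nrow(tabs[[1]])), "psi"))
  structure(list(phi = phi, psi = psi,
                 residues = tabs[[1]][, c("chain", "resno", "resid")]),
            class = "dihedral_series")
}

#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
.kB_kcal <- 0.0019872041

#' Ramachandran free-energy surface
#'
#' Periodic 2-D histogram of (phi, psi) over the selected residues, turned
#' into a relative free energy G = -kB T log(n_ij / n_max); empty bins get
#' +Inf. The minimum over occupied bins is exactly 0.
#'
#' @param series a [dihedral_series()].
#' @param select logical or integer residue selector over
#'   \code{series$residues} rows (default all); residues whose phi or psi
#'   is absent are dropped.
#' @param bins number of bins per axis over (-180, 180] (default 36, i.e.
#'   10 x 10 degree bins).
#' @param temperature temperature in K.
#' @return object of class \code{fes}: list with \code{edges} (degrees),
#'   \code{counts}, \code{free_energy} (kcal/mol), \code{temperature}.
#' @export
ramachandran_surface <- function(series, select = NULL, bins = 36,
                                 temperature = 300) {
  stopifnot(inherits(series, "dihedral_series"))
  nres <- nrow(series$residues)
  cols <- if (is.null(select)) seq_len(nres) else which(
    if (is.logical(select)) select else seq_len(nres) %in% select)
  if (!length(cols)) stop("empty residue selection")
  phi <- as.vector(series$phi[, cols])
  psi <- as.vector(series$psi[, cols])
  keep <- !is.na(phi) & !is.na(psi)
  phi <- phi[keep]; psi <- psi[keep]
  if (!length(phi)) stop("no complete (phi, psi) pairs in selection")
  edges <- seq(-180, 180, length.out = bins + 1)
  bin_of <- function(x) {
    ## wrap into (-180, 180]; right-closed bins so +180 falls in the last bin
    x <- ((x + 180) %% 360) - 180
    b <- ceiling((x + 180) / (360 / bins))
    pmin(pmax(b, 1L), bins)
  }
  counts <- matrix(0L, bins, bins)
  ij <- cbind(bin_of(phi), bin_of(psi))
  for (k in seq_len(nrow(ij)))
    counts[ij[k, 1], ij[k, 2]] <- counts[ij[k, 1], ij[k, 2]] + 1L
  fe <- matrix(Inf, bins, bins)
  occ <- counts > 0
  fe[occ] <- -.kB_kcal * temperature * log(counts[occ] / max(counts))
  structure(list(edges = edges, counts = counts, free_energy = fe,
                 temperature = temperature), class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  bins <- nrow(x$counts)
  imin <- which(x$free_energy == 0, arr.ind = TRUE)[1, ]
  ctr <- (x$edges[-1] + x$edges[-(bins + 1)]) / 2
  cat(sprintf(
    "Ramachandran free-energy surface: %d x %d bins, %d samples, T = %g K\n",
    bins, bins, sum(x$counts), x$temperature))
  cat(sprintf("  basin (G = 0) at phi = %g, psi = %g degrees\n",
              ctr[imin[1]], ctr[imin[2]]))
  invisible(x)
}

#' Export a free-energy surface as TSV matrix + JSON metadata
#'
#' @param fes a [ramachandran_surface()] result.
#' @param file TSV output path; metadata is written to \code{<file>.json}.
#' @export
write_fes <- function(fes, file) {
  fe <- fes$free_energy
  utils::write.table(fe, file, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(edges_deg = fes$edges, temperature_K = fes$temperature,
         n_samples = sum(fes$counts), units = "kcal/mol",
         empty_bin = "Inf"),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Segment-length histogram for a residue triplet pattern
#'
#' For every occurrence of the triplet pattern (e.g. \code{"Pro-Hyp-Gly"}),
#' measures the distance from the CA of the first matched residue to the CA
#' of the residue three positions downstream, in every snapshot, and bins
#' the pooled lengths.
#'
#' @param trajectory list of labeled [geometry()] frames.
#' @param triplet_spec pattern like \code{"Pro-Hyp-Gly"}.
#' @param breaks passed to [hist()]; default \code{"FD"}.
#' @return list with \code{lengths} (\enc{Å}{Angstrom}, snapshots x matches
#'   matrix), \code{histogram} (a [hist()] object, not plotted).
#' @export
segment_lengths <- function(trajectory, triplet_spec, breaks = "FD") {
  stopifnot(length(trajectory) >= 1)
  pat <- strsplit(triplet_spec, "-", fixed = TRUE)[[1]]
  if (length(pat) != 3) stop("triplet_spec must name three residues")
  lb <- trajectory[[1]]$labels
  if (is.null(lb)) stop("trajectory frames have no labels")
  starts <- list()
  for (ch in unique(lb$chain)) {
    resnos <- sort(unique(lb$resno[lb$chain == ch]))
    rid <- vapply(resnos, function(r)
      lb$resid[lb$chain == ch & lb$resno == r][1], "")
    for (k in seq_len(length(resnos) - 3)) {
      if (all(rid[k:(k + 2)] == pat))
        starts[[length(starts) + 1L]] <- list(chain = ch,
                                              from = resnos[k],
                                              to = resnos[k + 3])
    }
  }
  if (!length(starts))
    stop("pattern ", triplet_spec, " not found in trajectory labels")
  ca_idx <- function(ch, r) which(lb$chain == ch & lb$resno == r &
                                    lb$atom == "CA")
  lens <- vapply(trajectory, function(fr) {
    vapply(starts, function(s)
      sqrt(sum((fr$xyz[ca_idx(s$chain, s$from), ] -
                  fr$xyz[ca_idx(s$chain, s$to), ])^2)), 0)
  }, numeric(length(starts)))
  lens <- matrix(lens, nrow = length(starts))
  h <- graphics::hist(as.vector(lens), breaks = breaks, plot = FALSE)
  list(lengths = t(lens), histogram = h)
}
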