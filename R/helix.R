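## Idealized polyproline-II helix builder.
##
## Backbone grown by internal coordinates (NeRF placement) with ideal bond
## lengths/angles: N-CA 1.46 A, CA-C 1.52 A, C-N 1.33 A, C=O 1.23 A;
## angles N-CA-C 110 deg, CA-C-N 116 deg, C-N-CA 121 deg. Side chains are
## rigid local-frame templates; the proline ring is an idealized Cgamma-endo
## pucker closed numerically once at first use. Heavy atoms only.

.bond <- c(N_CA = 1.46, CA_C = 1.52, C_N = 1.33, C_O = 1.23,
           CA_CB = 1.53, ring = 1.52, C_OH = 1.41, C_OXT = 1.25)
.ang <- c(N_CA_C = 110, CA_C_N = 116, C_N_CA = 121, CA_C_O = 121,
          ring = 104, tet_half = 54.75)

.deg2rad <- pi / 180

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v^2))

## NeRF: place atom d with bond c-d = r, angle b-c-d = theta and
## torsion a-b-c-d = phi (IUPAC sign convention), angles in degrees.
place_atom <- function(a, b, c, r, theta, phi) {
  th <- theta * .deg2rad
  ph <- phi * .deg2rad
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  c + r * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

## Side-chain templates in the residue local frame:
##   origin CA, x along CA->N, z along x cross (CA->C); L chirality puts
##   CB at positive z (positive chirality determinant). Computed once and
##   cached.
.template_cache <- new.env(parent = emptyenv())

.local_backbone <- function() {
  list(N = .bond["N_CA"] * c(1, 0, 0),
       CA = c(0, 0, 0),
       C = .bond["CA_C"] * c(cos(.ang["N_CA_C"] * .deg2rad),
                             sin(.ang["N_CA_C"] * .deg2rad), 0))
}

.sidechain_template <- function(resid) {
  key <- resid
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  bb <- .local_backbone()
  d1 <- .unit(bb$N)                     # CA -> N
  d2 <- .unit(bb$C)                     # CA -> C
  e1 <- .unit(-(d1 + d2))
  e2 <- .unit(.cross3(d1, d2))          # +z
  a <- .ang["tet_half"] * .deg2rad
  ## L chirality: det[N-CA, C-CA, CB-CA] > 0, as in experimental structures
  CB <- .bond["CA_CB"] * (cos(a) * e1 + sin(a) * e2)
  tpl <- switch(resid,
    Gly = list(),
    Ala = list(CB = CB),
    Pro = ,
    Hyp = {
      chi1 <- -25
      CG_of <- function(chi1) place_atom(bb$N, bb$CA, CB, .bond["ring"],
                                         .ang["ring"], chi1)
      close_err <- function(chi2) {
        CG <- CG_of(chi1)
        CD <- place_atom(bb$CA, CB, CG, .bond["ring"], .ang["ring"], chi2)
        (sqrt(sum((CD - bb$N)^2)) - 1.47)^2
      }
      chi2 <- stats::optimize(close_err, c(-120, 120))$minimum
      CG <- CG_of(chi1)
      CD <- place_atom(bb$CA, CB, CG, .bond["ring"], .ang["ring"], chi2)
      out <- list(CB = CB, CG = CG, CD = CD)
      if (resid == "Hyp")   # 4-hydroxyl on CG, staggered away from CD
        out$OD1 <- place_atom(bb$CA, CB, CG, .bond["C_OH"], 109.5,
                              chi2 + 120)
      out
    },
    stop("no side-chain template for residue ", resid))
  .template_cache[[key]] <- tpl
  tpl
}

.element_of <- function(atom) {
  e <- substr(atom, 1, 1)
  if (!e %in% c("C", "N", "O")) stop("unknown atom name: ", atom)
  e
}

## Build one chain; phi/psi are per-residue vectors in degrees.
.build_chain <- function(residues, chirality, phi, psi, omega = 180,
                         chain_id = "A") {
  nres <- length(residues)
  bbN <- bbCA <- bbC <- matrix(NA_real_, nres, 3)
  ## first residue in the canonical local frame
  bb0 <- .local_backbone()
  bbN[1, ] <- bb0$N - bb0$N   # N at origin
  bbCA[1, ] <- -bb0$N
  bbC[1, ] <- bb0$C - bb0$N
  for (i in seq_len(nres)[-1]) {
    bbN[i, ] <- place_atom(bbN[i - 1, ], bbCA[i - 1, ], bbC[i - 1, ],
                           .bond["C_N"], .ang["CA_C_N"], psi[i - 1])
    bbCA[i, ] <- place_atom(bbCA[i - 1, ], bbC[i - 1, ], bbN[i, ],
                            .bond["N_CA"], .ang["C_N_CA"], omega)
    bbC[i, ] <- place_atom(bbC[i - 1, ], bbN[i, ], bbCA[i, ],
                           .bond["CA_C"], .ang["N_CA_C"], phi[i])
  }
  atoms <- character(0); xyz <- NULL
  lab_res <- integer(0); lab_resid <- character(0)
  for (i in seq_len(nres)) {
    res <- residues[i]
    ## carbonyl O anti to the next N (torsion psi + 180)
    O <- place_atom(bbN[i, ], bbCA[i, ], bbC[i, ], .bond["C_O"],
                    .ang["CA_C_O"], psi[i] + 180)
    names_i <- c("N", "CA", "C", "O")
    xyz_i <- rbind(bbN[i, ], bbCA[i, ], bbC[i, ], O)
    tpl <- .sidechain_template(res)
    if (length(tpl)) {
      ## local frame -> world
      xhat <- .unit(bbN[i, ] - bbCA[i, ])
      zhat <- .unit(.cross3(xhat, bbC[i, ] - bbCA[i, ]))
      yhat <- .cross3(zhat, xhat)
      Fm <- cbind(xhat, yhat, zhat)
      mirror <- if (identical(chirality[i], "D")) c(1, 1, -1) else c(1, 1, 1)
      for (nm in names(tpl)) {
        names_i <- c(names_i, nm)
        xyz_i <- rbind(xyz_i, bbCA[i, ] + as.vector(Fm %*% (tpl[[nm]] * mirror)))
      }
    }
    if (i == nres) {   # C-terminal carboxylate OXT where the next N would sit
      OXT <- place_atom(bbN[i, ], bbCA[i, ], bbC[i, ], .bond["C_OXT"],
                        .ang["CA_C_N"], psi[i])
      names_i <- c(names_i, "OXT")
      xyz_i <- rbind(xyz_i, OXT)
    }
    atoms <- c(atoms, names_i)
    xyz <- rbind(xyz, xyz_i)
    lab_res <- c(lab_res, rep(i - 1L, length(names_i)))
    lab_resid <- c(lab_resid, rep(res, length(names_i)))
  }
  labels <- data.frame(chain = chain_id, resno = lab_res, resid = lab_resid,
                       atom = atoms, stringsAsFactors = FALSE)
  geometry(vapply(atoms, .element_of, ""), xyz, labels = labels,
           check = FALSE)
}

#' Build an idealized PPII single- or triple-helix geometry
#'
#' Grows a heavy-atom backbone from ideal internal coordinates with the
#' requested backbone dihedrals on every residue (defaults are the canonical
#' polyproline-II values phi = -75, psi = +150, omega = 180 degrees).
#' D residues get mirrored side-chain chirality. For three chains, copies
#' labeled A/B/C are arranged on a triangle around the common axis with a
#' mutual stagger along the axis (one residue rise by default), emulating
#' the parallel-strand arrangement of the collagen triple superhelix.
#'
#' @param seq a [peptide_sequence()] (or notation string, parsed on the fly).
#' @param phi,psi backbone dihedrals in degrees, in (-180, 180]; scalars or
#'   per-residue vectors.
#' @param n_chains 1 or 3.
#' @param stagger inter-chain stagger in residues (0, 1 or 2); default 1.
#' @param omega peptide-bond dihedral in degrees (default 180, trans).
#' @param radius triangle radius for the 3-chain arrangement in
#'   \enc{Å}{Angstrom}.
#' @param check_clash error on steric clash (< 0.5 \enc{Å}{Angstrom});
#'   disable when rebuilding distorted snapshot geometries.
#' @return a labeled [geometry()] with amide units detected; chains labeled
#'   A/B/C.
#' @examples
#' g <- build_helix(parse_triplet_notation("(PHG)3"), n_chains = 1)
#' @export
build_helix <- function(seq, phi = -75, psi = 150, n_chains = 1,
                        stagger = 1, omega = 180, radius = 7,
                        check_clash = TRUE) {
  if (is.character(seq)) seq <- parse_triplet_notation(seq)
  stopifnot(inherits(seq, "peptide_sequence"))
  nres <- length(seq$residues)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  if (any(phi <= -180 | phi > 180) || any(psi <= -180 | psi > 180))
    stop("phi and psi must lie in (-180, 180] degrees")
  if (!n_chains %in% c(1, 3)) stop("n_chains must be 1 or 3")
  if (n_chains == 3 && !stagger %in% 0:2)
    stop("stagger must be 0, 1 or 2 residues")
  chainA <- .build_chain(seq$residues, seq$chirality, phi, psi, omega, "A")
  if (n_chains == 1) {
    g <- chainA
  } else {
    ca <- chainA$xyz[chainA$labels$atom == "CA", , drop = FALSE]
    axis <- .unit(ca[nrow(ca), ] - ca[1, ])
    rise <- sqrt(sum((ca[nrow(ca), ] - ca[1, ])^2)) / (nrow(ca) - 1)
    u <- .unit(.cross3(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    v <- .cross3(axis, u)
    frames <- lapply(0:2, function(k) {
      ang <- 2 * pi * k / 3
      off <- radius * (cos(ang) * u + sin(ang) * v) +
        stagger * k * rise * axis
      g <- transform_geometry(chainA, diag(3), off)
      g$labels$chain <- LETTERS[k + 1]
      g
    })
    g <- .bind_geometries(frames)
  }
  g$amide_units <- detect_amide_units(g)
  dmin <- if (check_clash) min_pair_distance(g) else Inf
  if (dmin < 0.5)
    stop(sprintf(paste0("steric clash after build (min distance %.3f A);",
                        " try different rise/radius parameters"), dmin))
  g
}

.bind_geometries <- function(gs) {
  geometry(unlist(lapply(gs, `[[`, "elements")),
           do.call(rbind, lapply(gs, `[[`, "xyz")),
           masses = unlist(lapply(gs, `[[`, "masses")),
           labels = do.call(rbind, lapply(gs, `[[`, "labels")),
           check = FALSE)
}
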