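## Cartesian tensor transfer between geometries via best-fit local rotations.

#' Kabsch best-fit proper rotation
#'
#' Least-squares proper rotation R minimizing ||R P - Q|| over rows of the
#' (already centered) coordinate sets. If the unconstrained optimum is a
#' reflection, the smallest singular direction is flipped so that a proper
#' rotation (det +1) is always returned.
#'
#' @param P,Q n x 3 matrices of matched, centered coordinates.
#' @return 3 x 3 proper rotation matrix.
#' @export
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)
}

#' Best-fit local rotation of an atomic neighborhood
#'
#' Finds the proper rotation that aligns the neighborhood of one atom in the
#' source geometry (the atom plus its nearest mapped neighbors, coordinates
#' centered on the atom) onto the corresponding neighborhood in the target.
#'
#' @param source,target [geometry()] objects.
#' @param atom_map two-column matrix/data.frame of (source_atom,
#'   target_atom) 1-based index pairs defining the correspondence.
#' @param atom source-geometry index of the central atom (must appear in the
#'   map).
#' @param n_neighbors number of nearest mapped neighbors to use (default
#'   12); ties broken by lower atom index.
#' @return list (class \code{local_frame_match}) with \code{atom_index},
#'   \code{rotation}, \code{rmsd} (\enc{Å}{A}), \code{support} (source
#'   indices used).
#' @export
local_rotation <- function(source, target, atom_map, atom,
                           n_neighbors = 12) {
  atom_map <- as.matrix(atom_map)[, 1:2, drop = FALSE]
  row <- which(atom_map[, 1] == atom)
  if (length(row) != 1) stop("atom ", atom, " is not in the atom map")
  others <- atom_map[atom_map[, 1] != atom, , drop = FALSE]
  if (nrow(others) < 3)
    stop("atom ", atom, ": fewer than 3 mapped neighbors available")
  d <- sqrt(colSums((t(source$xyz[others[, 1], , drop = FALSE]) -
                       source$xyz[atom, ])^2))
  ord <- order(d, others[, 1])
  take <- ord[seq_len(min(n_neighbors, length(ord)))]
  support <- others[take, , drop = FALSE]
  P <- source$xyz[support[, 1], , drop = FALSE] -
    matrix(source$xyz[atom, ], nrow(support), 3, byrow = TRUE)
  Q <- target$xyz[support[, 2], , drop = FALSE] -
    matrix(target$xyz[atom_map[row, 2], ], nrow(support), 3, byrow = TRUE)
  if (qr(P)$rank < 2)
    stop("atom ", atom, ": support atoms are collinear")
  ## identical neighborhoods align by the exact identity (keeps
  ## self-transfer bit-for-bit)
  R <- if (identical(P, Q)) diag(3) else kabsch_rotation(P, Q)
  rmsd <- sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  structure(list(atom_index = atom, rotation = R, rmsd = rmsd,
                 support = support[, 1]),
            class = "local_frame_match")
}

#' Transfer property tensors from fragments onto a target geometry
#'
#' For every target atom, averages the per-atom tensors over all fragments
#' containing it, rotating each contribution by that fragment's best-fit
#' local rotation for the atom (every Cartesian axis of every tensor
#' rotates). Hessian 3x3 blocks (a, b) are averaged over fragments
#' containing both atoms and rotated as \code{Ra \%*\% Hab \%*\% t(Rb)};
#' blocks for atom pairs never co-resident in any fragment are zero
#' (long-range force constants dropped); the result is symmetrized.
#'
#' @param fragments list of lists with elements \code{fragment} (a
#'   [cut_fragment()] result) and \code{tensors} (the fragment's
#'   [property_tensor_set()]).
#' @param target [geometry()] with the same atom numbering as the fragments'
#'   parent.
#' @param n_neighbors neighborhood size for [local_rotation()].
#' @param weighting \code{"edge"} (default; weight 1 + the atom's amide
#'   distance from the nearer fragment edge, so interior contributions
#'   dominate) or \code{"uniform"}.
#' @return a [property_tensor_set()] for the target.
#' @export
transfer_tensors <- function(fragments, target, n_neighbors = 12,
                             weighting = c("edge", "uniform")) {
  weighting <- match.arg(weighting)
  n <- n_atoms(target)
  covered <- logical(n)
  for (fe in fragments)
    covered[fe$fragment$atom_map$parent_atom[!fe$fragment$atom_map$is_cap]] <- TRUE
  if (!all(covered))
    stop("target atoms not covered by any fragment: ",
         paste(utils::head(which(!covered), 20), collapse = ", "))

  dip <- array(0, c(3, 3, n)); alp <- array(0, c(3, 3, 3, n))
  gpr <- array(0, c(3, 3, 3, n)); aa <- array(0, c(3, 3, 3, 3, n))
  H <- matrix(0, 3 * n, 3 * n)

  ## pass 1: per-fragment atom weights, so contributions can be added
  ## already normalized (single-fragment self-transfer stays bit-exact)
  frag_w <- lapply(fragments, function(fe) {
    fr <- fe$fragment
    map <- fr$atom_map[!fr$atom_map$is_cap, , drop = FALSE]
    if (weighting == "uniform" || is.null(fr$geometry$labels))
      rep(1, nrow(map))
    else {
      res <- fr$geometry$labels$resno[map$fragment_atom]
      1 + pmax(pmin(res - fr$start, fr$end - res), 0)
    }
  })
  wsum <- numeric(n)
  Hw <- matrix(0, n, n)
  for (i in seq_along(fragments)) {
    map <- fragments[[i]]$fragment$atom_map
    pidx <- map$parent_atom[!map$is_cap]
    w <- frag_w[[i]]
    wsum[pidx] <- wsum[pidx] + w
    Hw[pidx, pidx] <- Hw[pidx, pidx] + outer(w, w, pmin)
  }

  ## pass 2: rotate and accumulate normalized contributions
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]$fragment
    ts <- fragments[[i]]$tensors
    stopifnot(ts$n_atoms == n_atoms(fr$geometry))
    map <- fr$atom_map[!fr$atom_map$is_cap, , drop = FALSE]
    fidx <- map$fragment_atom
    pidx <- map$parent_atom
    w_at <- frag_w[[i]]
    am <- cbind(fidx, pidx)
    rots <- lapply(fidx, function(af)
      local_rotation(fr$geometry, target, am, af,
                     n_neighbors = n_neighbors)$rotation)
    for (k in seq_along(fidx)) {
      af <- fidx[k]; ap <- pidx[k]; R <- rots[[k]]
      w <- w_at[k] / wsum[ap]
      dip[, , ap] <- dip[, , ap] +
        w * rotate_cartesian_tensor(ts$dipole_deriv[, , af], R)
      alp[, , , ap] <- alp[, , , ap] +
        w * rotate_cartesian_tensor(ts$alpha_deriv[, , , af], R)
      gpr[, , , ap] <- gpr[, , , ap] +
        w * rotate_cartesian_tensor(ts$gprime_deriv[, , , af], R)
      aa[, , , , ap] <- aa[, , , , ap] +
        w * rotate_cartesian_tensor(ts$a_deriv[, , , , af], R)
    }
    for (k in seq_along(fidx)) {
      af <- fidx[k]; ap <- pidx[k]; Ra <- rots[[k]]
      ia_f <- (3 * (af - 1) + 1):(3 * af)
      ia_p <- (3 * (ap - 1) + 1):(3 * ap)
      for (l in seq_along(fidx)) {
        bf <- fidx[l]; bp <- pidx[l]; Rb <- rots[[l]]
        w <- min(w_at[k], w_at[l]) / Hw[ap, bp]
        ib_f <- (3 * (bf - 1) + 1):(3 * bf)
        ib_p <- (3 * (bp - 1) + 1):(3 * bp)
        H[ia_p, ib_p] <- H[ia_p, ib_p] +
          w * (Ra %*% ts$hessian[ia_f, ib_f] %*% t(Rb))
      }
    }
  }
  H <- (H + t(H)) / 2
  ## numerical symmetrization of the generated per-atom symmetries
  alp <- (alp + aperm(alp, c(2, 1, 3, 4))) / 2
  aa <- (aa + aperm(aa, c(1, 3, 2, 4, 5))) / 2
  property_tensor_set(H, dip, alp, gpr, aa, check = FALSE)
}
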