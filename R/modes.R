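## Harmonic normal-mode analysis with Eckart projection, and partial
## optimization restricted to a normal-mode subspace.

## Frequency conversion: nu~ [cm^-1] = .freq_const * sqrt(lambda) with
## lambda an eigenvalue of the mass-weighted Hessian in (mdyn/A)/Da.
## 1 mdyn/A = 100 N/m; .freq_const = sqrt(100/amu)/(2 pi c) ~ 1302.79.
.amu_kg <- 1.66053906660e-27
.c_cm_s <- 2.99792458e10
.freq_const <- sqrt(100 / .amu_kg) / (2 * pi * .c_cm_s)

## h c / kB in cm K, for the Boltzmann factor at wavenumber nu~.
.hc_over_kB <- 1.438776877

## Speed of light in atomic units; fixes the Raman-to-ROA intensity
## convention (G'/c scaling) used by backscatter_sticks().
.c_au <- 137.035999084

## Orthonormal basis of the column span via modified Gram-Schmidt with a
## relative rank tolerance. Used instead of qr() for the rigid-body basis:
## every operation is a sum of products, so the result is exactly
## equivariant under per-coordinate sign flips (mirror images).
.mgs_basis <- function(V, tol = 1e-8) {
  out <- NULL
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    norm0 <- sqrt(sum(v^2))
    if (!is.null(out))
      for (k in seq_len(ncol(out)))
        v <- v - sum(out[, k] * v) * out[, k]
    nv <- sqrt(sum(v^2))
    if (nv > tol * max(norm0, 1e-300)) out <- cbind(out, v / nv)
  }
  out
}

#' Harmonic normal modes of a geometry + Hessian
#'
#' Mass-weights the Hessian, projects out the 6 rigid-body directions (5
#' for collinear geometries) exactly by diagonalizing in their orthogonal
#' complement (Eckart projection), and converts eigenvalues to wavenumbers.
#' Imaginary modes are reported as negative wavenumbers.
#'
#' @param geometry a [geometry()].
#' @param hessian symmetric 3N x 3N matrix in mdyn/\enc{Å}{A}.
#' @return object of class \code{normal_modes}: list with
#'   \code{frequencies} (cm^-1, ascending), \code{displacements} (3N x
#'   n_modes, mass-weighted orthonormal columns), \code{n_projected},
#'   \code{masses}.
#' @export
normal_modes <- function(geometry, hessian) {
  n <- n_atoms(geometry)
  if (!is.matrix(hessian) || nrow(hessian) != 3 * n ||
      ncol(hessian) != 3 * n)
    stop("hessian must be a 3N x 3N matrix")
  if (max(abs(hessian - t(hessian))) >
      1e-8 * max(abs(hessian), 1e-300))
    stop("hessian is not symmetric")
  m3 <- rep(geometry$masses, each = 3)
  Hmw <- hessian / sqrt(outer(m3, m3))
  ## rigid-body directions in mass-weighted coordinates
  com <- center_of_mass(geometry)
  xs <- sweep(geometry$xyz, 2, com)
  V <- matrix(0, 3 * n, 6)
  sm <- sqrt(geometry$masses)
  for (k in 1:3) V[seq(k, 3 * n, by = 3), k] <- sm
  ex <- diag(3)
  for (k in 1:3) {
    rot <- t(vapply(seq_len(n), function(a) .cross3(ex[k, ], xs[a, ]),
                    numeric(3))) * sm
    V[, 3 + k] <- as.vector(t(rot))
  }
  ## modified Gram-Schmidt: unlike qr(), exactly equivariant under
  ## coordinate sign flips, which keeps enantiomeric inputs bit-for-bit
  ## mirror-antisymmetric all the way to the spectra
  Vb <- .mgs_basis(V)
  rank <- ncol(Vb)                      # 6, or 5 for collinear geometries
  ## project the rigid-body subspace out and diagonalize; the `rank`
  ## eigenvalues annihilated by the projector (smallest in magnitude by a
  ## wide margin) are the removed translations/rotations
  P <- diag(3 * n) - Vb %*% t(Vb)
  Hproj <- P %*% Hmw %*% P
  es <- eigen(Hproj, symmetric = TRUE)
  drop_idx <- order(abs(es$values))[seq_len(rank)]
  keep <- setdiff(seq_along(es$values), drop_idx)
  lambda <- es$values[keep]
  ord <- order(lambda)
  lambda <- lambda[ord]
  L <- es$vectors[, keep, drop = FALSE][, ord, drop = FALSE]
  freqs <- sign(lambda) * sqrt(abs(lambda)) * .freq_const
  structure(list(frequencies = freqs, displacements = L,
                 n_projected = rank, masses = geometry$masses),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  nim <- sum(x$frequencies < 0)
  cat(sprintf(
    "normal_modes: %d modes (%d rigid-body projected, %d imaginary)\n",
    length(x$frequencies), x$n_projected, nim))
  cat(sprintf("  range %.1f .. %.1f cm^-1\n", min(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

#' Partial optimization restricted to a normal-mode subspace
#'
#' Minimizes a model energy along the normal modes whose harmonic
#' wavenumbers fall inside \code{freq_window}, keeping the projections on
#' all other modes frozen. Newton iterations use the reduced Hessian of the
#' supplied force field with a backtracking line search.
#'
#' @param geometry starting [geometry()].
#' @param energy_and_gradient function(xyz matrix) returning
#'   \code{list(energy =, gradient =)} with the gradient as an N x 3 matrix
#'   (energy units consistent with \code{hessian}).
#' @param hessian 3N x 3N Hessian of the model at (or near) the start.
#' @param freq_window length-2 numeric: modes with \code{|nu|} inside
#'   \code{[freq_window[1], freq_window[2]]} cm^-1 are relaxed.
#' @param tol convergence threshold on the max projected gradient.
#' @param max_iter maximum Newton iterations.
#' @return the relaxed [geometry()] with attribute \code{"iterations"}.
#' @export
subspace_optimize <- function(geometry, energy_and_gradient, hessian,
                              freq_window = c(0, Inf), tol = 1e-8,
                              max_iter = 100) {
  nm <- normal_modes(geometry, hessian)
  sel <- which(abs(nm$frequencies) >= freq_window[1] &
                 abs(nm$frequencies) <= freq_window[2])
  if (!length(sel)) stop("no modes inside the frequency window")
  m3 <- rep(geometry$masses, each = 3)
  B <- nm$displacements[, sel, drop = FALSE] / sqrt(m3)  # Cartesian steps
  Hq <- t(B) %*% hessian %*% B
  Hq <- (Hq + t(Hq)) / 2
  ## regularize any non-positive curvature so Newton steps descend
  ev <- eigen(Hq, symmetric = TRUE)
  vals <- pmax(abs(ev$values), 1e-8 * max(abs(ev$values), 1e-12))
  Hq_inv <- ev$vectors %*% (t(ev$vectors) / vals)
  x <- as.vector(t(geometry$xyz))
  eg <- function(xv) {
    r <- energy_and_gradient(matrix(xv, ncol = 3, byrow = TRUE))
    list(e = r$energy, g = as.vector(t(r$gradient)))
  }
  cur <- eg(x)
  it <- 0
  repeat {
    gq <- as.vector(t(B) %*% cur$g)
    if (max(abs(gq)) < tol) break
    it <- it + 1
    if (it > max_iter)
      stop(sprintf(
        "subspace optimization did not converge in %d iterations (max projected gradient %.3g)",
        max_iter, max(abs(gq))))
    dq <- -as.vector(Hq_inv %*% gq)
    step <- 1
    repeat {
      xn <- x + as.vector(B %*% (step * dq))
      nxt <- eg(xn)
      if (nxt$e <= cur$e + 1e-12 * abs(cur$e) || step < 1e-8) break
      step <- step / 2
    }
    x <- xn
    cur <- nxt
  }
  out <- geometry
  out$xyz <- matrix(x, ncol = 3, byrow = TRUE)
  attr(out, "iterations") <- it
  out
}
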