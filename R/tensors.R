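## Per-atom Cartesian property-tensor container.
##
## Conventions: atom index is the LAST array dimension. dipole_deriv[i,b,a]
## is the derivative of dipole component i with respect to displacement b of
## atom a; alpha_deriv[i,j,b,a] and gprime_deriv[i,j,b,a] likewise for the
## electric-dipole polarizability and the electric-dipole--magnetic-dipole
## tensor; a_deriv[i,j,k,b,a] for the electric-dipole--electric-quadrupole
## tensor (symmetric in j,k). The Hessian is the full 3N x 3N matrix in
## mdyn/A with coordinates ordered (x1,y1,z1,x2,...).

#' Construct a property tensor set
#'
#' @param hessian symmetric 3N x 3N force-constant matrix (mdyn/\enc{Å}{A}).
#' @param dipole_deriv array dim c(3, 3, N).
#' @param alpha_deriv array dim c(3, 3, 3, N), symmetric in the first two
#'   indices.
#' @param gprime_deriv array dim c(3, 3, 3, N) (parity-odd tensor).
#' @param a_deriv array dim c(3, 3, 3, 3, N), symmetric in indices 2, 3.
#' @param check validate symmetries (default TRUE).
#' @return object of class \code{property_tensor_set}.
#' @export
property_tensor_set <- function(hessian, dipole_deriv, alpha_deriv,
                                gprime_deriv, a_deriv, check = TRUE) {
  n <- nrow(hessian) / 3
  stopifnot(n == round(n))
  ts <- structure(
    list(hessian = hessian, dipole_deriv = dipole_deriv,
         alpha_deriv = alpha_deriv, gprime_deriv = gprime_deriv,
         a_deriv = a_deriv, n_atoms = as.integer(n)),
    class = "property_tensor_set")
  if (check) validate_tensor_set(ts)
  ts
}

#' Validate the symmetry and shape invariants of a tensor set
#'
#' @param ts a [property_tensor_set()].
#' @param tol relative tolerance for Hessian symmetry.
#' @return \code{ts}, invisibly; stops on violation.
#' @export
validate_tensor_set <- function(ts, tol = 1e-10) {
  n <- ts$n_atoms
  H <- ts$hessian
  stopifnot(nrow(H) == 3 * n, ncol(H) == 3 * n)
  scale <- max(abs(H), 1e-300)
  if (max(abs(H - t(H))) / scale > tol)
    stop("hessian is not symmetric")
  stopifnot(identical(dim(ts$dipole_deriv), c(3L, 3L, n)),
            identical(dim(ts$alpha_deriv), c(3L, 3L, 3L, n)),
            identical(dim(ts$gprime_deriv), c(3L, 3L, 3L, n)),
            identical(dim(ts$a_deriv), c(3L, 3L, 3L, 3L, n)))
  if (max(abs(ts$alpha_deriv - aperm(ts$alpha_deriv, c(2, 1, 3, 4)))) >
      tol * max(abs(ts$alpha_deriv), 1e-300))
    stop("alpha_deriv not symmetric in i,j")
  if (max(abs(ts$a_deriv - aperm(ts$a_deriv, c(1, 3, 2, 4, 5)))) >
      tol * max(abs(ts$a_deriv), 1e-300))
    stop("a_deriv not symmetric in j,k")
  invisible(ts)
}

#' @export
print.property_tensor_set <- function(x, ...) {
  cat(sprintf("property_tensor_set: %d atoms (hessian %d x %d)\n",
              x$n_atoms, nrow(x$hessian), ncol(x$hessian)))
  invisible(x)
}

#' Rotate a Cartesian tensor of arbitrary rank
#'
#' Contracts one copy of the rotation matrix with every axis of the array;
#' for a rank-2 tensor this is \code{R T t(R)}.
#'
#' @param T numeric array with every dimension of length 3 (a plain
#'   length-3 vector is treated as rank 1).
#' @param R 3 x 3 orthogonal matrix.
#' @return rotated array of the same shape.
#' @export
rotate_cartesian_tensor <- function(T, R) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("R is not orthogonal")
  d <- dim(T)
  if (is.null(d)) {
    stopifnot(length(T) == 3)
    return(as.vector(R %*% T))
  }
  if (any(d != 3)) stop("every axis of T must have length 3")
  rank <- length(d)
  for (ax in seq_len(rank)) {
    perm <- c(ax, setdiff(seq_len(rank), ax))
    Tp <- aperm(T, perm)
    M <- R %*% matrix(Tp, nrow = 3)
    Tp <- array(M, dim = d[perm])
    T <- aperm(Tp, order(perm))
  }
  T
}

## Rotate only the first `naxes` axes of an array whose last dim is atoms;
## used when slicing per-atom blocks (all axes of the slice rotate).
.rotate_atom_slice <- function(slice, R) rotate_cartesian_tensor(slice, R)

#' Transform a whole tensor set by an orthogonal operation
#'
#' Applies the (possibly improper) orthogonal matrix to every Cartesian axis
#' of every per-atom tensor and conjugates the Hessian blocks. G' is a
#' parity-odd (axial) tensor and is additionally multiplied by det(R), which
#' is what makes the downstream ROA spectrum change sign under a mirror
#' operation while the Raman spectrum is preserved.
#'
#' @param ts a [property_tensor_set()].
#' @param R 3 x 3 orthogonal matrix (det +1 rotation or det -1 reflection).
#' @return transformed [property_tensor_set()].
#' @export
transform_tensor_set <- function(ts, R) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("R is not orthogonal")
  detR <- det(R)
  n <- ts$n_atoms
  W <- kronecker(diag(n), R)
  out <- ts
  out$hessian <- W %*% ts$hessian %*% t(W)
  for (a in seq_len(n)) {
    out$dipole_deriv[, , a] <-
      rotate_cartesian_tensor(ts$dipole_deriv[, , a], R)
    out$alpha_deriv[, , , a] <-
      rotate_cartesian_tensor(ts$alpha_deriv[, , , a], R)
    out$gprime_deriv[, , , a] <-
      detR * rotate_cartesian_tensor(ts$gprime_deriv[, , , a], R)
    out$a_deriv[, , , , a] <-
      rotate_cartesian_tensor(ts$a_deriv[, , , , a], R)
  }
  out
}

#' Mirror a geometry through the xy plane
#' @param g a [geometry()].
#' @export
mirror_geometry <- function(g) transform_geometry(g, diag(c(1, 1, -1)))

#' Write a tensor set (with its geometry) to a JSON container
#'
#' @param ts a [property_tensor_set()].
#' @param geometry the owning [geometry()]; stored alongside so the
#'   container is self-describing.
#' @param file output path.
#' @export
write_tensor_set <- function(ts, geometry, file) {
  stopifnot(ts$n_atoms == n_atoms(geometry))
  obj <- list(
    n_atoms = ts$n_atoms,
    elements = geometry$elements,
    masses = geometry$masses,
    xyz = geometry$xyz,
    hessian = ts$hessian,
    dipole_deriv = as.vector(ts$dipole_deriv),
    alpha_deriv = as.vector(ts$alpha_deriv),
    gprime_deriv = as.vector(ts$gprime_deriv),
    a_deriv = as.vector(ts$a_deriv))
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read a tensor set JSON container
#'
#' @param file path written by [write_tensor_set()].
#' @return list with \code{tensors} ([property_tensor_set()]) and
#'   \code{geometry} ([geometry()]).
#' @export
read_tensor_set <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  n <- as.integer(obj$n_atoms)
  ts <- property_tensor_set(
    hessian = matrix(unlist(obj$hessian), 3 * n, 3 * n),
    dipole_deriv = array(obj$dipole_deriv, c(3, 3, n)),
    alpha_deriv = array(obj$alpha_deriv, c(3, 3, 3, n)),
    gprime_deriv = array(obj$gprime_deriv, c(3, 3, 3, n)),
    a_deriv = array(obj$a_deriv, c(3, 3, 3, 3, n)))
  g <- geometry(obj$elements, matrix(unlist(obj$xyz), n, 3),
                masses = obj$masses, check = FALSE)
  list(tensors = ts, geometry = g)
}
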