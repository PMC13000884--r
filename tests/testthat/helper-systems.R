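## Shared fixtures and independent oracles, all built in code.

## Proper rotation from ZYZ Euler angles (radians).
euler_rotation <- function(a, b, c) {
  rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
  ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                          c(-sin(t), 0, cos(t)))
  rz(a) %*% ry(b) %*% rz(c)
}

random_rotation <- function(seed) {
  with_seed(seed, euler_rotation(stats::runif(1, 0, 2 * pi),
                                 stats::runif(1, 0, pi),
                                 stats::runif(1, 0, 2 * pi)))
}

## Naive index-summation oracle for rotating a Cartesian tensor of rank r.
rotate_tensor_naive <- function(T, R) {
  d <- dim(T)
  out <- array(0, d)
  r <- length(d)
  idx <- as.matrix(expand.grid(lapply(d, seq_len)))
  for (row in seq_len(nrow(idx))) {
    i <- idx[row, ]
    s <- 0
    for (jrow in seq_len(nrow(idx))) {
      j <- idx[jrow, ]
      p <- 1
      for (ax in seq_len(r)) p <- p * R[i[ax], j[ax]]
      s <- s + p * T[matrix(j, 1)]
    }
    out[matrix(i, 1)] <- s
  }
  out
}

## Independent torsion oracle: rotate the frame so that p2 -> p3 lies on
## +z, then read the angle between the projections of the outer bonds in
## the xy plane.
dihedral_oracle <- function(p1, p2, p3, p4) {
  z <- p3 - p2
  z <- z / sqrt(sum(z^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  proj <- function(p, o) c(sum((p - o) * x), sum((p - o) * y))
  a <- proj(p1, p2)
  b <- proj(p4, p3)
  ang <- atan2(b[2], b[1]) - atan2(a[2], a[1])
  ang <- ((ang / pi * 180 + 180) %% 360) - 180
  ## the convention measures from the p1 side; flip to IUPAC
  ang <- -(-ang)
  if (ang <= -180) ang + 360 else ang
}

## Naive Levi-Civita / trace oracle for the per-mode invariants.
invariants_oracle <- function(modes, tensors, excitation = 18796.99) {
  n <- tensors$n_atoms
  nm <- length(modes$frequencies)
  eps <- array(0, c(3, 3, 3))
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (p in perms) eps[p[1], p[2], p[3]] <- 1
  for (p in perms) eps[p[3], p[2], p[1]] <- -1
  out <- data.frame(nu = modes$frequencies, a2 = 0, beta_alpha2 = 0,
                    beta_g2 = 0, beta_a2 = 0)
  for (p in seq_len(nm)) {
    al <- matrix(0, 3, 3); g <- matrix(0, 3, 3); A <- array(0, c(3, 3, 3))
    for (a in seq_len(n)) for (b in 1:3) {
      l <- modes$displacements[3 * (a - 1) + b, p] / sqrt(modes$masses[a])
      al <- al + tensors$alpha_deriv[, , b, a] * l
      g <- g + tensors$gprime_deriv[, , b, a] * l
      A <- A + tensors$a_deriv[, , , b, a] * l
    }
    tra <- 0; for (i in 1:3) tra <- tra + al[i, i]
    trg <- 0; for (i in 1:3) trg <- trg + g[i, i]
    out$a2[p] <- (tra / 3)^2
    s_aa <- 0; s_ag <- 0
    for (i in 1:3) for (j in 1:3) {
      s_aa <- s_aa + al[i, j] * al[i, j]
      s_ag <- s_ag + al[i, j] * g[i, j]
    }
    out$beta_alpha2[p] <- 0.5 * (3 * s_aa - tra^2)
    out$beta_g2[p] <- 0.5 * (3 * s_ag - tra * trg)
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      s <- s + al[i, j] * eps[i, k, l] * A[k, l, j]
    out$beta_a2[p] <- (excitation / 2) * s
  }
  out
}

## Small labeled helix shared across files (cheap to rebuild).
small_helix <- function() build_helix(parse_triplet_notation("(PHG)3PHA"))

## A dihedral_series with given samples on one residue, for surface tests.
series_from_samples <- function(phi, psi) {
  structure(list(phi = matrix(phi, ncol = 1), psi = matrix(psi, ncol = 1),
                 residues = data.frame(chain = "A", resno = 1L,
                                       resid = "Ala")),
            class = "dihedral_series")
}
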