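## Seeded generators standing in for the quantum-chemistry and MD engines:
## toy spring force fields, chiral property-tensor sets with collagen-like
## CID magnitudes, experiment-like noisy spectra, and PPII-concentrated
## dihedral trajectories.

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores the global RNG state, so generators are pure in their
#' configuration without disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Toy spring system with analytic Hessian
#'
#' Builds a connected mass-and-spring network. \code{connectivity =
#' "chain"} places the atoms on a line with nearest-neighbor springs, whose
#' longitudinal frequencies have the closed form
#' \code{2 sqrt(k/m) |sin(j pi / (2 n))|} (free 1-D chain dispersion);
#' \code{"network"} jitters the positions into 3-D and connects each atom
#' to its three following neighbors, which makes the frame generically
#' rigid (exactly 6 zero modes).
#'
#' @param n_atoms number of atoms (>= 2).
#' @param k spring constant(s) in mdyn/\enc{Å}{A}; recycled over springs.
#' @param masses per-atom masses in Da; recycled.
#' @param connectivity \code{"chain"} or \code{"network"}.
#' @param spacing nearest-neighbor distance in \enc{Å}{A}.
#' @param jitter positional jitter (\enc{Å}{A}) for \code{"network"}.
#' @param seed RNG seed (used by \code{"network"} jitter).
#' @return list with \code{geometry}, \code{hessian} (3N x 3N, mdyn/A) and
#'   \code{springs} (matrix of index pairs and constants).
#' @export
make_spring_system <- function(n_atoms, k = 1, masses = 1,
                               connectivity = c("network", "chain"),
                               spacing = 1.5, jitter = 0.3, seed = 1) {
  connectivity <- match.arg(connectivity)
  if (n_atoms < 2) stop("n_atoms must be >= 2")
  masses <- rep_len(masses, n_atoms)
  xyz <- cbind(spacing * (seq_len(n_atoms) - 1), 0, 0)
  pairs <- cbind(seq_len(n_atoms - 1), 2:n_atoms)
  if (connectivity == "network") {
    xyz <- with_seed(seed, xyz + matrix(stats::rnorm(3 * n_atoms, 0, jitter),
                                        n_atoms, 3))
    for (off in 2:3)
      if (n_atoms > off)
        pairs <- rbind(pairs, cbind(seq_len(n_atoms - off),
                                    (1 + off):n_atoms))
  }
  kk <- rep_len(k, nrow(pairs))
  H <- matrix(0, 3 * n_atoms, 3 * n_atoms)
  for (s in seq_len(nrow(pairs))) {
    a <- pairs[s, 1]; b <- pairs[s, 2]
    u <- .unit(xyz[b, ] - xyz[a, ])
    K <- kk[s] * (u %o% u)
    ia <- (3 * (a - 1) + 1):(3 * a); ib <- (3 * (b - 1) + 1):(3 * b)
    H[ia, ia] <- H[ia, ia] + K
    H[ib, ib] <- H[ib, ib] + K
    H[ia, ib] <- H[ia, ib] - K
    H[ib, ia] <- H[ib, ia] - K
  }
  g <- geometry(rep("C", n_atoms), xyz, masses = masses, check = FALSE)
  list(geometry = g, hessian = H, springs = cbind(pairs, k = kk))
}

#' Chiral property-tensor set with a target CID magnitude
#'
#' Generates a full [property_tensor_set()] for a geometry: a spring-network
#' Hessian built on the geometry (each atom connected to its nearest
#' neighbors), random smooth symmetric polarizability derivatives, and G'/A
#' derivatives post-scaled so that the median per-mode |ROA|/|Raman| stick
#' ratio equals \code{roa_scale} (default 1e-3, the CID regime typical of
#' peptides). \code{mirror = TRUE} returns the tensor set of the mirrored
#' geometry (pair it with [mirror_geometry()]): parity-even tensors are
#' reflected, the parity-odd G' additionally changes sign, so downstream
#' ROA is exactly negated.
#'
#' @param geometry a [geometry()].
#' @param roa_scale target median per-mode |D_p|/S_p (> 0).
#' @param seed RNG seed.
#' @param mirror generate the enantiomeric tensor set.
#' @param n_neighbors spring connections per atom for the internal Hessian.
#' @param k_scale spring-constant scale in mdyn/\enc{Å}{A}.
#' @return a [property_tensor_set()].
#' @export
make_chiral_tensors <- function(geometry, roa_scale = 1e-3, seed = 1,
                                mirror = FALSE, n_neighbors = 6,
                                k_scale = 4) {
  if (roa_scale <= 0) stop("roa_scale must be positive")
  n <- n_atoms(geometry)
  stopifnot(n >= 4)
  ## distance-based spring network: each atom to its n_neighbors nearest
  D <- as.matrix(stats::dist(geometry$xyz))
  diag(D) <- Inf
  pairs <- NULL
  for (a in seq_len(n)) {
    nb <- order(D[a, ])[seq_len(min(n_neighbors, n - 1))]
    pairs <- rbind(pairs, cbind(pmin(a, nb), pmax(a, nb)))
  }
  pairs <- unique(pairs)
  H <- matrix(0, 3 * n, 3 * n)
  with_seed(seed, {
    kk <- k_scale * stats::runif(nrow(pairs), 0.5, 1.5)
    for (s in seq_len(nrow(pairs))) {
      a <- pairs[s, 1]; b <- pairs[s, 2]
      u <- .unit(geometry$xyz[b, ] - geometry$xyz[a, ])
      K <- kk[s] * (u %o% u)
      ia <- (3 * (a - 1) + 1):(3 * a); ib <- (3 * (b - 1) + 1):(3 * b)
      H[ia, ia] <- H[ia, ia] + K
      H[ib, ib] <- H[ib, ib] + K
      H[ia, ib] <- H[ia, ib] - K
      H[ib, ia] <- H[ib, ia] - K
    }
    dip <- array(stats::rnorm(9 * n), c(3, 3, n))
    alp <- array(stats::rnorm(27 * n), c(3, 3, 3, n))
    alp <- (alp + aperm(alp, c(2, 1, 3, 4))) / 2
    ## G' dominated by an alpha-correlated channel (so the per-mode
    ## ROA/Raman ratio stays within a decade of its median) plus noise;
    ## A scaled down by the excitation wavenumber entering beta(A)^2
    gpr <- alp + 0.25 * array(stats::rnorm(27 * n), c(3, 3, 3, n))
    aa <- array(stats::rnorm(81 * n), c(3, 3, 3, 3, n)) / 18797
    aa <- (aa + aperm(aa, c(1, 3, 2, 4, 5))) / 2
  })
  ts <- property_tensor_set(H, dip, alp, gpr, aa)
  ## calibrate the chiral blocks to the target per-mode CID scale
  nm <- normal_modes(geometry, H)
  inv <- mode_invariants(nm, ts)
  inv <- inv[inv$nu > 1, , drop = FALSE]
  st <- suppressWarnings(backscatter_sticks(inv))
  ok <- st$raman > 0
  med <- stats::median(abs(st$roa[ok]) / st$raman[ok])
  f <- roa_scale / med
  ts$gprime_deriv <- ts$gprime_deriv * f
  ts$a_deriv <- ts$a_deriv * f
  if (mirror) ts <- transform_tensor_set(ts, diag(c(1, 1, -1)))
  ts
}

#' Experiment-like noisy Raman/ROA spectrum
#'
#' Sum of unit-area Lorentzian bands plus a water Raman band at 1650
#' cm^-1, a polynomial fluorescence-like baseline and i.i.d. Gaussian
#' noise. The ground-truth band table is attached for recovery tests.
#'
#' @param bands data.frame with columns \code{center},
#'   \code{raman_weight}, \code{roa_weight} (and optional \code{fwhm}).
#' @param baseline_coeffs polynomial coefficients (intercept first) in the
#'   scaled variable \code{(nu - 1000)/1000}, added to the Raman array.
#' @param noise_sd Gaussian noise s.d. added to both arrays.
#' @param seed RNG seed.
#' @param grid wavenumber grid.
#' @param water_weight Raman weight of the 1650 cm^-1 water band (0
#'   disables it).
#' @param fwhm default band FWHM in cm^-1.
#' @return a [spectrum_pair()] with attribute \code{"truth"} (the band
#'   table including the water band).
#' @export
make_experiment_spectrum <- function(bands, baseline_coeffs = 0,
                                     noise_sd = 0, seed = 1,
                                     grid = seq(200, 1800, by = 1),
                                     water_weight = 50, fwhm = 10) {
  if (!"fwhm" %in% names(bands)) bands$fwhm <- fwhm
  if (water_weight > 0)
    bands <- rbind(bands,
                   data.frame(center = 1650, raman_weight = water_weight,
                              roa_weight = 0, fwhm = 35))
  raman <- numeric(length(grid)); roa <- numeric(length(grid))
  for (b in seq_len(nrow(bands))) {
    gam <- bands$fwhm[b] / 2
    L <- (gam / pi) / ((grid - bands$center[b])^2 + gam^2)
    raman <- raman + bands$raman_weight[b] * L
    roa <- roa + bands$roa_weight[b] * L
  }
  u <- (grid - 1000) / 1000
  base <- 0
  for (p in seq_along(baseline_coeffs))
    base <- base + baseline_coeffs[p] * u^(p - 1)
  raman <- raman + base
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(2 * length(grid), 0,
                                                 noise_sd), ncol = 2))
    raman <- raman + noise[, 1]
    roa <- roa + noise[, 2]
  }
  out <- spectrum_pair(grid, raman, roa,
                       meta = list(seed = seed, noise_sd = noise_sd))
  attr(out, "truth") <- bands
  out
}

#' Canonical synthetic collagen fixtures
#'
#' Encodes the marker-band rules into four spectra: \code{"type_I"}
#' (positive 473 cm^-1 ROA band, no 306/339 doublet), \code{"type_II"}
#' (306 + 339 cm^-1 Raman doublet, no 473 ROA), \code{"denatured_I"}
#' (221 cm^-1 Raman band, weakened amide-I ROA couplet) and
#' \code{"ambiguous"} (both type-I and type-II evidence). All carry a
#' (-/+) amide-I ROA couplet (weakened for the denatured form) with CID
#' magnitudes near 1e-3.
#'
#' @param type fixture name.
#' @param seed RNG seed for the noise.
#' @param noise_sd Gaussian noise s.d. (default 2e-5, a high
#'   signal-to-noise regime typical of long-accumulation measurements).
#' @return a [spectrum_pair()] with attribute \code{"truth"}.
#' @export
collagen_fixture <- function(type = c("type_I", "type_II", "denatured_I",
                                      "ambiguous"),
                             seed = 1, noise_sd = 2e-5) {
  type <- match.arg(type)
  cid0 <- 1e-3   # lobe CID scale of the amide-I couplet
  amide_roa <- if (type == "denatured_I") 0.2 else 1
  bands <- data.frame(center = numeric(0), raman_weight = numeric(0),
                      roa_weight = numeric(0))
  add <- function(center, rw, ow = 0)
    bands <<- rbind(bands, data.frame(center = center, raman_weight = rw,
                                      roa_weight = ow))
  ## amide I: Raman at 1668; ROA couplet (-) 1630 / (+) 1664
  add(1668, 8)
  add(1664, 0, amide_roa * cid0 * 12)
  add(1630, 0, -amide_roa * cid0 * 12)
  ## shared backbone/ring bands
  add(1455, 4); add(1345, 3); add(1268, 3); add(1247, 3)
  add(1033, 2); add(874, 2); add(765, 1.5); add(570, 1.5); add(535, 1.5)
  if (type %in% c("type_I", "ambiguous"))
    add(473, 2.5, 2.5 * cid0 * 3)              # Hyp-ring ROA fingerprint
  if (type %in% c("type_II", "ambiguous")) {
    add(468, 1)                                 # weak Raman counterpart
    add(306, 1.5); add(339, 1.5)               # type II Raman doublet
  }
  if (type == "denatured_I") {
    add(221, 1.5)                               # appears on denaturation
    add(473, 2.5)                               # Raman only, no ROA lobe
  }
  make_experiment_spectrum(bands, baseline_coeffs = 0, noise_sd = noise_sd,
                           seed = seed)
}

## von Mises sampler (Best & Fisher 1979 rejection method), radians.
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  ## above this concentration the distribution is numerically a point mass
  if (kappa > 1e8) return(rep(((mu + pi) %% (2 * pi)) - pi, n))
  kappa <- min(kappa, 1e6)
  if (kappa < 1e-8)
    return(((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

#' PPII-concentrated synthetic dihedral trajectory
#'
#' Samples per-residue backbone dihedrals from independent von Mises
#' distributions centered on the PPII basin and rebuilds the chain geometry
#' for every snapshot with the helix builder.
#'
#' @param seq a [peptide_sequence()], notation string, or an integer
#'   residue count (then a poly-Ala chain is used).
#' @param n_snapshots number of snapshots (>= 1).
#' @param kappa von Mises concentration (>= 0; capped at 1e6).
#' @param means length-2 (phi0, psi0) in degrees; default the PPII basin
#'   \code{c(-75, 150)}.
#' @param seed RNG seed.
#' @return list with \code{trajectory} (list of labeled [geometry()]
#'   frames) and \code{truth} (sampling parameters and the sampled
#'   dihedral matrices).
#' @export
make_ppii_trajectory <- function(seq, n_snapshots, kappa = 20,
                                 means = c(-75, 150), seed = 1) {
  if (is.numeric(seq) && length(seq) == 1)
    seq <- peptide_sequence(rep("Ala", seq))
  if (is.character(seq)) seq <- parse_triplet_notation(seq)
  stopifnot(n_snapshots >= 1)
  if (kappa < 0) stop("kappa must be non-negative")
  nres <- length(seq$residues)
  with_seed(seed, {
    phi <- matrix(.rvonmises(n_snapshots * nres, means[1] * .deg2rad,
                             kappa) / .deg2rad, n_snapshots, nres)
    psi <- matrix(.rvonmises(n_snapshots * nres, means[2] * .deg2rad,
                             kappa) / .deg2rad, n_snapshots, nres)
  })
  trajectory <- lapply(seq_len(n_snapshots), function(s) {
    g <- .build_chain(seq$residues, seq$chirality, phi[s, ], psi[s, ],
                      180, "A")
    g$amide_units <- detect_amide_units(g)
    g
  })
  list(trajectory = trajectory,
       truth = list(means = means, kappa = kappa, seed = seed,
                    phi = phi, psi = psi))
}
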