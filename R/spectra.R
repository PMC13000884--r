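## Backscattered SCP Raman/ROA intensities from tensor invariants, and
## Lorentzian spectral synthesis.

.levi_civita <- local({
  e <- array(0, c(3, 3, 3))
  e[1, 2, 3] <- e[2, 3, 1] <- e[3, 1, 2] <- 1
  e[3, 2, 1] <- e[1, 3, 2] <- e[2, 1, 3] <- -1
  e
})

#' Per-mode Raman/ROA tensor invariants
#'
#' Contracts the atomic property-tensor derivatives with the mass-weighted
#' normal-mode displacements to obtain per-mode alpha, G' and A derivative
#' tensors, then forms the standard far-from-resonance invariants:
#' \deqn{a_p = Tr(\alpha_p)/3}
#' \deqn{\beta(\alpha)_p^2 = (3 \alpha_p:\alpha_p - Tr(\alpha_p)^2)/2}
#' \deqn{\beta(G')_p^2 = (3 \alpha_{p,ij} G'_{p,ij} -
#'   \alpha_{p,ii} G'_{p,jj})/2}
#' \deqn{\beta(A)_p^2 = (\omega/2) \alpha_{p,ij} \epsilon_{ikl} A_{p,klj}}
#' with \eqn{\omega} represented by the excitation wavenumber (the global
#' intensity scale is arbitrary; spectra are compared after normalization).
#'
#' @param modes a [normal_modes()] result.
#' @param tensors a [property_tensor_set()] for the same geometry.
#' @param excitation excitation wavenumber in cm^-1 (default 532 nm).
#' @return data.frame with columns \code{nu} (cm^-1), \code{a2} (= a_p^2),
#'   \code{beta_alpha2}, \code{beta_g2}, \code{beta_a2}.
#' @export
mode_invariants <- function(modes, tensors, excitation = 18796.99) {
  n <- tensors$n_atoms
  if (nrow(modes$displacements) != 3 * n)
    stop("modes and tensors refer to different atom counts")
  nm <- length(modes$frequencies)
  ## derivative w.r.t. normal coordinate: sum_ab dT/dx_ab * L_ab / sqrt(m_a)
  Lw <- modes$displacements / sqrt(rep(modes$masses, each = 3))  # 3N x nm
  contract <- function(arr, rank) {
    ## arr dims: c(rep(3, rank), 3 (beta), n (atom)) -> per-mode array
    M <- matrix(arr, ncol = 3 * n)   # leading indices x (beta, atom)
    out <- M %*% Lw                  # leading x modes
    array(out, c(rep(3, rank), nm))
  }
  alpha_p <- contract(tensors$alpha_deriv, 2)    # 3 x 3 x nm
  g_p <- contract(tensors$gprime_deriv, 2)
  a_p <- contract(tensors$a_deriv, 3)            # 3 x 3 x 3 x nm
  out <- data.frame(nu = modes$frequencies, a2 = 0, beta_alpha2 = 0,
                    beta_g2 = 0, beta_a2 = 0)
  eps <- .levi_civita
  for (p in seq_len(nm)) {
    al <- alpha_p[, , p]; g <- g_p[, , p]; A <- a_p[, , , p]
    tra <- sum(diag(al)); trg <- sum(diag(g))
    out$a2[p] <- (tra / 3)^2
    out$beta_alpha2[p] <- 0.5 * (3 * sum(al * al) - tra^2)
    out$beta_g2[p] <- 0.5 * (3 * sum(al * g) - tra * trg)
    ## eps_ikl A_klj contracted against alpha_ij
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      s <- s + al[i, j] * eps[i, k, l] * A[k, l, j]
    out$beta_a2[p] <- (excitation / 2) * s
  }
  out
}

#' Backscattered Raman/ROA stick intensities
#'
#' Converts per-mode invariants into backscattering (180 degree) SCP stick
#' weights with the convention
#' \deqn{S_p = k_p (90 a_p^2 + 14 \beta(\alpha)_p^2)}
#' \deqn{D_p = k_p (4/c) (12 \beta(G')_p^2 + 4 \beta(A)_p^2)}
#' where c is the speed of light in atomic units (fixing the Raman-to-ROA
#' ratio convention) and
#' \deqn{k_p = (\nu_0 - \nu_p)^4 / \nu_p \cdot
#'   1/(1 - \exp(-h c \nu_p / k_B T))}
#' includes the fourth-power scattering factor and the Boltzmann
#' temperature factor. The global scale is arbitrary.
#'
#' @param invariants a [mode_invariants()] data.frame.
#' @param excitation excitation wavenumber nu_0 in cm^-1; must exceed all
#'   mode wavenumbers (default 18796.99, i.e. 532 nm).
#' @param temperature temperature in K (default 300).
#' @return object of class \code{stick_spectrum}: data.frame with columns
#'   \code{nu}, \code{raman}, \code{roa}.
#' @export
backscatter_sticks <- function(invariants, excitation = 18796.99,
                               temperature = 300) {
  inv <- invariants
  bad <- inv$nu <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive-frequency mode(s) skipped")
    inv <- inv[!bad, , drop = FALSE]
  }
  if (any(inv$nu >= excitation))
    stop("excitation wavenumber must exceed every mode wavenumber")
  boltz <- 1 / (1 - exp(-.hc_over_kB * inv$nu / temperature))
  k <- (excitation - inv$nu)^4 / inv$nu * boltz
  out <- data.frame(
    nu = inv$nu,
    raman = k * (90 * inv$a2 + 14 * inv$beta_alpha2),
    roa = k * (4 / .c_au) * (12 * inv$beta_g2 + 4 * inv$beta_a2))
  class(out) <- c("stick_spectrum", "data.frame")
  out
}

#' Spectrum pair container (Raman + ROA on a common grid)
#'
#' @param grid strictly increasing wavenumber grid (cm^-1).
#' @param raman,roa intensity arrays (I_R + I_L and I_R - I_L).
#' @param meta named list of metadata (excitation, temperature, fwhm, ...).
#' @return object of class \code{spectrum_pair}.
#' @export
spectrum_pair <- function(grid, raman, roa, meta = list()) {
  stopifnot(length(grid) == length(raman), length(grid) == length(roa))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  structure(list(grid = as.numeric(grid), raman = as.numeric(raman),
                 roa = as.numeric(roa), meta = meta),
            class = "spectrum_pair")
}

#' @export
print.spectrum_pair <- function(x, ...) {
  cat(sprintf(
    "spectrum_pair: %d points, %.0f..%.0f cm^-1; max Raman %.3g, max |ROA| %.3g\n",
    length(x$grid), min(x$grid), max(x$grid), max(x$raman),
    max(abs(x$roa))))
  invisible(x)
}

#' Convolve a stick spectrum with unit-area Lorentzians
#'
#' Each stick contributes \code{weight * L(nu; nu_p, Gamma)} with the
#' unit-area Lorentzian \code{L = (Gamma/pi) / ((nu - nu_p)^2 + Gamma^2)}
#' and \code{Gamma = fwhm/2}.
#'
#' @param sticks a [backscatter_sticks()] result (columns \code{nu},
#'   \code{raman}, \code{roa}).
#' @param fwhm full width at half maximum in cm^-1 (default 10).
#' @param grid wavenumber grid; must cover all sticks by at least 5 fwhm.
#' @param drop_outside if TRUE, sticks not covered by the grid (+/- 5 fwhm)
#'   are silently dropped instead of raising an error; used when
#'   synthesizing a fixed display window from a full mode list.
#' @param meta extra metadata stored on the result.
#' @return a [spectrum_pair()].
#' @export
convolve_sticks <- function(sticks, fwhm = 10, grid = seq(50, 1800, by = 1),
                            drop_outside = FALSE, meta = list()) {
  stopifnot(fwhm > 0)
  uncovered <- sticks$nu - 5 * fwhm < min(grid) |
    sticks$nu + 5 * fwhm > max(grid)
  if (any(uncovered)) {
    if (drop_outside) sticks <- sticks[!uncovered, , drop = FALSE]
    else stop("grid too narrow: must cover all sticks +/- 5 fwhm")
  }
  gam <- fwhm / 2
  raman <- numeric(length(grid))
  roa <- numeric(length(grid))
  for (p in seq_len(nrow(sticks))) {
    L <- (gam / pi) / ((grid - sticks$nu[p])^2 + gam^2)
    raman <- raman + sticks$raman[p] * L
    roa <- roa + sticks$roa[p] * L
  }
  spectrum_pair(grid, raman, roa,
                meta = c(list(fwhm = fwhm), meta))
}

#' Average spectra over snapshots
#'
#' Unweighted pointwise mean of the Raman and ROA arrays across snapshots.
#'
#' @param spectra list of [spectrum_pair()] objects on identical grids.
#' @return a [spectrum_pair()].
#' @export
average_snapshots <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  g0 <- spectra[[1]]$grid
  for (s in spectra)
    if (!isTRUE(all.equal(s$grid, g0, tolerance = 1e-12)))
      stop("snapshot spectra are not on identical grids")
  raman <- rowMeans(vapply(spectra, `[[`, g0, "raman"))
  roa <- rowMeans(vapply(spectra, `[[`, g0, "roa"))
  spectrum_pair(g0, raman, roa, meta = c(spectra[[1]]$meta,
                                         list(n_averaged = length(spectra))))
}

#' Write a spectrum pair as 3-column TSV
#'
#' Columns wavenumber, Raman, ROA, preceded by \code{# key: value} metadata
#' header lines.
#'
#' @param pair a [spectrum_pair()].
#' @param file output path.
#' @export
write_spectrum <- function(pair, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(pair$meta))
    writeLines(sprintf("# %s: %s", k, format(pair$meta[[k]])), con)
  writeLines("# wavenumber\traman\troa", con)
  writeLines(sprintf("%.6g\t%.10g\t%.10g", pair$grid, pair$raman, pair$roa),
             con)
  invisible(file)
}

#' Read a 3-column TSV spectrum (comment-tolerant)
#'
#' @param file path written by [write_spectrum()] (or any 3-column
#'   whitespace-separated file; \code{#} lines are ignored).
#' @return a [spectrum_pair()].
#' @export
read_spectrum <- function(file) {
  d <- utils::read.table(file, comment.char = "#", col.names =
                           c("wavenumber", "raman", "roa"))
  spectrum_pair(d$wavenumber, d$raman, d$roa)
}
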