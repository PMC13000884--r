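test_that("torsions reproduce planar references and the IUPAC sign", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(c(0, -1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, 1, 0))), 180)
  ## +90 reference: p1 on +y, p4 on +z around a +x central bond
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 0, 1)), 90)
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), "degenerate")
  expect_error(dihedral_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              c(2, 0, 0)), "degenerate")
})

test_that("random torsions match the frame-construction oracle", {
  worst <- 0
  for (i in 1:1000) {
    p <- with_seed(i, lapply(1:4, function(k) stats::rnorm(3) * 2))
    d1 <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    d2 <- dihedral_oracle(p[[1]], p[[2]], p[[3]], p[[4]])
    dd <- abs(d1 - d2)
    worst <- max(worst, min(dd, 360 - dd))
  }
  expect_lt(worst, 1e-9)
})

test_that("torsions are rigid-motion invariant and reflection odd", {
  p <- with_seed(5, lapply(1:4, function(k) stats::rnorm(3) * 3))
  d0 <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  R <- random_rotation(6)
  t <- c(1, -2, 0.5)
  pr <- lapply(p, function(v) as.vector(R %*% v) + t)
  expect_equal(dihedral_angle(pr[[1]], pr[[2]], pr[[3]], pr[[4]]), d0,
               tolerance = 1e-9)
  pm <- lapply(p, function(v) v * c(1, 1, -1))
  expect_equal(dihedral_angle(pm[[1]], pm[[2]], pm[[3]], pm[[4]]), -d0,
               tolerance = 1e-9)
})

test_that("measured dihedrals of built helices equal the build parameters", {
  g <- build_helix("(PPG)2", phi = -70, psi = 145)
  bd <- backbone_dihedrals(g)
  expect_lt(max(abs(bd$phi[!is.na(bd$phi)] + 70)), 1e-6)
  expect_lt(max(abs(bd$psi[!is.na(bd$psi)] - 145)), 1e-6)
})

test_that("a delta distribution occupies exactly one free-energy bin", {
  ds <- series_from_samples(rep(-75, 50), rep(150, 50))
  fes <- ramachandran_surface(ds, bins = 36)
  expect_equal(sum(is.finite(fes$free_energy)), 1)
  expect_equal(fes$free_energy[is.finite(fes$free_energy)], 0)
  expect_equal(sum(fes$counts), 50)
})

test_that("uniform angles give a flat surface within multinomial noise", {
  n_per_bin <- 100
  bins <- 12
  n <- bins * bins * n_per_bin
  ang <- with_seed(8, list(phi = stats::runif(n, -180, 180),
                           psi = stats::runif(n, -180, 180)))
  fes <- ramachandran_surface(series_from_samples(ang$phi, ang$psi),
                              bins = bins, temperature = 300)
  kT <- 0.0019872041 * 300
  expect_true(all(is.finite(fes$free_energy)))
  expect_lt(max(fes$free_energy), 3 * kT * sqrt(1 / n_per_bin) +
              2 * kT / sqrt(n_per_bin))
})

test_that("surfaces are invariant under snapshot relabeling", {
  ang <- with_seed(4, list(phi = stats::runif(500, -180, 180),
                           psi = stats::runif(500, -180, 180)))
  f1 <- ramachandran_surface(series_from_samples(ang$phi, ang$psi),
                             bins = 18)
  perm <- with_seed(5, sample(500))
  f2 <- ramachandran_surface(series_from_samples(ang$phi[perm],
                                                 ang$psi[perm]), bins = 18)
  expect_identical(f1$counts, f2$counts)
})

test_that("von Mises clouds are recovered at the PPII basin", {
  deg2rad <- pi / 180
  phi <- roacollagen:::.rvonmises(10000, -75 * deg2rad, 20) / deg2rad
  psi <- with_seed(31, roacollagen:::.rvonmises(10000, 150 * deg2rad,
                                                20) / deg2rad)
  fes <- ramachandran_surface(series_from_samples(phi, psi), bins = 36)
  imin <- which(fes$free_energy == 0, arr.ind = TRUE)[1, ]
  ctr <- (fes$edges[-1] + fes$edges[-length(fes$edges)]) / 2
  expect_lte(abs(ctr[imin[1]] - (-75)), 5)
  expect_lte(abs(ctr[imin[2]] - 150), 5)
  ## circular basin means recovered
  mean_ang <- function(x) atan2(mean(sin(x * deg2rad)),
                                mean(cos(x * deg2rad))) / deg2rad
  expect_lt(abs(mean_ang(phi) - (-75)), 2)
  expect_lt(abs(mean_ang(psi) - 150), 2)
})

test_that("fes export writes a readable matrix and metadata", {
  ds <- series_from_samples(rep(-75, 10), rep(150, 10))
  fes <- ramachandran_surface(ds, bins = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fes(fes, f)
  m <- as.matrix(utils::read.table(f, sep = "\t"))
  expect_equal(dim(m), c(12, 12))
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(meta$n_samples, 10)
})

test_that("segment lengths are constant on a rigid helix and scale affinely", {
  g <- build_helix("(PHG)3PHA")
  sl <- segment_lengths(list(g, g), "Pro-Hyp-Gly")
  expect_lt(diff(range(sl$lengths)), 1e-9)
  g2 <- g
  g2$xyz <- g$xyz * 1.1
  sl2 <- segment_lengths(list(g, g2), "Pro-Hyp-Gly")
  pops <- sort(unique(round(as.vector(sl2$lengths), 6)))
  expect_length(pops, 2)
  expect_equal(pops[2] / pops[1], 1.1, tolerance = 1e-6)
  expect_error(segment_lengths(list(g), "Ala-Ala-Ala"), "not found")
})

test_that("flexible-trajectory segment lengths center on the rigid value", {
  tr <- make_ppii_trajectory("(PHG)3PHA", 40, kappa = 500, seed = 6)
  rigid <- segment_lengths(list(build_helix("(PHG)3PHA")),
                           "Pro-Hyp-Gly")$lengths[1, 1]
  sl <- segment_lengths(tr$trajectory, "Pro-Hyp-Gly")
  lens <- as.vector(sl$lengths)
  se <- stats::sd(lens) / sqrt(length(lens))
  ## mean within a few standard errors plus the small flexibility bias
  expect_lt(abs(mean(lens) - rigid), max(4 * se, 0.05 * rigid))
  expect_gt(stats::sd(lens), 0)
})
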