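test_that("invariants obey isotropy and parity selection rules", {
  ss <- make_spring_system(5, connectivity = "network", seed = 8)
  n <- n_atoms(ss$geometry)
  nm <- normal_modes(ss$geometry, ss$hessian)
  ## isotropic alpha derivative, no chiral tensors
  ts <- property_tensor_set(
    hessian = ss$hessian,
    dipole_deriv = array(0, c(3, 3, n)),
    alpha_deriv = array(rep(as.vector(diag(3)),  3 * n), c(3, 3, 3, n)),
    gprime_deriv = array(0, c(3, 3, 3, n)),
    a_deriv = array(0, c(3, 3, 3, 3, n)))
  inv <- mode_invariants(nm, ts)
  expect_lt(max(abs(inv$beta_alpha2)), 1e-10 * max(inv$a2))
  expect_equal(inv$beta_g2, rep(0, nrow(inv)))
  expect_equal(inv$beta_a2, rep(0, nrow(inv)))
  ## a_p = (1/3) Tr alpha_p: alpha_deriv = I for every component sum
  expect_true(all(inv$a2 >= 0))
})

test_that("mirror-symmetric systems have vanishing chiral invariants", {
  ## planar geometry, tensors symmetrized under the mirror that fixes it
  xyz <- cbind(with_seed(3, matrix(stats::rnorm(10), 5, 2)), 0)
  g <- geometry(rep("C", 5), xyz, check = FALSE)
  ts0 <- make_chiral_tensors(g, seed = 4)
  tsm <- transform_tensor_set(ts0, diag(c(1, 1, -1)))
  sym <- ts0
  for (f in c("hessian", "dipole_deriv", "alpha_deriv", "gprime_deriv",
              "a_deriv"))
    sym[[f]] <- (ts0[[f]] + tsm[[f]]) / 2
  nm <- normal_modes(g, sym$hessian)
  inv <- mode_invariants(nm, sym)
  ## a planar spring network has no out-of-plane stiffness: its residual
  ## near-zero modes are arbitrary mixtures within the null space and are
  ## excluded, as they are from any spectrum
  inv <- inv[inv$nu > 1, , drop = FALSE]
  scale <- max(abs(inv$beta_alpha2))
  expect_lt(max(abs(inv$beta_g2)), 1e-10 * scale)
  expect_lt(max(abs(inv$beta_a2)), 1e-10 * scale)
})

test_that("invariants match the naive Levi-Civita oracle", {
  ss <- make_spring_system(6, connectivity = "network", seed = 2)
  ts <- make_chiral_tensors(ss$geometry, seed = 3)
  nm <- normal_modes(ss$geometry, ts$hessian)
  got <- mode_invariants(nm, ts)
  ref <- invariants_oracle(nm, ts)
  scale <- max(abs(as.matrix(ref[, -1])))
  expect_lt(max(abs(as.matrix(got[, -1]) - as.matrix(ref[, -1]))),
            1e-12 * scale)
})

test_that("the Boltzmann factor approaches one in the low-T limit", {
  inv <- data.frame(nu = 1000, a2 = 1, beta_alpha2 = 0, beta_g2 = 0,
                    beta_a2 = 0)
  cold <- backscatter_sticks(inv, temperature = 1)
  expect_equal(cold$raman, (18796.99 - 1000)^4 / 1000 * 90,
               tolerance = 1e-15)
  warm <- backscatter_sticks(inv, temperature = 300)
  expect_gt(warm$raman, cold$raman)   # thermal population only adds
})

test_that("achiral tensor sets give identically zero ROA sticks", {
  ss <- make_spring_system(5, connectivity = "network", seed = 6)
  ts <- make_chiral_tensors(ss$geometry, seed = 7)
  ts$gprime_deriv[] <- 0
  ts$a_deriv[] <- 0
  nm <- normal_modes(ss$geometry, ts$hessian)
  st <- backscatter_sticks(mode_invariants(nm, ts))
  expect_equal(st$roa, rep(0, nrow(st)))
  expect_true(all(st$raman > 0))
})

test_that("generator-scaled tensors land in the collagen CID regime", {
  meds <- maxs <- numeric(20)
  for (s in 1:20) {
    ss <- make_spring_system(7, connectivity = "network", seed = s)
    ts <- make_chiral_tensors(ss$geometry, seed = 1000 + s)
    nm <- normal_modes(ss$geometry, ts$hessian)
    st <- backscatter_sticks(mode_invariants(nm, ts))
    r <- abs(st$roa) / st$raman
    meds[s] <- stats::median(r)
    maxs[s] <- max(r)
  }
  expect_true(all(meds >= 3e-4 & meds <= 3e-3))
  expect_true(all(maxs >= 1e-4 & maxs <= 1e-2))
  ## physical bound |D_p| <= S_p holds comfortably
  expect_true(all(maxs < 1))
})

test_that("imaginary modes are excluded from sticks with a warning", {
  inv <- data.frame(nu = c(-50, 800), a2 = 1, beta_alpha2 = 0,
                    beta_g2 = 0, beta_a2 = 0)
  expect_warning(st <- backscatter_sticks(inv), "skipped")
  expect_equal(st$nu, 800)
  expect_error(backscatter_sticks(data.frame(nu = 2e4, a2 = 1,
                                             beta_alpha2 = 0, beta_g2 = 0,
                                             beta_a2 = 0)),
               "excitation")
})

test_that("Lorentzian convolution conserves area, height and linearity", {
  ## tails beyond a +/- 4500 cm^-1 window hold < 1e-3 of a 10 cm^-1 band
  grid <- seq(500, 9500, by = 0.5)
  one <- data.frame(nu = 5000, raman = 3.7, roa = -0.2)
  sp <- convolve_sticks(one, fwhm = 10, grid = grid)
  area <- sum(sp$raman) * 0.5
  expect_equal(area, 3.7, tolerance = 1e-3)
  expect_equal(max(sp$raman), 2 * 3.7 / (pi * 10), tolerance = 1e-3)
  ## two coincident sticks equal one of summed weight, pointwise
  two <- data.frame(nu = c(5000, 5000), raman = c(1.5, 2.2),
                    roa = c(-0.1, -0.1))
  sp2 <- convolve_sticks(two, fwhm = 10, grid = grid)
  sp1 <- convolve_sticks(data.frame(nu = 5000, raman = 3.7, roa = -0.2),
                         fwhm = 10, grid = grid)
  expect_lt(max(abs(sp2$raman - sp1$raman)), 1e-12 * max(sp1$raman))
  expect_error(convolve_sticks(one, fwhm = 10, grid = seq(4990, 5010, 1)),
               "too narrow")
})

test_that("snapshot averaging is an unweighted pointwise mean", {
  grid <- seq(800, 1200, 1)
  s1 <- convolve_sticks(data.frame(nu = 900, raman = 2, roa = 0.1),
                        fwhm = 10, grid = grid)
  s2 <- convolve_sticks(data.frame(nu = 1100, raman = 2, roa = -0.1),
                        fwhm = 10, grid = grid)
  expect_equal(average_snapshots(list(s1))$raman, s1$raman)
  expect_equal(average_snapshots(list(s1, s1, s1))$raman, s1$raman)
  avg <- average_snapshots(list(s1, s2))
  expect_equal(avg$raman, (s1$raman + s2$raman) / 2)
  ## each band sits at (essentially) half height in the mean
  i900 <- which(grid == 900)
  expect_equal(avg$raman[i900], s1$raman[i900] / 2, tolerance = 1e-3)
  bad <- spectrum_pair(seq(800, 1200, 2), numeric(201), numeric(201))
  expect_error(average_snapshots(list(s1, bad)), "grids")
})

test_that("averaging commutes with convolution", {
  grid <- seq(700, 1300, 1)
  st1 <- data.frame(nu = c(900, 950), raman = c(1, 2), roa = c(0.1, -0.2))
  st2 <- data.frame(nu = c(1100, 1050), raman = c(3, 1), roa = c(0.2, 0))
  mean_of_conv <- average_snapshots(list(
    convolve_sticks(st1, 10, grid), convolve_sticks(st2, 10, grid)))
  pooled <- rbind(st1, st2)
  pooled$raman <- pooled$raman / 2
  pooled$roa <- pooled$roa / 2
  conv_of_pool <- convolve_sticks(pooled, 10, grid)
  expect_lt(max(abs(mean_of_conv$raman - conv_of_pool$raman)),
            1e-12 * max(conv_of_pool$raman))
  expect_lt(max(abs(mean_of_conv$roa - conv_of_pool$roa)),
            1e-12 * max(abs(conv_of_pool$roa)))
})

test_that("enantiomeric input negates ROA and preserves Raman exactly", {
  ss <- make_spring_system(8, connectivity = "network", seed = 3)
  ts <- make_chiral_tensors(ss$geometry, seed = 5)
  tsm <- make_chiral_tensors(ss$geometry, seed = 5, mirror = TRUE)
  gm <- mirror_geometry(ss$geometry)
  grid <- seq(0, 4000, 1)
  sp <- convolve_sticks(suppressWarnings(backscatter_sticks(
    mode_invariants(normal_modes(ss$geometry, ts$hessian), ts))),
    grid = grid, drop_outside = TRUE)
  spm <- convolve_sticks(suppressWarnings(backscatter_sticks(
    mode_invariants(normal_modes(gm, tsm$hessian), tsm))),
    grid = grid, drop_outside = TRUE)
  expect_identical(sp$raman, spm$raman)
  expect_identical(sp$roa, -spm$roa)
})

test_that("rigid rotation leaves frequencies and spectra invariant", {
  ss <- make_spring_system(8, connectivity = "network", seed = 3)
  ts <- make_chiral_tensors(ss$geometry, seed = 5)
  R <- random_rotation(12)
  gr <- transform_geometry(ss$geometry, R, c(3, -2, 7))
  tsr <- transform_tensor_set(ts, R)
  nm <- normal_modes(ss$geometry, ts$hessian)
  nmr <- normal_modes(gr, tsr$hessian)
  expect_lt(max(abs(nm$frequencies - nmr$frequencies)), 1e-6)
  grid <- seq(0, 4000, 1)
  sp <- convolve_sticks(suppressWarnings(backscatter_sticks(
    mode_invariants(nm, ts))), grid = grid, drop_outside = TRUE)
  spr <- convolve_sticks(suppressWarnings(backscatter_sticks(
    mode_invariants(nmr, tsr))), grid = grid, drop_outside = TRUE)
  expect_lt(max(abs(sp$raman - spr$raman)), 1e-8 * max(sp$raman))
  expect_lt(max(abs(sp$roa - spr$roa)), 1e-8 * max(abs(sp$roa)))
})

test_that("spectrum TSV files round-trip through the tolerant reader", {
  grid <- seq(400, 1700, 1)
  sp <- convolve_sticks(data.frame(nu = 1000, raman = 1, roa = 1e-3),
                        fwhm = 10, grid = grid,
                        meta = list(fwhm = 10, temperature = 300))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$grid, sp$grid)
  expect_equal(back$raman, sp$raman, tolerance = 1e-9)
  expect_equal(back$roa, sp$roa, tolerance = 1e-9)
})
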