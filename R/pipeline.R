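## End-to-end orchestration: build -> fragment -> synthetic tensors ->
## transfer to snapshots -> spectra -> average -> analyze, with a JSON
## manifest carrying parameters and checksums.

#' Pipeline run configuration
#'
#' @param sequence triplet-notation string (e.g. \code{"(PHG)9PHA"}).
#' @param n_chains 1 or 3.
#' @param phi,psi build dihedrals in degrees.
#' @param window amide units per fragment.
#' @param n_snapshots number of synthetic conformational snapshots.
#' @param kappa von Mises concentration of the snapshot dihedrals.
#' @param roa_scale target median per-mode |ROA/Raman| of the synthetic
#'   tensors.
#' @param fwhm Lorentzian FWHM in cm^-1.
#' @param temperature temperature in K.
#' @param excitation excitation wavenumber in cm^-1.
#' @param grid_min,grid_max,grid_step spectral grid in cm^-1.
#' @param n_neighbors transfer neighborhood size.
#' @param seed master RNG seed.
#' @param outdir output directory.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(sequence = "(PHG)9PHA", n_chains = 3, phi = -75,
                       psi = 150, window = 4, n_snapshots = 10,
                       kappa = 200, roa_scale = 1e-3, fwhm = 10,
                       temperature = 300, excitation = 18796.99,
                       grid_min = 50, grid_max = 1800, grid_step = 1,
                       n_neighbors = 12, seed = 1, outdir = "roa_run") {
  structure(as.list(environment()), class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config a [run_config()].
#' @param file path.
#' @export
write_run_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(run_config, obj)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full simulation pipeline
#'
#' Executes build, fragment, synthetic tensor generation, transfer onto
#' conformational snapshots, harmonic spectral synthesis, snapshot
#' averaging and spectral analysis, writing every artifact plus a JSON
#' manifest (parameters, file list, md5 checksums) into
#' \code{config$outdir}. Deterministic for a fixed configuration.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return the manifest as a list, invisibly; the manifest is also written
#'   to \code{manifest.json}.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- seq(cfg$grid_min, cfg$grid_max, by = cfg$grid_step)

  say("stage build: %s, %d chain(s)", cfg$sequence, cfg$n_chains)
  seqO <- .stage("build", parse_triplet_notation(cfg$sequence))
  parent <- .stage("build", build_helix(seqO, phi = cfg$phi, psi = cfg$psi,
                                        n_chains = cfg$n_chains))
  write_pdb_geometry(parent, file.path(cfg$outdir, "helix.pdb"))
  write_xyz(parent, file.path(cfg$outdir, "helix.xyz"))

  say("stage fragment: window %d", cfg$window)
  scheme <- .stage("fragment", fragment_molecule(parent, cfg$window))
  write_fragments(scheme, file.path(cfg$outdir, "frags"))

  say("stage tensors: %d fragments", length(scheme$fragments))
  frag_sets <- .stage("tensors", lapply(seq_along(scheme$fragments),
    function(k) {
      fr <- scheme$fragments[[k]]
      list(fragment = fr,
           tensors = make_chiral_tensors(fr$geometry,
                                         roa_scale = cfg$roa_scale,
                                         seed = cfg$seed + 1000 + k))
    }))

  say("stage snapshots: %d snapshots, kappa = %g", cfg$n_snapshots,
      cfg$kappa)
  snaps <- .stage("snapshots", lapply(seq_len(cfg$n_snapshots),
    function(s) {
      tr <- make_ppii_trajectory(seqO, 1, kappa = cfg$kappa,
                                 means = c(cfg$phi, cfg$psi),
                                 seed = cfg$seed + 2000 + s)
      ph <- tr$truth$phi[1, ]; ps <- tr$truth$psi[1, ]
      g <- build_helix(seqO, phi = ph, psi = ps, n_chains = cfg$n_chains,
                       check_clash = FALSE)
      g
    }))
  write_xyz(snaps, file.path(cfg$outdir, "snapshots.xyz"),
            comment = sprintf("snapshot %d", seq_len(cfg$n_snapshots)))

  say("stage transfer + spectra")
  spec_files <- character(0)
  spectra <- .stage("spectrum", lapply(seq_along(snaps), function(s) {
    ts <- transfer_tensors(frag_sets, snaps[[s]],
                           n_neighbors = cfg$n_neighbors)
    nm <- normal_modes(snaps[[s]], ts$hessian)
    inv <- mode_invariants(nm, ts, excitation = cfg$excitation)
    st <- suppressWarnings(
      backscatter_sticks(inv, excitation = cfg$excitation,
                         temperature = cfg$temperature))
    sp <- convolve_sticks(st, fwhm = cfg$fwhm, grid = grid,
                          drop_outside = TRUE,
                          meta = list(snapshot = s, seed = cfg$seed))
    fn <- file.path(cfg$outdir, sprintf("snap_%03d.tsv", s))
    write_spectrum(sp, fn)
    spec_files <<- c(spec_files, fn)
    sp
  }))

  say("stage average")
  mean_sp <- .stage("average", average_snapshots(spectra))
  write_spectrum(mean_sp, file.path(cfg$outdir, "mean.tsv"))

  say("stage analyze")
  report <- .stage("analyze", {
    bands_r <- detect_bands(mean_sp$raman, mean_sp$grid,
                            0.02 * max(mean_sp$raman))
    bands_o <- detect_bands(mean_sp$roa, mean_sp$grid,
                            0.1 * max(abs(mean_sp$roa)), signed = TRUE)
    cup <- tryCatch(unclass(couplet_stats(mean_sp, c(1600, 1700))),
                    error = function(e) list(error = conditionMessage(e)))
    list(raman_bands = bands_r, roa_bands = bands_o, amide_I_couplet = cup)
  })
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  write_run_config(cfg, file.path(cfg$outdir, "config.json"))
  files <- c("helix.pdb", "helix.xyz", "frags/manifest.json",
             basename(spec_files), "mean.tsv", "report.json", "config.json")
  sums <- tools::md5sum(file.path(cfg$outdir, files))
  manifest <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("roacollagen")),
      error = function(e) "dev"),
    parameters = unclass(cfg),
    files = data.frame(file = files, md5 = unname(sums)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("done: %s", cfg$outdir)
  invisible(manifest)
}
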