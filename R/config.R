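#' Run a full simulation from a YAML configuration
#'
#' Orchestrates an end-to-end run -- filterbank, source prior, HRTF
#' subjects, direction grid, ripple and/or flat-spectrum experiments --
#' from a declarative YAML file, writing CSV result tables, a JSON prior
#' container, optional PNG figures, and a manifest (package version,
#' config hash, seeds) from which every number is reproducible.
#'
#' Config schema (see the bundled `inst/extdata/quickstart.yaml`):
#' ```yaml
#' seed: 1
#' output_dir: out            # optional; override with the out_dir arg
#' filterbank: {f_lo: 300, f_hi: 12000, spacing_erb: 1}
#' grid: {n_directions: 2000, min_elevation_deg: -45,
#'        region: {max_lateral_deg: 30, max_polar_band_deg: 60}}
#' hrtf: {type: synthetic, n_subjects: 20}      # or {type: sofa, paths: [...]}
#' prior: {type: synthetic, n_frames: 20000}    # or {type: corpus, dir: ...}
#'                                              # or {type: narrow, sigma_db: 3.5}
#' noise: {sigma_itd_jnd: 1, sigma_channel_db: 1}
#' experiments:
#'   ripple: {representations: [ISD, BIN_SG], depth_db: [40],
#'            density: [0.25, 1, 8], phase: [0]}
#'   flat:   {variants: [ISD, BIN_SG]}
#' plots: false
#' ```
#'
#' @param path Path to the YAML config.
#' @param out_dir Output directory (overrides `output_dir` in the file).
#' @return (Invisibly) a list with the computed objects and the manifest.
#' @export
run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  need <- function(x, field, parent) {
    if (is.null(x)) stop("config field missing: ", parent, "$", field)
    x
  }
  out_dir <- out_dir %||% cfg$output_dir %||% stop("config field missing: output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1)
  t0 <- Sys.time()
  log_line <- function(...) message(sprintf("[%s] %s",
                                            format(Sys.time(), "%H:%M:%S"),
                                            sprintf(...)))

  fbc <- cfg$filterbank %||% list()
  fb <- make_filterbank(fbc$f_lo %||% 300, fbc$f_hi %||% 12000,
                        fbc$spacing_erb %||% 1)
  log_line("filterbank: %d channels", fb$n_channels)

  gc_ <- cfg$grid %||% list()
  grid <- uniform_sphere_grid(gc_$n_directions %||% 2000, seed = seed)
  grid <- filter_grid(grid, gc_$min_elevation_deg %||% -45)
  regc <- gc_$region %||% list()
  region_idx <- which(region_mask(grid, regc$max_lateral_deg %||% 30,
                                  regc$max_polar_band_deg %||% 60))
  log_line("grid: %d directions, %d in region", grid$n, length(region_idx))

  hc <- cfg$hrtf %||% list(type = "synthetic")
  hrtfs <- switch(need(hc$type, "type", "hrtf"),
    synthetic = synth_hrtf_cohort(grid, fb, hc$n_subjects %||% 20,
                                  seed = derive_seed(seed, 7)),
    sofa = lapply(need(hc$paths, "paths", "hrtf"), load_sofa, fb = fb),
    stop("unknown hrtf$type: '", hc$type, "'"))
  log_line("hrtf: %d subjects (%s)", length(hrtfs), hc$type)

  pc <- cfg$prior %||% list(type = "synthetic")
  prior <- switch(need(pc$type, "type", "prior"),
    synthetic = build_prior(synth_corpus(fb, pc$n_frames %||% 20000,
                                         seed = derive_seed(seed, 11)),
                            provenance = "synthetic"),
    corpus = {
      files <- list.files(need(pc$dir, "dir", "prior"), "\\.wav$",
                          full.names = TRUE, ignore.case = TRUE)
      build_prior(corpus_logmag(chop_corpus(files), fb),
                  provenance = basename(pc$dir))
    },
    narrow = narrow_prior(rep(0, fb$n_channels), pc$sigma_db %||% 3.5),
    container = read_prior_json(need(pc$path, "path", "prior")),
    stop("unknown prior$type: '", pc$type, "'"))
  write_prior_json(prior, file.path(out_dir, "prior.json"), fb)
  log_line("prior: %s (SG std %.2f dB/ERB)", prior$provenance,
           sg_prior_std(prior))

  nc <- cfg$noise %||% list()
  noise <- noise_model(nc$sigma_itd_jnd %||% 1, nc$sigma_channel_db %||% 1)

  known_reps <- c("LOGMAG", "ISD", "BIN_SG", "POS_SG", "IPSI_SG")
  results <- list()
  ex <- cfg$experiments %||% list()
  if (!is.null(ex$ripple)) {
    rc <- ex$ripple
    reps <- unlist(need(rc$representations, "representations", "ripple"))
    bad <- setdiff(reps, known_reps)
    if (length(bad)) stop("unknown representation tag: '", bad[1], "'")
    conds <- expand.grid(depth_db = unlist(rc$depth_db %||% 40),
                         density = unlist(rc$density %||% 1),
                         phase = unlist(rc$phase %||% 0))
    results$ripple <- run_ripple_experiment(
      hrtfs, prior, reps, conds, region_idx, noise,
      seed = derive_seed(seed, 21), n_rep = rc$n_rep %||% 1)
    write.csv(results$ripple, file.path(out_dir, "ripple_summary.csv"),
              row.names = FALSE)
    log_line("ripple experiment: %d conditions", nrow(conds))
  }
  if (!is.null(ex$flat)) {
    fc <- ex$flat
    vr <- unlist(need(fc$variants, "variants", "flat"))
    bad <- setdiff(vr, known_reps)
    if (length(bad)) stop("unknown representation tag: '", bad[1], "'")
    variants <- lapply(vr, function(r)
      list(representation = r, source = if (r == "ISD") NULL else prior))
    names(variants) <- vr
    results$flat <- run_flat_experiment(hrtfs, variants,
                                        dirs_idx = region_idx, noise = noise,
                                        n_rep = fc$n_rep %||% 1,
                                        seed = derive_seed(seed, 22))
    write.csv(results$flat, file.path(out_dir, "flat_summary.csv"),
              row.names = FALSE)
    log_line("flat experiment: %d variants", length(variants))
  }

  if (isTRUE(cfg$plots)) {
    png(file.path(out_dir, "prior_covariance.png"), 700, 700)
    plot_prior_covariance(to_sg_prior(prior))
    dev.off()
    if (!is.null(results$ripple) && length(unique(results$ripple$density)) > 1) {
      png(file.path(out_dir, "error_rate_vs_density.png"), 700, 500)
      plot_error_rate_curves(results$ripple, "density")
      dev.off()
    }
  }

  manifest <- list(
    package = "soundloc",
    version = as.character(packageVersion("soundloc")),
    config = cfg,
    config_md5 = unname(tools::md5sum(path)),
    config_file = normalizePath(path),
    output_dir = normalizePath(out_dir),
    seed = seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_line("done in %.1f s", manifest$elapsed_s)
  invisible(list(filterbank = fb, grid = grid, region_idx = region_idx,
                 hrtfs = hrtfs, prior = prior, noise = noise,
                 results = results, manifest = manifest))
}
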