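#' Rippled-spectrum stimulus
#'
#' Log-magnitude spectrum modulated as a cosine of log-frequency,
#' evaluated at the filterbank centre frequencies:
#' `(A/2) cos(2 pi rho log2(f / f_ref) + phi)`, where `depth_db` is the
#' peak-to-trough amplitude A (dB), `density` the ripple density rho in
#' ripples/octave and `phase` phi in radians.
#'
#' @param fb An [make_filterbank()].
#' @param depth_db Peak-to-trough amplitude A in dB (>= 0).
#' @param density Ripple density in ripples/octave (>= 0).
#' @param phase Ripple phase in radians.
#' @param f_ref_hz Reference frequency for the log-frequency origin.
#' @return Per-channel spectrum (dB), zero-mean flat when `depth_db = 0`.
#' @export
ripple_spectrum <- function(fb, depth_db, density, phase = 0, f_ref_hz = 1000) {
  stopifnot(inherits(fb, "erb_filterbank"))
  if (depth_db < 0 || density < 0) stop("depth and density must be >= 0")
  (depth_db / 2) * cos(2 * pi * density *
                         log2(fb$centre_frequencies_hz / f_ref_hz) + phase)
}

#' Standard deviation of a stimulus' spectral gradient
#'
#' `sd(sg(x))` in dB per channel step: the summary that predicts when a
#' stimulus is "too unexpected" for the listener's gradient prior.
#'
#' @param x Per-channel spectrum (length >= 3).
#' @return Scalar, dB/ERB step.
#' @export
sg_std <- function(x) {
  if (length(x) < 3) stop("need at least 3 channels")
  sd(sg(x))
}

#' Simulate localization trials
#'
#' For each presented direction the observation is built from the true
#' direction's HRTF filtering of the actual stimulus spectrum -- stacked
#' `[itd_jnd; HRTF_l + S; HRTF_r + S]` -- plus measurement noise drawn
#' from the noise part of the model only (the source-uncertainty part of
#' the covariance is never sampled: the stimulus is what it is), then
#' decoded by the MAP criterion.
#'
#' @param model A [decoder_model()].
#' @param hrtf The [hrtf_set()] used as the true filtering (normally the
#'   one the decoder was built from).
#' @param stimulus_db Per-channel source spectrum (dB).
#' @param true_idx Vector of presented direction indices.
#' @param seed RNG seed; same seed, identical trials.
#' @param noise_draw If `FALSE`, no measurement noise is added (the
#'   zero-noise observer).
#' @return Data frame of [trial records][polar_error_rate]: columns
#'   `true_idx`, `resp_idx`, `representation`.
#' @export
simulate_trials <- function(model, hrtf, stimulus_db, true_idx, seed = 1,
                            noise_draw = TRUE) {
  stopifnot(inherits(model, "decoder_model"), inherits(hrtf, "hrtf_set"))
  if (hrtf$grid$n != model$grid$n)
    stop("decoder and HRTF set must share the direction grid")
  if (length(stimulus_db) != hrtf$fb$n_channels)
    stop("stimulus length does not match the filterbank")
  m <- length(true_idx)
  raw <- rbind(itd_to_jnd(hrtf$itd_us[true_idx], model$itd_curve),
               t(sweep(hrtf$logmag_left[true_idx, , drop = FALSE], 2,
                       -stimulus_db)),
               t(sweep(hrtf$logmag_right[true_idx, , drop = FALSE], 2,
                       -stimulus_db)))
  if (noise_draw) {
    sd_raw <- raw_noise_sd(model$noise, hrtf$fb)
    raw <- raw + with_seed(seed,
                           matrix(rnorm(length(raw), sd = sd_raw), nrow(raw)))
  }
  resp <- decode_map(model, featurize(model$fmap, raw))
  data.frame(true_idx = as.integer(true_idx), resp_idx = as.integer(resp),
             representation = model$representation)
}

#' @rdname simulate_trials
#' @param true_dir A single direction index.
#' @export
simulate_trial <- function(model, hrtf, stimulus_db, true_dir, seed = 1,
                           noise_draw = TRUE) {
  simulate_trials(model, hrtf, stimulus_db, true_dir, seed, noise_draw)
}

# wrapped absolute polar-angle difference, range [0, 180]
wrap_polar_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Polar error rate
#'
#' Proportion of responses whose wrapped polar-angle error exceeds
#' `threshold_deg` (default 45 degrees).  Optionally, trials whose
#' lateral error exceeds `exclude_lateral_deg` are excluded first (the
#' benchmark convention in which gross lateral confusions do not count
#' as polar errors); the default scores all trials.
#'
#' @param trials Data frame with `true_idx` and `resp_idx` columns (as
#'   from [simulate_trials()]).
#' @param grid The [direction_grid()] the indices refer to.
#' @param threshold_deg Polar error threshold, degrees (> 0).
#' @param exclude_lateral_deg Optional lateral-error exclusion threshold.
#' @return Proportion in \[0, 1\].
#' @export
polar_error_rate <- function(trials, grid, threshold_deg = 45,
                             exclude_lateral_deg = NULL) {
  stopifnot(inherits(grid, "direction_grid"))
  if (threshold_deg <= 0) stop("threshold must be > 0")
  if (nrow(trials) == 0) stop("no trials")
  t_i <- trials$true_idx; r_i <- trials$resp_idx
  if (!is.null(exclude_lateral_deg)) {
    lat_err <- abs(grid$lateral_deg[t_i] - grid$lateral_deg[r_i])
    keep <- lat_err <= exclude_lateral_deg
    if (!any(keep)) stop("lateral exclusion removed every trial")
    t_i <- t_i[keep]; r_i <- r_i[keep]
  }
  err <- wrap_polar_diff(grid$polar_deg[t_i], grid$polar_deg[r_i])
  mean(err > threshold_deg)
}

#' Ripple-stimulus Monte-Carlo experiment
#'
#' For every combination of representation and ripple condition, presents
#' each region direction once per subject (a fresh noise realization per
#' trial) and pools the polar error rate over subjects and directions
#' into a single value per condition.
#'
#' @param hrtfs List of [hrtf_set()] subjects (all on the same grid).
#' @param source A `LOGMAG` [source_prior()] (ignored by the ISD
#'   observer).
#' @param representations Character vector of representation tags.
#' @param conditions Data frame with columns `depth_db`, `density`,
#'   `phase` (one row per ripple condition).
#' @param region_idx Indices of the presented directions (e.g.
#'   `which(region_mask(grid))`).
#' @param noise A [noise_model()].
#' @param seed Master seed; per-subject/condition noise streams are
#'   derived from it.
#' @param n_rep Noise realizations per direction (default 1, as in a
#'   single-pass experiment).
#' @param per_subject Also return per-subject rates.
#' @param threshold_deg,exclude_lateral_deg Passed to
#'   [polar_error_rate()].
#' @return Data frame with one row per representation x condition:
#'   `representation`, `depth_db`, `density`, `phase`, `error_rate`,
#'   `n_trials` (and `subject` if `per_subject`).
#' @export
run_ripple_experiment <- function(hrtfs, source, representations, conditions,
                                  region_idx, noise = noise_model(), seed = 1,
                                  n_rep = 1, per_subject = FALSE,
                                  threshold_deg = 45,
                                  exclude_lateral_deg = NULL) {
  stopifnot(is.list(hrtfs), length(hrtfs) >= 1)
  grid <- hrtfs[[1]]$grid
  fb <- hrtfs[[1]]$fb
  out <- list()
  for (rep_tag in representations) {
    decoders <- lapply(hrtfs, decoder_model, source = source,
                       representation = rep_tag, noise = noise)
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      stim <- ripple_spectrum(fb, cond$depth_db, cond$density, cond$phase)
      rows <- lapply(seq_along(hrtfs), function(s) {
        tr <- lapply(seq_len(n_rep), function(r)
          simulate_trials(decoders[[s]], hrtfs[[s]], stim, region_idx,
                          seed = derive_seed(seed, match(rep_tag, representations),
                                             ci, s, r)))
        do.call(rbind, tr)
      })
      if (per_subject) {
        for (s in seq_along(rows))
          out[[length(out) + 1L]] <- data.frame(
            representation = rep_tag, subject = hrtfs[[s]]$subject_id,
            depth_db = cond$depth_db, density = cond$density,
            phase = cond$phase,
            error_rate = polar_error_rate(rows[[s]], grid, threshold_deg,
                                          exclude_lateral_deg),
            n_trials = nrow(rows[[s]]))
      }
      pooled <- do.call(rbind, rows)
      out[[length(out) + 1L]] <- data.frame(
        representation = rep_tag,
        subject = if (per_subject) "pooled" else NA_character_,
        depth_db = cond$depth_db, density = cond$density, phase = cond$phase,
        error_rate = polar_error_rate(pooled, grid, threshold_deg,
                                      exclude_lateral_deg),
        n_trials = nrow(pooled))
    }
  }
  res <- do.call(rbind, out)
  if (!per_subject) res$subject <- NULL
  rownames(res) <- NULL
  res
}

#' Flat-spectrum localization error map
#'
#' Presents a flat (all-zero dB) spectrum from every requested direction
#' and maps the mean great-circle error per true direction for each
#' decoder variant (e.g. ISD baseline, narrow prior, binaural /
#' ipsilateral / positive gradient with an ecological prior).
#'
#' @param hrtfs List of [hrtf_set()] subjects.
#' @param variants Named list; each element is a list with `representation`
#'   and `source` (a [source_prior()] or `NULL`).
#' @param dirs_idx Presented direction indices (default: all grid
#'   directions).
#' @param noise A [noise_model()].
#' @param n_rep Noise realizations per direction per subject.
#' @param seed Master seed.
#' @return Data frame: `variant`, `dir_idx`, `lateral_deg`, `polar_deg`,
#'   `mean_gc_error_deg`, `n`.
#' @export
run_flat_experiment <- function(hrtfs, variants, dirs_idx = NULL,
                                noise = noise_model(), n_rep = 1, seed = 1) {
  stopifnot(is.list(hrtfs), length(hrtfs) >= 1)
  grid <- hrtfs[[1]]$grid
  fb <- hrtfs[[1]]$fb
  if (is.null(dirs_idx)) dirs_idx <- seq_len(grid$n)
  flat <- rep(0, fb$n_channels)
  if (is.null(names(variants)))
    names(variants) <- vapply(variants, function(v) v$representation, "")
  out <- list()
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    err_sum <- numeric(length(dirs_idx)); n_tr <- 0L
    for (s in seq_along(hrtfs)) {
      dec <- decoder_model(hrtfs[[s]], v$source, v$representation, noise)
      for (r in seq_len(n_rep)) {
        tr <- simulate_trials(dec, hrtfs[[s]], flat, dirs_idx,
                              seed = derive_seed(seed, 500 + vi, s, r))
        err_sum <- err_sum + great_circle_error(tr$true_idx, tr$resp_idx, grid)
        n_tr <- n_tr + 1L
      }
    }
    out[[vi]] <- data.frame(variant = names(variants)[vi], dir_idx = dirs_idx,
                            lateral_deg = grid$lateral_deg[dirs_idx],
                            polar_deg = grid$polar_deg[dirs_idx],
                            mean_gc_error_deg = err_sum / n_tr, n = n_tr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Response distribution and attractor direction
#'
#' Histogram of response indices over the grid for a set of trials
#' (typically uniform presentation of all directions), plus the
#' "attractor": the direction drawing the most responses.
#'
#' @param trials Data frame with a `resp_idx` column.
#' @param grid The [direction_grid()].
#' @return List with `counts` (length `grid$n`, sums to the number of
#'   trials) and `attractor` (index of the modal response direction).
#' @export
response_distribution <- function(trials, grid) {
  stopifnot(inherits(grid, "direction_grid"))
  if (nrow(trials) < 1) stop("need at least one trial")
  counts <- tabulate(trials$resp_idx, nbins = grid$n)
  list(counts = counts, attractor = which.max(counts))
}

#' Spectral-gradient templates of an attractor direction
#'
#' Convenience accessor for attractor analyses: the left/right gradient
#' templates of one direction of a gradient-representation decoder,
#' alongside the gradient of a stimulus.
#'
#' @param model A `BIN_SG`-family [decoder_model()].
#' @param dir_idx Direction index.
#' @param stimulus_db Optional stimulus spectrum whose gradient is
#'   returned alongside.
#' @return List with `sg_left`, `sg_right`, and optionally `sg_stimulus`.
#' @export
attractor_templates <- function(model, dir_idx, stimulus_db = NULL) {
  stopifnot(inherits(model, "decoder_model"))
  if (length(model$fmap$sg_rows) == 0)
    stop("representation has no spectral-gradient block")
  res <- list(sg_left = model$templates[model$fmap$left_rows, dir_idx],
              sg_right = model$templates[model$fmap$right_rows, dir_idx])
  if (!is.null(stimulus_db)) res$sg_stimulus <- sg(stimulus_db)
  res
}
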