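# Frequency-sweep orchestration: forward fields -> Jacobians -> operators
# -> PSF simulation per seed voxel -> image-quality summaries, for every
# modulation frequency, measurement set (NN3/NN4) and noise state.

#' Default sweep configuration
#'
#' All tunable parameters of the simulation study in one nested list.
#' Defaults give the desk-scale study: 2-mm voxel slab, 7x7 checkerboard
#' array at 13-mm pitch, 11 frequencies from continuous wave to 1000 MHz,
#' one noise realization per seed voxel, seed voxels on an 8-mm lateral
#' lattice spanning all ROI depths.
#'
#' @param ... Named overrides of top-level entries (partial lists are
#'   merged).
#' @return A `dot_sweep_config` nested list.
#' @export
sweep_config <- function(...) {
  cfg <- list(
    frequencies = seq(0, 1000, by = 100),
    wavelengths = c(690, 850),
    nn_sets = c(3, 4),
    noise_states = c("off", "on"),
    master_seed = 1,
    realizations = 1,
    phantom = list(layer_thicknesses = c(scalp = 4, skull = 7, CSF = 2, gray = 4),
                   lateral_extent = 120, depth_extent = 60, voxel_size = 2,
                   refractive_index = 1.4),
    array = list(pitch = 13, n_rows = 7, n_cols = 7),
    roi = list(lateral_margin = 10, sensitivity_floor = 1e-5),
    regularization = list(lambda1_rel = 0.01, lambda2_rel = 0.1, form = "sqrt"),
    noise = list(params = default_noise_params(), coupled = TRUE, scale = 0.0015),
    perturbation = c(dHbO2 = 3.8, dHbR = -1.8),
    extinction = NULL,   # NULL -> extinction_matrix() defaults
    seeds = list(mode = "grid", lateral_spacing = 8),
    metrics = list(le_cutoff = 8, bin_width = 1, fbt_cutoffs = 1:8)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("dot_sweep_config", "list"))
}

#' Pick seed voxels within the ROI
#' @keywords internal
select_seeds <- function(roi, seeds_cfg, voxel_size) {
  if (seeds_cfg$mode == "profile") {
    cx <- stats::median(roi$coords[, 1]); cy <- stats::median(roi$coords[, 2])
    d2 <- (roi$coords[, 1] - cx)^2 + (roi$coords[, 2] - cy)^2
    near <- which.min(d2)
    sel <- which(roi$coords[, 1] == roi$coords[near, 1] &
                   roi$coords[, 2] == roi$coords[near, 2])
    rep_lat <- voxel_size^2
  } else {
    sp <- seeds_cfg$lateral_spacing
    x0 <- min(roi$coords[, 1]); y0 <- min(roi$coords[, 2])
    onx <- abs((roi$coords[, 1] - x0) %% sp) < 1e-9
    ony <- abs((roi$coords[, 2] - y0) %% sp) < 1e-9
    sel <- which(onx & ony)
    rep_lat <- sp^2
  }
  list(idx = sel, rep_volume = rep_lat * voxel_size)
}

#' Row subset of a Jacobian for a cumulative NN class
#' @keywords internal
subset_jacobian <- function(jac, max_nn) {
  keep_ch <- which(jac$channels$nn <= max_nn)
  nc <- jac$n_channels
  rows <- if (jac$frequency == 0) keep_ch else c(keep_ch, nc + keep_ch)
  structure(list(J = jac$J[rows, , drop = FALSE], datum = jac$datum[rows],
                 channels = jac$channels[keep_ch, ], frequency = jac$frequency,
                 wavelength = jac$wavelength, n_channels = length(keep_ch),
                 n_voxels = jac$n_voxels),
            class = "dot_jacobian")
}

#' Run the full frequency sweep
#'
#' For each modulation frequency and wavelength: layered forward solves for
#' every optode, Rytov Jacobian assembly, regularized inverse operators per
#' measurement set, batched PSF simulation over all seed voxels (noise-free
#' and/or with coupled noise draws keyed to the master seed), and PSF
#' metrics per seed. Fully deterministic given the configuration.
#'
#' @param config A `dot_sweep_config`.
#' @param quiet Suppress progress messages.
#' @return A `dot_sweep_summary`: per-seed `records`, `sr50` table,
#'   `sr_curves`, depth-binned `medians`, `fbt` volume table, Wilcoxon
#'   `tests` against continuous wave, plus `roi`, `seeds` and `config`.
#' @export
run_sweep <- function(config = sweep_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  pc <- config$phantom
  ph <- build_layered_slab(pc$layer_thicknesses, pc$lateral_extent,
                           pc$depth_extent, pc$voxel_size,
                           refractive_index = pc$refractive_index)
  arr <- place_checkerboard_array(config$array$pitch, config$array$n_rows,
                                  config$array$n_cols, ph)
  max_nn <- max(config$nn_sets)
  ch <- enumerate_channels(arr, max_nn)
  say("phantom ", ph$nx, "x", ph$ny, "x", ph$nz, ", ", nrow(ch), " channels (NN", max_nn, ")")

  sens <- summed_baseline_intensity(ph, arr, config$wavelengths)
  mask <- define_roi(ph, arr, config$roi$lateral_margin,
                     config$roi$sensitivity_floor, sens)
  roi <- roi_index(ph, mask)
  seeds <- select_seeds(roi, config$seeds, ph$h)
  say("ROI ", roi$n, " voxels (max depth ", max(roi$depth), " mm), ",
      length(seeds$idx), " seed voxels")

  E <- if (is.null(config$extinction)) extinction_matrix() else config$extinction
  dmua <- hb_to_mua(config$perturbation, E)
  Einv <- solve(E)
  reg <- regularization_params(config$regularization$lambda1_rel,
                               config$regularization$lambda2_rel,
                               config$regularization$form)
  wls <- config$wavelengths
  le_cut <- config$metrics$le_cutoff
  noise_on_states <- config$noise_states
  nreal <- config$realizations
  seed_ids <- roi$idx[seeds$idx]          # stable voxel ids for seeding

  rec_list <- list()
  for (f in config$frequencies) {
    say("frequency ", f, " MHz")
    jac <- list(); nz_draws <- list()
    for (wl in wls) {
      ff <- forward_fields(ph, arr, roi, wl, f)
      jac[[as.character(wl)]] <- assemble_rytov_jacobian(ff, ph, ch)
      if ("on" %in% noise_on_states) {
        # noise on the full channel set; NN subsets reuse the same draws
        nz_draws[[as.character(wl)]] <- lapply(seq_len(nreal), function(rz) {
          vapply(seq_along(seeds$idx), function(si) {
            nzi <- sample_noise(ch, f, wl,
                                seed = derive_seed(config$master_seed,
                                                   seed_ids[si], f, wl, rz),
                                params = config$noise$params,
                                coupled = config$noise$coupled,
                                scale = config$noise$scale)
            c(nzi$intensity, nzi$phase)
          }, numeric(if (f == 0) nrow(ch) else 2 * nrow(ch)))
        })
      }
    }
    for (nn in config$nn_sets) {
      jnn <- lapply(jac, subset_jacobian, max_nn = nn)
      ops <- lapply(jnn, build_inverse_operator, reg = reg)
      keep_ch <- which(ch$nn <= nn)
      rows_nn <- if (f == 0) keep_ch else c(keep_ch, nrow(ch) + keep_ch)
      for (state in noise_on_states) {
        for (rz in seq_len(if (state == "on") nreal else 1L)) {
          hbo2 <- 0
          for (i in seq_along(wls)) {
            wl <- as.character(wls[i])
            Y <- jnn[[wl]]$J[, seeds$idx, drop = FALSE] * dmua[[i]]
            if (state == "on") {
              Y <- Y + nz_draws[[wl]][[rz]][rows_nn, , drop = FALSE]
            }
            X <- reconstruct(ops[[wl]], Y)
            hbo2 <- hbo2 + Einv[1, i] * X
          }
          sc <- do.call(rbind, lapply(seq_along(seeds$idx), function(si) {
            score_psf(hbo2[, si], roi, roi$coords[seeds$idx[si], ], le_cut)
          }))
          sc$frequency <- f; sc$nn <- nn; sc$noise <- state; sc$realization <- rz
          sc$seed_id <- seed_ids
          sc$depth <- roi$depth[seeds$idx]
          sc$brain <- roi$brain[seeds$idx]
          sc$rep_volume <- seeds$rep_volume
          rec_list[[length(rec_list) + 1L]] <- sc
        }
      }
    }
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  summarize_sweep(records, roi, seeds, config)
}

#' Build summary tables from per-seed sweep records
#' @keywords internal
summarize_sweep <- function(records, roi, seeds, config) {
  bw <- config$metrics$bin_width
  cut <- config$metrics$le_cutoff
  arms <- unique(records[, c("frequency", "nn", "noise")])
  sr_curves <- list(); sr50 <- NULL
  for (i in seq_len(nrow(arms))) {
    sub <- records[records$frequency == arms$frequency[i] &
                     records$nn == arms$nn[i] & records$noise == arms$noise[i], ]
    crv <- success_rate_curve(sub, cutoff = cut, bin_width = bw)
    key <- sprintf("f%g_nn%d_%s", arms$frequency[i], arms$nn[i], arms$noise[i])
    sr_curves[[key]] <- crv
    sr50 <- rbind(sr50, data.frame(frequency = arms$frequency[i],
                                   nn = arms$nn[i], noise = arms$noise[i],
                                   sr50_depth = crv$sr50_depth,
                                   censored = crv$censored))
  }

  records$depth_bin <- (floor(records$depth / bw) + 0.5) * bw
  agg_med <- function(col, name) {
    out <- stats::aggregate(
      list(v = col), by = records[, c("frequency", "nn", "noise", "depth_bin")],
      FUN = function(v) if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
    names(out)[names(out) == "v"] <- name
    out
  }
  medians <- Reduce(function(a, b) merge(a, b, by = c("frequency", "nn", "noise", "depth_bin")),
                    list(agg_med(records$LE, "LE"),
                         agg_med(records$FWHM, "FWHM"),
                         agg_med(records$FVHM^(1/3), "FVHM_cbrt")))
  medians <- medians[order(medians$nn, medians$noise, medians$frequency,
                           medians$depth_bin), ]
  rownames(medians) <- NULL

  fbt <- NULL
  if (0 %in% records$frequency) {
    for (nn in unique(records$nn)) for (state in unique(records$noise)) {
      sub <- records[records$nn == nn & records$noise == state, ]
      b <- brain_volume_summary(sub, config$metrics$fbt_cutoffs)
      b$nn <- nn; b$noise <- state
      fbt <- rbind(fbt, b)
    }
  }

  tests <- NULL
  if (0 %in% records$frequency) {
    for (nn in unique(records$nn)) for (state in unique(records$noise)) {
      cw <- records[records$frequency == 0 & records$nn == nn &
                      records$noise == state & records$realization == 1, ]
      for (f in setdiff(unique(records$frequency), 0)) {
        fd <- records[records$frequency == f & records$nn == nn &
                        records$noise == state & records$realization == 1, ]
        tst <- compare_to_cw(fd, cw, metric = "LE")
        tests <- rbind(tests, data.frame(frequency = f, nn = nn, noise = state,
                                         metric = "LE", statistic = tst$statistic,
                                         p_value = tst$p_value, n_pairs = tst$n,
                                         median_diff = tst$median_diff))
      }
    }
  }

  structure(list(records = records, sr50 = sr50, sr_curves = sr_curves,
                 medians = medians, fbt = fbt, tests = tests,
                 roi = roi, seeds = seeds, config = config),
            class = "dot_sweep_summary")
}

#' @export
print.dot_sweep_summary <- function(x, ...) {
  cat("Frequency sweep:", length(unique(x$records$frequency)), "frequencies,",
      nrow(x$records), "PSF records\n")
  if (!is.null(x$sr50)) {
    cat("sr50 depths (mm):\n")
    print(utils::head(x$sr50, 12))
  }
  invisible(x)
}

#' Paired signed-rank comparison of a metric against continuous wave
#'
#' Wilcoxon signed-rank test on per-seed differences (FD minus CW), paired
#' by seed voxel. Seeds where either arm produced an empty reconstruction
#' are dropped pairwise.
#'
#' @param records_fd,records_cw data.frames with `seed_id` and the metric
#'   column.
#' @param metric Column to compare (default `"LE"`).
#' @return List: `statistic` (signed-rank V), `p_value` (two-sided), `n`
#'   pairs used, `median_diff`.
#' @export
compare_to_cw <- function(records_fd, records_cw, metric = "LE") {
  m <- match(records_fd$seed_id, records_cw$seed_id)
  if (any(is.na(m)) || nrow(records_fd) != nrow(records_cw)) {
    stop("contract error: records are not paired by seed voxel")
  }
  a <- records_fd[[metric]]
  b <- records_cw[[metric]][m]
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  if (length(d) == 0) stop("no paired records")
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n = length(d),
                median_diff = 0, note = "all differences zero"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a[keep], b[keep], paired = TRUE,
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(d), median_diff = stats::median(d))
}

#' Write sweep outputs to a directory
#'
#' CSV tables (per-seed records, sr50 depths, depth-binned medians, brain
#' volume/FBT ratios, signed-rank tests), a JSON run manifest with the full
#' configuration, and optional NIfTI metric maps (requires the RNifti
#' package).
#'
#' @param summary A `dot_sweep_summary`.
#' @param outdir Output directory (created if missing).
#' @param nifti Also write per-frequency LE maps as NIfTI volumes.
#' @return Invisibly, the paths written.
#' @export
report <- function(summary, outdir, nifti = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(summary$records, "psf_records.csv")
  wr(summary$sr50, "sr50_depths.csv")
  wr(summary$medians, "median_metric_curves.csv")
  wr(summary$fbt, "brain_volume_fbt.csv")
  wr(summary$tests, "wilcoxon_vs_cw.csv")
  manifest <- list(
    package = "fdhddot",
    package_version = as.character(utils::packageVersion("fdhddot")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    master_seed = summary$config$master_seed,
    n_records = if (is.null(summary$records)) 0L else nrow(summary$records),
    config = unclass(rapply(summary$config, unclass, how = "replace"))
  )
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  paths <- c(paths, mp)
  if (nifti && !is.null(summary$records)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      warning("RNifti not available; skipping NIfTI export")
    } else {
      paths <- c(paths, write_le_maps_nifti(summary, outdir))
    }
  }
  if (is.null(summary$records)) warning("empty summary: manifest only")
  invisible(paths)
}

#' Write per-frequency localization-error maps as NIfTI
#' @keywords internal
write_le_maps_nifti <- function(summary, outdir) {
  roi <- summary$roi
  cfg <- summary$config
  h <- cfg$phantom$voxel_size
  paths <- character(0)
  rec <- summary$records[summary$records$noise == summary$records$noise[1] &
                           summary$records$nn == max(summary$records$nn), ]
  for (f in unique(rec$frequency)) {
    sub <- rec[rec$frequency == f & rec$realization == 1, ]
    vol <- array(NA_real_, dim = dim(roi$mask))
    pos <- match(sub$seed_id, roi$idx)
    vol[roi$idx[pos]] <- sub$LE
    p <- file.path(outdir, sprintf("le_map_f%04d.nii", f))
    img <- RNifti::asNifti(vol, pixdim = c(h, h, h))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  paths
}
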