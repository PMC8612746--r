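# Point-spread-function image-quality metrics: half-maximum thresholding,
# localization error, FWHM, FVHM, depth-resolved success rate and the
# successfully imaged brain volume.

#' Half-maximum threshold of a reconstructed volume
#'
#' All voxels with value at least `frac` times the (positive) maximum; no
#' connected-component filtering by default, matching the definition of
#' the FWHM as the longest distance between any two retained voxels.
#'
#' @param values Numeric vector of reconstructed values (HbO2 convention:
#'   thresholding on positive values).
#' @param frac Threshold fraction (default 0.5).
#' @return Integer indices of retained voxels; `integer(0)` with attribute
#'   `empty = TRUE` when the volume has no positive maximum.
#' @export
threshold_half_max <- function(values, frac = 0.5) {
  m <- max(values)
  if (!is.finite(m) || m <= 0) {
    return(structure(integer(0), empty = TRUE))
  }
  which(values >= frac * m)
}

#' Localization error of a thresholded PSF
#'
#' Euclidean distance from the true perturbation position to the centroid
#' of the retained voxels (value-weighted by default).
#'
#' @param coords Matrix (n x 3) of retained voxel centers, mm.
#' @param values Their reconstructed values (weights).
#' @param true_position Numeric length-3, mm.
#' @param weighted Use value-weighted centroid (default) or unweighted.
#' @return Distance in mm; `NA` for an empty set.
#' @export
localization_error <- function(coords, values, true_position, weighted = TRUE) {
  if (NROW(coords) == 0) return(NA_real_)
  w <- if (weighted) values else rep(1, NROW(coords))
  centroid <- colSums(coords * w) / sum(w)
  sqrt(sum((centroid - true_position)^2))
}

#' Full width at half maximum: longest pairwise distance in the PSF
#'
#' @param coords Matrix (n x 3) of retained voxel centers, mm.
#' @return Maximum pairwise Euclidean distance (0 for a single voxel,
#'   `NA` for an empty set).
#' @export
fwhm <- function(coords) {
  n <- NROW(coords)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  # chunked exact O(n^2) scan, bounded memory
  best <- 0
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- coords[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(coords^2), "+") -
      2 * tcrossprod(block, coords)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Full volume at half maximum
#'
#' @param n_voxels Number of retained voxels.
#' @param voxel_volume Voxel volume, mm^3.
#' @return Volume in mm^3 (`NA` for an empty set).
#' @export
fvhm <- function(n_voxels, voxel_volume) {
  if (n_voxels == 0) return(NA_real_)
  n_voxels * voxel_volume
}

#' Score one reconstructed HbO2 volume against its seed location
#'
#' Thresholds at half maximum and computes LE, and - for successful
#' recoveries (LE at most `le_cutoff`) - FWHM and FVHM.
#'
#' @param values Reconstructed HbO2 over the ROI.
#' @param roi A `dot_roi`.
#' @param true_position Seed position, mm.
#' @param le_cutoff Success cutoff in mm (default 8).
#' @param weighted Value-weighted centroid.
#' @return One-row data.frame: `LE`, `FWHM`, `FVHM`, `success`, `empty`.
#' @export
score_psf <- function(values, roi, true_position, le_cutoff = 8, weighted = TRUE) {
  keep <- threshold_half_max(values)
  if (length(keep) == 0) {
    return(data.frame(LE = NA_real_, FWHM = NA_real_, FVHM = NA_real_,
                      success = FALSE, empty = TRUE))
  }
  le <- localization_error(roi$coords[keep, , drop = FALSE], values[keep],
                           true_position, weighted)
  success <- le <= le_cutoff
  data.frame(
    LE = le,
    FWHM = if (success) fwhm(roi$coords[keep, , drop = FALSE]) else NA_real_,
    FVHM = if (success) fvhm(length(keep), roi$voxel_volume) else NA_real_,
    success = success, empty = FALSE
  )
}

#' Simulate and score the point-spread function of one seed voxel
#'
#' The full chain for a single seed: hemoglobin perturbation to
#' wavelength-wise absorption, noiseless data as the seed's Jacobian
#' column (optionally plus a coupled noise draw), per-wavelength
#' reconstruction, spectral back-conversion, and HbO2 PSF metrics.
#'
#' @param seed_voxel ROI voxel index (column of the Jacobians).
#' @param jacobians Named list (`"690"`, `"850"`) of `dot_jacobian`s.
#' @param operators Named list (`"690"`, `"850"`) of inverse operators.
#' @param roi A `dot_roi` shared by both Jacobians.
#' @param perturbation Named numeric `dHbO2`, `dHbR` in uM.
#' @param noise NULL for noise-free, else a list with `master_seed` and
#'   optionally `params` (coefficients), `scale` and `realization`.
#' @param E Extinction matrix.
#' @param le_cutoff Success cutoff, mm.
#' @param return_volume Also return the HbO2 volume over the ROI.
#' @return One-row data.frame of metrics (plus `volume` attribute when
#'   requested).
#' @export
simulate_psf <- function(seed_voxel, jacobians, operators, roi,
                         perturbation = c(dHbO2 = 3.8, dHbR = -1.8),
                         noise = NULL, E = extinction_matrix(),
                         le_cutoff = 8, return_volume = FALSE) {
  dmua <- hb_to_mua(perturbation, E)
  xs <- vector("list", 2)
  for (i in 1:2) {
    wl <- c(690, 850)[i]
    jac <- jacobians[[as.character(wl)]]
    op <- operators[[as.character(wl)]]
    y <- jac$J[, seed_voxel] * dmua[[i]]
    if (!is.null(noise)) {
      nz <- sample_noise(jac$channels, jac$frequency, wl,
                         seed = derive_seed(noise$master_seed, seed_voxel,
                                            jac$frequency, wl,
                                            noise$realization %||% 1),
                         params = noise$params %||% default_noise_params(),
                         scale = noise$scale %||% 1)
      y <- y + c(nz$intensity, nz$phase)
    }
    xs[[i]] <- reconstruct(op, y)
  }
  hb <- mua_to_hb(xs[[1]], xs[[2]], E)
  res <- score_psf(hb$dHbO2, roi, roi$coords[seed_voxel, ], le_cutoff)
  if (return_volume) attr(res, "volume") <- hb$dHbO2
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Success-rate curve and 50% success depth
#'
#' Bins per-seed records by depth and computes the fraction with LE below
#' the cutoff per bin; the reliable-imaging boundary `sr50_depth` is the
#' first depth at which the curve crosses 0.5 from above (linearly
#' interpolated between bin centers). If the curve never falls below 0.5
#' within the sampled range the boundary is censored at the deepest bin.
#'
#' @param records data.frame with columns `depth` and `LE` (NA allowed for
#'   empty reconstructions, counted as failures).
#' @param cutoff LE success cutoff, mm (counted as success when LE < cutoff).
#' @param bin_width Depth bin width, mm.
#' @return A `dot_sr_curve` list: `depth` (bin centers), `sr` (fractions),
#'   `n` (records per bin), `sr50_depth`, `censored`.
#' @export
success_rate_curve <- function(records, cutoff = 8, bin_width = 1) {
  if (nrow(records) == 0) stop("no records")
  ok <- !is.na(records$LE) & records$LE < cutoff
  bin <- floor(records$depth / bin_width)
  agg <- stats::aggregate(ok, by = list(bin = bin), FUN = mean)
  cnt <- as.vector(table(bin))
  centers <- (agg$bin + 0.5) * bin_width
  sr <- agg$x
  o <- order(centers)
  centers <- centers[o]; sr <- sr[o]; cnt <- cnt[o]

  sr50 <- NA_real_; censored <- FALSE
  cross <- which(sr[-length(sr)] >= 0.5 & sr[-1] < 0.5)
  if (sr[1] < 0.5) {
    sr50 <- centers[1]
  } else if (length(cross) > 0) {
    i <- cross[1]
    sr50 <- centers[i] + (sr[i] - 0.5) / (sr[i] - sr[i + 1]) *
      (centers[i + 1] - centers[i])
  } else {
    sr50 <- centers[length(centers)]
    censored <- TRUE
  }
  structure(list(depth = centers, sr = sr, n = cnt,
                 sr50_depth = sr50, censored = censored),
            class = "dot_sr_curve")
}

#' Successfully imaged brain volume per frequency and LE cutoff
#'
#' FBTV: the brain-tissue volume represented by seeds reconstructed with
#' LE below each cutoff; the FBT ratio relates each frequency to the
#' continuous-wave (0 MHz) volume.
#'
#' @param records data.frame with columns `frequency`, `brain` (logical),
#'   `LE`, and `rep_volume` (brain volume each seed represents, mm^3).
#' @param le_cutoffs Cutoff sweep in mm.
#' @return data.frame with `frequency`, `le_cutoff`, `FBTV` (mm^3),
#'   `FBT_ratio` (NA-flagged when the CW volume is zero).
#' @export
brain_volume_summary <- function(records, le_cutoffs = 1:8) {
  if (!0 %in% records$frequency) stop("continuous-wave (0 MHz) records required")
  freqs <- sort(unique(records$frequency))
  out <- expand.grid(frequency = freqs, le_cutoff = le_cutoffs)
  out$FBTV <- mapply(function(f, cut) {
    r <- records[records$frequency == f & records$brain, ]
    sum(r$rep_volume[!is.na(r$LE) & r$LE < cut])
  }, out$frequency, out$le_cutoff)
  cw <- out$FBTV[match(paste(0, out$le_cutoff), paste(out$frequency, out$le_cutoff))]
  out$FBT_ratio <- ifelse(cw > 0, out$FBTV / cw, NA_real_)
  out
}
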