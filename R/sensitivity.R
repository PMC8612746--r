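# Rytov sensitivity assembly: adjoint (source field x detector field)
# kernels mapping voxel absorption changes to log-intensity and phase data.

#' Baseline forward fields for every optode at one frequency/wavelength
#'
#' Solves the layered forward model once per optode (sources and detectors
#' are both represented as isotropic sources at depth 1/musp below their
#' surface positions) and stores the complex fluence at the ROI voxels plus
#' the optode-to-optode measurement matrix needed for Rytov normalization.
#'
#' @param phantom A `dot_phantom`.
#' @param array A `dot_optodes`.
#' @param roi A `dot_roi` from [roi_index()].
#' @param wavelength 690 or 850 nm.
#' @param frequency Modulation frequency, MHz.
#' @return A `dot_fields` list: `F_src`, `F_det` (complex, ROI voxels x
#'   optodes), `M` (measurement of each source's field at each detector's
#'   stamp), plus provenance.
#' @export
forward_fields <- function(phantom, array, roi, wavelength, frequency) {
  z0 <- optode_source_depth(phantom, wavelength)
  spos <- array$sources; dpos <- array$detectors
  stamps_s <- lapply(seq_len(nrow(spos)), function(i)
    make_stamp(phantom, spos$x[i], spos$y[i], z0))
  stamps_d <- lapply(seq_len(nrow(dpos)), function(i)
    make_stamp(phantom, dpos$x[i], dpos$y[i], z0))
  stamps <- c(stamps_s, stamps_d)

  ent <- lapply(stamps_d, function(st) stamp_entries(phantom, st))
  stamp_idx <- sort(unique(unlist(lapply(ent, `[[`, "idx"))))
  ext <- c(roi$idx, setdiff(stamp_idx, roi$idx))
  lookup <- stats::setNames(seq_along(ext), ext)

  Fall <- solve_layered(phantom, wavelength, frequency, stamps, extract_idx = ext)
  ns <- length(stamps_s); nd <- length(stamps_d)
  nroi <- roi$n
  F_src <- Fall[seq_len(nroi), seq_len(ns), drop = FALSE]
  F_det <- Fall[seq_len(nroi), ns + seq_len(nd), drop = FALSE]

  # measurement of source i's field at detector j's trilinear stamp
  M <- matrix(0i, ns, nd)
  for (j in seq_len(nd)) {
    rows <- lookup[as.character(ent[[j]]$idx)]
    M[, j] <- crossprod(Fall[rows, seq_len(ns), drop = FALSE], ent[[j]]$w)
  }
  structure(list(F_src = F_src, F_det = F_det, M = M,
                 wavelength = wavelength, frequency = frequency,
                 n_src = ns, n_det = nd),
            class = "dot_fields")
}

#' Assemble the Rytov sensitivity matrix
#'
#' Adjoint formulation: the complex kernel for channel (s, d) and ROI voxel
#' j is `-h^3 * Phi_s(r_j) * Phi_d(r_j) / Phi_s(r_d)`, where `Phi_d` is the
#' field launched from the detector position (reciprocity). Its real part
#' is the log-intensity sensitivity row, its imaginary part the phase row
#' (radians per mm^-1 absorption change). Continuous-wave systems (f = 0)
#' carry intensity rows only.
#'
#' @param fields A `dot_fields` object from [forward_fields()].
#' @param phantom A `dot_phantom`.
#' @param channels A `dot_channels` data.frame.
#' @return A `dot_jacobian`: real matrix `J` (stacked intensity rows then
#'   phase rows, columns = ROI voxels), `datum` row labels, channel table
#'   and provenance.
#' @export
assemble_rytov_jacobian <- function(fields, phantom, channels) {
  nc <- nrow(channels)
  nroi <- nrow(fields$F_src)
  h3 <- phantom$h^3
  C <- matrix(0i, nc, nroi)
  for (ch in seq_len(nc)) {
    s <- channels$src[ch]; d <- channels$det[ch]
    base <- fields$M[s, d]
    if (Mod(base) == 0) stop("degenerate baseline: zero fluence for channel ", ch)
    C[ch, ] <- -h3 * fields$F_src[, s] * fields$F_det[, d] / base
  }
  if (any(!is.finite(Re(C))) || any(!is.finite(Im(C)))) {
    stop("non-finite Jacobian entries")
  }
  cw <- fields$frequency == 0
  J <- if (cw) Re(C) else rbind(Re(C), Im(C))
  datum <- if (cw) rep("intensity", nc) else rep(c("intensity", "phase"), each = nc)
  structure(list(J = J, datum = datum, channels = channels,
                 frequency = fields$frequency, wavelength = fields$wavelength,
                 n_channels = nc, n_voxels = nroi),
            class = "dot_jacobian")
}

#' @export
print.dot_jacobian <- function(x, ...) {
  cat("Rytov Jacobian:", nrow(x$J), "rows x", x$n_voxels, "voxels @",
      x$frequency, "MHz /", x$wavelength, "nm\n")
  invisible(x)
}

#' Differential Rytov data from complex measurements
#'
#' The complex-logarithm split of perturbed over baseline measurements:
#' log-amplitude ratio and phase difference wrapped to (-pi, pi].
#'
#' @param perturbed,baseline Complex measurement vectors (same length).
#' @return data.frame with `log_amp` and `phase` per channel.
#' @export
rytov_data <- function(perturbed, baseline) {
  if (length(perturbed) != length(baseline)) stop("length mismatch")
  if (any(Mod(baseline) == 0)) stop("degenerate baseline: zero measurement")
  ratio <- perturbed / baseline
  data.frame(log_amp = log(Mod(ratio)), phase = Arg(ratio))
}

#' Voxelwise summed log-intensity sensitivity
#'
#' Sum of absolute intensity-row sensitivities over all channels,
#' normalized to its maximum; a diagnostic of where the measurement set
#' actually sees.
#'
#' @param jacobian A `dot_jacobian`.
#' @return Numeric vector over ROI voxels with maximum exactly 1.
#' @export
summed_intensity_sensitivity <- function(jacobian) {
  rows <- jacobian$datum == "intensity"
  s <- colSums(abs(jacobian$J[rows, , drop = FALSE]))
  s / max(s)
}
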