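# Differential spectroscopy: hemoglobin <-> absorption conversion at the
# two source wavelengths.

#' Molar extinction matrix for HbO2 and HbR at 690 and 850 nm
#'
#' Extinction coefficients from the standard compiled hemoglobin spectra
#' (Prahl compilation), converted from cm^-1/M (base-10) to mm^-1 per uM of
#' chromophore via `ln(10) * eps * 1e-7`. Treated as configuration: the
#' image-quality metrics depend on the shape of the reconstructed HbO2
#' volume, not on the absolute extinction scale.
#'
#' @param eps_molar Named numeric of base-10 molar extinction coefficients
#'   in cm^-1/M: `HbO2_690`, `HbR_690`, `HbO2_850`, `HbR_850`.
#' @return 2x2 matrix, rows = wavelengths (690, 850), columns = chromophores
#'   (HbO2, HbR), units mm^-1 uM^-1.
#' @export
extinction_matrix <- function(eps_molar = c(HbO2_690 = 276.0, HbR_690 = 2051.96,
                                            HbO2_850 = 1058.0, HbR_850 = 691.32)) {
  E <- matrix(log(10) * eps_molar[c("HbO2_690", "HbR_690", "HbO2_850", "HbR_850")] * 1e-7,
              nrow = 2, byrow = TRUE,
              dimnames = list(c("690", "850"), c("HbO2", "HbR")))
  if (any(!is.finite(E)) || any(E <= 0)) stop("extinction coefficients must be positive")
  if (kappa(E) >= 100) stop("conditioning error: extinction matrix condition number >= 100")
  E
}

#' Convert a hemoglobin perturbation to absorption perturbations
#'
#' @param p Named numeric: `dHbO2`, `dHbR` in uM.
#' @param E Extinction matrix from [extinction_matrix()].
#' @return Named numeric `dmua690`, `dmua850` in mm^-1.
#' @export
hb_to_mua <- function(p = c(dHbO2 = 3.8, dHbR = -1.8), E = extinction_matrix()) {
  out <- as.vector(E %*% c(p[["dHbO2"]], p[["dHbR"]]))
  stats::setNames(out, c("dmua690", "dmua850"))
}

#' Convert absorption perturbations back to hemoglobin
#'
#' Applies the inverse extinction matrix; vectorized so that reconstructed
#' absorption volumes (one value per voxel and wavelength) map to HbO2 and
#' HbR volumes.
#'
#' @param dmua690,dmua850 Absorption perturbations (mm^-1), scalars or
#'   equal-length vectors.
#' @param E Extinction matrix.
#' @return List with `dHbO2` and `dHbR` (uM), same length as the inputs.
#' @export
mua_to_hb <- function(dmua690, dmua850, E = extinction_matrix()) {
  Einv <- solve(E)
  list(dHbO2 = Einv[1, 1] * dmua690 + Einv[1, 2] * dmua850,
       dHbR = Einv[2, 1] * dmua690 + Einv[2, 2] * dmua850)
}
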