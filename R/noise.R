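# Empirical measurement-noise model: a two-term exponential in
# source-detector distance scaled by a frequency-dependent factor
# normalized to 140 MHz,
#   N(r, f) = (a e^{b r} + c e^{d r}) * 10^{g (f - 140)},
# in percent (intensity) or degrees (phase).

#' Default noise-model coefficients
#'
#' Empirically derived coefficients per wavelength and datum type. `a`, `c`
#' are in percent (intensity) or degrees (phase); `b`, `d` in mm^-1; `g`
#' in MHz^-1.
#'
#' @return data.frame with columns `wavelength`, `datum`, `a`, `b`, `c`,
#'   `d`, `g`.
#' @export
default_noise_params <- function() {
  data.frame(
    wavelength = c(690, 850, 690, 850),
    datum = c("intensity", "intensity", "phase", "phase"),
    a = c(0.2502, 0.6019, 3.933e-11, 1.917e-10),
    b = c(0.02913, 0.01052, 0.4161, 0.3708),
    c = c(4.625e-06, 9.685e-05, 0.0105, 0.03573),
    d = c(0.2128, 0.1382, 0.05585, 0.02002),
    g = c(6.769e-04, 6.785e-04, 0.0013, 0.0013),
    stringsAsFactors = FALSE
  )
}

#' Noise standard deviation for a channel
#'
#' @param r Source-detector separation(s), mm.
#' @param f Modulation frequency, MHz. Continuous wave is `f = 0` (the
#'   frequency factor becomes `10^{-140 g}`).
#' @param wavelength 690 or 850 nm.
#' @param datum `"intensity"` or `"phase"`.
#' @param params Coefficient table ([default_noise_params()]).
#' @return Standard deviation in percent (intensity) or degrees (phase).
#' @export
noise_std <- function(r, f, wavelength, datum = c("intensity", "phase"),
                      params = default_noise_params()) {
  datum <- match.arg(datum)
  if (any(r < 0) || any(f < 0)) stop("r and f must be non-negative")
  row <- params[params$wavelength == wavelength & params$datum == datum, ]
  if (nrow(row) != 1L) {
    stop("configuration error: no noise coefficients for ", wavelength,
         " nm / ", datum)
  }
  (row$a * exp(row$b * r) + row$c * exp(row$d * r)) * 10^(row$g * (f - 140))
}

#' Deterministic seed derivation for noise realizations
#'
#' Mixes the master seed with the seed-voxel id, frequency, wavelength and
#' realization index into a reproducible stream seed below 2^31, so noise
#' is redrawn per (seed voxel, frequency, realization) but identical across
#' reruns and across channel subsets.
#'
#' @param master_seed Integer master seed.
#' @param voxel_id Seed-voxel identifier.
#' @param frequency Modulation frequency, MHz.
#' @param wavelength nm.
#' @param realization Realization index (default 1).
#' @return Integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, voxel_id = 0, frequency = 0,
                        wavelength = 0, realization = 1) {
  m <- 2147483647
  h <- 0
  for (k in c(master_seed, voxel_id, round(frequency), wavelength, realization, 17)) {
    h <- (h * 69069 + (k %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Draw a coupled noise realization for a channel set
#'
#' One standard normal draw per channel (per wavelength) scales both the
#' intensity and the phase noise of that channel, the strongest reading of
#' coupling "via matched random numbers". Intensity noise in percent is
#' injected additively in log-intensity units as sigma/100 (small-noise
#' equivalence of relative amplitude and log-amplitude noise); phase noise
#' is converted from degrees to radians. Continuous-wave realizations
#' (f = 0) carry intensity noise only.
#'
#' @param channels A `dot_channels` data.frame (column `sep_mm` used).
#' @param f Modulation frequency, MHz.
#' @param wavelength 690 or 850 nm.
#' @param seed Integer seed for the draw (see [derive_seed()]).
#' @param params Coefficient table.
#' @param coupled If FALSE, intensity and phase use independent draws
#'   (sensitivity analysis).
#' @param scale Global multiplier on both noise standard deviations
#'   (default 1); the sweep uses it to set the effective
#'   noise-to-signal regime (see the methods vignette).
#' @return A `dot_noise` list: `intensity` (log-intensity units), `phase`
#'   (radians, NULL when `f == 0`), `seed`, `frequency`.
#' @export
sample_noise <- function(channels, f, wavelength, seed,
                         params = default_noise_params(), coupled = TRUE,
                         scale = 1) {
  r <- channels$sep_mm
  sig_i <- scale * noise_std(r, f, wavelength, "intensity", params) / 100
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z <- stats::rnorm(length(r))
  out <- list(intensity = z * sig_i, phase = NULL, seed = seed, frequency = f,
              wavelength = wavelength)
  if (f > 0) {
    sig_p <- scale * noise_std(r, f, wavelength, "phase", params) * pi / 180
    zp <- if (coupled) z else stats::rnorm(length(r))
    out$phase <- zp * sig_p
  }
  structure(out, class = "dot_noise")
}
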