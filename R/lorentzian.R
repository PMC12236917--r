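#' Amplitude-normalized Lorentzian line
#'
#' \deqn{L(\Delta\omega) = A \frac{(\Gamma/2)^2}{(\Gamma/2)^2 +
#'   (\Delta\omega - \delta)^2}}
#' so the line equals `A` at its center `delta` and `A/2` at
#' `delta +/- fwhm/2`.
#'
#' @param x Offsets at which to evaluate, ppm.
#' @param A Peak amplitude (dimensionless, on the normalized-signal scale).
#' @param center Resonance center \eqn{\delta}, ppm.
#' @param fwhm Full width at half maximum \eqn{\Gamma}, ppm; must be > 0.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' lorentzian(2, A = 0.3, center = 2, fwhm = 1)    # 0.3 at the center
#' lorentzian(2.5, A = 0.3, center = 2, fwhm = 1)  # half maximum
#' @export
lorentzian <- function(x, A, center, fwhm) {
  if (any(fwhm <= 0)) stop("`fwhm` must be positive", call. = FALSE)
  hw2 <- (fwhm / 2)^2
  A * hw2 / (hw2 + (x - center)^2)
}

#' Canonical pool centers (ppm)
#'
#' Direct water saturation at 0 ppm, semi-solid MT at -1 ppm, creatine at
#' 2 ppm, glutamate at 3 ppm, relayed NOE at -3.5 ppm.
#' @return Named numeric vector.
#' @export
pool_centers <- function() {
  c(water = 0, mt = -1, creatine = 2, glutamate = 3, noe = -3.5)
}

#' Pool table for the five-pool Z-spectrum model
#'
#' The standard decomposition of a 7T brain Z-spectrum used here fits five
#' Lorentzian pools: direct water saturation at 0 ppm, semi-solid
#' magnetization transfer (MT) at -1 ppm, creatine at 2 ppm, glutamate at
#' 3 ppm and the relayed nuclear Overhauser effect (NOE) at -3.5 ppm.
#'
#' `default_pools()` returns the fit configuration table: per pool, the
#' center (fixed for all pools except water, whose center may float within
#' `+/-center_window` to absorb residual B0 error), amplitude bounds
#' \[0, 1), linewidth bounds encoding standard priors (MT broad, solutes
#' narrow), and deterministic initial values (linewidth at the midpoint of
#' its bounds, solute amplitudes at 0.02; the water amplitude is
#' initialized at run time from `1 - min(Z)`).
#'
#' @return A data frame with one row per pool and columns `name`, `center`,
#'   `center_fixed`, `center_window`, `amp_init`, `amp_lower`, `amp_upper`,
#'   `fwhm_init`, `fwhm_lower`, `fwhm_upper`.
#' @export
default_pools <- function() {
  data.frame(
    name          = c("water", "mt", "creatine", "glutamate", "noe"),
    center        = c(0, -1, 2, 3, -3.5),
    center_fixed  = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    center_window = c(0.2, 0, 0, 0, 0),
    amp_init      = c(NA, 0.02, 0.02, 0.02, 0.02),
    amp_lower     = 0,
    amp_upper     = 1 - 1e-6,
    fwhm_init     = c(2.15, 10.5, 1.65, 2.15, 3.25),
    fwhm_lower    = c(0.3, 1, 0.3, 0.3, 0.5),
    fwhm_upper    = c(4, 20, 3, 4, 6),
    stringsAsFactors = FALSE
  )
}

#' Construct a pool parameter table
#'
#' Convenience constructor for forward simulation: a table of pool
#' amplitudes, centers and linewidths (no bounds).
#'
#' @param name Character vector of pool names.
#' @param amplitude Peak amplitudes in \[0, 1).
#' @param center Centers in ppm.
#' @param fwhm Linewidths (FWHM) in ppm, > 0.
#' @return data frame with columns `name`, `amplitude`, `center`, `fwhm`.
#' @export
pool_params <- function(name, amplitude, center, fwhm) {
  stopifnot(length(name) == length(amplitude),
            length(name) == length(center),
            length(name) == length(fwhm))
  if (any(amplitude < 0 | amplitude >= 1))
    stop("pool amplitudes must lie in [0, 1)", call. = FALSE)
  if (any(fwhm <= 0)) stop("pool linewidths must be positive", call. = FALSE)
  data.frame(name = as.character(name), amplitude = as.numeric(amplitude),
             center = as.numeric(center), fwhm = as.numeric(fwhm),
             stringsAsFactors = FALSE)
}

#' Evaluate the multi-pool Z-spectrum model
#'
#' \deqn{Z(\Delta\omega) = 1 - \sum_i L_i(\Delta\omega)}
#' where each \eqn{L_i} is an amplitude/FWHM Lorentzian ([lorentzian()]).
#'
#' @param pools A pool table as from [pool_params()] (columns `amplitude`,
#'   `center`, `fwhm`); zero rows give a constant 1.
#' @param axis Offsets in ppm.
#' @return Numeric vector: model Z-values along `axis`.
#' @examples
#' p <- pool_params("glutamate", 0.05, 3, 1.2)
#' model_zspectrum(p, build_offset_axis())
#' @export
model_zspectrum <- function(pools, axis) {
  validate_axis(axis)
  z <- rep(1, length(axis))
  if (is.null(pools) || nrow(pools) == 0L) return(z)
  for (i in seq_len(nrow(pools)))
    z <- z - lorentzian(axis, pools$amplitude[i], pools$center[i],
                        pools$fwhm[i])
  z
}
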