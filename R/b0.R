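#' Estimate the B0 offset from a WASSR spectrum
#'
#' Locates the water line by upsampling the spectrum with a cubic smoothing
#' interpolant (linear for <= 4 valid points) at `factor` points per
#' measured interval and taking the argmin. The WASSR minimum sits at the
#' voxel's B0 offset, so the returned frequency is the per-voxel field
#' offset in ppm.
#'
#' A minimum on the axis boundary means the water line fell outside the
#' sampled window; such voxels are flagged invalid rather than clamped, as
#' is a flat spectrum (no minimum) or an offset beyond `bound`.
#'
#' @param values WASSR Z-values (NA allowed, treated as missing).
#' @param axis Offsets in ppm (>= 7 points required).
#' @param bound Maximum |offset| considered physically valid, ppm.
#' @param factor Upsampling factor (>= 100 recommended for sub-step
#'   resolution).
#' @return List with `offset` (ppm, NA when invalid), `valid` (logical) and
#'   `reason` (character, "" when valid).
#' @export
estimate_b0 <- function(values, axis, bound = 1.0, factor = 200L) {
  validate_axis(axis, min_len = 7L)
  if (length(values) != length(axis))
    stop("`values` and `axis` lengths differ", call. = FALSE)
  ok <- is.finite(values)
  bad <- function(reason) list(offset = NA_real_, valid = FALSE,
                               reason = reason)
  if (sum(ok) < 5L) return(bad("too few valid points"))
  x <- axis[ok]; y <- values[ok]
  if (diff(range(y)) < 1e-9) return(bad("flat spectrum, no minimum"))
  xout <- seq(min(x), max(x), length.out = (length(x) - 1L) * factor + 1L)
  yout <- if (sum(ok) <= 4L) {
    stats::approx(x, y, xout = xout)$y
  } else {
    stats::spline(x, y, xout = xout, method = "fmm")$y
  }
  i <- which.min(yout)
  if (i == 1L || i == length(yout))
    return(bad("minimum on axis boundary (water line out of window)"))
  off <- xout[i]
  if (abs(off) > bound)
    return(bad(sprintf("offset %.3f ppm exceeds bound %.3f ppm", off, bound)))
  list(offset = off, valid = TRUE, reason = "")
}

#' Re-reference a Z-spectrum onto the nominal axis
#'
#' Evaluates the measured spectrum at `axis + b0` by cubic-spline
#' interpolation and reports the result on the nominal axis, so that the
#' water minimum moves to 0 ppm. Points whose shifted frequency falls
#' outside the measured range are marked missing (`NA`) — never
#' extrapolated — and if more than `max_missing_frac` of the points would be
#' missing the voxel is flagged invalid.
#'
#' @param values Measured Z-values along `axis` (NA allowed).
#' @param axis Nominal offsets, ppm.
#' @param b0 Estimated B0 offset, ppm.
#' @param bound Maximum |b0| accepted, ppm.
#' @param max_missing_frac Invalidity threshold on the missing fraction.
#' @return List with `values` (corrected spectrum, NA where missing),
#'   `valid`, `reason`.
#' @export
correct_zspectrum <- function(values, axis, b0, bound = 1.0,
                              max_missing_frac = 0.2) {
  validate_axis(axis)
  if (length(values) != length(axis))
    stop("`values` and `axis` lengths differ", call. = FALSE)
  bad <- function(reason) list(values = rep(NA_real_, length(axis)),
                               valid = FALSE, reason = reason)
  if (!is.finite(b0)) return(bad("no valid B0 estimate"))
  if (abs(b0) > bound)
    return(bad(sprintf("|b0| = %.3f ppm exceeds bound %.3f ppm",
                       abs(b0), bound)))
  if (b0 == 0) return(list(values = values, valid = TRUE, reason = ""))
  ok <- is.finite(values)
  if (sum(ok) < 4L) return(bad("too few valid points"))
  x <- axis[ok]; y <- values[ok]
  target <- axis + b0
  tol <- 1e-9
  inside <- target >= min(x) - tol & target <= max(x) + tol
  out <- rep(NA_real_, length(axis))
  out[inside] <- stats::spline(x, y, xout = pmin(pmax(target[inside], min(x)),
                                                 max(x)),
                               method = "fmm")$y
  if (mean(!inside) > max_missing_frac)
    return(bad(sprintf("%.0f%% of points would need extrapolation",
                       100 * mean(!inside))))
  list(values = out, valid = TRUE, reason = "")
}

#' Voxelwise B0 map estimation
#'
#' Applies [estimate_b0()] to every voxel of a WASSR stack.
#'
#' @param wassr_stack 3-D array (row, col, offset).
#' @param axis WASSR offsets, ppm.
#' @param mask Optional logical matrix; voxels outside it are skipped.
#' @inheritParams estimate_b0
#' @return List of class `b0_map`: `offset` (matrix, ppm; NA where invalid)
#'   and `valid` (logical matrix).
#' @export
estimate_b0_map <- function(wassr_stack, axis, mask = NULL, bound = 1.0,
                            factor = 200L) {
  stopifnot(length(dim(wassr_stack)) == 3L)
  if (dim(wassr_stack)[3] != length(axis))
    stop(sprintf("stack has %d offsets but axis has %d",
                 dim(wassr_stack)[3], length(axis)), call. = FALSE)
  nr <- dim(wassr_stack)[1]; nc <- dim(wassr_stack)[2]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!all(dim(mask) == c(nr, nc)))
    stop("mask shape does not match stack", call. = FALSE)
  offset <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    est <- estimate_b0(wassr_stack[i, j, ], axis, bound = bound,
                       factor = factor)
    offset[i, j] <- est$offset
    valid[i, j] <- est$valid
  }
  structure(list(offset = offset, valid = valid), class = "b0_map")
}

#' Voxelwise B0 correction of a Z-spectrum stack
#'
#' Applies [correct_zspectrum()] per voxel with the voxel's estimated
#' offset. Voxels invalid in the B0 map stay invalid (all-NA spectrum);
#' validity is propagated, never widened.
#'
#' @param z_stack 3-D array (row, col, offset).
#' @param axis CEST offsets, ppm.
#' @param b0_map A `b0_map` from [estimate_b0_map()].
#' @inheritParams correct_zspectrum
#' @return List: `z` (corrected stack, NA where missing) and `valid`
#'   (logical matrix).
#' @export
correct_stack <- function(z_stack, axis, b0_map, bound = 1.0,
                          max_missing_frac = 0.2) {
  stopifnot(length(dim(z_stack)) == 3L)
  if (dim(z_stack)[3] != length(axis))
    stop(sprintf("stack has %d offsets but axis has %d",
                 dim(z_stack)[3], length(axis)), call. = FALSE)
  nr <- dim(z_stack)[1]; nc <- dim(z_stack)[2]
  if (!all(dim(b0_map$offset) == c(nr, nc)))
    stop("B0 map shape does not match stack", call. = FALSE)
  out <- array(NA_real_, dim = dim(z_stack))
  valid <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!isTRUE(b0_map$valid[i, j])) next
    cz <- correct_zspectrum(z_stack[i, j, ], axis, b0_map$offset[i, j],
                            bound = bound,
                            max_missing_frac = max_missing_frac)
    if (cz$valid) {
      out[i, j, ] <- cz$values
      valid[i, j] <- TRUE
    }
  }
  list(z = out, valid = valid)
}
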