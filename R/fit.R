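#' Fit configuration for multi-pool Lorentzian decomposition
#'
#' @param pools Pool configuration table (see [default_pools()]); any
#'   number of pools is accepted, e.g. a water-plus-one-solute table for
#'   two-pool fits.
#' @param max_iter Maximum optimizer iterations.
#' @param ftol,ptol Relative tolerances on the sum of squares and the
#'   parameter step; tight by default so noiseless spectra are recovered to
#'   solver precision.
#' @param min_points Minimum number of unmasked points required to attempt
#'   a fit; defaults to the free-parameter count plus 2.
#' @param value_range Plausibility window on normalized signal values;
#'   spectra with unmasked values outside it are flagged, not fitted.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(pools = default_pools(), max_iter = 500L,
                       ftol = 1e-15, ptol = 1e-15, min_points = NULL,
                       value_range = c(-0.1, 1.2)) {
  needed <- c("name", "center", "center_fixed", "center_window", "amp_init",
              "amp_lower", "amp_upper", "fwhm_init", "fwhm_lower",
              "fwhm_upper")
  if (!all(needed %in% names(pools)))
    stop("pool table is missing columns: ",
         paste(setdiff(needed, names(pools)), collapse = ", "), call. = FALSE)
  if (any(pools$fwhm_lower <= 0))
    stop("linewidth lower bounds must be positive", call. = FALSE)
  n_free <- 2L * nrow(pools) + sum(!pools$center_fixed)
  if (is.null(min_points)) min_points <- n_free + 2L
  structure(list(pools = pools, max_iter = as.integer(max_iter),
                 ftol = ftol, ptol = ptol, min_points = as.integer(min_points),
                 n_free = n_free, value_range = value_range),
            class = "fit_config")
}

# Parameter packing: per pool amplitude then fwhm, then free centers last.
fit_par_layout <- function(pools) {
  np <- nrow(pools)
  free_c <- which(!pools$center_fixed)
  list(np = np, free_c = free_c,
       i_amp = seq_len(np), i_fwhm = np + seq_len(np),
       i_ctr = if (length(free_c)) 2L * np + seq_along(free_c) else integer(0))
}

fit_unpack <- function(par, pools, lay) {
  ctr <- pools$center
  if (length(lay$free_c)) ctr[lay$free_c] <- par[lay$i_ctr]
  list(amp = par[lay$i_amp], fwhm = par[lay$i_fwhm], ctr = ctr)
}

# model and jacobian on the unmasked axis points
fit_model_eval <- function(p, x) {
  z <- rep(1, length(x))
  for (i in seq_along(p$amp)) {
    u <- (p$fwhm[i] / 2)^2
    z <- z - p$amp[i] * u / (u + (x - p$ctr[i])^2)
  }
  z
}

fit_jacobian <- function(p, x, lay) {
  J <- matrix(0, length(x), 2L * lay$np + length(lay$i_ctr))
  for (i in seq_len(lay$np)) {
    u <- (p$fwhm[i] / 2)^2
    d <- (x - p$ctr[i])^2
    den <- (u + d)^2
    J[, lay$i_amp[i]] <- -u / (u + d)
    J[, lay$i_fwhm[i]] <- -p$amp[i] * (p$fwhm[i] / 2) * d / den
  }
  for (jj in seq_along(lay$free_c)) {
    i <- lay$free_c[jj]
    u <- (p$fwhm[i] / 2)^2
    den <- (u + (x - p$ctr[i])^2)^2
    J[, lay$i_ctr[jj]] <- -p$amp[i] * u * 2 * (x - p$ctr[i]) / den
  }
  J
}

fit_skipped <- function(reason, config) {
  structure(list(ok = FALSE, reason = reason, pools = NULL, rss = NA_real_,
                 converged = FALSE, niter = 0L, at_bound = NULL,
                 n_points = 0L, config = config),
            class = "cest_fit")
}

#' Fit a Z-spectrum with a multi-pool Lorentzian model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box bounds,
#' analytic Jacobian) of `Z = 1 - sum(L_i)` against the observed spectrum,
#' minimizing `sum(w * (Z_obs - Z_model)^2)`. Weights are a mask: masked or
#' non-finite points never enter the objective. Deterministic given inputs
#' and configuration (no random restarts).
#'
#' Initialization is deterministic: water amplitude `1 - min(Z)`, solute
#' amplitudes and linewidths from the pool table, centers at their nominal
#' values. An `init` pool table can override this, e.g. to verify exact
#' recovery from a truth-valued start.
#'
#' @param values Observed Z-values along `axis` (NA = missing).
#' @param axis Offsets, ppm.
#' @param config A [fit_config()].
#' @param weights Optional 0/1 (or nonnegative) weights; 0 masks a point.
#' @param init Optional pool table (`name`, `amplitude`, `center`, `fwhm`)
#'   overriding the default initialization.
#' @return Object of class `cest_fit`: `ok`, `reason`, `pools` (fitted
#'   table), `rss`, `converged`, `niter`, `at_bound` (logical matrix
#'   pool x parameter), `n_points`.
#' @export
fit_zspectrum <- function(values, axis, config = fit_config(),
                          weights = NULL, init = NULL) {
  validate_axis(axis)
  stopifnot(inherits(config, "fit_config"))
  if (length(values) != length(axis))
    stop("`values` and `axis` lengths differ", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(axis))
  if (length(weights) != length(axis))
    stop("`weights` and `axis` lengths differ", call. = FALSE)
  use <- is.finite(values) & weights > 0
  if (sum(use) < config$min_points)
    return(fit_skipped(sprintf("only %d unmasked points (need >= %d)",
                               sum(use), config$min_points), config))
  vr <- config$value_range
  if (any(values[use] < vr[1] | values[use] > vr[2]))
    return(fit_skipped("signal values outside plausible range", config))

  pools <- config$pools
  lay <- fit_par_layout(pools)
  x <- axis[use]; y <- values[use]; w <- sqrt(weights[use])

  amp0 <- pools$amp_init
  amp0[is.na(amp0) & pools$name == "water"] <- max(min(1 - min(y), 1 - 1e-6), 0.01)
  amp0[is.na(amp0)] <- 0.02
  fwhm0 <- pools$fwhm_init
  ctr0 <- pools$center[lay$free_c]
  if (!is.null(init)) {
    m <- match(pools$name, init$name)
    if (any(is.na(m)))
      stop("`init` must cover every configured pool", call. = FALSE)
    amp0 <- init$amplitude[m]
    fwhm0 <- init$fwhm[m]
    ctr0 <- init$center[m][lay$free_c]
  }
  lower <- c(pools$amp_lower, pools$fwhm_lower,
             pools$center[lay$free_c] - pools$center_window[lay$free_c])
  upper <- c(pools$amp_upper, pools$fwhm_upper,
             pools$center[lay$free_c] + pools$center_window[lay$free_c])
  par0 <- pmin(pmax(c(amp0, fwhm0, ctr0), lower), upper)

  res_fn <- function(par) {
    p <- fit_unpack(par, pools, lay)
    w * (fit_model_eval(p, x) - y)
  }
  jac_fn <- function(par) {
    p <- fit_unpack(par, pools, lay)
    w * fit_jacobian(p, x, lay)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = res_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      ftol = config$ftol, ptol = config$ptol, gtol = 0,
      maxiter = min(config$max_iter, 1024L)))
  p <- fit_unpack(fit$par, pools, lay)
  fitted <- data.frame(name = pools$name, amplitude = p$amp,
                       center = p$ctr, fwhm = p$fwhm,
                       stringsAsFactors = FALSE)
  tol <- 1e-8
  at_bound <- cbind(
    amp_lower = p$amp - pools$amp_lower < tol,
    amp_upper = pools$amp_upper - p$amp < tol,
    fwhm_lower = p$fwhm - pools$fwhm_lower < tol,
    fwhm_upper = pools$fwhm_upper - p$fwhm < tol)
  rownames(at_bound) <- pools$name
  structure(list(ok = TRUE, reason = "", pools = fitted,
                 rss = sum(res_fn(fit$par)^2),
                 converged = fit$info %in% 1:4,
                 niter = fit$niter, at_bound = at_bound,
                 n_points = sum(use), config = config),
            class = "cest_fit")
}

#' @export
print.cest_fit <- function(x, ...) {
  if (!x$ok) {
    cat("<cest_fit> skipped:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<cest_fit> %d pools, %d points, RSS %.3g, %sconverged (%d it)\n",
              nrow(x$pools), x$n_points, x$rss,
              if (x$converged) "" else "NOT ", x$niter))
  print(x$pools, digits = 4)
  invisible(x)
}

#' Voxelwise Lorentzian fitting of a Z-spectrum stack
#'
#' Fits every voxel inside the mask independently. Voxels flagged invalid
#' by B0 correction (`valid`), or with too few finite points, are skipped
#' with a recorded reason count; nothing is silently dropped.
#'
#' @param z_stack 3-D array (row, col, offset), NA for missing points.
#' @param axis Offsets, ppm.
#' @param mask Logical matrix of voxels to fit (default: all).
#' @param config A [fit_config()].
#' @param valid Optional logical matrix from [correct_stack()].
#' @param verbose Log progress/failure counts.
#' @return Object of class `cest_fit_stack`: parameter arrays `amplitude`,
#'   `fwhm`, `center` (row x col x pool), matrices `rss`, `converged`,
#'   `fitted`, pool `names`, and `counts` (fitted / skipped / failed).
#' @export
fit_stack <- function(z_stack, axis, mask = NULL, config = fit_config(),
                      valid = NULL, verbose = FALSE) {
  stopifnot(length(dim(z_stack)) == 3L)
  nr <- dim(z_stack)[1]; nc <- dim(z_stack)[2]
  if (dim(z_stack)[3] != length(axis))
    stop(sprintf("stack has %d offsets but axis has %d",
                 dim(z_stack)[3], length(axis)), call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!all(dim(mask) == c(nr, nc)))
    stop("mask shape does not match stack", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nr, nc)
  np <- nrow(config$pools)
  amplitude <- array(NA_real_, c(nr, nc, np))
  fwhm <- array(NA_real_, c(nr, nc, np))
  center <- array(NA_real_, c(nr, nc, np))
  rss <- matrix(NA_real_, nr, nc)
  converged <- matrix(FALSE, nr, nc)
  fitted <- matrix(FALSE, nr, nc)
  n_skip <- 0L; n_fail <- 0L
  todo <- which(mask & valid, arr.ind = TRUE)
  if (nrow(todo) == 0L)
    stop("no valid voxels to fit", call. = FALSE)
  for (k in seq_len(nrow(todo))) {
    i <- todo[k, 1]; j <- todo[k, 2]
    f <- fit_zspectrum(z_stack[i, j, ], axis, config)
    if (!f$ok) { n_skip <- n_skip + 1L; next }
    fitted[i, j] <- TRUE
    amplitude[i, j, ] <- f$pools$amplitude
    fwhm[i, j, ] <- f$pools$fwhm
    center[i, j, ] <- f$pools$center
    rss[i, j] <- f$rss
    converged[i, j] <- f$converged
    if (!f$converged) n_fail <- n_fail + 1L
  }
  if (!any(fitted)) stop("all voxels skipped; nothing fitted", call. = FALSE)
  counts <- c(fitted = sum(fitted), skipped = n_skip, not_converged = n_fail)
  if (verbose)
    message(sprintf("fit_stack: %d fitted, %d skipped, %d not converged",
                    counts[1], counts[2], counts[3]))
  structure(list(amplitude = amplitude, fwhm = fwhm, center = center,
                 rss = rss, converged = converged, fitted = fitted,
                 names = config$pools$name, counts = counts,
                 config = config),
            class = "cest_fit_stack")
}

#' Numerical identifiability check of a fit configuration
#'
#' Verifies that the model Jacobian at the default initialization has full
#' column rank on the given axis, i.e. every free parameter is locally
#' identifiable. Run once per configuration, not per voxel.
#'
#' @param config A [fit_config()].
#' @param axis Offsets, ppm.
#' @return `TRUE` invisibly if full rank; otherwise an error.
#' @export
check_identifiability <- function(config = fit_config(),
                                  axis = build_offset_axis()) {
  pools <- config$pools
  lay <- fit_par_layout(pools)
  amp0 <- pools$amp_init
  amp0[is.na(amp0)] <- 0.8
  par0 <- c(amp0, pools$fwhm_init, pools$center[lay$free_c])
  p <- fit_unpack(par0, pools, lay)
  J <- fit_jacobian(p, axis, lay)
  r <- qr(J)$rank
  if (r < ncol(J))
    stop(sprintf("fit configuration not identifiable: Jacobian rank %d < %d",
                 r, ncol(J)), call. = FALSE)
  invisible(TRUE)
}
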