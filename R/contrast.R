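#' Area under a fitted Lorentzian
#'
#' The per-pool "CEST contrast" is the area under that pool's fitted
#' Lorentzian. Two modes are provided because either convention appears in
#' practice:
#' \describe{
#'   \item{analytic}{full-line integral, closed form
#'     \eqn{A \pi \Gamma / 2}; independent of the sampling window.}
#'   \item{numeric}{trapezoidal integral of the fitted line over a finite
#'     window (default the \[-5, 5\] ppm acquisition window).}
#' }
#' The exact integral over a window \[a, b\] is
#' \eqn{A (\Gamma/2) [\arctan(2(b-\delta)/\Gamma) -
#' \arctan(2(a-\delta)/\Gamma)]}, to which the trapezoid converges; the
#' closed form is exposed as [lorentzian_auc_window()] for verification.
#'
#' @param fit A `cest_fit` from [fit_zspectrum()].
#' @param pool Pool name.
#' @param mode `"analytic"` or `"numeric"`.
#' @param range Integration window in ppm (numeric mode).
#' @param n Number of trapezoid nodes (numeric mode).
#' @return AUC in ppm x normalized-signal units.
#' @examples
#' # closed form: A = 1, fwhm = 2 gives exactly pi
#' lorentzian_auc_analytic(1, 2)
#' @export
pool_auc <- function(fit, pool, mode = c("analytic", "numeric"),
                     range = c(-5, 5), n = 2001L) {
  mode <- match.arg(mode)
  if (!isTRUE(fit$ok)) stop("fit was skipped: ", fit$reason, call. = FALSE)
  i <- match(pool, fit$pools$name)
  if (is.na(i))
    stop(sprintf("unknown pool '%s'; fitted pools: %s", pool,
                 paste(fit$pools$name, collapse = ", ")), call. = FALSE)
  A <- fit$pools$amplitude[i]; G <- fit$pools$fwhm[i]
  d <- fit$pools$center[i]
  if (mode == "analytic") lorentzian_auc_analytic(A, G)
  else lorentzian_auc_numeric(A, d, G, range, n)
}

#' @rdname pool_auc
#' @param A,fwhm,center Lorentzian parameters (vectorized).
#' @export
lorentzian_auc_analytic <- function(A, fwhm) {
  A * pi * fwhm / 2
}

#' @rdname pool_auc
#' @param a,b Window endpoints in ppm.
#' @export
lorentzian_auc_window <- function(A, center, fwhm, a, b) {
  A * (fwhm / 2) * (atan(2 * (b - center) / fwhm) -
                      atan(2 * (a - center) / fwhm))
}

#' @rdname pool_auc
#' @export
lorentzian_auc_numeric <- function(A, center, fwhm, range = c(-5, 5),
                                   n = 2001L) {
  if (range[1] >= range[2]) stop("empty integration window", call. = FALSE)
  x <- seq(range[1], range[2], length.out = n)
  h <- x[2] - x[1]
  # vectorized over parameter vectors: rows = parameter sets, cols = nodes
  u <- (fwhm / 2)^2
  L <- outer(seq_along(A), x, function(i, xx)
    A[i] * u[i] / (u[i] + (xx - center[i])^2))
  s <- h * (rowSums(L) - 0.5 * (L[, 1] + L[, n]))
  if (length(A) == 1L) as.numeric(s) else s
}

#' Per-voxel contrast map for one pool
#'
#' Applies the AUC of the chosen pool to every fitted voxel of a
#' [fit_stack()] result; voxels that were skipped or did not converge are
#' masked (NA).
#'
#' @param fits A `cest_fit_stack`.
#' @inheritParams pool_auc
#' @return Matrix of class `contrast_map` with attributes `pool`, `mode`,
#'   `range`.
#' @export
contrast_map <- function(fits, pool, mode = c("analytic", "numeric"),
                         range = c(-5, 5), n = 2001L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fits, "cest_fit_stack"))
  i <- match(pool, fits$names)
  if (is.na(i))
    stop(sprintf("unknown pool '%s'; fitted pools: %s", pool,
                 paste(fits$names, collapse = ", ")), call. = FALSE)
  good <- fits$fitted & fits$converged
  if (!any(good)) stop("no converged voxels; empty map", call. = FALSE)
  A <- fits$amplitude[, , i]
  G <- fits$fwhm[, , i]
  D <- fits$center[, , i]
  m <- matrix(NA_real_, nrow(A), ncol(A))
  idx <- which(good)
  m[idx] <- if (mode == "analytic") {
    lorentzian_auc_analytic(A[idx], G[idx])
  } else {
    lorentzian_auc_numeric(A[idx], D[idx], G[idx], range, n)
  }
  structure(m, class = c("contrast_map", "matrix"), pool = pool,
            mode = mode, range = range)
}

#' Render a contrast map as a color heatmap PNG
#'
#' Writes a deterministic raster PNG: map values are color-mapped over a
#' fixed value window (shared across arms for comparability), masked voxels
#' show the grayscale underlay (or black), and a vertical colorbar strip is
#' appended at the right margin. The window limits and palette are also
#' written to a JSON sidecar (`<out>.json`) so rendered figures remain
#' comparable and auditable.
#'
#' @param map A [contrast_map()] (or plain matrix).
#' @param out Output PNG path.
#' @param underlay Optional anatomical matrix (same shape), shown in
#'   grayscale under masked voxels.
#' @param window Length-2 value range mapped onto the palette; default the
#'   finite range of `map`.
#' @param palette Palette name passed to [grDevices::hcl.colors()].
#' @param scale Integer pixel magnification.
#' @return `out`, invisibly.
#' @export
render_heatmap <- function(map, out, underlay = NULL, window = NULL,
                           palette = "viridis", scale = 4L) {
  m <- unclass(map)
  if (!is.null(underlay) && !all(dim(underlay) == dim(m)))
    stop("underlay shape does not match map", call. = FALSE)
  if (is.null(window)) window <- range(m, na.rm = TRUE)
  if (!is.numeric(window) || length(window) != 2L || window[1] >= window[2])
    stop("`window` must be an increasing value pair", call. = FALSE)
  cols <- grDevices::hcl.colors(256L, palette)
  rgbm <- grDevices::col2rgb(cols) / 255
  nr <- nrow(m); nc <- ncol(m)
  img <- array(0, c(nr, nc, 3))
  if (!is.null(underlay)) {
    u <- underlay - min(underlay, na.rm = TRUE)
    mx <- max(u, na.rm = TRUE)
    if (mx > 0) u <- u / mx
    u[!is.finite(u)] <- 0
    for (k in 1:3) img[, , k] <- u
  }
  idx <- which(is.finite(m))
  if (length(idx)) {
    t01 <- pmin(pmax((m[idx] - window[1]) / diff(window), 0), 1)
    ci <- 1L + as.integer(round(t01 * 255))
    for (k in 1:3) {
      plane <- img[, , k]
      plane[idx] <- rgbm[k, ci]
      img[, , k] <- plane
    }
  }
  # colorbar strip: 1/16 of the width, low values at the bottom
  bw <- max(2L, ceiling(nc / 16))
  bar <- array(0, c(nr, bw, 3))
  bi <- 1L + as.integer(round(seq(1, 0, length.out = nr) * 255))
  for (k in 1:3) bar[, , k] <- matrix(rgbm[k, bi], nr, bw)
  gap <- array(0, c(nr, 2L, 3))
  full <- array(0, c(nr, nc + 2L + bw, 3))
  full[, seq_len(nc), ] <- img
  full[, nc + 1:2, ] <- gap
  full[, nc + 2L + seq_len(bw), ] <- bar
  if (scale > 1L) {
    ri <- rep(seq_len(nrow(full)), each = scale)
    cj <- rep(seq_len(ncol(full)), each = scale)
    full <- full[ri, cj, , drop = FALSE]
  }
  png::writePNG(full, target = out)
  jsonlite::write_json(
    list(window = window, palette = palette,
         pool = attr(map, "pool"), auc_mode = attr(map, "mode")),
    paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
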