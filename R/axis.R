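#' Saturation-offset sampling schemes
#'
#' A scheme is a set of contiguous segments, each sampled as an arithmetic
#' progression `seq(from, to, by = step)`. Segments may share endpoints;
#' shared points are kept once. The default scheme is the acquisition axis
#' used throughout this package: 0.2 ppm steps on \[-5, -4\] and \[4, 5\] ppm
#' and 0.1 ppm steps on \[-4, 4\] ppm, giving 91 unique offsets over the
#' full -5 to +5 ppm window, denser where the creatine (2 ppm), glutamate
#' (3 ppm) and NOE (-3.5 ppm) resonances sit.
#'
#' @param from,to,step numeric vectors of equal length; one entry per
#'   segment, in ppm. `step` must be positive and `to > from`.
#' @return A data frame of class `offset_scheme` with columns
#'   `from`, `to`, `step`.
#' @examples
#' default_offset_scheme()
#' build_offset_axis(offset_scheme(-1, 1, 1))
#' @export
offset_scheme <- function(from, to, step) {
  if (length(from) != length(to) || length(from) != length(step))
    stop("`from`, `to` and `step` must have equal length", call. = FALSE)
  if (any(!is.finite(from)) || any(!is.finite(to)) || any(!is.finite(step)))
    stop("offset scheme values must be finite", call. = FALSE)
  if (any(step <= 0)) stop("segment steps must be positive", call. = FALSE)
  if (any(to <= from)) stop("each segment needs `to` > `from`", call. = FALSE)
  sc <- data.frame(from = as.numeric(from), to = as.numeric(to),
                   step = as.numeric(step))
  sc <- sc[order(sc$from), , drop = FALSE]
  rownames(sc) <- NULL
  if (nrow(sc) > 1L) {
    gap <- sc$from[-1L] - sc$to[-nrow(sc)]
    if (any(gap > 1e-9))
      stop("offset scheme segments must be contiguous", call. = FALSE)
    if (any(gap < -1e-9))
      stop("offset scheme segments overlap", call. = FALSE)
  }
  class(sc) <- c("offset_scheme", "data.frame")
  sc
}

#' @rdname offset_scheme
#' @export
default_offset_scheme <- function() {
  offset_scheme(from = c(-5, -4, 4),
                to   = c(-4,  4, 5),
                step = c(0.2, 0.1, 0.2))
}

#' Default WASSR offset axis
#'
#' WASSR spectra only need to bracket the water line, so the default axis is
#' a narrow, uniformly sampled window: -1 to +1 ppm in 0.05 ppm steps.
#'
#' @return Numeric vector of offsets in ppm.
#' @export
default_wassr_axis <- function() {
  build_offset_axis(offset_scheme(-1, 1, 0.05))
}

#' Build a frequency-offset axis from a sampling scheme
#'
#' Expands each segment of the scheme into an arithmetic progression and
#' merges them into one strictly increasing, de-duplicated axis.
#'
#' @param scheme An [offset_scheme()]; defaults to [default_offset_scheme()].
#' @return Numeric vector of unique offsets in ppm, strictly increasing.
#' @examples
#' axis <- build_offset_axis()
#' length(axis)  # 91
#' range(axis)   # -5 to 5
#' @export
build_offset_axis <- function(scheme = default_offset_scheme()) {
  if (!inherits(scheme, "offset_scheme"))
    scheme <- offset_scheme(scheme$from, scheme$to, scheme$step)
  pts <- unlist(lapply(seq_len(nrow(scheme)), function(i) {
    n <- round((scheme$to[i] - scheme$from[i]) / scheme$step[i])
    if (abs(scheme$from[i] + n * scheme$step[i] - scheme$to[i]) > 1e-9)
      stop(sprintf("segment [%g, %g] is not a whole number of steps of %g",
                   scheme$from[i], scheme$to[i], scheme$step[i]),
           call. = FALSE)
    scheme$from[i] + scheme$step[i] * (0:n)
  }))
  # snap to a fine grid before de-duplicating so shared endpoints collapse
  axis <- sort(unique(round(pts, 9)))
  if (any(diff(axis) <= 0)) stop("axis is not strictly increasing", call. = FALSE)
  axis
}

validate_axis <- function(axis, min_len = 2L) {
  if (!is.numeric(axis) || length(axis) < min_len)
    stop(sprintf("offset axis must be numeric with >= %d points", min_len),
         call. = FALSE)
  if (any(!is.finite(axis))) stop("offset axis must be finite", call. = FALSE)
  if (any(diff(axis) <= 0))
    stop("offset axis must be strictly increasing", call. = FALSE)
  invisible(axis)
}
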