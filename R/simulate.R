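#' Simulate a single Z-spectrum
#'
#' Forward-simulates a normalized Z-spectrum `Z = 1 - sum(L_i)` from a pool
#' table, with an optional B0 shift of the whole spectrum and additive
#' Gaussian noise on the normalized signal. Z-spectra are high-SNR magnitude
#' ratios, so additive Gaussian noise is an adequate model; Rician magnitude
#' bias is not simulated.
#'
#' @param pools Pool table ([pool_params()]); amplitudes must sum to < 1.
#' @param axis Offsets in ppm.
#' @param b0_offset Water-center displacement in ppm; the measured spectrum
#'   is the ideal spectrum evaluated at `axis - b0_offset`.
#' @param noise_sigma Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return Numeric vector of simulated Z-values along `axis`.
#' @examples
#' simulate_zspectrum(pool_params("glutamate", 0.2, 3, 1),
#'                    build_offset_axis())
#' @export
simulate_zspectrum <- function(pools, axis, b0_offset = 0, noise_sigma = 0,
                               seed = NULL) {
  validate_axis(axis)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (!is.null(pools) && nrow(pools) > 0L && sum(pools$amplitude) >= 1)
    stop("invalid pool system: amplitudes must sum to < 1", call. = FALSE)
  z <- model_zspectrum(pools, axis - b0_offset)
  if (noise_sigma > 0)
    z <- z + with_seed(seed, stats::rnorm(length(z), sd = noise_sigma))
  z
}

#' Simulate a WASSR spectrum
#'
#' A WASSR acquisition is a low-power, water-only Z-spectrum; its minimum
#' locates the per-voxel B0 offset. Simulated as a single water Lorentzian
#' displaced by `b0_offset`.
#'
#' @param b0_offset True B0 offset in ppm.
#' @param axis Offsets in ppm; default [default_wassr_axis()].
#' @param water_amplitude Depth of the water line (default 0.8).
#' @param water_linewidth FWHM of the water line in ppm (default 0.5).
#' @inheritParams simulate_zspectrum
#' @return Numeric vector of WASSR Z-values along `axis`.
#' @export
simulate_wassr <- function(b0_offset, axis = default_wassr_axis(),
                           water_amplitude = 0.8, water_linewidth = 0.5,
                           noise_sigma = 0, seed = NULL) {
  if (water_linewidth <= 0)
    stop("`water_linewidth` must be positive", call. = FALSE)
  simulate_zspectrum(
    pool_params("water", water_amplitude, 0, water_linewidth),
    axis, b0_offset = b0_offset, noise_sigma = noise_sigma, seed = seed)
}

# Run `expr` under a temporary RNG state when seed is non-NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Rectangular region helper
#'
#' @param rows,cols Integer ranges of voxel rows/columns (1-based).
#' @return Two-column integer matrix of (row, col) voxel coordinates.
#' @export
rect_region <- function(rows, cols) {
  as.matrix(expand.grid(row = as.integer(rows), col = as.integer(cols)))
}

#' Default region layout for a phantom grid
#'
#' Five square "regions" named after the quantified brain structures
#' (cortex, hippocampus, hypothalamus, piriform cortex, thalamus), placed
#' at the four quadrants and the center of the grid. Anatomical fidelity is
#' not a goal; the labels drive the region statistics.
#'
#' @param grid_shape Integer pair (rows, cols).
#' @param size Side length of each square region (voxels); default scales
#'   with the grid.
#' @return Named list of coordinate matrices as from [rect_region()].
#' @export
default_region_layout <- function(grid_shape, size = NULL) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  if (is.null(size)) size <- max(2L, floor(min(nr, nc) / 6))
  q <- function(r0, c0) rect_region(r0:(r0 + size - 1L), c0:(c0 + size - 1L))
  m <- floor(size / 2)
  list(
    cortex          = q(2L, 2L),
    hippocampus     = q(2L, nc - size),
    hypothalamus    = q(nr - size, 2L),
    piriform_cortex = q(nr - size, nc - size),
    thalamus        = q(floor(nr / 2) - m + 1L, floor(nc / 2) - m + 1L)
  )
}

#' Ground-truth pool amplitudes per arm and region
#'
#' Baseline amplitudes are typical of 7T mouse brain five-pool fits
#' (water 0.75, MT 0.06, creatine 0.04, glutamate 0.05, NOE 0.06). Arm
#' effects emulate the disease/treatment structure the pipeline is meant to
#' resolve: at 6 weeks creatine drops 10% in cortex and hippocampus and NOE
#' rises 10% in cortex; in the untreated 12-week arm glutamate drops 20% in
#' cortex, hippocampus and piriform cortex, creatine drops 15% in those
#' regions plus thalamus, and NOE rises 15% in cortex and thalamus; the
#' treated 12-week arm has glutamate and creatine restored to baseline while
#' the NOE elevation persists.
#'
#' @param arms Character vector of arm names.
#' @param regions Character vector of region names.
#' @return data frame with columns `arm`, `region`, `pool`, `amplitude`.
#' @export
default_pool_truth <- function(arms = c("baseline", "wk6", "wk12_vehicle",
                                        "wk12_art"),
                               regions = c("cortex", "hippocampus",
                                           "hypothalamus", "piriform_cortex",
                                           "thalamus")) {
  base <- c(water = 0.75, mt = 0.06, creatine = 0.04,
            glutamate = 0.05, noe = 0.06)
  tr <- expand.grid(pool = names(base), region = regions, arm = arms,
                    stringsAsFactors = FALSE)[, c("arm", "region", "pool")]
  tr$amplitude <- base[tr$pool]
  mul <- function(arm, pool, regs, f) {
    i <- tr$arm == arm & tr$pool == pool & tr$region %in% regs
    tr$amplitude[i] <<- tr$amplitude[i] * f
  }
  if ("wk6" %in% arms) {
    mul("wk6", "creatine", c("cortex", "hippocampus"), 0.90)
    mul("wk6", "noe", "cortex", 1.10)
  }
  if ("wk12_vehicle" %in% arms) {
    mul("wk12_vehicle", "glutamate",
        c("cortex", "hippocampus", "piriform_cortex"), 0.80)
    mul("wk12_vehicle", "creatine",
        c("cortex", "hippocampus", "piriform_cortex", "thalamus"), 0.85)
    mul("wk12_vehicle", "noe", c("cortex", "thalamus"), 1.15)
  }
  if ("wk12_art" %in% arms) {
    # glutamate/creatine restored; NOE elevation persists
    mul("wk12_art", "noe", c("cortex", "thalamus"), 1.15)
  }
  rownames(tr) <- NULL
  tr
}

#' Default ground-truth linewidths (FWHM, ppm) per pool
#' @return Named numeric vector.
#' @export
default_linewidths <- function() {
  c(water = 1.4, mt = 3.0, creatine = 1.0, glutamate = 1.2, noe = 2.5)
}

#' Phantom configuration
#'
#' Bundles everything [simulate_phantom()] needs: grid, region layout, study
#' arms with per-arm subject counts, ground-truth pool amplitudes and
#' linewidths, a smooth B0 field, noise level and seed.
#'
#' The default subject counts (14 baseline, 14 at week 6, 5 untreated and 4
#' treated at week 12) reproduce the unbalanced longitudinal design the
#' statistics module is built for. Between-subject variation is modelled as
#' i.i.d. Gaussian jitter on the region amplitudes with coefficient of
#' variation `subject_cv` (default 5%).
#'
#' @param grid_shape Integer pair (rows, cols) of the voxel grid.
#' @param region_layout Named list of coordinate matrices (disjoint voxel
#'   sets); default [default_region_layout()].
#' @param arms Character vector of arm names.
#' @param n_subjects_per_arm Named integer vector (per arm) or a single
#'   integer recycled over arms.
#' @param pool_truth data frame `arm, region, pool, amplitude`; default
#'   [default_pool_truth()].
#' @param linewidths Named vector of FWHM in ppm per pool.
#' @param b0_coef Coefficients `(c0, cx, cy, cxy, cxx, cyy)` of a quadratic
#'   B0 field in normalized coordinates u, v in \[-1, 1\]:
#'   `b0 = c0 + cx u + cy v + cxy u v + cxx u^2 + cyy v^2` (ppm).
#' @param b0_bound Maximum allowed |B0| of the field, ppm.
#' @param noise_sigma Additive noise SD on the CEST stack.
#' @param wassr_noise_sigma Additive noise SD on the WASSR stack.
#' @param subject_cv Coefficient of variation of between-subject amplitude
#'   jitter.
#' @param axis CEST offset axis; default [build_offset_axis()].
#' @param wassr_axis WASSR offset axis; default [default_wassr_axis()].
#' @param wassr_amplitude,wassr_linewidth Water-line shape of the WASSR
#'   acquisition.
#' @param seed Integer seed making the phantom reproducible.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L),
                           region_layout = default_region_layout(grid_shape),
                           arms = c("baseline", "wk6", "wk12_vehicle",
                                    "wk12_art"),
                           n_subjects_per_arm = c(baseline = 14L, wk6 = 14L,
                                                  wk12_vehicle = 5L,
                                                  wk12_art = 4L),
                           pool_truth = default_pool_truth(arms,
                                                           names(region_layout)),
                           linewidths = default_linewidths(),
                           b0_coef = c(0.05, 0.10, -0.08, 0.04, 0.06, -0.05),
                           b0_bound = 0.5,
                           noise_sigma = 0.005,
                           wassr_noise_sigma = 0.005,
                           subject_cv = 0.05,
                           axis = build_offset_axis(),
                           wassr_axis = default_wassr_axis(),
                           wassr_amplitude = 0.8, wassr_linewidth = 0.5,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 2L))
  if (length(n_subjects_per_arm) == 1L && is.null(names(n_subjects_per_arm)))
    n_subjects_per_arm <- stats::setNames(rep(as.integer(n_subjects_per_arm),
                                              length(arms)), arms)
  if (!all(arms %in% names(n_subjects_per_arm)))
    stop("`n_subjects_per_arm` must name every arm", call. = FALSE)
  n_subjects_per_arm <- n_subjects_per_arm[arms]
  if (any(n_subjects_per_arm < 1L))
    stop("subject counts must be positive", call. = FALSE)
  # regions disjoint and inside the grid
  seen <- matrix(FALSE, grid_shape[1], grid_shape[2])
  for (nm in names(region_layout)) {
    xy <- region_layout[[nm]]
    if (any(xy[, 1] < 1L | xy[, 1] > grid_shape[1] |
            xy[, 2] < 1L | xy[, 2] > grid_shape[2]))
      stop(sprintf("region '%s' exceeds the grid", nm), call. = FALSE)
    idx <- cbind(xy[, 1], xy[, 2])
    if (any(seen[idx]))
      stop(sprintf("region '%s' overlaps another region", nm), call. = FALSE)
    seen[idx] <- TRUE
  }
  needed <- expand.grid(arm = arms, region = names(region_layout),
                        pool = names(linewidths), stringsAsFactors = FALSE)
  key <- function(d) paste(d$arm, d$region, d$pool)
  if (!all(key(needed) %in% key(pool_truth)))
    stop("`pool_truth` must cover every (arm, region, pool)", call. = FALSE)
  sums <- tapply(pool_truth$amplitude,
                 paste(pool_truth$arm, pool_truth$region), sum)
  if (any(sums >= 1))
    stop("pool amplitudes must sum to < 1 in every (arm, region)",
         call. = FALSE)
  if (any(pool_truth$amplitude < 0 | pool_truth$amplitude >= 1))
    stop("amplitudes must lie in [0, 1)", call. = FALSE)
  if (any(linewidths <= 0)) stop("linewidths must be > 0", call. = FALSE)
  cfg <- list(grid_shape = grid_shape, region_layout = region_layout,
              arms = arms, n_subjects_per_arm = n_subjects_per_arm,
              pool_truth = pool_truth, linewidths = linewidths,
              b0_coef = as.numeric(b0_coef), b0_bound = b0_bound,
              noise_sigma = noise_sigma,
              wassr_noise_sigma = wassr_noise_sigma,
              subject_cv = subject_cv, axis = axis, wassr_axis = wassr_axis,
              wassr_amplitude = wassr_amplitude,
              wassr_linewidth = wassr_linewidth, seed = as.integer(seed))
  fld <- b0_field(cfg)
  if (max(abs(fld)) > b0_bound)
    stop(sprintf("B0 field exceeds its bound (max |b0| = %.3f > %.3f ppm)",
                 max(abs(fld)), b0_bound), call. = FALSE)
  class(cfg) <- "phantom_config"
  cfg
}

#' Evaluate the phantom's smooth B0 field
#' @param config A [phantom_config()].
#' @return Matrix (grid_shape) of B0 offsets in ppm.
#' @export
b0_field <- function(config) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  u <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  v <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  cf <- config$b0_coef
  cf[1] + cf[2] * u + cf[3] * v + cf[4] * u * v + cf[5] * u^2 + cf[6] * v^2
}

#' Region label map of a phantom configuration
#' @param config A [phantom_config()].
#' @return Integer matrix; 0 = background, i = i-th region of the layout
#'   (region names attached as attribute `regions`).
#' @export
region_labels <- function(config) {
  lab <- matrix(0L, config$grid_shape[1], config$grid_shape[2])
  for (i in seq_along(config$region_layout)) {
    xy <- config$region_layout[[i]]
    lab[cbind(xy[, 1], xy[, 2])] <- i
  }
  attr(lab, "regions") <- names(config$region_layout)
  lab
}

#' Simulate a phantom CEST study
#'
#' Generates, per subject, a CEST Z-spectrum stack and a paired WASSR stack
#' on a shared voxel grid with a common smooth B0 field, plus the region
#' label map, the subject/arm table and the full ground truth. Background
#' voxels carry a water-only spectrum. All randomness derives from
#' `config$seed`, so an identical configuration yields bit-identical output.
#'
#' @param config A [phantom_config()].
#' @return List of class `cest_phantom`: `config`, `axis`, `wassr_axis`,
#'   `labels` (integer matrix), `b0_true` (matrix, ppm), `subject_table`
#'   (data frame `subject`, `arm`), `truth` (data frame of per-subject
#'   jittered pool amplitudes), and `subjects` — a named list with, per
#'   subject, 3-D arrays `z` and `wassr` (row, col, offset).
#' @export
simulate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  labels <- region_labels(config)
  b0 <- b0_field(config)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  nv <- nr * nc
  regions <- names(config$region_layout)
  pools <- names(config$linewidths)

  tab <- do.call(rbind, lapply(config$arms, function(a) {
    n <- config$n_subjects_per_arm[[a]]
    data.frame(subject = sprintf("%s_%02d", a, seq_len(n)), arm = a,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  out <- with_seed(config$seed, {
    truth_rows <- list()
    subjects <- vector("list", nrow(tab))
    names(subjects) <- tab$subject
    doff <- outer(rep(1, nv), config$axis) - as.vector(b0)     # nv x n_off
    woff <- outer(rep(1, nv), config$wassr_axis) - as.vector(b0)
    lab_vec <- as.vector(labels)
    for (s in seq_len(nrow(tab))) {
      arm <- tab$arm[s]
      tr <- config$pool_truth[config$pool_truth$arm == arm, , drop = FALSE]
      jit <- stats::rnorm(nrow(tr), mean = 1, sd = config$subject_cv)
      amp <- pmin(pmax(tr$amplitude * jit, 0), 1 - 1e-6)
      tr_s <- data.frame(subject = tab$subject[s], arm = arm,
                         region = tr$region, pool = tr$pool,
                         amplitude = amp, stringsAsFactors = FALSE)
      truth_rows[[s]] <- tr_s
      z <- matrix(1, nv, length(config$axis))
      for (p in pools) {
        # per-voxel amplitude: region value, or water baseline in background
        av <- numeric(nv)
        for (ri in seq_along(regions)) {
          a_rp <- tr_s$amplitude[tr_s$region == regions[ri] &
                                   tr_s$pool == p]
          av[lab_vec == ri] <- a_rp
        }
        if (p == "water") av[lab_vec == 0L] <- 0.75
        g2 <- (config$linewidths[[p]] / 2)^2
        ctr <- pool_centers()[[p]]
        z <- z - av * g2 / (g2 + (doff - ctr)^2)
      }
      if (config$noise_sigma > 0)
        z <- z + stats::rnorm(length(z), sd = config$noise_sigma)
      gw2 <- (config$wassr_linewidth / 2)^2
      w <- 1 - config$wassr_amplitude * gw2 / (gw2 + woff^2)
      if (config$wassr_noise_sigma > 0)
        w <- w + stats::rnorm(length(w), sd = config$wassr_noise_sigma)
      subjects[[s]] <- list(
        id = tab$subject[s], arm = arm,
        z = array(z, dim = c(nr, nc, length(config$axis))),
        wassr = array(w, dim = c(nr, nc, length(config$wassr_axis))))
    }
    list(truth = do.call(rbind, truth_rows), subjects = subjects)
  })

  structure(list(config = config, axis = config$axis,
                 wassr_axis = config$wassr_axis, labels = labels,
                 b0_true = b0, subject_table = tab, truth = out$truth,
                 subjects = out$subjects),
            class = "cest_phantom")
}

#' Simulate a region/group contrast table directly
#'
#' Skips the imaging stages and draws per-subject region contrasts straight
#' from the ground-truth amplitudes on the analytic AUC scale
#' (`A * pi * Gamma / 2`), with multiplicative Gaussian between-subject
#' jitter. Useful for calibrating the statistics module (type-I error and
#' power) without the cost of voxelwise fitting.
#'
#' @param config A [phantom_config()] (only arms, counts, truth, linewidths
#'   and `subject_cv` are used).
#' @param null If `TRUE`, all arms use the baseline amplitudes (no group
#'   effects) — the null hypothesis of every comparison is then true.
#' @param seed Integer seed.
#' @return data frame with columns `subject`, `arm`, `region`, `pool`,
#'   `contrast`.
#' @export
simulate_group_table <- function(config = phantom_config(), null = FALSE,
                                 seed = config$seed) {
  tr <- config$pool_truth
  if (null) {
    base <- tr[tr$arm == config$arms[1], c("region", "pool", "amplitude")]
    tr$amplitude <- base$amplitude[match(paste(tr$region, tr$pool),
                                         paste(base$region, base$pool))]
  }
  rows <- with_seed(seed, {
    do.call(rbind, lapply(config$arms, function(a) {
      n <- config$n_subjects_per_arm[[a]]
      tra <- tr[tr$arm == a, , drop = FALSE]
      do.call(rbind, lapply(seq_len(n), function(s) {
        jit <- stats::rnorm(nrow(tra), mean = 1, sd = config$subject_cv)
        data.frame(subject = sprintf("%s_%02d", a, s), arm = a,
                   region = tra$region, pool = tra$pool,
                   contrast = tra$amplitude * jit * pi *
                     config$linewidths[tra$pool] / 2,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(rows) <- NULL
  rows
}
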