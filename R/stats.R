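#' Aggregate a contrast map over labeled regions
#'
#' Per-region mean of unmasked voxels, returned as tidy rows ready for the
#' group table. Regions whose voxels are all masked are reported missing
#' (dropped with a warning), never silently zeroed.
#'
#' @param map A [contrast_map()] or matrix (NA = masked).
#' @param labels Integer label matrix (0 = background) with region names in
#'   attribute `regions`, or supply `regions` explicitly.
#' @param subject,arm Metadata attached to every row.
#' @param regions Character vector naming labels `1..length(regions)`.
#' @param pool Pool name recorded in the rows (default from the map).
#' @return data frame with columns `subject`, `arm`, `region`, `pool`,
#'   `contrast`.
#' @export
aggregate_regions <- function(map, labels, subject, arm,
                              regions = attr(labels, "regions"),
                              pool = attr(map, "pool")) {
  m <- unclass(map)
  if (!all(dim(labels) == dim(m)))
    stop("label map shape does not match contrast map", call. = FALSE)
  if (is.null(regions))
    stop("region names missing: supply `regions` or a labeled matrix",
         call. = FALSE)
  ids <- sort(unique(as.integer(labels[labels > 0L])))
  unknown <- setdiff(ids, seq_along(regions))
  if (length(unknown))
    stop("label id(s) not in the region registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(pool)) pool <- NA_character_
  rows <- lapply(ids, function(id) {
    v <- m[labels == id]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      warning(sprintf("region '%s' has no unmasked voxels; reported missing",
                      regions[id]), call. = FALSE)
      return(NULL)
    }
    data.frame(subject = subject, arm = arm, region = regions[id],
               pool = pool, contrast = mean(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject = character(), arm = character(),
                      region = character(), pool = character(),
                      contrast = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Significance-tier label for a p-value
#'
#' Half-open bins: `[0, 1e-4)` "****", `[1e-4, 1e-3)` "***",
#' `[1e-3, 0.01)` "**", `[0.01, 0.05)` "*", `[0.05, 0.1)` "#",
#' `[0.1, 1]` "ns".
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of tier labels.
#' @examples
#' tier(c(0.04, 0.0006, 0.5))
#' @export
tier <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, 0.1, Inf), right = FALSE,
      labels = c("****", "***", "**", "*", "#", "ns")) |> as.character()
}

test_report <- function(comparison, variant, statistic, df, p,
                        degenerate = FALSE, df2 = NA_real_) {
  data.frame(comparison = comparison, variant = variant,
             statistic = statistic, df = df, df2 = df2, p = p,
             tier = if (is.na(p)) NA_character_ else tier(p),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' One-way fixed-effects ANOVA across arms
#'
#' Ordinary (equal-variance) one-way ANOVA of contrast values across
#' groups. Arms with fewer than 2 subjects are excluded with a warning;
#' all-identical data (zero within- and between-group variance) yields an
#' explicit degenerate report rather than NaN.
#'
#' @param values Numeric vector of per-subject contrasts.
#' @param groups Factor/character vector of arm labels, same length.
#' @return One-row data frame: `comparison`, `variant` ("anova"),
#'   `statistic` (F), `df` (between; within in `df2`), `p`, `tier`,
#'   `degenerate`.
#' @export
omnibus_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  n <- table(groups)
  small <- names(n)[n < 2L]
  if (length(small)) {
    warning("arm(s) with < 2 subjects excluded from ANOVA: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  k <- length(unique(groups))
  if (k < 2L)
    stop("ANOVA needs >= 2 arms with >= 2 subjects each", call. = FALSE)
  lab <- paste(sort(unique(groups)), collapse = " | ")
  N <- length(values)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw <= .Machine$double.eps * max(1, sum(values^2))) {
    return(test_report(lab, "anova", NA_real_, k - 1, NA_real_,
                       degenerate = TRUE, df2 = N - k))
  }
  fit <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
  test_report(lab, "anova", unname(fit$statistic),
              unname(fit$parameter[1]), fit$p.value,
              df2 = unname(fit$parameter[2]))
}

#' Two-tailed two-sample t-test
#'
#' Pooled-variance (Student) or Welch variant; Welch degrees of freedom by
#' Welch-Satterthwaite. Zero variance in both groups with equal means is
#' reported as degenerate.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @param comparison Label recorded in the report.
#' @return One-row data frame (`comparison`, `variant`, `statistic`, `df`,
#'   `p`, `tier`, `degenerate`).
#' @export
pairwise_ttest <- function(a, b, variant = c("pooled", "welch"),
                           comparison = "A vs B") {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(test_report(comparison, variant, NA_real_, NA_real_, NA_real_,
                         degenerate = TRUE))
    # zero variance but different means: infinitely strong evidence
    return(test_report(comparison, variant,
                       sign(mean(a) - mean(b)) * Inf,
                       length(a) + length(b) - 2, 0))
  }
  fit <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                       alternative = "two.sided")
  test_report(comparison, variant, unname(fit$statistic),
              unname(fit$parameter), fit$p.value)
}

#' Standard error of the mean
#' @param x Numeric vector.
#' @return `sd(x)/sqrt(n)`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' The full group-comparison suite
#'
#' For every (region, pool) present in the table, runs the study's
#' comparison scheme across the four arms:
#' one omnibus one-way ANOVA over all arms, then three post-hoc two-tailed
#' t-tests — baseline vs the 6-week arm (pooled variance), baseline vs the
#' untreated 12-week arm (Welch, accounting for the reduced group size),
#' and treated vs untreated at 12 weeks (`posthoc_variant`, pooled by
#' default). No multiplicity correction is applied across regions or pools
#' by default; `adjust = "holm"` applies a Holm correction within each
#' comparison family.
#'
#' @param table Tidy table with columns `subject`, `arm`, `region`, `pool`,
#'   `contrast` (e.g. from [aggregate_regions()] or
#'   [simulate_group_table()]).
#' @param arms Named character vector mapping roles `baseline`, `wk6`,
#'   `vehicle`, `art` to arm labels in the table.
#' @param posthoc_variant Variant of the treated-vs-untreated test.
#' @param paired If `TRUE`, timepoint contrasts against baseline use paired
#'   t-tests (pairing subjects by their order within each arm); applied
#'   only where the two arms have equal size, otherwise that comparison
#'   falls back to its unpaired form with a warning. Off by default, which
#'   treats arms as independent groups.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return List with `tests` (one row per test per region/pool) and
#'   `summary` (mean, SEM, n per arm/region/pool).
#' @export
comparison_suite <- function(table,
                             arms = c(baseline = "baseline", wk6 = "wk6",
                                      vehicle = "wk12_vehicle",
                                      art = "wk12_art"),
                             posthoc_variant = c("pooled", "welch"),
                             paired = FALSE,
                             adjust = c("none", "holm")) {
  posthoc_variant <- match.arg(posthoc_variant)
  adjust <- match.arg(adjust)
  need <- c("subject", "arm", "region", "pool", "contrast")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(table$contrast)))
    stop("table contains non-finite contrast values", call. = FALSE)
  combos <- unique(table[, c("region", "pool")])
  tests <- list(); summ <- list()
  for (r in seq_len(nrow(combos))) {
    sub <- table[table$region == combos$region[r] &
                   table$pool == combos$pool[r], , drop = FALSE]
    g <- function(role) sub$contrast[sub$arm == arms[[role]]]
    present <- vapply(names(arms), function(x) length(g(x)) >= 2L,
                      logical(1))
    block <- list()
    if (sum(present) >= 2L) {
      keep <- sub$arm %in% arms[present]
      block$anova <- omnibus_anova(sub$contrast[keep], sub$arm[keep])
    }
    pair <- function(x, y, variant, label, allow_paired = FALSE) {
      if (!present[[x]] || !present[[y]]) {
        warning(sprintf("skipping '%s' (missing arm)", label), call. = FALSE)
        return(NULL)
      }
      a <- g(x); b <- g(y)
      if (paired && allow_paired) {
        if (length(a) == length(b)) {
          fit <- stats::t.test(a, b, paired = TRUE)
          return(test_report(label, "paired", unname(fit$statistic),
                             unname(fit$parameter), fit$p.value))
        }
        warning(sprintf("'%s': unequal arm sizes, falling back to unpaired",
                        label), call. = FALSE)
      }
      pairwise_ttest(a, b, variant, comparison = label)
    }
    block$t_wk6 <- pair("baseline", "wk6", "pooled", "baseline vs wk6",
                        allow_paired = TRUE)
    block$t_vehicle <- pair("baseline", "vehicle", "welch",
                            "baseline vs wk12_vehicle", allow_paired = TRUE)
    block$t_art <- pair("art", "vehicle", posthoc_variant,
                        "wk12_art vs wk12_vehicle")
    block <- do.call(rbind, block)
    if (!is.null(block)) {
      block$region <- combos$region[r]
      block$pool <- combos$pool[r]
      tests[[r]] <- block
    }
    sm <- do.call(rbind, lapply(unique(sub$arm), function(a) {
      v <- sub$contrast[sub$arm == a]
      data.frame(region = combos$region[r], pool = combos$pool[r], arm = a,
                 n = length(v), mean = mean(v), sem = sem(v),
                 stringsAsFactors = FALSE)
    }))
    summ[[r]] <- sm
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  if (adjust == "holm" && !is.null(tests)) {
    for (cmp in unique(tests$comparison)) {
      i <- tests$comparison == cmp & !tests$degenerate
      tests$p[i] <- stats::p.adjust(tests$p[i], method = "holm")
    }
    tests$tier[!tests$degenerate] <- tier(tests$p[!tests$degenerate])
  }
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  list(tests = tests, summary = summ)
}
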