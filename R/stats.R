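# Region quantification: per-B-scan means over manually segmented masks,
# box-whisker summaries, Mann-Whitney U and Levene tests.

#' Labelled region masks aligned to a volume
#'
#' @param ... Named logical arrays (e.g. `tumor = `, `control = `) of the
#'   volume's `[nz, nx, ny]` shape (2-D input promoted to one B-scan).
#'   Labels must be disjoint in every B-scan.
#' @param volume_ref Optional identifier of the volume the masks belong
#'   to.
#' @return A `region_mask_set`.
#' @export
region_mask_set <- function(..., volume_ref = NULL) {
  masks <- list(...)
  if (length(masks) == 1 && is.list(masks[[1]]) && !is.array(masks[[1]]))
    masks <- masks[[1]]
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("masks must be named (e.g. tumor, control)")
  masks <- lapply(masks, function(m) {
    m <- as.array(m)
    if (length(dim(m)) == 2) dim(m) <- c(dim(m), 1L)
    storage.mode(m) <- "logical"
    m
  })
  dm <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), dm), logical(1))))
    stop("all masks must share one shape")
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(overlap > 1)) stop("labels must be disjoint (overlapping masks)")
  structure(list(masks = masks, volume_ref = volume_ref),
            class = "region_mask_set")
}

#' Per-B-scan mean of a contrast within each labelled region
#'
#' One data point per B-scan and label: the mean of the contrast over the
#' region's voxels in that B-scan, excluding undefined (`NA`) voxels.
#' B-scans where a label's mask is empty are skipped for that label.
#'
#' @param volume A [scalar_volume()].
#' @param masks A [region_mask_set()] aligned to the volume.
#' @return A tibble with columns `bscan`, `label`, `mean`, `n_voxels`.
#' @export
region_means_per_bscan <- function(volume, masks) {
  stopifnot(inherits(volume, "scalar_volume"),
            inherits(masks, "region_mask_set"))
  dm <- dim(volume$data)
  if (!identical(dim(masks$masks[[1]]), dm))
    stop("mask shape does not match the volume")
  purrr::map_dfr(names(masks$masks), function(lab) {
    m <- masks$masks[[lab]]
    purrr::map_dfr(seq_len(dm[3]), function(y) {
      sel <- volume$data[, , y][m[, , y]]
      sel <- sel[!is.na(sel)]
      if (!length(sel)) return(NULL)
      tibble::tibble(bscan = y, label = lab, mean = mean(sel),
                     n_voxels = length(sel))
    })
  })
}

#' Mann-Whitney U test (rank-sum) with exact small-sample enumeration
#'
#' U is computed from midrank sums. For `n1 + n2 <= 16` without ties the
#' two-sided p-value is exact, by enumeration of all rank assignments;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. Two samples with all values identical
#' give `p = 1`.
#'
#' @param a,b Numeric samples (each length >= 1).
#' @return A tibble with `u` (U of the first sample), `p` (two-sided),
#'   `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); nn <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)                            # midranks
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  m <- n1 * n2

  if (min(pooled) == max(pooled))
    return(tibble::tibble(u = u, p = 1, method = "degenerate"))

  if (nn <= 16 && !ties) {
    combos <- utils::combn(nn, n1)      # rank sets assigned to sample 1
    u_all <- colSums(combos) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - m / 2) >= abs(u - m / 2) - 1e-12)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    v <- m / 12 * ((nn + 1) - tie_corr)
    if (v <= 0) return(tibble::tibble(u = u, p = 1, method = "degenerate"))
    z <- (abs(u - m / 2) - 0.5) / sqrt(v)       # continuity correction
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal_approx"
  }
  tibble::tibble(u = u, p = p, method = method)
}

#' Levene's test for equality of variances (two groups)
#'
#' The classic form: a one-way ANOVA F statistic on the absolute
#' deviations from each group's center (mean by default; median gives the
#' Brown-Forsythe variant). p comes from the F distribution with
#' `(1, n1 + n2 - 2)` degrees of freedom.
#'
#' @param a,b Numeric samples (each length >= 2).
#' @param center `"mean"` or `"median"`.
#' @return A tibble with `w` (the F statistic), `p`, `center`.
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2)
  cfun <- if (center == "mean") mean else stats::median
  za <- abs(a - cfun(a)); zb <- abs(b - cfun(b))
  n1 <- length(za); n2 <- length(zb); nn <- n1 + n2
  zbar <- mean(c(za, zb))
  ssb <- n1 * (mean(za) - zbar)^2 + n2 * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (ssw == 0) {
    w <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    w <- (ssb / 1) / (ssw / (nn - 2))
    p <- stats::pf(w, 1, nn - 2, lower.tail = FALSE)
  }
  tibble::tibble(w = w, p = p, center = center)
}

#' Box-whisker summary of a sample
#'
#' Median and quartiles by linear interpolation between order statistics;
#' whiskers extend to the most extreme points within `1.5 * IQR` of the
#' box; points beyond the whiskers are outliers.
#'
#' @param values Numeric sample (NAs dropped).
#' @param whisker_mult Whisker reach as a multiple of the IQR.
#' @return A one-row tibble: `median`, `q25`, `q75`, `whisker_lo`,
#'   `whisker_hi`, `outliers` (list column), `n`.
#' @export
box_summary <- function(values, whisker_mult = 1.5) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  stopifnot(length(v) >= 1)
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - whisker_mult * iqr
  hi_lim <- q[3] + whisker_mult * iqr
  inside <- v[v >= lo_lim & v <= hi_lim]
  out <- v[v < lo_lim | v > hi_lim]
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3],
                 whisker_lo = min(inside), whisker_hi = max(inside),
                 outliers = list(sort(out)), n = length(v))
}

#' Quantify contrast differences between labelled regions
#'
#' The full quantification workflow: per-B-scan region means for every
#' contrast, box-whisker summaries per label, and two-sample tests
#' (Mann-Whitney U for distribution equality, Levene for variance
#' equality) between the two labels, flagged at the chosen significance
#' level. When `animal_id` is given (one id per B-scan), tests are
#' reported both pooled over all B-scans and per animal.
#'
#' @param volumes Named list of [scalar_volume()]s (the contrasts), all
#'   aligned to `masks`.
#' @param masks A [region_mask_set()] with exactly two labels.
#' @param alpha Significance level for the flags.
#' @param levene_center Passed to [levene_test()].
#' @param animal_id Optional vector of per-B-scan animal identifiers.
#' @return A `stats_report`: list with tibbles `means` (per B-scan),
#'   `summaries` (per label x contrast box summaries) and `tests` (per
#'   contrast, with `scope = "pooled"` and optionally per-animal rows).
#' @export
quantify_regions <- function(volumes, masks, alpha = 0.05,
                             levene_center = "mean", animal_id = NULL) {
  stopifnot(is.list(volumes), length(names(volumes)) == length(volumes))
  labs <- names(masks$masks)
  if (length(labs) != 2) stop("exactly two labels are required")
  means <- purrr::map_dfr(names(volumes), function(cn) {
    dplyr::mutate(region_means_per_bscan(volumes[[cn]], masks),
                  contrast = cn, .before = 1)
  })
  if (!is.null(animal_id))
    means <- dplyr::mutate(means, animal = animal_id[.data$bscan])

  summaries <- means |>
    dplyr::group_by(.data$contrast, .data$label) |>
    dplyr::reframe(box_summary(.data$mean))

  run_tests <- function(df, scope) {
    purrr::map_dfr(unique(df$contrast), function(cn) {
      x <- df$mean[df$contrast == cn & df$label == labs[1]]
      y <- df$mean[df$contrast == cn & df$label == labs[2]]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      mw <- mann_whitney_u(x, y)
      lv <- levene_test(x, y, center = levene_center)
      tibble::tibble(
        scope = scope, contrast = cn,
        u = mw$u, p_mann_whitney = mw$p, mw_method = mw$method,
        w = lv$w, p_levene = lv$p,
        mean_1 = mean(x), mean_2 = mean(y),
        direction = dplyr::case_when(
          stats::median(x) < stats::median(y) ~ paste(labs[1], "<", labs[2]),
          stats::median(x) > stats::median(y) ~ paste(labs[1], ">", labs[2]),
          TRUE ~ "equal"),
        significant_mw = mw$p < alpha,
        significant_levene = lv$p < alpha)
    })
  }
  tests <- run_tests(means, "pooled")
  if (!is.null(animal_id)) {
    for (an in unique(animal_id)) {
      tests <- dplyr::bind_rows(
        tests, run_tests(dplyr::filter(means, .data$animal == an),
                         paste0("animal:", an)))
    }
  }
  structure(list(means = means, summaries = summaries, tests = tests,
                 labels = labs, alpha = alpha),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> labels: %s vs %s, alpha = %g\n",
              x$labels[1], x$labels[2], x$alpha))
  print(x$tests, ...)
  invisible(x)
}

#' Tidy a stats report into its per-contrast test table
#'
#' @param x A `stats_report` from [quantify_regions()].
#' @param ... Unused.
#' @return The tests tibble (one row per contrast and scope).
#' @method tidy stats_report
#' @export
#' @importFrom generics tidy
tidy.stats_report <- function(x, ...) x$tests

#' One-row model-level summary of a stats report
#'
#' @param x A `stats_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of B-scans, contrasts, and how many
#'   contrasts reached significance in each test.
#' @method glance stats_report
#' @export
#' @importFrom generics glance
glance.stats_report <- function(x, ...) {
  pooled <- dplyr::filter(x$tests, .data$scope == "pooled")
  tibble::tibble(
    n_bscans = length(unique(x$means$bscan)),
    n_contrasts = length(unique(x$means$contrast)),
    n_significant_mw = sum(pooled$significant_mw),
    n_significant_levene = sum(pooled$significant_levene),
    alpha = x$alpha)
}

#' Box-whisker figure for a stats report
#'
#' Re-creates the per-contrast box-whisker presentation: one panel per
#' contrast, a box from the quartiles with a median line, whiskers at the
#' most extreme points within 1.5 IQR, outliers as crosses, and the
#' individual per-B-scan means jittered horizontally.
#'
#' @param object A `stats_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stats_report
#' @export
#' @importFrom ggplot2 autoplot
autoplot.stats_report <- function(object, ...) {
  s <- object$summaries
  outs <- tidyr::unnest(
    dplyr::select(s, "contrast", "label", "outliers"),
    cols = "outliers")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_lo, lower = .data$q25,
                   middle = .data$median, upper = .data$q75,
                   ymax = .data$whisker_hi),
      stat = "identity", width = 0.5) +
    ggplot2::geom_jitter(
      data = object$means,
      ggplot2::aes(y = .data$mean), width = 0.12, alpha = 0.5, size = 0.8) +
    ggplot2::geom_point(
      data = outs, ggplot2::aes(y = .data$outliers),
      shape = 4, color = "red") +
    ggplot2::facet_wrap(~contrast, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-B-scan region mean")
}
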