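#' Distance-factor-metric tortuosity curve
#'
#' Evaluates the DFM at every point along a centerline path from its first
#' point: \eqn{DFM_i = L_i / d_i}, where \eqn{L_i} is the cumulative arc
#' length along the path and \eqn{d_i} the straight-line distance from the
#' start. The DFM at the first point (d = 0) is defined as 1. A straight
#' vessel stays at 1; loops drive the curve up as the chord shrinks relative
#' to the arc.
#'
#' @param path a \code{\link{centerline_path}} with at least 2 points.
#' @return A data frame of class \code{tortuosity_curve} with columns
#'   \code{point}, \code{L} (mm), \code{d} (mm), \code{dfm}.
#' @export
dfm_curve <- function(path) {
  if (!inherits(path, "centerline_path"))
    stop("`path` must be a centerline_path")
  n <- nrow(path$coords)
  if (n < 2L) stop("a tortuosity curve needs a path with at least 2 points")
  L <- path$cumulative_length
  d <- sqrt(rowSums(sweep(path$coords, 2, path$coords[1, ], "-")^2))
  dfm <- ifelse(d > 0, L / d, 1)
  out <- data.frame(point = seq_len(n), L = L, d = d, dfm = dfm)
  class(out) <- c("tortuosity_curve", "data.frame")
  attr(out, "spacing") <- attr(path, "spacing")
  out
}

#' Read a single tortuosity measurement from a curve
#'
#' \code{end} mode returns the DFM at the final point; \code{peak} mode
#' returns the maximum of the discrete curve, excluding points whose chord
#' \code{d} is below a small floor (two voxel diagonals) where L/d is
#' near-singular.
#'
#' @param curve a \code{\link{dfm_curve}} result.
#' @param mode \code{"peak"} or \code{"end"}.
#' @param d_floor chord floor for the peak search, in mm; default two voxel
#'   diagonals of the stated spacing.
#' @param spacing voxel spacing used for the default floor.
#' @param label optional artery label carried into the measurement.
#' @return An object of class \code{tortuosity_measurement}: list with
#'   \code{value} (>= 1), \code{mode}, \code{label}, and the curve row index
#'   the value was read from.
#' @export
read_measurement <- function(curve, mode = c("peak", "end"), d_floor = NULL,
                             spacing = c(1, 1, 1), label = NA_character_) {
  mode <- match.arg(mode)
  if (!inherits(curve, "tortuosity_curve"))
    stop("`curve` must be a tortuosity_curve")
  if (nrow(curve) == 0L) stop("empty tortuosity curve")
  if (mode == "end") {
    i <- nrow(curve)
  } else {
    if (is.null(d_floor)) d_floor <- 2 * sqrt(sum(spacing^2))
    ok <- which(curve$d >= d_floor)
    if (length(ok) == 0L) ok <- nrow(curve)  # short path: fall back to end
    i <- ok[which.max(curve$dfm[ok])]
  }
  structure(list(value = curve$dfm[i], mode = mode, label = label,
                 point = curve$point[i], L = curve$L[i], d = curve$d[i]),
            class = "tortuosity_measurement")
}

#' @export
print.tortuosity_measurement <- function(x, ...) {
  cat("<tortuosity_measurement> ", format(x$value, digits = 6), " (",
      x$mode, if (!is.na(x$label)) paste0(", ", x$label), ") at L = ",
      format(x$L, digits = 5), " mm, d = ", format(x$d, digits = 5),
      " mm\n", sep = "")
  invisible(x)
}

#' Aggregate artery measurements per subject and artery group
#'
#' Computes the mean DFM per (subject, artery) group — e.g. the mean of up
#' to four prominent lenticulostriate arteries — and supports selecting the
#' left-most or right-most path by the x-coordinate of the path start.
#'
#' @param measurements a data frame with columns \code{subject},
#'   \code{artery}, \code{value}, and optionally \code{start_x}; or a plain
#'   numeric vector (treated as one group).
#' @param select \code{"mean"}, \code{"leftmost"} or \code{"rightmost"}.
#' @return A data frame with one row per (subject, artery) group.
#' @export
aggregate_arteries <- function(measurements,
                               select = c("mean", "leftmost", "rightmost")) {
  select <- match.arg(select)
  if (is.numeric(measurements))
    measurements <- data.frame(subject = 1L, artery = "artery",
                               value = measurements)
  if (nrow(measurements) == 0L) stop("no measurements to aggregate")
  if (select != "mean" && is.null(measurements$start_x))
    stop("left/right selection requires a `start_x` column")
  split_by <- interaction(measurements$subject, measurements$artery,
                          drop = TRUE)
  rows <- lapply(split(measurements, split_by), function(g) {
    value <- switch(select,
                    mean = mean(g$value),
                    leftmost = g$value[which.min(g$start_x)],
                    rightmost = g$value[which.max(g$start_x)])
    data.frame(subject = g$subject[1], artery = g$artery[1],
               n = nrow(g), value = value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison statistics for tortuosity values
#'
#' Runs the standard battery used for tortuosity comparisons: two-sided and
#' one-sided Wilcoxon rank-sum tests, a paired Wilcoxon signed-rank test,
#' one-way ANOVA, and an F-test of variances, together with the
#' Bonferroni-adjusted significance threshold \eqn{\beta = \alpha / n}.
#' The Wilcoxon tests use the exact distribution when the combined sample
#' size is at most 25 and there are no ties, and the normal approximation
#' with tie correction otherwise; the variant used is recorded.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each; the paired test
#'   additionally requires equal lengths).
#' @param tests subset of \code{c("wilcoxon_2sided", "wilcoxon_1sided",
#'   "wilcoxon_paired", "anova", "f_var")}.
#' @param n_comparisons number of comparisons for the Bonferroni threshold.
#' @param alpha family-wise significance level.
#' @return A list of class \code{group_comparison}: per-test p-values (NA
#'   with an explanatory flag when a test is not applicable), \code{beta}
#'   (the Bonferroni threshold), and the Wilcoxon variant used.
#' @export
compare_groups <- function(group_a, group_b,
                           tests = c("wilcoxon_2sided", "wilcoxon_1sided",
                                     "wilcoxon_paired", "anova", "f_var"),
                           n_comparisons = 1, alpha = 0.05) {
  tests <- match.arg(tests, several.ok = TRUE)
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b) <= 25) && !has_ties
  p <- list()
  notes <- list()
  wtest <- function(...) suppressWarnings(stats::wilcox.test(...))
  if ("wilcoxon_2sided" %in% tests)
    p$wilcoxon_2sided <- wtest(group_a, group_b, exact = exact,
                               correct = TRUE)$p.value
  if ("wilcoxon_1sided" %in% tests)
    p$wilcoxon_1sided <- wtest(group_a, group_b, alternative = "greater",
                               exact = exact, correct = TRUE)$p.value
  if ("wilcoxon_paired" %in% tests) {
    if (length(group_a) != length(group_b)) {
      p$wilcoxon_paired <- NA_real_
      notes$wilcoxon_paired <- "paired test requires equal group lengths"
    } else if (all(group_a == group_b)) {
      p$wilcoxon_paired <- 1
      notes$wilcoxon_paired <- "all pairwise differences are zero"
    } else {
      p$wilcoxon_paired <- wtest(group_a, group_b, paired = TRUE,
                                 exact = exact)$p.value
    }
  }
  if ("anova" %in% tests) {
    df <- data.frame(value = c(group_a, group_b),
                     group = factor(rep(c("a", "b"),
                                        c(length(group_a),
                                          length(group_b)))))
    if (stats::var(df$value) == 0) {
      p$anova <- 1
      notes$anova <- "zero total variance"
    } else {
      p$anova <- stats::anova(stats::lm(value ~ group,
                                        data = df))[["Pr(>F)"]][1]
    }
  }
  if ("f_var" %in% tests) {
    if (stats::var(group_a) == 0 || stats::var(group_b) == 0) {
      p$f_var <- NA_real_
      notes$f_var <- "zero variance in a group"
    } else {
      p$f_var <- stats::var.test(group_a, group_b)$p.value
    }
  }
  structure(list(p_values = p, beta = alpha / n_comparisons,
                 alpha = alpha, n_comparisons = n_comparisons,
                 wilcoxon_variant = if (exact) "exact" else
                   "normal approximation with tie correction",
                 notes = notes),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> Bonferroni beta = alpha/n = ", format(x$alpha),
      "/", x$n_comparisons, " = ", format(x$beta), "\n", sep = "")
  for (nm in names(x$p_values)) {
    cat("  ", format(nm, width = 16), " p = ",
        format(x$p_values[[nm]], digits = 4), sep = "")
    if (!is.null(x$notes[[nm]])) cat("  (", x$notes[[nm]], ")", sep = "")
    cat("\n")
  }
  cat("  Wilcoxon variant: ", x$wilcoxon_variant, "\n", sep = "")
  invisible(x)
}

#' Export a tortuosity curve as CSV
#'
#' Columns \code{point}, \code{L_mm}, \code{d_mm}, \code{DFM}; the curve can
#' be plotted against either \code{d_mm} or \code{L_mm}.
#'
#' @param curve a \code{\link{dfm_curve}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(point = curve$point, L_mm = curve$L, d_mm = curve$d,
                   DFM = curve$dfm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
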