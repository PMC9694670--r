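#' Dice index of two binary masks, as a percentage
#'
#' `100 * 2|A ∩ B| / (|A| + |B|)`. Two empty masks agree vacuously and give
#' 100 (such cases carry a `both_empty` attribute and are meant to be
#' excluded from aggregation).
#'
#' @param a,b 0/1 matrices of identical shape.
#' @return Percentage in `[0, 100]`.
#' @export
dice <- function(a, b) {
  a <- mask_pixels(a); b <- mask_pixels(b)
  if (!identical(dim(a), dim(b))) stop("masks must share a shape")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(structure(100, both_empty = TRUE))
  100 * 2 * sum(a * b) / denom
}

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Mean Dice for one bone/method selection
#'
#' Arithmetic mean of the selected records, reported with half-up rounding
#' to two decimals (the printed precision of the reference tables).
#'
#' @param records data frame with columns `bone`, `method`, `dice` (and
#'   optionally `case`/`dataset`).
#' @param bone,method selection; `NULL` keeps all.
#' @return Mean Dice percentage, rounded to 2 decimals.
#' @export
aggregate_dice <- function(records, bone = NULL, method = NULL) {
  sel <- rep(TRUE, nrow(records))
  if (!is.null(bone)) sel <- sel & records$bone == bone
  if (!is.null(method)) sel <- sel & records$method == method
  if (!any(sel)) stop("empty selection")
  round_half_up(mean(records$dice[sel]), 2L)
}

#' Packaged per-case Dice tables of the reference study
#'
#' Long-format data frame of the published per-series Dice indices:
#' `dataset` (`"ct"`: 31 CT series, transverse; `"mri"`: 50 T1 MR series,
#' sagittal; `"fastmri"`: 10 fastMRI T1 series, sagittal), `case`, `bone`,
#' `method` (`"FC"`/`"FCM"`) and `dice` (percent).
#'
#' @param dataset optional subset.
#' @return Data frame.
#' @export
load_reference_dice <- function(dataset = NULL) {
  fn <- system.file("extdata", "reference_dice.csv", package = "kneeatlas",
                    mustWork = TRUE)
  d <- utils::read.csv(fn)
  if (!is.null(dataset)) d <- d[d$dataset %in% dataset, ]
  d
}

#' Bland-Altman statistics for paired FC/FCM measurements
#'
#' Differences are taken as `d = FCM - FC` (FC is the reference method);
#' reported are their mean, sample standard deviation and the 95% limits of
#' agreement `mean ± 1.96 sd`.
#'
#' @param pairs two-column matrix or data frame: first column FC, second
#'   FCM (n >= 2 rows).
#' @return List of class `bland_altman`: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `differences`, `means`.
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L) stop("Bland-Altman needs at least 2 pairs")
  d <- pairs[, 2L] - pairs[, 1L]
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 differences = unname(d),
                 means = unname(rowMeans(pairs))),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean diff %.4f, sd %.4f, 95%% LoA [%.4f, %.4f] (n = %d)\n",
    x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, length(x$differences)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of methods",
                 ylab = "FCM - FC", ...)
  graphics::abline(h = c(x$mean_diff, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Paired Wilcoxon and one-sided t-test on FC/FCM Dice pairs
#'
#' The Wilcoxon signed-rank test (two-sided; exact for n <= 25 after
#' dropping zero differences, normal approximation with continuity
#' correction otherwise) and the paired one-sided t-test with alternative
#' "FCM < FC". All-zero differences make both tests inapplicable, mirrored
#' by `NA` p-values with `applicable = FALSE`.
#'
#' @param pairs two-column matrix/data frame: first column FC, second FCM.
#' @return List: `wilcoxon_p`, `ttest_p`, `applicable`, `n`, `n_nonzero`.
#' @export
paired_tests <- function(pairs) {
  pairs <- as.matrix(pairs)
  d <- pairs[, 2L] - pairs[, 1L]
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(wilcoxon_p = NA_real_, ttest_p = NA_real_,
                applicable = FALSE, n = length(d), n_nonzero = 0L))
  wp <- if (length(nz) < 5L) NA_real_ else suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = length(nz) <= 25L,
                       correct = TRUE)$p.value)
  tp <- if (stats::sd(d) == 0) 0 else
    stats::t.test(pairs[, 2L], pairs[, 1L], paired = TRUE,
                  alternative = "less")$p.value
  list(wilcoxon_p = wp, ttest_p = tp, applicable = TRUE,
       n = length(d), n_nonzero = length(nz))
}

#' Evaluation report over a Dice record table
#'
#' Per bone: FC and FCM mean Dice, Bland-Altman statistics and paired-test
#' p-values of the FC/FCM differences, plus the data series a box or
#' Bland-Altman plot needs.
#'
#' @param records long data frame (`case`, `bone`, `method`, `dice`).
#' @return Named list per bone, class `knee_report`.
#' @export
dice_report <- function(records) {
  out <- list()
  for (bone in intersect(BONES, unique(records$bone))) {
    fc <- records[records$bone == bone & records$method == "FC", ]
    fcm <- records[records$bone == bone & records$method == "FCM", ]
    fc <- fc[order(fc$case), ]; fcm <- fcm[order(fcm$case), ]
    common <- intersect(fc$case, fcm$case)
    pairs <- cbind(FC = fc$dice[match(common, fc$case)],
                   FCM = fcm$dice[match(common, fcm$case)])
    out[[bone]] <- list(
      mean_fc = aggregate_dice(records, bone, "FC"),
      mean_fcm = aggregate_dice(records, bone, "FCM"),
      bland_altman = if (nrow(pairs) >= 2L) bland_altman(pairs) else NULL,
      tests = paired_tests(pairs),
      pairs = pairs)
  }
  class(out) <- "knee_report"
  out
}

#' @export
print.knee_report <- function(x, ...) {
  for (bone in names(x)) {
    r <- x[[bone]]
    cat(sprintf("%-8s mean Dice: FC %.2f, FCM %.2f", bone,
                r$mean_fc, r$mean_fcm))
    if (!is.null(r$bland_altman))
      cat(sprintf("; diff %.3f +/- %.3f", r$bland_altman$mean_diff,
                  r$bland_altman$sd_diff))
    if (isTRUE(r$tests$applicable))
      cat(sprintf("; Wilcoxon p %.4g, t-test p %.4g",
                  r$tests$wilcoxon_p, r$tests$ttest_p))
    cat("\n")
  }
  invisible(x)
}

#' Volumetric Dice of predicted vs. truth masks for a segmented volume
#'
#' Per bone, intersections and mask areas are summed over all slices before
#' forming the Dice index (the standard one-number-per-series aggregation);
#' slices where both the prediction and the truth are empty contribute
#' nothing.
#'
#' @param results output of [segment_volume()].
#' @param truth_masks per-slice list of named 0/1 masks.
#' @return Named numeric vector of Dice percentages per bone.
#' @export
volume_dice <- function(results, truth_masks) {
  vapply(BONES, function(b) {
    inter <- 0; tot <- 0
    for (i in seq_along(results)) {
      pm <- mask_pixels(results[[i]][[b]]$mask)
      tm <- if (!is.null(truth_masks[[i]][[b]]))
        mask_pixels(truth_masks[[i]][[b]]) else matrix(0, nrow(pm), ncol(pm))
      inter <- inter + sum(pm * tm)
      tot <- tot + sum(pm) + sum(tm)
    }
    if (tot == 0) 100 else 100 * 2 * inter / tot
  }, numeric(1))
}
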