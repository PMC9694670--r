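#' Similarity configuration for gradient-based measures
#'
#' @param measure `"NCC"`, `"GC"` or `"GD"`.
#' @param s positive scaling factor applied to the second image's gradients
#'   in the gradient-difference measure. For images of a common size
#'   (matching runs at 256x256) the scale is 1.
#' @param sobel_size derivative mask size; only the 3x3 Sobel masks are
#'   supported.
#' @return A list of class `similarity_config`.
#' @export
similarity_config <- function(measure = c("NCC", "GC", "GD"), s = 1,
                              sobel_size = 3L) {
  measure <- match.arg(measure)
  if (s <= 0) stop("scaling factor s must be > 0")
  if (sobel_size != 3L) stop("only 3x3 Sobel masks are supported")
  structure(list(measure = measure, s = s, sobel_size = 3L),
            class = "similarity_config")
}

#' Sobel derivatives of a raster
#'
#' 3x3 horizontal/vertical Sobel masks with edge-replicated borders.
#'
#' @param m numeric matrix.
#' @return List with `gx` (derivative along columns/x) and `gy` (rows/y).
#' @export
sobel_gradients <- function(m) {
  m <- as.matrix(m)
  p <- pad_replicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) p[(2L + dr):(nr + 1L + dr),
                           (2L + dc):(nc + 1L + dc), drop = FALSE]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  list(gx = gx, gy = gy)
}

#' Normalized cross-correlation of two rasters
#'
#' Zero-mean NCC, i.e. the Pearson correlation over pixels; invariant to
#' positive affine intensity changes of either argument. If both rasters are
#' constant the measure is undefined and an error is raised; if exactly one
#' is constant, 0 (no linear association) is returned.
#'
#' @param a,b numeric matrices of identical shape.
#' @return Score in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("rasters must share a shape")
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  if (va == 0 && vb == 0) stop("NCC undefined: both rasters are constant")
  if (va == 0 || vb == 0) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

#' Gradient correlation of two rasters
#'
#' The mean of the NCCs of the horizontal and of the vertical 3x3 Sobel
#' derivatives; invariant to additive intensity offsets.
#'
#' @param a,b numeric matrices of identical shape.
#' @param cfg a [similarity_config()].
#' @return Score in `[-1, 1]`.
#' @export
gradient_correlation <- function(a, b, cfg = similarity_config("GC")) {
  ga <- sobel_gradients(a); gb <- sobel_gradients(b)
  (ncc(ga$gx, gb$gx) + ncc(ga$gy, gb$gy)) / 2
}

#' Gradient difference of two rasters
#'
#' Lorentzian-weighted residuals of the Sobel derivative images:
#' with `dV = dA/dy - s*dB/dy` and `dH = dA/dx - s*dB/dx`,
#' `GD = sum(Av / (Av + dV^2)) + sum(Ah / (Ah + dH^2))`
#' where `Av`, `Ah` are the variances of the first image's derivative
#' images. Identical inputs at `s = 1` give `2 * npixels`; the score
#' decreases as the images diverge.
#'
#' @param a,b numeric matrices of identical shape.
#' @param cfg a [similarity_config()]; `cfg$s` scales the second image's
#'   gradients (1 for same-size images).
#' @return Positive score (higher = more similar).
#' @export
gradient_difference <- function(a, b, cfg = similarity_config("GD")) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("rasters must share a shape")
  ga <- sobel_gradients(a); gb <- sobel_gradients(b)
  av <- stats::var(as.vector(ga$gy)); ah <- stats::var(as.vector(ga$gx))
  if (av == 0 || ah == 0)
    stop("gradient difference undefined: reference gradients have zero variance")
  dv <- ga$gy - cfg$s * gb$gy
  dh <- ga$gx - cfg$s * gb$gx
  sum(av / (av + dv^2)) + sum(ah / (ah + dh^2))
}

score_pair <- function(a, b, cfg) {
  switch(cfg$measure,
         NCC = ncc(a, b),
         GC = gradient_correlation(a, b, cfg),
         GD = gradient_difference(a, b, cfg))
}

#' Match every slice of a reference series against a candidate series
#'
#' For each reference slice the chosen similarity measure is evaluated
#' against every candidate slice and the best-scoring candidate reported
#' (ties broken by the lowest candidate index). By default both series are
#' first converted to entropy fuzziness maps, which highlight the bone
#' boundaries the match should key on; set `fuzzify = FALSE` to score raw
#' intensities.
#'
#' @param ref,cand [knee_volume] objects on the same plane and modality.
#' @param measure `"NCC"`, `"GC"` or `"GD"`.
#' @param fuzzify logical; compute fuzziness maps before scoring.
#' @param fuzziness_measure,window passed to [fuzziness_map()].
#' @param s gradient-difference scaling factor.
#' @return A data frame of class `knee_match` with one row per reference
#'   slice (`reference_index`, `best_index`, `best_score`) and the full
#'   score matrix in `attr(, "scores")` (rows = reference slices).
#' @export
match_series <- function(ref, cand, measure = c("NCC", "GC", "GD"),
                         fuzzify = TRUE,
                         fuzziness_measure = "entropy", window = 3L, s = 1) {
  measure <- match.arg(measure)
  stopifnot(inherits(ref, "knee_volume"), inherits(cand, "knee_volume"))
  if (cand$n_slices == 0L) stop("empty candidate series")
  if (ref$plane != cand$plane || ref$modality != cand$modality)
    stop("series must share plane and modality")
  cfg <- similarity_config(measure, s = s)
  grab <- function(v) lapply(v$slices, function(sl)
    if (fuzzify) fuzziness_map(sl, fuzziness_measure, window)$values
    else sl$pixels)
  rimgs <- grab(ref); cimgs <- grab(cand)
  # gradients are per-slice, not per-pair; precompute for GC/GD
  if (measure %in% c("GC", "GD")) {
    rg <- lapply(rimgs, sobel_gradients)
    cg <- lapply(cimgs, sobel_gradients)
  }
  scores <- matrix(NA_real_, ref$n_slices, cand$n_slices)
  for (i in seq_len(ref$n_slices)) {
    if (measure == "GD") {
      av <- stats::var(as.vector(rg[[i]]$gy))
      ah <- stats::var(as.vector(rg[[i]]$gx))
      if (av == 0 || ah == 0)
        stop("gradient difference undefined: reference gradients have zero variance")
    }
    for (j in seq_len(cand$n_slices)) {
      scores[i, j] <- switch(measure,
        NCC = ncc(rimgs[[i]], cimgs[[j]]),
        GC = (ncc(rg[[i]]$gx, cg[[j]]$gx) + ncc(rg[[i]]$gy, cg[[j]]$gy)) / 2,
        GD = {
          dv <- rg[[i]]$gy - cfg$s * cg[[j]]$gy
          dh <- rg[[i]]$gx - cfg$s * cg[[j]]$gx
          sum(av / (av + dv^2)) + sum(ah / (ah + dh^2))
        })
    }
  }
  best <- apply(scores, 1L, which.max)          # which.max takes lowest tie
  out <- data.frame(reference_index = seq_len(ref$n_slices),
                    best_index = as.integer(best),
                    best_score = scores[cbind(seq_len(ref$n_slices), best)])
  attr(out, "scores") <- scores
  attr(out, "measure") <- measure
  class(out) <- c("knee_match", class(out))
  out
}

#' @export
print.knee_match <- function(x, ...) {
  cat(sprintf("<knee_match> %s over %d reference slices\n",
              attr(x, "measure"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
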