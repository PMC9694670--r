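#' Window memberships for the fuzzy-image representation
#'
#' Memberships are the window-local min-max rescaling of intensity:
#' `mu = (I - min) / (max - min)`, with a constant window mapping to
#' all-zero memberships. This is the per-window building block of the
#' fuzziness measures; exposed mainly for testing and illustration.
#'
#' @param patch odd-sized square intensity matrix (w >= 3).
#' @return Matrix of memberships in `[0, 1]`.
#' @export
membership_window <- function(patch) {
  patch <- as.matrix(patch)
  w <- nrow(patch)
  if (w != ncol(patch) || w < 3L || w %% 2L == 0L)
    stop("patch must be square with odd size >= 3")
  rng <- range(patch)
  if (diff(rng) == 0) return(patch * 0)
  (patch - rng[1L]) / diff(rng)
}

# Pad a matrix by edge replication.
pad_replicate <- function(m, k) {
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

# Binary Shannon entropy of a membership value, normalized to [0,1].
.h2 <- function(mu) {
  out <- numeric(length(mu))
  inside <- mu > 0 & mu < 1
  m <- mu[inside]
  out[inside] <- -(m * log(m) + (1 - m) * log(1 - m)) / log(2)
  out
}

#' Per-pixel fuzziness map of a slice
#'
#' For each pixel, intensities in its `w x w` neighbourhood (edge-replicated
#' at the borders) are converted to memberships by window min-max rescaling,
#' and the De Luca-Termini logarithmic entropy
#' `H = -(1/(n ln 2)) * sum(mu*ln(mu) + (1-mu)*ln(1-mu))` (or the quadratic
#' energy `E = (1/n) * sum(4*mu*(1-mu))`) of those `n = w^2` memberships is
#' recorded. Both measures live in `[0, 1]`, peak at membership 0.5 and
#' vanish on constant windows, so the map highlights intensity transitions
#' (bone boundaries) and darkens flat tissue. It is invariant to affine
#' rescaling of the slice intensities.
#'
#' @param s a [knee_slice].
#' @param measure `"entropy"` or `"energy"`.
#' @param w odd window size, default 3.
#' @return An object of class `knee_fuzziness`: a list with `values`
#'   (matrix in `[0,1]`), `measure` and `window`.
#' @export
fuzziness_map <- function(s, measure = c("entropy", "energy"), w = 3L) {
  measure <- match.arg(measure)
  stopifnot(inherits(s, "knee_slice"))
  w <- as.integer(w)
  if (w < 3L || w %% 2L == 0L) stop("window must be odd and >= 3")
  img <- s$pixels
  if (nrow(img) < w || ncol(img) < w)
    stop("slice smaller than the fuzziness window")
  k <- (w - 1L) %/% 2L
  p <- pad_replicate(img, k)
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  # neighbourhood stack: one shifted copy of the image per window offset
  shift <- function(dr, dc) p[(1L + k + dr):(nr + k + dr),
                              (1L + k + dc):(nc + k + dc), drop = FALSE]
  mins <- shift(offs$dr[1L], offs$dc[1L])
  maxs <- mins
  for (i in 2:nrow(offs)) {
    sh <- shift(offs$dr[i], offs$dc[i])
    mins <- pmin(mins, sh)
    maxs <- pmax(maxs, sh)
  }
  span <- maxs - mins
  ok <- span > 0
  acc <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offs))) {
    sh <- shift(offs$dr[i], offs$dc[i])
    mu <- matrix(0, nr, nc)
    mu[ok] <- (sh[ok] - mins[ok]) / span[ok]
    acc <- acc + if (measure == "entropy") matrix(.h2(mu), nr, nc)
                 else 4 * mu * (1 - mu)
  }
  vals <- acc / (w * w)
  vals[vals < 0] <- 0; vals[vals > 1] <- 1
  structure(list(values = vals, measure = measure, window = w,
                 index = s$index),
            class = "knee_fuzziness")
}

#' @export
print.knee_fuzziness <- function(x, ...) {
  cat(sprintf("<knee_fuzziness> %dx%d %s map (window %d), range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$measure, x$window,
              min(x$values), max(x$values)))
  invisible(x)
}
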