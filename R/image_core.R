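#' Construct a single image slice
#'
#' A slice is a non-negative grayscale raster plus acquisition metadata.
#' Pixels are stored as a numeric matrix with rows indexing the image y
#' (top to bottom) and columns indexing x (left to right). Normalized
#' coordinates used throughout the package are `x_norm = (col-1)/(width-1)`
#' and `y_norm = (row-1)/(height-1)`, so a normalized centroid maps back to a
#' pixel by rounding.
#'
#' @param pixels numeric matrix of finite, non-negative intensities,
#'   at least 8x8.
#' @param index 1-based position of the slice within its volume.
#' @param modality `"CT"` or `"MR"`.
#' @param plane `"transverse"` or `"sagittal"`.
#' @return An object of class `knee_slice`.
#' @export
knee_slice <- function(pixels, index = 1L, modality = c("CT", "MR"),
                       plane = c("transverse", "sagittal")) {
  modality <- match.arg(modality)
  plane <- match.arg(plane)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("slice must be at least 8x8 pixels")
  if (!all(is.finite(pixels)))
    stop("slice intensities must be finite")
  if (any(pixels < 0))
    stop("slice intensities must be non-negative")
  if (index < 1L) stop("index_in_volume must be >= 1")
  structure(list(pixels = pixels, index = as.integer(index),
                 modality = modality, plane = plane),
            class = "knee_slice")
}

#' @export
print.knee_slice <- function(x, ...) {
  cat(sprintf("<knee_slice> %dx%d %s/%s slice #%d, intensity [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$modality, x$plane, x$index,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.knee_slice <- function(x) dim(x$pixels)

#' Construct a volume (ordered series of slices)
#'
#' @param slices list of [knee_slice] objects sharing shape, modality and
#'   plane. Their `index` fields are rewritten to `1..n`.
#' @param subject_id opaque label.
#' @return An object of class `knee_volume`.
#' @export
knee_volume <- function(slices, subject_id = "subject") {
  if (length(slices) == 0L) stop("a volume needs at least one slice")
  if (!all(vapply(slices, inherits, logical(1), "knee_slice")))
    stop("all elements must be knee_slice objects")
  shp <- dim(slices[[1L]]$pixels)
  for (s in slices) {
    if (!identical(dim(s$pixels), shp))
      stop("mixed slice shapes in volume")
    if (s$modality != slices[[1L]]$modality || s$plane != slices[[1L]]$plane)
      stop("mixed modality/plane in volume")
  }
  for (i in seq_along(slices)) slices[[i]]$index <- i
  structure(list(slices = slices, n_slices = length(slices),
                 subject_id = subject_id,
                 modality = slices[[1L]]$modality,
                 plane = slices[[1L]]$plane),
            class = "knee_volume")
}

#' @export
print.knee_volume <- function(x, ...) {
  cat(sprintf("<knee_volume> '%s': %d %s/%s slices of %dx%d\n",
              x$subject_id, x$n_slices, x$modality, x$plane,
              nrow(x$slices[[1L]]$pixels), ncol(x$slices[[1L]]$pixels)))
  invisible(x)
}

#' @export
length.knee_volume <- function(x) x$n_slices

#' Read a volume of slices from disk
#'
#' Supported formats: a directory of grayscale PNG slices (ordered by file
#' name) and a 3D NIfTI file (slices taken along the third axis, in stored
#' order). DICOM series are not supported by this build; convert to NIfTI
#' first.
#'
#' @param path directory (png-stack) or file (nifti).
#' @param format `"png-stack"` or `"nifti"`.
#' @param modality,plane metadata tags attached to every slice.
#' @param subject_id label for the volume.
#' @return A [knee_volume].
#' @export
read_volume <- function(path, format = c("png-stack", "nifti", "dicom-series"),
                        modality = "CT", plane = "transverse",
                        subject_id = basename(path)) {
  format <- match.arg(format)
  if (format == "dicom-series")
    stop("DICOM series reading is not supported; convert the series to ",
         "NIfTI (e.g. with dcm2niix) and use format = 'nifti'")
  if (format == "png-stack") {
    if (!dir.exists(path)) stop("png-stack path must be an existing directory")
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG slices found in ", path)
    mats <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1L]  # collapse grayscale channels
      m
    })
    shp <- dim(mats[[1L]])
    if (!all(vapply(mats, function(m) identical(dim(m), shp), logical(1))))
      stop("mixed slice shapes in PNG stack")
    slices <- lapply(seq_along(mats), function(i)
      knee_slice(mats[[i]], index = i, modality = modality, plane = plane))
    return(knee_volume(slices, subject_id = subject_id))
  }
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  arr <- RNifti::readNifti(path)
  arr <- as.array(arr)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume")
  slices <- lapply(seq_len(dim(arr)[3L]), function(i)
    knee_slice(arr[, , i], index = i, modality = modality, plane = plane))
  knee_volume(slices, subject_id = subject_id)
}

#' Write a volume to disk
#'
#' @param vol a [knee_volume].
#' @param path output directory (png-stack) or `.nii`/`.nii.gz` file (nifti).
#' @param format `"png-stack"` (8-bit grayscale, intensities min-max scaled
#'   to the volume range) or `"nifti"` (lossless float).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("png-stack", "nifti")) {
  format <- match.arg(format)
  if (format == "png-stack") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    rng <- range(vapply(vol$slices, function(s) range(s$pixels), numeric(2)))
    span <- diff(rng)
    for (s in vol$slices) {
      m <- if (span > 0) (s$pixels - rng[1L]) / span else s$pixels * 0
      fn <- file.path(path, sprintf("s%03d.png", s$index))
      png::writePNG(m, fn, dpi = NULL)
    }
  } else {
    arr <- array(0, c(dim(vol$slices[[1L]]$pixels), vol$n_slices))
    for (i in seq_len(vol$n_slices)) arr[, , i] <- vol$slices[[i]]$pixels
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  }
  invisible(path)
}

#' Bilinearly resample a slice to a target size
#'
#' All matching and segmentation in the pipeline run at a common working size
#' (256x256 by default elsewhere); masks are mapped back with nearest
#' neighbour. Resampling to the current size returns the slice unchanged.
#'
#' @param s a [knee_slice].
#' @param target_h,target_w target pixel counts (both >= 8).
#' @return A [knee_slice] of the requested size.
#' @export
resample_slice <- function(s, target_h, target_w = target_h) {
  stopifnot(inherits(s, "knee_slice"))
  if (target_h < 8L || target_w < 8L) stop("target size must be >= 8")
  if (nrow(s$pixels) == target_h && ncol(s$pixels) == target_w) return(s)
  # EBImage indexes dim1 as x; a plain matrix passes through symmetrically.
  m <- EBImage::resize(s$pixels, w = target_h, h = target_w,
                       filter = "bilinear")
  m <- pmax(as.matrix(m), 0)
  knee_slice(m, index = s$index, modality = s$modality, plane = s$plane)
}

#' Resample a binary mask with nearest-neighbour interpolation
#'
#' @param mask 0/1 matrix.
#' @param target_h,target_w target pixel counts.
#' @return 0/1 matrix of the requested size.
#' @export
resample_mask <- function(mask, target_h, target_w = target_h) {
  mask <- as.matrix(mask)
  if (nrow(mask) == target_h && ncol(mask) == target_w) return(mask)
  rows <- pmin(nrow(mask), pmax(1L, round((seq_len(target_h) - 0.5) *
                                            nrow(mask) / target_h + 0.5)))
  cols <- pmin(ncol(mask), pmax(1L, round((seq_len(target_w) - 0.5) *
                                            ncol(mask) / target_w + 0.5)))
  (mask[rows, cols, drop = FALSE] > 0) + 0
}

#' Min-max normalize slice intensities to [0, 1]
#'
#' A constant slice maps to all zeros so that degenerate inputs cannot
#' poison downstream stages.
#'
#' @param s a [knee_slice].
#' @return A [knee_slice] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(s) {
  stopifnot(inherits(s, "knee_slice"))
  rng <- range(s$pixels)
  m <- if (diff(rng) > 0) (s$pixels - rng[1L]) / diff(rng) else s$pixels * 0
  knee_slice(m, index = s$index, modality = s$modality, plane = s$plane)
}

#' Create a labelled binary mask
#'
#' @param pixels matrix coercible to 0/1.
#' @param bone `"patella"`, `"femur"`, `"tibia"` or `"knee"`.
#' @return An object of class `knee_mask` (a 0/1 matrix with a `bone`
#'   attribute).
#' @export
knee_mask <- function(pixels, bone = c("patella", "femur", "tibia", "knee")) {
  bone <- match.arg(bone)
  m <- (as.matrix(pixels) > 0) + 0
  structure(m, bone = bone, class = c("knee_mask", class(m)))
}

mask_pixels <- function(m) {
  m <- unclass(as.matrix(m))
  attr(m, "bone") <- NULL
  (m > 0) + 0
}
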