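#' Specification of a synthetic knee phantom series
#'
#' Emulates the two acquisition protocols of the clinical material:
#' sagittal T1-weighted MR series of 17-24 slices and transverse CT series
#' of 25-33 slices, at the 256x256 working size. Three disjoint bone-like
#' structures (patella = lens, femur = ellipse or two condyle discs in the
#' deepest transverse set, tibia = plateau ellipse splitting into two lobes
#' around the intercondylar eminence in transverse set 1) are drawn inside
#' a knee-shaped region; their per-set area fractions follow the reference
#' atlas area profile, so the patella is absent in sagittal sets 1, 2
#' and 11. MR-like phantoms invert the bone/tissue contrast relative to
#' CT-like ones (cortical bone is dark on T1 relative to soft tissue).
#'
#' @param plane `"sagittal"` or `"transverse"`.
#' @param n_slices slice count; defaults to 20 (sagittal) / 28 (transverse)
#'   and must lie in the protocol range 17-24 / 25-33.
#' @param image_size side length in pixels.
#' @param bone_intensity,tissue_intensity,background_intensity mean levels;
#'   defaults: CT 200/80/20 (bone bright), MR 90/190/20 (bone dark).
#' @param noise_sd additive Gaussian noise sd; defaults to 5% of the
#'   bone-tissue contrast.
#' @param geometry_jitter sd of the per-subject normalized displacement of
#'   each bone's position.
#' @param rng_seed integer seed; same seed, same volume, bit for bit.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(plane = c("sagittal", "transverse"),
                         n_slices = NULL, image_size = 256L,
                         bone_intensity = NULL, tissue_intensity = NULL,
                         background_intensity = 20,
                         noise_sd = NULL, geometry_jitter = 0.02,
                         rng_seed = 1L) {
  plane <- match.arg(plane)
  modality <- if (plane == "sagittal") "MR" else "CT"
  if (is.null(n_slices)) n_slices <- if (plane == "sagittal") 20L else 28L
  rng <- if (plane == "sagittal") c(17L, 24L) else c(25L, 33L)
  if (n_slices < rng[1L] || n_slices > rng[2L])
    stop(plane, " series must have ", rng[1L], "-", rng[2L], " slices")
  if (image_size < 64L) stop("image_size must be >= 64")
  if (is.null(bone_intensity))
    bone_intensity <- if (modality == "CT") 200 else 90
  if (is.null(tissue_intensity))
    tissue_intensity <- if (modality == "CT") 80 else 190
  if (background_intensity >= min(bone_intensity, tissue_intensity))
    stop("background must be darker than bone and tissue")
  if (bone_intensity == tissue_intensity)
    stop("bone and tissue intensities must differ")
  if (is.null(noise_sd))
    noise_sd <- 0.05 * abs(bone_intensity - tissue_intensity)
  structure(list(plane = plane, modality = modality,
                 n_slices = as.integer(n_slices),
                 image_size = as.integer(image_size),
                 bone_intensity = bone_intensity,
                 tissue_intensity = tissue_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, geometry_jitter = geometry_jitter,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Base layout of the phantom anatomy in normalized coordinates.
phantom_layout <- function(plane) {
  if (plane == "transverse") {
    list(knee = list(cx = 0.5, cy = 0.5, ax = 0.46, ay = 0.48),
         patella = list(cx = 0.47, cy = 0.13),
         femur = list(cx = 0.50, cy = 0.42, aspect = 1.5,
                      dual_sets = 11L,
                      dual_cx = c(0.35, 0.65), dual_cy = c(0.45, 0.45)),
         tibia = list(cx = 0.50, cy = 0.78, aspect = 2.2,
                      dual_sets = 1L,
                      dual_cx = c(0.34, 0.66), dual_cy = c(0.76, 0.76)),
         lens_flat = TRUE)
  } else {
    list(knee = list(cx = 0.5, cy = 0.5, ax = 0.45, ay = 0.47),
         patella = list(cx = 0.21, cy = 0.40),
         femur = list(cx = 0.47, cy = 0.30, aspect = 1 / 1.2,
                      dual_sets = integer(0)),
         tibia = list(cx = 0.52, cy = 0.72, aspect = 1.8,
                      dual_sets = integer(0)),
         lens_flat = FALSE)
  }
}

# Per-set bone area fractions (of the knee area) used by the generator:
# the reference atlas profile for the phantom's plane.
phantom_area_profile <- function(plane) {
  a <- load_reference_atlas(plane, if (plane == "sagittal") "MR" else "CT")
  sapply(BONES, function(b)
    vapply(1:11, function(k) atlas_bone(a, k, b)$area_fraction, numeric(1)))
}

.lens_area_coef <- 2 * pi / 3 - sqrt(3) / 2  # two unit discs at offset 1

raster_ellipse <- function(X, Y, cx, cy, ax, ay) {
  (((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1) + 0
}

raster_lens <- function(X, Y, cx, cy, r, flat) {
  if (flat) { c1 <- c(cx, cy - r / 2); c2 <- c(cx, cy + r / 2) }
  else      { c1 <- c(cx - r / 2, cy); c2 <- c(cx + r / 2, cy) }
  m <- (((X - c1[1L])^2 + (Y - c1[2L])^2 <= r^2) &
        ((X - c2[1L])^2 + (Y - c2[2L])^2 <= r^2)) + 0
  m
}

ensure_nonempty <- function(m, X, Y, cx, cy) {
  if (sum(m) == 0) {
    i <- which.min((X - cx)^2 + (Y - cy)^2)
    m[i] <- 1
  }
  m
}

#' Generate a phantom knee volume with ground-truth masks
#'
#' Deterministic for a fixed `rng_seed`. Bone positions are jittered once
#' per volume; if the jittered bones overlap on any slice the volume is
#' regenerated with the jitter halved (at most 10 attempts).
#'
#' @param spec a [phantom_spec()].
#' @return List: `volume` (a [knee_volume]), `masks` (per-slice list with
#'   `patella`, `femur`, `tibia`, `knee` 0/1 masks), `centroids` (the
#'   jittered generative bone centers, normalized), `spec`.
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed)

  size <- spec$image_size
  ax_grid <- (seq_len(size) - 1) / (size - 1)
  X <- matrix(ax_grid, size, size, byrow = TRUE)   # x = column coordinate
  Y <- matrix(ax_grid, size, size)                 # y = row coordinate
  lay <- phantom_layout(spec$plane)
  prof <- phantom_area_profile(spec$plane)
  knee_px <- pi * lay$knee$ax * lay$knee$ay * (size - 1)^2

  jit <- spec$geometry_jitter
  for (attempt in 1:10) {
    off <- stats::rnorm(6, 0, jit)
    cents <- list(patella = c(lay$patella$cx + off[1L], lay$patella$cy + off[2L]),
                  femur = c(lay$femur$cx + off[3L], lay$femur$cy + off[4L]),
                  tibia = c(lay$tibia$cx + off[5L], lay$tibia$cy + off[6L]))
    masks <- vector("list", spec$n_slices)
    ok <- TRUE
    for (i in seq_len(spec$n_slices)) {
      set <- assign_set(i, spec$n_slices)
      bm <- list()
      for (bone in BONES) {
        A <- prof[set, bone] * knee_px / (size - 1)^2  # normalized area
        if (A <= 0) { bm[[bone]] <- matrix(0, size, size); next }
        b <- lay[[bone]]
        if (bone == "patella") {
          r <- sqrt(A / .lens_area_coef)
          m <- raster_lens(X, Y, cents$patella[1L], cents$patella[2L], r,
                           lay$lens_flat)
          m <- ensure_nonempty(m, X, Y, cents$patella[1L], cents$patella[2L])
        } else if (set %in% b$dual_sets) {
          r <- sqrt(A / 2 / pi)
          dx <- cents[[bone]][1L] - b$cx; dy <- cents[[bone]][2L] - b$cy
          m <- pmax(raster_ellipse(X, Y, b$dual_cx[1L] + dx,
                                   b$dual_cy[1L] + dy, r, r),
                    raster_ellipse(X, Y, b$dual_cx[2L] + dx,
                                   b$dual_cy[2L] + dy, r, r))
        } else {
          ay <- sqrt(A / (pi * b$aspect))
          axl <- b$aspect * ay
          m <- raster_ellipse(X, Y, cents[[bone]][1L], cents[[bone]][2L],
                              axl, ay)
          m <- ensure_nonempty(m, X, Y, cents[[bone]][1L], cents[[bone]][2L])
        }
        bm[[bone]] <- m
      }
      if (any(bm$patella + bm$femur + bm$tibia > 1)) { ok <- FALSE; break }
      union <- pmax(bm$patella, bm$femur, bm$tibia)
      knee <- raster_ellipse(X, Y, lay$knee$cx, lay$knee$cy,
                             lay$knee$ax, lay$knee$ay)
      if (sum(union) > 0)
        knee <- pmax(knee, as.matrix(
          EBImage::dilate(union, EBImage::makeBrush(7L, "disc"))))
      bm$knee <- knee
      masks[[i]] <- bm
    }
    if (ok) break
    jit <- jit / 2
    if (attempt == 10L) stop("could not place disjoint bones after 10 attempts")
  }

  slices <- vector("list", spec$n_slices)
  for (i in seq_len(spec$n_slices)) {
    bm <- masks[[i]]
    img <- matrix(spec$background_intensity, size, size)
    img[bm$knee == 1] <- spec$tissue_intensity
    union <- pmax(bm$patella, bm$femur, bm$tibia)
    img[union == 1] <- spec$bone_intensity
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(size * size, 0, spec$noise_sd),
                          size, size)
    img <- pmax(img, 0)
    slices[[i]] <- knee_slice(img, index = i, modality = spec$modality,
                              plane = spec$plane)
  }
  list(volume = knee_volume(slices,
         subject_id = sprintf("phantom-%s-%d", spec$plane, spec$rng_seed)),
       masks = masks, centroids = cents, spec = spec)
}

#' Generate an annotated phantom teaching group
#'
#' Subject `i` uses seed `rng_seed + i`, so groups are reproducible and
#' subjects independent.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param spec a [phantom_spec()]; its `rng_seed` seeds the group.
#' @return List of `generate_volume()` outputs, directly usable as the
#'   teaching argument of [build_atlas()].
#' @export
generate_teaching_group <- function(n_subjects, spec) {
  if (n_subjects < 2L) stop("a teaching group needs at least 2 subjects")
  lapply(seq_len(n_subjects), function(i) {
    s <- spec
    s$rng_seed <- spec$rng_seed + i
    generate_volume(s)
  })
}
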