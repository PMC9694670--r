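#' Assign a slice to one of the 11 normalized position sets
#'
#' Volumes differ in slice count (17-24 sagittal MR, 25-33 transverse CT),
#' so slice positions are normalized and binned into 11 sets over which the
#' atlas averages features. The endpoint-anchored rule
#' `set = min(11, floor(11 * (index - 1) / (n_slices - 1)) + 1)`
#' is monotone, sends slice 1 to set 1 and slice `n` to set 11, and reduces
#' to the identity when `n = 11`.
#'
#' @param index_in_volume 1-based slice index (vectorized).
#' @param n_slices total slices in the volume (>= 2).
#' @return Integer set index in `1..11`.
#' @export
assign_set <- function(index_in_volume, n_slices) {
  if (n_slices < 2L) stop("set assignment needs n_slices >= 2")
  if (any(index_in_volume < 1L | index_in_volume > n_slices))
    stop("slice index out of range")
  pmin(11L, as.integer(floor(11 * (index_in_volume - 1) / (n_slices - 1))) + 1L)
}

boundary_pixels <- function(mask) {
  # pixels of the mask with at least one background 8-neighbour (or on the
  # image border)
  m <- mask_pixels(mask)
  p <- pad_replicate(m, 1L); p[1L, ] <- 0; p[nrow(p), ] <- 0
  p[, 1L] <- 0; p[, ncol(p)] <- 0
  nr <- nrow(m); nc <- ncol(m)
  allnb <- matrix(1, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    allnb <- allnb * p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  (m == 1) & (allnb == 0)
}

norm_centroid <- function(rows, cols, h, w) {
  c(x = mean(cols - 1) / (w - 1), y = mean(rows - 1) / (h - 1))
}

#' Per-slice bone features for atlas building
#'
#' Computes, for each bone mask, the normalized centroid(s), the area as a
#' fraction of the knee area, the 8-connected boundary (edge pixels and
#' perimeter) and the medial-axis skeleton. Bones whose mask splits into two
#' major connected components (the femoral condyles in the deepest
#' transverse sets; the tibial plateau around the intercondylar eminence in
#' the shallowest) yield two centroids, ordered by decreasing normalized x.
#'
#' @param s a [knee_slice].
#' @param masks named list with 0/1 masks for `patella`, `femur`, `tibia`
#'   (any subset; missing bones are treated as absent).
#' @param knee 0/1 mask of the entire knee (non-empty), the area normalizer.
#' @param dual_min_fraction a second component counts as "major" when its
#'   area is at least this fraction of the bone area.
#' @return Named list (per bone) of `bone_features` lists with fields
#'   `bone`, `present`, `centroids` (n x 2 matrix, columns x, y),
#'   `centroid_overall`, `area_fraction`, `perimeter`, `edges`, `skeleton`
#'   (two-column row/col matrices).
#' @export
slice_features <- function(s, masks, knee, dual_min_fraction = 0.2) {
  stopifnot(inherits(s, "knee_slice"))
  h <- nrow(s$pixels); w <- ncol(s$pixels)
  kn <- mask_pixels(knee)
  if (!identical(dim(kn), dim(s$pixels))) stop("knee mask shape mismatch")
  knee_area <- sum(kn)
  if (knee_area == 0) stop("empty knee mask")
  out <- list()
  for (bone in BONES) {
    m <- if (!is.null(masks[[bone]])) mask_pixels(masks[[bone]])
         else matrix(0, h, w)
    if (!identical(dim(m), dim(s$pixels))) stop("bone mask shape mismatch")
    area <- sum(m)
    if (area == 0) {
      out[[bone]] <- structure(list(bone = bone, present = FALSE,
        centroids = matrix(0, 1, 2, dimnames = list(NULL, c("x", "y"))),
        centroid_overall = c(x = 0, y = 0), area_fraction = 0,
        perimeter = 0L, edges = NULL, skeleton = NULL),
        class = "bone_features")
      next
    }
    idx <- which(m == 1, arr.ind = TRUE)
    cen_all <- norm_centroid(idx[, 1L], idx[, 2L], h, w)
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    major <- which(sizes >= dual_min_fraction * area)
    major <- major[order(sizes[major], decreasing = TRUE)][seq_len(min(2L, length(major)))]
    cents <- t(vapply(major, function(l) {
      ii <- which(lab == l, arr.ind = TRUE)
      norm_centroid(ii[, 1L], ii[, 2L], h, w)
    }, numeric(2)))
    colnames(cents) <- c("x", "y")
    if (nrow(cents) == 2L) cents <- cents[order(-cents[, "x"]), , drop = FALSE]
    bnd <- boundary_pixels(m)
    sk <- thin_cpp(m)
    out[[bone]] <- structure(list(bone = bone, present = TRUE,
      centroids = cents, centroid_overall = cen_all,
      area_fraction = area / knee_area,
      perimeter = sum(bnd),
      edges = which(bnd, arr.ind = TRUE),
      skeleton = which(sk == 1L, arr.ind = TRUE)),
      class = "bone_features")
  }
  out
}

#' Build the 11-set average feature atlas from an annotated teaching group
#'
#' Every slice of every teaching volume is assigned to a set by
#' [assign_set()]; per set and bone, centroids are averaged over the slices
#' where the bone is present (pooled across subjects, unweighted) and area
#' fractions over all member slices (absences count as area 0, matching the
#' near-zero printed values at the patella edge sets). A bone is recorded as
#' present in a set when it is present in at least half of the member
#' slices, and gets two averaged centroids when the majority of its present
#' slices show two major components.
#'
#' @param teaching list; each element is a list with `volume` (a
#'   [knee_volume]) and `masks` (per-slice list of named 0/1 masks including
#'   `knee`).
#' @return An object of class `knee_atlas`.
#' @export
build_atlas <- function(teaching) {
  if (length(teaching) == 0L) stop("empty teaching group")
  plane <- teaching[[1L]]$volume$plane
  modality <- teaching[[1L]]$volume$modality
  acc <- vector("list", 11L)
  for (k in 1:11) acc[[k]] <- list()
  for (subj in teaching) {
    vol <- subj$volume
    if (vol$plane != plane || vol$modality != modality)
      stop("teaching volumes must share plane and modality")
    n <- vol$n_slices
    for (i in seq_len(n)) {
      set <- assign_set(i, n)
      fl <- slice_features(vol$slices[[i]], subj$masks[[i]],
                           subj$masks[[i]]$knee)
      acc[[set]][[length(acc[[set]]) + 1L]] <- fl
    }
  }
  sets <- vector("list", 11L)
  for (k in 1:11) {
    members <- acc[[k]]
    if (length(members) == 0L)
      stop("set ", k, " has no member slices across the teaching group")
    bones <- list()
    for (bone in BONES) {
      fl <- lapply(members, `[[`, bone)
      pres <- vapply(fl, `[[`, logical(1), "present")
      areas <- vapply(fl, `[[`, numeric(1), "area_fraction")
      if (sum(pres) >= length(members) / 2) {
        fp <- fl[pres]
        ncomp <- vapply(fp, function(f) nrow(f$centroids), integer(1))
        dual <- sum(ncomp == 2L) >= length(fp) / 2
        if (dual) {
          two <- fp[ncomp == 2L]
          c1 <- colMeans(do.call(rbind, lapply(two, function(f) f$centroids[1L, ])))
          c2 <- colMeans(do.call(rbind, lapply(two, function(f) f$centroids[2L, ])))
          cents <- rbind(c1, c2)
        } else {
          cents <- matrix(colMeans(do.call(rbind,
                    lapply(fp, `[[`, "centroid_overall"))), 1L, 2L)
        }
        colnames(cents) <- c("x", "y"); rownames(cents) <- NULL
        bones[[bone]] <- list(bone = bone, present = TRUE, centroids = cents,
                              area_fraction = mean(areas))
      } else {
        bones[[bone]] <- list(bone = bone, present = FALSE,
          centroids = matrix(0, 1, 2, dimnames = list(NULL, c("x", "y"))),
          area_fraction = 0)
      }
    }
    sets[[k]] <- list(set_index = k, bones = bones,
                      n_member_slices = length(members))
  }
  structure(list(plane = plane, modality = modality, provenance = "built",
                 sets = sets),
            class = "knee_atlas")
}

#' @export
print.knee_atlas <- function(x, ...) {
  cat(sprintf("<knee_atlas> %s/%s (%s), 11 sets\n",
              x$plane, x$modality, x$provenance))
  for (st in x$sets) {
    parts <- vapply(BONES, function(b) {
      bn <- st$bones[[b]]
      if (!bn$present) return(sprintf("%s: -", substr(b, 1, 3)))
      sprintf("%s: (%.3f,%.3f)%s a=%.4f", substr(b, 1, 3),
              bn$centroids[1, 1], bn$centroids[1, 2],
              if (nrow(bn$centroids) == 2) "x2" else "", bn$area_fraction)
    }, character(1))
    cat(sprintf("  set %2d  %s\n", st$set_index, paste(parts, collapse = "  ")))
  }
  invisible(x)
}

#' Load the packaged reference atlas
#'
#' Returns the published normalized centroids and knee-area fractions for
#' the 11 sets, per bone: the transverse-plane CT atlas (with dual femur
#' centroids in set 11 and dual tibia centroids in set 1) or the
#' sagittal-plane MR atlas (patella absent in sets 1, 2 and 11).
#'
#' @param plane `"transverse"` or `"sagittal"`.
#' @param modality `"CT"` or `"MR"`.
#' @return A `knee_atlas` with provenance `"paper-tables"`.
#' @export
load_reference_atlas <- function(plane = c("transverse", "sagittal"),
                                 modality = c("CT", "MR")) {
  plane <- match.arg(plane)
  modality <- match.arg(modality)
  if (!((plane == "transverse" && modality == "CT") ||
        (plane == "sagittal" && modality == "MR")))
    stop("no reference atlas for plane=", plane, ", modality=", modality)
  fn <- system.file("extdata", "reference_atlas.csv", package = "kneeatlas",
                    mustWork = TRUE)
  tab <- utils::read.csv(fn)
  tab <- tab[tab$plane == plane & tab$modality == modality, ]
  sets <- vector("list", 11L)
  for (k in 1:11) {
    bones <- list()
    for (bone in BONES) {
      row <- tab[tab$set == k & tab$bone == bone, ]
      stopifnot(nrow(row) == 1L)
      present <- !(row$x1 == 0 && row$y1 == 0 && row$area == 0)
      cents <- matrix(c(row$x1, row$y1), 1L, 2L)
      if (!is.na(row$x2)) cents <- rbind(cents, c(row$x2, row$y2))
      colnames(cents) <- c("x", "y")
      bones[[bone]] <- list(bone = bone, present = present,
                            centroids = cents, area_fraction = row$area)
    }
    sets[[k]] <- list(set_index = k, bones = bones, n_member_slices = NA_integer_)
  }
  structure(list(plane = plane, modality = modality,
                 provenance = "paper-tables", sets = sets),
            class = "knee_atlas")
}

#' Serialize an atlas to JSON / read it back
#'
#' Round-trips all centroid and area values exactly (full double precision).
#'
#' @param a a `knee_atlas`.
#' @param path output (input) file.
#' @return `path` invisibly; `atlas_read_json` returns the `knee_atlas`.
#' @export
atlas_write_json <- function(a, path) {
  stopifnot(inherits(a, "knee_atlas"))
  obj <- list(plane = a$plane, modality = a$modality,
              provenance = a$provenance,
              sets = lapply(a$sets, function(st) list(
                set_index = st$set_index,
                bones = lapply(st$bones, function(b) list(
                  bone = b$bone, present = b$present,
                  x = unname(b$centroids[, 1L]), y = unname(b$centroids[, 2L]),
                  area_fraction = b$area_fraction)))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname atlas_write_json
#' @export
atlas_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  sets <- lapply(obj$sets, function(st) list(
    set_index = as.integer(st$set_index),
    bones = lapply(st$bones, function(b) {
      cents <- cbind(x = as.numeric(b$x), y = as.numeric(b$y))
      list(bone = b$bone, present = isTRUE(b$present), centroids = cents,
           area_fraction = as.numeric(b$area_fraction))
    }),
    n_member_slices = NA_integer_))
  structure(list(plane = obj$plane, modality = obj$modality,
                 provenance = obj$provenance, sets = sets),
            class = "knee_atlas")
}

atlas_bone <- function(a, set_index, bone) {
  stopifnot(inherits(a, "knee_atlas"), set_index >= 1L, set_index <= 11L)
  a$sets[[set_index]]$bones[[bone]]
}

#' Convert atlas centroids to pixel seed points
#'
#' Maps each normalized centroid `(x, y)` of the bone in the given set to
#' the pixel `(row, col) = (round(y * (h - 1)) + 1, round(x * (w - 1)) + 1)`
#' (1-based indices). Returns `NULL` when the atlas marks the bone absent in
#' the set ("no structure on this slice"; the caller skips segmentation).
#'
#' @param a a `knee_atlas`.
#' @param set_index set in `1..11`.
#' @param bone `"patella"`, `"femur"` or `"tibia"`.
#' @param slice_h,slice_w working slice size in pixels.
#' @return Data frame with columns `row`, `col`, `origin` (1 or 2 rows), or
#'   `NULL` if the bone is absent in the set.
#' @export
atlas_to_seed <- function(a, set_index, bone, slice_h, slice_w) {
  b <- atlas_bone(a, set_index, bone)
  if (!b$present) return(NULL)
  data.frame(row = as.integer(round(b$centroids[, "y"] * (slice_h - 1)) + 1),
             col = as.integer(round(b$centroids[, "x"] * (slice_w - 1)) + 1),
             origin = "atlas", stringsAsFactors = FALSE)
}

#' Estimate the knee region of a slice
#'
#' When no expert knee mask is supplied, the knee area normalizer is taken
#' as the largest connected foreground component after Otsu thresholding,
#' with holes filled.
#'
#' @param s a [knee_slice].
#' @return 0/1 matrix.
#' @export
estimate_knee_mask <- function(s) {
  img <- normalize_intensity(s)$pixels
  th <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  fg <- (img > th) + 0
  lab <- EBImage::bwlabel(fg)
  if (max(lab) == 0) return(fg)
  sizes <- tabulate(lab[lab > 0])
  big <- (lab == which.max(sizes)) + 0
  as.matrix(EBImage::fillHull(big))
}
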