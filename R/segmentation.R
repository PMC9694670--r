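#' Parameters for fuzzy-connectedness segmentation
#'
#' @param adjacency 4 or 8 pixel adjacency.
#' @param w1,w2 non-negative affinity feature weights (homogeneity of the
#'   mean intensity vs. smallness of the intensity step), summing to 1.
#' @param seed_stats_radius radius (pixels) of the disc around the seed used
#'   to estimate the object intensity mean/sd.
#' @return A list of class `fc_params`.
#' @export
fc_params <- function(adjacency = 8L, w1 = 0.5, w2 = 0.5,
                      seed_stats_radius = 3L) {
  if (!adjacency %in% c(4L, 8L)) stop("adjacency must be 4 or 8")
  if (w1 < 0 || w2 < 0 || abs(w1 + w2 - 1) > 1e-12)
    stop("w1 and w2 must be non-negative and sum to 1")
  if (seed_stats_radius < 1L) stop("seed_stats_radius must be >= 1")
  structure(list(adjacency = as.integer(adjacency), w1 = w1, w2 = w2,
                 seed_stats_radius = as.integer(seed_stats_radius)),
            class = "fc_params")
}

#' Parameters for fuzzy c-means clustering
#'
#' Defaults suit knee slices: three intensity classes (bone, soft tissue,
#' background), the standard fuzzifier 2, and a deterministic
#' initialization so repeated runs agree bit for bit.
#'
#' @param c cluster count (>= 2).
#' @param m fuzzifier (> 1).
#' @param tol convergence threshold on the maximum membership change.
#' @param max_iter iteration cap.
#' @return A list of class `fcm_params`.
#' @export
fcm_params <- function(c = 3L, m = 2, tol = 1e-4, max_iter = 200L) {
  if (c < 2L) stop("c must be >= 2")
  if (m <= 1) stop("fuzzifier m must be > 1")
  structure(list(c = as.integer(c), m = m, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "fcm_params")
}

#' Fuzzy c-means clustering of slice intensities
#'
#' Alternating Bezdek updates on the pixel intensities:
#' memberships `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and centers
#' `v_i = sum(u^m x) / sum(u^m)`, until the largest membership change drops
#' below `tol`. Centers are initialized from the seed intensities plus
#' evenly spaced intensity quantiles, making the iteration deterministic.
#'
#' @param s a [knee_slice] (or numeric matrix/vector of intensities).
#' @param p an [fcm_params()].
#' @param seeds optional data frame of seed pixels (`row`, `col`) whose
#'   intensities anchor the initial centers.
#' @return List of class `knee_fcm`: `memberships` (array
#'   `nrow x ncol x c`, summing to 1 over clusters at every pixel),
#'   `centers` (sorted ascending), `iterations`, `objective` (per-iteration
#'   values of `sum(u^m d^2)`).
#' @export
fcm_cluster <- function(s, p = fcm_params(), seeds = NULL) {
  img <- if (inherits(s, "knee_slice")) s$pixels else as.matrix(s)
  x <- as.vector(img)
  if (length(unique(x)) < p$c)
    stop("FCM needs at least c distinct intensities")
  seed_int <- if (!is.null(seeds) && nrow(seeds) > 0)
    img[cbind(seeds$row, seeds$col)] else numeric(0)
  cand <- c(seed_int,
            stats::quantile(x, probs = seq_len(p$c) / (p$c + 1), names = FALSE))
  centers <- numeric(0)
  for (v in cand) {
    if (length(centers) == p$c) break
    if (all(abs(centers - v) > 1e-9)) centers <- c(centers, v)
  }
  if (length(centers) < p$c) {  # fall back to distinct observed intensities
    extra <- setdiff(sort(unique(x)), centers)
    centers <- c(centers, extra[seq_len(p$c - length(centers))])
  }
  expo <- 2 / (p$m - 1)
  u <- NULL
  objective <- numeric(0)
  for (iter in seq_len(p$max_iter)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    w <- d2^(-expo / 2)                       # (1/d)^(2/(m-1))
    exact <- d2 <= .Machine$double.eps
    hit <- rowSums(exact) > 0
    u_new <- w / rowSums(w)
    if (any(hit)) {
      u_new[hit, ] <- exact[hit, , drop = FALSE] /
        rowSums(exact[hit, , drop = FALSE])
    }
    objective <- c(objective, sum(u_new^p$m * d2))
    delta <- if (is.null(u)) Inf else max(abs(u_new - u))
    u <- u_new
    um <- u^p$m
    centers <- colSums(um * x) / colSums(um)
    if (delta < p$tol) {
      ord <- order(centers)
      mem <- array(u[, ord], c(nrow(img), ncol(img), p$c))
      return(structure(list(memberships = mem, centers = centers[ord],
                            iterations = iter, objective = objective),
                       class = "knee_fcm"))
    }
  }
  stop("FCM did not converge in ", p$max_iter,
       " iterations (last max |du| = ", signif(delta, 3), ")")
}

disc_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, ]
}

fc_seed_stats <- function(img, seed, radius) {
  offs <- disc_offsets(radius)
  rr <- seed$row[1L] + offs$dr
  cc <- seed$col[1L] + offs$dc
  ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  vals <- img[cbind(rr[ok], cc[ok])]
  rng <- diff(range(img))
  floor_sd <- max(1e-3 * rng, 1e-9)
  mu_o <- mean(vals)
  sd_o <- max(stats::sd(vals), floor_sd)
  # spread of adjacent-pixel steps inside the disc, for the gradient feature
  dif <- abs(diff(vals))
  sd_g <- max(stats::sd(c(dif, -dif)), floor_sd)
  list(mu_o = mu_o, sd_o = sd_o, sd_g = sd_g)
}

#' Fuzzy-connectedness map from a seed
#'
#' Affinity between adjacent pixels combines a unit-peak Gaussian of their
#' mean intensity (centered on the object statistics estimated in a disc
#' around the seed) and a unit-peak Gaussian of their intensity step
#' (centered at 0). The connectivity of a pixel is the maximum over paths
#' from the seed of the minimum affinity along the path, computed by
#' best-first propagation; `conn(seed) = 1`.
#'
#' @param s a [knee_slice] or numeric matrix.
#' @param seed data frame with at least one row (`row`, `col`), 1-based.
#' @param p an [fc_params()].
#' @return List of class `knee_fc`: `connectivity` matrix in `[0, 1]`,
#'   `seed`, `stats` (the estimated object statistics).
#' @export
fc_connectivity <- function(s, seed, p = fc_params()) {
  img <- if (inherits(s, "knee_slice")) s$pixels else as.matrix(s)
  if (seed$row[1L] < 1 || seed$row[1L] > nrow(img) ||
      seed$col[1L] < 1 || seed$col[1L] > ncol(img))
    stop("seed out of slice bounds")
  st <- fc_seed_stats(img, seed, p$seed_stats_radius)
  conn <- fc_connectivity_cpp(img, seed$row[1L], seed$col[1L], p$adjacency,
                              p$w1, p$w2, st$mu_o, st$sd_o, st$sd_g)
  structure(list(connectivity = conn, seed = seed, stats = st, params = p),
            class = "knee_fc")
}

#' Area-constrained thresholding of a connectivity (or membership) map
#'
#' Sweeps thresholds over the map values; at each threshold the 8-connected
#' component(s) of `{values >= tau}` containing the seed(s) form the mask.
#' Because those components are nested, the threshold whose component area
#' is closest to the target (ties resolved toward the larger threshold,
#' i.e. the smaller mask) is found by bisection over the sorted unique
#' values. The target comes from the atlas area prior and shields the
#' segmentation from over-segmentation; if no threshold reaches the target
#' within `tol` relative error the best achievable mask is returned with
#' `conforming = FALSE`.
#'
#' @param values numeric matrix (connectivity in `[0,1]` or FCM
#'   memberships).
#' @param seeds data frame (`row`, `col`), 1 or more rows.
#' @param target_area desired mask area in pixels (>= 1).
#' @param tol relative area tolerance for the `conforming` flag.
#' @return List: `mask` (0/1 matrix), `threshold`, `area`, `target_area`,
#'   `conforming`.
#' @export
area_constrained_mask <- function(values, seeds, target_area, tol = 0.15) {
  values <- as.matrix(values)
  if (target_area < 1) stop("target_area must be >= 1")
  taus <- sort(unique(as.vector(values)), decreasing = TRUE)
  # seed pixels are always in their own component; cap at the seed values
  seed_vals <- values[cbind(seeds$row, seeds$col)]
  taus <- taus[taus <= max(seed_vals)]
  area_at <- function(j)
    sum(seed_component_cpp(values, taus[j], seeds$row, seeds$col))
  lo <- 1L; hi <- length(taus)
  # find the smallest j (largest threshold) whose area reaches the target
  if (area_at(hi) < target_area) {
    j <- hi
  } else {
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (area_at(mid) >= target_area) hi <- mid else lo <- mid + 1L
    }
    j <- hi
  }
  best <- j
  if (j > 1L) {
    a_j <- area_at(j); a_prev <- area_at(j - 1L)
    # ties toward the larger threshold (j - 1 has the larger tau)
    if (abs(a_prev - target_area) <= abs(a_j - target_area)) best <- j - 1L
  }
  mask <- seed_component_cpp(values, taus[best], seeds$row, seeds$col)
  area <- sum(mask)
  list(mask = mask, threshold = taus[best], area = area,
       target_area = target_area,
       conforming = abs(area - target_area) / target_area <= tol)
}

#' Relocate a patella seed onto the candidate skeleton
#'
#' On the sagittal plane the averaged patella centroid often falls outside
#' the thin, crescent-shaped patella. Candidate seed points on the skeleton
#' of the current slice's candidate bone region are visited in increasing
#' Euclidean distance from the atlas centroid (ties in row-major order);
#' the first whose guarded segmentation area conforms with the atlas area
#' prior (relative error <= `tol`) is adopted. If none conforms, the best
#' candidate is returned flagged.
#'
#' @param atlas_seed one-row data frame (`row`, `col`).
#' @param skeleton two-column matrix of skeleton pixel coordinates
#'   (row, col); must be non-empty.
#' @param engine function taking a one-row seed data frame and returning a
#'   list with at least `area` (achieved mask area in pixels).
#' @param target_area atlas target area in pixels.
#' @param tol relative area tolerance.
#' @param max_candidates cap on skeleton points tried.
#' @return One-row data frame (`row`, `col`, `origin`) with attributes
#'   `conforming` (logical) and `result` (the engine output at the chosen
#'   seed).
#' @export
relocate_patella_seed <- function(atlas_seed, skeleton, engine, target_area,
                                  tol = 0.15, max_candidates = 100L) {
  if (is.null(skeleton) || nrow(skeleton) == 0L)
    stop("empty skeleton: no candidate seed points")
  d2 <- (skeleton[, 1L] - atlas_seed$row[1L])^2 +
        (skeleton[, 2L] - atlas_seed$col[1L])^2
  ord <- order(d2, skeleton[, 1L], skeleton[, 2L])
  ord <- ord[seq_len(min(length(ord), max_candidates))]
  best <- NULL; best_err <- Inf; best_seed <- NULL
  for (i in ord) {
    cand <- data.frame(row = skeleton[i, 1L], col = skeleton[i, 2L],
                       origin = if (skeleton[i, 1L] == atlas_seed$row[1L] &&
                                    skeleton[i, 2L] == atlas_seed$col[1L])
                                  "atlas" else "relocated",
                       stringsAsFactors = FALSE)
    res <- engine(cand)
    err <- abs(res$area - target_area) / target_area
    if (err <= tol) {
      attr(cand, "conforming") <- TRUE
      attr(cand, "result") <- res
      return(cand)
    }
    if (err < best_err) { best_err <- err; best <- res; best_seed <- cand }
  }
  attr(best_seed, "conforming") <- FALSE
  attr(best_seed, "result") <- best
  best_seed
}

#' Morphological post-processing of a segmentation mask
#'
#' 3x3 mean filtering (threshold 0.5) smooths the boundary, opening then
#' closing with a radius-1 disc removes salt noise and thin bridges, holes
#' are filled, and only the component(s) containing the seed(s) are kept
#' (the largest component when no seeds are given). The result may be empty
#' if the seeds fall outside every remaining component.
#'
#' @param mask 0/1 matrix.
#' @param seeds optional data frame (`row`, `col`).
#' @return 0/1 matrix.
#' @export
postprocess <- function(mask, seeds = NULL) {
  m <- mask_pixels(mask)
  if (sum(m) == 0) return(m)
  # 3x3 mean filter by shifted sums, majority vote
  p <- pad_replicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    acc <- acc + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  m <- (acc / 9 >= 0.5) + 0
  brush <- EBImage::makeBrush(3L, shape = "disc")
  m <- as.matrix(EBImage::closing(EBImage::opening(m, brush), brush))
  m <- as.matrix(EBImage::fillHull(m))
  lab <- EBImage::bwlabel(m)
  if (max(lab) == 0) return(matrix(0, nr, nc))
  if (is.null(seeds)) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)
  } else {
    keep <- unique(lab[cbind(seeds$row, seeds$col)])
    keep <- keep[keep > 0]
    if (length(keep) == 0L) return(matrix(0, nr, nc))
  }
  (matrix(lab %in% keep, nr, nc)) + 0
}

empty_seg_result <- function(s, bone, method) {
  structure(list(mask = matrix(0, nrow(s$pixels), ncol(s$pixels)),
                 bone = bone, method = method, present = FALSE,
                 seeds_used = NULL, threshold = NA_real_,
                 area_achieved = 0, target_area = 0,
                 area_fraction_achieved = 0, conforming = NA),
            class = "knee_seg")
}

#' Segment one bone on one slice with the atlas-seeded fuzzy methods
#'
#' The slice is resampled to the working size; the atlas supplies the seed
#' centroid(s) for the slice's set and the target area (atlas area fraction
#' times the knee area). Sets with dual centroids (femoral condyles,
#' transverse set 11; tibial plateau, transverse set 1) contribute both
#' seeds and their extractions are unioned. On the sagittal plane the
#' patella seed is first relocated onto the skeleton of the FCM candidate
#' bone region. The FC path thresholds the fuzzy connectivity map under the
#' area guard; the FCM path applies the same guard to the membership map of
#' the cluster that dominates at the seed. Post-processing smooths and
#' de-spurs the mask, which is finally mapped back to the input slice size.
#'
#' @param s a [knee_slice].
#' @param a a `knee_atlas` covering the slice's plane/modality.
#' @param set_index set in `1..11` (normally `assign_set(s$index, n)`).
#' @param bone `"patella"`, `"femur"` or `"tibia"`.
#' @param method `"FC"` or `"FCM"`.
#' @param fcp,fcmp method parameters.
#' @param area_tol relative area tolerance of the guard.
#' @param knee 0/1 knee mask at the input slice size (estimated by Otsu +
#'   largest component if omitted).
#' @param working_size common analysis size in pixels.
#' @param relocate apply patella seed relocation (sagittal plane only).
#' @return An object of class `knee_seg`: `mask` (0/1, input size),
#'   `present`, `method`, `seeds_used`, `threshold`, `area_achieved`,
#'   `target_area`, `area_fraction_achieved`, `conforming`.
#' @export
segment_slice <- function(s, a, set_index, bone,
                          method = c("FC", "FCM"),
                          fcp = fc_params(), fcmp = fcm_params(),
                          area_tol = 0.15, knee = NULL,
                          working_size = 256L, relocate = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(s, "knee_slice"), inherits(a, "knee_atlas"))
  if (a$plane != s$plane || a$modality != s$modality)
    stop("atlas does not cover plane=", s$plane, ", modality=", s$modality)
  orig_h <- nrow(s$pixels); orig_w <- ncol(s$pixels)
  sw <- resample_slice(s, working_size, working_size)
  kn <- if (is.null(knee)) estimate_knee_mask(sw)
        else resample_mask(mask_pixels(knee), working_size, working_size)
  knee_area <- max(sum(kn), 1)
  seeds <- atlas_to_seed(a, set_index, bone, working_size, working_size)
  if (is.null(seeds)) return(empty_seg_result(s, bone, method))
  target <- max(1, atlas_bone(a, set_index, bone)$area_fraction * knee_area)

  fcm_fit <- NULL
  get_fcm <- function() {
    if (is.null(fcm_fit)) fcm_fit <<- fcm_cluster(sw, fcmp, seeds)
    fcm_fit
  }
  engine_for <- function(seed_df) {
    if (method == "FC") {
      fc <- fc_connectivity(sw, seed_df, fcp)
      area_constrained_mask(fc$connectivity, seed_df, target, area_tol)
    } else {
      fit <- get_fcm()
      k <- which.max(fit$memberships[seed_df$row[1L], seed_df$col[1L], ])
      area_constrained_mask(fit$memberships[, , k], seed_df, target, area_tol)
    }
  }

  if (bone == "patella" && s$plane == "sagittal" && relocate) {
    # Candidate bone region: assign pixels to their dominant FCM cluster,
    # identify the background cluster (dominant outside the knee) and the
    # soft-tissue cluster (dominant inside); what remains inside the knee
    # is bone-like tissue, whatever the modality's contrast polarity.
    fit <- get_fcm()
    hard <- apply(fit$memberships, c(1, 2), which.max)
    outside <- hard[kn == 0]
    bg_k <- if (length(outside)) which.max(tabulate(outside, fcmp$c)) else -1L
    inside <- hard[kn == 1]
    tis_k <- which.max(tabulate(inside, fcmp$c))
    cand <- (matrix(!(hard %in% c(bg_k, tis_k)), nrow(hard), ncol(hard)) &
               kn == 1) + 0
    sk <- thin_cpp(cand)
    skpts <- which(sk == 1L, arr.ind = TRUE)
    if (nrow(skpts) > 0L) {
      seeds <- tryCatch(
        relocate_patella_seed(seeds[1L, ], skpts, engine_for, target,
                              tol = area_tol),
        error = function(e) seeds)
    }
  }

  if (method == "FC") {
    conn <- NULL
    for (i in seq_len(nrow(seeds))) {
      fci <- fc_connectivity(sw, seeds[i, ], fcp)
      conn <- if (is.null(conn)) fci$connectivity
              else pmax(conn, fci$connectivity)
    }
    guarded <- area_constrained_mask(conn, seeds, target, area_tol)
  } else {
    fit <- get_fcm()
    k <- which.max(fit$memberships[seeds$row[1L], seeds$col[1L], ])
    guarded <- area_constrained_mask(fit$memberships[, , k], seeds, target,
                                     area_tol)
  }
  mask_w <- postprocess(guarded$mask, seeds)
  mask <- resample_mask(mask_w, orig_h, orig_w)
  structure(list(mask = mask, bone = bone, method = method, present = TRUE,
                 seeds_used = seeds, threshold = guarded$threshold,
                 area_achieved = sum(mask_w), target_area = target,
                 area_fraction_achieved = sum(mask_w) / knee_area,
                 conforming = guarded$conforming),
            class = "knee_seg")
}

#' @export
print.knee_seg <- function(x, ...) {
  if (!x$present) {
    cat(sprintf("<knee_seg> %s/%s: no structure on this set\n",
                x$bone, x$method))
  } else {
    cat(sprintf(
      "<knee_seg> %s/%s: area %d (target %.0f, %sconforming), threshold %.4f\n",
      x$bone, x$method, as.integer(x$area_achieved), x$target_area,
      if (isTRUE(x$conforming)) "" else "NOT ", x$threshold))
  }
  invisible(x)
}

#' Segment every bone on every slice of a volume
#'
#' @param vol a [knee_volume].
#' @param a a `knee_atlas`.
#' @param method `"FC"` or `"FCM"`.
#' @param knee_masks optional per-slice list of 0/1 knee masks.
#' @inheritParams segment_slice
#' @return Nested list `results[[slice]][[bone]]` of `knee_seg` objects.
#' @export
segment_volume <- function(vol, a, method = c("FC", "FCM"),
                           fcp = fc_params(), fcmp = fcm_params(),
                           area_tol = 0.15, knee_masks = NULL,
                           working_size = 256L, relocate = TRUE) {
  method <- match.arg(method)
  lapply(seq_len(vol$n_slices), function(i) {
    set <- assign_set(i, vol$n_slices)
    kn <- if (!is.null(knee_masks)) knee_masks[[i]] else NULL
    out <- lapply(BONES, function(b)
      segment_slice(vol$slices[[i]], a, set, b, method,
                    fcp = fcp, fcmp = fcmp, area_tol = area_tol,
                    knee = kn, working_size = working_size,
                    relocate = relocate))
    names(out) <- BONES
    out
  })
}
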