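#' Pipeline run configuration
#'
#' @param plane,modality acquisition tags of the input volume.
#' @param method `"FC"` or `"FCM"`.
#' @param atlas a `knee_atlas`, a path to an atlas JSON, or `NULL` to use
#'   the packaged reference atlas for the plane/modality.
#' @param working_size common analysis size (>= 64).
#' @param area_tol relative tolerance of the area guard.
#' @param similarity_measure,fuzziness_measure,fuzziness_window matching
#'   stage settings (kept in the manifest; matching is a separate stage via
#'   [match_series()]).
#' @param rng_seed recorded in the manifest; the segmentation path itself
#'   is deterministic.
#' @return List of class `run_config`.
#' @export
run_config <- function(plane = "sagittal", modality = "MR",
                       method = c("FC", "FCM"), atlas = NULL,
                       working_size = 256L, area_tol = 0.15,
                       similarity_measure = "NCC",
                       fuzziness_measure = "entropy",
                       fuzziness_window = 3L, rng_seed = 1L) {
  method <- match.arg(method)
  if (working_size < 64L) stop("working_size must be >= 64")
  structure(list(plane = plane, modality = modality, method = method,
                 atlas = atlas, working_size = as.integer(working_size),
                 area_tol = area_tol,
                 similarity_measure = similarity_measure,
                 fuzziness_measure = fuzziness_measure,
                 fuzziness_window = as.integer(fuzziness_window),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

resolve_atlas <- function(cfg) {
  a <- cfg$atlas
  if (is.null(a))
    return(load_reference_atlas(cfg$plane, cfg$modality))
  if (is.character(a)) {
    if (!file.exists(a)) stop("config error: atlas file not found: ", a)
    return(atlas_read_json(a))
  }
  stopifnot(inherits(a, "knee_atlas"))
  a
}

#' Run the full segmentation pipeline on a volume
#'
#' Normalizes slice positions into the 11 sets, seeds and runs the chosen
#' fuzzy method per bone and slice with the area guard and post-processing,
#' and (when ground-truth masks are supplied) evaluates volumetric per-bone
#' Dice. A machine-readable manifest records the configuration, a content
#' hash of it, package version and per-slice provenance (set, seeds,
#' thresholds, achieved areas).
#'
#' @param cfg a [run_config()].
#' @param volume a [knee_volume].
#' @param truth_masks optional per-slice list of named 0/1 masks (may
#'   include `knee`, used as the area normalizer).
#' @return List of class `knee_run`: `results` (per slice, per bone),
#'   `dice` (per-bone volumetric Dice or `NULL`), `manifest`.
#' @export
run_pipeline <- function(cfg, volume, truth_masks = NULL) {
  stopifnot(inherits(cfg, "run_config"), inherits(volume, "knee_volume"))
  atlas <- resolve_atlas(cfg)
  knee_masks <- if (!is.null(truth_masks))
    lapply(truth_masks, `[[`, "knee") else NULL
  results <- segment_volume(volume, atlas, cfg$method,
                            area_tol = cfg$area_tol,
                            knee_masks = knee_masks,
                            working_size = cfg$working_size)
  dv <- if (!is.null(truth_masks)) volume_dice(results, truth_masks) else NULL
  cfg_plain <- unclass(cfg)
  cfg_plain$atlas <- if (is.character(cfg$atlas)) cfg$atlas
                     else if (is.null(cfg$atlas)) "reference" else "in-memory"
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_plain, tf, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  provenance <- lapply(seq_along(results), function(i) {
    lapply(results[[i]], function(r) list(
      present = r$present,
      seeds = if (is.null(r$seeds_used)) NULL
              else r$seeds_used[, c("row", "col")],
      threshold = r$threshold, area = r$area_achieved,
      target_area = r$target_area, conforming = r$conforming))
  })
  manifest <- list(config = cfg_plain, config_hash = cfg_hash,
                   package_version = as.character(
                     utils::packageVersion("kneeatlas")),
                   subject_id = volume$subject_id,
                   n_slices = volume$n_slices,
                   atlas_provenance = atlas$provenance,
                   slices = provenance)
  structure(list(results = results, dice = dv, manifest = manifest),
            class = "knee_run")
}

#' @export
print.knee_run <- function(x, ...) {
  cat(sprintf("<knee_run> %s on '%s' (%d slices)\n",
              x$manifest$config$method, x$manifest$subject_id,
              x$manifest$n_slices))
  if (!is.null(x$dice)) {
    cat("  volumetric Dice vs truth:\n")
    for (b in names(x$dice))
      cat(sprintf("    %-8s %.2f%%\n", b, x$dice[[b]]))
  }
  invisible(x)
}

#' Write a run manifest to JSON
#'
#' @param run a `knee_run`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
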