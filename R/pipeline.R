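# End-to-end pipelines: static mode (a given standard plane is measured
# directly), dynamic mode (every video frame is scored and the best frame
# is measured), and batch evaluation of predictions against references.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the framework. Defaults: the standard
#' scoring weights, expansion margin 0.1 per side, type I/II boundary 60
#' degrees, the bundled heuristic detector.
#'
#' @param weights a [graf_weights()].
#' @param margin_fraction ilium box expansion per side.
#' @param boundary type I/II classification boundary, degrees.
#' @param detector `"reference"`, `"oracle"` (phantom videos only), or a
#'   `function(image, frame_index)` returning detections.
#' @param seed integer seed for any stochastic component.
#' @param verbose emit progress messages to standard error.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(weights = graf_weights(), margin_fraction = 0.1,
                            boundary = 60, detector = "reference",
                            seed = 1, verbose = FALSE) {
  structure(list(weights = weights, margin_fraction = margin_fraction,
                 boundary = boundary, detector = detector,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

resolve_detector <- function(config, frames = NULL) {
  d <- config$detector
  if (is.function(d)) return(d)
  if (identical(d, "reference"))
    return(function(image, frame_index) reference_detect(image))
  if (identical(d, "oracle")) {
    if (!inherits(frames, "phantom_video"))
      stop("the oracle detector requires a phantom video input")
    return(oracle_detector(frames))
  }
  stop("unknown detector: ", d)
}

note <- function(config, ...) {
  if (config$verbose) message(...)
}

#' Static-mode measurement of a given standard plane
#'
#' Measurement and classification are performed directly on the supplied
#' plane: detections are reduced to one box per structure, the clinical
#' layout is checked (a violation warns but does not abort, since the
#' plane was vouched for by its provider), and the angles are measured.
#'
#' @param image image matrix or path to a PNG/TIFF file.
#' @param detections annotation JSON path, list of [detection()], a
#'   [detection_set()], or `NULL` to run the configured detector.
#' @param config a [pipeline_config()].
#' @param out_json optional path for the result JSON.
#' @param out_overlay optional path for an annotated overlay PNG.
#' @return an `angle_result`.
#' @export
run_static <- function(image, detections = NULL, config = pipeline_config(),
                       out_json = NULL, out_overlay = NULL) {
  if (is.character(image)) image <- read_image(image)
  stopifnot(is.matrix(image))
  if (is.null(detections)) {
    det <- resolve_detector(config)
    detections <- det(image, 1L)
  } else if (is.character(detections)) {
    detections <- read_annotations(detections)
  }
  ds <- if (inherits(detections, "detection_set")) detections
        else select_best_per_class(detections)
  missing <- STRUCTURES[!ds$present]
  if (length(missing))
    stop("missing structure(s): ", paste(missing, collapse = ", "))
  pos <- check_relative_positions(ds, dim(image))
  if (!pos$valid)
    warning("relative-position check failed: ",
            paste(pos$reasons, collapse = "; "),
            "; proceeding with measurement", call. = FALSE)
  res <- measure(image, ds, config$boundary)
  note(config, sprintf("alpha %.2f beta %.2f type %s",
                       res$alpha, res$beta, res$graf_type))
  if (!is.null(out_json)) write_result_json(res, out_json)
  if (!is.null(out_overlay)) write_image(draw_overlay(image, res), out_overlay)
  res
}

# Load a frame sequence from a directory of images (lexicographic order),
# a multi-page TIFF, a list of matrices, or a phantom video.
load_frames <- function(frame_source) {
  if (inherits(frame_source, "phantom_video"))
    return(lapply(frame_source$frames, `[[`, "image"))
  if (is.character(frame_source) && length(frame_source) == 1) {
    if (dir.exists(frame_source)) {
      files <- sort(list.files(frame_source, pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) == 0) stop("no frames found in ", frame_source)
      return(lapply(files, read_image))
    }
    imgs <- read_image(frame_source)
    return(if (is.list(imgs)) imgs else list(imgs))
  }
  if (is.matrix(frame_source)) return(list(frame_source))
  stopifnot(is.list(frame_source))
  frame_source
}

#' Dynamic-mode measurement of a video
#'
#' Every frame is detected and scored; the highest-scoring frame is
#' selected as the standard plane and measured. Frames failing the
#' relative-position check score 0 and can never be selected.
#'
#' @param frame_source frame directory, multi-page TIFF path, list of
#'   image matrices, or a `phantom_video`.
#' @param config a [pipeline_config()].
#' @param out_json optional path for the result JSON.
#' @param out_csv optional path for the per-frame score CSV.
#' @return list with `frame_index` (selected frame, 1-based), `result`
#'   (an `angle_result`), and `scores` (per-frame summary data frame).
#' @export
run_dynamic <- function(frame_source, config = pipeline_config(),
                        out_json = NULL, out_csv = NULL) {
  detector <- resolve_detector(config, frame_source)
  frames <- load_frames(frame_source)
  sel <- select_standard_frame(frames, detector, config$weights)
  note(config, sprintf("selected frame %d of %d (score %.3f)",
                       sel$index, length(frames), sel$scores[sel$index]))
  ds <- sel$detections[[sel$index]]
  missing <- STRUCTURES[!ds$present]
  if (length(missing))
    stop("no usable plane: selected frame misses ",
         paste(missing, collapse = ", "))
  res <- measure(frames[[sel$index]], ds, config$boundary)
  res$frame_index <- sel$index
  if (!is.null(out_json)) write_result_json(res, out_json)
  if (!is.null(out_csv))
    utils::write.csv(sel$summary, out_csv, row.names = FALSE)
  list(frame_index = sel$index, result = res, scores = sel$summary)
}

#' Evaluate predicted measurements against references
#'
#' Reads two CSV files with columns `id`, `alpha`, `beta`, `graf_type`,
#' matches rows by `id`, and produces per-angle agreement reports plus a
#' classification report.
#'
#' @param predictions,references CSV paths or data frames.
#' @param out_dir optional directory for `agreement.csv` /
#'   `classification.csv` report files.
#' @return list with `alpha`, `beta` ([angle_agreement()] reports),
#'   `classification` ([classification_report()]), and `n`.
#' @export
run_evaluate <- function(predictions, references, out_dir = NULL) {
  rd <- function(x) if (is.character(x)) utils::read.csv(x) else x
  pred <- rd(predictions); ref <- rd(references)
  need <- c("id", "alpha", "beta", "graf_type")
  stopifnot(all(need %in% names(pred)), all(need %in% names(ref)))
  orphans <- c(setdiff(pred$id, ref$id), setdiff(ref$id, pred$id))
  if (length(orphans))
    stop("unmatched ids between predictions and references: ",
         paste(orphans, collapse = ", "))
  m <- merge(pred, ref, by = "id", suffixes = c("_method", "_ref"))
  rep_a <- angle_agreement(m$alpha_method, m$alpha_ref)
  rep_b <- angle_agreement(m$beta_method, m$beta_ref)
  rep_c <- classification_report(m$graf_type_method, m$graf_type_ref)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ag <- data.frame(
      angle = c("alpha", "beta"),
      mean_diff = c(rep_a$mean_diff, rep_b$mean_diff),
      sd_diff = c(rep_a$sd_diff, rep_b$sd_diff),
      mae = c(rep_a$mae, rep_b$mae),
      icc = c(rep_a$icc, rep_b$icc),
      loa_lower = c(rep_a$ba_limits[1], rep_b$ba_limits[1]),
      loa_upper = c(rep_a$ba_limits[2], rep_b$ba_limits[2]),
      pct_within = c(rep_a$pct_within_limits, rep_b$pct_within_limits)
    )
    utils::write.csv(ag, file.path(out_dir, "agreement.csv"),
                     row.names = FALSE)
    cl <- data.frame(agreement_rate = rep_c$agreement_rate,
                     kappa = rep_c$kappa)
    utils::write.csv(cl, file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
  }
  list(alpha = rep_a, beta = rep_b, classification = rep_c, n = nrow(m))
}
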