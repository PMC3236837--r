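#' Pipeline configuration
#'
#' Collects every stage parameter of the tortuosity pipeline with its
#' default. Interpolation and median filtering are optional stages
#' (disabled by default); segmentation can be skipped for noise-free binary
#' phantoms, where the foreground already is the mask.
#'
#' @param interpolate target spacing in mm (length 1 or 3) or \code{NULL} to
#'   skip sinc interpolation.
#' @param median_kernel odd kernel width or \code{NULL} to skip median
#'   subtraction.
#' @param segment \code{TRUE} to run Z-buffer segmentation, \code{FALSE} to
#'   threshold the volume at \code{binary_threshold} (binary phantoms).
#' @param binary_threshold foreground threshold used when \code{segment} is
#'   \code{FALSE}.
#' @param percentile,min_cluster,cluster_radius ZBS parameters.
#' @param hole_iterations,hole_span,hole_directions edge-hole-fill
#'   parameters.
#' @param cost_method \code{"dfe_com"}, \code{"com"} or \code{"mdfe"}.
#' @param com_iterations COM collapse iterations.
#' @param prune_factor,claim_factor tree-extraction parameters.
#' @param goal \code{"auto"} or a 1-based voxel index (x, y, z).
#' @param endpoints optional list of two 1-based voxel indices (start, end)
#'   selecting the measured path; when \code{NULL} the longest extracted
#'   branch is measured.
#' @param mode measurement mode, \code{"peak"} or \code{"end"}.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(interpolate = NULL, median_kernel = NULL,
                            segment = TRUE, binary_threshold = NULL,
                            percentile = 20, min_cluster = 5,
                            cluster_radius = sqrt(3), hole_iterations = 3,
                            hole_span = 8, hole_directions = 24,
                            cost_method = "dfe_com", com_iterations = 30,
                            prune_factor = 3, claim_factor = 1,
                            goal = "auto", endpoints = NULL,
                            mode = "peak") {
  if (!is.null(median_kernel) &&
      (median_kernel %% 2 == 0 || median_kernel < 3))
    stop("config invalid: `median_kernel` must be an odd integer >= 3")
  if (!cost_method %in% c("dfe_com", "com", "mdfe"))
    stop("config invalid: unknown cost method: ", cost_method)
  if (!mode %in% c("peak", "end"))
    stop("config invalid: `mode` must be \"peak\" or \"end\"")
  cfg <- list(interpolate = interpolate, median_kernel = median_kernel,
              segment = segment, binary_threshold = binary_threshold,
              percentile = percentile, min_cluster = min_cluster,
              cluster_radius = cluster_radius,
              hole_iterations = hole_iterations, hole_span = hole_span,
              hole_directions = hole_directions, cost_method = cost_method,
              com_iterations = com_iterations, prune_factor = prune_factor,
              claim_factor = claim_factor, goal = goal,
              endpoints = endpoints, mode = mode)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Stable hash of a pipeline configuration
#'
#' Polynomial rolling hash of the serialized configuration, embedded in
#' every output artifact so results can be traced back to their exact
#' parameters.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  raw <- serialize(unclass(config)[order(names(unclass(config)))], NULL,
                   version = 2)
  h <- 0
  for (b in as.integer(raw))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full tortuosity pipeline
#'
#' Stage sequence: optional sinc interpolation, optional median-filter
#' subtraction, segmentation (ZBS, or simple foreground thresholding for
#' noise-free binary phantoms), cost-field computation, Dijkstra centerline
#' tree extraction, tortuosity-curve calculation, and measurement readout.
#' Stage failures are reported with the stage name; intermediates computed
#' before the failure are attached to the error condition.
#'
#' @param volume an \code{\link{image_volume}} (or a \code{phantom}, whose
#'   volume is used).
#' @param config a \code{\link{pipeline_config}}.
#' @param verbose print per-stage voxel counts and timings.
#' @return A list of class \code{pipeline_result}: \code{measurements}
#'   (data frame with subject/label/mode/value), \code{curve},
#'   \code{path}, \code{tree}, \code{cost}, \code{segmentation},
#'   \code{config}, \code{config_hash}.
#' @export
run_pipeline <- function(volume, config = pipeline_config(),
                         verbose = FALSE) {
  if (inherits(volume, "phantom")) volume <- volume$volume
  if (!inherits(volume, "image_volume"))
    stop("`volume` must be an image_volume or phantom")
  stopifnot(inherits(config, "pipeline_config"))
  artifacts <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      cond <- simpleError(paste0("pipeline stage [", name, "] failed: ",
                                 conditionMessage(e)))
      cond$artifacts <- artifacts
      stop(cond)
    })
    if (verbose)
      message(sprintf("  stage %-16s %6.2f s", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  if (!is.null(config$interpolate))
    volume <- stage("interpolation",
                    sinc_interpolate(volume, config$interpolate))
  if (!is.null(config$median_kernel))
    volume <- stage("median filtering",
                    median_subtract(volume, config$median_kernel))
  seg <- if (isTRUE(config$segment)) {
    stage("segmentation",
          zbs_segment(volume, percentile = config$percentile,
                      cluster_radius = config$cluster_radius,
                      min_cluster = config$min_cluster,
                      iterations = config$hole_iterations,
                      ray_span = config$hole_span,
                      directions_required = config$hole_directions))
  } else {
    thr <- config$binary_threshold
    if (is.null(thr)) thr <- (max(volume$data) + min(volume$data)) / 2
    stage("thresholding",
          segmentation(volume$data >= thr, spacing = volume$spacing,
                       origin = volume$origin,
                       provenance = list(stage = "binary_threshold",
                                         threshold = thr)))
  }
  artifacts$segmentation <- seg
  cost <- stage("cost field",
                compute_cost(seg, config$cost_method,
                             iterations = config$com_iterations))
  artifacts$cost <- cost
  goal <- if (identical(config$goal, "auto")) NULL else
    as.integer(config$goal)
  tree <- stage("centerline tree",
                extract_tree(cost, goal = goal,
                             prune_factor = config$prune_factor,
                             claim_factor = config$claim_factor))
  artifacts$tree <- tree
  path <- stage("path selection", {
    if (!is.null(config$endpoints)) {
      path_between(cost, config$endpoints[[1]], config$endpoints[[2]])
    } else {
      if (tree$n_trees == 0L) stop("no branches extracted")
      tree_branch_path(tree, which.max(tree$branch_lengths))
    }
  })
  curve <- stage("tortuosity curve", dfm_curve(path))
  meas <- stage("measurement",
                read_measurement(curve, config$mode,
                                 spacing = seg$spacing))
  hash <- config_hash(config)
  measurements <- data.frame(label = "path", mode = meas$mode,
                             value = meas$value, L_mm = meas$L,
                             d_mm = meas$d, config_hash = hash)
  structure(list(measurements = measurements, curve = curve, path = path,
                 tree = tree, cost = cost, segmentation = seg,
                 config = config, config_hash = hash),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> config ", x$config_hash, "\n", sep = "")
  print(x$measurements)
  invisible(x)
}

#' Read a landmarks file
#'
#' Landmarks are named points in voxel (1-based) or mm coordinates; the
#' frame is recorded in the file. JSON format:
#' \code{{"frame": "voxel", "points": {"name": [x, y, z], ...}}}.
#'
#' @param path JSON landmarks file.
#' @param spacing,origin grid geometry used to convert mm landmarks to voxel
#'   indices.
#' @return Named list of 1-based voxel index vectors.
#' @export
read_landmarks <- function(path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!file.exists(path))
    stop("cannot read landmarks: file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$frame) || is.null(obj$points))
    stop("malformed landmarks file (", path,
         "): needs `frame` and `points`")
  pts <- lapply(obj$points, as.numeric)
  if (identical(obj$frame, "mm"))
    pts <- lapply(pts, function(p)
      as.integer(mm_to_voxel(p, spacing, origin)[1, ]))
  else
    pts <- lapply(pts, function(p) as.integer(round(p)))
  pts
}

#' Write a landmarks file
#'
#' @param points named list of 1-based voxel index vectors (or mm
#'   coordinates when \code{frame = "mm"}).
#' @param path output path.
#' @param frame \code{"voxel"} or \code{"mm"}.
#' @return \code{path}, invisibly.
#' @export
write_landmarks <- function(points, path, frame = c("voxel", "mm")) {
  frame <- match.arg(frame)
  jsonlite::write_json(list(frame = frame, points = points), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
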