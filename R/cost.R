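#' Per-voxel centerline cost field
#'
#' Container for a nonnegative scalar cost per object voxel; lower cost means
#' more central, so Dijkstra paths through the field hug the vessel core.
#'
#' @param values 3-D numeric array of costs (NA outside the mask).
#' @param seg the \code{\link{segmentation}} the field covers.
#' @param method one of \code{"DFE"}, \code{"MDFE"}, \code{"COM"},
#'   \code{"DFE_COM"}.
#' @param extra named list of method-specific by-products (e.g. the distance
#'   map or the raw collapse displacement).
#' @return An object of class \code{cost_field}.
#' @export
cost_field <- function(values, seg, method, extra = list()) {
  values <- as.array(values)
  if (!identical(dim(values), dim(seg$mask)))
    stop("cost values and mask dimensions differ")
  v <- values[seg$mask]
  if (any(!is.finite(v)) || any(v < 0))
    stop("cost values on the mask must be finite and nonnegative")
  structure(list(values = values, mask = seg, method = method,
                 extra = extra),
            class = "cost_field")
}

#' @export
print.cost_field <- function(x, ...) {
  v <- x$values[x$mask$mask]
  cat("<cost_field> method ", x$method, ", ", length(v),
      " voxels, cost range [", format(min(v)), ", ", format(max(v)), "]\n",
      sep = "")
  invisible(x)
}

#' Distance from edge (DFE)
#'
#' Exact Euclidean distance, in physical units, from each object voxel
#' centre to the nearest background voxel centre; zero on background. Large
#' in the middle of vessels, so it is used both directly (as MDFE's base and
#' as the DFE-COM weight) and for branch pruning.
#'
#' @param seg a \code{\link{segmentation}}.
#' @return 3-D numeric array of distances (mm).
#' @export
compute_dfe <- function(seg) {
  if (!inherits(seg, "segmentation")) stop("`seg` must be a segmentation")
  if (!any(seg$mask)) stop("empty mask")
  d <- dim(seg$mask)
  array(cpp_edt(seg$mask, d, seg$spacing), dim = d)
}

#' Center-of-mass (COM) collapse cost
#'
#' Maintains a continuous position per object voxel (initialised at the voxel
#' centre) and iteratively moves each position to the mean of the previous
#' iteration's positions over its 26-neighbourhood object voxels (self
#' included) — collapsing the object inward. The cumulative distance
#' travelled is divided by the minimum nonzero cumulative distance in the
#' segmentation and cubed: edge voxels travel far and get high cost, central
#' voxels barely move and get low cost. Supplying \code{dfe_weights} makes
#' the neighbourhood mean DFE-weighted, which is the DFE-COM cost.
#'
#' @param seg a \code{\link{segmentation}}.
#' @param iterations collapse iterations (default 30).
#' @param dfe_weights optional 3-D array of per-voxel weights (normally
#'   \code{\link{compute_dfe}(seg)}).
#' @return A \code{\link{cost_field}} (method \code{"COM"} or
#'   \code{"DFE_COM"}); the raw cumulative displacement is kept in
#'   \code{$extra$displacement}.
#' @export
compute_com_cost <- function(seg, iterations = 30, dfe_weights = NULL) {
  if (!inherits(seg, "segmentation")) stop("`seg` must be a segmentation")
  if (!any(seg$mask)) stop("empty mask")
  if (iterations < 1) stop("`iterations` must be >= 1")
  d <- dim(seg$mask)
  w <- NULL
  method <- "COM"
  if (!is.null(dfe_weights)) {
    if (!identical(dim(dfe_weights), d))
      stop("`dfe_weights` dimensions must match the mask")
    w <- as.numeric(dfe_weights)
    method <- "DFE_COM"
  }
  cum <- cpp_com_collapse(seg$mask, d, seg$spacing, as.integer(iterations),
                          w)
  cum <- array(cum, dim = d)
  moved <- cum[seg$mask]
  pos <- moved[moved > 0]
  if (length(pos) == 0L) {
    warning("no voxel moved during COM collapse (single-voxel object?); ",
            "returning uniform zero cost")
    vals <- array(NA_real_, dim = d)
    vals[seg$mask] <- 0
    return(cost_field(vals, seg, method,
                      extra = list(displacement = cum, iterations = iterations,
                                   min_displacement = NA_real_)))
  }
  mn <- min(pos)
  vals <- array(NA_real_, dim = d)
  vals[seg$mask] <- (cum[seg$mask] / mn)^3
  cost_field(vals, seg, method,
             extra = list(displacement = cum, iterations = iterations,
                          min_displacement = mn))
}

#' Modified DFE (MDFE) cost
#'
#' A strictly ordered refinement of inverted DFE. The base cost is
#' \code{max(DFE) - DFE}; equal-DFE neighbours are then separated by a
#' sub-gap tie-breaking term derived from the mean DFE of the
#' 26-neighbourhood, scaled to stay below the smallest gap between distinct
#' base costs, so the voxel with the more central neighbourhood always gets
#' the lower cost.
#'
#' @param seg a \code{\link{segmentation}}.
#' @return A \code{\link{cost_field}} (method \code{"MDFE"}); the distance
#'   map is kept in \code{$extra$dfe}.
#' @export
compute_mdfe_cost <- function(seg) {
  if (!inherits(seg, "segmentation")) stop("`seg` must be a segmentation")
  if (!any(seg$mask)) stop("empty mask")
  d <- dim(seg$mask)
  dfe <- compute_dfe(seg)
  dmax <- max(dfe[seg$mask])
  base <- array(NA_real_, dim = d)
  base[seg$mask] <- dmax - dfe[seg$mask]
  nm <- array(cpp_neighbor_mean(as.numeric(dfe), seg$mask, d), dim = d)
  # tie-break strictly inside the smallest base-cost gap
  uq <- sort(unique(base[seg$mask]))
  gap <- if (length(uq) > 1L) min(diff(uq)) else 1
  tb_raw <- dmax - nm[seg$mask]
  tb_span <- max(tb_raw) - min(tb_raw)
  tb <- if (tb_span > 0) (tb_raw - min(tb_raw)) / tb_span else
    rep(0, length(tb_raw))
  vals <- base
  vals[seg$mask] <- base[seg$mask] + 0.5 * gap * tb
  cost_field(vals, seg, "MDFE", extra = list(dfe = dfe, gap = gap))
}

#' Compute a centerline cost field
#'
#' Dispatch over the cost-function family: \code{"dfe_com"} (DFE-weighted
#' COM collapse, the default and the method used for tortuosity
#' measurements), \code{"com"} (unweighted collapse) and \code{"mdfe"}.
#'
#' @param seg a \code{\link{segmentation}}.
#' @param method one of \code{"dfe_com"}, \code{"com"}, \code{"mdfe"}.
#' @param iterations COM collapse iterations (ignored for MDFE).
#' @return A \code{\link{cost_field}}.
#' @export
compute_cost <- function(seg, method = c("dfe_com", "com", "mdfe"),
                         iterations = 30) {
  method <- match.arg(method)
  switch(method,
         dfe_com = compute_com_cost(seg, iterations,
                                    dfe_weights = compute_dfe(seg)),
         com = compute_com_cost(seg, iterations),
         mdfe = compute_mdfe_cost(seg))
}

#' Export a cost field as NIfTI for inspection
#'
#' @param cost a \code{\link{cost_field}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cost_field <- function(cost, path) {
  vals <- cost$values
  vals[is.na(vals)] <- 0
  write_volume(image_volume(vals, spacing = cost$mask$spacing,
                            origin = cost$mask$origin), path)
}
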