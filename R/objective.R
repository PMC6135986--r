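# The array design problem and its objective: normalized total ROI
# sensitivity (SA) plus weighted normalized coverage (CA), evaluated
# over the viable channels of a candidate layout.

#' Coverage threshold for a covered cortical node
#'
#' A node counts as covered when the summed channel sensitivity at that
#' node exceeds `Cthresh = ln((100 + pthresh)/100) * vhat /
#' (actvol * delta_mua)`: the sensitivity at which an absorption change
#' `delta_mua` in a block of tissue `actvol` produces a measured
#' intensity change of at least `pthresh` percent.
#'
#' @param pthresh Minimum detectable intensity change, percent
#'   (default 1).
#' @param actvol Activation volume, mm^3 (default 1000 = 1 cm^3).
#' @param delta_mua Absorption change during a hemodynamic response,
#'   per mm (default 0.001).
#' @param vhat Median per-node cortical volume, mm^3.
#' @return Coverage threshold in mm.
#' @export
coverage_threshold <- function(pthresh = 1, actvol = 1000,
                               delta_mua = 0.001, vhat) {
  stopifnot(pthresh > 0, actvol > 0, delta_mua > 0, vhat > 0)
  log((100 + pthresh) / 100) * vhat / (actvol * delta_mua)
}

# Median node volume of the reference adult-head configuration; gives
# the conventional default Cthresh of 0.1528 mm under the default
# pthresh / actvol / delta_mua.
DEFAULT_VHAT <- 15.3563
DEFAULT_CTHRESH <- 0.1528

#' Region of interest on the cortex
#'
#' @param nodes Integer vector of cortex node indices.
#' @param cortex The cortex `surface_mesh` the indices refer to.
#' @return An `roi` object with fields `nodes` and `ntot`.
#' @export
roi_from_nodes <- function(nodes, cortex) {
  nodes <- sort(unique(as.integer(nodes)))
  if (!length(nodes)) stop("ROI is empty")
  if (min(nodes) < 1L || max(nodes) > nrow(cortex$vertices)) {
    stop("ROI node index out of range")
  }
  structure(list(nodes = nodes, ntot = length(nodes),
                 xyz = cortex$vertices[nodes, , drop = FALSE]),
            class = "roi")
}

#' Region of interest from volumetric shapes
#'
#' The ROI is the set of cortex nodes contained in the union of the
#' given spheres/ellipsoids, so it includes both gyral (shallow) and
#' sulcal (deep) nodes.
#'
#' @param cortex Cortex `surface_mesh`.
#' @param shapes List of shapes; each a list with `center` (mm) and
#'   either `radius` (sphere) or `radii` (length-3, ellipsoid).
#' @return An `roi` object.
#' @export
roi_from_shapes <- function(cortex, shapes) {
  if (!length(shapes)) stop("no shapes given")
  v <- cortex$vertices
  inside <- rep(FALSE, nrow(v))
  for (sh in shapes) {
    ctr <- as.numeric(sh$center)
    radii <- if (!is.null(sh$radii)) as.numeric(sh$radii) else {
      rep(as.numeric(sh$radius), 3)
    }
    if (any(radii <= 0)) stop("shape radii must be positive")
    u <- sweep(sweep(v, 2, ctr, `-`), 2, radii, `/`)
    inside <- inside | rowSums(u^2) <= 1
  }
  if (!any(inside)) stop("ROI is empty: no cortex nodes inside the shapes")
  roi_from_nodes(which(inside), cortex)
}

#' Define an array design problem
#'
#' @param nS,nD Numbers of source and detector optodes.
#' @param roi An `roi` object.
#' @param positions A `position_system` (the solution space).
#' @param store A weighted `pmdf_store` over candidate channels of
#'   `positions`.
#' @param distances Distance table for `positions`; computed if omitted.
#' @param minRho Minimum separation of a viable channel, mm.
#' @param minRhoOpt Minimum physical distance between any two optodes,
#'   mm.
#' @param maxGoodRho Largest separation with good SNR, mm.
#' @param maxRho Largest viable separation, mm.
#' @param cW Coverage weight (>= 0) of the objective.
#' @param cthresh Coverage threshold, mm.
#' @param smax Normalisation for SA (total ROI sensitivity of the
#'   sensitivity-only optimum); usually filled in by the solver.
#' @return A `design_problem`.
#' @export
design_problem <- function(nS, nD, roi, positions, store,
                           distances = NULL,
                           minRho = 15, minRhoOpt = 10,
                           maxGoodRho = 30, maxRho = 60,
                           cW = 0, cthresh = DEFAULT_CTHRESH,
                           smax = NULL) {
  stopifnot(nS >= 1, nD >= 1, cW >= 0, cthresh > 0)
  if (!(minRhoOpt <= minRho && minRho <= maxGoodRho &&
        maxGoodRho <= maxRho)) {
    stop("need minRhoOpt <= minRho <= maxGoodRho <= maxRho")
  }
  if (!isTRUE(store$meta$weighted)) {
    stop("design_problem requires an SNR-weighted pmdf_store")
  }
  if (is.null(distances)) distances <- distance_table(positions)
  n_pos <- nrow(positions$positions)
  # unordered pair -> store channel row
  pair_idx <- matrix(0L, n_pos, n_pos)
  ch <- store$channels
  pair_idx[cbind(ch$src_pos, ch$det_pos)] <- ch$idx
  pair_idx[cbind(ch$det_pos, ch$src_pos)] <- ch$idx
  structure(list(nS = as.integer(nS), nD = as.integer(nD), roi = roi,
                 positions = positions, store = store,
                 distances = distances, pair_idx = pair_idx,
                 minRho = minRho, minRhoOpt = minRhoOpt,
                 maxGoodRho = maxGoodRho, maxRho = maxRho,
                 cW = cW, cthresh = cthresh, smax = smax),
            class = "design_problem")
}

#' @export
print.design_problem <- function(x, ...) {
  cat(sprintf(
    "design_problem: nS=%d nD=%d | minRho=%g minRhoOpt=%g maxGoodRho=%g maxRho=%g | cW=%g cthresh=%g | ROI %d nodes | %d positions\n",
    x$nS, x$nD, x$minRho, x$minRhoOpt, x$maxGoodRho, x$maxRho, x$cW,
    x$cthresh, x$roi$ntot, nrow(x$positions$positions)))
  invisible(x)
}

#' An array layout: sources and detectors on solution-space positions
#'
#' @param sources,detectors Integer position indices; disjoint.
#' @param problem Optional `design_problem`; when given, the layout is
#'   checked against `minRhoOpt` and the optode counts.
#' @return An `array_layout`.
#' @export
array_layout <- function(sources, detectors, problem = NULL) {
  sources <- as.integer(sources); detectors <- as.integer(detectors)
  if (anyDuplicated(c(sources, detectors))) {
    stop("optode positions must be distinct")
  }
  lay <- structure(list(sources = sources, detectors = detectors),
                   class = "array_layout")
  if (!is.null(problem)) {
    if (length(sources) != problem$nS || length(detectors) != problem$nD) {
      stop("layout size does not match nS/nD")
    }
    if (!layout_feasible(lay, problem)) {
      stop("layout violates the minimum inter-optode distance (minRhoOpt)")
    }
  }
  lay
}

layout_feasible <- function(layout, problem) {
  opt <- c(layout$sources, layout$detectors)
  if (length(opt) < 2L) return(TRUE)
  d <- problem$distances[opt, opt]
  all(d[upper.tri(d)] >= problem$minRhoOpt)
}

#' Viable channels of a layout
#'
#' All source-detector pairs with separation in `[minRho, maxRho]`.
#'
#' @param layout An `array_layout` (feasible under `minRhoOpt`).
#' @param problem A `design_problem`.
#' @return Data frame with `src`, `det`, `separation_mm`, `channel`
#'   (row in the PMDF store).
#' @export
viable_channels <- function(layout, problem) {
  if (!layout_feasible(layout, problem)) {
    stop("layout violates minRhoOpt; no viable channel set defined")
  }
  grid <- expand.grid(src = layout$sources, det = layout$detectors)
  sep <- problem$distances[cbind(grid$src, grid$det)]
  keep <- sep >= problem$minRho & sep <= problem$maxRho
  grid <- grid[keep, , drop = FALSE]
  sep <- sep[keep]
  chan <- problem$pair_idx[cbind(grid$src, grid$det)]
  if (any(chan == 0L)) {
    stop("channel missing from the PMDF store for pair(s): ",
         paste(sprintf("(%d,%d)", grid$src[chan == 0L],
                       grid$det[chan == 0L]), collapse = " "))
  }
  data.frame(src = grid$src, det = grid$det, separation_mm = sep,
             channel = chan, row.names = NULL)
}

#' Total sensitivity map of a layout
#'
#' Per-node sum of the weighted PMDFs of all viable channels.
#'
#' @param layout An `array_layout`.
#' @param problem A `design_problem` (weighted store).
#' @return Numeric vector over cortex nodes, mm.
#' @export
sensitivity_map <- function(layout, problem) {
  ch <- viable_channels(layout, problem)
  if (!nrow(ch)) return(numeric(ncol(problem$store$M)))
  as.numeric(Matrix::colSums(problem$store$M[ch$channel, , drop = FALSE]))
}

#' Evaluate a layout against the combined objective
#'
#' `objective = SA + cW * CA` with `SA` the ROI sensitivity normalised
#' by `smax` and `CA` the fraction of ROI nodes whose summed sensitivity
#' strictly exceeds the coverage threshold.
#'
#' @param layout An `array_layout`.
#' @param problem A `design_problem` with `smax` set (run the
#'   sensitivity-only optimisation first, see [solve_array()]).
#' @return A `quality_report` with the objective value.
#' @export
evaluate_layout <- function(layout, problem) {
  if (is.null(problem$smax) || !(problem$smax > 0)) {
    stop("problem$smax is not set; run the sensitivity-only phase first ",
         "(solve_array) or supply smax explicitly")
  }
  ch <- viable_channels(layout, problem)
  map_roi <- if (nrow(ch)) {
    as.numeric(Matrix::colSums(
      problem$store$M[ch$channel, problem$roi$nodes, drop = FALSE]))
  } else {
    numeric(problem$roi$ntot)
  }
  total <- sum(map_roi)
  nthresh <- sum(map_roi > problem$cthresh)
  sa <- total / problem$smax
  ca <- nthresh / problem$roi$ntot
  structure(list(
    objective = sa + problem$cW * ca,
    SA = sa, CA = ca,
    total_roi_sensitivity = total,
    nthresh = nthresh, ntot = problem$roi$ntot,
    n_channels = nrow(ch),
    separation_mean = if (nrow(ch)) mean(ch$separation_mm) else NA_real_,
    separation_min = if (nrow(ch)) min(ch$separation_mm) else NA_real_,
    separation_max = if (nrow(ch)) max(ch$separation_mm) else NA_real_,
    smax_used = problem$smax),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "quality_report: objective %.4f | SA %.4f CA %.4f | ROI sensitivity %.3f mm | %d channels, separations %.1f/%.1f/%.1f mm (min/mean/max)\n",
    x$objective, x$SA, x$CA, x$total_roi_sensitivity, x$n_channels,
    x$separation_min, x$separation_mean, x$separation_max))
  invisible(x)
}
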