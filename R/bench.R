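# Benchmark harness: a scaled-down reproduction of the simulation study
# design — a grid of (ROI x source/detector combination x coverage
# weight) cells, each solved by the requested methods (GRASP, manual
# baseline, exhaustive oracle) and scored by the four standard metrics:
# time, total ROI sensitivity, sensitivity ratio, and percent coverage.

#' Build an experiment grid
#'
#' Source-detector combinations are all pairs `(nS, nD)` from
#' `sd_values` with `nD >= nS` (the reciprocity convention); the grid is
#' the Cartesian product with the ROIs and coverage weights. With
#' `sd_values = c(1, 2, 4, 8, 16)` this yields 15 combinations, and 450
#' cells for 5 ROIs and 6 cW values.
#'
#' @param roi_specs Named list of ROI shape lists (see
#'   [roi_from_shapes()]).
#' @param sd_values Integer set of optode counts.
#' @param cw_values Coverage-weight values.
#' @return An `experiment_grid` with a `cells` data frame.
#' @export
make_grid <- function(roi_specs, sd_values = c(1, 2, 4, 8, 16),
                      cw_values = c(0, 1, 2, 3, 5, 10)) {
  stopifnot(length(roi_specs) >= 1, length(sd_values) >= 1,
            length(cw_values) >= 1)
  if (is.null(names(roi_specs))) {
    names(roi_specs) <- paste0("roi", seq_along(roi_specs))
  }
  sd_values <- sort(unique(as.integer(sd_values)))
  combos <- expand.grid(nS = sd_values, nD = sd_values)
  combos <- combos[combos$nD >= combos$nS, , drop = FALSE]
  combos <- combos[order(combos$nS, combos$nD), , drop = FALSE]
  cells <- expand.grid(roi = names(roi_specs),
                       combo = seq_len(nrow(combos)),
                       cW = cw_values, stringsAsFactors = FALSE)
  cells$nS <- combos$nS[cells$combo]
  cells$nD <- combos$nD[cells$combo]
  cells$combo <- NULL
  structure(list(roi_specs = roi_specs, combos = combos,
                 cw_values = cw_values,
                 cells = cells[, c("roi", "nS", "nD", "cW")]),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("experiment_grid: %d ROIs x %d combos x %d cW = %d cells\n",
              length(x$roi_specs), nrow(x$combos), length(x$cw_values),
              nrow(x$cells)))
  invisible(x)
}

#' Default synthetic benchmark setup
#'
#' A deterministic synthetic head, the 10-10 solution space on it, a
#' weighted PMDF store from the analytic fluence provider, and three
#' ROI shape classes: a focal sphere, an extended ellipsoid, and a
#' noncontiguous two-sphere region. The coverage threshold is computed
#' from this head's own median node volume.
#'
#' @param seed Seed for the synthetic head.
#' @param density Solution-space density (default `"10-10"`).
#' @return List with `head`, `contours`, `positions`, `distances`,
#'   `vols`, `store` (weighted), `roi_specs`, `cthresh`.
#' @export
bench_setup <- function(seed = 1L, density = "10-5") {
  head <- synth_head(seed = seed, cortex_subdiv = 3L)
  ct <- build_contours(head$scalp, head$landmarks)
  sys <- place_system(ct, density)
  dt <- distance_table(sys)
  cc <- candidate_channels(dt, cap = 60)
  vols <- node_volumes(head$cortex)
  store <- build_pmdf_store(sys, cc, head$cortex, vols,
                            head_id = sprintf("synth-%d", seed))
  model <- fit_snr_decay(store, maxGoodRho = 30, maxRho = 60)
  store <- apply_weights(store, model)
  roi_specs <- list(
    focal = list(list(center = c(-38, 42, 28), radius = 16)),
    extended = list(list(center = c(-42, 0, 38),
                         radii = c(22, 52, 26))),
    two_patch = list(list(center = c(-38, 42, 28), radius = 16),
                     list(center = c(38, -42, 28), radius = 16)))
  structure(list(head = head, contours = ct, positions = sys,
                 distances = dt, vols = vols, store = store,
                 snr_model = model,
                 roi_specs = roi_specs,
                 cthresh = coverage_threshold(vhat = vols$vhat)),
            class = "bench_setup")
}

serialize_layout <- function(lay) {
  sprintf("S:%s|D:%s", paste(lay$sources, collapse = ","),
          paste(lay$detectors, collapse = ","))
}

#' Run the benchmark grid
#'
#' Each cell is solved by each requested method. The sensitivity-only
#' phase (Smax) is shared across coverage weights of the same
#' (ROI, nS, nD), as it does not depend on cW. Per-cell failures are
#' recorded, not fatal. Deterministic given `seed`.
#'
#' @param grid An `experiment_grid`.
#' @param setup A `bench_setup` (or compatible list).
#' @param methods Subset of `c("grasp", "manual", "oracle")`.
#' @param seed Integer master seed.
#' @param config Base `grasp_config`; its seed is re-derived per cell.
#' @param oracle_cap Enumeration cap for the oracle method.
#' @return A `bench_result` with a tidy `records` data frame.
#' @export
run_bench <- function(grid, setup, methods = c("grasp", "manual"),
                      seed = 1L, config = grasp_config(),
                      oracle_cap = 2e5) {
  methods <- match.arg(methods, c("grasp", "manual", "oracle"),
                       several.ok = TRUE)
  # manual needs an Smax computed by another method; keep it last
  methods <- methods[order(match(methods, c("grasp", "oracle", "manual")))]
  rois <- lapply(grid$roi_specs, function(sh) {
    roi_from_shapes(setup$head$cortex, sh)
  })
  cells <- grid$cells
  smax_cache <- list()
  recs <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    problem <- design_problem(
      nS = cell$nS, nD = cell$nD, roi = rois[[cell$roi]],
      positions = setup$positions, store = setup$store,
      distances = setup$distances, cW = cell$cW,
      cthresh = setup$cthresh)
    cfg <- config
    cfg$seed <- (seed * 10007L + ci) %% .Machine$integer.max
    skey <- sprintf("%s_%d_%d", cell$roi, cell$nS, cell$nD)
    for (m in methods) {
      rec <- data.frame(cell, method = m, status = "ok",
                        objective = NA_real_, SA = NA_real_, CA = NA_real_,
                        total_roi_sensitivity = NA_real_,
                        n_channels = NA_integer_,
                        separation_mean = NA_real_,
                        separation_min = NA_real_,
                        separation_max = NA_real_,
                        smax = NA_real_, elapsed = NA_real_,
                        layout = NA_character_,
                        stringsAsFactors = FALSE)
      t0 <- Sys.time()
      res <- tryCatch({
        if (m == "grasp") {
          if (is.null(smax_cache[[skey]])) {
            scfg <- cfg
            scfg$seed <- (seed * 20011L + ci) %% .Machine$integer.max
            old_seed <- if (exists(".Random.seed", globalenv())) {
              get(".Random.seed", globalenv())
            } else NULL
            set.seed(scfg$seed)
            smax_cache[[skey]] <- phase1_smax(problem, scfg)
            if (!is.null(old_seed)) {
              assign(".Random.seed", old_seed, globalenv())
            }
          }
          sol <- solve_array(problem, cfg, smax = smax_cache[[skey]])
          list(layout = sol$layout, report = sol$report,
               smax = sol$smax_used)
        } else if (m == "manual") {
          if (is.null(smax_cache[[skey]])) {
            stop("manual evaluation needs Smax; include method 'grasp'")
          }
          problem$smax <- smax_cache[[skey]]
          lay <- manual_grid_array(problem)
          list(layout = lay, report = evaluate_layout(lay, problem),
               smax = problem$smax)
        } else {
          if (is.null(smax_cache[[skey]])) {
            so <- exhaustive_oracle(problem, "sensitivity_only",
                                    cap = oracle_cap)
            smax_cache[[skey]] <- so$objective
          }
          problem$smax <- smax_cache[[skey]]
          sol <- exhaustive_oracle(problem, "combined", cap = oracle_cap)
          list(layout = sol$layout, report = sol$report,
               smax = problem$smax)
        }
      }, error = function(e) e)
      rec$elapsed <- as.numeric(Sys.time() - t0, units = "secs")
      if (inherits(res, "error")) {
        rec$status <- paste("failed:", conditionMessage(res))
      } else {
        rep <- res$report
        rec$objective <- rep$objective
        rec$SA <- rep$SA; rec$CA <- rep$CA
        rec$total_roi_sensitivity <- rep$total_roi_sensitivity
        rec$n_channels <- rep$n_channels
        rec$separation_mean <- rep$separation_mean
        rec$separation_min <- rep$separation_min
        rec$separation_max <- rep$separation_max
        rec$smax <- res$smax
        rec$layout <- serialize_layout(res$layout)
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  # sensitivity ratio: per cell, total sensitivity / best total
  key <- interaction(records$roi, records$nS, records$nD, records$cW,
                     drop = TRUE)
  best <- tapply(records$total_roi_sensitivity, key, max, na.rm = TRUE)
  records$sens_ratio <- records$total_roi_sensitivity /
    as.numeric(best[as.character(key)])
  structure(list(records = records, seed = seed, methods = methods),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("bench_result: %d records (%d failed)\n",
              nrow(x$records), sum(x$records$status != "ok")))
  invisible(x)
}

#' Write benchmark results (tidy TSV + summary JSON)
#'
#' @param result A `bench_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bench <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$records, file.path(dir, "bench.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- result$records[result$records$status == "ok", ]
  summ <- list(
    n_records = nrow(result$records),
    n_failed = sum(result$records$status != "ok"),
    seed = result$seed,
    mean_CA_by_method_cw = stats::aggregate(
      CA ~ method + cW, data = ok, FUN = mean))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
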