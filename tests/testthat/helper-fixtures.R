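# Shared fixtures, built lazily once per test run. Everything is
# generated in code; no stored data.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_head <- function() fx("head", function() synth_head(seed = 1L))

fx_contours <- function() fx("contours", function() {
  h <- fx_head()
  build_contours(h$scalp, h$landmarks)
})

fx_sys5 <- function() fx("sys5", function() {
  place_system(fx_contours(), "10-5")
})

fx_sys25 <- function() fx("sys25", function() {
  refine_to_10_2_5(fx_sys5(), fx_contours())
})

# spherical head: analytic arc lengths are exact great circles
fx_sphere <- function() fx("sphere", function() {
  h <- synth_head(scalp_radii = c(80, 80, 80),
                  cortex_radii = c(64, 64, 64),
                  perturb_amp = 2, seed = 2L)
  list(head = h, contours = build_contours(h$scalp, h$landmarks))
})

# small head + 10-20 solution space + weighted store: cheap problems
fx_small <- function() fx("small", function() {
  h <- synth_head(seed = 3L, cortex_subdiv = 3L)
  ct <- build_contours(h$scalp, h$landmarks)
  sys <- place_system(ct, "10-20")
  dt <- distance_table(sys)
  cc <- candidate_channels(dt, cap = 60)
  vols <- node_volumes(h$cortex)
  store <- build_pmdf_store(sys, cc, h$cortex, vols, head_id = "small")
  # the sparse 10-20 spacing needs a wide reference band
  model <- fit_snr_decay(store, maxGoodRho = 30, maxRho = 60, band = 15)
  store <- apply_weights(store, model)
  v <- h$cortex$vertices
  anchor <- v[which.max(v[, 2] + v[, 3]), ]
  roi <- roi_from_shapes(h$cortex, list(list(center = anchor, radius = 25)))
  list(head = h, contours = ct, sys = sys, dt = dt, vols = vols,
       store = store, roi = roi,
       cthresh = coverage_threshold(vhat = vols$vhat))
})

fx_small_problem <- function(nS = 2, nD = 2, cW = 1, ...) {
  s <- fx_small()
  design_problem(nS = nS, nD = nD, roi = s$roi, positions = s$sys,
                 store = s$store, distances = s$dt, cW = cW,
                 cthresh = s$cthresh, ...)
}

# the benchmark run shared by the baseline-dominance and coverage-trend
# checks (the expensive fixture)
fx_bench <- function() fx("bench", function() {
  setup <- bench_setup(seed = 1L)
  grid <- make_grid(setup$roi_specs, sd_values = c(1, 2, 4),
                    cw_values = c(0, 1, 10))
  res <- run_bench(grid, setup, methods = c("grasp", "manual"),
                   seed = 3L)
  list(setup = setup, grid = grid, result = res)
})

# a deterministic family of tiny instances for oracle comparisons:
# n_pos positions subsampled from the small head's 10-5 system
fx_tiny_instance <- function(seed, n_pos = 16, nS = 1, nD = 2, cW = 1) {
  s <- fx_small()
  ct <- s$contours
  sys5 <- fx("small_sys5", function() place_system(fx_small()$contours,
                                                   "10-5"))
  set.seed(seed)
  keep <- sort(sample.int(nrow(sys5$positions), n_pos))
  sub <- structure(list(positions = sys5$positions[keep, ],
                        density = "subset", parent = NULL),
                   class = "position_system")
  rownames(sub$positions) <- NULL
  dt <- distance_table(sub)
  cc <- candidate_channels(dt, cap = 60)
  if (!nrow(cc)) return(NULL)
  store <- build_pmdf_store(sub, cc, s$head$cortex, s$vols)
  model <- tryCatch(
    fit_snr_decay(store, maxGoodRho = 30, maxRho = 60, band = 5),
    error = function(e) snr_weight_model(-0.1, 30, 60))
  store <- apply_weights(store, model)
  v <- s$head$cortex$vertices
  anchor <- v[sample.int(nrow(v), 1L), ]
  roi <- tryCatch(
    roi_from_shapes(s$head$cortex, list(list(center = anchor,
                                             radius = 30))),
    error = function(e) NULL)
  if (is.null(roi)) return(NULL)
  tryCatch(
    design_problem(nS = nS, nD = nD, roi = roi, positions = sub,
                   store = store, distances = dt, cW = cW,
                   cthresh = s$cthresh),
    error = function(e) NULL)
}
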