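# GRASP construction, local searches, the two-phase driver, the
# exhaustive oracle and the manual baseline.

tiny <- function(seed = 101, n_pos = 14, nS = 1, nD = 2, cW = 1) {
  fx_tiny_instance(seed, n_pos = n_pos, nS = nS, nD = nD, cW = cW)
}

oracle_pair <- function(pr) {
  # smax from the sensitivity-only oracle, then the combined oracle
  s0 <- exhaustive_oracle(pr, "sensitivity_only")
  pr$smax <- s0$objective
  list(problem = pr, sens = s0,
       comb = exhaustive_oracle(pr, "combined"))
}

test_that("greedy construction (RCL size 1) finds the best single pair", {
  pr <- tiny(201, nS = 1, nD = 1, cW = 0)
  expect_false(is.null(pr))
  op <- oracle_pair(pr)
  pr <- op$problem
  set.seed(1)
  lay <- construct_layout(pr, "sensitivity_only",
                          grasp_config(rcl_size = 1))
  ctx <- optodesign:::make_ctx(pr, "sensitivity_only")
  expect_equal(optodesign:::ctx_objective(ctx, lay$sources,
                                          lay$detectors),
               op$sens$objective, tolerance = 1e-9)
})

test_that("every constructed layout satisfies the distance constraints", {
  pr <- fx_small_problem(nS = 2, nD = 3)
  ctx <- optodesign:::make_ctx(pr, "sensitivity_only")
  for (s in 1:100) {
    set.seed(s)
    lay <- construct_layout(pr, "sensitivity_only", grasp_config(),
                            ctx = ctx)
    expect_false(is.null(lay))
    opt <- c(lay$sources, lay$detectors)
    expect_equal(length(opt), 5L)
    d <- pr$distances[opt, opt]
    expect_true(all(d[upper.tri(d)] >= pr$minRhoOpt))
  }
})

test_that("1-opt only improves and ends at a 1-opt local optimum", {
  pr <- tiny(301, nS = 2, nD = 2, cW = 1)
  expect_false(is.null(pr))
  op <- oracle_pair(pr); pr <- op$problem
  ctx <- optodesign:::make_ctx(pr, "combined")
  set.seed(5)
  lay0 <- construct_layout(pr, "combined", grasp_config(rcl_size = 4),
                           ctx = ctx)
  expect_false(is.null(lay0))
  o0 <- optodesign:::ctx_objective(ctx, lay0$sources, lay0$detectors)
  lay1 <- local_search_1opt(lay0, pr, "combined", ctx = ctx)
  o1 <- optodesign:::ctx_objective(ctx, lay1$sources, lay1$detectors)
  expect_gte(o1, o0 - 1e-12)
  # audit: no single relocation improves
  S <- lay1$sources; D <- lay1$detectors
  for (role in c("S", "D")) {
    set <- if (role == "S") S else D
    for (slot in seq_along(set)) {
      Sr <- S; Dr <- D
      if (role == "S") Sr <- Sr[-slot] else Dr <- Dr[-slot]
      for (p in optodesign:::ctx_feasible(ctx, c(Sr, Dr))) {
        S2 <- Sr; D2 <- Dr
        if (role == "S") S2 <- c(S2, p) else D2 <- c(D2, p)
        expect_lte(optodesign:::ctx_objective(ctx, S2, D2), o1 + 1e-9)
      }
    }
  }
})

test_that("flip-float rebuilds match the exhaustive best detector", {
  pr <- tiny(401, n_pos = 12, nS = 1, nD = 1, cW = 0)
  expect_false(is.null(pr))
  ctx <- optodesign:::make_ctx(pr, "sensitivity_only")
  # for each fixed source, the greedy single-detector rebuild equals the
  # exhaustive best detector
  for (s in which(ctx$useful)) {
    built <- optodesign:::greedy_rebuild(ctx, s, 1L)
    if (is.null(built)) next
    cand <- optodesign:::ctx_feasible(ctx, s)
    g <- ctx$gm[s, cand]
    expect_equal(ctx$gm[s, built], max(g), tolerance = 1e-12)
  }
})

test_that("flip-float is improvement-only and idempotent at the optimum", {
  pr <- tiny(501, nS = 2, nD = 2, cW = 0)
  expect_false(is.null(pr))
  op <- oracle_pair(pr); pr <- op$problem
  s_or <- exhaustive_oracle(pr, "sensitivity_only")
  ctx <- optodesign:::make_ctx(pr, "sensitivity_only")
  set.seed(3)
  lay0 <- construct_layout(pr, "sensitivity_only",
                           grasp_config(rcl_size = 5), ctx = ctx)
  expect_false(is.null(lay0))
  o0 <- optodesign:::ctx_objective(ctx, lay0$sources, lay0$detectors)
  lay1 <- local_search_flipfloat(lay0, pr, ctx = ctx)
  o1 <- optodesign:::ctx_objective(ctx, lay1$sources, lay1$detectors)
  expect_gte(o1, o0 - 1e-12)
  # idempotent on an oracle-optimal layout
  lay_opt <- s_or$layout
  lay2 <- local_search_flipfloat(lay_opt, pr, ctx = ctx)
  expect_equal(optodesign:::ctx_objective(ctx, lay2$sources,
                                          lay2$detectors),
               s_or$objective, tolerance = 1e-12)
})

test_that("2-opt reaches the oracle on two-optode problems", {
  for (seed in c(601, 602, 603)) {
    pr <- tiny(seed, n_pos = 12, nS = 1, nD = 1, cW = 1)
    if (is.null(pr)) next
    op <- oracle_pair(pr); pr <- op$problem
    ctx <- optodesign:::make_ctx(pr, "combined")
    set.seed(9)
    lay0 <- construct_layout(pr, "combined", grasp_config(rcl_size = 5),
                             ctx = ctx)
    if (is.null(lay0)) next
    lay2 <- local_search_2opt(lay0, pr, ctx = ctx)
    expect_equal(optodesign:::ctx_objective(ctx, lay2$sources,
                                            lay2$detectors),
                 op$comb$objective, tolerance = 1e-9)
    # a 2-opt optimum is also 1-opt optimal
    lay1 <- local_search_1opt(lay2, pr, "combined", ctx = ctx)
    expect_equal(optodesign:::ctx_objective(ctx, lay1$sources,
                                            lay1$detectors),
                 optodesign:::ctx_objective(ctx, lay2$sources,
                                            lay2$detectors),
                 tolerance = 1e-12)
  }
})

test_that("solve_array is deterministic given the seed", {
  pr <- fx_small_problem(nS = 2, nD = 2, cW = 1)
  cfg <- grasp_config(n_restarts = 4, seed = 77)
  s1 <- solve_array(pr, cfg)
  s2 <- solve_array(pr, cfg)
  expect_identical(s1$layout, s2$layout)
  expect_identical(s1$objective, s2$objective)
  expect_identical(s1$trace, s2$trace)
})

test_that("with cW = 0 the combined phase recovers Smax", {
  pr <- tiny(701, n_pos = 12, nS = 1, nD = 2, cW = 0)
  expect_false(is.null(pr))
  op <- oracle_pair(pr); pr <- op$problem
  sol <- solve_array(pr, grasp_config(n_restarts = 10, seed = 5),
                     smax = op$sens$objective)
  expect_equal(sol$report$total_roi_sensitivity, op$sens$objective,
               tolerance = 1e-9)
})

test_that("the oracle refuses oversized enumerations", {
  pr <- fx_small_problem(nS = 2, nD = 2)
  expect_error(exhaustive_oracle(pr, "sensitivity_only", cap = 10),
               "exceeds cap")
})

test_that("the manual star pattern rings detectors near 30 mm", {
  s <- fx_small()
  sys5 <- place_system(s$contours, "10-5")
  dt <- distance_table(sys5)
  cc <- candidate_channels(dt, cap = 60)
  store <- build_pmdf_store(sys5, cc, s$head$cortex, s$vols)
  store <- apply_weights(store, fit_snr_decay(store, 30, 60))
  pr <- design_problem(nS = 1, nD = 8, roi = s$roi, positions = sys5,
                       store = store, distances = dt,
                       cthresh = s$cthresh)
  lay <- manual_grid_array(pr, target_spacing = 30)
  expect_length(lay$sources, 1L)
  expect_length(lay$detectors, 8L)
  seps <- dt[lay$sources, lay$detectors]
  expect_lt(abs(mean(seps) - 30), 5)
  # nS = nD = 1: straddles the ROI projection near the target spacing
  pr1 <- design_problem(nS = 1, nD = 1, roi = s$roi, positions = sys5,
                        store = store, distances = dt,
                        cthresh = s$cthresh)
  lay1 <- manual_grid_array(pr1)
  expect_lt(abs(dt[lay1$sources, lay1$detectors] - 30), 12)
})
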