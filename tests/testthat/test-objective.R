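# ROI definition, viable channels, sensitivity maps, the combined
# objective, and the coverage threshold.

test_that("the coverage threshold reproduces the reference value", {
  expect_equal(round(coverage_threshold(1, 1000, 0.001, 15.36), 4),
               0.1528)
  expect_equal(coverage_threshold(1, 1000, 0.001, 2 * 15.36),
               2 * coverage_threshold(1, 1000, 0.001, 15.36),
               tolerance = 1e-14)
  expect_lt(coverage_threshold(1e-9, 1000, 0.001, 15.36), 1e-9)
  expect_error(coverage_threshold(-1, 1000, 0.001, 15.36))
})

test_that("ROIs from shapes are unions of contained nodes", {
  s <- fx_small()
  cortex <- s$head$cortex
  all_roi <- roi_from_shapes(cortex, list(list(center = c(0, 0, 0),
                                               radius = 500)))
  expect_equal(all_roi$ntot, nrow(cortex$vertices))

  c1 <- cortex$vertices[5, ]; c2 <- -cortex$vertices[5, ]
  r1 <- roi_from_shapes(cortex, list(list(center = c1, radius = 15)))
  r2 <- roi_from_shapes(cortex, list(list(center = c2, radius = 15)))
  expect_length(intersect(r1$nodes, r2$nodes), 0)
  ru <- roi_from_shapes(cortex, list(list(center = c1, radius = 15),
                                     list(center = c2, radius = 15)))
  expect_equal(ru$ntot, r1$ntot + r2$ntot)
  # brute-force membership check
  d1 <- sqrt(rowSums(sweep(cortex$vertices, 2, c1, `-`)^2))
  expect_setequal(r1$nodes, which(d1 <= 15))
  expect_error(roi_from_shapes(cortex,
                               list(list(center = c(500, 0, 0),
                                         radius = 1))),
               "empty")
})

# a hand-built micro problem: 4 positions on a 30 mm square
micro_problem <- function(nS = 2, nD = 2, cW = 0, minRho = 15,
                          minRhoOpt = 10, maxRho = 60, smax = NULL) {
  s <- fx_small()
  pos <- data.frame(label = c("A", "B", "C", "D"),
                    x = c(0, 30, 0, 30), y = c(0, 0, 30, 30),
                    z = 90)
  sys <- structure(list(positions = pos, density = "micro"),
                   class = "position_system")
  dt <- distance_table(sys)
  cc <- candidate_channels(dt, cap = 60)
  store <- build_pmdf_store(sys, cc, s$head$cortex, s$vols)
  store <- apply_weights(store, snr_weight_model(-0.15, 30, 60))
  roi <- roi_from_shapes(s$head$cortex,
                         list(list(center = c(15, 15, 60), radius = 30)))
  design_problem(nS = nS, nD = nD, roi = roi, positions = sys,
                 store = store, distances = dt, cW = cW,
                 minRho = minRho, minRhoOpt = minRhoOpt, maxRho = maxRho,
                 cthresh = fx_small()$cthresh, smax = smax)
}

test_that("viable channels respect minRho/maxRho but not minRhoOpt", {
  pr <- micro_problem(nS = 1, nD = 1)
  lay <- array_layout(1, 2, pr)           # 30 mm apart
  ch <- viable_channels(lay, pr)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$separation_mm, 30)

  # 12 mm apart: no viable channel, but the layout itself is feasible
  pos12 <- data.frame(label = c("A", "B"), x = c(0, 12), y = 0, z = 90)
  s <- fx_small()
  sys <- structure(list(positions = pos12, density = "micro"),
                   class = "position_system")
  dt <- distance_table(sys)
  store <- build_pmdf_store(sys, candidate_channels(dt, 60),
                            s$head$cortex, s$vols)
  store <- apply_weights(store, snr_weight_model(-0.15, 30, 60))
  roi <- roi_from_shapes(s$head$cortex,
                         list(list(center = c(6, 0, 60), radius = 30)))
  pr12 <- design_problem(1, 1, roi, sys, store, dt, minRho = 15,
                         minRhoOpt = 10)
  lay12 <- array_layout(1, 2, pr12)
  expect_equal(nrow(viable_channels(lay12, pr12)), 0L)

  # 2x2 square of side 30: all four source-detector pairs viable
  pr4 <- micro_problem(nS = 2, nD = 2)
  lay4 <- array_layout(c(1, 4), c(2, 3), pr4)
  ch4 <- viable_channels(lay4, pr4)
  expect_equal(nrow(ch4), 4L)
  expect_equal(ch4$separation_mm, rep(30, 4), tolerance = 1e-12)
})

test_that("infeasible layouts are rejected", {
  s <- fx_small()
  pos <- data.frame(label = c("A", "B", "C"),
                    x = c(0, 12, 40), y = 0, z = 90)
  sys <- structure(list(positions = pos, density = "micro"),
                   class = "position_system")
  dt <- distance_table(sys)
  store <- apply_weights(
    build_pmdf_store(sys, candidate_channels(dt, 60), s$head$cortex,
                     s$vols),
    snr_weight_model(-0.15, 30, 60))
  roi <- roi_from_shapes(s$head$cortex,
                         list(list(center = c(6, 0, 60), radius = 30)))
  pr <- design_problem(1, 1, roi, sys, store, dt, minRho = 15,
                       minRhoOpt = 14)
  expect_error(array_layout(1, 2, pr), "minRhoOpt")  # 12 mm apart
  lay <- structure(list(sources = 1L, detectors = 2L),
                   class = "array_layout")
  expect_error(viable_channels(lay, pr), "minRhoOpt")
  expect_silent(array_layout(1, 3, pr))              # 40 mm apart
  expect_error(array_layout(c(1, 1), 2), "distinct")
})

test_that("sensitivity maps add channel PMDFs", {
  pr <- micro_problem(nS = 2, nD = 2)
  lay1 <- array_layout(1, 2)
  m1 <- sensitivity_map(lay1, pr)
  ch1 <- viable_channels(lay1, pr)
  expect_equal(m1, as.numeric(pr$store$M[ch1$channel, ]))

  lay2 <- array_layout(c(1, 4), 2)
  m2 <- sensitivity_map(lay2, pr)
  ch2 <- viable_channels(lay2, pr)
  expect_equal(m2, as.numeric(Matrix::colSums(pr$store$M[ch2$channel, ])))
  expect_true(all(m2 >= m1 - 1e-15))

  # no viable channels: an all-zero map
  pos <- data.frame(label = c("A", "B"), x = c(0, 12), y = 0, z = 90)
  s <- fx_small()
  sys <- structure(list(positions = pos, density = "micro"),
                   class = "position_system")
  dt <- distance_table(sys)
  store <- apply_weights(
    build_pmdf_store(sys, candidate_channels(dt, 60), s$head$cortex,
                     s$vols),
    snr_weight_model(-0.15, 30, 60))
  roi <- roi_from_shapes(s$head$cortex,
                         list(list(center = c(6, 0, 60), radius = 30)))
  pr0 <- design_problem(1, 1, roi, sys, store, dt)
  expect_true(all(sensitivity_map(array_layout(1, 2, pr0), pr0) == 0))
})

test_that("the combined objective is SA + cW * CA", {
  pr <- micro_problem(nS = 2, nD = 2, cW = 0, smax = 1)
  lay <- array_layout(c(1, 4), c(2, 3), pr)
  # brute-force oracle for SA and CA from the sensitivity map
  map <- sensitivity_map(lay, pr)
  roi_map <- map[pr$roi$nodes]
  rep0 <- evaluate_layout(lay, pr)
  expect_equal(rep0$total_roi_sensitivity, sum(roi_map),
               tolerance = 1e-12)
  expect_equal(rep0$SA, sum(roi_map) / 1)
  expect_equal(rep0$CA, mean(roi_map > pr$cthresh))
  expect_equal(rep0$objective, rep0$SA)      # cW = 0

  pr10 <- micro_problem(nS = 2, nD = 2, cW = 10, smax = 1)
  rep10 <- evaluate_layout(lay, pr10)
  expect_equal(rep10$objective - rep0$objective, 10 * rep0$CA,
               tolerance = 1e-12)

  # smax must be present
  prx <- micro_problem()
  expect_error(evaluate_layout(lay, prx), "smax")
})

test_that("coverage is monotone in the threshold and in channels", {
  pr <- micro_problem(nS = 2, nD = 2, cW = 1, smax = 1)
  lay_small <- array_layout(1, 2)       # fewer channels
  lay_big <- array_layout(c(1, 4), c(2, 3), pr)
  map_s <- sensitivity_map(lay_small, pr)[pr$roi$nodes]
  map_b <- sensitivity_map(lay_big, pr)[pr$roi$nodes]
  expect_true(all(map_b >= map_s - 1e-15))
  ths <- sort(runif(6, 0, max(map_b)))
  nth <- vapply(ths, function(t) sum(map_b > t), numeric(1))
  expect_true(all(diff(nth) <= 0))
})

test_that("parameter ordering constraints are enforced", {
  expect_error(micro_problem(minRho = 5, minRhoOpt = 10),
               "minRhoOpt <= minRho")
  s <- fx_small()
  raw <- build_pmdf_store(s$sys, candidate_channels(s$dt, 60),
                          s$head$cortex, s$vols)
  expect_error(design_problem(1, 1, s$roi, s$sys, raw, s$dt),
               "weighted")
})
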