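# Fluence provider, PMDF assembly, sparsification, SNR weighting.

toy_fluence <- function(origin, values, probe_val) {
  structure(list(origin = as.numeric(origin), cortex_values = values,
                 scalp_probe = function(p) probe_val,
                 mu_eff = NA, r0 = NA),
            class = "surface_fluence")
}

unit_vols <- function(n) {
  structure(list(volumes = rep(1, n), vhat = 1), class = "node_volumes")
}

test_that("synthetic fluence follows exp(-mu r)/max(r, r0)", {
  cortex <- surface_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)),
                         rbind(c(1, 2, 3)), kind = "cortex")
  fl <- synthetic_fluence(c(0, 0, 0), cortex, mu_eff = 0.1, r0 = 1)
  expect_equal(fl$cortex_values[1], 1)             # capped at 1/r0
  expect_equal(fl$cortex_values[2] / fl$cortex_values[3],
               exp(1) * 2, tolerance = 1e-12)
  expect_true(all(diff(fl$cortex_values) < 0))
  expect_equal(fl$scalp_probe(c(10, 0, 0)), exp(-1) / 10,
               tolerance = 1e-14)
})

test_that("fluence decreases monotonically with distance on a real head", {
  s <- fx_small()
  origin <- s$sys$positions[1, c("x", "y", "z")]
  fl <- synthetic_fluence(unlist(origin), s$head$cortex)
  r <- sqrt(rowSums(sweep(s$head$cortex$vertices, 2,
                          unlist(origin), `-`)^2))
  expect_true(all(diff(fl$cortex_values[order(r)]) <= 0))
})

test_that("PMDF product rule and source/detector exchange symmetry", {
  src <- toy_fluence(c(0, 0, 0), c(1, 0.5, 0), 0.25)
  det <- toy_fluence(c(30, 0, 0), c(0.5, 1, 0), 0.25)
  vols <- unit_vols(3)
  pm <- compute_pmdf(src, det, vols)
  expect_equal(pm$values, c(2, 2, 0))
  expect_equal(pm$pmdf_norm, 0.25)
  expect_equal(pm$separation, 30)
  pm_sw <- compute_pmdf(det, src, vols)
  expect_identical(pm$values, pm_sw$values)
  expect_identical(pm$pmdf_norm, pm_sw$pmdf_norm)

  # disjoint cortical supports: an all-zero PMDF
  src2 <- toy_fluence(c(0, 0, 0), c(1, 1, 0), 0.25)
  det2 <- toy_fluence(c(30, 0, 0), c(0, 0, 1), 0.25)
  expect_true(all(compute_pmdf(src2, det2, vols)$values == 0))
  expect_error(compute_pmdf(src, src, vols), "distinct")
})

test_that("PMDF normalisation takes the larger cross-probed fluence", {
  src <- toy_fluence(c(0, 0, 0), c(1, 1, 1), 0.2)
  det <- toy_fluence(c(30, 0, 0), c(1, 1, 1), 0.7)
  pm <- compute_pmdf(src, det, unit_vols(3))
  expect_equal(pm$pmdf_norm, 0.7)
})

test_that("sparsification zeroes exactly the sub-threshold entries", {
  expect_equal(sparsify(c(1, 1e-7, 0.5)), c(1, 0, 0.5))
  expect_equal(sparsify(rep(0, 4)), rep(0, 4))
  v <- c(1, 1 - 5e-7, 1 - 2e-7)
  expect_equal(sparsify(v), v)
  # boundary: exactly 1e-6 * max is retained
  expect_equal(sparsify(c(1, 1e-6)), c(1, 1e-6))
  expect_equal(sparsify(c(1, 0.999999e-6)), c(1, 0))
})

test_that("the SNR weighting follows the piecewise law", {
  m <- snr_weight_model(a = -0.2, maxGoodRho = 30, maxRho = 40)
  expect_identical(wpmdf(25, m), 1)
  expect_identical(wpmdf(30, m), 1)          # boundary in first branch
  expect_identical(wpmdf(45, m), 0)
  expect_equal(wpmdf(35, m), exp(-1), tolerance = 1e-15)
  expect_equal(wpmdf(40, m), exp(-0.2 * 10), tolerance = 1e-15)
  sd <- seq(0, 60, by = 0.25)
  w <- wpmdf(sd, m)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0 & w <= 1))
  expect_error(snr_weight_model(0.1, 30, 40), "non-positive")
  expect_error(snr_weight_model(-0.1, 50, 40))
})

test_that("fit_snr_decay recovers a planted exponential slope", {
  mk_store <- function(pn, sep) {
    structure(list(M = NULL,
                   channels = data.frame(idx = seq_along(pn),
                                         src_pos = 1, det_pos = 2,
                                         separation_mm = sep,
                                         pmdf_norm = pn),
                   meta = list(weighted = FALSE)),
              class = "pmdf_store")
  }
  sep <- seq(20, 60, by = 2.5)
  store <- mk_store(7.3 * exp(-0.15 * sep), sep)
  m <- fit_snr_decay(store, maxGoodRho = 30, maxRho = 60, band = 1)
  expect_equal(m$a, -0.15, tolerance = 1e-6)
  # scale invariance of the ratio
  m2 <- fit_snr_decay(mk_store(2 * 7.3 * exp(-0.15 * sep), sep),
                      maxGoodRho = 30, maxRho = 60)
  expect_equal(m2$a, m$a, tolerance = 1e-12)
  # constant PMDFnorm: degenerate zero slope, flagged
  expect_warning(
    m0 <- fit_snr_decay(mk_store(rep(3, length(sep)), sep), 30, 60),
    "non-negative")
  expect_equal(m0$a, 0)
  expect_error(fit_snr_decay(mk_store(1, 50), 30, 60), "reference band")
})

test_that("weighting a store scales rows and cannot be applied twice", {
  s <- fx_small()
  sep <- s$store$channels$separation_mm
  w <- s$store$channels$weight
  expect_true(all(w[sep <= 30] == 1))
  expect_true(all(w[sep > 60] == 0))
  expect_error(apply_weights(s$store, snr_weight_model(-0.1, 30, 60)),
               "already weighted")

  # rebuild unweighted and compare mass
  cc <- candidate_channels(s$dt, cap = 60)
  raw <- build_pmdf_store(s$sys, cc, s$head$cortex, s$vols)
  model <- fit_snr_decay(raw, 30, 60, band = 15)
  wtd <- apply_weights(raw, model)
  expect_lte(sum(wtd$M), sum(raw$M) + 1e-12)
  beyond <- which(raw$channels$separation_mm > 60)
  if (length(beyond)) {
    expect_true(all(Matrix::rowSums(wtd$M[beyond, , drop = FALSE]) == 0))
  }
  within <- which(raw$channels$separation_mm <= 30)
  expect_equal(as.numeric(wtd$M[within[1], ]),
               as.numeric(raw$M[within[1], ]), tolerance = 1e-14)
})

test_that("PMDF stores round-trip through MatrixMarket + TSV + JSON", {
  s <- fx_small()
  dir <- withr::local_tempdir()
  write_pmdf_store(s$store, dir)
  expect_true(all(c("matrix.mtx", "channels.tsv", "meta.json") %in%
                    list.files(dir)))
  back <- read_pmdf_store(dir)
  expect_equal(dim(back$M), dim(s$store$M))
  expect_equal(max(abs(back$M - s$store$M)), 0, tolerance = 1e-12)
  expect_equal(back$channels$separation_mm,
               s$store$channels$separation_mm, tolerance = 1e-9)
  expect_true(isTRUE(back$meta$weighted))
})
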