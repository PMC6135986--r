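# Channel sensitivity distributions (photon measurement density
# functions, PMDFs) on the cortical surface. A PMDF is the product of the
# source and detector fluence fields projected on the cortex, corrected
# for per-node volumes and normalised by the larger of the two
# cross-probed volumetric fluence values (PMDFnorm), then sparsified.
# Fluence fields come from a pluggable provider; the synthetic analytic
# provider below stands in for finite-element photon transport.

#' Synthetic analytic fluence field
#'
#' A spherically symmetric diffusion-like field
#' `phi(r) = exp(-mu_eff * r) / max(r, r0)`, evaluated on the cortex
#' nodes and exposed as a volumetric probe for PMDF normalisation. Any
#' provider honouring this contract (cortex values + `scalp_probe`)
#' plugs into [compute_pmdf()] unchanged.
#'
#' @param origin Length-3 scalp position (mm), or a 1-row matrix.
#' @param cortex A cortex `surface_mesh`.
#' @param mu_eff Effective attenuation coefficient, per mm (default 0.1).
#' @param r0 Source-singularity floor, mm (default 1).
#' @return A `surface_fluence` object with fields `origin`,
#'   `cortex_values` and function `scalp_probe(p)`.
#' @export
synthetic_fluence <- function(origin, cortex, mu_eff = 0.1, r0 = 1) {
  stopifnot(mu_eff > 0, r0 > 0)
  origin <- as.numeric(origin)
  phi <- function(p) {
    r <- sqrt(sum((as.numeric(p) - origin)^2))
    exp(-mu_eff * r) / max(r, r0)
  }
  r <- sqrt(rowSums((cortex$vertices -
                       matrix(origin, nrow(cortex$vertices), 3,
                              byrow = TRUE))^2))
  structure(list(origin = origin,
                 cortex_values = exp(-mu_eff * r) / pmax(r, r0),
                 scalp_probe = phi, mu_eff = mu_eff, r0 = r0),
            class = "surface_fluence")
}

#' Sparsify a sensitivity vector
#'
#' Entries smaller than `1e-6` times the maximum are set to exactly
#' zero; all other entries are unchanged.
#'
#' @param values Numeric vector of non-negative sensitivities.
#' @param rel_tol Relative threshold (default `1e-6`).
#' @return The sparsified vector.
#' @export
sparsify <- function(values, rel_tol = 1e-6) {
  m <- max(values)
  if (m <= 0) return(values)
  values[values < rel_tol * m] <- 0
  values
}

#' Compute the PMDF of one channel
#'
#' @param src,det `surface_fluence` fields of the source and detector;
#'   must originate from distinct scalp positions.
#' @param vols `node_volumes` for the cortex.
#' @return A `pmdf` object: `values` (per cortex node, mm), `separation`
#'   (mm) and `pmdf_norm`.
#' @export
compute_pmdf <- function(src, det, vols) {
  sep <- sqrt(sum((src$origin - det$origin)^2))
  if (sep < 1e-9) stop("source and detector must be distinct positions")
  pn <- max(src$scalp_probe(det$origin), det$scalp_probe(src$origin))
  if (pn <= 0) stop("degenerate channel: zero PMDF normalisation")
  raw <- src$cortex_values * det$cortex_values * vols$volumes / pn
  structure(list(values = sparsify(raw), separation = sep, pmdf_norm = pn),
            class = "pmdf")
}

#' SNR separation-weighting model
#'
#' Piecewise weighting of channel separation: weight 1 up to
#' `maxGoodRho`, exponential decay `exp(a * (SD - maxGoodRho))` up to
#' `maxRho`, zero beyond.
#'
#' @param a Fitted decay slope, per mm (expected negative).
#' @param maxGoodRho Largest separation with acceptable SNR, mm.
#' @param maxRho Largest usable separation, mm.
#' @return An `snr_weight_model`.
#' @export
snr_weight_model <- function(a, maxGoodRho, maxRho) {
  stopifnot(maxGoodRho > 0, maxGoodRho <= maxRho)
  if (a > 0) stop("SNR decay slope must be non-positive")
  structure(list(a = a, maxGoodRho = maxGoodRho, maxRho = maxRho),
            class = "snr_weight_model")
}

#' Evaluate the SNR weighting factor
#'
#' @param SDi Source-detector separations, mm (vectorised).
#' @param model An `snr_weight_model`.
#' @return Weights in `[0, 1]`.
#' @export
wpmdf <- function(SDi, model) {
  stopifnot(all(SDi >= 0))
  ifelse(SDi <= model$maxGoodRho, 1,
         ifelse(SDi <= model$maxRho,
                exp(model$a * (SDi - model$maxGoodRho)), 0))
}

#' Assemble a PMDF store for a set of candidate channels
#'
#' @param positions Matrix or data frame of scalp positions (x, y, z) or
#'   a `position_system`.
#' @param channels Data frame with `idx_a`, `idx_b` (position indices),
#'   e.g. from [candidate_channels()].
#' @param cortex Cortex `surface_mesh`.
#' @param vols `node_volumes` for the cortex.
#' @param provider Function `(origin, cortex) -> surface_fluence`;
#'   defaults to [synthetic_fluence()] with its default optics.
#' @param head_id Free-text head identifier stored in the metadata.
#' @return A `pmdf_store`: sparse channels-by-nodes matrix `M`, channel
#'   table (`idx`, `src_pos`, `det_pos`, `separation_mm`, `pmdf_norm`)
#'   and metadata (weighting state).
#' @export
build_pmdf_store <- function(positions, channels, cortex, vols,
                             provider = synthetic_fluence,
                             head_id = "unnamed") {
  pos <- if (inherits(positions, "position_system")) {
    as.matrix(positions$positions[, c("x", "y", "z")])
  } else {
    as.matrix(positions[, c("x", "y", "z"), drop = FALSE])
  }
  used <- sort(unique(c(channels$idx_a, channels$idx_b)))
  flu <- vector("list", nrow(pos))
  for (i in used) flu[[i]] <- provider(pos[i, ], cortex)
  n_nodes <- nrow(cortex$vertices)
  nc <- nrow(channels)
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  sepv <- numeric(nc); pnv <- numeric(nc)
  for (k in seq_len(nc)) {
    pm <- compute_pmdf(flu[[channels$idx_a[k]]], flu[[channels$idx_b[k]]],
                       vols)
    nz <- which(pm$values > 0)
    if (length(nz)) {
      trip_i[[length(trip_i) + 1L]] <- rep(k, length(nz))
      trip_j[[length(trip_j) + 1L]] <- nz
      trip_x[[length(trip_x) + 1L]] <- pm$values[nz]
    }
    sepv[k] <- pm$separation; pnv[k] <- pm$pmdf_norm
  }
  M <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(nc, n_nodes))
  structure(list(
    M = M,
    channels = data.frame(idx = seq_len(nc),
                          src_pos = channels$idx_a, det_pos = channels$idx_b,
                          separation_mm = sepv, pmdf_norm = pnv),
    meta = list(head_id = head_id, weighted = FALSE,
                maxGoodRho = NA_real_, maxRho = NA_real_)),
    class = "pmdf_store")
}

#' @export
print.pmdf_store <- function(x, ...) {
  cat(sprintf("pmdf_store: %d channels x %d nodes (%s)\n",
              nrow(x$M), ncol(x$M),
              if (isTRUE(x$meta$weighted)) "weighted" else "unweighted"))
  invisible(x)
}

#' Fit the SNR decay slope from PMDF normalisation factors
#'
#' Takes the ratio of each channel's PMDFnorm (separation beyond
#' `maxGoodRho`) to the mean PMDFnorm of channels at `maxGoodRho`
#' (within a tolerance band), and fits a line to the natural log of
#' these ratios against separation. The slope is the decay coefficient
#' of the exponential branch of the weighting function.
#'
#' @param store A `pmdf_store`.
#' @param maxGoodRho Reference separation, mm.
#' @param maxRho Largest usable separation, mm (stored on the model).
#' @param band Half-width of the reference band, mm (default 1).
#' @return An `snr_weight_model`.
#' @export
fit_snr_decay <- function(store, maxGoodRho, maxRho, band = 1) {
  sep <- store$channels$separation_mm
  pn <- store$channels$pmdf_norm
  ref_idx <- which(abs(sep - maxGoodRho) <= band)
  far_idx <- which(sep > maxGoodRho)
  if (!length(ref_idx)) {
    stop("no channels within the reference band at maxGoodRho")
  }
  if (length(far_idx) < 2L) {
    stop("need at least two channels beyond maxGoodRho to fit the decay")
  }
  ref <- mean(pn[ref_idx])
  ratio <- pn[far_idx] / ref
  fit <- stats::lm(log(ratio) ~ sep[far_idx])
  a <- unname(stats::coef(fit)[2])
  if (a >= 0) {
    warning("fitted SNR decay slope is non-negative; expected a < 0")
    a <- min(a, 0)
  }
  snr_weight_model(a, maxGoodRho, maxRho)
}

#' Apply the SNR separation weighting to a PMDF store
#'
#' Each channel's sensitivity vector is multiplied by its weight;
#' channels beyond `maxRho` become all-zero. Weighting a store twice is
#' an error.
#'
#' @param store An unweighted `pmdf_store`.
#' @param model An `snr_weight_model`.
#' @return The weighted `pmdf_store`.
#' @export
apply_weights <- function(store, model) {
  if (isTRUE(store$meta$weighted)) {
    stop("store is already weighted; refusing to weight twice")
  }
  w <- wpmdf(store$channels$separation_mm, model)
  store$M <- Matrix::Diagonal(x = w) %*% store$M
  store$M <- methods::as(Matrix::drop0(store$M), "CsparseMatrix")
  store$channels$weight <- w
  store$meta$weighted <- TRUE
  store$meta$maxGoodRho <- model$maxGoodRho
  store$meta$maxRho <- model$maxRho
  store$meta$a <- model$a
  store
}

#' Write / read a PMDF store (MatrixMarket + TSV + JSON metadata)
#'
#' @param store A `pmdf_store`.
#' @param dir Directory to hold `matrix.mtx`, `channels.tsv`,
#'   `meta.json`.
#' @return `dir` (write) or a `pmdf_store` (read).
#' @export
write_pmdf_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(store$M, "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(store$channels, file.path(dir, "channels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(store$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_pmdf_store
#' @export
read_pmdf_store <- function(dir) {
  M <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  ch <- utils::read.table(file.path(dir, "channels.tsv"), sep = "\t",
                          header = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(M = M, channels = ch, meta = meta), class = "pmdf_store")
}
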