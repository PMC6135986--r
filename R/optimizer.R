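# GRASP metaheuristic for the array design problem: randomized greedy
# construction from restricted candidate lists, 1-opt relocation,
# flip-float (sensitivity-only) and 2-opt (combined) neighbourhoods,
# driven in two phases: sensitivity-only (to obtain the normalisation
# Smax) then the combined sensitivity + coverage objective. Also the
# exhaustive exact oracle for tiny instances and the manual
# single-distance baseline arrays.

#' GRASP configuration
#'
#' @param rcl_size Size of the restricted candidate list (default 5):
#'   each greedy step picks uniformly at random among the `rcl_size`
#'   best-ranked candidates.
#' @param n_restarts Number of GRASP restarts (default 20).
#' @param time_budget Optional wall-clock budget in seconds; restarts
#'   stop when it is exceeded (default `Inf`).
#' @param seed Integer seed; identical seeds give identical solutions.
#' @param two_opt_shortlist In large solution spaces, the 2-opt
#'   neighbourhood scans joint reinsertions over the top-`k` positions
#'   by marginal gain for each role (full scan when the candidate set is
#'   small).
#' @return A `grasp_config`.
#' @export
grasp_config <- function(rcl_size = 5, n_restarts = 20,
                         time_budget = Inf, seed = 1L,
                         two_opt_shortlist = 12L) {
  stopifnot(rcl_size >= 1, n_restarts >= 1, time_budget > 0)
  structure(list(rcl_size = as.integer(rcl_size),
                 n_restarts = as.integer(n_restarts),
                 time_budget = time_budget, seed = as.integer(seed),
                 two_opt_shortlist = as.integer(two_opt_shortlist)),
            class = "grasp_config")
}

# Evaluation context: dense gain matrix gm[p, q] = ROI sensitivity of
# the viable channel between positions p and q (0 if not viable), the
# ROI-restricted sparse store for coverage, and the distance rules.
make_ctx <- function(problem, mode = c("sensitivity_only", "combined")) {
  mode <- match.arg(mode)
  if (mode == "combined" &&
      (is.null(problem$smax) || !(problem$smax > 0))) {
    stop("combined mode requires problem$smax from the ",
         "sensitivity-only phase")
  }
  roi <- problem$roi$nodes
  Mroi <- problem$store$M[, roi, drop = FALSE]
  MroiT <- Matrix::t(Mroi)
  # dense ROI-restricted store when affordable: sparse subscripting
  # dominates the search otherwise
  Mroi_dense <- if (length(Mroi) <= 2e7) as.matrix(Mroi) else NULL
  chan_roi <- as.numeric(Matrix::rowSums(Mroi))
  npos <- nrow(problem$positions$positions)
  sep <- problem$distances
  V <- problem$pair_idx
  V[sep < problem$minRho | sep > problem$maxRho] <- 0L
  gm <- matrix(0, npos, npos)
  nz <- V > 0L
  gm[nz] <- chan_roi[V[nz]]
  list(mode = mode, npos = npos, V = V, gm = gm,
       MroiT = MroiT, Mroi_dense = Mroi_dense, chan_roi = chan_roi,
       useful = rowSums(gm) > 0,
       sep = sep, minRhoOpt = problem$minRhoOpt,
       cthresh = problem$cthresh, ntot = problem$roi$ntot,
       cW = problem$cW, smax = problem$smax,
       nS = problem$nS, nD = problem$nD)
}

ctx_channels <- function(ctx, S, D) {
  ids <- ctx$V[S, D, drop = FALSE]
  ids[ids > 0L]
}

ctx_nodevec <- function(ctx, chan_ids) {
  if (!length(chan_ids)) return(numeric(nrow(ctx$MroiT)))
  if (!is.null(ctx$Mroi_dense)) {
    if (length(chan_ids) == 1L) return(ctx$Mroi_dense[chan_ids, ])
    return(.colSums(ctx$Mroi_dense[chan_ids, ], length(chan_ids),
                    ncol(ctx$Mroi_dense)))
  }
  as.numeric(Matrix::rowSums(ctx$MroiT[, chan_ids, drop = FALSE]))
}

ctx_objective <- function(ctx, S, D) {
  raw <- sum(ctx$gm[S, D])
  if (ctx$mode == "sensitivity_only") return(raw)
  nv <- ctx_nodevec(ctx, ctx_channels(ctx, S, D))
  raw / ctx$smax + ctx$cW * sum(nv > ctx$cthresh) / ctx$ntot
}

# minRhoOpt-feasible, useful, unoccupied positions given placed optodes
ctx_feasible <- function(ctx, placed) {
  ok <- ctx$useful
  if (length(placed)) {
    viol <- .colSums(ctx$sep[placed, , drop = FALSE] < ctx$minRhoOpt,
                     length(placed), ctx$npos) > 0
    ok <- ok & !viol
    ok[placed] <- FALSE
  }
  which(ok)
}

# uniform draw from the rcl_size best candidates; ties and ranking are
# stable by ascending position index
rcl_pick <- function(cand, score, rcl_size) {
  ord <- order(-score, cand)
  top <- cand[ord[seq_len(min(rcl_size, length(cand)))]]
  top[sample.int(length(top), 1L)]
}

# objective gain of adding one optode at each candidate position
add_gains <- function(ctx, cand, opposite, base_nodevec = NULL) {
  if (!length(opposite)) return(rep(0, length(cand)))
  sa <- colSums(ctx$gm[opposite, cand, drop = FALSE])
  if (ctx$mode == "sensitivity_only") return(sa)
  g <- sa / ctx$smax
  if (ctx$cW > 0) {
    base_cov <- sum(base_nodevec > ctx$cthresh)
    for (k in seq_along(cand)) {
      ids <- ctx$V[cand[k], opposite]
      ids <- ids[ids > 0L]
      if (length(ids)) {
        nv <- base_nodevec + ctx_nodevec(ctx, ids)
        g[k] <- g[k] + ctx$cW * (sum(nv > ctx$cthresh) - base_cov) / ctx$ntot
      }
    }
  }
  g
}

#' Greedy randomized construction of a feasible layout
#'
#' Seeds the array with a source-detector pair drawn from the restricted
#' candidate list of the five best-scoring viable pairs, then adds one
#' optode at a time (alternating source/detector while both pools have
#' remaining optodes), each drawn from the RCL of best-scoring feasible
#' positions under the active objective. The feasible set is pruned
#' after every placement by the minRho/minRhoOpt/maxRho rules.
#'
#' @param problem A `design_problem`.
#' @param mode `"sensitivity_only"` or `"combined"`.
#' @param config A `grasp_config` (its `rcl_size` is used).
#' @param ctx Internal evaluation context (rebuilt if omitted).
#' @return An `array_layout`, or `NULL` when construction fails (no
#'   feasible position remains before the counts are met).
#' @export
construct_layout <- function(problem, mode = "sensitivity_only",
                             config = grasp_config(), ctx = NULL) {
  if (is.null(ctx)) ctx <- make_ctx(problem, mode)
  rcl <- config$rcl_size
  pair_ok <- which(ctx$gm > 0 & upper.tri(ctx$gm), arr.ind = TRUE)
  if (!nrow(pair_ok)) return(NULL)
  pscore <- ctx$gm[pair_ok]
  if (ctx$mode == "combined") {
    cov_chan <- as.numeric(Matrix::colSums(ctx$MroiT > ctx$cthresh))
    pscore <- pscore / ctx$smax +
      ctx$cW * cov_chan[ctx$V[pair_ok]] / ctx$ntot
  }
  ord <- order(-pscore, pair_ok[, 1], pair_ok[, 2])
  top <- ord[seq_len(min(rcl, length(ord)))]
  pick <- pair_ok[top[sample.int(length(top), 1L)], ]
  S <- pick[[1]]; D <- pick[[2]]
  nv <- if (ctx$mode == "combined") {
    ctx_nodevec(ctx, ctx_channels(ctx, S, D))
  } else NULL
  next_role <- "S"
  while (length(S) < ctx$nS || length(D) < ctx$nD) {
    role <- if (length(S) < ctx$nS && (next_role == "S" ||
                                       length(D) >= ctx$nD)) "S" else "D"
    next_role <- if (role == "S") "D" else "S"
    cand <- ctx_feasible(ctx, c(S, D))
    if (!length(cand)) return(NULL)
    opp <- if (role == "S") D else S
    g <- add_gains(ctx, cand, opp, nv)
    p <- rcl_pick(cand, g, rcl)
    if (role == "S") S <- c(S, p) else D <- c(D, p)
    if (!is.null(nv)) {
      ids <- ctx$V[p, opp]; ids <- ids[ids > 0L]
      if (length(ids)) nv <- nv + ctx_nodevec(ctx, ids)
    }
  }
  array_layout(S, D)
}

#' 1-opt local search: single-optode relocation
#'
#' Repeatedly relocates one source or detector to the best feasible
#' position while all other optodes stay in place, as long as the move
#' strictly improves the active objective.
#'
#' @inheritParams construct_layout
#' @param layout A feasible `array_layout`.
#' @return A 1-opt locally optimal `array_layout`.
#' @export
local_search_1opt <- function(layout, problem, mode = "sensitivity_only",
                              ctx = NULL) {
  if (is.null(ctx)) ctx <- make_ctx(problem, mode)
  S <- layout$sources; D <- layout$detectors
  cur <- ctx_objective(ctx, S, D)
  repeat {
    best <- list(obj = cur)
    for (role in c("S", "D")) {
      set <- if (role == "S") S else D
      for (slot in seq_along(set)) {
        Sr <- S; Dr <- D
        if (role == "S") Sr <- Sr[-slot] else Dr <- Dr[-slot]
        cand <- ctx_feasible(ctx, c(Sr, Dr))
        opp <- if (role == "S") Dr else Sr
        nv <- if (ctx$mode == "combined") {
          ctx_nodevec(ctx, ctx_channels(ctx, Sr, Dr))
        } else NULL
        base <- if (ctx$mode == "combined") {
          sum(ctx$gm[Sr, Dr]) / ctx$smax +
            ctx$cW * sum(nv > ctx$cthresh) / ctx$ntot
        } else sum(ctx$gm[Sr, Dr])
        g <- base + add_gains(ctx, cand, opp, nv)
        if (length(cand)) {
          k <- which(g == max(g))[1]
          if (g[k] > best$obj + 1e-12) {
            best <- list(obj = g[k], role = role, slot = slot,
                         pos = cand[k])
          }
        }
      }
    }
    if (is.null(best$role)) break
    if (best$role == "S") S[best$slot] <- best$pos else
      D[best$slot] <- best$pos
    cur <- best$obj
  }
  array_layout(S, D)
}

# greedy rebuild of one optode class against a fixed opposite class
greedy_rebuild <- function(ctx, fixed, n_build) {
  built <- integer(0)
  for (k in seq_len(n_build)) {
    cand <- ctx_feasible(ctx, c(fixed, built))
    if (!length(cand)) return(NULL)
    g <- colSums(ctx$gm[fixed, cand, drop = FALSE])
    built <- c(built, cand[which(g == max(g))[1]])
  }
  built
}

#' Flip-float local search (sensitivity-only mode)
#'
#' For each candidate relocation of one source (detector), the full
#' detector (source) set is rebuilt greedily by descending marginal
#' sensitivity contribution under the distance constraints; the best
#' improving neighbour is adopted, iterated to local optimality.
#'
#' @inheritParams local_search_1opt
#' @return A locally optimal `array_layout`.
#' @export
local_search_flipfloat <- function(layout, problem, ctx = NULL) {
  if (is.null(ctx)) ctx <- make_ctx(problem, "sensitivity_only")
  if (ctx$mode != "sensitivity_only") {
    stop("flip-float applies to the sensitivity-only objective")
  }
  S <- layout$sources; D <- layout$detectors
  cur <- ctx_objective(ctx, S, D)
  repeat {
    best <- list(obj = cur)
    for (role in c("S", "D")) {
      set <- if (role == "S") S else D
      n_opp <- if (role == "S") ctx$nD else ctx$nS
      for (slot in seq_along(set)) {
        keep <- set[-slot]
        cand <- ctx_feasible(ctx, keep)
        for (p in cand) {
          fixed <- c(keep, p)
          rebuilt <- greedy_rebuild(ctx, fixed, n_opp)
          if (is.null(rebuilt)) next
          obj <- sum(ctx$gm[fixed, rebuilt])
          if (obj > best$obj + 1e-12) {
            best <- list(obj = obj, fixed = fixed, rebuilt = rebuilt,
                         role = role)
          }
        }
      }
    }
    if (is.null(best$role)) break
    if (best$role == "S") { S <- best$fixed; D <- best$rebuilt }
    else { D <- best$fixed; S <- best$rebuilt }
    cur <- best$obj
  }
  array_layout(S, D)
}

#' 2-opt local search (combined mode)
#'
#' Removes one source-detector pair and reinserts both optodes jointly
#' at the best feasible position pair. Small candidate sets are scanned
#' exhaustively; large ones over a marginal-gain shortlist per role
#' (always including the removed positions).
#'
#' @inheritParams local_search_1opt
#' @param config A `grasp_config` (shortlist size).
#' @return A locally optimal `array_layout`.
#' @export
local_search_2opt <- function(layout, problem, config = grasp_config(),
                              ctx = NULL) {
  if (is.null(ctx)) ctx <- make_ctx(problem, "combined")
  if (ctx$mode != "combined") stop("2-opt applies to the combined objective")
  S <- layout$sources; D <- layout$detectors
  cur <- ctx_objective(ctx, S, D)
  klim <- config$two_opt_shortlist
  repeat {
    best <- list(obj = cur)
    for (si in seq_along(S)) for (di in seq_along(D)) {
      Sr <- S[-si]; Dr <- D[-di]
      cand <- ctx_feasible(ctx, c(Sr, Dr))
      if (length(cand) < 2L) next
      shortlist <- function(opp) {
        if (length(cand) <= 2L * klim) return(cand)
        g <- if (length(opp)) {
          colSums(ctx$gm[opp, cand, drop = FALSE])
        } else rowSums(ctx$gm[cand, , drop = FALSE])
        sel <- cand[order(-g, cand)[seq_len(klim)]]
        unique(c(sel, intersect(c(S[si], D[di]), cand)))
      }
      cs <- shortlist(Dr); cd <- shortlist(Sr)
      nv_base <- ctx_nodevec(ctx, ctx_channels(ctx, Sr, Dr))
      raw_base <- sum(ctx$gm[Sr, Dr])
      for (ps in cs) {
        nv_s <- nv_base
        ids <- ctx$V[ps, Dr]; ids <- ids[ids > 0L]
        if (length(ids)) nv_s <- nv_s + ctx_nodevec(ctx, ids)
        raw_s <- raw_base + sum(ctx$gm[ps, Dr])
        for (pd in cd) {
          if (pd == ps) next
          if (ctx$sep[ps, pd] < ctx$minRhoOpt) next
          raw <- raw_s + sum(ctx$gm[c(Sr, ps), pd])
          obj_sa <- raw / ctx$smax
          ids2 <- ctx$V[c(Sr, ps), pd]; ids2 <- ids2[ids2 > 0L]
          nv <- if (length(ids2)) nv_s + ctx_nodevec(ctx, ids2) else nv_s
          obj <- obj_sa + ctx$cW * sum(nv > ctx$cthresh) / ctx$ntot
          if (obj > best$obj + 1e-12) {
            best <- list(obj = obj, si = si, di = di, ps = ps, pd = pd)
          }
        }
      }
    }
    if (is.null(best$si)) break
    S[best$si] <- best$ps; D[best$di] <- best$pd
    cur <- best$obj
  }
  array_layout(S, D)
}

#' Sensitivity-only GRASP phase: the normalisation Smax
#'
#' Runs the sensitivity-only GRASP (construction + 1-opt + flip-float
#' per restart) and returns the best total ROI sensitivity found, the
#' normalisation constant of the combined objective. Uses the current
#' RNG state; [solve_array()] seeds it.
#'
#' @inheritParams solve_array
#' @param t0 Start time for the wall-clock budget.
#' @return Smax in mm.
#' @export
phase1_smax <- function(problem, config = grasp_config(), t0 = Sys.time()) {
  ctx1 <- make_ctx(problem, "sensitivity_only")
  best1 <- -Inf
  for (r in seq_len(config$n_restarts)) {
    if (as.numeric(Sys.time() - t0, units = "secs") > config$time_budget &&
        r > 1L) break
    lay <- construct_layout(problem, config = config, ctx = ctx1)
    if (is.null(lay)) next
    lay <- local_search_1opt(lay, problem, ctx = ctx1)
    lay <- local_search_flipfloat(lay, problem, ctx = ctx1)
    obj <- ctx_objective(ctx1, lay$sources, lay$detectors)
    if (obj > best1) best1 <- obj
  }
  if (!is.finite(best1) || best1 <= 0) {
    stop("ROI is unreachable: no feasible array has positive sensitivity")
  }
  best1
}

#' Solve an array design problem with two-phase GRASP
#'
#' Phase 1 maximizes total ROI sensitivity (construction + 1-opt +
#' flip-float per restart); its best value becomes the normalisation
#' `Smax`. Phase 2 maximizes the combined objective `SA + cW * CA`
#' (construction + 1-opt + 2-opt per restart). Fully reproducible given
#' the seed.
#'
#' @param problem A `design_problem`.
#' @param config A `grasp_config`.
#' @param smax Optional precomputed `Smax` (skips phase 1).
#' @return A `solution`: `layout`, `objective`, `report`
#'   (a `quality_report`), `smax_used`, per-restart `trace`, `elapsed`
#'   seconds.
#' @export
solve_array <- function(problem, config = grasp_config(), smax = NULL) {
  t0 <- Sys.time()
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  if (is.null(smax)) smax <- phase1_smax(problem, config, t0)
  problem$smax <- smax

  ctx2 <- make_ctx(problem, "combined")
  best <- NULL; trace <- numeric(0)
  for (r in seq_len(config$n_restarts)) {
    if (as.numeric(Sys.time() - t0, units = "secs") > config$time_budget &&
        r > 1L) break
    lay <- construct_layout(problem, "combined", config, ctx = ctx2)
    if (is.null(lay)) { trace <- c(trace, NA_real_); next }
    lay <- local_search_1opt(lay, problem, "combined", ctx = ctx2)
    lay <- local_search_2opt(lay, problem, config, ctx = ctx2)
    obj <- ctx_objective(ctx2, lay$sources, lay$detectors)
    trace <- c(trace, obj)
    if (is.null(best) || obj > best$obj + 1e-12) {
      best <- list(lay = lay, obj = obj)
    }
  }
  if (is.null(best)) stop("GRASP could not construct any feasible layout")
  structure(list(layout = best$lay, objective = best$obj,
                 report = evaluate_layout(best$lay, problem),
                 smax_used = smax, trace = trace,
                 elapsed = as.numeric(Sys.time() - t0, units = "secs"),
                 config = config),
            class = "solution")
}

#' @export
print.solution <- function(x, ...) {
  cat(sprintf("solution: objective %.4f (Smax %.3f mm, %.1fs)\n",
              x$objective, x$smax_used, x$elapsed))
  print(x$report)
  invisible(x)
}

#' Exhaustive exact oracle for tiny instances
#'
#' Enumerates every feasible assignment of source and detector sets and
#' returns the global optimum under the identical evaluation contract.
#' Refuses instances whose enumeration size exceeds `cap`.
#'
#' @param problem A `design_problem`.
#' @param mode `"combined"` (requires `smax`) or `"sensitivity_only"`.
#' @param cap Maximum number of enumerated layouts (default 2e5).
#' @return A `solution` (with `trace` empty). For sensitivity-only mode
#'   the objective is the raw ROI sensitivity in mm.
#' @export
exhaustive_oracle <- function(problem, mode = c("combined",
                                                "sensitivity_only"),
                              cap = 2e5) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  ctx <- make_ctx(problem, mode)
  cand <- which(ctx$useful)
  n <- length(cand)
  if (n < problem$nS + problem$nD) stop("not enough useful positions")
  size <- choose(n, problem$nS) * choose(n - problem$nS, problem$nD)
  if (size > cap) {
    stop(sprintf("enumeration size %.3g exceeds cap %.3g; refusing", size,
                 cap))
  }
  s_sets <- utils::combn(cand, problem$nS)
  best <- NULL
  for (i in seq_len(ncol(s_sets))) {
    S <- s_sets[, i]
    if (length(S) > 1L) {
      ds <- ctx$sep[S, S]
      if (any(ds[upper.tri(ds)] < ctx$minRhoOpt)) next
    }
    rest <- setdiff(cand, S)
    d_sets <- utils::combn(rest, problem$nD)
    for (j in seq_len(ncol(d_sets))) {
      D <- d_sets[, j]
      opt <- c(S, D)
      dd <- ctx$sep[opt, opt]
      if (any(dd[upper.tri(dd)] < ctx$minRhoOpt)) next
      obj <- ctx_objective(ctx, S, D)
      if (is.null(best) || obj > best$obj + 1e-12) {
        best <- list(S = S, D = D, obj = obj)
      }
    }
  }
  if (is.null(best)) stop("no feasible layout exists")
  lay <- array_layout(best$S, best$D)
  report <- if (mode == "combined") evaluate_layout(lay, problem) else NULL
  structure(list(layout = lay, objective = best$obj, report = report,
                 smax_used = problem$smax, trace = numeric(0),
                 elapsed = as.numeric(Sys.time() - t0, units = "secs"),
                 config = NULL),
            class = "solution")
}

#' Manual single-distance baseline array
#'
#' Emulates the traditional hand-designed array: the ROI centre of mass
#' is projected to the nearest solution-space position; around it, an
#' alternating grid template (or a star template with central sources
#' when `nD >= 4 * nS`) with nearest-neighbour spacing `target_spacing`
#' is laid out in the local tangent plane and snapped to the nearest
#' unused positions.
#'
#' @param problem A `design_problem`.
#' @param target_spacing Nominal first-nearest-neighbour source-detector
#'   distance, mm (default 30).
#' @return An `array_layout`.
#' @export
manual_grid_array <- function(problem, target_spacing = 30) {
  pos <- as.matrix(problem$positions$positions[, c("x", "y", "z")])
  com <- colMeans(problem$roi$xyz)
  d2 <- rowSums((pos - matrix(com, nrow(pos), 3, byrow = TRUE))^2)
  center_idx <- which.min(d2)
  ctr <- pos[center_idx, ]
  head_ctr <- colMeans(pos)
  nrm <- unitv(ctr - head_ctr)
  e1 <- cross3(nrm, c(0, 0, 1))
  if (vnorm(e1) < 1e-6) e1 <- cross3(nrm, c(0, 1, 0))
  e1 <- unitv(e1); e2 <- cross3(nrm, e1)
  nS <- problem$nS; nD <- problem$nD
  n_tot <- nS + nD
  template <- if (nD >= 4 * nS) {
    # star: sources central, detectors ringed at the target spacing
    src_off <- if (nS == 1L) list(c(0, 0)) else {
      lapply(seq_len(nS) - 1L, function(k) {
        th <- 2 * pi * k / nS
        0.5 * target_spacing * c(cos(th), sin(th))
      })
    }
    det_off <- list()
    ring <- 1L
    while (length(det_off) < nD) {
      n_ring <- min(nD - length(det_off), 8L * ring)
      for (k in seq_len(n_ring) - 1L) {
        th <- 2 * pi * k / n_ring + (ring - 1) * pi / 8
        det_off[[length(det_off) + 1L]] <-
          ring * target_spacing * c(cos(th), sin(th))
      }
      ring <- ring + 1L
    }
    list(src = src_off, det = det_off)
  } else {
    # alternating grid, spiral order from the centre, checkerboard roles
    k <- ceiling(sqrt(n_tot))
    cells <- expand.grid(i = seq_len(k + 1L) - 1L, j = seq_len(k + 1L) - 1L)
    cells$i <- cells$i - floor(k / 2); cells$j <- cells$j - floor(k / 2)
    cells <- cells[order(cells$i^2 + cells$j^2, cells$i, cells$j), ]
    src_off <- list(); det_off <- list()
    for (r in seq_len(nrow(cells))) {
      if (length(src_off) >= nS && length(det_off) >= nD) break
      off <- target_spacing * c(cells$i[r], cells$j[r])
      to_src <- (cells$i[r] + cells$j[r]) %% 2 == 0
      if (to_src && length(src_off) < nS) {
        src_off[[length(src_off) + 1L]] <- off
      } else if (length(det_off) < nD) {
        det_off[[length(det_off) + 1L]] <- off
      } else {
        src_off[[length(src_off) + 1L]] <- off
      }
    }
    list(src = src_off, det = det_off)
  }
  used <- integer(0)
  snap <- function(off) {
    target <- ctr + off[1] * e1 + off[2] * e2
    dd <- rowSums((pos - matrix(target, nrow(pos), 3, byrow = TRUE))^2)
    dd[used] <- Inf
    idx <- which.min(dd)
    used <<- c(used, idx)
    idx
  }
  S <- vapply(template$src, snap, integer(1))
  D <- vapply(template$det, snap, integer(1))
  lay <- array_layout(S, D)
  if (!layout_feasible(lay, problem)) {
    stop("manual baseline cannot place all optodes under minRhoOpt")
  }
  lay
}
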