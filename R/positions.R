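# The 10-20 / 10-10 / 10-5 / 10-2.5 positioning systems. The labelled
# inventory (which contours carry which positions, and which pairs of
# 10-5 positions receive an interleaved 10-2.5 position halfway between
# them) is a fixed combinatorial blueprint of the package; position
# counts (345 for 10-5, 1092 for 10-2.5) are therefore properties of the
# blueprint and identical on every valid head.

MIDLINE_LABELS <- c("Nz", "NFpz", "Fpz", "AFpz", "AFz", "AFFz", "Fz",
                    "FFCz", "FCz", "FCCz", "Cz", "CCPz", "CPz", "CPPz",
                    "Pz", "PPOz", "POz", "POOz", "Oz", "OIz", "Iz")

ROW_PREFIXES <- c("AFp", "AF", "AFF", "F", "FFC", "FC", "FCC", "C",
                  "CCP", "CP", "CPP", "P", "PPO", "PO", "POO")

COL_CODES <- c("9", "9h", "7", "7h", "5", "5h", "3", "3h", "1", "1h",
               "z", "2h", "2", "4h", "4", "6h", "6", "8h", "8", "10h", "10")

# traditional temporal renaming of the central rows at lateral columns
TEMPORAL <- c(FFC = "FFT", FC = "FT", FCC = "FTT", C = "T",
              CCP = "TTP", CP = "TP", CPP = "TPP")

row_label <- function(prefix, col) {
  if (col == "z") return(paste0(prefix, "z"))
  lateral <- col %in% c("7", "7h", "9", "9h", "8", "8h", "10", "10h")
  if (lateral && prefix %in% names(TEMPORAL)) prefix <- TEMPORAL[[prefix]]
  paste0(prefix, col)
}

ur_lateral <- list(front = c("Fp1", "Fp1h", "Fp2", "Fp2h"),
                   back = c("O1", "O1h", "O2", "O2h"))
lr_lateral <- list(front = c("N1", "N1h", "N2", "N2h"),
                   back = c("I1", "I1h", "I2", "I2h"))
stub_labels <- list(nfp = c("NFp1h", "NFp1", "NFpz", "NFp2", "NFp2h"),
                    oi = c("OI1h", "OI1", "OIz", "OI2", "OI2h"))

ten20_labels <- function() {
  c("Fpz", "Oz", "Fp1", "Fp2", "O1", "O2",
    unlist(lapply(c("F", "C", "P"), function(p) {
      vapply(c("7", "3", "z", "4", "8"), function(cc) row_label(p, cc), "")
    })))
}

ten10_labels <- function() {
  rows10 <- c("AF", "F", "FC", "C", "CP", "P", "PO")
  cols10 <- c("9", "7", "5", "3", "1", "2", "4", "6", "8", "10")
  c(MIDLINE_LABELS[seq(1, 21, by = 2)],
    "Fp1", "Fp2", "O1", "O2", "N1", "N2", "I1", "I2",
    unlist(lapply(rows10, function(p) {
      vapply(cols10, function(cc) row_label(p, cc), "")
    })))
}

consec_pairs <- function(labs, cyclic = FALSE) {
  n <- length(labs)
  a <- labs[-n]; b <- labs[-1]
  if (cyclic) { a <- c(a, labs[n]); b <- c(b, labs[1]) }
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

uring_order <- function() {
  left7 <- vapply(ROW_PREFIXES, function(p) row_label(p, "7"), "")
  right8 <- vapply(ROW_PREFIXES, function(p) row_label(p, "8"), "")
  c("Fpz", "Fp1", "Fp1h", left7, "O1h", "O1", "Oz",
    "O2", "O2h", rev(right8), "Fp2h", "Fp2")
}

lring_order <- function() {
  left9 <- vapply(ROW_PREFIXES, function(p) row_label(p, "9"), "")
  right10 <- vapply(ROW_PREFIXES, function(p) row_label(p, "10"), "")
  c("Nz", "N1", "N1h", left9, "I1h", "I1", "Iz",
    "I2", "I2h", rev(right10), "N2h", "N2")
}

# The interleaving inventory: pairs of 10-5 positions between which the
# 10-2.5 refinement inserts one new position at the scalp arc midpoint.
# Contour-arc pairs, longitudinal (column) pairs, lateral connectors and
# cell-diagonal pairs; the nasion-adjacent midline segment carries no
# interleaved position (no optode can sit on the nasion notch).
interleave_pairs <- function() {
  out <- list()
  add <- function(d) out[[length(out) + 1L]] <<- d

  m <- consec_pairs(MIDLINE_LABELS)
  add(m[-1L, ])                                   # 19: skip Nz-NFpz
  add(consec_pairs(uring_order(), cyclic = TRUE)) # 40
  add(consec_pairs(lring_order(), cyclic = TRUE)) # 40
  for (p in ROW_PREFIXES) {                       # 300
    add(consec_pairs(vapply(COL_CODES, function(cc) row_label(p, cc), "")))
  }
  add(consec_pairs(stub_labels$nfp))              # 8
  add(consec_pairs(stub_labels$oi))

  line_cols <- c("1", "1h", "3", "3h", "5", "5h", "7h", "9h",
                 "2", "2h", "4", "4h", "6", "6h", "8h", "10h")
  for (cc in line_cols) {                         # 224
    add(consec_pairs(vapply(ROW_PREFIXES, function(p) row_label(p, cc), "")))
  }

  front_t <- c("1" = "Fp1", "1h" = "Fp1h", "3" = "NFp1", "3h" = "NFp1h",
               "5" = "N1", "5h" = "N1h", "7h" = "N1h", "9h" = "N1",
               "2" = "Fp2", "2h" = "Fp2h", "4" = "NFp2", "4h" = "NFp2h",
               "6" = "N2", "6h" = "N2h", "8h" = "N2h", "10h" = "N2")
  back_t <- c("1" = "O1", "1h" = "O1h", "3" = "OI1", "3h" = "OI1h",
              "5" = "I1", "5h" = "I1h", "7h" = "I1h", "9h" = "I1",
              "2" = "O2", "2h" = "O2h", "4" = "OI2", "4h" = "OI2h",
              "6" = "I2", "6h" = "I2h", "8h" = "I2h", "10h" = "I2")
  add(data.frame(a = vapply(line_cols, function(cc) row_label("AFp", cc), ""),
                 b = unname(front_t[line_cols])))  # 16
  add(data.frame(a = vapply(line_cols, function(cc) row_label("POO", cc), ""),
                 b = unname(back_t[line_cols])))   # 16

  add(data.frame(                                  # 8 stub connectors
    a = c("NFp1h", "NFp1h", "NFp2h", "NFp2h", "OI1h", "OI1h", "OI2h", "OI2h"),
    b = c("Fp1h", "N1h", "Fp2h", "N2h", "O1h", "I1h", "O2h", "I2h")))
  add(data.frame(                                  # 8 lateral verticals
    a = c("Fp1", "NFp1", "Fp2", "NFp2", "O1", "OI1", "O2", "OI2"),
    b = c("NFp1", "N1", "NFp2", "N2", "OI1", "I1", "OI2", "I2")))

  gaps <- list(c("1", "1h"), c("1h", "z"), c("z", "2h"), c("2h", "2"))
  for (i in seq_len(length(ROW_PREFIXES) - 1L)) {  # 56 paramedian cells
    up <- ROW_PREFIXES[i]; lo <- ROW_PREFIXES[i + 1L]
    for (g in gaps) {
      add(data.frame(a = row_label(up, g[1]), b = row_label(lo, g[2])))
    }
  }
  add(data.frame(                                  # 12 polar cells
    a = c("NFpz", "NFp1", "Nz", "NFpz", "NFp2", "Nz",
          "OIz", "OI1", "Iz", "OIz", "OI2", "Iz"),
    b = c("Fp1", "Fp1h", "NFp1", "Fp2", "Fp2h", "NFp2",
          "O1", "O1h", "OI1", "O2", "O2h", "OI2")))

  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

place_on_loop <- function(loop, origin, step, k, side_sign, ex) {
  n <- nrow(loop)
  closed <- rbind(loop, loop[1, ])
  total <- poly_cumlen(closed)[n + 1L]
  s0 <- poly_locate(closed, origin)$s
  probe <- poly_point_at(closed, ((s0 + step) %% total) / total)
  plus_is_side <- sign(sum((probe - origin) * ex))
  dirn <- if (plus_is_side == side_sign) 1 else -1
  poly_point_at(closed, ((s0 + dirn * k * step) %% total) / total)
}

#' Place a 10-20 family positioning system on the scalp
#'
#' @param contours A `head_contours` object from [build_contours()].
#' @param density One of `"10-20"`, `"10-10"`, `"10-5"`.
#' @return A `position_system`: positions (label, x, y, z), density and
#'   a record of the parent density. The 10-5 system has exactly 345
#'   positions; coarser systems are labelled subsets of it.
#' @export
place_system <- function(contours, density = c("10-5", "10-10", "10-20")) {
  density <- match.arg(density)
  lat <- ten5_lattice(contours)
  keep <- switch(density,
                 "10-5" = lat$label,
                 "10-10" = ten10_labels(),
                 "10-20" = ten20_labels())
  pos <- lat[match(keep, lat$label), c("label", "x", "y", "z")]
  rownames(pos) <- NULL
  structure(list(positions = pos, density = density,
                 parent = if (density == "10-5") "10-10" else NULL),
            class = "position_system")
}

#' @export
print.position_system <- function(x, ...) {
  cat(sprintf("position_system %s: %d positions\n",
              x$density, nrow(x$positions)))
  invisible(x)
}

# Full 10-5 lattice with labelled coordinates.
ten5_lattice <- function(ct) {
  scalp <- ct$scalp
  mid <- ct$midline
  res <- list()
  emit <- function(label, xyz) {
    res[[length(res) + 1L]] <<- data.frame(
      label = label, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }

  mid_pts <- arc_points(mid, seq(0, 1, by = 0.05))
  for (i in seq_len(21)) emit(MIDLINE_LABELS[i], mid_pts[i, ])

  # upper ring quarters, pinned at T7/T8; each quarter in 10 equal arcs
  ring_half <- function(arc, tpin, lat_front, lat_back, anchors) {
    st <- poly_locate(arc, tpin)$s / poly_length(arc)
    frs <- c(st * (1:9) / 10, st + (1 - st) * (1:9) / 10)
    labs <- c(lat_front[1], lat_front[2], anchors[1:7],
              anchors[8:14], lat_back[2], lat_back[1])
    for (k in seq_along(frs)) emit(labs[k], poly_point_at(arc, frs[k]))
  }
  left7 <- vapply(ROW_PREFIXES, function(p) row_label(p, "7"), "")
  right8 <- vapply(ROW_PREFIXES, function(p) row_label(p, "8"), "")
  ring_half(ct$uring_left, ct$t7, c("Fp1", "Fp1h"), c("O1", "O1h"),
            left7[-8])
  emit(row_label("C", "7"), ct$t7)
  ring_half(ct$uring_right, ct$t8, c("Fp2", "Fp2h"), c("O2", "O2h"),
            right8[-8])
  emit(row_label("C", "8"), ct$t8)

  # transverse rows
  got <- function(lab) {
    for (d in res) if (d$label == lab) return(c(d$x, d$y, d$z))
    stop("internal: missing lattice point ", lab)
  }
  levels <- seq(15, 85, by = 5)
  row_lo_left <- row_lo_right <- list()
  for (ri in seq_along(ROW_PREFIXES)) {
    p <- ROW_PREFIXES[ri]
    zpt <- mid_pts[levels[ri] / 5 + 1L, ]
    aL <- got(row_label(p, "7")); aR <- got(row_label(p, "8"))
    nrm <- cross3(zpt - aL, aR - aL)
    loop <- slice_mesh(scalp, zpt, nrm)
    crossL <- loop_plane_crossings(ct$lring_left, zpt, nrm)
    crossR <- loop_plane_crossings(ct$lring_right, zpt, nrm)
    pick <- function(cr, anchor) {
      if (is.null(cr)) stop("row contour does not reach the lower ring")
      d2 <- colSums((t(cr) - anchor)^2)
      cr[which.min(d2), ]
    }
    c9 <- pick(crossL, aL); c10 <- pick(crossR, aR)
    arc <- arc_between(loop, c9, c10, via = zpt)
    L <- poly_length(arc)
    s7 <- poly_locate(arc, aL)$s / L
    sz <- poly_locate(arc, zpt)$s / L
    s8 <- poly_locate(arc, aR)$s / L
    fr <- c(0, s7 / 2, s7,
            s7 + (sz - s7) * (1:7) / 8, sz,
            sz + (s8 - sz) * (1:7) / 8, s8,
            s8 + (1 - s8) / 2, 1)
    labs <- vapply(COL_CODES, function(cc) row_label(p, cc), "")
    for (k in seq_along(labs)) {
      if (labs[k] %in% c(row_label(p, "7"), row_label(p, "8"), paste0(p, "z")))
        next
      emit(labs[k], poly_point_at(arc, fr[k]))
    }
    row_lo_left[[ri]] <- poly_point_at(arc, 0)
    row_lo_right[[ri]] <- poly_point_at(arc, 1)
  }

  # lower-ring laterals by equal subdivision of the end sections
  lr_section <- function(arc, s_from, s_to, labs) {
    for (k in 1:2) {
      emit(labs[k], poly_point_at(arc, s_from + (s_to - s_from) * k / 3))
    }
  }
  Ll <- poly_length(ct$lring_left); Lr <- poly_length(ct$lring_right)
  sA9 <- poly_locate(ct$lring_left, row_lo_left[[1]])$s / Ll
  sP9 <- poly_locate(ct$lring_left, row_lo_left[[15]])$s / Ll
  lr_section(ct$lring_left, 0, sA9, c("N1", "N1h"))
  lr_section(ct$lring_left, 1, sP9, c("I1", "I1h"))
  sA10 <- poly_locate(ct$lring_right, row_lo_right[[1]])$s / Lr
  sP10 <- poly_locate(ct$lring_right, row_lo_right[[15]])$s / Lr
  lr_section(ct$lring_right, 0, sA10, c("N2", "N2h"))
  lr_section(ct$lring_right, 1, sP10, c("I2", "I2h"))

  # frontal / occipital stub contours, perpendicular to the midline
  step_u <- 0.025 * (poly_length(ct$uring_left) + poly_length(ct$uring_right))
  stub <- function(frac, labs_left, labs_right) {
    zpt <- poly_point_at(mid, frac)
    tang <- poly_point_at(mid, frac + 0.01) - poly_point_at(mid, frac - 0.01)
    loop <- slice_mesh(scalp, zpt, tang)
    for (k in 1:2) {
      emit(labs_left[k],
           place_on_loop(loop, zpt, step_u, k, -1, ct$frame$ex))
      emit(labs_right[k],
           place_on_loop(loop, zpt, step_u, k, +1, ct$frame$ex))
    }
  }
  stub(0.05, c("NFp1", "NFp1h"), c("NFp2", "NFp2h"))
  stub(0.95, c("OI1", "OI1h"), c("OI2", "OI2h"))

  lat <- do.call(rbind, res)
  rownames(lat) <- NULL
  if (anyDuplicated(lat$label)) stop("internal: duplicate lattice labels")
  lat
}

#' Refine a 10-5 system to the 10-2.5 system
#'
#' Inserts one new position at the scalp arc-length midpoint between each
#' pair of the fixed interleaving inventory (arc-adjacent positions along
#' each contour, longitudinal neighbours, and cell diagonals), yielding
#' 1092 positions. New labels join the parent labels with an `h` suffix.
#'
#' @param sys A `position_system` of density `"10-5"`.
#' @param contours The `head_contours` the system was placed on.
#' @return A `position_system` of density `"10-2.5"` with 1092 positions.
#' @export
refine_to_10_2_5 <- function(sys, contours) {
  if (!inherits(sys, "position_system") || sys$density != "10-5") {
    stop("refine_to_10_2_5 requires a 10-5 position_system")
  }
  pos <- sys$positions
  coords <- as.matrix(pos[, c("x", "y", "z")])
  rownames(coords) <- pos$label
  prs <- interleave_pairs()
  miss <- setdiff(unique(c(prs$a, prs$b)), pos$label)
  if (length(miss)) stop("internal: blueprint labels missing: ",
                         paste(miss, collapse = ", "))
  ctr <- contours$center
  mids <- matrix(NA_real_, nrow(prs), 3)
  for (i in seq_len(nrow(prs))) {
    mids[i, ] <- scalp_arc_midpoint(contours$scalp, ctr,
                                    coords[prs$a[i], ], coords[prs$b[i], ])
  }
  newpos <- data.frame(label = paste0(prs$a, "_", prs$b, "_h"),
                       x = mids[, 1], y = mids[, 2], z = mids[, 3],
                       stringsAsFactors = FALSE)
  out <- rbind(pos, newpos)
  rownames(out) <- NULL
  structure(list(positions = out, density = "10-2.5", parent = "10-5"),
            class = "position_system")
}

#' Pairwise straight-line distance table for a position system
#'
#' Inter-optode distance is the 3-D chord distance between scalp
#' positions (the standard fNIRS separation convention), not geodesic.
#'
#' @param sys A `position_system` (or a data frame with x, y, z).
#' @return A symmetric matrix of distances in mm.
#' @export
distance_table <- function(sys) {
  pos <- if (inherits(sys, "position_system")) sys$positions else sys
  if (nrow(pos) < 2L) stop("need at least two positions")
  d <- as.matrix(stats::dist(pos[, c("x", "y", "z")]))
  dimnames(d) <- list(pos$label, pos$label)
  d
}

#' Candidate channels within a separation cap
#'
#' @param dist Distance table from [distance_table()].
#' @param cap Maximum source-detector separation for a candidate channel
#'   (mm; default 60).
#' @return Data frame with columns `idx_a`, `idx_b`, `separation_mm`,
#'   each unordered pair listed once.
#' @export
candidate_channels <- function(dist, cap = 60) {
  stopifnot(cap > 0)
  ut <- upper.tri(dist)
  sel <- which(ut & dist <= cap, arr.ind = TRUE)
  data.frame(idx_a = sel[, 1], idx_b = sel[, 2],
             separation_mm = dist[sel])
}

#' Write / read a position system as TSV
#' @param sys A `position_system`.
#' @param path TSV path.
#' @return `path` (write) or a `position_system` (read).
#' @export
write_positions <- function(sys, path) {
  d <- sys$positions
  d$density <- sys$density
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  structure(list(positions = d[, c("label", "x", "y", "z")],
                 density = d$density[1], parent = NULL),
            class = "position_system")
}
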