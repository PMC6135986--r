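# Geodesic-style contour construction on the scalp mesh. Contours are
# realised as plane/mesh intersection polylines (planes through anchor
# points and/or the head centre), which on convex head surfaces follow
# the great-arc paths used by scalp positioning conventions. All
# subdivision is by arc length along the polylines.

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

# Right-handed head frame from fiducials: +x toward the right ear,
# +y toward the nasion, +z superior; origin midway between the ears.
head_frame <- function(lm) {
  p <- lm$points
  origin <- (p["left_preauricular", ] + p["right_preauricular", ]) / 2
  ex <- unitv(p["right_preauricular", ] - p["left_preauricular", ])
  ey0 <- p["nasion", ] - origin
  ey <- unitv(ey0 - sum(ey0 * ex) * ex)
  ez <- unitv(c(ex[2] * ey[3] - ex[3] * ey[2],
                ex[3] * ey[1] - ex[1] * ey[3],
                ex[1] * ey[2] - ex[2] * ey[1]))
  list(origin = origin, ex = ex, ey = ey, ez = ez)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Intersect a closed triangle mesh with the plane through p0 with normal n.
# Returns the intersection as an ordered closed polyline (matrix, rows =
# points; first row is not repeated). Picks the longest loop if the plane
# produces several.
slice_mesh <- function(mesh, p0, n) {
  n <- unitv(n)
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.numeric((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% n)
  # avoid exact-zero vertices for robust sign bookkeeping
  eps <- 1e-9 * max(abs(d), 1)
  d[d == 0] <- eps
  s <- d > 0
  sf <- cbind(s[f[, 1]], s[f[, 2]], s[f[, 3]])
  cut <- which(rowSums(sf) %in% c(1L, 2L))
  if (!length(cut)) stop("plane does not intersect the mesh")
  edge_pt <- function(i, j) {
    ti <- d[i] / (d[i] - d[j])
    v[i, , drop = FALSE] * (1 - ti) + v[j, , drop = FALSE] * ti
  }
  ekey <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  segs_a <- character(length(cut)); segs_b <- character(length(cut))
  pts <- new.env(parent = emptyenv())
  for (kk in seq_along(cut)) {
    tri <- f[cut[kk], ]
    ss <- s[tri]
    keys <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- tri[e[1]]; j <- tri[e[2]]
      if (s[i] != s[j]) {
        k <- ekey(i, j)
        if (is.null(pts[[k]])) assign(k, as.numeric(edge_pt(i, j)), envir = pts)
        keys <- c(keys, k)
      }
    }
    segs_a[kk] <- keys[1]; segs_b[kk] <- keys[2]
  }
  # chain segments into loops by shared cut-edge keys
  adj <- split(rep(seq_along(cut), 2), c(segs_a, segs_b))
  used <- rep(FALSE, length(cut))
  loops <- list()
  for (start in seq_along(cut)) {
    if (used[start]) next
    used[start] <- TRUE
    chain <- c(segs_a[start], segs_b[start])
    cur_seg <- start
    repeat {
      key <- chain[length(chain)]
      nxt <- setdiff(adj[[key]], cur_seg)
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      nx <- nxt[1]
      used[nx] <- TRUE
      nk <- if (segs_a[nx] == key) segs_b[nx] else segs_a[nx]
      chain <- c(chain, nk)
      cur_seg <- nx
    }
    if (chain[1] == chain[length(chain)]) chain <- chain[-length(chain)]
    loops[[length(loops) + 1L]] <- chain
  }
  loop_len <- vapply(loops, length, integer(1))
  keys <- loops[[which.max(loop_len)]]
  do.call(rbind, lapply(keys, function(k) pts[[k]]))
}

poly_cumlen <- function(p) {
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  c(0, cumsum(d))
}

poly_length <- function(p) {
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# Point at arc-length fraction t (0..1) along an open polyline.
poly_point_at <- function(p, t) {
  cl <- poly_cumlen(p)
  target <- t * cl[length(cl)]
  i <- findInterval(target, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(p) - 1L)
  seg <- cl[i + 1L] - cl[i]
  w <- if (seg > 0) (target - cl[i]) / seg else 0
  p[i, ] * (1 - w) + p[i + 1L, ] * w
}

# Parameter (arc length) of the nearest point of an open polyline to q.
poly_locate <- function(p, q) {
  a <- p[-nrow(p), , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  ab <- b - a
  qa <- matrix(q, nrow(a), 3, byrow = TRUE) - a
  tt <- rowSums(qa * ab) / pmax(rowSums(ab^2), 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  proj <- a + ab * tt
  d2 <- rowSums((proj - matrix(q, nrow(a), 3, byrow = TRUE))^2)
  i <- which.min(d2)
  cl <- poly_cumlen(p)
  list(s = cl[i] + tt[i] * (cl[i + 1L] - cl[i]),
       point = proj[i, ], dist = sqrt(d2[i]))
}

# Extract the arc of a CLOSED polyline (rows = points, not repeated)
# running from a to b. Of the two candidate arcs, returns the one passing
# closer to `via`; with via = NULL, the shorter one. Endpoints are snapped
# to a and b exactly.
arc_between <- function(loop, a, b, via = NULL) {
  n <- nrow(loop)
  closed <- rbind(loop, loop[1, ])
  cl <- poly_cumlen(closed)
  total <- cl[n + 1L]
  sa <- poly_locate(closed, a)$s
  sb <- poly_locate(closed, b)$s
  sample_arc <- function(s0, s1) {
    # walk forward from s0 to s1 (mod total)
    len <- (s1 - s0) %% total
    if (len == 0) len <- total
    ss <- sort(unique(c(0, cl[cl > 0 & cl < total])))
    inner <- ((ss - s0) %% total)
    keep <- ss[inner > 1e-9 & inner < len - 1e-9]
    ord <- order(((keep - s0) %% total))
    mids <- keep[ord]
    pts <- lapply(mids, function(s) poly_point_at(closed, s / total))
    rbind(a, do.call(rbind, c(pts, list(b * 1))))
  }
  arc1 <- sample_arc(sa, sb)
  arc2_rev <- sample_arc(sb, sa)
  arc2 <- arc2_rev[rev(seq_len(nrow(arc2_rev))), , drop = FALSE]
  # arc2 runs b..a reversed -> a..b? sample_arc(sb, sa) starts at b: reverse
  arc2[1, ] <- a; arc2[nrow(arc2), ] <- b
  if (is.null(via)) {
    if (poly_length(arc1) <= poly_length(arc2)) arc1 else arc2
  } else {
    d1 <- min(colSums((t(arc1) - via)^2))
    d2 <- min(colSums((t(arc2) - via)^2))
    if (d1 <= d2) arc1 else arc2
  }
}

# Points at arc-length fractions along an open polyline arc.
arc_points <- function(arc, fracs) {
  t(vapply(fracs, function(t) poly_point_at(arc, t), numeric(3)))
}

# Great-arc segment between two scalp points: slice through the head
# centre, shorter arc. The workhorse for interleaved-position insertion.
scalp_arc <- function(mesh, center, p, q) {
  nrm <- cross3(p - center, q - center)
  if (vnorm(nrm) < 1e-9) stop("degenerate arc: collinear with centre")
  loop <- slice_mesh(mesh, center, nrm)
  arc_between(loop, p, q, via = NULL)
}

scalp_arc_midpoint <- function(mesh, center, p, q) {
  poly_point_at(scalp_arc(mesh, center, p, q), 0.5)
}

# Signed-distance zero crossings of a closed polyline against a plane.
loop_plane_crossings <- function(loop, p0, n) {
  n <- unitv(n)
  closed <- rbind(loop, loop[1, ])
  d <- as.numeric((closed - matrix(p0, nrow(closed), 3, byrow = TRUE)) %*% n)
  out <- list()
  for (i in seq_len(nrow(closed) - 1L)) {
    if ((d[i] > 0) != (d[i + 1L] > 0)) {
      w <- d[i] / (d[i] - d[i + 1L])
      out[[length(out) + 1L]] <- closed[i, ] * (1 - w) + closed[i + 1L, ] * w
    }
  }
  do.call(rbind, out)
}

#' Build the standard contour inventory on a scalp mesh
#'
#' Constructs the landmark-anchored contours from which the 10-20 family
#' of positioning systems is placed: the midline sagittal contour from
#' nasion to inion, the central coronal contour between the preauricular
#' points, the upper circumferential ring through Fpz/T7/Oz/T8, the lower
#' ring through nasion, preauricular points and inion, fifteen transverse
#' contours at 5% sagittal levels, and the short frontal/occipital stub
#' contours. Contours are geodesic polylines along the mesh surface.
#'
#' @param scalp A scalp `surface_mesh` (closed).
#' @param lm A `landmarks` object; landmarks must lie on the mesh surface
#'   within `tol`.
#' @param tol On-surface tolerance for landmarks, mm (default 0.5).
#' @return An object of class `head_contours`.
#' @export
build_contours <- function(scalp, lm, tol = 0.5) {
  frame <- head_frame(lm)
  ctr <- frame$origin
  p <- lm$points
  for (nm in rownames(p)) {
    dd <- min(sqrt(rowSums((scalp$vertices -
                              matrix(p[nm, ], nrow(scalp$vertices), 3,
                                     byrow = TRUE))^2)))
    if (dd > max(tol, 0.05 * vnorm(p[nm, ] - ctr))) {
      stop("landmark off the scalp surface: ", nm)
    }
  }
  nas <- p["nasion", ]; ini <- p["inion", ]
  lpa <- p["left_preauricular", ]; rpa <- p["right_preauricular", ]
  rad <- max(sqrt(rowSums((scalp$vertices -
                             matrix(ctr, nrow(scalp$vertices), 3,
                                    byrow = TRUE))^2)))
  apex <- ctr + frame$ez * rad

  mid_loop <- slice_mesh(scalp, nas, cross3(ini - nas, apex - nas))
  midline <- arc_between(mid_loop, nas, ini, via = apex)
  cz <- poly_point_at(midline, 0.5)

  cor_loop <- slice_mesh(scalp, lpa, cross3(rpa - lpa, cz - lpa))
  coronal <- arc_between(cor_loop, lpa, rpa, via = cz)
  t7 <- poly_point_at(coronal, 0.10)
  t8 <- poly_point_at(coronal, 0.90)

  fpz <- poly_point_at(midline, 0.10)
  oz <- poly_point_at(midline, 0.90)

  ur_left <- arc_between(slice_mesh(scalp, fpz, cross3(t7 - fpz, oz - fpz)),
                         fpz, oz, via = t7)
  ur_right <- arc_between(slice_mesh(scalp, fpz, cross3(t8 - fpz, oz - fpz)),
                          fpz, oz, via = t8)
  lr_left <- arc_between(slice_mesh(scalp, nas, cross3(lpa - nas, ini - nas)),
                         nas, ini, via = lpa)
  lr_right <- arc_between(slice_mesh(scalp, nas, cross3(rpa - nas, ini - nas)),
                          nas, ini, via = rpa)

  structure(list(scalp = scalp, landmarks = lm, frame = frame,
                 center = ctr, apex = apex,
                 midline = midline, coronal = coronal,
                 uring_left = ur_left, uring_right = ur_right,
                 lring_left = lr_left, lring_right = lr_right,
                 cz = cz, t7 = t7, t8 = t8, fpz = fpz, oz = oz),
            class = "head_contours")
}

#' @export
print.head_contours <- function(x, ...) {
  cat(sprintf("head_contours: midline %.1f mm, coronal %.1f mm\n",
              poly_length(x$midline), poly_length(x$coronal)))
  invisible(x)
}
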