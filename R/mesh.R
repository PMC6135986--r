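# Surface meshes, mesh I/O, per-node volumes, and the synthetic head
# generator. All coordinates are millimetres by contract; units are never
# inferred from file contents.

#' Construct a triangulated surface mesh
#'
#' @param vertices Numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces Integer matrix, one row per triangle, 1-based vertex indices.
#' @param kind Either `"scalp"` or `"cortex"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, kind = c("scalp", "cortex")) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must be triangles (3 columns)")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face index out of range")
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, kind = kind),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh (%s): %d vertices, %d faces\n",
              x$kind, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines[nzchar(trimws(lines))]
}

#' Read a surface mesh from an ASCII OFF or PLY file
#'
#' @param path Path to the mesh file.
#' @param fmt File format, `"off"` or `"ply"`. Defaults to the file
#'   extension.
#' @param kind Passed to [surface_mesh()].
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path, fmt = c("auto", "off", "ply"),
                      kind = c("scalp", "cortex")) {
  fmt <- match.arg(fmt)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  off = "off", ply = "ply",
                  stop("cannot infer mesh format from extension: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (fmt == "off") read_off_lines(lines, kind) else read_ply_lines(lines, kind)
}

read_off_lines <- function(lines, kind) {
  lines <- strip_comments(lines)
  if (!length(lines) || toupper(trimws(lines[[1L]])) != "OFF") {
    stop("not an OFF file (missing OFF header)")
  }
  counts <- scan(text = lines[[2L]], quiet = TRUE)
  nv <- as.integer(counts[[1L]]); nf <- as.integer(counts[[2L]])
  body <- scan(text = lines[-(1:2)], quiet = TRUE)
  if (length(body) < 3L * nv) stop("truncated OFF vertex block")
  v <- matrix(body[seq_len(3L * nv)], ncol = 3L, byrow = TRUE)
  rest <- body[-seq_len(3L * nv)]
  f <- matrix(NA_integer_, nf, 3L)
  pos <- 1L
  for (i in seq_len(nf)) {
    k <- as.integer(rest[[pos]])
    if (k != 3L) stop("only triangular faces are supported")
    f[i, ] <- as.integer(rest[pos + 1:3]) + 1L
    pos <- pos + 1L + k
  }
  surface_mesh(v, f, kind)
}

read_ply_lines <- function(lines, kind) {
  if (!length(lines) || trimws(lines[[1L]]) != "ply") stop("not a PLY file")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr))) {
    stop("only ASCII PLY is supported")
  }
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", hdr, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) stop("PLY header lacks vertex/face elements")
  body <- strip_comments(lines[-seq_len(hdr_end)])
  if (length(body) < nv + nf) stop("truncated PLY body")
  v <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
              ncol = 3L, byrow = TRUE)[, 1:3, drop = FALSE]
  f <- t(vapply(body[nv + seq_len(nf)], function(ln) {
    xs <- scan(text = ln, quiet = TRUE)
    if (xs[[1L]] != 3) stop("only triangular faces are supported")
    as.integer(xs[2:4]) + 1L
  }, integer(3L), USE.NAMES = FALSE))
  surface_mesh(v, f, kind)
}

#' Write a surface mesh to an ASCII OFF or PLY file
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param fmt `"off"` or `"ply"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fmt = c("auto", "off", "ply")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  off = "off", ply = "ply",
                  stop("cannot infer mesh format from extension: ", path))
  }
  v <- mesh$vertices
  f <- mesh$faces - 1L
  vtxt <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
  ftxt <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  out <- if (fmt == "off") {
    c("OFF", sprintf("%d %d 0", nrow(v), nrow(f) + 0L), vtxt, ftxt)
  } else {
    c("ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(f) + 0L),
      "property list uchar int vertex_indices", "end_header", vtxt, ftxt)
  }
  writeLines(out, path)
  invisible(path)
}

#' Fiducial landmarks on a scalp mesh
#'
#' @param nasion,inion,left_preauricular,right_preauricular Numeric
#'   length-3 points (mm) on the scalp surface.
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(nasion, inion, left_preauricular, right_preauricular) {
  pts <- rbind(nasion = as.numeric(nasion), inion = as.numeric(inion),
               left_preauricular = as.numeric(left_preauricular),
               right_preauricular = as.numeric(right_preauricular))
  if (ncol(pts) != 3L || !all(is.finite(pts))) {
    stop("landmarks must be finite 3-D points")
  }
  if (any(dist(pts) < 1e-9)) stop("landmarks must be pairwise distinct")
  structure(list(points = pts), class = "landmarks")
}

#' Read landmarks from a 4-row TSV (name, x, y, z)
#' @param path TSV path.
#' @return A `landmarks` object.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("nasion", "inion", "left_preauricular", "right_preauricular")
  if (!all(need %in% d$name)) {
    stop("landmark file must contain rows: ", paste(need, collapse = ", "))
  }
  rownames(d) <- d$name
  landmarks(unlist(d["nasion", c("x", "y", "z")]),
            unlist(d["inion", c("x", "y", "z")]),
            unlist(d["left_preauricular", c("x", "y", "z")]),
            unlist(d["right_preauricular", c("x", "y", "z")]))
}

#' Write landmarks to TSV
#' @param lm A `landmarks` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  d <- data.frame(name = rownames(lm$points), lm$points,
                  row.names = NULL, check.names = FALSE)
  names(d) <- c("name", "x", "y", "z")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-node cortical volumes
#'
#' Assigns each cortical node one third of the area of its incident
#' triangles (the barycentric node area) times a nominal cortical
#' thickness. The median node volume is the normalisation used by the
#' coverage threshold.
#'
#' @param cortex A cortex `surface_mesh`.
#' @param thickness Nominal cortical thickness in mm (default 3).
#' @return An object of class `node_volumes` with fields `volumes`
#'   (mm^3 per node) and `vhat` (median, mm^3).
#' @export
node_volumes <- function(cortex, thickness = 3) {
  stopifnot(thickness > 0)
  ta <- triangle_areas(cortex)
  if (any(ta <= 0)) stop("degenerate (zero-area) faces in cortex mesh")
  node_area <- rep(0, nrow(cortex$vertices))
  third <- ta / 3
  for (j in 1:3) {
    acc <- tapply(third, cortex$faces[, j], sum)
    idx <- as.integer(names(acc))
    node_area[idx] <- node_area[idx] + as.numeric(acc)
  }
  if (any(node_area <= 0)) stop("mesh has unreferenced nodes")
  vols <- node_area * thickness
  structure(list(volumes = vols, vhat = stats::median(vols)),
            class = "node_volumes")
}

# Deterministic unit icosphere: repeated 4-to-1 subdivision of an
# icosahedron, vertices re-projected to the unit sphere each level.
icosphere <- function(subdiv = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
    mids <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      hit <- mids[[k]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      idx <- nv + length(newv)
      assign(k, idx, envir = mids)
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, faces = f)
}

# Smooth deterministic radial perturbation in [-1, 1] on the unit sphere,
# built from a fixed low-order harmonic basis with seed-derived weights.
gyral_field <- function(unit_xyz, freq, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  nterm <- 6L
  w <- stats::runif(nterm, 0.5, 1)
  ph <- stats::runif(3L * nterm, 0, 2 * pi)
  ax <- matrix(stats::rnorm(3L * nterm), nterm, 3L)
  ax <- ax / sqrt(rowSums(ax^2))
  g <- rep(0, nrow(unit_xyz))
  for (k in seq_len(nterm)) {
    u <- unit_xyz %*% ax[k, ]
    g <- g + w[k] * sin(freq * u * pi + ph[k])
  }
  g / sum(w)
}

#' Generate a deterministic synthetic head model
#'
#' Builds a closed ellipsoidal scalp and an interior cortex whose radius
#' is smoothly perturbed to emulate gyri and sulci, so regions of
#' interest contain both shallow and deep nodes. Landmarks are placed at
#' the anterior, posterior, left and right extremes of the scalp on its
#' horizontal mid-plane (+y anterior, +x right, +z superior).
#'
#' @param scalp_radii Semi-axes (x, y, z) of the scalp ellipsoid, mm.
#' @param cortex_radii Semi-axes of the nominal cortex ellipsoid, mm.
#' @param perturb_amp Peak radial gyral perturbation of the cortex, mm.
#' @param perturb_freq Angular frequency of the perturbation field.
#' @param scalp_subdiv,cortex_subdiv Icosphere subdivision levels.
#' @param seed Integer seed controlling the perturbation phases.
#' @return A list with elements `scalp`, `cortex` (both `surface_mesh`)
#'   and `landmarks`.
#' @export
synth_head <- function(scalp_radii = c(75, 95, 70),
                       cortex_radii = c(60, 78, 56),
                       perturb_amp = 3, perturb_freq = 6,
                       scalp_subdiv = 4L, cortex_subdiv = 4L,
                       seed = 1L) {
  stopifnot(length(scalp_radii) == 3L, length(cortex_radii) == 3L,
            perturb_amp >= 0)
  if (any(cortex_radii + perturb_amp >= scalp_radii)) {
    stop("cortex radii plus perturbation must be strictly inside the scalp")
  }
  s <- icosphere(scalp_subdiv)
  scalp <- surface_mesh(sweep(s$vertices, 2, scalp_radii, `*`), s$faces,
                        kind = "scalp")
  cc <- icosphere(cortex_subdiv)
  base <- sweep(cc$vertices, 2, cortex_radii, `*`)
  if (perturb_amp > 0) {
    g <- gyral_field(cc$vertices, perturb_freq, seed)
    scale <- 1 + perturb_amp * g / sqrt(rowSums(base^2))
    base <- base * matrix(scale, nrow(base), 3)
  }
  cortex <- surface_mesh(base, cc$faces, kind = "cortex")
  lm <- landmarks(nasion = c(0, scalp_radii[2], 0),
                  inion = c(0, -scalp_radii[2], 0),
                  left_preauricular = c(-scalp_radii[1], 0, 0),
                  right_preauricular = c(scalp_radii[1], 0, 0))
  list(scalp = scalp, cortex = cortex, landmarks = lm)
}
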