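#' @useDynLib mapeval, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Tissue geometry
# ---------------------------------------------------------------------------

#' Construct a tissue geometry object
#'
#' A `tissue_geometry` holds a triangulated tissue surface embedded in 3-D:
#' node coordinates in cm, triangular elements over node indices, the set of
#' nodes forming the mapped (endocardial) surface, and outward unit normals at
#' those nodes.  Desk-scale fixtures built by [build_sheet_geometry()] and
#' [build_shell_geometry()] are thin surfaces carrying a nominal wall
#' `thickness` so that volume integrals over the myocardium remain defined.
#'
#' @param nodes numeric matrix, n x 3, coordinates in cm.
#' @param elements integer matrix, m x 3, 1-based node indices per triangle.
#' @param surface_nodes integer vector of node indices on the mapped surface.
#' @param surface_normals numeric matrix, length(surface_nodes) x 3, outward
#'   unit normals.
#' @param thickness nominal wall thickness in cm used for volume integrals.
#' @return An object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(nodes, elements, surface_nodes, surface_normals,
                            thickness = 0.03) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elements) == 3)
  if (nrow(elements) > 0 &&
      (min(elements) < 1L || max(elements) > nrow(nodes)))
    stop("element indices out of range")
  surface_nodes <- as.integer(surface_nodes)
  if (length(surface_nodes) == 0) stop("surface_nodes must be non-empty")
  surface_normals <- as.matrix(surface_normals)
  if (nrow(surface_normals) != length(surface_nodes))
    stop("one normal per surface node required")
  nrm <- sqrt(rowSums(surface_normals^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("surface normals must be unit length")
  structure(list(nodes = nodes, elements = elements,
                 surface_nodes = surface_nodes,
                 surface_normals = surface_normals,
                 thickness = as.numeric(thickness)),
            class = "tissue_geometry")
}

#' @exportS3Method base::print
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("<tissue_geometry> %d nodes, %d triangles, %d surface nodes\n",
              nrow(x$nodes), nrow(x$elements), length(x$surface_nodes)))
  ext <- apply(x$nodes, 2, range)
  cat(sprintf("  extent [cm]: x %.3g..%.3g  y %.3g..%.3g  z %.3g..%.3g\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

#' Build a planar triangulated tissue sheet
#'
#' Builds an `nx` x `ny` rectangular grid of nodes in the z = 0 plane with
#' spacing `spacing` cm, triangulated by splitting each grid cell into two
#' triangles.  All nodes belong to the mapped surface; normals point along +z.
#' Used as the desk-scale stand-in for an atrial wall patch.
#'
#' @param nx,ny node counts along x and y (both >= 2).
#' @param spacing node spacing in cm (> 0).
#' @param thickness nominal wall thickness in cm.
#' @return A [tissue_geometry()].
#' @examples
#' g <- build_sheet_geometry(41, 41, 0.025)  # 1 cm x 1 cm patch
#' @export
build_sheet_geometry <- function(nx, ny, spacing, thickness = 0.03) {
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  if (spacing <= 0) stop("spacing must be positive")
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i  # i along x, j along y
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  # two CCW triangles per cell (normal +z)
  t1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  t2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  elements <- rbind(t1, t2)
  n <- nx * ny
  normals <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  tissue_geometry(nodes, elements, seq_len(n), normals, thickness)
}

#' Build a closed spherical tissue shell
#'
#' Builds a watertight triangulated sphere of the given radius by repeated
#' 4-way subdivision of an icosahedron with projection back onto the sphere.
#' All nodes are surface nodes; normals are radial (outward).  Used as the
#' desk-scale stand-in for a closed atrial chamber, e.g. for basket-catheter
#' placement and phase-singularity charge accounting.
#'
#' @param radius sphere radius in cm (> 0).
#' @param subdivisions number of subdivision passes (0 = raw icosahedron).
#' @param center sphere center, length-3 numeric, cm.
#' @param thickness nominal wall thickness in cm.
#' @return A [tissue_geometry()].
#' @export
build_shell_geometry <- function(radius, subdivisions = 3, center = c(0, 0, 0),
                                 thickness = 0.03) {
  if (radius <= 0) stop("radius must be positive")
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (pass in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    midmap <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(midmap[[k]])) return(midmap[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nrow(v) + length(newv)
      midmap[[k]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  nodes <- sweep(v * radius, 2, center, "+")
  normals <- v  # already unit, radial
  tissue_geometry(nodes, f, seq_len(nrow(nodes)), normals, thickness)
}

#' Check whether the surface triangulation is watertight
#'
#' A surface is watertight when every edge is shared by exactly two facets.
#'
#' @param geom a [tissue_geometry()].
#' @return Logical scalar.
#' @export
is_watertight <- function(geom) {
  e <- rbind(geom$elements[, 1:2], geom$elements[, 2:3], geom$elements[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Total surface area of the triangulation in cm^2
#' @param geom a [tissue_geometry()].
#' @return Numeric scalar.
#' @export
surface_area <- function(geom) {
  sum(triangle_areas(geom))
}

triangle_areas <- function(geom) {
  p1 <- geom$nodes[geom$elements[, 1], , drop = FALSE]
  p2 <- geom$nodes[geom$elements[, 2], , drop = FALSE]
  p3 <- geom$nodes[geom$elements[, 3], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mean_edge_length <- function(geom) {
  e <- rbind(geom$elements[, 1:2], geom$elements[, 2:3], geom$elements[, c(3, 1)])
  mean(sqrt(rowSums((geom$nodes[e[, 1], , drop = FALSE] -
                     geom$nodes[e[, 2], , drop = FALSE])^2)))
}

# nearest surface node (index into geom$nodes) for each query point;
# ties broken toward the lowest node index
nearest_surface_node <- function(geom, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sn <- geom$surface_nodes
  coords <- geom$nodes[sn, , drop = FALSE]
  out <- integer(nrow(points))
  for (k in seq_len(nrow(points))) {
    d2 <- (coords[, 1] - points[k, 1])^2 + (coords[, 2] - points[k, 2])^2 +
      (coords[, 3] - points[k, 3])^2
    out[k] <- sn[which.min(d2)]  # which.min takes the first (lowest index)
  }
  out
}

# ---------------------------------------------------------------------------
# Electrode arrays
# ---------------------------------------------------------------------------

#' Construct an electrode array object
#'
#' An `electrode_array` is a labeled set of point electrodes arranged on a
#' logical rows x cols grid (8 x 8 basket splines or a 6 x 6 uniform grid),
#' with, for each electrode having a full ring of 8 grid neighbors, the
#' ordered neighbor ring (north first, proceeding clockwise), plus its nearest
#' surface mesh node and the distance to that node.
#'
#' @param labels character vector of unique electrode labels.
#' @param positions numeric matrix, n x 3, electrode coordinates in cm.
#' @param grid_shape integer c(rows, cols).
#' @param wrap_cols logical; TRUE for basket arrays where the spline
#'   (column) direction is azimuthally periodic (column A neighbors column H).
#' @param nearest_node integer vector of nearest surface node per electrode.
#' @param contact_distance numeric vector of distances (cm) to those nodes.
#' @return An object of class `electrode_array`.
#' @export
electrode_array <- function(labels, positions, grid_shape, wrap_cols = FALSE,
                            nearest_node = NULL, contact_distance = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  grid_shape <- as.integer(grid_shape)
  if (length(labels) != prod(grid_shape))
    stop("label count must equal rows * cols")
  arr <- structure(list(labels = labels, positions = positions,
                        grid_shape = grid_shape, wrap_cols = isTRUE(wrap_cols),
                        nearest_node = nearest_node,
                        contact_distance = contact_distance),
                   class = "electrode_array")
  arr$adjacency <- grid_adjacency(arr)
  arr
}

#' @exportS3Method base::print
print.electrode_array <- function(x, ...) {
  n_int <- sum(!vapply(x$adjacency, is.null, logical(1)))
  cat(sprintf("<electrode_array> %d electrodes (%d x %d%s), %d with full 8-neighbor ring\n",
              length(x$labels), x$grid_shape[1], x$grid_shape[2],
              if (x$wrap_cols) ", wrapped columns" else "", n_int))
  invisible(x)
}

# Ordered ring of the 8 grid neighbors for every electrode, NULL where the
# ring is incomplete.  Electrodes are stored row-major: index = (row-1)*cols
# + col.  Ring order: N, NE, E, SE, S, SW, W, NW ("north" = row - 1, "east" =
# col + 1), i.e. clockwise when viewed from outside the tissue.
grid_adjacency <- function(arr) {
  rows <- arr$grid_shape[1]; cols <- arr$grid_shape[2]
  ring_off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  res <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    for (c3 in seq_len(cols)) {
      id <- (r - 1L) * cols + c3
      nb <- integer(8)
      ok <- TRUE
      for (k in 1:8) {
        rr <- r + ring_off[[k]][1]
        cc <- c3 + ring_off[[k]][2]
        if (arr$wrap_cols) cc <- ((cc - 1L) %% cols) + 1L
        if (rr < 1 || rr > rows || cc < 1 || cc > cols) { ok <- FALSE; break }
        nb[k] <- (rr - 1L) * cols + cc
      }
      if (ok) res[[id]] <- nb
    }
  }
  res
}

basket_sphere_points <- function(center, diameter) {
  # 8 splines at uniform azimuth, 8 electrodes per spline at uniform polar
  # angle excluding the exact poles
  radius <- diameter / 2
  pts <- matrix(0, 64, 3)
  labs <- character(64)
  splines <- LETTERS[1:8]
  for (r in 1:8) {          # electrode position along spline = grid row
    theta <- pi * r / 9     # polar angle, poles excluded
    for (s in 1:8) {        # spline = grid column
      phi <- 2 * pi * (s - 1) / 8
      id <- (r - 1L) * 8L + s
      pts[id, ] <- center + radius * c(sin(theta) * cos(phi),
                                       sin(theta) * sin(phi),
                                       cos(theta))
      labs[id] <- paste0(splines[s], r)
    }
  }
  list(points = pts, labels = labs)
}

#' Place a 64-electrode basket catheter array
#'
#' Samples 64 points on a basket sphere (8 splines x 8 electrodes, labeled
#' A1-H8), finds for each the nearest endocardial surface node, and places the
#' electrode on the segment from the sphere point to that node: 0.05 cm
#' (0.5 mm) from the surface node for good contact, or at the segment midpoint
#' for poor contact.
#'
#' @param geom a [tissue_geometry()].
#' @param center basket center, length-3 numeric, cm.
#' @param diameter basket diameter in cm (default 3.8 cm, i.e. 38 mm).
#' @param contact `"good"` or `"poor"`.
#' @return An [electrode_array()] with azimuthally wrapped columns.
#' @export
place_basket_array <- function(geom, center, diameter = 3.8,
                               contact = c("good", "poor")) {
  contact <- match.arg(contact)
  sp <- basket_sphere_points(center, diameter)
  nn <- nearest_surface_node(geom, sp$points)
  target <- geom$nodes[nn, , drop = FALSE]
  seg <- sp$points - target                     # node -> sphere point
  seg_len <- sqrt(rowSums(seg^2))
  bb <- apply(geom$nodes, 2, range)
  if (any(center < bb[1, ] - diameter) || any(center > bb[2, ] + diameter))
    warning("basket sphere lies outside the geometry's bounding region")
  if (contact == "good") {
    # 0.05 cm from the surface node toward the sphere point; degenerate
    # zero-length segments (sphere point on a node) stay at the node
    s <- ifelse(seg_len > 0, pmin(0.05 / pmax(seg_len, 1e-300), 1), 0)
    pos <- target + seg * s
  } else {
    pos <- target + seg * 0.5
  }
  cd <- sqrt(rowSums((pos - target)^2))
  electrode_array(sp$labels, pos, c(8L, 8L), wrap_cols = TRUE,
                  nearest_node = nn, contact_distance = cd)
}

#' Place a uniform high-resolution grid array
#'
#' Lays a rows x cols grid (default 6 x 6, 0.4 cm pitch, labels a1-f6) in the
#' tangent plane of the surface node nearest `center`, then moves every
#' electrode to `standoff` cm from its nearest surface node along that node's
#' outward normal.
#'
#' @param geom a [tissue_geometry()].
#' @param center array center, length-3 numeric, cm.
#' @param rows,cols grid dimensions.
#' @param pitch inter-electrode spacing in cm.
#' @param standoff distance from the surface in cm (default 0.05 cm = 0.5 mm).
#' @return An [electrode_array()] (no column wrap).
#' @export
place_uniform_array <- function(geom, center, rows = 6, cols = 6,
                                pitch = 0.4, standoff = 0.05) {
  stopifnot(rows >= 1, cols >= 1, pitch > 0, standoff >= 0)
  anchor_node <- nearest_surface_node(geom, matrix(center, 1))
  nrm <- geom$surface_normals[match(anchor_node, geom$surface_nodes), ]
  # tangent basis
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * nrm) * nrm; u <- u / sqrt(sum(u^2))
  w <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  letters_col <- letters[seq_len(cols)]
  pts <- matrix(0, rows * cols, 3)
  labs <- character(rows * cols)
  for (r in seq_len(rows)) {
    for (c3 in seq_len(cols)) {
      id <- (r - 1L) * cols + c3
      du <- (c3 - (cols + 1) / 2) * pitch
      dw <- (r - (rows + 1) / 2) * pitch
      pts[id, ] <- center + du * u + dw * w
      labs[id] <- paste0(letters_col[c3], r)
    }
  }
  nn <- nearest_surface_node(geom, pts)
  target <- geom$nodes[nn, , drop = FALSE]
  nrm_nn <- geom$surface_normals[match(nn, geom$surface_nodes), , drop = FALSE]
  pos <- target + standoff * nrm_nn
  cd <- sqrt(rowSums((pos - target)^2))
  electrode_array(labs, pos, c(as.integer(rows), as.integer(cols)),
                  wrap_cols = FALSE, nearest_node = nn, contact_distance = cd)
}

#' Electrode-to-surface projection diagnostics
#'
#' For each electrode: the distance to its nearest surface node, and the mean
#' Euclidean distance from that projected node to the projected nodes of its 8
#' grid neighbors.  The second quantity is undefined (NA) for electrodes
#' without a full 8-neighbor ring; these characterize how densely the array
#' samples the endocardium near each electrode.
#'
#' @param array an [electrode_array()] with `nearest_node` populated.
#' @param geom the [tissue_geometry()] the array was placed on.
#' @return A data.frame with columns `label`, `distance_to_surface` (cm) and
#'   `mean_neighbor_projection_distance` (cm, NA on the grid border).
#' @export
surface_projection_stats <- function(array, geom) {
  if (is.null(array$nearest_node)) stop("array has no nearest_node mapping")
  proj <- geom$nodes[array$nearest_node, , drop = FALSE]
  d_surf <- sqrt(rowSums((array$positions - proj)^2))
  n <- length(array$labels)
  mnpd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- array$adjacency[[i]]
    if (is.null(nb)) next
    dd <- sqrt(rowSums((proj[nb, , drop = FALSE] -
                        matrix(proj[i, ], 8, 3, byrow = TRUE))^2))
    mnpd[i] <- mean(dd)
  }
  data.frame(label = array$labels, distance_to_surface = d_surf,
             mean_neighbor_projection_distance = mnpd,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Mesh and electrode I/O
# ---------------------------------------------------------------------------

#' Write a tissue geometry as legacy ASCII VTK
#' @param geom a [tissue_geometry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(geom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tissue geometry (cm)", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(geom$nodes))), con)
  write.table(format(geom$nodes, digits = 17, scientific = FALSE,
                     trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  m <- nrow(geom$elements)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  write.table(cbind(3L, geom$elements - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(5L, m)), con)  # VTK_TRIANGLE
  invisible(path)
}

#' Read a legacy ASCII VTK triangle mesh
#' @param path file written by [write_mesh_vtk()] (or compatible).
#' @param thickness nominal wall thickness in cm attached to the result.
#' @return A [tissue_geometry()]; all nodes are taken as surface nodes and
#'   normals are recomputed from incident facets.
#' @export
read_mesh_vtk <- function(path, thickness = 0.03) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  vals <- scan(text = paste(lines[(ip + 1):length(lines)], collapse = "\n"),
               what = double(), n = 3 * np, quiet = TRUE)
  nodes <- matrix(vals, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  nc <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cvals <- scan(text = paste(lines[(ic + 1):length(lines)], collapse = "\n"),
                what = integer(), n = 4 * nc, quiet = TRUE)
  cm <- matrix(cvals, ncol = 4, byrow = TRUE)
  if (any(cm[, 1] != 3L)) stop("only triangle meshes are supported")
  elements <- cm[, 2:4, drop = FALSE] + 1L
  geom_from_triangles(nodes, elements, thickness)
}

# Build a tissue_geometry from raw triangles: all nodes surface, vertex
# normals = normalized area-weighted incident facet normals.
geom_from_triangles <- function(nodes, elements, thickness = 0.03) {
  n <- nrow(nodes)
  p1 <- nodes[elements[, 1], , drop = FALSE]
  p2 <- nodes[elements[, 2], , drop = FALSE]
  p3 <- nodes[elements[, 3], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  vn <- matrix(0, n, 3)
  for (k in 1:3) {
    for (d in 1:3) {
      vn[, d] <- vn[, d] + unname(tapply(
        rep(fn[, d], 1), elements[, k],
        sum)[as.character(seq_len(n))])
    }
  }
  vn[is.na(vn)] <- 0
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn <- vn / len
  # fallback for isolated nodes
  vn[rowSums(abs(vn)) == 0, 3] <- 1
  tissue_geometry(nodes, elements, seq_len(n), vn, thickness)
}

#' Write node/element plain-text tables
#'
#' Writes `<stem>.nodes` (`id,x,y,z` in cm) and `<stem>.elements`
#' (`id,n1,n2,n3`, 1-based node ids), each with a header line.
#'
#' @param geom a [tissue_geometry()].
#' @param stem path stem (without extension).
#' @return The two paths, invisibly.
#' @export
write_mesh_tables <- function(geom, stem) {
  nf <- paste0(stem, ".nodes"); ef <- paste0(stem, ".elements")
  nd <- data.frame(id = seq_len(nrow(geom$nodes)), x = geom$nodes[, 1],
                   y = geom$nodes[, 2], z = geom$nodes[, 3])
  write.csv(nd, nf, row.names = FALSE, quote = FALSE)
  el <- data.frame(id = seq_len(nrow(geom$elements)),
                   n1 = geom$elements[, 1], n2 = geom$elements[, 2],
                   n3 = geom$elements[, 3])
  write.csv(el, ef, row.names = FALSE, quote = FALSE)
  invisible(c(nf, ef))
}

#' Read node/element plain-text tables written by [write_mesh_tables()]
#' @param stem path stem (without extension).
#' @param thickness nominal wall thickness in cm.
#' @return A [tissue_geometry()].
#' @export
read_mesh_tables <- function(stem, thickness = 0.03) {
  nd <- read.csv(paste0(stem, ".nodes"))
  el <- read.csv(paste0(stem, ".elements"))
  geom_from_triangles(as.matrix(nd[, c("x", "y", "z")]),
                      as.matrix(el[, c("n1", "n2", "n3")]), thickness)
}

#' Write an electrode table (`label,x,y,z` in cm)
#' @param array an [electrode_array()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_electrode_table <- function(array, path) {
  df <- data.frame(label = array$labels, x = array$positions[, 1],
                   y = array$positions[, 2], z = array$positions[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an electrode table (`label,x,y,z` in cm)
#'
#' @param path CSV file with header `label,x,y,z`.
#' @param grid_shape integer c(rows, cols); defaults to a single row.
#' @param wrap_cols logical, azimuthal wrap for basket-style arrays.
#' @param geom optional [tissue_geometry()]; when given, nearest surface
#'   nodes and contact distances are computed.
#' @return An [electrode_array()].
#' @export
read_electrode_table <- function(path, grid_shape = NULL, wrap_cols = FALSE,
                                 geom = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(df)))
  pos <- as.matrix(df[, c("x", "y", "z")])
  if (is.null(grid_shape)) grid_shape <- c(1L, nrow(df))
  nn <- NULL; cd <- NULL
  if (!is.null(geom)) {
    nn <- nearest_surface_node(geom, pos)
    cd <- sqrt(rowSums((pos - geom$nodes[nn, , drop = FALSE])^2))
  }
  electrode_array(df$label, pos, grid_shape, wrap_cols, nn, cd)
}
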