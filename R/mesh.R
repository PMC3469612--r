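#' Triangle meshes and cortical surfaces
#'
#' A `tri_mesh` is a closed, orientable triangle mesh: a numeric `vertices`
#' matrix (one row per vertex, columns x/y/z, mm) and an integer `faces`
#' matrix (one row per triangle, 1-based vertex indices, counter-clockwise
#' when seen from outside).  A `cortical_surface` pairs a folded (pial-like)
#' mesh with a topologically identical unit-sphere mesh plus outward unit
#' normals, and carries a hemisphere label.  A `source_space` is an ordered
#' list of cortical surfaces (left, right); dipoles are indexed by
#' concatenating the hemisphere vertex lists in that order.
#'
#' @name mesh-classes
NULL

tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("faces index invalid vertices")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Undirected edge list (each edge once) of a tri_mesh.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic of a triangle mesh
#'
#' V - E + F; equals 2 for any closed mesh of genus 0 (all meshes generated
#' by this package).
#'
#' @param mesh a `tri_mesh`.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

# Base icosahedron with outward-oriented faces, vertices on the unit sphere.
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  # enforce outward orientation: (v2-v1) x (v3-v1) . centroid > 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    n <- crossprod3(b - a, c3 - a)
    if (sum(n * (a + b + c3)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  tri_mesh(v, f)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Geodesic icosphere
#'
#' Repeated 4-to-1 midpoint subdivision of the icosahedron, re-projected to
#' the unit sphere after every pass.  Level `n` has `10 * 4^n + 2` vertices
#' and `20 * 4^n` faces.  Midpoints are cached per undirected edge
#' (lexicographic keys) so vertex ordering is reproducible bit-for-bit.
#'
#' @param level non-negative integer subdivision level (at most 8).
#' @return a `tri_mesh` with unit-norm vertices.
#' @export
icosphere <- function(level) {
  if (length(level) != 1L || is.na(level) || level < 0 || level != round(level))
    stop("level must be a single non-negative integer")
  if (level > 8) stop("level > 8 refused (memory guard)")
  mesh <- icosahedron()
  for (i in seq_len(level)) mesh <- subdivide_mesh(mesh)
  mesh
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- mesh_edges(mesh)
  # midpoint index per undirected edge, appended in edge-list order
  key <- function(a, b) pmin(a, b) * (nrow(v) + 1) + pmax(a, b)
  mid_idx <- nrow(v) + seq_len(nrow(e))
  names(mid_idx) <- as.character(key(e[, 1], e[, 2]))
  mids <- (v[e[, 1], , drop = FALSE] + v[e[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  v2 <- rbind(v, mids)
  m12 <- mid_idx[as.character(key(f[, 1], f[, 2]))]
  m23 <- mid_idx[as.character(key(f[, 2], f[, 3]))]
  m31 <- mid_idx[as.character(key(f[, 3], f[, 1]))]
  f2 <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(m12, f[, 2], m23),
    cbind(m31, m23, f[, 3]),
    cbind(m12, m23, m31)
  )
  tri_mesh(v2, unname(f2))
}

# Vertex adjacency list from faces.
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  both <- rbind(e, e[, 2:1])
  sp <- split(both[, 2], both[, 1])
  adj[as.integer(names(sp))] <- sp
  adj
}

#' Cortical surface fixture and constructor
#'
#' Bundles a folded mesh, its unit-sphere mapping (identical face list) and
#' outward unit vertex normals of the folded geometry.
#'
#' @param hemisphere `"left"` or `"right"`.
#' @param folded `tri_mesh` in mm.
#' @param sphere `tri_mesh` with unit-norm vertices, same topology.
#' @param normals optional matrix of outward unit normals; computed from the
#'   folded mesh when omitted.
#' @return a `cortical_surface`.
#' @export
cortical_surface <- function(hemisphere, folded, sphere, normals = NULL) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  if (!identical(dim(folded$faces), dim(sphere$faces)) ||
      !all(folded$faces == sphere$faces))
    stop("folded and sphere meshes must share an identical face list")
  if (max(abs(sqrt(rowSums(sphere$vertices^2)) - 1)) > 1e-9)
    stop("sphere vertices must have unit norm")
  if (is.null(normals)) normals <- vertex_normals(folded)
  structure(list(hemisphere = hemisphere, folded = folded, sphere = sphere,
                 normals = normals),
            class = "cortical_surface")
}

#' @export
print.cortical_surface <- function(x, ...) {
  cat(sprintf("cortical_surface (%s): %d vertices, %d faces\n",
              x$hemisphere, nrow(x$folded$vertices), nrow(x$folded$faces)))
  invisible(x)
}

#' Outward unit vertex normals
#'
#' Area-weighted average of the incident face normals; relies on the
#' consistent outward face orientation of generated meshes.
#'
#' @param mesh a `tri_mesh`.
#' @return matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2*area-weighted
  n <- rowsum(rbind(fn, fn, fn), group = c(f[, 1], f[, 2], f[, 3]))
  full <- matrix(0, nrow(v), 3)
  full[as.integer(rownames(n)), ] <- n
  full / pmax(sqrt(rowSums(full^2)), .Machine$double.eps)
}

#' Total surface area of a triangle mesh
#'
#' @param mesh a `tri_mesh` (mm).
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Effective spherical radius of a folded surface
#'
#' `sqrt(area / 4 pi)`: the radius of the sphere with the same total area,
#' used to convert great-arc angles on the sphere mapping into pial-surface
#' millimetres.
#'
#' @param surface a `cortical_surface`.
#' @return radius in mm.
#' @export
effective_radius <- function(surface) {
  sqrt(mesh_area(surface$folded) / (4 * pi))
}

#' k-ring source patch
#'
#' Breadth-first vertex neighborhood of graph depth `k` around a center
#' vertex; `k = 0` is the single-dipole patch.  On a regular interior vertex
#' of an icosphere, `k = 3` gives the 1 + 6 + 12 + 18 = 37 dipole patch.
#'
#' @param surface a `cortical_surface`.
#' @param center vertex index (1-based).
#' @param k ring count, non-negative.
#' @param amplitudes optional per-vertex dipole moments; default 1 for every
#'   patch vertex (uniform outward currents).
#' @return a `source_patch`: hemisphere, center vertex, ordered vertex set
#'   (by BFS depth then index) and amplitudes.
#' @export
k_ring_patch <- function(surface, center, k, amplitudes = NULL) {
  n <- nrow(surface$sphere$vertices)
  if (length(center) != 1L || is.na(center) || center < 1 || center > n)
    stop("invalid center vertex")
  if (k < 0) stop("k must be non-negative")
  adj <- vertex_adjacency(surface$sphere)
  depth <- rep(NA_integer_, n)
  depth[center] <- 0L
  frontier <- center
  d <- 0L
  while (d < k && length(frontier)) {
    nxt <- setdiff(sort(unique(unlist(adj[frontier]))), which(!is.na(depth)))
    depth[nxt] <- d + 1L
    frontier <- nxt
    d <- d + 1L
  }
  verts <- order(depth, na.last = NA)
  if (is.null(amplitudes)) amplitudes <- rep(1, length(verts))
  if (length(amplitudes) != length(verts))
    stop("amplitudes must match patch size")
  structure(list(hemisphere = surface$hemisphere, center_vertex = center,
                 vertices = verts, amplitudes = amplitudes,
                 orientation = "normal-constrained"),
            class = "source_patch")
}

#' Great-arc distance on the sphere mapping
#'
#' Angle (radians) between two vertices of the same hemisphere's sphere mesh:
#' `acos` of the clipped dot product of the unit positions.
#'
#' @param surface a `cortical_surface`.
#' @param i,j vertex indices.
#' @return angle in radians (vectorized over `i`/`j`).
#' @export
great_arc_distance <- function(surface, i, j) {
  v <- surface$sphere$vertices
  n <- nrow(v)
  if (any(i < 1 | i > n) || any(j < 1 | j > n)) stop("vertex index out of range")
  d <- rowSums(v[i, , drop = FALSE] * v[j, , drop = FALSE])
  out <- acos(pmin(1, pmax(-1, d)))
  out[i == j] <- 0          # exact, not acos(1 - rounding)
  out
}

# Arc angles (radians) from a unit point to each vertex of the sphere mesh.
arc_to_point <- function(surface, point) {
  p <- point / sqrt(sum(point^2))
  acos(pmin(1, pmax(-1, as.vector(surface$sphere$vertices %*% p))))
}

#' Convert a spherical arc to folded-surface millimetres
#'
#' Multiplies the arc angle by the effective radius of the folded surface,
#' exact for spherical geometry and a deterministic global scaling otherwise.
#'
#' @param surface a `cortical_surface`.
#' @param arc angle(s) in radians, within `[0, pi]`.
#' @return distance(s) in mm.
#' @export
sphere_to_folded_mm <- function(surface, arc) {
  arc * effective_radius(surface)
}

#' Synthetic folded pseudo-cortex
#'
#' Generates a sphere-topology "cortex" standing in for a segmented pial
#' surface: an icosphere scaled to `radius` mm with a smooth band-limited
#' radial perturbation (a seeded sum of rotated zonal ripples of angular
#' degree `fold_frequency`) creating gyrus/sulcus-like ridges, offset left or
#' right of the midline.  The sphere mapping is the generating icosphere
#' itself, so the mapping is exact; outward normals come from the folded
#' geometry.  `fold_amplitude = 0` yields an exact sphere with radial normals.
#'
#' @param level icosphere subdivision level.
#' @param fold_amplitude peak radial perturbation, mm (default 8, the order
#'   of real sulcal depths).
#' @param fold_frequency angular degree of the ripples (default 8).
#' @param hemisphere `"left"` or `"right"`.
#' @param seed integer seed for the ripple axes/phases.
#' @param radius mean radius in mm (default 52; with the default midline
#'   offset and fold amplitude this keeps every vertex strictly inside an
#'   80 mm inner skull).
#' @param offset absolute midline offset in mm (default 18; applied with the
#'   sign of the hemisphere).
#' @return a `cortical_surface`.
#' @export
make_pseudo_cortex <- function(level, fold_amplitude = 8, fold_frequency = 8,
                               hemisphere = c("left", "right"), seed = 1,
                               radius = 52, offset = 18) {
  hemisphere <- match.arg(hemisphere)
  if (fold_amplitude < 0) stop("fold_amplitude must be non-negative")
  sphere <- icosphere(level)
  v <- sphere$vertices
  r <- rep(radius, nrow(v))
  if (fold_amplitude > 0) {
    rng <- local_rng(seed + ifelse(hemisphere == "left", 0L, 1L))
    f <- numeric(nrow(v))
    for (k in 1:4) {
      ax <- rng$norm(3)
      ax <- ax / sqrt(sum(ax^2))
      w <- rng$unif(1, 0.5, 1)
      ph <- rng$unif(1, 0, 2 * pi)
      gamma <- acos(pmin(1, pmax(-1, as.vector(v %*% ax))))
      f <- f + w * cos(fold_frequency * gamma + ph)
    }
    f <- f / max(abs(f))
    r <- radius + fold_amplitude * f
  }
  folded_v <- v * r
  folded_v[, 1] <- folded_v[, 1] + ifelse(hemisphere == "left", -offset, offset)
  folded <- tri_mesh(folded_v, sphere$faces)
  # an unfolded hemisphere is an exact sphere: use the analytic radial normals
  normals <- if (fold_amplitude == 0) v else NULL
  cortical_surface(hemisphere, folded, sphere, normals = normals)
}

# Self-contained RNG so fixture generation never disturbs (or depends on)
# the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  assign("state", NULL, envir = env)
  run <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    fn()
  }
  list(
    norm = function(n, sd = 1) run(function() rnorm(n, sd = sd)),
    unif = function(n, a = 0, b = 1) run(function() runif(n, a, b)),
    sample = function(x, size) run(function() sample(x, size))
  )
}

#' Two-hemisphere source space
#'
#' @param left,right `cortical_surface` objects for the two hemispheres.
#' @return a `source_space` (list of surfaces); dipole indices run over the
#'   left hemisphere's vertices first, then the right's.
#' @export
source_space <- function(left, right) {
  stopifnot(left$hemisphere == "left", right$hemisphere == "right")
  structure(list(left = left, right = right), class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d + %d dipoles (left + right)\n",
              nrow(x$left$folded$vertices), nrow(x$right$folded$vertices)))
  invisible(x)
}

# Number of dipoles in a source space or single surface.
n_sources <- function(space) {
  if (inherits(space, "cortical_surface")) return(nrow(space$folded$vertices))
  sum(vapply(space, function(s) nrow(s$folded$vertices), 0L))
}

# Hemisphere label per dipole (concatenated order).
hemi_labels <- function(space) {
  if (inherits(space, "cortical_surface"))
    return(rep(space$hemisphere, n_sources(space)))
  unlist(lapply(space, function(s) rep(s$hemisphere, nrow(s$folded$vertices))),
         use.names = FALSE)
}

# Global dipole indices of one hemisphere.
hemi_offset <- function(space, hemisphere) {
  if (inherits(space, "cortical_surface")) return(0L)
  if (hemisphere == "left") 0L else nrow(space$left$folded$vertices)
}

# All folded vertex coordinates of a source space, concatenated.
space_vertices <- function(space) {
  if (inherits(space, "cortical_surface")) return(space$folded$vertices)
  rbind(space$left$folded$vertices, space$right$folded$vertices)
}

space_normals <- function(space) {
  if (inherits(space, "cortical_surface")) return(space$normals)
  rbind(space$left$normals, space$right$normals)
}

#' Head center from sensor positions
#'
#' Algebraic least-squares fit of an axis-aligned ellipsoid
#' `A x^2 + B y^2 + C z^2 + D x + E y + F z = 1` to the sensor cloud; the
#' returned point is the ellipsoid center `(-D/2A, -E/2B, -F/2C)`.
#'
#' @param positions numeric matrix of sensor positions (rows, mm) or a
#'   `sensor_array`.
#' @return length-3 numeric center (mm).
#' @export
head_center <- function(positions) {
  if (inherits(positions, "sensor_array")) positions <- positions$positions
  positions <- as.matrix(positions)
  if (nrow(positions) < 9) stop("need at least 9 sensors for the ellipsoid fit")
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  M <- cbind(x^2, y^2, z^2, x, y, z)
  coef <- tryCatch(qr.solve(M, rep(1, nrow(M))),
                   error = function(e) stop("degenerate sensor configuration: ", conditionMessage(e)))
  if (any(abs(coef[1:3]) < 1e-12)) stop("degenerate sensor configuration (flat quadric)")
  c(-coef[4] / (2 * coef[1]), -coef[5] / (2 * coef[2]), -coef[6] / (2 * coef[3]))
}
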