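#' @useDynLib neurosculpt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_membrane_mesh <- function(ptr) {
  structure(list(ptr = ptr), class = "membrane_mesh")
}

check_mesh <- function(mesh) {
  if (!inherits(mesh, "membrane_mesh")) stop("not a membrane_mesh")
  mesh
}

#' Build a halfedge membrane mesh from a vertex/face list
#'
#' Constructs the halfedge representation used throughout the package. The
#' mesh must be consistently oriented; by default it must also be closed
#' (every edge shared by exactly two faces). Meshes carry reference
#' semantics: local operators modify the mesh in place, as is usual for
#' halfedge kernels.
#'
#' @param V numeric n x 3 matrix of vertex positions (micrometers).
#' @param F integer m x 3 matrix of 1-based triangle indices, counter-
#'   clockwise when viewed from outside.
#' @param allow_boundary permit unmatched (boundary) halfedges; local
#'   operators refuse to touch boundary edges.
#' @return A `membrane_mesh`.
#' @export
mesh_from_faces <- function(V, F, allow_boundary = FALSE) {
  new_membrane_mesh(he_build(as.matrix(V), as.matrix(F), allow_boundary))
}

#' Duplicate a membrane mesh
#' @param mesh a `membrane_mesh`.
#' @return An independent copy.
#' @export
mesh_clone <- function(mesh) {
  new_membrane_mesh(he_clone(check_mesh(mesh)$ptr))
}

#' @export
print.membrane_mesh <- function(x, ...) {
  ct <- he_counts(x$ptr)
  cat(sprintf(
    "<membrane_mesh> V=%d E=%d F=%d (chi=%d)\n",
    ct[["V"]], ct[["E"]], ct[["F"]], ct[["V"]] - ct[["E"]] + ct[["F"]]
  ))
  invisible(x)
}

#' Element counts of a mesh
#' @param mesh a `membrane_mesh`.
#' @return Named integer vector `V`, `E`, `F`.
#' @export
mesh_counts <- function(mesh) he_counts(check_mesh(mesh)$ptr)

#' Live vertex handles / positions / faces
#'
#' `mesh_vertices` returns the live vertex handles; `vertex_positions` their
#' coordinates; `mesh_faces` a compacted vertex/face list (live elements
#' renumbered 1..V, with `vmap` giving the original handle of each row).
#'
#' @param mesh a `membrane_mesh`.
#' @param vids vertex handles (defaults to all live vertices).
#' @return See details.
#' @export
mesh_vertices <- function(mesh) he_live_vertices(check_mesh(mesh)$ptr)

#' @rdname mesh_vertices
#' @export
vertex_positions <- function(mesh, vids = mesh_vertices(mesh)) {
  he_positions(check_mesh(mesh)$ptr, as.integer(vids))
}

#' @rdname mesh_vertices
#' @export
mesh_faces <- function(mesh) he_compact(check_mesh(mesh)$ptr)

#' Edge table of a mesh
#'
#' @param mesh a `membrane_mesh`.
#' @return data.frame with the canonical `edge` handle, endpoint vertex
#'   handles `v0`, `v1`, and the Euclidean `length` of each live edge.
#' @export
mesh_edges <- function(mesh) {
  as.data.frame(he_edges(check_mesh(mesh)$ptr))
}

#' Construct an icosphere
#'
#' Icosahedron subdivided `level` times (each triangle 1-to-4), with every
#' vertex projected onto the sphere. Subdivision level k has
#' `V = 10 * 4^k + 2` vertices. This is the initial soma mesh of the
#' progressive meshing pipeline.
#'
#' @param center 3-vector, sphere center.
#' @param radius sphere radius (> 0).
#' @param level subdivision level (>= 0).
#' @return A closed `membrane_mesh` with all vertices at exact distance
#'   `radius` from `center`.
#' @export
make_icosphere <- function(center = c(0, 0, 0), radius = 1, level = 1L) {
  stopifnot(radius > 0, level >= 0)
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  lvl <- as.integer(level)
  while (lvl > 0L) {
    lvl <- lvl - 1L
    nv <- nrow(V)
    ea <- pmin(F[, c(1, 2, 3)], F[, c(2, 3, 1)])
    eb <- pmax(F[, c(1, 2, 3)], F[, c(2, 3, 1)])
    ekey <- paste(ea, eb)
    uk <- unique(as.vector(ekey))
    mid_idx <- matrix(match(ekey, uk) + nv, ncol = 3)
    ua <- ea[match(uk, ekey)]
    ub <- eb[match(uk, ekey)]
    M <- (V[ua, , drop = FALSE] + V[ub, , drop = FALSE]) / 2
    V <- rbind(V, M)
    F <- rbind(
      cbind(F[, 1], mid_idx[, 1], mid_idx[, 3]),
      cbind(F[, 2], mid_idx[, 2], mid_idx[, 1]),
      cbind(F[, 3], mid_idx[, 3], mid_idx[, 2]),
      mid_idx
    )
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, as.numeric(center), `+`)
  mesh_from_faces(V, F)
}

#' Local mesh operators: split, collapse, flip
#'
#' In-place halfedge operators on a closed mesh. `split_edge` adds a vertex
#' on an edge (default at the midpoint) and splits the two incident faces,
#' changing (V, E, F) by (+1, +3, +2). `collapse_edge` moves both endpoints
#' of an edge to its midpoint and removes the edge, changing counts by
#' (-1, -3, -2); it is refused (returning `FALSE`, mesh untouched) when the
#' link condition fails or when a surviving incident triangle's normal would
#' reverse (the local surrogate for producing intersected triangles).
#' `flip_edge` rotates an edge inside its two triangles, leaving all counts
#' unchanged; it is refused when it would duplicate an existing edge. The
#' Euler characteristic is invariant under all three.
#'
#' @param mesh a `membrane_mesh`.
#' @param edge canonical edge handle (see [mesh_edges()]); stale handles
#'   raise an error.
#' @param position optional 3-vector for the new vertex (split only).
#' @return `split_edge`: the new vertex handle. `collapse_edge`: `TRUE` on
#'   success with attribute `vertex` (the surviving handle), `FALSE` on
#'   refusal. `flip_edge`: logical success flag.
#' @export
split_edge <- function(mesh, edge, position = NULL) {
  he_split_edge(check_mesh(mesh)$ptr, as.integer(edge), position)
}

#' @rdname split_edge
#' @export
collapse_edge <- function(mesh, edge) {
  v <- he_collapse_edge(check_mesh(mesh)$ptr, as.integer(edge))
  if (v < 0) return(FALSE)
  structure(TRUE, vertex = v)
}

#' @rdname split_edge
#' @export
flip_edge <- function(mesh, edge) {
  he_flip_edge(check_mesh(mesh)$ptr, as.integer(edge))
}

#' Find the edge connecting two vertices
#' @param mesh a `membrane_mesh`.
#' @param v0,v1 vertex handles.
#' @return Canonical edge handle, or `NA` if the vertices are not adjacent.
#' @export
edge_between <- function(mesh, v0, v1) {
  e <- he_edge_between(check_mesh(mesh)$ptr, as.integer(v0), as.integer(v1))
  if (e < 0) NA_integer_ else e
}

#' Endpoints of an edge
#' @param mesh a `membrane_mesh`.
#' @param edge canonical edge handle.
#' @return Integer vector of the two vertex handles.
#' @export
edge_vertices <- function(mesh, edge) {
  he_edge_verts(check_mesh(mesh)$ptr, as.integer(edge))
}

#' Ordered one-ring neighbourhood of a vertex
#'
#' Neighbour vertices in cyclic order consistent with the surface
#' orientation; the length equals the vertex valence.
#'
#' @param mesh a `membrane_mesh`.
#' @param vertex vertex handle.
#' @return Integer vector of neighbour vertex handles.
#' @export
one_ring <- function(mesh, vertex) {
  he_one_ring(check_mesh(mesh)$ptr, as.integer(vertex))
}

#' Topology checks
#'
#' `is_manifold`: every edge has exactly two incident faces and every
#' vertex's face fan is a single cycle. `is_watertight`: no boundary
#' halfedge. `audit_mesh` additionally verifies orientation coherence,
#' triangle face cycles and the Euler characteristic, and is cheap enough to
#' run after every deformation step.
#'
#' @param mesh a `membrane_mesh`.
#' @return Logical flag; `audit_mesh` returns a list with `structure_ok`,
#'   `manifold`, `watertight`, `euler` and a diagnostic `message`.
#' @export
is_manifold <- function(mesh) he_is_manifold(check_mesh(mesh)$ptr)

#' @rdname is_manifold
#' @export
is_watertight <- function(mesh) he_is_watertight(check_mesh(mesh)$ptr)

#' @rdname is_manifold
#' @export
audit_mesh <- function(mesh) he_audit(check_mesh(mesh)$ptr)

#' Vertex valences
#' @param mesh a `membrane_mesh`.
#' @param vids vertex handles (defaults to all live vertices).
#' @return Integer vector of valences.
#' @export
vertex_valence <- function(mesh, vids = mesh_vertices(mesh)) {
  he_valences(check_mesh(mesh)$ptr, as.integer(vids))
}

#' Mesh quality report
#'
#' Summary statistics of a membrane mesh: element counts, Euler
#' characteristic, edge-length range, valence histogram, the mean valence
#' computed as 2E/V (exactly `6 - 12/V` for a closed genus-0 triangle
#' mesh), the minimum triangle angle, and the manifold/watertight flags.
#'
#' @param mesh a `membrane_mesh`.
#' @return A list of class `quality_report`.
#' @export
quality_report <- function(mesh) {
  check_mesh(mesh)
  ct <- he_counts(mesh$ptr)
  ed <- mesh_edges(mesh)
  val <- vertex_valence(mesh)
  hist <- table(val)
  rep <- list(
    vertices = unname(ct[["V"]]),
    edges = unname(ct[["E"]]),
    faces = unname(ct[["F"]]),
    euler = unname(ct[["V"]] - ct[["E"]] + ct[["F"]]),
    min_edge = min(ed$length),
    max_edge = max(ed$length),
    mean_edge = mean(ed$length),
    mean_valence = 2 * ct[["E"]] / ct[["V"]],
    valence_histogram = stats::setNames(as.integer(hist), names(hist)),
    min_triangle_angle = he_min_triangle_angle(mesh$ptr),
    manifold = is_manifold(mesh),
    watertight = is_watertight(mesh)
  )
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<quality_report> V=%d E=%d F=%d chi=%d\n",
      "  edges [%.4g, %.4g] mean %.4g; mean valence %.4f; min angle %.2f deg\n",
      "  manifold=%s watertight=%s\n"
    ),
    x$vertices, x$edges, x$faces, x$euler,
    x$min_edge, x$max_edge, x$mean_edge, x$mean_valence,
    x$min_triangle_angle, x$manifold, x$watertight
  ))
  invisible(x)
}
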