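#' Skeleton-vertex mapping
#'
#' Every live mesh vertex is owned by exactly one skeleton node, mirroring
#' the list container attached to each node in the skeletal-mapping ROI
#' scheme: the per-node vertex collections partition the set of live
#' vertices. Ownership is stored on the mesh and is updated automatically
#' by the local operators (an edge split's new vertex adopts the owner of
#' the nearer parent endpoint; a collapse's surviving vertex keeps an
#' endpoint owner, ties broken toward the lower node id; flips never touch
#' vertices).
#'
#' `assign_vertex` (re)binds vertices to the endpoint node nearest to their
#' closest-point projection among the active segments, ties to the lower
#' node id. `vertex_owners` reads the current assignment; `node_vertices`
#' gives one node's collection; `map_audit` verifies the partition
#' invariant.
#'
#' @param mesh a `membrane_mesh`.
#' @param vids vertex handles (defaults to all live vertices).
#' @param active_segments a [segment_sources()] table (or subset) of the
#'   currently active skeleton segments.
#' @param node_id skeleton node id.
#' @return `assign_vertex`: integer owners, invisibly; `vertex_owners`:
#'   integer vector of node ids; `node_vertices`: integer vertex handles;
#'   `map_audit`: list with `ok` and the number of unassigned vertices.
#' @export
assign_vertex <- function(mesh, vids = mesh_vertices(mesh), active_segments) {
  check_mesh(mesh)
  seg <- as.data.frame(active_segments)
  if (nrow(seg) == 0L) stop("no active segments")
  m <- cbind(source_matrix(seg)[, 1:6, drop = FALSE], seg$node_a, seg$node_b)
  invisible(sv_assign(mesh$ptr, as.integer(vids), m))
}

#' @rdname assign_vertex
#' @export
vertex_owners <- function(mesh, vids = mesh_vertices(mesh)) {
  he_owners(check_mesh(mesh)$ptr, as.integer(vids))
}

#' @rdname assign_vertex
#' @export
node_vertices <- function(mesh, node_id) {
  v <- mesh_vertices(mesh)
  v[vertex_owners(mesh, v) == as.integer(node_id)]
}

#' @rdname assign_vertex
#' @export
map_audit <- function(mesh) {
  v <- mesh_vertices(mesh)
  own <- vertex_owners(mesh, v)
  unassigned <- sum(own == 0L)
  list(ok = unassigned == 0L, unassigned = unassigned)
}

#' ROI query through the skeletal mapping
#'
#' Returns the mesh vertices within Euclidean `radius` of a query position
#' (a skeleton node, or any point on the skeleton during growth). The
#' mapped route first gathers the vertex collections of the skeleton nodes
#' within `radius + slack` of the query -- `slack` bounds how far a vertex
#' can sit from its owning node, so the prefilter loses nothing -- and then
#' applies the exact distance filter. With `brute_force = TRUE` every live
#' vertex is scanned instead; both routes return the identical set, which
#' makes the brute-force mode a built-in correctness oracle.
#'
#' @param mesh a `membrane_mesh`.
#' @param tree a [neuron_tree()].
#' @param node_id query skeleton node id (alternative to `position`).
#' @param position explicit 3-vector query position.
#' @param radius ROI radius; defaults to the support radius `R_i` of the
#'   query node's incident segments (requires `sources`).
#' @param sources [segment_sources()] table used for the default radius and
#'   the slack bound.
#' @param active_ids optional node ids to restrict the prefilter to (the
#'   active skeleton during growth).
#' @param brute_force scan all vertices instead of using the mapping.
#' @return Sorted integer vector of vertex handles.
#' @export
roi_vertices <- function(mesh, tree, node_id = NULL, position = NULL,
                         radius = NULL, sources = NULL, active_ids = NULL,
                         brute_force = FALSE) {
  check_mesh(mesh)
  stopifnot(inherits(tree, "neuron_tree"))
  if (is.null(position)) {
    if (is.null(node_id)) stop("give either node_id or position")
    position <- as.numeric(node_position(tree, node_id))
  }
  if (is.null(radius)) {
    if (is.null(sources) || is.null(node_id)) {
      stop("radius defaults to the node's support radius and needs `sources` and `node_id`")
    }
    inc <- sources$node_a == node_id | sources$node_b == node_id
    if (!any(inc)) stop("node ", node_id, " has no incident segment source")
    radius <- max(sources$R[inc])
  }
  n <- tree$nodes
  if (!is.null(active_ids)) n <- n[n$id %in% active_ids, , drop = FALSE]
  slack <- roi_slack(tree, sources)
  sv_roi(mesh$ptr, as.numeric(position), radius,
         as.matrix(n[, c("x", "y", "z")]), as.integer(n$id),
         slack, brute_force)
}

# upper bound on the distance from any mesh vertex to its owning node:
# vertices lie within max(support radius, soma radius) of the skeleton and
# an owning endpoint is at most half a segment length from the projection
roi_slack <- function(tree, sources = NULL) {
  r_soma <- tree$nodes$radius[tree$root]
  rmax <- if (!is.null(sources) && nrow(sources)) max(sources$R) else 2 * max(tree$nodes$radius)
  seg_max <- 0
  non_root <- which(tree$nodes$parent != -1L)
  if (length(non_root)) {
    par <- match(tree$nodes$parent[non_root], tree$nodes$id)
    seg_max <- max(sqrt(rowSums((as.matrix(tree$nodes[non_root, c("x", "y", "z")]) -
                                   as.matrix(tree$nodes[par, c("x", "y", "z")]))^2)))
  }
  max(rmax, r_soma) + seg_max
}
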