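#' Separating point of a branch
#'
#' At a bifurcation the two daughter tubes stay blended near the branch
#' node and split apart at the separating position `t`: the point on the
#' bisector of the two child directions whose perpendicular distance to
#' each child axis equals the support radius `R`. Right-triangle geometry
#' places it at distance `R / sin(theta/2)` from the branch node, with the
#' projection feet on the child axes at distance `R / tan(theta/2)`. The
#' separating region is where the surface curvature peaks, so it receives
#' the maximum vertex density. Collinear children (theta = 180 degrees)
#' have no separating point.
#'
#' @param tree a [neuron_tree()].
#' @param branch_node_id node with at least two children.
#' @param R support radius at the branch, micrometers.
#' @return List with `position` (t), `projections` (one per child axis),
#'   `theta_deg`, `distance` (|t - b|), `offset` (projection distance along
#'   each axis), `child_a`, `child_b`; or `NULL` when degenerate. For nodes
#'   with more than two children, `separating_points()` enumerates all
#'   child pairs.
#' @export
separating_point <- function(tree, branch_node_id, R) {
  stopifnot(R > 0)
  r <- node_row(tree, branch_node_id)
  kids <- tree$children[[r]]
  if (length(kids) < 2L) stop("node ", branch_node_id, " has fewer than 2 children")
  b <- as.numeric(tree$nodes[r, c("x", "y", "z")])
  sep_pair <- function(k1, k2) {
    u1 <- as.numeric(tree$nodes[k1, c("x", "y", "z")]) - b
    u2 <- as.numeric(tree$nodes[k2, c("x", "y", "z")]) - b
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- u2 / sqrt(sum(u2^2))
    cth <- max(-1, min(1, sum(u1 * u2)))
    theta <- acos(cth)
    if (theta >= pi - 1e-9) return(NULL) # collinear: straight continuation
    half <- theta / 2
    bis <- u1 + u2
    bis <- bis / sqrt(sum(bis^2))
    list(
      position = b + (R / sin(half)) * bis,
      projections = rbind(b + (R / tan(half)) * u1, b + (R / tan(half)) * u2),
      theta_deg = theta * 180 / pi,
      distance = R / sin(half),
      offset = R / tan(half),
      child_a = tree$nodes$id[k1],
      child_b = tree$nodes$id[k2],
      R = R
    )
  }
  sep_pair(kids[[1L]], kids[[2L]])
}

#' Separating points for every branch of a tree
#'
#' Enumerates all child pairs of every branching node (multifurcations are
#' handled pairwise) and computes each pair's separating point with the
#' support radius of the sources incident to the branch.
#'
#' @param tree a [neuron_tree()].
#' @param sources a [segment_sources()] table.
#' @return List of separating-point records (see [separating_point()]).
#' @export
separating_points <- function(tree, sources) {
  out <- list()
  for (r in seq_along(tree$children)) {
    kids <- tree$children[[r]]
    if (length(kids) < 2L) next
    id <- tree$nodes$id[r]
    inc <- sources$node_a == id | sources$node_b == id
    R <- if (any(inc)) max(sources$R[inc]) else 2 * tree$nodes$radius[r]
    b <- as.numeric(tree$nodes[r, c("x", "y", "z")])
    pairs <- utils::combn(kids, 2L)
    for (j in seq_len(ncol(pairs))) {
      k1 <- pairs[1L, j]; k2 <- pairs[2L, j]
      u1 <- as.numeric(tree$nodes[k1, c("x", "y", "z")]) - b
      u2 <- as.numeric(tree$nodes[k2, c("x", "y", "z")]) - b
      u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
      cth <- max(-1, min(1, sum(u1 * u2)))
      theta <- acos(cth)
      if (theta >= pi - 1e-9) next
      half <- theta / 2
      bis <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
      out[[length(out) + 1L]] <- list(
        node_id = id,
        position = b + (R / sin(half)) * bis,
        theta_deg = theta * 180 / pi,
        R = R
      )
    }
  }
  out
}

#' Adaptive target-edge-length field
#'
#' Builds the spatially varying edge-length target that drives the
#' quasi-uniform remeshing. The local maximum edge length is
#' radius-proportional, `l_soma * r(x) / r_soma` (thin neurites get
#' proportionally denser vertices), where `l_soma` is the mean edge length
#' of the initial soma mesh and `r(x)` the radius interpolated along the
#' nearest skeleton segment. Within the interpolation radius `rho = R` of a
#' separating point the target blends linearly down to the separating
#' minimum `l_min = kappa * l_max(local)`, reaching it at the point itself.
#' All emitted targets lie in `[l_floor, l_soma]`; the field also carries
#' the global quasi-uniform band: `d = 0.5 * l_floor` (no produced edge may
#' be shorter) and `l_T = beta_split * l_soma` (none longer).
#'
#' @param tree a (preconditioned) [neuron_tree()].
#' @param sources a [segment_sources()] table for the tree.
#' @param l_soma soma-level base edge length, micrometers (mean edge of the
#'   initial icosphere).
#' @param kappa ratio of the separating-region minimum target to the local
#'   maximum, default 0.25.
#' @param beta_split split threshold ratio of the remesher, default 4/3;
#'   only used to report `l_T`.
#' @return An object of class `sizing_field`.
#' @export
sizing_field <- function(tree, sources, l_soma, kappa = 0.25, beta_split = 4 / 3) {
  stopifnot(inherits(tree, "neuron_tree"), l_soma > 0, kappa > 0, kappa <= 1)
  n <- tree$nodes
  soma_radius <- n$radius[tree$root]
  non_root <- which(n$parent != -1L)
  if (length(non_root)) {
    par <- match(n$parent[non_root], n$id)
    segs <- cbind(
      n$x[par], n$y[par], n$z[par],
      n$x[non_root], n$y[non_root], n$z[non_root],
      n$radius[par], n$radius[non_root]
    )
  } else {
    segs <- matrix(numeric(0), 0L, 8L)
  }
  r_min <- min(n$radius)
  l_floor <- kappa * l_soma * r_min / soma_radius
  l_floor <- min(l_floor, l_soma)

  base <- list(
    segments = segs,
    separating = matrix(numeric(0), 0L, 5L),
    l_soma = l_soma, soma_radius = soma_radius,
    l_floor = l_floor, l_cap = l_soma
  )
  seps <- separating_points(tree, sources)
  sep_m <- matrix(numeric(0), 0L, 5L)
  if (length(seps)) {
    pos <- do.call(rbind, lapply(seps, `[[`, "position"))
    lmax_local <- sz_local_max(base, pos)
    sep_m <- cbind(pos, pmax(l_floor, kappa * lmax_local),
                   vapply(seps, `[[`, 1.0, "R"))
  }
  structure(
    list(
      segments = segs, separating = sep_m,
      l_soma = l_soma, soma_radius = soma_radius,
      l_floor = l_floor, l_cap = l_soma,
      d = 0.5 * l_floor, l_T = beta_split * l_soma,
      kappa = kappa
    ),
    class = "sizing_field"
  )
}

#' @export
print.sizing_field <- function(x, ...) {
  cat(sprintf(
    "<sizing_field> l_soma=%.4g targets=[%.4g, %.4g] band=(%.4g, %.4g) %d separating point(s)\n",
    x$l_soma, x$l_floor, x$l_cap, x$d, x$l_T, nrow(x$separating)
  ))
  invisible(x)
}

check_sizing <- function(sizing) {
  if (!inherits(sizing, "sizing_field")) stop("not a sizing_field")
  sizing
}

#' Evaluate the sizing field
#'
#' `local_max_edge` is the radius-proportional local maximum target (no
#' separating-point influence); `target_edge_length` additionally applies
#' the linear blend toward the separating minima; `marching_step` is half
#' the target, the arc-length increment used by the growth front so that
#' deformation never outruns the local edge budget.
#'
#' @param sizing a [sizing_field()].
#' @param position n x 3 matrix or 3-vector.
#' @return Numeric vector of lengths (micrometers).
#' @export
target_edge_length <- function(sizing, position) {
  sz_target(unclass(check_sizing(sizing)), rbind3(position))
}

#' @rdname target_edge_length
#' @export
local_max_edge <- function(sizing, position) {
  sz_local_max(unclass(check_sizing(sizing)), rbind3(position))
}

#' @rdname target_edge_length
#' @export
marching_step <- function(sizing, position) {
  0.5 * target_edge_length(sizing, position)
}
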