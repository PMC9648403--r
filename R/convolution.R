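#' Finite-support quartic kernel
#'
#' The fourth-degree polynomial kernel `(1 - r^2/R^2)^2` for `r <= R` and 0
#' beyond the effective radius `R`. The kernel is continuous at `r = R`,
#' which limits every skeleton segment's influence to a capsule of radius
#' `R` around it.
#'
#' @param r distance(s) from the evaluation point to a skeleton point,
#'   micrometers; must be non-negative.
#' @param R effective (support) radius, micrometers, > 0.
#' @return Kernel value(s) in `[0, 1]`.
#' @export
quartic_kernel <- function(r, R) {
  if (any(r < 0)) stop("r must be non-negative")
  if (any(R <= 0)) stop("R must be positive")
  ifelse(r > R, 0, (1 - r^2 / R^2)^2)
}

#' Analytic segment weight
#'
#' Weight `lambda = 15 * T * R^4 / (16 * (R^2 - d^2)^(5/2))` that makes the
#' infinite-line convolution field of the quartic kernel equal the
#' iso-value `T` at perpendicular distance `d` from the axis. This pins the
#' iso-surface of a long straight segment to the neurite radius `d`.
#'
#' @param d_i target surface offset (neurite radius), micrometers;
#'   `0 <= d_i < R_i`.
#' @param R_i kernel support radius, micrometers.
#' @param iso iso-value `T` (> 0 for a surface; the weight is linear in it).
#' @return Weight(s) `lambda_i`.
#' @export
lambda_weight <- function(d_i, R_i, iso = 1) {
  if (any(d_i < 0)) stop("d_i must be non-negative")
  if (any(d_i >= R_i)) stop("weight undefined for d_i >= R_i")
  15 * iso * R_i^4 / (16 * (R_i^2 - d_i^2)^(5 / 2))
}

#' Closed-form infinite-line field
#'
#' Potential of an infinitely long straight segment with quartic kernel at
#' perpendicular distance `x` from the axis:
#' `16 * lambda * (R^2 - x^2)^(5/2) / (15 * R^4)` for `x <= R`, else 0.
#' With `lambda` from [lambda_weight()], the field equals the iso-value
#' exactly at `x = d`. This closed form is the oracle against which the
#' finite-segment quadrature is validated.
#'
#' @param x perpendicular distance(s) from the axis, micrometers, >= 0.
#' @param lambda segment weight.
#' @param R kernel support radius.
#' @return Field value(s).
#' @export
line_field_closed_form <- function(x, lambda, R) {
  ifelse(x > R, 0, 16 * lambda * (R^2 - x^2)^(5 / 2) / (15 * R^4))
}

#' Convolution sources for a neuronal tree
#'
#' One convolution source per skeleton segment (parent-child pair): target
#' offset `d_i` = mean of the two endpoint radii, support radius
#' `R_i = kernel_mult * d_i`, weight from [lambda_weight()]. The resulting
#' summed field's `iso` level set passes at distance `d_i` from long
#' straight runs and blends smoothly at branches.
#'
#' @param tree a [neuron_tree()].
#' @param iso global iso-value (default 1; a free scale absorbed by the
#'   weights).
#' @param kernel_mult support radius as a multiple of `d_i` (default 2).
#' @return data.frame of class `segment_sources` with endpoint coordinates
#'   (`ax`..`bz`), `d`, `R`, `lambda`, and the endpoint node ids
#'   `node_a`, `node_b`.
#' @export
segment_sources <- function(tree, iso = 1, kernel_mult = 2) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (kernel_mult <= 1) stop("kernel_mult must exceed 1 (need d < R)")
  n <- tree$nodes
  child <- which(n$parent != -1L)
  if (!length(child)) {
    out <- data.frame(
      ax = numeric(0), ay = numeric(0), az = numeric(0),
      bx = numeric(0), by = numeric(0), bz = numeric(0),
      d = numeric(0), R = numeric(0), lambda = numeric(0),
      node_a = integer(0), node_b = integer(0)
    )
    class(out) <- c("segment_sources", class(out))
    return(out)
  }
  par <- match(n$parent[child], n$id)
  d <- (n$radius[child] + n$radius[par]) / 2
  R <- kernel_mult * d
  out <- data.frame(
    ax = n$x[par], ay = n$y[par], az = n$z[par],
    bx = n$x[child], by = n$y[child], bz = n$z[child],
    d = d, R = R, lambda = lambda_weight(d, R, iso),
    node_a = n$id[par], node_b = n$id[child]
  )
  class(out) <- c("segment_sources", class(out))
  out
}

source_matrix <- function(sources) {
  as.matrix(as.data.frame(sources)[, c("ax", "ay", "az", "bx", "by", "bz",
                                       "d", "R", "lambda")])
}

#' Convolution field evaluation
#'
#' `segment_potential` integrates the quartic kernel along one segment by
#' 16-point Gauss-Legendre quadrature (segments longer than their support
#' radius are internally subdivided so every piece resolves the narrow
#' kernel support); it is exactly 0 outside the segment's support capsule.
#' `field_value` sums the potentials of all sources whose capsule contains
#' the point, using a uniform spatial grid for culling (`brute = TRUE`
#' forces the plain full sum; both give identical values).
#' `field_gradient` uses central finite differences with step
#' `1e-4 * min(d_i)` and is identically zero outside every support capsule.
#'
#' @param points n x 3 matrix (or 3-vector) of evaluation positions.
#' @param source,sources one row of / a full [segment_sources()] table.
#' @param brute disable the culling grid (oracle mode).
#' @param h finite-difference step; default `1e-4 * min(d_i)`.
#' @return Numeric vector of field values, or n x 3 gradient matrix.
#' @export
segment_potential <- function(points, source) {
  P <- rbind3(points)
  fld_value(P, source_matrix(source[1, , drop = FALSE]), TRUE)
}

#' @rdname segment_potential
#' @export
field_value <- function(points, sources, brute = FALSE) {
  fld_value(rbind3(points), source_matrix(sources), brute)
}

#' @rdname segment_potential
#' @export
field_gradient <- function(points, sources, h = -1, brute = FALSE) {
  fld_gradient(rbind3(points), source_matrix(sources), h, brute)
}

rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

#' Project points onto the convolution iso-surface
#'
#' Safeguarded descent to the level set `F = iso`: each iterate moves by
#' `l_step` along the unit gradient, with the sign chosen so that
#' `|F - iso|` decreases, the step halved whenever `F - iso` changes sign
#' (bisection safeguard) or a trial fails to improve. Points where the
#' gradient vanishes (outside all support capsules) are returned unchanged
#' and flagged as non-converged; points already on the surface return with
#' zero iterations.
#'
#' @param points n x 3 matrix (or 3-vector) of starting positions.
#' @param sources a [segment_sources()] table.
#' @param l_step initial step length per point (recycled); typically half
#'   the shortest mesh edge incident to the vertex being projected.
#' @param iso iso-value `T`.
#' @param tol convergence tolerance on `|F - iso|` (default `1e-4 * iso`).
#' @param max_iter maximum iterations (default 30).
#' @return List with `position` (n x 3), logical `converged`, and
#'   `iterations` per point.
#' @export
project_vertex <- function(points, sources, l_step, iso = 1,
                           tol = 1e-4 * iso, max_iter = 30L) {
  P <- rbind3(points)
  ls <- rep_len(as.numeric(l_step), nrow(P))
  fld_project(P, source_matrix(sources), ls, iso, tol, as.integer(max_iter))
}
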