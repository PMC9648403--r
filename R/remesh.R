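#' Remeshing configuration
#'
#' Parameters of the quasi-uniform incremental remesher. Edges longer than
#' `beta` times the local target are split at their midpoint; edges shorter
#' than `alpha` times the target are collapsed (when legal and when the
#' collapse would not create an over-long edge); the classical 4/5 and 4/3
#' ratios keep the two operations from fighting. `lambda_damp` is the
#' damping factor of the tangential relaxation move; re-projection after
#' every pass already suppresses oscillation, so it defaults to 1.
#'
#' @param alpha collapse ratio, in (0, 1).
#' @param beta split ratio, > 1.
#' @param lambda_damp damping of the tangent-plane move, in (0, 1].
#' @param iterations remeshing iterations per region pass.
#' @return A list of class `remesh_config`.
#' @export
remesh_config <- function(alpha = 4 / 5, beta = 4 / 3, lambda_damp = 1,
                          iterations = 3L) {
  stopifnot(alpha > 0, alpha < 1, beta > 1, lambda_damp > 0, lambda_damp <= 1,
            iterations >= 1)
  structure(
    list(alpha = alpha, beta = beta, lambda_damp = lambda_damp,
         iterations = as.integer(iterations)),
    class = "remesh_config"
  )
}

#' Quasi-uniform remeshing of a vertex region
#'
#' One call runs, `iterations` times over the region: split long edges
#' (queue-driven, new edges re-enqueued), collapse short edges, equalize
#' vertex valences by edge flips (a flip is applied only when it strictly
#' decreases the summed squared deviation from valence 6 of the four
#' affected vertices), area-weighted tangential relaxation (Jacobi snapshot
#' of positions), and re-projection of the region onto the convolution
#' iso-surface. New vertices created by splits join the region; all edits
#' keep the mesh closed and preserve the Euler characteristic.
#'
#' @param mesh a `membrane_mesh`.
#' @param region vertex handles defining the region (edges with at least
#'   one endpoint in the region are processed).
#' @param sizing a [sizing_field()].
#' @param sources a [segment_sources()] table (may have zero rows, in which
#'   case no projection is performed).
#' @param cfg a [remesh_config()].
#' @param iso,tol,max_iter projection parameters, as in [project_vertex()].
#' @param project run the projection pass (default: when sources exist).
#' @param gate_unbound growth-pipeline semantics: vertices that have never
#'   reached the iso-surface are only projected once the field exceeds the
#'   iso-value beneath them (material is only ever added under them); with
#'   the default `FALSE` every vertex inside a support capsule is
#'   projected.
#' @return List of edit counts (`splits`, `collapses`, `flips`, `relaxed`,
#'   `projected`, `non_converged`) and the final `region` vertex handles.
#' @export
remesh_region <- function(mesh, region, sizing, sources,
                          cfg = remesh_config(), iso = 1, tol = 1e-4 * iso,
                          max_iter = 30L, project = NULL,
                          gate_unbound = FALSE) {
  check_mesh(mesh)
  check_sizing(sizing)
  S <- source_matrix(sources)
  if (is.null(project)) project <- nrow(S) > 0L
  rm_remesh_region(
    mesh$ptr, as.integer(region), unclass(sizing), S,
    cfg$alpha, cfg$beta, cfg$lambda_damp, cfg$iterations,
    iso, tol, as.integer(max_iter), project, NULL, gate_unbound
  )
}

#' Split long edges / collapse short edges / equalize valences
#'
#' The individual remeshing passes, exposed for inspection and testing;
#' [remesh_region()] runs them in sequence. Each returns its edit count.
#'
#' @inheritParams remesh_region
#' @return Integer edit count.
#' @export
split_long_edges <- function(mesh, region, sizing, cfg = remesh_config()) {
  run_single_pass(mesh, region, sizing, cfg, "split")
}

#' @rdname split_long_edges
#' @export
collapse_short_edges <- function(mesh, region, sizing, cfg = remesh_config()) {
  run_single_pass(mesh, region, sizing, cfg, "collapse")
}

#' @rdname split_long_edges
#' @export
equalize_valences <- function(mesh, region, sizing = NULL, cfg = remesh_config()) {
  if (is.null(sizing)) {
    # valence equalization needs no sizing; use a unit dummy field
    sizing <- structure(
      list(segments = matrix(numeric(0), 0, 8),
           separating = matrix(numeric(0), 0, 5),
           l_soma = 1, soma_radius = 1, l_floor = 1, l_cap = 1,
           d = 0.5, l_T = 4 / 3, kappa = 0.25),
      class = "sizing_field"
    )
  }
  run_single_pass(mesh, region, sizing, cfg, "equalize")
}

#' @rdname split_long_edges
#' @export
tangential_relaxation <- function(mesh, region, cfg = remesh_config()) {
  sz <- structure(
    list(segments = matrix(numeric(0), 0, 8),
         separating = matrix(numeric(0), 0, 5),
         l_soma = 1, soma_radius = 1, l_floor = 1, l_cap = 1,
         d = 0.5, l_T = 4 / 3, kappa = 0.25),
    class = "sizing_field"
  )
  run_single_pass(mesh, region, sz, cfg, "relax")
}

run_single_pass <- function(mesh, region, sizing, cfg, what) {
  check_mesh(mesh)
  S <- matrix(numeric(0), 0, 9)
  enable <- c(
    split = what == "split", collapse = what == "collapse",
    equalize = what == "equalize", relax = what == "relax"
  )
  res <- rm_remesh_region(
    mesh$ptr, as.integer(region), unclass(sizing), S,
    cfg$alpha, cfg$beta, cfg$lambda_damp, 1L, 1, 1e-4, 0L, FALSE,
    unname(enable)
  )
  switch(what,
    split = res$splits, collapse = res$collapses,
    equalize = res$flips, relax = res$relaxed
  )
}

#' Damped tangent-plane move
#'
#' The vertex update of the area-based tangential smoothing: the
#' displacement toward the weighted barycenter `g` is projected into the
#' tangent plane (the normal component is removed by `I - n n^T`) and
#' scaled by the damping factor.
#'
#' @param p current vertex position (3-vector).
#' @param g weighted barycentric target (3-vector).
#' @param n unit vertex normal (3-vector).
#' @param lambda_damp damping factor in (0, 1].
#' @return The updated position.
#' @export
apply_damped_tangent_move <- function(p, g, n, lambda_damp = 1) {
  n <- as.numeric(n)
  if (abs(sum(n^2) - 1) > 1e-8) stop("n must be a unit vector")
  d <- as.numeric(g) - as.numeric(p)
  as.numeric(p) + lambda_damp * (d - sum(d * n) * n)
}
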