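#' Pipeline configuration
#'
#' All tunable parameters of the progressive meshing pipeline, grouped as
#' they act: preconditioning (`epsilon`), the convolution field (`iso`,
#' `kernel_mult`), projection (`tol`, `max_iter`), remeshing
#' ([remesh_config()]), and sizing (`kappa`, `l_soma_factor`, optional
#' explicit `soma_level`). `brute_force_roi` disables the skeletal-mapping
#' acceleration (output must be identical); `debug_audit` runs the full
#' topology audit after every deformation step and stops on the first
#' violation.
#'
#' @param epsilon preconditioning threshold ratio (see
#'   [precondition_tree()]).
#' @param iso global iso-value of the convolution surface.
#' @param kernel_mult support radius multiplier `R_i / d_i`.
#' @param tol projection tolerance on `|F - iso|`.
#' @param max_iter projection iteration cap.
#' @param remesh a [remesh_config()].
#' @param kappa separating-region target ratio (see [sizing_field()]).
#' @param l_soma_factor desired initial mean edge length as a fraction of
#'   the soma radius; the icosphere subdivision level is chosen to match.
#' @param soma_level explicit icosphere subdivision level (overrides
#'   `l_soma_factor`).
#' @param brute_force_roi use the brute-force ROI scan instead of the
#'   skeletal mapping.
#' @param debug_audit audit topology after every step.
#' @param verbose print per-segment progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(epsilon = 0.1, iso = 1, kernel_mult = 2,
                            tol = 1e-4 * iso, max_iter = 30L,
                            remesh = remesh_config(), kappa = 0.25,
                            l_soma_factor = 0.3, soma_level = NULL,
                            brute_force_roi = FALSE, debug_audit = FALSE,
                            verbose = FALSE) {
  structure(
    list(
      epsilon = epsilon, iso = iso, kernel_mult = kernel_mult, tol = tol,
      max_iter = as.integer(max_iter), remesh = remesh, kappa = kappa,
      l_soma_factor = l_soma_factor, soma_level = soma_level,
      brute_force_roi = brute_force_roi, debug_audit = debug_audit,
      verbose = verbose
    ),
    class = "pipeline_config"
  )
}

#' Initial soma mesh
#'
#' Places an icosphere at the root node with the root (soma) radius. The
#' subdivision level is chosen so that the mean edge length lands within
#' the remesher's working band `[alpha * l, beta * l]` around the desired
#' soma-level edge length `l = l_soma_factor * soma radius`. All vertices
#' are mapped to the root node.
#'
#' @param tree a (preconditioned) [neuron_tree()].
#' @param cfg a [pipeline_config()].
#' @return List with `mesh` (a `membrane_mesh`) and `l_soma` (the measured
#'   mean edge length, the base of the sizing field).
#' @export
initialize_soma <- function(tree, cfg = pipeline_config()) {
  stopifnot(inherits(tree, "neuron_tree"))
  r <- tree$nodes$radius[tree$root]
  center <- as.numeric(tree$nodes[tree$root, c("x", "y", "z")])
  level <- cfg$soma_level
  if (is.null(level)) {
    # icosahedron edge on the unit sphere is ~1.0515; each subdivision halves it
    level <- max(0L, as.integer(round(log2(1.0515 / cfg$l_soma_factor))))
  }
  mesh <- make_icosphere(center, r, level)
  he_set_owners(mesh$ptr, mesh_vertices(mesh),
                rep(tree$nodes$id[tree$root], mesh_counts(mesh)[["V"]]))
  list(mesh = mesh, l_soma = mean(mesh_edges(mesh)$length), level = level)
}

# depth-first segment order (rows of child nodes): a segment is emitted
# when first reached, children visited by ascending node id
segment_order <- function(tree) {
  out <- integer(0)
  visit <- function(r) {
    kids <- tree$children[[r]]
    if (length(kids)) {
      for (k in kids[order(tree$nodes$id[kids])]) {
        out <<- c(out, k)
        visit(k)
      }
    }
  }
  visit(tree$root)
  out
}

#' Initialize the growth state
#'
#' Preconditions the tree, builds the convolution sources and the sizing
#' field, places the initial soma mesh, and sets the growth front at the
#' start of the first segment (depth-first order, children by ascending
#' id).
#'
#' @param tree a [neuron_tree()].
#' @param cfg a [pipeline_config()].
#' @return An environment of class `growth_state`.
#' @export
initialize_growth <- function(tree, cfg = pipeline_config()) {
  tree <- precondition_tree(tree, cfg$epsilon)
  sources <- segment_sources(tree, cfg$iso, cfg$kernel_mult)
  soma <- initialize_soma(tree, cfg)
  sizing <- sizing_field(tree, sources, soma$l_soma, cfg$kappa,
                         cfg$remesh$beta)
  order_rows <- segment_order(tree)
  # map child rows to source rows (sources are indexed by child node)
  src_row <- match(tree$nodes$id[order_rows], sources$node_b)
  st <- new.env(parent = emptyenv())
  st$tree <- tree
  st$cfg <- cfg
  st$sources <- sources
  st$mesh <- soma$mesh
  st$l_soma <- soma$l_soma
  st$sizing <- sizing
  st$order <- src_row       # source rows in growth order
  st$seg_idx <- if (length(src_row)) 1L else 0L
  st$s <- 0                 # grown arc length on the front segment
  st$active <- integer(0)   # completed source rows
  st$iteration <- 0L
  st$done <- length(src_row) == 0L
  st$non_converged <- 0L
  class(st) <- "growth_state"
  st
}

#' @export
print.growth_state <- function(x, ...) {
  cat(sprintf(
    "<growth_state> segment %d/%d, s=%.3g, %d active, iteration %d%s\n",
    x$seg_idx, length(x$order), x$s, length(x$active), x$iteration,
    if (x$done) " (done)" else ""
  ))
  invisible(x)
}

front_geometry <- function(state) {
  i <- state$order[[state$seg_idx]]
  src <- state$sources[i, ]
  a <- c(src$ax, src$ay, src$az)
  b <- c(src$bx, src$by, src$bz)
  L <- sqrt(sum((b - a)^2))
  u <- if (L > 0) (b - a) / L else c(1, 0, 0)
  list(row = i, src = src, a = a, b = b, L = L, u = u)
}

#' Advance the growth front
#'
#' Moves the front along the current segment by the local marching step
#' (half the local target edge length, so deformation keeps pace with the
#' edge budget and slows down near separating points). When a segment
#' completes it joins the active set and the next segment in depth-first
#' order begins.
#'
#' @param state a [initialize_growth()] state.
#' @return The state, invisibly; `state$front_pos` holds the new front
#'   position and `state$front_sources` the active + truncated source set.
#' @export
advance_front <- function(state) {
  if (state$done) stop("growth already complete")
  g <- front_geometry(state)
  pos_now <- g$a + state$s * g$u
  step <- max(marching_step(state$sizing, pos_now), 1e-9)
  state$s <- min(g$L, state$s + step)
  state$iteration <- state$iteration + 1L
  front <- g$a + state$s * g$u
  trunc_src <- g$src
  trunc_src$bx <- front[[1]]; trunc_src$by <- front[[2]]; trunc_src$bz <- front[[3]]
  state$front_pos <- front
  state$front_row <- g$row
  state$front_sources <- rbind(state$sources[state$active, , drop = FALSE], trunc_src)
  if (state$s >= g$L - 1e-12) {
    state$active <- c(state$active, g$row)
    state$s <- 0
    if (state$seg_idx >= length(state$order)) state$done <- TRUE
    else state$seg_idx <- state$seg_idx + 1L
  }
  invisible(state)
}

#' One deformation step at the growth front
#'
#' Queries the ROI around the current front position (radius = the front
#' segment's support radius), projects those vertices onto the field of
#' all active plus the truncated front source, rebinds their skeleton
#' owners, and runs the quasi-uniform remesher on the region. The mesh
#' remains closed, manifold and of Euler characteristic 2 throughout; with
#' `debug_audit` this is verified after the step.
#'
#' @param state a growth state on which [advance_front()] has been called.
#' @return Edit summary list from [remesh_region()], invisibly.
#' @export
deform_step <- function(state) {
  if (is.null(state$front_pos)) stop("call advance_front() first")
  cfg <- state$cfg
  srcs <- state$front_sources
  roi_r <- state$front_sources$R[[nrow(srcs)]]
  active_ids <- unique(c(srcs$node_a, srcs$node_b))
  roi <- roi_vertices(
    state$mesh, state$tree, position = state$front_pos, radius = roi_r,
    sources = state$sources, active_ids = active_ids,
    brute_force = cfg$brute_force_roi
  )
  summary <- list(splits = 0L, collapses = 0L, flips = 0L, projected = 0L,
                  non_converged = 0L)
  if (length(roi)) {
    rm_project_vertices(state$mesh$ptr, roi, source_matrix(srcs),
                        cfg$iso, cfg$tol, cfg$max_iter, TRUE)
    assign_vertex(state$mesh, roi, srcs)
    summary <- remesh_region(
      state$mesh, roi, state$sizing, srcs, cfg$remesh,
      iso = cfg$iso, tol = cfg$tol, max_iter = cfg$max_iter,
      gate_unbound = TRUE
    )
  }
  if (cfg$debug_audit) {
    aud <- audit_mesh(state$mesh)
    if (!aud$structure_ok || !aud$manifold || !aud$watertight || aud$euler != 2L) {
      stop("topology audit failed at iteration ", state$iteration, ": ",
           aud$message)
    }
    if (!map_audit(state$mesh)$ok) {
      stop("skeletal map partition violated at iteration ", state$iteration)
    }
  }
  invisible(summary)
}

#' Grow a neuronal membrane mesh
#'
#' The full progressive pipeline: precondition the tree, place the initial
#' soma sphere, then traverse the neuronal tree depth-first, advancing a
#' growth front in marching steps and deforming the region of influence
#' onto the convolution iso-surface with local quasi-uniform remeshing
#' after each step. A final global remeshing/projection sweep polishes the
#' mesh. The run is fully deterministic for a fixed input and
#' configuration.
#'
#' @param tree a [neuron_tree()].
#' @param cfg a [pipeline_config()].
#' @return List of class `grown_neuron`: `mesh` (a `membrane_mesh`),
#'   `report` (a [quality_report()] with an added `non_converged` count),
#'   `sizing`, `sources`, and the preconditioned `tree`.
#' @export
grow_neuron <- function(tree, cfg = pipeline_config()) {
  st <- initialize_growth(tree, cfg)
  while (!st$done) {
    advance_front(st)
    deform_step(st)
    if (cfg$verbose && st$iteration %% 50L == 0L) {
      message(sprintf("  step %d: segment %d/%d, V=%d",
                      st$iteration, st$seg_idx, length(st$order),
                      mesh_counts(st$mesh)[["V"]]))
    }
  }
  non_conv <- 0L
  if (length(st$active)) {
    # final sweep: full region, full source set
    final <- remesh_region(
      st$mesh, mesh_vertices(st$mesh), st$sizing, st$sources, cfg$remesh,
      iso = cfg$iso, tol = cfg$tol, max_iter = cfg$max_iter,
      gate_unbound = TRUE
    )
    non_conv <- final$non_converged
    # band enforcement: relaxation/projection may have stretched or shrunk
    # edges after the last split/collapse, so run one structural pass
    # without vertex smoothing (midpoints of on-surface edges stay within
    # tolerance of the surface at these edge lengths)
    rm_remesh_region(
      st$mesh$ptr, mesh_vertices(st$mesh), unclass(st$sizing),
      matrix(numeric(0), 0, 9),
      cfg$remesh$alpha, cfg$remesh$beta, 0, 1L, cfg$iso, cfg$tol, 0L, FALSE,
      c(TRUE, TRUE, FALSE, FALSE)
    )
    # structural passes place new vertices at chord midpoints and
    # projection returns them to the iso-surface, which can nudge edges
    # over a threshold again; alternate until the structural pass is a
    # no-op, so the final mesh is both in-band and on-surface
    structural_pass <- function() {
      rm_remesh_region(
        st$mesh$ptr, mesh_vertices(st$mesh), unclass(st$sizing),
        matrix(numeric(0), 0, 9),
        cfg$remesh$alpha, cfg$remesh$beta, 0, 1L, cfg$iso, cfg$tol, 0L, FALSE,
        c(TRUE, TRUE, FALSE, FALSE)
      )
    }
    in_band <- function() {
      rng <- range(mesh_edges(st$mesh)$length)
      rng[1] > st$sizing$d && rng[2] < st$sizing$l_T
    }
    for (k in 1:8) {
      fin <- rm_project_vertices(
        st$mesh$ptr, mesh_vertices(st$mesh), source_matrix(st$sources),
        cfg$iso, cfg$tol, cfg$max_iter, TRUE
      )
      non_conv <- fin$non_converged
      sc <- structural_pass()
      if (sc$splits + sc$collapses == 0L && in_band()) break
    }
    # settle the band without further vertex motion: structural edits move
    # points by at most a local chord sagitta, so the surface error this
    # leaves behind is far below the projection tolerance scale
    for (k in 1:8) {
      if (in_band()) break
      structural_pass()
    }
  }
  rep <- quality_report(st$mesh)
  rep$non_converged <- non_conv
  structure(
    list(mesh = st$mesh, report = rep, sizing = st$sizing,
         sources = st$sources, tree = st$tree),
    class = "grown_neuron"
  )
}

#' @export
print.grown_neuron <- function(x, ...) {
  cat("<grown_neuron>\n")
  print(x$report)
  invisible(x)
}
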