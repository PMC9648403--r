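# a uniform sizing field with constant target length l
const_sizing <- function(l) {
  structure(
    list(
      segments = matrix(numeric(0), 0, 8),
      separating = matrix(numeric(0), 0, 5),
      l_soma = l, soma_radius = 1, l_floor = l, l_cap = l,
      d = l / 2, l_T = 4 / 3 * l, kappa = 0.25
    ),
    class = "sizing_field"
  )
}

test_that("split_long_edges leaves compliant regions untouched", {
  m <- make_icosphere(level = 1)
  l <- max(mesh_edges(m)$length) # every edge <= beta * l
  n <- split_long_edges(m, mesh_vertices(m), const_sizing(l))
  expect_equal(n, 0L)
})

test_that("split_long_edges halves over-long edges until compliant", {
  m <- make_icosphere(level = 1)
  l0 <- mean(mesh_edges(m)$length)
  # target such that existing edges are ~2.5x the split threshold
  l <- l0 / 2.5
  sz <- const_sizing(l)
  before <- unname(mesh_counts(m))
  n <- split_long_edges(m, mesh_vertices(m), sz)
  expect_gt(n, 0L)
  after <- unname(mesh_counts(m))
  expect_equal(after - before, n * c(1L, 3L, 2L))
  ed <- mesh_edges(m)
  expect_true(all(ed$length <= 4 / 3 * l + 1e-12))
  ct <- mesh_counts(m)
  expect_equal(ct[["V"]] - ct[["E"]] + ct[["F"]], 2L)
  expect_true(is_manifold(m))
})

test_that("collapse_short_edges removes needle edges and honours the high guard", {
  m <- make_icosphere(level = 1)
  l <- mean(mesh_edges(m)$length)
  sz <- const_sizing(l)
  expect_equal(collapse_short_edges(m, mesh_vertices(m), sz), 0L)
  # create one needle edge by splitting near an endpoint
  ed <- mesh_edges(m)
  e <- ed$edge[[1L]]
  ends <- edge_vertices(m, e)
  p <- vertex_positions(m, ends)
  v <- split_edge(m, e, p[1, ] + 0.05 * (p[2, ] - p[1, ]))
  before <- unname(mesh_counts(m))
  n <- collapse_short_edges(m, mesh_vertices(m), sz)
  expect_gte(n, 1L)
  expect_equal(unname(mesh_counts(m)), before - n * c(1L, 3L, 2L))
  expect_true(is_manifold(m))

  # guard: a collapse that would create an over-long edge is skipped.
  # two distant vertices joined by a short edge via an elongated patch:
  # use a sphere scaled along z so its polar edges are long, then shrink
  # one equatorial edge; collapsing it would lengthen nothing beyond the
  # bound, so instead verify directly that the C++ guard path triggers
  # with a tiny target (every potential new edge > beta * l).
  m2 <- make_icosphere(level = 1)
  sz_tiny <- const_sizing(mean(mesh_edges(m2)$length) / 100)
  # all edges are << alpha * l? no: tiny target means edges are LONG ->
  # nothing short. Use a huge target instead: every edge is "short", but
  # any collapse would create edges longer than beta * l is false...
  # so test the guard with an anisotropic construction:
  mm <- make_icosphere(level = 2)
  edm <- mesh_edges(mm)
  e2 <- edm$edge[[10L]]
  ends2 <- edge_vertices(mm, e2)
  pp <- vertex_positions(mm, ends2)
  vnew <- split_edge(mm, e2, pp[1, ] + 0.02 * (pp[2, ] - pp[1, ]))
  # target slightly above the needle length but with beta*l below the
  # surrounding edge lengths: the collapse of the needle would create an
  # edge about as long as its neighbours, exceeding beta*l -> skipped
  needle_len <- 0.02 * sqrt(sum((pp[2, ] - pp[1, ])^2))
  sz_guard <- const_sizing(needle_len * 2)
  n2 <- collapse_short_edges(mm, ends2, sz_guard)
  expect_equal(n2, 0L)
  expect_true(vnew %in% mesh_vertices(mm))
})

test_that("equalize_valences flips only when the squared deviation drops", {
  # an icosphere has valences 5 and 6 only; a split creates a valence-4
  # vertex and two valence-7 vertices, which flips then improve
  m <- make_icosphere(level = 2)
  expect_equal(equalize_valences(m, mesh_vertices(m)), 0L)
  ed <- mesh_edges(m)
  # pick an edge whose four incident vertices all have valence 6
  pick <- NA
  for (i in seq_len(nrow(ed))) {
    ends <- edge_vertices(m, ed$edge[[i]])
    ring <- unique(c(one_ring(m, ends[[1]]), one_ring(m, ends[[2]])))
    if (all(vertex_valence(m, c(ends, ring)) == 6L)) { pick <- i; break }
  }
  expect_false(is.na(pick))
  split_edge(m, ed$edge[[pick]])
  dev <- function() sum((vertex_valence(m) - 6L)^2)
  d0 <- dev()
  nf <- equalize_valences(m, mesh_vertices(m))
  expect_gt(nf, 0L)
  expect_lt(dev(), d0) # flips strictly reduced the total deviation
  expect_true(is_manifold(m))
})

test_that("tangential relaxation is the area-weighted barycenter update", {
  # two-neighbour abstraction of the weighted barycenter: areas 3 and 1 at
  # +1 and -1 give g = 0.5
  g <- (3 * 1 + 1 * (-1)) / (3 + 1)
  expect_equal(g, 0.5)
  # apply_damped_tangent_move: the projector kills the normal component
  expect_equal(
    apply_damped_tangent_move(c(0, 0, 0), c(0, 0, 5), c(0, 0, 1), 1),
    c(0, 0, 0)
  )
  expect_equal(
    apply_damped_tangent_move(c(0, 0, 0), c(2, 0, 0), c(0, 0, 1), 1),
    c(2, 0, 0)
  )
  expect_equal(
    apply_damped_tangent_move(c(0, 0, 0), c(2, 0, 2), c(0, 0, 1), 0.5),
    c(1, 0, 0)
  )
  expect_error(apply_damped_tangent_move(c(0, 0, 0), c(1, 1, 1), c(0, 0, 2)),
               "unit")

  # symmetric fan: the apex of an icosahedron vertex is a fixed point
  m <- make_icosphere(level = 0)
  v <- mesh_vertices(m)[[1L]]
  p0 <- vertex_positions(m, v)
  tangential_relaxation(m, v)
  expect_equal(vertex_positions(m, v), p0, tolerance = 1e-12)
})

test_that("relaxation moves an off-center vertex toward its ring barycenter tangentially", {
  m <- make_icosphere(level = 1)
  v <- mesh_vertices(m)[[1L]]
  ring <- one_ring(m, v)
  # nudge v tangentially off its symmetric position
  p <- as.numeric(vertex_positions(m, v))
  n <- p / sqrt(sum(p^2))
  tang <- c(n[2], -n[1], 0)
  tang <- tang - sum(tang * n) * n
  tang <- tang / sqrt(sum(tang^2))
  he_set_positions(m$ptr, v, matrix(p + 0.1 * tang, 1))
  before <- as.numeric(vertex_positions(m, v))
  moved <- tangential_relaxation(m, v)
  expect_gte(moved, 1L)
  after <- as.numeric(vertex_positions(m, v))
  expect_false(identical(before, after))
  # the displacement is orthogonal to the (area-weighted) vertex normal by
  # construction; check it is nearly tangent to the sphere
  disp <- after - before
  expect_lt(abs(sum(disp * n)) / sqrt(sum(disp^2)), 0.2)
})

test_that("remesh_region against a long segment recovers the cylinder", {
  src <- data.frame(
    ax = -50, ay = 0, az = 0, bx = 50, by = 0, bz = 0,
    d = 1, R = 2, lambda = lambda_weight(1, 2, 1), node_a = 1L, node_b = 2L
  )
  # start from a sphere of radius 1 at a mid-segment position; every vertex
  # is inside the support and the field pushes/pulls it to distance 1
  m <- make_icosphere(c(0, 0, 0), 1.4, 2)
  sz <- const_sizing(0.35)
  res <- remesh_region(m, mesh_vertices(m), sz, src, remesh_config())
  P <- vertex_positions(m)
  mid <- P[abs(P[, 1]) < 20, , drop = FALSE]
  dist <- sqrt(mid[, 2]^2 + mid[, 3]^2)
  expect_lt(max(abs(dist - 1)), 1e-3)
  expect_true(is_manifold(m))
  expect_true(is_watertight(m))
  ct <- mesh_counts(m)
  expect_equal(ct[["V"]] - ct[["E"]] + ct[["F"]], 2L)
})

test_that("remeshing a settled surface is a structural fixed point", {
  # a finite capsule source whose closed iso-surface the mesh can wrap
  src <- data.frame(
    ax = -2, ay = 0, az = 0, bx = 2, by = 0, bz = 0,
    d = 1, R = 2, lambda = lambda_weight(1, 2, 1), node_a = 1L, node_b = 2L
  )
  m <- make_icosphere(c(0, 0, 0), 1.2, 2)
  sz <- const_sizing(0.4)
  settled <- FALSE
  for (k in 1:10) {
    r <- remesh_region(m, mesh_vertices(m), sz, src, remesh_config())
    if (r$splits + r$collapses == 0L) { settled <- TRUE; break }
  }
  expect_true(settled)
  res2 <- remesh_region(m, mesh_vertices(m), sz, src, remesh_config())
  expect_equal(res2$splits + res2$collapses, 0L)
  expect_true(is_manifold(m))
  expect_true(is_watertight(m))
})

test_that("remeshing keeps every region edge within the band", {
  m <- make_icosphere(level = 1)
  l <- mean(mesh_edges(m)$length) / 2
  sz <- const_sizing(l)
  remesh_region(m, mesh_vertices(m), sz, segment_sources(parse_swc("1 1 0 0 0 1 -1")),
                remesh_config(), project = FALSE)
  ed <- mesh_edges(m)
  expect_true(all(ed$length <= 4 / 3 * l + 1e-9))
  expect_true(all(ed$length >= l / 2 - 1e-9))
  expect_true(is_manifold(m))
})
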