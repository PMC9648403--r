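swc_text <- function(...) paste(c(...), collapse = "\n")

test_that("parse_swc reads a small chain and preserves fields exactly", {
  txt <- swc_text(
    "# comment line",
    "1 1 0 0 0 5.25 -1",
    "2 3 3.5 0 0 2.125 1",
    "3 3 7 0 0 2 2"
  )
  tr <- parse_swc(txt)
  expect_s3_class(tr, "neuron_tree")
  expect_equal(nrow(tr$nodes), 3L)
  expect_equal(tr$nodes$id[tr$root], 1L)
  expect_identical(tr$nodes$x, c(0, 3.5, 7))
  expect_identical(tr$nodes$radius, c(5.25, 2.125, 2))
  expect_equal(tr$nodes$parent, c(-1L, 1L, 2L))
})

test_that("parse_swc rejects malformed trees with informative errors", {
  expect_error(
    parse_swc(swc_text("1 1 0 0 0 1 -1", "2 3 1 0 0 1 99")),
    "unresolved parent"
  )
  expect_error(
    parse_swc(swc_text("1 1 0 0 0 1 -1", "2 1 9 0 0 1 -1")),
    "multiple roots"
  )
  expect_error(
    parse_swc(swc_text("1 1 0 0 0 1 -1", "1 3 1 0 0 1 1")),
    "duplicate id"
  )
  expect_error(
    parse_swc(swc_text("1 1 0 0 0 0 -1")),
    "non-positive radius"
  )
  expect_error(
    parse_swc(swc_text("1 1 0 0 0 1 2", "2 3 1 0 0 1 1")),
    "root"
  )
})

test_that("write_swc round-trips through parse_swc exactly", {
  for (kind in c("cable", "bifurcation", "random_binary")) {
    tr <- synth_morphology(kind, nodes = 12, seed = 4, taper = 0.9)
    rt <- parse_swc(write_swc(tr))
    expect_identical(rt$nodes, tr$nodes)
  }
  soma <- parse_swc("1 1 0 0 0 4 -1")
  lines <- write_swc(soma)
  expect_length(grep("^[^#]", lines), 1L)
  expect_match(grep("^[^#]", lines, value = TRUE), "-1$")
})

test_that("segment_length is the parent-child Euclidean distance", {
  tr <- parse_swc(swc_text(
    "1 1 0 0 0 1 -1", "2 3 3 4 0 1 1", "3 3 3 4 0 1 2"
  ))
  expect_equal(segment_length(tr, 2), 5)
  expect_equal(segment_length(tr, 3), 0)
  expect_error(segment_length(tr, 1), "root")
})

test_that("branch_angle matches vector geometry", {
  tr <- parse_swc(swc_text(
    "1 1 0 0 0 2 -1",
    "2 3 1 0 0 1 1",
    "3 3 0 1 0 1 1"
  ))
  expect_equal(branch_angle(tr, 1)$theta_deg, 90)

  opp <- parse_swc(swc_text(
    "1 1 0 0 0 2 -1", "2 3 1 0 0 1 1", "3 3 -2 0 0 1 1"
  ))
  expect_equal(branch_angle(opp, 1)$theta_deg, 180)

  diag45 <- parse_swc(swc_text(
    "1 1 0 0 0 2 -1", "2 3 1 0 0 1 1", "3 3 1 1 0 1 1"
  ))
  expect_equal(branch_angle(diag45, 1)$theta_deg, 45)

  single <- parse_swc(swc_text("1 1 0 0 0 2 -1", "2 3 1 0 0 1 1"))
  expect_error(branch_angle(single, 1), "fewer than 2")
})

test_that("precondition_tree removes coincident pass-through nodes", {
  tr <- parse_swc(swc_text(
    "1 1 0 0 0 2 -1",
    "2 3 5 0 0 1 1",
    "3 3 5 0 0 1 2", # coincident with its parent
    "4 3 10 0 0 1 3"
  ))
  out <- precondition_tree(tr)
  expect_equal(nrow(out$nodes), 3L)
  expect_false(3L %in% out$nodes$id)
  expect_equal(out$nodes$parent[out$nodes$id == 4L], 2L)
})

test_that("precondition_tree is the identity on clean trees and idempotent", {
  tr <- synth_morphology("bifurcation", theta = 60, step = 5, radius = 2)
  once <- precondition_tree(tr, epsilon = 0.1)
  expect_identical(once$nodes, tr$nodes)
  # a tree with short segments: applying twice equals applying once
  tr2 <- parse_swc(swc_text(
    "1 1 0 0 0 5 -1",
    "2 3 0.1 0 0 2 1",
    "3 3 0.2 0 0 2 2",
    "4 3 0.3 0 0 2 3",
    "5 3 10 0 0 2 4"
  ))
  a <- precondition_tree(tr2)
  b <- precondition_tree(a)
  expect_identical(a$nodes, b$nodes)
})

# independent oracle: exhaustively remove the shortest sub-threshold
# pass-through segment until none remains
brute_precondition <- function(tr, threshold) {
  nodes <- tr$nodes
  repeat {
    t2 <- neuron_tree(nodes)
    deg <- vapply(t2$children, length, 1L)
    parent_row <- match(t2$nodes$parent, t2$nodes$id)
    cand <- which(deg == 1L & seq_len(nrow(t2$nodes)) != t2$root)
    if (!length(cand)) return(t2)
    pos <- as.matrix(t2$nodes[, c("x", "y", "z")])
    len <- sqrt(rowSums((pos[cand, , drop = FALSE] -
                           pos[parent_row[cand], , drop = FALSE])^2))
    if (!any(len < threshold)) return(t2)
    victim <- cand[which.min(ifelse(len < threshold, len, Inf))]
    nodes <- t2$nodes
    nodes$parent[t2$children[[victim]]] <- nodes$parent[victim]
    nodes <- nodes[-victim, , drop = FALSE]
  }
}

test_that("precondition_tree matches the shortest-first removal oracle", {
  tr <- parse_swc(paste(
    "1 1 0 0 0 5 -1",
    "2 3 2 0 0 2 1",
    "3 3 2.2 0 0 2 2",
    "4 3 2.3 0 0 2 3",
    "5 3 2.45 0 0 2 4",
    "6 3 9 0 0 2 5",
    sep = "\n"
  ))
  got <- precondition_tree(tr, epsilon = 0.1, r_ref = 5) # threshold 0.5
  want <- brute_precondition(tr, 0.5)
  expect_identical(got$nodes$id, want$nodes$id)
  # no surviving pass-through segment below threshold
  deg <- vapply(got$children, length, 1L)
  for (r in which(deg == 1L)) {
    if (r == got$root) next
    expect_gte(segment_length(got, got$nodes$id[r]), 0.5)
  }
})

test_that("precondition_tree preserves branch points and tips", {
  tr <- synth_morphology("random_binary", nodes = 40, seed = 11, taper = 0.9)
  # inject short pass-through nodes between existing ones
  n <- tr$nodes
  extra <- n[n$parent != -1L, ][1:5, ]
  extra_new <- extra
  extra_new$id <- 1000L + seq_len(nrow(extra))
  par_row <- match(extra$parent, n$id)
  extra_new[, c("x", "y", "z")] <-
    n[par_row, c("x", "y", "z")] + 0.01 * (extra[, c("x", "y", "z")] - n[par_row, c("x", "y", "z")])
  extra_new$parent <- extra$parent
  n$parent[match(extra$id, n$id)] <- extra_new$id
  noisy <- neuron_tree(rbind(n, extra_new))

  clean <- precondition_tree(noisy)
  deg_pos <- function(t) {
    deg <- vapply(t$children, length, 1L)
    list(
      tips = sort(do.call(paste, t$nodes[deg == 0L, c("x", "y", "z")])),
      branches = sort(do.call(paste, t$nodes[deg >= 2L, c("x", "y", "z")]))
    )
  }
  expect_identical(deg_pos(clean)$tips, deg_pos(noisy)$tips)
  expect_identical(deg_pos(clean)$branches, deg_pos(noisy)$branches)
})

test_that("synth_morphology builds valid deterministic fixtures", {
  cab <- synth_morphology("cable", nodes = 10, step = 5, radius = 2)
  expect_equal(nrow(cab$nodes), 10L)
  expect_true(all(diff(cab$nodes$x) == 5))
  expect_true(all(cab$nodes$y == 0 & cab$nodes$z == 0))

  bif <- synth_morphology("bifurcation", theta = 90, step = 5, radius = 2)
  fork <- bif$nodes$id[vapply(bif$children, length, 1L) == 2L]
  expect_length(fork, 1L)
  expect_equal(branch_angle(bif, fork)$theta_deg, 90, tolerance = 1e-10)

  r1 <- synth_morphology("random_binary", nodes = 30, seed = 42, taper = 0.9)
  r2 <- synth_morphology("random_binary", nodes = 30, seed = 42, taper = 0.9)
  expect_identical(write_swc(r1), write_swc(r2))
  r3 <- synth_morphology("random_binary", nodes = 30, seed = 43, taper = 0.9)
  expect_false(identical(write_swc(r1), write_swc(r3)))

  # radii non-increasing from soma along every path
  par_row <- match(r1$nodes$parent, r1$nodes$id)
  non_root <- which(r1$nodes$parent != -1L)
  expect_true(all(r1$nodes$radius[non_root] <= r1$nodes$radius[par_row[non_root]] + 1e-12))

  expect_error(synth_morphology("cable", taper = 0), "taper")
})
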