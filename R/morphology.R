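#' Neuronal tree from a node table
#'
#' Constructs and validates the point-and-diameter representation of a
#' neuronal morphology: a rooted tree of skeleton nodes, each carrying a 3D
#' position (micrometers) and a radius (micrometers), linked by parent ids as
#' in the SWC convention (type code 1 = soma, parent -1 = root).
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`. Ids must be unique positive integers; ids need not
#'   be contiguous. Exactly one node must have `parent == -1`.
#' @return An object of class `neuron_tree`: a list with the validated
#'   `nodes` table, a `children` index (list of child row indices per row),
#'   and `root` (row index of the root).
#' @export
neuron_tree <- function(nodes) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    stop("`nodes` must be a data.frame with columns ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  for (col in c("x", "y", "z", "radius")) nodes[[col]] <- as.numeric(nodes[[col]])

  if (anyNA(nodes)) stop("NA values in node table")
  if (any(nodes$id <= 0L)) stop("node ids must be positive")
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) stop("duplicate id: ", dup[[1L]])
  if (any(nodes$radius <= 0)) {
    stop("non-positive radius at id ", nodes$id[which(nodes$radius <= 0)[1L]])
  }
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0L) stop("no root (parent -1) found")
  if (length(roots) > 1L) stop("multiple roots: ids ", paste(nodes$id[roots], collapse = ", "))

  parent_row <- match(nodes$parent, nodes$id)
  bad <- which(is.na(parent_row) & nodes$parent != -1L)
  if (length(bad)) {
    stop("unresolved parent ", nodes$parent[bad[[1L]]], " at id ", nodes$id[bad[[1L]]])
  }

  # cycle / connectivity check: every node must reach the root
  n <- nrow(nodes)
  reached <- logical(n)
  reached[roots] <- TRUE
  for (i in seq_len(n)) {
    if (reached[i]) next
    path <- integer(0)
    j <- i
    while (!reached[j]) {
      if (j %in% path) stop("cycle detected at id ", nodes$id[j])
      path <- c(path, j)
      j <- parent_row[j]
    }
    reached[path] <- TRUE
  }

  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent_row[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  structure(
    list(nodes = nodes, children = children, root = roots),
    class = "neuron_tree"
  )
}

#' @export
print.neuron_tree <- function(x, ...) {
  nb <- sum(vapply(x$children, length, 1L) >= 2L)
  tips <- sum(vapply(x$children, length, 1L) == 0L)
  cat(sprintf(
    "<neuron_tree> %d nodes, %d branch points, %d tips, root id %d (radius %.3g um)\n",
    nrow(x$nodes), nb, tips, x$nodes$id[x$root], x$nodes$radius[x$root]
  ))
  invisible(x)
}

node_row <- function(tree, id) {
  r <- match(as.integer(id), tree$nodes$id)
  if (anyNA(r)) stop("unknown node id ", id[which(is.na(r))[1L]])
  r
}

node_position <- function(tree, id) {
  r <- node_row(tree, id)
  unname(as.matrix(tree$nodes[r, c("x", "y", "z"), drop = FALSE]))
}

#' Parse SWC text into a neuronal tree
#'
#' Reads the standard whitespace-delimited 7-column SWC dialect
#' (`id type x y z radius parent`); lines starting with `#` are comments.
#' Unknown type codes are accepted. Positions and radii are preserved
#' exactly as parsed.
#'
#' @param text character vector: either a single string with embedded
#'   newlines or one element per line.
#' @return A [neuron_tree()].
#' @seealso [read_swc()], [write_swc()]
#' @export
parse_swc <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (!length(data_lines)) stop("SWC contains no data lines")
  fields <- strsplit(trimws(data_lines), "\\s+")
  nfield <- vapply(fields, length, 1L)
  if (any(nfield < 7L)) {
    i <- which(nfield < 7L)[1L]
    stop("line ", line_no[i], ": expected 7 SWC columns, found ", nfield[i])
  }
  m <- do.call(rbind, lapply(fields, function(f) suppressWarnings(as.numeric(f[1:7]))))
  if (anyNA(m)) {
    i <- which(apply(is.na(m), 1L, any))[1L]
    stop("line ", line_no[i], ": non-numeric SWC field")
  }
  nodes <- data.frame(
    id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
    x = m[, 3L], y = m[, 4L], z = m[, 5L],
    radius = m[, 6L], parent = as.integer(m[, 7L])
  )
  tryCatch(neuron_tree(nodes), error = function(e) {
    stop("SWC parse error: ", conditionMessage(e), call. = FALSE)
  })
}

#' Read an SWC morphology file
#' @param path file path.
#' @return A [neuron_tree()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  parse_swc(readLines(path, warn = FALSE))
}

#' Serialize a neuronal tree to SWC text
#'
#' Writes the 7-column SWC dialect. `parse_swc(write_swc(t))` reproduces the
#' tree exactly (positions and radii to full double precision); comments are
#' not preserved by the reader, so none are emitted beyond a minimal header.
#'
#' @param tree a [neuron_tree()].
#' @param path optional file path; when given the text is also written there.
#' @return The SWC text, one element per line, invisibly when `path` is given.
#' @export
write_swc <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "neuron_tree"))
  n <- tree$nodes
  lines <- c(
    "# SWC (id type x y z radius parent)",
    sprintf(
      "%d %d %.17g %.17g %.17g %.17g %d",
      n$id, n$type, n$x, n$y, n$z, n$radius, n$parent
    )
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Length of the segment ending at a node
#'
#' Euclidean distance between a node and its parent, in micrometers.
#'
#' @param tree a [neuron_tree()].
#' @param child_id node id; must not be the root.
#' @return scalar length.
#' @export
segment_length <- function(tree, child_id) {
  r <- node_row(tree, child_id)
  if (r == tree$root) stop("node ", child_id, " is the root and has no parent segment")
  p <- match(tree$nodes$parent[r], tree$nodes$id)
  sqrt(sum((as.numeric(tree$nodes[r, c("x", "y", "z")]) -
              as.numeric(tree$nodes[p, c("x", "y", "z")]))^2))
}

#' Branching angles at a node
#'
#' Angle between the unit direction vectors from a branch node to each pair
#' of its children, in degrees, in (0, 180].
#'
#' @param tree a [neuron_tree()].
#' @param branch_node_id id of a node with at least two children.
#' @return data.frame with columns `child_a`, `child_b` (ids) and
#'   `theta_deg`; one row per unordered child pair.
#' @export
branch_angle <- function(tree, branch_node_id) {
  r <- node_row(tree, branch_node_id)
  kids <- tree$children[[r]]
  if (length(kids) < 2L) stop("node ", branch_node_id, " has fewer than 2 children")
  b <- as.numeric(tree$nodes[r, c("x", "y", "z")])
  dirs <- lapply(kids, function(k) {
    v <- as.numeric(tree$nodes[k, c("x", "y", "z")]) - b
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("child id ", tree$nodes$id[k], " coincides with the branch node")
    v / nv
  })
  pairs <- utils::combn(seq_along(kids), 2L)
  theta <- apply(pairs, 2L, function(ij) {
    d <- sum(dirs[[ij[1L]]] * dirs[[ij[2L]]])
    acos(max(-1, min(1, d))) * 180 / pi
  })
  data.frame(
    child_a = tree$nodes$id[kids[pairs[1L, ]]],
    child_b = tree$nodes$id[kids[pairs[2L, ]]],
    theta_deg = theta
  )
}

#' Remove trivial (overly short) segments from a neuronal tree
#'
#' Neuronal reconstructions in public repositories frequently contain
#' pass-through nodes separated from their parent by less than the local
#' marching step, which slow down and can destabilise progressive meshing.
#' This preconditioning removes degree-2 (pass-through) nodes whose parent
#' segment is shorter than `epsilon * r_ref`, reconnecting each child to its
#' grandparent, shortest segment first, until no sub-threshold pass-through
#' segment remains. Branch points, tips and the root are never deleted, so
#' the topology (number of branch points and tips, and their positions) is
#' preserved exactly. The operation is idempotent.
#'
#' @param tree a [neuron_tree()].
#' @param epsilon dimensionless threshold ratio; a pass-through segment is
#'   trivial when shorter than `epsilon * r_ref`. Default 0.1.
#' @param r_ref reference radius in micrometers; defaults to the root (soma)
#'   radius.
#' @return The preconditioned [neuron_tree()].
#' @export
precondition_tree <- function(tree, epsilon = 0.1, r_ref = NULL) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (is.null(r_ref)) r_ref <- tree$nodes$radius[tree$root]
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (r_ref <= 0) stop("r_ref must be > 0")
  threshold <- epsilon * r_ref

  nodes <- tree$nodes
  repeat {
    t2 <- neuron_tree(nodes)
    deg_out <- vapply(t2$children, length, 1L)
    parent_row <- match(t2$nodes$parent, t2$nodes$id)
    # candidate removals: pass-through nodes (exactly one child, not root)
    cand <- which(deg_out == 1L & seq_len(nrow(t2$nodes)) != t2$root)
    if (!length(cand)) break
    pos <- as.matrix(t2$nodes[, c("x", "y", "z")])
    seg_len <- sqrt(rowSums((pos[cand, , drop = FALSE] -
                               pos[parent_row[cand], , drop = FALSE])^2))
    short <- seg_len < threshold
    if (!any(short)) break
    # remove the shortest trivial pass-through node; child reconnects to grandparent
    victim <- cand[which.min(ifelse(short, seg_len, Inf))]
    child <- t2$children[[victim]]
    nodes <- t2$nodes
    nodes$parent[child] <- nodes$parent[victim]
    nodes <- nodes[-victim, , drop = FALSE]
  }
  neuron_tree(nodes)
}

#' Generate synthetic neuronal morphologies
#'
#' Deterministic fixture morphologies at realistic micrometer scales:
#' straight cables, Y-bifurcations with a controlled branch angle, and
#' random binary trees with tapering radii. Radii are monotonically
#' non-increasing from the soma along every path.
#'
#' @param kind one of `"cable"`, `"bifurcation"`, `"random_binary"`.
#' @param nodes total number of skeleton nodes (cable and random_binary).
#' @param step segment length in micrometers (default 5).
#' @param soma_radius radius of the root node in micrometers.
#' @param radius neurite radius in micrometers; for `"cable"` every node gets
#'   this radius (and `soma_radius` defaults to it, giving a uniform cylinder).
#' @param taper multiplicative radius decay per segment, in (0, 1]; radii
#'   never fall below `0.4 * radius`.
#' @param theta branch angle in degrees (bifurcation only).
#' @param trunk_nodes number of trunk nodes before the fork (bifurcation).
#' @param branch_nodes nodes per daughter branch (bifurcation).
#' @param seed integer seed; the same seed gives a byte-identical SWC
#'   serialization.
#' @return A [neuron_tree()].
#' @export
synth_morphology <- function(kind = c("cable", "bifurcation", "random_binary"),
                             nodes = 10L, step = 5, soma_radius = NULL,
                             radius = 2, taper = 1, theta = 90,
                             trunk_nodes = 4L, branch_nodes = 4L, seed = 1L) {
  kind <- match.arg(kind)
  if (taper <= 0) stop("taper must be > 0")
  if (taper > 1) stop("taper must be <= 1 (radii are non-increasing from the soma)")
  if (step <= 0) stop("step must be > 0")
  if (radius <= 0) stop("radius must be > 0")
  r_floor <- 0.4 * radius

  if (kind == "cable") {
    if (is.null(soma_radius)) soma_radius <- radius
    n <- as.integer(nodes)
    if (n < 2L) stop("cable needs at least 2 nodes")
    r <- c(soma_radius, pmax(r_floor, radius * taper^(seq_len(n - 1L) - 1L)))
    r <- cummin(r) # enforce non-increasing when soma_radius < radius
    df <- data.frame(
      id = seq_len(n), type = c(1L, rep(3L, n - 1L)),
      x = (seq_len(n) - 1L) * step, y = 0, z = 0,
      radius = r, parent = c(-1L, seq_len(n - 1L))
    )
    return(neuron_tree(df))
  }

  if (kind == "bifurcation") {
    if (is.null(soma_radius)) soma_radius <- 2 * radius
    if (theta <= 0 || theta >= 180) stop("theta must lie in (0, 180) degrees")
    tn <- as.integer(trunk_nodes)
    bn <- as.integer(branch_nodes)
    if (tn < 2L || bn < 1L) stop("need trunk_nodes >= 2 and branch_nodes >= 1")
    ids <- xs <- ys <- rs <- ps <- c()
    # trunk along +x
    for (i in seq_len(tn)) {
      ids <- c(ids, i)
      xs <- c(xs, (i - 1L) * step); ys <- c(ys, 0)
      rs <- c(rs, if (i == 1L) soma_radius else max(r_floor, radius * taper^(i - 2L)))
      ps <- c(ps, if (i == 1L) -1L else i - 1L)
    }
    fork <- tn
    half <- theta / 2 * pi / 180
    nid <- tn
    for (side in c(1, -1)) {
      prev <- fork
      for (j in seq_len(bn)) {
        nid <- nid + 1L
        ids <- c(ids, nid)
        xs <- c(xs, xs[fork] + j * step * cos(half))
        ys <- c(ys, side * j * step * sin(half))
        rs <- c(rs, max(r_floor, radius * taper^(tn - 2L + j)))
        ps <- c(ps, prev)
        prev <- nid
      }
    }
    rs <- pmin(rs, c(soma_radius, rep(Inf, length(rs) - 1L)))
    df <- data.frame(
      id = ids, type = c(1L, rep(3L, length(ids) - 1L)),
      x = xs, y = ys, z = 0, radius = rs, parent = ps
    )
    return(neuron_tree(df))
  }

  # random binary tree
  if (is.null(soma_radius)) soma_radius <- 2.5 * radius
  n <- as.integer(nodes)
  if (n < 2L) stop("random_binary needs at least 2 nodes")
  set.seed(as.integer(seed))
  pos <- matrix(0, n, 3L)
  rad <- numeric(n); rad[1L] <- soma_radius
  par <- integer(n); par[1L] <- -1L
  dir <- matrix(0, n, 3L)
  n_children <- integer(n)
  # first neurite node leaves the soma in a random direction
  d0 <- stats::rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
  pos[2L, ] <- pos[1L, ] + step * d0
  dir[2L, ] <- d0
  rad[2L] <- radius
  par[2L] <- 1L
  n_children[1L] <- 1L
  for (i in 3:n) {
    # extendable: non-soma nodes with < 2 children (tips extend, others fork)
    cand <- which(n_children[2:(i - 1L)] < 2L) + 1L
    w <- ifelse(n_children[cand] == 0L, 4, 1) # prefer extending tips over forking
    p <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
    # new direction: parent direction perturbed; forks deviate harder
    jitter <- stats::rnorm(3, sd = if (n_children[p] == 0L) 0.35 else 0.9)
    d <- dir[p, ] + jitter
    nv <- sqrt(sum(d^2))
    if (nv < 1e-9) d <- dir[p, ] else d <- d / nv
    pos[i, ] <- pos[p, ] + step * d
    dir[i, ] <- d
    rad[i] <- max(r_floor, rad[p] * if (p == 1L) 1 else taper)
    rad[i] <- min(rad[i], if (p == 1L) radius else rad[p])
    par[i] <- p
    n_children[p] <- n_children[p] + 1L
  }
  df <- data.frame(
    id = seq_len(n), type = c(1L, rep(3L, n - 1L)),
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    radius = rad, parent = par
  )
  neuron_tree(df)
}

#' Standard synthetic-morphology validation batch
#'
#' A fixed, deterministic batch of 20 morphologies used to validate the
#' meshing pipeline: five straight cables of increasing length, six
#' Y-bifurcations with branch angles cycling through 45, 90 and 135
#' degrees, and nine random binary trees of 10-100 nodes. Each batch
#' member is generated with its own seed, so the batch is reproducible
#' element by element.
#'
#' @param seeds integer seeds, one morphology per seed (default 1:20).
#' @return Named list of [neuron_tree()] objects.
#' @export
morphology_batch <- function(seeds = 1:20) {
  out <- list()
  thetas <- c(45, 90, 135)
  for (s in seeds) {
    tree <- if (s <= 5L) {
      synth_morphology("cable", nodes = 7L + s, step = 5, radius = 2, seed = s)
    } else if (s <= 11L) {
      synth_morphology("bifurcation", theta = thetas[(s - 6L) %% 3L + 1L],
                       trunk_nodes = 4L, branch_nodes = 4L, step = 5,
                       radius = 2, taper = 0.95, seed = s)
    } else {
      synth_morphology("random_binary", nodes = 10L + (s * 37L) %% 91L,
                       step = 5, radius = 2, taper = 0.92, seed = s)
    }
    out[[sprintf("seed%02d", s)]] <- tree
  }
  out
}
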