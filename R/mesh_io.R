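#' Export a membrane mesh
#'
#' Writes Wavefront OBJ (1-based `v`/`f` lines), ascii PLY, or ascii STL.
#' Positions are written with 6 decimals, enough for micrometer-scale
#' neuronal geometry; re-importing an OBJ reproduces counts and positions
#' to that precision. The OBJ is what tetrahedral meshers such as TetGen
#' ingest as a surface.
#'
#' @param mesh a `membrane_mesh`.
#' @param path output file path; when `NULL` the text lines are returned.
#' @param format `"obj"`, `"ply"` or `"stl"`; inferred from the path
#'   extension when omitted.
#' @return The text lines, invisibly when written to a file.
#' @export
write_mesh <- function(mesh, path = NULL, format = NULL) {
  cm <- mesh_faces(mesh)
  V <- cm$V
  F <- cm$F
  if (is.null(format)) {
    if (is.null(path)) stop("need `format` when `path` is NULL")
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(tolower(format), c("obj", "ply", "stl"))
  lines <- switch(format,
    obj = c(
      sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]),
      sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])
    ),
    ply = c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(V)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(F)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]),
      sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
    ),
    stl = {
      a <- V[F[, 1], , drop = FALSE]
      b <- V[F[, 2], , drop = FALSE]
      cc <- V[F[, 3], , drop = FALSE]
      u <- b - a
      w <- cc - a
      n <- cbind(
        u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1]
      )
      nn <- sqrt(rowSums(n^2))
      nn[nn == 0] <- 1
      n <- n / nn
      body <- as.vector(rbind(
        sprintf("facet normal %.6f %.6f %.6f", n[, 1], n[, 2], n[, 3]),
        "  outer loop",
        sprintf("    vertex %.6f %.6f %.6f", a[, 1], a[, 2], a[, 3]),
        sprintf("    vertex %.6f %.6f %.6f", b[, 1], b[, 2], b[, 3]),
        sprintf("    vertex %.6f %.6f %.6f", cc[, 1], cc[, 2], cc[, 3]),
        "  endloop",
        "endfacet"
      ))
      c("solid membrane", body, "endsolid membrane")
    }
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a Wavefront OBJ triangle mesh
#'
#' Minimal OBJ reader for round-trips and audits: `v` and `f` records only;
#' `f` entries may carry `/vt/vn` suffixes, which are ignored.
#'
#' @param path file path (or character vector of OBJ lines).
#' @return List with `V` (n x 3) and `F` (m x 3, 1-based).
#' @export
read_obj <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("OBJ has no v/f records")
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*$", "", x))
    if (length(idx) != 3L) stop("only triangle faces are supported")
    idx
  }))
  list(V = V, F = F)
}

#' Topology checks on a raw face list
#'
#' Connectivity checks that do not require building a halfedge structure,
#' for auditing meshes from external files: watertight (every undirected
#' edge borders exactly two faces) and 2-manifold (watertight, opposite
#' orientations across each edge, and every vertex's face fan forms a
#' single cycle).
#'
#' @param F integer m x 3 face matrix (1-based).
#' @return List with logical `watertight` and `manifold`.
#' @export
check_face_soup <- function(F) {
  F <- as.matrix(F)
  a <- as.vector(F[, c(1, 2, 3)])
  b <- as.vector(F[, c(2, 3, 1)])
  key <- paste(pmin(a, b), pmax(a, b))
  cnt <- table(key)
  watertight <- all(cnt == 2L)
  manifold <- watertight
  if (manifold) {
    dir_key <- paste(a, b)
    if (anyDuplicated(dir_key)) {
      manifold <- FALSE # two faces traverse an edge the same way
    } else {
      # single-fan test: per vertex, incident faces must chain into one cycle
      nv <- max(F)
      nxt <- split(b, a) # at vertex v, each face maps one neighbour to the next
      prv <- split(a, b)
      for (v in seq_len(nv)) {
        outs <- nxt[[as.character(v)]]
        ins <- prv[[as.character(v)]]
        if (is.null(outs) && is.null(ins)) next
        # around v each incident face (v, x, y) contributes x -> y; a single
        # fan means these arrows form exactly one cycle
        fidx <- which(F[, 1] == v | F[, 2] == v | F[, 3] == v)
        arrows_from <- arrows_to <- integer(length(fidx))
        for (i in seq_along(fidx)) {
          tri <- F[fidx[i], ]
          k <- which(tri == v)
          arrows_from[i] <- tri[k %% 3 + 1]
          arrows_to[i] <- tri[(k + 1) %% 3 + 1]
        }
        m <- stats::setNames(arrows_to, arrows_from)
        start <- arrows_from[1]
        cur <- start
        steps <- 0L
        repeat {
          nxt_v <- m[[as.character(cur)]]
          if (is.null(nxt_v) || is.na(nxt_v)) { manifold <- FALSE; break }
          steps <- steps + 1L
          cur <- nxt_v
          if (cur == start) break
          if (steps > length(fidx)) { manifold <- FALSE; break }
        }
        if (!manifold) break
        if (steps != length(fidx)) { manifold <- FALSE; break }
      }
    }
  }
  list(watertight = watertight, manifold = manifold)
}
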