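# Polyhedral core lattices: vertices are trimer sites, edges are the twofold
# bridge interfaces between neighbouring trimers.

#' Construct a polyhedral core lattice
#'
#' Builds the trimer-site graph of a polyhedral enzyme core.  Vertices stand
#' for trimers of the core-forming domain (three subunits each) and edges for
#' the twofold bridge interfaces that connect neighbouring trimers; each edge
#' is one binding pocket for an interior-protein binding helix.
#'
#' Two cores are built in:
#' \describe{
#'   \item{`"icosahedral-60mer"`}{the dodecahedral lattice of the icosahedral
#'     60-subunit E2 core: 20 trimer vertices, 30 bridge edges.  Vertex
#'     coordinates are the standard golden-ratio dodecahedron
#'     \eqn{(\pm 1,\pm 1,\pm 1)}, \eqn{(0,\pm 1/\varphi,\pm\varphi)} and
#'     cyclic permutations, normalised to unit length.}
#'   \item{`"octahedral-24mer"`}{the cube lattice of an octahedral 24-subunit
#'     core: 8 trimer vertices, 12 edges.}
#' }
#' Vertex ids are assigned by lexicographic sort of the rounded unit-sphere
#' coordinates (x, then y, then z), so the indexing is reproducible across
#' sessions and platforms.
#'
#' Alternatively `name` may be the path of a JSON polyhedron
#' `{"coords": [[x,y,z], ...], "edges": [[i,j], ...]}` with 0-based vertex
#' ids.  Coordinates are normalised to the unit sphere; the edge list must
#' coincide with the nearest-neighbour pairs of the (normalised) coordinates,
#' i.e. all edges have the same length and every minimal-separation pair is
#' an edge.  If `"edges"` is omitted it is derived from the coordinates.
#'
#' @param name `"icosahedral-60mer"`, `"octahedral-24mer"`, or the path to a
#'   JSON polyhedron file.
#' @param n_subunits_per_vertex subunits per trimer site (default 3); only
#'   used for user polyhedra, the built-ins are trimeric.
#'
#' @return A `CoreLattice`: a list with elements `name`, `n_vertices`,
#'   `n_subunits_per_vertex`, `edges` (two-column matrix, `i < j`), `coords`
#'   (`n_vertices` x 3 matrix of unit vectors), and `dist` (integer matrix of
#'   all-pairs graph distances).
#' @examples
#' core <- build_core("icosahedral-60mer")
#' core$n_vertices                      # 20 trimer sites
#' nrow(core$edges)                     # 30 bridge binding pockets
#' core$n_vertices * core$n_subunits_per_vertex  # 60 E2 subunits
#' @export
build_core <- function(name, n_subunits_per_vertex = 3L) {
  if (identical(name, "icosahedral-60mer")) {
    coords <- dodecahedron_coords()
    edges <- NULL
  } else if (identical(name, "octahedral-24mer")) {
    coords <- cube_coords()
    edges <- NULL
  } else if (is.character(name) && length(name) == 1L && file.exists(name)) {
    poly <- read_polyhedron_json(name)
    coords <- poly$coords
    edges <- poly$edges
    name <- poly$name
  } else {
    stop("unknown core lattice identifier: ", name,
         " (expected \"icosahedral-60mer\", \"octahedral-24mer\", ",
         "or a JSON polyhedron path)")
  }
  new_core_lattice(name, coords, edges = edges,
                   n_subunits_per_vertex = as.integer(n_subunits_per_vertex))
}

dodecahedron_coords <- function() {
  phi <- (1 + sqrt(5)) / 2
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  rect <- NULL
  for (a in c(-1, 1) / phi) {
    for (b in c(-1, 1) * phi) {
      rect <- rbind(rect, c(0, a, b), c(a, b, 0), c(b, 0, a))
    }
  }
  coords <- rbind(unname(cube), rect)
  coords / sqrt(rowSums(coords^2))
}

cube_coords <- function() {
  coords <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  unname(coords) / sqrt(3)
}

#' @keywords internal
read_polyhedron_json <- function(path) {
  poly <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(poly$coords)) {
    stop("polyhedron JSON must contain a \"coords\" array")
  }
  coords <- as.matrix(poly$coords)
  if (ncol(coords) != 3L) stop("polyhedron coords must be n x 3")
  edges <- NULL
  if (!is.null(poly$edges)) {
    edges <- as.matrix(poly$edges) + 1L  # 0-based on disk
    storage.mode(edges) <- "integer"
  }
  list(name = if (!is.null(poly$name)) poly$name else basename(path),
       coords = coords, edges = edges)
}

# Assemble and validate a CoreLattice from coordinates (+ optional edge list).
new_core_lattice <- function(name, coords, edges = NULL,
                             n_subunits_per_vertex = 3L) {
  coords <- coords / sqrt(rowSums(coords^2))
  n <- nrow(coords)
  # reproducible vertex indexing: lexicographic sort of rounded coordinates
  ord <- do.call(order, as.data.frame(round(coords, 6)))
  coords <- coords[ord, , drop = FALSE]
  if (!is.null(edges)) {
    inv <- integer(n)
    inv[ord] <- seq_len(n)
    edges <- cbind(inv[edges[, 1]], inv[edges[, 2]])
  }

  sep <- as.matrix(stats::dist(coords))
  if (min(sep[upper.tri(sep)]) < 1e-8) {
    stop("polyhedron coordinates are not pairwise distinct on the unit sphere")
  }
  dmin <- min(sep[sep > 1e-8])
  near <- which(sep < dmin * (1 + 1e-6) & sep > 1e-8, arr.ind = TRUE)
  near <- near[near[, 1] < near[, 2], , drop = FALSE]
  derived <- near[order(near[, 1], near[, 2]), , drop = FALSE]

  if (is.null(edges)) {
    edges <- derived
  } else {
    edges <- t(apply(edges, 1, sort))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (!identical(dim(edges), dim(derived)) || !all(edges == derived)) {
      stop("polyhedron edge list is inconsistent with the coordinates: ",
           "edges must be exactly the constant nearest-neighbour pairs ",
           "(non-constant nearest-neighbour distance or missing/extra edges)")
    }
  }
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (!igraph::is_connected(g)) stop("polyhedron graph is not connected")
  dist <- igraph::distances(g)
  storage.mode(dist) <- "integer"
  dimnames(dist) <- NULL

  structure(
    list(name = name,
         n_vertices = n,
         n_subunits_per_vertex = as.integer(n_subunits_per_vertex),
         edges = edges,
         coords = coords,
         dist = dist),
    class = "CoreLattice")
}

#' @export
print.CoreLattice <- function(x, ...) {
  cat(sprintf("CoreLattice \"%s\": %d trimer sites (%d subunits), %d bridge edges\n",
              x$name, x$n_vertices,
              x$n_vertices * x$n_subunits_per_vertex, nrow(x$edges)))
  invisible(x)
}

#' Graph distance between two trimer sites
#'
#' Shortest-path length between vertices `u` and `v` in the lattice graph.
#' The steric-exclusion rule for interior trimers is phrased in this metric:
#' two occupied sites at graph distance 2 have one intermediate trimer
#' between them, at distance 3 two intermediate trimers, and so on.
#'
#' @param core a [`build_core()`] lattice.
#' @param u,v vertex ids in `1:core$n_vertices`.
#' @return non-negative integer distance; 0 iff `u == v`.
#' @export
graph_distance <- function(core, u, v) {
  stopifnot(inherits(core, "CoreLattice"))
  check_vertex_ids(core, c(u, v))
  core$dist[u, v]
}

check_vertex_ids <- function(core, ids) {
  ids <- as.integer(ids)
  if (anyNA(ids) || any(ids < 1L) || any(ids > core$n_vertices)) {
    stop("invalid vertex id(s); expected integers in 1..", core$n_vertices)
  }
  ids
}

#' Proper rotation group of a core lattice
#'
#' Enumerates every orientation-preserving rigid rotation that maps the
#' vertex coordinate set onto itself, paired with the vertex permutation it
#' induces.  Reflections and the central inversion are excluded: the core
#' scaffold has a fixed handedness, so only determinant +1 operations are
#' physical symmetries.
#'
#' Candidate rotations are generated by mapping a reference vertex and one of
#' its neighbours to every compatible image pair, completing each pair to a
#' right-handed orthonormal frame; a candidate is kept iff it permutes the
#' vertex set (coordinate match within 1e-9).  For the dodecahedral lattice
#' this yields the icosahedral rotation group I (order 60), for the cube
#' lattice the octahedral rotation group O (order 24).
#'
#' @param core a [`build_core()`] lattice.
#' @return A `RotationGroup`: list with `elements` (each a list with `perm`,
#'   an integer permutation such that vertex `i` maps to `perm[i]`, and
#'   `mat`, the 3x3 rotation matrix) and `order`.  Element 1 is always the
#'   identity; the remaining elements are in a deterministic order.
#' @examples
#' g <- rotation_group(build_core("icosahedral-60mer"))
#' g$order  # 60
#' @export
rotation_group <- function(core) {
  stopifnot(inherits(core, "CoreLattice"))
  co <- core$coords
  n <- core$n_vertices
  nbrs <- neighbour_list(core)

  frame_of <- function(a, b) {
    u1 <- co[a, ]
    u2 <- co[b, ] - sum(co[b, ] * u1) * u1
    u2 <- u2 / sqrt(sum(u2^2))
    cbind(u1, u2, cross3(u1, u2), deparse.level = 0)
  }
  a0 <- 1L
  b0 <- nbrs[[1L]][1L]
  f0t <- t(frame_of(a0, b0))

  elements <- list()
  seen <- character(0)
  for (a in seq_len(n)) {
    for (b in nbrs[[a]]) {
      rot <- frame_of(a, b) %*% f0t
      perm <- permutation_of(rot, co, tol = 1e-9)
      if (is.null(perm)) next
      if (abs(det(rot) - 1) > 1e-9) next
      key <- paste(perm, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      elements[[length(elements) + 1L]] <- list(perm = perm, mat = rot)
    }
  }
  id <- which(vapply(elements, function(e) all(e$perm == seq_len(n)), logical(1)))
  if (length(id) != 1L) {
    # trivial group for asymmetric user polyhedra
    elements <- c(list(list(perm = seq_len(n), mat = diag(3))), elements)
    id <- 1L
  }
  elements <- c(elements[id], elements[-id])
  structure(list(elements = elements, order = length(elements),
                 core_name = core$name),
            class = "RotationGroup")
}

#' @export
print.RotationGroup <- function(x, ...) {
  cat(sprintf("RotationGroup of \"%s\": order %d\n", x$core_name, x$order))
  invisible(x)
}

neighbour_list <- function(core) {
  lapply(seq_len(core$n_vertices), function(v) {
    sort(c(core$edges[core$edges[, 1] == v, 2],
           core$edges[core$edges[, 2] == v, 1]))
  })
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Vertex permutation induced by matrix `rot` on coordinate rows, or NULL if
# `rot` does not map the vertex set onto itself within `tol`.
permutation_of <- function(rot, coords, tol = 1e-9) {
  img <- coords %*% t(rot)
  n <- nrow(coords)
  perm <- integer(n)
  for (i in seq_len(n)) {
    d2 <- rowSums((coords - matrix(img[i, ], n, 3, byrow = TRUE))^2)
    j <- which.min(d2)
    if (d2[j] > tol^2) return(NULL)
    perm[i] <- j
  }
  if (anyDuplicated(perm)) return(NULL)
  perm
}

#' Vertex permutation of the central inversion
#'
#' Returns the permutation mapping every vertex to its antipode
#' (coordinates `x` to `-x`), or `NULL` if the vertex set is not
#' centrosymmetric.  The inversion is an automorphism of the lattice graph
#' but is *not* a member of [`rotation_group()`] (determinant -1): it is the
#' operation that exchanges the two mirror-related tetrahedral occupancy
#' classes, and serves as a negative control for the handedness restriction.
#'
#' @param core a [`build_core()`] lattice.
#' @return integer permutation or `NULL`.
#' @export
inversion_map <- function(core) {
  stopifnot(inherits(core, "CoreLattice"))
  permutation_of(-diag(3), core$coords, tol = 1e-9)
}
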