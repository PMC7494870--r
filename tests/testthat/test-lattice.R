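test_that("built-in lattices satisfy their geometric invariants", {
  for (core in list(dodeca, cube)) {
    n <- core$n_vertices
    expect_equal(nrow(core$edges), 3L * n %/% 2L)  # 3-regular
    expect_equal(sort(unique(tabulate(core$edges, nbins = n))), 3L)
    expect_equal(unname(rowSums(core$coords^2)), rep(1, n), tolerance = 1e-12)
    # adjacency iff minimal Euclidean separation
    sep <- as.matrix(dist(core$coords))
    dmin <- min(sep[sep > 1e-8])
    adj <- matrix(FALSE, n, n)
    adj[core$edges] <- TRUE
    adj <- adj | t(adj)
    expect_identical(unname(adj), unname(sep < dmin * (1 + 1e-6) & sep > 1e-8))
    # connected: every pairwise graph distance is finite
    expect_true(all(is.finite(core$dist)))
  }
  expect_equal(dodeca$n_vertices, 20L)
  expect_equal(dodeca$n_vertices * dodeca$n_subunits_per_vertex, 60L)
  expect_equal(cube$n_vertices, 8L)
  expect_equal(cube$n_vertices * cube$n_subunits_per_vertex, 24L)
  expect_error(build_core("icosahedral-61mer"), "unknown core lattice")
})

test_that("dodecahedral graph distances match the known shell profile", {
  # 3, 6, 6, 3, 1 vertices at graph distance 1..5 from every vertex
  for (v in seq_len(20)) {
    expect_equal(unname(tabulate(dodeca$dist[v, ], nbins = 5)),
                 c(3L, 6L, 6L, 3L, 1L))
  }
  expect_equal(max(dodeca$dist), 5L)  # diameter; antipodal pairs
  expect_equal(graph_distance(dodeca, 7, 7), 0L)
  e <- dodeca$edges[1, ]
  expect_equal(graph_distance(dodeca, e[1], e[2]), 1L)
  expect_identical(dodeca$dist, t(dodeca$dist))
  expect_error(graph_distance(dodeca, 0, 3), "invalid vertex")
  expect_error(graph_distance(dodeca, 1, 21), "invalid vertex")
})

test_that("rotation groups have the right order and group structure", {
  expect_equal(dodeca_group$order, 60L)
  expect_equal(cube_group$order, 24L)
  # identity first
  expect_equal(dodeca_group$elements[[1]]$perm, 1:20)
  expect_equal(unname(dodeca_group$elements[[1]]$mat), diag(3))
  for (grp in list(dodeca_group, cube_group)) {
    keys <- vapply(grp$elements, function(e) paste(e$perm, collapse = ","),
                   character(1))
    expect_false(anyDuplicated(keys) > 0)
    for (e in grp$elements) {
      # proper orthogonal matrices
      expect_equal(unname(crossprod(e$mat)), diag(3), tolerance = 1e-9)
      expect_equal(det(e$mat), 1, tolerance = 1e-9)
      # inverse present
      inv <- order(e$perm)
      expect_true(paste(inv, collapse = ",") %in% keys)
    }
    # closure on a deterministic subsample of pairs (full closure is
    # exercised for stabilizers inside point_group_label)
    idx <- seq(1, grp$order, by = 7)
    for (a in grp$elements[idx]) {
      for (b in grp$elements[idx]) {
        expect_true(paste(a$perm[b$perm], collapse = ",") %in% keys)
      }
    }
  }
})

test_that("group order equals half the graph automorphism count", {
  # the full graph automorphism group includes the improper operations;
  # both built-in lattices are centrosymmetric, so proper rotations are
  # exactly half
  for (case in list(list(dodeca, dodeca_group), list(cube, cube_group))) {
    g <- igraph::graph_from_edgelist(case[[1]]$edges, directed = FALSE)
    n_aut <- as.numeric(igraph::count_automorphisms(g)$group_size)
    expect_equal(case[[2]]$order * 2, n_aut)
  }
})

test_that("every rotation preserves edges and the distance table", {
  for (e in dodeca_group$elements) {
    p <- e$perm
    img <- cbind(pmin(p[dodeca$edges[, 1]], p[dodeca$edges[, 2]]),
                 pmax(p[dodeca$edges[, 1]], p[dodeca$edges[, 2]]))
    img <- img[order(img[, 1], img[, 2]), ]
    expect_identical(unname(img), unname(dodeca$edges))
    expect_identical(dodeca$dist[p, p], dodeca$dist)
  }
})

test_that("the central inversion is excluded despite fixing the vertex set", {
  inv <- inversion_map(dodeca)
  expect_false(is.null(inv))  # the dodecahedron is centrosymmetric
  keys <- vapply(dodeca_group$elements,
                 function(e) paste(e$perm, collapse = ","), character(1))
  expect_false(paste(inv, collapse = ",") %in% keys)
  # yet it is a graph automorphism: appending it would start doubling the group
  expect_identical(dodeca$dist[inv, inv], dodeca$dist)
})

test_that("user JSON polyhedra are read, validated and rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  write_tetrahedron_json(path)
  tet <- build_core(path)
  expect_equal(tet$n_vertices, 4L)
  expect_equal(nrow(tet$edges), 6L)
  expect_equal(rotation_group(tet)$order, 12L)  # tetrahedral rotations

  # rectangle on the unit sphere: nearest-neighbour distance is not
  # constant, so the claimed 4-cycle edge list is inconsistent
  bad <- withr::local_tempfile(fileext = ".json")
  coords <- rbind(c(2, 1, 0), c(2, -1, 0), c(-2, 1, 0), c(-2, -1, 0))
  jsonlite::write_json(list(coords = coords / sqrt(5),
                            edges = rbind(c(0, 1), c(0, 2), c(1, 3), c(2, 3))),
                       bad, digits = 12)
  expect_error(build_core(bad), "inconsistent|connected")
})
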