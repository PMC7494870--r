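rule2 <- exclusion_rule(2)
rule3 <- exclusion_rule(3)

test_that("validity is the pairwise graph-distance predicate", {
  e <- dodeca$edges[5, ]
  expect_false(is_valid(e, rule3, dodeca))   # adjacent pair
  expect_true(is_valid(e, exclusion_rule(1), dodeca))
  # the 8 vertices of an inscribed coordinate cube are pairwise at graph
  # distance 2: valid without occlusion, invalid with it
  cube_verts <- which(apply(abs(abs(dodeca$coords) -
                                  1 / sqrt(3)) < 1e-9, 1, all))
  expect_length(cube_verts, 8L)
  expect_true(is_valid(cube_verts, rule2, dodeca))
  expect_false(is_valid(cube_verts, rule3, dodeca))
  expect_true(is_valid(integer(0), rule3, dodeca))
  expect_true(is_valid(13L, rule3, dodeca))
  expect_error(is_valid(c(1, 99), rule3, dodeca), "invalid vertex")
  # agreement with the unpruned brute-force oracle on random subsets
  set.seed(11)
  for (i in 1:200) {
    occ <- sample(20, sample(0:6, 1))
    for (md in 2:3) {
      expect_equal(is_valid(occ, exclusion_rule(md), dodeca),
                   bf_valid(occ, md, dodeca))
    }
  }
})

test_that("exhaustive enumeration counts match brute force over subsets", {
  # occluding rule: 1, 20, 100, 100, 10 valid occupancies of sizes 0..4
  expect_length(enumerate_valid(dodeca, rule3, size = 2), 100L)
  expect_length(enumerate_valid(dodeca, rule3, size = 4), 10L)
  expect_length(enumerate_valid(dodeca, rule3, size = 5), 0L)
  all3 <- enumerate_valid(dodeca, rule3)
  expect_equal(unname(table(lengths(all3))), c(1L, 20L, 100L, 100L, 10L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(vapply(all3, paste, character(1),
                                    collapse = ",")) > 0)
  # against the combn oracle at each size
  for (k in 0:5) {
    expect_equal(length(enumerate_valid(dodeca, rule3, size = k)),
                 length(bf_enumerate(dodeca, 3, k)))
  }
  # non-occluding rule: independent sets; maximum size 8
  all2 <- enumerate_valid(dodeca, rule2)
  expect_equal(max(lengths(all2)), 8L)
  expect_length(enumerate_valid(dodeca, rule2, size = 8), 5L)
  expect_length(enumerate_valid(dodeca, rule2, size = 9), 0L)
  # monotonicity: occluding-valid sets are a subset of non-occluding-valid
  k2 <- vapply(all2, paste, character(1), collapse = ",")
  k3 <- vapply(all3, paste, character(1), collapse = ",")
  expect_true(all(k3 %in% k2))
})

test_that("the ten maximal occupancies form two tetrahedral mirror classes", {
  cfg4 <- enumerate_valid(dodeca, rule3, size = 4)
  cls <- classify(cfg4, dodeca_group, rule3, dodeca)
  expect_equal(nrow(cls), 2L)
  expect_equal(cls$orbit_size, c(5L, 5L))
  expect_equal(cls$stabilizer_order, c(12L, 12L))
  expect_equal(cls$point_group, c("T", "T"))
  expect_true(all(cls$jammed))
  # rotation-inequivalent ...
  expect_false(cls$canonical_key[1] == cls$canonical_key[2])
  # ... but exchanged by the central inversion (mirror pair)
  inv <- inversion_map(dodeca)
  mirrored <- canonical_form(inv[cls$canonical[[1]]], dodeca_group)
  expect_identical(mirrored, cls$canonical[[2]])
  # minimum pairwise distance within each maximal arrangement is exactly 3
  for (occ in cfg4) {
    d <- dodeca$dist[occ, occ]
    expect_equal(min(d[upper.tri(d)]), 3L)
  }
})

test_that("classification agrees with naive pairwise orbit testing", {
  all3 <- enumerate_valid(dodeca, rule3)
  cls <- classify(all3, dodeca_group, rule3, dodeca)
  bf <- bf_orbit_partition(all3, dodeca_group)
  expect_equal(nrow(cls), length(bf$representatives))
  # same partition sizes, matched through canonical forms
  bf_sizes <- table(vapply(bf$representatives[bf$assignment], function(s)
    corelattice:::occ_key(canonical_form(s, dodeca_group)), character(1)))
  expect_equal(cls$n_labeled,
               unname(as.integer(bf_sizes[cls$canonical_key])))
})

test_that("orbit-stabilizer and orbit-partition identities hold", {
  for (case in list(list(rule3, dodeca, dodeca_group, 60L),
                    list(rule2, cube, cube_group, 24L))) {
    cls <- configuration_classes(case[[2]], case[[1]], group = case[[3]])
    expect_true(all(cls$orbit_size * cls$stabilizer_order == case[[4]]))
    # orbit sizes at each size sum to the labelled enumeration count
    for (s in unique(cls$size)) {
      expect_equal(sum(cls$orbit_size[cls$size == s]),
                   length(enumerate_valid(case[[2]], case[[1]], size = s)))
    }
    expect_equal(cls$n_labeled, cls$orbit_size)  # full enumeration input
  }
})

test_that("point-group labels follow the element-order census", {
  # the empty occupancy is fixed by the whole icosahedral group
  cls0 <- classify(list(integer(0)), dodeca_group, rule3, dodeca)
  expect_equal(cls0$point_group, "I")
  expect_equal(cls0$stabilizer_order, 60L)
  expect_equal(point_group_label(dodeca_group$elements), "I")
  expect_equal(point_group_label(cube_group$elements), "O")
  expect_equal(point_group_label(dodeca_group$elements[1]), "C1")
  # antipodal pair: threefold axis through both plus three perpendicular
  # twofolds -> D3 (brute-force stabilizer, order 6)
  inv <- inversion_map(dodeca)
  pair <- classify(list(c(1L, inv[1])), dodeca_group, rule3, dodeca)
  expect_equal(pair$stabilizer_order, 6L)
  expect_equal(pair$point_group, "D3")
  # one pentagonal face -> C5; face plus its antipodal face -> D5
  face <- dodeca_face()
  cls_face <- classify(list(face), dodeca_group, NULL, dodeca)
  expect_equal(cls_face$point_group, "C5")
  cls_faces <- classify(list(c(face, inv[face])), dodeca_group, NULL, dodeca)
  expect_equal(cls_faces$point_group, "D5")
  # alternating cube vertices on the cube lattice -> tetrahedral T
  tet <- which(apply(cube$coords, 1, prod) > 0)
  cls_tet <- classify(list(tet), cube_group, NULL, cube)
  expect_equal(cls_tet$point_group, "T")
  expect_error(point_group_label(dodeca_group$elements[2]),
               "identity")
  expect_error(point_group_label(dodeca_group$elements[c(1, 2)]),
               "not closed")
})

test_that("jamming distinguishes suboptimal from unsaturated states", {
  inv <- inversion_map(dodeca)
  # antipodal pair: the two exclusion balls cover all 20 vertices
  expect_true(is_jammed(c(1L, inv[1]), rule3, dodeca))
  cfg4 <- enumerate_valid(dodeca, rule3, size = 4)
  for (occ in cfg4) {
    expect_true(is_jammed(occ, rule3, dodeca))
    # any 3-subset of a tetrahedral arrangement is unsaturated: the fourth
    # vertex remains addable
    for (drop in seq_along(occ)) {
      expect_false(is_jammed(occ[-drop], rule3, dodeca))
    }
  }
  expect_error(is_jammed(dodeca$edges[1, ], rule3, dodeca), "not valid")
})

test_that("aliases name saturated, suboptimal and unsaturated classes", {
  cls <- configuration_classes(dodeca, rule3)
  byalias <- function(a) cls[!is.na(cls$alias) & cls$alias == a, ]
  expect_equal(byalias("X4S")$size, 4L)
  expect_equal(byalias("Y4S")$size, 4L)
  expect_equal(byalias("2S")$size, 2L)
  expect_equal(byalias("2S")$point_group, "D3")
  expect_equal(byalias("3S")$size, 3L)
  expect_true(byalias("3S")$jammed)
  expect_false(byalias("X3U")$jammed)
  expect_false(byalias("Y3U")$jammed)
  # non-occluding rule: the single size-8 class (the inscribed cube) is
  # jammed and tetrahedral
  cls2 <- configuration_classes(dodeca, rule2)
  c8 <- cls2[cls2$size == 8L, ]
  expect_equal(nrow(c8), 1L)
  expect_equal(c8$alias, "8S")
  expect_equal(c8$point_group, "T")
  expect_equal(c8$orbit_size, 5L)
  expect_true(c8$jammed)
})
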