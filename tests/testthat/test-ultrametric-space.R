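test_that("worked distances on the two-branch three-level tree reproduce", {
  tr <- social_tree(2, 3)
  # pairs differing in the last coordinate only
  expect_equal(label_dist(tr, c(0, 2, 4, 6), c(1, 3, 5, 7)), rep(1L, 4))
  # two-level separations
  expect_equal(label_dist(tr, c(0, 0, 1, 1, 4, 5), c(2, 3, 2, 3, 6, 7)),
               rep(2L, 6))
  # opposite halves of the tree
  expect_equal(label_dist(tr, c(0, 3), c(6, 7)), rep(3L, 2))
  expect_equal(label_dist(tr, 0:7, 0:7), rep(0L, 8))
})

test_that("coordinate encoding matches the positional base-p rule", {
  tr <- social_tree(2, 3)
  expect_equal(encode_label(tr, c(0, 0, 1)), 1)
  expect_equal(encode_label(tr, c(1, 1, 1)), 7)
  expect_equal(encode_label(social_tree(3, 2), c(2, 1)), 7)
  expect_equal(decode_label(tr, 7)[1, ], c(1L, 1L, 1L))
  expect_equal(decode_label(tr, 0)[1, ], c(0L, 0L, 0L))
  expect_equal(decode_label(social_tree(5, 1), 4)[1, ], 4L)
})

test_that("encode and decode are mutually inverse bijections on small trees", {
  for (pn in list(c(2, 3), c(2, 4), c(3, 2), c(3, 3), c(5, 2))) {
    tr <- social_tree(pn[1], pn[2])
    labels <- 0:(tr$n_states - 1)
    cm <- decode_label(tr, labels)
    expect_equal(encode_label(tr, cm), labels)
    expect_equal(nrow(unique(cm)), tr$n_states)
    # agreement with an independent enumeration
    expect_equal(unname(cm), unname(enumerate_coords(tr$p, tr$n)))
  }
})

test_that("the distance is an ultrametric on small trees", {
  for (pn in list(c(2, 3), c(2, 4), c(3, 2), c(3, 3))) {
    tr <- social_tree(pn[1], pn[2])
    S <- tr$n_states
    cm <- decode_label(tr, 0:(S - 1))
    d <- distance_matrix(tr)
    # agrees with the naive longest-common-prefix computation
    for (i in 1:S) for (j in 1:S)
      expect_identical(d[i, j], brute_dist(cm[i, ], cm[j, ]))
    expect_true(all(d == t(d)))
    expect_true(all(d[upper.tri(d)] >= 1 & d[upper.tri(d)] <= tr$n))
    expect_true(all(diag(d) == 0))
    # strong triangle inequality over all triples
    for (k in 1:S) {
      expect_true(all(d <= pmax(matrix(d[, k], S, S), matrix(d[k, ], S, S, byrow = TRUE))))
    }
  }
})

test_that("dimension and range violations are rejected", {
  tr <- social_tree(2, 3)
  expect_error(ultra_dist(tr, c(0, 1), c(0, 0, 1)), "length n")
  expect_error(encode_label(tr, c(0, 0, 2)), "coordinates must lie")
  expect_error(decode_label(tr, 8), "labels must be")
  expect_error(decode_label(tr, -1), "labels must be")
  expect_error(social_tree(1, 3), "p")
  expect_error(social_tree(2, 0), "n")
})

test_that("ball members are exactly the prefix extensions", {
  tr <- social_tree(2, 3)
  expect_equal(ball_members(social_ball(tr))$label, 0:7)
  expect_equal(ball_members(social_ball(tr, c(0)))$label, 0:3)
  expect_equal(ball_members(social_ball(tr, c(1, 1, 1)))$label, 7)
  # brute-force oracle: enumerate all vectors and filter on the prefix
  tr2 <- social_tree(3, 3)
  cm <- enumerate_coords(3, 3)
  for (prefix in list(c(0), c(2), c(1, 0), c(2, 2, 1))) {
    keep <- apply(cm[, seq_along(prefix), drop = FALSE], 1,
                  function(r) all(r == prefix))
    expect_equal(ball_members(social_ball(tr2, prefix))$label,
                 which(keep) - 1)
  }
  expect_error(ball_members(social_ball(tr, c(0, 0, 0, 0))), "prefix longer")
})

test_that("prefix balls of each length partition the space", {
  for (pn in list(c(2, 3), c(3, 2), c(3, 3))) {
    tr <- social_tree(pn[1], pn[2])
    cm <- enumerate_coords(tr$p, tr$n)
    for (k in 0:tr$n) {
      prefixes <- if (k == 0) list(integer(0)) else
        asplit(unique(cm[, seq_len(k), drop = FALSE]), 1)
      all_members <- unlist(lapply(prefixes, function(pf)
        ball_members(social_ball(tr, pf))$label))
      expect_equal(sort(all_members), 0:(tr$n_states - 1))
      expect_equal(length(prefixes), tr$p^k)
    }
  }
})

test_that("subclusters split a ball into p disjoint children", {
  tr <- social_tree(2, 3)
  kids <- ball_children(social_ball(tr, c(0)))
  expect_length(kids, 2)
  expect_equal(lapply(kids, function(b) b$prefix), list(c(0L, 0L), c(0L, 1L)))
  expect_equal(sum(vapply(kids, ball_size, numeric(1))),
               ball_size(social_ball(tr, c(0))))
  kids3 <- ball_children(social_ball(social_tree(3, 2)))
  expect_length(kids3, 3)
  expect_error(ball_children(social_ball(tr, c(1, 1, 1))), "no subcluster")
})

test_that("balls are centre-free and any member reproduces the ball", {
  tr <- social_tree(3, 3)
  b <- social_ball(tr, c(1, 2))
  for (lab in ball_members(b)$label) {
    expect_equal(ball_around(tr, lab, b$radius)$prefix, b$prefix)
  }
  expect_equal(ball_point_dist(b, 0), 3L)
  expect_equal(ball_point_dist(b, ball_members(b)$label[2]), 0L)
})

test_that("Newick export is valid and round-trips leaf counts", {
  expect_match(gsub("[: 0-9.]", "", tree_newick(social_tree(2, 1))), "(,);",
               fixed = TRUE)
  for (pn in list(c(2, 3), c(3, 2))) {
    tr <- social_tree(pn[1], pn[2])
    phy <- ape::read.tree(text = tree_newick(tr))
    expect_equal(ape::Ntip(phy), tr$n_states)
    expect_equal(sort(as.integer(phy$tip.label)), 0:(tr$n_states - 1))
    expect_true(ape::is.ultrametric(phy))
  }
  # barrier-profile branch lengths: root-to-leaf depth stacks Delta_1..Delta_n
  prof <- barrier_profile(delta = 0.5)
  phy <- ape::read.tree(text = tree_newick(social_tree(2, 3), profile = prof))
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  expect_equal(unique(round(depths, 10)), sum(barrier_height(prof, 1:3)))
  expect_error(tree_newick(social_tree(2, 13)), "cap")
})

test_that("distance class sizes count the states at each distance", {
  tr <- social_tree(3, 3)
  cm <- enumerate_coords(3, 3)
  counts <- table(apply(cm, 1, function(r) brute_dist(cm[1, ], r)))
  sizes <- distance_class_sizes(tr)
  expect_equal(sizes$n_states, as.numeric(counts[as.character(1:3)]))
  expect_equal(sum(sizes$n_states) + 1, tr$n_states)
})

test_that("model objects serialise to compact JSON", {
  tr <- social_tree(2, 3)
  expect_equal(jsonlite::fromJSON(uw_json(tr)), list(p = 2L, n = 3L))
  expect_equal(jsonlite::fromJSON(uw_json(social_ball(tr, c(0, 1))))$prefix,
               c(0L, 1L))
  hm <- demo_model()
  parsed <- jsonlite::fromJSON(uw_json(hm))
  expect_equal(parsed$profile$delta, 1)
  expect_equal(parsed$tree$n, 3L)
})
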