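test_that("parsing yields unrooted trees with a suppressed root", {
  tr <- parse_newick("((a,b),(c,d));")
  expect_s3_class(tr, "phylo")
  expect_equal(write_newick(tr), "(a,b,(c,d));")
  expect_identical(write_newick(parse_newick("(a,b,(c,d));")),
                   write_newick(tr))
  # degenerate two-leaf tree is accepted by the parser
  expect_equal(write_newick(parse_newick("(a,b);")), "(a,b);")
})

test_that("malformed input and duplicate labels are rejected", {
  expect_error(parse_newick("((a,b),(c,d))"), "must end with ';'")
  expect_error(parse_newick("((a,b),(c,d);"), "unclosed")
  expect_error(parse_newick("((a,b)),(c,d));"), "position")
  expect_error(parse_newick("((a,b),(a,d));"), "duplicate")
})

test_that("quoted labels and branch lengths survive a round trip", {
  tr <- parse_newick("(('sp 1':0.5,b:1):0.25,(c:2,d:3):0.25);")
  expect_true("sp 1" %in% leaf_set(tr))
  with_len <- write_newick(tr, include_lengths = TRUE)
  expect_match(with_len, ":")
  expect_false(grepl(":", write_newick(tr, include_lengths = FALSE)))
  expect_identical(write_newick(parse_newick(with_len)), write_newick(tr))
})

test_that("write/parse round trip is the identity on random topologies", {
  set.seed(11)
  for (i in 1:50) {
    tr <- random_binary_tree(taxon_labels(sample(4:26, 1)))
    txt <- write_newick(tr)
    expect_identical(write_newick(parse_newick(txt)), txt)
  }
})

test_that("an n-leaf binary tree has n - 3 nontrivial bipartitions", {
  tr <- parse_newick("((a,b),(c,d));")
  bp <- tree_bipartitions(tr)
  expect_length(bp, 1L)
  expect_equal(format(bp[[1]]), "a b | c d")
  expect_length(tree_bipartitions(tr, include_trivial = TRUE), 5L)
  set.seed(5)
  for (n in c(5, 9, 17, 26)) {
    expect_length(tree_bipartitions(random_binary_tree(taxon_labels(n))),
                  n - 3L)
  }
})

test_that("a caterpillar's bipartitions are the nested splits", {
  cat8 <- parse_newick("(a,(b,(c,(d,(e,(f,(g,h)))))));")
  got <- sort(vapply(tree_bipartitions(cat8), format, character(1)))
  want <- sort(c("a b | c d e f g h", "a b c | d e f g h",
                 "a b c d | e f g h", "a b c d e | f g h",
                 "a b c d e f | g h"))
  expect_identical(got, want)
})

test_that("restriction suppresses degree-2 nodes and drops lost splits", {
  tr <- parse_newick("((a,b),(c,(d,e)));")
  expect_equal(write_newick(restrict_tree(tr, c("a", "c", "d", "e"))),
               "(a,c,(d,e));")
  expect_identical(write_newick(restrict_tree(tr, leaf_set(tr))),
                   write_newick(tr))
  two <- restrict_tree(tr, c("a", "e"))
  expect_identical(sort(two$tip.label), c("a", "e"))
  expect_error(restrict_tree(tr, c("a", "z")), "z")
})

test_that("restriction commutes with bipartition restriction", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(7:15, 1)
    tr <- random_binary_tree(taxon_labels(n))
    R <- sort(sample(taxon_labels(n), sample(4:(n - 1), 1)))
    direct <- vapply(split_sides(restrict_tree(tr, R)), side_key, "")
    induced <- lapply(split_sides(tr), function(s) {
      a <- intersect(s, R)
      if (!(R[1] %in% a)) a else setdiff(R, a)
    })
    induced <- induced[vapply(induced, length, 1L) >= 2 &
                       vapply(induced, length, 1L) <= length(R) - 2]
    expect_setequal(direct, unique(vapply(induced, side_key, "")))
  }
})

test_that("RF distance matches an independent implementation", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, parse_newick("((a,c),(b,d));")), 2L)
  set.seed(31)
  for (i in 1:30) {
    n <- sample(8:20, 1)
    a <- random_binary_tree(taxon_labels(n))
    b <- random_binary_tree(taxon_labels(n))
    expect_equal(rf_distance(a, b), as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("RF distance behaves as a metric on topologies", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(6:14, 1)
    a <- random_binary_tree(taxon_labels(n))
    b <- random_binary_tree(taxon_labels(n))
    c <- random_binary_tree(taxon_labels(n))
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_lte(rf_distance(a, c), rf_distance(a, b) + rf_distance(b, c))
    expect_equal(rf_distance(a, b) %% 2, 0)
    expect_identical(rf_distance(a, b) == 0L, same_topology(a, b))
  }
  expect_error(rf_distance(parse_newick("((a,b),(c,d));"),
                           parse_newick("((a,b),(c,e));")),
               "different leaf sets")
})

test_that("normalized RF divides by the total internal edge count", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_equal(normalized_rf(t1, t1), 0)
  expect_equal(normalized_rf(t1, parse_newick("((a,c),(b,d));")), 1)
  set.seed(51)
  n <- 12
  a <- random_binary_tree(taxon_labels(n))
  b <- random_binary_tree(taxon_labels(n))
  expect_equal(normalized_rf(a, b), rf_distance(a, b) / (2 * (n - 3)))
  star <- parse_newick("(a,b,c,d);")
  expect_error(normalized_rf(star, star), "star")
})

test_that("rooting at a leaf and pruning gives the expected rooted view", {
  tr <- parse_newick("((a,b),(c,d));")
  rv <- root_at_leaf(tr, "a")
  expect_true(ape::is.rooted(rv))
  expect_identical(sort(rv$tip.label), c("b", "c", "d"))
  expect_equal(ape::write.tree(rv), "(b,(c,d));")
  expect_error(root_at_leaf(tr, "z"), "not found")
  set.seed(61)
  big <- random_binary_tree(taxon_labels(10))
  rv2 <- root_at_leaf(big, "s05")
  expect_equal(length(rv2$tip.label), 9L)
})
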