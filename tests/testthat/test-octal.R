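test_that("edge classification marks everything shared for a restriction", {
  set.seed(71)
  ref <- random_binary_tree(taxon_labels(10))
  R <- taxon_labels(10)[1:7]
  gene <- restrict_tree(ref, R)
  ce <- classify_edges(ref, gene)
  expect_true(all(ce$gene_edges$status == "shared"))
  expect_true(all(ce$reference_edges$status == "shared"))
  expect_equal(ce$r, 0L)
  expect_equal(nrow(ce$pairs), nrow(ce$gene_edges))
})

test_that("a pair sharing no nontrivial split keeps only leaf edges shared", {
  ref <- parse_newick("((a,b),(c,(d,e)));")
  gene <- parse_newick("((a,d),(c,(b,e)));")
  ce <- classify_edges(ref, gene)
  expect_true(all(ce$gene_edges$status[ce$gene_edges$trivial] == "shared"))
  expect_true(all(ce$gene_edges$status[!ce$gene_edges$trivial] == "unique"))
  expect_equal(ce$r, 4L)
})

test_that("unique gene edges count half the RF distance on random pairs", {
  set.seed(81)
  for (i in 1:20) {
    inst <- rand_instance(sample(7:12, 1), sample(1:3, 1))
    ce <- classify_edges(inst$ref, inst$gene)
    r <- rf_distance(restrict_tree(inst$ref, inst$R), inst$gene)
    expect_equal(sum(ce$gene_edges$status == "unique"), r / 2)
    expect_equal(ce$r, r)
  }
})

test_that("add_leaf restores the restriction and places Type I at no cost", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    ref <- random_binary_tree(taxon_labels(n))
    x <- sample(taxon_labels(n), 1)
    R <- setdiff(taxon_labels(n), x)
    gene <- restrict_tree(ref, R)
    grown <- add_leaf(gene, ref, x)
    expect_true(same_topology(restrict_tree(grown, R), gene))
    expect_equal(rf_distance(ref, grown), 0L)
  }
  ref <- parse_newick("((a,b),(c,d));")
  expect_error(add_leaf(ref, ref, "a"), "already present")
  expect_error(add_leaf(restrict_tree(ref, c("a", "b", "c")), ref, "z"),
               "not present in the reference")
})

test_that("a single-leaf Type II superleaf costs exactly 2", {
  for (s in 1:10) {
    inst <- random_type2_instance(sample(6:10, 1), seed = 100 + s)
    before <- rf_distance(restrict_tree(inst$reference, leaf_set(inst$gene)),
                          inst$gene)
    grown <- add_leaf(inst$gene, inst$reference, inst$taxon)
    expect_equal(rf_distance(inst$reference, grown), before + 2L)
  }
})

test_that("shared edges other than the subdivided one stay shared", {
  # after each insertion every previously shared nontrivial split must
  # persist (with or without the new taxon), except possibly the one on the
  # subdivided edge
  set.seed(111)
  for (i in 1:15) {
    inst <- rand_instance(sample(8:14, 1), 1, gene_mode = "perturb")
    x <- setdiff(inst$S, inst$R)
    tr_R <- restrict_tree(inst$ref, inst$R)
    shared_before <- Filter(
      function(s) side_key(s) %in% vapply(split_sides(tr_R), side_key, ""),
      split_sides(inst$gene))
    grown <- add_leaf(inst$gene, inst$ref, x)
    tr_Rx <- restrict_tree(inst$ref, c(inst$R, x))
    shared_after <- vapply(Filter(
      function(s) side_key(s) %in% vapply(split_sides(tr_Rx), side_key, ""),
      split_sides(grown)), side_key, "")
    persists <- vapply(shared_before, function(s) {
      any(c(side_key(s), side_key(c(s, x)),
            side_key(setdiff(inst$R, s)),
            side_key(c(setdiff(inst$R, s), x))) %in% shared_after)
    }, logical(1))
    expect_lte(sum(!persists), 1L)
  }
})

test_that("superleaf members partition the missing taxa", {
  ref <- parse_newick("((a,b),((r,s),(c,d)));")
  gene <- parse_newick("((a,b),(c,d));")
  sl <- superleaf_decomposition(ref, gene)
  expect_length(sl, 1L)
  expect_identical(sl[[1]]$members, c("r", "s"))
  expect_equal(sl[[1]]$type, "I")
  expect_equal(format(sl[[1]]$attachment), "a b | c d")
  expect_length(superleaf_decomposition(ref, restrict_tree(ref, leaf_set(ref))), 0L)
  set.seed(121)
  for (i in 1:15) {
    inst <- rand_instance(sample(8:16, 1), sample(2:5, 1))
    sl <- superleaf_decomposition(inst$ref, inst$gene)
    members <- sort(unlist(lapply(sl, `[[`, "members")))
    expect_identical(members, sort(setdiff(inst$S, inst$R)))
  }
})

test_that("completion achieves the r + 2m certificate", {
  set.seed(131)
  for (i in 1:25) {
    inst <- rand_instance(sample(7:15, 1), sample(1:4, 1),
                          gene_mode = sample(c("random", "perturb"), 1))
    rep <- octal(inst$ref, inst$gene)
    expect_equal(rep$achieved_rf, rep$lower_bound)
    expect_equal(rep$lower_bound,
                 completion_lower_bound(inst$ref, inst$gene))
    expect_equal(rep$achieved_rf, rf_distance(inst$ref, rep$tree))
    expect_true(same_topology(restrict_tree(rep$tree, inst$R), inst$gene))
    expect_equal(nrow(rep$log), length(setdiff(inst$S, inst$R)))
  }
})

test_that("completing a restriction recovers the reference exactly", {
  set.seed(141)
  ref <- random_binary_tree(taxon_labels(12))
  R <- sort(sample(taxon_labels(12), 8))
  rep <- octal(ref, restrict_tree(ref, R))
  expect_equal(rep$r, 0L)
  expect_equal(rep$achieved_rf, 0L)
  expect_true(same_topology(rep$tree, ref))
})

test_that("superleaf topologies are preserved in the completed tree", {
  set.seed(151)
  for (i in 1:10) {
    inst <- rand_instance(sample(9:16, 1), sample(2:5, 1))
    rep <- octal(inst$ref, inst$gene)
    for (s in superleaf_decomposition(inst$ref, inst$gene)) {
      if (length(s$members) >= 2) {
        expect_true(same_topology(restrict_tree(rep$tree, s$members),
                                  restrict_tree(inst$ref, s$members)))
      }
    }
  }
})

test_that("degenerate and invalid inputs are rejected", {
  ref <- parse_newick("((a,b),(c,d));")
  expect_error(octal(ref, parse_newick("(a,b);")), "at least 3")
  expect_error(octal(ref, parse_newick("((a,b),(c,z));")),
               "not present in the reference")
  expect_error(octal(parse_newick("(a,b,c,d,e);"),
                     parse_newick("(a,b,c);")), "binary")
  expect_error(octal(ref, parse_newick("((a,b),(c,d));"), order = "nope"))
})
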