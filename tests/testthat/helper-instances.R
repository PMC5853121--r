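# Random instance builders used across the suite. All draw from the ambient
# RNG so callers control reproducibility with set.seed().

taxon_labels <- function(n) sprintf("s%02d", seq_len(n))

# reference tree on n_S taxa plus a gene tree missing n_missing of them;
# gene_mode "random" draws an unrelated topology on the retained taxa,
# "perturb" applies NNI moves to the restricted reference
rand_instance <- function(n_S, n_missing, gene_mode = "random", nni = 3L) {
  S <- taxon_labels(n_S)
  ref <- random_binary_tree(S)
  R <- sort(sample(S, n_S - n_missing))
  gene <- if (gene_mode == "random") {
    random_binary_tree(R)
  } else {
    g <- restrict_tree(ref, R)
    if (length(R) >= 5) {  # NNI needs an internal edge to act on
      for (i in seq_len(nni)) g <- phangorn::rNNI(g, moves = 1L)
    }
    parse_newick(write_newick(g))
  }
  list(ref = ref, gene = gene, S = S, R = R)
}

# sorted label sets of the nontrivial splits of `tree` (sides not containing
# the first taxon), used for set-level assertions
split_sides <- function(tree) {
  taxa <- leaf_set(tree)
  lapply(tree_bipartitions(tree), function(b) {
    if (taxa[1] %in% b$side_a) b$side_b else b$side_a
  })
}

side_key <- function(side) paste(sort(side), collapse = "|")
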