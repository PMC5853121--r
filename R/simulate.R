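# Synthetic instance generation: uniform random binary topologies, gene
# trees perturbed to a target discordance level (AD = mean normalized RF to
# the species tree), a clade-size-driven taxon deletion protocol, and the
# greedy (extended majority) consensus used to build reference trees.

#' Generate a uniform random unrooted binary tree topology
#'
#' Equivalent to resolving a star tree into a binary tree with all
#' topologies equiprobable: the first three taxa form the unique 3-leaf
#' tree and each subsequent taxon is attached to an edge chosen uniformly
#' at random, which makes every labelled topology equally likely.
#'
#' @param labels Character vector of at least 3 unique taxon names.
#' @param seed Optional integer seed; a fixed seed gives an identical tree
#'   across runs.
#' @return An unrooted binary \code{"phylo"} object.
#' @examples
#' write_newick(random_binary_tree(letters[1:6], seed = 1))
#' @export
random_binary_tree <- function(labels, seed = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 3L) stop("need at least 3 labels")
  if (anyDuplicated(labels)) stop("labels must be unique")
  with_seed(seed, {
    ut <- ut_new(list(4L, 4L, 4L, c(1L, 2L, 3L)),
                 c(labels[1:3], NA_character_))
    for (x in labels[-(1:3)]) {
      edges <- ut_edges(ut)
      i <- sample.int(nrow(edges), 1L)
      ut <- ut_attach(ut, edges[i, 1], edges[i, 2], x)
    }
    ut_to_phylo(ut)
  })
}

#' Perturb a tree to a target discordance level by random NNI moves
#'
#' Applies random nearest-neighbour-interchange moves to the species tree
#' until the normalized RF distance back to it first reaches the target (or
#' a move cap is hit), emulating gene trees that disagree with their species
#' tree at a controlled average level. Over many genes the mean realized
#' discordance slightly exceeds the target by at most one NNI step.
#'
#' @param species_tree An unrooted binary \code{"phylo"} object.
#' @param target_ad Target normalized RF distance in \eqn{[0, 1]};
#'   0 returns the species tree unchanged.
#' @param seed Optional integer seed.
#' @param max_moves Cap on the number of NNI moves (default 200).
#' @return A binary \code{"phylo"} gene tree with attributes
#'   \code{realized_ad} (the normalized RF actually reached) and
#'   \code{nni_moves}.
#' @export
perturb_to_ad <- function(species_tree, target_ad, seed = NULL,
                          max_moves = 200L) {
  stopifnot(target_ad >= 0, target_ad <= 1)
  check_binary(as_ut(species_tree), "species tree")
  if (target_ad == 0) {
    out <- species_tree
    attr(out, "realized_ad") <- 0
    attr(out, "nni_moves") <- 0L
    return(out)
  }
  with_seed(seed, {
    cur <- species_tree
    moves <- 0L
    ad <- 0
    while (ad < target_ad && moves < max_moves) {
      cur <- phangorn::rNNI(cur, moves = 1L)
      moves <- moves + 1L
      ad <- normalized_rf(cur, species_tree)
    }
    out <- ut_to_phylo(ut_from_phylo(cur))
    attr(out, "realized_ad") <- ad
    attr(out, "nni_moves") <- moves
    out
  })
}

#' Clade-size multiset of a species tree
#'
#' Roots the species tree at the declared outgroup and collects the number
#' of taxa in every non-trivial clade (internal nodes other than the root).
#' This multiset drives the taxon-deletion protocol: the number of taxa
#' deleted from a gene is drawn uniformly from it.
#'
#' @param species_tree An unrooted binary \code{"phylo"} object.
#' @param outgroup The leaf at which to root the tree.
#' @return An integer vector (multiset) of clade sizes, each between 2 and
#'   \eqn{n - 1}.
#' @export
clade_size_multiset <- function(species_tree, outgroup) {
  if (!(outgroup %in% species_tree$tip.label)) {
    stop("outgroup not present in the species tree: ", outgroup)
  }
  rooted <- ape::root(species_tree, outgroup = outgroup, resolve.root = TRUE)
  pp <- ape::prop.part(rooted)
  sizes <- lengths(pp)[-1]  # drop the root clade
  sizes <- sizes[sizes >= 2L]
  as.integer(unname(sizes))
}

#' Delete taxa from gene trees following the clade-size protocol
#'
#' A fraction of the genes is selected uniformly at random to be incomplete.
#' For each selected gene, a deletion count is drawn uniformly from the
#' species tree's [clade_size_multiset()] and that many taxa are removed
#' uniformly at random without replacement; draws that would leave fewer
#' than \code{min_leaves} taxa are redrawn. Unselected genes pass through
#' untouched.
#'
#' @param species_tree An unrooted binary \code{"phylo"} on the full taxon
#'   set; defines the clade-size multiset via \code{outgroup}.
#' @param gene_trees A list of \code{"phylo"} objects on the full taxon set.
#' @param outgroup Leaf used to root the species tree for clade extraction.
#' @param fraction_incomplete Fraction of genes to make incomplete
#'   (default 0.75).
#' @param seed Optional integer seed.
#' @param min_leaves Minimum number of leaves an incomplete gene tree may
#'   retain (default 3, the smallest size downstream algorithms accept).
#' @return A list with \code{trees} (the gene trees, incomplete where
#'   selected) and a \code{manifest} data frame (columns \code{gene},
#'   \code{incomplete}, \code{n_deleted}, \code{deleted_taxa},
#'   \code{n_leaves}).
#' @export
deletion_protocol <- function(species_tree, gene_trees, outgroup,
                              fraction_incomplete = 0.75, seed = NULL,
                              min_leaves = 3L) {
  stopifnot(fraction_incomplete >= 0, fraction_incomplete <= 1)
  taxa <- leaf_set(species_tree)
  for (g in gene_trees) {
    if (!identical(leaf_set(g), taxa)) {
      stop("all gene trees must be on the species tree's full taxon set")
    }
  }
  multiset <- clade_size_multiset(species_tree, outgroup)
  n_taxa <- length(taxa)
  if (!any(n_taxa - multiset >= min_leaves)) {
    stop("no clade size in the multiset leaves at least ", min_leaves,
         " taxa")
  }
  n_genes <- length(gene_trees)
  k <- round(fraction_incomplete * n_genes)
  with_seed(seed, {
    chosen <- if (k > 0) sort(sample.int(n_genes, k)) else integer(0)
    trees <- vector("list", n_genes)
    n_del <- integer(n_genes)
    del_lab <- character(n_genes)
    for (g in seq_len(n_genes)) {
      if (g %in% chosen) {
        repeat {
          nd <- multiset[sample.int(length(multiset), 1L)]
          if (n_taxa - nd >= min_leaves) break
        }
        del <- lab_sort(sample(taxa, nd))
        trees[[g]] <- restrict_tree(gene_trees[[g]], setdiff(taxa, del))
        n_del[g] <- nd
        del_lab[g] <- paste(del, collapse = ";")
      } else {
        trees[[g]] <- gene_trees[[g]]
        del_lab[g] <- ""
      }
    }
    list(trees = trees,
         manifest = data.frame(
           gene = seq_len(n_genes),
           incomplete = seq_len(n_genes) %in% chosen,
           n_deleted = n_del,
           deleted_taxa = del_lab,
           n_leaves = n_taxa - n_del,
           stringsAsFactors = FALSE))
  })
}

#' Generate a validation instance with one single-leaf Type II superleaf
#'
#' Draws random reference/gene tree pairs in which exactly one taxon is
#' missing from the gene tree, until that taxon forms a Type II superleaf
#' (its attachment edge in the reference is unique relative to the gene
#' tree). Such instances exercise the sharpest part of the optimality
#' certificate: every possible placement of the missing leaf raises the RF
#' distance by at least 2, and the best placement by exactly 2.
#'
#' @param n_taxa Total number of taxa in the reference tree (at least 5).
#' @param seed Optional integer seed.
#' @param max_tries Attempts before giving up (default 200).
#' @return A list with \code{reference}, \code{gene} (missing one taxon)
#'   and \code{taxon} (the missing leaf).
#' @export
random_type2_instance <- function(n_taxa, seed = NULL, max_tries = 200L) {
  stopifnot(n_taxa >= 5)
  with_seed(seed, {
    S <- sprintf("s%02d", seq_len(n_taxa))
    for (i in seq_len(max_tries)) {
      ref <- random_binary_tree(S)
      x <- S[sample.int(n_taxa, 1L)]
      gene <- random_binary_tree(setdiff(S, x))
      sl <- sl_decompose(as_ut(ref), as_ut(gene))
      if (length(sl) == 1L && sl[[1]]$type == "II") {
        return(list(reference = ref, gene = gene, taxon = x))
      }
    }
    stop("failed to generate a Type II instance in ", max_tries, " tries")
  })
}

#' Greedy (extended majority) consensus of a set of trees
#'
#' Ranks the nontrivial bipartitions occurring in the input trees by
#' frequency and scans them in descending order, accepting each bipartition
#' exactly when it is compatible with everything accepted so far. Frequency
#' ties are broken by the lexicographically smallest canonical bipartition,
#' making the result deterministic. The accepted set is returned as a
#' (possibly non-binary) unrooted tree.
#'
#' @param trees A nonempty list of \code{"phylo"} objects on identical leaf
#'   sets.
#' @return An unrooted \code{"phylo"} object realizing the accepted
#'   bipartitions.
#' @examples
#' trs <- list(parse_newick("((a,b),(c,(d,e)));"),
#'             parse_newick("((a,b),(d,(c,e)));"),
#'             parse_newick("((a,c),(b,(d,e)));"))
#' write_newick(greedy_consensus(trs))
#' @export
greedy_consensus <- function(trees) {
  if (!length(trees)) stop("need at least one tree")
  uts <- lapply(trees, as_ut)
  taxa <- lab_sort(ut_leaf_labels(uts[[1]]))
  for (u in uts[-1]) {
    if (!identical(lab_sort(ut_leaf_labels(u)), taxa)) {
      stop("all trees must share the same leaf set")
    }
  }
  side_of <- new.env(parent = emptyenv())
  per_tree <- lapply(uts, function(u) {
    st <- ut_split_table(u)
    keep <- which(!st$trivial)
    keep <- keep[!duplicated(st$key[keep])]
    for (i in keep) {
      if (is.null(side_of[[st$key[i]]])) {
        assign(st$key[i], st$side[[i]], envir = side_of)
      }
    }
    st$key[keep]
  })
  freq <- table(unlist(per_tree))
  keys <- names(freq)
  ord <- order(-as.integer(freq), keys, method = "radix")
  accepted <- list()
  compatible <- function(X, Y) {
    # both sides exclude the smallest taxon, so splits are compatible
    # exactly when the sides are nested or disjoint
    k <- length(intersect(X, Y))
    k == 0L || k == length(X) || k == length(Y)
  }
  for (key in keys[ord]) {
    X <- side_of[[key]]
    if (all(vapply(accepted, function(Y) compatible(X, Y), logical(1)))) {
      accepted[[length(accepted) + 1L]] <- X
    }
  }
  tree_from_clades(accepted, taxa)
}

# realize a laminar family of clades (subsets of taxa excluding the smallest
# taxon) as an unrooted tree
tree_from_clades <- function(clades, taxa) {
  if (length(clades)) {
    clades <- clades[order(-lengths(clades))]
  }
  nc <- length(clades)
  parent <- integer(nc)  # 0 = root
  for (i in seq_len(nc)) {
    for (j in rev(seq_len(i - 1L))) {  # nearest (smallest) superset wins
      if (all(clades[[i]] %in% clades[[j]])) {
        parent[i] <- j
        break
      }
    }
  }
  taxon_home <- rep(0L, length(taxa))  # deepest clade holding each taxon
  names(taxon_home) <- taxa
  for (i in seq_len(nc)) {
    taxon_home[clades[[i]]] <- i  # clades sorted big->small, deepest last
  }
  ser <- function(i) {
    kids <- which(parent == i)
    own <- taxa[taxon_home == i]
    if (i == 0L) own <- own  # includes the smallest taxon at the root
    parts <- c(lapply(kids, ser), as.list(quote_label(own)))
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  parse_newick(paste0(ser(0L), ";"))
}
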