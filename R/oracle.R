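# Exhaustive ground truth for small instances: attach each missing taxon to
# every edge of the growing gene tree, recursively. For k taxa added to a
# binary tree with l leaves this visits prod_{i=0..k-1} (2(l+i) - 3)
# leaf-addition sequences, each yielding a binary completion; every binary
# completion arises from at least one sequence (possibly several).

completion_sequence_count <- function(n_gene_leaves, n_missing) {
  if (n_missing == 0L) return(1)
  prod(2 * (n_gene_leaves + seq_len(n_missing) - 1) - 3)
}

#' Enumerate every binary completion of a gene tree
#'
#' Generates all binary trees on the reference taxon set that restrict to
#' the gene tree, by attaching each missing taxon to every edge in turn.
#' Different attachment sequences can rebuild the same topology, so the
#' stream may contain duplicates; the count of sequences is exactly
#' \eqn{\prod_{i=0}^{k-1} (2(\ell+i)-3)} for \eqn{k} missing taxa and an
#' \eqn{\ell}-leaf gene tree.
#'
#' @inheritParams classify_edges
#' @param cap Refuse to enumerate when the number of attachment sequences
#'   exceeds this value (default \code{1e6}); enumeration is never silently
#'   truncated.
#' @return A list of \code{"phylo"} completions (one per attachment
#'   sequence).
#' @export
enumerate_completions <- function(reference, gene, cap = 1e6) {
  ref_ut <- as_ut(reference); gene_ut <- as_ut(gene)
  sets <- validate_pair(ref_ut, gene_ut)
  missing <- setdiff(sets$S, sets$R)
  total <- completion_sequence_count(length(sets$R), length(missing))
  if (total > cap) {
    stop("refusing to enumerate ", format(total, big.mark = ","),
         " completion sequences (cap = ", format(cap, big.mark = ","), ")")
  }
  out <- vector("list", 0)
  recurse <- function(cur, todo) {
    if (!length(todo)) {
      out[[length(out) + 1L]] <<- cur
      return(invisible(NULL))
    }
    x <- todo[1]
    edges <- ut_edges(cur)
    for (i in seq_len(nrow(edges))) {
      recurse(ut_attach(cur, edges[i, 1], edges[i, 2], x), todo[-1])
    }
  }
  recurse(gene_ut, missing)
  lapply(out, ut_to_phylo)
}

#' Brute-force optimal completion by exhaustive enumeration
#'
#' Visits every completion sequence of the gene tree and returns the true
#' minimum RF distance to the reference together with one minimizing tree.
#' Intended as an independent certificate for the greedy algorithm on small
#' instances.
#'
#' @inheritParams enumerate_completions
#' @return An object of class \code{"completion_enumeration"}: a list with
#'   \code{best_rf}, one minimizing \code{tree}, the number of sequences
#'   \code{visited}, and \code{matches_lower_bound}, whether the optimum
#'   equals [completion_lower_bound()].
#' @export
brute_force_complete <- function(reference, gene, cap = 1e6) {
  ref_ut <- as_ut(reference); gene_ut <- as_ut(gene)
  sets <- validate_pair(ref_ut, gene_ut)
  missing <- setdiff(sets$S, sets$R)
  total <- completion_sequence_count(length(sets$R), length(missing))
  if (total > cap) {
    stop("refusing to enumerate ", format(total, big.mark = ","),
         " completion sequences (cap = ", format(cap, big.mark = ","), ")")
  }
  ref_keys <- ut_keyset(ref_ut)
  best <- Inf; best_tree <- NULL; visited <- 0L
  recurse <- function(cur, todo) {
    if (!length(todo)) {
      visited <<- visited + 1L
      keys <- ut_keyset(cur)
      rf <- sum(!(keys %in% ref_keys)) + sum(!(ref_keys %in% keys))
      if (rf < best) {
        best <<- rf
        best_tree <<- cur
      }
      return(invisible(NULL))
    }
    x <- todo[1]
    edges <- ut_edges(cur)
    for (i in seq_len(nrow(edges))) {
      recurse(ut_attach(cur, edges[i, 1], edges[i, 2], x), todo[-1])
    }
  }
  recurse(gene_ut, missing)
  lb <- completion_lower_bound(reference, gene)
  structure(list(best_rf = as.integer(best), tree = ut_to_phylo(best_tree),
                 visited = visited, expected_sequences = total,
                 matches_lower_bound = best == lb),
            class = "completion_enumeration")
}

#' @export
print.completion_enumeration <- function(x, ...) {
  cat("Exhaustive completion search\n")
  cat("  sequences visited:", x$visited, "\n")
  cat("  best RF distance: ", x$best_rf, "\n")
  cat("  equals r + 2m:    ", x$matches_lower_bound, "\n")
  invisible(x)
}

#' Complete a gene tree by uniformly random leaf attachment
#'
#' Attaches each missing taxon to an edge of the gene tree chosen uniformly
#' at random. This ignores the reference topology entirely and serves as a
#' naive baseline against which optimal completion is compared.
#'
#' @inheritParams classify_edges
#' @param seed Optional integer seed.
#' @return A binary \code{"phylo"} completion of \code{gene}.
#' @export
random_completion <- function(reference, gene, seed = NULL) {
  ref_ut <- as_ut(reference); gene_ut <- as_ut(gene)
  sets <- validate_pair(ref_ut, gene_ut)
  missing <- setdiff(sets$S, sets$R)
  with_seed(seed, {
    cur <- gene_ut
    for (x in missing) {
      edges <- ut_edges(cur)
      i <- sample.int(nrow(edges), 1L)
      cur <- ut_attach(cur, edges[i, 1], edges[i, 2], x)
    }
    ut_to_phylo(cur)
  })
}
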