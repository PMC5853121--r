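# Core completion machinery: shared/unique edge classification, superleaf
# decomposition, the AddLeaf primitive and the main greedy loop. All proofs
# of optimality rest on the invariant that inserting a leaf on a shared edge
# leaves every other shared edge shared, so the achieved RF distance equals
# r + 2m (r = RF between the restricted reference and the gene tree, m = the
# number of Type II superleaves).

# canonical nontrivial split keys of a tree, relative to the smallest leaf
ut_keyset <- function(ut) {
  st <- ut_split_table(ut)
  st$key[!st$trivial]
}

# canonical key of the split side/complement pair `side` vs rest of `taxa`
side_keyed <- function(side, taxa) {
  min_taxon <- taxa[1]  # taxa assumed sorted
  if (min_taxon %in% side) split_key(lab_sort(setdiff(taxa, side))) else split_key(side)
}

validate_pair <- function(ref_ut, gene_ut) {
  check_binary(ref_ut, "reference tree")
  check_binary(gene_ut, "gene tree")
  S <- lab_sort(ut_leaf_labels(ref_ut))
  R <- lab_sort(ut_leaf_labels(gene_ut))
  extra <- setdiff(R, S)
  if (length(extra)) {
    stop("gene tree leaves not present in the reference tree: ",
         paste(extra, collapse = ", "))
  }
  if (length(R) < 3L) stop("gene tree must have at least 3 leaves")
  list(S = S, R = R)
}

#' Classify edges as shared or unique between a reference and a gene tree
#'
#' Restricts the reference tree to the gene tree's taxa R and annotates every
#' edge of both trees: an edge is \emph{shared} when its bipartition,
#' restricted to R, occurs in both trees, and \emph{unique} otherwise. Every
#' leaf-incident edge is shared. The paired shared edges (one per tree,
#' defining the same split of R) form the correspondence used to decide
#' where missing leaves may be inserted.
#'
#' @param reference An unrooted binary \code{"phylo"} tree on the full taxon
#'   set.
#' @param gene An unrooted binary \code{"phylo"} tree on a subset R of the
#'   reference taxa, with \eqn{|R| \ge 3}.
#' @return An object of class \code{"edge_correspondence"}: a list with
#'   data frames \code{reference_edges} and \code{gene_edges} (columns
#'   \code{split}, \code{trivial}, \code{status}), the data frame
#'   \code{pairs} of matched shared edges, and \code{r}, the RF distance
#'   between the restricted reference tree and the gene tree.
#' @examples
#' ref <- parse_newick("((a,b),((c,d),(e,f)));")
#' gene <- parse_newick("((a,c),(b,(e,f)));")
#' classify_edges(ref, gene)
#' @export
classify_edges <- function(reference, gene) {
  ref_ut <- as_ut(reference); gene_ut <- as_ut(gene)
  sets <- validate_pair(ref_ut, gene_ut)
  tr_ut <- ut_restrict(ref_ut, sets$R)
  st_r <- ut_split_table(tr_ut)
  st_g <- ut_split_table(gene_ut)
  shared_r <- st_r$trivial | st_r$key %in% st_g$key[!st_g$trivial]
  shared_g <- st_g$trivial | st_g$key %in% st_r$key[!st_r$trivial]
  fmt <- function(st) vapply(st$side, function(s)
    format(bipartition_from_side(s, sets$R)), character(1))
  ref_edges <- data.frame(split = fmt(st_r), trivial = st_r$trivial,
                          status = ifelse(shared_r, "shared", "unique"),
                          stringsAsFactors = FALSE)
  gene_edges <- data.frame(split = fmt(st_g), trivial = st_g$trivial,
                           status = ifelse(shared_g, "shared", "unique"),
                           stringsAsFactors = FALSE)
  ij <- match(st_r$key[shared_r], st_g$key)
  pairs <- data.frame(ref_edge = which(shared_r), gene_edge = ij,
                      split = ref_edges$split[shared_r],
                      stringsAsFactors = FALSE)
  r <- sum(!shared_r & !st_r$trivial) + sum(!shared_g & !st_g$trivial)
  structure(list(reference_edges = ref_edges, gene_edges = gene_edges,
                 pairs = pairs, r = r, taxa = sets$R),
            class = "edge_correspondence")
}

#' @export
print.edge_correspondence <- function(x, ...) {
  cat("Edge correspondence on", length(x$taxa), "common taxa\n")
  cat("  RF(T|_R, t) =", x$r, "\n")
  cat("  shared edge pairs:", nrow(x$pairs), "\n")
  cat("  unique edges: ", sum(x$reference_edges$status == "unique"),
      " in restricted reference, ",
      sum(x$gene_edges$status == "unique"), " in gene tree\n", sep = "")
  invisible(x)
}

# internal superleaf decomposition on ut structures; returns a list of
# records (members, type, attachment side on R, root node in the reference)
sl_decompose <- function(ref_ut, gene_ut) {
  sets <- validate_pair(ref_ut, gene_ut)
  S <- sets$S; R <- sets$R
  extra <- setdiff(S, R)
  if (!length(extra)) return(list())
  st <- ut_split_table(ref_ut)
  n_in_R <- vapply(st$side, function(s) sum(s %in% R), integer(1))
  backbone <- n_in_R > 0L & n_in_R < length(R)
  bb_keys <- ekey(st$parent[backbone], st$child[backbone])
  # connected components of the reference minus its backbone edges
  nn <- ut_nnodes(ref_ut)
  comp <- integer(nn)
  cid <- 0L
  for (v0 in seq_len(nn)) {
    if (comp[v0] != 0L || length(ref_ut$adj[[v0]]) == 0L) next
    cid <- cid + 1L
    queue <- v0
    comp[v0] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in ref_ut$adj[[v]]) {
        if (comp[w] == 0L && !(ekey(v, w) %in% bb_keys)) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  gene_keys <- ut_keyset(gene_ut)
  edge_of <- structure(seq_along(st$key), names = ekey(st$parent, st$child))
  out <- list()
  for (k in seq_len(cid)) {
    nodes <- which(comp == k)
    members <- lab_sort(ref_ut$label[nodes][!is.na(ref_ut$label[nodes])])
    members <- members[members %in% extra]
    if (!length(members)) next
    # the root of the superleaf is its single node incident to backbone edges
    root <- nodes[vapply(nodes, function(v)
      any(ekey(v, ref_ut$adj[[v]]) %in% bb_keys), logical(1))]
    stopifnot(length(root) == 1L)
    bb_at_root <- ref_ut$adj[[root]][ekey(root, ref_ut$adj[[root]]) %in% bb_keys]
    i <- edge_of[[ekey(root, bb_at_root[1])]]
    A <- intersect(st$side[[i]], R)
    trivial <- length(A) == 1L || length(A) == length(R) - 1L
    shared <- trivial || side_keyed(lab_sort(A), R) %in% gene_keys
    out[[length(out) + 1L]] <- list(
      members = members,
      type = if (shared) "I" else "II",
      attachment = bipartition_from_side(lab_sort(A), R),
      root = root)
  }
  first <- vapply(out, function(s) s$members[1], character(1))
  out[order(first, method = "radix")]
}

#' Superleaf decomposition of the missing taxa
#'
#' The \emph{backbone} of the reference tree with respect to the gene tree is
#' the set of its edges on paths between taxa the two trees have in common.
#' Deleting the backbone edges splits the missing taxa into rooted pendant
#' groups called \emph{superleaves}, each attached to one backbone edge. A
#' superleaf is Type I when its attachment edge is shared between the
#' restricted reference tree and the gene tree, and Type II when that edge is
#' unique. Type I superleaves can be inserted at no RF cost; each Type II
#' superleaf adds exactly 2 to the optimal RF distance.
#'
#' @inheritParams classify_edges
#' @return An object of class \code{"superleaf_set"}: a list of superleaves,
#'   each with elements \code{members} (taxa), \code{type} (\code{"I"} or
#'   \code{"II"}) and \code{attachment} (the attachment edge's bipartition of
#'   the common taxa). The superleaf member sets partition the missing taxa.
#' @examples
#' ref <- parse_newick("((a,b),((r,s),(c,d)));")
#' gene <- parse_newick("((a,b),(c,d));")
#' superleaf_decomposition(ref, gene)
#' @export
superleaf_decomposition <- function(reference, gene) {
  out <- sl_decompose(as_ut(reference), as_ut(gene))
  structure(out, class = "superleaf_set")
}

#' @export
print.superleaf_set <- function(x, ...) {
  cat("Superleaf decomposition:", length(x), "superleaf(s),",
      sum(vapply(x, function(s) s$type == "II", logical(1))), "of Type II\n")
  for (s in x) {
    cat("  [", s$type, "] {", paste(s$members, collapse = ", "),
        "} on edge ", format(s$attachment), "\n", sep = "")
  }
  invisible(x)
}

#' Lower bound on the RF distance achievable by any completion
#'
#' Every completion of the gene tree to the full taxon set has RF distance to
#' the reference tree at least \eqn{r + 2m}, where \eqn{r} is the RF distance
#' between the restricted reference tree and the gene tree and \eqn{m} is the
#' number of Type II superleaves. The greedy completion attains this bound.
#'
#' @inheritParams classify_edges
#' @return A nonnegative even integer.
#' @export
completion_lower_bound <- function(reference, gene) {
  ref_ut <- as_ut(reference); gene_ut <- as_ut(gene)
  sets <- validate_pair(ref_ut, gene_ut)
  r <- ut_rf(ut_restrict(ref_ut, sets$R), gene_ut)
  sl <- sl_decompose(ref_ut, gene_ut)
  m <- sum(vapply(sl, function(s) s$type == "II", logical(1)))
  r + 2L * m
}

# One AddLeaf step on ut structures. Roots the reference restricted to
# R + {x} at x, walks down always taking the smallest-labelled child, and
# inserts x on the first shared edge met (leaf-incident edges are always
# shared, so the walk terminates). Returns the grown gene tree and the
# split of the subdivided edge.
addleaf_core <- function(ref_ut, gene_ut, x) {
  R <- lab_sort(ut_leaf_labels(gene_ut))
  tx <- ut_restrict(ref_ut, c(R, x))
  xn <- which(!is.na(tx$label) & tx$label == x)
  bs <- ut_below_sets(tx, root = xn)
  gene_st <- ut_split_table(gene_ut)
  gene_keys_nt <- gene_st$key[!gene_st$trivial]
  v <- tx$adj[[xn]][1]
  clade <- NULL
  repeat {
    kids <- setdiff(tx$adj[[v]], bs$parent[v])
    mins <- vapply(kids, function(c) bs$below[[c]][1], character(1))
    found <- FALSE
    for (c in kids[order(mins, method = "radix")]) {
      cl <- bs$below[[c]]
      shared <- length(cl) == 1L || length(cl) == length(R) - 1L ||
        side_keyed(cl, R) %in% gene_keys_nt
      if (shared) {
        clade <- cl
        found <- TRUE
        break
      }
      v <- c  # descend into the first (smallest-labelled) unshared child
      break
    }
    if (found) break
  }
  # locate the paired edge e' in the gene tree
  if (length(clade) == 1L || length(clade) == length(R) - 1L) {
    leaf_lab <- if (length(clade) == 1L) clade else setdiff(R, clade)
    ln <- which(!is.na(gene_ut$label) & gene_ut$label == leaf_lab)
    u1 <- ln; v1 <- gene_ut$adj[[ln]][1]
  } else {
    i <- match(side_keyed(clade, R), gene_st$key)
    stopifnot(!is.na(i))
    u1 <- gene_st$parent[i]; v1 <- gene_st$child[i]
  }
  list(ut = ut_attach(gene_ut, u1, v1, x),
       split = bipartition_from_side(lab_sort(intersect(clade, R)), R))
}

#' Insert one missing taxon into a gene tree
#'
#' A single step of the completion algorithm: the reference tree restricted
#' to the gene taxa plus \code{x} is rooted at \code{x}, the rooted view is
#' walked depth-first until the first shared edge is met, and \code{x} is
#' attached to the corresponding edge of the gene tree by subdividing it.
#' The result is binary and restricts back to the input gene tree.
#'
#' @inheritParams classify_edges
#' @param x A taxon present in \code{reference} but not in \code{gene}.
#' @return The gene tree with \code{x} inserted, as a \code{"phylo"} object.
#' @export
add_leaf <- function(gene, reference, x) {
  ref_ut <- as_ut(reference); gene_ut <- as_ut(gene)
  sets <- validate_pair(ref_ut, gene_ut)
  if (x %in% sets$R) stop("taxon already present in the gene tree: ", x)
  if (!(x %in% sets$S)) stop("taxon not present in the reference tree: ", x)
  ut_to_phylo(addleaf_core(ref_ut, gene_ut, x)$ut)
}

#' Optimally complete a gene tree against a reference tree
#'
#' Adds the taxa present in the reference tree but missing from the gene
#' tree, one at a time, always inserting on a shared edge of the current
#' gene tree. The returned completion provably minimizes the RF distance to
#' the reference over all completions of the gene tree, achieving exactly
#' \eqn{r + 2m} (see [completion_lower_bound()]). The achieved optimum does
#' not depend on the insertion order, although the completed tree itself may
#' (the problem can have many optima).
#'
#' @inheritParams classify_edges
#' @param order Insertion order for the missing taxa:
#'   \code{"lex"} (lexicographic, the default, fully deterministic) or
#'   \code{"random"}.
#' @param seed Optional integer seed used when \code{order = "random"}.
#' @return An object of class \code{"completion_report"}: a list with the
#'   completed tree (\code{tree}), the certificate quantities \code{r},
#'   \code{m}, \code{achieved_rf} and \code{lower_bound}, the insertion
#'   \code{order} used, and a per-insertion \code{log} recording which gene
#'   tree edge was subdivided for each taxon.
#' @examples
#' ref <- parse_newick("((a,b),((r,s),(c,d)));")
#' gene <- parse_newick("((a,c),(b,d));")
#' octal(ref, gene)
#' @export
octal <- function(reference, gene, order = c("lex", "random"), seed = NULL) {
  order <- match.arg(order)
  ref_ut <- as_ut(reference); gene_ut <- as_ut(gene)
  sets <- validate_pair(ref_ut, gene_ut)
  missing <- setdiff(sets$S, sets$R)
  if (order == "random" && length(missing) > 1L) {
    missing <- with_seed(seed, sample(missing))
  }
  r <- ut_rf(ut_restrict(ref_ut, sets$R), gene_ut)
  sl <- sl_decompose(ref_ut, gene_ut)
  m <- sum(vapply(sl, function(s) s$type == "II", logical(1)))
  cur <- gene_ut
  log_taxon <- character(0); log_split <- character(0)
  for (x in missing) {
    step <- addleaf_core(ref_ut, cur, x)
    cur <- step$ut
    log_taxon <- c(log_taxon, x)
    log_split <- c(log_split, format(step$split))
  }
  achieved <- ut_rf(ref_ut, cur)
  if (!ut_equal_topology(ut_restrict(cur, sets$R), gene_ut)) {
    stop("internal error: completed tree does not restrict to the gene tree")
  }
  structure(list(tree = ut_to_phylo(cur), r = r, m = m,
                 achieved_rf = achieved, lower_bound = r + 2L * m,
                 order = missing,
                 log = data.frame(taxon = log_taxon,
                                  subdivided_split = log_split,
                                  stringsAsFactors = FALSE)),
            class = "completion_report")
}

#' @export
print.completion_report <- function(x, ...) {
  cat("Gene tree completion\n")
  cat("  taxa added:       ", length(x$order), "\n")
  cat("  r = RF(T|_R, t):  ", x$r, "\n")
  cat("  m (Type II):      ", x$m, "\n")
  cat("  achieved RF:      ", x$achieved_rf,
      " (lower bound r + 2m = ", x$lower_bound, ")\n", sep = "")
  cat("  completed tree:    ", write_newick(x$tree), "\n", sep = "")
  invisible(x)
}
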