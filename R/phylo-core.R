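#' Parse a Newick string into an unrooted tree
#'
#' Reads a single Newick statement and returns the corresponding unrooted
#' tree as an ape \code{"phylo"} object in canonical form. A bifurcating
#' Newick root is suppressed, so rooted and unrooted serializations of the
#' same topology parse to equal trees. Branch lengths and quoted labels are
#' preserved; internal node labels are ignored.
#'
#' @param text A character scalar holding one Newick statement terminated
#'   by \code{";"}.
#' @return An unrooted \code{"phylo"} object in canonical orientation
#'   (see [write_newick()]).
#' @examples
#' tr <- parse_newick("((a,b),(c,d));")
#' write_newick(tr)
#' @seealso [write_newick()], [read_newick_file()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";")) {
    stop("malformed Newick: statement must end with ';'")
  }
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("malformed Newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of statement")
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("malformed Newick: could not be parsed")
  phy <- unquote_labels(phy)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  if (any(!nzchar(phy$tip.label))) stop("empty leaf labels are not allowed")
  ut_to_phylo(ut_from_phylo(phy))
}

#' Read trees from a Newick file, one tree per line
#'
#' @param path Path to a text file with one Newick statement per line.
#' @return A list of unrooted \code{"phylo"} objects.
#' @export
read_newick_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_newick)
}

#' Serialize a tree to canonical Newick
#'
#' The output is deterministic: the tree is written as a trifurcation at the
#' internal node adjacent to the lexicographically smallest leaf, and
#' children are ordered everywhere by their smallest descendant label.
#' Two trees have the same topology exactly when their canonical strings
#' (without lengths) are equal.
#'
#' @param tree A \code{"phylo"} object.
#' @param include_lengths Include branch lengths where present? Edges created
#'   by completion carry no length. Default \code{FALSE}.
#' @return A single Newick string terminated by \code{";"}.
#' @export
write_newick <- function(tree, include_lengths = FALSE) {
  ut_canonical_newick(as_ut(tree), include_lengths = include_lengths)
}

#' Write trees to a Newick file, one per line
#'
#' @param trees A \code{"phylo"} object or a list of them.
#' @param path Output file path.
#' @param include_lengths Include branch lengths where present?
#' @return The path, invisibly.
#' @export
write_newick_file <- function(trees, path, include_lengths = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1),
                    include_lengths = include_lengths), path)
  invisible(path)
}

as_ut <- function(tree) {
  if (inherits(tree, "phylo")) return(ut_from_phylo(tree))
  stop("expected a \"phylo\" object")
}

check_binary <- function(ut, what = "tree") {
  if (!ut_is_binary(ut)) {
    stop(what, " must be binary (every internal node of degree 3)")
  }
  invisible(TRUE)
}

#' Construct a bipartition (split) of a taxon set
#'
#' A bipartition is the split \eqn{A|B} of a tree's leaf set induced by
#' deleting one edge. Equality depends only on the unordered pair of sides;
#' the stored \code{side_a} is the side containing the lexicographically
#' smallest taxon.
#'
#' @param side_a,side_b Character vectors of taxon names; disjoint, both
#'   nonempty.
#' @return An object of class \code{"bipartition"} with elements
#'   \code{side_a}, \code{side_b} and \code{trivial} (\code{TRUE} when one
#'   side is a single taxon).
#' @examples
#' bipartition(c("c", "d"), c("a", "b"))
#' @export
bipartition <- function(side_a, side_b) {
  side_a <- lab_sort(unique(as.character(side_a)))
  side_b <- lab_sort(unique(as.character(side_b)))
  if (!length(side_a) || !length(side_b)) stop("both sides must be nonempty")
  if (length(intersect(side_a, side_b))) {
    stop("sides overlap: ", paste(intersect(side_a, side_b), collapse = ", "))
  }
  if (side_b[1] < side_a[1]) {
    tmp <- side_a; side_a <- side_b; side_b <- tmp
  }
  structure(list(side_a = side_a, side_b = side_b,
                 trivial = min(length(side_a), length(side_b)) == 1L),
            class = "bipartition")
}

#' @export
format.bipartition <- function(x, ...) {
  paste(paste(x$side_a, collapse = " "), "|", paste(x$side_b, collapse = " "))
}

#' @export
print.bipartition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
`==.bipartition` <- function(e1, e2) {
  identical(e1$side_a, e2$side_a) && identical(e1$side_b, e2$side_b)
}

bipartition_from_side <- function(side, all_taxa) {
  bipartition(side, setdiff(all_taxa, side))
}

#' Extract the bipartitions of a tree
#'
#' Returns one bipartition per edge of the tree (per internal edge when
#' \code{include_trivial = FALSE}). An n-leaf binary tree has \eqn{n - 3}
#' nontrivial bipartitions.
#'
#' @param tree A \code{"phylo"} object with at least 2 leaves.
#' @param include_trivial Also return the leaf-incident (trivial) splits?
#'   Default \code{FALSE}.
#' @return A list of [bipartition()] objects.
#' @examples
#' length(tree_bipartitions(parse_newick("((a,b),(c,(d,e)));")))  # 5 - 3 = 2
#' @export
tree_bipartitions <- function(tree, include_trivial = FALSE) {
  ut <- as_ut(tree)
  labs <- lab_sort(ut_leaf_labels(ut))
  if (length(labs) < 2L) stop("tree must have at least 2 leaves")
  st <- ut_split_table(ut)
  keep <- if (include_trivial) seq_along(st$key) else which(!st$trivial)
  keep <- keep[!duplicated(st$key[keep])]
  lapply(keep, function(i) bipartition_from_side(st$side[[i]], labs))
}

#' Restrict a tree to a subset of its taxa
#'
#' Computes the minimal subtree connecting the requested taxa and suppresses
#' the resulting degree-2 nodes, i.e. the induced topology on the subset.
#' Branch lengths along suppressed paths are summed.
#'
#' @param tree A \code{"phylo"} object.
#' @param taxa Character vector of taxon names, a subset of the tree's
#'   leaves with at least 2 elements.
#' @return The restricted tree as an unrooted \code{"phylo"} object.
#' @examples
#' write_newick(restrict_tree(parse_newick("((a,b),(c,(d,e)));"),
#'                            c("a", "c", "d", "e")))
#' @export
restrict_tree <- function(tree, taxa) {
  ut <- as_ut(tree)
  taxa <- as.character(taxa)
  missing <- setdiff(taxa, ut_leaf_labels(ut))
  if (length(missing)) {
    stop("taxa not present in the tree: ", paste(missing, collapse = ", "))
  }
  if (length(taxa) < 2L) stop("need at least 2 taxa to restrict to")
  ut_to_phylo(ut_restrict(ut, taxa))
}

#' Robinson-Foulds distance between two trees
#'
#' The number of nontrivial bipartitions present in exactly one of the two
#' trees (the size of the symmetric difference of their bipartition sets).
#' For two binary trees the counts unique to each tree are equal, so the
#' distance is always even.
#'
#' @param t1,t2 \code{"phylo"} objects on the same leaf set of size
#'   at least 3.
#' @return A nonnegative integer; 0 exactly when the topologies are equal.
#' @examples
#' rf_distance(parse_newick("((a,b),(c,d));"), parse_newick("((a,c),(b,d));"))
#' @export
rf_distance <- function(t1, t2) {
  u1 <- as_ut(t1); u2 <- as_ut(t2)
  if (length(ut_leaf_labels(u1)) < 3L) stop("trees must have at least 3 leaves")
  ut_rf(u1, u2)
}

#' Normalized Robinson-Foulds distance
#'
#' The RF distance divided by the total number of internal edges in the two
#' trees, giving a value in \eqn{[0, 1]}: 0 for identical topologies, 1 when
#' no nontrivial bipartition is shared. For two binary n-leaf trees the
#' denominator is \eqn{2(n-3)}.
#'
#' @inheritParams rf_distance
#' @return A real number in \eqn{[0, 1]}.
#' @export
normalized_rf <- function(t1, t2) {
  u1 <- as_ut(t1); u2 <- as_ut(t2)
  if (length(ut_leaf_labels(u1)) < 3L) stop("trees must have at least 3 leaves")
  ne1 <- sum(!ut_split_table(u1)$trivial)
  ne2 <- sum(!ut_split_table(u2)$trivial)
  if (ne1 + ne2 == 0L) {
    stop("normalized RF undefined: both trees are stars (no internal edges)")
  }
  ut_rf(u1, u2) / (ne1 + ne2)
}

#' Root a tree at a leaf and prune that leaf
#'
#' Roots the tree at leaf \code{x}, then removes \code{x} and its incident
#' edge, producing a rooted binary tree on the remaining leaves whose root
#' has exactly two children. This is the rooted view used when deciding
#' where a new leaf is inserted during completion.
#'
#' @param tree An unrooted binary \code{"phylo"} object with at least
#'   3 leaves.
#' @param x The name of a leaf of \code{tree}.
#' @return A rooted \code{"phylo"} object on \code{setdiff(leaves, x)} with
#'   deterministic child ordering (smallest descendant label first).
#' @export
root_at_leaf <- function(tree, x) {
  ut <- as_ut(tree)
  check_binary(ut)
  leaves <- ut_leaf_nodes(ut)
  if (length(leaves) < 3L) stop("tree must have at least 3 leaves")
  xn <- leaves[ut$label[leaves] == x]
  if (!length(xn)) stop("leaf not found in tree: ", x)
  root <- ut$adj[[xn]][1]
  ser <- function(v, parent) {
    if (!is.na(ut$label[v])) {
      return(list(str = quote_label(ut$label[v]), min = ut$label[v]))
    }
    kids <- setdiff(ut$adj[[v]], parent)
    parts <- lapply(kids, ser, parent = v)
    mins <- vapply(parts, `[[`, character(1), "min")
    o <- order(mins, method = "radix")
    list(str = paste0("(", paste(vapply(parts[o], `[[`, character(1), "str"),
                                 collapse = ","), ")"),
         min = mins[o[1]])
  }
  kids <- setdiff(ut$adj[[root]], xn)
  parts <- lapply(kids, ser, parent = root)
  mins <- vapply(parts, `[[`, character(1), "min")
  o <- order(mins, method = "radix")
  txt <- paste0("(", paste(vapply(parts[o], `[[`, character(1), "str"),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

#' Test whether two trees have the same unrooted topology
#'
#' @inheritParams rf_distance
#' @return \code{TRUE} when the two trees induce the same set of
#'   bipartitions.
#' @export
same_topology <- function(t1, t2) {
  identical(write_newick(t1), write_newick(t2))
}

#' Leaf labels of a tree, sorted
#'
#' @param tree A \code{"phylo"} object.
#' @return Character vector of taxon names in canonical (C-locale) order.
#' @export
leaf_set <- function(tree) {
  lab_sort(as_ut(tree)$label[!is.na(as_ut(tree)$label)])
}
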