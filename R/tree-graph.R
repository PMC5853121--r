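# Internal adjacency-list representation of an unrooted (possibly multifurcating)
# leaf-labelled tree. Public functions exchange ape "phylo" objects; the
# algorithmic core works on this lighter structure so that leaf insertion,
# restriction and split hashing stay cheap inside tight loops.
#
# Structure: list(adj   = list of integer neighbour vectors, one per node,
#                 label = character vector, NA for internal nodes,
#                 elen  = optional named numeric of branch lengths, names "u.v"
#                         with u < v; lengths are metadata only)

ut_new <- function(adj, label, elen = NULL) {
  list(adj = adj, label = label, elen = elen)
}

ut_nnodes <- function(ut) length(ut$adj)

ut_leaf_nodes <- function(ut) which(!is.na(ut$label))

ut_leaf_labels <- function(ut) ut$label[!is.na(ut$label)]

ut_degree <- function(ut) lengths(ut$adj)

# canonical C-locale sort used for every label ordering in the package
lab_sort <- function(x) sort(x, method = "radix")

ekey <- function(u, v) {
  paste0(pmin(u, v), ".", pmax(u, v))
}

ut_edge_length <- function(ut, u, v) {
  if (is.null(ut$elen)) return(NA_real_)
  len <- ut$elen[[ekey(u, v)]]
  if (is.null(len)) NA_real_ else len
}

# undirected edge list as a 2-column matrix (u < v), fixed deterministic order
ut_edges <- function(ut) {
  us <- integer(0); vs <- integer(0)
  for (u in seq_along(ut$adj)) {
    nb <- ut$adj[[u]]
    keep <- nb > u
    if (any(keep)) {
      us <- c(us, rep.int(u, sum(keep)))
      vs <- c(vs, nb[keep])
    }
  }
  cbind(u = us, v = vs)
}

ut_from_phylo <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  adj <- rep(list(integer(0)), nn)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  label <- rep(NA_character_, nn)
  label[seq_len(ntip)] <- phy$tip.label
  elen <- NULL
  if (!is.null(phy$edge.length)) {
    elen <- phy$edge.length
    names(elen) <- ekey(phy$edge[, 1], phy$edge[, 2])
  }
  ut <- ut_new(adj, label, elen)
  ut_suppress_degree2(ut)
}

# remove degree-2 nodes (e.g. a rooted Newick's basal node) and compact ids
ut_suppress_degree2 <- function(ut) {
  repeat {
    deg <- ut_degree(ut)
    sup <- which(deg == 2 & is.na(ut$label))
    if (!length(sup)) break
    v <- sup[1]
    nb <- ut$adj[[v]]
    a <- nb[1]; b <- nb[2]
    la <- ut_edge_length(ut, v, a); lb <- ut_edge_length(ut, v, b)
    ut$adj[[a]] <- c(setdiff(ut$adj[[a]], v), b)
    ut$adj[[b]] <- c(setdiff(ut$adj[[b]], v), a)
    ut$adj[[v]] <- integer(0)
    if (!is.null(ut$elen)) {
      ut$elen <- ut$elen[setdiff(names(ut$elen), c(ekey(v, a), ekey(v, b)))]
      if (!is.na(la) || !is.na(lb)) {
        ut$elen[[ekey(a, b)]] <- sum(c(la, lb), na.rm = TRUE)
      }
    }
  }
  ut_compact(ut)
}

# drop isolated nodes and renumber 1..n
ut_compact <- function(ut) {
  alive <- which(ut_degree(ut) > 0 | (ut_nnodes(ut) == 1 & !is.na(ut$label)))
  if (length(alive) == ut_nnodes(ut)) return(ut)
  map <- integer(ut_nnodes(ut))
  map[alive] <- seq_along(alive)
  adj <- lapply(ut$adj[alive], function(nb) map[nb])
  label <- ut$label[alive]
  elen <- NULL
  if (!is.null(ut$elen) && length(ut$elen)) {
    uv <- do.call(rbind, strsplit(names(ut$elen), ".", fixed = TRUE))
    u <- map[as.integer(uv[, 1])]; v <- map[as.integer(uv[, 2])]
    keep <- u > 0 & v > 0
    elen <- ut$elen[keep]
    names(elen) <- ekey(u[keep], v[keep])
  }
  ut_new(adj, label, elen)
}

# iterative preorder from `root`, never crossing into `forbid`
ut_preorder <- function(ut, root, forbid = 0L) {
  n <- ut_nnodes(ut)
  order <- integer(0)
  parent <- integer(n)
  stack <- root
  parent[root] <- forbid
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    for (w in ut$adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  list(order = order, parent = parent)
}

# For each node, the sorted labels of the leaves in its subtree when the tree
# is rooted at the leaf with the smallest label. The entry for a non-root node
# v is the side of edge (parent(v), v) that does not contain that smallest
# leaf -- the canonical side used to key bipartitions.
ut_below_sets <- function(ut, root = NULL) {
  labs <- ut_leaf_labels(ut)
  if (is.null(root)) {
    root <- ut_leaf_nodes(ut)[order(labs, method = "radix")[1]]
  }
  po <- ut_preorder(ut, root)
  below <- vector("list", ut_nnodes(ut))
  for (v in rev(po$order)) {
    if (!is.na(ut$label[v]) && v != root) {
      below[[v]] <- ut$label[v]
    } else {
      kids <- setdiff(ut$adj[[v]], po$parent[v])
      below[[v]] <- lab_sort(unlist(below[kids], use.names = FALSE))
    }
  }
  list(below = below, root = root, parent = po$parent, order = po$order)
}

split_key <- function(labels) paste(labels, collapse = "\x1f")

# one row per edge: canonical side (excluding the global smallest leaf),
# its key, and whether the split is trivial
ut_split_table <- function(ut) {
  bs <- ut_below_sets(ut)
  nleaf <- length(ut_leaf_nodes(ut))
  us <- integer(0); vs <- integer(0); keys <- character(0)
  sizes <- integer(0); sides <- list()
  for (v in bs$order) {
    p <- bs$parent[v]
    if (p == 0L) next
    us <- c(us, p); vs <- c(vs, v)
    side <- bs$below[[v]]
    sides[[length(sides) + 1L]] <- side
    keys <- c(keys, split_key(side))
    sizes <- c(sizes, length(side))
  }
  list(parent = us, child = vs, key = keys, size = sizes, side = sides,
       nleaf = nleaf, trivial = sizes == 1L | sizes == nleaf - 1L)
}

ut_nontrivial_keys <- function(ut) {
  st <- ut_split_table(ut)
  st$key[!st$trivial]
}

ut_rf <- function(ut1, ut2) {
  l1 <- lab_sort(ut_leaf_labels(ut1)); l2 <- lab_sort(ut_leaf_labels(ut2))
  if (!identical(l1, l2)) {
    stop("trees are on different leaf sets; only in first: ",
         paste(setdiff(l1, l2), collapse = ", "), "; only in second: ",
         paste(setdiff(l2, l1), collapse = ", "))
  }
  k1 <- ut_nontrivial_keys(ut1); k2 <- ut_nontrivial_keys(ut2)
  sum(!(k1 %in% k2)) + sum(!(k2 %in% k1))
}

# restriction to a taxon subset: strip unwanted leaves, then suppress
# degree-2 nodes (branch lengths along suppressed paths are summed)
ut_restrict <- function(ut, taxa) {
  keep_leaf <- !is.na(ut$label) & ut$label %in% taxa
  repeat {
    deg <- ut_degree(ut)
    drop <- which(deg == 1L & !keep_leaf)
    drop <- drop[vapply(drop, function(v) length(ut$adj[[v]]) > 0L, logical(1))]
    if (!length(drop)) break
    for (v in drop) {
      nb <- ut$adj[[v]]
      if (!length(nb)) next
      ut$adj[[nb]] <- setdiff(ut$adj[[nb]], v)
      ut$adj[[v]] <- integer(0)
      if (!is.null(ut$elen)) {
        ut$elen <- ut$elen[setdiff(names(ut$elen), ekey(v, nb))]
      }
      ut$label[v] <- NA_character_
    }
  }
  ut_suppress_degree2(ut)
}

# subdivide edge (u, v) with a new node and attach a new leaf to it;
# the three new edges carry no branch length
ut_attach <- function(ut, u, v, label) {
  stopifnot(v %in% ut$adj[[u]])
  n <- ut_nnodes(ut)
  w <- n + 1L; z <- n + 2L
  ut$adj[[u]][ut$adj[[u]] == v] <- w
  ut$adj[[v]][ut$adj[[v]] == u] <- w
  ut$adj[[w]] <- c(u, v, z)
  ut$adj[[z]] <- w
  ut$label <- c(ut$label, NA_character_, label)
  if (!is.null(ut$elen)) {
    ut$elen <- ut$elen[setdiff(names(ut$elen), ekey(u, v))]
  }
  ut
}

ut_is_binary <- function(ut) {
  deg <- ut_degree(ut)
  nleaf <- length(ut_leaf_nodes(ut))
  if (nleaf <= 2L) return(TRUE)
  all(deg[is.na(ut$label)] == 3L) && all(deg[!is.na(ut$label)] == 1L)
}

quote_label <- function(x) {
  needs <- grepl("[][ (),:;'\t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

# deterministic serialization: the tree is written as a trifurcation at the
# internal node adjacent to the smallest leaf, children everywhere ordered by
# their smallest descendant label
ut_canonical_newick <- function(ut, include_lengths = FALSE) {
  leaves <- ut_leaf_nodes(ut)
  if (length(leaves) < 2L) stop("cannot serialize a tree with fewer than 2 leaves")
  fmt_len <- function(u, v) {
    if (!include_lengths) return("")
    len <- ut_edge_length(ut, u, v)
    if (is.na(len)) "" else paste0(":", format(len, digits = 15))
  }
  if (length(leaves) == 2L) {
    labs <- lab_sort(quote_label(ut$label[leaves]))
    return(paste0("(", labs[1], ",", labs[2], ");"))
  }
  ser <- function(v, parent) {
    if (!is.na(ut$label[v])) {
      return(list(str = paste0(quote_label(ut$label[v]), fmt_len(parent, v)),
                  min = ut$label[v]))
    }
    kids <- setdiff(ut$adj[[v]], parent)
    parts <- lapply(kids, ser, parent = v)
    mins <- vapply(parts, `[[`, character(1), "min")
    o <- order(mins, method = "radix")
    list(str = paste0("(", paste(vapply(parts[o], `[[`, character(1), "str"),
                                 collapse = ","), ")", fmt_len(parent, v)),
         min = mins[o[1]])
  }
  start <- leaves[order(ut$label[leaves], method = "radix")[1]]
  root <- ut$adj[[start]][1]
  kids <- c(start, setdiff(ut$adj[[root]], start))
  parts <- lapply(kids, ser, parent = root)
  mins <- vapply(parts, `[[`, character(1), "min")
  o <- order(mins, method = "radix")
  paste0("(", paste(vapply(parts[o], `[[`, character(1), "str"),
                    collapse = ","), ");")
}

# ape keeps the surrounding quotes of quoted Newick labels; strip them and
# unescape doubled quotes
unquote_labels <- function(phy) {
  quoted <- grepl("^'.*'$", phy$tip.label)
  phy$tip.label[quoted] <- gsub("''", "'",
    substr(phy$tip.label[quoted], 2L, nchar(phy$tip.label[quoted]) - 1L))
  phy
}

ut_to_phylo <- function(ut) {
  unquote_labels(
    ape::read.tree(text = ut_canonical_newick(ut, include_lengths = TRUE)))
}

ut_equal_topology <- function(ut1, ut2) {
  identical(ut_canonical_newick(ut1), ut_canonical_newick(ut2))
}

# run code under a temporary RNG state seeded with `seed` (NULL = use the
# current stream untouched)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
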