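# Evaluation distances beyond RF: the quartet distance (number of 4-taxon
# subsets inducing different topologies) and the matching distance (minimum
# weight perfect matching between the two trees' nontrivial bipartition
# sets, weighted by the number of leaves that must move to turn one split
# into the other).

tree_distance <- function(metric, raw, denominator = NA_real_) {
  structure(list(metric = metric, raw = raw, denominator = denominator,
                 normalized = if (is.na(denominator)) NA_real_
                              else raw / denominator),
            class = "tree_distance")
}

#' @export
print.tree_distance <- function(x, ...) {
  cat(x$metric, "distance:", x$raw)
  if (!is.na(x$denominator)) {
    cat("  (normalized ", format(x$normalized, digits = 4),
        " over ", x$denominator, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

check_same_leaves <- function(u1, u2) {
  l1 <- lab_sort(ut_leaf_labels(u1)); l2 <- lab_sort(ut_leaf_labels(u2))
  if (!identical(l1, l2)) {
    stop("trees are on different leaf sets; only in first: ",
         paste(setdiff(l1, l2), collapse = ", "), "; only in second: ",
         paste(setdiff(l2, l1), collapse = ", "))
  }
  l1
}

# topological (unit branch length) leaf-to-leaf distance matrix,
# rows/columns in canonical label order
topo_dist <- function(tree, taxa) {
  phy <- tree
  phy$edge.length <- rep(1, nrow(phy$edge))
  D <- ape::cophenetic.phylo(phy)
  D[taxa, taxa]
}

#' Quartet distance between two trees
#'
#' Counts the 4-leaf subsets whose induced (unrooted) quartet topology
#' differs between the two trees, by exhaustive examination of all
#' \eqn{\binom{n}{4}} subsets. The induced topology of a quartet
#' \eqn{\{a,b,c,d\}} is read off the four-point condition on topological
#' path lengths: the pairing with the smallest summed path length is the one
#' the tree resolves.
#'
#' @param t1,t2 Binary \code{"phylo"} objects on the same leaf set of size
#'   at least 4.
#' @return A \code{"tree_distance"} object with the raw count, the
#'   denominator \eqn{\binom{n}{4}} and the normalized value.
#' @examples
#' quartet_distance(parse_newick("((a,b),(c,d));"),
#'                  parse_newick("((a,c),(b,d));"))
#' @export
quartet_distance <- function(t1, t2) {
  u1 <- as_ut(t1); u2 <- as_ut(t2)
  taxa <- check_same_leaves(u1, u2)
  check_binary(u1); check_binary(u2)
  n <- length(taxa)
  if (n < 4L) stop("quartet distance needs at least 4 leaves")
  D1 <- topo_dist(t1, taxa)
  D2 <- topo_dist(t2, taxa)
  q <- utils::combn(n, 4L)
  a <- q[1, ]; b <- q[2, ]; c <- q[3, ]; d <- q[4, ]
  top_of <- function(D) {
    s <- cbind(D[cbind(a, b)] + D[cbind(c, d)],
               D[cbind(a, c)] + D[cbind(b, d)],
               D[cbind(a, d)] + D[cbind(b, c)])
    max.col(-s, ties.method = "first")
  }
  raw <- sum(top_of(D1) != top_of(D2))
  tree_distance("quartet", raw, choose(n, 4L))
}

# Exact minimum-cost assignment (Hungarian algorithm with potentials,
# O(n^3)). Returns the assigned column for each row and the total cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(list(cols = integer(0), value = 0))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # row matched to each column; 0 = free
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      idx <- which(!used[seq_len(n)])
      cur <- cost[i0, idx] - u[i0] - v[idx]
      better <- cur < minv[idx]
      minv[idx[better]] <- cur[better]
      way[idx[better]] <- j0
      j1 <- idx[which.min(minv[idx])]
      delta <- minv[j1]
      su <- which(used)
      u[p[su]] <- u[p[su]] + delta
      v[su] <- v[su] - delta
      nu <- which(!used)
      minv[nu] <- minv[nu] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  cols <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) cols[p[j]] <- j
  list(cols = cols, value = sum(cost[cbind(seq_len(n), cols)]))
}

#' Matching distance between two trees
#'
#' The weight of a minimum-weight perfect matching between the two trees'
#' nontrivial bipartition sets, where matching a split \eqn{A|B} of one tree
#' to a split \eqn{C|D} of the other costs
#' \eqn{\min(|A \triangle C|, |A \triangle D|)} -- the number of leaves that
#' must be moved to transform one split into the other, taken over both
#' orientations. The assignment is solved exactly. Only the raw value is
#' reported; no normalization is defined for this distance.
#'
#' @param t1,t2 Binary \code{"phylo"} objects on the same leaf set of size
#'   at least 4 (so the two bipartition sets have equal size \eqn{n-3}).
#' @return A \code{"tree_distance"} object with the raw matching weight.
#' @examples
#' matching_distance(parse_newick("((a,b),(c,d));"),
#'                   parse_newick("((a,c),(b,d));"))
#' @export
matching_distance <- function(t1, t2) {
  u1 <- as_ut(t1); u2 <- as_ut(t2)
  taxa <- check_same_leaves(u1, u2)
  check_binary(u1); check_binary(u2)
  n <- length(taxa)
  if (n < 4L) stop("matching distance needs at least 4 leaves")
  side_matrix <- function(ut) {
    st <- ut_split_table(ut)
    sides <- st$side[!st$trivial]
    sides <- sides[!duplicated(st$key[!st$trivial])]
    t(vapply(sides, function(s) taxa %in% s, logical(n)))
  }
  M1 <- side_matrix(u1); M2 <- side_matrix(u2)
  if (nrow(M1) != nrow(M2)) {
    stop("trees have unequal numbers of nontrivial bipartitions (",
         nrow(M1), " vs ", nrow(M2), ")")
  }
  sz1 <- rowSums(M1); sz2 <- rowSums(M2)
  inter <- M1 %*% t(M2)
  d_same <- outer(sz1, sz2, "+") - 2 * inter
  d_flip <- n - outer(sz1, sz2, "+") + 2 * inter
  W <- pmin(d_same, d_flip)
  tree_distance("matching", solve_assignment(W)$value)
}
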