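# ET sequence distances, UPGMA tree construction, and the level-wise
# partition of sequences into groups that both scoring methods traverse.
#
# The tree is stored hclust-style (merge matrix + merge heights) because the
# scorers need the exact agglomeration order, which generic phylo objects do
# not preserve; conversion to ape::phylo is provided for export.

#' Evolutionary Trace distance between two aligned sequences
#'
#' Distance is 1 minus the number of aligned columns whose BLOSUM62 log-odds
#' reach the rule threshold, divided by the smaller of the two sequences'
#' non-gap lengths. Gap-against-anything has log-odds 0 and never counts as
#' a match at the default threshold.
#'
#' @param row_a,row_b Aligned sequences of equal length (strings over the
#'   20 amino acids and \code{"-"}).
#' @param rule A \code{\link{substitution_rule}}.
#' @return Distance in [0, 1]. If either sequence is entirely gaps the
#'   denominator is zero; the distance is defined as 1 with a warning.
#' @export
et_distance <- function(row_a, row_b, rule = substitution_rule()) {
  a <- aa_encode(strsplit(normalize_seq(row_a), "", fixed = TRUE)[[1]])
  b <- aa_encode(strsplit(normalize_seq(row_b), "", fixed = TRUE)[[1]])
  if (anyNA(a) || anyNA(b)) stop("sequence contains characters outside the alphabet")
  if (length(a) != length(b)) stop("sequences differ in aligned length")
  et_distance_coded(a, b, rule)
}

et_distance_coded <- function(a, b, rule) {
  gap <- 21L
  denom <- min(sum(a != gap), sum(b != gap))
  if (denom == 0L) {
    warning("sequence is entirely gaps; distance defined as 1")
    return(1)
  }
  matches <- sum(rule$match[cbind(a, b)])
  1 - matches / denom
}

#' Pairwise ET distance matrix for an alignment
#'
#' @param aln An \code{alignment} object.
#' @param rule A \code{\link{substitution_rule}}.
#' @return Symmetric N x N matrix with zero diagonal, dimnames the sequence
#'   identifiers.
#' @export
distance_matrix <- function(aln, rule = substitution_rule()) {
  stopifnot(inherits(aln, "alignment"))
  m <- alignment_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$sequence_ids, aln$sequence_ids))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- et_distance_coded(m[i, ], m[j, ], rule)
    }
  }
  # self-distance can exceed 0 for rows with gaps only; keep the diagonal
  # as computed from the definition (0 unless degenerate)
  d
}

#' Build a UPGMA tree from a distance matrix
#'
#' Standard unweighted pair group agglomeration: the two closest clusters
#' merge at a node whose height is half their distance, and distances to the
#' merged cluster are size-weighted averages. Ties on the merge distance are
#' broken deterministically: the candidate pair whose lexicographically
#' least member identifier is smallest wins (then the least identifier of
#' the other cluster).
#'
#' @param d Symmetric distance matrix with identifier dimnames, N >= 2.
#' @return An object of class \code{"et_tree"}: hclust-style \code{merge}
#'   matrix, \code{height} vector of node heights (merge distance / 2), and
#'   \code{labels}.
#' @export
build_upgma <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2L) stop("UPGMA requires at least 2 sequences")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")

  active <- seq_len(n)               # indices into node bookkeeping
  node_id <- -seq_len(n)             # hclust convention: negatives = leaves
  size <- rep(1L, n)
  least <- labels                    # lexicographically least member label
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    sub <- D[active, active, drop = FALSE]
    diag(sub) <- Inf
    mind <- min(sub)
    cand <- which(sub == mind, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on the least member labels of each pair
    lo <- pmin(least[active[cand[, 1]]], least[active[cand[, 2]]])
    hi <- pmax(least[active[cand[, 1]]], least[active[cand[, 2]]])
    pick <- order(lo, hi)[1]
    ia <- active[cand[pick, 1]]
    ib <- active[cand[pick, 2]]

    merge[step, ] <- sort(c(node_id[ia], node_id[ib]))
    height[step] <- mind / 2

    new_size <- size[ia] + size[ib]
    others <- setdiff(active, c(ia, ib))
    newd <- (size[ia] * D[ia, others] + size[ib] * D[ib, others]) / new_size
    # reuse slot ia for the merged cluster
    D[ia, others] <- newd
    D[others, ia] <- newd
    size[ia] <- new_size
    least[ia] <- min(least[ia], least[ib])
    node_id[ia] <- step
    active <- setdiff(active, ib)
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "et_tree")
}

#' @export
print.et_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4g\n",
              length(x$labels), x$height[length(x$height)]))
  invisible(x)
}

# Leaf index sets for every node: entries 1..N are leaves, N + r is the
# internal node created at merge step r.
tree_leaf_sets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n + nrow(tree$merge))
  for (i in seq_len(n)) sets[[i]] <- i
  for (r in seq_len(nrow(tree$merge))) {
    ch <- tree$merge[r, ]
    idx <- ifelse(ch < 0, -ch, n + ch)
    sets[[n + r]] <- sort(c(sets[[idx[1]]], sets[[idx[2]]]))
  }
  sets
}

# Order in which internal nodes are cut when descending the tree: highest
# merge height first, ties broken by the lexicographically least leaf label
# under the node; a node only becomes available once its parent is cut.
# Returns rank[r] in 1..N-1 for each merge step r (root has rank 1).
cut_ranks <- function(tree) {
  n <- length(tree$labels)
  m <- nrow(tree$merge)
  sets <- tree_leaf_sets(tree)
  least_leaf <- vapply(sets, function(s) min(tree$labels[s]), character(1))
  internal_children <- function(r) {
    ch <- tree$merge[r, ]
    ch[ch > 0]
  }
  rank <- integer(m)
  avail <- m  # root is the last merge
  for (k in seq_len(m)) {
    h <- tree$height[avail]
    ll <- least_leaf[n + avail]
    pick <- avail[order(-h, ll)][1]
    rank[pick] <- k
    avail <- c(setdiff(avail, pick), internal_children(pick))
  }
  rank
}

#' Level-wise partition of sequences along the tree
#'
#' Level n is obtained by cutting the n - 1 highest internal nodes (root
#' first): level 1 is one group holding every sequence, level N is all
#' singletons, and each level refines the previous by splitting exactly one
#' group in two. Group ids at each level are numbered by their smallest leaf
#' index.
#'
#' @param tree An \code{et_tree}.
#' @return An object of class \code{"level_partition"}: an N x N integer
#'   matrix \code{membership} (row = level, column = leaf, value = group id)
#'   plus \code{labels}.
#' @export
level_partition <- function(tree) {
  stopifnot(inherits(tree, "et_tree"))
  n <- length(tree$labels)
  groups <- tree_node_groups(tree)
  membership <- matrix(0L, n, n, dimnames = list(NULL, tree$labels))
  for (g in groups) {
    lv <- seq.int(g$level_lo, g$level_hi)
    membership[lv, g$members] <- min(g$members)
  }
  # renumber group ids 1..n by smallest member
  for (lv in seq_len(n)) {
    membership[lv, ] <- match(membership[lv, ], sort(unique(membership[lv, ])))
  }
  structure(list(membership = membership, labels = tree$labels),
            class = "level_partition")
}

# The group decomposition both scorers traverse. Every tree node (leaf or
# internal) is a group for a contiguous range of levels [level_lo, level_hi];
# weight is sum over that range (intersected with 1..N-1, the levels the
# scores sum over) of 1/n.
tree_node_groups <- function(tree) {
  n <- length(tree$labels)
  m <- nrow(tree$merge)
  rank <- cut_ranks(tree)
  sets <- tree_leaf_sets(tree)
  # parent rank for each node (0 for root)
  parent_rank <- integer(n + m)
  for (r in seq_len(m)) {
    ch <- tree$merge[r, ]
    idx <- ifelse(ch < 0, -ch, n + ch)
    parent_rank[idx] <- rank[r]
  }
  out <- vector("list", n + m)
  for (u in seq_len(n + m)) {
    lo <- if (u == n + m) 1L else parent_rank[u] + 1L
    hi <- if (u > n) rank[u - n] else n
    lv <- seq.int(lo, hi)
    w <- sum(1 / lv[lv <= n - 1L])
    out[[u]] <- list(members = sets[[u]], level_lo = lo, level_hi = hi,
                     weight = w)
  }
  out
}

#' Convert an ET tree to an ape phylo object
#'
#' @param tree An \code{et_tree}.
#' @return An \code{ape::phylo} with branch lengths derived from the merge
#'   heights (ultrametric).
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "et_tree"))
  hc <- structure(
    list(merge = tree$merge, height = tree$height,
         order = hclust_order(tree$merge), labels = tree$labels,
         method = "average"),
    class = "hclust"
  )
  ape::as.phylo(hc)
}

hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Write a tree in Newick format
#'
#' @param tree An \code{et_tree}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' Square TSV with identifier row and column headers.
#'
#' @param d Distance matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a distance matrix from TSV or PHYLIP square format
#'
#' @param path Input path. PHYLIP square files (first line the sequence
#'   count) are detected automatically.
#' @return Symmetric distance matrix with identifier dimnames.
#' @export
read_distance_tsv <- function(path) {
  first <- trimws(readLines(path, n = 1L))
  if (grepl("^[0-9]+$", first)) {
    n <- as.integer(first)
    rows <- utils::read.table(path, skip = 1L, stringsAsFactors = FALSE)
    if (nrow(rows) != n) stop("PHYLIP matrix row count does not match header")
    d <- as.matrix(rows[, -1, drop = FALSE])
    dimnames(d) <- list(rows[[1]], rows[[1]])
  } else {
    d <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    colnames(d) <- rownames(d)
  }
  storage.mode(d) <- "double"
  d
}
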