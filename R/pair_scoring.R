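# Pairwise transition classification and the two covariation scores.
#
# Both scores traverse the same level partition of the UPGMA tree; the sum
# over levels n = 1..N-1 of (1/n) * (per-group term) is computed node-wise:
# each tree node is a group over a contiguous range of levels, so its term
# is evaluated once and weighted by sum(1/n) over that range. A pair of
# invariant columns therefore scores exactly N under CovET (every group term
# is 1) and 0 under ET-MIp (every group term is 0).

#' Classify the transition of a residue pair between two sequences
#'
#' Comparing positions (i, j) between sequence a and sequence b gives an
#' ordered 4-tuple (xa_i, xa_j, xb_i, xb_j). It is \emph{conservation} when
#' neither position changes, \emph{concerted} variation when both change,
#' and \emph{nonconcerted} variation when exactly one changes; only the last
#' is evidence against a coupling and only it is penalized by CovET.
#'
#' @param xa_i,xa_j,xb_i,xb_j Characters from the 21-letter alphabet
#'   (vectorized; recycled to a common length).
#' @return Character vector with values \code{"conservation"},
#'   \code{"concerted"}, or \code{"nonconcerted"}.
#' @export
classify_transition <- function(xa_i, xa_j, xb_i, xb_j) {
  n <- max(length(xa_i), length(xa_j), length(xb_i), length(xb_j))
  enc <- function(x) {
    v <- aa_encode(rep_len(as.character(x), n))
    if (anyNA(v)) stop("character outside the 21-letter alphabet")
    v
  }
  ai <- enc(xa_i); aj <- enc(xa_j); bi <- enc(xb_i); bj <- enc(xb_j)
  di <- ai != bi
  dj <- aj != bj
  out <- rep("nonconcerted", n)
  out[!di & !dj] <- "conservation"
  out[di & dj] <- "concerted"
  out
}

#' Transition class counts for an alphabet
#'
#' Closed-form counts of the three transition classes over all ordered
#' 4-tuples from an alphabet of size \code{alphabet_size}: alpha^4 tuples in
#' total, alpha^2 conservations, alpha^2 (alpha - 1)^2 concerted, and
#' 2 alpha^2 (alpha - 1) nonconcerted. For the 21-letter protein alphabet
#' these are 194481, 441, 176400, and 17640.
#'
#' @param alphabet_size Integer >= 2.
#' @return Named list: \code{total}, \code{conservation}, \code{concerted},
#'   \code{nonconcerted}.
#' @export
enumerate_transition_classes <- function(alphabet_size = 21) {
  a <- as.numeric(alphabet_size)
  stopifnot(a >= 2)
  list(total = a^4,
       conservation = a^2,
       concerted = a^2 * (a - 1)^2,
       nonconcerted = 2 * a^2 * (a - 1))
}

#' Perplexity penalty of one sequence group at a position pair
#'
#' All C(m, 2) unordered within-group sequence comparisons (canonical
#' direction: earlier alignment row to later row) are classified; each
#' nonconcerted comparison falls into a category v, the ordered 4-tuple of
#' its characters. With f_v = count(v) / C(m, 2), the penalty is the
#' perplexity exp(-sum_v f_v log f_v) over nonconcerted categories only
#' (0 log 0 := 0). A group with one member, or with no nonconcerted
#' variation, has penalty 1; the penalty is always >= 1.
#'
#' @param column_i,column_j Character vectors: the group's rows at the two
#'   positions, in alignment row order.
#' @param normalize Denominator convention for f_v: \code{"comparisons"}
#'   (the default; all C(m, 2) comparisons, so sum(f_v) may be below 1) or
#'   \code{"events"} (nonconcerted events only, so f_v sums to 1).
#' @return Penalty value >= 1.
#' @export
covet_group_penalty <- function(column_i, column_j,
                                normalize = c("comparisons", "events")) {
  normalize <- match.arg(normalize)
  m <- length(column_i)
  if (m == 0L) stop("empty group")
  stopifnot(length(column_j) == m)
  ci <- aa_encode(as.character(column_i))
  cj <- aa_encode(as.character(column_j))
  if (anyNA(ci) || anyNA(cj)) stop("character outside the 21-letter alphabet")
  if (m == 1L) return(1)
  pr <- pair_index(m)
  penalty_from_codes(ci, cj, pr$a, pr$b, normalize)
}

# Unordered row-pair indices a < b for a group of size m.
pair_index <- function(m) {
  a <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  b <- sequence((m - 1L):1L) + a
  list(a = a, b = b)
}

# Core penalty: integer-coded columns ci, cj (length m) and row-pair index
# vectors A, B. Category key encodes the ordered 4-tuple.
penalty_from_codes <- function(ci, cj, A, B, normalize = "comparisons") {
  di <- ci[A] != ci[B]
  dj <- cj[A] != cj[B]
  nc <- xor(di, dj)
  if (!any(nc)) return(1)
  key <- ((ci[A][nc] * 21 + cj[A][nc]) * 21 + ci[B][nc]) * 21 + cj[B][nc]
  counts <- count_runs(key)
  denom <- if (normalize == "comparisons") length(A) else sum(counts)
  f <- counts / denom
  exp(-sum(f * log(f)))
}

# Counts of distinct values in an integer-ish vector (faster than table()).
count_runs <- function(key) {
  k <- sort.int(key, method = "quick")
  n <- length(k)
  if (n == 1L) return(1L)
  bounds <- c(which(k[-1L] != k[-n]), n)
  diff(c(0L, bounds))
}

# Shared scaffolding: restrict the alignment to query-mapped columns and
# enumerate all i < j pairs of query positions.
scoring_context <- function(aln, levels) {
  stopifnot(inherits(aln, "alignment"))
  if (!identical(levels$labels, aln$sequence_ids))
    stop("level partition was built from a different sequence set")
  qmap <- map_query_columns(aln)
  m <- alignment_matrix(aln)[, qmap$column, drop = FALSE]
  k <- nrow(qmap)
  if (k < 2L) stop("need at least two query-mapped columns")
  pr <- pair_index(k)
  list(m = m, k = k, pos_i = qmap$position[pr$a], pos_j = qmap$position[pr$b],
       col_i = pr$a, col_j = pr$b)
}

new_pair_scores <- function(ctx, score, method, lower_is_coupled, n_seq) {
  structure(
    data.frame(pos_i = ctx$pos_i, pos_j = ctx$pos_j, score = score),
    method = method, lower_is_coupled = lower_is_coupled,
    n_sequences = n_seq, class = c("pair_scores", "data.frame")
  )
}

#' @export
print.pair_scores <- function(x, ...) {
  cat(sprintf("%s scores for %d position pairs (%s is more coupled; N = %d)\n",
              attr(x, "method"), nrow(x),
              if (attr(x, "lower_is_coupled")) "lower" else "higher",
              attr(x, "n_sequences")))
  NextMethod()
}

#' CovET scores for all query-mapped position pairs
#'
#' For each pair (i, j), the score is N plus, over every tree group with at
#' least two members, the group's level weight times (perplexity penalty
#' minus 1). This equals 1 + sum over levels n = 1..N-1 of (1/n) times the
#' sum of group penalties at that level. Lower scores indicate stronger
#' coupling; the minimum N is attained exactly when no group shows any
#' entropy in its nonconcerted variation.
#'
#' @param aln An \code{alignment}.
#' @param levels A \code{\link{level_partition}} built from a tree over the
#'   same sequences, or an \code{et_tree} (partitioned internally).
#' @return A \code{pair_scores} data frame (columns \code{pos_i},
#'   \code{pos_j}, \code{score}) with orientation attribute
#'   \code{lower_is_coupled = TRUE}.
#' @param normalize Denominator convention for the nonconcerted frequencies,
#'   as in \code{\link{covet_group_penalty}}.
#' @export
covet_scores <- function(aln, levels,
                         normalize = c("comparisons", "events")) {
  normalize <- match.arg(normalize)
  gr <- resolve_groups(levels)
  ctx <- scoring_context(aln, list(labels = gr$labels))
  n_seq <- length(gr$labels)
  groups <- gr$groups
  score <- rep(n_seq, length(ctx$col_i))
  np <- length(ctx$col_i)
  for (g in groups) {
    m <- length(g$members)
    if (m < 2L || g$weight == 0) next
    sub <- ctx$m[g$members, , drop = FALSE]
    pr <- pair_index(m)
    A <- pr$a; B <- pr$b
    dif <- sub[A, , drop = FALSE] != sub[B, , drop = FALSE]
    subA <- sub[A, , drop = FALSE]
    subB <- sub[B, , drop = FALSE]
    ncomp <- length(A)
    pen <- numeric(np)
    for (p in seq_len(np)) {
      i <- ctx$col_i[p]; j <- ctx$col_j[p]
      nc <- dif[, i] != dif[, j]
      if (!any(nc)) { pen[p] <- 1; next }
      key <- ((subA[nc, i] * 21 + subA[nc, j]) * 21 + subB[nc, i]) * 21 +
        subB[nc, j]
      counts <- count_runs(key)
      f <- counts / (if (normalize == "comparisons") ncomp else sum(counts))
      pen[p] <- exp(-sum(f * log(f)))
    }
    score <- score + g$weight * (pen - 1)
  }
  new_pair_scores(ctx, score, "CovET", TRUE, n_seq)
}

# Collapse a level partition (or tree) to the distinct groups it contains,
# each with its accumulated level weight sum(1/n) over the levels n <= N-1
# at which the group is present.
resolve_groups <- function(levels) {
  if (inherits(levels, "et_tree")) {
    return(list(labels = levels$labels, groups = tree_node_groups(levels)))
  }
  if (!inherits(levels, "level_partition"))
    stop("levels must be an et_tree or level_partition")
  mem <- levels$membership
  n <- nrow(mem)
  acc <- new.env(parent = emptyenv())
  for (lv in seq_len(n - 1L)) {
    for (members in split(seq_len(ncol(mem)), mem[lv, ])) {
      key <- paste(members, collapse = ",")
      prev <- get0(key, envir = acc)
      if (is.null(prev)) {
        assign(key, list(members = members, weight = 1 / lv), envir = acc)
      } else {
        prev$weight <- prev$weight + 1 / lv
        assign(key, prev, envir = acc)
      }
    }
  }
  list(labels = levels$labels,
       groups = unname(as.list(as.list.environment(acc))))
}

#' Mutual information of two columns within a sequence group
#'
#' Plug-in mutual information MI = H_i + H_j - H_ij with natural-log Shannon
#' entropies of the within-group character frequencies over the 21-letter
#' alphabet (gap included).
#'
#' @param column_i,column_j Character vectors of the group's rows at the two
#'   positions.
#' @return MI in nats, >= 0 up to rounding; 0 for a single-member group.
#' @export
group_mutual_information <- function(column_i, column_j) {
  m <- length(column_i)
  if (m == 0L) stop("empty group")
  stopifnot(length(column_j) == m)
  ci <- aa_encode(as.character(column_i))
  cj <- aa_encode(as.character(column_j))
  if (anyNA(ci) || anyNA(cj)) stop("character outside the 21-letter alphabet")
  entropy_counts(count_runs(ci), m) + entropy_counts(count_runs(cj), m) -
    entropy_counts(count_runs(ci * 21L + cj), m)
}

entropy_counts <- function(counts, m) {
  f <- counts / m
  -sum(f * log(f))
}

#' Average product correction of a mutual information table
#'
#' MIp(i, j) = MI(i, j) - MI(i, .) * MI(j, .) / MIbar, where MI(i, .) is the
#' mean MI of position i with every other position and MIbar the mean over
#' all distinct pairs. If MIbar is 0 the correction is 0.
#'
#' @param mi Symmetric MI matrix (diagonal ignored).
#' @return Symmetric corrected matrix with zero diagonal.
#' @export
apc_correct <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  k <- nrow(mi)
  m <- mi
  diag(m) <- 0
  row_mean <- rowSums(m) / (k - 1)
  grand <- sum(m[upper.tri(m)]) / (k * (k - 1) / 2)
  apc <- if (grand == 0) matrix(0, k, k) else outer(row_mean, row_mean) / grand
  out <- m - apc
  diag(out) <- 0
  dimnames(out) <- dimnames(mi)
  out
}

#' ET-MIp scores for all query-mapped position pairs
#'
#' For each pair, the score is the sum over tree levels n = 1..N-1 of (1/n)
#' times the sum over that level's groups of the group's APC-corrected
#' mutual information. Higher scores indicate stronger coupling.
#'
#' @inheritParams covet_scores
#' @return A \code{pair_scores} data frame with orientation attribute
#'   \code{lower_is_coupled = FALSE}.
#' @export
etmip_scores <- function(aln, levels) {
  gr <- resolve_groups(levels)
  ctx <- scoring_context(aln, list(labels = gr$labels))
  n_seq <- length(gr$labels)
  groups <- gr$groups
  k <- ctx$k
  total <- matrix(0, k, k)
  for (g in groups) {
    m <- length(g$members)
    if (m < 2L || g$weight == 0) next
    sub <- ctx$m[g$members, , drop = FALSE]
    h <- vapply(seq_len(k), function(c) entropy_counts(count_runs(sub[, c]), m),
                numeric(1))
    mi <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        hij <- entropy_counts(count_runs(sub[, i] * 21L + sub[, j]), m)
        mi[i, j] <- mi[j, i] <- h[i] + h[j] - hij
      }
    }
    total <- total + g$weight * apc_correct(mi)
  }
  score <- total[cbind(ctx$col_i, ctx$col_j)]
  new_pair_scores(ctx, score, "ET-MIp", FALSE, n_seq)
}

#' Write pair scores as TSV
#'
#' Emits one row per pair with rank and coverage, preceded by comment-header
#' lines recording the method, orientation, sequence count, and an MD5
#' checksum of the alignment rows if supplied.
#'
#' @param pairs A \code{pair_scores} object.
#' @param path Output path.
#' @param aln Optional \code{alignment} used to record a checksum.
#' @return \code{path}, invisibly.
#' @export
write_pair_scores <- function(pairs, path, aln = NULL) {
  stopifnot(inherits(pairs, "pair_scores"))
  rk <- rank_pairs(pairs)
  hdr <- c(
    sprintf("# method=%s", attr(pairs, "method")),
    sprintf("# orientation=%s",
            if (attr(pairs, "lower_is_coupled")) "lower_is_coupled"
            else "higher_is_coupled"),
    sprintf("# n_sequences=%d", attr(pairs, "n_sequences"))
  )
  if (!is.null(aln)) {
    hdr <- c(hdr, sprintf("# alignment_md5=%s", alignment_checksum(aln)))
  }
  writeLines(hdr, path)
  out <- data.frame(pos_i = pairs$pos_i, pos_j = pairs$pos_j,
                    raw_score = pairs$score, rank = rk,
                    coverage = rk / nrow(pairs))
  suppressWarnings(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE)
  )
  invisible(path)
}

alignment_checksum <- function(aln) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(aln$sequence_ids, aln$rows), tmp)
  unname(tools::md5sum(tmp))
}

# Pair ranks in coupling order (1 = most coupled), deterministic: ties on
# the raw score are broken by (pos_i, pos_j) ascending.
rank_pairs <- function(pairs) {
  s <- if (attr(pairs, "lower_is_coupled")) pairs$score else -pairs$score
  ord <- order(s, pairs$pos_i, pairs$pos_j)
  rk <- integer(nrow(pairs))
  rk[ord] <- seq_len(nrow(pairs))
  rk
}
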