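# Pair scores -> single-residue rankings, and the coverage-cutoff selection
# of pairs used by the structural and functional evaluations.

#' Convert pair scores to a single-residue ranking
#'
#' Each residue is scored by the best (orientation-aware) covariation pair
#' it participates in, then ranked; coverage is rank divided by the number
#' of residues ranked. Ties on the best-pair score are broken by ascending
#' position index.
#'
#' @param pairs A \code{pair_scores} object.
#' @return Data frame with columns \code{position}, \code{score},
#'   \code{rank} (1 = most coupled) and \code{coverage}, ordered by rank.
#' @export
residue_scores <- function(pairs) {
  stopifnot(inherits(pairs, "pair_scores"), nrow(pairs) > 0)
  lower <- attr(pairs, "lower_is_coupled")
  long <- data.frame(position = c(pairs$pos_i, pairs$pos_j),
                     score = rep(pairs$score, 2L))
  agg <- if (lower) {
    stats::aggregate(score ~ position, long, min)
  } else {
    stats::aggregate(score ~ position, long, max)
  }
  ord <- order(if (lower) agg$score else -agg$score, agg$position)
  out <- agg[ord, ]
  out$rank <- seq_len(nrow(out))
  out$coverage <- out$rank / nrow(out)
  rownames(out) <- NULL
  out
}

#' Select top pairs up to a residue-coverage threshold
#'
#' Walks the pairs in rank order (most coupled first), accumulating the
#' union of their residues, and stops at the first pair whose inclusion
#' brings the union to at least \code{ceiling(threshold * residue_count)}
#' residues. A coverage cutoff of 10\% is thus "all the pairs it takes until
#' 10\% of residues are touched by at least one pair".
#'
#' @param pairs A \code{pair_scores} object.
#' @param threshold Coverage fraction in (0, 1].
#' @param residue_count Number of residues the coverage is measured against
#'   (defaults to the number of distinct positions in \code{pairs}).
#' @return An object of class \code{"coverage_selection"}: list with
#'   \code{pairs} (data frame of selected pairs in rank order),
#'   \code{residues} (sorted union), \code{threshold}, and
#'   \code{residue_count}. If the table is exhausted first, all pairs are
#'   returned with a warning.
#' @export
coverage_selection <- function(pairs, threshold, residue_count = NULL) {
  stopifnot(inherits(pairs, "pair_scores"),
            threshold > 0, threshold <= 1)
  if (is.null(residue_count))
    residue_count <- length(unique(c(pairs$pos_i, pairs$pos_j)))
  target <- ceiling(threshold * residue_count)
  ord <- order(rank_pairs(pairs))
  pi <- pairs$pos_i[ord]; pj <- pairs$pos_j[ord]; sc <- pairs$score[ord]
  seen <- integer(0)
  take <- 0L
  for (p in seq_along(pi)) {
    seen <- union(seen, c(pi[p], pj[p]))
    take <- p
    if (length(seen) >= target) break
  }
  if (length(seen) < target)
    warning("pair table exhausted before reaching ", target, " residues")
  sel <- data.frame(pos_i = pi[seq_len(take)], pos_j = pj[seq_len(take)],
                    score = sc[seq_len(take)])
  structure(list(pairs = sel, residues = sort(seen), threshold = threshold,
                 residue_count = residue_count),
            class = "coverage_selection")
}

#' AUROC of pair scores against a labeled pair set
#'
#' Measures how well the orientation-adjusted scores separate a positive
#' pair set (for instance the planted coupled pairs of a simulation) from
#' the remaining background pairs.
#'
#' @param pairs A \code{pair_scores} object.
#' @param positive_pairs Two-column matrix or data frame of positive
#'   position pairs (order within a pair irrelevant).
#' @return AUROC in [0, 1]; \code{NA} if either class is empty.
#' @export
pair_label_auroc <- function(pairs, positive_pairs) {
  stopifnot(inherits(pairs, "pair_scores"))
  pp <- as.matrix(positive_pairs)
  key_pos <- paste(pmin(pp[, 1], pp[, 2]), pmax(pp[, 1], pp[, 2]))
  lab <- paste(pairs$pos_i, pairs$pos_j) %in% key_pos
  sc <- if (attr(pairs, "lower_is_coupled")) -pairs$score else pairs$score
  auroc(sc, lab)
}

#' @export
print.coverage_selection <- function(x, ...) {
  cat(sprintf(
    "Coverage selection at %.1f%%: %d pairs covering %d of %d residues\n",
    100 * x$threshold, nrow(x$pairs), length(x$residues), x$residue_count))
  invisible(x)
}
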