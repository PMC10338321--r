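# Structure parsing, CASP-style contact evaluation, selection cluster
# weighting z-scores, ligand-proximity functional sites, and the auxiliary
# graph/overlap metrics used on ranked pair selections.

#' Construct a structure model
#'
#' A structure model is a flat atom table mapped to query positions. Every
#' residue must have at least one atom and positions must be unique per
#' residue.
#'
#' @param atoms Data frame with columns \code{position} (query position,
#'   integer), \code{resname} (3-letter residue name), \code{atom} (atom
#'   name, e.g. \code{"CA"}), and coordinates \code{x}, \code{y}, \code{z}
#'   in Angstrom.
#' @param resolution Optional resolution metadata in Angstrom (stored, not
#'   enforced).
#' @return An object of class \code{"structure_model"}.
#' @export
structure_model <- function(atoms, resolution = NA_real_) {
  need <- c("position", "resname", "atom", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)),
            nrow(atoms) > 0)
  atoms$position <- as.integer(atoms$position)
  # residue name must be constant within a position
  rn <- tapply(atoms$resname, atoms$position, function(v) length(unique(v)))
  if (any(rn > 1)) stop("conflicting residue names at a single position")
  structure(list(atoms = atoms[need], resolution = resolution),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d residues, %d atoms\n",
              length(unique(x$atoms$position)), nrow(x$atoms)))
  invisible(x)
}

structure_positions <- function(structure) {
  sort(unique(structure$atoms$position))
}

#' Read a PDB structure into a structure model
#'
#' Reads protein atoms of one chain. Positions default to the PDB residue
#' numbers; alternatively an explicit \code{positions} vector (one entry per
#' residue, in chain order) or a \code{query} sequence may be given. With a
#' \code{query}, the chain's one-letter sequence must match a substring of
#' the query exactly; mismatches are an error, never silently re-aligned.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; defaults to the first chain in the file.
#' @param query Optional ungapped query sequence (string) for mapping by
#'   exact match.
#' @param positions Optional explicit query positions, one per residue.
#' @return A \code{structure_model}.
#' @export
read_structure <- function(path, chain = NULL, query = NULL,
                           positions = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records for chain ", chain)
  resno <- unique(at$resno)
  pos <- resno
  if (!is.null(positions)) {
    if (length(positions) != length(resno))
      stop("positions length does not match residue count")
    pos <- as.integer(positions)
  } else if (!is.null(query)) {
    one <- vapply(resno, function(r) {
      bio3d::aa321(at$resid[at$resno == r][1])
    }, character(1))
    chain_seq <- paste(one, collapse = "")
    hit <- regexpr(chain_seq, query, fixed = TRUE)
    if (hit == -1)
      stop("chain sequence does not match the query exactly")
    pos <- seq.int(as.integer(hit), length.out = length(resno))
  }
  atoms <- data.frame(
    position = pos[match(at$resno, resno)],
    resname = at$resid, atom = at$elety,
    x = at$x, y = at$y, z = at$z
  )
  structure_model(atoms)
}

# Representative coordinate per residue for the CASP contact definition:
# C-beta, or C-alpha for glycine; non-glycine residues lacking a C-beta fall
# back to C-alpha; residues with neither are dropped with a message.
contact_coords <- function(structure) {
  at <- structure$atoms
  pos <- structure_positions(structure)
  xyz <- matrix(NA_real_, length(pos), 3, dimnames = list(pos, c("x", "y", "z")))
  drop <- logical(length(pos))
  for (k in seq_along(pos)) {
    rows <- at[at$position == pos[k], ]
    want <- if (toupper(rows$resname[1]) == "GLY") "CA" else "CB"
    hit <- which(rows$atom == want)
    if (!length(hit)) hit <- which(rows$atom == "CA")
    if (!length(hit)) { drop[k] <- TRUE; next }
    xyz[k, ] <- as.numeric(rows[hit[1], c("x", "y", "z")])
  }
  if (any(drop)) {
    message("excluded residues without CB or CA: ",
            paste(pos[drop], collapse = ", "))
  }
  list(positions = pos[!drop], xyz = xyz[!drop, , drop = FALSE])
}

#' Build a CASP-style contact map
#'
#' A residue pair is a contact when its representative atoms (C-beta;
#' C-alpha for glycine) are within \code{distance_cutoff} of each other and
#' the residues are at least \code{min_separation} apart in sequence. Pairs
#' closer in sequence are excluded; the remainder are classed short
#' (separation 6-11), medium (12-23) or long (24+).
#'
#' @param structure A \code{structure_model}.
#' @param distance_cutoff Contact distance in Angstrom (default 8).
#' @param min_separation Minimum sequence separation (default 6).
#' @return An object of class \code{"contact_map"}: data frame with
#'   \code{pos_i < pos_j}, \code{distance}, \code{contact}, \code{class}.
#' @export
build_contact_map <- function(structure, distance_cutoff = 8,
                              min_separation = 6) {
  cc <- contact_coords(structure)
  pos <- cc$positions
  if (length(pos) < 2L) stop("need at least two residues with coordinates")
  dm <- as.matrix(stats::dist(cc$xyz))
  pr <- pair_index(length(pos))
  pi <- pos[pr$a]; pj <- pos[pr$b]
  sep <- abs(pj - pi)
  d <- dm[cbind(pr$a, pr$b)]
  cls <- ifelse(sep < min_separation, "excluded",
         ifelse(sep <= 11, "short",
         ifelse(sep <= 23, "medium", "long")))
  out <- data.frame(pos_i = pi, pos_j = pj, distance = d,
                    contact = d < distance_cutoff & sep >= min_separation,
                    class = cls)
  structure(out, class = c("contact_map", "data.frame"),
            positions = pos, distance_cutoff = distance_cutoff,
            min_separation = min_separation)
}

# Probabilistic AUROC via midranks (equivalent to the Mann-Whitney
# statistic); ties contribute 1/2.
auroc <- function(score, label) {
  np <- sum(label); nn <- sum(!label)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - np * (np + 1) / 2) / (np * nn)
}

# Average precision over distinct score thresholds (descending), the
# standard step-wise AUPRC estimator.
average_precision <- function(score, label) {
  np <- sum(label)
  if (np == 0 || np == length(label)) return(NA_real_)
  ord <- order(-score)
  s <- score[ord]; y <- label[ord]
  ends <- c(which(s[-1] != s[-length(s)]), length(s))
  tp <- cumsum(y)[ends]
  n_at <- ends
  prec <- tp / n_at
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate contact prediction from pair scores
#'
#' Ranks all eligible pairs (not just top pairs) of the chosen separation
#' class by their orientation-adjusted score and measures AUROC, AUPRC, and
#' AUPRC adjusted by subtracting the positive rate (the expected AUPRC of a
#' random predictor).
#'
#' @param pairs A \code{pair_scores} object.
#' @param contacts A \code{contact_map}.
#' @param class_filter One of \code{"all"}, \code{"short"}, \code{"medium"},
#'   \code{"long"}.
#' @return List with \code{auroc}, \code{auprc}, \code{adjusted_auprc},
#'   \code{positive_rate}, \code{n_pairs}, \code{n_contacts}; metrics are
#'   \code{NA} (with a warning) if the class has no positives.
#' @export
evaluate_contact_prediction <- function(pairs, contacts,
                                        class_filter = "all") {
  stopifnot(inherits(pairs, "pair_scores"), inherits(contacts, "contact_map"))
  class_filter <- match.arg(class_filter, c("all", "short", "medium", "long"))
  cm <- contacts[contacts$class != "excluded", , drop = FALSE]
  if (class_filter != "all") cm <- cm[cm$class == class_filter, , drop = FALSE]
  key_c <- paste(cm$pos_i, cm$pos_j)
  key_p <- paste(pairs$pos_i, pairs$pos_j)
  idx <- match(key_c, key_p)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no scored pairs overlap the contact map")
  sc <- pairs$score[idx[ok]]
  if (attr(pairs, "lower_is_coupled")) sc <- -sc
  lab <- cm$contact[ok]
  if (!any(lab)) warning("no contacts in class '", class_filter, "'")
  pr <- mean(lab)
  ap <- average_precision(sc, lab)
  list(auroc = auroc(sc, lab), auprc = ap, adjusted_auprc = ap - pr,
       positive_rate = pr, n_pairs = length(lab), n_contacts = sum(lab))
}

#' Any-atom residue adjacency
#'
#' Two residues are adjacent when the shortest distance between any of
#' their atoms is below \code{cutoff} (4 Angstrom in the selection cluster
#' weighting definition). Distinct from the 8 Angstrom C-beta contact
#' definition: the two graphs are never conflated.
#'
#' @param structure A \code{structure_model}.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Symmetric logical matrix over residue positions (dimnames are
#'   positions, diagonal FALSE).
#' @export
scw_adjacency <- function(structure, cutoff = 4) {
  at <- structure$atoms
  pos <- structure_positions(structure)
  dm <- as.matrix(stats::dist(at[, c("x", "y", "z")]))
  idx <- match(at$position, pos)
  n <- length(pos)
  adj <- matrix(FALSE, n, n, dimnames = list(pos, pos))
  close <- dm < cutoff
  for (k in seq_len(n)) {
    rows <- idx == k
    hit <- idx[apply(close[rows, , drop = FALSE], 2, any)]
    adj[k, unique(hit)] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  adj
}

#' Selection cluster weighting statistic w
#'
#' w = sum over residue pairs i < j of S(i) S(j) A(i, j) b(i, j), where S
#' selects the chosen residues, A is the any-atom 4-Angstrom adjacency, and
#' b is 1 (unbiased) or the sequence separation |i - j| (biased).
#'
#' @param selected Integer vector of selected residue positions.
#' @param adjacency Adjacency matrix from \code{\link{scw_adjacency}} (or a
#'   \code{structure_model}, converted internally).
#' @param bias \code{"unbiased"} or \code{"biased"}.
#' @return The statistic w.
#' @export
scw_w <- function(selected, adjacency, bias = c("unbiased", "biased")) {
  bias <- match.arg(bias)
  if (inherits(adjacency, "structure_model"))
    adjacency <- scw_adjacency(adjacency)
  pos <- as.integer(rownames(adjacency))
  sel <- pos %in% selected
  if (sum(sel) < 2L) return(0)
  b <- scw_bias_matrix(pos, bias)
  sum((adjacency * b)[sel, sel][upper.tri(matrix(0, sum(sel), sum(sel)))])
}

scw_bias_matrix <- function(pos, bias) {
  if (bias == "biased") abs(outer(pos, pos, "-")) else
    matrix(1, length(pos), length(pos))
}

#' Selection cluster weighting z-score
#'
#' Measures whether \code{selected} is more spatially clustered than a
#' uniform random selection of the same size. The analytic null computes
#' E[w] and Var[w] exactly from the pair-overlap decomposition (edge pairs
#' sharing two, one, or zero residues); the Monte-Carlo null draws seeded
#' uniform selections. Significant clustering is conventionally z > 2.
#'
#' @param selected Integer vector of selected residue positions (at least 2,
#'   fewer than all residues for a defined variance).
#' @param structure A \code{structure_model} or a precomputed adjacency
#'   matrix from \code{\link{scw_adjacency}}.
#' @param bias \code{"unbiased"} or \code{"biased"}.
#' @param null \code{"analytic"} or \code{"montecarlo"}.
#' @param draws Monte-Carlo draw count (>= 10000 recommended).
#' @param seed Seed for the Monte-Carlo null.
#' @return An object of class \code{"scw_result"}: list with \code{w},
#'   \code{expected}, \code{sd}, \code{z}, \code{bias}, \code{null},
#'   \code{undefined} (TRUE when the null variance is zero).
#' @export
scw_zscore <- function(selected, structure, bias = c("unbiased", "biased"),
                       null = c("analytic", "montecarlo"),
                       draws = 10000L, seed = 1L) {
  bias <- match.arg(bias)
  null <- match.arg(null)
  adj <- if (inherits(structure, "structure_model"))
    scw_adjacency(structure) else structure
  pos <- as.integer(rownames(adj))
  R <- length(pos)
  k <- sum(pos %in% selected)
  if (k < 2L) stop("need at least 2 selected residues present in the structure")
  w <- scw_w(selected, adj, bias)
  bm <- scw_bias_matrix(pos, bias)
  e <- adj * bm        # edge weights
  if (null == "analytic") {
    ut <- upper.tri(e)
    w1 <- sum(e[ut])
    w2 <- sum(e[ut]^2)
    si2 <- sum(rowSums(e)^2)  # sum over residues of (sum of incident weights)^2
    p2 <- k * (k - 1) / (R * (R - 1))
    p3 <- if (R > 2) p2 * (k - 2) / (R - 2) else 0
    p4 <- if (R > 3) p3 * (k - 3) / (R - 3) else 0
    ew <- p2 * w1
    # ordered edge-pair sums: identical (w2), sharing one residue
    # (si2 - 2 w2), disjoint (w1^2 + w2 - si2)
    ew2 <- p2 * w2 + p3 * (si2 - 2 * w2) + p4 * (w1^2 + w2 - si2)
    varw <- ew2 - ew^2
    sdw <- sqrt(max(varw, 0))
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    ws <- vapply(seq_len(draws), function(i) {
      scw_w(sample(pos, k), adj, bias)
    }, numeric(1))
    ew <- mean(ws)
    sdw <- stats::sd(ws)
  }
  undef <- !is.finite(sdw) || sdw <= 0
  structure(list(w = w, expected = ew, sd = sdw,
                 z = if (undef) NA_real_ else (w - ew) / sdw,
                 bias = bias, null = null,
                 draws = if (null == "montecarlo") draws else NA_integer_,
                 seed = if (null == "montecarlo") seed else NA_integer_,
                 undefined = undef),
            class = "scw_result")
}

#' @export
print.scw_result <- function(x, ...) {
  cat(sprintf("SCW (%s, %s null): w = %.4g, E[w] = %.4g, sd = %.4g, z = %.3f\n",
              x$bias, x$null, x$w, x$expected, x$sd,
              if (x$undefined) NA else x$z))
  invisible(x)
}

#' Ligand-proximity functional residues
#'
#' Residues with any atom strictly closer than \code{cutoff} (4 Angstrom)
#' to any ligand atom are deemed functionally important.
#'
#' @param structure A \code{structure_model}.
#' @param ligand_atoms Matrix or data frame of ligand atom coordinates with
#'   columns x, y, z; must be non-empty.
#' @param cutoff Distance cutoff in Angstrom (strict inequality).
#' @return Sorted integer vector of residue positions.
#' @export
functional_residues <- function(structure, ligand_atoms, cutoff = 4) {
  lig <- as.matrix(as.data.frame(ligand_atoms)[, 1:3])
  if (!nrow(lig)) stop("ligand atom set is empty")
  at <- structure$atoms
  axyz <- as.matrix(at[, c("x", "y", "z")])
  hit <- logical(nrow(at))
  for (r in seq_len(nrow(lig))) {
    d2 <- rowSums(sweep(axyz, 2, lig[r, ])^2)
    hit <- hit | d2 < cutoff^2
  }
  sort(unique(at$position[hit]))
}

#' One-sided hypergeometric overlap test
#'
#' Upper-tail probability of observing at least the actual overlap between a
#' selection and a gold-standard residue set drawn from a universe of the
#' given size.
#'
#' @param selected,gold Residue sets (subsets of the universe).
#' @param universe Universe size (positive integer).
#' @return p-value in (0, 1].
#' @export
hypergeometric_overlap <- function(selected, gold, universe) {
  stopifnot(universe >= 1)
  selected <- unique(selected); gold <- unique(gold)
  if (length(selected) > universe || length(gold) > universe)
    stop("selection or gold set larger than the universe")
  obs <- length(intersect(selected, gold))
  stats::phyper(obs - 1, length(gold), universe - length(gold),
                length(selected), lower.tail = FALSE)
}

#' Mean sequence separation of selected pairs
#'
#' Mean of |i - j| over the pairs of a coverage selection, optionally
#' normalized by protein length.
#'
#' @param selection A \code{coverage_selection} (or data frame with
#'   \code{pos_i}, \code{pos_j}).
#' @param protein_length Length used for normalization.
#' @param normalized Divide the mean by \code{protein_length}?
#' @return Mean separation (possibly normalized).
#' @export
mean_sequence_separation <- function(selection, protein_length = NULL,
                                     normalized = FALSE) {
  pairs <- if (inherits(selection, "coverage_selection")) selection$pairs
           else selection
  if (!nrow(pairs)) stop("empty selection")
  m <- mean(abs(pairs$pos_j - pairs$pos_i))
  if (normalized) {
    stopifnot(!is.null(protein_length), protein_length > 0)
    m <- m / protein_length
  }
  m
}

#' Connected components of selected pairs
#'
#' Treats the selected pairs as edges of a graph over residues and returns
#' the connected components: the discrete residue clusters a coverage
#' cutoff defines.
#'
#' @param selection A \code{coverage_selection} (or pair data frame).
#' @return List of sorted integer vectors, ordered by smallest member.
#' @export
selected_pair_components <- function(selection) {
  pairs <- if (inherits(selection, "coverage_selection")) selection$pairs
           else selection
  if (!nrow(pairs)) stop("empty selection")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs$pos_i),
               to = as.character(pairs$pos_j)),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  comps <- unname(lapply(split(as.integer(names(comp)), comp), sort))
  comps[order(vapply(comps, min, integer(1)))]
}
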