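# Seeded simulators: tree-structured alignments with planted coupled
# position pairs, and toy structures with planted spatial clusters. These
# define the study conditions every evaluation module is exercised under.

#' Specification for a coupled-alignment simulation
#'
#' Defaults describe the reference condition used throughout the package's
#' self-evaluation: 64 leaves, 50 columns, per-branch substitution
#' probability 0.05, five disjoint planted pairs with coupling probability
#' 0.9.
#'
#' @param n_leaves Number of leaf sequences (>= 2).
#' @param length Alignment length.
#' @param sub_prob Per-branch, per-position substitution probability.
#' @param coupled_pairs Two-column matrix of planted position pairs
#'   (disjoint).
#' @param coupling Probability that a substitution at one member of a
#'   planted pair forces a simultaneous substitution at its partner.
#' @param seed Mandatory random seed.
#' @return A \code{"simulation_spec"} list.
#' @export
simulation_spec <- function(n_leaves = 64, length = 50, sub_prob = 0.05,
                            coupled_pairs = default_coupled_pairs(length),
                            coupling = 0.9, seed) {
  if (missing(seed)) stop("seed is mandatory")
  coupled_pairs <- as.matrix(coupled_pairs)
  stopifnot(n_leaves >= 2, length >= 2,
            sub_prob >= 0, sub_prob <= 1,
            coupling >= 0, coupling <= 1,
            ncol(coupled_pairs) == 2 || nrow(coupled_pairs) == 0)
  if (nrow(coupled_pairs)) {
    if (anyDuplicated(as.vector(coupled_pairs)))
      stop("planted pairs must be disjoint")
    if (any(coupled_pairs < 1) || any(coupled_pairs > length))
      stop("planted pair positions out of range")
  }
  if (length < 2 * nrow(coupled_pairs))
    stop("alignment length must be at least twice the number of planted pairs")
  structure(list(n_leaves = as.integer(n_leaves), length = as.integer(length),
                 sub_prob = sub_prob, coupled_pairs = coupled_pairs,
                 coupling = coupling, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Five planted pairs spread across the alignment (positions 1..length/2
# paired with offsets), used by the default spec.
default_coupled_pairs <- function(length) {
  if (length < 50) stop("default planted pairs need length >= 50")
  cbind(c(1L, 6L, 11L, 16L, 21L), c(26L, 31L, 36L, 41L, 46L))
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a tree-structured alignment with planted coupled pairs
#'
#' Draws a random coalescent bifurcating tree, a root sequence uniform over
#' the 20 amino acids, and evolves it to the leaves: along each branch every
#' position substitutes independently (to a uniformly chosen different
#' residue) with probability \code{sub_prob}; at a planted pair, a
#' substitution at one member additionally triggers a substitution at its
#' partner with probability \code{coupling}, creating concerted variation.
#' No indels are simulated, so the alignment is gap-free. Byte-identical
#' output for identical spec and seed.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return List with \code{alignment} (an \code{alignment}; query is the
#'   first leaf) and \code{truth} (coupled pair matrix, the generating
#'   \code{ape::phylo} tree, and the root sequence).
#' @export
simulate_coupled_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_leaves
    L <- spec$length
    tree <- ape::rcoal(n, tip.label = sprintf("s%03d", seq_len(n)))
    root_seq <- sample.int(20L, L, replace = TRUE)

    in_pair <- integer(L)                 # partner position, 0 if none
    if (nrow(spec$coupled_pairs)) {
      in_pair[spec$coupled_pairs[, 1]] <- spec$coupled_pairs[, 2]
      in_pair[spec$coupled_pairs[, 2]] <- spec$coupled_pairs[, 1]
    }

    mutate <- function(seq_codes) {
      s <- stats::runif(L) < spec$sub_prob
      if (any(s)) {
        coupled <- which(in_pair > 0L)
        for (i in coupled) {
          j <- in_pair[i]
          if (i < j) {  # handle each pair once
            if (s[i] && !s[j] && stats::runif(1) < spec$coupling) s[j] <- TRUE
            else if (s[j] && !s[i] && stats::runif(1) < spec$coupling)
              s[i] <- TRUE
          }
        }
      }
      for (i in which(s)) {
        seq_codes[i] <- sample(setdiff(seq_len(20L), seq_codes[i]), 1L)
      }
      seq_codes
    }

    # preorder traversal from the root
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    edges <- edges[rev(seq_len(nrow(edges))), , drop = FALSE]
    node_seq <- vector("list", n + tree$Nnode)
    root <- n + 1L
    node_seq[[root]] <- root_seq
    for (e in seq_len(nrow(edges))) {
      node_seq[[edges[e, 2]]] <- mutate(node_seq[[edges[e, 1]]])
    }
    ab <- aa_alphabet()
    rows <- vapply(seq_len(n), function(k) {
      paste(ab[node_seq[[k]]], collapse = "")
    }, character(1))
    aln <- new_alignment(tree$tip.label, rows, tree$tip.label[1])
    list(alignment = aln,
         truth = list(coupled_pairs = spec$coupled_pairs, tree = tree,
                      root_sequence = paste(ab[root_seq], collapse = "")))
  })
}

#' Build a toy structure with planted spatial clusters
#'
#' Residues are laid out as an extended chain (consecutive C-alpha 3.8
#' Angstrom apart, C-beta at a fixed 1.53 Angstrom offset), so only sequence
#' neighbors fall within the 4 Angstrom any-atom adjacency. Each planted
#' cluster's residues are then repositioned into a tight ball (jittered
#' within the stated radius, capped so every intra-cluster any-atom distance
#' stays below 4 Angstrom) far from the chain and from other clusters.
#'
#' @param residue_count Number of residues.
#' @param clusters List of \code{list(residues = <integer vector>, radius =
#'   <Angstrom>)}; residue sets must be disjoint subsets of
#'   \code{1:residue_count}.
#' @param seed Mandatory random seed.
#' @return A \code{structure_model} (all residues ALA, atoms CA and CB).
#' @export
toy_structure <- function(residue_count, clusters = list(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(residue_count >= 2)
  all_members <- unlist(lapply(clusters, `[[`, "residues"))
  if (length(all_members)) {
    if (anyDuplicated(all_members)) stop("cluster residue sets must be disjoint")
    if (any(all_members < 1) || any(all_members > residue_count))
      stop("cluster residues out of range")
  }
  with_seed(seed, {
    ca <- cbind(3.8 * (seq_len(residue_count) - 1), 0, 0)
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      r_eff <- min(cl$radius, 1.0)
      if (r_eff <= 0) stop("cluster radius must be positive")
      center <- c(3.8 * (mean(cl$residues) - 1), 60 * k, 0)
      for (res in cl$residues) {
        repeat {
          p <- stats::runif(3, -r_eff, r_eff)
          if (sum(p^2) <= r_eff^2) break
        }
        ca[res, ] <- center + p
      }
    }
    cb <- ca + matrix(rep(c(0, 0, 1.53), each = residue_count), ncol = 3)
    atoms <- data.frame(
      position = rep(seq_len(residue_count), 2L),
      resname = "ALA",
      atom = rep(c("CA", "CB"), each = residue_count),
      x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]),
      z = c(ca[, 3], cb[, 3])
    )
    st <- structure_model(atoms)
    # verify the planted geometry really satisfies the 4 A guarantee
    if (length(clusters)) {
      adj <- scw_adjacency(st)
      for (cl in clusters) {
        sub <- adj[as.character(cl$residues), as.character(cl$residues)]
        if (!all(sub[upper.tri(sub)]))
          stop("infeasible cluster geometry: intra-cluster distance >= 4 A")
      }
    }
    st
  })
}

#' Write a structure model as a PDB file
#'
#' @param structure A \code{structure_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$position, resid = at$resname,
                   elety = at$atom, chain = "A")
  invisible(path)
}

#' Write the planted truth of a simulation as TSV
#'
#' @param truth The \code{truth} element from
#'   \code{\link{simulate_coupled_alignment}}.
#' @param path Output path for the coupled-pair table.
#' @return \code{path}, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- as.data.frame(truth$coupled_pairs)
  names(df) <- c("pos_i", "pos_j")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
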