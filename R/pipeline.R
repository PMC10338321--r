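# End-to-end orchestration behind the command-line entry point
# (inst/cli/covet.R): read -> tree -> score -> rank -> requested
# evaluations, with deterministic outputs under a fixed config and seed.

#' Run configuration for the pipeline
#'
#' @param alignment Path to an aligned FASTA/Stockholm file.
#' @param query_id Query sequence identifier.
#' @param method \code{"covet"} or \code{"etmip"}.
#' @param structure Optional PDB path for structural evaluations.
#' @param chain Optional chain id for the structure.
#' @param ligand Optional TSV of ligand atom coordinates (columns x, y, z).
#' @param gold Optional TSV with a \code{position} column of known
#'   functional residues.
#' @param epistasis_doubles,epistasis_singles Optional fitness TSV paths
#'   (see \code{\link{read_fitness_tables}}).
#' @param coverage_thresholds Coverage cutoffs in (0, 1].
#' @param max_identity Redundancy filter threshold (NULL to skip filtering).
#' @param seed Seed for any stochastic evaluation (Monte-Carlo SCW).
#' @param out_dir Output directory (created if absent).
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(alignment, query_id, method = c("covet", "etmip"),
                       structure = NULL, chain = NULL, ligand = NULL,
                       gold = NULL, epistasis_doubles = NULL,
                       epistasis_singles = NULL,
                       coverage_thresholds = 0.3, max_identity = 0.98,
                       seed = 1L, out_dir = "covet_out") {
  method <- match.arg(method)
  stopifnot(all(coverage_thresholds > 0), all(coverage_thresholds <= 1))
  for (p in c(alignment, structure, ligand, gold,
              epistasis_doubles, epistasis_singles)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(alignment = alignment, query_id = query_id, method = method,
                 structure = structure, chain = chain, ligand = ligand,
                 gold = gold, epistasis_doubles = epistasis_doubles,
                 epistasis_singles = epistasis_singles,
                 coverage_thresholds = coverage_thresholds,
                 max_identity = max_identity, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Execute the covariation pipeline
#'
#' Reads and (optionally) de-redundifies the alignment, builds the ET
#' distance matrix and UPGMA tree, scores all query-mapped pairs with the
#' configured method, ranks residues, runs every evaluation whose inputs
#' are configured, and writes a score TSV, ranking TSV, and JSON report to
#' the output directory. Identical config and seed give identical outputs.
#'
#' @param config A \code{\link{run_config}}.
#' @return The report list, invisibly; files under \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  aln <- read_alignment(config$alignment, config$query_id)
  if (!is.null(config$max_identity))
    aln <- filter_redundant(aln, config$max_identity)
  d <- distance_matrix(aln)
  tree <- build_upgma(d)
  pairs <- if (config$method == "covet") covet_scores(aln, tree)
           else etmip_scores(aln, tree)
  ranking <- residue_scores(pairs)

  write_pair_scores(pairs, file.path(config$out_dir, "pair_scores.tsv"), aln)
  utils::write.table(ranking, file.path(config$out_dir, "residue_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tree_newick(tree, file.path(config$out_dir, "tree.nwk"))

  report <- list(
    method = attr(pairs, "method"),
    orientation = if (attr(pairs, "lower_is_coupled")) "lower_is_coupled"
                  else "higher_is_coupled",
    n_sequences = length(aln$sequence_ids),
    n_positions = nrow(ranking),
    seed = config$seed,
    alignment_md5 = alignment_checksum(aln)
  )

  if (!is.null(config$structure)) {
    st <- read_structure(config$structure, chain = config$chain)
    cm <- build_contact_map(st)
    report$contacts <- lapply(
      stats::setNames(nm = c("all", "short", "medium", "long")),
      function(cl) tryCatch(evaluate_contact_prediction(pairs, cm, cl),
                            error = function(e) list(error = conditionMessage(e)))
    )
    adj <- scw_adjacency(st)
    k_res <- length(structure_positions(st))
    report$scw <- lapply(config$coverage_thresholds, function(th) {
      sel <- coverage_selection(pairs, th, k_res)
      list(threshold = th,
           unbiased = unclass(scw_zscore(sel$residues, adj, "unbiased",
                                         seed = config$seed)),
           biased = unclass(scw_zscore(sel$residues, adj, "biased",
                                       seed = config$seed)),
           mean_separation = mean_sequence_separation(sel),
           mean_separation_normalized =
             mean_sequence_separation(sel, k_res, normalized = TRUE),
           n_components = length(selected_pair_components(sel)))
    })
    if (!is.null(config$ligand)) {
      lig <- utils::read.table(config$ligand, header = TRUE, sep = "\t")
      fres <- functional_residues(st, lig)
      sc <- if (attr(pairs, "lower_is_coupled")) -ranking$score
            else ranking$score
      report$functional <- list(
        residues = fres,
        auroc = auroc(sc, ranking$position %in% fres)
      )
    }
    if (!is.null(config$gold)) {
      gold <- utils::read.table(config$gold, header = TRUE, sep = "\t")$position
      report$gold_overlap <- lapply(config$coverage_thresholds, function(th) {
        sel <- coverage_selection(pairs, th, k_res)
        list(threshold = th,
             overlap = length(intersect(sel$residues, gold)),
             p_value = hypergeometric_overlap(sel$residues, gold, k_res))
      })
    }
  }

  if (!is.null(config$epistasis_doubles)) {
    recs <- read_fitness_tables(config$epistasis_doubles,
                                config$epistasis_singles)
    report$epistasis <- lapply(
      stats::setNames(nm = c("product", "additive", "log", "min")),
      function(mod) correlate_with_covariation(pairs,
                                               pair_epistasis(recs, mod))
    )
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
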