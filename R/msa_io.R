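# Reading, validating, filtering and indexing multiple sequence alignments.
# Alignments are stored as a simple S3 object: a character matrix of
# single-residue strings would be wasteful, so rows are kept as strings and
# an integer-encoded matrix is built lazily by consumers.

new_alignment <- function(ids, rows, query_id) {
  structure(
    list(sequence_ids = ids, rows = rows, query_id = query_id,
         column_count = nchar(rows[[1]])),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns (query: %s)\n",
              length(x$sequence_ids), x$column_count, x$query_id))
  invisible(x)
}

validate_alignment <- function(ids, rows, query_id) {
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!query_id %in% ids)
    stop("query sequence '", query_id, "' not found in alignment")
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1]][1]
    stop("ragged alignment: record '", bad, "' has length ",
         nchar(rows[ids == bad]), " but '", ids[1], "' has length ", lens[1])
  }
  if (lens[1] < 1L) stop("alignment has zero columns")
  allowed <- aa_alphabet()
  for (r in seq_along(rows)) {
    ch <- strsplit(rows[[r]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad))
      stop("illegal character '", ch[bad[1]], "' in record '", ids[r],
           "' at column ", bad[1],
           " (alphabet is the 20 standard amino acids and the gap)")
  }
  invisible(TRUE)
}

normalize_seq <- function(s) {
  gsub(".", "-", toupper(s), fixed = TRUE)
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA (or Pfam-dialect Stockholm) file, uppercases the
#' sequences, normalizes \code{"."} gaps to \code{"-"}, and validates that
#' every record has the same length and uses only the 20 standard amino
#' acids plus the gap character.
#'
#' @param path Path to an aligned FASTA or Stockholm file. Stockholm input
#'   is detected by the \code{"# STOCKHOLM"} header and converted internally.
#' @param query_id Identifier of the reference (query) sequence; must be
#'   present in the file.
#' @return An \code{alignment} object.
#' @export
read_alignment <- function(path, query_id) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (length(first) && grepl("^# STOCKHOLM", first)) {
    recs <- read_stockholm(path)
    ids <- names(recs)
    rows <- unname(recs)
  } else {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    rows <- as.character(set)
  }
  rows <- unname(normalize_seq(rows))
  validate_alignment(ids, rows, query_id)
  new_alignment(ids, rows, query_id)
}

# Minimal Pfam-dialect Stockholm parser: "name  sequence" lines, "#=" and
# "#" annotation lines skipped, terminated by "//"; wrapped records are
# concatenated.
read_stockholm <- function(path) {
  lines <- readLines(path)
  seqs <- list()
  for (ln in lines) {
    if (grepl("^(#|//)", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1]
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], parts[2])
  }
  if (!length(seqs)) stop("no sequence records in Stockholm file")
  unlist(seqs)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An \code{alignment} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  set <- Biostrings::BStringSet(stats::setNames(aln$rows, aln$sequence_ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Integer-coded matrix view (N x L, entries 1..21), rows in alignment order.
alignment_matrix <- function(aln) {
  m <- t(vapply(strsplit(aln$rows, "", fixed = TRUE), aa_encode,
                integer(aln$column_count)))
  rownames(m) <- aln$sequence_ids
  m
}

query_row <- function(aln) {
  aln$rows[match(aln$query_id, aln$sequence_ids)]
}

#' Map alignment columns to query positions
#'
#' Every alignment column where the query row carries a residue (not a gap)
#' is assigned a consecutive 1-based query position.
#'
#' @param aln An \code{alignment} object.
#' @return A data frame with columns \code{column} (alignment column index)
#'   and \code{position} (query position), both strictly increasing.
#' @export
map_query_columns <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  qc <- strsplit(query_row(aln), "", fixed = TRUE)[[1]]
  cols <- which(qc != GAP_CHAR)
  if (!length(cols)) stop("query row is entirely gaps")
  data.frame(column = cols, position = seq_along(cols))
}

# Pairwise identity between two encoded rows: matching non-gap columns over
# columns where at least one row is non-gap.
pair_identity <- function(a, b) {
  gap <- 21L
  both <- a != gap & b != gap
  any_ng <- a != gap | b != gap
  if (!any(any_ng)) return(0)
  sum(both & a == b) / sum(any_ng)
}

#' Remove redundant sequences from an alignment
#'
#' Clusters sequences whose pairwise identity exceeds \code{max_identity}
#' (single linkage) and keeps one representative per cluster: the member
#' most similar to the query (earliest alignment row on ties). The query is
#' always retained. Identity is the fraction of columns where both rows
#' carry the same residue, over columns where at least one is non-gap.
#'
#' @param aln An \code{alignment} object.
#' @param max_identity Maximum allowed pairwise identity, in (0, 1]. The
#'   redundancy convention in family-analysis pipelines is 0.98.
#' @return A filtered \code{alignment}; row order of retained sequences is
#'   preserved.
#' @export
filter_redundant <- function(aln, max_identity = 0.98) {
  stopifnot(inherits(aln, "alignment"),
            max_identity > 0, max_identity <= 1)
  m <- alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2L) return(aln)
  idm <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      idm[i, j] <- idm[j, i] <- pair_identity(m[i, ], m[j, ])
    }
  }
  adj <- idm > max_identity
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  qi <- match(aln$query_id, aln$sequence_ids)
  keep <- logical(n)
  for (k in unique(comp)) {
    members <- which(comp == k)
    if (qi %in% members) {
      keep[qi] <- TRUE
    } else {
      # representative: closest to query, ties to the earliest row
      best <- members[order(-idm[members, qi], members)][1]
      keep[best] <- TRUE
    }
  }
  keep[qi] <- TRUE
  new_alignment(aln$sequence_ids[keep], aln$rows[keep], aln$query_id)
}
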