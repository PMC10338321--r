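# Shared fixture builders. Everything is generated in code; no binary data.

# Build an alignment through the public reader (exercises I/O on the way).
aln_from <- function(rows, query_id = names(rows)[1]) {
  stopifnot(!is.null(names(rows)))
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(paste0(">", names(rows), "\n", rows), tmp)
  read_alignment(tmp, query_id)
}

# A hand-rolled pair_scores object for ranking/evaluation tests.
make_pairs <- function(pos_i, pos_j, score, lower = TRUE,
                       method = "test", n_seq = 4L) {
  structure(data.frame(pos_i = pos_i, pos_j = pos_j, score = score),
            method = method, lower_is_coupled = lower,
            n_sequences = n_seq, class = c("pair_scores", "data.frame"))
}

# A small structure model built from explicit coordinates: one CA (and
# optionally CB) per residue.
make_structure <- function(positions, ca, cb = NULL, resname = "ALA") {
  df <- data.frame(position = positions, resname = resname, atom = "CA",
                   x = ca[, 1], y = ca[, 2], z = ca[, 3])
  if (!is.null(cb)) {
    df <- rbind(df, data.frame(position = positions, resname = resname,
                               atom = "CB", x = cb[, 1], y = cb[, 2],
                               z = cb[, 3]))
  }
  structure_model(df)
}

# Adjacency matrix from an explicit edge list over residues 1..n.
make_adjacency <- function(n, edges) {
  adj <- matrix(FALSE, n, n, dimnames = list(seq_len(n), seq_len(n)))
  for (e in edges) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
  }
  adj
}
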