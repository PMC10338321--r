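# Independent brute-force oracle: a literal, loop-by-loop re-derivation of
# the ET distance, UPGMA agglomeration, level cutting, and both pair scores.
# Deliberately naive (string keys, nested loops, no shared code with the
# package internals beyond the BLOSUM62 data source).

oracle_blosum <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

oracle_f <- function(x, y) {
  if (x == "-" || y == "-") return(0L)             # gap log-odds fixed at 0
  if (oracle_blosum()[x, y] >= 2) 1L else 0L
}

oracle_et_distance <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  num <- 0L
  for (i in seq_along(a)) num <- num + oracle_f(a[i], b[i])
  den <- min(sum(a != "-"), sum(b != "-"))
  1 - num / den
}

# Naive UPGMA over label sets. Returns the merge history: a list of
# list(left, right, height) where left/right are label vectors.
oracle_upgma <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  cd <- d
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        key <- c(min(min(clusters[[i]]), min(clusters[[j]])),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || cd[i, j] < best$d - 1e-15 ||
            (abs(cd[i, j] - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = cd[i, j], key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merges[[length(merges) + 1L]] <-
      list(left = clusters[[i]], right = clusters[[j]], height = best$d / 2)
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    newrow <- (ni * cd[i, ] + nj * cd[j, ]) / (ni + nj)
    merged <- c(clusters[[i]], clusters[[j]])
    keep <- setdiff(seq_along(clusters), c(i, j))
    nd <- rbind(cbind(cd[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    clusters <- c(clusters[keep], list(merged))
    cd <- nd
  }
  merges
}

# Literal level cutting: start from one group of everything; at each step
# split the current group with the greatest merge height (ties: the group
# holding the smallest label). Returns groups per level 1..N, each a list
# of label vectors.
oracle_levels <- function(merges, labels) {
  find_merge <- function(members) {
    for (m in merges) {
      if (setequal(c(m$left, m$right), members)) return(m)
    }
    NULL
  }
  levels <- list(list(labels))
  current <- list(labels)
  while (length(current) < length(labels)) {
    split_h <- -Inf; split_k <- NULL
    for (k in seq_along(current)) {
      if (length(current[[k]]) < 2L) next
      m <- find_merge(current[[k]])
      if (is.null(split_k) || m$height > split_h + 1e-15 ||
          (abs(m$height - split_h) <= 1e-15 &&
           min(current[[k]]) < min(current[[split_k]]))) {
        split_h <- m$height; split_k <- k
      }
    }
    m <- find_merge(current[[split_k]])
    current <- c(current[-split_k], list(m$left), list(m$right))
    # order groups deterministically by smallest label
    current <- current[order(vapply(current, min, character(1)))]
    levels[[length(levels) + 1L]] <- current
  }
  levels
}

# Shared scaffolding: distance matrix, tree, levels, and query columns.
oracle_context <- function(rows, query_id) {
  n <- length(rows)
  ids <- names(rows)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- oracle_et_distance(rows[[i]], rows[[j]])
    }
  }
  merges <- oracle_upgma(d)
  levels <- oracle_levels(merges, ids)
  chars <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(chars) <- ids
  qchars <- strsplit(rows[[query_id]], "")[[1]]
  qcols <- which(qchars != "-")
  list(ids = ids, chars = chars, levels = levels, qcols = qcols, n = n)
}

# Literal CovET: 1 + sum over levels 1..N-1 of (1/n) * sum of group
# perplexities, each from a full nested-loop tally of nonconcerted
# variation categories.
oracle_covet <- function(rows, query_id) {
  ctx <- oracle_context(rows, query_id)
  k <- length(ctx$qcols)
  score <- matrix(0, k, k)
  for (lev in seq_len(ctx$n - 1L)) {
    for (grp in ctx$levels[[lev]]) {
      members <- sort(match(grp, ctx$ids))   # alignment row order
      m <- length(members)
      for (pi in seq_len(k - 1L)) {
        for (pj in seq.int(pi + 1L, k)) {
          ci <- ctx$chars[members, ctx$qcols[pi]]
          cj <- ctx$chars[members, ctx$qcols[pj]]
          tally <- list()
          if (m >= 2L) {
            for (a in seq_len(m - 1L)) {
              for (b in seq.int(a + 1L, m)) {
                nc <- (ci[a] == ci[b]) != (cj[a] == cj[b])
                if (nc) {
                  key <- paste(ci[a], cj[a], ci[b], cj[b])
                  tally[[key]] <- (if (is.null(tally[[key]])) 0 else
                                     tally[[key]]) + 1
                }
              }
            }
          }
          h <- 0
          for (cnt in tally) {
            f <- cnt / (m * (m - 1) / 2)
            h <- h - f * log(f)
          }
          score[pi, pj] <- score[pi, pj] + exp(h) / lev
        }
      }
    }
  }
  out <- NULL
  for (pi in seq_len(k - 1L)) {
    for (pj in seq.int(pi + 1L, k)) {
      out <- rbind(out, data.frame(pos_i = pi, pos_j = pj,
                                   score = 1 + score[pi, pj]))
    }
  }
  out
}

oracle_entropy <- function(x) {
  h <- 0
  for (cnt in table(x)) {
    f <- cnt / length(x)
    h <- h - f * log(f)
  }
  h
}

# Literal ET-MIp: per level and group, the full MI matrix over query
# columns, average product correction, then the (1/n)-weighted sum.
oracle_etmip <- function(rows, query_id) {
  ctx <- oracle_context(rows, query_id)
  k <- length(ctx$qcols)
  score <- matrix(0, k, k)
  for (lev in seq_len(ctx$n - 1L)) {
    for (grp in ctx$levels[[lev]]) {
      members <- sort(match(grp, ctx$ids))
      m <- length(members)
      mi <- matrix(0, k, k)
      for (pi in seq_len(k - 1L)) {
        for (pj in seq.int(pi + 1L, k)) {
          ci <- ctx$chars[members, ctx$qcols[pi]]
          cj <- ctx$chars[members, ctx$qcols[pj]]
          v <- oracle_entropy(ci) + oracle_entropy(cj) -
            oracle_entropy(paste(ci, cj))
          mi[pi, pj] <- mi[pj, pi] <- v
        }
      }
      grand <- mean(mi[upper.tri(mi)])
      mip <- matrix(0, k, k)
      for (pi in seq_len(k)) {
        for (pj in seq_len(k)) {
          if (pi == pj) next
          if (grand == 0) { mip[pi, pj] <- mi[pi, pj]; next }
          mbar_i <- mean(mi[pi, -pi])
          mbar_j <- mean(mi[pj, -pj])
          mip[pi, pj] <- mi[pi, pj] - mbar_i * mbar_j / grand
        }
      }
      score <- score + mip / lev
    }
  }
  out <- NULL
  for (pi in seq_len(k - 1L)) {
    for (pj in seq.int(pi + 1L, k)) {
      out <- rbind(out, data.frame(pos_i = pi, pos_j = pj,
                                   score = score[pi, pj]))
    }
  }
  out
}
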