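test_that("transition classification follows the exactly-one-change rule", {
  expect_equal(classify_transition("A", "D", "A", "D"), "conservation")
  expect_equal(classify_transition("A", "D", "C", "E"), "concerted")
  expect_equal(classify_transition("A", "W", "A", "E"), "nonconcerted")
  expect_equal(classify_transition("A", "-", "A", "E"), "nonconcerted")
  expect_equal(classify_transition("-", "-", "-", "-"), "conservation")
  expect_error(classify_transition("A", "B", "A", "D"), "outside")
})

test_that("exhaustive enumeration over the 21-letter alphabet reproduces the class counts", {
  ab <- aa_alphabet()
  tuples <- expand.grid(ai = ab, aj = ab, bi = ab, bj = ab,
                        stringsAsFactors = FALSE)
  cls <- classify_transition(tuples$ai, tuples$aj, tuples$bi, tuples$bj)
  counts <- table(cls)
  expected <- enumerate_transition_classes(21)
  expect_equal(nrow(tuples), expected$total)
  expect_equal(nrow(tuples), 194481)
  expect_equal(unname(counts[["conservation"]]), expected$conservation)
  expect_equal(unname(counts[["concerted"]]), expected$concerted)
  expect_equal(unname(counts[["concerted"]]), 176400)
  expect_equal(unname(counts[["nonconcerted"]]), expected$nonconcerted)
  expect_equal(unname(counts[["nonconcerted"]]), 17640)
  expect_equal(sum(counts), expected$total)
})

test_that("class counts for a 2-letter alphabet match exhaustive enumeration", {
  ab <- c("A", "C")
  tuples <- expand.grid(ai = ab, aj = ab, bi = ab, bj = ab,
                        stringsAsFactors = FALSE)
  cls <- classify_transition(tuples$ai, tuples$aj, tuples$bi, tuples$bj)
  expected <- enumerate_transition_classes(2)
  expect_equal(expected$total, 16)
  expect_equal(unname(table(cls)[["conservation"]]), 4)
  expect_equal(unname(table(cls)[["concerted"]]), 4)
  expect_equal(unname(table(cls)[["nonconcerted"]]), 8)
})

test_that("group perplexity penalty matches hand-evaluated cases", {
  # no variation: no nonconcerted events, penalty e^0 = 1
  expect_equal(covet_group_penalty(c("A", "A", "A"), c("W", "W", "W")), 1)
  # one NC category seen in 2 of 3 comparisons: f = 2/3
  expect_equal(covet_group_penalty(c("A", "A", "A"), c("W", "W", "C")),
               exp(-(2 / 3) * log(2 / 3)))
  # single comparison, f = 1, zero entropy
  expect_equal(covet_group_penalty(c("A", "C"), c("W", "W")), 1)
  # singleton group
  expect_equal(covet_group_penalty("A", "W"), 1)
  expect_error(covet_group_penalty(character(0), character(0)), "empty group")
})

test_that("penalty is at least 1 and counts ordered-tuple categories", {
  # two distinct NC categories, one each over 3 comparisons
  # rows (A,W),(C,W),(C,D): (1,2) NC at i; (1,3) concerted; (2,3) NC at j
  p <- covet_group_penalty(c("A", "C", "C"), c("W", "W", "D"))
  expect_equal(p, exp(-2 * (1 / 3) * log(1 / 3)))
  expect_gte(p, 1)
})

test_that("the events normalization renormalizes over nonconcerted events only", {
  # one category: f = 1 regardless of how many comparisons saw it
  expect_equal(covet_group_penalty(c("A", "A", "A"), c("W", "W", "C"),
                                   normalize = "events"), 1)
  # two categories, one event each: f = 1/2, perplexity 2
  expect_equal(covet_group_penalty(c("A", "C", "C"), c("W", "W", "D"),
                                   normalize = "events"), 2)
  set.seed(12)
  ab <- aa_alphabet()[1:20]
  rows <- vapply(1:6, function(i) paste(sample(ab, 5, replace = TRUE),
                                        collapse = ""), character(1))
  names(rows) <- paste0("s", 1:6)
  aln <- aln_from(rows, "s1")
  tr <- build_upgma(distance_matrix(aln))
  ev <- covet_scores(aln, tr, normalize = "events")
  expect_true(all(ev$score >= 6 - 1e-12))
})

test_that("invariant column pairs score exactly N and nothing scores below N", {
  set.seed(21)
  ab <- aa_alphabet()[1:20]
  n <- 8
  # columns 1 and 2 invariant, the rest random
  rows <- vapply(seq_len(n), function(i) {
    paste0("AC", paste(sample(ab, 6, replace = TRUE), collapse = ""))
  }, character(1))
  names(rows) <- sprintf("s%02d", seq_len(n))
  aln <- aln_from(rows, "s01")
  tr <- build_upgma(distance_matrix(aln))
  cv <- covet_scores(aln, tr)
  expect_equal(cv$score[cv$pos_i == 1 & cv$pos_j == 2], n)
  expect_true(all(cv$score >= n - 1e-12))
  expect_true(attr(cv, "lower_is_coupled"))
})

test_that("CovET and ET-MIp equal the literal brute-force re-derivation", {
  set.seed(33)
  ab <- aa_alphabet()[1:20]
  for (n in c(4, 6, 8)) {
    base <- sample(ab, 7, replace = TRUE)
    rows <- vapply(seq_len(n), function(i) {
      s <- base
      mut <- runif(7) < 0.35
      s[mut] <- sample(ab, sum(mut), replace = TRUE)
      if (i == 2) s[3] <- "-"  # a gap, first-class character
      paste(s, collapse = "")
    }, character(1))
    names(rows) <- sprintf("s%02d", seq_len(n))
    aln <- aln_from(rows, "s01")
    tr <- build_upgma(distance_matrix(aln))

    cv <- covet_scores(aln, tr)
    ref_cv <- oracle_covet(rows, "s01")
    expect_equal(cv$pos_i, ref_cv$pos_i)
    expect_equal(cv$score, ref_cv$score, tolerance = 1e-9)

    em <- etmip_scores(aln, tr)
    ref_em <- oracle_etmip(rows, "s01")
    expect_equal(em$score, ref_em$score, tolerance = 1e-9)
  }
})

test_that("scoring accepts a level partition as well as the tree", {
  set.seed(4)
  ab <- aa_alphabet()[1:20]
  rows <- vapply(1:5, function(i) {
    paste(sample(ab, 6, replace = TRUE), collapse = "")
  }, character(1))
  names(rows) <- paste0("s", 1:5)
  aln <- aln_from(rows, "s1")
  tr <- build_upgma(distance_matrix(aln))
  lp <- level_partition(tr)
  expect_equal(covet_scores(aln, lp)$score, covet_scores(aln, tr)$score)
  expect_equal(etmip_scores(aln, lp)$score, etmip_scores(aln, tr)$score)
  bad <- aln_from(rows[1:4], "s1")
  expect_error(covet_scores(bad, tr), "different sequence set")
})

test_that("CovET penalties are invariant to reversing row order within the alignment", {
  set.seed(55)
  ab <- aa_alphabet()[1:20]
  ci <- sample(ab, 8, replace = TRUE)
  cj <- sample(ab, 8, replace = TRUE)
  expect_equal(covet_group_penalty(ci, cj),
               covet_group_penalty(rev(ci), rev(cj)))
})

test_that("mutual information matches closed forms", {
  expect_equal(group_mutual_information(c("A", "A"), c("D", "D")), 0)
  expect_equal(group_mutual_information(c("A", "C"), c("D", "D")), 0)
  expect_equal(group_mutual_information(c("A", "A", "C", "C"),
                                        c("A", "A", "C", "C")), log(2))
  expect_equal(group_mutual_information("A", "D"), 0)
})

test_that("average product correction matches hand evaluation and is symmetric", {
  # uniform off-diagonal MI: correction removes everything
  u <- matrix(0.3, 4, 4); diag(u) <- 0
  expect_equal(apc_correct(u), matrix(0, 4, 4))
  # degenerate all-zero table
  expect_equal(apc_correct(matrix(0, 3, 3)), matrix(0, 3, 3))
  # 3-position toy, hand-worked
  mi <- matrix(0, 3, 3)
  mi[1, 2] <- mi[2, 1] <- 0.3
  mi[1, 3] <- mi[3, 1] <- 0.1
  mi[2, 3] <- mi[3, 2] <- 0.2
  out <- apc_correct(mi)
  expect_equal(out[1, 2], 0.3 - 0.2 * 0.25 / 0.2)
  expect_equal(out[1, 3], 0.1 - 0.2 * 0.15 / 0.2)
  expect_equal(out[2, 3], 0.2 - 0.25 * 0.15 / 0.2)
  expect_equal(out, t(out))
})

test_that("ET-MIp degenerate cases are forced", {
  rows <- c(a = "AAAA", b = "AAAA", c = "AAAA")
  aln <- aln_from(rows, "a")
  tr <- build_upgma(distance_matrix(aln))
  expect_true(all(etmip_scores(aln, tr)$score == 0))

  # N = 2: single level, score equals the root-level MIp table
  rows2 <- c(a = "ACDE", b = "CCDD")
  aln2 <- aln_from(rows2, "a")
  tr2 <- build_upgma(distance_matrix(aln2))
  em <- etmip_scores(aln2, tr2)
  m <- alignment_rows_matrix <- do.call(rbind, strsplit(unname(rows2), ""))
  mi <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    mi[i, j] <- mi[j, i] <- group_mutual_information(m[, i], m[, j])
  }
  mip <- apc_correct(mi)
  expect_equal(em$score, mip[cbind(em$pos_i, em$pos_j)])
})

test_that("pair score TSV records method, orientation and checksum", {
  rows <- c(a = "ACDE", b = "CCDD", c = "ACDD")
  aln <- aln_from(rows, "a")
  tr <- build_upgma(distance_matrix(aln))
  cv <- covet_scores(aln, tr)
  tmp <- tempfile(fileext = ".tsv")
  write_pair_scores(cv, tmp, aln)
  lines <- readLines(tmp)
  expect_true(any(grepl("method=CovET", lines)))
  expect_true(any(grepl("orientation=lower_is_coupled", lines)))
  expect_true(any(grepl("alignment_md5=", lines)))
  body <- utils::read.table(tmp, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(body), choose(4, 2))
  expect_setequal(body$rank, seq_len(nrow(body)))
  unlink(tmp)
})
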