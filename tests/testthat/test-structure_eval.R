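test_that("contact map applies the CASP distance, separation and glycine rules", {
  # residues 10 and 16: CB atoms 7.9 A apart -> short contact
  # residues 10 and 14: excluded (separation 4) regardless of distance
  # residue 3 is GLY: CA is its representative atom
  pos <- c(3L, 10L, 14L, 16L, 40L)
  ca <- rbind(c(0, 0, 0), c(50, 0, 0), c(50, 1, 0), c(50, 0, 10),
              c(200, 0, 0))
  cb <- rbind(c(0, 0, 100), c(50, 0, 2), c(50, 1, 2), c(50, 0, 9.9),
              c(200, 0, 2))
  st <- make_structure(pos, ca, cb,
                       resname = c("GLY", "ALA", "ALA", "ALA", "ALA"))
  cm <- build_contact_map(st)

  r1016 <- cm[cm$pos_i == 10 & cm$pos_j == 16, ]
  expect_true(r1016$contact)
  expect_equal(r1016$class, "short")
  expect_equal(r1016$distance, 7.9)

  r1014 <- cm[cm$pos_i == 10 & cm$pos_j == 14, ]
  expect_equal(r1014$class, "excluded")
  expect_false(r1014$contact)

  # GLY at 3 is measured from CA (its CB decoy sits 100 A away)
  r310 <- cm[cm$pos_i == 3 & cm$pos_j == 10, ]
  expect_equal(r310$distance, sqrt(50^2 + 2^2))

  expect_equal(cm[cm$pos_i == 16 & cm$pos_j == 40, "class"], "long")
  expect_equal(cm[cm$pos_i == 3 & cm$pos_j == 14, "class"], "short")
  expect_equal(cm[cm$pos_i == 3 & cm$pos_j == 16, "class"], "medium")
  # every non-excluded pair has separation >= 6
  expect_true(all(abs(cm$pos_j - cm$pos_i)[cm$class != "excluded"] >= 6))
})

test_that("contact prediction metrics hit the forced extremes", {
  pos <- seq_len(20)
  set.seed(6)
  st <- toy_structure(20, clusters = list(list(residues = c(1, 8, 15),
                                               radius = 0.8)), seed = 6)
  cm <- build_contact_map(st)
  eligible <- cm[cm$class != "excluded", ]
  # perfect scores: contacts get the best (lowest) CovET-style raw score
  sc <- ifelse(eligible$contact, 1, 2)
  p_perfect <- make_pairs(eligible$pos_i, eligible$pos_j, sc, lower = TRUE)
  ev <- evaluate_contact_prediction(p_perfect, cm, "all")
  expect_equal(ev$auroc, 1)
  p_anti <- make_pairs(eligible$pos_i, eligible$pos_j, -sc, lower = TRUE)
  expect_equal(evaluate_contact_prediction(p_anti, cm, "all")$auroc, 0)
  expect_equal(ev$positive_rate, mean(eligible$contact))
})

test_that("adjusted AUPRC of a random predictor is centred near zero", {
  # Average precision has an exact permutation-null mean of
  # H_n/n + (P-1)(n - H_n)/(n(n-1)), slightly above the positive rate P/n
  # at finite n; the simulation must match that closed form, and the
  # adjusted AUPRC must sit correspondingly close to zero.
  set.seed(17)
  n <- 200; npos <- 20
  lab <- c(rep(TRUE, npos), rep(FALSE, n - npos))
  reps <- 1000
  vals <- vapply(seq_len(reps), function(i) {
    covet:::average_precision(runif(n), lab)
  }, numeric(1))
  hn <- sum(1 / seq_len(n))
  exact_mean <- hn / n + (npos - 1) * (n - hn) / (n * (n - 1))
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - exact_mean), 3 * se)
  expect_lt(abs(mean(vals) - npos / n), 0.05)
  # exhaustive check of the exact null at tiny n
  tiny_lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  perms <- combn(5, 2)
  aps <- apply(perms, 2, function(ix) {
    l <- rep(FALSE, 5); l[ix] <- TRUE
    covet:::average_precision(5:1, l)
  })
  h5 <- sum(1 / (1:5))
  expect_equal(mean(aps), h5 / 5 + (2 - 1) * (5 - h5) / (5 * 4))
})

test_that("SCW w statistic counts adjacent selected pairs with the chosen bias", {
  adj <- make_adjacency(5, list(c(1, 2), c(3, 4)))
  expect_equal(scw_w(integer(0), adj), 0)
  expect_equal(scw_w(c(1, 2), adj, "unbiased"), 1)
  expect_equal(scw_w(c(1, 2), adj, "biased"), 1)     # |1-2| = 1
  expect_equal(scw_w(c(1, 4), adj, "unbiased"), 0)   # no edge
  expect_equal(scw_w(c(1, 2, 3, 4), adj, "unbiased"), 2)
  adj2 <- make_adjacency(6, list(c(1, 5), c(2, 3)))
  expect_equal(scw_w(c(1, 2, 3, 5), adj2, "biased"), 4 + 1)
})

test_that("biased w dominates unbiased w on separations >= 1", {
  set.seed(3)
  st <- toy_structure(25, clusters = list(list(residues = c(2, 9, 17, 21),
                                               radius = 0.9)), seed = 3)
  adj <- scw_adjacency(st)
  for (i in 1:10) {
    sel <- sample(1:25, 8)
    expect_gte(scw_w(sel, adj, "biased"), scw_w(sel, adj, "unbiased"))
  }
})

test_that("analytic SCW null matches the Monte-Carlo null on a toy structure", {
  st <- toy_structure(20, clusters = list(list(residues = c(2, 5, 9, 13, 16, 19),
                                               radius = 0.9)), seed = 11)
  adj <- scw_adjacency(st)
  cluster <- c(2, 5, 9, 13, 16, 19)
  for (bias in c("unbiased", "biased")) {
    an <- scw_zscore(cluster, adj, bias, null = "analytic")
    mc <- scw_zscore(cluster, adj, bias, null = "montecarlo",
                     draws = 10000, seed = 99)
    se_mean <- mc$sd / sqrt(mc$draws)
    expect_lt(abs(an$expected - mc$expected), 3 * se_mean)
    se_sd <- mc$sd / sqrt(2 * mc$draws)
    expect_lt(abs(an$sd - mc$sd), 3 * se_sd)
    expect_equal(an$w, mc$w)
  }
  # the planted cluster is significantly clustered by the usual z > 2 rule
  expect_gt(scw_zscore(cluster, adj, "unbiased")$z, 2)
})

test_that("random selections have SCW z centred at zero", {
  st <- toy_structure(20, clusters = list(list(residues = c(2, 5, 9, 13, 16, 19),
                                               radius = 0.9)), seed = 11)
  adj <- scw_adjacency(st)
  set.seed(123)
  zs <- vapply(1:300, function(i) {
    scw_zscore(sample(1:20, 6), adj, "unbiased")$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
  expect_lt(sd(zs), 2)   # unit-scale spread
  expect_gt(sd(zs), 0.3)
})

test_that("degenerate selections flag an undefined z", {
  adj <- make_adjacency(6, list(c(1, 2), c(2, 3), c(4, 5)))
  res <- scw_zscore(1:6, adj, "unbiased")
  expect_true(res$undefined)
  expect_true(is.na(res$z))
  expect_error(scw_zscore(1L, adj), "at least 2")
})

test_that("functional residues use a strict 4 A any-atom rule", {
  ca <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  st <- make_structure(1:3, ca)
  lig <- data.frame(x = c(3.9, 10), y = c(0, 4.0), z = c(0, 0))
  expect_equal(functional_residues(st, lig), 1L)   # 3.9 in, exactly 4.0 out
  far <- data.frame(x = 1000, y = 0, z = 0)
  expect_equal(functional_residues(st, far), integer(0))
  expect_error(functional_residues(st, far[0, ]), "empty")
})

test_that("hypergeometric overlap matches exact combinatorics", {
  expect_equal(hypergeometric_overlap(1:4, 1:5, 10), 5 / choose(10, 4))
  expect_equal(hypergeometric_overlap(integer(0), 1:3, 10), 1)
  expect_equal(hypergeometric_overlap(c(7, 9), 1:12, 12), 1)  # gold = universe
  expect_error(hypergeometric_overlap(1:3, 1:2, 0), ">= 1")
})

test_that("hypergeometric overlap equals exhaustive enumeration on small universes", {
  for (cfg in list(c(u = 8, g = 3, k = 4), c(u = 12, g = 5, k = 6),
                   c(u = 10, g = 4, k = 2))) {
    u <- cfg["u"]; g <- cfg["g"]; k <- cfg["k"]
    gold <- seq_len(g)
    sels <- combn(u, k)
    overlaps <- apply(sels, 2, function(s) length(intersect(s, gold)))
    for (obs in 0:min(g, k)) {
      exact <- mean(overlaps >= obs)
      sel <- c(seq_len(obs), setdiff(seq.int(g + 1, u), 0)[seq_len(k - obs)])
      expect_equal(hypergeometric_overlap(sel, gold, u), exact,
                   tolerance = 1e-12)
    }
  }
})

test_that("mean sequence separation and its normalization", {
  sel <- structure(list(pairs = data.frame(pos_i = c(1, 2), pos_j = c(5, 10)),
                        residues = c(1, 2, 5, 10), threshold = 0.3,
                        residue_count = 100),
                   class = "coverage_selection")
  expect_equal(mean_sequence_separation(sel), 6)
  expect_equal(mean_sequence_separation(sel, 100, normalized = TRUE), 0.06)
  expect_equal(mean_sequence_separation(data.frame(pos_i = 2, pos_j = 8)), 6)
  expect_error(mean_sequence_separation(data.frame(pos_i = numeric(0),
                                                   pos_j = numeric(0))),
               "empty")
})

test_that("selected pairs decompose into connected components", {
  comp <- selected_pair_components(data.frame(pos_i = c(1, 2, 7),
                                              pos_j = c(2, 3, 8)))
  expect_equal(comp, list(c(1L, 2L, 3L), c(7L, 8L)))
  expect_equal(selected_pair_components(data.frame(pos_i = 4, pos_j = 9)),
               list(c(4L, 9L)))
  cyc <- selected_pair_components(data.frame(pos_i = c(1, 2, 1),
                                             pos_j = c(2, 3, 3)))
  expect_equal(cyc, list(c(1L, 2L, 3L)))
})

test_that("toy structures round-trip through PDB", {
  st <- toy_structure(10, seed = 8)
  tmp <- tempfile(fileext = ".pdb")
  write_structure_pdb(st, tmp)
  back <- read_structure(tmp, chain = "A")
  expect_equal(structure_positions(back), structure_positions(st))
  bt <- back$atoms[order(back$atoms$position, back$atoms$atom), ]
  ot <- st$atoms[order(st$atoms$position, st$atoms$atom), ]
  expect_equal(bt$x, ot$x, tolerance = 1e-3)
  expect_equal(bt$z, ot$z, tolerance = 1e-3)
  unlink(tmp)
})

test_that("query mapping by exact sequence match is strict", {
  st <- toy_structure(5, seed = 2)
  tmp <- tempfile(fileext = ".pdb")
  write_structure_pdb(st, tmp)
  # all residues are ALA; the query must contain AAAAA exactly
  mapped <- read_structure(tmp, chain = "A", query = "GGAAAAAGG")
  expect_equal(structure_positions(mapped), 3:7)
  expect_error(read_structure(tmp, chain = "A", query = "GWGWGWG"),
               "does not match")
  unlink(tmp)
})
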