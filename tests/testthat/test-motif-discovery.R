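test_that("k-mer enumeration is complete and lexicographic", {
  expect_equal(enumerate_kmers(1), c("A", "C", "G", "T"))
  k2 <- enumerate_kmers(2)
  expect_length(k2, 16L)
  expect_equal(k2[1], "AA")
  expect_equal(k2[2], "AC")
  expect_equal(k2[16], "TT")
  expect_identical(k2, sort(k2))
  expect_length(enumerate_kmers(c(2, 3)), 16L + 64L)
})

test_that("promoter indexing records binary forward-strand presence", {
  idx <- index_promoters(c(g1 = "ACGTACG"), 6)
  P <- idx$presence[["6"]]
  present <- rownames(P)[P[, "g1"] != 0]
  expect_setequal(present, c("ACGTAC", "CGTACG"))

  # multiple occurrences count once
  idx2 <- index_promoters(c(g1 = "AAAAAAAA"), 6)
  expect_equal(sum(idx2$presence[["6"]][, "g1"]), 1)
  expect_equal(as.numeric(idx2$presence[["6"]]["AAAAAA", "g1"]), 1)

  # windows containing N never match
  idx3 <- index_promoters(c(g1 = "AANAAAAAA"), 6)
  expect_equal(as.numeric(idx3$presence[["6"]]["AAAAAA", "g1"]), 1)
  idx4 <- index_promoters(c(g1 = "AANAAA"), 6)
  expect_equal(sum(idx4$presence[["6"]]), 0)

  expect_error(index_promoters(setNames(c("ACGTAA", "ACGTAA"), c("a", "a")), 6),
               "unique")
  expect_error(index_promoters(c(g1 = "ACG"), 6), "shortest")

  # reverse-complement mode ORs in the other strand
  idx5 <- index_promoters(c(g1 = "AAACCC"), 6, both_strands = TRUE)
  expect_equal(as.numeric(idx5$presence[["6"]]["GGGTTT", "g1"]), 1)
})

test_that("motif enrichment equals the exhaustive-enumeration oracle", {
  # fixed example: n = 10, L = 4, k = 3, l = 2 -> 40/120
  seqs <- setNames(c(rep("ACGTACG", 4), rep("TTTTTTT", 6)),
                   paste0("g", 1:10))
  idx <- index_promoters(seqs, 7)
  hit <- motif_enrichment(paste0("g", c(1, 2, 5)), "ACGTACG", idx)
  expect_equal(hit$overlap, 2L)
  expect_equal(hit$motif_total, 4L)
  expect_equal(hit$p_value, 40 / 120, tolerance = 1e-12)
  # full enumeration over all C(10,3) pools
  combos <- combn(10, 3)
  frac <- mean(colSums(matrix(combos %in% 1:4, nrow = 3)) >= 2)
  expect_equal(hit$p_value, frac, tolerance = 1e-12)

  # motif in every promoter: l = k and p = 1
  all_idx <- index_promoters(setNames(rep("ACGTACGT", 5), paste0("g", 1:5)), 7)
  h2 <- motif_enrichment(c("g1", "g2"), "ACGTACG", all_idx)
  expect_equal(h2$overlap, h2$pool_size)
  expect_equal(h2$p_value, 1)
  # absent motif: l = 0, p = 1
  h3 <- motif_enrichment(c("g1", "g2"), "CCCCCCC", all_idx)
  expect_equal(h3$overlap, 0L)
  expect_equal(h3$p_value, 1)

  expect_error(motif_enrichment(c("gX"), "ACGTACG", all_idx), "outside")
})

test_that("BH correction reproduces the textbook step-up adjustment", {
  hits <- data.frame(p_value = c(0.001, 0.013, 0.04, 0.8))
  out <- bh_correct(hits, q = 0.05)
  expect_equal(out$bh_adjusted, c(0.004, 0.026, 4 * 0.04 / 3, 0.8),
               tolerance = 1e-12)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))

  same <- bh_correct(data.frame(p_value = rep(0.03, 5)), q = 0.05)
  expect_true(all(same$bh_adjusted == 0.03))
  one <- bh_correct(data.frame(p_value = 0.2))
  expect_equal(one$bh_adjusted, 0.2)
  empty <- bh_correct(data.frame(p_value = numeric()))
  expect_equal(nrow(empty), 0L)
  # monotone in raw ranks
  set.seed(51)
  p <- runif(30)
  adj <- bh_correct(data.frame(p_value = p))$bh_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("rewiring preserves pool cardinalities and is reproducible", {
  sim <- small_planted(seed = 52, n_genes = 80)
  tfs <- network_tfs(sim$truth)
  model <- plant_motifs(sim$model,
                        setNames(enumerate_kmers(7)[seq_along(tfs) * 777],
                                 tfs), pi = 1)
  proms <- generate_promoters(model, sim$truth, sim$expr$gene_ids,
                              length = 150, seed = 53)
  idx <- index_promoters(proms, 7)
  rn <- rewire_null(sim$truth, idx, reps = 5, seed = 54)
  rn2 <- rewire_null(sim$truth, idx, reps = 5, seed = 54)
  expect_identical(rn$null_counts, rn2$null_counts)
  expect_gt(rn$observed, 0)
  expect_equal(rn$exceedance, mean(rn$null_counts >= rn$observed))

  # the permutation variant preserves the total target multiset size bound
  rp <- rewire_null(sim$truth, idx, reps = 3, seed = 55,
                    permute_targets = TRUE)
  expect_length(rp$null_counts, 3L)
})

test_that("discover_motifs flags planted motifs per TF", {
  sim <- small_planted(seed = 56, n_genes = 100)
  tfs <- network_tfs(sim$truth)
  motifs <- setNames(enumerate_kmers(7)[seq_along(tfs) * 999], tfs)
  model <- plant_motifs(sim$model, motifs, pi = 1)
  proms <- generate_promoters(model, sim$truth, sim$expr$gene_ids,
                              length = 400, seed = 57)
  idx <- index_promoters(proms, 7)
  hits <- discover_motifs(sim$truth, idx, k = 7, q = 0.05)
  for (tf in tfs)
    expect_true(motifs[[tf]] %in% hits$motif[hits$tf == tf])
  # global-FDR variant still finds them
  hg <- discover_motifs(sim$truth, idx, k = 7, q = 0.05, global_fdr = TRUE)
  for (tf in tfs)
    expect_true(motifs[[tf]] %in% hg$motif[hg$tf == tf])
})

test_that("IC alignment scores follow the information-content scheme", {
  consensus_A <- pwm(matrix(rep(c(1, 0, 0, 0), 7), nrow = 4), id = "pA")
  a <- ic_score(consensus_A, "AAAAAAA")
  expect_equal(a$ic_score, 1, tolerance = 1e-12)
  expect_equal(a$window_score, 14)   # 7 columns x 1*log2(1/0.25)
  expect_equal(a$s_max, 14)

  b <- ic_score(consensus_A, "AAAAAAC")
  expect_equal(b$ic_score, 12 / 14, tolerance = 1e-12)
  expect_equal(b$window_score, 12)

  # best window start: motif matches columns 3..9 of a 10-wide PWM
  m <- matrix(0.25, 4, 10)
  m[, 3:9] <- 0
  m[cbind(match(strsplit("GATTACA", "")[[1]], c("A", "C", "G", "T")), 3:9)] <- 1
  p10 <- pwm(m, id = "p10")
  g <- ic_score(p10, "GATTACA")
  expect_equal(g$best_start, 3L)
  expect_equal(g$ic_score, 1)
  # appending uniform columns adds nothing to s_max
  expect_equal(g$s_max, 14)

  expect_error(ic_score(pwm(matrix(0.25, 4, 5)), "AAAAAAA"), "shorter")
  expect_error(ic_score(consensus_A, "AAAA"), "7-mer")

  # literal-minus convention flips the preference away from conserved columns
  lit <- suppressWarnings(ic_score(consensus_A, "AAAAAAA",
                                   convention = "literal"))
  expect_lte(lit$window_score, 0)
})

test_that("uninformative PWMs and random pairs keep ic_score bounded", {
  flat <- pwm(matrix(0.25, 4, 8))
  expect_warning(r <- ic_score(flat, "ACGTACG"), "no information")
  expect_true(is.nan(r$ic_score))

  set.seed(58)
  for (i in 1:100) {
    w <- sample(7:12, 1)
    m <- matrix(rexp(4 * w), nrow = 4)
    m <- sweep(m, 2, colSums(m), "/")
    mot <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                 collapse = "")
    expect_lte(ic_score(pwm(m), mot)$ic_score, 1 + 1e-12)
  }
})

test_that("true TF-motif assignments outscore shuffled ones on planted data", {
  set.seed(59)
  tfs <- paste0("TF", 1:6)
  cores <- vapply(tfs, function(i)
    paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = ""),
    character(1))
  make_pwm <- function(core) {
    m <- matrix(0.25, 4, 9)
    q <- match(strsplit(core, "")[[1]], c("A", "C", "G", "T"))
    for (j in seq_len(7)) {
      m[, j + 1] <- 0.04
      m[q[j], j + 1] <- 0.88
    }
    m <- sweep(m, 2, colSums(m), "/")
    pwm(m)
  }
  pwms <- setNames(lapply(cores, make_pwm), tfs)
  assignments <- setNames(as.list(cores), tfs)
  res <- score_shuffle_baseline(assignments, pwms, seed = 60)
  expect_gt(mean(res$true_scores), mean(res$shuffled_scores))
  expect_lt(res$p_value, 0.01)
  res2 <- score_shuffle_baseline(assignments, pwms, seed = 60)
  expect_identical(res$shuffled_scores, res2$shuffled_scores)
})
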