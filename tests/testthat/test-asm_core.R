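test_that("summarize_sites tallies per-position methylation", {
  mat <- pattern_rows(pat(3, "M", "M"), pat(2, "U", NA), pat(2, NA, "U"))
  fr <- frags_from_matrix(mat, c(10L, 20L))
  s <- summarize_sites(fr)
  expect_equal(s$pos, c(10L, 20L))
  expect_equal(s$n_meth, c(3L, 3L))
  expect_equal(s$n_unmeth, c(2L, 2L))
  expect_equal(s$level, c(0.6, 0.6))
  # uncovered positions are absent
  expect_false(30L %in% s$pos)
})

test_that("effective-site filter removes extreme and shallow sites", {
  sites <- data.frame(
    chrom = "chr1", strand = "+", pos = 1:5 * 10L, context = "CpG",
    n_meth = c(19L, 1L, 5L, 2L, 5L), n_unmeth = c(1L, 19L, 5L, 1L, 5L))
  sites$level <- sites$n_meth / (sites$n_meth + sites$n_unmeth)
  eff <- select_effective_sites(sites)
  # 0.95 and 0.05 removed; coverage 3 removed; the two balanced sites stay
  expect_equal(eff$pos, c(30L, 50L))
  # boundary levels 0.1 and 0.9 are retained (removal is strict)
  sites2 <- data.frame(chrom = "chr1", strand = "+", pos = c(1L, 2L),
                       context = "CpG", n_meth = c(1L, 9L),
                       n_unmeth = c(9L, 1L))
  sites2$level <- sites2$n_meth / 10
  expect_equal(nrow(select_effective_sites(sites2)), 2L)
  expect_error(select_effective_sites(sites, low = 0.9, high = 0.1),
               "configuration")
  expect_error(select_effective_sites(sites, min_cov = 0), "configuration")
})

test_that("count_pair matches a brute-force per-fragment tally", {
  set.seed(7)
  for (rep in 1:20) {
    mat <- matrix(sample(c("M", "U", NA), 30 * 2, replace = TRUE,
                         prob = c(0.4, 0.4, 0.2)), ncol = 2)
    fr <- frags_from_matrix(mat, c(10L, 25L))
    pc <- count_pair(fr, 10L, 25L)
    expect_equal(c(pc$n11, pc$n12, pc$n21, pc$n22),
                 oracle_pair_counts(mat, 1L, 2L))
    expect_equal(pc$total, pc$n11 + pc$n12 + pc$n21 + pc$n22)
  }
  fr <- frags_from_matrix(pattern_rows(pat(5, "M", "M"), pat(5, "U", "U")),
                          c(10L, 25L))
  pc <- count_pair(fr, 10L, 25L)
  expect_equal(c(pc$n11, pc$n12, pc$n21, pc$n22), c(5L, 0L, 0L, 5L))
  # a fragment covering only one site contributes nothing
  fr2 <- frags_from_matrix(rbind(c("M", NA)), c(10L, 25L))
  expect_equal(count_pair(fr2, 10L, 25L)$total, 0L)
  expect_error(count_pair(fr, 25L, 10L), "pos_i")
})

test_that("pair_pvalue reproduces hand-enumerated exact probabilities", {
  # Hyper(N=10, K=5, n=5): only X=5 and X=0 have point prob <= 1/252
  expect_equal(pair_pvalue(c(5, 0, 0, 5)), 2 / 252, tolerance = 1e-12)
  # the observed table is the mode: every outcome is included
  expect_equal(pair_pvalue(c(2, 2, 2, 2)), 1)
  # degenerate margins admit a single table
  expect_equal(pair_pvalue(c(0, 0, 3, 4)), 1)
  expect_equal(pair_pvalue(c(3, 0, 4, 0)), 1)
  expect_error(pair_pvalue(c(0, 0, 0, 0)), "zero-total")
})

test_that("pair_pvalue agrees with fisher.test on random tables", {
  set.seed(11)
  for (i in 1:200) {
    cells <- as.numeric(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    p_mine <- pair_pvalue(cells)
    p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p_mine, p_ref, tolerance = 1e-7)
  }
})

test_that("adjust_fdr implements Benjamini-Hochberg step-up", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.3), 0.3)
  p <- c(0.001, 0.2, 0.04, 0.9, 0.02)
  expect_equal(adjust_fdr(p), oracle_bh(p))
  # order-preserving under permutation
  set.seed(3)
  perm <- sample(5)
  expect_equal(adjust_fdr(p[perm]), adjust_fdr(p)[perm])
  # monotone: adjusted >= raw, capped at 1
  expect_true(all(adjust_fdr(p) >= p))
  expect_error(adjust_fdr(numeric(0)), "empty")
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("classify_pair applies the three ASM criteria strictly", {
  mk <- function(cells, p_adj) {
    data.frame(n11 = cells[1], n12 = cells[2], n21 = cells[3],
               n22 = cells[4], total = sum(cells), p_adj = p_adj)
  }
  expect_equal(classify_pair(mk(c(10, 0, 0, 10), 1e-4)), "ASM")
  # ratio 18/1 >= 2 fails criterion 3
  expect_equal(classify_pair(mk(c(18, 1, 1, 0), 0.01)), "not-ASM")
  # top2 = 15/20 <= 90% fails criterion 2
  expect_equal(classify_pair(mk(c(9, 6, 3, 2), 0.01)), "not-ASM")
  # p_adj at threshold fails criterion 1
  expect_equal(classify_pair(mk(c(10, 0, 0, 10), 0.05)), "not-ASM")
  # top2 exactly 90% fails (strict >): 9+9 of 20
  expect_equal(classify_pair(mk(c(9, 1, 1, 9), 1e-4)), "not-ASM")
  # ratio exactly 2 fails (strict <)
  expect_equal(classify_pair(mk(c(12, 0, 0, 6), 1e-4)), "not-ASM")
  # second max 0: fully concordant single pattern, not ASM
  expect_equal(classify_pair(mk(c(20, 0, 0, 0), 1e-4)), "not-ASM")
  expect_error(classify_pair(mk(c(1, 1, 1, 1), NA_real_)), "p_adj")
})

test_that("extend_blocks chains accepted pairs and splits on rejection", {
  # five sites; consecutive pairs: ASM, ASM, reject (independent), ASM
  pos <- c(10L, 20L, 30L, 40L, 50L)
  asm_pat <- function(i, j) {
    m <- matrix(NA_character_, 24, 5)
    m[1:12, i] <- c(rep("M", 6), rep("U", 6))
    m[1:12, j] <- c(rep("M", 6), rep("U", 6))
    m
  }
  rej_pat <- function(i, j) {
    m <- matrix(NA_character_, 24, 5)
    m[1:24, i] <- rep(c("M", "U"), 12)
    m[1:24, j] <- rep(c("M", "M", "U", "U"), 6)
    m
  }
  mat <- rbind(asm_pat(1, 2), asm_pat(2, 3), rej_pat(3, 4), asm_pat(4, 5))
  fr <- frags_from_matrix(mat, pos)
  eff <- select_effective_sites(summarize_sites(fr))
  expect_equal(eff$pos, pos)
  blocks <- extend_blocks(eff, fr)
  expect_length(blocks, 2L)
  expect_equal(blocks[[1]]$sites$pos, c(10L, 20L, 30L))
  expect_equal(blocks[[2]]$sites$pos, c(40L, 50L))
  expect_equal(blocks[[1]]$n_cytosines, 3L)
  # every consecutive pair of an emitted block is an accepted ASM pair
  expect_error(extend_blocks(eff[c(2, 1, 3, 4, 5), ], fr), "sorted")
})

test_that("extend_blocks returns nothing when no pair is accepted", {
  mat <- pattern_rows(pat(6, "M", "M"), pat(6, "M", "U"),
                      pat(6, "U", "M"), pat(6, "U", "U"))
  fr <- frags_from_matrix(mat, c(10L, 20L))
  eff <- select_effective_sites(summarize_sites(fr))
  expect_length(extend_blocks(eff, fr), 0L)
})

test_that("anti-correlated adjacent sites chain with flipped phase", {
  # M at site 1 travels with U at site 2: still ASM, opposite orientation
  mat <- pattern_rows(pat(10, "M", "U"), pat(10, "U", "M"))
  fr <- frags_from_matrix(mat, c(10L, 20L))
  eff <- select_effective_sites(summarize_sites(fr))
  blocks <- extend_blocks(eff, fr)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$sites$hapA_code, c(1L, 2L))
})
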