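test_that("count_meth_snp_pair tallies methylation x allele co-occurrence", {
  mat <- pattern_rows(pat(6, "M", "R"), pat(6, "U", "V"))
  fr <- frags_from_matrix(mat, c(10L, 30L))
  snp <- list(chrom = "chr1", pos = 30L)
  pc <- count_meth_snp_pair(fr, 10L, snp)
  expect_equal(c(pc$n11, pc$n12, pc$n21, pc$n22), c(6L, 0L, 0L, 6L))
  expect_equal(pc$kind, "meth-snp")
  # fragment with a methylation call but no (suppressed) allele call
  mat2 <- rbind(mat, c("M", NA))
  fr2 <- frags_from_matrix(mat2, c(10L, 30L))
  expect_equal(count_meth_snp_pair(fr2, 10L, snp)$total, 12L)
  # zero-total table is signaled
  fr3 <- frags_from_matrix(rbind(c("M", NA), c("U", NA)), c(10L, 30L))
  expect_warning(pc3 <- count_meth_snp_pair(fr3, 10L, snp), "zero-total")
  expect_equal(pc3$total, 0L)
})

test_that("count_meth_snp_pair matches a brute-force tally", {
  set.seed(19)
  for (rep in 1:20) {
    meth_col <- sample(c("M", "U", NA), 40, replace = TRUE)
    snp_col <- sample(c("R", "V", NA), 40, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2))
    mat <- cbind(meth_col, snp_col)
    fr <- frags_from_matrix(mat, c(10L, 30L))
    pc <- suppressWarnings(
      count_meth_snp_pair(fr, 10L, list(chrom = "chr1", pos = 30L)))
    expect_equal(c(pc$n11, pc$n12, pc$n21, pc$n22),
                 oracle_pair_counts(mat, 1L, 2L, c("M", "U"), c("R", "V")))
  }
})

test_that("phase_snps assigns the allele co-occurring with haplotype A", {
  # block of two concordant cytosines; SNP whose R allele rides with M
  mat <- rbind(
    cbind(pattern_rows(pat(10, "M", "M"), pat(9, "U", "U")),
          NA_character_),
    cbind(matrix(NA_character_, 19, 2),
          c(rep("R", 10), rep("V", 9))))
  # fragments covering cytosine 20 and the SNP together
  link <- matrix(NA_character_, 19, 3)
  link[, 2] <- c(rep("M", 10), rep("U", 9))
  link[, 3] <- c(rep("R", 10), rep("V", 9))
  mat <- rbind(mat, link)
  fr <- frags_from_matrix(mat, c(10L, 20L, 35L))
  het <- data.frame(chrom = "chr1", pos = 35L, ref = "A", alt = "G",
                    id = NA_character_, stringsAsFactors = FALSE)
  eff <- select_effective_sites(summarize_sites(fr))
  blocks <- extend_blocks(eff, fr)
  expect_length(blocks, 1L)
  pv <- phase_snps(blocks[[1]], fr, het)
  expect_equal(pv$pos, 35L)
  expect_equal(pv$phase, 0L)  # ref allele on the methylated haplotype A
})

test_that("conflicting cytosine votes leave the SNP unphased", {
  # chain pair c1-c2 concordant; SNP votes 0 via c1 but 1 via c2
  chain <- cbind(pattern_rows(pat(8, "M", "M"), pat(8, "U", "U")),
                 NA_character_)
  v1 <- matrix(NA_character_, 16, 3)
  v1[, 1] <- c(rep("M", 8), rep("U", 8))
  v1[, 3] <- c(rep("R", 8), rep("V", 8))
  v2 <- matrix(NA_character_, 16, 3)
  v2[, 2] <- c(rep("M", 8), rep("U", 8))
  v2[, 3] <- c(rep("V", 8), rep("R", 8))
  fr <- frags_from_matrix(rbind(chain, v1, v2), c(10L, 20L, 35L))
  het <- data.frame(chrom = "chr1", pos = 35L, ref = "A", alt = "G",
                    id = NA_character_, stringsAsFactors = FALSE)
  eff <- select_effective_sites(summarize_sites(fr))
  blocks <- extend_blocks(eff, fr)
  pv <- phase_snps(blocks[[1]], fr, het)
  expect_true(is.na(pv$phase[pv$pos == 35L]))
  expect_equal(pv$n_votes[pv$pos == 35L], 2L)
})

test_that("phased_fraction counts distinct phased SNPs over the input set", {
  het <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                    ref = "A", alt = "G", id = NA_character_,
                    stringsAsFactors = FALSE)
  ph <- data.frame(block_id = "b1", chrom = "chr1",
                   pos = c(10L, 20L, 30L),
                   phase = c(0L, 1L, NA_integer_))
  expect_equal(phased_fraction(ph, het), 0.5)
  ph$phase[3] <- 0L
  expect_equal(phased_fraction(ph, het), 0.75)
  expect_equal(phased_fraction(ph[0, ], het), 0)
  expect_error(phased_fraction(ph, het[0, ]), "empty")
})

test_that("snp-aware mode never phases fewer SNPs than snp-only mode", {
  sim <- small_noiseless_sim(seed = 5)
  res_snp <- call_asm_blocks(sim$frags, sim$het, mode = "snp")
  res_asm <- call_asm_blocks(sim$frags, sim$het, mode = "asm+snp")
  expect_gte(phased_fraction(res_asm, sim$het),
             phased_fraction(res_snp, sim$het))
  expect_gte(total_block_span(res_asm), total_block_span(res_snp))
})
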