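test_that("identical seed and parameters give byte-identical outputs", {
  t1 <- make_truth(genome_length = 5000, n_asm_regions = 1, n_snps = 5,
                   depth = 4, seed = 9)
  t2 <- make_truth(genome_length = 5000, n_asm_regions = 1, n_snps = 5,
                   depth = 4, seed = 9)
  expect_identical(t1, t2)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- simulate_bisulfite(t1, d1)
  p2 <- simulate_bisulfite(t2, d2)
  expect_identical(readLines(p1$sam), readLines(p2$sam))
  expect_identical(readLines(p1$vcf), readLines(p2$vcf))
  h1 <- simulate_hic(t1)
  h2 <- simulate_hic(t2)
  expect_identical(h1$snps, h2$snps)
})

test_that("zero ASM regions leave the alleles identically methylated", {
  tr <- make_truth(genome_length = 5000, n_asm_regions = 0, n_snps = 5,
                   depth = 4, seed = 3)
  expect_equal(nrow(tr$regions), 0L)
  expect_equal(tr$cpgs$level_hap1, tr$cpgs$level_hap2)
})

test_that("planted regions reach the requested CpG density", {
  tr <- make_truth(genome_length = 30000, n_asm_regions = 3,
                   region_length = 2000, cpg_spacing = 25, n_snps = 0,
                   seed = 4)
  for (r in seq_len(nrow(tr$regions))) {
    n_cpg <- sum(tr$cpgs$pos >= tr$regions$start[r] &
                   tr$cpgs$pos <= tr$regions$end[r])
    # at least one dyad per (spacing + max jitter) bp
    expect_gte(n_cpg, floor(2000 / 30))
  }
  expect_error(make_truth(genome_length = 5000, n_asm_regions = 10),
               "capacity")
})

test_that("emitted VCF carries exactly the planted het SNPs", {
  tr <- make_truth(genome_length = 8000, n_asm_regions = 1, n_snps = 8,
                   depth = 4, seed = 12)
  d <- tempfile()
  paths <- simulate_bisulfite(tr, d)
  het <- load_het_snps(paths$vcf)
  expect_equal(nrow(het), nrow(tr$snps))
  expect_equal(het$pos, tr$snps$pos)
  expect_equal(het$ref, tr$snps$ref)
  expect_equal(het$alt, tr$snps$alt)
})

test_that("noiseless reads reproduce the planted site states exactly", {
  sim <- small_noiseless_sim(seed = 21)
  sites <- summarize_sites(sim$frags)
  tp <- truth_pairs(sim$truth)
  # heterotypic planted sites: one allele M, one U, equal depth -> level 1/2
  het_plus <- tp$sites$pos[tp$sites$strand == "+"]
  obs <- sites[sites$strand == "+" & sites$pos %in% het_plus, ]
  expect_true(all(obs$level == 0.5))
  # homotypic background (non-fluctuating) sites are fully M or fully U
  bg <- sim$truth$cpgs[is.na(sim$truth$cpgs$region) &
                         sim$truth$cpgs$level_hap1 %in% c(0, 1), ]
  obs_bg <- sites[sites$strand == "+" & sites$pos %in% bg$pos, ]
  expect_true(all(obs_bg$level %in% c(0, 1)))
})

test_that("paired-end mode yields one deduplicated fragment per pair", {
  tr <- make_truth(genome_length = 6000, n_asm_regions = 1, n_snps = 4,
                   depth = 4, conv_fail_rate = 0, seq_error_rate = 0,
                   paired = TRUE, seed = 8)
  d <- tempfile()
  paths <- simulate_bisulfite(tr, d)
  sam_qnames <- table(vapply(strsplit(grep("^@", readLines(paths$sam),
                                           invert = TRUE, value = TRUE),
                                      "\t"), `[`, character(1), 1L))
  expect_true(all(sam_qnames == 2L))  # two mates per fragment
  genome <- load_genome(paths$fasta)
  fr <- extract_fragments(paths$sam, genome)
  expect_equal(nrow(fr$fragments), paths$n_fragments)
  # no duplicate calls per fragment (constructor enforces; spot-check)
  expect_false(anyDuplicated(fr$meth[c("fragment_id", "pos")]) > 0)
})

test_that("simulated Hi-C phases equal truth up to a global flip per block", {
  tr <- make_truth(genome_length = 30000, n_asm_regions = 3, n_snps = 20,
                   depth = 4, seed = 31)
  hic <- simulate_hic(tr, n_pairs = 200, error_rate = 0,
                      missing_rate = 0)
  expect_gt(nrow(hic$blocks), 0L)
  truth_ph <- stats::setNames(tr$snps$hap1_allele, tr$snps$pos)
  for (bid in hic$blocks$block_id) {
    s <- hic$snps[hic$snps$block_id == bid, ]
    tt <- truth_ph[as.character(s$pos)]
    agree <- s$phase == tt
    expect_true(all(agree) || all(!agree))
  }
  # missing rate 1 leaves every phase missing
  hic_m <- simulate_hic(tr, n_pairs = 200, error_rate = 0, missing_rate = 1)
  expect_true(all(is.na(hic_m$snps$phase)))
})

test_that("Hi-C per-SNP error rate matches the requested rate", {
  tr <- make_truth(genome_length = 80000, n_asm_regions = 0, n_snps = 400,
                   depth = 4, seed = 77)
  hic <- simulate_hic(tr, n_pairs = 5000, error_rate = 0.15,
                      missing_rate = 0, max_span = 80000)
  truth_ph <- stats::setNames(tr$snps$hap1_allele, tr$snps$pos)
  mismatch <- 0L; n <- 0L
  for (bid in hic$blocks$block_id) {
    s <- hic$snps[hic$snps$block_id == bid, ]
    tt <- truth_ph[as.character(s$pos)]
    agree <- mean(s$phase == tt)
    # undo the arbitrary global flip by majority orientation
    err <- min(agree, 1 - agree)
    mismatch <- mismatch + round(err * nrow(s)); n <- n + nrow(s)
  }
  expect_gt(n, 200L)
  expect_lt(abs(mismatch / n - 0.15), 0.05)
})
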