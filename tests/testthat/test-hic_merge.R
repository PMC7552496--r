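pv <- function(pos, phase, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, phase = phase,
             stringsAsFactors = FALSE)
}

mk_ps <- function(..., source = "WGBS") {
  blocks <- list(...)
  bdf <- NULL; sdf <- NULL
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    bid <- sprintf("%s_%d", tolower(source), i)
    bdf <- rbind(bdf, data.frame(block_id = bid, chrom = "chr1",
                                 start = min(b$pos), end = max(b$pos),
                                 source = source, stringsAsFactors = FALSE))
    sdf <- rbind(sdf, data.frame(block_id = bid, chrom = "chr1",
                                 pos = b$pos, ref = "A", alt = "G",
                                 phase = b$phase, source = source,
                                 stringsAsFactors = FALSE))
  }
  phase_set(bdf, sdf)
}

test_that("site_scores applies the three per-SNP score cases", {
  b <- pv(1:4 * 10L, c(0L, 1L, 0L, 1L))
  expect_equal(site_scores(b, pv(1:4 * 10L, c(0L, 1L, 0L, 1L))), rep(1, 4))
  expect_equal(site_scores(b, pv(1:4 * 10L, c(1L, 0L, 1L, 0L))), rep(-1, 4))
  h <- pv(1:3 * 10L, c(0L, NA, 1L))
  expect_equal(site_scores(pv(1:3 * 10L, c(0L, 1L, 0L)), h), c(1, 0, -1))
  # k scales the scores
  expect_equal(site_scores(b, pv(1:4 * 10L, c(0L, 1L, 0L, 1L)), k = 3),
               rep(3, 4))
  # no shared SNPs
  expect_length(site_scores(b, pv(99L, 0L)), 0L)
})

test_that("hapscore is the absolute score sum with its bounds", {
  expect_equal(hapscore(c(1, 1, 1, 1)), 4)
  expect_equal(hapscore(c(1, 1, -1, -1)), 0)
  expect_equal(hapscore(c(-1, -1, -1)), 3)
  # bound 0 <= hs <= k*n and flip invariance on random vectors
  set.seed(23)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    ph_b <- sample(c(0L, 1L, NA), n, replace = TRUE)
    ph_h <- sample(c(0L, 1L, NA), n, replace = TRUE)
    b <- pv(seq_len(n) * 5L, ph_b)
    h <- pv(seq_len(n) * 5L, ph_h)
    hs <- hapscore(site_scores(b, h))
    expect_gte(hs, 0)
    expect_lte(hs, n)
    hflip <- pv(seq_len(n) * 5L, 1L - ph_h)
    expect_equal(hapscore(site_scores(b, hflip)), hs)
  }
})

test_that("a Hi-C block chains two WGBS blocks into one merged block", {
  w <- mk_ps(list(pos = c(100L, 200L, 300L), phase = c(0L, 1L, 0L)),
             list(pos = c(5000L, 5100L, 5200L), phase = c(1L, 1L, 0L)),
             source = "WGBS")
  h <- mk_ps(list(pos = c(100L, 200L, 300L, 5000L, 5100L, 5200L),
                  phase = c(0L, 1L, 0L, 1L, 1L, 0L)), source = "HiC")
  m <- merge_blocks(w, h)
  expect_equal(nrow(m$blocks), 1L)
  expect_equal(m$blocks$start, 100L)
  expect_equal(m$blocks$end, 5200L)
  expect_equal(sum(!is.na(m$snps$phase)), 6L)
  # WGBS assignments preserved in the merged block
  expect_equal(m$snps$phase[m$snps$pos == 200L], 1L)
})

test_that("merging is invariant under a global flip of the Hi-C phases", {
  w <- mk_ps(list(pos = c(100L, 200L, 300L), phase = c(0L, 1L, 0L)),
             list(pos = c(5000L, 5100L), phase = c(1L, 0L)),
             source = "WGBS")
  h1 <- mk_ps(list(pos = c(100L, 200L, 5000L, 5100L),
                   phase = c(0L, 1L, 1L, 0L)), source = "HiC")
  h2 <- mk_ps(list(pos = c(100L, 200L, 5000L, 5100L),
                   phase = c(1L, 0L, 0L, 1L)), source = "HiC")
  m1 <- merge_blocks(w, h1)
  m2 <- merge_blocks(w, h2)
  expect_equal(m1$snps$phase, m2$snps$phase)
  expect_equal(m1$blocks$start, m2$blocks$start)
})

test_that("an undecided (hs = 0) overlap never merges", {
  w <- mk_ps(list(pos = c(100L, 200L, 300L, 400L),
                  phase = c(0L, 1L, 0L, 1L)), source = "WGBS")
  h <- mk_ps(list(pos = c(100L, 200L, 300L, 400L),
                  phase = c(0L, 1L, 1L, 0L)), source = "HiC")
  m <- merge_blocks(w, h)
  expect_equal(nrow(m$blocks), 2L)
  expect_setequal(m$blocks$source, c("WGBS", "HiC"))
})

test_that("merge output is independent of input block order", {
  w1 <- mk_ps(list(pos = c(100L, 200L), phase = c(0L, 1L)),
              list(pos = c(5000L, 5100L), phase = c(1L, 0L)),
              source = "WGBS")
  # same blocks, reversed order (ids follow position of definition)
  w2 <- mk_ps(list(pos = c(5000L, 5100L), phase = c(1L, 0L)),
              list(pos = c(100L, 200L), phase = c(0L, 1L)),
              source = "WGBS")
  h <- mk_ps(list(pos = c(100L, 200L, 5000L, 5100L),
                  phase = c(0L, 1L, 1L, 0L)), source = "HiC")
  m1 <- merge_blocks(w1, h)
  m2 <- merge_blocks(w2, h)
  expect_equal(m1$snps[c("chrom", "pos", "phase")],
               m2$snps[c("chrom", "pos", "phase")])
  expect_equal(m1$blocks[c("chrom", "start", "end")],
               m2$blocks[c("chrom", "start", "end")])
})

test_that("orientation parity conflicts abort the component merge", {
  w <- mk_ps(list(pos = c(100L, 200L), phase = c(0L, 1L)),
             list(pos = c(5000L, 5100L), phase = c(1L, 0L)),
             source = "WGBS")
  # H1 links both WGBS blocks consistently; H2 links them with W2 flipped
  h <- mk_ps(list(pos = c(100L, 200L, 5000L, 5100L),
                  phase = c(0L, 1L, 1L, 0L)),
             list(pos = c(100L, 200L, 5000L, 5100L),
                  phase = c(0L, 1L, 0L, 1L)), source = "HiC")
  expect_warning(m <- merge_blocks(w, h), "conflict")
  expect_gt(length(attr(m, "conflicts")), 0L)
  # nothing merged: all four blocks pass through
  expect_equal(nrow(m$blocks), 4L)
  expect_false(any(m$blocks$source == "merged"))
})

test_that("merging never loses phased SNPs or span", {
  w <- mk_ps(list(pos = c(100L, 200L, 300L), phase = c(0L, 1L, 0L)),
             list(pos = c(5000L, 5100L), phase = c(1L, 0L)),
             source = "WGBS")
  h <- mk_ps(list(pos = c(200L, 300L, 5000L, 5100L, 9000L),
                  phase = c(1L, 0L, 1L, 0L, 1L)), source = "HiC")
  m <- merge_blocks(w, h)
  expect_gte(sum(!is.na(m$snps$phase)), sum(!is.na(w$snps$phase)))
  expect_gte(total_block_span(m), total_block_span(w))
  # the Hi-C-only SNP at 9000 is now phased with the WGBS blocks
  expect_equal(nrow(m$blocks), 1L)
  expect_true(9000L %in% m$snps$pos)
})
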