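# Fixture builders and independent oracles shared across test files.

# Build a meth_fragments object from a status matrix: one row per fragment,
# one column per site position; entries "M"/"U" (cytosine), "R"/"V" (SNP)
# or NA (no call at that site).
frags_from_matrix <- function(mat, pos, chrom = "chr1", strand = "+") {
  stopifnot(ncol(mat) == length(pos))
  ids <- sprintf("f%03d", seq_len(nrow(mat)))
  meth <- NULL; snp <- NULL
  for (j in seq_along(pos)) {
    st <- mat[, j]
    keep <- !is.na(st)
    if (!any(keep)) next
    df <- data.frame(fragment_id = ids[keep], chrom = chrom, strand = strand,
                     pos = pos[j], status = st[keep],
                     stringsAsFactors = FALSE)
    if (all(st[keep] %in% c("M", "U"))) {
      df$context <- "CpG"
      meth <- rbind(meth, df[c("fragment_id", "chrom", "strand", "pos",
                               "context", "status")])
    } else {
      snp <- rbind(snp, df)
    }
  }
  if (is.null(meth)) {
    meth <- data.frame(fragment_id = character(), chrom = character(),
                       strand = character(), pos = integer(),
                       context = character(), status = character(),
                       stringsAsFactors = FALSE)
  }
  meth_fragments(
    data.frame(fragment_id = ids, chrom = chrom, strand = strand,
               stringsAsFactors = FALSE),
    meth, snp)
}

# n_mm fragments with pattern c(s_i, s_j) at two sites, stacked
pattern_rows <- function(...) {
  pats <- list(...)
  do.call(rbind, lapply(pats, function(p) {
    matrix(rep(p$pattern, p$n), nrow = p$n, byrow = TRUE)
  }))
}
pat <- function(n, ...) list(n = n, pattern = c(...))

# Exact two-sided Fisher p by integer-weight enumeration (independent of
# the implementation's dhyper route; binomial coefficients are exact
# integers in double precision at these sizes).
oracle_fisher_p <- function(n11, n12, n21, n22) {
  N <- n11 + n12 + n21 + n22
  K <- n11 + n12
  n <- n11 + n21
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  xs <- lo:hi
  w <- choose(K, xs) * choose(N - K, n - xs)
  wobs <- choose(K, n11) * choose(N - K, n - n11)
  sum(w[w <= wobs]) / choose(N, n)
}

# Naive BH step-up, written directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force per-fragment tally of a two-site 2x2 table.
oracle_pair_counts <- function(mat, i, j, lev_i = c("M", "U"),
                               lev_j = c("M", "U")) {
  out <- c(0L, 0L, 0L, 0L)
  for (r in seq_len(nrow(mat))) {
    a <- mat[r, i]; b <- mat[r, j]
    if (is.na(a) || is.na(b)) next
    ai <- match(a, lev_i); bi <- match(b, lev_j)
    k <- (ai - 1L) * 2L + bi
    out[k] <- out[k] + 1L
  }
  out
}

# Minimal SAM writer for handcrafted alignment records.
write_test_sam <- function(path, chrom, chrom_len, records) {
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  for (r in records) {
    tags <- if (!is.null(r$xg)) paste0("\tXG:Z:", r$xg) else ""
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t42\t%s\t*\t0\t0\t%s\t%s%s",
                              r$qname, r$flag, chrom, r$pos, r$cigar, r$seq,
                              strrep("I", nchar(r$seq)), tags))
  }
  writeLines(lines, path)
  path
}

write_test_vcf <- function(path, rows) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
             rows)
  writeLines(lines, path)
  path
}

# A small planted-truth simulation used by several files (noiseless).
small_noiseless_sim <- function(seed = 42) {
  tr <- make_truth(genome_length = 20000, n_asm_regions = 3, n_snps = 12,
                   depth = 10, conv_fail_rate = 0, seq_error_rate = 0,
                   seed = seed)
  d <- tempfile("sim")
  paths <- simulate_bisulfite(tr, d)
  genome <- load_genome(paths$fasta)
  het <- load_het_snps(paths$vcf)
  frags <- extract_fragments(paths$sam, genome, het)
  list(truth = tr, paths = paths, genome = genome, het = het, frags = frags)
}
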