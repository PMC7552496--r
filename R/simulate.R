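#' Plant a diploid truth set with allele-specific methylation regions
#'
#' Generates a random genome with ASM regions (CpGs planted at controlled
#' spacing), background CpGs, heterozygous SNPs with known phase, and
#' per-site per-allele methylation states. All randomness flows from `seed`
#' (stream order: genome, region placement, planted CpGs, per-site states,
#' SNPs), so identical seed + parameters give identical truth.
#'
#' Methylation is modelled at the site level: inside an ASM region each CpG
#' dyad's state on the methylated allele is drawn Bernoulli(`p_hi`) and on
#' the other allele Bernoulli(`p_lo`); reads later copy the state exactly,
#' corrupted only by the conversion-failure and sequencing-error rates. A
#' region dyad whose two alleles happen to share a state is therefore not
#' allele-informative, and the truth tables record the realized states.
#' Outside the regions both alleles share a common state (methylated with
#' probability `bg_meth_prob`), except for a `bg_intermediate_frac` fraction
#' of dyads fluctuating at per-read level `bg_intermediate_level` on both
#' alleles — these pass the effective-site filter and exercise the
#' rejection path.
#'
#' @param genome_length Genome size in bp (default 100000).
#' @param chrom Chromosome name.
#' @param n_asm_regions Number of non-overlapping ASM regions (default 10).
#' @param region_length Region size in bp (default 2000).
#' @param region_gap Minimum gap between regions and to the genome ends, bp
#'   (default 1000; must exceed the read length so no fragment bridges two
#'   regions).
#' @param cpg_spacing Planted CpG spacing inside regions, bp (default 25).
#' @param n_snps Number of heterozygous SNPs (default 50).
#' @param snp_in_region_frac Fraction of SNPs placed inside ASM regions,
#'   distributed round-robin over the regions (default 0.5).
#' @param p_hi,p_lo Per-dyad methylation-state probabilities for the
#'   methylated / unmethylated allele inside regions (defaults 0.95, 0.05).
#' @param bg_meth_prob Background common-state methylation probability
#'   (default 0.7).
#' @param bg_intermediate_frac,bg_intermediate_level Fluctuating background
#'   fraction and its per-read level (defaults 0.1, 0.5).
#' @param depth Read depth per allele per bisulfite strand (default 20).
#' @param read_length Read length, bp (default 100).
#' @param conv_fail_rate Probability an unmethylated C escapes conversion
#'   (default 0.01).
#' @param seq_error_rate Per-base sequencing substitution rate
#'   (default 0.001).
#' @param paired Emit overlapping read pairs instead of single-end reads
#'   (default FALSE; exercises mate deduplication).
#' @param seed Integer RNG seed.
#' @return A `sim_truth` object.
#' @export
make_truth <- function(genome_length = 100000, chrom = "chr1",
                       n_asm_regions = 10, region_length = 2000,
                       region_gap = 1000, cpg_spacing = 25,
                       n_snps = 50, snp_in_region_frac = 0.5,
                       p_hi = 0.95, p_lo = 0.05,
                       bg_meth_prob = 0.7, bg_intermediate_frac = 0.1,
                       bg_intermediate_level = 0.5,
                       depth = 20, read_length = 100,
                       conv_fail_rate = 0.01, seq_error_rate = 0.001,
                       paired = FALSE, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (n_asm_regions < 0) stop("n_asm_regions must be >= 0")
  need <- n_asm_regions * region_length + (n_asm_regions + 1L) * region_gap
  if (need > genome_length) {
    stop("requested ASM regions exceed genome capacity (need ", need,
         " bp, have ", genome_length, ")")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  g <- sample(bases, genome_length, replace = TRUE)

  regions <- NULL
  if (n_asm_regions > 0) {
    slack <- genome_length - need
    offs <- sort(floor(stats::runif(n_asm_regions, 0, slack + 1)))
    starts <- region_gap + 1L +
      (seq_len(n_asm_regions) - 1L) * (region_length + region_gap) +
      as.integer(offs)
    regions <- data.frame(region = seq_len(n_asm_regions),
                          start = starts, end = starts + region_length - 1L,
                          meth_hap = sample(1:2, n_asm_regions,
                                            replace = TRUE))
    for (r in seq_len(n_asm_regions)) {
      q <- regions$start[r]
      while (q <= regions$end[r] - 1L) {
        g[q] <- "C"; g[q + 1L] <- "G"
        q <- q + cpg_spacing + sample(-5:5, 1L)
      }
    }
  }

  cpos <- which(g[-genome_length] == "C" & g[-1L] == "G")
  reg_id <- rep(NA_integer_, length(cpos))
  if (!is.null(regions)) {
    for (r in seq_len(nrow(regions))) {
      reg_id[cpos >= regions$start[r] & cpos <= regions$end[r]] <- r
    }
  }
  lvA <- numeric(length(cpos)); lvB <- numeric(length(cpos))
  inreg <- !is.na(reg_id)
  if (any(inreg)) {
    s_meth <- stats::rbinom(sum(inreg), 1L, p_hi)
    s_other <- stats::rbinom(sum(inreg), 1L, p_lo)
    mh <- regions$meth_hap[reg_id[inreg]]
    lvA[inreg] <- ifelse(mh == 1L, s_meth, s_other)
    lvB[inreg] <- ifelse(mh == 1L, s_other, s_meth)
  }
  if (any(!inreg)) {
    nbg <- sum(!inreg)
    fluct <- stats::runif(nbg) < bg_intermediate_frac
    state <- stats::rbinom(nbg, 1L, bg_meth_prob)
    lv <- ifelse(fluct, bg_intermediate_level, state)
    lvA[!inreg] <- lv
    lvB[!inreg] <- lv
  }
  cpgs <- data.frame(pos = cpos, region = reg_id,
                     level_hap1 = lvA, level_hap2 = lvB)

  # SNP candidates: never inside a CpG dyad, never creating one on either
  # allele (left neighbour not C, right neighbour not G)
  p_all <- 2:(genome_length - 1L)
  cand <- p_all[g[p_all - 1L] != "C" & g[p_all + 1L] != "G"]
  snp_pos <- integer(0)
  if (n_snps > 0) {
    n_in <- round(n_snps * snp_in_region_frac)
    if (is.null(regions)) n_in <- 0L
    if (n_in > 0) {
      rr <- rep(seq_len(nrow(regions)), length.out = n_in)
      for (r in seq_len(nrow(regions))) {
        k <- sum(rr == r)
        if (!k) next
        rc <- cand[cand >= regions$start[r] & cand <= regions$end[r]]
        rc <- setdiff(rc, snp_pos)
        if (length(rc) < k) k <- length(rc)
        snp_pos <- c(snp_pos, sample(rc, k))
      }
    }
    n_out <- n_snps - length(snp_pos)
    oc <- cand
    if (!is.null(regions)) {
      for (r in seq_len(nrow(regions))) {
        oc <- oc[oc < regions$start[r] | oc > regions$end[r]]
      }
    }
    oc <- setdiff(oc, snp_pos)
    snp_pos <- sort(c(snp_pos, sample(oc, min(n_out, length(oc)))))
  }
  snps <- data.frame(pos = snp_pos, ref = g[snp_pos],
                     alt = vapply(snp_pos, function(p) {
                       sample(setdiff(bases, g[p]), 1L)
                     }, character(1)),
                     hap1_allele = stats::rbinom(length(snp_pos), 1L, 0.5),
                     stringsAsFactors = FALSE)

  structure(list(
    genome = paste(g, collapse = ""), chrom = chrom,
    regions = if (is.null(regions))
      data.frame(region = integer(), start = integer(), end = integer(),
                 meth_hap = integer()) else regions,
    cpgs = cpgs, snps = snps,
    params = list(genome_length = genome_length, n_asm_regions = n_asm_regions,
                  region_length = region_length, region_gap = region_gap,
                  cpg_spacing = cpg_spacing, n_snps = n_snps,
                  snp_in_region_frac = snp_in_region_frac,
                  p_hi = p_hi, p_lo = p_lo, bg_meth_prob = bg_meth_prob,
                  bg_intermediate_frac = bg_intermediate_frac,
                  bg_intermediate_level = bg_intermediate_level,
                  depth = depth, read_length = read_length,
                  conv_fail_rate = conv_fail_rate,
                  seq_error_rate = seq_error_rate, paired = paired),
    seed = seed), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nchar(x$genome), "bp,", nrow(x$regions),
      "ASM region(s),", nrow(x$cpgs), "CpG dyad(s),", nrow(x$snps),
      "het SNP(s), seed", x$seed, "\n")
  invisible(x)
}

#' Simulate bisulfite reads from a planted truth set
#'
#' Emits already-aligned, coordinate-sorted single-end (or overlapping
#' paired-end) bisulfite reads as SAM, the reference FASTA, the het-SNP VCF
#' and tab-separated truth tables. Fragment starts tile each strand on a
#' regular lattice and every start yields one fragment per allele, so both
#' alleles are observed at equal depth. Original-top-strand reads (XG:Z:CT,
#' forward FLAG) report C/T at cytosines; original-bottom-strand reads
#' (XG:Z:GA, reverse FLAG) report G/A at the G of each dyad. Unmethylated
#' cytosines convert except with probability `conv_fail_rate`; sequencing
#' substitution errors are applied at `seq_error_rate` per base. The RNG
#' stream is seeded with `truth$seed + 1`.
#'
#' @param truth A `sim_truth` from [make_truth()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "sim").
#' @return List of file paths: `sam`, `fasta`, `vcf`, `truth_regions`,
#'   `truth_cpgs`, `truth_snps`, plus `n_fragments`.
#' @export
simulate_bisulfite <- function(truth, dir, prefix = "sim") {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(truth$seed + 1L)
  p <- truth$params
  rl <- p$read_length
  L <- p$genome_length
  g <- strsplit(truth$genome, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  other <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                 c("A", "C", "T"), c("A", "C", "G"))

  hapchars <- list(g, g)
  if (nrow(truth$snps)) {
    a1 <- ifelse(truth$snps$hap1_allele == 1L, truth$snps$alt, truth$snps$ref)
    a2 <- ifelse(truth$snps$hap1_allele == 1L, truth$snps$ref, truth$snps$alt)
    hapchars[[1L]][truth$snps$pos] <- a1
    hapchars[[2L]][truth$snps$pos] <- a2
  }
  lvl <- list(truth$cpgs$level_hap1, truth$cpgs$level_hap2)

  step <- rl / p$depth
  mk_reads <- function(strand, hap, starts) {
    hc <- hapchars[[hap]]
    if (strand == "+") {
      sitepos <- which(hc == "C")
      mchar <- "C"
    } else {
      sitepos <- which(hc == "G")
      mchar <- "G"
    }
    lv <- numeric(length(sitepos))
    cp <- if (strand == "+") truth$cpgs$pos else truth$cpgs$pos + 1L
    mi <- match(cp, sitepos)
    ok <- !is.na(mi)
    lv[mi[ok]] <- lvl[[hap]][ok]
    tmpl <- hc
    tmpl[sitepos] <- if (strand == "+") "T" else "A"

    n_r <- length(starts)
    idx <- rep(starts, each = rl) + rep.int(0:(rl - 1L), n_r)
    chars <- tmpl[idx]

    # site x read incidence over the lattice
    i2 <- findInterval(sitepos, starts)
    i1 <- findInterval(sitepos - rl, starts) + 1L
    cnt <- pmax(i2 - i1 + 1L, 0L)
    keep <- cnt > 0L
    sidx <- rep(which(keep), cnt[keep])
    ridx <- i1[sidx] + (sequence(cnt[keep]) - 1L)
    m_draw <- stats::rbinom(length(sidx), 1L, lv[sidx]) == 1L
    fail <- !m_draw & stats::runif(length(sidx)) < p$conv_fail_rate
    setM <- m_draw | fail
    if (any(setM)) {
      cell <- (ridx[setM] - 1L) * rl + (sitepos[sidx[setM]] -
                                          starts[ridx[setM]] + 1L)
      chars[cell] <- mchar
    }
    ne <- stats::rbinom(1L, length(chars), p$seq_error_rate)
    if (ne > 0) {
      cells <- sample.int(length(chars), ne)
      pick <- sample.int(3L, ne, replace = TRUE)
      chars[cells] <- other[cbind(match(chars[cells], bases), pick)]
    }
    m <- matrix(chars, nrow = rl)
    list(pos = starts,
         seq = do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE)),
         strand = strand, hap = hap)
  }

  starts_plus <- unique(pmin(as.integer(seq(1, L - rl + 1, by = step)),
                             L - rl + 1L))
  starts_minus <- unique(pmin(as.integer(seq(1 + floor(step / 2),
                                             L - rl + 1, by = step)),
                              L - rl + 1L))
  recs <- list()
  if (!p$paired) {
    for (strand in c("+", "-")) for (hap in 1:2) {
      st <- if (strand == "+") starts_plus else starts_minus
      r <- mk_reads(strand, hap, st)
      recs[[length(recs) + 1L]] <- data.frame(
        pos = r$pos, seq = r$seq, strand = strand, hap = hap,
        flag = if (strand == "+") 0L else 16L,
        mate = 0L, pair_id = NA_integer_, stringsAsFactors = FALSE)
    }
  } else {
    # overlapping mates: mate2 starts half a read downstream of mate1
    shift <- floor(rl / 2)
    for (strand in c("+", "-")) for (hap in 1:2) {
      st1 <- if (strand == "+") starts_plus else starts_minus
      st2 <- pmin(st1 + shift, L - rl + 1L)
      r1 <- mk_reads(strand, hap, st1)
      r2 <- mk_reads(strand, hap, st2)
      f1 <- if (strand == "+") 99L else 83L
      f2 <- if (strand == "+") 147L else 163L
      pid <- seq_along(st1)
      recs[[length(recs) + 1L]] <- data.frame(
        pos = c(r1$pos, r2$pos), seq = c(r1$seq, r2$seq), strand = strand,
        hap = hap, flag = c(rep(f1, length(st1)), rep(f2, length(st2))),
        mate = c(rep(1L, length(st1)), rep(2L, length(st2))),
        pair_id = c(pid, pid), stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, recs)
  if (!p$paired) {
    o <- order(recs$pos, recs$strand, recs$hap)
    recs <- recs[o, , drop = FALSE]
    recs$qname <- sprintf("frag%07d", seq_len(nrow(recs)))
  } else {
    key <- paste(recs$strand, recs$hap, recs$pair_id, sep = ":")
    uk <- unique(key)
    qmap <- stats::setNames(sprintf("frag%07d", seq_along(uk)), uk)
    recs$qname <- unname(qmap[key])
    recs <- recs[order(recs$pos, recs$qname, recs$mate), , drop = FALSE]
  }

  sam_path <- file.path(dir, paste0(prefix, ".sam"))
  qual <- strrep("I", rl)
  xg <- ifelse(recs$strand == "+", "CT", "GA")
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", truth$chrom, L),
    sprintf("%s\t%d\t%s\t%d\t42\t%dM\t%s\t%d\t0\t%s\t%s\tXG:Z:%s",
            recs$qname, recs$flag, truth$chrom, recs$pos, rl,
            ifelse(recs$mate > 0L, "=", "*"),
            ifelse(recs$mate > 0L, recs$pos, 0L),
            recs$seq, qual, xg))
  writeLines(lines, sam_path)

  fa_path <- file.path(dir, paste0(prefix, ".fa"))
  ref <- Biostrings::DNAStringSet(truth$genome)
  names(ref) <- truth$chrom
  Biostrings::writeXStringSet(ref, fa_path, width = 70L)

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  vl <- c("##fileformat=VCFv4.2",
          sprintf("##contig=<ID=%s,length=%d>", truth$chrom, L),
          "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
          "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample1")
  if (nrow(truth$snps)) {
    vl <- c(vl, sprintf("%s\t%d\tsnp%d\t%s\t%s\t.\tPASS\t.\tGT\t0/1",
                        truth$chrom, truth$snps$pos,
                        seq_len(nrow(truth$snps)),
                        truth$snps$ref, truth$snps$alt))
  }
  writeLines(vl, vcf_path)

  tr_paths <- list(
    truth_regions = file.path(dir, paste0(prefix, ".truth_regions.tsv")),
    truth_cpgs = file.path(dir, paste0(prefix, ".truth_cpgs.tsv")),
    truth_snps = file.path(dir, paste0(prefix, ".truth_snps.tsv")))
  utils::write.table(truth$regions, tr_paths$truth_regions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$cpgs, tr_paths$truth_cpgs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$snps, tr_paths$truth_snps, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  c(list(sam = sam_path, fasta = fa_path, vcf = vcf_path,
         n_fragments = length(unique(recs$qname))), tr_paths)
}

#' Simulate Hi-C-derived phased haplotype blocks
#'
#' Draws long-range within-allele SNP-pair observations, groups linked SNPs
#' into blocks (connected components), and emits each block's phase vector:
#' the planted truth up to a random global flip per block, with a per-SNP
#' error rate (phase flipped) and missing rate (phase dropped). RNG stream
#' seeded with `truth$seed + 2`.
#'
#' @param truth A `sim_truth`.
#' @param n_pairs Number of SNP-pair observations to draw (default 300).
#' @param error_rate Per-SNP phase-flip probability (default 0.02).
#' @param missing_rate Per-SNP missing probability (default 0.05).
#' @param max_span Maximum genomic distance of a drawn pair, bp
#'   (default 50000).
#' @param path Optional path; when given, the blocks are also written with
#'   [write_phased_blocks()].
#' @return A `phase_set` with source `"HiC"`.
#' @export
simulate_hic <- function(truth, n_pairs = 300, error_rate = 0.02,
                         missing_rate = 0.05, max_span = 50000,
                         path = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed + 2L)
  sn <- truth$snps
  n <- nrow(sn)
  empty <- phase_set(
    data.frame(block_id = character(), chrom = character(),
               start = integer(), end = integer(), source = character(),
               stringsAsFactors = FALSE),
    data.frame(block_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), phase = integer(),
               source = character(), stringsAsFactors = FALSE))
  if (n < 2L || n_pairs < 1L) return(empty)
  eligible <- which(outer(sn$pos, sn$pos, function(a, b) abs(a - b)) <=
                      max_span & upper.tri(diag(n)), arr.ind = TRUE)
  if (!nrow(eligible)) return(empty)
  draw <- eligible[sample.int(nrow(eligible), n_pairs, replace = TRUE), ,
                   drop = FALSE]
  # connected components via union-find
  parent <- seq_len(n)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(draw))) {
    a <- findr(draw[r, 1L]); b <- findr(draw[r, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), findr, integer(1))
  blocks <- list(); snps <- list(); bi <- 0L
  for (rt in sort(unique(root))) {
    members <- which(root == rt)
    if (length(members) < 2L) next
    bi <- bi + 1L
    bid <- sprintf("hic_%d", bi)
    ph <- sn$hap1_allele[members]
    if (stats::runif(1L) < 0.5) ph <- 1L - ph
    flip <- stats::runif(length(members)) < error_rate
    ph[flip] <- 1L - ph[flip]
    miss <- stats::runif(length(members)) < missing_rate
    ph[miss] <- NA_integer_
    snps[[bi]] <- data.frame(
      block_id = bid, chrom = truth$chrom, pos = sn$pos[members],
      ref = sn$ref[members], alt = sn$alt[members], phase = ph,
      source = "HiC", stringsAsFactors = FALSE)
    blocks[[bi]] <- data.frame(
      block_id = bid, chrom = truth$chrom, start = min(sn$pos[members]),
      end = max(sn$pos[members]), source = "HiC", stringsAsFactors = FALSE)
  }
  if (!bi) return(empty)
  ps <- phase_set(do.call(rbind, blocks), do.call(rbind, snps))
  if (!is.null(path)) write_phased_blocks(ps, path)
  ps
}
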