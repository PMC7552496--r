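#' Load a reference genome into an indexed, in-memory container
#'
#' Reads a (multi-)FASTA file, uppercases every sequence and returns a
#' `genome_index` object mapping chromosome name to sequence. Only the first
#' whitespace-delimited token of each FASTA header is used as the name, as in
#' SAM/VCF practice.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `genome_index`: list with `sequences` (named character vector of
#'   uppercase sequences) and `lengths` (named integer vector, bp).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTacgt"), fa)
#' g <- load_genome(fa)
#' g$lengths
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("FASTA file contains no sequences: ", fasta_path)
  }
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  names(sq) <- nm
  bad <- grepl("[^ACGTN]", sq)
  if (any(bad)) {
    stop("sequence alphabet outside {A,C,G,T,N} in: ",
         paste(nm[bad], collapse = ", "))
  }
  structure(
    list(sequences = sq,
         lengths = stats::setNames(nchar(sq), nm)),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$sequences), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Load heterozygous biallelic SNVs from a VCF
#'
#' Retains only biallelic single-nucleotide records whose genotype (first
#' sample, GT field) is heterozygous (0/1, 1/0, 0|1 or 1|0). These are the
#' only variants that carry phase information for haplotype assembly.
#'
#' @param vcf_path Path to a VCF 4.x file with at least one sample and a GT
#'   FORMAT field.
#' @return A `het_snps` data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `id`, sorted by (chrom, pos).
#' @export
load_het_snps <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_het_snps())
  }
  if (ncol(v@gt) < 2L) stop("VCF has no sample genotype (GT) column")
  gt_raw <- v@gt[, 2L]
  fmt <- strsplit(v@gt[, 1L], ":", fixed = TRUE)
  gt <- mapply(function(f, g) {
    i <- match("GT", f)
    if (is.na(i)) NA_character_ else strsplit(g, ":", fixed = TRUE)[[1L]][i]
  }, fmt, gt_raw, USE.NAMES = FALSE)
  if (all(is.na(gt))) stop("VCF records carry no GT field")
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  snv <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T") &
    fix$REF != fix$ALT
  keep <- het & snv & !is.na(gt)
  out <- data.frame(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                NA_character_, fix$ID[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("het_snps", "data.frame")
  out
}

empty_het_snps <- function() {
  out <- data.frame(chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    id = character(), stringsAsFactors = FALSE)
  class(out) <- c("het_snps", "data.frame")
  out
}

#' Write an ASMR (allele-specific methylated region) table
#'
#' One tab-separated line per block with the five columns
#' `chromosome start end LengthofBlock NumberofCytosines`. `start`/`end` are
#' the 1-based inclusive coordinates of the first and last member cytosine,
#' `LengthofBlock = end - start + 1` and `NumberofCytosines` the count of
#' member cytosine sites. Blocks with fewer than two member cytosines are not
#' representable in this format and are skipped.
#'
#' @param blocks An `asm_result` (see [call_asm_blocks()]) or a list of
#'   blocks as stored in `asm_result$blocks`.
#' @param out_path Output file path.
#' @return Invisibly, the number of lines written.
#' @export
write_asmr <- function(blocks, out_path) {
  if (inherits(blocks, "asm_result")) blocks <- blocks$blocks
  lines <- character(0)
  for (b in blocks) {
    cyt <- b$sites$pos[b$sites$type == "C"]
    if (length(cyt) < 2L) next
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d\t%d",
                              b$chrom, min(cyt), max(cyt),
                              max(cyt) - min(cyt) + 1L, length(cyt)))
  }
  con <- file(out_path, "w")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(length(lines))
}

#' Write phased blocks in a HapCUT2-style block file
#'
#' Each block with at least one SNP entry gets a `BLOCK:` header followed by
#' one line per SNP (`index hap0 hap1 chrom pos ref alt`, tab-separated) and
#' a `********` terminator. A missing phase is written as `-`. Blocks with no
#' SNP entries are omitted (there is nothing to phase). The file round-trips
#' through [read_phased_blocks()].
#'
#' @param ps A `phase_set` (see [as_phase_set()]) or an `asm_result`.
#' @param out_path Output file path.
#' @return Invisibly, the number of blocks written.
#' @export
write_phased_blocks <- function(ps, out_path) {
  if (inherits(ps, "asm_result")) ps <- as_phase_set(ps)
  stopifnot(inherits(ps, "phase_set"))
  con <- file(out_path, "w")
  on.exit(close(con))
  idx <- 0L
  nblk <- 0L
  for (bid in ps$blocks$block_id) {
    sn <- ps$snps[ps$snps$block_id == bid, , drop = FALSE]
    if (nrow(sn) == 0L) next
    sn <- sn[order(sn$pos), , drop = FALSE]
    nblk <- nblk + 1L
    writeLines(sprintf("BLOCK: offset: %d len: %d phased: %d",
                       idx + 1L, nrow(sn), sum(!is.na(sn$phase))), con)
    for (i in seq_len(nrow(sn))) {
      idx <- idx + 1L
      h0 <- if (is.na(sn$phase[i])) "-" else as.character(sn$phase[i])
      h1 <- if (is.na(sn$phase[i])) "-" else as.character(1L - sn$phase[i])
      writeLines(sprintf("%d\t%s\t%s\t%s\t%d\t%s\t%s",
                         idx, h0, h1, sn$chrom[i], sn$pos[i],
                         sn$ref[i], sn$alt[i]), con)
    }
    writeLines("********", con)
  }
  invisible(nblk)
}

#' Read a HapCUT2-style phased block file
#'
#' Parses `BLOCK:` sections into a `phase_set`. Column layout per SNP line is
#' `index hap0 hap1 chrom pos ref alt [...]`; extra trailing columns (as
#' written by HapCUT2 itself) are ignored. `-` entries are kept as missing.
#'
#' @param path Path to the block file.
#' @param source Label for the evidence source of these phases
#'   (default `"HiC"`).
#' @return A `phase_set`.
#' @export
read_phased_blocks <- function(path, source = "HiC") {
  if (!file.exists(path)) stop("block file not found: ", path)
  lines <- readLines(path)
  blocks <- list()
  snps <- list()
  cur <- NULL
  bi <- 0L
  for (ln in lines) {
    if (ln == "" ) next
    if (startsWith(ln, "BLOCK:")) {
      bi <- bi + 1L
      cur <- sprintf("%s_%d", tolower(source), bi)
      next
    }
    if (startsWith(ln, "****")) { cur <- NULL; next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 7L) stop("malformed block file line: ", ln)
    if (is.null(cur)) stop("SNP line outside a BLOCK section: ", ln)
    phase <- if (f[2L] %in% c("0", "1")) as.integer(f[2L]) else NA_integer_
    snps[[length(snps) + 1L]] <- data.frame(
      block_id = cur, chrom = f[4L], pos = as.integer(f[5L]),
      ref = f[6L], alt = f[7L], phase = phase, source = source,
      stringsAsFactors = FALSE)
  }
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(block_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), phase = integer(),
               source = character(), stringsAsFactors = FALSE)
  bdf <- if (nrow(snps)) {
    agg <- do.call(rbind, lapply(split(snps, snps$block_id), function(s) {
      data.frame(block_id = s$block_id[1L], chrom = s$chrom[1L],
                 start = min(s$pos), end = max(s$pos), source = source,
                 stringsAsFactors = FALSE)
    }))
    agg[order(agg$chrom, agg$start), , drop = FALSE]
  } else {
    data.frame(block_id = character(), chrom = character(), start = integer(),
               end = integer(), source = character(), stringsAsFactors = FALSE)
  }
  rownames(bdf) <- NULL
  rownames(snps) <- NULL
  phase_set(bdf, snps)
}

#' Construct a phase set (blocks plus per-SNP phase assignments)
#'
#' @param blocks data.frame with columns `block_id`, `chrom`, `start`, `end`,
#'   `source`.
#' @param snps data.frame with columns `block_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `phase` (0/1/NA; 0 = ref allele on haplotype A), `source`.
#' @return A `phase_set` object.
#' @export
phase_set <- function(blocks, snps) {
  structure(list(blocks = blocks, snps = snps), class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat("phase_set:", nrow(x$blocks), "block(s),",
      sum(!is.na(x$snps$phase)), "phased SNP(s) of", nrow(x$snps), "\n")
  invisible(x)
}
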