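#' Construct a meth_fragments container
#'
#' Holds per-fragment methylation calls (M/U at cytosine sites) and allele
#' calls (R/V at heterozygous SNP sites). A physical read pair contributes
#' exactly one fragment.
#'
#' @param fragments data.frame with columns `fragment_id`, `chrom`, `strand`
#'   (bisulfite strand of origin, "+" or "-").
#' @param meth data.frame with columns `fragment_id`, `chrom`, `strand`,
#'   `pos` (1-based), `context` ("CpG"/"CHG"/"CHH"), `status` ("M"/"U").
#' @param snp data.frame with columns `fragment_id`, `chrom`, `strand`,
#'   `pos`, `status` ("R" = reference allele, "V" = alternate allele).
#' @return A `meth_fragments` object.
#' @export
meth_fragments <- function(fragments, meth, snp = NULL) {
  if (is.null(snp)) {
    snp <- data.frame(fragment_id = character(), chrom = character(),
                      strand = character(), pos = integer(),
                      status = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("fragment_id", "chrom", "strand") %in% names(fragments)),
            all(c("fragment_id", "pos", "status") %in% names(meth)))
  if (nrow(meth) && anyDuplicated(meth[c("fragment_id", "pos")])) {
    stop("duplicate methylation-call positions within a fragment")
  }
  if (nrow(snp) && anyDuplicated(snp[c("fragment_id", "pos")])) {
    stop("duplicate SNP-call positions within a fragment")
  }
  structure(list(fragments = fragments, meth = meth, snp = snp),
            class = "meth_fragments")
}

#' @export
print.meth_fragments <- function(x, ...) {
  cat("meth_fragments:", nrow(x$fragments), "fragment(s),",
      nrow(x$meth), "methylation call(s),", nrow(x$snp), "SNP call(s)\n")
  invisible(x)
}

# Convert SAM to a (sorted) BAM in tempdir when needed.
ensure_bam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

# Reference/query coordinate map for one CIGAR string.
# Returns matrix with columns rpos (reference, 1-based) and qpos (query).
cigar_map <- function(cigar, pos) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  r <- pos; q <- 1L
  rp <- integer(0); qp <- integer(0)
  for (i in seq_along(ops)) {
    L <- lens[i]
    switch(ops[i],
      "M" = , "=" = , "X" = {
        rp <- c(rp, r:(r + L - 1L)); qp <- c(qp, q:(q + L - 1L))
        r <- r + L; q <- q + L
      },
      "I" = , "S" = { q <- q + L },
      "D" = , "N" = { r <- r + L },
      "H" = , "P" = { }
    )
  }
  cbind(rpos = rp, qpos = qp)
}

#' Extract per-fragment methylation and SNP calls from bisulfite alignments
#'
#' Walks coordinate-sorted bisulfite alignments (SAM or BAM; only mapped,
#' primary, non-duplicate, non-supplementary records are used) and emits one
#' [meth_fragments()] record per physical fragment.
#'
#' Calls follow bisulfite chemistry. On an original-top-strand ("+") fragment,
#' every reference C whose context passes `context_filter` yields `M` when the
#' read base is C (unconverted, methylated) and `U` when it is T (converted,
#' unmethylated); any other base yields no call. On an original-bottom-strand
#' ("-") fragment the cytosine sits on the minus strand, so reference G
#' positions are inspected: read G is `M`, read A is `U`.
#'
#' At a covered heterozygous SNP the read base equal to the reference allele
#' yields `R` and equal to the alternate yields `V`. Allele pairs confounded
#' by conversion are suppressed entirely rather than guessed: ref/alt {C,T}
#' on "+" fragments and {G,A} on "-" fragments (a read T/A there is ambiguous
#' between the alternate allele and a converted reference base).
#'
#' Bisulfite strand is taken from the aligner's `XG` tag when present
#' (Bismark convention, `CT` = original top, `GA` = original bottom);
#' otherwise it is inferred for a directional library from FLAG orientation:
#' a single-end or first-in-pair read mapping forward is "+", reverse is "-",
#' and a second-in-pair read is the opposite of its own orientation.
#'
#' Overlapping mate positions are counted once; the first-in-pair call wins
#' on conflict.
#'
#' @param alignments Path to a coordinate-sorted SAM or BAM file.
#' @param genome A `genome_index` from [load_genome()].
#' @param het_snps Optional `het_snps` data.frame from [load_het_snps()].
#' @param context_filter Cytosine context(s) to call: "CpG" (default),
#'   "CHG", "CHH" or "all".
#' @return A `meth_fragments` object.
#' @export
extract_fragments <- function(alignments, genome, het_snps = NULL,
                              context_filter = c("CpG", "CHG", "CHH", "all")) {
  context_filter <- match.arg(context_filter)
  bam <- ensure_bam(alignments)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "XG")
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  flag <- res$flag
  keep <- !is.na(res$pos) &
    bitwAnd(flag, 0x4) == 0L &    # mapped
    bitwAnd(flag, 0x100) == 0L &  # primary
    bitwAnd(flag, 0x400) == 0L &  # not duplicate
    bitwAnd(flag, 0x800) == 0L    # not supplementary
  if (!any(keep)) {
    return(meth_fragments(
      data.frame(fragment_id = character(), chrom = character(),
                 strand = character(), stringsAsFactors = FALSE),
      data.frame(fragment_id = character(), chrom = character(),
                 strand = character(), pos = integer(), context = character(),
                 status = character(), stringsAsFactors = FALSE)))
  }
  qname <- res$qname[keep]
  flag <- flag[keep]
  rname <- as.character(res$rname)[keep]
  pos <- res$pos[keep]
  cigar <- res$cigar[keep]
  seqs <- as.character(res$seq[keep])
  xg <- res$tag$XG
  xg <- if (is.null(xg)) rep(NA_character_, length(flag)) else xg[keep]

  missing_chrom <- setdiff(unique(rname), names(genome$sequences))
  if (length(missing_chrom)) {
    stop("alignment references chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  }
  unsorted <- vapply(split(pos, rname), is.unsorted, logical(1))
  if (any(unsorted)) {
    stop("alignments are not coordinate-sorted (chromosome(s): ",
         paste(names(unsorted)[unsorted], collapse = ", "), ")")
  }

  # bisulfite strand of origin
  revd <- bitwAnd(flag, 0x10) > 0L
  second <- bitwAnd(flag, 0x80) > 0L
  bs <- ifelse(!is.na(xg) & xg %in% c("CT", "GA"),
               ifelse(xg == "CT", "+", "-"),
               ifelse(xor(revd, second), "-", "+"))

  # fragment table: one row per qname; chrom/strand from the first mate
  ord <- order(second, method = "radix")
  first_idx <- ord[!duplicated(qname[ord])]
  frag <- data.frame(fragment_id = qname[first_idx],
                     chrom = rname[first_idx],
                     strand = bs[first_idx],
                     stringsAsFactors = FALSE)
  # expand alignments into (record, refpos, querypos) rows
  qlen <- nchar(seqs)
  simple <- grepl("^[0-9]+M$", cigar)
  ridx <- rep(which(simple), qlen[simple])
  off <- sequence(qlen[simple]) - 1L
  rpos <- pos[ridx] + off
  qpos <- off + 1L
  if (any(!simple)) {
    for (i in which(!simple)) {
      m <- cigar_map(cigar[i], pos[i])
      ridx <- c(ridx, rep(i, nrow(m)))
      rpos <- c(rpos, m[, "rpos"])
      qpos <- c(qpos, m[, "qpos"])
    }
  }
  allchars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  cumoff <- cumsum(qlen) - qlen
  bases4 <- c("A", "C", "G", "T")
  basecode <- match(allchars, bases4)[cumoff[ridx] + qpos]  # NA for N etc.
  chroms <- names(genome$sequences)
  chrom_idx <- match(rname, chroms)
  row_chrom <- chrom_idx[ridx]
  plusrow <- bs == "+"
  row_plus <- plusrow[ridx]

  meth_rows <- list(); snp_rows <- list()
  for (ck in unique(row_chrom)) {
    ch <- chroms[ck]
    g <- strsplit(genome$sequences[[ch]], "", fixed = TRUE)[[1L]]
    gl <- length(g)
    gcode <- match(g, bases4)                  # NA for N
    pad <- c(NA_integer_, NA_integer_, gcode, NA_integer_, NA_integer_)
    # per-position context, computed once per chromosome
    ctx_plus <- ifelse(pad[seq_len(gl) + 3L] == 3L, "CpG",
                       ifelse(pad[seq_len(gl) + 4L] == 3L, "CHG", "CHH"))
    ctx_plus[is.na(ctx_plus)] <- "CHH"
    ctx_minus <- ifelse(pad[seq_len(gl) + 1L] == 2L, "CpG",
                        ifelse(pad[seq_len(gl)] == 2L, "CHG", "CHH"))
    ctx_minus[is.na(ctx_minus)] <- "CHH"
    sel <- which(row_chrom == ck & rpos >= 1L & rpos <= gl)
    if (!length(sel)) next
    rp <- rpos[sel]; bse <- basecode[sel]; rd <- ridx[sel]
    isp <- row_plus[sel]
    refb <- gcode[rp]

    # --- methylation calls (base codes: A=1, C=2, G=3, T=4) ---
    isplus <- isp & !is.na(refb) & refb == 2L
    isminus <- !isp & !is.na(refb) & refb == 3L
    ctx <- rep(NA_character_, length(sel))
    ip <- which(isplus); im <- which(isminus)
    ctx[ip] <- ctx_plus[rp[ip]]
    ctx[im] <- ctx_minus[rp[im]]
    status <- rep(NA_character_, length(sel))
    status[ip][bse[ip] == 2L] <- "M"
    status[ip][bse[ip] == 4L] <- "U"
    status[im][bse[im] == 3L] <- "M"
    status[im][bse[im] == 1L] <- "U"
    okctx <- if (context_filter == "all") !is.na(ctx) else
      !is.na(ctx) & ctx == context_filter
    mk <- which(okctx & !is.na(status))
    bss <- ifelse(isp, "+", "-")
    qn <- qname[rd]; sec <- second[rd]
    if (length(mk)) {
      meth_rows[[length(meth_rows) + 1L]] <- data.frame(
        fragment_id = qn[mk], chrom = ch, strand = bss[mk], pos = rp[mk],
        context = ctx[mk], status = status[mk], second = sec[mk],
        stringsAsFactors = FALSE)
    }

    # --- SNP allele calls ---
    if (!is.null(het_snps) && nrow(het_snps)) {
      sn <- het_snps[het_snps$chrom == ch, , drop = FALSE]
      if (nrow(sn)) {
        refc <- match(sn$ref, bases4)
        altc <- match(sn$alt, bases4)
        j <- match(rp, sn$pos)
        hit <- which(!is.na(j))
        if (length(hit)) {
          jj <- j[hit]
          st <- ifelse(!is.na(bse[hit]) & bse[hit] == refc[jj], "R",
                       ifelse(!is.na(bse[hit]) & bse[hit] == altc[jj], "V",
                              NA_character_))
          pair <- paste0(pmin(sn$ref[jj], sn$alt[jj]),
                         pmax(sn$ref[jj], sn$alt[jj]))
          confounded <- (pair == "CT" & bss[hit] == "+") |
                        (pair == "AG" & bss[hit] == "-")
          sk <- which(!is.na(st) & !confounded)
          if (length(sk)) {
            snp_rows[[length(snp_rows) + 1L]] <- data.frame(
              fragment_id = qn[hit][sk], chrom = ch, strand = bss[hit][sk],
              pos = rp[hit][sk], status = st[sk], second = sec[hit][sk],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  dedup <- function(df) {
    if (!nrow(df)) return(df[, setdiff(names(df), "second"), drop = FALSE])
    # first-in-pair wins on mate overlap; drop calls whose strand conflicts
    # with the fragment's assigned strand
    fs <- frag$strand[match(df$fragment_id, frag$fragment_id)]
    df <- df[df$strand == fs, , drop = FALSE]
    o <- order(df$fragment_id, df$pos, df$second, method = "radix")
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(df[c("fragment_id", "pos")]), , drop = FALSE]
    df$second <- NULL
    rownames(df) <- NULL
    df
  }
  meth <- dedup(if (length(meth_rows)) do.call(rbind, meth_rows) else
    data.frame(fragment_id = character(), chrom = character(),
               strand = character(), pos = integer(), context = character(),
               status = character(), second = logical(),
               stringsAsFactors = FALSE))
  snp <- dedup(if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(fragment_id = character(), chrom = character(),
               strand = character(), pos = integer(), status = character(),
               second = logical(), stringsAsFactors = FALSE))
  meth_fragments(frag, meth, snp)
}
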