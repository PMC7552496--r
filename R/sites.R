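#' Tally per-cytosine methylation counts from fragments
#'
#' Aggregates fragment-level M/U calls into per-site counts and methylation
#' levels, separately per chromosome and bisulfite strand.
#'
#' @param fragments A `meth_fragments` object.
#' @param chrom,strand Optional filters; by default all groups are
#'   summarized together (the grouping columns are kept in the output).
#' @return data.frame with columns `chrom`, `strand`, `pos`, `context`,
#'   `n_meth`, `n_unmeth`, `level`, sorted by (chrom, strand, pos). Positions
#'   never covered are absent.
#' @export
summarize_sites <- function(fragments, chrom = NULL, strand = NULL) {
  m <- fragments$meth
  if (!is.null(chrom)) m <- m[m$chrom %in% chrom, , drop = FALSE]
  if (!is.null(strand)) m <- m[m$strand %in% strand, , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), context = character(),
                      n_meth = integer(), n_unmeth = integer(),
                      level = numeric(), stringsAsFactors = FALSE))
  }
  groups <- unique(m[c("chrom", "strand")])
  groups <- groups[order(groups$chrom, groups$strand), , drop = FALSE]
  out <- NULL
  for (gi in seq_len(nrow(groups))) {
    sub <- m[m$chrom == groups$chrom[gi] & m$strand == groups$strand[gi], ,
             drop = FALSE]
    isM <- as.integer(sub$status == "M")
    nm <- rowsum(isM, sub$pos)
    nu <- rowsum(1L - isM, sub$pos)
    posu <- as.integer(rownames(nm))
    df <- data.frame(
      chrom = groups$chrom[gi], strand = groups$strand[gi], pos = posu,
      context = sub$context[match(posu, sub$pos)],
      n_meth = as.integer(nm[, 1L]), n_unmeth = as.integer(nu[, 1L]),
      stringsAsFactors = FALSE)
    out <- rbind(out, df)
  }
  out$level <- out$n_meth / (out$n_meth + out$n_unmeth)
  rownames(out) <- NULL
  out
}

#' Retain effective (partially methylated, covered) cytosine sites
#'
#' Totally methylated (level above `high`) and totally unmethylated (level
#' below `low`) sites carry no allele-discriminating signal and are removed;
#' only partially methylated sites with at least `min_cov` covering reads —
#' the effective sites — are kept for pairing.
#'
#' @param sites data.frame from [summarize_sites()].
#' @param low,high Methylation-level cutoffs (defaults 0.1 and 0.9); a site
#'   is retained when `low <= level <= high`.
#' @param min_cov Minimum read coverage (default 4).
#' @return The filtered data.frame.
#' @export
select_effective_sites <- function(sites, low = 0.1, high = 0.9, min_cov = 4) {
  if (low >= high) stop("configuration error: low (", low,
                        ") must be < high (", high, ")")
  if (min_cov < 1) stop("configuration error: min_cov must be >= 1")
  cov <- sites$n_meth + sites$n_unmeth
  keep <- cov >= min_cov & sites$level >= low & sites$level <= high
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
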