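#' Per-SNP consistency scores between two phase vectors
#'
#' For every SNP shared by the WGBS-derived vector `b` and the Hi-C-derived
#' vector `h`, the score is `+k` when the phases agree, `-k` when they are
#' opposite (one haplotype labelling is the flip of the other), and `0` when
#' either phase is missing.
#'
#' @param b,h Phase vectors: data.frames with `chrom`, `pos`, `phase`
#'   (0/1/NA) columns.
#' @param k Positive integer weight (default 1).
#' @return Numeric vector of scores over the shared SNPs in position order;
#'   empty when no SNP is shared.
#' @export
site_scores <- function(b, h, k = 1) {
  if (k < 1) stop("k must be >= 1")
  sh <- merge(b[c("chrom", "pos", "phase")], h[c("chrom", "pos", "phase")],
              by = c("chrom", "pos"), suffixes = c("_b", "_h"))
  sh <- sh[order(sh$chrom, sh$pos), , drop = FALSE]
  if (!nrow(sh)) return(numeric(0))
  ifelse(is.na(sh$phase_b) | is.na(sh$phase_h), 0,
         ifelse(sh$phase_b == sh$phase_h, k, -k))
}

#' HapScore: consistency of two phase vectors over their shared SNPs
#'
#' The absolute value of the summed per-SNP scores. It is invariant under a
#' global flip of either vector and ranges from 0 (no net consistency) to
#' `k * n` (all shared, non-missing SNPs agree under one orientation).
#'
#' @param scores Numeric vector from [site_scores()].
#' @return Non-negative number.
#' @export
hapscore <- function(scores) {
  abs(sum(scores))
}

#' Merge WGBS-phased blocks with Hi-C-phased blocks
#'
#' Every WGBS/Hi-C block pair sharing at least `min_shared` SNPs is scored
#' with [hapscore()]; when `hs > min_score_frac * k * n_shared` (and the sign
#' of the score sum decides an orientation) the pair is linked, the Hi-C
#' phases flipped into the WGBS orientation if needed. Links are closed
#' transitively — one Hi-C block can chain several WGBS blocks into a single
#' merged block — via union-find with orientation parity. A parity conflict
#' (a block that must both flip and not flip along two link paths) aborts the
#' merge of that whole component: its blocks pass through unchanged and a
#' warning record is attached. On a SNP phased by both sources, the WGBS
#' (read-local) assignment wins. Unlinked blocks pass through unchanged.
#' Output is deterministic and independent of input block order.
#'
#' @param wgbs,hic `phase_set` objects (e.g. [as_phase_set()] of an
#'   `asm_result`, and [read_phased_blocks()] output).
#' @param k Score weight (default 1; cancels in the threshold).
#' @param min_score_frac Fraction of the maximum attainable score required
#'   to merge (default 0.9).
#' @param min_shared Minimum number of shared SNPs (default 2).
#' @return A `phase_set` of merged plus passed-through blocks; attribute
#'   `"conflicts"` holds a character vector of conflicted component
#'   descriptions (empty when none).
#' @export
merge_blocks <- function(wgbs, hic, k = 1, min_score_frac = 0.9,
                         min_shared = 2) {
  stopifnot(inherits(wgbs, "phase_set"), inherits(hic, "phase_set"))
  if (min_shared < 1) stop("min_shared must be >= 1")
  wb <- wgbs$blocks[order(wgbs$blocks$chrom, wgbs$blocks$start,
                          wgbs$blocks$block_id), , drop = FALSE]
  hb <- hic$blocks[order(hic$blocks$chrom, hic$blocks$start,
                         hic$blocks$block_id), , drop = FALSE]
  nodes <- c(paste0("W:", wb$block_id), paste0("H:", hb$block_id))
  src_snps <- function(set, bid) {
    s <- set$snps[set$snps$block_id == bid, , drop = FALSE]
    s[order(s$chrom, s$pos), , drop = FALSE]
  }

  # union-find with orientation parity relative to parent
  parent <- seq_along(nodes)
  parity <- integer(length(nodes))
  conflict <- logical(length(nodes))
  find <- function(i) {
    p <- 0L
    while (parent[i] != i) {
      p <- bitwXor(p, parity[i])
      i <- parent[i]
    }
    c(i, p)
  }
  link <- function(i, j, flip) {
    fi <- find(i); fj <- find(j)
    if (fi[1L] == fj[1L]) {
      if (bitwXor(fi[2L], fj[2L]) != flip) {
        conflict[fi[1L]] <<- TRUE
      }
      return(invisible(NULL))
    }
    # attach root of j under root of i
    parent[fj[1L]] <<- fi[1L]
    parity[fj[1L]] <<- bitwXor(bitwXor(fi[2L], fj[2L]), flip)
    if (conflict[fj[1L]]) conflict[fi[1L]] <<- TRUE
    invisible(NULL)
  }

  for (wi in seq_len(nrow(wb))) {
    bsn <- src_snps(wgbs, wb$block_id[wi])
    if (!nrow(bsn)) next
    for (hi in seq_len(nrow(hb))) {
      hsn <- src_snps(hic, hb$block_id[hi])
      if (!nrow(hsn)) next
      sc <- site_scores(bsn, hsn, k = k)
      n_shared <- length(sc)
      if (n_shared < min_shared) next
      hs <- hapscore(sc)
      if (hs <= min_score_frac * k * n_shared) next
      ssum <- sum(sc)
      if (ssum == 0) next  # undecided orientation
      link(wi, nrow(wb) + hi, as.integer(ssum < 0))
    }
  }

  roots <- vapply(seq_along(nodes), function(i) find(i)[1L], integer(1))
  pars <- vapply(seq_along(nodes), function(i) find(i)[2L], integer(1))
  comp <- split(seq_along(nodes), roots)

  out_blocks <- list(); out_snps <- list(); warns <- character(0)
  mi <- 0L
  flip_phase <- function(p) ifelse(is.na(p), NA_integer_, 1L - p)
  emit_single <- function(i) {
    if (i <= nrow(wb)) {
      b <- wb[i, , drop = FALSE]
      out_blocks[[length(out_blocks) + 1L]] <<- b
      out_snps[[length(out_snps) + 1L]] <<- src_snps(wgbs, b$block_id)
    } else {
      b <- hb[i - nrow(wb), , drop = FALSE]
      out_blocks[[length(out_blocks) + 1L]] <<- b
      out_snps[[length(out_snps) + 1L]] <<- src_snps(hic, b$block_id)
    }
  }

  # deterministic component order: by (chrom, start) of first member block
  comp_key <- vapply(comp, function(members) {
    starts <- vapply(members, function(i) {
      if (i <= nrow(wb)) wb$start[i] else hb$start[i - nrow(wb)]
    }, numeric(1))
    chs <- vapply(members, function(i) {
      if (i <= nrow(wb)) wb$chrom[i] else hb$chrom[i - nrow(wb)]
    }, character(1))
    sprintf("%s:%012.0f", min(chs), min(starts))
  }, character(1))
  comp <- comp[order(comp_key)]

  for (members in comp) {
    if (length(members) == 1L) { emit_single(members); next }
    if (any(conflict[members])) {
      ids <- nodes[members]
      warns <- c(warns, paste0("orientation conflict; not merged: ",
                               paste(ids, collapse = ", ")))
      for (i in sort(members)) emit_single(i)
      next
    }
    # orientation anchor: first WGBS member (lowest start), else first member
    wmem <- members[members <= nrow(wb)]
    anchor <- if (length(wmem)) {
      wmem[order(wb$start[wmem])][1L]
    } else members[1L]
    anchor_par <- pars[anchor]
    # WGBS members first (sorted) so their assignments win on conflicts
    hmem <- members[members > nrow(wb)]
    ord <- c(wmem[order(wb$start[wmem])],
             hmem[order(hb$start[hmem - nrow(wb)])])
    mi <- mi + 1L
    mid <- sprintf("merged_%d", mi)
    snps <- list()
    for (i in ord) {
      s <- if (i <= nrow(wb)) src_snps(wgbs, wb$block_id[i]) else
        src_snps(hic, hb$block_id[i - nrow(wb)])
      if (!nrow(s)) next
      if (bitwXor(pars[i], anchor_par) == 1L) s$phase <- flip_phase(s$phase)
      snps[[length(snps) + 1L]] <- s
    }
    snps <- do.call(rbind, snps)
    snps <- snps[!duplicated(paste(snps$chrom, snps$pos)), , drop = FALSE]
    snps$block_id <- mid
    snps$source <- "merged"
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
    starts <- vapply(ord, function(i) {
      if (i <= nrow(wb)) wb$start[i] else hb$start[i - nrow(wb)]
    }, numeric(1))
    ends <- vapply(ord, function(i) {
      if (i <= nrow(wb)) wb$end[i] else hb$end[i - nrow(wb)]
    }, numeric(1))
    out_blocks[[length(out_blocks) + 1L]] <- data.frame(
      block_id = mid, chrom = snps$chrom[1L],
      start = as.integer(min(starts)), end = as.integer(max(ends)),
      source = "merged", stringsAsFactors = FALSE)
    out_snps[[length(out_snps) + 1L]] <- snps
  }

  bdf <- do.call(rbind, out_blocks)
  sdf <- do.call(rbind, out_snps)
  if (is.null(bdf)) {
    bdf <- data.frame(block_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      source = character(), stringsAsFactors = FALSE)
  }
  if (is.null(sdf)) {
    sdf <- data.frame(block_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      phase = integer(), source = character(),
                      stringsAsFactors = FALSE)
  }
  bdf <- bdf[order(bdf$chrom, bdf$start, bdf$block_id), , drop = FALSE]
  rownames(bdf) <- NULL
  rownames(sdf) <- NULL
  out <- phase_set(bdf, sdf)
  attr(out, "conflicts") <- warns
  if (length(warns)) warning(paste(warns, collapse = "; "))
  out
}
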