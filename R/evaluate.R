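#' Planted allele-informative sites and adjacent pairs of a truth set
#'
#' A region CpG dyad is allele-informative (heterotypic) when its two
#' alleles carry different realized states. Each dyad contributes its C
#' position on the "+" strand and the G position (pos + 1) on the "-"
#' strand. Planted pairs are consecutive heterotypic sites within the same
#' region, per strand.
#'
#' @param truth A `sim_truth`.
#' @return List with `sites` (chrom, strand, pos, region) and `pairs`
#'   (chrom, strand, pos_i, pos_j, region).
#' @export
truth_pairs <- function(truth) {
  cp <- truth$cpgs
  het <- !is.na(cp$region) & cp$level_hap1 != cp$level_hap2 &
    abs(cp$level_hap1 - cp$level_hap2) == 1
  sites <- NULL; pairs <- NULL
  for (strand in c("+", "-")) {
    pos <- if (strand == "+") cp$pos[het] else cp$pos[het] + 1L
    reg <- cp$region[het]
    o <- order(pos)
    pos <- pos[o]; reg <- reg[o]
    sites <- rbind(sites, data.frame(chrom = truth$chrom, strand = strand,
                                     pos = pos, region = reg,
                                     stringsAsFactors = FALSE))
    if (length(pos) >= 2L) {
      same <- reg[-1L] == reg[-length(reg)]
      pairs <- rbind(pairs, data.frame(
        chrom = truth$chrom, strand = strand,
        pos_i = pos[-length(pos)][same], pos_j = pos[-1L][same],
        region = reg[-1L][same], stringsAsFactors = FALSE))
    }
  }
  list(sites = sites, pairs = pairs)
}

#' Compare called ASM pairs with the planted truth
#'
#' A planted pair is *testable* when a path of tested adjacent site-list
#' pairs connects its two sites in the result (both sites effective, all
#' connecting pairs covered at the floor) — a pair the exact test never saw
#' cannot count against recall. A testable planted pair is *recovered* when
#' every pair on that path was accepted (equivalently, both sites ended up
#' in the same block). Precision is measured over consecutive member-
#' cytosine pairs of the emitted blocks: such a pair is a true positive when
#' both sites are heterotypic planted sites, adjacent within one region.
#'
#' @param result An `asm_result`.
#' @param truth A `sim_truth`.
#' @return List: `recall`, `precision`, `n_testable`, `n_recovered`,
#'   `n_called`, `n_called_true`.
#' @export
evaluate_pairs <- function(result, truth) {
  tp <- truth_pairs(truth)
  pr <- result$pairs[result$pairs$adjacent, , drop = FALSE]
  n_testable <- 0L; n_recovered <- 0L
  if (!is.null(tp$pairs)) {
    for (strand in unique(tp$pairs$strand)) {
      sub <- pr[pr$chrom == truth$chrom & pr$strand == strand, , drop = FALSE]
      sub <- sub[order(sub$pos_i), , drop = FALSE]
      tps <- tp$pairs[tp$pairs$strand == strand, , drop = FALSE]
      for (r in seq_len(nrow(tps))) {
        a <- tps$pos_i[r]; b <- tps$pos_j[r]
        path <- sub[sub$pos_i >= a & sub$pos_j <= b, , drop = FALSE]
        if (!nrow(path)) next
        contiguous <- path$pos_i[1L] == a &&
          path$pos_j[nrow(path)] == b &&
          (nrow(path) == 1L ||
             all(path$pos_j[-nrow(path)] == path$pos_i[-1L]))
        if (!contiguous || !all(path$total >= result$params$min_cov)) next
        n_testable <- n_testable + 1L
        if (all(path$asm & path$oriented)) n_recovered <- n_recovered + 1L
      }
    }
  }
  # precision over consecutive member-cytosine pairs of the emitted blocks
  truth_keys <- if (!is.null(tp$pairs)) {
    paste(tp$pairs$strand, tp$pairs$pos_i, tp$pairs$pos_j)
  } else character(0)
  n_called <- 0L; n_true <- 0L
  for (b in result$blocks) {
    cy <- b$sites$pos[b$sites$type == "C"]
    if (length(cy) < 2L) next
    keys <- paste(b$strand, cy[-length(cy)], cy[-1L])
    n_called <- n_called + length(keys)
    n_true <- n_true + sum(keys %in% truth_keys)
  }
  list(recall = if (n_testable) n_recovered / n_testable else NA_real_,
       precision = if (n_called) n_true / n_called else NA_real_,
       n_testable = n_testable, n_recovered = n_recovered,
       n_called = n_called, n_called_true = n_true)
}

#' Planted-region recovery at effective-site resolution
#'
#' For each region and strand with at least two heterotypic sites present in
#' the result's effective-site list, the region counts as recovered when a
#' single block contains all of those sites as members.
#'
#' @param result An `asm_result`.
#' @param truth A `sim_truth`.
#' @return List: `n_regions` (region-strand units evaluated), `n_recovered`,
#'   `fraction`.
#' @export
evaluate_regions <- function(result, truth) {
  tp <- truth_pairs(truth)
  eff <- result$sites
  n_eval <- 0L; n_rec <- 0L
  if (!is.null(tp$sites) && !is.null(eff)) {
    for (strand in c("+", "-")) {
      es <- eff$pos[eff$strand == strand & eff$chrom == truth$chrom]
      ts <- tp$sites[tp$sites$strand == strand, , drop = FALSE]
      for (r in unique(ts$region)) {
        want <- intersect(ts$pos[ts$region == r], es)
        if (length(want) < 2L) next
        n_eval <- n_eval + 1L
        hit <- any(vapply(result$blocks, function(b) {
          b$strand == strand && b$chrom == truth$chrom &&
            all(want %in% b$sites$pos[b$sites$type == "C"])
        }, logical(1)))
        if (hit) n_rec <- n_rec + 1L
      }
    }
  }
  list(n_regions = n_eval, n_recovered = n_rec,
       fraction = if (n_eval) n_rec / n_eval else NA_real_)
}

#' Switch-error rate of phased SNPs against planted truth
#'
#' Within each block the phased SNPs are compared with the planted phase:
#' the relative phase of every consecutive phased pair either matches the
#' truth or is a switch error. The block-level haplotype labelling is
#' arbitrary, so only relative phase is compared.
#'
#' @param x An `asm_result` or `phase_set` (or phase data.frame with
#'   `block_id`, `chrom`, `pos`, `phase`).
#' @param truth A `sim_truth`.
#' @return List: `n_phased` (distinct phased SNPs), `n_comparisons`,
#'   `n_switch_errors`, `rate` (NA when no comparison is possible).
#' @export
switch_error <- function(x, truth) {
  ph <- if (inherits(x, "asm_result")) x$phase else
    if (inherits(x, "phase_set")) x$snps else x
  ph <- ph[!is.na(ph$phase) & ph$chrom == truth$chrom, , drop = FALSE]
  truth_ph <- stats::setNames(truth$snps$hap1_allele, truth$snps$pos)
  ncmp <- 0L; nerr <- 0L
  for (bid in unique(ph$block_id)) {
    sub <- ph[ph$block_id == bid, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    tt <- truth_ph[as.character(sub$pos)]
    keep <- !is.na(tt)
    sub <- sub[keep, , drop = FALSE]; tt <- tt[keep]
    if (nrow(sub) < 2L) next
    rel_called <- abs(diff(sub$phase))
    rel_truth <- abs(diff(unname(tt)))
    ncmp <- ncmp + length(rel_called)
    nerr <- nerr + sum(rel_called != rel_truth)
  }
  list(n_phased = length(unique(ph$pos)), n_comparisons = ncmp,
       n_switch_errors = nerr,
       rate = if (ncmp) nerr / ncmp else NA_real_)
}

#' Total span of a set of blocks
#'
#' Sum of `end - start + 1` over blocks, for an `asm_result` (block member
#' sites plus phased SNPs) or a `phase_set`.
#'
#' @param x An `asm_result` or `phase_set`.
#' @return Total span in bp.
#' @export
total_block_span <- function(x) {
  if (inherits(x, "asm_result")) x <- as_phase_set(x)
  if (!nrow(x$blocks)) return(0)
  sum(x$blocks$end - x$blocks$start + 1)
}
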