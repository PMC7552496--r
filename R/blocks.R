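#' Call allele-specific methylation haplotype blocks
#'
#' The main pipeline. Per chromosome and bisulfite strand it
#' \enumerate{
#'   \item tallies per-cytosine methylation and keeps the effective sites
#'     (partially methylated, sufficiently covered; see
#'     [select_effective_sites()]);
#'   \item counts per-read co-occurrence for every consecutive pair of sites
#'     (cytosines, and heterozygous SNP sites in the snp-aware modes) that
#'     share at least `min_cov` covering reads, plus every co-covered
#'     cytosine-by-SNP pair used for phasing;
#'   \item computes the two-sided exact p-value for each tested pair and
#'     adjusts all of them in one genome-wide Benjamini-Hochberg family;
#'   \item chains accepted ASM pairs left to right into blocks — a rejected,
#'     untestable or orientation-ambiguous pair closes the open block — and
#'   \item phases heterozygous SNPs into the blocks by majority vote over
#'     their accepted pairs with member cytosines (ties stay unphased).
#' }
#'
#' Within a block, haplotype A is anchored at the first member site: it is
#' the haplotype carrying the lexicographically smaller status (M for a
#' cytosine, the reference allele for a SNP) there. A SNP phase of 0 means
#' the reference allele lies on haplotype A.
#'
#' @param fragments A `meth_fragments` object (see [extract_fragments()]).
#' @param het_snps Optional `het_snps` data.frame; required for modes other
#'   than `"asm"`.
#' @param mode `"asm+snp"` (default): chain cytosines and SNPs and phase
#'   SNPs; `"asm"`: cytosine-only blocks; `"snp"`: SNP-only chaining from
#'   the same read evidence (the baseline without methylation information).
#' @param min_cov Minimum coverage for an effective site and minimum shared
#'   coverage for a tested pair (default 4).
#' @param meth_low,meth_high Effective-site level cutoffs (defaults 0.1, 0.9).
#' @param fdr Adjusted-p threshold for an ASM pair (default 0.05).
#' @param top2_frac,max_ratio Pair-pattern criteria (defaults 0.9 and 2);
#'   see [classify_pair()].
#' @return An `asm_result` object: list with `blocks` (list of block
#'   records), `pairs` (all tested/attempted pairs with p-values and the ASM
#'   flag), `phase` (per-SNP phase assignments), `sites` (effective sites),
#'   `mode` and `params`.
#' @export
call_asm_blocks <- function(fragments, het_snps = NULL,
                            mode = c("asm+snp", "asm", "snp"),
                            min_cov = 4, meth_low = 0.1, meth_high = 0.9,
                            fdr = 0.05, top2_frac = 0.9, max_ratio = 2.0) {
  mode <- match.arg(mode)
  if (meth_low >= meth_high) {
    stop("configuration error: meth_low must be < meth_high")
  }
  if (min_cov < 1) stop("configuration error: min_cov must be >= 1")
  if (fdr <= 0 || fdr > 1) stop("configuration error: fdr must be in (0, 1]")
  if (mode != "asm" && (is.null(het_snps) || nrow(het_snps) == 0L)) {
    if (mode == "snp") stop("mode 'snp' requires het_snps")
    mode_has_snps <- FALSE
  } else {
    mode_has_snps <- mode != "asm"
  }
  params <- list(min_cov = min_cov, meth_low = meth_low,
                 meth_high = meth_high, fdr = fdr, top2_frac = top2_frac,
                 max_ratio = max_ratio)

  groups <- unique(rbind(fragments$meth[c("chrom", "strand")],
                         fragments$snp[c("chrom", "strand")]))
  groups <- groups[order(groups$chrom, groups$strand), , drop = FALSE]

  pair_list <- list()
  site_list <- list()
  eff_list <- list()
  for (gi in seq_len(nrow(groups))) {
    ch <- groups$chrom[gi]; st <- groups$strand[gi]
    eff <- NULL
    cyt_pos <- integer(0)
    if (mode != "snp") {
      eff <- select_effective_sites(summarize_sites(fragments, ch, st),
                                    meth_low, meth_high, min_cov)
      cyt_pos <- eff$pos
      eff_list[[length(eff_list) + 1L]] <- eff
    }
    snp_pos <- integer(0)
    if (mode_has_snps) {
      sc <- fragments$snp
      sc <- sc[sc$chrom == ch & sc$strand == st, , drop = FALSE]
      sc <- sc[sc$pos %in% het_snps$pos[het_snps$chrom == ch], , drop = FALSE]
      if (nrow(sc)) {
        # effective-SNP filter, the allele analog of the effective-site
        # filter: both alleles must be observed at adequate balance, else
        # the site carries no phase information (e.g. one allele destroyed
        # by bisulfite conversion) and would only sever the chain
        nr <- tapply(sc$status == "R", sc$pos, sum)
        nv <- tapply(sc$status == "V", sc$pos, sum)
        tot <- nr + nv
        maf <- pmin(nr, nv) / tot
        snp_pos <- sort(as.integer(names(tot)[tot >= min_cov &
                                                maf >= meth_low]))
      }
    }
    gp <- group_pairs(fragments, ch, st, cyt_pos, snp_pos,
                      vote = mode == "asm+snp")
    if (!is.null(gp$pairs) && nrow(gp$pairs)) {
      pair_list[[length(pair_list) + 1L]] <- gp$pairs
    }
    site_list[[length(site_list) + 1L]] <- gp$sites
  }

  pairs <- if (length(pair_list)) do.call(rbind, pair_list) else
    empty_pairs_df()
  pairs$tested <- pairs$total >= min_cov
  pairs$p_raw <- rep(NA_real_, nrow(pairs))
  pairs$p_adj <- rep(NA_real_, nrow(pairs))
  if (any(pairs$tested)) {
    ti <- which(pairs$tested)
    pairs$p_raw[ti] <- vapply(ti, function(i) {
      pair_pvalue(c(pairs$n11[i], pairs$n12[i], pairs$n21[i], pairs$n22[i]))
    }, numeric(1))
    pairs$p_adj[ti] <- adjust_fdr(pairs$p_raw[ti])
  }
  pairs$asm <- classify_pairs_vec(pairs, fdr, top2_frac, max_ratio) &
    pairs$tested
  # an orientation-ambiguous pair cannot link two haplotype patterns
  pairs$concordant <- (pairs$n11 + pairs$n22) > (pairs$n12 + pairs$n21)
  pairs$oriented <- (pairs$n11 + pairs$n22) != (pairs$n12 + pairs$n21)

  blocks <- list()
  for (gi in seq_len(nrow(groups))) {
    ch <- groups$chrom[gi]; st <- groups$strand[gi]
    sites <- site_list[[gi]]
    if (is.null(sites) || nrow(sites) < 2L) next
    gp <- pairs[pairs$chrom == ch & pairs$strand == st & pairs$adjacent, ,
                drop = FALSE]
    link_row <- match(paste(sites$pos[-nrow(sites)], sites$pos[-1L]),
                      paste(gp$pos_i, gp$pos_j))
    linked <- !is.na(link_row) & gp$asm[link_row] & gp$oriented[link_row]
    blocks <- c(blocks, chain_blocks(ch, st, sites, linked,
                                     gp$concordant[link_row]))
  }
  blocks <- blocks[order(vapply(blocks, function(b) b$chrom, character(1)),
                         vapply(blocks, function(b) b$start, integer(1)),
                         vapply(blocks, function(b) b$strand, character(1)))]
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- sprintf("wgbs_%d", i)

  phase <- empty_phase_df()
  if (mode_has_snps && length(blocks)) {
    phase <- phase_blocks_snps(blocks, pairs, het_snps, mode)
  }

  structure(list(blocks = blocks, pairs = pairs, phase = phase,
                 sites = if (length(eff_list)) do.call(rbind, eff_list)
                         else NULL,
                 het_snps = het_snps, mode = mode, params = params),
            class = "asm_result")
}

empty_pairs_df <- function() {
  data.frame(chrom = character(), strand = character(), pos_i = integer(),
             pos_j = integer(), kind = character(), type_i = character(),
             type_j = character(), n11 = integer(), n12 = integer(),
             n21 = integer(), n22 = integer(), total = integer(),
             adjacent = logical(), stringsAsFactors = FALSE)
}

empty_phase_df <- function() {
  data.frame(block_id = character(), chrom = character(),
             strand = character(), pos = integer(), ref = character(),
             alt = character(), phase = integer(), n_votes = integer(),
             member = logical(), source = character(),
             stringsAsFactors = FALSE)
}

# Per-group co-occurrence counting: consecutive-site pairs over the combined
# (cytosine + SNP) site list, plus all co-covered cytosine x SNP vote pairs.
group_pairs <- function(fragments, ch, st, cyt_pos, snp_pos, vote) {
  sites <- rbind(
    if (length(cyt_pos)) data.frame(pos = cyt_pos, type = "C",
                                    stringsAsFactors = FALSE),
    if (length(snp_pos)) data.frame(pos = setdiff(snp_pos, cyt_pos),
                                    type = "S", stringsAsFactors = FALSE))
  if (is.null(sites) || nrow(sites) == 0L) {
    return(list(sites = NULL, pairs = NULL))
  }
  sites <- sites[order(sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  m <- fragments$meth
  m <- m[m$chrom == ch & m$strand == st & m$pos %in% cyt_pos, , drop = FALSE]
  s <- fragments$snp
  s <- s[s$chrom == ch & s$strand == st & s$pos %in% sites$pos[sites$type == "S"], ,
         drop = FALSE]
  calls <- rbind(
    data.frame(fragment_id = m$fragment_id, pos = m$pos,
               code = ifelse(m$status == "M", 1L, 2L),
               stringsAsFactors = FALSE),
    data.frame(fragment_id = s$fragment_id, pos = s$pos,
               code = ifelse(s$status == "R", 1L, 2L),
               stringsAsFactors = FALSE))
  if (nrow(calls) == 0L) return(list(sites = sites, pairs = NULL))
  calls$rank <- match(calls$pos, sites$pos)
  calls$fid <- match(calls$fragment_id, unique(calls$fragment_id))

  o <- order(calls$fid, calls$rank, method = "radix")
  calls <- calls[o, , drop = FALSE]
  n <- nrow(calls)
  adj_df <- NULL
  if (n >= 2L) {
    same <- calls$fid[-1L] == calls$fid[-n] &
      calls$rank[-1L] == calls$rank[-n] + 1L
    ii <- which(same)
    if (length(ii)) {
      ri <- calls$rank[ii]
      cc <- paste0(calls$code[ii], calls$code[ii + 1L])
      tab <- table(factor(ri, levels = sort(unique(ri))),
                   factor(cc, levels = c("11", "12", "21", "22")))
      rks <- as.integer(rownames(tab))
      adj_df <- data.frame(
        chrom = ch, strand = st,
        pos_i = sites$pos[rks], pos_j = sites$pos[rks + 1L],
        kind = ifelse(sites$type[rks] == "C" & sites$type[rks + 1L] == "C",
                      "meth-meth",
               ifelse(sites$type[rks] == "S" & sites$type[rks + 1L] == "S",
                      "snp-snp", "meth-snp")),
        type_i = sites$type[rks], type_j = sites$type[rks + 1L],
        n11 = as.integer(tab[, "11"]), n12 = as.integer(tab[, "12"]),
        n21 = as.integer(tab[, "21"]), n22 = as.integer(tab[, "22"]),
        stringsAsFactors = FALSE)
      adj_df$total <- adj_df$n11 + adj_df$n12 + adj_df$n21 + adj_df$n22
      adj_df$adjacent <- TRUE
    }
  }

  vote_df <- NULL
  if (vote && nrow(m) && nrow(s)) {
    vm <- merge(data.frame(fragment_id = m$fragment_id, cpos = m$pos,
                           mcode = ifelse(m$status == "M", 1L, 2L),
                           stringsAsFactors = FALSE),
                data.frame(fragment_id = s$fragment_id, spos = s$pos,
                           scode = ifelse(s$status == "R", 1L, 2L),
                           stringsAsFactors = FALSE),
                by = "fragment_id")
    if (nrow(vm)) {
      cyt_first <- vm$cpos < vm$spos
      pos_i <- ifelse(cyt_first, vm$cpos, vm$spos)
      pos_j <- ifelse(cyt_first, vm$spos, vm$cpos)
      ci <- ifelse(cyt_first, vm$mcode, vm$scode)
      cj <- ifelse(cyt_first, vm$scode, vm$mcode)
      key <- paste(pos_i, pos_j)
      cc <- paste0(ci, cj)
      tab <- table(factor(key, levels = unique(key)),
                   factor(cc, levels = c("11", "12", "21", "22")))
      kp <- do.call(rbind, strsplit(rownames(tab), " ", fixed = TRUE))
      pi <- as.integer(kp[, 1L]); pj <- as.integer(kp[, 2L])
      ti <- ifelse(pi %in% m$pos, "C", "S")
      vote_df <- data.frame(
        chrom = ch, strand = st, pos_i = pi, pos_j = pj,
        kind = "meth-snp", type_i = ti, type_j = ifelse(ti == "C", "S", "C"),
        n11 = as.integer(tab[, "11"]), n12 = as.integer(tab[, "12"]),
        n21 = as.integer(tab[, "21"]), n22 = as.integer(tab[, "22"]),
        stringsAsFactors = FALSE)
      vote_df$total <- vote_df$n11 + vote_df$n12 + vote_df$n21 + vote_df$n22
      vote_df$adjacent <- FALSE
      if (!is.null(adj_df)) {
        dupkey <- paste(vote_df$pos_i, vote_df$pos_j) %in%
          paste(adj_df$pos_i, adj_df$pos_j)
        vote_df <- vote_df[!dupkey, , drop = FALSE]
      }
    }
  }
  pr <- rbind(adj_df, vote_df)
  if (!is.null(pr)) {
    pr <- pr[order(pr$pos_i, pr$pos_j), , drop = FALSE]
    rownames(pr) <- NULL
  }
  list(sites = sites, pairs = pr)
}

# Greedy left-to-right chaining of accepted links into blocks with
# haplotype-A status propagation (first member site anchors haplotype A at
# the lexicographically smaller status, code 1).
chain_blocks <- function(ch, st, sites, linked, concordant) {
  blocks <- list()
  i <- 1L
  nlink <- length(linked)
  while (i <= nlink) {
    if (!isTRUE(linked[i])) { i <- i + 1L; next }
    j <- i
    while (j < nlink && isTRUE(linked[j + 1L])) j <- j + 1L
    idx <- i:(j + 1L)
    hap <- integer(length(idx))
    hap[1L] <- 1L
    for (k in seq_len(length(idx) - 1L)) {
      hap[k + 1L] <- if (isTRUE(concordant[idx[k]])) hap[k] else 3L - hap[k]
    }
    sdf <- data.frame(pos = sites$pos[idx], type = sites$type[idx],
                      hapA_code = hap, stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1L]] <- list(
      chrom = ch, strand = st, sites = sdf,
      start = min(sdf$pos), end = max(sdf$pos),
      n_cytosines = sum(sdf$type == "C"))
    i <- j + 1L
  }
  blocks
}

# Assign SNP phases per block: majority vote over accepted cytosine x SNP
# pairs against member cytosines; a chain-member SNP with no cytosine votes
# keeps its propagated phase; vote ties stay missing.
phase_blocks_snps <- function(blocks, pairs, het_snps, mode) {
  vp <- pairs[pairs$asm & pairs$oriented & pairs$kind == "meth-snp", ,
              drop = FALSE]
  out <- list()
  for (b in blocks) {
    cy <- b$sites[b$sites$type == "C", , drop = FALSE]
    cand <- list()
    if (nrow(cy) && nrow(vp)) {
      bp <- vp[vp$chrom == b$chrom & vp$strand == b$strand, , drop = FALSE]
      for (r in seq_len(nrow(bp))) {
        cpos <- if (bp$type_i[r] == "C") bp$pos_i[r] else bp$pos_j[r]
        spos <- if (bp$type_i[r] == "C") bp$pos_j[r] else bp$pos_i[r]
        ci <- match(cpos, cy$pos)
        if (is.na(ci)) next
        scode <- if (bp$concordant[r]) cy$hapA_code[ci] else
          3L - cy$hapA_code[ci]
        cand[[length(cand) + 1L]] <- c(pos = spos, code = scode)
      }
    }
    votes <- if (length(cand)) as.data.frame(do.call(rbind, cand)) else
      data.frame(pos = integer(), code = integer())
    member_snps <- b$sites[b$sites$type == "S", , drop = FALSE]
    all_pos <- sort(unique(c(votes$pos, member_snps$pos)))
    for (p in all_pos) {
      v <- votes$code[votes$pos == p]
      nv <- length(v)
      if (nv) {
        n1 <- sum(v == 1L); n2 <- nv - n1
        code <- if (n1 > n2) 1L else if (n2 > n1) 2L else NA_integer_
      } else {
        mi <- match(p, member_snps$pos)
        code <- if (!is.na(mi)) member_snps$hapA_code[mi] else NA_integer_
      }
      hs <- het_snps[het_snps$chrom == b$chrom & het_snps$pos == p, ,
                     drop = FALSE]
      if (!nrow(hs)) next
      out[[length(out) + 1L]] <- data.frame(
        block_id = b$block_id, chrom = b$chrom, strand = b$strand, pos = p,
        ref = hs$ref[1L], alt = hs$alt[1L],
        phase = if (is.na(code)) NA_integer_ else code - 1L,
        n_votes = nv, member = p %in% member_snps$pos, source = "WGBS",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_phase_df())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chain effective cytosine sites into ASM blocks
#'
#' Cytosine-only block extension (the `"asm"` mode of [call_asm_blocks()]
#' restricted to a caller-supplied effective-site list): consecutive
#' effective-site pairs sharing at least `min_cov` reads are tested, the
#' whole run is FDR-adjusted, and accepted ASM pairs are chained greedily —
#' a rejected or uncovered pair closes the block.
#'
#' @param effective_sites data.frame from [select_effective_sites()]
#'   (one chromosome + strand, sorted by position).
#' @param fragments A `meth_fragments` object.
#' @param min_cov,fdr,top2_frac,max_ratio Thresholds as in
#'   [call_asm_blocks()].
#' @return List of block records (each with `chrom`, `strand`, `sites`,
#'   `start`, `end`, `n_cytosines`).
#' @export
extend_blocks <- function(effective_sites, fragments, min_cov = 4,
                          fdr = 0.05, top2_frac = 0.9, max_ratio = 2.0) {
  if (is.unsorted(effective_sites$pos)) {
    stop("effective_sites must be sorted by position")
  }
  if (length(unique(effective_sites$chrom)) > 1L ||
      length(unique(effective_sites$strand)) > 1L) {
    stop("extend_blocks expects sites from a single chromosome and strand")
  }
  ch <- effective_sites$chrom[1L]; st <- effective_sites$strand[1L]
  gp <- group_pairs(fragments, ch, st, effective_sites$pos, integer(0),
                    vote = FALSE)
  if (is.null(gp$pairs) || !nrow(gp$pairs)) return(list())
  pr <- gp$pairs
  pr$tested <- pr$total >= min_cov
  pr$p_raw <- NA_real_; pr$p_adj <- NA_real_
  ti <- which(pr$tested)
  if (length(ti)) {
    pr$p_raw[ti] <- vapply(ti, function(i) {
      pair_pvalue(c(pr$n11[i], pr$n12[i], pr$n21[i], pr$n22[i]))
    }, numeric(1))
    pr$p_adj[ti] <- adjust_fdr(pr$p_raw[ti])
  }
  pr$asm <- classify_pairs_vec(pr, fdr, top2_frac, max_ratio) & pr$tested
  pr$concordant <- (pr$n11 + pr$n22) > (pr$n12 + pr$n21)
  pr$oriented <- (pr$n11 + pr$n22) != (pr$n12 + pr$n21)
  sites <- gp$sites
  link_row <- match(paste(sites$pos[-nrow(sites)], sites$pos[-1L]),
                    paste(pr$pos_i, pr$pos_j))
  linked <- !is.na(link_row) & pr$asm[link_row] & pr$oriented[link_row]
  blocks <- chain_blocks(ch, st, sites, linked, pr$concordant[link_row])
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- sprintf("wgbs_%d", i)
  blocks
}

#' Phase heterozygous SNPs against one ASM block
#'
#' Standalone per-block phasing: every SNP co-covered with a member cytosine
#' is tested (methylation x allele 2x2 table, exact test, BH adjustment over
#' the pairs tested here), and each accepted pair votes for the allele
#' carried by haplotype A; the majority wins, ties stay missing. Within
#' [call_asm_blocks()] the same votes are computed inside the single
#' genome-wide FDR family instead.
#'
#' @param block One block record (from [extend_blocks()] or
#'   `asm_result$blocks`).
#' @param fragments A `meth_fragments` object.
#' @param het_snps `het_snps` data.frame.
#' @param min_cov,fdr,top2_frac,max_ratio Thresholds as in
#'   [call_asm_blocks()].
#' @return data.frame (phase vector): `chrom`, `pos`, `ref`, `alt`, `phase`
#'   (0 = reference allele on haplotype A, NA = unphased), `n_votes`.
#' @export
phase_snps <- function(block, fragments, het_snps, min_cov = 4, fdr = 0.05,
                       top2_frac = 0.9, max_ratio = 2.0) {
  cy <- block$sites[block$sites$type == "C", , drop = FALSE]
  sc <- fragments$snp
  sc <- sc[sc$chrom == block$chrom & sc$strand == block$strand, , drop = FALSE]
  cand_pos <- sort(intersect(unique(sc$pos),
                             het_snps$pos[het_snps$chrom == block$chrom]))
  rows <- list()
  for (sp in cand_pos) {
    hs <- het_snps[het_snps$chrom == block$chrom & het_snps$pos == sp, ,
                   drop = FALSE][1L, ]
    for (ci in seq_len(nrow(cy))) {
      pc <- suppressWarnings(
        count_meth_snp_pair(fragments, cy$pos[ci], hs, strand = block$strand))
      if (pc$total < min_cov) next
      pc$cyt_idx <- ci
      pc$snp_pos <- sp
      rows[[length(rows) + 1L]] <- pc
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), phase = integer(),
                      n_votes = integer(), stringsAsFactors = FALSE))
  }
  pr <- do.call(rbind, rows)
  pr$p_raw <- vapply(seq_len(nrow(pr)), function(i) {
    pair_pvalue(c(pr$n11[i], pr$n12[i], pr$n21[i], pr$n22[i]))
  }, numeric(1))
  pr$p_adj <- adjust_fdr(pr$p_raw)
  pr$asm <- classify_pairs_vec(pr, fdr, top2_frac, max_ratio)
  pr$concordant <- (pr$n11 + pr$n22) > (pr$n12 + pr$n21)
  pr$oriented <- (pr$n11 + pr$n22) != (pr$n12 + pr$n21)
  out <- list()
  for (sp in unique(pr$snp_pos)) {
    sub <- pr[pr$snp_pos == sp & pr$asm & pr$oriented, , drop = FALSE]
    codes <- integer(0)
    if (nrow(sub)) {
      codes <- ifelse(sub$concordant,
                      cy$hapA_code[sub$cyt_idx],
                      3L - cy$hapA_code[sub$cyt_idx])
    }
    n1 <- sum(codes == 1L); n2 <- sum(codes == 2L)
    code <- if (n1 > n2) 1L else if (n2 > n1) 2L else NA_integer_
    hs <- het_snps[het_snps$chrom == block$chrom & het_snps$pos == sp, ,
                   drop = FALSE][1L, ]
    out[[length(out) + 1L]] <- data.frame(
      chrom = block$chrom, pos = sp, ref = hs$ref, alt = hs$alt,
      phase = if (is.na(code)) NA_integer_ else code - 1L,
      n_votes = length(codes), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of input heterozygous SNPs that received a phase
#'
#' @param x An `asm_result`, `phase_set`, or a phase data.frame with
#'   `chrom`, `pos`, `phase` columns.
#' @param het_snps The full input `het_snps` set (denominator).
#' @return Ratio in \[0, 1\] (a SNP phased in several blocks counts once).
#' @export
phased_fraction <- function(x, het_snps) {
  if (is.null(het_snps) || nrow(het_snps) == 0L) {
    stop("phased_fraction is undefined for an empty het SNP set")
  }
  ph <- if (inherits(x, "asm_result")) x$phase else
    if (inherits(x, "phase_set")) x$snps else x
  if (is.null(ph) || nrow(ph) == 0L) return(0)
  ph <- ph[!is.na(ph$phase), , drop = FALSE]
  length(unique(paste(ph$chrom, ph$pos))) / nrow(het_snps)
}

#' Convert an asm_result into a phase_set
#'
#' Blocks become `phase_set` block records (span = member sites plus phased
#' SNP positions); the per-SNP phase assignments become the SNP table
#' (source `"WGBS"`).
#'
#' @param result An `asm_result`.
#' @return A `phase_set`.
#' @export
as_phase_set <- function(result) {
  stopifnot(inherits(result, "asm_result"))
  bl <- result$blocks
  ph <- result$phase
  bdf <- if (length(bl)) do.call(rbind, lapply(bl, function(b) {
    sp <- ph$pos[ph$block_id == b$block_id]
    data.frame(block_id = b$block_id, chrom = b$chrom,
               start = min(c(b$start, sp)), end = max(c(b$end, sp)),
               source = "WGBS", stringsAsFactors = FALSE)
  })) else data.frame(block_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      source = character(), stringsAsFactors = FALSE)
  snps <- if (nrow(ph)) data.frame(
    block_id = ph$block_id, chrom = ph$chrom, pos = ph$pos, ref = ph$ref,
    alt = ph$alt, phase = ph$phase, source = "WGBS",
    stringsAsFactors = FALSE) else
    data.frame(block_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), phase = integer(),
               source = character(), stringsAsFactors = FALSE)
  phase_set(bdf, snps)
}

#' @export
print.asm_result <- function(x, ...) {
  cat("asm_result (mode ", x$mode, "): ", length(x$blocks), " block(s), ",
      sum(x$pairs$asm), " ASM pair(s) of ", sum(x$pairs$tested),
      " tested, ", sum(!is.na(x$phase$phase)), " phased SNP assignment(s)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.asm_result <- function(object, ...) {
  bl <- object$blocks
  span <- sum(vapply(bl, function(b) b$end - b$start + 1L, integer(1)))
  ph <- object$phase[!is.na(object$phase$phase), , drop = FALSE]
  out <- list(
    mode = object$mode,
    n_pairs_tested = sum(object$pairs$tested),
    n_pairs_asm = sum(object$pairs$asm),
    n_blocks = length(bl),
    total_block_span = span,
    n_cytosines_in_blocks = sum(vapply(bl, function(b) b$n_cytosines,
                                       integer(1))),
    n_phased_snps = length(unique(paste(ph$chrom, ph$pos))),
    phased_fraction = if (!is.null(object$het_snps) &&
                          nrow(object$het_snps)) {
      length(unique(paste(ph$chrom, ph$pos))) / nrow(object$het_snps)
    } else NA_real_
  )
  class(out) <- "summary.asm_result"
  out
}

#' @export
print.summary.asm_result <- function(x, ...) {
  for (k in names(x)) cat(k, "\t", format(x[[k]]), "\n", sep = "")
  invisible(x)
}
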