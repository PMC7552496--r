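#' Count per-read co-occurrence of methylation states at an adjacent site pair
#'
#' Builds the 2x2 table over fragments carrying a methylation call at *both*
#' positions: `n11 = N(M_i, M_j)`, `n12 = N(M_i, U_j)`, `n21 = N(U_i, M_j)`,
#' `n22 = N(U_i, U_j)`. The four cells sum to the number of such fragments.
#'
#' @param fragments A `meth_fragments` object.
#' @param pos_i,pos_j Site coordinates with `pos_j > pos_i`.
#' @param chrom,strand Optional restriction when the container holds several
#'   chromosomes/strands.
#' @return One-row data.frame (`pair_counts`) with cells, `total`, and
#'   `p_raw`/`p_adj` slots initialized to `NA`.
#' @export
count_pair <- function(fragments, pos_i, pos_j, chrom = NULL, strand = NULL) {
  if (pos_i >= pos_j) stop("pos_i must be < pos_j")
  m <- fragments$meth
  if (!is.null(chrom)) m <- m[m$chrom == chrom, , drop = FALSE]
  if (!is.null(strand)) m <- m[m$strand == strand, , drop = FALSE]
  a <- m[m$pos == pos_i, c("fragment_id", "status")]
  b <- m[m$pos == pos_j, c("fragment_id", "status")]
  tab <- cross_counts(a, b, c("M", "U"), c("M", "U"))
  pair_counts_row(pos_i, pos_j, "meth-meth", "C", "C", tab)
}

#' Count per-read co-occurrence of methylation state and SNP allele
#'
#' The methylation-by-allele analog of [count_pair()]:
#' `n11 = N(M, R)`, `n12 = N(M, V)`, `n21 = N(U, R)`, `n22 = N(U, V)` over
#' fragments with both a methylation call at `cyt_pos` and an allele call at
#' the SNP. A conversion-confounded SNP has all its allele calls suppressed
#' upstream and yields a zero-total table, which is signaled with a warning.
#'
#' @param fragments A `meth_fragments` object.
#' @param cyt_pos Cytosine position.
#' @param snp One row of a `het_snps` data.frame (or a list with `chrom`,
#'   `pos`).
#' @param strand Optional strand restriction.
#' @return One-row `pair_counts` data.frame (kind `"meth-snp"`).
#' @export
count_meth_snp_pair <- function(fragments, cyt_pos, snp, strand = NULL) {
  m <- fragments$meth
  s <- fragments$snp
  m <- m[m$chrom == snp$chrom & m$pos == cyt_pos, , drop = FALSE]
  s <- s[s$chrom == snp$chrom & s$pos == snp$pos, , drop = FALSE]
  if (!is.null(strand)) {
    m <- m[m$strand == strand, , drop = FALSE]
    s <- s[s$strand == strand, , drop = FALSE]
  }
  tab <- cross_counts(m[c("fragment_id", "status")],
                      s[c("fragment_id", "status")],
                      c("M", "U"), c("R", "V"))
  out <- pair_counts_row(cyt_pos, snp$pos, "meth-snp", "C", "S", tab)
  if (out$total == 0L) {
    warning("zero-total methylation x SNP table at ", snp$chrom, ":",
            snp$pos, " (no co-covering informative reads)")
  }
  out
}

cross_counts <- function(a, b, lev_a, lev_b) {
  j <- match(a$fragment_id, b$fragment_id)
  hit <- !is.na(j)
  sa <- factor(a$status[hit], levels = lev_a)
  sb <- factor(b$status[j[hit]], levels = lev_b)
  table(sa, sb)
}

pair_counts_row <- function(pos_i, pos_j, kind, type_i, type_j, tab) {
  data.frame(pos_i = pos_i, pos_j = pos_j, kind = kind,
             type_i = type_i, type_j = type_j,
             n11 = as.integer(tab[1, 1]), n12 = as.integer(tab[1, 2]),
             n21 = as.integer(tab[2, 1]), n22 = as.integer(tab[2, 2]),
             total = as.integer(sum(tab)),
             p_raw = NA_real_, p_adj = NA_real_,
             stringsAsFactors = FALSE)
}

#' Two-sided exact p-value for a 2x2 co-occurrence table
#'
#' Fisher's exact test by direct hypergeometric enumeration: with all margins
#' fixed, the p-value is the sum of point probabilities of every table at
#' least as extreme as — i.e. with point probability no larger than — the
#' observed one (the minimum-likelihood two-sided rule). A table with an
#' all-zero row or column admits a single configuration and returns 1.
#'
#' @param pc A one-row `pair_counts` data.frame (from [count_pair()] or
#'   [count_meth_snp_pair()]) or a numeric vector `c(n11, n12, n21, n22)`.
#' @return p-value in \[0, 1\].
#' @export
pair_pvalue <- function(pc) {
  if (is.data.frame(pc)) {
    cells <- c(pc$n11[1L], pc$n12[1L], pc$n21[1L], pc$n22[1L])
  } else {
    cells <- as.numeric(pc)
  }
  if (length(cells) != 4L || any(is.na(cells)) || any(cells < 0)) {
    stop("pair_pvalue needs four non-negative counts")
  }
  N <- sum(cells)
  if (N == 0) stop("undefined p-value: zero-total table")
  n11 <- cells[1L]; n12 <- cells[2L]; n21 <- cells[3L]; n22 <- cells[4L]
  K <- n11 + n12          # row-1 margin
  n <- n11 + n21          # column-1 margin
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  xs <- lo:hi
  lp <- stats::dhyper(xs, K, N - K, n, log = TRUE)
  lobs <- stats::dhyper(n11, K, N - K, n, log = TRUE)
  # relative tolerance guards against ties broken by floating-point rounding
  p <- sum(exp(lp[lp <= lobs + log1p(1e-7)]))
  min(1, p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (`q_(i) = min_{k >= i} p_(k) * m / k`, capped
#' at 1), returned in input order. Wraps [stats::p.adjust()].
#'
#' @param pvalues Non-empty numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify an adjacent-site pair as ASM or not
#'
#' A pair is allele-specifically methylated when all three criteria hold:
#' \enumerate{
#'   \item the FDR-adjusted p-value is below `alpha` (default 0.05);
#'   \item the two largest cells of the 2x2 table together exceed
#'     `top2_frac` (default 90\%) of the covering reads — the reads
#'     concentrate on two state combinations;
#'   \item the ratio of the largest to the second-largest cell is below
#'     `max_ratio` (default 2) — the two combinations are balanced, as
#'     expected for two alleles at roughly equal dosage. A second-largest
#'     cell of 0 is treated as ratio +Inf and fails this criterion.
#' }
#' Ties at the thresholds fail (strict inequalities).
#'
#' @param pc One-row `pair_counts` data.frame with `p_adj` set.
#' @param alpha,top2_frac,max_ratio Thresholds as above.
#' @return `"ASM"` or `"not-ASM"`.
#' @export
classify_pair <- function(pc, alpha = 0.05, top2_frac = 0.9, max_ratio = 2.0) {
  if (is.na(pc$p_adj[1L])) stop("classify_pair requires p_adj to be set")
  cells <- sort(c(pc$n11[1L], pc$n12[1L], pc$n21[1L], pc$n22[1L]),
                decreasing = TRUE)
  ok <- pc$p_adj[1L] < alpha &&
    (cells[1L] + cells[2L]) > top2_frac * pc$total[1L] &&
    cells[2L] > 0 && cells[1L] / cells[2L] < max_ratio
  if (ok) "ASM" else "not-ASM"
}

# vectorized variant over a pairs data.frame; returns logical
classify_pairs_vec <- function(pairs, alpha, top2_frac, max_ratio) {
  if (!nrow(pairs)) return(logical(0))
  cells <- cbind(pairs$n11, pairs$n12, pairs$n21, pairs$n22)
  srt <- t(apply(cells, 1L, sort, decreasing = TRUE))
  !is.na(pairs$p_adj) & pairs$p_adj < alpha &
    (srt[, 1L] + srt[, 2L]) > top2_frac * pairs$total &
    srt[, 2L] > 0 & srt[, 1L] < max_ratio * srt[, 2L]
}
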