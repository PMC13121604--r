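profile_matrix <- function(profiles) {
  v <- vapply(profiles, function(p) p$values, numeric(length(profiles[[1]]$values)))
  m <- vapply(profiles, function(p) p$mask, logical(length(profiles[[1]]$mask)))
  v[!m] <- NA_real_
  list(values = matrix(v, ncol = length(profiles)),
       mask = matrix(m, ncol = length(profiles)))
}

row_means_masked <- function(vm) {
  n <- rowSums(vm$mask)
  s <- rowSums(ifelse(vm$mask, vm$values, 0))
  ifelse(n > 0, s / n, NA_real_)
}

window_frame <- function(grid) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(grid)),
             start = GenomicRanges::start(grid) - 1L,
             end = GenomicRanges::end(grid),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo window test for RT change between two conditions
#'
#' The per-window statistic is `|mean(B) - mean(A)|` over unmasked
#' replicate RT values. The empirical null is built from the
#' within-condition replicate-difference pool across all genome windows:
#' for every replicate pair within a condition, the per-window value
#' differences are pooled, rescaled by `sqrt((1/nA + 1/nB)/2)` so the pool
#' matches the sampling variance of the between-condition mean difference,
#' and `n_mc` draws are taken with replacement (seeded). The add-one
#' empirical p-value `(1 + #(null >= observed)) / (1 + n_mc)` is never 0.
#' Windows lacking unmasked data on either side are skipped. q-values are
#' Benjamini-Hochberg over the tested windows.
#'
#' @param profiles_A,profiles_B Lists of `rt_profile` replicates on a
#'   shared grid (condition A is the reference; positive delta = advance
#'   in B).
#' @param n_mc Number of Monte-Carlo null draws.
#' @param seed Integer seed for the null draws.
#' @return `data.frame` with `chrom, start, end, delta_rt, p, q,
#'   direction, n_A, n_B` (one row per tested window), plus the scaled
#'   null pool in attribute `"null_pool"`.
#' @export
monte_carlo_window_test <- function(profiles_A, profiles_B, n_mc = 1e5,
                                    seed = 1L) {
  if (n_mc < 1) stop("n_mc must be >= 1")
  A <- profile_matrix(profiles_A); B <- profile_matrix(profiles_B)
  nA <- ncol(A$values); nB <- ncol(B$values)
  pool <- replicate_difference_pool(A, B)
  if (length(pool) == 0)
    stop(paste("empty null pool: the Monte-Carlo mode needs >= 2 replicates",
               "in at least one condition; with single replicates use more",
               "replicates or an explicit noise model"))
  scale_f <- sqrt((1 / nA + 1 / nB) / 2)
  null_abs <- with_seed(seed, abs(sample(pool, n_mc, replace = TRUE)) * scale_f)
  null_sorted <- sort(null_abs)

  mA <- row_means_masked(A); mB <- row_means_masked(B)
  ok <- is.finite(mA) & is.finite(mB)
  delta <- mB[ok] - mA[ok]
  stat <- abs(delta)
  # p = (1 + #{null >= stat}) / (1 + n_mc) via a single sorted null sample
  ge <- n_mc - findInterval(stat, null_sorted, left.open = TRUE)
  p <- (1 + ge) / (1 + n_mc)

  res <- window_frame(profiles_A[[1]]$grid)[ok, , drop = FALSE]
  res$delta_rt <- delta
  res$p <- p
  res$q <- bh_qvalues(p)
  res$direction <- ifelse(delta > 0, "advance", ifelse(delta < 0, "delay", "none"))
  res$n_A <- rowSums(A$mask)[ok]
  res$n_B <- rowSums(B$mask)[ok]
  rownames(res) <- NULL
  attr(res, "null_pool") <- pool * scale_f
  attr(res, "n_mc") <- n_mc
  res
}

# Pool of within-condition replicate-pair differences over all windows.
replicate_difference_pool <- function(A, B) {
  pool_one <- function(vm) {
    n <- ncol(vm$values)
    if (n < 2) return(numeric(0))
    out <- list()
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      both <- vm$mask[, i] & vm$mask[, j]
      out[[length(out) + 1]] <- vm$values[both, i] - vm$values[both, j]
    }
    unlist(out)
  }
  c(pool_one(A), pool_one(B))
}

#' Paired / Welch t-test per window
#'
#' Vectorized two-sided t-tests on unmasked replicate RT values, one per
#' window. In paired mode replicates are paired by position (declare the
#' pairing by ordering the profile lists); windows where any member of a
#' pair is masked are skipped. Zero-variance windows get `p = 1` when the
#' difference is exactly 0 and a `NA` sentinel otherwise (excluded from
#' BH and flagged in the `degenerate` column).
#'
#' @inheritParams monte_carlo_window_test
#' @param paired Use the paired test (default); otherwise Welch.
#' @return `data.frame` as [monte_carlo_window_test()], plus `t`, `df`,
#'   `degenerate`.
#' @export
ttest_window_test <- function(profiles_A, profiles_B, paired = TRUE) {
  A <- profile_matrix(profiles_A); B <- profile_matrix(profiles_B)
  nA <- ncol(A$values); nB <- ncol(B$values)
  if (paired && nA != nB)
    stop("paired mode requires equal replicate counts")
  if (min(nA, nB) < 2) stop("t-test mode needs >= 2 replicates per side")
  if (paired) {
    both <- A$mask & B$mask
    d <- B$values - A$values
    d[!both] <- NA_real_
    n <- rowSums(both)
    ok <- n >= 2
    md <- rowMeans(d, na.rm = TRUE)
    vd <- apply(d, 1, stats::var, na.rm = TRUE)
    tt <- md / sqrt(vd / n)
    df <- n - 1
    delta <- md
  } else {
    nAr <- rowSums(A$mask); nBr <- rowSums(B$mask)
    ok <- nAr >= 2 & nBr >= 2
    mA <- row_means_masked(A); mB <- row_means_masked(B)
    vA <- apply(ifelse(A$mask, A$values, NA), 1, stats::var, na.rm = TRUE)
    vB <- apply(ifelse(B$mask, B$values, NA), 1, stats::var, na.rm = TRUE)
    se2 <- vA / nAr + vB / nBr
    tt <- (mB - mA) / sqrt(se2)
    df <- se2^2 / ((vA / nAr)^2 / (nAr - 1) + (vB / nBr)^2 / (nBr - 1))
    delta <- mB - mA
    vd <- se2
  }
  p <- 2 * pt(-abs(tt), df)
  degenerate <- ok & (vd == 0)
  p[degenerate & delta == 0] <- 1
  p[degenerate & delta != 0] <- NA_real_

  res <- window_frame(profiles_A[[1]]$grid)[ok, , drop = FALSE]
  res$delta_rt <- delta[ok]
  res$t <- tt[ok]
  res$df <- df[ok]
  res$p <- p[ok]
  res$q <- NA_real_
  use <- !is.na(res$p)
  res$q[use] <- bh_qvalues(res$p[use])
  res$direction <- ifelse(res$delta_rt > 0, "advance",
                          ifelse(res$delta_rt < 0, "delay", "none"))
  res$degenerate <- degenerate[ok]
  res$n_A <- rowSums(A$mask)[ok]
  res$n_B <- rowSums(B$mask)[ok]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min over {j : p_j >= p_i} of
#' (m * p_j / rank_j)`, capped at 1.
#'
#' @param p Numeric p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Stitch significant windows into switching regions
#'
#' Windows with `q <= q_cut` are partitioned by direction and merged per
#' direction allowing `gap_bp` separation (bedtools `merge -d`
#' semantics); advance and delay windows are never merged together.
#' Region statistics aggregate over the constituent significant windows.
#'
#' @param results Window table from a window test (needs `q`, `direction`,
#'   `delta_rt`).
#' @param q_cut Significance threshold on q.
#' @param gap_bp Maximum stitching gap in bp.
#' @return `data.frame`: `chrom, start, end, direction, mean_delta_rt,
#'   min_q, n_windows, span`.
#' @export
call_switch_regions <- function(results, q_cut = 0.001, gap_bp = 300000) {
  sig <- results[!is.na(results$q) & results$q <= q_cut &
                   results$direction %in% c("advance", "delay"), , drop = FALSE]
  out <- NULL
  for (dir in c("advance", "delay")) {
    w <- sig[sig$direction == dir, , drop = FALSE]
    if (nrow(w) == 0) next
    gr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1, w$end))
    mg <- merge_with_gap(gr, gap_bp)
    hit <- GenomicRanges::findOverlaps(gr, mg)
    idx <- S4Vectors::subjectHits(hit)
    out <- rbind(out, data.frame(
      chrom = as.character(GenomicRanges::seqnames(mg)),
      start = GenomicRanges::start(mg) - 1L,
      end = GenomicRanges::end(mg),
      direction = dir,
      mean_delta_rt = as.numeric(tapply(w$delta_rt, idx, mean)),
      min_q = as.numeric(tapply(w$q, idx, min)),
      n_windows = as.integer(tapply(w$q, idx, length)),
      span = GenomicRanges::width(mg)))
  }
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), mean_delta_rt = numeric(),
                      min_q = numeric(), n_windows = integer(),
                      span = numeric()))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allelic RT advance of a mutant over wild type, within a region
#'
#' Per 50 kb bin, `d = (mut_allele1 - mut_allele2) - (wt_allele1 -
#' wt_allele2)`: the mutant's allelic RT difference normalized for the
#' baseline allelic difference seen in wild type. Returns the mean over
#' unmasked region bins plus the per-bin values (for replicate-range
#' error bars).
#'
#' @param mut_a1,mut_a2,wt_a1,wt_a2 `rt_profile`s of the two alleles in
#'   mutant and wild type, on a shared grid.
#' @param region `GRanges` (length 1) or `data.frame(chrom, start, end)`
#'   with 0-based half-open coordinates, bin-aligned.
#' @return List: `mean_advance` (log2 units) and `per_bin`
#'   (`data.frame(chrom, start, end, d)`).
#' @export
allelic_rt_advance <- function(mut_a1, mut_a2, wt_a1, wt_a2, region) {
  grid <- mut_a1$grid
  if (is.data.frame(region))
    region <- GenomicRanges::GRanges(region$chrom,
                                     IRanges::IRanges(region$start + 1, region$end))
  sel <- S4Vectors::queryHits(GenomicRanges::findOverlaps(grid, region,
                                                          type = "within"))
  if (length(sel) == 0) stop("region covers no whole bin")
  mask <- mut_a1$mask & mut_a2$mask & wt_a1$mask & wt_a2$mask
  sel <- sel[mask[sel]]
  if (length(sel) == 0) stop("all bins in the region are masked")
  d <- (mut_a1$values[sel] - mut_a2$values[sel]) -
    (wt_a1$values[sel] - wt_a2$values[sel])
  per_bin <- window_frame(grid)[sel, , drop = FALSE]
  per_bin$d <- d
  rownames(per_bin) <- NULL
  list(mean_advance = mean(d), per_bin = per_bin)
}

#' Flag windows whose RT differs significantly from wild type
#'
#' Monte-Carlo window test of a sample against the wild-type reference,
#' flagging windows with `p < p_cut` (the windows that would be shaded on
#' an RT track figure).
#'
#' @param sample_profiles,wt_profiles Lists of `rt_profile` replicates.
#' @inheritParams monte_carlo_window_test
#' @param p_cut Flagging threshold on the MC p-value.
#' @return Window table as [monte_carlo_window_test()] plus logical
#'   `significant`.
#' @export
significance_vs_wt <- function(sample_profiles, wt_profiles, n_mc = 1e5,
                               seed = 1L, p_cut = 0.01) {
  res <- monte_carlo_window_test(wt_profiles, sample_profiles,
                                 n_mc = n_mc, seed = seed)
  res$significant <- res$p < p_cut
  res
}
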