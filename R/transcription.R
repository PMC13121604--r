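as_region_granges <- function(regions) {
  if (is.data.frame(regions))
    GenomicRanges::GRanges(regions$chrom,
                           IRanges::IRanges(regions$start + 1, regions$end))
  else regions
}

#' Region transcription in RPKM
#'
#' Reads in each region (overlap-apportioned from the coverage track)
#' divided by region length in kb and library size in millions:
#' `RPKM = reads / (kb * millions)`. Strand-agnostic.
#'
#' @param track Coverage `GRanges` with `score` = read counts.
#' @param regions `GRanges` or `data.frame(chrom, start, end)` (0-based
#'   half-open).
#' @param library_size Total mapped reads of the library.
#' @return Numeric RPKM per region.
#' @export
region_rpkm <- function(track, regions, library_size) {
  stopifnot_scalar_number(library_size, "library_size", positive = TRUE)
  gr <- as_region_granges(regions)
  if (any(IRanges::width(gr) <= 0)) stop("zero-length region")
  hits <- GenomicRanges::findOverlaps(track, gr, ignore.strand = TRUE)
  reads <- numeric(length(gr))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(track)[qh], GenomicRanges::ranges(gr)[sh]))
    contrib <- S4Vectors::mcols(track)$score[qh] * ov /
      IRanges::width(track)[qh]
    agg <- rowsum(contrib, sh)
    reads[as.integer(rownames(agg))] <- agg[, 1]
  }
  reads / ((IRanges::width(gr) / 1000) * (library_size / 1e6))
}

#' Per-replicate RPKM matrix over regions, for one condition
#'
#' @param tx A `tx_coverage` (or list with `grid`, `counts`, `samples`,
#'   `library_size`).
#' @param regions Regions as in [region_rpkm()].
#' @param condition Condition label to select replicate columns.
#' @return Matrix regions x replicates.
#' @export
region_rpkm_matrix <- function(tx, regions, condition) {
  sel <- which(tx$samples$condition == condition)
  if (!length(sel)) stop("no replicates for condition ", condition)
  gr <- as_region_granges(regions)
  out <- vapply(sel, function(j)
    region_rpkm(grid_granges_with_score(tx$grid, tx$counts[, j]), gr,
                tx$library_size),
    numeric(length(gr)))
  matrix(out, nrow = length(gr),
         dimnames = list(NULL, tx$samples$sample[sel]))
}

#' Intergenic-shuffle transcription noise threshold
#'
#' Places the RT-advancing regions uniformly at random inside intergenic
#' space `n_shuffles` times, computes each placement's RPKM (averaged
#' over the supplied replicate tracks), and takes a high quantile of the
#' pooled shuffled RPKMs as the transcriptional noise threshold: regions
#' below it are indistinguishable from gene-free background.
#'
#' @param tx `tx_coverage` supplying the replicate tracks.
#' @param condition Condition whose replicates to average.
#' @param regions RT-advancing regions to shuffle.
#' @param genes Gene spans (`GRanges`) defining the excluded space.
#' @param layout [genome_layout()].
#' @param n_shuffles Number of shuffles.
#' @param quantile_p Quantile of the pooled shuffled RPKMs (default 0.99).
#' @param seed Integer seed.
#' @return List of class `noise_threshold`: `threshold` (RPKM),
#'   `quantile`, `n_shuffles`, `sample` (pooled shuffled RPKMs, for the
#'   diagnostic plot).
#' @export
noise_threshold <- function(tx, condition, regions, genes, layout,
                            n_shuffles = 100, quantile_p = 0.99, seed = 1L) {
  stopifnot(quantile_p > 0, quantile_p <= 1)
  allowed <- intergenic(genes, layout)
  gr <- as_region_granges(regions)
  shuffles <- shuffle_into(gr, allowed, n_shuffles = n_shuffles, seed = seed)
  pooled <- unlist(lapply(shuffles, function(s)
    rowMeans(region_rpkm_matrix(tx, s, condition))))
  structure(list(threshold = as.numeric(quantile(pooled, quantile_p,
                                                 names = FALSE)),
                 quantile = quantile_p, n_shuffles = n_shuffles,
                 sample = pooled),
            class = "noise_threshold")
}

#' @export
print.noise_threshold <- function(x, ...) {
  cat(sprintf("noise_threshold: %.4g RPKM (q = %.3g over %d shuffles, %d placements)\n",
              x$threshold, x$quantile, x$n_shuffles, length(x$sample)))
  invisible(x)
}

#' Paired t-test of transcription change per region
#'
#' Two-sided paired t-test on per-replicate RPKM (condition 2 vs 1;
#' replicates paired by column position), with
#' `log2 FC = log2((mean2 + c) / (mean1 + c))` for pseudocount `c`.
#' Zero-variance differences give `p = 1` when the difference is 0 and a
#' `NA` sentinel otherwise.
#'
#' @param rpkm_1,rpkm_2 Matrices regions x replicates (same shape).
#' @param pseudocount Pseudocount `c` in RPKM for the fold change.
#' @return `data.frame(mean_rpkm_1, mean_rpkm_2, log2_fc, p, degenerate)`.
#' @export
transcription_change_test <- function(rpkm_1, rpkm_2, pseudocount = 0.01) {
  stopifnot(all(dim(rpkm_1) == dim(rpkm_2)), ncol(rpkm_1) >= 2,
            pseudocount > 0)
  d <- rpkm_2 - rpkm_1
  n <- ncol(d)
  md <- rowMeans(d)
  vd <- (rowSums(d^2) - n * md^2) / (n - 1)
  vd <- pmax(vd, 0)
  tt <- md / sqrt(vd / n)
  p <- 2 * pt(-abs(tt), n - 1)
  degenerate <- vd == 0
  p[degenerate & md == 0] <- 1
  p[degenerate & md != 0] <- NA_real_
  m1 <- rowMeans(rpkm_1); m2 <- rowMeans(rpkm_2)
  data.frame(mean_rpkm_1 = m1, mean_rpkm_2 = m2,
             log2_fc = log2((m2 + pseudocount) / (m1 + pseudocount)),
             p = p, degenerate = degenerate)
}

#' Assign each region an RT direction from called switching regions
#'
#' A region is labelled `advance` or `delay` when at least half of it is
#' covered by called switching regions of that direction, `no-change`
#' otherwise.
#'
#' @param regions Regions (`GRanges` or data.frame, 0-based half-open).
#' @param switch_regions Output of [call_switch_regions()].
#' @param min_cover Minimum covered fraction to inherit a direction.
#' @return Character vector of RT labels.
#' @export
label_rt_direction <- function(regions, switch_regions, min_cover = 0.5) {
  gr <- as_region_granges(regions)
  lab <- rep("no-change", length(gr))
  best <- rep(0, length(gr))
  for (dir in c("advance", "delay")) {
    sw <- switch_regions[switch_regions$direction == dir, , drop = FALSE]
    if (!nrow(sw)) next
    sg <- GenomicRanges::reduce(as_region_granges(sw))
    hits <- GenomicRanges::findOverlaps(gr, sg)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gr)[qh],
      GenomicRanges::ranges(sg)[S4Vectors::subjectHits(hits)]))
    cov <- rep(0, length(gr))
    agg <- rowsum(ov, qh)
    cov[as.integer(rownames(agg))] <- agg[, 1]
    frac <- cov / IRanges::width(gr)
    take <- frac >= min_cover & frac > best
    lab[take] <- dir
    best <- pmax(best, frac)
  }
  lab
}

#' Classify regions jointly by RT and transcription behaviour
#'
#' Transcription is `sig_up` / `sig_down` when the paired-test p-value is
#' below `p_cut` (split by fold-change sign); otherwise `ns_expressed` or
#' `ns_silent` by whether the condition-2 mean RPKM clears the noise
#' threshold. Cross-tabulated against the RT direction
#' (`advance` / `delay` / `no-change`). Every region lands in exactly one
#' cell.
#'
#' @param rt_label Character RT direction per region
#'   (from [label_rt_direction()] or truth).
#' @param change Output of [transcription_change_test()] for the same
#'   regions.
#' @param p_cut Transcription significance threshold (p, uncorrected).
#' @param noise A `noise_threshold` (or a bare RPKM number).
#' @return List of class `rt_tx_classification`: `labels` (per-region
#'   `data.frame(rt, tx, class)`) and `table` (RT x transcription counts).
#' @export
classify_regions <- function(rt_label, change, p_cut = 0.01, noise) {
  thr <- if (inherits(noise, "noise_threshold")) noise$threshold else noise
  stopifnot(length(rt_label) == nrow(change), is.numeric(thr))
  if (any(is.na(rt_label))) stop("region with missing RT label: row ",
                                 which(is.na(rt_label))[1])
  sig <- !is.na(change$p) & change$p < p_cut
  tx <- ifelse(sig, ifelse(change$log2_fc > 0, "sig_up", "sig_down"),
               ifelse(change$mean_rpkm_2 >= thr, "ns_expressed", "ns_silent"))
  rt <- factor(rt_label, levels = c("advance", "delay", "no-change"))
  txf <- factor(tx, levels = c("sig_up", "sig_down", "ns_expressed", "ns_silent"))
  labels <- data.frame(rt = as.character(rt), tx = tx,
                       class = paste(rt, tx, sep = ":"))
  structure(list(labels = labels, table = table(rt = rt, tx = txf)),
            class = "rt_tx_classification")
}

#' @export
print.rt_tx_classification <- function(x, ...) {
  cat("RT x transcription classification of", nrow(x$labels), "regions\n")
  print(x$table)
  invisible(x)
}

#' Integrate RT and transcription changes over replication domains
#'
#' For each domain, the mean unmasked RT per replicate feeds a paired
#' t-test for RT change, and the domain RPKM per replicate feeds a paired
#' t-test for transcription change; domains whose RT is entirely masked
#' in some replicate are excluded and flagged.
#'
#' @param domains Domain intervals (`GRanges` or data.frame, 0-based
#'   half-open).
#' @param profiles_A,profiles_B Lists of `rt_profile` replicates (paired
#'   by position across conditions).
#' @param tx `tx_coverage` with both conditions.
#' @param conditions Length-2 character, condition labels in `tx`.
#' @param pseudocount Fold-change pseudocount (RPKM).
#' @return `data.frame`: domain coordinates, `delta_rt`, `p_rt`,
#'   `mean_rpkm_1`, `mean_rpkm_2`, `log2_fc`, `p_tx`, `excluded`.
#' @export
domain_integration <- function(domains, profiles_A, profiles_B, tx,
                               conditions = unique(tx$samples$condition),
                               pseudocount = 0.01) {
  gr <- as_region_granges(domains)
  grid <- profiles_A[[1]]$grid
  hits <- GenomicRanges::findOverlaps(grid, gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  domain_rt <- function(p) {
    use <- p$mask[qh]
    s <- rowsum(ifelse(use, p$values[qh], 0), sh)
    n <- rowsum(as.numeric(use), sh)
    out <- rep(NA_real_, length(gr))
    idx <- as.integer(rownames(s))
    out[idx] <- ifelse(n[, 1] > 0, s[, 1] / n[, 1], NA_real_)
    out
  }
  rtA <- vapply(profiles_A, domain_rt, numeric(length(gr)))
  rtB <- vapply(profiles_B, domain_rt, numeric(length(gr)))
  excluded <- apply(cbind(rtA, rtB), 1, function(z) any(!is.finite(z)))

  n <- ncol(rtA)
  d <- rtB - rtA
  md <- rowMeans(d)
  vd <- pmax((rowSums(d^2) - n * md^2) / (n - 1), 0)
  p_rt <- 2 * pt(-abs(md / sqrt(vd / n)), n - 1)
  p_rt[vd == 0 & md == 0] <- 1
  p_rt[vd == 0 & md != 0] <- NA_real_

  r1 <- region_rpkm_matrix(tx, gr, conditions[1])
  r2 <- region_rpkm_matrix(tx, gr, conditions[2])
  txc <- transcription_change_test(r1, r2, pseudocount = pseudocount)

  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    delta_rt = md, p_rt = p_rt,
                    mean_rpkm_1 = txc$mean_rpkm_1,
                    mean_rpkm_2 = txc$mean_rpkm_2,
                    log2_fc = txc$log2_fc, p_tx = txc$p,
                    excluded = excluded)
  out$delta_rt[excluded] <- NA_real_
  out$p_rt[excluded] <- NA_real_
  out
}

#' Count exact-barcode reads in a FASTQ file (RPM)
#'
#' A read counts for a barcode iff the exact 16-mer occurs as a substring
#' of the read sequence (a read containing it twice counts once);
#' reverse-complement matching is off by default. RPM normalizes by the
#' library's total read count.
#'
#' @param fastq Path to a FASTQ file (plain or gzipped).
#' @param barcodes Character vector of 16-mers over \{A, C, G, T\}.
#' @param total_reads Library size for RPM (defaults to the number of
#'   reads in the file).
#' @param revcomp Also match the reverse complement.
#' @return `data.frame(barcode, count, rpm)`.
#' @export
count_barcode_reads <- function(fastq, barcodes, total_reads = NULL,
                                revcomp = FALSE) {
  if (any(nchar(barcodes) != 16))
    stop("barcodes must be exactly 16 nt")
  if (any(grepl("[^ACGT]", barcodes)))
    stop("barcodes must use the ACGT alphabet only")
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  if (is.null(total_reads)) total_reads <- length(reads)
  stopifnot_scalar_number(total_reads, "total_reads", positive = TRUE)
  counts <- vapply(barcodes, function(bc) {
    hit <- Biostrings::vcountPattern(bc, reads, fixed = TRUE) > 0
    if (revcomp) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(bc)))
      hit <- hit | Biostrings::vcountPattern(rc, reads, fixed = TRUE) > 0
    }
    sum(hit)
  }, numeric(1))
  data.frame(barcode = barcodes, count = as.integer(counts),
             rpm = counts / total_reads * 1e6, row.names = NULL)
}
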