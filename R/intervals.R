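#' Apportion a coverage track onto a bin grid
#'
#' Each track interval's value is split across the bins it overlaps in
#' proportion to the overlap length, so total signal is conserved exactly
#' (an interval fully inside one bin contributes its whole value there).
#'
#' @param track `GRanges` with numeric `score` (e.g. from [read_bedgraph()]).
#' @param grid Bin `GRanges` from [bin_grid()].
#' @return Numeric vector of per-bin totals, `length(grid)`.
#' @examples
#' layout <- genome_layout(c(chr1 = 200e3))
#' grid <- bin_grid(layout, 50e3)
#' trk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100e3), score = 10)
#' bin_coverage(trk, grid)  # 5 5 0 0
#' @export
bin_coverage <- function(track, grid) {
  if (!"score" %in% names(S4Vectors::mcols(track)))
    stop("track must carry a numeric 'score' column")
  known <- unique(as.character(GenomicRanges::seqnames(grid)))
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(track))), known)
  if (length(bad))
    stop("track entries on chromosome(s) absent from the grid: ",
         paste(bad, collapse = ", "))
  hits <- GenomicRanges::findOverlaps(track, grid, ignore.strand = TRUE)
  out <- numeric(length(grid))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(track)[qh], GenomicRanges::ranges(grid)[sh]))
    contrib <- S4Vectors::mcols(track)$score[qh] * ov /
      IRanges::width(track)[qh]
    agg <- rowsum(contrib, sh)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Merge intervals allowing a gap (bedtools `merge -d` semantics)
#'
#' Intervals on the same chromosome whose separation (start of next minus
#' end of previous) is less than or equal to `gap` are merged; intervals on
#' different chromosomes never merge. Idempotent for fixed `gap`.
#'
#' @param gr `GRanges`.
#' @param gap Maximum separation in bp (>= 0).
#' @return Merged, sorted `GRanges`.
#' @export
merge_with_gap <- function(gr, gap = 0) {
  stopifnot(gap >= 0)
  GenomicRanges::reduce(GenomicRanges::sort(gr, ignore.strand = TRUE),
                        min.gapwidth = gap + 1, ignore.strand = TRUE)
}

#' Count genes overlapping each region
#'
#' Overlap by >= 1 bp, strand-agnostic.
#'
#' @param regions,genes `GRanges`.
#' @return Integer vector, one count per region.
#' @export
intersect_count <- function(regions, genes) {
  GenomicRanges::countOverlaps(regions, genes, ignore.strand = TRUE)
}

#' Bucket per-region gene counts into \{0, 1, >1\}
#'
#' Helper for the gene-count histogram over switching regions.
#'
#' @param counts Integer vector from [intersect_count()].
#' @return Named integer vector with entries `"0"`, `"1"`, `">1"`.
#' @export
gene_count_histogram <- function(counts) {
  c("0" = sum(counts == 0L), "1" = sum(counts == 1L), ">1" = sum(counts > 1L))
}

#' Intergenic complement of a gene set
#'
#' Set complement of the merged gene spans, per chromosome, over the whole
#' layout. `union(genes, intergenic(genes))` tiles every chromosome.
#'
#' @param genes `GRanges` of gene spans.
#' @param layout [genome_layout()].
#' @return Unstranded `GRanges` of intergenic space.
#' @export
intergenic <- function(genes, layout) {
  genome <- GenomicRanges::GRanges(
    names(layout), IRanges::IRanges(1, as.numeric(layout)),
    seqinfo = layout_seqinfo(layout))
  if (length(genes) == 0) return(genome)
  g <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  GenomeInfoDb::seqlevels(g, pruning.mode = "coarse") <- names(layout)
  GenomeInfoDb::seqinfo(g) <- layout_seqinfo(layout)
  GenomicRanges::setdiff(genome, g, ignore.strand = TRUE)
}

#' Randomly re-place regions inside an allowed set
#'
#' Each region keeps its length and is placed uniformly at random over all
#' eligible start positions that keep it fully inside one allowed interval
#' (the null placement used for the intergenic transcription-noise
#' threshold). Placements are independent across regions and shuffles, so
#' shuffled regions may overlap one another unless `allow_self_overlap` is
#' `FALSE`, in which case placements within one shuffle are drawn by
#' rejection until disjoint.
#'
#' @param regions `GRanges` to re-place.
#' @param allowed `GRanges` of allowed space (e.g. from [intergenic()]).
#' @param n_shuffles Number of independent shuffles.
#' @param seed Integer seed; placements are deterministic given it.
#' @param allow_self_overlap Allow shuffled regions to overlap one another
#'   within a shuffle (default `TRUE`, the bedtools-shuffle-like null).
#' @return List of `n_shuffles` `GRanges`, each parallel to `regions`.
#' @export
shuffle_into <- function(regions, allowed, n_shuffles = 1, seed = NULL,
                         allow_self_overlap = TRUE) {
  allowed <- GenomicRanges::reduce(GenomicRanges::sort(allowed, ignore.strand = TRUE),
                                   ignore.strand = TRUE)
  aw <- IRanges::width(allowed)
  achr <- as.character(GenomicRanges::seqnames(allowed))
  astart <- GenomicRanges::start(allowed)
  rw <- IRanges::width(regions)
  too_long <- rw > max(aw)
  if (any(too_long))
    stop("region(s) longer than every allowed interval: ",
         paste(utils::head(which(too_long), 5), collapse = ", "))

  place_one <- function(len) {
    # eligible start count in allowed interval i: max(0, aw[i] - len + 1)
    elig <- pmax(0, aw - len + 1)
    i <- sample.int(length(allowed), 1, prob = elig)
    off <- sample.int(elig[i], 1) - 1L
    c(i, off)
  }

  with_seed(seed, {
    lapply(seq_len(n_shuffles), function(s) {
      repeat {
        picks <- vapply(rw, place_one, numeric(2))
        idx <- picks[1, ]
        st <- astart[idx] + picks[2, ]
        gr <- GenomicRanges::GRanges(achr[idx], IRanges::IRanges(st, width = rw))
        if (allow_self_overlap ||
            !any(GenomicRanges::countOverlaps(gr, gr) > 1L))
          return(gr)
      }
    })
  })
}
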