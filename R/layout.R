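#' Genome layout: ordered chromosomes and their lengths
#'
#' A thin constructor around a named integer vector of chromosome lengths,
#' the coordinate frame every other object in the package is laid out on.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a two-column data.frame
#'   (chrom, length).
#' @return Named numeric vector of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 50e6, chr2 = 50e6))
#' @export
genome_layout <- function(lengths) {
  if (is.data.frame(lengths)) {
    stopifnot(ncol(lengths) >= 2)
    lengths <- setNames(as.numeric(lengths[[2]]), as.character(lengths[[1]]))
  }
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("chromosome names must be present and unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(lengths, class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  invisible(x)
}

layout_seqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = names(layout),
                        seqlengths = as.integer(unclass(layout)))
}

#' Drop chromosomes from a layout
#'
#' Chromosome-exclusion filter applied before any statistics (e.g. dropping
#' a chromosome that is homozygous in one clone and therefore not
#' allele-resolvable).
#'
#' @param layout A [genome_layout()].
#' @param exclude Character vector of chromosome names to drop.
#' @return Filtered `genome_layout`.
#' @export
exclude_chromosomes <- function(layout, exclude) {
  keep <- !(names(layout) %in% exclude)
  if (!any(keep)) stop("excluding every chromosome leaves an empty layout")
  genome_layout(setNames(as.numeric(layout)[keep], names(layout)[keep]))
}

#' Tile a genome into fixed-width bins
#'
#' Builds the half-open bin grid (50 kb for statistics, 5 kb for display
#' profiles) as a `GRanges`; the last bin on each chromosome is truncated at
#' the chromosome end, so bins tile each chromosome without gaps or
#' overlaps.
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @return `GRanges` of bins, in layout order.
#' @examples
#' bin_grid(genome_layout(c(chr1 = 120e3)), 50e3)  # 3 bins, last 20 kb
#' @export
bin_grid <- function(layout, bin_size = 50000) {
  stopifnot_scalar_number(bin_size, "bin_size", positive = TRUE)
  si <- layout_seqinfo(layout)
  gr <- GenomicRanges::tileGenome(si, tilewidth = bin_size,
                                  cut.last.tile.in.chrom = TRUE)
  gr
}

#' Read / write a two-column chrom.sizes table
#'
#' @param path File path; tab- or space-delimited `chrom<TAB>length` rows.
#' @return [genome_layout()] for the reader; invisibly `path` for the writer.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  genome_layout(setNames(df$length, df$chrom))
}

#' @rdname read_chrom_sizes
#' @param layout Layout to write.
#' @export
write_chrom_sizes <- function(layout, path) {
  write.table(data.frame(names(layout), format(as.numeric(layout), scientific = FALSE, trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
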