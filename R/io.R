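#' Read a bedGraph coverage track
#'
#' bedGraph entries are 0-based half-open on disk; the returned `GRanges`
#' uses the usual 1-based closed convention, with the value in `score`.
#' `track`/`browser` header lines and space or tab delimiters are tolerated
#' (both are legal bedGraph).
#'
#' @param path Path to a bedGraph file.
#' @param layout Optional [genome_layout()]; if given, entries are checked
#'   against it and the result carries its seqinfo.
#' @return `GRanges` with numeric `score`.
#' @export
read_bedgraph <- function(path, layout = NULL) {
  # rtracklayer handles plain tab-delimited files; normalize mixed
  # space/tab delimiters and drop track/browser headers first so both
  # legal bedGraph dialects are accepted
  head_lines <- readLines(path, n = 50)
  if (any(grepl("^(track|browser|#)", head_lines)) ||
      any(grepl("[^\t]* [^\t]*", head_lines))) {
    all_lines <- readLines(path)
    all_lines <- all_lines[!grepl("^(track|browser|#)", all_lines)]
    all_lines <- gsub("[ \t]+", "\t", trimws(all_lines))
    tmp <- tempfile(fileext = ".bedGraph")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(all_lines[nzchar(all_lines)], tmp)
    path <- tmp
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(layout)) {
    bad <- setdiff(as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(gr))),
                   names(layout))
    bad <- intersect(bad, unique(as.character(GenomicRanges::seqnames(gr))))
    if (length(bad))
      stop("bedGraph entries on unknown chromosome(s): ",
           paste(bad, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(layout)
    GenomeInfoDb::seqinfo(gr) <- layout_seqinfo(layout)
  }
  gr
}

#' Write a bedGraph coverage track
#'
#' Emits tab-delimited, position-sorted 4-column bedGraph (0-based
#' half-open). Zero-score intervals are kept so round-trips are lossless.
#'
#' @param gr `GRanges` with a numeric `score` column.
#' @param path Output path.
#' @export
write_bedgraph <- function(gr, path) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED6 (or shorter) files; 0-based half-open on disk, `GRanges` in memory.
#'
#' @param path File path.
#' @param layout Optional [genome_layout()] used to validate and set seqinfo.
#' @return `GRanges` (reader); invisibly `path` (writer).
#' @export
read_bed <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(layout)) {
    bad <- intersect(setdiff(GenomeInfoDb::seqlevels(gr), names(layout)),
                     unique(as.character(GenomicRanges::seqnames(gr))))
    if (length(bad))
      stop("BED entries on unknown chromosome(s): ", paste(bad, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(layout)
    GenomeInfoDb::seqinfo(gr) <- layout_seqinfo(layout)
  }
  gr
}

#' @rdname read_bed
#' @param gr `GRanges` to write; `name`, `score` and strand are emitted when
#'   present.
#' @export
write_bed <- function(gr, path) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
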