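# Shared in-code fixtures for the suite.

# Single-chromosome profile on a 50 kb grid from bare values.
make_profile <- function(values, mask = rep(TRUE, length(values)),
                         bin = 50e3) {
  grid <- bin_grid(genome_layout(c(chr1 = length(values) * bin)), bin)
  rt_profile(grid, ifelse(mask, values, 0), mask)
}

# A GRanges on chr1 from 0-based half-open starts/ends.
gr1 <- function(starts, ends, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1, ends))
}

# GRanges from a chrom/start/end data.frame with alphabetical seqlevels,
# so output ordering matches a plain sort on (chrom, start).
gr_df <- function(df) {
  GenomicRanges::GRanges(factor(df$chrom, levels = sort(unique(df$chrom))),
                         IRanges::IRanges(df$start + 1, df$end))
}

# Brute-force interval merge with gap (independent of GenomicRanges).
brute_merge <- function(df, gap) {
  out <- NULL
  for (cn in sort(unique(df$chrom))) {
    d <- df[df$chrom == cn, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur_s <- d$start[1]; cur_e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] - cur_e <= gap) {
        cur_e <- max(cur_e, d$end[i])
      } else {
        out <- rbind(out, data.frame(chrom = cn, start = cur_s, end = cur_e))
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = cn, start = cur_s, end = cur_e))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Brute-force Benjamini-Hochberg by its definition.
brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- p >= p[i]
    min(1, min(m * p[cand] / rank(p, ties.method = "max")[cand]))
  }, numeric(1))
}

# Write a plain-text FASTQ from a character vector of sequences.
write_fastq <- function(seqs, path) {
  lines <- character(4 * length(seqs))
  lines[seq(1, length(lines), 4)] <- paste0("@read", seq_along(seqs))
  lines[seq(2, length(lines), 4)] <- seqs
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(lines, path)
  path
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Two-condition replicate profile sets with N(0, sd) noise around a base
# field, plus an optional per-bin shift applied to condition B.
noise_profiles <- function(n_bins, n_reps, sd = 0.2, shift = 0,
                           base = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(base)) base <- rnorm(n_bins, 0, 1)
  A <- lapply(seq_len(n_reps), function(i)
    make_profile(base + rnorm(n_bins, 0, sd)))
  B <- lapply(seq_len(n_reps), function(i)
    make_profile(base + shift + rnorm(n_bins, 0, sd)))
  list(A = A, B = B)
}

# Match planted regions against called switching regions: recovered iff a
# called region of the same direction overlaps with both boundaries within
# `tol` bp. Returns recovery flags and the false-call count.
match_regions <- function(truth, called, tol = 1e5) {
  tg <- gr1(truth$start, truth$end, truth$chrom)
  cg <- gr1(called$start, called$end, called$chrom)
  hit <- GenomicRanges::findOverlaps(tg, cg)
  rec <- logical(length(tg))
  used <- integer(0)
  for (i in seq_along(tg)) {
    js <- S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == i]
    js <- js[called$direction[js] == truth$direction[i]]
    for (j in js) {
      if (abs(called$start[j] - truth$start[i]) <= tol &&
          abs(called$end[j] - truth$end[i]) <= tol) {
        rec[i] <- TRUE; used <- c(used, j); break
      }
    }
  }
  matched_any <- unique(S4Vectors::subjectHits(hit)[
    called$direction[S4Vectors::subjectHits(hit)] ==
      truth$direction[S4Vectors::queryHits(hit)]])
  list(recovered = rec, false_calls = nrow(called) - length(matched_any))
}
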