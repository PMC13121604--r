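test_that("bin_coverage apportions by overlap and conserves signal", {
  layout <- genome_layout(c(chr1 = 200e3))
  grid <- bin_grid(layout, 50e3)

  trk <- gr1(0, 100e3); trk$score <- 10
  expect_equal(bin_coverage(trk, grid), c(5, 5, 0, 0))

  trk <- gr1(60e3, 70e3); trk$score <- 7
  expect_equal(bin_coverage(trk, grid), c(0, 7, 0, 0))

  trk <- gr1(25e3, 75e3); trk$score <- 4
  expect_equal(bin_coverage(trk, grid), c(2, 2, 0, 0))

  # conservation on random tracks
  set.seed(42)
  for (rep in 1:20) {
    st <- sort(sample(0:190e3, 30))
    en <- pmin(st + sample(1e3:40e3, 30, replace = TRUE), 200e3)
    keep <- en > st
    trk <- gr1(st[keep], en[keep]); trk$score <- runif(sum(keep), 0, 50)
    expect_equal(sum(bin_coverage(trk, grid)), sum(trk$score),
                 tolerance = 1e-9)
  }

  bad <- GenomicRanges::GRanges("chrUn", IRanges::IRanges(1, 10))
  bad$score <- 1
  expect_error(bin_coverage(bad, grid), "chrUn")
})

test_that("merge_with_gap matches bedtools -d semantics and brute force", {
  # separation 250k <= 300k gap: all merged
  m <- merge_with_gap(gr1(c(0, 50e3, 350e3), c(50e3, 100e3, 400e3)), 300e3)
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::start(m) - 1, 0)
  expect_equal(GenomicRanges::end(m), 400e3)

  # adjacency at gap 0
  m <- merge_with_gap(gr1(c(0, 50e3), c(50e3, 100e3)), 0)
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::end(m), 100e3)

  # separation exactly gap merges; gap+1 does not
  m <- merge_with_gap(gr1(c(0, 150e3), c(100e3, 200e3)), 50e3)
  expect_equal(length(m), 1L)
  m <- merge_with_gap(gr1(c(0, 150e3 + 1), c(100e3, 200e3)), 50e3)
  expect_equal(length(m), 2L)

  # different chromosomes never merge
  g <- GenomicRanges::GRanges(c("chr1", "chr2"),
                              IRanges::IRanges(c(1, 1), c(100, 100)))
  expect_equal(length(merge_with_gap(g, 1e9)), 2L)

  set.seed(7)
  for (rep in 1:100) {
    n <- sample(2:30, 1)
    df <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = sample(0:500, n) * 1e3)
    df$end <- df$start + sample(1:100, n, replace = TRUE) * 1e3
    gap <- sample(c(0, 50e3, 300e3), 1)
    got <- merge_with_gap(gr_df(df), gap)
    want <- brute_merge(df, gap)
    expect_equal(as.character(GenomicRanges::seqnames(got)), want$chrom)
    expect_equal(GenomicRanges::start(got) - 1, want$start)
    expect_equal(GenomicRanges::end(got), want$end)
    # idempotence
    again <- merge_with_gap(got, gap)
    expect_identical(GenomicRanges::ranges(got), GenomicRanges::ranges(again))
  }
})

test_that("intersect_count matches a quadratic all-pairs oracle", {
  regions <- gr1(0, 100e3)
  genes <- gr1(c(10e3, 150e3), c(20e3, 160e3))
  expect_equal(intersect_count(regions, genes), 1L)
  expect_equal(intersect_count(regions, GenomicRanges::GRanges()), 0L)

  set.seed(11)
  for (rep in 1:20) {
    r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      start = sample(0:900, 15) * 1e3 + 1, width = sample(1e3:80e3, 15)))
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      start = sample(0:900, 25) * 1e3 + 1, width = sample(1e3:50e3, 25)))
    oracle <- vapply(seq_along(r), function(i)
      sum(GenomicRanges::start(g) <= GenomicRanges::end(r)[i] &
            GenomicRanges::end(g) >= GenomicRanges::start(r)[i]), numeric(1))
    expect_equal(intersect_count(r, g), as.integer(oracle))
  }
  expect_equal(gene_count_histogram(c(0L, 0L, 1L, 3L, 2L)),
               c("0" = 2L, "1" = 1L, ">1" = 2L))
})

test_that("intergenic complement tiles the genome", {
  layout <- genome_layout(c(chr1 = 1e6))
  expect_equal(IRanges::width(intergenic(GenomicRanges::GRanges(), layout)),
               1e6)
  ig <- intergenic(gr1(100e3, 200e3), layout)
  expect_equal(GenomicRanges::start(ig) - 1, c(0, 200e3))
  expect_equal(GenomicRanges::end(ig), c(100e3, 1e6))

  set.seed(3)
  layout2 <- genome_layout(c(chr1 = 1e6, chr2 = 5e5))
  for (rep in 1:10) {
    st <- sample(0:900, 12) * 1e3
    g <- GenomicRanges::GRanges(
      factor(sample(names(layout2), 12, replace = TRUE),
             levels = names(layout2)),
      IRanges::IRanges(st + 1, st + sample(1e3:90e3, 12)))
    g <- g[GenomicRanges::end(g) <= as.numeric(layout2)[
      match(as.character(GenomicRanges::seqnames(g)), names(layout2))]]
    comp <- intergenic(g, layout2)
    expect_equal(sum(IRanges::width(comp)) +
                   sum(IRanges::width(GenomicRanges::reduce(g, ignore.strand = TRUE))),
                 sum(as.numeric(layout2)))
    expect_length(GenomicRanges::findOverlaps(comp, g), 0)
    # complement of the complement is the merge of the input
    back <- intergenic(comp, layout2)
    expect_identical(GenomicRanges::ranges(back),
                     GenomicRanges::ranges(GenomicRanges::reduce(
                       GenomicRanges::sort(g), ignore.strand = TRUE)))
  }
})

test_that("shuffle_into respects containment, determinism and uniformity", {
  layout <- genome_layout(c(chr1 = 300e3))
  allowed <- intergenic(gr1(100e3, 200e3), layout)
  region <- gr1(0, 50e3)

  draws <- shuffle_into(region, allowed, n_shuffles = 1000, seed = 9)
  starts <- vapply(draws, function(g) GenomicRanges::start(g) - 1, numeric(1))
  expect_true(all(starts <= 50e3 | (starts >= 200e3 & starts <= 250e3)))
  for (g in draws[1:50])
    expect_length(GenomicRanges::findOverlaps(g, gr1(100e3, 200e3)), 0)

  # forced placement: region as long as the only allowed interval
  whole <- intergenic(GenomicRanges::GRanges(), layout)
  one <- shuffle_into(gr1(0, 300e3), whole, n_shuffles = 5, seed = 1)
  expect_true(all(vapply(one, function(g) GenomicRanges::start(g) == 1,
                         logical(1))))

  expect_identical(shuffle_into(region, allowed, 10, seed = 4),
                   shuffle_into(region, allowed, 10, seed = 4))

  expect_error(shuffle_into(gr1(0, 150e3), allowed, 1, seed = 1),
               "longer than every allowed")

  # uniformity over eligible starts: chi-squared not rejected at 0.001
  draws <- shuffle_into(region, allowed, n_shuffles = 10000, seed = 2)
  starts <- vapply(draws, function(g) GenomicRanges::start(g) - 1, numeric(1))
  eligible <- ifelse(starts <= 50e3, starts, starts - 150e3)  # fold to 0..100k
  bucket <- cut(eligible, breaks = seq(0, 100001, length.out = 11),
                include.lowest = TRUE)
  expect_gt(stats::chisq.test(table(bucket))$p.value, 0.001)
})

test_that("bedGraph, BED and chrom.sizes round-trip losslessly", {
  layout <- genome_layout(c(chr1 = 500e3, chr2 = 200e3))
  td <- withr::local_tempdir()

  p <- file.path(td, "x.chrom.sizes")
  write_chrom_sizes(layout, p)
  expect_equal(unclass(read_chrom_sizes(p)), unclass(layout),
               ignore_attr = TRUE)
  expect_equal(names(read_chrom_sizes(p)), names(layout))

  gr <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                               IRanges::IRanges(c(1, 50001, 1),
                                                c(50000, 100000, 200000)))
  gr$score <- c(1.5, 0, 42)
  bg <- file.path(td, "x.bedGraph")
  write_bedgraph(gr, bg)
  back <- read_bedgraph(bg, layout)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$score, gr$score)

  # header lines and space delimiters are tolerated
  messy <- file.path(td, "messy.bedGraph")
  writeLines(c("track type=bedGraph name=\"t\"",
               "chr1 0 50000 1.5",
               "chr1\t50000\t100000\t2.5"), messy)
  m <- read_bedgraph(messy)
  expect_equal(m$score, c(1.5, 2.5))
  expect_equal(GenomicRanges::start(m) - 1, c(0, 50000))

  bed <- file.path(td, "x.bed")
  g2 <- gr1(c(0, 100e3), c(50e3, 150e3))
  g2$name <- c("a", "b"); g2$score <- c(1, 2)
  GenomicRanges::strand(g2) <- c("+", "-")
  write_bed(g2, bed)
  b <- read_bed(bed, layout)
  expect_equal(GenomicRanges::start(b) - 1, c(0, 100e3))
  expect_equal(b$name, c("a", "b"))
  expect_equal(as.character(GenomicRanges::strand(b)), c("+", "-"))
  # on-disk coordinates are 0-based half-open
  raw <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_equal(as.numeric(raw[2:3]), c(0, 50e3))
})

test_that("chromosome exclusion filters the layout", {
  layout <- genome_layout(c(chr1 = 1e6, chr9 = 1e6, chrX = 1e6))
  kept <- exclude_chromosomes(layout, c("chr9", "chrX"))
  expect_equal(names(kept), "chr1")
  expect_error(exclude_chromosomes(layout, names(layout)), "empty")
})
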