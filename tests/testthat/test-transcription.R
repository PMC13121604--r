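test_that("region RPKM follows reads / (kb * millions)", {
  grid <- bin_grid(genome_layout(c(chr1 = 500e3)), 50e3)
  track <- grid
  track$score <- c(2000, rep(0, 9))
  region <- data.frame(chrom = "chr1", start = 0, end = 100e3)
  expect_equal(region_rpkm(track, region, 20e6), 2000 / (100 * 20))

  empty <- data.frame(chrom = "chr1", start = 200e3, end = 300e3)
  expect_equal(region_rpkm(track, empty, 20e6), 0)

  expect_error(region_rpkm(track, gr1(1, 1), 20e6) , "zero-length|width|start")

  # RPKM over a union of disjoint equal-length regions is their mean
  track$score <- rpois(10, 100)
  parts <- data.frame(chrom = "chr1", start = c(0, 200e3), end = c(50e3, 250e3))
  per <- region_rpkm(track, parts, 1e6)
  joint <- (sum(track$score[c(1, 5)])) / (100 * 1)   # 100 kb total
  expect_equal(mean(per), joint, tolerance = 1e-12)
})

test_that("planted gene RPKM is recovered from simulated coverage", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), replicates = 4,
                    alleles = "both",
                    genes = data.frame(chrom = "chr1", start = 5e5, end = 6e5,
                                       strand = "+", name = "g",
                                       rpkm_A = 10, rpkm_B = 10),
                    background_rpkm = 0, library_size = 1e7, seed = 41)
  tx <- simulate_transcription(simulate_rt_field(cfg))
  m <- region_rpkm_matrix(tx, data.frame(chrom = "chr1", start = 5e5, end = 6e5),
                          "ESC")
  # expected count 1000 per replicate; 3 Poisson SD on the RPKM scale
  expect_true(all(abs(m - 10) < 3 * sqrt(1000) / 100))
})

test_that("the intergenic shuffle threshold separates noise from signal", {
  cfg <- demo_config(seed = 42, classes = c(advance_up = 2, advance_silent = 2),
                     chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                     span_range = c(4e5, 6e5), constitutive_genes = 10,
                     background_rpkm = 0.01)
  tr <- simulate_rt_field(cfg)
  tx <- simulate_transcription(tr)
  adv <- cfg$region_classes[grepl("advance", cfg$region_classes$class), ]
  genes <- gr1(cfg$genes$start, cfg$genes$end, cfg$genes$chrom)
  nt <- noise_threshold(tx, "NPC", adv, genes, cfg$layout,
                        n_shuffles = 50, quantile_p = 0.99, seed = 1)
  expect_gt(nt$threshold, 0.003)
  expect_lt(nt$threshold, 0.5)
  # planted silent regions fall below the threshold
  silent <- cfg$region_classes[cfg$region_classes$class == "advance_silent", ]
  rp <- rowMeans(region_rpkm_matrix(tx, silent, "NPC"))
  expect_true(all(rp < nt$threshold))
  # expressed planted genes sit far above it
  up <- cfg$region_classes[cfg$region_classes$class == "advance_up", ]
  expect_true(all(rowMeans(region_rpkm_matrix(tx, up, "NPC")) > nt$threshold))

  # nondecreasing in the quantile
  n90 <- noise_threshold(tx, "NPC", adv, genes, cfg$layout,
                         n_shuffles = 50, quantile_p = 0.90, seed = 1)
  expect_lte(n90$threshold, nt$threshold)

  # zero background, no genes: threshold 0
  cfg0 <- sim_config(chrom_lengths = c(chr1 = 1e7), replicates = 2,
                     alleles = "both", background_rpkm = 0, seed = 43)
  tx0 <- simulate_transcription(simulate_rt_field(cfg0))
  nt0 <- noise_threshold(tx0, "ESC",
                         data.frame(chrom = "chr1", start = 1e6, end = 1.4e6),
                         GenomicRanges::GRanges(), cfg0$layout,
                         n_shuffles = 10, seed = 2)
  expect_equal(nt0$threshold, 0)
})

test_that("paired transcription tests match the closed form", {
  set.seed(44)
  r1 <- matrix(runif(40, 1, 5), 10, 4)
  r2 <- r1 + 0.5 + matrix(rnorm(40, 0, 0.2), 10, 4)
  res <- transcription_change_test(r1, r2)
  for (i in 1:10)
    expect_equal(res$p[i], stats::t.test(r2[i, ], r1[i, ], paired = TRUE)$p.value,
                 tolerance = 1e-10)

  same <- transcription_change_test(r1, r1)
  expect_true(all(same$p == 1))
  expect_true(all(same$log2_fc == 0))

  # silent-to-induced fold change with pseudocount
  a <- matrix(0, 1, 4); b <- matrix(0.99, 1, 4)
  fc <- transcription_change_test(a, b, pseudocount = 0.01)
  expect_equal(fc$log2_fc, log2(100))
  expect_true(fc$degenerate)          # zero-variance difference sentinel
  expect_true(is.na(fc$p))
})

test_that("joint classification matches hand tabulation and partitions", {
  rt <- c("advance", "advance", "delay", "no-change", "no-change", "advance")
  change <- data.frame(
    mean_rpkm_1 = c(0, 2, 0, 0, 1, 3),
    mean_rpkm_2 = c(5, 0.5, 4, 0.02, 1.1, 3.1),
    log2_fc = c(8, -2, 7, 1, 0.1, 0.05),
    p = c(0.001, 0.004, 0.002, 0.5, 0.9, 0.2),
    degenerate = FALSE)
  cl <- classify_regions(rt, change, p_cut = 0.01, noise = 0.1)
  expect_equal(cl$labels$tx,
               c("sig_up", "sig_down", "sig_up", "ns_silent",
                 "ns_expressed", "ns_expressed"))
  tab <- cl$table
  expect_equal(sum(tab), 6)
  expect_equal(unname(tab["advance", "sig_up"]), 1)
  expect_equal(unname(tab["advance", "sig_down"]), 1)
  expect_equal(unname(tab["delay", "sig_up"]), 1)
  expect_equal(unname(tab["no-change", "ns_silent"]), 1)
  expect_equal(unname(tab["no-change", "ns_expressed"]), 1)
  expect_equal(unname(tab["advance", "ns_expressed"]), 1)

  # partition: every region in exactly one cell, any input
  set.seed(45)
  for (rep in 1:10) {
    n <- sample(3:40, 1)
    rt2 <- sample(c("advance", "delay", "no-change"), n, replace = TRUE)
    ch2 <- data.frame(mean_rpkm_1 = runif(n), mean_rpkm_2 = runif(n),
                      log2_fc = rnorm(n), p = runif(n), degenerate = FALSE)
    cl2 <- classify_regions(rt2, ch2, noise = 0.1)
    expect_equal(sum(cl2$table), n)
    expect_equal(nrow(cl2$labels), n)
  }

  # all below noise, no RT calls: a single populated cell
  ch3 <- data.frame(mean_rpkm_1 = rep(0, 4), mean_rpkm_2 = rep(0.01, 4),
                    log2_fc = rep(0.5, 4), p = rep(0.6, 4), degenerate = FALSE)
  cl3 <- classify_regions(rep("no-change", 4), ch3, noise = 0.1)
  expect_equal(unname(cl3$table["no-change", "ns_silent"]), 4)
  expect_equal(sum(cl3$table != 0), 1)
})

test_that("domain integration agrees with region-level quantification", {
  cfg <- demo_config(seed = 46, classes = c(advance_up = 2),
                     chrom_lengths = c(chr1 = 2e7), replicates = 3,
                     constitutive_genes = 5)
  tr <- simulate_rt_field(cfg)
  cov <- simulate_fraction_counts(tr)
  tx <- simulate_transcription(tr)
  profs <- compute_log2_ratio(cov)
  A <- profs[cov$samples$condition == "ESC"]
  B <- profs[cov$samples$condition == "NPC"]
  domains <- data.frame(chrom = "chr1",
                        start = seq(0, 1.8e7, by = 2e6),
                        end = seq(2e6, 2e7, by = 2e6))
  di <- domain_integration(domains, A, B, tx, conditions = c("ESC", "NPC"))
  expect_equal(nrow(di), 10L)
  expect_false(any(di$excluded))
  # domain RPKM equals region_rpkm on the same intervals
  m2 <- region_rpkm_matrix(tx, domains, "NPC")
  expect_equal(di$mean_rpkm_2, rowMeans(m2), tolerance = 1e-12)
  # planted advancing+induced domain classified advance+up
  rc <- cfg$region_classes[1, ]
  host <- which(domains$start <= rc$start & domains$end >= rc$end)
  if (length(host) == 1) {
    expect_lt(di$p_rt[host], 0.05)
    expect_gt(di$delta_rt[host], 0)
    expect_lt(di$p_tx[host], 0.05)
    expect_gt(di$log2_fc[host], 0)
  }
  # identical conditions: all RT p-values 1
  di0 <- domain_integration(domains, A, A, tx, conditions = c("ESC", "NPC"))
  expect_true(all(di0$p_rt == 1))
})

test_that("barcode counting matches an independent regex scan", {
  set.seed(47)
  bc <- c("ACGTACGTACGTACGT", paste(sample(c("A", "C", "G", "T"), 16,
                                           replace = TRUE), collapse = ""))
  reads <- random_dna(400, 60)
  # plant single and double occurrences of the first barcode
  reads[1:30] <- paste0(substr(reads[1:30], 1, 20), bc[1],
                        substr(reads[1:30], 37, 60))
  reads[31:35] <- paste0(bc[1], substr(reads[31:35], 17, 40), bc[1])
  td <- withr::local_tempdir()
  fq <- write_fastq(reads, file.path(td, "r.fastq"))

  res <- count_barcode_reads(fq, bc)
  oracle <- vapply(bc, function(b) sum(grepl(b, reads, fixed = TRUE)),
                   numeric(1))
  expect_equal(res$count, as.integer(oracle))
  expect_gte(res$count[1], 35)               # double occurrences count once
  expect_equal(res$rpm, oracle / 400 * 1e6, ignore_attr = TRUE)

  # 50 matches per million reads -> 50 RPM exactly
  res2 <- count_barcode_reads(fq, bc[1], total_reads = 1e6)
  expect_equal(res2$rpm, res2$count / 1e6 * 1e6)
  planted_only <- write_fastq(c(rep(paste0("TTTT", bc[1], "GGGG"), 50)),
                              file.path(td, "p.fastq"))
  expect_equal(count_barcode_reads(planted_only, bc[1],
                                   total_reads = 1e6)$rpm, 50)

  absent <- paste(rep("A", 16), collapse = "")
  expect_equal(count_barcode_reads(fq, absent)$count, 0L)

  expect_error(count_barcode_reads(fq, "ACGT"), "16")
  expect_error(count_barcode_reads(fq, "ACGTACGTACGTACGN"), "ACGT")

  # reverse-complement flag (barcode must not be its own palindrome)
  bc_rc <- "AAAAAAAACCCCCCCC"
  rcbc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(bc_rc)))
  fq2 <- write_fastq(c(paste0("TTTT", rcbc, "CCCC")), file.path(td, "rc.fastq"))
  expect_equal(count_barcode_reads(fq2, bc_rc)$count, 0L)
  expect_equal(count_barcode_reads(fq2, bc_rc, revcomp = TRUE)$count, 1L)
})
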