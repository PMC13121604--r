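#' Average replicate RT profiles
#'
#' Per-bin mean over the replicates' unmasked values; a bin is masked only
#' where every replicate is masked.
#'
#' @param profiles List of `rt_profile` on a shared grid.
#' @return A single `rt_profile`.
#' @export
average_profiles <- function(profiles) {
  vm <- profile_matrix(profiles)
  m <- rowSums(vm$mask) > 0
  v <- row_means_masked(vm)
  rt_profile(profiles[[1]]$grid, ifelse(m, v, 0), m,
             state = profiles[[1]]$state, sample = list(averaged = TRUE))
}

# Parse "advance_up" style class names into RT delta sign and expression.
parse_class <- function(cls, delta, expressed_rpkm) {
  parts <- strsplit(cls, "_", fixed = TRUE)[[1]]
  rt <- parts[1]; tx <- parts[2]
  if (!rt %in% c("advance", "delay", "nochange"))
    stop("unknown RT class part: ", rt)
  if (!tx %in% c("up", "silent", "expressed"))
    stop("unknown transcription class part: ", tx)
  list(delta = switch(rt, advance = delta, delay = -delta, nochange = 0),
       rpkm_A = if (tx == "expressed") expressed_rpkm else 0,
       rpkm_B = if (tx %in% c("up", "expressed")) expressed_rpkm else 0,
       has_gene = tx != "silent")
}

#' Build a study-scale demo configuration with planted classes
#'
#' Plants non-overlapping, bin-aligned regions of the requested joint
#' RT x transcription classes (`advance`/`delay`/`nochange` crossed with
#' `up` = induced from silence, `silent` = no gene, `expressed` =
#' constitutively expressed) at well-separated random positions, together
#' with constitutive background genes, on a 100 Mb two-chromosome genome
#' with 50 kb bins, 4 replicates per condition and a Poisson read depth of
#' 100 reads per bin per fraction.
#'
#' @param seed Integer seed controlling placement and all downstream draws.
#' @param classes Named integer vector: planted regions per class.
#' @param chrom_lengths,bin_size,replicates,lambda,alleles See [sim_config()].
#' @param delta Planted |RT change| (log2 units).
#' @param span_range Min/max planted region span (bp; rounded to bins).
#' @param expressed_rpkm RPKM of expressed/induced planted genes.
#' @param constitutive_genes Number of constitutive background genes.
#' @param constitutive_rpkm Their RPKM (both conditions).
#' @param min_separation Minimum distance between planted regions (bp).
#' @param ... Further arguments passed to [sim_config()].
#' @return A [sim_config()] whose `region_classes` table records the truth.
#' @export
demo_config <- function(seed = 1L,
                        classes = c(advance_up = 4, advance_silent = 4,
                                    delay_up = 4, nochange_up = 4,
                                    nochange_silent = 4),
                        chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                        bin_size = 50000, replicates = 4, lambda = 100,
                        alleles = "both", delta = 2,
                        span_range = c(2e5, 6e5), expressed_rpkm = 5,
                        constitutive_genes = 40, constitutive_rpkm = 2,
                        min_separation = 1.5e6, ...) {
  layout <- genome_layout(chrom_lengths)
  n_regions <- sum(classes)
  cls <- rep(names(classes), classes)
  dots <- list(...)
  ttr_slope <- dots$ttr_slope %||% 4
  domain_levels <- dots$domain_levels %||% c(-3, -1.5, 0, 1.5, 3)
  domain_length_range <- dots$domain_length_range %||% c(6e5, 1.6e6)
  domains <- draw_domains(layout, domain_levels, domain_length_range,
                          seed = seed + 7L)
  flats <- domain_flat_interiors(domains, ttr_slope)
  # a switching domain must stay inside the baseline dynamic range: plant
  # advances in late-or-mid domains and delays in early-or-mid domains, in
  # the flat interior so the planted |dRT| is exact at every bin
  placed <- with_seed(seed, {
    out <- NULL
    edge <- min(1e6, 0.05 * min(as.numeric(layout)))
    span_min <- max(bin_size, round(span_range[1] / bin_size) * bin_size)
    flo <- pmax(flats$flat_start, edge)
    fhi <- pmin(flats$flat_end,
                as.numeric(layout)[match(flats$chrom, names(layout))] - edge)
    avail <- fhi - flo
    for (k in order(runif(n_regions))) {
      span <- round(runif(1, span_range[1], span_range[2]) / bin_size) * bin_size
      rt_part <- sub("_.*", "", cls[k])
      lv <- flats$level
      elig <- which(avail >= span_min + 2 * bin_size &
                      switch(rt_part, advance = lv <= 0, delay = lv >= 0,
                             rep(TRUE, length(lv))))
      if (!is.null(out)) elig <- setdiff(elig, out$domain)
      if (!length(elig)) stop("could not place planted regions; genome too small")
      di <- elig[sample.int(length(elig), 1)]
      # shrink the drawn span if the domain interior cannot host it
      span <- min(span, floor((avail[di] - 2 * bin_size) / bin_size) * bin_size)
      lo <- ceiling(flo[di] / bin_size)
      hi <- floor((fhi[di] - span) / bin_size)
      start <- (lo:hi)[sample.int(hi - lo + 1, 1)] * bin_size
      out <- rbind(out, data.frame(chrom = flats$chrom[di], start = start,
                                   end = start + span, class = cls[k],
                                   domain = di))
    }
    out[order(out$chrom, out$start), setdiff(names(out), "domain")]
  })
  info <- lapply(placed$class, parse_class, delta = delta,
                 expressed_rpkm = expressed_rpkm)
  placed$delta <- vapply(info, `[[`, numeric(1), "delta")

  switches <- placed[placed$delta != 0,
                     c("chrom", "start", "end", "delta")]
  switches$allele <- NA_character_

  genes <- NULL
  for (i in seq_len(nrow(placed))) {
    if (!info[[i]]$has_gene) next
    genes <- rbind(genes, data.frame(
      chrom = placed$chrom[i], start = placed$start[i], end = placed$end[i],
      strand = "+", name = sprintf("planted_%d_%s", i, placed$class[i]),
      rpkm_A = info[[i]]$rpkm_A, rpkm_B = info[[i]]$rpkm_B))
  }
  # constitutive genes in the space between planted regions
  genes <- rbind(genes, with_seed(seed + 17L, {
    out <- NULL
    glen <- 30000
    lv <- names(layout)
    pg <- GenomicRanges::GRanges(factor(placed$chrom, levels = lv),
                                 IRanges::IRanges(pmax(1, placed$start + 1 - min_separation),
                                                  placed$end + min_separation))
    tries <- 0
    while (is.null(out) || nrow(out) < constitutive_genes) {
      tries <- tries + 1
      if (tries > 10000) break
      ci <- sample(seq_along(layout), 1, prob = as.numeric(layout))
      L <- as.numeric(layout[[ci]])
      start <- floor(runif(1, 0, L - glen))
      cand <- GenomicRanges::GRanges(factor(lv[ci], levels = lv),
                                     IRanges::IRanges(start + 1, start + glen))
      if (length(GenomicRanges::findOverlaps(cand, pg)) > 0) next
      if (!is.null(out)) {
        prev <- GenomicRanges::GRanges(factor(out$chrom, levels = lv),
                                       IRanges::IRanges(out$start + 1, out$end))
        if (length(GenomicRanges::findOverlaps(cand, prev)) > 0) next
      }
      out <- rbind(out, data.frame(chrom = names(layout)[ci], start = start,
                                   end = start + glen, strand = "+",
                                   name = sprintf("gene_%d", nrow(out) %||% 0 + 1),
                                   rpkm_A = constitutive_rpkm,
                                   rpkm_B = constitutive_rpkm))
    }
    out
  }))

  sim_config(chrom_lengths = chrom_lengths, bin_size = bin_size,
             replicates = replicates, lambda = lambda,
             alleles = alleles, switches = switches, genes = genes,
             domains = domains, region_classes = placed, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demo configuration for an allele-specific RT advance
#'
#' One chromosome, two alleles, two replicates: a planted advance on one
#' allele of the second condition over a 400 kb region, plus a baseline
#' allelic-asynchrony region present in both conditions (which the
#' wild-type normalization must cancel). The baseline RT field is fixed
#' (alternating early/late domains) rather than random, and the engineered
#' region sits inside a late-replicating domain advancing toward early --
#' the scenario of a cis-element insertion advancing a late domain. A
#' fixed field keeps the fixture's measurement-noise level deterministic:
#' the variance of log2(E/L) grows steeply at extreme RT, so a random
#' placement would make recovery precision depend on the draw.
#'
#' @param seed Integer seed.
#' @param advance Planted one-allele RT advance (log2 units).
#' @param span Planted region span (bp).
#' @param baseline_offset Baseline allelic offset elsewhere (log2 units).
#' @param chrom_length,bin_size,replicates,lambda See [sim_config()].
#' @return A [sim_config()].
#' @export
allelic_demo_config <- function(seed = 1L, advance = 1.0, span = 4e5,
                                baseline_offset = 0.5,
                                chrom_length = 2e8, bin_size = 50000,
                                replicates = 2, lambda = 100) {
  # alternating +1.5 / -1.5 domains of 2 Mb; the switch sits mid-domain in
  # a late domain, clear of the TTR ramps flanking it
  n_dom <- ceiling(chrom_length / 2e6)
  domains <- data.frame(chrom = "chr1",
                        start = (seq_len(n_dom) - 1) * 2e6,
                        end = pmin(seq_len(n_dom) * 2e6, chrom_length),
                        level = rep(c(1.5, -1.5), length.out = n_dom))
  sim_config(
    chrom_lengths = c(chr1 = chrom_length),
    bin_size = bin_size, replicates = replicates, lambda = lambda,
    conditions = c("WT", "MUT"), alleles = c("mus", "cas"),
    domains = domains,
    switches = data.frame(chrom = "chr1", start = 10.6e6, end = 10.6e6 + span,
                          delta = advance, allele = "mus"),
    allelic_offsets = data.frame(chrom = "chr1", start = 20.6e6, end = 21.6e6,
                                 offset = baseline_offset, allele = "mus"),
    seed = seed)
}

#' Generate and write the demo dataset
#'
#' Runs the full generator ([simulate_rt_field()],
#' [simulate_fraction_counts()], [simulate_transcription()]) for a
#' [demo_config()] and writes the dataset plus truth tables with
#' [write_dataset()].
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param config Optional ready-made [sim_config()]; default
#'   `demo_config(seed)`.
#' @return Invisibly, list with `config`, `truth`, `coverage`, `tx`,
#'   `dir`.
#' @export
make_demo <- function(outdir, seed = 1L, config = demo_config(seed)) {
  truth <- simulate_rt_field(config)
  coverage <- simulate_fraction_counts(truth)
  tx <- simulate_transcription(truth)
  write_dataset(truth, coverage, tx, outdir)
  invisible(list(config = config, truth = truth, coverage = coverage,
                 tx = tx, dir = outdir))
}

#' Run the full analysis pipeline on a written dataset
#'
#' Stages: read the dataset, compute log2(E/L) profiles (with optional
#' quantile normalization of every sample to the first reference-condition
#' replicate), test every window for RT change between the two conditions
#' (Monte-Carlo or paired t-test mode), BH-correct, stitch significant
#' windows into switching regions, quantify region transcription (RPKM),
#' derive the intergenic-shuffle noise threshold, test transcription
#' change, and classify regions jointly. Writes per-window and per-region
#' TSV/BED outputs, a noise-threshold JSON report and a parameter log.
#'
#' @param dataset_dir Directory written by [write_dataset()]/[make_demo()].
#' @param out_dir Output directory.
#' @param mode `"mc"` or `"ttest"`.
#' @param q_cut q-value threshold for significant RT-change windows.
#' @param p_cut Transcription significance threshold (p).
#' @param gap_bp Stitching gap.
#' @param n_mc Monte-Carlo draws.
#' @param floor,epsilon See [compute_log2_ratio()].
#' @param normalize Quantile-normalize profiles to the reference sample.
#' @param noise_quantile,n_shuffles See [noise_threshold()].
#' @param exclude_chroms Chromosomes dropped before any statistics.
#' @param seed Integer seed (MC null and shuffles).
#' @return Invisibly, list with `profiles`, `windows`, `regions`,
#'   `noise`, `classification`, `quant`.
#' @export
run_pipeline <- function(dataset_dir, out_dir, mode = c("mc", "ttest"),
                         q_cut = 0.001, p_cut = 0.01, gap_bp = 300000,
                         n_mc = 1e5, floor = 20, epsilon = 0.5,
                         normalize = TRUE, noise_quantile = 0.99,
                         n_shuffles = 100, exclude_chroms = character(),
                         seed = 1L) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  say <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  cat("", file = logf)
  say("rtswitch pipeline | mode=%s q_cut=%g p_cut=%g gap=%d n_mc=%d seed=%d",
      mode, q_cut, p_cut, as.integer(gap_bp), as.integer(n_mc),
      as.integer(seed))
  say("floor=%g epsilon=%g normalize=%s noise_quantile=%g n_shuffles=%d",
      floor, epsilon, normalize, noise_quantile, as.integer(n_shuffles))

  ds <- read_dataset(dataset_dir)
  if (length(exclude_chroms)) {
    say("excluding chromosomes: %s", paste(exclude_chroms, collapse = ","))
    keep_layout <- exclude_chromosomes(ds$layout, exclude_chroms)
    keep <- !(as.character(GenomicRanges::seqnames(ds$coverage$grid)) %in%
                exclude_chroms)
    ds$coverage$grid <- ds$coverage$grid[keep]
    ds$coverage$E <- ds$coverage$E[keep, , drop = FALSE]
    ds$coverage$L <- ds$coverage$L[keep, , drop = FALSE]
    if (!is.null(ds$tx)) {
      tkeep <- !(as.character(GenomicRanges::seqnames(ds$tx$grid)) %in%
                   exclude_chroms)
      ds$tx$grid <- ds$tx$grid[tkeep]
      ds$tx$counts <- ds$tx$counts[tkeep, , drop = FALSE]
    }
    ds$layout <- keep_layout
  }
  conditions <- unique(ds$coverage$samples$condition)
  stopifnot(length(conditions) == 2)

  profiles <- compute_log2_ratio(ds$coverage, floor = floor, epsilon = epsilon)
  say("profiles: %d samples, %d bins, %d masked in reference",
      length(profiles), length(profiles[[1]]$values),
      sum(!profiles[[1]]$mask))
  if (normalize) {
    ref <- profiles[[which(ds$coverage$samples$condition == conditions[1])[1]]]
    profiles <- lapply(profiles, quantile_normalize, reference = ref)
  }
  A <- profiles[ds$coverage$samples$condition == conditions[1]]
  B <- profiles[ds$coverage$samples$condition == conditions[2]]

  windows <- if (mode == "mc")
    monte_carlo_window_test(A, B, n_mc = n_mc, seed = seed)
  else ttest_window_test(A, B, paired = TRUE)
  regions <- call_switch_regions(windows, q_cut = q_cut, gap_bp = gap_bp)
  say("windows tested: %d; significant at q<=%g: %d; regions: %d",
      nrow(windows), q_cut, sum(windows$q <= q_cut, na.rm = TRUE),
      nrow(regions))

  write.table(windows, file.path(out_dir, "windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(regions, file.path(out_dir, "switch_regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(regions)) {
    rg <- as_region_granges(regions)
    S4Vectors::mcols(rg)$name <- regions$direction
    S4Vectors::mcols(rg)$score <- regions$mean_delta_rt
    write_bed(rg, file.path(out_dir, "switch_regions.bed"))
  }

  noise <- classification <- quant <- NULL
  if (!is.null(ds$tx) && nrow(regions)) {
    adv <- regions[regions$direction == "advance", , drop = FALSE]
    genes <- ds$genes %||% GenomicRanges::GRanges()
    if (nrow(adv)) {
      noise <- noise_threshold(ds$tx, conditions[2], adv, genes, ds$layout,
                               n_shuffles = n_shuffles,
                               quantile_p = noise_quantile, seed = seed + 1L)
      say("noise threshold: %.4g RPKM (quantile %.2f, %d shuffles)",
          noise$threshold, noise_quantile, as.integer(n_shuffles))
      jsonlite::write_json(list(threshold = noise$threshold,
                                quantile = noise_quantile,
                                n_shuffles = n_shuffles),
                           file.path(out_dir, "noise_threshold.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    r1 <- region_rpkm_matrix(ds$tx, regions, conditions[1])
    r2 <- region_rpkm_matrix(ds$tx, regions, conditions[2])
    chg <- transcription_change_test(r1, r2)
    quant <- cbind(regions[, c("chrom", "start", "end", "direction")], chg)
    write.table(quant, file.path(out_dir, "region_quant.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(noise)) {
      classification <- classify_regions(regions$direction, chg,
                                         p_cut = p_cut, noise = noise)
      write.table(cbind(regions[, c("chrom", "start", "end")],
                        classification$labels),
                  file.path(out_dir, "classification.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      say("classification: %s",
          paste(sprintf("%s=%d", names(as.list(table(classification$labels$class))),
                        as.integer(table(classification$labels$class))),
                collapse = " "))
    }
  }
  invisible(list(profiles = profiles, windows = windows, regions = regions,
                 noise = noise, classification = classification,
                 quant = quant))
}
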