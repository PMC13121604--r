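#' Configuration for the synthetic Repli-seq / nascent-transcription generator
#'
#' The generator emulates an allele-resolved E/L Repli-seq experiment on a
#' hybrid diploid genome: a piecewise-constant replication-timing (RT)
#' field in log2(Early/Late) units with linear timing-transition-region
#' (TTR) ramps between domains, planted RT switches applied to the second
#' condition (optionally to one allele only), baseline allelic asynchrony
#' regions, Poisson read sampling of Early/Late fraction counts consistent
#' with the planted RT, and gene-level nascent transcription with a low
#' uniform intergenic background. Allelic structure is modelled as two
#' labelled coverage tracks (the pipeline consumes allele-parsed coverage,
#' so upstream read-level simulation adds no test power).
#'
#' All interval coordinates in configuration data frames are 0-based
#' half-open (BED convention) and must be bin-aligned for planted regions.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size RT bin width in bp (50 kb grid for statistics).
#' @param replicates Replicates per condition.
#' @param lambda Mean reads per bin per fraction (Poisson mean scale).
#' @param conditions Two condition labels (reference first).
#' @param alleles Allele labels; use a single label for an unphased design.
#' @param switches `data.frame(chrom, start, end, delta, allele)` of planted
#'   RT switches (log2 units) applied to the second condition; `allele = NA`
#'   hits both alleles.
#' @param allelic_offsets `data.frame(chrom, start, end, offset, allele)` of
#'   baseline allelic RT asynchrony applied in both conditions.
#' @param domains Optional `data.frame(chrom, start, end, level)` fixing the
#'   baseline RT field; when `NULL` domains are drawn at random
#'   (lengths uniform in `domain_length_range`, levels from `domain_levels`).
#' @param domain_levels Candidate domain RT levels (log2 units).
#' @param domain_length_range Min/max random domain length (bp).
#' @param ttr_slope TTR slope in log2 units per Mb.
#' @param genes `data.frame(chrom, start, end, strand, name, rpkm_A, rpkm_B)`
#'   gene models with condition-specific expression (RPKM).
#' @param background_rpkm Uniform intergenic nascent background (RPKM).
#' @param library_size Nominal nascent-RNA library size per replicate
#'   (reads); RPKM in the generator is defined against this value.
#' @param tx_bin_size Bin width of the emitted transcription coverage (bp).
#' @param overdispersion Extra-Poisson noise: per-bin gamma multiplier with
#'   variance `overdispersion` (0 = pure Poisson).
#' @param region_classes Optional `data.frame(chrom, start, end, class)`
#'   book-keeping table of planted joint RT x transcription classes.
#' @param seed Integer seed; every downstream draw is deterministic in it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                       bin_size = 50000,
                       replicates = 4,
                       lambda = 100,
                       conditions = c("ESC", "NPC"),
                       alleles = c("mus", "cas"),
                       switches = NULL,
                       allelic_offsets = NULL,
                       domains = NULL,
                       domain_levels = c(-3, -1.5, 0, 1.5, 3),
                       domain_length_range = c(6e5, 1.6e6),
                       ttr_slope = 4,
                       genes = NULL,
                       background_rpkm = 0.01,
                       library_size = 1e7,
                       tx_bin_size = 5000,
                       overdispersion = 0,
                       region_classes = NULL,
                       seed = 1L) {
  layout <- genome_layout(chrom_lengths)
  stopifnot_scalar_number(bin_size, "bin_size", positive = TRUE)
  stopifnot_scalar_number(lambda, "lambda", positive = TRUE)
  stopifnot(length(conditions) == 2, replicates >= 1, ttr_slope > 0,
            background_rpkm >= 0, library_size > 0, overdispersion >= 0)
  empty_iv <- function(extra) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric())
    for (nm in names(extra)) df[[nm]] <- extra[[nm]]
    df
  }
  if (is.null(switches))
    switches <- empty_iv(list(delta = numeric(), allele = character()))
  if (is.null(switches$allele)) switches$allele <- NA_character_
  if (is.null(allelic_offsets))
    allelic_offsets <- empty_iv(list(offset = numeric(), allele = character()))
  if (is.null(genes))
    genes <- empty_iv(list(strand = character(), name = character(),
                           rpkm_A = numeric(), rpkm_B = numeric()))
  check_iv <- function(df, what) {
    if (nrow(df) == 0) return(invisible())
    if (any(df$start < 0 | df$end <= df$start))
      stop(what, ": need 0 <= start < end")
    bad <- !(df$chrom %in% names(layout))
    if (any(bad)) stop(what, ": unknown chromosome ", df$chrom[which(bad)[1]])
    over <- df$end > as.numeric(layout)[match(df$chrom, names(layout))]
    if (any(over)) stop(what, " extends beyond chromosome end: row ",
                        which(over)[1])
  }
  check_iv(switches, "switches"); check_iv(allelic_offsets, "allelic_offsets")
  check_iv(genes, "genes")
  if (nrow(switches)) {
    if (any(switches$start %% bin_size != 0 | switches$end %% bin_size != 0))
      stop("planted switch regions must be bin-aligned")
    gr <- GenomicRanges::GRanges(switches$chrom,
                                 IRanges::IRanges(switches$start + 1, switches$end))
    if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
      stop("planted switch regions overlap")
  }
  if (any(genes$rpkm_A < 0) || any(genes$rpkm_B < 0))
    stop("gene RPKM must be >= 0")
  structure(list(
    layout = layout, bin_size = bin_size, replicates = as.integer(replicates),
    lambda = lambda, conditions = conditions, alleles = alleles,
    switches = switches, allelic_offsets = allelic_offsets,
    domains = domains, domain_levels = domain_levels,
    domain_length_range = domain_length_range, ttr_slope = ttr_slope,
    genes = genes, background_rpkm = background_rpkm,
    library_size = library_size, tx_bin_size = tx_bin_size,
    overdispersion = overdispersion, region_classes = region_classes,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$layout), "chromosome(s),",
      format(sum(x$layout), big.mark = ","), "bp;",
      x$bin_size / 1000, "kb bins;", x$replicates, "replicates x",
      length(x$alleles), "allele(s); lambda =", x$lambda,
      "; planted switches:", nrow(x$switches), "\n")
  invisible(x)
}

#' Draw a random replication-domain layout
#'
#' Tiles each chromosome with domains of random length (uniform in
#' `length_range`) and RT levels sampled from `levels` with no immediate
#' repeats; the baseline field joins them with TTR ramps.
#'
#' @param layout [genome_layout()].
#' @param levels Candidate domain RT levels (log2 units).
#' @param length_range Min/max domain length (bp).
#' @param seed Integer seed.
#' @return `data.frame(chrom, start, end, level)`, 0-based half-open.
#' @export
draw_domains <- function(layout, levels = c(-3, -1.5, 0, 1.5, 3),
                         length_range = c(6e5, 1.6e6), seed = 1L) {
  with_seed(seed, {
    out <- lapply(names(layout), function(cn) {
      L <- as.numeric(layout[[cn]])
      starts <- 0; lens <- numeric(0); lev <- numeric(0)
      pos <- 0
      repeat {
        l <- runif(1, length_range[1], length_range[2])
        cand <- sample(levels, 1)
        if (length(lev) && cand == lev[length(lev)]) next
        lev <- c(lev, cand); lens <- c(lens, l)
        pos <- pos + l
        if (pos >= L) break
        starts <- c(starts, pos)
      }
      ends <- pmin(cumsum(lens), L)
      data.frame(chrom = cn, start = starts, end = ends, level = lev)
    })
    do.call(rbind, out)
  })
}

# Flat (ramp-free) interior of each domain, given the TTR slope used by
# the field builder; returns the same frame with flat_start/flat_end.
domain_flat_interiors <- function(domains, slope) {
  out <- NULL
  for (cn in unique(domains$chrom)) {
    d <- domains[domains$chrom == cn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    len <- d$end - d$start
    ramp <- if (n > 1) pmin(abs(diff(d$level)) / slope * 1e6,
                            pmin(len[-n], len[-1])) else numeric(0)
    d$flat_start <- d$start + c(0, ramp / 2)
    d$flat_end <- d$end - c(ramp / 2, 0)
    out <- rbind(out, d)
  }
  out
}

# Piecewise baseline RT field for one chromosome: constant domain levels
# joined by linear TTR ramps of the configured slope (centred on the
# junction, capped so anchors stay ordered within short domains).
rt_field_chrom <- function(dom_start, dom_end, level, slope, mids) {
  n <- length(level)
  if (n == 1) return(rep(level, length(mids)))
  ramp <- abs(diff(level)) / slope * 1e6          # bp per junction
  len <- dom_end - dom_start
  cap <- pmin(len[-n], len[-1])                   # keep anchors inside domains
  ramp <- pmin(ramp, cap)
  x <- y <- numeric(0)
  for (i in seq_len(n)) {
    lo <- dom_start[i] + if (i > 1) ramp[i - 1] / 2 else 0
    hi <- dom_end[i] - if (i < n) ramp[i] / 2 else 0
    x <- c(x, lo, hi); y <- c(y, level[i], level[i])
  }
  approx(x, y, xout = mids, rule = 2, ties = "ordered")$y
}

#' Simulate the true replication-timing field
#'
#' Builds the per-bin true RT value `s` (log2 units) for each condition and
#' allele: a shared baseline field of constant-RT domains joined by linear
#' TTR ramps, plus baseline allelic offsets (both conditions) and planted
#' switches (second condition only, optionally one allele). With zero
#' planted switches the two conditions are identical at every bin.
#'
#' @param config A [sim_config()].
#' @return `sim_truth` list: `grid` (bin `GRanges`), `s` (array bins x
#'   condition x allele), `switches` truth table with `direction`
#'   (`advance` for delta > 0, `delay` for delta < 0), `domains` used,
#'   `classes` (if configured), and the `config`.
#' @export
simulate_rt_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  grid <- bin_grid(layout, config$bin_size)
  mids <- (GenomicRanges::start(grid) + GenomicRanges::end(grid)) / 2
  chr <- as.character(GenomicRanges::seqnames(grid))

  domains <- config$domains
  if (is.null(domains))
    domains <- draw_domains(layout, config$domain_levels,
                            config$domain_length_range, config$seed)

  base <- numeric(length(grid))
  for (cn in unique(chr)) {
    d <- domains[domains$chrom == cn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    sel <- chr == cn
    base[sel] <- rt_field_chrom(d$start, d$end, d$level, config$ttr_slope,
                                mids[sel])
  }

  nc <- 2L; na <- length(config$alleles)
  s <- array(rep(base, nc * na),
             dim = c(length(grid), nc, na),
             dimnames = list(NULL, config$conditions, config$alleles))

  bins_of <- function(row) {
    which(chr == row$chrom &
            GenomicRanges::start(grid) - 1 >= row$start &
            GenomicRanges::end(grid) <= row$end)
  }
  ao <- config$allelic_offsets
  for (i in seq_len(nrow(ao))) {
    row <- ao[i, ]; b <- bins_of(row)
    s[b, , row$allele] <- s[b, , row$allele] + row$offset
  }
  sw <- config$switches
  for (i in seq_len(nrow(sw))) {
    row <- sw[i, ]; b <- bins_of(row)
    al <- if (is.na(row$allele)) config$alleles else row$allele
    s[b, 2, al] <- s[b, 2, al] + row$delta
  }
  switches <- sw
  if (nrow(switches))
    switches$direction <- ifelse(switches$delta > 0, "advance", "delay")

  structure(list(grid = grid, s = s, switches = switches, domains = domains,
                 classes = config$region_classes, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$grid), "bins x", dim(x$s)[2], "conditions x",
      dim(x$s)[3], "allele(s);", nrow(x$switches), "planted switch(es)\n")
  invisible(x)
}

#' Simulate Early/Late fraction read counts
#'
#' For a bin with true RT `s`, the early-fraction probability is the
#' base-2 logistic `pE = 2^s / (1 + 2^s)`, so the expected measured
#' log2(E/L) equals the planted `s`. Counts are
#' `E ~ Poisson(2*lambda*pE)`, `L ~ Poisson(2*lambda*(1-pE))`,
#' independent per replicate and allele, optionally overdispersed by a
#' per-bin gamma multiplier.
#'
#' @param truth A `sim_truth` from [simulate_rt_field()].
#' @param config The [sim_config()] (defaults to the one inside `truth`).
#' @param seed Seed for the count draws (default derived from the config).
#' @return `fraction_coverage` list: `grid`, `samples`
#'   (`data.frame(sample, condition, replicate, allele)`), and integer
#'   matrices `E`, `L` (bins x samples).
#' @export
simulate_fraction_counts <- function(truth, config = truth$config,
                                     seed = config$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  pE <- 2^truth$s / (1 + 2^truth$s)
  samples <- expand.grid(replicate = seq_len(config$replicates),
                         allele = config$alleles,
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "replicate", "allele")]
  samples$sample <- sprintf("%s_%s_rep%d", samples$condition, samples$allele,
                            samples$replicate)
  nb <- length(truth$grid)
  E <- L <- matrix(0L, nb, nrow(samples),
                   dimnames = list(NULL, samples$sample))
  with_seed(seed, {
    for (j in seq_len(nrow(samples))) {
      ci <- match(samples$condition[j], config$conditions)
      ai <- match(samples$allele[j], config$alleles)
      muE <- 2 * config$lambda * pE[, ci, ai]
      muL <- 2 * config$lambda * (1 - pE[, ci, ai])
      if (config$overdispersion > 0) {
        sh <- 1 / config$overdispersion
        muE <- muE * rgamma(nb, shape = sh, rate = sh)
        muL <- muL * rgamma(nb, shape = sh, rate = sh)
      }
      E[, j] <- rpois(nb, muE)
      L[, j] <- rpois(nb, muL)
    }
  })
  structure(list(grid = truth$grid, samples = samples, E = E, L = L),
            class = "fraction_coverage")
}

#' @export
print.fraction_coverage <- function(x, ...) {
  cat("fraction_coverage:", nrow(x$E), "bins x", ncol(x$E), "samples;",
      "total E =", sum(x$E), ", total L =", sum(x$L), "\n")
  invisible(x)
}

#' Simulate nascent transcription coverage and per-gene counts
#'
#' Per replicate and condition, each gene receives a Poisson total read
#' count matching its target RPKM at the nominal library size
#' (`expected = RPKM * gene_kb * library_millions`); reads are spread over
#' the gene body multinomially by bin overlap. Intergenic background is
#' Poisson per bin at the configured background RPKM over the gene-free
#' fraction of the bin. Totals are conserved: the coverage track sums to
#' gene totals plus background.
#'
#' @inheritParams simulate_fraction_counts
#' @return `tx_coverage` list: `grid` (fine transcription bins), `samples`
#'   (`data.frame(sample, condition, replicate)`), `counts` matrix
#'   (bins x samples), `gene_counts` (`data.frame(name, condition,
#'   replicate, count)`), and `library_size` (the nominal per-replicate
#'   size RPKM is defined against).
#' @export
simulate_transcription <- function(truth, config = truth$config,
                                   seed = config$seed + 2L) {
  stopifnot(inherits(truth, "sim_truth"))
  layout <- config$layout
  grid <- bin_grid(layout, config$tx_bin_size)
  genes <- config$genes
  if (nrow(genes) && any(genes$end > as.numeric(layout)[match(genes$chrom, names(layout))]))
    stop("gene extends beyond chromosome end")
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end),
                               seqinfo = layout_seqinfo(layout))
  # per-bin gene-free width, for the intergenic background
  cov_gene <- if (nrow(genes)) bin_coverage(
    {g <- GenomicRanges::reduce(gg)
     S4Vectors::mcols(g)$score <- as.numeric(IRanges::width(g)); g},
    grid) else numeric(length(grid))
  free_bp <- pmax(0, IRanges::width(grid) - cov_gene)
  per_bp <- config$library_size / 1e9      # reads per bp per unit RPKM
  bg_mu <- config$background_rpkm * per_bp * free_bp

  hits <- GenomicRanges::findOverlaps(gg, grid, ignore.strand = TRUE)
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gg)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(grid)[S4Vectors::subjectHits(hits)]))

  samples <- expand.grid(replicate = seq_len(config$replicates),
                         condition = config$conditions,
                         stringsAsFactors = FALSE)[, c("condition", "replicate")]
  samples$sample <- sprintf("%s_rep%d", samples$condition, samples$replicate)
  counts <- matrix(0, length(grid), nrow(samples),
                   dimnames = list(NULL, samples$sample))
  gene_counts <- NULL
  with_seed(seed, {
    for (j in seq_len(nrow(samples))) {
      rpkm <- if (samples$condition[j] == config$conditions[1])
        genes$rpkm_A else genes$rpkm_B
      v <- rpois(length(grid), bg_mu)
      if (nrow(genes)) {
        mu_gene <- rpkm * (genes$end - genes$start) * per_bp
        tot <- rpois(nrow(genes), mu_gene)
        for (g in which(tot > 0)) {
          sel <- S4Vectors::queryHits(hits) == g
          bins <- S4Vectors::subjectHits(hits)[sel]
          v[bins] <- v[bins] + as.vector(rmultinom(1, tot[g], prob = ov[sel]))
        }
        gene_counts <- rbind(gene_counts, data.frame(
          name = genes$name, condition = samples$condition[j],
          replicate = samples$replicate[j], count = tot))
      }
      counts[, j] <- v
    }
  })
  structure(list(grid = grid, samples = samples, counts = counts,
                 gene_counts = gene_counts, library_size = config$library_size),
            class = "tx_coverage")
}

#' @export
print.tx_coverage <- function(x, ...) {
  cat("tx_coverage:", nrow(x$counts), "bins x", ncol(x$counts), "samples;",
      "total reads =", sum(x$counts), "\n")
  invisible(x)
}

grid_granges_with_score <- function(grid, score) {
  gr <- grid
  S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write a simulated dataset to standard genomics formats
#'
#' Emits one bedGraph per fraction/replicate/allele (raw bin counts), one
#' bedGraph per transcription replicate, BED6 gene and planted-region
#' files, a chrom.sizes table, TSV truth tables, a YAML parameter file and
#' a manifest; the set round-trips losslessly through [read_dataset()].
#'
#' @param truth `sim_truth`.
#' @param coverage `fraction_coverage`.
#' @param tx `tx_coverage` (optional).
#' @param outdir Output directory (created if needed).
#' @return The manifest `data.frame`, invisibly.
#' @export
write_dataset <- function(truth, coverage, tx = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- truth$config
  man <- NULL
  add <- function(file, role, condition = NA, replicate = NA, allele = NA,
                  fraction = NA) {
    man <<- rbind(man, data.frame(file = file, role = role,
                                  condition = condition, replicate = replicate,
                                  allele = allele, fraction = fraction))
  }
  write_chrom_sizes(config$layout, file.path(outdir, "chrom.sizes"))
  add("chrom.sizes", "layout")

  for (j in seq_len(nrow(coverage$samples))) {
    s <- coverage$samples[j, ]
    for (fr in c("E", "L")) {
      fn <- sprintf("repliseq_%s_%s.bedGraph", s$sample, fr)
      write_bedgraph(grid_granges_with_score(coverage$grid, coverage[[fr]][, j]),
                     file.path(outdir, fn))
      add(fn, "repliseq", s$condition, s$replicate, s$allele, fr)
    }
  }
  if (!is.null(tx)) {
    for (j in seq_len(nrow(tx$samples))) {
      s <- tx$samples[j, ]
      fn <- sprintf("bru_%s.bedGraph", s$sample)
      write_bedgraph(grid_granges_with_score(tx$grid, tx$counts[, j]),
                     file.path(outdir, fn))
      add(fn, "transcription", s$condition, s$replicate)
    }
    if (!is.null(tx$gene_counts)) {
      write.table(tx$gene_counts, file.path(outdir, "truth_gene_counts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      add("truth_gene_counts.tsv", "truth")
    }
  }
  genes <- config$genes
  if (nrow(genes)) {
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end),
                                 strand = genes$strand)
    S4Vectors::mcols(gg)$name <- genes$name
    write_bed(gg, file.path(outdir, "genes.bed"))
    add("genes.bed", "genes")
  }
  sw <- truth$switches
  if (!is.null(sw) && nrow(sw)) {
    rg <- GenomicRanges::GRanges(sw$chrom, IRanges::IRanges(sw$start + 1, sw$end))
    S4Vectors::mcols(rg)$name <- sw$direction
    S4Vectors::mcols(rg)$score <- sw$delta
    write_bed(rg, file.path(outdir, "planted_regions.bed"))
    add("planted_regions.bed", "truth")
    write.table(sw, file.path(outdir, "truth_switches.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add("truth_switches.tsv", "truth")
  }
  if (!is.null(truth$classes)) {
    write.table(truth$classes, file.path(outdir, "truth_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    add("truth_classes.tsv", "truth")
  }
  params <- list(bin_size = config$bin_size, tx_bin_size = config$tx_bin_size,
                 replicates = config$replicates, lambda = config$lambda,
                 conditions = as.list(config$conditions),
                 alleles = as.list(config$alleles),
                 library_size = config$library_size,
                 background_rpkm = config$background_rpkm, seed = config$seed)
  yaml::write_yaml(params, file.path(outdir, "params.yaml"))
  add("params.yaml", "params")
  write.table(man, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.tsv`.
#' @return List with `layout`, `params`, `coverage` (`fraction_coverage`),
#'   `tx` (`tx_coverage` or `NULL`), `genes` (`GRanges` or `NULL`),
#'   `planted` (`GRanges` or `NULL`), `truth_classes` (data.frame or NULL).
#' @export
read_dataset <- function(dir) {
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  layout <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  params <- yaml::read_yaml(file.path(dir, "params.yaml"))
  grid <- bin_grid(layout, params$bin_size)

  rs <- man[man$role == "repliseq", , drop = FALSE]
  key <- unique(rs[, c("condition", "replicate", "allele")])
  key$sample <- sprintf("%s_%s_rep%d", key$condition, key$allele, key$replicate)
  E <- L <- matrix(0, length(grid), nrow(key), dimnames = list(NULL, key$sample))
  for (i in seq_len(nrow(rs))) {
    j <- which(key$condition == rs$condition[i] &
                 key$replicate == rs$replicate[i] & key$allele == rs$allele[i])
    v <- bin_coverage(read_bedgraph(file.path(dir, rs$file[i]), layout), grid)
    if (rs$fraction[i] == "E") E[, j] <- v else L[, j] <- v
  }
  coverage <- structure(list(grid = grid,
                             samples = key[, c("condition", "replicate", "allele", "sample")],
                             E = E, L = L), class = "fraction_coverage")

  txm <- man[man$role == "transcription", , drop = FALSE]
  tx <- NULL
  if (nrow(txm)) {
    tgrid <- bin_grid(layout, params$tx_bin_size)
    tkey <- unique(txm[, c("condition", "replicate")])
    tkey$sample <- sprintf("%s_rep%d", tkey$condition, tkey$replicate)
    counts <- matrix(0, length(tgrid), nrow(tkey),
                     dimnames = list(NULL, tkey$sample))
    for (i in seq_len(nrow(txm))) {
      j <- which(tkey$condition == txm$condition[i] &
                   tkey$replicate == txm$replicate[i])
      counts[, j] <- bin_coverage(read_bedgraph(file.path(dir, txm$file[i]), layout),
                                  tgrid)
    }
    tx <- structure(list(grid = tgrid, samples = tkey, counts = counts,
                         gene_counts = NULL,
                         library_size = params$library_size),
                    class = "tx_coverage")
  }
  genes <- if ("genes.bed" %in% man$file)
    read_bed(file.path(dir, "genes.bed"), layout) else NULL
  planted <- if ("planted_regions.bed" %in% man$file)
    read_bed(file.path(dir, "planted_regions.bed"), layout) else NULL
  classes <- if ("truth_classes.tsv" %in% man$file)
    read.table(file.path(dir, "truth_classes.tsv"), header = TRUE, sep = "\t",
               stringsAsFactors = FALSE) else NULL
  list(layout = layout, params = params, coverage = coverage, tx = tx,
       genes = genes, planted = planted, truth_classes = classes,
       manifest = man)
}
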