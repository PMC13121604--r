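#' Replication-timing profile
#'
#' Per-bin log2(Early/Late) values on a bin grid, with a usability mask
#' (bins below the raw-coverage floor are masked) and a provenance state
#' (`raw`, `quantile-normalized`, `scaled`, `smoothed`).
#'
#' @param grid Bin `GRanges`.
#' @param values Numeric per-bin log2(E/L) values.
#' @param mask Logical per-bin usability (`TRUE` = usable).
#' @param state Character provenance tag.
#' @param sample Named list identifying condition/replicate/allele.
#' @return Object of class `rt_profile`.
#' @export
rt_profile <- function(grid, values, mask = is.finite(values),
                       state = "raw", sample = list()) {
  stopifnot(length(values) == length(grid), length(mask) == length(grid))
  if (any(!is.finite(values[mask])))
    stop("values must be finite wherever the mask is TRUE")
  structure(list(grid = grid, values = as.numeric(values),
                 mask = as.logical(mask), state = state, sample = sample),
            class = "rt_profile")
}

#' @export
print.rt_profile <- function(x, ...) {
  cat("rt_profile [", paste(x$state, collapse = "+"), "]: ",
      length(x$values), " bins, ", sum(x$mask), " usable; ",
      if (length(x$sample)) paste(unlist(x$sample), collapse = "/") else "",
      "\n", sep = "")
  invisible(x)
}

#' Compute log2(E/L) RT profiles from fraction counts
#'
#' Each fraction is first scaled to reads per million of its own library,
#' then the per-bin value is `log2((E_rpm + eps) / (L_rpm + eps))`. Bins
#' whose raw `E + L` falls below `floor` are masked (insufficient
#' coverage). The symmetric pseudocount keeps the profile antisymmetric
#' under swapping E and L.
#'
#' @param cov A `fraction_coverage`.
#' @param floor Minimum raw `E + L` per bin; below it the bin is masked.
#' @param epsilon Pseudocount in RPM units, applied to both fractions.
#' @return Named list of `rt_profile`, one per sample column.
#' @export
compute_log2_ratio <- function(cov, floor = 20, epsilon = 0.5) {
  stopifnot(inherits(cov, "fraction_coverage"))
  if (any(cov$E < 0) || any(cov$L < 0)) stop("negative fraction counts")
  out <- lapply(seq_len(ncol(cov$E)), function(j) {
    E <- cov$E[, j]; L <- cov$L[, j]
    Erpm <- E / sum(E) * 1e6
    Lrpm <- L / sum(L) * 1e6
    v <- log2((Erpm + epsilon) / (Lrpm + epsilon))
    m <- (E + L) >= floor & is.finite(v)
    v[!m] <- NA_real_
    rt_profile(cov$grid, ifelse(m, v, 0), m, "raw",
               as.list(cov$samples[j, c("condition", "replicate", "allele")]))
  })
  names(out) <- cov$samples$sample
  out
}

#' Quantile-normalize an RT profile to a reference
#'
#' Unmasked target values are replaced by reference quantiles at matching
#' ranks: when the unmasked counts agree, the sorted output equals the
#' sorted unmasked reference exactly; otherwise reference quantiles are
#' linearly interpolated. Ties in the target receive the mean of the tied
#' reference quantiles. Masked bins are untouched. Idempotent against a
#' fixed reference.
#'
#' @param target,reference `rt_profile`s on the same grid.
#' @return Normalized `rt_profile`.
#' @export
quantile_normalize <- function(target, reference) {
  stopifnot(inherits(target, "rt_profile"), inherits(reference, "rt_profile"))
  if (length(target$values) != length(reference$values))
    stop("profiles must share a grid")
  tv <- target$values[target$mask]
  rv <- sort(reference$values[reference$mask])
  if (length(tv) == 0 || length(rv) == 0)
    stop("no unmasked values to normalize")
  r <- rank(tv, ties.method = "average")
  if (length(rv) == 1) {
    mapped <- rep(rv, length(tv))
  } else {
    # map rank 1..n_t onto index 1..n_r, interpolating reference order stats
    pos <- if (length(tv) == length(rv)) r else
      1 + (r - 1) * (length(rv) - 1) / (length(tv) - 1)
    mapped <- approx(seq_along(rv), rv, xout = pos, rule = 2)$y
  }
  out <- target
  out$values[target$mask] <- mapped
  out$state <- unique(c(setdiff(target$state, "raw"), "quantile-normalized"))
  out
}

#' Rescale an RT profile to a fixed display dynamic range
#'
#' Affine map sending the `lo_q` and `hi_q` quantiles of the unmasked
#' values to `-bound` and `+bound` (defaults map the 0.5% and 99.5%
#' quantiles to -3 and +3, compressing a typical raw range of about -7..7
#' to about -3..3). Values outside the quantiles are mapped linearly, not
#' clipped, unless `clip = TRUE`. Scaled values are for display tracks
#' only; statistics must run on unscaled profiles.
#'
#' @param p `rt_profile`.
#' @param lo_q,hi_q Quantile probabilities anchoring the map.
#' @param bound Half-range the anchors map to.
#' @param clip Clip outputs into `[-bound, bound]`.
#' @return Scaled `rt_profile`.
#' @export
scale_profile <- function(p, lo_q = 0.005, hi_q = 0.995, bound = 3,
                          clip = FALSE) {
  stopifnot(inherits(p, "rt_profile"))
  v <- p$values[p$mask]
  if (length(v) == 0) stop("no unmasked values to scale")
  qs <- quantile(v, c(lo_q, hi_q), names = FALSE, type = 7)
  if (qs[2] <= qs[1]) stop("degenerate spread: scaling quantiles coincide")
  out <- p
  sc <- 2 * bound / (qs[2] - qs[1])
  out$values[p$mask] <- (v - (qs[1] + qs[2]) / 2) * sc
  if (clip) out$values[p$mask] <- pmin(bound, pmax(-bound, out$values[p$mask]))
  out$state <- unique(c(out$state, "scaled"))
  out
}

#' Smooth an RT profile with a centred moving average
#'
#' Per chromosome, each bin is replaced by the mean of the unmasked values
#' in the window of `round(window_bp / bin_size)` bins centred on it (for
#' an even window the extra bin falls on the right). Windows shrink at
#' chromosome ends; all-masked windows stay masked. Linear, and
#' mean-preserving on gap-free chromosomes.
#'
#' @param p `rt_profile`.
#' @param window_bp Smoothing window in bp (>= bin size).
#' @return Smoothed `rt_profile`.
#' @export
smooth_profile <- function(p, window_bp = 300000) {
  stopifnot(inherits(p, "rt_profile"))
  w <- IRanges::width(p$grid)[1]
  if (window_bp < w) stop("window_bp must be >= bin size")
  n_win <- max(1L, as.integer(round(window_bp / w)))
  lo <- -((n_win - 1L) %/% 2L); hi <- n_win - 1L + lo
  chr <- as.character(GenomicRanges::seqnames(p$grid))
  out_v <- p$values; out_m <- p$mask
  for (cn in unique(chr)) {
    sel <- which(chr == cn)
    v <- p$values[sel]; m <- p$mask[sel]
    v[!m] <- 0
    n <- length(v)
    cs_v <- cumsum(c(0, v)); cs_m <- cumsum(c(0, as.numeric(m)))
    i <- seq_len(n)
    a <- pmax(1L, i + lo); b <- pmin(n, i + hi)
    sums <- cs_v[b + 1] - cs_v[a]
    cnts <- cs_m[b + 1] - cs_m[a]
    sm <- ifelse(cnts > 0, sums / cnts, NA_real_)
    out_v[sel] <- ifelse(cnts > 0, sm, 0)
    out_m[sel] <- cnts > 0
  }
  res <- p
  res$values <- out_v; res$mask <- out_m
  res$state <- unique(c(res$state, "smoothed"))
  res
}

#' Export RT profiles as bedGraph tracks and a wide TSV matrix
#'
#' One bedGraph per sample (masked bins omitted) plus a bins-by-samples
#' TSV with `NA` at masked bins.
#'
#' @param profiles Named list of `rt_profile` on a shared grid.
#' @param outdir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_rt_profiles <- function(profiles, outdir, prefix = "rt") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- profiles[[1]]$grid
  paths <- character(0)
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    gr <- grid[p$mask]
    S4Vectors::mcols(gr)$score <- p$values[p$mask]
    fn <- file.path(outdir, sprintf("%s_%s.bedGraph", prefix, nm))
    write_bedgraph(gr, fn)
    paths <- c(paths, fn)
  }
  mat <- data.frame(chrom = as.character(GenomicRanges::seqnames(grid)),
                    start = GenomicRanges::start(grid) - 1L,
                    end = GenomicRanges::end(grid))
  for (nm in names(profiles))
    mat[[nm]] <- ifelse(profiles[[nm]]$mask, profiles[[nm]]$values, NA)
  fn <- file.path(outdir, paste0(prefix, "_matrix.tsv"))
  write.table(mat, fn, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, fn))
}
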