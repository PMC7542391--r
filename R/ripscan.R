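#' Overlapping dinucleotide counts
#'
#' Counts the 16 A/C/G/T dinucleotides over all overlapping positions of a
#' sequence, left to right; any pair containing `N` is skipped. Counting is
#' delegated to [Biostrings::dinucleotideFrequency()], whose step-1 mode
#' implements exactly this rule.
#'
#' @param seq Character scalar or `DNAString`. Empty or length-1 input
#'   yields all-zero counts.
#' @return List with `counts` (named integer vector of the 16
#'   dinucleotides) and `n_valid` (number of counted positions,
#'   `sum(counts)`).
#' @export
#' @examples
#' dinucleotide_counts("TATACA")$counts[c("TA", "AT", "CA")]
dinucleotide_counts <- function(seq) {
  dn <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        paste0))
  if (is.character(seq)) {
    if (nchar(seq) < 2L) {
      z <- setNames(integer(16L), sort(dn))
      return(list(counts = z, n_valid = 0L))
    }
    seq <- Biostrings::DNAString(toupper(seq))
  }
  cnt <- Biostrings::dinucleotideFrequency(seq, step = 1L)
  list(counts = cnt, n_valid = sum(cnt))
}

#' RIP product and substrate indices
#'
#' The two dinucleotide indices used to recognise repeat-induced point
#' mutation. RIP converts CpA to TpA (and, read on the other strand, TpG
#' to TpA's complement), so affected sequence accumulates TpA at the
#' expense of CpA/TpG:
#'
#' * product index = TpA / ApT (high after RIP),
#' * substrate index = (CpA + TpG) / (ApC + GpT) (low after RIP).
#'
#' An index whose denominator is zero is undefined and returned as `NA`;
#' `NA` never satisfies a RIP threshold. The composite (product -
#' substrate) is reported for exploration only; no threshold is attached
#' to it. Both indices are invariant under reverse complement of the
#' sequence (TA and AT are their own reverse complements; CpA/TpG and
#' ApC/GpT swap within their sums).
#'
#' @param counts Result of [dinucleotide_counts()] (or its `counts`
#'   component).
#' @return Named numeric vector: `product`, `substrate`, `composite`.
#' @export
rip_indices <- function(counts) {
  if (is.list(counts) && !is.null(counts$counts)) counts <- counts$counts
  product <- if (counts[["AT"]] > 0) counts[["TA"]] / counts[["AT"]] else
    NA_real_
  den <- counts[["AC"]] + counts[["GT"]]
  substrate <- if (den > 0) (counts[["CA"]] + counts[["TG"]]) / den else
    NA_real_
  c(product = product, substrate = substrate,
    composite = product - substrate)
}

#' RIP calling thresholds
#'
#' A window is called RIP when both indices are defined and the product
#' index exceeds `product_min` while the substrate index is below
#' `substrate_max`. The defaults (1.61 and 0.53) are the conventional
#' cutoffs for fungal genome scans.
#'
#' @param product_min Minimum TpA/ApT (exclusive).
#' @param substrate_max Maximum (CpA+TpG)/(ApC+GpT) (exclusive).
#' @return Object of class `rip_thresholds`.
#' @export
rip_thresholds <- function(product_min = 1.61, substrate_max = 0.53) {
  stopifnot(product_min > 0 || is.infinite(product_min), substrate_max > 0)
  structure(list(product_min = product_min, substrate_max = substrate_max),
            class = "rip_thresholds")
}

# window start/end tiling for one contig: full windows at the given step;
# the tail is covered by a final partial window if it is at least half a
# window, otherwise by a final full window anchored at the contig end, so
# that every base is covered whenever step <= window
tile_windows <- function(L, window, step) {
  if (L <= window) return(data.frame(start = 1L, end = L))
  starts <- seq.int(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  last <- ends[length(ends)]
  if (last < L) {
    tail_start <- starts[length(starts)] + step
    if (L - tail_start + 1L >= window / 2) {
      starts <- c(starts, tail_start)
      ends <- c(ends, L)
    } else {
      starts <- c(starts, L - window + 1L)
      ends <- c(ends, L)
    }
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Scan a genome for RIP-mutated regions
#'
#' Tiles each contig with sliding windows, computes both RIP indices per
#' window, calls windows passing both thresholds, and merges consecutive
#' or overlapping RIP windows into regions.
#'
#' @param genome `DNAStringSet` (or named character vector).
#' @param window Window size in bases (>= 2; default 1000).
#' @param step Step in bases (1 <= step <= window; default 500).
#' @param thresholds A [rip_thresholds()] object.
#' @return List of class `rip_scan` with `windows` (data frame: `contig`,
#'   `start`, `end`, `product_index`, `substrate_index`, `composite`,
#'   `is_rip`) and `regions` (a `GRanges` of merged RIP regions).
#' @export
scan_rip <- function(genome, window = 1000L, step = 500L,
                     thresholds = rip_thresholds()) {
  stopifnot(window >= 2L, step >= 1L, step <= window,
            inherits(thresholds, "rip_thresholds"))
  genome <- as_genome(genome)
  wins <- list()
  for (ctg in names(genome)) {
    tl <- tile_windows(length(genome[[ctg]]), window, step)
    v <- Views(genome[[ctg]], start = tl$start, end = tl$end)
    cnt <- Biostrings::dinucleotideFrequency(v, step = 1L)
    product <- ifelse(cnt[, "AT"] > 0, cnt[, "TA"] / cnt[, "AT"], NA_real_)
    den <- cnt[, "AC"] + cnt[, "GT"]
    substrate <- ifelse(den > 0, (cnt[, "CA"] + cnt[, "TG"]) / den, NA_real_)
    is_rip <- !is.na(product) & !is.na(substrate) &
      product > thresholds$product_min & substrate < thresholds$substrate_max
    wins[[ctg]] <- data.frame(contig = ctg, start = tl$start, end = tl$end,
                              product_index = product,
                              substrate_index = substrate,
                              composite = product - substrate,
                              is_rip = is_rip, stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, wins)
  rownames(windows) <- NULL
  rip <- windows[windows$is_rip, , drop = FALSE]
  regions <- if (nrow(rip))
    reduce(GRanges(rip$contig, IRanges(rip$start, rip$end)),
           min.gapwidth = 1L)
  else GRanges()
  structure(list(windows = windows, regions = regions,
                 window = window, step = step, thresholds = thresholds),
            class = "rip_scan")
}

#' @export
print.rip_scan <- function(x, ...) {
  cat("RIP scan:", nrow(x$windows), "windows (window", x$window,
      "bp, step", x$step, "bp);", sum(x$windows$is_rip),
      "called RIP;", length(x$regions), "merged regions\n")
  invisible(x)
}

#' Write merged RIP regions as BED
#'
#' BED uses 0-based half-open coordinates; the conversion from the
#' package's 1-based closed intervals happens here.
#'
#' @param scan A `rip_scan` object (or a `GRanges` of regions).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rip_bed <- function(scan, path) {
  regions <- if (inherits(scan, "rip_scan")) scan$regions else scan
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   name = sprintf("RIP%04d", seq_along(regions)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write merged RIP regions as GFF3
#' @param scan A `rip_scan` object (or a `GRanges` of regions).
#' @param path Output path.
#' @param genome Genome used for sequence-region headers.
#' @return Invisibly, `path`.
#' @export
write_rip_gff3 <- function(scan, path, genome) {
  regions <- if (inherits(scan, "rip_scan")) scan$regions else scan
  genome <- as_genome(genome)
  if (length(regions)) {
    mcols(regions)$type <- "region"
    mcols(regions)$ID <- sprintf("RIP%04d", seq_along(regions))
  }
  seqlevels(regions) <- names(genome)
  seqlengths(regions) <- width(genome)
  rtracklayer::export(regions, path, format = "gff3")
  invisible(path)
}

#' Per-window RIP table writer
#' @param scan A `rip_scan` object.
#' @param path Output path (tab-separated with header).
#' @return Invisibly, `path`.
#' @export
write_rip_windows <- function(scan, path) {
  write.table(scan$windows, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
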