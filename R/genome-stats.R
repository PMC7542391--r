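#' N50 of a set of contig lengths
#'
#' The smallest length L such that contigs of length >= L together cover
#' at least half the assembly (equivalently: sort descending, accumulate,
#' return the first length at which the running sum reaches half the
#' total).
#'
#' @param contig_lengths Non-empty numeric vector of positive lengths.
#' @return The N50 in bases.
#' @export
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
n50 <- function(contig_lengths) {
  if (!length(contig_lengths)) stop("empty length list")
  stopifnot(all(contig_lengths > 0))
  s <- sort(contig_lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' GC content of a genome, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` is excluded from both numerator
#' and denominator.
#'
#' @param genome `DNAStringSet`, named character vector, or a single
#'   sequence string.
#' @return GC percentage.
#' @export
gc_content <- function(genome) {
  if (is.character(genome) && is.null(names(genome)) && length(genome) == 1L)
    names(genome) <- "seq"
  genome <- as_genome(genome)
  lf <- colSums(Biostrings::letterFrequency(genome,
                                            letters = c("A", "C", "G", "T")))
  tot <- sum(lf)
  if (tot == 0) stop("no non-N bases")
  100 * (lf[["C"]] + lf[["G"]]) / tot
}

#' Sequencing coverage fold
#'
#' @param total_sequenced_bases Total bases sequenced across platforms.
#' @param genome_size Assembly size in bases.
#' @return The coverage fold (ratio).
#' @export
#' @examples
#' coverage_fold(2.7e9 + 7.5e9, 119.2e6)  # prints 85.6 at one decimal
coverage_fold <- function(total_sequenced_bases, genome_size) {
  stopifnot(total_sequenced_bases > 0, genome_size > 0)
  total_sequenced_bases / genome_size
}

#' Genome composition report
#'
#' Accounts for what the genome is made of: per-repeat-category bases and
#' percent of genome, total (merged) repeat fraction, coding fraction,
#' genome GC and coding GC. Within a category, overlapping intervals are
#' merged and counted once; across categories, overlaps are counted in
#' each category (the categories are independent tracks, which is why
#' their percentages need not sum to 100).
#'
#' @param genome `DNAStringSet` (or named character vector).
#' @param genes `GRanges` of coding exons (optional).
#' @param repeats `GRanges` with a `category` column (optional).
#' @return List of class `composition_report`: `genome_size`, `categories`
#'   (data frame with `category`, `bases`, `pct`), `repeat_total_bases`,
#'   `repeat_total_pct`, `coding_bases`, `coding_pct`, `gc_pct`,
#'   `coding_gc_pct`.
#' @export
composition_report <- function(genome, genes = NULL, repeats = NULL) {
  genome <- as_genome(genome)
  gsize <- sum(width(genome))
  cats <- if (!is.null(repeats) && length(repeats))
    sort(unique(repeats$category)) else character()
  cat_df <- do.call(rbind, lapply(cats, function(cc) {
    b <- merged_bases(repeats[repeats$category == cc])
    data.frame(category = cc, bases = b, pct = 100 * b / gsize,
               stringsAsFactors = FALSE)
  })) %||% data.frame(category = character(), bases = numeric(),
                      pct = numeric(), stringsAsFactors = FALSE)
  rep_tot <- if (!is.null(repeats) && length(repeats))
    merged_bases(repeats) else 0
  coding <- if (!is.null(genes) && length(genes))
    reduce(genes, ignore.strand = TRUE) else GRanges()
  coding_bases <- sum(width(coding))
  coding_gc <- if (coding_bases > 0) {
    lc <- region_letter_counts(genome, coding, c("A", "C", "G", "T"))
    100 * (lc[["C"]] + lc[["G"]]) / sum(lc)
  } else NA_real_
  structure(list(genome_size = gsize, categories = cat_df,
                 repeat_total_bases = rep_tot,
                 repeat_total_pct = 100 * rep_tot / gsize,
                 coding_bases = coding_bases,
                 coding_pct = 100 * coding_bases / gsize,
                 gc_pct = gc_content(genome),
                 coding_gc_pct = coding_gc),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Genome size (bp):", x$genome_size, "\n")
  cat("GC content (%):", fmt1(x$gc_pct), "\n")
  if (!is.na(x$coding_gc_pct))
    cat("Coding GC content (%):", fmt1(x$coding_gc_pct), "\n")
  cat("Coding region (%):", fmt1(x$coding_pct), "\n")
  cat("Repetitive sequences (%):", fmt1(x$repeat_total_pct), "\n")
  if (nrow(x$categories)) {
    cat("Per-category (independent tracks):\n")
    for (i in seq_len(nrow(x$categories)))
      cat(sprintf("  %-15s %12.0f bp  %s%%\n", x$categories$category[i],
                  x$categories$bases[i], fmt1(x$categories$pct[i])))
  }
  invisible(x)
}

#' LTR superfamily abundance table
#'
#' Counts and summed lengths per superfamily with each superfamily's
#' percent of total LTR length, plus a totals row computed as the true
#' column sum. When the input carries its own totals row (label `Total`),
#' it is compared against the computed sums and a warning is emitted on
#' disagreement.
#'
#' @param superfamily Character vector of superfamily labels (`Unknown`
#'   allowed), one per element; a `Total` entry is treated as a claimed
#'   margin, not data.
#' @param length_bp Numeric vector of element span lengths in bases.
#' @param counts Optional vector of element counts per row (defaults to 1
#'   per row, i.e. per-element input).
#' @return Data frame: `superfamily`, `n`, `length_kbp`, `pct` (percent of
#'   total LTR length), with the totals row last.
#' @export
ltr_type_table <- function(superfamily, length_bp, counts = NULL) {
  stopifnot(length(superfamily) == length(length_bp))
  if (is.null(counts)) counts <- rep(1L, length(superfamily))
  claimed <- superfamily == "Total"
  cl_len <- sum(length_bp[claimed])
  cl_n <- sum(counts[claimed])
  superfamily <- superfamily[!claimed]
  length_bp <- length_bp[!claimed]
  counts <- counts[!claimed]
  agg_len <- tapply(length_bp, superfamily, sum)
  agg_n <- tapply(counts, superfamily, sum)
  fams <- names(agg_len)
  tot_len <- sum(agg_len)
  out <- data.frame(superfamily = c(fams, "Total"),
                    n = c(as.vector(agg_n), sum(agg_n)),
                    length_kbp = c(as.vector(agg_len), tot_len) / 1000,
                    pct = 100 * c(as.vector(agg_len), tot_len) / tot_len,
                    stringsAsFactors = FALSE)
  if (any(claimed) &&
      (abs(cl_len - tot_len) > 0.5 || (cl_n != sum(agg_n))))
    warning(sprintf(
      "input totals row (n=%s, %.3f kbp) disagrees with column sums (n=%s, %.3f kbp)",
      format(cl_n), cl_len / 1000, format(sum(agg_n)), tot_len / 1000))
  rownames(out) <- NULL
  out
}

#' Gene-model summary statistics
#'
#' Gene span runs from the first exon start to the last exon end; introns
#' are the gaps between consecutive exons (single-exon genes contribute
#' none). Means are taken over all genes, all exons and all introns
#' respectively.
#'
#' @param genes `GRanges` of coding exons with a `gene_id` column.
#' @return List: `n_genes`, `mean_gene_span`, `mean_exons_per_gene`,
#'   `mean_exon_length`, `mean_intron_length` (`NaN` when no introns).
#' @export
gene_model_stats <- function(genes) {
  stopifnot(length(genes) >= 1L)
  sp <- split(genes, genes$gene_id)
  spans <- vapply(sp, function(g) max(end(g)) - min(start(g)) + 1L, numeric(1))
  nex <- lengths(sp)
  introns <- unlist(lapply(sp, function(g) {
    if (length(g) < 2L) return(numeric())
    g <- g[order(start(g))]
    start(g)[-1L] - end(g)[-length(g)] - 1L
  }))
  list(n_genes = length(sp), mean_gene_span = mean(spans),
       mean_exons_per_gene = mean(nex),
       mean_exon_length = mean(width(genes)),
       mean_intron_length = if (length(introns)) mean(introns) else NaN)
}

#' Summary of complete (full-length) LTR elements
#'
#' @param elements Elements data frame (see [read_annotations()]).
#' @return List: `n_complete`, `mean_span_length` (`NA` when no complete
#'   elements), `total_span_length`.
#' @export
#' @examples
#' # reported assembly totals: 35.1 Mbp over 5996 complete elements
#' 35.1e6 / 5996 / 1000  # mean length, prints 5.9 kbp at one decimal
complete_ltr_stats <- function(elements) {
  cmp <- elements[elements$complete, , drop = FALSE]
  tot <- if (nrow(cmp)) sum(cmp$end - cmp$start + 1) else 0
  list(n_complete = nrow(cmp),
       mean_span_length = if (nrow(cmp)) tot / nrow(cmp) else NA_real_,
       total_span_length = tot)
}
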