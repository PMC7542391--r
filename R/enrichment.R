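#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with no continuity approximation, delegated
#' to [stats::fisher.test()]: one-sided tails sum the hypergeometric terms
#' at least as extreme as observed; the two-sided p sums all tables with
#' probability not exceeding the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"` (default, over-representation), `"less"`
#'   or `"two_sided"`.
#' @return The p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 17/70
fisher_exact_2x2 <- function(table,
                             alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("table total is zero")
  alt <- c(greater = "greater", less = "less", two_sided = "two.sided")
  stats::fisher.test(table, alternative = alt[[alternative]])$p.value
}

#' Pearson chi-square test on an r x c table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expected counts from the
#' margins, df = (r-1)(c-1), upper-tail chi-square p-value, and no
#' continuity correction (this is the "multi-group" comparison used for
#' k x 2 category tables across genomes). Cells with expected count below
#' 5 trigger a warning; a zero row or column margin is an error.
#'
#' @param table Matrix of non-negative counts (at least 2x2).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_rxc <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2L, ncol(table) >= 2L)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5))
    warning("expected cell count(s) below 5; chi-square approximation may be poor")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = expected)
}

#' Genes whose coding regions fall in or near LTR regions
#'
#' Extends every LTR region by `flank` bases on both sides (clipped at
#' contig boundaries), then reports each gene at most once if any of its
#' coding intervals overlaps any extended region by at least one base.
#'
#' @param ltr_regions `GRanges` of LTR element spans (e.g. from
#'   `elements_granges` of an annotation set, or the repeat track's LTR
#'   category).
#' @param genes `GRanges` of coding exons with metadata columns `gene_id`
#'   and `family` (see [read_annotations()]).
#' @param flank Flank size in bases (default 1000).
#' @return Data frame with `gene_id` and `family`, one row per gene.
#' @export
flank_overlap_genes <- function(ltr_regions, genes, flank = 1000L) {
  stopifnot(flank >= 0L)
  sl <- seqlengths(ltr_regions)
  newend <- end(ltr_regions) + flank
  if (!all(is.na(sl))) {
    lim <- sl[as.character(seqnames(ltr_regions))]
    newend <- ifelse(is.na(lim), newend, pmin(newend, lim))
  }
  ext <- GRanges(seqnames(ltr_regions),
                 IRanges(pmax(1L, start(ltr_regions) - flank), newend))
  hits <- findOverlaps(genes, ext, minoverlap = 1L, ignore.strand = TRUE)
  g <- genes[unique(queryHits(hits))]
  df <- unique(data.frame(gene_id = g$gene_id, family = g$family,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Per-family enrichment of a gene set against the genome background
#'
#' For each family, builds the 2x2 table (in-set & in-family, in-set &
#' not, out-of-set & in-family, out & not) and tests over-representation
#' one-sided with [fisher_exact_2x2()]. Results are ordered by p-value
#' then descending count; Benjamini-Hochberg q-values are appended
#' alongside the raw p-values (raw p is the primary report).
#'
#' @param overlap_genes Character vector of foreground gene ids (e.g. from
#'   [flank_overlap_genes()]).
#' @param gene_families Data frame with `gene_id`, `family` covering the
#'   background (genes without a family may carry `NA` and are counted
#'   only in totals).
#' @param all_genes Character vector of all background gene ids.
#' @return Data frame: `family`, `count` (foreground in-family),
#'   `background` (background in-family), `p_value`, `q_value`.
#' @export
family_enrichment <- function(overlap_genes, gene_families, all_genes) {
  stopifnot(all(overlap_genes %in% all_genes))
  fam_of <- setNames(gene_families$family, gene_families$gene_id)
  fams <- sort(unique(stats::na.omit(gene_families$family)))
  in_set <- all_genes %in% overlap_genes
  fam_all <- fam_of[all_genes]
  rows <- lapply(fams, function(f) {
    bg_f <- sum(fam_all == f, na.rm = TRUE)
    if (bg_f == 0L) stop("family absent from background: ", f)
    a <- sum(in_set & !is.na(fam_all) & fam_all == f)
    b <- sum(in_set) - a
    c_ <- bg_f - a
    d <- length(all_genes) - a - b - c_
    data.frame(family = f, count = a, background = bg_f,
               p_value = fisher_exact_2x2(matrix(c(a, b, c_, d), 2L,
                                                 byrow = TRUE),
                                          alternative = "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, -out$count), , drop = FALSE]
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

hit_columns <- c("query", "subject", "identity_pct", "aln_length",
                 "query_length", "mismatches", "gap_opens", "q_start",
                 "q_end", "s_start", "s_end", "p_value")

#' Thresholds for filtering tabular homology hits
#'
#' @param min_identity_pct Minimum percent identity (default 30; the
#'   pathogen-host-interaction variant uses 50).
#' @param min_coverage_pct Minimum query coverage percent,
#'   100 * aln_length / query_length (default 50).
#' @param max_p Maximum reported p-value (default 1e-10). The score column
#'   of BLAST-like tables is conventionally an e-value; it is filtered
#'   as-is against this cutoff.
#' @return Object of class `hit_filter`.
#' @export
hit_filter <- function(min_identity_pct = 30, min_coverage_pct = 50,
                       max_p = 1e-10) {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            min_coverage_pct >= 0, min_coverage_pct <= 100,
            max_p > 0, max_p <= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 min_coverage_pct = min_coverage_pct, max_p = max_p),
            class = "hit_filter")
}

#' Read a 12-column tabular homology hit file
#'
#' Tab-separated, no header, in a BLAST-outfmt-6-like dialect with the
#' query length in column 5 so that coverage is computable:
#' query, subject, identity_pct, aln_length, query_length, mismatches,
#' gap_opens, q_start, q_end, s_start, s_end, p_value.
#'
#' @param path Path to the hit table.
#' @return Data frame with those columns. Malformed rows are an error
#'   naming the line number.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(setNames(as.data.frame(matrix(nrow = 0, ncol = 12)), hit_columns))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop(sprintf("hit table line %d: expected 12 tab-separated fields, got %d",
                 bad[1L], length(parts[[bad[1L]]])))
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- hit_columns
  num <- c("identity_pct", "aln_length", "query_length", "mismatches",
           "gap_opens", "q_start", "q_end", "s_start", "s_end", "p_value")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stop(sprintf("hit table line %d: non-numeric value in column %s",
                   which(is.na(v))[1L], cn))
    df[[cn]] <- v
  }
  df
}

#' Filter homology hits by identity, coverage and p-value
#'
#' Keeps rows with identity >= `min_identity_pct`, query coverage
#' (100 * aln_length / query_length) >= `min_coverage_pct`, and
#' p <= `max_p`. Row order is preserved.
#'
#' @param hits Data frame from [read_hits()].
#' @param filter A [hit_filter()] object.
#' @return The filtered data frame.
#' @export
filter_hits <- function(hits, filter = hit_filter()) {
  stopifnot(inherits(filter, "hit_filter"),
            all(hit_columns %in% names(hits)))
  cov <- 100 * hits$aln_length / hits$query_length
  keep <- hits$identity_pct >= filter$min_identity_pct &
    cov >= filter$min_coverage_pct & hits$p_value <= filter$max_p
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
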