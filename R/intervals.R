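#' Overlap length of two genomic intervals
#'
#' Number of shared bases between two single-interval `GRanges` (or
#' `contig`/`start`/`end` triples). Intervals on different contigs share
#' nothing; abutting intervals share nothing. Symmetric, and never exceeds
#' the shorter interval's length.
#'
#' @param a,b Single-range `GRanges` objects, or lists/data-frame rows with
#'   `contig`, `start`, `end` (1-based closed).
#' @return Integer number of overlapping bases (>= 0).
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10))
#' b <- GenomicRanges::GRanges("c1", IRanges::IRanges(6, 20))
#' interval_overlap(a, b)  # 5
interval_overlap <- function(a, b) {
  norm <- function(x) {
    if (is(x, "GRanges")) {
      stopifnot(length(x) == 1L)
      list(contig = as.character(seqnames(x)), start = start(x), end = end(x))
    } else {
      list(contig = as.character(x$contig), start = x$start, end = x$end)
    }
  }
  a <- norm(a); b <- norm(b)
  if (a$contig != b$contig) return(0L)
  max(0L, as.integer(min(a$end, b$end) - max(a$start, b$start) + 1L))
}

#' Reverse complement of a nucleotide sequence
#'
#' Works on plain character vectors over the alphabet A, C, G, T, N.
#' An involution: applying it twice returns the input.
#'
#' @param seq Character vector of sequences (may include `""`).
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' reverse_complement("TATACA")  # "TGTATA"
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  if (any(grepl("[^ACGTN]", seq)))
    stop("sequence contains symbols outside A, C, G, T, N")
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# sum of letterFrequency over genome regions given as GRanges
region_letter_counts <- function(genome, gr, letters = c("A", "C", "G", "T", "N")) {
  genome <- as_genome(genome)
  tot <- setNames(numeric(length(letters)), letters)
  for (ctg in unique(as.character(seqnames(gr)))) {
    sub <- gr[as.character(seqnames(gr)) == ctg]
    v <- Views(genome[[ctg]], start = start(sub), end = end(sub))
    lf <- Biostrings::letterFrequency(v, letters = letters)
    tot <- tot + colSums(lf)
  }
  tot
}

# total bases covered by a GRanges after merging overlaps
merged_bases <- function(gr) sum(width(reduce(gr, ignore.strand = TRUE)))

#' Element spans as a GRanges
#'
#' Converts an elements data frame (see [read_annotations()]) into a
#' `GRanges` of full element spans, carrying `element_id` and
#' `superfamily` — the shape wanted by [flank_overlap_genes()] and
#' overlap-based reporting.
#'
#' @param elements Elements data frame.
#' @return A `GRanges` with one range per element.
#' @export
elements_granges <- function(elements) {
  if (!nrow(elements))
    return(GRanges(element_id = character(), superfamily = character()))
  GRanges(elements$contig, IRanges(elements$start, elements$end),
          element_id = elements$element_id, superfamily = elements$superfamily)
}
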