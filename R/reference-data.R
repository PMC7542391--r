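#' Reported assembly summary for Ophiocordyceps sinensis CC1406-203
#'
#' Published summary statistics of the *O. sinensis* CC1406-203 genome
#' assembly (GenBank NGJJ00000000, BioProject PRJNA386225), the repeat-rich
#' high-plateau fungus whose LTR-driven genome inflation motivates this
#' package. These are inputs for desk arithmetic (superfamily shares,
#' coverage fold, coding and repeat fractions), not values the package
#' computes; every derived percentage is recomputed from them at full
#' precision.
#'
#' The Pao superfamily row of the published abundance table is typeset
#' ambiguously; reading it as 143 elements / 15.967 kbp makes both the
#' count column sum to the printed total (61,748) and the length column
#' sum to the printed total (85,535.796 kbp) exactly, so that reading is
#' used here.
#'
#' @return A list: `genome_size_bp`, `n_contigs`, `largest_contig_bp`,
#'   `n50_bp`, `illumina_bp`, `pacbio_bp`, `coding_bp`, `n_genes`,
#'   `complete_ltr_count`, `complete_ltr_total_bp`, `ltr_superfamilies`
#'   (data frame: `superfamily`, `count`, `length_kbp`), and the
#'   gene-family expansion counts used for enrichment arithmetic
#'   (`expanded_genes`, `expanded_secondary_metabolic`,
#'   `genome_secondary_metabolic`).
#' @export
osinensis_summary <- function() {
  list(
    genome_size_bp = 119.2e6,
    n_contigs = 1685L,
    largest_contig_bp = 1.8e6,
    n50_bp = 326.7e3,
    illumina_bp = 2.7e9,
    pacbio_bp = 7.5e9,
    coding_bp = 15.0e6,
    n_genes = 8621L,
    complete_ltr_count = 5996L,
    complete_ltr_total_bp = 35.1e6,
    ltr_superfamilies = data.frame(
      superfamily = c("Copia", "ERV1", "Gypsy", "Ngaro", "Pao", "Unknown"),
      count = c(27699L, 269L, 26672L, 147L, 143L, 6818L),
      length_kbp = c(36125.849, 172.594, 39230.793, 186.706, 15.967,
                     9803.887),
      stringsAsFactors = FALSE),
    expanded_genes = 243L,
    contracted_genes = 89L,
    expanded_secondary_metabolic = 26L,
    genome_secondary_metabolic = 68L
  )
}

#' 2x2 table for secondary-metabolite enrichment in the expansion subset
#'
#' Builds the contingency table contrasting secondary-metabolic genes in
#' the expanded-gene subset against the rest of the genome, using the
#' exclusive (subset-vs-rest) construction: the background cells exclude
#' the subset, so the four cells partition the gene catalogue. With the
#' reported counts (26 of 243 expanded genes secondary-metabolic; 68 of
#' 8621 genome-wide) the one-sided enrichment p-value is far below the
#' conventional reporting floor of 2.2e-16 under either the exclusive or
#' the inclusive construction.
#'
#' @param subset_total Genes in the subset.
#' @param subset_hits Secondary-metabolic genes in the subset.
#' @param genome_total All genes.
#' @param genome_hits All secondary-metabolic genes.
#' @return 2x2 integer matrix (rows: subset, rest; columns: in-category,
#'   not).
#' @export
expansion_enrichment_table <- function(subset_total = 243L,
                                       subset_hits = 26L,
                                       genome_total = 8621L,
                                       genome_hits = 68L) {
  stopifnot(subset_hits <= subset_total, subset_hits <= genome_hits,
            subset_total <= genome_total)
  matrix(c(subset_hits, subset_total - subset_hits,
           genome_hits - subset_hits,
           genome_total - subset_total - (genome_hits - subset_hits)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("expanded", "rest"),
                         c("secondary_metabolic", "other")))
}
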