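#' Read a genome from a FASTA file
#'
#' Reads a multi-record FASTA file into a named [Biostrings::DNAStringSet].
#' The contig identifier is the header token before the first whitespace.
#' Sequences are uppercased on read. IUPAC ambiguity codes other than `N`
#' (R, Y, S, W, K, M, B, D, H, V) are coerced to `N` with a warning, since
#' repeat libraries routinely contain them and every analysis in this
#' package skips `N` anyway; any symbol outside the IUPAC alphabet is a
#' hard error reporting contig and position.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A `DNAStringSet` with unique, non-empty names.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(ids == "")) stop("empty contig id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTNRYSWKMBDHVU]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid nucleotide symbol '%s' in contig '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (any(grepl("[RYSWKMBDHVU]", seqs))) {
    warning("IUPAC ambiguity codes coerced to N")
    seqs <- chartr("RYSWKMBDHVU", "NNNNNNNNNNN", seqs)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 70L)
  invisible(path)
}

#' Total genome length in bases
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @return Integer sum of contig lengths.
#' @export
genome_size <- function(genome) sum(width(as_genome(genome)))

# hard-validate the raw GFF3 text so errors can name the offending line,
# which rtracklayer's parser does not do
validate_gff3_lines <- function(path, genome) {
  lines <- readLines(path)
  widths <- setNames(width(genome), names(genome))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) {
      if (startsWith(ln, "##FASTA")) break
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop(sprintf("GFF3 line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)))
    s <- suppressWarnings(as.numeric(f[4L]))
    e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("GFF3 line %d: non-numeric coordinates", i))
    if (s < 1 || s > e)
      stop(sprintf("GFF3 line %d: start > end (or start < 1)", i))
    if (!(f[1L] %in% names(widths)))
      stop(sprintf("GFF3 line %d: unknown contig '%s'", i, f[1L]))
    if (e > widths[[f[1L]]])
      stop(sprintf("GFF3 line %d: feature end %d beyond contig '%s' length %d",
                   i, as.integer(e), f[1L], widths[[f[1L]]]))
  }
  invisible(TRUE)
}

repeat_categories <- c("LTR", "DNA_transposon", "LINE", "SINE",
                       "simple_repeat", "low_complexity", "small_RNA", "other")
ltr_superfamilies <- c("Copia", "Gypsy", "ERV1", "Ngaro", "Pao", "Unknown")

first_or_na <- function(x) {
  vapply(x, function(p) if (length(p)) as.character(p)[1L] else NA_character_,
         character(1))
}

#' Read gene, repeat and LTR-element annotations from GFF3
#'
#' Parses a GFF3 file (1-based inclusive coordinates, as printed) against a
#' genome and splits features into the three annotation tracks used by the
#' package. The feature-type mapping is:
#'
#' * `gene` -> a gene model; its coding intervals are its `CDS` children
#'   (`Parent` = gene `ID`), or the gene interval itself when it has none.
#' * `dispersed_repeat` -> a repeat annotation; its category is taken from
#'   the `repeat_class` attribute (one of `LTR`, `DNA_transposon`, `LINE`,
#'   `SINE`, `simple_repeat`, `low_complexity`, `small_RNA`, `other`), with
#'   a `superfamily` attribute allowed only for `LTR`.
#' * `LTR_retrotransposon` with paired `long_terminal_repeat` children ->
#'   one LTR element (complete when both terminal repeats are present); the
#'   element span also enters the repeat track under category `LTR`.
#'
#' Coordinates are kept in the Bioconductor 1-based closed convention
#' (`GRanges`), so round-tripping through [write_annotations()] preserves
#' the printed coordinates exactly.
#'
#' @param path Path to a GFF3 file.
#' @param genome The `DNAStringSet` the annotations refer to. Features on
#'   unknown contigs, outside contig bounds, or with `start > end` are hard
#'   errors naming the offending line.
#' @param min_ltr_len Minimum accepted terminal-repeat length (bases);
#'   shorter `long_terminal_repeat` children are an error.
#' @return A list with components `genes` (a `GRanges` of coding exons with
#'   metadata columns `gene_id` and `family`), `repeats` (a `GRanges` with
#'   `category` and `superfamily`), and `elements` (a data frame with one
#'   row per LTR element: `element_id`, `contig`, `start`, `end`,
#'   `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`, `superfamily`,
#'   `complete`).
#' @export
read_annotations <- function(path, genome, min_ltr_len = 1L) {
  genome <- as_genome(genome)
  if (!file.exists(path)) stop("file not found: ", path)
  validate_gff3_lines(path, genome)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- if ("ID" %in% names(mcols(gr))) as.character(gr$ID) else
    rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(mcols(gr))) first_or_na(gr$Parent) else
    rep(NA_character_, length(gr))
  getattr <- function(nm) {
    if (nm %in% names(mcols(gr))) as.character(mcols(gr)[[nm]]) else
      rep(NA_character_, length(gr))
  }
  family <- getattr("family")
  repeat_class <- getattr("repeat_class")
  superfamily <- getattr("superfamily")

  ## ---- genes ----
  gi <- which(type == "gene")
  ci <- which(type == "CDS")
  if (any(is.na(id[gi]))) stop("gene feature without ID attribute")
  if (any(is.na(parent[ci]))) stop("CDS feature without Parent attribute")
  if (length(ci) && !all(parent[ci] %in% id[gi]))
    stop("CDS with unknown Parent: ",
         paste(setdiff(parent[ci], id[gi]), collapse = ", "))
  exon_list <- lapply(gi, function(g) {
    kids <- ci[parent[ci] == id[g]]
    rows <- if (length(kids)) kids else g
    ex <- gr[rows]
    if (length(unique(as.character(seqnames(ex)))) != 1L ||
        as.character(seqnames(ex))[1L] != as.character(seqnames(gr[g])))
      stop("exons of gene ", id[g], " on multiple contigs")
    ex <- ex[order(start(ex))]
    if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      stop("overlapping exons in gene ", id[g])
    GRanges(seqnames(ex), IRanges(start(ex), end(ex)),
            strand = as.character(GenomicRanges::strand(gr[g])),
            gene_id = id[g], family = family[g])
  })
  genes <- if (length(exon_list)) do.call(c, exon_list) else
    GRanges(gene_id = character(), family = character())

  ## ---- repeats ----
  ri <- which(type == "dispersed_repeat")
  cat_r <- ifelse(is.na(repeat_class[ri]), "other", repeat_class[ri])
  if (length(ri) && !all(cat_r %in% repeat_categories))
    stop("unknown repeat_class: ",
         paste(setdiff(cat_r, repeat_categories), collapse = ", "))
  if (any(!is.na(superfamily[ri]) & cat_r != "LTR"))
    stop("superfamily attribute on a non-LTR repeat")

  ## ---- LTR elements ----
  ei <- which(type == "LTR_retrotransposon")
  ti <- which(type == "long_terminal_repeat")
  if (any(is.na(id[ei]))) stop("LTR_retrotransposon without ID attribute")
  if (any(is.na(parent[ti]))) stop("long_terminal_repeat without Parent")
  if (length(ti) && !all(parent[ti] %in% id[ei]))
    stop("long_terminal_repeat with unknown Parent: ",
         paste(setdiff(parent[ti], id[ei]), collapse = ", "))
  elements <- do.call(rbind, lapply(ei, function(e) {
    kids <- ti[parent[ti] == id[e]]
    if (length(kids) > 2L)
      stop("element ", id[e], " has more than two terminal repeats")
    ctg <- as.character(seqnames(gr[e]))
    if (length(kids) && any(as.character(seqnames(gr[kids])) != ctg))
      stop("terminal repeats of element ", id[e], " on a different contig")
    if (length(kids) && any(width(gr[kids]) < min_ltr_len))
      stop("terminal repeat of element ", id[e], " shorter than ", min_ltr_len)
    kids <- kids[order(start(gr[kids]))]
    sf <- superfamily[e]
    if (is.na(sf)) sf <- "Unknown"
    data.frame(
      element_id = id[e], contig = ctg,
      start = start(gr[e]), end = end(gr[e]),
      ltr5_start = if (length(kids) >= 1L) start(gr[kids[1L]]) else NA_integer_,
      ltr5_end   = if (length(kids) >= 1L) end(gr[kids[1L]]) else NA_integer_,
      ltr3_start = if (length(kids) == 2L) start(gr[kids[2L]]) else NA_integer_,
      ltr3_end   = if (length(kids) == 2L) end(gr[kids[2L]]) else NA_integer_,
      superfamily = sf,
      complete = length(kids) == 2L,
      stringsAsFactors = FALSE)
  }))
  if (is.null(elements)) elements <- empty_elements()
  # element spans join the repeat track under category LTR
  rep_gr <- c(
    if (length(ri)) GRanges(seqnames(gr[ri]), IRanges(start(gr[ri]), end(gr[ri])),
                            category = cat_r, superfamily = superfamily[ri])
    else GRanges(category = character(), superfamily = character()),
    if (length(ei)) GRanges(seqnames(gr[ei]), IRanges(start(gr[ei]), end(gr[ei])),
                            category = "LTR",
                            superfamily = ifelse(is.na(superfamily[ei]),
                                                 "Unknown", superfamily[ei]))
    else GRanges(category = character(), superfamily = character()))

  list(genes = genes, repeats = rep_gr, elements = elements)
}

empty_elements <- function() {
  data.frame(element_id = character(), contig = character(),
             start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             superfamily = character(), complete = logical(),
             stringsAsFactors = FALSE)
}

#' Write annotations to GFF3
#'
#' Emits genes (with CDS children), repeat annotations and LTR elements
#' (parent `LTR_retrotransposon` with `long_terminal_repeat` children) in
#' the dialect read by [read_annotations()], with deterministic ordering:
#' contig order of the genome, then start coordinate, parents before
#' children.
#'
#' @param ann Annotation list as returned by [read_annotations()] or
#'   [simulate_genome()]; components `genes`, `repeats`, `elements` are all
#'   optional.
#' @param path Output path.
#' @param genome The `DNAStringSet` the annotations refer to (used for
#'   `##sequence-region` headers).
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path, genome) {
  genome <- as_genome(genome)
  rows <- list()
  mk <- function(contig, s, e, strand, type, ID = NA, Parent = NA,
                 family = NA, repeat_class = NA, superfamily = NA) {
    GRanges(contig, IRanges(s, e), strand = strand,
            type = type, ID = as.character(ID), Parent = as.character(Parent),
            family = as.character(family),
            repeat_class = as.character(repeat_class),
            superfamily = as.character(superfamily),
            phase = if (identical(type, "CDS")) 0L else NA_integer_)
  }
  genes <- ann$genes
  if (!is.null(genes) && length(genes)) {
    for (gid in unique(genes$gene_id)) {
      ex <- genes[genes$gene_id == gid]
      ex <- ex[order(start(ex))]
      st <- as.character(GenomicRanges::strand(ex))[1L]
      rows[[length(rows) + 1L]] <-
        mk(as.character(seqnames(ex))[1L], min(start(ex)), max(end(ex)), st,
           "gene", ID = gid, family = ex$family[1L])
      for (k in seq_along(ex))
        rows[[length(rows) + 1L]] <-
          mk(as.character(seqnames(ex))[k], start(ex)[k], end(ex)[k], st,
             "CDS", ID = sprintf("%s.cds%d", gid, k), Parent = gid)
    }
  }
  reps <- ann$repeats
  if (!is.null(reps) && length(reps)) {
    # element spans are written from the elements table, not the repeat track
    keep <- reps$category != "LTR" |
      !overlaps_any_element(reps, ann$elements)
    reps <- reps[keep]
    for (k in seq_along(reps))
      rows[[length(rows) + 1L]] <-
        mk(as.character(seqnames(reps))[k], start(reps)[k], end(reps)[k], "*",
           "dispersed_repeat", ID = sprintf("rep%d", k),
           repeat_class = reps$category[k], superfamily = reps$superfamily[k])
  }
  el <- ann$elements
  if (!is.null(el) && nrow(el)) {
    for (k in seq_len(nrow(el))) {
      rows[[length(rows) + 1L]] <-
        mk(el$contig[k], el$start[k], el$end[k], "*",
           "LTR_retrotransposon", ID = el$element_id[k],
           superfamily = el$superfamily[k])
      if (!is.na(el$ltr5_start[k]))
        rows[[length(rows) + 1L]] <-
          mk(el$contig[k], el$ltr5_start[k], el$ltr5_end[k], "*",
             "long_terminal_repeat",
             ID = paste0(el$element_id[k], ".ltr5"), Parent = el$element_id[k])
      if (!is.na(el$ltr3_start[k]))
        rows[[length(rows) + 1L]] <-
          mk(el$contig[k], el$ltr3_start[k], el$ltr3_end[k], "*",
             "long_terminal_repeat",
             ID = paste0(el$element_id[k], ".ltr3"), Parent = el$element_id[k])
    }
  }
  gr <- if (length(rows)) do.call(c, rows) else
    mk(character(), integer(), integer(), character(), character())[0]
  # deterministic order: contig order of genome, start, parents first
  rank <- ifelse(gr$type %in% c("CDS", "long_terminal_repeat"), 1L, 0L)
  ctg <- match(as.character(seqnames(gr)), names(genome))
  gr <- gr[order(ctg, start(gr), rank)]
  mcols(gr) <- mcols(gr)[, c("type", "ID", "Parent", "family",
                             "repeat_class", "superfamily", "phase")]
  seqlevels(gr) <- names(genome)
  seqlengths(gr) <- width(genome)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# TRUE for repeat-track entries that duplicate an element span
overlaps_any_element <- function(reps, elements) {
  if (is.null(elements) || !nrow(elements)) return(rep(FALSE, length(reps)))
  key_r <- paste(as.character(seqnames(reps)), start(reps), end(reps))
  key_e <- paste(elements$contig, elements$start, elements$end)
  key_r %in% key_e
}
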