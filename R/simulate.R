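#' Specification of a planted LTR element cohort
#'
#' Describes one cohort of full-length LTR retrotransposons to plant in a
#' simulated genome: identical twin terminal repeats at insertion, a random
#' internal region, and a known insertion age. Defaults approximate a
#' fungal full-length element of a few kilobases.
#'
#' @param superfamily Superfamily label (e.g. `"Gypsy"`, `"Copia"`).
#' @param ltr_length Terminal-repeat length in bases (>= 100).
#' @param internal_length Internal-region length in bases.
#' @param age_years Insertion age in years (>= 0).
#' @param copies Number of copies to plant.
#' @return An object of class `element_spec`.
#' @export
element_spec <- function(superfamily = "Gypsy", ltr_length = 300L,
                         internal_length = 5300L, age_years = 30e6,
                         copies = 1L) {
  stopifnot(ltr_length >= 100L, internal_length >= 0L, age_years >= 0,
            copies >= 0L)
  structure(list(superfamily = superfamily, ltr_length = as.integer(ltr_length),
                 internal_length = as.integer(internal_length),
                 age_years = age_years, copies = as.integer(copies)),
            class = "element_spec")
}

#' Configuration for a synthetic genome
#'
#' Collects every knob of the generator in one place. Defaults mirror the
#' composition of a repeat-rich fungal assembly: background GC 44.7%,
#' coding GC 61%, genes of ~3 exons with mean exon length 539 bp and mean
#' intron length 112 bp, a molecular-clock substitution rate of
#' 1.02e-9 substitutions per site per year, and 4-6 bp target-site
#' duplications flanking each insertion.
#'
#' @param seed Integer seed; a fixed seed makes FASTA/GFF3/truth outputs
#'   byte-identical across runs.
#' @param n_contigs,contig_length Number and length (bases) of contigs.
#' @param gc_fraction Background GC fraction in (0, 1).
#' @param n_genes Number of genes to plant.
#' @param exons_per_gene,mean_exon_len,mean_intron_len Gene structure
#'   parameters (exon/intron lengths are Poisson-dispersed around the
#'   means, floored at 30/20 bp).
#' @param coding_gc_fraction GC fraction used for planted exon sequence.
#' @param elements List of [element_spec()] cohorts.
#' @param clock_rate Substitutions per site per year used to convert ages
#'   into expected divergence.
#' @param rip_fraction Fraction of planted elements passed through
#'   [apply_rip()].
#' @param rip_intensity Per-site mutation probability handed to
#'   [apply_rip()].
#' @param tsd_length_range Two integers; target-site duplication lengths
#'   are drawn uniformly from this range.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 1L, contig_length = 200000L,
                       gc_fraction = 0.447, n_genes = 0L,
                       exons_per_gene = 3L, mean_exon_len = 539L,
                       mean_intron_len = 112L, coding_gc_fraction = 0.61,
                       elements = list(), clock_rate = 1.02e-9,
                       rip_fraction = 0, rip_intensity = 0.5,
                       tsd_length_range = c(4L, 6L)) {
  stopifnot(n_contigs >= 1L, contig_length >= 1L,
            gc_fraction > 0, gc_fraction < 1,
            n_genes >= 0L, exons_per_gene >= 1L,
            clock_rate > 0, rip_fraction >= 0, rip_fraction <= 1,
            rip_intensity >= 0, rip_intensity <= 1,
            length(tsd_length_range) == 2L,
            tsd_length_range[1] <= tsd_length_range[2])
  if (length(elements) && inherits(elements, "element_spec"))
    elements <- list(elements)
  stopifnot(all(vapply(elements, inherits, TRUE, "element_spec")))
  structure(as.list(environment()), class = "sim_config")
}

random_seq <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Mutate a sequence under a Jukes-Cantor molecular clock
#'
#' Applies the JC69 endpoint distribution for an expected number of
#' substitutions per site `d`: each non-N site is substituted with
#' probability (3/4)(1 - exp(-4d/3)), uniformly to one of the three other
#' bases. This is the exact finite-time solution of the equal-rates
#' substitution process, so multiple hits are accounted for: as d grows the
#' p-distance to the input saturates at 3/4, and the Jukes-Cantor
#' correction applied downstream is unbiased for sequences generated here.
#' Uses the current R random number generator state.
#'
#' @param seq A single nucleotide sequence (character scalar).
#' @param expected_subs_per_site Expected substitutions per site, `d >= 0`.
#' @return The mutated sequence; length preserved; `N` sites untouched.
#' @export
mutate_clock <- function(seq, expected_subs_per_site) {
  stopifnot(is.character(seq), length(seq) == 1L, expected_subs_per_site >= 0)
  n <- nchar(seq)
  if (expected_subs_per_site == 0 || n == 0L) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pc <- 0.75 * (1 - exp(-4 * expected_subs_per_site / 3))
  hit <- which(runif(n) < pc & s != "N")
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T",   # alternatives to A
                    "A", "G", "T",   # C
                    "A", "C", "T",   # G
                    "A", "C", "G"),  # T
                  nrow = 3L)
    col <- match(s[hit], c("A", "C", "G", "T"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    s[hit] <- alt[cbind(pick, col)]
  }
  paste(s, collapse = "")
}

#' Apply RIP-like C-to-T hypermutation
#'
#' Emulates repeat-induced point mutation: in a single left-to-right pass
#' over the *input* sequence's dinucleotide contexts, each `C` in a CpA
#' context is mutated to `T` with probability `intensity`, and each `G` in
#' a TpG context (the same event viewed on the opposite strand) is mutated
#' to `A` with the same probability. Contexts are determined on the input,
#' so one mutation never creates or destroys another's context.
#'
#' @param seq A single nucleotide sequence.
#' @param intensity Per-site mutation probability in \[0, 1\].
#' @return The mutated sequence.
#' @export
#' @examples
#' apply_rip("CACA", 1)  # "TATA"
apply_rip <- function(seq, intensity) {
  stopifnot(is.character(seq), length(seq) == 1L,
            intensity >= 0, intensity <= 1)
  n <- nchar(seq)
  if (n < 2L || intensity == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ca <- which(s[-n] == "C" & s[-1L] == "A")         # the C of CpA
  tg <- which(s[-n] == "T" & s[-1L] == "G") + 1L    # the G of TpG
  if (length(ca)) s[ca[runif(length(ca)) < intensity]] <- "T"
  if (length(tg)) s[tg[runif(length(tg)) < intensity]] <- "A"
  paste(s, collapse = "")
}

set_termini <- function(seq) {
  # canonical TG...CA dinucleotides at the ends of a terminal repeat
  paste0("TG", substr(seq, 3L, nchar(seq) - 2L), "CA")
}

#' Simulate a genome with planted genes and LTR elements of known age
#'
#' Generates i.i.d. background contigs at the configured GC, plants
#' non-overlapping genes (exon/intron structure, elevated coding GC) and
#' full-length LTR elements, and returns ground truth for every element.
#' Each element is built from an ancestral terminal repeat with TG...CA
#' termini; its two copies are mutated independently by [mutate_clock()]
#' for `age_years` at `clock_rate`, so the expected pairwise divergence is
#' `K = 2 * clock_rate * age_years`. A target-site duplication of uniform
#' length in `tsd_length_range` flanks both sides. A configured fraction of
#' elements is additionally passed through [apply_rip()].
#'
#' @param config A [sim_config()] object.
#' @return A list with components `genome` (`DNAStringSet`), `annotations`
#'   (list of `genes`, `repeats`, `elements` as in [read_annotations()]),
#'   and `truth` (data frame: `element_id`, `superfamily`,
#'   `true_age_years`, `realized_p`, `rip_applied`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ctg <- config$n_contigs
  L <- config$contig_length
  contigs <- lapply(seq_len(n_ctg), function(i)
    strsplit(random_seq(L, config$gc_fraction), "", fixed = TRUE)[[1L]])
  names(contigs) <- sprintf("ctg%d", seq_len(n_ctg))
  occupied <- lapply(seq_len(n_ctg), function(i) IRanges())

  place <- function(len, buffer = 10L) {
    for (try in seq_len(200L)) {
      ctg <- if (n_ctg == 1L) 1L else sample.int(n_ctg, 1L)
      if (L - len + 1L < 1L) next
      st <- sample.int(L - len + 1L, 1L)
      cand <- IRanges(max(1L, st - buffer), min(L, st + len - 1L + buffer))
      if (length(findOverlaps(cand, occupied[[ctg]])) == 0L) {
        occupied[[ctg]] <<- c(occupied[[ctg]], IRanges(st, st + len - 1L))
        return(list(ctg = ctg, start = st))
      }
    }
    stop("placement failure: genome too small for the requested features")
  }

  ## ---- elements ----
  el_specs <- do.call(rbind, lapply(config$elements, function(sp)
    data.frame(superfamily = sp$superfamily, ltr_length = sp$ltr_length,
               internal_length = sp$internal_length,
               age_years = sp$age_years, copies = sp$copies)))
  el_rows <- list()
  truth_rows <- list()
  n_el <- if (is.null(el_specs)) 0L else sum(el_specs$copies)
  rip_ids <- integer()
  if (n_el > 0L) {
    n_rip <- round(config$rip_fraction * n_el)
    rip_ids <- if (n_rip > 0L) sort(sample.int(n_el, n_rip)) else integer()
  }
  eid <- 0L
  if (n_el > 0L) {
    for (r in seq_len(nrow(el_specs))) {
      sp <- el_specs[r, ]
      d <- config$clock_rate * sp$age_years
      for (cp in seq_len(sp$copies)) {
        eid <- eid + 1L
        tsd_len <- sample(seq(config$tsd_length_range[1L],
                              config$tsd_length_range[2L]), 1L)
        span <- 2L * sp$ltr_length + sp$internal_length
        foot <- span + 2L * tsd_len
        pos <- place(foot)
        anc <- set_termini(random_seq(sp$ltr_length, config$gc_fraction))
        ltr5 <- set_termini(mutate_clock(anc, d))
        ltr3 <- set_termini(mutate_clock(anc, d))
        internal <- mutate_clock(random_seq(sp$internal_length,
                                            config$gc_fraction), d)
        ripped <- eid %in% rip_ids
        if (ripped) {
          whole <- apply_rip(paste0(ltr5, internal, ltr3),
                             config$rip_intensity)
          ltr5 <- substr(whole, 1L, sp$ltr_length)
          internal <- substr(whole, sp$ltr_length + 1L,
                             sp$ltr_length + sp$internal_length)
          ltr3 <- substr(whole, sp$ltr_length + sp$internal_length + 1L,
                         nchar(whole))
        }
        tsd <- random_seq(tsd_len, config$gc_fraction)
        block <- paste0(tsd, ltr5, internal, ltr3, tsd)
        idx <- pos$start:(pos$start + foot - 1L)
        contigs[[pos$ctg]][idx] <- strsplit(block, "", fixed = TRUE)[[1L]]
        span_start <- pos$start + tsd_len
        span_end <- span_start + span - 1L
        el_rows[[eid]] <- data.frame(
          element_id = sprintf("elem%04d", eid),
          contig = names(contigs)[pos$ctg],
          start = span_start, end = span_end,
          ltr5_start = span_start, ltr5_end = span_start + sp$ltr_length - 1L,
          ltr3_start = span_end - sp$ltr_length + 1L, ltr3_end = span_end,
          superfamily = sp$superfamily, complete = TRUE,
          stringsAsFactors = FALSE)
        a <- strsplit(ltr5, "", fixed = TRUE)[[1L]]
        b <- strsplit(ltr3, "", fixed = TRUE)[[1L]]
        truth_rows[[eid]] <- data.frame(
          element_id = sprintf("elem%04d", eid),
          superfamily = sp$superfamily,
          true_age_years = sp$age_years,
          realized_p = mean(a != b),
          rip_applied = ripped,
          stringsAsFactors = FALSE)
      }
    }
  }
  elements <- if (length(el_rows)) do.call(rbind, el_rows) else
    empty_elements()
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(element_id = character(), superfamily = character(),
               true_age_years = numeric(), realized_p = numeric(),
               rip_applied = logical(), stringsAsFactors = FALSE)

  ## ---- genes ----
  gene_rows <- list()
  for (g in seq_len(config$n_genes)) {
    ex_len <- pmax(30L, stats::rpois(config$exons_per_gene,
                                     config$mean_exon_len))
    in_len <- if (config$exons_per_gene > 1L)
      pmax(20L, stats::rpois(config$exons_per_gene - 1L,
                             config$mean_intron_len)) else integer()
    span <- sum(ex_len) + sum(in_len)
    pos <- place(span)
    off <- pos$start
    for (k in seq_along(ex_len)) {
      idx <- off:(off + ex_len[k] - 1L)
      contigs[[pos$ctg]][idx] <-
        strsplit(random_seq(ex_len[k], config$coding_gc_fraction), "",
                 fixed = TRUE)[[1L]]
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        contig = names(contigs)[pos$ctg], start = off,
        end = off + ex_len[k] - 1L, gene_id = sprintf("gene%04d", g),
        stringsAsFactors = FALSE)
      off <- off + ex_len[k] + if (k <= length(in_len)) in_len[k] else 0L
    }
  }
  genes <- if (length(gene_rows)) {
    gdf <- do.call(rbind, gene_rows)
    GRanges(gdf$contig, IRanges(gdf$start, gdf$end), strand = "+",
            gene_id = gdf$gene_id, family = NA_character_)
  } else GRanges(gene_id = character(), family = character())

  genome <- Biostrings::DNAStringSet(
    vapply(contigs, paste, character(1), collapse = ""))
  names(genome) <- names(contigs)
  repeats <- if (nrow(elements))
    GRanges(elements$contig, IRanges(elements$start, elements$end),
            category = "LTR", superfamily = elements$superfamily)
  else GRanges(category = character(), superfamily = character())

  list(genome = genome,
       annotations = list(genes = genes, repeats = repeats,
                          elements = elements),
       truth = truth)
}

#' Write a simulation to disk (FASTA + GFF3 + truth table)
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotations = file.path(dir, "annotations.gff3"),
             truth = file.path(dir, "truth.tsv"))
  write_genome(sim$genome, paths[["genome"]])
  write_annotations(sim$annotations, paths[["annotations"]], sim$genome)
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read a truth table written by [write_simulation()]
#' @param path Path to `truth.tsv`.
#' @return Data frame of truth records.
#' @export
read_truth <- function(path)
  read.delim(path, stringsAsFactors = FALSE)
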