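test_that("N50 matches its definition and the brute-force oracle", {
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(n50(10), 10)
  expect_equal(n50(c(1, 1, 1, 1)), 1)
  expect_error(n50(numeric()), "empty")
  set.seed(10)
  for (i in 1:50) {
    lens <- sample.int(500, sample(1:20, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens), info = paste(lens, collapse = ","))
  }
})

test_that("GC content excludes N from numerator and denominator", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("ACGN"), 200 / 3)
  expect_error(gc_content("NNN"), "no non-N bases")
})

test_that("coverage fold is a plain ratio printed at one decimal", {
  expect_equal(coverage_fold(3e9, 1e9), 3)
  expect_equal(coverage_fold(5, 5), 1)
  expect_equal(round_half_up(coverage_fold(2.7e9 + 7.5e9, 119.2e6)), 85.6)
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(5.85), 5.9)
  expect_equal(round_half_up(-5.85), -5.9)
  expect_equal(round_half_up(12.55), 12.6)
  expect_equal(round_half_up(2.25, 1), 2.3)  # base round() would give 2.2
})

test_that("composition report merges within categories, not across", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", strrep("ACGT", 250)), f)  # 1000 bp
  genome <- read_genome(f)
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 250),
                                  gene_id = "g1", family = NA)
  # duplicate LTR interval must be counted once; DNA transposon overlapping
  # the LTR is a separate, independently counted track
  reps <- GenomicRanges::GRanges(
    rep("c1", 3), IRanges::IRanges(c(301, 301, 401), c(500, 500, 550)),
    category = c("LTR", "LTR", "DNA_transposon"),
    superfamily = c("Gypsy", "Gypsy", NA))
  rep_ <- composition_report(genome, genes, reps)
  expect_equal(rep_$coding_pct, 15)
  cats <- setNames(rep_$categories$bases, rep_$categories$category)
  expect_equal(cats[["LTR"]], 200)
  expect_equal(cats[["DNA_transposon"]], 150)
  # merged union across categories for the repeat total
  expect_equal(rep_$repeat_total_bases, 250)
  expect_equal(rep_$gc_pct, 50)
})

test_that("composition report reproduces generator truth exactly", {
  cfg <- sim_config(seed = 71, contig_length = 100000, n_genes = 6,
                    elements = list(
                      element_spec("Gypsy", 200, 700, 10e6, copies = 4),
                      element_spec("Copia", 200, 700, 10e6, copies = 3)))
  sim <- simulate_genome(cfg)
  rep_ <- composition_report(sim$genome, sim$annotations$genes,
                             sim$annotations$repeats)
  el <- sim$annotations$elements
  expect_equal(rep_$repeat_total_bases, sum(el$end - el$start + 1))
  expect_equal(rep_$coding_bases, sum(IRanges::width(sim$annotations$genes)))
  expect_equal(rep_$genome_size, 100000)
})

test_that("LTR superfamily table computes shares from the length column", {
  # single element -> 100% of total
  one <- ltr_type_table("Gypsy", 6000)
  expect_equal(one$pct, c(100, 100))
  # per-element input aggregates counts and lengths
  t2 <- ltr_type_table(c("Gypsy", "Gypsy", "Copia"), c(6000, 4000, 5000))
  g <- t2[t2$superfamily == "Gypsy", ]
  expect_equal(g$n, 2)
  expect_equal(g$length_kbp, 10)
  expect_equal(g$pct, 100 * 10 / 15)
  # percent column sums to 100 over the superfamily rows
  expect_equal(sum(t2$pct[t2$superfamily != "Total"]), 100)
  # a claimed totals row that disagrees with the column sums warns
  expect_warning(
    ltr_type_table(c("Gypsy", "Copia", "Total"), c(6000, 4000, 11000),
                   counts = c(1, 1, 2)),
    "disagrees")
})

test_that("gene model statistics follow the span/exon/intron definitions", {
  genes <- GenomicRanges::GRanges(
    rep("c1", 3), IRanges::IRanges(c(1, 201, 501), c(100, 300, 700)),
    gene_id = c("g1", "g1", "g2"), family = NA)
  st <- gene_model_stats(genes)
  expect_equal(st$n_genes, 2)
  expect_equal(st$mean_gene_span, mean(c(300, 200)))
  expect_equal(st$mean_exons_per_gene, 1.5)
  expect_equal(st$mean_exon_length, mean(c(100, 100, 200)))
  expect_equal(st$mean_intron_length, 100)  # single-exon g2 contributes none

  solo <- gene_model_stats(genes[3])
  expect_true(is.nan(solo$mean_intron_length))
})

test_that("complete-element summary restricts to paired-repeat elements", {
  el <- data.frame(element_id = c("a", "b", "c"), contig = "c1",
                   start = c(1, 10001, 20001), end = c(6000, 12000, 24000),
                   ltr5_start = 1, ltr5_end = 10, ltr3_start = 20,
                   ltr3_end = 30, superfamily = "Gypsy",
                   complete = c(TRUE, FALSE, TRUE))
  st <- complete_ltr_stats(el)
  expect_equal(st$n_complete, 2)
  expect_equal(st$total_span_length, 6000 + 4000)
  expect_equal(st$mean_span_length, 5000)

  none <- complete_ltr_stats(el[el$complete == FALSE, ])
  expect_equal(none$n_complete, 0)
  expect_true(is.na(none$mean_span_length))
  expect_equal(none$total_span_length, 0)
})
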