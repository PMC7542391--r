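test_that("exact 2x2 test equals hypergeometric enumeration", {
  # hand-enumerated: P(X >= 3) = (16 + 1)/70
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE),
                                "greater"), 17 / 70)
  # observed table least extreme in the greater direction
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2, byrow = TRUE),
                                "greater"), 1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "zero")
  expect_error(fisher_exact_2x2(matrix(c(1, -1, 1, 1), 2)), "non-negative")

  # full enumeration oracle over all tables with margins <= 12
  for (alt in c("greater", "less", "two_sided")) {
    for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
      tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
      if (sum(tab) == 0) next
      expect_equal(fisher_exact_2x2(tab, alt), oracle_fisher(tab, alt),
                   tolerance = 1e-10,
                   info = paste(alt, a, b, cc, d))
    }
  }

  # monotonicity: shifting successes into the foreground cell (margins
  # feasible) never increases the one-sided greater p
  set.seed(6)
  for (i in 1:50) {
    m <- sample(2:12, 1); n <- sample(2:12, 1); k <- sample(1:(m + n - 1), 1)
    xs <- max(0, k - n):min(m, k)
    p <- vapply(xs, function(x)
      fisher_exact_2x2(matrix(c(x, m - x, k - x, n - k + x), 2,
                              byrow = TRUE), "greater"), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("chi-square uses Pearson's statistic with margin-based expecteds", {
  r <- suppressWarnings(chi_square_rxc(matrix(c(10, 90, 30, 70), 2,
                                              byrow = TRUE)))
  # margins 100/100 and 40/160 give expecteds 20/80; hand sum = 12.5
  expect_equal(r$statistic, 12.5, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_equal(r$expected, outer(c(100, 100), c(40, 160)) / 200,
               ignore_attr = TRUE)

  same <- chi_square_rxc(matrix(c(20, 30, 20, 30), 2, byrow = TRUE))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(chi_square_rxc(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero row or column margin")
  expect_warning(chi_square_rxc(matrix(c(1, 9, 3, 7), 2, byrow = TRUE)),
                 "below 5")

  # brute-force expected-count oracle on random k x 2 tables
  set.seed(14)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    tab <- matrix(sample(5:40, 2 * k, replace = TRUE), nrow = k)
    ex <- matrix(0, k, 2)
    for (r_ in 1:k) for (c_ in 1:2)
      ex[r_, c_] <- sum(tab[r_, ]) * sum(tab[, c_]) / sum(tab)
    got <- suppressWarnings(chi_square_rxc(tab))
    expect_equal(got$statistic, sum((tab - ex)^2 / ex), tolerance = 1e-10)
    expect_equal(got$df, k - 1)
  }
})

test_that("flank extension finds genes near LTRs with clipping at contig ends", {
  genes <- GenomicRanges::GRanges(
    c("c1", "c1", "c1"), IRanges::IRanges(c(2501, 3001, 100), c(2800, 3200, 200)),
    gene_id = c("gNear", "gFar", "gStart"), family = c("F1", "F2", "F3"))
  ltr <- GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 2000))
  # flank 1000: window covers 1..3000; gNear (<=3000) in, gFar (3001+) out,
  # gStart caught by the clipped left flank
  got <- flank_overlap_genes(ltr, genes, flank = 1000)
  expect_setequal(got$gene_id, c("gNear", "gStart"))
  # flank 0 reduces to direct overlap
  expect_equal(nrow(flank_overlap_genes(ltr, genes, flank = 0)), 0L)
  # enlarging the flank never shrinks the set
  sizes <- vapply(c(0, 500, 1000, 5000), function(fl)
    nrow(flank_overlap_genes(ltr, genes, flank = fl)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("family enrichment composes per-family exact tests", {
  fams <- data.frame(gene_id = sprintf("g%02d", 1:40),
                     family = rep(c("inLTR", "spread", "outside", "none"),
                                  each = 10))
  all_genes <- fams$gene_id
  fg <- c(sprintf("g%02d", 1:10),      # the whole inLTR family
          sprintf("g%02d", 11:12))     # a sliver of spread
  res <- family_enrichment(fg, fams, all_genes)
  expect_equal(res$family[1], "inLTR")
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  # family entirely outside the foreground -> p = 1
  expect_equal(res$p_value[res$family == "outside"], 1)
  # p-values match direct 2x2 construction
  a <- sum(fg %in% fams$gene_id[fams$family == "spread"])
  tab <- matrix(c(a, length(fg) - a, 10 - a, 40 - length(fg) - (10 - a)),
                2, byrow = TRUE)
  expect_equal(res$p_value[res$family == "spread"],
               fisher_exact_2x2(tab, "greater"))
  # a family label whose carriers are all outside the background
  ghost <- rbind(fams, data.frame(gene_id = "gX", family = "ghost"))
  expect_error(family_enrichment("g01", ghost, all_genes),
               "absent from background")

  # planted-enrichment simulation: genes packed against an LTR flank
  cfg <- sim_config(seed = 61, contig_length = 60000,
                    elements = list(element_spec("Gypsy", 300, 1500, 0,
                                                 copies = 2)))
  sim <- simulate_genome(cfg)
  el <- sim$annotations$elements
  near <- GenomicRanges::GRanges(
    el$contig, IRanges::IRanges(el$end + 200, el$end + 400),
    gene_id = paste0("near", seq_len(nrow(el))), family = "flankFam")
  set.seed(62)
  far_pos <- seq(1, 50000, by = 2500)
  far_pos <- far_pos[!far_pos %in% unlist(Map(seq, el$start - 3000,
                                              el$end + 3000))][1:12]
  far <- GenomicRanges::GRanges(
    el$contig[1], IRanges::IRanges(far_pos, far_pos + 150),
    gene_id = paste0("far", seq_along(far_pos)), family = "bgFam")
  genes <- c(near, far)
  fg <- flank_overlap_genes(elements_granges(el), genes, flank = 1000)
  res <- family_enrichment(fg$gene_id,
                           data.frame(gene_id = genes$gene_id,
                                      family = genes$family),
                           genes$gene_id)
  expect_equal(res$family[1], "flankFam")
  expect_lt(res$p_value[1], res$p_value[res$family == "bgFam"])
})

test_that("hit filtering applies identity, coverage and p cutoffs in order", {
  rows <- c(
    "q1\ts1\t75.0\t80\t100\t3\t0\t1\t80\t5\t84\t1e-20",   # keep (GO filter)
    "q2\ts2\t45.0\t90\t100\t3\t0\t1\t90\t2\t91\t1e-20",   # id < 50 under PHI
    "q3\ts3\t60.0\t40\t100\t3\t0\t1\t40\t2\t41\t1e-20",   # coverage 40 < 50
    "q4\ts4\t90.0\t95\t100\t3\t0\t1\t95\t2\t96\t1e-5",    # p too large
    "q5\ts5\t55.0\t60\t100\t3\t0\t1\t60\t2\t61\t1e-12")   # keep
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(rows, f)
  hits <- read_hits(f)
  expect_equal(nrow(hits), 5L)

  # the permissive filter keeps q2 (identity 45 >= 30); the
  # pathogen-host-interaction variant (identity >= 50) drops it
  go <- filter_hits(hits, hit_filter(30, 50, 1e-10))
  expect_equal(go$query, c("q1", "q2", "q5"))
  phi <- filter_hits(hits, hit_filter(50, 50, 1e-10))
  expect_equal(phi$query, c("q1", "q5"))
  strict <- filter_hits(hits, hit_filter(70, 50, 1e-10))
  expect_equal(strict$query, "q1")

  writeLines(c(rows[1], "q6\tbad\trow"), f)
  expect_error(read_hits(f), "line 2")
})

test_that("the expansion-subset table construction partitions the catalogue", {
  tab <- expansion_enrichment_table()
  expect_equal(sum(tab), 8621)
  expect_equal(tab[1, 1], 26)
  expect_equal(sum(tab[1, ]), 243)
  expect_equal(sum(tab[, 1]), 68)
})
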