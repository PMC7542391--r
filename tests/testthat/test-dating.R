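test_that("global aligner reproduces hand-derived and oracle scores", {
  sc <- c(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
  al <- align_twin_ltrs("ACGT", "ACGT", sc)
  expect_equal(al$score, 4)
  expect_equal(al$aligned1, al$aligned2)

  # one gap column: 3 matches + gap_open = 1 (enumerated by hand)
  al <- align_twin_ltrs("ACGT", "AGT", sc)
  expect_equal(al$score, 1)
  expect_equal(nchar(al$aligned1), 4)

  # oracle agreement on random short pairs, two scoring schemes
  set.seed(13)
  for (trial in 1:100) {
    sc2 <- if (trial %% 2) sc else
      c(match = 2, mismatch = -3, gap_open = -4, gap_extend = -1)
    a <- rand_seq(sample(1:12, 1))
    b <- rand_seq(sample(1:12, 1))
    al <- align_twin_ltrs(a, b, sc2)
    expect_equal(al$score, oracle_align_score(a, b, sc2),
                 info = paste(a, b))
    # gapped rows reproduce the inputs
    expect_equal(gsub("-", "", al$aligned1), a)
    expect_equal(gsub("-", "", al$aligned2), b)
  }
})

test_that("p-distance uses pairwise deletion and flags empty alignments", {
  expect_equal(p_distance(strrep("A", 100), strrep("A", 100)),
               list(p = 0, aligned_sites = 100L))
  # 10 columns, 2 gap columns excluded, 1 mismatch among the 8 kept
  al1 <- "ACGTACGT-A"
  al2 <- "ACGAACGTT-"
  pd <- p_distance(al1, al2)
  expect_equal(pd$aligned_sites, 8L)
  expect_equal(pd$p, 1 / 8)
  # N columns are excluded like gaps
  expect_equal(p_distance("ANA", "AAA")$aligned_sites, 2L)
  expect_error(p_distance("--", "AA"), class = "undefined_distance")
})

test_that("JC correction matches its closed form and numerical inversion", {
  expect_equal(jc_correction(0), 0)
  expect_equal(jc_correction(0.05), 0.05174465, tolerance = 1e-7)
  expect_equal(jc_correction(0.74), 3.238116085, tolerance = 1e-8)
  expect_error(jc_correction(0.75), class = "saturation_error")

  # monotone, K >= p, and inverts the expected-p curve p = (3/4)(1-e^(-4K/3))
  p <- seq(0, 0.74, by = 0.005)
  K <- jc_correction(p)
  expect_true(all(diff(K) > 0))
  expect_true(all(K >= p))
  for (k0 in c(0.01, 0.0612, 0.3, 1, 3)) {
    p0 <- 0.75 * (1 - exp(-4 * k0 / 3))
    inv <- uniroot(function(x) 0.75 * (1 - exp(-4 * x / 3)) - p0,
                   c(0, 10), tol = 1e-14)$root
    expect_equal(jc_correction(p0), inv, tolerance = 1e-10)
  }
})

test_that("insertion age is K/2r and the K2P option agrees at low divergence", {
  expect_equal(insertion_age(0), 0)
  expect_equal(insertion_age(0.0612, 1.02e-9), 3.0e7)
  expect_equal(insertion_age(0.1, 1.02e-9), 4.901961e7, tolerance = 1e-6)
  # K2P collapses to JC when transitions/transversions are balanced
  expect_equal(k2p_correction(0.02, 0.04),
               -0.5 * log((1 - 0.08) * sqrt(1 - 0.08)), tolerance = 1e-12)
})

test_that("element dating recovers planted ages and skips incomplete elements", {
  cfg <- sim_config(seed = 19, contig_length = 300000,
                    elements = list(element_spec("Gypsy", 600, 600, 30e6,
                                                 copies = 40)))
  sim <- simulate_genome(cfg)
  el <- sim$annotations$elements
  # cripple one element to exercise the skipped-elements log
  el$complete[1] <- FALSE
  el$ltr3_start[1] <- NA
  el$ltr3_end[1] <- NA
  expect_message(ages <- date_elements(sim$genome, el), "skipping 1")
  expect_equal(attr(ages, "skipped"), el$element_id[1])
  expect_equal(nrow(ages), 39L)
  expect_true(all(ages$datable))
  expect_equal(ages$T, insertion_age(ages$K), tolerance = 1e-12)
  expect_lt(abs(mean(ages$T) - 30e6) / 30e6, 0.1)
})

test_that("landscape bins conserve element length and locate cohorts", {
  # one element, K = 0.03, length 6000 -> single bin [0.03, 0.04)
  ages <- data.frame(element_id = "e", superfamily = "Gypsy",
                     contig = "c", span_length = 6000,
                     aligned_sites = 1000L, p = 0.0294, K = 0.03, T = 1,
                     datable = TRUE)
  l <- build_landscape(ages, bin_width_K = 0.01)
  expect_equal(nrow(l), 1L)
  expect_equal(l$K_low, 0.03)
  expect_equal(l$length_bp, 6000)

  # saturated elements go to the undatable side of the conservation sum
  ages2 <- rbind(ages, data.frame(element_id = "f", superfamily = "Copia",
                                  contig = "c", span_length = 4000,
                                  aligned_sites = 10L, p = 0.8, K = NA,
                                  T = NA, datable = FALSE))
  l2 <- build_landscape(ages2)
  expect_equal(sum(l2$length_bp) + sum(attr(l2, "undatable")),
               sum(ages2$span_length))

  # empty input -> empty landscape, conservation trivially holds
  l0 <- build_landscape(ages2[0, ])
  expect_equal(nrow(l0), 0L)
  expect_equal(sum(l0$length_bp) + sum(attr(l0, "undatable")), 0)
})

test_that("direct-repeat detection recovers planted elements, not background", {
  # age-0 element: identical repeats recovered at planted coordinates
  cfg <- sim_config(seed = 31, contig_length = 30000,
                    elements = list(element_spec("Gypsy", 300, 1200, 0,
                                                 copies = 1)))
  sim <- simulate_genome(cfg)
  det <- detect_ltr_pairs(as.character(sim$genome[[1]]),
                          min_ltr_len = 100, max_internal_len = 5000)
  el <- sim$annotations$elements
  expect_equal(nrow(det), 1L)
  slop <- 20
  expect_lt(abs(det$start - el$start), slop)
  expect_lt(abs(det$end - el$end), slop)
  expect_gt(det$identity, 0.99)

  # two disjoint planted elements -> both recovered
  cfg2 <- sim_config(seed = 32, contig_length = 40000,
                     elements = list(element_spec("Gypsy", 300, 1200, 0,
                                                  copies = 2)))
  sim2 <- simulate_genome(cfg2)
  det2 <- detect_ltr_pairs(as.character(sim2$genome[[1]]),
                           min_ltr_len = 100, max_internal_len = 5000)
  expect_equal(nrow(det2), 2L)

  # random background: no false positives at default thresholds
  set.seed(33)
  bg <- rand_seq(100000)
  expect_equal(nrow(detect_ltr_pairs(bg)), 0L)
})
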