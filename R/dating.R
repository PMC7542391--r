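#' Global alignment of twin terminal repeats
#'
#' End-to-end (Needleman-Wunsch/Gotoh) alignment with affine gap costs. A
#' gap run of length k costs `gap_open + (k - 1) * gap_extend`. Traceback
#' ties are resolved deterministically: diagonal, then up, then left. `N`
#' scores as a mismatch against everything.
#'
#' @param seq5,seq3 The two sequences (non-empty character scalars).
#' @param scoring Named numeric vector with `match`, `mismatch`,
#'   `gap_open`, `gap_extend`.
#' @return List with `score`, `aligned1`, `aligned2` (equal-length gapped
#'   strings).
#' @export
#' @examples
#' align_twin_ltrs("ACGT", "AGT",
#'   scoring = c(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1))
align_twin_ltrs <- function(seq5, seq3,
                            scoring = c(match = 1, mismatch = -1,
                                        gap_open = -4, gap_extend = -1)) {
  stopifnot(is.character(seq5), is.character(seq3),
            nchar(seq5) > 0L, nchar(seq3) > 0L,
            all(c("match", "mismatch", "gap_open", "gap_extend") %in%
                  names(scoring)))
  .gotoh_align_cpp(toupper(seq5), toupper(seq3),
                   scoring[["match"]], scoring[["mismatch"]],
                   scoring[["gap_open"]], scoring[["gap_extend"]])
}

#' Observed proportion of differing sites in an alignment
#'
#' Pairwise-deletion p-distance: columns containing a gap (`-`) or `N` in
#' either row are excluded; `p` is the fraction of the remaining columns
#' whose two residues differ.
#'
#' @param aligned1,aligned2 Equal-length gapped strings (an alignment), or
#'   a list with components `aligned1`/`aligned2` as returned by
#'   [align_twin_ltrs()] passed as the first argument.
#' @return List with `p` and `aligned_sites` (number of included columns).
#'   Zero included columns is an error of class `undefined_distance`.
#' @export
p_distance <- function(aligned1, aligned2 = NULL) {
  if (is.list(aligned1) && is.null(aligned2)) {
    aligned2 <- aligned1$aligned2
    aligned1 <- aligned1$aligned1
  }
  stopifnot(nchar(aligned1) == nchar(aligned2), nchar(aligned1) >= 1L)
  a <- strsplit(toupper(aligned1), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(aligned2), "", fixed = TRUE)[[1L]]
  keep <- a != "-" & b != "-" & a != "N" & b != "N"
  sites <- sum(keep)
  if (sites == 0L)
    stop(structure(class = c("undefined_distance", "error", "condition"),
                   list(message = "no gap-free, N-free aligned columns",
                        call = sys.call())))
  list(p = sum(a[keep] != b[keep]) / sites, aligned_sites = sites)
}

#' Jukes-Cantor divergence correction
#'
#' Converts an observed p-distance into the expected number of
#' substitutions per site under the equal-rates (JC69) model:
#' `K = -(3/4) * log(1 - 4p/3)`. Strictly increasing, with `K(0) = 0` and
#' `K >= p` (the correction re-adds multiple hits).
#'
#' @param p Observed p-distance(s), `0 <= p < 0.75`. Values at or beyond
#'   the saturation point 3/4 are an error of class `saturation_error`;
#'   callers dating whole element sets should catch it and report the
#'   element as undatable rather than dropping it silently.
#' @return Corrected divergence `K` (substitutions per site).
#' @export
#' @examples
#' jc_correction(0.05)  # 0.051745...
jc_correction <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0))
  if (any(p >= 0.75))
    stop(structure(class = c("saturation_error", "error", "condition"),
                   list(message = "p-distance at or beyond JC saturation (3/4)",
                        call = sys.call())))
  -0.75 * log(1 - 4 * p / 3)
}

#' Kimura two-parameter divergence correction
#'
#' `K = -(1/2) log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are the
#' observed transition and transversion proportions. Provided as an
#' alternative to [jc_correction()] for dating; the two agree closely at
#' the low divergences typical of datable elements.
#'
#' @param P,Q Transition and transversion proportions.
#' @return Corrected divergence `K`.
#' @export
k2p_correction <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0))
    stop(structure(class = c("saturation_error", "error", "condition"),
                   list(message = "divergence beyond K2P saturation",
                        call = sys.call())))
  -0.5 * log(w1 * sqrt(w2))
}

transition_transversion <- function(aligned1, aligned2) {
  a <- strsplit(toupper(aligned1), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(aligned2), "", fixed = TRUE)[[1L]]
  keep <- a != "-" & b != "-" & a != "N" & b != "N"
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  pur <- c("A", "G")
  ts <- diff & ((a %in% pur) == (b %in% pur))
  list(P = sum(ts) / length(a), Q = sum(diff & !ts) / length(a),
       aligned_sites = length(a))
}

#' Insertion age from corrected divergence
#'
#' The molecular-clock estimate `T = K / (2 r)`: the twin terminal repeats
#' are identical at insertion and each accumulates substitutions at rate
#' `r` per site per year, so their divergence K counts 2rT expected
#' substitutions.
#'
#' @param K Corrected substitutions per site (>= 0).
#' @param rate Clock rate `r` in substitutions per site per year
#'   (default 1.02e-9).
#' @return Age in years.
#' @export
#' @examples
#' insertion_age(0.0612)  # 3e7 years at the default rate
insertion_age <- function(K, rate = 1.02e-9) {
  stopifnot(all(K >= 0), rate > 0)
  K / (2 * rate)
}

#' Date every complete LTR element in a genome
#'
#' For each element with both terminal repeats, extracts the two repeat
#' sequences, aligns them end-to-end, computes the pairwise-deletion
#' p-distance, corrects it (Jukes-Cantor by default, Kimura two-parameter
#' on request) and converts to years via `T = K/2r`. Elements lacking a
#' twin repeat (`complete = FALSE`) are excluded from dating and listed in
#' the `"skipped"` attribute of the result; saturated elements (p >= 3/4
#' under JC) are kept with `datable = FALSE` and `K`/`T` of `NA`.
#'
#' @param genome `DNAStringSet` the elements live on.
#' @param elements Elements data frame (see [read_annotations()]).
#' @param rate Clock rate in substitutions/site/year.
#' @param scoring Alignment scoring passed to [align_twin_ltrs()].
#' @param model `"JC"` (default) or `"K2P"`.
#' @return Data frame with one row per complete element: `element_id`,
#'   `superfamily`, `contig`, `span_length`, `aligned_sites`, `p`, `K`,
#'   `T`, `datable`. Attribute `"skipped"` holds the ids of incomplete
#'   elements.
#' @export
date_elements <- function(genome, elements, rate = 1.02e-9,
                          scoring = c(match = 1, mismatch = -1,
                                      gap_open = -4, gap_extend = -1),
                          model = c("JC", "K2P")) {
  model <- match.arg(model)
  genome <- as_genome(genome)
  skipped <- elements$element_id[!elements$complete]
  if (length(skipped))
    message("skipping ", length(skipped),
            " element(s) without both terminal repeats")
  el <- elements[elements$complete, , drop = FALSE]
  rows <- lapply(seq_len(nrow(el)), function(i) {
    e <- el[i, ]
    s5 <- as.character(Biostrings::subseq(genome[[e$contig]],
                                          e$ltr5_start, e$ltr5_end))
    s3 <- as.character(Biostrings::subseq(genome[[e$contig]],
                                          e$ltr3_start, e$ltr3_end))
    al <- align_twin_ltrs(s5, s3, scoring)
    pd <- p_distance(al)
    K <- tryCatch({
      if (model == "JC") jc_correction(pd$p)
      else {
        tt <- transition_transversion(al$aligned1, al$aligned2)
        k2p_correction(tt$P, tt$Q)
      }
    }, saturation_error = function(e) NA_real_)
    data.frame(element_id = e$element_id, superfamily = e$superfamily,
               contig = e$contig, span_length = e$end - e$start + 1L,
               aligned_sites = pd$aligned_sites, p = pd$p, K = K,
               T = if (is.na(K)) NA_real_ else insertion_age(K, rate),
               datable = !is.na(K), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(), superfamily = character(),
               contig = character(), span_length = integer(),
               aligned_sites = integer(), p = numeric(), K = numeric(),
               T = numeric(), datable = logical(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Superfamily-stacked insertion landscape
#'
#' Bins each datable element's full span length (bases) by its corrected
#' divergence K, stacked by superfamily: the repeat-landscape histogram
#' read as an insertion-activity timeline (bin K corresponds to age
#' K/2r). Undatable (saturated) elements are reported separately in the
#' `"undatable"` attribute, so that total length is conserved:
#' sum(bins) + undatable = sum(element span lengths).
#'
#' @param ages Result of [date_elements()].
#' @param bin_width_K Bin width in substitutions/site (default 0.01, which
#'   resolves a 30-40 My cohort at the default clock rate into distinct
#'   bins).
#' @return Data frame with `K_low`, `K_high`, `superfamily`, `length_bp`
#'   (only non-empty combinations). Attributes: `"undatable"` (named
#'   vector of summed undatable length per superfamily) and `"bin_width"`.
#' @export
build_landscape <- function(ages, bin_width_K = 0.01) {
  stopifnot(bin_width_K > 0)
  dat <- ages[ages$datable, , drop = FALSE]
  und <- ages[!ages$datable, , drop = FALSE]
  if (nrow(dat)) {
    bin <- floor(dat$K / bin_width_K)
    agg <- stats::aggregate(dat$span_length,
                            by = list(bin = bin, superfamily = dat$superfamily),
                            FUN = sum)
    out <- data.frame(K_low = agg$bin * bin_width_K,
                      K_high = (agg$bin + 1) * bin_width_K,
                      superfamily = agg$superfamily,
                      length_bp = agg$x, stringsAsFactors = FALSE)
    out <- out[order(out$K_low, out$superfamily), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(K_low = numeric(), K_high = numeric(),
                      superfamily = character(), length_bp = numeric(),
                      stringsAsFactors = FALSE)
  }
  undat <- if (nrow(und))
    tapply(und$span_length, und$superfamily, sum) else
      setNames(numeric(), character())
  attr(out, "undatable") <- undat
  attr(out, "bin_width") <- bin_width_K
  out
}

#' Write a per-element age table
#' @param ages Result of [date_elements()].
#' @param path Output path (tab-separated with header).
#' @return Invisibly, `path`.
#' @export
write_age_table <- function(ages, path) {
  write.table(ages, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect candidate full-length LTR elements by direct-repeat search
#'
#' A deliberately simple detector so that synthetic genomes can be run
#' end-to-end without external annotation: exact k-mer seeds shared by two
#' positions on the same diagonal (fixed offset) are extended without gaps
#' under an X-drop rule, trimmed back to the maximum-scoring extent, and
#' accepted as a twin-repeat pair when both repeats are at least
#' `min_ltr_len` long, at least `min_identity` identical, and separated by
#' an internal region of 1..`max_internal_len` bases. Overlapping
#' candidates are resolved by identity, then length, then leftmost
#' position. This is detection plumbing, not a reimplementation of a
#' structural LTR finder: it knows nothing of TSDs or TG...CA termini.
#'
#' @param seq Contig sequence (character scalar) or `DNAString`.
#' @param min_ltr_len Minimum terminal-repeat length (default 100).
#' @param max_internal_len Maximum internal-region length (default 15000).
#' @param min_identity Minimum twin-repeat identity in (0, 1\] (default 0.8).
#' @param contig Contig name recorded in the output.
#' @param k Seed k-mer length.
#' @param xdrop X-drop threshold for ungapped extension (score units:
#'   match +1, mismatch -2).
#' @return Elements data frame in the layout of [read_annotations()]
#'   (possibly zero rows), with an extra `identity` column.
#' @export
detect_ltr_pairs <- function(seq, min_ltr_len = 100L, max_internal_len = 15000L,
                             min_identity = 0.8, contig = "contig",
                             k = 12L, xdrop = 20L) {
  stopifnot(min_ltr_len > 0L, max_internal_len > 0L,
            min_identity > 0, min_identity <= 1)
  seq <- if (is(seq, "DNAString")) as.character(seq) else toupper(seq)
  n <- nchar(seq)
  if (n < 2L * min_ltr_len + 1L) return(cbind(empty_elements(),
                                              identity = numeric()))
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  nk <- n - k + 1L
  kmers <- substring(seq, seq_len(nk), seq_len(nk) + k - 1L)
  grp <- split(seq_len(nk), kmers)
  grp <- grp[lengths(grp) >= 2L & lengths(grp) <= 64L]
  diags <- unique(unlist(lapply(grp, function(pos) {
    d <- as.vector(outer(pos, pos, "-"))
    d <- d[d >= min_ltr_len & d <= max_internal_len + n %/% 2L]
    d
  }), use.names = FALSE))
  cand <- list()
  for (d in sort(diags)) {
    m <- s[seq_len(n - d)] == s[(d + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= k)
    if (!length(runs)) next
    runs <- runs[order(-r$lengths[runs])]
    claimed <- IRanges()
    for (ri in runs) {
      a0 <- starts[ri]; b0 <- ends[ri]
      if (length(findOverlaps(IRanges(a0, b0), claimed))) next
      # x-drop extension right
      sc <- 0; best <- 0; bp <- b0
      x <- b0
      while (x < length(m)) {
        x <- x + 1L
        sc <- sc + if (m[x]) 1 else -2
        if (sc > best) { best <- sc; bp <- x }
        if (sc < best - xdrop) break
      }
      br <- bp
      # x-drop extension left
      sc <- 0; best <- 0; bp <- a0
      x <- a0
      while (x > 1L) {
        x <- x - 1L
        sc <- sc + if (m[x]) 1 else -2
        if (sc > best) { best <- sc; bp <- x }
        if (sc < best - xdrop) break
      }
      al <- bp
      len <- br - al + 1L
      gap <- d - len
      ident <- sum(m[al:br]) / len
      if (len >= min_ltr_len && ident >= min_identity &&
          gap >= 1L && gap <= max_internal_len) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = al, end = al + d + len - 1L,
          ltr5_start = al, ltr5_end = br,
          ltr3_start = al + d, ltr3_end = br + d,
          identity = ident, len = len)
        claimed <- c(claimed, IRanges(al, br))
      }
    }
  }
  if (!length(cand)) return(cbind(empty_elements(), identity = numeric()))
  cd <- do.call(rbind, cand)
  cd <- cd[order(-cd$identity, -cd$len, cd$start), , drop = FALSE]
  taken <- IRanges()
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    iv <- IRanges(cd$start[i], cd$end[i])
    if (length(findOverlaps(iv, taken)) == 0L) {
      keep[i] <- TRUE
      taken <- c(taken, iv)
    }
  }
  cd <- cd[keep, , drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  data.frame(element_id = sprintf("ltrpair%03d", seq_len(nrow(cd))),
             contig = contig, start = cd$start, end = cd$end,
             ltr5_start = cd$ltr5_start, ltr5_end = cd$ltr5_end,
             ltr3_start = cd$ltr3_start, ltr3_end = cd$ltr3_end,
             superfamily = "Unknown", complete = TRUE,
             identity = cd$identity, stringsAsFactors = FALSE)
}
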