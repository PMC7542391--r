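# Independent oracles and small fixture builders shared across tests.
# Each oracle is written from the definition, not from the package's code
# path, so agreement is evidence rather than tautology.

# -- brute-force affine-gap global alignment score ---------------------------
# Memoized recursion over (i, j, state-of-last-column). A gap run of length
# k costs gap_open + (k - 1) * gap_extend. Independent of the C++ matrix
# recurrences: states here are "last column was diagonal / gap-in-b /
# gap-in-a" and the recursion descends from the ends of both strings.
oracle_align_score <- function(a, b, sc) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, last) {
    if (i == 0L && j == 0L) return(0)
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (av[i] == bv[j]) sc[["match"]] else sc[["mismatch"]]
      best <- max(best, rec(i - 1L, j - 1L, "d") + s)
    }
    if (i > 0L) {
      g <- if (last == "u") sc[["gap_extend"]] else sc[["gap_open"]]
      best <- max(best, rec(i - 1L, j, "u") + g)
    }
    if (j > 0L) {
      g <- if (last == "l") sc[["gap_extend"]] else sc[["gap_open"]]
      best <- max(best, rec(i, j - 1L, "l") + g)
    }
    memo[[key]] <- best
    best
  }
  # the cost of a gap column depends on the column AFTER it in this
  # top-down formulation, so recurse from the right end with "no gap yet"
  rec(length(av), length(bv), "d")
}

# -- hypergeometric enumeration for the 2x2 exact test -----------------------
# Enumerates every table with the observed margins via dhyper and sums the
# relevant tail; "two_sided" sums tables no more probable than observed.
oracle_fisher <- function(tab, alternative = "greater") {
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # row-1 margin
  n <- sum(tab[2, ])          # row-2 margin
  k <- sum(tab[, 1])          # column-1 margin
  xs <- max(0, k - n):min(m, k)
  probs <- dhyper(xs, m, n, k)
  switch(alternative,
         greater = sum(probs[xs >= a]),
         less = sum(probs[xs <= a]),
         two_sided = sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)]))
}

# -- brute-force N50: largest length whose tail sum still covers half -------
oracle_n50 <- function(lens) {
  cand <- sort(unique(lens))
  half <- sum(lens) / 2
  max(cand[vapply(cand, function(L) sum(lens[lens >= L]) >= half, TRUE)])
}

# -- random sequence helper --------------------------------------------------
rand_seq <- function(n, letters = c("A", "C", "G", "T"))
  paste(sample(letters, n, replace = TRUE), collapse = "")

# string p-distance for equal-length ungapped strings (truth checks)
string_pdist <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av != bv)
}

# write a tiny FASTA from a named character vector without Biostrings
write_fasta_plain <- function(seqs, path) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
}
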