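#' Round half away from zero
#'
#' Display rounding used throughout the package's reports: ties round away
#' from zero (so 5.85 kbp prints as 5.9, 12.55 as 12.6), unlike base
#' [round()]'s round-half-even. All internal computation is done at full
#' precision; this is applied only at presentation time.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(5.85)  # 5.9
#' round_half_up(85.57047)  # 85.6
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# format at one decimal with half-away-from-zero ties, as in printed tables
fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a genome argument (DNAStringSet or named character) to DNAStringSet
as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) {
    if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == ""))
      stop("a character genome must have non-empty contig names")
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a DNAStringSet or a named character vector")
}
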