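---
title: "Dating LTR retrotransposon insertions and scanning for RIP"
author: "ltrclock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating LTR retrotransposon insertions and scanning for RIP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrclock)
```

## The problem

Fungal genomes are usually compact. When one is several times larger than
its relatives — as the caterpillar fungus *Ophiocordyceps sinensis* is,
with a 119.2 Mbp assembly that is ~81% repeats and ~72% LTR
retrotransposons — the interesting questions are *when* the repeat
expansion happened and *how the host fought back*. `ltrclock` packages the
standard analyses behind those questions:

1. **insertion dating** of full-length LTR elements from the divergence of
   their twin terminal repeats,
2. the **repeat landscape** (element length binned by divergence, read as
   an insertion-activity timeline),
3. a **RIP scanner** for the C→T hypermutation fungi direct at repeats,
4. **enrichment machinery** for genes in and near LTR regions, and
5. assembly/composition bookkeeping (N50, GC, coding and repeat
   fractions).

Because the real genome is large and its annotation pipeline long, the
package also ships a **synthetic-genome generator** that plants elements
of *known* age so that every stage can be validated against ground truth
on a laptop.

## The clock model

An LTR retrotransposon inserts with two byte-identical terminal repeats.
Each repeat then accumulates substitutions independently at clock rate
$r$ (substitutions/site/year), so after $T$ years the expected divergence
between the twins is $K = 2rT$, inverted as

$$T = \frac{K}{2r}, \qquad r = 1.02\times10^{-9}\ \text{subs/site/year by default.}$$

The observed p-distance $p$ underestimates $K$ because of multiple hits;
we correct with Jukes–Cantor,

$$K = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4p}{3}\right),$$

which is exact under equal substitution rates. A Kimura two-parameter
correction is available via `date_elements(model = "K2P")`; at the low
divergences of datable elements the two agree closely. Elements with
$p \ge 3/4$ are *saturated*: they are reported as undatable
(`datable = FALSE`), never silently dropped, and the landscape accounts
for their length separately so total element length is conserved.

Divergence is computed between the two *terminal repeats* — the standard
construction for insertion dating, since the repeats are non-coding and
identical at insertion. Synonymous-site machinery is deliberately not
used here: there is no reading frame on an LTR.

### Numerical choices

* **Alignment.** Twin repeats are aligned end-to-end with an affine-gap
  Gotoh aligner (Rcpp). Default scoring {match +1, mismatch −1, gap open
  −4, gap extend −1}; a gap run of length $k$ costs
  `gap_open + (k−1)·gap_extend`. Traceback ties break deterministically
  (diagonal, then up, then left), so outputs are reproducible to the
  byte. The aligner is verified against a brute-force recursion on all
  random pairs up to length 12.
* **Gap policy.** p-distance uses pairwise deletion only: columns with a
  gap or `N` in either row are excluded. Indels carry no signal under the
  substitution-clock model, so no indel-aware variant is offered.
* **Landscape bins.** Default width 0.01 substitutions/site: at the
  default $r$, a 30 My cohort sits at $K \approx 0.061$ and a 40 My
  cohort at $K \approx 0.082$, two distinct bins. Note that a cohort mean
  can sit arbitrarily close to a bin edge (0.0612 nearly straddles the
  0.06 edge), so "which bin is modal" for such a cohort is decided by
  sampling noise between the two adjoining bins; conclusions should be
  drawn from the histogram, not from a single modal bin label.
* **Incomplete elements** (one terminal repeat) are excluded from dating
  and listed in the result's `"skipped"` attribute, mirroring the usual
  restriction of dating to elements complete at both ends.

## The RIP scanner

Repeat-induced point mutation converts C→T preferentially in CpA context
(equivalently G→A in TpG on the other strand), enriching TpA at the
expense of CpA/TpG. Two dinucleotide indices capture this:

* product index $= \mathrm{TpA}/\mathrm{ApT}$ — rises with RIP;
* substrate index $= (\mathrm{CpA}+\mathrm{TpG})/(\mathrm{ApC}+\mathrm{GpT})$
  — falls with RIP.

`scan_rip()` tiles each contig (default 1 kb windows, 500 bp step — a
conventional genome-scan resolution that still resolves element-scale
features of ~6 kb) and calls a window RIP when **both** thresholds hold:
product > 1.61 **and** substrate < 0.53, the conventional cutoffs.
Consecutive RIP windows merge into regions, exported as BED (0-based
half-open) or GFF3.

Degenerate windows are handled explicitly: a zero denominator makes the
index *undefined* (`NA`), and an undefined index never satisfies a
threshold — a pure AT microsatellite has an enormous product index but no
substrate signal, and is not called. Both indices are invariant under
reverse complement (TA and AT are their own reverse complements; the CpA/TpG
and ApC/GpT pairs swap within their sums), so scanning is strand-agnostic.
The tail of a contig is covered either by a final partial window (kept
when at least half a window long) or by a final full window anchored at
the contig end, so every base is covered whenever `step <= window`.

## Enrichment machinery

`flank_overlap_genes()` implements the flank rule used for LTR-adjacent
gene analysis: each element span is extended 1 kb both ways (clipped at
contig ends) and a gene counts — once — if any coding interval overlaps
any extended region by at least one base. `family_enrichment()` then
tests each gene family one-sided (over-representation) with Fisher's
exact test against the whole-gene background, reporting raw p-values
first and Benjamini–Hochberg q-values alongside.

For the expansion-subset question (are secondary-metabolite genes
over-represented among expanded gene families?) the 2×2 table is built
subset-vs-rest (exclusive): the subset row against the remainder of the
gene catalogue, so the four cells partition it. The published counts
(26/243 vs 68/8621) give $p \approx 2\times10^{-23}$ under this
construction and also under the inclusive alternative — both far below
the conventional reporting floor of $2.2\times10^{-16}$, which this
package never imposes: p-values are reported at full precision.

`chi_square_rxc()` covers the multi-genome k×2 category comparisons
(Pearson statistic, margin-based expecteds, no continuity correction,
warning on expected counts < 5), and `filter_hits()` applies the standard
identity/coverage/p thresholds (30 or 50 / 50 / 1e-10) to 12-column
tabular homology hits. The hit table's score column is conventionally an
e-value even when labelled p; it is filtered as-is.

## The synthetic-genome generator

`simulate_genome()` builds contigs of i.i.d. bases at a configurable GC
(default 44.7%, the *O. sinensis* genome value), then plants
non-overlapping features:

* **genes** with exon/intron structure (defaults: 3 exons of mean 539 bp,
  introns of mean 112 bp, Poisson-dispersed; exon sequence at coding GC
  61%) — these defaults echo the published gene-model statistics;
* **LTR elements** from `element_spec()` cohorts: an ancestral terminal
  repeat with canonical TG…CA termini is copied twice around a random
  internal region; each copy is mutated independently for `age_years` at
  `clock_rate`; a 4–6 bp target-site duplication flanks the insertion.

`mutate_clock()` applies the *exact JC69 endpoint distribution*: a site
substitutes with probability $\tfrac{3}{4}(1-e^{-4d/3})$ for branch
length $d$, uniformly to another base. This keeps the generator matched
to the estimator's model — twin divergence is exactly JC with $K = 2rT$
in expectation, so age recovery tests measure estimator error, not model
mismatch. No indels are simulated; gap handling is exercised separately
with hand-built alignments.

`apply_rip()` mutates each CpA's C (and TpG's G) with a configurable
intensity, judging contexts on the input in one left-to-right pass, so a
mutation never creates or destroys another's context. True biological RIP
parameters are unknown; intensity is a simulation knob, not an estimate.

A single seeded generator drives all draws in documented order, making
FASTA/GFF3/truth outputs byte-identical across runs of the same
configuration.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: nested and recombining insertions (solo
LTRs), transposition bursts as a stochastic process (ages are specified,
not drawn), selection, indels, compositional heterogeneity of real
chromatin, and the action of real RIP machinery over evolutionary time.
Recovery results on simulations bound estimator error under the stated
model only.

## Problem sizes and verification

The test-suite and acceptance runs use cohorts of 100 elements with 1 kb
terminal repeats on 1 Mb contigs — at that size the standard error of a
cohort's mean p-distance is ~0.0007, so mean age recovery within 10% of
truth is a comfortable but non-trivial bar; smaller unit-test simulations
use proportionally looser or exactly-derived expectations. The
direct-repeat detector (`detect_ltr_pairs()`, exact k-mer seeds + X-drop
ungapped extension) is plumbing so synthetic genomes run end-to-end
without external annotation; it is validated on planted elements and on
100 kb of element-free background (zero false pairs), and is not a
substitute for a structural LTR finder on real genomes.

Every numeric claim above is recomputed by the package's tests or by
`scripts/acceptance.R`; neither this vignette nor the README states
results the code does not produce.

## Known limitations

* Dating assumes a single constant clock rate; rate variation across
  lineages or time biases ages proportionally.
* Saturated and incomplete elements are reported but not dated; solo-LTR
  dating is out of scope.
* Superfamily labels are taken from the annotation, never inferred from
  sequence.
* The RIP scanner is window-based; it does not implement alignment-based
  (repeat-family) RIP analysis.
* `run_pipeline()` guarantees determinism, not parallel speed; it is a
  thin orchestration over the exported functions, which remain the
  primary interface.
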