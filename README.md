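# ltrclock

Molecular-clock dating of LTR retrotransposon insertions, RIP scanning,
flank-gene enrichment and genome-composition accounting — the analysis
stack for asking *when* a repeat-inflated genome expanded and how the
host suppressed its transposons. The motivating case is the caterpillar
fungus *Ophiocordyceps sinensis*, whose 119.2 Mbp assembly is ~81%
repeats and ~72% LTR retrotransposons, but every stage works on any
FASTA + GFF3 pair (or on the package's own simulated genomes).

For whom: genome-evolution researchers with an assembled genome and a
repeat annotation who want per-element insertion ages, a repeat
landscape, RIP calls and enrichment statistics from one reproducible
toolchain — with a seeded synthetic-genome generator so each stage is
testable against ground truth.

## The model

An LTR element inserts with two identical terminal repeats that then
diverge neutrally under a clock of rate *r* substitutions/site/year
(default 1.02 × 10⁻⁹). From the twin-repeat alignment we take the
pairwise-deletion p-distance, correct for multiple hits with
Jukes–Cantor,

    K = -(3/4) · ln(1 - 4p/3),        T = K / (2r),

and stack each element's span length by K to build the insertion
landscape. RIP (repeat-induced point mutation, the fungal C→T defence at
CpA sites) is scanned in sliding windows with the two dinucleotide
indices — product TpA/ApT > 1.61 and substrate (CpA+TpG)/(ApC+GpT) <
0.53, both required. Gene-family enrichment in LTR ± 1 kb flanks uses
one-sided Fisher exact tests with BH q-values alongside. See the
methods vignette (`vignettes/ltr-insertion-dating.Rmd`) for assumptions,
numerical choices and limitations.

## Worked example

Plant two cohorts of known age, date them back, and scan for RIP:

```r
library(ltrclock)

cfg <- sim_config(seed = 7, contig_length = 500000,
  elements = list(
    element_spec("Gypsy", ltr_length = 500, internal_length = 4900,
                 age_years = 30e6, copies = 20),
    element_spec("Copia", ltr_length = 500, internal_length = 4900,
                 age_years = 10e6, copies = 10)))
sim  <- simulate_genome(cfg)
ages <- date_elements(sim$genome, sim$annotations$elements)
head(ages[, c("element_id", "superfamily", "aligned_sites", "p", "K", "T")], 4)
#>   element_id superfamily aligned_sites     p       K        T
#> 1   elem0001       Gypsy           500 0.056 0.05820 28529870
#> 2   elem0002       Gypsy           500 0.066 0.06909 33865915
#> 3   elem0003       Gypsy           500 0.060 0.06254 30655003
#> 4   elem0004       Gypsy           500 0.068 0.07128 34942481
mean(ages$T[ages$superfamily == "Gypsy"]) / 1e6   # 31.55 (truth: 30 My)
mean(ages$T[ages$superfamily == "Copia"]) / 1e6   # 11.87 (truth: 10 My)

head(build_landscape(ages), 3)      # element bases stacked by K, per superfamily
#>   K_low K_high superfamily length_bp
#> 1  0.01   0.02       Copia     17700
#> 2  0.02   0.03       Copia     29500
#> 3  0.03   0.04       Copia     11800

scan_rip(sim$genome)   # no RIP simulated here, none called
#> RIP scan: 999 windows (window 1000 bp, step 500 bp); 0 called RIP; 0 merged regions
```

Each `T` is that element's estimated insertion age in years: the p =
0.056 element carries K ≈ 0.058 substitutions/site between its twin
repeats, i.e. ~28.5 My at the default clock. Cohort means land within a
few percent of the planted ages; the landscape rows are the histogram
bars of the insertion-activity timeline.

Desk arithmetic on the published *O. sinensis* summary tables is built
in:

```r
os  <- osinensis_summary()
tab <- ltr_type_table(os$ltr_superfamilies$superfamily,
                      os$ltr_superfamilies$length_kbp * 1000,
                      counts = os$ltr_superfamilies$count)
tab$pct <- round_half_up(tab$pct)
tab
#>   superfamily     n length_kbp   pct
#> 1       Copia 27699  36125.849  42.2
#> 2        ERV1   269    172.594   0.2
#> 3       Gypsy 26672  39230.793  45.9
#> 4       Ngaro   147    186.706   0.2
#> 5         Pao   143     15.967   0.0
#> 6     Unknown  6818   9803.887  11.5
#> 7       Total 61748  85535.796 100.0

fisher_exact_2x2(expansion_enrichment_table(), "greater")
#> 2.03e-23  (secondary-metabolite enrichment of the expansion subset)
```

Gypsy and Copia account for 45.9% and 42.2% of total LTR length; the
enrichment p-value is reported at full precision rather than floored at
2.2e-16.

A YAML-driven orchestration (`run_pipeline()`, with a thin CLI wrapper in
`inst/scripts/ltrclock`) chains simulate → date-ltrs → rip-scan → stats
and writes a manifest with file digests for reproducibility.

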