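# mitoprofiler

Tidy descriptive analytics for circular annotated mitochondrial genomes.

Insect mitogenomes are compact circular molecules — 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs and one A+T-rich control region (CR) — and papers
describing a newly sequenced mitogenome report a standard repertoire of
statistics: per-partition nucleotide composition and strand skews, codon
usage and RSCU, gene overlaps and intergenic spacers around the circle,
start/stop-codon classes (including truncated stops completed by
polyadenylation), gene-order rearrangements relative to the ancestral insect
arrangement, structural elements of the control region, tRNA stem pairing,
and a concatenated PCG supermatrix handed to tree inference. `mitoprofiler`
implements that repertoire as composable, tested R functions, for
mitogenome annotators who want those tables reproducible from the annotation
rather than re-derived by hand.

Every user-facing function takes a data frame (or a light `mitogenome`
object) and returns a tibble, so results chain with the pipe; fitted-object
style summaries come from `glance()`/`tidy()`, and each result type has an
`autoplot()` method.

## The statistics at the core

* **Strand skews**: AT skew = (A − T)/(A + T), GC skew = (G − C)/(G + C),
  computed either from raw counts or from rounded printed percentages — the
  two modes can differ in the third decimal, so both are first-class and
  every profile is labelled with its `source_mode`.
* **RSCU** (relative synonymous codon usage): RSCU_c = n_c · k / Σ n_family,
  with k the synonymous-family size under the invertebrate mitochondrial
  code (translation table 5). The default pooled scheme treats leucine as
  one six-codon family (UUR + CUN) and serine as one eight-codon family
  (UCN + AGN), the convention used by codon-usage software; a `split`
  scheme (L1/L2, S1/S2) is available.
* **Circular adjacency**: for consecutive features, signed gap =
  downstream start − upstream end − 1 (negative = overlap, positive =
  spacer), closed around the origin.
* **Breakpoint distance**: directed adjacencies present in one circular
  gene order but absent in the other; 0 iff the orders match up to rotation.
  `compare_gene_order()` also names genes whose single relocation
  reconciles the orders.
* **Repeat scanning**: exact homopolymer, microsatellite and tandem-repeat
  detection over every unit length, verified against a brute-force oracle
  in the test suite.

## Worked example

The package ships the annotated gene table and the 64-codon count table of
the *Monema flavescens* mitogenome (15,396 bp, Lepidoptera: Limacodidae) as
plain-text fixtures. A fixtures-only report:

```r
library(mitoprofiler)
rep <- generate_report(gene_table = table2_fixture(),
                       codon_counts = table3_fixture())
rep
#> <mito_report>
#>   adjacency: 38 junctions; overlap 24 bp / 5 sites; spacer 218 bp / 18 sites
#>   strand census: 23 forward / 14 reverse
#>   codon table: 3716 codons counted
#>   gene order: 3 breakpoint(s) vs reference; moved: trnM
#>   skipped: composition_table: missing sequence; codon_calls: missing sequence; ...
```

The adjacency line is coordinate-derived; the published intergenic column
(which disagrees with the coordinates at one junction) is carried alongside
and summarised with `overlap_summary(rep$adjacency_table, source =
"declared")`, giving the paper's 29 bp over 6 locations. The longest
overlap (9 bp, trnW/trnC) and longest spacer (50 bp, trnQ/nad2) are in
`glance(rep$adjacency_table)`. The gene-order line reports the
lepidopteran trnM translocation relative to the ancestral insect
arrangement.

Codon usage:

```r
library(dplyr)
rscu(table3_fixture()) |>
  filter(codon %in% c("UUA", "UCU", "UGA", "AUU")) |>
  mutate(rscu = round_half_up(rscu, 2))
#>   codon aa    family count  rscu
#> 1 UUA   L2    Leu      459  5.1
#> 2 UCU   S2    Ser       99  2.39
#> 3 UGA   W     W         89  1.87
#> 4 AUU   I     I        424  1.86
```

UUA is the most over-represented codon (RSCU 5.1 in a six-codon family):
the A+T-rich genome strongly prefers A/T-ending synonymous codons.

A synthetic genome with a full truth ledger, and its composition profile:

```r
sim <- simulate_mitogenome(simulation_config(seed = 7))
sim$genome
#> <mitogenome> SIM000007: circular, 15,396 bp, 38 features
#>    PCG: 13, tRNA: 22, rRNA: 2, control_region: 1

partition_composition(sim$genome) |>
  transmute(partition, size, pct_AT = round_half_up(pct_AT, 1))
#>   partition       size pct_AT
#> 1 mitogenome     15396   80.3
#> 2 PCGs           11151   78.7
#> 3 tRNAs           1499   83.7
#> 4 rRNAs           2151   84.1
#> 5 control region   401   92.0
```

The planted control-region elements (ATAGA motif, poly-T/poly-A runs,
(AT)10 microsatellite, 51 bp tandem repeat) are recovered exactly by
`find_motif()`, `longest_run()`, `find_microsatellite()` and
`find_tandem_repeats()` at the positions recorded in `sim$truth`.

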