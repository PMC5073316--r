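---
title: "Methods: descriptive mitogenome analytics and the synthetic-genome generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptive mitogenome analytics and the synthetic-genome generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofiler)
```

`mitoprofiler` reimplements the descriptive statistics that mitogenome
papers report — composition and skew, RSCU, adjacency geometry, start/stop
classes, gene-order rearrangement, control-region elements, tRNA stem
pairing, supermatrix export — as a tested pipeline, together with a
synthetic-genome generator that makes every stage checkable against planted
ground truth. This vignette records the modelling conventions, the
parameters that matter, and the design decisions taken where more than one
defensible choice existed.

## Coordinate and strand conventions

All coordinates are 1-based and fully inclusive, the convention of
published mitogenome gene tables; conversion to other conventions happens
only at I/O boundaries. The circle is linearised with position 1 at the
first annotated gene; a feature wrapping the origin is stored with
`end < start` and sorted last. "Forward" is the majority (J) strand —
`F` in gene tables — and "reverse" the minority (N) strand. Declared sizes
from source tables are carried verbatim (`declared_size`) but never
trusted: computed lengths from coordinates are authoritative. The packaged
gene table itself contains one such conflict (trnY declared 67 bp, span
69 bp); the package flags rather than resolves it.

Unknown bases (`N`) are legal in sequences; composition counts report them
separately and exclude them from the A/C/G/T denominators.

## Composition and skew: two modes, deliberately

AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C) are scale
invariant, so they can be computed from raw counts or from percentages.
Published tables print percentages rounded to one decimal, and skews
recomputed from those rounded values can differ from count-based skews in
the third decimal — for the packaged genome, the whole-molecule AT skew is
0.0137 from percentages (1.1/80.5) but 0.0129 from the printed raw counts
(160/12390). Neither is "the" right number, so both modes are first-class:
`partition_composition()` produces `source_mode = "from_counts"` profiles,
`profile_from_percentages()` reproduces printed table skews exactly, and
every profile row is labelled with the mode that produced it.

Partition profiles concatenate category members in genomic order. By
default member sequences are taken in coding orientation (reverse-strand
genes reverse-complemented), because strand-pooled statistics are not
recoverable from published tables; `orientation = "genomic"` switches to
the stored strand. Overlapping features contribute their full span to
their own partition — partitions are reported independently, as in the
literature, and may double-count shared bases.

Report-time rounding is half-away-from-zero (`round_half_up()`), three
decimals for skews and one for percentages, matching how these tables are
printed; stored values are always full precision.

## Codon usage and RSCU

`count_codons()` mirrors how published codon totals are compiled: per CDS,
the initiation codon is excluded; a trailing 1–2 nt remainder is excluded
as a truncated stop; a final complete TAA/TAG is excluded; a final complete
non-stop codon is kept. Codons are keyed as RNA in outputs and DNA
internally.

RSCU_c = n_c · k / Σ_{family} n, with k the synonymous-family size under
the invertebrate mitochondrial code (AGA/AGG = Ser, AUA = Met, UGA = Trp).
Published mitogenome RSCU tables do not state how the six-fold and
eight-fold degeneracies are pooled; the package's default `pooled` scheme —
leucine one six-codon family (UUR + CUN), serine one eight-codon family
(UCN + AGN), Trp {UGA, UGG}, Met {AUA, AUG}, and the two terminators
{UAA, UAG} as their own family — is the scheme that reproduces every RSCU
value in the packaged count table at printed precision, and is the
convention of standard codon-usage software. A `split` scheme (L1/L2,
S1/S2 as separate families) is provided for comparison. Treating the
terminators as a countable family looks odd next to the "termination
codons excluded" footnote such tables carry, but the packaged table prints
a UAA count of 8 with RSCU 2; the fixture reproduces the table at face
value and the tension is simply documented here.

## Adjacency auditing

Signed gaps are computed from coordinates only: gap = downstream start −
upstream end − 1, with circular closure from the last feature back to the
first. Published gene tables also print an intergenic column; for the
packaged table that column disagrees with the coordinates at one junction
(the trnS2 row prints −5 where the coordinates give +25), which cascades
into different totals (coordinates: 24 bp of overlap at 5 junctions;
printed column: 29 bp at 6). The ledger therefore carries both a computed
and a `declared_gap` column, and `overlap_summary()`/`spacer_summary()`
take `source = "computed"` (default) or `"declared"` so either accounting
is available explicitly — neither is silently preferred. The two accounts
agree on the extremes (longest overlap 9 bp at trnW/trnC, longest spacer
50 bp at trnQ/nad2).

Start codons are canonical iff they match ATN. Truncated stops are any
trailing 1–2 nt remainder; T, TA and A are accepted silently (T and TA
complete to UAA by polyadenylation; a bare A is conventionally annotated
as a truncated stop in these genomes even though polyadenylation cannot
complete it to UAA), and other literals warn.

Gene-order comparison treats the circle as rotation-equivalent but not
reflection-equivalent, and ignores strand: the rearrangement argument in
this literature is positional. Breakpoints are directed adjacencies of the
observed order absent from the reference; `moved_genes` lists every gene
whose single deletion makes the orders rotation-identical, which for the
lepidopteran vs ancestral-insect arrangements singles out trnM. The
ancestral arrangement ships as the built-in `"ancestral_insect"` preset
(the *Drosophila*-type order with trnM between trnQ and nad2).

## Control-region scanning

All scanners are exact (no mismatches or indels) and deterministic. This
is a deliberate simplification of dedicated tandem-repeat software:
at control-region scale (hundreds of bp) exhaustive exact scanning over
every unit length is affordable and fully verifiable — the test suite
checks the tandem scanner against an independent brute-force oracle on
hundreds of random strings. Matching with mismatches is out of scope for
v1.

Conventions: homopolymer ties break to the smallest start; microsatellite
units are normalised to their primitive root; partial trailing copies
count fractionally; tandem candidates whose unit is itself a repetition
are dropped (they re-appear at the smaller period); overlapping candidates
are resolved by longest total length, then smallest unit, then smallest
start. The conserved pentamer scanned by default is ATAGA; ATATG is a
known variant reported for the same region, so the motif is a parameter
rather than a constant, and `find_motif()` can scan both strands.

## tRNA stem auditing

De novo tRNA folding is out of scope (that is the job of dedicated
structure predictors); stem layouts are inputs — from the simulator's
truth ledger or a user's JSON file. Pairs are classified Watson–Crick /
G-U wobble / mismatch; because the descriptive literature counts wobble
pairs among "unmatched" base pairs, `glance()` reports wobble and mismatch
separately plus a combined `non_wc` tally matching that vocabulary.

## Supermatrix construction

`extract_pcgs()` returns the 13 canonical PCGs in coding orientation;
`translate_mito()` applies translation table 5, drops a trailing truncated
stop and a final complete stop, renders internal stops as `*` with a
warning, and translates the first codon by the table (a CGA start stays
arginine — no forced methionine). Alignment and masking are delegated to
the standard external tools; `concatenate_alignments()` consumes
pre-aligned blocks and records partition intervals that tile the matrix.
Writers emit FASTA plus a RAxML-style partition sidecar, relaxed PHYLIP,
and NEXUS with a sets block. The concatenation order defaults to
alphabetical canonical order since source publications rarely state one;
it is overridable.

## The synthetic-genome generator

`simulate_mitogenome()` emulates the study system the package describes: a
~15.4 kb lepidopteran mitogenome with 37 genes plus control region. Gene
sizes, strands, anticodons, start/stop codons and default junction gaps
(including the real overlaps) come from the packaged gene table, so the
default genome reproduces the published architecture coordinate-for-
coordinate; the gene order is the derived lepidopteran arrangement, with
`"ancestral_insect"` and explicit orders as alternatives.

Composition targets default to the published per-partition values (whole
genome 80.5% A+T, PCGs 78.7%, tRNAs 82.4%, rRNAs 84.5%, CR 93.3%, with
the corresponding skews). Targets are met in expectation, not exactly; the
truth ledger records realized counts, and tests use sampling-concentration
bounds (at n ≈ 15,000 a binomial draw concentrates well within one
percentage point).

PCGs are built codon-by-codon: the printed start codon, internal codons
sampled i.i.d. from a stop-free codon distribution, and a stop derived
from the gene length mod 3 (coordinates are authoritative, so a printed
complete stop on a non-multiple-of-three span becomes a truncated stop).
The internal-codon distribution is induced by i.i.d. base probabilities
with TAA/TAG removed; because removing the two A+T-rich terminators drags
the realized A+T content below the base-level parameter, the parameter is
calibrated by a one-dimensional root solve so the stop-free distribution
hits the target exactly in expectation. An alternative `codon_bias` mode
draws per-family Dirichlet weights with a configurable concentration for
studying synonymous-codon bias itself.

tRNAs get explicit cloverleaf layouts — acceptor 7 bp, D 4 bp, anticodon
5 bp with a 7 nt loop holding the anticodon, T 4 bp (the 7-component
anticodon element is read as the loop; stems are sized to fit 63–74 nt
genes), trnS1(AGN) without a D arm — with wobble and mismatch pairs
planted at configurable per-pair rates (defaults emulate the ~18 wobble
and ~7 mismatch pairs reported across 22 tRNAs). Complementing the stems
necessarily neutralises skew inside stem regions, so realized tRNA-partition
skews sit nearer zero than the nominal targets; A+T content is unaffected.

The control region plants, in order: the conserved pentamer, a poly-T run
(12 nt default), an (AT)10 microsatellite, a tandem repeat (51 bp unit,
two copies), and a poly-A run (10 nt default), at seed-determined
positions separated by single non-extending flank bases. Published
descriptions of this region name the elements but not the run lengths;
the defaults are within the range reported for lepidopteran control
regions and are configurable. A sanitiser then removes chance look-alikes
from the background (stray motif occurrences, competing homopolymer runs
or AT chains) by flipping single bases to C — a base no element contains —
flipping inside the tandem only in mirrored positions so the repeat stays
exact. This guarantees the recovery tests are exact: each planted element
is the unique hit its scanner reports.

Overlapping junctions share sequence, with the upstream feature owning the
shared bases; a downstream feature whose prefix is overwritten (e.g. atp6
under the real 7 bp atp8 overlap) has its truth-ledger entries recomputed
from the realized sequence at generation time, so the ledger always
describes the genome as built. The recomputation uses the generator's own
bookkeeping (direct substring extraction and codon splitting), separate
from the analysis-path functions it is later checked against.

Determinism: all randomness flows through R's RNG from the single config
seed; a config reproduces its genome and ledger byte-for-byte, and the
simulator writes a GenBank + FASTA + truth-JSON triplet whose ledger is
never re-derived from the GenBank file.

## Numerical and degenerate-input choices

* Skews are undefined (an error, not 0) when the denominator is zero.
* Zero-count synonymous families get all-zero RSCU without error.
* `longest_run()` returns a zero-length sentinel when the base is absent.
* Repeat spans use `floor(copies × unit)` with a 1e-9 guard so exact
  ratios survive floating-point round trips.
* GenBank support is deliberately minimal: single record, locations
  `a..b`, `complement(a..b)` and one origin-wrapping `join`; anything else
  errors loudly. Multi-record files, EMBL and GFF3 are out of scope.

## Problem sizes used in the tests

The suite runs entirely on generated data and the packaged fixtures:
full-size (~15.4 kb) simulated genomes for recovery and round-trip checks,
random strings of 30–200 nt (500 seeds) for the tandem-scanner-vs-oracle
sweep, and 20 kb uniform sequences for skew-noise bounds. These sizes were
chosen so each property is exercised at the scale the method targets while
the whole suite stays interactive.

## Known limitations

* Exact matching only in all repeat scanners; diverged tandem copies are
  not found.
* No replication-origin inference, no sliding-window skew plots.
* Gene-order comparison ignores strand and does not reconstruct
  rearrangement histories (no tandem-duplication/random-loss or inversion
  distances).
* The simulator plants composition at the partition level; it does not
  model codon-position heterogeneity, gene-specific composition, or
  within-partition autocorrelation, so passing recovery tests demonstrates
  pipeline correctness, not realism of fine-scale sequence structure.
* Translation handles ambiguity as X; frameshifts and RNA editing are out
  of scope.
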