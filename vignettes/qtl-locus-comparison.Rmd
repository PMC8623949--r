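---
title: "Comparing insect-tolerance QTL loci across cereal genomes"
author: "qtloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing insect-tolerance QTL loci across cereal genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtloci)
```

## The problem

Major insect-tolerance loci in wheat — the stem-solidness QTL on 3BL that
limits wheat stem sawfly damage, and the 2B/1A/4A QTLs associated with
orange wheat blossom midge resistance — are delineated genetically by panels
of molecular markers (SNP-array probes and similar short sequences). To ask
how such a locus has been shaped in related cereals (barley, rye, oat,
rice), one projects the marker panel onto each genome assembly, takes the
chromosomal interval the markers delineate, compares the gene content and
order of the homologous intervals, and searches the intervals for conserved
non-coding features, in particular miRNA precursors.

`qtloci` implements that workflow as composable, tested R functions:

1. **Marker projection** — alignment hits of each probe against an
   assembly, filtered by species-scaled coverage/identity thresholds.
2. **Region inference** — a homologous interval per genome from the span
   of the retained hits, with a continuity rule against scattered paralogs.
3. **Gene extraction** — every gene intersecting the interval, represented
   by its longest coding isoform.
4. **Synteny comparison** — best-hit homolog assignment against a chosen
   reference genotype, gene-order comparison, inversion calling.
5. **miRNA discovery** — a homology scan of the interval against a mature
   miRNA reference set, precursor window folding, four structural
   acceptance criteria, family summaries, and miRNA target scoring.

Because the real inputs are multi-gigabyte assemblies, the package also
ships a synthetic multi-genome locus simulator with complete ground truth,
so that every stage — and the pipeline end to end — is testable at desk
scale. The exported functions and `run_pipeline()` are the interface; each
stage is independently callable on data loaded through the `read_*`
functions.

## Homology filtering

External aligner output is accepted as the standard 12-column tabular
format plus query and subject lengths (`read_hit_table()`). Internally,
`internal_scan()` provides an ungapped ≤ *k*-mismatch scanner (every
full-length placement of the query on either strand with at most *k*
substitutions), which is exact, sufficient for marker panels, synthetic
fixtures and the miRNA mature scan, and is checked in the test suite
against a brute-force window enumeration. Gapped transcript-level homology
on real data remains the job of an external aligner, fed in through the
hit-table interface.

Filter presets scale identity with evolutionary distance from wheat
(`homology_presets()`):

| context | coverage | identity |
|---|---|---|
| marker, wheat genotypes | 0.90 | 95 |
| marker, barley/rye | 0.90 | 90 |
| marker, oat | 0.90 | 85 |
| marker, rice | 0.90 | 80 |
| transcript projection, wheat | 0.80 | 95 |
| transcript projection, barley/rye | 0.80 | 90 |
| transcript projection, rice | 0.50 | 80 |
| CDS region-identification, rice | 0.50 | 80 |
| CDS region-identification, barley | 0.80 | 90 |

Query coverage is computed from the aligned query interval
(`qend − qstart + 1`)/`qlen`, not from the alignment length, which gaps
inflate. Three further rules mirror the workflow's special cases:

* **Ambiguity** (`drop_ambiguous_markers()`): a marker whose best
  coverage/identity is achieved at two or more distinct locations is
  discarded entirely; otherwise only its best hit is kept. "Distinct"
  means different chromosomes or intervals ≥ 10 kb apart — split or tandem
  local hits do not disqualify a marker.
* **Oat contigs** (`match_oat_contigs()`): oat is matched at the contig
  level; since contigs are genomic and transcripts are spliced, a contig
  counts when any hit exceeds 85% identity (strictly) over ≥ 300 aligned
  nucleotides.
* **Protein annotation** (`filter_protein_matches()`): Uniprot
  (Viridiplantae) matches at ≥ 50% similarity and ≥ 50% coverage;
  Brachypodium proteome matches at ≥ 75% similarity and ≥ 50% coverage.

## Region inference

`infer_interval()` groups filtered hits by chromosome and, whenever at
least `min_support` (default 3) distinct queries support a chromosome,
emits the interval from the minimum to the maximum strand-normalized hit
position. One spurious hit can never nominate a region, which mirrors the
failure mode where a distant genome yields too few marker hits and the
region must instead come from transcript projection. Borders snap to hit
extremes; gene-aware interpretation happens downstream.

`continuity_filter()` implements the retention rule used with permissive
transcript-projection thresholds: hits are clustered by single linkage with
a maximum inter-hit gap (default 2 Mb for transcript projections; 5 Mb is
suggested for sparse marker panels), and only the cluster with the most
distinct queries survives (ties by summed bitscore, then leftmost). The
defaults are package choices — no numeric continuity definition exists in
the source workflow — and both parameters are recorded in every run
report.

## Gene extraction and synteny

`extract_locus_genes()` lists genes intersecting the interval (any overlap
by default; strict containment is available) and keeps, per gene, the
isoform with the maximal summed CDS length; ties resolve to the
lexicographically smaller transcript id so reruns are bit-identical. Genes
without coding isoforms (e.g. ncRNA genes) are excluded from transcript
sets and counted separately.

`assign_homologs()` filters query-CDS-vs-reference-CDS hits by a preset and
assigns each query gene its best reference gene by bitscore, then percent
identity, then proximity of the reference rank to the assignments of the
query's chromosomal neighbours. The one-to-one best-hit scheme matches the
"one reference color per gene" semantics of comparative locus figures;
genes without a passing hit stay unassigned.

`call_inversions()` makes explicit what such figures show by eye: every
maximal run of at least `min_run` (default 4) consecutive *mapped* genes
whose reference ranks strictly decrease is reported as a candidate
inversion. It is a reproducible surrogate, not a breakpoint mapper;
unmapped genes inside a run are skipped, so a lost boundary gene shortens
but does not break a call.

## miRNA discovery

`scan_matures()` finds every window on both strands of the interval within
Hamming distance 1 of any mature in the reference set (miRBase-style ids;
family names are normalized as in `tae-miR1122b-3p → miR1122`).

`extract_candidates()` proposes precursor windows of 100/150/200/250 nt
around each hit, with the mature anchored near the 5′ or the 3′ arm. The
anchored end keeps a 10-nt margin beyond the mature: matures do not sit at
the precursor terminus (the Dicer duplex has a lower stem), and the margin
keeps the sequence that pairs with the mature-proximal stem inside the
window — with a zero margin, the orphaned partner strand is free to pair
elsewhere and minimum-free-energy refolding can turn a structurally
defective hairpin into a compliant one purely through window placement.
The geometry (lengths and margin) is a package decision; the source
workflow does not state one.

`fold_rna()` folds windows with ViennaRNA's `RNAfold` (deterministic for a
fixed engine version; tests assert structural predicates, never exact free
energies, to stay robust to engine updates). `evaluate_criteria()` then
applies the four acceptance criteria on the dot-bracket structure:

1. **Dicer cut sites** — the first and last 2 bases of the mature are
   paired (the cut-site width is configurable, 1–3 bp);
2. **no multibranch** — no loop within the mature/star span has more than
   one emanating helix;
3. **not in head** — the mature does not overlap the terminal loop of its
   hairpin;
4. **duplex mismatches** — at most 4 unpaired bases within the mature and
   at most 6 within the star, where the star is read off the structure as
   the partners of the mature plus the canonical 2-nt 3′ overhang.

A candidate is accepted only if all four hold. Criterion 4 counts unpaired
positions (so an opposite-arm bulge shows up as unpaired mature bases);
"head" is the terminal loop as parsed from the structure. Overlapping
accepted windows of one family — including the mature-arm and star-arm
anchored windows of a single hairpin, whose anchors lie within ~100 nt —
collapse to the lowest-energy representative (`dedupe_precursors()`). A
consequence worth noting when comparing counts with other pipelines: a
precursor is counted once per deduplicated genomic window, not once per
mature hit.

`summarize_families()` reports per-genome family sets, per-family precursor
counts, and the full sharing partition over every subset of genomes (the
numbers a multi-set Venn diagram displays), optionally merging wheat
genotypes into a single set as such figures conventionally do.

`score_target()` scores miRNA–transcript complementarity as a weighted
penalty ("expectation"): mismatch 1, G:U wobble 0.5, gap 2, every penalty
doubled at mature positions 2–13 (the seed region); sites at expectation
≤ 3 are retained. Site accessibility (UPE) is *not* computed — it would
require a windowed partition-function calculation that the expectation
filter does not depend on — and the disabled cutoff is recorded in the run
report so downstream users know the difference from a full psRNAtarget-style
screen.

## The synthetic locus generator

`simulate_locus_set()` builds an ancestral locus of alternating genes and
intergenic segments, then derives each genome by i.i.d. substitutions with
a 2:1 transition bias, planted structural events (inversion, translocation,
gene loss), and post-divergence hairpin insertions. Defaults describe the
desk-scale study the acceptance run uses: four genomes (an undiverged
reference and relatives at 2%, 5% and 8% substitution rates, spanning the
identity range the filter presets are scaled for), 20 genes of 300–1200 nt
with 1–3 isoforms, a 12-probe marker panel of 60–200 nt drawn from genic
sequence, and nine hairpin plantings (five clean, one decoy per criterion).
Markers are ancestral subsequences, so their divergence from each genome
tracks that genome's substitution rate, which is what makes the scaled
presets meaningful in tests; hairpins are inserted after divergence so the
planted mature always matches the reference set exactly, spread across the
central part of the locus so they fall inside the marker-delineated
interval.

`make_hairpin()` engineers the plantings: a perfect inverted repeat
(mature, A/C-only loop, star, GC-rich scaffold flanks) for clean
precursors, and single-criterion decoys — terminal mature mismatches
(criterion 1), two GC-rich stemlets replacing the loop (criterion 2), a
fold-back mature overlapping its own terminal loop (criterion 3), and a
star-side deletion forcing > 4 unpaired mature bases (criterion 4). Every
construct is folded and verified to produce exactly the intended criterion
profile before use; the duplex decoy deepens its deletion if the folding
engine ever redistributes the bulge. Substitution-only duplex decoys were
found to be rescued occasionally by register-shifting on AU-rich matures,
which is why the deletion design is used.

What the generator does **not** emulate: repeat and transposon landscapes
(real Triticeae intergenic space is mostly repeats, which inflate
ambiguous marker hits), gene families with recent paralogs, gapped
divergence (indels), fragmented assemblies, and annotation noise. Passing
tests therefore demonstrate correctness of the inference machinery under
the stated model, not robustness to every artifact of real assemblies; on
real data the hit tables should come from a gapped aligner and the presets
carry that burden.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout; BED export converts in one
  place (`to_bed_coords()`).
* Minus-strand hits keep `sstart > send` until interval construction
  normalizes them, so parsing is lossless.
* All randomness flows from one mandatory seed; the same seed gives
  byte-identical fixtures and reports.
* Ties: longest-isoform by lexicographic transcript id; homolog assignment
  by bitscore → identity → neighbour rank proximity → reference gene id;
  continuity clusters by support → summed bitscore → leftmost.
* Degenerate inputs: an empty hit list yields an empty interval table (not
  an error); an empty marker panel aborts the pipeline with an explicit
  message; a mature shorter than 18 nt is scanned with a warning; windows
  clipped at locus edges are flagged.

## A worked run

```{r run, eval = has_rnafold <- nzchar(Sys.which("RNAfold"))}
cfg <- simulation_config(
  seed = 1,
  events = list(list(genome = "genomeB", type = "inversion", genes = 5:12))
)
sim <- simulate_locus_set(cfg)
run <- run_pipeline(sim, marker_presets = c(
  genomeA = "wheat_marker", genomeB = "barley_rye_marker",
  genomeC = "rice_marker", genomeD = "rice_marker"))
run
run$inversions
subset(run$families$partition, n_families > 0)
```

The run report (`run$report`, serialized to `report.json` when an output
directory is given) contains every threshold actually used, so a run is
reproducible from the report alone. The problem sizes above — and the
smaller ones used inside the test suite (2–3 genomes, 10–16 genes) — are
the package's chosen desk-scale study conditions; `scripts/acceptance.R`
re-runs this default study from scratch and writes its headline quantities
as JSON.

## Known limitations

* Inversion calling assumes a single dominant ordering; nested or
  overlapping rearrangements produce fragmented calls.
* The internal scanner is ungapped; real diverged transcripts need an
  external gapped aligner.
* Precursor acceptance is sensitive to window placement in repetitive or
  self-complementary neighbourhoods; the 10-nt anchor margin mitigates but
  cannot eliminate context-dependent refolding.
* UPE (target-site accessibility) is not computed.
* One interval per genome: a locus split across chromosomes (beyond what a
  genome-wide marker scan resolves) is out of scope.
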