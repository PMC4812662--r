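---
title: "Consensus CNV calling, polarization and mechanism classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus CNV calling, polarization and mechanism classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Population resequencing of a crop species yields, per accession, copy-number
variant (CNV) calls from three complementary evidence classes: paired-end
discordance (PE), split reads (SR) and read depth (RD).  Each class has a
blind spot — RD cannot resolve events below its bin size, SR cannot span
events longer than a read, PE breakpoints are imprecise — and each caller
emits private false positives.  `cnvpol` implements the downstream analysis
that turns these per-accession call sets into an interpretable population
catalog of deletions-relative-to-the-reference:

1. **Integration** — per-accession consensus of calls supported by at least
   two methods under a 50% reciprocal-overlap criterion, breakpoint
   refinement, and a population merge keeping events present in at least
   three accessions.
2. **Polarization** — classification of every event as an *insertion*
   acquired by the reference lineage, a *bona fide deletion* in the
   carriers, or *undefined*, by projecting it onto an outgroup genome
   through ortholog anchors and aligning the event with 2-kb flanks.
3. **Mechanism classification** — NAHR, NHR (NHEJ/MMEJ), MEI or VNTR from
   diagnostic breakpoint signatures.
4. **Annotation** — gene-impact categories (full / partial-CDS / UTR /
   intron), population sharing across cultivated/wild and
   indica/japonica partitions, hypergeometric term enrichment with BH-FDR.
5. **Non-co-linear genes** — CNV genes without a co-linear outgroup
   counterpart are traced to their ancestral copy in the reference and
   their duplication origin (TE capture, NHEJ, NAHR) inferred from
   boundary signatures.

Everything is exercised end-to-end on a synthetic genome whose implanted
events carry known mechanisms, polarities and carriers, so each stage is
validated by parameter recovery rather than by inspection.

# The synthetic study

`sim_config()` defines the study conditions; `simulate_cnv_study()` builds
the whole system.  Defaults: 2 chromosomes of 1 Mb, GC 0.44; 100 gene
models (exon/CDS/UTR structure) plus sentinel genes near the chromosome
ends so the ortholog anchor set spans the full sequence, as real core
ortholog sets do; 50 TE copies from a 6-family library (one Mutator-like);
70 tandem arrays (period 40-60 bp, 16-24 copies); 50 events for each of
the four mechanisms; 12 accessions (roughly 80% cultivated, split into
japonica/indica/other, 20% wild).

Event signatures are written into the reference sequence:

* **MEI** — a diverged TE family copy covering ≥90% of the event plus a
  5-20 bp target-site duplication copied from the left flank, so excising
  the event restores a single TSD copy in the ancestor.
* **NAHR** — a 100-200 bp repeat (copies ~1% diverged) at the event start
  and again immediately after the event end: the recombination substrate
  that leaves extended junction homology.  Event sizes start at 1.5 kb so
  the repeat is a small fraction of the event (this matters for
  polarization, below).
* **NHR** — 0-10 bp of engineered junction microhomology with forced
  mismatches at both borders.
* **VNTR** — an integer number of periods of an annotated array, both
  breakpoints inside the array.

Polarity is assigned by exact count (`insertion_fraction`, default 0.8):
the estimator's error is then purely downstream, which is what the
recovery tests measure.  The ancestral haplotype is materialized
explicitly — the reference minus all insertion-state intervals — and the
outgroup derives from it by per-site substitutions (default 2%), small
indels (default divergence/10) and assembly gaps (N runs, expected
`outgroup_gap_rate` per chromosome).  Gap placement draws its candidate
stream once and lets the rate decide how many candidates are realized, so
raising the rate adds gaps monotonically for a fixed seed — the property
the undefined-count monotonicity test relies on.

A VNTR copy-number change is intrinsically hard to polarize by alignment:
whatever the true history, the residual array copies in the outgroup align
to the event sequence.  Insertion-state VNTR events therefore expand
nearly the whole array (the ancestor keeps two periods), which is the
regime where the alignment rule is informative; this is a deliberate
generator choice, stated here rather than hidden in a threshold.

The caller emulator reflects the documented method biases: sensitivity is
configured per caller and size class (`small` 50-500 bp, `mid` 0.5-10 kb,
`large` >10 kb), with RD blind below 500 bp and SR blind above 10 kb by
default.  SR calls are exact; PE calls get rounded Gaussian jitter
(default sd 50 bp); RD calls snap outward to 100-bp bins; false calls
arrive at 5 per Mb per caller per accession with sizes resampled from the
truth distribution.

What the generator does *not* emulate: read-level artifacts (mapping
bias, duplicates), diploid genotypes (presence/absence only), population
structure and linkage, realistic TE taxonomy, and caller-specific error
models beyond the size-class biases.  Passing tests therefore demonstrate
the correctness of the integration/polarization/classification logic
under controlled conditions, not the field performance of any particular
caller stack.

# Integration

Clustering is single-linkage under the predicate
`reciprocal_overlap >= 0.5` on the same chromosome — the standard
transitive RO merge for SV call sets, chosen because it is oracle-testable
(the suite compares it against an explicit all-pairs transitive closure).
Candidate pairs come from an interval-overlap query; a pair with positive
RO must overlap, so the sweep is exact.

Breakpoint refinement replaces local de-novo assembly with an
evidence-class priority: the modal SR pair (ties: smallest start, then
end) wins and is *precise*; otherwise the lower-median PE start/end;
RD-only clusters keep their widest member's bounds and are *imprecise*.
SR breakpoints are single-nucleotide by construction, so in the noise-free
limit refinement is exact — preserving the property that almost all
catalog breakpoints have single-nucleotide resolution without wrapping an
assembler.

The population representative is the precise member whose length is
closest to the cluster's lower-median length (ties: smallest start, then
end).  All tie-breaks are deterministic; the merge is invariant to input
order, which the suite asserts by permutation.

# Polarization

Anchors (ortholog gene pairs) are chained into co-linear blocks when
consecutive anchors share the chromosome pair and strand, preserve
outgroup order, and are ≤500 kb apart in both genomes.  An event interval
is projected by linear interpolation between flanking anchor midpoints.
Interpolation between anchors can be wrong by as much as the length
difference of the anchor gap in the two genomes (exactly the unbalanced
material the catalog is made of), so the projection also reports that
difference as an *uncertainty* and the search window is widened by it.

Within the window, each flank is located by exact 16-mer seed voting
(sampled every 4 bp; the modal diagonal band wins).  At 2% divergence an
exact 16-mer survives with probability ~0.72, so a genuinely orthologous
flank is covered densely while an absent one produces no consistent band.
Anchoring uses the junction-proximal kilobase of each 2-kb flank: the
outer flank may legitimately overlap a neighbouring variant, which should
not veto the verdict for this event.  A flank anchors when ≥50% of its
bases are covered by band-consistent seeds.

The anchored flank positions delimit the *core* window — the orthologous
image of the CNV interior.  The event sequence is then locally aligned
(BLAST-like scoring: +2/−3, gap 5/2; N scores −1 against everything)
against the core plus a 150-bp margin, and

* aligned fraction `< 0.2` → **insertion** (sequence absent from the
  outgroup),
* `>= 0.8` → **deletion** (sequence present),
* anything else, a failed projection, unanchored flanks, or a window
  covered >10% by assembly gaps → **undefined**, with a reason code.

Short spurious local hits are suppressed by requiring the aligned stretch
to reach `min(30, len/2)` bp at ≥75% identity before it counts.  Events
larger than 100 kb would be polarized by ten evenly spaced 1-kb probes
instead of one whole-event alignment; the default study never reaches
that size, but the path exists for real catalogs.  The 0.2/0.8/0.5/0.1
thresholds are exposed in `polarize_params()`; they were chosen to be
robust at 2% divergence, and the insertion threshold interacts with the
generator's NAHR and VNTR geometry (the residual repeat or array copies
in the outgroup must stay below 20% of the event length).

# Mechanism classification

All signatures are read on the reference interval.  The catalog is
deletions-relative-to-reference, so the affected allele is present in the
reference for *both* polarity states — an insertion-state event is the
inserted sequence itself, and a deletion-state event is the ancestral
allele that the carriers lost but the reference retains.  No outgroup
reconstruction is needed.

Decision order, first match wins: **VNTR** (both breakpoints inside one
annotated array, length within 10% of a period multiple of a non-zero
period count) → **MEI** (TE coverage of the body ≥0.8) → **NAHR**
(junction-anchored homology ≥50 bp at ≥90% identity within a 500-bp
scan window) → **NHR** (total junction microhomology ≤10 bp) →
**ambiguous** (microhomology in the 10-50 bp gap with no body
signature).  Body signatures precede junction signatures because they are
more specific; the order is fixed so ties are deterministic.  NHR is
sub-labelled NHEJ (0 bp) vs MMEJ (1-10 bp) without changing the main
category.  Imprecise events and events whose junction windows are mostly
N are ambiguous with a reason code.

`junction_microhomology` is the longest common prefix of the sequences
starting at the event start and at the event end, plus the longest common
suffix of the prefixes ending there — case-insensitive, N matches
nothing, capped at the scan window.  `flanking_homology` is an ungapped
junction-anchored scan: the largest extent whose cumulative identity
stays above the threshold and that ends on a match.  Both are simple
enough to be verified against brute-force string scans, which the suite
does on a thousand random cases.

# Gene impact, sharing, enrichment

Impact categories follow a strict precedence per (gene, event) pair:
*full* (event contains the annotated gene span), else *partial_cds*,
else *utr_only*, else *intron_only*.  Summaries count distinct genes,
each at its best category, so a gene hit by several CNVs is not counted
twice — and `full + partial_cds` equals the number of CDS-disrupted
genes by construction, an identity the tests assert.  A configuration
flag is deliberately absent: *full* requires containment of the whole
annotated span including UTRs.

Sharing labels an event by its carriers' groups; the indica/japonica
partition is computed over the carriers belonging to those subgroups and
events with no such carrier are reported as `neither` and excluded from
the subgroup fractions, so each partition's fractions sum to one.

Enrichment is the upper-tail hypergeometric probability (`phyper`) per
term with BH adjustment (`p.adjust`); terms with no annotated gene in the
universe are skipped.  The term map is an input table — ontology
propagation and cross-species clustering (e.g. the rice-specific vs
conserved split) are upstream inputs, not computed here.

# Non-co-linear genes

A CNV gene is co-linear when its span projects through the anchor blocks
and its exonic sequence aligns to the projected window over ≥50% of its
length (per-exon alignment, so intron-length drift cannot break
coverage).  Genes whose projection fails — typically genes inside
insertion-state events, which have no orthologous position — are
non-co-linear.

The ancestral-copy search is seed-and-extend: exact 16-mer seeds of the
gene span are hashed genome-wide, grouped by diagonal, self-overlapping
candidates removed, and candidates scored by local alignment.  A hit
requires ≥80% identity over ≥50% of the gene; ties prefer identity, then
length, then the leftmost locus, and a self-hit exclusion is asserted on
every call.  For hits ≥90% identity, the duplication boundaries are fixed
by extending the alignment outward base-by-base from the alignment's
matched end pairs (stopping when identity over the trailing 20 bp drops
below 70%), and the origin is decided in the order **TE** (TE annotations
within 1 kb on both sides) → **NAHR** (aligned junction homology ≥50 bp
at ≥90%; alignment-based rather than ungapped because the extension
boundary can be off by a few bases) → **NHEJ** (boundary microhomology
≤10 bp) → unresolved.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; conversion happens only
  at I/O boundaries (GFF3, VCF, BED via rtracklayer/Biostrings).
* Calls on different chromosomes never cluster; strand is ignored
  (deletions are unstranded).
* Empty inputs (no calls, no anchors, empty consensus) flow through every
  stage and the report prints zeros rather than failing.
* All randomness derives from a single integer seed via fixed stage
  offsets; two runs with the same configuration are byte-identical,
  including FASTA/GFF3/BED/TSV outputs.
* Problem sizes: the default study (2 x 1 Mb, 200 events, 12 accessions)
  keeps a full pipeline run in the low minutes on one CPU, which is the
  scale at which the whole test suite, including three insertion-share
  recovery runs, stays comfortable on a laptop.

# Known limitations

* Polarization assumes one outgroup; multi-genome parsimony is out of
  scope.
* Anchor-midpoint interpolation cannot place events that lie outside the
  outermost anchors of a chromosome; such events are `undefined` with a
  projection failure reason.
* The ungapped junction homology scan underestimates NAHR homology
  interrupted by indels; on real data a gapped scan (as used in the
  origin inference) would be the first thing to swap in.
* Mechanism accuracy is measured on implanted signatures; real
  breakpoints carry compound signatures (e.g. nested TEs in arrays) that
  the precedence order resolves deterministically but not necessarily
  biologically.
* The caller emulator's error model is generic, not calibrated to any
  specific tool.
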