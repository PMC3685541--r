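---
title: "Assessing alternative transcript isoforms: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing alternative transcript isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txiso)
```

## The problem

Genome annotations routinely list several transcripts per gene, but a listed
alternative transcript is not automatically evidence for a distinct protein
isoform. Many annotated alternatives trace back to single cDNA reads, and a
single-pass cDNA can mislead in stereotyped ways: incomplete first-strand
synthesis truncates the 5' end and mimics a downstream transcript start; a
read of the unspliced primary transcript (or of contaminating genomic DNA)
mimics a retained intron; a PCR primer can *impose* a transcript start that
was never observed. On top of that, an annotated alternative may be
structurally real but translationally dead: its open reading frame may meet
a premature termination codon and be degraded by nonsense-mediated decay
(NMD), its proposed 5' UTR may contain upstream AUGs that preclude
initiation at the main start, or it may require a different reading frame
altogether. This package implements, as a tested pipeline, the
assessment workflow that separates plausible protein-isoform-encoding
alternatives from such artifacts, together with the in-silico counterpart of
the reporter-fusion experiments used to test isoform-specific expression.

For transcription-factor genes the question is acute because their
expression is low: background transcriptional noise is a larger fraction of
the observed reads, and the evidence behind any individual gene model is
correspondingly thin.

## Structural mechanism detection

Six mechanism classes are detected from exon chains alone, by pairwise
comparison on genomic half-open intervals:

* **Unique starting exons** (`find_unique_starts`): a transcript whose
  first exon overlaps no exon of any other transcript, implying its own
  promoter. One base of overlap disqualifies (configurable). Uniqueness
  arising purely from nesting is excluded: if the only reason a first exon
  is unshared is that the other transcripts are truncated suffixes of the
  same chain, the gene belongs to the nested class below, not here.
* **Nested starts** (`find_nested_starts`): a transcript whose 5' terminus
  lies inside an exon of a longer transcript and whose splice junctions are
  a suffix of the longer transcript's. Among qualifying hosts the one with
  the most-5' start is reported. Whether the nested start coincides with a
  splice acceptor (compatible with trans-splicing onto an internal
  acceptor) is recorded as a flag but not acted upon, since structure alone
  cannot distinguish an internal promoter from aberrant trans-splicing or
  5'-truncated cDNA.
* **Alternative terminal exons** (`find_alt_terminals`): either an internal
  exon extended 3' into what is otherwise intron (the foreshortened
  transcript terminating early; these calls carry an NMD hint) or a unique
  exon 3' of the shared junction chain.
* **Cassette exons** (`find_cassette_exons`): an internal exon lying wholly
  within a single intron of another transcript whose boundaries coincide
  with the flanking junctions.
* **Retained introns** (`find_retained_introns`): an intron of one
  transcript fully exonic in another, the two otherwise junction-identical
  over their genomic overlap.
* **Splice-site shifts** (`find_splice_shifts`): two introns sharing one
  boundary and differing at the other by `d > 0` bases, with the region
  between the alternative sites free of complete exons (otherwise the
  difference is a cassette/terminal exon, not a site shift). The shift is
  frame-preserving iff `d mod 3 = 0`; shifts of 3, 6, 9 or 12 bases are the
  ones that survive NMD and dominate real annotations.

All detectors are symmetric in transcript order and invariant under a
strand flip of the locus; multi-transcript genes are reduced to ordered
pairs and calls de-duplicated.

## Evidence grading

Transcript support arrives as aligned exon chains (`support_records`): ESTs,
RT-PCR products and ORFeome clones, each with a library key, a 5'
completeness flag and a primer-derived-start flag. A record supports a
transcript when all of its junctions match a consecutive run of the
transcript's junctions (within a configurable tolerance, default 0: the
synthetic data is exact, real alignments may need slack) and the record is
a contiguous sub-path of the exon chain. Records compatible with several
transcripts count for all of them.

Grades follow the strong / weak / unsupported scheme: **strong** requires at
least `strong_threshold` (default 2) supporting ESTs with *distinct library
keys* and no artifact flags — the published surveys never quantify
"multiple independent", so two distinct libraries is our operational
reading, exposed as a parameter; **weak** is any support short of that;
**unsupported** is none. Three artifact flags feed the discount rules:
`TRUNCATED_5P` (a 5'-incomplete read never defines a transcript start by
itself), `UNSPLICED` (a junctionless record spanning an annotated intron —
the primary transcript read-through), and `PRIMER_DERIVED` (the only
start-defining record had its 5' end encoded in a PCR primer).

## Translation-based discounting

For each alternative (non-reference) transcript four rules may fire:

* `BLOCKING_UORF`: the proposed 5' UTR contains an out-of-frame upstream
  ATG whose reading frame has no stop before the main start. In that
  configuration a scanning ribosome initiating at the uATG reads through
  the main start out of frame and cannot terminate-and-reinitiate, so
  translation of the main ORF is implausible. (An in-frame uATG merely
  extends the protein; an out-of-frame uORF that *terminates* in the UTR
  permits reinitiation; neither blocks.) This is one defensible
  formalization of "unlikely to be translated" and is reported as a reason
  rather than silently applied.
* `NO_PRODUCTIVE_ALTERNATIVE`: translation from the annotated start meets a
  stop at least 50 nt (configurable, the classical NMD rule-of-thumb)
  upstream of the final exon-exon junction in spliced coordinates; NMD
  would be expected to degrade the transcript. Single-exon transcripts are
  never flagged. The rule depends only on spliced coordinates, so intron
  lengths are irrelevant.
* `WRONG_FRAME`: the transcript's final exon is translated in a different
  frame than the reference transcript's (phase difference mod 3 at a
  shared terminal exon) and the transcript rests on a single record — a
  rare splicing error is then the more parsimonious reading.
* `UNSPLICED_PRIMARY`: every record supporting the transcript is an
  unspliced genomic-span read.

The *reference* transcript — the one the alternatives are judged against —
is the best-supported transcript that is itself productive (not
NMD-doomed), with ties broken by CDS length and then by identifier. This
keeps a PTC-bearing alternative from being exempted from assessment merely
because its annotated CDS is longest.

## Per-gene classification

`classify_gene` assigns exactly one category per gene, in priority order:
one distinct transcript → `NO_ALTERNATIVE`; identical spliced CDS in every
transcript → `SAME_PROTEIN` (the alternatives differ only in UTRs); every
alternative discounted → `DISCOUNTED`; one surviving mechanism type → that
mechanism's category with a strong/weak grade (strong only when *every*
transcript involved grades strong — the weakest link sets the grade;
ungraded/unsupported counts as weak); two or more surviving mechanism
*types* → `MULTIPLE_STRONG/WEAK`. Nested-start genes carry no strong/weak
split: structure alone cannot validate a nested start, so the class is
reported as one row. Repeated calls of a single type (e.g. five unique
starts) remain a single-mechanism category. `summarize_cohort` counts
categories; the counts always partition the cohort.

The packaged survey tables (`isoform_survey_counts`, `assayed_genes`) ship
the published category counts for the 938-gene transcription-factor
complement and the 29 reporter-assayed genes; `survey_aggregates`
reproduces their arithmetic (50 genes with alternative starts, 23 with
alternative ends, 35 with alternative splicing, 34 multiple, 55
discounted). Re-deriving those counts from primary database snapshots is
out of scope; the tables are inputs, and the package's algorithmic claims
are validated on synthetic data instead.

## In-silico recombineering

`apply_edits` performs seamless edits — reporter insertion, single-base
insertion, substitution, deletion — shifting all downstream annotation
coordinates by the net length change, so exon boundaries keep their local
sequence context. Splicing is assumed unchanged unless an edit touches a
splice dinucleotide (the GT/AG intron ends), in which case a warning is
raised instead of a silent prediction: edits placed between a splice
acceptor and an immediately adjacent start codon have been observed to
perturb expression in practice, and the model cannot predict that.

`predict_reporter` then decides, per transcript, whether a translational
reporter would be expressed: the reporter must lie in the transcript's
exons downstream of its start codon (else `REPORTER_NOT_IN_TRANSCRIPT` /
`SPLICED_OUT`), and translation from the transcript's *annotated* start
(ATGs created by edits are deliberately ignored) must reach the reporter
with no intervening stop (`PREMATURE_STOP`) and in frame 0
(`FRAMESHIFTED_UPSTREAM` otherwise). Expression is binary; relative
strengths are out of model.

`design_constructs` enumerates the assay panel used for real loci: the
reporter inserted immediately after each distinct initiation codon
(optionally with a single extra base just 5' of that codon, to frameshift
translation arriving from upstream starts — the trick that isolates nested
transcripts), immediately before each distinct termination codon, and
terminal fusions combined with a single base inserted into each optional
exon or retained intron to knock out the transcripts that include it.
Candidates with identical expression-indicator vectors are collapsed
(keeping terminal fusions by preference) and all-negative candidates
dropped; transcript pairs identical across *all* candidates are reported
as inseparable — e.g. two transcripts differing only by a 3-base acceptor
shift cannot be distinguished by insertion constructs. We return the
collapsed panel rather than a strictly minimal separating subset because
the panel also carries the summation check below; for a three-promoter
gene this yields the expected four constructs (three start tags plus the
common terminal fusion).

Two properties anchor the reporter model in the tests: the terminal
fusion's expression indicator equals the union of the start fusions'
indicators on unambiguous genes ("expression patterns of the former sum to
the latter"), and a +1 insertion followed by a +2 insertion at the same
point restores expression (mod-3 arithmetic). `homology_arms` extracts the
50-base flanks (configurable) that target each edit.

## The synthetic-data generator

`generate_gene` builds a locus realizing one planted mechanism, and
`generate_cohort` a reproducible cohort with evidence and a truth table.
Defaults describe a compact, well-expressed locus: 4–6 exons of 90–240
bases, introns of 48–150 bases, canonical GT..AG splice sites only, an
ATG-free 5' UTR of 15–45 bases, a 3' UTR of 30–60 bases, 500 bases of
flanking padding (so 50-base homology arms always exist), and three
independent full-length ESTs per transcript — the strong-evidence condition
of the study design. Cohort evidence therefore guarantees per-transcript
coverage; the weighted sampler `generate_ests` (expression-weight draws,
truncation and unspliced artifacts at specified rates) is the model of the
raw evidence process and is what the artifact-robustness checks use.

Construction choices worth knowing:

* Exon/intron boundaries are placed on codon boundaries, and optional
  elements (cassette exons, retainable introns, terminal extensions) are
  built from stop-free sense codons, so a planted mechanism is guaranteed
  productive — no accidental stop codons or frame surprises. Real genes
  have phase-1/2 junctions; the detectors never look at sequence, so this
  simplification costs nothing for structure detection, but it means the
  generator does not exercise stops that straddle junctions.
* A retainable intron is codon-structured: first codon `GTN` (valine,
  preserving the donor), last codon `CAG` (preserving the acceptor), so
  retention adds in-frame codons. A frame-shifting cassette (length 1 mod
  3) carries an internal in-frame stop and is kept out of the final
  intron, so the including transcript is unambiguously an NMD candidate.
* A splice-site shift is planted by setting the codon ending at the
  alternative acceptor to `CAG`, so both acceptor contexts end in AG.
* Nested starts are planted as an in-frame ATG (a methionine substitution
  in the host's protein) at a codon boundary inside an internal exon; the
  nested transcript gets a zero-length 5' UTR, so no uORF rule can fire on
  clean genes.
* Minus-strand loci are the mirrored, reverse-complemented plus-strand
  construction (`mirror_gene_model`), which also powers the strand-flip
  invariance tests.

What passing on synthetic data does **not** show: robustness to alignment
noise at junctions (the synthetic evidence is exact; the junction-match
tolerance exists for real data but defaults to 0), non-canonical splice
sites, realistic nucleotide composition, sequencing error, trans-spliced
leader sequences (modelled as a flag only), or genes whose annotation is
wrong in ways not covered by the artifact modes.

## Problem sizes and numerical choices

The test suite exercises: 200-gene artifact-free cohorts per mechanism
(both strands) for category recovery; 1,000 random exon-chain pairs for
detector–oracle equivalence (the oracles enumerate base sets rather than
doing interval arithmetic); 500 random (gene, edit) pairs for the
reporter-prediction oracle; and 40–60-gene batches for the summation,
frame-restoration and artifact-robustness properties. The acceptance
script uses 50 genes per mechanism and 40–60-gene batches for the property
rates; these sizes give exact-recovery checks adequate power while keeping
a single run comfortably fast on one core.

All coordinates are 0-based half-open internally, converted at the GFF3
boundary (1-based inclusive); round-tripping write→parse is the identity.
Ties in reference-transcript selection resolve by support, productivity,
CDS length, then identifier, making every result deterministic. Cohort
generation derives per-gene seeds from the global seed, so a cohort is
byte-reproducible from `(spec, seed)`.

## Known limitations

* The uORF blocking rule and the 50-nt NMD rule are deliberate
  simplifications of initiation-context and decay biology (no Kozak
  scoring, no ribosome profiling).
* Reporter prediction treats splicing as fixed; any edit touching a splice
  dinucleotide yields a warning, not a prediction.
* `WRONG_FRAME` compares terminal frames only when two transcripts share a
  terminal exon boundary; frame differences elsewhere are expressed
  through the PTC/NMD rule instead.
* The mechanism taxonomy is per-gene and categorical; it does not quantify
  isoform abundance, and "multiple" means distinct mechanism *types*
  co-occur, not repeated events of one type.
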