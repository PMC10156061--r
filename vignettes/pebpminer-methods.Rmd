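---
title: "Methods and design notes for pebpminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pebpminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pebpminer)
```

# Scope

`pebpminer` implements a complete allele-mining workflow for the plant
PEBP gene family (*FT*-like floral inducers, *TFL1*-like repressors,
*MFT*-like seed-dormancy genes): translated homology search over genome
scaffolds, spliced CDS-to-genome alignment and gene-structure validation,
cross-assembly consensus calling, diagnostic-residue clade and function
prediction, neighbour-joining phylogenies with bootstrap support,
long-amplicon demultiplexing and allele phasing, and allele-pair variant
annotation. This vignette records the models and the design decisions a
maintainer would want to know, in the order the pipeline runs.

# Synthetic data: what the generator emulates

Every stage is exercised on data from the package's own generators, which
are pure functions of their inputs and a seed.

**Gene templates.** A template is a four-exon gene whose concatenated
exons form a CDS (ATG start, stop end). The canonical family structure is
used for defaults: exon II of 62 bp and exon III of 41 bp (conserved
across the family), exon I and exon IV in the 192–216 bp and 209–233 bp
ranges. Intron lengths default to 150/200/250 bp; the family's introns
vary widely and carry no signal here, so any plausible lengths serve.
Intron bodies are random sequence wrapped in canonical GT...AG splice
dinucleotides. The packaged worked-example genes use intron lengths of
150/160/158 bp (gene of 981 bp with a 513 bp CDS, 170 aa) and
166/167/166 bp (1027 bp gene, 528 bp CDS, 175 aa) so that gene and CDS
lengths equal the published values for the two loci they emulate.

**Fixture proteins and references.** Real reference proteins are not
bundled; instead short synthetic PEBP-like scaffolds carry the published
diagnostic states at the published coordinates (Tyr85, Glu109, segment B
`LGRQTVYAPGWRQN` at 128–141 — hence Tyr134, Gly137, Trp138, Gln140 — the
LYN triad, Asn152; His88/Asp144 on TFL1 numbering; Trp at the clade
position for MFT). Users can substitute real sequences by file; only the
numbering metadata matters to the classifier. The worked-example MFT-type
protein fixes codons 21, 93, 117 and 123 to GTT, ATC, ATA and GCT so that
the documented single-base changes produce the documented amino-acid
changes (V21F, I93L, I117R, A123T); codon 117 must be ATA specifically,
since the change is at the codon's second position.

**Amplicon cohort.** Twelve samples with amplicon counts between 91 and
186 (the scale of the published screening table), eleven homozygous for
allele 1 and one heterozygous at weights 0.5/0.5. Reads are
`fwd_barcode + insert + revcomp(rev_barcode)`, with roughly half emitted
reverse-complemented. The default error model is 0.3% substitutions,
0.1% insertions and 0.1% deletions per base, mimicking
circular-consensus-quality long reads; barcodes are 16-mers with pairwise
edit distance of at least 6. Allele counts per sample are the
deterministic largest-remainder shares of the plan weights with the read
order randomized, not multinomial draws: the study condition being
reproduced is a 1:1 heterozygote, and at ~119 reads a binomial draw would
leave the 1:1 ratio outside the 0.45–0.55 rounding band about a quarter
of the time, making the condition itself unstable rather than testing the
phasing method. Truth labels are encoded in read names for testing only.

**What the generator does not emulate.** Real instrument subread/ZMW
structure, chimeric molecules, length-dependent loading biases,
context-dependent (homopolymer) errors, and barcode-region errors are not
simulated. Passing tests therefore show that the algorithms are correct
under a clean long-read error model, not that they are robust to every
artifact of a real sequencing run.

# Homology search

Scaffolds are translated in six frames (codons containing N give X;
trailing partial codons drop). Exact protein 4-mers seed candidate
diagonals; seeds of one gap-free segment share a diagonal while an intron
shifts it by a third of the intron length, so seeds are banded with a
diagonal gap limit of 5 and each band is extended by local alignment
(BLOSUM62, gap open 11, extend 1) inside a window spanning the band's
seeds plus a 10-residue margin. Hits below score 60 or 40% identity are
discarded; defaults chosen to be generous for intra-family divergence
while rejecting a shuffled-scaffold null (tested). Same-strand hits
within 5 kb merge into one candidate locus. E-value statistics and
profile models are out of scope.

# Spliced alignment and structure validation

The CDS is placed on the locus as a chain of maximal exact match blocks
(12-mer anchored, extended both ways). A maximal block can overshoot an
exon boundary by chance (the intron may begin with the same bases the
next exon contributes), so chaining allows small CDS overlaps and the
exon boundary is chosen afterwards: among all split points consistent
with the two blocks, the leftmost one giving a GT...AG intron wins, then
the leftmost overall. Within-exon mismatches are bridged and flagged
`mismatch`; placement fails if more than 10% of CDS bases lack support.
This prefers solutions maximizing exon lengths with deterministic
tie-breaks.

Structure validation runs six checks. Exon count = 4 and GT...AG
boundaries are hard failures; exon II = 62 bp and exon III = 41 bp are
also failures (they are conserved family-wide); exon I in 192–216 bp and
exon IV in 209–233 bp are warnings only, because in-family length
variation at those exons is documented (an unusually short exon IV is
exactly what a premature-stop pseudogene shows, and should be surfaced,
not rejected).

# Consensus across assemblies

Loci are matched across assemblies by reciprocal best global identity at
≥95% (connected groups of reciprocal best pairs form a locus). The
consensus is the sequence shared verbatim by the largest subset of at
least two assemblies — no base-level majority voting of non-identical
sequences. Divergent assemblies are diffed against the consensus with the
variant-annotation module. A tie between two disjoint agreeing pairs is
resolved toward the group containing the lexicographically first assembly
name and flagged; partial CDS fragments are excluded from consensus and
reported separately.

# Residue classification

Candidates are aligned globally (BLOSUM62, gap open 10, extend 1) to both
the FT-numbered and TFL1-numbered references; below 25% identity the
sequence is rejected as not a PEBP candidate. The higher-identity mapping
supplies the clade residue (85 FT / 88 TFL1): Tyr → FT-like, His →
TFL1-like, Trp → MFT-like, anything else (or a gap) unclassified, with
the supporting Gln140/Asp144 state recorded as evidence. Mappings whose
identities differ by under 2 points are flagged. For FT-like candidates,
function is inducer iff Tyr134 and Trp138 are both present; any change at
either is repressor-like; a lone change at Gly137 keeps the inducer call
with a `G137_variant` note (changes there are documented not to confer
repressive activity). Glu109, Gln140 and Asn152 are recorded as
annotations only. The exact gap placements inside the alignment are this
package's; published per-gene residue numbers (e.g. Tyr84 in one paralog)
arise naturally from small indels and are reproduced by the mapping
tests.

# Phylogeny

Distances use pairwise deletion (columns with a gap in either row are
excluded): p-distance, Poisson `d = -ln(1-p)`, or gamma
`d = alpha((1-p)^(-1/alpha)-1)` with shape defaulting to 1.0 (the shape
used in the original software run is unstated, so it is exposed as a
parameter). Tree building delegates to the standard neighbour-joining
implementation in `ape`; tests check it against a brute-force
least-squares quartet oracle and exact recovery of 50 random additive
matrices. Negative NJ branch estimates are clamped to zero and flagged.
Bootstrap resamples alignment columns with replacement, rebuilds the NJ
tree per replicate, and reports the fraction of replicates containing
each internal split of the original tree; everything is deterministic
given the seed. Multiple alignment of unequal-length inputs goes through
the system MAFFT binary; the fixture families are generated pre-aligned,
and tests exercise clade monophyly, which is insensitive to the aligner
choice at the divergences used. The default test scale is 100 replicates;
the method supports arbitrarily many.

# Demultiplexing and allele phasing

Both read ends are scored against every sample's forward barcode and
reverse-complemented reverse barcode, in both read orientations, by edit
distance (each end gets a window of barcode length plus the edit budget).
Assignment requires both ends within 2 edits (default) and a unique best
total; ties are ambiguous. Inserts are reported barcode-trimmed in
forward orientation.

Phasing clusters one sample's inserts greedily. Read-vs-read and
read-vs-consensus identities are `1 - d/max(length)` with `d` the
unit-cost global edit distance. The admission threshold (default 0.995)
is calibrated to the consensus: a raw read at the default error rate
carries ~0.5% errors of its own, so applying 0.995 directly between two
raw reads would reject nearly everything. Cluster formation therefore
admits at a band twice the admission width against the seed read, builds
a per-column majority consensus (MAFFT alignment of up to 30 reads;
deterministic tie-breaks, gap-majority columns dropped), and then applies
the strict threshold against that consensus. The first cluster is seeded
by the longest read (full-length molecule); later clusters are seeded by
the read least explained by existing consensuses — farthest-first — which
matters when the second allele is the shorter one (a deletion allele
would otherwise never be seeded). Clusters converging to the same
consensus within the admission band are merged, and two consecutive
duplicates end the search. Finally every read is assigned to its best
consensus at a looser floor (0.98) to obtain subread and amplicon
coverages (equal in simulated data, where each read is one molecule);
clusters below 20% of locus coverage are discarded as noise. Coverage
ratios are reported rounded to one decimal, matching the convention of
the published screening table, with raw fractions retained. One retained
cluster calls a homozygote; two call a heterozygote when both ratios lie
in [0.2, 0.8]; more than two are flagged as multi-allelic/contamination.
The upstream phasing tool's parameters are unpublished; all thresholds
here are this package's own and are exposed as arguments.

# Variant annotation

Allele pairs are aligned globally with match +2 / mismatch −3 / gap open
−5 / gap extend −2, and every gap run is post-shifted to its leftmost
equivalent placement so deletion calls are canonical and comparable
across runs. Each mismatch column is one substitution; each maximal gap
run is one deletion event (a 12 bp gap is "a 12 bp deletion", never 12
events); adjacent variants are never merged. Variants are placed in
exon/intron by the gene model; exonic substitutions get CDS and protein
coordinates (protein position = ceil(CDS position / 3)) and a coding
effect from translating the affected codon in both alleles — synonymous,
non-synonymous, or stop-gained when the alternate codon is a stop.
Exonic deletions get a `frameshift/indel` placeholder and are not
classified further. Deleteriousness prediction (SIFT-style) is
database-dependent and out of scope; the output leaves room for
user-supplied external predictions.

The upstream scan extracts up to 8 kb 5′ of the ATG on the coding strand
(position −k is k bases before the A), truncating with a flag at scaffold
edges, and locally aligns each repeat-library entry; hits of ≥200 bp and
≥70% identity are reported with ATG-relative near/far coordinates and
span `|far| − |near|`. The span is a difference, not an inclusive count,
because the published example's printed endpoints and length satisfy
exactly that convention; the reported interval is the alignment edge
(whether the original report used element annotations or alignment edges
is unstated).

# Numerical and degenerate-input conventions

All external coordinates are 1-based inclusive (GFF3/VCF convention);
deletions in VCF are left-aligned and anchored on the preceding base.
Duplicate FASTA ids are errors; empty files are errors unless strict mode
is off. NJ on an all-zero matrix returns a zero-length tree with a
warning attribute. Poisson/gamma distances are undefined at p = 1 and
error. The protein-length rule `aa = CDS/3 − 1` is applied uniformly; one
published family-table row (534 bp with 175 aa) contradicts the rule that
the rest of the same table follows, and the package computes 177 for that
length rather than adopting the printed value.

# Problem sizes

The test suite and acceptance script run everything at desk scale chosen
to keep the full pipeline reproducible on a laptop: scaffolds of 3.5–10.5
kb, one embedded gene per scaffold, a 12-sample cohort of ~1,600 reads of
~1 kb, 100-replicate bootstraps on 9-taxon families, and 100 random
variant specifications for the round-trip property. These sizes are the
package's test conditions, not limits of the methods.

# Known limitations

* Homology search has no significance statistics; thresholds are
  score/identity cutoffs tuned against a shuffled null at desk scale.
* Spliced alignment assumes colinear exons and canonical splice sites;
  non-canonical introns and rearranged loci are flagged or fail rather
  than being modeled.
* Allele separation during phasing requires the alleles to differ by more
  than the admission band (~0.5% at defaults); alleles differing by a
  single base in a ~1 kb amplicon would merge into one cluster.
* The heterozygosity rule expects near-balanced alleles; strong allelic
  amplification bias would present as a skewed minor cluster and be
  dropped by the noise filter.
* The bundled references are synthetic scaffolds carrying the published
  diagnostic states, adequate for residue-rule classification but not a
  substitute for real curated references in comparative analyses.
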