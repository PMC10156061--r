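# pebpminer

Mining, classification and allele phasing of plant PEBP (*FT*/*TFL1*/*MFT*)
gene homologs.

## The problem

The plant phosphatidylethanolamine-binding protein (PEBP) family splits
into three clades with opposing developmental roles: *FT*-like genes
(florigen) generally promote flowering, *TFL1*-like genes repress it, and
*MFT*-like genes act in seed dormancy and germination. Surveying a crop's
genome assemblies for this family, validating each candidate's gene
structure, predicting whether an *FT* paralog acts as a floral inducer or
repressor, and phasing the alleles segregating among cultivars are the
routine steps of a PEBP allele-mining study. `pebpminer` implements that
workflow as a tested, reusable R package for people doing crop-genetics
and flowering-time work:

* **Homolog mining** — six-frame translation of scaffolds and seeded
  protein local alignment (BLOSUM62, affine gaps 11/1) against query PEBP
  proteins; per-exon hits are merged into candidate loci.
* **Gene-structure validation** — spliced CDS-to-genome alignment
  recovering the family's canonical four-exon structure, with hard checks
  on exon count and GT...AG intron boundaries and range checks on exon
  lengths (exon II 62 bp and exon III 41 bp are conserved; exons I and IV
  vary within 192–216 bp and 209–233 bp).
* **Cross-assembly consensus** — a locus's CDS is accepted when at least
  two assemblies agree at 100% identity; divergent alleles are diffed
  against the consensus and reported as variants.
* **Diagnostic-residue classification** — candidates are mapped onto
  reference numbering by global alignment; Tyr85 calls FT-like, His88
  (TFL1 numbering) TFL1-like, and Trp at that position MFT-like. For
  FT-like proteins, Tyr134 plus Trp138 in the exon-IV external loop calls
  an inducer and any change there calls repressor-like, while a change at
  Gly137 alone is annotated but does not flip the call. The segment-B
  motif `LGRQTVYAPGWRQN` (positions 128–141) and the LYN triad are
  scanned and reported.
* **Phylogeny** — p, Poisson (d = −ln(1−p)) and gamma-corrected protein
  distances with pairwise-deletion gap handling, neighbour-joining trees,
  bootstrap support by column resampling, and clade-monophyly checks.
* **Amplicon allele phasing** — demultiplexing of asymmetric dual-barcoded
  long-amplicon reads (edit-distance barcode matching, both orientations),
  greedy identity clustering into phased alleles with majority-rule
  consensus, per-allele subread/amplicon coverages, coverage ratios
  rounded to one decimal, and homozygous/heterozygous locus calls.
* **Variant annotation** — global allele-pair alignment (match +2,
  mismatch −3, gap open −5, extend −2) with left-aligned deletions,
  exon/intron placement, synonymous / non-synonymous / stop-gained
  classification, CDS-to-protein position mapping (ceil(p/3)), and
  upstream (~8 kb) repeat/transposon scanning with ATG-relative
  coordinates.
* **Synthetic data** — seeded generators for scaffolds with embedded
  genes, multi-assembly variant sets, allele pairs and barcoded read
  pools, plus a packaged fixture bundle realizing the worked examples, so
  the entire pipeline runs at desk scale with no downloads.

## Worked example

```r
library(pebpminer)
fx <- paper_fixtures()

# variant calling on the MFT-2 allele pair (981 vs 976 bp)
al <- align_alleles(fx$alleles$mft2[["allele1"]], fx$alleles$mft2[["allele2"]])
v  <- call_variants(al, fx$genes$mft2$model)
subset(v, grepl("exon", region),
       select = c(pos_cds, ref, alt, effect, aa_ref, aa_pos, aa_alt))
#>   pos_cds ref alt         effect aa_ref aa_pos aa_alt
#> 1      61   G   T non-synonymous      V     21      F
#> 5     277   A   C non-synonymous      I     93      L
#> 7     350   T   G non-synonymous      I    117      R
#> 8     367   G   A non-synonymous      A    123      T
```

The four exonic substitutions are all non-synonymous — V21F, I93L, I117R
and A123T — and the intronic rows (not shown) hold two substitutions plus
a 1 bp and a 4 bp deletion, which together account for the 5 bp length
difference between the alleles. Phasing the simulated 12-sample cohort
(`simulate_amplicon_reads`, `demultiplex`, `phase_alleles`,
`genotype_locus`) recovers both alleles exactly, with eleven homozygous
samples at coverage ratio 1 and the single heterozygous sample at
0.5/0.5.

An end-to-end run (`run_pipeline(read_run_config())`) chains simulation,
mining, annotation, consensus, classification, phylogeny, demultiplexing,
phasing and variant calling into one seeded, reproducible report; a thin
command-line wrapper lives at `inst/cli/pebpminer.R`.

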