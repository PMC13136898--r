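# pgsplice

Proteogenomic detection of translated alternative splicing (AS) isoforms.

Shotgun proteomics usually cannot say *which* isoform of a gene a peptide
came from: most peptides are shared by every isoform of their locus. This
package implements the complementary workflow for the cases where
peptides *are* informative. It is aimed at plant proteogenomics, where
intron retention (IR) dominates alternative splicing, but nothing in it
is organism-specific.

The toolkit covers five connected tasks:

1. **Isoform-specific peptide inference.** Peptide tables from one or
   more search engines are merged on plain sequence (decoys removed,
   N-terminal Met loss adjusted). Peptides mapping to single-isoform
   genes or to several gene loci are set aside. At a multi-isoform
   locus, a peptide is *isoform-specific* when its matched-isoform set
   is disjoint from that of at least one other peptide of the locus —
   two disjoint sets are evidence for two distinct translated isoforms.
   The number of isoforms supported at a locus is the maximum set
   packing over the peptides' matched sets.
2. **Peptide-to-genome mapping.** Residue *i* of a protein occupies CDS
   nucleotides `3i−2 … 3i`; pushing these through the cumulative CDS
   segment lengths yields genomic blocks and junction-spanning flags
   (strand-aware, BED12 export for genome browsers).
3. **AS event catalog and event calls.** A SUPPA-style catalog (RI, SE,
   A5, A3, AF, AL, MX) is enumerated by exhaustive pairwise isoform
   comparison. RI/A5/A3/AF/AL events are called from ≥1-nt coordinate
   overlap with the event's discriminating region; SE/MX require
   junction-spanning peptides; exclusion forms require the junction
   whose flanks abut the discriminating region.
4. **Retained-intron discovery from RNA-seq depth.** The intron depth
   ratio is `IDratio = depth(intron) / mean(depth(flanking exons))`,
   with terminal introns using only their non-terminal flank. Introns
   with IDratio ≥ 0.15 in any sample group, minus annotated RI events,
   are fitted back to transcripts, translated (first in-frame stop
   truncates), classified as truncated / extended-in-frame /
   frameshift-extended, and appended to the protein database as
   `GENE.N_IRk` entries for a second search round.
5. **Quantitative post-processing.** Protein-group selection per locus,
   Perseus-style downshifted-normal imputation
   (Normal(μ−1.8σ, (0.3σ)²) for rows fully missing in one condition),
   p < 0.05 & |log2FC| > 1 differential flags, increased-IR (IIR) calls
   (mutant IR depth ≥ 0.15 and fold change ≥ 1.5, with 5′UTR/CDS/3′UTR
   assignment), and classification of quantified peptides as
   upstream/downstream/spanning relative to a retained intron.

A deterministic synthetic-fixture generator
(`make_genome_and_annotation()`) builds a two-chromosome toy genome with
known ground truth for all of the above, so the full pipeline is
testable offline.

## Worked example

```r
library(pgsplice)

fx <- make_genome_and_annotation(seed = 42)          # toy world + truth
ev <- generate_events(fx$transcripts)
head(events_to_df(ev)[, c("event_id", "event_type", "gene_id")], 3)
#>                                event_id event_type gene_id
#> 1     GA31;A3:toyChr1:733-792:733-795:+         A3    GA31
#> 2 GA51;A5:toyChr1:1067-1133:1061-1133:+         A5    GA51
#> 3 GAF1;AF:toyChr1:1313-1357:1408-1461:+         AF    GAF1
```

Event ids follow the SUPPA ioe dialect
(`GENE;TYPE:chrom:coords:strand`); for an A3 event the two
coordinate pairs are the inclusion- and exclusion-form junctions.

```r
tabs <- digest_and_sample_peptides(fx$proteins, fx$manifest, seed = 42)
peps <- ingest_and_merge(list(tabs$prospector, tabs$msfragger),
                         list(engine_colmap("prospector"),
                              engine_colmap("msfragger")), fx$proteins)
peps <- adjust_met_loss(peps, fx$proteins)
cls <- classify_locus(peps, fx$transcripts)
cls$counts
#> single_isoform_gene          multi_gene shared_all_isoforms
#>                  49                   1                  45
#>    isoform_specific     subset_unpaired
#>                  67                   0
```

The five categories partition the non-decoy peptides: 49 peptides come
from genes with one isoform, 1 tryptic peptide is shared between two
different genes (excluded), 45 match every isoform of their locus, and
67 are isoform-specific.

```r
maps <- map_peptides(cls$peptides[cls$peptides$category ==
                                    "isoform_specific", ], fx$transcripts)
sup <- call_events(maps, restrict_to_cds(ev, fx$transcripts))
summarize_event_counts(sup)
#>    event_type n_events n_both_forms
#> 1:         RI        1            1
#> 2:         SE        1            1
#> 3:         A5        1            1
#> 4:         A3        1            1
#> 5:         AF        1            1
#> 6:         AL        1            1
#> 7:         MX        1            1
```

All seven embedded events are recovered, each with peptide evidence for
both the inclusion and the exclusion form. Retained-intron discovery,
run on the fixture's coverage track, finds the unannotated introns and
translates them:

```r
tm <- fx$transcripts[["GIRA1.1"]]
intr <- enumerate_introns(tm)[1, ]
build_ir_protein(tm, list(chrom = intr$chrom, start = intr$start,
                          end = intr$end), fx$genome)
#> <custom_protein_entry> GIRA1.1_IR1 (extended_in_frame+27 aa, CDS)
#>   intron toyChr1:2361-2441
```

An 81-nt stop-free, frame-preserving intron extends the protein by
exactly 27 residues — the arithmetic behind `delta = length/3`.

## Command line

```sh
Rscript -e 'pgsplice::pg_cli()' fixtures --out demo --seed 42
Rscript -e 'pgsplice::pg_cli()' call --gff3 demo/annotation.gff3 \
    --genome demo/genome.fa --proteins demo/proteins.fa \
    --tables demo/peptides_prospector.tsv,demo/peptides_msfragger.tsv \
    --dialects prospector,msfragger --out demo_calls
```

Subcommands: `fixtures`, `events`, `peptides`, `map`, `call`,
`idratio`, `build-db`, `quant`. Thresholds can come from a flat
`key = value` config file (`--config`), with flags taking precedence.

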