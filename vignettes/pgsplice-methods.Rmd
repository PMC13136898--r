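---
title: "pgsplice: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pgsplice: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsplice)
```

This vignette documents the scientific model behind each module, the
tunable parameters with their defaults, the numerical and design choices
made where the problem left room, and what the synthetic fixtures do and
do not establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The inference problem

A gene with several annotated isoforms yields, after proteolytic
digestion, mostly peptides common to all isoforms. Isoform-level
conclusions need peptides whose matched-isoform sets discriminate:
`pgsplice` calls a peptide *isoform-specific* when its set of matched
isoforms at a locus is **disjoint** from the set of at least one other
peptide of the same locus. Two disjoint sets cannot come from one
translated isoform, so each disjoint pair witnesses (at least) two
protein products. This is deliberately stricter than "maps to a proper
subset of isoforms": a subset-mapping peptide with no disjoint partner
is compatible with a single expressed isoform and is therefore kept in
a separate `subset_unpaired` diagnostic bucket, not counted as
specific. The supported-isoform count per locus is the maximum number
of pairwise-disjoint matched sets (exact maximum set packing via
branch-and-bound; isoform counts per locus are small, so this is
always feasible).

Upstream of the rule, peptides are merged across engines on the plain
sequence (modification annotations stripped), decoys are removed by
their accession prefix (`DECOY_` and `rev_` dialects built in), and
claimed matches are verified by substring search against the protein
database. A peptide that occurs at residue 2 of a Met-initiated
protein, and not at residue 1, is flagged as an N-terminal Met-loss
match (methionine aminopeptidase removes the initiator Met when the
second residue is small); this anchors the peptide at protein
coordinate 2 rather than discarding it. I and L are treated as
distinct residues by default, because search engines emit
database-resident sequences; `il_equivalent = TRUE` collapses them for
sensitivity analyses.

## Peptide-to-genome mapping

Residue `i` of a protein occupies CDS nucleotides `3i−2 … 3i`. These
CDS coordinates are pushed through the cumulative lengths of the CDS
segments (in translation order; on the minus strand CDS position 1
anchors at the genomically last CDS base) to produce genomic blocks. A
peptide is junction-spanning exactly when its blocks number more than
one; a codon split across a junction counts with no minimum-overhang
requirement, since downstream event calling is purely coordinate
based. Every occurrence of a peptide in a protein produces its own map
record — collapsing multiple occurrences silently would bias event
evidence. Stop codons are never part of a map because protein
coordinates end before the stop.

Internally all coordinates are 1-based closed genomic intervals, the
native convention of GFF3 and of R's interval infrastructure. The cost
of this choice (±1 arithmetic at block boundaries) is controlled by
round-trip tests: every mapped peptide is re-extracted from the raw
genome, spliced, strand-flipped and re-translated with an independent
translator, and must reproduce the peptide string exactly.

## The AS event catalog

Events follow the SUPPA taxonomy — RI, SE, A5, A3, AF, AL, MX — and
are enumerated by exhaustive pairwise comparison of each gene's
isoform structures, deduplicated by anchor coordinates. Each event
carries two *forms* (inclusion = the form containing the
discriminating region; exclusion = the form splicing it out), each
with its transcript set, private region(s), and diagnostic
junction(s).

Definition notes:

- **RI** is generated in "variable" mode by default: the retention
  exon may have flanking boundaries differing from the spliced form's
  exons, and all such pairs collapse to one event per intron interval
  (`ri_variable = FALSE` restores the strict same-boundaries mode).
- **A5/A3** require the two introns to share one splice site, and
  additionally require the alternative sites to lie on *overlapping*
  exons of the two forms. Without the overlap constraint, every AF/AL
  terminal-exon swap and every MX pair would also emit a spurious
  A5/A3 event, because those structures also contain intron pairs
  sharing one boundary. The A5/A3 label is strand-aware: differing
  intron starts are a 5′-site choice on the plus strand and a 3′-site
  choice on the minus strand.
- **AF/AL** require non-overlapping terminal exons splicing into the
  same shared boundary; the inclusion form is, by convention, the one
  whose alternative exon has the smaller genomic start (a deterministic
  tie-break, not a biological claim).
- **MX** requires the two internal exons to share both flanking
  junction partners, to be non-overlapping, and to be mutually absent
  from the partner transcript.

## Event calling from peptides

For RI, A5, A3, AF and AL, a peptide supports the inclusion form when
at least one genomic block overlaps the discriminating region by
`min_overlap_nt` (default 1 nt — the weakest faithful reading of
"coordinate overlap"; raise it for stricter calls) *and* the peptide
maps to an inclusion transcript. The exclusion form needs the peptide
to span the exclusion junction whose flanks abut the discriminating
region. SE and MX are called from junction-spanning peptides only, in
both directions, because any overlap-based rule would be ambiguous for
an exon present in both forms' genomic span. AF/AL additionally accept
peptides lying wholly inside the alternative terminal exon without
junction evidence (N-terminal peptides of an alternative first exon
are themselves form-specific). Peptides whose coordinates overlap a
form's private region while mapping only to the opposite form's
transcripts indicate annotation inconsistencies; they are quarantined
in a conflicts table and never counted. The caller expects its input
maps to come from isoform-specific peptides; feeding it all peptides
is possible but dilutes the evidential meaning of a call.

## Intron depth ratios and retained-intron discovery

For an intron with mean read depth `d_i` and flanking exon depths
`d_5`, `d_3` (5′/3′ in transcript orientation):

```
IDratio = d_i / mean(d_5, d_3)
```

Terminal introns use only their non-terminal flank — the first intron
divides by the second exon's depth, the last intron by its upstream
exon's — because terminal-exon depths are biased by library
preparation and soft-clipping. A transcript with a single intron is
simultaneously "first" and "last"; no choice avoids a terminal exon
there, so the package falls back to the mean of both flanks (this edge
case is not specified anywhere upstream and is our choice). A zero or
missing flank depth flags the record undefined rather than producing
infinities.

Candidate unannotated retained introns are those with IDratio ≥ 0.15
(inclusive) in **any** sample group, minus introns whose interval
equals an annotated RI event's discriminating region. Whether the
threshold should apply to the group mean or to each replicate is
genuinely open; the default is the group mean (more robust at 4–5
replicates), with `mode = "per_replicate"` available. Candidates are
fitted back to every transcript of their gene: an intron fits when its
boundaries exactly abut two consecutive exons (then it *is* that
transcript's intron) or abut the transcript's terminal exon
(flagged `upstream`/`downstream`). Fitted introns are inserted into
the mature transcript and re-translated from the annotated CDS start
of the base transcript — no re-scanning for alternative AUGs, which
keeps the construction per-transcript and deterministic. The first
in-frame stop truncates; a frameshifted read-through continues to the
transcript end and is flagged partial. Outcomes:

- `truncated` — shorter than the base isoform (premature stop);
- `extended_in_frame` — intron length divisible by 3, stop-free in
  frame; the length gain is exactly `length/3` residues;
- `frameshift_extended` — longer via frameshift;
- `unchanged` — UTR-retained introns that leave the CDS intact
  (emitted with a non-CDS flag rather than dropped, since UTR IR is
  analyzed separately downstream).

Accessions are `GENE.N_IRk`, with `k` the plus-strand intron slot
(0 = upstream of the first genomic exon). Entries whose protein equals
an annotated isoform (possible for frame-preserving IR) are dropped at
database-writing time with a log message; an empty entry set copies
the base FASTA byte-identically.

## Quantitative post-processing

- **Protein groups**: groups spanning several gene loci are discarded;
  among groups of one locus the one with most quantified peptides
  wins; ties break to the lexicographically smallest member accession
  (logged) — determinism over any deeper claim.
- **Imputation**: only rows observed in *every* replicate of one
  condition and in *none* of the other are imputed, from
  Normal(μ − 1.8·σ, (0.3·σ)²) with μ, σ the mean/SD of all observed
  values. The width/downshift are interpreted in total-matrix-SD units
  (the Perseus convention for MaxQuant-style data); `units = "raw"`
  switches to absolute log2 units. Imputation never touches an
  observed value and is bit-reproducible under a seed.
- **Differential flags**: rows with missing p-values are removed, then
  `p < 0.05 & |log2FC| > 1`. The "fold change greater than 1 or less
  than −1" rule is read on the log2 scale — a natural-scale fold
  change cannot be negative. The built-in per-row Welch t-test is a
  clearly labeled stand-in for moderated tests (limma/MSstatsTMT);
  external statistics tables are accepted as input.
- **IIR calls**: an intron shows increased retention when the mutant
  group's mean IDratio is ≥ 0.15 and its fold change over wild type is
  ≥ 1.5. A zero wild-type depth is floored at `eps = 0.01` (flagged)
  so the fold change stays finite. Introns are assigned to 5′UTR, CDS
  or 3′UTR strand-aware, by position relative to the source
  transcript's CDS span.
- **Peptide vs. intron position**: the insertion residue is
  `ceiling((CDS nt upstream of the intron + 1)/3)`; a peptide interval
  entirely before it is `upstream`, entirely after `downstream`,
  otherwise `spanning`. For truncated IR isoforms this is consistent
  with the IR builder: downstream peptides cannot occur in the
  truncated entry, which the tests verify.

## What the synthetic fixtures emulate — and what they do not

The default fixture is a ~6 kb two-chromosome genome with one gene per
AS type on both strands, a UTR-intron gene, the three IR outcome
archetypes (81-nt in-frame stop-free, early-stop, 80-nt frameshift), a
Met-loss protein, and a two-gene shared tryptic peptide. Coding filler
is drawn from the 61 non-stop codons under a fixed seed, so every CDS
translates cleanly by construction; byte-identical regeneration under
the same seed is tested. Coverage tables realize target IDratios
exactly at `noise_sd = 0` (the fixture's stated world: exon baseline
100× in wild type, 80× in mutant, 4 replicates per group, matching
RNA-seq designs of this scale) and in expectation under multiplicative
noise.

A green test on this fixture establishes coordinate arithmetic,
classification logic and end-to-end plumbing. It does **not**
establish robustness to real data: no splice-site motifs, no
sequencing-depth heteroskedasticity, no missed-cleavage bias, no
chimeric or modified peptides, no FDR behavior (decoys here only
exercise the removal path), and peptide uniqueness is near-certain by
random-codon construction rather than enforced. Claims about the
source study's headline counts require its deposited data and are out
of scope.

## Known limitations

- No PSI quantification from RNA-seq and no NMD-susceptibility
  prediction.
- Event calling consumes annotation-consistent maps; transcripts
  without annotated CDS are not mapped.
- The A5/A3 exon-overlap constraint is our reading of the SUPPA
  definitions; catalogs from annotations rich in terminal-exon
  variation may differ from other tools at the margins.
- Trans-splicing, fusion transcripts and organellar genetic codes are
  unsupported.
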