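#!/usr/bin/env Rscript

# Optional worked examples against the public Arabidopsis annotation.
#
# Usage:
#   Rscript scripts/worked_examples.R --gff3 Araport11.gff3 --genome TAIR10.fa
#
# Requires a local copy of the Araport11 GFF3 and TAIR10 genome FASTA
# (one-time ~50 MB download; not bundled and not used by the test suite,
# which runs fully offline on synthetic fixtures). Reproduces printed
# isoform lengths from the study system:
#   - RCA (AT2G39730): annotated isoforms of 474, 446 and 441 aa
#   - SOQ1 (AT1G56500): retention of intron 7 truncates to 299 aa
#   - BTZ2 (AT1G15280): an intron retention truncates 584 -> 500 aa
#   - PXL2 (AT4G28650): an intron retention truncates 1013 -> 878 aa

suppressPackageStartupMessages(library(pgsplice))

args <- commandArgs(trailingOnly = TRUE)
opt <- list()
i <- 1L
while (i < length(args)) {
  if (startsWith(args[i], "--")) opt[[sub("^--", "", args[i])]] <- args[i + 1L]
  i <- i + 2L
}
if (is.null(opt$gff3) || is.null(opt$genome))
  stop("need --gff3 and --genome (Araport11 GFF3 + TAIR10 FASTA)")

message("reading genome ...")
genome <- read_genome(opt$genome)
message("reading annotation ...")
txs <- read_annotation(opt$gff3, genome)
by_gene <- transcripts_by_gene(txs)

show_lengths <- function(gene) {
  for (tm in by_gene[[gene]])
    cat(sprintf("%-14s %4d aa\n", tm$transcript_id, nchar(tm$protein)))
}

cat("== RCA (AT2G39730) annotated isoform lengths ==\n")
show_lengths("AT2G39730")

ir_scan <- function(gene, expect_aa = NULL) {
  cat(sprintf("== %s retained-intron proteins ==\n", gene))
  for (tm in by_gene[[gene]]) {
    for (k in seq_len(nrow(enumerate_introns(tm)))) {
      intr <- enumerate_introns(tm)[k, ]
      e <- build_ir_protein(tm, list(chrom = intr$chrom, start = intr$start,
                                     end = intr$end), genome)
      hit <- !is.null(expect_aa) && nchar(e$protein_sequence) %in% expect_aa
      cat(sprintf("%s intron %d (display %d): %s, %d aa%s\n",
                  tm$transcript_id, intr$plus_strand_index,
                  intr$display_index, e$outcome,
                  nchar(e$protein_sequence),
                  if (hit) "   <-- printed value" else ""))
    }
  }
}

ir_scan("AT1G56500", 299L)   # SOQ1, expect intron 7 -> 299 aa
ir_scan("AT1G15280", 500L)   # BTZ2, expect 500 aa (base 584)
ir_scan("AT4G28650", 878L)   # PXL2, expect 878 aa (base 1013)
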