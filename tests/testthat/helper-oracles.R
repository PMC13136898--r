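# Independent oracles, deliberately using different code paths than the
# implementation under test.

# translation oracle: Biostrings' own translate()
oracle_translate <- function(nt, strand = "+") {
  if (strand == "-")
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  n3 <- nchar(nt) - nchar(nt) %% 3L
  if (n3 == 0L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n3)), if.fuzzy.codon = "X",
    no.init.codon = TRUE))
  sub("\\*.*$", "", aa)
}

# plain double-loop disjointness classifier
oracle_classify <- function(sets, full_isoforms) {
  n <- length(sets)
  out <- character(n)
  for (i in seq_len(n)) {
    disjoint <- FALSE
    for (j in seq_len(n))
      if (j != i && length(intersect(sets[[i]], sets[[j]])) == 0L)
        disjoint <- TRUE
    out[i] <- if (disjoint) "isoform_specific"
      else if (setequal(sets[[i]], full_isoforms)) "shared_all_isoforms"
      else "subset_unpaired"
  }
  out
}

# per-base scan: genomic position of every CDS nucleotide in translation
# order, then direct slicing for a peptide's codons
oracle_cds_positions <- function(tm) {
  segs <- tm$cds
  if (tm$strand == "+") {
    unlist(lapply(seq_len(nrow(segs)), function(k)
      seq(segs$start[k], segs$end[k])))
  } else {
    unlist(lapply(rev(seq_len(nrow(segs))), function(k)
      seq(segs$end[k], segs$start[k])))
  }
}

oracle_peptide_scan <- function(tm, protein_start, pep_len) {
  pos <- oracle_cds_positions(tm)
  a <- 3L * protein_start - 2L
  b <- 3L * (protein_start + pep_len - 1L)
  p <- pos[a:b]
  list(positions = sort(p), spans = any(abs(diff(p)) != 1L))
}

# splice-aware re-translation of a peptide map from the raw genome
oracle_remap_peptide <- function(map, genome) {
  nt <- paste(substring(genome[[map$chrom]], map$blocks$start,
                        map$blocks$end), collapse = "")
  oracle_translate(nt, map$strand)
}
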