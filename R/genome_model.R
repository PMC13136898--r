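#' Read a genome FASTA into named uppercase sequences
#'
#' Sequences are validated against the A/C/G/T/N alphabet. Header lines are
#' truncated at the first whitespace, matching common chromosome naming.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("genome sequence ", names(seqs)[bad][1L],
         " contains symbols outside {A,C,G,T,N}")
  if (any(!nzchar(seqs)))
    stop("empty genome sequence: ", names(seqs)[!nzchar(seqs)][1L])
  seqs
}

#' Reverse-complement a DNA string
#'
#' @param x DNA string over {A,C,G,T,N}.
#' @return reverse complement, same case convention (uppercase).
#' @export
reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(toupper(x), NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

#' Translate a CDS nucleotide string
#'
#' Input is the coding sequence in genomic plus-strand orientation; for
#' minus-strand transcripts it is reverse-complemented before translation.
#' Translation uses the standard nuclear genetic code, stops at the first
#' in-frame stop codon (the stop is not emitted), renders any codon
#' containing N as \code{X}, and drops a trailing partial codon while
#' setting the \code{"partial"} attribute.
#'
#' @param nt DNA string (A/C/G/T/N).
#' @param strand \code{"+"} or \code{"-"}.
#' @return single character string of amino acids with a logical
#'   \code{"partial"} attribute (TRUE when a trailing partial codon was
#'   dropped before a stop was reached).
#' @export
translate_cds <- function(nt, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (length(nt) != 1L || is.na(nt) || !nzchar(nt))
    stop("translate_cds: empty input")
  nt <- toupper(nt)
  if (grepl("[^ACGTN]", nt))
    stop("translate_cds: symbol outside {A,C,G,T,N}")
  if (strand == "-") nt <- reverse_complement(nt)
  n <- nchar(nt)
  n_codons <- n %/% 3L
  partial <- (n %% 3L) != 0L
  if (n_codons == 0L) {
    out <- ""
    attr(out, "partial") <- partial
    return(out)
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(nt, starts, starts + 2L)
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
               unname(Biostrings::GENETIC_CODE[codons]))
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    aa <- aa[seq_len(stop_at[1L] - 1L)]
    partial <- FALSE          # a stop terminated translation cleanly
  }
  out <- paste(aa, collapse = "")
  attr(out, "partial") <- partial
  out
}

#' Construct a transcript model
#'
#' Exons and CDS segments are 1-based closed genomic intervals, sorted
#' ascending by start. When a genome is supplied the protein sequence is
#' derived by strand-aware translation of the concatenated CDS.
#'
#' @param transcript_id,gene_id identifiers (Araport11-style
#'   \code{GENE.N} transcript ids are conventional but not required).
#' @param chrom,strand chromosome name and \code{"+"}/\code{"-"}.
#' @param exons,cds data.frames with integer \code{start}, \code{end}.
#' @param genome optional named character vector from [read_genome()].
#' @return object of class \code{"transcript_model"}.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds, genome = NULL) {
  exons <- .norm_intervals(exons)
  cds <- .norm_intervals(cds)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(exons) == 0L) stop("transcript ", transcript_id, " has no exons")
  if (any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("transcript ", transcript_id, " has overlapping/unsorted exons")
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    if (!inside)
      stop("CDS segment outside exon space in transcript ", transcript_id)
  }
  tm <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds,
         protein = NA_character_, cds_partial = NA),
    class = "transcript_model")
  if (!is.null(genome) && nrow(cds) > 0L) {
    nt <- cds_nt_sequence(tm, genome)
    prot <- translate_cds(nt, strand)
    tm$protein <- as.character(prot)
    tm$cds_partial <- (sum(cds$end - cds$start + 1L) %% 3L) != 0L
  }
  tm
}

.norm_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L))
    return(data.frame(start = integer(0), end = integer(0)))
  x <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  x <- x[order(x$start), , drop = FALSE]
  rownames(x) <- NULL
  if (any(x$end < x$start)) stop("interval with end < start")
  x
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), %d CDS segment(s)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Concatenated CDS sequence of a transcript (plus-strand orientation)
#'
#' Segments are concatenated in ascending genomic order; the result feeds
#' [translate_cds()] with the transcript's strand.
#'
#' @param tm a \code{transcript_model}.
#' @param genome named character vector from [read_genome()].
#' @return DNA string.
#' @export
cds_nt_sequence <- function(tm, genome) {
  if (!tm$chrom %in% names(genome))
    stop("chromosome ", tm$chrom, " absent from genome")
  paste(substring(genome[[tm$chrom]], tm$cds$start, tm$cds$end),
        collapse = "")
}

#' Read GFF3 annotation into transcript models
#'
#' Expects gene/mRNA/exon/CDS features with resolvable ID/Parent links
#' (Araport11 style). Records whose Parent cannot be resolved are dropped
#' with a warning; a CDS segment outside its transcript's exons is a hard
#' error. Protein sequences are translated from the CDS chain; transcripts
#' whose CDS length is not divisible by 3 are flagged \code{cds_partial}.
#'
#' @param gff3_path path to an uncompressed GFF3 file.
#' @param genome named character vector from [read_genome()].
#' @return named list of \code{transcript_model} objects, keyed by
#'   transcript id.
#' @export
read_annotation <- function(gff3_path, genome) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  typ <- tolower(as.character(gr$type))
  ids <- as.character(gr$ID)
  parents <- lapply(gr$Parent, as.character)

  mrna_idx <- which(typ %in% c("mrna", "transcript"))
  gene_idx <- which(typ == "gene")
  gene_ids <- ids[gene_idx]

  tx_gene <- character(0)
  for (i in mrna_idx) {
    p <- parents[[i]]
    if (length(p) == 0L || !p[1L] %in% gene_ids) {
      warning("mRNA ", ids[i], " has no resolvable gene parent; dropped")
      next
    }
    tx_gene[ids[i]] <- p[1L]
  }

  coords <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))

  collect <- function(kind) {
    idx <- which(typ == kind)
    out <- list()
    for (i in idx) {
      for (p in parents[[i]]) {
        if (!p %in% names(tx_gene)) {
          warning(kind, " feature with unresolvable parent ", p, "; dropped")
          next
        }
        out[[p]] <- rbind(out[[p]], coords[i, c("start", "end")])
      }
    }
    out
  }
  exon_by_tx <- collect("exon")
  cds_by_tx <- collect("cds")

  txs <- list()
  for (tx in names(tx_gene)) {
    i <- mrna_idx[ids[mrna_idx] == tx][1L]
    ex <- exon_by_tx[[tx]]
    if (is.null(ex)) {
      warning("mRNA ", tx, " has no exons; dropped")
      next
    }
    txs[[tx]] <- transcript_model(
      transcript_id = tx, gene_id = tx_gene[[tx]],
      chrom = coords$chrom[i], strand = coords$strand[i],
      exons = ex, cds = cds_by_tx[[tx]], genome = genome)
  }
  txs
}

#' Group transcript models by gene
#'
#' @param transcripts named list of \code{transcript_model}s.
#' @return named list (gene id -> list of transcript models).
#' @export
transcripts_by_gene <- function(transcripts) {
  split(transcripts, vapply(transcripts, `[[`, "", "gene_id"))
}

#' Enumerate the introns of a transcript
#'
#' Introns are numbered relative to the plus strand, 5' to 3'
#' (\code{plus_strand_index}); for minus-strand genes the display index
#' runs in descending order, i.e. \code{display_index = n - index + 1}.
#'
#' @param tm a \code{transcript_model}.
#' @return data.frame with one row per intron (zero rows for single-exon
#'   transcripts): gene_id, transcript_id, chrom, strand, start, end,
#'   plus_strand_index, display_index.
#' @export
enumerate_introns <- function(tm) {
  n <- nrow(tm$exons)
  if (n < 2L)
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      plus_strand_index = integer(0),
                      display_index = integer(0)))
  idx <- seq_len(n - 1L)
  data.frame(
    gene_id = tm$gene_id, transcript_id = tm$transcript_id,
    chrom = tm$chrom, strand = tm$strand,
    start = tm$exons$end[-n] + 1L, end = tm$exons$start[-1L] - 1L,
    plus_strand_index = idx,
    display_index = if (tm$strand == "-") rev(idx) else idx)
}

#' Write protein sequences of transcript models to FASTA
#'
#' Headers follow the \code{>GENE.N} accession convention (the transcript
#' id itself). Transcripts without a derived protein are skipped.
#'
#' @param transcripts named list of \code{transcript_model}s.
#' @param path output FASTA path.
#' @return invisibly, the number of records written.
#' @export
write_protein_fasta <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- 0L
  for (tm in transcripts) {
    if (is.na(tm$protein) || !nzchar(tm$protein)) next
    writeLines(c(paste0(">", tm$transcript_id), tm$protein), con)
    n <- n + 1L
  }
  invisible(n)
}

#' Read a protein FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
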