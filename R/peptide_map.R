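#' Locate all exact occurrences of a peptide in a protein
#'
#' Overlapping occurrences are reported; positions are 1-based.
#'
#' @param peptide,protein uppercase amino-acid strings.
#' @return integer vector of start positions (empty when absent).
#' @export
locate_in_protein <- function(peptide, protein) {
  np <- nchar(peptide); n <- nchar(protein)
  if (np == 0L || np > n) return(integer(0))
  starts <- seq_len(n - np + 1L)
  starts[substring(protein, starts, starts + np - 1L) == peptide]
}

#' Map a peptide occurrence to genomic coordinates
#'
#' Residue positions are converted to CDS nucleotide positions by the
#' standard arithmetic (first residue: position*3 - 2; last residue:
#' position*3) and pushed through the cumulative CDS-segment lengths to
#' genomic blocks. On the minus strand, CDS position 1 anchors at the
#' genomically last CDS base. A peptide is junction-spanning when its
#' codons are split over more than one CDS segment (any split counts; no
#' minimum overhang).
#'
#' @param peptide amino-acid string.
#' @param tm \code{transcript_model} whose protein contains the peptide.
#' @param protein_start 1-based residue position of the first peptide
#'   residue (e.g. from [locate_in_protein()]).
#' @return object of class \code{"peptide_map"}: peptide, transcript_id,
#'   chrom, strand, protein_start/end, cds_nt_start/end, blocks
#'   (ascending genomic intervals), spans_junction, junctions (2-column
#'   matrix of flanking exon end / next exon start pairs).
#' @export
map_to_genome <- function(peptide, tm, protein_start) {
  np <- nchar(peptide)
  a <- 3L * protein_start - 2L
  b <- 3L * (protein_start + np - 1L)
  segs <- tm$cds
  if (!nrow(segs)) stop("transcript ", tm$transcript_id, " has no CDS")
  if (tm$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  lens <- segs$end - segs$start + 1L
  total <- sum(lens)
  if (b > total)
    stop("peptide extends past CDS end of ", tm$transcript_id,
         " (annotation/protein mismatch)")
  cum0 <- cumsum(c(0L, lens))[seq_along(lens)]
  blocks <- NULL
  for (k in seq_along(lens)) {
    lo <- max(a, cum0[k] + 1L); hi <- min(b, cum0[k] + lens[k])
    if (lo > hi) next
    l1 <- lo - cum0[k]; l2 <- hi - cum0[k]
    gb <- if (tm$strand == "+")
      c(segs$start[k] + l1 - 1L, segs$start[k] + l2 - 1L)
    else
      c(segs$end[k] - l2 + 1L, segs$end[k] - l1 + 1L)
    blocks <- rbind(blocks, gb)
  }
  blocks <- data.frame(start = blocks[, 1L], end = blocks[, 2L])
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  nb <- nrow(blocks)
  junctions <- if (nb > 1L)
    cbind(left = blocks$end[-nb], right = blocks$start[-1L])
  else cbind(left = integer(0), right = integer(0))
  structure(list(
    peptide = peptide, transcript_id = tm$transcript_id, chrom = tm$chrom,
    strand = tm$strand, protein_start = protein_start,
    protein_end = protein_start + np - 1L,
    cds_nt_start = a, cds_nt_end = b, blocks = blocks,
    spans_junction = nb > 1L, junctions = junctions),
    class = "peptide_map")
}

#' @export
print.peptide_map <- function(x, ...) {
  cat(sprintf("<peptide_map> %s on %s (%s:%s) aa %d-%d, %d block(s)%s\n",
              x$peptide, x$transcript_id, x$chrom, x$strand,
              x$protein_start, x$protein_end, nrow(x$blocks),
              if (x$spans_junction) ", junction-spanning" else ""))
  invisible(x)
}

#' Map a set of peptides onto all their matched isoforms
#'
#' Every exact occurrence of every peptide on every matched isoform's
#' protein yields one map record (multiple occurrences are not collapsed).
#'
#' @param peptides data.table with \code{sequence} and
#'   \code{matched_isoforms} columns (see [classify_locus()]).
#' @param transcripts named list of \code{transcript_model}s.
#' @return list of \code{peptide_map} objects.
#' @export
map_peptides <- function(peptides, transcripts) {
  maps <- list()
  for (k in seq_len(nrow(peptides))) {
    pep <- peptides$sequence[k]
    for (tx in peptides$matched_isoforms[[k]]) {
      tm <- transcripts[[tx]]
      if (is.null(tm) || is.na(tm$protein)) next
      for (pos in locate_in_protein(pep, tm$protein))
        maps[[length(maps) + 1L]] <- map_to_genome(pep, tm, pos)
    }
  }
  maps
}

#' Reconstruct a peptide from its genomic map
#'
#' Extracts the genomic blocks, splices them in ascending order,
#' reverse-complements on the minus strand, and translates. Used as a
#' self-consistency check: the result must equal the mapped peptide.
#'
#' @param map a \code{peptide_map}.
#' @param genome named character vector from [read_genome()].
#' @return amino-acid string.
#' @export
peptide_from_map <- function(map, genome) {
  nt <- paste(substring(genome[[map$chrom]], map$blocks$start,
                        map$blocks$end), collapse = "")
  as.character(translate_cds(nt, map$strand))
}

#' Export peptide maps as BED12
#'
#' One line per map; blocks become blockStarts/blockSizes so junction
#' peptides render as spliced features in a genome browser.
#'
#' @param maps list of \code{peptide_map}s.
#' @param path output BED path.
#' @export
write_maps_bed12 <- function(maps, path) {
  lines <- vapply(maps, function(m) {
    b <- m$blocks
    chromStart <- min(b$start) - 1L
    paste(m$chrom, chromStart, max(b$end),
          paste0(m$peptide, "|", m$transcript_id), 0L, m$strand,
          chromStart, max(b$end), "0,0,0", nrow(b),
          paste0(paste(b$end - b$start + 1L, collapse = ","), ","),
          paste0(paste(b$start - 1L - chromStart, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Tabulate peptide maps
#'
#' @param maps list of \code{peptide_map}s.
#' @return data.frame with one row per map.
#' @export
maps_to_df <- function(maps) {
  if (!length(maps))
    return(data.frame(peptide = character(0), transcript_id = character(0),
                      chrom = character(0), strand = character(0),
                      protein_start = integer(0), protein_end = integer(0),
                      cds_nt_start = integer(0), cds_nt_end = integer(0),
                      blocks = character(0), spans_junction = logical(0)))
  do.call(rbind, lapply(maps, function(m) data.frame(
    peptide = m$peptide, transcript_id = m$transcript_id, chrom = m$chrom,
    strand = m$strand, protein_start = m$protein_start,
    protein_end = m$protein_end, cds_nt_start = m$cds_nt_start,
    cds_nt_end = m$cds_nt_end,
    blocks = paste(sprintf("%d-%d", m$blocks$start, m$blocks$end),
                   collapse = ";"),
    spans_junction = m$spans_junction)))
}
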