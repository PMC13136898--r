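#' Column maps for supported search-engine export dialects
#'
#' @param dialect "prospector" (Protein Prospector-style: \code{DB.Peptide},
#'   \code{Acc..} semicolon-separated, decoys prefixed \code{DECOY_}) or
#'   "msfragger" (philosopher-style: \code{Peptide}, \code{Protein} plus
#'   comma-separated \code{Mapped.Proteins}, decoys prefixed \code{rev_}).
#' @return list with fields peptide, proteins, sep, decoy_prefix, engine.
#' @export
engine_colmap <- function(dialect = c("prospector", "msfragger")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    prospector = list(peptide = "DB.Peptide", proteins = "Acc..",
                      sep = ";", decoy_prefix = "DECOY_",
                      engine = "prospector"),
    msfragger = list(peptide = "Peptide", proteins = "Mapped.Proteins",
                     sep = ",", decoy_prefix = "rev_", engine = "msfragger"))
}

.strip_mods <- function(x) gsub("[^A-Z]", "", toupper(gsub("\\[[^]]*\\]|\\([^)]*\\)", "", x)))

#' Ingest and merge peptide tables from one or more search engines
#'
#' Modification annotations are stripped to the plain sequence, decoy
#' matches are removed, and records are merged on exact sequence with
#' engine labels and matched accessions unioned. When a protein database
#' is supplied, accessions absent from it are dropped with a message;
#' peptides left with no accession are dropped as unmapped.
#'
#' @param tables list of data.frames (one per engine export).
#' @param colmaps list of column maps ([engine_colmap()]), recycled.
#' @param proteins optional named character vector (protein database) used
#'   to validate accessions.
#' @return data.table with columns sequence, engines (list),
#'   matched_isoforms (list), matched_genes (list), nterm_met_loss.
#'   Attribute \code{"counts"} holds input/decoy/unmapped tallies of
#'   distinct sequences.
#' @export
ingest_and_merge <- function(tables, colmaps = list(engine_colmap()),
                             proteins = NULL) {
  if (!length(tables))
    return(.empty_peptides(counts = list(input = 0L, decoy = 0L,
                                         unmapped = 0L)))
  if (length(colmaps) == 1L) colmaps <- rep(colmaps, length(tables))
  rows <- list()
  for (i in seq_along(tables)) {
    tab <- as.data.frame(tables[[i]])
    cm <- colmaps[[i]]
    if (!all(c(cm$peptide, cm$proteins) %in% names(tab)))
      stop("table ", i, " lacks mapped columns ", cm$peptide, "/", cm$proteins)
    accs <- strsplit(as.character(tab[[cm$proteins]]), cm$sep, fixed = TRUE)
    rows[[i]] <- data.table::data.table(
      sequence = .strip_mods(as.character(tab[[cm$peptide]])),
      accs = accs, engine = cm$engine, decoy_prefix = cm$decoy_prefix)
  }
  dt <- data.table::rbindlist(rows)
  dt <- dt[nchar(sequence) > 0L]
  dt[, is_decoy_acc := lapply(seq_len(.N), function(k)
    startsWith(accs[[k]], decoy_prefix[k]))]
  n_input <- length(unique(dt$sequence))

  # a sequence is a decoy when every accession supporting it is a decoy
  seq_decoy <- dt[, .(decoy = all(unlist(is_decoy_acc))), by = sequence]
  decoy_seqs <- seq_decoy$sequence[seq_decoy$decoy]
  dt <- dt[!sequence %in% decoy_seqs]
  # drop decoy accessions from surviving rows
  dt[, accs := lapply(seq_len(.N), function(k) accs[[k]][!is_decoy_acc[[k]]])]

  merged <- dt[, .(engines = list(sort(unique(engine))),
                   matched_isoforms = list(sort(unique(unlist(accs))))),
               by = sequence]
  n_unmapped <- 0L
  if (!is.null(proteins)) {
    merged[, matched_isoforms := lapply(matched_isoforms, function(a) {
      known <- a %in% names(proteins)
      if (any(!known))
        message("dropping unknown accession(s): ",
                paste(a[!known], collapse = ", "))
      a[known]
    })]
  }
  keep <- vapply(merged$matched_isoforms, length, integer(1)) > 0L
  n_unmapped <- sum(!keep)
  if (n_unmapped)
    message(n_unmapped, " peptide(s) without known accession dropped")
  merged <- merged[keep]
  merged[, matched_genes := lapply(matched_isoforms, accession_gene)]
  merged[, nterm_met_loss := FALSE]
  data.table::setattr(merged, "counts",
                      list(input = n_input, decoy = length(decoy_seqs),
                           unmapped = n_unmapped))
  merged[]
}

.empty_peptides <- function(counts = NULL) {
  out <- data.table::data.table(
    sequence = character(0), engines = list(), matched_isoforms = list(),
    matched_genes = list(), nterm_met_loss = logical(0))
  if (!is.null(counts)) data.table::setattr(out, "counts", counts)
  out
}

#' Gene locus of an accession
#'
#' Araport11-style accessions are \code{GENE.N}; the gene id is the part
#' before the final dot-number.
#'
#' @param acc character vector of accessions.
#' @return character vector of gene ids (sorted unique).
#' @export
accession_gene <- function(acc) sort(unique(sub("\\.[0-9]+$", "", acc)))

#' Validate peptide-protein matches and adjust N-terminal Met loss
#'
#' Each peptide's claimed accessions are verified by exact substring
#' search. A peptide that fails the exact match but equals the protein
#' starting at residue 2 of a protein whose first residue is M is kept
#' with the \code{nterm_met_loss} flag set (mature N-terminus after
#' Met-aminopeptidase processing). Peptides matching neither form on any
#' accession are dropped with a message.
#'
#' @param peptides data.table from [ingest_and_merge()].
#' @param proteins named character vector of protein sequences.
#' @param il_equivalent treat I and L as indistinguishable during matching.
#' @return filtered data.table with accessions restricted to verified
#'   matches and \code{nterm_met_loss} set where the rule applied.
#' @export
adjust_met_loss <- function(peptides, proteins, il_equivalent = FALSE) {
  if (!nrow(peptides)) return(peptides)
  canon <- function(x) if (il_equivalent) chartr("L", "I", x) else x
  prot_c <- canon(proteins)
  out <- data.table::copy(peptides)
  keep <- logical(nrow(out))
  for (k in seq_len(nrow(out))) {
    pep <- canon(out$sequence[k])
    accs <- out$matched_isoforms[[k]]
    accs <- accs[accs %in% names(proteins)]
    met <- FALSE
    matched <- character(0)
    for (a in accs) {
      pos <- locate_in_protein(pep, prot_c[[a]])
      if (!length(pos)) next
      matched <- c(matched, a)
      # mature N-terminus after Met removal: anchored at residue 2 of a
      # Met-initiated protein, with no full-length (position 1) match
      if (startsWith(prot_c[[a]], "M") && 2L %in% pos && !1L %in% pos)
        met <- TRUE
    }
    if (length(matched)) {
      data.table::set(out, k, "matched_isoforms", list(list(sort(matched))))
      data.table::set(out, k, "nterm_met_loss", met)
      keep[k] <- TRUE
    } else {
      message("peptide ", out$sequence[k],
              " matches no claimed protein (exact or Met-loss); dropped")
    }
  }
  out <- out[keep]
  out[, matched_genes := lapply(matched_isoforms, accession_gene)]
  out[]
}

#' Classify peptides by locus specificity
#'
#' Peptides mapping to multiple gene loci are \code{multi_gene}; peptides
#' of single-isoform genes are \code{single_isoform_gene}. At
#' multi-isoform loci a peptide is \code{isoform_specific} when its
#' matched-isoform set is disjoint from that of at least one other
#' peptide of the same locus; a peptide matching the full isoform set is
#' \code{shared_all_isoforms}; subset-mapping peptides with no disjoint
#' partner land in the diagnostic \code{subset_unpaired} bucket.
#'
#' @param peptides data.table from [adjust_met_loss()].
#' @param transcripts named list of \code{transcript_model}s defining the
#'   full isoform inventory per gene.
#' @return list with \code{peptides} (input plus \code{category} column),
#'   \code{locus_summary} (per-locus peptide tallies and the supported
#'   isoform count from [count_supported_isoforms()]), and \code{counts}
#'   (category tally named vector).
#' @export
classify_locus <- function(peptides, transcripts) {
  if (any(vapply(peptides$matched_isoforms, length, integer(1)) == 0L))
    stop("peptide with empty matched_isoforms (upstream bug)")
  iso_by_gene <- lapply(transcripts_by_gene(transcripts), names)
  out <- data.table::copy(peptides)
  n <- nrow(out)
  category <- character(n)
  n_genes <- vapply(out$matched_genes, length, integer(1))
  category[n_genes > 1L] <- "multi_gene"
  single_gene <- which(n_genes == 1L)
  gene_of <- vapply(out$matched_genes, function(g) g[1L], "")
  for (k in single_gene) {
    full <- iso_by_gene[[gene_of[k]]]
    if (length(full) < 2L) category[k] <- "single_isoform_gene"
  }
  todo <- which(category == "")
  for (g in unique(gene_of[todo])) {
    idx <- todo[gene_of[todo] == g]
    sets <- out$matched_isoforms[idx]
    full <- iso_by_gene[[g]]
    for (a in seq_along(idx)) {
      disjoint <- any(vapply(seq_along(idx), function(b)
        b != a && !length(intersect(sets[[a]], sets[[b]])), logical(1)))
      category[idx[a]] <-
        if (disjoint) "isoform_specific"
        else if (setequal(sets[[a]], full)) "shared_all_isoforms"
        else "subset_unpaired"
    }
  }
  out[, category := category]
  loci <- unique(gene_of[category %in%
                           c("isoform_specific", "shared_all_isoforms",
                             "subset_unpaired")])
  locus_summary <- data.table::rbindlist(lapply(loci, function(g) {
    idx <- which(gene_of == g & n_genes == 1L)
    data.table::data.table(
      gene_id = g, n_peptides = length(idx),
      n_isoform_specific = sum(category[idx] == "isoform_specific"),
      supported_isoforms = count_supported_isoforms(
        out$matched_isoforms[idx]))
  }))
  counts <- table(factor(category,
    levels = c("single_isoform_gene", "multi_gene", "shared_all_isoforms",
               "isoform_specific", "subset_unpaired")))
  list(peptides = out[], locus_summary = locus_summary,
       counts = c(counts))
}

#' Maximum number of isoforms supported by peptide evidence at one locus
#'
#' The maximum number of pairwise-disjoint matched-isoform sets among the
#' locus's peptides (maximum set packing, exhaustive branch-and-bound;
#' isoform counts are small).
#'
#' @param sets list of character vectors (matched isoform sets).
#' @return integer >= 0 (0 for an empty list).
#' @export
count_supported_isoforms <- function(sets) {
  sets <- unique(lapply(sets, function(s) sort(unique(s))))
  if (!length(sets)) return(0L)
  iso <- sort(unique(unlist(sets)))
  if (length(iso) > 30L) stop("too many isoforms for exact packing")
  masks <- unique(vapply(sets, function(s)
    sum(bitwShiftL(1L, match(s, iso) - 1L)), integer(1)))
  best <- 0L
  m <- length(masks)
  rec <- function(i, used, count) {
    if (count > best) best <<- count
    if (i > m || count + (m - i + 1L) <= best) return()
    if (bitwAnd(masks[i], used) == 0L)
      rec(i + 1L, bitwOr(used, masks[i]), count + 1L)
    rec(i + 1L, used, count)
  }
  rec(1L, 0L, 0L)
  best
}

#' Write the per-peptide classification table
#'
#' @param classification result of [classify_locus()].
#' @param path output TSV path.
#' @export
write_peptide_classification <- function(classification, path) {
  dt <- data.table::copy(classification$peptides)
  dt[, `:=`(engines = vapply(engines, paste, "", collapse = ";"),
            matched_isoforms = vapply(matched_isoforms, paste, "",
                                      collapse = ";"),
            matched_genes = vapply(matched_genes, paste, "", collapse = ";"))]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
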