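#' Unique intron inventory of a transcript set
#'
#' One row per distinct intron interval per gene, with flanking-exon
#' intervals and terminal-intron flags taken from the first transcript
#' (by id) containing the intron. 5'/3' designations are in transcript
#' orientation (strand-aware).
#'
#' @param transcripts named list of \code{transcript_model}s.
#' @return data.table: gene_id, transcript_id, chrom, strand, start, end,
#'   plus_strand_index, display_index, five-/three-prime exon intervals,
#'   is_first, is_last.
#' @export
gene_intron_inventory <- function(transcripts) {
  rows <- list()
  for (tm in transcripts[order(names(transcripts))]) {
    intr <- enumerate_introns(tm)
    if (!nrow(intr)) next
    n <- nrow(intr)
    for (k in seq_len(n)) {
      left <- c(tm$exons$start[k], tm$exons$end[k])
      right <- c(tm$exons$start[k + 1L], tm$exons$end[k + 1L])
      plus <- tm$strand == "+"
      five <- if (plus) left else right    # upstream exon, transcript sense
      three <- if (plus) right else left
      # terminal status in transcript orientation
      is_first <- if (plus) k == 1L else k == n
      is_last <- if (plus) k == n else k == 1L
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = tm$gene_id, transcript_id = tm$transcript_id,
        chrom = tm$chrom, strand = tm$strand,
        start = intr$start[k], end = intr$end[k],
        plus_strand_index = intr$plus_strand_index[k],
        display_index = intr$display_index[k],
        five_start = five[1L], five_end = five[2L],
        three_start = three[1L], three_end = three[2L],
        is_first = is_first, is_last = is_last)
    }
  }
  if (!length(rows)) return(data.table::data.table())
  dt <- data.table::rbindlist(rows)
  dt[!duplicated(dt[, .(gene_id, chrom, start, end)])]
}

#' Compute intron depth ratios (IDratio)
#'
#' IDratio = mean read depth of the intron divided by the mean depth of
#' its flanking exons. Terminal introns use only the non-terminal flank
#' (first intron: the 3' exon; last intron: the 5' exon), because terminal
#' exon depths are biased; a transcript's single intron (both first and
#' last) falls back to the mean of both flanks. A zero or missing flank
#' depth flags the record undefined.
#'
#' @param depths data.frame keyed by genomic interval per sample:
#'   chrom, start, end, sample_id, mean_depth.
#' @param inventory intron inventory from [gene_intron_inventory()].
#' @return data.table with one row per intron per sample: the inventory
#'   columns plus sample_id, intron_depth, five_prime_exon_depth,
#'   three_prime_exon_depth, idratio, flag
#'   ("ok"/"missing"/"undefined").
#' @export
compute_idratio <- function(depths, inventory) {
  depths <- data.table::as.data.table(depths)
  key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")
  samples <- sort(unique(depths$sample_id))
  lookup <- split(stats::setNames(depths$mean_depth,
                                  key(depths$chrom, depths$start, depths$end)),
                  depths$sample_id)
  rows <- list()
  for (s in samples) {
    dmap <- lookup[[s]]
    get_depth <- function(chrom, start, end) {
      v <- dmap[key(chrom, start, end)]
      if (is.na(v)) NA_real_ else unname(v)
    }
    for (k in seq_len(nrow(inventory))) {
      iv <- inventory[k]
      d_i <- get_depth(iv$chrom, iv$start, iv$end)
      d_5 <- get_depth(iv$chrom, iv$five_start, iv$five_end)
      d_3 <- get_depth(iv$chrom, iv$three_start, iv$three_end)
      use <- if (iv$is_first && iv$is_last) c(d_5, d_3)
             else if (iv$is_first) d_3
             else if (iv$is_last) d_5
             else c(d_5, d_3)
      flag <- "ok"; ratio <- NA_real_
      if (is.na(d_i) || anyNA(use)) flag <- "missing"
      else if (mean(use) == 0) flag <- "undefined"
      else ratio <- d_i / mean(use)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        iv[, .(gene_id, transcript_id, chrom, strand, start, end,
               plus_strand_index, display_index, is_first, is_last)],
        sample_id = s, intron_depth = d_i,
        five_prime_exon_depth = d_5, three_prime_exon_depth = d_3,
        idratio = ratio, flag = flag)
    }
  }
  data.table::rbindlist(rows)
}

#' Select unannotated retained-intron candidates
#'
#' Introns whose IDratio reaches the threshold (inclusive) in any sample
#' group are selected; introns whose interval equals the discriminating
#' region of an annotated RI event are excluded as redundant. By default
#' the group mean IDratio is compared to the threshold; in
#' "per_replicate" mode a single replicate suffices.
#'
#' @param records data.table from [compute_idratio()].
#' @param annotated_ri list of \code{as_event}s (the RI subset is used).
#' @param threshold IDratio cutoff (default 0.15, inclusive).
#' @param sample_groups named character vector mapping sample_id to group
#'   (e.g. WT / mutant); defaults to each sample being its own group.
#' @param mode "group_mean" or "per_replicate".
#' @return data.table of selected introns (unique intervals, with the
#'   per-group statistic in wide columns).
#' @export
select_candidates <- function(records, annotated_ri = list(),
                              threshold = 0.15, sample_groups = NULL,
                              mode = c("group_mean", "per_replicate")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  rec <- records[flag == "ok"]
  if (is.null(sample_groups))
    sample_groups <- stats::setNames(unique(rec$sample_id),
                                     unique(rec$sample_id))
  rec[, group := sample_groups[sample_id]]
  stat <- if (mode == "group_mean")
    rec[, .(stat = mean(idratio)), by = .(gene_id, chrom, start, end, group)]
  else
    rec[, .(stat = max(idratio)), by = .(gene_id, chrom, start, end, group)]
  sel <- stat[, .(max_stat = max(stat),
                  hit = any(stat >= threshold)),
              by = .(gene_id, chrom, start, end)][hit == TRUE]
  if (length(annotated_ri)) {
    ri <- Filter(function(e) e$event_type == "RI", annotated_ri)
    if (length(ri)) {
      ri_keys <- vapply(ri, function(e)
        paste(e$chrom, e$disc$start[1L], e$disc$end[1L], sep = ":"), "")
      sel <- sel[!paste(chrom, start, end, sep = ":") %in% ri_keys]
    }
  }
  info <- unique(records[, .(gene_id, transcript_id, chrom, strand, start,
                             end, plus_strand_index, display_index)])
  merge(sel[, .(gene_id, chrom, start, end, max_stat)], info,
        by = c("gene_id", "chrom", "start", "end"), sort = TRUE)
}

#' Which transcripts does an intron fit without gaps?
#'
#' An intron fits internally when its boundaries exactly abut two
#' consecutive exons; it fits terminally when it abuts immediately
#' upstream of the transcript's first exon or downstream of its last
#' exon (transcript orientation).
#'
#' @param intron list or one-row data.frame with chrom, start, end.
#' @param transcripts transcript models of the intron's gene.
#' @return data.frame(transcript_id, mode) with mode in
#'   "internal"/"upstream"/"downstream"; zero rows when nothing fits.
#' @export
fit_intron_to_transcripts <- function(intron, transcripts) {
  out <- list()
  for (tm in transcripts) {
    if (tm$chrom != intron$chrom) next
    ex <- tm$exons; n <- nrow(ex)
    mode <- NULL
    if (n >= 2L &&
        any(ex$end[-n] + 1L == intron$start & intron$end + 1L == ex$start[-1L]))
      mode <- "internal"
    else if (intron$end + 1L == ex$start[1L])
      mode <- if (tm$strand == "+") "upstream" else "downstream"
    else if (ex$end[n] + 1L == intron$start)
      mode <- if (tm$strand == "+") "downstream" else "upstream"
    if (!is.null(mode))
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tm$transcript_id, mode = mode)
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), mode = character(0)))
  do.call(rbind, out)
}

.tx_coord <- function(exons, strand, g) {
  # transcript-orientation coordinate of genomic position g
  lens <- exons$end - exons$start + 1L
  if (strand == "+") {
    k <- which(exons$start <= g & g <= exons$end)
    sum(lens[seq_len(k - 1L)]) + (g - exons$start[k] + 1L)
  } else {
    k <- which(exons$start <= g & g <= exons$end)
    after <- if (k < nrow(exons)) sum(lens[(k + 1L):nrow(exons)]) else 0L
    after + (exons$end[k] - g + 1L)
  }
}

#' Build the retained-intron protein for one transcript
#'
#' The intron is inserted into the mature transcript at its genomic
#' position (the flanking exons and intron merge into one exon) and the
#' sequence is re-translated from the annotated CDS start of the base
#' transcript; the first in-frame stop truncates. The outcome is
#' classified against the base isoform: \code{truncated} (shorter),
#' \code{extended_in_frame} (longer, frame-preserving stop-free intron),
#' \code{frameshift_extended} (longer via frameshift), or
#' \code{unchanged} (UTR-retained introns leaving the protein intact).
#'
#' @param tm base \code{transcript_model}.
#' @param intron list/one-row data.frame with chrom, start, end.
#' @param genome named character vector from [read_genome()].
#' @return object of class \code{"custom_protein_entry"}: accession
#'   (\code{GENE.N_IRk}, k = plus-strand intron slot), base_transcript_id,
#'   intron interval, protein_sequence, outcome, delta_length_aa, in_cds,
#'   partial (translation ran off the transcript end without a stop).
#' @export
build_ir_protein <- function(tm, intron, genome) {
  fit <- fit_intron_to_transcripts(intron, list(tm))
  if (!nrow(fit))
    stop("intron ", intron$start, "-", intron$end, " does not fit ",
         tm$transcript_id)
  ex <- tm$exons
  n <- nrow(ex)
  slot <- sum(ex$start < intron$start)
  if (fit$mode[1L] == "internal") {
    k <- which(ex$end + 1L == intron$start)
    new_ex <- rbind(
      if (k > 1L) ex[seq_len(k - 1L), ] else NULL,
      data.frame(start = ex$start[k], end = ex$end[k + 1L]),
      if (k + 1L < n) ex[(k + 2L):n, ] else NULL)
  } else if (intron$end + 1L == ex$start[1L]) {
    new_ex <- ex; new_ex$start[1L] <- intron$start
  } else {
    new_ex <- ex; new_ex$end[n] <- intron$end
  }
  rownames(new_ex) <- NULL
  if (!nrow(tm$cds)) stop(tm$transcript_id, " has no CDS")
  cds_start_g <- if (tm$strand == "+") min(tm$cds$start) else max(tm$cds$end)
  mature <- paste(substring(genome[[tm$chrom]], new_ex$start, new_ex$end),
                  collapse = "")
  if (tm$strand == "-") mature <- reverse_complement(mature)
  t0 <- .tx_coord(new_ex, tm$strand, cds_start_g)
  prot <- translate_cds(substring(mature, t0), "+")
  partial <- isTRUE(attr(prot, "partial"))
  prot <- as.character(prot)
  base_len <- nchar(tm$protein)
  new_len <- nchar(prot)
  delta <- new_len - base_len
  cds_span <- c(min(tm$cds$start), max(tm$cds$end))
  in_cds <- intron$start <= cds_span[2L] && intron$end >= cds_span[1L] &&
    fit$mode[1L] == "internal"
  intron_len <- intron$end - intron$start + 1L
  outcome <- if (delta < 0L) "truncated"
    else if (prot == tm$protein) "unchanged"
    else if (intron_len %% 3L == 0L && delta == intron_len %/% 3L)
      "extended_in_frame"
    else "frameshift_extended"
  structure(list(
    accession = paste0(tm$transcript_id, "_IR", slot),
    base_transcript_id = tm$transcript_id, gene_id = tm$gene_id,
    chrom = tm$chrom, strand = tm$strand,
    intron_start = intron$start, intron_end = intron$end,
    protein_sequence = prot, outcome = outcome,
    delta_length_aa = delta, in_cds = in_cds, fit_mode = fit$mode[1L],
    partial = partial), class = "custom_protein_entry")
}

#' @export
print.custom_protein_entry <- function(x, ...) {
  cat(sprintf("<custom_protein_entry> %s (%s%+d aa, %s) intron %s:%d-%d\n",
              x$accession, x$outcome, x$delta_length_aa,
              if (x$in_cds) "CDS" else "non-CDS",
              x$chrom, x$intron_start, x$intron_end))
  invisible(x)
}

#' Build IR protein entries for a set of candidate introns
#'
#' Each candidate is fitted against all transcripts of its gene; every
#' fitting transcript yields one entry.
#'
#' @param candidates data.table from [select_candidates()] (or any table
#'   with gene_id, chrom, start, end).
#' @param transcripts named list of \code{transcript_model}s.
#' @param genome named character vector.
#' @return list of \code{custom_protein_entry} objects.
#' @export
build_ir_entries <- function(candidates, transcripts, genome) {
  by_gene <- transcripts_by_gene(transcripts)
  entries <- list()
  for (k in seq_len(nrow(candidates))) {
    cand <- candidates[k, ]
    gtx <- by_gene[[cand$gene_id]]
    if (is.null(gtx)) next
    fits <- fit_intron_to_transcripts(
      list(chrom = cand$chrom, start = cand$start, end = cand$end), gtx)
    for (tx in fits$transcript_id)
      entries[[length(entries) + 1L]] <- build_ir_protein(
        transcripts[[tx]],
        list(chrom = cand$chrom, start = cand$start, end = cand$end), genome)
  }
  entries
}

#' Summarize predicted IR protein outcomes
#'
#' @param entries list of \code{custom_protein_entry}s.
#' @param set_labels character vector (recycled) labeling each entry's
#'   set, e.g. "annotated" / "unannotated".
#' @return data.table per set: n, n_truncated, frac_truncated.
#' @export
summarize_outcomes <- function(entries, set_labels = "all") {
  if (!length(entries))
    return(data.table::data.table(set = character(0), n = integer(0),
                                  n_truncated = integer(0),
                                  frac_truncated = numeric(0)))
  dt <- data.table::data.table(
    set = rep_len(set_labels, length(entries)),
    outcome = vapply(entries, `[[`, "", "outcome"))
  dt[, .(n = .N, n_truncated = sum(outcome == "truncated"),
         frac_truncated = mean(outcome == "truncated")), by = set]
}

#' Append IR proteins to a base protein database
#'
#' Accession collisions with the base database are a hard error; entries
#' whose protein sequence already exists in the base (a frame-preserved
#' IR can equal an annotated isoform) are dropped with a message. With no
#' entries the output is a byte-identical copy of the base FASTA.
#'
#' @param base_fasta path to the base protein FASTA.
#' @param entries list of \code{custom_protein_entry}s.
#' @param path output FASTA path.
#' @return invisibly, the number of entries appended.
#' @export
write_custom_database <- function(base_fasta, entries, path) {
  if (!length(entries)) {
    file.copy(base_fasta, path, overwrite = TRUE)
    return(invisible(0L))
  }
  base <- read_protein_fasta(base_fasta)
  accs <- vapply(entries, `[[`, "", "accession")
  if (any(accs %in% names(base)))
    stop("accession collision with base database: ",
         paste(intersect(accs, names(base)), collapse = ", "))
  if (anyDuplicated(accs))
    stop("duplicate entry accessions: ", accs[duplicated(accs)][1L])
  keep <- vapply(entries, function(e)
    !e$protein_sequence %in% base, logical(1))
  if (any(!keep))
    message(sum(!keep), " IR entr(ies) identical to an annotated isoform; ",
            "dropped: ", paste(accs[!keep], collapse = ", "))
  file.copy(base_fasta, path, overwrite = TRUE)
  con <- file(path, "a")
  on.exit(close(con))
  for (e in entries[keep])
    writeLines(c(sprintf(">%s IR=%s:%d-%d outcome=%s delta=%+d",
                         e$accession, e$chrom, e$intron_start, e$intron_end,
                         e$outcome, e$delta_length_aa),
                 e$protein_sequence), con)
  invisible(sum(keep))
}
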