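#' Select one protein group per gene locus
#'
#' Groups whose member accessions span more than one gene locus are
#' discarded as ambiguous. When several groups remain for one locus, the
#' group with the most quantified peptides is kept; ties are broken by
#' the lexicographically smallest member accession (logged).
#'
#' @param groups data.frame with columns \code{group_id},
#'   \code{accessions} (";"-separated) and \code{n_peptides}.
#' @return filtered data.table with an added \code{gene_id} column.
#' @export
select_protein_groups <- function(groups) {
  dt <- data.table::as.data.table(groups)
  accs <- strsplit(dt$accessions, ";", fixed = TRUE)
  loci <- lapply(accs, accession_gene)
  n_loci <- vapply(loci, length, integer(1))
  dt <- dt[n_loci == 1L]
  dt[, gene_id := vapply(loci[n_loci == 1L], `[[`, "", 1L)]
  dt[, min_acc := vapply(strsplit(accessions, ";", fixed = TRUE),
                         function(a) min(a), "")]
  data.table::setorder(dt, gene_id, -n_peptides, min_acc)
  dup <- duplicated(dt$gene_id)
  ties <- dt[, .(tie = .N > 1L &&
                   sum(n_peptides == max(n_peptides)) > 1L), by = gene_id]
  for (g in ties$gene_id[ties$tie])
    message("tie at locus ", g, "; keeping lexicographically smallest ",
            "accession group")
  out <- dt[!dup]
  out[, min_acc := NULL]
  out[]
}

#' Impute fully missing-in-one-condition rows from a downshifted normal
#'
#' Only rows quantified in every replicate of one condition and missing
#' in every replicate of the other are imputed. Draws come from
#' Normal(mu - shift*sigma, (width*sigma)^2) where mu and sigma are the
#' mean and SD of all observed values of the matrix (Perseus-style
#' downshifted imputation in total-matrix-SD units; set
#' \code{units = "raw"} to interpret width/shift on the log2 scale
#' directly).
#'
#' @param m numeric matrix (log2 abundances, NA = missing).
#' @param condition character/factor vector, one label per column;
#'   exactly two conditions.
#' @param width,shift imputation parameters (defaults 0.3 and 1.8).
#' @param seed optional integer for reproducible draws.
#' @param units "sd" (default) or "raw".
#' @return matrix of the same shape; attribute \code{"imputed"} holds the
#'   logical mask of imputed cells.
#' @export
impute_missing <- function(m, condition, width = 0.3, shift = 1.8,
                           seed = NULL, units = c("sd", "raw")) {
  units <- match.arg(units)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(m))
  conds <- unique(condition)
  if (length(conds) != 2L) stop("exactly two conditions required")
  obs <- m[!is.na(m)]
  if (length(obs) < 2L) stop("fewer than 2 observed values; SD undefined")
  mu <- mean(obs); sigma <- stats::sd(obs)
  mean_imp <- if (units == "sd") mu - shift * sigma else mu - shift
  sd_imp <- if (units == "sd") width * sigma else width
  if (!is.null(seed)) set.seed(seed)
  imputed <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  out <- m
  for (r in seq_len(nrow(m))) {
    for (cond in conds) {
      this <- condition == cond
      if (all(is.na(m[r, this])) && !anyNA(m[r, !this])) {
        out[r, this] <- stats::rnorm(sum(this), mean_imp, sd_imp)
        imputed[r, this] <- TRUE
      }
    }
  }
  attr(out, "imputed") <- imputed
  out
}

#' Per-row Welch two-sample test (stand-in for moderated testing)
#'
#' A plain Welch's t-test per row, provided as a clearly labeled stand-in
#' for moderated tests (e.g. MSstatsTMT's groupComparisonTMT) whose
#' outputs can equally be fed to [call_differential()].
#'
#' @param m numeric matrix (log2 scale).
#' @param condition two-level label vector per column.
#' @param ref reference condition (denominator of the fold change).
#' @return data.table(id, log2fc, pvalue); rows with fewer than two
#'   observations per side get NA p-values.
#' @export
welch_differential <- function(m, condition, ref = unique(condition)[1L]) {
  condition <- as.character(condition)
  other <- setdiff(unique(condition), ref)
  if (length(other) != 1L) stop("exactly two conditions required")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  res <- lapply(seq_len(nrow(m)), function(r) {
    x <- m[r, condition == other]; y <- m[r, condition == ref]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    lfc <- mean(x) - mean(y)
    p <- if (length(x) >= 2L && length(y) >= 2L)
      tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.table::data.table(id = ids[r], log2fc = lfc, pvalue = p)
  })
  data.table::rbindlist(res)
}

#' Flag differentially abundant rows
#'
#' Rows with missing p-values are filtered out first; the remaining rows
#' are flagged when p < p_cut and |log2FC| > lfc_cut (the "fold change
#' greater than 1 or less than -1" rule on the log2 scale).
#'
#' @param stats data.frame with \code{log2fc} and \code{pvalue} columns.
#' @param p_cut,lfc_cut thresholds (defaults 0.05 and 1).
#' @return data.table with a logical \code{differential} column.
#' @export
call_differential <- function(stats, p_cut = 0.05, lfc_cut = 1) {
  dt <- data.table::as.data.table(stats)
  dt <- dt[!is.na(pvalue)]
  dt[, differential := pvalue < p_cut & abs(log2fc) > lfc_cut]
  dt[]
}

.intron_region <- function(tm, intron_start, intron_end) {
  if (!nrow(tm$cds)) return(NA_character_)
  lo <- min(tm$cds$start); hi <- max(tm$cds$end)
  if (intron_end >= lo && intron_start <= hi) return("CDS")
  before <- intron_end < lo     # genomically left of the CDS span
  if (tm$strand == "+") { if (before) "5UTR" else "3UTR" }
  else { if (before) "3UTR" else "5UTR" }
}

#' Call increased intron retention (IIR) events
#'
#' An intron is an IIR when its mutant IR depth is at least
#' \code{depth_min} and its fold change over wild type is at least
#' \code{fold_min} (defaults: >= 15% depth and >= 1.5-fold). Group mean
#' IDratios are used; a zero wild-type depth is floored at \code{eps}
#' (flagged). The intron is assigned to 5'UTR, CDS, or 3'UTR by its
#' position relative to the CDS span of its source transcript.
#'
#' @param records data.table from [compute_idratio()].
#' @param sample_groups named character vector mapping sample_id to
#'   group.
#' @param wt_group,mut_group group labels.
#' @param transcripts named list of \code{transcript_model}s (for region
#'   assignment).
#' @param depth_min,fold_min,eps thresholds and zero-depth floor.
#' @return data.table with one row per intron: gene_id, chrom, start,
#'   end, region, ir_depth_wt, ir_depth_mut, fold_change, wt_floored,
#'   is_iir.
#' @export
call_iir <- function(records, sample_groups, wt_group, mut_group,
                     transcripts, depth_min = 0.15, fold_min = 1.5,
                     eps = 0.01) {
  rec <- records[flag == "ok"]
  rec[, group := sample_groups[sample_id]]
  agg <- rec[group %in% c(wt_group, mut_group),
             .(mean_idr = mean(idratio)),
             by = .(gene_id, transcript_id, chrom, strand, start, end, group)]
  wide <- data.table::dcast(agg,
    gene_id + transcript_id + chrom + strand + start + end ~ group,
    value.var = "mean_idr")
  data.table::setnames(wide, c(wt_group, mut_group),
                       c("ir_depth_wt", "ir_depth_mut"))
  wide <- wide[!is.na(ir_depth_wt) & !is.na(ir_depth_mut)]
  wide[, wt_floored := ir_depth_wt < eps]
  wide[, fold_change := ir_depth_mut / pmax(ir_depth_wt, eps)]
  wide[, is_iir := ir_depth_mut >= depth_min & fold_change >= fold_min]
  wide[, region := vapply(seq_len(.N), function(k) {
    tm <- transcripts[[transcript_id[k]]]
    if (is.null(tm)) NA_character_
    else .intron_region(tm, start[k], end[k])
  }, character(1))]
  wide[]
}

#' Amino-acid position of an intron insertion in an isoform
#'
#' The residue whose codon begins at or spans the first inserted
#' nucleotide: ceiling((cumulative CDS nt upstream of the intron + 1)/3).
#'
#' @param tm \code{transcript_model} the intron fits into (internally).
#' @param intron list with start, end (genomic).
#' @return integer residue position, or NA when the intron lies outside
#'   the transcript's CDS.
#' @export
intron_insertion_aa <- function(tm, intron) {
  if (!nrow(tm$cds)) return(NA_integer_)
  if (is.na(.intron_region(tm, intron$start, intron$end)) ||
      .intron_region(tm, intron$start, intron$end) != "CDS")
    return(NA_integer_)
  lens <- tm$cds$end - tm$cds$start + 1L
  upstream <- if (tm$strand == "+")
    sum(lens[tm$cds$end < intron$start])
  else
    sum(lens[tm$cds$start > intron$end])
  as.integer(ceiling((upstream + 1L) / 3))
}

#' Classify a peptide relative to a retained intron
#'
#' Compares the peptide's protein-coordinate interval with the intron's
#' insertion residue on the isoform: wholly before is "upstream", wholly
#' after is "downstream", otherwise "spanning". Introns outside the
#' isoform's CDS give "not_applicable".
#'
#' @param protein_start,protein_end 1-based residue interval of the
#'   peptide on the isoform's protein.
#' @param tm \code{transcript_model}.
#' @param intron list with start, end (genomic).
#' @return one of "upstream", "downstream", "spanning", "not_applicable".
#' @export
annotate_peptide_vs_intron <- function(protein_start, protein_end, tm,
                                       intron) {
  pos <- intron_insertion_aa(tm, intron)
  if (is.na(pos)) return("not_applicable")
  if (protein_end < pos) "upstream"
  else if (protein_start > pos) "downstream"
  else "spanning"
}
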