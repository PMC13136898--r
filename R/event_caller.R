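.overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)

.map_overlaps_regions <- function(map, regions, min_overlap) {
  if (!nrow(regions)) return(FALSE)
  for (k in seq_len(nrow(regions)))
    if (any(.overlap_len(map$blocks$start, map$blocks$end,
                         regions$start[k], regions$end[k]) >= min_overlap))
      return(TRUE)
  FALSE
}

.map_has_junction <- function(map, junctions) {
  if (!nrow(junctions) || !nrow(map$junctions)) return(FALSE)
  any(apply(junctions, 1L, function(j)
    any(map$junctions[, 1L] == j[1L] & map$junctions[, 2L] == j[2L])))
}

#' Call proteomically supported AS events
#'
#' Integrates peptide genomic maps with the event catalog. For RI, A5, A3,
#' AF, and AL the inclusion form is supported by a peptide whose blocks
#' overlap the event's discriminating region by at least
#' \code{min_overlap_nt} on an inclusion transcript; the exclusion form by
#' a peptide spanning the exclusion-form junction. For SE and MX only
#' junction-spanning evidence counts, in either direction. Peptides whose
#' blocks overlap a form's private region while mapping only to the
#' opposite form's transcripts are recorded in the \code{"conflicts"}
#' attribute and not counted.
#'
#' Maps are expected to come from isoform-specific peptides
#' (see [classify_locus()]); the function does not re-check specificity.
#'
#' @param maps list of \code{peptide_map}s.
#' @param events list of \code{as_event}s.
#' @param min_overlap_nt minimum overlap (nt) for coordinate-overlap calls.
#' @return data.table with one row per (event, form) that has support:
#'   event_id, event_type, form, evidence, n_peptides, peptides (list).
#' @export
call_events <- function(maps, events, min_overlap_nt = 1L) {
  rows <- list()
  conflicts <- list()
  for (ev in events) {
    ev_maps <- Filter(function(m) m$chrom == ev$chrom, maps)
    for (form in c("inclusion", "exclusion")) {
      f <- ev$forms[[form]]
      other <- ev$forms[[setdiff(c("inclusion", "exclusion"), form)]]
      peps <- character(0); kinds <- character(0)
      for (m in ev_maps) {
        on_form <- m$transcript_id %in% f$transcripts
        jn <- .map_has_junction(m, f$junctions)
        ov <- .map_overlaps_regions(m, f$regions, min_overlap_nt)
        if (on_form && (jn || ov)) {
          peps <- c(peps, m$peptide)
          kinds <- c(kinds, if (jn) "junction" else "overlap")
        } else if (!on_form && ov && m$transcript_id %in% other$transcripts) {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            event_id = ev$event_id, form = form, peptide = m$peptide,
            transcript_id = m$transcript_id)
        }
      }
      if (length(peps)) {
        keep <- !duplicated(peps)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          event_id = ev$event_id, event_type = ev$event_type,
          gene_id = ev$gene_id, form = form,
          evidence = if (any(kinds[keep] == "junction")) "junction"
                     else "overlap",
          n_peptides = sum(keep), peptides = list(peps[keep]))
      }
    }
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(event_id = character(0), event_type = character(0),
                           gene_id = character(0), form = character(0),
                           evidence = character(0), n_peptides = integer(0),
                           peptides = list())
  data.table::setattr(out, "conflicts",
                      if (length(conflicts)) do.call(rbind, conflicts)
                      else data.frame(event_id = character(0),
                                      form = character(0),
                                      peptide = character(0),
                                      transcript_id = character(0)))
  out[]
}

#' Summarize supported events per AS type
#'
#' Each event counts once regardless of how many of its forms are
#' supported; events with both forms supported are tallied separately.
#'
#' @param supports data.table from [call_events()].
#' @return data.table with event_type, n_events, n_both_forms (all seven
#'   types always present).
#' @export
summarize_event_counts <- function(supports) {
  types <- c("RI", "SE", "A5", "A3", "AF", "AL", "MX")
  if (!nrow(supports))
    return(data.table::data.table(event_type = types, n_events = 0L,
                                  n_both_forms = 0L))
  per_event <- supports[, .(n_forms = length(unique(form))),
                        by = .(event_id, event_type)]
  agg <- per_event[, .(n_events = .N, n_both_forms = sum(n_forms == 2L)),
                   by = event_type]
  out <- data.table::data.table(event_type = types)
  out <- merge(out, agg, by = "event_type", all.x = TRUE, sort = FALSE)
  out[is.na(n_events), `:=`(n_events = 0L)]
  out[is.na(n_both_forms), `:=`(n_both_forms = 0L)]
  out[]
}

#' Write the per-event support table
#'
#' @param supports data.table from [call_events()].
#' @param path output TSV path.
#' @export
write_event_support <- function(supports, path) {
  dt <- data.table::copy(supports)
  dt[, peptides := vapply(peptides, paste, "", collapse = ";")]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
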