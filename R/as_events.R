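#' @section Event model:
#' An AS event is a pairwise contrast between transcript structures of one
#' gene, in the SUPPA sense: RI (retained intron), SE (skipped exon),
#' A5/A3 (alternative 5'/3' splice site), AF/AL (alternative first/last
#' exon), MX (mutually exclusive exons). Each event carries two forms,
#' "inclusion" (the form containing the discriminating region) and
#' "exclusion", each with its transcript set, the genomic region(s)
#' private to that form, and the splice junction(s) diagnostic for it.
#' @name as-events
#' @keywords internal
NULL

.tx_introns <- function(tm) {
  n <- nrow(tm$exons)
  if (n < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = tm$exons$end[-n] + 1L, end = tm$exons$start[-1L] - 1L)
}

.tx_junctions <- function(tm) {
  n <- nrow(tm$exons)
  if (n < 2L) return(cbind(left = integer(0), right = integer(0)))
  cbind(left = tm$exons$end[-n], right = tm$exons$start[-1L])
}

.has_junction <- function(tm, left, right) {
  j <- .tx_junctions(tm)
  any(j[, 1L] == left & j[, 2L] == right)
}

.has_exon <- function(tm, start, end) {
  any(tm$exons$start == start & tm$exons$end == end)
}

.has_covering_exon <- function(tm, start, end) {
  any(tm$exons$start <= start & tm$exons$end >= end)
}

.first_exon <- function(tm) {
  i <- if (tm$strand == "+") 1L else nrow(tm$exons)
  c(tm$exons$start[i], tm$exons$end[i])
}

.last_exon <- function(tm) {
  i <- if (tm$strand == "+") nrow(tm$exons) else 1L
  c(tm$exons$start[i], tm$exons$end[i])
}

.new_event <- function(type, gene_id, chrom, strand, event_id, disc,
                       incl, excl, alt2 = NULL) {
  structure(list(
    event_id = event_id, gene_id = gene_id, event_type = type,
    chrom = chrom, strand = strand,
    disc = disc,                     # discriminating region (inclusion side)
    alt2 = alt2,                     # second alternative region (AF/AL/MX)
    forms = list(inclusion = incl, exclusion = excl),
    region_label = NA_character_), class = "as_event")
}

.form <- function(transcripts, regions = NULL, junctions = NULL) {
  if (is.null(regions))
    regions <- data.frame(start = integer(0), end = integer(0))
  if (is.null(junctions))
    junctions <- cbind(left = integer(0), right = integer(0))
  list(transcripts = transcripts, regions = regions, junctions = junctions)
}

#' Generate a SUPPA-style catalog of AS events from transcript models
#'
#' Events are enumerated by exhaustive pairwise comparison of the isoforms
#' of each gene and deduplicated by their anchor coordinates. RI events
#' follow the "variable" interpretation by default: the retention exon may
#' have flanking boundaries that differ from the spliced form's exons, and
#' multiple such pairs collapse to one event per intron interval.
#'
#' @param transcripts named list of \code{transcript_model}s.
#' @param types subset of c("RI","SE","A5","A3","AF","AL","MX").
#' @param ri_variable logical; if FALSE the retention exon must exactly
#'   span the spliced form's two flanking exons (SUPPA default mode).
#' @return list of \code{as_event} objects.
#' @export
generate_events <- function(transcripts,
                            types = c("RI", "SE", "A5", "A3", "AF", "AL", "MX"),
                            ri_variable = TRUE) {
  types <- match.arg(types, several.ok = TRUE)
  events <- list()
  for (gene_txs in transcripts_by_gene(transcripts)) {
    if (length(gene_txs) < 2L) next
    events <- c(events, .gene_events(gene_txs, types, ri_variable))
  }
  events
}

.gene_events <- function(txs, types, ri_variable) {
  gene <- txs[[1L]]$gene_id
  chrom <- txs[[1L]]$chrom
  strand <- txs[[1L]]$strand
  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(key, ev) {
    if (!is.null(ev) && is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <<- ev
    }
  }
  tx_ids <- names(txs)

  if ("RI" %in% types) {
    for (b in txs) {
      intr <- .tx_introns(b)
      for (k in seq_len(nrow(intr))) {
        is <- intr[k, 1L]; ie <- intr[k, 2L]
        key <- sprintf("RI:%d-%d", is, ie)
        if (!is.null(seen[[key]])) next
        incl_tx <- tx_ids[vapply(txs, function(a) {
          if (ri_variable) .has_covering_exon(a, is - 1L, ie + 1L)
          else .has_exon(a, b$exons$start[k], b$exons$end[k + 1L])
        }, logical(1))]
        excl_tx <- tx_ids[vapply(txs, .has_junction, logical(1),
                                 left = is - 1L, right = ie + 1L)]
        if (!length(incl_tx) || !length(excl_tx) ||
            length(intersect(incl_tx, excl_tx))) next
        s1 <- min(vapply(txs[excl_tx], function(t)
          max(t$exons$start[t$exons$end == is - 1L]), integer(1)))
        e2 <- max(vapply(txs[excl_tx], function(t)
          min(t$exons$end[t$exons$start == ie + 1L]), integer(1)))
        disc <- data.frame(start = is, end = ie)
        add(key, .new_event("RI", gene, chrom, strand,
          sprintf("%s;RI:%s:%d:%d-%d:%d:%s", gene, chrom, s1, is - 1L,
                  ie + 1L, e2, strand),
          disc,
          incl = .form(incl_tx, regions = disc),
          excl = .form(excl_tx,
                       junctions = cbind(left = is - 1L, right = ie + 1L))))
      }
    }
  }

  if ("SE" %in% types) {
    for (a in txs) {
      n <- nrow(a$exons)
      if (n < 3L) next
      for (k in 2:(n - 1L)) {
        e1 <- a$exons$end[k - 1L]; s <- a$exons$start[k]
        e <- a$exons$end[k]; s3 <- a$exons$start[k + 1L]
        if (!any(vapply(txs, .has_junction, logical(1), left = e1, right = s3)))
          next
        key <- sprintf("SE:%d:%d:%d:%d", e1, s, e, s3)
        incl_tx <- tx_ids[vapply(txs, function(t)
          .has_junction(t, e1, s) && .has_junction(t, e, s3), logical(1))]
        excl_tx <- tx_ids[vapply(txs, .has_junction, logical(1),
                                 left = e1, right = s3)]
        if (!length(incl_tx) || !length(excl_tx) ||
            length(intersect(incl_tx, excl_tx))) next
        add(key, .new_event("SE", gene, chrom, strand,
          sprintf("%s;SE:%s:%d-%d:%d-%d:%s", gene, chrom, e1, s, e, s3, strand),
          data.frame(start = s, end = e),
          incl = .form(incl_tx,
                       junctions = cbind(left = c(e1, e), right = c(s, s3))),
          excl = .form(excl_tx, junctions = cbind(left = e1, right = s3))))
      }
    }
  }

  if (any(c("A5", "A3") %in% types)) {
    all_introns <- unique(do.call(rbind, lapply(txs, .tx_introns)))
    if (length(all_introns) && nrow(all_introns) >= 2L) {
      for (i in seq_len(nrow(all_introns) - 1L)) {
        for (j in (i + 1L):nrow(all_introns)) {
          a <- all_introns[i, ]; b <- all_introns[j, ]
          same_start <- a[1L] == b[1L]; same_end <- a[2L] == b[2L]
          if (same_start == same_end) next  # need exactly one shared side
          # donor side differs on '+' when starts differ; strand flips the label
          type <- if (xor(same_end, strand == "-")) "A5" else "A3"
          if (!type %in% types) next
          if (same_end) {
            s_short <- max(a[1L], b[1L]); s_long <- min(a[1L], b[1L])
            short <- c(s_short, a[2L]); long <- c(s_long, a[2L])
            disc <- data.frame(start = s_long, end = s_short - 1L)
          } else {
            e_short <- min(a[2L], b[2L]); e_long <- max(a[2L], b[2L])
            short <- c(a[1L], e_short); long <- c(a[1L], e_long)
            disc <- data.frame(start = e_short + 1L, end = e_long)
          }
          incl_tx <- tx_ids[vapply(txs, .has_junction, logical(1),
                                   left = short[1L] - 1L,
                                   right = short[2L] + 1L)]
          excl_tx <- tx_ids[vapply(txs, .has_junction, logical(1),
                                   left = long[1L] - 1L,
                                   right = long[2L] + 1L)]
          if (!length(incl_tx) || !length(excl_tx) ||
              length(intersect(incl_tx, excl_tx))) next
          # the alternative sites must lie on overlapping exons of the two
          # forms, else the contrast is an AF/AL-type terminal-exon swap
          flank_ok <- if (same_end)
            any(vapply(txs[incl_tx], function(t)
              any(t$exons$end == short[1L] - 1L &
                    t$exons$start <= long[1L] - 1L), logical(1)))
          else
            any(vapply(txs[incl_tx], function(t)
              any(t$exons$start == short[2L] + 1L &
                    t$exons$end >= long[2L] + 1L), logical(1)))
          if (!flank_ok) next
          key <- sprintf("%s:%d-%d:%d-%d", type, short[1L], short[2L],
                         long[1L], long[2L])
          add(key, .new_event(type, gene, chrom, strand,
            sprintf("%s;%s:%s:%d-%d:%d-%d:%s", gene, type, chrom,
                    short[1L] - 1L, short[2L] + 1L,
                    long[1L] - 1L, long[2L] + 1L, strand),
            disc,
            incl = .form(incl_tx, regions = disc,
                         junctions = cbind(left = short[1L] - 1L,
                                           right = short[2L] + 1L)),
            excl = .form(excl_tx,
                         junctions = cbind(left = long[1L] - 1L,
                                           right = long[2L] + 1L))))
        }
      }
    }
  }

  for (type in intersect(c("AF", "AL"), types)) {
    pick <- if (type == "AF") .first_exon else .last_exon
    multi <- Filter(function(t) nrow(t$exons) >= 2L, txs)
    if (length(multi) >= 2L) {
      ids <- names(multi)
      for (i in seq_len(length(multi) - 1L)) {
        for (j in (i + 1L):length(multi)) {
          ta <- multi[[i]]; tb <- multi[[j]]
          fa <- pick(ta); fb <- pick(tb)
          if (identical(fa, fb)) next
          if (fa[1L] <= fb[2L] && fb[1L] <= fa[2L]) next  # overlapping
          # shared boundary: the junction partner on the gene-body side
          adj <- function(t, f) {
            jn <- .tx_junctions(t)
            hit <- jn[jn[, 1L] == f[2L] | jn[, 2L] == f[1L], , drop = FALSE]
            hit[1L, ]
          }
          ja <- adj(ta, fa); jb <- adj(tb, fb)
          terminal_left <- xor(strand == "+", type == "AL")
          shared <- if (terminal_left) c(ja[2L], jb[2L]) else c(ja[1L], jb[1L])
          if (shared[1L] != shared[2L]) next
          if (fa[1L] > fb[1L]) {           # inclusion = genomically first exon
            tmp <- fa; fa <- fb; fb <- tmp
            tmp <- ja; ja <- jb; jb <- tmp
          }
          key <- sprintf("%s:%d-%d:%d-%d", type, fa[1L], fa[2L], fb[1L], fb[2L])
          has_terminal <- function(t, f, jn)
            nrow(t$exons) >= 2L && identical(pick(t), unname(f)) &&
              .has_junction(t, jn[1L], jn[2L])
          incl_tx <- ids[vapply(multi, has_terminal, logical(1), f = fa, jn = ja)]
          excl_tx <- ids[vapply(multi, has_terminal, logical(1), f = fb, jn = jb)]
          if (!length(incl_tx) || !length(excl_tx) ||
              length(intersect(incl_tx, excl_tx))) next
          add(key, .new_event(type, gene, chrom, strand,
            sprintf("%s;%s:%s:%d-%d:%d-%d:%s", gene, type, chrom,
                    fa[1L], fa[2L], fb[1L], fb[2L], strand),
            data.frame(start = fa[1L], end = fa[2L]),
            incl = .form(incl_tx, regions = data.frame(start = fa[1L],
                                                       end = fa[2L]),
                         junctions = cbind(left = ja[1L], right = ja[2L])),
            excl = .form(excl_tx, regions = data.frame(start = fb[1L],
                                                       end = fb[2L]),
                         junctions = cbind(left = jb[1L], right = jb[2L])),
            alt2 = data.frame(start = fb[1L], end = fb[2L])))
        }
      }
    }
  }

  if ("MX" %in% types) {
    internal <- function(t) {
      n <- nrow(t$exons)
      if (n < 3L) return(NULL)
      data.frame(e0 = t$exons$end[1:(n - 2L)],
                 s = t$exons$start[2:(n - 1L)], e = t$exons$end[2:(n - 1L)],
                 s3 = t$exons$start[3:n])
    }
    for (i in seq_along(txs)) {
      ia <- internal(txs[[i]])
      if (is.null(ia)) next
      for (j in seq_along(txs)) {
        if (i == j) next
        ib <- internal(txs[[j]])
        if (is.null(ib)) next
        for (ka in seq_len(nrow(ia))) for (kb in seq_len(nrow(ib))) {
          A <- ia[ka, ]; B <- ib[kb, ]
          if (A$e0 != B$e0 || A$s3 != B$s3) next
          if (A$s <= B$e && B$s <= A$e) next          # must not overlap
          if (.has_exon(txs[[j]], A$s, A$e)) next      # mutually absent
          if (.has_exon(txs[[i]], B$s, B$e)) next
          if (A$s > B$s) next  # canonical order: handled by the swapped pair
          key <- sprintf("MX:%d:%d-%d:%d-%d:%d", A$e0, A$s, A$e, B$s, B$e, A$s3)
          x1_tx <- tx_ids[vapply(txs, function(t)
            .has_junction(t, A$e0, A$s) && .has_junction(t, A$e, A$s3),
            logical(1))]
          x2_tx <- tx_ids[vapply(txs, function(t)
            .has_junction(t, B$e0, B$s) && .has_junction(t, B$e, B$s3),
            logical(1))]
          if (!length(x1_tx) || !length(x2_tx) ||
              length(intersect(x1_tx, x2_tx))) next
          add(key, .new_event("MX", gene, chrom, strand,
            sprintf("%s;MX:%s:%d-%d:%d-%d:%d-%d:%d-%d:%s", gene, chrom,
                    A$e0, A$s, A$e, A$s3, B$e0, B$s, B$e, B$s3, strand),
            data.frame(start = A$s, end = A$e),
            incl = .form(x1_tx, junctions = cbind(left = c(A$e0, A$e),
                                                  right = c(A$s, A$s3))),
            excl = .form(x2_tx, junctions = cbind(left = c(B$e0, B$e),
                                                  right = c(B$s, B$s3))),
            alt2 = data.frame(start = B$s, end = B$e)))
        }
      }
    }
  }

  out
}

.event_regions <- function(ev) {
  r <- ev$disc
  if (!is.null(ev$alt2)) r <- rbind(r, ev$alt2)
  r
}

#' Restrict an event catalog to coding regions
#'
#' Retains events whose discriminating region(s) overlap the CDS of at
#' least one participating transcript by >= 1 nt. All input events are
#' labeled "CDS" or "UTR"; the full label table is attached as the
#' \code{"labels"} attribute of the returned list.
#'
#' @param events list of \code{as_event}s from [generate_events()].
#' @param transcripts the transcript models the catalog was built from.
#' @return filtered list of events (each with \code{$region_label} set).
#' @export
restrict_to_cds <- function(events, transcripts) {
  labels <- character(length(events))
  for (i in seq_along(events)) {
    ev <- events[[i]]
    txs <- unique(c(ev$forms$inclusion$transcripts,
                    ev$forms$exclusion$transcripts))
    cds <- do.call(rbind, lapply(transcripts[txs], function(t) t$cds))
    reg <- .event_regions(ev)
    hit <- FALSE
    if (!is.null(cds) && nrow(cds))
      for (k in seq_len(nrow(reg)))
        if (any(reg$start[k] <= cds$end & cds$start <= reg$end[k])) {
          hit <- TRUE; break
        }
    labels[i] <- if (hit) "CDS" else "UTR"
    events[[i]]$region_label <- labels[i]
  }
  out <- events[labels == "CDS"]
  attr(out, "labels") <- data.frame(
    event_id = vapply(events, `[[`, "", "event_id"), label = labels)
  out
}

#' Tabulate an event catalog
#'
#' @param events list of \code{as_event}s.
#' @return data.frame with one row per event.
#' @export
events_to_df <- function(events) {
  if (!length(events))
    return(data.frame(event_id = character(0), gene_id = character(0),
                      event_type = character(0), chrom = character(0),
                      strand = character(0), disc_start = integer(0),
                      disc_end = integer(0),
                      inclusion_transcripts = character(0),
                      exclusion_transcripts = character(0)))
  do.call(rbind, lapply(events, function(ev) data.frame(
    event_id = ev$event_id, gene_id = ev$gene_id, event_type = ev$event_type,
    chrom = ev$chrom, strand = ev$strand,
    disc_start = ev$disc$start[1L], disc_end = ev$disc$end[1L],
    inclusion_transcripts = paste(ev$forms$inclusion$transcripts,
                                  collapse = ","),
    exclusion_transcripts = paste(ev$forms$exclusion$transcripts,
                                  collapse = ","))))
}

#' Write an ioe-like event table
#'
#' Columns follow SUPPA's .ioe layout: seqname, gene_id, event_id,
#' alternative_transcripts (inclusion form), total_transcripts.
#'
#' @param events list of \code{as_event}s.
#' @param path output TSV path.
#' @export
write_events_ioe <- function(events, path) {
  df <- data.frame(
    seqname = vapply(events, `[[`, "", "chrom"),
    gene_id = vapply(events, `[[`, "", "gene_id"),
    event_id = vapply(events, `[[`, "", "event_id"),
    alternative_transcripts = vapply(events, function(e)
      paste(e$forms$inclusion$transcripts, collapse = ","), ""),
    total_transcripts = vapply(events, function(e)
      paste(sort(unique(c(e$forms$inclusion$transcripts,
                          e$forms$exclusion$transcripts))), collapse = ","), ""))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write discriminating regions as BED
#'
#' @param events list of \code{as_event}s.
#' @param path output BED path (0-based half-open intervals).
#' @export
write_events_bed <- function(events, path) {
  rows <- lapply(events, function(ev) {
    reg <- .event_regions(ev)
    data.frame(chrom = ev$chrom, start = reg$start - 1L, end = reg$end,
               name = ev$event_id, score = 0L, strand = ev$strand)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
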