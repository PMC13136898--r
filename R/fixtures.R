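#' @section Fixture world:
#' The default fixture is a two-chromosome toy genome (~6 kb) whose genes
#' each embed one known feature: one gene per AS type (RI, SE, A5, A3,
#' AF, AL, MX) on both strands, a gene with UTR introns (a 5'UTR RI
#' event plus a 3'UTR intron), three single-isoform genes whose introns
#' realize the three retained-intron outcomes (an 81-nt stop-free
#' in-frame intron adding 27 aa, an early-stop intron, and an 80-nt
#' frameshift intron reading through to the transcript end), a gene whose
#' protein starts M-A... to exercise N-terminal Met loss, and a pair of
#' genes sharing an identical tryptic peptide. Coding sequence filler is
#' drawn from the 61 non-stop codons under the fixture seed, so every
#' annotated CDS translates without internal stops by construction.
#' Splice-site dinucleotides are not modeled.
#' @name fixtures
#' @keywords internal
NULL

.STOP_FREE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                             c("TAA", "TAG", "TGA"))

.rcodons <- function(n) paste(sample(.STOP_FREE_CODONS, n, replace = TRUE),
                              collapse = "")
.rnt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

#' Default fixture specification
#'
#' @param types AS event types to embed (one gene each).
#' @param n_isoforms isoform count for AS genes (must be >= 2).
#' @return fixture spec list consumed by [make_genome_and_annotation()].
#' @export
default_fixture_spec <- function(types = c("RI", "SE", "A5", "A3", "AF",
                                           "AL", "MX"),
                                 n_isoforms = 2L) {
  list(types = types, n_isoforms = n_isoforms,
       with_utr_gene = TRUE, with_ir_genes = TRUE,
       with_duplicate_pair = TRUE, with_single_isoform = TRUE,
       intergenic = 120L)
}

# -- gene assembly ----------------------------------------------------------

# pieces: named DNA strings in transcript (5'->3') orientation.
# isoforms: list(tx suffix -> list of exon piece groups, transcript order).
# cds: optional list(tx suffix -> list(start = c(piece, offset),
#      end = c(piece, offset))) in transcript orientation; default: all.
.gene_spec <- function(gene_id, strand, pieces, isoforms, cds = NULL) {
  list(gene_id = gene_id, strand = strand, pieces = pieces,
       isoforms = isoforms, cds = cds)
}

.place_gene <- function(gs, chrom, offset) {
  lens <- vapply(gs$pieces, nchar, integer(1))
  total <- sum(lens)
  cum0 <- cumsum(c(0L, lens))[seq_along(lens)]
  seq_tx <- paste(unlist(gs$pieces), collapse = "")
  gseq <- if (gs$strand == "+") seq_tx else reverse_complement(seq_tx)
  piece_coords <- list()
  for (j in seq_along(gs$pieces)) {
    nm <- names(gs$pieces)[j]
    piece_coords[[nm]] <- if (gs$strand == "+")
      c(offset + cum0[j] + 1L, offset + cum0[j] + lens[j])
    else
      c(offset + total - cum0[j] - lens[j] + 1L, offset + total - cum0[j])
  }
  txs <- list()
  for (sfx in names(gs$isoforms)) {
    groups <- gs$isoforms[[sfx]]
    exons <- do.call(rbind, lapply(groups, function(g) {
      iv <- do.call(rbind, piece_coords[g])
      data.frame(start = min(iv[, 1L]), end = max(iv[, 2L]))
    }))
    # CDS from transcript-coordinate marks
    mark <- if (!is.null(gs$cds)) gs$cds[[sfx]] else NULL
    exon_tx_len <- vapply(groups, function(g) sum(lens[g]), integer(1))
    cumx <- cumsum(c(0L, exon_tx_len))
    tx_pos_of <- function(piece, off_in_piece) {
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        if (piece %in% g) {
          before <- if (match(piece, g) > 1L)
            sum(lens[g[seq_len(match(piece, g) - 1L)]]) else 0L
          return(cumx[gi] + before + off_in_piece)
        }
      }
      stop("cds mark piece ", piece, " not in isoform ", sfx)
    }
    c1 <- if (is.null(mark)) 1L
      else tx_pos_of(mark$start[[1L]], as.integer(mark$start[[2L]]))
    c2 <- if (is.null(mark)) sum(exon_tx_len)
      else tx_pos_of(mark$end[[1L]], as.integer(mark$end[[2L]]))
    # project [c1, c2] through exons to genomic CDS segments
    cds_rows <- NULL
    exons_o <- exons[order(exons$start), , drop = FALSE]
    ord <- if (gs$strand == "+") order(exons$start) else order(-exons$start)
    m1 <- 1L
    for (gi in ord) {
      w <- exons$end[gi] - exons$start[gi] + 1L
      m2 <- m1 + w - 1L
      lo <- max(c1, m1); hi <- min(c2, m2)
      if (lo <= hi) {
        seg <- if (gs$strand == "+")
          c(exons$start[gi] + (lo - m1), exons$start[gi] + (hi - m1))
        else
          c(exons$end[gi] - (hi - m1), exons$end[gi] - (lo - m1))
        cds_rows <- rbind(cds_rows, seg)
      }
      m1 <- m2 + 1L
    }
    cds <- data.frame(start = cds_rows[, 1L], end = cds_rows[, 2L])
    txs[[paste0(gs$gene_id, ".", sfx)]] <- list(
      transcript_id = paste0(gs$gene_id, ".", sfx), gene_id = gs$gene_id,
      chrom = chrom, strand = gs$strand, exons = exons_o,
      cds = cds[order(cds$start), , drop = FALSE])
  }
  list(seq = gseq, length = total, transcripts = txs,
       piece_coords = piece_coords)
}

.default_gene_specs <- function(spec) {
  n_iso <- spec$n_isoforms
  if (any(spec$types %in% c("RI", "SE", "A5", "A3", "AF", "AL", "MX")) &&
      n_iso < 2L)
    stop("infeasible fixture spec: AS event types need >= 2 isoforms")
  g <- list()
  if ("RI" %in% spec$types)
    g$GRI1 <- .gene_spec("GRI1", "+",
      pieces = list(e1 = paste0("ATG", .rcodons(29)), i1 = .rcodons(27),
                    e2 = .rcodons(30), i2 = .rnt(70),
                    e3 = paste0(.rcodons(29), "TAA")),
      isoforms = list(`1` = list("e1", "e2", "e3"),
                      `2` = list(c("e1", "i1", "e2"), "e3")))
  if ("A3" %in% spec$types)
    g$GA31 <- .gene_spec("GA31", "+",
      pieces = list(e1 = paste0("ATG", .rcodons(23)), i1 = .rnt(58),
                    q = "CAG", e2 = paste0(.rcodons(24), "TAA")),
      isoforms = list(`1` = list("e1", c("q", "e2")),
                      `2` = list("e1", "e2")))
  if ("A5" %in% spec$types)
    g$GA51 <- .gene_spec("GA51", "+",
      pieces = list(e1 = paste0("ATG", .rcodons(23)), x = .rcodons(2),
                    i1 = .rnt(65), e2 = paste0(.rcodons(19), "TAA")),
      isoforms = list(`1` = list(c("e1", "x"), "e2"),
                      `2` = list("e1", "e2")))
  if ("AF" %in% spec$types)
    g$GAF1 <- .gene_spec("GAF1", "+",
      pieces = list(a1 = paste0("ATG", .rcodons(14)), iA = .rnt(50),
                    a2 = paste0("ATG", .rcodons(17)), iB = .rnt(55),
                    e2 = .rcodons(30), i2 = .rnt(48),
                    e3 = paste0(.rcodons(14), "TAA")),
      isoforms = list(`1` = list("a1", "e2", "e3"),
                      `2` = list("a2", "e2", "e3")))
  if ("MX" %in% spec$types)
    g$GMX1 <- .gene_spec("GMX1", "+",
      pieces = list(e1 = paste0("ATG", .rcodons(19)), i1 = .rnt(45),
                    x1 = .rcodons(12), i2 = .rnt(40), x2 = .rcodons(15),
                    i3 = .rnt(45), e3 = paste0(.rcodons(19), "TAA")),
      isoforms = list(`1` = list("e1", "x1", "e3"),
                      `2` = list("e1", "x2", "e3")))
  if (isTRUE(spec$with_ir_genes)) {
    g$GIRA1 <- .gene_spec("GIRA1", "+",
      pieces = list(e1 = paste0("ATG", .rcodons(29)), i1 = .rcodons(27),
                    e2 = paste0(.rcodons(29), "TAA")),
      isoforms = list(`1` = list("e1", "e2")))
    g$GIRB1 <- .gene_spec("GIRB1", "+",
      pieces = list(e1 = paste0("ATG", .rcodons(29)),
                    i1 = paste0(.rcodons(4), "TAA", .rnt(30)),
                    e2 = paste0(.rcodons(29), "TAA")),
      isoforms = list(`1` = list("e1", "e2")))
  }
  if (isTRUE(spec$with_utr_gene))
    g$GUTR1 <- .gene_spec("GUTR1", "+",
      pieces = list(u1 = .rnt(60), i1 = .rnt(50),
                    e2 = paste0(.rnt(9), "ATG", .rcodons(20)),
                    i2 = .rnt(40),
                    e3 = paste0(.rcodons(20), "TAA", .rnt(12)),
                    i3 = .rnt(45), e4 = .rnt(30)),
      isoforms = list(`1` = list("u1", "e2", "e3", "e4"),
                      `2` = list(c("u1", "i1", "e2"), "e3", "e4")),
      cds = list(`1` = list(start = list("e2", 10L), end = list("e3", 63L)),
                 `2` = list(start = list("e2", 10L), end = list("e3", 63L))))
  g
}

.default_gene_specs2 <- function(spec) {
  g <- list()
  if ("SE" %in% spec$types)
    g$GSE1 <- .gene_spec("GSE1", "-",
      pieces = list(e1 = paste0("ATG", .rcodons(19)), i1 = .rnt(50),
                    e2 = .rcodons(12), i2 = .rnt(55),
                    e3 = paste0(.rcodons(19), "TAA")),
      isoforms = list(`1` = list("e1", "e2", "e3"),
                      `2` = list("e1", "e3")))
  if ("AL" %in% spec$types)
    g$GAL1 <- .gene_spec("GAL1", "-",
      pieces = list(e1 = paste0("ATG", .rcodons(29)), i1 = .rnt(50),
                    z1 = paste0(.rcodons(19), "TAA"), i2 = .rnt(40),
                    z2 = paste0(.rcodons(24), "TAA")),
      isoforms = list(`1` = list("e1", "z1"),
                      `2` = list("e1", "z2")))
  if (isTRUE(spec$with_single_isoform))
    g$GSGL1 <- .gene_spec("GSGL1", "+",
      pieces = list(e1 = paste0("ATGGCTGCTGTTCTTGATTCTCTTAGA",
                                .rcodons(20)),
                    i1 = .rnt(44), e2 = paste0(.rcodons(19), "TAA")),
      isoforms = list(`1` = list("e1", "e2")))
  if (isTRUE(spec$with_ir_genes))
    g$GIRC1 <- .gene_spec("GIRC1", "-",
      pieces = list(e1 = paste0("ATG", strrep("GCA", 29)),
                    i1 = paste0(strrep("GCA", 26), "GC"),
                    e2 = paste0(strrep("GCA", 19), "TAA")),
      isoforms = list(`1` = list("e1", "e2")))
  if (isTRUE(spec$with_duplicate_pair)) {
    shared <- "GCTGATTTCGAATGGGCTTCAGAGGTTCACAAG"   # ADFEWASEVHK
    g$GDUP1 <- .gene_spec("GDUP1", "+",
      pieces = list(e1 = paste0("ATG", .rcodons(10), "AAG", shared,
                                .rcodons(12), "TAA")),
      isoforms = list(`1` = list("e1")))
    g$GDUP2 <- .gene_spec("GDUP2", "+",
      pieces = list(e1 = paste0("ATG", .rcodons(14), "AGA", shared,
                                .rcodons(8), "TAA")),
      isoforms = list(`1` = list("e1")))
  }
  g
}

#' Generate the fixture genome, annotation, and ground-truth manifest
#'
#' Deterministic under \code{seed}: regenerating with the same seed and
#' spec reproduces byte-identical files.
#'
#' @param spec fixture spec from [default_fixture_spec()].
#' @param seed integer seed for the codon filler.
#' @param dir optional output directory; when given, writes
#'   \code{genome.fa}, \code{annotation.gff3}, \code{proteins.fa} and
#'   \code{manifest.json}.
#' @return list with genome (named character), transcripts (list of
#'   \code{transcript_model}s), proteins (named character), manifest
#'   (ground-truth list), and the written paths (when \code{dir} given).
#' @export
make_genome_and_annotation <- function(spec = default_fixture_spec(),
                                       seed = 42L, dir = NULL) {
  set.seed(seed)
  chrom_specs <- list(toyChr1 = .default_gene_specs(spec),
                      toyChr2 = .default_gene_specs2(spec))
  genome <- character(0)
  placed <- list()
  for (chrom in names(chrom_specs)) {
    off <- 0L
    seqparts <- character(0)
    for (gs in chrom_specs[[chrom]]) {
      gap <- .rnt(spec$intergenic)
      seqparts <- c(seqparts, gap)
      off <- off + nchar(gap)
      pg <- .place_gene(gs, chrom, off)
      seqparts <- c(seqparts, pg$seq)
      off <- off + pg$length
      placed[[gs$gene_id]] <- pg
    }
    seqparts <- c(seqparts, .rnt(spec$intergenic))
    genome[[chrom]] <- paste(seqparts, collapse = "")
  }
  raw_txs <- unlist(lapply(placed, `[[`, "transcripts"), recursive = FALSE)
  names(raw_txs) <- vapply(raw_txs, `[[`, "", "transcript_id")
  transcripts <- lapply(raw_txs, function(t)
    transcript_model(t$transcript_id, t$gene_id, t$chrom, t$strand,
                     t$exons, t$cds, genome))
  proteins <- vapply(transcripts, `[[`, "", "protein")
  manifest <- .fixture_manifest(spec, seed, placed, transcripts)
  out <- list(genome = genome, transcripts = transcripts,
              proteins = proteins, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "annotation.gff3"),
                  proteins = file.path(dir, "proteins.fa"),
                  manifest = file.path(dir, "manifest.json"))
    .write_fasta(genome, paths$genome)
    writeLines(.gff3_lines(transcripts), paths$gff3)
    write_protein_fasta(transcripts, paths$proteins)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}

.write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.gff3_lines <- function(transcripts) {
  lines <- "##gff-version 3"
  by_gene <- transcripts_by_gene(transcripts)
  for (gid in names(by_gene)) {
    txs <- by_gene[[gid]]
    gstart <- min(vapply(txs, function(t) min(t$exons$start), integer(1)))
    gend <- max(vapply(txs, function(t) max(t$exons$end), integer(1)))
    t1 <- txs[[1L]]
    lines <- c(lines, paste(t1$chrom, "pgsplice", "gene", gstart, gend, ".",
                            t1$strand, ".", paste0("ID=", gid), sep = "\t"))
    for (tm in txs) {
      lines <- c(lines, paste(
        tm$chrom, "pgsplice", "mRNA", min(tm$exons$start), max(tm$exons$end),
        ".", tm$strand, ".",
        paste0("ID=", tm$transcript_id, ";Parent=", gid), sep = "\t"))
      for (k in seq_len(nrow(tm$exons)))
        lines <- c(lines, paste(
          tm$chrom, "pgsplice", "exon", tm$exons$start[k], tm$exons$end[k],
          ".", tm$strand, ".", paste0("Parent=", tm$transcript_id),
          sep = "\t"))
      segs <- tm$cds
      ord <- if (tm$strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
      phase <- 0L
      for (k in ord) {
        lines <- c(lines, paste(
          tm$chrom, "pgsplice", "CDS", segs$start[k], segs$end[k], ".",
          tm$strand, phase, paste0("Parent=", tm$transcript_id), sep = "\t"))
        phase <- (3L - ((segs$end[k] - segs$start[k] + 1L - phase) %% 3L)) %% 3L
      }
    }
  }
  lines
}

.piece_iv <- function(placed, gene, piece) {
  iv <- unname(placed[[gene]]$piece_coords[[piece]])
  list(start = iv[1L], end = iv[2L])
}

.fixture_manifest <- function(spec, seed, placed, transcripts) {
  proteins <- vapply(transcripts, `[[`, "", "protein")
  pep <- function(tx, from, to) substr(proteins[[tx]], from, to)
  events <- list(); planted <- list(); ir <- list()

  add_event <- function(type, gene, piece, label) {
    iv <- .piece_iv(placed, gene, piece)
    events[[length(events) + 1L]] <<- list(
      event_type = type, gene_id = gene,
      disc_start = iv$start, disc_end = iv$end, region_label = label)
  }
  plant <- function(gene, type, form, tx, from, to) {
    planted[[length(planted) + 1L]] <<- list(
      peptide = pep(tx, from, to), isoform = tx, gene_id = gene,
      event_type = type, form = form)
  }

  if (!is.null(placed$GRI1)) {
    add_event("RI", "GRI1", "i1", "CDS")
    plant("GRI1", "RI", "inclusion", "GRI1.2", 33L, 47L)  # inside intron
    plant("GRI1", "RI", "exclusion", "GRI1.1", 27L, 36L)  # e1-e2 junction
  }
  if (!is.null(placed$GSE1)) {
    add_event("SE", "GSE1", "e2", "CDS")
    plant("GSE1", "SE", "inclusion", "GSE1.1", 17L, 26L)  # e1-e2 junction
    plant("GSE1", "SE", "exclusion", "GSE1.2", 17L, 26L)  # e1-e3 junction
  }
  if (!is.null(placed$GA31)) {
    add_event("A3", "GA31", "q", "CDS")
    plant("GA31", "A3", "inclusion", "GA31.1", 20L, 30L)  # covers the extra Q
    plant("GA31", "A3", "exclusion", "GA31.2", 20L, 30L)
  }
  if (!is.null(placed$GA51)) {
    add_event("A5", "GA51", "x", "CDS")
    plant("GA51", "A5", "inclusion", "GA51.1", 20L, 28L)
    plant("GA51", "A5", "exclusion", "GA51.2", 20L, 28L)
  }
  if (!is.null(placed$GAF1)) {
    add_event("AF", "GAF1", "a1", "CDS")
    plant("GAF1", "AF", "inclusion", "GAF1.1", 3L, 12L)   # inside alt exon a1
    plant("GAF1", "AF", "exclusion", "GAF1.2", 3L, 12L)   # inside alt exon a2
  }
  if (!is.null(placed$GAL1)) {
    add_event("AL", "GAL1", "z2", "CDS")  # inclusion = genomically first exon
    plant("GAL1", "AL", "exclusion", "GAL1.1", 31L, 40L)  # inside z1
    plant("GAL1", "AL", "inclusion", "GAL1.2", 31L, 40L)  # inside z2
  }
  if (!is.null(placed$GMX1)) {
    add_event("MX", "GMX1", "x1", "CDS")
    plant("GMX1", "MX", "inclusion", "GMX1.1", 17L, 26L)  # e1-x1 junction
    plant("GMX1", "MX", "exclusion", "GMX1.2", 17L, 26L)  # e1-x2 junction
  }
  if (!is.null(placed$GUTR1))
    add_event("RI", "GUTR1", "i1", "UTR")

  add_ir <- function(gene, piece, outcome, delta) {
    iv <- .piece_iv(placed, gene, piece)
    ir[[length(ir) + 1L]] <<- list(
      gene_id = gene, start = iv$start, end = iv$end,
      outcome = outcome, delta_length_aa = delta)
  }
  if (!is.null(placed$GIRA1)) add_ir("GIRA1", "i1", "extended_in_frame", 27L)
  if (!is.null(placed$GIRB1)) add_ir("GIRB1", "i1", "truncated", 34L - 59L)
  if (!is.null(placed$GIRC1)) add_ir("GIRC1", "i1", "frameshift_extended", 27L)

  # coverage targets: IDratio per intron per group (others default low)
  cov <- list(
    list(gene = "GRI1", piece = "i1", WT = 0.30, mut = 0.30),
    list(gene = "GIRA1", piece = "i1", WT = 0.30, mut = 0.30),
    list(gene = "GIRB1", piece = "i1", WT = 0.05, mut = 0.20),
    list(gene = "GIRC1", piece = "i1", WT = 0.16, mut = 0.16),
    list(gene = "GSGL1", piece = "i1", WT = 0.15, mut = 0.15),
    list(gene = "GUTR1", piece = "i1", WT = 0.04, mut = 0.25),
    list(gene = "GUTR1", piece = "i3", WT = 0.05, mut = 0.18))
  cov <- Filter(function(x) !is.null(placed[[x$gene]]), cov)
  depth_targets <- data.table::rbindlist(lapply(cov, function(x) {
    iv <- .piece_iv(placed, x$gene, x$piece)
    data.table::data.table(gene_id = x$gene, start = iv$start, end = iv$end,
                           WT = x$WT, mut = x$mut)
  }))

  exists_ <- function(g) !is.null(placed[[g]])
  expected_candidates <- Filter(Negate(is.null), list(
    if (exists_("GIRA1")) c("GIRA1", "i1"), if (exists_("GIRB1")) c("GIRB1", "i1"),
    if (exists_("GIRC1")) c("GIRC1", "i1"), if (exists_("GSGL1")) c("GSGL1", "i1"),
    if (exists_("GUTR1")) c("GUTR1", "i3")))
  expected_candidates <- lapply(expected_candidates, function(x) {
    iv <- .piece_iv(placed, x[1L], x[2L])
    list(gene_id = x[1L], start = iv$start, end = iv$end)
  })
  expected_iir <- Filter(Negate(is.null), list(
    if (exists_("GIRB1")) list(gene = "GIRB1", piece = "i1", region = "CDS"),
    if (exists_("GUTR1")) list(gene = "GUTR1", piece = "i1", region = "5UTR"),
    if (exists_("GUTR1")) list(gene = "GUTR1", piece = "i3", region = "3UTR")))
  expected_iir <- lapply(expected_iir, function(x) {
    iv <- .piece_iv(placed, x$gene, x$piece)
    list(gene_id = x$gene, start = iv$start, end = iv$end, region = x$region)
  })

  category_examples <- Filter(Negate(is.null), list(
    if (exists_("GRI1")) list(peptide = pep("GRI1.2", 33L, 47L),
                              category = "isoform_specific"),
    if (exists_("GRI1")) list(peptide = pep("GRI1.1", 75L, 85L),
                              category = "shared_all_isoforms"),
    if (exists_("GDUP1")) list(peptide = "ADFEWASEVHK",
                               category = "multi_gene"),
    if (exists_("GSGL1")) list(peptide = pep("GSGL1.1", 32L, 42L),
                               category = "single_isoform_gene")))

  list(seed = seed, spec = spec[c("types", "n_isoforms")],
       expected_events = events, planted_peptides = planted,
       expected_ir_outcomes = ir, depth_targets = depth_targets,
       expected_candidates = expected_candidates,
       expected_iir = expected_iir,
       category_examples = category_examples,
       met_loss = if (exists_("GSGL1"))
         list(peptide = "AAVLDSLR", accession = "GSGL1.1") else NULL)
}

# -- peptide tables ---------------------------------------------------------

#' Digest fixture proteins and emit engine-style peptide tables
#'
#' All trypsin (engine "prospector" and "msfragger") and AspN (engine
#' "prospector" only) peptides within the length bounds are emitted, plus
#' the manifest's planted event-support peptides, one N-terminal-Met-loss
#' peptide, and reversed-sequence decoy rows at the requested fraction.
#' Accessions are assigned by exhaustive substring search over the
#' protein database (ground truth), so engine claims are always
#' verifiable.
#'
#' @param proteins named character vector of protein sequences.
#' @param manifest fixture manifest (for planted peptides), or NULL.
#' @param decoy_fraction fraction of decoy rows to add (default 0.1).
#' @param min_length,max_length peptide length bounds (defaults 7, 30).
#' @param seed integer seed (decoy sampling).
#' @return list of two data.frames, \code{prospector} and
#'   \code{msfragger}, in their respective column dialects.
#' @export
digest_and_sample_peptides <- function(proteins, manifest = NULL,
                                       decoy_fraction = 0.1,
                                       min_length = 7L, max_length = 30L,
                                       seed = 42L) {
  set.seed(seed + 1L)
  tryp <- unique(unlist(lapply(proteins, function(p)
    digest_protein(p, "trypsin", missed = 1L, min_length = min_length,
                   max_length = max_length)$peptide)))
  aspn <- unique(unlist(lapply(proteins, function(p)
    digest_protein(p, "aspn", missed = 1L, min_length = min_length,
                   max_length = max_length)$peptide)))
  planted <- if (!is.null(manifest))
    c(vapply(manifest$planted_peptides, `[[`, "", "peptide"),
      vapply(manifest$category_examples, `[[`, "", "peptide"))
  else character(0)

  match_accs <- function(pep) {
    hit <- names(proteins)[vapply(proteins, function(p)
      grepl(pep, p, fixed = TRUE), logical(1))]
    metloss <- names(proteins)[vapply(proteins, function(p)
      startsWith(p, "M") && substr(p, 2L, nchar(pep) + 1L) == pep,
      logical(1))]
    sort(unique(c(hit, metloss)))
  }

  build <- function(peps) {
    peps <- unique(peps)
    accs <- lapply(peps, match_accs)
    keep <- vapply(accs, length, integer(1)) > 0L
    data.frame(peptide = peps[keep],
               accs = vapply(accs[keep], paste, "", collapse = "\x01"))
  }
  prosp <- build(c(tryp, aspn, planted,
                   if (!is.null(manifest$met_loss)) manifest$met_loss$peptide))
  frag <- build(c(tryp,
                  if (!is.null(manifest$met_loss)) manifest$met_loss$peptide))

  add_decoys <- function(df, prefix) {
    n_dec <- round(decoy_fraction * nrow(df))
    if (n_dec == 0L) return(df)
    pick <- sample.int(nrow(df), n_dec)
    dec <- df[pick, , drop = FALSE]
    dec$peptide <- vapply(strsplit(dec$peptide, NULL), function(s)
      paste(rev(s), collapse = ""), "")
    dec$accs <- vapply(strsplit(dec$accs, "\x01", fixed = TRUE), function(a)
      paste(paste0(prefix, a), collapse = "\x01"), "")
    # a reversed sequence could coincide with a real peptide; drop those
    dec <- dec[!dec$peptide %in% df$peptide, , drop = FALSE]
    rbind(df, dec)
  }
  prosp <- add_decoys(prosp, "DECOY_")
  frag <- add_decoys(frag, "rev_")

  # dress one Met-containing row with a modification annotation
  mod_idx <- which(grepl("M", prosp$peptide, fixed = TRUE) &
                     !startsWith(prosp$peptide, "M"))[1L]
  if (!is.na(mod_idx))
    prosp$peptide[mod_idx] <- sub("M", "M(ox)", prosp$peptide[mod_idx])

  prospector <- data.frame(
    `DB.Peptide` = prosp$peptide,
    `Acc..` = gsub("\x01", ";", prosp$accs, fixed = TRUE),
    check.names = FALSE)
  msfragger <- data.frame(
    Peptide = frag$peptide,
    `Mapped.Proteins` = gsub("\x01", ",", frag$accs, fixed = TRUE),
    check.names = FALSE)
  list(prospector = prospector, msfragger = msfragger)
}

# -- coverage ---------------------------------------------------------------

#' Emit a region-depth table realizing target IDratios
#'
#' Every unique exon and intron interval of the annotation receives a
#' per-sample mean depth. Exons get the group's baseline depth; each
#' intron's depth is set so its IDratio (computed with the terminal-exon
#' rule) equals the target for its group, default 0.02 where no target is
#' given. Multiplicative Gaussian noise of relative SD \code{noise_sd}
#' is applied per replicate (default 0: exact recovery).
#'
#' @param transcripts named list of \code{transcript_model}s.
#' @param depth_targets data.table(gene_id, start, end, WT, mut) of
#'   target IDratios (e.g. \code{manifest$depth_targets}).
#' @param replicates named integer vector, samples per group.
#' @param exon_depth named numeric vector, baseline exon depth per group.
#' @param default_ratio IDratio for untargeted introns.
#' @param noise_sd relative (fractional) noise SD.
#' @param seed integer seed.
#' @return data.table(chrom, start, end, sample_id, group, mean_depth).
#' @export
make_coverage <- function(transcripts, depth_targets,
                          replicates = c(WT = 4L, mut = 4L),
                          exon_depth = c(WT = 100, mut = 80),
                          default_ratio = 0.02, noise_sd = 0,
                          seed = 42L) {
  set.seed(seed + 2L)
  inv <- gene_intron_inventory(transcripts)
  exon_iv <- unique(data.table::rbindlist(lapply(transcripts, function(t)
    data.table::data.table(chrom = t$chrom, start = t$exons$start,
                           end = t$exons$end))))
  noise <- function(n) if (noise_sd > 0)
    pmax(0.01, 1 + stats::rnorm(n, 0, noise_sd)) else rep(1, n)
  rows <- list()
  for (grp in names(replicates)) {
    for (r in seq_len(replicates[[grp]])) {
      sid <- sprintf("%s_%d", grp, r)
      ex_depth <- exon_depth[[grp]] * noise(nrow(exon_iv))
      ex <- data.table::data.table(exon_iv, sample_id = sid, group = grp,
                                   mean_depth = ex_depth)
      dmap <- stats::setNames(ex_depth, paste(exon_iv$chrom, exon_iv$start,
                                              exon_iv$end, sep = ":"))
      intr <- data.table::copy(inv)
      target <- rep(default_ratio, nrow(intr))
      if (!is.null(depth_targets) && nrow(depth_targets)) {
        m <- match(paste(intr$gene_id, intr$start, intr$end),
                   paste(depth_targets$gene_id, depth_targets$start,
                         depth_targets$end))
        hit <- !is.na(m)
        target[hit] <- depth_targets[[grp]][m[hit]]
      }
      flank <- vapply(seq_len(nrow(intr)), function(k) {
        iv <- intr[k]
        d5 <- dmap[[paste(iv$chrom, iv$five_start, iv$five_end, sep = ":")]]
        d3 <- dmap[[paste(iv$chrom, iv$three_start, iv$three_end, sep = ":")]]
        if (iv$is_first && iv$is_last) mean(c(d5, d3))
        else if (iv$is_first) d3 else if (iv$is_last) d5 else mean(c(d5, d3))
      }, numeric(1))
      it <- data.table::data.table(
        chrom = intr$chrom, start = intr$start, end = intr$end,
        sample_id = sid, group = grp,
        mean_depth = target * flank * noise(nrow(intr)))
      rows[[length(rows) + 1L]] <- ex
      rows[[length(rows) + 1L]] <- it
    }
  }
  data.table::rbindlist(rows)
}
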