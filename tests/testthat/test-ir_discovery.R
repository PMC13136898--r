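# one plus-strand 3-exon transcript: introns at 201-300 and 401-500
tm3 <- toy_tx("D.1", "D", cbind(c(101L, 301L, 501L), c(200L, 400L, 600L)))

depth_row <- function(start, end, depth, sample = "s1")
  data.frame(chrom = "chrT", start = start, end = end,
             sample_id = sample, mean_depth = depth)

test_that("compute_idratio divides by the mean flanking exon depth", {
  inv <- gene_intron_inventory(list(D.1 = tm3))
  depths <- rbind(depth_row(101L, 200L, 40), depth_row(301L, 400L, 40),
                  depth_row(501L, 600L, 60),
                  depth_row(201L, 300L, 6),    # first intron
                  depth_row(401L, 500L, 5))    # last intron
  rec <- compute_idratio(depths, inv)
  # first intron: only the 3' exon (depth 40) -> 6/40
  expect_equal(rec[rec$start == 201L, ]$idratio, 0.15, tolerance = 1e-12)
  # last intron: only the 5' exon (depth 40) -> 5/40
  expect_equal(rec[rec$start == 401L, ]$idratio, 0.125, tolerance = 1e-12)
  # internal example with both flanks: 5 / mean(40, 60) = 0.1
  tm2 <- toy_tx("E.1", "E",
                cbind(c(101L, 301L, 501L, 701L), c(200L, 400L, 600L, 800L)))
  inv2 <- gene_intron_inventory(list(E.1 = tm2))
  depths2 <- rbind(depth_row(101L, 200L, 10), depth_row(301L, 400L, 40),
                   depth_row(501L, 600L, 60), depth_row(701L, 800L, 10),
                   depth_row(201L, 300L, 1), depth_row(401L, 500L, 5),
                   depth_row(601L, 700L, 0))
  rec2 <- compute_idratio(depths2, inv2)
  expect_equal(rec2[rec2$start == 401L, ]$idratio, 0.1, tolerance = 1e-12)
  expect_equal(rec2[rec2$start == 601L, ]$idratio, 0)   # zero intron depth
})

test_that("terminal-intron rule is strand-aware", {
  tmm <- toy_tx("F.1", "F", cbind(c(101L, 301L, 501L), c(200L, 400L, 600L)),
                strand = "-")
  inv <- gene_intron_inventory(list(F.1 = tmm))
  # on minus strand the transcript-first intron is the genomically last one
  expect_true(inv[inv$start == 401L, ]$is_first)
  expect_true(inv[inv$start == 201L, ]$is_last)
  depths <- rbind(depth_row(101L, 200L, 10), depth_row(301L, 400L, 40),
                  depth_row(501L, 600L, 80),
                  depth_row(201L, 300L, 8), depth_row(401L, 500L, 8))
  rec <- compute_idratio(depths, inv)
  # first intron (401-500): 3' flank in transcript sense = exon 301-400
  expect_equal(rec[rec$start == 401L, ]$idratio, 0.2, tolerance = 1e-12)
  # last intron (201-300): 5' flank = exon 301-400
  expect_equal(rec[rec$start == 201L, ]$idratio, 0.2, tolerance = 1e-12)
})

test_that("idratio is invariant under uniform depth scaling (property)", {
  inv <- gene_intron_inventory(list(D.1 = tm3))
  set.seed(5)
  for (i in 1:10) {
    d <- runif(5, 1, 100)
    base <- rbind(depth_row(101L, 200L, d[1]), depth_row(301L, 400L, d[2]),
                  depth_row(501L, 600L, d[3]), depth_row(201L, 300L, d[4]),
                  depth_row(401L, 500L, d[5]))
    c_ <- runif(1, 0.1, 10)
    scaled <- base; scaled$mean_depth <- scaled$mean_depth * c_
    expect_equal(compute_idratio(base, inv)$idratio,
                 compute_idratio(scaled, inv)$idratio, tolerance = 1e-12)
  }
})

test_that("select_candidates: inclusive threshold, either-group rule, RI exclusion", {
  fx <- get_fixture()
  cov <- get_fixture_coverage()
  inv <- gene_intron_inventory(fx$transcripts)
  rec <- compute_idratio(cov, inv)
  groups <- stats::setNames(cov$group, cov$sample_id)
  ev <- generate_events(fx$transcripts)
  cand <- select_candidates(rec, ev, sample_groups = groups)
  got <- sort(paste(cand$gene_id, cand$start, cand$end))
  want <- sort(vapply(fx$manifest$expected_candidates, function(x)
    paste(x$gene_id, x$start, x$end), ""))
  expect_equal(got, want)
  # GSGL1 sits exactly at 0.15 and is selected (inclusive >=)
  expect_true("GSGL1" %in% cand$gene_id)
  # GIRB1 passes only in the mutant group ("in either" semantics)
  expect_true("GIRB1" %in% cand$gene_id)
  # annotated RI introns (GRI1 i1, GUTR1 i1) are excluded despite high ratios
  expect_false("GRI1" %in% cand$gene_id)
  # threshold monotonicity: higher cutoff never adds introns
  for (thr in c(0.16, 0.2, 0.31)) {
    sub <- select_candidates(rec, ev, threshold = thr,
                             sample_groups = groups)
    expect_true(all(paste(sub$gene_id, sub$start) %in%
                      paste(cand$gene_id, cand$start)), info = thr)
  }
})

test_that("fit_intron_to_transcripts requires exact abutment", {
  fits <- fit_intron_to_transcripts(
    list(chrom = "chrT", start = 201L, end = 300L), list(tm3))
  expect_equal(fits$mode, "internal")
  # a 1-nt gap breaks the fit
  expect_equal(nrow(fit_intron_to_transcripts(
    list(chrom = "chrT", start = 202L, end = 300L), list(tm3))), 0L)
  # terminal fits are flagged with their mode
  up <- fit_intron_to_transcripts(
    list(chrom = "chrT", start = 51L, end = 100L), list(tm3))
  expect_equal(up$mode, "upstream")
  dn <- fit_intron_to_transcripts(
    list(chrom = "chrT", start = 601L, end = 650L), list(tm3))
  expect_equal(dn$mode, "downstream")
})

test_that("build_ir_protein reproduces the three designed outcomes", {
  fx <- get_fixture()
  by_gene <- transcripts_by_gene(fx$transcripts)
  for (want in fx$manifest$expected_ir_outcomes) {
    tm <- by_gene[[want$gene_id]][[1L]]
    e <- build_ir_protein(tm, list(chrom = tm$chrom, start = want$start,
                                   end = want$end), fx$genome)
    expect_equal(e$outcome, want$outcome, info = want$gene_id)
    expect_equal(e$delta_length_aa, want$delta_length_aa,
                 info = want$gene_id)
    expect_false(grepl("*", e$protein_sequence, fixed = TRUE))
    # independent splice-aware re-translation from raw genome coordinates
    ex <- tm$exons
    lo <- min(ex$start); hi <- max(ex$end)
    nt <- substring(fx$genome[[tm$chrom]], lo, hi)  # retained: contiguous
    aa <- oracle_translate(nt, tm$strand)
    cds_off <- if (tm$strand == "+") min(tm$cds$start) - lo
               else hi - max(tm$cds$end)
    nt_cds <- if (tm$strand == "+")
      substring(fx$genome[[tm$chrom]], min(tm$cds$start), hi)
    else substring(fx$genome[[tm$chrom]], lo, max(tm$cds$end))
    expect_equal(e$protein_sequence, oracle_translate(nt_cds, tm$strand),
                 info = want$gene_id)
  }
  # frame-preserving stop-free intron: delta == length/3 exactly
  ira <- fx$manifest$expected_ir_outcomes[[1L]]
  expect_equal(ira$delta_length_aa, (ira$end - ira$start + 1L) %/% 3L)
})

test_that("early-stop intron yields upstream CDS plus four intronic residues", {
  fx <- get_fixture()
  irb <- Filter(function(x) x$gene_id == "GIRB1",
                fx$manifest$expected_ir_outcomes)[[1L]]
  tm <- fx$transcripts[["GIRB1.1"]]
  e <- build_ir_protein(tm, list(chrom = tm$chrom, start = irb$start,
                                 end = irb$end), fx$genome)
  expect_equal(nchar(e$protein_sequence), 34L)
  expect_equal(substr(e$protein_sequence, 1L, 30L),
               substr(tm$protein, 1L, 30L))
  # residues 31-34 are the intron's first four codons
  intron_nt <- substring(fx$genome[[tm$chrom]], irb$start, irb$start + 11L)
  expect_equal(substr(e$protein_sequence, 31L, 34L),
               oracle_translate(intron_nt))
})

test_that("write_custom_database appends, dedups, and copies byte-identically", {
  fx <- get_fixture()
  dir <- withr::local_tempdir()
  base <- file.path(dir, "base.fa")
  write_protein_fasta(fx$transcripts[1:10], base)
  cov <- get_fixture_coverage()
  inv <- gene_intron_inventory(fx$transcripts)
  rec <- compute_idratio(cov, inv)
  cand <- select_candidates(rec, generate_events(fx$transcripts),
                            sample_groups = stats::setNames(cov$group,
                                                            cov$sample_id))
  entries <- build_ir_entries(cand, fx$transcripts, fx$genome)
  out <- file.path(dir, "custom.fa")
  n <- write_custom_database(base, entries[1:2], out)
  expect_equal(n, 2L)
  expect_length(read_protein_fasta(out), 12L)
  # empty entry set: byte-identical copy
  out2 <- file.path(dir, "copy.fa")
  write_custom_database(base, list(), out2)
  expect_equal(unname(tools::md5sum(base)), unname(tools::md5sum(out2)))
  # duplicate sequence dropped with a message
  dup <- entries[[1L]]
  dup$accession <- "DUP_TEST.1_IR9"
  dup$protein_sequence <- fx$transcripts[[1L]]$protein
  expect_message(n2 <- write_custom_database(base, list(dup),
                                             file.path(dir, "d.fa")),
                 "dropped")
  expect_equal(n2, 0L)
  # accession collision is a hard error
  bad <- entries[[1L]]
  bad$accession <- names(read_protein_fasta(base))[1L]
  expect_error(write_custom_database(base, list(bad),
                                     file.path(dir, "c.fa")), "collision")
})

test_that("summarize_outcomes tallies truncated fractions per set", {
  mk <- function(outcome) structure(list(outcome = outcome),
                                    class = "custom_protein_entry")
  entries <- lapply(c("truncated", "truncated", "truncated",
                      "extended_in_frame"), mk)
  smry <- summarize_outcomes(entries, "unannotated")
  expect_equal(smry$frac_truncated, 0.75)
  expect_equal(nrow(summarize_outcomes(list())), 0L)
  smry2 <- summarize_outcomes(lapply(rep("extended_in_frame", 3), mk))
  expect_equal(smry2$frac_truncated, 0)
})
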