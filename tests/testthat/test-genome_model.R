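test_that("translate_cds follows the standard code with stop/strand rules", {
  expect_equal(as.character(translate_cds("ATGGCTTAA", "+")), "MA")
  expect_equal(as.character(translate_cds("TTAAGCCAT", "-")), "MA")
  # stop terminates translation, not emitted
  expect_equal(as.character(translate_cds("ATGTAAGCT", "+")), "M")
  # codon containing N renders X
  expect_equal(as.character(translate_cds("ATGGNTGCT", "+")), "MXA")
  # trailing partial codon dropped with flag
  out <- translate_cds("ATGGCTTA", "+")
  expect_equal(as.character(out), "MA")
  expect_true(attr(out, "partial"))
  out2 <- translate_cds("ATGGCTTAA", "+")
  expect_false(attr(out2, "partial"))
  expect_error(translate_cds("", "+"), "empty")
  expect_error(translate_cds("ATGU", "+"), "outside")
})

test_that("translate_cds minus strand equals plus strand of revcomp (property)", {
  set.seed(7)
  for (i in 1:25) {
    x <- paste(sample(c("A", "C", "G", "T"), sample(3:60, 1),
                      replace = TRUE), collapse = "")
    expect_equal(as.character(translate_cds(reverse_complement(x), "-")),
                 as.character(translate_cds(x, "+")))
    expect_equal(as.character(translate_cds(x, "+")), oracle_translate(x))
  }
})

test_that("enumerate_introns numbers plus-strand ascending, minus display descending", {
  ex <- cbind(c(101L, 301L, 501L), c(200L, 400L, 600L))
  tp <- toy_tx("G.1", "G", ex)
  intr <- enumerate_introns(tp)
  expect_equal(intr$start, c(201L, 401L))
  expect_equal(intr$end, c(300L, 500L))
  expect_equal(intr$plus_strand_index, 1:2)
  expect_equal(intr$display_index, 1:2)
  tm <- toy_tx("G.2", "G", ex, strand = "-")
  intr2 <- enumerate_introns(tm)
  expect_equal(intr2$plus_strand_index, 1:2)
  expect_equal(intr2$display_index, 2:1)
  expect_equal(nrow(enumerate_introns(toy_tx("G.3", "G", cbind(1L, 50L)))), 0L)
})

test_that("read_annotation parses GFF3, translates CDS, and rejects bad CDS", {
  dir <- withr::local_tempdir()
  genome <- c(chr1 = paste0(strrep("T", 100),
                            "ATGGCTGCTGCTGCTGCTGCTGCTGCTTAA",  # 10 codons
                            strrep("C", 50)))
  gfa <- file.path(dir, "g.fa")
  writeLines(c(">chr1", genome[["chr1"]]), gfa)
  gff <- file.path(dir, "a.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t130\t.\t+\t.\tID=G1",
    "chr1\tx\tmRNA\t101\t130\t.\t+\t.\tID=G1.1;Parent=G1",
    "chr1\tx\texon\t101\t130\t.\t+\t.\tParent=G1.1",
    "chr1\tx\tCDS\t101\t130\t.\t+\t0\tParent=G1.1",
    "chr1\tx\tmRNA\t101\t127\t.\t+\t.\tID=G1.2;Parent=G1",
    "chr1\tx\texon\t101\t127\t.\t+\t.\tParent=G1.2",
    "chr1\tx\tCDS\t101\t127\t.\t+\t0\tParent=G1.2"), gff)
  txs <- read_annotation(gff, read_genome(gfa))
  expect_length(txs, 2L)
  expect_equal(unique(vapply(txs, `[[`, "", "gene_id")), "G1")
  # 30 nt CDS whose final codon is a stop -> 9 aa; 33 nt variant below
  expect_equal(txs[["G1.1"]]$protein, "MAAAAAAAA")
  # CDS outside exon space is a hard error naming the transcript
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t130\t.\t+\t.\tID=G1",
    "chr1\tx\tmRNA\t101\t130\t.\t+\t.\tID=G1.1;Parent=G1",
    "chr1\tx\texon\t101\t120\t.\t+\t.\tParent=G1.1",
    "chr1\tx\tCDS\t101\t130\t.\t+\t0\tParent=G1.1"),
    file.path(dir, "bad.gff3"))
  expect_error(read_annotation(file.path(dir, "bad.gff3"),
                               read_genome(gfa)), "G1.1")
})

test_that("mRNA with 33 nt CDS ending in stop yields 10 aa", {
  genome <- c(c1 = paste0("ATG", strrep("GCT", 10), "TAA"))  # 36 nt
  tm <- transcript_model("T.1", "T", "c1", "+",
                         data.frame(start = 1L, end = 36L),
                         data.frame(start = 1L, end = 33L), genome)
  # 33 nt, no stop inside: translated fully, 11 aa, flagged non-multiple? no:
  expect_equal(nchar(tm$protein), 11L)
  tm2 <- transcript_model("T.2", "T", "c1", "+",
                          data.frame(start = 1L, end = 36L),
                          data.frame(start = 4L, end = 36L), genome)
  # 33 nt whose final codon is the stop -> 10 aa
  expect_equal(nchar(tm2$protein), 10L)
})

test_that("fixture round-trip: protein equals oracle translation of spliced CDS", {
  fx <- get_fixture()
  for (tm in fx$transcripts) {
    nt <- cds_nt_sequence(tm, fx$genome)
    expect_equal(tm$protein, oracle_translate(nt, tm$strand),
                 info = tm$transcript_id)
    # exon + intron lengths partition the genomic span
    intr <- enumerate_introns(tm)
    span <- max(tm$exons$end) - min(tm$exons$start) + 1L
    expect_equal(sum(tm$exons$end - tm$exons$start + 1L) +
                   sum(intr$end - intr$start + 1L), span,
                 info = tm$transcript_id)
  }
})

test_that("81-nt stop-free in-frame insert lengthens the protein by 27 aa", {
  fx <- get_fixture()
  expect_equal(nchar(fx$proteins[["GRI1.2"]]) - nchar(fx$proteins[["GRI1.1"]]),
               27L)
})
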