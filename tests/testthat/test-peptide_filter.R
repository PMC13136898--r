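proteins_toy <- c(
  "P1.1" = "MKPEPTIDEKAVLSTR",
  "P1.2" = "MKPEPTIDEKSSS",
  "P2.1" = "MAVLKWWEEK")

test_that("ingest merges engines, strips modifications, removes decoys", {
  t1 <- data.frame(`DB.Peptide` = c("PEPTIDEK", "AVLS(ph)TR", "EDITPEP"),
                   `Acc..` = c("P1.1;P1.2", "P1.1", "DECOY_P1.1"),
                   check.names = FALSE)
  t2 <- data.frame(Peptide = c("PEPTIDEK"), `Mapped.Proteins` = c("P1.1"),
                   check.names = FALSE)
  peps <- suppressMessages(ingest_and_merge(
    list(t1, t2), list(engine_colmap("prospector"),
                       engine_colmap("msfragger")), proteins_toy))
  expect_setequal(peps$sequence, c("PEPTIDEK", "AVLSTR"))
  rec <- peps[peps$sequence == "PEPTIDEK", ]
  expect_setequal(rec$engines[[1L]], c("msfragger", "prospector"))
  expect_setequal(rec$matched_isoforms[[1L]], c("P1.1", "P1.2"))
  counts <- attr(peps, "counts")
  expect_equal(counts$decoy, 1L)
  # counting identity: |in| = |out| + |decoys| + |unmapped|
  expect_equal(counts$input, nrow(peps) + counts$decoy + counts$unmapped)
})

test_that("unknown accessions are dropped; fully unmapped peptides removed", {
  t1 <- data.frame(`DB.Peptide` = c("AAAA", "PEPTIDEK"),
                   `Acc..` = c("NOPE.1", "P1.1;NOPE.2"), check.names = FALSE)
  peps <- suppressMessages(ingest_and_merge(
    list(t1), list(engine_colmap("prospector")), proteins_toy))
  expect_equal(peps$sequence, "PEPTIDEK")
  expect_equal(peps$matched_isoforms[[1L]], "P1.1")
  expect_equal(attr(peps, "counts")$unmapped, 1L)
  empty <- ingest_and_merge(list(), proteins = proteins_toy)
  expect_equal(nrow(empty), 0L)
})

test_that("adjust_met_loss flags residue-2 anchored matches on Met proteins", {
  peps <- toy_peptides(c("AVLKWWEEK", "MAVLKWWEEK", "PEPTIDEK"),
                       list("P2.1", "P2.1", "P1.1"))
  out <- adjust_met_loss(peps, proteins_toy)
  expect_true(out[out$sequence == "AVLKWWEEK", ]$nterm_met_loss)
  expect_false(out[out$sequence == "MAVLKWWEEK", ]$nterm_met_loss)
  # internal (not position-2) match: no flag
  expect_false(out[out$sequence == "PEPTIDEK", ]$nterm_met_loss)
  # matching neither form: dropped with a message
  bad <- toy_peptides("QQQQQQ", list("P2.1"))
  expect_message(res <- adjust_met_loss(bad, proteins_toy), "dropped")
  expect_equal(nrow(res), 0L)
})

test_that("classify_locus implements the disjointness rule", {
  txs <- toy_locus("G1", 2L)
  peps <- toy_peptides(c("PA", "PB", "PAB"),
                       list("G1.1", "G1.2", c("G1.1", "G1.2")))
  cls <- classify_locus(peps, txs)
  cat_of <- stats::setNames(cls$peptides$category, cls$peptides$sequence)
  expect_equal(unname(cat_of[c("PA", "PB")]),
               rep("isoform_specific", 2L))
  expect_equal(unname(cat_of[["PAB"]]), "shared_all_isoforms")
  expect_equal(cls$locus_summary$supported_isoforms, 2L)

  # everyone maps to the full set: nobody specific
  peps2 <- toy_peptides(c("X1", "X2"), list(c("G1.1", "G1.2"),
                                            c("G1.1", "G1.2")))
  cls2 <- classify_locus(peps2, txs)
  expect_equal(unique(cls2$peptides$category), "shared_all_isoforms")

  # subset peptide with no disjoint partner -> diagnostic bucket
  txs3 <- toy_locus("G3", 3L)
  peps3 <- toy_peptides(c("S1", "S2"), list(c("G3.1", "G3.2"),
                                            c("G3.2", "G3.3")))
  cls3 <- classify_locus(peps3, txs3)
  expect_equal(unique(cls3$peptides$category), "subset_unpaired")
})

test_that("multi-gene and single-isoform-gene peptides are excluded buckets", {
  txs <- c(toy_locus("G1", 2L), toy_locus("G2", 1L))
  peps <- toy_peptides(c("MG", "SG"),
                       list(c("G1.1", "G2.1"), "G2.1"))
  cls <- classify_locus(peps, txs)
  cat_of <- stats::setNames(cls$peptides$category, cls$peptides$sequence)
  expect_equal(unname(cat_of[["MG"]]), "multi_gene")
  expect_equal(unname(cat_of[["SG"]]), "single_isoform_gene")
  expect_error(classify_locus(toy_peptides("E", list(character(0))), txs),
               "empty matched_isoforms")
})

test_that("count_supported_isoforms is an exact maximum set packing", {
  expect_equal(count_supported_isoforms(list("A", "B", c("A", "B"))), 2L)
  expect_equal(count_supported_isoforms(list("A", "B", "C")), 3L)
  expect_equal(count_supported_isoforms(list(c("A", "B"))), 1L)
  expect_equal(count_supported_isoforms(list()), 0L)
  # monotone non-decreasing under adding peptides
  set.seed(11)
  iso <- LETTERS[1:6]
  sets <- replicate(12, sample(iso, sample(1:3, 1)), simplify = FALSE)
  vals <- vapply(seq_along(sets), function(k)
    count_supported_isoforms(sets[seq_len(k)]), integer(1))
  expect_true(all(diff(vals) >= 0L))
})

test_that("fixture categories match manifest examples and partition input", {
  fx <- get_fixture()
  st <- get_fixture_classified()
  cat_of <- stats::setNames(st$cls$peptides$category,
                            st$cls$peptides$sequence)
  for (ex in fx$manifest$category_examples)
    expect_equal(unname(cat_of[[ex$peptide]]), ex$category,
                 info = ex$peptide)
  expect_true(st$cls$peptides[sequence == fx$manifest$met_loss$peptide,
                              nterm_met_loss])
  # categories partition the classified set
  expect_equal(sum(st$cls$counts), nrow(st$cls$peptides))
})
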