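test_that("select_protein_groups keeps one unambiguous group per locus", {
  groups <- data.frame(
    group_id = c("g1", "g2", "g3", "g4", "g5"),
    accessions = c("AT1.1;AT2.1",      # spans two loci -> discarded
                   "AT3.1;AT3.2", "AT3.2",   # same locus, 7 vs 3 peptides
                   "AT4.2", "AT4.1"),        # tie at 5 vs 5
    n_peptides = c(9L, 7L, 3L, 5L, 5L))
  out <- suppressMessages(select_protein_groups(groups))
  expect_false("g1" %in% out$group_id)
  expect_equal(out[out$gene_id == "AT3", ]$group_id, "g2")
  # tie broken by lexicographically smallest accession, with a log message
  expect_message(res <- select_protein_groups(groups), "tie")
  expect_equal(res[res$gene_id == "AT4", ]$group_id, "g5")
})

test_that("impute_missing touches only all-missing-in-one-condition rows", {
  cond <- rep(c("A", "B"), each = 5)
  m <- matrix(20, nrow = 4, ncol = 10,
              dimnames = list(paste0("r", 1:4), NULL))
  m[1, 6:10] <- NA            # eligible: 5/5 in A, 0/5 in B
  m[2, 6:8] <- NA             # 2/5 observed in B: untouched
  m[3, 1] <- NA; m[3, 6:10] <- NA   # 4/5 in A: untouched
  set.seed(1); m[4, ] <- rnorm(10, 20)
  out <- impute_missing(m, cond, seed = 9L)
  imp <- attr(out, "imputed")
  expect_equal(which(rowSums(imp) > 0), c(r1 = 1L))
  expect_equal(sum(imp), 5L)         # replicates x eligible rows
  expect_true(all(is.na(out[2, 6:8])))
  expect_true(all(is.na(out[3, c(1, 6:10)])))
  # observed values are never altered
  expect_equal(out[!imp & !is.na(m)], m[!imp & !is.na(m)])
  # seed-pinned bit reproducibility
  out2 <- impute_missing(m, cond, seed = 9L)
  expect_identical(out, out2)
  expect_error(impute_missing(matrix(c(20, NA), 1, 2), c("A", "B")),
               "fewer than 2")
})

test_that("imputed draws follow the downshifted normal (Monte-Carlo)", {
  cond <- rep(c("A", "B"), each = 5)
  set.seed(3)
  m <- matrix(rnorm(2000 * 10, 20, 1), nrow = 2000)
  m[, 6:10] <- NA                          # every row eligible
  obs <- m[!is.na(m)]
  mu <- mean(obs); sigma <- sd(obs)
  out <- impute_missing(m, cond, seed = 77L)
  draws <- out[attr(out, "imputed")]
  expect_length(draws, 10000L)
  expect_lt(abs(mean(draws) - (mu - 1.8 * sigma)), 0.02 * sigma)
  expect_lt(abs(sd(draws) - 0.3 * sigma), 0.01 * sigma)
})

test_that("call_differential applies the p/fold thresholds after NA removal", {
  tab <- data.frame(id = c("a", "b", "c"),
                    log2fc = c(1.2, 0.9, 2),
                    pvalue = c(0.01, 0.001, NA))
  out <- call_differential(tab)
  expect_equal(out$id, c("a", "b"))          # NA p filtered out
  expect_equal(out$differential, c(TRUE, FALSE))
})

test_that("welch stand-in recovers a planted shift", {
  set.seed(21)
  m <- rbind(shifted = c(rnorm(5, 10, .1), rnorm(5, 13, .1)),
             flat = c(rnorm(10, 10, .1)))
  colnames(m) <- paste0(rep(c("A", "B"), each = 5), 1:5)
  res <- welch_differential(m, rep(c("A", "B"), each = 5), ref = "A")
  out <- call_differential(res)
  expect_true(out[out$id == "shifted", ]$differential)
  expect_false(out[out$id == "flat", ]$differential)
})

iir_records <- function(wt, mut, tm, start, end) {
  data.table::rbindlist(lapply(seq_along(c(wt, mut)), function(k) {
    v <- c(wt, mut)[k]
    grp <- if (k <= length(wt)) "WT" else "mut"
    data.table::data.table(
      gene_id = tm$gene_id, transcript_id = tm$transcript_id,
      chrom = tm$chrom, strand = tm$strand, start = start, end = end,
      sample_id = paste0(grp, "_", k), idratio = v, flag = "ok")
  }))
}

test_that("call_iir applies the depth-and-fold rule with boundaries", {
  tm <- toy_tx("Q.1", "Q", cbind(c(101L, 301L), c(200L, 400L)))
  txs <- list(Q.1 = tm)
  case <- function(wt, mut) {
    rec <- iir_records(wt, mut, tm, 201L, 300L)
    groups <- stats::setNames(rec$sample_id, rec$sample_id)
    groups[] <- ifelse(grepl("^WT", rec$sample_id), "WT", "mut")
    call_iir(rec, groups, "WT", "mut", txs)
  }
  r1 <- case(0.10, 0.30)
  expect_equal(r1$fold_change, 3.0)
  expect_true(r1$is_iir)
  expect_false(case(0.05, 0.14)$is_iir)     # depth below 0.15
  r3 <- case(0.15, 0.20)                    # fold 1.33 < 1.5
  expect_equal(r3$fold_change, 0.2 / 0.15, tolerance = 1e-12)
  expect_false(r3$is_iir)
  # zero WT depth floored at eps and flagged
  r4 <- case(0, 0.30)
  expect_true(r4$wt_floored)
  expect_equal(r4$fold_change, 0.30 / 0.01)
  # monotone: raising either threshold never adds calls
  rec <- iir_records(c(0.1, 0.12), c(0.3, 0.28), tm, 201L, 300L)
  groups <- stats::setNames(ifelse(grepl("^WT", rec$sample_id), "WT", "mut"),
                            rec$sample_id)
  base <- call_iir(rec, groups, "WT", "mut", txs)
  for (dm in c(0.15, 0.3, 0.5)) for (fm in c(1.5, 3, 10)) {
    r <- call_iir(rec, groups, "WT", "mut", txs, depth_min = dm,
                  fold_min = fm)
    expect_true(all(!r$is_iir | base$is_iir))
  }
})

test_that("fixture IIR calls match the manifest with correct regions", {
  fx <- get_fixture()
  cov <- get_fixture_coverage()
  rec <- compute_idratio(cov, gene_intron_inventory(fx$transcripts))
  groups <- stats::setNames(cov$group, cov$sample_id)
  iir <- call_iir(rec, groups, "WT", "mut", fx$transcripts)
  called <- iir[iir$is_iir == TRUE, ]
  got <- sort(paste(called$gene_id, called$start, called$region))
  want <- sort(vapply(fx$manifest$expected_iir, function(x)
    paste(x$gene_id, x$start, x$region), ""))
  expect_equal(got, want)
})

test_that("peptides classify upstream/downstream/spanning of an insertion", {
  # plus strand, CDS 1-297 then 398-1000: insertion residue ceil(298/3)=100
  tm <- toy_tx("Z.1", "Z", cbind(c(1L, 398L), c(297L, 1000L)))
  intron <- list(start = 298L, end = 397L)
  expect_equal(intron_insertion_aa(tm, intron), 100L)
  expect_equal(annotate_peptide_vs_intron(80L, 95L, tm, intron), "upstream")
  expect_equal(annotate_peptide_vs_intron(105L, 120L, tm, intron),
               "downstream")
  expect_equal(annotate_peptide_vs_intron(95L, 105L, tm, intron), "spanning")
  # intron outside the CDS of the isoform
  tm2 <- toy_tx("Z.2", "Z", cbind(c(1L, 398L), c(297L, 1000L)),
                cds = cbind(500L, 1000L))
  expect_equal(annotate_peptide_vs_intron(10L, 20L, tm2, intron),
               "not_applicable")
})

test_that("truncated IR entries carry no downstream peptides", {
  fx <- get_fixture()
  tm <- fx$transcripts[["GIRB1.1"]]
  irb <- Filter(function(x) x$gene_id == "GIRB1",
                fx$manifest$expected_ir_outcomes)[[1L]]
  e <- build_ir_protein(tm, list(chrom = tm$chrom, start = irb$start,
                                 end = irb$end), fx$genome)
  expect_equal(e$outcome, "truncated")
  pos <- intron_insertion_aa(tm, list(start = irb$start, end = irb$end))
  # a peptide downstream of the insertion on the base isoform
  down <- substr(tm$protein, pos + 5L, pos + 15L)
  expect_equal(annotate_peptide_vs_intron(pos + 5L, pos + 15L, tm,
                                          list(start = irb$start,
                                               end = irb$end)),
               "downstream")
  expect_length(locate_in_protein(down, e$protein_sequence), 0L)
  # while an upstream peptide survives in the truncated entry
  up <- substr(tm$protein, 5L, 15L)
  expect_gt(length(locate_in_protein(up, e$protein_sequence)), 0L)
})
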