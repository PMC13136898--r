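# Shared fixture state, built once per test run.

.fx_env <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fx_env$fx))
    .fx_env$fx <- make_genome_and_annotation(seed = 42L)
  .fx_env$fx
}

get_fixture_classified <- function() {
  if (is.null(.fx_env$cls)) {
    fx <- get_fixture()
    tabs <- digest_and_sample_peptides(fx$proteins, fx$manifest, seed = 42L)
    peps <- suppressMessages(ingest_and_merge(
      list(tabs$prospector, tabs$msfragger),
      list(engine_colmap("prospector"), engine_colmap("msfragger")),
      fx$proteins))
    counts <- attr(peps, "counts")
    peps <- suppressMessages(adjust_met_loss(peps, fx$proteins))
    cls <- classify_locus(peps, fx$transcripts)
    .fx_env$tabs <- tabs
    .fx_env$ingest_counts <- counts
    .fx_env$cls <- cls
  }
  list(cls = .fx_env$cls, tabs = .fx_env$tabs,
       ingest_counts = .fx_env$ingest_counts)
}

get_fixture_coverage <- function() {
  if (is.null(.fx_env$cov)) {
    fx <- get_fixture()
    .fx_env$cov <- make_coverage(fx$transcripts, fx$manifest$depth_targets,
                                 seed = 42L)
  }
  .fx_env$cov
}

# minimal transcript without genome-derived protein, for structural tests
toy_tx <- function(id, gene, exons, cds = exons, strand = "+",
                   chrom = "chrT") {
  transcript_model(id, gene, chrom, strand,
                   data.frame(start = exons[, 1L], end = exons[, 2L]),
                   data.frame(start = cds[, 1L], end = cds[, 2L]))
}

# a gene locus of k featureless isoforms (for classification tests)
toy_locus <- function(gene, k) {
  txs <- lapply(seq_len(k), function(i)
    toy_tx(paste0(gene, ".", i), gene, cbind(1L, 99L)))
  stats::setNames(txs, vapply(txs, `[[`, "", "transcript_id"))
}

# peptide data.table in the shape classify_locus() expects
toy_peptides <- function(seqs, iso_sets) {
  data.table::data.table(
    sequence = seqs, engines = rep(list("e1"), length(seqs)),
    matched_isoforms = lapply(iso_sets, sort),
    matched_genes = lapply(iso_sets, accession_gene),
    nterm_met_loss = FALSE)
}
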