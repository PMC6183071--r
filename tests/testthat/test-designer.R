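# A hand-built compliant window: guide = U + potent 4-mer (AGCA) + 13 nt +
# C, with 7 G/C, no stretches. Flanks are periodic so the planted window is
# the only thing under test.
GUIDE_OK <- "UAGCAAUGAUGCAUGAUAC"
SITE_OK <- rna_revcomp(GUIDE_OK)
FLANK <- strrep("AUCG", 30)

make_tx <- function(site = SITE_OK, masks = NULL) {
  transcript_record("TX01", "GENE01", paste0(FLANK, site, FLANK), masks)
}

test_that("a compliant window passes the whole cascade", {
  ctl <- build_potency_catalog()
  expect_identical(filter_window(make_tx(), 120L, ctl), character(0))
})

test_that("each rule is reported by its reason code", {
  ctl <- build_potency_catalog()
  # guide position 1 must be U <=> target-site position 19 must be A
  s <- SITE_OK; substr(s, 19, 19) <- "G"
  expect_true("POS1_NOT_U" %in% filter_window(make_tx(s), 120L, ctl))
  # non-potent nucleation (GGAA scores -3.4, just outside the window)
  g <- GUIDE_OK; substr(g, 2, 5) <- "GGAA"
  expect_identical(filter_window(make_tx(rna_revcomp(g)), 120L, ctl),
                   "NUCLEATION_NOT_POTENT")
  # window touching the first 100 nt of the CDS
  expect_true("ORF_EDGE" %in% filter_window(make_tx(), 50L, ctl))
  # mononucleotide stretch in the guide
  g <- GUIDE_OK; substr(g, 8, 11) <- "AAAA"
  expect_true("STRETCH" %in% filter_window(make_tx(rna_revcomp(g)), 120L, ctl))
  # G/C-only stretch counts as a stretch too
  g <- GUIDE_OK; substr(g, 8, 11) <- "GCGC"
  expect_true("STRETCH" %in% filter_window(make_tx(rna_revcomp(g)), 120L, ctl))
  # guide position 19 must be G or C
  g <- GUIDE_OK; substr(g, 19, 19) <- "A"
  expect_true("POS19_NOT_GC" %in%
                filter_window(make_tx(rna_revcomp(g)), 120L, ctl))
  # mask overlap
  tx <- make_tx(masks = matrix(c(130L, 145L), ncol = 2))
  expect_identical(filter_window(tx, 120L, ctl), "MASKED")
  expect_error(filter_window(make_tx(), 100000L, ctl), "out of range")
})

test_that("transcripts load with merged masks and per-gene mask union", {
  dir <- withr::local_tempdir()
  seqs <- c(TXA = strrep("AUCG", 30), TXB = strrep("AUCG", 30),
            TXC = strrep("GAUC", 25))
  paths <- write_mini_inputs(dir, seqs, c("G1", "G1", "G2"),
                             bed = data.frame(c("TXA", "TXA", "TXB"),
                                              c(10L, 15L, 40L),
                                              c(20L, 30L, 50L)))
  tx <- load_transcripts(paths$fasta, paths$genes, paths$bed)
  expect_length(tx, 3)
  # overlapping [10,20) and [15,30) merge; TXA and TXB share a gene and an
  # identical CDS length, so their masks are unioned
  expect_equal(unname(tx[[1]]$mask_intervals),
               matrix(c(10L, 40L, 30L, 50L), ncol = 2))
  expect_equal(tx[[1]]$mask_intervals, tx[[2]]$mask_intervals)
  expect_equal(nrow(tx[[3]]$mask_intervals), 0L)
})

test_that("malformed masks warn and are clamped or skipped", {
  dir <- withr::local_tempdir()
  seqs <- c(TXA = strrep("AUCG", 30))
  paths <- write_mini_inputs(dir, seqs, "G1",
                             bed = data.frame(c("TXA", "NOPE"),
                                              c(100L, 0L), c(999L, 5L)))
  expect_warning(expect_warning(
    tx <- load_transcripts(paths$fasta, paths$genes, paths$bed),
    "unknown transcript"), "clamped")
  expect_equal(unname(tx[[1]]$mask_intervals),
               matrix(c(100L, 120L), ncol = 2))
})

test_that("uniqueness distinguishes unique, duplicated and cross-gene sites", {
  shared <- SITE_OK
  tx <- list(
    transcript_record("T1", "G1", paste0(FLANK, shared, FLANK)),
    transcript_record("T2", "G2", paste0(FLANK, shared, FLANK)),
    transcript_record("T3", "G3", paste0(FLANK, strrep("A", 19), FLANK)))
  idx <- build_kmer_index(tx)
  expect_false(uniqueness_check(shared, idx, "G1"))
  expect_true(uniqueness_check(strrep("A", 19), idx, "G3",
                               unique_within_gene = FALSE))
  # the poly-A site occurs at many starts of T3: strict mode rejects it
  expect_false(uniqueness_check(strrep("A", 19), idx, "G3"))
  expect_error(uniqueness_check(strrep("G", 19), idx, "G1"),
               "not present")
})

test_that("uniqueness agrees with naive text search on random sites", {
  set.seed(41)
  tx <- lapply(1:4, function(i) {
    transcript_record(paste0("T", i), paste0("G", i %% 2), random_seq(400))
  })
  idx <- build_kmer_index(tx)
  for (r in 1:100) {
    ti <- sample(4, 1)
    s0 <- sample(0:(400 - 19), 1)
    site <- substr(tx[[ti]]$cds, s0 + 1, s0 + 19)
    counts <- vapply(tx, function(t) naive_count(site, t$cds), numeric(1))
    genes <- vapply(tx, `[[`, "", "gene_symbol")
    naive_pass <- all(genes[counts > 0] == tx[[ti]]$gene_symbol) &&
      all(counts <= 1)
    expect_identical(uniqueness_check(site, idx, tx[[ti]]$gene_symbol),
                     naive_pass)
  }
})

test_that("design on an empty transcriptome yields an empty table", {
  out <- design(list())
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(out), 0L)
  expect_true(all(c("gene", "target_site", "dg_nucleation", "dg_total")
                  %in% names(out)))
})

test_that("design recovers exactly the planted truth table", {
  fx <- synth_transcriptome(fixture_spec(seed = 101))
  cand <- design(fx$transcripts)
  truth_acc <- fx$truth[fx$truth$expected == "accept", ]
  expect_setequal(paste(cand$transcript, cand$start),
                  paste(truth_acc$transcript, truth_acc$start))
  expect_setequal(cand$target_site, truth_acc$target_site)
  # decoys and duplicated sites never appear
  truth_rej <- fx$truth[fx$truth$expected == "reject", ]
  expect_false(any(paste(truth_rej$transcript, truth_rej$start) %in%
                     paste(cand$transcript, cand$start)))
})

test_that("every emitted candidate satisfies the record invariants", {
  fx <- synth_transcriptome(fixture_spec(seed = 102))
  cand <- design(fx$transcripts)
  expect_gt(nrow(cand), 0)
  expect_equal(cand$guide, rna_revcomp(cand$target_site))
  expect_true(all(substr(cand$guide, 1, 1) == "U"))
  expect_true(all(substr(cand$guide, 19, 19) %in% c("G", "C")))
  expect_true(all(cand$gc_count >= 6 & cand$gc_count <= 10))
  expect_equal(cand$gc_percent, round(100 * cand$gc_count / 19, 1))
  expect_true(all(cand$dg_nucleation >= -6 & cand$dg_nucleation <= -3.5))
  expect_equal(cand$nucleation_4mer, substr(cand$guide, 2, 5))
  for (i in seq_len(nrow(cand))) {
    tx <- fx$transcripts[[match(cand$transcript[i],
                                vapply(fx$transcripts, `[[`, "",
                                       "transcript_id"))]]
    expect_gte(cand$start[i], 100)
    expect_lte(cand$start[i] + 19, nchar(tx$cds) - 100)
  }
})

test_that("adding mask intervals never adds a candidate", {
  fx <- synth_transcriptome(fixture_spec(seed = 103))
  before <- design(fx$transcripts)
  masked <- fx$transcripts
  # mask the first accepted window of the first candidate's transcript
  stopifnot(nrow(before) > 0)
  ti <- match(before$transcript[1],
              vapply(masked, `[[`, "", "transcript_id"))
  masked[[ti]] <- transcript_record(
    masked[[ti]]$transcript_id, masked[[ti]]$gene_symbol, masked[[ti]]$cds,
    rbind(masked[[ti]]$mask_intervals,
          c(before$start[1] + 5L, before$start[1] + 9L)))
  after <- design(masked)
  expect_lt(nrow(after), nrow(before))
  expect_true(all(paste(after$transcript, after$start) %in%
                    paste(before$transcript, before$start)))
})

test_that("design is deterministic and idempotent", {
  fx <- synth_transcriptome(fixture_spec(seed = 104))
  expect_identical(design(fx$transcripts), design(fx$transcripts))
})

test_that("design output matches the brute-force oracle", {
  ctl <- build_potency_catalog()
  for (seed in c(201, 202)) {
    fx <- synth_transcriptome(fixture_spec(seed = seed))
    expect_equal(design(fx$transcripts, ctl), brute_design(fx$transcripts, ctl))
  }
})

test_that("candidates are written with 1-based coordinates and X pivot", {
  fx <- synth_transcriptome(fixture_spec(seed = 105))
  cand <- design(fx$transcripts)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cand, path)
  tab <- utils::read.delim(path)
  expect_equal(tab$start_1based, cand$start + 1L)
  expect_equal(tab$end_1based, cand$start + 19L)
  expect_true(all(substr(tab$guide_6O, 6, 6) == "X"))
  expect_equal(substr(tab$guide_6O, 1, 5), substr(cand$guide, 1, 5))
  expect_equal(substr(tab$guide_6O, 7, 19), substr(cand$guide, 7, 19))
})
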