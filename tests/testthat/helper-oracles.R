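# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything with naive string operations and
# share no code path with the package internals.

BASES <- c("A", "C", "G", "U")

random_seq <- function(n, bases = BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

naive_revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# sup-difference of the two empirical CDFs over all pooled breakpoints
brute_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(fa - fb))
}

# overlapping occurrence count of a pattern in a subject
naive_count <- function(pattern, subject) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  sum(hits > 0)
}

# Naive re-implementation of the full designer: enumerate every window,
# re-test every rule with plain string code, re-check uniqueness by text
# search, and score accepted guides with the external reference duplex
# program. Returns a data.frame shaped like design()'s output.
brute_design <- function(transcripts, catalog, config = design_config()) {
  potent <- catalog$entries$kmer[catalog$entries$selected]
  dg_of <- stats::setNames(catalog$entries$dg, catalog$entries$kmer)
  rows <- list()
  for (tx in transcripts) {
    cds <- tx$cds
    L <- nchar(cds)
    if (L < 19) next
    for (s0 in 0:(L - 19)) {
      site <- substr(cds, s0 + 1, s0 + 19)
      guide <- naive_revcomp(site)
      ch <- strsplit(guide, "")[[1]]
      if (ch[1] != "U") next
      nuc <- paste(ch[2:5], collapse = "")
      if (!nuc %in% potent) next
      if (s0 < config$edge_exclude ||
          s0 + 19 > L - config$edge_exclude) next
      r <- rle(ch)
      if (any(r$lengths >= config$stretch_len)) next
      rs <- rle(ch %in% c("G", "C"))
      if (any(rs$values & rs$lengths >= config$stretch_len)) next
      gc <- sum(ch %in% c("G", "C"))
      if (gc < config$gc_min || gc > config$gc_max) next
      if (!ch[19] %in% c("G", "C")) next
      m <- tx$mask_intervals
      if (nrow(m) > 0 && any(m[, 1] < s0 + 19 & m[, 2] > s0)) next
      rows[[length(rows) + 1]] <- data.frame(
        gene = tx$gene_symbol, transcript = tx$transcript_id, start = s0,
        target_site = site, guide = guide, nucleation_4mer = nuc,
        dg_nucleation = unname(dg_of[nuc]), gc_count = gc,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(gene = character(0), transcript = character(0),
                      start = integer(0), target_site = character(0),
                      guide = character(0), nucleation_4mer = character(0),
                      dg_nucleation = numeric(0), dg_total = numeric(0),
                      gc_count = integer(0), gc_percent = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0) return(empty)
  cand <- do.call(rbind, rows)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    total <- 0; foreign <- FALSE; multi <- FALSE
    for (tx in transcripts) {
      n <- naive_count(cand$target_site[i], tx$cds)
      total <- total + n
      if (n > 0 && tx$gene_symbol != cand$gene[i]) foreign <- TRUE
      if (n > 1) multi <- TRUE
    }
    keep[i] <- !foreign && (!config$unique_within_gene || !multi)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  guides_n <- vapply(cand$guide, function(g) {
    substr(g, 6, 6) <- "N"
    substr(g, 2, 19)
  }, character(1), USE.NAMES = FALSE)
  cand$dg_total <- rnaduplex_energy(guides_n)
  cand$gc_percent <- round(100 * cand$gc_count / 19, 1)
  cand <- cand[, c("gene", "transcript", "start", "target_site", "guide",
                   "nucleation_4mer", "dg_nucleation", "dg_total",
                   "gc_count", "gc_percent")]
  cand <- cand[order(cand$gene, cand$dg_nucleation, cand$start,
                     cand$transcript), ]
  rownames(cand) <- NULL
  cand
}

# write a tiny FASTA/TSV/BED trio for load_transcripts tests
write_mini_inputs <- function(dir, seqs, genes, bed = NULL) {
  fa <- file.path(dir, "cds.fa")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fa)
  gm <- file.path(dir, "genes.tsv")
  writeLines(paste(names(seqs), genes, sep = "\t"), gm)
  bd <- NULL
  if (!is.null(bed)) {
    bd <- file.path(dir, "masks.bed")
    writeLines(apply(bed, 1, paste, collapse = "\t"), bd)
  }
  list(fasta = fa, genes = gm, bed = bd)
}
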