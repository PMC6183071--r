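#' Target-site scanner for abasic-pivot siRNAs
#'
#' Scans coding sequences for 19-nt target sites whose guide (the reverse
#' complement of the sense window, carrying an abasic spacer at position 6)
#' passes the full design filter cascade:
#'
#' * `POS1_NOT_U` - guide position 1 must be U (target-site position 19 is A;
#'   efficient Argonaute loading),
#' * `NUCLEATION_NOT_POTENT` - the nucleation 4-mer (guide positions 2-5)
#'   must lie in the potency catalog's selected set,
#' * `ORF_EDGE` - no window base may lie within the first or last 100 nt of
#'   the CDS,
#' * `STRETCH` - no mononucleotide run and no G/C-only run of length >= the
#'   configured threshold (default 4) anywhere in the guide,
#' * `GC_CONTENT` - 6..10 G/C in the 19-nt guide (32-52%),
#' * `POS19_NOT_GC` - guide position 19 must be G or C (blocks passenger
#'   strand loading),
#' * `MASKED` - the window must not overlap any mask interval (SNPs,
#'   repeats),
#'
#' followed by a transcriptome-uniqueness check: the 19-mer must occur only
#' in transcripts of the intended gene (and, strictly, at most once per
#' transcript).
#'
#' Coordinates are 0-based half-open internally and 1-based inclusive in
#' written TSV output.
#'
#' @name designer
NULL

#' Designer configuration
#'
#' @param gmin,gmax inclusive potency window for the nucleation energy
#'   (kcal/mol).
#' @param stretch_len reject runs of identical nucleotides, or of G/C-only
#'   sequence, of at least this length (default 4).
#' @param gc_min,gc_max allowed G/C count in the 19-nt guide.
#' @param edge_exclude number of nucleotides at each CDS end that no window
#'   base may touch.
#' @param unique_within_gene strict uniqueness: additionally require at most
#'   one occurrence of the site per transcript of the intended gene.
#' @param thermo a [thermo_config()].
#' @return object of class `design_config`.
#' @export
design_config <- function(gmin = -6, gmax = -3.5, stretch_len = 4,
                          gc_min = 6, gc_max = 10, edge_exclude = 100,
                          unique_within_gene = TRUE,
                          thermo = thermo_config()) {
  stopifnot(gmin <= gmax, stretch_len >= 2, gc_min <= gc_max,
            edge_exclude >= 0)
  structure(list(gmin = gmin, gmax = gmax,
                 stretch_len = as.integer(stretch_len),
                 gc_min = as.integer(gc_min), gc_max = as.integer(gc_max),
                 edge_exclude = as.integer(edge_exclude),
                 unique_within_gene = isTRUE(unique_within_gene),
                 thermo = thermo),
            class = "design_config")
}

#' Load transcripts with gene mapping and mask intervals
#'
#' Reads a CDS FASTA (RNA or DNA alphabet; T is converted to U), a
#' two-column TSV mapping transcript id to gene symbol, and optionally a BED
#' file of mask intervals in transcript coordinates (0-based half-open).
#' Overlapping intervals are merged. For a gene with several transcripts of
#' identical CDS length, mask intervals are unioned across those
#' transcripts.
#'
#' @param cds_fasta path to the CDS FASTA.
#' @param gene_map path to a TSV with columns `transcript_id`,
#'   `gene_symbol` (header optional).
#' @param masks optional path to a BED file (`transcript_id  start  end`).
#' @return list of `transcript_record` objects, each with `transcript_id`,
#'   `gene_symbol`, `cds` (RNA alphabet) and `mask_intervals` (two-column
#'   matrix of merged 0-based half-open intervals).
#' @export
load_transcripts <- function(cds_fasta, gene_map, masks = NULL) {
  seqs <- Biostrings::readBStringSet(cds_fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  cds <- as_rna(as.character(seqs))
  gm <- utils::read.delim(gene_map, header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(gm[1, 1]), "transcript_id")) gm <- gm[-1, , drop = FALSE]
  gene_of <- stats::setNames(as.character(gm[[2]]), as.character(gm[[1]]))
  missing_ids <- setdiff(ids, names(gene_of))
  if (length(missing_ids) > 0L) {
    stop("FASTA ids missing from gene map: ",
         paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  mask_list <- stats::setNames(vector("list", length(ids)), ids)
  if (!is.null(masks)) {
    bed <- utils::read.delim(masks, header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    for (i in seq_len(nrow(bed))) {
      tx <- as.character(bed[i, 1])
      if (!tx %in% ids) {
        warning("mask interval for unknown transcript ", tx, ": skipped",
                call. = FALSE)
        next
      }
      s <- as.integer(bed[i, 2]); e <- as.integer(bed[i, 3])
      len <- nchar(cds[[match(tx, ids)]])
      if (s < 0L || e > len) {
        warning("mask interval [", s, ",", e, ") out of range for ", tx,
                ": clamped", call. = FALSE)
        s <- max(s, 0L); e <- min(e, len)
      }
      if (e > s) mask_list[[tx]] <- rbind(mask_list[[tx]], c(s, e))
    }
  }
  # per-gene union of masks across transcripts with identical CDS length
  lens <- nchar(cds)
  for (g in unique(gene_of[ids])) {
    tx_g <- ids[gene_of[ids] == g]
    for (L in unique(lens[match(tx_g, ids)])) {
      grp <- tx_g[lens[match(tx_g, ids)] == L]
      if (length(grp) > 1L) {
        pooled <- do.call(rbind, mask_list[grp])
        for (tx in grp) mask_list[[tx]] <- pooled
      }
    }
  }
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- transcript_record(ids[i], unname(gene_of[ids[i]]),
                                  cds[[i]], mask_list[[ids[i]]])
  }
  out
}

#' Construct a transcript record
#'
#' @param transcript_id,gene_symbol identifiers.
#' @param cds RNA (or DNA; converted) coding sequence.
#' @param mask_intervals two-column matrix or NULL; 0-based half-open
#'   intervals, merged and sorted on construction.
#' @return object of class `transcript_record`.
#' @export
transcript_record <- function(transcript_id, gene_symbol, cds,
                              mask_intervals = NULL) {
  cds <- as_rna(cds)
  if (!is.null(mask_intervals) && nrow(mask_intervals) > 0L) {
    ir <- IRanges::reduce(IRanges::IRanges(start = mask_intervals[, 1] + 1L,
                                           end = mask_intervals[, 2]))
    mask_intervals <- cbind(start = IRanges::start(ir) - 1L,
                            end = IRanges::end(ir))
  } else {
    mask_intervals <- matrix(integer(0), ncol = 2,
                             dimnames = list(NULL, c("start", "end")))
  }
  structure(list(transcript_id = transcript_id, gene_symbol = gene_symbol,
                 cds = cds, mask_intervals = mask_intervals),
            class = "transcript_record")
}

gc_count_of <- function(x) {
  nchar(x) - nchar(gsub("[GC]", "", x))
}

has_stretch <- function(x, len) {
  grepl(sprintf("([ACGUN])\\1{%d}", len - 1L), x) |
    grepl(sprintf("[GC]{%d}", len), x)
}

#' Evaluate the filter cascade for one window
#'
#' Applies every sequence and location rule to the 19-nt window starting at
#' 0-based position `start` and returns all failing reason codes (an empty
#' character vector means accept). Uniqueness is checked separately by
#' [uniqueness_check()].
#'
#' @param transcript a `transcript_record`.
#' @param start 0-based window start, `0 <= start <= nchar(cds) - 19`.
#' @param catalog a `potency_catalog` built at k = 4.
#' @param config a [design_config()].
#' @return character vector of reason codes among `POS1_NOT_U`,
#'   `NUCLEATION_NOT_POTENT`, `ORF_EDGE`, `STRETCH`, `GC_CONTENT`,
#'   `POS19_NOT_GC`, `MASKED`.
#' @export
filter_window <- function(transcript, start, catalog,
                          config = design_config()) {
  stopifnot(inherits(transcript, "transcript_record"))
  len <- nchar(transcript$cds)
  start <- as.integer(start)
  if (is.na(start) || start < 0L || start > len - 19L) {
    stop("start out of range", call. = FALSE)
  }
  site <- substr(transcript$cds, start + 1L, start + 19L)
  guide <- rna_revcomp(site)
  reasons <- character(0)
  if (substr(guide, 1, 1) != "U") reasons <- c(reasons, "POS1_NOT_U")
  nuc <- substr(guide, 2, 5)
  sel <- catalog$entries$selected[match(nuc, catalog$entries$kmer)]
  if (!isTRUE(sel)) reasons <- c(reasons, "NUCLEATION_NOT_POTENT")
  if (start < config$edge_exclude ||
      start + 19L > len - config$edge_exclude) {
    reasons <- c(reasons, "ORF_EDGE")
  }
  if (has_stretch(guide, config$stretch_len)) {
    reasons <- c(reasons, "STRETCH")
  }
  gc <- gc_count_of(guide)
  if (gc < config$gc_min || gc > config$gc_max) {
    reasons <- c(reasons, "GC_CONTENT")
  }
  if (!substr(guide, 19, 19) %in% c("G", "C")) {
    reasons <- c(reasons, "POS19_NOT_GC")
  }
  m <- transcript$mask_intervals
  if (nrow(m) > 0L && any(m[, 1] < start + 19L & m[, 2] > start)) {
    reasons <- c(reasons, "MASKED")
  }
  reasons
}

#' Build an exact 19-mer index over a transcriptome
#'
#' Indexes every occurrence of every 19-mer (sense strand) in the input
#' transcripts, for transcriptome-uniqueness checks.
#'
#' @param transcripts list of `transcript_record`s.
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(transcripts) {
  pieces <- lapply(transcripts, function(tx) {
    len <- nchar(tx$cds)
    if (len < 19L) return(NULL)
    starts <- seq_len(len - 18L)
    data.table::data.table(
      kmer = substring(tx$cds, starts, starts + 18L),
      transcript_id = tx$transcript_id,
      gene_symbol = tx$gene_symbol,
      pos = starts - 1L)
  })
  dt <- data.table::rbindlist(pieces)
  data.table::setkey(dt, kmer)
  structure(list(occurrences = dt), class = "kmer_index")
}

#' Transcriptome-uniqueness check for a target site
#'
#' Passes iff every indexed occurrence of the 19-mer belongs to the intended
#' gene and (strict mode) each transcript of that gene contains it at most
#' once.
#'
#' @param target_site 19-nt sense sequence.
#' @param index a `kmer_index` built over the full input transcriptome.
#' @param intended_gene gene symbol the site is designed against.
#' @param unique_within_gene strict per-transcript uniqueness (default TRUE).
#' @return logical: TRUE = pass.
#' @export
uniqueness_check <- function(target_site, index, intended_gene,
                             unique_within_gene = TRUE) {
  stopifnot(inherits(index, "kmer_index"), nchar(target_site) == 19L)
  occ <- index$occurrences[list(target_site), nomatch = NULL]
  if (nrow(occ) == 0L) {
    stop("site not present in index; it should originate from the indexed ",
         "transcriptome", call. = FALSE)
  }
  if (any(occ$gene_symbol != intended_gene)) return(FALSE)
  if (unique_within_gene &&
      any(table(occ$transcript_id) > 1L)) return(FALSE)
  TRUE
}

# vectorized evaluation of all windows of one transcript; returns a logical
# vector (sequence + edge + mask rules only) plus per-window annotations
scan_transcript <- function(tx, catalog, config) {
  len <- nchar(tx$cds)
  if (len < 19L) {
    return(data.table::data.table())
  }
  starts0 <- 0:(len - 19L)
  site <- substring(tx$cds, starts0 + 1L, starts0 + 19L)
  # guide rules expressed on the sense window: guide position i pairs
  # target-site position 20 - i
  last <- substring(site, 19L, 19L)          # guide position 1 complement
  first <- substring(site, 1L, 1L)           # guide position 19 complement
  pos1_u <- last == "A"
  pos19_gc <- first %in% c("G", "C")
  nuc <- rna_revcomp(substring(site, 15L, 18L))  # guide positions 2-5
  cat_sel <- stats::setNames(catalog$entries$selected, catalog$entries$kmer)
  cat_dg <- stats::setNames(catalog$entries$dg, catalog$entries$kmer)
  nuc_ok <- unname(cat_sel[nuc]); nuc_ok[is.na(nuc_ok)] <- FALSE
  edge_ok <- starts0 >= config$edge_exclude &
    starts0 + 19L <= len - config$edge_exclude
  guide <- rna_revcomp(site)
  stretch_bad <- has_stretch(guide, config$stretch_len)
  gc <- gc_count_of(site)
  gc_ok <- gc >= config$gc_min & gc <= config$gc_max
  m <- tx$mask_intervals
  masked <- rep(FALSE, length(starts0))
  if (nrow(m) > 0L) {
    for (r in seq_len(nrow(m))) {
      masked <- masked | (m[r, 1] < starts0 + 19L & m[r, 2] > starts0)
    }
  }
  ok <- pos1_u & nuc_ok & edge_ok & !stretch_bad & gc_ok & pos19_gc & !masked
  data.table::data.table(
    gene = tx$gene_symbol, transcript = tx$transcript_id, start = starts0,
    target_site = site, guide = guide, nucleation_4mer = nuc,
    dg_nucleation = unname(cat_dg[nuc]), gc_count = gc, ok = ok)
}

#' Design abasic-pivot siRNA candidates over a transcriptome
#'
#' Evaluates every 19-nt window of every transcript against the filter
#' cascade, applies the transcriptome-uniqueness check to accepted windows,
#' and reports candidate records sorted by gene, then nucleation energy
#' (ascending), then position.
#'
#' @param transcripts list of `transcript_record`s (see
#'   [load_transcripts()]).
#' @param catalog a `potency_catalog` at k = 4 built with the configured
#'   window; built automatically if NULL.
#' @param config a [design_config()].
#' @return data.frame of candidates with columns `gene`, `transcript`,
#'   `start` (0-based), `target_site`, `guide` (unmodified bases; the abasic
#'   position is position 6), `nucleation_4mer`, `dg_nucleation`, `dg_total`
#'   (total duplex energy with the abasic pivot), `gc_count`, `gc_percent`.
#' @export
design <- function(transcripts, catalog = NULL, config = design_config()) {
  if (is.null(catalog)) {
    catalog <- build_potency_catalog(4, c(config$gmin, config$gmax),
                                     config$thermo)
  }
  stopifnot(inherits(catalog, "potency_catalog"), catalog$k == 4L)
  scans <- data.table::rbindlist(
    lapply(transcripts, scan_transcript, catalog = catalog, config = config))
  empty <- data.frame(gene = character(0), transcript = character(0),
                      start = integer(0), target_site = character(0),
                      guide = character(0), nucleation_4mer = character(0),
                      dg_nucleation = numeric(0), dg_total = numeric(0),
                      gc_count = integer(0), gc_percent = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(scans) == 0L || !any(scans$ok)) return(empty)
  cand <- as.data.frame(scans)[scans$ok, ]
  index <- build_kmer_index(transcripts)
  uniq <- vapply(seq_len(nrow(cand)), function(i) {
    uniqueness_check(cand$target_site[i], index, cand$gene[i],
                     config$unique_within_gene)
  }, logical(1))
  cand <- cand[uniq, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  dg_total <- vapply(cand$guide, function(g) {
    region_energy(g, 2, 19, config$thermo, abasic_position = 6)
  }, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(gene = cand$gene, transcript = cand$transcript,
                    start = cand$start, target_site = cand$target_site,
                    guide = cand$guide,
                    nucleation_4mer = cand$nucleation_4mer,
                    dg_nucleation = cand$dg_nucleation, dg_total = dg_total,
                    gc_count = cand$gc_count,
                    gc_percent = round(100 * cand$gc_count / 19, 1),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$dg_nucleation, out$start, out$transcript), ]
  rownames(out) <- NULL
  out
}

#' Write candidates as TSV
#'
#' Emits 1-based inclusive coordinates and renders the abasic position of
#' the guide as `X`.
#'
#' @param candidates data.frame from [design()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  guide_6o <- candidates$guide
  if (length(guide_6o) > 0L) substr(guide_6o, 6, 6) <- "X"
  out <- data.frame(gene = candidates$gene, transcript = candidates$transcript,
                    start_1based = candidates$start + 1L,
                    end_1based = candidates$start + 19L,
                    target_site = candidates$target_site,
                    guide_6O = guide_6o,
                    nucleation_4mer = candidates$nucleation_4mer,
                    dG_2_5 = candidates$dg_nucleation,
                    dG_total = candidates$dg_total,
                    gc_count = candidates$gc_count,
                    gc_percent = candidates$gc_percent,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
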