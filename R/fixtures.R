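#' Deterministic synthetic-data generators
#'
#' Every generator is a pure function of a [fixture_spec()]: the same spec
#' (including its seed) reproduces byte-identical output. The transcriptome
#' generator plants target sites that satisfy the whole filter cascade,
#' decoys that each violate exactly one named rule, and cross-gene duplicate
#' sites that exercise the uniqueness check; everything planted is recorded
#' in a truth table. The screen generator emulates the observed
#' energy-activity relation: a potency plateau inside the nucleation-energy
#' window with linear decline outside it. The dose-response generator draws
#' four-parameter logistic curves with replicate noise.
#'
#' @name fixtures
NULL

#' Specification for the synthetic-data generators
#'
#' Defaults describe the study conditions the generators emulate: CDS-scale
#' transcripts with balanced GC, a potency plateau spanning the
#' [-6, -3.5] kcal/mol nucleation window, and reporter dose-response curves
#' measured over a log-spaced nanomolar dose ladder with six replicates.
#'
#' @param seed integer RNG seed; one shared generator is seeded once per
#'   fixture run.
#' @param n_genes number of genes (one transcript each).
#' @param cds_length length-2 range of CDS lengths (nt); at least 240 so a
#'   window fits between the 100-nt edge exclusions.
#' @param gc_fraction background GC fraction.
#' @param n_planted compliant target sites planted across genes.
#' @param decoys_per_rule decoy sites per filter rule, each violating
#'   exactly that rule.
#' @param n_offtarget_duplicates compliant sites planted into two genes to
#'   exercise the uniqueness check.
#' @param screen_n screening records.
#' @param plateau_window nucleation-energy window (kcal/mol) of full
#'   activity.
#' @param plateau_activity activity level on the plateau.
#' @param decline_slope activity loss per kcal/mol outside the window.
#' @param screen_noise_sd Gaussian noise sd on activities.
#' @param ic50,hill,floor,ceiling dose-response truth parameters (nM /
#'   unitless).
#' @param dose_range length-2 range of the log-spaced dose ladder (nM).
#' @param n_doses number of doses.
#' @param replicates replicates per dose.
#' @param dose_noise_sd Gaussian noise sd on responses.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 6L, cds_length = c(450L, 800L),
                         gc_fraction = 0.5, n_planted = 4L,
                         decoys_per_rule = 1L, n_offtarget_duplicates = 1L,
                         screen_n = 300L, plateau_window = c(-6, -3.5),
                         plateau_activity = 0.85, decline_slope = 0.25,
                         screen_noise_sd = 0.05, ic50 = 0.1, hill = 1,
                         floor = 0.1, ceiling = 1,
                         dose_range = c(1e-3, 100), n_doses = 8L,
                         replicates = 6L, dose_noise_sd = 0.05) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               cds_length = as.integer(cds_length),
               gc_fraction = gc_fraction, n_planted = as.integer(n_planted),
               decoys_per_rule = as.integer(decoys_per_rule),
               n_offtarget_duplicates = as.integer(n_offtarget_duplicates),
               screen_n = as.integer(screen_n),
               plateau_window = plateau_window,
               plateau_activity = plateau_activity,
               decline_slope = decline_slope,
               screen_noise_sd = screen_noise_sd, ic50 = ic50, hill = hill,
               floor = floor, ceiling = ceiling, dose_range = dose_range,
               n_doses = as.integer(n_doses),
               replicates = as.integer(replicates),
               dose_noise_sd = dose_noise_sd)
  if (spec$cds_length[1] < 240L) {
    stop("cds_length must be at least 240 nt (two 100-nt edges plus a ",
         "19-nt window)", call. = FALSE)
  }
  if (spec$n_planted < 0L) stop("n_planted must be >= 0", call. = FALSE)
  structure(spec, class = "fixture_spec")
}

spec_header <- function(spec, prefix = "# ") {
  flat <- vapply(unclass(spec), function(v) paste(v, collapse = ","),
                 character(1))
  paste0(prefix, "fixture_spec: ",
         paste(names(flat), flat, sep = "=", collapse = "; "))
}

random_rna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# sample a guide satisfying all sequence rules; returns the guide (pos 2-5
# drawn from the potent set)
sample_compliant_guide <- function(potent, cfg) {
  repeat {
    g <- paste0("U", sample(potent, 1),
                random_rna(13, 0.45), sample(c("G", "C"), 1))
    gc <- gc_count_of(g)
    if (gc < cfg$gc_min || gc > cfg$gc_max) next
    if (has_stretch(g, cfg$stretch_len)) next
    return(g)
  }
}

# mutate a guide so that exactly one named rule fails
make_decoy_guide <- function(rule, potent, not_potent, cfg) {
  repeat {
    g <- sample_compliant_guide(potent, cfg)
    g2 <- switch(rule,
      POS1_NOT_U = { substr(g, 1, 1) <- "A"; g },
      NUCLEATION_NOT_POTENT = {
        substr(g, 2, 5) <- sample(not_potent, 1); g
      },
      STRETCH = { substr(g, 8, 11) <- "AAAA"; g },
      GC_CONTENT = {
        # push the GC count above the maximum without creating an S-run
        ch <- seq_chars(g)[[1]]
        au <- which(ch %in% c("A", "U") & seq_along(ch) > 6 &
                      seq_along(ch) < 19)
        for (i in au) {
          if (gc_count_of(g) > cfg$gc_max) break
          for (b in c("G", "C")) {
            cand <- g; substr(cand, i, i) <- b
            if (!has_stretch(cand, cfg$stretch_len)) { g <- cand; break }
          }
        }
        g
      },
      POS19_NOT_GC = { substr(g, 19, 19) <- "A"; g },
      # location rules keep a fully compliant sequence
      ORF_EDGE = g,
      MASKED = g,
      stop("unknown decoy rule: ", rule))
    viol <- character(0)
    if (substr(g2, 1, 1) != "U") viol <- c(viol, "POS1_NOT_U")
    if (!substr(g2, 2, 5) %in% potent) {
      viol <- c(viol, "NUCLEATION_NOT_POTENT")
    }
    if (has_stretch(g2, cfg$stretch_len)) viol <- c(viol, "STRETCH")
    gc <- gc_count_of(g2)
    if (gc < cfg$gc_min || gc > cfg$gc_max) viol <- c(viol, "GC_CONTENT")
    if (!substr(g2, 19, 19) %in% c("G", "C")) {
      viol <- c(viol, "POS19_NOT_GC")
    }
    want <- setdiff(rule, c("ORF_EDGE", "MASKED"))
    if (identical(sort(viol), sort(want))) return(g2)
  }
}

#' Generate a synthetic transcriptome with planted sites
#'
#' Builds random coding sequences, embeds compliant target sites, decoys
#' (one per filter rule by default, each violating exactly that rule),
#' and cross-gene duplicate sites, then sweeps the background so that no
#' unplanned window passes the filter cascade. Planted items and their
#' expected design outcome are recorded in a truth table.
#'
#' @param spec a [fixture_spec()].
#' @param outdir optional directory; when given, writes `cds.fa`,
#'   `genes.tsv`, `masks.bed` and `truth.tsv` (TSVs carry the spec in a
#'   header comment) and returns the paths.
#' @param config a [design_config()]; the planted sites comply with it.
#' @return list with `transcripts` (list of `transcript_record`), `truth`
#'   (data.frame: gene, transcript, start, target_site, kind, expected,
#'   reason) and, if `outdir` was given, `paths`.
#' @export
synth_transcriptome <- function(spec = fixture_spec(), outdir = NULL,
                                config = design_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  catalog <- build_potency_catalog(4, c(config$gmin, config$gmax),
                                   config$thermo)
  potent <- potent_kmers(catalog)
  not_potent <- setdiff(catalog$entries$kmer, potent)
  rules <- c("POS1_NOT_U", "NUCLEATION_NOT_POTENT", "ORF_EDGE", "STRETCH",
             "GC_CONTENT", "POS19_NOT_GC", "MASKED")
  n_decoys <- spec$decoys_per_rule * length(rules)
  lens <- sample(seq(spec$cds_length[1], spec$cds_length[2]), spec$n_genes,
                 replace = TRUE)
  genes <- sprintf("GENE%02d", seq_len(spec$n_genes))
  txids <- sprintf("TX%02d", seq_len(spec$n_genes))
  seqs <- vapply(lens, random_rna, character(1), gc = spec$gc_fraction)
  names(seqs) <- txids

  truth <- data.frame(gene = character(0), transcript = character(0),
                      start = integer(0), target_site = character(0),
                      kind = character(0), expected = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  masks <- data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  occupied <- lapply(seq_len(spec$n_genes), function(i) integer(0))

  place <- function(gi, site, interior = TRUE) {
    len <- lens[gi]
    lo <- if (interior) config$edge_exclude else 30L
    hi0 <- len - 19L - config$edge_exclude
    for (try in 1:200) {
      s <- if (interior) sample(lo:hi0, 1) else sample(30:80, 1)
      win <- s:(s + 18L)
      if (length(intersect(win, occupied[[gi]])) > 0L) next
      substr(seqs[gi], s + 1L, s + 19L) <<- site
      # reserve a one-window buffer so planted windows never overlap
      occupied[[gi]] <<- c(occupied[[gi]], (s - 19L):(s + 37L))
      return(s)
    }
    stop("could not place a site: transcript too crowded; enlarge ",
         "cds_length or reduce the number of planted items", call. = FALSE)
  }

  add_truth <- function(gi, s, site, kind, expected, reason) {
    truth[nrow(truth) + 1L, ] <<- list(genes[gi], txids[gi], s, site, kind,
                                       expected, reason)
  }

  gi_seq <- rep(seq_len(spec$n_genes), length.out = max(1L, spec$n_planted))
  if (spec$n_planted > 0L) {
    for (j in seq_len(spec$n_planted)) {
      gi <- gi_seq[j]
      site <- rna_revcomp(sample_compliant_guide(potent, config))
      s <- place(gi, site)
      add_truth(gi, s, site, "planted", "accept", "")
    }
  }
  for (r in rules) {
    for (d in seq_len(spec$decoys_per_rule)) {
      gi <- sample(spec$n_genes, 1)
      g <- make_decoy_guide(r, potent, not_potent, config)
      site <- rna_revcomp(g)
      s <- place(gi, site, interior = r != "ORF_EDGE")
      if (r == "MASKED") {
        masks[nrow(masks) + 1L, ] <- list(txids[gi], s + 5L, s + 9L)
      }
      add_truth(gi, s, site, paste0("decoy_", r), "reject", r)
    }
  }
  if (spec$n_offtarget_duplicates > 0L && spec$n_genes >= 2L) {
    for (d in seq_len(spec$n_offtarget_duplicates)) {
      gis <- sample(spec$n_genes, 2)
      site <- rna_revcomp(sample_compliant_guide(potent, config))
      s1 <- place(gis[1], site)
      s2 <- place(gis[2], site)
      add_truth(gis[1], s1, site, "offtarget_dup", "reject", "OFFTARGET")
      add_truth(gis[2], s2, site, "offtarget_dup", "reject", "OFFTARGET")
    }
  }

  # sweep the background: break any unplanned window that would pass the
  # sequence/location rules, flipping a base outside every planted window
  planted_pos <- split(truth$start, truth$transcript)
  for (sweep in 1:50) {
    txs <- lapply(seq_len(spec$n_genes), function(i) {
      tr <- transcript_record(txids[i], genes[i], seqs[i],
                              as.matrix(masks[masks$transcript == txids[i],
                                              c("start", "end")]))
    })
    scans <- data.table::rbindlist(
      lapply(txs, scan_transcript, catalog = catalog, config = config))
    okd <- as.data.frame(scans)[scans$ok, ]
    keys <- paste(truth$transcript, truth$start)
    unplanned <- okd[!paste(okd$transcript, okd$start) %in% keys, , drop = FALSE]
    if (nrow(unplanned) == 0L) break
    for (i in seq_len(nrow(unplanned))) {
      gi <- match(unplanned$transcript[i], txids)
      win <- unplanned$start[i]:(unplanned$start[i] + 18L)
      prot <- unlist(lapply(planted_pos[[txids[gi]]],
                            function(s) s:(s + 18L)))
      free <- setdiff(win, prot)
      if (length(free) == 0L) next  # overlaps only planted bases; leave it
      last_pos <- unplanned$start[i] + 18L
      first_pos <- unplanned$start[i]
      if (last_pos %in% free) {
        # target position 19 != A <=> guide position 1 != U: a stable break
        substr(seqs[gi], last_pos + 1L, last_pos + 1L) <- "G"
      } else if (first_pos %in% free) {
        # target position 1 = A <=> guide position 19 = U: POS19 rule fails
        substr(seqs[gi], first_pos + 1L, first_pos + 1L) <- "A"
      } else {
        pos <- free[length(free)]
        cur <- substr(seqs[gi], pos + 1L, pos + 1L)
        substr(seqs[gi], pos + 1L, pos + 1L) <- if (cur == "A") "C" else "A"
      }
    }
  }

  transcripts <- lapply(seq_len(spec$n_genes), function(i) {
    transcript_record(txids[i], genes[i], seqs[i],
                      as.matrix(masks[masks$transcript == txids[i],
                                      c("start", "end")]))
  })
  out <- list(transcripts = transcripts, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(cds = file.path(outdir, "cds.fa"),
                  genes = file.path(outdir, "genes.tsv"),
                  masks = file.path(outdir, "masks.bed"),
                  truth = file.path(outdir, "truth.tsv"))
    writeLines(paste0(">", txids, "\n", seqs), paths$cds)
    writeLines(c(spec_header(spec),
                 paste(txids, genes, sep = "\t")), paths$genes)
    writeLines(sprintf("%s\t%d\t%d", masks$transcript, masks$start,
                       masks$end), paths$masks)
    con <- file(paths$truth, "w")
    writeLines(spec_header(spec), con)
    utils::write.table(truth, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    out$paths <- paths
  }
  out
}

#' Generate a synthetic siRNA screen
#'
#' Random 19-nt duplexes whose activity follows a piecewise-linear function
#' of the antisense nucleation energy dG[2:6]: a plateau inside the potency
#' window and linear decline outside it, plus Gaussian noise.
#'
#' @param spec a [fixture_spec()].
#' @param outdir optional directory; writes `screen.tsv` when given.
#' @param config a [thermo_config()].
#' @return data.frame with `antisense`, `sense`, `dg26`, `activity`;
#'   attribute `truth` carries the generating parameters.
#' @export
synth_screen <- function(spec = fixture_spec(), outdir = NULL,
                         config = thermo_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  anti <- vapply(seq_len(spec$screen_n), function(i) random_rna(19, 0.5),
                 character(1))
  dg <- kmer_energies(substr(anti, 2, 6), config)
  lo <- spec$plateau_window[1]; hi <- spec$plateau_window[2]
  mu <- spec$plateau_activity -
    spec$decline_slope * pmax(0, lo - dg) -
    spec$decline_slope * pmax(0, dg - hi)
  act <- mu + stats::rnorm(length(mu), sd = spec$screen_noise_sd)
  out <- data.frame(antisense = anti, sense = rna_revcomp(anti),
                    dg26 = dg, activity = act, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(plateau_window = spec$plateau_window,
                             plateau_activity = spec$plateau_activity,
                             decline_slope = spec$decline_slope,
                             noise_sd = spec$screen_noise_sd, mean = mu)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outdir, "screen.tsv")
    con <- file(path, "w")
    writeLines(spec_header(spec), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    attr(out, "path") <- path
  }
  out
}

#' Generate a synthetic dose-response table
#'
#' Four-parameter logistic responses over a log-spaced dose ladder with
#' replicates and Gaussian noise.
#'
#' @param spec a [fixture_spec()].
#' @param outdir optional directory; writes `dose_response.tsv` when given.
#' @return data.frame with `concentration` (nM), `replicate`, `response`;
#'   attribute `truth` carries the generating parameters.
#' @export
synth_dose_response <- function(spec = fixture_spec(), outdir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  doses <- 10^seq(log10(spec$dose_range[1]), log10(spec$dose_range[2]),
                  length.out = spec$n_doses)
  grid <- expand.grid(concentration = doses,
                      replicate = seq_len(spec$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- spec$floor + (spec$ceiling - spec$floor) /
    (1 + (grid$concentration / spec$ic50)^spec$hill)
  out <- data.frame(concentration = grid$concentration,
                    replicate = grid$replicate,
                    response = mu + stats::rnorm(nrow(grid),
                                                 sd = spec$dose_noise_sd))
  attr(out, "truth") <- list(ic50 = spec$ic50, hill = spec$hill,
                             floor = spec$floor, ceiling = spec$ceiling,
                             noise_sd = spec$dose_noise_sd)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outdir, "dose_response.tsv")
    con <- file(path, "w")
    writeLines(spec_header(spec), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    attr(out, "path") <- path
  }
  out
}
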