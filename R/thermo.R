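#' Nearest-neighbor duplex thermodynamics
#'
#' Free energies of short, perfectly complementary RNA:RNA duplexes at 37 C,
#' computed from a nearest-neighbor parameter table under an N-padding
#' convention: one unknown base (N) is appended at both ends of both strands
#' so that helix ends are scored with unknown-base terminal mismatches rather
#' than sequence-specific dangling ends. An interior N (the abasic pivot)
#' splits the helix and is scored as a 1x1 internal loop over unknown bases.
#'
#' @name thermo
NULL

.param_cache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor parameter set
#'
#' Parameter tables ship as plain-text TSV files under
#' `inst/extdata/nn_rna_<set>.tsv`. Energies are stored in kcal/mol and
#' converted to integer tenths internally so stack sums are exact.
#'
#' @param parameter_set identifier, currently `"turner2004"`.
#' @return list with integer-tenths components `stack` (named by doublet),
#'   `init`, `terminal_au`, `mm_ext` (named by closing pair), `int11`
#'   (named by "left.right" closing-pair keys).
#' @keywords internal
load_nn_params <- function(parameter_set = "turner2004") {
  key <- parameter_set
  if (!is.null(.param_cache[[key]])) return(.param_cache[[key]])
  path <- system.file("extdata", sprintf("nn_rna_%s.tsv", parameter_set),
                      package = "abasicsirna")
  if (path == "") {
    stop("unknown parameter set: ", parameter_set, call. = FALSE)
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  deka <- as.integer(round(tab$dg * 10))
  pick <- function(cat) {
    sel <- tab$category == cat
    stats::setNames(deka[sel], tab$key[sel])
  }
  p <- list(
    stack       = pick("stack"),
    init        = unname(pick("init")),
    terminal_au = unname(pick("terminal_au")),
    mm_ext      = pick("mismatch_ext_nn"),
    int11       = pick("int11_nn")
  )
  # reverse-complement symmetry of the stack table is a structural invariant
  rc2 <- rna_revcomp(names(p$stack))
  stopifnot(all(p$stack == p$stack[rc2]))
  .param_cache[[key]] <- p
  p
}

#' Thermodynamic engine configuration
#'
#' @param parameter_set nearest-neighbor table identifier (default
#'   `"turner2004"`, the default set of standard RNA duplex programs).
#' @param include_initiation include the duplex initiation term.
#' @param include_terminal_au include the terminal A:U penalty.
#' @param pad_with_n score helix ends as N/N terminal mismatches, emulating
#'   one N appended at both ends of both strands. This is the convention the
#'   potency window and all printed anchor energies were calibrated under.
#' @param engine `"internal"` for the built-in nearest-neighbor engine or
#'   `"oracle"` to delegate to an external reference duplex program
#'   (`RNAduplex` on the PATH) on identically N-padded input.
#' @return object of class `thermo_config`.
#' @export
thermo_config <- function(parameter_set = "turner2004",
                          include_initiation = TRUE,
                          include_terminal_au = TRUE,
                          pad_with_n = TRUE,
                          engine = c("internal", "oracle")) {
  engine <- match.arg(engine)
  structure(list(parameter_set = parameter_set,
                 include_initiation = isTRUE(include_initiation),
                 include_terminal_au = isTRUE(include_terminal_au),
                 pad_with_n = isTRUE(pad_with_n),
                 engine = engine),
            class = "thermo_config")
}

# closing-pair key for the left helix end / left int11 closure: base X paired
# with its complement, read 5'->3' on the strand carrying X
pair_key_left <- function(base) paste0(base, RNA_COMPLEMENT[base])
# closing-pair key as read outward at the right helix end (or rightward int11
# closure): complement first
pair_key_right <- function(base) paste0(RNA_COMPLEMENT[base], base)

#' Internal scalar engine over integer tenths of kcal/mol
#'
#' @param core character scalar over {A,C,G,U,N}.
#' @param cfg `thermo_config`.
#' @return integer tenths of kcal/mol.
#' @keywords internal
duplex_energy_deka <- function(core, cfg) {
  p <- load_nn_params(cfg$parameter_set)
  ch <- seq_chars(core)[[1]]
  # leading/trailing N runs merge with the padding and contribute nothing
  real <- which(ch != "N")
  if (length(real) == 0L) {
    stop("core is all N: duplex energy undefined", call. = FALSE)
  }
  ch <- ch[real[1L]:real[length(real)]]
  n <- length(ch)
  is_n <- ch == "N"
  # segments of contiguous pairable bases separated by single interior Ns
  r <- rle(is_n)
  if (any(r$values & r$lengths > 1L)) {
    stop("runs of more than one interior N are not supported ",
         "(only a single abasic/unknown position may interrupt the helix)",
         call. = FALSE)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_start <- starts[!r$values]
  seg_end <- ends[!r$values]
  if (max(seg_end - seg_start + 1L) < 2L) {
    stop("core must contain at least 2 contiguous pairable bases",
         call. = FALSE)
  }
  e <- 0L
  # stacks within segments
  for (s in seq_along(seg_start)) {
    i <- seg_start[s]; j <- seg_end[s]
    if (j > i) {
      doublets <- paste0(ch[i:(j - 1L)], ch[(i + 1L):j])
      e <- e + sum(p$stack[doublets])
    }
  }
  # 1x1 unknown-base internal loops between consecutive segments
  if (length(seg_start) > 1L) {
    for (s in seq_len(length(seg_start) - 1L)) {
      left <- pair_key_left(ch[seg_end[s]])
      right <- pair_key_right(ch[seg_start[s + 1L]])
      e <- e + p$int11[paste0(left, ".", right)]
    }
  }
  first <- ch[1L]; last <- ch[n]
  if (cfg$include_initiation) e <- e + p$init
  if (cfg$include_terminal_au) {
    e <- e + (first %in% c("A", "U")) * p$terminal_au
    e <- e + (last %in% c("A", "U")) * p$terminal_au
  }
  if (cfg$pad_with_n) {
    e <- e + p$mm_ext[pair_key_left(first)] + p$mm_ext[pair_key_right(last)]
  }
  as.integer(e)
}

#' Duplex free energy of a core against its perfect reverse complement
#'
#' Computes the hybridization free energy of `core` with its Watson-Crick
#' reverse complement, with one N appended at both ends of both strands
#' (default), so that no sequence-specific dangling-end term from real bases
#' is added. An interior N (abasic spacer) is unpaired on both strands and
#' scored as a 1x1 internal loop over unknown bases.
#'
#' @param core RNA sequence(s), length 2..21, each containing at least two
#'   contiguous pairable bases. Vectorized.
#' @param config a [thermo_config()].
#' @return numeric vector of free energies in kcal/mol
#'   (negative = more stable).
#' @examples
#' duplex_energy("AGCA")  # transitional nucleation of the PCS-B1 guide
#' duplex_energy("UUCA")  # transitional nucleation of the siE6 guide
#' @export
duplex_energy <- function(core, config = thermo_config()) {
  assert_rna(core, "core")
  if (any(nchar(core) < 2L | nchar(core) > 21L)) {
    stop("core length must be in 2..21", call. = FALSE)
  }
  if (config$engine == "oracle") {
    return(rnaduplex_energy(core, pad_with_n = config$pad_with_n))
  }
  vapply(core, function(s) duplex_energy_deka(s, config) / 10,
         numeric(1), USE.NAMES = FALSE)
}

#' Vectorized duplex energies for equal-length N-free k-mers
#'
#' Fast path used by the catalog and the designer scan; identical results to
#' [duplex_energy()] for N-free input.
#'
#' @param kmers character vector of N-free RNA k-mers, k >= 2.
#' @param config a [thermo_config()] with `engine = "internal"`.
#' @return numeric vector, kcal/mol.
#' @keywords internal
kmer_energies <- function(kmers, config = thermo_config()) {
  p <- load_nn_params(config$parameter_set)
  k <- nchar(kmers[1L])
  stopifnot(all(nchar(kmers) == k), k >= 2L, !grepl("N", kmers, fixed = TRUE))
  e <- integer(length(kmers))
  for (i in seq_len(k - 1L)) {
    e <- e + p$stack[substr(kmers, i, i + 1L)]
  }
  first <- substr(kmers, 1L, 1L)
  last <- substr(kmers, k, k)
  if (config$include_initiation) e <- e + p$init
  if (config$include_terminal_au) {
    e <- e + (first %in% c("A", "U")) * p$terminal_au +
      (last %in% c("A", "U")) * p$terminal_au
  }
  if (config$pad_with_n) {
    e <- e + p$mm_ext[pair_key_left(first)] + p$mm_ext[pair_key_right(last)]
  }
  unname(e) / 10
}

#' Free energy of a guide region
#'
#' Duplex free energy of `guide[first..last]` against its perfect complement,
#' with the abasic position (if it falls inside the region) substituted by N.
#' Region (2,5) yields the transitional-nucleation energy dG[2:5] of an
#' abasic-pivot siRNA, (2,6) yields dG[2:6] of an intact guide, and (2,19)
#' yields the total duplex energy dG_t.
#'
#' @param guide a [guide_record()] or a 19-nt RNA sequence.
#' @param first,last region bounds, 1 <= first < last <= 19 (guide positions,
#'   5'->3').
#' @param config a [thermo_config()].
#' @param abasic_position abasic position override when `guide` is a plain
#'   sequence; ignored when `guide` is a `guide_record`.
#' @return free energy in kcal/mol.
#' @examples
#' pcs_b1 <- guide_record(rna_revcomp("UUCUAGACCUGUUUUGCUU"), abasic_position = 6)
#' region_energy(pcs_b1, 2, 5)   # -3.6
#' @export
region_energy <- function(guide, first, last, config = thermo_config(),
                          abasic_position = NULL) {
  if (inherits(guide, "guide_record")) {
    abasic_position <- guide$abasic_position
    guide <- guide$guide
  }
  assert_rna(guide, "guide")
  if (nchar(guide) != 19L) {
    stop("guide must be 19 nt", call. = FALSE)
  }
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first < 1L || last > 19L ||
      first >= last) {
    stop("region must satisfy 1 <= first < last <= 19", call. = FALSE)
  }
  if (!is.null(abasic_position) && abasic_position >= 1L &&
      abasic_position <= nchar(guide)) {
    substr(guide, abasic_position, abasic_position) <- "N"
  }
  duplex_energy(substr(guide, first, last), config)
}

#' Strand bias of an siRNA duplex
#'
#' The difference in transitional-nucleation stability between the two
#' strands, ddG = dG[2:6](antisense) - dG[2:6](sense). Negative values favor
#' antisense (guide) loading into Argonaute and were the high-confidence
#' selection criterion for screening data.
#'
#' @param sense,antisense 19-nt RNA sequences.
#' @param config a [thermo_config()].
#' @return ddG in kcal/mol.
#' @export
strand_bias <- function(sense, antisense, config = thermo_config()) {
  assert_rna(sense, "sense"); assert_rna(antisense, "antisense")
  if (nchar(sense) != 19L || nchar(antisense) != 19L) {
    stop("both strands must be 19 nt", call. = FALSE)
  }
  region_energy(antisense, 2, 6, config) - region_energy(sense, 2, 6, config)
}
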