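#' RNA sequence utilities
#'
#' Sequences are plain uppercase character strings over the alphabet
#' A, C, G, U, N. The abasic spacer (a backbone unit with no base) is
#' represented as `N`: it never pairs and contributes no stacking or
#' dangling energy.
#'
#' @name sequences
NULL

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

#' Validate an RNA sequence
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
assert_rna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) == 0L || anyNA(x)) {
    stop(what, " must be a non-missing character vector", call. = FALSE)
  }
  if (any(nchar(x) == 0L)) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  bad <- grepl(sprintf("[^%s]", paste(RNA_ALPHABET, collapse = "")), x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,U,N}: ",
         x[bad][1L], call. = FALSE)
  }
  invisible(x)
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U so DNA-alphabet FASTA input can be
#' consumed directly.
#'
#' @param x character vector.
#' @return character vector over {A,C,G,U,N}.
#' @export
as_rna <- function(x) {
  x <- chartr("acgutnT", "ACGUUNU", toupper(x))
  assert_rna(x)
  x
}

#' Reverse complement of RNA sequences
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorized.
#'
#' @param x character vector of RNA sequences over {A,C,G,U,N}.
#' @return character vector of reverse complements.
#' @examples
#' rna_revcomp("GUGCCAGAAACCGUUGAAU")
#' @export
rna_revcomp <- function(x) {
  assert_rna(x)
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Split sequences into character matrices
#' @keywords internal
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)
}

#' A 19-nt guide strand with an optional abasic position
#'
#' Constructs a guide record for an siRNA guide (antisense) strand,
#' numbered 1..19 from its 5' end. 3' overhangs (e.g. dTdT) are excluded:
#' they take no part in the energy model. An abasic spacer at the pivot
#' (position 6) defines the off-target-free configuration.
#'
#' @param guide 19-nt RNA sequence (character scalar).
#' @param abasic_position optional integer in 1..19; `6` for the abasic-pivot
#'   configuration, `NULL` for an unmodified guide.
#' @param passenger optional passenger (sense) strand sequence.
#' @return an object of class `guide_record`.
#' @examples
#' g <- guide_record("AAGCAAAACAGGUCUAGAA", abasic_position = 6)
#' @export
guide_record <- function(guide, abasic_position = NULL, passenger = NULL) {
  assert_rna(guide, "guide")
  if (length(guide) != 1L || nchar(guide) != 19L) {
    stop("guide must be a single 19-nt sequence", call. = FALSE)
  }
  if (!is.null(abasic_position)) {
    abasic_position <- as.integer(abasic_position)
    if (length(abasic_position) != 1L || is.na(abasic_position) ||
        abasic_position < 1L || abasic_position > 19L) {
      stop("abasic_position must be a single integer in 1..19", call. = FALSE)
    }
  }
  if (!is.null(passenger)) assert_rna(passenger, "passenger")
  structure(list(guide = guide, abasic_position = abasic_position,
                 passenger = passenger),
            class = "guide_record")
}

#' @export
print.guide_record <- function(x, ...) {
  shown <- x$guide
  if (!is.null(x$abasic_position)) {
    substr(shown, x$abasic_position, x$abasic_position) <- "X"
  }
  cat("siRNA guide (5'->3'): ", shown, "\n", sep = "")
  if (!is.null(x$abasic_position)) {
    cat("abasic spacer at position ", x$abasic_position, "\n", sep = "")
  }
  invisible(x)
}
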