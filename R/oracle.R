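#' External reference duplex engine
#'
#' Delegates energy evaluation to the `RNAduplex` program (ViennaRNA) on the
#' same N-padded input the internal engine models: each core and its perfect
#' reverse complement get one N appended at both ends. Used as the
#' independent oracle for the internal nearest-neighbor engine.
#'
#' @param core character vector of RNA cores over {A,C,G,U,N}.
#' @param pad_with_n append one N at both ends of both strands.
#' @return numeric vector of duplex free energies in kcal/mol.
#' @export
rnaduplex_energy <- function(core, pad_with_n = TRUE) {
  assert_rna(core, "core")
  exe <- Sys.which("RNAduplex")
  if (exe == "") {
    stop("RNAduplex not found on PATH; the external oracle engine is ",
         "unavailable", call. = FALSE)
  }
  rc <- rna_revcomp(core)
  if (pad_with_n) {
    core <- paste0("N", core, "N")
    rc <- paste0("N", rc, "N")
  }
  input <- paste(rbind(core, rc), collapse = "\n")
  out <- system2(exe, stdout = TRUE, input = input)
  out <- out[grepl("\\(\\s*-?[0-9.]+\\)\\s*$", out)]
  if (length(out) != length(rc)) {
    stop("unexpected RNAduplex output (", length(out), " results for ",
         length(rc), " inputs)", call. = FALSE)
  }
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", out))
}
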