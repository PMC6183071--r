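#' Screening-data statistics
#'
#' Operations over siRNA screening tables (19-nt antisense sequence plus a
#' measured activity): high-confidence selection by position-1 base and
#' strand bias, frequency-weighted family energies, energy-normalized
#' correlation, and energy-binned activity summaries.
#'
#' @name screen_analysis
NULL

#' Select high-confidence screening records
#'
#' Keeps records whose antisense position-1 base lies in `pos1_alphabet`
#' and, optionally, whose strand bias ddG = dG[2:6](antisense) -
#' dG[2:6](sense) is negative (antisense-favored Argonaute loading). Input
#' order is preserved; the two filter counts are reported separately in the
#' `summary` attribute.
#'
#' @param records data.frame with columns `antisense` (19-nt), optionally
#'   `sense` (19-nt), and any activity columns, which are carried through.
#' @param pos1_alphabet allowed antisense position-1 bases.
#' @param require_ddg_negative also require ddG < 0 (needs `sense`).
#' @param config a [thermo_config()].
#' @return subset of `records`, with attribute `summary` = list(n_input,
#'   n_pos1, n_selected).
#' @export
select_high_confidence <- function(records, pos1_alphabet = c("U", "A"),
                                   require_ddg_negative = FALSE,
                                   config = thermo_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- records
    attr(out, "summary") <- list(n_input = 0L, n_pos1 = 0L, n_selected = 0L)
    return(out)
  }
  assert_rna(records$antisense, "antisense")
  keep_pos1 <- substr(records$antisense, 1, 1) %in% pos1_alphabet
  keep <- keep_pos1
  if (require_ddg_negative) {
    if (is.null(records$sense)) {
      stop("sense strands are required when require_ddg_negative = TRUE",
           call. = FALSE)
    }
    ok_sense <- !is.na(records$sense) & nchar(records$sense) == 19L
    if (any(!ok_sense)) {
      warning(sum(!ok_sense), " record(s) without a valid sense strand ",
              "dropped from the strand-bias filter", call. = FALSE)
    }
    ddg <- rep(NA_real_, nrow(records))
    idx <- which(keep_pos1 & ok_sense)
    ddg[idx] <- vapply(idx, function(i) {
      strand_bias(records$sense[i], records$antisense[i], config)
    }, numeric(1))
    keep <- keep_pos1 & ok_sense & !is.na(ddg) & ddg < 0
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(n_input = nrow(records),
                               n_pos1 = sum(keep_pos1),
                               n_selected = sum(keep))
  out
}

#' Frequency-weighted family energy
#'
#' Average free energy of a small-RNA family, weighted by the sequencing
#' frequency of each member: sum(frequency_i * dg_i) / sum(frequency_i).
#'
#' @param dg numeric free energies of the members (kcal/mol).
#' @param frequency non-negative weights (e.g. Argonaute-associated read
#'   counts); total must be positive.
#' @return weighted mean energy in kcal/mol.
#' @export
weighted_family_energy <- function(dg, frequency) {
  stopifnot(length(dg) == length(frequency), all(frequency >= 0))
  tot <- sum(frequency)
  if (tot <= 0) stop("total frequency must be positive", call. = FALSE)
  sum(frequency * dg) / tot
}

#' Energy-normalized target-site correlation
#'
#' Coefficient of determination (squared Pearson correlation, equivalent to
#' the OLS R-squared with intercept) between small-RNA expression and its
#' target-site count, either raw or with the count normalized by the
#' negative nucleation free energy (`site_count / (-dg)`).
#'
#' @param rows data.frame with columns `expression` (log2 abundance),
#'   `site_count` (non-negative) and `dg` (kcal/mol, negative in normalized
#'   mode).
#' @param mode `"energy_normalized"` or `"raw"`.
#' @return R-squared.
#' @export
normalized_correlation <- function(rows,
                                   mode = c("energy_normalized", "raw")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(rows),
            all(c("expression", "site_count", "dg") %in% names(rows)))
  if (nrow(rows) < 3L) stop("at least 3 rows are required", call. = FALSE)
  x <- rows$site_count
  if (mode == "energy_normalized") {
    if (any(rows$dg >= 0)) {
      stop("all dg must be negative in energy_normalized mode",
           call. = FALSE)
    }
    x <- rows$site_count / (-rows$dg)
  }
  if (stats::sd(x) == 0 || stats::sd(rows$expression) == 0) {
    stop("degenerate fit: zero variance", call. = FALSE)
  }
  unname(stats::cor(rows$expression, x)^2)
}

#' Bin screening activity by nucleation energy
#'
#' Assigns each record to the left-closed energy bin (anchored at 0
#' kcal/mol) containing its antisense dG[2:6] and reports per-bin counts and
#' mean activity. Empty bins are omitted.
#'
#' @param records data.frame with columns `antisense` (19-nt) and
#'   `activity`.
#' @param bin_width positive bin width in kcal/mol.
#' @param config a [thermo_config()].
#' @return data.frame with `bin_lo`, `bin_hi` (bin is `[bin_lo, bin_hi)`),
#'   `n`, `mean_activity`, ordered by `bin_lo`.
#' @export
bin_activity_by_energy <- function(records, bin_width = 0.5,
                                   config = thermo_config()) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  assert_rna(records$antisense, "antisense")
  dg <- kmer_energies(substr(records$antisense, 2, 6), config)
  idx <- floor(round(dg, 6) / bin_width)
  agg <- stats::aggregate(records$activity, by = list(idx = idx),
                          FUN = function(v) c(n = length(v), m = mean(v)))
  out <- data.frame(bin_lo = agg$idx * bin_width,
                    bin_hi = (agg$idx + 1) * bin_width,
                    n = as.integer(agg$x[, "n"]),
                    mean_activity = agg$x[, "m"])
  out[order(out$bin_lo), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
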