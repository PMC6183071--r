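#' Nucleation k-mer catalogs and distribution comparisons
#'
#' Enumerates all nucleation k-mers (4-mers for the abasic-pivot
#' configuration, whose transitional nucleation spans guide positions 2-5;
#' 5-mers for intact guides, positions 2-6), scores each by the N-padded
#' duplex engine, and flags the potent set: k-mers whose nucleation free
#' energy falls inclusively inside the potency window, by default
#' [-6, -3.5] kcal/mol.
#'
#' @name catalog
NULL

#' Build the potency catalog of nucleation k-mers
#'
#' @param k k-mer length, 1..8 (4 for abasic-pivot siRNAs).
#' @param window numeric length-2, inclusive energy window (kcal/mol),
#'   `c(g_min, g_max)` with `g_min <= g_max`.
#' @param config a [thermo_config()].
#' @return object of class `potency_catalog`: list with `k`, `window` and
#'   `entries`, a data.frame of all `4^k` k-mers with columns `kmer`, `dg`
#'   and `selected`. Energies are rounded to 0.01 kcal/mol before the window
#'   test (nearest-neighbor parameters are tabulated constants, so this is
#'   exact).
#' @examples
#' cat4 <- build_potency_catalog()
#' sum(cat4$entries$selected)  # 94
#' @export
build_potency_catalog <- function(k = 4, window = c(-6, -3.5),
                                  config = thermo_config()) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 8L) stop("k must be in 1..8", call. = FALSE)
  if (length(window) != 2L || any(!is.finite(window) & !is.infinite(window)) ||
      window[1] > window[2]) {
    stop("window must be c(g_min, g_max) with g_min <= g_max", call. = FALSE)
  }
  bases <- c("A", "C", "G", "U")
  grid <- do.call(expand.grid,
                  c(rev(rep(list(bases), k)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, rev(grid))  # lexicographic order
  if (k == 1L) {
    # single base pairs cannot stack; score via the scalar engine's rules is
    # undefined, so a 1-mer catalog carries NA energies and selects nothing
    dg <- rep(NA_real_, length(kmers))
    selected <- rep(FALSE, length(kmers))
  } else {
    dg <- kmer_energies(kmers, config)
    dgr <- round(dg, 2)
    selected <- dgr >= window[1] & dgr <= window[2]
  }
  structure(list(k = k, window = window,
                 entries = data.frame(kmer = kmers, dg = dg,
                                      selected = selected,
                                      stringsAsFactors = FALSE)),
            class = "potency_catalog")
}

#' @export
print.potency_catalog <- function(x, ...) {
  cat(sprintf(
    "potency catalog: %d %d-mers, %d selected in [%.2f, %.2f] kcal/mol\n",
    nrow(x$entries), x$k, sum(x$entries$selected),
    x$window[1], x$window[2]))
  invisible(x)
}

#' Selected k-mers of a potency catalog
#' @param catalog a `potency_catalog`.
#' @return character vector of selected k-mers.
#' @export
potent_kmers <- function(catalog) {
  stopifnot(inherits(catalog, "potency_catalog"))
  catalog$entries$kmer[catalog$entries$selected]
}

#' Empirical cumulative distribution of energies
#'
#' Standard ECDF over a set of free-energy values, the form used for
#' cumulative-fraction comparisons of nucleation stability distributions.
#'
#' @param values non-empty numeric vector (kcal/mol).
#' @return object of class `energy_ecdf`: data.frame with sorted unique
#'   `value` and non-decreasing `fraction` ending at 1.
#' @export
energy_ecdf <- function(values) {
  if (length(values) == 0L || !is.numeric(values) || anyNA(values)) {
    stop("values must be non-empty and finite", call. = FALSE)
  }
  v <- sort(unique(values))
  frac <- cumsum(tabulate(match(sort(values), v))) / length(values)
  structure(data.frame(value = v, fraction = frac),
            class = c("energy_ecdf", "data.frame"))
}

#' Evaluate an ECDF at given points
#' @param e an `energy_ecdf`.
#' @param q numeric query points.
#' @return cumulative fractions at `q`.
#' @export
ecdf_at <- function(e, q) {
  stopifnot(inherits(e, "energy_ecdf"))
  idx <- findInterval(q, e$value)
  c(0, e$fraction)[idx + 1L]
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided KS statistic D = sup |ECDF_a - ECDF_b| with the asymptotic
#' p-value (the convention of the usual scientific-computing KS routines).
#'
#' @param a,b non-empty numeric samples.
#' @return list with `d_statistic` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(d_statistic = unname(res$statistic), p_value = unname(res$p.value))
}
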