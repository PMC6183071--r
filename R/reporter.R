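#' Reporter-assay statistics
#'
#' Dose-response IC50 fitting for luciferase reporter assays, on-target
#' conservation ratios between unmodified and abasic-pivot siRNAs, and
#' cumulative-fraction derepression analysis on fold-change tables.
#'
#' @name reporter_stats
NULL

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least-squares fit of
#' `response = floor + (ceiling - floor) / (1 + (c / ic50)^hill)`
#' over all replicate points. Initialization is deterministic from the data
#' (ceiling = largest dose-mean, floor = smallest, ic50 = dose whose mean is
#' nearest half-range, hill = 1); bounds are `hill` in (0, 10], `floor >= 0`.
#'
#' @param data data.frame with columns `concentration` (nM, positive) and
#'   `response` (relative reporter activity, ~1 at zero inhibition);
#'   replicates are separate rows.
#' @param fix_asymptotes fix `floor = 0`, `ceiling = 1` instead of fitting
#'   them.
#' @return object of class `ic50_fit`: list with `ic50` (nM), `hill`,
#'   `floor`, `ceiling`, `converged`, `residual_sse`, `n`. When no
#'   inhibition signal is present (or the optimizer fails), `converged` is
#'   FALSE and `ic50` is NA.
#' @export
fit_ic50 <- function(data, fix_asymptotes = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("concentration", "response") %in% names(data)))
  conc <- data$concentration; resp <- data$response
  if (any(conc <= 0) || any(!is.finite(conc)) || any(!is.finite(resp))) {
    stop("concentrations must be positive and responses finite",
         call. = FALSE)
  }
  if (length(unique(conc)) < 4L) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  dm <- tapply(resp, conc, mean)
  doses <- as.numeric(names(dm))
  hi <- max(dm); lo <- min(dm)
  fail <- function() {
    structure(list(ic50 = NA_real_, hill = NA_real_, floor = NA_real_,
                   ceiling = NA_real_, converged = FALSE,
                   residual_sse = NA_real_, n = length(resp)),
              class = "ic50_fit")
  }
  if (hi - lo < 1e-8) return(fail())  # flat: no inhibition signal
  mid <- (hi + lo) / 2
  lic0 <- log10(doses[which.min(abs(dm - mid))])
  df <- data.frame(lc = log10(conc), y = resp)
  fit <- tryCatch({
    if (fix_asymptotes) {
      minpack.lm::nlsLM(
        y ~ 1 / (1 + 10^(hill * (lc - lic))), data = df,
        start = list(lic = lic0, hill = 1),
        lower = c(lic = -12, hill = 1e-3),
        upper = c(lic = 12, hill = 10),
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 500))
    } else {
      minpack.lm::nlsLM(
        y ~ fl + (ce - fl) / (1 + 10^(hill * (lc - lic))), data = df,
        start = list(fl = lo, ce = hi, lic = lic0, hill = 1),
        lower = c(fl = 0, ce = lo, lic = -12, hill = 1e-3),
        upper = c(fl = hi, ce = Inf, lic = 12, hill = 10),
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 500))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  flr <- if (fix_asymptotes) 0 else unname(cf["fl"])
  cei <- if (fix_asymptotes) 1 else unname(cf["ce"])
  if (!(cei > flr) || cei - flr < 1e-6) return(fail())
  structure(list(ic50 = 10^unname(cf["lic"]), hill = unname(cf["hill"]),
                 floor = flr, ceiling = cei, converged = TRUE,
                 residual_sse = sum(stats::resid(fit)^2), n = length(resp)),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "4PL fit: IC50 = %.4g nM, hill = %.3g, floor = %.3g, ceiling = %.3g (n = %d, SSE = %.3g)\n",
      x$ic50, x$hill, x$floor, x$ceiling, x$n, x$residual_sse))
  } else {
    cat("4PL fit: did not converge (no inhibition signal?)\n")
  }
  invisible(x)
}

#' On-target conservation ratio
#'
#' `log2(ic50_wt / ic50_mod)`: the log ratio of the unmodified siRNA's IC50
#' to that of its abasic-pivot version. Negative values mean the modified
#' siRNA needs a higher dose, i.e. lost on-target activity.
#'
#' @param ic50_wt,ic50_mod positive IC50 values (nM).
#' @return log2 ratio.
#' @export
relative_on_target <- function(ic50_wt, ic50_mod) {
  if (any(ic50_wt <= 0) || any(ic50_mod <= 0)) {
    stop("IC50 values must be positive", call. = FALSE)
  }
  log2(ic50_wt / ic50_mod)
}

#' Cumulative derepression analysis
#'
#' ECDFs of log2 fold changes for a target set versus the background, plus
#' their two-sample Kolmogorov-Smirnov comparison. A target-set ECDF lying
#' left of the background indicates repression; coincidence (high KS p)
#' indicates derepression.
#'
#' @param table data.frame with columns `log2fc` and `membership`.
#' @param target_label value of `membership` defining the target set; all
#'   other rows form the background.
#' @return list with `ecdf_target`, `ecdf_background` (class `energy_ecdf`)
#'   and `ks` (list `d_statistic`, `p_value`).
#' @export
cumulative_derepression <- function(table, target_label = "target") {
  stopifnot(is.data.frame(table),
            all(c("log2fc", "membership") %in% names(table)))
  tg <- table$log2fc[table$membership == target_label]
  bg <- table$log2fc[table$membership != target_label]
  if (length(tg) == 0L || length(bg) == 0L) {
    stop("both the target set and the background must be non-empty",
         call. = FALSE)
  }
  list(ecdf_target = energy_ecdf(tg),
       ecdf_background = energy_ecdf(bg),
       ks = ks_two_sample(tg, bg))
}
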