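#' Fit activation thresholds from an untreated control population
#'
#' Activation cutoffs are taken from the upper tail of a dose-0 control:
#' `foxo_nf_cut` is the `q`-quantile of the control FOXO1 nuclear fraction and
#' `p53_log_cut` the `q`-quantile of control `log10` nuclear p53 (method
#' `"quantile"`, the default), or mean + 3 sd of the same quantities (method
#' `"mean_sd"`). By construction roughly `(1-q)` of the control itself exceeds
#' each cutoff.
#'
#' @param control a `snapshot_cells` data frame, all at dose 0, >= 100 cells.
#' @param q tail quantile (default 0.99).
#' @param method `"quantile"` or `"mean_sd"`.
#' @return object of class `activation_thresholds`: list with `foxo_nf_cut`,
#'   `p53_log_cut` and a `method` record.
#' @export
#' @examples
#' ctrl <- generate_snapshot(200, dose_preset(0), seed = 1)
#' fit_thresholds(ctrl)
fit_thresholds <- function(control, q = 0.99,
                           method = c("quantile", "mean_sd")) {
  method <- match.arg(method)
  if (!is.data.frame(control) ||
      !all(c("dose_uM", "foxo1_nf", "p53_nuc") %in% names(control))) {
    stop("input error: 'control' must be a snapshot table with dose_uM, foxo1_nf, p53_nuc")
  }
  if (nrow(control) < 100L) {
    stop("input error: control population must have >= 100 cells")
  }
  if (any(control$dose_uM != 0)) {
    stop("input error: control population contains non-zero doses")
  }
  lp <- log10(control$p53_nuc)
  if (method == "quantile") {
    fc <- stats::quantile(control$foxo1_nf, q, names = FALSE, type = 7)
    pc <- stats::quantile(lp, q, names = FALSE, type = 7)
  } else {
    fc <- mean(control$foxo1_nf) + 3 * stats::sd(control$foxo1_nf)
    pc <- mean(lp) + 3 * stats::sd(lp)
  }
  structure(list(foxo_nf_cut = fc, p53_log_cut = pc,
                 method = list(statistic = method,
                               parameter = if (method == "quantile") q else 3,
                               n_control = nrow(control))),
            class = "activation_thresholds")
}

#' @export
print.activation_thresholds <- function(x, ...) {
  cat(sprintf("activation thresholds (%s, parameter %g, n = %d control cells)\n",
              x$method$statistic, x$method$parameter, x$method$n_control))
  cat(sprintf("  FOXO1 nuclear fraction > %.4f\n", x$foxo_nf_cut))
  cat(sprintf("  log10 nuclear p53      > %.4f\n", x$p53_log_cut))
  invisible(x)
}

#' Classify snapshot cells into activation quadrants
#'
#' A cell is FOXO1-active iff its nuclear fraction strictly exceeds
#' `foxo_nf_cut`, and p53-active iff `log10(p53_nuc)` strictly exceeds
#' `p53_log_cut`; a cell exactly at a cutoff is not active (strict
#' inequality). The label is the conjunction: `both`, `foxo_only`,
#' `p53_only` or `neither`.
#'
#' @param cells snapshot table with `foxo1_nf` and `p53_nuc`.
#' @param th an [fit_thresholds()] object.
#' @return factor with levels `both`, `foxo_only`, `p53_only`, `neither`.
#' @export
classify_cells <- function(cells, th) {
  stopifnot(inherits(th, "activation_thresholds"))
  if (!all(c("foxo1_nf", "p53_nuc") %in% names(cells))) {
    stop("input error: 'cells' must contain foxo1_nf and p53_nuc")
  }
  f <- cells$foxo1_nf > th$foxo_nf_cut
  p <- log10(cells$p53_nuc) > th$p53_log_cut
  lab <- ifelse(f & p, "both",
         ifelse(f, "foxo_only",
         ifelse(p, "p53_only", "neither")))
  factor(lab, levels = c("both", "foxo_only", "p53_only", "neither"))
}

#' Per-dose quadrant fractions
#'
#' Tabulates the four activation-quadrant fractions per dose; the fractions
#' sum to one within each dose. The maximum dual-activation fraction over
#' doses (the mutual-exclusivity summary) is attached as attribute
#' `max_frac_both`.
#'
#' @param labels factor from [classify_cells()].
#' @param dose dose (uM) per cell, same length as `labels`.
#' @return data frame of class `quadrant_table` with columns `dose_uM`, `n`,
#'   `frac_both`, `frac_foxo_only`, `frac_p53_only`, `frac_neither`.
#' @export
quadrant_table <- function(labels, dose) {
  if (length(labels) != length(dose)) {
    stop("input error: 'labels' and 'dose' lengths differ")
  }
  if (length(labels) == 0L) stop("input error: empty dose group")
  tab <- table(dose, labels)
  if (any(rowSums(tab) == 0L)) stop("input error: empty dose group")
  fr <- prop.table(tab, margin = 1L)
  out <- data.frame(dose_uM = as.numeric(rownames(tab)),
                    n = as.integer(rowSums(tab)),
                    frac_both = as.numeric(fr[, "both"]),
                    frac_foxo_only = as.numeric(fr[, "foxo_only"]),
                    frac_p53_only = as.numeric(fr[, "p53_only"]),
                    frac_neither = as.numeric(fr[, "neither"]))
  out <- out[order(out$dose_uM), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_frac_both") <- max(out$frac_both)
  class(out) <- c("quadrant_table", "data.frame")
  out
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat("activation quadrant fractions by dose (max frac_both =",
      format(attr(x, "max_frac_both"), digits = 3), ")\n")
  NextMethod()
}
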