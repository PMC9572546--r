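#' Percent inhibition from plate signal ratios
#'
#' Normalizes sample signal ratios between the two plate controls:
#' `inhibition = 100 * (R_noCompound - R_sample) / (R_noCompound - R_noKinase)`,
#' so a sample indistinguishable from the compound-free control scores 0% and
#' one indistinguishable from the kinase-free control scores 100%. Replicated
#' control wells are averaged; replicated sample wells are averaged per
#' concentration. Invariant under any common positive rescaling of the
#' ratios.
#'
#' @param plate Data frame with columns `well`, `role` (one of `sample`,
#'   `no_compound_control`, `no_kinase_control`), `concentration_um` and
#'   `signal_ratio` (the 665 nm / 615 nm emission ratio).
#' @return Data frame `concentration_um, inhibition_percent, n_wells`,
#'   sorted by descending concentration.
#' @export
percent_inhibition <- function(plate) {
  needed <- c("role", "concentration_um", "signal_ratio")
  missing <- setdiff(needed, names(plate))
  if (length(missing)) {
    stop("plate table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  r_nc <- mean(plate$signal_ratio[plate$role == "no_compound_control"])
  r_nk <- mean(plate$signal_ratio[plate$role == "no_kinase_control"])
  if (!is.finite(r_nc) || !is.finite(r_nk)) {
    stop("plate must contain both control roles", call. = FALSE)
  }
  if (isTRUE(all.equal(r_nc, r_nk))) {
    stop("assay window collapsed: control ratios are equal", call. = FALSE)
  }
  samples <- plate[plate$role == "sample", , drop = FALSE]
  inh <- 100 * (r_nc - samples$signal_ratio) / (r_nc - r_nk)
  agg <- stats::aggregate(inh, by = list(concentration_um = samples$concentration_um),
                          FUN = mean)
  counts <- stats::aggregate(inh, by = list(concentration_um = samples$concentration_um),
                             FUN = length)
  out <- data.frame(concentration_um = agg$concentration_um,
                    inhibition_percent = agg$x, n_wells = counts$x)
  out <- out[order(-out$concentration_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serial dilution series
#'
#' Concentrations `initial / factor^k` for `k = 0 .. points - 1`, descending.
#'
#' @param initial_um Top concentration in micromolar; default 50.
#' @param points Number of points (>= 2); default 10.
#' @param factor Dilution factor (> 1); default 2 (two-fold).
#' @return Descending numeric vector of concentrations in micromolar.
#' @export
dilution_series <- function(initial_um = 50, points = 10, factor = 2) {
  if (!is.numeric(initial_um) || initial_um <= 0) {
    stop("initial concentration must be positive", call. = FALSE)
  }
  stopifnot(points >= 2, factor > 1)
  initial_um / factor^(seq_len(points) - 1)
}

# Four-parameter logistic on log10 concentration: response rises from
# `bottom` towards `top` with midpoint at log10(ic50) and slope `hill`.
fourpl <- function(logc, bottom, top, lic50, hill) {
  bottom + (top - bottom) / (1 + 10^((lic50 - logc) * hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Levenberg-Marquardt fit of inhibition (%) against log10 concentration with
#' all four parameters free: bottom and top box-constrained to \[-10, 110\]%,
#' the Hill slope to \[0.1, 10\], and log10(IC50) to the tested range widened
#' by three decades. Initial values take top/bottom from the data extremes,
#' IC50 from linear interpolation of the 50% crossing and Hill slope 1.
#'
#' Two potencies are reported: the relative IC50 (the fitted midpoint
#' between bottom and top) and the absolute IC50 (the concentration where the
#' fitted curve crosses 50% inhibition). When the maximum observed inhibition
#' never reaches 50% the result is right-censored at the highest tested
#' concentration (reported as `> max` rather than a number), and
#' non-convergence yields a censored result with diagnostics instead of an
#' exception.
#'
#' @param concentrations_um Positive concentrations (any order).
#' @param inhibition_percent Aligned inhibition values (%).
#' @return Object of class `dose_response_fit`: list with `ic50_um`
#'   (relative; `NA` when censored), `ic50_abs_um`, `hill`, `top`, `bottom`,
#'   `censored`, `censor_bound_um`, `rss`, `converged`, and the input data.
#' @export
fit_ic50 <- function(concentrations_um, inhibition_percent) {
  stopifnot(length(concentrations_um) == length(inhibition_percent))
  if (length(concentrations_um) < 4) {
    stop("need at least 4 concentration points", call. = FALSE)
  }
  if (any(concentrations_um <= 0) || !all(is.finite(inhibition_percent))) {
    stop("concentrations must be positive and inhibition finite", call. = FALSE)
  }
  ord <- order(concentrations_um)
  conc <- concentrations_um[ord]
  inh <- inhibition_percent[ord]
  logc <- log10(conc)

  censored <- max(inh) < 50
  # start values: extremes for the asymptotes, interpolated 50% crossing
  lic50_0 <- {
    above <- which(inh >= 50)
    if (length(above) && min(above) > 1) {
      i <- min(above)
      logc[i - 1] + (50 - inh[i - 1]) / (inh[i] - inh[i - 1]) * (logc[i] - logc[i - 1])
    } else stats::median(logc)
  }
  lower <- c(bottom = -10, top = -10, lic50 = min(logc) - 3, hill = 0.1)
  upper <- c(bottom = 110, top = 110, lic50 = max(logc) + 3, hill = 10)
  # multi-start over the Hill slope: steep curves and top-censored windows
  # have shallow local minima around hill = 1
  fit <- NULL
  for (hill0 in c(1, 0.5, 2, 4)) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        inh ~ fourpl(logc, bottom, top, lic50, hill),
        start = list(bottom = max(-10, min(inh)), top = min(110, max(inh)),
                     lic50 = lic50_0, hill = hill0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 1000)
      ),
      error = function(e) NULL
    )
    if (!is.null(cand) &&
        (is.null(fit) || sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2))) {
      fit <- cand
    }
  }
  # an interpolating solution counts as converged even when the optimizer
  # stopped on its iteration cap short of the step tolerance
  converged <- !is.null(fit) &&
    (fit$convInfo$isConv || sum(stats::resid(fit)^2) < 1e-6)

  if (!converged) {
    return(structure(list(
      concentrations_um = rev(conc), inhibition_percent = rev(inh),
      ic50_um = NA_real_, ic50_abs_um = NA_real_, hill = NA_real_,
      top = NA_real_, bottom = NA_real_, censored = TRUE,
      censor_bound_um = max(conc), rss = NA_real_, converged = FALSE
    ), class = "dose_response_fit"))
  }

  cf <- stats::coef(fit)
  ic50_rel <- 10^cf[["lic50"]]
  ic50_abs <- NA_real_
  if (cf[["bottom"]] < 50 && cf[["top"]] > 50) {
    ic50_abs <- 10^(cf[["lic50"]] - log10((cf[["top"]] - cf[["bottom"]]) /
                                            (50 - cf[["bottom"]]) - 1) / cf[["hill"]])
  }
  structure(list(
    concentrations_um = rev(conc), inhibition_percent = rev(inh),
    ic50_um = if (censored) NA_real_ else ic50_rel,
    ic50_abs_um = if (censored) NA_real_ else ic50_abs,
    hill = cf[["hill"]], top = cf[["top"]], bottom = cf[["bottom"]],
    censored = censored, censor_bound_um = if (censored) max(conc) else NA_real_,
    rss = sum(stats::resid(fit)^2), converged = TRUE
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Dose-response fit: IC50 > %g uM (censored%s)\n",
                x$censor_bound_um,
                if (x$converged) "" else ", fit did not converge"))
  } else {
    cat(sprintf("Dose-response fit: IC50 %.4g uM (relative), %.4g uM (absolute 50%% crossing)\n",
                x$ic50_um, x$ic50_abs_um))
    cat(sprintf("  hill %.3g, top %.3g%%, bottom %.3g%%, RSS %.3g\n",
                x$hill, x$top, x$bottom, x$rss))
  }
  invisible(x)
}

#' Format an IC50 result for reporting
#'
#' @param fit A `dose_response_fit`.
#' @return Character scalar, e.g. `"17.7"` or `"> 50"`.
#' @export
format_ic50 <- function(fit) {
  if (fit$censored) paste0("> ", format(fit$censor_bound_um)) else
    format(signif(fit$ic50_um, 4))
}
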