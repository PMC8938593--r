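#' Linear regression with 95% confidence intervals
#'
#' OLS of `y` on `x` with the coefficient of determination and a t-based
#' 95% confidence interval on the slope, as used to compare per-subject
#' mean doses across modalities.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return List: `slope`, `intercept`, `r_squared`, `slope_ci95`, `fit`.
#' @export
linreg_ci <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0) stop("degenerate: `x` has zero variance")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate input
  perfect <- sm$sigma < .Machine$double.eps^0.5 * max(abs(y), 1)
  ci <- if (perfect) rep(unname(coef(fit)[2]), 2)
        else as.numeric(suppressWarnings(confint(fit, "x")))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, slope_ci95 = ci, fit = fit)
}

#' Bland-Altman agreement analysis
#'
#' Paired differences `d = a - b`: bias is `mean(d)`, spread the sample
#' (n-1) standard deviation, and the 95% limits of agreement are
#' `bias +/- 1.96 sd`.
#'
#' @param a,b paired numeric vectors (n >= 2).
#' @return List: `bias`, `sd`, `limits` (lower, upper), `differences`,
#'   `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired")
  if (length(a) < 2) stop("need n >= 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd = s, limits = bias + c(-1, 1) * 1.96 * s,
       differences = d, means = (a + b) / 2)
}

#' One-way analysis of variance
#'
#' Classic equal-variance between/within decomposition; `F`, degrees of
#' freedom and the p-value from the F distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List: `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ft <- oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ft$statistic), df_between = unname(ft$parameter[1]),
       df_within = unname(ft$parameter[2]), p = unname(ft$p.value))
}

#' Cross-modality agreement summary
#'
#' Fixed pairing convention: the CT mean dose over the liver `L` against
#' the PET mean dose over the extended liver `L_shell`, compared by
#' regression (PET on CT), Bland-Altman (CT minus PET) and, when MIRD
#' doses are supplied, one-way ANOVA across the three dose estimates.
#'
#' @param ct_dmu per-subject CT mean doses (Gy, over `L`).
#' @param pet_dmu per-subject PET mean doses (Gy, over `L_shell`).
#' @param mird optional per-subject MIRD mean doses (Gy).
#' @return Object of class `AgreementSummary` with `regression`,
#'   `bland_altman` and (optionally) `anova` components.
#' @export
agreement_summary <- function(ct_dmu, pet_dmu, mird = NULL) {
  out <- list(regression = linreg_ci(ct_dmu, pet_dmu),
              bland_altman = bland_altman(ct_dmu, pet_dmu))
  if (!is.null(mird))
    out$anova <- one_way_anova(list(ct = ct_dmu, pet = pet_dmu, mird = mird))
  structure(out, class = "AgreementSummary")
}

#' @export
print.AgreementSummary <- function(x, ...) {
  cat(sprintf("<AgreementSummary> slope %.3f (r^2 %.3f); bias %.2f Gy, LoA [%.2f, %.2f]\n",
              x$regression$slope, x$regression$r_squared,
              x$bland_altman$bias, x$bland_altman$limits[1],
              x$bland_altman$limits[2]))
  if (!is.null(x$anova))
    cat(sprintf("  ANOVA F(%d, %d) = %.2f, p = %.3g\n", x$anova$df_between,
                x$anova$df_within, x$anova$F, x$anova$p))
  invisible(x)
}
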