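#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a growth fit
#'
#' @param x A `growth_fit` from [fit_growth()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = c("od_asym", "k", "tc"),
                 estimate = c(x$par$od_asym, x$par$k, x$par$tc))
}

#' @rdname tidy.growth_fit
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged,
                 no_growth = x$no_growth)
}

#' Tidy a shunt fit
#'
#' @param x A `shunt_fit` from [fit_shunt()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy shunt_fit
#' @export
tidy.shunt_fit <- function(x, ...) {
  tibble::tibble(term = c("f", "g", "substrate_consumed_mM"),
                 estimate = c(x$par$f, x$par$g, x$par$substrate_consumed_mM))
}

#' @rdname tidy.shunt_fit
#' @method glance shunt_fit
#' @export
glance.shunt_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm,
                 boundary_hit = x$boundary_hit,
                 g_identifiable = x$g_identifiable)
}

#' Tidy a calibration curve
#'
#' @param x A `calibration` from [build_calibration()].
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @method tidy calibration
#' @export
tidy.calibration <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @rdname tidy.calibration
#' @method glance calibration
#' @export
glance.calibration <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_standards = nrow(x$standards),
                 analyte = x$analyte)
}

#' Tidy an ANOVA/Tukey result
#'
#' `tidy()` returns the pairwise Tukey comparisons; `glance()` the ANOVA
#' table itself.
#'
#' @param x An `anova_tukey` from [anova_tukey()].
#' @param ... Unused.
#' @method tidy anova_tukey
#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' @rdname tidy.anova_tukey
#' @method glance anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) x$anova
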