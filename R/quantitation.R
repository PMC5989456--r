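# Carbons per mole of each secreted metabolite (molecular formulas:
# lactate C3H6O3, acetate C2H4O2, formate CH2O2, ethanol C2H6O).
# No CO2 term: pyruvate-formate lyase retains the carboxyl carbon in formate.
METABOLITE_CARBONS <- c(lactate = 3, acetate = 2, formate = 1, ethanol = 2)

#' Fit an external-standard calibration curve
#'
#' Ordinary least-squares line `response = slope * concentration + intercept`
#' over an external-standard dilution series (typically the six levels 0.5,
#' 1, 5, 10, 20 and 50 mM used for organic-acid HPLC). A warning is raised
#' when r-squared falls below `r2_floor` or the slope is not positive.
#'
#' @param standards Data frame with columns `concentration_mM` and `response`
#'   (detector units); an `analyte` column is carried through if present.
#' @param zero_intercept Force the line through the origin. Default `FALSE`.
#' @param r2_floor Warn below this r-squared; default 0.99.
#' @return Object of class `calibration`: list with `analyte`, `slope`,
#'   `intercept`, `r_squared`, `standards`.
#' @export
#' @examples
#' std <- tibble::tibble(concentration_mM = c(0.5, 1, 5, 10, 20, 50),
#'                       response = 2 * c(0.5, 1, 5, 10, 20, 50) + 1)
#' build_calibration(std)
build_calibration <- function(standards, zero_intercept = FALSE,
                              r2_floor = 0.99) {
  stopifnot(is.data.frame(standards),
            all(c("concentration_mM", "response") %in% names(standards)))
  conc <- as.numeric(standards$concentration_mM)
  resp <- as.numeric(standards$response)
  if (length(unique(conc)) < 2) {
    stop("need at least 2 distinct standard concentrations", call. = FALSE)
  }
  if (stats::sd(resp) == 0) {
    stop("standard responses have zero variance", call. = FALSE)
  }
  fit <- if (zero_intercept) stats::lm(resp ~ conc + 0) else stats::lm(resp ~ conc)
  cf <- stats::coef(fit)
  slope <- unname(cf[["conc"]])
  intercept <- if (zero_intercept) 0 else unname(cf[["(Intercept)"]])
  r2 <- if (zero_intercept) {
    1 - sum(stats::resid(fit)^2) / sum(resp^2)
  } else {
    1 - sum(stats::resid(fit)^2) / sum((resp - mean(resp))^2)
  }
  if (slope <= 0) warning("calibration slope is not positive", call. = FALSE)
  if (r2 < r2_floor) {
    warning(sprintf("calibration r-squared %.4f below floor %.2f", r2, r2_floor),
            call. = FALSE)
  }
  out <- list(
    analyte = if ("analyte" %in% names(standards))
      as.character(standards$analyte[1]) else NA_character_,
    slope = slope, intercept = intercept, r_squared = r2,
    standards = tibble::tibble(concentration_mM = conc, response = resp)
  )
  class(out) <- "calibration"
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Calibration%s: response = %.6g * conc + %.6g (r^2 = %.5f, n = %d)\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' Convert detector responses to concentrations
#'
#' Inverts a [build_calibration()] line: `(response - intercept) / slope`.
#' Results below zero (response under the intercept) are clipped to 0 and
#' flagged.
#'
#' @param response Detector responses (vectorized).
#' @param curve A `calibration` object.
#' @return Tibble with `response`, `concentration_mM`, `clipped`.
#' @export
quantify <- function(response, curve) {
  stopifnot(inherits(curve, "calibration"))
  if (curve$slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  raw <- (as.numeric(response) - curve$intercept) / curve$slope
  tibble::tibble(
    response = as.numeric(response),
    concentration_mM = pmax(raw, 0),
    clipped = raw < 0
  )
}

#' Average duplicate technical HPLC measurements
#'
#' Technical duplicates are averaged per sample x analyte; pairs whose
#' relative spread exceeds `discord_tol` are flagged.
#'
#' @param measurements Tibble with `sample`, `analyte`, `concentration_mM`
#'   (one row per injection).
#' @param discord_tol Relative range above which duplicates are flagged
#'   discordant; default 0.10.
#' @return Tibble with `sample`, `analyte`, `concentration_mM` (mean),
#'   `n_injections`, `discordant`.
#' @export
average_duplicates <- function(measurements, discord_tol = 0.10) {
  stopifnot(all(c("sample", "analyte", "concentration_mM") %in%
                  names(measurements)))
  measurements |>
    dplyr::group_by(.data$sample, .data$analyte) |>
    dplyr::summarise(
      n_injections = dplyr::n(),
      discordant = dplyr::n() > 1 &&
        diff(range(.data$concentration_mM)) >
          discord_tol * max(mean(.data$concentration_mM), .Machine$double.eps),
      concentration_mM = mean(.data$concentration_mM),
      .groups = "drop"
    ) |>
    dplyr::relocate("concentration_mM", .after = "analyte")
}

#' Percent sugar consumption
#'
#' `100 * (pre - post) / pre`. Values below zero (more sugar after
#' fermentation than before) are reported as negative with a warning, not
#' clipped, since they flag measurement or hydrolysis artifacts.
#'
#' @param pre_mM Substrate concentration before fermentation (> 0).
#' @param post_mM Residual concentration after fermentation (>= 0).
#' @return Percent consumed (vectorized).
#' @export
#' @examples
#' sugar_consumption(111, 55.5)  # 50
sugar_consumption <- function(pre_mM, post_mM) {
  pre_mM <- as.numeric(pre_mM); post_mM <- as.numeric(post_mM)
  if (any(!is.finite(pre_mM) | pre_mM <= 0)) {
    stop("pre-fermentation concentration must be positive", call. = FALSE)
  }
  if (any(post_mM < 0, na.rm = TRUE)) {
    stop("post-fermentation concentration must be non-negative", call. = FALSE)
  }
  pct <- 100 * (pre_mM - post_mM) / pre_mM
  if (any(pct < 0, na.rm = TRUE)) {
    warning("negative consumption (post > pre); reporting as-is", call. = FALSE)
  }
  pct
}

#' Percent carbon recovery of a fermentation
#'
#' Carbon recovered in secreted metabolites as a percentage of the carbon in
#' the substrate consumed: `100 * sum(metabolite mM x carbons per mole) /
#' (consumed carbon mM)`. Consumed carbon is the pre-fermentation substrate
#' carbon minus the carbon still present as residual sugars. Recovery above
#' 100% is possible on real data (e.g., residual disaccharide hydrolyzed to
#' monosaccharides inflates the apparent metabolite pool) and is reported
#' as-is.
#'
#' @param panel One-row data frame with metabolite columns `lactate_mM`,
#'   `acetate_mM`, `formate_mM`, `ethanol_mM` (missing analytes treated as
#'   absent), `pre_fermentation_substrate_mM`, and optionally residual-sugar
#'   columns `residual_<sugar>_mM` naming registry sugars.
#' @param substrate Substrate tibble from [get_substrate()].
#' @param registry Registry for resolving residual-sugar carbon counts.
#' @return Percent carbon recovery (scalar).
#' @export
carbon_recovery <- function(panel, substrate,
                            registry = substrate_registry()) {
  substrate <- validate_substrate(substrate)
  stopifnot(is.data.frame(panel), nrow(panel) == 1)
  if (!"pre_fermentation_substrate_mM" %in% names(panel)) {
    stop("panel must contain pre_fermentation_substrate_mM", call. = FALSE)
  }
  pre <- as.numeric(panel$pre_fermentation_substrate_mM)

  met_carbon <- sum(vapply(names(METABOLITE_CARBONS), function(a) {
    cc <- paste0(a, "_mM")
    if (cc %in% names(panel) && is.finite(panel[[cc]])) {
      panel[[cc]] * METABOLITE_CARBONS[[a]]
    } else 0
  }, numeric(1)))

  residual_cols <- grep("^residual_.*_mM$", names(panel), value = TRUE)
  residual_carbon <- sum(vapply(residual_cols, function(cc) {
    val <- as.numeric(panel[[cc]])
    if (!is.finite(val)) return(0)  # analyte not measured for this sample
    sugar <- sub("^residual_(.*)_mM$", "\\1", cc)
    hit <- registry[tolower(registry$name) == tolower(sugar), , drop = FALSE]
    if (nrow(hit) == 0) {
      stop("residual sugar '", sugar, "' not in registry", call. = FALSE)
    }
    val * hit$carbon_atoms[1]
  }, numeric(1)))

  consumed_carbon <- pre * substrate$carbon_atoms - residual_carbon
  if (!is.finite(consumed_carbon) || consumed_carbon <= 0) {
    stop("consumed substrate carbon must be positive", call. = FALSE)
  }
  100 * met_carbon / consumed_carbon
}
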