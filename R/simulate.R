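#' Default simulation designs
#'
#' Preset parameter tables for the synthetic-data generators, named after the
#' study conditions they emulate (B. infantis growing on 2% w/v galactose,
#' lactose, LNT or LNnT). Growth parameters use the reported kinetics of the
#' type strain (e.g. lactose: asymptote 1.27, k = 0.56 h^-1); the inflection
#' time, not reported, defaults to 8 h, a realistic value for an overnight
#' 1% inoculum. Fermentation presets are illustrative flux partitions chosen
#' to qualitatively mimic the measured endproduct shifts (LNnT-like f = 0.5,
#' g = 0.9 gives elevated acetate:lactate with measurable formate), not
#' fitted ground truth. Pre-fermentation substrate concentrations correspond
#' to 20 g/L at each substrate's molar mass.
#'
#' @return A tibble of per-condition parameters.
#' @name presets
NULL

#' @rdname presets
#' @export
growth_presets <- function() {
  tibble::tribble(
    ~strain,      ~substrate,  ~od_asym, ~k,   ~tc,
    "ATCC15697",  "galactose", 1.20,     0.61, 8,
    "ATCC15697",  "lactose",   1.27,     0.56, 8,
    "ATCC15697",  "lnt",       1.19,     0.51, 8,
    "ATCC15697",  "lnnt",      0.85,     0.57, 8
  )
}

#' @rdname presets
#' @export
fermentation_presets <- function() {
  reg <- substrate_registry()
  pre <- function(s) 20 / reg$molar_mass[reg$name == s] * 1000  # 20 g/L in mM
  tibble::tribble(
    ~strain,     ~substrate,  ~f,   ~g,   ~substrate_consumed_mM,
    "ATCC15697", "galactose", 0.02, 0.9,  43,
    "ATCC15697", "lactose",   0.03, 0.9,  24.5,
    "ATCC15697", "lnt",       0.05, 0.9,  12.2,
    "ATCC15697", "lnnt",      0.50, 0.9,  14.75
  ) |>
    dplyr::mutate(pre_fermentation_substrate_mM =
                    vapply(.data$substrate, pre, numeric(1)))
}

#' @rdname presets
#' @export
expression_presets <- function() {
  tibble::tribble(
    ~gene,        ~condition, ~fold,
    "Blon_0881",  "lactose",  1,
    "Blon_0881",  "lnt",      19.34,
    "Blon_0881",  "lnnt",     18.71,
    "Blon_0882",  "lactose",  1,
    "Blon_0882",  "lnt",      21.84,
    "Blon_0882",  "lnnt",     20.61
  )
}

#' @rdname presets
#' @export
calibration_presets <- function() {
  tibble::tibble(
    analyte = c("lactate", "acetate", "formate", "ethanol",
                "glucose", "galactose", "lactose", "glcnac"),
    slope = c(1200, 900, 700, 500, 1500, 1500, 2800, 1700),
    intercept = c(30, 25, 15, 10, 40, 40, 60, 45)
  )
}

with_sim_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Simulate microplate growth curves
#'
#' Evaluates the sigmoidal growth model for each design row and replicate on
#' a common time grid, adds i.i.d. Gaussian reading noise, clips at 0, and
#' appends a no-carbohydrate blank series (noise around zero) per strain.
#'
#' @param design Tibble with columns `strain`, `substrate`, `od_asym`, `k`,
#'   `tc`; defaults to [growth_presets()].
#' @param times Time grid in hours; default hourly over the 48 h assay.
#' @param n_replicates Biological replicates per condition; default 3.
#' @param noise_sd SD of additive OD600 noise; default 0.02.
#' @param seed Integer seed for reproducibility (`NULL` leaves the RNG state
#'   alone).
#' @return Long tibble: `strain`, `substrate`, `replicate`, `time_h`,
#'   `od600`. Blank series have `substrate = "none"`.
#' @export
simulate_growth <- function(design = growth_presets(),
                            times = seq(0, 48, by = 1),
                            n_replicates = 3, noise_sd = 0.02, seed = NULL) {
  stopifnot(noise_sd >= 0,
            all(c("strain", "substrate", "od_asym", "k", "tc") %in%
                  names(design)))
  with_sim_seed(seed, {
    blank <- dplyr::distinct(design, .data$strain) |>
      dplyr::mutate(substrate = "none", od_asym = 0, k = 1, tc = 1)
    full <- dplyr::bind_rows(design, blank)
    purrr::pmap_dfr(full, function(strain, substrate, od_asym, k, tc, ...) {
      purrr::map_dfr(seq_len(n_replicates), function(r) {
        mu <- growth_model(times, od_asym, k, tc)
        tibble::tibble(
          strain = strain, substrate = substrate,
          replicate = paste0("rep", r),
          time_h = times,
          od600 = pmax(mu + stats::rnorm(length(times), 0, noise_sd), 0)
        )
      })
    })
  })
}

#' Simulate fermentation endproduct panels
#'
#' Concentrations are `S * predict_fluxes()` per-mole yields under the design
#' flux partition, perturbed by multiplicative lognormal noise with the given
#' coefficient of variation (unit mean), so concentrations stay positive.
#' Residual substrate is the noiseless `pre - consumed`, reported in a
#' `residual_<substrate>_mM` column.
#'
#' @param design Tibble with columns `strain`, `substrate`, `f`, `g`,
#'   `substrate_consumed_mM`, `pre_fermentation_substrate_mM`; defaults to
#'   [fermentation_presets()].
#' @param n_replicates Biological replicates per condition; default 3.
#' @param cv Coefficient of variation of the multiplicative noise; default
#'   0.05. `cv = 0` reproduces the forward model exactly (carbon recovery
#'   100%).
#' @param seed Integer seed.
#' @param registry Substrate registry for composition lookup.
#' @return Panel tibble: `sample`, `strain`, `substrate`, `f_true`, `g_true`,
#'   `acetate_mM`, `lactate_mM`, `formate_mM`, `ethanol_mM`,
#'   `pre_fermentation_substrate_mM`, and one `residual_*_mM` column per
#'   substrate present.
#' @export
simulate_fermentation <- function(design = fermentation_presets(),
                                  n_replicates = 3, cv = 0.05, seed = NULL,
                                  registry = substrate_registry()) {
  stopifnot(cv >= 0,
            all(c("strain", "substrate", "f", "g", "substrate_consumed_mM",
                  "pre_fermentation_substrate_mM") %in% names(design)))
  sdlog <- sqrt(log(1 + cv^2))
  with_sim_seed(seed, {
    purrr::pmap_dfr(design, function(strain, substrate, f, g,
                                     substrate_consumed_mM,
                                     pre_fermentation_substrate_mM, ...) {
      sub <- get_substrate(substrate, registry)
      y <- shunt_yields(sub, f, g)
      purrr::map_dfr(seq_len(n_replicates), function(r) {
        noise <- if (cv == 0) rep(1, 4) else
          stats::rlnorm(4, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        conc <- substrate_consumed_mM * y * noise
        row <- tibble::tibble(
          sample = paste(strain, substrate, paste0("rep", r), sep = "_"),
          strain = strain, substrate = substrate,
          f_true = f, g_true = g,
          acetate_mM = conc[["acetate"]],
          lactate_mM = conc[["lactate"]],
          formate_mM = conc[["formate"]],
          ethanol_mM = conc[["ethanol"]],
          pre_fermentation_substrate_mM = pre_fermentation_substrate_mM
        )
        row[[paste0("residual_", substrate, "_mM")]] <-
          pre_fermentation_substrate_mM - substrate_consumed_mM
        row
      })
    })
  })
}

#' Simulate qPCR Ct records
#'
#' Endogenous-control Cts are drawn Normal(`base_ct`, `ct_noise_sd`) per
#' sample; each target Ct is the sample's control Ct plus a gene-level
#' reference offset (`ref_delta_ct`) minus `log2(fold)` for the condition,
#' plus reading noise. Running [ddct_fold_change()] on the output recovers
#' the configured folds (exactly when `ct_noise_sd = 0`).
#'
#' @param design Tibble with columns `gene`, `condition`, `fold`; defaults to
#'   [expression_presets()]. Must include the reference condition at fold 1.
#' @param n_replicates Biological replicates per condition; default 3.
#' @param ct_noise_sd SD of Ct noise (cycles); default 0.3.
#' @param base_ct Mean endogenous-control Ct; default 20.
#' @param ref_delta_ct Target-minus-control Ct offset in the reference
#'   condition; default 4.
#' @param control_gene Name for the endogenous control; default "Blon_0393".
#' @param seed Integer seed.
#' @return Ct record tibble with columns `sample`, `condition`, `gene`,
#'   `role`, `ct`.
#' @export
simulate_cts <- function(design = expression_presets(), n_replicates = 3,
                         ct_noise_sd = 0.3, base_ct = 20, ref_delta_ct = 4,
                         control_gene = "Blon_0393", seed = NULL) {
  stopifnot(ct_noise_sd >= 0,
            all(c("gene", "condition", "fold") %in% names(design)))
  with_sim_seed(seed, {
    conditions <- unique(design$condition)
    purrr::map_dfr(conditions, function(cond) {
      purrr::map_dfr(seq_len(n_replicates), function(r) {
        id <- paste(cond, paste0("rep", r), sep = "_")
        ct_ctrl <- base_ct + stats::rnorm(1, 0, ct_noise_sd)
        genes <- design[design$condition == cond, , drop = FALSE]
        dplyr::bind_rows(
          tibble::tibble(sample = id, condition = cond, gene = control_gene,
                         role = "endogenous_control", ct = ct_ctrl),
          purrr::pmap_dfr(genes, function(gene, condition, fold, ...) {
            tibble::tibble(
              sample = id, condition = cond, gene = gene, role = "target",
              ct = ct_ctrl + ref_delta_ct - log2(fold) +
                stats::rnorm(1, 0, ct_noise_sd))
          })
        )
      })
    })
  })
}

#' Simulate external-standard calibration series
#'
#' Linear detector responses at the standard dilution levels (0.5, 1, 5, 10,
#' 20, 50 mM) with additive Gaussian noise.
#'
#' @param design Tibble with columns `analyte`, `slope`, `intercept`;
#'   defaults to [calibration_presets()].
#' @param levels_mM Standard concentrations; default the six-level series.
#' @param noise_sd SD of response noise (detector units); default 0.
#' @param seed Integer seed.
#' @return Tibble: `analyte`, `concentration_mM`, `response`.
#' @export
simulate_standards <- function(design = calibration_presets(),
                               levels_mM = c(0.5, 1, 5, 10, 20, 50),
                               noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0,
            all(c("analyte", "slope", "intercept") %in% names(design)))
  with_sim_seed(seed, {
    purrr::pmap_dfr(design, function(analyte, slope, intercept, ...) {
      tibble::tibble(
        analyte = analyte,
        concentration_mM = levels_mM,
        response = slope * levels_mM + intercept +
          stats::rnorm(length(levels_mM), 0, noise_sd)
      )
    })
  })
}
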