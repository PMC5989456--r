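#' Flux-partition parameters of the bifid shunt
#'
#' Two fractions govern how carbon leaves the lower half of the F6PPK
#' ("bifid shunt") pathway. `f` is the fraction of the pyruvate pool routed
#' through pyruvate-formate lyase (PFL) to formate plus acetyl-CoA; the
#' remainder (1 - f) is reduced to lactate, regenerating NAD+. `g` is the
#' fraction of that acetyl-CoA converted to acetate (gaining one ATP via
#' acetate kinase); the remainder (1 - g) is reduced twice to ethanol,
#' regenerating two NAD+ per mole.
#'
#' With `enforce_redox_balance = TRUE` and `f > 0`, `g` is pinned at 1/2:
#' the ethanol arm then regenerates exactly the NAD+ that lactate no longer
#' recycles, closing the redox balance without lactate.
#'
#' @param f Fraction of pyruvate routed to PFL, in `[0, 1]`.
#' @param g Fraction of acetyl-CoA converted to acetate, in `[0, 1]`.
#' @param enforce_redox_balance If `TRUE` and `f > 0`, fix `g = 1/2`.
#' @return A one-row tibble with columns `f`, `g`, `enforce_redox_balance`.
#' @export
#' @examples
#' shunt_params(0)            # classical bifid shunt, no PFL flux
#' shunt_params(0.5, 0.9)     # LNnT-like shift toward formate and acetate
shunt_params <- function(f, g = 0.5, enforce_redox_balance = FALSE) {
  f <- as.numeric(f); g <- as.numeric(g)
  if (!is.finite(f) || f < 0 || f > 1) {
    stop("f must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(g) || g < 0 || g > 1) {
    stop("g must lie in [0, 1]", call. = FALSE)
  }
  if (isTRUE(enforce_redox_balance) && f > 0) g <- 0.5
  tibble::tibble(f = f, g = g,
                 enforce_redox_balance = isTRUE(enforce_redox_balance))
}

#' Predict fermentative endproducts from substrate composition
#'
#' Forward stoichiometric model of the F6PPK pathway. Per hexose equivalent,
#' phosphoketolase chemistry yields 3/2 acetyl-phosphate (dephosphorylated to
#' acetate with one ATP each) and one glyceraldehyde-3-phosphate that is
#' oxidized to pyruvate with ATP gain. Pyruvate is partitioned by `f` between
#' lactate and the PFL branch (formate + acetyl-CoA), and the acetyl-CoA by
#' `g` between acetate (ATP gain) and ethanol (NAD+ regeneration). Each GlcNAc
#' residue releases one additional free acetate on deacetylation, carrying no
#' ATP.
#'
#' With `H` hexose equivalents and `N` GlcNAc residues per mole substrate:
#' acetate = 3/2 H + H f g + N; lactate = H (1 - f); formate = H f;
#' ethanol = H f (1 - g); ATP = 3/2 H + `atp_per_gap` H + H f g minus the
#' activation cost; NADH residual (produced minus consumed) = H f (2g - 1).
#' Carbon is conserved exactly: 2 acetate + 3 lactate + formate + 2 ethanol
#' equals the substrate's carbon count for every (f, g).
#'
#' @param substrate A one-row substrate tibble from [substrate_spec()] or
#'   [get_substrate()].
#' @param shunt Flux-partition parameters from [shunt_params()].
#' @param atp_per_gap ATP gained per glyceraldehyde-3-phosphate oxidized to
#'   pyruvate. Default 1 (single substrate-level phosphorylation); set 2 for
#'   the textbook lower-glycolysis count.
#' @param glcnac_bypass Fraction of GlcNAc residues diverted to anabolism
#'   (peptidoglycan and other biosyntheses) instead of being catabolized;
#'   diverted residues contribute neither a hexose equivalent nor a
#'   deacetylation acetate. Default 0.
#' @return A one-row tibble (class `flux_prediction`) with per-mole-substrate
#'   columns `acetate_mol`, `lactate_mol`, `formate_mol`, `ethanol_mol`,
#'   `deacetylation_acetate_mol`, `atp_mol`, `nadh_residual_mol`,
#'   `carbon_in_products_mol`, plus `substrate`, `f`, `g`.
#' @export
#' @examples
#' hexose2 <- substrate_spec("hexose-pair", 2)
#' predict_fluxes(hexose2, shunt_params(0))          # 3 acetate : 2 lactate
#' predict_fluxes(get_substrate("lnnt"), shunt_params(0.5, 0.9))
predict_fluxes <- function(substrate, shunt = shunt_params(0),
                           atp_per_gap = 1, glcnac_bypass = 0) {
  substrate <- validate_substrate(substrate)
  stopifnot(is.data.frame(shunt), nrow(shunt) == 1)
  f <- shunt$f; g <- shunt$g
  if (f < 0 || f > 1 || g < 0 || g > 1) {
    stop("f and g must lie in [0, 1]", call. = FALSE)
  }
  if (glcnac_bypass < 0 || glcnac_bypass > 1) {
    stop("glcnac_bypass must lie in [0, 1]", call. = FALSE)
  }

  N <- substrate$glcnac_residues * (1 - glcnac_bypass)
  H <- substrate$hexose_equivalents - substrate$glcnac_residues * glcnac_bypass

  akp_acetate <- 1.5 * H            # acetyl-phosphate -> acetate via acetate kinase
  lactate <- H * (1 - f)
  formate <- H * f
  shunt_acetate <- H * f * g
  ethanol <- H * f * (1 - g)
  deac_acetate <- N                 # free acetate from GlcNAc deacetylation, no ATP
  acetate <- akp_acetate + shunt_acetate + deac_acetate

  atp <- akp_acetate + atp_per_gap * H + shunt_acetate -
    substrate$activation_atp_per_hexose * H
  nadh_residual <- H * f * (2 * g - 1)
  carbon <- 2 * acetate + 3 * lactate + formate + 2 * ethanol

  out <- tibble::tibble(
    substrate = substrate$name,
    f = f, g = g,
    acetate_mol = acetate,
    lactate_mol = lactate,
    formate_mol = formate,
    ethanol_mol = ethanol,
    deacetylation_acetate_mol = deac_acetate,
    atp_mol = atp,
    nadh_residual_mol = nadh_residual,
    carbon_in_products_mol = carbon
  )
  class(out) <- c("flux_prediction", class(out))
  out
}

#' Molar endproduct ratios of a flux prediction or metabolite panel
#'
#' Computes the field's standard readouts of F6PPK flux partitioning:
#' acetate:lactate (`aa_la`), formate:lactate (`fa_la`), formate:acetate
#' (`fa_aa`) and ethanol:lactate (`et_la`). A ratio whose denominator is zero
#' is returned as `NA` with its `*_defined` flag set `FALSE` — never as an
#' infinity — and such values should be excluded (not zero-filled) from
#' downstream statistics.
#'
#' Accepts either a [predict_fluxes()] result (columns `*_mol`) or a measured
#' panel in mM (columns `*_mM`); rows are processed independently so
#' per-replicate ratios are returned, never ratios of group means.
#'
#' @param x A tibble with acetate/lactate/formate/ethanol columns suffixed
#'   `_mol` or `_mM`.
#' @return `x`'s identifying columns with `aa_la`, `fa_la`, `fa_aa`, `et_la`
#'   and logical `aa_la_defined`, ..., one row per input row.
#' @export
#' @examples
#' theoretical_ratios(predict_fluxes(substrate_spec("hexose-pair", 2)))
theoretical_ratios <- function(x) {
  stopifnot(is.data.frame(x))
  suffix <- if ("acetate_mol" %in% names(x)) "_mol" else if
    ("acetate_mM" %in% names(x)) "_mM" else
    stop("need acetate/lactate columns suffixed _mol or _mM", call. = FALSE)
  need <- paste0(c("acetate", "lactate", "formate", "ethanol"), suffix)
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  aa <- x[[paste0("acetate", suffix)]]
  la <- x[[paste0("lactate", suffix)]]
  fa <- x[[paste0("formate", suffix)]]
  et <- x[[paste0("ethanol", suffix)]]

  safe_ratio <- function(num, den) {
    defined <- is.finite(den) & den > 0 & is.finite(num)
    val <- ifelse(defined, num / den, NA_real_)
    list(value = val, defined = defined)
  }
  r1 <- safe_ratio(aa, la); r2 <- safe_ratio(fa, la)
  r3 <- safe_ratio(fa, aa); r4 <- safe_ratio(et, la)

  id_cols <- intersect(c("sample", "strain", "substrate", "replicate", "f", "g"),
                       names(x))
  out <- dplyr::bind_cols(
    x[id_cols],
    tibble::tibble(
      aa_la = r1$value, aa_la_defined = r1$defined,
      fa_la = r2$value, fa_la_defined = r2$defined,
      fa_aa = r3$value, fa_aa_defined = r3$defined,
      et_la = r4$value, et_la_defined = r4$defined
    )
  )
  tibble::as_tibble(out)
}

# Per-mole endproduct yields in panel order (acetate, lactate, formate,
# ethanol) for a substrate at (f, g); the inner model of fit_shunt.
shunt_yields <- function(substrate, f, g) {
  H <- substrate$hexose_equivalents
  N <- substrate$glcnac_residues
  c(acetate = 1.5 * H + H * f * g + N,
    lactate = H * (1 - f),
    formate = H * f,
    ethanol = H * f * (1 - g))
}

#' Estimate flux-partition parameters from a measured endproduct panel
#'
#' Inverse of [predict_fluxes()]: finds the PFL fraction `f`, the
#' acetate fraction `g`, and the substrate consumed `S` (mM) whose predicted
#' endproduct concentrations `S * yield(f, g)` best match an observed panel,
#' by bounded least squares. Given (f, g) the optimal `S` has a closed form,
#' so the optimizer profiles over (f, g) from a 5 x 5 multi-start grid
#' (25 points); ties are broken by smallest residual then smallest `f`.
#'
#' When formate and ethanol are both absent from the panel (zero or
#' unmeasured) the data carry no information about the acetyl-CoA split:
#' `f` is returned as 0 and `g` as `NA` with `g_identifiable = FALSE`.
#'
#' @param panel A one-row data frame (or named vector) with concentrations in
#'   mM: `lactate_mM` plus at least one of `acetate_mM`, `formate_mM`,
#'   `ethanol_mM`; unmeasured analytes may be `NA` or absent.
#' @param substrate Substrate tibble from [substrate_spec()]/[get_substrate()].
#' @return An object of class `shunt_fit`: list with `par` (tibble `f`, `g`,
#'   `substrate_consumed_mM`), `residual_norm`, `boundary_hit`,
#'   `g_identifiable`, `fitted`, `observed`.
#' @seealso [tidy.shunt_fit()], [glance.shunt_fit()]
#' @export
#' @examples
#' sub <- get_substrate("lnnt")
#' truth <- predict_fluxes(sub, shunt_params(0.5, 0.9))
#' panel <- tibble::tibble(
#'   acetate_mM = 20 * truth$acetate_mol, lactate_mM = 20 * truth$lactate_mol,
#'   formate_mM = 20 * truth$formate_mol, ethanol_mM = 20 * truth$ethanol_mol)
#' fit_shunt(panel, sub)
fit_shunt <- function(panel, substrate) {
  substrate <- validate_substrate(substrate)
  if (is.numeric(panel)) panel <- tibble::as_tibble(as.list(panel))
  stopifnot(is.data.frame(panel), nrow(panel) == 1)

  analytes <- c("acetate", "lactate", "formate", "ethanol")
  cols <- paste0(analytes, "_mM")
  obs <- vapply(cols, function(cc) {
    if (cc %in% names(panel)) as.numeric(panel[[cc]]) else NA_real_
  }, numeric(1))
  names(obs) <- analytes
  measured <- !is.na(obs)
  if (!measured["lactate"] || sum(measured) < 2) {
    stop("panel must measure lactate_mM and at least one other analyte",
         call. = FALSE)
  }
  if (any(obs[measured] < 0)) {
    stop("panel concentrations must be non-negative", call. = FALSE)
  }
  if (all(obs[measured] == 0)) {
    stop("all measured concentrations are zero; cannot estimate fluxes",
         call. = FALSE)
  }

  shunt_absent <- (!measured["formate"] || obs["formate"] == 0) &&
    (!measured["ethanol"] || obs["ethanol"] == 0)

  # residual sum of squares at (f, g) with profiled-out scale S >= 0
  rss_at <- function(f, g) {
    y <- shunt_yields(substrate, f, g)[measured]
    o <- obs[measured]
    S <- max(0, sum(y * o) / sum(y * y))
    list(rss = sum((o - S * y)^2), S = S)
  }

  if (shunt_absent) {
    sol <- rss_at(0, 0.5)
    fitted <- sol$S * shunt_yields(substrate, 0, 0.5)
    out <- list(
      par = tibble::tibble(f = 0, g = NA_real_,
                           substrate_consumed_mM = sol$S),
      residual_norm = sqrt(sol$rss),
      boundary_hit = TRUE,
      g_identifiable = FALSE,
      fitted = fitted,
      observed = obs
    )
    class(out) <- "shunt_fit"
    return(out)
  }

  starts <- expand.grid(f = seq(0.1, 0.9, length.out = 5),
                        g = seq(0.1, 0.9, length.out = 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(
      par = c(f = starts$f[i], g = starts$g[i]),
      fn = function(p) rss_at(p[1], p[2])$rss,
      method = "L-BFGS-B", lower = c(0, 0), upper = c(1, 1),
      control = list(factr = 10, pgtol = 1e-14, maxit = 500)
    )
    if (is.null(best) ||
        opt$value < best$value - 1e-12 ||
        (abs(opt$value - best$value) <= 1e-12 && opt$par[1] < best$par[1])) {
      best <- opt
    }
  }
  polish <- stats::nlminb(
    start = best$par, objective = function(p) rss_at(p[1], p[2])$rss,
    lower = c(0, 0), upper = c(1, 1),
    control = list(abs.tol = 0, rel.tol = 1e-15, x.tol = 1e-12,
                   iter.max = 500))
  if (polish$objective <= best$value) best$par <- polish$par
  f_hat <- unname(best$par[1]); g_hat <- unname(best$par[2])
  sol <- rss_at(f_hat, g_hat)
  fitted <- sol$S * shunt_yields(substrate, f_hat, g_hat)

  out <- list(
    par = tibble::tibble(f = f_hat, g = g_hat,
                         substrate_consumed_mM = sol$S),
    residual_norm = sqrt(sol$rss),
    boundary_hit = any(abs(c(f_hat, g_hat) - 0) < 1e-8 |
                         abs(c(f_hat, g_hat) - 1) < 1e-8),
    g_identifiable = TRUE,
    fitted = fitted,
    observed = obs
  )
  class(out) <- "shunt_fit"
  out
}

#' @export
print.shunt_fit <- function(x, ...) {
  cat("Bifid-shunt flux-partition fit\n")
  cat(sprintf("  f (pyruvate -> PFL)        : %s\n",
              format(x$par$f, digits = 4)))
  cat(sprintf("  g (acetyl-CoA -> acetate)  : %s%s\n",
              format(x$par$g, digits = 4),
              if (!x$g_identifiable) " (unidentifiable: no shunt products)" else ""))
  cat(sprintf("  substrate consumed (mM)    : %s\n",
              format(x$par$substrate_consumed_mM, digits = 5)))
  cat(sprintf("  residual norm (mM)         : %s\n",
              format(x$residual_norm, digits = 4)))
  invisible(x)
}
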