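#' Substrate registry
#'
#' Carbohydrate substrates are described by their composition in hexose
#' equivalents: each hexose residue (glucose, galactose, or the glucosamine
#' backbone of a deacetylated/deaminated GlcNAc) enters the
#' fructose-6-phosphate phosphoketolase (F6PPK) pathway as one fermentable
#' unit. A GlcNAc residue additionally releases one free acetate on
#' deacetylation and carries two extra carbons (the acetyl group), so
#' `carbon_atoms = 6 * (hexose_equivalents - glcnac_residues) + 8 *
#' glcnac_residues` for the built-in substrates.
#'
#' The shipped registry covers glucose, galactose, lactose, GlcNAc, and the
#' isomeric milk-oligosaccharide tetrasaccharides LNT and LNnT
#' (4 hexose equivalents, 1 GlcNAc, 26 carbons each). Users may point at an
#' edited copy of the CSV to add substrates.
#'
#' @param path Path to a registry CSV with columns `name`,
#'   `hexose_equivalents`, `glcnac_residues`, `carbon_atoms`, `molar_mass`.
#'   Defaults to the registry shipped with the package.
#' @return A tibble, one row per substrate.
#' @export
#' @examples
#' substrate_registry()
substrate_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "substrates.csv", package = "bifidshunt")
  }
  reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("name", "hexose_equivalents", "glcnac_residues",
                "carbon_atoms", "molar_mass")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0) {
    stop("substrate registry is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  purrr::pwalk(reg, function(name, hexose_equivalents, glcnac_residues,
                             carbon_atoms, molar_mass, ...) {
    validate_substrate(substrate_spec(name, hexose_equivalents,
                                      glcnac_residues, carbon_atoms,
                                      molar_mass))
  })
  reg
}

#' Define a fermentable substrate
#'
#' @param name Substrate name (matched case-insensitively by [get_substrate()]).
#' @param hexose_equivalents Hexose units entering the F6PPK pathway per mole
#'   of substrate (>= 1 for fermentable substrates).
#' @param glcnac_residues N-acetylglucosamine residues per mole; each
#'   contributes its glucosamine backbone as one of the hexose equivalents and
#'   releases one free acetate on deacetylation.
#' @param carbon_atoms Carbons per mole of substrate.
#' @param molar_mass Molar mass in g/mol (informational).
#' @param activation_atp_per_hexose ATP spent activating each hexose
#'   equivalent (phosphorylation on uptake/entry); default 1.
#' @return A one-row tibble.
#' @export
#' @examples
#' substrate_spec("lnnt", 4, 1, 26, 707.63)
substrate_spec <- function(name, hexose_equivalents, glcnac_residues = 0,
                           carbon_atoms = 6 * (hexose_equivalents - glcnac_residues) +
                             8 * glcnac_residues,
                           molar_mass = NA_real_,
                           activation_atp_per_hexose = 1) {
  spec <- tibble::tibble(
    name = as.character(name),
    hexose_equivalents = as.numeric(hexose_equivalents),
    glcnac_residues = as.numeric(glcnac_residues),
    carbon_atoms = as.numeric(carbon_atoms),
    molar_mass = as.numeric(molar_mass),
    activation_atp_per_hexose = as.numeric(activation_atp_per_hexose)
  )
  validate_substrate(spec)
}

validate_substrate <- function(spec) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  if (!is.finite(spec$hexose_equivalents) || spec$hexose_equivalents <= 0) {
    stop("hexose_equivalents must be positive for a fermentable substrate",
         call. = FALSE)
  }
  if (spec$glcnac_residues < 0 || spec$glcnac_residues > spec$hexose_equivalents) {
    stop("glcnac_residues must lie in [0, hexose_equivalents]", call. = FALSE)
  }
  if (!is.finite(spec$carbon_atoms) || spec$carbon_atoms <= 0) {
    stop("carbon_atoms must be positive", call. = FALSE)
  }
  spec
}

#' Look up a substrate in a registry
#'
#' @param name Substrate name (case-insensitive).
#' @param registry A registry tibble from [substrate_registry()].
#' @inheritParams substrate_spec
#' @return A one-row substrate tibble as from [substrate_spec()].
#' @export
get_substrate <- function(name, registry = substrate_registry(),
                          activation_atp_per_hexose = 1) {
  hit <- registry[tolower(registry$name) == tolower(name), , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("substrate '", name, "' not found in registry (available: ",
         paste(registry$name, collapse = ", "), ")", call. = FALSE)
  }
  substrate_spec(hit$name[1], hit$hexose_equivalents[1], hit$glcnac_residues[1],
                 hit$carbon_atoms[1], hit$molar_mass[1],
                 activation_atp_per_hexose)
}
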