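hexose2 <- substrate_spec("hexose-pair", 2)

test_that("classical bifid shunt yields 3 acetate and 2 lactate per 2 hexose", {
  flux <- predict_fluxes(hexose2, shunt_params(0))
  expect_equal(flux$acetate_mol, 3)
  expect_equal(flux$lactate_mol, 2)
  expect_equal(flux$formate_mol, 0)
  expect_equal(flux$ethanol_mol, 0)
  r <- theoretical_ratios(flux)
  expect_equal(r$aa_la, 1.5)
  expect_true(r$aa_la_defined)
})

test_that("full PFL shunt with all acetyl-CoA to acetate gives formate:acetate 2:5", {
  flux <- predict_fluxes(hexose2, shunt_params(1, 1))
  expect_equal(flux$formate_mol, 2)
  expect_equal(flux$acetate_mol, 5)
  expect_equal(theoretical_ratios(flux)$fa_aa, 0.4)
})

test_that("ethanol:lactate reaches 1 at f = 2/3, g = 1/2", {
  flux <- predict_fluxes(hexose2, shunt_params(2 / 3, 1 / 2))
  expect_equal(flux$ethanol_mol, flux$lactate_mol)
  expect_equal(theoretical_ratios(flux)$et_la, 1)
})

test_that("GlcNAc deacetylation adds free acetate: LNT at f = 0", {
  # hand stoichiometry: 3/2 * 4 hexose-equivalents + 1 deacetylation acetate
  flux <- predict_fluxes(get_substrate("lnt"), shunt_params(0))
  expect_equal(flux$acetate_mol, 7)
  expect_equal(flux$lactate_mol, 4)
  expect_equal(flux$deacetylation_acetate_mol, 1)
  expect_equal(theoretical_ratios(flux)$aa_la, 1.75)
})

test_that("no shunt flux means no formate, no ethanol, closed redox", {
  for (sub in list(hexose2, get_substrate("lnnt"), get_substrate("galactose"))) {
    flux <- predict_fluxes(sub, shunt_params(0))
    expect_equal(flux$formate_mol, 0)
    expect_equal(flux$ethanol_mol, 0)
    expect_equal(flux$nadh_residual_mol, 0)
  }
})

test_that("carbon is conserved exactly for random substrates and partitions", {
  set.seed(101)
  for (i in 1:200) {
    H <- sample(1:6, 1)
    N <- sample(0:H, 1)
    sub <- substrate_spec("rand", H, N)
    f <- runif(1); g <- runif(1)
    flux <- predict_fluxes(sub, shunt_params(f, g))
    expect_equal(flux$carbon_in_products_mol, sub$carbon_atoms,
                 tolerance = 1e-12)
  }
})

test_that("acetate:lactate ratio is nondecreasing in f and in g", {
  grid <- seq(0, 1, by = 0.1)
  for (g in c(0.2, 0.5, 0.9)) {
    aa_la <- vapply(grid[grid < 1], function(f) {
      theoretical_ratios(predict_fluxes(hexose2, shunt_params(f, g)))$aa_la
    }, numeric(1))
    expect_true(all(diff(aa_la) >= -1e-12))
  }
  for (f in c(0.2, 0.5, 0.9)) {
    aa_la <- vapply(grid, function(g) {
      theoretical_ratios(predict_fluxes(hexose2, shunt_params(f, g)))$aa_la
    }, numeric(1))
    expect_true(all(diff(aa_la) >= -1e-12))
  }
})

test_that("NADH residual follows the closed form H*f*(2g-1)", {
  set.seed(7)
  for (i in 1:50) {
    f <- runif(1); g <- runif(1); H <- sample(1:4, 1)
    flux <- predict_fluxes(substrate_spec("s", H), shunt_params(f, g))
    expect_equal(flux$nadh_residual_mol, H * f * (2 * g - 1),
                 tolerance = 1e-12)
    # zero iff f = 0 or g = 1/2
    expect_equal(flux$nadh_residual_mol == 0, f == 0 || g == 0.5)
  }
  expect_equal(predict_fluxes(hexose2, shunt_params(0.7, 0.5))$nadh_residual_mol, 0)
  expect_equal(predict_fluxes(hexose2, shunt_params(0, 0.9))$nadh_residual_mol, 0)
})

test_that("ATP per hexose equivalent is 1.5 at f = 0 with unit activation cost", {
  for (H in 1:4) {
    flux <- predict_fluxes(substrate_spec("s", H), shunt_params(0))
    expect_equal(flux$atp_mol / H, 1.5)
  }
  # atp_per_gap knob switches to the textbook two-ATP count
  flux2 <- predict_fluxes(hexose2, shunt_params(0), atp_per_gap = 2)
  expect_equal(flux2$atp_mol / 2, 2.5)
})

test_that("redox-balance enforcement pins g at one half when f > 0", {
  expect_equal(shunt_params(0.4, 0.9, enforce_redox_balance = TRUE)$g, 0.5)
  expect_equal(shunt_params(0, 0.9, enforce_redox_balance = TRUE)$g, 0.9)
})

test_that("glcnac bypass removes the diverted residue from catabolism", {
  lnt <- get_substrate("lnt")
  full <- predict_fluxes(lnt, shunt_params(0), glcnac_bypass = 0)
  none <- predict_fluxes(lnt, shunt_params(0), glcnac_bypass = 1)
  expect_equal(none$deacetylation_acetate_mol, 0)
  expect_equal(none$lactate_mol, 3)          # only 3 hexose equivalents remain
  expect_lt(none$acetate_mol, full$acetate_mol)
})

test_that("invalid partitions and substrates are rejected", {
  expect_error(shunt_params(-0.1), "f must")
  expect_error(shunt_params(0.5, 1.2), "g must")
  expect_error(substrate_spec("bad", 0), "hexose_equivalents")
  expect_error(substrate_spec("bad", 1, 2), "glcnac_residues")
})

test_that("ratios with zero denominators are flagged undefined, not infinite", {
  flux <- predict_fluxes(hexose2, shunt_params(1, 1))  # lactate = 0
  r <- theoretical_ratios(flux)
  expect_false(r$aa_la_defined)
  expect_true(is.na(r$aa_la))
  expect_false(any(is.infinite(c(r$aa_la, r$fa_la, r$et_la)), na.rm = TRUE))
})

test_that("substrate registry carries the expected built-in compositions", {
  reg <- substrate_registry()
  lnnt <- get_substrate("lnnt", reg)
  expect_equal(lnnt$hexose_equivalents, 4)
  expect_equal(lnnt$glcnac_residues, 1)
  expect_equal(lnnt$carbon_atoms, 26)
  # composition identity 6*(H - N) + 8*N holds for every built-in
  expect_equal(reg$carbon_atoms,
               6 * (reg$hexose_equivalents - reg$glcnac_residues) +
                 8 * reg$glcnac_residues)
  expect_error(get_substrate("sucrose", reg), "not found")
})
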