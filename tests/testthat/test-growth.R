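test_that("growth model is anchored at zero and approaches its plateau", {
  expect_equal(growth_model(0, 1.27, 0.56, 8), 0)
  expect_equal(growth_model(0, 0.3, 2, 15), 0)
  # closed-form value at large t: a * (1 - 1/(1 + exp(k*tc)))
  expect_equal(growth_model(1e6, 1, 0.5, 8), 1 - 1 / (1 + exp(4)),
               tolerance = 1e-9)
  expect_equal(1 - 1 / (1 + exp(4)), 0.98201, tolerance = 1e-5)
  # strictly increasing, supremum below od_asym
  t <- seq(0, 48, by = 0.5)
  y <- growth_model(t, 1.27, 0.56, 8)
  expect_true(all(diff(y) > 0))
  expect_lt(max(y), 1.27)
})

test_that("growth rate peaks at the inflection time", {
  t <- seq(0, 30, by = 0.01)
  y <- growth_model(t, 1.1, 0.6, 9)
  slopes <- diff(y) / diff(t)
  expect_equal(t[which.max(slopes)], 9, tolerance = 0.02)
})

test_that("noiseless round trip recovers the lactose-like parameters to 1e-6", {
  truth <- c(od_asym = 1.27, k = 0.56, tc = 8)
  d <- tibble::tibble(time_h = seq(0, 48, length.out = 30))
  d$od600 <- growth_model(d$time_h, truth[1], truth[2], truth[3])
  fit <- fit_growth(d)
  expect_true(fit$converged)
  expect_equal(fit$par$od_asym, truth[["od_asym"]], tolerance = 1e-6)
  expect_equal(fit$par$k, truth[["k"]], tolerance = 1e-6)
  expect_equal(fit$par$tc, truth[["tc"]], tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("flat series report no growth instead of crashing", {
  d <- tibble::tibble(time_h = 0:10, od600 = rep(0.01, 11))
  fit <- fit_growth(d)
  expect_true(fit$no_growth)
  expect_false(fit$converged)
  expect_true(is.na(fit$par$od_asym))
})

test_that("k is recovered within 5% on average across noisy curves", {
  set.seed(11)
  times <- seq(0, 48, by = 1)
  rel_err <- replicate(100, {
    a <- runif(1, 0.8, 1.4); k <- runif(1, 0.4, 0.7); tc <- runif(1, 6, 12)
    d <- tibble::tibble(
      time_h = times,
      od600 = pmax(growth_model(times, a, k, tc) + rnorm(length(times), 0, 0.02), 0))
    fit <- fit_growth(d)
    if (!fit$converged) return(NA_real_)
    abs(fit$par$k - k) / k
  })
  expect_true(all(!is.na(rel_err)))
  expect_lt(mean(rel_err), 0.05)
})

test_that("fits are invariant to a uniform time-axis offset", {
  d <- tibble::tibble(time_h = seq(0, 40, length.out = 25))
  d$od600 <- growth_model(d$time_h, 1.1, 0.5, 9)
  base <- fit_growth(d)
  shifted <- fit_growth(tibble::tibble(time_h = d$time_h + 5, od600 = d$od600))
  # tc moves by the offset; k and od_asym change only through the small
  # zero-anchor term (the family is not exactly closed under translation)
  expect_equal(shifted$par$k, base$par$k, tolerance = 0.05)
  expect_equal(shifted$par$tc - 5, base$par$tc, tolerance = 0.02)
})

test_that("blank correction subtracts the control mean and clips at zero", {
  expect_equal(blank_correct(c(0.2, 0.05), c(0.1, 0.1)), c(0.1, 0))
})

test_that("kinetic summaries report group means, SDs and sizes", {
  fits <- tibble::tibble(
    strain = "s", substrate = rep(c("lactose", "lnnt"), c(3, 1)),
    replicate = c("r1", "r2", "r3", "r1"),
    od_asym = c(1.0, 1.2, 1.4, 0.8), k = c(0.5, 0.5, 0.5, 0.6),
    tc = 8, rss = 0, converged = TRUE, no_growth = FALSE, n_points = 30L)
  s <- summarize_kinetics(fits)
  lac <- s[s$substrate == "lactose", ]
  expect_equal(lac$od_asym_mean, 1.2)
  expect_equal(lac$od_asym_sd, 0.2)
  expect_equal(lac$k_sd, 0)
  expect_equal(lac$n, 3L)
  # single-fit group: SD undefined
  expect_true(is.na(s$od_asym_sd[s$substrate == "lnnt"]))
})

test_that("groups with no converged fit are excluded with a warning", {
  fits <- tibble::tibble(
    strain = "s", substrate = c("lactose", "glcnac"), replicate = "r1",
    od_asym = c(1.2, NA), k = c(0.5, NA), tc = c(8, NA), rss = c(0, NA),
    converged = c(TRUE, FALSE), no_growth = c(FALSE, TRUE), n_points = 30L)
  expect_warning(s <- summarize_kinetics(fits), "glcnac")
  expect_equal(nrow(s), 1)
})

test_that("replicate-outlier rule flags only a single far-out value", {
  expect_equal(flag_replicate_outlier(c(1.0, 1.01, 0.99, 5)),
               c(FALSE, FALSE, FALSE, TRUE))
  # must keep at least three replicates
  expect_equal(flag_replicate_outlier(c(1.0, 1.01, 5)), rep(FALSE, 3))
  # tight cluster: nothing flagged
  expect_equal(flag_replicate_outlier(c(1.0, 1.05, 0.95, 1.02)), rep(FALSE, 4))
})

test_that("grouped fitting returns one row per replicate curve", {
  sim <- simulate_growth(noise_sd = 0, seed = 3,
                         design = growth_presets()[1:2, ])
  fits <- fit_growth_curves(dplyr::filter(sim, substrate != "none"))
  expect_equal(nrow(fits), 6)
  expect_true(all(fits$converged))
  expect_equal(fits$k[fits$substrate == "lactose"], rep(0.56, 3),
               tolerance = 1e-5)
})
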