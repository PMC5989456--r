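test_that("panel ratios are computed per replicate with undefined flags", {
  panel <- tibble::tibble(
    sample = c("a", "b", "c"),
    substrate = c("lactose", "lnt", "odd"),
    acetate_mM = c(3, 84.8, 5),
    lactate_mM = c(2, 46.5, 0),
    formate_mM = c(0, 1, 2),
    ethanol_mM = c(0, 0.5, 1))
  r <- compute_ratios(panel)
  expect_equal(r$aa_la[1], 1.5)
  expect_equal(r$aa_la[2], 84.8 / 46.5, tolerance = 1e-12)
  expect_equal(round(r$aa_la[2], 3), 1.824)
  expect_true(is.na(r$aa_la[3]))
  expect_false(r$aa_la_defined[3])
  # per-replicate, not ratio of means: mean of ratios differs from ratio of means
  expect_false(isTRUE(all.equal(mean(r$aa_la[1:2]),
                                sum(panel$acetate_mM[1:2]) /
                                  sum(panel$lactate_mM[1:2]))))
})

test_that("one-way ANOVA reproduces the hand-computed three-group instance", {
  d <- tibble::tibble(value = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                      grp = rep(c("g1", "g2", "g3"), each = 3))
  res <- anova_tukey(d, "value", "grp")
  a <- res$anova[res$anova$term == "grp", ]
  expect_equal(a$statistic, 3)
  expect_equal(a$df, 2)
  expect_equal(res$anova$df[res$anova$term == "Residuals"], 6)
  expect_equal(a$sumsq, 6)
})

test_that("identical groups give F = 0 and translation leaves F unchanged", {
  d <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                      grp = rep(c("a", "b"), each = 3))
  res <- anova_tukey(d, "value", "grp")
  expect_equal(res$anova$statistic[1], 0)

  set.seed(9)
  d2 <- tibble::tibble(value = rnorm(12), grp = rep(letters[1:3], 4))
  f0 <- anova_tukey(d2, "value", "grp")$anova$statistic[1]
  d2$value <- d2$value + 100
  expect_equal(anova_tukey(d2, "value", "grp")$anova$statistic[1], f0,
               tolerance = 1e-9)
})

test_that("Tukey adjusted p-values dominate unadjusted pairwise t-tests", {
  set.seed(31)
  for (i in 1:10) {
    d <- tibble::tibble(value = rnorm(12, mean = rep(c(0, 0.5, 1, 2), 3)),
                        grp = rep(letters[1:4], 3))
    res <- anova_tukey(d, "value", "grp")
    mse <- res$anova$meansq[res$anova$term == "Residuals"]
    dfr <- res$anova$df[res$anova$term == "Residuals"]
    for (j in seq_len(nrow(res$tukey))) {
      pair <- strsplit(res$tukey$contrast[j], "-", fixed = TRUE)[[1]]
      x1 <- d$value[d$grp == pair[1]]; x2 <- d$value[d$grp == pair[2]]
      tstat <- (mean(x1) - mean(x2)) /
        sqrt(mse * (1 / length(x1) + 1 / length(x2)))
      p_unadj <- 2 * stats::pt(-abs(tstat), dfr)
      expect_gte(res$tukey$adj_p_value[j] + 1e-12, p_unadj)
    }
  }
})

test_that("Tukey at two groups reproduces the pooled-variance t-test", {
  set.seed(17)
  for (i in 1:20) {
    d <- tibble::tibble(value = rnorm(10, mean = rep(c(0, runif(1, 0, 2)),
                                                     each = 5)),
                        grp = rep(c("a", "b"), each = 5))
    res <- anova_tukey(d, "value", "grp")
    p_t <- stats::t.test(value ~ grp, data = d, var.equal = TRUE)$p.value
    expect_equal(res$tukey$adj_p_value, p_t, tolerance = 1e-6)
    expect_equal(res$tukey$adj_p_value < 0.05, p_t < 0.05)
  }
})

test_that("studentized-range quantiles match published 5% critical values", {
  # Harter (1960) tables, alpha = 0.05
  published <- tibble::tribble(
    ~k, ~df, ~q,
    3,  10,  3.88,
    4,  20,  3.96,
    6,  30,  4.30,
    2,  10,  3.15
  )
  got <- mapply(function(k, df) stats::qtukey(0.95, k, df),
                published$k, published$df)
  expect_equal(got, published$q, tolerance = 0.005)
})

test_that("two-way ANOVA reports both factors and simple effects", {
  set.seed(25)
  d <- tidyr::expand_grid(strain = c("s1", "s2"),
                          substrate = c("lactose", "lnt", "lnnt"),
                          rep = 1:3)
  d$value <- rnorm(nrow(d)) +
    ifelse(d$substrate == "lnnt", 2, 0) + ifelse(d$strain == "s2", 1, 0)
  res <- anova_tukey(d, "value", "substrate", "strain")
  expect_setequal(res$anova$term,
                  c("substrate", "strain", "substrate:strain", "Residuals"))
  expect_true(all(c("substrate", "strain") %in% res$tukey$term))
  expect_true(nrow(res$simple_effects) > 0)
  expect_true(any(grepl("strain=", res$simple_effects$within)))
  expect_true(any(grepl("substrate=", res$simple_effects$within)))
})

test_that("PCA captures collinear data on one component and is rotation-stable", {
  x <- cbind(1:6, 2 * (1:6))
  p <- pca_ordination(x)
  expect_equal(p$variance_explained[1], 1)
  # orthogonal rotation leaves the spectrum unchanged
  set.seed(2)
  m <- matrix(rnorm(40), 10, 4)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  ve1 <- pca_ordination(m)$variance_explained
  ve2 <- pca_ordination(m %*% q)$variance_explained
  expect_equal(ve1, ve2, tolerance = 1e-9)
  expect_true(all(diff(ve1) <= 1e-12))
  expect_equal(sum(ve1), 1)
})

test_that("PCA total variance equals the summed column variances", {
  set.seed(8)
  m <- matrix(rnorm(30), 10, 3)
  p <- pca_ordination(m)
  total <- sum(apply(p$scores[paste0("PC", 1:3)], 2, stats::var))
  expect_equal(total, sum(apply(m, 2, stats::var)), tolerance = 1e-9)
})

test_that("PCA canonicalizes loading signs and rejects constant scaled columns", {
  set.seed(4)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- pca_ordination(m)
  for (j in paste0("PC", 1:3)) {
    v <- p$loadings[[j]]
    expect_gt(v[which.max(abs(v))], 0)
  }
  m[, 2] <- 5
  expect_error(pca_ordination(m, scale = TRUE), "b")
})

test_that("Ward clustering merges the close pair first and handles duplicates", {
  x <- rbind(c(0, 0), c(0.1, 0), c(10, 10))
  hc <- hierarchical_cluster(x)
  expect_equal(sort(hclust_merge_sets(hc$hclust)[[1]]), c(1, 2))
  xd <- rbind(c(1, 1), c(1, 1), c(5, 5))
  expect_equal(hierarchical_cluster(xd)$hclust$height[1], 0)
  expect_error(hierarchical_cluster(rbind(c(NaN, 1), c(1, 2))), "NaN")
})

test_that("Ward heights are monotone and topology matches the brute-force oracle", {
  for (s in 1:50) {
    set.seed(s)
    x <- matrix(rnorm(12), 6, 2)
    hc <- hierarchical_cluster(x)
    expect_true(all(diff(hc$hclust$height) >= -1e-12))
    expect_equal(merge_signature(hclust_merge_sets(hc$hclust)),
                 merge_signature(ward_oracle_merges(x)))
  }
})

test_that("dendrograms serialize to parseable Newick with the right tips", {
  x <- matrix(rnorm(10), 5, 2,
              dimnames = list(paste0("s", 1:5), NULL))
  nwk <- as_newick(hierarchical_cluster(x))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, paste0("s", 1:5))
})
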