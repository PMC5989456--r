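#' Per-replicate endproduct ratios of a metabolite panel
#'
#' Computes acetate:lactate, formate:lactate, formate:acetate and
#' ethanol:lactate ratios for every row (replicate) of a measured panel —
#' never ratios of group means, matching the per-replicate treatment used for
#' fermentation endproduct statistics. Zero-denominator ratios are `NA` with
#' their `*_defined` flag `FALSE` and must be excluded, not zero-filled,
#' downstream.
#'
#' @param panel Tibble with columns `acetate_mM`, `lactate_mM`, `formate_mM`,
#'   `ethanol_mM` (plus any identifying columns).
#' @return Tibble of per-row ratios; see [theoretical_ratios()].
#' @export
#' @examples
#' compute_ratios(tibble::tibble(acetate_mM = 3, lactate_mM = 2,
#'                               formate_mM = 0, ethanol_mM = 0))
compute_ratios <- function(panel) {
  theoretical_ratios(panel)
}

#' One- or two-way ANOVA with Tukey HSD comparisons
#'
#' One-way designs use `aov` F tests; two-way designs fit `value ~ A * B`
#' and report type II sums of squares (robust to the mild imbalance left by
#' replicate-outlier removal). All pairwise comparisons use Tukey's honest
#' significant difference with studentized-range quantiles at level `alpha`
#' (the Tukey-Kramer adjustment under imbalance, as implemented by
#' `TukeyHSD`). For two-way designs, simple-effect comparisons — levels of
#' one factor within each level of the other — are computed by within-level
#' Tukey HSD.
#'
#' @param data Data frame of grouped measurements.
#' @param response,factor_a,factor_b Column names (strings); `factor_b = NULL`
#'   selects a one-way design.
#' @param alpha Family-wise error rate for Tukey intervals; default 0.05.
#' @return Object of class `anova_tukey`: list with `anova` (term, df, sumsq,
#'   meansq, statistic, p_value), `tukey` (per-term pairwise table),
#'   `simple_effects` (two-way only), `alpha`, `design`,
#'   `zero_residual_variance`.
#' @export
#' @examples
#' d <- tibble::tibble(value = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                     grp = rep(c("a", "b", "c"), each = 3))
#' anova_tukey(d, "value", "grp")
anova_tukey <- function(data, response, factor_a, factor_b = NULL,
                        alpha = 0.05) {
  stopifnot(is.data.frame(data), response %in% names(data),
            factor_a %in% names(data))
  if (!is.null(factor_b)) stopifnot(factor_b %in% names(data))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)

  d <- data.frame(
    value = as.numeric(data[[response]]),
    A = factor(data[[factor_a]])
  )
  if (!is.null(factor_b)) d$B <- factor(data[[factor_b]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$A)) < 2) {
    stop("need at least 2 groups in ", factor_a, call. = FALSE)
  }

  two_way <- !is.null(factor_b)
  form <- if (two_way) value ~ A * B else value ~ A
  fit <- stats::aov(form, data = d)
  if (stats::df.residual(fit) < 1) {
    stop("residual degrees of freedom must be at least 1", call. = FALSE)
  }

  zero_resid <- stats::deviance(fit) <= .Machine$double.eps^0.75 *
    max(sum(d$value^2), 1)

  term_names <- function(x) {
    x[x == "A"] <- factor_a
    if (two_way) {
      x[x == "B"] <- factor_b
      x[x == "A:B"] <- paste(factor_a, factor_b, sep = ":")
    }
    x
  }
  if (two_way) {
    a2 <- car::Anova(fit, type = "II")
    terms <- rownames(a2)
    keep <- terms != "Residuals"
    anova_tbl <- tibble::tibble(
      term = term_names(c(terms[keep], "Residuals")),
      df = c(a2[["Df"]][keep], a2[["Df"]][!keep]),
      sumsq = c(a2[["Sum Sq"]][keep], a2[["Sum Sq"]][!keep]),
      meansq = .data$sumsq / .data$df,
      statistic = c(a2[["F value"]][keep], NA_real_),
      p_value = c(a2[["Pr(>F)"]][keep], NA_real_)
    )
  } else {
    s <- summary(fit)[[1]]
    anova_tbl <- tibble::tibble(
      term = term_names(trimws(rownames(s))),
      df = s$Df, sumsq = s$`Sum Sq`, meansq = s$`Mean Sq`,
      statistic = s$`F value`, p_value = s$`Pr(>F)`
    )
  }

  tukey_tidy <- function(aov_fit, which, level) {
    th <- stats::TukeyHSD(aov_fit, which = which, conf.level = 1 - level)
    purrr::imap_dfr(th, function(m, term) {
      tibble::tibble(
        term = term,
        contrast = rownames(m),
        estimate = m[, "diff"],
        conf_low = m[, "lwr"],
        conf_high = m[, "upr"],
        adj_p_value = m[, "p adj"]
      )
    })
  }
  which_terms <- if (two_way) c("A", "B") else "A"
  tukey_tbl <- tukey_tidy(fit, which_terms, alpha)
  relabel <- c(A = factor_a, B = if (two_way) factor_b else NULL)
  tukey_tbl$term <- unname(relabel[tukey_tbl$term])

  simple_effects <- NULL
  if (two_way) {
    one_within <- function(split_col, comp_col, split_name, comp_name) {
      purrr::map_dfr(levels(d[[split_col]]), function(lev) {
        sub <- d[d[[split_col]] == lev, , drop = FALSE]
        sub[[comp_col]] <- droplevels(sub[[comp_col]])
        if (nlevels(sub[[comp_col]]) < 2) return(NULL)
        counts <- table(sub[[comp_col]])
        if (sum(counts) - length(counts) < 1) return(NULL)
        subfit <- stats::aov(stats::reformulate(comp_col, "value"), data = sub)
        tt <- tukey_tidy(subfit, comp_col, alpha)
        tt$term <- comp_name
        tt$within <- paste0(split_name, "=", lev)
        tt
      })
    }
    simple_effects <- dplyr::bind_rows(
      one_within("B", "A", factor_b, factor_a),
      one_within("A", "B", factor_a, factor_b)
    )
  }

  out <- list(anova = anova_tbl, tukey = tukey_tbl,
              simple_effects = simple_effects, alpha = alpha,
              design = if (two_way) "two_way" else "one_way",
              zero_residual_variance = zero_resid)
  class(out) <- "anova_tukey"
  out
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("%s ANOVA with Tukey HSD (alpha = %g)\n",
              if (x$design == "two_way") "Two-way" else "One-way", x$alpha))
  print(x$anova)
  if (x$zero_residual_variance) {
    cat("note: zero residual variance; p-values are boundary cases\n")
  }
  invisible(x)
}

#' Principal component analysis of a samples x variables table
#'
#' Columns are mean-centered (and optionally scaled to unit variance) and
#' decomposed by SVD. Loadings signs are canonicalized so the
#' largest-magnitude element of each component is positive, making results
#' reproducible across platforms. Samples absent for a condition (no growth)
#' should be encoded as 0 before calling, or excluded, per the caller's
#' missing-data policy.
#'
#' @param x Numeric matrix or data frame (samples in rows); non-numeric
#'   columns of a data frame are carried into the scores as identifiers.
#' @param scale Scale columns to unit variance; errors on a constant column.
#' @return Object of class `pca_ord`: list with `scores` tibble, `loadings`
#'   tibble, `variance_explained` (fractions, nonincreasing).
#' @export
pca_ordination <- function(x, scale = FALSE) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    ids <- x[!num, drop = FALSE]
    mat <- as.matrix(x[num])
  } else {
    ids <- NULL
    mat <- as.matrix(x)
  }
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need at least 2 samples and 2 variables", call. = FALSE)
  }
  if (any(!is.finite(mat))) stop("matrix contains non-finite values", call. = FALSE)
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  }
  if (scale) {
    sds <- apply(mat, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column(s) cannot be scaled: ",
           paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale)

  # canonical signs: largest-|loading| entry of each PC positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)

  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  if (!is.null(ids) && ncol(ids) > 0) {
    scores <- dplyr::bind_cols(tibble::as_tibble(ids), scores)
  }
  out <- list(
    scores = scores,
    loadings = dplyr::bind_cols(
      tibble::tibble(variable = rownames(pc$rotation)),
      tibble::as_tibble(pc$rotation)),
    variance_explained = ve
  )
  class(out) <- "pca_ord"
  out
}

#' @export
print.pca_ord <- function(x, ...) {
  cat("PCA ordination:",
      paste0("PC", seq_along(x$variance_explained), " ",
             sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Ward hierarchical clustering on Euclidean distances
#'
#' Agglomerative clustering minimizing the Ward variance increase at each
#' merge (`hclust` method `ward.D2` on Euclidean distances, the formulation
#' whose merge heights are guaranteed monotone nondecreasing). Ties are
#' resolved deterministically by lowest observation index.
#'
#' @param x Numeric matrix or data frame of samples x variables; row names
#'   (or a `label` column) label the leaves.
#' @param scale_columns Mean-center and unit-scale each variable first (the
#'   convention used for metabolite heatmaps); default `FALSE`.
#' @return Object of class `ward_clust` wrapping the `hclust` result:
#'   `merge`, `height`, `labels` accessible as in `hclust`.
#' @export
hierarchical_cluster <- function(x, scale_columns = FALSE) {
  if (is.data.frame(x)) {
    labs <- if ("label" %in% names(x)) as.character(x$label) else rownames(x)
    mat <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  } else {
    labs <- rownames(x)
    mat <- as.matrix(x)
  }
  if (nrow(mat) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(is.nan(mat)) || any(!is.finite(mat))) {
    stop("matrix contains NaN or non-finite values", call. = FALSE)
  }
  if (scale_columns) mat <- scale(mat)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(mat)))
  rownames(mat) <- labs
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  out <- list(hclust = hc, labels = labs)
  class(out) <- "ward_clust"
  out
}

#' @export
print.ward_clust <- function(x, ...) {
  cat("Ward/Euclidean hierarchical clustering of", length(x$labels),
      "samples\n")
  cat("merge heights:", paste(signif(x$hclust$height, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize a dendrogram to Newick
#'
#' @param clust A `ward_clust` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
as_newick <- function(clust, path = NULL) {
  stopifnot(inherits(clust, "ward_clust"))
  phy <- ape::as.phylo(clust$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
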