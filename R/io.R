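# CSV schemas shared by the readers, writers and the pipeline.
SCHEMAS <- list(
  growth = c("strain", "substrate", "replicate", "time_h", "od600"),
  standards = c("analyte", "concentration_mM", "response"),
  panel = c("sample", "strain", "substrate", "acetate_mM", "lactate_mM",
            "formate_mM", "ethanol_mM", "pre_fermentation_substrate_mM"),
  ct = c("sample", "condition", "gene", "role", "ct")
)

read_schema_csv <- function(path, schema) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(SCHEMAS[[schema]], names(x))
  if (length(missing) > 0) {
    stop(schema, " CSV '", path, "' is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read and write the pipeline CSV schemas
#'
#' Header-validated UTF-8 CSV I/O for the four interchange tables: growth
#' time series (`strain`, `substrate`, `replicate`, `time_h`, `od600`),
#' calibration standards (`analyte`, `concentration_mM`, `response`),
#' metabolite panels (`sample`, `strain`, `substrate`, the four `*_mM`
#' endproducts, `pre_fermentation_substrate_mM`, optional `residual_*_mM`),
#' and qPCR Ct records (`sample`, `condition`, `gene`, `role`, `ct`). A
#' missing column raises an error naming it; CRLF and LF files parse
#' identically (readr). Panels with negative concentrations are rejected.
#' Numbers are written with 12 significant digits so that write-read round
#' trips preserve values to the precision the analysis uses.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return Readers return a validated tibble; writers return `x` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_growth_csv <- function(path) read_schema_csv(path, "growth")

#' @rdname pipeline_io
#' @export
read_standards_csv <- function(path) read_schema_csv(path, "standards")

#' @rdname pipeline_io
#' @export
read_panel_csv <- function(path) {
  x <- read_schema_csv(path, "panel")
  conc_cols <- grep("_mM$", names(x), value = TRUE)
  for (cc in conc_cols) {
    if (any(x[[cc]] < 0, na.rm = TRUE)) {
      stop("panel CSV '", path, "' has negative values in ", cc, call. = FALSE)
    }
  }
  x
}

#' @rdname pipeline_io
#' @export
read_ct_csv <- function(path) read_schema_csv(path, "ct")

#' @rdname pipeline_io
#' @export
write_table_csv <- function(x, path) {
  out <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double),
                                        ~ signif(.x, 12)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(x)
}

#' Run the full fermentation-analysis pipeline
#'
#' Orchestrates every stage on in-memory inputs: growth-curve fitting and
#' kinetic summaries, per-replicate endproduct ratios, carbon recovery,
#' inverse flux-partition estimation per sample, one-way ANOVA with Tukey HSD
#' on the acetate:lactate ratio across substrates, PCA and Ward clustering of
#' the endproduct panel, and delta-delta-Ct fold changes. Results are
#' returned as a named list of tibbles and, when `out_dir` is given, written
#' as CSV tables (plus a Newick dendrogram and a run log); every table
#' carries `run_id` and `seed` provenance columns. Identical inputs and seed
#' give identical outputs.
#'
#' @param growth Growth time-series tibble (schema of [read_growth_csv()]);
#'   `NULL` skips the stage.
#' @param panels Metabolite panel tibble ([read_panel_csv()] schema); `NULL`
#'   skips fermentation stages.
#' @param cts Ct record tibble ([read_ct_csv()] schema); `NULL` skips the
#'   expression stage.
#' @param reference_condition Reference for fold changes; default "lactose".
#' @param registry Substrate registry tibble.
#' @param alpha Significance level for Tukey intervals.
#' @param seed Integer seed recorded in provenance and used for any stochastic
#'   step.
#' @param out_dir Output directory; created if needed. `NULL` suppresses file
#'   output.
#' @return Named list: `growth_fits`, `kinetics`, `ratios`, `recovery`,
#'   `shunt_fits`, `ratio_anova`, `pca`, `clustering`, `fold_changes`,
#'   `run_id`.
#' @export
run_pipeline <- function(growth = NULL, panels = NULL, cts = NULL,
                         reference_condition = "lactose",
                         registry = substrate_registry(), alpha = 0.05,
                         seed = 1, out_dir = NULL) {
  run_id <- sprintf("bifidshunt-%d", as.integer(seed))
  res <- list(run_id = run_id)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(growth)) {
    res$growth_fits <- stage("fit-growth", fit_growth_curves(growth))
    res$kinetics <- stage("kinetics", summarize_kinetics(res$growth_fits))
  }

  if (!is.null(panels)) {
    res$ratios <- stage("ratios", compute_ratios(panels))
    res$recovery <- stage("carbon-recovery", {
      purrr::map_dfr(seq_len(nrow(panels)), function(i) {
        row <- panels[i, , drop = FALSE]
        tibble::tibble(
          sample = row$sample, strain = row$strain, substrate = row$substrate,
          carbon_recovery_pct = carbon_recovery(
            row, get_substrate(row$substrate, registry), registry))
      })
    })
    res$shunt_fits <- stage("fluxfit", {
      purrr::map_dfr(seq_len(nrow(panels)), function(i) {
        row <- panels[i, , drop = FALSE]
        fit <- fit_shunt(row, get_substrate(row$substrate, registry))
        dplyr::bind_cols(
          tibble::tibble(sample = row$sample, strain = row$strain,
                         substrate = row$substrate),
          fit$par,
          tibble::tibble(residual_norm = fit$residual_norm,
                         g_identifiable = fit$g_identifiable))
      })
    })
    if (length(unique(panels$substrate)) >= 2) {
      usable <- res$ratios[res$ratios$aa_la_defined, , drop = FALSE]
      res$ratio_anova <- stage("stats-anova",
                               anova_tukey(usable, "aa_la", "substrate",
                                           alpha = alpha))
    }
    met <- as.matrix(panels[, c("acetate_mM", "lactate_mM", "formate_mM",
                                "ethanol_mM")])
    rownames(met) <- panels$sample
    if (nrow(met) >= 3) {
      res$pca <- stage("stats-pca", pca_ordination(met, scale = FALSE))
      res$clustering <- stage("stats-cluster", hierarchical_cluster(met))
    }
  }

  if (!is.null(cts)) {
    res$fold_changes <- stage("ddct",
                              ddct_fold_change(cts, reference_condition))
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    written <- character(0)
    on_fail_cleanup <- function() unlink(written)
    tryCatch({
      emit <- function(tbl, file) {
        if (is.null(tbl)) return(invisible(NULL))
        path <- file.path(out_dir, file)
        write_table_csv(dplyr::mutate(tbl, run_id = run_id, seed = seed), path)
        written <<- c(written, path)
      }
      emit(res$growth_fits, "growth_fits.csv")
      emit(res$kinetics, "kinetics.csv")
      emit(res$ratios, "ratios.csv")
      emit(res$recovery, "carbon_recovery.csv")
      emit(res$shunt_fits, "shunt_fits.csv")
      if (!is.null(res$ratio_anova)) {
        emit(res$ratio_anova$anova, "anova.csv")
        emit(res$ratio_anova$tukey, "tukey.csv")
      }
      if (!is.null(res$pca)) {
        emit(res$pca$scores, "pca_scores.csv")
        emit(res$pca$loadings, "pca_loadings.csv")
      }
      if (!is.null(res$clustering)) {
        as_newick(res$clustering, file.path(out_dir, "dendrogram.nwk"))
        written <- c(written, file.path(out_dir, "dendrogram.nwk"))
      }
      emit(res$fold_changes, "fold_changes.csv")
      log_lines <- c(
        paste0("run_id: ", run_id),
        paste0("seed: ", seed),
        paste0("alpha: ", alpha),
        paste0("reference_condition: ", reference_condition),
        paste0("R: ", R.version.string),
        paste0("bifidshunt: ",
               as.character(utils::packageVersion("bifidshunt"))),
        paste0("stages: ", paste(setdiff(names(res), "run_id"),
                                 collapse = ", "))
      )
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    }, error = function(e) {
      on_fail_cleanup()
      stop(e)
    })
  }
  res
}
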