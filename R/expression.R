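#' Relative gene expression by the comparative Ct (delta-delta-Ct) method
#'
#' For each sample, technical replicates are averaged per gene, then
#' `ΔCt = Ct_target - Ct_control` is formed against the sample's endogenous
#' control (e.g. the cysteinyl-tRNA synthetase gene Blon_0393 for
#' B. infantis). `ΔΔCt = ΔCt - mean(ΔCt in the reference condition)` and the
#' fold change is `E^(-ΔΔCt)` with amplification efficiency `E = 2` (perfect
#' doubling) by default.
#'
#' Per gene and condition the biological summary is the geometric mean fold
#' change (`E^(-mean ΔΔCt)`); dispersion is computed as the SD of log2 fold
#' changes across biological replicates and reported on the linear scale as
#' `fold * (2^sd - 1)`.
#'
#' Samples lacking an endogenous-control measurement are excluded with a
#' warning; a missing reference condition is an error.
#'
#' @param records Tibble with columns `sample`, `condition`, `gene`, `role`
#'   (`"target"` or `"endogenous_control"`), `ct`; a `tech_rep` column is
#'   optional (technical replicates are simply all rows of a sample x gene).
#' @param reference_condition Condition the fold changes are relative to
#'   (e.g. growth on lactose).
#' @param efficiency Amplification efficiency per cycle; default 2.
#' @return Tibble with `gene`, `condition`, `n` (biological replicates),
#'   `fold_change`, `log2_fold_sd`, `fold_sd`. Per-replicate folds are
#'   attached as attribute `"replicates"`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   sample = rep(c("s1", "s2"), each = 2),
#'   condition = rep(c("lactose", "lnt"), each = 2),
#'   gene = rep(c("ctrl", "nagB"), 2),
#'   role = rep(c("endogenous_control", "target"), 2),
#'   ct = c(20, 24, 20, 23))
#' ddct_fold_change(rec, "lactose")   # nagB fold 2 on lnt
ddct_fold_change <- function(records, reference_condition, efficiency = 2) {
  need <- c("sample", "condition", "gene", "role", "ct")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(records$ct <= 0 | records$ct >= 45, na.rm = TRUE)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  if (!reference_condition %in% records$condition) {
    stop("reference condition '", reference_condition, "' absent from records",
         call. = FALSE)
  }
  if (efficiency <= 1) stop("efficiency must exceed 1", call. = FALSE)

  # average technical replicates per sample x gene before anything else
  avg <- records |>
    dplyr::group_by(.data$sample, .data$condition, .data$gene, .data$role) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  ctrl <- avg |>
    dplyr::filter(.data$role == "endogenous_control") |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ct_control = mean(.data$ct), .groups = "drop")

  targets <- dplyr::filter(avg, .data$role == "target")
  no_ctrl <- setdiff(unique(targets$sample), ctrl$sample)
  if (length(no_ctrl) > 0) {
    warning("samples without endogenous control excluded: ",
            paste(no_ctrl, collapse = ", "), call. = FALSE)
    targets <- dplyr::filter(targets, !.data$sample %in% no_ctrl)
  }
  if (nrow(targets) == 0) stop("no usable target measurements", call. = FALSE)

  dct <- targets |>
    dplyr::inner_join(ctrl, by = "sample") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ct_control)

  ref_means <- dct |>
    dplyr::filter(.data$condition == reference_condition) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ref_delta_ct = mean(.data$delta_ct), .groups = "drop")
  missing_ref <- setdiff(unique(dct$gene), ref_means$gene)
  if (length(missing_ref) > 0) {
    stop("no reference-condition measurements for gene(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }

  reps <- dct |>
    dplyr::inner_join(ref_means, by = "gene") |>
    dplyr::mutate(
      ddct = .data$delta_ct - .data$ref_delta_ct,
      fold = efficiency^(-.data$ddct),
      log2_fold = log2(.data$fold)
    )

  out <- reps |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_log2 = mean(.data$log2_fold),
      log2_fold_sd = stats::sd(.data$log2_fold),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold_change = 2^.data$mean_log2,
      fold_sd = .data$fold_change * (2^.data$log2_fold_sd - 1)
    ) |>
    dplyr::select("gene", "condition", "n", "fold_change", "log2_fold_sd",
                  "fold_sd")
  attr(out, "replicates") <- dplyr::select(
    reps, "sample", "condition", "gene", "delta_ct", "ddct", "fold")
  out
}
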