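#' Sigmoidal growth model for blank-corrected OD600
#'
#' Three-parameter logistic used for microplate growth kinetics:
#' \deqn{\Delta OD(t) = \Delta OD_{asym}\left[\frac{1}{1 + e^{k (t_c - t)}}
#'   - \frac{1}{1 + e^{k t_c}}\right]}
#' `od_asym` is the growth level at stationary phase, `k` the growth rate
#' (h^-1), and `tc` the inflection time — the time of maximal growth rate.
#' The second term anchors the curve so that `ΔOD(0) = 0` exactly; the
#' attainable plateau is `od_asym * (1 - 1/(1 + exp(k * tc)))`, slightly
#' below `od_asym`.
#'
#' @param t Time in hours (vectorized).
#' @param od_asym Asymptotic growth level (OD600 units).
#' @param k Growth rate, h^-1.
#' @param tc Inflection time, h.
#' @return ΔOD600 at each `t`.
#' @export
#' @examples
#' growth_model(0:48, od_asym = 1.27, k = 0.56, tc = 8)
growth_model <- function(t, od_asym, k, tc) {
  od_asym * (stats::plogis(k * (t - tc)) - stats::plogis(-k * tc))
}

#' Blank-correct OD600 readings
#'
#' Subtracts the mean of a no-carbohydrate negative-control series and clips
#' negative corrected values at 0.
#'
#' @param od OD600 readings.
#' @param blank Negative-control OD600 readings (same plate).
#' @return Corrected ΔOD600.
#' @export
blank_correct <- function(od, blank) {
  pmax(od - mean(blank, na.rm = TRUE), 0)
}

#' Fit the growth model to one OD600 time series
#'
#' Nonlinear least squares (Levenberg-Marquardt) with data-driven starts:
#' `od_asym` from the maximal OD, `tc` from the time of steepest
#' finite-difference slope, and `k` from that slope via the logistic
#' derivative (`slope_max = od_asym * k / 4`). If the first fit fails, a
#' small multi-start over perturbed `k` and `tc` is tried.
#'
#' A series whose dynamic range `max(od) - min(od)` is below `floor` is
#' reported as "no growth" with `NA` parameters rather than an error, since
#' flat wells are routine in substrate panels.
#'
#' @param data Data frame with a time column (hours) and an OD column.
#' @param time,od Column names (strings) for time and blank-corrected OD600.
#' @param floor Minimal dynamic range (OD units) to attempt a fit; default 0.05.
#' @return An object of class `growth_fit`: list with `par` (tibble
#'   `od_asym`, `k`, `tc`), `rss`, `converged`, `no_growth`, `n`, `data`.
#' @seealso [tidy.growth_fit()], [glance.growth_fit()], [autoplot.growth_fit()]
#' @export
#' @examples
#' d <- tibble::tibble(time_h = 0:30,
#'                     od600 = growth_model(0:30, 1.27, 0.56, 8))
#' fit_growth(d)
fit_growth <- function(data, time = "time_h", od = "od600", floor = 0.05) {
  stopifnot(is.data.frame(data), time %in% names(data), od %in% names(data))
  t <- as.numeric(data[[time]]); y <- as.numeric(data[[od]])
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  ord <- order(t); t <- t[ord]; y <- y[ord]
  if (length(t) < 5) stop("need at least 5 time points", call. = FALSE)
  if (any(duplicated(t))) stop("times must be strictly increasing", call. = FALSE)

  no_fit <- function() {
    out <- list(par = tibble::tibble(od_asym = NA_real_, k = NA_real_,
                                     tc = NA_real_),
                rss = NA_real_, converged = FALSE, no_growth = TRUE,
                n = length(t),
                data = tibble::tibble(time_h = t, od600 = y))
    class(out) <- "growth_fit"
    out
  }
  if (max(y) - min(y) < floor) return(no_fit())

  slopes <- diff(y) / diff(t)
  i_max <- which.max(slopes)
  tc0 <- mean(t[c(i_max, i_max + 1)])
  a0 <- max(y)
  k0 <- max(4 * slopes[i_max] / a0, 0.05)  # logistic: max slope = a*k/4

  df <- data.frame(t = t, y = y)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ growth_model(t, od_asym, k, tc),
        data = df, start = start,
        lower = c(od_asym = 1e-6, k = 1e-6, tc = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  starts <- list(list(od_asym = a0, k = k0, tc = tc0))
  for (mk in c(0.5, 2)) for (mt in c(0.5, 1.5)) {
    starts <- c(starts, list(list(od_asym = a0, k = k0 * mk,
                                  tc = max(tc0 * mt, 0.5))))
  }
  fit <- NULL
  for (s in starts) {
    cand <- try_fit(s)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    out <- no_fit()
    out$no_growth <- FALSE
    return(out)
  }
  cf <- stats::coef(fit)
  out <- list(
    par = tibble::tibble(od_asym = unname(cf["od_asym"]),
                         k = unname(cf["k"]), tc = unname(cf["tc"])),
    rss = stats::deviance(fit),
    converged = TRUE, no_growth = FALSE, n = length(t),
    data = tibble::tibble(time_h = t, od600 = y)
  )
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$no_growth) {
    cat("Growth fit: no growth (dynamic range below floor)\n")
  } else if (!x$converged) {
    cat("Growth fit: did not converge\n")
  } else {
    cat(sprintf(
      "Growth fit: od_asym = %.4g, k = %.4g h^-1, tc = %.4g h (RSS %.3g, n %d)\n",
      x$par$od_asym, x$par$k, x$par$tc, x$rss, x$n))
  }
  invisible(x)
}

#' Fit growth curves for every strain x substrate x replicate
#'
#' @param data Long-format tibble with columns `strain`, `substrate`,
#'   `replicate`, `time_h`, `od600` (blank-corrected).
#' @inheritParams fit_growth
#' @return A tibble with one row per curve: grouping columns, `od_asym`, `k`,
#'   `tc`, `rss`, `converged`, `no_growth`, `n_points`.
#' @export
fit_growth_curves <- function(data, floor = 0.05) {
  need <- c("strain", "substrate", "replicate", "time_h", "od600")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::group_by(.data$strain, .data$substrate, .data$replicate) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(fit = purrr::map(data, fit_growth, floor = floor)) |>
    dplyr::mutate(
      od_asym = purrr::map_dbl(.data$fit, ~ .x$par$od_asym),
      k = purrr::map_dbl(.data$fit, ~ .x$par$k),
      tc = purrr::map_dbl(.data$fit, ~ .x$par$tc),
      rss = purrr::map_dbl(.data$fit, "rss"),
      converged = purrr::map_lgl(.data$fit, "converged"),
      no_growth = purrr::map_lgl(.data$fit, "no_growth"),
      n_points = purrr::map_int(.data$fit, "n")
    ) |>
    dplyr::select(-"data", -"fit")
}

#' Flag a single far-out replicate
#'
#' Replicate-outlier rule for biological replicates: the single farthest-from-
#' mean value is flagged only if its absolute deviation exceeds `k_sd` times
#' the SD of the remaining values and at least `min_keep` replicates remain
#' after removal.
#'
#' @param x Numeric replicate values.
#' @param k_sd Deviation multiplier; default 3.
#' @param min_keep Minimum replicates that must remain; default 3.
#' @return Logical vector, `TRUE` for the flagged outlier (at most one).
#' @export
flag_replicate_outlier <- function(x, k_sd = 3, min_keep = 3) {
  out <- rep(FALSE, length(x))
  if (length(x) <= min_keep) return(out)
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  sd_rest <- stats::sd(x[-i])
  if (is.finite(sd_rest) && sd_rest > 0 && dev[i] > k_sd * sd_rest) {
    out[i] <- TRUE
  }
  out
}

#' Summarize growth kinetics per strain x substrate
#'
#' Mean and sample SD of the fitted asymptote and growth rate across
#' biological replicates; groups with a single converged fit report `NA` SD,
#' and empty groups (no converged fits) are dropped with a warning.
#'
#' @param fits Tibble from [fit_growth_curves()].
#' @param drop_outliers Apply [flag_replicate_outlier()] to `od_asym` within
#'   each group before summarizing; default `FALSE`.
#' @return Tibble with `strain`, `substrate`, `n`, `od_asym_mean`,
#'   `od_asym_sd`, `k_mean`, `k_sd`.
#' @export
summarize_kinetics <- function(fits, drop_outliers = FALSE) {
  ok <- fits[fits$converged & !fits$no_growth, , drop = FALSE]
  dropped <- dplyr::anti_join(
    dplyr::distinct(fits, .data$strain, .data$substrate),
    dplyr::distinct(ok, .data$strain, .data$substrate),
    by = c("strain", "substrate"))
  if (nrow(dropped) > 0) {
    warning("groups with no converged fits excluded: ",
            paste(dropped$strain, dropped$substrate, sep = "/",
                  collapse = ", "), call. = FALSE)
  }
  if (drop_outliers) {
    ok <- ok |>
      dplyr::group_by(.data$strain, .data$substrate) |>
      dplyr::filter(!flag_replicate_outlier(.data$od_asym)) |>
      dplyr::ungroup()
  }
  ok |>
    dplyr::group_by(.data$strain, .data$substrate) |>
    dplyr::summarise(
      n = dplyr::n(),
      od_asym_mean = mean(.data$od_asym),
      od_asym_sd = stats::sd(.data$od_asym),
      k_mean = mean(.data$k),
      k_sd = stats::sd(.data$k),
      .groups = "drop"
    )
}
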