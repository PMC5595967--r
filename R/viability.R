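# Viability normalisation, the 3-SD cytotoxicity call, and four-parameter
# logistic dose-response fitting (EC50 / ECf).

#' Percent viability relative to the DMSO mean
#'
#' `100 * raw / dmso_mean`; can exceed 100 for wells brighter than the
#' vehicle control.
#'
#' @param raw Raw luminescence reading(s).
#' @param dmso_mean Mean DMSO-well luminescence (> 0).
#' @return Percent viability, vectorised over `raw`.
#' @export
percent_viability <- function(raw, dmso_mean) {
  if (!is.numeric(dmso_mean) || length(dmso_mean) != 1 || dmso_mean <= 0) {
    stop("`dmso_mean` must be a single positive number", call. = FALSE)
  }
  100 * raw / dmso_mean
}

#' Summarise a viability plate into per-compound percent viability
#'
#' Normalises every well to the plate's DMSO mean and averages replicate
#' wells per compound.
#'
#' @param plate Tibble of readings with columns `compound`, `role`, `reading`
#'   (e.g. [simulate_viability_plate()]).
#' @return List with `viability` (tibble `compound`, `n_wells`,
#'   `viability_pct`) and `dmso_percents` (per-DMSO-well percent viabilities,
#'   for the cytotoxicity call).
#' @export
summarise_viability <- function(plate) {
  stopifnot(is.data.frame(plate),
            all(c("compound", "role", "reading") %in% names(plate)))
  dmso <- plate$reading[plate$role == "dmso_control"]
  if (length(dmso) < 2) {
    stop("need at least 2 DMSO control wells on the plate", call. = FALSE)
  }
  dmso_mean <- mean(dmso)
  viability <- plate |>
    dplyr::filter(.data$role == "compound") |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      viability_pct = mean(percent_viability(.data$reading, dmso_mean)),
      .groups = "drop"
    )
  list(
    viability = viability,
    dmso_percents = percent_viability(dmso, dmso_mean)
  )
}

#' Cytotoxicity call: viability reduced more than k SD below the DMSO control
#'
#' A compound is a cytotoxic hit when its percent viability falls strictly
#' below `mean(dmso) - k * sd(dmso)` (sample standard deviation).
#'
#' @param compound_viability Tibble with columns `compound` and
#'   `viability_pct`.
#' @param dmso_percents Per-well DMSO percent viabilities (length >= 2).
#' @param k Number of standard deviations (default 3).
#' @return Tibble of hits: `compound`, `viability_pct`, `threshold`, `margin`
#'   (how far below the threshold, in percent points), sorted by margin
#'   descending.
#' @export
cytotoxic_hits <- function(compound_viability, dmso_percents, k = 3) {
  stopifnot(is.data.frame(compound_viability),
            all(c("compound", "viability_pct") %in% names(compound_viability)),
            k > 0)
  if (length(dmso_percents) < 2) {
    stop("need at least 2 DMSO values to estimate the control SD", call. = FALSE)
  }
  threshold <- mean(dmso_percents) - k * stats::sd(dmso_percents)
  compound_viability |>
    dplyr::mutate(threshold = threshold,
                  margin = threshold - .data$viability_pct) |>
    dplyr::filter(.data$viability_pct < threshold) |>
    dplyr::arrange(dplyr::desc(.data$margin))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose / ec50)^hill)` with the
#' EC50 parameterised on the log10-dose scale. Initialisation is multi-start:
#' the EC50 start ranges over the geometric mean of the doses and each
#' interior dose, and the best-RSS converged start wins. An inhibitory fit is
#' declared non-converged (flat) when the fitted dynamic range `top - bottom`
#' is negligible against the response spread or the Hill slope collapses to
#' zero — no spurious EC50 is reported for non-descending data.
#'
#' @param data Data frame with columns `dose_uM` and `response` (replicates
#'   as extra rows); or pass `doses`/`responses` vectors.
#' @param doses,responses Alternative vector interface.
#' @param top_bounds,bottom_bounds Optional `c(lo, hi)` box constraints on
#'   the asymptotes.
#' @return An object of class `"cc_drfit"`: list with `ec50`, `hill`, `top`,
#'   `bottom`, `rss`, `converged`, `n` and the fitting `data`. Methods:
#'   [tidy()], [glance()], [autoplot()], [effective_concentration()].
#' @export
#' @examples
#' d <- simulate_dose_response(ec50 = 1, hill = 1, cv = 0, replicates = 1)
#' fit <- fit_dose_response(d)
#' fit$ec50
fit_dose_response <- function(data = NULL, doses = NULL, responses = NULL,
                              top_bounds = NULL, bottom_bounds = NULL) {
  if (!is.null(data)) {
    stopifnot(is.data.frame(data),
              all(c("dose_uM", "response") %in% names(data)))
    doses <- data$dose_uM
    responses <- data$response
  }
  stopifnot(length(doses) == length(responses), all(is.finite(responses)))
  if (any(doses <= 0)) stop("all doses must be positive", call. = FALSE)
  if (length(unique(doses)) < 4) {
    stop("insufficient design: need at least 4 distinct doses", call. = FALSE)
  }
  if (length(unique(responses)) == 1) {
    stop("flat curve: all responses equal, EC50 undefined", call. = FALSE)
  }

  ld <- log10(doses)
  lo <- c(lec50 = min(ld) - 2, hill = 1e-6, top = -Inf, bottom = -Inf)
  hi <- c(lec50 = max(ld) + 2, hill = Inf, top = Inf, bottom = Inf)
  if (!is.null(top_bounds)) { lo["top"] <- top_bounds[1]; hi["top"] <- top_bounds[2] }
  if (!is.null(bottom_bounds)) { lo["bottom"] <- bottom_bounds[1]; hi["bottom"] <- bottom_bounds[2] }

  mean_by_dose <- tapply(responses, ld, mean)
  top0 <- unname(mean_by_dose[which.min(as.numeric(names(mean_by_dose)))])
  bottom0 <- unname(mean_by_dose[which.max(as.numeric(names(mean_by_dose)))])
  if (top0 <= bottom0) { # non-descending data: still try, flat check catches it
    top0 <- max(responses); bottom0 <- min(responses)
  }
  interior <- sort(unique(ld))
  interior <- interior[-c(1, length(interior))]
  starts <- unique(c(mean(ld), interior))

  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ bottom + (top - bottom) / (1 + 10^((ld - lec50) * hill)),
        start = list(lec50 = s0, hill = 1, top = top0, bottom = bottom0),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    out <- list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
                bottom = NA_real_, rss = Inf, converged = FALSE,
                n = length(doses),
                data = tibble::tibble(dose_uM = doses, response = responses))
    class(out) <- "cc_drfit"
    return(out)
  }

  p <- stats::coef(best$fit)
  span <- diff(range(responses))
  # flat when the fitted curve barely moves across the observed dose range
  # (covers both collapsed asymptotes and an EC50 pushed off the grid)
  pred <- p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + 10^((sort(unique(ld)) - p[["lec50"]]) * p[["hill"]]))
  # inhibitory orientation requires top > bottom; a swapped fit means the
  # data rise with dose and no EC50 should be claimed
  flat <- diff(range(pred)) < 0.05 * span || p[["hill"]] < 1e-4 ||
    p[["top"]] <= p[["bottom"]]
  out <- list(
    ec50 = 10^p[["lec50"]],
    hill = p[["hill"]],
    top = p[["top"]],
    bottom = p[["bottom"]],
    rss = best$rss,
    converged = !flat,
    n = length(doses),
    data = tibble::tibble(dose_uM = doses, response = responses)
  )
  class(out) <- "cc_drfit"
  out
}

#' @export
print.cc_drfit <- function(x, ...) {
  cat("<cc_drfit> 4PL dose-response fit on", x$n, "points\n")
  cat(sprintf("  EC50 = %.4g uM, hill = %.3g, top = %.4g, bottom = %.4g, rss = %.4g (%s)\n",
              x$ec50, x$hill, x$top, x$bottom, x$rss,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Effective concentration at f% effect
#'
#' `ECf = EC50 * (f / (100 - f))^(1 / hill)`; `f = 50` returns the EC50 and
#' `f = 90` the EC90 used for short-exposure follow-up assays.
#'
#' @param fit A `"cc_drfit"` object, or any list with `ec50` and `hill`.
#' @param f Percent effect, strictly between 0 and 100 (default 90).
#' @return Dose in the EC50's units.
#' @export
#' @examples
#' effective_concentration(list(ec50 = 1, hill = 1), f = 90) # 9
effective_concentration <- function(fit, f = 90) {
  stopifnot(f > 0, f < 100)
  if (is.null(fit$ec50) || is.null(fit$hill) || is.na(fit$ec50)) {
    stop("`fit` must carry ec50 and hill estimates", call. = FALSE)
  }
  if (fit$hill == 0) stop("ECf undefined for hill = 0", call. = FALSE)
  fit$ec50 * (f / (100 - f))^(1 / fit$hill)
}

#' Fit dose-response curves for every compound in a long table
#'
#' @param doses_df Tibble with columns `compound`, `dose_uM`, `response`.
#' @param ... Passed to [fit_dose_response()].
#' @return Tibble `compound`, `ec50_uM`, `hill`, `top`, `bottom`, `rss`,
#'   `converged`, `ec90_uM` (NA when not converged).
#' @export
fit_potency_table <- function(doses_df, ...) {
  stopifnot(is.data.frame(doses_df),
            all(c("compound", "dose_uM", "response") %in% names(doses_df)))
  doses_df |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(function(d, g) {
      fit <- tryCatch(fit_dose_response(d, ...), error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble::tibble(ec50_uM = NA_real_, hill = NA_real_,
                              top = NA_real_, bottom = NA_real_,
                              rss = NA_real_, converged = FALSE,
                              ec90_uM = NA_real_))
      }
      tibble::tibble(
        ec50_uM = fit$ec50, hill = fit$hill, top = fit$top,
        bottom = fit$bottom, rss = fit$rss, converged = fit$converged,
        ec90_uM = if (isTRUE(fit$converged))
          effective_concentration(fit, 90) else NA_real_
      )
    }) |>
    dplyr::ungroup()
}
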