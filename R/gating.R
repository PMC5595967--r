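# Histogram gating of DNA-content distributions into the four cell-cycle
# phases, plus Z'-factor plate QC.

#' Bin per-cell intensities into a DNA-content histogram
#'
#' Bins are half-open `[lo, hi)` with the last bin closed, so counts are
#' bit-reproducible. The default range is `[0, 1.05 * q99.5]` of the
#' intensities, which keeps rare bright outliers from stretching the axis.
#'
#' @param events Numeric intensity vector, or a data frame with an
#'   `intensity` column (e.g. from [simulate_well()]).
#' @param bins Number of bins (>= 10; default 128).
#' @param range Optional `c(lo, hi)` intensity range; events outside it are
#'   dropped from the counts.
#' @return A tibble of class `"cc_histogram"` with columns `bin_lo`, `bin_hi`,
#'   `mid`, `count`, and attributes `edges` and `well_id` (if the input
#'   carried one).
#' @export
build_histogram <- function(events, bins = 128, range = NULL) {
  well_id <- NA_character_
  if (is.data.frame(events)) {
    if (!is.null(events[["well_id"]]) && nrow(events) > 0) {
      well_id <- events$well_id[1]
    }
    events <- events[["intensity"]]
  }
  if (length(events) == 0) {
    stop("empty well: no events to histogram (well ",
         if (is.na(well_id)) "<unknown>" else well_id, ")", call. = FALSE)
  }
  if (bins < 10) stop("`bins` must be at least 10", call. = FALSE)
  if (is.null(range)) {
    range <- c(0, 1.05 * stats::quantile(events, 0.995, names = FALSE))
  }
  stopifnot(length(range) == 2, range[2] > range[1])
  edges <- seq(range[1], range[2], length.out = bins + 1)
  idx <- findInterval(events, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= bins]
  counts <- tabulate(idx, nbins = bins)
  out <- tibble::tibble(
    bin_lo = edges[-(bins + 1)],
    bin_hi = edges[-1],
    mid = (edges[-(bins + 1)] + edges[-1]) / 2,
    count = counts
  )
  class(out) <- c("cc_histogram", class(out))
  attr(out, "edges") <- edges
  attr(out, "well_id") <- well_id
  out
}

# 3-bin moving average; endpoints keep their raw counts.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  s[1] <- x[1]
  s[n] <- x[n]
  s
}

# Indices of local maxima of a smoothed count vector. A position qualifies if
# it is >= both neighbours and > at least one (plateaus contribute their
# leftmost index).
local_maxima <- function(s) {
  n <- length(s)
  if (n < 3) return(integer(0))
  idx <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (s[i] >= s[i - 1] && s[i] >= s[i + 1] && (s[i] > s[i - 1] || s[i] > s[i + 1])) {
      idx <- c(idx, i)
      # skip over a flat plateau so it is reported once, at its left edge
      j <- i + 1
      while (j <= n - 1 && s[j] == s[i]) j <- j + 1
      i <- j
    } else {
      i <- i + 1
    }
  }
  idx
}

# sigma from full width at half maximum around peak index `p` on the smoothed
# profile; NA when a half-max crossing is not found on either side. The 3-bin
# boxcar smoothing adds (w^2-1)/12 = 2/3 bin-widths^2 of variance and binning
# itself adds bw^2/12; both are subtracted so the estimate is unbiased for a
# Gaussian peak.
fwhm_sigma <- function(s, mids, p) {
  bw <- mids[2] - mids[1]
  raw <- fwhm_sigma_raw(s, mids, p)
  if (is.na(raw)) return(NA_real_)
  sqrt(max(raw^2 - (2 / 3) * bw^2 - bw^2 / 12, (bw / 2.355)^2))
}

fwhm_sigma_raw <- function(s, mids, p) {
  half <- s[p] / 2
  li <- p
  while (li > 1 && s[li] > half) li <- li - 1
  ri <- p
  n <- length(s)
  while (ri < n && s[ri] > half) ri <- ri + 1
  if (s[li] > half || s[ri] > half) return(NA_real_)
  # linear interpolation of the crossing positions
  xl <- mids[li] + (half - s[li]) / (s[li + 1] - s[li]) * (mids[li + 1] - mids[li])
  xr <- mids[ri - 1] + (half - s[ri - 1]) / (s[ri] - s[ri - 1]) * (mids[ri] - mids[ri - 1])
  (xr - xl) / 2.355
}

#' Locate the 2N (G1) and 4N (G2/M) peaks of a DNA-content histogram
#'
#' Counts are smoothed with a 3-bin moving average before peak detection.
#' The tallest local maximum anchors the search: if a companion peak sits at
#' twice its position (within the 1.8-2.2x DNA-mass window) the tallest peak
#' is G1; if instead a companion sits at half its position (a G2/M-arrested
#' well where the 4N peak dominates) the lower peak is G1. With no companion,
#' the G2 peak is synthesized at exactly `2 * g1_peak`. Peak widths come from
#' the full width at half maximum (`sigma = FWHM / 2.355`), falling back to
#' `cv_assumed * peak` when a half-max crossing is not resolvable.
#'
#' Among equal-height candidate peaks the leftmost wins.
#'
#' @param hist A [build_histogram()] result.
#' @param cv_assumed Fallback coefficient of variation for peak widths.
#' @return One-row tibble `g1_peak`, `g2_peak`, `g1_sigma`, `g2_sigma`,
#'   `g2_synthesized` (logical).
#' @export
detect_g1_g2_peaks <- function(hist, cv_assumed = 0.05) {
  stopifnot(inherits(hist, "cc_histogram"))
  s <- smooth3(hist$count)
  mids <- hist$mid
  cand <- local_maxima(s)
  if (length(cand) == 0) {
    # monotone or flat profile: fall back to the global mode if it is unique
    if (max(hist$count) == 0 || all(s == s[1])) {
      stop("gating failure: no discernible peak in well ",
           attr(hist, "well_id"), call. = FALSE)
    }
    cand <- which.max(s)
  }
  # tallest candidate; leftmost on ties
  tallest <- cand[which.max(s[cand])]
  in_window <- function(center, lo, hi) {
    w <- cand[mids[cand] >= lo * center & mids[cand] <= hi * center & cand != tallest]
    if (length(w) == 0) return(NA_integer_)
    w[which.max(s[w])]
  }
  up <- in_window(mids[tallest], 1.8, 2.2)
  down <- in_window(mids[tallest], 1 / 2.2, 1 / 1.8)
  if (!is.na(up)) {
    g1_i <- tallest; g2_i <- up
  } else if (!is.na(down)) {
    g1_i <- down; g2_i <- tallest
  } else {
    g1_i <- tallest; g2_i <- NA_integer_
  }
  # smoothing can drag a sparse peak's apex onto a neighbour bin; snap each
  # peak to the raw-count argmax within one bin of the smoothed maximum
  refine <- function(i) {
    win <- max(1, i - 1):min(length(s), i + 1)
    win[which.max(hist$count[win])]
  }
  g1_i <- refine(g1_i)
  if (!is.na(g2_i)) g2_i <- refine(g2_i)
  g1_peak <- mids[g1_i]
  g1_sigma <- fwhm_sigma(s, mids, g1_i)
  if (is.na(g1_sigma)) g1_sigma <- cv_assumed * g1_peak
  if (is.na(g2_i)) {
    g2_peak <- 2 * g1_peak
    g2_sigma <- 2 * g1_sigma
    synth <- TRUE
  } else {
    g2_peak <- mids[g2_i]
    g2_sigma <- fwhm_sigma(s, mids, g2_i)
    if (is.na(g2_sigma)) g2_sigma <- cv_assumed * g2_peak
    synth <- FALSE
  }
  tibble::tibble(g1_peak = g1_peak, g2_peak = g2_peak,
                 g1_sigma = g1_sigma, g2_sigma = g2_sigma,
                 g2_synthesized = synth)
}

#' Assign events to cell-cycle phases by intensity gates
#'
#' Gate boundaries are `b0 = g1_peak - k * g1_sigma`,
#' `b1 = g1_peak + k * g1_sigma` and `b2 = g2_peak - k * g2_sigma`:
#' sub-G1 is `intensity < b0`, G1 is `[b0, b1)`, S is `[b1, b2)` and G2/M is
#' `>= b2` (events above 4N are counted as G2/M). Every event is assigned, so
#' the four fractions sum to exactly 1.
#'
#' @param events Intensity vector or data frame with an `intensity` column.
#' @param peaks A [detect_g1_g2_peaks()] row.
#' @param k Gate half-width in peak sigmas (default 2).
#' @return One-row tibble `g1`, `s`, `g2m`, `subg1` (fractions) with an
#'   `n_events` column.
#' @export
gate_phases <- function(events, peaks, k = 2) {
  if (is.data.frame(events)) events <- events[["intensity"]]
  stopifnot(k > 0, length(events) > 0)
  b0 <- peaks$g1_peak - k * peaks$g1_sigma
  b1 <- peaks$g1_peak + k * peaks$g1_sigma
  b2 <- peaks$g2_peak - k * peaks$g2_sigma
  if (b1 >= b2) {
    stop("gating failure: G1 and G2 gates overlap (b1 = ", round(b1, 3),
         " >= b2 = ", round(b2, 3), ")", call. = FALSE)
  }
  n <- length(events)
  tibble::tibble(
    g1 = sum(events >= b0 & events < b1) / n,
    s = sum(events >= b1 & events < b2) / n,
    g2m = sum(events >= b2) / n,
    subg1 = sum(events < b0) / n,
    n_events = n
  )
}

#' Gate one well end to end
#'
#' Convenience wrapper: histogram, peak detection, phase gating.
#'
#' @inheritParams build_histogram
#' @inheritParams gate_phases
#' @inheritParams detect_g1_g2_peaks
#' @return As [gate_phases()].
#' @export
gate_well <- function(events, bins = 128, k = 2, cv_assumed = 0.05) {
  h <- build_histogram(events, bins = bins)
  p <- detect_g1_g2_peaks(h, cv_assumed = cv_assumed)
  gate_phases(events, p, k = k)
}

#' Gate every well of a plate into a phase-percentage table
#'
#' @param events Long tibble of per-cell events with columns `well_id`,
#'   `intensity` and optionally `compound`, `role` (e.g.
#'   `simulate_plate()$events`).
#' @inheritParams gate_well
#' @return Tibble `well_id`, `compound`, `role`, `g1`, `s`, `g2m`, `subg1`
#'   (percentages, 0-100) and `n_events` — one cell-cycle fingerprint per well.
#' @export
gate_plate <- function(events, bins = 128, k = 2, cv_assumed = 0.05) {
  stopifnot(is.data.frame(events), "well_id" %in% names(events),
            "intensity" %in% names(events))
  if (!"compound" %in% names(events)) events$compound <- NA_character_
  if (!"role" %in% names(events)) events$role <- "compound"
  events |>
    dplyr::group_by(.data$well_id, .data$compound, .data$role) |>
    dplyr::group_modify(function(d, g) {
      f <- gate_well(d$intensity, bins = bins, k = k, cv_assumed = cv_assumed)
      dplyr::mutate(f, dplyr::across(c("g1", "s", "g2m", "subg1"), ~ 100 * .x))
    }) |>
    dplyr::ungroup()
}

#' Z'-factor assay quality statistic
#'
#' `Z' = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n|`, with sample (n - 1)
#' standard deviations. Z' <= 1 always; values above 0.5 indicate a robust
#' separation between positive and negative controls.
#'
#' @param pos,neg Numeric readings for positive and negative control wells
#'   (each length >= 2).
#' @return One-row tibble `mu_p`, `sigma_p`, `mu_n`, `sigma_n`, `zprime`.
#' @export
#' @examples
#' zprime_factor(rnorm(16, 100, 5), rnorm(16, 0, 5))
zprime_factor <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    stop("need at least 2 readings per control group", call. = FALSE)
  }
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (mu_p == mu_n) {
    stop("undefined separation: positive and negative control means are equal",
         call. = FALSE)
  }
  sigma_p <- stats::sd(pos); sigma_n <- stats::sd(neg)
  tibble::tibble(
    mu_p = mu_p, sigma_p = sigma_p, mu_n = mu_n, sigma_n = sigma_n,
    zprime = 1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n)
  )
}
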