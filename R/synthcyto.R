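# Synthetic DNA-content cytometry data with known ground truth.
#
# The generator emulates a 384-well imaging-cytometry screen: a DNA-selective
# stain emits fluorescence proportional to DNA mass, so 2N (G1) cells form a
# peak at `g1_mean`, 4N (G2/M) cells at 2 * g1_mean, S-phase cells fill the
# inter-peak region, and fragmented apoptotic (sub-G1) cells fall below the
# G1 peak.

#' Validate a four-phase composition vector
#'
#' @param fractions Numeric vector of length 4, in the order
#'   (G1, S, G2/M, sub-G1), or a one-row data frame with columns
#'   `g1`, `s`, `g2m`, `subg1`. Values are fractions in \[0, 1\] and must sum
#'   to 1 within 1e-9.
#' @return A named numeric vector `c(g1, s, g2m, subg1)`.
#' @export
phase_fractions <- function(fractions) {
  if (is.data.frame(fractions)) {
    stopifnot(nrow(fractions) == 1)
    fractions <- unlist(fractions[, c("g1", "s", "g2m", "subg1")])
  }
  f <- as.numeric(fractions)
  if (length(f) != 4 || anyNA(f)) {
    stop("`fractions` must be 4 finite values (g1, s, g2m, subg1)", call. = FALSE)
  }
  if (any(f < 0) || any(f > 1)) {
    stop("phase fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stop("phase fractions must sum to 1 (got ", format(sum(f), digits = 12), ")",
         call. = FALSE)
  }
  stats::setNames(f, c("g1", "s", "g2m", "subg1"))
}

# Deterministic 32-bit per-well seed from (plate_seed, well_id); a small
# polynomial string hash so well streams are independent of simulation order
# and identical across platforms.
well_seed <- function(plate_seed, well_id) {
  h <- as.double(plate_seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(well_id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Normal deviates truncated to be strictly positive (resampling; negligible
# rejection mass for cv < 0.3).
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Simulate per-cell DNA-stain intensities for one well
#'
#' Event counts per phase are multinomial in the true fractions. G1 events are
#' Normal(`g1_mean`, `cv * g1_mean`), G2/M events Normal(`2 g1_mean`,
#' `cv * 2 g1_mean`) (both truncated positive), S events Uniform between the
#' two peak means with multiplicative Normal(0, cv) perturbation, and sub-G1
#' events Uniform on `(subg1_low * g1_mean, g1_mean * (1 - 2 cv))` — a debris
#' band bounded away from the G1 peak.
#'
#' @param fractions True phase composition; see [phase_fractions()].
#' @param g1_mean Location of the 2N peak (arbitrary fluorescence units).
#' @param cv Coefficient of variation of each peak (0 < cv < 0.3).
#' @param n_events Number of cells detected in the well.
#' @param subg1_low Lower edge of the sub-G1 band, as a fraction of `g1_mean`.
#' @param seed Optional integer seed; the same seed reproduces the well exactly.
#' @param well_id Plate coordinate label stored in the output.
#' @return A tibble with columns `well_id`, `phase` (true generator label,
#'   one of `"g1"`, `"s"`, `"g2m"`, `"subg1"`) and `intensity`.
#' @export
#' @examples
#' ev <- simulate_well(c(0.54, 0.10, 0.31, 0.05), n_events = 1000, seed = 1)
#' table(ev$phase)
simulate_well <- function(fractions, g1_mean = 100, cv = 0.05, n_events = 5000,
                          subg1_low = 0.25, seed = NULL, well_id = "A01") {
  f <- phase_fractions(fractions)
  stopifnot(g1_mean > 0, cv > 0, cv < 0.3, n_events >= 1,
            subg1_low > 0, subg1_low < 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  counts <- as.vector(stats::rmultinom(1, n_events, f))
  g2_mean <- 2 * g1_mean
  ints <- vector("list", 4)
  ints[[1]] <- rnorm_pos(counts[1], g1_mean, cv * g1_mean)
  if (counts[2] > 0) {
    u <- stats::runif(counts[2], g1_mean, g2_mean)
    ints[[2]] <- pmax(u + stats::rnorm(counts[2], 0, cv * u), .Machine$double.eps)
  } else {
    ints[[2]] <- numeric(0)
  }
  ints[[3]] <- rnorm_pos(counts[3], g2_mean, cv * g2_mean)
  ints[[4]] <- stats::runif(counts[4], subg1_low * g1_mean, g1_mean * (1 - 2 * cv))
  tibble::tibble(
    well_id = well_id,
    phase = rep(c("g1", "s", "g2m", "subg1"), counts),
    intensity = unlist(ints)
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Build a 384-well plate map
#'
#' Lays out DMSO control wells, optional positive-control wells and compound
#' wells row-major on a 16 x 24 grid. Remaining wells are `"empty"`.
#'
#' @param compounds Character vector of compound names (one well each).
#' @param n_dmso Number of DMSO (vehicle) control wells.
#' @param n_pos Number of positive-control wells.
#' @param concentration_uM Screening concentration recorded for compound wells.
#' @param n_rows,n_cols Plate geometry (default 384-well, 16 x 24).
#' @return A tibble with columns `well_id`, `row`, `col`, `role`
#'   (`"dmso_control"`, `"positive_control"`, `"compound"` or `"empty"`),
#'   `compound` and `concentration_uM`.
#' @export
plate_map_384 <- function(compounds, n_dmso = 16, n_pos = 0,
                          concentration_uM = 10, n_rows = 16, n_cols = 24) {
  n_wells <- n_rows * n_cols
  n_cmpd <- length(compounds)
  if (n_dmso < 1) stop("at least one DMSO control well is required", call. = FALSE)
  if (n_dmso + n_pos + n_cmpd > n_wells) {
    stop("plate map needs ", n_dmso + n_pos + n_cmpd, " wells but the plate has ",
         n_wells, call. = FALSE)
  }
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  well_id <- sprintf("%s%02d", LETTERS[rows], cols)
  role <- rep("empty", n_wells)
  compound <- rep(NA_character_, n_wells)
  conc <- rep(NA_real_, n_wells)
  idx <- seq_len(n_dmso)
  role[idx] <- "dmso_control"
  compound[idx] <- "DMSO"
  if (n_pos > 0) {
    idx <- n_dmso + seq_len(n_pos)
    role[idx] <- "positive_control"
    compound[idx] <- "POS"
  }
  if (n_cmpd > 0) {
    idx <- n_dmso + n_pos + seq_len(n_cmpd)
    role[idx] <- "compound"
    compound[idx] <- compounds
    conc[idx] <- concentration_uM
  }
  tibble::tibble(well_id = well_id, row = rows, col = cols, role = role,
                 compound = compound, concentration_uM = conc)
}

#' Default DMSO (unperturbed) phase composition
#'
#' Vehicle-treated cycling cells: just over half in G1, ~10% in S, ~30% in
#' G2/M and under 5% sub-G1.
#' @return Named fraction vector.
#' @export
dmso_truth <- function() {
  c(g1 = 0.54, s = 0.10, g2m = 0.31, subg1 = 0.05)
}

#' Simulate a full screening plate of DNA-content wells
#'
#' One [simulate_well()] call per non-empty well of the plate map; compound
#' wells draw their true composition from `truth`, DMSO wells from
#' [dmso_truth()] and positive-control wells from `pos_truth` (default: a
#' strong G2/M arrest). Per-well seeds are derived deterministically from
#' `(seed, well_id)` so the plate is reproducible independent of well order.
#'
#' @param map Plate map from [plate_map_384()] (or same columns).
#' @param truth Tibble with columns `compound`, `g1`, `s`, `g2m`, `subg1`
#'   (fractions) giving each compound's true composition.
#' @param g1_mean,cv,n_events,subg1_low Passed to [simulate_well()].
#' @param seed Plate-level seed.
#' @param pos_truth Composition used for positive-control wells.
#' @return A list of class `"cc_plate_sim"` with elements `events` (tibble
#'   `well_id`, `compound`, `role`, `phase`, `intensity`), `truth` (the
#'   compound rows used, as fractions) and `plate_map`.
#' @export
simulate_plate <- function(map, truth, g1_mean = 100, cv = 0.05,
                           n_events = 5000, subg1_low = 0.25, seed = 1,
                           pos_truth = c(0.08, 0.05, 0.82, 0.05)) {
  stopifnot(is.data.frame(map), is.data.frame(truth))
  active <- map[map$role != "empty", ]
  cmpds <- active$compound[active$role == "compound"]
  missing <- setdiff(cmpds, truth$compound)
  if (length(missing) > 0) {
    stop("no truth entry for compound(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dmso <- dmso_truth()
  pos <- phase_fractions(pos_truth)
  events <- purrr::pmap(
    list(active$well_id, active$role, active$compound),
    function(wid, role, cmpd) {
      f <- switch(role,
        dmso_control = dmso,
        positive_control = pos,
        compound = {
          r <- truth[match(cmpd, truth$compound), ]
          phase_fractions(c(r$g1, r$s, r$g2m, r$subg1))
        }
      )
      ev <- simulate_well(f, g1_mean = g1_mean, cv = cv, n_events = n_events,
                          subg1_low = subg1_low,
                          seed = well_seed(seed, wid), well_id = wid)
      ev$compound <- if (is.na(cmpd)) role else cmpd
      ev$role <- role
      ev[, c("well_id", "compound", "role", "phase", "intensity")]
    }
  )
  out <- list(
    events = dplyr::bind_rows(events),
    truth = truth[truth$compound %in% cmpds, ],
    plate_map = map
  )
  class(out) <- "cc_plate_sim"
  out
}

#' @export
print.cc_plate_sim <- function(x, ...) {
  cat("<cc_plate_sim> ", dplyr::n_distinct(x$events$well_id), " wells, ",
      nrow(x$events), " events, ", nrow(x$truth), " compounds with truth\n",
      sep = "")
  invisible(x)
}

#' Simulate an end-point viability (luminescence) plate
#'
#' Each well reads `true_viability * signal_mean * (1 + Normal(0, cv))`,
#' floored at zero — the CellTiterGlo-style readout where luminescence is
#' proportional to viable cell number. DMSO wells have viability 1,
#' positive-control wells 0.
#'
#' @param map Plate map (see [plate_map_384()]).
#' @param true_viability Tibble with columns `compound` and `viability`
#'   (fraction in \[0, 1\]).
#' @param signal_mean Mean luminescence of a fully viable well (a.u.).
#' @param cv Multiplicative noise coefficient of variation (> 0).
#' @param seed Integer seed.
#' @return Tibble `well_id`, `compound`, `role`, `reading`.
#' @export
simulate_viability_plate <- function(map, true_viability, signal_mean = 10000,
                                     cv = 0.05, seed = 1) {
  if (cv <= 0) stop("`cv` must be positive", call. = FALSE)
  stopifnot(signal_mean > 0)
  if (any(true_viability$viability < 0 | true_viability$viability > 1)) {
    stop("`viability` must lie in [0, 1]", call. = FALSE)
  }
  active <- map[map$role != "empty", ]
  cmpds <- active$compound[active$role == "compound"]
  missing <- setdiff(cmpds, true_viability$compound)
  if (length(missing) > 0) {
    stop("no viability entry for compound(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- dplyr::case_when(
    active$role == "dmso_control" ~ 1,
    active$role == "positive_control" ~ 0,
    TRUE ~ true_viability$viability[match(active$compound, true_viability$compound)]
  )
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  reading <- pmax(v * signal_mean * (1 + stats::rnorm(nrow(active), 0, cv)), 0)
  tibble::tibble(
    well_id = active$well_id,
    compound = ifelse(is.na(active$compound), active$role, active$compound),
    role = active$role,
    reading = reading
  )
}

#' The default 8-point final-concentration dose grid
#'
#' Final assay concentrations of the screen's 8-point serial dilution, 50 uM
#' at the top: 50, 12.5, 3.125, 0.781, 0.26, 0.065, 0.016, 0.004 uM.
#' @return Numeric vector of doses in uM, descending.
#' @export
dose_grid_8pt <- function() {
  c(50, 12.5, 3.125, 0.781, 0.26, 0.065, 0.016, 0.004)
}

#' Four-parameter logistic (4PL) dose-response curve
#'
#' `bottom + (top - bottom) / (1 + (dose / ec50)^hill)`. With `hill > 0` and
#' `top > bottom` the curve decreases from `top` (dose -> 0) to `bottom`
#' (dose -> Inf), the usual inhibitory viability curve; the response at
#' `dose = ec50` is the midpoint.
#'
#' @param dose Dose(s), same units as `ec50` (conventionally uM).
#' @param ec50 Half-maximal effective concentration (> 0).
#' @param hill Hill slope.
#' @param top,bottom Upper and lower asymptotes (conventionally % viability).
#' @return Numeric response(s).
#' @export
#' @examples
#' four_param_logistic(1, ec50 = 1, hill = 1, top = 100, bottom = 0) # 50
four_param_logistic <- function(dose, ec50, hill, top = 100, bottom = 0) {
  stopifnot(ec50 > 0)
  bottom + (top - bottom) / (1 + (dose / ec50)^hill)
}

#' Simulate replicate dose-response measurements from a known 4PL curve
#'
#' @param ec50,hill,top,bottom True curve parameters ([four_param_logistic()]).
#' @param doses Dose grid in uM (all > 0); default [dose_grid_8pt()].
#' @param cv Multiplicative noise CV (>= 0; 0 gives noiseless responses).
#' @param replicates Wells per dose.
#' @param seed Optional integer seed.
#' @return Tibble `dose_uM`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(ec50, hill = 1, top = 100, bottom = 0,
                                   doses = dose_grid_8pt(), cv = 0.05,
                                   replicates = 3, seed = NULL) {
  if (any(doses <= 0)) stop("all doses must be positive", call. = FALSE)
  stopifnot(ec50 > 0, cv >= 0, replicates >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  grid <- tidyr::expand_grid(dose_uM = doses, replicate = seq_len(replicates))
  mu <- four_param_logistic(grid$dose_uM, ec50, hill, top, bottom)
  noise <- if (cv > 0) stats::rnorm(nrow(grid), 0, cv) else 0
  grid$response <- mu * (1 + noise)
  grid
}
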