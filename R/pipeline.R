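# End-to-end screen orchestration: gate -> CCI -> hit selection -> viability
# -> potency -> clustering, with persisted intermediates and a run manifest.

#' Read a compound phase-percentage table
#'
#' Reads a CSV (or XLSX, via the readxl package) of per-compound cell-cycle
#' fingerprints. `column_map` maps the standard names to the file's column
#' headers, e.g. `c(compound = "Drug", g1 = "G1 (%)", s = "S (%)",
#' g2m = "G2/M (%)", subg1 = "subG1 (%)")`, so supplementary-style
#' spreadsheets can be ingested without editing. Rows whose four percentages
#' do not sum to 100 within 0.5 are loaded but flagged.
#'
#' @param path File path (`.csv`, `.tsv` or `.xlsx`).
#' @param column_map Optional named character vector mapping
#'   `compound`, `g1`, `s`, `g2m`, `subg1` to the file's column names.
#' @param sheet Sheet name/number for XLSX input.
#' @return Tibble `compound`, `g1`, `s`, `g2m`, `subg1`, `flagged`.
#' @export
read_profile_table <- function(path, column_map = NULL, sheet = 1) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    xlsx = , xls = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("the 'readxl' package is required for XLSX input", call. = FALSE)
      }
      readxl::read_excel(path, sheet = sheet)
    },
    tsv = readr::read_tsv(path, show_col_types = FALSE),
    readr::read_csv(path, show_col_types = FALSE)
  )
  std <- c("compound", PHASES)
  if (is.null(column_map)) {
    column_map <- stats::setNames(std, std)
  }
  miss_map <- setdiff(std, names(column_map))
  if (length(miss_map) > 0) {
    stop("`column_map` must map: ", paste(miss_map, collapse = ", "),
         call. = FALSE)
  }
  miss_col <- setdiff(unname(column_map[std]), names(raw))
  if (length(miss_col) > 0) {
    stop("column(s) not found in ", basename(path), ": ",
         paste(miss_col, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    compound = as.character(raw[[column_map[["compound"]]]]),
    g1 = as.numeric(raw[[column_map[["g1"]]]]),
    s = as.numeric(raw[[column_map[["s"]]]]),
    g2m = as.numeric(raw[[column_map[["g2m"]]]]),
    subg1 = as.numeric(raw[[column_map[["subg1"]]]])
  )
  out$flagged <- abs(out$g1 + out$s + out$g2m + out$subg1 - 100) > 0.5
  out
}

#' Write a phase-percentage table (2 decimal places)
#'
#' @param phases Fingerprint tibble with columns `g1`, `s`, `g2m`, `subg1`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(phases, path) {
  check_fingerprints(phases)
  out <- dplyr::mutate(phases,
                       dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Screen run configuration
#'
#' Bundles the cascade constants: the CCI hit cutoff, the viability
#' standard-deviation multiplier, the potency ceiling, and the gating
#' parameters. All cutoffs must be positive.
#'
#' @param seed Root seed for any randomness in the run.
#' @param cci_cutoff CCI hit threshold (strict `>`; default 10).
#' @param sd_k Cytotoxicity call, SDs below the DMSO mean (default 3).
#' @param ec50_max Potency ceiling in uM (strict `<`; default 20).
#' @param bins,gate_k Histogram bins and gate half-width for [gate_plate()].
#' @param out_dir Optional directory; when set, every intermediate is written
#'   as CSV along with a JSON run manifest.
#' @return A list of class `"cc_config"`.
#' @export
screen_config <- function(seed = 1, cci_cutoff = 10, sd_k = 3, ec50_max = 20,
                          bins = 128, gate_k = 2, out_dir = NULL) {
  stopifnot(cci_cutoff >= 0, sd_k > 0, ec50_max > 0, bins >= 10, gate_k > 0)
  structure(
    list(seed = as.integer(seed), cci_cutoff = cci_cutoff, sd_k = sd_k,
         ec50_max = ec50_max, bins = bins, gate_k = gate_k, out_dir = out_dir),
    class = "cc_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full profiling cascade
#'
#' Executes, in order: per-well gating, plate QC (Z' on the positive-control
#' G2/M fraction when positive controls are present), per-compound CCI against
#' the plate's DMSO reference, CCI hit selection, viability normalisation and
#' the k-SD cytotoxicity call (restricted to CCI hits), 4PL potency fits with
#' the EC50 ceiling (restricted to viability hits), and complete-linkage
#' clustering of the final hits' fingerprints. The hit sets are nested by
#' construction: potency hits are a subset of viability hits, which are a
#' subset of CCI hits.
#'
#' @param config A [screen_config()].
#' @param cytometry List with `events` (per-cell tibble: `well_id`,
#'   `compound`, `role`, `intensity`) and optionally `plate_map`; a
#'   [simulate_plate()] result works directly.
#' @param viability_plate Optional readings tibble (`compound`, `role`,
#'   `reading`), e.g. [simulate_viability_plate()].
#' @param potency Optional long dose-response tibble (`compound`, `dose_uM`,
#'   `response`), raw readings normalised externally or percent viability.
#' @return A list of class `"cc_screen"` with elements `phases`, `qc`,
#'   `fingerprints` (per-compound means), `cci`, `cci_hits`, `viability`,
#'   `viability_hits`, `potency`, `potency_hits`, `tree`, `zmatrix`,
#'   `manifest`.
#' @export
run_screen <- function(config, cytometry, viability_plate = NULL,
                       potency = NULL) {
  stopifnot(inherits(config, "cc_config"))
  events <- if (is.data.frame(cytometry)) cytometry else cytometry$events

  phases <- run_stage("gating",
    gate_plate(events, bins = config$bins, k = config$gate_k))

  qc <- NULL
  if (any(phases$role == "positive_control")) {
    qc <- run_stage("qc", zprime_factor(
      pos = phases$g2m[phases$role == "positive_control"],
      neg = phases$g2m[phases$role == "dmso_control"]
    ))
  }

  cci_tab <- run_stage("cci", {
    ref <- dmso_reference(phases[phases$role == "dmso_control", ])
    fingerprints <- phases |>
      dplyr::filter(.data$role == "compound") |>
      dplyr::group_by(.data$compound) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(PHASES), mean),
                       .groups = "drop")
    compute_cci(fingerprints, ref)
  })
  fingerprints <- cci_tab[, c("compound", PHASES)]
  cci_hits <- run_stage("hit selection", select_hits(cci_tab, config$cci_cutoff))

  viability <- NULL; viability_hits <- NULL
  if (!is.null(viability_plate)) {
    via <- run_stage("viability", summarise_viability(viability_plate))
    viability <- via$viability
    viability_hits <- run_stage("cytotoxicity call", {
      evaluated <- dplyr::semi_join(viability, cci_hits, by = "compound")
      cytotoxic_hits(evaluated, via$dmso_percents, k = config$sd_k)
    })
  }

  potency_fits <- NULL; potency_hits <- NULL
  if (!is.null(potency) && !is.null(viability_hits) && nrow(viability_hits) > 0) {
    potency_fits <- run_stage("potency", {
      evaluated <- dplyr::semi_join(potency, viability_hits, by = "compound")
      fit_potency_table(evaluated)
    })
    potency_hits <- potency_fits |>
      dplyr::filter(.data$converged, .data$ec50_uM < config$ec50_max) |>
      dplyr::arrange(.data$ec50_uM)
  }

  tree <- NULL; zmatrix <- NULL
  final <- if (!is.null(potency_hits)) potency_hits
           else if (!is.null(viability_hits)) viability_hits
           else cci_hits
  if (nrow(final) >= 2) {
    hit_fps <- dplyr::semi_join(fingerprints, final, by = "compound")
    tree <- run_stage("clustering", cluster_fingerprints(hit_fps))
    zmatrix <- run_stage("clustering", zscore_transform(hit_fps))
  }

  manifest <- list(
    config = unclass(config)[c("seed", "cci_cutoff", "sd_k", "ec50_max",
                               "bins", "gate_k")],
    counts = list(
      wells_gated = nrow(phases),
      compounds = nrow(cci_tab),
      cci_hits = nrow(cci_hits),
      viability_hits = if (is.null(viability_hits)) NA else nrow(viability_hits),
      potency_hits = if (is.null(potency_hits)) NA else nrow(potency_hits)
    )
  )

  out <- list(phases = phases, qc = qc, fingerprints = fingerprints,
              cci = cci_tab, cci_hits = cci_hits, viability = viability,
              viability_hits = viability_hits, potency = potency_fits,
              potency_hits = potency_hits, tree = tree, zmatrix = zmatrix,
              manifest = manifest)
  class(out) <- "cc_screen"

  if (!is.null(config$out_dir)) write_screen(out, config$out_dir)
  out
}

#' @export
print.cc_screen <- function(x, ...) {
  m <- x$manifest$counts
  cat("<cc_screen>\n")
  cat("  wells gated:   ", m$wells_gated, "\n")
  cat("  compounds:     ", m$compounds, "\n")
  cat("  CCI hits:      ", m$cci_hits, "\n")
  if (!is.na(m$viability_hits)) cat("  viability hits:", m$viability_hits, "\n")
  if (!is.na(m$potency_hits)) cat("  potency hits:  ", m$potency_hits, "\n")
  if (!is.null(x$qc)) cat("  plate Z':      ", round(x$qc$zprime, 3), "\n")
  invisible(x)
}

#' Persist every intermediate of a screen run
#'
#' Writes the phase table, QC report, CCI table, hit lists, viability and
#' potency tables, the clustering outputs (ordered Z-matrix and merge list)
#' and a JSON manifest into `dir`. Re-running an identical configuration
#' reproduces byte-identical files.
#'
#' @param screen A `"cc_screen"` result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "cc_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) if (!is.null(x))

    readr::write_csv(dplyr::mutate(x, dplyr::across(dplyr::where(is.numeric),
                                                    ~ round(.x, 6))),
                     file.path(dir, f))
  w(screen$phases, "phases.csv")
  w(screen$qc, "qc.csv")
  w(screen$cci, "cci.csv")
  w(screen$cci_hits, "cci_hits.csv")
  w(screen$viability, "viability.csv")
  w(screen$viability_hits, "viability_hits.csv")
  w(screen$potency, "potency.csv")
  w(screen$potency_hits, "potency_hits.csv")
  if (!is.null(screen$tree)) {
    w(screen$tree$merges, "merges.csv")
    w(ordered_matrix(screen$tree, screen$zmatrix), "ordered_zmatrix.csv")
  }
  jsonlite::write_json(screen$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a complete synthetic screen with known ground truth
#'
#' Builds every input of the cascade from one seed: a 384-well DNA-content
#' plate where `n_shifted` compounds have true fingerprints displaced from
#' the DMSO composition by at least `shift` percent points (rotating the
#' affected phase among S, G2/M and sub-G1) and the rest sit exactly at the
#' DMSO composition; a viability plate where shifted compounds have low true
#' viability; and 8-point triplicate dose-response series for the shifted
#' compounds with known EC50s.
#'
#' @param n_compounds Total compounds on the plate.
#' @param n_shifted Number with genuinely perturbed cell-cycle truth.
#' @param shift Size of the true fingerprint displacement, percent points
#'   (moved out of G1 into one other phase; Euclidean size is
#'   `shift * sqrt(2)`).
#' @param n_dmso,n_pos Control well counts.
#' @param n_events Cells per cytometry well.
#' @param cv Peak coefficient of variation (cytometry) and readout CV
#'   (viability / dose-response).
#' @param seed Root seed.
#' @return List with `cytometry` ([simulate_plate()] result),
#'   `viability_plate`, `potency` (long dose-response tibble), and `truth`
#'   (list: `fingerprints` in percent, `shifted` compound names, `viability`,
#'   `ec50`).
#' @export
simulate_screen <- function(n_compounds = 96, n_shifted = 20, shift = 20,
                            n_dmso = 16, n_pos = 8, n_events = 5000,
                            cv = 0.05, seed = 1) {
  stopifnot(n_shifted <= n_compounds)
  cmpds <- sprintf("CMPD%03d", seq_len(n_compounds))
  shifted <- cmpds[seq_len(n_shifted)]
  base <- dmso_truth()

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  truth <- purrr::map_dfr(seq_len(n_compounds), function(i) {
    f <- base
    if (i <= n_shifted) {
      target <- c("s", "g2m", "subg1")[(i - 1) %% 3 + 1]
      d <- shift / 100
      f["g1"] <- f["g1"] - d
      f[target] <- f[target] + d
    }
    tibble::tibble(compound = cmpds[i], g1 = f[["g1"]], s = f[["s"]],
                   g2m = f[["g2m"]], subg1 = f[["subg1"]])
  })

  viab <- tibble::tibble(
    compound = cmpds,
    viability = ifelse(cmpds %in% shifted,
                       stats::runif(n_compounds, 0.10, 0.45),
                       stats::runif(n_compounds, 0.92, 1.00))
  )
  ec50 <- stats::setNames(10^stats::runif(n_shifted, -1, log10(15)), shifted)

  map <- plate_map_384(cmpds, n_dmso = n_dmso, n_pos = n_pos)
  cytometry <- simulate_plate(map, truth, cv = cv, n_events = n_events,
                              seed = seed)
  viability_plate <- simulate_viability_plate(map, viab, cv = cv,
                                              seed = seed + 1)
  potency <- tibble::tibble(compound = character(0), dose_uM = numeric(0),
                            replicate = integer(0), response = numeric(0))
  if (n_shifted > 0) {
    potency <- purrr::imap_dfr(ec50, function(e, cmpd) {
      d <- simulate_dose_response(ec50 = e, hill = 1.5, top = 100, bottom = 5,
                                  cv = cv, replicates = 3,
                                  seed = well_seed(seed + 2, cmpd))
      d$compound <- cmpd
      d
    })
  }

  list(
    cytometry = cytometry,
    viability_plate = viability_plate,
    potency = potency[, c("compound", "dose_uM", "replicate", "response")],
    truth = list(
      fingerprints = dplyr::mutate(truth,
                                   dplyr::across(dplyr::all_of(PHASES),
                                                 ~ 100 * .x)),
      shifted = shifted,
      viability = viab,
      ec50 = ec50
    )
  )
}
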