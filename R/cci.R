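# Cell-cycle fingerprints, the Cell Cycle Index (CCI), and hit selection.
#
# A fingerprint is the four phase percentages <G1, S, G2/M, subG1> of one
# compound; the CCI is the Euclidean distance between a compound's
# fingerprint and the DMSO reference fingerprint, on the percent scale.

PHASES <- c("g1", "s", "g2m", "subg1")

check_fingerprints <- function(x, what = "fingerprints") {
  stopifnot(is.data.frame(x))
  miss <- setdiff(PHASES, names(x))
  if (length(miss) > 0) {
    stop(what, " must have columns ", paste(PHASES, collapse = ", "),
         " (missing: ", paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

#' Aggregate DMSO wells into a reference fingerprint
#'
#' The component-wise arithmetic mean of the vehicle-control fingerprints,
#' conventionally computed per plate so plate effects cancel.
#'
#' @param fingerprints Data frame of DMSO-well fingerprints with percent
#'   columns `g1`, `s`, `g2m`, `subg1`.
#' @return One-row tibble with `compound = "DMSO_REF"` and the mean
#'   percentages.
#' @export
dmso_reference <- function(fingerprints) {
  check_fingerprints(fingerprints, "DMSO fingerprints")
  if (nrow(fingerprints) == 0) {
    stop("at least one DMSO fingerprint is required", call. = FALSE)
  }
  tibble::tibble(
    compound = "DMSO_REF",
    g1 = mean(fingerprints$g1),
    s = mean(fingerprints$s),
    g2m = mean(fingerprints$g2m),
    subg1 = mean(fingerprints$subg1)
  )
}

#' Relative fingerprints: drug minus DMSO reference
#'
#' Component-wise signed differences
#' `<RG1, RS, RG2/M, RsG1> = <G1 - G1_0, S - S_0, G2/M - G2/M_0, sG1 - sG1_0>`,
#' where the zero subscript is the DMSO reference point.
#'
#' @param fingerprints Data frame of compound fingerprints (percent columns
#'   `g1`, `s`, `g2m`, `subg1`; other columns are kept).
#' @param ref One-row reference fingerprint (see [dmso_reference()]).
#' @return The input tibble with added columns `rg1`, `rs`, `rg2m`, `rsg1`.
#' @export
relative_fingerprints <- function(fingerprints, ref) {
  check_fingerprints(fingerprints)
  check_fingerprints(ref, "`ref`")
  stopifnot(nrow(ref) == 1)
  dplyr::mutate(
    tibble::as_tibble(fingerprints),
    rg1 = .data$g1 - ref$g1,
    rs = .data$s - ref$s,
    rg2m = .data$g2m - ref$g2m,
    rsg1 = .data$subg1 - ref$subg1
  )
}

#' Cell Cycle Index: Euclidean norm of a relative fingerprint
#'
#' `CCI = sqrt(RG1^2 + RS^2 + RG2M^2 + RsG1^2)`, the magnitude of a
#' compound's cell-cycle perturbation relative to the DMSO control, on the
#' percent scale.
#'
#' @param rel Either a data frame with columns `rg1`, `rs`, `rg2m`, `rsg1`
#'   (e.g. from [relative_fingerprints()]) or a numeric vector of length 4.
#' @return For a data frame input, the tibble with an added `cci` column;
#'   for a numeric vector, the scalar CCI.
#' @export
#' @examples
#' cell_cycle_index(c(3, 4, 0, 0)) # 5
cell_cycle_index <- function(rel) {
  if (is.numeric(rel)) {
    stopifnot(length(rel) == 4)
    return(sqrt(sum(rel^2)))
  }
  stopifnot(is.data.frame(rel))
  miss <- setdiff(c("rg1", "rs", "rg2m", "rsg1"), names(rel))
  if (length(miss) > 0) {
    stop("`rel` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(rel),
    cci = sqrt(.data$rg1^2 + .data$rs^2 + .data$rg2m^2 + .data$rsg1^2)
  )
}

#' Compute CCIs for a fingerprint table against a DMSO reference
#'
#' Convenience wrapper chaining [dmso_reference()] (when `ref` is a multi-row
#' table of DMSO wells), [relative_fingerprints()] and [cell_cycle_index()].
#'
#' @param fingerprints Compound fingerprint table (percent columns).
#' @param ref DMSO reference: a one-row fingerprint, or a table of DMSO-well
#'   fingerprints to be averaged.
#' @return Tibble with `rg1`, `rs`, `rg2m`, `rsg1` and `cci` columns added.
#' @export
compute_cci <- function(fingerprints, ref) {
  if (nrow(ref) > 1) ref <- dmso_reference(ref)
  fingerprints |>
    relative_fingerprints(ref) |>
    cell_cycle_index()
}

#' Select screening hits by CCI cutoff
#'
#' Compounds with `cci` strictly greater than `cutoff`, ordered by descending
#' CCI with alphabetical tie-breaking.
#'
#' @param ccis Data frame with columns `compound` and `cci`.
#' @param cutoff Non-negative CCI threshold (default 10).
#' @return The qualifying rows, sorted.
#' @export
select_hits <- function(ccis, cutoff = 10) {
  stopifnot(is.data.frame(ccis), all(c("compound", "cci") %in% names(ccis)),
            cutoff >= 0)
  ccis |>
    dplyr::filter(.data$cci > cutoff) |>
    dplyr::arrange(dplyr::desc(.data$cci), .data$compound)
}
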